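#' Training configuration
#'
#' @param learning_rate Adam learning rate (default 0.001).
#' @param dropout_rate Dropout rate of the fully connected layer (recorded
#'   here; the rate actually used lives in the model spec).
#' @param batch_size Minibatch size (default 16).
#' @param n_epochs Number of training epochs.
#' @param seed Integer seed (weight init, shuffling, dropout).
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 0.001, dropout_rate = 0.5,
                         batch_size = 16L, n_epochs = 50L, seed = 1L) {
  stopifnot(learning_rate >= 0, batch_size >= 1, n_epochs >= 0)
  structure(list(learning_rate = learning_rate, dropout_rate = dropout_rate,
                 batch_size = as.integer(batch_size),
                 n_epochs = as.integer(n_epochs), seed = as.integer(seed)),
            class = "train_config")
}

adam_init <- function(weights) {
  lapply(weights, function(w) {
    if (is.null(w)) return(NULL)
    lapply(w, function(p) list(m = p * 0, v = p * 0))
  })
}

adam_step <- function(weights, grads, st, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(weights)) {
    if (is.null(grads[[i]])) next
    for (nm in names(grads[[i]])) {
      g <- grads[[i]][[nm]]
      st[[i]][[nm]]$m <- beta1 * st[[i]][[nm]]$m + (1 - beta1) * g
      st[[i]][[nm]]$v <- beta2 * st[[i]][[nm]]$v + (1 - beta2) * g^2
      mhat <- st[[i]][[nm]]$m / (1 - beta1^t)
      vhat <- st[[i]][[nm]]$v / (1 - beta2^t)
      weights[[i]][[nm]] <- weights[[i]][[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(weights = weights, st = st)
}

as_binary_labels <- function(y) {
  if (is.factor(y)) y <- as.character(y)
  if (is.character(y)) y <- as.integer(y == "DYS")
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L))) stop("labels must be binary (0/1 or TYP/DYS)")
  y
}

#' Train a CNN classifier with Adam
#'
#' Minibatch training with cross-entropy loss on the softmax outputs and the
#' Adam optimizer. Deterministic for a fixed seed (fixed initialisation,
#' shuffling and dropout masks).
#'
#' @param spec A `model_spec`.
#' @param config A [train_config()].
#' @param x_train Training batch, `(voxels x N)` matrix or `c(input_shape, N)`
#'   array.
#' @param y_train Binary labels (0/1, or TYP/DYS with DYS = 1).
#' @param x_val,y_val Optional validation data evaluated after each epoch.
#' @param seed Seed override (defaults to `config$seed`).
#' @param verbose Print per-epoch progress.
#' @return A `cnn_fit`: list with the trained `model`, `history` (per-epoch
#'   train/val loss and accuracy), `config` and `seed`.
#' @export
train_cnn <- function(spec, config, x_train, y_train,
                      x_val = NULL, y_val = NULL,
                      seed = config$seed, verbose = FALSE) {
  y_train <- as_binary_labels(y_train)
  n <- length(y_train)
  if (n == 0L) stop("empty training set")
  V <- prod(spec$input_shape)
  x_train <- matrix(as.vector(x_train), V, n)
  model <- cnn_model(spec, seed = derive_seed(seed, 1L))

  old <- set_local_seed(derive_seed(seed, 2L))
  on.exit(restore_seed(old), add = TRUE)

  st <- adam_init(model$weights)
  t_step <- 0L
  hist <- vector("list", config$n_epochs)
  for (epoch in seq_len(config$n_epochs)) {
    perm <- sample.int(n)
    losses <- c(); correct <- 0L
    for (b in seq_len(ceiling(n / config$batch_size))) {
      ids <- perm[((b - 1L) * config$batch_size + 1L):min(b * config$batch_size, n)]
      nb <- length(ids)
      yb <- y_train[ids]
      X <- batch_to_mat(x_train[, ids, drop = FALSE], spec, nb)
      fwd <- nn_forward_mat(model, X, nb, mode = "train", keep_cache = TRUE,
                            update_state = TRUE)
      model <- fwd$model
      probs <- fwd$probs
      loss <- -mean(log(pmax(probs[cbind(yb + 1L, seq_len(nb))], 1e-12)))
      if (!is.finite(loss))
        stop(sprintf("non-finite loss at epoch %d, batch %d", epoch, b))
      losses <- c(losses, loss)
      correct <- correct + sum(max.col(t(probs), ties.method = "first") - 1L == yb)
      onehot <- matrix(0, 2L, nb)
      onehot[cbind(yb + 1L, seq_len(nb))] <- 1
      d_logits <- (probs - onehot) / nb
      bwd <- nn_backward_mat(model, fwd, d_logits, nb)
      t_step <- t_step + 1L
      upd <- adam_step(model$weights, bwd$grads, st,
                       config$learning_rate, t_step)
      model$weights <- upd$weights
      st <- upd$st
    }
    row <- data.frame(epoch = epoch, train_loss = mean(losses),
                      train_acc = 100 * correct / n,
                      val_loss = NA_real_, val_acc = NA_real_)
    if (!is.null(x_val) && length(y_val)) {
      ev <- eval_model(model, x_val, y_val)
      row$val_loss <- ev$loss; row$val_acc <- ev$accuracy
    }
    hist[[epoch]] <- row
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  acc %5.1f%%  val %5.1f%%",
                      epoch, row$train_loss, row$train_acc, row$val_acc))
  }
  structure(list(model = model,
                 history = if (config$n_epochs) do.call(rbind, hist)
                           else data.frame(),
                 config = config, seed = as.integer(seed)),
            class = "cnn_fit")
}

eval_model <- function(model, x, y, batch_size = 32L) {
  y <- as_binary_labels(y)
  n <- length(y)
  if (n == 0L) stop("empty evaluation set")
  V <- prod(model$spec$input_shape)
  x <- matrix(as.vector(x), V, n)
  correct <- 0L; loss_sum <- 0
  for (b in seq_len(ceiling(n / batch_size))) {
    ids <- ((b - 1L) * batch_size + 1L):min(b * batch_size, n)
    nb <- length(ids)
    X <- batch_to_mat(x[, ids, drop = FALSE], model$spec, nb)
    fwd <- nn_forward_mat(model, X, nb, mode = "eval")
    probs <- fwd$probs
    correct <- correct + sum(max.col(t(probs), ties.method = "first") - 1L == y[ids])
    loss_sum <- loss_sum -
      sum(log(pmax(probs[cbind(y[ids] + 1L, seq_len(nb))], 1e-12)))
  }
  list(accuracy = 100 * correct / n, loss = loss_sum / n)
}

#' Evaluate a trained model's accuracy on held-out data
#'
#' Runs in eval mode (no dropout, frozen batch-norm statistics) and reports
#' `100 * correct / n`.
#'
#' @param fit A `cnn_fit` or `cnn_model`.
#' @param x,y Test inputs and binary labels.
#' @return Accuracy in percent.
#' @export
evaluate_cnn <- function(fit, x, y) {
  model <- if (inherits(fit, "cnn_fit")) fit$model else fit
  eval_model(model, x, y)$accuracy
}

#' @export
predict.cnn_fit <- function(object, x, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  V <- prod(object$model$spec$input_shape)
  n <- length(x) %/% V
  x <- matrix(as.vector(x), V, n)
  probs <- matrix(NA_real_, n, 2L,
                  dimnames = list(NULL, c("TYP", "DYS")))
  bs <- 32L
  for (b in seq_len(ceiling(n / bs))) {
    ids <- ((b - 1L) * bs + 1L):min(b * bs, n)
    X <- batch_to_mat(x[, ids, drop = FALSE], object$model$spec, length(ids))
    probs[ids, ] <- t(nn_forward_mat(object$model, X, length(ids))$probs)
  }
  if (type == "prob") probs else c("TYP", "DYS")[max.col(probs, ties.method = "first")]
}

#' @export
print.cnn_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf("CNN fit: %d epochs, final train acc %.1f%%%s\n",
              nrow(h), if (nrow(h)) h$train_acc[nrow(h)] else NA,
              if (nrow(h) && is.finite(h$val_acc[nrow(h)]))
                sprintf(", val acc %.1f%%", h$val_acc[nrow(h)]) else ""))
  invisible(x)
}

#' @export
summary.cnn_fit <- function(object, ...) {
  cat("Model:\n"); print(object$model$spec)
  cat(sprintf("Config: lr %g, batch %d, %d epochs, seed %d\n",
              object$config$learning_rate, object$config$batch_size,
              object$config$n_epochs, object$seed))
  if (nrow(object$history)) {
    cat("History (last 5 epochs):\n")
    print(utils::tail(object$history, 5), row.names = FALSE)
  }
  invisible(object)
}

#' Assemble slice-as-channel training data from a cohort and split
#'
#' Each volume is z-scored within the brain mask and packed with
#' [pack_slices_as_channels()]. Training subjects additionally receive
#' `augment` augmented copies each (Gaussian voxel noise followed by a random
#' global offset, both within the mask); validation and test parts are never
#' augmented, so held-out evaluation stays at the subject level on original
#' volumes.
#'
#' @param cohort A [simulate_cohort()] cohort (or compatible list).
#' @param split A [split_cohort()] assignment.
#' @param axis Channel axis for packing (default `"z"`).
#' @param augment Augmented copies per training subject (default 10).
#' @param noise_sigma,offset_sigma Augmentation SDs relative to the
#'   (z-scored, hence unit) in-mask intensity SD; defaults 0.1.
#' @param seed Integer seed for the augmentation draws.
#' @return List with `train`, `val`, `test` (each `list(x, y, subject_id)`
#'   where `x` is a voxels-by-samples matrix), plus `input_shape` and `axis`.
#' @export
prepare_cnn_data <- function(cohort, split, axis = "z", augment = 10L,
                             noise_sigma = 0.1, offset_sigma = 0.1,
                             seed = 1L) {
  mask <- cohort$geometry$mask
  parts <- split$part[match(cohort$subjects$subject_id, split$subject_id)]
  shp <- NULL
  pack_one <- function(vol) {
    ct <- pack_slices_as_channels(vol, axis)
    if (is.null(shp)) shp <<- dim(ct$data)
    as.vector(ct$data)
  }
  out <- list()
  for (p in c("train", "val", "test")) {
    ids <- which(parts == p)
    cols <- list(); labs <- integer(0); sids <- character(0)
    for (i in ids) {
      v <- zscore_volume(cohort$volumes[[i]], mask)
      cols[[length(cols) + 1L]] <- pack_one(v)
      labs <- c(labs, as.integer(cohort$subjects$group[i] == "DYS"))
      sids <- c(sids, cohort$subjects$subject_id[i])
      if (p == "train" && augment > 0L) {
        for (a in seq_len(augment)) {
          va <- augment_noise(v, noise_sigma, mask = mask,
                              seed = derive_seed(seed, 1000L * i + 2L * a))
          va <- augment_offset(va, offset_sigma, mask = mask,
                               seed = derive_seed(seed, 1000L * i + 2L * a + 1L))
          cols[[length(cols) + 1L]] <- pack_one(va)
          labs <- c(labs, labs[length(labs)])
          sids <- c(sids, cohort$subjects$subject_id[i])
        }
      }
    }
    out[[p]] <- list(x = if (length(cols)) do.call(cbind, cols)
                         else matrix(0, 0, 0),
                     y = labs, subject_id = sids)
  }
  out$input_shape <- shp
  out$axis <- axis
  out
}

#' Per-subject flattened in-mask voxel features
#'
#' @param cohort A cohort.
#' @return `n_subjects x n_voxels` matrix of masked voxel values (rows in
#'   cohort subject order).
#' @export
cohort_features <- function(cohort) {
  mask <- cohort$geometry$mask
  t(vapply(cohort$volumes, function(v) flatten_masked(v, mask),
           numeric(sum(mask != 0))))
}
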