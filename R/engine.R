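# CNN compute engine.
#
# Internal activation layout: convolutional layers carry a (P*N) x C matrix
# (P spatial positions fastest, then the N batch samples; channels as
# columns), so batch-norm statistics are plain colMeans and convolution is a
# single GEMM against an im2col gather. After flatten, activations are
# (features x N). Gather/scatter index vectors are precomputed per layer and
# cached per batch size.

build_plan <- function(spec) {
  shapes <- model_shapes(spec)
  nd <- spec$ndim
  in_spatial <- spec$input_shape[seq_len(nd)]
  in_ch <- spec$input_shape[nd + 1L]
  plans <- vector("list", length(spec$layers))
  for (i in seq_along(spec$layers)) {
    l <- spec$layers[[i]]
    p <- list(kind = l$kind)
    if (l$kind %in% c("conv2d", "conv3d", "maxpool")) {
      clip <- l$kind == "maxpool"
      out_spatial <- vapply(in_spatial, out_size, integer(1),
                            kernel = l$kernel, stride = l$stride, clip = clip)
      m <- cumprod(c(1, in_spatial))[seq_len(nd)]      # axis multipliers
      out_grid <- as.matrix(do.call(expand.grid, lapply(out_spatial, seq_len)))
      base <- 1 + as.vector((out_grid - 1) %*% (l$stride * m))
      off_grid <- as.matrix(do.call(expand.grid,
                                    lapply(rep(l$kernel, nd), function(k) 0:(k - 1))))
      offlin <- as.vector(off_grid %*% m)
      sp <- outer(base, offlin, "+")                   # Pout x K
      if (clip) {
        # NA out members whose window coordinate falls outside the input
        for (a in seq_len(nd)) {
          coord <- outer((out_grid[, a] - 1) * l$stride, off_grid[, a], "+") + 1
          sp[coord > in_spatial[a]] <- NA_real_
        }
      }
      p$Pin <- prod(in_spatial); p$Pout <- prod(out_spatial)
      p$K <- nrow(off_grid); p$Cin <- in_ch
      p$in_spatial <- in_spatial; p$out_spatial <- out_spatial
      if (l$kind == "maxpool") {
        storage.mode(sp) <- "integer"
        p$spi <- sp                        # Pout x K, 1-based, NA = clipped
      } else {
        p$base0 <- as.integer(base - 1)    # 0-based window origins
        p$offlin1 <- as.integer(offlin + 1)  # 1-based kernel tap offsets
        p$Cout <- l$n_filters
      }
    } else if (l$kind == "flatten") {
      p$P <- prod(in_spatial); p$C <- in_ch
    } else if (l$kind == "dense") {
      p$n_in <- in_ch; p$n_out <- l$n_units
    } else if (l$kind == "batchnorm") {
      p$C <- in_ch
    }
    plans[[i]] <- p
    in_spatial <- shapes[[i]]$spatial
    in_ch <- shapes[[i]]$channels
  }
  list(layers = plans, cache = new.env(parent = emptyenv()))
}

he_uniform <- function(n_out, fan_in) {
  lim <- sqrt(6 / fan_in)
  stats::runif(n_out, -lim, lim)
}

init_weights <- function(spec, plan, seed) {
  old <- set_local_seed(derive_seed(seed, 0L))
  on.exit(restore_seed(old), add = TRUE)
  weights <- vector("list", length(spec$layers))
  state <- vector("list", length(spec$layers))
  for (i in seq_along(spec$layers)) {
    l <- spec$layers[[i]]
    p <- plan$layers[[i]]
    if (l$kind %in% c("conv2d", "conv3d")) {
      fan_in <- p$K * p$Cin
      weights[[i]] <- list(
        W = matrix(he_uniform(fan_in * p$Cout, fan_in), fan_in, p$Cout),
        b = numeric(p$Cout))
    } else if (l$kind == "dense") {
      weights[[i]] <- list(
        W = matrix(he_uniform(p$n_in * p$n_out, p$n_in), p$n_in, p$n_out),
        b = numeric(p$n_out))
    } else if (l$kind == "batchnorm") {
      weights[[i]] <- list(gamma = rep(1, p$C), beta = numeric(p$C))
      state[[i]] <- list(mean = numeric(p$C), var = rep(1, p$C))
    }
  }
  list(weights = weights, state = state)
}

#' Instantiate a CNN model with freshly initialised weights
#'
#' Convolution and dense weights use He-uniform initialisation; batch-norm
#' scale/shift start at 1/0 and its running statistics (exponential moving
#' average, momentum 0.9) at 0/1.
#'
#' @param spec A `model_spec`.
#' @param seed Integer seed fixing the initialisation.
#' @return A `cnn_model` object (spec, weights, batch-norm state).
#' @export
cnn_model <- function(spec, seed = 1L) {
  validate_model_spec(spec)
  plan <- build_plan(spec)
  ws <- init_weights(spec, plan, seed)
  structure(list(spec = spec, plan = plan, weights = ws$weights,
                 state = ws$state, seed = as.integer(seed)),
            class = "cnn_model")
}

#' @export
print.cnn_model <- function(x, ...) {
  cat("CNN model (seed", x$seed, "):\n")
  print(x$spec)
  invisible(x)
}

.bn_momentum <- 0.9
.bn_eps <- 1e-5

# X: layout described above; N: batch size. Returns probs, logits and
# per-layer caches sufficient for the backward pass.
nn_forward_mat <- function(model, X, N, mode = "eval", keep_cache = FALSE,
                           update_state = FALSE) {
  spec <- model$spec; plan <- model$plan
  caches <- if (keep_cache) vector("list", length(spec$layers)) else NULL
  logits <- NULL
  for (i in seq_along(spec$layers)) {
    l <- spec$layers[[i]]
    p <- plan$layers[[i]]
    if (l$kind %in% c("conv2d", "conv3d")) {
      Xc <- nc_im2col(X, p$base0, p$offlin1, p$Pin, N, p$Cin)
      dim(Xc) <- c(p$Pout * N, p$K * p$Cin)
      Y <- Xc %*% model$weights[[i]]$W
      Y <- Y + rep(model$weights[[i]]$b, each = p$Pout * N)
      if (keep_cache) caches[[i]] <- list(Xc = Xc)
      X <- Y
    } else if (l$kind == "maxpool") {
      mp <- nc_maxpool(X, p$spi, p$Pin, N)
      if (keep_cache) caches[[i]] <- list(arg = mp$arg)
      X <- mp$m
    } else if (l$kind == "batchnorm") {
      w <- model$weights[[i]]
      if (mode == "train") {
        mu <- colMeans(X)
        v <- colMeans(X^2) - mu^2
        if (update_state) {
          st <- model$state[[i]]
          model$state[[i]]$mean <- .bn_momentum * st$mean + (1 - .bn_momentum) * mu
          model$state[[i]]$var <- .bn_momentum * st$var + (1 - .bn_momentum) * v
        }
      } else {
        mu <- model$state[[i]]$mean
        v <- model$state[[i]]$var
      }
      invstd <- 1 / sqrt(v + .bn_eps)
      xhat <- sweep(sweep(X, 2, mu), 2, invstd, "*")
      Y <- sweep(sweep(xhat, 2, w$gamma, "*"), 2, w$beta, "+")
      if (keep_cache) caches[[i]] <- list(xhat = xhat, invstd = invstd,
                                          mode = mode)
      X <- Y
    } else if (l$kind == "relu") {
      X <- pmax(X, 0)
      if (keep_cache) caches[[i]] <- list(Y = X)
    } else if (l$kind == "flatten") {
      X <- matrix(aperm(array(X, c(p$P, N, p$C)), c(1, 3, 2)), p$P * p$C, N)
    } else if (l$kind == "dense") {
      w <- model$weights[[i]]
      if (keep_cache) caches[[i]] <- list(X = X)
      X <- crossprod(w$W, X) + w$b
    } else if (l$kind == "dropout") {
      if (mode == "train" && l$rate > 0) {
        keep <- matrix(stats::runif(length(X)) >= l$rate, nrow(X), ncol(X))
        X <- X * keep / (1 - l$rate)
        if (keep_cache) caches[[i]] <- list(keep = keep)
      }
    } else if (l$kind == "softmax") {
      logits <- X
      e <- exp(sweep(X, 2, apply(X, 2, max)))
      X <- sweep(e, 2, colSums(e), "/")
    }
  }
  list(probs = X, logits = logits, caches = caches, model = model)
}

# Backward pass. d_out is the gradient w.r.t. the pre-softmax logits.
# If stop_at is a layer index, returns the gradient w.r.t. that layer's
# output without descending further (no parameter gradients accumulated
# below). guided = TRUE applies the guided-backpropagation rule at every
# ReLU: the signal is zeroed where the forward activation <= 0 *or* the
# incoming backward signal <= 0.
nn_backward_mat <- function(model, fwd, d_out, N, guided = FALSE,
                            stop_at = NULL, want_grads = TRUE) {
  spec <- model$spec; plan <- model$plan
  caches <- fwd$caches
  grads <- if (want_grads) vector("list", length(spec$layers)) else NULL
  kinds <- vapply(spec$layers, `[[`, "", "kind")
  start <- max(which(kinds == "softmax")) - 1L
  dY <- d_out
  for (i in seq(start, 1L)) {
    if (!is.null(stop_at) && i == stop_at)
      return(list(d_layer = dY, grads = grads))
    l <- spec$layers[[i]]
    p <- plan$layers[[i]]
    cc <- caches[[i]]
    if (l$kind %in% c("conv2d", "conv3d")) {
      if (want_grads)
        grads[[i]] <- list(W = crossprod(cc$Xc, dY), b = colSums(dY))
      dXc <- tcrossprod(dY, model$weights[[i]]$W)
      dY <- nc_col2im(dXc, p$base0, p$offlin1, p$Pin, N, p$Cin)
      dim(dY) <- c(p$Pin * N, p$Cin)
    } else if (l$kind == "maxpool") {
      dY <- nc_maxpool_backward(dY, cc$arg, p$Pin * N)
    } else if (l$kind == "batchnorm") {
      w <- model$weights[[i]]
      if (want_grads)
        grads[[i]] <- list(gamma = colSums(dY * cc$xhat), beta = colSums(dY))
      if (cc$mode == "train") {
        m <- nrow(dY)
        dxhat <- sweep(dY, 2, w$gamma, "*")
        dY <- sweep(dxhat - rep(colMeans(dxhat), each = m) -
                      cc$xhat * rep(colMeans(dxhat * cc$xhat), each = m),
                    2, cc$invstd, "*")
      } else {
        dY <- sweep(dY, 2, w$gamma * cc$invstd, "*")
      }
    } else if (l$kind == "relu") {
      dY <- dY * (cc$Y > 0)
      if (guided) dY <- dY * (dY > 0)
    } else if (l$kind == "flatten") {
      dY <- matrix(aperm(array(dY, c(p$P, p$C, N)), c(1, 3, 2)), p$P * N, p$C)
    } else if (l$kind == "dense") {
      if (want_grads)
        grads[[i]] <- list(W = tcrossprod(cc$X, dY), b = rowSums(dY))
      dY <- model$weights[[i]]$W %*% dY
    } else if (l$kind == "dropout") {
      if (!is.null(cc)) dY <- dY * cc$keep / (1 - l$rate)
    }
  }
  list(d_input = dY, grads = grads)
}

# Resume the forward pass with an injected activation A standing in for the
# output of layer `layer_index` (used by finite-difference test oracles).
nn_forward_from <- function(model, layer_index, A, N, mode = "eval") {
  spec <- model$spec; plan <- model$plan
  X <- A
  for (i in seq(layer_index + 1L, length(spec$layers))) {
    l <- spec$layers[[i]]
    p <- plan$layers[[i]]
    if (l$kind %in% c("conv2d", "conv3d")) {
      Xc <- nc_im2col(X, p$base0, p$offlin1, p$Pin, N, p$Cin)
      dim(Xc) <- c(p$Pout * N, p$K * p$Cin)
      X <- Xc %*% model$weights[[i]]$W +
        rep(model$weights[[i]]$b, each = p$Pout * N)
    } else if (l$kind == "maxpool") {
      X <- nc_maxpool(X, p$spi, p$Pin, N)$m
    } else if (l$kind == "batchnorm") {
      w <- model$weights[[i]]
      invstd <- 1 / sqrt(model$state[[i]]$var + .bn_eps)
      X <- sweep(sweep(sweep(X, 2, model$state[[i]]$mean), 2, invstd, "*"),
                 2, w$gamma, "*")
      X <- sweep(X, 2, w$beta, "+")
    } else if (l$kind == "relu") {
      X <- pmax(X, 0)
    } else if (l$kind == "flatten") {
      X <- matrix(aperm(array(X, c(p$P, N, p$C)), c(1, 3, 2)), p$P * p$C, N)
    } else if (l$kind == "dense") {
      w <- model$weights[[i]]
      X <- crossprod(w$W, X) + w$b
    } else if (l$kind == "softmax") {
      logits <- X
      e <- exp(sweep(X, 2, apply(X, 2, max)))
      return(list(probs = sweep(e, 2, colSums(e), "/"), logits = logits))
    }
  }
  list(probs = X, logits = NULL)
}

# Convert a batch given as (spatial..., C, N) array or (V x N) matrix into the
# engine's (S*N) x C layout.
batch_to_mat <- function(x, spec, N) {
  nd <- spec$ndim
  S <- prod(spec$input_shape[seq_len(nd)])
  C <- spec$input_shape[nd + 1L]
  if (is.matrix(x) && !is.null(dim(x)) && nrow(x) == S * C) {
    v <- x
  } else {
    v <- matrix(as.vector(x), S * C, N)
  }
  matrix(aperm(array(v, c(S, C, N)), c(1, 3, 2)), S * N, C)
}

mat_to_batch <- function(M, spec, N) {
  nd <- spec$ndim
  S <- prod(spec$input_shape[seq_len(nd)])
  C <- spec$input_shape[nd + 1L]
  array(aperm(array(M, c(S, N, C)), c(1, 3, 2)),
        dim = c(spec$input_shape, N))
}

#' Run a CNN forward pass
#'
#' Propagates a batch through the model and returns class probabilities;
#' with `cache = TRUE` the per-layer activations (and, through
#' [nn_backward_mat] internally, gradients of any class score with respect to
#' any convolutional layer's feature maps) are retrievable, which is the
#' access contract the Grad-CAM explainer relies on.
#'
#' @param model A [cnn_model()].
#' @param x Input batch: array `c(input_shape, N)`, a single `c(input_shape)`
#'   array, or a `(voxels x N)` matrix in array order.
#' @param mode `"eval"` (deterministic; dropout off, frozen batch-norm) or
#'   `"train"`.
#' @param cache Keep per-layer activations for explanation/backprop.
#' @return List with `probs` (N x n_classes matrix, rows summing to 1),
#'   `logits`, and (if requested) the layer caches.
#' @export
cnn_forward <- function(model, x, mode = c("eval", "train"), cache = FALSE) {
  mode <- match.arg(mode)
  spec <- model$spec
  V <- prod(spec$input_shape)
  n_el <- length(if (is.list(x)) stop("'x' must be an array or matrix") else x)
  if (n_el %% V != 0) stop("input shape does not match model input_shape")
  N <- n_el %/% V
  X <- batch_to_mat(x, spec, N)
  fwd <- nn_forward_mat(model, X, N, mode = mode, keep_cache = cache)
  out <- list(probs = t(fwd$probs), logits = t(fwd$logits), n = N)
  if (cache) out$fwd <- fwd
  out
}
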