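#' Linear SVM voxel baseline
#'
#' Trains a linear-kernel maximum-margin classifier on flattened in-mask
#' voxel features. Features are standardised per voxel using training-set
#' statistics; the cost parameter is chosen by exhaustive search over
#' `c_grid`, scored on the validation part (training accuracy when the split
#' has no validation part), ties going to the smaller C.
#'
#' @param features `n_subjects x n_voxels` matrix (see [cohort_features()]).
#' @param labels Binary labels (0/1 or TYP/DYS), one per row.
#' @param split Character vector of parts (`train`/`val`/`test`) per row, or
#'   a [split_cohort()] data.frame aligned with the rows.
#' @param c_grid Candidate cost values (default `c(0.01, 0.1, 1, 10, 100)`).
#' @param seed Integer seed (e1071 uses none for deterministic linear fits,
#'   recorded for provenance).
#' @return A `run_result`: technique, test accuracy (%), `n_test`, the
#'   per-C validation history, selected cost and seed.
#' @export
train_svm_baseline <- function(features, labels, split,
                               c_grid = c(0.01, 0.1, 1, 10, 100), seed = 1L) {
  labels <- as_binary_labels(labels)
  parts <- if (is.data.frame(split)) split$part else split
  stopifnot(length(parts) == nrow(features), length(labels) == nrow(features))
  tr <- parts == "train"; va <- parts == "val"; te <- parts == "test"
  if (length(unique(labels[tr])) < 2L)
    stop("training part must contain both classes")

  mu <- colMeans(features[tr, , drop = FALSE])
  sdv <- apply(features[tr, , drop = FALSE], 2, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  std <- sweep(sweep(features, 2, mu), 2, sdv, "/")
  ytr <- factor(labels[tr], levels = c(0L, 1L))

  acc_of <- function(fit, rows) {
    if (!any(rows)) return(NA_real_)
    pred <- stats::predict(fit, std[rows, , drop = FALSE])
    100 * mean(as.integer(as.character(pred)) == labels[rows])
  }
  fits <- lapply(c_grid, function(C)
    e1071::svm(std[tr, , drop = FALSE], ytr, kernel = "linear", cost = C,
               scale = FALSE))
  val_acc <- vapply(seq_along(fits), function(j)
    acc_of(fits[[j]], if (any(va)) va else tr), numeric(1))
  best <- which.max(val_acc)          # first max: ties go to smaller C
  fit <- fits[[best]]

  structure(list(technique = "SVM", accuracy = acc_of(fit, te),
                 n_test = sum(te),
                 history = data.frame(C = c_grid, val_accuracy = val_acc),
                 config = list(c_grid = c_grid, C = c_grid[best]),
                 seed = as.integer(seed), fit = fit,
                 standardize = list(mean = mu, sd = sdv)),
            class = "run_result")
}

#' @export
print.run_result <- function(x, ...) {
  cat(sprintf("%s: %.2f%% test accuracy (n_test = %d)\n",
              x$technique, x$accuracy, x$n_test))
  invisible(x)
}

#' Bundle named run results into a ranked results table
#'
#' @param results List of `run_result` objects (or any lists with `technique`
#'   and `accuracy`).
#' @return A `results_table` data.frame with columns `technique` and
#'   `accuracy`, sorted by descending accuracy; ties are broken by technique
#'   name so the ordering is stable.
#' @export
make_results_table <- function(results) {
  if (length(results) < 1L) stop("need at least one result")
  df <- data.frame(
    technique = vapply(results, `[[`, "", "technique"),
    accuracy = vapply(results, function(r) as.numeric(r$accuracy), numeric(1)),
    stringsAsFactors = FALSE)
  df <- df[order(-df$accuracy, df$technique), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("results_table", "data.frame"))
}

#' @export
print.results_table <- function(x, ...) {
  cat("Technique                     Accuracy (%)\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("%-30s %10.2f\n", x$technique[i], x$accuracy[i]))
  invisible(x)
}

#' Run the reference phantom classification experiment
#'
#' End-to-end protocol used for benchmarking the pinned 2D CNN on synthetic
#' data: simulate a two-group cohort with a group effect injected into
#' designated parcels, split it 80/10/10 stratified by group, train the
#' modified LeNet-5 on the (augmented) training part, and report held-out
#' subject-level test accuracy. Optionally fits the linear SVM baseline on
#' the identical split.
#'
#' @param seed Integer seed driving every stochastic step.
#' @param shape Volume shape (default `c(32, 32, 16)`).
#' @param n_regions Number of parcels (default 10).
#' @param target_labels Parcels carrying the group effect (default `1:4`).
#' @param amplitude Effect size in noise-SD units (default 3).
#' @param n_per_group Subjects per group (default 100).
#' @param n_epochs,learning_rate,batch_size,dropout Training hyperparameters
#'   (defaults 25, 0.001, 16, 0.5).
#' @param augment Augmented copies per training subject (default 10).
#' @param fractions Split fractions (default `c(0.8, 0.1, 0.1)`).
#' @param with_svm Also fit the SVM baseline (default FALSE).
#' @param keep_cohort Keep the cohort and geometry in the result (needed for
#'   downstream explanation; default TRUE).
#' @param verbose Print training progress.
#' @return List with `accuracy` (% on the test part), `n_test`, `fit`,
#'   `svm` (a `run_result` or NULL), `split`, `data`, `cohort`, `geometry`.
#' @export
run_phantom_experiment <- function(seed = 42L, shape = c(32L, 32L, 16L),
                                   n_regions = 10L, target_labels = 1:4,
                                   amplitude = 3, n_per_group = 100L,
                                   n_epochs = 25L, learning_rate = 0.001,
                                   batch_size = 16L, dropout = 0.5,
                                   augment = 10L,
                                   fractions = c(0.8, 0.1, 0.1),
                                   with_svm = FALSE, keep_cohort = TRUE,
                                   verbose = FALSE) {
  geometry <- make_brain_geometry(shape, n_regions, seed = derive_seed(seed, 101L))
  effect <- effect_spec(target_labels, amplitude)
  cohort <- simulate_cohort(geometry, n_per_group, effect,
                            seed = derive_seed(seed, 1L))
  split <- split_cohort(cohort, fractions, stratify_by_group = TRUE,
                        seed = derive_seed(seed, 2L))
  data <- prepare_cnn_data(cohort, split, augment = augment,
                           seed = derive_seed(seed, 3L))
  spec <- build_modified_lenet5(data$input_shape, dropout = dropout)
  config <- train_config(learning_rate = learning_rate,
                         batch_size = batch_size, n_epochs = n_epochs,
                         dropout_rate = dropout, seed = derive_seed(seed, 4L))
  fit <- train_cnn(spec, config, data$train$x, data$train$y,
                   data$val$x, data$val$y, verbose = verbose)
  accuracy <- evaluate_cnn(fit, data$test$x, data$test$y)

  svm_res <- NULL
  if (with_svm) {
    feats <- cohort_features(cohort)
    parts <- split$part[match(cohort$subjects$subject_id, split$subject_id)]
    svm_res <- train_svm_baseline(feats,
                                  cohort$subjects$group, parts,
                                  seed = derive_seed(seed, 5L))
  }
  out <- list(accuracy = accuracy, n_test = length(data$test$y), fit = fit,
              svm = svm_res, split = split, data = data)
  if (keep_cohort) {
    out$cohort <- cohort
    out$geometry <- geometry
  }
  out
}
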