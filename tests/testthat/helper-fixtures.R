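# Shared fixtures and independent oracles for the test suite.

# small two-conv-block model for gradient checks
toy_spec <- function(input_shape = c(8, 8, 3), filters = c(4, 4),
                     fc_units = 5, dropout = 0.5) {
  layers <- list()
  for (i in seq_along(filters)) {
    layers <- c(layers, list(
      neurocam:::layer_conv(3L, 1L, filters[i], name = paste0("conv", i)),
      neurocam:::layer_batchnorm(), neurocam:::layer_relu()))
    if (i == 1) layers <- c(layers, list(neurocam:::layer_maxpool(2L, 2L)))
  }
  layers <- c(layers, list(neurocam:::layer_flatten(),
                           neurocam:::layer_dense(fc_units),
                           neurocam:::layer_dropout(dropout),
                           neurocam:::layer_dense(2L),
                           neurocam:::layer_softmax()))
  neurocam:::new_model_spec(layers, input_shape)
}

# central finite difference of the class-1 logit w.r.t. selected input voxels
fd_input_gradient <- function(model, x, voxels, eps = 1e-5, class_index = 1L) {
  spec <- model$spec
  f <- function(xv) {
    X <- neurocam:::batch_to_mat(array(xv, dim = spec$input_shape), spec, 1L)
    neurocam:::nn_forward_mat(model, X, 1L)$logits[class_index + 1L, 1L]
  }
  xv <- as.vector(x)
  vapply(voxels, function(j) {
    xp <- xv; xm <- xv
    xp[j] <- xp[j] + eps; xm[j] <- xm[j] - eps
    (f(xp) - f(xm)) / (2 * eps)
  }, numeric(1))
}

# finite-difference Grad-CAM alpha weights: perturb the rectified feature
# maps of the conv block directly and average the score gradient over space
fd_alphas <- function(model, x, relu_index, eps = 1e-5, class_index = 1L) {
  spec <- model$spec
  X <- neurocam:::batch_to_mat(x, spec, 1L)
  fwd <- neurocam:::nn_forward_mat(model, X, 1L, keep_cache = TRUE)
  A <- fwd$caches[[relu_index]]$Y
  f <- function(Amat)
    neurocam:::nn_forward_from(model, relu_index, Amat,
                               1L)$logits[class_index + 1L, 1L]
  vapply(seq_len(ncol(A)), function(k) {
    g <- vapply(seq_len(nrow(A)), function(p) {
      Ap <- A; Am <- A
      Ap[p, k] <- Ap[p, k] + eps; Am[p, k] <- Am[p, k] - eps
      (f(Ap) - f(Am)) / (2 * eps)
    }, numeric(1))
    mean(g)
  }, numeric(1))
}

# brute-force flood fill, 26-connectivity: independent oracle for
# connected_clusters(); plain per-voxel stack walk over array coordinates
floodfill_components <- function(binary_map) {
  dims <- dim(binary_map)
  lab <- array(0L, dim = dims)
  nxt <- 0L
  sizes <- integer(0)
  for (x in seq_len(dims[1])) for (y in seq_len(dims[2]))
    for (z in seq_len(dims[3])) {
      if (binary_map[x, y, z] == 0 || lab[x, y, z] != 0L) next
      nxt <- nxt + 1L
      stack <- list(c(x, y, z))
      lab[x, y, z] <- nxt
      n <- 0L
      while (length(stack)) {
        c0 <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        n <- n + 1L
        for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
          if (dx == 0 && dy == 0 && dz == 0) next
          p <- c0 + c(dx, dy, dz)
          if (any(p < 1) || any(p > dims)) next
          if (binary_map[p[1], p[2], p[3]] != 0 &&
              lab[p[1], p[2], p[3]] == 0L) {
            lab[p[1], p[2], p[3]] <- nxt
            stack[[length(stack) + 1L]] <- p
          }
        }
      }
      sizes <- c(sizes, n)
    }
  list(labels = lab, sizes = sizes)
}

# closed-form mean of a normal truncated to [lo, hi]
truncnorm_mean <- function(mu, sd, lo, hi) {
  a <- (lo - mu) / sd; b <- (hi - mu) / sd
  mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / (stats::pnorm(b) - stats::pnorm(a))
}

# sample of size n with exactly the given mean and sd
sample_with_summary <- function(n, mean, sd) {
  z <- stats::rnorm(n)
  z <- as.vector(scale(z))
  mean + sd * z
}
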