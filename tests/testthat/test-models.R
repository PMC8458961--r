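test_that("pinned modified LeNet-5 has the expected structure", {
  spec <- build_modified_lenet5(c(60, 73, 60))
  kinds <- vapply(spec$layers, `[[`, "", "kind")
  convs <- spec$layers[kinds == "conv2d"]
  expect_length(convs, 3L)
  expect_identical(vapply(convs, `[[`, integer(1), "n_filters"),
                   c(16L, 32L, 64L))
  expect_true(all(vapply(convs, `[[`, integer(1), "kernel") == 5L))
  # each conv is followed by batchnorm, relu, maxpool
  expect_identical(kinds[1:4], c("conv2d", "batchnorm", "relu", "maxpool"))
  drop <- spec$layers[kinds == "dropout"][[1]]
  expect_identical(drop$rate, 0.5)
  expect_identical(kinds[(length(kinds) - 3):length(kinds)],
                   c("dense", "dropout", "dense", "softmax"))
  expect_identical(spec$layers[[length(spec$layers) - 1L]]$n_units, 2L)
})

test_that("parameter counts match independent per-layer arithmetic", {
  # dense 4 -> 2 (+2 bias): input (1,1,4), flatten -> dense(2) -> softmax
  small <- neurocam:::new_model_spec(
    list(neurocam:::layer_flatten(), neurocam:::layer_dense(2L),
         neurocam:::layer_softmax()), c(1L, 1L, 4L))
  expect_identical(count_params(small), 10L)

  # single 5x5 conv, 60 -> 16 channels: 5*5*60*16 + 16 = 24016, plus the
  # head on the 4x4x16 conv output
  one_conv <- neurocam:::new_model_spec(
    list(neurocam:::layer_conv(5L, 1L, 16L), neurocam:::layer_flatten(),
         neurocam:::layer_dense(2L), neurocam:::layer_softmax()),
    c(8L, 8L, 60L))
  expect_identical(count_params(one_conv),
                   as.integer(5 * 5 * 60 * 16 + 16 + (4 * 4 * 16 * 2 + 2)))

  # empty layer list
  empty <- structure(list(layers = list(), input_shape = c(2L, 2L, 1L),
                          ndim = 2L, n_classes = 2L), class = "model_spec")
  expect_identical(count_params(empty), 0L)
})

test_that("the pinned model's size matches a hand count and the published scale", {
  # independent oracle: accumulate layer by layer for a 60x73 input with 60
  # slice channels, 5x5 valid convs, 2x2/2 pools with floor semantics
  shapes <- list(c(60, 73)); ch <- 60
  filt <- c(16, 32, 64); total <- 0
  for (i in 1:3) {
    s <- shapes[[length(shapes)]] - 4          # 5x5 valid conv
    total <- total + 5 * 5 * ch * filt[i] + filt[i]  # conv weights + bias
    total <- total + 2 * filt[i]               # batchnorm scale + shift
    ch <- filt[i]
    s <- floor(s / 2)                          # 2x2 max pool, stride 2
    shapes[[length(shapes) + 1]] <- s
  }
  flat <- prod(shapes[[length(shapes)]]) * ch
  total <- total + flat * 64 + 64              # fc
  total <- total + 64 * 2 + 2                  # logits

  spec <- build_modified_lenet5(c(60, 73, 60))
  expect_identical(count_params(spec), as.integer(total))
  expect_gte(count_params(spec), 150000L)
  expect_lte(count_params(spec), 200000L)
})

test_that("3D conversion preserves structure, extends kernels isotropically and grows the count", {
  spec2 <- build_modified_lenet5(c(60, 73, 60))
  spec3 <- to_3d(spec2)
  kinds2 <- vapply(spec2$layers, `[[`, "", "kind")
  kinds3 <- vapply(spec3$layers, `[[`, "", "kind")
  expect_identical(sum(kinds3 == "conv3d"), 3L)
  expect_identical(kinds3[kinds2 == "conv2d"], rep("conv3d", 3))
  expect_identical(kinds3[!kinds2 %in% "conv2d"], kinds2[!kinds2 %in% "conv2d"])
  expect_identical(spec3$input_shape, c(60L, 73L, 60L, 1L))
  k2 <- vapply(spec2$layers[kinds2 == "conv2d"], `[[`, integer(1), "kernel")
  k3 <- vapply(spec3$layers[kinds3 == "conv3d"], `[[`, integer(1), "kernel")
  expect_identical(k3, k2)                    # k x k -> k x k x k
  expect_gt(count_params(spec3), count_params(spec2))
  expect_error(to_3d(spec3), "not a 2D model")
})

test_that("specs whose spatial dimensions collapse are rejected naming the layer", {
  expect_error(build_modified_lenet5(c(20, 20, 4)), "collapses")
  expect_error(build_modified_lenet5(c(20, 40, 4)), "conv2d")
})

test_that("forward pass yields normalised probabilities, deterministically in eval mode", {
  spec <- toy_spec()
  m <- cnn_model(spec, seed = 4)
  set.seed(2)
  x <- array(rnorm(8 * 8 * 3 * 200), c(8, 8, 3, 200))
  out <- cnn_forward(m, x)
  expect_identical(dim(out$probs), c(200L, 2L))
  expect_true(all(out$probs >= 0 & out$probs <= 1))
  expect_true(all(abs(rowSums(out$probs) - 1) < 1e-6))
  expect_identical(cnn_forward(m, x)$probs, out$probs)
  expect_error(cnn_forward(m, array(0, c(4, 4, 3))), "shape")
})

test_that("backward gradients match central finite differences on a toy model", {
  spec <- toy_spec(filters = c(4, 4))
  m <- cnn_model(spec, seed = 2)
  set.seed(7)
  x <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
  X <- neurocam:::batch_to_mat(x, spec, 1L)
  fwd <- neurocam:::nn_forward_mat(m, X, 1L, keep_cache = TRUE)
  bwd <- neurocam:::nn_backward_mat(m, fwd, matrix(c(0, 1), 2, 1), 1L)

  voxels <- sample(length(x), 25)
  gan <- as.vector(neurocam:::mat_to_batch(bwd$d_input, spec, 1L))[voxels]
  gfd <- fd_input_gradient(m, x, voxels)
  expect_lt(max(abs(gan - gfd) / pmax(abs(gfd), 1e-6)), 1e-4)

  # conv weight gradients, second conv block (layer 5)
  W <- m$weights[[5]]$W
  ij <- cbind(sample(nrow(W), 8, TRUE), sample(ncol(W), 8, TRUE))
  f_w <- function(mm) neurocam:::nn_forward_mat(mm, X, 1L)$logits[2, 1]
  for (r in seq_len(nrow(ij))) {
    e <- 1e-5
    mp <- m; mp$weights[[5]]$W[ij[r, 1], ij[r, 2]] <- W[ij[r, 1], ij[r, 2]] + e
    mn <- m; mn$weights[[5]]$W[ij[r, 1], ij[r, 2]] <- W[ij[r, 1], ij[r, 2]] - e
    fd <- (f_w(mp) - f_w(mn)) / (2 * e)
    expect_lt(abs(fd - bwd$grads[[5]]$W[ij[r, 1], ij[r, 2]]),
              1e-4 * max(1, abs(fd)))
  }
})

test_that("spec JSON serialisation round-trips", {
  spec <- build_modified_lenet5(c(32, 32, 16), fc_units = 128L, dropout = 0.1)
  path <- tempfile(fileext = ".json")
  write_model_spec(spec, path)
  spec2 <- read_model_spec(path)
  expect_identical(count_params(spec2), count_params(spec))
  expect_identical(vapply(spec2$layers, `[[`, "", "kind"),
                   vapply(spec$layers, `[[`, "", "kind"))
  unlink(path)
})
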