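test_that("Grad-CAM reduces to the rectified feature map when the score is its spatial mean", {
  # one 1x1 conv filter, identity-ish head: class-1 logit = mean(relu(conv(x)))
  spec <- neurocam:::new_model_spec(
    list(neurocam:::layer_conv(1L, 1L, 1L, name = "conv1"),
         neurocam:::layer_relu(),
         neurocam:::layer_flatten(),
         neurocam:::layer_dense(2L),
         neurocam:::layer_softmax()), c(6L, 6L, 1L))
  m <- cnn_model(spec, seed = 1)
  P <- 36
  m$weights[[1]]$W <- matrix(1, 1, 1); m$weights[[1]]$b <- 0
  m$weights[[4]]$W <- cbind(rep(0, P), rep(1 / P, P))
  m$weights[[4]]$b <- c(0, 0)
  set.seed(3)
  x <- array(rnorm(36), c(6, 6, 1))
  gc <- gradcam(m, x, class_index = 1, layer = "last")
  A <- pmax(x[, , 1], 0)
  expect_equal(gc$alphas, 1 / P, tolerance = 1e-12)
  expect_equal(gc$map, A / P, tolerance = 1e-12)
  expect_identical(dim(gc$upsampled), dim(gc$map))  # same resolution here
})

test_that("Grad-CAM alpha weights match finite differences on a random 2-conv model", {
  spec <- toy_spec(filters = c(4, 5))
  m <- cnn_model(spec, seed = 6)
  set.seed(8)
  x <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
  # finite differences are only valid away from max-pool tie points, so the
  # FD comparison targets the final conv block (no pooling after it)
  loc <- neurocam:::resolve_conv_layer(spec, "last")
  gc <- gradcam(m, x, class_index = 1, layer = "last")
  afd <- fd_alphas(m, x, loc$relu)
  expect_lt(max(abs(gc$alphas - afd) / pmax(abs(afd), 1e-6)), 1e-4)
  for (layer in c(1, 2)) {
    gcl <- gradcam(m, x, class_index = 1, layer = layer)
    expect_true(all(gcl$map >= 0))
    expect_identical(dim(gcl$upsampled), c(8L, 8L))
  }
  expect_error(gradcam(m, x, layer = "conv9"), "available conv layers")
})

test_that("an all-zero input to a bias-free network yields an all-zero map", {
  spec <- neurocam:::new_model_spec(
    list(neurocam:::layer_conv(3L, 1L, 2L, name = "conv1"),
         neurocam:::layer_relu(), neurocam:::layer_flatten(),
         neurocam:::layer_dense(2L), neurocam:::layer_softmax()),
    c(6L, 6L, 2L))
  m <- cnn_model(spec, seed = 2)
  m$weights[[1]]$b <- c(0, 0)
  m$weights[[4]]$b <- c(0, 0)
  gc <- gradcam(m, array(0, c(6, 6, 2)), class_index = 1)
  expect_true(all(gc$map == 0))
  expect_true(all(gc$upsampled == 0))
})

test_that("guided backprop equals the vanilla gradient when nothing is masked", {
  # all-positive weights and inputs keep every activation and every backward
  # signal positive, so the guided rule never fires
  spec <- neurocam:::new_model_spec(
    list(neurocam:::layer_conv(3L, 1L, 3L, name = "conv1"),
         neurocam:::layer_relu(), neurocam:::layer_maxpool(2L, 2L),
         neurocam:::layer_flatten(), neurocam:::layer_dense(2L),
         neurocam:::layer_softmax()), c(8L, 8L, 2L))
  m <- cnn_model(spec, seed = 3)
  m$weights[[1]]$W <- abs(m$weights[[1]]$W); m$weights[[1]]$b <- c(1, 1, 1)
  m$weights[[5]]$W <- abs(m$weights[[5]]$W); m$weights[[5]]$b <- c(0, 0)
  set.seed(4)
  x <- array(runif(8 * 8 * 2, 0.1, 1), c(8, 8, 2))
  gb <- guided_backprop(m, x, class_index = 1)
  vanilla <- neurocam:::input_gradient(m, x, class_index = 1)
  expect_equal(gb$data, vanilla, tolerance = 1e-12)
  expect_identical(dim(gb$data), c(8L, 8L, 2L))

  # and the vanilla gradient itself is exact (finite differences)
  voxels <- sample(length(x), 10)
  gfd <- fd_input_gradient(m, x, voxels)
  expect_lt(max(abs(as.vector(vanilla)[voxels] - gfd) / pmax(abs(gfd), 1e-6)),
            1e-4)
})

test_that("guided backprop zeroes the contribution of a negative pre-activation unit", {
  # hand-built two-layer net on 2 inputs: h = relu(W1 x), score = w2 . h
  spec <- neurocam:::new_model_spec(
    list(neurocam:::layer_flatten(), neurocam:::layer_dense(2L),
         neurocam:::layer_relu(), neurocam:::layer_dense(2L),
         neurocam:::layer_softmax()), c(1L, 1L, 2L))
  m <- cnn_model(spec, seed = 1)
  W1 <- matrix(c(1, 2, -1, 1), 2, 2)    # columns are the two hidden units
  w2 <- c(3, 4)
  m$weights[[2]]$W <- W1; m$weights[[2]]$b <- c(0, 0)
  m$weights[[4]]$W <- cbind(c(0, 0), w2); m$weights[[4]]$b <- c(0, 0)
  x <- array(c(1, 0.5), c(1, 1, 2))
  # manual backward: pre-activations h_pre = t(W1) %*% x = (2.0, -0.5);
  # unit 2 is negative, so only unit 1 contributes: grad = w2[1] * W1[,1]
  manual <- 3 * W1[, 1]
  gb <- guided_backprop(m, x, class_index = 1)
  expect_equal(as.vector(gb$data), manual, tolerance = 1e-12)
  # the vanilla gradient would agree here (negative unit passes nothing
  # forward either); a negative *backward* signal case:
  m$weights[[4]]$W <- cbind(c(0, 0), c(3, -4))
  x2 <- array(c(1, 2), c(1, 1, 2))      # both units now active
  gb2 <- guided_backprop(m, x2, class_index = 1)
  expect_equal(as.vector(gb2$data), 3 * W1[, 1], tolerance = 1e-12)
  van2 <- neurocam:::input_gradient(m, x2, class_index = 1)
  expect_equal(as.vector(van2), 3 * W1[, 1] - 4 * W1[, 2], tolerance = 1e-12)
})

test_that("guided Grad-CAM is the channel-broadcast map times the guided saliency", {
  spec <- toy_spec()
  m <- cnn_model(spec, seed = 9)
  set.seed(10)
  x <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
  gg <- guided_gradcam(m, x, class_index = 1)
  gc <- gradcam(m, x, class_index = 1)
  gb <- guided_backprop(m, x, class_index = 1)
  broad <- array(rep(as.vector(gc$upsampled), 3), c(8, 8, 3))
  expect_equal(gg$data, broad * gb$data, tolerance = 1e-12)
  expect_identical(dim(gg$data), c(8L, 8L, 3L))
  # annihilation: a zero map kills the product
  zero_vox <- which(broad == 0)
  expect_true(all(gg$data[zero_vox] == 0))
})

test_that("normalize01 rescales to [0,1], maps constants to zero and is idempotent", {
  expect_identical(normalize01(c(0, 5, 10)), c(0, 0.5, 1))
  expect_identical(normalize01(array(3, c(2, 2))), array(0, c(2, 2)))
  set.seed(1)
  x <- array(rnorm(24), c(2, 3, 4))
  n1 <- normalize01(x)
  expect_identical(range(n1), c(0, 1))
  expect_equal(normalize01(n1), n1, tolerance = 1e-15)
  expect_error(normalize01(c(1, NA)), "finite")
})

test_that("Grad-CAM maps are nonnegative across random models and inputs", {
  for (s in 1:60) {
    spec <- toy_spec(filters = c(sample(2:5, 1), sample(2:5, 1)),
                     fc_units = sample(3:6, 1))
    m <- cnn_model(spec, seed = s)
    set.seed(s + 1000)
    for (r in 1:5) {
      gc <- gradcam(m, array(rnorm(8 * 8 * 3), c(8, 8, 3)),
                    class_index = sample(0:1, 1))
      expect_true(all(gc$map >= 0))
      expect_true(all(gc$upsampled >= -1e-12))
    }
  }
})

test_that("scaling the class logit scales the alphas but not the normalised map", {
  spec <- toy_spec()
  # scan seeds for a configuration with a non-degenerate (nonzero) map
  for (s in 12:30) {
    m <- cnn_model(spec, seed = s)
    set.seed(s + 1)
    x <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
    gc1 <- gradcam(m, x, class_index = 1)
    if (max(gc1$map) > 0) break
  }
  m2 <- m
  last_dense <- max(which(vapply(spec$layers, `[[`, "", "kind") == "dense"))
  m2$weights[[last_dense]]$W <- 3.7 * m$weights[[last_dense]]$W
  m2$weights[[last_dense]]$b <- 3.7 * m$weights[[last_dense]]$b
  gc2 <- gradcam(m2, x, class_index = 1)
  expect_equal(gc2$alphas, 3.7 * gc1$alphas, tolerance = 1e-10)
  skip_if(max(gc1$map) == 0, "degenerate zero map")
  expect_equal(normalize01(gc2$upsampled), normalize01(gc1$upsampled),
               tolerance = 1e-10)
})

test_that("bilinear upsampling interpolates with half-pixel centres", {
  # doubling a 2x2 grid: centre rows/cols are 25/75 blends
  up <- upsample_bilinear(matrix(c(0, 1, 0, 1), 2, 2, byrow = FALSE), c(4, 4))
  expect_identical(dim(up), c(4L, 4L))
  expect_equal(up[, 1], c(0, 0.25, 0.75, 1))
  expect_equal(up[1, ], rep(0, 4))
  # constant fields stay constant under any resampling
  expect_equal(upsample_bilinear(matrix(2, 3, 3), c(7, 5)),
               matrix(2, 7, 5))
  expect_equal(upsample_bilinear(array(1.5, c(2, 2, 2)), c(3, 4, 5)),
               array(1.5, c(3, 4, 5)))
})

test_that("saliency unpacks to a brain volume in the original axis order", {
  spec <- toy_spec(input_shape = c(8, 8, 4))
  m <- cnn_model(spec, seed = 2)
  vol <- array(rnorm(4 * 8 * 8), c(4, 8, 8))     # pack along x
  ct <- pack_slices_as_channels(vol, axis = "x")
  gb <- guided_backprop(m, ct, class_index = 0)
  bv <- saliency_to_volume(gb, axis = "x")
  expect_identical(dim(bv$data), dim(vol))
})
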