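# Visual explanation of trained CNN classifiers: Grad-CAM on the feature maps
# of a chosen convolutional block, guided backpropagation to the input, and
# their pointwise product (guided Grad-CAM). Gradients are taken from the
# pre-softmax class score.

# resolve a conv-block reference ("last", "conv2", or block number) to the
# layer index of the conv layer and of its rectified output (the ReLU
# following it)
resolve_conv_layer <- function(spec, layer) {
  convs <- conv_layer_indices(spec)
  names(convs) <- vapply(convs, function(i)
    spec$layers[[i]]$name %||% paste0("conv", match(i, convs)), "")
  if (identical(layer, "last")) {
    ci <- convs[length(convs)]
  } else if (is.character(layer)) {
    if (!layer %in% names(convs))
      stop("layer '", layer, "' not found; available conv layers: ",
           paste(names(convs), collapse = ", "))
    ci <- convs[[layer]]
  } else {
    if (!layer %in% seq_along(convs))
      stop("conv block ", layer, " not found; available conv layers: ",
           paste(names(convs), collapse = ", "))
    ci <- convs[[layer]]
  }
  kinds <- vapply(spec$layers, `[[`, "", "kind")
  after <- which(kinds == "relu" & seq_along(kinds) > ci)
  if (!length(after)) stop("no rectifier follows conv layer ", ci)
  list(conv = unname(ci), relu = min(after))
}

check_rectified <- function(spec) {
  kinds <- vapply(spec$layers, `[[`, "", "kind")
  # the contract covers ReLU networks; any other activation kind would be
  # rejected at spec validation already, so just require at least one ReLU
  if (!any(kinds == "relu"))
    stop("guided backpropagation requires a network with rectified activations")
}

as_input_tensor <- function(model, input) {
  if (inherits(input, "channel_tensor")) input <- input$data
  if (!isTRUE(all.equal(dim(input), as.integer(model$spec$input_shape),
                        check.attributes = FALSE)))
    stop("input shape ", paste(dim(input), collapse = "x"),
         " does not match model input ",
         paste(model$spec$input_shape, collapse = "x"))
  input
}

#' Grad-CAM class activation map
#'
#' Forward-propagates the input, backpropagates the pre-softmax score of
#' `class_index` to the rectified feature maps of the chosen convolutional
#' block, averages each map's gradient over space to get the per-filter
#' weights `alpha_k`, combines `relu(sum_k alpha_k A_k)` at conv resolution,
#' and bilinearly upsamples the result to the input's spatial shape.
#'
#' @param model A `cnn_model` or `cnn_fit`.
#' @param input The input tensor (`channel_tensor` or H x W x C array).
#' @param class_index Class of interest: 0 (TYP) or 1 (DYS).
#' @param layer Conv block to explain: `"last"` (default), a conv layer name
#'   or block number.
#' @return A `gradcam_map`: list with `map` (conv-resolution H' x W',
#'   nonnegative), `upsampled` (input-resolution H x W), `alphas`,
#'   `class_index` and `layer`.
#' @export
gradcam <- function(model, input, class_index = 1L, layer = "last") {
  if (inherits(model, "cnn_fit")) model <- model$model
  if (!class_index %in% c(0L, 1L)) stop("class_index must be 0 or 1")
  loc <- resolve_conv_layer(model$spec, layer)
  x <- as_input_tensor(model, input)
  X <- batch_to_mat(x, model$spec, 1L)
  fwd <- nn_forward_mat(model, X, 1L, mode = "eval", keep_cache = TRUE)

  d_logits <- matrix(0, model$spec$n_classes, 1L)
  d_logits[class_index + 1L, 1L] <- 1
  bwd <- nn_backward_mat(model, fwd, d_logits, 1L, stop_at = loc$relu,
                         want_grads = FALSE)
  A <- fwd$caches[[loc$relu]]$Y        # (P' x K) rectified feature maps
  dA <- bwd$d_layer
  alphas <- colMeans(dA)               # spatial mean of d score / d A_k
  cam <- pmax(as.vector(A %*% alphas), 0)

  out_spatial <- model_shapes(model$spec)[[loc$relu]]$spatial
  map <- array(cam, dim = out_spatial)
  in_spatial <- model$spec$input_shape[seq_len(model$spec$ndim)]
  structure(list(map = map,
                 upsampled = upsample_bilinear(map, in_spatial),
                 alphas = alphas, class_index = as.integer(class_index),
                 layer = layer),
            class = "gradcam_map")
}

#' Guided backpropagation saliency
#'
#' A backward pass of the class score in which, at every rectifier, the
#' signal is zeroed wherever the forward activation was non-positive or the
#' incoming backward signal is non-positive; the result has the input's
#' shape.
#'
#' @inheritParams gradcam
#' @return A `saliency` object: list with `data` (H x W x C array,
#'   input-shaped), `class_index`.
#' @export
guided_backprop <- function(model, input, class_index = 1L) {
  if (inherits(model, "cnn_fit")) model <- model$model
  if (!class_index %in% c(0L, 1L)) stop("class_index must be 0 or 1")
  check_rectified(model$spec)
  x <- as_input_tensor(model, input)
  X <- batch_to_mat(x, model$spec, 1L)
  fwd <- nn_forward_mat(model, X, 1L, mode = "eval", keep_cache = TRUE)
  d_logits <- matrix(0, model$spec$n_classes, 1L)
  d_logits[class_index + 1L, 1L] <- 1
  bwd <- nn_backward_mat(model, fwd, d_logits, 1L, guided = TRUE,
                         want_grads = FALSE)
  structure(list(data = array(mat_to_batch(bwd$d_input, model$spec, 1L),
                              dim = model$spec$input_shape),
                 class_index = as.integer(class_index)),
            class = "saliency")
}

# plain (non-guided) input gradient; used as an oracle companion
input_gradient <- function(model, input, class_index = 1L) {
  if (inherits(model, "cnn_fit")) model <- model$model
  x <- as_input_tensor(model, input)
  X <- batch_to_mat(x, model$spec, 1L)
  fwd <- nn_forward_mat(model, X, 1L, mode = "eval", keep_cache = TRUE)
  d_logits <- matrix(0, model$spec$n_classes, 1L)
  d_logits[class_index + 1L, 1L] <- 1
  bwd <- nn_backward_mat(model, fwd, d_logits, 1L, want_grads = FALSE)
  array(mat_to_batch(bwd$d_input, model$spec, 1L),
        dim = model$spec$input_shape)
}

#' Guided Grad-CAM saliency
#'
#' The upsampled Grad-CAM map, broadcast across the channel axis, multiplied
#' pointwise with the guided-backpropagation saliency. Because the channel
#' axis holds brain slices, the result resolves relevance along all three
#' volume axes and can be unpacked to brain space with [unpack_channels()].
#'
#' @inheritParams gradcam
#' @return A `saliency` object with the input's shape.
#' @export
guided_gradcam <- function(model, input, class_index = 1L, layer = "last") {
  gc <- gradcam(model, input, class_index, layer)
  gb <- guided_backprop(model, input, class_index)
  C <- dim(gb$data)[length(dim(gb$data))]
  broad <- array(rep(as.vector(gc$upsampled), C), dim = dim(gb$data))
  structure(list(data = broad * gb$data,
                 class_index = gb$class_index, gradcam = gc),
            class = "saliency")
}

#' Min-max normalisation to [0, 1]
#'
#' Linearly rescales so the minimum maps to 0 and the maximum to 1; a
#' constant input maps to all zeros. Idempotent.
#'
#' @param x Numeric array/vector with finite values.
#' @return Same shape, values in `[0, 1]`.
#' @export
normalize01 <- function(x) {
  v <- if (is.list(x)) x$data else x
  if (!all(is.finite(v))) stop("input must be finite")
  rng <- range(v)
  out <- if (rng[2] > rng[1]) (v - rng[1]) / (rng[2] - rng[1]) else v * 0
  if (is.list(x)) { x$data <- out; x } else out
}

#' Bilinear (2D) / trilinear (3D) upsampling
#'
#' Half-pixel-centre convention (align-corners off): output pixel `i` samples
#' source coordinate `(i + 0.5) * scale - 0.5`, clamped at the borders, with
#' linear interpolation weights per axis.
#'
#' @param x 2D or 3D numeric array.
#' @param out_shape Integer vector of output sizes, one per axis.
#' @return Upsampled array of shape `out_shape`.
#' @export
upsample_bilinear <- function(x, out_shape) {
  d <- dim(x)
  stopifnot(length(d) == length(out_shape))
  weight_matrix <- function(n_in, n_out) {
    if (n_in == 1L) return(matrix(1, n_out, 1L))
    scale <- n_in / n_out
    s <- pmin(pmax((seq_len(n_out) - 0.5) * scale - 0.5, 0), n_in - 1)
    lo <- pmin(floor(s), n_in - 2)
    w <- s - lo
    W <- matrix(0, n_out, n_in)
    W[cbind(seq_len(n_out), lo + 1)] <- 1 - w
    W[cbind(seq_len(n_out), lo + 2)] <- W[cbind(seq_len(n_out), lo + 2)] + w
    W
  }
  if (length(d) == 2L) {
    weight_matrix(d[1], out_shape[1]) %*% x %*% t(weight_matrix(d[2], out_shape[2]))
  } else if (length(d) == 3L) {
    W1 <- weight_matrix(d[1], out_shape[1])
    W2 <- weight_matrix(d[2], out_shape[2])
    W3 <- weight_matrix(d[3], out_shape[3])
    # contract one axis at a time
    y <- apply(x, 3, function(sl) W1 %*% sl %*% t(W2))
    y <- array(y, dim = c(out_shape[1], out_shape[2], d[3]))
    y <- aperm(apply(y, c(1, 2), function(v) W3 %*% v), c(2, 3, 1))
    array(y, dim = out_shape)
  } else stop("only 2D and 3D arrays supported")
}

#' Convert a saliency tensor to a brain-space volume
#'
#' Unpacks the slice-as-channel saliency back along the original volume axis
#' and attaches the geometry's affine.
#'
#' @param saliency A `saliency` (input-shaped tensor).
#' @param axis The channel axis used when packing (default `"z"`).
#' @param affine Voxel-to-mm affine for the returned volume.
#' @param subject_id Optional identifier.
#' @return A [brain_volume()] of relevance values.
#' @export
saliency_to_volume <- function(saliency, axis = "z", affine = diag(4),
                               subject_id = NULL) {
  arr <- unpack_channels(saliency$data, axis = axis)
  brain_volume(arr, affine = affine, subject_id = subject_id)
}
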