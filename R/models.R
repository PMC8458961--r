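# Declarative CNN architecture description. A model_spec is an ordered list of
# layers; the engine (engine.R) interprets it. Convolutions are "valid" (no
# padding); pooling windows are clipped at the border when the input is
# smaller than the kernel, so a pool on a length-1 side is the identity.

layer_conv <- function(kernel, stride, n_filters, ndim = 2L, name = NULL) {
  stopifnot(kernel >= 1, stride >= 1, n_filters >= 1)
  list(kind = if (ndim == 3L) "conv3d" else "conv2d",
       kernel = as.integer(kernel), stride = as.integer(stride),
       n_filters = as.integer(n_filters), name = name)
}
layer_batchnorm <- function() list(kind = "batchnorm")
layer_relu <- function() list(kind = "relu")
layer_maxpool <- function(kernel = 2L, stride = 2L)
  list(kind = "maxpool", kernel = as.integer(kernel), stride = as.integer(stride))
layer_flatten <- function() list(kind = "flatten")
layer_dense <- function(n_units, name = NULL)
  list(kind = "dense", n_units = as.integer(n_units), name = name)
layer_dropout <- function(rate) {
  stopifnot(rate >= 0, rate < 1)
  list(kind = "dropout", rate = rate)
}
layer_softmax <- function() list(kind = "softmax")

new_model_spec <- function(layers, input_shape, n_classes = 2L) {
  ndim <- length(input_shape) - 1L
  spec <- structure(list(layers = layers, input_shape = as.integer(input_shape),
                         ndim = as.integer(ndim), n_classes = as.integer(n_classes)),
                    class = "model_spec")
  validate_model_spec(spec)
  spec
}

# output spatial size of one axis for a kernel/stride, valid padding;
# pooling clips its window at the border (out >= 1 whenever in >= 1)
out_size <- function(n, kernel, stride, clip = FALSE) {
  if (n >= kernel) (n - kernel) %/% stride + 1L
  else if (clip) 1L
  else 0L
}

#' Per-layer output shapes of a model
#'
#' @param spec A `model_spec`.
#' @return List, one element per layer, each `list(spatial =, channels =)`
#'   giving the shape after that layer (dense layers report
#'   `spatial = integer(0)` and `channels = n_units`).
#' @export
model_shapes <- function(spec) {
  spatial <- spec$input_shape[seq_len(spec$ndim)]
  channels <- spec$input_shape[spec$ndim + 1L]
  flat <- FALSE
  out <- vector("list", length(spec$layers))
  for (i in seq_along(spec$layers)) {
    l <- spec$layers[[i]]
    if (l$kind %in% c("conv2d", "conv3d")) {
      spatial <- vapply(spatial, out_size, integer(1),
                        kernel = l$kernel, stride = l$stride)
      channels <- l$n_filters
      if (any(spatial < 1L))
        stop(sprintf("layer %d (%s) collapses the spatial dimensions to %s",
                     i, l$kind, paste(spatial, collapse = "x")))
    } else if (l$kind == "maxpool") {
      spatial <- vapply(spatial, out_size, integer(1),
                        kernel = l$kernel, stride = l$stride, clip = TRUE)
    } else if (l$kind == "flatten") {
      channels <- prod(spatial) * channels
      spatial <- integer(0)
      flat <- TRUE
    } else if (l$kind == "dense") {
      channels <- l$n_units
    }
    out[[i]] <- list(spatial = spatial, channels = as.integer(channels))
  }
  out
}

validate_model_spec <- function(spec) {
  kinds <- vapply(spec$layers, `[[`, "", "kind")
  allowed <- c("conv2d", "conv3d", "batchnorm", "relu", "maxpool", "flatten",
               "dense", "dropout", "softmax")
  if (length(bad <- setdiff(kinds, allowed)))
    stop("unknown layer kind(s): ", paste(bad, collapse = ", "))
  shapes <- model_shapes(spec)  # errors if spatial dims collapse
  last_dense <- rev(which(kinds == "dense"))[1]
  if (is.na(last_dense) || spec$layers[[last_dense]]$n_units != spec$n_classes)
    stop("final dense layer must have n_units = n_classes")
  if (kinds[length(kinds)] != "softmax")
    stop("model must end in a softmax layer")
  invisible(spec)
}

#' Build the pinned modified LeNet-5 2D CNN
#'
#' Three convolutional blocks (5x5 valid convolution, stride 1, filter counts
#' 16/32/64 doubling per block) each followed by batch normalisation, ReLU and
#' 2x2 max pooling (stride 2), then flatten, a fully connected layer, dropout
#' and a 2-class softmax. The four departures from classic LeNet-5 are the
#' batch-norm layers, ReLU instead of tanh, max instead of average pooling,
#' and the dropout on the fully connected layer.
#'
#' @param input_shape `c(H, W, C)`: spatial size and channel count of the
#'   slice-as-channel input tensor.
#' @param fc_units Width of the fully connected layer (default 64).
#' @param dropout Dropout rate on the fully connected layer (default 0.5).
#' @return A `model_spec`.
#' @export
build_modified_lenet5 <- function(input_shape, fc_units = 64L, dropout = 0.5) {
  stopifnot(length(input_shape) == 3L)
  layers <- list()
  for (i in 1:3) {
    layers <- c(layers, list(
      layer_conv(5L, 1L, 16L * 2L^(i - 1L), ndim = 2L, name = paste0("conv", i)),
      layer_batchnorm(), layer_relu(), layer_maxpool(2L, 2L)))
  }
  layers <- c(layers, list(layer_flatten(),
                           layer_dense(fc_units, name = "fc1"),
                           layer_dropout(dropout),
                           layer_dense(2L, name = "logits"),
                           layer_softmax()))
  new_model_spec(layers, input_shape)
}

#' Convert a 2D model spec to its 3D counterpart
#'
#' 2D convolutions become isotropic 3D convolutions (a k x k kernel becomes
#' k x k x k), max pooling becomes 3D max pooling, and the input becomes a
#' single-channel 4D array `c(D, H, W, 1)`.
#'
#' @param spec A 2D `model_spec`.
#' @param input_shape Spatial shape `c(D, H, W)` of the 3D input; defaults to
#'   the 2D spec's `c(H, W, C)` reinterpreted as a volume.
#' @return A 3D `model_spec`.
#' @export
to_3d <- function(spec, input_shape = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  if (spec$ndim != 2L) stop("'spec' is not a 2D model")
  if (is.null(input_shape)) input_shape <- spec$input_shape
  stopifnot(length(input_shape) == 3L)
  layers <- lapply(spec$layers, function(l) {
    if (l$kind == "conv2d") l$kind <- "conv3d"
    l
  })
  new_model_spec(layers, c(input_shape, 1L), n_classes = spec$n_classes)
}

#' Count trainable parameters of a model
#'
#' Convolutions count `kernel^nd * C_in * C_out + C_out`, dense layers
#' `n_in * n_out + n_out`, batch normalisation 2 per channel (scale and
#' shift); other layers have none.
#'
#' @param spec A `model_spec`.
#' @return Integer parameter count (0 for an empty layer list).
#' @export
count_params <- function(spec) {
  if (length(spec$layers) == 0L) return(0L)
  nd <- spec$ndim
  channels <- spec$input_shape[nd + 1L]
  shapes <- model_shapes(spec)
  total <- 0
  ch_in <- channels
  for (i in seq_along(spec$layers)) {
    l <- spec$layers[[i]]
    if (l$kind %in% c("conv2d", "conv3d")) {
      k <- l$kernel^(if (l$kind == "conv3d") 3L else 2L)
      total <- total + k * ch_in * l$n_filters + l$n_filters
    } else if (l$kind == "dense") {
      total <- total + ch_in * l$n_units + l$n_units
    } else if (l$kind == "batchnorm") {
      total <- total + 2L * ch_in
    }
    ch_in <- shapes[[i]]$channels
  }
  as.integer(total)
}

conv_layer_indices <- function(spec) {
  which(vapply(spec$layers, function(l) l$kind %in% c("conv2d", "conv3d"),
               logical(1)))
}

#' @export
print.model_spec <- function(x, ...) {
  shapes <- model_shapes(x)
  cat(sprintf("CNN model spec (%dD input %s, %d classes, %s parameters)\n",
              x$ndim, paste(x$input_shape, collapse = "x"), x$n_classes,
              format(count_params(x), big.mark = ",")))
  for (i in seq_along(x$layers)) {
    l <- x$layers[[i]]
    desc <- switch(l$kind,
      conv2d = , conv3d = sprintf("%s k=%d s=%d filters=%d", l$kind, l$kernel,
                                  l$stride, l$n_filters),
      maxpool = sprintf("maxpool k=%d s=%d", l$kernel, l$stride),
      dense = sprintf("dense units=%d", l$n_units),
      dropout = sprintf("dropout rate=%.2f", l$rate),
      l$kind)
    sh <- shapes[[i]]
    cat(sprintf("  %2d. %-28s -> %s\n", i, desc,
                paste(c(sh$spatial, sh$channels), collapse = "x")))
  }
  invisible(x)
}

#' Serialize / deserialize a model spec as JSON
#'
#' @param spec A `model_spec`.
#' @param path File path.
#' @return `read_model_spec` returns the `model_spec`.
#' @export
write_model_spec <- function(spec, path) {
  jsonlite::write_json(list(layers = spec$layers,
                            input_shape = spec$input_shape,
                            n_classes = spec$n_classes),
                       path, auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}

#' @rdname write_model_spec
#' @export
read_model_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  layers <- lapply(x$layers, function(l) l[!vapply(l, is.null, logical(1))])
  new_model_spec(layers, x$input_shape, x$n_classes)
}
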