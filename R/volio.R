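#' Construct a brain volume
#'
#' A `brain_volume` couples a 3D activation array with its voxel-to-mm affine
#' and an optional subject identifier.
#'
#' @param data 3D numeric array (x, y, z voxels); must be finite.
#' @param affine 4x4 voxel-to-mm transform (RAS, 0-based voxel indices).
#' @param subject_id Optional identifier.
#' @return A `brain_volume` object.
#' @export
brain_volume <- function(data, affine = diag(4), subject_id = NULL) {
  if (length(dim(data)) != 3L) stop("'data' must be a 3D array")
  if (!all(is.finite(data))) stop("'data' must be finite")
  structure(list(data = data, affine = affine,
                 subject_id = subject_id %||% NA_character_),
            class = "brain_volume")
}

#' @export
print.brain_volume <- function(x, ...) {
  cat("Brain volume", if (!is.na(x$subject_id)) paste0("'", x$subject_id, "'"),
      ":", paste(dim(x$data), collapse = " x "), "voxels\n")
  invisible(x)
}

#' Read / write a NIfTI-1 volume
#'
#' Volumes are stored as NIfTI-1 (optionally gzipped); the affine is written
#' to the sform and recovered exactly on read. Data round-trips at float32
#' precision.
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @param vol A [brain_volume()].
#' @param subject_id Optional identifier attached to the volume on read.
#' @return `read_volume` returns a `brain_volume`; `write_volume` returns
#'   `path` invisibly.
#' @export
read_volume <- function(path, subject_id = NULL) {
  if (!file.exists(path)) stop("no such NIfTI file: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("cannot read '", path,
                                           "' as NIfTI-1: ", conditionMessage(e)))
  aff <- matrix(as.numeric(RNifti::xform(img)), 4L, 4L)
  d <- dim(img)
  if (length(d) != 3L) stop("'", path, "' is not a 3D volume")
  id <- subject_id %||% sub("\\.nii(\\.gz)?$", "", basename(path))
  brain_volume(array(as.numeric(img), dim = d), affine = aff, subject_id = id)
}

#' @rdname read_volume
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "brain_volume"))
  img <- RNifti::asNifti(vol$data)
  img <- RNifti::`sform<-`(img, structure(vol$affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Pack a volume's slices along one axis as channels
#'
#' Feeds a 3D volume to a 2D CNN by treating the slices along `axis` as input
#' channels: the chosen axis is moved last, giving an H x W x C tensor.
#' [unpack_channels()] restores the original volume exactly.
#'
#' @param vol A [brain_volume()] or 3D array.
#' @param axis Which volume axis becomes the channel axis: `"x"`, `"y"` or
#'   `"z"` (default, axial slices).
#' @return A `channel_tensor`: list with `data` (H x W x C array), `axis`,
#'   `affine`, `subject_id`.
#' @export
pack_slices_as_channels <- function(vol, axis = c("z", "x", "y")) {
  axis <- match.arg(axis)
  arr <- if (inherits(vol, "brain_volume")) vol$data else vol
  stopifnot(length(dim(arr)) == 3L)
  perm <- switch(axis, x = c(2L, 3L, 1L), y = c(1L, 3L, 2L), z = c(1L, 2L, 3L))
  structure(list(data = aperm(arr, perm), axis = axis,
                 affine = if (inherits(vol, "brain_volume")) vol$affine else diag(4),
                 subject_id = if (inherits(vol, "brain_volume")) vol$subject_id
                              else NA_character_),
            class = "channel_tensor")
}

#' @rdname pack_slices_as_channels
#' @param x A `channel_tensor` (or an H x W x C array plus `axis`).
#' @export
unpack_channels <- function(x, axis = NULL) {
  if (inherits(x, "channel_tensor")) {
    arr <- x$data; axis <- axis %||% x$axis
  } else {
    arr <- x
    if (is.null(axis)) stop("'axis' required when unpacking a bare array")
  }
  inv <- switch(axis, x = c(3L, 1L, 2L), y = c(1L, 3L, 2L), z = c(1L, 2L, 3L))
  aperm(arr, inv)
}

#' Split a cohort into train / validation / test parts
#'
#' Validation and test sizes are `floor(n * fraction)` with a minimum of 1
#' whenever the fraction is positive and subjects remain; the remainder goes
#' to train (32 subjects at 0.8/0.1/0.1 gives 26/3/3). With
#' `stratify_by_group` the rule is applied within each group.
#'
#' @param cohort A `cohort`, or a data.frame with `subject_id` and `group`.
#' @param fractions Numeric length 3 `(train, val, test)` summing to 1.
#' @param stratify_by_group Apply the split within each group (default TRUE).
#' @param seed Integer seed; assignment is deterministic for a fixed seed.
#' @return `data.frame(subject_id, group, part)` with
#'   `part in {train, val, test}`.
#' @export
split_cohort <- function(cohort, fractions = c(0.8, 0.1, 0.1),
                         stratify_by_group = TRUE, seed = 1L) {
  subjects <- if (inherits(cohort, "cohort")) cohort$subjects else cohort
  stopifnot(is.data.frame(subjects), "subject_id" %in% names(subjects))
  if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-8)
    stop("'fractions' must be three values summing to 1")
  if (!"group" %in% names(subjects)) subjects$group <- "all"

  old <- set_local_seed(derive_seed(seed, 0L))
  on.exit(restore_seed(old), add = TRUE)

  assign_one <- function(ids) {
    n <- length(ids)
    n_val <- floor(n * fractions[2])
    n_test <- floor(n * fractions[3])
    if (fractions[2] > 0 && n_val == 0L && n > 0L) n_val <- 1L
    if (fractions[3] > 0 && n_test == 0L && n > n_val) n_test <- 1L
    while (n_val + n_test > n) {  # tiny cohorts: shrink back
      if (n_test > 0L) n_test <- n_test - 1L else n_val <- n_val - 1L
    }
    n_train <- n - n_val - n_test
    for (p in c("train", "val", "test")) {
      f <- fractions[match(p, c("train", "val", "test"))]
      np <- c(train = n_train, val = n_val, test = n_test)[[p]]
      if (f > 0 && np == 0L && n > 0L)
        warning(sprintf("'%s' part is empty although its fraction is %.2f", p, f))
    }
    perm <- sample(ids)
    parts <- rep("train", n)
    names(parts) <- perm
    if (n_val > 0L) parts[seq_len(n_val)] <- "val"
    if (n_test > 0L) parts[n_val + seq_len(n_test)] <- "test"
    parts
  }

  if (stratify_by_group) {
    parts <- do.call(c, unname(lapply(split(subjects$subject_id, subjects$group),
                                      assign_one)))
  } else {
    parts <- assign_one(subjects$subject_id)
  }
  out <- data.frame(subject_id = names(parts), part = unname(parts),
                    stringsAsFactors = FALSE)
  out <- merge(subjects[, c("subject_id", "group")], out, by = "subject_id",
               sort = FALSE)
  out[match(subjects$subject_id, out$subject_id), , drop = FALSE]
}

in_mask_of <- function(vol, mask) {
  arr <- if (inherits(vol, "brain_volume")) vol$data else vol
  if (is.null(mask)) mask <- (arr != 0) + 0L
  m <- if (inherits(mask, "brain_geometry")) mask$mask else mask
  if (!identical(dim(m), dim(arr)))
    stop("mask shape does not match volume shape")
  m != 0
}

#' Data augmentation: voxelwise Gaussian noise
#'
#' Adds i.i.d. `N(0, sigma^2)` noise to in-mask voxels; out-of-mask voxels are
#' untouched (bit-identical).
#'
#' @param vol A [brain_volume()].
#' @param sigma Noise SD (>= 0; 0 is the identity).
#' @param seed Integer seed.
#' @param mask Binary array or `brain_geometry`; defaults to the volume's
#'   nonzero support.
#' @return An augmented `brain_volume`.
#' @export
augment_noise <- function(vol, sigma, seed = 1L, mask = NULL) {
  stopifnot(inherits(vol, "brain_volume"))
  if (sigma < 0) stop("'sigma' must be >= 0")
  if (sigma == 0) return(vol)
  inm <- in_mask_of(vol, mask)
  old <- set_local_seed(derive_seed(seed, 0L))
  on.exit(restore_seed(old), add = TRUE)
  out <- vol$data
  out[inm] <- out[inm] + stats::rnorm(sum(inm), 0, sigma)
  brain_volume(out, vol$affine, vol$subject_id)
}

#' Data augmentation: random global intensity offset
#'
#' Draws one scalar `c ~ N(0, sigma^2)` per call and adds it uniformly to all
#' in-mask voxels (a random contrast/offset augmentation).
#'
#' @inheritParams augment_noise
#' @return An augmented `brain_volume`.
#' @export
augment_offset <- function(vol, sigma, seed = 1L, mask = NULL) {
  stopifnot(inherits(vol, "brain_volume"))
  if (sigma < 0) stop("'sigma' must be >= 0")
  if (sigma == 0) return(vol)
  inm <- in_mask_of(vol, mask)
  old <- set_local_seed(derive_seed(seed, 0L))
  on.exit(restore_seed(old), add = TRUE)
  off <- stats::rnorm(1L, 0, sigma)
  out <- vol$data
  out[inm] <- out[inm] + off
  brain_volume(out, vol$affine, vol$subject_id)
}

#' Flatten in-mask voxels to a feature vector (and back)
#'
#' Voxels are taken in the array's native column-major order (x fastest), so
#' the ordering is fixed and `unflatten_masked(flatten_masked(v)) == v` on the
#' mask support.
#'
#' @param vol A [brain_volume()] or 3D array.
#' @param mask Binary 3D array or `brain_geometry` of the same shape.
#' @param values Numeric vector of length `sum(mask)`.
#' @return `flatten_masked`: numeric vector of length `sum(mask)`.
#'   `unflatten_masked`: 3D array with `values` on the mask and 0 elsewhere.
#' @export
flatten_masked <- function(vol, mask) {
  arr <- if (inherits(vol, "brain_volume")) vol$data else vol
  m <- if (inherits(mask, "brain_geometry")) mask$mask else mask
  if (!identical(dim(m), dim(arr)))
    stop("mask shape ", paste(dim(m), collapse = "x"),
         " does not match volume shape ", paste(dim(arr), collapse = "x"))
  as.numeric(arr[m != 0])
}

#' @rdname flatten_masked
#' @export
unflatten_masked <- function(values, mask) {
  m <- if (inherits(mask, "brain_geometry")) mask$mask else mask
  if (length(values) != sum(m != 0))
    stop("length(values) != mask voxel count")
  out <- array(0, dim = dim(m))
  out[m != 0] <- values
  out
}

#' Z-score a volume within its mask
#'
#' Centres and scales in-mask voxels to mean 0, SD 1 (out-of-mask voxels stay
#' 0). Standard per-subject normalisation before model input, removing
#' arbitrary scanner scaling.
#'
#' @inheritParams augment_noise
#' @return A normalised `brain_volume`.
#' @export
zscore_volume <- function(vol, mask = NULL) {
  stopifnot(inherits(vol, "brain_volume"))
  inm <- in_mask_of(vol, mask)
  v <- vol$data[inm]
  s <- stats::sd(v)
  out <- vol$data
  out[inm] <- if (s > 0) (v - mean(v)) / s else 0
  out[!inm] <- 0
  brain_volume(out, vol$affine, vol$subject_id)
}
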