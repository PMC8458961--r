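#' Synthetic brain geometry: ellipsoidal mask plus contiguous parcellation
#'
#' Builds an ellipsoidal in-brain mask centred in the array and partitions its
#' voxels into `n_regions` spatially contiguous parcels by nearest-seed-voxel
#' growth (each mask voxel is assigned to the closest of `n_regions` randomly
#' placed seed voxels).
#'
#' @param shape Integer vector of length 3, voxel counts per axis (each >= 8).
#' @param n_regions Number of parcels (>= 1, at most the mask voxel count).
#' @param seed Integer seed; the result is deterministic for a fixed seed.
#' @param voxel_mm Voxel edge length in mm used to build the affine (default 3,
#'   the template resolution the classifier inputs are defined on).
#'
#' @return A `brain_geometry` object: list with `mask` (0/1 3D array),
#'   `parcellation` (integer 3D array, 0 = background), `region_names`
#'   (named character vector, names are the labels), and `affine`
#'   (4x4 voxel-to-mm RAS transform, 0-based voxel indices).
#' @export
make_brain_geometry <- function(shape, n_regions, seed = 1L, voxel_mm = 3) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 8L))
    stop("'shape' must be three voxel counts, each >= 8")
  if (n_regions < 1L) stop("'n_regions' must be >= 1")

  centre <- (shape + 1) / 2
  radii <- shape * 0.42
  ax <- lapply(1:3, function(k) ((seq_len(shape[k]) - centre[k]) / radii[k])^2)
  d2 <- outer(outer(ax[[1]], ax[[2]], "+"), ax[[3]], "+")
  mask <- array(as.integer(d2 <= 1), dim = shape)

  idx <- which(mask == 1L)
  n_mask <- length(idx)
  if (n_regions > n_mask)
    stop(sprintf("n_regions (%d) exceeds mask voxel count (%d)", n_regions, n_mask))

  coords <- arrayInd(idx, shape)
  parc <- array(0L, dim = shape)
  if (n_regions == 1L) {
    parc[idx] <- 1L
  } else {
    rs <- derive_seed(seed, 0L)
    old <- set_local_seed(rs)
    on.exit(restore_seed(old), add = TRUE)
    seeds <- coords[sample.int(n_mask, n_regions), , drop = FALSE]
    # squared Euclidean distance of every mask voxel to every seed voxel;
    # ties go to the lowest label so the partition is deterministic
    d <- matrix(0, n_mask, n_regions)
    for (k in 1:3)
      d <- d + outer(coords[, k], seeds[, k], "-")^2
    parc[idx] <- max.col(-d, ties.method = "first")
  }

  labels <- seq_len(n_regions)
  region_names <- sprintf("parcel_%02d", labels)
  names(region_names) <- labels

  affine <- diag(c(rep(voxel_mm, 3), 1))
  affine[1:3, 4] <- -voxel_mm * (centre - 1)

  structure(list(mask = mask, parcellation = parc,
                 region_names = region_names, affine = affine),
            class = "brain_geometry")
}

#' @export
print.brain_geometry <- function(x, ...) {
  cat("Brain geometry:", paste(dim(x$mask), collapse = " x "), "voxels;",
      sum(x$mask), "in mask;", length(x$region_names), "parcels\n")
  invisible(x)
}

#' Specify a group-dependent activation effect
#'
#' The effect is additive and constant within the target parcels: subjects of
#' the elevated group get `amplitude * noise_sd` added to every voxel of the
#' target parcels.
#'
#' @param target_labels Integer parcel labels carrying the effect.
#' @param amplitude Effect size in units of the noise standard deviation (>= 0).
#' @param group_sign Which group is elevated, `"DYS"` (default) or `"TYP"`.
#' @return An `effect_spec` object.
#' @export
effect_spec <- function(target_labels, amplitude, group_sign = "DYS") {
  if (amplitude < 0) stop("'amplitude' must be >= 0")
  group_sign <- match.arg(group_sign, c("DYS", "TYP"))
  structure(list(target_labels = as.integer(target_labels),
                 amplitude = amplitude, group_sign = group_sign),
            class = "effect_spec")
}

#' Simulate one subject's contrast volume
#'
#' In-mask voxels are `baseline` plus the group effect (for voxels in the
#' target parcels when `group` matches the effect's elevated group) plus
#' Gaussian-smoothed zero-mean noise. Out-of-mask voxels are exactly 0.
#'
#' @param geometry A [make_brain_geometry()] object.
#' @param group `"DYS"` or `"TYP"`.
#' @param effect An [effect_spec()].
#' @param baseline Scalar in-mask baseline intensity.
#' @param noise_sd Noise standard deviation before smoothing (>= 0).
#' @param smooth_sigma Gaussian smoothing sigma in voxels applied to the noise
#'   field only (>= 0; 0 disables smoothing).
#' @param seed Integer seed.
#' @param subject_id Optional subject identifier stored on the volume.
#' @return A `brain_volume`: list with `data` (3D array), `affine`, `subject_id`.
#' @export
simulate_subject <- function(geometry, group, effect,
                             baseline = 0, noise_sd = 1, smooth_sigma = 1,
                             seed = 1L, subject_id = NULL) {
  stopifnot(inherits(geometry, "brain_geometry"))
  if (!group %in% c("DYS", "TYP"))
    stop(sprintf("unknown group '%s'; must be \"DYS\" or \"TYP\"", group))
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (smooth_sigma < 0) stop("'smooth_sigma' must be >= 0")
  bad <- setdiff(effect$target_labels, as.integer(names(geometry$region_names)))
  if (length(bad))
    stop("effect target labels not in parcellation: ", paste(bad, collapse = ", "))

  shape <- dim(geometry$mask)
  vol <- array(baseline, dim = shape)
  if (effect$amplitude > 0 && group == effect$group_sign) {
    hit <- geometry$parcellation %in% effect$target_labels
    vol[hit] <- vol[hit] + effect$amplitude * noise_sd
  }
  if (noise_sd > 0) {
    old <- set_local_seed(derive_seed(seed, 0L))
    on.exit(restore_seed(old), add = TRUE)
    noise <- array(stats::rnorm(prod(shape), 0, noise_sd), dim = shape)
    if (smooth_sigma > 0) noise <- gaussian_smooth(noise, smooth_sigma)
    vol <- vol + noise
  }
  vol[geometry$mask == 0L] <- 0
  brain_volume(vol, affine = geometry$affine, subject_id = subject_id)
}

#' Separable Gaussian smoothing of a 3D array
#'
#' Convolves with a normalised 1D Gaussian kernel (radius 3 sigma) along each
#' axis in turn, zero-padded at the edges.
#'
#' @param arr 3D numeric array.
#' @param sigma Kernel sigma in voxels (> 0).
#' @return Smoothed array of the same shape.
#' @export
gaussian_smooth <- function(arr, sigma) {
  stopifnot(sigma > 0)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  dims <- dim(arr)
  for (axis in 1:3) {
    out <- array(0, dim = dims)
    n <- dims[axis]
    for (j in seq_along(k)) {
      off <- j - r - 1L
      src <- seq_len(n) + off
      keep <- src >= 1L & src <= n
      dst_idx <- which(keep)
      src_idx <- src[keep]
      if (axis == 1L) {
        out[dst_idx, , ] <- out[dst_idx, , ] + k[j] * arr[src_idx, , ]
      } else if (axis == 2L) {
        out[, dst_idx, ] <- out[, dst_idx, ] + k[j] * arr[, src_idx, ]
      } else {
        out[, , dst_idx] <- out[, , dst_idx] + k[j] * arr[, , src_idx]
      }
    }
    arr <- out
  }
  arr
}

#' Per-group demographic distribution parameters
#'
#' Means and standard deviations of the cohort demographics for the typical
#' (TYP) and dyslexic (DYS) reader groups, together with the male proportion.
#' Units: age in years, reading speed in words/minute, task accuracy in %,
#' response time in ms.
#'
#' @return Nested list `list(TYP = ..., DYS = ...)`; each group holds
#'   `c(mean, sd)` pairs for `age`, `iq`, `ses`, `reading_speed`,
#'   `task_accuracy`, `task_rt`, and a scalar `p_male`.
#' @export
default_demographics <- function() {
  list(
    TYP = list(age = c(8.44, 0.51), iq = c(102.73, 15.37), ses = c(24.1, 4.9),
               reading_speed = c(84.71, 31.89), task_accuracy = c(54.68, 6.71),
               task_rt = c(2039.2, 423.56), p_male = 9 / 16),
    DYS = list(age = c(9.63, 0.88), iq = c(107.85, 26.6), ses = c(26.4, 6.5),
               reading_speed = c(13.07, 7.68), task_accuracy = c(35.06, 14),
               task_rt = c(2981.06, 954.82), p_male = 11 / 16)
  )
}

# truncation bounds keeping draws inside plausible printed ranges
.demo_bounds <- list(age = c(7, 13), iq = c(60, 150), ses = c(0, Inf),
                     reading_speed = c(0, Inf), task_accuracy = c(0, 100),
                     task_rt = c(0, Inf))

rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (n == 0L) return(numeric(0))
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x < lower | x > upper)
  }
  x
}

#' Draw demographic records for one group
#'
#' Continuous variables are drawn from truncated normal distributions (age
#' clipped to 7-13 years, IQ to 60-150, reading speed / SES / response time
#' to nonnegative values, task accuracy to 0-100%); sex is Bernoulli with the
#' group's male proportion.
#'
#' @param n Number of subjects.
#' @param group `"DYS"` or `"TYP"`.
#' @param params Per-group parameter list as in [default_demographics()].
#' @param seed Integer seed.
#' @return `data.frame` with columns `subject_id, group, age, sex, iq, ses,
#'   reading_speed, task_accuracy, task_rt`.
#' @export
sample_demographics <- function(n, group, params = default_demographics(),
                                seed = 1L) {
  if (n < 0) stop("'n' must be >= 0")
  group <- match.arg(group, c("DYS", "TYP"))
  p <- params[[group]]
  old <- set_local_seed(derive_seed(seed, 0L))
  on.exit(restore_seed(old), add = TRUE)
  draw <- function(var) {
    b <- .demo_bounds[[var]]
    rtruncnorm(n, p[[var]][1], p[[var]][2], b[1], b[2])
  }
  data.frame(
    subject_id = sprintf("sub-%s-%03d", group, seq_len(n)),
    group = rep(group, n),
    age = draw("age"),
    sex = ifelse(stats::runif(n) < p$p_male, "M", "F"),
    iq = draw("iq"),
    ses = draw("ses"),
    reading_speed = draw("reading_speed"),
    task_accuracy = draw("task_accuracy"),
    task_rt = draw("task_rt"),
    stringsAsFactors = FALSE
  )
}

#' Simulate a two-group cohort of contrast volumes with demographics
#'
#' Generates `n_per_group` subjects per group. Each subject's volume comes from
#' [simulate_subject()] with a per-subject seed derived as global seed plus
#' subject index; demographics are drawn from the per-group truncated normals.
#'
#' @inheritParams simulate_subject
#' @param n_per_group Subjects per group (>= 0).
#' @param demo_params Demographic parameters, defaulting to
#'   [default_demographics()].
#' @return A `cohort` object: list with `subjects` (demographics data.frame),
#'   `volumes` (list of `brain_volume`, same order), and `geometry`.
#' @export
simulate_cohort <- function(geometry, n_per_group = 16L, effect,
                            demo_params = default_demographics(),
                            baseline = 0, noise_sd = 1, smooth_sigma = 1,
                            seed = 1L) {
  if (n_per_group < 0) stop("'n_per_group' must be >= 0")
  demo <- rbind(
    sample_demographics(n_per_group, "TYP", demo_params, seed = derive_seed(seed, 1L)),
    sample_demographics(n_per_group, "DYS", demo_params, seed = derive_seed(seed, 2L))
  )
  vols <- vector("list", nrow(demo))
  for (i in seq_len(nrow(demo))) {
    vols[[i]] <- simulate_subject(geometry, demo$group[i], effect,
                                  baseline = baseline, noise_sd = noise_sd,
                                  smooth_sigma = smooth_sigma,
                                  seed = derive_seed(seed, 10L + i),
                                  subject_id = demo$subject_id[i])
  }
  names(vols) <- demo$subject_id
  structure(list(subjects = demo, volumes = vols, geometry = geometry),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("Cohort:", nrow(x$subjects), "subjects (",
      paste(sprintf("%s=%d", names(table(x$subjects$group)),
                    as.integer(table(x$subjects$group))), collapse = ", "),
      ")\n")
  invisible(x)
}

#' Write a cohort to disk
#'
#' Volumes go to `<dir>/<subject_id>.nii.gz`, the mask and parcellation to
#' `mask.nii.gz` / `parcellation.nii.gz`, and demographics to
#' `demographics.tsv`.
#'
#' @param cohort A [simulate_cohort()] object.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  g <- cohort$geometry
  f <- file.path(dir, "mask.nii.gz")
  write_volume(brain_volume(g$mask + 0, g$affine), f); files <- c(files, f)
  f <- file.path(dir, "parcellation.nii.gz")
  write_volume(brain_volume(g$parcellation + 0, g$affine), f); files <- c(files, f)
  for (v in cohort$volumes) {
    f <- file.path(dir, paste0(v$subject_id, ".nii.gz"))
    write_volume(v, f); files <- c(files, f)
  }
  f <- file.path(dir, "demographics.tsv")
  utils::write.table(cohort$subjects, f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(files, f)
  invisible(files)
}
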