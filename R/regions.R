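#' Group-level mean saliency
#'
#' Each subject's saliency volume is min-max normalised to [0, 1] and the
#' voxelwise mean is taken over the correctly-classified subjects of the
#' class (explanations of misclassified subjects explain the wrong decision;
#' set `use_all = TRUE` to include everyone).
#'
#' @param volumes List of 3D saliency arrays (or `brain_volume`s) in brain
#'   space, one per subject of the class.
#' @param correct Logical vector, one flag per volume.
#' @param use_all Include misclassified subjects (default FALSE).
#' @return A `group_saliency`: list with `data` (mean normalised volume,
#'   values in [0, 1]) and `n_subjects` contributing.
#' @export
group_mean_saliency <- function(volumes, correct = NULL, use_all = FALSE) {
  if (length(volumes) < 1L) stop("need at least one saliency volume")
  arrs <- lapply(volumes, function(v)
    if (inherits(v, "brain_volume")) v$data else v)
  if (is.null(correct)) correct <- rep(TRUE, length(arrs))
  keep <- if (use_all) rep(TRUE, length(arrs)) else as.logical(correct)
  if (!any(keep))
    stop("no correctly-classified subjects; rerun with use_all = TRUE")
  arrs <- lapply(arrs[keep], normalize01)
  structure(list(data = Reduce(`+`, arrs) / length(arrs),
                 n_subjects = sum(keep)),
            class = "group_saliency")
}

#' Threshold a saliency volume at an in-mask percentile
#'
#' A voxel is kept iff it is in the mask and its value is greater than or
#' equal to the `q`-th percentile of in-mask values (so ties at the
#' threshold are kept, and `q = 0` keeps every in-mask voxel).
#'
#' @param volume 3D array, `brain_volume` or `group_saliency`.
#' @param mask Binary 3D array or `brain_geometry`.
#' @param q Percentile in `[0, 100)` (default 90).
#' @return Binary 3D array (1 = kept).
#' @export
threshold_map <- function(volume, mask, q = 90) {
  arr <- if (inherits(volume, c("brain_volume", "group_saliency")))
    volume$data else volume
  m <- if (inherits(mask, "brain_geometry")) mask$mask else mask
  if (!identical(dim(m), dim(arr))) stop("mask and volume shapes differ")
  if (q < 0 || q >= 100) stop("'q' must be in [0, 100)")
  inm <- m != 0
  if (!any(inm)) stop("empty mask")
  thr <- stats::quantile(arr[inm], q / 100, names = FALSE)
  out <- array(0L, dim = dim(arr))
  out[inm & arr >= thr] <- 1L
  out
}

# 26-neighbourhood offsets (3x3x3 minus the centre)
.offsets26 <- local({
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
})

#' Label connected clusters of a binary map
#'
#' Components under 26-connectivity; components smaller than `min_size` are
#' discarded. Labels are assigned in order of descending component size
#' (ties broken by the smallest member voxel index), so labelling is
#' deterministic.
#'
#' @param binary_map Binary 3D array.
#' @param min_size Minimum cluster size in voxels (>= 1, default 1).
#' @return Integer 3D array of cluster labels (0 = background), with an
#'   attribute `sizes` giving voxel counts per label.
#' @export
connected_clusters <- function(binary_map, min_size = 1L) {
  if (min_size < 1L) stop("'min_size' must be >= 1")
  dims <- dim(binary_map)
  on_voxels <- which(binary_map != 0)
  labels <- array(0L, dim = dims)
  if (!length(on_voxels)) return(structure(labels, sizes = integer(0)))
  comp <- integer(length(on_voxels))
  names(comp) <- on_voxels
  pos <- array(0L, dim = dims)      # membership lookup: index into on_voxels
  pos[on_voxels] <- seq_along(on_voxels)
  visited <- logical(length(on_voxels))
  comp_id <- 0L
  members <- list()
  for (s in seq_along(on_voxels)) {
    if (visited[s]) next
    comp_id <- comp_id + 1L
    frontier <- on_voxels[s]
    visited[s] <- TRUE
    got <- frontier
    while (length(frontier)) {
      co <- arrayInd(frontier, dims)
      # all 26-neighbours of the frontier, vectorised
      nb <- do.call(rbind, lapply(seq_len(nrow(.offsets26)), function(o)
        sweep(co, 2, .offsets26[o, ], "+")))
      ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
        nb[, 2] >= 1 & nb[, 2] <= dims[2] &
        nb[, 3] >= 1 & nb[, 3] <= dims[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- unique(nb[, 1] + (nb[, 2] - 1L) * dims[1] +
                      (nb[, 3] - 1L) * dims[1] * dims[2])
      p <- pos[lin]
      new <- lin[p > 0L & !visited[pmax(p, 1L)]]
      pnew <- pos[new]
      visited[pnew] <- TRUE
      frontier <- new
      got <- c(got, new)
    }
    members[[comp_id]] <- sort(got)
  }
  sizes <- lengths(members)
  keep <- which(sizes >= min_size)
  ord <- keep[order(-sizes[keep], vapply(members[keep], min, numeric(1)))]
  out_sizes <- integer(length(ord))
  for (j in seq_along(ord)) {
    labels[members[[ord[j]]]] <- j
    out_sizes[j] <- sizes[ord[j]]
  }
  structure(labels, sizes = out_sizes)
}

#' Per-cluster region table with voxel counts and peak coordinates
#'
#' For each cluster: the voxel count of every parcellation region it
#' intersects (voxels outside the parcellation are counted under
#' "unlabeled"), the peak (highest-saliency voxel in the cluster) in mm via
#' the affine, and the cluster label, i.e. the region name at the peak.
#' Clusters appear in label order (largest first); within a cluster, region
#' rows are sorted by descending voxel count.
#'
#' @param clusters Labelled cluster array from [connected_clusters()].
#' @param saliency 3D saliency array (or `brain_volume`/`group_saliency`)
#'   on the same grid.
#' @param geometry A [make_brain_geometry()] with the parcellation and
#'   affine.
#' @return A `region_table` data.frame with columns `cluster_id`,
#'   `cluster_label`, `region_name`, `voxel_count`, `peak_x`, `peak_y`,
#'   `peak_z`.
#' @export
region_table <- function(clusters, saliency, geometry) {
  sal <- if (inherits(saliency, c("brain_volume", "group_saliency")))
    saliency$data else saliency
  if (!identical(dim(clusters), dim(sal)) ||
      !identical(dim(clusters), dim(geometry$parcellation)))
    stop("clusters, saliency and geometry must share the same grid")
  n_cl <- max(clusters)
  rows <- list()
  region_name_of <- function(label) {
    if (label == 0L) "unlabeled"
    else unname(geometry$region_names[as.character(label)])
  }
  for (k in seq_len(n_cl)) {
    vox <- which(clusters == k)
    peak <- vox[which.max(sal[vox])]
    pc <- arrayInd(peak, dim(clusters)) - 1L       # 0-based voxel indices
    mm <- as.vector(geometry$affine %*% c(pc, 1))[1:3]
    cl_label <- region_name_of(geometry$parcellation[peak])
    counts <- table(geometry$parcellation[vox])
    cnt <- as.integer(counts)
    labs <- as.integer(names(counts))
    ord <- order(-cnt, labs)
    for (j in ord) {
      rows[[length(rows) + 1L]] <- data.frame(
        cluster_id = k, cluster_label = cl_label,
        region_name = region_name_of(labs[j]), voxel_count = cnt[j],
        peak_x = mm[1], peak_y = mm[2], peak_z = mm[3],
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
  else data.frame(cluster_id = integer(0), cluster_label = character(0),
                  region_name = character(0), voxel_count = integer(0),
                  peak_x = numeric(0), peak_y = numeric(0),
                  peak_z = numeric(0))
  structure(out, class = c("region_table", "data.frame"))
}

#' @export
print.region_table <- function(x, ...) {
  if (!nrow(x)) { cat("(no clusters)\n"); return(invisible(x)) }
  cat("Brain regions                         No. of voxels   Peak (x, y, z) mm\n")
  for (k in unique(x$cluster_id)) {
    rows <- x[x$cluster_id == k, , drop = FALSE]
    cat(sprintf("%-40s %8d   %6.0f %5.0f %5.0f\n",
                toupper(rows$cluster_label[1]), sum(rows$voxel_count),
                rows$peak_x[1], rows$peak_y[1], rows$peak_z[1]))
    for (i in seq_len(nrow(rows)))
      cat(sprintf("  %-38s %8d\n", rows$region_name[i], rows$voxel_count[i]))
  }
  invisible(x)
}

#' Write a region table as TSV
#'
#' @param x A `region_table`.
#' @param path Output file.
#' @export
write_region_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Two-sample t-test from printed group summaries
#'
#' Recomputes an independent-samples t-test from group means, standard
#' deviations and sizes (pooled variance by default, Welch-Satterthwaite
#' when `welch = TRUE`), with a two-sided p-value from the t distribution.
#' Useful for checking the significance column of a published demographics
#' table.
#'
#' @param mean1,sd1,n1 Summary of group 1.
#' @param mean2,sd2,n2 Summary of group 2.
#' @param welch Use Welch's unequal-variance form (default FALSE).
#' @return An object of class `htest` with `statistic` (t), `parameter`
#'   (df) and `p.value`.
#' @export
ttest_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2, welch = FALSE) {
  if (n1 < 2 || n2 < 2) stop("group sizes must be >= 2")
  if (sd1 <= 0 || sd2 <= 0) stop("standard deviations must be > 0")
  if (welch) {
    se2 <- sd1^2 / n1 + sd2^2 / n2
    t <- (mean1 - mean2) / sqrt(se2)
    df <- se2^2 / ((sd1^2 / n1)^2 / (n1 - 1) + (sd2^2 / n2)^2 / (n2 - 1))
    method <- "Welch two-sample t-test from summaries"
  } else {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
    t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    method <- "Pooled two-sample t-test from summaries"
  }
  structure(list(statistic = c(t = t), parameter = c(df = df),
                 p.value = 2 * stats::pt(-abs(t), df),
                 estimate = c(`mean difference` = mean1 - mean2),
                 method = method,
                 data.name = sprintf("%.4g+-%.4g (n=%d) vs %.4g+-%.4g (n=%d)",
                                     mean1, sd1, n1, mean2, sd2, n2)),
            class = "htest")
}
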