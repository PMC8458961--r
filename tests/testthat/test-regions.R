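test_that("group mean saliency averages normalised volumes over correct subjects", {
  a <- array(runif(4 * 4 * 3), c(4, 4, 3))
  expect_equal(group_mean_saliency(list(a))$data, normalize01(a))
  expect_equal(group_mean_saliency(list(a, a))$data, normalize01(a))

  # k one-hot volumes with disjoint hot voxels -> 1/k at each hot voxel
  k <- 4L
  vols <- lapply(1:k, function(i) {
    v <- array(0, c(4, 4, 3)); v[i, 1, 1] <- 5; v
  })
  gm <- group_mean_saliency(vols)
  expect_identical(gm$n_subjects, k)
  for (i in 1:k) expect_equal(gm$data[i, 1, 1], 1 / k)
  expect_true(all(gm$data >= 0 & gm$data <= 1))

  expect_error(group_mean_saliency(vols, correct = rep(FALSE, k)),
               "use_all")
  expect_identical(group_mean_saliency(vols, correct = rep(FALSE, k),
                                       use_all = TRUE)$n_subjects, k)
})

test_that("percentile thresholding keeps the right in-mask fraction with ties kept", {
  mask <- array(1L, c(50, 50, 40))
  set.seed(2)
  vol <- array(runif(1e5), c(50, 50, 40))
  kept <- threshold_map(vol, mask, q = 90)
  frac <- sum(kept) / 1e5
  expect_gt(frac, 0.09); expect_lt(frac, 0.11)

  expect_identical(sum(threshold_map(vol, mask, q = 0)), 100000L)
  # constant volume: every in-mask voxel ties the threshold and is kept
  const <- array(1, c(6, 6, 4))
  m2 <- array(1L, c(6, 6, 4)); m2[1, , ] <- 0L
  expect_identical(sum(threshold_map(const, m2, q = 50)), sum(m2))
  # out-of-mask voxels never survive
  expect_true(all(threshold_map(vol, m2 <- array(0:1, c(50, 50, 40)),
                                q = 10)[m2 == 0L] == 0))
  expect_error(threshold_map(vol, array(0L, c(50, 50, 40))), "empty mask")
  expect_error(threshold_map(vol, mask, q = 100), "q")
})

test_that("connected component labelling matches a brute-force flood fill", {
  # hand cases
  single <- array(0L, c(5, 5, 5)); single[3, 3, 3] <- 1L
  cl <- connected_clusters(single)
  expect_identical(attr(cl, "sizes"), 1L)
  expect_identical(cl[3, 3, 3], 1L)

  touching <- array(0L, c(5, 5, 5))
  touching[2, 2, 2] <- 1L; touching[3, 2, 2] <- 1L    # face-adjacent
  expect_identical(attr(connected_clusters(touching), "sizes"), 2L)
  diagonal <- array(0L, c(5, 5, 5))
  diagonal[2, 2, 2] <- 1L; diagonal[3, 3, 3] <- 1L    # corner-adjacent
  expect_identical(attr(connected_clusters(diagonal), "sizes"), 2L)

  # oracle comparison on random maps
  set.seed(5)
  for (i in 1:100) {
    bm <- array(rbinom(8 * 8 * 6, 1, 0.25), c(8, 8, 6))
    cl <- connected_clusters(bm)
    oracle <- floodfill_components(bm)
    expect_identical(sort(attr(cl, "sizes"), decreasing = TRUE),
                     sort(oracle$sizes, decreasing = TRUE))
    # identical partition: component co-membership agrees
    if (max(oracle$labels) > 0) {
      map <- table(cl[bm == 1L], oracle$labels[bm == 1L])
      expect_true(all(rowSums(map > 0) == 1))
      expect_true(all(colSums(map > 0) == 1))
    }
  }

  # min_size filter and deterministic size-ordered labels
  two <- array(0L, c(10, 10, 4))
  two[1:3, 1, 1] <- 1L          # size 3
  two[6:10, 5, 2] <- 1L         # size 5
  cl2 <- connected_clusters(two, min_size = 4L)
  expect_identical(attr(cl2, "sizes"), 5L)
  cl3 <- connected_clusters(two)
  expect_identical(attr(cl3, "sizes"), c(5L, 3L))
  expect_identical(cl3[6, 5, 2], 1L)   # largest first
  expect_error(connected_clusters(two, min_size = 0), "min_size")
})

test_that("region tables conserve voxel counts and report in-cluster peaks in mm", {
  g <- make_brain_geometry(c(14, 14, 10), 5, seed = 8)
  set.seed(3)
  sal <- array(runif(prod(dim(g$mask))), dim(g$mask)) * (g$mask == 1L)
  bin <- threshold_map(sal, g$mask, q = 80)
  cl <- connected_clusters(bin, min_size = 2L)
  tab <- region_table(cl, sal, g)
  expect_s3_class(tab, "region_table")
  # conservation: region rows sum to the surviving voxel count, per cluster
  expect_identical(sum(tab$voxel_count), sum(cl > 0L))
  for (k in unique(tab$cluster_id)) {
    rows <- tab[tab$cluster_id == k, ]
    expect_identical(sum(rows$voxel_count), sum(cl == k))
    # peak voxel is a member of the cluster and the label names its region
    vox_mm <- t(g$affine %*% rbind(t(arrayInd(which(cl == k), dim(cl)) - 1L),
                                   1))[, 1:3, drop = FALSE]
    hit <- which(abs(vox_mm[, 1] - rows$peak_x[1]) < 1e-9 &
                   abs(vox_mm[, 2] - rows$peak_y[1]) < 1e-9 &
                   abs(vox_mm[, 3] - rows$peak_z[1]) < 1e-9)
    expect_length(hit, 1L)
    expect_true(rows$cluster_label[1] %in% g$region_names)
  }
  # clusters ordered largest first in the table
  cluster_sizes <- vapply(unique(tab$cluster_id), function(k)
    sum(tab$voxel_count[tab$cluster_id == k]), integer(1))
  expect_true(all(diff(cluster_sizes) <= 0))
})

test_that("single-voxel clusters and unlabeled voxels are reported explicitly", {
  g <- make_brain_geometry(c(12, 12, 8), 3, seed = 2)
  cl <- array(0L, dim(g$mask))
  inm <- which(g$parcellation == 2L)[1]
  cl[inm] <- 1L
  sal <- array(0, dim(g$mask)); sal[inm] <- 1
  tab <- region_table(cl, sal, g)
  expect_identical(nrow(tab), 1L)
  expect_identical(tab$voxel_count, 1L)
  expect_identical(tab$region_name, unname(g$region_names["2"]))
  mm <- g$affine %*% c(arrayInd(inm, dim(cl)) - 1L, 1)
  expect_equal(c(tab$peak_x, tab$peak_y, tab$peak_z), mm[1:3])

  # cluster reaching outside the parcellation support -> "unlabeled" row
  outside <- which(g$mask == 0L)[1]
  cl[outside] <- 2L
  tab2 <- region_table(cl, sal, g)
  expect_true("unlabeled" %in% tab2$region_name)
  expect_identical(sum(tab2$voxel_count), 2L)
})

test_that("summary t-tests reproduce the cohort table significance pattern", {
  # identical summaries
  t0 <- ttest_from_summary(5, 1, 16, 5, 1, 16)
  expect_identical(unname(t0$statistic), 0)
  expect_identical(t0$p.value, 1)

  p <- default_demographics()
  reading <- ttest_from_summary(p$TYP$reading_speed[1], p$TYP$reading_speed[2],
                                16, p$DYS$reading_speed[1],
                                p$DYS$reading_speed[2], 16)
  expect_lt(reading$p.value, 0.001)
  age <- ttest_from_summary(p$TYP$age[1], p$TYP$age[2], 16,
                            p$DYS$age[1], p$DYS$age[2], 16)
  expect_lt(age$p.value, 0.001)
  # response time: the printed summaries are in fact nominally significant
  rt <- ttest_from_summary(p$TYP$task_rt[1], p$TYP$task_rt[2], 16,
                           p$DYS$task_rt[1], p$DYS$task_rt[2], 16)
  expect_gt(rt$p.value, 0.0005); expect_lt(rt$p.value, 0.002)
  expect_error(ttest_from_summary(1, 1, 1, 2, 1, 16), "sizes")
})

test_that("summary t-tests agree with t.test on reconstructed samples", {
  set.seed(11)
  for (i in 1:100) {
    n1 <- sample(3:30, 1); n2 <- sample(3:30, 1)
    m1 <- rnorm(1, 0, 5); m2 <- rnorm(1, 0, 5)
    s1 <- runif(1, 0.5, 4); s2 <- runif(1, 0.5, 4)
    x1 <- sample_with_summary(n1, m1, s1)
    x2 <- sample_with_summary(n2, m2, s2)
    pooled <- ttest_from_summary(m1, s1, n1, m2, s2, n2)
    ref <- t.test(x1, x2, var.equal = TRUE)
    expect_lt(abs(pooled$statistic - ref$statistic), 1e-10)
    expect_lt(abs(pooled$p.value - ref$p.value), 1e-10)
    welch <- ttest_from_summary(m1, s1, n1, m2, s2, n2, welch = TRUE)
    refw <- t.test(x1, x2)
    expect_lt(abs(welch$statistic - refw$statistic), 1e-10)
    expect_lt(abs(unname(welch$parameter) - unname(refw$parameter)), 1e-8)
  }
})
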