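test_that("Brunner-Munzel handles symmetry and ties", {
  b <- brunner_munzel(c(3, 1, 4, 2), c(3, 1, 4, 2))
  expect_equal(b$relative_effect, 0.5)
  expect_equal(b$statistic, 0)
  expect_equal(b$p, 1)
  full_ties <- brunner_munzel(rep(2, 4), rep(2, 5))
  expect_equal(full_ties$relative_effect, 0.5)
  expect_equal(full_ties$statistic, 0)
  expect_error(brunner_munzel(1, c(1, 2)), "at least 2")
})

test_that("relative effect equals the exhaustive pairwise count", {
  set.seed(64)
  for (i in 1:200) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    x <- sample(seq_len(50), n1)        # tie-free within and across
    y <- sample(setdiff(seq_len(50), x), n2)
    b <- brunner_munzel(x, y)
    expect_equal(b$relative_effect, pairwise_relative_effect(x, y))
  }
  # with ties the midrank estimator still matches the pairwise definition
  for (i in 1:50) {
    x <- sample(1:4, 5, replace = TRUE)
    y <- sample(1:4, 4, replace = TRUE)
    expect_equal(brunner_munzel(x, y)$relative_effect,
                 pairwise_relative_effect(x, y))
  }
})

test_that("the statistic is antisymmetric and rank-invariant", {
  set.seed(65)
  for (i in 1:50) {
    x <- rnorm(sample(4:10, 1)); y <- rnorm(sample(4:10, 1), 0.5)
    b <- brunner_munzel(x, y)
    swapped <- brunner_munzel(y, x)
    expect_equal(swapped$statistic, -b$statistic)
    expect_equal(swapped$p, b$p)
    expect_equal(swapped$relative_effect, 1 - b$relative_effect)
    # strictly monotone transforms leave everything unchanged
    tr <- brunner_munzel(exp(x), exp(y))
    expect_equal(tr$statistic, b$statistic)
    expect_equal(tr$relative_effect, b$relative_effect)
  }
})

test_that("complete separation falls back to the permutation bound", {
  b <- brunner_munzel(1:5, 6:9)
  expect_true(b$degenerate)
  expect_equal(b$p, 2 / choose(9, 5))
  expect_gt(b$statistic, 0)
  expect_equal(brunner_munzel(6:9, 1:5)$statistic, -b$statistic)
})

test_that("coverage filter applies the 20% and feasibility rules", {
  dims <- c(4L, 4L, 4L)
  # voxel [1,1,1] lesioned by 5/25, [2,1,1] by 4/25, [3,1,1] by all,
  # [4,1,1] by none
  masks <- lapply(1:25, function(i) {
    g <- array(0L, dims)
    if (i <= 5) g[1, 1, 1] <- 1L
    if (i <= 4) g[2, 1, 1] <- 1L
    g[3, 1, 1] <- 1L
    lesion_mask(g)
  })
  inc <- coverage_filter(masks, 0.2)
  expect_true(inc[1, 1, 1])        # 5 >= ceiling(0.2 * 25)
  expect_false(inc[2, 1, 1])       # 4 < 5
  expect_false(inc[3, 1, 1])       # no spared patients
  expect_false(inc[4, 1, 1])       # no lesioned patients
  # near-1 fraction: a universal voxel passes the count rule but not
  # the spared-side requirement
  inc2 <- coverage_filter(masks, 0.99)
  expect_false(any(inc2))
})

test_that("FDR step-up returns the documented cutoffs", {
  expect_equal(fdr_threshold(c(0.01, 0.02, 0.03, 0.04), 0.05), 0.04)
  expect_true(is.na(fdr_threshold(rep(1, 5), 0.05)))
  expect_equal(fdr_threshold(0.04, 0.05), 0.04)
  expect_true(is.na(fdr_threshold(numeric(0), 0.05)))
  # only the small block passes once the large p's dilute the ranks
  expect_equal(fdr_threshold(c(0.001, 0.2, 0.3, 0.9), 0.05), 0.001)
  expect_error(fdr_threshold(c(0.1, 0)), "0, 1")
})

test_that("power map needs enough patients on both sides", {
  dims <- c(3L, 3L, 3L)
  masks <- lapply(1:24, function(i) {
    g <- array(0L, dims)
    if (i <= 12) g[1, 1, 1] <- 1L   # balanced 12/12 split
    if (i <= 5) g[2, 1, 1] <- 1L    # 5/19 split
    lesion_mask(g)
  })
  pw <- power_map(masks, min_fraction = 0.2, q = 0.05)
  expect_true(pw[1, 1, 1])                     # 2/C(24,12) << 0.05
  expect_true(pw[2, 1, 1])                     # 2/C(24,5) < 0.05
  inc <- coverage_filter(masks, 0.2)
  expect_true(all(which(pw) %in% which(inc)))  # powered subset of included
  # a 1-vs-n split can never reach q (and fails feasibility anyway)
  masks1 <- lapply(1:20, function(i) {
    g <- array(0L, dims)
    if (i == 1) g[1, 1, 1] <- 1L
    lesion_mask(g)
  })
  expect_false(any(power_map(masks1, min_fraction = 0.01)))
})

test_that("connected components respect the connectivity scheme", {
  arr <- array(FALSE, c(5L, 5L, 5L))
  arr[1:2, 1, 1] <- TRUE          # component A
  arr[4, 4, 4] <- TRUE            # isolated voxel B
  arr[5, 5, 5] <- TRUE            # diagonal neighbor of B
  lab26 <- label_components(arr, 26L)
  expect_equal(max(lab26), 2L)    # diagonal connects under 26
  lab6 <- label_components(arr, 6L)
  expect_equal(max(lab6), 3L)     # but not under 6
  expect_setequal(attr(lab26, "sizes"), c(2L, 2L))
  expect_equal(sum(attr(lab6, "sizes")), sum(arr))
})

test_that("run_vlsm finds a planted association and applies the filters", {
  dims <- c(8L, 8L, 8L)
  set.seed(30)
  lesioned <- sample(25, 10)
  masks <- lapply(1:25, function(i) {
    g <- array(0L, dims)
    if (i %in% lesioned) g[2:5, 2:5, 2:5] <- 1L   # 64-voxel block
    lesion_mask(g)
  })
  scores <- rnorm(25, 0, 0.1)
  scores[lesioned] <- scores[lesioned] + 10      # huge planted effect
  res <- run_vlsm(masks, scores, vlsm_config(min_cluster_voxels = 50L))
  expect_equal(nrow(res$clusters), 1L)
  expect_equal(res$clusters$size_voxels, 64L)
  expect_gt(res$clusters$max_statistic, 0)       # lesioned score higher
  expect_true(all(res$significant_map[2:5, 2:5, 2:5]))
  # extent filter: demanding more voxels than the block kills the cluster
  res2 <- run_vlsm(masks, scores, vlsm_config(min_cluster_voxels = 65L))
  expect_equal(nrow(res2$clusters), 0L)
  expect_false(any(res2$significant_map))
  expect_gt(res2$n_fdr_voxels, 0L)               # FDR itself still fires
  # flipping the score direction flips the reported sign
  res3 <- run_vlsm(masks, -scores, vlsm_config(min_cluster_voxels = 50L))
  expect_lt(res3$clusters$max_statistic, 0)
  expect_error(run_vlsm(masks, scores[-1]), "one score per patient")
})

test_that("significant voxels are powered and included", {
  cfg <- recovery_config(delta = -0.7)
  co <- sample_cohort(cfg, seed = 6)
  res <- run_vlsm(co$masks, log10(co$subjects$k_now))
  sig <- which(res$significant_map)
  pow <- which(res$power_map)
  inc <- which(res$included_map)
  expect_true(all(sig %in% pow))
  expect_true(all(pow %in% inc))
  expect_equal(res$n_included, length(inc))
  # z and p maps live exactly on the included voxels
  expect_identical(which(!is.na(res$z_map)), inc)
  expect_identical(which(!is.na(res$p_map)), inc)
})

test_that("cluster centers of mass land in world coordinates", {
  dims <- c(8L, 8L, 8L)
  masks <- lapply(1:20, function(i) {
    g <- array(0L, dims)
    if (i <= 8) g[3:6, 3:6, 3:6] <- 1L
    lesion_mask(g, voxel_size_mm = c(2, 2, 2), origin = c(-7, -7, -7))
  })
  scores <- c(rep(5, 8), rep(0, 12)) + seq(0.001, 0.02, length.out = 20)
  res <- run_vlsm(masks, scores, vlsm_config(min_cluster_voxels = 10L))
  expect_equal(nrow(res$clusters), 1L)
  # block center voxel index 4.5 -> world -7 + 3.5 * 2 = 0
  expect_equal(res$clusters$x, 0, tolerance = 1e-9)
  expect_equal(res$clusters$y, 0, tolerance = 1e-9)
  expect_identical(res$clusters$hemisphere, "right")
})
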