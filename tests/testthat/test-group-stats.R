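test_that("degenerate designs give the boundary F values", {
  vals <- cbind(now = rep(1.5, 10), notnow = rep(1.5, 10))
  grp <- rep(c("a", "b"), each = 5)
  res <- mixed_anova(vals, grp)
  expect_equal(res$effects$F, c(0, 0, 0))
  expect_equal(res$effects$p, c(1, 1, 1))
  # pure within-subject shift, no noise: Condition maximal, Group null
  vals2 <- cbind(now = rep(2, 10), notnow = rep(2, 10) + 0.7)
  res2 <- mixed_anova(vals2, grp)
  eff <- setNames(res2$effects$F, res2$effects$name)
  expect_equal(unname(eff["group"]), 0)
  expect_identical(unname(eff["condition"]), Inf)
  expect_equal(res2$effects$p[res2$effects$name == "condition"], 0)
})

test_that("the sum-of-squares decomposition conserves the total", {
  set.seed(15)
  for (i in 1:25) {
    nj <- sample(3:20, 3)
    grp <- rep(c("a", "b", "c"), nj)
    vals <- cbind(rnorm(sum(nj), 0, 2), rnorm(sum(nj), 0.5, 2))
    res <- mixed_anova(vals, grp)
    parts <- res$ss[c("group", "subjects_within_group", "condition",
                      "group_x_condition", "condition_x_subjects")]
    expect_equal(sum(parts), unname(res$ss["total"]),
                 tolerance = 1e-8)
  }
})

test_that("split-plot dfs follow the design", {
  vals <- cbind(rnorm(89), rnorm(89))
  grp <- rep(c("ins", "non", "hc"), c(12, 13, 64))
  res <- mixed_anova(vals, grp)
  expect_equal(res$effects$df_num, c(2L, 1L, 2L))
  expect_equal(unique(res$effects$df_den), 86)
})

test_that("each effect holds its nominal type-I rate under the null", {
  set.seed(1001)
  nrep <- 2000
  grp <- rep(c("a", "b", "c"), c(12, 13, 64))
  hits <- matrix(FALSE, nrep, 3)
  for (r in seq_len(nrep)) {
    vals <- matrix(rnorm(89 * 2), ncol = 2)
    hits[r, ] <- mixed_anova(vals, grp)$effects$p < 0.05
  }
  rates <- colMeans(hits)
  for (rate in rates) {
    expect_gt(rate, 0.03)
    expect_lt(rate, 0.07)
  }
})

test_that("Fisher LSD equals the omnibus test for two groups", {
  set.seed(3)
  vals <- cbind(rnorm(20), rnorm(20))
  grp <- rep(c("a", "b"), each = 10)
  res <- mixed_anova(vals, grp)
  lsd <- fisher_lsd(res, c("a", "b"), "group")
  expect_equal(lsd$p, res$effects$p[res$effects$name == "group"],
               tolerance = 1e-12)
  expect_equal(lsd$t^2, res$effects$F[res$effects$name == "group"],
               tolerance = 1e-12)
  # condition LSD reproduces the omnibus condition test
  lsd_c <- fisher_lsd(res, colnames(res$cell_means)[1:2], "condition")
  expect_equal(lsd_c$p, res$effects$p[res$effects$name == "condition"],
               tolerance = 1e-12)
  expect_error(fisher_lsd(res, c("a", "zzz"), "group"), "group levels")
})

test_that("LSD power matches the noncentral-t closed form", {
  # one pooled-SD shift between groups of 12 and 13, third group idle
  delta <- 1
  nj <- c(12, 13, 64)
  ncp <- delta / sqrt(1 / 12 + 1 / 13)
  crit <- qt(0.975, sum(nj) - 3)
  power_theory <- pt(-crit, sum(nj) - 3, ncp) +
    pt(crit, sum(nj) - 3, ncp, lower.tail = FALSE)
  set.seed(55)
  hits <- replicate(400, {
    m <- c(rnorm(12, 0), rnorm(13, delta), rnorm(64, 0.5))
    vals <- cbind(m + rnorm(89, 0, 0.4), m + rnorm(89, 0, 0.4))
    res <- mixed_anova(vals, rep(c("a", "b", "c"), nj))
    fisher_lsd(res, c("a", "b"), "group")$p < 0.05
  })
  expect_lt(abs(mean(hits) - power_theory), 0.07)
})

test_that("group separation at the published means is reliably detected", {
  g <- study_groups()
  set.seed(202)
  detected <- replicate(200, {
    lk_now <- rnorm(sum(g$n), rep(g$mean_log10_k_now, g$n), 0.5)
    lk_nn <- rnorm(sum(g$n), rep(g$mean_log10_k_notnow, g$n), 0.5)
    grp <- rep(g$label, g$n)
    m <- (lk_now + lk_nn) / 2
    means <- tapply(m, grp, mean)
    means[["insular"]] < means[["non_insular"]] &&
      means[["insular"]] < means[["healthy_control"]]
  })
  expect_gte(mean(detected), 0.95)
})

test_that("KS screen behaves on known distributions", {
  set.seed(10)
  big <- rnorm(10000)
  res <- ks_normality(big)
  expect_lt(res$d, 0.02)
  expect_gt(res$p, 0.2)
  # constructed near-perfect normal: quantiles at plotting positions
  q <- qnorm(ppoints(200), 3, 2)
  expect_lt(ks_normality(q)$d, ks_normality(rnorm(200, 3, 2))$d + 0.02)
  skewed <- rexp(500)
  expect_lt(ks_normality(skewed)$p, 0.05)
  expect_error(ks_normality(rep(1, 10)), "constant")
  expect_error(ks_normality(c(1, 2)), "at least 5")
})
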