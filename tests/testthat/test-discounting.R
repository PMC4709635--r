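test_that("noiseless model data recover the generative rate exactly", {
  for (k in c(0.005, 0.026, 0.1)) {
    for (model in c("hyperbolic", "exponential")) {
      fit <- fit_discount_model(exact_curve(k, model = model), model)
      expect_lt(abs(fit$k - k), 1e-6)
      expect_equal(fit$r_squared, 1, tolerance = 1e-9)
      expect_true(fit$converged)
    }
  }
})

test_that("model mismatch leaves residual variance", {
  curve <- exact_curve(0.026, model = "hyperbolic")
  fit <- fit_discount_model(curve, "exponential")
  expect_lt(fit$r_squared, 1)
  expect_gt(fit$r_squared, 0)  # still a passable description
})

test_that("flat curves are flagged as not converged", {
  ones <- sv_curve("now", c(2, 14, 30, 90, 180, 365), rep(40, 6))
  fit <- fit_discount_model(ones)
  expect_false(fit$converged)
  expect_lte(fit$k, 1e-5)   # the k -> 0 boundary
  half <- sv_curve("now", c(2, 14, 30), rep(20, 3))
  expect_false(fit_discount_model(half)$converged)
  expect_error(fit_discount_model(sv_curve("now", 30, 20)), "2 points")
})

test_that("AUC matches the hand-computed trapezoid cases", {
  gaps <- c(2, 14, 30, 90, 180, 365)
  expect_equal(compute_auc(sv_curve("now", gaps, rep(40, 6)))$auc, 1)
  expect_equal(compute_auc(sv_curve("now", 365, 0))$auc, 0.5)
  # all-zero values: only the anchor trapezoid contributes
  expect_equal(compute_auc(sv_curve("now", gaps, rep(0, 6)))$auc, 1 / 365)
  # unsorted inputs are sorted on curve construction
  sh <- sample(6)
  curve <- sv_curve("now", gaps[sh], (40 / (1 + 0.02 * gaps))[sh])
  expect_equal(compute_auc(curve)$auc,
               compute_auc(sv_curve("now", gaps, 40 / (1 + 0.02 * gaps)))$auc)
})

test_that("AUC stays in [0, 1] and the anchor matters for shallow curves", {
  set.seed(12)
  for (i in 1:200) {
    n <- sample(2:8, 1)
    gaps <- sort(sample(1:400, n))
    sv <- runif(n, 0, 40)
    auc <- compute_auc(sv_curve("now", gaps, sv))$auc
    expect_gte(auc, 0)
    expect_lte(auc, 1)
  }
  shallow <- sv_curve("now", c(2, 14, 30, 90, 180, 365),
                      40 / (1 + 0.001 * c(2, 14, 30, 90, 180, 365)))
  expect_gt(compute_auc(shallow)$auc, 0.8)
  expect_lt(compute_auc(shallow, anchor = FALSE)$auc,
            compute_auc(shallow)$auc)
})

test_that("trapezoid AUC upper-bounds the analytic hyperbolic integral", {
  # hyperbolic SV is convex in delay, so chords lie above the curve
  for (k in c(0.005, 0.01, 0.026, 0.05, 0.1)) {
    auc <- compute_auc(exact_curve(k))$auc
    integral <- log(1 + k * 365) / (k * 365)
    expect_gte(auc, integral)
    expect_lt(auc - integral, 0.1)
  }
})

test_that("half-value delay inverts the discount rate", {
  expect_equal(floor(half_value_delay(0.026)), 38)
  expect_equal(floor(half_value_delay(0.011)), 90)
  expect_equal(half_value_delay(1), 1)
  expect_equal(half_value_delay(0.01, "exponential"), log(2) / 0.01)
  expect_error(half_value_delay(0), "> 0")
})

test_that("rate summaries use the geometric mean", {
  s <- summarize_k(c(0.066, 0.018))
  expect_equal(round(s$mean_log10, 2), -1.46)
  expect_equal(summarize_k(c(0.3, 0.3))$geometric_mean, 0.3)
  expect_equal(summarize_k(c(0.01, 0.0001))$geometric_mean, 0.001)
  expect_error(summarize_k(numeric(0)), "empty")
  expect_error(summarize_k(c(0.1, -0.1)), "> 0")
})

test_that("noisy staircase sessions still recover k to ~15% in the median", {
  d <- session_design(include_controls = FALSE)
  for (k in c(0.005, 0.02, 0.1)) {
    set.seed(round(1000 * k))
    fits <- replicate(200, {
      ses <- run_session(choice_agent("hyperbolic", k = k, beta = 2), d)
      fit_discount_model(ses$curves$now)$k
    })
    expect_lt(abs(median(fits) - k) / k, 0.15)
  }
})

test_that("AUC and k are inversely rank-correlated across a cohort", {
  groups <- data.frame(label = "g", n = 60L, mean_log10_k_now = -1.6,
                       sd_log10_k = 0.5, placement = "none",
                       stringsAsFactors = FALSE)
  co <- sample_cohort(cohort_config(groups, beta = Inf), seed = 21)
  aucs <- vapply(co$subjects$k_now, function(k)
    compute_auc(exact_curve(k))$auc, numeric(1))
  expect_lt(cor(co$subjects$k_now, aucs, method = "spearman"), 0)
})

test_that("hyperbolic fits beat exponential fits on hyperbolic cohorts", {
  d <- session_design(include_controls = FALSE)
  set.seed(77)
  r2 <- t(replicate(60, {
    k <- 10^rnorm(1, -1.6, 0.5)
    ses <- run_session(choice_agent("hyperbolic", k = k, beta = 2), d)
    c(hyp = fit_discount_model(ses$curves$now, "hyperbolic")$r_squared,
      exo = fit_discount_model(ses$curves$now, "exponential")$r_squared)
  }))
  expect_gt(mean(r2[, "hyp"]), mean(r2[, "exo"]))
})
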