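# Shared fixtures, all built in code.

# exact model-generated subjective-value curve
exact_curve <- function(k, gaps = c(2, 14, 30, 90, 180, 365),
                        model = "hyperbolic", amount = 40,
                        condition = "now") {
  f <- if (model == "hyperbolic") 1 / (1 + k * gaps) else exp(-k * gaps)
  sv_curve(condition, gaps, amount * f, amount)
}

# deterministic agents at the behavioral extremes (within the staircase's
# reachable amounts the later option always/never dominates)
always_later_agent <- function() choice_agent("hyperbolic", k = 1e-9)
always_sooner_agent <- function() choice_agent("hyperbolic", k = 1e6)

# two-group cohort used by the VLSM recovery checks: common base rate,
# behavior shifted only through the critical-lesion coupling
recovery_config <- function(delta = -0.7, beta = Inf,
                            geometry = lesion_geometry()) {
  groups <- data.frame(
    label = c("critical", "elsewhere"), n = c(12L, 13L),
    mean_log10_k_now = log10(0.026), sd_log10_k = 0.5,
    placement = c("critical", "elsewhere"), stringsAsFactors = FALSE)
  cohort_config(groups, beta = beta, geometry = geometry,
                effect_delta_log10_k = delta, seed = 1L)
}

# logical array marking the critical region of a geometry
critical_box_array <- function(geometry) {
  cr <- geometry$critical_region
  arr <- array(FALSE, dim = geometry$grid_shape)
  arr[cr["lo", 1]:cr["hi", 1], cr["lo", 2]:cr["hi", 2],
      cr["lo", 3]:cr["hi", 3]] <- TRUE
  arr
}

# small lesion mask from explicit voxel index rows
mask_from_voxels <- function(voxels, dims = c(6L, 6L, 6L),
                             voxel_size = c(1, 1, 1)) {
  grid <- array(0L, dim = dims)
  grid[voxels] <- 1L
  lesion_mask(grid, voxel_size)
}

# brute-force pairwise relative effect P(X < Y) + P(X = Y)/2
pairwise_relative_effect <- function(x, y) {
  cmp <- outer(x, y, function(a, b) (a < b) + 0.5 * (a == b))
  mean(cmp)
}

# exact two-sided permutation p of the studentized BM statistic
bm_permutation_p <- function(x, y) {
  N <- length(x) + length(y)
  pooled <- c(x, y)
  obs <- abs(brunner_munzel(x, y)$statistic)
  splits <- utils::combn(N, length(x))
  stats <- apply(splits, 2, function(ix)
    abs(brunner_munzel(pooled[ix], pooled[-ix])$statistic))
  mean(stats >= obs - 1e-12)
}
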