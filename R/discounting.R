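# Discount-function fitting, AUC, and summary quantities.

#' Fit a discount function to a subjective-value curve
#'
#' Subjective values are first expressed as fractions of the later amount;
#' the discount rate k then minimizes the residual sum of squares of
#' \eqn{1/(1 + kD)} (hyperbolic) or \eqn{e^{-kD}} (exponential) over the
#' curve's delay gaps D (days). The search is bounded
#' (k in [1e-6, 10]/day) and started from a log-spaced grid before a
#' golden-section refinement, so local minima in k are not an issue for
#' these monotone one-parameter models. \code{r_squared} is
#' \eqn{1 - SS_{res}/SS_{tot}} about the mean subjective-value fraction and
#' can be negative for a badly mis-specified model. Fits whose optimum
#' sticks to a bound (e.g. no measurable discounting, the k -> 0 limit) or
#' whose data are flat are flagged \code{converged = FALSE}.
#'
#' @param curve An \code{\link{sv_curve}} with at least 2 points.
#' @param model \code{"hyperbolic"} or \code{"exponential"}.
#' @return An object of class \code{discount_fit}: list with \code{model},
#'   \code{k}, \code{log10_k}, \code{r_squared}, \code{converged}.
#' @export
fit_discount_model <- function(curve,
                               model = c("hyperbolic", "exponential")) {
  stopifnot(inherits(curve, "sv_curve"))
  model <- match.arg(model)
  if (length(curve$sv) < 2L)
    stop("need at least 2 points to fit", call. = FALSE)
  y <- curve$sv / curve$later_amount
  d <- curve$delay_gap
  ssq <- function(lk) sum((y - discount_factor(model, 10^lk, d))^2)
  grid <- seq(-6, 1, by = 0.25)
  vals <- vapply(grid, ssq, numeric(1))
  i <- which.min(vals)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(ssq, c(lo, hi), tol = 1e-12)
  lk <- opt$minimum
  ss_res <- opt$objective
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  converged <- ss_tot > 0 && lk > -6 + 1e-3 && lk < 1 - 1e-3
  structure(list(model = model, k = 10^lk, log10_k = lk, r_squared = r2,
                 converged = converged),
            class = "discount_fit")
}

#' @export
print.discount_fit <- function(x, ...) {
  cat(sprintf("<discount_fit> %s: k = %.6g/day (log10 k = %.3f), R2 = %s%s\n",
              x$model, x$k, x$log10_k,
              if (is.na(x$r_squared)) "NA" else sprintf("%.4f", x$r_squared),
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' Area under the empirical discounting curve
#'
#' Normalizes delays to proportions of the maximum delay and subjective
#' values to proportions of the later amount, then sums trapezoids
#' \eqn{(x_2 - x_1)(y_1 + y_2)/2} between successive delays. The
#' undiscounted anchor point (0, 1) is prepended by default (otherwise the
#' index does not span [0, 1] for shallow discounters); disable it with
#' \code{anchor = FALSE} for sensitivity analysis. Smaller AUC = steeper
#' discounting.
#'
#' @param curve An \code{\link{sv_curve}} (points are sorted by gap on
#'   construction; duplicate gaps are rejected there).
#' @param anchor Prepend the (0, 1) anchor point?
#' @return An object of class \code{auc_result}: list with \code{auc} in
#'   [0, 1] and \code{normalized_points} (data frame of x, y).
#' @export
compute_auc <- function(curve, anchor = TRUE) {
  stopifnot(inherits(curve, "sv_curve"))
  x <- curve$delay_gap / max(curve$delay_gap)
  y <- curve$sv / curve$later_amount
  if (anchor && x[1L] > 0) {
    x <- c(0, x)
    y <- c(1, y)
  }
  auc <- if (length(x) > 1L)
    sum(diff(x) * (y[-length(y)] + y[-1L]) / 2)
  else 0
  structure(list(auc = auc,
                 normalized_points = data.frame(x = x, y = y)),
            class = "auc_result")
}

#' @export
print.auc_result <- function(x, ...) {
  cat(sprintf("<auc_result> AUC = %.4f over %d normalized points\n",
              x$auc, nrow(x$normalized_points)))
  invisible(x)
}

#' Half-value delay of a discount rate
#'
#' The delay at which the later reward falls to half its undiscounted
#' value: \eqn{1/k} for the hyperbolic model, \eqn{\ln 2 / k} for the
#' exponential. For example, hyperbolic k = 0.026/day halves 40 euros in
#' about 38 days; k = 0.011/day in about 90 days.
#'
#' @param k Discount rate per day (> 0); vectorized.
#' @param model \code{"hyperbolic"} or \code{"exponential"}.
#' @return Delay in days.
#' @export
half_value_delay <- function(k, model = c("hyperbolic", "exponential")) {
  model <- match.arg(model)
  if (!is.numeric(k) || any(k <= 0))
    stop("'k' must be > 0", call. = FALSE)
  switch(model, hyperbolic = 1 / k, exponential = log(2) / k)
}

#' Summarize a set of discount rates
#'
#' Central tendency for positively skewed rates: the geometric mean
#' \eqn{10^{\mathrm{mean}(\log_{10} k)}} (base-invariant), with the mean
#' and SD of log10 k.
#'
#' @param ks Vector of discount rates (> 0, nonempty).
#' @return List with \code{geometric_mean}, \code{mean_log10},
#'   \code{sd_log10} (NA for a single rate).
#' @export
summarize_k <- function(ks) {
  if (length(ks) == 0L) stop("empty rate vector", call. = FALSE)
  if (!is.numeric(ks) || any(is.na(ks)) || any(ks <= 0))
    stop("all rates must be > 0", call. = FALSE)
  lk <- log10(ks)
  list(geometric_mean = 10^mean(lk), mean_log10 = mean(lk),
       sd_log10 = if (length(lk) > 1L) stats::sd(lk) else NA_real_)
}
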