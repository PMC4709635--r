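# Group-level inference: split-plot ANOVA, Fisher LSD post hocs,
# Kolmogorov-Smirnov normality screens.

#' Mixed (split-plot) ANOVA: one between factor, two within-subject cells
#'
#' Analyses a subject x condition table (two repeated measurements per
#' subject, e.g. Now and Not-now scores) with a between-subject grouping
#' factor: main effects of Group and Condition plus their interaction.
#' Every subject contributes both conditions, so cell frequencies are
#' proportional and the classical sum-of-squares decomposition is
#' orthogonal (it is returned in \code{ss} and adds up to the total).
#'
#' With unbalanced group sizes the Condition main effect depends on the
#' sums-of-squares convention: \code{ss_type = "III"} (default) tests the
#' unweighted mean of the per-group condition differences, \code{"I"} the
#' subject-weighted mean. Group and interaction tests coincide across
#' types here (single between factor). Denominator degrees of freedom
#' follow the split-plot scheme: N - g for all three effects, with N
#' subjects and g groups.
#'
#' Implementation note: the tests are computed via the exact subject-mean /
#' difference-score equivalences (between-subject effects on
#' \code{(y1 + y2)/2}, within-subject effects on \code{y2 - y1}), not via a
#' general linear-model solver.
#'
#' @param values Two-column numeric matrix or data frame, one row per
#'   subject (column order = condition order).
#' @param group Group labels, one per subject (>= 2 groups).
#' @param ss_type \code{"III"} (unweighted means) or \code{"I"} (weighted).
#' @return An object of class \code{anova_result}: \code{effects} data
#'   frame (name, F, df_num, df_den, p), \code{cell_means} (group x
#'   condition plus marginals), \code{ss} (orthogonal decomposition),
#'   \code{mse_between}, \code{mse_within}, and the data needed by
#'   \code{\link{fisher_lsd}}.
#' @export
mixed_anova <- function(values, group, ss_type = c("III", "I")) {
  ss_type <- match.arg(ss_type)
  values <- as.matrix(values)
  if (ncol(values) != 2L)
    stop("'values' must have exactly two condition columns", call. = FALSE)
  if (anyNA(values) || anyNA(group))
    stop("missing cells are not allowed", call. = FALSE)
  if (nrow(values) != length(group))
    stop("one group label per subject required", call. = FALSE)
  g <- factor(group)
  if (nlevels(g) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(table(g) < 2L))
    stop("each group needs at least 2 subjects", call. = FALSE)
  cond_names <- colnames(values) %||% c("cond1", "cond2")
  y1 <- values[, 1L]
  y2 <- values[, 2L]
  N <- length(y1)
  G <- nlevels(g)
  nj <- as.vector(table(g))
  m <- (y1 + y2) / 2          # subject means  -> between-subject part
  d <- y2 - y1                # condition differences -> within part
  grand <- mean(c(y1, y2))
  mbar <- tapply(m, g, mean)
  dbar <- tapply(d, g, mean)
  dbar_w <- mean(d)
  ss_group <- 2 * sum(nj * (mbar - grand)^2)
  ss_subj_err <- 2 * sum((m - mbar[g])^2)
  ss_cond <- N * dbar_w^2 / 2
  ss_int <- sum(nj * (dbar - dbar_w)^2) / 2
  ss_d_err <- sum((d - dbar[g])^2)
  ss_cond_err <- ss_d_err / 2
  ss_total <- sum((c(y1, y2) - grand)^2)
  df_err <- N - G
  ms_subj_err <- ss_subj_err / df_err
  ms_cond_err <- ss_cond_err / df_err
  # Type III condition effect: unweighted mean of group difference means
  L <- mean(dbar)
  ss_cond_iii <- L^2 / (sum(1 / nj) / G^2) / 2
  f_of <- function(ss_eff, df_num, ms_err) {
    if (ss_eff <= 0) return(c(0, 1))
    if (ms_err <= 0) return(c(Inf, 0))
    f <- (ss_eff / df_num) / ms_err
    c(f, stats::pf(f, df_num, df_err, lower.tail = FALSE))
  }
  grp <- f_of(ss_group, G - 1L, ms_subj_err)
  cnd <- f_of(if (ss_type == "III") ss_cond_iii else ss_cond, 1L,
              ms_cond_err)
  itx <- f_of(ss_int, G - 1L, ms_cond_err)
  effects <- data.frame(
    name = c("group", "condition", "group:condition"),
    F = c(grp[1L], cnd[1L], itx[1L]),
    df_num = c(G - 1L, 1L, G - 1L),
    df_den = df_err,
    p = c(grp[2L], cnd[2L], itx[2L]),
    stringsAsFactors = FALSE)
  cell <- rbind(cbind(tapply(y1, g, mean), tapply(y2, g, mean)),
                overall = c(mean(y1), mean(y2)))
  colnames(cell) <- cond_names
  cell_means <- cbind(cell, marginal = c(mbar, grand))
  ss <- c(group = ss_group, subjects_within_group = ss_subj_err,
          condition = ss_cond, group_x_condition = ss_int,
          condition_x_subjects = ss_cond_err, total = ss_total)
  structure(list(effects = effects, cell_means = cell_means, ss = ss,
                 mse_between = ms_subj_err, mse_within = ms_cond_err,
                 df_error = df_err, ss_type = ss_type,
                 data = list(m = m, d = d, group = g, nj = nj,
                             group_means = mbar, diff_means = dbar,
                             cond_names = cond_names)),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("<anova_result> split-plot ANOVA (type %s SS)\n", x$ss_type))
  eff <- x$effects
  eff$F <- signif(eff$F, 4)
  eff$p <- signif(eff$p, 4)
  print(eff, row.names = FALSE)
  invisible(x)
}

#' Fisher LSD post hoc comparison
#'
#' Unprotected pairwise t test using the omnibus error mean square and its
#' degrees of freedom; no multiplicity correction (the "Fisher test").
#' Group comparisons are on condition-averaged subject means against the
#' between-subject error; the condition comparison reproduces the omnibus
#' Condition test (two within levels). With exactly two groups the group
#' LSD p equals the omnibus Group p.
#'
#' @param result An \code{\link{anova_result}}.
#' @param pair Character vector of two levels to compare (group labels, or
#'   the two condition names for \code{factor = "condition"}).
#' @param factor \code{"group"} or \code{"condition"}.
#' @return List with \code{estimate} (difference first minus second),
#'   \code{t}, \code{df}, \code{p}.
#' @export
fisher_lsd <- function(result, pair, factor = c("group", "condition")) {
  stopifnot(inherits(result, "anova_result"))
  factor <- match.arg(factor)
  dat <- result$data
  if (factor == "group") {
    if (length(pair) != 2L || !all(pair %in% levels(dat$group)))
      stop("'pair' must name two group levels", call. = FALSE)
    i <- match(pair, levels(dat$group))
    diff <- unname(dat$group_means[i[1L]] - dat$group_means[i[2L]])
    # subject means m have residual variance mse_between / 2
    se <- sqrt(result$mse_between / 2 *
                 (1 / dat$nj[i[1L]] + 1 / dat$nj[i[2L]]))
    tval <- if (se > 0) diff / se else if (diff == 0) 0 else Inf * sign(diff)
  } else {
    if (length(pair) != 2L || !all(pair %in% dat$cond_names))
      stop("'pair' must name the two conditions", call. = FALSE)
    sgn <- if (pair[1L] == dat$cond_names[1L]) -1 else 1
    # difference scores d = cond2 - cond1
    est <- if (result$ss_type == "III") mean(dat$diff_means)
    else mean(dat$d)
    diff <- sgn * est
    vfac <- if (result$ss_type == "III")
      sum(1 / dat$nj) / length(dat$nj)^2 else 1 / length(dat$d)
    se <- sqrt(2 * result$mse_within * vfac)
    tval <- if (se > 0) diff / se else if (diff == 0) 0 else Inf * sign(diff)
  }
  p <- 2 * stats::pt(-abs(tval), result$df_error)
  list(estimate = diff, t = tval, df = result$df_error, p = p)
}

#' Kolmogorov-Smirnov normality screen
#'
#' One-sample KS distance between the empirical distribution and a normal
#' law with mean and SD estimated from the same data, with the standard
#' asymptotic p-value. Because the reference parameters are estimated, the
#' p-value is conservative (the Lilliefors correction would be smaller);
#' it matches the screen conventionally reported alongside discounting
#' analyses ("d < 0.09, p > 0.20").
#'
#' @param values Numeric vector, n >= 5, non-constant.
#' @return List with \code{d} (KS distance) and \code{p}.
#' @export
ks_normality <- function(values) {
  if (!is.numeric(values) || length(values) < 5L)
    stop("need at least 5 numeric values", call. = FALSE)
  if (stats::sd(values) == 0)
    stop("constant input has no normal fit", call. = FALSE)
  res <- suppressWarnings(
    stats::ks.test(values, "pnorm", mean(values), stats::sd(values),
                   exact = FALSE))
  list(d = unname(res$statistic), p = res$p.value)
}
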