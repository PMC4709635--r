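# Choice-consistency auditing of subjective-value curves and raw choices.

#' Count inconsistent preferences along a discounting curve
#'
#' Discounting implies a monotone decrease of subjective value with delay,
#' so a value that exceeds the one at the preceding delay marks an
#' inconsistent preference. The lenient rule tolerates noise and only
#' counts increases above 10% of the future outcome R (i.e.
#' \eqn{R_2 > R_1 + R/10}; 4 euros for R = 40); the strict rule counts any
#' increase (\eqn{R_2 > R_1}). Only adjacent delays are compared.
#'
#' @param curve An \code{\link{sv_curve}} (sorted by gap on construction).
#' @param mode \code{"lenient"} or \code{"strict"}.
#' @param threshold_fraction Lenient threshold as a fraction of the later
#'   amount (default 0.1).
#' @return Integer count (0 for curves with fewer than 2 points).
#' @export
count_inconsistencies <- function(curve, mode = c("lenient", "strict"),
                                  threshold_fraction = 0.1) {
  stopifnot(inherits(curve, "sv_curve"))
  mode <- match.arg(mode)
  check_scalar(threshold_fraction, "threshold_fraction", nonneg = TRUE)
  if (length(curve$sv) < 2L) return(0L)
  jumps <- diff(curve$sv)
  thr <- if (mode == "lenient") threshold_fraction * curve$later_amount
  else 0
  sum(jumps > thr)
}

#' Full consistency report for one curve plus its session trials
#'
#' @param curve An \code{\link{sv_curve}}.
#' @param trials Optional trial table (see \code{\link{run_session}}) used
#'   for heuristic detection; controls are excluded there.
#' @return An object of class \code{consistency_report}: list with
#'   \code{n_lenient}, \code{n_strict} (n_strict >= n_lenient) and
#'   \code{heuristic}.
#' @export
consistency_report <- function(curve, trials = NULL) {
  rep <- list(n_lenient = count_inconsistencies(curve, "lenient"),
              n_strict = count_inconsistencies(curve, "strict"),
              heuristic = if (is.null(trials)) NA_character_
              else detect_heuristic(trials))
  structure(rep, class = "consistency_report")
}

#' Detect response heuristics in raw choices
#'
#' Flags subjects who always select the larger-delayed amount
#' (\code{"always_later"}) or always the smaller-sooner amount
#' (\code{"always_sooner"}) across the temporal conditions. Control blocks
#' are excluded: always taking the larger reward there is the expected,
#' task-comprehension behavior.
#'
#' @param trials Data frame with columns \code{condition} and
#'   \code{choice} (as produced by \code{\link{run_session}}), or a
#'   character vector of choices.
#' @return \code{"none"}, \code{"always_sooner"} or \code{"always_later"}.
#' @export
detect_heuristic <- function(trials) {
  choices <- if (is.data.frame(trials)) {
    keep <- if ("condition" %in% names(trials))
      trials$condition %in% c("now", "notnow") else TRUE
    trials$choice[keep]
  } else as.character(trials)
  if (length(choices) == 0L)
    stop("no temporal-condition trials to audit", call. = FALSE)
  if (all(choices == "later")) return("always_later")
  if (all(choices == "sooner")) return("always_sooner")
  "none"
}
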