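# Adjusting-amount staircase elicitation of indifference points.

#' Session design for the staircase task
#'
#' Defaults mirror the standard design: a 40-euro later reward, a sooner
#' amount starting at 20 euros, five choices per delay block, Now-condition
#' delays of 2, 14, 30, 90, 180 and 365 days, and a Not-now condition whose
#' sooner option is front-delayed by 60 days with later delays of 62, 74,
#' 90, 150, 240 and 425 days -- the same sooner-later gaps as the Now
#' condition. Two control blocks (both options immediate; both options at
#' 365 days) check that the larger reward is always taken.
#'
#' @param later_amount Later (larger) reward in euros.
#' @param start_sooner Sooner amount on the first trial of every block.
#' @param choices_per_block Trials per delay block (>= 1).
#' @param now_delays Later-option delays (days) in the Now condition.
#' @param notnow_sooner_delay Front-end delay (days) of the sooner option in
#'   the Not-now condition.
#' @param notnow_delays Later-option delays (days) in the Not-now condition;
#'   must equal \code{now_delays + notnow_sooner_delay} gap-for-gap.
#' @param include_controls Run the two control blocks?
#' @return An object of class \code{session_design}.
#' @export
session_design <- function(later_amount = 40, start_sooner = 20,
                           choices_per_block = 5L,
                           now_delays = c(2, 14, 30, 90, 180, 365),
                           notnow_sooner_delay = 60,
                           notnow_delays = notnow_sooner_delay + now_delays,
                           include_controls = TRUE) {
  check_scalar(later_amount, "later_amount", positive = TRUE)
  check_scalar(start_sooner, "start_sooner", positive = TRUE)
  if (start_sooner >= later_amount)
    stop("'start_sooner' must be below 'later_amount'", call. = FALSE)
  choices_per_block <- as.integer(choices_per_block)
  if (choices_per_block < 1L)
    stop("'choices_per_block' must be >= 1", call. = FALSE)
  if (any(now_delays <= 0) || is.unsorted(now_delays, strictly = TRUE))
    stop("'now_delays' must be positive and strictly increasing",
         call. = FALSE)
  check_scalar(notnow_sooner_delay, "notnow_sooner_delay", positive = TRUE)
  if (length(notnow_delays) != length(now_delays) ||
      any(abs((notnow_delays - notnow_sooner_delay) - now_delays) > 1e-9))
    stop("'notnow_delays' minus the sooner delay must equal 'now_delays'",
         call. = FALSE)
  structure(list(later_amount = later_amount, start_sooner = start_sooner,
                 choices_per_block = choices_per_block,
                 now_delays = now_delays,
                 notnow_sooner_delay = notnow_sooner_delay,
                 notnow_delays = notnow_delays,
                 include_controls = isTRUE(include_controls)),
            class = "session_design")
}

#' Staircase adjustment schedule
#'
#' The first adjustment is half the difference between the starting sooner
#' amount and the later amount; each subsequent adjustment is half the
#' previous one. With the defaults: 10, 5, 2.5, 1.25, 0.625 euros.
#'
#' @param design A \code{\link{session_design}}.
#' @return Numeric vector of length \code{choices_per_block}.
#' @export
step_schedule <- function(design) {
  stopifnot(inherits(design, "session_design"))
  (design$later_amount - design$start_sooner) /
    2^seq_len(design$choices_per_block)
}

#' Run one staircase block
#'
#' Titrates the sooner amount against a fixed later reward: after each
#' choice the sooner amount moves down (sooner chosen) or up (later chosen)
#' by the current step, halving the step each trial. The sooner amount that
#' would have been shown on the next trial after the block is the
#' indifference-point estimate (a bisection search, so for any deterministic
#' agent with monotone preference the estimate is within the final step --
#' 0.625 euros by default -- of the true indifference value).
#'
#' Equal sooner and later delays are allowed: the control blocks use them.
#'
#' @param agent A \code{\link{choice_agent}}.
#' @param sooner_delay,later_delay Delivery delays in days
#'   (\code{sooner_delay <= later_delay}).
#' @param design A \code{\link{session_design}}.
#' @param condition Label stored in the trial table.
#' @return List with \code{estimate} (euros) and \code{trials}, a data
#'   frame with one row per choice (trial, sooner_amount, sooner_delay,
#'   later_amount, later_delay, choice).
#' @examples
#' a <- choice_agent("hyperbolic", k = 0.02)
#' run_staircase(a, 0, 100, session_design())$estimate # 13.125
#' @export
run_staircase <- function(agent, sooner_delay, later_delay, design,
                          condition = "now") {
  stopifnot(inherits(agent, "choice_agent"),
            inherits(design, "session_design"))
  check_scalar(sooner_delay, "sooner_delay", nonneg = TRUE)
  check_scalar(later_delay, "later_delay", nonneg = TRUE)
  if (later_delay < sooner_delay)
    stop("'later_delay' must be >= 'sooner_delay'", call. = FALSE)
  steps <- step_schedule(design)
  n <- design$choices_per_block
  amount <- design$start_sooner
  sooner_amounts <- numeric(n)
  choices <- character(n)
  for (i in seq_len(n)) {
    sooner_amounts[i] <- amount
    choices[i] <- choose_option(agent,
                                sooner = c(amount, sooner_delay),
                                later = c(design$later_amount, later_delay))
    amount <- amount + if (choices[i] == "later") steps[i] else -steps[i]
  }
  trials <- data.frame(condition = condition, trial = seq_len(n),
                       sooner_amount = sooner_amounts,
                       sooner_delay = sooner_delay,
                       later_amount = design$later_amount,
                       later_delay = later_delay,
                       choice = choices, stringsAsFactors = FALSE)
  list(estimate = amount, trials = trials)
}

#' Subjective-value curve
#'
#' Per-condition list of (delay gap, indifference value) pairs -- the
#' output of elicitation and the input to fitting. Points are sorted by
#' gap; gaps must be distinct and values within [0, later_amount].
#'
#' @param condition Condition label (e.g. \code{"now"}, \code{"notnow"}).
#' @param delay_gap Delay gaps in days (distinct, > 0).
#' @param sv Indifference values in euros (same length).
#' @param later_amount The delayed reward the values refer to.
#' @return An object of class \code{sv_curve}.
#' @export
sv_curve <- function(condition, delay_gap, sv, later_amount = 40) {
  if (length(delay_gap) != length(sv) || length(sv) < 1L)
    stop("'delay_gap' and 'sv' must be nonempty and matched", call. = FALSE)
  if (anyDuplicated(delay_gap))
    stop("duplicate delay gaps", call. = FALSE)
  if (any(delay_gap <= 0)) stop("delay gaps must be > 0", call. = FALSE)
  check_scalar(later_amount, "later_amount", positive = TRUE)
  if (any(sv < 0) || any(sv > later_amount))
    stop("subjective values must lie in [0, later_amount]", call. = FALSE)
  o <- order(delay_gap)
  structure(list(condition = condition, delay_gap = delay_gap[o],
                 sv = sv[o], later_amount = later_amount),
            class = "sv_curve")
}

#' @export
print.sv_curve <- function(x, ...) {
  cat(sprintf("<sv_curve> condition '%s', later amount %g\n", x$condition,
              x$later_amount))
  print(data.frame(delay_gap = x$delay_gap, sv = x$sv), row.names = FALSE)
  invisible(x)
}

#' Run a full elicitation session
#'
#' One staircase per delay per temporal condition plus (optionally) the two
#' control blocks, with block order uniformly shuffled as in the task
#' (14 blocks with the defaults). Curves are indexed by the sooner-later
#' gap, so the Now and Not-now curves of a single-rate deterministic agent
#' coincide. Control blocks report whether the larger reward was chosen on
#' every trial.
#'
#' @param agent A \code{\link{choice_agent}}.
#' @param design A \code{\link{session_design}}.
#' @return List with \code{curves} (named list of \code{\link{sv_curve}}:
#'   now, notnow), \code{control_pass} (named logicals: immediate, delayed;
#'   NA when controls are off) and \code{trials} (data frame over all
#'   blocks in presentation order, with a \code{block} column).
#' @export
run_session <- function(agent, design = session_design()) {
  stopifnot(inherits(agent, "choice_agent"),
            inherits(design, "session_design"))
  blocks <- data.frame(
    condition = c(rep("now", length(design$now_delays)),
                  rep("notnow", length(design$notnow_delays))),
    sooner_delay = c(rep(0, length(design$now_delays)),
                     rep(design$notnow_sooner_delay,
                         length(design$notnow_delays))),
    later_delay = c(design$now_delays, design$notnow_delays),
    stringsAsFactors = FALSE)
  if (design$include_controls) {
    last <- max(design$now_delays)
    blocks <- rbind(blocks,
                    data.frame(condition = c("control_immediate",
                                             "control_delayed"),
                               sooner_delay = c(0, last),
                               later_delay = c(0, last)))
  }
  order_idx <- sample.int(nrow(blocks))
  estimates <- numeric(nrow(blocks))
  all_later <- logical(nrow(blocks))
  trial_list <- vector("list", nrow(blocks))
  for (pos in seq_along(order_idx)) {
    b <- order_idx[pos]
    res <- run_staircase(agent, blocks$sooner_delay[b],
                         blocks$later_delay[b], design,
                         condition = blocks$condition[b])
    estimates[b] <- res$estimate
    all_later[b] <- all(res$trials$choice == "later")
    res$trials$block <- pos
    trial_list[[pos]] <- res$trials
  }
  trials <- do.call(rbind, trial_list)
  trials <- trials[, c("condition", "block", "trial", "sooner_amount",
                       "sooner_delay", "later_amount", "later_delay",
                       "choice")]
  is_now <- blocks$condition == "now"
  is_nn <- blocks$condition == "notnow"
  curves <- list(
    now = sv_curve("now", blocks$later_delay[is_now] -
                     blocks$sooner_delay[is_now],
                   estimates[is_now], design$later_amount),
    notnow = sv_curve("notnow", blocks$later_delay[is_nn] -
                        blocks$sooner_delay[is_nn],
                      estimates[is_nn], design$later_amount))
  control_pass <- c(immediate = NA, delayed = NA)
  if (design$include_controls) {
    control_pass <- c(
      immediate = all_later[blocks$condition == "control_immediate"],
      delayed = all_later[blocks$condition == "control_delayed"])
  }
  list(curves = curves, control_pass = control_pass, trials = trials)
}
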