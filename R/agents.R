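# Generative intertemporal-choice agents.

#' Create a generative choice agent
#'
#' An agent discounts a delayed amount with a hyperbolic
#' (\eqn{SV = A/(1 + kD)}) or exponential (\eqn{SV = A e^{-kD}}) function of
#' the delay gap \eqn{D} (days) and chooses between a sooner and a later
#' monetary option. With \code{beta = Inf} (default) the agent
#' deterministically picks the option with the larger subjective value; with
#' finite \code{beta} the probability of taking the later option is
#' \code{plogis(beta * (SV_later - SV_sooner))}, a logistic (softmax) noise
#' model on the value difference in euros.
#'
#' @param model Discounting model, \code{"hyperbolic"} or
#'   \code{"exponential"}.
#' @param k Discount rate per day (> 0).
#' @param beta Choice-noise inverse temperature in 1/euro (>= 0).
#'   \code{Inf} means deterministic value maximization; \code{0} means
#'   random 50/50 choice.
#' @param tie_rule How a deterministic agent resolves exactly equal
#'   subjective values: \code{"later"}, \code{"sooner"}, or \code{"random"}.
#' @param k_notnow Optional second discount rate applied when the sooner
#'   option itself is front-delayed (sooner delay > 0), letting simulated
#'   subjects discount more shallowly when both options lie in the future.
#'   \code{NULL} (default) uses \code{k} in every frame.
#' @return An object of class \code{choice_agent}.
#' @examples
#' a <- choice_agent("hyperbolic", k = 0.01)
#' subjective_value(a, amount = 40, delay_gap = 100) # 20
#' @export
choice_agent <- function(model = c("hyperbolic", "exponential"), k,
                         beta = Inf,
                         tie_rule = c("later", "sooner", "random"),
                         k_notnow = NULL) {
  model <- match.arg(model)
  tie_rule <- match.arg(tie_rule)
  check_scalar(k, "k", positive = TRUE)
  check_scalar(beta, "beta", nonneg = TRUE, allow_inf = TRUE)
  if (!is.null(k_notnow)) check_scalar(k_notnow, "k_notnow", positive = TRUE)
  structure(
    list(model = model, k = k, beta = beta, tie_rule = tie_rule,
         k_notnow = k_notnow),
    class = "choice_agent"
  )
}

#' @export
print.choice_agent <- function(x, ...) {
  cat(sprintf("<choice_agent> %s, k = %g/day%s, beta = %s, ties -> %s\n",
              x$model, x$k,
              if (!is.null(x$k_notnow))
                sprintf(" (front-delayed frame: %g/day)", x$k_notnow) else "",
              if (is.infinite(x$beta)) "Inf (deterministic)"
              else format(x$beta), x$tie_rule))
  invisible(x)
}

# vectorized discount factor in (0, 1]
discount_factor <- function(model, k, delay_gap) {
  switch(model,
         hyperbolic  = 1 / (1 + k * delay_gap),
         exponential = exp(-k * delay_gap))
}

#' Subjective value of a delayed amount
#'
#' Scales the nominal amount by the agent's discount function of the delay
#' gap: \code{amount / (1 + k * D)} (hyperbolic) or
#' \code{amount * exp(-k * D)} (exponential). At zero gap the amount is
#' returned exactly.
#'
#' @param agent A \code{\link{choice_agent}}.
#' @param amount Monetary amount (> 0); vectorized.
#' @param delay_gap Delay gap in days (>= 0); vectorized.
#' @return Subjective value in (0, amount].
#' @export
subjective_value <- function(agent, amount, delay_gap) {
  stopifnot(inherits(agent, "choice_agent"))
  if (!is.numeric(amount) || any(amount <= 0))
    stop("'amount' must be positive", call. = FALSE)
  if (!is.numeric(delay_gap) || any(delay_gap < 0))
    stop("'delay_gap' must be non-negative", call. = FALSE)
  amount * discount_factor(agent$model, agent$k, delay_gap)
}

as_option <- function(x, name) {
  if (is.list(x)) x <- c(x$amount, x$delay)
  if (!is.numeric(x) || length(x) != 2L || any(is.na(x)))
    stop(sprintf("'%s' must be c(amount, delay)", name), call. = FALSE)
  list(amount = x[[1L]], delay = x[[2L]])
}

# Effective rate and SVs inside one trial frame: the sooner option is taken
# at face value; the later option is discounted by the gap between the two
# delivery times. Agents with a k_notnow rate use it whenever the sooner
# option is itself delayed.
trial_values <- function(agent, sooner, later) {
  if (sooner$amount <= 0 || later$amount <= 0)
    stop("amounts must be positive", call. = FALSE)
  if (later$delay < sooner$delay)
    stop("later option must not be delivered before the sooner one",
         call. = FALSE)
  k_eff <- if (sooner$delay > 0 && !is.null(agent$k_notnow))
    agent$k_notnow else agent$k
  gap <- later$delay - sooner$delay
  list(sv_sooner = sooner$amount,
       sv_later = later$amount * discount_factor(agent$model, k_eff, gap))
}

#' Probability that an agent takes the later option
#'
#' @param agent A \code{\link{choice_agent}}.
#' @param sooner,later Options as \code{c(amount, delay)} (euros, days).
#' @return P(later) in [0, 1]. Deterministic agents return 0, 1, or the
#'   tie-rule probability (0.5 for \code{tie_rule = "random"}).
#' @export
choice_probability <- function(agent, sooner, later) {
  stopifnot(inherits(agent, "choice_agent"))
  sooner <- as_option(sooner, "sooner")
  later <- as_option(later, "later")
  sv <- trial_values(agent, sooner, later)
  if (is.infinite(agent$beta)) {
    if (sv$sv_later > sv$sv_sooner) return(1)
    if (sv$sv_later < sv$sv_sooner) return(0)
    return(switch(agent$tie_rule, later = 1, sooner = 0, random = 0.5))
  }
  stats::plogis(agent$beta * (sv$sv_later - sv$sv_sooner))
}

#' Simulate one choice between a sooner and a later option
#'
#' Deterministic agents (\code{beta = Inf}) pick the larger subjective
#' value, resolving exact ties by their tie rule; noisy agents sample from
#' the logistic choice probability using R's global random number stream
#' (seed with \code{set.seed} for reproducibility).
#'
#' @inheritParams choice_probability
#' @return \code{"sooner"} or \code{"later"}.
#' @examples
#' a <- choice_agent("hyperbolic", k = 0.02)
#' choose_option(a, sooner = c(15, 0), later = c(40, 100)) # "sooner"
#' @export
choose_option <- function(agent, sooner, later) {
  p_later <- choice_probability(agent, sooner, later)
  if (p_later == 1) return("later")
  if (p_later == 0) return("sooner")
  if (stats::runif(1) < p_later) "later" else "sooner"
}
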