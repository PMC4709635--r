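---
title: "Methods: temporal discounting elicitation, model fitting, and lesion-symptom mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: temporal discounting elicitation, model fitting, and lesion-symptom mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(discountmap)
```

# The problem

In intertemporal choice, people trade off smaller-sooner against
larger-later rewards. The decline of a reward's subjective value with the
delay to its receipt is *temporal discounting* (TD): steeper discounting
means more impulsive choice. Lesion studies ask whether damage to a
specific brain region *causes* abnormal discounting, by comparing the
behavior of patients with and without damage at each brain location
(voxel-based lesion-symptom mapping, VLSM).

`discountmap` implements that full analysis chain as tested, seedable
code, together with a synthetic-data generator that stands in for patient
cohorts: since raw clinical data of this kind are not public, every
claim the package makes is certified on simulated cohorts whose ground
truth is known.

# Choice agents and the noise model

A simulated subject is a `choice_agent`: a discount function (hyperbolic
$SV = A/(1+kD)$ or exponential $SV = A e^{-kD}$, with $D$ the delay gap in
days and $k$ the discount rate per day), plus a choice rule. Within a
trial the sooner option is taken at face value and the later option is
discounted by the gap between the two delivery times, so an agent's
preferences depend only on the gap — the same convention the fitting
stage uses, which keeps simulation and estimation mutually consistent.

Humans are not deterministic, so agents accept an inverse temperature
$\beta$ (per euro): the probability of taking the later option is
$\mathrm{logit}^{-1}(\beta\,(SV_\text{later}-SV_\text{sooner}))$.
$\beta = \infty$ (the unit-test default) is deterministic value
maximization with an explicit tie rule; $\beta = 0$ is coin flipping. The
logistic form is a modeling choice — the behavioral task literature does
not specify a noise model — made because the tests need graded
stochasticity with a single interpretable knob.

The cohort default is $\beta = 2$ per euro. At that level choices more
than ~1 euro from indifference are nearly deterministic while the last
staircase steps remain noisy, which is the qualitative signature of real
adjusting-amount data. Two honest limitations of any single-$\beta$
logistic agent, documented rather than hidden: (i) near the staircase's
convergence point the value difference shrinks toward zero, so a noisy
agent occasionally violates dominance on late control trials (human
cohorts pass the control blocks universally); (ii) lenient inconsistency
counts (see below) come out near zero, lower than the ~0.6–1 per curve
reported for human groups. No single $\beta$ reproduces tight staircase
convergence, universal control passing, and human-scale inconsistency
rates simultaneously; we prioritize convergence quality, which is what
the recovery guarantees rest on.

Agents optionally carry a second rate `k_notnow`, used when the sooner
option itself is front-delayed. This reproduces the robust empirical
finding that discounting is shallower when both options are in the
future; without it, Now and Not-now curves of a deterministic agent
coincide exactly (a property the test suite asserts).

# The staircase task

Each delay block titrates the sooner amount against a fixed 40 € later
reward: five choices, starting at 20 €, the first adjustment half the
sooner–later difference and each later adjustment half the previous one
(10, 5, 2.5, 1.25, 0.625 € with the defaults). The would-be sixth-trial
amount is the indifference-point estimate. This is bisection: for any
deterministic agent with monotone preference the estimate is within the
final step (0.625 €) of the true indifference value, and estimates live
on a dyadic grid of 32 reachable values in [0.625, 39.375]. Both
properties are asserted exhaustively in the tests, and the second
explains the estimator's granularity floor: a fitted $k$ cannot be more
accurate than a 0.625 € grid allows, which is why the package's recovery
guarantee is stated in median relative error (15%), not per-subject
error.

A session runs six Now blocks (delays 2–365 days), six Not-now blocks
(sooner option at 60 days, same gaps), and two control blocks (both
options immediate; both at 365 days) in uniformly shuffled order.
Controls use the identical staircase; "pass" means the larger reward was
taken on all five trials. Equal delays are permitted in `run_staircase`
precisely for these blocks.

# Fitting, AUC, and summaries

Subjective values are converted to fractions of the later amount and the
discount rate is fitted by bounded least squares
($k \in [10^{-6}, 10]$/day) with a log-spaced multi-start grid followed
by golden-section refinement; for these monotone one-parameter models
that is exact enough that noiseless model data are recovered to
$10^{-6}$. $R^2 = 1 - SS_\text{res}/SS_\text{tot}$ is reported as
computed (it may be negative for a mis-specified model). A fit whose
optimum sticks to a bound — e.g. flat, non-discounting data pushing
$k \to 0$ — is flagged `converged = FALSE` rather than silently returned.

The model-free area under the discounting curve (AUC) normalizes delays
by the maximum delay and values by the later amount, then sums
trapezoids $(x_2-x_1)(y_1+y_2)/2$. The undiscounted anchor $(0, 1)$ is
prepended by default: without it the index cannot reach 1 even for an
agent who never discounts, contradicting the "varies between 0 and 1"
definition. Whether the original analyses included the anchor is not
stated anywhere we could verify, so the anchor is a flag
(`anchor = FALSE`) for sensitivity analysis. Because hyperbolic decay is
convex, trapezoid AUC of exact model points upper-bounds the analytic
integral — a property the tests check across the relevant $k$ range.

Discount rates are summarized by geometric means ($10^{\text{mean}
\log_{10} k}$), the standard central tendency for positively skewed
rates, and by the half-value delay ($1/k$ hyperbolic, $\ln 2/k$
exponential) — the delay at which the reward loses half its value, a
directly interpretable anchor (e.g. $k = 0.026$/day halves 40 € in about
38 days; $k = 0.011$/day in about 90).

# Consistency auditing

Discounting implies monotonically decreasing subjective value with
delay. The lenient rule counts adjacent-delay increases exceeding 10% of
the later amount ($R_2 > R_1 + R/10$, i.e. > 4 € here); the strict rule
counts any increase. Only adjacent delays are compared, and $R$ is the
condition's later amount, not a per-trial quantity. Separately, subjects
whose every temporal-condition choice is identical are flagged as
following a response heuristic (`always_later` / `always_sooner`);
control blocks are excluded from that audit since always taking the
larger reward there is the correct behavior.

A useful consequence of the staircase grid: deterministic agents can
never produce a strict violation, because adjacent estimates differ by
at least 1.25 € on the grid while their errors are at most 0.625 € each.
The tests assert this across the $k$ range.

# Group statistics

The group-level analysis is a split-plot ANOVA: one between-subject
factor (group) and one two-level within-subject factor (condition),
applied to $\log_{10} k$ and to AUC. With two within-subject cells the
design decomposes exactly into subject means (between part) and
difference scores (within part), which is how `mixed_anova` computes it —
no general linear-model solver, and the sum-of-squares table is
orthogonal because every subject contributes both conditions.

With unequal group sizes the condition main effect depends on the
sums-of-squares convention. The default is Type III (unweighted means),
switchable to Type I; the original analyses predate any statement of
their convention, so this is recorded as a package decision, not a fact
about the source analyses. Post hoc comparisons use Fisher's LSD —
deliberately uncorrected, as is traditional after a significant omnibus
F — against the split-plot error terms with $N - g$ degrees of freedom.
With exactly two groups the LSD p provably equals the omnibus p, which
the tests verify numerically.

The Kolmogorov–Smirnov normality screen estimates the reference normal's
parameters from the data, as the conventional "KS d, p" screen does.
That makes the asymptotic p conservative (the Lilliefors correction
would be smaller); the caveat is documented here on purpose, since the
screen is used only to justify parametric tests, where conservatism is
the safe direction.

# The synthetic cohort

`study_groups()` encodes the emulated study: an insular-lesion group
(n = 12), a non-insular lesion control group (n = 13), and healthy
controls (n = 64). Per-condition group mean $\log_{10} k$ values are set
to the published group geometric means (Now: 0.011, 0.066, 0.026/day;
Not-now: 0.005, 0.018, 0.014/day). Individual rates are log-normal:
$\log_{10} k \sim N(\mu_g, \sigma)$ — a modeling choice, since no
generative model of individual variability accompanies the published
summaries, but the natural one given that log-transformed rates pass
normality screens. The default $\sigma = 0.5$ was derived once by moment
matching: the published SD-to-geometric-mean ratios imply $\log_{10}$
SDs of roughly 0.42–0.75 across groups and conditions.

Lesions are axis-aligned random boxes on a 20×20×20 grid of 3 mm
voxels — deliberately simple geometry, sufficient for testing VLSM
recovery and nothing more. The critical region is an 8×8×8 box.
`"critical"` placement draws a lesion that *covers* the critical region
(edge lengths 6–12 voxels, raised to the region width where needed):
the behavioral coupling (`effect_delta_log10_k`, the shift in mean
$\log_{10} k$ for critically lesioned subjects) is defined at the region
level, so a "critically lesioned" subject is damaged throughout the
region. Partial-overlap placement was tried and rejected: it dilutes the
per-voxel lesioned/spared contrast with mixed-membership groups and
makes region recovery unreliable at clinical sample sizes. `"elsewhere"`
placement rejection-samples until the lesion misses the region entirely.
At 3 mm voxels the default boxes have volumes around 20–30 cc, the scale
of real middle-cerebral-artery stroke lesions. What this generator does
*not* emulate: anatomically shaped lesions, spatial correlation
structure between neighboring patients' lesions beyond box overlap,
registration error, or partial-volume effects — so a green recovery test
certifies the *statistical machinery*, not robustness to realistic
lesion anatomy.

# VLSM

At every voxel lesioned in at least 20% of patients (and spared by at
least two), patients lesioned there are compared to patients spared
there on the behavioral score with the Brunner–Munzel rank test: the
relative effect $\hat p = P(X < Y) + \tfrac12 P(X = Y)$ estimated from
midranks, rank-based variance, Satterthwaite degrees of freedom. The
statistic is signed (mean rank of lesioned minus spared), so maps for
$k$ and for AUC naturally carry opposite signs for the same anatomy.

**p-values.** The published t-approximation of the Brunner–Munzel
statistic is anticonservative in the far tail at cohort sizes of a few
dozen — exactly the regime where FDR thresholds live — which we measured
directly during development (and which destroys null calibration of the
significance maps if ignored). For tie-free scores the exact permutation
distribution of the relative effect is the Wilcoxon rank-sum law, so the
voxelwise p defaults to that exact law (`p_method = "exact_rank"`), with
the t-approximation as the fallback for tied scores and available as an
option. `brunner_munzel()` itself reports the published t-based p
(floored at the attainable permutation minimum $2/\binom{N}{n_1}$, and
falling back to that bound under complete separation, where the t
formula is undefined).

Significance is controlled by Benjamini–Hochberg FDR at $q = 0.05$
across included voxels, followed by a 50-voxel cluster extent threshold
on the surviving map (the ordering — extent after FDR — is a package
decision; the source procedure does not state it). Components are found
under 26-connectivity by default (standard in lesion mapping),
configurable to 18 or 6. Clusters report size, the signed statistic of
largest magnitude, and a $|statistic|$-weighted center of mass in world
mm through the mask's axis-aligned affine. The power map marks voxels
whose lesioned/spared split could reach $q$ at all under the most
extreme rank separation (minimal attainable two-sided p
$2/\binom{n}{n_2} \le q$); significant voxels are by construction a
subset of powered voxels, which are a subset of included voxels.

Voxels sharing a lesion pattern across patients are tested once and
share the result, which makes cohort-scale maps fast without changing
any value.

# Determinism and numerics

Every stochastic stage draws from R's global RNG under seeds spawned
deterministically from one master seed (`spawn_seeds`), so a fixed seed
reproduces the entire experiment — cohort, trials, fits, maps — exactly,
and per-subject streams can be rerun in isolation. Staircase amounts are
dyadic rationals (multiples of 0.625 €), exactly representable in
floating point, so estimates carry no accumulation error. The discount-
rate optimizer works on $\log_{10} k$ with a bracketed golden-section
search at tolerance $10^{-12}$.

# Known limitations

- The noise model is a single logistic $\beta$; see the agent section
  for the behavioral signatures it cannot reproduce simultaneously.
- The KS screen is conservative by construction (estimated parameters).
- The published group-level F statistics and cluster coordinates depend
  on the unavailable raw patient data and are out of scope: the package
  reproduces the *pipeline* and certifies it on synthetic ground truth,
  not the original numbers.
- Lesion geometry is deliberately schematic (boxes); anatomical realism
  and template registration are out of scope.
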