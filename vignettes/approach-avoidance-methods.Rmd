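---
title: "Models and methods behind aacsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind aacsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aacsim)
```

# The task model

`aacsim` simulates and analyzes a token-foraging game that puts reward
seeking and predator avoidance in direct conflict. A player rests in a safe
place; up to six reward tokens per epoch appear at random times on the left
or right; collecting a token requires leaving the safe place, where a
"sleeping predator" can wake at any moment. A wake-up means certain capture
and the loss of every token collected in that epoch. The design crosses
**threat level** (the predator's wake-up hazard: 0.1, 0.2 or 0.3 per 100 ms
outside the safe place) with **potential loss** (the 0–5 tokens already
held), giving an 18-cell within-subject design. A companion task (the safe
predator exposure task) uses the same screen but the player can only try to
"expose" the awake predator with up to six key presses per epoch, each
succeeding with the threat level's wake-up probability; tokens still appear
but are explicitly irrelevant.

## Timing

Token availability is exponential with mean 1.25 s; the wait before each
token is the same exponential plus 500 ms. A Task-1 block has 45 epochs,
balanced 15/15/15 over threat levels and shuffled (the randomization scheme
is a package choice; only balance matters downstream). The hazard is
realized in discrete 100-ms steps, matching the unit in which it is
defined: an excursion of `d` ms contributes `floor(d/100)` Bernoulli steps,
so survival over 1 s at the highest threat is exactly `0.7^10`.

## The foraging agent

The simulated agent stands in for a human player, healthy or lesioned. Its
decision component is deliberately matched to the analysis that will be run
on the data. The decision readout scores, for each possible token `i`,
whether the player collected at least `i` tokens — a cumulative quantity.
The agent therefore forages sequentially: it keeps collecting until its
first decline and then sits out the epoch, and its conditional continue
probabilities are derived from a *marginal* model
`P(collect >= i) = plogis(b0 + b_t * threat + b_l * (i - 1))` with threat
coded -1/0/1. Two consequences drove this choice:

* the quantity the readout estimates is exactly the quantity the policy
  parameterizes, so an agent with `approach_coef_loss = 0` yields a flat
  reconstructed approach profile and a fitted loss slope of 0 — parameter
  recovery is meaningful;
* a per-token independent-Bernoulli agent would *mechanically* produce a
  declining cumulative profile (a binomial tail) even with zero loss
  sensitivity, confounding lesion perturbations with arithmetic.

When the marginal probabilities increase between consecutive tokens the
conditional probability is capped at 1; the marginal model is then not
attainable exactly (a documented property of increasing profiles, which the
default and lesion policies avoid).

Approach latency (token onset to leaving the safe place) is Gaussian,
linear in threat and loss, truncated to the token's availability window —
a decision to approach always yields a collection, so catches are the only
censoring mechanism, exactly as in the analyzed design. Return latency
(collection to re-entering) is Gaussian truncated at 1 ms and sets the
exposure time to the hazard. Defaults (`approach_policy()`): intercept 2.2,
threat coefficient -0.8, loss coefficient -0.45 on the logit scale, giving
approach proportions from ~0.95 (low threat, nothing to lose) to ~0.30
(high threat, five tokens at stake); approach latency 450 ms with -30
ms/threat and -25 ms/loss; return latency 150 ms with -10 ms/threat and
-5 ms/loss (escape vigor rises with danger); shared noise SD 80 ms. These
produce realized catch rates of roughly 11/18/29 % per excursion across
threat levels — catch risk that is real but leaves enough uncaught epochs
to analyze.

In Task 2, press times are a two-component process: with probability `w` a
press is uniform over the epoch timeline (token-unrelated checking),
otherwise it is an exGauss-delayed reaction to a token onset. After a
successful exposure the key is disabled but the epoch's token schedule
still runs to its end; keeping the epoch timeline identical across epochs
makes the uniform null well defined. (A live game would advance to the next
epoch; nothing downstream depends on that difference because presses cannot
occur after a success either way.)

## Cohorts and lesion agents

`simulate_cohort()` draws each control's policy around a control mean
(between-subject SDs on a subset of parameters) and builds each patient
from explicit parameter perturbations — an attenuated loss coefficient, a
slowed return, a smaller exposure-response decay rate, and so on. One
master seed spawns per-subject seeds, so cohorts are exactly reproducible.
Memory ratings of catch probability are a clipped linear function of the
true catch rate; the defaults (slope 0.99, intercept +36.3 percentage
points) reproduce the near-unit slope with substantial overestimation seen
in healthy players of this game.

# Readout extraction

* **Decisions**: six records per epoch, record `i` scoring
  `collected >= i`, with potential loss `i - 1`. Caught epochs cannot be
  reconstructed and contribute nothing.
* **Latencies**: approach latencies are analyzed only strictly inside
  (150, 2000) ms and return latencies strictly inside (0, 2000) ms — the
  bounds themselves are excluded; the windows are read as strict because
  they are stated as strict inequalities. The sixth token is excluded from
  all latency analysis (its design cells are too often empty). Excluded
  records are kept with audit flags rather than dropped.
* **True catch rates**: catches over excursions per threat level, undefined
  (not zero) for levels without excursions.
* **Performance QC**: a control is excluded when its approach-and-survive
  count is more than 4 SD below the leave-one-out mean of the remaining
  controls, iterated to a fixed point; a zero leave-one-out SD never
  excludes.

# Condition-effects statistics

The group analysis is a linear mixed model with crossed fixed factors
(threat x loss, optionally x group) and a random subject intercept, fitted
by `lmerTest`. F tests use a single un-partitioned residual variance and
Satterthwaite denominator degrees of freedom. For the approach-proportion
outcome, which enters as 18 condition means per subject, p values are
additionally Greenhouse–Geisser corrected: epsilon is estimated per effect
from the subject-by-condition means (`tr(CSC')^2 / (q tr((CSC')^2))` with
orthonormal effect contrasts `C`, clipped to `[1/q, 1]`) and multiplies
*both* degrees of freedom of the F test. Group-by-within interactions use
the within-effect's epsilon, as in split-plot ANOVA. A companion model with
numeric codes (threat -1/0/1, loss 0–5) supplies the linear-contrast rows.

Per-subject summary statistics — the inputs to the single-case analysis —
are ordinary least-squares slopes of the subject's condition means on loss
(or on the threat code), or the subject's overall mean. OLS per subject was
chosen over mixed-model BLUPs to keep single-case values model-independent;
shrinkage toward the group mean is exactly what a single-case comparison
must avoid.

# Single-case machinery

A patient's score is located in its own control group as a percentile rank
with midrank tie handling: `100 * (#below + 0.5 #ties) / n`. Under
exchangeability the rank is uniform over the `n + 1` interleaving slots —
`null_rank_pmf()` is this exact distribution.

The **ordinal dissociation test** compares
`mean(ranks_A) - mean(ranks_B)` between two groups of patients, each
member ranked within its own (possibly different-sized) control group,
against the same statistic computed in simulated control-only worlds of the
empirical group sizes. Because the statistic is purely ordinal, the null
depends only on those sizes, so the simulation draws ranks directly from
the exchangeability pmf — equivalent to resampling raw control scores but
distribution-free, and invariant under any monotone transform of the
underlying scores. The p value uses the add-one estimator
`(1 + #{null >= obs}) / (n_sim + 1)` (default 10,000 simulations), which
never returns 0. The default is one-sided in the direction of the stated
hypothesis, configurable to two-sided; group scores aggregate as the mean
of member ranks. Both choices are defaults rather than derivations — the
procedure is reported with directional hypotheses and does not further
specify multi-patient aggregation — and both are exposed as arguments.

# The exposure-time model

For every exposure press after the first token, `T2` is the time since the
most recent token onset. Two empirical nulls formalize "presses are
unrelated to tokens": fresh epoch timelines with uniformly scattered
presses (`uniform_time`, simulated from the task timing model rather than a
closed form), and re-pairing observed press times with token streams of
other observed epochs (`permutation`). Distributional comparisons use
standard KS tests (one-sample against the empirical null CDF, two-sample
between groups) and a t test on per-subject means.

The generative model fitted to `T2` is a weighted mixture,

```
p(t) = w * f_null(t) + (1 - w) * f_exG(t; mu, sigma, lambda),
```

with the exponentially modified Gaussian in the (Gaussian mean `mu`,
Gaussian SD `sigma`, exponential rate `lambda`) parameterization. The
exact formulas of the source analysis are not printed in accessible form,
so the mixture is reconstructed from its verbal description and parameter
list; the parameterization is the standard response-time one. Both
components are renormalized over the observed latency window so the
likelihood is proper under truncation. The exGauss log-density needs care:
the textbook formula loses all floating-point precision when
`lambda * sigma` is large, so the implementation switches to a Mills-ratio
asymptotic expansion in that regime — without this the optimizer can climb
into regions where rounding noise looks like likelihood.

Maximum likelihood uses box-constrained quasi-Newton optimization on
transformed parameters (logit `w`, log `sigma`, log `lambda`) from a
moment-based start plus seeded jittered restarts (10 by default). Pure-null
data drive `w` to its upper bound; the exGauss parameters are then
unidentifiable and the fit is flagged rather than trusted.

Model variants share all four parameters between groups ("combined") or
split `lambda`, `mu`, `sigma`, `w`, or `lambda` and `w`. All five splits
are implemented even though the verbal description lists slightly
different subsets in different places. Evidence is compared through
`BIC = k log n - 2 logLik` and log Bayes factors
`LBF = 0.5 * (BIC_ref - BIC)` against the combined model, with
`|delta LBF| > 3` between best and second best flagged as decisive.

# Problem sizes and verification

The test suite verifies, among others: the per-step activation hazard and
token timing against their configured values within 3 SE (>= 10,000 steps /
tokens); exact inversion of the simulator by the decision reconstruction;
agreement of the Monte-Carlo dissociation p with full enumeration for
control groups up to size 4 and a type-I error within [0.03, 0.07] at
alpha = 0.05 over 1,000 null replicates (control groups of 10 and 9, one
patient per side); mixture parameter recovery at n = 2000 with median
relative error under 15% over 20 replicates, and BIC selection of the
generating lambda-split variant in >= 80% of 20 replicates; and the two
analytic Greenhouse–Geisser regimes (sphericity and rank-one covariance)
to 1e-10. These sizes are the package's chosen verification conditions;
they keep the full suite in the minutes range on one CPU.

# What the generator does and does not emulate

The simulator reproduces the task's printed constants (hazards, timing,
counts, attempt caps), linear condition effects on decisions and
latencies, censoring by capture, heterogeneous control groups, lesion-like
parameter perturbations, and a two-process exposure-press mechanism. It
does **not** emulate: learning or adaptation across epochs (policies are
stationary; real players learn the color–threat mapping), serial
correlation beyond the within-epoch stopping rule, motor noise in
grid movement (movement is an abstraction over three positions: safe,
left, right — a simplification that preserves every analyzed quantity),
wall-clock epoch duration limits (epochs end with the sixth token cycle),
or any neural quantity. Green tests therefore certify the procedures and
their calibration on data of known structure — not clinical conclusions,
which require real patients.

# Known limitations

* The marginal-logistic stopping agent cannot represent non-monotone
  foraging (skip a token, then resume); the analysis pipeline handles such
  behavior in imported logs, scoring it cumulatively.
* Epsilon estimates for the threat-by-loss interaction need complete
  18-cell subject means; subjects with empty cells are dropped from the
  epsilon estimate (not from the model).
* The permutation null's construction in the original line of work is not
  fully specified in accessible text; the re-pairing scheme here is a
  reasonable stand-in and is labelled as such.
* With a single patient per group the between-group t test on mean
  exposure times is undefined and omitted; the KS tests remain available.
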