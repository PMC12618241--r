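---
title: "Modelling asymmetric learning and changepoint adaptation in transitive inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling asymmetric learning and changepoint adaptation in transitive inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tiadapt)
```

## The scientific problem

In transitive-inference (TI) learning, an agent observes binary feedback
about comparisons between items of *neighbouring* rank in a latent
hierarchy and must infer unseen relations between *non-neighbouring*
items (knowing A < B and B < C licenses A < C).  A robust empirical
finding is that humans learn such hierarchies with an *asymmetric*
update rule: the winner of a comparison is revalued more strongly than
the loser.  This package implements a task and model family for asking
what that asymmetry costs (or buys) when the hierarchy itself *changes*:
halfway through a session one anchor item moves to the opposite end of
the scale, either the bottom item rising to the top ("up") or the top
item falling to the bottom ("down").  A winner-biased learner should
accommodate the "up" change almost for free — it only has to keep
inflating one item — but the "down" change forces it to do the thing it
is bad at, revaluing a loser downward, and the resulting mis-allocation
of updates propagates compression through the whole value space and
damages inference even about items whose ranks never changed.

## The task

`generate_session()` builds a 7-item session of 6 blocks x 54 trials.
Each block contains every one of the 21 unordered item pairs once per
half-block ("sub-block"), plus one extra presentation of each of the 6
adjacent pairs per sub-block, with left/right placement mirrored between
sub-blocks — 24 feedback (adjacent) and 30 silent (TI) trials per block.
Feedback is determined solely by rank adjacency under the hierarchy *in
force*, so after the block-4 changepoint the feedback structure changes
minimally: both conditions gain the former-top-vs-former-bottom pair,
and each condition loses exactly one old adjacent pair.  Trials are
labelled `pre`/`post` around the first changepoint-block presentation of
the moved-anchor pair, regardless of the response made on it.

Design choices the task description leaves open, fixed here once:

* sub-blocks are shuffled independently and uniformly from a
  session-level seeded RNG;
* left/right placement in sub-block 1 is uniform per pair, and
  sub-block 2 is its deterministic mirror;
* the extra adjacent-pair presentations are placed one per sub-block
  (one per left/right orientation);
* simulated agents respond on every trial by default; a `miss_rate`
  can inject missed responses for testing the inclusion filter.

Timing parameters of the on-screen task (0.5 s fixation, 2.5 s response
window, 0.6 s inter-trial interval) are documentation only — nothing in
the package runs in real time.

## The model family

All four agents share one stepping engine.  On every trial the
probability of choosing the higher item is logistic in the value
difference,

$$p_t(x > y) = \frac{1}{1 + e^{-(Q_t(x) - Q_t(y))/\tau}},$$

and on feedback trials the winner $x$ and loser $y$ are updated with a
difference-weighted Rescorla–Wagner rule

$$Q_{t+1}(x) = Q_t(x) + \alpha^{+}\,[\,1 - d_t - Q_t(x)\,], \qquad
  Q_{t+1}(y) = Q_t(y) + \alpha^{-}\,[-1 + d_t - Q_t(y)\,],$$

where $d_t = \eta\,[Q_t(x) - Q_t(y)]$ scales updates by how expected the
outcome was.  Because $d_t$ can overflow the $\pm 1$ targets, the winner
update is clipped below at 0 and the loser update above at 0: feedback
can never move the winner down or the loser up.  Both updates share the
same pre-update $d_t$ and are applied simultaneously.

The family members differ only in how $(\alpha^{+}, \alpha^{-})$ are
supplied:

| model | rates | free parameters (k) |
|---|---|---|
| `qsymm` | $\alpha^{+} = \alpha^{-} = \alpha$ | $\alpha, \eta, \tau$ (3) |
| `qasymm` | free static pair | $\alpha^{+}, \alpha^{-}, \eta, \tau$ (4) |
| `qasymm2` | separate pairs before/after the changepoint | 2 pairs $+\ \eta, \tau$ (6) |
| `qadapt` | trial-wise split of a signed base rate | $\alpha^{0}, \omega, \eta, \tau$ (4) |

`qadapt` computes, on each feedback trial, a modulator
$\lambda = -4\omega p^2 + 4\omega p + 1 - \omega \in [1-\omega,\, 1]$
from the pre-update probability $p$ assigned to the feedback winner
(the choice of reference is immaterial for $\lambda$, which is symmetric
under $p \leftrightarrow 1-p$), and splits the base rate as
$\alpha^{+}_t = \alpha^{0}(1+\lambda)/2 - \min(\alpha^{0}, 0)$,
$\alpha^{-}_t = \alpha^{0}(1-\lambda)/2 - \min(\alpha^{0}, 0)$.  The
rates always sum to $|\alpha^{0}|$ and the sign of $\alpha^{0}$ fixes
which dominates: adaptation can soften but never reverse the bias.
Strong preferences ($p$ near 0 or 1) shrink $\lambda$ and make updating
more symmetric; indifference ($p = 0.5$) leaves it fully asymmetric.

The learning-rate asymmetry is summarised by
$A = (\alpha^{+} - \alpha^{-}) / |\alpha^{+} + \alpha^{-}|$: $+1$ full
winner bias, $-1$ full loser bias.

Deliberate omissions: the episodic "pair-level" learning component known
to improve fits of direct comparisons is out of scope here (the model
space isolates asymmetric value learning), and the entropy-based variant
of the $\lambda$ function is noted but not implemented.

Numerical conventions: values start at $Q = 0$ for all items (the
symmetric mid-point of the bounded scale); `qasymm2` switches to its
post rates *on* the first moved-anchor feedback trial (that trial is
already labelled `post`); updates are keyed to the feedback outcome,
never to the simulated choice, so the predicted probability sequence is
independent of the responses — which is also why fitting can evaluate
the engine once per parameter vector.  The engine exists twice, as a
compiled Rcpp path used by the fitter and a pure-R reference
(`simulate_agent()`) that also exposes the latent trace
$(Q, d_t, \lambda_t, \alpha^{+}_t, \alpha^{-}_t)$; the test suite holds
the two equal to machine precision.

## Fitting and model comparison

`fit_model()` minimises the negative log-likelihood of a participant's
trial-level responses over the bounded parameter space —
$\alpha^{\pm} \in (0, 0.5)$, $\alpha^{0} \in (-0.5, 0.5)$,
$\eta \in (0, 10)$, $\tau \in (0, 1]$ with a $10^{-9}$ floor excluding
the deterministic-choice degenerate limit — using an authored
differential-evolution optimiser (rand/1/bin, population $15 \times$
dimension, 500 generations by default, seeded and reproducible),
followed by a bounded L-BFGS-B polish.  Model-predicted probabilities,
not sampled choices, enter the likelihood, and probabilities are floored
at $10^{-12}$ before the log.  Missed trials contribute neither updates
nor likelihood.  Both feedback and silent TI trials contribute to the
likelihood by default (`likelihood = "feedback"` restricts the sum for
sensitivity analyses, since descriptions of such fitting procedures do
not always pin this down).  `fit_models()` fits the family in nesting
order and warm-starts each richer model from the optimum of the models
it nests (`qsymm` $\subset$ `qasymm` $\subset$ `qasymm2`, plus the
one-sided `qadapt` collapse at $\omega = 0$), which keeps the analytic
ordering $\mathrm{nll}(\texttt{qasymm}) \le \mathrm{nll}(\texttt{qsymm})$
intact even at reduced iteration budgets.  Pre-changepoint-only fits
truncate the session at the phase boundary; post-only fitting is
rejected because the pre-changepoint value history would be missing, and
`qasymm2` refuses datasets without a changepoint (its post rates would
be inert).

Evidence is approximated per participant as $-\mathrm{AIC}/2$
($\mathrm{AIC} = 2\,\mathrm{nll} + 2k$; BIC is also reported).
`rfx_bms()` then performs random-effects Bayesian model selection:
a variational Dirichlet–multinomial scheme (uniform prior concentration
1 per model, tolerance $10^{-6}$, iteration cap $10^4$) yields posterior
frequencies; exceedance probabilities come from the exact Beta integral
for two models and from $10^6$ seeded Dirichlet draws otherwise; the
Bayes omnibus risk (BOR) compares the variational free energy of the
random-effects model against the fixed equal-frequency null; and the
protected exceedance probability is
$\mathrm{pxp} = \mathrm{xp}\,(1 - \mathrm{BOR}) + \mathrm{BOR}/M$.
Only within-participant evidence differences matter: pxp is invariant to
per-participant offsets, which the tests verify.

## Behavioural metrics

* **Inclusion filter**: a participant is retained iff their
  pre-changepoint correct count reaches the smallest $k$ with exact
  binomial tail $P(X \ge k \mid n, 0.5) < 0.01$ ($n$ = scoreable
  pre-changepoint trials), and their missed-response proportion over the
  observed trial count does not exceed 0.6.  Both denominators come from
  the data, never from a hard-coded session length.
* **Value-compression (asymmetry) slope**: OLS slope of per-pair TI
  accuracy on *combined pair value*, operationalised as the sum of the
  two items' pre-changepoint ground-truth ranks (a mean-rank variant is
  a trivial rescaling).  Negative slopes mark winner bias, positive
  slopes loser bias.  Per-pair accuracies are participant-level means.
* **Symbolic distance effect**: OLS slope of per-pair accuracy on
  ordinal distance.
* **Sliding TI accuracy**: trailing (right-aligned) windowed mean,
  default 70 trials, over each category's own trial sequence, indexed
  relative to the first post-changepoint trial.  The low/mid/high
  categories are tertiles of combined rank over the six non-anchor TI
  pairs: {(2,4),(2,5)}, {(2,6),(3,5)}, {(3,6),(4,6)}.
* **Choice matrix**: mean probability of choosing the row-rank item over
  the column-rank item (pre-changepoint ranks), antisymmetric by
  construction, averaged cellwise over participants.
* **Anchor preference**: probability of choosing a former anchor on
  silent trials containing it, excluding the anchor-vs-anchor pair, per
  phase.
* **Nonparametric effect sizes**: $r = z/\sqrt{N}$ with $z$ from the
  normal approximation of the signed-rank / rank-sum statistic and a
  10,000-resample seeded bootstrap CI.  Standard tests themselves
  (t, ANOVA, Wilcoxon, Mann-Whitney, Spearman) are deliberately left to
  stock routines; only the bespoke metrics are implemented here.

The non-anchor item set is fixed to pre-changepoint ranks 2–6
throughout.

## The synthetic cohort generator

`generate_cohort()` stands in for a human cohort: each synthetic
participant gets a fresh randomised session (own item-to-rank allocation
and trial order), parameters drawn uniformly from a preset box, and
either exact model probabilities or Bernoulli-sampled binary choices.
The `winner` preset ($\alpha^{+} \sim U(0.15, 0.4)$,
$\alpha^{-} \sim U(0, 0.1)$, $\eta \sim U(1, 2.5)$,
$\tau \sim U(0.1, 0.3)$) emulates the winner-biased regime reported for
human TI learners; `loser` is its mirror; `uniform` spans the interior
of the fitting bounds.

The $\eta$ cap at 2.5 is a stability constraint, not a tuning knob: the
winner update moves $Q(x)$ toward the target $1 - d_t$ with gain
$\alpha^{+}$, and for $\alpha^{+}\eta > 1$ a surprising outcome (large
negative $d_t$) can overshoot so strongly that post-changepoint
"down" sessions enter a runaway re-inflation cascade — each item leaps
above the previously inflated one, value spacings diverge far beyond the
model's $\pm 1$ scale and choices become deterministic.  Fitted human
parameters do not occupy that divergent regime, so a generator meant to
emulate them must stay in the non-overshooting region
$\alpha^{+}\eta \le 1$.

What the generator does *not* emulate: reaction times, attention-check
behaviour, episodic pair memory, fatigue or drift in motivation, and any
within-participant correlation structure beyond the model itself.
Passing tests on synthetic cohorts therefore demonstrate that the
pipeline recovers what the generating process put in — not that human
data obey the models.

## Recovery suites

`model_recovery()` simulates agents per generating model, fits all
candidates to each, and tallies winners by AIC (or BIC); ties within
$10^{-6}$ go to the simpler model.  Each generating model is sampled
where it is identifiable in principle: notably, `qasymm` draws
$\alpha^{-} \sim U(0.08, 0.2)$ because at $\alpha^{-} = 0$ it coincides
exactly with `qadapt` at $\omega = 0$ and the generating model would be
undecidable; `qasymm2` is sampled with a pre-to-post bias reversal so
its extra rates matter; `qadapt` with $\omega \in (0.7, 1)$ so its
trial-wise modulation is expressed.  Residual `qsymm`/`qasymm`
confusion is the expected nesting ambiguity: under a true symmetric
generator the likelihood-ratio gain of the extra rate exceeds the AIC
margin on a minority of runs.  `parameter_recovery()` reports
generating-vs-recovered Spearman correlations per parameter (and for the
`qasymm` asymmetry index $A$).  `generative_check()` closes the loop by
simulating fitted parameters on the fitted participants' sessions and
re-deriving the behavioural metrics from the simulated probabilities.

## Problem sizes and budgets

The shipped tests run the full pipeline at desk scale, as a package
design choice: recovery suites use 5 agents per generating model
(model recovery) and 20 agents (parameter recovery) at the full 324
trials per session, with the optimiser reduced to 60 generations and
population 16 plus the L-BFGS-B polish; the nesting property uses 20
synthetic datasets; the direction-asymmetry property uses 50 sampled
parameter sets.  Larger runs only sharpen the same statistics.

## Known limitations

* The BMS implementation follows the standard variational scheme; exact
  numerical agreement with any particular external toolbox build is not
  claimed beyond the calibration properties verified in the tests.
* The rank-sum/signed-rank $z$ uses the normal approximation without
  tie corrections; with heavily tied data the bootstrap CI is the more
  trustworthy summary.
* Imported CSVs must contain the block structure of this task family
  (the hierarchy is inferred from the `correct_item` pattern); arbitrary
  external trial schedules need an import adapter.
* `run_pipeline()` is a thin, reproducible driver for the common
  simulate–filter–fit–compare–analyse path; bespoke analyses should call
  the stage functions directly.
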