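---
title: "Models and methods behind goalpursuit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind goalpursuit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(goalpursuit)
```

## The task

An agent fills a "net" with one kind of good over a sequence of trials. On
every trial three goods carry offers (quantities added to the net if chosen);
only one kind of good may accumulate, so choosing a different good from the
one in the net forfeits all accumulated contents. Completing a net — reaching
its target size — earns one point and starts a fresh block. Offers evolve as
independent Gaussian random walks (variance 0.8 points² per trial) around
block-specific starting levels drawn from N(6, 1), and on each trial each
offer independently jumps with probability 0.1 up / 0.1 down to a level
3–9 points above/below its block-start offer. Net sizes are uniform on
[12, 72], rounded to integers (nets are discrete quantities on screen; the
offers are kept continuous). Offers are not clipped and can be negative;
choosing a negative offer drains the net, but an empty net cannot lose more
(the floor is zero), and overshooting the net size counts as completion.

Schedules are rejection-sampled: a candidate block is accepted only if a
greedy tree-search agent (below) completes its net in strictly more than 3
and strictly fewer than 15 trials, so that completion is non-trivial but
feasible. The standard session is 45 accepted blocks of 100 trials,
truncated to a fixed session horizon (e.g. 300 trials); agents do not reason
about the horizon.

Two interpretation choices in the generator deserve note. First, the jump
reference: a jump lands relative to the option's *block-start* offer (not
its pre-jump level), and the walk then continues from the landed value; a
later jump again references the block-start offer. Second, inside planner
rollouts (below), the offer level at rollout start plays the role of the
start offer.

## Valuation models

Four models assign values to the three goods in a state
(net size $N$, accumulated $a$, offers $o_g$):

* **offer-max** — $v_g = o_g$; ignores the net entirely.
* **myopic** — $v_{\text{goal}} = a + o_{\text{goal}}$, $v_{\text{alt}} =
  o_{\text{alt}}$; maximizes the post-choice net on the current trial.
* **simple prospective** — values offers as proportions of net filled:
  $v_{\text{goal}} = o_{\text{goal}} / (N - a)$ (progress through the
  *remaining* net) and $v_{\text{alt}} = o_{\text{alt}} / N$. Negative
  offers would invert this ranking, so a negative alternative offer keeps
  its raw value and a negative goal offer is valued as the proportion of
  progress destroyed, $o_{\text{goal}} / a$ (zero when $a = 0$, since an
  empty net cannot lose).
* **stochastic tree-search** — for each candidate good the planner simulates
  `n_rollouts` futures in which the agent takes the candidate now (applying
  the forfeiture rule) and commits to it on every later trial, the
  candidate's offer evolving under the task's own generative statistics.
  $v_g$ is minus the mean number of trials until the net fills, censored at
  `max_horizon`; the greedy planner therefore picks the good forecast to
  fill the net fastest.

The rollout policy is commit-to-candidate: no within-rollout switching. This
matches the planner's definition as a completion-time forecast per option;
a full expectimax over switch sequences is unbounded and is not what the
model describes. Rollout count (default 100) and horizon (default 200
trials) are configuration, not substance: values stabilise well below the
default (at 1,000 vs 10,000 rollouts a typical state moves by well under a
trial), and the horizon only binds for pathological states (all offers
persistently negative), where censoring gives a bounded, pessimistic value
rather than discarding the rollout. With the walk variance and jump
probabilities set to zero the planner collapses to the exact closed form
$-\lceil (N-a)/o \rceil$ (persist) and $-\lceil N/o \rceil$ (switch), which
the tests exercise directly.

The abandonment value of a state under model $m$ is
$\mathrm{sv}_m = \max_{\text{alt}} v_m - v_m(\text{goal})$.

## Choice model, persistence bias, model comparison

Choices are modelled by a two-parameter logistic:
$P(\text{abandon}) = \mathrm{logit}^{-1}(\beta_0 + \beta_1\,\mathrm{sv})$.
$\beta_1$ is the inverse temperature; the indifference point
$\mathrm{IP} = -\beta_0 / \beta_1$ is the abandonment value at which
switching and persisting are equally likely. A positive IP is a persistence
bias: the best alternative must beat the current goal by that many (planner)
trials before the agent is indifferent.

Fitting is Newton/IRLS with a ridge penalty of $10^{-4}$ on both
coefficients (tolerance $10^{-8}$, 100 iterations). The penalty exists only
to keep near-separated fits finite; on identifiable data the estimates agree
with unpenalized maximum likelihood to four decimals, and the tests compare
the fitter against both `glm()` and a brute-force likelihood grid. Fits with
constant responses, a constant predictor, or non-convergence are flagged and
excluded downstream. The cohort-level test of IP > 0 is the one-sample
Wilcoxon signed-rank test (IPs are not normal).

Models are compared by leave-one-participant-out cross-validation: for each
held-out participant a *pooled* logistic (a fixed-effects surrogate for the
hierarchical fit used with human data; true random-effects estimation is
deliberately out of scope) is fitted to everyone else, per-trial abandonment
probabilities are predicted through the softmax, and accuracy is
$1 - \overline{|\hat P - y|}$. Ties in per-participant best-model counts go
to the first listed model.

## Synthetic cohorts

Participants are drawn from population distributions chosen once to land in
the qualitative regime the analyses assume — a clearly positive mean
persistence bias, moderate choice stochasticity, and coupled
attention/persistence individual differences:

* persistence bias `ip_bias` ~ N(3, 1.5²) planner-trials — the scale on
  which group contrasts of a few planner-trials are meaningful effects;
* inverse temperature log-normal, `meanlog = log(0.75)`, `sdlog = 0.5`.
  The median of 0.75 keeps choices stochastic enough that a session
  produces a healthy number of abandonment events near the indifference
  point; with a much sharper median the cohort abandons so rarely (well
  under ten percent of trials) that the logistic slope is unidentifiable at
  session length, violating the generative self-consistency the cohort is
  required to have (fits of simulated data must recover the simulated
  parameters);
* progress-attenuation slopes `atten_cur` ~ N(0.3, 0.1²) and
  `atten_alt` ~ N(0.6, 0.1²), clamped to [0, 1] — alternative value loses
  influence faster than current-goal value;
* an attention-bias parameter (expected spatial-error advantage for the goal
  stimulus) ~ N(0.04, 0.02²) screen units.

Persistence bias and attention bias load on a shared standard-normal latent
factor (a Gaussian copula). For a target Spearman correlation $\rho_s$
(default 0.5) the Pearson loading is $2\sin(\pi\rho_s/6)$, the inverse of
the bivariate-normal rank-correlation map, so the induced rank correlation
matches the target under any monotone downstream transformation.

Simulated decisions follow
$\mathrm{SV} = \beta_1[(1 - \text{atten}_\text{alt} p)\,V_\text{alt} -
(1 - \text{atten}_\text{cur} p)\,V_\text{goal} - \mathrm{IP}]$ with
$p = a/N$ the pre-choice goal progress, abandonment probability
$\mathrm{logit}^{-1}(\mathrm{SV})$, and switches directed to the best
alternative. With attenuation zero this is exactly the two-parameter
logistic in $\mathrm{sv}$, with $\beta_0 = -\beta_1\,\mathrm{IP}$ — the
identity the recovery study exploits. Recovery is summarized by the Pearson
correlation for the indifference point and by the Spearman correlation for
the inverse temperature: the MLE of a log-normal scale parameter is
heavy-tailed near quasi-separation (a handful of fits can return slopes an
order of magnitude too large, with standard errors to match), so the rank
correlation is the stable summary; both are reported.

The spatial task is simulated as three stimuli per trial at uniform random
screen locations, reported with isotropic Gaussian error. The goal
stimulus's error s.d. sits below baseline (0.12 screen units) by the
participant's attention bias divided by the Rayleigh factor
$\sqrt{\pi/2}$ (so the *mean-error* advantage matches the parameter) and
shrinks further with trials invested (default slope −0.008 per trial);
alternative stimuli keep the baseline s.d. and a zero-mean slope. All s.d.s
are floored at 0.02. Reaction times are log-normal with a −0.08 s additive
shift for the goal stimulus. This Gaussian-report model is an assumption —
nothing in the task fixes how humans misreport locations — and is the main
respect in which passing tests say less about real data: real report errors
have guesses, swaps and edge effects that this generator does not emulate.

Lesion cohorts are binary 20 × 24 × 20 grids (nominal 2.4 mm pitch — small
enough that full permutation pipelines run at a desk), one contiguous
random-growth lesion of 50–400 voxels per patient. When an effect is
implanted, five lesion seeds are placed inside the ROI ball so the cohort
actually contains ROI-damaged patients (purely random seeds would give only
about two), and ROI-overlapping patients have their behavioural bias reduced
by `effect_delta` (default 3, the scale of the persistence-bias s.d.) plus
N(0, 1) noise.

## Behavioural analyses

**Goal-progress effect.** A pooled likelihood-ratio test between logistics
with and without a progress term on top of the tree-search abandonment
value; one degree of freedom.

**Temptation vs frustration.** Per participant, abandonment is regressed on
the current-goal value, the best-alternative value, goal progress, and the
two value-by-progress interactions — with *raw* (unstandardized) values.
This is deliberate: under the attenuated choice rule the interaction
coefficients are $-\beta_1\,\text{atten}_\text{alt}$ and
$+\beta_1\,\text{atten}_\text{cur}$ — they share the participant's inverse
temperature and are directly comparable, and the comparable
"influence-loss" slopes are the sign-adjusted interactions (the goal value
pushes *against* abandonment, so its fading influence is a positive
coefficient). Standardizing the values within participant would rescale the
two coefficients by each value's own s.d., which differ systematically
between goal and alternative, and simulation shows the resulting paired
contrast rejects a symmetric null far above nominal rate. The progress main
effect must also be present: without it the value means fold into the
interactions. The cohort-level tests are t-tests of each interaction
against zero and a paired comparison of the loss slopes, reported both as a
paired t-test and as a Wilcoxon signed-rank test; the signed-rank version
is the recommended directional test because per-participant logistic
interaction estimates are heavy-tailed near quasi-separation.

For calibration and power studies of this analysis the regression uses the
planner values recorded at choice time (`use_logged_values = TRUE` in
`build_dataset()`), which makes the likelihood exactly specified.
Recomputing values with fresh rollouts — the only route available with real
data — adds progress-dependent measurement noise that biases the asymmetry
contrast; this caveat applies equally to analyses of human data and is a
limitation worth knowing about.

**Attention metrics.** Excluding first trials of blocks (no goal exists
yet): per-participant mean error and RT by stimulus status, OLS slopes of
error on trials invested per status, the attention bias
(mean alternative error − mean goal error), paired t-tests across
participants, and a Spearman correlation between attention bias and
persistence bias with a Fisher-transform interval using
$\mathrm{se} = 1/\sqrt{n-3}$ (an approximation; rank correlations have
slightly heavier-tailed transforms, but at cohort sizes of 30+ the
difference is immaterial).

**Performance.** Mean trials per *completed* net (unfinished trailing
blocks excluded); lower is better. Group contrasts use label-shuffling
permutation tests with the add-one convention $p = (b+1)/(n+1)$.

## Lesion mapping

Per voxel with at least `min_overlap` (default 2) damaged and intact
patients, the two-group pooled-variance t statistic — algebraically the
regression t on a binary damage regressor — is computed, signed so positive
t means damage predicts lower persistence bias. Supra-threshold voxels
(default t > 2.3) are grouped into connected components; the default
connectivity is 6-neighbour face adjacency (18/26 available; the convention
is not fixed by any external constraint, and face adjacency is the most
conservative). Untested voxels carry `NA`, never a zero that could be
mistaken for a real statistic.

Cluster correction shuffles the biases across patients (default 1,000
permutations), recomputes the map and clusters, and returns the minimum
significant size: the smallest integer $m$ such that the chance of a null
cluster of size ≥ $m$ is at most α. Two null conventions are provided:
`pooled` (all chance clusters across permutations pooled — the 95% cut-off
of all clusters found by chance) and `max` (per-permutation maximum
cluster size, the standard family-wise-error control). The pooled cut-off
is not FWER-controlling — with $K$ chance clusters per map the family-wise
rate is roughly $1 - 0.95^K$ — so calibration studies in the test suite
use `max`, while detection/power studies use `pooled`, the convention this
design descends from; under the stricter max-statistic threshold the
default implanted effect sits at the edge of 80% detection. The ROI split labels a patient
ROI-damaged iff any lesioned voxel lies within a Euclidean ball (default
radius 3 voxels) around the ROI centre.

## Numerical and design notes

* All randomness flows through R's RNG, including the C++ rollout core, so
  `set.seed()` makes every simulation bit-reproducible.
* Greedy ties are broken uniformly at random; they have measure zero for
  the stochastic planner and matter only in degenerate fixtures.
* The prospective model's value formulas are used as continuous
  proportions; rounding them to integers would collapse all positive values
  to a single level and make the model degenerate.
* Rejection sampling of schedules caps candidates at 10,000 per accepted
  block and fails loudly rather than looping forever.
* Problem sizes in the test suite are the package's own choices: full
  45-block schedules where schedule structure is the object of the test;
  cohorts of 30 participants at 300 trials for recovery, 8 participants
  per cohort (at 40 planner rollouts) for the ten-repeat model
  identifiability sweep, and 30 participants at 400 trials for the
  attenuation-asymmetry power study; 100 null
  lesion cohorts at 200 permutations for FWER calibration. Each choice
  trades Monte-Carlo precision against keeping the full suite comfortably
  reproducible on a laptop.
* Known limitations: no hierarchical (random-effects) choice fitting; no
  learning within the session; the attention generator is an assumption
  (above); lesion simulation grows blobs, not vascular territories; and the
  value-recomputation route for interaction analyses carries the
  errors-in-variables caveat described earlier.

## A worked example

```{r example, eval = FALSE}
set.seed(1)
cfg <- ts_config(n_rollouts = 100)
schedule <- gen_schedule(n_blocks = 45, n_trials_per_block = 100,
                         ts_cfg = cfg)
cohort <- gen_cohort(cohort_hyperparams(n = 30))
choices <- simulate_cohort_decisions(cohort, schedule, cfg, max_trials = 300)
dataset <- build_dataset(choices, cfg)

fits <- fit_cohort(dataset, "tree_search")
wilcox.test(fits$ip, alternative = "greater")   # cohort persistence bias > 0

cv <- loo_cv_compare(dataset)                    # model comparison
progress_bias_test(dataset)                      # progress beyond sv
spatial <- simulate_cohort_attention(cohort, choices)
att <- attention_analysis(spatial)
bias_correlation(att$per_participant$atten_bias, fits$ip)
```
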