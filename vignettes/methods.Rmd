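---
title: "Models and methods behind pagfear"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pagfear}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

pagfear analyses single-unit recordings from rats discriminating three
auditory cues that predict foot shock with probability 1.00 (danger),
0.375 (uncertainty) and 0.00 (safety). This vignette is the package's own
account of the models it implements, the parameters that matter, the
numerical conventions that make its tests exact, and the design choices
that were genuinely open.

## The behavioral model: conditioned suppression

Fear output is measured as suppression of rewarded nose poking. For a
pre-cue baseline poke rate $b$ and a cue-period rate $c$,

$$\rho = \frac{b - c}{b + c} \in [-1, 1],$$

with $\rho = 1$ complete suppression and $\rho = 0$ none. The ratio is
computed for the whole 10 s cue (*total fear*) and for each 1 s cue
interval (*interval fear*), always against the same pre-cue baseline.
When $b + c = 0$ the ratio is undefined; it is returned as `NA` and
excluded from averages, never imputed as zero — a silent zero would read
as "no fear".

Two conventions the data do not dictate:

* **Baseline window** (`baseline_window`, seconds; default 10). A
  behavioral baseline must be long enough to estimate a poke rate of
  order 1 poke/s; 10 s immediately pre-cue is the default and it may not
  reach into the previous trial's shock window (an error, unless
  `auto_shorten = TRUE` clips it).
* **Short-interval inflation.** At low poke rates a 1 s ratio is upward
  biased (counts of 0 dominate), so interval ratios overstate *absolute*
  fear while remaining a valid *relative* measure across cues. The test
  suite demonstrates the inflation by simulation.

## The neural response variable: two Z schemes

**Whole-epoch scheme.** Per unit and trial type, firing is binned at
100 ms from 10 s before cue onset to 12 s after cue offset (320 bins for
a 10 s cue), averaged over trials, and the type's own 2 s pre-cue mean is
subtracted. One Z transform (single mean and SD) is then applied across
all trial types × bins. Because phasic excitation contributes to the
pooled mean, baseline-period Z sits below zero in responsive units — an
expected feature, not a bug.

**Per-interval scheme.** For one analysis window, each trial's rate minus
that trial's own 2 s pre-cue rate is Z-scored across the session's 32
trials. Each window is normalized independently, maximizing the spread of
firing within the window; this is the response of every trial-by-trial
regression.

Numerical contracts: both schemes use the population SD (divide by $N$),
so "mean 0, SD 1" is exact to 1e-9 and asserted as such in tests. The
choice of population vs. sample SD does not change any test statistic
(both rescale uniformly); it is fixed so the contract is testable.
Degenerate inputs (zero SD: silent or constant units) raise an error
naming the unit, which callers treat as exclusion.

PSTH smoothing, used only for display, is a centered moving average
(default width 5 bins) whose kernel is renormalized at the edges so the
total is conserved exactly.

## The regression model

For one unit and one interval, the design has 32 rows ordered by trial
type (danger, uncertainty-shock, uncertainty-omission, safety) and columns

$$z \sim \beta_0 + \beta_{if}\,\mathrm{interval\ fear} +
\beta_{tf}\,\mathrm{total\ fear} + \beta_p\,\mathrm{probability},$$

where probability is the cue's programmed shock contingency (uncertainty
entry settable, `u_assign`, default 0.375). Fits are ordinary least
squares; coefficient standard errors come from the residual variance and
p values from the t distribution with $n - k$ degrees of freedom. A
rank-deficient design (e.g. behavioral variance collapsed onto the
intercept) is an error naming the collinear columns. Tests verify the
fitted coefficients against an independent normal-equations solver to
1e-9 on a thousand random designs.

Post-cue regression uses 500 ms windows over the 5 s after cue offset,
excluding the 2.0–2.5 s shock window (nine intervals: four delay, five
post-shock). Total fear is omitted there because it samples only the cue
period; interval fear is the suppression ratio in the matching 500 ms
window, applying the cue-period definition unchanged.

## The threat-probability tuning sweep

Holding danger at 1.00 and safety at 0.00, the regression is refit with
the uncertainty assignment swept over $\{0, 0.125, \ldots, 1\}$; the
curve is the mean probability beta per assignment and its argmax is the
peak. With the default 6/16 uncertainty composition, the variance of the
probability column is minimized exactly at 0.375, so for a population
whose firing is linear in the true probability the expected curve peaks
at the programmed value.

One estimator subtlety, discovered while validating parameter recovery
and worth stating plainly: for a well-discriminating subject the
*total-fear* regressor is nearly deterministic in the cue (danger trials
sit at ratio ≈ 1). Residualizing the probability column on such a
cue-locked covariate biases the recovered peak of a *pure* probability
signal rightward (toward 0.5) even in the noise-free limit. The package's
recovery harness (acceptance script and tests) therefore controls fear
output through the trial-level interval-fear regressor only; the
full-regressor sweep remains available and is what the pipeline runs,
since with real, mixed-coding populations it is the analysis of record.
The mixed-coding contrast is preserved either way: adding a cue-level
fear component (uncertainty weighted nearer danger) shifts the recovered
peak strictly above 0.375.

## Population analyses

* **Sliding departure.** Paired two-tailed t-tests across units on mean
  normalized firing in 1 s windows stepped 100 ms across the cue (91
  windows); the departure is the start of the first window below
  threshold, reported at p < 0.05 and at 0.05/divisor. The divisor
  defaults to windows × comparisons (182 for two cue contrasts) and is
  overridable, because the correction base is a reporting convention, not
  a property of the data. The uncorrected "first p < 0.05 window" rule
  carries an irreducible ~5% per-window false rate, so tests assert its
  median over replicates and require the corrected departure to localize
  a planted step exactly.
* **Pattern categorization.** Units are labelled by the strict ordering
  of their mean interval Z across cues; exact ties (measure-zero for
  continuous data) break deterministically danger > uncertainty > safety
  and are flagged. The chance distribution permutes each unit's three
  values independently (1000 shuffles), summarized box-plot style
  (median, quartiles, 1.5-IQR whiskers); an observed count above the
  upper whisker exceeds chance.
* **Bias tests.** Pearson R² with t-based p, plus an exact two-tailed
  binomial sign test with ties excluded (all-ties gives an undefined p,
  flagged). Under an exchangeable null the exact test is conservative,
  not uniform — the test suite checks CDF dominance, not uniformity.
* **Proportion comparisons** use the Pearson chi-square without
  continuity correction by default (Yates available by flag).
* **Nose-poke-cessation control.** Spontaneous poke-free gaps (≥ 5 s,
  configurable) fully inside inter-trial intervals are aligned at gap
  onset and post-onset firing is tested against the pre-gap baseline.
  Gap threshold and the 2 s pre-gap baseline are package conventions,
  recorded in the output.

## Unit classification

Units are partitioned by k-means (k = 2) on baseline firing rate (2 s
pre-cue), waveform half-duration and amplitude ratio
$(n - p)/(n + p)$; the lower-rate cluster is labelled LFR (putative
glutamatergic), the other HFR (putative GABAergic). Features enter in
their **native units** by default. This was a genuinely open choice:
standardizing to unit variance gives the two waveform features — which
carry no class information in these cohorts — the same weight as the
strongly bimodal rate axis, and lets waveform noise flip borderline
units. In native units the Hz scale dominates the Euclidean distance, a
planted rate mixture is recovered exactly, and assignments are invariant
to shuffling waveform features across units; `standardize = TRUE` is
available. A one-way ANOVA per feature across the clusters reports which
features actually differ, so rate dominance is verified rather than
assumed.

Cue-responsiveness screening is a paired two-tailed t-test of per-trial
raw rate, 2 s baseline vs. the first (or last) 1 s cue interval, per cue
at p < 0.05/3 ≈ 0.017, and additionally requires a firing *increase* —
the screen targets excitatory responses, and the direction requirement
keeps the realized false-positive rate at or below the corrected nominal
level. Labels follow a fixed precedence: first-interval responsive →
onset; else last-interval responsive and LFR → ramping; else
last-interval responsive and HFR → hfr-cue-responsive; else
nonresponsive. Onset units are expected, not forced, to be LFR.

## The synthetic generator

The generator emulates the statistical structure the analyses assume:

* **Trial sequences.** Types shuffled uniformly; inter-trial intervals
  (cue-free gap, shock-window end to next cue onset) drawn as
  `min_iti + Exponential(mean_iti − min_iti)`, mean 3.5 min by default
  (the stated condition), configurable shorter for fast tests.
* **Pokes.** Homogeneous Poisson at `baseline_poke_rate` outside cues;
  during a cue the rate is the closed-form inversion
  $c = b(1-\rho)/(1+\rho)$ of that trial's target ratio, perturbed by
  Gaussian trial noise (`trial_noise_sd`, default 0.15) so interval fear,
  total fear and probability are not collinear — the regression needs
  within-cue behavioral variance, which real subjects show. The default
  baseline rate is 1.0 pokes/s, a realistic variable-interval response
  rate chosen so the small-count bias of the ratio in 10 s windows is
  negligible and measured ratios converge to their targets
  (0.80/0.53/0.03 by default).
* **Spikes.** Inhomogeneous Poisson by thinning (exact for bounded
  intensities). Onset units add a decaying exponential transient
  (`onset_decay_tau`, default 1 s) from cue onset; ramping units a linear
  ramp from `ramp_start` (default 2 s) to the expected shock time,
  sustained through the delay and optionally truncated after shock; both
  scale as `probability_gain × p(cue) + fear_gain × trial fear`. Decay
  constant and ramp slope are not quantities the recordings pin down;
  the defaults reproduce the qualitative shapes (first-interval onset
  response about 3× baseline; ramping maximal in the last interval) and
  are exposed. Baseline rates draw from a low (2–5 Hz) or high
  (13–18 Hz) range, giving the bimodal mixture the clustering expects.

What it does **not** emulate: bursting or refractory spike statistics,
firing-rate drift, learning across sessions, reward-delivery dynamics,
electrode artifacts (beyond optional blanking of the 0.5 s shock window),
or correlated noise across units. Passing recovery tests therefore shows
the estimators are correct under the assumed generative structure, not
that real vlPAG data meet those assumptions.

## Problem sizes and determinism

Tests run on 32-trial sessions with shortened inter-trial intervals
(typically 15–40 s) so a full session spans minutes, not hours, of
simulated time; Monte-Carlo checks use 10–60 replicates, cohort-recovery
checks 30–60 units, and the OLS oracle property 1000 random designs —
sizes at which every stochastic bound in the suite holds with margin.
All generators accept seeds; a fixed seed reproduces sessions, shuffles
and pipeline outputs exactly (CSV-identical), and the acceptance script
derives every stream from its `--seed` argument.

## Known limitations

* Suppression ratios are undefined for fully poke-free windows; sessions
  from poorly trained (low-poking) subjects will generate many exclusions
  and the summaries report the excluded count rather than compensating.
* The repeated-measures ANOVAs reported alongside the original analyses
  (with sphericity corrections and observed power) are out of scope; the
  package reports its own t, chi-square, sign-test and regression
  statistics, delegating standard tests to base R.
* The sliding-departure time is a first-crossing statistic and inherits
  first-crossing noise; prefer the Bonferroni-corrected departure when a
  conservative latency is needed.
* Tuning-curve peaks are grid-valued (0.125 resolution); differences
  smaller than the grid step are not resolvable by design.
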