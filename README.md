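# pagfear

Analysis of ventrolateral periaqueductal gray (vlPAG) single-unit activity
recorded during three-cue Pavlovian fear discrimination, together with a
synthetic session generator that makes every stage of the pipeline runnable
and testable at desk scale.

The package is aimed at systems-neuroscience analysts working with
timestamped spike/event recordings from probabilistic fear-conditioning
tasks: three auditory cues predict foot shock with probability 1.00
(*danger*), 0.375 (*uncertainty*) and 0.00 (*safety*), cues last 10 s, and
shock (0.5 s) arrives 2 s after cue offset on danger and uncertainty-shock
trials. Each session has 32 trials: 6 danger, 6 uncertainty-shock, 10
uncertainty-omission, 10 safety.

## What it computes

**Fear output** is conditioned suppression of rewarded nose poking,

```
ratio = (baseline poke rate − cue poke rate) / (baseline poke rate + cue poke rate)
```

computed for the whole 10 s cue (*total fear*) and per 1 s cue interval
(*interval fear*); 1 = complete suppression (high fear), 0 = none.

**Neural output** is Z-normalized firing, in two schemes: a whole-epoch
scheme (differential 100 ms-bin rates, −10 s to cue offset +12 s, 320 bins,
one Z transform per unit across all trial types) and a per-interval scheme
(each trial's interval rate minus its own 2 s pre-cue baseline, Z-scored
across the session's 32 trials).

The core statistic is a per-unit, per-interval trial-by-trial OLS
regression

```
z_firing ~ constant + interval_fear + total_fear + probability
```

whose beta coefficients separate fear-output coding from
threat-probability coding. Around it the package provides: k-means
classification of units into low/high firing-rate clusters from baseline
rate and waveform features; screening for onset (first 1 s interval) and
ramping (last interval) cue-responsive units at a Bonferroni-corrected
p < 0.017; sliding-window population departure times with rate-of-increase;
firing-pattern categorization (d>u>s etc.) against a 1000-shuffle null;
correlation/sign-test bias analyses; the nine-point threat-probability
tuning sweep (uncertainty assignment 0 → 1 in 0.125 steps); post-cue
regression in 500 ms intervals (shock interval excluded); beta correlation
matrices across delay and post-shock intervals; and a nose-poke-cessation
control.

The synthetic module generates full sessions — randomized trial sequences,
Poisson nose pokes whose cue-period rate inverts a target suppression
ratio (defaults 0.80 / 0.53 / 0.03, the nonlinear fear profile), and
inhomogeneous-Poisson spike trains (thinning) with onset, ramping,
high-firing and nonresponsive profiles — with ground-truth labels for
recovery testing.

## Worked example

The packaged fixture is the complete regression input for first-interval
firing of one onset-type unit (32 trials ordered by type):

```r
library(pagfear)
fit_ols(load_worked_example())
#> # A tibble: 4 × 5
#>   term          estimate    se statistic        p
#>   <chr>            <dbl> <dbl>     <dbl>    <dbl>
#> 1 constant        -0.876 0.243    -3.60  0.00122
#> 2 interval_fear    0.244 0.191     1.28  0.211
#> 3 total_fear      -0.137 0.484    -0.284 0.779
#> 4 probability      2.19  0.492     4.45  0.000124
```

The betas round to 0.24 (interval fear), −0.14 (total fear) and 2.19
(probability): this unit's first-interval firing is captured by threat
probability — the probability beta is large, positive and significant —
while neither fear regressor differs from zero.

An end-to-end synthetic run, with planted unit classes recovered by the
classification stage:

```r
cfg <- pipeline_config(
  design = session_design(mean_iti = 30, min_iti = 15),
  cohort = cohort_spec(n_onset = 6, n_ramping = 6, n_hfr = 3,
                       n_nonresponsive = 15),
  seed = 42, n_shuffles = 500)
res <- run_pipeline(cfg)
table(res$unit_labels$label)
#> hfr_cue_responsive      nonresponsive              onset            ramping
#>                  3                 15                  6                  6
```

`res` also carries the suppression table, cluster assignments, pattern
counts vs. shuffle, per-interval betas, tuning curves and post-cue
regressions; `export_report(res, "report/")` writes summary figures.

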