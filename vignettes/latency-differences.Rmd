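---
title: "Estimating perceptual latency differences from temporal judgments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating perceptual latency differences from temporal judgments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(latdiff)
```

## The problem

Perceiving a stimulus takes time, and that perceptual latency differs
between modalities: a brief sound and a brief flash presented at the same
physical moment are generally not perceived at the same moment.  The
difference in perceptual latency between a visual and an auditory stimulus,

$$\Delta L_{VA} = L_V - L_A,$$

is classically estimated from three psychophysical tasks, and `latdiff`
implements the complete analysis for all three so that the estimates can be
compared within the same observer:

* **Temporal order judgments (TOJ).** The two stimuli are presented at an
  asynchrony $s$ (here coded as $\mathrm{onset}(A) - \mathrm{onset}(V)$, so
  positive $s$ means the sound came second) and the observer reports which
  came first.  The proportion of "V first" reports is fit with a
  four-parameter cumulative normal
  $$\psi(s) = \gamma + (1 - \gamma - \lambda)\,
    \Phi\!\left(\frac{s - \mu}{\sigma}\right),$$
  with an independent lapse rate on each side ($\gamma$, $1-\lambda$ are the
  asymptotes): order judgments are hard, and some observers stay well below
  perfect report even at long asynchronies.  $\Delta L_{VA}$ is the
  asynchrony at which $\psi(s) = 1/2$,
  $\mu + \sigma\,\Phi^{-1}\!\big((1/2-\gamma)/(1-\gamma-\lambda)\big)$.
* **Simultaneity judgments (SJ).** The observer reports whether the two
  stimuli were simultaneous.  The proportion of "simultaneous" reports is
  fit with a three-parameter scaled Gaussian
  $a \exp\{-(s-\mu)^2 / 2\sigma^2\}$, and $\Delta L_{VA}$ is its centre
  $\mu$ (the point of subjective simultaneity).  The amplitude $a$ absorbs
  response-level biases that change the height but not the location of the
  curve.
* **Duration judgments.** Two intervals are compared, one delimited by
  audio-then-video ($AV$), the other by video-then-audio ($VA$).  A latency
  difference stretches the perceived $AV$ interval and shrinks the
  perceived $VA$ interval: $D_{AV} = d + 2\Delta L_{VA}$ and
  $D_{VA} = d - 2\Delta L_{VA}$ for a physical duration $d$ when the
  comparison interval has the reversed order (the factor 2 is the gain of
  the reversed-order design).  Fitting a two-parameter cumulative normal to
  "variable longer" proportions in each condition gives the two points of
  subjective equality, and
  $$\Delta L_{VA} = \tfrac{1}{4}\,(\mathrm{PSE}_{AVVA} -
  \mathrm{PSE}_{VAAV}).$$
  Because the estimator is a difference, any constant shift common to both
  conditions drops out.  In particular the *time-order error* — a bias to
  perceive the first of two compared intervals as shorter or longer, which
  afflicts this design because the standard is always presented first —
  cancels exactly.  The companion *asymmetry statistic*
  $(\mathrm{PSE}_{AVVA} - d) - (d - \mathrm{PSE}_{VAAV})$ isolates that
  common shift: it equals $2\times$ the time-order error under the
  generative model, and its bootstrap interval flags samples where the two
  deviations from the standard are not mirror images.

The motivating empirical finding is that these three estimates of the same
quantity are *inconsistent* across observers.  The package's job is the
machinery for measuring that inconsistency — and, via simulation, for
showing that the estimators themselves do not produce it.

## The synthetic-observer generator

The package replaces human data with parametric observers
(`observer_params()`) whose ground truth instantiates the theory above: one
`delta_l` drives all three tasks, and each task adds only its own noise.
The default designs (`default_design()`) are the published ones: 11
asynchronies from $-0.25$ to $0.25$ s in $0.05$ s steps with 20 trials per
level (220 trials) for TOJ and SJ, and five variable durations per standard
(0.6 s: 0.3–0.8 s; 1.2 s: 1.0–2.4 s) for the duration task.

Default observer parameters are chosen as typical of audiovisual timing
studies: `delta_l = 0.05` s (about the average reported for such stimuli),
TOJ noise SD 0.07 s with 5% lapse rates on each side (order judgments are
lapse-prone), simultaneity window SD 0.12 s with peak report probability
0.95, duration-comparison noise SD 0.1 s, and no time-order error or
duration order bias unless injected.  Distortions are explicit parameters
(`toe`, `dur_order_bias`, the lapse rates, `amp_sj`) so tests can switch a
single bias on and observe its signature.

The generator is deliberately *model-true*: the SJ observer is the same
scaled-Gaussian family the fitter uses, because the literature does not
commit to a process model for simultaneity judgments, and matched
generation is what makes parameter-recovery and coverage statements about
the estimators crisp.  Consequences for interpretation: passing tests show
the estimation pipeline is unbiased and calibrated *under its own model
family*; they say nothing about misspecification on real data (asymmetric
simultaneity criteria, response-button biases near the PSE, sequential
effects), which is exactly why the cross-task battery exists.  An
asymmetric-criterion observer (distinct left/right SDs in the SJ window)
would be the natural first extension; it is not implemented.

## Fitting

Fits maximise the aggregated binomial likelihood (identical to the
trial-level Bernoulli likelihood, cheaper).  Numerical choices, all part of
the function contracts:

* probabilities are clamped to $[10^{-9}, 1-10^{-9}]$ inside the likelihood
  only, so saturated levels keep the objective finite;
* box bounds: location within the level range extended by one range either
  side; SD in $[\mathrm{range}/1000,\,10\cdot\mathrm{range}]$; lapse rates
  in $[0, 0.49]$ — 0.49 keeps the 50% point of the order-judgment curve
  defined while accommodating observers far below ceiling; amplitude in
  $[0.01, 1]$;
* optimisation by `L-BFGS-B` with analytic gradients, restarted from a
  coarse grid (every observed level as a starting location $\times$ three
  starting SDs $\times$ lapse rates $\{0, 0.1\}$ for the order task): the
  four-parameter family on a dozen binomial points has local optima, and a
  test asserts the fitted likelihood beats an exhaustive 41-points-per-
  parameter grid;
* in the clamp region the gradient is set to zero, matching the locally
  flat clamped objective (otherwise near-separated duration data abort the
  line search);
* non-convergence is reported (`converged = FALSE`), never silent.

## Uncertainty

Plotted proportions get exact Clopper–Pearson intervals (beta-quantile
characterisation; an enumeration test verifies coverage is at least nominal
for every $n \le 25$ and every true probability on a 0.01 grid).  Fitted
and derived quantities get 95% parametric-bootstrap percentile intervals
with 1,000 replicates as the study convention: counts are resimulated from
the fitted curve at the original levels and refit.  Design choices:

* refits warm-start from the original maximum-likelihood solution rather
  than rerunning the full multi-start grid — the replicate data are drawn
  from that very curve, so the original optimum is an excellent start, and
  the saving is what makes 300-replication coverage experiments routine;
* failed refits are dropped and counted (retrying would bias the bootstrap
  distribution), with a warning above 5% failure;
* the duration-task interval pairs the two conditions' bootstrap PSE
  distributions by index and takes percentiles of
  $(\mathrm{PSE}^*_{AVVA} - \mathrm{PSE}^*_{VAAV})/4$; the two fits are
  independent, so any pairing is valid, and index pairing keeps the
  computation deterministic;
* one master seed; per-replicate substreams are drawn up front
  (`sample.int(2^31 - 2, n_boot)` under the master seed), so each replicate
  is reproducible in isolation and order of execution is irrelevant;
* percentile method only, no BCa — matching the study convention.

## The consistency battery

`consistency_battery()` compares per-observer estimates across the four
task labels (TOJ, SJ, and the two duration standards): Pearson correlations
with percentile-bootstrap CIs from resampling observers and classical
t-transform p values, one-sample t tests of each task's estimates against
zero, the paired t test across duration standards, and the per-observer
conservative criterion of 95%-CI non-overlap (roughly $p < .006$ for
independent intervals; touching endpoints count as overlap).  Tests are
two-sided throughout and deliberately uncorrected for multiplicity — the
report carries the comparison count so users can correct post hoc.
Observers missing a cell are excluded per comparison, not listwise, and are
named in the report.

## Reproducible runs

`run_pipeline(run_config(...))` chains simulate → fit → estimate →
bootstrap → consistency and writes plain CSV tables plus a manifest (seed,
config hash, package version); identical configurations give byte-identical
outputs.  Times are seconds in all files and milliseconds only in columns
suffixed `_ms`.  The package's users work in R, so the exported functions
and this vignette are the interface; no shell wrapper is shipped.

## Problem sizes and what the checks compute

The package's own verification uses desk-scale versions of the study
conditions, chosen to keep each property cleanly measurable: parameter
recovery and immunity checks run 7 synthetic observers at 2,000 trials per
level (where sampling error is a few ms, so bias bounds of 5 ms are
meaningful); bootstrap calibration runs 300 independent replications at the
published trial counts (20 per level for the order and simultaneity tasks;
28 per level and interval order for the duration task, matching the
published minimum of 280 trials per standard) with 200 bootstrap
replicates each; the
null-agreement cohort uses 20 observers at 1,000 trials per level; t-test
calibration uses 2,000 null cohorts of seven.  The acceptance script
(`scripts/acceptance.R`) reruns the full seven-observer study at the
published trial counts with the full 1,000 bootstrap replicates.

## Known limitations

* The generator and fitter share model families; misspecification is out of
  scope (see above).
* Only the reversed-order duration design is implemented; estimation with a
  neutral comparison interval (half the gain) is not.
* No goodness-of-fit statistic is computed for individual fits, and no
  correction for the biases the battery detects is attempted — the package
  measures inconsistency, it does not explain it.
* The time-order error is modelled as additive and condition-independent,
  which is precisely the structure the duration estimator cancels; a
  duration-dependent variant is only representable through
  `dur_order_bias`.
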