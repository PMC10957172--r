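---
title: "Trajectory-specific coding in VTA units: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trajectory-specific coding in VTA units: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vtamemcode)
```

## The scientific problem

Mice running a figure-eight T-maze choose a left or right arm on the
instruction of a visual cue, with a short memory delay between cue offset
and the choice point.  Extracellular recordings from optogenetically
identified dopamine (DA) and GABA neurons of the ventral tegmental area
(VTA) raise the question this package addresses: do single midbrain units
fire differently on left-bound versus right-bound laps, in particular in
the memory delay where the two trajectories are physically identical and
the only difference is the content of working memory?

Because the animal controls the timing of every event, analyses are
arranged by *position* rather than time.  Each trial's trajectory is
linearized onto a 150 cm track, divided into 100 position bins, with
sections start (0–50 cm), visual cue (50–80 cm), memory delay (80–120 cm)
and side arms (120–150 cm).  The reward epoch is not a spatial section: it
is the first second of consumption, anchored at the first lick of the
waterspout, and analysed in the time domain.

## The rate estimator

For unit and trial $k$, let $n_k(x)$ be the spike count and $t_k(x)$ the
occupancy (s) in bin $x$.  The firing-rate map is the trial-averaged
occupancy-normalized rate

$$\hat\lambda(x) = \frac{1}{K}\sum_{k=1}^{K} \frac{n_k(x)}{t_k(x)},$$

taken over the $K$ trials that occupied bin $x$ (trials with
$t_k(x) = 0$ are skipped at that bin, because $n/t$ is undefined there and
imputing zero would bias a Poisson rate estimate downward).  Occupancy is
accumulated by splitting each inter-sample tracking interval across the
bins its position range covers, proportionally to the path length in each
bin.  This is the same piecewise-linear position model used to place
spikes, which keeps the numerator and denominator of $\hat\lambda$
consistent: the simpler alternative of assigning each whole interval to
its midpoint bin mismatches the spike placement and carries a systematic
positive bias of 1–2% at typical tracking rates and running speeds (and
quantizes bin speeds to multiples of the sample interval), which is why
the proportional rule is the default here.  Spikes are
assigned to the bin of their linearly interpolated position at spike time.
The analysis span of each trial runs from trial start to the first lick;
the return run to the start box is excluded.  Only correct trials enter
the trajectory analyses; error trials are kept for the regression
covariates.

Maps are smoothed with a unit-sum Gaussian kernel.  The kernel has
standard deviation `sigma` and support `half_width` bins on each side;
edge bins renormalize the kernel over the available support so constants
are preserved exactly.  The defaults are `sigma = 5` bins with
`half_width = 10`: a kernel described only by σ = 0.5 and a 20-point
window is ambiguous, and we read the σ as a fraction of the half-window
(σ = 0.5 bins would barely smooth at all), exposing `sigma` in bin units
for users who read it otherwise.

## The permutation test for trajectory-specific firing

The observed statistic per bin is
$D_0(x) = \hat\lambda_{\text{left}}(x) - \hat\lambda_{\text{right}}(x)$,
computed on smoothed maps.  Trajectory labels are then randomly
reassigned across trials, preserving the left/right counts, and the
smoothed difference is recomputed `n_perms` times (default 1000).  The
pointwise two-sided p-value uses the add-one correction
$p(x) = (1 + \#\{|D_j(x)| \ge |D_0(x)|\})/(n_\text{perms}+1)$, which keeps
the test valid at finite permutation counts (verified against exhaustive
enumeration for 3+3 trials).

A bin is flagged significant when $p(x) < \alpha$ **and** it belongs to a
run of at least `min_run` consecutive sub-alpha bins; a unit is flagged in
a maze section when at least one flagged bin falls there.  The run
criterion is the multiplicity control.  Because smoothing correlates
neighbouring bins, short runs arise easily under the null: on a
200-unit null simulation (constant-rate Poisson units, 90 trials) the
per-section unit-flag rate was ~0.17 at `min_run = 3`, ~0.10 at 7, ~0.06
at 9 and ~0.03 at 11.  The default is therefore `min_run = 11`,
calibrated so the null flag rate sits near the few-percent operating
point observed for the least-modulated maze section in vivo; both `alpha`
and `min_run` are configurable.

## The firing-rate regression model

To ask whether covariates other than the trajectory could produce the
left/right differences, firing rate is modelled per (trial, bin)
observation as a Gaussian linear model

$$FR = \beta_0 + \sum_{k=1}^{6}\beta_{T P^k}\, T P^k
      + \sum_{k=1}^{6}\beta_{S^k} S^k
      + \beta_{TN} TN + \beta_R R + \beta_{A_0} A_0 + \beta_{A_{-1}} A_{-1}
      + \varepsilon,$$

with $T$ the trajectory coded 1 (left) / 2 (right), $P \in (0,1]$ the
normalized position, $S$ the running speed, $TN$ the trial number, $R$
the cumulative correct rate, and $A_0$, $A_{-1}$ the current and previous
trial accuracy (the first trial's $A_{-1}$ is set to 1: animals enter
sessions trained).  This is deliberately the formula as published —
trajectory multiplies the position polynomial and there is no position
main effect.  One consequence worth knowing: with the 1/2 coding, the
*sign* of the model-predicted left−right difference is not interpretable
on its own (the polynomial absorbs shared structure); all inference is on
its magnitude.  The 17 coefficients are fitted by ordinary least squares.
Internally the position and speed polynomial blocks are orthonormalized
(QR of the scaled monomial columns) for conditioning and the coefficients
are mapped back to the monomial basis; both parameterizations span the
same model and give identical predictions to ~1e−12.  The polynomial
order is chosen by the Bayesian information criterion computed from the
Gaussian log-likelihood (`select_order()`), with 6 the default.

Predictor significance is shuffle-calibrated.  From the fit we compute
$\hat D_0$, the mean predicted left−right rate difference over the bins of
the region under test (the memory delay by default).  For each tested
predictor, its *trial-level* values are shuffled across trials (speed is
shuffled as whole trial profiles), the model is refitted and the predicted
difference recomputed, 500 times.  The predictor is significant when
$|\hat D_0|$ exceeds the $1-\alpha/m$ quantile of the $|\hat D_j|$, with
Bonferroni $m = 6$ for the six predictors — the most natural reading of a
correction "across predictors"; both $m$ and the region are configurable.
For the trajectory predictor, the predicted left/right means of each
shuffled refit are grouped by the shuffled assignment — the model's own
trajectory variable — which makes the shuffled differences exchangeable
with the observed one under the null; grouping by the original labels
instead lets the trajectory polynomial's overfit of side-aligned noise
inflate the observed difference but never the null, and the test becomes
strongly anti-conservative.  With this grouping the T test is
well-calibrated (its null rejection rate matches the Bonferroni-nominal
level in simulation) and is the package's inferential output.  A caveat
applies to the trial-history covariates: trial number and the cumulative
correct rate are deterministically coupled, so shuffling one while
holding the other breaks their joint structure and the resulting null is
mis-specified — simulations show the trial-number test over-flags well
above its nominal level even on null units.  Flags on those covariates
should be read qualitatively, not as calibrated hypothesis tests.  The
shuffle loop exploits the fact that only one column block changes per
shuffle: fixed cross-products are cached and each refit is a small
normal-equations solve, which keeps 3000 refits per unit to a few
seconds.

## Reward-epoch analysis

Per trial, spikes are binned at 10 ms over the first second after the
first lick, averaged per side, and smoothed with the same kernel
machinery (σ = 5 time bins = 50 ms).  Excitation/inhibition is judged on
the preferred side by paired t-tests of each 100 ms post-delivery segment
(and of the whole epoch) against the 100 ms pre-lick baseline.  For the
left/right reward preference the trial counts differ between sides, so a
literal paired test is not defined; the default is Welch's two-sample
t-test on per-trial epoch means, with pairing-by-rank available as an
option.  The link between spatial and reward coding is summarised by the
per-unit mean smoothed left−right difference in each section
($D_{start}, D_{cue}, D_{delay}, D_{arms}$) and in the reward epoch
($D_{reward}$), correlated across units (Pearson), and by the
six-category classification crossing delay preference
(left/right/ns, from the permutation test) with reward-side preference.

## Optotagging

Units are classed as light-responsive from pulse-aligned PSTHs: 1 ms bins
over the 12 ms pulse window, pooled over pulses; the 0–1 and 11–12 ms
bins contain stimulation artifacts and are excluded from testing.  The
decision statistic is a single upper confidence limit on baseline
activity, built here by resampling: `n_resamples`
(default 1000) surrogate pulse-onset sets are drawn uniformly from the
inter-stimulus baseline period, each surrogate's maximum non-artifact bin
rate is recorded, and the limit is the $1-\alpha$ quantile of those
maxima (default α = 0.01) — a global band controlling the family-wise
error across bins.  A unit is responsive when any non-artifact bin of its
real PSTH exceeds the limit.  Where mean waveforms for spontaneous and
light-evoked spikes exist, their Pearson correlation (flattened
channel-major) is attached; values above ~0.9 support that evoked spikes
come from the tagged unit itself.

## The synthetic-session generator

Every analysis stage is validated against sessions with planted ground
truth (`simulate_session()`).  The generator emulates the study's
conditions: 90 trials per session (80–100 in vivo) at an 87% correct
rate; balanced pseudo-random left/right trajectories; a 150 cm track with
the section layout above; per-trial mean running speed drawn lognormally
around 20 cm/s with smooth within-trial modulation floored at 20% of the
trial mean (enough structure to exercise occupancy normalization, which
is the point of the estimator); reward dwell uniform in 1–10 s; tracking
at 50 Hz.  Spikes are drawn from an inhomogeneous Poisson process by
thinning: rate = base rate × Gaussian place-field gain × trajectory gain
(2× on the preferred side inside the planted sections) × a step reward
factor over the 1 s consumption epoch.  DA-like units default to 5 Hz and
GABA-like units to 20 Hz base rates (the in-vivo account says only that
DA units fire more slowly; both are configurable), with lognormal spread
across units.  Tagged units answer each of 600 light pulses (4 blocks of
150, 12 ms pulses at 1–10 Hz and 1–4 mW) with probability 0.9 at a
4 ± 1 ms latency truncated to (1, 11) ms.

Planted unit counts use deterministic rounding (half away from zero) so
recovery tests have exact expected counts.  The default cohort plants
delay-modulated fractions of 0.20 (DA-like, of 100 units) and 0.47
(GABA-like, of 74), matching the reported in-vivo proportions, plus 0.25
arms+reward-coupled units per class whose trajectory gain lives in the
outer half of the side arms (135–150 cm, an anticipatory build-up on the
reward approach) and whose reward epoch carries a same-side 2× gain.
Keeping the delay- and arms-modulated sets disjoint, and the arms gain
outside the smoothing kernel's reach of the delay (the kernel support is
10 bins), makes the planted dissociation clean: the arms difference
correlates with the reward difference across units while the delay
difference does not — the structure the correlation analysis is designed
to detect.

What the generator does *not* emulate: bursting and refractoriness,
waveform drift, error-trial kinematics, overlapping delay+arms
modulation within one unit, and any reward-prediction-error structure.
Passing recovery tests therefore demonstrates correctness of the
estimators on Poisson-like spiking under realistic occupancy variation,
not performance on every feature of in-vivo data.

## Numerical choices and degenerate inputs

* Bins are 1..100; bin $x$ covers $((x-1)/100, x/100] \times 150$ cm,
  upper-inclusive, bin 1 closed at 0.  Sections are assigned by bin
  centre.
* Occupancy conservation ($\sum_x t_k(x)$ = start→lick duration) holds to
  one tracking sample; spike conservation is exact.
* Zero-variance paired differences (identical pre/post rates, constant
  predictor columns) are reported as degenerate rather than producing
  NaN t-statistics; all-zero units get empty significance masks.
* Chi-squared independence tests use no continuity correction and report
  absence (with a reason) when a margin of the 2×2 table is zero; the
  α = 0.05 criterion is the χ²(1) critical value 3.841.
* Every stochastic routine takes an explicit seed; the pipeline derives
  per-stage seeds from one master seed with fixed offsets, so any stage
  can be rerun in isolation and full runs are bit-reproducible.

## Simulation sizes used by the validation suite

The acceptance-style checks run at these problem sizes, chosen as a
balance between statistical resolution and a desk-scale run: estimator
bias on 500 constant-rate trials; permutation exactness against the
exhaustive 20-assignment oracle at 3+3 trials; type-I error over 200 null
units and power over 100 planted units (90 trials, 1000 permutations);
GLM recovery and shuffle operating characteristics over 24 modulated plus
24 null units (100 trials, 500 shuffles, the planted coefficient vector
encoding a delay-localized trajectory bump and a smooth speed tuning);
optotagging sensitivity/specificity over 100 tagged and 100 untagged
units (600 pulses each); and one full default cohort (100 DA-like + 74
GABA-like units) end to end.

## Known limitations

* The package analyses linearized positions; raising 2-D video
  coordinates to a lap path is out of scope.
* The published exact test behind the optotag confidence limit and the
  permutation count/multiplicity handling of the original analysis are
  not fully specified in the text we implement from; the resampling band
  and the calibrated run-length criterion are this package's documented
  choices, not claims about the original code.
* The regression model is reproduced verbatim, including the trajectory
  coding quirk discussed above; users wanting an interpretable position
  main effect should treat the shuffle test, not individual coefficients,
  as the inferential output.
* Spike sorting, LFP analysis and reward-prediction-error modelling are
  out of scope.
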