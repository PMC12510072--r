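---
title: "Projecting long-term seizure rates to monitor drug effects: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projecting long-term seizure rates to monitor drug effects: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Deciding whether an anti-seizure medication (ASM) works is confounded by
multidien seizure cycles: periodic fluctuations in seizure risk with
periods of days to weeks. A seizure rate that falls after a drug change may
simply be a cycle trough. Chronic implanted EEG gives two objective
streams — detected seizure times and the hourly rate of interictal
epileptiform discharges (IEDs), which carries the cycle information — and
this package turns them into a personalised statistical answer: a rolling
projection of the long-term seizure rate whose residuals, compared against
a reference band, separate *expected* cyclical variation from *abnormal*,
possibly drug-related change.

The workflow has five stages, each usable on its own:

1. **preprocess** — detection filtering, daily counts, gap filling, causal
   90-day moving average;
2. **cycles** — Morlet wavelet scan of the hourly IED rate for significant
   1–45-day periods, with per-day sine/cosine phase regressors;
3. **forecast** — rolling ARIMAX projection of the smoothed rate 14 days
   ahead, updated daily;
4. **evaluate** — per-segment performance comparison across drug regimens,
   with a value-shuffled surrogate control;
5. **monitor** — residuals against a ±3 SD reference band with
   persistence-based changepoints.

`run_pipeline()` composes them; a synthetic virtual-participant generator
makes every stage testable without patient data.

## The smoothed seizure rate

Detections with estimated probability below 0.99 are discarded
(`filter_detections`), the remainder binned into calendar-day counts
(half-open UTC day bins). Recording gaps in the hourly IED stream are
filled by linear interpolation between the flanking observations plus
zero-mean Gaussian noise (`fill_gaps`); the noise SD is estimated as
`sd(diff(observed))/sqrt(2)` — the innovation scale implied by first
differences of a random-walk-like series — and can be overridden
(`noise_sd = 0` gives plain interpolation). Leading and trailing missing
samples are trimmed rather than extrapolated, because interpolation needs
two anchors.

The modelled quantity is the *causal* 90-day moving average of daily
counts, in seizures/day: the value at day *t* averages days
*t − 89 … t* only, so it is available in real time. The first 89 days are
a warm-up, flagged in the series mask and excluded from model fitting
(during warm-up the running mean over the available days is stored, so the
series is still plottable). Smoothing this heavily attenuates the 1–45-day
cycles themselves; what remains is the slow trend the clinician actually
tracks, plus noise whose variance scales with the underlying Poisson
level — a point that matters for regimen discrimination below.

## Cycle detection

The hourly IED rate is scanned with a continuous Morlet wavelet transform
(centre frequency ω₀ = 6), implemented in the frequency domain: the
daughter wavelet at scale *s* is
√(2πs/Δt)·π^(−1/4)·exp(−(sω − ω₀)²/2) on positive frequencies, and
period and scale are related by T = s·4π/(ω₀ + √(2 + ω₀²)). Candidate
periods span 1–45 days on a logarithmic grid with 24 periods per octave
(133 periods). No zero-padding is applied: the FFT is taken at native
length (mixed-radix), wrap-around edge effects are handled by excluding
the cone of influence (samples closer to an edge than the e-folding time
√2·s) from all power averages, and the unpadded transform admits an exact
Parseval identity used by the significance test.

**Significance.** Each period's global (time-averaged, COI-excluded)
power is compared with a null distribution obtained by shuffling the
series values `n_perm` times; p = (1 + #{null ≥ observed})/(n_perm + 1),
Benjamini–Hochberg corrected at q = 1 − `fdr_level` (0.05 at the default
level 0.95), and contiguous significant periods are collapsed to their
local power maximum. For each shuffle the global power is evaluated in
closed spectral form — by Parseval, the time-mean of |W|² equals
Σ_k |x̂_k|²·|ψ̂(sω_k)|² — so a permutation costs one FFT plus a matrix
product. The null therefore averages over *all* samples while the observed
statistic excludes the COI; for a value-shuffled (exchangeable) series
both averages have the same expectation, and per-period p-values were
verified uniform on white noise by simulation.

**A calibration caveat worth knowing.** With `n_perm = 200` the smallest
attainable p-value is 1/201 ≈ 0.005, while the BH rank-1 threshold over
133 periods is 0.05/133 ≈ 0.0004. An isolated period can therefore never
be declared significant at that permutation resolution; a discovery
requires a run of ≥ 14 contiguous periods at the permutation floor, which
a genuine cycle produces (the wavelet response is about an octave wide)
but white noise essentially never does. The test is thus *conservative*
at small `n_perm`: its family-wise false-alarm rate on noise is far below
the nominal q, never above it. Detection power is unaffected in practice —
injected 5-day and 20-day cycles of modest depth are both recovered within
one scale step in ≥ 90% of simulated datasets — but users wanting
calibrated single-period inference should raise `n_perm` toward
3000 (where the floor drops below the rank-1 threshold).

**Phases.** The phase at a significant period is the argument of the
complex coefficient at that scale; hourly phases are reduced to daily
values at the 12:00 sample (the day-bin midpoint), and the regressor
matrix holds (sin φ, cos φ) per period, so each row satisfies
sin²+cos² = 1. Period *selection* runs on the training span only (no
test-set leakage); phase *extraction* runs over the full series, because
the pre-drug test segments predate the training window and need
regressors too. Future phases, needed to project ahead, advance at the
constant angular velocity 2π/T per day from the origin's phase.

## Rolling projection

The smoothed rate y_t is modelled as a regression with ARIMA(p,d,q)
errors: y_t = β′x_t + η_t, with x_t the sin/cos phase regressors and η_t
an ARIMA process, estimated by maximum likelihood (`stats::arima`,
CSS-ML with a CSS fallback). A constant series yields a degenerate fit
(intercept, zero innovation variance) rather than an error, and
non-convergence is flagged so the grid search can skip the candidate.

Projections are produced on a rolling origin, one per day: at origin *t*
the model conditions on the trailing window of the longest lag plus one
day (max(p + d, q) + 1 points) and forecasts 14 days ahead; the record
stores the point projection, a Gaussian 95% interval (±1.96 × the
forecast SE, scaled by the *training* innovation variance, not a
re-estimate from the short window), the observed value at the target
date, and the residual (observed − projected, indexed by target date).

Two update policies exist. The default, `refit_policy = "fixed"`,
estimates coefficients once (on the training span) and treats the daily
update as advancing the Kalman conditioning window — with a window of
max-lag + 1 points there are no degrees of freedom left to re-estimate
p + q + 1 coefficients daily, so this is the only identifiable reading of
a minimised input window. `"refit"` re-estimates daily on an enlarged
trailing window (p + d + q + 20 points at minimum) for users who want
coefficients to drift.

Hyperparameters are chosen by grid search with repeated hold-out: each of
`n_iter` iterations draws a random contiguous validation block covering
30% of the train/validation span, fits each candidate on the data strictly
before the block, and scores the rolling horizon-ahead MSE across it;
candidates are ranked by average MSE with ties broken toward the smaller
p + d + q. Naive AR(1) and MA(5) benchmarks run under the identical
rolling protocol. The bundled default projection order is ARIMAX(5,1,1):
d = 1 absorbs the slow trend, five AR lags plus one MA term are the
smallest structure that tracked the smoothed series' short-range
dynamics, and larger orders (including the 51-lag variant the grid
admits) change desk-scale results only marginally while multiplying cost.

## Regimen comparison

Performance is compared across labelled date segments (two pre-drug and
two post-drug test segments of ~3 months, plus the 369-day training
span). The compared samples are **per-block mean squared errors** over
non-overlapping 14-day (one-horizon) blocks within each segment, not raw
daily residuals, for two reasons. First, the scientific contrast is about
*performance* (error magnitude): signed residuals of a model trained on
one regimen have near-zero mean in every segment, so a location test on
them is blind to the contrast, whereas squared errors express it
directly. Second, daily 14-step-ahead errors from overlapping origins
share innovations over a range of one horizon; rank tests assume
exchangeable observations, and non-overlapping blocks restore that
approximately under the null. The omnibus test is Kruskal–Wallis (tie
corrected; H is defined as 0 when every value is tied), followed by
pairwise two-sided Wilcoxon rank-sum tests with Bonferroni correction
(multiplier = number of pairs; exact p-values for small tie-free groups).

The surrogate control re-runs fit, projection and comparison on a copy of
the smoothed series whose values are randomly permuted (dates kept, the
value multiset preserved, train/test splits unchanged). Shuffling
destroys the temporal structure the model exploits, so segment
differences should vanish — and an intact difference on surrogates would
flag an artefact of the evaluation itself.

## Residual monitoring

The reference band is r̄ ± 3·s_r, with r̄ and s_r the mean and SD of the
training/validation residuals. Days outside the band are flagged; a
changepoint is declared at the first day of a run of at least
`persistence_days` (default 14, one horizon — chosen to suppress
single-day flag chatter) consecutive days in one flag state following the
opposite confirmed state. A sustained excursion therefore produces
exactly two changepoints: onset and return to the normal range. The SD of
a constant reference is rejected rather than silently producing a
zero-width band.

## The virtual participant

No public recording accompanies this kind of single-participant study, so
the generator produces data with the statistical structure the analysis
assumes, emulating a ~3-year implanted-EEG case history:

* **Seizures**: an inhomogeneous Poisson process with daily intensity
  λ(t) = r₀·(1 + Σ_k d_k·cos(2πt/T_k + φ_k))·f_drug(t); defaults r₀ = 2.8
  seizures/day over 1100 days (≈ 3100 detected events, the scale of the
  recorded case), cycles of 20 d (depth 0.3) and 5 d (depth 0.15).
  Depths must sum below 1 so the intensity stays positive.
* **Drug**: a multiplicative factor from the change day (day 300)
  onward — 1.0 is an inert drug — optionally times a short-lived
  titration dip (default 45 days at 0.6) that fades, emulating tolerance.
  In the *active* discrimination scenario the chronic factor is 0.3,
  chosen so the implied pre/post error-variance contrast (the smoothed
  count noise scales with the Poisson level, ratio 1/0.3 ≈ 3.3×) matches
  the magnitude of contrast the method is designed to flag (≈ 4×).
* **IEDs**: hourly rate r_IED·(1 + Σ_k g_k·cos(2πt/T_k + φ_k)) + Gaussian
  noise truncated at zero (baseline 40/h, gains 0.3/0.15, noise SD 8) —
  phase-locked to the seizure intensity, which is exactly the assumption
  the ARIMAX exploits.
* **Gaps and diary**: two extended recording gaps (30 and 21 days) marked
  missing, and a diary that records each detected event independently
  with probability 0.3744 (the reported-fraction of the recorded case).

What the generator does **not** emulate: circadian (sub-daily) structure
beyond uniform within-day event times, circannual cycles (> 45 d),
detector false positives/negatives, drifting cycle periods, or
state-dependent reporting. Passing tests therefore show the pipeline is
correct and powerful *under its own assumptions* — phase-locked
stationary cycles and level-type drug effects — not that real recordings
satisfy those assumptions.

## Numerical choices and degenerate inputs

* Day bins are half-open [00:00, 24:00) UTC; all timestamps are stored in
  UTC and no DST arithmetic is attempted.
* The wavelet scan refuses series shorter than twice the longest
  candidate period; phase extraction and the transform refuse gapped
  input (fill first).
* `fill_gaps` errors on all-missing input and needs two observed anchors;
  filled values are clipped at 0.
* The random walk (0,1,0) is an admitted order (p + d + q ≥ 1 is the
  validity rule), and its projection is exactly the last value.
* Grid-search candidates that fail to converge score NA per iteration and
  are dropped from the ranking only if they never converge.
* Every stochastic step (simulation, gap noise, shuffles, hold-out
  blocks) takes an explicit integer seed; identical configuration and
  seeds give byte-identical pipeline artifacts.

## Problem sizes used in the tests

The test-suite simulations use: 1100-day virtual participants (hourly IED
series of 26,400 samples) for end-to-end runs, 25 seeds per arm of the
discrimination property; 730-day hourly series with 200 permutations and
100 seeds for cycle recovery; 730-day daily white-noise series with 200
permutations and 500 seeds for the false-alarm calibration; AR(1) series
of n = 5000 with 50 seeds for parameter recovery. These sizes were chosen
so the whole suite documents the method's behaviour at the scale of the
emulated case while remaining convenient to run routinely.

## Known limitations

* Cycle detection is retrospective (the full-series wavelet transform is
  acausal); an online variant would need causal filters.
* Period selection assumes cycles are stationary over the training span.
* The ±3 SD band assumes roughly Gaussian, homoscedastic reference
  residuals; heavy-tailed residuals would widen it unduly.
* With `n_perm = 200` the permutation/BH combination is conservative for
  isolated periods (see the calibration caveat above).
* The block-MSE rank tests treat blocks as exchangeable; residual
  dependence beyond one horizon (e.g. from cycles longer than the
  candidate range) would inflate their size somewhat.
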