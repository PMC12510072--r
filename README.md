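# szproject

Personalised seizure-rate projection and drug-effect monitoring from
chronic implanted-EEG detections.

## The problem

Judging whether an anti-seizure medication works from seizure counts alone
is unreliable: diaries under-report heavily, and multidien seizure cycles
(periodic risk fluctuations with periods of days to weeks) make natural
rate changes look like treatment effects. For people with a sub-scalp
EEG implant, two objective streams are available instead — detected
seizure times and the hourly rate of interictal epileptiform discharges
(IEDs), which tracks the cycles. `szproject` is aimed at researchers and
methodologists working on objective ASM-efficacy assessment from such
recordings.

## The method

The package models the long-term seizure rate
`y_t` (a causal 90-day moving average of daily seizure counts,
seizures/day) as a regression with ARIMA errors on cycle phases:

    y_t = beta' x_t + eta_t,        eta_t ~ ARIMA(p, d, q)

where `x_t = (sin phi_T(t), cos phi_T(t))` for each significant IED-cycle
period `T`. Periods in 1–45 days are found by a continuous Morlet wavelet
transform (omega_0 = 6) of the hourly IED rate, tested against a
value-shuffling permutation null with Benjamini–Hochberg correction;
phases are the arguments of the wavelet coefficients at the significant
scales. The fitted model produces rolling daily projections 14 days
ahead (conditioning on the longest lag plus one day of history) with 95%
intervals. Projection performance — per-block mean squared error — is then
compared across drug-regimen segments with a Kruskal–Wallis omnibus test
and Wilcoxon/Bonferroni post-hocs, with a value-shuffled surrogate as a
negative control, and daily residuals are monitored against the
`mean ± 3 SD` band of the training residuals: a sustained excursion marks
an abnormal (possibly drug-related) seizure-rate change, and its onset
and return are reported as changepoints.

Because single-participant recordings of this kind are not publicly
available, the package ships a virtual-participant generator (cyclically
modulated Poisson seizures, phase-locked IED rates, drug changepoints
with titration transients, recording gaps, diary thinning) so the whole
pipeline is testable end to end.

## Worked example

Simulate a participant whose drug change reduces the seizure intensity to
30% (with a 45-day titration dip), then run the full pipeline:

```r
library(szproject)
cfg <- sim_config(seed = 3, drug_effect = 0.3)
res <- run_pipeline(pipeline_config(sim = cfg, n_perm = 200, seed = 3),
                    out_dir = "demo")
res$cycles
res$report
res$monitor
```

which prints:

```
<cycle_set> 2 significant period(s): 5.04 d, 20.16 d; 1100 days of phase regressors
<evaluation_report> Kruskal-Wallis H = 14.97, df = 4, p = 0.00476
  per-segment MSE:
      train  pre-drug-1  pre-drug-2 post-drug-1 post-drug-2
     0.0042      0.0104      0.0069      0.0018      0.0060
  post-hoc (Bonferroni-adjusted, alpha = 0.05):
             train pre-drug-1 pre-drug-2 post-drug-1 post-drug-2
train           NA     0.3778     0.0711      1.0000      0.6949
pre-drug-1  0.3778         NA     1.0000      0.1515      1.0000
pre-drug-2  0.0711     1.0000         NA      0.0216      1.0000
post-drug-1 1.0000     0.1515     0.0216          NA      0.4113
post-drug-2 0.6949     1.0000     1.0000      0.4113          NA
<monitor_state> band -0.1987 .. 0.1916 (+/- 3 SD); 80/990 days flagged
  changepoints: 2020-11-07, 2021-01-29
```

Reading the output: both injected IED cycles (5 d and 20 d) are recovered
within one step of the scale grid. The model — trained on a 369-day
post-drug span — projects post-drug test segments with MSEs of
0.0018–0.0060 (seizures/day)^2 but pre-drug segments 2–5× worse, and the
Kruskal–Wallis test rejects equal performance across regimen segments
(p = 0.0048); on the same data with values shuffled (`res$surrogate`) the
difference disappears. The residual monitor flags the post-titration
excursion and brackets it with an onset and a return changepoint. With an
inert drug (`drug_effect = 1`) the omnibus test does not reject.

The pipeline writes plain-text artifacts (`events.csv`, `ied_filled.csv`,
`smoothed.csv`, `cycles.csv`, `projections.csv`, `report.json`,
`run.log`) so each stage can be inspected or re-run independently.

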