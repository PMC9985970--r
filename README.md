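# vocalrhythm

Tools for quantifying the rhythm of *interactive* animal vocalization:
who calls when, relative to whom, and by what timing mechanism. The package
was built around harbour seal pup call exchanges recorded in four
behavioural contexts — calling alone, with a silent partner, answering a
one-way playback, and in a two-way exchange with a real partner — but it
operates on plain annotated event tables (onset/offset times per caller)
and applies to any turn-taking signal system with discrete events.

It is aimed at bioacousticians and behavioural ecologists who have
time-stamped call annotations and want a tested, reproducible route from
those annotations to the standard rhythm statistics.

## What it computes

Given calls grouped into **bouts** (runs of ≥ 3 calls whose silent gaps stay
within 1.5× the median inter-call interval), four analysis families:

1. **Response-phase circular statistics.** Each focal response is an angle
   `θ = (t_focal − t_p2) / (t_p2 − t_p1) × 360°` — the latency after the
   partner's last call as a fraction of the partner's preceding
   inter-onset interval (IOI). Summaries (circular mean μ, mean resultant
   length ρ) and a test battery: Rayleigh, V-test against a specified
   direction, Kuiper, Rao spacing (Monte Carlo p), Watson one-sample U²
   von Mises goodness of fit (parametric bootstrap p), Watson two-sample
   U² for cross-context comparison (permutation p).
2. **Categorical rhythm analysis.** Ratios of adjacent IOIs,
   `r_k = t_k / (t_k + t_{k+1})` (isochrony ↦ 0.5), compared by one-sample
   KS test against a simulated null built from uniform IOIs over the
   observed range, with paired Wilcoxon tests for peaks at small integer
   ratios (1:4 … 4:1) in an on-/off-integer binning, and two-sample KS
   tests across contexts.
3. **Granger causality.** Does the partner's call timing improve
   prediction of the focal caller's timing beyond its own history? OLS
   F-tests over lags 1–5, both directions, at session and bout level, with
   bout-boundary masking.
4. **ADAM** (adaptation and anticipation model). A timekeeper model of the
   responding caller: phase correction α and period correction β
   (adaptation), prediction–tracking weight m and anticipatory error
   correction γ (joint version), noise σ. Fitted by bounded least squares
   on one-step-ahead onset predictions over concatenated bouts; estimate
   reliability is judged against permutation envelopes obtained by
   shuffling the partner's interval order. Under tempo-matched noiseless
   conditions the asynchrony obeys `A_{n+1} = (1 − α) A_n` exactly.

A synthetic-data module generates full four-context datasets with known
coupling structure (ground-truth manifest included), so the entire pipeline
can be validated without any recordings.

## Worked example

Simulate a playback session in which the focal animal answers at one
quarter of the stimulus period, then analyse it:

```r
library(vocalrhythm)

cfg <- sim_config(context = "one_way", partner_jitter = 0.05, seed = 42,
                  responder_params = list(fraction = 0.25, noise = 0.05))
partner <- gen_partner_sequence(cfg)
focal   <- gen_responder(partner, cfg)
calls   <- rbind(partner, focal); calls$true_bout <- NULL

seg    <- segment_bouts(calls, ici_scope = "per_individual")
phases <- response_phases(seg, "focal1", "partner1")
circular_summary(phases$angle_deg)
#> Circular summary (n = 68)
#>   mean direction mu  : 91.28 deg
#>   resultant length   : 0.9810
#>   circular SD        : 11.21 deg

rayleigh_test(phases$angle_deg)[, c("test_name", "statistic", "p_value")]
#> # A tibble: 1 × 3
#>   test_name statistic  p_value
#>   <chr>         <dbl>    <dbl>
#> 1 rayleigh      0.981 3.56e-27
```

The phases cluster tightly at a quarter period (μ ≈ 91°, ρ ≈ 0.98): the
caller is answering asynchronously, not in synchrony (a V-test against 0°
is non-significant, against 90° highly significant). To see the timekeeper
model at work, simulate a responder governed by known ADAM gains
(`alpha = 0.5`, `beta = 0.1`, 0.05 s noise) and fit it blind:

```r
cfg2 <- sim_config(context = "one_way", partner_jitter = 0.1, seed = 42,
                   responder_model = "adam",
                   responder_params = list(
                     adam = adam_params(alpha = 0.5, beta = 0.1, sigma = 0.05)))
p2 <- gen_partner_sequence(cfg2)
calls2 <- rbind(p2, gen_responder(p2, cfg2)); calls2$true_bout <- NULL
seg2 <- segment_bouts(calls2, ici_scope = "per_individual")
series <- build_paired_series(seg2, "focal1", "partner1", level = "bout")
fit <- adam_permutation_test(concatenate_bouts(series), "adaptation_only",
                             n_perm = 200, seed = 1)
fit$fit
#> ADAM fit (adaptation_only), 68 prediction terms
#>   alpha  =   0.5453 [two_tailed]
#>   beta   =   0.0862 [two_tailed]
#>   sigma  =   0.0442 s
#>   sse    = 0.133076
```

Both gains are recovered near their true values and fall outside the
2.5–97.5% permutation envelope (`two_tailed`): the responder's timing is
genuinely contingent on the partner, not an artifact of matched tempos.
(A `quarter_phase` responder, by contrast, fits with near-zero gains and
`ns` flags — it anticipates the upcoming stimulus rather than correcting
past asynchronies, a distinction the model family is built to expose.)
The full pipeline — all contexts, all analyses, tidy CSV/JSON outputs — is
one call:

```r
gen_dataset(default_study_configs(3), "calls.csv")
run_pipeline("calls.csv", "results/", seed = 11)
```

writing `circular_results.csv`, `ratio_results.csv`, `granger_results.csv`,
`adam_results.json` and `summary.json`.

## Layout

| Path | Contents |
| --- | --- |
| `R/annotations.R`, `R/timing.R` | annotation I/O, intervals, bouts, interactions, phases |
| `R/circular.R` | circular summaries and the six-test battery |
| `R/ratios.R` | IOI ratios, SIR binning, simulated nulls, KS/Wilcoxon |
| `R/granger.R` | paired series construction and Granger F-tests |
| `R/adam.R` | ADAM simulation, fitting, permutation envelopes, recovery |
| `R/synthetic.R` | four-context synthetic data with ground-truth manifests |
| `R/pipeline.R` | `run_pipeline()` orchestration |
| `vignettes/methods.Rmd` | the models, assumptions and design choices |
| `inst/scripts/vocalrhythm-pipeline.R` | thin command-line wrapper |
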