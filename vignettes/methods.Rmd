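---
title: "Quantifying interactive vocal rhythm: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying interactive vocal rhythm: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`vocalrhythm` quantifies the temporal structure of interactive vocal
sequences — who calls when, relative to whom — using four complementary
analytical families: circular statistics on response phases, categorical
rhythm analysis of inter-onset-interval (IOI) ratios, Granger causality
between paired call-timing series, and a generative sensorimotor
synchronization model (ADAM) with adaptation and anticipation modules. The
package was developed around harbour seal pup call exchanges recorded in
four behavioural contexts (calling alone, with a silent partner, responding
to a one-way playback, and in a two-way interaction with a real partner),
but every function operates on plain annotated event tables and applies to
any species or signal modality with discrete, time-stamped events.

This vignette explains each method as implemented, the tunable parameters
and their defaults, the synthetic data used for validation, and the design
choices made where the underlying methodology is genuinely open.

## The data model

The unit of input is a *call annotation*: session, behavioural context,
caller identity, role (`focal`, `partner`, or `playback`), onset and offset
in seconds. From onsets and offsets we derive, per caller or pooled:

* **IOI** (inter-onset interval): `onset[n+1] - onset[n]`;
* **duration**: `offset[n] - onset[n]`;
* **ICI** (inter-call interval, the silent gap): `onset[n+1] - offset[n]`,
  so `IOI = ICI + duration` by construction.

Calls are grouped into **bouts**: runs of at least three consecutive calls
whose internal gaps do not exceed 1.5 times the median ICI; any gap above
that threshold splits the sequence, and runs of fewer than three calls are
discarded. Bouts are the unit within which all ratio, Granger and ADAM
analyses operate — intervals never span a bout boundary.

One decision here is genuinely open: *which gaps enter the threshold
median* when several animals interleave their calls. The default
(`ici_scope = "pooled"`) takes the pooled onset-sorted sequence, which is
the most literal reading of a gap rule on "the recorded calls". In
overlapping duets, however, the pooled gaps alternate between near-zero
(stimulus-to-response) and most of a period (response-to-next-stimulus), so
1.5 times their median falls *between* the two modes and the rule shreds
every exchange into fragments. The `per_individual` option takes the median
over within-caller gaps instead, which recovers the intuitive bout
structure of a duet; `run_pipeline()` uses it throughout. Neither choice
affects single-caller contexts, where the two medians coincide.

## Response phases

A *vocal interaction* is a triplet within one bout: two partner calls
followed by a focal response. Its **response phase** is

$$\theta = \frac{t_{\mathrm{focal}} - t_{\mathrm{p2}}}
               {t_{\mathrm{p2}} - t_{\mathrm{p1}}} \times 360^\circ,$$

the focal latency as a fraction of the partner's preceding IOI, read as an
angle: 0° is synchrony with the partner's (extrapolated) next call, 90° is
a quarter period later. Responses later than one full period are wrapped
onto the circle (`raw mod 360`), with the number of elapsed whole periods
retained as a *winding* count; a discard mode (`wrap = FALSE`) is provided
for sensitivity analysis. Wrapping keeps sample sizes and treats the phase
as the circular quantity the statistics assume.

Intervening focal calls between the two partner calls of a triplet do not
disqualify it: the two *most recent* partner onsets before each focal call
are used. This matches playback designs in which responses fall between
periodic stimuli.

In the non-interactive contexts there is no external reference interval.
The package constructs *self-referential* phases — for call $n \ge 3$,
$\theta_n = (\mathrm{IOI}_{n-1} / \mathrm{IOI}_{n-2}) \times 360^\circ$ —
mirroring the interactive formula with the caller as its own reference. An
isochronous caller thus sits at 0° (one full period, winding 1), and
irregular solitary calling spreads over the circle. This construction is a
package decision: phase distributions are routinely reported for solitary
contexts without a stated reference, and the self-referential ratio is the
only definition that needs no partner while preserving the formula's
scale-invariance. Cross-context comparisons involving these phases should
be read with that in mind.

## Circular statistics

Angles are degrees at every interface and radians internally. For a sample
of $n$ angles, the mean resultant vector has direction $\mu$ (the circular
mean) and length $\rho \in [0, 1]$; the circular standard deviation is
$\sqrt{-2 \ln \rho}$, converted to degrees. $\rho$ is rotation-invariant
and equals 1 only for a point mass.

The test battery:

* **Rayleigh test** of uniformity against a unimodal alternative. The
  *reported* statistic is $\rho$ itself — the convention under which
  published statistics of order 0.04–0.4 at large $n$ are mutually
  consistent with their p-values — while the p-value uses the standard
  approximation based on $z = n\rho^2$.
* **V-test** of uniformity against a *specified* direction $\mu_0$:
  $V = \rho\cos(\mu - \mu_0)$, one-tailed normal approximation on
  $V\sqrt{2n}$. $V \le \rho$ always, with equality at $\mu_0 = \mu$; $V$
  is negative when the sample points away from $\mu_0$.
* **Kuiper's test**, the rotation-invariant analogue of the
  Kolmogorov–Smirnov test, with Stephens' small-sample correction on the
  asymptotic series.
* **Rao's spacing test**, $U = \tfrac12\sum_i |T_i - 360/n|$ over arc
  spacings $T_i$, sensitive to multimodal departures; its p-value is Monte
  Carlo against $10^4$ uniform samples (the classical tables interpolate
  awkwardly, and the null depends only on $n$, so the simulated null is
  reusable across samples via `rao_null_statistics()`).
* **Watson's one-sample $U^2$** as a von Mises goodness-of-fit test: the
  sample is transformed through the CDF of a von Mises distribution fitted
  by maximum likelihood ($\mu$ from the resultant, $\kappa$ by inverting
  $I_1/I_0$), and the p-value comes from a parametric bootstrap (default
  999 replicates) that refits in every replicate, so the estimation step is
  accounted for — classical $U^2$ tables assume fully specified parameters.
* **Watson's two-sample $U^2$** for comparing phase distributions across
  contexts, with a label-permutation p-value (default 999 permutations;
  reported as $(k+1)/(N+1)$) and the standard asymptotic series alongside.

The von Mises CDF is computed by trapezoidal integration of the density on
a 1024-point grid (error well below the $U^2$ resolution at any feasible
$\kappa$); von Mises sampling uses the Best–Fisher rejection algorithm.
All six tests hold their nominal type-I error within the binomial 95%
confidence band at $\alpha = 0.05$, $n = 50$, 1000 replicates — this is
asserted in the acceptance test suite, not merely claimed.

## Categorical rhythm analysis

For each pair of adjacent IOIs within a bout, the ratio
$r_k = t_k / (t_k + t_{k+1})$ maps isochrony to 0.5 and satisfies
$r(t_1, t_2) + r(t_2, t_1) = 1$. Which onsets define the IOIs depends on
the analysis: only the focal caller's own calls (`ioi_mode = "own"`, also
covering the disregard-the-partner analysis of interactive bouts) or all
calls in the bout (`"pooled"`, the responding-to-partner analysis).

The null hypothesis of *no rhythmic categories* is made concrete by
simulation: IOI pairs drawn i.i.d. from a uniform law over the observed IOI
range, their ratios forming an interpolated ECDF that is continuous and
fully specified, as the one-sample KS test requires. For unit-uniform IOIs
this null has the closed form $F(r) = r / (2(1-r))$ for $r \le \tfrac12$
(and its reflection above), which the simulated ECDF matches to sup-distance
< 0.01 at $10^5$ draws — the analytic oracle in the acceptance suite. A
bootstrap-from-empirical-IOIs generator is available but not the default.
Empirical ratio sets with fewer than 10 ratios are excluded (the
well-sampled criterion), mirroring standard practice.

Where the empirical distribution departs from the null, evidence for
*small-integer-ratio* (SIR) categories is sought at 1:4, 1:3, 1:2, 1:1,
2:1, 3:1 and 4:1 (ratio values $a/(a+b)$). The published boundaries of the
on/off-integer bins are not available in the source text, so the package
uses a symmetric midpoint geometry: cell edges at midpoints between
adjacent SIR values (outer cells extended symmetrically), each cell's
on-integer bin centred on the SIR value with width `on_fraction` (default
0.5) of the cell, the remainder split into two flanking off-bins. The
fraction is configurable; the default reproduces the alternating on/off
band structure of published ratio-density figures. Per bout, on-bin density
(count over width) is paired with flanking off-bin density and tested with
a two-sided paired Wilcoxon signed-rank test across bouts (at least 6
bouts; the pairing unit is the bout, with per-individual pooling available,
since the published analyses do not name the unit). Ratios outside the
outermost cells are excluded from SIR tests but retained in KS tests.

## Granger causality

Within each session, the $n$-th focal call is matched with the $n$-th
partner call (the longer stream trimmed), giving two aligned series of
onsets (default) or IOIs. The exact pairing construction is not specified
in the methodology this package re-implements; index-matching after
trimming is the simplest construction consistent with "paired calls", and
an interaction-cycle pairing can be emulated by restricting to alternating
bouts. Bout-level series require at least five paired calls (shorter bouts
are excluded with a logged reason); session-level series concatenate all
bouts with a boundary mask at the joins, and any regression row whose lag
window crosses a masked position is dropped rather than differenced across
the gap.

For lags 1–5 and each direction, a restricted autoregression of the target
on its own lags is compared with an unrestricted model adding the
predictor's lags, via the standard OLS F-test on the joint exclusion of the
predictor lags. Onset series are non-stationary by construction (they
trend); results in onset mode are invariant to time-origin shifts but
should be read with that stationarity caveat, and an IOI mode is provided
for sensitivity analysis. No multiple-testing correction is applied across
the 10 direction-lag cells (each cell is reported on its own), but a
Bonferroni column is emitted for the user. Scans report every cell,
flagging failed preconditions (`excluded_reason`) instead of dropping rows.

## The ADAM model

ADAM describes a caller as a noisy timekeeper coupled to its partner. With
focal onsets $f_n$, partner onsets $p_n$, asynchrony $A_n = f_n - p_n$ and
timekeeper interval $T$ (initialised to the mean partner interval):

**Adaptation-only** (phase correction $\alpha$, period correction $\beta$):

$$T \leftarrow T - \beta A_n, \qquad
  f_{n+1} = f_n + T - \alpha A_n + \varepsilon_n .$$

Under an isochronous partner with matched tempo and no noise, the
asynchrony obeys $A_{n+1} = (1 - \alpha) A_n$ exactly — the closed-form
oracle asserted to machine precision in the tests.

**Joint** (period correction $\beta$, prediction–tracking weight $m$,
anticipatory error correction $\gamma$): the anticipation module predicts
the partner's next interval as a weighted sum of linear extrapolation over
the last 3 partner intervals (window configurable) and tracking (copying)
of the last interval, $\hat S_n = m\,\mathrm{extrap} + (1 - m)\,S_{n-1}$;
the planned onset $f^* = f_n + T$ (with the same period update) is then
corrected toward the predicted partner onset:

$$f_{n+1} = f^* - \gamma\,\bigl(f^* - (p_n + \hat S_n + \tau)\bigr)
            + \varepsilon_n,$$

with target asynchrony $\tau = 0$ by default (a configurable offset target,
e.g. a quarter period, suits regimes where the species avoids overlap
rather than synchronising). At $\gamma = 0$ the joint model reduces exactly
to period-only adaptation; at $m = 0$ the prediction is pure tracking. The
noise $\varepsilon$ is i.i.d. Gaussian with scale $\sigma$.

These recursions follow the ADAM literature's module structure (the
original estimation code is in an unavailable supplement); bounds
$\alpha, \beta \in [-2, 2]$, $m \in [-3, 3]$, $\gamma \in [0, 2]$ are wide
and sign-symmetric because empirical estimates in vocal interaction data
are frequently *negative* — a caller that speeds up after calling late,
enhancing rather than reducing timing contrast.

**Estimation.** Parameters minimise the summed squared one-step-ahead
prediction error of the observed focal onsets over the bounded box, on
concatenated bouts with masked joins; the timekeeper state re-initialises
at each bout start (to that bout's mean partner interval), which makes a
fit on concatenated bouts agree with a fit on an equally long unbroken
series — verified in the tests. The adaptation-only predictions are
*linear* in $(\alpha, \beta)$, so that version is solved exactly by least
squares (falling back to the bounded optimiser only if the unconstrained
optimum leaves the box); the joint version is smooth but bilinear in its
parameters, and is optimised by bounded quasi-Newton (L-BFGS-B) from 16
Latin-hypercube starts, keeping the best local solution. A quasi-Newton
search was preferred over derivative-free alternatives because the
objective is smooth and cheap to evaluate after vectorisation, and the
multi-start envelope guards against local minima; fits are deterministic
given the seed. Noiseless simulations are recovered to $10^{-4}$; at 5%
relative noise and 60 calls, the mean absolute error of $\alpha$ stays
within 0.15.

**Permutation significance.** The reliability of each estimate is judged
against refits to data in which the *order of the partner's intervals* is
randomly permuted within each bout — preserving the marginal interval
distribution and bout structure while destroying temporal contingency.
(Permuting focal intervals instead is available as an alternative scheme.)
From `n_perm` (default 1000) refits, per-parameter percentiles {2.5, 5, 25,
50, 75, 95, 97.5} form the envelope; an estimate outside the 2.5–97.5 band
is flagged `two_tailed`, outside the 5–95 band in the direction of its own
sign `one_tailed`, otherwise `ns`. Under uncoupled simulation the
two-tailed flag fires at its nominal 5% rate per parameter (acceptance
check at 200 datasets × 200 permutations).

## Synthetic data: what it emulates and what it does not

The generator produces the study conditions end to end: sessions of 34–121
paired calls, bouts of 5–20 calls, four behavioural contexts. Defaults that
the emulated study does not print are engineering choices, stated once
here: partner period 2 s, multiplicative truncated-normal IOI jitter (5%
for playback streams, 25% for solitary callers, keeping intervals
positive), call durations uniform on 0.3–1.0 s, inter-bout gaps of 10 s
(validated at construction to exceed 1.5 partner periods so the generated
bouts survive the segmentation rule). Responders are `quarter_phase`
(onset at a fixed fraction — default one quarter — of the current partner
interval, the regime that produces a 90° phase peak), `adam`
(an `adam_simulate()` agent), or `uniform_random` (phase-uniform null).
Two-way data come from two mutually correcting timekeeper agents targeting
half-period offsets from each other, with per-agent gains and noise —
asymmetric gains produce asymmetric Granger detectability, symmetric gains
symmetric detectability, and a ground-truth manifest (seeds, true
parameters) accompanies every dataset for recovery scoring.

What the synthetic data do *not* contain: amplitude and spectral cues,
call-type variation, drifting base tempo, overlapping background callers
from neighbouring enclosures, and annotation error. Passing tests on these
data therefore validate the *statistical machinery* — calibration, power,
recovery, determinism — not the ethological conclusions one would draw
from real recordings.

## Numerical choices and degenerate inputs

* Onset ties are broken by (individual, offset); zero or negative IOIs are
  rejected at the interval layer with row-level errors.
* Tests refuse samples below their validity floor (Rayleigh/V at $n < 4$,
  suite and two-sample $U^2$ at $n < 8$, KS at fewer than 10 ratios,
  Wilcoxon at fewer than 6 bouts, ADAM at fewer than 10 prediction terms)
  with typed `insufficient data` errors rather than returning fragile
  numbers; resampling replicate counts below 99 (bootstrap/permutation) or
  $10^4$ (ratio nulls) are configuration errors.
* Permutation and bootstrap p-values are $(k+1)/(N+1)$, never 0.
* A constant predictor series makes the Granger design singular and raises
  a degeneracy error; an all-zero set of Wilcoxon paired differences is
  returned as a `degenerate` flag rather than a p-value.
* The mean direction is flagged undefined when $\rho = 0$ (e.g. four
  equally spaced angles); $\kappa$ estimation caps at $10^6$ with an
  asymptotic Bessel-ratio branch above $10^4$.
* All randomness flows from explicit seeds; per-stage seeds are derived
  from the master seed by a fixed integer hash, and identical
  (input, seed) pairs produce byte-identical pipeline outputs.

## Problem sizes used in the validation suite

The packaged tests exercise: calibration at $n = 50$ with 1000 replicates
per circular test (199 bootstrap/permutation replicates inside each);
ratio-null convergence at $10^5$ simulated pairs; ADAM recovery at 60-call
series with 100 noisy replicates; Granger calibration at 1000 replicates of
length-50 series; and permutation-envelope calibration at 200 datasets ×
200 permutations. These sizes give the stated statistical resolution (e.g.
binomial 95% bands of roughly ±1.4 percentage points on a 5% rate at 1000
replicates) while keeping the full suite runnable on a laptop in minutes.

## Known limitations

* Granger analysis in onset mode inherits the non-stationarity of onset
  series; the IOI mode is the more defensible variant and both are one
  F-test per cell, not a model-selection procedure.
* The ADAM noise model is additive Gaussian on onsets; heavy-tailed motor
  noise or drifting tempo will bias $\sigma$ and can leak into $\beta$.
* Phase analysis in non-interactive contexts depends on the
  self-referential construction above; alternative references (e.g. the
  session-median IOI) would change those distributions.
* The SIR bin geometry is a reconstruction, not the published table; SIR
  test outcomes can shift with `on_fraction`.
* With fewer than about 30 prediction terms, joint-model parameters are
  weakly identified and the permutation envelope widens accordingly.
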