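---
title: "Quantifying EEG burst suppression: models, parameters and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying EEG burst suppression: models, parameters and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7,
                      fig.height = 3.5)
library(bspquant)
```

## The problem

Patients with refractory status epilepticus are commonly placed in a
pharmacologically induced coma with intravenous anesthetics (propofol,
midazolam, ketamine, pentobarbital), titrated against the EEG until it shows
*burst suppression*: an alternation of high-voltage bursts and low-voltage
suppressions. Institutional guidelines phrase the target as a suppression
fraction — for example one burst per ten seconds, i.e. about 80% of time
suppressed. `bspquant` implements the quantitative machinery needed to audit
how much suppression was actually achieved: segmentation of multichannel EEG
into a binary burst/suppression signal, estimation of the *burst suppression
probability* (BSP) with uncertainty, compliance metrics against a reference
band, Bayesian comparison of patient groups, and analysis of BSP drift and
between-patient spread at matched anesthetic doses. A synthetic cohort
generator with a known ground truth stands in for clinical recordings, which
cannot be redistributed.

## Segmentation

The preprocessing chain follows clinical convention: epochs (1 s, half-open)
containing any sample above 500 µV on any channel are discarded; the record
is band-pass filtered at 0.5–55 Hz and re-referenced to the average montage;
each channel is binarized; and a global signal is formed by voting.

Numerical choices:

* **Filtering** is done in the frequency domain with a real, symmetric
  (hence zero-phase) response and raised-cosine transitions, after mirror
  padding and mean removal. There is no IIR filter-design dependency in the
  supported environment, and the FFT route gives exactly unit passband gain.
* **Binarization** thresholds a rectified-amplitude envelope
  $e_t = \beta e_{t-1} + (1-\beta)\,|v_t|$ at $\theta = 5$ µV with a
  ±20% hysteresis band and a 0.5 s minimum state duration. The envelope
  time constant defaults to $\tau = 0.2$ s. A multi-second constant, which
  one might expect from smoothing-based burst-suppression ratios, is not
  usable here: an exponential envelope falling from a 25 µV burst to a
  2.5 µV suppression crosses the lower hysteresis bound only after
  $\approx 2.2\,\tau$, so with $\tau = 2$ s every burst shorter than
  several seconds — i.e. the typical 1–2 s burst — would be missed
  entirely. With $\tau = 0.2$ s transitions are localized to within half
  the minimum state duration, and on noise-free synthetic records the full
  chain reproduces the generating state sequence essentially exactly away
  from ±0.5 s transition zones.
* **Voting** marks a sample suppressed when *strictly more than half* of
  the contributing channels say so; ties go to burst, which is the
  conservative direction (toward detecting cerebral activity). Channels can
  abstain per sample (`NA`), in which case the majority is taken over the
  contributors.

## The BSP state-space model

The global binary signal is aggregated into per-epoch binomial counts
($n_t$ suppressed of $N_t$ valid samples; artifact-masked epochs have
$N_t = 0$). The BSP is the observation probability of a latent logit-scale
random walk,

$$x_t = x_{t-1} + v_t,\quad v_t \sim \mathcal N(0, \sigma_v^2), \qquad
  n_t \sim \mathrm{Binomial}\!\left(N_t,\ \mathrm{logistic}(x_t)\right),$$

estimated by a forward filter (posterior mode by damped Newton iteration,
variance from the curvature at the mode) and a Rauch–Tung–Striebel
fixed-interval smoother. Missing epochs propagate the prediction, so gaps
widen — never shrink — the credible interval. Credible bounds are
$\mathrm{logistic}(x_t \pm 1.96\sqrt{\mathrm{var}_t})$; the Gaussian
approximation on the logit scale is standard for this model family and no
exactness is claimed. The initial state is the logit of the first valid
epoch's rate clipped to $[0.01, 0.99]$, with prior variance 1 (weakly
informative); the Newton iteration converges to $|\Delta x| < 10^{-8}$,
with the step clamped to ±4 because the binomial log-likelihood saturates
far from the data.

**Serial correlation and the effective sample size.** Bursts and
suppressions last seconds, so the ~256 samples inside a 1 s epoch are far
from independent: treating them as independent makes the filter chase the
noisy per-epoch fraction instead of the underlying probability. For an
alternating-renewal process with mean burst duration $\mu_b$ and mean
suppression duration $\mu_s$, the correlation time is
$\tau = \mu_b\mu_s/(\mu_b+\mu_s)$ and a $T$-second average carries
$T/2\tau$ effective observations. `estimate_epoch_ess()` estimates this
from the signal's own run lengths, and `bsp_filter()` down-weights each
epoch by $\min(1, \mathrm{ess}/N_t)$. For genuinely independent data
(ess $\gg N$) the correction vanishes automatically; it can be disabled
with `ess = NA`.

The process-noise variance defaults to $\sigma_v^2 = 0.005$ per epoch and
can be estimated by EM (`estimate_sigma_v2()`, requiring ≥ 100 valid
epochs); the EM M-step uses smoothed means, variances, and lag-one
covariances, and the estimate is floored at $10^{-8}$. The windowed burst
suppression ratio (`windowed_bsr()`) is provided as the traditional
steady-state cross-check; its centered window holds exactly
`window * fs` valid samples.

```{r bsp-demo}
truth <- rep(c(0.3, 0.8), each = 1800)            # one hour, step at 30 min
st <- simulate_state_sequence(truth, fs = 64, seed = 1)
sig <- binary_signal(st, fs = 64)
traj <- bsp_estimate(epoch_counts(sig))
glance(traj)
autoplot(traj)
```

## Compliance metrics and group comparison

The guideline target of 80% suppression is interpreted as the reference
band BSP $0.8 \pm 0.15$. Per subject, over valid epochs within documented
intent periods only, the package reports the percentage of time above
(`pt_a`, BSP > 0.95), within (`pt_i`, 0.65 ≤ BSP ≤ 0.95, inclusive at both
edges) and below (`pt_b`, BSP < 0.65) the band; the three always sum to
100. An interval with no valid epochs yields `NA`, flagged rather than
zeroed.

Control is **accurate** when the BSP is statistically indistinguishable
from 0.8 with 95% confidence — per epoch, the 95% credible interval
contains 0.8 — and **reliable** when |BSP − 0.8| < 0.15 with 95%
confidence — per epoch, at least 95% posterior mass inside the band. The
per-patient binary label is a time aggregation the underlying definition
leaves open; the package requires the per-epoch criterion to hold on at
least half of the valid intent epochs (`control_frac`, configurable).

With $k$ of $n$ patients labeled, a uniform prior gives the group posterior
$\mathrm{Beta}(k+1, n-k+1)$, whose MAP is $k/n$; the 95% Bayesian
credibility interval is equal-tailed (central), a convention chosen because
nothing pins down HPD instead. Two groups are compared by the fraction of
100,000 Monte Carlo posterior draws in which one proportion exceeds the
other (standard error ≤ 0.0016). The uniform draws are assigned to the two
posteriors in a canonical order so that swapping the arguments reuses the
same pairs: the two directions sum to one exactly.

## Constant-dose variability

Constant-dose segments are windows in which no infusion rate of any drug
changes for at least 2 h; 30 min are trimmed at each end (and at record
boundaries), any bolus inside the raw window discards the segment
entirely — the strictest reading of "affected by boluses" — and segments
with median BSP below 0.05 are excluded. A 2 h raw window therefore yields
the 1 h minimum segment. Within each segment, ordinary least squares of BSP
on time (in days) captures drift; the four-way trend label is

* *increasing* / *decreasing* when |slope| > 2.4/day (0.1 BSP units per
  hour, the "10% in an hour" threshold),
* *constant* when |slope| ≤ 2.4/day and the BSP standard deviation ≤ 0.1,
* *varying* otherwise (small net slope, large scatter).

`slope_to_delta()` converts slopes to changes over an interval
(6.77/day → 0.141 per 30 min). Across subjects, segments whose per-drug
weight-normalized rates agree exactly after rounding to 0.1 mg/kg/hr form
dose-match groups (singletons dropped); within a group, every subject pair
is compared by the exceedance probability
$P(X < Y) + \tfrac12 P(X = Y)$ with the lower-median subject as reference.
This Mann–Whitney-type statistic is computed exactly at any sample size by
sorted-rank counting, so no pair subsampling is ever needed.

## The synthetic cohort

Because no clinical recordings ship with the package, validation rests on a
generator whose statistical structure matches what the analysis assumes:

* **PK/PD**: a one-effect-compartment model
  $\dot C_e = k_{in} R(t) - k_{out} C_e$ per drug (boluses add
  $\mathrm{dose}\cdot k_{in}$ instantaneously; drugs combine additively),
  integrated exactly over the piecewise-constant regimen, with a Hill link
  $\mathrm{BSP} = C_e^{\gamma}/(C_{50}^{\gamma}+C_e^{\gamma})$. Defaults:
  $k_{in}=1$, $k_{out}=\ln 2/0.25$ h⁻¹ (15 min effect-site half-life),
  $C_{50}=2.5$, $\gamma=4$. These are stand-ins, not calibrated estimates —
  the clinical study reports no patient-level PK/PD parameters.
* **Within-patient drift**: $\log C_{50}$ performs a seeded Gaussian random
  walk (default sd 0.05 per √hour), producing BSP drift at constant dose of
  the magnitude reported clinically (slopes up to several BSP units/day).
* **Between-patient spread**: $C_{50}$ and $k_{out}$ are log-normal across
  subjects (CV 0.3 each), so matched weight-normalized rates produce
  distinct BSPs.
* **State sequence**: an alternating renewal process; burst durations are
  exponential with mean 1.5 s (bursts typically last one to two seconds),
  suppression durations exponential with mean $\mu_b\, p/(1-p)$, both
  floored at 0.3 s. The floor biases occupancy toward
  $0.3/(0.3+\mu_b)$ at extreme $p$ (e.g. long-run fraction 0.949 at
  $p = 0.95$, 0.23 at $p = 0.2$); mid-range occupancy is essentially
  unbiased.
* **EEG**: per channel, independent 1–30 Hz Gaussian noise scaled to
  25 µV RMS in bursts and 2.5 µV in suppressions with a 100 ms cross-fade,
  plus optional 600 µV half-sine artifacts that exercise the >500 µV
  rejection. This emulates two-state amplitude modulation only — no
  spectral structure, spindles, or asymmetries — so a green segmentation
  test establishes correct recovery of amplitude-coded states, not
  performance on clinical artifact.
* **Regimens**: single-drug stepped infusions; the initial rate is uniform
  on 4–9 mg/kg/hr, chosen so that steady-state concentrations straddle
  $C_{50}$ under the PK defaults above (the half-maximal rate is
  $C_{50} k_{out}/k_{in} \approx 6.9$) — a cohort actually being titrated
  toward burst suppression, mostly undershooting the band, as observed
  clinically. Adjustments arrive with ~2 h mean spacing (the reported
  median inter-adjustment interval), multiplicative ±20–25%.

Everything is a pure function of `(config, seed)`.

```{r cohort-demo}
cfg <- cohort_config(n_subjects = 3, n_arse = 1, duration_h = 3,
                     fs = 64, n_channels = 2)
cohort <- make_cohort(cfg, seed = 1, eeg = FALSE)
res <- run_pipeline(cohort, pipeline_config(seed = 1))
res$summary[, c("subject_id", "group", "pt_a", "pt_i", "pt_b",
                "accurate", "reliable")]
```

## Known limitations

* The per-channel binarizer is an envelope-threshold stand-in for validated
  adaptive classifiers; its θ = 5 µV and τ = 0.2 s defaults are tuned to
  the two-amplitude synthetic world and are configuration, not clinical
  recommendations. Likewise the strict-majority voting fraction is a
  design choice.
* ICA-based artifact reduction used in clinical preprocessing is
  proprietary and is not reimplemented; only the amplitude rule is applied.
* The Gaussian/logit posterior is approximate; credible intervals near 0 or
  1 inherit the usual delta-method distortion.
* A band edge is a knife edge: when the true BSP sits exactly on 0.95, any
  consistent estimator splits its time between "within" and "above", so
  occupancy percentages at such operating points are intrinsically
  unstable (see the band-recovery test, where this is visible at the
  0.95 level).
* Duration floors make the renewal generator's occupancy slightly biased at
  extreme probabilities, as quantified above.
* The EDF support covers the continuous, equal-rate, 16-bit subset the
  package itself writes (0.1 µV quantization), not the full format.
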