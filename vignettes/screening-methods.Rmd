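---
title: "Methods: oximetry-based central sleep apnea screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: oximetry-based central sleep apnea screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apneascreen)
```

# The screening problem

Patients with stable heart failure have a high prevalence of
sleep-disordered breathing, much of it central sleep apnea (CSA) with
Cheyne-Stokes respiration: periodic crescendo–decrescendo breathing whose
apneic phases produce cyclic arterial desaturations. The reference
diagnosis comes from respiratory polygraphy: a scored list of apnea and
hypopnea events, each labelled central or obstructive. The candidate
screen is far simpler — overnight fingertip pulse oximetry and a count of
desaturation dips.

`apneascreen` implements the full comparison: the dip/ODI computation on
the screen side, the rule-based diagnosis on the reference side, and the
paired agreement statistics connecting them.

# The dip detector and ODI

A **dip** is a maximal run of consecutive *valid* samples with value
$\le b - \delta$, where $b$ is the baseline saturation and $\delta$ the
minimum drop (default 3 percentage points, absolute — not relative — per
standard oximetry practice), whose span (run length / $f_s$) is at least
the minimum duration (default 10 s). Both thresholds are inclusive: a
sample exactly at $b-3$ is in-dip and a run of exactly 10.0 s qualifies.
The **ODI** is the dip count divided by recording hours.

Numerical and boundary choices, all testable and tested:

* **Dip termination.** A dip ends as soon as saturation returns above
  $b-\delta$; there is no hysteresis or recovery-to-baseline requirement.
  This is the simplest rule consistent with the printed threshold
  definition; stricter variants can be emulated by raising `min_drop`.
* **Invalid samples.** Dropouts split runs — the detector never assumes a
  desaturation continued through missing signal. `bridge_gap_s` can bridge
  short gaps for sensitivity analyses (default 0).
* **ODI denominator.** Total recording span by default;
  `use_valid_time = TRUE` switches to valid time only. With heavy signal
  loss the default is conservative (biases ODI down); the choice is
  explicit because source conventions differ.
* **Degenerate inputs.** An all-invalid trace yields zero dips with a
  warning (not an error); summary statistics on a trace with no valid
  samples are an error.

Two **baseline conventions** are provided, mirroring the two devices'
workflows. `fixed` passes through a hookup-time measurement; in the
synthetic pipeline it is emulated as the rounded mean of the first minute
of the polygraph trace. `eleventh_minute` averages valid samples with
onsets in $[600, 660)$ s; a recording shorter than 11 minutes, or one with
the whole window dropped out, is an explicit error — in the cohort
pipeline such patients land in the exclusion log rather than receiving a
silently improvised baseline. The 11th minute is used because the first
minutes of self-applied recordings are frequently unsettled.

# Reference classification

From a scored event list and the sleep duration (an input — no sleep
staging is attempted): AHI = events/hour; **sleep apnea** iff AHI
$\ge 15$/h; **CSA** iff additionally the central fraction is $\ge 0.5$
(the boundary counts as central, following the usual "at least half"
phrasing), otherwise **OSA**. The three labels partition every input.
Events labelled anything other than central/obstructive (e.g. "mixed")
are rejected at read time: silently bucketing them would move patients
across the CSA/OSA boundary invisibly.

# Agreement statistics

Screen-vs-reference pairs become a 2×2 table with screen positivity
ODI $\ge$ 15/h (inclusive). The **McNemar test** uses only the discordant
cells $b, c$: the exact version doubles the binomial tail
$P(X \le \min(b,c))$, $X \sim \mathrm{Bin}(b+c, 1/2)$, capped at 1; the
continuity-corrected version refers $(|b-c|-1)^2/(b+c)$ to $\chi^2_1$.
Exact is the default at the discordant counts typical of small paired
studies ($b+c \approx 11$). With $b=c=0$ the p-value is defined as 1.
Sensitivity, specificity, PPV and NPV use the standard count ratios; a
zero denominator yields `NA` ("undefined"), never 0.

The **sample-size formula** for a paired design parameterised by
$\psi = p_{01}/p_{10}$ and $p_d = p_{01}+p_{10}$ is the conditional
normal approximation

$$n = \left\lceil \frac{\left[z_{1-\alpha/2}\sqrt{p_d} +
z_{1-\beta}\sqrt{p_d-(p_{01}-p_{10})^2}\right]^2}
{(p_{01}-p_{10})^2}\right\rceil .$$

At $\alpha=.05$, $1-\beta=.80$, $\psi=12$, $p_d=0.39$ it gives 26 pairs.
A caveat the test suite makes explicit: this formula is the power
function of the *asymptotic* (uncorrected) McNemar $\chi^2$ test, and
Monte-Carlo simulation at the returned $n$ confirms $\ge 80\%$ power for
that test. The *exact* binomial McNemar test is conservative because of
its discreteness and sits below nominal power at the same $n$; designs
intending to analyse with the exact test should inflate $n$ accordingly.

**Bland–Altman** agreement reports bias $=\overline{x-y}$ and limits
$\pm 1.96\,SD_{n-1}$; the exported plot data put the *first* measurement
on the abscissa (the variant used for first-vs-second-night ODI
reproducibility) rather than the pairwise mean. Medians and quartiles use
linear interpolation between order statistics (`quantile` type 7), fixed
as the package's reporting convention; reported percentages round
half-up to integers and p-values to two decimals.

# The synthetic cohort generator

The generator produces what the analysis *assumes* about overnight
saturation data, with ground truth attached, so every downstream stage
can be validated without patient data.

**What it emulates.** A stable integer baseline (default randomized over
94–97 %); desaturation events with a piecewise-linear descent (10–20 s) /
nadir plateau / recovery (10–20 s) shape — the simplest waveform that
controllably satisfies the depth-and-duration dip criterion, with the
plateau holding the full stated depth for the stated duration; a
central phenotype laying events out as a periodic train spaced
`cycle_length` s (default 60 s, range 45–90 s, Cheyne-Stokes periodicity)
with ±10 % jitter; an obstructive phenotype with exponential
inter-arrivals (clustered); integer quantization (oximeters report
integer percent); additive integer-rounded Gaussian sensor noise (default
SD 0.5 points); dropout artifacts (exponential lengths, mean 30 s);
values clipped to $[50, 100]$ with clipping flagged in the ground truth.
Paired 8 Hz polygraph and 1 Hz app traces are rendered from one shared
event plan per patient; the app trace carries the device noise and
dropouts, the polygraph trace is rendered clean.

**Key defaults.** Event rates 35/h for the apneic phenotypes (upper
quartile of heart-failure sleep-cohort AHI ranges, well separated from
the 15/h cutoff) and 4/h for the non-apneic phenotype (safely below it in
expectation and, given Poisson sampling, in practice); mean depths 6/5/4
points (central/obstructive/none) with SD 1, floor 3; mean plateau 20 s
with SD 3, floor 10; nights 6–8.5 h. The first ~11.5 minutes are kept
event-free so both baseline conventions see undisturbed signal.
Mechanism labels are assigned as deterministic counts (90 % central for
the central phenotype, 25 % for obstructive), so the $\ge 50\%$-central
rule holds on every draw, not merely in expectation. Ground-truth
diagnosis is computed by running the event list through the same
classification rules as the analysis arm; the ground-truth ODI is the
dip count of the clean 8 Hz rendering.

**What it does not emulate — and what passing tests therefore do not
show.** No cardiorespiratory physiology (loop gain, chemoreflex), no
motion artifacts correlated with arousals, no wake periods (recording
span = sleep span, so the known app-vs-polygraph total-sleep-time
discrepancy is not modelled), no oximeter firmware averaging, no
hypopneas without desaturation. Tests passing on this generator show the
*pipeline's* correctness — detection, classification, statistics — under
the stated signal model; they do not certify screening performance on
real patients, where the published agreement was weak precisely because
real signals violate these idealisations.

# The packaged study fixture

The replicated study published only four marginal 2×2 tables over 22
analyzable patients (7 CSA, 6 OSA, 9 none) plus diagnosis counts over the
24-patient polygraph cohort. The shipped per-patient table
(`study_patients_synthetic.csv`) is a *reconstruction*: one assignment of
per-patient diagnosis and mobile/polygraph screen calls simultaneously
consistent with all four tables (the test suite proves cell-for-cell
agreement). The ODI magnitudes in it are synthetic; only their side of
the 15/h cutoff is determined by the published tables. Checksums guard
the fixtures at load time. A documented inconsistency in the source
tables — reported polygraph specificity 53 % where the corresponding
table implies 9/15 = 60 % — is resolved in favour of the table; the
package reports what its own 2×2 computation yields.

# Problem sizes and runtimes

The test suite validates the dip detector against a brute-force scan on
1000 random traces (60–400 samples, 1 and 8 Hz), the exact McNemar test
against full combinatorial enumeration for every discordant total up to
20, the sample-size formula against 10,000-replicate Monte-Carlo power,
planted-event recovery on zero-noise nights at both rates, and prevalence
recovery pooled over six independent 22-patient cohorts; the whole suite
runs in about a minute on one CPU. These sizes were chosen to make
binomial/Poisson sampling error small relative to the tested margins.

# Known limitations

* The generator's phenotypes are strongly separated by construction;
  synthetic screening accuracy is near-ceiling and should be read as a
  pipeline check, not an effect-size estimate.
* The exact McNemar p-value is conservative at small discordant counts
  (see the sample-size caveat above).
* Only binary central/obstructive mechanisms are supported; mixed-event
  scoring schemes require a pre-processing decision.
* The fixed polygraph baseline is taken literally as a single hookup
  value; vendor software with moving baselines will produce different
  dip counts on real exports.
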