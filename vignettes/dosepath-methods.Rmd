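---
title: "Methods: imaging-dose accounting and NTCP modelling with dosepath"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: imaging-dose accounting and NTCP modelling with dosepath}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dosepath)
```

## The problem

A child treated with craniospinal irradiation (the standard of care for
medulloblastoma) is exposed to ionizing radiation at three stages: the
planning CT scan, a cone-beam CT (CBCT) before treatment sessions for
position verification, and the therapeutic beams themselves. The
therapeutic prescription here is 36 Gy to the craniospinal axis in 20
fractions plus an 18 Gy boost in 10 fractions. Individually the imaging
doses are a few mGy per organ — three orders of magnitude below therapy —
but they recur, they land partly outside the treatment field, and
pediatric tissues are both more radiosensitive and have decades in which
late effects can manifest. `dosepath` quantifies this pathway end to end:
it calibrates OSL dosimeter counts to absorbed dose, accumulates per-organ
imaging dose across the workflow, expresses it against the prescription,
and converts treatment-plan dose distributions into organ-level risk via
equivalent uniform dose (EUD) and normal tissue complication probability
(NTCP).

## Dose-volume histograms

A DVH is stored as strictly increasing bin doses (internally always Gy)
with one volume fraction per bin, in one of two forms:

* **differential** — fraction of organ volume in each dose bin; fractions
  sum to 1 (tolerance 1e-9). Bin doses are bin centers.
* **cumulative** — fraction of volume receiving *at least* each bin dose;
  non-increasing, starting at 1.

Conversion between forms is an exact cumulative-sum / first-difference
pair on the shared bin doses, so a round trip is lossless. Volume
fractions are relative, never cm^3^: the EUD formula requires relative
volumes and Vx metrics are reported as percent volume. Vx is *inclusive*
at the threshold (volume receiving >= x), so a threshold equal to a bin
dose counts that bin; Dmax is the highest bin dose carrying nonzero
volume and Dmean the volume-weighted mean.

All I/O declares units explicitly (`dose_value`, `dose_convert`), because
the three workflow stages naturally live on three scales: organ imaging
doses in mGy, calibration doses in cGy, plan doses in Gy. Conversions are
exact powers of ten applied on ingest; the canonical internal unit is Gy.

## EUD and NTCP

The equivalent uniform dose follows Niemierko's generalized-mean
formalism over the differential DVH,

$$EUD = \left(\sum_i v_i D_i^{\,a}\right)^{1/a},$$

where $a$ is a tissue-specific volume-effect exponent: $a = 1$ recovers
the mean dose (parallel organs), large positive $a$ approaches the
maximum dose (serial organs), and negative $a$ emphasizes cold spots.
Implementation detail: the dominating dose is factored out of the power
sum, so the computation cannot overflow even for $|a|$ in the hundreds;
with negative $a$ a zero-dose bin carrying volume is rejected because the
generalized mean diverges there.

Complication probability uses the sigmoidal dose-response

$$NTCP = \frac{1}{1 + (D_{50}/EUD)^{4\gamma_{50}}},$$

with $D_{50}$ the dose giving 50% complication probability and
$\gamma_{50}$ the normalized slope at that point. The curve passes
through 0.5 exactly at $EUD = D_{50}$ and is strictly increasing in EUD.
On the logit scale the model is linear in log dose,

$$\ln\frac{1-N}{N} = 4\gamma_{50}\,(\ln D_{50} - \ln EUD),$$

which `fit_ntcp_params()` exploits: two (EUD, NTCP) pairs give the
closed-form two-equation solution, more pairs an ordinary least-squares
fit. Back-substitution through `compute_ntcp()` reproduces two input
pairs exactly, which makes the inversion a self-consistency check for
published (EUD, NTCP) pairs whose underlying parameters were not
reported.

### Parameter provenance

The shipped parameter file (`default_ntcp_params_path()`) contains two
kinds of entries, distinguished by their `source` tag. The heart and
thyroid sets are *fitted*: two-point inversions of reported pairs —
heart (16 Gy, 30%) and (6.6 Gy, 0.4%) giving $D_{50} = 18.79$ Gy,
$\gamma_{50} = 1.318$; thyroid (27.1 Gy, 12%) and (8.7 Gy, <1%). A
reported bound "<1%" is not a number, so the fit takes 0.5%; the choice
only affects the fitted slope, not the reproduction of the 12% point,
and any value below 1% leaves the back-substituted low-dose NTCP below
1%. All other entries are labelled `illustrative` and exist so the
pipeline runs out of the box; they are placeholders meant to be replaced
with institution-specific values, not literature claims.

The fitted heart $D_{50}$ of 18.8 Gy is far below classical
whole-organ cardiac tolerance values — a reminder that two-point
inversions inherit whatever endpoint, volume effect, and rounding the
source pairs carried. They are reproduction aids, not clinical
parameters.

### Fractionation

No fractionation correction is applied by default: the EUD/NTCP chain
operates on physical DVH doses. `eqd2_transform()` is available as an
opt-in preprocessing step (linear-quadratic EQD2 with a user-supplied
$\alpha/\beta$); it is off by default so that the default computation
remains the plain physical-dose formalism, and 2 Gy per fraction is its
fixed point.

## OSL calibration

The nanoDot OSL dosimeter reports stimulated-luminescence counts; a
modality-specific calibration (planning CT, CBCT, megavoltage RT differ
in beam quality) converts counts to dose. The calibration factor is the
*mean of per-point dose/count ratios* across the calibration exposures —
matching how such factors are computed from dose/count tables — with a
least-squares slope through the origin available for comparison
(`method = "slope"`). The factor's relative uncertainty is the spread of
the per-point ratios. Count-to-dose conversion is

$$D\,[\mathrm{cGy}] = (\text{raw} - \text{background}) \cdot k \cdot
  k_{beam} \cdot k_{lin} \cdot k_{ang} \cdot k_{fad},$$

linear in net counts and in each correction factor; all corrections
default to 1. One published CBCT factor is stated as
$4.77 \times 10^{5}$ cGy/count alongside its own inverse of 20957.66
counts/cGy; the two are reciprocal only if the exponent is $-5$, so the
package treats the factor as $4.77 \times 10^{-5}$ cGy/count (physically
plausible and internally consistent) and enforces
`factor * inverse == 1` as a class invariant.

Replicate statistics use the sample (n−1) standard deviation — replicate
sets are small, so the metrology convention matters — and a single
reading has sd 0 by definition. Bleaching verification (`zero_check()`)
is inclusive at its threshold; the default threshold is the reader's 0.7
mGy sensitivity converted through the active calibration curve.

### Uncertainty propagation

Two combination rules are provided because the appropriate one for
multi-stage dosimetry is genuinely open. `quadrature` is the standard
root-sum-of-squares of relative standard deviations. `monte_carlo`
perturbs each multiplicative factor independently as $N(1, s_k)$, forms
the product over $10^5$ seeded draws (default seed recorded in the
budget), and reports the empirical relative sd of the product — this
captures the small lognormal-like skew of a product of factors that
quadrature ignores. For component sds at or below 0.1 the two agree
within a few percent, and the combined value always dominates every
individual component.

## Workflow accounting

`cumulative_imaging_dose()` implements the ledger arithmetic: total =
CT + n x CBCT per organ, exactly, with per-acquisition CBCT
uncertainties combined in quadrature scaled by $\sqrt{n}$ — repeated
acquisitions are treated as independent measurements, not a systematic
shift. The packaged table `phantom_organ_doses()` holds the measured
per-organ doses for one planning CT and one CBCT acquisition in a
5-year-old anthropomorphic phantom (20 organs, mGy, one-sigma
uncertainties). With the default 15 CBCT acquisitions and the 36 Gy
prescription this reproduces the headline accounting: CBCT-only totals
from 48 mGy (vertebrae) to 95 mGy (abdominal cavity), and a maximum
imaging total below 0.3% of the prescription for every organ.

Percentages are computed against the 36 Gy craniospinal prescription by
default, with the 54 Gy prescription-plus-boost as a second column —
both references are in clinical use and the package never silently picks
one. Full precision is kept internally; `format_exposure_report()`
applies the report conventions (mGy to the nearest integer, percents to
two decimals) only at display time. Organs present in the dose table but
absent from a treatment plan yield `NA` cells, never zeros — a missing
plan dose is not a zero dose.

## Synthetic data

The generators exist so every stage is testable without scanner access,
and their defaults are the study conditions, not tuning knobs:

* **Counts** (`generate_osl_counts`): truncated Gaussian with sd =
  cv x mean. The noise is deliberately *not* Poisson: observed replicate
  CVs of 2–8% at ~1e8 counts are orders of magnitude above counting
  statistics, so the dominant variation is per-dosimeter systematic
  (sensitivity, positioning), which a relative-sd Gaussian represents.
  The default pipeline CV of 0.05 sits mid-band.
* **Organ dose tables** (`generate_organ_dose_table`): organ means drawn
  uniformly in the measured envelopes (CT 3.7–7.8 mGy, CBCT 3.2–6.3 mGy
  per acquisition) with a relative uncertainty of 0.16, the ratio of
  quoted uncertainties to means in the measured table.
* **DVHs** (`generate_dvh`): the cumulative form is a logistic fall-off
  in dose — two interpretable knobs (center, steepness) span
  near-uniform "step" DVHs and long-tailed ones. The differential
  weights are truncated-logistic densities evaluated on the log scale
  (stable for any center), and the center is solved numerically so the
  generated Dmean matches the request (well within the documented 2%).
  Requests below the shallow-tail floor (~1/steepness Gy) or above its
  mirror near Dmax are rejected as infeasible rather than silently
  missed. Steepness -> infinity approaches a uniform dose at the
  requested mean.

What the generator does *not* emulate: anatomical correlation between
organs, scanner geometry (the reason thyroid CT dose exceeds its CBCT
dose in the measured table), multi-modal DVHs from field junctions, and
detector energy response. Passing tests on synthetic data therefore
demonstrate the correctness of the arithmetic chain, not the realism of
any particular dose distribution.

## Pipeline and reproducibility

`run_pipeline()` chains calibration, accounting, EUD/NTCP and
technique comparison, writing CSV/JSON outputs plus a manifest (package
version, seed, every generator parameter, NTCP parameter provenance,
file list). A run is a pure function of its config: the same seed gives
byte-identical CSVs, and the manifest alone suffices to reconstruct the
config and reproduce the run. Stage failures remove partial outputs and
re-throw with a stage tag. Default problem sizes — 4 organs, 3
techniques, 120-bin DVHs, 5 calibration replicates per dose level —
keep a full run around a second while exercising every code path;
nothing in the method depends on these sizes.

## Known limitations

* The sigmoid NTCP model is the only dose-response implemented (no
  Lyman-Kutcher-Burman probit, relative seriality, or Poisson TCP).
* DVH input is the documented CSV dialect only; DICOM-RT exports must be
  converted upstream.
* Two-point NTCP inversion is exactly determined, hence has no goodness
  measure; with more pairs the logit least-squares fit weights all pairs
  equally, which over-weights extreme probabilities if their absolute
  uncertainty is constant.
* The volume-effect exponent $a$ cannot be inferred from (EUD, NTCP)
  pairs; it must come from the parameter file.
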