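# dosepath

Organ dose accounting and NTCP risk modelling across the radiotherapy
imaging pathway.

## What it is for

In pediatric craniospinal radiotherapy (the standard treatment for
medulloblastoma) a patient is irradiated at three stages: the planning CT
scan, repeated cone-beam CT (CBCT) acquisitions for position verification
before treatment sessions, and the therapeutic beams. The imaging doses
are small — a few mGy per organ per acquisition — but they recur over
15+ sessions, and pediatric tissues combine high radiosensitivity with
decades of remaining life expectancy. `dosepath` is for medical
physicists and researchers who need to quantify that whole pathway:

* **OSL calibration** — convert optically stimulated luminescence
  dosimeter counts to absorbed dose, per modality (planning CT, CBCT,
  RT), with multiplicative correction factors, replicate statistics and
  uncertainty propagation (quadrature or seeded Monte-Carlo).
* **Cumulative imaging-dose accounting** — per-organ ledger of planning
  CT + n × CBCT dose, with quadrature uncertainties and
  percent-of-prescription reporting.
* **DVH radiobiology** — dose-volume histogram metrics (Dmax, Dmean,
  Vx), the Niemierko equivalent uniform dose

  EUD = (Σᵢ vᵢ Dᵢᵃ)^(1/a),

  and the sigmoidal normal tissue complication probability

  NTCP = 1 / (1 + (D₅₀/EUD)^(4γ₅₀)),

  including closed-form two-point inversion of (EUD, NTCP) pairs back to
  (D₅₀, γ₅₀).
* **Technique comparison** — organ × technique EUD and NTCP matrices
  (e.g. 3D-CRT prone/supine vs VMAT) with deltas against a reference
  technique.
* **Synthetic data** — seeded generators for noisy OSL counts, organ
  dose tables and parametric logistic DVHs, so the full pipeline runs
  and is testable without scanner access.

## Worked example

The packaged table `phantom_organ_doses()` holds measured per-organ
absorbed doses (mGy) for one planning-CT scan and one CBCT acquisition in
a 5-year-old anthropomorphic phantom. Accumulate it over 15 CBCT
acquisitions against a 36 Gy + 18 Gy boost prescription:

```r
library(dosepath)

tab    <- phantom_organ_doses()
report <- build_exposure_report(tab, prescription(), n_cbct = 15)
format_exposure_report(report)[report$organ %in%
  c("brain", "thyroid", "heart"),
  c("organ", "cbct_total_mgy", "imaging_total_mgy",
    "pct_of_prescription", "pct_of_total_with_boost")]
#>    organ cbct_total_mgy imaging_total_mgy pct_of_prescription pct_of_total_with_boost
#>    brain             86                91                0.25                    0.17
#>  thyroid             54                62                0.17                    0.11
#>    heart             66                72                0.20                    0.13
attr(report, "summary")$max_pct_of_prescription
#> [1] 0.2814167
```

The brain accumulates 86 mGy from CBCT alone (91 mGy with the planning
CT); the worst-case organ stays below 0.3% of the prescribed 36 Gy.

NTCP parameters can be recovered from published (EUD, NTCP) pairs and
used to compare techniques:

```r
heart <- fit_ntcp_params(c(16, 6.6), c(0.30, 0.004), organ = "heart")
heart
#> NTCP params heart: a=1, D50=18.79 Gy, gamma50=1.318 [] (fitted)

long <- data.frame(organ = "heart",
                   technique = c("3dcrt_pp", "vmat"),
                   eud_gy = c(16, 6.6))
compare_techniques(long, list(heart = heart), reference = "3dcrt_pp")
#> EUD (Gy) by organ and technique:
#>       3dcrt_pp vmat
#> heart       16  6.6
#> NTCP (%) by organ and technique:
#>       3dcrt_pp vmat
#> heart       30  0.4
#> Reference technique: 3dcrt_pp
```

Switching the heart from a 16 Gy mean-dose conformal plan to a 6.6 Gy
VMAT plan drops the modelled complication probability from 30% to 0.4%.

The full chain — simulated calibration, dose accounting, EUD/NTCP,
comparison matrices, run manifest — is one call:

```r
out <- run_pipeline(study_config(seed = 1), output_dir = "run1")
```

A thin command-line wrapper over the same functions ships at
`inst/scripts/dosepath.R` (subcommands `calibrate`, `convert-counts`,
`zero-check`, `uncertainty`, `imaging-dose`, `eud`, `ntcp`, `fit-ntcp`,
`dvh-metrics`, `simulate`, `run`).

See `vignettes/dosepath-methods.Rmd` for the model assumptions,
parameter provenance and numerical conventions.

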