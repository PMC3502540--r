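# acthfcs

Quantification of the stress hormone ACTH from **fluorescence correlation
spectroscopy (FCS) immunoassay** data, and **mechanistic ODE modelling** of
how cortisol feeds back on ACTH secretion in anterior pituitary cells —
for endocrinologists and systems biologists who want absolute nanomolar
peptide concentrations out of single-molecule fluctuation data and a tested
modelling pipeline on top of them.

## What it computes

**Assay side.** A sandwich immunoassay makes the 4.5-kDa ACTH peptide
visible to FCS: a DyLight-labeled anti-ACTH IgG (N-terminal epitope) plus an
unlabeled capture IgG (C-terminal) form an immunocomplex that diffuses
through the confocal volume about twice as slowly (dwell time τ_D2 ≈ 483 µs)
as the free labeled antibody (τ_D1 ≈ 220 µs). The measured autocorrelation
is fitted with the two-component Gaussian-volume model

    G(τ) = 1 + (1/N') [ (1−Y) g1(τ) + Y g2(τ) ],
    g(τ) = (1 + τ/τ_D)^−1 (1 + τ/(s² τ_D))^−1/2,   τ_D = r²/(4D),

with τ_D1 held fixed and the structural parameter s = 5. The bound mole
fraction Y and total particle number N' give absolute concentrations via
the calibrated effective volume: c = N / (6.023·10²³ · 5·10⁻¹⁶ l), i.e.
one particle ≈ 3.32 nM. Series statistics are Student-t half-widths
(α = 0.1). A Brownian-dynamics photon-trace simulator with a multiple-tau
correlator serves as a brute-force oracle for the closed-form models.

**Modelling side.** Two ODE models of glucocorticoid negative feedback are
fitted to packaged percent-change time courses (basal, +10 nM CRH,
+10 nM CRH + 100 nM cortisol) by Tikhonov-regularized weighted least squares
with a genetic search plus local refinement:

* a *parsimonious* model — ACTH production repressed by the intracellular
  cortisol·GR transcription factor only (slow genomic feedback), and
* an *extended* three-compartment model adding membrane CRH and
  glucocorticoid receptors, a releasable ACTH pool and nuclear GR-dimer
  repression — hence both the fast non-genomic and the slow genomic arm.

`compare_models()` reproduces the headline structural result: the
parsimonious model fits either experimental arm alone but no single
parameter set fits both, while the extended model fits all three arms
jointly.

## Worked example

```r
library(acthfcs)

## synthetic 50 x 10 s immunoassay series at a true 15 nM ACTH
proto  <- assay_protocol()                       # 60 nM + 60 nM antibodies
curves <- generate_assay_series(15e-9, proto, seed = 1)
fit_assay_series(curves, tau_d1_fixed_s = 220e-6)
#> FCS immunoassay series (n = 50 runs)
#>   c_ACTH = 15.067 +/- 0.382 nM
#>   tau_D2 = 485.7 +/- 8.2 us
#>   Y      = 0.251 +/- 0.006
```

The series recovers the true concentration (15 nM) within a sub-nanomolar
Student-t half-width, the immunocomplex dwell time (483 µs generating
value) within its own interval, and the bound mole fraction 0.25 implied by
complete capture of 15 nM ACTH in 60 nM labeled antibody.

```r
## which feedback topology explains all three experimental arms at once?
datasets <- table2_fit_datasets()
cmp <- compare_models(datasets, population = 200, generations = 100,
                      alpha = 1e-3, seeds = 1:3)
subset(cmp$verdicts, combo == "joint")
#>         model combo seed objective frac_within    ok
#>  parsimonious joint    1    20.417       0.562 FALSE
#>  parsimonious joint    2    20.419       0.562 FALSE
#>  parsimonious joint    3    20.385       0.625 FALSE
#>      extended joint    1     7.713       0.875  TRUE
#>      extended joint    2     0.403       1.000  TRUE
#>      extended joint    3     0.416       1.000  TRUE
```

`frac_within` is the fraction of time points reproduced within their
tabulated deviations (the verdict threshold is 0.8): the parsimonious model
cannot reconcile the creeping basal arm with the still-climbing CRH arm,
the extended model reproduces every arm, including the early cortisol
suppression (fast feedback) and the 22-h endpoints.

## Layout

| path | content |
|---|---|
| `R/fcs-core.R` | closed-form G(τ) models, calibration, unit conversion |
| `R/fcs-fitting.R` | one-/two-component fits, assay extraction, series statistics |
| `R/fcs-synth.R` | protocol generator, Brownian oracle, multiple-tau correlator |
| `R/hpa-models.R` | the two ODE models, scenarios, steady states, simulation |
| `R/hpa-fitting.R` | Tikhonov objective, genetic search, model comparison |
| `R/data-io.R`, `inst/extdata/` | packaged dose-response and time-course tables |
| `R/cli.R`, `inst/cli/acthfcs` | command-line dispatcher over the above |
| `vignettes/` | methods vignette: models, assumptions, limitations |
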