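# cmrpet

Quantitative analysis of simultaneous PET/CMR imaging after revascularized
acute myocardial infarction (AMI), for imaging scientists who want the full
numeric chain from raw maps to cohort statistics in one tested, scriptable
package:

- **MOLLI T1 mapping** — pixelwise fitting of magnitude inversion-recovery
  series, `S(TI) = |A − B·e^(−TI/T1*)|`, with exhaustive polarity
  restoration and the Look-Locker correction `T1 = T1*·(B/A − 1)`.
- **ECV mapping** — extracellular volume fraction from registered native /
  post-contrast T1 and individually measured hematocrit,
  `ECV = (1 − Hct)·ΔR1_myo / ΔR1_blood`, `R1 = 1/T1`.
- **PET quantification** — standardized uptake values normalized to lean
  body mass (`SUV = activity / (decay-corrected dose / LBM)`, James
  formula) and blood-normalized tissue-to-background ratios (TBR).
- **Sector segmentation** — the LV annulus between endo-/epicardial
  contours split into 32 (16 apical) equal transmural sectors along a
  centerline; per-sector means with artifact exclusion propagated across
  the co-registered signals.
- **"Imaging biopsy" statistics** — per patient and signal: the maximum
  (mean of the two highest sector values), a remote reference (the three
  sectors most distal on the ring from the highest sector), and
  cross-modality argmax distances.
- **Correlation layer** — between-subject correlation of per-subject
  means; within-subject correlation as the repeated-measures / ANCOVA
  statistic (pooled Pearson r of patient-mean-centered pairs,
  `df = N − k − 1`); per-patient regression slopes; image-maximum versus
  blood-marker / infarct-size correlations with pairwise deletion.

Because the patient data behind such studies is not public, the package
ships a first-class **synthetic cohort generator**: seeded phantom patients
(LV annulus, raised-cosine infarct wedge, co-localized native T1 / ECV /
FDG elevations, MOLLI 3(3)3(3)6 magnitude series, cavity blood pool,
lognormal blood-marker peaks driven by latent infarct-extent and
inflammation variables) with analytically controlled couplings, so every
stage — and the statistical dichotomy between within- and between-subject
correlation — is testable end to end.

## Worked example

```r
library(cmrpet)

co  <- make_cohort(8, cohort_params(), seed = 42)   # 8 phantom patients
res <- analyze_cohort(co)
res
#> <cohort_result> 8 patients, 224 analyzed sectors per signal
#>   ecv/fdg              within R = 0.97, between R = -0.75
#>   native_t1/fdg        within R = 0.94, between R = -0.02
#>   ecv/native_t1        within R = 0.92, between R = 0.04

subset(res$marker_correlations,
       image == "max_ecv" & marker %in% c("ck_mb", "infarct_size_pct_lv"))
#>    image              marker n         r           p
#>  max_ecv               ck_mb 8 0.8807693 0.003867557
#>  max_ecv infarct_size_pct_lv 8 0.7747048 0.023975774
```

The printout shows the core phenomenon the analysis isolates: sector
profiles of the three signals are almost perfectly co-localized *within*
each slice (within-subject R ≳ 0.9) while the absolute per-patient maxima
are essentially unrelated *between* patients — and the ECV maximum, an
"imaging biopsy" of peak tissue damage, correlates with peak CK-MB and with
infarct size.

A single pixel fit:

```r
ti <- sort(molli_ti(molli_scheme(), heart_rate = 62))
fit_t1_pixel(ti, molli_signal(ti, 1163))
#> <t1_fit> T1 = 1163.00 ms (T1* = 1163.00, B/A = 2.000, 3 flips, rms 0)
```

The full pipeline (simulate → fit T1 from MOLLI → ECV → SUV → sectors →
biopsy → correlations, with NIfTI/CSV/JSON outputs and a provenance
record):

```r
run_pipeline(run_config(mode = "synthetic", n_patients = 25, seed = 1,
                        out_dir = "out"))
```

A thin CLI wrapper lives at `inst/cli/cmrpet.R`
(`cmrpet.R simulate|run --config run.yaml`).

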