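# bolusqc

Quality assessment of contrast-medium boluses delivered by MRI power
injectors, from photometric time-contrast (TC) recordings.

## The problem

Dynamic and time-critical contrast-enhanced MRI assumes that a power
injector programmed for volume *V* at flow rate *Q* delivers a clean,
reproducible bolus: ideally a **boxcar** — steep wash-in, a flat plateau of
width *V/Q* seconds, steep wash-out. In reality the pump mechanism
(piston-syringe vs peristaltic roller pump) and the filling volume of the
attached tube line reshape the bolus before it ever reaches the patient.
Measuring a dye-stained bolus photometrically at the line outlet yields a
TC-curve whose departure from the ideal can be quantified.

`bolusqc` is for medical physicists and radiology technologists who want to
compare injector systems (or line configurations) on such recordings. It
implements two quality criteria:

* **cBCF** — the Pearson correlation *R*<sub>P</sub> between a TC-curve and
  the boxcar function least-squares-fitted to it (higher is better). The
  fit places both discontinuities on the sample grid and finds the global
  optimum by an exhaustive O(n²) changepoint scan with closed-form levels.
* **dBIT** — effective minus expected injection time, in seconds, where the
  effective time is the width of the fitted plateau and the expected time
  is *V/Q* (smaller magnitude is better).

plus the comparative statistics built on them: Kruskal–Wallis tests,
Dunnett-modified Tukey–Kramer pairwise comparisons (unpooled variances,
Welch per-pair df, Bonferroni-corrected studentized-range quantile),
Type II ANCOVA of the technical covariates, a contrast-medium compliance
odds-ratio test, and rank-ordered median-and-range summaries.

Because bench recordings of this kind are not publicly available, the
package ships a physically-motivated synthetic injector simulator
(tanks-in-series tube-line dilution, pump-specific flow profiles,
Beer–Lambert photometric readout with sensor noise) that generates
reproducible studies with the structure the analysis assumes.

## Worked example

Simulate one 15 ml @ 5 ml/s Gadoterate injection on a piston-syringe and on
a roller-pump injector from the bundled five-injector design, and score
them:

```r
library(bolusqc)

design <- default_study_design()
cfg    <- simulation_config(seed = 1L)
prot   <- design$protocols[["vVol_15_Gadoterate"]]

rec_ps <- simulate_recording(design$injectors[["MedAcc"]], prot, cfg)
rec_rp <- simulate_recording(design$injectors[["UMiss"]],  prot, cfg)

score_recording(rec_ps, prot)
#> <quality_result> MedAcc_vVol_15_Gadoterate_d1: cBCF 0.998, dBIT 0.033 s (expected 3 s), valid TRUE
score_recording(rec_rp, prot)
#> <quality_result> UMiss_vVol_15_Gadoterate_d1: cBCF 0.9217, dBIT 5.443 s (expected 3 s), valid TRUE
```

The piston-syringe bolus is near-ideal (cBCF 0.998; plateau within 0.03 s
of the programmed 3 s). The roller-pump bolus, diluted along its 95 ml
line, correlates visibly worse with its boxcar and overshoots the
programmed time by more than 5 s.

Scoring the full default study (5 injectors × 14 protocols × 2 days) and
ranking injectors on cBCF over all protocols:

```r
recs <- generate_study(design, cfg)
q    <- score_study(recs, design)
rank_summary(q, "cbcf", "all")
#>   rank injector_id pump_type  n median   min   max
#> 1    1      MedSol        PS 28  0.995 0.973 0.998
#> 2    2      CovOpt        PS 28  0.992 0.956 0.996
#> 3    3      MedAcc        PS 28  0.992 0.968 0.998
#> 4    4       UMax3        RP 28  0.927 0.894 0.937
#> 5    5       UMiss        RP 28  0.915 0.857 0.925
```

Every piston-syringe model outranks every roller-pump model — the
simulator's line-volume and pump-mechanism effects expressed through the
analysis. `kruskal_wallis()`, `dtk_pairwise()`, `ancova()` and
`compliance_odds_ratio()` take it from there; `run_pipeline()` writes the
whole bundle (per-recording CSV, rank tables, test results, manifest, and
optional per-recording figures) in one call, and
`inst/scripts/bolusqc-pipeline.R` wraps it for the shell.

Real recordings are read with `read_recording()` (two-column `time_s,signal`
CSV) against a study design described in YAML (`read_study_design()`; see
`?read_study_design` for the schema).

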