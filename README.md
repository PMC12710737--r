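# semcine

Semantic encoding of naturalistic movie fMRI with interpretable features.

## What this is for

Naturalistic movie-watching fMRI produces rich, continuous brain responses
that are hard to link to movie content in an interpretable way. `semcine`
implements one complete, testable pipeline for doing so with a small set of
prompt-defined semantic features (the kind a multimodal language model can
score per clip), aimed at researchers who have parcel-averaged BOLD time
series and want per-region *semantic explainability* maps plus
individual-difference analyses:

1. **Segmentation** — run timing tables (movie/rest intervals) become a
   manifest of overlapping clips: 20-s targets, 16-s minimum, 10-s step,
   5-s end-of-segment buffer.
2. **Clip responses** — per run: z-score each parcel on non-rest TRs,
   remove the frame-wise global mean, average over each clip's 5-s-lagged
   window; subjects are aggregated with a 5%-per-tail trimmed mean.
3. **Encoding** — per parcel, ridge regression (λ = 1, standardized scale)
   with leave-one-clip-out cross-validation predicts clip responses from
   the 11 features; the pooled held-out R² (which may be negative) is the
   explainability map, with mean-|β| and R²-weighted feature importance.
4. **Connectivity** — resting-state FC (Fisher-z Pearson), nodewise
   strength = mean positively-clipped z per parcel.
5. **PLS** — cross-covariance SVD between subject-wise R² profiles and
   strength profiles, permutation p-values for the singular values,
   bootstrap-ratio stability maps for the loadings.
6. **Cognition** — cross-subject Spearman maps against 7 age-adjusted
   cognitive scores, pooled Benjamini–Hochberg FDR at q = 0.05.

A synthetic-data generator plants a known ground truth (sparse encoding
weights, subject gain/trait factors, a rank-one connectivity axis, linked
cognition scores) so every stage is verified by parameter recovery — the
original study's data are restricted-access, so the test suite never needs
them. See `vignettes/semcine-methods.Rmd` for the model details and the
design decisions.

## Worked example

```r
library(semcine)

truth <- ground_truth(n_parcels = 60, n_subjects = 12, seed = 3)
cfg   <- pipeline_config(n_parcels = 60, rng_seed = 3,
                         n_permutations = 200L, n_bootstrap = 200L)
study <- simulate_study(truth, cfg, n_runs = 2, segments_per_run = 3,
                        n_TR_rest = 300, seed = 3)
res   <- run_pipeline(study, cfg)

nrow(res$manifest)
#> [1] 24
round(mean(res$group_encoding$r2[truth$active_parcels]), 3)
#> [1] 0.982
round(mean(res$group_encoding$r2[-truth$active_parcels]), 3)
#> [1] -0.178
names(which.max(res$importance$weighted_abs_beta))
#> [1] "dialogue"
```

24 clips come from six 60-s segments (four 20-s clips each). Active
parcels — those with non-zero planted weights — are explained almost
perfectly at this noise level, while inactive parcels are *negative*:
with 24 clips and 11 features a cross-validated null model overfits, and
R² = 1 − SS_res/SS_tot is designed to show that. The planted
dominant feature (`dialogue`, 2.5× weight scale) tops the R²-weighted
importance ranking. At this small n (12 subjects) the PLS permutation p
is typically not significant; the planted subject-level axis needs ~100
subjects (see the acceptance tests).

## Command line

```sh
Rscript inst/cli/semcine.R simulate --seed 7 --out-dir sim/
Rscript inst/cli/semcine.R segment --timing sim/timing.csv --out manifest.csv
Rscript inst/cli/semcine.R run-all --seed 7 --out-dir results/
```

Subcommands: `simulate`, `segment`, `extract`, `encode`, `fc`, `pls`,
`cognition`, `run-all`; global flags `--config cfg.yaml`, `--seed`,
`--out-dir`, `--verbose`. Two `run-all` invocations with the same seed
produce bitwise-identical outputs.

## Data formats

- timing CSV: `run_id, start_s, end_s, label` (`movie`/`rest`), half-open
  intervals in seconds;
- feature CSV: `clip_id` + 11 schema columns in `[0, 1]`;
- parcel matrices: TSV, parcels × TRs, `#` header lines with
  `subject_id`, `run_id`, `tr_seconds`;
- cognition CSV: `subject_id` + `PMAT24, PicSeq, ListSort, CardSort,
  Flanker, CogFluidComp, CogCrystalComp`.

No neuroimaging formats are read; export parcel matrices with your
surface/volume toolchain of choice.
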