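# reinstatr

Multivoxel reinstatement and gist indices, with PLSC brain–behavior
analysis, for memory-consolidation studies.

## The problem

In system-level memory-consolidation experiments, participants learn
object–location associations embedded in scenes and retrieve them in the
scanner after different delays (immediately, after one night, after two
weeks). Two complementary multivoxel questions arise from the trial-wise
beta patterns of the retrieval runs:

1. **Scene-specific reinstatement.** During the pre-scene fixation window,
   does the voxel pattern of a region re-express the pattern evoked by the
   specific scene itself? The index is the mean Fisher-z within-trial
   fixation–scene pattern correlation minus the mean *set-based* baseline
   (a trial's fixation pattern correlated with every *other* trial's scene
   pattern in the same run and condition):

   `Δz = mean_i z(r(F_i, S_i)) − mean_{i≠j} z(r(F_i, S_j))`

   Positive values mean reinstatement carries scene-specific content over
   and above nonspecific similarity; its decay across delays tracks the
   time-related loss of detailed memory.

2. **Gist-like representation.** Do fixation patterns of different trials
   from the same scene *category* resemble each other more than trials from
   different categories? Pair correlations (within-run and cross-run
   blocks, each Fisher-transformed and Z-standardized against all pair
   similarities in its block) are averaged into
   `gist = mean(same-category pairs) − mean(different-category pairs)`.
   Positive values indicate a generic category-level memory trace.

Per-subject indices feed a mixed-effects condition model (delay x group,
subject random intercept, Satterthwaite degrees of freedom, Sidak post
hocs, omega-squared effect sizes, FDR across regions) and a **partial least
squares correlation** (PLSC): the 1 x k correlation matrix between behavior
(retention rate) and k standardized ROI metrics is decomposed as
`R = U S V'`; the salience vector V weights regions, per-subject *brain
scores* are `Z_metrics · V`, significance comes from permuting behavior
(5000 draws), and salience stability from bootstrap ratios
(`BSR = V / SD_boot`, robust when `|BSR| > 1.96`).

Because trial-wise fMRI betas are rarely shippable, the package includes a
first-class synthetic-cohort generator that emulates the whole design —
240 scene/object stimuli in 7 categories, adaptive 2–4 learning cycles to
an 83% criterion, 3 runs x (10 recent + 10 remote) retrieval trials per
scanning session, group- and delay-dependent retention — and plants a
parameterized effect structure in the beta patterns (scene loadings
decaying over delay, a child-only category loading at the long delay,
pure-noise control ROIs), so every stage of the analysis is testable
end-to-end without any data download.

## Worked example

```r
library(reinstatr)

catalog  <- build_catalog()                       # 240 scenes / 240 objects
design   <- build_design(catalog, design_config(n_children = 6, n_adults = 6),
                         seed = 2)
learning <- simulate_learning(design, seed = 3)
behavior <- simulate_behavior(design, learning, seed = 4)
patterns <- simulate_patterns(design, behavior, planted_effects(), seed = 5,
                              windows = c("fixation", "scene"),
                              rois = c("HCa", "WM"))

idx <- rbind(scene_reinstatement_index(patterns, "HCa", "recent"),
             scene_reinstatement_index(patterns, "HCa", "remote_short"),
             scene_reinstatement_index(patterns, "HCa", "remote_long"))
aggregate(value ~ condition, idx, mean, na.rm = TRUE)
#>      condition        value
#> 1       recent 0.0665345918
#> 2  remote_long 0.0069716699
#> 3 remote_short 0.0492029820
```

The group-mean corrected index recovers the planted decay (loadings 0.10,
0.06, 0.02 across delays; the analytic within-trial expectation at the
recent delay is `z(0.10/sqrt(1.01 * 2.01)) ≈ 0.070`). The same cohort's
white-matter control ROI (`"WM"`) shows no delay gradient (mean 0.007 at
this cohort size).

A full pipeline run (simulate → indices → mixed models → PLSC → report):

```r
run_pipeline(default_config(seed = 1), stages = "all", out_dir = "out")
```

writes `indices.tsv`, `stats.tsv`/`stats.json`, `roi_metrics.tsv`,
`brain_scores.tsv`, `plsc.json`, `report.txt`/`report.json` and a
checksum-guarded `run_manifest.json` under `out/`. The same pipeline is
scriptable via `exec/reinstatr`:

```sh
Rscript exec/reinstatr all --seed 1 --out out      # or --dump-config
```

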