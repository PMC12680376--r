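---
title: "Models and methods behind reinstatr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind reinstatr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the generative
model the synthetic cohorts follow, the similarity indices and their
estimation order, the inferential machinery, and the numerical and design
choices made where the methodology left room. It states no empirical result
that the test suite or the acceptance script does not itself compute.

## 1. The experimental world being emulated

The package targets consolidation studies of object–location associations:
children and young adults learn scene–object pairs to a criterion and
retrieve them in the scanner at three delays — immediately (recent), after
one night (short-delay remote), and after two weeks (long-delay remote).
The emulated design is:

* a stimulus catalog of 60 themes x 4 exemplars = 240 scenes and 240
  thematically congruent objects, themes assigned round-robin to 7
  categories (field, water, housing, forest, infrastructure, indoor,
  farming), so category sizes differ by at most one theme;
* per subject, 120 items: 60 encoded on day 0 (the remote pool, split
  category-balanced into the two remote sets), 30 new items on day 1 and
  30 on day 14 (recent sets); no item appears in more than one retrieval
  session;
* two scanning sessions of 3 runs x (10 recent + 10 remote) = 60 retrieval
  trials each; run orders are re-drawn until no more than two consecutive
  trials share a category (a greedy fallback handles degenerate catalogs);
* an adaptive learning phase of minimum 2 and maximum 4 retrieval–encoding
  cycles, stopping early once cycle accuracy reaches the 83% criterion
  (inclusive).

## 2. The pattern-generating model

For each subject, ROI and trial, three event windows are emulated at the
level of trial-wise (LSS-style) beta patterns on `n_voxels` voxels. With
`u_s`, `v_c`, `w_o` independent voxel templates for scene s, category c
and object o, and `eps ~ N(0, sigma^2)` iid per voxel:

| window   | correct trial                                  | incorrect trial      |
|----------|------------------------------------------------|----------------------|
| scene    | `a u_s + b v_c + eps`                          | same                 |
| fixation | `rho[g,d] u_s + gamma[g,d] v_c + eps`          | `gamma' v_c + eps`   |
| object   | `w_o + eps`                                    | same                 |

Control ROIs are pure noise in every window. Templates are drawn once per
cohort and shared across a subject's sessions, because stimuli are fixed
entities; this makes cross-session comparisons of recent conditions
meaningful.

**Template scaling.** Templates are normalized to unit root-mean-square
(`||u||^2 = n_voxels`), i.e. unit per-voxel variance. Under this scaling a
loading `w` contributes variance `w^2` per voxel regardless of ROI size,
and the expected within-trial fixation–scene correlation has the closed
form `rho a / sqrt((rho^2 + gamma^2 + sigma^2)(a^2 + b^2 + sigma^2))`,
which the test suite verifies by simulation. Under a literal unit-norm
scaling the planted signal would vanish as `n_voxels` grows and no
recovery property could hold; unit RMS is therefore the scaling the
package commits to.

**Defaults and why.** `sigma = 1`, `a = 1`, `b = 0.1`, `n_voxels = 200`.
The fixation scene loading decays over delay identically in both groups,
`rho = (0.10, 0.06, 0.02)` for recent / short / long: at `a = 1,
sigma = 1` this puts the recent index near `z = 0.070` and preserves a
strictly decreasing gradient, the qualitative signature of time-related
decay of detailed memory. The category loading is zero everywhere except
`gamma = 0.15` for children at the long delay, reproducing the
qualitative child-only emergence of prefrontal gist structure. The
magnitude is a power choice, made once: children retain ~55% of ~30
learned long-delay items, leaving ~16 correct trials and so roughly
`C(16,2)/7 ≈ 17` same-category pairs per subject; a pair correlation of
`gamma^2 / (gamma^2 + rho^2 + sigma^2) ≈ 0.022` then gives a single-subject
standardized effect large enough that the one-sample group test at
`n = 40` has ~99% power, and the joint "children significant, adults not"
pattern holds in ~95% of cohorts — the ceiling set by the adults' 5%
false-positive rate. (An earlier draft sized gamma assuming ~27 correct
trials; the corrected count raised it from 0.12 to 0.15. The decisions
ledger records this.)

Incorrect-trial fixation patterns carry no scene loading, mirroring the
empirical observation that incorrect trials show no session-related
reinstatement decline. Retention rates are drawn per subject and delay
around group means — children (80, 78, 55)%, adults (94, 93, 75)%, SD 10,
clipped to [0, 100] (clipping preferred over truncated-normal sampling for
simplicity; at these means the clip is rarely active) — and trial
correctness is Bernoulli at the subject's rate for learned items and at
3AFC chance (1/3) for unlearned ones. Reaction times are shifted-lognormal
plumbing; no drift-diffusion modeling. ROI mean-activation covariates are
plain Normal draws per subject/session; there is no hemodynamic model, no
temporal autocorrelation, and iid voxel noise is assumed (real LSS betas
have spatial covariance; this is flagged as a known simplification).

**What a green test does and does not establish.** The generator plants
exactly the covariance structure the indices are designed to detect, with
exchangeable subjects and Gaussian noise. Green recovery tests establish
that the estimators are unbiased, correctly ordered and calibrated *under
that model* — they do not certify behavior under spatially correlated
noise, motion artifacts, session-specific scanner effects, or the temporal
autocorrelation that real fixation–scene windows share.

## 3. Similarity indices

All indices use plain Pearson correlation across voxels, Fisher-transformed
per pair before any averaging (averaging z, not r). Analyses are
restricted to correct trials; timeouts/missed trials are excluded before
pairing.

**Corrected scene-specific reinstatement** (per subject x ROI x delay
condition x session): the specific term is the mean `z(r(F_i, S_i))` over
correct trials i; the set-based term is the mean `z(r(F_i, S_j))` over all
ordered pairs `i != j` of correct trials in the *same run and condition*;
each term is averaged within run, then across runs; the corrected index is
specific − set-based, so positive values mean more specific reinstatement.
Whether the set-based mean uses ordered or unordered pairs is
observationally equivalent here: the mean over ordered pairs equals the
unordered mean of the two directed correlations, and both directions are
computed. The object-window control substitutes the object pattern for the
scene pattern and should show no delay gradient. Cells with fewer than 3
correct trials yield an NA record with a reason — never a silent drop.

**Gist index** (per subject x ROI x condition x session): all unordered
pairs of correct fixation patterns, pooled from the within-run and
cross-run blocks. Each block's Fisher-z values are Z-standardized against
the distribution of *all* pair similarities in that block (the pooled
mean/SD convention; computed per subject x ROI x condition), then within-
and between-category pair means are differenced. Standardizing per block
before pooling removes block-level offsets (cross-run similarities sit on
a different baseline than within-run ones) at the cost of expressing the
index in block-SD units rather than raw z. A condition with a single
category is undefined (NA with reason); fewer than 3 same- or
different-category pairs also yields NA.

**Recent-session aggregation**: recent items are measured once per
scanning session; a paired t-test (pluggable) gates merging. If
non-significant at alpha = 0.05 the subject-wise mean is returned as one
pooled record; otherwise both sessions are kept with a flag.

## 4. Inference

* **Sign-flip permutation test**: one-sample t statistic; exhaustive
  enumeration of all `2^n` sign assignments when `2^n <= n_perm` (exact
  proportion), otherwise sampled flips with the observed statistic counted
  (`(1 + #extreme)/(1 + n_draws)`), guaranteeing validity. Two-sided by
  default; the sidedness choice is recorded in the result.
* **Multiplicity**: Benjamini–Hochberg step-up FDR across ROIs/terms;
  Sidak `1 − (1 − p)^m` for post hoc families, with m = the number of
  pairwise contrasts actually tested.
* **Effect size**: `omega^2 = (SS_eff − df_eff MS_err)/(SS_tot + MS_err)`,
  computed for mixed models from the sequential ANOVA decomposition of the
  fixed part (an OLS approximation, labeled as such in the output).
* **Condition models**: `response ~ factors (full factorial) + covariates +
  (1 | subject)`, fit with lme4. Omnibus F tests use sum-to-zero coding
  (marginal, Type-III-style) and Satterthwaite denominator degrees of
  freedom computed in-package from the analytic REML-adjusted expected
  information of the two variance components of the random-intercept
  model; pairwise contrasts are built on marginal means with per-contrast
  Satterthwaite df. REML (not plain ML) supplies the variance components:
  in the zero-between-subject-variance limit this reproduces the
  fixed-effects ANOVA F exactly, which is the behavior the test suite
  pins; the df method is recorded in the output metadata.
  Kenward–Roger is out of scope.
* **IQR outlier screen**: type-7 quartiles, `k = 3` extreme fences.

## 5. PLSC

Metrics and behavior are z-standardized; `R = cor(behavior, metrics)` is a
`1 x k` row vector, so the SVD `R = U S V'` is rank one and analytic:
`V = R'/||R||`, `S = ||R||`. The implementation takes the numeric SVD and
asserts the analytic identity on every fit (dual-route check). Saliences
are oriented so the Spearman correlation between brain scores
(`Z_metrics V`) and behavior is non-negative; individual ROI signs are
interpreted relative to that orientation. Pearson is used inside R (the
correlation step); Spearman for the reported latent and per-ROI
correlations. The per-ROI r reported beside each bootstrap ratio is the
Spearman correlation between that ROI's metric and behavior (an
interpretation choice, documented; correlating with the brain score would
be the alternative). Significance: permute behavior, recompute S, count
with the +1 convention. Stability: resample subjects with replacement,
sign-align each draw's salience vector to the original by dot product
(the standard remedy for reflection indeterminacy), and divide the
original salience by the bootstrap SD; `|BSR| > 1.96` flags robustness.
Degenerate draws (constant column or behavior) are redrawn with a capped
retry count. Missing rows are dropped listwise and logged. Group
differences in latent expression use a Welch t-test on brain scores.

## 6. Pipeline and reproducibility

Stages `simulate → rsa → stats → plsc → report` exchange fixed-name TSV
(data) and JSON (models, manifests); the pattern archive is one directory
per subject with one `roi_window.tsv` per ROI and event window plus
cohort-level `trials.tsv`, `mean_activation.tsv` and `meta.json`. The same
layout accepts real trial-wise betas exported to TSV. Configuration is a
single JSON document merged over `default_config()` and validated
(missing sections are named in the error); `--dump-config` prints the
defaults. All randomness descends from one master seed through a counter
scheme (`derive_seed`), recorded in `run_manifest.json` together with the
config hash, stage timings and output checksums; a later stage refuses to
run on inputs whose checksums no longer match the manifest. Identical
config + seed reproduces byte-identical outputs.

## 7. Known limitations

iid Gaussian voxel noise (no spatial covariance, no temporal
autocorrelation); no searchlight or whole-brain maps; no NIfTI/BIDS I/O;
no Kenward–Roger df; no multi-column behavior blocks or task-PLS variant
(the single behavior vector makes the latent space rank one by
construction); omega-squared for mixed models is an OLS-based
approximation; the within-group PLSC instability reported for small real
samples is represented only mechanistically (smaller n gives wider
bootstrap SDs), not as a pinned outcome.
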