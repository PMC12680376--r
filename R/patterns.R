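#' Planted effect structure for the pattern generator
#'
#' Houses the loadings of the generative model for trial-wise beta
#' patterns. For a trial showing scene s (category c, object o):
#' \itemize{
#'   \item scene window: `a * u_s + b * v_c + eps`
#'   \item fixation window, correct trial:
#'     `rho[group, delay] * u_s + gamma[group, delay] * v_c + eps`
#'   \item fixation window, incorrect trial:
#'     `gamma_incorrect[group, delay] * v_c + eps` (no scene loading)
#'   \item object window: `w_o + eps`
#' }
#' with u_s, v_c, w_o independent unit-norm voxel templates per ROI drawn
#' once per cohort, and `eps` iid Normal(0, sigma^2). Control ROIs are pure
#' noise in every window.
#'
#' Defaults: scene-specific reinstatement decays over delay identically in
#' both groups (0.10, 0.06, 0.02); a category (gist) loading appears only in
#' children at the long delay (0.15, sized so the category signal is
#' detectable at the single-subject level given 200 voxels and the roughly
#' 16 correct long-delay trials that 55% child retention leaves).
#'
#' @param rho matrix \[group x delay\] scene-template loading of the
#'   fixation pattern; rows `children`, `adults`; columns `recent`,
#'   `remote_short`, `remote_long`.
#' @param gamma matrix like `rho`: category-template loading of the fixation
#'   pattern.
#' @param gamma_incorrect category loading on incorrect trials (defaults to
#'   `gamma`); the scene loading of incorrect trials is always 0.
#' @param a,b scene- and category-template weights of the scene-window
#'   pattern.
#' @param sigma voxel noise SD (> 0).
#' @param n_voxels voxels per ROI (>= 10).
#' @param rois character vector of signal-carrying ROI names.
#' @param control_rois ROIs generated as pure noise (white-matter-style
#'   controls).
#' @param act_mean matrix \[group x session\] of the ROI mean-activation
#'   covariate; `act_sd` its SD.
#' @return a `planted_effects` list.
#' @export
planted_effects <- function(
    rho = rbind(children = c(recent = 0.10, remote_short = 0.06,
                             remote_long = 0.02),
                adults   = c(recent = 0.10, remote_short = 0.06,
                             remote_long = 0.02)),
    gamma = rbind(children = c(recent = 0, remote_short = 0,
                               remote_long = 0.15),
                  adults   = c(recent = 0, remote_short = 0,
                               remote_long = 0)),
    gamma_incorrect = gamma,
    a = 1, b = 0.1, sigma = 1, n_voxels = 200L,
    rois = c("HCa", "PHGa", "mPFC", "vlPFC", "LOC"),
    control_rois = "WM",
    act_mean = rbind(children = c(day1 = 0.30, day14 = 0.35),
                     adults = c(day1 = 0.40, day14 = 0.50)),
    act_sd = 0.15) {
  assert_config(sigma > 0, "sigma must be > 0")
  assert_config(n_voxels >= 10L, "n_voxels must be >= 10")
  stopifnot(identical(rownames(rho), c("children", "adults")),
            identical(rownames(gamma), c("children", "adults")))
  structure(list(rho = rho, gamma = gamma,
                 gamma_incorrect = gamma_incorrect, a = a, b = b,
                 sigma = sigma, n_voxels = as.integer(n_voxels),
                 rois = rois, control_rois = control_rois,
                 act_mean = act_mean, act_sd = act_sd),
            class = "planted_effects")
}

# Templates are normalized to unit root-mean-square (||u||^2 = n_voxels),
# i.e. unit per-voxel variance, so a loading w contributes variance w^2 per
# voxel regardless of ROI size and the within-trial fixation-scene
# correlation has the closed form rho*a / sqrt((rho^2+s2)(a^2+s2)).
unit_templates <- function(n, n_voxels, ids) {
  m <- matrix(stats::rnorm(n * n_voxels), n, n_voxels)
  m <- m / sqrt(rowMeans(m^2))
  rownames(m) <- ids
  m
}

#' Simulate trial-wise multivoxel beta patterns
#'
#' Generates, for every subject, ROI and event window, a trials-x-voxels
#' matrix of beta values carrying the planted effect structure of
#' [planted_effects()], emulating trial-wise (LSS-style) beta estimates.
#' Rows align with the subject's rows of `design$trials` (both retrieval
#' sessions, run and trial order).
#'
#' @param design an `experimental_design`.
#' @param behavior a `behavioral_table` (correctness gates the scene loading
#'   of fixation patterns).
#' @param planted a `planted_effects`.
#' @param seed integer seed.
#' @param windows subset of `c("object", "fixation", "scene")` to generate
#'   (all by default; recovery simulations can skip unused windows).
#' @param rois optional subset of ROIs (signal + control) to generate.
#' @return a `pattern_set`: `patterns[[subject]][[roi]][[window]]` matrices,
#'   `trials` metadata, `mean_activation` (subject x session x ROI), and
#'   seed/config provenance.
#' @export
simulate_patterns <- function(design, behavior, planted = planted_effects(),
                              seed = 1L,
                              windows = c("object", "fixation", "scene"),
                              rois = NULL) {
  stopifnot(inherits(design, "experimental_design"),
            inherits(planted, "planted_effects"))
  windows <- match.arg(windows, c("object", "fixation", "scene"),
                       several.ok = TRUE)
  all_rois <- c(planted$rois, planted$control_rois)
  if (is.null(rois)) rois <- all_rois
  assert_config(all(rois %in% all_rois), "unknown ROI requested")

  trials <- as.data.frame(behavior)
  nv <- planted$n_voxels
  scene_ids <- unique(trials$item_id)
  cats <- sort(unique(trials$category))

  with_seed(seed, {
    # cohort-level templates per ROI (only signal ROIs need them)
    templ <- list()
    for (roi in setdiff(rois, planted$control_rois)) {
      templ[[roi]] <- list(
        scene = unit_templates(length(scene_ids), nv, scene_ids),
        category = unit_templates(length(cats), nv, cats),
        object = unit_templates(length(scene_ids), nv, scene_ids))
    }
    subjects <- design$subjects
    patterns <- vector("list", nrow(subjects))
    names(patterns) <- subjects$subject_id
    act <- array(NA_real_,
                 dim = c(nrow(subjects), 2L, length(rois)),
                 dimnames = list(subjects$subject_id, c("day1", "day14"),
                                 rois))
    for (si in seq_len(nrow(subjects))) {
      sid <- subjects$subject_id[si]
      grp <- subjects$group[si]
      tr <- trials[trials$subject_id == sid, ]
      nt <- nrow(tr)
      per_roi <- list()
      for (roi in rois) {
        ctrl <- roi %in% planted$control_rois
        mats <- list()
        for (w in windows) {
          noise <- matrix(stats::rnorm(nt * nv, sd = planted$sigma), nt, nv)
          if (ctrl) {
            mats[[w]] <- noise
          } else {
            tp <- templ[[roi]]
            sig <- switch(w,
              scene = planted$a * tp$scene[tr$item_id, , drop = FALSE] +
                planted$b * tp$category[tr$category, , drop = FALSE],
              object = tp$object[tr$item_id, , drop = FALSE],
              fixation = {
                rho_t <- ifelse(tr$correct == 1L,
                                planted$rho[grp, tr$delay], 0)
                gam_t <- ifelse(tr$correct == 1L,
                                planted$gamma[grp, tr$delay],
                                planted$gamma_incorrect[grp, tr$delay])
                rho_t * tp$scene[tr$item_id, , drop = FALSE] +
                  gam_t * tp$category[tr$category, , drop = FALSE]
              })
            mats[[w]] <- sig + noise
          }
          rownames(mats[[w]]) <- tr$trial_uid
        }
        per_roi[[roi]] <- mats
        act[sid, , roi] <- stats::rnorm(2L, planted$act_mean[grp, ],
                                        planted$act_sd)
      }
      patterns[[sid]] <- per_roi
    }
    structure(list(patterns = patterns, trials = trials,
                   mean_activation = act, rois = rois, windows = windows,
                   planted = planted, seed = seed,
                   config_hash = config_hash(unclass(planted))),
              class = "pattern_set")
  })
}

#' @export
print.pattern_set <- function(x, ...) {
  cat(sprintf("pattern_set: %d subjects, %d ROIs (%s), windows: %s, %d voxels\n",
              length(x$patterns), length(x$rois),
              paste(x$rois, collapse = ", "),
              paste(x$windows, collapse = ", "), x$planted$n_voxels))
  invisible(x)
}

#' Simulate a subjects-x-ROIs metric table with a single latent factor
#'
#' Each subject carries a latent factor f ~ N(0, 1); the metric for ROI j is
#' `saliences[j] * f + noise * e_j` and behavior is
#' `latent_strength * f + sqrt(1 - latent_strength^2) * e`, so the
#' behavior-latent correlation equals `latent_strength` in expectation.
#'
#' @param design an `experimental_design`, or an integer subject count (then
#'   groups split half/half).
#' @param saliences numeric vector of ROI loadings (names become ROI ids).
#' @param latent_strength target behavior-latent correlation, |.| <= 1.
#' @param noise metric noise SD.
#' @param group_latent_offset shift added to adults' latent factor (in SD
#'   units); 0 by default, used to plant group differences in brain scores.
#' @param seed integer seed.
#' @return a `roi_metric_table`: list(metrics, behavior, group, subject_id).
#' @export
simulate_roi_metrics <- function(design, saliences, latent_strength = 0.5,
                                 noise = 1, group_latent_offset = 0,
                                 seed = 1L) {
  assert_config(length(saliences) >= 1L, "salience vector must be non-empty")
  assert_config(abs(latent_strength) <= 1, "|latent_strength| must be <= 1")
  if (inherits(design, "experimental_design")) {
    ids <- design$subjects$subject_id
    grp <- design$subjects$group
  } else {
    n <- as.integer(design)
    assert_config(n >= 2L, "need at least 2 subjects")
    ids <- sprintf("s%04d", seq_len(n))
    grp <- rep(c("children", "adults"), c(ceiling(n / 2), floor(n / 2)))
  }
  k <- length(saliences)
  roi_names <- names(saliences) %||% sprintf("roi%02d", seq_len(k))
  with_seed(seed, {
    f <- stats::rnorm(length(ids)) + group_latent_offset * (grp == "adults")
    metrics <- outer(f, as.numeric(saliences)) +
      noise * matrix(stats::rnorm(length(ids) * k), length(ids), k)
    dimnames(metrics) <- list(ids, roi_names)
    behavior <- latent_strength * f +
      sqrt(max(0, 1 - latent_strength^2)) * stats::rnorm(length(ids))
    structure(list(metrics = metrics, behavior = behavior, group = grp,
                   subject_id = ids, seed = seed),
              class = "roi_metric_table")
  })
}
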