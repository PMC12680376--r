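# In-code fixtures and independent brute-force oracles. The oracles go
# pair by pair through pattern_similarity() / atanh(cor(...)) double loops
# and never touch the vectorized index implementations they check.

tiny_cohort <- function(n_children = 4, n_adults = 4, seed = 11,
                        planted = planted_effects(n_voxels = 40L),
                        windows = c("object", "fixation", "scene"),
                        rois = NULL) {
  catalog <- build_catalog()
  design <- build_design(catalog, design_config(n_children, n_adults),
                         seed = derive_seed(seed, 1))
  learning <- simulate_learning(design, seed = derive_seed(seed, 2))
  behavior <- simulate_behavior(design, learning,
                                seed = derive_seed(seed, 3))
  pset <- simulate_patterns(design, behavior, planted,
                            seed = derive_seed(seed, 4),
                            windows = windows, rois = rois)
  list(catalog = catalog, design = design, learning = learning,
       behavior = behavior, pset = pset)
}

# construct a pattern_set around hand-written matrices (one subject, one
# ROI); `fix`, `scene`, `object` are trials x voxels, rows in trial order
manual_pset <- function(fix, scene = NULL, object = NULL, run, category,
                        correct = rep(1L, nrow(fix)), session = "day1",
                        delay = "remote_short", roi = "ROI1",
                        subject = "s1", group = "adults") {
  n <- nrow(fix)
  uid <- sprintf("%s_%s_r%d_t%02d", subject, session, run, seq_len(n) - 1L)
  rownames(fix) <- uid
  mats <- list(fixation = fix)
  if (!is.null(scene)) { rownames(scene) <- uid; mats$scene <- scene }
  if (!is.null(object)) { rownames(object) <- uid; mats$object <- object }
  trials <- data.frame(
    subject_id = subject, group = group, session = session, run = run,
    trial = seq_len(n) - 1L, item_id = sprintf("item%02d", seq_len(n)),
    item_type = "remote", category = category, delay = delay,
    correct = correct, rt = 1.5, learned = TRUE, trial_uid = uid,
    stringsAsFactors = FALSE)
  structure(list(patterns = setNames(list(setNames(list(mats), roi)),
                                     subject),
                 trials = trials,
                 mean_activation = array(0, c(1, 2, 1),
                                         dimnames = list(subject,
                                                         c("day1", "day14"),
                                                         roi)),
                 rois = roi, windows = names(mats),
                 planted = list(n_voxels = ncol(fix)), seed = 0,
                 config_hash = "manual"),
            class = "pattern_set")
}

# brute-force corrected reinstatement: explicit double loop, Fisher per
# pair, average within run then across runs, specific - set-based
oracle_reinstatement <- function(fix, event, run, correct) {
  keep <- which(correct == 1L)
  spec_runs <- base_runs <- numeric(0)
  for (r in sort(unique(run[keep]))) {
    idx <- keep[run[keep] == r]
    zs <- vapply(idx, function(i)
      atanh(cor(fix[i, ], event[i, ])), numeric(1))
    spec_runs <- c(spec_runs, mean(zs))
    zb <- c()
    for (i in idx) for (j in idx) if (i != j)
      zb <- c(zb, atanh(cor(fix[i, ], event[j, ])))
    if (length(zb)) base_runs <- c(base_runs, mean(zb))
  }
  list(specific = mean(spec_runs), baseline = mean(base_runs),
       value = mean(spec_runs) - mean(base_runs))
}

# brute-force gist: all C(n,2) unordered pairs, Fisher z, Z-standardize the
# within-run and cross-run blocks separately, within - between category
oracle_gist <- function(fix, run, category) {
  n <- nrow(fix)
  pairs <- t(combn(n, 2))
  z <- apply(pairs, 1, function(p) atanh(cor(fix[p[1], ], fix[p[2], ])))
  same_run <- run[pairs[, 1]] == run[pairs[, 2]]
  same_cat <- category[pairs[, 1]] == category[pairs[, 2]]
  zstd <- rep(NA_real_, length(z))
  for (blk in c(TRUE, FALSE)) {
    b <- same_run == blk
    if (sum(b) >= 2) zstd[b] <- (z[b] - mean(z[b])) / sd(z[b])
  }
  w <- mean(zstd[same_cat], na.rm = TRUE)
  btw <- mean(zstd[!same_cat], na.rm = TRUE)
  list(within = w, between = btw, value = w - btw)
}
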