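#' Fisher z-transform of a correlation
#'
#' `z = arctanh(r)`, making correlations approximately normal for averaging
#' and testing. Vectorized; any |r| >= 1 is a domain error (degenerate
#' constant patterns must be guarded by the caller).
#'
#' @param r correlation value(s), |r| < 1.
#' @return transformed value(s).
#' @export
fisher_z <- function(r) {
  if (any(!is.finite(r)) || any(abs(r) >= 1))
    stop(errorCondition("fisher_z: |r| >= 1 (or non-finite) is outside the domain",
                        class = c("reinstatr_domain_error", "error")))
  atanh(r)
}

#' Pearson similarity between two voxel patterns
#'
#' Plain Pearson correlation over voxels (no centering beyond Pearson's own
#' mean removal), with its Fisher z value. A correlation at the +/-1
#' boundary is returned with `boundary = TRUE` and `z = NA` rather than
#' passed to [fisher_z()].
#'
#' @param p1,p2 numeric voxel vectors of equal length >= 2, non-constant.
#' @return a `similarity_value` list: `r`, `z`, `boundary`.
#' @export
pattern_similarity <- function(p1, p2) {
  stopifnot(length(p1) == length(p2), length(p1) >= 2)
  if (stats::sd(p1) == 0 || stats::sd(p2) == 0)
    stop(errorCondition("pattern_similarity: constant (degenerate) pattern",
                        class = c("reinstatr_degenerate_error", "error")))
  r <- stats::cor(p1, p2)
  boundary <- abs(r) >= 1 - 1e-12
  structure(list(r = r, z = if (boundary) NA_real_ else atanh(r),
                 boundary = boundary),
            class = "similarity_value")
}

# correlation matrix between rows of A and rows of B (trials x voxels);
# rows with zero variance yield NA columns/rows
row_standardize <- function(m) {
  mu <- rowMeans(m)
  ctr <- m - mu
  s <- sqrt(rowSums(ctr^2))
  s[s == 0] <- NA_real_
  ctr / s
}

cross_cor <- function(a, b) {
  tcrossprod(row_standardize(a), row_standardize(b))
}

na_record <- function(sid, grp, roi, session, condition, index_type, reason,
                      n_items = 0L, n_pairs = 0L) {
  data.frame(subject_id = sid, group = grp, roi = roi, session = session,
             condition = condition, index_type = index_type,
             term_specific = NA_real_, term_baseline = NA_real_,
             value = NA_real_, n_items = n_items, n_pairs = n_pairs,
             reason = reason, stringsAsFactors = FALSE)
}

sessions_for <- function(condition) {
  switch(condition,
         recent = c("day1", "day14"),
         remote_short = "day1",
         remote_long = "day14",
         config_error("unknown condition '%s'", condition))
}

#' Corrected scene-specific reinstatement index
#'
#' For one subject x ROI x delay condition x session: the *specific* term is
#' the mean Fisher-z correlation between each correct trial's fixation
#' pattern and its own scene-window (or, for the control, object-window)
#' pattern; the *set-based* term is the mean Fisher-z correlation between a
#' trial's fixation pattern and every *other* correct trial's window pattern
#' in the same run and condition. Pairs are Fisher-transformed first, then
#' averaged within run, then across runs. The corrected index is
#' specific - set-based (positive = more scene-specific reinstatement).
#'
#' @param pset a `pattern_set`.
#' @param roi ROI name.
#' @param condition one of `recent`, `remote_short`, `remote_long`. Recent
#'   items yield one record per scanning session (merge with
#'   [aggregate_recent()]).
#' @param event comparison window: `"scene"` (main index) or `"object"`
#'   (control index).
#' @param min_trials minimum correct trials per session cell; below it the
#'   record's value is NA with a reason, never silently dropped.
#' @return data frame of index records (one row per subject x session).
#' @export
scene_reinstatement_index <- function(pset, roi, condition,
                                      event = c("scene", "object"),
                                      min_trials = 3L) {
  stopifnot(inherits(pset, "pattern_set"))
  event <- match.arg(event)
  index_type <- if (event == "scene") "scene_reinstatement" else "object_control"
  trials <- pset$trials
  out <- list()
  for (sid in names(pset$patterns)) {
    grp <- trials$group[match(sid, trials$subject_id)]
    mats <- pset$patterns[[sid]][[roi]]
    if (is.null(mats) || is.null(mats$fixation) || is.null(mats[[event]]))
      config_error("ROI '%s' lacks fixation/%s patterns", roi, event)
    for (session in sessions_for(condition)) {
      sel <- trials$subject_id == sid & trials$session == session &
        trials$delay == condition & trials$correct == 1L
      tr <- trials[sel, ]
      if (nrow(tr) < min_trials) {
        out[[length(out) + 1L]] <- na_record(
          sid, grp, roi, session, condition, index_type,
          sprintf("only %d correct trials (min %d)", nrow(tr), min_trials))
        next
      }
      spec_runs <- base_runs <- numeric(0)
      n_pairs <- 0L
      for (r in sort(unique(tr$run))) {
        uid <- tr$trial_uid[tr$run == r]
        fx <- mats$fixation[uid, , drop = FALSE]
        ev <- mats[[event]][uid, , drop = FALSE]
        cc <- cross_cor(fx, ev)
        zz <- suppressWarnings(atanh(cc))
        zz[abs(cc) >= 1] <- NA_real_  # degenerate pair: excluded
        spec_runs <- c(spec_runs, mean(diag(zz), na.rm = TRUE))
        if (length(uid) >= 2L) {
          off <- zz[row(zz) != col(zz)]
          base_runs <- c(base_runs, mean(off, na.rm = TRUE))
          n_pairs <- n_pairs + sum(!is.na(off))
        }
      }
      term_specific <- mean(spec_runs)
      term_baseline <- if (length(base_runs)) mean(base_runs) else NA_real_
      out[[length(out) + 1L]] <- data.frame(
        subject_id = sid, group = grp, roi = roi, session = session,
        condition = condition, index_type = index_type,
        term_specific = term_specific, term_baseline = term_baseline,
        value = term_specific - term_baseline,
        n_items = nrow(tr), n_pairs = n_pairs, reason = NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Gist-like representation index
#'
#' Within- minus between-category similarity of fixation patterns across
#' correct trials of a condition, pooling within-run and cross-run pairs.
#' Pair correlations are Fisher-transformed and each block (within-run vs
#' cross-run) is Z-standardized against the distribution of all pair
#' similarities in that block before pooling; the index is the mean
#' standardized similarity of same-category pairs minus that of
#' different-category pairs. Positive values indicate a generic
#' category-level (gist) representation.
#'
#' @inheritParams scene_reinstatement_index
#' @param min_pairs minimum same-category and different-category pair count;
#'   below it the record is NA with a reason.
#' @return data frame of index records (one row per subject x session);
#'   `term_specific` holds the within-category term and `term_baseline` the
#'   between-category term.
#' @export
gist_index <- function(pset, roi, condition, min_pairs = 3L) {
  stopifnot(inherits(pset, "pattern_set"))
  trials <- pset$trials
  out <- list()
  for (sid in names(pset$patterns)) {
    grp <- trials$group[match(sid, trials$subject_id)]
    mats <- pset$patterns[[sid]][[roi]]
    if (is.null(mats) || is.null(mats$fixation))
      config_error("ROI '%s' lacks fixation patterns", roi)
    for (session in sessions_for(condition)) {
      sel <- trials$subject_id == sid & trials$session == session &
        trials$delay == condition & trials$correct == 1L
      tr <- trials[sel, ]
      if (length(unique(tr$category)) < 2L) {
        out[[length(out) + 1L]] <- na_record(
          sid, grp, roi, session, condition, "gist",
          "fewer than 2 categories among correct trials", nrow(tr))
        next
      }
      fx <- mats$fixation[tr$trial_uid, , drop = FALSE]
      cc <- cross_cor(fx, fx)
      n <- nrow(tr)
      pair_i <- which(upper.tri(cc), arr.ind = TRUE)
      r <- cc[pair_i]
      z <- suppressWarnings(atanh(r))
      z[abs(r) >= 1] <- NA_real_
      same_run <- tr$run[pair_i[, 1]] == tr$run[pair_i[, 2]]
      same_cat <- tr$category[pair_i[, 1]] == tr$category[pair_i[, 2]]
      zstd <- rep(NA_real_, length(z))
      for (blk in c(TRUE, FALSE)) {
        in_blk <- same_run == blk & !is.na(z)
        if (sum(in_blk) >= 2L && stats::sd(z[in_blk]) > 0)
          zstd[in_blk] <- (z[in_blk] - mean(z[in_blk])) / stats::sd(z[in_blk])
      }
      n_within <- sum(same_cat & !is.na(zstd))
      n_between <- sum(!same_cat & !is.na(zstd))
      if (n_within < min_pairs || n_between < min_pairs) {
        out[[length(out) + 1L]] <- na_record(
          sid, grp, roi, session, condition, "gist",
          sprintf("too few pairs (within %d, between %d, min %d)",
                  n_within, n_between, min_pairs),
          nrow(tr), n_within + n_between)
        next
      }
      w <- mean(zstd[same_cat], na.rm = TRUE)
      b <- mean(zstd[!same_cat], na.rm = TRUE)
      out[[length(out) + 1L]] <- data.frame(
        subject_id = sid, group = grp, roi = roi, session = session,
        condition = condition, index_type = "gist",
        term_specific = w, term_baseline = b, value = w - b,
        n_items = n, n_pairs = n_within + n_between,
        reason = NA_character_, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Merge recent-condition records across scanning sessions
#'
#' Recent items are measured once per scanning session; if the supplied
#' session-difference test is non-significant the subject-wise mean is
#' returned as a single record per subject, otherwise both sessions are
#' returned unmerged with a flag.
#'
#' @param records_day1,records_day14 index-record data frames for the recent
#'   condition (same subjects and ROI).
#' @param test function(v1, v2) returning a p-value for a session
#'   difference; default paired t-test.
#' @param alpha significance level gating the merge (default 0.05).
#' @return list with `merged` (logical), `p` (test p-value) and `records`.
#' @export
aggregate_recent <- function(records_day1, records_day14, test = NULL,
                             alpha = 0.05) {
  if (!setequal(records_day1$subject_id, records_day14$subject_id))
    stop(errorCondition("aggregate_recent: subject sets differ between sessions",
                        class = c("reinstatr_alignment_error", "error")))
  d1 <- records_day1[order(records_day1$subject_id), ]
  d14 <- records_day14[order(records_day14$subject_id), ]
  if (is.null(test))
    test <- function(v1, v2) {
      keep <- is.finite(v1) & is.finite(v2)
      if (sum(keep) < 3L) return(1)
      d <- v1[keep] - v2[keep]
      # an (essentially) constant difference defeats the t-test (error or
      # NaN): treat a constant zero as "no session effect", any other
      # constant as a shift
      p <- tryCatch(stats::t.test(v1[keep], v2[keep], paired = TRUE)$p.value,
                    error = function(e) NaN)
      if (!is.finite(p)) p <- if (abs(mean(d)) <= 1e-12) 1 else 0
      p
    }
  p <- test(d1$value, d14$value)
  if (p >= alpha) {
    merged <- d1
    merged$session <- "pooled"
    merged$term_specific <- rowMeans(cbind(d1$term_specific,
                                           d14$term_specific))
    merged$term_baseline <- rowMeans(cbind(d1$term_baseline,
                                           d14$term_baseline))
    merged$value <- rowMeans(cbind(d1$value, d14$value))
    merged$n_items <- d1$n_items + d14$n_items
    merged$n_pairs <- d1$n_pairs + d14$n_pairs
    list(merged = TRUE, p = p, records = merged)
  } else {
    list(merged = FALSE, p = p, records = rbind(d1, d14))
  }
}

#' Compute all similarity indices for a pattern set
#'
#' Convenience wrapper producing the long-format index table (one row per
#' subject x ROI x condition x session x index type). Recent records are
#' merged across sessions per ROI and index type via [aggregate_recent()]
#' when the session test permits.
#'
#' @param pset a `pattern_set`.
#' @param rois ROIs to analyze (default: all in the set).
#' @param index_types subset of `scene_reinstatement`, `object_control`,
#'   `gist`.
#' @param merge_recent merge recent sessions when non-significant (default
#'   TRUE).
#' @return long data frame of index records.
#' @export
compute_indices <- function(pset, rois = pset$rois,
                            index_types = c("scene_reinstatement",
                                            "object_control", "gist"),
                            merge_recent = TRUE) {
  index_types <- match.arg(index_types, several.ok = TRUE)
  conditions <- c("recent", "remote_short", "remote_long")
  out <- list()
  for (roi in rois) {
    for (it in index_types) {
      fn <- switch(it,
        scene_reinstatement = function(cond)
          scene_reinstatement_index(pset, roi, cond, event = "scene"),
        object_control = function(cond)
          scene_reinstatement_index(pset, roi, cond, event = "object"),
        gist = function(cond) gist_index(pset, roi, cond))
      for (cond in conditions) {
        rec <- fn(cond)
        if (cond == "recent" && merge_recent) {
          agg <- aggregate_recent(rec[rec$session == "day1", ],
                                  rec[rec$session == "day14", ])
          rec <- agg$records
        }
        out[[length(out) + 1L]] <- rec
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
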