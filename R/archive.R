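#' Write a pattern archive to disk
#'
#' Layout: one directory per subject containing one TSV per ROI x event
#' window (`<roi>_<window>.tsv`, columns `trial_uid` then `v0001...vNNNN`);
#' a cohort-level `trials.tsv` metadata table, `mean_activation.tsv`, and a
#' `meta.json` with seed, config hash and planted parameters. The same
#' layout can hold real trial-wise beta estimates exported to TSV.
#'
#' @param pset a `pattern_set`.
#' @param dir target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pattern_archive <- function(pset, dir) {
  stopifnot(inherits(pset, "pattern_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cols <- c("subject_id", "group", "session", "run", "trial", "item_id",
            "item_type", "category", "delay", "correct", "rt", "learned",
            "trial_uid")
  tr <- as.data.frame(pset$trials)[, cols]
  data.table::fwrite(tr, file.path(dir, "trials.tsv"), sep = "\t")

  act <- pset$mean_activation
  act_long <- do.call(rbind, lapply(dimnames(act)[[3]], function(roi) {
    data.frame(subject_id = rep(rownames(act), times = ncol(act)),
               session = rep(colnames(act), each = nrow(act)),
               roi = roi, mean_activation = as.vector(act[, , roi]),
               stringsAsFactors = FALSE)
  }))
  data.table::fwrite(act_long, file.path(dir, "mean_activation.tsv"),
                     sep = "\t")

  for (sid in names(pset$patterns)) {
    sdir <- file.path(dir, sid)
    dir.create(sdir, showWarnings = FALSE)
    for (roi in names(pset$patterns[[sid]])) {
      for (w in names(pset$patterns[[sid]][[roi]])) {
        m <- pset$patterns[[sid]][[roi]][[w]]
        df <- data.table::as.data.table(m)
        data.table::setnames(df, sprintf("v%04d", seq_len(ncol(m))))
        df <- cbind(data.table::data.table(trial_uid = rownames(m)), df)
        data.table::fwrite(df, file.path(sdir, sprintf("%s_%s.tsv", roi, w)),
                           sep = "\t")
      }
    }
  }
  meta <- list(seed = pset$seed, config_hash = pset$config_hash,
               rois = pset$rois, windows = pset$windows,
               n_voxels = pset$planted$n_voxels,
               planted = unclass(pset$planted))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a pattern archive from disk
#'
#' @param dir archive directory written by [write_pattern_archive()] (or any
#'   archive following that layout).
#' @return a `pattern_set` (the `planted` element is the deserialized
#'   metadata, not a live `planted_effects` object, when read from disk).
#' @export
read_pattern_archive <- function(dir) {
  assert_config(file.exists(file.path(dir, "trials.tsv")),
                "no trials.tsv found under '%s'", dir)
  trials <- as.data.frame(data.table::fread(file.path(dir, "trials.tsv")))
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  act_long <- as.data.frame(
    data.table::fread(file.path(dir, "mean_activation.tsv")))
  subjects <- unique(trials$subject_id)
  sessions <- sort(unique(act_long$session))
  rois <- unlist(meta$rois)
  act <- array(NA_real_, dim = c(length(subjects), length(sessions),
                                 length(rois)),
               dimnames = list(subjects, sessions, rois))
  act[cbind(act_long$subject_id, act_long$session, act_long$roi)] <-
    act_long$mean_activation

  patterns <- list()
  for (sid in subjects) {
    sdir <- file.path(dir, sid)
    per_roi <- list()
    for (roi in rois) {
      mats <- list()
      for (w in unlist(meta$windows)) {
        f <- file.path(sdir, sprintf("%s_%s.tsv", roi, w))
        if (!file.exists(f)) next
        dt <- data.table::fread(f)
        uid <- dt$trial_uid
        m <- as.matrix(dt[, -1])
        dimnames(m) <- list(uid, NULL)
        mats[[w]] <- m
      }
      per_roi[[roi]] <- mats
    }
    patterns[[sid]] <- per_roi
  }
  structure(list(patterns = patterns, trials = trials,
                 mean_activation = act, rois = rois,
                 windows = unlist(meta$windows), planted = meta$planted,
                 seed = meta$seed, config_hash = meta$config_hash),
            class = "pattern_set")
}
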