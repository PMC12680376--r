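#' Default pipeline configuration
#'
#' A nested list covering every stage: the demo cohort is 20 subjects per
#' group, five signal ROIs plus one pure-noise control, 200 voxels. All
#' values can be overridden via a JSON config file (see [run_pipeline()]);
#' the CLI prints this structure with `--dump-config`.
#'
#' @param seed master seed; per-stage seeds are derived from it.
#' @return nested configuration list.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    design = design_config(),
    learning = list(learner_accuracy = c(children = 0.75, adults = 0.92),
                    criterion = 0.83, min_cycles = 2L, max_cycles = 4L),
    behavior = list(group_retention_means = default_retention_means(),
                    retention_sd = 10),
    patterns = unclass(planted_effects()),
    rsa = list(min_trials = 3L, min_pairs = 3L),
    plsc = list(n_perm = 1000L, n_boot = 1000L, z_threshold = 1.96,
                condition = "remote_long", index_type = "scene_reinstatement",
                behavior_delay = "remote_long")
  )
}

validate_config <- function(cfg) {
  need <- c("seed", "design", "learning", "behavior", "patterns", "rsa",
            "plsc")
  missing <- setdiff(need, names(cfg))
  assert_config(length(missing) == 0,
                "config is missing section(s): %s",
                paste(missing, collapse = ", "))
  assert_config(is.numeric(cfg$seed), "config$seed must be numeric")
  invisible(cfg)
}

read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- default_config()
  # shallow-merge user sections over defaults
  for (nm in names(cfg)) {
    if (is.list(base[[nm]]) && is.list(cfg[[nm]]))
      base[[nm]] <- utils::modifyList(base[[nm]], cfg[[nm]])
    else base[[nm]] <- cfg[[nm]]
  }
  # matrices arrive as data frames / nested lists from JSON; coerce
  base$behavior$group_retention_means <-
    as_group_matrix(base$behavior$group_retention_means,
                    default_retention_means())
  for (mn in c("rho", "gamma", "gamma_incorrect", "act_mean"))
    base$patterns[[mn]] <- as_group_matrix(base$patterns[[mn]],
                                           unclass(planted_effects())[[mn]])
  validate_config(base)
}

as_group_matrix <- function(x, template) {
  # JSON round-trips drop matrix dimnames; restore them from the template
  # (row/column order is fixed by the writer)
  m <- if (is.matrix(x)) x else as.matrix(as.data.frame(x))
  if (is.null(rownames(m))) rownames(m) <- rownames(template)
  if (is.null(colnames(m)) || all(grepl("^V[0-9]+$", colnames(m))))
    colnames(m) <- colnames(template)
  m[rownames(template), colnames(template), drop = FALSE]
}

planted_from_config <- function(p) {
  planted_effects(rho = p$rho, gamma = p$gamma,
                  gamma_incorrect = p$gamma_incorrect, a = p$a, b = p$b,
                  sigma = p$sigma, n_voxels = p$n_voxels, rois = p$rois,
                  control_rois = p$control_rois, act_mean = p$act_mean,
                  act_sd = p$act_sd)
}

log_msg <- function(..., logfile = NULL) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(...))
  message(msg)
  if (!is.null(logfile)) cat(msg, "\n", file = logfile, append = TRUE)
}

checksum_of <- function(paths) {
  paths <- paths[file.exists(paths)]
  setNames(as.vector(tools::md5sum(paths)), basename(paths))
}

require_inputs <- function(out_dir, files, stage, manifest) {
  paths <- file.path(out_dir, files)
  miss <- files[!file.exists(paths)]
  if (length(miss))
    config_error("stage '%s' needs missing input(s): %s (run the upstream stage first)",
                 stage, paste(miss, collapse = ", "))
  if (!is.null(manifest$checksums)) {
    rec <- manifest$checksums[files]
    now <- checksum_of(paths)
    stale <- names(rec)[!is.na(names(rec)) & !is.null(unlist(rec)) &
                          unlist(rec) != now[files]]
    if (length(stale) && any(!is.na(stale)))
      config_error("stage '%s': input(s) changed since the manifest was written: %s",
                   stage, paste(stale, collapse = ", "))
  }
  invisible(paths)
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order: `simulate` (cohort,
#' behavior and pattern archive), `rsa` (similarity indices), `stats`
#' (retention and index condition models, gist permutation tests), `plsc`
#' (brain-behavior model) and `report`. Each stage writes fixed-name TSV /
#' JSON outputs under `out_dir`; a `run_manifest.json` records the config
#' hash, per-stage seeds and timings, and output checksums, and guards
#' later stages against stale upstream files.
#'
#' @param config a config list from [default_config()] / [read_config()],
#'   or a path to a JSON config file.
#' @param stages character vector, subset of
#'   `c("simulate", "rsa", "stats", "plsc", "report")` or `"all"`.
#' @param out_dir output directory.
#' @return the run manifest, invisibly.
#' @export
run_pipeline <- function(config = default_config(), stages = "all",
                         out_dir = "reinstatr_out") {
  if (is.character(config) && length(config) == 1L)
    config <- read_config(config)
  validate_config(config)
  all_stages <- c("simulate", "rsa", "stats", "plsc", "report")
  if (identical(stages, "all")) stages <- all_stages
  assert_config(all(stages %in% all_stages), "unknown stage requested")
  stages <- all_stages[all_stages %in% stages]
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(out_dir, "run.log")

  manifest_path <- file.path(out_dir, "run_manifest.json")
  manifest <- if (file.exists(manifest_path))
    jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  else list(checksums = NULL)
  manifest$config_hash <- config_hash(config)
  manifest$package_version <-
    as.character(utils::packageVersion("reinstatr"))
  manifest$seeds <- list(master = config$seed,
                         simulate = derive_seed(config$seed, 10L),
                         plsc = derive_seed(config$seed, 40L))
  manifest$timings <- manifest$timings %||% list()

  archive_dir <- file.path(out_dir, "archive")

  for (stage in stages) {
    t0 <- Sys.time()
    log_msg("stage %s: start", stage, logfile = logfile)
    switch(stage,
      simulate = {
        catalog <- build_catalog()
        design <- build_design(catalog, config$design,
                               seed = derive_seed(config$seed, 10L))
        learning <- simulate_learning(
          design, learner_accuracy = unlist(config$learning$learner_accuracy),
          criterion = config$learning$criterion,
          min_cycles = config$learning$min_cycles,
          max_cycles = config$learning$max_cycles,
          seed = derive_seed(config$seed, 11L))
        behavior <- simulate_behavior(
          design, learning,
          group_retention_means = config$behavior$group_retention_means,
          retention_sd = config$behavior$retention_sd,
          seed = derive_seed(config$seed, 12L))
        planted <- planted_from_config(config$patterns)
        pset <- simulate_patterns(design, behavior, planted,
                                  seed = derive_seed(config$seed, 13L))
        write_pattern_archive(pset, archive_dir)
        data.table::fwrite(learning$sessions,
                           file.path(out_dir, "learning.tsv"), sep = "\t")
        data.table::fwrite(retention_rates(behavior),
                           file.path(out_dir, "behavior.tsv"), sep = "\t")
      },
      rsa = {
        require_inputs(out_dir, "archive/trials.tsv", stage, manifest)
        pset <- read_pattern_archive(archive_dir)
        idx <- compute_indices(pset)
        data.table::fwrite(idx, file.path(out_dir, "indices.tsv"),
                           sep = "\t")
      },
      stats = {
        require_inputs(out_dir, c("behavior.tsv", "indices.tsv"), stage,
                       manifest)
        behavior <- as.data.frame(
          data.table::fread(file.path(out_dir, "behavior.tsv")))
        idx <- as.data.frame(
          data.table::fread(file.path(out_dir, "indices.tsv")))
        res <- list()
        res$retention <- fit_condition_model(behavior, "retention",
                                             c("delay", "group"))
        rein <- idx[idx$index_type == "scene_reinstatement", ]
        res$reinstatement <- lapply(split(rein, rein$roi), function(d)
          fit_condition_model(d, "value", c("condition", "group")))
        gist <- idx[idx$index_type == "gist" & is.finite(idx$value), ]
        perm_rows <- list()
        for (roi in unique(gist$roi)) for (cond in unique(gist$condition))
          for (grp in unique(gist$group)) {
            v <- gist$value[gist$roi == roi & gist$condition == cond &
                              gist$group == grp]
            if (sum(is.finite(v)) < 3) next
            pr <- sign_flip_perm_test(v, n_perm = 1999L,
                                      seed = derive_seed(config$seed, 30L))
            perm_rows[[length(perm_rows) + 1L]] <- data.frame(
              roi = roi, condition = cond, group = grp, n = sum(is.finite(v)),
              mean = mean(v, na.rm = TRUE), t = pr$statistic, p = pr$p,
              stringsAsFactors = FALSE)
          }
        gist_tests <- do.call(rbind, perm_rows)
        if (!is.null(gist_tests)) gist_tests$p_fdr <- fdr_bh(gist_tests$p)
        stat_rows <- do.call(rbind, c(
          list(cbind(analysis = "retention", res$retention$effects)),
          lapply(names(res$reinstatement), function(r)
            cbind(analysis = paste0("reinstatement.", r),
                  res$reinstatement[[r]]$effects))))
        data.table::fwrite(stat_rows, file.path(out_dir, "stats.tsv"),
                           sep = "\t")
        jsonlite::write_json(
          list(df_method = "satterthwaite",
               seed = config$seed,
               retention = res$retention[c("effects", "contrasts",
                                           "varcomp")],
               reinstatement = lapply(res$reinstatement,
                                      function(m) m[c("effects", "contrasts",
                                                      "varcomp")]),
               gist_permutation = gist_tests),
          file.path(out_dir, "stats.json"), auto_unbox = TRUE, digits = NA,
          pretty = TRUE, force = TRUE)
      },
      plsc = {
        require_inputs(out_dir, c("behavior.tsv", "indices.tsv"), stage,
                       manifest)
        behavior <- as.data.frame(
          data.table::fread(file.path(out_dir, "behavior.tsv")))
        idx <- as.data.frame(
          data.table::fread(file.path(out_dir, "indices.tsv")))
        pc <- config$plsc
        sel <- idx[idx$index_type == pc$index_type &
                     idx$condition == pc$condition, ]
        wide <- stats::reshape(
          sel[, c("subject_id", "group", "roi", "value")],
          idvar = c("subject_id", "group"), timevar = "roi",
          direction = "wide")
        names(wide) <- sub("^value\\.", "", names(wide))
        beh <- behavior[behavior$delay == pc$behavior_delay,
                        c("subject_id", "retention")]
        wide <- merge(wide, beh, by = "subject_id")
        rois <- setdiff(names(wide), c("subject_id", "group", "retention"))
        tbl <- list(metrics = as.matrix(wide[, rois, drop = FALSE]),
                    behavior = wide$retention, group = wide$group,
                    subject_id = wide$subject_id)
        rownames(tbl$metrics) <- wide$subject_id
        data.table::fwrite(wide[, c("subject_id", "group", "retention",
                                    rois)],
                           file.path(out_dir, "roi_metrics.tsv"), sep = "\t")
        cfg <- plsc_config(pc$n_perm, pc$n_boot, pc$z_threshold,
                           seed = derive_seed(config$seed, 40L))
        model <- plsc_fit(tbl, cfg)
        perm <- plsc_perm_test(model)
        boot <- plsc_bootstrap_bsr(model)
        grp_cmp <- compare_brain_scores(model)
        data.table::fwrite(
          data.frame(subject_id = names(model$brain_scores),
                     group = model$group, brain_score = model$brain_scores),
          file.path(out_dir, "brain_scores.tsv"), sep = "\t")
        jsonlite::write_json(
          list(R = model$R, S = model$S, V = model$V, U = model$U,
               latent_r = model$latent_r, roi_r = model$roi_r,
               p_perm = perm$p, bsr = boot$bsr, robust = boot$robust,
               n = model$n, n_dropped = model$n_dropped,
               group_comparison = grp_cmp,
               config = cfg, condition = pc$condition,
               index_type = pc$index_type),
          file.path(out_dir, "plsc.json"), auto_unbox = TRUE, digits = NA,
          pretty = TRUE, force = TRUE)
      },
      report = {
        make_report(out_dir)
      })
    dt <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    manifest$timings[[stage]] <- round(dt, 2)
    log_msg("stage %s: done in %.1f s", stage, dt, logfile = logfile)
  }

  outs <- c("behavior.tsv", "learning.tsv", "indices.tsv", "stats.tsv",
            "stats.json", "roi_metrics.tsv", "brain_scores.tsv",
            "plsc.json", "archive/trials.tsv", "report.txt", "report.json")
  manifest$checksums <- as.list(checksum_of(file.path(out_dir, outs)))
  names(manifest$checksums) <- outs[file.exists(file.path(out_dir, outs))]
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(manifest)
}

#' Collate pipeline outputs into a summary report
#'
#' Produces `report.txt` (human-readable) and `report.json` from the stats
#' and PLSC outputs: per-ROI index means by group and condition, the
#' permutation/FDR table, PLSC saliences with robustness flags, and -- for
#' synthetic runs -- a recovered-vs-planted ordering check on the
#' reinstatement index.
#'
#' @param out_dir pipeline output directory.
#' @return list with the report contents, invisibly.
#' @export
make_report <- function(out_dir) {
  need <- c("indices.tsv", "stats.json")
  miss <- need[!file.exists(file.path(out_dir, need))]
  if (length(miss) == length(need))
    config_error("make_report: no stats outputs in '%s'", out_dir)
  warnings_out <- character(0)
  rep <- list()
  idx <- as.data.frame(data.table::fread(file.path(out_dir, "indices.tsv")))
  rein <- idx[idx$index_type == "scene_reinstatement", ]
  means <- aggregate(value ~ roi + group + condition, rein, mean,
                     na.rm = TRUE)
  rep$index_means <- means
  # recovered ordering vs planted ordering (synthetic runs)
  meta_path <- file.path(out_dir, "archive", "meta.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    rho <- as_group_matrix(meta$planted$rho,
                           unclass(planted_effects())$rho)
    ord <- c("recent", "remote_short", "remote_long")
    signal_rois <- unlist(meta$planted$rois)
    rec <- aggregate(value ~ condition, rein[rein$roi %in% signal_rois, ],
                     mean, na.rm = TRUE)
    recovered <- rec$value[match(ord, rec$condition)]
    planted_order <- order(-colMeans(rho[, ord, drop = FALSE]))
    rep$recovery <- list(
      planted_rho = colMeans(rho[, ord, drop = FALSE]),
      recovered_means = setNames(recovered, ord),
      ordering_matches = identical(order(-recovered), planted_order))
  }
  if (file.exists(file.path(out_dir, "stats.json")))
    rep$stats <- jsonlite::read_json(file.path(out_dir, "stats.json"),
                                     simplifyVector = TRUE)
  else warnings_out <- c(warnings_out, "stats.json missing: partial report")
  if (file.exists(file.path(out_dir, "plsc.json")))
    rep$plsc <- jsonlite::read_json(file.path(out_dir, "plsc.json"),
                                    simplifyVector = TRUE)
  else warnings_out <- c(warnings_out, "plsc.json missing: partial report")
  rep$warnings <- warnings_out

  txt <- c("reinstatr pipeline report", strrep("=", 25), "")
  if (!is.null(rep$recovery)) {
    txt <- c(txt, "Recovered vs planted reinstatement ordering:",
             sprintf("  planted rho:   %s",
                     paste(sprintf("%s=%.3f", names(rep$recovery$planted_rho),
                                   rep$recovery$planted_rho), collapse = ", ")),
             sprintf("  recovered dz:  %s",
                     paste(sprintf("%s=%.4f",
                                   names(rep$recovery$recovered_means),
                                   rep$recovery$recovered_means),
                           collapse = ", ")),
             sprintf("  ordering matches planted: %s",
                     rep$recovery$ordering_matches), "")
  }
  txt <- c(txt, "Mean corrected reinstatement by ROI/group/condition:",
           utils::capture.output(print(means, row.names = FALSE)), "")
  if (!is.null(rep$plsc)) {
    txt <- c(txt, sprintf("PLSC (%s, %s): S=%.4f, latent r=%.3f, p_perm=%.4g",
                          rep$plsc$index_type, rep$plsc$condition,
                          rep$plsc$S, rep$plsc$latent_r, rep$plsc$p_perm),
             "  saliences (robust flagged *):",
             sprintf("    %s: V=%.3f BSR=%.2f%s", names(rep$plsc$V),
                     unlist(rep$plsc$V), unlist(rep$plsc$bsr),
                     ifelse(unlist(rep$plsc$robust), " *", "")), "")
  }
  if (length(warnings_out))
    txt <- c(txt, "WARNINGS:", paste(" -", warnings_out))
  writeLines(txt, file.path(out_dir, "report.txt"))
  jsonlite::write_json(rep, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(rep)
}
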