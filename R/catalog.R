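#' Default category labels for the object-location association design
#'
#' Seven scene categories used by the stimulus catalog (field, water,
#' housing, forest, infrastructure, indoor, farming).
#' @export
default_categories <- function() {
  c("field", "water", "housing", "forest", "infrastructure", "indoor",
    "farming")
}

#' Build a stimulus catalog of themed object-scene pairs
#'
#' Themes are assigned to categories round-robin, so category sizes (counted
#' in themes) differ by at most one. Each theme contributes
#' `exemplars_per_theme` scenes and as many thematically congruent objects;
#' scene and object form one retrievable item.
#'
#' @param n_themes number of themes (default 60).
#' @param exemplars_per_theme scenes/objects per theme (default 4).
#' @param categories character vector of category labels (default the seven
#'   standard labels).
#' @return a `stimulus_catalog` list with `themes`, `scenes`, `objects`,
#'   `exemplars_per_theme`.
#' @export
build_catalog <- function(n_themes = 60L, exemplars_per_theme = 4L,
                          categories = default_categories()) {
  assert_config(length(categories) >= 1L && !anyNA(categories),
                "category list must be non-empty")
  assert_config(n_themes >= 1L, "n_themes must be >= 1")
  assert_config(exemplars_per_theme >= 1L, "exemplars_per_theme must be >= 1")
  assert_config(!anyDuplicated(categories), "category labels must be unique")

  themes <- sprintf("theme%03d", seq_len(n_themes))
  theme_cat <- categories[((seq_len(n_themes) - 1L) %% length(categories)) + 1L]

  idx <- expand.grid(exemplar = seq_len(exemplars_per_theme),
                     theme_i = seq_len(n_themes))
  scenes <- data.frame(
    scene_id = sprintf("scene_%s_e%d", themes[idx$theme_i], idx$exemplar),
    theme = themes[idx$theme_i],
    category = theme_cat[idx$theme_i],
    stringsAsFactors = FALSE
  )
  objects <- data.frame(
    object_id = sprintf("object_%s_e%d", themes[idx$theme_i], idx$exemplar),
    theme = themes[idx$theme_i],
    stringsAsFactors = FALSE
  )
  structure(list(themes = themes,
                 theme_category = setNames(theme_cat, themes),
                 scenes = scenes, objects = objects,
                 exemplars_per_theme = as.integer(exemplars_per_theme),
                 categories = categories),
            class = "stimulus_catalog")
}

#' @export
print.stimulus_catalog <- function(x, ...) {
  cat(sprintf("stimulus_catalog: %d themes x %d exemplars = %d scenes/%d objects, %d categories\n",
              length(x$themes), x$exemplars_per_theme, nrow(x$scenes),
              nrow(x$objects), length(x$categories)))
  invisible(x)
}

#' Default design parameters
#'
#' Three scanning sessions' worth of structure: two retrieval sessions
#' (short delay after one night, long delay after two weeks), each with
#' `runs_per_session` runs of `recent_per_run` recently learned and
#' `remote_per_run` remotely learned items, all drawn without reuse from a
#' subject's 120-item set.
#' @param n_children,n_adults group sizes.
#' @param runs_per_session runs per retrieval session (default 3).
#' @param recent_per_run,remote_per_run trials per run by item type
#'   (default 10 each).
#' @return named list of design parameters.
#' @export
design_config <- function(n_children = 20L, n_adults = 20L,
                          runs_per_session = 3L, recent_per_run = 10L,
                          remote_per_run = 10L) {
  list(n_children = as.integer(n_children), n_adults = as.integer(n_adults),
       runs_per_session = as.integer(runs_per_session),
       recent_per_run = as.integer(recent_per_run),
       remote_per_run = as.integer(remote_per_run))
}

# split item indices into two category-balanced halves
split_balanced <- function(items, categories) {
  a <- integer(0)
  for (cat in unique(categories)) {
    in_cat <- items[categories == cat]
    take <- floor(length(in_cat) / 2)
    # alternate the odd leftover across categories via the running imbalance
    if (length(in_cat) %% 2 == 1 && length(a) * 2 < length(items)) take <- take + 1L
    if (take > 0) a <- c(a, sample(in_cat, take))
  }
  a
}

# order trials so that no more than two consecutive trials share a category
order_no_category_runs <- function(categories, max_run = 2L, tries = 200L) {
  n <- length(categories)
  ok <- function(ord) {
    r <- rle(categories[ord])
    all(r$lengths <= max_run)
  }
  for (i in seq_len(tries)) {
    ord <- sample.int(n)
    if (ok(ord)) return(ord)
  }
  # greedy fallback: always pick an item that does not extend a run of max_run
  remaining <- seq_len(n)
  ord <- integer(0)
  while (length(remaining) > 0) {
    last <- if (length(ord) >= max_run)
      categories[utils::tail(ord, max_run)] else character(0)
    blocked <- length(last) == max_run && length(unique(last)) == 1L
    cand <- if (blocked) remaining[categories[remaining] != last[1]] else remaining
    if (length(cand) == 0) cand <- remaining  # degenerate catalog; accept run
    pick <- if (length(cand) == 1L) cand else sample(cand, 1L)
    ord <- c(ord, pick)
    remaining <- setdiff(remaining, pick)
  }
  ord
}

#' Build a per-subject experimental design
#'
#' Each subject receives a 120-item subset of the catalog: 60 items encoded
#' on day 0 (the remote pool, split category-balanced into the short- and
#' long-delay remote sets), 30 new items learned on day 1 and 30 on day 14
#' (the recent sets). Retrieval trials are laid out run by run with recent
#' and remote items interleaved and no more than two consecutive trials of
#' the same scene category. Trial and run indices are 0-based.
#'
#' @param catalog a `stimulus_catalog`.
#' @param config list from [design_config()].
#' @param seed integer seed.
#' @return an `experimental_design` list with `subjects` and `trials` data
#'   frames plus `encoded` (items encoded per subject/day) and `config`.
#' @export
build_design <- function(catalog, config = design_config(), seed = 1L) {
  stopifnot(inherits(catalog, "stimulus_catalog"))
  assert_config(config$runs_per_session >= 1L, "runs_per_session must be >= 1")
  assert_config(config$recent_per_run >= 1L && config$remote_per_run >= 1L,
                "recent_per_run and remote_per_run must be >= 1")
  per_session_recent <- config$runs_per_session * config$recent_per_run
  per_session_remote <- config$runs_per_session * config$remote_per_run
  need <- 2L * per_session_recent + 2L * per_session_remote
  assert_config(nrow(catalog$scenes) >= need,
                "catalog too small: %d items needed, %d available",
                need, nrow(catalog$scenes))

  subjects <- data.frame(
    subject_id = c(sprintf("ch%03d", seq_len(config$n_children)),
                   sprintf("ya%03d", seq_len(config$n_adults))),
    group = rep(c("children", "adults"),
                c(config$n_children, config$n_adults)),
    stringsAsFactors = FALSE
  )

  with_seed(seed, {
    trials_list <- vector("list", nrow(subjects))
    encoded_list <- vector("list", nrow(subjects))
    for (si in seq_len(nrow(subjects))) {
      sid <- subjects$subject_id[si]
      pool <- sample.int(nrow(catalog$scenes), need)
      cat_of <- catalog$scenes$category[pool]
      remote_pool <- pool[seq_len(2L * per_session_remote)]
      recent_d1 <- pool[2L * per_session_remote + seq_len(per_session_recent)]
      recent_d14 <- pool[2L * per_session_remote + per_session_recent +
                           seq_len(per_session_recent)]
      rp_cat <- catalog$scenes$category[remote_pool]
      rd1_idx <- split_balanced(seq_along(remote_pool), rp_cat)
      # guard: exact half split regardless of category parity bookkeeping
      if (length(rd1_idx) > per_session_remote)
        rd1_idx <- rd1_idx[seq_len(per_session_remote)]
      if (length(rd1_idx) < per_session_remote)
        rd1_idx <- c(rd1_idx, sample(setdiff(seq_along(remote_pool), rd1_idx),
                                     per_session_remote - length(rd1_idx)))
      remote_d1 <- remote_pool[rd1_idx]
      remote_d14 <- remote_pool[-rd1_idx]

      encoded_list[[si]] <- data.frame(
        subject_id = sid,
        session = rep(c("day0", "day1", "day14"),
                      c(length(remote_pool), length(recent_d1),
                        length(recent_d14))),
        item_id = catalog$scenes$scene_id[c(remote_pool, recent_d1, recent_d14)],
        stringsAsFactors = FALSE
      )

      mk_session <- function(session, recent_items, remote_items, delay_remote) {
        runs <- config$runs_per_session
        # items arrive pre-shuffled; consecutive blocks become the runs, so
        # every run holds exactly recent_per_run + remote_per_run trials
        df <- data.frame(
          subject_id = sid, session = session,
          run = c(rep(seq_len(runs) - 1L, each = config$recent_per_run),
                  rep(seq_len(runs) - 1L, each = config$remote_per_run)),
          item_idx = c(recent_items, remote_items),
          item_type = rep(c("recent", "remote"),
                          c(length(recent_items), length(remote_items))),
          stringsAsFactors = FALSE
        )
        out <- do.call(rbind, lapply(seq_len(runs) - 1L, function(r) {
          sub <- df[df$run == r, ]
          ord <- order_no_category_runs(catalog$scenes$category[sub$item_idx])
          sub <- sub[ord, ]
          sub$trial <- seq_len(nrow(sub)) - 1L
          sub
        }))
        out$category <- catalog$scenes$category[out$item_idx]
        out$item_id <- catalog$scenes$scene_id[out$item_idx]
        out$delay <- ifelse(out$item_type == "recent", "recent", delay_remote)
        out$item_idx <- NULL
        out
      }
      trials_list[[si]] <- rbind(
        mk_session("day1", sample(recent_d1), sample(remote_d1), "remote_short"),
        mk_session("day14", sample(recent_d14), sample(remote_d14), "remote_long")
      )
    }
    trials <- do.call(rbind, trials_list)
    rownames(trials) <- NULL
    trials <- merge(trials, subjects, by = "subject_id", sort = FALSE)
    trials <- trials[order(match(trials$subject_id, subjects$subject_id),
                           trials$session, trials$run, trials$trial), ]
    rownames(trials) <- NULL
    trials$trial_uid <- sprintf("%s_%s_r%d_t%02d", trials$subject_id,
                                trials$session, trials$run, trials$trial)
    structure(list(subjects = subjects, trials = trials,
                   encoded = do.call(rbind, encoded_list),
                   config = config, seed = seed),
              class = "experimental_design")
  })
}

#' @export
print.experimental_design <- function(x, ...) {
  cat(sprintf("experimental_design: %d subjects (%d children, %d adults), %d retrieval trials\n",
              nrow(x$subjects), sum(x$subjects$group == "children"),
              sum(x$subjects$group == "adults"), nrow(x$trials)))
  invisible(x)
}
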