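#' Simulate the adaptive learning-to-criterion phase
#'
#' Each encoding day, a subject cycles through 3AFC retrieval-encoding
#' rounds. Per cycle, each item is answered correctly with the subject's
#' per-cycle success probability; cycling halts at the first cycle whose
#' accuracy reaches `criterion` once `min_cycles` have run, and never
#' exceeds `max_cycles`. Items correct on the final cycle form that day's
#' `learned_items`.
#'
#' @param design an `experimental_design`.
#' @param learner_accuracy success probability per item and cycle. A scalar,
#'   or a named vector with entries `children`/`adults`.
#' @param criterion halt threshold on cycle accuracy, in (0, 1] (default
#'   0.83).
#' @param min_cycles,max_cycles cycle bounds (defaults 2 and 4).
#' @param seed integer seed.
#' @return a `learning_result`: data frame `sessions` (subject_id, session,
#'   cycles_executed, final_accuracy) and list `learned_items` keyed by
#'   `subject_id.session`.
#' @export
simulate_learning <- function(design, learner_accuracy = c(children = 0.75,
                                                           adults = 0.92),
                              criterion = 0.83, min_cycles = 2L,
                              max_cycles = 4L, seed = 1L) {
  stopifnot(inherits(design, "experimental_design"))
  assert_config(criterion > 0 && criterion <= 1,
                "criterion must lie in (0, 1]")
  assert_config(min_cycles <= max_cycles && min_cycles >= 1L,
                "need 1 <= min_cycles <= max_cycles")
  assert_config(all(learner_accuracy >= 0 & learner_accuracy <= 1),
                "learner_accuracy must lie in [0, 1]")

  acc_of <- function(group) {
    if (length(learner_accuracy) == 1L) unname(learner_accuracy)
    else {
      assert_config(group %in% names(learner_accuracy),
                    "learner_accuracy lacks an entry for group '%s'", group)
      unname(learner_accuracy[[group]])
    }
  }

  with_seed(seed, {
    rows <- list()
    learned <- list()
    cyc <- list()
    for (si in seq_len(nrow(design$subjects))) {
      sid <- design$subjects$subject_id[si]
      p <- acc_of(design$subjects$group[si])
      enc <- design$encoded[design$encoded$subject_id == sid, ]
      for (session in unique(enc$session)) {
        items <- enc$item_id[enc$session == session]
        cycles <- 0L
        acc_trace <- numeric(0)
        correct <- logical(length(items))
        repeat {
          cycles <- cycles + 1L
          correct <- stats::runif(length(items)) < p
          acc <- mean(correct)
          acc_trace <- c(acc_trace, acc)
          if (cycles >= max_cycles) break
          if (cycles >= min_cycles && acc >= criterion) break
        }
        key <- paste(sid, session, sep = ".")
        learned[[key]] <- items[correct]
        cyc[[key]] <- acc_trace
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = sid, group = design$subjects$group[si],
          session = session, cycles_executed = cycles,
          final_accuracy = acc_trace[length(acc_trace)],
          stringsAsFactors = FALSE)
      }
    }
    structure(list(sessions = do.call(rbind, rows),
                   learned_items = learned, cycle_accuracy = cyc,
                   criterion = criterion, min_cycles = as.integer(min_cycles),
                   max_cycles = as.integer(max_cycles), seed = seed),
              class = "learning_result")
  })
}

#' Default group-by-delay retention means (percent correct)
#'
#' Retention of initially learned items: near-ceiling for recent and
#' short-delay remote items with a marked long-delay drop, children roughly
#' 11-15 points below adults throughout.
#' @export
default_retention_means <- function() {
  rbind(children = c(recent = 80, remote_short = 78, remote_long = 55),
        adults   = c(recent = 94, remote_short = 93, remote_long = 75))
}

#' Simulate trial-level retrieval behavior
#'
#' Each subject draws one retention rate per delay condition around the
#' group mean (Normal, clipped to \[0, 100\]); retrieval correctness is
#' Bernoulli at that rate for items learned on their encoding day, and at
#' 3AFC chance (1/3) for unlearned items. Reaction times are shifted
#' lognormal plumbing. Retention rates are later computed over learned items
#' only.
#'
#' @param design an `experimental_design`.
#' @param learning a `learning_result`.
#' @param group_retention_means matrix \[group x delay\] of percent-correct
#'   means, rows `children`/`adults`, columns `recent`, `remote_short`,
#'   `remote_long`.
#' @param retention_sd between-subject SD of retention, percent points.
#' @param rt_meanlog,rt_sdlog,rt_shift shifted-lognormal RT parameters
#'   (seconds).
#' @param seed integer seed.
#' @return a `behavioral_table` data frame: one row per retrieval trial with
#'   `correct`, `rt`, `learned` and the design columns; attribute
#'   `subject_rates` holds the per-subject planted retention rates.
#' @export
simulate_behavior <- function(design, learning,
                              group_retention_means = default_retention_means(),
                              retention_sd = 10,
                              rt_meanlog = 0.2, rt_sdlog = 0.45,
                              rt_shift = 0.8, seed = 1L) {
  stopifnot(inherits(design, "experimental_design"),
            inherits(learning, "learning_result"))
  assert_config(all(group_retention_means >= 0 & group_retention_means <= 100),
                "retention means must lie in [0, 100]")
  assert_config(retention_sd >= 0, "retention_sd must be >= 0")

  trials <- design$trials
  # encoding day of each item: remote items were encoded on day0
  enc_day <- ifelse(trials$item_type == "remote", "day0", trials$session)
  key <- paste(trials$subject_id, enc_day, sep = ".")
  trials$learned <- mapply(function(k, item)
    item %in% (learning$learned_items[[k]] %||% character(0)),
    key, trials$item_id, USE.NAMES = FALSE)

  with_seed(seed, {
    subs <- design$subjects
    delays <- colnames(group_retention_means)
    rates <- matrix(NA_real_, nrow(subs), length(delays),
                    dimnames = list(subs$subject_id, delays))
    for (si in seq_len(nrow(subs))) {
      mu <- group_retention_means[subs$group[si], ]
      rates[si, ] <- pmin(100, pmax(0, stats::rnorm(length(delays), mu,
                                                    retention_sd)))
    }
    p <- rates[cbind(trials$subject_id, trials$delay)] / 100
    p[!trials$learned] <- 1 / 3
    trials$correct <- as.integer(stats::runif(nrow(trials)) < p)
    trials$rt <- rt_shift + stats::rlnorm(nrow(trials), rt_meanlog, rt_sdlog)
    attr(trials, "subject_rates") <- rates
    class(trials) <- c("behavioral_table", class(trials))
    trials
  })
}

#' Retention rates over initially learned items
#'
#' Percent correct per subject x delay condition, restricted to trials whose
#' item was learned (correct at the final learning cycle) on its encoding
#' day.
#'
#' @param behavior a `behavioral_table`.
#' @return data frame subject_id, group, delay, n_items, retention (percent).
#' @export
retention_rates <- function(behavior) {
  b <- behavior[behavior$learned, ]
  agg <- aggregate(correct ~ subject_id + group + delay, data = b,
                   FUN = function(x) c(n = length(x), rate = 100 * mean(x)))
  out <- data.frame(subject_id = agg$subject_id, group = agg$group,
                    delay = agg$delay,
                    n_items = agg$correct[, "n"],
                    retention = agg$correct[, "rate"],
                    stringsAsFactors = FALSE)
  out[order(out$subject_id, out$delay), ]
}
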