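test_that("catalog reproduces the stated design counts and balance", {
  cat240 <- build_catalog(60, 4, default_categories())
  expect_equal(nrow(cat240$scenes), 240)
  expect_equal(nrow(cat240$objects), 240)
  expect_equal(length(unique(cat240$scenes$category)), 7)
  expect_false(anyDuplicated(cat240$scenes$scene_id) > 0)
  # round-robin: 60 themes over 7 categories -> four categories of 9, three of 8
  sizes <- table(cat240$theme_category)
  expect_equal(sort(as.vector(sizes)), c(8, 8, 8, 9, 9, 9, 9))
  # identity case
  cat1 <- build_catalog(1, 1, "only")
  expect_equal(nrow(cat1$scenes), 1)
  expect_error(build_catalog(60, 4, character(0)),
               class = "reinstatr_config_error")
})

test_that("design yields 60 trials per scanning session with balanced runs and no item reuse", {
  cohort <- tiny_cohort()
  tr <- cohort$design$trials
  for (sid in cohort$design$subjects$subject_id) {
    for (ses in c("day1", "day14")) {
      s <- tr[tr$subject_id == sid & tr$session == ses, ]
      expect_equal(nrow(s), 60)
      counts <- table(s$run, s$item_type)
      expect_true(all(counts == 10))  # every run: 10 recent + 10 remote
    }
    # items never repeat across retrieval sessions
    expect_false(anyDuplicated(tr$item_id[tr$subject_id == sid]) > 0)
    # no more than 2 consecutive same-category trials within a run
    for (ses in c("day1", "day14")) for (r in 0:2) {
      s <- tr[tr$subject_id == sid & tr$session == ses & tr$run == r, ]
      expect_true(all(rle(s$category[order(s$trial)])$lengths <= 2))
    }
  }
  expect_true(all(tr$delay[tr$item_type == "recent"] == "recent"))
  expect_equal(unique(tr$delay[tr$session == "day1" &
                                 tr$item_type == "remote"]), "remote_short")
  expect_error(build_design(cohort$catalog,
                            design_config(runs_per_session = 0)),
               class = "reinstatr_config_error")
  expect_error(build_design(build_catalog(5, 1), design_config()),
               class = "reinstatr_config_error")
})

test_that("learning cycles respect the 2-4 bounds and the inclusive criterion", {
  cohort <- tiny_cohort()
  d <- cohort$design
  # perfect learner stops at the minimum of two cycles
  lr <- simulate_learning(d, learner_accuracy = 1, seed = 1)
  expect_true(all(lr$sessions$cycles_executed == 2))
  # chance-level learner always runs to the maximum of four
  lr <- simulate_learning(d, learner_accuracy = 0.5, seed = 1)
  expect_true(all(lr$sessions$cycles_executed == 4))
  # accuracy exactly at the criterion stops ("at least 83%"): force a
  # deterministic accuracy equal to the criterion via criterion = 1
  lr <- simulate_learning(d, learner_accuracy = 1, criterion = 1, seed = 1)
  expect_true(all(lr$sessions$cycles_executed == 2))
  expect_error(simulate_learning(d, criterion = 0),
               class = "reinstatr_config_error")
  # bounds hold for stochastic learners too, and cycling stops at the first
  # criterion crossing
  lr <- simulate_learning(d, seed = 5)
  expect_true(all(lr$sessions$cycles_executed >= 2 &
                    lr$sessions$cycles_executed <= 4))
})

test_that("behavior honors planted retention structure", {
  cohort <- tiny_cohort()
  # zero noise: every subject's retention rate is centered on the group mean
  bh0 <- simulate_behavior(cohort$design, cohort$learning,
                           retention_sd = 0, seed = 9)
  rates <- attr(bh0, "subject_rates")
  mns <- default_retention_means()
  for (sid in rownames(rates)) {
    grp <- cohort$design$subjects$group[
      cohort$design$subjects$subject_id == sid]
    expect_equal(unname(rates[sid, colnames(mns)]), unname(mns[grp, ]))
  }
  # retention is computed over learned items only
  rr <- retention_rates(bh0)
  expect_true(all(rr$retention >= 0 & rr$retention <= 100))
  # determinism
  bh_a <- simulate_behavior(cohort$design, cohort$learning, seed = 42)
  bh_b <- simulate_behavior(cohort$design, cohort$learning, seed = 42)
  expect_identical(bh_a, bh_b)
  expect_error(
    simulate_behavior(cohort$design, cohort$learning,
                      group_retention_means = default_retention_means() + 50),
    class = "reinstatr_config_error")
})

test_that("group retention ordering is recovered across seeds", {
  # children means below adults at every delay -> sample group means
  # ordered accordingly (scaled-down Monte-Carlo: 25 seeds, n = 8/group)
  catalog <- build_catalog()
  design <- build_design(catalog, design_config(8, 8), seed = 1)
  learning <- simulate_learning(design, seed = 1)
  ok <- vapply(1:25, function(s) {
    bh <- simulate_behavior(design, learning, seed = s)
    rr <- retention_rates(bh)
    m <- tapply(rr$retention, list(rr$group, rr$delay), mean)
    all(m["children", ] < m["adults", ])
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("pattern generator is deterministic and matches its closed form", {
  catalog <- build_catalog()
  design <- build_design(catalog, design_config(2, 2), seed = 3)
  learning <- simulate_learning(design, seed = 3)
  behavior <- simulate_behavior(design, learning, seed = 3)
  pl <- planted_effects(n_voxels = 60L, rois = "HCa", control_rois = "WM")
  a <- simulate_patterns(design, behavior, pl, seed = 7)
  b <- simulate_patterns(design, behavior, pl, seed = 7)
  expect_identical(a$patterns, b$patterns)
  expect_error(planted_effects(n_voxels = 5), class = "reinstatr_config_error")
  expect_error(planted_effects(sigma = 0), class = "reinstatr_config_error")

  # noise-free limit: rho = a, gamma = b = 0 -> within-trial fixation-scene
  # correlation -> 1
  pl0 <- planted_effects(
    rho = rbind(children = c(recent = 1, remote_short = 1, remote_long = 1),
                adults = c(recent = 1, remote_short = 1, remote_long = 1)),
    gamma = rbind(children = c(recent = 0, remote_short = 0, remote_long = 0),
                  adults = c(recent = 0, remote_short = 0, remote_long = 0)),
    a = 1, b = 0, sigma = 1e-8, n_voxels = 60L, rois = "HCa",
    control_rois = "WM")
  ps0 <- simulate_patterns(design, behavior, pl0, seed = 7,
                           windows = c("fixation", "scene"))
  sid <- design$subjects$subject_id[1]
  tr <- ps0$trials[ps0$trials$subject_id == sid & ps0$trials$correct == 1, ]
  fx <- ps0$patterns[[sid]]$HCa$fixation[tr$trial_uid, ]
  sc <- ps0$patterns[[sid]]$HCa$scene[tr$trial_uid, ]
  rs <- vapply(seq_len(nrow(tr)), function(i) cor(fx[i, ], sc[i, ]),
               numeric(1))
  expect_true(all(rs > 0.999))

  # closed form: rho = 0.6, a = 1, b = gamma = 0, sigma = 1 ->
  # E[r] = rho*a / sqrt((rho^2 + sigma^2) (a^2 + sigma^2))
  # (scaled-down Monte-Carlo: 20 seeds x 4 subjects x 120 trials)
  plc <- planted_effects(
    rho = matrix(0.6, 2, 3, dimnames = dimnames(pl0$rho)),
    gamma = matrix(0, 2, 3, dimnames = dimnames(pl0$rho)),
    a = 1, b = 0, sigma = 1, n_voxels = 200L, rois = "HCa",
    control_rois = character(0))
  expected <- 0.6 / sqrt((0.36 + 1) * (1 + 1))
  rbar <- vapply(1:20, function(s) {
    ps <- simulate_patterns(design, behavior, plc, seed = s,
                            windows = c("fixation", "scene"))
    mean(vapply(design$subjects$subject_id, function(sid) {
      tr <- ps$trials[ps$trials$subject_id == sid & ps$trials$correct == 1, ]
      fx <- ps$patterns[[sid]]$HCa$fixation[tr$trial_uid, ]
      sc <- ps$patterns[[sid]]$HCa$scene[tr$trial_uid, ]
      mean(vapply(seq_len(nrow(tr)), function(i) cor(fx[i, ], sc[i, ]),
                  numeric(1)))
    }, numeric(1)))
  }, numeric(1))
  expect_lt(abs(mean(rbar) - expected), 0.01)
})

test_that("roi metric generator has the stated latent structure", {
  # noiseless single ROI with salience 1: behavior and metric rank-identical
  m <- simulate_roi_metrics(40L, saliences = c(roi = 1), latent_strength = 1,
                            noise = 0, seed = 2)
  expect_equal(cor(m$metrics[, 1], m$behavior, method = "spearman"), 1)
  # latent_strength = 0: no association at large n
  m0 <- simulate_roi_metrics(2000L, saliences = c(a = 1, b = 0.5),
                             latent_strength = 0, seed = 3)
  expect_lt(max(abs(cor(m0$metrics, m0$behavior,
                        method = "spearman"))), 0.06)
  expect_error(simulate_roi_metrics(40L, numeric(0)),
               class = "reinstatr_config_error")
  expect_error(simulate_roi_metrics(40L, 1, latent_strength = 1.2),
               class = "reinstatr_config_error")
})

test_that("pattern archive round-trips through disk", {
  cohort <- tiny_cohort(n_children = 2, n_adults = 2,
                        planted = planted_effects(
                          n_voxels = 12L, rois = "HCa", control_rois = "WM"))
  dir <- withr::local_tempdir()
  write_pattern_archive(cohort$pset, dir)
  expect_true(file.exists(file.path(dir, "trials.tsv")))
  expect_true(file.exists(file.path(dir, "meta.json")))
  back <- read_pattern_archive(dir)
  sid <- names(cohort$pset$patterns)[1]
  expect_equal(back$patterns[[sid]]$HCa$fixation,
               cohort$pset$patterns[[sid]]$HCa$fixation, tolerance = 1e-12)
  expect_equal(nrow(back$trials), nrow(cohort$pset$trials))
  expect_equal(back$mean_activation, cohort$pset$mean_activation,
               tolerance = 1e-12)
})
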