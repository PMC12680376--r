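test_that("fisher_z matches arctanh and rejects the boundary", {
  expect_identical(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.549306144334055, tolerance = 1e-12)
  expect_equal(fisher_z(c(-0.3, 0.9)), atanh(c(-0.3, 0.9)))
  expect_error(fisher_z(1), class = "reinstatr_domain_error")
  expect_error(fisher_z(-1), class = "reinstatr_domain_error")
})

test_that("pattern_similarity is plain Pearson with boundary flagging", {
  p1 <- c(1, 2, 3, 4)
  expect_equal(pattern_similarity(p1, p1)$r, 1)
  expect_true(pattern_similarity(p1, p1)$boundary)
  expect_true(pattern_similarity(p1, -p1)$boundary)
  expect_equal(pattern_similarity(p1, -p1)$r, -1)
  # hand-computed covariance / SD oracle
  p2 <- c(1, 3, 2, 5)
  r_hand <- sum((p1 - mean(p1)) * (p2 - mean(p2))) /
    sqrt(sum((p1 - mean(p1))^2) * sum((p2 - mean(p2))^2))
  sv <- pattern_similarity(p1, p2)
  expect_equal(sv$r, r_hand, tolerance = 1e-12)
  expect_equal(sv$z, atanh(r_hand), tolerance = 1e-12)
  expect_error(pattern_similarity(c(1, 1, 1), c(1, 2, 3)),
               class = "reinstatr_degenerate_error")
})

test_that("corrected reinstatement equals the exhaustive-pair oracle", {
  # 3 correct trials, 4 voxels, one run
  set.seed(5)
  fix <- matrix(c(1, 2, 3, 4,
                  2, 1, 4, 3,
                  0, 1, 0, 2), 3, 4, byrow = TRUE)
  sc <- matrix(c(1, 2, 2, 5,
                 3, 1, 4, 2,
                 1, 1, 0, 3), 3, 4, byrow = TRUE)
  ps <- manual_pset(fix, scene = sc, run = rep(0L, 3),
                    category = c("field", "water", "field"))
  rec <- scene_reinstatement_index(ps, "ROI1", "remote_short")
  orc <- oracle_reinstatement(fix, sc, rep(0L, 3), rep(1L, 3))
  expect_equal(rec$term_specific, orc$specific, tolerance = 1e-10)
  expect_equal(rec$term_baseline, orc$baseline, tolerance = 1e-10)
  expect_equal(rec$value, orc$value, tolerance = 1e-10)
  expect_equal(rec$n_items, 3L)
  expect_equal(rec$n_pairs, 6L)  # ordered pairs

  # multi-run, mixed-correctness fixture with random patterns
  n <- 10; nv <- 8
  fix <- matrix(rnorm(n * nv), n, nv)
  sc <- matrix(rnorm(n * nv), n, nv)
  run <- rep(0:1, each = 5)
  correct <- c(1, 1, 1, 0, 1, 1, 0, 1, 1, 1)
  ps <- manual_pset(fix, scene = sc, run = run,
                    category = rep(c("field", "water"), 5),
                    correct = correct)
  rec <- scene_reinstatement_index(ps, "ROI1", "remote_short")
  orc <- oracle_reinstatement(fix, sc, run, correct)
  expect_equal(rec$value, orc$value, tolerance = 1e-10)

  # object-window control uses the object patterns
  ob <- matrix(rnorm(n * nv), n, nv)
  ps2 <- manual_pset(fix, scene = sc, object = ob, run = run,
                     category = rep(c("field", "water"), 5),
                     correct = correct)
  rec_o <- scene_reinstatement_index(ps2, "ROI1", "remote_short",
                                     event = "object")
  orc_o <- oracle_reinstatement(fix, ob, run, correct)
  expect_equal(rec_o$value, orc_o$value, tolerance = 1e-10)
  expect_equal(rec_o$index_type, "object_control")

  # below the minimum trial count: NA record with reason, never dropped
  ps3 <- manual_pset(fix[1:2, ], scene = sc[1:2, ], run = rep(0L, 2),
                     category = c("field", "water"))
  rec3 <- scene_reinstatement_index(ps3, "ROI1", "remote_short")
  expect_equal(nrow(rec3), 1L)
  expect_true(is.na(rec3$value))
  expect_match(rec3$reason, "correct trials")
})

test_that("set-based term is invariant to trial relabeling", {
  set.seed(8)
  n <- 8; nv <- 10
  fix <- matrix(rnorm(n * nv), n, nv)
  sc <- matrix(rnorm(n * nv), n, nv)
  run <- rep(0L, n)
  cats <- rep(c("field", "water"), 4)
  ps <- manual_pset(fix, scene = sc, run = run, category = cats)
  rec <- scene_reinstatement_index(ps, "ROI1", "remote_short")
  perm <- sample(n)
  ps_p <- manual_pset(fix[perm, ], scene = sc[perm, ], run = run,
                      category = cats[perm])
  rec_p <- scene_reinstatement_index(ps_p, "ROI1", "remote_short")
  expect_equal(rec$term_baseline, rec_p$term_baseline, tolerance = 1e-12)
  expect_equal(rec$value, rec_p$value, tolerance = 1e-12)
})

test_that("gist index equals the exhaustive C(n,2) oracle", {
  # 6 trials in 2 categories, single run: cross-run block empty
  set.seed(6)
  fix <- matrix(rnorm(6 * 8), 6, 8)
  cats <- rep(c("field", "water"), each = 3)
  ps <- manual_pset(fix, run = rep(0L, 6), category = cats)
  rec <- gist_index(ps, "ROI1", "remote_short")
  orc <- oracle_gist(fix, rep(0L, 6), cats)
  expect_equal(rec$term_specific, orc$within, tolerance = 1e-10)
  expect_equal(rec$term_baseline, orc$between, tolerance = 1e-10)
  expect_equal(rec$value, orc$value, tolerance = 1e-10)
  expect_equal(rec$n_pairs, choose(6, 2))

  # two runs: within-run and cross-run blocks standardized separately
  set.seed(7)
  fix <- matrix(rnorm(10 * 8), 10, 8)
  run <- rep(0:1, each = 5)
  cats <- rep(c("field", "water"), 5)
  ps <- manual_pset(fix, run = run, category = cats)
  rec <- gist_index(ps, "ROI1", "remote_short")
  orc <- oracle_gist(fix, run, cats)
  expect_equal(rec$value, orc$value, tolerance = 1e-10)

  # pair similarity is order-invariant: permuting trials leaves it unchanged
  perm <- sample(10)
  ps_p <- manual_pset(fix[perm, ], run = run[perm], category = cats[perm])
  rec_p <- gist_index(ps_p, "ROI1", "remote_short")
  expect_equal(rec_p$value, rec$value, tolerance = 1e-12)

  # single category: undefined between term -> NA record with reason
  ps1 <- manual_pset(fix, run = run, category = rep("field", 10))
  rec1 <- gist_index(ps1, "ROI1", "remote_short")
  expect_true(is.na(rec1$value))
  expect_match(rec1$reason, "categories")
})

test_that("aggregate_recent merges when sessions agree and flags when not", {
  rec <- data.frame(subject_id = sprintf("s%02d", 1:10), group = "adults",
                    roi = "ROI1", session = "day1", condition = "recent",
                    index_type = "scene_reinstatement",
                    term_specific = rnorm(10, 0.1, 0.01),
                    term_baseline = 0, value = rnorm(10, 0.1, 0.01),
                    n_items = 10L, n_pairs = 45L, reason = NA_character_,
                    stringsAsFactors = FALSE)
  # identical records: merged mean equals either input
  agg <- aggregate_recent(rec, transform(rec, session = "day14"))
  expect_true(agg$merged)
  expect_equal(agg$records$value, rec$value)
  # a large planted session shift: unmerged flag raised
  shifted <- transform(rec, session = "day14", value = value + 1)
  agg2 <- aggregate_recent(rec, shifted)
  expect_false(agg2$merged)
  expect_equal(nrow(agg2$records), 20L)
  # mismatching subject sets: alignment error
  expect_error(aggregate_recent(rec, shifted[-1, ]),
               class = "reinstatr_alignment_error")
})

test_that("null generator gives null indices and monotone rho gives monotone recovery", {
  # planted-null fidelity, scaled down: 12 cohorts of 6 subjects, one ROI;
  # all planted weights zero -> index means within 3 MC SEs of zero
  zero <- matrix(0, 2, 3,
                 dimnames = list(c("children", "adults"),
                                 c("recent", "remote_short", "remote_long")))
  pl0 <- planted_effects(rho = zero, gamma = zero, b = 0, n_voxels = 60L,
                         rois = "HCa", control_rois = character(0))
  catalog <- build_catalog()
  design <- build_design(catalog, design_config(3, 3), seed = 2)
  learning <- simulate_learning(design, seed = 2)
  means_r <- means_g <- numeric(12)
  for (s in 1:12) {
    behavior <- simulate_behavior(design, learning, seed = 100 + s)
    ps <- simulate_patterns(design, behavior, pl0, seed = 200 + s,
                            windows = c("fixation", "scene"))
    rr <- scene_reinstatement_index(ps, "HCa", "remote_short")
    gg <- gist_index(ps, "HCa", "remote_short")
    means_r[s] <- mean(rr$value, na.rm = TRUE)
    means_g[s] <- mean(gg$value, na.rm = TRUE)
  }
  expect_lt(abs(mean(means_r)), 3 * sd(means_r) / sqrt(12))
  expect_lt(abs(mean(means_g)), 3 * sd(means_g) / sqrt(12))

  # monotone recovery at reduced scale: one cohort, n = 8/group, planted
  # rho decaying across delays -> group-mean corrected index ordered
  cohort <- tiny_cohort(8, 8, seed = 31,
                        planted = planted_effects(n_voxels = 200L,
                                                  rois = "HCa",
                                                  control_rois = "WM"),
                        windows = c("fixation", "scene"))
  idx <- do.call(rbind, lapply(c("recent", "remote_short", "remote_long"),
                               function(cond)
    scene_reinstatement_index(cohort$pset, "HCa", cond)))
  m <- tapply(idx$value, idx$condition, mean, na.rm = TRUE)
  expect_gt(m[["recent"]], m[["remote_short"]])
  expect_gt(m[["remote_short"]], m[["remote_long"]])
  # control ROI shows no such gradient structure: all means near zero
  idxw <- do.call(rbind, lapply(c("recent", "remote_short", "remote_long"),
                                function(cond)
    scene_reinstatement_index(cohort$pset, "WM", cond)))
  mw <- tapply(idxw$value, idxw$condition, mean, na.rm = TRUE)
  expect_lt(max(abs(mw)), 0.02)
})
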