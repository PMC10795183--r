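toy_targets <- function() {
  data.frame(
    equipment_id = c("A", "B", "C", "D"),
    X11 = c(0.9, 0.7, 0.5, 0.8),
    X12 = c(0.8, 0.6, 0.5, 0.7),
    X13 = c(1.0, 0.8, 0.5, 0.9),
    X21 = c(30, 20, 10, 25),
    X22 = c(10, 15, 25, 12),
    X31 = c(1.5, 1.0, 0.5, 1.2),
    X32 = c(8, 4, 1, 6),
    X41 = c(1.5, 2.0, 3.0, 1.8),
    X42 = c(9, 5, 3, 7),
    stringsAsFactors = FALSE
  )
}

test_that("a zero-noise cohort round-trips through the indicator pipeline exactly", {
  spec <- cohort_spec(toy_targets(), days = 30)
  cohort <- generate_cohort(spec, seed = 4)
  dm <- build_decision_matrix(cohort$profiles, cohort$records)
  expect_equal(dm$values, cohort$ground_truth, tolerance = 1e-9)
  # deterministic targets are met exactly as requested
  tg <- toy_targets()
  for (col in c("X11", "X12", "X21", "X22", "X31", "X32", "X41", "X42")) {
    expect_equal(unname(dm$values[, col]), tg[[col]], tolerance = 1e-9)
  }
  # X13 only moves by the integer rounding of the exam count
  expect_equal(unname(dm$values[, "X13"]), tg$X13, tolerance = 0.01)
})

test_that("target inversion recovers age from the life-index target", {
  spec <- cohort_spec(toy_targets())
  cohort <- generate_cohort(spec, seed = 1)
  expect_equal(cohort$profiles$age_years[cohort$profiles$equipment_id == "B"], 6)
  expect_equal(cohort$profiles$age_years[cohort$profiles$equipment_id == "C"], 3)
})

test_that("noisy cohorts still round-trip against realized ground truth", {
  spec <- cohort_spec(toy_targets(), wait_sd = 5, gap_sd = 3, duration_sd = 4)
  cohort <- generate_cohort(spec, seed = 11)
  dm <- build_decision_matrix(cohort$profiles, cohort$records)
  expect_equal(dm$values, cohort$ground_truth, tolerance = 1e-9)
  # noise moved the realized waits/gaps off the requested targets
  expect_false(isTRUE(all.equal(unname(dm$values[, "X21"]), toy_targets()$X21)))
})

test_that("the generator is a pure function of spec and seed", {
  spec <- cohort_spec(toy_targets(), wait_sd = 5, gap_sd = 3)
  c1 <- generate_cohort(spec, seed = 8)
  c2 <- generate_cohort(spec, seed = 8)
  c3 <- generate_cohort(spec, seed = 9)
  expect_identical(c1$records, c2$records)
  expect_identical(c1$ground_truth, c2$ground_truth)
  expect_false(identical(c1$records$exam_start, c3$records$exam_start))
  # deterministic indicator fields are seed-independent
  det <- c("X11", "X12", "X31", "X32", "X41", "X42")
  expect_equal(c1$ground_truth[, det], c3$ground_truth[, det])
})

test_that("infeasible targets are rejected with the violated constraint named", {
  tg <- toy_targets()
  tg$X12[1] <- 1.2
  expect_error(cohort_spec(tg), "X12")
  tg <- toy_targets()
  tg$X32[2] <- 2.5
  expect_error(cohort_spec(tg), "X32")
  tg <- toy_targets()
  tg$X41[3] <- 0.9
  expect_error(cohort_spec(tg), "X41")
  # schedule that cannot fit the horizon
  tg <- toy_targets()
  tg$X22[1] <- 5000
  expect_error(generate_cohort(cohort_spec(tg, days = 2), seed = 1), "horizon")
})

test_that("a planted run-down device ranks first under all four methods", {
  tg <- toy_targets()
  # device A dominated on the direction-adjusted reading: strictly the
  # minimum on every benefit column, strictly the maximum on both costs
  tg[1, c("X11", "X12", "X13")] <- c(0.3, 0.3, 0.3)
  tg$X21[1] <- min(tg$X21) - 2
  tg$X22[1] <- min(tg$X22) - 5
  tg$X31[1] <- min(tg$X31) - 0.2
  tg$X32[1] <- 0
  tg$X41[1] <- max(tg$X41) + 2
  tg$X42[1] <- max(tg$X42) + 5
  cohort <- generate_cohort(cohort_spec(tg), seed = 2)
  dm <- build_decision_matrix(cohort$profiles, cohort$records)
  w <- random_weights(seed = 55)
  expect_equal(rank_gra_topsis(dm, w)$rank[1], 1)
  expect_equal(rank_gra(dm, w)$rank[1], 1)
  expect_equal(rank_topsis(dm, w)$rank[1], 1)
  expect_equal(rank_vikor(dm, w)$rank[1], 1)
})

test_that("expert panels respect consensus and the seed contract", {
  anchors <- setNames(c(9, 8, 8, 8, 8, 7, 7, 6, 5), indicator_ids())
  exact <- generate_expert_panel(8, anchors, consensus = 1, seed = 3)
  expect_equal(unname(unclass(exact)),
               matrix(rep(anchors, each = 8), 8, 9), ignore_attr = TRUE)
  # full consensus: COWA weights proportional to the anchors
  w <- cowa_weights(exact)
  expect_equal(unname(w$weights), unname(anchors / sum(anchors)))
  p1 <- generate_expert_panel(8, anchors, consensus = 0.6, seed = 3)
  p2 <- generate_expert_panel(8, anchors, consensus = 0.6, seed = 3)
  p3 <- generate_expert_panel(8, anchors, consensus = 0.6, seed = 4)
  expect_identical(p1, p2)
  expect_false(identical(p1, p3))
  expect_true(all(p1 >= 0 & p1 <= 10))
  expect_equal(dim(p3), dim(p1))
})

test_that("a panel anchored to the worked example reproduces its contribution vector", {
  anchors <- setNames(rep(7, 9), indicator_ids())
  scores <- c(9, 8, 8, 8, 8, 7, 7, 6)
  panel <- generate_expert_panel(8, anchors, consensus = 1, seed = 1)
  panel[, "X11"] <- scores
  w <- cowa_weights(expert_panel(unclass(panel)))
  expect_equal(round(attr(w, "contributions")$X11, 2),
               c(0.07, 0.44, 1.31, 2.19, 2.19, 1.15, 0.38, 0.05))
})

test_that("embedded reference values carry the printed case-study tables", {
  expect_equal(unname(ref$fusion_measures["Signa HDx", ]), c(1.000, 0.646, 0.873, 1.000))
  expect_equal(ref$method_scores["MR750", "GRA-TOPSIS"], 0.433)
  expect_equal(sum(ref$pca$variance_shares), 0.8640, tolerance = 0.02)
  expect_equal(ref$cowa_example$sorted_scores, c(9, 8, 8, 8, 8, 7, 7, 6))
  d <- withr::local_tempdir()
  write_reference_fixtures(d)
  expect_true(all(file.exists(file.path(d, c("pca_loadings.csv", "fusion_measures.csv",
                                             "method_scores.csv", "method_ranks.csv")))))
  back <- read.csv(file.path(d, "fusion_measures.csv"), check.names = FALSE)
  expect_equal(back$D_pos, unname(ref$fusion_measures[, "D_pos"]))
})
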