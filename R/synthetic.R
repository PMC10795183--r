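# Synthetic cohort generator: invert the indicator formulas so that a
# requested indicator profile per device is turned into profiles and
# per-exam logs from which the pipeline recovers known ground truth.
# Also embeds the four-scanner MRI case-study reference values used by
# the validation suite.

#' Specify a synthetic equipment cohort
#'
#' @param targets Data.frame with `equipment_id` and target columns
#'   `X11`, `X12`, `X13`, `X21`, `X22`, `X31`, `X32`, `X41`, `X42`
#'   (one row per device).  Constraints: `X11 > 0`, `X12` in (0, 1\],
#'   `X13 > 0`, `X21, X22 >= 0`, `X31 >= 0`, `X32` integer >= 0,
#'   `X41 > 1` (cost-recovering devices) and `X42 > 0`.
#' @param days Length of the observation period in days (default 30);
#'   rated working time is 480 min/day.
#' @param mean_exam_minutes Mean exam duration tau (default 28).
#' @param prep_minutes Per-exam preparation allowance (default 2).
#' @param revenue_per_exam Revenue per exam, constant within a device
#'   (default 600).
#' @param duration_sd,wait_sd,gap_sd Truncated-normal noise (minutes) on
#'   exam durations, waits and inter-exam gaps (default 0 = exact logs).
#' @param expected_life_years Reference useful life (default 6).
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(targets, days = 30, mean_exam_minutes = 28,
                        prep_minutes = 2, revenue_per_exam = 600,
                        duration_sd = 0, wait_sd = 0, gap_sd = 0,
                        expected_life_years = 6) {
  targets <- as.data.frame(targets, stringsAsFactors = FALSE)
  need <- c("equipment_id", INDICATOR_IDS)
  miss <- setdiff(need, names(targets))
  if (length(miss) > 0) stop(sprintf("targets missing columns: %s", paste(miss, collapse = ", ")))
  with(targets, {
    if (any(X11 <= 0)) stop("infeasible target: X11 must be > 0")
    if (any(X12 <= 0 | X12 > 1)) stop("infeasible target: X12 must lie in (0, 1]")
    if (any(X13 <= 0)) stop("infeasible target: X13 must be > 0")
    if (any(X21 < 0 | X22 < 0)) stop("infeasible target: waits/intervals must be >= 0")
    if (any(X31 < 0)) stop("infeasible target: X31 must be >= 0")
    if (any(X32 < 0 | X32 != round(X32))) stop("infeasible target: X32 must be a non-negative integer")
    if (any(X41 <= 1)) {
      stop("infeasible target: X41 must be > 1 (the generator emulates cost-recovering devices)")
    }
    if (any(X42 <= 0)) stop("infeasible target: X42 must be > 0")
  })
  structure(list(targets = targets, days = days,
                 mean_exam_minutes = mean_exam_minutes,
                 prep_minutes = prep_minutes,
                 revenue_per_exam = revenue_per_exam,
                 duration_sd = duration_sd, wait_sd = wait_sd, gap_sd = gap_sd,
                 expected_life_years = expected_life_years),
            class = "cohort_spec")
}

#' Generate a synthetic equipment cohort with known ground truth
#'
#' Inverts the indicator formulas: the exam count comes from the work
#' intensity target and the rated time, powered-on time from the
#' saturation target, working time from utilization, financials from
#' the cost-benefit and payback targets (constant revenue per exam),
#' and the exam log is scheduled sequentially with the requested mean
#' wait and inter-exam gap plus optional truncated-normal noise.
#'
#' The returned `ground_truth` holds the indicator values actually
#' realized (the exam count is rounded to an integer and noisy waits /
#' gaps are summarized from the generated log), so
#' [build_decision_matrix()] on the output reproduces `ground_truth`
#' to numerical precision at any noise level; with zero noise the
#' realized X21/X22 equal the requested targets exactly.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; the generator is a pure function of
#'   `(spec, seed)`.
#' @return List with `profiles` ([equipment_profile()]), `records`
#'   ([exam_records()]), `failures` (data.frame of failure events) and
#'   `ground_truth` (devices x 9 matrix).
#' @export
generate_cohort <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::local_seed(as.integer(seed))
  tg <- spec$targets
  tau <- spec$mean_exam_minutes
  prep <- spec$prep_minutes
  eta_r <- 480 * spec$days
  horizon_min <- spec$days * 1440
  origin <- as.POSIXct("2024-01-01 00:00:00", tz = "UTC")

  profiles <- NULL
  records <- NULL
  failures <- NULL
  gt <- matrix(NA_real_, nrow(tg), 9, dimnames = list(tg$equipment_id, INDICATOR_IDS))

  for (i in seq_len(nrow(tg))) {
    t1 <- tg[i, ]
    n_exams <- max(2L, as.integer(round(t1$X13 * eta_r / (tau + prep))))
    eta_b <- (tau + prep) * n_exams / t1$X11
    eta_w <- t1$X12 * eta_b
    if (n_exams * (tau + t1$X22) > horizon_min) {
      stop(sprintf("infeasible target for %s: %d exams of %g min with %g min gaps exceed the %d-day horizon",
                   t1$equipment_id, n_exams, tau, t1$X22, spec$days))
    }
    durations <- pmax(1, tau + rnorm(n_exams, 0, spec$duration_sd))
    gaps <- pmax(0, t1$X22 + rnorm(n_exams - 1, 0, spec$gap_sd))
    waits <- pmax(0, t1$X21 + rnorm(n_exams, 0, spec$wait_sd))
    starts <- origin + 60 * (8 * 60 + cumsum(c(0, durations[-n_exams] + gaps)))
    ends <- starts + 60 * durations
    sched <- starts - 60 * waits

    r_t <- n_exams * spec$revenue_per_exam
    c_t <- r_t / t1$X41
    c_v <- t1$X42 * (r_t - c_t)
    prof <- data.frame(
      equipment_id = t1$equipment_id,
      model_name = t1$equipment_id,
      purchase_price = c_v,
      operating_cost = c_t,
      total_revenue = r_t,
      age_years = t1$X31 * spec$expected_life_years,
      expected_life_years = spec$expected_life_years,
      power_on_minutes = eta_b,
      working_minutes = eta_w,
      rated_minutes = eta_r,
      failure_count = as.integer(t1$X32),
      mean_exam_minutes = tau,
      prep_minutes = prep,
      stringsAsFactors = FALSE
    )
    recs <- data.frame(
      equipment_id = t1$equipment_id,
      scheduled_time = sched,
      exam_start = starts,
      exam_end = ends,
      revenue = spec$revenue_per_exam,
      stringsAsFactors = FALSE
    )
    nf <- as.integer(t1$X32)
    fails <- if (nf > 0) {
      data.frame(equipment_id = t1$equipment_id,
                 time = origin + sort(runif(nf, 0, horizon_min)) * 60,
                 stringsAsFactors = FALSE)
    } else NULL

    gt[i, ] <- c(
      X11 = t1$X11,
      X12 = t1$X12,
      X13 = (tau + prep) * n_exams / eta_r,
      X21 = mean(waits),
      X22 = mean(gaps),
      X31 = t1$X31,
      X32 = nf,
      X41 = t1$X41,
      X42 = t1$X42
    )
    profiles <- rbind(profiles, prof)
    records <- rbind(records, recs)
    failures <- rbind(failures, fails)
  }
  list(profiles = equipment_profile(profiles),
       records = exam_records(records),
       failures = failures,
       ground_truth = gt)
}

#' Generate a synthetic expert score panel
#'
#' Scores are drawn around per-indicator anchor importances with
#' dispersion shrinking to zero as consensus approaches 1, then clipped
#' to \[0, 10\].  At full consensus every expert returns the anchors
#' exactly, so the COWA weights are proportional to the anchors.
#'
#' @param n_experts Number of experts (>= 1).
#' @param anchors Named numeric vector of anchor scores in \[0, 10\]
#'   (names = indicator ids).
#' @param consensus Agreement level in \[0, 1\]; score s.d. is
#'   `2 * (1 - consensus)` points.
#' @param seed Integer seed.
#' @return An [expert_panel()].
#' @export
generate_expert_panel <- function(n_experts, anchors, consensus = 0.8, seed = 1L) {
  if (n_experts < 1) stop("n_experts must be >= 1")
  if (consensus < 0 || consensus > 1) stop("consensus must lie in [0, 1]")
  if (is.null(names(anchors))) stop("anchors must be named by indicator id")
  if (any(anchors < 0 | anchors > 10)) stop("anchors must lie in [0, 10]")
  withr::local_seed(as.integer(seed))
  sdv <- 2 * (1 - consensus)
  m <- vapply(anchors, function(a) pmin(10, pmax(0, a + rnorm(n_experts, 0, sdv))),
              numeric(n_experts))
  if (n_experts == 1) m <- matrix(m, nrow = 1, dimnames = list(NULL, names(anchors)))
  rownames(m) <- paste0("expert", seq_len(n_experts))
  expert_panel(m)
}

#' Reference values from the four-scanner MRI case study
#'
#' The published validation case: four MRI scanners (Signa HDx, MR750,
#' MR750W, Prisma) in one tertiary hospital.  Embeds, at printed
#' precision, the PCA loading matrix with its eigenvalues and variance
#' shares plus the printed indicator scores/weights; the normalized
#' distance and gray-relation measures (D+, D-, L+, L-) per scanner;
#' the four methods' final scores and printed rank columns; and the
#' eight sorted expert scores for indicator X11 with their published
#' COWA contribution vector.
#'
#' @return A list with elements `pca` (loadings, eigenvalues,
#'   variance_shares, scores, weights), `fusion_measures` (4 x 4 matrix
#'   D_pos/D_neg/L_pos/L_neg), `method_scores` and `method_ranks`
#'   (4 scanners x 4 methods), and `cowa_example` (sorted_scores,
#'   contributions).
#' @export
mri_reference <- function() {
  scanners <- c("Signa HDx", "MR750", "MR750W", "Prisma")
  loadings <- matrix(c(
    0.443, 0.158, 0.297, 0.218,
    0.402, 0.246, 0.325, 0.321,
    0.392, 0.195, 0.123, 0.335,
    0.226, 0.576, 0.062, 0.057,
    0.358, 0.151, 0.229, 0.348,
    0.388, 0.151, 0.367, 0.397,
    0.097, 0.612, 0.336, 0.046,
    0.381, 0.099, 0.432, 0.328,
    0.065, 0.339, 0.549, 0.588
  ), nrow = 9, byrow = TRUE,
  dimnames = list(INDICATOR_IDS, paste0("PC", 1:4)))
  fusion <- matrix(c(
    1.000, 0.646, 0.873, 1.000,
    0.622, 0.985, 0.979, 0.875,
    0.410, 1.000, 1.000, 0.818,
    0.570, 0.959, 0.982, 0.859
  ), nrow = 4, byrow = TRUE,
  dimnames = list(scanners, c("D_pos", "D_neg", "L_pos", "L_neg")))
  scores <- matrix(c(
    0.864, 0.613, 0.568, 0.000,
    0.756, 0.393, 0.433, 0.831,
    0.707, 0.296, 0.380, 0.807,
    0.742, 0.379, 0.424, 0.990
  ), nrow = 4, byrow = TRUE,
  dimnames = list(scanners, c("GRA", "TOPSIS", "GRA-TOPSIS", "VIKOR")))
  ranks <- matrix(c(
    1, 1, 1, 1,
    3, 2, 2, 3,
    4, 4, 4, 2,
    2, 3, 3, 4
  ), nrow = 4, byrow = TRUE,
  dimnames = list(scanners, c("GRA", "TOPSIS", "GRA-TOPSIS", "VIKOR")))
  list(
    pca = list(
      loadings = loadings,
      eigenvalues = c(4.013, 1.652, 1.186, 0.924),
      variance_shares = c(0.4459, 0.1836, 0.1318, 0.1027),
      scores = setNames(c(0.333, 0.347, 0.302, 0.255, 0.293, 0.335, 0.237, 0.322, 0.259),
                        INDICATOR_IDS),
      weights = setNames(c(0.124, 0.129, 0.113, 0.095, 0.109, 0.125, 0.088, 0.120, 0.096),
                         INDICATOR_IDS)
    ),
    fusion_measures = fusion,
    method_scores = scores,
    method_ranks = ranks,
    cowa_example = list(
      sorted_scores = c(9, 8, 8, 8, 8, 7, 7, 6),
      contributions = c(0.07, 0.44, 1.31, 2.19, 2.19, 1.15, 0.38, 0.05)
    )
  )
}

#' Write the embedded MRI reference values as CSV files
#'
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_reference_fixtures <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ref <- mri_reference()
  wr <- function(m, nm, idcol) {
    df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
    names(df)[1] <- idcol
    write.csv(df, file.path(dir, nm), row.names = FALSE, quote = FALSE)
  }
  wr(ref$pca$loadings, "pca_loadings.csv", "indicator_id")
  wr(ref$fusion_measures, "fusion_measures.csv", "equipment_id")
  wr(ref$method_scores, "method_scores.csv", "equipment_id")
  wr(ref$method_ranks, "method_ranks.csv", "equipment_id")
  invisible(dir)
}
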