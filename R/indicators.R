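# Nine usage/benefit indicators computed from an equipment profile and
# (for X21/X22) the per-exam log.  All durations in minutes.

exam_count <- function(records, id) {
  sum(records$equipment_id == id)
}

#' Operating saturation (X11)
#'
#' Exam workload, including a fixed per-exam preparation allowance,
#' relative to powered-on time: `(tau + prep) * n_exams / power_on`.
#'
#' @param profile One-row [equipment_profile()] (or a row of one).
#' @param n_exams Number of exams performed in the period.
#' @return Dimensionless saturation (can exceed 1 when prep time pushes
#'   workload past powered-on time).
#' @export
#' @examples
#' p <- data.frame(mean_exam_minutes = 28, prep_minutes = 2, power_on_minutes = 600)
#' operating_saturation(p, n_exams = 16) # 0.8
operating_saturation <- function(profile, n_exams) {
  if (any(profile$power_on_minutes <= 0)) {
    stop(sprintf("power_on_minutes is zero for %s: saturation undefined",
                 paste(profile$equipment_id[profile$power_on_minutes <= 0], collapse = ", ")))
  }
  (profile$mean_exam_minutes + profile$prep_minutes) * n_exams / profile$power_on_minutes
}

#' Equipment utilization (X12)
#'
#' Working time as a fraction of powered-on time, in \[0, 1\].
#'
#' @param profile One-row [equipment_profile()].
#' @return `working_minutes / power_on_minutes`.
#' @export
equipment_utilization <- function(profile) {
  if (any(profile$power_on_minutes <= 0)) stop("power_on_minutes must be > 0")
  if (any(profile$working_minutes > profile$power_on_minutes + 1e-9)) {
    stop("working_minutes exceeds power_on_minutes")
  }
  profile$working_minutes / profile$power_on_minutes
}

#' Work intensity (X13)
#'
#' Exam workload (including preparation) relative to the rated working
#' time (8 h per day by convention).
#'
#' @inheritParams operating_saturation
#' @return `(tau + prep) * n_exams / rated_minutes`.
#' @export
work_intensity <- function(profile, n_exams) {
  if (any(profile$rated_minutes <= 0)) stop("rated_minutes must be > 0")
  (profile$mean_exam_minutes + profile$prep_minutes) * n_exams / profile$rated_minutes
}

#' Mean patient waiting time (X21)
#'
#' Mean of `exam_start - scheduled_time` in minutes over the records
#' that carry an appointment, each wait clamped at zero (an exam that
#' started early contributes no wait).
#'
#' @param records [exam_records()] for one device.
#' @return Mean wait in minutes.
#' @export
mean_wait <- function(records) {
  has_appt <- !is.na(records$scheduled_time)
  if (!any(has_appt)) stop("no appointments: mean wait undefined")
  waits <- as.numeric(difftime(records$exam_start[has_appt],
                               records$scheduled_time[has_appt], units = "mins"))
  mean(pmax(waits, 0))
}

#' Mean inter-exam interval (X22)
#'
#' Mean gap in minutes between consecutive exams (start of exam i minus
#' end of exam i-1, records sorted by start time); overlapping exams
#' contribute a zero gap.
#'
#' @param records [exam_records()] for one device, >= 2 rows.
#' @return Mean gap in minutes.
#' @export
mean_interval <- function(records) {
  if (nrow(records) < 2) stop("mean interval needs at least 2 exam records")
  ord <- order(records$exam_start)
  starts <- records$exam_start[ord]
  ends <- records$exam_end[ord]
  gaps <- as.numeric(difftime(starts[-1], ends[-length(ends)], units = "mins"))
  mean(pmax(gaps, 0))
}

#' Life index (X31)
#'
#' Age relative to the expected useful life (6 years by convention);
#' values above 1 mean the device has outlived its reference life.
#'
#' @param profile One-row [equipment_profile()].
#' @return `age_years / expected_life_years`.
#' @export
life_index <- function(profile) {
  if (any(profile$expected_life_years <= 0)) stop("expected_life_years must be > 0")
  profile$age_years / profile$expected_life_years
}

#' Failure count (X32)
#' @param profile One-row [equipment_profile()].
#' @return Total number of recorded failures.
#' @export
failure_count <- function(profile) {
  profile$failure_count
}

#' Cost-benefit ratio (X41)
#'
#' Period revenue over period operating cost.  Cost-direction: a lower
#' ratio argues for earlier replacement.
#'
#' @param profile One-row [equipment_profile()].
#' @return `total_revenue / operating_cost`.
#' @export
cost_benefit_ratio <- function(profile) {
  if (any(profile$operating_cost <= 0)) stop("operating_cost must be > 0")
  profile$total_revenue / profile$operating_cost
}

#' Payback period (X42)
#'
#' Purchase price over period net revenue, in periods.  A device that
#' fails to cover its operating cost has no finite payback; such devices
#' are flagged and assigned a large sentinel so the cost-direction
#' ranking stays monotone ("longer payback, delay replacement") — see
#' [build_decision_matrix()] for the cohort-level sentinel rule.
#'
#' @param profile [equipment_profile()] rows.
#' @param sentinel Value standing in for an infinite payback; default
#'   `Inf` (replaced by a cohort-scaled value in
#'   [build_decision_matrix()]).
#' @return `purchase_price / (total_revenue - operating_cost)`, with
#'   non-recoverable devices set to `sentinel`.
#' @export
payback_period <- function(profile, sentinel = Inf) {
  net <- profile$total_revenue - profile$operating_cost
  if (any(net == 0)) {
    stop(sprintf("undefined payback (revenue equals cost) for %s",
                 paste(profile$equipment_id[net == 0], collapse = ", ")))
  }
  out <- profile$purchase_price / net
  if (any(net < 0)) {
    warning(sprintf("non-recoverable investment (revenue < cost) for %s; payback set to sentinel",
                    paste(profile$equipment_id[net < 0], collapse = ", ")))
    out[net < 0] <- sentinel
  }
  out
}

#' Assemble the decision matrix from profiles and exam logs
#'
#' Computes all nine indicators per device and attaches the canonical
#' benefit/cost directions.  X21 and X22 need per-exam records; the
#' remaining indicators come from the profile aggregates (the exam count
#' for X11/X13 is taken from the records when present, otherwise from a
#' profile column `n_exams`).
#'
#' @param profiles [equipment_profile()] table, one row per device.
#' @param records [exam_records()] covering the same devices (optional
#'   only if every profile has an `n_exams` column and X21/X22 are not
#'   needed — in that case an error names the first indicator that
#'   cannot be computed).
#' @param payback_sentinel_factor When a device's revenue does not cover
#'   its cost, its payback (X42) is set to the largest finite payback in
#'   the cohort times this factor (default 10).
#' @return A [decision_matrix()] (m x 9).
#' @export
build_decision_matrix <- function(profiles, records = NULL,
                                  payback_sentinel_factor = 10) {
  profiles <- equipment_profile(profiles)
  ids <- profiles$equipment_id
  if (!is.null(records)) {
    records <- exam_records(records)
    stray <- setdiff(unique(records$equipment_id), ids)
    if (length(stray) > 0) {
      stop(sprintf("exam records reference unknown equipment: %s",
                   paste(stray, collapse = ", ")))
    }
  }
  per_dev <- function(id) {
    p <- profiles[profiles$equipment_id == id, , drop = FALSE]
    if (!is.null(records)) {
      rec <- records[records$equipment_id == id, , drop = FALSE]
    } else {
      rec <- NULL
    }
    if (is.null(rec) || nrow(rec) == 0) {
      stop(sprintf("no exam records for %s: X21 (mean wait) undefined", id))
    }
    n <- nrow(rec)
    c(X11 = operating_saturation(p, n),
      X12 = equipment_utilization(p),
      X13 = work_intensity(p, n),
      X21 = mean_wait(rec),
      X22 = mean_interval(rec),
      X31 = life_index(p),
      X32 = failure_count(p),
      X41 = cost_benefit_ratio(p),
      X42 = payback_period(p, sentinel = Inf))
  }
  vals <- t(vapply(ids, per_dev, numeric(9)))
  rownames(vals) <- ids
  # cohort sentinel for non-recoverable paybacks
  inf42 <- !is.finite(vals[, "X42"])
  if (any(inf42)) {
    if (all(inf42)) stop("no device has a finite payback; X42 sentinel undefined")
    vals[inf42, "X42"] <- max(vals[!inf42, "X42"]) * payback_sentinel_factor
  }
  decision_matrix(vals)
}
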