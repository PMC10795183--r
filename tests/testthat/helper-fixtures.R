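# Small in-code fixtures shared across tests.

indicator_ids <- function() default_indicators()$indicator_id

# A profile row with convenient round numbers.
toy_profile <- function(id = "MR1", tau = 28, prep = 2, power_on = 600,
                        working = 480, rated = 480, age = 3, life = 6,
                        failures = 2, price = 5e6, cost = 1e6, revenue = 2e6) {
  data.frame(
    equipment_id = id, model_name = id,
    purchase_price = price, operating_cost = cost, total_revenue = revenue,
    age_years = age, expected_life_years = life,
    power_on_minutes = power_on, working_minutes = working,
    rated_minutes = rated, failure_count = failures,
    mean_exam_minutes = tau, prep_minutes = prep,
    stringsAsFactors = FALSE
  )
}

# Exam records built from waits (minutes before start), durations and gaps.
toy_records <- function(id = "MR1", waits = c(10, 20, 30),
                        durations = rep(30, length(waits)),
                        gaps = rep(10, length(waits) - 1),
                        revenue = 500) {
  origin <- as.POSIXct("2024-03-01 08:00:00", tz = "UTC")
  n <- length(waits)
  starts <- origin + 60 * cumsum(c(0, durations[-n] + gaps))
  exam_records(data.frame(
    equipment_id = id,
    scheduled_time = starts - 60 * waits,
    exam_start = starts,
    exam_end = starts + 60 * durations,
    revenue = revenue,
    stringsAsFactors = FALSE
  ))
}

random_decision_matrix <- function(m = 6, seed = 42) {
  withr::with_seed(seed, {
    vals <- matrix(runif(m * 9, 1, 10), m, 9,
                   dimnames = list(paste0("E", seq_len(m)), indicator_ids()))
    decision_matrix(vals)
  })
}

random_weights <- function(seed = 7, ids = indicator_ids()) {
  withr::with_seed(seed, {
    w <- runif(length(ids), 0.2, 1)
    weight_vector(setNames(w / sum(w), ids), method = "custom")
  })
}

# Reference four-scanner measures/scores (printed precision).
ref <- mri_reference()
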