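#' medequip: multi-criteria replacement prioritization for large medical equipment
#'
#' Builds a nine-indicator usage/benefit profile for each device from
#' operational logs, weights the indicators by expert opinion (COWA),
#' by the data (PCA) and by a game-theoretic combination of the two,
#' and ranks the devices for replacement with a GRA-TOPSIS fusion score
#' (plus plain GRA, plain TOPSIS and VIKOR comparators and a Kendall-W
#' concordance check).
#'
#' @section Typical workflow:
#' 1. [build_decision_matrix()] from profiles + exam logs (or
#'    [read_decision_matrix()] from a prepared CSV);
#' 2. [cowa_weights()] on an expert panel, [pca_weights()] on the matrix,
#'    [combine_weights()] for the game-theoretic mix;
#' 3. [rank_gra_topsis()] (and [rank_gra()], [rank_topsis()],
#'    [rank_vikor()]) to rank;
#' 4. [kendall_w()] to check cross-method agreement;
#' 5. or run the whole chain with [run_pipeline()].
#'
#' @importFrom stats cor rnorm runif median pchisq sd setNames
#' @importFrom utils read.csv write.csv head
#' @keywords internal
"_PACKAGE"

# Canonical indicator system: 4 first-level groups, 9 second-level
# indicators.  Direction "benefit" = larger value counts toward the
# positive ideal under min-max normalization; "cost" columns are reversed.
INDICATOR_IDS <- c("X11", "X12", "X13", "X21", "X22", "X31", "X32", "X41", "X42")

#' Canonical indicator definitions
#'
#' The nine-indicator evaluation system for equipment replacement
#' priority: operational security (X11 operating saturation, X12
#' utilization, X13 work intensity), social benefit (X21 mean patient
#' wait, X22 mean inter-exam interval), technical condition (X31 life
#' index, X32 failure count) and economic benefit (X41 cost-benefit
#' ratio, X42 payback period).  X41 and X42 are cost-direction; all
#' others benefit-direction.
#'
#' @return A data.frame with columns `indicator_id`, `name`, `direction`
#'   (`"benefit"` or `"cost"`).
#' @export
#' @examples
#' default_indicators()
default_indicators <- function() {
  data.frame(
    indicator_id = INDICATOR_IDS,
    name = c(
      "operating saturation", "equipment utilization", "work intensity",
      "mean patient wait", "mean inter-exam interval",
      "life index", "failure count",
      "cost-benefit ratio", "payback period"
    ),
    direction = c(rep("benefit", 7), rep("cost", 2)),
    stringsAsFactors = FALSE
  )
}

default_direction_map <- function() {
  defs <- default_indicators()
  setNames(defs$direction, defs$indicator_id)
}

#' Construct a decision matrix
#'
#' An equipment-by-indicator matrix of raw indicator values together
#' with the direction (benefit/cost) of each indicator column.
#'
#' @param values Numeric matrix, equipment in rows (rownames = equipment
#'   ids), indicators in columns (colnames = indicator ids).  No missing
#'   values; at least 2 rows and 2 columns.
#' @param directions Named character vector mapping each column id to
#'   `"benefit"` or `"cost"`.  Defaults to the canonical directions for
#'   the nine standard indicators; any non-standard column must be named
#'   here explicitly.
#' @return An object of class `decision_matrix`: a list with elements
#'   `values` and `directions`.
#' @export
#' @examples
#' m <- matrix(runif(18), 2, 9, dimnames = list(c("A", "B"), default_indicators()$indicator_id))
#' dm <- decision_matrix(m)
decision_matrix <- function(values, directions = NULL) {
  values <- as.matrix(values)
  if (nrow(values) < 2 || ncol(values) < 2) {
    stop("decision matrix needs at least 2 equipment rows and 2 indicator columns")
  }
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("E", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    stop("decision matrix columns must be named with indicator ids")
  }
  if (anyDuplicated(rownames(values))) stop("duplicate equipment ids")
  if (anyDuplicated(colnames(values))) stop("duplicate indicator ids")
  bad <- which(!is.finite(values), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "missing value at (%s, %s)",
      rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]]
    ))
  }
  dirmap <- default_direction_map()
  if (!is.null(directions)) dirmap[names(directions)] <- directions
  unknown <- setdiff(colnames(values), names(dirmap))
  if (length(unknown) > 0) {
    stop(sprintf(
      "unknown indicator id(s) without a direction override: %s",
      paste(unknown, collapse = ", ")
    ))
  }
  dirs <- dirmap[colnames(values)]
  if (!all(dirs %in% c("benefit", "cost"))) {
    stop("directions must be 'benefit' or 'cost'")
  }
  structure(list(values = values, directions = dirs), class = "decision_matrix")
}

#' @export
print.decision_matrix <- function(x, ...) {
  cat(sprintf(
    "Decision matrix: %d equipment x %d indicators\n",
    nrow(x$values), ncol(x$values)
  ))
  marks <- ifelse(x$directions == "benefit", "(+)", "(-)")
  hdr <- x$values
  colnames(hdr) <- paste(colnames(x$values), marks)
  print(round(hdr, 4), ...)
  invisible(x)
}

#' Read a decision matrix from CSV
#'
#' Expects a header row of indicator ids with the first column holding
#' equipment ids.  Directions default to the canonical nine-indicator
#' system; extra columns require an entry in `direction_map`.
#'
#' @param path CSV file path.
#' @param direction_map Optional named character vector of direction
#'   overrides (`"benefit"`/`"cost"`).
#' @return A [decision_matrix()].
#' @export
read_decision_matrix <- function(path, direction_map = NULL) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("matrix CSV needs an id column plus >= 2 indicator columns")
  ids <- as.character(df[[1]])
  vals <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- ids
  decision_matrix(vals, directions = direction_map)
}

#' Write a decision matrix to CSV
#'
#' @param x A [decision_matrix()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_decision_matrix <- function(x, path) {
  stopifnot(inherits(x, "decision_matrix"))
  df <- data.frame(equipment_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct an expert score panel
#'
#' Scores are importances on a 0-10 scale, one row per expert and one
#' column per indicator.
#'
#' @param scores Numeric matrix (experts x indicators), all values in
#'   \[0, 10\].  Rownames = expert ids (generated if absent), colnames =
#'   indicator ids (required).
#' @return An object of class `expert_panel` (a validated matrix).
#' @export
expert_panel <- function(scores) {
  scores <- as.matrix(scores)
  storage.mode(scores) <- "double"
  if (is.null(colnames(scores))) stop("expert panel columns must be named with indicator ids")
  if (is.null(rownames(scores))) rownames(scores) <- paste0("expert", seq_len(nrow(scores)))
  if (nrow(scores) < 1) stop("expert panel needs at least one expert")
  if (any(!is.finite(scores))) stop("expert panel contains missing scores")
  if (any(scores < 0 | scores > 10)) {
    bad <- which(scores < 0 | scores > 10, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "score %g at (%s, %s) outside [0, 10]",
      scores[bad[1], bad[2]], rownames(scores)[bad[1]], colnames(scores)[bad[2]]
    ))
  }
  structure(scores, class = c("expert_panel", "matrix", "array"))
}

#' Read an expert score panel from CSV
#'
#' @param path CSV with one row per expert; either all columns are
#'   indicator scores, or a first non-numeric column holds expert ids.
#' @return An [expert_panel()].
#' @export
read_expert_panel <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.numeric(df[[1]])) {
    ids <- as.character(df[[1]])
    df <- df[, -1, drop = FALSE]
    m <- as.matrix(df)
    rownames(m) <- ids
  } else {
    m <- as.matrix(df)
  }
  storage.mode(m) <- "double"
  expert_panel(m)
}

#' Write an expert score panel to CSV
#' @param x An [expert_panel()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_expert_panel <- function(x, path) {
  stopifnot(inherits(x, "expert_panel"))
  df <- data.frame(expert_id = rownames(x), unclass(x),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a weight vector
#'
#' @param weights Named non-negative numeric vector summing to 1
#'   (names = indicator ids).
#' @param method Tag recording how the weights were derived
#'   (e.g. `"cowa"`, `"pca"`, `"game"`).
#' @return An object of class `weight_vector`.
#' @export
weight_vector <- function(weights, method = "custom") {
  if (is.null(names(weights))) stop("weights must be named by indicator id")
  weights <- unlist(weights)
  if (any(!is.finite(weights))) stop("weights contain missing values")
  if (any(weights < -1e-12)) stop("weights must be non-negative")
  weights <- pmax(weights, 0)
  if (abs(sum(weights) - 1) > 1e-9) {
    stop(sprintf("weights must sum to 1 (got %.12g)", sum(weights)))
  }
  structure(list(indicator_ids = names(weights), weights = weights, method = method),
            class = "weight_vector")
}

#' @export
print.weight_vector <- function(x, ...) {
  cat(sprintf("Weight vector (%s):\n", x$method))
  print(round(x$weights, 4), ...)
  invisible(x)
}

#' Write a weight vector to JSON
#' @param x A [weight_vector()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_weights <- function(x, path) {
  stopifnot(inherits(x, "weight_vector"))
  jsonlite::write_json(
    list(indicator_ids = x$indicator_ids,
         weights = unname(x$weights),
         method = x$method),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a weight vector from JSON
#' @param path JSON written by [write_weights()].
#' @return A [weight_vector()].
#' @export
read_weights <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  weight_vector(setNames(obj$weights, obj$indicator_ids), method = obj$method)
}

#' Construct a ranking result
#'
#' Scores are oriented so that larger means higher replacement priority
#' for `"gra"`, `"topsis"` and `"gra_topsis"`; VIKOR's Q is ascending
#' (0 = replace first).  Ranks are 1 = replace first, ties averaged.
#'
#' @param equipment_ids Character vector of device ids.
#' @param scores Numeric method scores.
#' @param method One of `"gra"`, `"topsis"`, `"gra_topsis"`, `"vikor"`.
#' @param ascending Logical: if `TRUE` smaller scores rank first (VIKOR).
#' @param diagnostics Optional list of intermediate quantities.
#' @return An object of class `ranking_result`: a data.frame with
#'   columns `equipment_id`, `score`, `rank`, plus attributes `method`
#'   and `diagnostics`.
#' @export
ranking_result <- function(equipment_ids, scores, method,
                           ascending = identical(method, "vikor"),
                           diagnostics = NULL) {
  stopifnot(length(equipment_ids) == length(scores))
  if (any(!is.finite(scores))) stop("ranking scores contain missing values")
  r <- if (ascending) rank(scores, ties.method = "average")
       else rank(-scores, ties.method = "average")
  out <- data.frame(equipment_id = as.character(equipment_ids),
                    score = as.numeric(scores), rank = r,
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, class = c("ranking_result", "data.frame"),
            method = method, diagnostics = diagnostics)
}

#' @export
print.ranking_result <- function(x, ...) {
  cat(sprintf("Ranking (%s); rank 1 = replace first\n", attr(x, "method")))
  df <- as.data.frame(x)
  df$score <- round(df$score, 4)
  print(df[order(df$rank), ], row.names = FALSE, ...)
  invisible(x)
}

#' Write a ranking result to JSON
#' @param x A [ranking_result()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(x, path) {
  stopifnot(inherits(x, "ranking_result"))
  jsonlite::write_json(
    list(equipment_ids = x$equipment_id,
         scores = x$score,
         ranks = x$rank,
         method = attr(x, "method"),
         diagnostics = attr(x, "diagnostics")),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a ranking result from JSON
#' @param path JSON written by [write_ranking()].
#' @return A [ranking_result()].
#' @export
read_ranking <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ranking_result(obj$equipment_ids, obj$scores, obj$method,
                 ascending = identical(obj$method, "vikor"),
                 diagnostics = obj$diagnostics)
}

#' Construct an equipment profile table
#'
#' One row per device with the aggregate fields the indicator formulas
#' consume.  Durations are minutes; financial fields share one currency.
#'
#' @param df A data.frame with columns `equipment_id`, `purchase_price`,
#'   `operating_cost`, `total_revenue`, `age_years`,
#'   `expected_life_years` (default 6), `power_on_minutes`,
#'   `working_minutes`, `rated_minutes`, `failure_count`,
#'   `mean_exam_minutes`, `prep_minutes` (default 2) and optionally
#'   `model_name`.
#' @return A validated data.frame of class `equipment_profile`.
#' @export
equipment_profile <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!"expected_life_years" %in% names(df)) df$expected_life_years <- 6
  if (!"prep_minutes" %in% names(df)) df$prep_minutes <- 2
  if (!"model_name" %in% names(df)) df$model_name <- df$equipment_id
  need <- c("equipment_id", "purchase_price", "operating_cost", "total_revenue",
            "age_years", "expected_life_years", "power_on_minutes",
            "working_minutes", "rated_minutes", "failure_count",
            "mean_exam_minutes", "prep_minutes")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) stop(sprintf("profile missing fields: %s", paste(miss, collapse = ", ")))
  if (anyDuplicated(df$equipment_id)) stop("duplicate equipment ids in profile")
  num <- setdiff(need, "equipment_id")
  if (any(!is.finite(as.matrix(df[num])))) stop("profile contains missing values")
  if (any(df$expected_life_years <= 0)) stop("expected_life_years must be > 0")
  dur <- c("power_on_minutes", "working_minutes", "rated_minutes",
           "mean_exam_minutes", "prep_minutes", "age_years")
  if (any(as.matrix(df[dur]) < 0)) stop("durations must be >= 0")
  bad <- df$working_minutes > df$power_on_minutes + 1e-9
  if (any(bad)) {
    stop(sprintf("working_minutes exceeds power_on_minutes for %s",
                 paste(df$equipment_id[bad], collapse = ", ")))
  }
  class(df) <- c("equipment_profile", "data.frame")
  df
}

#' Read equipment profiles from CSV
#' @param path CSV with one row per device (fields of [equipment_profile()]).
#' @return An `equipment_profile` data.frame.
#' @export
read_profiles <- function(path) {
  equipment_profile(read.csv(path, stringsAsFactors = FALSE))
}

#' Construct an exam record table
#'
#' @param df A data.frame with columns `equipment_id`, `exam_start`,
#'   `exam_end` (POSIXct or ISO-8601 strings), `revenue` (>= 0) and
#'   optionally `scheduled_time` (NA when the exam was unscheduled).
#' @return A validated data.frame of class `exam_records`, timestamps as
#'   POSIXct (UTC).
#' @export
exam_records <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("equipment_id", "exam_start", "exam_end", "revenue")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) stop(sprintf("exam records missing fields: %s", paste(miss, collapse = ", ")))
  if (!"scheduled_time" %in% names(df)) df$scheduled_time <- NA
  to_time <- function(x) {
    if (inherits(x, "POSIXct")) return(x)
    as.POSIXct(as.character(x), tz = "UTC",
               tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d"))
  }
  df$exam_start <- to_time(df$exam_start)
  df$exam_end <- to_time(df$exam_end)
  sched_given <- !is.na(df$scheduled_time)
  sched <- .POSIXct(rep(NA_real_, nrow(df)), tz = "UTC")
  if (any(sched_given)) sched[sched_given] <- to_time(df$scheduled_time[sched_given])
  df$scheduled_time <- sched
  if (any(is.na(df$exam_start)) || any(is.na(df$exam_end))) {
    stop("unparseable exam_start/exam_end timestamp")
  }
  if (any(df$exam_end < df$exam_start)) stop("exam_end before exam_start")
  if (any(!is.finite(df$revenue)) || any(df$revenue < 0)) stop("revenue must be >= 0")
  class(df) <- c("exam_records", "data.frame")
  df
}

#' Read exam records from CSV
#' @param path CSV with columns of [exam_records()]; ISO-8601 timestamps.
#' @return An `exam_records` data.frame.
#' @export
read_exams <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if ("scheduled_time" %in% names(df)) df$scheduled_time[df$scheduled_time == ""] <- NA
  exam_records(df)
}
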