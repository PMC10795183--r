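# Cross-method agreement: Kendall's coefficient of concordance W with
# its chi-square test, per-method rank averages and medians, and a
# Pearson correlation report over indicator columns.

#' Kendall's coefficient of concordance across ranking methods
#'
#' Each block (by default, each device) ranks the k treatments (the
#' methods' scores) ascending, ties averaged.  Then
#' `W = 12 * S / (n^2 * (k^3 - k))` with `S` the sum of squared
#' deviations of the treatment rank sums from their mean,
#' `chi2 = n * (k - 1) * W`, and the p-value is the chi-square upper
#' tail with `k - 1` degrees of freedom.
#'
#' The default orientation treats the rows of `scores` as blocks
#' (devices) ranking the columns (methods) — the "k related samples"
#' convention.  `transpose = TRUE` swaps the roles.
#'
#' @param scores Numeric matrix, blocks x treatments (devices x
#'   methods), no missing values.
#' @param transpose If `TRUE`, treat methods as blocks ranking devices.
#' @param tie_correction If `TRUE`, apply the tie-correction term
#'   `n * sum(t^3 - t)` in the denominator.
#' @return List of class `concordance_result`: `W`, `chi2`, `df`,
#'   `p_value`, `rank_matrix` (blocks x treatments), `rank_averages`
#'   and `medians` per treatment, `n_blocks`, `k_treatments`.
#' @export
kendall_w <- function(scores, transpose = FALSE, tie_correction = FALSE) {
  scores <- as.matrix(scores)
  if (transpose) scores <- t(scores)
  if (any(!is.finite(scores))) stop("scores contain missing values")
  n <- nrow(scores)
  k <- ncol(scores)
  if (n < 2 || k < 2) stop("need at least 2 blocks and 2 treatments")
  rank_matrix <- t(apply(scores, 1, rank, ties.method = "average"))
  dimnames(rank_matrix) <- dimnames(scores)
  Rj <- colSums(rank_matrix)
  S <- sum((Rj - n * (k + 1) / 2)^2)
  denom <- n^2 * (k^3 - k)
  if (tie_correction) {
    Tcorr <- sum(apply(rank_matrix, 1, function(r) {
      t <- table(r)
      sum(t^3 - t)
    }))
    denom <- denom - n * Tcorr
  }
  if (denom <= 0) stop("degenerate ranks: tie correction exhausts the denominator")
  W <- 12 * S / denom
  chi2 <- n * (k - 1) * W
  structure(list(
    W = W, chi2 = chi2, df = k - 1,
    p_value = pchisq(chi2, df = k - 1, lower.tail = FALSE),
    rank_matrix = rank_matrix,
    rank_averages = colMeans(rank_matrix),
    medians = apply(scores, 2, median),
    n_blocks = n, k_treatments = k
  ), class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("Kendall's W = %.3f  (chi2 = %.3f, df = %d, p = %.3g)\n",
              x$W, x$chi2, x$df, x$p_value))
  cat("Rank averages:\n")
  print(round(x$rank_averages, 3))
  cat("Medians:\n")
  print(round(x$medians, 3))
  invisible(x)
}

#' Per-method rank averages and score medians
#'
#' @inheritParams kendall_w
#' @return Data.frame with one row per treatment: `rank_average` (mean
#'   within-block rank) and `median` (median score).
#' @export
method_summaries <- function(scores, transpose = FALSE) {
  cw <- kendall_w(scores, transpose = transpose)
  data.frame(method = names(cw$rank_averages) %||% seq_along(cw$rank_averages),
             rank_average = unname(cw$rank_averages),
             median = unname(cw$medians),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pearson correlation report over indicator columns
#'
#' Pairwise Pearson correlations of the raw indicator columns of a
#' decision matrix; zero-variance columns are flagged `NA` rather than
#' failing the whole report.
#'
#' @param matrix A [decision_matrix()] with >= 3 rows.
#' @return List with `correlations` (symmetric, unit diagonal, `NA` for
#'   undefined pairs), `undefined` (ids of zero-variance columns) and
#'   `signs` (sign matrix of the correlations).
#' @export
pearson_report <- function(matrix) {
  stopifnot(inherits(matrix, "decision_matrix"))
  x <- matrix$values
  if (nrow(x) < 3) stop("correlation report needs at least 3 equipment rows")
  sds <- apply(x, 2, sd)
  undef <- colnames(x)[sds == 0]
  r <- suppressWarnings(cor(x))
  r[undef, ] <- NA
  r[, undef] <- NA
  d <- diag(r)
  d[!(colnames(x) %in% undef)] <- 1
  diag(r) <- d
  list(correlations = r, undefined = undef, signs = sign(r))
}
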