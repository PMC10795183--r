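# Expert-opinion weighting by the combined ordered weighted averaging
# (COWA) operator: scores are sorted, then averaged under binomial
# position weights, which damps extreme opinions at either end.

#' COWA position weights
#'
#' Binomial position weights for `n` sorted scores:
#' `theta[j+1] = choose(n-1, j) / 2^(n-1)`, `j = 0..n-1`.  Symmetric and
#' summing to 1; the middle positions carry the most weight.
#'
#' @param n_experts Number of experts (>= 1).
#' @return Numeric vector of length `n_experts`.
#' @export
#' @examples
#' cowa_position_weights(8) * 128  # the binomial row 1 7 21 35 35 21 7 1
cowa_position_weights <- function(n_experts) {
  if (length(n_experts) != 1 || is.na(n_experts) || n_experts < 1 ||
      n_experts != round(n_experts)) {
    stop("n_experts must be a positive integer")
  }
  n <- as.integer(n_experts)
  choose(n - 1, 0:(n - 1)) / 2^(n - 1)
}

#' COWA absolute weight of one indicator
#'
#' Sorts the expert scores descending and takes the position-weighted
#' sum.  The weighted contribution of each sorted position is exposed so
#' the damping of extreme scores can be inspected.
#'
#' @param scores Numeric expert scores for one indicator, each in
#'   \[0, 10\].
#' @return List with `absolute_weight` (the position-weighted sum, a
#'   convex combination of the scores), `sorted_scores` and
#'   `contributions` (`theta[j+1] * b[j]` per sorted position).
#' @export
#' @examples
#' cowa_absolute_weight(c(9, 8, 8, 8, 8, 7, 7, 6))$contributions
cowa_absolute_weight <- function(scores) {
  if (length(scores) == 0) stop("empty score vector")
  if (any(!is.finite(scores))) stop("scores contain missing values")
  if (any(scores < 0 | scores > 10)) stop("scores must lie in [0, 10]")
  b <- unname(sort(scores, decreasing = TRUE, method = "radix")) # stable
  theta <- cowa_position_weights(length(scores))
  contrib <- theta * b
  list(absolute_weight = sum(contrib), sorted_scores = b, contributions = contrib)
}

#' COWA weights for an expert panel
#'
#' Applies [cowa_absolute_weight()] to each indicator column and
#' normalizes the absolute weights to sum to 1.
#'
#' @param panel An [expert_panel()] (experts x indicators).
#' @return A [weight_vector()] with `method = "cowa"`; the per-indicator
#'   absolute weights and contribution vectors are attached as
#'   attributes `absolute_weights` and `contributions`.
#' @export
cowa_weights <- function(panel) {
  panel <- expert_panel(panel)
  if (ncol(panel) < 2) stop("need at least 2 indicators")
  per_col <- lapply(seq_len(ncol(panel)), function(j) cowa_absolute_weight(panel[, j]))
  absw <- vapply(per_col, `[[`, numeric(1), "absolute_weight")
  names(absw) <- colnames(panel)
  if (sum(absw) <= 0) stop("degenerate panel: all absolute weights are zero")
  wv <- weight_vector(absw / sum(absw), method = "cowa")
  attr(wv, "absolute_weights") <- absw
  attr(wv, "contributions") <- setNames(lapply(per_col, `[[`, "contributions"),
                                        colnames(panel))
  wv
}
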