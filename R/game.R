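# Game-theoretic combination weighting: find the convex mix of L
# candidate weight vectors that compromises between them by solving the
# pairwise-dot-product normal system, then normalizing the combination
# coefficients to sum to 1.

#' Combine weight vectors by game-theoretic combination weighting
#'
#' Solves the L x L linear system `A lambda = b` with
#' `A[j,k] = W_j . W_k` and `b[j] = W_j . W_j` (the first-order
#' optimality system of the combination-weighting compromise), then
#' normalizes `lambda` to sum to 1 and returns
#' `W* = sum_k lambda*_k W_k`.  Negative coefficients are clipped to 0
#' and renormalized (with a warning) so the result stays a convex
#' combination; a singular system (e.g. identical inputs) falls back to
#' equal coefficients with a warning.
#'
#' @param ... Two or more [weight_vector()]s over the same indicator
#'   set, or a single list of them.
#' @return A [weight_vector()] with `method = "game"`; attributes
#'   `lambda_raw` (system solution) and `lambda` (normalized, clipped
#'   coefficients).
#' @export
#' @examples
#' w1 <- weight_vector(c(a = 0.8, b = 0.2), "cowa")
#' w2 <- weight_vector(c(a = 0.2, b = 0.8), "pca")
#' attr(combine_weights(w1, w2), "lambda")
combine_weights <- function(...) {
  inputs <- list(...)
  if (length(inputs) == 1 && is.list(inputs[[1]]) && !inherits(inputs[[1]], "weight_vector")) {
    inputs <- inputs[[1]]
  }
  L <- length(inputs)
  if (L < 2) stop("need at least 2 weight vectors to combine")
  for (w in inputs) {
    if (!inherits(w, "weight_vector")) stop("all inputs must be weight_vector objects")
  }
  ids <- inputs[[1]]$indicator_ids
  for (w in inputs[-1]) {
    if (!setequal(w$indicator_ids, ids)) stop("mismatched indicator sets")
  }
  W <- t(vapply(inputs, function(w) w$weights[ids], numeric(length(ids)))) # L x n
  A <- W %*% t(W)
  b <- diag(A)
  lambda_raw <- tryCatch(
    as.vector(solve(A, b)),
    error = function(e) NULL
  )
  if (is.null(lambda_raw) || rcond(A) < 1e-12) {
    warning("singular coefficient system (near-identical inputs); using equal coefficients")
    lambda_raw <- rep(1 / L, L)
  }
  if (sum(lambda_raw) <= 0) {
    warning("non-positive coefficient sum; using equal coefficients")
    lambda_raw <- rep(1 / L, L)
  }
  lambda <- lambda_raw / sum(lambda_raw)
  if (any(lambda < 0)) {
    warning("negative combination coefficient clipped to 0")
    lambda <- pmax(lambda, 0)
    lambda <- lambda / sum(lambda)
  }
  combined <- as.vector(t(W) %*% lambda)
  names(combined) <- ids
  combined <- combined / sum(combined) # guard roundoff
  out <- weight_vector(combined, method = "game")
  attr(out, "lambda_raw") <- lambda_raw
  attr(out, "lambda") <- lambda
  attr(out, "input_methods") <- vapply(inputs, `[[`, character(1), "method")
  out
}

# Total squared deviation of a combined vector from each input;
# the compromise objective the combination is judged against.
combination_objective <- function(combined, inputs) {
  ids <- combined$indicator_ids
  sum(vapply(inputs, function(w) sum((combined$weights[ids] - w$weights[ids])^2),
             numeric(1)))
}
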