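# Objective indicator weighting by principal component analysis:
# direction-aware min-max normalization, Pearson correlation matrix,
# eigendecomposition with a retention policy, then a variance-weighted
# loading score per indicator, normalized into weights.

#' Direction-aware min-max normalization
#'
#' Benefit columns map to `(x - min) / (max - min)`, cost columns to
#' `(max - x) / (max - min)`, so larger normalized values always mean
#' better performance.  A constant column is set to 0.5 everywhere with
#' a warning (it carries no ranking information either way).
#'
#' @param matrix A [decision_matrix()].
#' @return Numeric matrix of the same shape with values in \[0, 1\].
#' @export
minmax_normalize <- function(matrix) {
  stopifnot(inherits(matrix, "decision_matrix"))
  x <- matrix$values
  out <- x
  for (j in seq_len(ncol(x))) {
    rng <- range(x[, j])
    if (rng[1] == rng[2]) {
      warning(sprintf("constant column %s normalized to 0.5", colnames(x)[j]))
      out[, j] <- 0.5
    } else if (matrix$directions[j] == "benefit") {
      out[, j] <- (x[, j] - rng[1]) / (rng[2] - rng[1])
    } else {
      out[, j] <- (rng[2] - x[, j]) / (rng[2] - rng[1])
    }
  }
  out
}

# z-score normalization with the same direction handling (cost columns
# negated before standardizing); exposed through pca_weights(normalization=).
zscore_normalize <- function(matrix) {
  stopifnot(inherits(matrix, "decision_matrix"))
  x <- matrix$values
  sgn <- ifelse(matrix$directions == "benefit", 1, -1)
  x <- sweep(x, 2, sgn, `*`)
  out <- scale(x)
  const <- attr(out, "scaled:scale") == 0 | !is.finite(attr(out, "scaled:scale"))
  if (any(const)) {
    warning(sprintf("constant column %s set to 0",
                    paste(colnames(x)[const], collapse = ", ")))
    out[, const] <- 0
  }
  out <- out[, , drop = FALSE]
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  out
}

#' Pearson correlation matrix of indicator columns
#'
#' @param normalized Numeric matrix (equipment x indicators), >= 3 rows.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
indicator_correlations <- function(normalized) {
  normalized <- as.matrix(normalized)
  if (nrow(normalized) < 3) stop("correlations need at least 3 equipment rows")
  sds <- apply(normalized, 2, sd)
  if (any(sds == 0)) {
    stop(sprintf("zero-variance column(s): %s",
                 paste(colnames(normalized)[sds == 0], collapse = ", ")))
  }
  r <- cor(normalized)
  diag(r) <- 1
  r
}

#' Eigendecompose a correlation matrix and choose components to retain
#'
#' @param R Symmetric correlation matrix.
#' @param retention Retention policy: `"cumulative"` keeps the smallest
#'   p whose cumulative variance share reaches `threshold`; `"kaiser"`
#'   keeps eigenvalues >= 1; `"fixed"` keeps exactly `p`.
#' @param threshold Cumulative variance threshold (default 0.85).
#' @param p Component count for `retention = "fixed"`.
#' @return List with `eigenvalues` (descending), `loadings` (indicators
#'   x components), `variance_contribution` (shares `a_j` summing to 1),
#'   `cumulative_contribution`, and `n_retained`.
#' @export
eigendecompose_and_retain <- function(R, retention = c("cumulative", "kaiser", "fixed"),
                                      threshold = 0.85, p = NULL) {
  retention <- match.arg(retention)
  R <- as.matrix(R)
  if (!isSymmetric(R, tol = 1e-8)) stop("correlation matrix must be symmetric")
  eg <- eigen(R, symmetric = TRUE)
  lambda <- pmax(eg$values, 0) # tiny negatives from roundoff
  a <- lambda / sum(lambda)
  cum <- cumsum(a)
  n_ret <- switch(retention,
    cumulative = which(cum >= threshold - 1e-12)[1],
    kaiser = max(1L, sum(lambda >= 1)),
    fixed = {
      if (is.null(p) || p < 1 || p > length(lambda)) stop("fixed retention needs 1 <= p <= n")
      as.integer(p)
    }
  )
  loadings <- eg$vectors
  rownames(loadings) <- colnames(R)
  colnames(loadings) <- paste0("PC", seq_len(ncol(loadings)))
  list(eigenvalues = lambda, loadings = loadings,
       variance_contribution = a, cumulative_contribution = cum,
       n_retained = n_ret)
}

#' Indicator scores and weights from retained loadings
#'
#' Each indicator's score is the variance-share-weighted mean of its
#' absolute loadings over the retained components, renormalized by the
#' cumulative variance retained:
#' `score_i = sum_j(a_j * |c_ij|) / sum_j(a_j)` for `j <= p`; weights
#' are the scores normalized to sum to 1.  Absolute values make the
#' result invariant to the sign indeterminacy of eigenvectors.
#'
#' @param loadings Indicators x components matrix (at least `p` columns).
#' @param variance_contribution Variance shares `a_j` per component.
#' @param p Number of retained components.
#' @return List with `scores` (named) and `weights` (a [weight_vector()]
#'   with `method = "pca"`).
#' @export
pca_scores_and_weights <- function(loadings, variance_contribution, p) {
  loadings <- as.matrix(loadings)
  if (p < 1 || p > ncol(loadings)) stop("p out of range")
  a <- variance_contribution[seq_len(p)]
  L <- abs(loadings[, seq_len(p), drop = FALSE])
  if (all(L == 0)) stop("all retained loadings are zero")
  scores <- as.vector(L %*% a) / sum(a)
  names(scores) <- rownames(loadings)
  if (sum(scores) <= 0) stop("degenerate loadings: zero total score")
  list(scores = scores,
       weights = weight_vector(scores / sum(scores), method = "pca"))
}

#' PCA-based indicator weights from a decision matrix
#'
#' Full chain: normalize, correlate, eigendecompose, retain, score.
#'
#' @param matrix A [decision_matrix()] with >= 3 equipment rows.
#' @param retention,threshold,p Passed to [eigendecompose_and_retain()].
#' @param normalization `"minmax"` (direction-aware, the default) or
#'   `"zscore"`.
#' @return A [weight_vector()] with `method = "pca"`; the full
#'   decomposition is attached as attribute `pca` (normalized matrix,
#'   correlation matrix, eigenvalues, loadings, variance shares,
#'   retained count, indicator scores).
#' @export
pca_weights <- function(matrix, retention = "cumulative", threshold = 0.85,
                        p = NULL, normalization = c("minmax", "zscore")) {
  normalization <- match.arg(normalization)
  norm <- if (normalization == "minmax") minmax_normalize(matrix) else zscore_normalize(matrix)
  # re-center degenerate 0.5 columns would be zero-variance; drop them from
  # the correlation with an upstream error is unhelpful for weighting, so
  # give them a vanishing jitter-free treatment: a constant column gets
  # zero correlation with everything by convention.
  sds <- apply(norm, 2, sd)
  if (any(sds == 0)) {
    R <- diag(ncol(norm))
    dimnames(R) <- list(colnames(norm), colnames(norm))
    live <- sds > 0
    if (sum(live) >= 2 && nrow(norm) >= 3) {
      R[live, live] <- indicator_correlations(norm[, live, drop = FALSE])
    }
  } else {
    R <- indicator_correlations(norm)
  }
  dec <- eigendecompose_and_retain(R, retention = retention, threshold = threshold, p = p)
  sw <- pca_scores_and_weights(dec$loadings, dec$variance_contribution, dec$n_retained)
  wv <- sw$weights
  attr(wv, "pca") <- c(list(normalized = norm, correlation = R,
                            indicator_scores = sw$scores), dec)
  wv
}
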