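# GRA-TOPSIS fusion ranking plus plain GRA, plain TOPSIS and VIKOR
# comparators.  All methods work on the direction-adjusted min-max
# normalized matrix, where larger values always mean better performance;
# "replace first" is then read off by the fusion orientation (far from
# the best-performing ideal, close to the worst-performing one).

#' Weighted normalized decision matrix
#'
#' `s_ij = w_j * z_ij` with `z` the direction-aware min-max normalized
#' matrix, so each column's maximum equals its weight.
#'
#' @param matrix A [decision_matrix()].
#' @param weights A [weight_vector()] covering the matrix columns.
#' @return Numeric matrix `S` (equipment x indicators).
#' @export
weighted_normalized_matrix <- function(matrix, weights) {
  stopifnot(inherits(matrix, "decision_matrix"), inherits(weights, "weight_vector"))
  cols <- colnames(matrix$values)
  if (!setequal(cols, weights$indicator_ids)) {
    stop("weights do not match decision-matrix columns")
  }
  z <- minmax_normalize(matrix)
  sweep(z, 2, weights$weights[cols], `*`)
}

#' Euclidean distances to the ideal solutions
#'
#' The positive ideal takes each column's maximum (best-performing
#' profile), the negative ideal the minimum.
#'
#' @param S Weighted normalized matrix.
#' @return List with `d_pos`, `d_neg` (per-equipment distances) and
#'   `ideal_pos`, `ideal_neg` (the ideal rows).
#' @export
euclidean_distances <- function(S) {
  S <- as.matrix(S)
  if (nrow(S) < 2) stop("need at least 2 equipment rows")
  sp <- apply(S, 2, max)
  sn <- apply(S, 2, min)
  list(
    d_pos = sqrt(rowSums(sweep(S, 2, sp)^2)),
    d_neg = sqrt(rowSums(sweep(S, 2, sn)^2)),
    ideal_pos = sp, ideal_neg = sn
  )
}

#' Gray relational coefficient matrices
#'
#' For each entry, `h_ij = (Dmin + rho * Dmax) / (D_ij + rho * Dmax)`
#' where `D_ij = |s_j(ideal) - s_ij|` and `Dmin`/`Dmax` are the global
#' extremes of that deviation matrix; computed against both the
#' positive and the negative ideal.  With `Dmin = 0` the coefficients
#' lie in `[rho/(1+rho), 1]`.
#'
#' @param S Weighted normalized matrix.
#' @param rho Resolution factor in (0, 1], default 0.5.
#' @return List with matrices `h_pos`, `h_neg`.
#' @export
gray_coefficients <- function(S, rho = 0.5) {
  if (rho <= 0 || rho > 1) stop("rho must lie in (0, 1]")
  S <- as.matrix(S)
  coeff <- function(ideal) {
    D <- abs(sweep(-S, 2, ideal, `+`))
    dmax <- max(D)
    if (dmax == 0) {
      warning("all rows identical: gray coefficients degenerate to 1")
      return(array(1, dim(S), dimnames(S)))
    }
    dmin <- min(D)
    (dmin + rho * dmax) / (D + rho * dmax)
  }
  sp <- apply(S, 2, max)
  sn <- apply(S, 2, min)
  list(h_pos = coeff(sp), h_neg = coeff(sn))
}

#' Gray relational degrees
#'
#' Row-aggregates of the coefficient matrices.  With
#' `weighting = "weights"` (the default) the indicator weights enter a
#' second time (they are already inside `S`); `"uniform"` takes the
#' plain row mean.  Either way the degree is a convex combination of
#' the row's coefficients.
#'
#' @param h Coefficient matrix (`h_pos` or `h_neg`).
#' @param weights A [weight_vector()] (ignored under
#'   `weighting = "uniform"`).
#' @param weighting `"weights"` or `"uniform"`.
#' @return Per-equipment degrees.
#' @export
gray_degrees <- function(h, weights = NULL, weighting = c("weights", "uniform")) {
  weighting <- match.arg(weighting)
  h <- as.matrix(h)
  if (weighting == "uniform") return(rowMeans(h))
  if (is.null(weights)) stop("weights required unless weighting = 'uniform'")
  w <- weights$weights[colnames(h)]
  if (any(is.na(w))) stop("weights do not cover all columns")
  as.vector(h %*% w)
}

#' Normalize distance and relation measures by their own maxima
#'
#' @param d_pos,d_neg,l_pos,l_neg Per-equipment vectors.
#' @return List `D_pos`, `D_neg`, `L_pos`, `L_neg`, each divided by its
#'   maximum (so every vector has maximum 1).
#' @export
normalize_measures <- function(d_pos, d_neg, l_pos, l_neg) {
  one <- function(v, nm) {
    m <- max(v)
    if (m <= 0) stop(sprintf("%s has non-positive maximum; cannot normalize", nm))
    v / m
  }
  list(D_pos = one(d_pos, "d_pos"), D_neg = one(d_neg, "d_neg"),
       L_pos = one(l_pos, "l_pos"), L_neg = one(l_neg, "l_neg"))
}

#' Fuse normalized distances and gray relations into decision factors
#'
#' Under the default `orientation = "priority"`,
#' `T+ = a1*D+ + a2*L-` and `T- = a1*D- + a2*L+`: a device far from the
#' best-performing ideal and closely related to the worst-performing
#' one accumulates `T+`, so a larger decision factor
#' `xi = T+ / (T+ + T-)` means replace sooner.
#' `orientation = "proximity"` swaps the two aggregates (closeness to
#' the good ideal scores high); the two orientations are complementary:
#' `xi_priority + xi_proximity = 1`.
#'
#' @param D_pos,D_neg,L_pos,L_neg Normalized measures from
#'   [normalize_measures()].
#' @param alpha1,alpha2 Preference weights for distance vs relation;
#'   must be positive and sum to 1 (default 0.5 each).
#' @param orientation `"priority"` (default) or `"proximity"`.
#' @return List with `xi`, `T_pos`, `T_neg`.
#' @export
#' @examples
#' fuse(1.000, 0.646, 0.873, 1.000)$xi # 0.568...
fuse <- function(D_pos, D_neg, L_pos, L_neg, alpha1 = 0.5, alpha2 = 0.5,
                 orientation = c("priority", "proximity")) {
  orientation <- match.arg(orientation)
  if (abs(alpha1 + alpha2 - 1) > 1e-9 || alpha1 <= 0 || alpha2 <= 0 ||
      alpha1 >= 1 || alpha2 >= 1) {
    stop("alpha1, alpha2 must lie in (0, 1) and sum to 1")
  }
  if (orientation == "priority") {
    T_pos <- alpha1 * D_pos + alpha2 * L_neg
    T_neg <- alpha1 * D_neg + alpha2 * L_pos
  } else {
    T_pos <- alpha1 * D_neg + alpha2 * L_pos
    T_neg <- alpha1 * D_pos + alpha2 * L_neg
  }
  tot <- T_pos + T_neg
  if (any(tot == 0)) stop("degenerate fusion: T+ + T- is zero")
  list(xi = T_pos / tot, T_pos = T_pos, T_neg = T_neg)
}

#' GRA-TOPSIS fusion ranking
#'
#' Full chain: weighted normalized matrix, Euclidean distances to the
#' ideals, gray relational degrees to the ideals, own-max normalization
#' of the four measures, and the fused replacement decision factor.
#' Rank 1 = replace first.
#'
#' @param matrix A [decision_matrix()].
#' @param weights A [weight_vector()].
#' @param rho Gray resolution factor (default 0.5).
#' @param alpha1,alpha2 Fusion preferences (default 0.5 / 0.5).
#' @param orientation See [fuse()].
#' @param gray_degree_weighting See [gray_degrees()].
#' @return A [ranking_result()] with `method = "gra_topsis"`; the
#'   diagnostics attribute carries S, d/D, l/L, H matrices, T and the
#'   parameters.
#' @export
rank_gra_topsis <- function(matrix, weights, rho = 0.5,
                            alpha1 = 0.5, alpha2 = 0.5,
                            orientation = "priority",
                            gray_degree_weighting = "weights") {
  S <- weighted_normalized_matrix(matrix, weights)
  dd <- euclidean_distances(S)
  H <- gray_coefficients(S, rho = rho)
  l_pos <- gray_degrees(H$h_pos, weights, weighting = gray_degree_weighting)
  l_neg <- gray_degrees(H$h_neg, weights, weighting = gray_degree_weighting)
  nm <- normalize_measures(dd$d_pos, dd$d_neg, l_pos, l_neg)
  fz <- fuse(nm$D_pos, nm$D_neg, nm$L_pos, nm$L_neg,
             alpha1 = alpha1, alpha2 = alpha2, orientation = orientation)
  ranking_result(
    rownames(matrix$values), fz$xi, "gra_topsis",
    diagnostics = list(
      S = S, d_pos = dd$d_pos, d_neg = dd$d_neg,
      h_pos = H$h_pos, h_neg = H$h_neg,
      l_pos = l_pos, l_neg = l_neg,
      D_pos = nm$D_pos, D_neg = nm$D_neg, L_pos = nm$L_pos, L_neg = nm$L_neg,
      T_pos = fz$T_pos, T_neg = fz$T_neg,
      rho = rho, alpha1 = alpha1, alpha2 = alpha2,
      orientation = orientation, gray_degree_weighting = gray_degree_weighting
    )
  )
}

#' Plain GRA ranking
#'
#' Gray relational degree of each device to the replacement reference
#' row (the worst-performing, i.e. negative, ideal of the weighted
#' normalized matrix): the device most resembling the run-down
#' archetype scores highest and is replaced first.
#'
#' @inheritParams rank_gra_topsis
#' @return A [ranking_result()] with `method = "gra"`.
#' @export
rank_gra <- function(matrix, weights, rho = 0.5,
                     gray_degree_weighting = "weights") {
  S <- weighted_normalized_matrix(matrix, weights)
  H <- gray_coefficients(S, rho = rho)
  score <- gray_degrees(H$h_neg, weights, weighting = gray_degree_weighting)
  ranking_result(rownames(matrix$values), score, "gra",
                 diagnostics = list(S = S, h_neg = H$h_neg, rho = rho))
}

#' Plain TOPSIS ranking
#'
#' Relative closeness to the worst-performing ideal,
#' `score = d+ / (d+ + d-)`: the device farthest from the
#' best-performing profile scores highest and is replaced first.
#'
#' @inheritParams rank_gra_topsis
#' @return A [ranking_result()] with `method = "topsis"`.
#' @export
rank_topsis <- function(matrix, weights) {
  S <- weighted_normalized_matrix(matrix, weights)
  dd <- euclidean_distances(S)
  tot <- dd$d_pos + dd$d_neg
  if (any(tot == 0)) stop("degenerate matrix: identical rows give zero total distance")
  score <- dd$d_pos / tot
  ranking_result(rownames(matrix$values), score, "topsis",
                 diagnostics = list(S = S, d_pos = dd$d_pos, d_neg = dd$d_neg))
}

#' VIKOR compromise ranking
#'
#' Standard VIKOR on the direction-adjusted normalized matrix, oriented
#' so that the replacement-priority sense is "best": the group utility
#' `S_i` and individual regret `R_i` measure how far each device sits
#' from the most-replacement-worthy (worst-performing) profile, and the
#' compromise index `Q_i = v*(S_i - S*)/(S- - S*) +
#' (1 - v)*(R_i - R*)/(R- - R*)` is ranked ascending: `Q = 0` means
#' replace first.
#'
#' @inheritParams rank_gra_topsis
#' @param v Weight of group utility vs individual regret (default 0.5).
#' @return A [ranking_result()] with `method = "vikor"` (scores = Q,
#'   ascending ranks); diagnostics carry S_i and R_i.
#' @export
rank_vikor <- function(matrix, weights, v = 0.5) {
  stopifnot(inherits(matrix, "decision_matrix"), inherits(weights, "weight_vector"))
  if (v < 0 || v > 1) stop("v must lie in [0, 1]")
  z <- minmax_normalize(matrix)
  w <- weights$weights[colnames(z)]
  if (any(is.na(w))) stop("weights do not match decision-matrix columns")
  # replacement-best value per column = worst performance (min z);
  # per-column regret (z - min)/(max - min) = z itself after min-max,
  # but recompute from the column range for generality.
  reg <- z
  for (j in seq_len(ncol(z))) {
    rng <- range(z[, j])
    reg[, j] <- if (rng[2] > rng[1]) (z[, j] - rng[1]) / (rng[2] - rng[1]) else 0
  }
  Si <- as.vector(reg %*% w)
  Ri <- apply(sweep(reg, 2, w, `*`), 1, max)
  qpart <- function(x) {
    rng <- range(x)
    if (rng[2] == rng[1]) return(rep(0, length(x)))
    (x - rng[1]) / (rng[2] - rng[1])
  }
  if (max(Si) == min(Si) && max(Ri) == min(Ri)) {
    warning("all devices equivalent: VIKOR Q identically 0")
  }
  Q <- v * qpart(Si) + (1 - v) * qpart(Ri)
  ranking_result(rownames(matrix$values), Q, "vikor", ascending = TRUE,
                 diagnostics = list(S_i = Si, R_i = Ri, v = v))
}
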