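uniform_weights <- function(ids = indicator_ids()) {
  weight_vector(setNames(rep(1 / length(ids), length(ids)), ids), "uniform")
}

test_that("weighted normalized matrix has column maxima equal to the weights", {
  dm <- random_decision_matrix(m = 6, seed = 1)
  w <- random_weights(seed = 2)
  S <- weighted_normalized_matrix(dm, w)
  expect_equal(apply(S, 2, max), w$weights[colnames(S)])
  expect_equal(apply(S, 2, min), setNames(rep(0, 9), colnames(S)))
  # unit weights reproduce the normalized matrix
  ones <- uniform_weights()
  expect_equal(weighted_normalized_matrix(dm, ones),
               minmax_normalize(dm) / 9)
  expect_error(weighted_normalized_matrix(dm, weight_vector(c(a = 1), "x")),
               "do not match")
})

test_that("Euclidean distances match the direct formula and its edge cases", {
  withr::with_seed(8, {
    S <- matrix(runif(24), 6, 4)
    dd <- euclidean_distances(S)
    sp <- apply(S, 2, max); sn <- apply(S, 2, min)
    for (i in 1:6) {
      expect_equal(dd$d_pos[i], sqrt(sum((S[i, ] - sp)^2)))
      expect_equal(dd$d_neg[i], sqrt(sum((S[i, ] - sn)^2)))
    }
  })
  # one all-max row and one all-min row sit at distance ||w|| from each other
  w <- c(0.6, 0.4)
  S2 <- rbind(w, c(0, 0))
  dd2 <- euclidean_distances(S2)
  expect_equal(unname(dd2$d_pos), c(0, sqrt(sum(w^2))))
  expect_equal(unname(dd2$d_neg), c(sqrt(sum(w^2)), 0))
})

test_that("gray coefficients hit their bounds and stay within them", {
  S <- rbind(c(0.5, 0.3), c(0.2, 0.1), c(0.35, 0.22))
  H <- gray_coefficients(S, rho = 0.5)
  # the row attaining an ideal column has coefficient 1 there (global Dmin = 0)
  expect_equal(H$h_pos[1, 1], 1)
  expect_equal(H$h_neg[2, 2], 1)
  # the largest deviation attains the lower bound 1/3 at rho = 0.5
  expect_equal(min(H$h_pos), 1 / 3)
  withr::with_seed(12, {
    S3 <- matrix(runif(40), 8, 5)
    H3 <- gray_coefficients(S3, rho = 0.5)
    expect_true(all(H3$h_pos >= 1 / 3 - 1e-12 & H3$h_pos <= 1))
    expect_true(all(H3$h_neg >= 1 / 3 - 1e-12 & H3$h_neg <= 1))
  })
  msgs <- testthat::capture_warnings(Hd <- gray_coefficients(matrix(0.4, 3, 2)))
  expect_match(msgs, "identical", all = TRUE)
  expect_true(all(Hd$h_pos == 1))
  expect_error(gray_coefficients(S, rho = 0), "rho")
})

test_that("gray degrees are convex combinations of the row coefficients", {
  withr::with_seed(14, {
    H <- matrix(runif(27, 1 / 3, 1), 9, 3, dimnames = list(NULL, c("X11", "X12", "X13")))
    ids <- colnames(H)
    w <- weight_vector(setNames(c(0.5, 0.3, 0.2), ids), "custom")
    l <- gray_degrees(H, w)
    expect_equal(l, as.vector(H %*% c(0.5, 0.3, 0.2)))
    expect_true(all(l >= apply(H, 1, min) - 1e-12 & l <= apply(H, 1, max) + 1e-12))
    expect_equal(gray_degrees(H, weighting = "uniform"), rowMeans(H))
    expect_equal(gray_degrees(matrix(1, 4, 3, dimnames = list(NULL, ids)), w), rep(1, 4))
  })
})

test_that("measure normalization is scale invariant with unit maxima", {
  m <- ref$fusion_measures
  nm <- normalize_measures(m[, "D_pos"], m[, "D_neg"], m[, "L_pos"], m[, "L_neg"])
  expect_equal(max(nm$D_pos), 1)
  expect_equal(max(nm$D_neg), 1)
  expect_equal(max(nm$L_pos), 1)
  expect_equal(max(nm$L_neg), 1)
  nm2 <- normalize_measures(3 * m[, "D_pos"], 3 * m[, "D_neg"],
                            3 * m[, "L_pos"], 3 * m[, "L_neg"])
  expect_equal(nm2, nm)
  expect_equal(unname(normalize_measures(c(2, 2), c(1, 1), c(1, 1), c(1, 1))$D_pos),
               c(1, 1))
  expect_error(normalize_measures(c(0, 0), c(1, 1), c(1, 1), c(1, 1)), "d_pos")
})

test_that("fusing the published measures reproduces the published decision factors", {
  m <- ref$fusion_measures
  fz <- fuse(m[, "D_pos"], m[, "D_neg"], m[, "L_pos"], m[, "L_neg"])
  expect_equal(round(unname(fz$xi), 3), c(0.568, 0.433, 0.380, 0.424))
  expect_equal(rank(-fz$xi), setNames(c(1, 2, 4, 3), rownames(m)),
               ignore_attr = TRUE)
  # symmetry and duality
  sym <- fuse(0.7, 0.7, 0.4, 0.4)
  expect_equal(sym$xi, 0.5)
  prox <- fuse(m[, "D_pos"], m[, "D_neg"], m[, "L_pos"], m[, "L_neg"],
               orientation = "proximity")
  expect_equal(unname(fz$xi + prox$xi), rep(1, 4))
  expect_error(fuse(1, 1, 1, 1, alpha1 = 0.7, alpha2 = 0.5), "sum to 1")
})

test_that("full fusion ranking keeps xi in (0,1) and is weight-scale invariant", {
  dm <- random_decision_matrix(m = 5, seed = 21)
  w <- random_weights(seed = 22)
  r <- rank_gra_topsis(dm, w)
  expect_true(all(r$score > 0 & r$score < 1))
  expect_setequal(r$rank, 1:5)
  d <- attr(r, "diagnostics")
  expect_equal(max(d$D_pos), 1)
  expect_equal(max(d$L_neg), 1)
  expect_equal(unname(d$T_pos / (d$T_pos + d$T_neg)), r$score)
  # scaling raw weights before renormalization changes nothing
  w2 <- weight_vector(w$weights * 5 / sum(w$weights * 5), "custom")
  expect_equal(rank_gra_topsis(dm, w2)$score, r$score)
})

test_that("a dominated device is always ranked first for replacement", {
  withr::with_seed(33, {
    for (rep in 1:5) {
      vals <- matrix(runif(45, 2, 9), 5, 9,
                     dimnames = list(paste0("E", 1:5), indicator_ids()))
      # device E5 is strictly worst on the direction-adjusted reading:
      # lowest on benefit columns, highest on cost columns
      vals[5, 1:7] <- apply(vals[1:4, 1:7], 2, min) - runif(7, 0.5, 1)
      vals[5, 8:9] <- apply(vals[1:4, 8:9, drop = FALSE], 2, max) + runif(2, 0.5, 1)
      dm <- decision_matrix(vals)
      w <- random_weights(seed = 100 + rep)
      expect_equal(rank_gra_topsis(dm, w)$rank[5], 1)
      expect_equal(rank_gra(dm, w)$rank[5], 1)
      expect_equal(rank_topsis(dm, w)$rank[5], 1)
      expect_equal(rank_vikor(dm, w)$rank[5], 1)
      # dominance consistency for the fusion score: every other device
      # performs better, so E5 carries the largest xi
      xi <- rank_gra_topsis(dm, w)$score
      expect_true(all(xi[5] > xi[1:4]))
    }
  })
})

test_that("plain TOPSIS matches the direct formula and averages ties", {
  dm <- random_decision_matrix(m = 6, seed = 44)
  w <- random_weights(seed = 45)
  r <- rank_topsis(dm, w)
  S <- weighted_normalized_matrix(dm, w)
  sp <- apply(S, 2, max); sn <- apply(S, 2, min)
  dpos <- sqrt(rowSums(sweep(S, 2, sp)^2))
  dneg <- sqrt(rowSums(sweep(S, 2, sn)^2))
  expect_equal(r$score, unname(dpos / (dpos + dneg)))
  # duplicated row -> tied, averaged ranks
  vals <- dm$values
  vals[2, ] <- vals[1, ]
  r2 <- rank_topsis(decision_matrix(vals), w)
  expect_equal(r2$rank[1], r2$rank[2])
  expect_equal(sum(r2$rank), sum(1:6))
})

test_that("VIKOR matches a hand-computed 3x2 example and its boundary cases", {
  # raw values, both benefit columns; direction-adjusted z equals minmax:
  # A = (1, 1), B = (0, 0), C = (0.5, 0.25) with weights (0.6, 0.4)
  vals <- matrix(c(10, 8, 2, 4, 6, 5), 3, 2, byrow = TRUE,
                 dimnames = list(c("A", "B", "C"), c("X11", "X12")))
  w <- weight_vector(c(X11 = 0.6, X12 = 0.4), "custom")
  r <- rank_vikor(decision_matrix(vals), w, v = 0.5)
  d <- attr(r, "diagnostics")
  # S = w . z ; R = max_j w_j z_j  (distance from the replacement-best row B)
  expect_equal(unname(d$S_i), c(1.0, 0.0, 0.4))
  expect_equal(unname(d$R_i), c(0.6, 0.0, 0.3))
  # Q = 0.5*(S-0)/(1-0) + 0.5*(R-0)/(0.6-0)
  expect_equal(r$score, c(1.0, 0.0, 0.45))
  expect_equal(r$rank, c(3, 1, 2))
  # the uniformly worst performer gets Q = 0, the uniformly best Q = 1
  expect_equal(r$score[which.min(vals[, 1])], 0)
  expect_equal(r$score[which.max(vals[, 1])], 1)
})

test_that("methods agree on a matrix with a common dominance order", {
  # rows strictly ordered on every direction-adjusted column
  vals <- cbind(X11 = c(9, 6, 4, 1), X12 = c(8, 6, 4, 2), X41 = c(1, 3, 6, 9))
  rownames(vals) <- paste0("E", 1:4)
  dm <- decision_matrix(vals)
  w <- weight_vector(c(X11 = 0.4, X12 = 0.3, X41 = 0.3), "custom")
  expect_equal(rank_gra_topsis(dm, w)$rank, c(4, 3, 2, 1))
  expect_equal(rank_topsis(dm, w)$rank, c(4, 3, 2, 1))
  expect_equal(rank_gra(dm, w)$rank, c(4, 3, 2, 1))
  expect_equal(rank_vikor(dm, w)$rank, c(4, 3, 2, 1))
})
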