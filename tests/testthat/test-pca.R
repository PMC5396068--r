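# deterministic factories for matrices with a prescribed correlation
# spectrum: T has exactly uncorrelated, unit-variance, mean-zero columns
uncorrelated_scores <- function(n, k) {
  X <- matrix(stats::rnorm(n * k), n, k)
  X <- sweep(X, 2L, colMeans(X))
  sv <- svd(X)
  sqrt(n - 1) * sv$u[, seq_len(k), drop = FALSE]
}

spectrum_matrix <- function(n, lambda, seed = 1) {
  set.seed(seed)
  k <- length(lambda)
  T0 <- uncorrelated_scores(n, k)
  Q <- qr.Q(qr(matrix(stats::rnorm(k * k), k, k)))
  T0 %*% diag(sqrt(lambda)) %*% t(Q)
}

test_that("standardization: hand case, idempotence, zero-variance error", {
  V <- cbind(a = c(1, 2, 3), b = c(5, 1, 0))
  Z <- standardize_matrix(V)
  expect_equal(unname(Z[, "a"]), c(-1, 0, 1))
  expect_equal(colMeans(Z), c(a = 0, b = 0), tolerance = 1e-12)
  expect_equal(apply(Z, 2L, sd), c(a = 1, b = 1), tolerance = 1e-12)
  # idempotence
  expect_equal(unname(standardize_matrix(Z)), unname(Z), tolerance = 1e-12,
               ignore_attr = TRUE)
  # constant column names the property
  expect_error(standardize_matrix(cbind(ok = c(1, 2), flat = c(4, 4))),
               "flat")
})

test_that("PCA matches an independent eigendecomposition of the correlation matrix", {
  set.seed(401)
  for (rep in 1:5) {
    n <- sample(10:50, 1)
    V <- matrix(stats::rnorm(n * 6), n, 6)
    V[, 2] <- V[, 1] * 2 + stats::rnorm(n, sd = 1e-6)  # near-duplicated pair
    Z <- standardize_matrix(V)
    p <- pca_fragments(Z)
    o <- oracle_pca(Z)
    expect_equal(p$sdev, o$sdev, tolerance = 1e-8)
    expect_equal(unname(sign_align(p$loadings, o$loadings)),
                 unname(o$loadings), tolerance = 1e-8)
    # loadings are unit-norm; scores reconstruct Z through the rotation
    expect_equal(unname(colSums(p$loadings^2)), rep(1, 6), tolerance = 1e-10)
    expect_equal(unname(p$scores %*% t(p$loadings)), unname(Z),
                 tolerance = 1e-8, ignore_attr = TRUE)
    # proportions sum to one exactly
    expect_equal(sum(p$prop), 1, tolerance = 1e-12)
    # duplicated direction dominates
    expect_gt(p$prop[1], 1 / 3)
  }
  # isotropic case: uncorrelated unit-variance columns give 1/6 each
  Ziso <- uncorrelated_scores(40, 6)
  piso <- pca_fragments(Ziso)
  expect_equal(unname(piso$prop), rep(1 / 6, 6), tolerance = 1e-10)
})

test_that("retention and varimax: identity for one factor, conservation for two", {
  # spectrum with a single sd > 1 component
  Z1 <- spectrum_matrix(60, 6 * c(0.80, 0.04, 0.04, 0.04, 0.04, 0.04),
                        seed = 11)
  f1 <- retain_and_rotate(pca_fragments(Z1))
  expect_identical(f1$retained, 1L)
  expect_equal(unname(f1$rotmat), matrix(1, 1, 1))
  expect_identical(f1$chosen, 1L)
  expect_equal(unname(f1$weights), 1)
  # w = 1 collapse: L(i) = |f_1(i)|
  expect_equal(fragment_scores(f1), abs(as.vector(f1$scores_rot)),
               tolerance = 1e-12)

  # two retained components explaining 73% and 22%: both chosen as FLs
  Z2 <- spectrum_matrix(80, 6 * c(0.73, 0.22, 0.0125, 0.0125, 0.0125, 0.0125),
                        seed = 12)
  p2 <- pca_fragments(Z2)
  expect_equal(p2$prop[1:2], c(0.73, 0.22), tolerance = 1e-8)
  f2 <- retain_and_rotate(p2)
  expect_identical(f2$retained, 1:2)
  expect_identical(sort(f2$chosen), 1:2)
  expect_equal(sum(f2$var_share), 0.95, tolerance = 1e-8)
  # rotation is orthogonal and conserves the block's squared loadings
  expect_equal(crossprod(f2$rotmat), diag(2), tolerance = 1e-10,
               ignore_attr = TRUE)
  lam <- p2$loadings[, 1:2] %*% diag(p2$sdev[1:2])
  expect_equal(sum(f2$loadings_rot^2), sum(lam^2), tolerance = 1e-10)
  # varimax simplicity criterion does not decrease
  expect_gte(varimax_criterion(f2$loadings_rot) + 1e-12,
             varimax_criterion(lam))

  # nothing above the threshold is an error advising review
  Z3 <- uncorrelated_scores(40, 6) * 0.999
  expect_error(retain_and_rotate(pca_fragments(standardize_matrix(Z3)),
                                 sd_threshold = 3), "review")
})

test_that("fragment scores: null fragment, sign invariance, non-negativity", {
  # V with exact +/- row pairs plus a zero row: column means are 0, so the
  # null fragment keeps score 0 through standardization
  set.seed(402)
  B <- matrix(stats::rnorm(10 * 6), 10, 6)
  V <- rbind(B, -B, 0)
  sm <- thermodet:::score_matrix(V)
  expect_equal(sm$scores[21], 0, tolerance = 1e-10)
  expect_true(all(sm$scores >= 0))

  # flipping the sign of any component's loadings and scores leaves L unchanged
  f <- sm$fls
  for (j in seq_along(f$chosen)) {
    f2 <- f
    f2$scores_rot[, f$chosen[j]] <- -f2$scores_rot[, f$chosen[j]]
    expect_equal(fragment_scores(f2), fragment_scores(f), tolerance = 1e-12)
  }
})

test_that("candidate detection: identical groups yield none; small n_perm warns", {
  ramp <- ramp_table()
  seqs <- c(T1 = "ARNDCQEGHILK", T2 = "GHILKMFPSTWY",
            M1 = "ARNDCQEGHILK", M2 = "GHILKMFPSTWY")
  set <- make_set(seqs, group = c("thermophilic", "thermophilic",
                                  "mesophilic", "mesophilic"),
                  ogt = c(60, 55, 30, 25))
  fm <- fragment_matrix(set, ramp)
  cand <- candidate_fragments(fm, n_perm = 19, seed = 1)
  expect_false(any(cand$candidate))
  expect_true(all(cand$score == 0))

  set.seed(403)
  set2 <- random_set(10, 6, 25, gap_prob = 0)
  fm2 <- fragment_matrix(set2, random_table())
  expect_warning(candidate_fragments(fm2, n_perm = 50, seed = 1),
                 "alpha = 0.01")
})
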