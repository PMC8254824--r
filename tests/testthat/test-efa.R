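# minres extraction, oblimin rotation, Schmid-Leiman orthogonalisation and
# factor-count diagnostics

test_that("minres recovers an exact rank-1 structure", {
  lam <- c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4)
  R <- tcrossprod(lam)
  diag(R) <- 1
  L <- minres_factor(R, 1)
  expect_lt(max(abs(as.vector(L) - lam)), 1e-6)
  expect_lt(attr(L, "rmsr"), 1e-7)
})

test_that("minres reproduces a constructed two-factor matrix", {
  L0 <- cbind(c(0.8, 0.7, 0.6, 0, 0, 0), c(0, 0, 0, 0.75, 0.65, 0.55))
  R <- tcrossprod(L0)
  diag(R) <- 1
  L <- minres_factor(R, 2)
  E <- R - tcrossprod(L)
  diag(E) <- 0
  expect_lt(sqrt(mean(E[upper.tri(E)]^2)), 1e-6)
  # sign convention: largest |loading| per column is positive
  expect_true(all(apply(L, 2, function(x) x[which.max(abs(x))]) > 0))
})

test_that("minres beats a random-restart optimizer on its own criterion", {
  set.seed(5)
  offdiag_obj <- function(L, R) {
    E <- R - tcrossprod(L)
    diag(E) <- 0
    sum(E^2) / 2
  }
  for (rep in 1:3) {
    p <- 8
    L0 <- matrix(runif(p * 2, -0.3, 0.9), p, 2)
    R <- tcrossprod(L0) + diag(runif(p, 0.2, 0.6))
    R <- stats::cov2cor(R)
    L <- minres_factor(R, 2)
    f_mine <- offdiag_obj(L, R)
    # brute-force random restarts of a generic optimizer on the criterion
    for (i in 1:25) {
      st <- runif(p * 2, -1, 1)
      op <- optim(st, function(v) offdiag_obj(matrix(v, p, 2), R),
                  method = "BFGS", control = list(maxit = 200))
      expect_gte(op$value, f_mine - 1e-7)
    }
  }
})

test_that("minres validates identification limits", {
  R <- bifactor_corr(p = 5, g = 0.7, f = 0.3)
  expect_error(minres_factor(R, 4), "identified")
  expect_error(minres_factor(diag(3) - 0.5, 1), "positive definite")
})

test_that("oblimin leaves a single factor unchanged", {
  A <- matrix(c(0.8, 0.7, 0.6), 3, 1)
  out <- oblimin_rotate(A)
  expect_equal(out$pattern, A)
  expect_equal(out$phi, diag(1))
})

test_that("oblimin preserves orthogonal simple structure up to permutation/sign", {
  L0 <- cbind(c(0.8, 0.7, 0.6, 0, 0, 0), c(0, 0, 0, 0.75, 0.65, 0.55))
  out <- oblimin_rotate(L0)
  al <- align_factors(L0, out$pattern)
  expect_true(all(al$tucker_phi > 0.9999))
  expect_lt(max(abs(out$phi[upper.tri(out$phi)])), 0.01)
})

test_that("oblimin criterion beats random oblique rotations", {
  set.seed(7)
  quartimin <- function(L) {
    k <- ncol(L)
    Nm <- matrix(1, k, k) - diag(k)
    sum(L^2 * (L^2 %*% Nm)) / 4
  }
  R <- bifactor_corr(p = 12, g = 0.6, f = 0.5)
  A <- minres_factor(R, 2)
  out <- oblimin_rotate(A)
  f_mine <- quartimin(out$pattern)
  for (i in 1:100) {
    Tm <- matrix(rnorm(4), 2, 2)
    Tm <- Tm %*% diag(1 / sqrt(colSums(Tm^2)))
    Lr <- A %*% t(solve(Tm))
    expect_gte(quartimin(Lr), f_mine - 1e-9)
  }
})

test_that("pattern times factor structure reproduces the unrotated common part", {
  R <- bifactor_corr(p = 10, g = 0.65, f = 0.45)
  A <- minres_factor(R, 2)
  out <- oblimin_rotate(A)
  # Lambda_rot %*% Phi %*% t(Lambda_rot) equals A %*% t(A)
  expect_equal(out$pattern %*% out$phi %*% t(out$pattern), tcrossprod(A),
               tolerance = 1e-8)
})

test_that("Schmid-Leiman returns zero general loadings for orthogonal factors", {
  L0 <- cbind(c(rep(0.7, 5), rep(0, 5)), c(rep(0, 5), rep(0.6, 5)))
  R <- tcrossprod(L0)
  diag(R) <- 1
  rownames(R) <- colnames(R) <- paste0("v", 1:10)
  expect_warning(sl <- schmid_leiman(R, k = 2), "uncorrelated")
  expect_true(sl$no_general)
  expect_lt(max(abs(sl$general)), 1e-6)
  al <- align_factors(L0, sl$group)
  expect_true(all(al$tucker_phi > 0.999))
})

test_that("Schmid-Leiman recovers a constructed bifactor structure", {
  R <- bifactor_corr(p = 34, g = 0.7, f = 0.4)
  sl <- schmid_leiman(R, k = 2)
  expect_lt(mean(abs(sl$general - 0.7)), 0.05)
  # permutation-safe: each variable's single nonzero group loading
  grp <- apply(abs(sl$group), 1, max)
  expect_lt(mean(abs(grp - 0.4)), 0.05)
  # and the zero entries really are zero
  expect_lt(mean(apply(abs(sl$group), 1, min)), 0.05)
})

test_that("Schmid-Leiman solution satisfies its algebraic identities", {
  R <- bifactor_corr(p = 12, g = 0.75, f = 0.45)
  sl <- schmid_leiman(R, k = 2)
  # reconstruction: gg' + FF' + uniquenesses equals the model-implied matrix
  # from the first-order solution
  implied_first <- sl$oblique_pattern %*% sl$factor_corr %*%
    t(sl$oblique_pattern)
  implied_sl <- tcrossprod(sl$general) + tcrossprod(sl$group)
  expect_equal(implied_sl, implied_first, tolerance = 1e-8)
  # communalities bounded
  expect_true(all(sl$general^2 + rowSums(sl$group^2) <= 1 + 1e-8))
  # variance shares sum to the first-order common variance share
  expect_equal(sum(sl$variance_shares),
               sum(diag(implied_first)) / nrow(R), tolerance = 1e-8)
})

test_that("factor-count diagnostics flag empty factors", {
  # identity: nothing is salient at any k
  I8 <- diag(8)
  rownames(I8) <- colnames(I8) <- paste0("v", 1:8)
  d0 <- suppressWarnings(select_nfactors(I8 + 0.001 - diag(0.001, 8),
                                         k_min = 2, k_max = 3))
  expect_true(all(d0$min_salient == 0, na.rm = TRUE))

  # constructed general + 2 groups: k = 2 passes, k = 3 has an empty factor
  R <- bifactor_corr(p = 18, g = 0.7, f = 0.45)
  d <- select_nfactors(R, k_min = 2, k_max = 4)
  expect_false(d$empty_factor[d$k == 2])
  expect_true(any(d$empty_factor[d$k > 2]))
  expect_equal(attr(d, "recommended"), 2)

  # one-factor matrix: every k >= 2 is flagged
  lam <- seq(0.5, 0.85, length.out = 12)
  R1 <- tcrossprod(lam)
  diag(R1) <- 1
  rownames(R1) <- colnames(R1) <- paste0("v", 1:12)
  d1 <- suppressWarnings(select_nfactors(R1, k_min = 2, k_max = 3))
  expect_true(all(d1$empty_factor, na.rm = TRUE))

  # well-specified solutions keep RMSR below the acceptance level used for
  # real data
  expect_true(all(d$rmsr[!d$empty_factor] < 0.05, na.rm = TRUE))
})
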