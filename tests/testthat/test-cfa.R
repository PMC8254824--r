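# confirmatory bifactor model: specification, fitting, variance decomposition
# and fit indices

test_that("specification assigns clean blocks and honours salience", {
  R <- bifactor_corr(p = 12, g = 0.7, f = 0.45,
                     groups = rep(1:2, each = 6))
  sl <- schmid_leiman(R, k = 2)
  spec <- build_bifactor_spec(sl, adjacency = NULL)
  grp <- spec$assignments$group
  # each constructed block lands on one factor (up to factor labelling)
  expect_equal(length(unique(grp[1:6])), 1)
  expect_equal(length(unique(grp[7:12])), 1)
  expect_true(grp[1] != grp[7])
  expect_null(spec$residual_pairs)
})

test_that("a variable with no salient group loading loads on general only", {
  R <- bifactor_corr(p = 13, g = 0.7, f = 0.45,
                     groups = rep(1:2, length.out = 13))
  # variable 13: general only
  L <- attr(R, "loadings")
  L[13, 2:3] <- 0
  R2 <- L %*% diag(3) %*% t(L)
  diag(R2) <- 1
  dimnames(R2) <- dimnames(R)
  sl <- schmid_leiman(R2, k = 2)
  spec <- build_bifactor_spec(sl, adjacency = NULL)
  expect_equal(spec$assignments$group[13], 0)
})

test_that("tied group loadings break deterministically with a warning", {
  sl <- list(general = rep(0.7, 4),
             group = matrix(0.5, 4, 2,
                            dimnames = list(paste0("v", 1:4), NULL)),
             no_general = FALSE)
  class(sl) <- "schmid_leiman"
  ws <- capture_warnings(spec <- build_bifactor_spec(sl, adjacency = NULL))
  expect_true(all(grepl("ties", ws)))
  expect_length(ws, 4)
  expect_true(all(spec$assignments$group == 1))
})

test_that("the fitted model reproduces an exact bifactor structure", {
  cfg <- cohort_config()
  L <- cfg$slope_loadings
  R <- L %*% cfg$phi_change %*% t(L)
  diag(R) <- 1
  rownames(R) <- colnames(R) <- paste0(cfg$roi_names, "_slp")
  sl <- schmid_leiman(R, k = 2)
  spec <- build_bifactor_spec(sl)
  fit <- fit_bifactor(spec, R, n = 600, sl = sl)
  expect_lt(mean(abs(fit$loadings_std[, 1] - L[, 1])), 1e-4)
  expect_equal(fit$group_corr[1, 2], -0.25, tolerance = 1e-3)
  # structure identity: implied covariance equals L Phi L' + Theta exactly
  expect_equal(fit$sem$sigma,
               fit$loadings %*% fit$phi %*% t(fit$loadings) + fit$theta,
               tolerance = 1e-12)
  # orthogonality constraints are exact in the fitted parameter set
  expect_identical(unname(fit$phi[1, 2:3]), c(0, 0))
})

test_that("zero group variance prunes group loadings and recovers general", {
  set.seed(20)
  p <- 16
  g <- runif(p, 0.5, 0.85)
  R <- tcrossprod(g)
  diag(R) <- 1
  # add sampling noise like a correlation estimated at n = 1000
  E <- matrix(rnorm(p * p, 0, 0.015), p, p)
  E <- (E + t(E)) / 2
  diag(E) <- 0
  Rn <- nearest_pd(R + E)$matrix
  rownames(Rn) <- colnames(Rn) <- paste0("v", 1:p, "_slp")
  spec <- list(assignments = data.frame(variable = rownames(Rn),
                                        group = rep(1:2, length.out = p)),
               residual_pairs = NULL, k = 2, salience = 0.3)
  class(spec) <- "bifactor_spec"
  fit <- suppressWarnings(fit_bifactor(spec, Rn, n = 1000))
  # group loadings near zero are pruned away; general recovered
  kept_groups <- fit$loading_table$factor != "general"
  expect_lt(sum(kept_groups), p / 2)
  expect_lt(mean(abs(fit$loadings_std[, 1] - g)), 0.05)
})

test_that("pruning is monotone in the discrepancy", {
  R <- bifactor_corr(p = 12, g = 0.7, f = 0.4,
                     groups = rep(1:2, each = 6))
  set.seed(21)
  E <- matrix(rnorm(144, 0, 0.03), 12, 12); E <- (E + t(E)) / 2; diag(E) <- 0
  Rn <- nearest_pd(R + E)$matrix
  sl <- schmid_leiman(Rn, k = 2)
  spec <- build_bifactor_spec(sl, adjacency = NULL)
  full <- fit_bifactor(spec, Rn, n = 300, sl = sl, prune = FALSE)
  pruned <- fit_bifactor(spec, Rn, n = 300, sl = sl, prune = TRUE)
  if (nrow(pruned$pruned) > 0) {
    expect_gte(pruned$sem$objective, full$sem$objective - 1e-10)
  }
  succeed()
})

test_that("variance decomposition matches independent arithmetic", {
  L <- cbind(general = c(1, 1, 1), F1 = c(0, 0, 0))
  expect_equal(unname(variance_explained(L)["total"]), 1)
  L2 <- cbind(g = c(0.6, 0.5), F1 = c(0.3, 0.2))
  oracle <- c((0.36 + 0.25) / 2, (0.09 + 0.04) / 2)
  expect_equal(unname(variance_explained(L2))[1:2], oracle)
  expect_equal(unname(variance_explained(matrix(0, 4, 2))["total"]), 0)
})

test_that("fit indices follow their formulas", {
  expect_equal(unname(fit_indices(10, 10, 200, 15, 100)["rmsea"]), 0)
  expect_equal(unname(fit_indices(200, 10, 200, 15, 100)["cfi"]), 0)
  # worked numeric case, independent evaluation
  chi2 <- 58.3; df <- 20; chi20 <- 512.4; df0 <- 28; n <- 251
  idx <- fit_indices(chi2, df, chi20, df0, n)
  expect_equal(unname(idx["cfi"]), 1 - (chi2 - df) / (chi20 - df0))
  expect_equal(unname(idx["tli"]),
               ((chi20 / df0) - (chi2 / df)) / ((chi20 / df0) - 1))
  expect_equal(unname(idx["rmsea"]), sqrt((chi2 - df) / (df * (n - 1))))
  expect_warning(fit_indices(100, 10, 50, 15, 100), "null model")
})

test_that("group-factor correlation sign is recovered across replicates", {
  # mirrors the directional check on the generating value of -0.25
  cfg <- cohort_config(n_participants = 600)
  signs <- logical(5)
  for (r in 1:5) {
    s <- simulate_cohort(cfg, seed = 500 + r)
    Rreal <- cor(s$truth$slopes)
    rownames(Rreal) <- colnames(Rreal) <- paste0(cfg$roi_names, "_slp")
    sl <- schmid_leiman(Rreal, k = 2)
    fit <- suppressWarnings(fit_bifactor(build_bifactor_spec(sl), Rreal,
                                         n = 600, sl = sl))
    signs[r] <- fit$group_corr[1, 2] < 0
  }
  expect_gte(mean(signs), 0.8)
})
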