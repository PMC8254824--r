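# congruence coefficients, factor alignment and sensitivity filtering

test_that("Tucker congruence satisfies its defining identities", {
  x <- c(0.8, 0.6, 0.4, 0.2)
  expect_equal(tucker_congruence(x, x), 1)
  expect_equal(tucker_congruence(x, -x), -1)
  expect_equal(tucker_congruence(c(1, 0), c(0, 1)), 0)
  expect_error(tucker_congruence(x, rep(0, 4)), "zero")
})

test_that("Tucker congruence matches a direct formula evaluation", {
  set.seed(9)
  for (i in 1:10) {
    a <- rnorm(10); b <- rnorm(10)
    oracle <- sum(a * b) / sqrt(sum(a * a) * sum(b * b))   # independent path
    expect_equal(tucker_congruence(a, b), oracle)
  }
})

test_that("Tucker congruence is scale-invariant up to sign", {
  set.seed(10)
  a <- rnorm(8); b <- rnorm(8)
  phi <- tucker_congruence(a, b)
  for (c0 in c(0.3, 2, -1.5, -0.01)) {
    expect_equal(tucker_congruence(a, c0 * b), sign(c0) * phi)
  }
})

test_that("alignment recovers a known permutation and sign flip", {
  set.seed(2)
  A <- matrix(runif(30, 0.2, 0.9), 10, 3)
  B <- A[, c(3, 1, 2)]
  B[, 2] <- -B[, 2]
  al <- align_factors(A, B)
  expect_true(all(al$tucker_phi > 0.999999))
  expect_equal(unname(al$B_aligned), unname(A), tolerance = 1e-12)
})

test_that("alignment attains the exhaustive-enumeration optimum", {
  set.seed(4)
  A <- matrix(runif(24, -0.2, 0.9), 8, 3)
  B <- A + matrix(rnorm(24, 0, 0.3), 8, 3)
  al <- align_factors(A, B)
  perms <- list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
  best <- -Inf
  for (pm in perms) {
    phis <- sapply(1:3, function(j) abs(tucker_congruence(A[, j], B[, pm[j]])))
    best <- max(best, mean(phis))
  }
  expect_equal(al$mean_phi, best, tolerance = 1e-12)
})

test_that("alignment of a single factor reduces to a sign decision", {
  a <- matrix(c(0.7, 0.6, 0.5), 3, 1)
  al <- align_factors(a, -a)
  expect_equal(al$signs, -1)
  expect_equal(al$tucker_phi, 1)
})

test_that("aligning A to B and B to A give inverse permutations", {
  set.seed(6)
  A <- matrix(runif(36, 0.1, 0.9), 12, 3)
  B <- A[, c(2, 3, 1)] + matrix(rnorm(36, 0, 0.05), 12, 3)
  ab <- align_factors(A, B)
  ba <- align_factors(B, A)
  expect_equal(order(ab$permutation), ba$permutation)
})

test_that("participant filtering removes every wave on any-wave criteria", {
  cfg <- small_config(n = 80)
  s <- simulate_cohort(cfg, seed = 21)
  panel <- apply_exclusion_flags(s$panel, cfg, seed = 22)
  # plant a known low MMSE at wave 3 only
  victim <- panel$id[panel$wave == 3][1]
  panel$mmse[panel$id == victim & panel$wave == 3] <- 23
  filt <- filter_panel(panel, criteria = c("dementia", "mmse"))
  expect_false(victim %in% filt$id)
  # a score of exactly 24 is retained (strict < 24 rule)
  survivor <- setdiff(unique(panel$id), attr(filt, "removed_ids"))[1]
  panel2 <- panel
  panel2$mmse[panel2$id == survivor] <- 24
  filt2 <- filter_panel(panel2, criteria = "mmse")
  expect_true(survivor %in% filt2$id)
})

test_that("with no flags set the filtered panel is identical", {
  cfg <- small_config(n = 60, exclusion_prevalence = c(dementia_mmse = 0,
                                                       stroke = 0))
  s <- simulate_cohort(cfg, seed = 31)
  panel <- apply_exclusion_flags(s$panel, cfg, seed = 32)
  expect_equal(sum(panel$dementia), 0)
  filt <- filter_panel(panel, criteria = c("dementia", "stroke"))
  expect_equal(nrow(filt), nrow(panel))
  expect_length(attr(filt, "removed_ids"), 0)
})

test_that("sensitivity rerun reproduces the full-sample structure under light
           random exclusions", {
  cfg <- small_config(n = 350)
  s <- simulate_cohort(cfg, seed = 41)
  panel <- apply_exclusion_flags(s$panel, cfg, seed = 42)
  out <- suppressWarnings(
    sensitivity_rerun(panel, criteria = c("dementia", "mmse"), k = 2))
  expect_true(length(out$removed_ids) > 0)
  expect_false(any(out$panel_filtered$id %in% out$removed_ids))
  expect_gt(out$comparison$general[["tucker_phi"]], 0.95)
})
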