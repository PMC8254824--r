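# synthetic cohort generator: ground truth consistency, attrition, flags

test_that("degenerate variances give identical mean-line trajectories", {
  cfg <- small_config(n = 20, intercept_sd_frac = 0, slope_sd_frac = 0,
                      noise_sd_frac = 0, attrition_rates = c(0, 0))
  s <- simulate_cohort(cfg, seed = 1)
  v <- cfg$roi_names[1]
  line <- cfg$intercept_means[1] + cfg$slope_means[1] *
    (s$panel$age - stats::ave(s$panel$age, s$panel$id, FUN = min))
  expect_equal(s$panel[[v]], line, tolerance = 1e-10)
  # every participant on the same line at each wave
  by_wave <- split(s$panel[[v]], s$panel$wave)
  expect_true(all(vapply(by_wave, function(x) diff(range(x)) < 1e-8,
                         logical(1))))
})

test_that("wave-1 age matches the configured cohort age", {
  s <- simulate_cohort(cohort_config(), seed = 2)   # default n = 629
  expect_lt(abs(mean(s$panel$age[s$panel$wave == 1]) - 72.49), 0.1)
  expect_lt(abs(sd(s$panel$age[s$panel$wave == 1]) - 0.71), 0.15)
})

test_that("generated slopes match configured means within Monte-Carlo error", {
  cfg <- cohort_config(n_participants = 2000)
  s <- simulate_cohort(cfg, seed = 3)
  emp <- colMeans(s$truth$slopes)
  mcse <- apply(s$truth$slopes, 2, sd) / sqrt(2000)
  expect_true(all(abs(emp - cfg$slope_means) < 3 * mcse))
})

test_that("population slope covariance equals loadings Phi loadings' + residuals", {
  cfg <- cohort_config(n_participants = 100000)
  old <- .Random.seed <- NULL
  s <- simulate_cohort(cfg, seed = 4)
  S_emp <- cov(s$truth$slopes)
  L <- cfg$slope_loadings * cfg$slope_sd
  S_th <- L %*% cfg$phi_change %*% t(L) + diag(cfg$slope_residual_sd^2)
  # Monte-Carlo tolerance: correlations to ~1/sqrt(n)
  C_emp <- stats::cov2cor(S_emp)
  C_th <- stats::cov2cor(S_th)
  expect_lt(max(abs(C_emp - C_th)), 0.02)
})

test_that("attrition is monotone and MAR-related to baseline cognition", {
  cfg <- cohort_config(n_participants = 2000)
  s <- simulate_cohort(cfg, seed = 5)
  waves <- split(s$panel$wave, s$panel$id)
  expect_true(all(vapply(waves, function(w) identical(sort(w), seq_along(w)),
                         logical(1))))
  # retention close to the configured schedule
  n_w <- table(s$panel$wave)
  expect_lt(abs(n_w[[2]] / n_w[[1]] - (1 - 0.320)), 0.04)
  expect_lt(abs(n_w[[3]] / n_w[[2]] - (1 - 0.255)), 0.04)
  # wave-3 returners are cognitively abler at baseline than dropouts
  ret3 <- unique(s$panel$id[s$panel$wave == 3])
  z <- s$truth$baseline_cognition
  expect_gt(mean(z[ret3]), mean(z[-ret3]))
})

test_that("exclusion flags appear at the configured prevalence", {
  cfg <- cohort_config(n_participants = 629)
  s <- simulate_cohort(cfg, seed = 6)
  panel <- apply_exclusion_flags(s$panel, cfg, seed = 7)
  ids <- unique(panel$id)
  flagged <- vapply(ids, function(i) {
    any(panel$dementia[panel$id == i]) ||
      any(panel$mmse[panel$id == i] < 24, na.rm = TRUE)
  }, logical(1))
  # binomial consistency with prevalence 31/629 (allowing for the background
  # rate of naturally low MMSE scores)
  pr <- 31 / 629
  ci <- qbinom(c(0.0005, 0.9995), 629, pr) + c(0, 25)
  expect_gte(sum(flagged), ci[1])
  expect_lte(sum(flagged), ci[2])

  cfg0 <- cohort_config(exclusion_prevalence = c(dementia_mmse = 0, stroke = 0))
  p0 <- apply_exclusion_flags(simulate_cohort(cfg0, seed = 8)$panel, cfg0, 9)
  expect_equal(sum(p0$dementia), 0)
  expect_equal(sum(p0$stroke), 0)

  cfg1 <- small_config(n = 40,
                       exclusion_prevalence = c(dementia_mmse = 1, stroke = 1))
  p1 <- apply_exclusion_flags(simulate_cohort(cfg1, seed = 10)$panel, cfg1, 11)
  expect_true(all(p1$stroke))
  ids1 <- unique(p1$id)
  all_flagged <- vapply(ids1, function(i)
    any(p1$dementia[p1$id == i]) || any(p1$mmse[p1$id == i] < 24), logical(1))
  expect_true(all(all_flagged))
})

test_that("simulation is deterministic given the seed", {
  cfg <- small_config(n = 50)
  a <- simulate_cohort(cfg, seed = 99)
  b <- simulate_cohort(cfg, seed = 99)
  expect_identical(a$panel, b$panel)
  expect_identical(a$truth$slopes, b$truth$slopes)
  c <- simulate_cohort(cfg, seed = 100)
  expect_false(identical(a$panel, c$panel))
})

test_that("non-PSD configurations are rejected with a named block", {
  expect_error(cohort_config(group_factor_corr = -1.2), "change-factor")
  expect_error(cohort_config(brain_cognition_coupling = c(visuospatial = 0.99,
                                                          speed = 0.99,
                                                          memory = 0.99),
                             domain_slope_corr = 0),
               "coupling")
})

test_that("the truth record round-trips through serialisation", {
  cfg <- small_config(n = 25)
  s <- simulate_cohort(cfg, seed = 12)
  f <- tempfile(fileext = ".txt")
  write_truth(s$truth, f)
  back <- read_truth(f)
  # lossless: bitwise equality of the realized latents
  expect_identical(as.vector(back$slopes), as.vector(s$truth$slopes))
  expect_identical(as.vector(back$intercepts), as.vector(s$truth$intercepts))
  expect_identical(back$carrier, s$truth$carrier)
  expect_identical(as.vector(back$factors), as.vector(s$truth$factors))
  expect_identical(back$dropout_wave, s$truth$dropout_wave)
  expect_identical(back$seed, s$truth$seed)
  unlink(f)
})
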