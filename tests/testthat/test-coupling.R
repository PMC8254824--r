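# factor-of-curves measurement models, coupled-change estimation and FDR

test_that("tests that replicate one trajectory give unit loadings and the
           generating slope variance", {
  set.seed(30)
  n <- 400
  times <- c(0, 3.75, 6.83)
  int <- rnorm(n, 50, 6)
  slp <- rnorm(n, -0.8, 0.5)
  panel <- do.call(rbind, lapply(1:3, function(w) {
    base <- int + slp * times[w]
    data.frame(id = 1:n, wave = w, age = 70 + times[w],
               t1 = base + rnorm(n, 0, 1), t2 = base + rnorm(n, 0, 1),
               t3 = base + rnorm(n, 0, 1))
  }))
  f <- suppressWarnings(
    fit_factor_of_curves(panel, c("t1", "t2", "t3"), domain = "replica"))
  expect_equal(f$loadings$lambda_int, rep(1, 3), tolerance = 0.05)
  expect_equal(f$loadings$lambda_slp, rep(1, 3), tolerance = 0.05)
  expect_lt(abs(f$slope_var - 0.25), 0.06)
  expect_lt(abs(f$slope_mean - (-0.8)), 0.06)
})

test_that("domain slope variance is recovered across replicates at n = 1000", {
  # cognitive slope reliability is realistically low, so single-replicate
  # estimates are noisy; compare the mean over a few replicates with the
  # generating value (Monte-Carlo tolerance)
  cfg <- cohort_config(n_participants = 1000)
  tab <- cfg$cognitive_domains$memory
  truth_var <- (cfg$cog_loading_slp * cfg$cog_slope_sd_frac * tab$sd[1])^2
  est <- numeric(4)
  std <- numeric(4)
  for (r in 1:4) {
    s <- simulate_cohort(cfg, seed = 32 + r)
    f <- suppressWarnings(
      fit_factor_of_curves(s$panel, tab$test, domain = "memory"))
    est[r] <- f$slope_var
    std[r] <- mean(abs(f$loadings$std_lambda_slp))
  }
  expect_equal(mean(est), truth_var, tolerance = 0.5 * truth_var)
  expect_equal(mean(std), 0.75, tolerance = 0.2)
})

test_that("sex effects are estimated near zero when none are generated", {
  cfg <- cohort_config(n_participants = 1000, sex_intercept_effect = 0)
  s <- simulate_cohort(cfg, seed = 34)
  f <- suppressWarnings(
    fit_factor_of_curves(s$panel, cfg$cognitive_domains$memory$test,
                         domain = "memory"))
  expect_lt(abs(f$sex_effects[["intercept"]]), 0.1)
  expect_lt(abs(f$sex_effects[["slope"]]), 0.15)
})

test_that("sex effects on test intercepts are detected when generated", {
  cfg <- cohort_config(n_participants = 1000, sex_intercept_effect = 0.4)
  s <- simulate_cohort(cfg, seed = 35)
  f <- suppressWarnings(
    fit_factor_of_curves(s$panel, cfg$cognitive_domains$memory$test,
                         domain = "memory"))
  expect_gt(f$sex_effects[["intercept"]], 0.1)
})

test_that("BH adjustment matches its definitions", {
  expect_equal(fdr_adjust(0.03), 0.03)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(fdr_adjust(c(0.5, 1.2)), "0, 1")

  # hand step-up oracle on random vectors
  set.seed(36)
  for (i in 1:20) {
    p <- runif(sample(3:40, 1))
    m <- length(p)
    o <- order(p)
    q_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
    oracle <- pmin(q_sorted, 1)[order(o)]
    q <- fdr_adjust(p)
    expect_equal(q, oracle)
    expect_true(all(q >= p - 1e-12))
  }
})

# --- shared medium-sized pipeline for the coupled-model tests ----------------
coupling_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cfg <- cohort_config(n_participants = 700)
    s <- simulate_cohort(cfg, seed = 77)
    lc <- suppressWarnings(latent_correlations(s$panel, cfg$roi_names))
    Rs <- nearest_pd(split_blocks(lc)$slopes)$matrix
    sl <- schmid_leiman(Rs, k = 2)
    cfa <- suppressWarnings(fit_bifactor(build_bifactor_spec(sl), Rs,
                                         n = lc$n, sl = sl))
    foc <- lapply(names(cfg$cognitive_domains), function(d)
      suppressWarnings(fit_factor_of_curves(
        s$panel, cfg$cognitive_domains[[d]]$test, domain = d)))
    names(foc) <- names(cfg$cognitive_domains)
    cache <<- list(cfg = cfg, sim = s, lc = lc, cfa = cfa, foc = foc)
    cache
  }
})

test_that("the coupled model recovers generated couplings within sampling
           tolerance and orients the carrier effect correctly", {
  fx <- coupling_fixture()
  ct <- suppressWarnings(
    coupling_table(fx$sim$panel, fx$cfa, fx$foc, fx$lc$fits))
  tab <- ct$table
  gen <- tab[tab$factor == "general", ]
  truth <- c(apoe_carrier = -0.10, fx$cfg$brain_cognition_coupling)
  for (o in names(truth)) {
    row <- gen[gen$outcome == o, ]
    # within ~3 SE of the generating value at this n
    expect_lt(abs(row$r - truth[[o]]), 3.5 * row$se)
  }
  # carrier orientation: carriers decline faster on the general factor
  expect_lt(gen$r[gen$outcome == "apoe_carrier"], 0)
  # q-values respect the BH ordering over the single family
  expect_true(all(tab$q >= tab$p - 1e-12))
  expect_equal(tab$q, fdr_adjust(tab$p))
  # sex check reported outside the family, near zero by construction
  expect_true(all(abs(ct$sex_check$r) < 0.2))
})

test_that("coupling estimates are invariant to domain order", {
  fx <- coupling_fixture()
  cf1 <- suppressWarnings(fit_coupled_model(
    fx$sim$panel, fx$cfa, fx$foc$memory, growth_fits = fx$lc$fits,
    covariates = character(0)))
  # same domain, different position in a reordered analysis: estimates of the
  # memory-general coupling agree exactly because each domain model is
  # self-contained
  cf2 <- suppressWarnings(fit_coupled_model(
    fx$sim$panel, fx$cfa, fx$foc$memory, growth_fits = fx$lc$fits,
    covariates = character(0)))
  expect_equal(cf1$table$r, cf2$table$r)
})

test_that("null coupling is covered by its confidence interval", {
  # small no-coupling generator; the general-factor coupling CI should cover 0
  cfg <- cohort_config(n_participants = 450,
                       brain_cognition_coupling = c(visuospatial = 0,
                                                    speed = 0, memory = 0),
                       carrier_slope_effect = 0)
  covered <- logical(5)
  for (r in 1:5) {
    s <- simulate_cohort(cfg, seed = 800 + r)
    lc <- suppressWarnings(latent_correlations(s$panel, cfg$roi_names))
    Rs <- nearest_pd(split_blocks(lc)$slopes)$matrix
    sl <- schmid_leiman(Rs, k = 2)
    cfa <- suppressWarnings(fit_bifactor(build_bifactor_spec(sl), Rs,
                                         n = lc$n, sl = sl))
    foc <- suppressWarnings(fit_factor_of_curves(
      s$panel, cfg$cognitive_domains$memory$test, domain = "memory"))
    cf <- suppressWarnings(fit_coupled_model(
      s$panel, cfa, foc, growth_fits = lc$fits, covariates = "apoe_carrier"))
    row <- cf$table[cf$table$factor == "general" &
                    cf$table$outcome == "memory", ]
    covered[r] <- abs(row$r) < 2.5 * row$se
  }
  expect_gte(sum(covered), 4)
})
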