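# univariate FIML growth curves and latent correlations

test_that("noise-free straight-line data give zero residual variance and
           sample latent moments", {
  # per-subject lines with negligible wave noise (0.01 on a scale of 100);
  # the likelihood surface is near-singular there, so accept the optimizer's
  # caution flag and check the estimates themselves
  panel <- make_line_panel(n = 80, noise = 0.01, seed = 2)
  lat <- attr(panel, "latents")
  f <- suppressWarnings(fit_growth_curve(panel, "y"))
  e <- f$estimates
  expect_lt(e[["residual_var"]], 1e-3)
  expect_equal(e[["intercept_mean"]], mean(lat[, 1]), tolerance = 1e-4)
  expect_equal(e[["slope_mean"]], mean(lat[, 2]), tolerance = 1e-3)
  # ML (divisor n) latent moments
  n <- nrow(lat)
  expect_equal(e[["intercept_var"]], var(lat[, 1]) * (n - 1) / n,
               tolerance = 5e-3)
  expect_equal(e[["slope_var"]], var(lat[, 2]) * (n - 1) / n,
               tolerance = 5e-3)
})

test_that("balanced complete data match a brute-force likelihood optimizer", {
  panel <- make_line_panel(n = 50, noise = 3, seed = 3)
  f <- fit_growth_curve(panel, "y")
  # independent oracle: direct per-subject multivariate-normal likelihood,
  # maximised by a generic optimizer
  times <- c(0, 3.75, 6.83)
  Y <- matrix(panel$y[order(panel$wave, panel$id)], ncol = 3)
  Z <- cbind(1, times)
  nll <- function(th) {
    mu <- drop(Z %*% th[1:2])
    P <- matrix(c(th[3], th[4], th[4], th[5]), 2)
    Sg <- Z %*% P %*% t(Z) + diag(th[6], 3)
    ev <- eigen(Sg, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) return(1e10)
    Si <- solve(Sg)
    0.5 * sum(apply(Y, 1, function(y) {
      d <- y - mu
      drop(t(d) %*% Si %*% d)
    })) + nrow(Y) / 2 * (determinant(Sg)$modulus[1] + 3 * log(2 * pi))
  }
  st <- c(100, -2, 80, 0, 0.8, 10)
  op <- optim(st, nll, method = "BFGS",
              control = list(maxit = 2000, reltol = 1e-14))
  op <- optim(op$par, nll, method = "BFGS",
              control = list(maxit = 2000, reltol = 1e-14))
  est <- f$estimates[c("intercept_mean", "slope_mean", "intercept_var",
                       "int_slope_cov", "slope_var", "residual_var")]
  expect_equal(unname(est), op$par, tolerance = 1e-5)
  expect_equal(f$loglik, -nll(op$par), tolerance = 1e-6)
})

test_that("FIML agrees with the mixed-model oracle on unbalanced data", {
  skip_if_not_installed("lme4")
  cfg <- small_config(n = 200)
  s <- simulate_cohort(cfg, seed = 5)
  f <- fit_growth_curve(s$panel, "precuneus")
  p <- s$panel
  p$t <- p$age - stats::ave(p$age, p$id, FUN = min)
  m <- lme4::lmer(precuneus ~ t + (t | id), data = p, REML = FALSE)
  expect_equal(f$loglik, as.numeric(stats::logLik(m)), tolerance = 1e-4)
  expect_equal(f$estimates[["slope_mean"]], unname(lme4::fixef(m)[2]),
               tolerance = 1e-3)
})

test_that("FIML is less biased than complete-case analysis under MAR dropout", {
  set.seed(77)
  times <- c(0, 3.75, 6.83)
  bias_fiml <- bias_cc <- numeric(120)
  for (r in seq_len(120)) {
    n <- 120
    int <- rnorm(n, 100, 8)
    slp <- rnorm(n, -2, 0.8)
    y1 <- int + rnorm(n, 0, 3)
    # MAR: dropout probability depends on the observed baseline value
    keep2 <- runif(n) > plogis(-(y1 - 100) / 4 - 0.5)
    keep3 <- keep2 & (runif(n) > 0.15)
    y2 <- int + slp * times[2] + rnorm(n, 0, 3)
    y3 <- int + slp * times[3] + rnorm(n, 0, 3)
    rows <- list(data.frame(id = 1:n, wave = 1, age = 70, y = y1))
    rows$w2 <- data.frame(id = which(keep2), wave = 2, age = 70 + times[2],
                          y = y2[keep2])
    rows$w3 <- data.frame(id = which(keep3), wave = 3, age = 70 + times[3],
                          y = y3[keep3])
    panel <- do.call(rbind, rows)
    # dropout here depends on the baseline OUTCOME, so intercept estimates are
    # where complete-case analysis breaks
    f <- suppressWarnings(fit_growth_curve(panel, "y", starts = 1, se = FALSE))
    cc <- panel[panel$id %in% names(which(table(panel$id) == 3)), ]
    fc <- suppressWarnings(fit_growth_curve(cc, "y", starts = 1, se = FALSE))
    bias_fiml[r] <- f$estimates[["intercept_mean"]] - 100
    bias_cc[r] <- fc$estimates[["intercept_mean"]] - 100
  }
  expect_lt(abs(mean(bias_fiml)), abs(mean(bias_cc)))
  expect_lt(abs(mean(bias_fiml)), 1)
})

test_that("percent annual change follows its definition", {
  expect_equal(round(percent_annual_change(-3475, 398508), 2), -0.87)
  expect_equal(percent_annual_change(0, 500), 0)
  expect_equal(percent_annual_change(-5, 500), -1)
  expect_error(percent_annual_change(-5, 0), "positive")
  f <- fit_growth_curve(make_line_panel(seed = 8), "y", starts = 1, se = FALSE)
  expect_equal(f$pct_per_annum,
               100 * f$estimates[["slope_mean"]] / f$estimates[["intercept_mean"]])
})

test_that("duplicated latent slopes give a slope-slope correlation of one", {
  set.seed(12)
  n <- 150
  times <- c(0, 3.75, 6.83)
  int1 <- rnorm(n, 100, 10); int2 <- rnorm(n, 60, 6)
  slp <- rnorm(n, -2, 1)   # shared slope
  panel <- do.call(rbind, lapply(1:3, function(w)
    data.frame(id = 1:n, wave = w, age = 70 + times[w],
               a = int1 + slp * times[w] + rnorm(n, 0, 0.5),
               b = int2 + slp * times[w] + rnorm(n, 0, 0.5))))
  lc <- suppressWarnings(latent_correlations(panel, c("a", "b")))
  expect_equal(lc$corr["a_slp", "b_slp"], 1, tolerance = 0.01)
})

test_that("latent slope correlations recover truth and nulls", {
  set.seed(13)
  n <- 2000
  times <- c(0, 3.75, 6.83)
  CS <- matrix(c(1, 0.8, 0.8, 1), 2)
  S <- mvn_fixture(n, c(-2, -1.5), diag(c(1, 0.8)) %*% CS %*% diag(c(1, 0.8)))
  I <- mvn_fixture(n, c(100, 70), diag(c(100, 64)))
  Z <- rnorm(n, -2, 1)   # slope independent of everything
  panel <- do.call(rbind, lapply(1:3, function(w)
    data.frame(id = 1:n, wave = w, age = 70 + times[w],
               a = I[, 1] + S[, 1] * times[w] + rnorm(n, 0, 2),
               b = I[, 2] + S[, 2] * times[w] + rnorm(n, 0, 2),
               c = 80 + Z * times[w] + rnorm(n, 0, 2))))
  lc <- latent_correlations(panel, c("a", "b", "c"))
  truth_ab <- cor(S)[1, 2]
  expect_equal(lc$corr["a_slp", "b_slp"], truth_ab, tolerance = 0.04)
  expect_lt(abs(lc$corr["a_slp", "c_slp"]), 0.05)
})

test_that("pairwise and simultaneous methods agree on complete data", {
  set.seed(14)
  n <- 400
  times <- c(0, 3.75, 6.83)
  CS <- 0.5 + 0.5 * diag(4)
  lat <- mvn_fixture(n, rep(0, 4), CS)
  I <- mvn_fixture(n, c(100, 90, 80, 70), diag(rep(64, 4)) + 20)
  panel <- do.call(rbind, lapply(1:3, function(w) {
    d <- data.frame(id = 1:n, wave = w, age = 70 + times[w])
    for (j in 1:4) d[[paste0("v", j)]] <-
      I[, j] + (lat[, j] - 1.5) * times[w] + rnorm(n, 0, 2)
    d
  }))
  vars <- paste0("v", 1:4)
  lp <- latent_correlations(panel, vars, method = "pairwise")
  ls <- latent_correlations(panel, vars, method = "simultaneous")
  expect_lt(max(abs(lp$corr - ls$corr), na.rm = TRUE), 0.02)
  lf <- latent_correlations(panel, vars, method = "pairwise_ml")
  expect_lt(max(abs(lp$corr - lf$corr), na.rm = TRUE), 0.02)
})

test_that("the reported optimum beats random parameter perturbations", {
  panel <- make_line_panel(n = 60, noise = 2, seed = 15)
  f <- fit_growth_curve(panel, "y", starts = 1, se = FALSE)
  pat <- cortage:::build_patterns(panel, "y")
  tmpl <- list(nu = rep(NA_real_, 2), psi = matrix(NA_real_, 2, 2),
               theta = NA_real_)
  idx <- cortage:::template_index(tmpl)
  sv <- cortage:::growth_scale_vec(pat$scales[[1]], pat$t_span)
  est <- f$estimates[c(1, 2, 3, 4, 5, 6)] / sv
  par_hat <- unname(c(est[1:2], est[3], est[4], est[5], est[6]))
  nll_hat <- cortage:::pattern_nll(
    cortage:::template_fill(tmpl, idx, par_hat), pat)
  set.seed(16)
  for (i in 1:50) {
    pp <- par_hat * exp(rnorm(6, 0, 0.15))
    expect_gte(cortage:::pattern_nll(
      cortage:::template_fill(tmpl, idx, pp), pat), nll_hat - 1e-6)
  }
})

test_that("correlation summaries equal direct enumeration", {
  set.seed(17)
  M <- stats::cov2cor(crossprod(matrix(rnorm(200), 20, 10)))
  vals <- M[upper.tri(M)]
  expect_equal(unname(correlation_summary(M)), c(mean(vals), sd(vals)))
  # constant off-diagonal
  C <- matrix(0.5, 4, 4); diag(C) <- 1
  expect_equal(unname(correlation_summary(C)), c(0.5, 0))
  expect_equal(unname(correlation_summary(diag(3) + 0)), c(0, 0))
  expect_error(correlation_summary(matrix(1, 1, 1)), "2 x 2")
})

test_that("parameter recovery at cohort scale is nearly unbiased", {
  # n = 600, 3 waves, default noise: slope mean bias below 2% of the
  # generating value (checked on a handful of replicates to stay quick;
  # per-replicate estimates average many ROIs)
  cfg <- cohort_config(n_participants = 600)
  rel_bias <- numeric(3)
  for (r in 1:3) {
    s <- simulate_cohort(cfg, seed = 300 + r)
    est <- vapply(c("superiorfrontal", "precuneus", "fusiform",
                    "lateraloccipital"), function(v)
      fit_growth_curve(s$panel, v, starts = 1, se = FALSE)$estimates[["slope_mean"]],
      numeric(1))
    tru <- cfg$slope_means[match(names(est), cfg$roi_names)]
    rel_bias[r] <- mean((est - tru) / abs(tru))
  }
  expect_lt(abs(mean(rel_bias)), 0.02)
})
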