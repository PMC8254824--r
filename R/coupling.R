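# Coupling of cortical change factors to cognitive decline and binary
# covariates: factor-of-curves measurement models for cognitive domains,
# Bartlett-weighted composites tracking the cortical change factors, a joint
# FIML model estimating the structural correlation block, and FDR control.

# joint FIML growth model for a small set of variables (plus optional static
# covariates): free means, full latent covariance, free residual variances;
# analytic gradient throughout. Estimates are reported in original units.
#' @keywords internal
fit_joint_growth <- function(panel, vars, time = "baseline",
                             statics = character(0),
                             method = c("joint", "pairwise")) {
  method <- match.arg(method)
  p <- length(vars)
  ns <- length(statics)
  m <- 2 * p + ns
  pat <- build_patterns(panel, vars, static_vars = statics, time = time)
  ols <- ols_lines(panel, vars, time)
  fits <- lapply(seq_len(p), function(i)
    fit_growth_curve(panel, vars[i], time = time, starts = 1, se = FALSE,
                     pat = subset_patterns(pat, i), ols = ols[[i]]))
  psi0 <- matrix(0, m, m)
  nu0 <- numeric(m); th0 <- numeric(p)
  for (i in seq_len(p)) {
    e <- fits[[i]]$estimates
    nu0[2 * i - 1] <- e[["intercept_mean"]]; nu0[2 * i] <- e[["slope_mean"]]
    psi0[2 * i - 1, 2 * i - 1] <- max(e[["intercept_var"]], 1e-10)
    psi0[2 * i, 2 * i] <- max(e[["slope_var"]], 1e-12)
    psi0[2 * i - 1, 2 * i] <- psi0[2 * i, 2 * i - 1] <- e[["int_slope_cov"]]
    th0[i] <- max(e[["residual_var"]], 1e-10)
  }
  if (p > 1) {
    rr <- ols_cross_cov(ols, p)
    for (i in seq_len(p - 1)) for (j in (i + 1):p) {
      bi <- (2 * i - 1):(2 * i); bj <- (2 * j - 1):(2 * j)
      blk <- rr[[paste(i, j)]]
      psi0[bi, bj] <- blk; psi0[bj, bi] <- t(blk)
    }
  }
  if (ns) {
    ids <- unique(panel$id)
    for (s_i in seq_len(ns)) {
      x <- panel[[statics[s_i]]][match(ids, panel$id)]
      nu0[2 * p + s_i] <- mean(x, na.rm = TRUE)
      psi0[2 * p + s_i, 2 * p + s_i] <- max(stats::var(x, na.rm = TRUE), 1e-10)
    }
  }
  psi0 <- pd_start(psi0)
  if (method == "pairwise") {
    # assembled estimate: univariate FIML marginals plus profiled pairwise
    # cross blocks (consistent; used where the block is a fixed nuisance)
    if (p > 1 && !ns) {
      for (i in seq_len(p - 1)) for (j in (i + 1):p) {
        f <- tryCatch(fit_pair_cross(subset_patterns(pat, c(i, j)),
                                     fits[[i]], fits[[j]],
                                     rr[[paste(i, j)]]),
                      error = function(e) NULL)
        if (!is.null(f) && f$converged) {
          bi <- (2 * i - 1):(2 * i); bj <- (2 * j - 1):(2 * j)
          psi0[bi, bj] <- f$psi[1:2, 3:4]
          psi0[bj, bi] <- t(f$psi[1:2, 3:4])
        }
      }
      psi0 <- pd_start(psi0)
    }
    return(list(fill = list(nu = nu0, psi = psi0, theta = th0),
                vars = vars, statics = statics, n = pat$n_total,
                convergence = 0, converged = TRUE, method = "pairwise"))
  }
  tmpl <- list(nu = rep(NA_real_, m),
               psi = matrix(NA_real_, m, m),
               theta = rep(NA_real_, p))
  s <- latent_scales(pat)
  start <- c(nu0 / s, ut_pack(psi0 / outer(s, s)), th0 / pat$scales^2)
  lower <- rep(-Inf, length(start))
  lower[m + ut_diag_pos(m)] <- 0
  lower[(length(start) - p + 1):length(start)] <- 0
  fit <- fiml_fit(pat, tmpl, start, lower = lower)
  fit$fill <- unscale_fill(fit$fill, pat)   # report in original units
  fit$vars <- vars
  fit$statics <- statics
  fit$n <- pat$n_total
  fit
}

#' Fit a factor-of-curves model for one cognitive domain
#'
#' Each test has its own latent intercept and slope; these load on a
#' domain-level intercept and slope factor. Estimation is two-stage: (1) a
#' joint FIML growth model of all tests (full latent covariance, missing
#' waves handled by pattern likelihood) and (2) a maximum-likelihood factor
#' structure fit to the estimated latent covariance matrix. Reported factor
#' quantities use marker identification (the first test's loadings equal 1),
#' and standardized loadings are also returned. When \code{sex_adjust} is
#' \code{TRUE} and the panel has a \code{sex} column, sex enters the joint
#' model and its standardized associations with the domain factors are
#' reported.
#'
#' @param panel long-format panel.
#' @param tests character vector of test columns (>= 2).
#' @param domain label for the domain.
#' @param time time coding.
#' @param sex_adjust include sex as a correlate of the domain factors.
#' @return object of class \code{foc_fit}: loadings (marker metric and
#'   standardized), domain factor means/variances, residual variances, sex
#'   effects, log-likelihood of the stage-1 model.
#' @export
fit_factor_of_curves <- function(panel, tests, domain = "domain",
                                 time = "baseline", sex_adjust = TRUE) {
  p <- length(tests)
  stopifnot(p >= 2)
  use_sex <- sex_adjust && "sex" %in% names(panel)
  statics <- if (use_sex) "sex" else character(0)

  joint <- fit_joint_growth(panel, tests, time = time, statics = statics)
  m <- 2 * p + length(statics)
  Slat <- pd_start(joint$fill$psi)
  D <- sqrt(diag(Slat))
  R <- Slat / outer(D, D)

  # stage 2: two correlated factors (domain intercept, domain slope) over the
  # latent intercepts and slopes, sex as a single-indicator factor
  mfac <- 2 + length(statics)
  lam <- matrix(0, m, mfac)
  lam[seq(1, 2 * p, by = 2), 1] <- NA_real_
  lam[seq(2, 2 * p, by = 2), 2] <- NA_real_
  if (use_sex) lam[m, 3] <- 1
  phi <- diag(mfac)
  phi[upper.tri(phi)] <- NA_real_
  phi[lower.tri(phi)] <- NA_real_
  th <- matrix(0, m, m)
  diag(th)[seq_len(2 * p)] <- NA_real_
  tm <- list(lambda = lam, phi = phi, theta = th)

  ix <- sem_index(tm)
  start <- numeric(ix$n_par)
  # loading starts carry the sign of the latent covariance with the marker
  sgn_i <- sign(R[seq(1, 2 * p, 2), 1]); sgn_i[sgn_i == 0] <- 1
  sgn_s <- sign(R[seq(2, 2 * p, 2), 2]); sgn_s[sgn_s == 0] <- 1
  start[seq_len(nrow(ix$lam))] <- 0.7 * ifelse(ix$lam[, 2] == 1,
                                               sgn_i[(ix$lam[, 1] + 1) / 2],
                                               sgn_s[ix$lam[, 1] / 2])
  start[nrow(ix$lam) + seq_len(nrow(ix$phi))] <- 0
  start[nrow(ix$lam) + nrow(ix$phi) + seq_len(nrow(ix$th))] <- 0.4
  lo <- rep(-Inf, ix$n_par)
  lo[nrow(ix$lam) + seq_len(nrow(ix$phi))] <- -0.995
  hi <- rep(Inf, ix$n_par)
  hi[nrow(ix$lam) + seq_len(nrow(ix$phi))] <- 0.995
  lo[nrow(ix$lam) + nrow(ix$phi) + seq_len(nrow(ix$th))] <- 0
  sem <- sem_fit(R, joint$n, tm, start, lower = lo, upper = hi, se = FALSE)

  L <- sem$lambda
  Phi <- sem$phi
  flip <- c(sign(L[1, 1]), sign(L[2, 2]), if (use_sex) 1)
  flip[flip == 0] <- 1
  L <- sweep(L, 2, flip, "*")
  Phi <- diag(flip) %*% Phi %*% diag(flip)

  li <- L[seq(1, 2 * p, 2), 1]
  ls <- L[seq(2, 2 * p, 2), 2]
  sdI <- D[seq(1, 2 * p, 2)]
  sdS <- D[seq(2, 2 * p, 2)]
  a1 <- li[1] * sdI[1]
  b1 <- ls[1] * sdS[1]
  lamI <- li * sdI / ifelse(abs(a1) > 1e-300, a1, 1)
  lamS <- ls * sdS / ifelse(abs(b1) > 1e-300, b1, 1)
  thI <- diag(sem$theta)[seq(1, 2 * p, 2)] * sdI^2
  thS <- diag(sem$theta)[seq(2, 2 * p, 2)] * sdS^2

  # domain slope mean in the marker metric from the per-test slope means
  mu_t <- joint$fill$nu[seq(2, 2 * p, 2)]
  muS <- sum(lamS * mu_t) / sum(lamS^2)

  sex_eff <- NULL
  sex_cov_int <- sex_cov_slp <- NULL
  if (use_sex) {
    sex_eff <- c(intercept = Phi[1, 3], slope = Phi[2, 3])
    sex_cov_int <- Phi[1, 3] * a1 * D[m]
    sex_cov_slp <- Phi[2, 3] * b1 * D[m]
  }
  out <- list(domain = domain, tests = tests,
              loadings = data.frame(test = tests,
                                    lambda_int = lamI, lambda_slp = lamS,
                                    std_lambda_int = li, std_lambda_slp = ls),
              slope_mean = muS, slope_var = b1^2,
              intercept_var = a1^2, int_slope_cov = Phi[1, 2] * a1 * b1,
              resid_int_var = thI, resid_slope_var = thS,
              resid_var = joint$fill$theta, test_means = joint$fill$nu[seq(1, 2 * p, 2)],
              test_slope_means = mu_t,
              sex_cov_int = sex_cov_int, sex_cov_slp = sex_cov_slp,
              sex_effects = sex_eff,
              sex_var = if (use_sex) Slat[m, m] else NULL,
              sex_mean = if (use_sex) joint$fill$nu[m] else NULL,
              latent_cov = Slat, stage2 = sem, joint = joint,
              loglik = joint$loglik,
              convergence = max(joint$convergence, sem$convergence),
              converged = joint$converged && sem$converged,
              time = time)
  if (!out$converged)
    warning("factor-of-curves model for '", domain, "' may not have converged")
  class(out) <- "foc_fit"
  out
}

#' Bartlett-weighted composites tracking the cortical change factors
#'
#' From a fitted bifactor model, computes Bartlett weights
#' \code{W = Theta^-1 Lambda (Lambda' Theta^-1 Lambda)^-1} on the
#' standardized-slope scale, so the latent slope of the f-th weighted
#' composite of raw volumes equals the f-th change factor plus uncorrelated
#' residual contamination (\code{W' Lambda = I}). The model-implied
#' attenuation factor \code{(1 + w' Theta w)^-1/2} converts composite-factor
#' correlations into factor-factor correlations.
#'
#' @param brain_fit a \code{bifactor_fit} over ROI slopes.
#' @param slope_sd named vector of latent slope SDs per ROI (from the
#'   univariate growth fits), used to map standardized weights to raw volumes.
#' @return list: \code{weights_std}, \code{weights_raw}, \code{attenuation},
#'   \code{variables}, \code{factor_names}.
#' @export
factor_composites <- function(brain_fit, slope_sd) {
  stopifnot(inherits(brain_fit, "bifactor_fit"))
  L <- brain_fit$loadings
  Th <- brain_fit$theta
  # the bifactor model is fitted to the latent slope block, whose labels
  # carry the _slp suffix; composites are built from the raw panel columns
  vars <- sub("_slp$", "", rownames(L))
  if (!all(vars %in% names(slope_sd)))
    names(slope_sd) <- sub("_slp$", "", names(slope_sd))
  stopifnot(all(vars %in% names(slope_sd)))
  d <- diag(Th)
  ridge <- pmax(0.01 - d, 0)
  Thr <- Th + diag(ridge)
  Thi <- solve(Thr)
  M <- t(L) %*% Thi %*% L
  W <- Thi %*% L %*% solve(M)
  att <- 1 / sqrt(1 + diag(t(W) %*% Thr %*% W))
  W_raw <- W / slope_sd[vars]
  list(weights_std = W, weights_raw = W_raw, attenuation = att,
       variables = vars, factor_names = colnames(L))
}

#' @keywords internal
add_composites <- function(panel, comp, prefix = "comp_") {
  V <- as.matrix(panel[, comp$variables, drop = FALSE])
  sc <- V %*% comp$weights_raw
  nm <- paste0(prefix, comp$factor_names)
  scl <- numeric(length(nm))
  for (j in seq_along(nm)) {
    v <- sc[, j]
    s <- stats::sd(v[panel$wave == min(panel$wave)], na.rm = TRUE)
    scl[j] <- if (is.finite(s) && s > 0) s else 1
    panel[[nm[j]]] <- v / scl[j]
  }
  attr(panel, "composite_names") <- nm
  # the composite's latent slope is w'S (unit loading on its change factor)
  # divided by this scale; coupling correlations are recovered through it
  attr(panel, "composite_scales") <- stats::setNames(scl, nm)
  panel
}

# core coupled model: joint FIML over composite trajectories, optionally one
# cognitive domain's tests, and static covariates. Measurement parameters
# are fixed from the prior fits; the cross-covariance block — including the
# composite-slope x marker-residual-slope covariances that carry the
# marker-identified coupling — is free, and every free parameter is a
# covariance or mean, so the analytic pattern gradient applies throughout.
#' @keywords internal
fit_structural_block <- function(panel, comp_names, comp_fit, foc = NULL,
                                 covariates = character(0), time = "baseline") {
  nc <- length(comp_names)
  tests <- if (!is.null(foc)) foc$tests else character(0)
  p_t <- length(tests)
  statics <- covariates[covariates %in% names(panel)]
  if (length(statics) != length(covariates))
    stop("covariate column(s) missing from panel: ",
         paste(setdiff(covariates, statics), collapse = ", "))
  pat <- build_patterns(panel, c(comp_names, tests), static_vars = statics,
                        time = time)

  ids <- unique(panel$id)
  st_mean <- vapply(statics, function(v) mean(panel[[v]][match(ids, panel$id)],
                                              na.rm = TRUE), numeric(1))
  st_var <- vapply(statics, function(v) stats::var(panel[[v]][match(ids, panel$id)],
                                                   na.rm = TRUE), numeric(1))

  # core latents: comp (I,S) x nc, [etaI, etaS], statics; the test-level
  # residual latents stay in the pattern metric via the fixed map B
  ncore <- 2 * nc + (if (p_t) 2 else 0) + (if (p_t) 2 * p_t else 0) +
    length(statics)
  m_pat <- 2 * (nc + p_t) + length(statics)
  B <- matrix(0, m_pat, ncore)
  for (i in seq_len(2 * nc)) B[i, i] <- 1
  off <- 2 * nc
  if (p_t) {
    for (t in seq_len(p_t)) {
      B[off + 2 * t - 1, 2 * nc + 1] <- foc$loadings$lambda_int[t]
      B[off + 2 * t - 1, 2 * nc + 2 + t] <- 1
      B[off + 2 * t, 2 * nc + 2] <- foc$loadings$lambda_slp[t]
      B[off + 2 * t, 2 * nc + 2 + p_t + t] <- 1
    }
  }
  for (s in seq_along(statics))
    B[m_pat - length(statics) + s, ncore - length(statics) + s] <- 1

  # fixed parts of the core covariance and means
  psi <- matrix(0, ncore, ncore)
  nu <- numeric(ncore)
  psi[1:(2 * nc), 1:(2 * nc)] <- comp_fit$fill$psi
  nu[1:(2 * nc)] <- comp_fit$fill$nu
  if (p_t) {
    i1 <- 2 * nc + 1; i2 <- 2 * nc + 2
    psi[i1, i1] <- foc$intercept_var
    psi[i2, i2] <- foc$slope_var
    psi[i1, i2] <- psi[i2, i1] <- foc$int_slope_cov
    diag(psi)[2 * nc + 2 + seq_len(p_t)] <- foc$resid_int_var
    diag(psi)[2 * nc + 2 + p_t + seq_len(p_t)] <- foc$resid_slope_var
    nu[i2] <- foc$slope_mean
    nu[2 * nc + 2 + seq_len(p_t)] <- foc$test_means
  }
  for (s in seq_along(statics)) {
    j <- ncore - length(statics) + s
    psi[j, j] <- st_var[s]
    nu[j] <- st_mean[s]
  }
  theta <- c(comp_fit$fill$theta,
             if (p_t) foc$resid_var)

  # free cross-covariances: comp latents x (eta, statics), eta x statics,
  # among statics; additionally comp slopes x the marker test's residual
  # slope, so the factor-outcome covariance is identified through the marker
  # indicator (whose loading is exactly 1 by construction) rather than pooled
  # over estimated loadings
  core_idx <- list(comp = 1:(2 * nc),
                   eta = if (p_t) 2 * nc + 1:2 else integer(0),
                   es1 = if (p_t) 2 * nc + 2 + p_t + 1 else integer(0),
                   st = if (length(statics)) ncore - length(statics) +
                     seq_along(statics) else integer(0))
  free_tgt <- c(core_idx$eta, core_idx$st)
  psi[core_idx$comp, free_tgt] <- NA_real_
  psi[free_tgt, core_idx$comp] <- NA_real_
  if (p_t) {
    slp_rows <- seq(2, 2 * nc, by = 2)
    psi[slp_rows, core_idx$es1] <- NA_real_
    psi[core_idx$es1, slp_rows] <- NA_real_
  }
  if (p_t && length(statics)) {
    psi[core_idx$eta, core_idx$st] <- NA_real_
    psi[core_idx$st, core_idx$eta] <- NA_real_
  }
  if (length(statics) > 1) {
    blk <- core_idx$st
    for (a in blk) for (b in blk) if (a < b) psi[a, b] <- psi[b, a] <- NA_real_
  }

  # transform patterns to the core metric: pattern latents are standardized
  # internally, so Lambda_eff = Lambda_pattern %*% diag(1/s) %*% B, with the
  # core parameters kept in original data units
  Bs <- B / latent_scales(pat)
  theta <- theta / pat$scales^2
  pat2 <- pat
  pat2$patterns <- lapply(pat$patterns, function(pp) {
    pp$lambda <- pp$lambda %*% Bs
    pp
  })
  pat2$m <- ncore
  pat2$scales <- rep(1, length(pat$scales))
  pat2$latent_names <- c(paste0(rep(comp_names, each = 2), c("_int", "_slp")),
                         if (p_t) c("etaI", "etaS",
                                    paste0("eI_", tests), paste0("eS_", tests)),
                         statics)
  pat2$growth_vars <- c(comp_names, tests)

  tmpl <- list(nu = nu, psi = psi, theta = theta)
  idx <- template_index(tmpl)
  # starting values: measurement frees at their measurement-model estimates,
  # cross-covariances at zero
  start <- rep(0, idx$n_par)
  lower <- rep(-Inf, idx$n_par)
  if (length(idx$nu_free)) {
    # the only free mean is the domain slope mean
    start[seq_along(idx$nu_free)] <- foc$slope_mean
  }
  if (nrow(idx$psi_free)) {
    dg <- which(idx$psi_free[, 1] == idx$psi_free[, 2])
    for (jj in seq_len(nrow(idx$psi_free))) {
      a <- idx$psi_free[jj, 1]; b <- idx$psi_free[jj, 2]
      pos <- length(idx$nu_free) + jj
      if (a == b) {
        lower[pos] <- 0
        start[pos] <- if (p_t && a == 2 * nc + 2) foc$slope_var else
          if (p_t && a > 2 * nc + 2 + p_t && a <= 2 * nc + 2 + 2 * p_t)
            foc$resid_slope_var[a - (2 * nc + 2 + p_t)] else 0
      } else if (p_t && a == 2 * nc + 1 && b == 2 * nc + 2) {
        start[pos] <- foc$int_slope_cov
      }
    }
  }

  fit <- fiml_fit(pat2, tmpl, start, lower = lower, hessian = TRUE)
  fit$core_idx <- core_idx
  fit$latent_names <- pat2$latent_names
  fit
}

# Correlation + Wald inference for a free psi entry between a composite's
# latent slope (row i) and an outcome latent (column j). Because the
# Bartlett composite's latent slope equals (factor + uncorrelated
# contamination) / comp_scale, cov(comp slope, outcome) identifies the
# factor-outcome correlation directly:
#   rho = psi_ij * comp_scale / sd(outcome),
# with no reliance on the estimated contamination variance. The Wald z is
# computed on the covariance itself, so p-values are unaffected by the
# rescaling.
#' @keywords internal
psi_corr <- function(fit, i, j, comp_scale = NULL) {
  psi <- fit$fill$psi
  est <- psi[i, j]
  dnm <- if (is.null(comp_scale)) sqrt(psi[i, i] * psi[j, j]) else
    sqrt(psi[j, j]) / unname(comp_scale)
  # locate the free-parameter position
  pf <- fit$idx$psi_free
  pos <- which((pf[, 1] == min(i, j) & pf[, 2] == max(i, j)))
  se_psi <- if (!is.null(fit$se) && length(pos))
    unname(fit$se[length(fit$idx$nu_free) + pos]) else NA_real_
  z <- est / se_psi
  r <- est / dnm
  c(r = min(max(r, -1), 1), se = se_psi / dnm, z = z,
    p = 2 * stats::pnorm(-abs(z)))
}

# Factor-outcome correlation identified through the marker indicator: the
# marker test's latent slope is eta_S + e_1 with a unit loading, so
# cov(comp slope, eta_S) + cov(comp slope, e_1) equals the composite's
# covariance with the marker's latent slope, free of estimated-loading
# attenuation; rho = that sum times comp_scale / sd(eta_S). The Wald test
# uses the sum's standard error from the joint observed information.
#' @keywords internal
psi_marker_corr <- function(fit, i, j_eta, j_es1, comp_scale, sd_eta) {
  psi <- fit$fill$psi
  est <- psi[i, j_eta] + psi[i, j_es1]
  pf <- fit$idx$psi_free
  n_nu <- length(fit$idx$nu_free)
  pos1 <- which(pf[, 1] == min(i, j_eta) & pf[, 2] == max(i, j_eta))
  pos2 <- which(pf[, 1] == min(i, j_es1) & pf[, 2] == max(i, j_es1))
  se_sum <- NA_real_
  if (!is.null(fit$vcov) && length(pos1) && length(pos2)) {
    a <- n_nu + pos1; b <- n_nu + pos2
    se_sum <- sqrt(max(fit$vcov[a, a] + fit$vcov[b, b] +
                       2 * fit$vcov[a, b], 0))
  } else if (!is.null(fit$se) && length(pos1)) {
    se_sum <- unname(fit$se[n_nu + pos1])
  }
  dnm <- sd_eta / unname(comp_scale)
  z <- est / se_sum
  r <- est / dnm
  c(r = min(max(r, -1), 1), se = se_sum / dnm, z = z,
    p = 2 * stats::pnorm(-abs(z)))
}

#' Fit the coupled brain-cognition change model for one domain
#'
#' Two-stage estimator of the correlations between the cortical change
#' factors (general, fronto-temporal, occipito-parietal) and a cognitive
#' domain's latent slope, plus binary covariates. Measurement parameters are
#' fixed from the brain bifactor fit and the domain's factor-of-curves fit
#' (mirroring an analysis that fixes loadings from its initial measurement
#' models); the structural cross-covariance block is estimated by FIML on
#' the joint trajectories of the factor composites, the domain's tests and
#' the covariates. Factor-outcome correlations are identified through the
#' composite slope's unit loading on its factor (its covariance with the
#' outcome equals the correlation times the outcome SD over the composite
#' scale), so no estimated attenuation factor enters the point estimate;
#' Wald z and p come from the covariance itself.
#'
#' @param panel long-format panel.
#' @param brain_fit \code{bifactor_fit} over the ROI slopes.
#' @param foc \code{foc_fit} for the cognitive domain.
#' @param growth_fits list of univariate \code{growth_fit}s for the ROIs
#'   (provides latent slope SDs); required unless \code{composites} given.
#' @param covariates static binary/numeric covariate columns entered as
#'   correlates of the change factors (point-biserial for binary).
#' @param composites optional precomputed \code{\link{factor_composites}}.
#' @param comp_fit optional precomputed joint growth fit of the composites.
#' @param time time coding.
#' @return object of class \code{coupled_fit} with a results table (factor x
#'   outcome correlations, SEs, p) and the underlying fit.
#' @export
fit_coupled_model <- function(panel, brain_fit, foc, growth_fits = NULL,
                              covariates = c("apoe_carrier", "sex"),
                              composites = NULL, comp_fit = NULL,
                              time = "baseline") {
  if (is.null(composites)) {
    stopifnot(!is.null(growth_fits))
    ssd <- vapply(growth_fits, function(f) sqrt(f$estimates[["slope_var"]]),
                  numeric(1))
    names(ssd) <- vapply(growth_fits, `[[`, character(1), "variable")
    composites <- factor_composites(brain_fit, ssd)
  }
  panel <- add_composites(panel, composites)
  comp_names <- attr(panel, "composite_names")
  if (is.null(comp_fit))
    comp_fit <- fit_joint_growth(panel, comp_names, time,
                                 method = "pairwise")

  fit <- fit_structural_block(panel, comp_names, comp_fit, foc = foc,
                              covariates = covariates, time = time)
  comp_scales <- attr(panel, "composite_scales")
  nc <- length(comp_names)
  slp_idx <- seq(2, 2 * nc, by = 2)
  eta_s <- fit$core_idx$eta[2]
  es1 <- fit$core_idx$es1
  k <- length(composites$factor_names)

  rows <- list()
  for (f in seq_len(k)) {
    v <- psi_marker_corr(fit, slp_idx[f], eta_s, es1, comp_scales[f],
                         sd_eta = sqrt(foc$slope_var))
    rows[[length(rows) + 1]] <- data.frame(
      outcome = foc$domain, factor = composites$factor_names[f],
      r = v[["r"]], se = v[["se"]], z = v[["z"]], p = v[["p"]])
  }
  for (s in seq_along(fit$core_idx$st)) {
    for (f in seq_len(k)) {
      v <- psi_corr(fit, slp_idx[f], fit$core_idx$st[s], comp_scales[f])
      rows[[length(rows) + 1]] <- data.frame(
        outcome = covariates[s], factor = composites$factor_names[f],
        r = v[["r"]], se = v[["se"]], z = v[["z"]], p = v[["p"]])
    }
  }
  out <- list(table = do.call(rbind, rows), fit = fit, domain = foc$domain,
              composites = composites, convergence = fit$convergence)
  class(out) <- "coupled_fit"
  out
}

#' Coupling results table across domains and covariates
#'
#' Runs the coupled model for each cognitive domain and one covariate-only
#' model for the binary covariate(s), then applies Benjamini-Hochberg FDR
#' over the single family of all change-factor x (covariate + domain)
#' associations. Sex associations with the cortical factors are reported as a
#' separate check, outside the FDR family.
#'
#' @param panel long-format panel.
#' @param brain_fit \code{bifactor_fit} over ROI slopes.
#' @param foc_fits named list of \code{foc_fit} objects (one per domain).
#' @param growth_fits list of univariate ROI \code{growth_fit}s.
#' @param covariates binary covariate(s) in the FDR family.
#' @param fdr_level q-value flag threshold.
#' @param time time coding.
#' @return object of class \code{coupling_result}.
#' @export
coupling_table <- function(panel, brain_fit, foc_fits, growth_fits,
                           covariates = "apoe_carrier", fdr_level = 0.05,
                           time = "baseline") {
  ssd <- vapply(growth_fits, function(f) sqrt(f$estimates[["slope_var"]]),
                numeric(1))
  names(ssd) <- vapply(growth_fits, `[[`, character(1), "variable")
  comp <- factor_composites(brain_fit, ssd)
  panel2 <- add_composites(panel, comp)
  comp_names <- attr(panel2, "composite_names")
  comp_fit <- fit_joint_growth(panel2, comp_names, time,
                                method = "pairwise")

  sex_available <- "sex" %in% names(panel2)
  cov_all <- unique(c(covariates, if (sex_available) "sex"))

  # covariate-only model (no cognitive side)
  cov_tab <- NULL
  if (length(cov_all)) {
    fitc <- fit_structural_block(panel2, comp_names, comp_fit, foc = NULL,
                                 covariates = cov_all, time = time)
    comp_scales <- attr(panel2, "composite_scales")
    nc <- length(comp_names)
    slp_idx <- seq(2, 2 * nc, by = 2)
    rows <- list()
    for (s in seq_along(fitc$core_idx$st)) {
      for (f in seq_along(comp$factor_names)) {
        v <- psi_corr(fitc, slp_idx[f], fitc$core_idx$st[s],
                      comp_scales[f])
        rows[[length(rows) + 1]] <- data.frame(
          outcome = cov_all[s], factor = comp$factor_names[f],
          r = v[["r"]], se = v[["se"]], z = v[["z"]], p = v[["p"]])
      }
    }
    cov_tab <- do.call(rbind, rows)
  }

  dom_tab <- list()
  fits <- list()
  for (d in names(foc_fits)) {
    cf <- fit_coupled_model(panel, brain_fit, foc_fits[[d]],
                            covariates = character(0), composites = comp,
                            comp_fit = comp_fit, time = time)
    fits[[d]] <- cf
    dom_tab[[d]] <- cf$table
  }
  tab <- rbind(cov_tab[cov_tab$outcome %in% covariates, , drop = FALSE],
               do.call(rbind, dom_tab))
  rownames(tab) <- NULL
  tab$q <- fdr_adjust(tab$p)
  tab$fdr_significant <- tab$q < fdr_level

  sex_tab <- if (sex_available)
    cov_tab[cov_tab$outcome == "sex", , drop = FALSE] else NULL

  out <- list(table = tab, sex_check = sex_tab, fdr_level = fdr_level,
              factors = comp$factor_names,
              outcomes = c(covariates, names(foc_fits)),
              fits = fits, composites = comp)
  class(out) <- "coupling_result"
  out
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment:
#' \code{q_(i) = min_{j >= i} p_(j) * m / j}, capped at 1, returned in the
#' input order.
#'
#' @param p vector of p-values in [0, 1].
#' @return q-values, same length and order.
#' @export
#' @examples
#' fdr_adjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
fdr_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
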