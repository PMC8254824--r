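# Latent growth curves per variable and latent intercept/slope correlations.

# per-participant OLS lines, used for starting values (vectorised via rowsum)
#' @keywords internal
ols_lines <- function(panel, vars, time = "baseline") {
  tsc <- panel_time_scores(panel, time)
  ids <- unique(panel$id)
  fid <- factor(panel$id, levels = ids)
  out <- lapply(vars, function(v) {
    y <- panel[[v]]
    ok <- !is.na(y)
    w <- as.numeric(ok)
    yw <- ifelse(ok, y, 0)
    n_i <- rowsum(w, fid)[, 1]
    St <- rowsum(tsc * w, fid)[, 1]
    Stt <- rowsum(tsc^2 * w, fid)[, 1]
    Sy <- rowsum(yw, fid)[, 1]
    Sty <- rowsum(tsc * yw, fid)[, 1]
    den <- n_i * Stt - St^2
    usable <- n_i >= 2 & den > 1e-12
    slp <- ifelse(usable, (n_i * Sty - St * Sy) / den, NA_real_)
    int <- ifelse(usable, (Sy - slp * St) / n_i, NA_real_)
    # pooled residual variance from participants with >= 3 observations
    ai <- int[fid]; bi <- slp[fid]
    res2 <- ifelse(ok & !is.na(ai), (y - ai - bi * tsc)^2, 0)
    rss_i <- rowsum(res2, fid)[, 1]
    use3 <- usable & n_i >= 3
    dfres <- sum(n_i[use3] - 2)
    rv <- if (dfres > 0) sum(rss_i[use3]) / dfres else NA_real_
    # average OLS sampling covariance of (intercept, slope), used to
    # noise-correct moment-based starting values
    u <- which(usable)
    samp <- c(int = mean(Stt[u] / den[u]), cov = mean(-St[u] / den[u]),
              slp = mean(n_i[u] / den[u]))
    list(int = unname(int), slp = unname(slp), resid_var = rv, samp = samp)
  })
  names(out) <- vars
  out
}

#' Fit a univariate linear latent growth curve by FIML
#'
#' Estimates latent intercept and slope means, variances and covariance plus a
#' wave-invariant residual variance for one longitudinal variable, maximising
#' the observed-data multivariate-normal likelihood over all missingness
#' patterns (participants with any number of observed waves contribute).
#' Standard errors come from the observed information matrix.
#'
#' @param panel long-format panel with columns \code{id}, \code{wave},
#'   \code{age} and the variable.
#' @param variable column name to model.
#' @param time time coding: \code{"baseline"} (years since the participant's
#'   first observed wave; default) or \code{"occasion"} (years between mean
#'   wave ages). In a narrow-age cohort the two are nearly equivalent.
#' @param starts number of deterministic multi-starts (perturbed around
#'   moment-based values); the best likelihood wins.
#' @param se compute standard errors from the observed information.
#' @param pat,ols optionally, precomputed pattern statistics and per-person
#'   OLS lines (internal fast path used by \code{\link{latent_correlations}}).
#' @return An object of class \code{growth_fit}.
#' @export
fit_growth_curve <- function(panel, variable, time = "baseline", starts = 3,
                             se = TRUE, pat = NULL, ols = NULL) {
  if (is.null(pat)) pat <- build_patterns(panel, variable, time = time)
  if (is.null(ols)) ols <- ols_lines(panel, variable, time)[[1]]
  ok <- !is.na(ols$int)
  if (sum(ok) < 3) stop("too few participants with >= 2 waves for '", variable, "'")
  sv <- growth_scale_vec(pat$scales[[1]], pat$t_span)
  mu0 <- c(mean(ols$int[ok]), mean(ols$slp[ok])) / sv[1:2]
  P0 <- stats::cov(cbind(ols$int[ok], ols$slp[ok]))
  th_raw <- ols$resid_var
  if (!is.finite(th_raw) || th_raw <= 0) th_raw <- 0.25 * P0[1, 1]
  # noise-correct the OLS moments (method-of-moments, close to the MLE)
  if (!is.null(ols$samp) && all(is.finite(ols$samp))) {
    corr <- th_raw * matrix(ols$samp[c("int", "cov", "cov", "slp")], 2, 2)
    P0c <- P0 - corr
    e <- eigen(P0c, symmetric = TRUE)
    P0 <- e$vectors %*% (pmax(e$values, 0.02 * max(e$values)) * t(e$vectors))
  }
  P0 <- P0 / matrix(sv[c(3, 4, 4, 5)], 2, 2)
  th0 <- max(th_raw / sv[6], 1e-10)

  tmpl <- list(nu = rep(NA_real_, 2),
               psi = matrix(NA_real_, 2, 2),
               theta = NA_real_)
  base_start <- c(mu0, P0[1, 1], P0[1, 2], P0[2, 2], th0)
  scl <- list(c(1, 1, 1, 1, 1, 1), c(1, 1, 0.5, 0.5, 2, 0.5), c(1, 1, 2, 0.25, 0.5, 2))
  lower <- c(-Inf, -Inf, 0, -Inf, 0, 0)
  best <- NULL
  for (s in seq_len(max(1, starts))) {
    st <- base_start * scl[[1 + (s - 1) %% 3]]
    f <- fiml_fit(pat, tmpl, st, lower = lower)
    if (is.null(best) || f$nll < best$nll) best <- f
  }
  if (se) {
    best2 <- fiml_fit(pat, tmpl, best$par, lower = lower, hessian = TRUE)
    if (best2$nll <= best$nll + 1e-8) best <- best2
  }
  p <- best$par * sv                                  # back to original units
  est <- c(intercept_mean = p[[1]], slope_mean = p[[2]], intercept_var = p[[3]],
           int_slope_cov = p[[4]], slope_var = p[[5]], residual_var = p[[6]])
  r_is <- if (est["intercept_var"] > 0 && est["slope_var"] > 0)
    est[["int_slope_cov"]] / sqrt(est[["intercept_var"]] * est[["slope_var"]]) else NA_real_
  if (!best$converged)
    warning("growth curve for '", variable, "' did not converge (gradient norm ",
            format(best$grad_norm, digits = 3), ")")
  out <- list(variable = variable, estimates = est,
              se = if (!is.null(best$se))
                stats::setNames(best$se * sv, names(est)) else NULL,
              loglik = best$loglik,
              int_slope_corr = r_is,
              pct_per_annum = if (est[["intercept_mean"]] > 0)
                100 * est[["slope_mean"]] / est[["intercept_mean"]] else NA_real_,
              heywood = unname(est[c("intercept_var", "slope_var", "residual_var")] < 1e-10),
              convergence = best$convergence, converged = best$converged,
              grad_norm = best$grad_norm,
              n = pat$n_total, time = time, patterns = length(pat$patterns))
  class(out) <- "growth_fit"
  out
}

#' Percent change per annum implied by a growth curve
#'
#' The unstandardised slope expressed as a percentage of the mean level:
#' \code{100 * slope_mean / intercept_mean}.
#'
#' @param x a \code{growth_fit}, or the slope (units per year).
#' @param level the mean level (same units); required when \code{x} is numeric.
#' @return percent change per annum (numeric scalar).
#' @export
#' @examples
#' percent_annual_change(-3475, 398508)  # about -0.87 %/yr
percent_annual_change <- function(x, level = NULL) {
  if (inherits(x, "growth_fit")) {
    slope <- x$estimates[["slope_mean"]]
    level <- x$estimates[["intercept_mean"]]
  } else {
    slope <- x
    if (is.null(level)) stop("supply the mean level")
  }
  if (!is.finite(level) || level <= 0) stop("mean level must be positive")
  100 * slope / level
}

# profiled bivariate FIML: univariate parameters fixed, cross-covariances free
#' @keywords internal
fit_pair_cross <- function(pat, uni1, uni2, cov0, full = FALSE) {
  e1 <- uni1$estimates; e2 <- uni2$estimates
  psi_fix <- matrix(0, 4, 4)
  psi_fix[1:2, 1:2] <- matrix(c(e1[["intercept_var"]], e1[["int_slope_cov"]],
                                e1[["int_slope_cov"]], e1[["slope_var"]]), 2)
  psi_fix[3:4, 3:4] <- matrix(c(e2[["intercept_var"]], e2[["int_slope_cov"]],
                                e2[["int_slope_cov"]], e2[["slope_var"]]), 2)
  sds <- sqrt(pmax(diag(psi_fix), 0))
  start_cross <- cov0

  shrink <- 1
  repeat {
    psi_try <- psi_fix
    psi_try[1:2, 3:4] <- start_cross * shrink
    psi_try[3:4, 1:2] <- t(start_cross * shrink)
    if (min(eigen(psi_try, symmetric = TRUE, only.values = TRUE)$values) > 1e-10 ||
        shrink < 1e-4) break
    shrink <- shrink / 2
  }
  start_cross <- start_cross * shrink

  s <- latent_scales(pat)
  if (!full) {
    tmpl <- list(nu = c(e1[["intercept_mean"]], e1[["slope_mean"]],
                        e2[["intercept_mean"]], e2[["slope_mean"]]),
                 psi = psi_fix, theta = c(e1[["residual_var"]], e2[["residual_var"]]))
    tmpl$psi[1:2, 3:4] <- NA_real_
    tmpl$psi[3:4, 1:2] <- NA_real_
    # row-major upper triangle order, scaled elementwise
    start <- as.vector(t(start_cross / outer(s[1:2], s[3:4])))
    tmpl_s <- scale_template(tmpl, pat)
    idx <- template_index(tmpl_s)
    memo_par <- NULL; memo_val <- NULL
    compute <- function(par) {
      if (!is.null(memo_par) && identical(par, memo_par)) return(memo_val)
      v <- pattern_nll_grad(template_fill(tmpl_s, idx, par), pat, idx)
      memo_par <<- par; memo_val <<- v
      v
    }
    op <- tryCatch(stats::optim(start, function(p) compute(p)$nll,
                                function(p) compute(p)$grad,
                                method = "L-BFGS-B",
                                control = list(maxit = 300, factr = 1e5)),
                   error = function(e) NULL)
    if (!is.null(op) && op$convergence == 0 && op$value < BIG_NLL / 2) {
      fill <- template_fill(tmpl_s, idx, op$par)
      fit <- list(par = op$par, nll = op$value, convergence = 0,
                  converged = TRUE, fill = fill)
    } else {
      # robust fallback on the same objective
      fit <- fiml_fit(pat, tmpl_s,
                      if (is.null(op)) start else op$par,
                      control = list(iter.max = 300, eval.max = 600,
                                     rel.tol = 1e-9))
    }
  } else {
    tmpl <- list(nu = rep(NA_real_, 4), psi = matrix(NA_real_, 4, 4),
                 theta = rep(NA_real_, 2))
    psi_start <- psi_fix
    psi_start[1:2, 3:4] <- start_cross
    psi_start[3:4, 1:2] <- t(start_cross)
    start <- c(c(e1[["intercept_mean"]], e1[["slope_mean"]],
                 e2[["intercept_mean"]], e2[["slope_mean"]]) / s,
               ut_pack(pd_start(psi_start) / outer(s, s)),
               max(e1[["residual_var"]], 1e-10) / pat$scales[1]^2,
               max(e2[["residual_var"]], 1e-10) / pat$scales[2]^2)
    lower <- rep(-Inf, length(start))
    # variance positions within the packed psi block + thetas
    lower[4 + ut_diag_pos(4)] <- 0
    lower[(length(start) - 1):length(start)] <- 0
    fit <- fiml_fit(pat, tmpl, start, lower = lower)
  }
  fit$psi <- unscale_fill(fit$fill, pat)$psi
  fit
}

# row-major upper-triangle packing (matches template_index order)
#' @keywords internal
ut_pack <- function(M) {
  ij <- which(upper.tri(M, diag = TRUE), arr.ind = TRUE)
  ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE]
  M[ij]
}

#' @keywords internal
ut_diag_pos <- function(m) {
  ij <- which(upper.tri(diag(m), diag = TRUE), arr.ind = TRUE)
  ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE]
  which(ij[, 1] == ij[, 2])
}

#' Latent intercept/slope correlations across variables
#'
#' Estimates the correlation matrix of latent growth intercepts and slopes for
#' a set of longitudinal variables. The default \code{"pairwise"} method fixes
#' each variable's own growth parameters at their univariate FIML estimates
#' and estimates the four cross-covariances of every pair by FIML (a profiled
#' pairwise likelihood); \code{"pairwise_ml"} re-estimates all sixteen
#' bivariate parameters per pair; \code{"simultaneous"} fits one joint model
#' (at most 6 variables). Entries from non-converged pairs are set to
#' \code{NA} and the matrix is flagged.
#'
#' @param panel long-format panel.
#' @param variables character vector of longitudinal variable names.
#' @param method estimation method (see above).
#' @param time time coding, see \code{\link{fit_growth_curve}}.
#' @param fits optional pre-computed list of \code{growth_fit} objects.
#' @return An object of class \code{latent_corr}: a labelled correlation
#'   matrix over \code{<var>_int} and \code{<var>_slp} with positive
#'   definiteness status.
#' @export
latent_correlations <- function(panel, variables,
                                method = c("pairwise", "pairwise_ml", "simultaneous"),
                                time = "baseline", fits = NULL) {
  method <- match.arg(method)
  p <- length(variables)
  stopifnot(p >= 2)
  if (method == "simultaneous" && p > 6)
    stop("simultaneous estimation is limited to 6 variables; use pairwise")

  master <- build_patterns(panel, variables, time = time)
  ols <- ols_lines(panel, variables, time)
  if (is.null(fits)) {
    fits <- lapply(seq_len(p), function(i)
      fit_growth_curve(panel, variables[i], time = time, starts = 1,
                       se = FALSE, pat = subset_patterns(master, i),
                       ols = ols[[i]]))
    names(fits) <- variables
  }

  labels <- c(paste0(variables, "_int"), paste0(variables, "_slp"))
  failures <- character(0)

  if (method == "simultaneous") {
    pat <- master
    tmpl <- list(nu = rep(NA_real_, 2 * p),
                 psi = matrix(NA_real_, 2 * p, 2 * p),
                 theta = rep(NA_real_, p))
    psi0 <- matrix(0, 2 * p, 2 * p)
    nu0 <- numeric(2 * p)
    th0 <- numeric(p)
    for (i in seq_len(p)) {
      e <- fits[[i]]$estimates
      nu0[2 * i - 1] <- e[["intercept_mean"]]; nu0[2 * i] <- e[["slope_mean"]]
      psi0[2 * i - 1, 2 * i - 1] <- e[["intercept_var"]]
      psi0[2 * i, 2 * i] <- e[["slope_var"]]
      psi0[2 * i - 1, 2 * i] <- psi0[2 * i, 2 * i - 1] <- e[["int_slope_cov"]]
      th0[i] <- max(e[["residual_var"]], 1e-10)
    }
    cov_ols <- ols_cross_cov(ols, p)
    sds <- sqrt(diag(psi0))
    for (i in seq_len(p - 1)) for (j in (i + 1):p) {
      bi <- (2 * i - 1):(2 * i); bj <- (2 * j - 1):(2 * j)
      blk <- cov_ols[[paste(i, j)]]
      psi0[bi, bj] <- blk; psi0[bj, bi] <- t(blk)
    }
    psi0 <- pd_start(psi0)
    s <- latent_scales(pat)
    start <- c(nu0 / s, ut_pack(psi0 / outer(s, s)), th0 / pat$scales^2)
    lower <- rep(-Inf, length(start))
    lower[2 * p + ut_diag_pos(2 * p)] <- 0
    lower[(length(start) - p + 1):length(start)] <- 0
    fit <- fiml_fit(pat, tmpl, start, lower = lower)
    if (!fit$converged) failures <- "simultaneous"
    psi <- unscale_fill(fit$fill, pat)$psi
  } else {
    cov_ols <- ols_cross_cov(ols, p)
    psi <- matrix(NA_real_, 2 * p, 2 * p)
    for (i in seq_len(p)) {
      e <- fits[[i]]$estimates
      psi[2 * i - 1, 2 * i - 1] <- e[["intercept_var"]]
      psi[2 * i, 2 * i] <- e[["slope_var"]]
      psi[2 * i - 1, 2 * i] <- psi[2 * i, 2 * i - 1] <- e[["int_slope_cov"]]
    }
    for (i in seq_len(p - 1)) for (j in (i + 1):p) {
      pat <- subset_patterns(master, c(i, j))
      f <- tryCatch(fit_pair_cross(pat, fits[[i]], fits[[j]],
                                   cov_ols[[paste(i, j)]],
                                   full = (method == "pairwise_ml")),
                    error = function(e) NULL)
      bi <- (2 * i - 1):(2 * i); bj <- (2 * j - 1):(2 * j)
      if (is.null(f) || !f$converged) {
        failures <- c(failures, paste(variables[i], variables[j], sep = ":"))
        next
      }
      # express the cross block as correlations under the pair fit's own
      # variances, then rescale to the assembled (univariate) variances so
      # every entry of the matrix is a genuine correlation
      dp <- sqrt(pmax(diag(f$psi), 1e-300))
      cross_r <- f$psi[1:2, 3:4] / outer(dp[1:2], dp[3:4])
      d_asm <- sqrt(pmax(c(diag(psi[bi, bi]), diag(psi[bj, bj])), 0))
      psi[bi, bj] <- cross_r * outer(d_asm[1:2], d_asm[3:4])
      psi[bj, bi] <- t(psi[bi, bj])
    }
  }

  # reorder latents: all intercepts first, then all slopes
  ord <- c(seq(1, 2 * p, by = 2), seq(2, 2 * p, by = 2))
  psi <- psi[ord, ord]
  d <- sqrt(pmax(diag(psi), 0))
  cmat <- psi / outer(d, d)
  diag(cmat) <- 1
  dimnames(cmat) <- list(labels, labels)

  is_pd <- !anyNA(cmat) &&
    min(eigen(cmat, symmetric = TRUE, only.values = TRUE)$values) > 0
  if (length(failures))
    warning("non-converged pairs flagged as missing: ",
            paste(failures, collapse = ", "))
  out <- list(corr = cmat, labels = labels,
              type = rep(c("intercept", "slope"), each = p),
              variables = variables, is_pd = is_pd, source = method,
              failures = failures, n = length(unique(panel$id)), fits = fits)
  class(out) <- "latent_corr"
  out
}

# cross-covariance of per-person OLS intercepts/slopes between variable
# pairs; unbiased for the latent cross block (per-person noise is independent
# across variables), which makes it a near-MLE starting value
#' @keywords internal
ols_cross_cov <- function(ols, p) {
  out <- list()
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    M <- cbind(ols[[i]]$int, ols[[i]]$slp, ols[[j]]$int, ols[[j]]$slp)
    cc <- suppressWarnings(stats::cov(M, use = "pairwise.complete.obs"))
    blk <- cc[1:2, 3:4]
    blk[!is.finite(blk)] <- 0
    out[[paste(i, j)]] <- blk
  }
  out
}

# nudge a symmetric start matrix to strict positive definiteness
#' @keywords internal
pd_start <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  floor_ev <- max(e$values) * 1e-6
  if (min(e$values) >= floor_ev) return(S)
  v <- pmax(e$values, floor_ev)
  out <- e$vectors %*% (v * t(e$vectors))
  (out + t(out)) / 2
}

#' Mean and SD of a latent correlation block
#'
#' Summarises the unique off-diagonal entries of the intercept or slope block
#' of a latent correlation matrix (the "average r" statistic).
#'
#' @param x a \code{latent_corr} object or a square correlation matrix.
#' @param block \code{"slopes"} or \code{"intercepts"} (ignored for a plain
#'   matrix).
#' @return named numeric vector \code{c(mean, sd)}.
#' @export
correlation_summary <- function(x, block = c("slopes", "intercepts")) {
  block <- match.arg(block)
  if (inherits(x, "latent_corr")) {
    keep <- x$type == sub("s$", "", block)
    M <- x$corr[keep, keep, drop = FALSE]
  } else M <- as.matrix(x)
  if (nrow(M) < 2) stop("block must be at least 2 x 2")
  v <- M[upper.tri(M)]
  c(mean = mean(v), sd = stats::sd(v))
}
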