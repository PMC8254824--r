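# Maximum-likelihood covariance structure engine: fits Sigma(theta) =
# Lambda Phi Lambda' + Theta to a sample covariance/correlation matrix by
# minimising the normal-theory discrepancy
#   F = log det Sigma - log det S + tr(S Sigma^-1) - p
# with analytic gradients. Free entries of Lambda, Phi and Theta are marked
# NA in the templates.

#' @keywords internal
sem_index <- function(tm) {
  lam_free <- which(is.na(tm$lambda), arr.ind = TRUE)
  lam_free <- lam_free[order(lam_free[, 1], lam_free[, 2]), , drop = FALSE]
  phi_free <- which(upper.tri(tm$phi, diag = TRUE) & is.na(tm$phi), arr.ind = TRUE)
  phi_free <- phi_free[order(phi_free[, 1], phi_free[, 2]), , drop = FALSE]
  th_free <- which(upper.tri(tm$theta, diag = TRUE) & is.na(tm$theta), arr.ind = TRUE)
  th_free <- th_free[order(th_free[, 1], th_free[, 2]), , drop = FALSE]
  list(lam = lam_free, phi = phi_free, th = th_free,
       n_par = nrow(lam_free) + nrow(phi_free) + nrow(th_free))
}

#' @keywords internal
sem_fill <- function(tm, ix, par) {
  L <- tm$lambda; P <- tm$phi; Th <- tm$theta
  i <- 0L
  if (nrow(ix$lam)) { L[ix$lam] <- par[seq_len(nrow(ix$lam))]; i <- nrow(ix$lam) }
  if (nrow(ix$phi)) {
    v <- par[i + seq_len(nrow(ix$phi))]
    P[ix$phi] <- v; P[ix$phi[, c(2, 1), drop = FALSE]] <- v
    i <- i + nrow(ix$phi)
  }
  if (nrow(ix$th)) {
    v <- par[i + seq_len(nrow(ix$th))]
    Th[ix$th] <- v; Th[ix$th[, c(2, 1), drop = FALSE]] <- v
  }
  list(lambda = L, phi = P, theta = Th)
}

#' @keywords internal
sem_sigma <- function(fl) fl$lambda %*% fl$phi %*% t(fl$lambda) + fl$theta

#' Fit a covariance structure model by maximum likelihood
#'
#' @param S sample covariance or correlation matrix.
#' @param n sample size used for the chi-square and standard errors.
#' @param tm templates: list(lambda, phi, theta) with NA marking free entries.
#' @param start start vector (packed lambda, phi upper triangle, theta upper
#'   triangle, row-major).
#' @param lower,upper box constraints (defaults: free Theta and Phi diagonals
#'   bounded below at 0).
#' @param discrepancy \code{"ml"} (normal-theory maximum likelihood) or
#'   \code{"uls"} (unweighted least squares on all matrix elements, with
#'   normal-theory corrected standard errors and a mean-scaled test
#'   statistic). ULS is the stable choice when \code{S} is an assembled or
#'   projected matrix with near-zero eigenvalues.
#' @keywords internal
sem_fit <- function(S, n, tm, start, lower = NULL, upper = NULL,
                    se = TRUE, discrepancy = c("ml", "uls")) {
  discrepancy <- match.arg(discrepancy)
  S <- as.matrix(S)
  p <- nrow(S)
  ix <- sem_index(tm)
  stopifnot(length(start) == ix$n_par)
  logdetS <- if (discrepancy == "ml")
    determinant(S, logarithm = TRUE)$modulus[1] else 0

  objective <- function(par) {
    fl <- sem_fill(tm, ix, par)
    Sg <- sem_sigma(fl)
    if (discrepancy == "uls") return(0.5 * sum((S - Sg)^2))
    ch <- tryCatch(chol(Sg), error = function(e) NULL)
    if (is.null(ch)) return(BIG_NLL)
    Sinv <- chol2inv(ch)
    val <- 2 * sum(log(diag(ch))) - logdetS + sum(Sinv * S) - p
    if (!is.finite(val)) BIG_NLL else val
  }
  gradient <- function(par) {
    fl <- sem_fill(tm, ix, par)
    Sg <- sem_sigma(fl)
    if (discrepancy == "uls") {
      V <- Sg - S
    } else {
      ch <- tryCatch(chol(Sg), error = function(e) NULL)
      if (is.null(ch)) return(rep(0, length(par)))
      Sinv <- chol2inv(ch)
      V <- Sinv - Sinv %*% S %*% Sinv
    }
    g <- numeric(length(par))
    i <- 0L
    if (nrow(ix$lam)) {
      GL <- 2 * V %*% fl$lambda %*% fl$phi
      g[seq_len(nrow(ix$lam))] <- GL[ix$lam]
      i <- nrow(ix$lam)
    }
    if (nrow(ix$phi)) {
      GP <- t(fl$lambda) %*% V %*% fl$lambda
      mult <- ifelse(ix$phi[, 1] == ix$phi[, 2], 1, 2)
      g[i + seq_len(nrow(ix$phi))] <- GP[ix$phi] * mult
      i <- i + nrow(ix$phi)
    }
    if (nrow(ix$th)) {
      mult <- ifelse(ix$th[, 1] == ix$th[, 2], 1, 2)
      g[i + seq_len(nrow(ix$th))] <- V[ix$th] * mult
    }
    g
  }

  if (is.null(lower)) {
    lower <- rep(-Inf, ix$n_par)
    if (nrow(ix$phi)) {
      pos <- nrow(ix$lam) + which(ix$phi[, 1] == ix$phi[, 2])
      lower[pos] <- 0
    }
    if (nrow(ix$th)) {
      pos <- nrow(ix$lam) + nrow(ix$phi) + which(ix$th[, 1] == ix$th[, 2])
      lower[pos] <- 0
    }
  }
  if (is.null(upper)) upper <- rep(Inf, ix$n_par)

  ctrl <- list(iter.max = 1000, eval.max = 2000, rel.tol = 1e-12)
  opt <- stats::nlminb(start, objective, gradient = gradient,
                       lower = lower, upper = upper, control = ctrl)
  for (r in 1:2) {
    if (opt$convergence == 0) break
    opt2 <- stats::nlminb(opt$par, objective, gradient = gradient,
                          lower = lower, upper = upper, control = ctrl)
    if (opt2$objective <= opt$objective) opt <- opt2 else break
  }
  if (opt$convergence != 0) {
    op <- stats::optim(opt$par, objective, gradient, method = "L-BFGS-B",
                       lower = lower, upper = upper,
                       control = list(maxit = 300, factr = 1e4))
    if (op$value <= opt$objective + 1e-12)
      opt <- list(par = op$par, objective = op$value,
                  convergence = op$convergence, message = op$message)
  }
  gfin <- gradient(opt$par)
  # at box bounds the raw gradient need not vanish; project it
  at_lo <- opt$par <= lower + 1e-10
  at_hi <- opt$par >= upper - 1e-10
  gproj <- gfin
  gproj[at_lo & gfin > 0] <- 0
  gproj[at_hi & gfin < 0] <- 0
  rel_g <- max(abs(gproj) * pmax(abs(opt$par), 1)) / (1 + abs(opt$objective))
  fl <- sem_fill(tm, ix, opt$par)
  Sg <- sem_sigma(fl)
  Fmin <- opt$objective
  df <- p * (p + 1) / 2 - ix$n_par

  # residuals / SRMR on the correlation scale
  d <- sqrt(diag(S))
  Rres <- (S - Sg) / outer(d, d)
  srmr <- sqrt(sum(Rres[lower.tri(Rres, diag = TRUE)]^2) / (p * (p + 1) / 2))

  out <- list(par = opt$par, objective = Fmin, convergence = opt$convergence,
              converged = opt$convergence == 0 || rel_g < 1e-5,
              message = opt$message, lambda = fl$lambda, phi = fl$phi,
              theta = fl$theta, sigma = Sg, df = df, n = n,
              srmr = srmr, ix = ix, tm = tm, S = S,
              discrepancy = discrepancy)
  if (discrepancy == "ml") {
    out$chi2 <- (n - 1) * Fmin
    if (se) {
      H <- grad_jacobian(gradient, opt$par)
      V <- tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(V)) {
        out$vcov <- (2 / (n - 1)) * V
        out$se <- sqrt(pmax(diag(out$vcov), 0))
      }
    }
  } else if (se || TRUE) {
    gam <- uls_inference(S, n, tm, ix, opt$par, Sg, df)
    out$vcov <- gam$vcov
    out$se <- gam$se
    out$chi2 <- gam$chi2_scaled
    out$chi2_null <- gam$chi2_null_scaled
    out$df_null <- p * (p - 1) / 2
  }
  out
}

# Normal-theory corrected inference for the ULS estimator: sandwich standard
# errors acov = (D'D)^-1 D' Gamma D (D'D)^-1 / (n-1) with Gamma the
# normal-theory covariance of the sample (co)variances, and a mean-scaled
# test statistic T = (n-1) * 2F * df / tr(U Gamma) where U projects onto the
# residual space of the model derivatives.
#' @keywords internal
uls_inference <- function(S, n, tm, ix, par, Sg, df) {
  p <- nrow(S)
  ut <- which(upper.tri(S, diag = TRUE), arr.ind = TRUE)
  ut <- ut[order(ut[, 1], ut[, 2]), , drop = FALSE]
  np <- nrow(ut)
  # duplication weights: off-diagonal elements count twice in the full-matrix
  # least squares
  w <- ifelse(ut[, 1] == ut[, 2], 1, 2)

  vech_sigma <- function(pp) {
    fl <- sem_fill(tm, ix, pp)
    sem_sigma(fl)[ut]
  }
  q <- length(par)
  D <- matrix(0, np, q)
  for (j in seq_len(q)) {
    h <- 1e-6 * max(1, abs(par[j]))
    pp <- par; pp[j] <- pp[j] + h
    pm <- par; pm[j] <- pm[j] - h
    D[, j] <- (vech_sigma(pp) - vech_sigma(pm)) / (2 * h)
  }
  # normal-theory Gamma for vech(S): cov(s_ij, s_kl) =
  # (s_ik s_jl + s_il s_jk) / (n - 1)
  i1 <- ut[, 1]; j1 <- ut[, 2]
  Gam <- S[i1, i1] * S[j1, j1] + S[i1, j1] * S[j1, i1]
  Dw <- D * w
  A <- crossprod(D, Dw)                    # D' W D with W = diag(w)
  Ai <- tryCatch(solve(A), error = function(e) NULL)
  out <- list(vcov = NULL, se = NULL)
  GW <- Gam * outer(w, w)                  # W Gamma W
  if (!is.null(Ai)) {
    mid <- crossprod(Dw, Gam %*% Dw)
    V <- Ai %*% mid %*% Ai / (n - 1)
    out$vcov <- V
    out$se <- sqrt(pmax(diag(V), 0))
  }
  # mean-scaled test statistic: E[ (n-1) 2F ] approx tr(U Gamma) under the
  # model, so T_scaled = (n-1) * 2F * df / tr(U Gamma)
  F_uls <- 0.5 * sum((S - Sg)^2)
  trUG <- sum(diag(GW)) -
    if (!is.null(Ai)) sum(Ai * crossprod(Dw, GW %*% D)) else 0
  out$chi2_scaled <- if (trUG > 0) (n - 1) * 2 * F_uls * df / trUG else NA_real_
  # independence model (identity Sigma for a correlation matrix)
  off <- ut[, 1] != ut[, 2]
  F0 <- 0.5 * sum(w[off] * (S[ut][off])^2)
  trU0G <- sum(diag(GW)[off])
  df0 <- sum(off)
  out$chi2_null_scaled <- if (trU0G > 0) (n - 1) * 2 * F0 * df0 / trU0G else NA_real_
  out
}

#' Incremental and absolute fit indices
#'
#' Standard formulas: CFI and TLI against a null (independence) model, RMSEA
#' \code{sqrt(max(0, chi2 - df) / (df * (n - 1)))}. The null model must not
#' fit better than the target model.
#'
#' @param chi2,df target model chi-square and degrees of freedom.
#' @param chi2_null,df_null independence model chi-square and df.
#' @param n sample size.
#' @return named vector: chi2, df, cfi, tli, rmsea.
#' @export
fit_indices <- function(chi2, df, chi2_null, df_null, n) {
  stopifnot(df > 0, df_null > 0, n > 1)
  if (chi2_null < chi2 - 1e-8)
    warning("null model fits better than the target model")
  num <- max(chi2 - df, 0)
  den <- max(chi2_null - df_null, chi2 - df, 0)
  cfi <- if (den == 0) 1 else 1 - num / den
  tli <- if (chi2_null / df_null - 1 <= 0) 1 else
    ((chi2_null / df_null) - (chi2 / df)) / ((chi2_null / df_null) - 1)
  rmsea <- sqrt(max(0, (chi2 - df) / (df * (n - 1))))
  c(chi2 = chi2, df = df, cfi = cfi, tli = min(tli, 1), rmsea = rmsea)
}
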