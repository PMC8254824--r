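# Confirmatory bifactor model of ROI slope correlations: specification from
# the exploratory solution, constrained ML fit, iterative pruning of
# non-significant loadings, Heywood handling and variance decomposition.

#' Build a confirmatory bifactor specification from an exploratory solution
#'
#' Every variable loads on the general factor; each variable is assigned to at
#' most one group factor, the one with its largest salient (strictly above the
#' threshold) residualised group loading. Variables with no salient group
#' loading load on the general factor only. Ties between group loadings are
#' broken towards the lower factor index with a warning. Residual correlations
#' are placed between spatially contiguous pairs found in the adjacency list.
#'
#' @param sl a \code{schmid_leiman} solution.
#' @param adjacency two-column data.frame of contiguous variable pairs
#'   (default: the shipped Desikan-Killiany adjacency); pairs involving
#'   variables absent from the solution are dropped. Use \code{NULL} for no
#'   residual correlations.
#' @param salience salience threshold (strict inequality).
#' @return object of class \code{bifactor_spec}: data.frame
#'   \code{assignments} (variable, group; 0 = general only) and
#'   \code{residual_pairs}.
#' @export
build_bifactor_spec <- function(sl, adjacency = dk_adjacency(), salience = 0.3) {
  stopifnot(inherits(sl, "schmid_leiman"))
  if (sl$no_general) stop("the exploratory solution has no general factor")
  G <- sl$group
  vars <- rownames(G)
  k <- ncol(G)
  group <- integer(length(vars))
  for (i in seq_along(vars)) {
    sal <- which(abs(G[i, ]) > salience)
    if (!length(sal)) next
    mags <- abs(G[i, sal])
    top <- sal[mags == max(mags)]
    if (length(top) > 1)
      warning("variable '", vars[i], "' ties between group factors ",
              paste(top, collapse = " and "), "; assigned to the lower index")
    group[i] <- min(top)
  }
  pairs <- NULL
  if (!is.null(adjacency)) {
    adjacency <- as.data.frame(adjacency)
    keep <- adjacency[[1]] %in% vars & adjacency[[2]] %in% vars
    pairs <- adjacency[keep, 1:2, drop = FALSE]
    names(pairs) <- c("a", "b")
    rownames(pairs) <- NULL
  }
  out <- list(assignments = data.frame(variable = vars, group = group,
                                       stringsAsFactors = FALSE),
              residual_pairs = pairs, k = k, salience = salience)
  class(out) <- "bifactor_spec"
  out
}

#' Fit a confirmatory bifactor model to a slope correlation matrix
#'
#' Maximum-likelihood fit of the constrained structure: a general factor on
#' which every variable loads, group factors orthogonal to it (but free to
#' correlate with one another), free residual variances bounded at zero
#' (Heywood cases end on the boundary and are reported), and free residual
#' covariances between contiguous pairs. Loadings whose Wald test is
#' non-significant are pruned one at a time (largest p first) and the model
#' is refit until all retained loadings are significant.
#'
#' @param spec a \code{bifactor_spec}.
#' @param R correlation matrix over the variables in \code{spec} (e.g. the
#'   projected latent slope correlation block).
#' @param n effective sample size.
#' @param sl optional \code{schmid_leiman} solution supplying starting values.
#' @param alpha pruning significance level (two-sided Wald z).
#' @param prune logical; prune non-significant loadings.
#' @param max_prune safety cap on pruning iterations.
#' @param discrepancy fitting function: \code{"uls"} (default; unweighted
#'   least squares with normal-theory corrected standard errors and a
#'   mean-scaled test statistic, stable for assembled/projected latent
#'   correlation matrices) or \code{"ml"}.
#' @return object of class \code{bifactor_fit}.
#' @export
fit_bifactor <- function(spec, R, n, sl = NULL, alpha = 0.05, prune = TRUE,
                         max_prune = 30, discrepancy = c("uls", "ml")) {
  discrepancy <- match.arg(discrepancy)
  stopifnot(inherits(spec, "bifactor_spec"))
  R <- as.matrix(R)
  vars <- spec$assignments$variable
  stopifnot(all(vars %in% rownames(R)))
  R <- R[vars, vars]
  p <- length(vars)
  k <- spec$k
  m <- 1 + k

  lam <- matrix(0, p, m, dimnames = list(vars, c("general", paste0("F", 1:k))))
  lam[, 1] <- NA_real_
  for (i in seq_len(p)) {
    g <- spec$assignments$group[i]
    if (g > 0) lam[i, 1 + g] <- NA_real_
  }
  phi <- diag(m)
  if (k > 1) {
    blk <- matrix(NA_real_, k, k)
    diag(blk) <- 1
    phi[2:m, 2:m] <- blk
  }
  th <- matrix(0, p, p, dimnames = list(vars, vars))
  diag(th) <- NA_real_
  if (!is.null(spec$residual_pairs) && nrow(spec$residual_pairs)) {
    for (r in seq_len(nrow(spec$residual_pairs))) {
      a <- spec$residual_pairs$a[r]; b <- spec$residual_pairs$b[r]
      th[a, b] <- th[b, a] <- NA_real_
    }
  }
  tm <- list(lambda = lam, phi = phi, theta = th)

  # starting values
  lam0 <- matrix(0, p, m)
  if (!is.null(sl)) {
    lam0[, 1] <- pmin(pmax(sl$general[vars], -0.9), 0.95)
    for (i in seq_len(p)) {
      g <- spec$assignments$group[i]
      if (g > 0) lam0[i, 1 + g] <- pmin(pmax(sl$group[vars[i], g], -0.8), 0.8)
    }
  } else {
    lam0[, 1] <- 0.6
    for (i in seq_len(p)) {
      g <- spec$assignments$group[i]
      if (g > 0) lam0[i, 1 + g] <- 0.3
    }
  }
  comm <- rowSums(lam0^2)
  th0 <- pmax(1 - comm, 0.1)

  pack_start <- function(tm) {
    ix <- sem_index(tm)
    st <- numeric(ix$n_par)
    if (nrow(ix$lam)) st[seq_len(nrow(ix$lam))] <- lam0[ix$lam]
    i <- nrow(ix$lam)
    if (nrow(ix$phi)) {
      v <- ifelse(ix$phi[, 1] == ix$phi[, 2], 1, -0.1)
      st[i + seq_len(nrow(ix$phi))] <- v
      i <- i + nrow(ix$phi)
    }
    if (nrow(ix$th)) {
      v <- ifelse(ix$th[, 1] == ix$th[, 2], th0[ix$th[, 1]], 0)
      st[i + seq_len(nrow(ix$th))] <- v
    }
    st
  }
  bounds <- function(tm) {
    ix <- sem_index(tm)
    lo <- rep(-Inf, ix$n_par); hi <- rep(Inf, ix$n_par)
    if (nrow(ix$phi)) {
      dpos <- nrow(ix$lam) + which(ix$phi[, 1] == ix$phi[, 2])
      opos <- nrow(ix$lam) + which(ix$phi[, 1] != ix$phi[, 2])
      lo[dpos] <- 0
      lo[opos] <- -0.995; hi[opos] <- 0.995
    }
    if (nrow(ix$th)) {
      dpos <- nrow(ix$lam) + nrow(ix$phi) + which(ix$th[, 1] == ix$th[, 2])
      lo[dpos] <- 0
    }
    list(lo = lo, hi = hi)
  }

  pruned <- data.frame(variable = character(0), factor = character(0),
                       p = numeric(0))
  fit <- NULL
  for (round in seq_len(max_prune + 1)) {
    b <- bounds(tm)
    fit <- sem_fit(R, n, tm, pack_start(tm), lower = b$lo, upper = b$hi,
                   discrepancy = discrepancy)
    if (!prune) break
    ix <- fit$ix
    if (!nrow(ix$lam) || is.null(fit$se)) break
    lam_se <- fit$se[seq_len(nrow(ix$lam))]
    est <- fit$par[seq_len(nrow(ix$lam))]
    z <- est / pmax(lam_se, 1e-12)
    pv <- 2 * stats::pnorm(-abs(z))
    worst <- which.max(pv)
    if (pv[worst] <= alpha) break
    i <- ix$lam[worst, 1]; j <- ix$lam[worst, 2]
    pruned <- rbind(pruned, data.frame(
      variable = vars[i], factor = colnames(lam)[j], p = pv[worst]))
    tm$lambda[i, j] <- 0
    if (round > max_prune) break
  }

  # standardized solution (input is a correlation matrix; rescale by implied
  # variances so diag(Sigma-hat) deviations don't leak into the shares)
  sdev <- sqrt(pmax(diag(fit$sigma), 1e-12))
  lam_std <- fit$lambda / sdev
  heywood <- vars[diag(fit$theta) < 1e-8]

  # loading table with SEs
  ix <- fit$ix
  ltab <- NULL
  if (nrow(ix$lam)) {
    ltab <- data.frame(variable = vars[ix$lam[, 1]],
                       factor = colnames(lam)[ix$lam[, 2]],
                       est = fit$par[seq_len(nrow(ix$lam))],
                       se = if (!is.null(fit$se)) fit$se[seq_len(nrow(ix$lam))] else NA_real_,
                       stringsAsFactors = FALSE)
    ltab$z <- ltab$est / ltab$se
    ltab$p <- 2 * stats::pnorm(-abs(ltab$z))
  }

  group_corr <- if (k > 1) fit$phi[2:m, 2:m] else NULL

  # fit indices vs independence model
  if (discrepancy == "uls") {
    chi2_null <- fit$chi2_null
    df_null <- fit$df_null
  } else {
    chi2_null <- (n - 1) * (-determinant(R, logarithm = TRUE)$modulus[1] +
                            sum(diag(R %*% diag(1 / diag(R)))) - p)
    df_null <- p * (p - 1) / 2
  }
  idx <- c(fit_indices(fit$chi2, fit$df, chi2_null, df_null, n),
           srmr = fit$srmr)

  ve <- c(colSums(lam_std^2), total = sum(lam_std^2)) / p
  names(ve)[seq_len(m)] <- colnames(lam)

  out <- list(spec = spec, loadings = fit$lambda, loadings_std = lam_std,
              loading_table = ltab, phi = fit$phi, group_corr = group_corr,
              theta = fit$theta, variance_explained = ve,
              fit_indices = idx, chi2 = fit$chi2, df = fit$df, n = n,
              pruned = pruned, heywood = heywood,
              convergence = fit$convergence, sem = fit)
  class(out) <- "bifactor_fit"
  out
}

#' Variance explained by each factor
#'
#' Per factor, the sum of squared standardized loadings divided by the number
#' of variables; the total is the sum over factors.
#'
#' @param x a \code{bifactor_fit}, or a (standardized) loadings matrix.
#' @return named proportions per factor plus \code{total}.
#' @export
variance_explained <- function(x) {
  if (inherits(x, "bifactor_fit")) return(x$variance_explained)
  L <- as.matrix(x)
  v <- colSums(L^2) / nrow(L)
  c(v, total = sum(v))
}
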