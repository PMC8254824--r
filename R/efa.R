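# Exploratory bifactor analysis: minimum-residual extraction, oblimin
# rotation by gradient projection, Schmid-Leiman orthogonalisation and
# factor-count diagnostics.

#' Minimum-residual (minres) factor extraction
#'
#' Finds loadings minimising the sum of squared off-diagonal residuals of
#' \code{R - L L'}. A profile search over uniquenesses (loadings obtained by
#' eigendecomposition of the reduced matrix) is followed by a direct
#' quasi-Newton polish of the loadings on the exact off-diagonal criterion.
#' Column signs are fixed so each column's largest-magnitude loading is
#' positive, and columns are ordered by decreasing sum of squares.
#'
#' @param R correlation matrix (positive definite).
#' @param k number of factors (at least 1, with non-negative residual
#'   degrees of freedom).
#' @return loadings matrix with attributes \code{uniquenesses},
#'   \code{rmsr} (root mean square off-diagonal residual), \code{objective}
#'   and \code{eigenvalues} (of \code{R}).
#' @export
minres_factor <- function(R, k) {
  R <- as.matrix(R)
  p <- nrow(R)
  stopifnot(k >= 1)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("correlation matrix is not positive definite")
  df <- ((p - k)^2 - p - k) / 2
  if (df < 0) stop("k = ", k, " factors cannot be identified for ", p, " variables")

  loadings_from_psi <- function(psi) {
    Rs <- R
    diag(Rs) <- 1 - psi
    e <- eigen(Rs, symmetric = TRUE)
    lam <- sqrt(pmax(e$values[seq_len(k)], 0))
    e$vectors[, seq_len(k), drop = FALSE] %*% diag(lam, k)
  }
  offdiag_obj <- function(L) {
    E <- R - tcrossprod(L)
    diag(E) <- 0
    sum(E^2) / 2
  }
  f_psi <- function(psi) offdiag_obj(loadings_from_psi(psi))

  smc <- 1 - 1 / diag(solve(R))
  start <- pmin(pmax(1 - smc, 1e-3), 0.999)
  op <- stats::optim(start, f_psi, method = "L-BFGS-B",
                     lower = 1e-4, upper = 1, control = list(maxit = 500))
  L <- loadings_from_psi(op$par)

  # polish directly on the off-diagonal least-squares criterion
  fn <- function(v) offdiag_obj(matrix(v, p, k))
  gr <- function(v) {
    L <- matrix(v, p, k)
    E <- R - tcrossprod(L)
    diag(E) <- 0
    as.vector(-2 * E %*% L)
  }
  op2 <- stats::optim(as.vector(L), fn, gr, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  L <- matrix(op2$par, p, k)

  # order and sign conventions
  ssq <- colSums(L^2)
  L <- L[, order(ssq, decreasing = TRUE), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) L[, j] <- -L[, j]
  }
  rownames(L) <- rownames(R)
  colnames(L) <- paste0("MR", seq_len(k))
  E <- R - tcrossprod(L)
  diag(E) <- 0
  attr(L, "uniquenesses") <- 1 - rowSums(L^2)
  attr(L, "rmsr") <- sqrt(sum(E^2) / (p * (p - 1)))
  attr(L, "objective") <- op2$value
  attr(L, "eigenvalues") <- ev
  L
}

# random oblique T matrices for multi-start rotation
#' @keywords internal
random_oblq <- function(k) {
  Tm <- matrix(stats::rnorm(k * k), k, k)
  Tm %*% diag(1 / sqrt(colSums(Tm^2)), k)
}

# quartimin criterion and its gradient wrt the rotated pattern
#' @keywords internal
quartimin_vg <- function(L) {
  k <- ncol(L)
  Nm <- matrix(1, k, k) - diag(k)
  L2 <- L^2
  X <- L2 %*% Nm
  list(f = sum(L2 * X) / 4, Gq = L * X)
}

#' Oblimin (quartimin) rotation by gradient projection
#'
#' Oblique analytic rotation of an unrotated loadings matrix minimising the
#' direct quartimin criterion (oblimin with gamma = 0) via the gradient
#' projection algorithm. For a single factor the input is returned unchanged.
#' Several starts (identity plus random oblique transforms under a fixed seed)
#' guard against local minima; the best criterion value wins.
#'
#' @param A unrotated loadings (variables x factors).
#' @param n_starts number of starts (first is the identity).
#' @param max_iter,eps gradient-projection iteration cap and gradient
#'   tolerance.
#' @param seed seed for the random starts.
#' @return list with \code{pattern}, \code{phi} (factor correlations),
#'   \code{criterion}, \code{convergence} and the criterion \code{trace}.
#' @export
oblimin_rotate <- function(A, n_starts = 5, max_iter = 1000, eps = 1e-7,
                           seed = 1) {
  A <- as.matrix(A)
  k <- ncol(A)
  if (k < 2) {
    return(list(pattern = A, phi = diag(1), criterion = 0,
                convergence = TRUE, trace = numeric(0)))
  }
  gp_one <- function(Tmat) {
    al <- 1
    Ti <- solve(Tmat)
    L <- A %*% t(Ti)
    vg <- quartimin_vg(L)
    f <- vg$f
    G <- -t(t(L) %*% vg$Gq %*% Ti)
    trace <- f
    conv <- FALSE
    for (iter in seq_len(max_iter)) {
      Gp <- G - Tmat %*% diag(colSums(Tmat * G), k)
      s <- sqrt(sum(Gp^2))
      if (s < eps) { conv <- TRUE; break }
      al <- 2 * al
      for (half in 1:20) {
        X <- Tmat - al * Gp
        Tt <- X %*% diag(1 / sqrt(colSums(X^2)), k)
        Tti <- tryCatch(solve(Tt), error = function(e) NULL)
        if (!is.null(Tti)) {
          Lt <- A %*% t(Tti)
          vgt <- quartimin_vg(Lt)
          if (vgt$f < f - 0.5 * s^2 * al) break
        }
        al <- al / 2
      }
      Tmat <- Tt
      Ti <- Tti
      L <- Lt
      f <- vgt$f
      G <- -t(t(L) %*% vgt$Gq %*% Ti)
      trace <- c(trace, f)
    }
    list(pattern = L, phi = crossprod(Tmat), criterion = f,
         convergence = conv, trace = trace)
  }

  rng <- local_rng(seed)
  starts <- c(list(diag(k)),
              if (n_starts > 1) replicate(n_starts - 1, random_oblq(k), simplify = FALSE))
  restore_rng(rng)

  best <- NULL
  for (Tm in starts) {
    sol <- tryCatch(gp_one(Tm), error = function(e) NULL)
    if (!is.null(sol) && (is.null(best) || sol$criterion < best$criterion))
      best <- sol
  }
  if (is.null(best) || !best$convergence)
    stop("oblimin rotation failed to converge; criterion trace: ",
         paste(format(utils::tail(if (is.null(best)) NA else best$trace, 5),
                      digits = 6), collapse = ", "))

  # order factors by SS pattern loadings, fix signs, adjust phi accordingly
  L <- best$pattern
  phi <- best$phi
  ord <- order(colSums(L^2), decreasing = TRUE)
  L <- L[, ord, drop = FALSE]
  phi <- phi[ord, ord, drop = FALSE]
  sgn <- vapply(seq_len(k), function(j) {
    i <- which.max(abs(L[, j])); sign(L[i, j])
  }, numeric(1))
  sgn[sgn == 0] <- 1
  L <- sweep(L, 2, sgn, "*")
  phi <- diag(sgn) %*% phi %*% diag(sgn)
  rownames(L) <- rownames(A)
  colnames(L) <- paste0("F", seq_len(k))
  dimnames(phi) <- list(colnames(L), colnames(L))
  list(pattern = L, phi = phi, criterion = best$criterion,
       convergence = TRUE, trace = best$trace)
}

# save/seed and restore the global RNG so fitting functions are
# deterministic without clobbering the caller's stream
#' @keywords internal
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  old
}

#' @keywords internal
restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible()
}

#' Schmid-Leiman transformation (exploratory bifactor solution)
#'
#' Extracts \code{k} oblique first-order factors (minres + oblimin), factors
#' their correlation matrix at the second order, and orthogonalises: general
#' loadings are \code{pattern \%*\% b} and residualised group loadings are the
#' pattern scaled by the second-order uniquenesses' square roots. With two
#' first-order factors the second-order model is just-identified and the two
#' second-order loadings are set proportionally via the single correlation
#' (both \code{sqrt(phi_12)}). If the first-order factors are essentially
#' uncorrelated there is no general variance to extract: general loadings are
#' zero, groups equal the pattern, and the solution is flagged.
#'
#' @param R correlation matrix (positive definite).
#' @param k number of first-order (group) factors, at least 2.
#' @param salience threshold used by the print method and downstream
#'   confirmatory specification.
#' @return object of class \code{schmid_leiman} with general and group
#'   loadings, the oblique pattern and factor correlations, second-order
#'   loadings, eigenvalues, RMSR and variance shares.
#' @export
schmid_leiman <- function(R, k = 3, salience = 0.3) {
  stopifnot(k >= 2)
  A <- minres_factor(R, k)
  rot <- oblimin_rotate(A)
  P <- rot$pattern
  phi <- rot$phi
  p <- nrow(P)

  no_general <- FALSE
  if (max(abs(phi[upper.tri(phi)])) < 0.01) {
    no_general <- TRUE
    b <- rep(0, k)
  } else if (k == 2) {
    r12 <- phi[1, 2]
    if (r12 <= 0) {
      no_general <- TRUE
      b <- rep(0, k)
    } else b <- rep(sqrt(r12), 2)
  } else {
    b <- as.vector(minres_factor(phi, 1))
    if (mean(b) < 0) b <- -b
    if (any(b < 0)) b[b < 0] <- 0
  }
  b <- pmin(b, 0.999)
  if (no_general)
    warning("first-order factors are essentially uncorrelated; ",
            "no general factor extracted")

  g <- drop(P %*% b)
  Fg <- P %*% diag(sqrt(1 - b^2), k)
  colnames(Fg) <- paste0("F", seq_len(k))
  names(g) <- rownames(P)

  shares <- c(general = sum(g^2), colSums(Fg^2)) / p
  out <- list(general = g, group = Fg, oblique_pattern = P, factor_corr = phi,
              second_order = b, eigenvalues = attr(A, "eigenvalues"),
              rmsr = attr(A, "rmsr"),
              uniquenesses = 1 - (g^2 + rowSums(Fg^2)),
              variance_shares = shares, k = k, salience = salience,
              no_general = no_general)
  class(out) <- "schmid_leiman"
  out
}

#' Factor-count diagnostics over a range of k
#'
#' For each candidate number of group factors, runs the exploratory bifactor
#' analysis and reports eigenvalues, RMSR and the count of salient loadings
#' (absolute loading above \code{salience}, strict) per factor, flagging
#' solutions that contain a group factor with no salient loadings.
#'
#' @param R correlation matrix.
#' @param k_min,k_max candidate range.
#' @param salience salience threshold.
#' @return data.frame with one row per k, plus the solutions as an attribute;
#'   \code{recommended} attribute gives the largest unflagged k.
#' @export
select_nfactors <- function(R, k_min = 2, k_max = 4, salience = 0.3) {
  stopifnot(k_min >= 2, k_max >= k_min)
  ks <- k_min:k_max
  rows <- list()
  sols <- list()
  for (k in ks) {
    sol <- tryCatch(schmid_leiman(R, k, salience), error = function(e) e)
    if (inherits(sol, "error")) {
      rows[[as.character(k)]] <- data.frame(
        k = k, rmsr = NA_real_, min_salient = NA_integer_,
        empty_factor = NA, error = conditionMessage(sol))
      next
    }
    salient <- colSums(abs(sol$group) > salience)
    rows[[as.character(k)]] <- data.frame(
      k = k, rmsr = sol$rmsr, min_salient = min(salient),
      empty_factor = any(salient == 0), error = NA_character_)
    sols[[as.character(k)]] <- sol
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  ok <- out$k[!is.na(out$empty_factor) & !out$empty_factor]
  attr(out, "recommended") <- if (length(ok)) max(ok) else NA_integer_
  attr(out, "solutions") <- sols
  attr(out, "eigenvalues") <- eigen(as.matrix(R), symmetric = TRUE,
                                    only.values = TRUE)$values
  out
}
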