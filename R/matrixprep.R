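# Block separation and nearest positive-definite projection of latent
# correlation matrices.

#' Split a latent correlation matrix into intercept and slope blocks
#'
#' @param x a \code{latent_corr} object, or a labelled square matrix whose row
#'   names end in \code{"_int"} or \code{"_slp"}.
#' @return list with \code{intercepts}, \code{slopes} (square labelled
#'   matrices preserving order) and \code{cross} (intercept x slope block).
#' @export
split_blocks <- function(x) {
  if (inherits(x, "latent_corr")) {
    M <- x$corr
    type <- x$type
  } else {
    M <- as.matrix(x)
    lab <- rownames(M)
    if (is.null(lab)) stop("matrix must carry row labels")
    type <- ifelse(grepl("_int$", lab), "intercept",
                   ifelse(grepl("_slp$", lab), "slope", NA))
    if (anyNA(type))
      stop("unlabelled row(s): ", paste(lab[is.na(type)], collapse = ", "))
  }
  ii <- which(type == "intercept")
  ss <- which(type == "slope")
  list(intercepts = M[ii, ii, drop = FALSE],
       slopes = M[ss, ss, drop = FALSE],
       cross = M[ii, ss, drop = FALSE])
}

#' Nearest correlation matrix (alternating projections)
#'
#' Projects a symmetric unit-diagonal matrix onto the set of positive
#' semi-definite correlation matrices using Higham's alternating projections
#' with Dykstra's correction: alternately project onto the PSD cone (eigenvalue
#' clipping at \code{eig_floor}) and onto the unit-diagonal affine set, with
#' entries clipped to [-1, 1]. Idempotent on matrices that are already valid
#' correlation matrices.
#'
#' @param x symmetric matrix with unit diagonal (e.g. an estimated latent
#'   correlation matrix containing out-of-range values).
#' @param eig_floor smallest admissible eigenvalue of the output.
#' @param max_iter iteration cap; exceeding it is an error.
#' @param tol relative Frobenius convergence tolerance.
#' @return list with \code{matrix} (the projection, labels preserved) and
#'   \code{report} (input minimum eigenvalue, iterations, Frobenius distance,
#'   convergence flag).
#' @export
nearest_pd <- function(x, eig_floor = 1e-8, max_iter = 500, tol = 1e-9) {
  A <- as.matrix(x)
  if (!isTRUE(all.equal(A, t(A), tolerance = 1e-8, check.attributes = FALSE)))
    stop("input must be symmetric")
  if (max(abs(diag(A) - 1)) > 1e-8) stop("input must have a unit diagonal")
  A <- (A + t(A)) / 2
  ev_in <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  report <- list(input_min_eigenvalue = min(ev_in), n_iterations = 0L,
                 frobenius_distance = 0, converged = TRUE)
  if (min(ev_in) >= eig_floor && max(abs(A)) <= 1 + 1e-12) {
    out <- A
    dimnames(out) <- dimnames(as.matrix(x))
    return(list(matrix = out, report = report))
  }

  Y <- A
  DS <- matrix(0, nrow(A), ncol(A))
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    R <- Y - DS
    e <- eigen(R, symmetric = TRUE)
    Xp <- e$vectors %*% (pmax(e$values, eig_floor) * t(e$vectors))
    Xp <- (Xp + t(Xp)) / 2
    DS <- Xp - R
    Ynew <- Xp
    diag(Ynew) <- 1
    Ynew[Ynew > 1] <- 1
    Ynew[Ynew < -1] <- -1
    delta <- norm(Ynew - Y, "F") / max(norm(Ynew, "F"), 1e-12)
    Y <- Ynew
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  # final symmetrisation and eigenvalue check
  Y <- (Y + t(Y)) / 2
  diag(Y) <- 1
  ev_out <- eigen(Y, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev_out) < eig_floor * 0.9) {
    e <- eigen(Y, symmetric = TRUE)
    Y <- e$vectors %*% (pmax(e$values, eig_floor) * t(e$vectors))
    d <- sqrt(diag(Y))
    Y <- Y / outer(d, d)
    Y <- (Y + t(Y)) / 2
    diag(Y) <- 1
  }
  report$n_iterations <- iter
  report$frobenius_distance <- norm(Y - A, "F")
  report$converged <- converged
  if (!converged)
    stop("nearest_pd did not converge in ", max_iter, " iterations ",
         "(Frobenius distance ", format(report$frobenius_distance, digits = 4), ")")
  dimnames(Y) <- dimnames(as.matrix(x))
  list(matrix = Y, report = report)
}
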