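# Full-information maximum likelihood machinery for linear latent growth
# structures with missing waves.
#
# The observed-data likelihood is evaluated per missingness/timing pattern:
# participants sharing the same set of observed columns and the same time
# scores contribute through the pattern's sufficient statistics (n, mean,
# ML covariance), so the objective costs a handful of small matrix
# operations per pattern rather than per participant. Under monotone
# attrition with a shared visit schedule there are as many patterns as
# waves; with individually varying times the grouping degrades gracefully
# to one pattern per distinct time signature.
#
# Model: for observed vector y_p in pattern p,
#   mu_p    = Lambda_p %*% nu
#   Sigma_p = Lambda_p %*% Psi %*% t(Lambda_p) + diag(theta[theta_map_p])
# where the latent vector stacks (intercept, slope) per longitudinal
# variable followed by one latent per static covariate (observed directly,
# zero residual). Lambda_p is fixed (design times), so the analytic
# gradient only involves nu, Psi and theta.

#' @keywords internal
panel_time_scores <- function(panel, time = c("baseline", "occasion")) {
  time <- match.arg(time)
  if (time == "baseline") {
    base <- tapply(panel$age, panel$id, min)
    panel$age - base[as.character(panel$id)]
  } else {
    wave_means <- tapply(panel$age, panel$wave, mean)
    unname(wave_means[as.character(panel$wave)] - wave_means[[1]])
  }
}

# Build pattern sufficient statistics for a set of growth variables and
# static (time-invariant) covariates.
#' @keywords internal
build_patterns <- function(panel, growth_vars, static_vars = character(),
                           time = "baseline", standardize = TRUE) {
  stopifnot(all(c("id", "wave", "age") %in% names(panel)))
  miss <- setdiff(c(growth_vars, static_vars), names(panel))
  if (length(miss)) stop("variables not in panel: ", paste(miss, collapse = ", "))
  for (v in growth_vars) {
    if (all(is.na(panel[[v]]))) stop("variable '", v, "' is entirely missing")
  }
  # internal standardization (scale only, no centering): keeps all optimizer
  # parameters O(1); estimates are mapped back to original units by callers
  scales <- vapply(growth_vars, function(v) {
    s <- stats::sd(panel[[v]], na.rm = TRUE)
    if (!is.finite(s) || s <= 0) 1 else s
  }, numeric(1))
  if (!standardize) scales[] <- 1
  for (g in seq_along(growth_vars))
    panel[[growth_vars[g]]] <- panel[[growth_vars[g]]] / scales[g]

  t_scores <- panel_time_scores(panel, time)
  # time is also rescaled by the study span so slope-related parameters are
  # O(1); the slope latent scale becomes scales/t_span
  t_span <- max(abs(t_scores), 1)
  if (!standardize) t_span <- 1
  t_scores <- t_scores / t_span
  ids <- unique(panel$id)
  n_ids <- length(ids)
  fid <- match(panel$id, ids)

  ng <- length(growth_vars)
  ns <- length(static_vars)
  m <- 2L * ng + ns
  latent_names <- c(as.vector(rbind(paste0(growth_vars, "_int"),
                                    paste0(growth_vars, "_slp"))),
                    static_vars)

  # stack observed cells in (participant, variable, wave) order; a
  # participant's observation vector and design key fall out of one split
  row_ord <- order(fid, panel$wave)
  fid_o <- fid[row_ord]
  t_o <- t_scores[row_ord]
  acc <- vector("list", ng)
  for (g in seq_len(ng)) {
    v <- panel[[growth_vars[g]]][row_ord]
    ok <- which(!is.na(v))
    acc[[g]] <- list(id = fid_o[ok], g = rep.int(g, length(ok)),
                     y = v[ok], t = t_o[ok])
  }
  cid <- unlist(lapply(acc, `[[`, "id"), use.names = FALSE)
  cg <- unlist(lapply(acc, `[[`, "g"), use.names = FALSE)
  cy <- unlist(lapply(acc, `[[`, "y"), use.names = FALSE)
  ct <- unlist(lapply(acc, `[[`, "t"), use.names = FALSE)
  ord <- order(cid, cg)
  cid <- cid[ord]; cg <- cg[ord]; cy <- cy[ord]; ct <- ct[ord]
  ckey <- sprintf("%d:%.6f", cg, ct)

  f_cells <- factor(cid, levels = seq_len(n_ids))
  y_by_id <- split(cy, f_cells)
  g_by_id <- split(cg, f_cells)
  t_by_id <- split(ct, f_cells)
  key_by_id <- vapply(split(ckey, f_cells), paste, character(1),
                      collapse = "|")

  s_by_id <- NULL
  if (ns) {
    first_row <- match(seq_len(n_ids), fid)
    s_by_id <- vapply(static_vars, function(v) panel[[v]][first_row],
                      numeric(n_ids))
    if (ns == 1) s_by_id <- matrix(s_by_id, ncol = 1)
    s_obs <- !is.na(s_by_id)
    skey <- apply(s_obs, 1, function(z) paste0("s", which(z), collapse = "|"))
    key_by_id <- paste(key_by_id, skey, sep = "||")
  }

  usable <- lengths(y_by_id) > 0
  if (ns) usable <- usable | rowSums(!is.na(s_by_id)) > 0
  keep <- which(usable)
  if (!length(keep)) stop("no usable observations for the requested variables")
  groups <- split(keep, key_by_id[keep])

  patterns <- lapply(groups, function(g_idx) {
    i1 <- g_idx[1]
    gg <- g_by_id[[i1]]
    tt <- t_by_id[[i1]]
    kg <- length(gg)
    s_ok <- if (ns) which(!is.na(s_by_id[i1, ])) else integer(0)
    k <- kg + length(s_ok)
    Y <- matrix(0, length(g_idx), k)
    if (kg) Y[, seq_len(kg)] <- matrix(unlist(y_by_id[g_idx],
                                              use.names = FALSE),
                                       nrow = length(g_idx), byrow = TRUE)
    if (length(s_ok)) Y[, kg + seq_along(s_ok)] <-
      s_by_id[g_idx, s_ok, drop = FALSE]
    n <- nrow(Y)
    ybar <- colMeans(Y)
    S <- if (n > 1) crossprod(sweep(Y, 2, ybar)) / n else
      matrix(0, k, k)
    L <- matrix(0, k, m)
    theta_map <- integer(k)
    static_map <- integer(k)
    times <- rep(NA_real_, k)
    if (kg) {
      L[cbind(seq_len(kg), 2 * gg - 1)] <- 1
      L[cbind(seq_len(kg), 2 * gg)] <- tt
      theta_map[seq_len(kg)] <- gg
      times[seq_len(kg)] <- tt
    }
    for (j in seq_along(s_ok)) {
      L[kg + j, 2 * ng + s_ok[j]] <- 1
      static_map[kg + j] <- s_ok[j]
    }
    tg <- theta_map[theta_map > 0]
    list(n = n, ybar = ybar, S = S, lambda = L, theta_map = theta_map,
         theta_rows = split(which(theta_map > 0), tg),
         static_map = static_map, times = times, ids = ids[g_idx])
  })

  loglik_adj <- sum(vapply(patterns, function(p)
    p$n * sum(log(scales[p$theta_map[p$theta_map > 0]])), numeric(1)))
  list(patterns = unname(patterns), m = m, ng = ng, ns = ns,
       growth_vars = growth_vars, static_vars = static_vars,
       latent_names = latent_names, scales = scales, t_span = t_span,
       loglik_adj = loglik_adj,
       n_total = length(keep), n_dropped = length(ids) - length(keep))
}

# latent-space scale vector of a pattern object: c_v for the intercept and
# c_v / t_span for the slope latent of growth variable v, 1 for statics
#' @keywords internal
latent_scales <- function(pat) {
  c(rbind(pat$scales, pat$scales / pat$t_span), rep(1, pat$ns))
}

# scale vector for the packed univariate growth parameter set
# (int mean, slope mean, int var, int-slope cov, slope var, resid var)
#' @keywords internal
growth_scale_vec <- function(cv, t_span) {
  c(cv, cv / t_span, cv^2, cv^2 / t_span, (cv / t_span)^2, cv^2)
}

# convert a template expressed in original data units into the pattern's
# standardized space (free NA entries pass through)
#' @keywords internal
scale_template <- function(tmpl, pat) {
  s <- latent_scales(pat)
  list(nu = tmpl$nu / s,
       psi = tmpl$psi / outer(s, s),
       theta = tmpl$theta / pat$scales^2)
}

# convert filled (estimated) matrices back to original data units
#' @keywords internal
unscale_fill <- function(fill, pat) {
  s <- latent_scales(pat)
  list(nu = fill$nu * s,
       psi = fill$psi * outer(s, s),
       theta = fill$theta * pat$scales^2)
}

# Restrict a master pattern object (built once over many variables) to a
# subset of growth variables and statics: sufficient statistics and design
# rows are simply subset, which avoids rebuilding patterns per variable pair.
#' @keywords internal
subset_patterns <- function(master, g_sel, s_sel = integer(0)) {
  ngs <- length(g_sel)
  lat_cols <- c(as.vector(rbind(2 * g_sel - 1, 2 * g_sel)),
                2 * master$ng + s_sel)
  pats <- lapply(master$patterns, function(p) {
    rows <- which(p$theta_map %in% g_sel |
                  (p$theta_map == 0 & p$static_map %in% s_sel))
    if (!length(rows)) return(NULL)
    theta_new <- match(p$theta_map[rows], g_sel)
    theta_new[is.na(theta_new)] <- 0L
    tg <- theta_new[theta_new > 0]
    list(n = p$n, ybar = p$ybar[rows],
         S = p$S[rows, rows, drop = FALSE],
         lambda = p$lambda[rows, lat_cols, drop = FALSE],
         theta_map = theta_new,
         theta_rows = split(which(theta_new > 0), tg),
         static_map = p$static_map[rows], times = p$times[rows],
         ids = p$ids)
  })
  pats <- pats[!vapply(pats, is.null, logical(1))]
  loglik_adj <- sum(vapply(pats, function(p)
    p$n * sum(log(master$scales[g_sel][p$theta_map[p$theta_map > 0]])),
    numeric(1)))
  list(patterns = pats, m = length(lat_cols), ng = ngs, ns = length(s_sel),
       scales = master$scales[g_sel], t_span = master$t_span,
       loglik_adj = loglik_adj,
       growth_vars = master$growth_vars[g_sel],
       static_vars = master$static_vars[s_sel],
       latent_names = c(as.vector(rbind(
         paste0(master$growth_vars[g_sel], "_int"),
         paste0(master$growth_vars[g_sel], "_slp"))),
         master$static_vars[s_sel]),
       n_total = master$n_total, n_dropped = master$n_dropped)
}

# --- parameter templates -----------------------------------------------------
# A template fixes some entries of (nu, psi, theta) and leaves others NA (free).
# Free parameters are packed in the order: nu, then the upper triangle of psi
# (row-major, diagonal included), then theta.

#' @keywords internal
template_index <- function(tmpl) {
  m <- length(tmpl$nu)
  psi_free <- which(upper.tri(tmpl$psi, diag = TRUE) & is.na(tmpl$psi),
                    arr.ind = TRUE)
  # order by row then col for reproducibility
  psi_free <- psi_free[order(psi_free[, 1], psi_free[, 2]), , drop = FALSE]
  list(nu_free = which(is.na(tmpl$nu)),
       psi_free = psi_free,
       theta_free = which(is.na(tmpl$theta)),
       n_par = sum(is.na(tmpl$nu)) + nrow(psi_free) + sum(is.na(tmpl$theta)))
}

#' @keywords internal
template_fill <- function(tmpl, idx, par) {
  nu <- tmpl$nu; psi <- tmpl$psi; theta <- tmpl$theta
  i <- 0L
  if (length(idx$nu_free)) {
    nu[idx$nu_free] <- par[seq_along(idx$nu_free)]
    i <- length(idx$nu_free)
  }
  if (nrow(idx$psi_free)) {
    v <- par[i + seq_len(nrow(idx$psi_free))]
    psi[idx$psi_free] <- v
    psi[idx$psi_free[, c(2, 1), drop = FALSE]] <- v
    i <- i + nrow(idx$psi_free)
  }
  if (length(idx$theta_free)) theta[idx$theta_free] <- par[i + seq_along(idx$theta_free)]
  list(nu = nu, psi = psi, theta = theta)
}

#' @keywords internal
param_names <- function(tmpl, idx, latent_names, theta_names) {
  c(if (length(idx$nu_free)) paste0("mean_", latent_names[idx$nu_free]),
    if (nrow(idx$psi_free)) paste0("psi_", latent_names[idx$psi_free[, 1]], ".",
                                   latent_names[idx$psi_free[, 2]]),
    if (length(idx$theta_free)) paste0("resid_", theta_names[idx$theta_free]))
}

BIG_NLL <- 1e12

# negative log-likelihood over patterns given filled parameter matrices
#' @keywords internal
pattern_nll <- function(fill, pat) {
  nll <- 0
  for (p in pat$patterns) {
    L <- p$lambda
    Sg <- L %*% fill$psi %*% t(L)
    dd <- which(p$theta_map > 0)
    if (length(dd)) {
      di <- cbind(dd, dd)
      Sg[di] <- Sg[di] + fill$theta[p$theta_map[dd]]
    }
    ch <- tryCatch(chol(Sg), error = function(e) NULL)
    if (is.null(ch)) return(BIG_NLL)
    mu <- drop(L %*% fill$nu)
    delta <- p$ybar - mu
    Sinv_S <- chol2inv(ch)
    quad <- drop(crossprod(delta, Sinv_S %*% delta))
    nll <- nll + 0.5 * p$n * (length(mu) * log(2 * pi) +
                              2 * sum(log(diag(ch))) +
                              sum(Sinv_S * p$S) + quad)
    if (!is.finite(nll)) return(BIG_NLL)
  }
  nll
}

# analytic gradient wrt free (nu, psi, theta); valid because Lambda is fixed
#' @keywords internal
pattern_grad <- function(fill, pat, idx) {
  g_nu <- numeric(length(fill$nu))
  g_psi <- matrix(0, length(fill$nu), length(fill$nu))
  g_theta <- numeric(length(fill$theta))
  for (p in pat$patterns) {
    L <- p$lambda
    Sg <- L %*% fill$psi %*% t(L)
    dd <- which(p$theta_map > 0)
    if (length(dd)) {
      di <- cbind(dd, dd)
      Sg[di] <- Sg[di] + fill$theta[p$theta_map[dd]]
    }
    ch <- tryCatch(chol(Sg), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    Sinv <- chol2inv(ch)
    mu <- drop(L %*% fill$nu)
    delta <- p$ybar - mu
    sdel <- drop(Sinv %*% delta)
    A <- p$S + tcrossprod(delta)
    V <- Sinv - Sinv %*% A %*% Sinv          # dNLL/dSigma = 0.5 n V
    g_nu <- g_nu - p$n * drop(crossprod(L, sdel))
    M <- crossprod(L, V %*% L)
    g_psi <- g_psi + 0.5 * p$n * M
    if (length(dd)) {
      dV <- diag(V)
      tr_names <- as.integer(names(p$theta_rows))
      for (k in seq_along(p$theta_rows)) {
        g_theta[tr_names[k]] <- g_theta[tr_names[k]] +
          0.5 * p$n * sum(dV[p$theta_rows[[k]]])
      }
    }
  }
  # map to free parameters; off-diagonal psi entries appear twice
  gp <- numeric(idx$n_par)
  i <- 0L
  if (length(idx$nu_free)) {
    gp[seq_along(idx$nu_free)] <- g_nu[idx$nu_free]
    i <- length(idx$nu_free)
  }
  if (nrow(idx$psi_free)) {
    mult <- ifelse(idx$psi_free[, 1] == idx$psi_free[, 2], 1, 2)
    gp[i + seq_len(nrow(idx$psi_free))] <- g_psi[idx$psi_free] * mult
    i <- i + nrow(idx$psi_free)
  }
  if (length(idx$theta_free)) gp[i + seq_along(idx$theta_free)] <- g_theta[idx$theta_free]
  gp
}

# combined objective + gradient sharing one factorisation per pattern
#' @keywords internal
pattern_nll_grad <- function(fill, pat, idx) {
  m <- length(fill$nu)
  nll <- 0
  g_nu <- numeric(m)
  g_psi <- matrix(0, m, m)
  g_theta <- numeric(length(fill$theta))
  fail <- list(nll = BIG_NLL, grad = numeric(idx$n_par))
  for (p in pat$patterns) {
    L <- p$lambda
    Sg <- L %*% fill$psi %*% t(L)
    dd <- which(p$theta_map > 0)
    if (length(dd)) {
      di <- cbind(dd, dd)
      Sg[di] <- Sg[di] + fill$theta[p$theta_map[dd]]
    }
    ch <- tryCatch(chol(Sg), error = function(e) NULL)
    if (is.null(ch)) return(fail)
    Sinv <- chol2inv(ch)
    mu <- drop(L %*% fill$nu)
    delta <- p$ybar - mu
    sdel <- drop(Sinv %*% delta)
    quad <- sum(delta * sdel)
    nll <- nll + 0.5 * p$n * (length(mu) * log(2 * pi) +
                              2 * sum(log(diag(ch))) +
                              sum(Sinv * p$S) + quad)
    if (!is.finite(nll)) return(fail)
    A <- p$S + tcrossprod(delta)
    V <- Sinv - Sinv %*% A %*% Sinv
    g_nu <- g_nu - p$n * drop(crossprod(L, sdel))
    g_psi <- g_psi + 0.5 * p$n * crossprod(L, V %*% L)
    if (length(dd)) {
      dV <- diag(V)
      tr_names <- as.integer(names(p$theta_rows))
      for (k in seq_along(p$theta_rows)) {
        g_theta[tr_names[k]] <- g_theta[tr_names[k]] +
          0.5 * p$n * sum(dV[p$theta_rows[[k]]])
      }
    }
  }
  gp <- numeric(idx$n_par)
  i <- 0L
  if (length(idx$nu_free)) {
    gp[seq_along(idx$nu_free)] <- g_nu[idx$nu_free]
    i <- length(idx$nu_free)
  }
  if (nrow(idx$psi_free)) {
    mult <- ifelse(idx$psi_free[, 1] == idx$psi_free[, 2], 1, 2)
    gp[i + seq_len(nrow(idx$psi_free))] <- g_psi[idx$psi_free] * mult
    i <- i + nrow(idx$psi_free)
  }
  if (length(idx$theta_free)) gp[i + seq_along(idx$theta_free)] <- g_theta[idx$theta_free]
  list(nll = nll, grad = gp)
}

#' Fit a pattern-likelihood FIML model
#'
#' Internal driver shared by the growth-curve, latent-correlation and
#' coupled-change fitting functions.
#'
#' @keywords internal
fiml_fit <- function(pat, tmpl, start, lower = NULL, upper = NULL,
                     hessian = FALSE,
                     control = list(iter.max = 500, eval.max = 1000,
                                    rel.tol = 1e-10)) {
  idx <- template_index(tmpl)
  stopifnot(length(start) == idx$n_par)
  if (is.null(lower)) lower <- rep(-Inf, idx$n_par)
  if (is.null(upper)) upper <- rep(Inf, idx$n_par)

  # optimizers request f and its gradient at the same point; share the
  # factorisations through a one-slot memo
  memo_par <- NULL
  memo_val <- NULL
  compute <- function(par) {
    if (!is.null(memo_par) && identical(par, memo_par)) return(memo_val)
    v <- pattern_nll_grad(template_fill(tmpl, idx, par), pat, idx)
    memo_par <<- par
    memo_val <<- v
    v
  }
  obj <- function(par) compute(par)$nll
  gr <- function(par) compute(par)$grad
  fit <- stats::nlminb(start, obj, gradient = gr, lower = lower, upper = upper,
                       control = control)
  # PORT occasionally stalls ("false convergence" / iteration limit) on
  # ill-conditioned problems; restarting from the incumbent fixes it
  for (r in 1:2) {
    if (fit$convergence == 0) break
    fit2 <- stats::nlminb(fit$par, obj, gradient = gr, lower = lower,
                          upper = upper, control = control)
    if (fit2$objective <= fit$objective) fit <- fit2 else break
  }
  if (fit$convergence != 0) {
    op <- stats::optim(fit$par, obj, gr, method = "L-BFGS-B",
                       lower = lower, upper = upper,
                       control = list(maxit = 300, factr = 1e4))
    if (op$value <= fit$objective + 1e-10)
      fit <- list(par = op$par, objective = op$value,
                  convergence = op$convergence, message = op$message)
  }
  gfin <- gr(fit$par)
  grad_norm <- sqrt(sum(gfin^2))
  rel_g <- max(abs(gfin) * pmax(abs(fit$par), 1)) / (1 + abs(fit$objective))
  adj <- if (!is.null(pat$loglik_adj)) pat$loglik_adj else 0
  out <- list(par = fit$par, nll = fit$objective + adj,
              loglik = -(fit$objective + adj),
              convergence = fit$convergence, message = fit$message,
              converged = fit$convergence == 0 || rel_g < 1e-6,
              grad_norm = grad_norm, idx = idx, tmpl = tmpl,
              names = param_names(tmpl, idx, pat$latent_names, pat$growth_vars),
              fill = template_fill(tmpl, idx, fit$par))
  names(out$par) <- out$names
  if (hessian) {
    H <- grad_jacobian(gr, fit$par)
    out$hessian <- H
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V)) {
      se <- sqrt(pmax(diag(V), 0))
      names(se) <- out$names
      out$vcov <- V
      out$se <- se
    }
  }
  out
}

# central-difference jacobian of a gradient function (i.e. a Hessian)
#' @keywords internal
grad_jacobian <- function(gr, par, h_rel = 1e-5) {
  np <- length(par)
  H <- matrix(0, np, np)
  for (j in seq_len(np)) {
    h <- h_rel * max(1, abs(par[j]))
    pp <- par; pp[j] <- pp[j] + h
    pm <- par; pm[j] <- pm[j] - h
    H[, j] <- (gr(pp) - gr(pm)) / (2 * h)
  }
  (H + t(H)) / 2
}
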