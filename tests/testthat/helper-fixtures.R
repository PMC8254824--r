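# shared fixtures: small panels and constructed correlation matrices

# balanced complete-data panel from known lines: y = int + slope * t + noise
make_line_panel <- function(n = 60, times = c(0, 3.75, 6.83), int_mean = 100,
                            int_sd = 10, slope_mean = -2, slope_sd = 1,
                            is_cov = 0, noise = 1, seed = 1) {
  set.seed(seed)
  S <- matrix(c(int_sd^2, is_cov, is_cov, slope_sd^2), 2)
  lat <- mvn_fixture(n, c(int_mean, slope_mean), S)
  rows <- lapply(seq_along(times), function(w) {
    data.frame(id = seq_len(n), wave = w, age = 70 + times[w],
               y = lat[, 1] + lat[, 2] * times[w] + rnorm(n, 0, noise))
  })
  structure(do.call(rbind, rows), latents = lat)
}

mvn_fixture <- function(n, mu, S) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  rt <- e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
  matrix(rnorm(n * length(mu)), n) %*% rt + matrix(mu, n, length(mu), byrow = TRUE)
}

# exact bifactor correlation matrix: p variables, general loading g,
# two group factors with loading f on an alternating block split
bifactor_corr <- function(p = 34, g = 0.75, f = 0.45, rho = 0,
                          groups = rep(1:2, length.out = p)) {
  L <- matrix(0, p, 3)
  L[, 1] <- g
  L[cbind(seq_len(p), 1 + groups)] <- f
  Phi <- diag(3); Phi[2, 3] <- Phi[3, 2] <- rho
  R <- L %*% Phi %*% t(L)
  diag(R) <- 1
  rownames(R) <- colnames(R) <- paste0("v", seq_len(p), "_slp")
  attr(R, "loadings") <- L
  attr(R, "groups") <- groups
  R
}

# small cohort configuration for pipeline-level tests (explicitly scaled
# down from the study-sized defaults to keep unit tests quick)
small_config <- function(n = 250, ...) {
  cohort_config(n_participants = n, ...)
}

skip_slow <- function() invisible(TRUE)  # all tests run; placeholder
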