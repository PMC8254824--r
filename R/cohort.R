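# Synthetic longitudinal cohort generator: a narrow-age cohort measured at
# three waves, with correlated ROI intercepts, a known bifactor structure on
# ROI slopes (general + fronto-temporal + occipito-parietal change factors),
# factor-of-curves cognitive batteries coupled to the general change factor,
# a binary allele-carrier covariate, exclusion flags and MAR attrition
# driven by baseline cognition.

#' @keywords internal
default_cognitive_domains <- function() {
  dom <- function(tests, mean, sd, slope, sign) {
    data.frame(test = tests, mean = mean, sd = sd, slope_mean = slope,
               sign = sign, stringsAsFactors = FALSE)
  }
  list(
    visuospatial = dom(c("matrix_reasoning", "block_design", "spatial_span"),
                       c(13.17, 33.64, 14.69), c(4.96, 10.08, 2.76),
                       c(-0.040, -0.357, -0.082), c(1, 1, 1)),
    speed = dom(c("symbol_search", "digit_symbol", "inspection_time", "choice_rt"),
                c(24.61, 56.40, 111.22, 0.65), c(6.18, 12.31, 11.79, 0.09),
                c(-0.275, -0.755, -0.624, 0.0088), c(1, 1, 1, -1)),
    memory = dom(c("logical_memory", "verbal_pairs", "digit_span_back"),
                 c(74.23, 27.18, 7.81), c(17.89, 9.46, 2.29),
                 c(-0.222, -0.006, -0.037), c(1, 1, 1))
  )
}

#' Configuration for the synthetic longitudinal cohort
#'
#' Assembles and validates all generating parameters. Defaults emulate a
#' same-year-of-birth ageing cohort scanned at mean ages 72.49, 76.24 and
#' 79.32 years with retention 629 -> 428 -> 319, regional volumes and decline
#' rates on the Desikan-Killiany atlas, a bifactor structure on the latent
#' slopes (general factor plus negatively correlated fronto-temporal and
#' occipito-parietal group factors), a deliberately different group structure
#' on the latent intercepts, three cognitive domains whose latent slopes
#' correlate with the general change factor, a binary allele-carrier flag
#' that steepens general decline, and missing-at-random monotone attrition
#' weighted by baseline cognition.
#'
#' @param n_participants cohort size at wave 1.
#' @param wave_age_means mean age (years) at each wave, strictly increasing.
#' @param wave_age_sd SD of the (participant-constant) birth-date offset.
#' @param roi ROI attribute table (see \code{\link{dk_rois}}).
#' @param intercept_sd_frac between-person SD of the latent level, as a
#'   fraction of the mean regional volume.
#' @param slope_sd_frac between-person SD of the latent slope, as a fraction
#'   of mean regional volume per year.
#' @param noise_sd_frac wave-specific measurement noise SD as a fraction of
#'   mean regional volume.
#' @param intercept_g_loading,intercept_group_loading standardized loadings of
#'   latent levels on their general and group factors.
#' @param slope_group_loading_ft,slope_group_loading_op standardized group
#'   loadings of latent slopes (fronto-temporal, occipito-parietal).
#' @param group_factor_corr correlation between the two slope group factors.
#' @param cognitive_domains list of per-domain test tables (name, mean, sd,
#'   slope_mean, sign).
#' @param cog_loading_int,cog_loading_slp standardized loadings of test
#'   intercepts/slopes on the domain factors (sign-adjusted per test).
#' @param cog_int_sd_frac,cog_slope_sd_frac,cog_noise_sd_frac test intercept
#'   SD, slope SD (per year) and measurement noise SD as fractions of the
#'   test's cross-sectional SD.
#' @param brain_cognition_coupling named correlations between the general
#'   change factor and each domain's slope factor.
#' @param domain_slope_corr,domain_int_corr correlations among domain slope
#'   factors and among domain intercept factors.
#' @param sex_intercept_effect additive sex effect on test intercepts (in
#'   test-SD units; males minus females).
#' @param carrier_prevalence allele-carrier prevalence.
#' @param carrier_slope_effect standardized mean difference on the general
#'   change factor for carriers (negative = steeper decline).
#' @param attrition_rates per-transition dropout probabilities (length
#'   \code{n_waves - 1}).
#' @param attrition_cognition_weight log-odds of retention per SD of baseline
#'   cognition (positive = cognitively abler participants return more).
#' @param exclusion_prevalence named vector: \code{dementia_mmse} and
#'   \code{stroke} participant-level flag prevalences.
#' @param seed default seed used by \code{\link{simulate_cohort}}.
#' @return object of class \code{cohort_config}.
#' @export
cohort_config <- function(n_participants = 629,
                          wave_age_means = c(72.49, 76.24, 79.32),
                          wave_age_sd = 0.71,
                          roi = dk_rois(),
                          intercept_sd_frac = 0.12,
                          slope_sd_frac = 0.0045,
                          noise_sd_frac = 0.01,
                          intercept_g_loading = 0.55,
                          intercept_group_loading = 0.40,
                          slope_group_loading_ft = 0.58,
                          slope_group_loading_op = 0.49,
                          group_factor_corr = -0.25,
                          cognitive_domains = default_cognitive_domains(),
                          cog_loading_int = 0.8,
                          cog_loading_slp = 0.75,
                          cog_int_sd_frac = 0.87,
                          cog_slope_sd_frac = 0.04,
                          cog_noise_sd_frac = 0.5,
                          brain_cognition_coupling = c(visuospatial = 0.415,
                                                       speed = 0.369,
                                                       memory = 0.363),
                          domain_slope_corr = 0.6,
                          domain_int_corr = 0.5,
                          sex_intercept_effect = 0.2,
                          carrier_prevalence = 0.30,
                          carrier_slope_effect = -0.22,
                          attrition_rates = c(0.320, 0.255),
                          attrition_cognition_weight = 0.5,
                          exclusion_prevalence = c(dementia_mmse = 31 / 629,
                                                   stroke = 119 / 629),
                          seed = 1L) {
  nw <- length(wave_age_means)
  if (nw < 2 || any(diff(wave_age_means) <= 0))
    stop("wave_age_means must be strictly increasing (>= 2 waves)")
  if (length(attrition_rates) != nw - 1)
    stop("attrition_rates must have length n_waves - 1")
  stopifnot(all(attrition_rates >= 0), all(attrition_rates < 1),
            carrier_prevalence >= 0, carrier_prevalence <= 1)

  p <- nrow(roi)
  intercept_means <- roi$volume
  intercept_sd <- intercept_sd_frac * intercept_means
  slope_means <- roi$pct_change / 100 * intercept_means
  slope_sd <- slope_sd_frac * intercept_means
  noise_sd <- noise_sd_frac * intercept_means

  # standardized slope loadings: general + one group per ROI, capped so the
  # communality stays below 0.95
  slope_loadings <- matrix(0, p, 3,
                           dimnames = list(roi$name, c("g", "F1", "F2")))
  slope_loadings[, 1] <- roi$g_loading
  # per-ROI group loadings if the atlas table carries them (heterogeneous,
  # as reported for real parcels); otherwise the per-factor constants
  grp_val <- if (!is.null(roi$grp_loading)) roi$grp_loading else
    ifelse(roi$change_group == 1, slope_group_loading_ft,
           slope_group_loading_op)
  grp_val <- pmin(grp_val, sqrt(pmax(0.95 - roi$g_loading^2, 0)))
  slope_loadings[cbind(seq_len(p), 1 + roi$change_group)] <- grp_val

  phi_chg <- diag(3)
  phi_chg[2, 3] <- phi_chg[3, 2] <- group_factor_corr
  if (min(eigen(phi_chg, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("non-PSD change-factor block: group_factor_corr = ", group_factor_corr)

  comm <- rowSums((slope_loadings %*% phi_chg) * slope_loadings)
  if (any(comm > 1))
    stop("non-PSD slope model: communalities exceed 1 for ",
         paste(roi$name[comm > 1], collapse = ", "))
  slope_residual_sd <- slope_sd * sqrt(1 - comm)

  # intercept (level) structure: general + two group factors on a different
  # partition of the cortex than the change structure
  int_loadings <- matrix(0, p, 3,
                         dimnames = list(roi$name, c("gI", "L1", "L2")))
  int_loadings[, 1] <- intercept_g_loading
  int_loadings[cbind(seq_len(p), 1 + roi$level_group)] <- intercept_group_loading
  comm_i <- rowSums(int_loadings^2)
  if (any(comm_i > 1)) stop("non-PSD intercept model: communalities exceed 1")
  C_int <- int_loadings %*% t(int_loadings) + diag(1 - comm_i)
  intercept_cov <- C_int * outer(intercept_sd, intercept_sd)

  doms <- names(cognitive_domains)
  if (is.null(doms) || any(!nzchar(doms)))
    stop("cognitive_domains must be a named list")
  if (!all(doms %in% names(brain_cognition_coupling)))
    stop("brain_cognition_coupling must name every cognitive domain")
  brain_cognition_coupling <- brain_cognition_coupling[doms]

  # latent factor correlation matrix: (g, F1, F2, domain slopes, domain
  # intercepts); the carrier-effect variance correction is applied at
  # generation time
  D <- length(doms)
  mfac <- 3 + 2 * D
  Sf <- diag(mfac)
  nm <- c("g", "F1", "F2", paste0("slp_", doms), paste0("int_", doms))
  dimnames(Sf) <- list(nm, nm)
  Sf[2, 3] <- Sf[3, 2] <- group_factor_corr
  alpha <- sqrt(1 - carrier_slope_effect^2 *
                carrier_prevalence * (1 - carrier_prevalence))
  for (d in seq_len(D)) {
    Sf[1, 3 + d] <- Sf[3 + d, 1] <- brain_cognition_coupling[[d]] / alpha
    for (e in seq_len(D)) {
      if (d != e) {
        Sf[3 + d, 3 + e] <- domain_slope_corr
        Sf[3 + D + d, 3 + D + e] <- domain_int_corr
      }
    }
  }
  if (min(eigen(Sf, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("non-PSD cognitive coupling block: check brain_cognition_coupling ",
         "and domain correlations")

  out <- list(n_participants = n_participants,
              wave_age_means = wave_age_means, wave_age_sd = wave_age_sd,
              roi = roi, roi_names = roi$name,
              intercept_means = intercept_means, intercept_sd = intercept_sd,
              intercept_cov = intercept_cov, intercept_loadings = int_loadings,
              slope_means = slope_means, slope_sd = slope_sd,
              slope_loadings = slope_loadings,
              slope_residual_sd = slope_residual_sd,
              group_factor_corr = group_factor_corr, phi_change = phi_chg,
              measurement_noise_sd = noise_sd,
              cognitive_domains = cognitive_domains,
              cog_loading_int = cog_loading_int,
              cog_loading_slp = cog_loading_slp,
              cog_int_sd_frac = cog_int_sd_frac,
              cog_slope_sd_frac = cog_slope_sd_frac,
              cog_noise_sd_frac = cog_noise_sd_frac,
              brain_cognition_coupling = brain_cognition_coupling,
              domain_slope_corr = domain_slope_corr,
              domain_int_corr = domain_int_corr,
              sex_intercept_effect = sex_intercept_effect,
              carrier_prevalence = carrier_prevalence,
              carrier_slope_effect = carrier_slope_effect,
              factor_corr = Sf,
              attrition_rates = attrition_rates,
              attrition_cognition_weight = attrition_cognition_weight,
              exclusion_prevalence = exclusion_prevalence,
              seed = seed)
  class(out) <- "cohort_config"
  out
}

# symmetric PSD square root draw: X = Z %*% msqrt(S) with eigenvalue clipping
# so degenerate (zero-variance) configurations remain valid
#' @keywords internal
mvn_draw <- function(n, mu, S) {
  p <- length(mu)
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  rt <- e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
  matrix(stats::rnorm(n * p), n, p) %*% rt + matrix(mu, n, p, byrow = TRUE)
}

#' Simulate a longitudinal cohort
#'
#' Generates the panel implied by a \code{\link{cohort_config}}: ROI value =
#' latent intercept + latent slope x (age - baseline age) + noise, with slopes
#' composed as loadings x change factors + residual; cognitive tests built
#' from domain intercept/slope factors; monotone MAR attrition weighted by
#' baseline cognition. Deterministic given the seed.
#'
#' @param config a \code{cohort_config}.
#' @param seed integer seed (defaults to \code{config$seed}).
#' @return list with \code{panel} (long-format data.frame: one row per
#'   retained participant-wave) and \code{truth} (all generating parameters
#'   plus realized latents).
#' @export
simulate_cohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  old <- local_rng(seed)
  on.exit(restore_rng(old), add = TRUE)

  n <- config$n_participants
  nw <- length(config$wave_age_means)
  p <- length(config$roi_names)
  doms <- names(config$cognitive_domains)
  D <- length(doms)

  offset <- stats::rnorm(n, 0, config$wave_age_sd)
  ages <- outer(offset, rep(1, nw)) +
    matrix(config$wave_age_means, n, nw, byrow = TRUE)
  tsc <- ages - ages[, 1]

  sex <- stats::rbinom(n, 1, 0.515)                 # 1 = male
  carrier <- stats::rbinom(n, 1, config$carrier_prevalence)

  fac <- mvn_draw(n, rep(0, nrow(config$factor_corr)), config$factor_corr)
  colnames(fac) <- rownames(config$factor_corr)
  d <- config$carrier_slope_effect
  alpha <- sqrt(1 - d^2 * config$carrier_prevalence *
                (1 - config$carrier_prevalence))
  fac[, "g"] <- alpha * fac[, "g"] +
    d * (carrier - config$carrier_prevalence)

  # ROI latents
  intercepts <- mvn_draw(n, config$intercept_means, config$intercept_cov)
  colnames(intercepts) <- config$roi_names
  resid_std <- matrix(stats::rnorm(n * p), n, p)
  slopes_std <- fac[, 1:3] %*% t(config$slope_loadings) +
    resid_std * matrix(sqrt(pmax(1 - rowSums((config$slope_loadings %*%
      config$phi_change) * config$slope_loadings), 0)), n, p, byrow = TRUE)
  slopes <- matrix(config$slope_means, n, p, byrow = TRUE) +
    slopes_std * matrix(config$slope_sd, n, p, byrow = TRUE)
  colnames(slopes) <- config$roi_names

  # cognitive test latents
  test_int <- list(); test_slp <- list(); test_meta <- list()
  for (di in seq_len(D)) {
    tbl <- config$cognitive_domains[[di]]
    etaI <- fac[, 3 + D + di]
    etaS <- fac[, 3 + di]
    for (r in seq_len(nrow(tbl))) {
      lamI <- config$cog_loading_int * tbl$sign[r]
      lamS <- config$cog_loading_slp * tbl$sign[r]
      int_sd <- config$cog_int_sd_frac * tbl$sd[r]
      slp_sd <- config$cog_slope_sd_frac * tbl$sd[r]
      ti <- tbl$mean[r] + int_sd * (lamI * etaI +
              sqrt(1 - lamI^2) * stats::rnorm(n)) +
            config$sex_intercept_effect * tbl$sd[r] * (sex - 0.5)
      ts <- tbl$slope_mean[r] + slp_sd * (lamS * etaS +
              sqrt(1 - lamS^2) * stats::rnorm(n))
      test_int[[tbl$test[r]]] <- ti
      test_slp[[tbl$test[r]]] <- ts
      test_meta[[tbl$test[r]]] <- list(domain = doms[di], sd = tbl$sd[r])
    }
  }
  tests <- names(test_int)

  # baseline cognition score driving attrition (standardized mean domain
  # intercept factor)
  zc_raw <- rowMeans(fac[, 3 + D + seq_len(D), drop = FALSE])
  zc <- if (stats::sd(zc_raw) > 0) as.vector(scale(zc_raw)) else rep(0, n)

  retained <- matrix(TRUE, n, nw)
  w_att <- config$attrition_cognition_weight
  for (w in 2:nw) {
    prev <- retained[, w - 1]
    rate <- config$attrition_rates[w - 1]
    if (rate <= 0) { retained[, w] <- prev; next }
    if (rate >= 1) { retained[, w] <- FALSE; next }
    zsub <- zc[prev]
    a <- stats::uniroot(function(a) mean(stats::plogis(a - w_att * zsub)) - rate,
                        c(-30, 30))$root
    drop_p <- stats::plogis(a - w_att * zc)
    retained[, w] <- prev & (stats::runif(n) > drop_p)
  }
  dropout_wave <- apply(retained, 1, function(r) if (all(r)) NA_integer_
                        else min(which(!r)))

  # assemble the long panel
  rows <- which(retained, arr.ind = TRUE)
  rows <- rows[order(rows[, 1], rows[, 2]), , drop = FALSE]
  idx <- rows[, 1]; wv <- rows[, 2]
  t_row <- tsc[cbind(idx, wv)]
  nr <- length(idx)

  panel <- data.frame(id = idx, wave = wv, age = ages[cbind(idx, wv)],
                      sex = sex[idx], apoe_carrier = carrier[idx])
  mmse_lin <- 28.6 + 0.8 * zc[idx] - 0.06 * t_row + stats::rnorm(nr, 0, 0.9)
  panel$mmse <- pmin(30, pmax(0, round(mmse_lin)))

  for (j in seq_len(p)) {
    panel[[config$roi_names[j]]] <- intercepts[idx, j] + slopes[idx, j] * t_row +
      stats::rnorm(nr, 0, config$measurement_noise_sd[j])
  }
  for (tn in tests) {
    noise_sd <- config$cog_noise_sd_frac * test_meta[[tn]]$sd
    panel[[tn]] <- test_int[[tn]][idx] + test_slp[[tn]][idx] * t_row +
      stats::rnorm(nr, 0, noise_sd)
  }

  truth <- list(seed = seed, n_participants = n,
                wave_age_means = config$wave_age_means,
                slope_loadings = config$slope_loadings,
                phi_change = config$phi_change,
                slope_means = config$slope_means, slope_sd = config$slope_sd,
                brain_cognition_coupling = config$brain_cognition_coupling,
                carrier_slope_effect = config$carrier_slope_effect,
                intercepts = intercepts, slopes = slopes,
                factors = fac[, 1:3, drop = FALSE],
                domain_slopes = fac[, 3 + seq_len(D), drop = FALSE],
                domain_intercepts = fac[, 3 + D + seq_len(D), drop = FALSE],
                test_slopes = do.call(cbind, test_slp),
                carrier = carrier, sex = sex, age_offset = offset,
                dropout_wave = dropout_wave, baseline_cognition = zc)
  class(truth) <- "truth_record"
  list(panel = panel, truth = truth)
}

#' Attach exclusion flags to a simulated panel
#'
#' Plants participant-level dementia/low-MMSE and stroke flags at the
#' configured prevalences: flagged "dementia-or-MMSE" participants are split
#' between an explicit dementia diagnosis flag and a forced sub-24 MMSE score
#' at one randomly chosen observed wave; stroke is a separate flag.
#'
#' @param panel panel from \code{\link{simulate_cohort}}.
#' @param config the generating \code{cohort_config}.
#' @param seed seed (default: \code{config$seed + 1}).
#' @return the panel with logical \code{dementia} and \code{stroke} columns
#'   (constant within participant) and possibly lowered \code{mmse} values.
#' @export
apply_exclusion_flags <- function(panel, config, seed = config$seed + 1) {
  old <- local_rng(seed)
  on.exit(restore_rng(old), add = TRUE)
  ids <- unique(panel$id)
  n <- length(ids)
  prev <- config$exclusion_prevalence
  dm <- stats::rbinom(n, 1, min(max(prev[["dementia_mmse"]], 0), 1)) == 1
  st <- stats::rbinom(n, 1, min(max(prev[["stroke"]], 0), 1)) == 1
  via_mmse <- dm & (stats::runif(n) < 0.5)

  panel$dementia <- (dm & !via_mmse)[match(panel$id, ids)]
  panel$stroke <- st[match(panel$id, ids)]
  for (i in which(via_mmse)) {
    rows <- which(panel$id == ids[i])
    pick <- rows[sample.int(length(rows), 1)]
    panel$mmse[pick] <- sample(20:23, 1)
  }
  panel
}
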