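# print / summary / coef / plot methods for the fitted objects.

#' @export
print.growth_fit <- function(x, ...) {
  cat("Latent growth curve (FIML):", x$variable, "\n")
  cat(sprintf("  n = %d participants, %d missingness pattern(s), logLik = %.2f\n",
              x$n, x$patterns, x$loglik))
  est <- x$estimates
  tab <- data.frame(estimate = est,
                    se = if (!is.null(x$se)) x$se else NA_real_)
  print(round(tab, 5))
  cat(sprintf("  implied intercept-slope r = %.3f; %% change per annum = %.3f\n",
              x$int_slope_corr, x$pct_per_annum))
  if (any(x$heywood)) cat("  note: boundary (Heywood) variance estimate present\n")
  invisible(x)
}

#' @export
coef.growth_fit <- function(object, ...) object$estimates

#' @export
logLik.growth_fit <- function(object, ...) {
  structure(object$loglik, df = 6L, class = "logLik")
}

#' @export
plot.growth_fit <- function(x, panel, n_lines = 50, ...) {
  v <- x$variable
  tsc <- panel_time_scores(panel, x$time)
  ids <- unique(panel$id)
  ids <- ids[seq_len(min(n_lines, length(ids)))]
  graphics::plot(tsc, panel[[v]], type = "n",
                 xlab = "years since baseline", ylab = v, ...)
  for (i in ids) {
    s <- panel$id == i
    graphics::lines(tsc[s], panel[[v]][s], col = grDevices::grey(0.75))
  }
  e <- x$estimates
  graphics::abline(a = e[["intercept_mean"]], b = e[["slope_mean"]],
                   col = "steelblue", lwd = 2)
  invisible(x)
}

#' @export
print.latent_corr <- function(x, ...) {
  cat(sprintf("Latent correlation matrix (%s): %d variables (%d x %d), n = %d\n",
              x$source, length(x$variables), nrow(x$corr), ncol(x$corr), x$n))
  ss <- correlation_summary(x, "slopes")
  is <- correlation_summary(x, "intercepts")
  cat(sprintf("  slope block     : mean r = %.3f (SD %.3f)\n", ss[1], ss[2]))
  cat(sprintf("  intercept block : mean r = %.3f (SD %.3f)\n", is[1], is[2]))
  cat("  positive definite:", x$is_pd,
      if (length(x$failures)) paste0("; failed pairs: ",
                                     length(x$failures)) else "", "\n")
  invisible(x)
}

#' @export
plot.latent_corr <- function(x, block = "slopes", ...) {
  M <- split_blocks(x)[[block]]
  ord <- stats::hclust(stats::as.dist(1 - M))$order
  M <- M[ord, ord]
  graphics::image(seq_len(nrow(M)), seq_len(ncol(M)), t(M[nrow(M):1, ]),
                  zlim = c(-1, 1), xlab = "", ylab = "", axes = FALSE,
                  col = grDevices::hcl.colors(51, "Blue-Red 3", rev = TRUE),
                  main = paste("latent", block, "correlations"), ...)
  invisible(x)
}

#' @export
print.schmid_leiman <- function(x, digits = 2, ...) {
  cat(sprintf("Schmid-Leiman solution: general + %d group factor(s); RMSR = %.4f\n",
              x$k, x$rmsr))
  if (x$no_general) cat("  (no general variance: first-order factors uncorrelated)\n")
  cat(sprintf("  variance shares: %s (total %.2f)\n",
              paste(names(x$variance_shares),
                    round(x$variance_shares, 2), sep = " = ", collapse = ", "),
              sum(x$variance_shares)))
  L <- cbind(g = x$general, x$group)
  Ld <- round(L, digits)
  Ld[abs(L) <= x$salience] <- NA
  cat("  salient loadings (|loading| >", x$salience, "):\n")
  print(Ld, na.print = ".")
  invisible(x)
}

#' @export
coef.schmid_leiman <- function(object, ...) cbind(g = object$general, object$group)

#' @export
plot.schmid_leiman <- function(x, ...) {
  L <- cbind(g = x$general, x$group)
  graphics::barplot(t(L), beside = TRUE, las = 2, cex.names = 0.5,
                    legend.text = colnames(L), ylab = "loading", ...)
  graphics::abline(h = c(-x$salience, x$salience), lty = 3)
  invisible(x)
}

#' @export
print.congruence_report <- function(x, ...) {
  cat("Factor alignment: permutation (", paste(x$permutation, collapse = ", "),
      "), signs (", paste(x$signs, collapse = ", "), ")\n", sep = "")
  print(round(rbind(tucker_phi = x$tucker_phi, pearson_r = x$pearson_r), 3))
  invisible(x)
}

#' @export
print.bifactor_spec <- function(x, ...) {
  cat("Bifactor specification:", nrow(x$assignments), "variables,",
      x$k, "group factor(s)\n")
  print(table(group = x$assignments$group))
  cat("residual correlation pairs:",
      if (is.null(x$residual_pairs)) 0 else nrow(x$residual_pairs), "\n")
  invisible(x)
}

#' @export
print.bifactor_fit <- function(x, ...) {
  cat("Confirmatory bifactor model of latent slopes\n")
  cat(sprintf("  chi2(%d) = %.1f, CFI = %.3f, TLI = %.3f, RMSEA = %.3f, SRMR = %.3f\n",
              x$df, x$chi2, x$fit_indices[["cfi"]], x$fit_indices[["tli"]],
              x$fit_indices[["rmsea"]], x$fit_indices[["srmr"]]))
  ve <- x$variance_explained
  cat(sprintf("  variance explained: %s\n",
              paste(names(ve), sprintf("%.0f%%", 100 * ve),
                    sep = " = ", collapse = ", ")))
  if (!is.null(x$group_corr) && nrow(x$group_corr) == 2)
    cat(sprintf("  group-factor correlation r = %.3f\n", x$group_corr[1, 2]))
  if (nrow(x$pruned)) cat("  pruned loadings:", nrow(x$pruned), "\n")
  if (length(x$heywood))
    cat("  residual variances constrained to zero:",
        paste(x$heywood, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.bifactor_fit <- function(object, ...) object$loadings_std

#' @export
plot.bifactor_fit <- function(x, ...) {
  L <- x$loadings_std
  graphics::barplot(t(L), beside = TRUE, las = 2, cex.names = 0.5,
                    legend.text = colnames(L), ylab = "standardized loading",
                    ...)
  invisible(x)
}

#' @export
print.foc_fit <- function(x, ...) {
  cat("Factor-of-curves model, domain:", x$domain, "\n")
  cat(sprintf("  domain slope mean = %.4f, variance = %.5f; logLik = %.2f\n",
              x$slope_mean, x$slope_var, x$loglik))
  print(round(x$loadings[, -1], 3))
  if (!is.null(x$sex_effects))
    cat(sprintf("  sex effects (standardized): intercept %.3f, slope %.3f\n",
                x$sex_effects[["intercept"]], x$sex_effects[["slope"]]))
  invisible(x)
}

#' @export
print.coupled_fit <- function(x, ...) {
  cat("Coupled change model, domain:", x$domain, "\n")
  print(transform(x$table, r = round(r, 3), se = round(se, 3),
                  z = round(z, 2), p = signif(p, 3)))
  invisible(x)
}

#' @export
print.coupling_result <- function(x, ...) {
  cat("Coupling of cortical change factors with covariates and cognitive",
      "domain slopes\n")
  wide <- stats::reshape(
    transform(x$table,
              cell = sprintf("%6.3f (%.3f)%s", r, p,
                             ifelse(fdr_significant, " *", "  ")))[,
              c("outcome", "factor", "cell")],
    idvar = "outcome", timevar = "factor", direction = "wide")
  names(wide) <- sub("^cell\\.", "", names(wide))
  print(wide, row.names = FALSE, right = TRUE)
  cat("  cells: r (p); * = FDR q <", x$fdr_level, "\n")
  if (!is.null(x$sex_check)) {
    cat("  sex check (not in FDR family): ",
        paste(sprintf("%s r = %.3f (p = %.3f)", x$sex_check$factor,
                      x$sex_check$r, x$sex_check$p), collapse = "; "), "\n")
  }
  invisible(x)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  n = %d, waves at ages %s (SD %.2f)\n", x$n_participants,
              paste(x$wave_age_means, collapse = ", "), x$wave_age_sd))
  cat(sprintf("  %d ROIs; slope structure: general + 2 group factors (r = %.2f)\n",
              length(x$roi_names), x$group_factor_corr))
  cat(sprintf("  cognitive domains: %s\n",
              paste(names(x$cognitive_domains), collapse = ", ")))
  cat(sprintf("  carrier prevalence %.2f, effect %.2f SD; attrition %s\n",
              x$carrier_prevalence, x$carrier_slope_effect,
              paste(x$attrition_rates, collapse = ", ")))
  invisible(x)
}

#' @export
print.cortical_pipeline <- function(x, ...) {
  cat("Cortical change pipeline (seed", x$seed, ")\n")
  cat(sprintf("  panel: %d participants, %d rows\n",
              length(unique(x$panel$id)), nrow(x$panel)))
  cat(sprintf("  mean latent slope r = %.3f (SD %.3f); mean intercept r = %.3f (SD %.3f)\n",
              x$slope_summary[1], x$slope_summary[2],
              x$intercept_summary[1], x$intercept_summary[2]))
  ve <- x$cfa$variance_explained
  cat(sprintf("  CFA variance explained: %s\n",
              paste(names(ve), sprintf("%.0f%%", 100 * ve),
                    sep = " = ", collapse = ", ")))
  if (!is.null(x$coupling)) {
    g <- x$coupling$table
    g <- g[g$factor == "general", ]
    cat("  general-factor couplings:\n")
    print(transform(g[, c("outcome", "r", "p", "q")],
                    r = round(r, 3), p = signif(p, 2), q = signif(q, 2)),
          row.names = FALSE)
  }
  cat(sprintf("  elapsed %.1fs\n", x$elapsed))
  invisible(x)
}

#' @export
summary.cortical_pipeline <- function(object, ...) {
  out <- list(
    n = length(unique(object$panel$id)),
    slope_summary = object$slope_summary,
    intercept_summary = object$intercept_summary,
    efa_shares = object$efa$slopes$variance_shares,
    cfa_shares = object$cfa$variance_explained,
    group_corr = if (!is.null(object$cfa$group_corr))
      object$cfa$group_corr[1, 2] else NA_real_,
    level_vs_change = object$level_vs_change,
    coupling = if (!is.null(object$coupling)) object$coupling$table,
    fit_indices = object$cfa$fit_indices)
  class(out) <- "summary.cortical_pipeline"
  out
}

#' @export
print.summary.cortical_pipeline <- function(x, ...) {
  utils::str(x, max.level = 1)
  invisible(x)
}
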