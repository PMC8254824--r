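# End-to-end pipeline: simulate (optional) -> growth curves -> latent
# correlations -> projection -> exploratory bifactor -> comparisons ->
# confirmatory bifactor -> cognitive coupling.

#' Run the full dimensions-of-cortical-change pipeline
#'
#' Executes every stage on a supplied panel or on a freshly simulated cohort:
#' univariate growth curves per ROI, pairwise latent intercept/slope
#' correlations, nearest-correlation projection, Schmid-Leiman exploratory
#' bifactor analysis of both blocks (with an intercepts-versus-slopes
#' congruence comparison), the confirmatory bifactor model of slopes, the
#' factor-of-curves cognitive measurement models and the coupled-change
#' correlations with FDR control. Each stage logs its timing; any stage
#' failure halts with the stage name.
#'
#' @param config \code{\link{cohort_config}} used when \code{panel} is NULL
#'   (its ground truth is attached to the result).
#' @param panel optionally, an existing long-format panel.
#' @param seed simulation seed (defaults to \code{config$seed}).
#' @param k number of first-order group factors for the exploratory solution.
#' @param time time coding for all growth models.
#' @param method latent correlation method.
#' @param salience salience threshold for loadings.
#' @param alpha pruning level in the confirmatory model.
#' @param fdr_level FDR flag threshold for the coupling table.
#' @param covariates binary covariates in the coupling family.
#' @param sensitivity if TRUE, rerun the exploratory analysis after applying
#'   the exclusion criteria and report congruence with the full sample.
#' @param select_k if TRUE, also run factor-count diagnostics (k = 2..4).
#' @param out_dir optional directory; stage artifacts are written there as
#'   delimited text.
#' @param quiet suppress stage messages.
#' @return object of class \code{cortical_pipeline}.
#' @export
run_pipeline <- function(config = cohort_config(), panel = NULL,
                         seed = config$seed, k = 2, time = "baseline",
                         method = "pairwise", salience = 0.3, alpha = 0.05,
                         fdr_level = 0.05, covariates = "apoe_carrier",
                         sensitivity = FALSE, select_k = FALSE,
                         out_dir = NULL, quiet = FALSE) {
  stages <- list()
  res <- list(seed = seed, config = config)
  t_all <- proc.time()[3]
  say <- function(...) if (!quiet) message(...)
  run_stage <- function(name, expr) {
    t0 <- proc.time()[3]
    out <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    stages[[name]] <<- proc.time()[3] - t0
    say(sprintf("[%s] %.1fs", name, stages[[name]]))
    out
  }

  truth <- NULL
  if (is.null(panel)) {
    sim <- run_stage("simulate", {
      s <- simulate_cohort(config, seed)
      s$panel <- apply_exclusion_flags(s$panel, config, seed + 1)
      s
    })
    panel <- sim$panel
    truth <- sim$truth
  }
  rois <- intersect(config$roi_names, names(panel))
  stopifnot(length(rois) >= 4)

  # the latent-correlation stage fits the univariate growth curves through
  # its shared-pattern fast path; reuse those fits everywhere downstream
  lc <- run_stage("latent_correlations",
                  latent_correlations(panel, rois, method = method,
                                      time = time))
  growth_fits <- lc$fits
  growth_table <- data.frame(
    roi = rois,
    t(vapply(growth_fits, function(f) f$estimates, numeric(6))),
    pct_per_annum = vapply(growth_fits, `[[`, numeric(1), "pct_per_annum"),
    row.names = NULL)
  blocks <- split_blocks(lc)
  prep <- run_stage("nearest_pd", list(
    slopes = nearest_pd(blocks$slopes),
    intercepts = nearest_pd(blocks$intercepts)))
  R_slp <- prep$slopes$matrix
  R_int <- prep$intercepts$matrix

  efa <- run_stage("efa", list(
    slopes = schmid_leiman(R_slp, k = k, salience = salience),
    intercepts = schmid_leiman(R_int, k = k, salience = salience)))
  level_vs_change <- run_stage("compare",
                               compare_solutions(efa$intercepts, efa$slopes))
  kdiag <- if (select_k) run_stage("select_k", select_nfactors(R_slp)) else NULL

  sens <- NULL
  if (sensitivity) {
    sens <- run_stage("sensitivity",
                      sensitivity_rerun(panel, variables = rois, k = k,
                                        time = time, method = method))
  }

  cfa <- run_stage("cfa", {
    spec <- build_bifactor_spec(efa$slopes, salience = salience)
    fit_bifactor(spec, R_slp, n = lc$n, sl = efa$slopes, alpha = alpha)
  })

  doms <- names(config$cognitive_domains)
  have_tests <- vapply(doms, function(d)
    all(config$cognitive_domains[[d]]$test %in% names(panel)), logical(1))
  coupling <- NULL
  foc_fits <- NULL
  if (any(have_tests)) {
    foc_fits <- run_stage("factor_of_curves", {
      f <- lapply(doms[have_tests], function(d)
        fit_factor_of_curves(panel, config$cognitive_domains[[d]]$test,
                             domain = d, time = time))
      names(f) <- doms[have_tests]
      f
    })
    coupling <- run_stage("coupling",
                          coupling_table(panel, cfa, foc_fits, growth_fits,
                                         covariates = covariates,
                                         fdr_level = fdr_level, time = time))
  }

  res <- c(res, list(
    panel = panel, truth = truth, growth_fits = growth_fits,
    growth_table = growth_table, latent_corr = lc, prep = prep,
    slope_corr = R_slp, intercept_corr = R_int, efa = efa,
    level_vs_change = level_vs_change, k_diagnostics = kdiag,
    sensitivity = sens, cfa = cfa, foc_fits = foc_fits, coupling = coupling,
    slope_summary = correlation_summary(lc, "slopes"),
    intercept_summary = correlation_summary(lc, "intercepts"),
    stage_seconds = unlist(stages),
    elapsed = proc.time()[3] - t_all))
  class(res) <- "cortical_pipeline"

  if (!is.null(out_dir)) write_pipeline(res, out_dir)
  res
}

#' @keywords internal
write_pipeline <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f) utils::write.table(
    x, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  write_panel(res$panel, file.path(out_dir, "panel.tsv"))
  if (!is.null(res$truth)) write_truth(res$truth, file.path(out_dir, "truth.txt"))
  wt(res$growth_table, "growth_fits.tsv")
  wm <- function(M, f) utils::write.table(
    data.frame(label = rownames(M), M, check.names = FALSE),
    file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wm(res$slope_corr, "slope_correlations.tsv")
  wm(res$intercept_corr, "intercept_correlations.tsv")
  sl <- res$efa$slopes
  wt(data.frame(roi = names(sl$general), g = sl$general, sl$group),
     "efa_slope_loadings.tsv")
  if (!is.null(res$cfa$loading_table)) wt(res$cfa$loading_table, "cfa_loadings.tsv")
  if (!is.null(res$coupling)) wt(res$coupling$table, "coupling.tsv")
  writeLines(c(paste("seed:", res$seed),
               paste("package:", as.character(utils::packageVersion("cortage"))),
               paste("R:", R.version.string),
               paste(names(res$stage_seconds),
                     sprintf("%.2fs", res$stage_seconds), sep = ": ")),
             file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}
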