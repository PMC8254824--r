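# Replication metrics for loading structures: Tucker congruence, factor
# alignment, and sensitivity reruns under participant exclusion criteria.

#' Tucker coefficient of factor congruence
#'
#' \code{sum(a*b) / sqrt(sum(a^2) * sum(b^2))}: a cosine-type similarity in
#' [-1, 1]; 1 means the two loading vectors are proportional.
#'
#' @param a,b loading vectors of equal length (>= 2), neither all-zero.
#' @return numeric scalar.
#' @export
#' @examples
#' tucker_congruence(c(0.8, 0.6, 0.4), c(0.4, 0.3, 0.2))  # 1
tucker_congruence <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  sa <- sum(a^2); sb <- sum(b^2)
  if (sa == 0 || sb == 0) stop("congruence is undefined for a zero vector")
  sum(a * b) / sqrt(sa * sb)
}

#' @keywords internal
all_perms <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (i in seq_len(k)) {
    for (rest in all_perms(k - 1)) {
      out[[length(out) + 1L]] <- c(i, setdiff(seq_len(k), i)[rest])
    }
  }
  out
}

#' Align the factors of two loading matrices
#'
#' Chooses the column permutation and signs of \code{B} that maximise the mean
#' Tucker congruence with \code{A} (exhaustive over permutations, optimal sign
#' per factor), and reports per-factor congruence and Pearson correlations
#' after matching.
#'
#' @param A,B loading matrices over the same variables with the same number of
#'   factors (k <= 5).
#' @return object of class \code{congruence_report}: \code{tucker_phi},
#'   \code{pearson_r}, \code{permutation}, \code{signs}, \code{B_aligned}.
#' @export
align_factors <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (nrow(A) != nrow(B) || ncol(A) != ncol(B))
    stop("loading matrices must have matching variables and factor counts")
  if (!is.null(rownames(A)) && !is.null(rownames(B)) &&
      !identical(rownames(A), rownames(B)))
    stop("variable sets differ between the two solutions")
  k <- ncol(A)
  if (k > 5) stop("exhaustive alignment supports at most 5 factors")

  best <- NULL
  for (pm in all_perms(k)) {
    phis <- vapply(seq_len(k), function(j)
      tucker_congruence(A[, j], B[, pm[j]]), numeric(1))
    sgn <- ifelse(phis >= 0, 1, -1)
    score <- mean(abs(phis))
    if (is.null(best) || score > best$score)
      best <- list(score = score, perm = pm, signs = sgn, phis = abs(phis))
  }
  Bal <- sweep(B[, best$perm, drop = FALSE], 2, best$signs, "*")
  r <- vapply(seq_len(k), function(j) stats::cor(A[, j], Bal[, j]), numeric(1))
  out <- list(tucker_phi = best$phis, pearson_r = r,
              permutation = best$perm, signs = best$signs,
              mean_phi = best$score, B_aligned = Bal)
  class(out) <- "congruence_report"
  out
}

#' Compare two exploratory bifactor solutions
#'
#' Convenience wrapper: compares the general loadings directly (sign-aware
#' congruence and Pearson r) and aligns the group factors of two
#' \code{schmid_leiman} solutions (or two loading matrices).
#'
#' @param a,b \code{schmid_leiman} objects over the same variables.
#' @return list with \code{general} (phi, r) and \code{groups} (a
#'   \code{congruence_report}).
#' @export
compare_solutions <- function(a, b) {
  stopifnot(inherits(a, "schmid_leiman"), inherits(b, "schmid_leiman"))
  # intercept and slope solutions label variables with _int/_slp suffixes;
  # compare on the base variable names
  base <- function(x) sub("_(int|slp)$", "", x)
  Ga <- a$group; Gb <- b$group
  rownames(Ga) <- base(rownames(Ga))
  rownames(Gb) <- base(rownames(Gb))
  if (!identical(rownames(Ga), rownames(Gb)))
    stop("variable sets differ between the two solutions")
  phig <- tucker_congruence(a$general, b$general)
  rg <- stats::cor(a$general, b$general)
  grp <- align_factors(Ga, Gb)
  list(general = c(tucker_phi = phig, pearson_r = rg), groups = grp)
}

#' Filter a panel on exclusion criteria
#'
#' Removes every wave of any participant who meets one of the criteria at any
#' wave: a dementia diagnosis flag, an MMSE score below the cutoff, or a
#' stroke flag. Note the cutoff convention: a score below 24 excludes (a
#' score of exactly 24 is retained).
#'
#' @param panel panel carrying \code{dementia}, \code{mmse} and/or
#'   \code{stroke} columns as required by \code{criteria}.
#' @param criteria subset of \code{c("dementia", "mmse", "stroke")}.
#' @param mmse_cutoff exclusion threshold (exclusive) for the MMSE.
#' @return the filtered panel, with attribute \code{removed_ids}.
#' @export
filter_panel <- function(panel, criteria = c("dementia", "mmse"),
                         mmse_cutoff = 24) {
  criteria <- match.arg(criteria, c("dementia", "mmse", "stroke"),
                        several.ok = TRUE)
  bad <- rep(FALSE, nrow(panel))
  if ("dementia" %in% criteria) {
    if (is.null(panel$dementia)) stop("panel carries no 'dementia' flag")
    bad <- bad | panel$dementia %in% TRUE
  }
  if ("mmse" %in% criteria) {
    if (is.null(panel$mmse)) stop("panel carries no 'mmse' column")
    bad <- bad | (!is.na(panel$mmse) & panel$mmse < mmse_cutoff)
  }
  if ("stroke" %in% criteria) {
    if (is.null(panel$stroke)) stop("panel carries no 'stroke' flag")
    bad <- bad | panel$stroke %in% TRUE
  }
  drop_ids <- unique(panel$id[bad])
  out <- panel[!(panel$id %in% drop_ids), , drop = FALSE]
  if (!nrow(out)) stop("all participants removed by the exclusion criteria")
  rownames(out) <- NULL
  attr(out, "removed_ids") <- drop_ids
  out
}

#' Sensitivity rerun of the exploratory change-structure analysis
#'
#' Re-runs the growth -> latent correlation -> projection -> Schmid-Leiman
#' pipeline on the slope block after removing participants meeting the
#' exclusion criteria, and quantifies agreement with the full-sample solution
#' (congruence of the general factor and aligned group factors).
#'
#' @param panel panel with exclusion flag columns.
#' @param criteria see \code{\link{filter_panel}}.
#' @param variables longitudinal variables (default: all DK ROI columns
#'   present).
#' @param k number of group factors.
#' @param time,method passed to \code{\link{latent_correlations}}.
#' @param mmse_cutoff MMSE exclusion threshold.
#' @return list: \code{panel_filtered}, \code{removed_ids}, \code{sl_full},
#'   \code{sl_filtered}, \code{comparison}.
#' @export
sensitivity_rerun <- function(panel, criteria = c("dementia", "mmse"),
                              variables = NULL, k = 2, time = "baseline",
                              method = "pairwise", mmse_cutoff = 24) {
  if (is.null(variables))
    variables <- intersect(dk_rois()$name, names(panel))
  stopifnot(length(variables) >= 4)
  sl_of <- function(pp) {
    lc <- latent_correlations(pp, variables, method = method, time = time)
    blocks <- split_blocks(lc)
    Rs <- nearest_pd(blocks$slopes)$matrix
    schmid_leiman(Rs, k = k)
  }
  filtered <- filter_panel(panel, criteria, mmse_cutoff)
  sl_full <- sl_of(panel)
  sl_filt <- sl_of(filtered)
  cmp <- compare_solutions(sl_full, sl_filt)
  list(panel_filtered = filtered,
       removed_ids = attr(filtered, "removed_ids"),
       sl_full = sl_full, sl_filtered = sl_filt, comparison = cmp)
}
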