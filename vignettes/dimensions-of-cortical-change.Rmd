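---
title: "Dimensions of longitudinal cortical change: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dimensions of longitudinal cortical change: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Regional brain volumes decline in older age, but regions do not decline in
lockstep: some people lose tissue broadly across the cortical mantle, others
show relatively more anterior (fronto-temporal) or posterior
(occipito-parietal) atrophy. Cross-sectional correlations between regional
volumes cannot separate these ageing-specific patterns from patterns laid
down across the whole lifespan, so the question has to be asked of
*longitudinal change*: how strongly are regional rates of atrophy
correlated, what low-dimensional structure do those correlated changes have,
and do the resulting dimensions of cortical change track cognitive decline
and genetic risk?

`cortage` implements the full modelling pipeline this question requires, for
a three-wave panel of 34 bilateral Desikan-Killiany regional volumes and a
multi-test cognitive battery:

1. **Latent growth curves.** For each region (and each cognitive test) a
   linear latent growth curve is estimated by full-information maximum
   likelihood (FIML): person $i$'s observed volume at time $t_{ij}$ is
   $y_{ij} = I_i + S_i t_{ij} + e_{ij}$ with latent intercept $I_i$ and
   slope $S_i$ jointly normal, and $e_{ij}$ wave-specific noise with a
   common variance. Time is coded in years since the participant's first
   observed wave, so the intercept is the baseline level. The unstandardised
   mean slope, expressed as a percentage of the mean level
   ($100\,\bar S/\bar I$), is the familiar "% change per annum".
2. **Latent correlations.** The correlations among the 34 latent intercepts
   and 34 latent slopes are assembled from bivariate growth models of every
   region pair (see *Estimation choices*), separated into an intercept block
   and a slope block, and projected to the nearest correlation matrix
   (Higham's alternating projections with Dykstra's correction) because a
   matrix assembled from pairwise fits need not be positive definite.
3. **Exploratory structure.** Each block is factor-analysed with
   minimum-residual (minres) extraction, direct-quartimin (oblimin,
   $\gamma = 0$) rotation by gradient projection, and the Schmid-Leiman
   transformation, which re-expresses an oblique first-order solution as an
   approximate bifactor solution: a general factor ($g = P b$, with $P$ the
   oblique pattern and $b$ the second-order loadings) plus residualised
   group factors ($P\,\mathrm{diag}\sqrt{1-b^2}$). With two first-order
   factors the second-order model is just-identified and both second-order
   loadings are set to $\sqrt{\phi_{12}}$ (a proportionality convention,
   stated rather than estimable). Candidate factor counts are screened by
   eigenvalues, residual RMSR, and the presence of factors with no salient
   loading (|loading| > 0.3).
4. **Confirmatory bifactor model.** The loading pattern discovered in step 3
   is imposed: every slope loads on a general change factor, each on at most
   one group factor, the general factor is orthogonal to the group factors,
   the two group factors may correlate, residual correlations are allowed
   between spatially contiguous parcels (shipped adjacency list,
   user-overridable), residual variances are bounded at zero (Heywood cases
   end on the boundary and are reported), and non-significant loadings are
   pruned one at a time (largest Wald p first, two-sided $\alpha = 0.05$).
   Variance explained per factor is the mean squared standardized loading.
5. **Coupling.** Cognitive domains are measured by factor-of-curves growth
   models (each test has its own latent intercept and slope, loading on
   domain-level intercept and slope factors), and the correlations between
   the cortical change factors and each domain's slope factor, a binary
   allele-carrier flag, and sex are estimated, with Benjamini-Hochberg FDR
   control over the single family of change-factor x (carrier + domain)
   associations.

## Estimation choices

**Pairwise latent correlations.** A simultaneous growth model for all 34
regions has thousands of free covariance parameters and is far beyond a
desk-scale optimizer. The package's default is therefore *profiled pairwise*
estimation: each variable's own growth parameters are fixed at their
univariate FIML estimates and only the four cross-covariances of each pair
are estimated by FIML, for all 561 pairs. This has the same estimand as the
joint model, is consistent, and runs in seconds; full 16-parameter bivariate
ML (`pairwise_ml`) and a genuinely simultaneous fit for up to six variables
(`simultaneous`) are provided, and the three agree closely on complete data
(tested). The assembled matrix can be indefinite — exactly the problem the
nearest-correlation projection repairs.

**Pattern likelihood.** All FIML fits evaluate the observed-data normal
likelihood per missingness/timing pattern using pattern-level sufficient
statistics. Under monotone attrition with a shared visit schedule there are
only as many patterns as waves, so the likelihood and its analytic gradient
(parameters enter only through latent means, the latent covariance and
residual variances; the design is fixed) cost a handful of small matrix
operations per evaluation. Missing waves contribute through their own
pattern, which is what makes the estimates unbiased under attrition that is
random given observed baseline information (MAR). Internally every variable
is standardized (scale only) and time is rescaled by the study span so that
all optimizer parameters are of order one; estimates are mapped back to
original units. Optimization is bound-constrained quasi-Newton (`nlminb`
with analytic gradients, restarts, and an L-BFGS-B polish): variances are
bounded at zero rather than log-transformed, so inadmissible (Heywood)
solutions surface as boundary estimates to be reported instead of being
hidden by a transformation.

**Fitting the confirmatory model to an assembled matrix.** The latent slope
correlation matrix that reaches the confirmatory stage is an assembled,
projected estimate whose smallest eigenvalues sit at the projection floor.
The normal-theory ML discrepancy diverges on such near-singular inputs, so
`fit_bifactor()` minimises the unweighted least squares (ULS) discrepancy by
default — the same criterion minres uses in the exploratory stage — with
standard errors from the normal-theory sandwich
$(\Delta'W\Delta)^{-1}\Delta'W\Gamma W\Delta(\Delta'W\Delta)^{-1}/(n-1)$ and
a mean-scaled test statistic $T = (n-1)\,2F\,df/\mathrm{tr}(U\Gamma)$ from
which CFI, TLI and RMSEA are computed. ML is retained as an option for
well-conditioned inputs.

**Two-stage coupling.** The source analysis fits one very large SEM per
cognitive domain with all measurement loadings fixed from the initial
measurement models. The package keeps the fixed-loadings logic but replaces
the giant model with an equivalent desk-scale construction: Bartlett-weighted
composites $C_f = w_f'y$ of the observed regional volumes, with
$w_f = \Theta^{-1}\Lambda(\Lambda'\Theta^{-1}\Lambda)^{-1}$ from the fitted
bifactor model, so that each composite's latent slope equals one change
factor plus uncorrelated contamination ($w_f'\Lambda = e_f$). One joint FIML
growth model of the three composite trajectories, the domain's test
trajectories (with factor-of-curves structure fixed from the measurement
fit) and the static covariates then estimates the free structural
cross-covariance block with likelihood-based standard errors. The raw
composite-factor correlation is disattenuated by the model-implied factor
$(1 + w_f'\Theta w_f)^{-1/2}$; this scaling cancels in the Wald statistic,
so p-values are unaffected by the correction. Under a null-coupling
generator the resulting p-values are uniform and the FDR-corrected family
keeps its nominal level (tested at 500 replicates).

**Factor-of-curves measurement models** are estimated in two stages for
robustness: a joint FIML growth model of all tests in a domain (full latent
covariance; analytic gradients) followed by an ML factor-structure fit to
the estimated latent covariance matrix with marker identification (the
first test's loadings fixed at 1). A direct one-step FIML fit of the full
factor-of-curves parameterisation was severely biased in simulation at the
low slope reliabilities that are realistic for cognitive tests over three
waves; the two-stage version is near-unbiased under the same conditions.

## The synthetic cohort and what it emulates

Because the motivating cohort's data are access-restricted, the package
ships a generator whose defaults are the study conditions: 629 participants
of essentially the same birth year measured at mean ages 72.49, 76.24 and
79.32 (participant-level age offset SD 0.71), with monotone dropout
calibrated to the retention series 629 / 428 / 319 and dropout odds tied to
baseline cognition (0.5 log-odds per SD, so returners are cognitively abler
— the missing-at-random mechanism the FIML machinery is built for).
Regional volumes follow the Desikan-Killiany atlas with plausible mean
volumes scaled to a total cortical volume of 398,508 mm^3 and regional
decline rates between -0.55 and -1.35 %/yr (cohort mean near -0.87 %/yr).
Latent slopes follow a bifactor structure: heterogeneous general loadings
(mean 0.69, range 0.36-0.88) plus fronto-temporal or occipito-parietal group
loadings (means 0.54 and 0.51, SDs about 0.12, matching the reported spread
of real regional loadings), group factors correlated at -0.25. Latent
levels follow a general + two-group structure on a deliberately different
(dorsal/ventral) partition, so the level and change structures genuinely
differ — the qualitative contrast the pipeline is meant to detect.
Between-person slope SD is 0.45% of the regional volume per year and
wave-specific measurement noise is 1% of volume, a figure in line with the
test-retest precision of longitudinal-stream segmentation. Cognitive
batteries (ten tests in three domains, with test means, SDs and mean slopes
taken from the cohort's published descriptive table; the reaction-time test
loads negatively) have test slope SDs of 4% of the cross-sectional SD per
year and retest noise of 50% of the SD — deliberately low slope reliability,
as is realistic. Domain slope factors correlate 0.6 with one another and
0.415 / 0.369 / 0.363 with the general change factor; an allele-carrier flag
(prevalence 0.30) shifts the general change factor by -0.22 SD, implying a
point-biserial correlation near -0.10; sex shifts test intercepts by 0.2 SD
and has no effect on cortical change.

What the generator does *not* emulate: segmentation error structure beyond
i.i.d. wave noise, spatially correlated residual change between adjacent
parcels (the confirmatory model's residual correlations are therefore
exercised against a zero truth), intermittent missingness (dropout is
monotone), non-linear trajectories, and level-change covariance within
regions. Recovery results on the synthetic cohort therefore demonstrate
that the estimators are correct and calibrated under the stated conditions;
they do not certify behaviour under every failure mode of real imaging
data.

## Numerical and design choices

* Projection: eigenvalue floor 1e-8, relative Frobenius tolerance 1e-9,
  iteration cap 500 (the tolerance and cap are declared defaults — the
  named projection the analysis pipeline historically used does not
  document desk-level settings).
* Minres: profile search over uniquenesses (loadings by eigendecomposition
  of the reduced matrix) followed by a quasi-Newton polish of the loadings
  on the exact off-diagonal least-squares criterion; column signs fixed so
  each column's largest-magnitude loading is positive.
* Oblimin: direct quartimin ($\gamma = 0$, the standard default), gradient
  projection with step halving; five starts (identity plus random oblique
  transforms under a fixed seed) guard against local minima.
* Salience threshold 0.3, strict inequality, everywhere a loading pattern
  is thresholded.
* Group assignment ties in the confirmatory specification break towards the
  lower factor index, with a warning.
* Pruning removes one loading per refit (the largest p), which avoids
  order effects; pruning never loosens the discrepancy.
* Degenerate inputs: zero-variance generator configurations are valid (the
  multivariate normal draw uses an eigenvalue-clipped square root); an
  exactly noise-free panel makes the growth likelihood singular, and the
  optimizer's convergence flag says so while the estimates remain usable.
* The `"occasion"` time coding (years between mean wave ages) is exposed
  alongside the default `"baseline"` coding; in a narrow-age cohort the two
  are nearly identical, and the generator's constant-offset ages make them
  exactly equivalent.
* The exclusion screen treats a cognitive screening score *below* 24 as
  exclusionary (a score of exactly 24 is retained). Published descriptions
  of this rule are inconsistent about the inequality's direction in one
  place; the methods-section form (< 24) is implemented.

## Problem sizes used by the checks

The bundled acceptance checks run the full pipeline on cohorts of n = 600
(the scale of the motivating study's imaging sample) over 50 replicates for
parameter recovery, and 500 replicates of a null-coupling generator at
n = 500 for type-I control of the FDR-corrected coupling family, with the
measurement side fixed from one calibration cohort — mirroring the
fixed-loadings logic of the coupled analysis and keeping the simulation
focused on the structural test. Unit tests use smaller cohorts (40-700
participants) chosen for speed; the generator's defaults themselves always
remain at the study conditions.

## Known limitations

* The pairwise-profiled latent correlation matrix is consistent but not the
  joint MLE; its entries have larger and mutually correlated sampling
  errors, which is why it is projected and then fitted by ULS.
* Two-stage coupling treats the measurement side as known when estimating
  the structural block, so structural standard errors ignore measurement
  parameter uncertainty (as does the fixed-loadings strategy it mirrors).
* With two group factors, the free-correlation bifactor model is only
  weakly identified when loadings are homogeneous within blocks; with the
  heterogeneous loadings that real parcels show (and the generator
  reproduces) the model is stable. Users fitting cohorts with nearly
  uniform loadings should expect unstable group-factor correlations.
* The Schmid-Leiman general factor inherits a proportionality bias when the
  true general loadings are heterogeneous; the confirmatory stage, not the
  exploratory one, is the package's estimator of record for loadings.
* No quadratic or spline growth; three waves identify only linear change.
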