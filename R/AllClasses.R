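#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData rowData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats aggregate anova as.dist cmdscale dist isoreg lm
#'   logLik pf pt qt rbinom rlnorm rnorm rpois runif sd setNames t.test var
#'   AIC coef complete.cases cor p.adjust poly predict quantile rhyper
#' @importFrom utils read.csv write.csv head
NULL

#' Sample-by-taxon abundance matrix for temporal diversity analysis
#'
#' Extends \linkS4class{SummarizedExperiment}: taxa are rows, temporal
#' samples (one plot on one sampling date) are columns.  The \code{counts}
#' assay holds non-negative integer abundances; \code{colData} carries
#' \code{plot_id}, \code{treatment}, \code{year} and \code{julian_date};
#' \code{rowData} carries the taxon traits (diet category, native flag,
#' genus).  Validity enforces no all-zero taxon rows and a single treatment
#' label per plot within a year.
#'
#' @slot level character; \code{"species"} or \code{"genus"} taxon level.
#' @slot pooled logical; \code{TRUE} after \code{\link{poolByPlot}}, when
#'   columns are whole plots rather than single dates.
#'
#' @seealso \code{\link{abundanceMatrix}}, \code{\link{poolByPlot}}
#' @export
setClass("AbundanceMatrix",
  contains = "SummarizedExperiment",
  slots = c(level = "character", pooled = "logical"),
  prototype = prototype(level = "species", pooled = FALSE)
)

setValidity("AbundanceMatrix", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    cts <- SummarizedExperiment::assay(object, "counts")
    if (any(cts < 0)) msg <- c(msg, "counts must be non-negative")
    if (any(cts != round(cts))) msg <- c(msg, "counts must be integers")
    if (nrow(cts) > 0 && ncol(cts) > 0 && any(rowSums(cts) == 0))
      msg <- c(msg, "all-zero taxon rows are not allowed")
  }
  cd <- SummarizedExperiment::colData(object)
  need <- c("plot_id", "treatment", "year")
  if (!all(need %in% colnames(cd)))
    msg <- c(msg, paste("colData must contain:", paste(need, collapse = ", ")))
  else {
    key <- paste(cd$plot_id, cd$year)
    tt <- tapply(as.character(cd$treatment), key, function(z) length(unique(z)))
    if (length(tt) && any(tt > 1))
      msg <- c(msg, "treatment must be constant within plot_id x year")
  }
  if (!identical(object@pooled, TRUE) && !"julian_date" %in% colnames(cd))
    msg <- c(msg, "colData must contain julian_date for sample-level matrices")
  if (length(msg)) msg else TRUE
})

#' Non-metric multidimensional scaling result
#'
#' Holds the ordination configuration returned by
#' \code{\link{nmdsOrdination}} (or the classical-scaling engine): centred
#' sample coordinates, Kruskal stress-1 of the best restart, and restart
#' bookkeeping.
#'
#' @slot coordinates numeric matrix, samples x k, column means ~ 0.
#' @slot stress Kruskal stress-1 of the returned configuration (0 for the
#'   \code{"pcoa"} engine, where stress is not defined).
#' @slot k integer, ordination dimensionality.
#' @slot converged logical, whether any restart met the convergence rule.
#' @slot restartsRun integer, number of starts actually evaluated.
#' @slot engine character, \code{"nmds"} or \code{"pcoa"}.
#' @export
setClass("Ordination",
  slots = c(coordinates = "matrix", stress = "numeric", k = "integer",
            converged = "logical", restartsRun = "integer", engine = "character")
)

setValidity("Ordination", function(object) {
  msg <- character()
  if (length(object@stress) != 1 || object@stress < 0)
    msg <- c(msg, "stress must be a single non-negative number")
  if (ncol(object@coordinates) != object@k)
    msg <- c(msg, "coordinate columns must equal k")
  if (nrow(object@coordinates) > 0 &&
      max(abs(colMeans(object@coordinates))) > 1e-6)
    msg <- c(msg, "coordinates must be centred")
  if (length(msg)) msg else TRUE
})

#' Per-plot multivariate dispersion scores
#'
#' Temporal beta diversity of each plot: the mean Euclidean distance in
#' ordination space between the plot's centroid and its constituent temporal
#' samples.  Plots contributing a single sample get \code{NA} with an
#' exclusion flag rather than being dropped.
#'
#' @slot scores data.frame with \code{plot_id}, \code{treatment},
#'   \code{n_samples}, \code{dispersion}, \code{exclusion_reason}.
#' @slot centroids numeric matrix, plots x k.
#' @slot ordination the \linkS4class{Ordination} the scores were computed in.
#' @export
setClass("DispersionResult",
  slots = c(scores = "data.frame", centroids = "matrix",
            ordination = "Ordination")
)

#' Random-intercept trend model fit
#'
#' A Gaussian mixed model of one response against treatment, an orthogonal
#' polynomial in julian date, and their interaction, with plot identity as a
#' random intercept.  Both maximum-likelihood (for AIC comparison across
#' polynomial degrees) and REML (for the reported sequential F tests with
#' between-within denominator df) fits are retained.
#'
#' @slot response character, response column name.
#' @slot degree integer, polynomial degree in julian date.
#' @slot covariate character (possibly empty), optional plot-level covariate.
#' @slot fitML,fitREML the underlying \code{nlme::lme} fits.
#' @slot aic AIC of the ML fit.
#' @slot anovaTable data.frame of sequential F tests (REML): term, numDF,
#'   denDF, F, p.
#' @slot fixef named numeric, REML fixed-effect estimates.
#' @slot varcor named numeric: between-plot and residual variances.
#' @slot nObs,nPlots integers.
#' @export
setClass("LmmFit",
  slots = c(response = "character", degree = "integer", covariate = "character",
            fitML = "ANY", fitREML = "ANY", aic = "numeric",
            anovaTable = "data.frame", fixef = "numeric", varcor = "numeric",
            nObs = "integer", nPlots = "integer")
)

#' Configuration of the seasonal community simulator
#'
#' Full parameterisation of a two-treatment (reserve vs fragment) seasonal
#' survey simulation: design (plots per treatment, samples per plot, season
#' window), assemblage structure (species pool size, species-abundance
#' distribution, phenology), sampling intensity, and the treatment effects
#' injected into fragment plots.
#'
#' @slot nPlots named integer vector \code{c(reserve=, fragment=)}.
#' @slot nSamples integer, temporal samples per plot.
#' @slot season numeric length-2, first and last julian day of the season.
#' @slot poolSize integer, species-pool size.
#' @slot sad list: \code{type} ("lognormal" or "logseries") plus its
#'   parameters (\code{sdlog}, or \code{x} for the log-series).
#' @slot phenologyWidth mean activity-window s.d. in days.
#' @slot phenologyWidthSdlog lognormal spread of window widths.
#' @slot effects named numeric: \code{richness_deficit_frac},
#'   \code{evenness_skew}, \code{turnover_compression},
#'   \code{peak_shift_days}, \code{generalist_boost}.
#' @slot generalistFrac,parasiticFrac,unknownFrac,nonnativeFrac trait
#'   assignment probabilities.
#' @slot meanPerSample expected bee individuals per bowl-trap sample.
#' @slot netFraction sampling intensity of the netting method relative to
#'   bowls (netted records are generated so method filters can be exercised).
#' @slot genusOnlyFrac fraction of species identifiable only to genus.
#' @slot plotSigma s.d. (log scale) of the bounded log-uniform per-plot
#'   abundance multiplier.
#' @slot plotSpeciesSigma s.d. (log scale) of the bounded log-uniform
#'   per-plot, per-species relative-abundance jitter: the local
#'   heterogeneity among plots that gives plot identity a genuine variance
#'   component.
#' @slot seed integer master seed.
#' @seealso \code{\link{simConfig}}, \code{\link{scenarioPreset}},
#'   \code{\link{simulateSurvey}}
#' @export
setClass("SimConfig",
  slots = c(nPlots = "integer", nSamples = "integer", season = "numeric",
            poolSize = "integer", sad = "list",
            phenologyWidth = "numeric", phenologyWidthSdlog = "numeric",
            effects = "numeric",
            generalistFrac = "numeric", parasiticFrac = "numeric",
            unknownFrac = "numeric", nonnativeFrac = "numeric",
            meanPerSample = "numeric", netFraction = "numeric",
            genusOnlyFrac = "numeric", plotSigma = "numeric",
            plotSpeciesSigma = "numeric", seed = "integer")
)

setValidity("SimConfig", function(object) {
  msg <- character()
  e <- object@effects
  need <- c("richness_deficit_frac", "evenness_skew", "turnover_compression",
            "peak_shift_days", "generalist_boost")
  if (!all(need %in% names(e)))
    msg <- c(msg, paste("effects must contain:", paste(need, collapse = ", ")))
  else {
    if (e[["richness_deficit_frac"]] < 0 || e[["richness_deficit_frac"]] >= 1)
      msg <- c(msg, "richness_deficit_frac must be in [0, 1)")
    if (e[["evenness_skew"]] < 1) msg <- c(msg, "evenness_skew must be >= 1")
    if (e[["turnover_compression"]] <= 0 || e[["turnover_compression"]] > 1)
      msg <- c(msg, "turnover_compression must be in (0, 1]")
    if (e[["generalist_boost"]] < 1) msg <- c(msg, "generalist_boost must be >= 1")
  }
  if (length(object@season) != 2 || object@season[1] >= object@season[2])
    msg <- c(msg, "season must be [day_start, day_end] with day_start < day_end")
  if (object@poolSize < 2) msg <- c(msg, "species pool must have >= 2 species")
  if (!all(c("reserve", "fragment") %in% names(object@nPlots)))
    msg <- c(msg, "nPlots must be named c(reserve=, fragment=)")
  for (fr in c("generalistFrac", "parasiticFrac", "unknownFrac",
               "nonnativeFrac", "genusOnlyFrac")) {
    v <- slot(object, fr)
    if (v < 0 || v > 1) msg <- c(msg, paste(fr, "must be in [0, 1]"))
  }
  if (object@meanPerSample <= 0) msg <- c(msg, "meanPerSample must be positive")
  if (length(msg)) msg else TRUE
})
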