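#' Pool a sample-level abundance matrix to one column per plot
#'
#' Sums counts column-wise over each plot's temporal samples, implementing
#' the temporal gamma pooling step.  The grand total of individuals is
#' conserved.
#'
#' @param x an \linkS4class{AbundanceMatrix}.
#' @return an \linkS4class{AbundanceMatrix} with \code{pooled = TRUE}, one
#'   column per plot (per year), whose \code{colData} records the number of
#'   temporal samples pooled (\code{n_samples}).
#' @examples
#' cfg <- scenarioPreset("paper_like_2011", seed = 1)
#' sim <- simulateSurvey(cfg)
#' am <- abundanceMatrix(filterRecords(sim$records, traits = sim$traits),
#'                       sim$traits)
#' pooled <- poolByPlot(am)
#' sum(counts(pooled)) == sum(counts(am))
#' @export
setGeneric("poolByPlot", function(x) standardGeneric("poolByPlot"))

#' @rdname ordinationAccessors
#' @export
setGeneric("scores", function(x, ...) standardGeneric("scores"))

#' @rdname ordinationAccessors
#' @export
setGeneric("stressValue", function(x) standardGeneric("stressValue"))

#' Per-plot dispersion scores from an ordination
#'
#' Temporal beta diversity as multivariate dispersion: for every plot the
#' centroid of its samples is computed in the full k-dimensional ordination
#' space and the plot's score is the mean Euclidean distance between that
#' centroid and the plot's samples.  Scores are invariant under rigid
#' motions (rotation, reflection, translation) of the coordinates.
#'
#' @param ordination an \linkS4class{Ordination} (or a bare coordinate
#'   matrix).
#' @param plots character/factor of plot assignments, one per sample row.
#' @param treatments optional treatment labels, one per sample row (carried
#'   into the score table).
#' @return a \linkS4class{DispersionResult}; plots with a single sample get
#'   \code{NA} scores flagged \code{"single_sample"}.
#' @export
setGeneric("dispersionScores",
           function(ordination, plots, treatments = NULL)
             standardGeneric("dispersionScores"))
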