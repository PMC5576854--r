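# Construction of the taxon-by-sample count matrix and plot-level pooling.

#' Build an AbundanceMatrix from survey records
#'
#' Pivots long-format records into a taxon-by-sample integer count matrix.
#' A sample is one plot on one julian date within one year; samples with no
#' surviving records simply do not appear (a warning lists how many record
#' keys collapsed).  At \code{taxonLevel = "genus"} counts are summed across
#' congeners using the trait table's genus column.
#'
#' @param records filtered, validated survey data.frame.
#' @param traits validated trait table covering every species in
#'   \code{records} (required; also attached as \code{rowData}).
#' @param taxonLevel \code{"species"} (default) or \code{"genus"}.
#' @return an \linkS4class{AbundanceMatrix}.
#' @export
abundanceMatrix <- function(records, traits, taxonLevel = c("species", "genus")) {
  taxonLevel <- match.arg(taxonLevel)
  records <- validateSurvey(records)
  traits <- validateTraits(traits)

  uncovered <- setdiff(records$species_id, traits$species_id)
  if (length(uncovered))
    stopf("species missing from trait table: %s",
          paste(head(uncovered, 5), collapse = ", "))

  if (taxonLevel == "genus") {
    g <- traits$genus[match(records$species_id, traits$species_id)]
    if (anyNA(g) || any(!nzchar(g)))
      stopf("species lacking genus in trait table; cannot aggregate")
    records$species_id <- g
  }

  sampleKey <- paste(records$plot_id, records$year, records$julian_date,
                     sep = "|")
  taxa <- sort(unique(records$species_id))
  samples <- unique(sampleKey)
  # stable sample order: plot, then year, then date
  ord <- order(records$plot_id[match(samples, sampleKey)],
               records$year[match(samples, sampleKey)],
               records$julian_date[match(samples, sampleKey)])
  samples <- samples[ord]

  cts <- matrix(0L, nrow = length(taxa), ncol = length(samples),
                dimnames = list(taxa, samples))
  flat <- (match(sampleKey, samples) - 1L) * length(taxa) +
    match(records$species_id, taxa)
  agg <- rowsum(records$count, flat)
  cts[as.integer(rownames(agg))] <- as.integer(agg[, 1])

  first <- records[match(samples, sampleKey), ]
  cd <- S4Vectors::DataFrame(plot_id = first$plot_id,
                             treatment = first$treatment,
                             year = first$year,
                             julian_date = first$julian_date,
                             row.names = samples)
  rd <- if (taxonLevel == "species") {
    tr <- traits[match(taxa, traits$species_id), ]
    S4Vectors::DataFrame(diet = tr$diet, native = tr$native, genus = tr$genus,
                         row.names = taxa)
  } else {
    # genus-level diet: "generalist"/"specialist" only if unanimous among
    # classifiable congeners, else "unknown"; parasitic-only genera stay
    # parasitic
    per <- lapply(taxa, function(g) traits$diet[traits$genus == g])
    diet <- vapply(per, function(d) {
      d2 <- setdiff(unique(d), c("unknown"))
      if (length(d2) == 1) d2 else "unknown"
    }, character(1))
    S4Vectors::DataFrame(diet = diet, native = NA, genus = taxa,
                         row.names = taxa)
  }

  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = cts), colData = cd, rowData = rd)
  new("AbundanceMatrix", se, level = taxonLevel, pooled = FALSE)
}

#' Counts assay accessor
#' @param x an \linkS4class{AbundanceMatrix}.
#' @return integer matrix, taxa x samples.
#' @export
counts <- function(x) SummarizedExperiment::assay(x, "counts")

#' Sample metadata accessors
#'
#' @param x an \linkS4class{AbundanceMatrix}.
#' @name sampleMeta
#' @return character/integer vectors aligned to the matrix columns.
NULL

#' @rdname sampleMeta
#' @export
plotIds <- function(x) SummarizedExperiment::colData(x)$plot_id

#' @rdname sampleMeta
#' @export
treatments <- function(x) SummarizedExperiment::colData(x)$treatment

#' @rdname sampleMeta
#' @export
julianDates <- function(x) SummarizedExperiment::colData(x)$julian_date

#' @rdname sampleMeta
#' @export
sampleYears <- function(x) SummarizedExperiment::colData(x)$year

#' @rdname sampleMeta
#' @export
sampleTotals <- function(x) colSums(counts(x))

#' Taxon traits accessor
#' @param x an \linkS4class{AbundanceMatrix}.
#' @return data.frame of per-taxon traits aligned to rows.
#' @export
taxonTraits <- function(x) as.data.frame(SummarizedExperiment::rowData(x))

#' @rdname poolByPlot
#' @export
setMethod("poolByPlot", "AbundanceMatrix", function(x) {
  if (x@pooled) return(x)
  cd <- SummarizedExperiment::colData(x)
  key <- paste(cd$plot_id, cd$year, sep = "|")
  plots <- unique(key)
  cts <- counts(x)
  pooled <- vapply(plots, function(k) rowSums(cts[, key == k, drop = FALSE]),
                   numeric(nrow(cts)))
  pooled <- matrix(as.integer(pooled), nrow = nrow(cts),
                   dimnames = list(rownames(cts), plots))
  first <- match(plots, key)
  cd2 <- S4Vectors::DataFrame(
    plot_id = cd$plot_id[first], treatment = cd$treatment[first],
    year = cd$year[first],
    n_samples = as.integer(table(key)[plots]),
    row.names = plots)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = pooled), colData = cd2,
    rowData = SummarizedExperiment::rowData(x))
  new("AbundanceMatrix", se, level = x@level, pooled = TRUE)
})

setMethod("show", "AbundanceMatrix", function(object) {
  cat(sprintf("AbundanceMatrix: %d %s x %d %s, %d individuals\n",
              nrow(object), ifelse(object@level == "genus", "genera", "taxa"),
              ncol(object),
              if (object@pooled) "plots (pooled)" else "temporal samples",
              sum(counts(object))))
  cd <- SummarizedExperiment::colData(object)
  cat(sprintf("  years: %s | treatments: %s\n",
              paste(sort(unique(cd$year)), collapse = ", "),
              paste(table(cd$treatment)[unique(cd$treatment)],
                    unique(cd$treatment), collapse = ", ")))
})
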