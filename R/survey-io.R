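# Survey and trait table I/O, validation, filtering, and summary reporting.

.surveyCols <- c("plot_id", "treatment", "year", "julian_date", "method",
                 "species_id", "count", "id_level")
.traitCols  <- c("species_id", "diet", "native", "genus")
.treatments <- c("reserve", "fragment")
.methods    <- c("bowl", "net")
.idLevels   <- c("species", "morphospecies", "genus_only")
.diets      <- c("generalist", "specialist", "parasitic", "unknown")

#' Validate a long-format survey table
#'
#' Checks the column set, enumerations and row-level invariants of a survey
#' table (one row per plot x date x method x species observation) and
#' collapses duplicate rows for the same observation key by summing counts.
#'
#' @param records data.frame with columns \code{plot_id}, \code{treatment},
#'   \code{year}, \code{julian_date}, \code{method}, \code{species_id},
#'   \code{count}, \code{id_level}.
#' @return the validated (possibly duplicate-collapsed) data.frame.
#' @export
validateSurvey <- function(records) {
  if (isTRUE(attr(records, "surveyValidated"))) return(records)
  missing <- setdiff(.surveyCols, names(records))
  if (length(missing))
    stopf("survey table is missing column(s): %s", paste(missing, collapse = ", "))
  records <- as.data.frame(records)[.surveyCols]

  cnt <- suppressWarnings(as.numeric(records$count))
  bad <- which(is.na(cnt) | cnt != round(cnt))
  if (length(bad))
    stopf("non-integer count in row(s): %s", paste(head(bad, 5), collapse = ", "))
  bad <- which(cnt < 1)
  if (length(bad))
    stopf("count must be >= 1; violated in row(s): %s",
          paste(head(bad, 5), collapse = ", "))
  records$count <- as.integer(cnt)

  jd <- suppressWarnings(as.numeric(records$julian_date))
  bad <- which(is.na(jd) | jd < 1 | jd > 366 | jd != round(jd))
  if (length(bad))
    stopf("julian_date must be an integer in [1, 366]; violated in row(s): %s",
          paste(head(bad, 5), collapse = ", "))
  records$julian_date <- as.integer(jd)
  records$year <- as.integer(records$year)

  chk <- function(col, allowed) {
    v <- as.character(records[[col]])
    bad <- which(!v %in% allowed)
    if (length(bad))
      stopf("unknown %s '%s' in row %d (allowed: %s)", col, v[bad[1]], bad[1],
            paste(allowed, collapse = ", "))
    v
  }
  records$treatment <- chk("treatment", .treatments)
  records$method    <- chk("method", .methods)
  records$id_level  <- chk("id_level", .idLevels)
  records$plot_id   <- as.character(records$plot_id)
  records$species_id <- as.character(records$species_id)

  key <- paste(records$plot_id, records$year, records$julian_date,
               records$method, records$species_id, sep = "\r")
  if (anyDuplicated(key)) {
    ndup <- sum(duplicated(key))
    agg <- rowsum(records$count, key)
    first <- records[!duplicated(key), ]
    first$count <- as.integer(agg[match(
      paste(first$plot_id, first$year, first$julian_date, first$method,
            first$species_id, sep = "\r"), rownames(agg)), 1])
    records <- first
    warnf("summed %d duplicate (plot, date, method, species) row(s)", ndup)
  }

  tw <- tapply(records$treatment, paste(records$plot_id, records$year),
               function(z) length(unique(z)))
  if (any(tw > 1))
    stopf("treatment is not constant within plot x year: %s",
          names(tw)[which(tw > 1)[1]])
  rownames(records) <- NULL
  attr(records, "surveyValidated") <- TRUE
  records
}

#' Read and validate a survey CSV
#'
#' @param path CSV with a header row and the survey columns (see
#'   \code{\link{validateSurvey}}).
#' @return validated survey data.frame.
#' @export
readSurvey <- function(path) {
  if (!file.exists(path)) stopf("survey file not found: %s", path)
  validateSurvey(read.csv(path, stringsAsFactors = FALSE))
}

#' Validate a species-trait table
#'
#' @param traits data.frame with \code{species_id}, \code{diet} (generalist,
#'   specialist, parasitic or unknown), \code{native} (logical) and
#'   \code{genus}.
#' @return validated trait data.frame, one row per species.
#' @export
validateTraits <- function(traits) {
  missing <- setdiff(.traitCols, names(traits))
  if (length(missing))
    stopf("trait table is missing column(s): %s", paste(missing, collapse = ", "))
  traits <- as.data.frame(traits)[.traitCols]
  traits$species_id <- as.character(traits$species_id)
  traits$genus <- as.character(traits$genus)
  if (anyDuplicated(traits$species_id))
    stopf("duplicate species_id in trait table: %s",
          traits$species_id[duplicated(traits$species_id)][1])
  bad <- which(!traits$diet %in% .diets)
  if (length(bad))
    stopf("unknown diet '%s' for species %s", traits$diet[bad[1]],
          traits$species_id[bad[1]])
  traits$native <- as.logical(traits$native)
  if (anyNA(traits$native)) stopf("native flag must be TRUE/FALSE")
  rownames(traits) <- NULL
  traits
}

#' @rdname validateTraits
#' @param path CSV path.
#' @export
readTraits <- function(path) {
  if (!file.exists(path)) stopf("trait file not found: %s", path)
  validateTraits(read.csv(path, stringsAsFactors = FALSE))
}

#' Write survey or trait tables back to CSV
#'
#' Round-trippable writers for the two external table formats.
#' @param x validated survey or trait data.frame.
#' @param path output CSV path.
#' @export
writeSurvey <- function(x, path) {
  write.csv(validateSurvey(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeSurvey
#' @export
writeTraits <- function(x, path) {
  write.csv(validateTraits(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Filter survey records to the analysis set
#'
#' Applies the standard exclusion rules: keep only the requested collection
#' methods (bowl traps by default, avoiding collector bias in netting),
#' drop non-native species (trait-driven), and drop specimens not
#' identifiable beyond genus.  The removal counts per rule are attached as
#' the \code{"filterReport"} attribute (see \code{\link{filterReport}}).
#'
#' @param records validated survey data.frame.
#' @param keepMethods methods to retain (default \code{"bowl"}).
#' @param dropNonnative drop species whose trait row has \code{native =
#'   FALSE} (default \code{TRUE}); requires \code{traits}.
#' @param dropGenusOnly drop records with \code{id_level = "genus_only"}
#'   (default \code{TRUE}).
#' @param traits validated trait table (needed when \code{dropNonnative}).
#' @return filtered records with a \code{filterReport} attribute listing the
#'   number of rows and individuals removed by each rule.
#' @export
filterRecords <- function(records, keepMethods = "bowl",
                          dropNonnative = TRUE, dropGenusOnly = TRUE,
                          traits = NULL) {
  records <- validateSurvey(records)
  report <- list()
  tally <- function(mask) list(rows = sum(mask),
                               individuals = sum(records$count[mask]))

  keep <- records$method %in% keepMethods
  report$method <- tally(!keep)
  records2 <- records[keep, ]

  if (dropNonnative) {
    if (is.null(traits)) stopf("dropNonnative = TRUE requires a trait table")
    traits <- validateTraits(traits)
    nn <- traits$species_id[!traits$native]
    mask <- records2$species_id %in% nn
    report$nonnative <- list(rows = sum(mask),
                             individuals = sum(records2$count[mask]))
    records2 <- records2[!mask, ]
  } else report$nonnative <- list(rows = 0L, individuals = 0L)

  if (dropGenusOnly) {
    mask <- records2$id_level == "genus_only"
    report$genus_only <- list(rows = sum(mask),
                              individuals = sum(records2$count[mask]))
    records2 <- records2[!mask, ]
  } else report$genus_only <- list(rows = 0L, individuals = 0L)

  if (nrow(records2) == 0) stopf("no records survive filters")
  rownames(records2) <- NULL
  attr(records2, "filterReport") <- report
  attr(records2, "surveyValidated") <- TRUE
  records2
}

#' @rdname filterRecords
#' @param x output of \code{filterRecords}.
#' @export
filterReport <- function(x) attr(x, "filterReport")

#' Composition summary of a survey
#'
#' Reporting utility: per-method specimen and species tallies with their
#' percentage shares, and the identification-level breakdown, computed from
#' the records as given (no filtering is applied).  Percentage denominators
#' are the totals present in \code{records}.
#'
#' @param records validated survey data.frame.
#' @param speciesTotal optional denominator for the species-share column;
#'   defaults to the number of distinct taxa in \code{records}.
#' @return list with \code{methods} and \code{id_levels} data.frames and the
#'   overall totals.
#' @export
surveySummary <- function(records, speciesTotal = NULL) {
  records <- validateSurvey(records)
  nTot <- sum(records$count)
  sTot <- if (is.null(speciesTotal)) length(unique(records$species_id))
          else speciesTotal
  meth <- do.call(rbind, lapply(unique(records$method), function(m) {
    r <- records[records$method == m, ]
    data.frame(method = m,
               n_specimens = sum(r$count),
               pct_specimens = 100 * sum(r$count) / nTot,
               n_species = length(unique(r$species_id)),
               pct_species = 100 * length(unique(r$species_id)) / sTot)
  }))
  idl <- do.call(rbind, lapply(unique(records$id_level), function(l) {
    r <- records[records$id_level == l, ]
    data.frame(id_level = l,
               n_specimens = sum(r$count),
               pct_specimens = 100 * sum(r$count) / nTot)
  }))
  list(methods = meth, id_levels = idl,
       total_specimens = nTot, total_species = sTot)
}
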