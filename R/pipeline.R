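# One-call orchestration: filter -> matrices -> gamma / alpha / beta ->
# Welch and mixed-model comparisons, with optional tidy-CSV output.

.responses <- c("rarefied_richness", "evenness_logit",
                "generalist_prop_logit", "abundance_transformed")

#' Welch comparisons of the four plot-level gamma responses
#'
#' @param gtab a \code{\link{gammaTable}} data.frame.
#' @return data.frame, one Welch row per response, reserve vs fragment.
#' @export
gammaTests <- function(gtab) {
  nper <- table(gtab$treatment[!duplicated(gtab$plot_id)])
  if (any(!c("reserve", "fragment") %in% names(nper)) || any(nper < 2))
    stopf("gamma stage: need at least 2 plots per treatment (have: %s)",
          paste(names(nper), nper, collapse = ", "))
  do.call(rbind, lapply(.responses, function(r) {
    w <- welchTest(gtab[[r]][gtab$treatment == "reserve"],
                   gtab[[r]][gtab$treatment == "fragment"])
    cbind(data.frame(response = r, stringsAsFactors = FALSE), w)
  }))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stopf("[%s stage] %s", name, conditionMessage(e)))
}

#' Run the full temporal-diversity analysis
#'
#' Per year: (1) filter records to the analysis set, (2) pivot to a
#' taxon-by-sample matrix, (3) temporal gamma table plus Welch tests on the
#' four plot-level responses, (4) temporal alpha table plus an AIC-selected
#' random-intercept trend model per response, (5) Bray-Curtis
#' dissimilarities across all samples jointly, NMDS ordination, per-plot
#' dispersion scores and their Welch test.  Any stage failure aborts with a
#' stage-named message.  All randomness flows from the single \code{seed}.
#'
#' @param survey survey data.frame or CSV path.
#' @param traits trait data.frame or CSV path.
#' @param year year(s) to analyse; default all years present, each
#'   separately.
#' @param keepMethods,dropNonnative,dropGenusOnly filter settings (see
#'   \code{\link{filterRecords}}).
#' @param taxonLevel \code{"species"} or \code{"genus"}.
#' @param alphaDepth per-sample rarefaction depth (default 20).
#' @param gammaDepth \code{"auto"} (yearly minimum pooled plot abundance)
#'   or integer.
#' @param iterations rarefaction iterations (default 1000).
#' @param k,nRestarts,maxIter,tol NMDS settings (see
#'   \code{\link{nmdsOrdination}}).
#' @param engine \code{"nmds"} (default) or \code{"pcoa"} ordination engine
#'   for the dispersion scores.
#' @param anovaType sequential (default) or marginal mixed-model F tests.
#' @param seed master seed.
#' @param outDir optional output directory; tidy CSVs, the config echo and
#'   a run log are written there (removed again if a later stage fails).
#' @return list with one element per year: \code{gamma} (table, tests),
#'   \code{alpha} (table, one \linkS4class{LmmFit} per response, term
#'   tables), \code{beta} (ordination, dispersion, test), \code{filter}
#'   report and the echoed settings.
#' @export
runAnalysis <- function(survey, traits, year = NULL,
                        keepMethods = "bowl", dropNonnative = TRUE,
                        dropGenusOnly = TRUE,
                        taxonLevel = c("species", "genus"),
                        alphaDepth = 20, gammaDepth = "auto",
                        iterations = 1000,
                        k = 2, nRestarts = 20, maxIter = 300, tol = 1e-7,
                        engine = c("nmds", "pcoa"),
                        anovaType = c("sequential", "marginal"),
                        seed = 1, outDir = NULL) {
  taxonLevel <- match.arg(taxonLevel)
  engine <- match.arg(engine)
  anovaType <- match.arg(anovaType)
  if (is.character(survey)) survey <- readSurvey(survey)
  if (is.character(traits)) traits <- readTraits(traits)
  settings <- list(keepMethods = keepMethods, dropNonnative = dropNonnative,
                   dropGenusOnly = dropGenusOnly, taxonLevel = taxonLevel,
                   alphaDepth = alphaDepth, gammaDepth = gammaDepth,
                   iterations = iterations, k = k, nRestarts = nRestarts,
                   maxIter = maxIter, tol = tol, engine = engine,
                   anovaType = anovaType, seed = seed)
  wroteDir <- !is.null(outDir) && !dir.exists(outDir)
  cleanup <- function() if (!is.null(outDir)) {
    if (wroteDir) unlink(outDir, recursive = TRUE)
    else unlink(list.files(outDir, full.names = TRUE))
  }
  res <- tryCatch({
    filtered <- .stage("filter",
      filterRecords(survey, keepMethods = keepMethods,
                    dropNonnative = dropNonnative,
                    dropGenusOnly = dropGenusOnly, traits = traits))
    years <- if (is.null(year)) sort(unique(filtered$year)) else year
    perYear <- lapply(years, function(yr) {
      recs <- filtered[filtered$year == yr, ]
      if (!nrow(recs)) stopf("[filter stage] no records for year %d", yr)
      am <- .stage("matrix", abundanceMatrix(recs, traits, taxonLevel))

      gtab <- .stage("gamma", gammaTable(am, depth = gammaDepth,
                                         iterations = iterations,
                                         seed = seed))
      gtests <- .stage("gamma", gammaTests(gtab))

      atab <- .stage("alpha", alphaTable(am, depth = alphaDepth,
                                         iterations = iterations,
                                         seed = seed))
      lmms <- .stage("alpha", lapply(setNames(nm = .responses), function(r)
        selectTrendModel(atab, r, anovaType = anovaType)))
      lmmTerms <- do.call(rbind, lapply(.responses, function(r) {
        f <- lmms[[r]]
        cbind(data.frame(response = r, degree = degreeOf(f),
                         aic_ml = aicValue(f), stringsAsFactors = FALSE),
              anovaTable(f))
      }))

      D <- .stage("beta", dissimilarityMatrix(am))
      ord <- .stage("beta", if (engine == "nmds")
        nmdsOrdination(D, k = k, nRestarts = nRestarts, maxIter = maxIter,
                       tol = tol, seed = seed)
        else {
          pts <- pcoaCoords(D, k)
          pts <- scale(pts, center = TRUE, scale = FALSE)
          attr(pts, "scaled:center") <- NULL
          new("Ordination", coordinates = pts, stress = kruskalStress(D, pts),
              k = as.integer(ncol(pts)), converged = TRUE, restartsRun = 1L,
              engine = "pcoa")
        })
      disp <- .stage("beta", dispersionScores(ord, plotIds(am),
                                              treatments(am)))
      dtab <- dispersionTable(disp)
      dtest <- .stage("beta",
        welchTest(dtab$dispersion[dtab$treatment == "reserve"],
                  dtab$dispersion[dtab$treatment == "fragment"]))

      list(year = yr,
           gamma = list(table = gtab, tests = gtests),
           alpha = list(table = atab, fits = lmms, terms = lmmTerms),
           beta = list(ordination = ord, dispersion = disp,
                       table = dtab, test = dtest))
    })
    names(perYear) <- paste0("year", years)
    c(perYear, list(filter = filterReport(filtered), settings = settings))
  }, error = function(e) { cleanup(); stop(e) })

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    log <- c(sprintf("temporaldiv run, seed %s", seed),
             sprintf("filter report: %s",
                     paste(names(res$filter), vapply(res$filter,
                           function(z) z$rows, numeric(1)),
                           sep = "=", collapse = ", ")))
    for (nm in grep("^year", names(res), value = TRUE)) {
      yr <- res[[nm]]$year
      write.csv(res[[nm]]$gamma$table,
                file.path(outDir, sprintf("gamma_table_%d.csv", yr)),
                row.names = FALSE)
      write.csv(res[[nm]]$gamma$tests,
                file.path(outDir, sprintf("gamma_tests_%d.csv", yr)),
                row.names = FALSE)
      write.csv(res[[nm]]$alpha$table,
                file.path(outDir, sprintf("alpha_table_%d.csv", yr)),
                row.names = FALSE)
      write.csv(res[[nm]]$alpha$terms,
                file.path(outDir, sprintf("alpha_lmm_terms_%d.csv", yr)),
                row.names = FALSE)
      write.csv(res[[nm]]$beta$table,
                file.path(outDir, sprintf("dispersion_%d.csv", yr)),
                row.names = FALSE)
      write.csv(res[[nm]]$beta$test,
                file.path(outDir, sprintf("dispersion_test_%d.csv", yr)),
                row.names = FALSE)
      log <- c(log, sprintf(
        "year %d: %d samples, gamma depth %d, NMDS stress %.4f", yr,
        nrow(res[[nm]]$alpha$table), attr(res[[nm]]$gamma$table, "depth"),
        stressValue(res[[nm]]$beta$ordination)))
    }
    jsonlite::write_json(settings, file.path(outDir, "settings.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    writeLines(log, file.path(outDir, "run_log.txt"))
  }
  res
}

#' Simulate a survey and write its files
#'
#' Writes \code{survey.csv}, \code{traits.csv} and \code{truth.json}
#' (injected effects, seed, config echo) to \code{outDir}.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param outDir output directory (created if needed).
#' @param year year stamped into the records.
#' @return (invisibly) the list from \code{\link{simulateSurvey}} plus the
#'   file paths.
#' @export
runSimulation <- function(config, outDir, year = 2011L) {
  sim <- simulateSurvey(config, year = year)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(survey = file.path(outDir, "survey.csv"),
                traits = file.path(outDir, "traits.csv"),
                truth = file.path(outDir, "truth.json"))
  writeSurvey(sim$records, paths$survey)
  writeTraits(sim$traits, paths$traits)
  jsonlite::write_json(sim$truth, paths$truth, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(c(sim, list(paths = paths)))
}
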