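# Welch comparisons, polynomial bases, random-intercept trend models and
# AIC degree selection.

#' Welch two-sample t-test
#'
#' Location test without the equal-variance assumption;
#' Welch-Satterthwaite denominator degrees of freedom.  Reduces to the
#' classical pooled test when group sizes and variances are equal.
#'
#' @param x,y numeric vectors (each n >= 2, finite).
#' @return data.frame row: \code{t}, \code{df}, \code{p}, \code{mean_x},
#'   \code{mean_y}, \code{var_x}, \code{var_y}, \code{n_x}, \code{n_y}.
#' @export
welchTest <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2)
    stopf("welchTest: both groups need at least 2 non-missing values")
  if (var(x) == 0 && var(y) == 0)
    stopf("welchTest: zero variance in both groups")
  ht <- t.test(x, y, var.equal = FALSE)
  data.frame(t = unname(ht$statistic), df = unname(ht$parameter),
             p = ht$p.value, mean_x = mean(x), mean_y = mean(y),
             var_x = var(x), var_y = var(y),
             n_x = length(x), n_y = length(y))
}

#' Orthonormal polynomial basis
#'
#' Columns are mutually orthonormal, orthogonal to the constant vector, and
#' span the same space as the raw powers 1..degree.  The input is centred
#' and scaled before construction for conditioning; a deterministic sign
#' convention is enforced (the leading raw-power coefficient of each column
#' is positive), so the basis does not depend on storage order quirks.
#'
#' @param x numeric vector with at least \code{degree + 1} distinct values.
#' @param degree 1, 2 or 3.
#' @return matrix with \code{degree} columns named \code{poly1..}; the
#'   Gram matrix is the identity.
#' @export
orthPoly <- function(x, degree) {
  stopifnot(degree %in% 1:3)
  if (length(unique(x)) < degree + 1)
    stopf("orthPoly: need at least %d distinct values, got %d",
          degree + 1, length(unique(x)))
  z <- (x - mean(x)) / sd(x)
  b <- unclass(poly(z, degree = degree))
  # sign convention: leading coefficient on the highest raw power positive
  for (j in seq_len(degree)) {
    cf <- coef(lm(b[, j] ~ stats::poly(z, degree = j, raw = TRUE)))
    if (cf[length(cf)] < 0) b[, j] <- -b[, j]
  }
  colnames(b) <- paste0("poly", seq_len(degree))
  attributes(b)$degree <- NULL
  attributes(b)$coefs <- NULL
  b
}

.buildLmmData <- function(table, response, degree, covariate) {
  need <- c(response, "treatment", "plot_id", "julian_date", covariate)
  miss <- setdiff(need, names(table))
  if (length(miss))
    stopf("table lacks column(s): %s", paste(miss, collapse = ", "))
  d <- table[!is.na(table[[response]]), , drop = FALSE]
  if (length(covariate)) d <- d[!is.na(d[[covariate]]), , drop = FALSE]
  d$.resp <- as.numeric(d[[response]])
  d$.trt <- factor(d$treatment, levels = c("reserve", "fragment"))
  d$.plot <- factor(d$plot_id)
  pb <- orthPoly(d$julian_date, degree)
  for (j in seq_len(degree)) d[[paste0(".date", j)]] <- pb[, j]
  d
}

#' Random-intercept seasonal trend model
#'
#' Fits the Gaussian mixed model
#' \code{response ~ treatment * poly(julian_date, degree) [+ covariate]}
#' with a plot-identity random intercept, via \code{nlme::lme}.  The model
#' is fit twice: by maximum likelihood (whose AIC is comparable across
#' fixed-effect structures, i.e. across polynomial degrees) and by REML,
#' from which the sequential per-term F tests are reported with nlme's
#' between-within denominator df -- plot-level terms (treatment, plot-level
#' covariates) are tested against the plot stratum, date terms and
#' interactions against the within-plot stratum.  A boundary fit
#' (between-plot variance indistinguishable from zero) is retained with a
#' warning rather than errored.
#'
#' @param table a temporal alpha \code{\link{alphaTable}}-style data.frame
#'   (rows with missing response are dropped).
#' @param response response column name.
#' @param degree polynomial degree in julian date (1-3).
#' @param covariate optional plot-level covariate column name.
#' @param anovaType \code{"sequential"} (default; terms in entry order
#'   treatment, date terms, interactions) or \code{"marginal"}.
#' @param reml if \code{FALSE}, only the ML fit (and its AIC) is computed --
#'   enough for degree selection; the F-test table is left empty until a
#'   full refit.
#' @return an \linkS4class{LmmFit}.
#' @export
fitTrendLmm <- function(table, response, degree = 1, covariate = NULL,
                        anovaType = c("sequential", "marginal"),
                        reml = TRUE) {
  anovaType <- match.arg(anovaType)
  covariate <- if (is.null(covariate)) character(0) else covariate
  d <- .buildLmmData(table, response, degree, covariate)
  if (length(unique(d$.plot[d$.trt == "reserve"])) < 2 ||
      length(unique(d$.plot[d$.trt == "fragment"])) < 2)
    stopf("need at least 2 plots per treatment")
  dateTerms <- paste0(".date", seq_len(degree))
  rhs <- c(".trt", dateTerms,
           if (length(covariate)) covariate,
           paste0(".trt:", dateTerms))
  fml <- stats::as.formula(paste(".resp ~", paste(rhs, collapse = " + ")))

  fitWith <- function(method)
    nlme::lme(fixed = fml, random = ~ 1 | .plot, data = d, method = method,
              control = nlme::lmeControl(opt = "optim", maxIter = 200,
                                         msMaxIter = 200, returnObject = TRUE))
  fitML <- fitWith("ML")
  if (!reml) {
    return(new("LmmFit", response = response, degree = as.integer(degree),
               covariate = covariate, fitML = fitML, fitREML = NULL,
               aic = AIC(fitML),
               anovaTable = data.frame(term = character(), numDF = integer(),
                                       denDF = integer(), F = numeric(),
                                       p = numeric()),
               fixef = nlme::fixef(fitML),
               varcor = c(plot = NA_real_, residual = NA_real_),
               nObs = nrow(d), nPlots = length(unique(d$.plot))))
  }
  fitREML <- fitWith("REML")

  vc <- nlme::VarCorr(fitREML)
  varPlot <- suppressWarnings(as.numeric(vc["(Intercept)", "Variance"]))
  varRes <- suppressWarnings(as.numeric(vc["Residual", "Variance"]))
  if (is.finite(varPlot) && is.finite(varRes) && varPlot < 1e-8 * varRes)
    warnf("between-plot variance is at the boundary (~0); fit retained")

  an <- anova(fitREML, type = anovaType)
  anTab <- data.frame(term = rownames(an), numDF = an$numDF,
                      denDF = an$denDF, F = an$`F-value`,
                      p = an$`p-value`, stringsAsFactors = FALSE)

  new("LmmFit", response = response, degree = as.integer(degree),
      covariate = covariate, fitML = fitML, fitREML = fitREML,
      aic = AIC(fitML), anovaTable = anTab,
      fixef = nlme::fixef(fitREML),
      varcor = c(plot = varPlot, residual = varRes),
      nObs = nrow(d), nPlots = length(unique(d$.plot)))
}

#' LmmFit accessors
#' @param x an \linkS4class{LmmFit}.
#' @name lmmAccessors
#' @return \code{anovaTable}: sequential F tests (term, numDF, denDF, F, p);
#'   \code{aicValue}: maximum-likelihood AIC; \code{fixedEffects}: REML
#'   fixed-effect estimates; \code{degreeOf}: the polynomial degree.
NULL

#' @rdname lmmAccessors
#' @export
anovaTable <- function(x) x@anovaTable

#' @rdname lmmAccessors
#' @export
aicValue <- function(x) x@aic

#' @rdname lmmAccessors
#' @export
fixedEffects <- function(x) x@fixef

#' @rdname lmmAccessors
#' @export
degreeOf <- function(x) x@degree

setMethod("show", "LmmFit", function(object) {
  cat(sprintf(
    "Random-intercept trend model: %s ~ treatment * poly(date, %d)%s\n",
    object@response, object@degree,
    if (length(object@covariate)) paste0(" + ", object@covariate) else ""))
  cat(sprintf("  %d observations, %d plots; AIC(ML) = %.2f\n",
              object@nObs, object@nPlots, object@aic))
  cat(sprintf("  variances: plot %.4g, residual %.4g\n",
              object@varcor[["plot"]], object@varcor[["residual"]]))
  print(object@anovaTable, row.names = FALSE)
})

#' AIC-based polynomial degree selection
#'
#' Among candidate fits of increasing polynomial degree (on identical
#' rows), those within 2 AIC units of the minimum are treated as equally
#' supported and the lowest degree among them is returned.
#'
#' @param fits list of \linkS4class{LmmFit} objects, one per degree.
#' @return the selected \linkS4class{LmmFit}.
#' @export
selectDegree <- function(fits) {
  if (!length(fits)) stopf("selectDegree: empty fit list")
  nObs <- vapply(fits, function(f) f@nObs, integer(1))
  if (length(unique(nObs)) > 1)
    stopf("fits were computed on differing row sets; AICs not comparable")
  aics <- vapply(fits, aicValue, numeric(1))
  degs <- vapply(fits, degreeOf, integer(1))
  candidates <- which(aics - min(aics) < 2)
  fits[[candidates[which.min(degs[candidates])]]]
}

#' Fit, select and report the seasonal trend model for one response
#'
#' Convenience wrapper: fits the random-intercept model at polynomial
#' degrees 1-3 by ML, applies the \code{\link{selectDegree}} rule, and
#' refits the chosen degree with REML to obtain the reported F-test table.
#'
#' @inheritParams fitTrendLmm
#' @param degrees candidate polynomial degrees (default 1:3).
#' @return the selected, fully fitted \linkS4class{LmmFit}.
#' @export
selectTrendModel <- function(table, response, covariate = NULL,
                             anovaType = c("sequential", "marginal"),
                             degrees = 1:3) {
  anovaType <- match.arg(anovaType)
  fits <- lapply(degrees, function(dg)
    fitTrendLmm(table, response, degree = dg, covariate = covariate,
                reml = FALSE))
  sel <- selectDegree(fits)
  fitTrendLmm(table, response, degree = degreeOf(sel),
              covariate = covariate, anovaType = anovaType, reml = TRUE)
}

#' Plot-level regression with an added covariate
#'
#' Ordinary least squares of a plot-level response on the treatment
#' indicator plus a covariate (e.g. plant richness), with the AIC of the
#' treatment-only model on the same rows for comparison.  A covariate
#' collinear with the design aborts; a covariate that reproduces the
#' response essentially exactly triggers a structural warning.
#'
#' @param table plot-level data.frame with \code{treatment}, the response
#'   and the covariate.
#' @param response,covariate column names.
#' @return list: \code{fit} (lm), \code{aic}, \code{aic_treatment_only},
#'   \code{delta_aic} (covariate model minus treatment-only).
#' @export
olsWithCovariate <- function(table, response, covariate) {
  d <- table[!is.na(table[[response]]) & !is.na(table[[covariate]]), ]
  if (nrow(d) < 4) stopf("need at least 4 complete rows")
  d$.trt <- factor(d$treatment, levels = c("reserve", "fragment"))
  if (var(d[[covariate]]) == 0) stopf("covariate has zero variance")
  fml <- stats::as.formula(paste(response, "~ .trt +", covariate))
  fit <- lm(fml, data = d)
  if (anyNA(coef(fit))) stopf("covariate is collinear with the design")
  if (suppressWarnings(summary(fit)$r.squared) > 1 - 1e-10)
    warnf("covariate reproduces the response almost exactly")
  fit0 <- lm(stats::as.formula(paste(response, "~ .trt")), data = d)
  list(fit = fit, aic = AIC(fit), aic_treatment_only = AIC(fit0),
       delta_aic = AIC(fit) - AIC(fit0))
}
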