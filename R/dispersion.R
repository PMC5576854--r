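# Per-plot multivariate dispersion (temporal beta diversity) scores.

.dispersionCompute <- function(coords, plots, treatments = NULL) {
  plots <- as.character(plots)
  if (nrow(coords) != length(plots))
    stopf("one plot assignment per sample row is required")
  if (is.null(treatments)) treatments <- rep(NA_character_, length(plots))
  up <- unique(plots)
  cent <- matrix(NA_real_, length(up), ncol(coords),
                 dimnames = list(up, colnames(coords)))
  rows <- lapply(seq_along(up), function(i) {
    idx <- which(plots == up[i])
    xs <- coords[idx, , drop = FALSE]
    cent[i, ] <<- colMeans(xs)
    if (length(idx) < 2) {
      data.frame(plot_id = up[i], treatment = treatments[idx[1]],
                 n_samples = length(idx), dispersion = NA_real_,
                 exclusion_reason = "single_sample",
                 stringsAsFactors = FALSE)
    } else {
      dev <- sweep(xs, 2, colMeans(xs))
      data.frame(plot_id = up[i], treatment = treatments[idx[1]],
                 n_samples = length(idx),
                 dispersion = mean(sqrt(rowSums(dev^2))),
                 exclusion_reason = NA_character_,
                 stringsAsFactors = FALSE)
    }
  })
  scores <- do.call(rbind, rows)
  rownames(scores) <- NULL
  list(scores = scores, centroids = cent)
}

#' @rdname dispersionScores
#' @export
setMethod("dispersionScores", "Ordination",
  function(ordination, plots, treatments = NULL) {
    res <- .dispersionCompute(scores(ordination), plots, treatments)
    new("DispersionResult", scores = res$scores, centroids = res$centroids,
        ordination = ordination)
  })

#' @rdname dispersionScores
#' @export
setMethod("dispersionScores", "matrix",
  function(ordination, plots, treatments = NULL) {
    res <- .dispersionCompute(ordination, plots, treatments)
    coords <- scale(ordination, center = TRUE, scale = FALSE)
    attr(coords, "scaled:center") <- NULL
    ord <- new("Ordination", coordinates = coords, stress = 0,
               k = as.integer(ncol(ordination)), converged = TRUE,
               restartsRun = 0L, engine = "pcoa")
    new("DispersionResult", scores = res$scores, centroids = res$centroids,
        ordination = ord)
  })

#' Dispersion score table accessor
#' @param x a \linkS4class{DispersionResult}.
#' @return data.frame of per-plot scores (see \code{\link{dispersionScores}}).
#' @export
dispersionTable <- function(x) x@scores

setMethod("show", "DispersionResult", function(object) {
  ok <- !is.na(object@scores$dispersion)
  cat(sprintf("Dispersion scores for %d plots (%d excluded):\n",
              nrow(object@scores), sum(!ok)))
  print(object@scores, row.names = FALSE)
})
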