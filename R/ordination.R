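# Bray-Curtis dissimilarity, classical scaling, Kruskal NMDS and stress.

#' Bray-Curtis dissimilarity between two count vectors
#'
#' \eqn{\sum_i |x_i - y_i| / \sum_i (x_i + y_i)}: 0 for identical
#' assemblages, 1 for disjoint supports.
#'
#' @param x,y equal-length non-negative vectors, not both all-zero.
#' @return dissimilarity in [0, 1].
#' @export
brayCurtis <- function(x, y) {
  if (length(x) != length(y)) stopf("brayCurtis: unequal lengths")
  tot <- sum(x) + sum(y)
  if (tot == 0) stopf("brayCurtis: both vectors are all-zero")
  sum(abs(x - y)) / tot
}

#' All-pairs Bray-Curtis dissimilarity matrix
#'
#' One matrix per year across all plots' samples jointly, computed with
#' \code{vegan::vegdist}.  An all-zero sample has no defined dissimilarity
#' and aborts with the sample named.
#'
#' @param x an \linkS4class{AbundanceMatrix} (>= 3 samples), or a bare
#'   samples-x-taxa count matrix.
#' @return square symmetric numeric matrix with zero diagonal, sample keys
#'   as dimnames.
#' @export
dissimilarityMatrix <- function(x) {
  m <- if (is(x, "AbundanceMatrix")) t(counts(x)) else as.matrix(x)
  if (nrow(m) < 3) stopf("need at least 3 samples for an ordination")
  zero <- rownames(m)[rowSums(m) == 0]
  if (length(zero))
    stopf("all-zero sample(s): %s", paste(head(zero, 5), collapse = ", "))
  as.matrix(vegan::vegdist(m, method = "bray"))
}

#' Classical (metric) multidimensional scaling
#'
#' Torgerson scaling of the double-centred \eqn{-D^2/2} matrix; used as the
#' deterministic starting configuration for NMDS and as an alternative
#' ordination engine.  If fewer than \code{k} positive eigenvalues exist,
#' the dimensionality is reduced with a warning.
#'
#' @param D dissimilarity matrix (or \code{dist}).
#' @param k requested dimensions.
#' @return numeric matrix, samples x k' (k' <= k), centred.
#' @export
pcoaCoords <- function(D, k = 2) {
  n <- attr(as.dist(D), "Size")
  if (k > n - 1) {  # classical scaling spans at most n - 1 axes
    warnf("k reduced from %d to %d (only %d samples)", k, n - 1, n)
    k <- n - 1
  }
  fit <- suppressWarnings(cmdscale(as.dist(D), k = k, eig = TRUE))
  pts <- fit$points
  if (ncol(pts) < k)
    warnf("only %d positive eigenvalue axes available; k reduced from %d",
          ncol(pts), k)
  pts
}

#' Least-squares monotone (isotonic) regression
#'
#' Pool-adjacent-violators fit of a non-decreasing step function, the inner
#' step of Kruskal stress computation.  Input must already be ordered by
#' dissimilarity rank; ties in the dissimilarities are handled by the
#' caller (Kruskal's primary approach: within a tie block the fitted values
#' are unconstrained relative to each other, achieved by pre-sorting the
#' block by configuration distance).
#'
#' @param x numeric vector ordered by dissimilarity rank.
#' @return fitted non-decreasing vector of the same length.
#' @export
isotonicFit <- function(x) {
  if (length(x) <= 1) return(as.numeric(x))
  isoreg(seq_along(x), x)$yf
}

#' Kruskal stress-1 of a configuration
#'
#' \eqn{\sqrt{\sum (d_{ij} - \hat d_{ij})^2 / \sum d_{ij}^2}} where
#' \eqn{\hat d} is the isotonic regression of the configuration distances on
#' the rank order of the dissimilarities (primary tie treatment).
#'
#' @param D dissimilarity matrix or \code{dist}.
#' @param conf coordinate matrix (samples x k).
#' @return stress-1 value.
#' @export
kruskalStress <- function(D, conf) {
  dv <- as.vector(as.dist(D))
  cv <- as.vector(dist(conf))
  ord <- order(dv, cv)
  fit <- isotonicFit(cv[ord])
  sqrt(sum((cv[ord] - fit)^2) / sum(cv^2))
}

#' Non-metric multidimensional scaling with restarts
#'
#' Minimises Kruskal stress-1 (via \code{vegan::monoMDS}, global model,
#' primary tie treatment) from a deterministic classical-scaling start plus
#' \code{nRestarts - 1} random starts, returning the lowest-stress
#' configuration, centred.  A warning is emitted when the best stress
#' exceeds 0.20, the conventional adequacy threshold.
#'
#' @param D dissimilarity matrix or \code{dist}.
#' @param k ordination dimensions (default 2).
#' @param nRestarts total number of starts including the classical-scaling
#'   start (default 20).
#' @param maxIter iteration cap per start (default 300).
#' @param tol relative stress-change convergence tolerance (default 1e-7).
#' @param seed integer seed for the random starts.
#' @return an \linkS4class{Ordination}.
#' @export
nmdsOrdination <- function(D, k = 2, nRestarts = 20, maxIter = 300,
                           tol = 1e-7, seed = 42) {
  Dd <- as.dist(D)
  n <- attr(Dd, "Size")
  if (k < 1) stopf("k must be >= 1")
  start <- pcoaCoords(D, k)
  if (ncol(start) < k)
    start <- cbind(start, matrix(0, n, k - ncol(start)))

  runOne <- function(y) {
    vegan::monoMDS(Dd, y = y, k = k, model = "global", threshold = 0.8,
                   maxit = maxIter, smin = 1e-8, sfgrmin = 1e-9,
                   sratmax = 1 - tol)
  }
  fits <- withSeed(seed, {
    out <- vector("list", nRestarts)
    out[[1]] <- runOne(start)
    if (nRestarts > 1) for (r in 2:nRestarts) {
      y0 <- matrix(rnorm(n * k), n, k)
      out[[r]] <- runOne(y0)
    }
    out
  })
  stresses <- vapply(fits, function(f) f$stress, numeric(1))
  best <- fits[[which.min(stresses)]]
  pts <- scale(best$points, center = TRUE, scale = FALSE)
  attr(pts, "scaled:center") <- NULL
  dimnames(pts) <- list(labels(Dd), paste0("NMDS", seq_len(k)))
  converged <- vapply(fits, function(f) isTRUE(f$icause %in% 2:4), logical(1))
  if (!any(converged))
    warnf("no NMDS restart converged; returning best of %d starts", nRestarts)
  if (min(stresses) > 0.20)
    warnf("NMDS stress %.3f exceeds 0.20; ordination may be inadequate",
          min(stresses))
  new("Ordination", coordinates = pts, stress = min(stresses),
      k = as.integer(k), converged = any(converged),
      restartsRun = as.integer(nRestarts), engine = "nmds")
}

#' Ordination accessors
#'
#' @param x an \linkS4class{Ordination}.
#' @param ... unused.
#' @return \code{scores}: the centred coordinate matrix;
#'   \code{stressValue}: the Kruskal stress-1 of the returned solution.
#' @name ordinationAccessors
NULL

#' @rdname ordinationAccessors
#' @export
setMethod("scores", "Ordination", function(x, ...) x@coordinates)

#' @rdname ordinationAccessors
#' @export
setMethod("stressValue", "Ordination", function(x) x@stress)

setMethod("show", "Ordination", function(object) {
  cat(sprintf("%s ordination: %d samples in %d dimensions, stress %.4g (%s, %d starts)\n",
              toupper(object@engine), nrow(object@coordinates), object@k,
              object@stress,
              if (object@converged) "converged" else "NOT converged",
              object@restartsRun))
})
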