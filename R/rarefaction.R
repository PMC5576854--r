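# Individual-based rarefaction and the per-unit diversity metrics.

#' Shannon entropy of a count vector
#'
#' \eqn{H' = -\sum p_i \log p_i} over the non-zero proportions, natural log.
#'
#' @param counts non-negative count (or abundance) vector with at least one
#'   positive entry.
#' @return Shannon entropy (nats).
#' @export
shannonIndex <- function(counts) {
  counts <- counts[counts > 0]
  if (!length(counts)) stopf("shannonIndex: all counts are zero")
  p <- counts / sum(counts)
  -sum(p * log(p))
}

#' Pielou evenness J
#'
#' \eqn{J = H'/\log S}, with S the number of taxa present.  Undefined (and
#' returned as \code{NA}) for single-taxon vectors, where \eqn{\log S = 0}.
#' Invariant to rescaling all counts by a common factor.
#'
#' @inheritParams shannonIndex
#' @return evenness in [0, 1], or \code{NA} when only one taxon is present.
#' @export
pielouEvenness <- function(counts) {
  s <- sum(counts > 0)
  if (s == 0) stopf("pielouEvenness: all counts are zero")
  if (s == 1) return(NA_real_)
  shannonIndex(counts) / log(s)
}

#' Analytic expected rarefied richness
#'
#' Hurlbert's exact expectation of the number of taxa in a random draw of
#' \code{depth} individuals without replacement:
#' \eqn{E[S] = \sum_i [1 - C(N - N_i, d)/C(N, d)]}.  Serves as the
#' closed-form oracle for the Monte-Carlo rarefaction.
#'
#' @inheritParams shannonIndex
#' @param depth number of individuals drawn; must not exceed the total.
#' @return expected richness (real).
#' @export
expectedRichness <- function(counts, depth) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (depth > n) stopf("depth (%d) exceeds total individuals (%d)", depth, n)
  sum(1 - exp(lchoose(n - counts, depth) - lchoose(n, depth)))
}

#' Monte-Carlo rarefied richness and evenness
#'
#' Repeatedly draws \code{depth} individuals without replacement from the
#' community (equivalently, a multivariate hypergeometric draw on the count
#' vector, generated species-by-species with vectorised conditional
#' hypergeometric sampling) and averages taxon richness and Pielou evenness
#' over the draws.  Draws yielding a single taxon have undefined evenness;
#' they are skipped from the evenness mean and counted.
#'
#' When \code{depth} equals the total the draw is exhaustive and the result
#' is deterministic.
#'
#' @inheritParams expectedRichness
#' @param iterations number of Monte-Carlo draws (default 1000).
#' @param seed integer seed for the draw stream; the caller's RNG state is
#'   left untouched.
#' @return list of class \code{"rarefiedStats"}: \code{mean_richness},
#'   \code{sd_richness} (across draws; 0 for the exhaustive case),
#'   \code{mean_evenness} (\code{NA} if every draw was skipped),
#'   \code{iterations_used}, \code{draws_skipped_evenness}, \code{depth}.
#' @export
rarefyStats <- function(counts, depth, iterations = 1000, seed = 1) {
  counts <- as.integer(counts[counts > 0])
  n <- sum(counts)
  if (depth > n)
    stopf("rarefyStats: depth (%d) exceeds total individuals (%d)", depth, n)
  if (depth == n) {
    out <- list(mean_richness = as.numeric(length(counts)),
                sd_richness = 0,
                mean_evenness = pielouEvenness(counts),
                iterations_used = 1L, draws_skipped_evenness =
                  if (length(counts) == 1) 1L else 0L,
                depth = as.integer(depth))
    class(out) <- "rarefiedStats"
    return(out)
  }
  draws <- withSeed(seed, {
    s <- length(counts)
    k <- matrix(0L, nrow = s, ncol = iterations)
    remainingDepth <- rep.int(as.integer(depth), iterations)
    remainingPool <- n
    for (i in seq_len(s)) {
      remainingPool <- remainingPool - counts[i]
      if (i == s) k[i, ] <- remainingDepth
      else {
        ki <- rhyper(iterations, m = counts[i], n = remainingPool,
                     k = remainingDepth)
        k[i, ] <- ki
        remainingDepth <- remainingDepth - ki
      }
    }
    k
  })
  rich <- colSums(draws > 0)
  p <- draws / depth
  hl <- p * log(p)
  hl[draws == 0] <- 0
  H <- -colSums(hl)
  J <- ifelse(rich >= 2, H / log(rich), NA_real_)
  skipped <- sum(is.na(J))
  out <- list(mean_richness = mean(rich),
              sd_richness = sd(rich),
              mean_evenness = if (skipped == iterations) NA_real_
                              else mean(J, na.rm = TRUE),
              iterations_used = as.integer(iterations),
              draws_skipped_evenness = as.integer(skipped),
              depth = as.integer(depth))
  class(out) <- "rarefiedStats"
  out
}

#' @export
print.rarefiedStats <- function(x, ...) {
  cat(sprintf(paste0("rarefied to %d individuals (%d iterations): ",
                     "richness %.3f, evenness %s (%d draws skipped)\n"),
              x$depth, x$iterations_used, x$mean_richness,
              ifelse(is.na(x$mean_evenness), "NA",
                     sprintf("%.4f", x$mean_evenness)),
              x$draws_skipped_evenness))
  invisible(x)
}

#' Proportion of individuals belonging to pollen generalists
#'
#' Generalist individuals divided by classifiable (generalist + specialist)
#' individuals.  Parasitic and unknown-diet taxa are excluded from both the
#' numerator and the denominator, since only non-parasitic bees carry a
#' pollen-diet classification.
#'
#' @param counts named count vector (names are taxon ids) or unnamed vector
#'   aligned with \code{traits} rows.
#' @param traits trait data.frame with \code{species_id} and \code{diet}
#'   (or a per-taxon diet vector aligned with \code{counts}).
#' @return list: \code{proportion} (NA when no classifiable individuals),
#'   \code{n_classifiable}.
#' @export
generalistProportion <- function(counts, traits) {
  diet <- if (is.data.frame(traits)) {
    if (is.null(names(counts)))
      stopf("counts must be named by taxon id when traits is a data.frame")
    miss <- setdiff(names(counts)[counts > 0], traits$species_id)
    if (length(miss))
      stopf("taxa without trait rows: %s", paste(head(miss, 5), collapse = ", "))
    traits$diet[match(names(counts), traits$species_id)]
  } else as.character(traits)
  gen <- sum(counts[diet == "generalist"])
  spc <- sum(counts[diet == "specialist"])
  denom <- gen + spc
  list(proportion = if (denom == 0) NA_real_ else gen / denom,
       n_classifiable = as.integer(denom))
}
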