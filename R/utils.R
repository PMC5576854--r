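# Internal helpers shared across modules.

# Deterministic 31-bit substream seed from a master seed and a unit key, so
# per-unit computations are reproducible regardless of evaluation order.
unitSeed <- function(seed, key) {
  h <- sum(utf8ToInt(as.character(key)) * seq_along(utf8ToInt(as.character(key))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647L)
}

# Run expr with a local RNG state: the caller's .Random.seed is untouched.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

cubeRoot <- function(x) sign(x) * abs(x)^(1 / 3)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Logit transform with boundary shrinkage
#'
#' Plain log-odds for interior proportions; exact 0 or 1 is first shrunk by
#' the empirical-logit adjustment \eqn{p' = (p(n-1) + 0.5)/n}, where n is the
#' number of individuals behind the proportion, so the transform is finite
#' while interior values are preserved exactly.  Strictly increasing on
#' (0, 1) and odd around 0.5.
#'
#' @param p proportion(s) in [0, 1]; \code{NA} passes through.
#' @param n number of individuals the proportion is based on (used only at
#'   the boundaries).
#' @return \code{log(p/(1-p))}, with shrinkage applied where \code{p} is
#'   exactly 0 or 1.
#' @examples
#' logitAdjusted(0.75, 20)          # log(3)
#' logitAdjusted(1, 20)             # log(0.975/0.025)
#' @export
logitAdjusted <- function(p, n) {
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  boundary <- !is.na(p) & (p == 0 | p == 1)
  p2 <- p
  nb <- rep_len(n, length(p))[boundary]
  p2[boundary] <- (p[boundary] * (nb - 1) + 0.5) / nb
  log(p2 / (1 - p2))
}
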