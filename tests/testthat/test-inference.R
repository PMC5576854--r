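test_that("Welch test matches hand-computed statistics", {
  w <- welchTest(c(1, 2, 3), c(2, 3, 4))
  # means 2 vs 3, both variances 1: t = -1/sqrt(2/3), df = 4
  expect_equal(w$t, -1 / sqrt(2 / 3), tolerance = 1e-10)
  expect_equal(w$df, 4, tolerance = 1e-10)

  ident <- welchTest(c(1, 2, 3), c(3, 1, 2))
  expect_equal(ident$t, 0)
  expect_equal(ident$p, 1)

  wr <- welchTest(c(2, 3, 4), c(1, 2, 3))
  expect_equal(wr$t, -w$t)
  expect_equal(wr$p, w$p)

  expect_error(welchTest(c(1, 1, 1), c(2, 2, 2)), "zero variance")
  expect_error(welchTest(1, c(1, 2)), "at least 2")
})

test_that("Welch equals the pooled t-test for balanced equal-variance groups", {
  set.seed(8)
  for (r in 1:10) {
    x <- rnorm(6); y <- rnorm(6)
    y <- (y - mean(y)) / sd(y) * sd(x) + mean(y)  # force s1 = s2
    w <- welchTest(x, y)
    cl <- t.test(x, y, var.equal = TRUE)
    expect_equal(w$t, unname(cl$statistic), tolerance = 1e-10)
    expect_equal(w$df, unname(cl$parameter), tolerance = 1e-10)
  }
})

test_that("Welch p-values are uniform under the null", {
  set.seed(19)
  p <- replicate(10000, {
    x <- rnorm(5); y <- rnorm(5)
    t.test(x, y)$p.value
  })
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_lt(unname(ks$statistic), 0.02)
})

test_that("orthogonal polynomial bases are orthonormal with a fixed sign", {
  b <- orthPoly(c(1, 2, 3), 1)
  expect_equal(unname(b[, 1]), c(-1, 0, 1) / sqrt(2))
  set.seed(23)
  x <- sample(100:250, 14)
  for (dg in 1:3) {
    b <- orthPoly(x, dg)
    expect_equal(colMeans(b), setNames(rep(0, dg), colnames(b)),
                 tolerance = 1e-12)
    expect_equal(crossprod(b), diag(dg), ignore_attr = TRUE,
                 tolerance = 1e-10)
  }
  # symmetric x: the quadratic column is even in the centred variable
  xs <- c(-2, -1, 0, 1, 2) + 150
  b2 <- orthPoly(xs, 2)
  expect_equal(b2[, 2], rev(b2[, 2]))
  expect_error(orthPoly(c(1, 1, 2), 2), "distinct")
})

test_that("regression fits are identical under raw and orthogonal bases", {
  set.seed(3)
  x <- sample(90:240, 20, replace = TRUE)
  x <- x[!duplicated(x)][1:12]
  y <- 0.5 + 0.01 * x - 2e-4 * x^2 + rnorm(12, 0, 0.1)
  f1 <- lm(y ~ orthPoly(x, 2))
  f2 <- lm(y ~ x + I(x^2))
  expect_equal(fitted(f1), fitted(f2), tolerance = 1e-10)
})

test_that("trend LMM reproduces the between-within df pattern", {
  set.seed(71)
  cfg <- scenarioPreset("paper_like_2011", seed = 71)
  res <- simToMatrix(cfg)
  a <- alphaTable(res$am, iterations = 40, seed = 5)
  # df structure only: a complete response over 72 samples, one row removed
  a$rarefied_richness <- rnorm(nrow(a), 10, 2)
  a <- a[-1, ]
  f <- fitTrendLmm(a, "rarefied_richness", degree = 1)
  tab <- anovaTable(f)
  expect_equal(tab$denDF[tab$term == ".trt"], 6)        # 8 plots - 2
  expect_equal(tab$denDF[tab$term == ".date1"], 61)     # 71 - 8 - 2
  expect_equal(tab$numDF[tab$term == ".trt"], 1)
  expect_true(all(f@varcor >= 0, na.rm = TRUE))
})

test_that("a boundary (zero) plot variance reproduces the OLS fixed effects", {
  set.seed(2)
  d <- expand.grid(plot_id = paste0("P", 1:8),
                   julian_date = seq(100, 220, 15), stringsAsFactors = FALSE)
  d$treatment <- ifelse(d$plot_id %in% paste0("P", 1:4), "reserve",
                        "fragment")
  y <- rnorm(nrow(d))
  pm <- tapply(y, d$plot_id, mean)
  d$rarefied_richness <- y - as.numeric(pm[as.character(d$plot_id)])
  f <- suppressWarnings(fitTrendLmm(d, "rarefied_richness", degree = 1))
  expect_lt(f@varcor[["plot"]], 1e-3 * f@varcor[["residual"]])
  pb <- orthPoly(d$julian_date, 1)
  ols <- lm(d$rarefied_richness ~
              factor(d$treatment, levels = c("reserve", "fragment")) * pb)
  expect_lt(max(abs(fixedEffects(f) - coef(ols))), 1e-6)
})

test_that("degree selection prefers the simplest equivalently supported model", {
  fakeFit <- function(aic, degree) {
    new("LmmFit", response = "r", degree = as.integer(degree),
        covariate = character(0), fitML = NULL, fitREML = NULL, aic = aic,
        anovaTable = data.frame(), fixef = c(x = 0),
        varcor = c(plot = 0, residual = 1), nObs = 10L, nPlots = 4L)
  }
  sel <- selectDegree(list(fakeFit(100.5, 1), fakeFit(100, 2),
                           fakeFit(99.9, 3)))
  expect_equal(degreeOf(sel), 1L)
  sel2 <- selectDegree(list(fakeFit(110, 1), fakeFit(100, 2),
                            fakeFit(101.5, 3)))
  expect_equal(degreeOf(sel2), 2L)

  bad <- list(fakeFit(100, 1), fakeFit(99, 2))
  bad[[2]]@nObs <- 9L
  expect_error(selectDegree(bad), "differing row sets")
})

test_that("AIC drops when the true generating term enters the model", {
  set.seed(55)
  d <- expand.grid(plot_id = paste0("P", 1:8),
                   julian_date = seq(100, 230, length.out = 9))
  d$plot_id <- as.character(d$plot_id)
  d$treatment <- ifelse(d$plot_id %in% paste0("P", 1:4), "reserve",
                        "fragment")
  z <- scale(d$julian_date)
  d$rarefied_richness <- 5 + 2 * z^2 + rnorm(nrow(d), 0, 0.5) +
    rnorm(8, 0, 0.3)[match(d$plot_id, paste0("P", 1:8))]
  f1 <- fitTrendLmm(d, "rarefied_richness", 1, reml = FALSE)
  f2 <- fitTrendLmm(d, "rarefied_richness", 2, reml = FALSE)
  expect_lt(aicValue(f2), aicValue(f1) - 2)
})

test_that("covariate regressions compare against the treatment-only AIC", {
  set.seed(33)
  d <- data.frame(treatment = rep(c("reserve", "fragment"), each = 5),
                  resp = rnorm(10), cov = rnorm(10))
  d$resp <- d$resp + ifelse(d$treatment == "fragment", -1, 0)
  out <- olsWithCovariate(d, "resp", "cov")
  expect_s3_class(out$fit, "lm")
  expect_type(out$delta_aic, "double")

  # a pure-noise covariate does not improve AIC on average
  deltas <- replicate(200, {
    dd <- data.frame(treatment = rep(c("reserve", "fragment"), each = 5),
                     resp = rnorm(10), cov = rnorm(10))
    olsWithCovariate(dd, "resp", "cov")$delta_aic
  })
  expect_gt(mean(deltas), 0)

  d$cz <- 1
  expect_error(olsWithCovariate(d, "resp", "cz"), "zero variance")
  d$dup <- d$resp
  expect_warning(olsWithCovariate(d, "resp", "dup"), "almost exactly")
})
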