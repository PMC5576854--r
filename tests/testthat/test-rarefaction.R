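test_that("Shannon entropy and Pielou evenness match closed forms", {
  expect_equal(shannonIndex(5), 0)
  expect_equal(shannonIndex(c(1, 1, 1, 1)), log(4))
  # -sum(p log p) for p = (1/4, 1/4, 1/2)
  expect_equal(shannonIndex(c(1, 1, 2)),
               -(0.25 * log(0.25) * 2 + 0.5 * log(0.5)))
  expect_error(shannonIndex(c(0, 0)), "all counts are zero")

  expect_equal(pielouEvenness(c(7, 7, 7)), 1)
  expect_true(is.na(pielouEvenness(10)))
  expect_equal(pielouEvenness(c(1, 1, 2)), shannonIndex(c(1, 1, 2)) / log(3))
})

test_that("Pielou evenness is invariant to count rescaling", {
  set.seed(41)
  for (i in 1:20) {
    v <- rpois(sample(3:12, 1), 4) + 1
    k <- sample(2:6, 1)
    expect_equal(pielouEvenness(v), pielouEvenness(k * v))
  }
})

test_that("analytic expected richness matches exact combinatorics", {
  # two species of 5: per species 1 - C(5,2)/C(10,2) = 35/45; total 14/9
  expect_equal(expectedRichness(c(5, 5), 2), 14 / 9)
  expect_equal(expectedRichness(c(3, 1), 1), 1)
  v <- c(4, 2, 9, 1)
  expect_equal(expectedRichness(v, sum(v)), 4)
  expect_error(expectedRichness(c(2, 2), 5), "exceeds total")
})

test_that("analytic expected richness agrees with vegan::rarefy", {
  set.seed(7)
  for (i in 1:10) {
    v <- rpois(15, 3) + c(rep(0, 12), 5, 9, 20)
    v <- v[v > 0]
    d <- sample(2:(sum(v) - 1), 1)
    expect_equal(expectedRichness(v, d), as.numeric(vegan::rarefy(v, d)),
                 ignore_attr = TRUE, tolerance = 1e-10)
  }
})

test_that("Monte-Carlo rarefaction matches the analytic oracle and is deterministic", {
  rs <- rarefyStats(c(5, 5), 2, iterations = 10000, seed = 3)
  se <- rs$sd_richness / sqrt(rs$iterations_used)
  expect_lt(abs(rs$mean_richness - 14 / 9), 3 * se)

  # exhaustive draw is deterministic
  ex <- rarefyStats(c(4, 6), 10, iterations = 500, seed = 1)
  expect_equal(ex$mean_richness, 2)
  expect_equal(ex$iterations_used, 1L)
  expect_equal(ex$mean_evenness, pielouEvenness(c(4, 6)))

  # same seed, same result; different seed differs
  a <- rarefyStats(c(9, 3, 1, 7), 8, 200, seed = 5)
  b <- rarefyStats(c(9, 3, 1, 7), 8, 200, seed = 5)
  cc <- rarefyStats(c(9, 3, 1, 7), 8, 200, seed = 6)
  expect_identical(a, b)
  expect_false(identical(a$mean_richness, cc$mean_richness))

  expect_error(rarefyStats(c(2, 2), 10), "exceeds total")
})

test_that("single-taxon draws are skipped from the evenness mean and counted", {
  rs <- rarefyStats(c(50, 1), 2, iterations = 400, seed = 2)
  expect_gt(rs$draws_skipped_evenness, 0)
  one <- rarefyStats(20, 5, iterations = 50, seed = 1)
  expect_true(is.na(one$mean_evenness))
  expect_equal(one$draws_skipped_evenness, 50L)
})

test_that("rarefied richness is monotone non-decreasing in depth (analytic)", {
  set.seed(13)
  for (i in 1:10) {
    v <- rpois(10, 2) + 1
    depths <- sort(sample(1:sum(v), 5))
    er <- vapply(depths, function(d) expectedRichness(v, d), numeric(1))
    expect_true(all(diff(er) >= -1e-12))
  }
})

test_that("generalist proportion excludes parasitic and unknown diets", {
  tr <- data.frame(species_id = c("g", "s", "p"),
                   diet = c("generalist", "specialist", "parasitic"),
                   native = TRUE, genus = "G", stringsAsFactors = FALSE)
  expect_equal(generalistProportion(c(g = 5, s = 0, p = 0), tr)$proportion, 1)
  expect_equal(generalistProportion(c(g = 3, s = 1, p = 0), tr)$proportion,
               0.75)
  expect_equal(generalistProportion(c(g = 3, s = 1, p = 6), tr)$proportion,
               0.75)
  only_p <- generalistProportion(c(g = 0, s = 0, p = 4), tr)
  expect_true(is.na(only_p$proportion))
  expect_equal(only_p$n_classifiable, 0L)
})

test_that("logit transform matches closed forms and is increasing and odd", {
  expect_equal(logitAdjusted(0.5, 20), 0)
  expect_equal(logitAdjusted(0.75, 20), log(3))
  expect_equal(logitAdjusted(1, 20), log(0.975 / 0.025))
  expect_equal(logitAdjusted(0, 20), -logitAdjusted(1, 20))
  p <- seq(0.01, 0.99, 0.01)
  expect_true(all(diff(logitAdjusted(p, 50)) > 0))
  expect_equal(logitAdjusted(p, 50), -logitAdjusted(1 - p, 50))
})

test_that("gamma table uses the yearly minimum pooled abundance as depth", {
  res <- simToMatrix(scenarioPreset("paper_like_2011", seed = 21))
  g <- gammaTable(res$am, iterations = 50, seed = 1)
  pooled <- poolByPlot(res$am)
  expect_equal(attr(g, "depth"), min(colSums(counts(pooled))))
  expect_equal(nrow(g), 8)
  expect_true(all(is.na(g$exclusion_reason)))

  # explicit override beyond some plots' totals flags them
  g2 <- gammaTable(res$am, depth = max(colSums(counts(pooled))) + 1,
                   iterations = 10, seed = 1)
  expect_true(all(g2$exclusion_reason == "below_depth"))
  expect_true(all(is.na(g2$rarefied_richness)))

  # repeated call with the same seed is identical
  expect_identical(g, gammaTable(res$am, iterations = 50, seed = 1))
})

test_that("gamma rarefied richness tracks the analytic oracle per plot", {
  res <- simToMatrix(simConfig(nPlots = c(reserve = 2L, fragment = 1L),
                               nSamples = 4L, poolSize = 60L,
                               meanPerSample = 40, seed = 31))
  g <- gammaTable(res$am, iterations = 400, seed = 2)
  pooled <- poolByPlot(res$am)
  d <- attr(g, "depth")
  for (j in seq_len(ncol(counts(pooled)))) {
    an <- expectedRichness(counts(pooled)[, j], d)
    expect_lt(abs(g$rarefied_richness[j] - an), max(3 * 2 / sqrt(400), 0.3))
  }
})

test_that("alpha table keeps under-depth samples for abundance but flags metrics", {
  tr <- data.frame(species_id = paste0("s", 1:6), diet = "generalist",
                   native = TRUE, genus = "G", stringsAsFactors = FALSE)
  mkrec <- function(plot, trt, date, n) {
    sp <- paste0("s", 1:min(n, 6))
    cnt <- rep(n %/% length(sp), length(sp))
    cnt[1] <- cnt[1] + n - sum(cnt)
    data.frame(plot_id = plot, treatment = trt, year = 2012L,
               julian_date = date, method = "bowl", species_id = sp,
               count = cnt, id_level = "species", stringsAsFactors = FALSE)
  }
  recs <- rbind(mkrec("P1", "reserve", 100L, 25), mkrec("P1", "reserve", 130L, 19),
                mkrec("P2", "fragment", 100L, 40), mkrec("P2", "fragment", 130L, 20))
  am <- abundanceMatrix(recs, tr)
  a <- alphaTable(am, depth = 20, iterations = 50, seed = 9)
  expect_equal(nrow(a), 4)
  expect_equal(sum(a$exclusion_reason == "below_depth", na.rm = TRUE), 1)
  under <- a[!is.na(a$exclusion_reason), ]
  expect_true(is.na(under$rarefied_richness))
  expect_equal(under$abundance_transformed, 19^(1 / 3))
  # exactly at depth: exhaustive, deterministic richness = S
  at20 <- a[a$raw_abundance == 20 & is.na(a$exclusion_reason), ]
  expect_equal(at20$rarefied_richness, 6)
})

test_that("single-sample plots make gamma and alpha metrics coincide", {
  res <- simToMatrix(simConfig(nPlots = c(reserve = 2L, fragment = 2L),
                               nSamples = 1L, poolSize = 40L,
                               meanPerSample = 50, seed = 17))
  totals <- sampleTotals(res$am)
  d <- min(totals)
  g <- gammaTable(res$am, iterations = 600, seed = 4)
  a <- alphaTable(res$am, depth = d, iterations = 600, seed = 4)
  expect_equal(g$raw_abundance, a$raw_abundance)
  expect_equal(g$generalist_prop_logit, a$generalist_prop_logit)
  expect_lt(max(abs(g$rarefied_richness - a$rarefied_richness)), 0.4)
})
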