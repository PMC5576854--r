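test_that("Bray-Curtis matches its formula on hand cases", {
  expect_equal(brayCurtis(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(brayCurtis(c(3, 0, 1), c(0, 4, 0)), 1)
  expect_equal(brayCurtis(c(1, 2, 0), c(0, 2, 4)), 5 / 9)
  expect_error(brayCurtis(c(0, 0), c(0, 0)), "all-zero")
  expect_error(brayCurtis(1:3, 1:4), "unequal")
})

test_that("Bray-Curtis is symmetric, bounded, and zero iff equal", {
  set.seed(91)
  for (i in 1:30) {
    x <- rpois(8, 2); y <- rpois(8, 2)
    if (sum(x) + sum(y) == 0) next
    b <- brayCurtis(x, y)
    expect_equal(b, brayCurtis(y, x))
    expect_gte(b, 0); expect_lte(b, 1)
    expect_equal(b == 0, all(x == y))
  }
})

test_that("dissimilarity matrices match the pairwise oracle and relabel cleanly", {
  m <- rbind(a = c(1, 2, 0, 1), b = c(0, 2, 4, 0),
             c = c(5, 0, 1, 1), d = c(1, 1, 1, 1))
  D <- dissimilarityMatrix(m)
  expect_equal(diag(D), setNames(rep(0, 4), rownames(m)))
  expect_equal(D, t(D))
  for (i in 1:4) for (j in 1:4)
    expect_equal(D[i, j], brayCurtis(m[i, ], m[j, ]))

  perm <- c(3, 1, 4, 2)
  expect_equal(unname(dissimilarityMatrix(m[perm, ])), unname(D[perm, perm]))

  ident <- rbind(x = c(1, 2), y = c(1, 2), z = c(1, 2))
  expect_true(all(dissimilarityMatrix(ident) == 0))

  expect_error(dissimilarityMatrix(m[1:2, ]), "at least 3")
  m0 <- m; m0[2, ] <- 0
  expect_error(dissimilarityMatrix(m0), "all-zero sample.*b")
})

test_that("classical scaling recovers collinear and equilateral geometries", {
  x <- c(0, 1, 3)
  D <- as.matrix(dist(x))
  p <- pcoaCoords(D, 1)
  expect_equal(unname(sort(abs(diff(sort(p[, 1]))))),
               sort(abs(diff(sort(x)))), tolerance = 1e-10)

  Deq <- matrix(1, 3, 3) - diag(3)
  ev <- cmdscale(as.dist(Deq), k = 2, eig = TRUE)$eig
  expect_equal(ev[1], ev[2], tolerance = 1e-10)
  peq <- pcoaCoords(Deq, 2)
  expect_equal(max(dist(peq)) / min(dist(peq)), 1, tolerance = 1e-8)

  D2 <- matrix(c(0, 2, 2, 0), 2, 2)
  p2 <- pcoaCoords(D2, 1)
  expect_equal(sort(p2[, 1]), c(-1, 1))
  expect_warning(pcoaCoords(D2, 2), "reduced")
})

test_that("isotonic regression agrees with the minimax closed form", {
  expect_equal(isotonicFit(c(1, 2, 3)), c(1, 2, 3))
  expect_equal(isotonicFit(c(1, 3, 2)), c(1, 2.5, 2.5))
  expect_equal(isotonicFit(rep(2, 4)), rep(2, 4))

  # oracle: yf[i] = max_{j<=i} min_{k>=i} mean(x[j..k])
  pavaOracle <- function(x) {
    n <- length(x)
    vapply(seq_len(n), function(i)
      max(vapply(1:i, function(j)
        min(vapply(i:n, function(k) mean(x[j:k]), numeric(1))),
        numeric(1))), numeric(1))
  }
  set.seed(5)
  for (r in 1:10) {
    x <- round(rnorm(7), 2)
    expect_equal(isotonicFit(x), pavaOracle(x), tolerance = 1e-10)
  }
})

test_that("kruskalStress agrees with the monoMDS stress of a fit", {
  set.seed(12)
  m <- matrix(rpois(60, 4), 10, 6)
  D <- dissimilarityMatrix(m)
  fit <- vegan::monoMDS(as.dist(D), k = 2)
  expect_equal(kruskalStress(D, fit$points), fit$stress, tolerance = 1e-4)
})

test_that("NMDS recovers exactly embeddable configurations", {
  set.seed(3)
  xy <- matrix(runif(20), 10, 2)
  D <- as.matrix(dist(xy))
  ord <- nmdsOrdination(D, k = 2, nRestarts = 4, seed = 8)
  expect_lt(stressValue(ord), 1e-3)
  expect_gt(cor(as.dist(D), dist(scores(ord)), method = "spearman"), 0.99)
  expect_true(ord@converged)
  expect_lt(max(abs(colMeans(scores(ord)))), 1e-8)

  # equilateral triangle: stress ~ 0, equal output distances
  Deq <- matrix(1, 3, 3) - diag(3)
  oe <- nmdsOrdination(Deq, k = 2, nRestarts = 3, seed = 2)
  expect_lt(stressValue(oe), 1e-6)
  dd <- dist(scores(oe))
  expect_lt(max(dd) - min(dd), 1e-4)
})

test_that("NMDS is deterministic given a seed and never worse than its start", {
  set.seed(14)
  m <- matrix(rpois(120, 3), 15, 8)
  D <- dissimilarityMatrix(m)
  o1 <- nmdsOrdination(D, k = 2, nRestarts = 5, seed = 31)
  o2 <- nmdsOrdination(D, k = 2, nRestarts = 5, seed = 31)
  expect_identical(scores(o1), scores(o2))
  expect_identical(stressValue(o1), stressValue(o2))
  expect_lte(stressValue(o1), kruskalStress(D, pcoaCoords(D, 2)) + 1e-12)
})

test_that("NMDS preserves distance ranks for low-dimensional structure", {
  set.seed(44)
  for (r in 1:3) {
    xy <- matrix(rnorm(24), 12, 2)
    D <- as.matrix(dist(xy))
    ord <- nmdsOrdination(D, k = 2, nRestarts = 4, seed = r)
    expect_gt(cor(as.dist(D), dist(scores(ord)), method = "spearman"), 0.99)
  }
})

test_that("dispersion scores are mean centroid distances with flags", {
  coords <- rbind(c(0, 0), c(2, 0), c(1, 1), c(1, 1), c(5, 5))
  res <- dispersionScores(coords, c("A", "A", "B", "B", "C"))
  tab <- dispersionTable(res)
  expect_equal(tab$dispersion[tab$plot_id == "A"], 1)
  expect_equal(tab$dispersion[tab$plot_id == "B"], 0)
  expect_true(is.na(tab$dispersion[tab$plot_id == "C"]))
  expect_equal(tab$exclusion_reason[tab$plot_id == "C"], "single_sample")
})

test_that("dispersion is invariant under rigid motions", {
  set.seed(6)
  coords <- matrix(rnorm(40), 20, 2)
  plots <- rep(c("A", "B", "C", "D"), 5)
  base <- dispersionTable(dispersionScores(coords, plots))$dispersion
  for (r in 1:5) {
    th <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    if (r %% 2) R[, 1] <- -R[, 1]  # include reflections
    moved <- coords %*% R + matrix(rnorm(2), 20, 2, byrow = TRUE)
    got <- dispersionTable(dispersionScores(moved, plots))$dispersion
    expect_lt(max(abs(got - base)), 1e-9)
  }
})

test_that("compositionally stable plots disperse less than turnover plots", {
  # paired synthetic: plot S repeats one assemblage; plot T rotates through
  # disjoint assemblages
  stable <- matrix(rep(c(5, 5, 5, 0, 0, 0, 0, 0, 0), 4), 4, byrow = TRUE)
  turn <- rbind(c(9, 1, 0, 0, 0, 0, 0, 0, 0),
                c(0, 0, 0, 8, 2, 0, 0, 0, 0),
                c(0, 0, 0, 0, 0, 9, 1, 0, 0),
                c(0, 0, 0, 0, 0, 0, 0, 5, 5))
  m <- rbind(stable + 1L, turn * 2L)  # +1 keeps stable rows slightly noisy-free nonzero
  rownames(m) <- paste0("s", 1:8)
  D <- dissimilarityMatrix(m)
  ord <- nmdsOrdination(D, k = 2, nRestarts = 5, seed = 4)
  tab <- dispersionTable(dispersionScores(ord, rep(c("S", "T"), each = 4)))
  expect_lt(tab$dispersion[tab$plot_id == "S"] + 1e-6,
            tab$dispersion[tab$plot_id == "T"])
})
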