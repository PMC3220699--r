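test_that("Spearman correlation matches its closed form and rank-then-Pearson oracle", {
  m <- rbind(a = c(1, 2, 3), b = c(3, 1, 2), c = c(1, 2, 3))
  rho <- spearmanMatrix(m)
  expect_equal(rho["a", "b"], -0.5, tolerance = 1e-12)  # 1 - 6*6/(3*8)
  expect_equal(rho["a", "c"], 1)
  expect_true(is.na(rho["a", "a"]))
  expect_identical(rho, t(rho))

  set.seed(42)
  x <- matrix(rnorm(80), 10, 8,
              dimnames = list(sprintf("p%02d", 1:10), NULL))
  rho <- spearmanMatrix(x)
  for (i in 1:9) for (j in (i + 1):10)
    expect_equal(rho[i, j], oracleSpearman(x[i, ], x[j, ]),
                 tolerance = 1e-12)
  expect_true(all(rho >= -1 - 1e-12 & rho <= 1 + 1e-12, na.rm = TRUE))
})

test_that("constant profile rows get rho 0 with a warning", {
  m <- rbind(a = c(5, 5, 5, 5), b = c(1, 2, 3, 4), c = c(4, 3, 2, 1))
  expect_warning(rho <- spearmanMatrix(m), "constant")
  expect_equal(unname(rho["a", c("b", "c")]), c(0, 0))
  expect_equal(rho["b", "c"], -1)
})

test_that("top-k correlate graph equals the sort-and-slice oracle", {
  set.seed(7)
  x <- matrix(rnorm(20 * 12), 20, 12,
              dimnames = list(sprintf("n%02d", 1:20), NULL))
  rho <- suppressWarnings(spearmanMatrix(x))
  g <- topCorrelates(rho, k = 5)
  el <- igraph::as_edgelist(g, names = FALSE)
  got <- sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])))
  expect_identical(got, oracleTopkEdges(rho, 5))
  expect_true(all(igraph::E(g)$rho > 0))

  # intersection mode is a subset of union mode
  gi <- topCorrelates(rho, k = 5, mode = "intersection")
  expect_lte(igraph::ecount(gi), igraph::ecount(g))
})

test_that("fewer than k positive correlates are all kept; none leaves an isolated node", {
  rho <- matrix(c(NA, 0.9, -0.2, -0.5,
                  0.9, NA, 0.1, -0.1,
                  -0.2, 0.1, NA, -0.3,
                  -0.5, -0.1, -0.3, NA), 4, 4,
                dimnames = list(letters[1:4], letters[1:4]))
  g <- topCorrelates(rho, k = 50)
  expect_equal(igraph::degree(g)[["a"]], 1L)   # only b is positive for a
  expect_true(igraph::V(g)$isolated[4])        # d: all rho <= 0
  expect_equal(igraph::degree(g)[["d"]], 0L)
})

test_that("embedding is deterministic, separates planted cliques and keeps twins together", {
  sim <- simulateProfileMatrix(profileSimSpec(
    40, 24, 2, c(20, 20), presenceProbIn = 1, presenceProbOut = 0,
    noiseFlipProb = 0, seed = 2))
  rho <- spearmanMatrix(sim$matrix)
  g <- topCorrelates(rho, k = 50)
  co1 <- embedMap(g, seed = 5)
  co2 <- embedMap(g, seed = 5)
  expect_identical(co1, co2)

  d <- as.matrix(dist(co1))
  same <- outer(sim$labels, sim$labels, "==")
  diag(same) <- NA
  expect_lt(mean(d[same & upper.tri(d)]), mean(d[!same & upper.tri(d)]))

  # members of one zero-noise module are exact profile twins up to scores;
  # construct true twins from the adjacency instead
  rho2 <- matrix(0.05, 6, 6, dimnames = list(letters[1:6], letters[1:6]))
  rho2[1, 3:6] <- rho2[3:6, 1] <- 0.8  # t1 = node 1
  rho2[2, 3:6] <- rho2[3:6, 2] <- 0.8  # t2 = node 2, same neighbors/rho
  rho2[1, 2] <- rho2[2, 1] <- -1       # twins not linked to each other
  diag(rho2) <- NA
  gt <- topCorrelates(rho2, k = 3)
  ct <- embedMap(gt, seed = 1)
  expect_lt(sqrt(sum((ct["a", ] - ct["b", ])^2)), 1e-6)
})

test_that("mountain detection recovers zero-noise plantings exactly", {
  sim <- simulateProfileMatrix(profileSimSpec(
    45, 30, 3, c(15, 15, 15), presenceProbIn = 1, presenceProbOut = 0,
    noiseFlipProb = 0, seed = 4))
  mp <- phylogenomicMap(sim$matrix, k = 50, seed = 4)
  expect_equal(nrow(mountainSummary(mp)), 3L)
  expect_equal(adjustedRand(mountainId(mp), sim$labels), 1)
  expect_true(all(mountainSummary(mp)$members == 15))
  # labels ordered by descending member count
  expect_true(!is.unsorted(-mountainSummary(mp)$members))
})

test_that("a single tight cluster forms one mountain; a strict floor forms none", {
  set.seed(3)
  co <- cbind(rnorm(30, sd = 0.05), rnorm(30, sd = 0.05))
  rownames(co) <- sprintf("p%02d", 1:30)
  mp <- detectMountains(co)
  expect_equal(nrow(mountainSummary(mp)), 1L)
  expect_true(all(mountainId(mp) == 1L))

  set.seed(8)
  un <- cbind(runif(40), runif(40))
  rownames(un) <- sprintf("u%02d", 1:40)
  expect_warning(mp0 <- detectMountains(un, densityFloor = 1e9), "floor")
  expect_equal(nrow(mountainSummary(mp0)), 0L)
  expect_true(all(mountainId(mp0) == 0L))
})

test_that("permuting protein input order permutes labels identically", {
  sim <- simulateProfileMatrix(profileSimSpec(
    45, 30, 3, c(15, 15, 15), noiseFlipProb = 0.03, seed = 6))
  pm <- sim$matrix
  mp1 <- phylogenomicMap(pm, seed = 6)

  set.seed(99)
  perm <- sample(nrow(profileScores(pm)))
  pm2 <- new("ProfileMatrix", scores = profileScores(pm)[perm, ],
             params = filterParams(pm))
  mp2 <- phylogenomicMap(pm2, seed = 6)

  ids1 <- mountainId(mp1)
  names(ids1) <- rownames(mapCoords(mp1))
  ids2 <- mountainId(mp2)
  names(ids2) <- rownames(mapCoords(mp2))
  common <- names(ids1)
  expect_equal(adjustedRand(ids1[common], ids2[common]), 1)
})

test_that("adjusted Rand agrees with an independent implementation", {
  set.seed(10)
  for (i in 1:20) {
    a <- sample(1:4, 50, replace = TRUE)
    b <- sample(1:5, 50, replace = TRUE)
    expect_equal(adjustedRand(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
  expect_equal(adjustedRand(1:10, 1:10), 1)
})
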