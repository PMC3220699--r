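test_that("hypergeometric upper tail matches direct enumeration", {
  # N=10, K=5, n=5, k=5 -> C(5,5)C(5,0)/C(10,5) = 1/252
  expect_equal(hypergeomUpperTail(5, 5, 5, 10), 1 / 252, tolerance = 1e-12)
  set.seed(1)
  for (rep in 1:60) {
    N <- sample(5:200, 1)
    K <- sample(1:(N - 1), 1)
    n <- sample(1:(N - 1), 1)
    k <- sample(0:min(n, K), 1)
    expect_equal(hypergeomUpperTail(k, K, n, N),
                 oracleHyperUpper(k, K, n, N), tolerance = 1e-12)
  }
})

test_that("upper-tail p never increases with larger overlap at fixed margins", {
  for (k in 1:9)
    expect_gte(hypergeomUpperTail(k, 10, 10, 40),
               hypergeomUpperTail(k + 1, 10, 10, 40))
})

test_that("two-sided Fisher matches full enumeration and labels direction", {
  ft <- fisherExact2x2(matrix(c(3, 1, 1, 3), 2, byrow = TRUE))
  expect_equal(ft$p, 34 / 70, tolerance = 1e-12)
  expect_equal(ft$direction, "Over")  # OR = 9

  set.seed(2)
  for (rep in 1:80) {
    N <- sample(4:60, 1)
    parts <- sort(sample(0:N, 3, replace = TRUE))
    tab <- matrix(c(parts[1], parts[2] - parts[1],
                    parts[3] - parts[2], N - parts[3]), 2, byrow = TRUE)
    ft <- fisherExact2x2(tab)
    if (!ft$degenerate)
      expect_equal(ft$p, oracleFisher2x2(tab), tolerance = 1e-12)
  }

  under <- fisherExact2x2(matrix(c(1, 3, 3, 1), 2, byrow = TRUE))
  expect_equal(under$direction, "Under")
})

test_that("zero-margin tables are degenerate with p 1", {
  ft <- fisherExact2x2(matrix(c(0, 5, 0, 7), 2, byrow = TRUE))
  expect_equal(ft$p, 1)
  expect_true(ft$degenerate)
  expect_true(is.na(ft$direction))
})

test_that("GO enrichment: mountain equal to background gives p 1 everywhere", {
  ann <- data.frame(gene_id = c("g1", "g2", "g3", "g1"),
                    term_id = c("T1", "T1", "T2", "T2"))
  bg <- c("g1", "g2", "g3")
  res <- goEnrichment(bg, bg, ann)
  expect_true(all(res$p == 1))
  expect_true(all(res$p_corrected == 1))
})

test_that("GO enrichment detects a planted term and enforces the background", {
  sim <- simulateAnnotations(annotationSimSpec(
    nGenes = 1000, enrichedSetSize = 20, enrichmentFactor = 5, seed = 3))
  res <- goEnrichment(sim$enrichedGenes, sim$genes, sim$annotations)
  top <- attr(res, "top")
  expect_equal(nrow(top), 3L)
  expect_equal(res$term_id[1], sim$enrichedCategory)
  expect_lt(res$p_corrected[1], 0.01)
  # corrected p is Bonferroni over tested terms
  expect_equal(res$p_corrected, pmin(1, res$p * nrow(res)))

  bad <- rbind(sim$annotations,
               data.frame(gene_id = "not_a_gene", category = "cat1"))
  expect_error(goEnrichment(sim$enrichedGenes, sim$genes, bad),
               "not_a_gene")
  expect_error(goEnrichment(c(sim$enrichedGenes, "ghost"), sim$genes,
                            sim$annotations), "ghost")
})

test_that("profile category tallies pool organisms per protein without deduplication", {
  sc <- matrix(0, 4, 6,
               dimnames = list(paste0("p", 1:4), paste0("g", 1:6)))
  sc[1, 1:3] <- 100   # p1 hits three host-associated genomes
  sc[2, 1:3] <- 100   # p2 the same three
  sc[3, c(4, 5)] <- 80
  # p4: empty profile row
  pm <- new("ProfileMatrix", scores = sc,
            params = list(minBitscore = 50, maxEvalue = 1e-5,
                          minGenomes = 1L))
  categories <- c(g1 = "host", g2 = "host", g3 = "host",
                  g4 = "free", g5 = "free", g6 = "free")
  tally <- profileCategoryCounts(c("p1", "p2"), pm, categories)
  expect_equal(tally[["host"]], 6L)    # 2 proteins x 3 organisms
  expect_equal(tally[["free"]], 0L)
  expect_equal(sum(profileCategoryCounts("p4", pm, categories)), 0L)

  # exhaustive hand count over the full toy matrix
  full <- profileCategoryCounts(paste0("p", 1:4), pm, categories)
  expect_equal(unname(full[c("host", "free")]), c(6L, 2L))
  expect_error(profileCategoryCounts("p1", pm, categories[-1]), "g1")
})

test_that("Fisher category test builds a disjoint contingency against the background", {
  mtn <- c(host = 9L, free = 1L)
  genome <- c(host = 30L, free = 70L)
  res <- fisherCategoryTest(mtn, genome, "host")
  expect_equal(c(res$a, res$b, res$c, res$d), c(9, 1, 21, 69))
  expect_equal(res$direction, "Over")
  expect_equal(res$p,
               oracleFisher2x2(matrix(c(9, 1, 21, 69), 2, byrow = TRUE)),
               tolerance = 1e-12)
  # keeping the mountain inside the background is exposed as an option
  res2 <- fisherCategoryTest(mtn, genome, "host", subtractMountain = FALSE)
  expect_equal(c(res2$c, res2$d), c(30, 70))
})

test_that("per-mountain enrichment over a map has consistent margins", {
  sim <- simulateProfileMatrix(profileSimSpec(
    45, 30, 3, c(15, 15, 15), noiseFlipProb = 0.02, seed = 12))
  mp <- phylogenomicMap(sim$matrix, seed = 12)
  categories <- stats::setNames(
    rep(c("host", "free"), length.out = 30), genomeIds(sim$matrix))
  res <- mountainCategoryEnrichment(mp, sim$matrix, categories)
  expect_true(all(res$p > 0 & res$p <= 1))
  expect_true(all(c("host", "free") %in% res$category))
  # a + b equals the mountain's pooled profile count
  for (m in unique(res$mountain)) {
    prot <- rownames(mapCoords(mp))[mountainId(mp) == m]
    tot <- sum(profileCategoryCounts(prot, sim$matrix, categories))
    expect_true(all(res$a[res$mountain == m] +
                    res$b[res$mountain == m] == tot))
  }
})

test_that("measured detection rate matches exact analytic power at a weak plant", {
  # probability-calculus oracle: k ~ Bin(20, 5*bg) enriched carriers,
  # background carriers K2 ~ Bin(980, bg); detect iff upper-tail p < thr
  bg <- 0.1; pe <- min(1, bg * 5); thr <- 0.002
  power <- 0
  for (k in 0:20) {
    pk <- stats::dbinom(k, 20, pe)
    if (pk < 1e-12) next
    K2 <- 0:980
    pv <- stats::phyper(k - 1, k + K2, 1000 - (k + K2), 20,
                        lower.tail = FALSE)
    power <- power + pk * sum(stats::dbinom(K2, 980, bg) * (pv < thr))
  }
  nrep <- 200
  det <- 0
  for (i in seq_len(nrep)) {
    sim <- simulateAnnotations(annotationSimSpec(
      nGenes = 1000, backgroundFreq = bg, enrichedSetSize = 20,
      enrichmentFactor = 5, seed = 5000 + i))
    res <- goEnrichment(sim$enrichedGenes, sim$genes, sim$annotations,
                        correction = "none")
    p <- res$p[res$term_id == sim$enrichedCategory]
    if (length(p) && p < thr) det <- det + 1
  }
  expect_lt(abs(det / nrep - power), 3 * sqrt(power * (1 - power) / nrep))
})
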