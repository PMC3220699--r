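test_that("minLrap is alignment length over the shorter protein, capped at 1", {
  expect_equal(minLrap(60, 100, 80), 0.75)
  expect_equal(minLrap(90, 90, 90), 1)
  expect_warning(r <- minLrap(120, 100, 110), "capped")
  expect_equal(r, 1)
  expect_error(minLrap(10, 0, 50), ">= 1")
})

mkHit <- function(q, qg, s, sg, id, alen, qlen, slen, bit, e = 1e-30) {
  data.frame(query_id = q, subject_id = s, query_genome = qg,
             subject_genome = sg, identity_pct = id, align_len = alen,
             e_value = e, bit_score = bit, q_len = qlen, s_len = slen,
             stringsAsFactors = FALSE)
}

test_that("ortholog thresholds are inclusive exactly at the printed boundaries", {
  hits <- rbind(
    mkHit("a1", "gA", "b1", "gB", 29.9, 100, 100, 100, 200),  # identity fails
    mkHit("b1", "gB", "a1", "gA", 29.9, 100, 100, 100, 200),
    mkHit("a2", "gA", "b2", "gB", 30.0, 60, 100, 100, 210),   # minLrap = 0.6
    mkHit("b2", "gB", "a2", "gA", 30.0, 60, 100, 100, 210),
    mkHit("a3", "gA", "b3", "gB", 45.0, 59, 100, 100, 220),   # minLrap 0.59
    mkHit("b3", "gB", "a3", "gA", 45.0, 59, 100, 100, 220))
  ot <- callOrthologs(hits, universes = list(
    gA = c("a1", "a2", "a3"), gB = c("b1", "b2", "b3")))
  expect_equal(orthologPairs(ot)$gene_A, "a2")
  expect_equal(orthologPairs(ot)$minlrap, 0.6)
})

test_that("missing protein lengths are an error naming the hit", {
  h <- mkHit("a1", "gA", "b1", "gB", 50, 100, 100, 100, 200)
  h$q_len <- NA_integer_
  expect_error(callOrthologs(h, universes = list(gA = "a1", gB = "b1")),
               "a1->b1")
})

test_that("reciprocal best hits resolve planted duplications and match the oracle", {
  sim <- simulateHomologyHits(nCore = 12, nUnique = 4, nParalogs = 3,
                              seed = 2)
  ot <- callOrthologs(sim$hits, universes = sim$universes)
  got <- sort(paste(orthologPairs(ot)$gene_A, orthologPairs(ot)$gene_B))
  expect_identical(got, oracleRBH(sim$hits, 0.6, 30))
  # duplicates never enter the pair set: the best-scoring copy wins
  expect_false(any(grepl("_dup", got)))
  # with no paralogs, recall and precision against the planted truth are 1
  sim0 <- simulateHomologyHits(nCore = 15, nUnique = 3, nParalogs = 0,
                               seed = 5)
  ot0 <- callOrthologs(sim0$hits, universes = sim0$universes)
  got0 <- sort(paste(orthologPairs(ot0)$gene_A, orthologPairs(ot0)$gene_B))
  want0 <- sort(paste(sim0$truth$gene_A, sim0$truth$gene_B))
  expect_identical(got0, want0)
})

test_that("the pair set is independent of hit direction and row order", {
  sim <- simulateHomologyHits(nCore = 8, nUnique = 2, seed = 7)
  ot1 <- callOrthologs(sim$hits, universes = sim$universes)
  set.seed(1)
  shuffled <- sim$hits[sample(nrow(sim$hits)), ]
  ot2 <- callOrthologs(shuffled, universes = sim$universes)
  key <- function(ot) sort(paste(orthologPairs(ot)$gene_A,
                                 orthologPairs(ot)$gene_B))
  expect_identical(key(ot1), key(ot2))
})

test_that("raising either threshold never adds ortholog pairs", {
  sim <- simulateHomologyHits(nCore = 12, nUnique = 3, nParalogs = 2,
                              seed = 9)
  base <- callOrthologs(sim$hits, universes = sim$universes,
                        minMinlrap = 0.4, minIdentity = 25)
  nbase <- nrow(orthologPairs(base))
  for (ml in c(0.6, 0.9)) for (id in c(40, 70)) {
    ot <- callOrthologs(sim$hits, universes = sim$universes,
                        minMinlrap = ml, minIdentity = id)
    expect_lte(nrow(orthologPairs(ot)), nbase)
  }
})

test_that("Venn partition reproduces direct set arithmetic", {
  # A = {g1,g2,g3}; B has orthologs to g2,g3; C to g3; D none
  hits <- rbind(
    mkHit("g2", "A", "b2", "B", 80, 100, 100, 100, 300),
    mkHit("b2", "B", "g2", "A", 80, 100, 100, 100, 300),
    mkHit("g3", "A", "b3", "B", 80, 100, 100, 100, 300),
    mkHit("b3", "B", "g3", "A", 80, 100, 100, 100, 300),
    mkHit("g3", "A", "c3", "C", 80, 100, 100, 100, 300),
    mkHit("c3", "C", "g3", "A", 80, 100, 100, 100, 300))
  ot <- callOrthologs(hits, universes = list(
    A = c("g1", "g2", "g3"), B = c("b2", "b3"), C = "c3", D = "d9"))
  vp <- vennPartition(ot)
  va <- vp[vp$anchor == "A", ]
  expect_equal(va$n[va$region == "A"], 1L)        # g1 alone
  expect_equal(va$n[va$region == "A+B"], 1L)      # g2
  expect_equal(va$n[va$region == "A+B+C"], 1L)    # g3
  expect_false("A+B+C+D" %in% va$region)
  genes <- attr(vp, "genes")[["A"]]
  expect_equal(genes[["A+B+C"]], "g3")

  # per anchor, region counts always sum to the universe size
  for (anc in c("A", "B", "C", "D"))
    expect_equal(sum(vp$n[vp$anchor == anc]),
                 length(geneUniverse(ot, anc)))
})

test_that("an empty ortholog table leaves every gene species-unique", {
  hits <- mkHit("a1", "gA", "b1", "gB", 10, 10, 100, 100, 20)
  ot <- callOrthologs(hits, universes = list(gA = c("a1", "a2"),
                                             gB = "b1"))
  expect_equal(nrow(orthologPairs(ot)), 0L)
  vp <- vennPartition(ot)
  expect_true(all(vp$region %in% c("gA", "gB")))
  expect_equal(sum(vp$n), 3L)
})

test_that("Venn counts on random fixtures equal exhaustive presence-set enumeration", {
  sim <- simulateHomologyHits(
    genomes = c("w", "x", "y", "z"), nCore = 10,
    presence = list(c("w", "x"), c("w", "x"), c("y", "z"),
                    c("w", "x", "y")),
    nUnique = 6, seed = 13)
  ot <- callOrthologs(sim$hits, universes = sim$universes)
  vp <- vennPartition(ot)
  p <- orthologPairs(ot)
  for (anc in names(sim$universes)) {
    for (g in sim$universes[[anc]]) {
      partners <- c(p$genome_B[p$gene_A == g], p$genome_A[p$gene_B == g])
      region <- paste(sort(unique(c(anc, partners))), collapse = "+")
      lists <- attr(vp, "genes")[[anc]]
      expect_true(g %in% lists[[region]])
    }
  }
})

test_that("class extraction applies require/exclude presence rules", {
  sim <- simulateHomologyHits(
    genomes = c("xn", "xb", "pl", "pa", "ec", "st"), nCore = 5,
    presence = list(c("xn", "xb", "pl", "pa"),       # genus-shared class
                    c("xn", "xb", "pl", "pa"),
                    c("xn", "xb"),                   # Xenorhabdus-only
                    c("xn", "xb", "ec"),             # leaks into outgroup
                    c("xn", "pl")),
    nUnique = 2, seed = 21)
  ot <- callOrthologs(sim$hits, universes = sim$universes)

  xp <- classExtract(ot, "xn", require = c("xb", "pl", "pa"),
                     exclude = c("ec", "st"))
  expect_equal(sort(xp), c("fam006_xn", "fam007_xn"))
  xonly <- classExtract(ot, "xn", require = "xb",
                        exclude = c("pl", "pa", "ec", "st"))
  expect_equal(xonly, "fam008_xn")
  # empty exclude reduces to an intersection query (brute-force predicate)
  inter <- classExtract(ot, "xn", require = "xb")
  p <- orthologPairs(ot)
  brute <- vapply(geneUniverse(ot, "xn"), function(g) {
    partners <- c(p$genome_B[p$gene_A == g], p$genome_A[p$gene_B == g])
    "xb" %in% partners
  }, TRUE)
  expect_setequal(inter, names(brute)[brute])
  expect_error(classExtract(ot, "xn", require = "xb", exclude = "xb"),
               "overlap")
  expect_error(classExtract(ot, "xn", require = "nope"), "nope")
})
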