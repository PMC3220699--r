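# independent brute-force oracles, kept deliberately naive

# upper-tail hypergeometric by direct enumeration of binomial coefficients
oracleHyperUpper <- function(k, K, n, N) {
  hi <- min(n, K)
  if (k > hi) return(0)
  sum(vapply(k:hi, function(a)
    choose(K, a) * choose(N - K, n - a) / choose(N, n), 0))
}

# two-sided Fisher by full enumeration over the table's support
oracleFisher2x2 <- function(tab) {
  a <- tab[1, 1]; K <- tab[1, 1] + tab[2, 1]
  n <- tab[1, 1] + tab[1, 2]; N <- sum(tab)
  lo <- max(0, n + K - N); hi <- min(n, K)
  pr <- choose(K, lo:hi) * choose(N - K, n - (lo:hi)) / choose(N, n)
  min(1, sum(pr[pr <= pr[a - lo + 1] * (1 + 1e-7)]))
}

# Spearman as explicit rank transform followed by product-moment correlation
oracleSpearman <- function(x, y) {
  stats::cor(rank(x), rank(y), method = "pearson")
}

# exhaustive profile filter: best hit per (query, genome), strict
# thresholds, min-genome row rule
oracleProfileFilter <- function(hits, minBit, maxE, minGenomes) {
  prot <- unique(hits$query_id)
  gen <- unique(hits$subject_genome)
  m <- matrix(0, length(prot), length(gen), dimnames = list(prot, gen))
  for (p in prot) for (g in gen) {
    h <- hits[hits$query_id == p & hits$subject_genome == g, , drop = FALSE]
    if (!nrow(h)) next
    h <- h[order(-h$bit_score, h$e_value, h$subject_id), , drop = FALSE]
    if (h$bit_score[1] > minBit && h$e_value[1] < maxE)
      m[p, g] <- h$bit_score[1]
  }
  m[rowSums(m > 0) >= minGenomes, , drop = FALSE]
}

# per-node sort-and-slice top-k positive correlates, union-symmetrized
oracleTopkEdges <- function(rho, k) {
  ids <- rownames(rho)
  edges <- character()
  for (i in seq_len(nrow(rho))) {
    r <- rho[i, ]
    cand <- setdiff(which(!is.na(r) & r > 0), i)
    if (!length(cand)) next
    cand <- cand[order(-r[cand], ids[cand])][seq_len(min(k, length(cand)))]
    edges <- c(edges, paste(pmin(i, cand), pmax(i, cand)))
  }
  sort(unique(edges))
}

# exhaustive reciprocal-best-hit orthology with threshold filtering
oracleRBH <- function(hits, minMl, minId) {
  ml <- hits$align_len / pmin(hits$q_len, hits$s_len)
  ml <- pmin(ml, 1)
  h <- hits[ml >= minMl & hits$identity_pct >= minId &
            hits$query_genome != hits$subject_genome, , drop = FALSE]
  best <- function(q, tg) {
    hh <- h[h$query_id == q & h$subject_genome == tg, , drop = FALSE]
    if (!nrow(hh)) return(NA_character_)
    hh <- hh[order(-hh$bit_score, hh$e_value, hh$subject_id), , drop = FALSE]
    hh$subject_id[1]
  }
  out <- character()
  for (i in seq_len(nrow(h))) {
    q <- h$query_id[i]; s <- h$subject_id[i]
    qg <- h$query_genome[i]; sg <- h$subject_genome[i]
    if (identical(best(q, sg), s) && identical(best(s, qg), q)) {
      key <- if (qg < sg) paste(q, s) else paste(s, q)
      out <- c(out, key)
    }
  }
  sort(unique(out))
}

# write a 12-column tabular hit file
writeHitsFile <- function(hits, path) {
  df <- data.frame(hits$query_id, hits$subject_id, hits$identity_pct,
                   hits$align_len, 0L, 0L, 1L, hits$align_len, 1L,
                   hits$align_len, hits$e_value, hits$bit_score)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  path
}

# small random hit table over nP proteins x nG genomes
randomHits <- function(nP, nG, nHits, seed) {
  set.seed(seed)
  data.frame(
    query_id = sample(sprintf("p%02d", seq_len(nP)), nHits, replace = TRUE),
    subject_id = sprintf("s%03d", seq_len(nHits)),
    subject_genome = sample(sprintf("g%02d", seq_len(nG)), nHits,
                            replace = TRUE),
    identity_pct = round(runif(nHits, 20, 95), 1),
    align_len = sample(80:400, nHits, replace = TRUE),
    e_value = 10^runif(nHits, -40, -2),
    bit_score = round(runif(nHits, 30, 300), 1),
    stringsAsFactors = FALSE)
}
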