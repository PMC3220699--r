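#' Hypergeometric upper-tail probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the chance of drawing at
#' least `k` category members in a sample of `n` from a background of `N`
#' genes of which `K` carry the category.
#'
#' @param k observed category members in the sample.
#' @param K category members in the background.
#' @param n sample size.
#' @param N background size.
#' @return upper-tail probability in (0, 1].
#' @export
hypergeomUpperTail <- function(k, K, n, N) {
  stopifnot(N >= 1, K >= 0, K <= N, n >= 0, n <= N, k >= 0)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Exact two-sided p: the sum of hypergeometric probabilities of every
#' table with the same margins whose probability does not exceed the
#' observed table's (with a 1e-7 relative guard against floating-point
#' ties). The direction is labeled `Over` when the sample odds ratio
#' exceeds 1, `Under` when below. A table with a zero margin carries no
#' information: p = 1, direction `NA`, `degenerate = TRUE`.
#'
#' @param tab 2x2 integer matrix: rows = in-set / out-of-set, columns =
#'   in-category / not-in-category.
#' @return list with `p`, `oddsRatio` (sample ad/bc), `direction`
#'   (`"Over"`/`"Under"`/`NA`) and `degenerate`.
#' @export
fisherExact2x2 <- function(tab) {
  stopifnot(is.matrix(tab), all(dim(tab) == 2), all(tab >= 0))
  a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
  K <- a + cc   # category total
  n <- a + b    # set size
  N <- a + b + cc + d
  if (K == 0 || n == 0 || K == N || n == N)
    return(list(p = 1, oddsRatio = NA_real_, direction = NA_character_,
                degenerate = TRUE))
  support <- max(0, n + K - N):min(n, K)
  dens <- stats::dhyper(support, K, N - K, n)
  dObs <- stats::dhyper(a, K, N - K, n)
  p <- min(1, sum(dens[dens <= dObs * (1 + 1e-7)]))
  or <- (a * d) / (b * cc)
  direction <- if (is.nan(or) || or == 1) NA_character_
               else if (or > 1) "Over" else "Under"
  list(p = p, oddsRatio = or, direction = direction, degenerate = FALSE)
}

#' GO-term over-representation for a mountain
#'
#' Hypergeometric upper-tail test per term against the genome background,
#' with multiple-testing correction over the number of tested terms
#' (Bonferroni by default, the classical term-finder convention). Only
#' terms carried by at least one mountain gene are tested. Results are
#' sorted by corrected p; the top `topN` rows (the summary convention for
#' reporting a mountain) are attached as attribute `top`.
#'
#' @param mountainGenes character vector; must be a subset of
#'   `backgroundGenes`.
#' @param backgroundGenes the gene universe (typically all mapped genes of
#'   the genome).
#' @param annotations data.frame with columns `gene_id`, `term_id` (extra
#'   columns ignored). Every annotated gene must belong to the background.
#' @param correction `"bonferroni"` (default), `"BH"` or `"none"`.
#' @param topN rows to retain in the `top` attribute (default 3).
#' @return data.frame with `term_id`, `k`, `K`, `n`, `N`, `p`,
#'   `p_corrected`, sorted by corrected then raw p.
#' @export
goEnrichment <- function(mountainGenes, backgroundGenes, annotations,
                         correction = c("bonferroni", "BH", "none"),
                         topN = 3L) {
  correction <- match.arg(correction)
  if (!all(mountainGenes %in% backgroundGenes))
    stop("mountain genes missing from the background: ",
         paste(head(setdiff(mountainGenes, backgroundGenes), 5),
               collapse = ", "))
  names(annotations)[1:2] <- c("gene_id", "term_id")
  stray <- setdiff(annotations$gene_id, backgroundGenes)
  if (length(stray))
    stop("annotated genes absent from the background (annotation ",
         "inconsistency): ", paste(head(stray, 5), collapse = ", "))
  ann <- annotations[!duplicated(paste(annotations$gene_id,
                                       annotations$term_id)), ]
  N <- length(unique(backgroundGenes))
  n <- length(unique(mountainGenes))
  inMtn <- ann$gene_id %in% mountainGenes
  terms <- sort(unique(ann$term_id[inMtn]))
  if (!length(terms))
    return(structure(data.frame(term_id = character(), k = integer(),
                                K = integer(), n = integer(), N = integer(),
                                p = numeric(), p_corrected = numeric()),
                     top = NULL))
  Ktab <- table(factor(ann$term_id, levels = terms))
  ktab <- table(factor(ann$term_id[inMtn], levels = terms))
  res <- data.frame(term_id = terms,
                    k = as.integer(ktab), K = as.integer(Ktab),
                    n = n, N = N, stringsAsFactors = FALSE)
  res$p <- hypergeomUpperTail(res$k, res$K, n, N)
  res$p_corrected <- switch(correction,
    bonferroni = pmin(1, res$p * nrow(res)),
    BH = stats::p.adjust(res$p, method = "BH"),
    none = res$p)
  res <- res[order(res$p_corrected, res$p, res$term_id), ]
  rownames(res) <- NULL
  attr(res, "top") <- head(res, topN)
  res
}

#' Tally profile organisms of a mountain by category
#'
#' For each protein in the mountain, every genome with a positive profile
#' cell contributes one count to that genome's category. Counts are summed
#' over the mountain's proteins without deduplication: an organism seen in
#' the profiles of three proteins counts three times, pooling the per-gene
#' profiles the way the niche-enrichment contingency is built.
#'
#' @param proteins character vector of mountain protein ids.
#' @param pm a [ProfileMatrix-class].
#' @param categories named character vector mapping genome id to a category
#'   label (e.g. host-associated / not). Every genome column must have an
#'   entry.
#' @return named integer vector of per-category counts (all category
#'   levels, zeros included).
#' @export
profileCategoryCounts <- function(proteins, pm, categories) {
  sc <- profileScores(pm)
  missingProt <- setdiff(proteins, rownames(sc))
  if (length(missingProt))
    stop("proteins absent from the matrix: ",
         paste(head(missingProt, 5), collapse = ", "))
  missingOrg <- setdiff(colnames(sc), names(categories))
  if (length(missingOrg))
    stop("organisms missing category metadata: ",
         paste(head(missingOrg, 5), collapse = ", "))
  lev <- sort(unique(unname(categories)))
  hitsPerGenome <- colSums(sc[proteins, , drop = FALSE] > 0)
  counts <- tapply(hitsPerGenome, factor(categories[colnames(sc)],
                                         levels = lev), sum)
  counts[is.na(counts)] <- 0
  stats::setNames(as.integer(counts), lev)
}

#' Fisher category test for a mountain tally against the genome background
#'
#' Builds the 2x2 contingency (mountain vs background-minus-mountain by
#' category vs not) and applies the two-sided exact test. The background
#' tally is expected to include the mountain (totals over the whole
#' genome); the mountain's own counts are subtracted so the table is
#' disjoint, unless `subtractMountain = FALSE`.
#'
#' @param mountainTally named counts from [profileCategoryCounts()] for the
#'   mountain.
#' @param genomeTally same, for every protein on the map (the background).
#' @param category which category label to test.
#' @param subtractMountain keep the two table rows disjoint (default TRUE).
#' @return one-row data.frame: `category`, `a`, `b`, `c`, `d`,
#'   `odds_ratio`, `p`, `direction`, `degenerate`.
#' @export
fisherCategoryTest <- function(mountainTally, genomeTally, category,
                               subtractMountain = TRUE) {
  if (!category %in% names(mountainTally) ||
      !category %in% names(genomeTally))
    stop("category '", category, "' absent from the tallies")
  a <- mountainTally[[category]]
  b <- sum(mountainTally) - a
  bgIn <- genomeTally[[category]]
  bgOut <- sum(genomeTally) - bgIn
  if (subtractMountain) { bgIn <- bgIn - a; bgOut <- bgOut - b }
  if (bgIn < 0 || bgOut < 0)
    stop("mountain tally exceeds the background tally; the background ",
         "must cover the mountain")
  tab <- matrix(c(a, b, bgIn, bgOut), 2, byrow = TRUE)
  ft <- fisherExact2x2(tab)
  data.frame(category = category, a = a, b = b, c = bgIn, d = bgOut,
             odds_ratio = ft$oddsRatio, p = ft$p,
             direction = if (is.na(ft$direction)) NA_character_
                         else ft$direction,
             degenerate = ft$degenerate, stringsAsFactors = FALSE)
}

#' Per-mountain category enrichment over a whole map
#'
#' Runs [profileCategoryCounts()] and [fisherCategoryTest()] for every
#' mountain and every category level, against the tally of all proteins on
#' the map.
#'
#' @param map a [MountainMap-class].
#' @param pm the [ProfileMatrix-class] the map was built from.
#' @param categories named genome -> category vector.
#' @param subtractMountain see [fisherCategoryTest()].
#' @return data.frame with one row per (mountain, category):
#'   `mountain`, `n_genes`, plus the [fisherCategoryTest()] columns.
#' @export
mountainCategoryEnrichment <- function(map, pm, categories,
                                       subtractMountain = TRUE) {
  ids <- mountainId(map)
  prot <- rownames(mapCoords(map))
  genomeTally <- profileCategoryCounts(prot, pm, categories)
  out <- list()
  for (m in sort(unique(ids[ids > 0L]))) {
    mp <- prot[ids == m]
    tally <- profileCategoryCounts(mp, pm, categories)
    for (lev in names(tally)) {
      row <- fisherCategoryTest(tally, genomeTally, lev,
                                subtractMountain = subtractMountain)
      out[[length(out) + 1L]] <- cbind(
        data.frame(mountain = m, n_genes = length(mp)), row)
    }
  }
  if (!length(out))
    return(data.frame(mountain = integer(), n_genes = integer(),
                      category = character(), a = integer(), b = integer(),
                      c = integer(), d = integer(), odds_ratio = numeric(),
                      p = numeric(), direction = character(),
                      degenerate = logical()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
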