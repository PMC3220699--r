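#' minLrap: alignment length over the shorter protein
#'
#' The homology-calling length ratio: alignment length divided by the
#' length of the shorter of the two proteins, capped at 1 (overhanging
#' alignments can nominally exceed the shorter sequence).
#'
#' @param alignLen alignment length in columns.
#' @param qLen,sLen query and subject protein lengths in residues.
#' @return fraction in (0, 1].
#' @export
minLrap <- function(alignLen, qLen, sLen) {
  if (any(qLen < 1) || any(sLen < 1) || any(alignLen < 1))
    stop("lengths must be >= 1")
  r <- alignLen / pmin(qLen, sLen)
  if (any(r > 1)) {
    warning(sum(r > 1), " minLrap value(s) above 1 capped ",
            "(alignment longer than the shorter protein)")
    r <- pmin(r, 1)
  }
  r
}

#' Call orthologs as thresholded reciprocal best hits
#'
#' Filters cross-genome hits by minLrap (inclusive, default >= 0.6) and
#' percent identity (inclusive, default >= 30), then keeps, within each
#' genome pair, reciprocal best hits by bit score (ties: lower e-value,
#' then lexicographically smaller subject id).
#'
#' @param hits data.frame with `query_id`, `subject_id`, `query_genome`,
#'   `subject_genome`, `identity_pct`, `align_len`, `e_value`, `bit_score`,
#'   `q_len`, `s_len` (lengths may instead be supplied via `lengths`).
#' @param universes named list: genome id -> full gene-id vector. When
#'   NULL, inferred from the hit table's query ids (incomplete: genes with
#'   no hits are invisible; a warning is issued).
#' @param minMinlrap inclusive minLrap threshold (default 0.6).
#' @param minIdentity inclusive percent-identity threshold (default 30).
#' @param lengths optional named integer vector gene id -> protein length,
#'   used to fill missing `q_len`/`s_len`.
#' @return an [OrthologTable-class].
#' @export
callOrthologs <- function(hits, universes = NULL, minMinlrap = 0.6,
                          minIdentity = 30, lengths = NULL) {
  stopifnot(minMinlrap > 0, minMinlrap <= 1,
            minIdentity > 0, minIdentity <= 100)
  req <- c("query_id", "subject_id", "query_genome", "subject_genome",
           "identity_pct", "align_len", "e_value", "bit_score")
  if (!all(req %in% names(hits)))
    stop("hits must have columns: ", paste(req, collapse = ", "))
  if (!is.null(lengths)) {
    if (!"q_len" %in% names(hits)) hits$q_len <- NA_integer_
    if (!"s_len" %in% names(hits)) hits$s_len <- NA_integer_
    hits$q_len[is.na(hits$q_len)] <- lengths[hits$query_id[is.na(hits$q_len)]]
    hits$s_len[is.na(hits$s_len)] <- lengths[hits$subject_id[is.na(hits$s_len)]]
  }
  if (!all(c("q_len", "s_len") %in% names(hits)) ||
      anyNA(hits$q_len) || anyNA(hits$s_len)) {
    bad <- if (all(c("q_len", "s_len") %in% names(hits)))
      which(is.na(hits$q_len) | is.na(hits$s_len)) else seq_len(nrow(hits))
    stop("protein lengths missing for hit(s): ",
         paste(head(paste(hits$query_id[bad], hits$subject_id[bad],
                          sep = "->"), 5), collapse = ", "))
  }

  hits <- hits[hits$query_genome != hits$subject_genome, , drop = FALSE]
  if (is.null(universes)) {
    warning("no gene universes supplied; inferring from hit queries ",
            "(genes without hits will be missing)")
    universes <- split(hits$query_id, hits$query_genome)
    universes <- lapply(universes, function(x) sort(unique(x)))
  }

  ml <- minLrap(hits$align_len, hits$q_len, hits$s_len)
  keep <- ml >= minMinlrap & hits$identity_pct >= minIdentity
  h <- hits[keep, , drop = FALSE]
  h$minlrap <- ml[keep]

  pairs <- NULL
  if (nrow(h)) {
    # best hit per (query, target genome)
    ord <- order(h$query_id, h$subject_genome, -h$bit_score, h$e_value,
                 h$subject_id)
    h <- h[ord, , drop = FALSE]
    best <- h[!duplicated(paste(h$query_id, h$subject_genome,
                                sep = "\r")), , drop = FALSE]
    fwdKey <- paste(best$query_genome, best$query_id,
                    best$subject_genome, sep = "\r")
    bestOf <- stats::setNames(best$subject_id, fwdKey)
    # reciprocal: best(q -> gB) == s and best(s -> gA) == q
    backKey <- paste(best$subject_genome, best$subject_id,
                     best$query_genome, sep = "\r")
    recip <- !is.na(bestOf[backKey]) & bestOf[backKey] == best$query_id
    rb <- best[recip, , drop = FALSE]
    # store each pair once with genome_A < genome_B
    flip <- rb$query_genome > rb$subject_genome
    pairs <- data.frame(
      gene_A = ifelse(flip, rb$subject_id, rb$query_id),
      genome_A = ifelse(flip, rb$subject_genome, rb$query_genome),
      gene_B = ifelse(flip, rb$query_id, rb$subject_id),
      genome_B = ifelse(flip, rb$query_genome, rb$subject_genome),
      identity_pct = rb$identity_pct, minlrap = rb$minlrap,
      bit_score = rb$bit_score, stringsAsFactors = FALSE)
    dupKey <- paste(pairs$gene_A, pairs$gene_B, sep = "\r")
    agg <- !duplicated(dupKey)
    pairs <- pairs[agg, , drop = FALSE]
    pairs <- pairs[order(pairs$genome_A, pairs$genome_B, pairs$gene_A), ,
                   drop = FALSE]
    rownames(pairs) <- NULL
  }
  if (is.null(pairs))
    pairs <- data.frame(gene_A = character(), genome_A = character(),
                        gene_B = character(), genome_B = character(),
                        identity_pct = numeric(), minlrap = numeric(),
                        bit_score = numeric(), stringsAsFactors = FALSE)
  new("OrthologTable", pairs = pairs, universes = universes,
      params = list(minMinlrap = minMinlrap, minIdentity = minIdentity))
}

# presence set per gene of an anchor genome: the anchor genome plus every
# genome holding an ortholog pair with the gene
.presenceSets <- function(ot, anchor) {
  genes <- geneUniverse(ot, anchor)
  p <- orthologPairs(ot)
  sets <- stats::setNames(lapply(genes, function(g) anchor), genes)
  add <- function(gene, genome) {
    if (gene %in% genes) sets[[gene]] <<- union(sets[[gene]], genome)
  }
  pa <- p[p$genome_A == anchor, , drop = FALSE]
  pb <- p[p$genome_B == anchor, , drop = FALSE]
  for (i in seq_len(nrow(pa))) add(pa$gene_A[i], pa$genome_B[i])
  for (i in seq_len(nrow(pb))) add(pb$gene_B[i], pb$genome_A[i])
  sets
}

#' Venn partition of ortholog presence over n genomes
#'
#' For each anchor genome, every gene is assigned to the region named by
#' its presence set: the anchor genome plus all genomes with an ortholog
#' pair to the gene. With n genomes each anchor's genes fall into the
#' 2^(n-1) regions containing that anchor, so per anchor the region counts
#' sum to the anchor's universe size. Counting is per anchor genome (the
#' counts for a shared region, e.g. the 4-genome core, are reported once
#' per anchor and need not coincide when orthology is not one-to-one).
#'
#' @param ot an [OrthologTable-class].
#' @param genomes genomes to include (default: all in the universe).
#' @return data.frame with `anchor`, `region` (genome ids joined by `+`,
#'   sorted), `n`; attribute `genes` holds the per-anchor, per-region gene
#'   lists.
#' @export
vennPartition <- function(ot, genomes = NULL) {
  if (is.null(genomes)) genomes <- sort(names(geneUniverse(ot)))
  out <- list(); geneLists <- list()
  for (anchor in genomes) {
    sets <- .presenceSets(ot, anchor)
    sets <- lapply(sets, function(s) sort(intersect(s, genomes)))
    region <- vapply(sets, paste, "", collapse = "+")
    tab <- table(region)
    out[[anchor]] <- data.frame(anchor = anchor,
                                region = names(tab),
                                n = as.integer(tab),
                                stringsAsFactors = FALSE)
    geneLists[[anchor]] <- split(names(sets), region)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "genes") <- geneLists
  res
}

#' Extract a gene class by required and excluded ortholog presence
#'
#' Returns the anchor genome's genes that have an ortholog in *every*
#' required genome and in *none* of the excluded genomes — the rule behind
#' genus-specific gene classes (e.g. genes shared by the mutualist genera
#' but absent from the enteric outgroups).
#'
#' @param ot an [OrthologTable-class].
#' @param anchor anchor genome id.
#' @param require genomes an ortholog must be present in.
#' @param exclude genomes an ortholog must be absent from.
#' @return character vector of anchor gene ids.
#' @export
classExtract <- function(ot, anchor, require = character(),
                         exclude = character()) {
  known <- names(geneUniverse(ot))
  unknown <- setdiff(c(anchor, require, exclude), known)
  if (length(unknown))
    stop("genomes not in the ortholog table: ",
         paste(unknown, collapse = ", "))
  if (length(intersect(require, exclude)))
    stop("require and exclude sets overlap: ",
         paste(intersect(require, exclude), collapse = ", "))
  sets <- .presenceSets(ot, anchor)
  keep <- vapply(sets, function(s)
    all(require %in% s) && !any(exclude %in% s), TRUE)
  sort(names(sets)[keep])
}
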