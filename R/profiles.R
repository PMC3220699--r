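#' Read 12-column tabular homology-search hits
#'
#' Parses the standard 12-column tab-separated output of an all-vs-all
#' protein search (query, subject, \% identity, alignment length,
#' mismatches, gap opens, q.start, q.end, s.start, s.end, e-value, bit
#' score) and resolves each subject to its source genome. Malformed lines
#' are rejected with their line numbers. Exact self-hits (query id equal to
#' subject id) are dropped, and when the query itself is present in the
#' genome map, all hits to the query's own genome are dropped as well: a
#' protein's profile describes its presence in *other* genomes, and
#' self-genome matches would dominate every row.
#'
#' @param path path to the tabular hits file (no header).
#' @param genomeMap named character vector or two-column data.frame
#'   (`subject_id`, `genome`) mapping protein ids to genome ids.
#' @param strict if TRUE (default), an unmappable subject id is an error
#'   listing the offending ids; otherwise such hits are skipped with a
#'   warning.
#' @param dropSelfGenome drop hits whose subject genome equals the query's
#'   genome (requires the query to be mappable; unmappable queries are left
#'   alone).
#' @return data.frame of hits with columns `query_id`, `subject_id`,
#'   `subject_genome`, `identity_pct`, `align_len`, `e_value`, `bit_score`
#'   (plus the remaining tabular columns).
#' @export
readSearchHits <- function(path, genomeMap, strict = TRUE,
                           dropSelfGenome = TRUE) {
  if (is.data.frame(genomeMap)) {
    gm <- stats::setNames(as.character(genomeMap[[2]]),
                          as.character(genomeMap[[1]]))
  } else gm <- genomeMap
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L)) {
    bad <- which(nf != 12L)
    stop("malformed hit lines (expected 12 tab-separated columns): line",
         if (length(bad) > 1) "s " else " ",
         paste(head(bad, 10), collapse = ", "),
         if (length(bad) > 10) " ..." else "")
  }
  m <- matrix(unlist(fields), ncol = 12L, byrow = TRUE)
  hits <- data.frame(
    query_id = m[, 1], subject_id = m[, 2],
    identity_pct = as.numeric(m[, 3]), align_len = as.integer(m[, 4]),
    mismatches = as.integer(m[, 5]), gap_opens = as.integer(m[, 6]),
    q_start = as.integer(m[, 7]), q_end = as.integer(m[, 8]),
    s_start = as.integer(m[, 9]), s_end = as.integer(m[, 10]),
    e_value = as.numeric(m[, 11]), bit_score = as.numeric(m[, 12]),
    stringsAsFactors = FALSE)
  if (anyNA(hits$e_value) || anyNA(hits$bit_score) ||
      anyNA(hits$identity_pct) || anyNA(hits$align_len)) {
    bad <- which(is.na(hits$e_value) | is.na(hits$bit_score) |
                 is.na(hits$identity_pct) | is.na(hits$align_len))
    stop("non-numeric fields on line",
         if (length(bad) > 1) "s " else " ",
         paste(head(bad, 10), collapse = ", "))
  }

  hits <- hits[hits$query_id != hits$subject_id, , drop = FALSE]

  sg <- unname(gm[hits$subject_id])
  if (anyNA(sg)) {
    missing <- sort(unique(hits$subject_id[is.na(sg)]))
    if (strict)
      stop("subject ids absent from genome map: ",
           paste(head(missing, 10), collapse = ", "),
           if (length(missing) > 10) " ..." else "")
    warning("skipping ", sum(is.na(sg)), " hits with unmapped subjects (",
            length(missing), " ids)")
    hits <- hits[!is.na(sg), , drop = FALSE]
    sg <- sg[!is.na(sg)]
  }
  hits$subject_genome <- sg

  if (dropSelfGenome) {
    qg <- unname(gm[hits$query_id])
    keep <- is.na(qg) | qg != hits$subject_genome
    hits <- hits[keep, , drop = FALSE]
  }
  rownames(hits) <- NULL
  hits
}

#' Reduce hits to the best hit per (query, subject genome)
#'
#' Each profile cell holds the bit score of the best hit to a protein in a
#' given genome: within each (query, genome) group the maximum bit score is
#' kept, ties broken by lower e-value, then lexicographically smaller
#' subject id.
#'
#' @param hits data.frame as returned by [readSearchHits()] (needs
#'   `query_id`, `subject_id`, `subject_genome`, `e_value`, `bit_score`).
#' @return the reduced hits data.frame, one row per (query, genome).
#' @export
bestHitPerGenome <- function(hits) {
  req <- c("query_id", "subject_id", "subject_genome", "e_value", "bit_score")
  if (!all(req %in% names(hits)))
    stop("hits must have columns: ", paste(req, collapse = ", "))
  if (!nrow(hits)) return(hits)
  ord <- order(hits$query_id, hits$subject_genome, -hits$bit_score,
               hits$e_value, hits$subject_id)
  h <- hits[ord, , drop = FALSE]
  keep <- !duplicated(paste(h$query_id, h$subject_genome, sep = "\r"))
  out <- h[keep, , drop = FALSE]
  # restore the input's first-appearance order of queries/genomes
  out <- out[order(match(out$query_id, hits$query_id),
                   match(out$subject_genome, hits$subject_genome)), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the thresholded phylogenetic-profile matrix
#'
#' Retains, per protein, the best-hit bit score in each genome where the
#' hit has bit score strictly greater than `minBitscore` and e-value
#' strictly less than `maxEvalue`; proteins qualifying in fewer than
#' `minGenomes` genomes are dropped entirely. Both inequalities are strict,
#' mirroring the ">50 bits, <1e-5" retention rule the profile method is
#' defined with. Row and column order follow first appearance in the input.
#'
#' @param hits data.frame of per-genome best hits (see
#'   [bestHitPerGenome()]; raw hits are reduced automatically).
#' @param minBitscore retention threshold, exclusive (default 50).
#' @param maxEvalue retention threshold, exclusive (default 1e-5).
#' @param minGenomes minimum qualifying genomes per retained protein
#'   (default 5).
#' @param genomes optional character vector fixing the genome (column)
#'   universe and order; defaults to genomes seen in `hits`.
#' @return a [ProfileMatrix-class].
#' @export
buildProfileMatrix <- function(hits, minBitscore = 50, maxEvalue = 1e-5,
                               minGenomes = 5L, genomes = NULL) {
  stopifnot(minBitscore >= 0, maxEvalue > 0, minGenomes >= 1)
  hits <- bestHitPerGenome(hits)
  ok <- hits$bit_score > minBitscore & hits$e_value < maxEvalue
  qual <- hits[ok, , drop = FALSE]

  prot <- unique(hits$query_id)
  if (is.null(genomes)) genomes <- unique(hits$subject_genome)
  nq <- table(factor(qual$query_id, levels = prot))
  prot <- prot[nq[prot] >= minGenomes]
  if (!length(prot))
    stop("no proteins retained: every profile has fewer than ",
         minGenomes, " qualifying genomes")
  qual <- qual[qual$query_id %in% prot, , drop = FALSE]

  scores <- matrix(0, length(prot), length(genomes),
                   dimnames = list(prot, genomes))
  scores[cbind(match(qual$query_id, prot),
               match(qual$subject_genome, genomes))] <- qual$bit_score
  new("ProfileMatrix", scores = scores,
      params = list(minBitscore = minBitscore, maxEvalue = maxEvalue,
                    minGenomes = as.integer(minGenomes)))
}

#' Re-express a ProfileMatrix as a best-hit table
#'
#' Inverse view of [buildProfileMatrix()]: each positive cell becomes one
#' hit row (with a nominal qualifying e-value). Useful for idempotence
#' checks and for feeding a stored matrix back through the pipeline.
#'
#' @param pm a [ProfileMatrix-class].
#' @return a hits data.frame.
#' @export
profileAsHits <- function(pm) {
  sc <- profileScores(pm)
  idx <- which(sc > 0, arr.ind = TRUE)
  data.frame(query_id = rownames(sc)[idx[, 1]],
             subject_id = paste0(colnames(sc)[idx[, 2]], ":best"),
             subject_genome = colnames(sc)[idx[, 2]],
             identity_pct = NA_real_, align_len = 1L,
             e_value = filterParams(pm)$maxEvalue / 10,
             bit_score = sc[idx], stringsAsFactors = FALSE)
}
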