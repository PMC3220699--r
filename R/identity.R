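#' Cut a genome into fixed-size fragments
#'
#' Consecutive non-overlapping windows (default 1,020 bp, the classical
#' fragment size for BLAST-based average nucleotide identity). The final
#' fragment, when shorter than the window, is retained and flagged.
#' Coordinates are 0-based half-open so fragments round-trip exactly.
#'
#' @param seq a [Biostrings::DNAString] or character sequence.
#' @param size window size in bp (default 1020).
#' @param genomeId label recorded on the result.
#' @return a [FragmentSet-class].
#' @export
fragmentGenome <- function(seq, size = 1020L, genomeId = "genome") {
  if (is.character(seq)) seq <- Biostrings::DNAString(seq)
  n <- length(seq)
  if (n < 1) stop("empty sequence")
  starts <- seq.int(1L, n, by = size)
  ends <- pmin(starts + size - 1L, n)
  frags <- Biostrings::DNAStringSet(seq, start = starts, end = ends)
  names(frags) <- sprintf("frag%05d", seq_along(starts))
  coords <- data.frame(start = starts - 1L, end = ends,
                       short = (ends - starts + 1L) < size)
  new("FragmentSet", fragments = frags, coords = coords,
      genomeId = genomeId)
}

#' Align fragments to a collinear reference
#'
#' Per-fragment identity against the same-coordinate window of a reference
#' genome. This is an exact, gap-free aligner for collinear genome pairs
#' (such as the indel-free output of [simulateGenomePair()]); for diverged
#' or rearranged genomes, supply alignment records from an external search
#' tool to [anib()] instead.
#'
#' @param fragset a [FragmentSet-class].
#' @param ref the reference sequence ([Biostrings::DNAString] or character).
#' @return data.frame with `fragment`, `identity_pct`, `aligned_fraction`.
#' @export
alignFragmentsCollinear <- function(fragset, ref) {
  if (is.character(ref)) ref <- Biostrings::DNAString(ref)
  co <- fragmentCoords(fragset)
  fr <- fragments(fragset)
  refChars <- strsplit(as.character(ref), "", fixed = TRUE)[[1]]
  nref <- length(refChars)
  out <- data.frame(fragment = names(fr),
                    identity_pct = NA_real_,
                    aligned_fraction = 0)
  for (i in seq_len(nrow(co))) {
    s <- co$start[i] + 1L
    e <- min(co$end[i], nref)
    if (s > nref) next
    fchars <- strsplit(as.character(fr[[i]]), "", fixed = TRUE)[[1]]
    ov <- e - s + 1L
    matches <- sum(fchars[seq_len(ov)] == refChars[s:e])
    out$identity_pct[i] <- 100 * matches / ov
    out$aligned_fraction[i] <- ov / length(fchars)
  }
  out
}

#' Average nucleotide identity from fragment alignments (ANIb)
#'
#' Mean percent identity over fragments whose best alignment has identity
#' of at least `minIdentity` percent over at least `minAlnFraction` of the
#' fragment length; fragments without a qualifying hit are excluded from
#' the mean.
#'
#' @param alignments data.frame with `identity_pct` and `aligned_fraction`,
#'   one best record per fragment (`NA` identity = no hit).
#' @param minIdentity retention threshold in percent (default 30).
#' @param minAlnFraction minimum aligned fraction of the fragment
#'   (default 0.70).
#' @return ANI in percent, or `NA` (with a warning) when no fragment
#'   qualifies.
#' @export
anib <- function(alignments, minIdentity = 30, minAlnFraction = 0.70) {
  ok <- !is.na(alignments$identity_pct) &
    alignments$identity_pct >= minIdentity &
    alignments$aligned_fraction >= minAlnFraction
  if (!any(ok)) {
    warning("no fragment passed the ", minIdentity, "% identity / ",
            minAlnFraction, " coverage retention rule; ANI undefined")
    return(NA_real_)
  }
  mean(alignments$identity_pct[ok])
}

#' Two-way ANIb for a collinear genome pair
#'
#' Fragments each genome, aligns against the other with
#' [alignFragmentsCollinear()], and reports both one-directional ANI
#' values and their mean.
#'
#' @param seqA,seqB the two genome sequences.
#' @param size fragment size (default 1020).
#' @inheritParams anib
#' @return list with `ab`, `ba` and `mean`.
#' @export
anibPair <- function(seqA, seqB, size = 1020L, minIdentity = 30,
                     minAlnFraction = 0.70) {
  ab <- anib(alignFragmentsCollinear(fragmentGenome(seqA, size, "A"), seqB),
             minIdentity, minAlnFraction)
  ba <- anib(alignFragmentsCollinear(fragmentGenome(seqB, size, "B"), seqA),
             minIdentity, minAlnFraction)
  list(ab = ab, ba = ba, mean = mean(c(ab, ba)))
}

#' Tetranucleotide z-scores of a genome
#'
#' Observed tetramer counts over both strands (the sequence and its
#' reverse complement, counted separately so no word spans the junction)
#' against maximal-order Markov expectations
#' `E(w1w2w3w4) = N(w1w2w3) * N(w2w3w4) / N(w2w3)`, standardized as
#' `z = (O - E) / sqrt(E)` (Poisson approximation; `z = 0` where
#' `E = 0`). Ambiguous bases break words: windows containing them count
#' toward no tetramer.
#'
#' @param seq a [Biostrings::DNAString] or character sequence (length >= 4).
#' @return named numeric vector of 256 z-scores, indexed by tetramer in
#'   alphabetical order.
#' @export
tetraZscores <- function(seq) {
  if (is.character(seq)) seq <- Biostrings::DNAString(seq)
  if (length(seq) < 4) stop("sequence shorter than a tetramer")
  rc <- Biostrings::reverseComplement(seq)
  cnt <- function(width) {
    Biostrings::oligonucleotideFrequency(seq, width) +
      Biostrings::oligonucleotideFrequency(rc, width)
  }
  n4 <- cnt(4L); n3 <- cnt(3L); n2 <- cnt(2L)
  if (sum(n4) == 0)
    stop("no unambiguous tetramer in the sequence")
  w <- names(n4)
  E <- ifelse(n2[substr(w, 2, 3)] > 0,
              n3[substr(w, 1, 3)] * n3[substr(w, 2, 4)] /
                n2[substr(w, 2, 3)],
              0)
  z <- ifelse(E > 0, (n4 - E) / sqrt(E), 0)
  stats::setNames(as.numeric(z), w)
}

#' Pearson correlation between two tetranucleotide z-score vectors
#'
#' The TETRA genome-signature similarity: product-moment correlation over
#' the 256 tetramer z-scores.
#'
#' @param vecA,vecB numeric vectors of length 256 from [tetraZscores()].
#' @return Pearson r, or `NA` (with a warning) when a vector has zero
#'   variance.
#' @export
tetraCorrelation <- function(vecA, vecB) {
  stopifnot(length(vecA) == 256, length(vecB) == 256)
  if (stats::sd(vecA) == 0 || stats::sd(vecB) == 0) {
    warning("zero-variance z-score vector; correlation undefined")
    return(NA_real_)
  }
  stats::cor(vecA, vecB)
}

#' Global pairwise identity between two nucleotide sequences
#'
#' Needleman-Wunsch global alignment (default scoring: match +1, mismatch
#' -1, gap -2 per gapped column) via [Biostrings::pairwiseAlignment];
#' identity is matches over alignment columns, in percent.
#'
#' @param seqA,seqB sequences ([Biostrings::DNAString] or character).
#' @param match,mismatch substitution scores.
#' @param gap per-column gap penalty (applied as gap extension; no
#'   separate opening cost).
#' @return percent identity in \[0, 100\].
#' @export
pairwiseIdentityPct <- function(seqA, seqB, match = 1, mismatch = -1,
                                gap = -2) {
  if (is.character(seqA)) seqA <- Biostrings::DNAString(seqA)
  if (is.character(seqB)) seqB <- Biostrings::DNAString(seqB)
  if (length(seqA) < 1 || length(seqB) < 1) stop("empty sequence")
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(
    seqA, seqB, type = "global", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = -gap)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  100 * sum(pa == sa & pa != "-") / length(pa)
}
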