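#' Read a GenBank flat file (minimal parser)
#'
#' Parses the LOCUS line, the FEATURES table (feature keys, their interval
#' locations — `join`, `order` and `complement` are flattened to their
#' intervals — and no qualifiers beyond the raw text) and the ORIGIN
#' sequence. Covers what [genomeStats()] needs from a deposited bacterial
#' genome record; it is not a general-purpose GenBank reader.
#'
#' @param path path to a GenBank flat file (one or more records separated
#'   by `//`).
#' @return list of records; each a list with `locus`, `length`,
#'   `sequence` ([Biostrings::DNAString]) and `features` (data.frame
#'   `type`, `start`, `end`, `feature` — 1-based inclusive interval per
#'   row, `feature` indexing intervals of one multi-interval feature
#'   together).
#' @export
readGenBank <- function(path) {
  lines <- readLines(path)
  recBreaks <- c(0L, which(trimws(lines) == "//"))
  if (length(recBreaks) == 1L) recBreaks <- c(0L, length(lines) + 1L)
  records <- list()
  for (r in seq_len(length(recBreaks) - 1L)) {
    rl <- lines[(recBreaks[r] + 1L):(recBreaks[r + 1L] - 1L)]
    if (!length(rl) || !any(nzchar(rl))) next
    records[[length(records) + 1L]] <- .parseGenBankRecord(rl)
  }
  if (!length(records)) stop("no GenBank records found in ", path)
  records
}

.parseGenBankRecord <- function(rl) {
  locusLine <- grep("^LOCUS", rl, value = TRUE)
  locus <- if (length(locusLine))
    strsplit(trimws(sub("^LOCUS", "", locusLine[1])), "\\s+")[[1]][1]
  else NA_character_

  featStart <- grep("^FEATURES", rl)
  originStart <- grep("^ORIGIN", rl)
  seqChar <- ""
  if (length(originStart)) {
    end <- length(rl)
    sl <- rl[(originStart[1] + 1L):end]
    seqChar <- toupper(gsub("[^A-Za-z]", "", paste(sl, collapse = "")))
  }
  if (!nzchar(seqChar)) stop("GenBank record has no ORIGIN sequence")

  features <- data.frame(type = character(), start = integer(),
                         end = integer(), feature = integer())
  if (length(featStart)) {
    featEnd <- if (length(originStart)) originStart[1] - 1L else length(rl)
    fl <- rl[(featStart[1] + 1L):featEnd]
    # a feature line has its key in columns 6-20; continuation lines are
    # indented to column 22 (location continuations have no leading "/")
    isKey <- grepl("^ {5}\\S", fl)
    keyIdx <- which(isKey)
    type <- character(); start <- integer(); end <- integer()
    featIdx <- integer()
    fid <- 0L
    for (ki in seq_along(keyIdx)) {
      first <- keyIdx[ki]
      last <- if (ki < length(keyIdx)) keyIdx[ki + 1L] - 1L else length(fl)
      key <- sub("^\\s*(\\S+).*$", "\\1", fl[first])
      loc <- sub("^\\s*\\S+\\s*", "", fl[first])
      li <- first + 1L
      while (li <= last && !grepl("^\\s+/", fl[li])) {
        loc <- paste0(loc, trimws(fl[li]))
        li <- li + 1L
      }
      ranges <- regmatches(loc, gregexpr("[0-9]+(\\.\\.[0-9]+)?", loc))[[1]]
      if (!length(ranges)) next
      fid <- fid + 1L
      for (rg in ranges) {
        ab <- as.integer(strsplit(rg, "..", fixed = TRUE)[[1]])
        if (length(ab) == 1L) ab <- c(ab, ab)
        type <- c(type, key); start <- c(start, ab[1]); end <- c(end, ab[2])
        featIdx <- c(featIdx, fid)
      }
    }
    features <- data.frame(type = type, start = start, end = end,
                           feature = featIdx, stringsAsFactors = FALSE)
  }
  list(locus = locus, length = nchar(seqChar),
       sequence = Biostrings::DNAString(seqChar), features = features)
}

#' Genome statistics from a parsed GenBank record
#'
#' Replicates the usual genome-table summary: sequence length, G+C percent
#' (over unambiguous bases, rounded to 2 decimals), CDS count, percent of
#' the genome covered by the union of CDS intervals, and rRNA/tRNA feature
#' counts.
#'
#' @param record one record from [readGenBank()] (a list with `sequence`
#'   and `features`).
#' @return list with `length_bp`, `gc_percent`, `n_cds`, `percent_coding`,
#'   `n_rrna`, `n_trna`.
#' @export
genomeStats <- function(record) {
  if (is.null(record$sequence)) stop("record has no sequence")
  seq <- record$sequence
  n <- length(seq)
  freq <- Biostrings::alphabetFrequency(seq)
  acgt <- sum(freq[c("A", "C", "G", "T")])
  if (acgt == 0) stop("sequence has no unambiguous bases")
  gc <- round(100 * sum(freq[c("G", "C")]) / acgt, 2)

  feats <- record$features
  cds <- feats[feats$type == "CDS", , drop = FALSE]
  nCds <- length(unique(cds$feature))
  coding <- 0
  if (nrow(cds)) {
    ir <- IRanges::reduce(IRanges::IRanges(cds$start, cds$end))
    coding <- sum(IRanges::width(ir))
  }
  list(length_bp = n, gc_percent = gc, n_cds = nCds,
       percent_coding = 100 * coding / n,
       n_rrna = length(unique(feats$feature[feats$type == "rRNA"])),
       n_trna = length(unique(feats$feature[feats$type == "tRNA"])))
}
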