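#' phylomapr: phylogenomic profile maps for bacterial comparative genomics
#'
#' Builds phylogenetic-profile bit-score matrices from all-vs-all protein
#' homology searches, embeds proteins into 2D "phylogenomic maps" whose
#' density mountains approximate functional modules, and tests mountains for
#' category enrichment. Companion modules provide reciprocal-best-hit
#' orthology with minLrap/identity thresholds, Venn partitioning of gene
#' sets, whole-genome identity metrics (ANIb, tetranucleotide correlation)
#' and a fully seeded synthetic-data generator with planted ground truth.
#'
#' @importFrom methods new validObject is slot
#' @importFrom stats cor cmdscale rnorm runif dhyper phyper p.adjust rbinom
#' @import Biostrings
#' @importFrom IRanges IRanges reduce width
#' @importFrom S4Vectors mcols mcols<-
#' @name phylomapr-package
#' @aliases phylomapr
#' @keywords internal
"_PACKAGE"

#' ProfileMatrix: thresholded phylogenetic-profile bit-score matrix
#'
#' A proteins-by-genomes matrix of best qualifying homology-search bit
#' scores. A cell of 0 means "no qualifying hit" (not missing): hits are
#' retained only when bit score and e-value pass the filter thresholds, and
#' rows (proteins) are retained only when they qualify in at least
#' `minGenomes` genomes.
#'
#' @slot scores numeric matrix; rownames are protein ids, colnames genome ids.
#' @slot params named list with `minBitscore`, `maxEvalue`, `minGenomes`
#'   recording the filter under which the matrix was built.
#'
#' @seealso [buildProfileMatrix()], [simulateProfileMatrix()]
#' @export
setClass("ProfileMatrix",
  representation(scores = "matrix", params = "list"))

setValidity("ProfileMatrix", function(object) {
  msg <- character()
  sc <- object@scores
  if (!is.numeric(sc)) msg <- c(msg, "scores must be a numeric matrix")
  if (is.null(rownames(sc)) || is.null(colnames(sc)))
    msg <- c(msg, "scores must have protein rownames and genome colnames")
  if (anyDuplicated(rownames(sc))) msg <- c(msg, "duplicated protein ids")
  if (anyDuplicated(colnames(sc))) msg <- c(msg, "duplicated genome ids")
  if (length(sc) && any(sc < 0)) msg <- c(msg, "bit scores must be >= 0")
  req <- c("minBitscore", "maxEvalue", "minGenomes")
  if (!all(req %in% names(object@params)))
    msg <- c(msg, "params must contain minBitscore, maxEvalue, minGenomes")
  if (length(msg)) msg else TRUE
})

#' MountainMap: 2D phylogenomic map with detected density mountains
#'
#' Per-protein planar coordinates from the profile-similarity embedding,
#' kernel density at each protein's position, and an integer mountain label
#' (0 = unassigned plain). Mountain labels are ordered by descending member
#' count, so mountain 1 is always the largest.
#'
#' @slot coords numeric matrix (n x 2), rownames are protein ids.
#' @slot density numeric vector, kernel density estimate per protein.
#' @slot mountainId integer vector, 0 for unassigned.
#' @slot summaries data.frame with one row per mountain: `mountain`,
#'   `members`, `peakDensity`.
#' @slot converged logical; FALSE when the layout refinement hit its
#'   iteration cap before reaching its movement tolerance.
#'
#' @seealso [detectMountains()], [phylogenomicMap()]
#' @export
setClass("MountainMap",
  representation(coords = "matrix", density = "numeric",
                 mountainId = "integer", summaries = "data.frame",
                 converged = "logical"))

setValidity("MountainMap", function(object) {
  msg <- character()
  n <- nrow(object@coords)
  if (ncol(object@coords) != 2) msg <- c(msg, "coords must have 2 columns")
  if (is.null(rownames(object@coords)))
    msg <- c(msg, "coords must have protein rownames")
  if (length(object@density) != n) msg <- c(msg, "density length mismatch")
  if (length(object@mountainId) != n)
    msg <- c(msg, "mountainId length mismatch")
  if (length(object@mountainId) && any(object@mountainId < 0))
    msg <- c(msg, "mountainId must be >= 0")
  if (nrow(object@summaries) && sum(object@summaries$members) > n)
    msg <- c(msg, "mountain member counts exceed number of proteins")
  if (length(msg)) msg else TRUE
})

#' OrthologTable: thresholded reciprocal-best-hit ortholog pairs
#'
#' Cross-genome ortholog pairs passing minLrap and percent-identity
#' thresholds, reduced to reciprocal best hits within each genome pair,
#' together with the per-genome gene universes they were called against.
#'
#' @slot pairs data.frame with columns `gene_A`, `genome_A`, `gene_B`,
#'   `genome_B`, `identity_pct`, `minlrap`, `bit_score`. Pairs are stored
#'   once, with `genome_A < genome_B` lexicographically.
#' @slot universes named list mapping genome id to its full gene-id vector.
#' @slot params named list with `minMinlrap`, `minIdentity`.
#'
#' @seealso [callOrthologs()], [vennPartition()], [classExtract()]
#' @export
setClass("OrthologTable",
  representation(pairs = "data.frame", universes = "list", params = "list"))

setValidity("OrthologTable", function(object) {
  msg <- character()
  req <- c("gene_A", "genome_A", "gene_B", "genome_B",
           "identity_pct", "minlrap", "bit_score")
  if (!all(req %in% names(object@pairs)))
    msg <- c(msg, paste("pairs must have columns:", paste(req, collapse = ", ")))
  if (is.null(names(object@universes)) && length(object@universes))
    msg <- c(msg, "universes must be a named list")
  if (nrow(object@pairs)) {
    if (any(object@pairs$genome_A >= object@pairs$genome_B))
      msg <- c(msg, "pairs must be stored with genome_A < genome_B")
    for (g in unique(c(object@pairs$genome_A, object@pairs$genome_B)))
      if (!g %in% names(object@universes))
        msg <- c(msg, paste0("genome '", g, "' missing from universes"))
  }
  if (length(msg)) msg else TRUE
})

#' FragmentSet: fixed-size genome fragments for ANIb
#'
#' Consecutive non-overlapping windows cut from a genome sequence. The
#' final fragment may be shorter than the window size; it is retained and
#' flagged. Coordinates are 0-based half-open, so extracting
#' `[start, end)` from the source reconstructs each fragment.
#'
#' @slot fragments [Biostrings::DNAStringSet] of fragment sequences.
#' @slot coords data.frame with `start`, `end` (0-based half-open) and
#'   logical `short` flag.
#' @slot genomeId single character, the source genome id.
#'
#' @seealso [fragmentGenome()], [anib()]
#' @export
setClass("FragmentSet",
  representation(fragments = "DNAStringSet", coords = "data.frame",
                 genomeId = "character"))

setValidity("FragmentSet", function(object) {
  msg <- character()
  if (nrow(object@coords) != length(object@fragments))
    msg <- c(msg, "coords rows must match number of fragments")
  if (!all(c("start", "end", "short") %in% names(object@coords)))
    msg <- c(msg, "coords must have start, end, short")
  if (nrow(object@coords)) {
    w <- object@coords$end - object@coords$start
    if (any(w != Biostrings::width(object@fragments)))
      msg <- c(msg, "coordinate spans must match fragment widths")
  }
  if (length(msg)) msg else TRUE
})
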