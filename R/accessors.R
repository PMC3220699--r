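#' @describeIn ProfileMatrix-accessors the proteins x genomes score matrix
#' @export
profileScores <- function(x) {
  stopifnot(is(x, "ProfileMatrix"))
  x@scores
}

#' Accessors for ProfileMatrix
#'
#' @param x a [ProfileMatrix-class] object.
#' @return `profileScores` the numeric matrix; `proteinIds` / `genomeIds`
#'   character vectors; `filterParams` the filter parameter list.
#' @name ProfileMatrix-accessors
NULL

#' @describeIn ProfileMatrix-accessors protein (row) identifiers
#' @export
proteinIds <- function(x) rownames(profileScores(x))

#' @describeIn ProfileMatrix-accessors genome (column) identifiers
#' @export
genomeIds <- function(x) colnames(profileScores(x))

#' @describeIn ProfileMatrix-accessors filter parameters the matrix was built under
#' @export
filterParams <- function(x) {
  stopifnot(is(x, "ProfileMatrix"))
  x@params
}

#' Accessors for MountainMap
#'
#' @param x a [MountainMap-class] object.
#' @name MountainMap-accessors
NULL

#' @describeIn MountainMap-accessors n x 2 coordinate matrix
#' @export
mapCoords <- function(x) {
  stopifnot(is(x, "MountainMap"))
  x@coords
}

#' @describeIn MountainMap-accessors per-protein kernel density
#' @export
pointDensity <- function(x) {
  stopifnot(is(x, "MountainMap"))
  x@density
}

#' @describeIn MountainMap-accessors per-protein mountain label (0 = plain)
#' @export
mountainId <- function(x) {
  stopifnot(is(x, "MountainMap"))
  x@mountainId
}

#' @describeIn MountainMap-accessors one row per mountain: members, peak density
#' @export
mountainSummary <- function(x) {
  stopifnot(is(x, "MountainMap"))
  x@summaries
}

#' Accessors for OrthologTable
#'
#' @param x an [OrthologTable-class] object.
#' @param genome optional genome id; when given, `geneUniverse` returns that
#'   genome's gene vector instead of the full list.
#' @name OrthologTable-accessors
NULL

#' @describeIn OrthologTable-accessors the reciprocal-best-hit pair table
#' @export
orthologPairs <- function(x) {
  stopifnot(is(x, "OrthologTable"))
  x@pairs
}

#' @describeIn OrthologTable-accessors per-genome gene universes
#' @export
geneUniverse <- function(x, genome = NULL) {
  stopifnot(is(x, "OrthologTable"))
  if (is.null(genome)) return(x@universes)
  if (!genome %in% names(x@universes))
    stop("unknown genome: ", genome)
  x@universes[[genome]]
}

#' Accessors for FragmentSet
#'
#' @param x a [FragmentSet-class] object.
#' @name FragmentSet-accessors
NULL

#' @describeIn FragmentSet-accessors the fragment sequences
#' @export
fragments <- function(x) {
  stopifnot(is(x, "FragmentSet"))
  x@fragments
}

#' @describeIn FragmentSet-accessors 0-based half-open fragment coordinates
#' @export
fragmentCoords <- function(x) {
  stopifnot(is(x, "FragmentSet"))
  x@coords
}

#' @importFrom methods show
setMethod("show", "ProfileMatrix", function(object) {
  sc <- object@scores
  p <- object@params
  cat("ProfileMatrix:", nrow(sc), "proteins x", ncol(sc), "genomes\n")
  cat(sprintf("  filter: bit score > %s, e-value < %s, >= %d genomes\n",
              format(p$minBitscore), format(p$maxEvalue), p$minGenomes))
  cat(sprintf("  positive cells: %d (%.1f%%)\n", sum(sc > 0),
              if (length(sc)) 100 * mean(sc > 0) else 0))
})

setMethod("show", "MountainMap", function(object) {
  n <- nrow(object@coords)
  k <- nrow(object@summaries)
  cat("MountainMap:", n, "proteins,", k, "mountains",
      sprintf("(%d unassigned)\n", sum(object@mountainId == 0L)))
  if (k) {
    cat("  largest mountains:\n")
    print(head(object@summaries, 5), row.names = FALSE)
  }
  if (!object@converged) cat("  note: layout refinement did not converge\n")
})

setMethod("show", "OrthologTable", function(object) {
  cat("OrthologTable:", nrow(object@pairs), "reciprocal-best-hit pairs,",
      length(object@universes), "genomes\n")
  cat(sprintf("  thresholds: minLrap >= %s, identity >= %s%%\n",
              format(object@params$minMinlrap),
              format(object@params$minIdentity)))
})

setMethod("show", "FragmentSet", function(object) {
  n <- length(object@fragments)
  cat("FragmentSet:", n, "fragments from genome", object@genomeId, "\n")
  if (n && any(object@coords$short))
    cat("  final fragment short:",
        object@coords$end[n] - object@coords$start[n], "bp\n")
})
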