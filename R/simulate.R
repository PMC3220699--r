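#' Specification for a planted-module profile simulation
#'
#' Describes a proteins x genomes bit-score matrix with planted correlated
#' modules. Each module is assigned one characteristic genome set (each
#' genome joins it independently with probability `charFrac`); proteins in
#' a module produce a qualifying hit in characteristic genomes with
#' probability `presenceProbIn` and elsewhere with `presenceProbOut`, after
#' which each cell's presence state is flipped with `noiseFlipProb`.
#' Proteins outside any module carry independent background patterns at
#' `presenceProbOut`. Present cells get bit scores from a normal
#' distribution truncated below just above the 50-bit retention threshold
#' so every simulated hit passes the profile filter.
#'
#' @param nProteins,nGenomes matrix dimensions.
#' @param nModules number of planted modules.
#' @param moduleSizes integer vector of length `nModules`; must sum to at
#'   most `nProteins`.
#' @param presenceProbIn hit probability in a module's characteristic genomes.
#' @param presenceProbOut background hit probability.
#' @param bitscoreMean,bitscoreSd normal parameters (bits) for present cells.
#' @param noiseFlipProb probability a cell's presence state is flipped.
#' @param charFrac probability each genome joins a module's characteristic set.
#' @param seed integer seed; a fixed seed makes the output bit-identical.
#' @return a validated `ProfileSimSpec` list.
#' @export
profileSimSpec <- function(nProteins, nGenomes, nModules,
                           moduleSizes = rep(nProteins %/% nModules, nModules),
                           presenceProbIn = 1, presenceProbOut = 0.05,
                           bitscoreMean = 150, bitscoreSd = 30,
                           noiseFlipProb = 0, charFrac = 0.5, seed = 1L) {
  spec <- list(nProteins = as.integer(nProteins),
               nGenomes = as.integer(nGenomes),
               nModules = as.integer(nModules),
               moduleSizes = as.integer(moduleSizes),
               presenceProbIn = presenceProbIn,
               presenceProbOut = presenceProbOut,
               bitscoreMean = bitscoreMean, bitscoreSd = bitscoreSd,
               noiseFlipProb = noiseFlipProb, charFrac = charFrac,
               seed = as.integer(seed))
  if (spec$nProteins < 1 || spec$nGenomes < 1)
    stop("nProteins and nGenomes must be positive")
  if (length(spec$moduleSizes) != spec$nModules)
    stop("moduleSizes must have length nModules")
  if (any(spec$moduleSizes < 1)) stop("moduleSizes must be positive")
  if (sum(spec$moduleSizes) > spec$nProteins)
    stop("moduleSizes sum to more than nProteins")
  probs <- c(spec$presenceProbIn, spec$presenceProbOut,
             spec$noiseFlipProb, spec$charFrac)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  structure(spec, class = "ProfileSimSpec")
}

#' Simulate a phylogenetic-profile matrix with planted modules
#'
#' @param spec a [profileSimSpec()].
#' @return list with `matrix` (a [ProfileMatrix-class]; params record the
#'   50-bit / 1e-5 filter its scores respect, with `minGenomes = 1` since
#'   background rows are not pruned) and `labels`, the planted module label
#'   per protein (0 = background singleton).
#' @export
simulateProfileMatrix <- function(spec) {
  stopifnot(inherits(spec, "ProfileSimSpec"))
  set.seed(spec$seed)
  np <- spec$nProteins; ng <- spec$nGenomes
  prot <- sprintf("prot%04d", seq_len(np))
  gen <- sprintf("g%03d", seq_len(ng))

  labels <- integer(np)
  idx <- 1L
  for (m in seq_len(spec$nModules)) {
    labels[idx:(idx + spec$moduleSizes[m] - 1L)] <- m
    idx <- idx + spec$moduleSizes[m]
  }

  # one characteristic genome set per module
  charSets <- matrix(runif(spec$nModules * ng) < spec$charFrac,
                     nrow = spec$nModules)

  present <- matrix(FALSE, np, ng)
  for (i in seq_len(np)) {
    if (labels[i] > 0L) {
      p <- ifelse(charSets[labels[i], ], spec$presenceProbIn,
                  spec$presenceProbOut)
    } else {
      p <- rep(spec$presenceProbOut, ng)
    }
    present[i, ] <- runif(ng) < p
  }
  if (spec$noiseFlipProb > 0)
    present <- xor(present, matrix(runif(np * ng) < spec$noiseFlipProb,
                                   np, ng))

  scores <- matrix(0, np, ng, dimnames = list(prot, gen))
  npos <- sum(present)
  if (npos)
    scores[present] <- pmax(rnorm(npos, spec$bitscoreMean, spec$bitscoreSd),
                            50 + 1e-6)
  pm <- new("ProfileMatrix", scores = scores,
            params = list(minBitscore = 50, maxEvalue = 1e-5,
                          minGenomes = 1L))
  list(matrix = pm, labels = labels)
}

#' Specification for a diverged genome pair
#'
#' @param lengthBp ancestor length in bp.
#' @param substitutionRate per-site substitution probability; substituted
#'   sites change to one of the three alternative bases uniformly.
#' @param indelRate per-site probability of a single-base indel (split
#'   evenly between insertion and deletion); default 0 keeps the pair
#'   collinear so divergence bookkeeping is exact.
#' @param gcContent ancestor G+C fraction.
#' @param seed integer seed.
#' @export
genomePairSpec <- function(lengthBp, substitutionRate = 0, indelRate = 0,
                           gcContent = 0.5, seed = 1L) {
  spec <- list(lengthBp = as.integer(lengthBp),
               substitutionRate = substitutionRate, indelRate = indelRate,
               gcContent = gcContent, seed = as.integer(seed))
  if (spec$lengthBp < 1) stop("lengthBp must be positive")
  rates <- c(spec$substitutionRate, spec$indelRate, spec$gcContent)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  structure(spec, class = "GenomePairSpec")
}

#' Simulate a pair of genomes diverged from a common ancestor
#'
#' Point-mutates an ancestor at the specified per-site rate. The realized
#' divergence is reported exactly: substituted (and not subsequently
#' deleted) sites divided by the number of ancestor sites still aligned.
#'
#' @param spec a [genomePairSpec()].
#' @return list with `seqA`, `seqB` ([Biostrings::DNAString]) and
#'   `realizedDivergence`.
#' @export
simulateGenomePair <- function(spec) {
  stopifnot(inherits(spec, "GenomePairSpec"))
  set.seed(spec$seed)
  n <- spec$lengthBp
  bases <- c("A", "C", "G", "T")
  pr <- c((1 - spec$gcContent) / 2, spec$gcContent / 2,
          spec$gcContent / 2, (1 - spec$gcContent) / 2)
  a <- sample(bases, n, replace = TRUE, prob = pr)

  b <- a
  sub <- runif(n) < spec$substitutionRate
  if (any(sub)) {
    # uniform over the three alternative bases
    alt <- vapply(b[sub], function(x) sample(setdiff(bases, x), 1L), "")
    b[sub] <- alt
  }

  deleted <- rep(FALSE, n)
  if (spec$indelRate > 0) {
    ev <- runif(n)
    deleted <- ev < spec$indelRate / 2
    inserted <- ev >= spec$indelRate / 2 & ev < spec$indelRate
    pieces <- b
    pieces[deleted] <- ""
    if (any(inserted))
      pieces[inserted] <- paste0(pieces[inserted],
                                 sample(bases, sum(inserted), replace = TRUE))
    b <- strsplit(paste(pieces, collapse = ""), "")[[1]]
  }

  aligned <- sum(!deleted)
  divergence <- if (aligned) sum(sub & !deleted) / aligned else NA_real_
  list(seqA = Biostrings::DNAString(paste(a, collapse = "")),
       seqB = Biostrings::DNAString(paste(b, collapse = "")),
       realizedDivergence = divergence)
}

#' Specification for an annotation table with a planted enrichment
#'
#' Genes carry each category independently at its background frequency; the
#' genes of one enriched set carry `enrichedCategory` at
#' `min(1, backgroundFreq * enrichmentFactor)` instead. When the product
#' exceeds 1 it is clamped with a warning unless `clamp = FALSE`, in which
#' case an error is raised.
#'
#' @param nGenes background size.
#' @param categories category labels.
#' @param backgroundFreq per-category background frequency (recycled).
#' @param enrichedSetSize size of the planted enriched gene set.
#' @param enrichedCategory which category is enriched.
#' @param enrichmentFactor multiplier on the background frequency inside the
#'   enriched set; `Inf` forces certain annotation.
#' @param clamp clamp probabilities at 1 (with a warning) instead of erroring.
#' @param seed integer seed.
#' @export
annotationSimSpec <- function(nGenes = 1000L, categories = paste0("cat", 1:5),
                              backgroundFreq = 0.1, enrichedSetSize = 20L,
                              enrichedCategory = categories[1],
                              enrichmentFactor = 5, clamp = TRUE, seed = 1L) {
  backgroundFreq <- rep_len(backgroundFreq, length(categories))
  spec <- list(nGenes = as.integer(nGenes), categories = categories,
               backgroundFreq = backgroundFreq,
               enrichedSetSize = as.integer(enrichedSetSize),
               enrichedCategory = enrichedCategory,
               enrichmentFactor = enrichmentFactor, clamp = clamp,
               seed = as.integer(seed))
  if (spec$nGenes < 1) stop("nGenes must be positive")
  if (any(backgroundFreq < 0 | backgroundFreq > 1))
    stop("backgroundFreq must lie in [0, 1]")
  if (spec$enrichedSetSize > spec$nGenes)
    stop("enrichedSetSize exceeds nGenes")
  if (!enrichedCategory %in% categories)
    stop("enrichedCategory must be one of categories")
  if (enrichmentFactor < 0) stop("enrichmentFactor must be >= 0")
  structure(spec, class = "AnnotationSimSpec")
}

#' Simulate a gene-category annotation table with one planted enrichment
#'
#' @param spec an [annotationSimSpec()].
#' @return list with `annotations` (data.frame `gene_id`, `category`),
#'   `genes` (the full gene universe), `enrichedGenes` (the planted set)
#'   and `enrichedCategory`.
#' @export
simulateAnnotations <- function(spec) {
  stopifnot(inherits(spec, "AnnotationSimSpec"))
  set.seed(spec$seed)
  genes <- sprintf("gene%05d", seq_len(spec$nGenes))
  enriched <- sample(genes, spec$enrichedSetSize)

  pEnr <- spec$backgroundFreq[match(spec$enrichedCategory, spec$categories)] *
    spec$enrichmentFactor
  if (pEnr > 1) {
    if (!spec$clamp)
      stop("enrichment pushes annotation probability above 1 (",
           format(pEnr), "); set clamp = TRUE to truncate")
    warning("enriched-category probability clamped from ", format(pEnr),
            " to 1")
    pEnr <- 1
  }

  rows <- vector("list", length(spec$categories))
  for (j in seq_along(spec$categories)) {
    cat_j <- spec$categories[j]
    p <- rep(spec$backgroundFreq[j], spec$nGenes)
    if (cat_j == spec$enrichedCategory) p[genes %in% enriched] <- pEnr
    hit <- runif(spec$nGenes) < p
    if (any(hit))
      rows[[j]] <- data.frame(gene_id = genes[hit], category = cat_j,
                              stringsAsFactors = FALSE)
  }
  ann <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(ann))
    ann <- data.frame(gene_id = character(), category = character())
  rownames(ann) <- NULL
  list(annotations = ann, genes = genes, enrichedGenes = enriched,
       enrichedCategory = spec$enrichedCategory)
}

#' Simulate all-vs-all homology hits with known ortholog structure
#'
#' Builds per-genome gene sets from shared families (each family
#' contributes one gene per genome in its presence set) plus per-genome
#' unique genes, and emits a reciprocal hit table in which true co-family
#' pairs score highest. Optional paralogs (duplicated family members in the
#' first genome of a family's presence set) score strictly below the true
#' ortholog, so a reciprocal-best-hit caller should resolve them.
#'
#' @param genomes character vector of genome ids.
#' @param nCore families present in every genome.
#' @param presence optional named list of extra families: each element a
#'   character vector of member genomes (length >= 2).
#' @param nUnique unique (family-less) genes per genome.
#' @param nParalogs number of core families that additionally get a
#'   lower-scoring duplicate copy in the first genome.
#' @param seed integer seed.
#' @return list with `hits` (a hit data.frame suitable for
#'   [callOrthologs()]), `universes`, and `truth` (data.frame of true
#'   ortholog pairs with `gene_A`, `genome_A`, `gene_B`, `genome_B`,
#'   genome_A < genome_B).
#' @export
simulateHomologyHits <- function(genomes = c("gA", "gB", "gC", "gD"),
                                 nCore = 20L, presence = list(),
                                 nUnique = 5L, nParalogs = 0L, seed = 1L) {
  set.seed(as.integer(seed))
  genomes <- sort(genomes)
  fams <- c(lapply(seq_len(nCore), function(i) genomes),
            unname(presence))
  famId <- sprintf("fam%03d", seq_along(fams))

  universes <- stats::setNames(
    lapply(genomes, function(g) character()), genomes)
  member <- list()  # famId -> named chr (genome -> gene)
  for (k in seq_along(fams)) {
    gs <- fams[[k]]
    genes <- stats::setNames(paste0(famId[k], "_", gs), gs)
    member[[famId[k]]] <- genes
    for (g in gs) universes[[g]] <- c(universes[[g]], genes[[g]])
  }
  for (g in genomes)
    universes[[g]] <- c(universes[[g]],
                        sprintf("%s_uniq%03d", g, seq_len(nUnique)))

  rows <- list()
  emit <- function(qg, q, sg, s, bit, ident) {
    len <- 300L
    rows[[length(rows) + 1L]] <<- data.frame(
      query_id = q, subject_id = s, query_genome = qg, subject_genome = sg,
      identity_pct = ident, align_len = len, e_value = 2^(-bit / 2),
      bit_score = bit, q_len = len, s_len = len, stringsAsFactors = FALSE)
  }
  truth <- list()
  for (k in seq_along(fams)) {
    mem <- member[[famId[k]]]
    gs <- names(mem)
    for (i in seq_along(gs)) for (j in seq_along(gs)) {
      if (i == j) next
      bit <- 400 + round(runif(1, 0, 50), 1)
      ident <- 60 + round(runif(1, 0, 30), 1)
      emit(gs[i], mem[[i]], gs[j], mem[[j]], bit, ident)
      if (i < j)
        truth[[length(truth) + 1L]] <- data.frame(
          gene_A = mem[[i]], genome_A = gs[i],
          gene_B = mem[[j]], genome_B = gs[j], stringsAsFactors = FALSE)
    }
  }
  if (nParalogs > 0L) {
    for (k in seq_len(min(nParalogs, nCore))) {
      mem <- member[[famId[k]]]
      host <- names(mem)[1]
      dup <- paste0(famId[k], "_", host, "_dup")
      universes[[host]] <- c(universes[[host]], dup)
      for (g in setdiff(names(mem), host)) {
        bit <- 200 + round(runif(1, 0, 50), 1)  # below the true copy
        ident <- 40 + round(runif(1, 0, 10), 1)
        emit(host, dup, g, mem[[g]], bit, ident)
        emit(g, mem[[g]], host, dup, bit, ident)
      }
    }
  }
  hits <- do.call(rbind, rows)
  rownames(hits) <- NULL
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  list(hits = hits, universes = universes, truth = truth)
}
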