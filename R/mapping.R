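#' Pairwise Spearman correlation between protein profiles
#'
#' Rank correlation across genomes for every pair of profile rows, with
#' average ranks for ties (0-cells make ties heavy, so the tie rule
#' matters). Constant rows have undefined correlation; their entries are
#' recorded as 0 with a warning. The diagonal is excluded (set to `NA`).
#'
#' @param x a [ProfileMatrix-class] or a numeric proteins x genomes matrix.
#' @return symmetric matrix of Spearman rho with `NA` diagonal.
#' @export
spearmanMatrix <- function(x) {
  sc <- if (is(x, "ProfileMatrix")) profileScores(x) else x
  if (nrow(sc) < 2) stop("need at least 2 proteins")
  if (ncol(sc) < 3) stop("need at least 3 genomes")
  constant <- apply(sc, 1, function(r) length(unique(r)) == 1L)
  rho <- suppressWarnings(stats::cor(t(sc), method = "spearman"))
  if (any(constant)) {
    warning(sum(constant), " constant profile row(s); their correlations ",
            "are undefined and recorded as 0")
    rho[constant, ] <- 0
    rho[, constant] <- 0
  }
  rho[is.na(rho)] <- 0
  diag(rho) <- NA_real_
  rho
}

#' Retain each protein's top-k positive correlates
#'
#' Keeps, per protein, the k largest strictly positive correlations (ties
#' at the cutoff broken by lexicographically smaller partner id), then
#' symmetrizes the directed lists into an undirected graph. With
#' `mode = "union"` an edge survives if either endpoint retained it
#' (default); `"intersection"` requires both. Proteins with no positive
#' correlate remain as isolated vertices.
#'
#' @param rho correlation matrix from [spearmanMatrix()].
#' @param k correlates retained per protein (default 50).
#' @param mode symmetrization rule.
#' @return an [igraph::graph] with edge attribute `rho` and vertex
#'   attribute `isolated`.
#' @export
topCorrelates <- function(rho, k = 50L, mode = c("union", "intersection")) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(rho), nrow(rho) == ncol(rho), k >= 1)
  ids <- rownames(rho)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(rho)))
  n <- nrow(rho)
  from <- to <- integer(0)
  for (i in seq_len(n)) {
    r <- rho[i, ]
    cand <- which(!is.na(r) & r > 0 & seq_len(n) != i)
    if (!length(cand)) next
    cand <- cand[order(-r[cand], ids[cand])]
    cand <- cand[seq_len(min(k, length(cand)))]
    from <- c(from, rep.int(i, length(cand)))
    to <- c(to, cand)
  }
  key <- paste(pmin(from, to), pmax(from, to))
  if (mode == "union") {
    keep <- !duplicated(key)
  } else {
    keep <- duplicated(key)  # second occurrence => both directions present
  }
  from <- from[keep]; to <- to[keep]
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  if (length(from)) {
    g <- igraph::add_edges(g, rbind(from, to))
    g <- igraph::set_edge_attr(g, "rho", value = rho[cbind(from, to)])
  }
  igraph::set_vertex_attr(g, "isolated", value = igraph::degree(g) == 0)
}

#' Embed the correlate graph in the plane
#'
#' Deterministic two-stage layout combining multi-dimensional scaling with
#' force-directed placement: classical metric MDS on graph shortest-path
#' distances (edge length `1 - rho`) initializes the coordinates, which
#' are then refined by Fruchterman-Reingold-style iterations — edge
#' springs pulling neighbors toward distance `1 - rho` with stiffness rho,
#' all-pairs repulsion, and a linearly cooling step cap. The refinement
#' uses no random numbers: the result is identical across runs, and
#' structurally identical twin nodes (same neighbors, same rho, hence
#' coincident after MDS) receive identical coordinates because coincident
#' points exert no repulsion on each other. Connected components are laid
#' out independently and placed in disjoint bounding boxes.
#'
#' @param graph graph from [topCorrelates()].
#' @param seed integer seed (the layout is deterministic but the seed is
#'   honored for any downstream stochastic use).
#' @param nIter refinement iterations (default 200; 0 = pure MDS).
#' @param tol tolerance on the final-iteration maximum displacement,
#'   relative to the layout scale, below which the layout is flagged
#'   converged.
#' @return numeric n x 2 matrix of coordinates (rownames = protein ids)
#'   with attribute `converged`.
#' @export
embedMap <- function(graph, seed = 1L, nIter = 200L, tol = 1e-3) {
  set.seed(as.integer(seed))
  ids <- igraph::V(graph)$name
  n <- igraph::vcount(graph)
  comp <- igraph::components(graph)
  coords <- matrix(0, n, 2, dimnames = list(ids, c("x", "y")))
  converged <- TRUE

  for (ci in seq_len(comp$no)) {
    vs <- which(comp$membership == ci)
    m <- length(vs)
    if (m == 1L) next
    sub <- igraph::induced_subgraph(graph, vs)
    w <- 1 - igraph::E(sub)$rho
    w <- pmax(w, 1e-9)  # rho = 1 edges: keep weights valid for Dijkstra
    D <- igraph::distances(sub, weights = w)
    xy <- stats::cmdscale(D, k = 2)
    if (ncol(xy) < 2) xy <- cbind(xy, 0)[, 1:2, drop = FALSE]

    el <- igraph::as_edgelist(sub, names = FALSE)
    if (nrow(el)) {
      rhoE <- igraph::E(sub)$rho
      res <- .refineLayout(xy, el, rhoE, nIter = nIter, tol = tol)
      xy <- res$coords
      converged <- converged && res$converged
    }
    coords[vs, ] <- xy
  }

  # place components side by side in disjoint boxes
  if (comp$no > 1L) {
    gap <- 0
    widths <- numeric(comp$no)
    for (ci in seq_len(comp$no)) {
      vs <- which(comp$membership == ci)
      widths[ci] <- diff(range(coords[vs, 1])) + 1
    }
    offset <- 0
    for (ci in seq_len(comp$no)) {
      vs <- which(comp$membership == ci)
      coords[vs, 1] <- coords[vs, 1] - min(coords[vs, 1]) + offset
      offset <- offset + widths[ci] + gap + max(widths) * 0.1
    }
  }
  attr(coords, "converged") <- converged
  coords
}

# deterministic Fruchterman-Reingold refinement: edge springs toward
# length 1 - rho with stiffness rho, all-pairs repulsion (zero between
# coincident points so structural twins stay together), linear cooling
.refineLayout <- function(xy, edges, rho, nIter, tol) {
  n <- nrow(xy)
  if (nIter < 1L || !nrow(edges) || n < 2)
    return(list(coords = xy, converged = TRUE))
  area <- max(diff(range(xy[, 1])) * diff(range(xy[, 2])), 1)
  k <- sqrt(area / n)
  i <- c(edges[, 1], edges[, 2])
  j <- c(edges[, 2], edges[, 1])
  w <- rep(rho, 2)
  L <- rep(1 - rho, 2)
  t0 <- 0.1 * sqrt(area)
  move <- Inf
  for (it in seq_len(nIter)) {
    temp <- t0 * (1 - (it - 1) / nIter)
    dx <- outer(xy[, 1], xy[, 1], "-")
    dy <- outer(xy[, 2], xy[, 2], "-")
    d2 <- dx * dx + dy * dy
    diag(d2) <- Inf
    d2[d2 < 1e-18] <- Inf           # coincident pairs: no repulsion
    fr <- k * k / d2
    fx <- rowSums(fr * dx)
    fy <- rowSums(fr * dy)
    ex <- xy[i, 1] - xy[j, 1]
    ey <- xy[i, 2] - xy[j, 2]
    ed <- sqrt(ex * ex + ey * ey)
    f <- ifelse(ed > 1e-12, w * (ed - L) / ed, 0)
    sfx <- tapply(-f * ex, i, sum)
    sfy <- tapply(-f * ey, i, sum)
    idx <- as.integer(names(sfx))
    fx[idx] <- fx[idx] + sfx
    fy[idx] <- fy[idx] + sfy
    fd <- sqrt(fx * fx + fy * fy)
    sc <- ifelse(fd > 1e-12, pmin(fd, temp) / fd, 0)
    xy[, 1] <- xy[, 1] + fx * sc
    xy[, 2] <- xy[, 2] + fy * sc
    move <- max(fd * sc)
  }
  scale0 <- max(diff(range(xy[, 1])), diff(range(xy[, 2])), 1e-9)
  list(coords = xy, converged = move < tol * scale0)
}

#' Detect density mountains on the map
#'
#' Gaussian kernel density on a regular grid; each grid cell is assigned to
#' the basin of the local density maximum reached by steepest ascent over
#' its 8-neighborhood (a watershed-by-flooding equivalent, processed in
#' decreasing density order). Basins whose peak density does not exceed
#' `densityFloor` stay unassigned, and basins with fewer than `minMembers`
#' proteins are merged into the basin of the nearest qualifying peak (or
#' left unassigned when none exists). Mountain labels are renumbered by
#' descending member count.
#'
#' @param coords n x 2 coordinate matrix from [embedMap()].
#' @param bandwidth kernel bandwidth in [MASS::kde2d()]'s `h` convention
#'   (scalar or per-axis length-2). Default `NULL` sets the kernel
#'   standard deviation to the mean distance to each point's
#'   `minMembers`-th nearest neighbor, i.e. to the spacing of the smallest
#'   cluster worth calling; the normal-reference rule is a poor default
#'   here because between-mountain spread inflates it.
#' @param minMembers minimum proteins per mountain (default 5).
#' @param densityFloor minimum peak density for a basin to count
#'   (default 0 = every basin eligible).
#' @param gridSize density grid resolution per axis (default 128).
#' @param mergeSmall merge undersized basins into the nearest qualifying
#'   basin (default TRUE); FALSE marks their members unassigned.
#' @param prominence minimum relative prominence of a peak: a basin whose
#'   peak density exceeds its highest saddle by less than
#'   `prominence * peak` is merged into the basin across that saddle
#'   (default 0.1; 0 disables merging).
#' @return a [MountainMap-class].
#' @export
detectMountains <- function(coords, bandwidth = NULL, minMembers = 5L,
                            densityFloor = 0, gridSize = 128L,
                            mergeSmall = TRUE, prominence = 0.1) {
  stopifnot(is.matrix(coords), ncol(coords) == 2)
  n <- nrow(coords)
  x <- coords[, 1]; y <- coords[, 2]
  if (is.null(bandwidth)) {
    # kernel scale tied to the smallest meaningful cluster: the mean
    # distance to the minMembers-th nearest neighbor (kde2d's h is 4x the
    # Gaussian sd, so this sets kernel sd = that neighbor distance)
    kk <- min(minMembers, n - 1L)
    d <- as.matrix(stats::dist(coords))
    diag(d) <- Inf
    dk <- apply(d, 1, function(r) sort(r)[kk])
    h <- 4 * mean(dk)
    if (!is.finite(h) || h <= 0)
      h <- 0.05 * max(diff(range(x)), diff(range(y)), 1)
    bw <- c(h, h)
  } else bw <- rep_len(bandwidth, 2L)
  pad <- bw
  kd <- MASS::kde2d(x, y, h = bw, n = gridSize,
                    lims = c(range(x) + c(-1, 1) * pad,
                             range(y) + c(-1, 1) * pad))
  z <- kd$z
  gs <- gridSize

  # basin assignment: decreasing-density flood
  ord <- order(z, decreasing = TRUE)
  lab <- matrix(0L, gs, gs)
  peaks <- list()  # label -> c(i, j, density)
  nb <- rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
              c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  nextLab <- 0L
  saddle <- matrix(0, 0, 0)
  for (cell in ord) {
    i <- (cell - 1L) %% gs + 1L
    j <- (cell - 1L) %/% gs + 1L
    bestLab <- 0L; bestZ <- z[i, j]; found <- FALSE
    nbrLabs <- integer(0)
    for (q in seq_len(8)) {
      ii <- i + nb[q, 1]; jj <- j + nb[q, 2]
      if (ii < 1 || ii > gs || jj < 1 || jj > gs) next
      if (lab[ii, jj] > 0L && z[ii, jj] >= bestZ) {
        nbrLabs <- c(nbrLabs, lab[ii, jj])
        if (!found || z[ii, jj] > bestZ) {
          bestZ <- z[ii, jj]; bestLab <- lab[ii, jj]; found <- TRUE
        }
      }
    }
    if (found) {
      lab[i, j] <- bestLab
      # a cell touching two basins is their saddle; keep the highest one
      for (other in setdiff(unique(nbrLabs), bestLab))
        saddle[bestLab, other] <- saddle[other, bestLab] <-
          max(saddle[bestLab, other], z[i, j])
    } else {
      # local maximum: open a new basin if above the floor
      if (z[i, j] > densityFloor) {
        nextLab <- nextLab + 1L
        lab[i, j] <- nextLab
        peaks[[nextLab]] <- c(kd$x[i], kd$y[j], z[i, j])
        s2 <- matrix(0, nextLab, nextLab)
        if (nextLab > 1L) s2[-nextLab, -nextLab] <- saddle
        saddle <- s2
      }
    }
  }
  if (nextLab == 0L)
    warning("all density below the floor: no mountains detected")

  # merge non-prominent basins: a peak that barely rises above its highest
  # saddle is a density ripple, not a mountain of its own
  if (nextLab > 1L && prominence > 0) {
    parent <- seq_len(nextLab)
    root <- function(v) { while (parent[v] != v) v <- parent[v]; v }
    repeat {
      pk <- vapply(seq_len(nextLab), function(v) peaks[[v]][3], 0)
      act <- which(parent == seq_len(nextLab))
      merged <- FALSE
      for (b in act[order(pk[act])]) {
        sb <- saddle[b, ]
        sb[b] <- 0
        if (all(sb <= 0)) next
        tgt <- which.max(sb)
        if (pk[b] - sb[tgt] < prominence * pk[b]) {
          tr <- root(tgt)
          if (tr == b) next
          parent[b] <- tr
          peaks[[tr]][3] <- max(peaks[[tr]][3], pk[b])
          saddle[tr, ] <- pmax(saddle[tr, ], saddle[b, ])
          saddle[, tr] <- pmax(saddle[, tr], saddle[, b])
          saddle[tr, tr] <- 0
          saddle[b, ] <- saddle[, b] <- 0
          merged <- TRUE
          break
        }
      }
      if (!merged) break
    }
    relab <- vapply(seq_len(nextLab), root, 1L)
    lab[lab > 0L] <- relab[lab[lab > 0L]]
  }

  # map proteins to their nearest grid cell
  gi <- pmin(pmax(round(stats::approx(kd$x, seq_len(gs), xout = x,
                                      rule = 2)$y), 1), gs)
  gj <- pmin(pmax(round(stats::approx(kd$y, seq_len(gs), xout = y,
                                      rule = 2)$y), 1), gs)
  plab <- lab[cbind(gi, gj)]
  pdens <- z[cbind(gi, gj)]

  # prune / merge undersized basins
  counts <- tabulate(plab, nbins = max(nextLab, 1L))
  big <- which(counts >= minMembers)
  if (length(big) == 0L) {
    plab <- rep(0L, n)
  } else {
    small <- setdiff(which(counts > 0L), big)
    for (s in small) {
      members <- plab == s
      if (mergeSmall) {
        pk <- peaks[[s]]
        dd <- vapply(big, function(b)
          sum((peaks[[b]][1:2] - pk[1:2])^2), 0)
        plab[members] <- big[which.min(dd)]
      } else plab[members] <- 0L
    }
  }

  # renumber by descending member count (ties: original label order)
  if (any(plab > 0L)) {
    counts <- tabulate(plab)
    used <- which(counts > 0L)
    used <- used[order(-counts[used], used)]
    remap <- integer(max(plab))
    remap[used] <- seq_along(used)
    newlab <- ifelse(plab > 0L, remap[pmax(plab, 1L)], 0L)
    summ <- data.frame(
      mountain = seq_along(used),
      members = counts[used],
      peakDensity = vapply(used, function(u) peaks[[u]][3], 0))
    plab <- as.integer(newlab)
  } else {
    summ <- data.frame(mountain = integer(), members = integer(),
                       peakDensity = numeric())
  }

  new("MountainMap", coords = coords, density = pdens,
      mountainId = as.integer(plab), summaries = summ,
      converged = isTRUE(attr(coords, "converged")) ||
        is.null(attr(coords, "converged")))
}

#' Build a phylogenomic map from a profile matrix
#'
#' Convenience pipeline: Spearman correlation of profiles, top-k positive
#' correlate graph, MDS-initialized spring embedding, and kernel-density
#' mountain detection.
#'
#' @param pm a [ProfileMatrix-class].
#' @param k correlates per protein (default 50).
#' @param seed layout seed.
#' @param mode symmetrization mode for [topCorrelates()].
#' @param nIter,tol layout refinement controls, see [embedMap()].
#' @inheritParams detectMountains
#' @return a [MountainMap-class].
#' @export
phylogenomicMap <- function(pm, k = 50L, seed = 1L,
                            mode = c("union", "intersection"),
                            nIter = 200L, tol = 1e-3, bandwidth = NULL,
                            minMembers = 5L, densityFloor = 0,
                            gridSize = 128L, prominence = 0.1) {
  rho <- spearmanMatrix(pm)
  g <- topCorrelates(rho, k = k, mode = match.arg(mode))
  coords <- embedMap(g, seed = seed, nIter = nIter, tol = tol)
  detectMountains(coords, bandwidth = bandwidth, minMembers = minMembers,
                  densityFloor = densityFloor, gridSize = gridSize,
                  prominence = prominence)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items;
#' used to score recovery of planted modules by mountain detection.
#'
#' @param a,b label vectors of equal length.
#' @return the adjusted Rand index (1 = identical partitions).
#' @export
adjustedRand <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expd <- si * sj / choose(n, 2)
  mx <- (si + sj) / 2
  if (mx == expd) return(ifelse(sij == expd, 1, 0))
  (sij - expd) / (mx - expd)
}
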