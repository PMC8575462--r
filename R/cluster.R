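#' DBSCAN on a precomputed distance matrix
#'
#' Classic density-based clustering: a point is a core point when its
#' eps-neighbourhood (itself included) holds at least \code{minPts} points;
#' clusters are the density-connected components of core points; a non-core
#' point within eps of a core point is a border point and joins the cluster
#' of its lowest-indexed core neighbour (a deterministic tie rule); all
#' remaining points are noise.  Implemented here because the analysis needs
#' DBSCAN under a custom torsion metric; checked against a definitional
#' brute-force oracle in the test suite.
#'
#' @param D symmetric distance matrix.
#' @param eps neighbourhood radius (same units as \code{D}), > 0.
#' @param minPts minimum neighbourhood size for a core point, >= 1.
#' @return integer vector of cluster labels, 0 = noise; clusters are
#'   numbered 1..k in order of their lowest-indexed core member.
#' @export
dbscanLabels <- function(D, eps, minPts) {
  if (!is.matrix(D) || nrow(D) != ncol(D))
    stop("'D' must be a square distance matrix")
  if (!is.numeric(eps) || length(eps) != 1L || eps <= 0)
    stop("'eps' must be a single positive number")
  if (!is.numeric(minPts) || length(minPts) != 1L || minPts < 1)
    stop("'minPts' must be >= 1")
  n <- nrow(D)
  inEps <- D <= eps
  core <- which(rowSums(inEps) >= minPts)
  labels <- integer(n)
  cl <- 0L
  for (p in core) {
    if (labels[p] != 0L) next
    cl <- cl + 1L
    labels[p] <- cl
    frontier <- p
    while (length(frontier)) {
      nxt <- integer(0)
      for (q in frontier) {
        reach <- intersect(which(inEps[q, ]), core)
        new <- reach[labels[reach] == 0L]
        labels[new] <- cl
        nxt <- c(nxt, new)
      }
      frontier <- nxt
    }
  }
  for (p in setdiff(seq_len(n), core)) {
    nb <- intersect(which(inEps[p, ]), core)
    if (length(nb)) labels[p] <- labels[min(nb)]
  }
  labels
}

#' Cluster fragment conformers by backbone dihedrals
#'
#' Computes all pairwise [dihedralDistance()] values and clusters with
#' [dbscanLabels()].  The eps / minPts defaults (60 degrees, 5) are package
#' defaults chosen to merge thermal variation within a backbone class while
#' separating secondary-structure classes; both are echoed in the result.
#'
#' @param fragments list of [PeptideFragment-class] objects.
#' @param eps DBSCAN radius in degrees.
#' @param minPts DBSCAN minimum neighbourhood size.
#' @param coreOnly compare core residues only (see [dihedralDistance()]).
#' @return list with \code{labels} (0 = noise), \code{distances} (matrix),
#'   \code{eps}, \code{minPts}.
#' @export
clusterFragments <- function(fragments, eps = 60, minPts = 5,
                             coreOnly = TRUE) {
  if (length(fragments) == 0L) stop("no fragments to cluster")
  profiles <- lapply(fragments, backboneDihedrals)
  n <- length(profiles)
  D <- matrix(0, n, n)
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- dihedralDistance(profiles[[i]], profiles[[j]],
                                             coreOnly = coreOnly)
    }
  }
  labels <- dbscanLabels(D, eps = eps, minPts = minPts)
  message(sprintf("DBSCAN: eps=%g deg, minPts=%d -> %d cluster(s), %d noise",
                  eps, minPts, max(labels), sum(labels == 0L)))
  list(labels = labels, distances = D, eps = eps, minPts = minPts)
}

#' Select the reference fragment from a clustering
#'
#' Picks the largest cluster, then the member whose source structure has the
#' numerically lowest resolution.  Ties between equal-sized clusters go to
#' the cluster whose best member has the lower resolution, then
#' lexicographic fragment id; members without a resolution (e.g. NMR
#' models) rank last.
#'
#' @param fragments the fragment list that was clustered.
#' @param labels integer labels from [clusterFragments()] (its
#'   \code{$labels}), 0 = noise.
#' @return the selected [PeptideFragment-class].
#' @export
selectReference <- function(fragments, labels) {
  if (is.list(labels) && !is.null(labels$labels)) labels <- labels$labels
  stopifnot(length(fragments) == length(labels))
  if (all(labels == 0L)) stop("all fragments are noise; no cluster to pick")
  res <- vapply(fragments, function(f)
    if (is.finite(f@resolution)) f@resolution else Inf, numeric(1))
  ids <- vapply(fragments, function(f) f@id, character(1))
  sizes <- table(labels[labels != 0L])
  best <- NULL
  for (cl in as.integer(names(sizes))) {
    mem <- which(labels == cl)
    ord <- mem[order(res[mem], ids[mem])]
    cand <- list(size = length(mem), res = res[ord[1]],
                 id = ids[ord[1]], idx = ord[1])
    if (is.null(best) ||
        cand$size > best$size ||
        (cand$size == best$size && cand$res < best$res) ||
        (cand$size == best$size && cand$res == best$res &&
         cand$id < best$id))
      best <- cand
  }
  fragments[[best$idx]]
}
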