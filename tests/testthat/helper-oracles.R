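## Independent brute-force oracles used to validate the fast implementations.

AA20h <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AAWILDh <- c(AA20h, "X")

## Literal motif-match oracle: enumerates every start position and every gap
## assignment, checking element membership character by character, then
## deduplicates to one hit per (phospho_pos, anchor_pos) pair.
oracleScan <- function(pattern, sequence) {
  chars <- strsplit(sequence, "")[[1]]
  L <- length(chars)
  el <- pattern@elements
  gapIdx <- which(vapply(el, function(e) e$type == "gap", logical(1)))
  grids <- if (length(gapIdx)) {
    as.matrix(expand.grid(lapply(gapIdx, function(i)
      seq.int(el[[i]]$min, el[[i]]$max))))
  } else matrix(integer(0), nrow = 1)
  pairs <- list()
  for (s in seq_len(L)) {
    for (r in seq_len(nrow(grids))) {
      pos <- s; ok <- TRUE; ph <- NA_integer_; an <- NA_integer_
      gi <- 0L
      for (k in seq_along(el)) {
        e <- el[[k]]
        if (e$type == "gap") {
          gi <- gi + 1L
          g <- grids[r, gi]
          if (pos + g - 1L > L) { ok <- FALSE; break }
          if (g > 0 && !all(chars[pos:(pos + g - 1L)] %in% AAWILDh)) {
            ok <- FALSE; break
          }
          pos <- pos + g
        } else {
          if (pos > L) { ok <- FALSE; break }
          ch <- chars[pos]
          good <- switch(e$type,
            wild = ch %in% AAWILDh,
            fixed = ch == e$residues,
            class = ch %in% e$residues)
          if (!good) { ok <- FALSE; break }
          if (k == pattern@phosphoIndex) ph <- pos
          if (!is.na(pattern@anchorIndex) && k == pattern@anchorIndex)
            an <- pos
          pos <- pos + 1L
        }
      }
      if (ok) pairs[[length(pairs) + 1L]] <- c(ph, an)
    }
  }
  if (length(pairs) == 0L)
    return(matrix(integer(0), 0, 2,
                  dimnames = list(NULL, c("phospho", "anchor"))))
  m <- unique(do.call(rbind, pairs))
  m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
  colnames(m) <- c("phospho", "anchor")
  m
}

## Definitional DBSCAN oracle: neighbourhoods, core points, transitive
## closure of core-core reachability, border points assigned to the cluster
## of their lowest-indexed core neighbour.
oracleDbscan <- function(D, eps, minPts) {
  n <- nrow(D)
  inE <- D <= eps
  core <- which(rowSums(inE) >= minPts)
  labels <- integer(n)
  if (length(core)) {
    reach <- inE[core, core, drop = FALSE]
    diag(reach) <- TRUE
    repeat {
      nxt <- (reach %*% reach) > 0
      if (identical(nxt, reach)) break
      reach <- nxt
    }
    comp <- rep(NA_integer_, length(core))
    cl <- 0L
    for (i in seq_along(core)) {
      if (!is.na(comp[i])) next
      cl <- cl + 1L
      comp[which(reach[i, ])] <- cl
    }
    labels[core] <- comp
    for (p in setdiff(seq_len(n), core)) {
      nb <- core[inE[p, core]]
      if (length(nb)) labels[p] <- labels[min(nb)]
    }
  }
  labels
}

## Dihedral sets for the builder: extended strand / alpha helix / cis-rich
extendedAngles <- function(n) cbind(phi = rep(-135, n), psi = rep(135, n),
                                    omega = rep(180, n))
helixAngles <- function(n) cbind(phi = rep(-57, n), psi = rep(-47, n),
                                 omega = rep(180, n))

## A small conformer set with known labels, shared across tests
makeLibrary <- function(membersPerCluster = 6, noiseSd = 5, seed = 421) {
  genConformerLibrary(list(extendedAngles(9), helixAngles(9)),
                      membersPerCluster, noiseSd, "GEPLMHPRG", seed = seed)
}

## all pairwise Euclidean distances between rows of two matrices
crossDist <- function(a, b) {
  a <- rbind(a); b <- rbind(b)
  out <- matrix(0, nrow(a), nrow(b))
  for (i in seq_len(nrow(a)))
    out[i, ] <- sqrt(colSums((t(b) - a[i, ])^2))
  out
}

## circular angle difference in degrees, wrapped to [0, 180]
wrapAngleDiff <- function(a, b) abs(((a - b + 180) %% 360) - 180)

randomRotationMatrix <- function() {
  q <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(q) %*% diag(sign(diag(qr.R(q))))
  if (det(Q) < 0) Q[, 3] <- -Q[, 3]
  Q
}
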