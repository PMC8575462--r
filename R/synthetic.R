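#' Ideal backbone stereochemistry for the peptide builder
#'
#' Bond lengths (Angstrom) and bond angles (degrees) used by
#' [buildPeptide()], plus the stub geometry used to attach the Glu OE and
#' Arg NH pseudo-atoms.  These are standard implementation constants,
#' recorded in generator truth records so built fixtures are reproducible.
#'
#' @return named list of constants.
#' @export
builderGeometry <- function() {
  list(bNCA = 1.458, bCAC = 1.525, bCN = 1.329, bCO = 1.231,
       aNCAC = 111.2, aCACN = 116.2, aCNCA = 121.7, aCACO = 120.5,
       bCACB = 1.53, aNCACB = 110.5, tCNCACB = 123.0,
       ## pseudo side-chain reach (CA to carboxylate O / guanidinium N
       ## along the CA->CB direction) emulating extended Glu/Arg side
       ## chains, and the O-O / N-N separation within each pair
       stubReachGlu = 4.9, stubReachArg = 7.0, stubSep = 2.2)
}

# place atom D given A-B-C with bond |CD|, angle B-C-D, torsion A-B-C-D
# (standard internal-coordinate / NeRF step)
placeAtom <- function(A, B, C, bond, angle, torsion) {
  if (!(bond > 0)) stop("bond length must be positive")
  if (!(angle > 0 && angle < 180))
    stop("bond angle must be in (0, 180) degrees")
  ang <- angle * pi / 180; tor <- torsion * pi / 180
  bc <- unitv(C - B)
  n <- c((B - A)[2] * bc[3] - (B - A)[3] * bc[2],
         (B - A)[3] * bc[1] - (B - A)[1] * bc[3],
         (B - A)[1] * bc[2] - (B - A)[2] * bc[1])
  n <- unitv(n)
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(tor),
          -bond * sin(ang) * sin(tor))
  C + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Build a peptide structure from backbone dihedrals
#'
#' Sequential internal-coordinate construction: residue i+1 is placed from
#' residue i using psi(i), omega(i) and phi(i+1) with the ideal
#' stereochemistry of [builderGeometry()].  Carbonyl oxygens are placed anti
#' to the next amide nitrogen.  Glu and Arg residues receive OE1/OE2 and
#' NH1/NH2 pseudo-atoms at fixed stub geometry (rigid with the backbone) so
#' that built conformers carry the atoms the mining and fitting steps
#' measure; no other side-chain atoms are generated.
#'
#' @param dihedrals n x 3 matrix (columns phi, psi, omega, degrees); phi of
#'   the first row and psi/omega of the last row are ignored.
#' @param sequence 1-letter amino-acid string of length n.
#' @param geometry constants from [builderGeometry()].
#' @param id,chain identifiers for the output structure.
#' @param resolution recorded resolution (NA for a pure fixture).
#' @return a [PeptideStructure-class], re-readable by the mining module.
#' @export
buildPeptide <- function(dihedrals, sequence, geometry = builderGeometry(),
                         id = "BUILT", chain = "A",
                         resolution = NA_real_) {
  seqChars <- strsplit(sequence, "")[[1]]
  n <- length(seqChars)
  dihedrals <- rbind(dihedrals)
  if (nrow(dihedrals) != n)
    stop("sequence length (", n, ") must equal number of dihedral rows (",
         nrow(dihedrals), ")")
  if (!all(seqChars %in% names(AA123)))
    stop("sequence must use the 20 standard 1-letter codes")
  g <- geometry
  stopifnot(g$bNCA > 0, g$bCAC > 0, g$bCN > 0)
  N <- matrix(NA_real_, n, 3); CA <- N; Cc <- N; O <- N
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$bNCA, 0, 0)
  a <- g$aNCAC * pi / 180
  Cc[1, ] <- CA[1, ] + g$bCAC * c(-cos(a), sin(a), 0)
  for (i in seq_len(n - 1)) {
    psi <- dihedrals[i, 2]; omg <- dihedrals[i, 3]
    phi <- dihedrals[i + 1, 1]
    if (anyNA(c(psi, omg, phi)))
      stop("psi/omega of residue ", i, " and phi of residue ", i + 1,
           " must be defined")
    N[i + 1, ] <- placeAtom(N[i, ], CA[i, ], Cc[i, ], g$bCN, g$aCACN, psi)
    CA[i + 1, ] <- placeAtom(CA[i, ], Cc[i, ], N[i + 1, ], g$bNCA,
                             g$aCNCA, omg)
    Cc[i + 1, ] <- placeAtom(Cc[i, ], N[i + 1, ], CA[i + 1, ], g$bCAC,
                             g$aNCAC, phi)
  }
  for (i in seq_len(n)) {
    tor <- if (i < n) dihedrals[i, 2] + 180 else -45
    O[i, ] <- placeAtom(N[i, ], CA[i, ], Cc[i, ], g$bCO, g$aCACO, tor)
  }
  rows <- list()
  addRow <- function(i, elety, v, res3) {
    rows[[length(rows) + 1L]] <<- data.frame(
      chain = chain, resno = i, insert = "", resid = res3,
      elety = elety, element = substr(elety, 1, 1),
      x = v[1], y = v[2], z = v[3], occ = 1, stringsAsFactors = FALSE)
  }
  for (i in seq_len(n)) {
    res3 <- AA123[[seqChars[i]]]
    addRow(i, "N", N[i, ], res3)
    addRow(i, "CA", CA[i, ], res3)
    addRow(i, "C", Cc[i, ], res3)
    addRow(i, "O", O[i, ], res3)
    if (seqChars[i] %in% c("E", "R")) {
      CB <- placeAtom(Cc[i, ], N[i, ], CA[i, ], g$bCACB, g$aNCACB,
                      g$tCNCACB)
      addRow(i, "CB", CB, res3)
      reach <- if (seqChars[i] == "E") g$stubReachGlu else g$stubReachArg
      nm <- if (seqChars[i] == "E") c("OE1", "OE2") else c("NH1", "NH2")
      u <- unitv(CB - CA[i, ])
      ax <- Cc[i, ] - N[i, ]
      w <- unitv(c(u[2] * ax[3] - u[3] * ax[2],
                   u[3] * ax[1] - u[1] * ax[3],
                   u[1] * ax[2] - u[2] * ax[1]))
      t1 <- CA[i, ] + reach * u
      addRow(i, nm[1], t1, res3)
      addRow(i, nm[2], t1 + g$stubSep * w, res3)
    }
  }
  peptideStructure(do.call(rbind, rows), id = id, resolution = resolution)
}

# instantiate one string from the pattern language; returns the string and
# the local phospho/anchor offsets (1-based within the instance)
sampleInstance <- function(pattern) {
  el <- pattern@elements
  parts <- character(length(el)); lens <- integer(length(el))
  for (i in seq_along(el)) {
    e <- el[[i]]
    parts[i] <- switch(e$type,
      fixed = e$residues,
      class = sample(e$residues, 1L),
      wild  = sample(AA20, 1L),
      gap   = {
        gl <- sample(seq.int(e$min, e$max), 1L)
        paste(sample(AA20, gl, replace = TRUE), collapse = "")
      })
    lens[i] <- nchar(parts[i])
  }
  phOff <- if (pattern@phosphoIndex > 1L)
    sum(lens[seq_len(pattern@phosphoIndex - 1L)]) + 1L else 1L
  anOff <- if (!is.na(pattern@anchorIndex)) {
    if (pattern@anchorIndex > 1L)
      sum(lens[seq_len(pattern@anchorIndex - 1L)]) + 1L else 1L
  } else NA_integer_
  list(instance = paste(parts, collapse = ""), phosphoOffset = phOff,
       anchorOffset = anOff)
}

#' Generate a synthetic proteome with planted motif instances
#'
#' Background sequences are drawn i.i.d. from \code{residueFreqs} with
#' lengths uniform over \code{lengthRange}; each protein independently
#' receives one planted pattern instance with probability \code{plantRate}
#' (instance sampled uniformly from the pattern's language: gap length
#' uniform over its bounds, class/wildcard letters uniform), written over
#' the background at a uniform position.  The truth record lists every
#' plant and, for convenience, the full scanner hit table of the emitted
#' proteome (so chance background hits are recorded too).
#'
#' @param nProteins number of proteins.
#' @param pattern a [MotifPattern-class].
#' @param plantRate per-protein plant probability in [0, 1].
#' @param lengthRange integer range of sequence lengths.
#' @param residueFreqs named numeric vector over the 20 residues summing to
#'   1; \code{NULL} = uniform.  \code{"human"} selects a human-like
#'   composition preset.
#' @param seed integer seed; same seed, same output, byte for byte.
#' @param idPrefix protein id prefix.
#' @return list with \code{proteome} (named character vector) and
#'   \code{truth} (list: generator, seed, parameters, plants data.frame,
#'   allHits data.frame).
#' @export
genProteome <- function(nProteins, pattern, plantRate,
                        lengthRange = c(200L, 400L), residueFreqs = NULL,
                        seed, idPrefix = "SYNP") {
  stopifnot(nProteins >= 1L, plantRate >= 0, plantRate <= 1)
  if (identical(residueFreqs, "human")) residueFreqs <- humanResidueFreqs()
  if (is.null(residueFreqs))
    residueFreqs <- setNames(rep(1 / 20, 20), AA20)
  stopifnot(abs(sum(residueFreqs) - 1) < 1e-6,
            all(names(residueFreqs) %in% AA20))
  maxInst <- sum(vapply(pattern@elements, function(e)
    if (e$type == "gap") e$max else 1L, integer(1)))
  if (lengthRange[1] < maxInst)
    stop("minimum sequence length is shorter than the longest pattern ",
         "instance (", maxInst, "); pattern cannot be planted")
  withSeed(seed, {
    seqs <- character(nProteins)
    plants <- list()
    ids <- sprintf("%s%05d", idPrefix, seq_len(nProteins))
    for (i in seq_len(nProteins)) {
      L <- sample(seq.int(lengthRange[1], lengthRange[2]), 1L)
      s <- paste(sample(names(residueFreqs), L, replace = TRUE,
                        prob = residueFreqs), collapse = "")
      if (runif(1) < plantRate) {
        inst <- sampleInstance(pattern)
        k <- nchar(inst$instance)
        pos <- sample.int(L - k + 1L, 1L)
        s <- paste0(substr(s, 1, pos - 1L), inst$instance,
                    substr(s, pos + k, L))
        plants[[length(plants) + 1L]] <- data.frame(
          protein_id = ids[i], start = pos, end = pos + k - 1L,
          phospho_pos = pos + inst$phosphoOffset - 1L,
          anchor_pos = pos + inst$anchorOffset - 1L,
          instance = inst$instance, stringsAsFactors = FALSE)
      }
      seqs[i] <- s
    }
    proteome <- setNames(seqs, ids)
    plantsDf <- if (length(plants)) do.call(rbind, plants) else
      data.frame(protein_id = character(), start = integer(),
                 end = integer(), phospho_pos = integer(),
                 anchor_pos = integer(), instance = character())
    allHits <- scanProteome(pattern, proteome)$hits
    list(proteome = proteome,
         truth = list(generator = "genProteome", seed = seed,
                      parameters = list(nProteins = nProteins,
                                        pattern = formatPattern(pattern),
                                        plantRate = plantRate,
                                        lengthRange = lengthRange),
                      plants = plantsDf, allHits = allHits))
  })
}

#' Human-like amino-acid background frequencies
#'
#' Approximate residue composition of the human proteome, available as a
#' named preset for [genProteome()].
#' @return named numeric vector summing to 1.
#' @export
humanResidueFreqs <- function() {
  f <- c(A = 7.0, C = 2.3, D = 4.7, E = 7.1, F = 3.7, G = 6.6, H = 2.6,
         I = 4.3, K = 5.7, L = 10.0, M = 2.1, N = 3.6, P = 6.3, Q = 4.8,
         R = 5.6, S = 8.3, T = 5.3, V = 6.0, W = 1.2, Y = 2.7)
  f / sum(f)
}

#' Sample an interactor set with controlled motif enrichment
#'
#' Draws \code{setSize} proteins without replacement, weighting
#' motif-positive proteins by \code{enrichmentFactor} against 1 for
#' negatives.  Factor 1 reproduces the hypergeometric null (used for
#' calibration); \code{Inf} takes positives first.
#'
#' @param allIds background protein ids.
#' @param positiveIds ids of motif-positive proteins (subset of
#'   \code{allIds}).
#' @param enrichmentFactor >= 0 selection weight for positives.
#' @param setSize target set size.
#' @param seed integer seed.
#' @return list with \code{ids} and \code{truth}.
#' @export
genInteractorSets <- function(allIds, positiveIds, enrichmentFactor,
                              setSize, seed) {
  stopifnot(setSize >= 1L, setSize <= length(allIds),
            enrichmentFactor >= 0, all(positiveIds %in% allIds))
  pos <- allIds %in% positiveIds
  withSeed(seed, {
    ids <- if (is.infinite(enrichmentFactor)) {
      nPos <- sum(pos)
      if (nPos >= setSize) sample(allIds[pos], setSize)
      else c(allIds[pos], sample(allIds[!pos], setSize - nPos))
    } else {
      w <- ifelse(pos, enrichmentFactor, 1)
      if (sum(w > 0) < setSize)
        stop("infeasible composition: not enough selectable proteins")
      sample(allIds, setSize, prob = w)
    }
    list(ids = ids,
         truth = list(generator = "genInteractorSets", seed = seed,
                      parameters = list(enrichmentFactor = enrichmentFactor,
                                        setSize = setSize),
                      nPositiveSelected = sum(ids %in% positiveIds)))
  })
}

#' Generate a conformer library from dihedral cluster centres
#'
#' Each member's backbone dihedrals are its cluster centre plus wrapped
#' Gaussian angular noise (mod 360, re-centred to (-180, 180]); members are
#' built with [buildPeptide()] and stamped with a synthetic resolution drawn
#' uniformly from \code{resolutionRange}.  Truth records cluster labels and
#' the exact angles.
#'
#' @param centres list of n x 3 dihedral matrices (one per cluster).
#' @param membersPerCluster members per centre (recycled).
#' @param noiseSd angular noise standard deviation in degrees (>= 0).
#' @param sequence peptide sequence shared by all members.
#' @param seed integer seed.
#' @param resolutionRange synthetic resolution range in Angstrom.
#' @param dir when non-NULL, members are also written as PDB files here.
#' @return list with \code{structures} (list of
#'   [PeptideStructure-class]), \code{truth} (labels, exact dihedrals,
#'   parameters).
#' @export
genConformerLibrary <- function(centres, membersPerCluster, noiseSd,
                                sequence, seed,
                                resolutionRange = c(1.5, 2.8),
                                dir = NULL) {
  stopifnot(noiseSd >= 0, length(centres) >= 1L)
  membersPerCluster <- rep_len(membersPerCluster, length(centres))
  withSeed(seed, {
    structures <- list(); labels <- integer(0); dihedrals <- list()
    for (cl in seq_along(centres)) {
      ctr <- rbind(centres[[cl]])
      for (m in seq_len(membersPerCluster[cl])) {
        ang <- wrapAngle(ctr + matrix(rnorm(length(ctr), 0, noiseSd),
                                      nrow(ctr), 3))
        id <- sprintf("SYNC%02dM%03d", cl, m)
        res <- runif(1, resolutionRange[1], resolutionRange[2])
        structures[[length(structures) + 1L]] <-
          buildPeptide(ang, sequence, id = id, resolution = res)
        labels <- c(labels, cl)
        dihedrals[[length(dihedrals) + 1L]] <- ang
      }
    }
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      for (s in structures)
        writeStructure(s, file.path(dir, paste0(s@id, ".pdb")))
    }
    list(structures = structures,
         truth = list(generator = "genConformerLibrary", seed = seed,
                      parameters = list(membersPerCluster = membersPerCluster,
                                        noiseSd = noiseSd,
                                        sequence = sequence),
                      labels = labels, dihedrals = dihedrals))
  })
}

# proper random rotation matrix (QR of a Gaussian matrix, sign-fixed)
randomRotation <- function() {
  qr. <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr.)
  Q <- Q %*% diag(sign(diag(qr.R(qr.))))
  if (det(Q) < 0) Q[, 3] <- -Q[, 3]
  Q
}

# base-frame anchor geometry: OE pair, NH pair at exactly `span`,
# OD pair behind the NH pair at exactly `contact`, Mn pair near the OE side
anchorGeometry <- function(span, contact) {
  oe <- rbind(OE1 = c(0, 0, 0), OE2 = c(-1.0, 2.0, 0))
  nh <- rbind(NH1 = c(span, 0, 0), NH2 = c(span, 2.2, 0))
  od <- rbind(OD1 = nh[1, ] + c(contact, 0, 0),
              OD2 = nh[2, ] + c(contact, 0, 0))
  mn <- rbind(c(-2.2, 0.4, 0.5), c(-2.2, -2.4, 0.5))
  list(oe = oe, nh = nh, od = od, mn = mn)
}

#' Generate a mock anchor scene
#'
#' Places the Mn pair, Asp OD pair, Glu OE pair and Arg NH pair so that the
#' minimum OE x NH distance equals \code{span} exactly and the minimum
#' NH-OD distance equals \code{contactDistance} exactly, then applies a
#' seeded random global rotation and translation.
#'
#' @param span Angstrom, > 0 (the published two-fragment geometry spans
#'   27.5).
#' @param contactDistance Angstrom, > 0.
#' @param seed integer seed.
#' @return list with \code{scene} (an [AnchorScene-class]) and \code{truth}.
#' @export
genAnchorScene <- function(span = 27.5, contactDistance = 3.0, seed) {
  if (!(span > 0)) stop("'span' must be positive")
  if (!(contactDistance > 0)) stop("'contactDistance' must be positive")
  withSeed(seed, {
    g <- anchorGeometry(span, contactDistance)
    R <- randomRotation(); tr <- runif(3, -20, 20)
    mv <- function(m) unname(sweep(m %*% t(R), 2, -tr))
    scene <- new("AnchorScene",
                 mnPositions = mv(g$mn), aspOd = mv(g$od),
                 gluOeRef = mv(g$oe), argNhRef = mv(g$nh),
                 contextAtoms = matrix(numeric(0), 0, 3),
                 contactDistance = contactDistance,
                 meta = list(generator = "genAnchorScene", seed = seed))
    list(scene = scene,
         truth = list(generator = "genAnchorScene", seed = seed,
                      span = span, contactDistance = contactDistance))
  })
}

#' Generate a mock holoenzyme/donor complex for assembly tests
#'
#' Builds a synthetic receptor ("holoenzyme") carrying a di-Mn centre with
#' coordinating Asp residues, an anchor Asp (author number
#' \code{aspResno}) whose carboxylate sits so that an Arg placed against it
#' at \code{contactDistance} spans exactly \code{span} to the
#' Glu-phosphomimetic reference, and a receptor wall behind the Asp that
#' leaves only the active-site approach open.  The donor structure holds a
#' copy of the same metal centre plus a Glu with OE1/OE2 at the reference
#' positions, displaced by a seeded rigid motion that
#' [assembleAnchorScene()] must recover.  Everything is synthetic: the mock
#' reproduces the geometry of the published two-fragment model, not its
#' coordinates.
#'
#' @param span designed min OE x NH span in Angstrom.
#' @param contactDistance designed NH-OD contact in Angstrom.
#' @param seed integer seed.
#' @param aspResno author number given to the anchor Asp (default 197).
#' @return list with \code{holoenzyme}, \code{donor}
#'   ([PeptideStructure-class]) and \code{truth} (designed span/contact and
#'   the reference positions in the holoenzyme frame).
#' @export
genMockComplex <- function(span = 27.5, contactDistance = 3.0, seed,
                           aspResno = 197) {
  withSeed(seed, {
    g <- anchorGeometry(span, contactDistance)
    R0 <- randomRotation(); t0 <- runif(3, -10, 10)
    mv <- function(m) sweep(rbind(m) %*% t(R0), 2, -t0)

    rows <- list(); eleno <- 0L
    addAtom <- function(chain, resno, resid, elety, element, v) {
      rows[[length(rows) + 1L]] <<- data.frame(
        chain = chain, resno = resno, insert = "", resid = resid,
        elety = elety, element = element, x = v[1], y = v[2], z = v[3],
        occ = 1, stringsAsFactors = FALSE)
    }
    mn <- mv(g$mn); od <- mv(g$od); oe <- mv(g$oe); nh <- mv(g$nh)
    ## di-Mn centre with three coordinating Asp per ion
    addAtom("C", 901, "MN", "MN", "MN", mn[1, ])
    addAtom("C", 902, "MN", "MN", "MN", mn[2, ])
    resno <- 100L
    for (k in 1:2) {
      for (j in 0:2) {
        th <- (j * 120 + 15) * pi / 180
        dir <- as.numeric(c(cos(th), sin(th), 0.35 * (-1)^j) %*% t(R0))
        dir <- unitv(dir)
        resno <- resno + 1L
        addAtom("C", resno, "ASP", "OD1", "O", mn[k, ] + 2.2 * dir)
        ## distinct CA radii so distance-ranked correspondence is tie-free
        addAtom("C", resno, "ASP", "CA", "C", mn[k, ] + (3.5 + 0.2 * j) * dir)
      }
    }
    ## anchor Asp: carboxylate at the designed OD positions; stub CB/CG
    back <- unitv(od[1, ] - nh[1, ])  # away from the approach side
    addAtom("B", aspResno, "ASP", "OD1", "O", od[1, ])
    addAtom("B", aspResno, "ASP", "OD2", "O", od[2, ])
    cg <- (od[1, ] + od[2, ]) / 2 + back * 1.1
    addAtom("B", aspResno, "ASP", "CG", "C", cg)
    addAtom("B", aspResno, "ASP", "CB", "C", cg + back * 1.5)
    addAtom("B", aspResno, "ASP", "CA", "C", cg + back * 2.9)
    ## receptor wall behind the Asp so only the approach cone is open
    perp1 <- unitv(od[2, ] - od[1, ])
    perp2 <- unitv(c(perp1[2] * back[3] - perp1[3] * back[2],
                     perp1[3] * back[1] - perp1[1] * back[3],
                     perp1[1] * back[2] - perp1[2] * back[1]))
    resno <- 300L
    for (u in seq(-6, 6, by = 2)) for (v in seq(-6, 6, by = 2)) {
      resno <- resno + 1L
      p <- cg + back * 2.5 + perp1 * u + perp2 * v
      addAtom("B", resno, "GLY", "CA", "C", p)
    }
    holo <- peptideStructure(do.call(rbind, rows), id = "SYNHOLO",
                             resolution = 2.0)

    ## donor: metal centre copy + phosphomimetic Glu, displaced rigidly
    R1 <- randomRotation(); t1 <- runif(3, -15, 15)
    mv1 <- function(m) sweep(rbind(m) %*% t(R1), 2, -t1)
    drows <- list()
    addD <- function(chain, resno, resid, elety, element, v) {
      drows[[length(drows) + 1L]] <<- data.frame(
        chain = chain, resno = resno, insert = "", resid = resid,
        elety = elety, element = element, x = v[1], y = v[2], z = v[3],
        occ = 1, stringsAsFactors = FALSE)
    }
    holoCat <- do.call(rbind, rows)
    holoCat <- holoCat[holoCat$chain == "C", , drop = FALSE]
    for (i in seq_len(nrow(holoCat))) {
      v <- mv1(as.numeric(holoCat[i, c("x", "y", "z")]))
      addD("C", holoCat$resno[i], holoCat$resid[i], holoCat$elety[i],
           holoCat$element[i], v)
    }
    addD("P", 500, "GLU", "OE1", "O", mv1(oe[1, ]))
    addD("P", 500, "GLU", "OE2", "O", mv1(oe[2, ]))
    addD("P", 500, "GLU", "CD", "C",
         mv1((oe[1, ] + oe[2, ]) / 2 + c(0, 0, 1.2) %*% t(R0)))
    addD("P", 500, "GLU", "CA", "C",
         mv1((oe[1, ] + oe[2, ]) / 2 + c(0, 0, 3.2) %*% t(R0)))
    donor <- peptideStructure(do.call(rbind, drows), id = "SYNDONOR",
                              resolution = 2.2)
    list(holoenzyme = holo, donor = donor,
         truth = list(generator = "genMockComplex", seed = seed,
                      span = span, contactDistance = contactDistance,
                      gluOeRef = oe, argNhRef = nh,
                      donorMotion = list(rotation = R1, translation = t1)))
  })
}
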