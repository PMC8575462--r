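MARKED_ORDER <- c("GLU_OE1", "GLU_OE2", "ARG_NH1", "ARG_NH2")

#' Fit a candidate fragment into an anchor scene
#'
#' Superposes the fragment's four anchor atoms (Glu OE1/OE2, Arg NH1/NH2)
#' onto the scene's reference positions by least squares ([superpose()]) and
#' scores the pose: the displacement score is the sum of the residual
#' distances of the four fitted anchor atoms from their references; the
#' pose's Glu-to-metal distances (min over OE atoms, one per Mn2+ ion) and
#' the Arg-to-Asp distance (min NH x OD) are measured in the fitted frame.
#'
#' @param fragment a [PeptideFragment-class] with all four marked anchor
#'   atoms.
#' @param scene an [AnchorScene-class].
#' @return list (a candidate record) with \code{fragmentId},
#'   \code{transform}, \code{displacementScore}, \code{dGluMn} (length 2),
#'   \code{dArgAsp}, \code{threadedSequence} (NA until threading).
#' @export
fitCandidate <- function(fragment, scene) {
  stopifnot(is(fragment, "PeptideFragment"), is(scene, "AnchorScene"))
  m <- fragment@markedAtoms
  if (!all(MARKED_ORDER %in% rownames(m)))
    stop("fragment ", fragment@id, " lacks marked anchor atoms: ",
         paste(setdiff(MARKED_ORDER, rownames(m)), collapse = ", "))
  mobile <- m[MARKED_ORDER, , drop = FALSE]
  target <- rbind(scene@gluOeRef, scene@argNhRef)
  fit <- superpose(mobile, target)
  moved <- applyTransform(fit$transform, mobile)
  disp <- sum(sqrt(rowSums((moved - target)^2)))
  oe <- moved[1:2, , drop = FALSE]; nh <- moved[3:4, , drop = FALSE]
  dGluMn <- apply(crossDist(scene@mnPositions, oe), 1, min)
  dArgAsp <- min(crossDist(nh, scene@aspOd))
  list(fragmentId = fragment@id, transform = fit$transform,
       displacementScore = disp, dGluMn = as.numeric(dGluMn),
       dArgAsp = dArgAsp, threadedSequence = NA_character_)
}

#' Rank fitted candidates and pick the final model
#'
#' Sorts candidates by ascending displacement score (ties by fragment id,
#' giving a total order independent of input order), retains the best
#' \code{topK}, and selects as final the retained candidate minimising the
#' combined anchor distance: (min over the two metals of the Glu OE
#' distance) + (min Arg NH to Asp OD distance).
#'
#' @param candidates list of records from [fitCandidate()].
#' @param topK how many to retain (default 20).
#' @return list with \code{table} (data.frame: fragment_id,
#'   displacement_score, d_glu_mn1, d_glu_mn2, d_arg_asp, combined, rank),
#'   \code{retained} (the records, ranked) and \code{best} (one record).
#' @export
rankCandidates <- function(candidates, topK = 20) {
  if (length(candidates) == 0L) stop("no candidates to rank")
  stopifnot(topK >= 1)
  df <- data.frame(
    fragment_id = vapply(candidates, `[[`, character(1), "fragmentId"),
    displacement_score = vapply(candidates, `[[`, numeric(1),
                                "displacementScore"),
    d_glu_mn1 = vapply(candidates, function(x) x$dGluMn[1], numeric(1)),
    d_glu_mn2 = vapply(candidates, function(x) x$dGluMn[2], numeric(1)),
    d_arg_asp = vapply(candidates, `[[`, numeric(1), "dArgAsp"),
    stringsAsFactors = FALSE)
  df$combined <- pmin(df$d_glu_mn1, df$d_glu_mn2) + df$d_arg_asp
  ord <- order(df$displacement_score, df$fragment_id)
  df <- df[ord, , drop = FALSE]
  keep <- seq_len(min(topK, nrow(df)))
  df <- df[keep, , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  retained <- candidates[ord][keep]
  bestIdx <- order(df$combined, df$fragment_id)[1]
  list(table = df, retained = retained, best = retained[[bestIdx]])
}

#' Thread a target sequence onto a fragment backbone
#'
#' Renames the fragment's pattern-core residues to the target identities
#' (which must have the same length as the core), renumbers to author
#' numbering starting at \code{offset}, and optionally replaces the wildcard
#' flanks with prefix/suffix extensions built in an extended conformation
#' (phi -135, psi 135, omega 180) continued from the existing backbone.
#' Side chains beyond the anchor Glu OE / Arg NH atoms are not carried
#' (the builder works at backbone + anchor-stub resolution), so anchor-fit
#' scores are unchanged by threading.  With no extensions and an identical
#' target the coordinates are returned unchanged.
#'
#' @param fragment a [PeptideFragment-class].
#' @param targetCore replacement sequence for the core residues.
#' @param prefix,suffix extension sequences (replace the flanks; "" keeps
#'   the original flank residues in place).
#' @param offset author number of the first residue of the threaded peptide.
#' @param geometry backbone stereochemistry from [builderGeometry()].
#' @return a [PeptideFragment-class] for the threaded peptide.
#' @examples
#' \dontrun{
#' threadSequence(frag, "EPLMHPR", prefix = "MPM", suffix = "V",
#'                offset = 612)  # -> "MPMEPLMHPRV", residues 612-622
#' }
#' @export
threadSequence <- function(fragment, targetCore, prefix = "", suffix = "",
                           offset = 1L, geometry = builderGeometry()) {
  stopifnot(is(fragment, "PeptideFragment"))
  core <- fragment@coreSpan
  if (nchar(targetCore) != length(core))
    stop("target core length (", nchar(targetCore),
         ") must equal fragment core length (", length(core), ")")
  n <- nchar(fragment@sequence)
  seqChars <- strsplit(fragment@sequence, "")[[1]]
  extend <- nchar(prefix) > 0L || nchar(suffix) > 0L
  if (extend) {
    keep <- min(core):max(core)
  } else {
    keep <- seq_len(n)
  }
  bb <- fragment@backbone[keep, , , drop = FALSE]
  newChars <- seqChars[keep]
  newChars[match(core, keep)] <- strsplit(targetCore, "")[[1]]

  ext <- function(bbArr, letters, where) {
    if (length(letters) == 0L) return(bbArr)
    g <- geometry
    m <- dim(bbArr)[1]
    for (l in letters) {
      if (where == "suffix") {
        ## continue C-terminally: psi(last)=135, omega=180, phi(new)=-135
        Nn <- placeAtom(bbArr[m, "N", ], bbArr[m, "CA", ], bbArr[m, "C", ],
                        g$bCN, g$aCACN, 135)
        CAn <- placeAtom(bbArr[m, "CA", ], bbArr[m, "C", ], Nn,
                         g$bNCA, g$aCNCA, 180)
        Cn <- placeAtom(bbArr[m, "C", ], Nn, CAn, g$bCAC, g$aNCAC, -135)
        On <- placeAtom(Nn, CAn, Cn, g$bCO, g$aCACO, -45)
        add <- array(rbind(Nn, CAn, Cn, On), dim = c(1, 4, 3))
        bbArr2 <- array(NA_real_, dim = c(m + 1, 4, 3),
                        dimnames = dimnames(bbArr))
        bbArr2[1:m, , ] <- bbArr; bbArr2[m + 1, , ] <- add
        bbArr <- bbArr2; m <- m + 1
      } else {
        ## continue N-terminally (reverse construction)
        Cp <- placeAtom(bbArr[1, "C", ], bbArr[1, "CA", ], bbArr[1, "N", ],
                        g$bCN, g$aCNCA, -135)    # torsion = phi(first)
        CAp <- placeAtom(bbArr[1, "CA", ], bbArr[1, "N", ], Cp,
                         g$bCAC, g$aCACN, 180)   # torsion = omega
        Np <- placeAtom(bbArr[1, "N", ], Cp, CAp, g$bNCA, g$aNCAC, 135)
        Op <- placeAtom(Np, CAp, Cp, g$bCO, g$aCACO, -45)
        add <- array(rbind(Np, CAp, Cp, Op), dim = c(1, 4, 3))
        bbArr2 <- array(NA_real_, dim = c(m + 1, 4, 3),
                        dimnames = dimnames(bbArr))
        bbArr2[2:(m + 1), , ] <- bbArr; bbArr2[1, , ] <- add
        bbArr <- bbArr2; m <- m + 1
      }
    }
    bbArr
  }
  preChars <- if (nchar(prefix)) strsplit(prefix, "")[[1]] else character(0)
  sufChars <- if (nchar(suffix)) strsplit(suffix, "")[[1]] else character(0)
  bb <- ext(bb, sufChars, "suffix")
  bb <- ext(bb, rev(preChars), "prefix")
  allChars <- c(preChars, newChars, sufChars)
  nOut <- length(allChars)
  offset <- as.integer(offset)

  coreOut <- which(seq_len(nOut) %in%
                     (length(preChars) + match(core, keep)))
  new("PeptideFragment",
      id = paste0(fragment@id, "_threaded"),
      structureId = fragment@structureId, chain = fragment@chain,
      resno = offset + seq_len(nOut) - 1L,
      insert = rep("", nOut),
      sequence = paste(allChars, collapse = ""),
      coreSpan = as.integer(coreOut),
      backbone = bb, markedAtoms = fragment@markedAtoms,
      resolution = fragment@resolution)
}

#' Convert a fragment to a writable structure
#'
#' Backbone atoms (plus the anchor OE/NH pseudo-atoms attached to their
#' residues) as a [PeptideStructure-class], e.g. for [writeStructure()].
#'
#' @param fragment a [PeptideFragment-class].
#' @param chain chain id for the output.
#' @return a [PeptideStructure-class].
#' @export
fragmentToStructure <- function(fragment, chain = "P") {
  n <- nchar(fragment@sequence)
  seqChars <- strsplit(fragment@sequence, "")[[1]]
  rows <- list()
  for (i in seq_len(n)) {
    res3 <- if (seqChars[i] %in% names(AA123)) AA123[[seqChars[i]]] else "UNK"
    for (at in BACKBONE) {
      v <- fragment@backbone[i, at, ]
      rows[[length(rows) + 1L]] <- data.frame(
        chain = chain, resno = fragment@resno[i], insert = "",
        resid = res3, elety = at, element = substr(at, 1, 1),
        x = v[1], y = v[2], z = v[3], occ = 1,
        stringsAsFactors = FALSE)
    }
    m <- fragment@markedAtoms
    if (nrow(m)) {
      tagRes <- if (seqChars[i] == "E") "GLU" else
        if (seqChars[i] == "R") "ARG" else NA
      if (!is.na(tagRes)) {
        sel <- grepl(paste0("^", tagRes), rownames(m))
        gluPos <- which(seqChars == "E")[1]
        argPos <- tail(which(seqChars == "R"), 1)
        owner <- if (tagRes == "GLU") gluPos else argPos
        if (length(owner) && !is.na(owner) && owner == i) {
          for (rn in rownames(m)[sel]) {
            at <- sub("^(GLU|ARG)_", "", rn)
            rows[[length(rows) + 1L]] <- data.frame(
              chain = chain, resno = fragment@resno[i], insert = "",
              resid = res3, elety = at, element = substr(at, 1, 1),
              x = m[rn, 1], y = m[rn, 2], z = m[rn, 3], occ = 1,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  peptideStructure(do.call(rbind, rows), id = fragment@id,
                   resolution = fragment@resolution)
}
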