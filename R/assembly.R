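METAL_ELEMENTS <- c("MN", "FE", "ZN", "MG")

# metals + coordinating-residue CA positions for one structure; the metal
# pair is the two metals closest to each other when more than two are present
catalyticSiteAtoms <- function(structure, coordCutoff = 2.6) {
  a <- structure@atoms
  met <- a[a$element %in% METAL_ELEMENTS | a$resid %in% METAL_ELEMENTS, ,
           drop = FALSE]
  if (nrow(met) < 2L)
    stop("structure ", structure@id,
         ": need two metal ions for active-site alignment, found ",
         nrow(met))
  mxyz <- as.matrix(met[, c("x", "y", "z")])
  if (nrow(met) > 2L) {
    d <- crossDist(mxyz, mxyz); diag(d) <- Inf
    ij <- which(d == min(d), arr.ind = TRUE)[1, ]
    mxyz <- mxyz[ij, , drop = FALSE]
  }
  metalChains <- unique(a$chain[a$element %in% METAL_ELEMENTS |
                                  a$resid %in% METAL_ELEMENTS])
  ## coordinating residues are sought only on chains holding a metal: this
  ## keeps substrate/tag peptides (e.g. a phosphomimetic Glu parked in the
  ## active site) out of the alignment atom set
  prot <- a[a$resid %in% names(AA321) & !startsWith(a$element, "H") &
              a$chain %in% metalChains, , drop = FALSE]
  pxyz <- as.matrix(prot[, c("x", "y", "z")])
  caList <- list()
  for (k in 1:2) {
    dd <- sqrt(colSums((t(pxyz) - mxyz[k, ])^2))
    resKey <- with(prot, paste(chain, resno, insert))
    coordRes <- unique(resKey[dd < coordCutoff])
    cas <- do.call(rbind, lapply(coordRes, function(rk) {
      sel <- prot[resKey == rk & prot$elety == "CA", , drop = FALSE]
      if (nrow(sel)) as.numeric(sel[1, c("x", "y", "z")]) else NULL
    }))
    if (is.null(cas)) cas <- matrix(numeric(0), 0, 3)
    ord <- order(sqrt(rowSums(sweep(cas, 2, mxyz[k, ])^2)))
    caList[[k]] <- cas[ord, , drop = FALSE]
  }
  list(metals = mxyz, cas = caList)
}

#' Align a donor phosphatase onto the holoenzyme catalytic subunit
#'
#' Superposes the donor's catalytic di-metal centre onto the holoenzyme's:
#' the paired atom set is the two metals plus the CA atoms of
#' metal-coordinating residues (protein heavy atoms within the cutoff of a
#' metal), each metal's coordinating CAs sorted by distance and truncated to
#' the count shared by both structures.  Both metal pairings are tried and
#' the one with the lower fit RMSD is kept.
#'
#' @param holoenzyme,donor [PeptideStructure-class] objects, each with a
#'   di-metal centre.
#' @param coordCutoff Angstrom; metal-coordination distance (default 2.6).
#' @return list with \code{transform} (donor -> holoenzyme
#'   [RigidTransform-class]) and \code{rmsd}.
#' @export
alignActiveSite <- function(holoenzyme, donor, coordCutoff = 2.6) {
  H <- catalyticSiteAtoms(holoenzyme, coordCutoff)
  D <- catalyticSiteAtoms(donor, coordCutoff)
  tryOrder <- function(ord) {
    mob <- D$metals[ord, , drop = FALSE]
    tar <- H$metals
    for (k in 1:2) {
      m <- min(nrow(D$cas[[ord[k]]]), nrow(H$cas[[k]]))
      if (m > 0) {
        mob <- rbind(mob, D$cas[[ord[k]]][seq_len(m), , drop = FALSE])
        tar <- rbind(tar, H$cas[[k]][seq_len(m), , drop = FALSE])
      }
    }
    if (nrow(mob) < 3L)
      stop("fewer than 3 alignment atoms at the catalytic site")
    superpose(mob, tar)
  }
  f1 <- tryOrder(c(1L, 2L)); f2 <- tryOrder(c(2L, 1L))
  if (f1$rmsd <= f2$rmsd) f1 else f2
}

# direction grid on the unit sphere (theta from +z, step degrees)
directionGrid <- function(step = 10) {
  dirs <- list()
  for (th in seq(0, 180, by = step)) {
    phis <- if (th %in% c(0, 180)) 0 else seq(0, 360 - step, by = step)
    for (ph in phis) {
      t <- th * pi / 180; p <- ph * pi / 180
      dirs[[length(dirs) + 1L]] <- c(sin(t) * cos(p), sin(t) * sin(p),
                                     cos(t))
    }
  }
  do.call(rbind, dirs)
}

#' Place Arg guanidinium nitrogens against an Asp carboxylate
#'
#' Deterministic grid search replacing manual placement: candidate NH1/NH2
#' positions are built bidentately (NH1 offset from OD1 and NH2 from OD2
#' along a common direction at the contact distance) for every direction on
#' an angular grid.  Directions whose realised minimum NH-OD distance drifts
#' from the contact distance (because they point into the carboxylate) are
#' discarded; among the rest, the orientation with the fewest heavy-atom
#' clashes (receptor contacts < 2.5 Angstrom) wins.  Ties are broken toward
#' the \code{approach} direction when one is supplied (the side the peptide
#' spans in from), otherwise by the largest clearance from the receptor,
#' then by grid order.  Context atoms should exclude the Asp residue itself.
#'
#' @param aspOd 2 x 3 matrix of OD1/OD2 coordinates.
#' @param contextAtoms receptor heavy-atom coordinates for clash checks
#'   (matrix, may be NULL/empty).
#' @param contactDistance target min NH-OD distance in Angstrom
#'   (default 3.0).
#' @param gridStep angular grid step in degrees (default 10).
#' @param approach optional length-3 vector; tie-break preference direction.
#' @return list with \code{nh} (2 x 3 matrix, rows NH1/NH2),
#'   \code{direction}, \code{nClashes}, \code{clashFree}; a warning is
#'   emitted when no clash-free orientation exists.
#' @export
placeArgAnchor <- function(aspOd, contextAtoms = NULL, contactDistance = 3.0,
                           gridStep = 10, approach = NULL) {
  stopifnot(all(dim(rbind(aspOd)) == c(2L, 3L)), contactDistance > 0,
            gridStep > 0)
  aspOd <- rbind(aspOd)
  dirs <- directionGrid(gridStep)
  ctx <- if (is.null(contextAtoms) || nrow(rbind(contextAtoms)) == 0L)
    matrix(numeric(0), 0, 3) else rbind(contextAtoms)
  best <- NULL
  app <- if (is.null(approach)) NULL else unitv(approach)
  for (i in seq_len(nrow(dirs))) {
    u <- dirs[i, ]
    nh <- rbind(NH1 = aspOd[1, ] + u * contactDistance,
                NH2 = aspOd[2, ] + u * contactDistance)
    realised <- min(crossDist(nh, aspOd))
    if (realised < contactDistance - 0.05) next
    if (nrow(ctx)) {
      dctx <- crossDist(nh, ctx)
      nCl <- sum(dctx < 2.5)
      clearance <- min(dctx)
    } else {
      nCl <- 0L; clearance <- Inf
    }
    score <- if (!is.null(app)) sum(u * app) else clearance
    cand <- list(nh = nh, direction = u, nClashes = nCl, score = score)
    if (is.null(best) || cand$nClashes < best$nClashes ||
        (cand$nClashes == best$nClashes && cand$score > best$score))
      best <- cand
  }
  if (is.null(best)) stop("no admissible orientation on the search grid")
  if (best$nClashes > 0L)
    warning("no clash-free orientation; least-clash orientation returned (",
            best$nClashes, " contacts < 2.5 Angstrom)")
  list(nh = best$nh, direction = best$direction,
       nClashes = best$nClashes, clashFree = best$nClashes == 0L)
}

# locate an Asp residue's OD1/OD2 (and its atom rows) in a structure
findAspCarboxylate <- function(structure, resno, chain = NULL) {
  a <- structure@atoms
  sel <- a$resid == "ASP" & a$resno == resno
  if (!is.null(chain)) sel <- sel & a$chain == chain
  asp <- a[sel, , drop = FALSE]
  if (nrow(asp) == 0L)
    stop("structure ", structure@id, " has no ASP residue ", resno,
         if (!is.null(chain)) paste0(" in chain ", chain) else "")
  ch <- asp$chain[1]
  asp <- asp[asp$chain == ch, , drop = FALSE]
  od <- asp[asp$elety %in% c("OD1", "OD2"), , drop = FALSE]
  if (nrow(od) != 2L)
    stop("ASP ", resno, " in ", structure@id,
         " lacks a complete OD1/OD2 carboxylate")
  od <- od[order(od$elety), , drop = FALSE]
  list(od = as.matrix(od[, c("x", "y", "z")]), chain = ch,
       aspRows = which(sel & a$chain == ch))
}

#' Assemble the two-fragment anchor scene
#'
#' Builds the placement target for candidate peptides: the Mn2+ pair and the
#' anchor-Asp carboxylate come from the holoenzyme; the Glu-phosphomimetic
#' OE1/OE2 reference comes from the donor structure after [alignActiveSite()]
#' (the donor Glu whose carboxylate lands closest to the metal pair); the
#' Arg NH1/NH2 reference is placed against the Asp with [placeArgAnchor()],
#' approaching from the active-site side.  The span between the OE and NH
#' references is the scene's anchor span.
#'
#' @param holoenzyme [PeptideStructure-class] holding the catalytic di-metal
#'   centre and the regulatory-subunit anchor Asp.
#' @param donor [PeptideStructure-class] carrying the Glu phosphomimetic in
#'   an equivalent active site.
#' @param aspResno author number of the anchor Asp (default 197).
#' @param aspChain chain of the anchor Asp; \code{NULL} finds the first
#'   matching ASP.
#' @param contactDistance NH-OD contact in Angstrom (default 3.0).
#' @param gridStep anchor-placement grid step in degrees (default 10).
#' @return an [AnchorScene-class]; its meta records the alignment rmsd,
#'   donor Glu, and realised span.
#' @export
assembleAnchorScene <- function(holoenzyme, donor, aspResno = 197,
                                aspChain = NULL, contactDistance = 3.0,
                                gridStep = 10) {
  fit <- alignActiveSite(holoenzyme, donor)
  site <- catalyticSiteAtoms(holoenzyme)
  asp <- findAspCarboxylate(holoenzyme, aspResno, aspChain)

  da <- donor@atoms
  glu <- da[da$resid == "GLU" & da$elety %in% c("OE1", "OE2"), ,
            drop = FALSE]
  if (nrow(glu) == 0L)
    stop("donor ", donor@id, " has no Glu OE atoms")
  key <- with(glu, paste(chain, resno, insert))
  bestGlu <- NULL
  for (k in unique(key)) {
    oe <- glu[key == k, , drop = FALSE]
    if (nrow(oe) != 2L) next
    oe <- oe[order(oe$elety), , drop = FALSE]
    moved <- applyTransform(fit$transform,
                            as.matrix(oe[, c("x", "y", "z")]))
    dmin <- min(crossDist(moved, site$metals))
    if (is.null(bestGlu) || dmin < bestGlu$dmin)
      bestGlu <- list(key = k, oe = moved, dmin = dmin)
  }
  if (is.null(bestGlu))
    stop("donor ", donor@id, " has no Glu with a complete OE1/OE2 pair")

  ha <- holoenzyme@atoms
  ctxSel <- !startsWith(ha$element, "H") & ha$resid != "HOH"
  ctxSel[asp$aspRows] <- FALSE
  ctx <- as.matrix(ha[ctxSel, c("x", "y", "z")])
  approach <- colMeans(bestGlu$oe) - colMeans(asp$od)
  arg <- placeArgAnchor(asp$od, contextAtoms = ctx,
                        contactDistance = contactDistance,
                        gridStep = gridStep, approach = approach)

  scene <- new("AnchorScene",
               mnPositions = unname(site$metals), aspOd = unname(asp$od),
               gluOeRef = unname(bestGlu$oe), argNhRef = unname(arg$nh),
               contextAtoms = unname(ctx),
               contactDistance = contactDistance,
               meta = list(holoenzyme = holoenzyme@id, donor = donor@id,
                           alignmentRmsd = fit$rmsd,
                           donorGlu = bestGlu$key,
                           gluToMetal = bestGlu$dmin,
                           argClashFree = arg$clashFree))
  scene@meta$anchorSpan <- endpointSpan(scene)
  scene
}

setMethod("show", "AnchorScene", function(object) {
  cat("AnchorScene\n")
  cat(sprintf("  anchor span (min OE x NH): %.2f Angstrom\n",
              endpointSpan(object)))
  cat(sprintf("  NH-OD contact: %.2f Angstrom; context atoms: %d\n",
              min(crossDist(object@argNhRef, object@aspOd)),
              nrow(object@contextAtoms)))
})

#' Serialise / restore an anchor scene as JSON
#'
#' @param scene an [AnchorScene-class].
#' @param path JSON file.
#' @return \code{writeScene} the path invisibly; \code{readScene} the scene.
#' @export
writeScene <- function(scene, path) {
  stopifnot(is(scene, "AnchorScene"))
  obj <- list(mn_positions = scene@mnPositions, asp_od = scene@aspOd,
              glu_oe_ref = scene@gluOeRef, arg_nh_ref = scene@argNhRef,
              context_atoms = scene@contextAtoms,
              contact_distance = scene@contactDistance,
              meta = scene@meta)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeScene
#' @export
readScene <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  toMat <- function(m) matrix(as.numeric(unlist(m)), ncol = 3,
                              byrow = !is.matrix(m))
  ctx <- if (length(obj$context_atoms)) toMat(obj$context_atoms) else
    matrix(numeric(0), 0, 3)
  new("AnchorScene",
      mnPositions = toMat(obj$mn_positions), aspOd = toMat(obj$asp_od),
      gluOeRef = toMat(obj$glu_oe_ref), argNhRef = toMat(obj$arg_nh_ref),
      contextAtoms = ctx,
      contactDistance = as.numeric(obj$contact_distance),
      meta = as.list(obj$meta))
}
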