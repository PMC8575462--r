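#' @import methods
NULL

#' Parsed short-linear-motif pattern
#'
#' A PROSITE-style pattern over the amino-acid alphabet with fixed residues,
#' residue classes (\code{[RK]}), single-position wildcards (\code{x}) and
#' variable-length gaps (\code{x(m,n)}).  Exactly one element, flagged with a
#' leading \code{p} in the pattern text, is the phosphoacceptor (the Ser/Thr
#' carrying the phosphate targeted for dephosphorylation).  The anchor element
#' is the first basic-residue class (letters drawn from \code{{R,K}}) after the
#' variable gap; it models the conserved Arg/Lys proposed to contact the
#' regulatory-subunit surface (D197 on B55alpha).
#'
#' @slot elements list of parsed elements; each element is a list with
#'   \code{type} one of \code{"fixed"}, \code{"class"}, \code{"wild"},
#'   \code{"gap"}, plus \code{residues} (fixed/class) or \code{min}/\code{max}
#'   (gap) and logical \code{phospho}.
#' @slot phosphoIndex integer index of the phosphoacceptor element.
#' @slot anchorIndex integer index of the basic-anchor element
#'   (\code{NA_integer_} when the pattern has none).
#' @slot source the original pattern string.
#' @seealso [parsePattern()], [formatPattern()], [scanSequence()]
#' @export
setClass("MotifPattern",
  representation(elements = "list",
                 phosphoIndex = "integer",
                 anchorIndex = "integer",
                 source = "character"))

setValidity("MotifPattern", function(object) {
  el <- object@elements
  if (length(el) == 0L) return("pattern has no elements")
  nPhos <- sum(vapply(el, function(e) isTRUE(e$phospho), logical(1)))
  if (nPhos != 1L) return("exactly one phosphoacceptor element required")
  for (e in el) {
    if (e$type == "gap" && e$min > e$max)
      return("gap with min > max")
    if (e$type %in% c("fixed", "class") && length(e$residues) == 0L)
      return("empty residue class")
  }
  if (!is.na(object@anchorIndex) &&
      object@phosphoIndex >= object@anchorIndex)
    return("phosphoacceptor must precede the anchor element")
  TRUE
})

#' Macromolecular structure as a flat atom table
#'
#' A light container for coordinate files (PDB/mmCIF) and for synthetic
#' peptides built from internal coordinates.  Atom records are kept as a
#' single data frame in author numbering; alternate locations are resolved on
#' construction (highest occupancy kept, ties preferring altloc 'A').
#'
#' @slot id accession or fixture name.
#' @slot resolution crystallographic resolution in Angstrom
#'   (\code{NA_real_} when absent, e.g. NMR models).
#' @slot atoms data.frame with columns \code{chain}, \code{resno},
#'   \code{insert}, \code{resid}, \code{elety}, \code{element}, \code{x},
#'   \code{y}, \code{z}, \code{occ}.
#' @seealso [readStructure()], [writeStructure()], [buildPeptide()]
#' @export
setClass("PeptideStructure",
  representation(id = "character",
                 resolution = "numeric",
                 atoms = "data.frame"))

setValidity("PeptideStructure", function(object) {
  need <- c("chain", "resno", "insert", "resid", "elety", "element",
            "x", "y", "z", "occ")
  if (!all(need %in% names(object@atoms)))
    return(paste("atoms must have columns:", paste(need, collapse = ", ")))
  xyz <- as.matrix(object@atoms[, c("x", "y", "z")])
  if (nrow(xyz) > 0 && !all(is.finite(xyz)))
    return("atom coordinates must be finite")
  key <- with(object@atoms, paste(chain, resno, insert, elety))
  if (anyDuplicated(key))
    return("duplicate atom records after altloc resolution")
  TRUE
})

#' Contiguous peptide fragment excised from a structure
#'
#' A pattern-matched stretch of residues with complete backbone (N, CA, C, O
#' on every residue, consecutive CA-CA distances below the chain-break cutoff)
#' plus role-tagged side-chain atoms for the pattern's Glu (OE1/OE2) and Arg
#' (NH1/NH2), when present, used for end-to-end span measurement and
#' anchor-atom superposition.
#'
#' @slot id unique fragment identifier
#'   (\code{"<structure>_<chain>_<start resno>"}).
#' @slot structureId source structure id.
#' @slot chain source chain id.
#' @slot resno author residue numbers (integer vector, one per residue).
#' @slot insert insertion codes, "" when none.
#' @slot sequence 1-letter sequence of the fragment.
#' @slot coreSpan integer positions (1-based within the fragment) of the
#'   pattern core: the contiguous stretch from the first to the last
#'   non-wildcard element (internal wildcards included).
#' @slot backbone numeric array \code{[residue, atom, xyz]} with atom slices
#'   N, CA, C, O.
#' @slot markedAtoms numeric matrix (rows among \code{GLU_OE1},
#'   \code{GLU_OE2}, \code{ARG_NH1}, \code{ARG_NH2}; columns x, y, z); may
#'   have zero rows.
#' @slot resolution resolution of the source structure (Angstrom, NA allowed).
#' @seealso [extractFragments()], [backboneDihedrals()], [endpointSpan()]
#' @export
setClass("PeptideFragment",
  representation(id = "character",
                 structureId = "character",
                 chain = "character",
                 resno = "integer",
                 insert = "character",
                 sequence = "character",
                 coreSpan = "integer",
                 backbone = "array",
                 markedAtoms = "matrix",
                 resolution = "numeric"))

setValidity("PeptideFragment", function(object) {
  n <- nchar(object@sequence)
  d <- dim(object@backbone)
  if (length(d) != 3L || d[1] != n || d[2] != 4L || d[3] != 3L)
    return("backbone must be an n x 4 x 3 array matching the sequence")
  if (!all(is.finite(object@backbone)))
    return("backbone coordinates must be finite (all four atoms per residue)")
  if (length(object@resno) != n)
    return("resno length must equal sequence length")
  ca <- object@backbone[, "CA", , drop = FALSE]
  if (n > 1) {
    dd <- sqrt(rowSums((ca[-1, 1, , drop = FALSE] -
                        ca[-n, 1, , drop = FALSE])^2))
    if (any(dd > 4.5))
      return("chain break: consecutive CA-CA distance exceeds 4.5 Angstrom")
  }
  if (length(object@coreSpan) &&
      (min(object@coreSpan) < 1 || max(object@coreSpan) > n))
    return("coreSpan indices out of range")
  TRUE
})

#' Rigid-body transform (proper rotation + translation)
#'
#' @slot rotation 3x3 orthonormal matrix with determinant +1.
#' @slot translation length-3 numeric vector (Angstrom).
#' @seealso [superpose()], [applyTransform()]
#' @export
setClass("RigidTransform",
  representation(rotation = "matrix", translation = "numeric"))

setValidity("RigidTransform", function(object) {
  R <- object@rotation
  if (!all(dim(R) == c(3L, 3L))) return("rotation must be 3x3")
  if (max(abs(crossprod(R) - diag(3))) > 1e-9)
    return("rotation must be orthonormal within 1e-9")
  if (abs(det(R) - 1) > 1e-9)
    return("rotation must be proper (det +1, no reflection)")
  if (length(object@translation) != 3L)
    return("translation must have length 3")
  TRUE
})

#' Anchor scene: the placement target for candidate peptides
#'
#' The geometric reference combining the phosphatase active site (two
#' Mn2+ ions and the Glu-phosphomimetic OE1/OE2 reference positions) with the
#' regulatory-subunit anchor point (Asp OD1/OD2 carboxylate and the Arg
#' NH1/NH2 reference positions placed against it).  Candidate fragments are
#' superposed onto the OE/NH reference atoms and scored by their residual
#' displacement and by distances to the metals and the Asp.
#'
#' @slot mnPositions 2x3 matrix, the di-metal pair.
#' @slot aspOd 2x3 matrix, OD1/OD2 of the anchor Asp.
#' @slot gluOeRef 2x3 matrix, reference OE1/OE2 positions.
#' @slot argNhRef 2x3 matrix, reference NH1/NH2 positions.
#' @slot contextAtoms numeric matrix of receptor heavy-atom coordinates used
#'   for clash checks (possibly 0 rows).
#' @slot contactDistance Angstrom, the NH-OD contact used when the Arg
#'   reference was placed.
#' @slot meta free-form provenance list.
#' @seealso [assembleAnchorScene()], [genAnchorScene()], [fitCandidate()]
#' @export
setClass("AnchorScene",
  representation(mnPositions = "matrix",
                 aspOd = "matrix",
                 gluOeRef = "matrix",
                 argNhRef = "matrix",
                 contextAtoms = "matrix",
                 contactDistance = "numeric",
                 meta = "list"))

setValidity("AnchorScene", function(object) {
  for (nm in c("mnPositions", "aspOd", "gluOeRef", "argNhRef")) {
    m <- slot(object, nm)
    if (!all(dim(m) == c(2L, 3L)))
      return(sprintf("%s must be a 2x3 matrix", nm))
    if (!all(is.finite(m))) return(sprintf("%s must be finite", nm))
  }
  span <- min(crossDist(object@gluOeRef, object@argNhRef))
  if (!(span > 0)) return("anchor span (min OE x NH distance) must be > 0")
  TRUE
})
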