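# torsion angle in degrees for points a-b-c-d, in (-180, 180];
# NA (with warning) when the geometry is degenerate
torsionAngle <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  if (vnorm(n1) < 1e-9 || vnorm(n2) < 1e-9) {
    warning("degenerate (colinear) geometry: torsion undefined")
    return(NA_real_)
  }
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / vnorm(b2)
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  wrapAngle(ang)
}

#' Backbone dihedral profile of a fragment
#'
#' Standard IUPAC torsions: \code{phi(i)} over C(i-1)-N(i)-CA(i)-C(i),
#' \code{psi(i)} over N(i)-CA(i)-C(i)-N(i+1), and \code{omega(i)} over the
#' peptide bond following residue i, CA(i)-C(i)-N(i+1)-CA(i+1).  The first
#' residue has undefined phi; the last has undefined psi and omega.
#'
#' @param fragment a [PeptideFragment-class].
#' @return numeric matrix with columns \code{phi}, \code{psi}, \code{omega}
#'   (degrees in (-180, 180], NA where undefined) and attribute \code{core}
#'   (logical vector marking the fragment's pattern-core residues).
#' @export
backboneDihedrals <- function(fragment) {
  stopifnot(is(fragment, "PeptideFragment"))
  bb <- fragment@backbone
  n <- dim(bb)[1]
  out <- matrix(NA_real_, n, 3,
                dimnames = list(NULL, c("phi", "psi", "omega")))
  for (i in seq_len(n)) {
    if (i > 1)
      out[i, "phi"] <- torsionAngle(bb[i - 1, "C", ], bb[i, "N", ],
                                    bb[i, "CA", ], bb[i, "C", ])
    if (i < n) {
      out[i, "psi"] <- torsionAngle(bb[i, "N", ], bb[i, "CA", ],
                                    bb[i, "C", ], bb[i + 1, "N", ])
      out[i, "omega"] <- torsionAngle(bb[i, "CA", ], bb[i, "C", ],
                                      bb[i + 1, "N", ], bb[i + 1, "CA", ])
    }
  }
  core <- rep(FALSE, n)
  core[fragment@coreSpan] <- TRUE
  attr(out, "core") <- core
  out
}

#' Max-circular distance between two dihedral profiles
#'
#' The distance between two conformers is the maximum, over compared residue
#' positions and over the three angle types, of the circular difference
#' wrapped to [0, 180] degrees.  Angle pairs where either side is undefined
#' (termini, degenerate geometry) are skipped.  With \code{coreOnly = TRUE}
#' (the default) only pattern-core residues are compared, so fragments mined
#' with the same pattern are always comparable regardless of flank length.
#'
#' @param a,b dihedral matrices from [backboneDihedrals()].
#' @param coreOnly compare only core residues (requires equal core lengths).
#' @return distance in degrees, in [0, 180].
#' @export
dihedralDistance <- function(a, b, coreOnly = TRUE) {
  pick <- function(m) {
    core <- attr(m, "core")
    if (coreOnly && !is.null(core)) m[core, , drop = FALSE]
    else m[, , drop = FALSE]
  }
  ma <- pick(a); mb <- pick(b)
  if (nrow(ma) != nrow(mb))
    stop("profiles have different numbers of compared residues (",
         nrow(ma), " vs ", nrow(mb), ")")
  ok <- !is.na(ma) & !is.na(mb)
  if (!any(ok)) stop("no comparable angle pair between the two profiles")
  max(circularDiff(ma[ok], mb[ok]))
}
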