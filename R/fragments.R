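BACKBONE <- c("N", "CA", "C", "O")

# parse a gap-free mining pattern such as "xHPRVx" or "xEPxxxPRx":
# one element per character, '[' classes allowed
parseMiningPattern <- function(patternText) {
  chars <- strsplit(patternText, "")[[1]]
  out <- list()
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "x") {
      out[[length(out) + 1L]] <- list(type = "wild")
      i <- i + 1L
    } else if (ch == "[") {
      j <- which(chars == "]" & seq_along(chars) > i)[1]
      if (is.na(j)) stop("unterminated class in '", patternText, "'")
      out[[length(out) + 1L]] <- list(type = "class",
                                      residues = chars[(i + 1):(j - 1)])
      i <- j + 1L
    } else if (grepl("^[A-Z]$", ch)) {
      out[[length(out) + 1L]] <- list(type = "fixed", residues = ch)
      i <- i + 1L
    } else stop("bad character '", ch, "' in mining pattern")
  }
  out
}

#' Extract pattern-matched peptide fragments from structures
#'
#' Slides a gap-free sequence pattern (1-letter codes with \code{x}
#' wildcards, e.g. \code{"xHPRVx"} or \code{"xEPxxxPRx"}) over every chain of
#' every structure.  A window becomes a fragment only when every residue has
#' a complete N/CA/C/O backbone, consecutive CA-CA distances stay below the
#' chain-break cutoff (4.5 Angstrom), and all residues are standard (MSE is
#' read as Met; any other nonstandard residue rejects the window, as does a
#' wildcard falling off the chain terminus).  When Glu or Arg occur at
#' non-wildcard pattern positions their OE1/OE2 (first such Glu) and NH1/NH2
#' (last such Arg) side-chain atoms are role-tagged for span measurement and
#' anchor fitting.
#'
#' @param structures list of [PeptideStructure-class] objects (a single
#'   object is accepted).
#' @param patternText gap-free pattern string.
#' @return list of [PeptideFragment-class] objects (possibly empty).
#' @export
extractFragments <- function(structures, patternText) {
  if (is(structures, "PeptideStructure")) structures <- list(structures)
  pat <- parseMiningPattern(patternText)
  plen <- length(pat)
  nonWild <- which(vapply(pat, function(e) e$type != "wild", logical(1)))
  ## the pattern core is the contiguous stretch from the first to the last
  ## non-wildcard element (internal wildcards belong to the core); an
  ## all-wildcard pattern makes the whole window the core
  core <- if (length(nonWild)) seq.int(min(nonWild), max(nonWild))
    else seq_len(plen)
  frags <- list()
  for (s in structures) {
    for (ch in unique(s@atoms$chain)) {
      resList <- chainResidues(s, ch)
      n <- length(resList)
      if (n < plen) next
      letters1 <- vapply(resList, function(r) {
        nm <- r$resid[1]
        if (nm %in% names(AA321)) unname(AA321[nm]) else NA_character_
      }, character(1))
      bbOK <- vapply(resList, function(r)
        all(BACKBONE %in% r$elety), logical(1))
      caMat <- t(vapply(resList, function(r) {
        v <- atomXyz(r, "CA")
        if (is.null(v)) c(NA_real_, NA_real_, NA_real_) else v
      }, numeric(3)))
      for (w in seq_len(n - plen + 1L)) {
        idx <- w:(w + plen - 1L)
        if (anyNA(letters1[idx]) || !all(bbOK[idx])) next
        ok <- TRUE
        for (k in seq_len(plen)) {
          e <- pat[[k]]
          if (e$type != "wild" && !(letters1[idx[k]] %in% e$residues)) {
            ok <- FALSE; break
          }
        }
        if (!ok) next
        dca <- sqrt(rowSums((caMat[idx[-1], , drop = FALSE] -
                             caMat[idx[-plen], , drop = FALSE])^2))
        if (any(dca > 4.5)) next
        bb <- array(NA_real_, dim = c(plen, 4L, 3L),
                    dimnames = list(NULL, BACKBONE, c("x", "y", "z")))
        for (k in seq_len(plen))
          for (at in BACKBONE)
            bb[k, at, ] <- atomXyz(resList[[idx[k]]], at)
        marked <- matrix(numeric(0), 0, 3,
                         dimnames = list(NULL, c("x", "y", "z")))
        coreLetters <- letters1[idx[core]]
        gluAt <- core[which(coreLetters == "E")]
        argAt <- core[which(coreLetters == "R")]
        if (length(gluAt)) {
          r <- resList[[idx[gluAt[1]]]]
          for (at in c("OE1", "OE2")) {
            v <- atomXyz(r, at)
            if (!is.null(v)) {
              marked <- rbind(marked, v)
              rownames(marked)[nrow(marked)] <- paste0("GLU_", at)
            }
          }
        }
        if (length(argAt)) {
          r <- resList[[idx[argAt[length(argAt)]]]]
          for (at in c("NH1", "NH2")) {
            v <- atomXyz(r, at)
            if (!is.null(v)) {
              marked <- rbind(marked, v)
              rownames(marked)[nrow(marked)] <- paste0("ARG_", at)
            }
          }
        }
        resnos <- unname(vapply(resList[idx], function(r) r$resno[1],
                                integer(1)))
        inserts <- unname(vapply(resList[idx], function(r)
          as.character(r$insert[1]), character(1)))
        frags[[length(frags) + 1L]] <- new("PeptideFragment",
          id = sprintf("%s_%s_%d", s@id, ch, resnos[1]),
          structureId = s@id, chain = ch,
          resno = resnos, insert = inserts,
          sequence = paste(letters1[idx], collapse = ""),
          coreSpan = as.integer(core),
          backbone = bb, markedAtoms = marked,
          resolution = s@resolution)
      }
    }
  }
  frags
}

setMethod("show", "PeptideFragment", function(object) {
  cat("PeptideFragment", object@id, " seq:", object@sequence, "\n")
  cat("  residues", object@resno[1], "-", tail(object@resno, 1),
      " core positions:", paste(object@coreSpan, collapse = ","),
      " marked atoms:",
      if (nrow(object@markedAtoms))
        paste(rownames(object@markedAtoms), collapse = ",") else "<none>",
      "\n")
})
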