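AA321 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
           GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
           LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
           SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
           MSE = "M")  # selenomethionine read as Met

AA123 <- setNames(names(AA321)[1:20], unname(AA321[1:20]))

#' Construct a PeptideStructure from an atom table
#'
#' Resolves alternate locations (highest occupancy kept; ties prefer
#' altloc 'A', then the empty altloc) and validates the result.
#'
#' @param atoms data.frame with columns \code{chain}, \code{resno},
#'   \code{insert}, \code{resid}, \code{elety}, \code{element}, \code{x},
#'   \code{y}, \code{z}, \code{occ} and optionally \code{altloc}.
#' @param id structure identifier.
#' @param resolution resolution in Angstrom, \code{NA} when absent.
#' @return a [PeptideStructure-class].
#' @export
peptideStructure <- function(atoms, id = "struct", resolution = NA_real_) {
  atoms$insert[is.na(atoms$insert)] <- ""
  atoms$chain[is.na(atoms$chain)] <- " "
  if (is.null(atoms$occ)) atoms$occ <- 1
  atoms$occ[is.na(atoms$occ)] <- 1
  if (!is.null(atoms$altloc)) {
    atoms$altloc[is.na(atoms$altloc)] <- ""
    pref <- ifelse(atoms$altloc %in% c("", "A"), 0L, 1L)
    ord <- order(atoms$chain, atoms$resno, atoms$insert, atoms$elety,
                 -atoms$occ, pref)
    atoms <- atoms[ord, , drop = FALSE]
    key <- with(atoms, paste(chain, resno, insert, elety))
    atoms <- atoms[!duplicated(key), , drop = FALSE]
    atoms$altloc <- NULL
  }
  atoms <- atoms[order(atoms$chain, atoms$resno, atoms$insert), ,
                 drop = FALSE]
  rownames(atoms) <- NULL
  new("PeptideStructure", id = id, resolution = as.numeric(resolution),
      atoms = atoms)
}

#' Read a coordinate file (PDB or mmCIF)
#'
#' Uses \pkg{bio3d} readers and extracts the resolution from
#' \code{REMARK 2} (PDB) or \code{_refine.ls_d_res_high}/
#' \code{_reflns.d_resolution_high} (mmCIF) when present.
#'
#' @param path file ending in \code{.pdb} or \code{.cif} (case-insensitive).
#' @param id identifier; defaults to the file base name.
#' @return a [PeptideStructure-class].
#' @export
readStructure <- function(path, id = NULL) {
  if (is.null(id))
    id <- toupper(sub("\\.(pdb|cif)$", "", basename(path),
                      ignore.case = TRUE))
  isCif <- grepl("\\.cif$", path, ignore.case = TRUE)
  pdb <- if (isCif) bio3d::read.cif(path) else
    bio3d::read.pdb(path, verbose = FALSE)
  a <- pdb$atom
  atoms <- data.frame(chain = as.character(a$chain),
                      resno = as.integer(a$resno),
                      insert = ifelse(is.na(a$insert), "",
                                      as.character(a$insert)),
                      resid = as.character(a$resid),
                      elety = as.character(a$elety),
                      element = toupper(as.character(a$elesy)),
                      x = a$x, y = a$y, z = a$z,
                      occ = a$o,
                      altloc = ifelse(is.na(a$alt), "",
                                      as.character(a$alt)),
                      stringsAsFactors = FALSE)
  miss <- is.na(atoms$element) | atoms$element == ""
  atoms$element[miss] <- substr(gsub("[0-9]", "", atoms$elety[miss]), 1, 1)
  lines <- readLines(path, warn = FALSE)
  res <- NA_real_
  if (isCif) {
    hit <- grep("_refine\\.ls_d_res_high|_reflns\\.d_resolution_high",
                lines, value = TRUE)
    if (length(hit)) {
      val <- suppressWarnings(as.numeric(sub("^\\S+\\s+", "", hit[1])))
      if (is.finite(val)) res <- val
    }
  } else {
    hit <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
    if (length(hit)) {
      m <- regexec("RESOLUTION\\.?\\s+([0-9]+\\.?[0-9]*)", hit[1])
      val <- suppressWarnings(as.numeric(regmatches(hit[1], m)[[1]][2]))
      if (length(val) && is.finite(val)) res <- val
    }
  }
  peptideStructure(atoms, id = id, resolution = res)
}

#' Write a PeptideStructure as a PDB file
#'
#' Coordinates are written with \code{bio3d::write.pdb} (occupancy 1.0,
#' element fields populated); when the structure has a resolution a
#' \code{REMARK 2} line is prepended so that [readStructure()] round-trips
#' it.
#'
#' @param structure a [PeptideStructure-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeStructure <- function(structure, path) {
  stopifnot(is(structure, "PeptideStructure"))
  a <- structure@atoms
  het <- a$resid %in% c("MN", "PO4", "HOH", "ZN", "FE", "MG")
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   type = ifelse(het, "HETATM", "ATOM"),
                   resno = a$resno, resid = a$resid,
                   eleno = seq_len(nrow(a)), elety = a$elety,
                   chain = a$chain, insert = a$insert,
                   o = rep(1, nrow(a)), b = rep(0, nrow(a)),
                   elesy = a$element)
  if (is.finite(structure@resolution)) {
    lines <- readLines(path, warn = FALSE)
    hdr <- sprintf("REMARK   2 RESOLUTION.    %.2f ANGSTROMS.",
                   structure@resolution)
    writeLines(c(hdr, lines), path)
  }
  invisible(path)
}

setMethod("show", "PeptideStructure", function(object) {
  a <- object@atoms
  cat("PeptideStructure", object@id,
      if (is.finite(object@resolution))
        sprintf("(%.2f Angstrom)", object@resolution) else "(resolution NA)",
      "\n")
  cat(" ", nrow(a), "atoms,", length(unique(a$chain)), "chain(s):",
      paste(unique(a$chain), collapse = " "), "\n")
})

# per-chain residue bookkeeping: ordered residues with their atoms
chainResidues <- function(structure, chain) {
  a <- structure@atoms[structure@atoms$chain == chain, , drop = FALSE]
  key <- paste(a$resno, a$insert, sep = "_")
  split(a, factor(key, levels = unique(key)))
}

# xyz of one named atom in a residue atom-table, or NULL
atomXyz <- function(res, name) {
  i <- which(res$elety == name)
  if (length(i) == 0L) return(NULL)
  as.numeric(res[i[1], c("x", "y", "z")])
}
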