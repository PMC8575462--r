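emptyHits <- function() {
  data.frame(protein_id = character(), start = integer(), end = integer(),
             phospho_pos = integer(), anchor_pos = integer(),
             gap_len = integer(), spacing = integer(),
             matched_seq = character(), stringsAsFactors = FALSE)
}

#' Scan one sequence for a SLiM pattern
#'
#' Finds every match of the pattern, including overlapping ones, and reports
#' one hit per distinct (phospho position, anchor position) pair: multiple
#' gap-length realisations landing on the same pair collapse to a single hit
#' (the one with the smallest start, then smallest end).  Ambiguity letters
#' B, Z and U never satisfy any pattern position; X satisfies only wildcard
#' and gap positions.  Lowercase sequences are uppercased with a warning.
#'
#' @param pattern a [MotifPattern-class].
#' @param sequence amino-acid string (may be empty).
#' @param id protein identifier recorded in the hit table.
#' @param offset integer added to all reported positions, mapping local
#'   coordinates to author numbering (e.g. \code{offset = 611} for a
#'   fragment whose first residue is author residue 612).
#' @return data.frame with columns \code{protein_id}, \code{start},
#'   \code{end}, \code{phospho_pos}, \code{anchor_pos}, \code{gap_len},
#'   \code{spacing}, \code{matched_seq}, sorted by
#'   (\code{phospho_pos}, \code{anchor_pos}).  \code{spacing} is the number
#'   of residues strictly between phosphoacceptor and anchor.
#' @examples
#' pat <- parsePattern(slimPatterns()$strict)
#' scanSequence(pat, "MPMSPLMHPRVKEVR", id = "p107_R1", offset = 611)
#' @export
scanSequence <- function(pattern, sequence, id = "seq", offset = 0L) {
  stopifnot(is(pattern, "MotifPattern"))
  validObject(pattern)
  if (length(sequence) != 1L || !is.character(sequence))
    stop("'sequence' must be a single string")
  if (grepl("[a-z]", sequence)) {
    warning("lowercase letters in sequence '", id, "' uppercased")
    sequence <- toupper(sequence)
  }
  offset <- as.integer(offset)
  if (nchar(sequence) == 0L) return(emptyHits())

  el <- pattern@elements
  gapIdx <- which(vapply(el, function(e) e$type == "gap", logical(1)))
  gapGrid <- if (length(gapIdx) == 0L) {
    matrix(integer(0), nrow = 1L)
  } else {
    as.matrix(expand.grid(lapply(gapIdx, function(i)
      seq.int(el[[i]]$min, el[[i]]$max))))
  }

  rows <- list()
  for (r in seq_len(nrow(gapGrid))) {
    g <- gapGrid[r, ]
    lens <- integer(length(el))
    rx <- character(length(el))
    gi <- 0L
    for (i in seq_along(el)) {
      if (el[[i]]$type == "gap") {
        gi <- gi + 1L
        lens[i] <- g[gi]
        rx[i] <- elementRegex(el[[i]], g[gi])
      } else {
        lens[i] <- 1L
        rx[i] <- elementRegex(el[[i]])
      }
    }
    tot <- sum(lens)
    offPhos <- if (pattern@phosphoIndex > 1L)
      sum(lens[seq_len(pattern@phosphoIndex - 1L)]) else 0L
    offAnch <- if (!is.na(pattern@anchorIndex)) {
      if (pattern@anchorIndex > 1L)
        sum(lens[seq_len(pattern@anchorIndex - 1L)]) else 0L
    } else NA_integer_
    ## lookahead capture so overlapping matches are all found
    hitsAt <- gregexpr(paste0("(?=", paste(rx, collapse = ""), ")"),
                       sequence, perl = TRUE)[[1]]
    if (hitsAt[1] == -1L) next
    starts <- as.vector(hitsAt, mode = "integer")
    g <- unname(g)
    rows[[length(rows) + 1L]] <- data.frame(
      protein_id = id,
      start = starts,
      end = starts + tot - 1L,
      phospho_pos = starts + offPhos,
      anchor_pos = if (is.na(offAnch)) NA_integer_ else starts + offAnch,
      gap_len = if (length(gapIdx)) g[1] else NA_integer_,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(emptyHits())
  h <- do.call(rbind, rows)
  ## one hit per distinct (phospho_pos, anchor_pos); representative is the
  ## realisation with smallest (start, end)
  h <- h[order(h$phospho_pos, h$anchor_pos, h$start, h$end), , drop = FALSE]
  h <- h[!duplicated(h[, c("phospho_pos", "anchor_pos")]), , drop = FALSE]
  h$spacing <- h$anchor_pos - h$phospho_pos - 1L
  h$matched_seq <- substring(sequence, h$start, h$end)
  for (cc in c("start", "end", "phospho_pos", "anchor_pos"))
    h[[cc]] <- h[[cc]] + offset
  rownames(h) <- NULL
  h[, names(emptyHits())]
}

#' Scan a proteome for a SLiM pattern
#'
#' @param pattern a [MotifPattern-class].
#' @param proteome a named character vector or a
#'   [Biostrings::AAStringSet-class]; names are protein ids and must be
#'   unique.
#' @return list with \code{hits} (row-bound [scanSequence()] tables) and
#'   \code{summary}: \code{n_hits}, \code{n_proteins_with_hit},
#'   \code{n_proteins_total}, \code{fraction_with_hit}.
#' @examples
#' pat <- parsePattern(slimPatterns()$strict)
#' prot <- c(a = "MPMSPLMHPRVKEVR", b = "AAAA", c = "GGGG")
#' scanProteome(pat, prot)$summary
#' @export
scanProteome <- function(pattern, proteome) {
  if (is(proteome, "AAStringSet"))
    proteome <- setNames(as.character(proteome), names(proteome))
  if (length(proteome) == 0L) stop("empty proteome")
  ids <- names(proteome)
  if (is.null(ids) || any(ids == "") || anyNA(ids))
    stop("proteome sequences must be named with protein ids")
  if (anyDuplicated(ids))
    stop("duplicate protein ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  hits <- do.call(rbind, lapply(ids, function(i)
    scanSequence(pattern, proteome[[i]], id = i)))
  if (is.null(hits)) hits <- emptyHits()
  nWith <- length(unique(hits$protein_id))
  list(hits = hits,
       summary = list(n_hits = nrow(hits),
                      n_proteins_with_hit = nWith,
                      n_proteins_total = length(proteome),
                      fraction_with_hit = nWith / length(proteome)))
}

#' Histogram of phospho-to-anchor spacings
#'
#' Counts hits by the number of residues strictly between the matched
#' phosphoacceptor and the basic anchor (5 in p107, 7 in TAU, 11 in MAP2).
#'
#' @param hits hit table from [scanSequence()]/[scanProteome()].
#' @return named integer vector (names are spacing values); sums to the
#'   number of hits.
#' @export
spacingDistribution <- function(hits) {
  if (nrow(hits) == 0L) return(setNames(integer(0), character(0)))
  tab <- table(hits$spacing)
  setNames(as.integer(tab), names(tab))
}

#' Read a proteome FASTA
#'
#' Reads with [Biostrings::readAAStringSet()]; the id is the first
#' whitespace-delimited header token, with UniProt \code{db|ACC|name} headers
#' reduced to the accession.  Gap characters and asterisks are stripped with
#' a warning and sequences are uppercased.
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
readProteome <- function(path) {
  aas <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(aas))
  uni <- grepl("^[a-z]+\\|[^|]+\\|", ids)
  ids[uni] <- vapply(strsplit(ids[uni], "|", fixed = TRUE),
                     `[[`, character(1), 2L)
  seqs <- toupper(as.character(aas))
  bad <- grepl("[-.*]", seqs)
  if (any(bad)) {
    warning(sum(bad), " sequence(s) contained gaps or '*'; stripped")
    seqs <- gsub("[-.*]", "", seqs)
  }
  setNames(seqs, ids)
}

#' Write a hit table as TSV
#'
#' @param hits hit table.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeHits <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
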