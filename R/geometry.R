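#' Glu-to-Arg end-to-end span
#'
#' Distance between the Glu carboxylate oxygens (OE1/OE2) and the Arg
#' guanidinium nitrogens (NH1/NH2), summarised over the up-to-four OE x NH
#' atom pairs.  The default statistic is the minimum, matching the
#' shortest-distance convention used for the metal-phosphate survey;
#' \code{"max"} and \code{"mean"} are available for sensitivity checks.
#'
#' @param x a [PeptideFragment-class] with marked OE and NH atoms, or an
#'   [AnchorScene-class] (span between its OE and NH reference positions).
#' @param stat one of \code{"min"}, \code{"max"}, \code{"mean"}.
#' @return distance in Angstrom.
#' @export
setGeneric("endpointSpan", function(x, stat = c("min", "max", "mean"))
  standardGeneric("endpointSpan"))

#' @rdname endpointSpan
#' @export
setMethod("endpointSpan", "PeptideFragment", function(x, stat = c("min",
    "max", "mean")) {
  stat <- match.arg(stat)
  m <- x@markedAtoms
  oe <- m[grepl("^GLU_OE", rownames(m)), , drop = FALSE]
  nh <- m[grepl("^ARG_NH", rownames(m)), , drop = FALSE]
  if (nrow(oe) == 0L || nrow(nh) == 0L)
    stop("fragment ", x@id, " lacks marked GLU_OE and/or ARG_NH atoms")
  d <- crossDist(oe, nh)
  switch(stat, min = min(d), max = max(d), mean = mean(d))
})

#' @rdname endpointSpan
#' @export
setMethod("endpointSpan", "AnchorScene", function(x, stat = c("min", "max",
    "mean")) {
  stat <- match.arg(stat)
  d <- crossDist(x@gluOeRef, x@argNhRef)
  switch(stat, min = min(d), max = max(d), mean = mean(d))
})

#' Filter fragments by minimum end-to-end span
#'
#' Retains exactly the fragments whose [endpointSpan()] is greater than or
#' equal to \code{minSpan} (boundary inclusive).  The default of 20
#' Angstrom is the span a peptide needs to bridge the phosphatase active
#' site and the regulatory-subunit anchor.
#'
#' @param fragments list of [PeptideFragment-class] objects.
#' @param minSpan Angstrom.
#' @param stat passed to [endpointSpan()].
#' @return the retained sublist, input order preserved.
#' @export
filterBySpan <- function(fragments, minSpan = 20, stat = "min") {
  keep <- vapply(fragments, function(f)
    endpointSpan(f, stat = stat) >= minSpan, logical(1))
  fragments[keep]
}

#' Survey metal-phosphate coordination distances
#'
#' For every Mn2+ ion in every structure, finds the shortest distance to any
#' phosphate oxygen (residue PO4, or atoms named O1P-O4P / OP1-OP4) and
#' aggregates the per-ion shortest distances.  Structures lacking either a
#' Mn ion or a phosphate group are skipped with a warning and recorded.
#' The spread is reported as the population standard deviation
#' (n denominator), stated here because the convention matters when
#' comparing against published summaries.
#'
#' @param structures list of [PeptideStructure-class] objects.
#' @return list with \code{perIon} (data.frame: structure, ion index,
#'   shortest distance), \code{mean}, \code{sd} (population), \code{n_ions},
#'   \code{skipped} (ids), \code{sd_convention}.
#' @export
mnPhosphateSurvey <- function(structures) {
  if (is(structures, "PeptideStructure")) structures <- list(structures)
  rows <- list(); skipped <- character(0)
  for (s in structures) {
    a <- s@atoms
    mn <- a[a$element == "MN" | a$resid == "MN", , drop = FALSE]
    po <- a[(a$resid == "PO4" & startsWith(a$elety, "O")) |
              a$elety %in% c("O1P", "O2P", "O3P", "O4P",
                             "OP1", "OP2", "OP3", "OP4"), , drop = FALSE]
    if (nrow(mn) == 0L || nrow(po) == 0L) {
      warning("structure ", s@id, " lacks Mn and/or phosphate; skipped")
      skipped <- c(skipped, s@id)
      next
    }
    d <- crossDist(as.matrix(mn[, c("x", "y", "z")]),
                   as.matrix(po[, c("x", "y", "z")]))
    rows[[length(rows) + 1L]] <- data.frame(
      structure = s@id, ion = seq_len(nrow(mn)),
      shortest = apply(d, 1, min), stringsAsFactors = FALSE)
  }
  perIon <- if (length(rows)) do.call(rbind, rows) else
    data.frame(structure = character(), ion = integer(),
               shortest = numeric())
  v <- perIon$shortest
  list(perIon = perIon,
       mean = if (length(v)) mean(v) else NA_real_,
       sd = if (length(v)) sqrt(mean((v - mean(v))^2)) else NA_real_,
       n_ions = length(v), skipped = skipped,
       sd_convention = "population (n denominator)")
}
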