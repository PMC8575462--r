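#' Parse a SLiM pattern string
#'
#' Parses the dash-separated motif dialect used throughout the package:
#' tokens are a single residue letter (\code{P}), a residue class
#' (\code{[RK]}), a single-position wildcard (\code{x}), or a variable gap
#' (\code{x(4,10)}).  A leading \code{p} on exactly one letter or class marks
#' the phosphoacceptor, e.g. \code{p[ST]}.  The basic-anchor element is
#' detected as the first class/letter made up of R/K after the variable gap
#' (after the phosphoacceptor when the pattern has no gap).
#'
#' @param patternText pattern string, e.g.
#'   \code{"p[ST]-P-x(4,10)-[RK]-V-x-x-[VI]-R"}.
#' @return a [MotifPattern-class] object.
#' @examples
#' pat <- parsePattern("p[ST]-P-x(4,10)-[RK]-V-x-x-[VI]-R")
#' formatPattern(pat)
#' @export
parsePattern <- function(patternText) {
  stopifnot(is.character(patternText), length(patternText) == 1L)
  tokens <- strsplit(patternText, "-", fixed = TRUE)[[1]]
  if (length(tokens) == 0L || any(tokens == ""))
    stop("malformed pattern: empty token in '", patternText, "'")
  elements <- vector("list", length(tokens))
  for (i in seq_along(tokens)) {
    tok <- tokens[i]
    if (tok == "x") {
      elements[[i]] <- list(type = "wild", phospho = FALSE)
    } else if (grepl("^x\\(([0-9]+),([0-9]+)\\)$", tok)) {
      m <- regmatches(tok, regexec("^x\\(([0-9]+),([0-9]+)\\)$", tok))[[1]]
      lo <- as.integer(m[2]); hi <- as.integer(m[3])
      if (lo > hi)
        stop("malformed token '", tok, "': gap with min > max")
      elements[[i]] <- list(type = "gap", min = lo, max = hi,
                            phospho = FALSE)
    } else if (grepl("^p?[A-Z]$", tok)) {
      phos <- startsWith(tok, "p")
      elements[[i]] <- list(type = "fixed",
                            residues = sub("^p", "", tok),
                            phospho = phos)
    } else if (grepl("^p?\\[[A-Z]+\\]$", tok)) {
      phos <- startsWith(tok, "p")
      body <- gsub("^p?\\[|\\]$", "", tok)
      elements[[i]] <- list(type = "class",
                            residues = strsplit(body, "")[[1]],
                            phospho = phos)
    } else {
      stop("malformed token '", tok, "' in pattern '", patternText, "'")
    }
  }
  nPhos <- sum(vapply(elements, function(e) isTRUE(e$phospho), logical(1)))
  if (nPhos == 0L)
    stop("pattern has no phosphoacceptor ('p'-prefixed) element")
  if (nPhos > 1L)
    stop("pattern has ", nPhos, " phosphoacceptor elements; exactly 1 allowed")
  phosIdx <- which(vapply(elements, function(e) isTRUE(e$phospho),
                          logical(1)))
  gapIdx <- which(vapply(elements, function(e) e$type == "gap", logical(1)))
  after <- if (length(gapIdx)) gapIdx[1] else phosIdx
  anchorIdx <- NA_integer_
  for (i in seq_along(elements)) {
    e <- elements[[i]]
    if (i > after && e$type %in% c("fixed", "class") &&
        all(e$residues %in% c("R", "K"))) {
      anchorIdx <- i
      break
    }
  }
  new("MotifPattern", elements = elements,
      phosphoIndex = phosIdx, anchorIndex = anchorIdx,
      source = patternText)
}

#' Canonical text form of a parsed pattern
#'
#' @param pattern a [MotifPattern-class].
#' @return a single string; \code{formatPattern(parsePattern(s))} is stable.
#' @export
formatPattern <- function(pattern) {
  stopifnot(is(pattern, "MotifPattern"))
  toks <- vapply(pattern@elements, function(e) {
    p <- if (isTRUE(e$phospho)) "p" else ""
    switch(e$type,
      wild  = "x",
      gap   = sprintf("x(%d,%d)", e$min, e$max),
      fixed = paste0(p, e$residues),
      class = paste0(p, "[", paste(e$residues, collapse = ""), "]"))
  }, character(1))
  paste(toks, collapse = "-")
}

setMethod("show", "MotifPattern", function(object) {
  cat("MotifPattern:", formatPattern(object), "\n")
  cat("  elements:", length(object@elements),
      " phosphoacceptor at element", object@phosphoIndex,
      " anchor at element",
      if (is.na(object@anchorIndex)) "<none>" else object@anchorIndex, "\n")
})

#' Built-in B55alpha substrate SLiM patterns
#'
#' The strict consensus and the two degenerate relaxations used for
#' proteome-frequency estimates: the first substitutes conservative
#' hydrophobics and a basic terminal residue, the second additionally drops
#' the terminal constraint to a wildcard.
#'
#' @return named list of pattern strings
#'   (\code{strict}, \code{degenerate1}, \code{degenerate2}).
#' @examples
#' slimPatterns()$strict
#' @export
slimPatterns <- function() {
  list(strict      = "p[ST]-P-x(4,10)-[RK]-V-x-x-[VI]-R",
       degenerate1 = "p[ST]-P-x(4,10)-[RK]-[VIL]-x-x-[VILM]-[RK]",
       degenerate2 = "p[ST]-P-x(4,10)-[RK]-[VIL]-x-x-[VILM]-x")
}

# fixed span contributed by an element under one gap-length assignment
elementLength <- function(e, g = NULL) {
  if (e$type == "gap") g else 1L
}

# regex chunk for one element; wildcards admit X but not B/Z/U,
# fixed/class elements admit only their own letters
elementRegex <- function(e, g = NULL) {
  switch(e$type,
    wild  = paste0("[", paste(AA_WILD, collapse = ""), "]"),
    gap   = sprintf("[%s]{%d}", paste(AA_WILD, collapse = ""), g),
    fixed = e$residues,
    class = paste0("[", paste(e$residues, collapse = ""), "]"))
}
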