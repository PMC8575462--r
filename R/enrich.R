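#' Exact hypergeometric enrichment test on positive-protein counts
#'
#' One-sided Fisher exact test for over- (or under-) representation of
#' motif-positive proteins in a target set drawn from a background.  The
#' direction is taken from the observed fractions: when the target fraction
#' exceeds the background fraction the upper tail
#' \eqn{P(X \ge k)} is reported; when it is lower, the mirror (lower) tail;
#' equal fractions give \code{p_value = 1} and direction \code{"none"}.
#'
#' @param kTarget number of positive proteins in the target set.
#' @param nTarget target set size.
#' @param kBackground number of positive proteins in the whole background
#'   (target included).
#' @param nBackground background size.
#' @return list with the counts, \code{fraction_target},
#'   \code{fraction_background}, \code{odds_ratio} (target vs rest;
#'   \code{Inf} on a zero cell), \code{p_value} and \code{direction}.
#' @examples
#' enrichmentTest(4, 5, 4, 10)  # p = 6/252
#' @export
enrichmentTest <- function(kTarget, nTarget, kBackground, nBackground) {
  stopifnot(kTarget <= nTarget, kBackground <= nBackground,
            nTarget <= nBackground, kTarget <= kBackground)
  fT <- kTarget / nTarget
  fB <- kBackground / nBackground
  ## 2x2 of target vs rest-of-background
  a <- kTarget
  b <- nTarget - kTarget
  cc <- kBackground - kTarget
  d <- (nBackground - nTarget) - cc
  oddsRatio <- if (b * cc == 0) Inf else (a * d) / (b * cc)
  if (fT > fB) {
    direction <- "enriched"
    p <- phyper(kTarget - 1L, kBackground, nBackground - kBackground,
                nTarget, lower.tail = FALSE)
  } else if (fT < fB) {
    direction <- "depleted"
    p <- phyper(kTarget, kBackground, nBackground - kBackground, nTarget)
  } else {
    direction <- "none"
    p <- 1
  }
  list(n_background = nBackground, k_background_positive = kBackground,
       n_target = nTarget, k_target_positive = kTarget,
       fraction_target = fT, fraction_background = fB,
       odds_ratio = oddsRatio, p_value = min(p, 1), direction = direction)
}

#' Motif enrichment of a protein set within a proteome
#'
#' Scans the background proteome, marks a protein positive when it carries at
#' least one motif hit (hit multiplicity is ignored), and tests whether the
#' target set is enriched for positives with [enrichmentTest()].
#'
#' @param pattern a [MotifPattern-class].
#' @param targetIds character vector of protein ids; must be a non-empty
#'   subset of the background ids.
#' @param proteome named character vector or
#'   [Biostrings::AAStringSet-class] (the background).
#' @return as [enrichmentTest()].
#' @export
motifEnrichment <- function(pattern, targetIds, proteome) {
  if (is(proteome, "AAStringSet"))
    proteome <- setNames(as.character(proteome), names(proteome))
  targetIds <- unique(as.character(targetIds))
  if (length(targetIds) == 0L) stop("empty target set")
  missing <- setdiff(targetIds, names(proteome))
  if (length(missing))
    stop("target ids not in background: ",
         paste(head(missing, 5), collapse = ", "))
  scan <- scanProteome(pattern, proteome)
  positives <- unique(scan$hits$protein_id)
  enrichmentTest(kTarget = sum(targetIds %in% positives),
                 nTarget = length(targetIds),
                 kBackground = length(positives),
                 nBackground = length(proteome))
}
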