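strictPat <- parsePattern(slimPatterns()$strict)

test_that("generators are pure functions of (parameters, seed)", {
  g1 <- genProteome(20, strictPat, 0.2, seed = 7)
  g2 <- genProteome(20, strictPat, 0.2, seed = 7)
  expect_identical(g1, g2)
  g3 <- genProteome(20, strictPat, 0.2, seed = 8)
  expect_false(identical(g1$proteome, g3$proteome))

  l1 <- makeLibrary(seed = 3); l2 <- makeLibrary(seed = 3)
  expect_identical(l1$truth, l2$truth)
  expect_identical(l1$structures[[1]]@atoms, l2$structures[[1]]@atoms)

  s1 <- genAnchorScene(27.5, 3, seed = 5)
  s2 <- genAnchorScene(27.5, 3, seed = 5)
  expect_identical(s1$scene@gluOeRef, s2$scene@gluOeRef)

  i1 <- genInteractorSets(letters, letters[1:5], 2, 10, seed = 2)
  i2 <- genInteractorSets(letters, letters[1:5], 2, 10, seed = 2)
  expect_identical(i1$ids, i2$ids)
  ## generators restore the caller's RNG stream
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(genProteome(5, strictPat, 0.5, seed = 99))
  expect_identical(runif(1), before)
})

test_that("proteome FASTA output is byte-identical under one seed", {
  f1 <- tempfile(fileext = ".fasta"); f2 <- tempfile(fileext = ".fasta")
  for (f in c(f1, f2)) {
    g <- genProteome(10, strictPat, 0.3, seed = 41)
    Biostrings::writeXStringSet(
      Biostrings::AAStringSet(g$proteome), f)
  }
  expect_identical(readLines(f1), readLines(f2))
})

test_that("plants are all recoverable and positives match the truth", {
  gen <- genProteome(500, strictPat, plantRate = 0.1,
                     lengthRange = c(150L, 250L), seed = 2024)
  res <- scanProteome(strictPat, gen$proteome)
  ## every planted instance appears among the reported hits
  key <- function(df) paste(df$protein_id, df$phospho_pos, df$anchor_pos)
  expect_true(all(key(gen$truth$plants) %in% key(res$hits)))
  ## truth-recorded hit table equals the scanner output (self-consistency)
  expect_equal(gen$truth$allHits, res$hits)
  ## positive-protein count within the exact binomial 99% interval around
  ## plantRate, once proteins with only background (chance) hits are set
  ## aside
  bgOnly <- setdiff(unique(res$hits$protein_id),
                    unique(gen$truth$plants$protein_id))
  nPlanted <- length(unique(gen$truth$plants$protein_id))
  ci <- qbinom(c(0.005, 0.995), 500, 0.1)
  expect_gte(nPlanted, ci[1])
  expect_lte(nPlanted, ci[2])
  expect_equal(res$summary$n_proteins_with_hit,
               nPlanted + length(bgOnly))
})

test_that("a zero plant rate over a motif-free alphabet yields no hits", {
  gen <- genProteome(30, strictPat, plantRate = 0,
                     residueFreqs = c(A = 0.5, G = 0.5),
                     lengthRange = c(60L, 80L), seed = 10)
  expect_equal(nrow(gen$truth$plants), 0L)
  expect_equal(scanProteome(strictPat, gen$proteome)$summary$n_hits, 0L)
})

test_that("unsatisfiable plant requests are rejected", {
  expect_error(genProteome(5, strictPat, 0.5, lengthRange = c(5L, 8L),
                           seed = 1), "cannot be planted")
})

test_that("interactor sampling respects the enrichment factor limits", {
  allIds <- paste0("P", 1:50)
  positives <- paste0("P", 1:20)
  inf <- genInteractorSets(allIds, positives, Inf, 15, seed = 4)
  expect_true(all(inf$ids %in% positives))
  zero <- genInteractorSets(allIds, positives, 0, 15, seed = 4)
  expect_false(any(zero$ids %in% positives))
  expect_error(genInteractorSets(allIds, positives, 0, 40, seed = 4),
               "infeasible")
})

test_that("built peptides honour the geometry constants", {
  g <- builderGeometry()
  s <- buildPeptide(extendedAngles(3), "GAG")
  at <- function(resno, name) {
    r <- s@atoms[s@atoms$resno == resno & s@atoms$elety == name, ]
    as.numeric(r[, c("x", "y", "z")])
  }
  expect_equal(sqrt(sum((at(1, "N") - at(1, "CA"))^2)), g$bNCA,
               tolerance = 1e-9)
  expect_equal(sqrt(sum((at(1, "CA") - at(1, "C"))^2)), g$bCAC,
               tolerance = 1e-9)
  expect_equal(sqrt(sum((at(1, "C") - at(2, "N"))^2)), g$bCN,
               tolerance = 1e-9)
  ## one-residue chain: four backbone atoms, no defined dihedrals
  one <- buildPeptide(cbind(NA, NA, NA), "G")
  expect_equal(nrow(one@atoms), 4L)
  expect_error(buildPeptide(cbind(0, 0, 0), "GG"), "length")
})

test_that("anchor scenes realise span and contact exactly", {
  for (sp in c(10, 20, 27.5, 35)) {
    sc <- genAnchorScene(sp, 3.0, seed = 60 + sp)$scene
    expect_equal(endpointSpan(sc), sp, tolerance = 1e-6)
    expect_equal(min(crossDist(sc@argNhRef, sc@aspOd)), 3.0,
                 tolerance = 1e-6)
  }
  expect_error(genAnchorScene(-1, 3, seed = 1), "positive")
  expect_error(genAnchorScene(10, 0, seed = 1), "positive")
})

test_that("span filtering is boundary-inclusive, idempotent, order-stable", {
  lib <- makeLibrary(seed = 421)   # extended (~20.5) + helix (~16) spans
  frags <- extractFragments(lib$structures, "xEPxxxPRx")
  spans <- vapply(frags, endpointSpan, numeric(1))
  thr <- sort(spans)[7]            # an attained span: boundary case
  kept <- filterBySpan(frags, thr)
  expect_equal(vapply(kept, function(f) f@id, character(1)),
               vapply(frags[spans >= thr], function(f) f@id, character(1)))
  expect_identical(filterBySpan(kept, thr), kept)  # idempotent
  expect_identical(filterBySpan(frags, 0), frags)
})
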