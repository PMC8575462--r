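strictPat <- parsePattern(slimPatterns()$strict)

test_that("the reconstructed p107 fragment yields exactly one strict hit", {
  hits <- scanSequence(strictPat, "MPMSPLMHPRVKEVR", id = "p107",
                       offset = 611)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$phospho_pos, 615L)   # pSer-615 in author numbering
  expect_equal(hits$anchor_pos, 621L)    # R621
  expect_equal(hits$gap_len, 4L)
  expect_equal(hits$spacing, 5L)
  expect_equal(hits$matched_seq, "SPLMHPRVKEVR")
})

test_that("sequences lacking Ser/Thr never match", {
  expect_equal(nrow(scanSequence(strictPat,
    paste(rep(c("A", "G"), 40), collapse = ""))), 0L)
  expect_equal(nrow(scanSequence(strictPat, "")), 0L)
})

test_that("a minimal synthetic match is found where the oracle says", {
  hits <- scanSequence(strictPat, "ASPAAAARVAAVR")
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$phospho_pos, 2L)
  expect_equal(hits$anchor_pos, 8L)
  expect_equal(hits$spacing, 5L)
  orc <- oracleScan(strictPat, "ASPAAAARVAAVR")
  expect_equal(unname(orc[, "phospho"]), hits$phospho_pos)
  expect_equal(unname(orc[, "anchor"]), hits$anchor_pos)
})

test_that("ambiguity letters behave per the matching rules", {
  ## X in a gap position is tolerated; X at the phosphoacceptor is not
  expect_equal(nrow(scanSequence(strictPat, "ASPXXAARVAAVR")), 1L)
  expect_equal(nrow(scanSequence(strictPat, "AXPAAAARVAAVR")), 0L)
  ## B/Z/U fail even at wildcard/gap positions
  expect_equal(nrow(scanSequence(strictPat, "ASPBAAARVAAVR")), 0L)
  ## lowercase input is uppercased with a warning
  expect_warning(h <- scanSequence(strictPat, "aspaaaarvaavr"),
                 "lowercase")
  expect_equal(nrow(h), 1L)
})

test_that("scanner equals the brute-force oracle on random sequences", {
  set.seed(20240915)
  alphabet <- c(AA20h, "X", "B", "Z", "U")
  ## biased toward motif letters, and with pattern-language instances
  ## embedded in a third of the sequences, so matches actually occur
  w <- ifelse(alphabet %in% c("S", "T", "P", "R", "K", "V", "I"), 4, 1)
  nMatch <- 0L
  for (i in seq_len(1000)) {
    L <- sample(20:200, 1)
    s <- paste(sample(alphabet, L, replace = TRUE, prob = w),
               collapse = "")
    if (i %% 3 == 0) {
      inst <- phosphoSLiM:::sampleInstance(strictPat)$instance
      pos <- sample.int(L - nchar(inst) + 1L, 1)
      substr(s, pos, pos + nchar(inst) - 1L) <- inst
    }
    hits <- scanSequence(strictPat, s)
    orc <- oracleScan(strictPat, s)
    expect_equal(nrow(hits), nrow(orc), info = paste("seq", i))
    if (nrow(orc)) {
      expect_equal(hits$phospho_pos, unname(orc[, "phospho"]),
                   info = paste("seq", i))
      expect_equal(hits$anchor_pos, unname(orc[, "anchor"]),
                   info = paste("seq", i))
      nMatch <- nMatch + nrow(orc)
    }
  }
  expect_gt(nMatch, 200)  # the comparison actually exercised matches
})

test_that("proteome scan composes per-sequence scans and counts proteins", {
  prot <- c(one = "MPMSPLMHPRVKEVR",
            two = paste(rep("P", 50), collapse = ""),
            three = paste(rep("G", 30), collapse = ""))
  res <- scanProteome(strictPat, prot)
  expect_equal(res$summary$n_hits, 1L)
  expect_equal(res$summary$n_proteins_with_hit, 1L)
  expect_equal(res$summary$n_proteins_total, 3L)
  expect_equal(res$summary$fraction_with_hit, 1 / 3)
  expect_equal(res$hits$protein_id, "one")

  allPro <- setNames(rep(paste(rep("P", 40), collapse = ""), 4),
                     paste0("p", 1:4))
  res0 <- scanProteome(strictPat, allPro)
  expect_equal(res0$summary$n_hits, 0L)
  expect_equal(res0$summary$fraction_with_hit, 0)

  expect_error(scanProteome(strictPat, character(0)), "empty")
  expect_error(scanProteome(strictPat, c(a = "AAA", a = "CCC")),
               "duplicate")
})

test_that("relaxing the pattern never loses hits (monotonicity)", {
  pats <- lapply(slimPatterns(), parsePattern)
  gen <- genProteome(60, pats$degenerate2, plantRate = 0.3,
                     lengthRange = c(80L, 160L), seed = 99)
  res <- lapply(pats, function(p) scanProteome(p, gen$proteome)$summary)
  expect_lte(res$strict$n_hits, res$degenerate1$n_hits)
  expect_lte(res$degenerate1$n_hits, res$degenerate2$n_hits)
  expect_lte(res$strict$n_proteins_with_hit,
             res$degenerate1$n_proteins_with_hit)
  expect_lte(res$degenerate1$n_proteins_with_hit,
             res$degenerate2$n_proteins_with_hit)
})

test_that("spacing histogram counts residues between phospho and anchor", {
  hits <- scanSequence(strictPat, "MPMSPLMHPRVKEVR")
  expect_equal(spacingDistribution(hits), c("5" = 1L))
  expect_length(spacingDistribution(emptyish <- hits[0, ]), 0L)
  two <- hits[c(1, 1), ]
  two$anchor_pos <- two$phospho_pos + 8L
  two$spacing <- two$anchor_pos - two$phospho_pos - 1L
  expect_equal(spacingDistribution(two), c("7" = 2L))
})

test_that("FASTA reading extracts UniProt accessions and strips gaps", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">sp|P28749|RBL1_HUMAN Retinoblastoma-like protein 1",
               "MPMSPLMHPRVKEVR",
               ">simple description here", "AAAG-GG*"), fa)
  expect_warning(prot <- readProteome(fa), "gaps")
  expect_equal(names(prot), c("P28749", "simple"))
  expect_equal(unname(prot["simple"]), "AAAGGG")
})

test_that("hit tables round-trip through TSV", {
  hits <- scanSequence(strictPat, "MPMSPLMHPRVKEVR", id = "p107")
  f <- tempfile(fileext = ".tsv")
  writeHits(hits, f)
  back <- utils::read.delim(f, stringsAsFactors = FALSE)
  expect_equal(back$phospho_pos, hits$phospho_pos)
  expect_equal(back$matched_seq, hits$matched_seq)
})
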