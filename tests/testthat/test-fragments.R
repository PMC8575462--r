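test_that("a planted motif window becomes one fragment with flanks", {
  s <- buildPeptide(extendedAngles(6), "AHPRVG")
  fr <- extractFragments(s, "xHPRVx")
  expect_length(fr, 1)
  f <- fr[[1]]
  expect_equal(f@sequence, "AHPRVG")
  expect_equal(f@coreSpan, 2:5)
  expect_equal(f@resno, 1:6)
  ## Arg at a core position is role-tagged
  expect_true(all(c("ARG_NH1", "ARG_NH2") %in% rownames(f@markedAtoms)))
})

test_that("motifs at chain termini are excluded (flanks required)", {
  s <- buildPeptide(extendedAngles(5), "HPRVG")   # no N-terminal flank
  expect_length(extractFragments(s, "xHPRVx"), 0)
  s2 <- buildPeptide(extendedAngles(5), "AHPRV")  # no C-terminal flank
  expect_length(extractFragments(s2, "xHPRVx"), 0)
})

test_that("incomplete backbone or nonstandard residues reject the window", {
  s <- buildPeptide(extendedAngles(6), "AHPRVG")
  drop <- s@atoms[!(s@atoms$resno == 3 & s@atoms$elety == "CA"), ]
  sBroken <- peptideStructure(drop, id = "BROKEN")
  expect_length(extractFragments(sBroken, "xHPRVx"), 0)

  odd <- s@atoms
  odd$resid[odd$resno == 6] <- "PTR"   # nonstandard flank residue
  expect_length(extractFragments(peptideStructure(odd, id = "ODD"),
                                 "xHPRVx"), 0)
  ## but selenomethionine reads as Met
  mse <- s@atoms
  mse$resid[mse$resno == 1] <- "MSE"
  expect_length(extractFragments(peptideStructure(mse, id = "MSE"),
                                 "xHPRVx"), 1)
})

test_that("chain breaks split matches", {
  s <- buildPeptide(extendedAngles(6), "AHPRVG")
  a <- s@atoms
  sel <- a$resno >= 5
  a[sel, c("x", "y", "z")] <- a[sel, c("x", "y", "z")] + 50
  expect_length(extractFragments(peptideStructure(a, id = "SPLIT"),
                                 "xHPRVx"), 0)
})

test_that("structures round-trip through PDB files", {
  s <- buildPeptide(helixAngles(6), "GEPLMR", id = "RT1", resolution = 1.75)
  f <- tempfile(fileext = ".pdb")
  writeStructure(s, f)
  back <- readStructure(f)
  expect_equal(back@resolution, 1.75)
  expect_equal(nrow(back@atoms), nrow(s@atoms))
  ## coordinates preserved at PDB precision (1e-3)
  m1 <- as.matrix(s@atoms[order(s@atoms$resno, s@atoms$elety),
                          c("x", "y", "z")])
  m2 <- as.matrix(back@atoms[order(back@atoms$resno, back@atoms$elety),
                             c("x", "y", "z")])
  expect_lt(max(abs(m1 - m2)), 1e-3 + 1e-9)
  ## and mining works identically on the re-read structure
  expect_length(extractFragments(back, "xEPxxRx"), 0)  # pattern mismatch
  expect_length(extractFragments(back, "xEPLMx"), 1)
})

test_that("altloc resolution keeps the highest-occupancy copy", {
  s <- buildPeptide(extendedAngles(4), "GAGA")
  a <- s@atoms
  dup <- a[a$resno == 2 & a$elety == "CA", ]
  a$altloc <- ""
  aA <- dup; aA$altloc <- "A"; aA$occ <- 0.4
  aB <- dup; aB$altloc <- "B"; aB$occ <- 0.6; aB$x <- aB$x + 1
  a <- rbind(a[!(a$resno == 2 & a$elety == "CA"), ], aA, aB)
  st <- peptideStructure(a, id = "ALT")
  kept <- st@atoms[st@atoms$resno == 2 & st@atoms$elety == "CA", ]
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$x, aB$x)  # higher occupancy wins
})

test_that("metal-phosphate survey takes per-ion shortest distances", {
  mkAtom <- function(resno, resid, elety, element, v, chain = "A")
    data.frame(chain = chain, resno = resno, insert = "", resid = resid,
               elety = elety, element = element, x = v[1], y = v[2],
               z = v[3], occ = 1, stringsAsFactors = FALSE)
  oxys <- do.call(rbind, lapply(seq_along(d <- c(2.1, 2.6, 3.0, 3.3)),
    function(i) mkAtom(500, "PO4", paste0("O", i), "O", c(d[i], 0, 0))))
  s1 <- peptideStructure(rbind(mkAtom(900, "MN", "MN", "MN", c(0, 0, 0)),
                               oxys), id = "S1")
  r1 <- mnPhosphateSurvey(list(s1))
  expect_equal(r1$perIon$shortest, 2.1)

  s2 <- peptideStructure(rbind(
    mkAtom(900, "MN", "MN", "MN", c(0, 0, 0)),
    mkAtom(901, "MN", "MN", "MN", c(10, 0, 0)),
    mkAtom(500, "PO4", "O1", "O", c(2, 0, 0)),
    mkAtom(500, "PO4", "O2", "O", c(7.2, 0, 0))), id = "S2")
  r2 <- mnPhosphateSurvey(list(s2))
  expect_equal(sort(r2$perIon$shortest), c(2.0, 2.8))
  expect_equal(r2$mean, 2.4)
  expect_equal(r2$sd, sqrt(mean((c(2, 2.8) - 2.4)^2)))  # population sd

  sNo <- peptideStructure(mkAtom(1, "GLY", "CA", "C", c(0, 0, 0)),
                          id = "NOMN")
  expect_warning(r3 <- mnPhosphateSurvey(list(s1, sNo)), "skipped")
  expect_equal(r3$skipped, "NOMN")
  expect_equal(r3$n_ions, 1L)
})
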