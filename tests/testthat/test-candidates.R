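sceneForTests <- function(seed = 314) genAnchorScene(27.5, 3.0, seed)$scene

## fragment whose anchor atoms are the scene references moved by a known
## rigid motion (so a perfect fit exists)
congruentFragment <- function(scene, seed) {
  set.seed(seed)
  lib <- makeLibrary(membersPerCluster = c(1, 0), noiseSd = 0,
                     seed = seed)
  f <- extractFragments(lib$structures, "xEPxxxPRx")[[1]]
  R <- randomRotationMatrix()
  tr <- new("RigidTransform", rotation = R, translation = rnorm(3, 0, 8))
  refs <- rbind(scene@gluOeRef, scene@argNhRef)
  moved <- applyTransform(invertTransform(tr), refs)
  rownames(moved) <- c("GLU_OE1", "GLU_OE2", "ARG_NH1", "ARG_NH2")
  f@markedAtoms <- moved
  f
}

test_that("fit score is zero iff anchor atoms are congruent to references", {
  scene <- sceneForTests()
  for (seed in 1:8) {
    f <- congruentFragment(scene, seed)
    cand <- fitCandidate(f, scene)
    expect_lt(cand$displacementScore, 1e-6)
    ## and congruence broken by a 1 Angstrom nudge scores positive
    f@markedAtoms[1, 1] <- f@markedAtoms[1, 1] + 1
    expect_gt(fitCandidate(f, scene)$displacementScore, 0.1)
  }
})

test_that("a fragment already in place fits with the identity transform", {
  scene <- sceneForTests()
  f <- congruentFragment(scene, 99)
  refs <- rbind(scene@gluOeRef, scene@argNhRef)
  rownames(refs) <- c("GLU_OE1", "GLU_OE2", "ARG_NH1", "ARG_NH2")
  f@markedAtoms <- refs
  cand <- fitCandidate(f, scene)
  expect_lt(cand$displacementScore, 1e-9)
  expect_lt(max(abs(cand$transform@rotation - diag(3))), 1e-9)
})

test_that("anchor distances are measured in the fitted pose", {
  scene <- sceneForTests()
  f <- congruentFragment(scene, 7)
  cand <- fitCandidate(f, scene)
  expect_length(cand$dGluMn, 2)
  expect_equal(cand$dGluMn,
               apply(crossDist(scene@mnPositions, scene@gluOeRef), 1, min),
               tolerance = 1e-6)
  expect_equal(cand$dArgAsp, scene@contactDistance, tolerance = 1e-6)
})

test_that("missing marked atoms abort the fit", {
  scene <- sceneForTests()
  f <- congruentFragment(scene, 3)
  f@markedAtoms <- f@markedAtoms[1:3, , drop = FALSE]
  expect_error(fitCandidate(f, scene), "ARG_NH2")
})

test_that("ranking is a stable total order with top-k retention", {
  mk <- function(id, score, comb) {
    list(fragmentId = id, transform = NULL, displacementScore = score,
         dGluMn = c(comb / 2, comb), dArgAsp = comb / 2,
         threadedSequence = NA_character_)
  }
  cands <- list(mk("c", 5, 9), mk("a", 2, 5), mk("b", 9, 1))
  rk <- rankCandidates(cands, topK = 2)
  expect_equal(rk$table$fragment_id, c("a", "c"))
  expect_equal(rk$table$displacement_score, c(2, 5))
  ## best by combined distance among retained
  expect_equal(rk$best$fragmentId, "a")
  ## equal scores break ties by id; permutation never changes the result
  ties <- list(mk("z", 1, 3), mk("y", 1, 2), mk("x", 1, 1))
  for (perm in list(c(1, 2, 3), c(3, 1, 2), c(2, 3, 1))) {
    rkT <- rankCandidates(ties[perm], topK = 2)
    expect_equal(rkT$table$fragment_id, c("x", "y"))
    expect_equal(rkT$best$fragmentId, "x")
  }
  ## 30 candidates, top 20 = the 20 smallest scores
  set.seed(44)
  scores <- sample(100, 30)
  many <- lapply(seq_along(scores), function(i)
    mk(sprintf("f%02d", i), scores[i], i))
  rkM <- rankCandidates(many, topK = 20)
  expect_equal(sort(rkM$table$displacement_score), sort(scores)[1:20])
  expect_error(rankCandidates(list()), "no candidates")
})

test_that("threading renames, renumbers, and preserves anchor atoms", {
  lib <- makeLibrary(membersPerCluster = c(1, 0), noiseSd = 0, seed = 55)
  f <- extractFragments(lib$structures, "xEPxxxPRx")[[1]]
  th <- threadSequence(f, "EPLMHPR", prefix = "MPM", suffix = "V",
                       offset = 612)
  expect_equal(th@sequence, "MPMEPLMHPRV")
  expect_equal(th@resno, 612:622)
  expect_identical(th@markedAtoms, f@markedAtoms)
  ## core backbone coordinates are untouched by threading
  expect_identical(th@backbone[4:10, , ], f@backbone[2:8, , ])
  ## extensions are clean extended-conformation backbone
  d <- backboneDihedrals(th)
  expect_lt(max(abs(d[2:3, "phi"] + 135)), 1e-6)
  expect_lt(max(abs(d[1:3, "psi"] - 135)), 1e-6)

  same <- threadSequence(f, substr(f@sequence, 2, 8), offset = f@resno[1])
  expect_identical(same@backbone[, , ], f@backbone[, , ])
  expect_error(threadSequence(f, "EPLMHP"), "core length")
})

test_that("threaded models convert to writable structures", {
  lib <- makeLibrary(membersPerCluster = c(1, 0), noiseSd = 0, seed = 56)
  f <- extractFragments(lib$structures, "xEPxxxPRx")[[1]]
  th <- threadSequence(f, "EPLMHPR", prefix = "MPM", suffix = "V",
                       offset = 612)
  st <- fragmentToStructure(th)
  expect_equal(sort(unique(st@atoms$resno)), 612:622)
  expect_true(all(c("OE1", "OE2") %in%
                    st@atoms$elety[st@atoms$resid == "GLU"]))
  expect_true(all(c("NH1", "NH2") %in%
                    st@atoms$elety[st@atoms$resid == "ARG"]))
  f2 <- tempfile(fileext = ".pdb")
  writeStructure(st, f2)
  expect_true(any(grepl("^ATOM", readLines(f2))))
})
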