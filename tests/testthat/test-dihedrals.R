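test_that("build-then-measure round-trips arbitrary dihedrals", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(5:10, 1)
    dih <- cbind(phi = runif(n, -179, 179), psi = runif(n, -179, 179),
                 omega = sample(c(180, 178, -178, 0), n, replace = TRUE))
    s <- buildPeptide(dih, paste(sample(AA20h, n, replace = TRUE),
                                 collapse = ""), id = "RT")
    fr <- extractFragments(s, paste(rep("x", n), collapse = ""))
    ## full-window fragment exists exactly once
    full <- Filter(function(f) nchar(f@sequence) == n, fr)
    expect_length(full, 1)
    d <- backboneDihedrals(full[[1]])
    cmp <- !is.na(dih) & !is.na(d)
    cmp[1, "phi"] <- FALSE; cmp[n, c("psi", "omega")] <- FALSE
    expect_lt(max(abs(wrapAngleDiff(d[cmp], dih[cmp]))), 1e-6)
  }
})

test_that("cis peptide bonds (omega = 0) are recovered exactly", {
  dih <- cbind(phi = rep(-80, 5), psi = rep(150, 5), omega = rep(0, 5))
  s <- buildPeptide(dih, "GAGAG")
  fr <- extractFragments(s, "xxxxx")[[1]]
  d <- backboneDihedrals(fr)
  expect_lt(max(abs(d[1:4, "omega"])), 1e-6)
})

test_that("terminal angles are undefined as per the torsion definitions", {
  s <- buildPeptide(extendedAngles(4), "GAGA")
  d <- backboneDihedrals(extractFragments(s, "xxxx")[[1]])
  expect_true(is.na(d[1, "phi"]))
  expect_true(is.na(d[4, "psi"]))
  expect_true(is.na(d[4, "omega"]))
  expect_false(anyNA(d[2:3, ]))
})

test_that("dihedral profiles are invariant under rigid motion", {
  set.seed(5)
  s <- buildPeptide(helixAngles(6), "GEPLMR")
  f <- extractFragments(s, "xxxxxx")[[1]]
  d0 <- backboneDihedrals(f)
  R <- randomRotationMatrix()
  tr <- new("RigidTransform", rotation = R, translation = rnorm(3, 0, 10))
  f2 <- f
  for (at in c("N", "CA", "C", "O"))
    f2@backbone[, at, ] <- applyTransform(tr, f@backbone[, at, ])
  d1 <- backboneDihedrals(f2)
  expect_lt(max(abs(wrapAngleDiff(d0[!is.na(d0)], d1[!is.na(d1)]))), 1e-6)
})

test_that("dihedral distance follows its definition on simple cases", {
  m <- cbind(phi = c(NA, -60), psi = c(120, NA), omega = c(180, NA))
  attr(m, "core") <- c(TRUE, TRUE)
  expect_equal(dihedralDistance(m, m), 0)
  m2 <- m; m2[1, "psi"] <- 150
  expect_equal(dihedralDistance(m, m2), 30)
  m3 <- m; m3[1, "psi"] <- 179; m4 <- m; m4[1, "psi"] <- -179
  expect_equal(dihedralDistance(m3, m4), 2)   # circular wrap
  mna <- m; mna[] <- NA
  attr(mna, "core") <- c(TRUE, TRUE)
  expect_error(dihedralDistance(m, mna), "no comparable")
})

test_that("dihedral distance is a metric (symmetry, identity, triangle)", {
  set.seed(77)
  mk <- function() {
    m <- cbind(phi = runif(4, -180, 180), psi = runif(4, -180, 180),
               omega = runif(4, -180, 180))
    attr(m, "core") <- rep(TRUE, 4)
    m
  }
  for (i in 1:50) {
    a <- mk(); b <- mk(); cc <- mk()
    dab <- dihedralDistance(a, b)
    expect_equal(dab, dihedralDistance(b, a))
    expect_equal(dihedralDistance(a, a), 0)
    expect_lte(dab, dihedralDistance(a, cc) + dihedralDistance(cc, b) + 1e-9)
    expect_gte(dab, 0); expect_lte(dab, 180)
  }
})

test_that("degenerate colinear geometry warns instead of crashing", {
  expect_warning(v <- phosphoSLiM:::torsionAngle(c(0, 0, 0), c(1, 0, 0),
                                                 c(2, 0, 0), c(3, 1, 0)),
                 "degenerate")
  expect_true(is.na(v))
})
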