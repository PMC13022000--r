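test_that("parseStructure reads minimal PDB text and flags records", {
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   5.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.200   0.000   5.000  1.00  0.00           C",
    "ATOM      3  N   GLY A   2       0.000   0.000   8.000  1.00  0.00           N",
    "ATOM      4  CA  GLY A   2       1.200   0.000   8.000  1.00  0.00           C",
    "HETATM    5  C1  LIG A   9       0.000   0.000   0.000  1.00  0.00           C",
    "HETATM    6  O1  LIG A   9       1.000   0.000   0.000  1.00  0.00           O",
    "END")
  f <- tempfile(fileext = ".pdb"); writeLines(lines, f)
  atoms <- parseStructure(f)
  expect_equal(nrow(atoms), 6)
  expect_equal(length(unique(atoms$resno[atoms$type == "ATOM"])), 2)
  expect_equal(sum(atoms$isLigand), 2)
  expect_equal(nrow(ligandCandidates(atoms)), 1)
  expect_false(any(atoms$isHydrogen))
})

test_that("waters are never ligand candidates", {
  lines <- c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   3.000  1.00  0.00           C",
    "HETATM    2  O   HOH A   5       0.000   0.000   0.000  1.00  0.00           O",
    "HETATM    3  O   HOH A   6       2.000   0.000   0.000  1.00  0.00           O",
    "END")
  f <- tempfile(fileext = ".pdb"); writeLines(lines, f)
  atoms <- parseStructure(f)
  expect_equal(sum(atoms$isLigand), 0)
  expect_equal(nrow(ligandCandidates(atoms)), 0)
  expect_error(extractPocketDistance(atoms, "HOH"), "no ligand")
})

test_that("fixture structures round-trip through the parser", {
  for (seed in c(1, 2, 3)) {
    fx <- makeStructure(nResidues = 8, seed = seed)
    atoms <- parseStructure(fx$path)
    expect_equal(nrow(atoms), nrow(fx$atoms))
    expect_equal(atoms$x, fx$atoms$x, tolerance = 1e-3)
    expect_equal(atoms$y, fx$atoms$y, tolerance = 1e-3)
    expect_equal(atoms$z, fx$atoms$z, tolerance = 1e-3)
  }
})

test_that("distance rule honours the closed cutoff boundary", {
  atoms <- rbind(
    mkAtoms(c(4.9, 0, 0), "C", resno = 1),               # residue A inside
    mkAtoms(c(5.1, 0, 0), "C", resno = 2),               # residue B outside
    mkAtoms(c(0, 0, 0), "C", resno = 9, resid = "LIG", type = "HETATM"))
  p <- extractPocketDistance(atoms, "LIG", cutoff = 5)
  expect_equal(pocketResidues(p)$resno, 1)
  ## exact boundary is inside (closed)
  atomsB <- atoms; atomsB$x[1] <- 5.0
  pB <- extractPocketDistance(atomsB, "LIG", cutoff = 5)
  expect_equal(pocketResidues(pB)$resno, 1)
  ## larger cutoff only adds residues
  p6 <- extractPocketDistance(atoms, "LIG", cutoff = 6)
  expect_true(all(pocketKeys(p) %in% pocketKeys(p6)))
  expect_equal(sort(pocketResidues(p6)$resno), c(1, 2))
})

test_that("both extraction rules match the brute-force oracle", {
  for (seed in 1:8) {
    fx <- makeStructure(nResidues = 20, nLigandAtoms = 6,
                        residueDistances = seq(2.5, 14, length.out = 20),
                        seed = seed)
    atoms <- parseStructure(fx$path)
    p5 <- extractPocketDistance(atoms, "LIG", cutoff = 5)
    expect_identical(pocketKeys(p5),
                     bruteForceDistancePocket(atoms, 5))
    pv <- extractPocketVdw(atoms, "LIG", pad = 0.5, minContacts = 2)
    expect_identical(pocketKeys(pv),
                     bruteForceVdwPocket(atoms, 0.5, 2))
  }
})

test_that("pocket membership is invariant under rigid motion", {
  fx <- makeStructure(nResidues = 15, seed = 4)
  atoms <- parseStructure(fx$path)
  ref <- pocketKeys(extractPocketDistance(atoms, "LIG"))
  for (s in 1:3) {
    moved <- rigidTransform(atoms, seed = s)
    expect_identical(pocketKeys(extractPocketDistance(moved, "LIG")), ref)
  }
})

test_that("monotonicity: pocket grows with the cutoff", {
  fx <- makeStructure(nResidues = 18, seed = 9)
  atoms <- parseStructure(fx$path)
  cuts <- c(3, 4, 5, 6.5, 8)
  pockets <- lapply(cuts, function(cc)
    pocketKeys(suppressWarnings(
      extractPocketDistance(atoms, "LIG", cutoff = cc))))
  for (i in seq_along(cuts)[-1])
    expect_true(all(pockets[[i - 1]] %in% pockets[[i]]))
})

test_that("vdW rule counts distinct atom pairs against minContacts", {
  ## two C atoms of one residue each 3.8 A from a ligand C
  ## (limit 1.70 + 1.70 + 0.5 = 3.90)
  atoms2 <- rbind(
    mkAtoms(rbind(c(3.8, 0, 0), c(0, 3.8, 0)), "C", resno = 1),
    mkAtoms(c(0, 0, 0), "C", resno = 9, resid = "LIG", type = "HETATM"))
  expect_equal(nResidues(extractPocketVdw(atoms2, "LIG")), 1)
  atoms1 <- rbind(
    mkAtoms(rbind(c(3.8, 0, 0), c(0, 8, 0)), "C", resno = 1),
    mkAtoms(c(0, 0, 0), "C", resno = 9, resid = "LIG", type = "HETATM"))
  expect_equal(nResidues(suppressWarnings(
    extractPocketVdw(atoms1, "LIG"))), 0)
  ## pad 0: atoms exactly at r_a + r_b count (closed boundary)
  atomsB <- rbind(
    mkAtoms(rbind(c(3.4, 0, 0), c(0, 3.4, 0)), "C", resno = 1),
    mkAtoms(c(0, 0, 0), "C", resno = 9, resid = "LIG", type = "HETATM"))
  expect_equal(nResidues(extractPocketVdw(atomsB, "LIG", pad = 0)), 1)
  ## unknown element is a named error
  atomsX <- atoms2; atomsX$element[1] <- "QQ"
  expect_error(extractPocketVdw(atomsX, "LIG"), "QQ")
})

test_that("clash report equals explicit pair enumeration", {
  ## one ligand pair at 1.0 A -> fraction 1.0 over its single pair
  lig <- mkAtoms(rbind(c(0, 0, 0), c(1, 0, 0)), "C", resno = 9,
                 resid = "LIG", type = "HETATM")
  poc <- mkAtoms(rbind(c(5, 0, 0), c(9, 0, 0)), "C", resno = 1)
  r <- clashReport(poc, lig)
  expect_equal(r@ligandClashFraction, 1.0)
  expect_equal(r@pocketClashFraction, 0.0)
  expect_equal(r@crossClashCount, 0L)
  ## all pairwise distances above the threshold -> all zero
  far <- mkAtoms(rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0)), "C", resno = 9,
                 resid = "LIG", type = "HETATM")
  r0 <- clashReport(poc, far)
  expect_equal(c(r0@pocketClashFraction, r0@ligandClashFraction,
                 r0@crossClashCount), c(0, 0, 0))
  ## randomized 20-atom fixtures with planted overlaps vs the oracle
  for (seed in 1:5) {
    set.seed(seed)
    pxyz <- matrix(runif(30, 0, 4), ncol = 3)
    lxyz <- matrix(runif(30, 0, 4), ncol = 3)
    pa <- mkAtoms(pxyz, "C", resno = 1)
    la <- mkAtoms(lxyz, "C", resno = 9, resid = "LIG", type = "HETATM")
    rr <- clashReport(pa, la)
    expect_equal(rr@pocketClashFraction, bruteForceClash(pxyz))
    expect_equal(rr@ligandClashFraction, bruteForceClash(lxyz))
    expect_equal(rr@crossClashCount,
                 as.integer(bruteForceClash(pxyz, lxyz)))
    ## permutation invariance in atom order
    perm <- sample(nrow(pa))
    rp <- clashReport(pa[perm, ], la[sample(nrow(la)), ])
    expect_equal(rp@pocketClashFraction, rr@pocketClashFraction)
    expect_equal(rp@crossClashCount, rr@crossClashCount)
  }
  ## single-atom group has fraction 0 by convention
  one <- mkAtoms(c(0, 0, 0), "C", resno = 9, resid = "LIG",
                 type = "HETATM")
  expect_equal(clashReport(poc, one)@ligandClashFraction, 0)
})

test_that("clash filter discards at every boundary", {
  mk <- function(p, l, x) new("ClashReport", pocketClashFraction = p,
                              ligandClashFraction = l,
                              crossClashCount = as.integer(x),
                              threshold = 1.2)
  expect_true(passesClashFilter(mk(0.004, 0.009, 4)))
  expect_false(passesClashFilter(mk(0.005, 0.0, 0)))
  expect_false(passesClashFilter(mk(0.0, 0.01, 0)))
  expect_false(passesClashFilter(mk(0.0, 0.0, 5)))
})

test_that("amino-acid enrichment matches hand-tallied counts", {
  mkPocket <- function(resids) {
    new("PocketDefinition", structureId = "s",
        ligandId = c("LIG", "A", "9"),
        residues = data.frame(chain = "A", resno = seq_along(resids),
                              insert = "", resid = resids,
                              stringsAsFactors = FALSE),
        rule = "distance_5A", params = list(cutoff = 5))
  }
  ## composition equal to the reference -> all ratios 1
  ref <- pdbAaFrequencies()
  names3 <- names(erepoc:::.aa3)
  counts <- round(ref[erepoc:::.aa3[names3]] * 10000)
  pool <- rep(names3, counts)
  ratios <- aaEnrichment(mkPocket(pool),
                         referenceFreq = table(erepoc:::.aa3[pool]) /
                           length(pool))
  expect_equal(as.numeric(ratios), rep(1, 20), tolerance = 1e-12)
  ## degenerate composition: all MET with reference freq 0.02
  refMet <- setNames(rep(0.049, 20), names(ref)); refMet["M"] <- 0.02
  refMet <- refMet / sum(refMet)   # keep sum 1; M stays at 0.02 approx
  refMet["M"] <- 0.02
  r2 <- aaEnrichment(mkPocket(rep("MET", 40)), referenceFreq = refMet)
  expect_equal(unname(r2["M"]), 1 / 0.02, tolerance = 1e-6)
  expect_true(all(r2[setdiff(names(r2), "M")] == 0))
  ## mixed fixture of 200 residues vs direct tally
  set.seed(3)
  resids <- sample(names3, 200, replace = TRUE, prob = runif(20, 0.5, 2))
  r3 <- aaEnrichment(mkPocket(resids))
  tab <- table(factor(erepoc:::.aa3[resids], levels = names(ref)))
  expect_equal(as.numeric(r3), unname(as.numeric(tab) / 200 / ref),
               tolerance = 1e-12)
  ## non-standard residues excluded with a count
  r4 <- aaEnrichment(mkPocket(c(rep("MET", 10), "MSE", "LLP")),
                     referenceFreq = refMet)
  expect_equal(attr(r4, "nExcluded"), 2)
})

test_that("pockets survive the TSV round trip", {
  fx <- makeStructure(nResidues = 12, seed = 2)
  atoms <- parseStructure(fx$path)
  p <- extractPocketDistance(atoms, "LIG", structureId = "fix2")
  f <- tempfile(fileext = ".tsv")
  writePocketsTsv(p, f)
  back <- readBindingResiduesTsv(f)[[1]]
  expect_equal(pocketResidues(back)$resno, pocketResidues(p)$resno)
  expect_equal(back@structureId, "fix2")
})
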