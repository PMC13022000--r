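test_that("knn equals an exhaustive scan-and-sort oracle", {
  set.seed(8)
  R <- matrix(rnorm(30 * 16), 30, 16,
              dimnames = list(sprintf("r%02d", 1:30), NULL))
  Q <- matrix(rnorm(4 * 16), 4, 16,
              dimnames = list(sprintf("q%d", 1:4), NULL))
  hits <- knnSearch(Q, R, k = 5)
  for (qi in rownames(Q)) {
    cs <- apply(R, 1, function(r) latentCosine(Q[qi, ], r))
    ord <- order(-cs, names(cs))[1:5]
    got <- hits[hits$query == qi, ]
    expect_identical(got$ref, names(cs)[ord])
    expect_equal(got$cosine, unname(cs[ord]), tolerance = 1e-12)
    expect_identical(got$rank, 1:5)
    expect_true(all(diff(got$cosine) <= 1e-12))
  }
  ## query identical to a reference -> rank 1, cosine 1
  Q2 <- R[3, , drop = FALSE]; rownames(Q2) <- "probe"
  h2 <- knnSearch(Q2, R, k = 1)
  expect_identical(h2$ref, "r03")
  expect_equal(h2$cosine, 1.0)
  ## k equal to the reference size returns everything sorted
  hAll <- knnSearch(Q2, R, k = 30)
  expect_equal(nrow(hAll), 30)
  expect_identical(hAll$rank, 1:30)
  expect_error(knnSearch(Q2, R, k = 31), "exceeds")
  ## self-hits excluded when ids overlap
  h3 <- knnSearch(R[3, , drop = FALSE], R, k = 2)
  expect_false("r03" %in% h3$ref)
})

test_that("threshold filter is strictly greater-than", {
  s <- c(a = 0.8, b = 0.80000, c = 0.81, d = 1.0, e = 0.2)
  kept <- thresholdNeighbors(s, tau = 0.8)
  expect_identical(names(kept), c("c", "d"))
  expect_identical(names(thresholdNeighbors(setNames(rep(0.8, 4),
                                                     letters[1:4]))),
                   character(0))
  all1 <- setNames(rep(1, 3), letters[1:3])
  expect_identical(names(thresholdNeighbors(all1)), letters[1:3])
  ## scan oracle on a mixed fixture
  set.seed(2)
  v <- setNames(runif(50, 0.5, 1), sprintf("p%02d", 1:50))
  expect_identical(thresholdNeighbors(v, 0.8), v[v > 0.8])
})

test_that("screening filter reproduces the boundary semantics", {
  rec <- data.frame(
    accession = c("P1", "P2", "P3", "P4", "P4", "P4", "P5"),
    pocketId = sprintf("k%d", 1:7),
    volume = c(799, 1000, 1000, 900, 1200, 850, 800),
    plddt = c(0.99, 0.69, 0.90, 0.95, 0.92, 0.9, 0.7),
    maxCosine = c(0.95, 0.95, 0.80, 0.85, 0.92, 0.9, 0.81),
    stringsAsFactors = FALSE)
  out <- screenPockets(rec)
  ## volume 799 excluded; plddt 0.69 excluded; cosine exactly 0.8 excluded
  expect_false(any(out$pockets$accession %in% c("P1", "P2", "P3")))
  ## volume 800 and plddt 0.70 at the boundary are kept
  expect_true("P5" %in% out$pockets$accession)
  ## dedupe keeps the max-cosine pocket per accession
  expect_equal(sum(out$pockets$accession == "P4"), 3)
  expect_equal(out$accessions$pocketId[out$accessions$accession == "P4"],
               "k5")
  expect_equal(nrow(out$accessions), 2)
})

test_that("screening accepts 0-100 pLDDT and is monotone in thresholds", {
  set.seed(4)
  rec <- data.frame(
    accession = sprintf("P%03d", 1:60), pocketId = sprintf("k%03d", 1:60),
    volume = runif(60, 400, 2000), plddt = runif(60, 40, 100),
    maxCosine = runif(60, 0.5, 1), stringsAsFactors = FALSE)
  rec01 <- rec; rec01$plddt <- rec$plddt / 100
  expect_equal(screenPockets(rec)$pockets$pocketId,
               screenPockets(rec01)$pockets$pocketId)
  base <- screenPockets(rec)$pockets$pocketId
  expect_true(all(screenPockets(rec, tau = 0.9)$pockets$pocketId %in% base))
  expect_true(all(screenPockets(rec, minVolume = 1200)$pockets$pocketId
                  %in% base))
})

test_that("ligand-pocket correlation matches the closed-form Pearson", {
  set.seed(6)
  bits <- matrix(rbinom(20 * 128, 1, 0.25), 20, 128)
  bits[rowSums(bits) == 0, 1] <- 1L
  rownames(bits) <- sprintf("p%02d", 1:20)
  fps <- fingerprintSet(bits)
  L <- matrix(rnorm(20 * 12), 20, 12, dimnames = list(rownames(bits), NULL))
  r <- ligandPocketCorrelation(L, fps, seed = 3)
  ## direct covariance-formula oracle over the same pairs
  tm <- tanimoto(fps); cs <- cosineMatrix(L)
  up <- upper.tri(tm)
  x <- tm[up]; y <- cs[up]
  oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(r, oracle, tolerance = 1e-12)
  ## identity construction: ligand cosine vs the same vectors -> r = 1
  rId <- ligandPocketCorrelation(bits, fps, metric = "cosine")
  expect_equal(rId, 1.0, tolerance = 1e-12)
  expect_error(ligandPocketCorrelation(matrix(1, 20, 4) +
                                         diag(20)[, 1:4] * 0, fps),
               "constant")
})
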