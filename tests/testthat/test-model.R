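test_that("projection has the documented shape and eval determinism", {
  m <- projectionModel()                       # 1280 -> 512 -> 256
  expect_equal(c(m@inputDim, m@hiddenDim, m@latentDim),
               c(1280L, 512L, 256L))
  x <- matrix(rnorm(3 * 1280), 3)
  L1 <- projectPockets(m, x)
  L2 <- projectPockets(m, x)
  expect_equal(dim(L1), c(3L, 256L))
  expect_identical(L1, L2)
  expect_error(projectPockets(m, matrix(0, 2, 100)), "1280")
})

test_that("zero affine maps with identity normalization give GELU(0) = 0", {
  m <- projectionModel(inputDim = 8, hiddenDim = 6, latentDim = 4, seed = 1)
  for (l in 1:2) {
    m@layers[[l]]$W[] <- 0; m@layers[[l]]$b[] <- 0
    m@layers[[l]]$gamma[] <- 1; m@layers[[l]]$beta[] <- 0
    m@layers[[l]]$runMean[] <- 0; m@layers[[l]]$runVar[] <- 1
  }
  out <- projectPockets(m, matrix(rnorm(16), 2, 8))
  expect_equal(unname(out), matrix(0, 2, 4))
})

test_that("toDistribution matches direct softmax evaluation", {
  ## constant row -> uniform
  expect_equal(toDistribution(rep(0.4, 7)), rep(1 / 7, 7))
  ## frozen two-entry softmax: (e/(e+1), 1/(e+1))
  p <- toDistribution(c(1, 0))
  expect_equal(p, c(exp(1) / (exp(1) + 1), 1 / (exp(1) + 1)),
               tolerance = 1e-12)
  ## temperature -> 0 concentrates mass on the argmax
  p0 <- toDistribution(c(0.2, 0.9, 0.1), temperature = 1e-3)
  expect_gt(p0[2], 1 - 1e-6)
  expect_error(toDistribution(numeric(0)), "empty")
  ## probabilities: non-negative, sum 1
  set.seed(1)
  for (i in 1:20) {
    p <- toDistribution(rnorm(31), temperature = runif(1, 0.1, 3))
    expect_true(all(p >= 0))
    expect_equal(sum(p), 1, tolerance = 1e-8)
  }
})

test_that("KL loss is zero at identity and matches a direct-sum oracle", {
  set.seed(2)
  P <- t(apply(matrix(runif(5 * 9), 5), 1, function(r) r / sum(r)))
  expect_equal(klLoss(P, P), 0)
  u <- matrix(1 / 9, 5, 9)
  expect_equal(klLoss(u, u), 0)
  ## swapped near-degenerate distributions -> large positive, equal to
  ## explicit summation
  eps <- 1e-8
  P2 <- rbind(c(1 - eps, eps)); Q2 <- rbind(c(eps, 1 - eps))
  direct <- (1 - eps) * log((1 - eps) / eps) + eps * log(eps / (1 - eps))
  expect_equal(klLoss(P2, Q2), direct, tolerance = 1e-12)
  expect_gt(klLoss(P2, Q2), 17)
  expect_error(klLoss(P, P[, 1:5]), "identical index sets")
  ## non-negativity over random pairs
  for (i in 1:50) {
    A <- t(apply(matrix(runif(3 * 8), 3), 1, function(r) r / sum(r)))
    B <- t(apply(matrix(runif(3 * 8), 3), 1, function(r) r / sum(r)))
    expect_gte(klLoss(A, B), 0)
  }
})

test_that("analytic gradients match central finite differences", {
  set.seed(9)
  X <- matrix(rnorm(4 * 8), 4, 8)
  m <- projectionModel(inputDim = 8, hiddenDim = 6, latentDim = 4,
                       dropout = 0, seed = 2)
  Qs <- matrix(runif(16, 0.5, 2), 4); Qs <- (Qs + t(Qs)) / 2
  Qd <- erepoc:::.batchDistributionsFull(Qs, 1, 1e-8)
  st <- erepoc:::contrastiveStep(m@layers, X, Qd, training = TRUE,
                                 dropout = 0, temperature = 1,
                                 epsilon = 1e-8)
  ng <- erepoc:::numericalGradients(m@layers, X, Qd, 1, 1e-8)
  for (l in 1:2)
    for (p in c("W", "b", "gamma", "beta")) {
      a <- st$grads[[l]][[p]]; b <- ng[[l]][[p]]
      rel <- max(abs(a - b) / pmax(abs(b), 1e-6))
      expect_lt(rel, 1e-4)
    }
})

test_that("training is reproducible and returns the argmin checkpoint", {
  ds <- smallDataset()
  cfg <- quickConfig()
  f1 <- trainProjection(ds$pockets, ds$fingerprints, cfg)
  f2 <- trainProjection(ds$pockets, ds$fingerprints, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model@layers, f2$model@layers)
  ## returned checkpoint no worse than the first epoch
  expect_lte(min(f1$history$valLoss),
             f1$history$valLoss[1] + 1e-12)
  expect_equal(f1$history$valLoss[f1$bestEpoch], min(f1$history$valLoss))
  expect_true(f1$model@trained)
})

test_that("training improves the ligand-latent alignment over raw pooling", {
  ds <- smallDataset(n = 384, classes = 4, dim = 48, seed = 13)
  cfg <- trainingConfig(trainBatches = 12L, valBatches = 4L,
                        batchSize = 96L, patience = 5L, maxEpochs = 25L,
                        seed = 13L)
  fit <- trainProjection(ds$pockets, ds$fingerprints, cfg)
  pe <- encodePockets(fit$model, ds$pockets)
  rLat <- ligandPocketCorrelation(t(latent(pe)), ds$fingerprints,
                                  seed = 13)
  rRaw <- ligandPocketCorrelation(t(pooled(pe)), ds$fingerprints,
                                  seed = 13)
  expect_gt(rLat, rRaw)
  ## within/between latent cosine gap beats the raw-embedding gap
  gapOf <- function(M) {
    C <- cosineMatrix(M); up <- upper.tri(C)
    same <- outer(ligandClass(pe), ligandClass(pe), "==")
    mean(C[up & same]) - mean(C[up & !same])
  }
  expect_gt(gapOf(t(latent(pe))), gapOf(t(pooled(pe))))
})

test_that("encoding is batch-order invariant and order preserving", {
  ds <- smallDataset(n = 150, classes = 3, dim = 32, seed = 5)
  m <- projectionModel(inputDim = 32, seed = 3)
  X <- t(pooled(ds$pockets))
  L <- encodePockets(m, X)
  expect_equal(nrow(L), nrow(X))
  perm <- sample(nrow(X))
  Lp <- encodePockets(m, X[perm, ])
  expect_equal(Lp, L[perm, ], tolerance = 1e-12)
  ## single input equals its row of the batched output
  expect_equal(unname(encodePockets(m, X[7, , drop = FALSE])),
               unname(L[7, , drop = FALSE]), tolerance = 1e-12)
})

test_that("checkpoints round-trip through save/load", {
  m <- projectionModel(inputDim = 16, seed = 4)
  f <- tempfile(fileext = ".ckpt")
  saveProjectionModel(m, f)
  m2 <- loadProjectionModel(f)
  expect_identical(m2@layers, m@layers)
  expect_equal(m2@latentDim, m@latentDim)
  x <- matrix(rnorm(32), 2, 16)
  expect_identical(projectPockets(m, x), projectPockets(m2, x))
})
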