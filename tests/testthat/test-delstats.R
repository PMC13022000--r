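test_that("Z-scores are exactly standardized", {
  z <- dockingZscores(c(-1, 0, 1))
  expect_equal(z, c(-sqrt(3 / 2), 0, sqrt(3 / 2)), tolerance = 1e-12)
  set.seed(1)
  s <- rnorm(500, -6, 1.3)
  z2 <- dockingZscores(s)
  expect_equal(mean(z2), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(z2^2)), 1, tolerance = 1e-12)   # population sd
  z3 <- dockingZscores(s, sdType = "sample")
  expect_equal(sd(z3), 1, tolerance = 1e-12)
  expect_equal(dockingZscores(c(-6, -6, -5))[1],
               dockingZscores(c(-6, -6, -5))[2])
  expect_error(dockingZscores(rep(-3, 5)), "zero variance")
})

test_that("enrichment factor counts scores at or below the cutoff", {
  pos <- c(-9, -8, -7, -6); neg <- c(-9, -8, -7, -6)
  expect_equal(unname(enrichmentFactor(pos, neg, c(-9, -7.5, -6))),
               c(1, 1, 1))
  ## cutoff below all scores is undefined, reported missing
  expect_true(is.na(enrichmentFactor(pos, neg, -20)))
  ## counting oracle on a shifted fixture
  set.seed(2)
  p2 <- rnorm(400, -7.5); n2 <- rnorm(400, -6)
  for (c_ in c(-9, -8.5, -8, -7.5)) {
    ef <- unname(enrichmentFactor(p2, n2, c_))
    if (sum(n2 <= c_) == 0) {
      expect_true(is.na(ef))      # undefined, reported missing
    } else {
      oracle <- (sum(p2 <= c_) / 400) / (sum(n2 <= c_) / 400)
      expect_equal(ef, oracle, tolerance = 1e-12)
    }
  }
  ## scale invariance
  expect_equal(unname(enrichmentFactor(p2, n2, -8)),
               unname(enrichmentFactor(2.5 * p2, 2.5 * n2, 2.5 * -8)),
               tolerance = 1e-12)
})

test_that("Monte Carlo EF is reproducible and unbiased under the null", {
  set.seed(3)
  pool <- rnorm(2000, -6)
  mc1 <- monteCarloEF(pool, pool, sampleSize = 150, iterations = 200,
                      cutoffs = c(-7.5, -7, -6.5, -6), seed = 5)
  mc2 <- monteCarloEF(pool, pool, sampleSize = 150, iterations = 200,
                      cutoffs = c(-7.5, -7, -6.5, -6), seed = 5)
  expect_identical(mc1, mc2)
  ## identical pools: mean EF near 1 at interior cutoffs
  interior <- mc1$cutoff >= -7
  expect_true(all(abs(mc1$efMean[interior] - 1) <=
                    3 * mc1$efSd[interior] / sqrt(200) + 0.05))
  expect_error(monteCarloEF(pool[1:50], pool, sampleSize = 100), "pool")
})

test_that("Monte Carlo EF converges to the full-pool analytic value", {
  ## interior cutoffs: subsample counts are large enough that the
  ## ratio-of-counts estimator is effectively unbiased, so the mean must
  ## sit within 3 standard errors of the full-pool EF
  set.seed(4)
  shift <- 1.2
  pos <- rnorm(4000, -6 - shift); neg <- rnorm(4000, -6)
  cutoffs <- c(-6.5, -6, -5.5)
  full <- enrichmentFactor(pos, neg, cutoffs)
  mc <- monteCarloEF(pos, neg, sampleSize = 200, iterations = 1000,
                     cutoffs = cutoffs, seed = 6)
  expect_true(all(abs(mc$efMean - full) <=
                    3 * mc$efSd / sqrt(mc$nDefined)))
  ## more iterations track the full-pool EF at least as well on average
  mc100 <- monteCarloEF(pos, neg, sampleSize = 200, iterations = 100,
                        cutoffs = cutoffs, seed = 6)
  mc2k <- monteCarloEF(pos, neg, sampleSize = 200, iterations = 2000,
                       cutoffs = cutoffs, seed = 6)
  expect_lt(mean(abs(mc2k$efMean - full)),
            mean(abs(mc100$efMean - full)) + 0.02)
})

test_that("top-fraction extraction is deterministic under ties", {
  df <- data.frame(compound_id = sprintf("c%03d", 1:100),
                   target_id = "T1",
                   score = c(-9, rep(-5, 99)), stringsAsFactors = FALSE)
  top <- topFraction(df, 0.01)
  expect_equal(nrow(top), 1)
  expect_equal(top$score, -9)
  expect_equal(nrow(topFraction(df, 1.0)), 100)
  ## boundary ties broken by compound id: sort-and-slice oracle
  set.seed(5)
  df2 <- data.frame(compound_id = sprintf("c%03d", sample(250)),
                    target_id = rep(c("A", "B"), 125),
                    score = round(rnorm(250, -6), 1),
                    stringsAsFactors = FALSE)
  top2 <- topFraction(df2, 0.02)
  for (tg in c("A", "B")) {
    sub <- df2[df2$target_id == tg, ]
    oracle <- sub[order(sub$score, sub$compound_id), ][
      seq_len(ceiling(0.02 * nrow(sub))), ]
    expect_equal(top2[top2$target_id == tg, ]$compound_id,
                 oracle$compound_id)
  }
})

test_that("Mann-Whitney U matches exhaustive enumeration and wilcox.test", {
  ## identical samples: no evidence
  r0 <- mannWhitneyOneSided(c(1, 2, 3), c(1, 2, 3))
  expect_gt(r0$p, 0.3); expect_lt(abs(r0$effectR), 0.35)
  ## {1,2} vs {3,4}: U = 0; one-sided exact p = 1/C(4,2)
  r1 <- mannWhitneyOneSided(c(1, 2), c(3, 4))
  expect_equal(r1$U, 0)
  expect_equal(r1$p, 1 / choose(4, 2))
  ## all x below all y at n = 10 each: exact minimum
  r2 <- mannWhitneyOneSided(1:10, 101:110)
  expect_equal(r2$U, 0)
  expect_equal(r2$p, 1 / choose(20, 10))
  expect_lt(r2$effectR, 0)
  ## random fixtures with n_x + n_y <= 12 vs enumeration
  set.seed(6)
  for (i in 1:12) {
    nx <- sample(2:6, 1); ny <- sample(2:6, 1)
    x <- sample(1:6, nx, replace = TRUE)  # ties on purpose
    y <- sample(1:6, ny, replace = TRUE)
    res <- mannWhitneyOneSided(x, y)
    r <- rank(c(x, y))
    idx <- combn(nx + ny, nx)
    us <- colSums(matrix(r[idx], nrow = nx)) - nx * (nx + 1) / 2
    uObs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
    expect_equal(res$p, mean(us <= uObs + 1e-9), tolerance = 1e-12)
    expect_equal(res$U, uObs)
  }
  ## large-sample normal approximation against the reference test
  set.seed(7)
  x <- rnorm(80, -0.4); y <- rnorm(90)
  res <- mannWhitneyOneSided(x, y)
  ref <- wilcox.test(x, y, alternative = "less", exact = FALSE,
                     correct = TRUE)
  expect_equal(res$p, ref$p.value, tolerance = 1e-10)
  expect_equal(res$U, unname(ref$statistic))
})
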