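## Docking-score screening statistics: global Z-scores, enrichment
## factors, Monte Carlo EF curves, top-fraction extraction, and the
## one-sided Mann-Whitney U test.

#' Global Z-score transformation of docking scores
#'
#' `Z_i = (S_i - mu_all) / sigma_all`, using the global mean and standard
#' deviation over all scores.  More negative docking scores (stronger
#' predicted binding) map to more negative Z.
#'
#' @param scores numeric docking scores, kcal/mol (>= 2 values).
#' @param sdType `"population"` (divide by N, default) or `"sample"`.
#' @return Numeric Z-scores (mean 0, chosen sd exactly 1).
#' @export
dockingZscores <- function(scores, sdType = c("population", "sample")) {
  sdType <- match.arg(sdType)
  stopifnot(length(scores) >= 2L, all(is.finite(scores)))
  mu <- mean(scores)
  s2 <- sum((scores - mu)^2) /
    (if (sdType == "population") length(scores) else length(scores) - 1L)
  if (s2 == 0) stop("zero variance: Z-scores undefined")
  (scores - mu) / sqrt(s2)
}

#' Enrichment factor at a docking-score cutoff
#'
#' `EF(c) = (N_pos(c)/N_pos_total) / (N_neg(c)/N_neg_total)` where `N(c)`
#' counts scores <= c.  Cutoffs where the comparison pool has no score
#' at or below c give `NA` (undefined, never infinity).
#'
#' @param pos,neg docking-score pools (e.g. screening-enriched vs neutral
#'   target families).
#' @param cutoffs numeric cutoff(s), kcal/mol.
#' @return Numeric EF per cutoff (named by cutoff).
#' @export
enrichmentFactor <- function(pos, neg, cutoffs) {
  stopifnot(length(pos) > 0, length(neg) > 0)
  vapply(cutoffs, function(c_) {
    np <- sum(pos <= c_); nn <- sum(neg <= c_)
    if (nn == 0) return(NA_real_)
    (np / length(pos)) / (nn / length(neg))
  }, numeric(1)) |> stats::setNames(cutoffs)
}

#' Monte Carlo enrichment-factor curve
#'
#' Repeatedly subsamples the two score pools (without replacement within
#' each iteration), computes the EF at every cutoff, and summarizes the
#' mean and standard deviation across iterations.  By default
#' `sampleSize` compounds are drawn from each pool per iteration;
#' `mode = "combined"` draws `sampleSize` from the pooled scores instead
#' and splits them by their group of origin.
#'
#' @inheritParams enrichmentFactor
#' @param sampleSize compounds drawn per iteration.
#' @param iterations Monte Carlo iterations.
#' @param seed RNG seed.
#' @param mode `"per-group"` (default) or `"combined"`.
#' @return `data.frame`: cutoff, efMean, efSd, nDefined (iterations where
#'   the EF was defined), plus attributes `iterations` and `sampleSize`.
#' @export
monteCarloEF <- function(pos, neg, sampleSize = 200L, iterations = 1000L,
                         cutoffs = seq(-10, -8, by = 0.25), seed = 1L,
                         mode = c("per-group", "combined")) {
  mode <- match.arg(mode)
  if (mode == "per-group" &&
      (sampleSize > length(pos) || sampleSize > length(neg)))
    stop("sampleSize exceeds a pool size")
  if (mode == "combined" && sampleSize > length(pos) + length(neg))
    stop("sampleSize exceeds the combined pool size")
  efs <- withSeed(seed, {
    vapply(seq_len(iterations), function(i) {
      if (mode == "per-group") {
        sp <- sample(pos, sampleSize)
        sn <- sample(neg, sampleSize)
      } else {
        lab <- c(rep(TRUE, length(pos)), rep(FALSE, length(neg)))
        all_ <- c(pos, neg)
        take <- sample.int(length(all_), sampleSize)
        sp <- all_[take][lab[take]]
        sn <- all_[take][!lab[take]]
        if (!length(sp) || !length(sn)) return(rep(NA_real_, length(cutoffs)))
      }
      enrichmentFactor(sp, sn, cutoffs)
    }, numeric(length(cutoffs)))
  })
  efs <- matrix(efs, nrow = length(cutoffs))
  out <- data.frame(
    cutoff = cutoffs,
    efMean = apply(efs, 1L, mean, na.rm = TRUE),
    efSd = apply(efs, 1L, sd, na.rm = TRUE),
    nDefined = apply(efs, 1L, function(v) sum(!is.na(v))))
  attr(out, "iterations") <- iterations
  attr(out, "sampleSize") <- sampleSize
  attr(out, "mode") <- mode
  out
}

#' Extract the top-scoring fraction per target
#'
#' For each target, returns the `ceiling(fraction * n)` most negative
#' docking scores (never zero for a non-empty target); ties at the
#' boundary are broken by compound id, so the extraction is
#' deterministic.
#'
#' @param scores `data.frame` with columns `compound_id`, `target_id`,
#'   `score`.
#' @param fraction fraction in (0, 1\]; default 0.01 (top 1%).
#' @return Subset of `scores`, ordered by target then score.
#' @export
topFraction <- function(scores, fraction = 0.01) {
  stopifnot(fraction > 0, fraction <= 1,
            all(c("compound_id", "target_id", "score") %in% names(scores)))
  parts <- split(scores, scores$target_id)
  out <- lapply(parts, function(df) {
    if (!nrow(df)) return(NULL)
    k <- ceiling(fraction * nrow(df))
    df[order(df$score, df$compound_id), , drop = FALSE][seq_len(k), ,
                                                        drop = FALSE]
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

## Mann-Whitney U of x against y with midrank ties: number of (x, y)
## pairs with x < y counting ties as 1/2.
.uStatistic <- function(x, y) {
  r <- rank(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

#' One-sided Mann-Whitney U test
#'
#' Tests whether `x` is stochastically smaller than `y` (the alternative
#' used when comparing screening-enriched against neutral docking
#' scores).  U is computed from rank sums with midrank ties.  For
#' combined sample sizes below 20 the p-value is exact, by exhaustive
#' enumeration of all group assignments of the observed values (ties
#' handled naturally); otherwise the normal approximation with
#' tie-corrected variance and continuity correction is used.  The effect
#' size is z divided by the square root of the combined sample size
#' (signed; negative when x tends smaller).
#'
#' @param x,y numeric samples.
#' @param exactLimit use exact enumeration when `length(x) + length(y)`
#'   is at most this (default 20).
#' @return List: `U`, `p`, `z`, `effectR`, `method`.
#' @export
mannWhitneyOneSided <- function(x, y, exactLimit = 20L) {
  stopifnot(length(x) >= 1L, length(y) >= 1L)
  nx <- length(x); ny <- length(y); N <- nx + ny
  U <- .uStatistic(x, y)
  mu <- nx * ny / 2
  ties <- table(c(x, y))
  tieCorr <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- nx * ny / 12 * ((N + 1) - tieCorr)
  if (sigma2 <= 0) {
    ## all values identical: no evidence either way
    z <- 0
  } else {
    z <- (U - mu + 0.5) / sqrt(sigma2)   # continuity correction toward null
  }
  if (N <= exactLimit) {
    r <- rank(c(x, y))
    idx <- combn(N, nx)
    us <- colSums(matrix(r[idx], nrow = nx)) - nx * (nx + 1) / 2
    p <- mean(us <= U + 1e-9)
    method <- "exact enumeration"
    if (sigma2 > 0) z <- qnorm(pmin(pmax(p, 1e-300), 1 - 1e-16))
  } else {
    p <- pnorm(z)
    method <- "normal approximation"
  }
  list(U = U, p = p, z = z, effectR = z / sqrt(N), method = method)
}
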