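## Internal helpers shared across modules.

## Run `expr` under a temporary RNG state seeded with `seed`, restoring the
## caller's .Random.seed afterwards.  All user-facing seeded operations go
## through this so library calls never disturb the session RNG.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old))
        rm(".Random.seed", envir = globalenv())
      else
        assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

## Sub-seed derivation: keep well below 2^31.
subSeed <- function(seed, k) (as.integer(seed) * 101L + as.integer(k)) %% 1000000007L

erepocLog <- function(...) message("[erepoc] ", ...)

writeTsv <- function(df, path) {
  ## fixed numeric formatting keeps CLI outputs byte-reproducible
  df <- as.data.frame(df)
  for (j in seq_along(df))
    if (is.numeric(df[[j]]) && !is.integer(df[[j]]))
      df[[j]] <- sprintf("%.8g", df[[j]])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

readTsv <- function(path, ...) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             check.names = FALSE, comment.char = "", quote = "\"", ...)
}

## Matrix <-> TSV with ids in the first column.
writeMatrixTsv <- function(m, path, idCol = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c(idCol, colnames(m) %||% sprintf("v%04d", seq_len(ncol(m))))
  writeTsv(df, path)
}

readMatrixTsv <- function(path, idCol = 1L) {
  df <- readTsv(path)
  m <- as.matrix(df[, -idCol, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[idCol]])
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Squared Euclidean cross-distances between row-coordinate matrices.
crossDist2 <- function(a, b) {
  d2 <- outer(rowSums(a * a), rowSums(b * b), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

## Row-normalize to unit L2 norm; errors on zero rows.
rowUnit <- function(m, what = "vector") {
  n <- sqrt(rowSums(m * m))
  if (any(n == 0)) stop("zero-norm ", what, " cannot be normalized")
  m / n
}
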