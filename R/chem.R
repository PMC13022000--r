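## Ligand chemistry: Morgan fingerprints and fingerprint similarities.
## Fingerprints are computed by RDKit (the field-standard implementation)
## through the environment's Python; everything downstream operates on the
## returned 0/1 bit matrices in R.

.pythonBinary <- function() {
  py <- Sys.which("python")
  if (py == "") py <- Sys.which("python3")
  if (py == "")
    stop("no python interpreter found on PATH; Morgan fingerprints ",
         "require python with rdkit installed")
  py
}

#' Morgan (ECFP4) fingerprints from SMILES
#'
#' Computes fixed-width binary circular fingerprints (default radius 2,
#' 2048 bits) for a vector of SMILES.  SMILES are canonicalized before
#' hashing, so different writings of the same molecule yield identical bit
#' vectors; salts/fragments are kept as given.  The computation is
#' delegated to RDKit via the system Python.
#'
#' @param smiles character vector of SMILES.
#' @param ids ligand identifiers (defaults to `lig0001`, ...).
#' @param radius circular fingerprint radius.
#' @param nbits fingerprint width in bits.
#' @return A [FingerprintSet-class].
#' @examples
#' \donttest{
#' fps <- morganFingerprints(c("CCO", "CCCO"), ids = c("etoh", "proh"))
#' tanimoto(fps)["etoh", "proh"]
#' }
#' @export
morganFingerprints <- function(smiles, ids = NULL, radius = 2L,
                               nbits = 2048L) {
  stopifnot(length(smiles) > 0)
  if (is.null(ids)) ids <- sprintf("lig%04d", seq_along(smiles))
  stopifnot(length(ids) == length(smiles), !anyDuplicated(ids))
  script <- system.file("python", "morgan_fp.py", package = "erepoc",
                        mustWork = TRUE)
  fin <- tempfile(fileext = ".tsv")
  on.exit(unlink(fin))
  writeLines(paste(ids, smiles, sep = "\t"), fin)
  out <- suppressWarnings(system2(.pythonBinary(),
                                  c(shQuote(script), shQuote(fin),
                                    radius, nbits),
                                  stdout = TRUE, stderr = TRUE))
  fields <- strsplit(out, "\t", fixed = TRUE)
  bad <- vapply(fields, function(f) f[1] == "ERROR", logical(1))
  if (any(bad))
    stop("unparseable SMILES: ",
         paste(vapply(fields[bad], function(f)
           paste0(f[2], " ('", f[3], "')"), character(1)), collapse = ", "))
  bits <- matrix(0L, length(smiles), nbits,
                 dimnames = list(ids, NULL))
  canon <- character(length(smiles))
  for (f in fields) {
    i <- match(f[1], ids)
    canon[i] <- f[2]
    if (length(f) >= 3 && nzchar(f[3]))
      bits[i, as.integer(strsplit(f[3], ",", fixed = TRUE)[[1]])] <- 1L
  }
  if (any(rowSums(bits) == 0))
    warning("fingerprint with no set bits for: ",
            paste(ids[rowSums(bits) == 0], collapse = ", "))
  new("FingerprintSet", bits = bits, smiles = canon)
}

.asBitMatrix <- function(x) {
  if (is(x, "FingerprintSet")) return(fingerprintBits(x))
  x <- if (is.null(dim(x))) matrix(x, nrow = 1L) else as.matrix(x)
  storage.mode(x) <- "double"
  x
}

#' Tanimoto similarity of binary fingerprints
#'
#' `|a AND b| / |a OR b|`.  With one argument, returns the full pairwise
#' similarity matrix of a fingerprint set; with two bit vectors, a scalar.
#' Two all-zero vectors compare as 0 with a warning.
#'
#' @param a,b fingerprint bit vectors, 0/1 matrices (rows = ligands) or a
#'   [FingerprintSet-class].
#' @return Similarity scalar or matrix in \[0,1\].
#' @export
tanimoto <- function(a, b = NULL) {
  A <- .asBitMatrix(a)
  B <- if (is.null(b)) A else .asBitMatrix(b)
  stopifnot(ncol(A) == ncol(B))
  inter <- tcrossprod(A, B)
  union <- outer(rowSums(A), rowSums(B), "+") - inter
  zero <- union == 0
  if (any(zero)) {
    warning("all-zero fingerprint pair(s): similarity defined as 0")
    union[zero] <- 1
    inter[zero] <- 0
  }
  s <- inter / union
  if (nrow(A) == 1L && nrow(B) == 1L) s[1, 1] else s
}

#' Cosine similarity of binary fingerprints
#'
#' `a . b / (|a| |b|)`; for binary vectors the result lies in \[0,1\].
#' Zero vectors are an error (undefined direction).
#'
#' @inheritParams tanimoto
#' @return Similarity scalar or matrix in \[0,1\].
#' @export
fpCosine <- function(a, b = NULL) {
  A <- .asBitMatrix(a)
  B <- if (is.null(b)) A else .asBitMatrix(b)
  stopifnot(ncol(A) == ncol(B))
  na <- sqrt(rowSums(A * A)); nb <- sqrt(rowSums(B * B))
  if (any(na == 0) || any(nb == 0))
    stop("cosine similarity undefined for all-zero fingerprints")
  s <- tcrossprod(A, B) / outer(na, nb)
  if (nrow(A) == 1L && nrow(B) == 1L) s[1, 1] else s
}

#' Pairwise ligand similarity matrix
#'
#' @param fps a [FingerprintSet-class] (or 0/1 matrix).
#' @param metric `"cosine"` or `"tanimoto"`.
#' @return Symmetric similarity matrix with unit diagonal.
#' @export
similarityMatrix <- function(fps, metric = c("cosine", "tanimoto")) {
  metric <- match.arg(metric)
  s <- if (metric == "cosine") fpCosine(fps) else tanimoto(fps)
  diag(s) <- 1
  s
}

#' Fingerprints as compact hex strings
#'
#' @param fps a [FingerprintSet-class].
#' @return Character vector, one hex string (4 bits per character, MSB
#'   first) per ligand.
#' @export
fpToHex <- function(fps) {
  bits <- fingerprintBits(fps)
  hexChars <- strsplit("0123456789abcdef", "")[[1]]
  apply(bits, 1L, function(v) {
    nyb <- matrix(v, nrow = 4L)
    paste(hexChars[colSums(nyb * c(8L, 4L, 2L, 1L)) + 1L], collapse = "")
  })
}

#' @rdname fpToHex
#' @param hex character vector of hex strings.
#' @param ids ligand identifiers.
#' @return `hexToFp` returns a [FingerprintSet-class].
#' @export
hexToFp <- function(hex, ids = names(hex)) {
  bits <- t(vapply(hex, function(h) {
    v <- strtoi(strsplit(h, "")[[1]], 16L)
    as.integer(rbind(bitwAnd(v, 8L) > 0, bitwAnd(v, 4L) > 0,
                     bitwAnd(v, 2L) > 0, bitwAnd(v, 1L) > 0))
  }, integer(nchar(hex[1]) * 4L)))
  fingerprintSet(bits, ids = ids %||% sprintf("lig%04d", seq_along(hex)))
}

#' Read a ligand table and write fingerprints as TSV
#'
#' `readSmilesTsv` expects columns `ligand_id` and `smiles`;
#' `writeFingerprintsTsv` stores ids and hex-encoded bits,
#' `readFingerprintsTsv` restores the [FingerprintSet-class].
#'
#' @param path TSV file.
#' @return `readSmilesTsv`: data.frame; see Details for the others.
#' @export
readSmilesTsv <- function(path) {
  df <- readTsv(path)
  stopifnot(all(c("ligand_id", "smiles") %in% names(df)))
  df
}

#' @rdname readSmilesTsv
#' @param fps a [FingerprintSet-class].
#' @export
writeFingerprintsTsv <- function(fps, path) {
  writeTsv(data.frame(ligand_id = rownames(fingerprintBits(fps)),
                      nbits = ncol(fingerprintBits(fps)),
                      fp_hex = fpToHex(fps), stringsAsFactors = FALSE),
           path)
}

#' @rdname readSmilesTsv
#' @export
readFingerprintsTsv <- function(path) {
  df <- readTsv(path, colClasses = "character")
  hexToFp(df$fp_hex, ids = df$ligand_id)
}
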