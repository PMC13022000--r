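## Per-residue embeddings from a pluggable provider, mean pooling over
## pocket residues, and author-numbering -> sequence-position mapping.

.aaAlphabet <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                 "K", "M", "F", "P", "S", "T", "W", "Y", "V", "X")

## Deterministic per-amino-acid base vectors: the synthetic provider maps a
## residue to a fixed pseudo-random vector keyed by (letter, dim), so the
## same sequence always embeds to the same matrix, in any session.
.syntheticRow <- function(letter, dim) {
  withSeed(dim * 1009L + utf8ToInt(letter), rnorm(dim))
}

#' Synthetic per-residue embedding provider
#'
#' A deterministic stand-in for a protein language model, labelled
#' synthetic: each residue type maps to a fixed pseudo-random vector of
#' the requested dimension.  It satisfies the provider contract (one row
#' per residue, finite, reproducible) and lets the full pipeline run
#' offline; it carries no evolutionary information.
#'
#' @param dim embedding dimension (default 1280, matching the 650M
#'   language-model checkpoint's per-residue width).
#' @return A provider object for [embedSequence()].
#' @export
syntheticEmbeddingProvider <- function(dim = 1280L) {
  dim <- as.integer(dim)
  structure(list(
    tag = sprintf("synthetic-%d", dim),
    dim = dim,
    embed = function(sequence) {
      letters1 <- strsplit(sequence, "")[[1]]
      t(vapply(letters1, .syntheticRow, numeric(dim), dim = dim))
    }), class = "erepocProvider")
}

#' Embed a protein sequence
#'
#' Produces the per-residue embedding matrix (L x dim) for a sequence over
#' the 20-letter amino-acid alphabet (X tolerated).  The reference
#' provider is the 650M-parameter protein language model checkpoint
#' (1280-d per residue); it is not bundled, so requesting `"esm2"` without
#' network access raises an error advising the synthetic provider.
#'
#' @param sequence amino-acid sequence (single string).
#' @param provider `"synthetic"`, `"esm2"`, or a provider object from
#'   [syntheticEmbeddingProvider()].
#' @param dim embedding dimension for the synthetic provider.
#' @return Numeric matrix with one row per residue and attribute
#'   `providerTag`.
#' @export
embedSequence <- function(sequence, provider = "synthetic", dim = 1280L) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!nzchar(sequence)) stop("empty sequence cannot be embedded")
  letters1 <- strsplit(toupper(sequence), "")[[1]]
  if (!all(letters1 %in% .aaAlphabet))
    stop("sequence contains non-amino-acid letters: ",
         paste(unique(setdiff(letters1, .aaAlphabet)), collapse = ", "))
  if (is.character(provider)) {
    provider <- match.arg(provider, c("synthetic", "esm2"))
    if (provider == "esm2")
      stop("the pretrained language-model provider is not bundled; ",
           "use provider = 'synthetic' for offline work or supply ",
           "precomputed embedding matrices")
    provider <- syntheticEmbeddingProvider(dim)
  }
  stopifnot(inherits(provider, "erepocProvider"))
  m <- provider$embed(paste(letters1, collapse = ""))
  rownames(m) <- NULL
  stopifnot(nrow(m) == length(letters1), all(is.finite(m)))
  attr(m, "providerTag") <- provider$tag
  m
}

#' Mean-pool residue embeddings into a pocket feature
#'
#' The pocket feature vector is the arithmetic mean of the embedding rows
#' of the pocket residues.
#'
#' @param emb residue embedding matrix (L x dim) from [embedSequence()].
#' @param indices 1-based sequence positions of the pocket residues.
#' @return Numeric vector of length dim with attribute `nPooled`.
#' @export
poolPocket <- function(emb, indices) {
  if (!length(indices)) stop("empty pocket cannot be pooled")
  indices <- as.integer(indices)
  if (any(indices < 1L | indices > nrow(emb)))
    stop("pocket residue index out of range [1, ", nrow(emb), "]")
  v <- colMeans(emb[indices, , drop = FALSE])
  attr(v, "nPooled") <- length(indices)
  v
}

#' Chain sequence from parsed atoms
#'
#' Reconstructs the one-letter amino-acid sequence of a chain from the
#' polymer atom records, in author residue-number order.
#'
#' @param atoms atom table from [parseStructure()].
#' @param chain chain identifier.
#' @return Character string; attribute `keys` holds the author residue
#'   keys (chain.resno.insert) in sequence order.
#' @export
chainSequence <- function(atoms, chain) {
  a <- atoms[atoms$type == "ATOM" & atoms$chain == chain, , drop = FALSE]
  if (!nrow(a)) stop("no polymer residues in chain '", chain, "'")
  key <- paste(a$chain, a$resno, a$insert, sep = ".")
  first <- !duplicated(key)
  ord <- order(a$resno[first], a$insert[first])
  res3 <- a$resid[first][ord]
  aa <- .aa3[res3]
  aa[is.na(aa)] <- "X"
  s <- paste(aa, collapse = "")
  attr(s, "keys") <- key[first][ord]
  s
}

#' Map pocket residues to sequence positions
#'
#' Translates a pocket's author residue keys into 1-based positions of the
#' chain sequence used for embedding.  Residues whose 3-letter name
#' disagrees with the sequence raise an error; residues missing from the
#' mapped range (gaps, tags) are dropped with a warning, and pooling can
#' proceed over the mapped subset.
#'
#' @param atoms atom table from [parseStructure()].
#' @param pocket a [PocketDefinition-class].
#' @return Named integer vector of sequence positions, one per mapped
#'   pocket residue (possibly spanning several chains).
#' @export
residueIndices <- function(atoms, pocket) {
  res <- pocketResidues(pocket)
  out <- integer(0)
  for (ch in unique(res$chain)) {
    s <- chainSequence(atoms, ch)
    keys <- attr(s, "keys")
    r <- res[res$chain == ch, , drop = FALSE]
    want <- paste(r$chain, r$resno, r$insert, sep = ".")
    pos <- match(want, keys)
    if (anyNA(pos)) {
      warning("dropping ", sum(is.na(pos)),
              " pocket residue(s) not mappable to the chain ", ch,
              " sequence")
      r <- r[!is.na(pos), , drop = FALSE]
      want <- want[!is.na(pos)]
      pos <- pos[!is.na(pos)]
    }
    seqAA <- strsplit(s, "")[[1]][pos]
    pocketAA <- unname(.aa3[r$resid])
    bad <- !is.na(pocketAA) & seqAA != pocketAA
    if (any(bad))
      stop("residue name mismatch at ", paste(want[bad], collapse = ", "),
           ": pocket says ", paste(pocketAA[bad], collapse = ""),
           ", sequence says ", paste(seqAA[bad], collapse = ""))
    names(pos) <- want
    out <- c(out, pos)
  }
  if (!length(out))
    stop("no pocket residue could be mapped to a sequence position")
  out
}
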