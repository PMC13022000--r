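## Cosine-similarity search and screening over latent pocket vectors.

.latentMatrix <- function(x) {
  m <- if (is(x, "PocketExperiment")) t(latent(x)) else as.matrix(x)
  if (is.null(rownames(m)))
    rownames(m) <- sprintf("pocket%05d", seq_len(nrow(m)))
  m
}

#' k-nearest-neighbour search by cosine similarity
#'
#' Exhaustive (exact) scan: for every query the top-k reference pockets by
#' cosine similarity, ties broken by reference id in lexicographic order.
#' When the query set overlaps the reference set, exact pocket-id
#' self-matches are excluded.
#'
#' @param query,reference latent matrices (pockets x dim, rownames = ids)
#'   or [PocketExperiment-class] objects with a latent assay.
#' @param k number of neighbours.
#' @param excludeSelf drop hits whose reference id equals the query id.
#' @return `data.frame` with columns `query`, `ref`, `cosine`, `rank`
#'   (ranks contiguous from 1, cosine non-increasing within query).
#' @export
knnSearch <- function(query, reference, k = 5L, excludeSelf = TRUE) {
  Q <- .latentMatrix(query); R <- .latentMatrix(reference)
  if (k > nrow(R)) stop("k = ", k, " exceeds reference size ", nrow(R))
  S <- rowUnit(Q, "latent") %*% t(rowUnit(R, "latent"))
  hits <- lapply(seq_len(nrow(Q)), function(i) {
    s <- S[i, ]
    ids <- colnames(S) %||% rownames(R)
    if (excludeSelf) {
      keep <- ids != rownames(Q)[i]
      s <- s[keep]; ids <- ids[keep]
    }
    ord <- order(-s, ids)[seq_len(min(k, length(ids)))]
    data.frame(query = rownames(Q)[i], ref = ids[ord],
               cosine = unname(s[ord]), rank = seq_along(ord),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out
}

#' Strict threshold filter on similarities
#'
#' Retains entries with similarity strictly greater than `tau` (values
#' equal to the threshold are dropped).
#'
#' @param similarities named numeric vector, or a data.frame with a
#'   `cosine` column (e.g. [knnSearch()] output).
#' @param tau similarity threshold in (-1, 1); default 0.8.
#' @return Filtered object of the same shape.
#' @export
thresholdNeighbors <- function(similarities, tau = 0.8) {
  stopifnot(tau > -1, tau < 1)
  if (is.data.frame(similarities))
    return(similarities[similarities$cosine > tau, , drop = FALSE])
  similarities[similarities > tau]
}

#' Proteome screening filter
#'
#' Applies the pocket-quality and similarity filters used for proteome
#' screening: keep a pocket iff volume >= `minVolume` (default 800 A^3,
#' the boundary itself kept), mean pocket pLDDT >= `minPlddt`, and maximum
#' cosine to the reference panel strictly greater than `tau`.  pLDDT is
#' accepted on either the 0--1 or 0--100 scale and normalized internally.
#' Accessions are deduplicated keeping the maximal-cosine pocket.
#'
#' @param records `data.frame` with columns `accession`, `pocketId`,
#'   `volume` (A^3), `plddt`, `maxCosine`.
#' @param minVolume minimal pocket volume, A^3.
#' @param minPlddt minimal mean per-residue confidence (0--1 scale).
#' @param tau strict cosine threshold.
#' @return List with `pockets` (passing records) and `accessions`
#'   (deduplicated per-accession best pockets).
#' @export
screenPockets <- function(records, minVolume = 800, minPlddt = 0.7,
                          tau = 0.8) {
  need <- c("accession", "pocketId", "volume", "plddt", "maxCosine")
  stopifnot(all(need %in% names(records)))
  bad <- !is.finite(records$volume) | !is.finite(records$plddt)
  if (any(bad)) {
    erepocLog("screenPockets: skipped ", sum(bad),
              " record(s) with missing volume/plddt")
    records <- records[!bad, , drop = FALSE]
  }
  plddt <- records$plddt
  if (length(plddt) && max(plddt) > 1) plddt <- plddt / 100
  pass <- records$volume >= minVolume & plddt >= minPlddt &
    records$maxCosine > tau
  pockets <- records[pass, , drop = FALSE]
  ord <- order(-pockets$maxCosine, pockets$pocketId)
  dedup <- pockets[ord, , drop = FALSE]
  dedup <- dedup[!duplicated(dedup$accession), , drop = FALSE]
  dedup <- dedup[order(dedup$accession), , drop = FALSE]
  rownames(pockets) <- rownames(dedup) <- NULL
  list(pockets = pockets, accessions = dedup)
}

#' Correlation between ligand and latent pocket similarity
#'
#' Samples `nSample` pockets with the seeded generator, computes all
#' pairwise ligand fingerprint similarities and latent cosine
#' similarities, and returns their Pearson correlation.  This is the
#' desk-scale analogue of validating a trained model against the chemical
#' similarity of the bound ligands.
#'
#' @param latents latent matrix (pockets x dim) or
#'   [PocketExperiment-class] with latent assay.
#' @param fingerprints paired [FingerprintSet-class] (pocket order).
#' @param nSample number of pockets to sample (default: all).
#' @param seed sampling seed.
#' @param metric ligand similarity, `"tanimoto"` (default) or `"cosine"`.
#' @return Pearson r over all sampled pairs.
#' @export
ligandPocketCorrelation <- function(latents, fingerprints, nSample = NULL,
                                    seed = 1L,
                                    metric = c("tanimoto", "cosine")) {
  metric <- match.arg(metric)
  L <- .latentMatrix(latents)
  bits <- fingerprintBits(fingerprints)
  stopifnot(nrow(bits) == nrow(L))
  n <- nrow(L)
  nSample <- min(nSample %||% n, n)
  idx <- withSeed(seed, sample.int(n, nSample))
  lig <- if (metric == "tanimoto") tanimoto(bits[idx, , drop = FALSE])
         else fpCosine(bits[idx, , drop = FALSE])
  poc <- cosineMatrix(L[idx, , drop = FALSE])
  up <- upper.tri(lig)
  x <- lig[up]; y <- poc[up]
  if (sd(x) == 0 || sd(y) == 0)
    stop("correlation undefined: constant similarity values")
  cor(x, y)
}
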