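## Hypergeometric over-representation analysis of protein classes among
## screening hits.

.checkCounts <- function(NiM, NiTotal, NM, NTotal) {
  if (NiTotal > NTotal) stop("N_i_total exceeds N_total")
  if (NM > NTotal) stop("N_M exceeds N_total")
  if (NiM > min(NiTotal, NM))
    stop("N_i_M exceeds min(N_i_total, N_M)")
  if (NiM < 0 || NiTotal < 0 || NM < 0 || NTotal <= 0)
    stop("counts must be non-negative (N_total positive)")
}

#' Class enrichment score
#'
#' `ES = (N_i_M / N_i_total) / (N_M / N_total)`: the proportion of class-i
#' proteins among the hits relative to their proportion in the background.
#' ES > 1 means over-representation.
#'
#' @param NiM hits in class i.
#' @param NiTotal background members of class i (> 0).
#' @param NM total hits (> 0).
#' @param NTotal background size.
#' @return Numeric enrichment score >= 0.
#' @export
enrichmentScore <- function(NiM, NiTotal, NM, NTotal) {
  .checkCounts(NiM, NiTotal, NM, NTotal)
  if (NiTotal == 0) stop("zero denominator: N_i_total")
  if (NM == 0) stop("zero denominator: N_M")
  (NiM / NiTotal) / (NM / NTotal)
}

#' One-sided hypergeometric over-representation p-value
#'
#' Upper-tail probability `P(X >= N_i_M)` for
#' `X ~ Hypergeometric(N_total, N_i_total, N_M)`: the chance of drawing at
#' least the observed number of class-i proteins in a random hit set of
#' the same size.  `pointMass = TRUE` returns the point probability
#' `P(X = N_i_M)` instead (a debug mode, not a test).
#'
#' @inheritParams enrichmentScore
#' @param pointMass return the point probability instead of the tail.
#' @return p-value in \[0,1\].
#' @export
hypergeomP <- function(NiM, NiTotal, NM, NTotal, pointMass = FALSE) {
  .checkCounts(NiM, NiTotal, NM, NTotal)
  if (pointMass)
    return(dhyper(NiM, NiTotal, NTotal - NiTotal, NM))
  phyper(NiM - 1L, NiTotal, NTotal - NiTotal, NM, lower.tail = FALSE)
}

#' Class enrichment of screening hits
#'
#' One result per class present in the background annotations, sorted by
#' enrichment score descending.  Proteins annotated with several classes
#' (multifunctional enzymes) count in each class; the background size
#' `N_total` counts proteins once.  p-values are reported raw (no
#' multiple-testing adjustment by default, matching the reference
#' analysis); `adjust = "BH"` optionally adds an adjusted column.
#'
#' @param hits character vector of hit accessions (must all appear in the
#'   background annotations).
#' @param annotations `data.frame` with columns `accession`, `class`, one
#'   row per membership.
#' @param alpha significance flag threshold on the raw p-value.
#' @param adjust `"none"` (default) or `"BH"`.
#' @param pointMass see [hypergeomP()].
#' @return `data.frame`: class, N_i_M, N_i_total, ES, p, significant
#'   (and p_adj when requested).
#' @export
enrichClasses <- function(hits, annotations, alpha = 0.05,
                          adjust = c("none", "BH"), pointMass = FALSE) {
  adjust <- match.arg(adjust)
  stopifnot(all(c("accession", "class") %in% names(annotations)))
  hits <- unique(as.character(hits))
  background <- unique(annotations$accession)
  missing <- setdiff(hits, background)
  if (length(missing))
    stop("hit accession(s) missing from the background annotations: ",
         paste(missing, collapse = ", "))
  NTotal <- length(background)
  NM <- length(hits)
  classes <- sort(unique(annotations$class))
  rows <- lapply(classes, function(cl) {
    members <- unique(annotations$accession[annotations$class == cl])
    NiTotal <- length(members)
    NiM <- length(intersect(members, hits))
    data.frame(class = cl, N_i_M = NiM, N_i_total = NiTotal,
               ES = enrichmentScore(NiM, NiTotal, NM, NTotal),
               p = hypergeomP(NiM, NiTotal, NM, NTotal,
                              pointMass = pointMass),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$ES, out$class), , drop = FALSE]
  if (adjust == "BH") out$p_adj <- p.adjust(out$p, method = "BH")
  out$significant <- out$p < alpha
  rownames(out) <- NULL
  out
}
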