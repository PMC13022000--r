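## Independent oracles and fixture helpers.  Everything here deliberately
## avoids the package's vectorized code paths: plain double loops and
## direct combinatorial sums, so oracle and implementation can only agree
## if both are right.

## Build an atom table in the parseStructure() layout from raw pieces.
mkAtoms <- function(xyz, element, resno, resid = "ALA", chain = "A",
                    type = "ATOM", insert = "") {
  xyz <- matrix(xyz, ncol = 3)
  n <- nrow(xyz)
  data.frame(
    type = rep_len(type, n), eleno = seq_len(n),
    elety = rep_len(element, n), element = rep_len(element, n),
    resid = rep_len(resid, n), chain = rep_len(chain, n),
    resno = rep_len(resno, n), insert = rep_len(insert, n),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occupancy = 1, isHydrogen = rep_len(element, n) %in% c("H", "D"),
    isLigand = rep_len(type, n) == "HETATM" &
      !(rep_len(resid, n) %in% c("HOH", "WAT", "DOD", "H2O")),
    stringsAsFactors = FALSE)
}

## Brute-force distance-rule pocket membership: plain loops over every
## residue atom / ligand atom pair.
bruteForceDistancePocket <- function(atoms, cutoff) {
  lig <- atoms[atoms$isLigand & !atoms$isHydrogen, , drop = FALSE]
  prot <- atoms[atoms$type == "ATOM" & !atoms$isHydrogen, , drop = FALSE]
  keys <- unique(paste(prot$chain, prot$resno, prot$insert))
  member <- character(0)
  for (k in keys) {
    ra <- prot[paste(prot$chain, prot$resno, prot$insert) == k, ,
               drop = FALSE]
    hit <- FALSE
    for (i in seq_len(nrow(ra))) {
      for (j in seq_len(nrow(lig))) {
        d <- sqrt((ra$x[i] - lig$x[j])^2 + (ra$y[i] - lig$y[j])^2 +
                    (ra$z[i] - lig$z[j])^2)
        if (d <= cutoff) { hit <- TRUE; break }
      }
      if (hit) break
    }
    if (hit) member <- c(member, k)
  }
  sort(member)
}

## Brute-force vdW contact-rule membership.
bruteForceVdwPocket <- function(atoms, pad, minContacts) {
  lig <- atoms[atoms$isLigand & !atoms$isHydrogen, , drop = FALSE]
  prot <- atoms[atoms$type == "ATOM" & !atoms$isHydrogen, , drop = FALSE]
  keys <- unique(paste(prot$chain, prot$resno, prot$insert))
  member <- character(0)
  for (k in keys) {
    ra <- prot[paste(prot$chain, prot$resno, prot$insert) == k, ,
               drop = FALSE]
    contacts <- 0L
    for (i in seq_len(nrow(ra))) {
      for (j in seq_len(nrow(lig))) {
        d <- sqrt((ra$x[i] - lig$x[j])^2 + (ra$y[i] - lig$y[j])^2 +
                    (ra$z[i] - lig$z[j])^2)
        lim <- vdwRadius(ra$element[i]) + vdwRadius(lig$element[j]) + pad
        if (d <= lim) contacts <- contacts + 1L
      }
    }
    if (contacts >= minContacts) member <- c(member, k)
  }
  sort(member)
}

pocketKeys <- function(pocket) {
  r <- pocketResidues(pocket)
  sort(paste(r$chain, r$resno, r$insert))
}

## Clash fractions by explicit pair enumeration.
bruteForceClash <- function(xyzA, xyzB = NULL, threshold = 1.2) {
  if (is.null(xyzB)) {
    n <- nrow(xyzA); clash <- 0L; pairs <- 0L
    for (i in seq_len(n)) for (j in seq_len(n)) if (i < j) {
      pairs <- pairs + 1L
      if (sqrt(sum((xyzA[i, ] - xyzA[j, ])^2)) < threshold)
        clash <- clash + 1L
    }
    return(if (pairs == 0) 0 else clash / pairs)
  }
  cnt <- 0L
  for (i in seq_len(nrow(xyzA))) for (j in seq_len(nrow(xyzB)))
    if (sqrt(sum((xyzA[i, ] - xyzB[j, ])^2)) < threshold) cnt <- cnt + 1L
  cnt
}

## Upper-tail hypergeometric probability by direct binomial-coefficient
## summation (no phyper/dhyper).
chooseSumHyper <- function(k, K, M, N) {
  js <- seq(k, min(K, M))
  sum(choose(K, js) * choose(N - K, M - js)) / choose(N, M)
}

## Literal subset enumeration for small backgrounds: every M-subset of
## 1..N counted.
enumerateHyper <- function(k, K, M, N) {
  subsets <- combn(N, M)
  inClass <- subsets <= K          # classes 1..K are "class i" members
  mean(colSums(inClass) >= k)
}

## Random rigid motion applied to the xyz columns of an atom table.
rigidTransform <- function(atoms, seed = 1) {
  set.seed(seed)
  th <- runif(3, 0, 2 * pi)
  Rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])),
              c(0, sin(th[1]), cos(th[1])))
  Rz <- rbind(c(cos(th[2]), -sin(th[2]), 0),
              c(sin(th[2]), cos(th[2]), 0), c(0, 0, 1))
  R <- Rz %*% Rx
  shift <- runif(3, -20, 20)
  xyz <- t(R %*% t(as.matrix(atoms[, c("x", "y", "z")]))) +
    matrix(shift, nrow(atoms), 3, byrow = TRUE)
  atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
  atoms
}

## Shared small fixture dataset for model-level tests (fast mode).
smallDataset <- function(n = 320, classes = 4, dim = 48, seed = 11) {
  makeEmbeddingDataset(nPockets = n, nClasses = classes, dim = dim,
                       seed = seed)
}

quickConfig <- function(seed = 11L, epochs = 8L) {
  trainingConfig(trainBatches = 6L, valBatches = 3L, batchSize = 64L,
                 patience = 3L, maxEpochs = epochs, seed = seed)
}
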