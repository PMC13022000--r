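## Synthetic fixtures: toy structures with known pocket membership and
## clash geometry, embedding datasets with planted ligand-class structure,
## and two-group docking-score pools.  Every generator is a pure function
## of its arguments and seed.

.pdbAtomLine <- function(record, serial, name, resName, chain, resSeq,
                         xyz, element) {
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name, "", resName, chain, resSeq, "",
          xyz[1], xyz[2], xyz[3], 1.00, 0.00, element)
}

## Unit vector from spherical angles.
.dirVec <- function(theta, phi)
  c(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))

#' Generate a toy protein--ligand structure
#'
#' Emits minimal PDB text with one ligand (`LIG`) near the origin and
#' `nResidues` three-atom glycine residues placed at controlled distances
#' from the ligand, plus ground-truth pocket membership computed directly
#' from the generating coordinates by an all-pairs distance scan.
#' Optionally plants a ligand atom pair at exactly 1.0 Angstrom (a steric
#' clash at the 1.2 Angstrom threshold).
#'
#' @param nResidues number of residues (>= 2).
#' @param nLigandAtoms ligand heavy-atom count.
#' @param residueDistances distances (Angstrom) from the ligand centroid
#'   at which residues are placed; recycled.  Default spreads 3--12 A.
#' @param clashPairs number of ligand atom pairs planted at 1.0 A.
#' @param cutoff cutoff used for the reported ground-truth membership.
#' @param seed RNG seed.
#' @return List: `path` (temp PDB file), `text` (PDB lines), `atoms`
#'   (generating coordinates with residue labels), `membership`
#'   (logical per residue at `cutoff`), `ligandClashFraction` planted.
#' @export
makeStructure <- function(nResidues = 10L, nLigandAtoms = 5L,
                          residueDistances = NULL, clashPairs = 0L,
                          cutoff = 5.0, seed = 1L) {
  stopifnot(nResidues >= 2L, nLigandAtoms >= 1L)
  withSeed(seed, {
    if (is.null(residueDistances))
      residueDistances <- seq(3, 12, length.out = nResidues)
    residueDistances <- rep_len(residueDistances, nResidues)
    ## ligand atoms in a compact cluster around the origin
    lig <- matrix(runif(nLigandAtoms * 3, -0.8, 0.8), ncol = 3)
    if (clashPairs > 0) {
      for (k in seq_len(clashPairs)) {
        i <- 2 * k - 1
        if (2 * k > nLigandAtoms) break
        lig[2 * k, ] <- lig[i, ] + c(1, 0, 0)   # exactly 1.0 A apart
      }
    }
    centroid <- colMeans(lig)
    resAtoms <- vector("list", nResidues)
    for (r in seq_len(nResidues)) {
      ok <- FALSE
      for (try_ in 1:50) {
        u <- .dirVec(runif(1, 0, 2 * pi), acos(runif(1, -1, 1)))
        ca <- centroid + residueDistances[r] * u
        ## N and C flank CA at backbone-like bond lengths, perpendicular
        ## to the ligand direction so the placed distance is respected
        v <- c(-u[2], u[1], 0)
        if (sum(v * v) < 1e-8) v <- c(1, 0, 0)
        v <- v / sqrt(sum(v * v))
        w <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
               u[1] * v[2] - u[2] * v[1])
        n_ <- ca + 1.46 * v
        c_ <- ca - 1.52 * (0.5 * v - 0.866 * w)
        cand <- rbind(N = n_, CA = ca, C = c_)
        prev <- do.call(rbind, resAtoms[seq_len(r - 1L)])
        if (is.null(prev) ||
            min(crossDist2(cand, prev[, 1:3, drop = FALSE])) > 2.2^2) {
          ok <- TRUE; break
        }
      }
      if (!ok) stop("could not place residue ", r,
                    " without overlap; vary the seed")
      resAtoms[[r]] <- cand
    }
    ## ground truth by direct distance scan of the generating coordinates
    membership <- vapply(resAtoms, function(m)
      min(crossDist2(m, lig)) <= cutoff^2, logical(1))
    lines <- character(0)
    serial <- 0L
    atomRows <- list()
    for (r in seq_len(nResidues)) {
      for (a in rownames(resAtoms[[r]])) {
        serial <- serial + 1L
        el <- substr(a, 1, 1)
        lines <- c(lines, .pdbAtomLine("ATOM", serial, a, "GLY", "A", r,
                                       resAtoms[[r]][a, ], el))
        atomRows[[length(atomRows) + 1L]] <- data.frame(
          resno = r, name = a, x = resAtoms[[r]][a, 1],
          y = resAtoms[[r]][a, 2], z = resAtoms[[r]][a, 3],
          isLigand = FALSE, stringsAsFactors = FALSE)
      }
    }
    for (i in seq_len(nLigandAtoms)) {
      serial <- serial + 1L
      lines <- c(lines, .pdbAtomLine("HETATM", serial, sprintf("C%d", i),
                                     "LIG", "A", nResidues + 1L,
                                     lig[i, ], "C"))
      atomRows[[length(atomRows) + 1L]] <- data.frame(
        resno = nResidues + 1L, name = sprintf("C%d", i),
        x = lig[i, 1], y = lig[i, 2], z = lig[i, 3], isLigand = TRUE,
        stringsAsFactors = FALSE)
    }
    lines <- c(lines, "END")
    path <- tempfile(fileext = ".pdb")
    writeLines(lines, path)
    nPairs <- nLigandAtoms * (nLigandAtoms - 1) / 2
    planted <- if (nPairs > 0)
      sum(crossDist2(lig, lig) < 1.2^2 & upper.tri(diag(nLigandAtoms))) / nPairs
    else 0
    list(path = path, text = lines,
         atoms = do.call(rbind, atomRows),
         membership = membership, cutoff = cutoff,
         ligandClashFraction = planted)
  })
}

#' Generate a planted-cluster embedding dataset
#'
#' The desk-scale analogue of a pocket--ligand training set: `nClasses`
#' ligand classes, each with a Gaussian embedding cloud (center scale
#' `classCenterScale` per coordinate, residual noise `noiseSigma`) and a
#' fingerprint template of `bitsPerClass` class-specific bits plus
#' `sharedBits` bits common to all classes, perturbed by independent
#' per-sample bit flips at rate `flipRate`.  Within-class fingerprint
#' similarity exceeds between-class similarity by construction; the
#' realized Tanimoto gap is reported in the metadata.
#'
#' With seven classes the labels are named after the seven benchmark
#' ligand types (ADP, COA, FAD, HEM, NAD, NADP, SAM).
#'
#' @param nPockets total pockets (split evenly over classes).
#' @param nClasses number of ligand classes (>= 2).
#' @param dim embedding dimension (1280 exercises the full model shape; a
#'   small value such as 64 gives a fast mode with proportionally scaled
#'   network widths).
#' @param classCenterScale per-coordinate sd of the class centers.
#' @param noiseSigma per-coordinate sd of the residual noise.
#' @param bitsPerClass,sharedBits fingerprint template structure.
#' @param flipRate independent bit-flip probability per fingerprint bit.
#' @param nbits fingerprint width.
#' @param seed RNG seed.
#' @return List: `pockets` (a [PocketExperiment-class] with `ligandClass`
#'   labels), `fingerprints` (a [FingerprintSet-class]), `metadata`
#'   (realized within/between similarity gap and the generator settings).
#' @export
makeEmbeddingDataset <- function(nPockets = 1400L, nClasses = 7L,
                                 dim = 1280L, classCenterScale = 1.0,
                                 noiseSigma = 1.5, bitsPerClass = 48L,
                                 sharedBits = 16L, flipRate = 0.005,
                                 nbits = 2048L, seed = 7L) {
  stopifnot(nClasses >= 2L, noiseSigma >= 0, dim > 0, nPockets >= nClasses)
  if (nClasses * bitsPerClass + sharedBits > nbits)
    stop("fingerprint templates exceed the fingerprint width")
  classNames <- if (nClasses == 7L)
    c("ADP", "COA", "FAD", "HEM", "NAD", "NADP", "SAM")
  else sprintf("class%02d", seq_len(nClasses))
  withSeed(seed, {
    perClass <- rep(nPockets %/% nClasses, nClasses)
    extra <- nPockets - sum(perClass)
    if (extra > 0) perClass[seq_len(extra)] <- perClass[seq_len(extra)] + 1L
    labels <- rep(classNames, perClass)
    centers <- matrix(rnorm(nClasses * dim, sd = classCenterScale),
                      nClasses, dim)
    X <- centers[match(labels, classNames), , drop = FALSE] +
      matrix(rnorm(nPockets * dim, sd = noiseSigma), nPockets, dim)
    ## fingerprint templates: shared block + disjoint class blocks
    pool <- sample.int(nbits, nClasses * bitsPerClass + sharedBits)
    shared <- pool[seq_len(sharedBits)]
    classBits <- split(pool[-seq_len(sharedBits)],
                       rep(seq_len(nClasses), each = bitsPerClass))
    bits <- matrix(0L, nPockets, nbits)
    for (i in seq_len(nPockets)) {
      k <- match(labels[i], classNames)
      bits[i, c(shared, classBits[[k]])] <- 1L
    }
    if (flipRate > 0) {
      flips <- matrix(rbinom(nPockets * nbits, 1L, flipRate),
                      nPockets, nbits)
      bits <- abs(bits - flips)
    }
    empty <- rowSums(bits) == 0
    bits[empty, shared[1]] <- 1L   # guarantee a non-empty fingerprint
    ids <- sprintf("pocket%05d", seq_len(nPockets))
    rownames(bits) <- ids
    pe <- pocketExperiment(t(X), pocketIds = ids, ligandClass = labels)
    fps <- new("FingerprintSet", bits = bits,
               smiles = character(nPockets))
    ## realized similarity gap on a deterministic subsample (kept small so
    ## generation stays cheap at full fixture size)
    sub <- seq(1L, nPockets, length.out = min(nPockets, 280L))
    tn <- tanimoto(bits[sub, , drop = FALSE])
    same <- outer(labels[sub], labels[sub], "==")
    up <- upper.tri(tn)
    gap <- mean(tn[up & same]) - mean(tn[up & !same])
    list(pockets = pe, fingerprints = fps,
         metadata = list(similarityGap = gap, perClass = perClass,
                         classNames = classNames, dim = dim,
                         classCenterScale = classCenterScale,
                         noiseSigma = noiseSigma,
                         bitsPerClass = bitsPerClass,
                         sharedBits = sharedBits, flipRate = flipRate,
                         seed = seed))
  })
}

#' Generate two-group docking-score pools
#'
#' Emulates an enriched-vs-neutral docking comparison: neutral scores are
#' Normal(mu0, sigma), enriched scores are Normal(mu0 - shift, sigma)
#' (more negative = stronger predicted binding).
#'
#' @param nPerGroup compounds per group (>= 10).
#' @param shift location shift of the enriched group, kcal/mol.
#' @param sigma score standard deviation (> 0).
#' @param mu0 neutral-group mean, kcal/mol.
#' @param seed RNG seed.
#' @return `data.frame`: `compound_id`, `target_id`, `score`, `group`.
#' @export
makeDockingScores <- function(nPerGroup = 5000L, shift = 1.5, sigma = 1.0,
                              mu0 = -6.0, seed = 1L) {
  stopifnot(nPerGroup >= 10L)
  if (sigma <= 0) stop("sigma must be positive")
  withSeed(seed, {
    data.frame(
      compound_id = sprintf("cmpd%06d", seq_len(2L * nPerGroup)),
      target_id = rep(c("T_enriched", "T_neutral"), each = nPerGroup),
      score = c(rnorm(nPerGroup, mu0 - shift, sigma),
                rnorm(nPerGroup, mu0, sigma)),
      group = rep(c("enriched", "neutral"), each = nPerGroup),
      stringsAsFactors = FALSE)
  })
}
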