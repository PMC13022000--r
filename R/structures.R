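## Structure parsing, ligand-defined pocket extraction, steric-clash QC and
## amino-acid enrichment.

.waterNames <- c("HOH", "WAT", "DOD", "H2O")

## Elements treated as free metal ions; never ligands for pocket extraction.
.metalElements <- c("LI", "NA", "K", "RB", "CS", "MG", "CA", "SR", "BA",
                    "MN", "FE", "CO", "NI", "CU", "ZN", "CD", "HG", "AL",
                    "GA", "PB", "PT", "PD", "AG", "AU", "MO", "W", "V", "CR")

## Bondi-style van der Waals radii (Angstrom); metals fall back to 2.0.
.vdwTable <- c(H = 1.20, D = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
               P = 1.80, S = 1.80, CL = 1.75, BR = 1.85, I = 1.98,
               SE = 1.90, B = 1.92, SI = 2.10, AS = 1.85, TE = 2.06)

#' Van der Waals radius lookup
#'
#' Bondi-style radii for the elements common in protein--ligand complexes;
#' metal ions fall back to 2.0 Angstrom.  Unknown elements raise an error
#' naming the element.
#'
#' @param element character vector of element symbols.
#' @return Numeric vector of radii in Angstrom.
#' @export
vdwRadius <- function(element) {
  el <- toupper(trimws(element))
  r <- .vdwTable[el]
  r[is.na(r) & el %in% .metalElements] <- 2.0
  if (anyNA(r))
    stop("no van der Waals radius for element(s): ",
         paste(unique(el[is.na(r)]), collapse = ", "))
  unname(r)
}

## Derive element symbol from a PDB atom name when the element column is
## blank (e.g. minimal fixture files).
.elementFromName <- function(elety) {
  nm <- gsub("[0-9']", "", toupper(trimws(elety)))
  two <- substr(nm, 1, 2)
  ifelse(two %in% names(.vdwTable) | two %in% .metalElements,
         two, substr(nm, 1, 1))
}

#' Parse a protein--ligand complex structure
#'
#' Reads a PDB or mmCIF file into a flat atom table.  HETATM groups are
#' flagged as ligand atoms unless they are waters; hydrogens (and deuterium)
#' are flagged; for atoms with alternate locations only the
#' highest-occupancy conformer is kept.
#'
#' @param path path to a structure file (or literal PDB text lines via a
#'   connection written to a temporary file by the caller).
#' @param format `"auto"` (by extension), `"pdb"` or `"mmcif"`.
#' @return A `data.frame` of atom records with columns `type`, `eleno`,
#'   `elety`, `element`, `resid`, `chain`, `resno`, `insert`,
#'   `x`, `y`, `z`, `isLigand`, `isHydrogen`.
#' @examples
#' pdb <- makeStructure(nResidues = 4, seed = 1)
#' atoms <- parseStructure(pdb$path)
#' table(atoms$isLigand)
#' @export
parseStructure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  parsed <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, verbose = FALSE)
    else bio3d::read.cif(path, verbose = FALSE),
    error = function(e)
      stop("failed to parse structure file '", path, "' as ", format, ": ",
           conditionMessage(e)))
  a <- parsed$atom
  if (!any(a$type == "ATOM"))
    stop("no polymer chain found in '", path, "'")
  element <- toupper(trimws(a$elesy %||% ""))
  blank <- is.na(element) | element == ""
  element[blank] <- .elementFromName(a$elety[blank])
  insert <- a$insert
  insert[is.na(insert)] <- ""
  atoms <- data.frame(
    type = a$type, eleno = a$eleno, elety = trimws(a$elety),
    element = element, resid = trimws(a$resid), chain = a$chain,
    resno = a$resno, insert = insert,
    x = a$x, y = a$y, z = a$z,
    occupancy = ifelse(is.na(a$o), 1, a$o),
    stringsAsFactors = FALSE)
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates in '", path, "'")
  ## altloc: keep highest-occupancy conformer per (residue key, atom name)
  alt <- trimws(a$alt %||% "")
  alt[is.na(alt)] <- ""
  if (any(alt != "")) {
    key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety)
    ord <- order(-atoms$occupancy)
    keep <- logical(nrow(atoms))
    keep[ord[!duplicated(key[ord])]] <- TRUE
    atoms <- atoms[keep, , drop = FALSE]
  }
  atoms$isHydrogen <- atoms$element %in% c("H", "D")
  atoms$isLigand <- atoms$type == "HETATM" & !(atoms$resid %in% .waterNames)
  rownames(atoms) <- NULL
  atoms
}

#' Enumerate candidate ligands in a parsed structure
#'
#' HET groups excluding waters and free metal ions (single-atom metal
#' groups), following the exclusion of metals, peptides and nucleic acids
#' from the regular-ligand definition.
#'
#' @param atoms atom table from [parseStructure()].
#' @return `data.frame` with columns `resid`, `chain`, `resno`, `nAtoms`.
#' @export
ligandCandidates <- function(atoms) {
  het <- atoms[atoms$isLigand, , drop = FALSE]
  if (!nrow(het))
    return(data.frame(resid = character(), chain = character(),
                      resno = integer(), nAtoms = integer()))
  key <- paste(het$resid, het$chain, het$resno, sep = ":")
  groups <- split(het, key)
  out <- do.call(rbind, lapply(groups, function(g)
    data.frame(resid = g$resid[1], chain = g$chain[1], resno = g$resno[1],
               nAtoms = nrow(g), stringsAsFactors = FALSE)))
  isMetalIon <- out$nAtoms == 1L & vapply(groups, function(g)
    g$element[1] %in% .metalElements, logical(1))
  out <- out[!isMetalIon, , drop = FALSE]
  rownames(out) <- NULL
  out[order(out$chain, out$resno, out$resid), , drop = FALSE]
}

## Resolve a ligand id "HET" or "HET:chain:resno" to an atom mask.
.ligandMask <- function(atoms, ligandId) {
  parts <- strsplit(ligandId, ":", fixed = TRUE)[[1]]
  mask <- atoms$isLigand & atoms$resid == parts[1]
  if (length(parts) >= 2L && nzchar(parts[2]))
    mask <- mask & atoms$chain == parts[2]
  if (length(parts) >= 3L && nzchar(parts[3]))
    mask <- mask & atoms$resno == as.integer(parts[3])
  if (!any(mask))
    stop("no ligand '", ligandId, "' found in structure (candidates: ",
         paste(unique(atoms$resid[atoms$isLigand]), collapse = ", ") %||% "none",
         ")")
  mask
}

.resolvedLigandId <- function(atoms, mask) {
  c(atoms$resid[mask][1], atoms$chain[mask][1],
    as.character(atoms$resno[mask][1]))
}

## Protein heavy atoms eligible for pocket membership: polymer (ATOM)
## records, non-hydrogen.
.pocketCandidates <- function(atoms) {
  atoms[atoms$type == "ATOM" & !atoms$isHydrogen, , drop = FALSE]
}

.orderedResidues <- function(prot, include) {
  key <- paste(prot$chain, prot$resno, prot$insert, sep = "\r")
  sel <- unique(key[include])
  first <- !duplicated(key)
  res <- data.frame(chain = prot$chain[first], resno = prot$resno[first],
                    insert = prot$insert[first], resid = prot$resid[first],
                    stringsAsFactors = FALSE)
  res <- res[paste(res$chain, res$resno, res$insert, sep = "\r") %in% sel, ,
             drop = FALSE]
  res <- res[order(res$chain, res$resno, res$insert), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Extract a pocket by the fixed distance rule
#'
#' A residue belongs to the pocket iff any of its heavy atoms lies within
#' `cutoff` (closed boundary, d <= cutoff) of any heavy atom of the bound
#' ligand.  The default 5 Angstrom cutoff is the standard ligand-proximity
#' definition.  Hydrogens are ignored on both sides, so the rule is
#' independent of structure protonation.
#'
#' @param atoms atom table from [parseStructure()].
#' @param ligandId ligand selector, `"HET"` or `"HET:chain:resno"`.
#' @param cutoff distance cutoff in Angstrom (> 0).
#' @param structureId identifier stored on the result.
#' @return A [PocketDefinition-class]; empty (with a warning) when no
#'   residue is in range.
#' @export
extractPocketDistance <- function(atoms, ligandId, cutoff = 5.0,
                                  structureId = "structure") {
  stopifnot(cutoff > 0)
  mask <- .ligandMask(atoms, ligandId)
  lig <- atoms[mask & !atoms$isHydrogen, , drop = FALSE]
  prot <- .pocketCandidates(atoms)
  d2 <- crossDist2(as.matrix(prot[, c("x", "y", "z")]),
                   as.matrix(lig[, c("x", "y", "z")]))
  nearAtom <- apply(d2 <= cutoff^2, 1L, any)
  res <- .orderedResidues(prot, nearAtom)
  if (!nrow(res))
    warning("empty pocket: no residue within ", cutoff, " A of ", ligandId)
  new("PocketDefinition", structureId = structureId,
      ligandId = .resolvedLigandId(atoms, mask), residues = res,
      rule = "distance_5A", params = list(cutoff = cutoff))
}

#' Extract a pocket by the van-der-Waals contact rule
#'
#' BioLiP2-style binding-residue rule: an atom pair is a contact when its
#' distance is at most the sum of the two van der Waals radii plus `pad`
#' (closed boundary); a residue belongs to the pocket iff it has at least
#' `minContacts` such heavy-atom contacts with the ligand.
#'
#' @inheritParams extractPocketDistance
#' @param pad padding added to the summed radii, Angstrom.
#' @param minContacts minimum number of contacting atom pairs.
#' @return A [PocketDefinition-class].
#' @export
extractPocketVdw <- function(atoms, ligandId, pad = 0.5, minContacts = 2L,
                             structureId = "structure") {
  stopifnot(pad >= 0, minContacts >= 1L)
  mask <- .ligandMask(atoms, ligandId)
  lig <- atoms[mask & !atoms$isHydrogen, , drop = FALSE]
  prot <- .pocketCandidates(atoms)
  d2 <- crossDist2(as.matrix(prot[, c("x", "y", "z")]),
                   as.matrix(lig[, c("x", "y", "z")]))
  lim <- outer(vdwRadius(prot$element), vdwRadius(lig$element), "+") + pad
  contact <- d2 <= lim^2
  key <- paste(prot$chain, prot$resno, prot$insert, sep = "\r")
  perRes <- rowsum(rowSums(contact), key, reorder = FALSE)
  keep <- key %in% rownames(perRes)[perRes[, 1] >= minContacts]
  res <- .orderedResidues(prot, keep)
  if (!nrow(res))
    warning("empty pocket: no residue with >= ", minContacts,
            " vdW contacts to ", ligandId)
  new("PocketDefinition", structureId = structureId,
      ligandId = .resolvedLigandId(atoms, mask), residues = res,
      rule = "vdw_pad", params = list(pad = pad, min_contacts = minContacts))
}

## Number of heavy-atom pairs below the threshold plus the pair count.
.clashPairs <- function(xyz, threshold) {
  n <- nrow(xyz)
  if (n < 2L) return(c(clash = 0L, pairs = 0L))
  d2 <- crossDist2(xyz, xyz)
  clash <- (sum(d2 < threshold^2) - n) / 2   # off-diagonal, counted once
  c(clash = clash, pairs = n * (n - 1L) / 2)
}

#' Steric-clash report for a pocket--ligand pair
#'
#' Counts heavy-atom pairs closer than `threshold`: the clash fraction of
#' the pocket (ligand) is the clashing fraction of all intra-pocket
#' (intra-ligand) pairs, and `crossClashCount` is the number of
#' pocket--ligand pairs below the threshold.  Hydrogens are removed before
#' counting; single-atom groups have fraction 0.
#'
#' @param pocketAtoms,ligandAtoms atom tables (rows of
#'   [parseStructure()] output) for the pocket residues and the ligand.
#' @param threshold clash distance in Angstrom.
#' @return A [ClashReport-class].
#' @export
clashReport <- function(pocketAtoms, ligandAtoms, threshold = 1.2) {
  stopifnot(nrow(pocketAtoms) > 0, nrow(ligandAtoms) > 0)
  p <- as.matrix(pocketAtoms[!pocketAtoms$isHydrogen, c("x", "y", "z")])
  l <- as.matrix(ligandAtoms[!ligandAtoms$isHydrogen, c("x", "y", "z")])
  pp <- .clashPairs(p, threshold)
  ll <- .clashPairs(l, threshold)
  cross <- if (nrow(p) && nrow(l))
    sum(crossDist2(p, l) < threshold^2) else 0L
  new("ClashReport",
      pocketClashFraction =
        unname(if (pp["pairs"] > 0) pp["clash"] / pp["pairs"] else 0),
      ligandClashFraction =
        unname(if (ll["pairs"] > 0) ll["clash"] / ll["pairs"] else 0),
      crossClashCount = as.integer(cross), threshold = threshold)
}

#' Clash-based structure quality filter
#'
#' A complex is kept iff the pocket clash fraction is below 0.005, the
#' ligand clash fraction is below 0.01 and the number of pocket--ligand
#' clashes is below 5; each boundary value itself is discarded.
#'
#' @param report a [ClashReport-class].
#' @param maxPocketFraction,maxLigandFraction,maxCrossCount discard
#'   boundaries (a report at or above any boundary is discarded).
#' @return `TRUE` to keep, `FALSE` to discard.
#' @export
passesClashFilter <- function(report, maxPocketFraction = 0.005,
                              maxLigandFraction = 0.01, maxCrossCount = 5L) {
  stopifnot(is(report, "ClashReport"))
  report@pocketClashFraction < maxPocketFraction &&
    report@ligandClashFraction < maxLigandFraction &&
    report@crossClashCount < maxCrossCount
}

.aa3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
          GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
          LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
          SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

#' Background amino-acid frequencies
#'
#' A typical PDB-wide amino-acid composition (proportions summing to 1),
#' used as the default normalization reference for pocket composition
#' enrichment.  Supply your own reference to [aaEnrichment()] to use a
#' different background.
#'
#' @return Named numeric vector over the 20 one-letter codes.
#' @export
pdbAaFrequencies <- function() {
  f <- c(A = 8.0, R = 5.0, N = 4.3, D = 5.5, C = 1.3, Q = 3.8, E = 6.6,
         G = 7.4, H = 2.6, I = 5.6, L = 9.0, K = 5.9, M = 2.2, F = 4.0,
         P = 4.6, S = 6.3, T = 5.6, W = 1.4, Y = 3.5, V = 6.9)
  f / sum(f)
}

#' Amino-acid enrichment of pocket composition
#'
#' Pools the residues of all supplied pockets, computes per-amino-acid
#' frequencies, and divides by a reference composition, giving a ratio > 1
#' for residues over-represented in pockets.  Non-standard residue names
#' are excluded (their count is reported via a message and an attribute).
#'
#' @param pockets list of [PocketDefinition-class] objects.
#' @param referenceFreq named positive frequencies summing to about 1.
#' @return Named numeric vector of ratios over the 20 amino acids, with
#'   attribute `nExcluded`.
#' @export
aaEnrichment <- function(pockets, referenceFreq = pdbAaFrequencies()) {
  stopifnot(all(referenceFreq > 0),
            abs(sum(referenceFreq) - 1) < 0.01)
  if (is(pockets, "PocketDefinition")) pockets <- list(pockets)
  res3 <- unlist(lapply(pockets, function(p) pocketResidues(p)$resid))
  aa <- .aa3[res3]
  nExcluded <- sum(is.na(aa))
  if (nExcluded > 0)
    erepocLog("aaEnrichment: excluded ", nExcluded,
              " non-standard residue(s)")
  aa <- aa[!is.na(aa)]
  if (!length(aa)) stop("no standard residues in the supplied pockets")
  counts <- table(factor(aa, levels = names(pdbAaFrequencies())))
  ratio <- as.numeric(counts) / length(aa) /
    as.numeric(referenceFreq[names(pdbAaFrequencies())])
  names(ratio) <- names(pdbAaFrequencies())
  attr(ratio, "nExcluded") <- nExcluded
  ratio
}

#' Write pockets to TSV
#'
#' One row per pocket: structure id, HET code, ligand chain and residue
#' number, comma-joined residue list (`chain.resno.insert.resid`),
#' extraction rule and residue count.
#'
#' @param pockets list of [PocketDefinition-class] objects.
#' @param path output file.
#' @return The path, invisibly.
#' @export
writePocketsTsv <- function(pockets, path) {
  if (is(pockets, "PocketDefinition")) pockets <- list(pockets)
  rows <- lapply(pockets, function(p) {
    r <- pocketResidues(p)
    data.frame(
      structure_id = p@structureId, het = p@ligandId[1],
      ligand_chain = p@ligandId[2], ligand_resno = p@ligandId[3],
      residues = paste(sprintf("%s.%s.%s.%s", r$chain, r$resno,
                               r$insert, r$resid), collapse = ","),
      rule = p@rule, n_residues = nrow(r), stringsAsFactors = FALSE)
  })
  writeTsv(do.call(rbind, rows), path)
}

#' Read annotated binding residues as pockets
#'
#' Accepts externally annotated binding-residue lists (e.g. database
#' exports) as an alternative pocket source.  Expected columns:
#' `structure_id`, `het`, `ligand_chain`, `ligand_resno`, `residues`
#' (comma-joined `chain.resno.insert.resid` tokens; insert may be empty).
#'
#' @param path TSV file.
#' @return List of [PocketDefinition-class] objects with rule
#'   `"vdw_pad"` (the convention of curated binding-residue databases).
#' @export
readBindingResiduesTsv <- function(path) {
  df <- readTsv(path)
  lapply(seq_len(nrow(df)), function(i) {
    toks <- strsplit(df$residues[i], ",", fixed = TRUE)[[1]]
    parts <- do.call(rbind, strsplit(toks, ".", fixed = TRUE))
    res <- data.frame(chain = parts[, 1], resno = as.integer(parts[, 2]),
                      insert = parts[, 3], resid = parts[, 4],
                      stringsAsFactors = FALSE)
    res <- res[order(res$chain, res$resno, res$insert), , drop = FALSE]
    new("PocketDefinition", structureId = as.character(df$structure_id[i]),
        ligandId = c(df$het[i], as.character(df$ligand_chain[i]),
                     as.character(df$ligand_resno[i])),
        residues = res, rule = "vdw_pad",
        params = list(pad = 0.5, min_contacts = 2L))
  })
}
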