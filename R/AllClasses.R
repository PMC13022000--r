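#' @include AllGenerics.R
NULL

## ---------------------------------------------------------------------------
## PocketDefinition
## ---------------------------------------------------------------------------

#' Ligand-defined binding pocket
#'
#' A pocket is the set of protein residues selected around one bound ligand
#' under a named extraction rule: either every residue with a heavy atom
#' within a fixed distance of a heavy ligand atom (`"distance_5A"`), or every
#' residue with at least `min_contacts` atom pairs inside the summed
#' van der Waals radii plus a pad (`"vdw_pad"`, the BioLiP2-style rule).
#' Residue identity follows PDB author convention: chain, author residue
#' number and insertion code.
#'
#' @slot structureId character, identifier of the parent structure.
#' @slot ligandId character of length 3: HET code, chain, residue number.
#' @slot residues `data.frame` with columns `chain`, `resno`, `insert`,
#'   `resid` (3-letter residue name), ordered by residue key.
#' @slot rule character, `"distance_5A"` or `"vdw_pad"`.
#' @slot params named list of positive rule parameters (`cutoff`, or
#'   `pad` + `min_contacts`).
#'
#' @seealso [extractPocketDistance()], [extractPocketVdw()]
#' @export
setClass("PocketDefinition",
  representation(
    structureId = "character",
    ligandId    = "character",
    residues    = "data.frame",
    rule        = "character",
    params      = "list"
  )
)

setValidity("PocketDefinition", function(object) {
  msg <- character()
  if (length(object@ligandId) != 3L)
    msg <- c(msg, "ligandId must be (HET code, chain, residue number)")
  if (!object@rule %in% c("distance_5A", "vdw_pad"))
    msg <- c(msg, "rule must be 'distance_5A' or 'vdw_pad'")
  p <- object@params
  if (!is.null(p$cutoff) && p$cutoff <= 0)
    msg <- c(msg, "cutoff must be positive")
  if (!is.null(p$pad) && p$pad < 0)
    msg <- c(msg, "pad must be non-negative")
  if (!is.null(p$min_contacts) && p$min_contacts <= 0)
    msg <- c(msg, "min_contacts must be positive")
  r <- object@residues
  need <- c("chain", "resno", "insert", "resid")
  if (!all(need %in% names(r))) {
    msg <- c(msg, "residues must have columns chain, resno, insert, resid")
  } else if (nrow(r)) {
    key <- paste(r$chain, r$resno, r$insert)
    if (anyDuplicated(key))
      msg <- c(msg, "residue keys must be unique")
    if (any(r$resid %in% .waterNames))
      msg <- c(msg, "pocket residues must not contain waters")
    lk <- paste(object@ligandId[2], object@ligandId[3], "")
    if (any(key == lk & r$resid == object@ligandId[1]))
      msg <- c(msg, "pocket residues must not contain the ligand itself")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn PocketDefinition residue table accessor
#' @param x a `PocketDefinition`.
#' @export
setMethod("pocketResidues", "PocketDefinition", function(x) x@residues)

#' @describeIn PocketDefinition number of residues
#' @export
setMethod("nResidues", "PocketDefinition",
          function(x) nrow(x@residues))

setMethod("show", "PocketDefinition", function(object) {
  cat("PocketDefinition:", object@structureId, "/",
      paste(object@ligandId, collapse = ":"), "\n")
  cat("  rule:", object@rule, "(",
      paste(names(object@params), unlist(object@params),
            sep = "=", collapse = ", "), ")\n")
  cat("  residues:", nrow(object@residues), "\n")
})

## ---------------------------------------------------------------------------
## ClashReport
## ---------------------------------------------------------------------------

#' Steric-clash quality report for a pocket--ligand pair
#'
#' Clashes are heavy-atom pairs closer than `threshold` (default 1.2 A).
#' The two fractions are computed over all intra-pocket and intra-ligand
#' heavy-atom pairs respectively; `crossClashCount` counts pocket-ligand
#' pairs below the threshold.  Groups with fewer than two atoms have
#' fraction 0 by convention (no pairs).
#'
#' @slot pocketClashFraction numeric in \[0,1\].
#' @slot ligandClashFraction numeric in \[0,1\].
#' @slot crossClashCount non-negative integer.
#' @slot threshold clash distance threshold in Angstrom.
#'
#' @seealso [clashReport()], [passesClashFilter()]
#' @export
setClass("ClashReport",
  representation(
    pocketClashFraction = "numeric",
    ligandClashFraction = "numeric",
    crossClashCount     = "integer",
    threshold           = "numeric"
  )
)

setValidity("ClashReport", function(object) {
  msg <- character()
  f <- c(object@pocketClashFraction, object@ligandClashFraction)
  if (any(!is.finite(f)) || any(f < 0) || any(f > 1))
    msg <- c(msg, "clash fractions must lie in [0,1]")
  if (object@crossClashCount < 0L)
    msg <- c(msg, "crossClashCount must be >= 0")
  if (object@threshold <= 0)
    msg <- c(msg, "threshold must be positive")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ClashReport", function(object) {
  cat(sprintf(
    "ClashReport (< %.2f A): pocket %.4g, ligand %.4g, cross %d\n",
    object@threshold, object@pocketClashFraction,
    object@ligandClashFraction, object@crossClashCount))
})

## ---------------------------------------------------------------------------
## FingerprintSet
## ---------------------------------------------------------------------------

#' Set of binary ligand fingerprints
#'
#' Fixed-width binary substructure fingerprints, by default 2048-bit
#' radius-2 circular (Morgan/ECFP4) fingerprints.  Rows are ligands.
#'
#' @slot bits integer 0/1 matrix, ligands x bits; rownames are ligand ids.
#' @slot smiles character, canonical SMILES per ligand ("" when the set was
#'   generated synthetically rather than computed from molecules).
#'
#' @seealso [morganFingerprints()], [tanimoto()], [fpCosine()]
#' @export
setClass("FingerprintSet",
  representation(bits = "matrix", smiles = "character")
)

setValidity("FingerprintSet", function(object) {
  msg <- character()
  b <- object@bits
  if (!is.numeric(b) && !is.integer(b))
    msg <- c(msg, "bits must be a numeric 0/1 matrix")
  else if (length(b) && !all(b %in% c(0L, 1L)))
    msg <- c(msg, "bits must contain only 0 and 1")
  if (is.null(rownames(b)))
    msg <- c(msg, "bits must carry ligand ids as rownames")
  else if (anyDuplicated(rownames(b)))
    msg <- c(msg, "ligand ids must be unique")
  if (length(object@smiles) != nrow(b))
    msg <- c(msg, "one smiles entry per ligand required")
  if (length(msg)) msg else TRUE
})

#' @describeIn FingerprintSet bit matrix accessor
#' @param x a `FingerprintSet`.
#' @export
setMethod("fingerprintBits", "FingerprintSet", function(x) x@bits)

setMethod("show", "FingerprintSet", function(object) {
  cat("FingerprintSet:", nrow(object@bits), "ligands x",
      ncol(object@bits), "bits;",
      "mean on-bits", round(mean(rowSums(object@bits)), 1), "\n")
})

#' Construct a FingerprintSet from a bit matrix
#'
#' @param bits 0/1 matrix, ligands x bits.
#' @param ids ligand identifiers (defaults to existing rownames).
#' @param smiles optional canonical SMILES per ligand.
#' @return A [FingerprintSet-class].
#' @export
fingerprintSet <- function(bits, ids = rownames(bits),
                           smiles = character(nrow(bits))) {
  bits <- as.matrix(bits)
  storage.mode(bits) <- "integer"
  if (is.null(ids))
    ids <- sprintf("lig%04d", seq_len(nrow(bits)))
  rownames(bits) <- ids
  new("FingerprintSet", bits = bits, smiles = as.character(smiles))
}

## ---------------------------------------------------------------------------
## PocketExperiment
## ---------------------------------------------------------------------------

#' Pocket embeddings as a SummarizedExperiment
#'
#' Container for a set of pockets with their mean-pooled language-model
#' embeddings (assay `"pooled"`, features x pockets) and, after encoding
#' through a trained projection model, their latent representations
#' (assay `"latent"`).  `colData` carries per-pocket metadata such as the
#' ligand class label and the number of pooled residues.
#'
#' @seealso [pocketExperiment()], [makeEmbeddingDataset()], [encodePockets()]
#' @export
setClass("PocketExperiment", contains = "SummarizedExperiment")

setValidity("PocketExperiment", function(object) {
  msg <- character()
  if (!"pooled" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'pooled' is required")
  else if (!all(is.finite(SummarizedExperiment::assay(object, "pooled"))))
    msg <- c(msg, "pooled embeddings must be finite")
  if (is.null(colnames(object)))
    msg <- c(msg, "pockets must carry ids as colnames")
  if (length(msg)) msg else TRUE
})

#' Construct a PocketExperiment
#'
#' @param pooled numeric matrix of pooled embeddings, features x pockets.
#' @param pocketIds pocket identifiers (defaults to colnames of `pooled`).
#' @param ligandClass optional per-pocket ligand class labels.
#' @param nPooled optional per-pocket residue counts used in pooling.
#' @param latent optional latent matrix (latent dim x pockets).
#' @return A [PocketExperiment-class].
#' @export
pocketExperiment <- function(pooled, pocketIds = colnames(pooled),
                             ligandClass = NULL, nPooled = NULL,
                             latent = NULL) {
  pooled <- as.matrix(pooled)
  if (is.null(pocketIds))
    pocketIds <- sprintf("pocket%05d", seq_len(ncol(pooled)))
  colnames(pooled) <- pocketIds
  cd <- S4Vectors::DataFrame(row.names = pocketIds)
  if (!is.null(ligandClass)) cd$ligandClass <- ligandClass
  if (!is.null(nPooled)) cd$nPooled <- as.integer(nPooled)
  assays <- list(pooled = pooled)
  if (!is.null(latent)) {
    latent <- as.matrix(latent)
    colnames(latent) <- pocketIds
    assays$latent <- latent
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays[1], colData = cd)
  pe <- new("PocketExperiment", se)
  if (!is.null(latent)) pe <- setLatent(pe, latent)
  pe
}

#' @describeIn PocketExperiment pooled embedding accessor
#' @param x a `PocketExperiment`.
#' @export
setMethod("pooled", "PocketExperiment", function(x)
  SummarizedExperiment::assay(x, "pooled"))

#' @describeIn PocketExperiment latent representation accessor
#' @export
setMethod("latent", "PocketExperiment", function(x) {
  L <- S4Vectors::metadata(x)$latent
  if (is.null(L))
    stop("no latent representation yet; run encodePockets() first")
  L
})

#' @describeIn PocketExperiment ligand class labels
#' @export
setMethod("ligandClass", "PocketExperiment", function(x) {
  cd <- SummarizedExperiment::colData(x)
  if (!"ligandClass" %in% names(cd))
    stop("no ligandClass column in colData")
  as.character(cd$ligandClass)
})

## latent dim generally differs from pooled dim, so it cannot live in
## assays() (which enforces equal nrow); stored in metadata instead.
setLatent <- function(pe, latentMatrix) {
  stopifnot(ncol(latentMatrix) == ncol(pe))
  S4Vectors::metadata(pe)$latent <- latentMatrix
  pe
}

setMethod("show", "PocketExperiment", function(object) {
  callNextMethod()
  if (!is.null(S4Vectors::metadata(object)$latent))
    cat("latent dim:", nrow(latent(object)), "\n")
})

## ---------------------------------------------------------------------------
## ProjectionModel
## ---------------------------------------------------------------------------

#' Contrastive pocket projection network
#'
#' A two-layer perceptron mapping pooled pocket embeddings (1280-d by
#' default) through a hidden layer (512) to the latent space (256).  Each
#' layer applies an affine map, batch normalization, dropout (rate 0.1
#' during training) and GELU activation.  In `eval` mode dropout is off and
#' the stored running normalization statistics are used, so inference is
#' deterministic and batch-order invariant.
#'
#' @slot layers list of per-layer parameter lists (`W`, `b`, `gamma`,
#'   `beta`, `runMean`, `runVar`).
#' @slot inputDim,hiddenDim,latentDim layer widths.
#' @slot dropout dropout rate used in training mode.
#' @slot providerTag tag of the embedding provider the model was trained on.
#' @slot trained logical; TRUE after [trainProjection()].
#' @slot schemaVersion checkpoint schema identifier.
#'
#' @seealso [projectionModel()], [projectPockets()], [trainProjection()]
#' @export
setClass("ProjectionModel",
  representation(
    layers        = "list",
    inputDim      = "integer",
    hiddenDim     = "integer",
    latentDim     = "integer",
    dropout       = "numeric",
    providerTag   = "character",
    trained       = "logical",
    schemaVersion = "character"
  )
)

setValidity("ProjectionModel", function(object) {
  msg <- character()
  if (length(object@layers) != 2L)
    msg <- c(msg, "exactly two layers expected")
  ok <- vapply(object@layers, function(l)
    all(c("W", "b", "gamma", "beta", "runMean", "runVar") %in% names(l)) &&
      all(vapply(l, function(p) all(is.finite(p)), logical(1))),
    logical(1))
  if (!all(ok))
    msg <- c(msg, "layer parameters must be complete and finite")
  if (object@dropout < 0 || object@dropout >= 1)
    msg <- c(msg, "dropout must be in [0,1)")
  if (length(object@layers) == 2L &&
      !is.null(dim(object@layers[[2]]$W)) &&
      ncol(object@layers[[2]]$W) != object@latentDim)
    msg <- c(msg, "output dimension must equal latentDim")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ProjectionModel", function(object) {
  cat(sprintf("ProjectionModel: %d -> %d -> %d (dropout %.2g, %s)\n",
              object@inputDim, object@hiddenDim, object@latentDim,
              object@dropout,
              if (object@trained) "trained" else "untrained"))
})

## ---------------------------------------------------------------------------
## TrainingConfig
## ---------------------------------------------------------------------------

#' Training configuration for the contrastive model
#'
#' Defaults follow the reference recipe: Adam with learning rate 0.001,
#' early stopping with patience 100 epochs, at most 2000 epochs, 4096
#' training batches of 128 per epoch and 256 fixed validation batches.
#' `temperature` and `epsilon` control the softmax similarity
#' distributions fed to the KL loss.
#'
#' @slot learningRate Adam learning rate.
#' @slot patience epochs without validation improvement before stopping.
#' @slot maxEpochs maximum number of epochs.
#' @slot trainBatches training batches per epoch (with replacement).
#' @slot valBatches fixed validation batches drawn once at startup.
#' @slot batchSize samples per batch.
#' @slot temperature softmax temperature for the similarity distributions.
#' @slot epsilon probability floor applied before the log.
#' @slot valFraction fraction of pockets held out for validation.
#' @slot similarity ligand similarity used for the target distribution,
#'   `"cosine"` (default) or `"tanimoto"`.
#' @slot bnMomentum running-statistics momentum of batch normalization.
#' @slot seed integer seed controlling every random choice in training.
#'
#' @seealso [trainingConfig()], [trainProjection()]
#' @export
setClass("TrainingConfig",
  representation(
    learningRate = "numeric",
    patience     = "integer",
    maxEpochs    = "integer",
    trainBatches = "integer",
    valBatches   = "integer",
    batchSize    = "integer",
    temperature  = "numeric",
    epsilon      = "numeric",
    valFraction  = "numeric",
    similarity   = "character",
    bnMomentum   = "numeric",
    seed         = "integer"
  )
)

setValidity("TrainingConfig", function(object) {
  msg <- character()
  counts <- c(object@patience, object@maxEpochs, object@trainBatches,
              object@valBatches, object@batchSize)
  if (any(counts <= 0L)) msg <- c(msg, "all counts must be positive")
  if (object@patience >= object@maxEpochs)
    msg <- c(msg, "patience must be smaller than maxEpochs")
  if (object@temperature <= 0) msg <- c(msg, "temperature must be positive")
  if (object@epsilon <= 0 || object@epsilon >= 1 / object@batchSize)
    msg <- c(msg, "epsilon must be a small positive floor")
  if (!object@similarity %in% c("cosine", "tanimoto"))
    msg <- c(msg, "similarity must be 'cosine' or 'tanimoto'")
  if (object@valFraction <= 0 || object@valFraction >= 1)
    msg <- c(msg, "valFraction must be in (0,1)")
  if (length(msg)) msg else TRUE
})

#' Create a training configuration
#'
#' @param learningRate,patience,maxEpochs,trainBatches,valBatches,batchSize
#'   optimizer and schedule settings; defaults are the reference recipe.
#' @param temperature,epsilon similarity-distribution settings.
#' @param valFraction held-out pocket fraction for validation.
#' @param similarity ligand similarity for the target distribution.
#' @param bnMomentum batch-normalization running-statistics momentum.
#' @param seed integer seed.
#' @return A [TrainingConfig-class].
#' @export
trainingConfig <- function(learningRate = 0.001, patience = 100L,
                           maxEpochs = 2000L, trainBatches = 4096L,
                           valBatches = 256L, batchSize = 128L,
                           temperature = 1.0, epsilon = 1e-8,
                           valFraction = 0.1, similarity = "cosine",
                           bnMomentum = 0.1, seed = 1L) {
  new("TrainingConfig",
      learningRate = learningRate, patience = as.integer(patience),
      maxEpochs = as.integer(maxEpochs),
      trainBatches = as.integer(trainBatches),
      valBatches = as.integer(valBatches),
      batchSize = as.integer(batchSize),
      temperature = temperature, epsilon = epsilon,
      valFraction = valFraction, similarity = similarity,
      bnMomentum = bnMomentum, seed = as.integer(seed))
}

setMethod("show", "TrainingConfig", function(object) {
  cat(sprintf(
    "TrainingConfig: lr %.4g, %d x %d batches/epoch (val %d), patience %d/%d, T %.3g, seed %d\n",
    object@learningRate, object@trainBatches, object@batchSize,
    object@valBatches, object@patience, object@maxEpochs,
    object@temperature, object@seed))
})
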