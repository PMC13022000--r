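#' @import methods
#' @importFrom stats cor dnorm pnorm qnorm phyper dhyper rnorm runif rbinom
#'   sd predict quantile setNames p.adjust
#' @importFrom utils read.table write.table combn head packageVersion
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData
#' @importFrom S4Vectors DataFrame metadata
NULL

#' Residue table of a pocket definition
#'
#' @param x a [PocketDefinition-class] object.
#' @return A `data.frame` with columns `chain`, `resno`, `insert`, `resid`,
#'   one row per pocket residue, ordered by residue key.
#' @export
setGeneric("pocketResidues", function(x) standardGeneric("pocketResidues"))

#' Number of residues in a pocket
#'
#' @param x a [PocketDefinition-class] object.
#' @return Integer residue count.
#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))

#' Fingerprint bit matrix
#'
#' @param x a [FingerprintSet-class] object.
#' @return Integer 0/1 matrix, one row per ligand, one column per bit.
#' @export
setGeneric("fingerprintBits", function(x) standardGeneric("fingerprintBits"))

#' Pooled pocket embedding matrix
#'
#' @param x a [PocketExperiment-class] object.
#' @return Numeric matrix, embedding dimension x pockets.
#' @export
setGeneric("pooled", function(x) standardGeneric("pooled"))

#' Latent pocket representation matrix
#'
#' @param x a [PocketExperiment-class] object.
#' @return Numeric matrix, latent dimension x pockets, or an error if the
#'   object has not been encoded yet.
#' @export
setGeneric("latent", function(x) standardGeneric("latent"))

#' Ligand class labels of a pocket set
#'
#' @param x a [PocketExperiment-class] object.
#' @return Character vector of per-pocket ligand class labels.
#' @export
setGeneric("ligandClass", function(x) standardGeneric("ligandClass"))
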