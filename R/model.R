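## The contrastive projection network: initialization, forward projection,
## similarity distributions, the KL distillation loss with its analytic
## gradient, the training loop with early stopping, and encoding.

#' Initialize a projection model
#'
#' Builds the two-layer network (affine -> batch norm -> dropout -> GELU
#' per layer).  At the default input width 1280 the hidden and latent
#' widths are 512 and 256; for other input widths they scale
#' proportionally (hidden = 0.4 d, latent = 0.2 d) unless given.
#'
#' @param inputDim width of the pooled pocket embeddings.
#' @param hiddenDim,latentDim layer widths (defaults scale with input).
#' @param dropout dropout rate in training mode.
#' @param seed seed for the weight initialization.
#' @param providerTag tag of the embedding provider the model expects.
#' @return An untrained [ProjectionModel-class].
#' @export
projectionModel <- function(inputDim = 1280L, hiddenDim = NULL,
                            latentDim = NULL, dropout = 0.1, seed = 1L,
                            providerTag = "unspecified") {
  inputDim <- as.integer(inputDim)
  hiddenDim <- as.integer(hiddenDim %||% max(4L, round(0.4 * inputDim)))
  latentDim <- as.integer(latentDim %||% max(2L, round(0.2 * inputDim)))
  dims <- c(inputDim, hiddenDim, latentDim)
  layers <- withSeed(seed, lapply(1:2, function(l) {
    fanIn <- dims[l]; fanOut <- dims[l + 1L]
    list(W = matrix(rnorm(fanIn * fanOut, sd = sqrt(2 / fanIn)),
                    fanIn, fanOut),
         b = numeric(fanOut), gamma = rep(1, fanOut),
         beta = numeric(fanOut), runMean = numeric(fanOut),
         runVar = rep(1, fanOut))
  }))
  new("ProjectionModel", layers = layers, inputDim = inputDim,
      hiddenDim = hiddenDim, latentDim = latentDim, dropout = dropout,
      providerTag = providerTag, trained = FALSE, schemaVersion = "erepoc-ckpt-1")
}

#' Project pocket embeddings into the latent space
#'
#' Runs the network forward.  In `eval` mode (inference) dropout is off
#' and running normalization statistics are used, so the output is
#' deterministic and batch-order invariant; `train` mode uses batch
#' statistics and is only meaningful inside the training loop.
#'
#' @param model a [ProjectionModel-class].
#' @param x pooled embeddings: a vector, a pockets-in-rows matrix, or a
#'   [PocketExperiment-class].
#' @param mode `"eval"` or `"train"`.
#' @return Latent matrix (pockets x latentDim).
#' @export
projectPockets <- function(model, x, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  if (is(x, "PocketExperiment")) x <- t(pooled(x))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != model@inputDim)
    stop("input dimension ", ncol(x), " does not match the model's ",
         "expected ", model@inputDim)
  out <- mlpForward(model@layers, x, training = (mode == "train"),
                    dropout = if (mode == "train") model@dropout else 0)
  rownames(out$y) <- rownames(x)
  out$y
}

#' Cosine similarity
#'
#' `latentCosine` compares two non-zero vectors; `cosineMatrix` returns
#' all pairwise cosines of a rows-are-vectors matrix.
#'
#' @param u,v numeric vectors.
#' @return Scalar in \[-1,1\].
#' @export
latentCosine <- function(u, v) {
  nu <- sqrt(sum(u * u)); nv <- sqrt(sum(v * v))
  if (nu == 0 || nv == 0) stop("cosine undefined for zero-norm vectors")
  sum(u * v) / (nu * nv)
}

#' @rdname latentCosine
#' @param m numeric matrix, one vector per row.
#' @return `cosineMatrix`: symmetric matrix of pairwise cosines.
#' @export
cosineMatrix <- function(m) {
  u <- rowUnit(as.matrix(m))
  s <- tcrossprod(u)
  pmin(pmax(s, -1), 1)
}

#' Similarity row to probability distribution
#'
#' Converts one anchor's similarities to the other batch members into a
#' probability distribution: softmax at the given temperature, then an
#' epsilon floor and renormalization (the floor guards the log in the KL
#' loss; it is inactive for ordinary batches).
#'
#' @param simRow similarities to the other batch members (self excluded).
#' @param temperature softmax temperature (> 0).
#' @param epsilon probability floor.
#' @return Numeric probability vector summing to 1.
#' @export
toDistribution <- function(simRow, temperature = 1.0, epsilon = 1e-8) {
  stopifnot(temperature > 0, epsilon > 0)
  if (!length(simRow)) stop("empty similarity row")
  z <- simRow / temperature
  z <- z - max(z)
  p <- exp(z) / sum(exp(z))
  p <- pmax(p, epsilon)
  p / sum(p)
}

## All anchor distributions of a batch similarity matrix (diagonal = self,
## excluded).  Returns an n x (n-1) matrix, row i = distribution over j != i.
.batchDistributions <- function(simMat, temperature, epsilon) {
  P <- .batchDistributionsFull(simMat, temperature, epsilon)
  n <- nrow(P)
  matrix(t(P)[!diag(n)], n, n - 1L, byrow = TRUE)
}

## Same, but as an n x n matrix with a structural-zero diagonal;
## vectorized equivalent of applying toDistribution() to every row.
.batchDistributionsFull <- function(simMat, temperature, epsilon) {
  Z <- simMat / temperature
  diag(Z) <- -Inf
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  P <- E / rowSums(E)
  P <- pmax(P, epsilon)
  diag(P) <- 0
  P / rowSums(P)
}

#' Kullback-Leibler distillation loss
#'
#' Mean over anchors i of `sum_j P_ij log(P_ij / Q_ij)`, where P are the
#' learned pocket-similarity distributions and Q the ligand-similarity
#' targets.  Zero iff P = Q; non-negative up to the epsilon floor.
#'
#' @param P,Q matrices of row distributions over identical index sets
#'   (anchors x batch-1), e.g. from [toDistribution()].
#' @return Scalar loss.
#' @export
klLoss <- function(P, Q) {
  P <- rbind(P); Q <- rbind(Q)
  if (!all(dim(P) == dim(Q)))
    stop("P and Q must be distributions over identical index sets")
  mean(rowSums(P * (log(P) - log(Q))))
}

## Forward + loss + full analytic backward for one batch.
## X: batch x inputDim; Qd: n x (n-1) target distributions.
## The epsilon floor is treated as inactive in the gradient (it never
## binds for softmax rows at batch sizes used here).
contrastiveStep <- function(layers, X, Qd, training, dropout, temperature,
                            epsilon, bnMomentum = 0.1, wantGrads = TRUE) {
  n <- nrow(X)
  fw <- mlpForward(layers, X, training, dropout, bnMomentum)
  T <- fw$y
  norms <- sqrt(rowSums(T * T))
  if (any(norms == 0)) stop("zero-norm latent vector in batch")
  Tn <- T / norms
  C <- tcrossprod(Tn)
  Pd <- .batchDistributionsFull(C, temperature, epsilon)
  ## KL per anchor over the structural-zero diagonal
  M <- Pd * (log(pmax(Pd, 1e-300)) - log(pmax(Qd, 1e-300)))
  diag(M) <- 0
  loss <- mean(rowSums(M))
  if (!wantGrads)
    return(list(loss = loss, layers = fw$layers, latent = T))
  ## dL/dC: for anchor i over j != i,
  ##   (1/n) * P_ij * (log(P_ij/Q_ij) - KL_i) / temperature
  lr <- log(pmax(Pd, 1e-300)) - log(pmax(Qd, 1e-300))
  kli <- rowSums(M)
  S <- Pd * (lr - kli) / (n * temperature)
  diag(S) <- 0
  ## dL/dTn = (S + S^T) Tn ; then through row normalization
  G <- (S + t(S)) %*% Tn
  dT <- (G - Tn * rowSums(G * Tn)) / norms
  bw <- mlpBackward(dT, fw$layers, fw$caches)
  list(loss = loss, layers = fw$layers, grads = bw$grads, latent = T)
}

## Flatten/unflatten helpers for the finite-difference gradient check.
flattenParams <- function(layers) {
  unlist(lapply(layers, function(l) l[c("W", "b", "gamma", "beta")]))
}

## Central finite-difference gradient of the batch loss with respect to
## every trainable parameter; used to validate the analytic backward pass.
numericalGradients <- function(layers, X, Qd, temperature, epsilon, h = 1e-5) {
  lossAt <- function(ls) contrastiveStep(ls, X, Qd, training = TRUE,
                                         dropout = 0,
                                         temperature = temperature,
                                         epsilon = epsilon,
                                         wantGrads = FALSE)$loss
  lapply(seq_along(layers), function(l) {
    out <- list()
    for (p in c("W", "b", "gamma", "beta")) {
      g <- array(0, dim(layers[[l]][[p]]) %||% length(layers[[l]][[p]]))
      for (k in seq_along(g)) {
        lp <- layers; lp[[l]][[p]][k] <- lp[[l]][[p]][k] + h
        lm <- layers; lm[[l]][[p]][k] <- lm[[l]][[p]][k] - h
        g[k] <- (lossAt(lp) - lossAt(lm)) / (2 * h)
      }
      out[[p]] <- g
    }
    out
  })
}

## Batch target distributions (full-matrix form) from a fingerprint bit
## matrix subset.
.batchTargets <- function(bits, idx, similarity, temperature, epsilon) {
  sub <- bits[idx, , drop = FALSE]
  qs <- if (similarity == "cosine") fpCosine(sub) else tanimoto(sub)
  .batchDistributionsFull(qs, temperature, epsilon)
}

#' Train the contrastive projection model
#'
#' Distills ligand-similarity structure into the pocket latent space:
#' every batch builds ligand-similarity target distributions Q from the
#' fingerprints and pocket-similarity distributions P from the projected
#' latents, and minimizes mean KL(P || Q) with Adam.  Pockets are split
#' into train/validation by pocket; training batches are drawn with
#' replacement from the training pool, validation batches are fixed at
#' startup.  The returned model is the checkpoint with the lowest
#' validation loss; training stops after `patience` epochs without
#' improvement or at `maxEpochs`.  Fully reproducible given `cfg@seed`.
#'
#' @param pockets a [PocketExperiment-class] (assay `"pooled"`) or a
#'   pockets-in-rows embedding matrix.
#' @param fingerprints a [FingerprintSet-class], one fingerprint per
#'   pocket, in pocket order.
#' @param cfg a [TrainingConfig-class].
#' @param model optional pre-initialized [ProjectionModel-class].
#' @return List with elements `model` (best checkpoint), `history`
#'   (data.frame epoch/trainLoss/valLoss) and `bestEpoch`.
#' @export
trainProjection <- function(pockets, fingerprints, cfg = trainingConfig(),
                            model = NULL) {
  X <- if (is(pockets, "PocketExperiment")) t(pooled(pockets))
       else as.matrix(pockets)
  bits <- fingerprintBits(fingerprints)
  storage.mode(bits) <- "double"
  if (nrow(bits) != nrow(X))
    stop("one fingerprint per pocket required (got ", nrow(bits),
         " fingerprints for ", nrow(X), " pockets)")
  if (nrow(X) < 2L * cfg@batchSize)
    stop("need at least 2 * batchSize = ", 2L * cfg@batchSize, " samples")
  model <- model %||% projectionModel(inputDim = ncol(X), seed = cfg@seed)
  withSeed(cfg@seed, {
    n <- nrow(X)
    nVal <- max(cfg@batchSize %/% 4L, round(cfg@valFraction * n))
    valIdx <- sample.int(n, nVal)
    trainIdx <- setdiff(seq_len(n), valIdx)
    valBatches <- lapply(seq_len(cfg@valBatches), function(b)
      sample(valIdx, cfg@batchSize, replace = TRUE))
    valTargets <- lapply(valBatches, .batchTargets, bits = bits,
                         similarity = cfg@similarity,
                         temperature = cfg@temperature,
                         epsilon = cfg@epsilon)
    layers <- model@layers
    opt <- adamInit(lapply(layers, function(l) l[c("W", "b", "gamma", "beta")]))
    history <- data.frame(epoch = integer(), trainLoss = numeric(),
                          valLoss = numeric())
    best <- list(loss = Inf, layers = layers, epoch = 0L)
    sinceBest <- 0L
    for (epoch in seq_len(cfg@maxEpochs)) {
      trLoss <- 0
      for (b in seq_len(cfg@trainBatches)) {
        idx <- sample(trainIdx, cfg@batchSize, replace = TRUE)
        Qd <- .batchTargets(bits, idx, cfg@similarity, cfg@temperature,
                            cfg@epsilon)
        st <- contrastiveStep(layers, X[idx, , drop = FALSE], Qd,
                              training = TRUE, dropout = model@dropout,
                              temperature = cfg@temperature,
                              epsilon = cfg@epsilon,
                              bnMomentum = cfg@bnMomentum)
        if (!is.finite(st$loss))
          stop("non-finite training loss at epoch ", epoch, ", batch ", b,
               "; lower the learning rate or raise epsilon")
        layers <- st$layers
        upd <- adamStep(layers, st$grads, opt, cfg@learningRate)
        for (l in seq_along(layers))
          layers[[l]][c("W", "b", "gamma", "beta")] <-
            upd$params[[l]][c("W", "b", "gamma", "beta")]
        opt <- upd$state
        trLoss <- trLoss + st$loss
      }
      vaLoss <- mean(vapply(seq_along(valBatches), function(b)
        contrastiveStep(layers, X[valBatches[[b]], , drop = FALSE],
                        valTargets[[b]], training = FALSE, dropout = 0,
                        temperature = cfg@temperature,
                        epsilon = cfg@epsilon, wantGrads = FALSE)$loss,
        numeric(1)))
      history <- rbind(history, data.frame(
        epoch = epoch, trainLoss = trLoss / cfg@trainBatches,
        valLoss = vaLoss))
      if (vaLoss < best$loss) {
        best <- list(loss = vaLoss, layers = layers, epoch = epoch)
        sinceBest <- 0L
      } else {
        sinceBest <- sinceBest + 1L
        if (sinceBest >= cfg@patience) break
      }
    }
  })
  model@layers <- best$layers
  model@trained <- TRUE
  list(model = model, history = history, bestEpoch = best$epoch)
}

#' Encode pockets with a trained model
#'
#' Eval-mode projection of every pocket: deterministic and batch-order
#' invariant.  For a [PocketExperiment-class] the latent matrix is stored
#' on the object (accessible via [latent()]); for a matrix the latent
#' matrix is returned directly.
#'
#' @param model a trained [ProjectionModel-class].
#' @param pockets a [PocketExperiment-class] or pockets-in-rows matrix.
#' @return The updated `PocketExperiment`, or a latent matrix.
#' @export
encodePockets <- function(model, pockets) {
  if (is(pockets, "PocketExperiment")) {
    L <- projectPockets(model, t(pooled(pockets)), mode = "eval")
    return(setLatent(pockets, t(L)))
  }
  projectPockets(model, pockets, mode = "eval")
}

#' Save / load a projection-model checkpoint
#'
#' Single-file checkpoint holding the parameter tensors, normalization
#' statistics and metadata under a versioned schema id.
#'
#' @param model a [ProjectionModel-class].
#' @param path checkpoint file.
#' @return `saveProjectionModel`: the path, invisibly;
#'   `loadProjectionModel`: the restored model.
#' @export
saveProjectionModel <- function(model, path) {
  stopifnot(is(model, "ProjectionModel"))
  saveRDS(list(schema = model@schemaVersion,
               layers = model@layers,
               dims = c(model@inputDim, model@hiddenDim, model@latentDim),
               dropout = model@dropout, providerTag = model@providerTag,
               trained = model@trained), path)
  invisible(path)
}

#' @rdname saveProjectionModel
#' @export
loadProjectionModel <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$schema, "erepoc-ckpt-1"))
    stop("unknown checkpoint schema: ", ck$schema %||% "<none>")
  new("ProjectionModel", layers = ck$layers,
      inputDim = ck$dims[1], hiddenDim = ck$dims[2], latentDim = ck$dims[3],
      dropout = ck$dropout, providerTag = ck$providerTag,
      trained = ck$trained, schemaVersion = ck$schema)
}
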