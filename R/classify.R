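## The pocket-type classification benchmark: stratified split, two
## classifier families over either representation, and the
## precision/recall/F1 metrics.

#' Stratified train/test split
#'
#' Splits samples 9:1 (by default) into disjoint, exhaustive train and
#' test sets, stratified by label so every class appears in the test set.
#'
#' @param labels per-sample class labels.
#' @param ratio training fraction.
#' @param seed split seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
stratifiedSplit <- function(labels, ratio = 0.9, seed = 1L) {
  stopifnot(length(labels) >= 10L, ratio > 0, ratio < 1)
  tab <- table(labels)
  if (any(tab < 2L))
    stop("class with fewer than 2 members: ",
         paste(names(tab)[tab < 2L], collapse = ", "))
  test <- withSeed(seed, unlist(lapply(names(tab), function(cl) {
    idx <- which(labels == cl)
    nTest <- max(1L, round((1 - ratio) * length(idx)))
    sample(idx, nTest)
  }), use.names = FALSE))
  list(train = setdiff(seq_along(labels), test), test = sort(test))
}

## Feedforward softmax classifier: one hidden layer (GELU), cross-entropy,
## full-batch Adam.  Small and deterministic given the seed.
.fitFeedforward <- function(x, y, hidden = 128L, epochs = 200L, lr = 1e-3,
                            seed = 1L) {
  classes <- levels(y)
  K <- length(classes)
  d <- ncol(x)
  Y <- diag(K)[as.integer(y), , drop = FALSE]
  withSeed(seed, {
    W1 <- matrix(rnorm(d * hidden, sd = sqrt(2 / d)), d, hidden)
    b1 <- numeric(hidden)
    W2 <- matrix(rnorm(hidden * K, sd = sqrt(2 / hidden)), hidden, K)
    b2 <- numeric(K)
    params <- list(list(W = W1, b = b1), list(W = W2, b = b2))
    opt <- adamInit(params)
    n <- nrow(x)
    for (e in seq_len(epochs)) {
      Z1 <- sweep(x %*% params[[1]]$W, 2L, params[[1]]$b, "+")
      H <- gelu(Z1)
      Z2 <- sweep(H %*% params[[2]]$W, 2L, params[[2]]$b, "+")
      Z2 <- Z2 - apply(Z2, 1L, max)
      P <- exp(Z2) / rowSums(exp(Z2))
      dZ2 <- (P - Y) / n
      g2 <- list(W = crossprod(H, dZ2), b = colSums(dZ2))
      dH <- (dZ2 %*% t(params[[2]]$W)) * geluGrad(Z1)
      g1 <- list(W = crossprod(x, dH), b = colSums(dH))
      upd <- adamStep(params, list(g1, g2), opt, lr)
      params <- upd$params; opt <- upd$state
    }
  })
  structure(list(family = "feedforward", params = params,
                 classes = classes), class = "pocketClassifier")
}

#' Fit a pocket-type classifier
#'
#' Two families: `"feedforward"` (one hidden layer of 128 GELU units,
#' softmax cross-entropy, Adam, 200 full-batch epochs — a fixed contract,
#' deterministic given the seed) and `"svm_rbf"` (one-vs-rest support
#' vector machine with RBF kernel and the default bandwidth heuristic).
#'
#' @param x feature matrix (samples x features): raw pooled embeddings or
#'   latent representations.
#' @param y class labels.
#' @param family `"feedforward"` or `"svm_rbf"`.
#' @param seed seed for the feedforward initialization.
#' @param hidden,epochs,lr feedforward hyperparameters.
#' @return A `pocketClassifier` object with a [predict][stats::predict]
#'   method returning a factor of labels.
#' @export
fitPocketClassifier <- function(x, y, family = c("feedforward", "svm_rbf"),
                                seed = 1L, hidden = 128L, epochs = 200L,
                                lr = 1e-3) {
  family <- match.arg(family)
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2L)
    stop("need at least 2 classes to fit a classifier")
  if (family == "feedforward")
    return(.fitFeedforward(x, y, hidden, epochs, lr, seed))
  fit <- e1071::svm(x, y, kernel = "radial", scale = FALSE)
  structure(list(family = "svm_rbf", fit = fit, classes = levels(y)),
            class = "pocketClassifier")
}

#' @export
predict.pocketClassifier <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (object$family == "svm_rbf")
    return(factor(as.character(predict(object$fit, newdata)),
                  levels = object$classes))
  p <- object$params
  H <- gelu(sweep(newdata %*% p[[1]]$W, 2L, p[[1]]$b, "+"))
  Z <- sweep(H %*% p[[2]]$W, 2L, p[[2]]$b, "+")
  factor(object$classes[max.col(Z, ties.method = "first")],
         levels = object$classes)
}

#' Classification metrics from predictions
#'
#' Per-class precision TP/(TP+FP), recall TP/(TP+FN) and F1 (harmonic
#' mean), their unweighted macro averages, overall accuracy, and the
#' confusion matrix (rows = truth, columns = prediction).  A class with a
#' zero denominator gets metric 0 (logged), keeping macro averages
#' defined.
#'
#' @param predicted,truth label vectors of equal length.
#' @return List of class `classMetrics`: `confusion`, `perClass`
#'   (data.frame), `macroPrecision`, `macroRecall`, `macroF1`, `accuracy`.
#' @export
classMetrics <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth), length(truth) > 0)
  lev <- sort(union(as.character(predicted), as.character(truth)))
  p <- factor(as.character(predicted), levels = lev)
  t_ <- factor(as.character(truth), levels = lev)
  cm <- table(truth = t_, predicted = p)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  safe <- function(num, den, what) {
    out <- ifelse(den == 0, 0, num / pmax(den, 1))
    if (any(den == 0))
      erepocLog("classMetrics: ", what, " denominator 0 for ",
                paste(lev[den == 0], collapse = ", "), "; defined as 0")
    out
  }
  precision <- safe(tp, tp + fp, "precision")
  recall <- safe(tp, tp + fn, "recall")
  f1 <- ifelse(precision + recall == 0, 0,
               2 * precision * recall / (precision + recall))
  structure(list(
    confusion = cm,
    perClass = data.frame(class = lev, precision = as.numeric(precision),
                          recall = as.numeric(recall), f1 = as.numeric(f1),
                          support = as.numeric(rowSums(cm)),
                          stringsAsFactors = FALSE),
    macroPrecision = mean(precision), macroRecall = mean(recall),
    macroF1 = mean(f1), accuracy = sum(tp) / length(truth)),
    class = "classMetrics")
}

#' @export
print.classMetrics <- function(x, ...) {
  cat(sprintf("accuracy %.4f | macro P %.4f R %.4f F1 %.4f (%d classes)\n",
              x$accuracy, x$macroPrecision, x$macroRecall, x$macroF1,
              nrow(x$perClass)))
  invisible(x)
}

#' Evaluate a classifier on a test set
#'
#' @param classifier a `pocketClassifier`.
#' @param x test feature matrix.
#' @param y test labels.
#' @return A `classMetrics` object, see [classMetrics()].
#' @export
evaluateClassifier <- function(classifier, x, y) {
  stopifnot(length(y) > 0)
  classMetrics(predict(classifier, x), y)
}

#' Compare raw and latent representations across classifier families
#'
#' Runs the four benchmark variants (raw/latent x feedforward/svm) on an
#' identical stratified split and reports one table.
#'
#' @param pockets a [PocketExperiment-class] carrying both the pooled and
#'   latent representations and a `ligandClass` label column.
#' @param ratio,seed split settings.
#' @return `data.frame` with one row per variant: representation, family,
#'   accuracy, macroF1.
#' @export
benchmarkRepresentations <- function(pockets, ratio = 0.9, seed = 7L) {
  y <- factor(ligandClass(pockets))
  sp <- stratifiedSplit(as.character(y), ratio = ratio, seed = seed)
  reps <- list(raw = t(pooled(pockets)), latent = t(latent(pockets)))
  grid <- expand.grid(representation = names(reps),
                      family = c("feedforward", "svm_rbf"),
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    X <- reps[[grid$representation[i]]]
    clf <- fitPocketClassifier(X[sp$train, , drop = FALSE], y[sp$train],
                               family = grid$family[i], seed = seed)
    m <- evaluateClassifier(clf, X[sp$test, , drop = FALSE], y[sp$test])
    data.frame(representation = grid$representation[i],
               family = grid$family[i], accuracy = m$accuracy,
               macroF1 = m$macroF1, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Held-out ligand-class ablation
#'
#' Retrains the contrastive model with the given ligand classes entirely
#' excluded from training, encodes the held-out pockets with the
#' resulting model, and measures how well the never-seen classes separate
#' in the latent space: the mean within-class latent cosine of held-out
#' pockets versus the mean cosine across the held-out classes.
#'
#' @param pockets a [PocketExperiment-class] with `ligandClass` labels.
#' @param fingerprints paired [FingerprintSet-class].
#' @param holdoutClasses two or more class labels to exclude.
#' @param cfg a [TrainingConfig-class].
#' @return List: `model`, `history`, `withinCosine`, `crossCosine`,
#'   `gap` (within minus cross), `holdout`.
#' @export
ablationHoldout <- function(pockets, fingerprints, holdoutClasses,
                            cfg = trainingConfig()) {
  y <- ligandClass(pockets)
  stopifnot(length(holdoutClasses) >= 2L,
            all(holdoutClasses %in% y))
  keep <- !(y %in% holdoutClasses)
  X <- t(pooled(pockets))
  bits <- fingerprintBits(fingerprints)
  fit <- trainProjection(X[keep, , drop = FALSE],
                         fingerprintSet(bits[keep, , drop = FALSE]), cfg)
  Lhold <- encodePockets(fit$model, X[!keep, , drop = FALSE])
  yh <- y[!keep]
  C <- cosineMatrix(Lhold)
  up <- upper.tri(C)
  same <- outer(yh, yh, "==")
  within <- mean(C[up & same])
  cross <- mean(C[up & !same])
  list(model = fit$model, history = fit$history, withinCosine = within,
       crossCosine = cross, gap = within - cross,
       holdout = holdoutClasses)
}
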