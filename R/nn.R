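## Internal dense-network machinery: GELU, batch normalization, dropout,
## Adam, and forward/backward passes.  Written on base matrix ops (BLAS);
## no external autodiff is involved, gradients are derived analytically and
## verified against finite differences in the test suite.

.BN_EPS <- 1e-5

gelu <- function(x) x * pnorm(x)
geluGrad <- function(x) pnorm(x) + x * dnorm(x)

## Batch normalization over columns.  In training mode uses batch
## statistics and updates running statistics with momentum `mom`; in eval
## mode applies the stored running statistics (deterministic).
bnForward <- function(x, layer, training, mom = 0.1) {
  if (training) {
    n <- nrow(x)
    mu <- colMeans(x)
    xc <- sweep(x, 2L, mu)
    va <- colMeans(xc * xc)           # population variance, as batch norm uses
    istd <- 1 / sqrt(va + .BN_EPS)
    xhat <- sweep(xc, 2L, istd, "*")
    y <- sweep(sweep(xhat, 2L, layer$gamma, "*"), 2L, layer$beta, "+")
    ## unbiased variance feeds the running estimate (torch convention)
    runVar <- if (n > 1L) va * n / (n - 1L) else va
    layer$runMean <- (1 - mom) * layer$runMean + mom * mu
    layer$runVar  <- (1 - mom) * layer$runVar + mom * runVar
    list(y = y, layer = layer,
         cache = list(xhat = xhat, istd = istd, xc = xc))
  } else {
    istd <- 1 / sqrt(layer$runVar + .BN_EPS)
    xhat <- sweep(sweep(x, 2L, layer$runMean), 2L, istd, "*")
    y <- sweep(sweep(xhat, 2L, layer$gamma, "*"), 2L, layer$beta, "+")
    list(y = y, layer = layer, cache = list(xhat = xhat, istd = istd))
  }
}

## Backward through training-mode batch normalization.
bnBackward <- function(dy, layer, cache) {
  n <- nrow(dy)
  dgamma <- colSums(dy * cache$xhat)
  dbeta <- colSums(dy)
  dxhat <- sweep(dy, 2L, layer$gamma, "*")
  ## dx = istd/n * (n*dxhat - sum(dxhat) - xhat * sum(dxhat*xhat))
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * cache$xhat)
  dx <- sweep(n * dxhat, 2L, s1) - sweep(cache$xhat, 2L, s2, "*")
  dx <- sweep(dx, 2L, cache$istd / n, "*")
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

## One block: affine -> batch norm -> dropout -> GELU.
blockForward <- function(x, layer, training, dropout, mom) {
  z <- x %*% layer$W
  z <- sweep(z, 2L, layer$b, "+")
  bn <- bnForward(z, layer, training, mom)
  d <- bn$y
  mask <- NULL
  if (training && dropout > 0) {
    mask <- matrix(rbinom(length(d), 1L, 1 - dropout), nrow(d)) / (1 - dropout)
    d <- d * mask
  }
  a <- gelu(d)
  list(y = a, layer = bn$layer,
       cache = list(x = x, bn = bn$cache, preact = d, mask = mask,
                    training = training))
}

blockBackward <- function(dy, layer, cache) {
  dd <- dy * geluGrad(cache$preact)
  if (!is.null(cache$mask)) dd <- dd * cache$mask
  if (cache$training) {
    bb <- bnBackward(dd, layer, cache$bn)
  } else {
    istd <- 1 / sqrt(layer$runVar + .BN_EPS)
    bb <- list(dx = sweep(dd, 2L, layer$gamma * istd, "*"),
               dgamma = colSums(dd * cache$bn$xhat),
               dbeta = colSums(dd))
  }
  dz <- bb$dx
  list(dx = tcrossprod(dz, layer$W),
       grads = list(W = crossprod(cache$x, dz), b = colSums(dz),
                    gamma = bb$dgamma, beta = bb$dbeta))
}

## Adam optimizer state over a nested parameter list.
adamInit <- function(params) {
  zeros <- function(p) lapply(p, function(v) array(0, dim(v) %||% length(v)))
  list(m = lapply(params, zeros), v = lapply(params, zeros), t = 0L)
}

adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (l in seq_along(params)) {
    for (p in names(grads[[l]])) {
      g <- grads[[l]][[p]]
      state$m[[l]][[p]] <- beta1 * state$m[[l]][[p]] + (1 - beta1) * g
      state$v[[l]][[p]] <- beta2 * state$v[[l]][[p]] + (1 - beta2) * g * g
      mhat <- state$m[[l]][[p]] / c1
      vhat <- state$v[[l]][[p]] / c2
      params[[l]][[p]] <- params[[l]][[p]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(params = params, state = state)
}

## Full network forward.  Returns output and caches for backward.
mlpForward <- function(layers, x, training, dropout, mom = 0.1) {
  caches <- vector("list", length(layers))
  for (l in seq_along(layers)) {
    out <- blockForward(x, layers[[l]], training, dropout, mom)
    layers[[l]] <- out$layer
    caches[[l]] <- out$cache
    x <- out$y
  }
  list(y = x, layers = layers, caches = caches)
}

mlpBackward <- function(dy, layers, caches) {
  grads <- vector("list", length(layers))
  for (l in rev(seq_along(layers))) {
    bb <- blockBackward(dy, layers[[l]], caches[[l]])
    grads[[l]] <- bb$grads
    dy <- bb$dx
  }
  list(grads = grads, dx = dy)
}
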