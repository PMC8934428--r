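# Shared pieces of the neural-detector training loop. The per-batch forward
# and backward passes run in the compiled float32 kernels
# (src/nn_kernels.cpp); this file holds the optimizer and the epoch/loss
# plumbing that drives them. Window arrays are (N, time, channels).

.sigmoid <- function(x) 1 / (1 + exp(-x))

# --- Adam optimizer -------------------------------------------------------

.adamInit <- function(params) {
  zero <- lapply(params, function(p) p * 0)
  list(m = zero, v = zero, t = 0)
}

.adamStep <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  for (k in names(params)) {
    g <- grads[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g^2
    mhat <- state$m[[k]] / (1 - beta1^state$t)
    vhat <- state$v[[k]] / (1 - beta2^state$t)
    params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# --- per-batch steps (fused kernels) --------------------------------------

.cnnStep <- function(model, Xb, yb, wb, wantGrad = TRUE) {
  out <- .cnnPassCpp(Xb, yb, wb, model$params, model$bnState,
                     TRUE, model$dropout, wantGrad)
  model$bnState <- out$bnState
  list(model = model, loss = out$loss, grads = out$grads)
}

.cnnLogits <- function(model, X) {
  n <- dim(X)[1]
  .cnnPassCpp(X, numeric(n), rep(1, n), model$params, model$bnState,
              FALSE, 0, FALSE)$logits
}

.rnnStep <- function(model, Xb, yb, wb, wantGrad = TRUE) {
  out <- .rnnPassCpp(aperm(Xb, c(1, 3, 2)), yb, wb, model$params,
                     TRUE, model$dropout, wantGrad)
  list(model = model, loss = out$loss, grads = out$grads)
}

.rnnLogits <- function(model, X) {
  n <- dim(X)[1]
  .rnnPassCpp(aperm(X, c(1, 3, 2)), numeric(n), rep(1, n), model$params,
              FALSE, 0, FALSE)$logits
}

.nnStep <- function(model, ...) {
  if (inherits(model, "cnnModel")) .cnnStep(model, ...)
  else .rnnStep(model, ...)
}

.nnLogits <- function(model, X, batch = 1024) {
  n <- dim(X)[1]
  fun <- if (inherits(model, "cnnModel")) .cnnLogits else .rnnLogits
  unlist(lapply(seq(1, n, by = batch), function(b0) {
    fun(model, X[b0:min(n, b0 + batch - 1), , , drop = FALSE])
  }))
}

# mean (unweighted) BCE of a model over a labelled window set
.nnLoss <- function(model, X, y) {
  p <- .sigmoid(.nnLogits(model, X))
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# one shuffled pass over the data
.runEpoch <- function(model, X, y, w, batch, opt, lr) {
  n <- length(y)
  ord <- sample.int(n)
  lossSum <- 0
  for (b0 in seq(1, n, by = batch)) {
    idx <- ord[b0:min(n, b0 + batch - 1)]
    st <- .nnStep(model, X[idx, , , drop = FALSE], y[idx], w[idx])
    model <- st$model
    lossSum <- lossSum + st$loss * length(idx)
    up <- .adamStep(model$params, st$grads, opt, lr = lr)
    model$params <- up$params
    opt <- up$state
  }
  list(model = model, opt = opt, loss = lossSum / n)
}

.glorot <- function(nin, nout, n = nin * nout) {
  lim <- sqrt(6 / (nin + nout))
  stats::runif(n, -lim, lim)
}
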