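# Minimal backpropagation neural network (multilayer perceptron) used as
# the particle classifier: ReLU hidden layers, softmax cross-entropy
# output, Adam updates, early stopping on validation loss. Written in
# base-R matrix code; sized for feature tables of a few thousand rows by
# a few dozen columns.

mlp_init <- function(d_in, hidden, k_out) {
  sizes <- c(d_in, hidden, k_out)
  lapply(seq_len(length(sizes) - 1L), function(i) {
    list(W = matrix(rnorm(sizes[i] * sizes[i + 1L],
                          sd = sqrt(2 / sizes[i])),
                    nrow = sizes[i]),
         b = rep(0, sizes[i + 1L]))
  })
}

mlp_forward <- function(params, X) {
  acts <- vector("list", length(params) + 1L)
  acts[[1L]] <- X
  L <- length(params)
  for (i in seq_len(L)) {
    Z <- acts[[i]] %*% params[[i]]$W +
      matrix(params[[i]]$b, nrow(X), length(params[[i]]$b), byrow = TRUE)
    acts[[i + 1L]] <- if (i < L) pmax(Z, 0) else Z   # ReLU / linear logits
  }
  acts
}

softmax <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

mlp_probs <- function(params, X) {
  acts <- mlp_forward(params, X)
  softmax(acts[[length(acts)]])
}

# mean cross-entropy of one-hot Y
mlp_loss <- function(params, X, Y) {
  P <- mlp_probs(params, X)
  -mean(rowSums(Y * log(pmax(P, 1e-12))))
}

mlp_grad <- function(params, X, Y) {
  acts <- mlp_forward(params, X)
  n <- nrow(X)
  L <- length(params)
  P <- softmax(acts[[L + 1L]])
  delta <- (P - Y) / n
  grads <- vector("list", L)
  for (i in rev(seq_len(L))) {
    grads[[i]] <- list(W = crossprod(acts[[i]], delta),
                       b = colSums(delta))
    if (i > 1L) {
      delta <- (delta %*% t(params[[i]]$W)) * (acts[[i]] > 0)
    }
  }
  grads
}

adam_state <- function(params) {
  lapply(params, function(p)
    list(mW = p$W * 0, vW = p$W * 0, mb = p$b * 0, vb = p$b * 0))
}

adam_step <- function(params, grads, state, t, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  c1 <- 1 - beta1^t
  c2 <- 1 - beta2^t
  for (i in seq_along(params)) {
    s <- state[[i]]
    g <- grads[[i]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$W
    s$vW <- beta2 * s$vW + (1 - beta2) * g$W^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    params[[i]]$W <- params[[i]]$W - lr * (s$mW / c1) / (sqrt(s$vW / c2) + eps)
    params[[i]]$b <- params[[i]]$b - lr * (s$mb / c1) / (sqrt(s$vb / c2) + eps)
    state[[i]] <- s
  }
  list(params = params, state = state)
}
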