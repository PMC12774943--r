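# Minimal fully connected network engine used by the self-supervised fit and
# the dual-network protocol selector. Implements exactly what those two small
# models need: dense layers, ELU/ReLU, inverted dropout, batch normalisation
# and the Adam optimiser, all in base R matrix operations. Networks here have
# 18-27 inputs and one to three hidden layers, for which this is plenty fast.

.dense_init <- function(n_in, n_out) {
  # Glorot-uniform weights, zero bias
  lim <- sqrt(6 / (n_in + n_out))
  list(W = matrix(runif(n_in * n_out, -lim, lim), n_in, n_out),
       b = numeric(n_out))
}

.elu <- function(x) ifelse(x > 0, x, exp(x) - 1)
.elu_grad <- function(x) ifelse(x > 0, 1, exp(x))
.relu <- function(x) pmax(x, 0)
.relu_grad <- function(x) (x > 0) * 1
.sigmoid <- function(x) 1 / (1 + exp(-x))

# inverted dropout mask; keep probability 1 - p
.dropout_mask <- function(nr, nc, p) {
  if (p <= 0) return(NULL)
  matrix((runif(nr * nc) >= p) / (1 - p), nr, nc)
}

# Adam: params and grads are flat lists of arrays with matching shapes
.adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

.adam_step <- function(params, grads, state, lr,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in seq_along(params)) {
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * grads[[k]]
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * grads[[k]]^2
    params[[k]] <- params[[k]] -
      lr * (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# batch normalisation over rows (samples); returns forward cache for backprop
.bn_forward <- function(A, gamma, beta, running, momentum = 0.1,
                        training = TRUE, eps = 1e-5) {
  if (training) {
    mu <- colMeans(A)
    v <- colMeans(sweep(A, 2, mu)^2)
    running$mean <- (1 - momentum) * running$mean + momentum * mu
    running$var <- (1 - momentum) * running$var + momentum * v
  } else {
    mu <- running$mean
    v <- running$var
  }
  xhat <- sweep(sweep(A, 2, mu), 2, sqrt(v + eps), "/")
  out <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  list(out = out, xhat = xhat, var = v, running = running, eps = eps)
}

.bn_backward <- function(dout, cache, gamma) {
  B <- nrow(dout)
  dgamma <- colSums(dout * cache$xhat)
  dbeta <- colSums(dout)
  dxhat <- sweep(dout, 2, gamma, "*")
  inv_sd <- 1 / sqrt(cache$var + cache$eps)
  dA <- sweep(B * dxhat - matrix(colSums(dxhat), B, ncol(dout), byrow = TRUE) -
                cache$xhat * matrix(colSums(dxhat * cache$xhat), B,
                                    ncol(dout), byrow = TRUE),
              2, inv_sd / B, "*")
  list(dA = dA, dgamma = dgamma, dbeta = dbeta)
}
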