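# Neural-network primitives -------------------------------------------------
#
# Minimal 3D convolutional network machinery used by the conditional VAE:
# kernel-3 convolutions via im2col gathers and BLAS matrix products, 2x
# average pooling, nearest-neighbor upsampling, dense layers, leaky-ReLU and
# softplus activations, and spectral normalization of weight matrices. All
# backward passes are hand-derived; a finite-difference check in the test
# suite guards them. Feature maps are (voxels x channels) matrices with the
# x index fastest, matching the channel-first grid arrays after reshape.

# Memoized index tables per grid size.
.nn_cache <- new.env(parent = emptyenv())

# 2x average pooling: (V/8) x 8 children table, and the inverse fine->coarse
# map used by both pooling backward and nearest-neighbor upsampling.
pool_idx <- function(P) {
  key <- paste0("pool", P)
  if (!is.null(.nn_cache[[key]])) return(.nn_cache[[key]])
  stopifnot(P %% 2 == 0)
  Q <- P %/% 2L
  fine <- arrayInd(seq_len(P^3), c(P, P, P))
  parent <- (((fine[, 3] + 1L) %/% 2L) - 1L) * Q * Q +
    (((fine[, 2] + 1L) %/% 2L) - 1L) * Q + ((fine[, 1] + 1L) %/% 2L)
  children <- matrix(0L, Q^3, 8L)
  cnt <- integer(Q^3)
  for (v in seq_len(P^3)) {
    p <- parent[v]; cnt[p] <- cnt[p] + 1L; children[p, cnt[p]] <- v
  }
  out <- list(children = children, parent = parent)
  .nn_cache[[key]] <- out
  out
}

# Weight layout: row (k-1)*cin + c for neighbor offset k (dx fastest in
# {-1,0,1}^3) and input channel c; one column per output channel.
conv3_fwd <- function(X, W, b, P) {
  list(Y = cpp_conv3_fwd(X, W, b, P), X = X)
}

conv3_bwd <- function(dY, X, W, P) {
  cpp_conv3_bwd(X, W, dY, P)
}

pool_fwd <- function(X, pt) {
  ch <- ncol(X)
  Y <- matrix(0, nrow(pt$children), ch)
  for (k in seq_len(8L)) Y <- Y + X[pt$children[, k], , drop = FALSE]
  Y / 8
}

pool_bwd <- function(dY, pt) dY[pt$parent, , drop = FALSE] / 8

up_fwd <- function(X, pt) X[pt$parent, , drop = FALSE]

up_bwd <- function(dY, pt) {
  ch <- ncol(dY)
  dX <- matrix(0, nrow(pt$children), ch)
  for (k in seq_len(8L)) dX <- dX + dY[pt$children[, k], , drop = FALSE]
  dX
}

lrelu_fwd <- function(X, alpha = 0.1) ifelse(X > 0, X, alpha * X)
lrelu_bwd <- function(dY, X, alpha = 0.1) dY * ifelse(X > 0, 1, alpha)

softplus_fwd <- function(X) {
  # numerically stable log(1 + exp(x))
  pmax(X, 0) + log1p(exp(-abs(X)))
}
softplus_bwd <- function(dY, X) dY * (1 / (1 + exp(-X)))

# Spectral normalization ------------------------------------------------------
#
# Each weight matrix W is used as W / sigma, with sigma the leading singular
# value estimated by power iteration; u, v are persisted in the model state
# and advanced once per optimizer step (frozen during plain inference and
# during finite-difference checks). The gradient treats u, v as constants:
# d(W/sigma)/dW contributes dW = dWn/sigma - (sum(dWn * Wn)/sigma) u v'.

sn_init <- function(W, n_iter = 20L) {
  st <- list(u = stats::rnorm(nrow(W)), v = stats::rnorm(ncol(W)))
  sn_power_iterate(W, st, n_iter)
}

sn_power_iterate <- function(W, st, n_iter = 1L) {
  u <- st$u; v <- st$v
  for (i in seq_len(n_iter)) {
    v <- drop(crossprod(W, u)); v <- v / max(sqrt(sum(v^2)), 1e-12)
    u <- drop(W %*% v);         u <- u / max(sqrt(sum(u^2)), 1e-12)
  }
  list(u = u, v = v)
}

sn_sigma <- function(W, st) {
  # u is aligned with W v by the power iteration, so u'Wv >= 0
  s <- drop(crossprod(st$u, W %*% st$v))
  max(s, 1e-12)
}

sn_normalize <- function(W, st) W / sn_sigma(W, st)

sn_grad <- function(dWn, W, st) {
  sigma <- sn_sigma(W, st)
  Wn <- W / sigma
  dWn / sigma - (sum(dWn * Wn) / sigma) * (st$u %o% st$v)
}
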