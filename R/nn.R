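# Minimal 1-D convolutional network primitives built on BLAS matrix
# products. A batch of B sequences of length L with C channels is a
# C x (L*B) matrix, columns ordered position-major within sample. "Same"
# padding keeps sequence length; a convolution is evaluated by gathering
# the K shifted views of the zero-padded batch into one (C*K) x (L*B)
# im2col matrix and applying a single GEMM, so forward and backward passes
# are each one or two dgemm calls per layer.

conv_index <- function(L, B, K) {
  pad <- (K - 1L) %/% 2L
  Lp <- L + 2L * pad
  base <- rep((0:(B - 1L)) * Lp, each = L)
  pos <- rep(seq_len(L), B)
  list(K = K, Lp = Lp, B = B, LB = L * B,
       data_cols = base + pos + pad,
       tap_cols = lapply(seq_len(K), function(t) base + pos + (t - 1L)))
}

# weight layout: c_out x (c_in*K), column blocks ordered by tap
conv_init <- function(c_in, c_out, K) {
  sd <- sqrt(2 / (c_in * K))
  list(W = matrix(stats::rnorm(c_out * c_in * K, 0, sd), c_out, c_in * K),
       b = numeric(c_out), c_in = c_in, K = K)
}

conv_fwd <- function(layer, X, idx) {
  c_in <- layer$c_in; K <- layer$K
  Xp <- matrix(0, c_in, idx$Lp * idx$B)
  Xp[, idx$data_cols] <- X
  M <- matrix(0, c_in * K, idx$LB)
  for (t in seq_len(K))
    M[((t - 1L) * c_in + 1L):(t * c_in), ] <- Xp[, idx$tap_cols[[t]], drop = FALSE]
  list(out = layer$W %*% M + layer$b, M = M)
}

conv_bwd <- function(layer, cache, dOut, idx, need_dx = TRUE) {
  c_in <- layer$c_in; K <- layer$K
  g <- list(dW = tcrossprod(dOut, cache$M), db = rowSums(dOut))
  if (need_dx) {
    dM <- crossprod(layer$W, dOut)
    dXp <- matrix(0, c_in, idx$Lp * idx$B)
    for (t in seq_len(K)) {
      cols <- idx$tap_cols[[t]]
      dXp[, cols] <- dXp[, cols, drop = FALSE] +
        dM[((t - 1L) * c_in + 1L):(t * c_in), , drop = FALSE]
    }
    g$dX <- dXp[, idx$data_cols, drop = FALSE]
  }
  g
}

dense_init <- function(n_in, n_out) {
  list(W = matrix(stats::rnorm(n_out * n_in, 0, sqrt(2 / n_in)), n_out, n_in),
       b = numeric(n_out))
}

dense_fwd <- function(layer, X) layer$W %*% X + layer$b
dense_bwd <- function(layer, X, dOut)
  list(dW = tcrossprod(dOut, X), db = rowSums(dOut),
       dX = crossprod(layer$W, dOut))

# temporal mean pool: C x (L*B) -> C x B, and its adjoint
pool_fwd <- function(X, L, B)
  t(rowsum(t(X), rep(seq_len(B), each = L), reorder = FALSE)) / L
pool_bwd <- function(dP, L, B) dP[, rep(seq_len(B), each = L), drop = FALSE] / L

# RMSprop; state mirrors the parameter list structure
rmsprop_step <- function(params, grads, state, lr = 1e-3, rho = 0.9, eps = 1e-8) {
  for (i in seq_along(grads)) {
    for (nm in c("W", "b")) {
      g <- grads[[i]][[paste0("d", nm)]]
      s <- rho * state[[i]][[nm]] + (1 - rho) * g * g
      params[[i]][[nm]] <- params[[i]][[nm]] - lr * g / (sqrt(s) + eps)
      state[[i]][[nm]] <- s
    }
  }
  list(params = params, state = state)
}

rmsprop_state <- function(params)
  lapply(params, function(p) list(W = 0 * p$W, b = numeric(length(p$b))))

# stack padded dynamics series into the C x (L*B) batch layout,
# channel 1 = hold times, channel 2 = flight times
stack_dynamics <- function(series_list, L = 100L) {
  B <- length(series_list)
  X <- matrix(0, 2, L * B)
  for (b in seq_len(B)) {
    s <- series_list[[b]]
    if (is.null(s$padded_ht) || length(s$padded_ht) != L)
      stop(sprintf("series %s is not padded to length %d", s$session_id, L))
    cols <- ((b - 1L) * L + 1L):(b * L)
    X[1, cols] <- s$padded_ht
    X[2, cols] <- s$padded_ft
  }
  X
}
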