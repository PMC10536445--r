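# Internal neural-network primitives with hand-derived backward passes.
#
# Activations flow through plain numeric matrices; every *_forward returns
# what its matching *_backward needs. Batches are stacked sample-major:
# row (s - 1) * T + t holds timestep t of sample s.

softmax_rows <- function(s) {
  e <- exp(s - apply(s, 1, max))
  e / rowSums(e)
}

# ---- layer normalization over the feature dimension (per row) ----

ln_forward <- function(x, gamma, beta, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  y <- sweep(sweep(xhat, 2, gamma, `*`), 2, beta, `+`)
  list(y = y, xhat = xhat, inv = inv)
}

ln_backward <- function(dy, cache, gamma) {
  xhat <- cache$xhat
  dxhat <- sweep(dy, 2, gamma, `*`)
  dx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) * cache$inv
  list(dx = dx, dg = colSums(dy * xhat), db = colSums(dy))
}

# ---- inverted dropout ----

dropout_forward <- function(x, p) {
  if (p <= 0) return(list(y = x, mask = NULL))
  mask <- array((stats::runif(length(x)) >= p) / (1 - p), dim = dim(x))
  list(y = x * mask, mask = mask)
}

dropout_backward <- function(dy, mask) {
  if (is.null(mask)) dy else dy * mask
}

# ---- 1-D convolution with "same" padding ----
#
# Index map shared by conv and transposed conv: output position t taps input
# positions (t-1)*stride + j - pad_left for j = 1..k; out-of-range taps read
# (or write) zero padding.

conv_same_idx <- function(L, k, stride) {
  L_out <- as.integer(ceiling(L / stride))
  pad_total <- max((L_out - 1L) * stride + k - L, 0L)
  pad_left <- pad_total %/% 2L
  idx <- outer((seq_len(L_out) - 1L) * stride, seq_len(k) - pad_left, `+`)
  list(L_out = L_out, idx = idx)
}

# x: L x Ci, W: (k*Ci) x Co with row block j holding tap j, b: length Co
conv1d_forward <- function(x, W, b, stride, k) {
  L <- nrow(x)
  Ci <- ncol(x)
  map <- conv_same_idx(L, k, stride)
  P <- matrix(0, map$L_out, k * Ci)
  for (j in seq_len(k)) {
    src <- map$idx[, j]
    ok <- src >= 1L & src <= L
    P[ok, ((j - 1L) * Ci + 1L):(j * Ci)] <- x[src[ok], , drop = FALSE]
  }
  y <- sweep(P %*% W, 2, b, `+`)
  list(y = y, P = P, map = map, L = L, Ci = Ci, k = k)
}

conv1d_backward <- function(dy, cache, W) {
  k <- cache$k
  Ci <- cache$Ci
  dP <- dy %*% t(W)
  dx <- matrix(0, cache$L, Ci)
  for (j in seq_len(k)) {
    src <- cache$map$idx[, j]
    ok <- src >= 1L & src <= cache$L
    dx[src[ok], ] <- dx[src[ok], , drop = FALSE] +
      dP[ok, ((j - 1L) * Ci + 1L):(j * Ci), drop = FALSE]
  }
  list(dx = dx, dW = crossprod(cache$P, dy), db = colSums(dy))
}

# Transposed 1-D convolution: the adjoint of a stride-`stride` same-padded
# conv mapping length L_out -> L_in, so it upsamples L_in -> L_out exactly
# (L_in == ceiling(L_out / stride) is required). W: (k*Co) x Ci.
convt1d_forward <- function(x, W, b, stride, L_out, k) {
  L_in <- nrow(x)
  Co <- nrow(W) %/% k
  map <- conv_same_idx(L_out, k, stride)
  stopifnot(map$L_out == L_in)
  P <- x %*% t(W) # L_in x (k*Co)
  y <- matrix(0, L_out, Co)
  for (j in seq_len(k)) {
    src <- map$idx[, j]
    ok <- src >= 1L & src <= L_out
    y[src[ok], ] <- y[src[ok], , drop = FALSE] +
      P[ok, ((j - 1L) * Co + 1L):(j * Co), drop = FALSE]
  }
  y <- sweep(y, 2, b, `+`)
  list(y = y, x = x, map = map, L_in = L_in, L_out = L_out, k = k, Co = Co)
}

convt1d_backward <- function(dy, cache, W) {
  k <- cache$k
  Co <- cache$Co
  dP <- matrix(0, cache$L_in, k * Co)
  for (j in seq_len(k)) {
    src <- cache$map$idx[, j]
    ok <- src >= 1L & src <= cache$L_out
    dP[ok, ((j - 1L) * Co + 1L):(j * Co)] <- dy[src[ok], , drop = FALSE]
  }
  list(dx = dP %*% W, dW = crossprod(dP, cache$x), db = colSums(dy))
}

# ---- Adam optimizer over a nested parameter list ----

adam_init <- function(params) {
  list(m = zeros_like(params), v = zeros_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- list(p = p, m = m, v = v)
      for (nm in names(p)) {
        r <- walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        out$p[[nm]] <- r$p
        out$m[[nm]] <- r$m
        out$v[[nm]] <- r$v
      }
      return(out)
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  r <- walk(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = t))
}
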