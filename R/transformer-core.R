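# Transformer encoder for per-second sequence labeling of SpO2 windows.
#
# The model lifts the scalar SpO2 value at each second to a d_model-wide
# embedding, injects positional information (none / constant / sinusoidal /
# learnable CAE), passes the sequence through a stack of post-norm encoder
# layers (multi-head self-attention + position-wise feedforward, each with
# residual connection and layer normalization), and emits one apnea
# probability per second through a pointwise sigmoid head.
#
# Everything, including backpropagation, runs on base R matrices; batches
# are stacked sample-major (see nn-ops.R).

#' Model architecture configuration
#'
#' @param n_encoder_layers Number of stacked encoder layers (default 4).
#' @param d_model Embedding width (default 32); must be divisible by
#'   `n_heads`.
#' @param n_heads Attention heads (default 4).
#' @param d_ff Hidden width of the position-wise feedforward sublayer.
#' @param dropout_rate Dropout applied after each sublayer while training.
#' @param sequence_length Window length in seconds the model is trained on
#'   (10-360, default 120).
#' @param pe Positional-encoding variant: `"learnable"` (CAE), `"none"`,
#'   `"constant"`, or `"sinusoidal"`.
#' @param cae A [cae_config()]; required when `pe = "learnable"`.
#' @param sinusoidal_length Minimum length of the sinusoidal table; the
#'   table is built at `max(sequence_length, sinusoidal_length)` and
#'   truncated to the window, so windows longer than the canonical 64-row
#'   table are still covered.
#' @param pe_additive For the learnable variant: add the CAE reconstruction
#'   to the raw input instead of replacing it (default `FALSE`, i.e. the
#'   reconstruction is what the encoder sees).
#' @param head `"per_second"` (sequence labeling, the default) or
#'   `"segment"` (mean-pool then a single sigmoid per window).
#' @return A list of class `model_config`.
#' @export
model_config <- function(n_encoder_layers = 4L, d_model = 32L, n_heads = 4L,
                         d_ff = 64L, dropout_rate = 0.1,
                         sequence_length = 120L,
                         pe = c("learnable", "none", "constant", "sinusoidal"),
                         cae = cae_config(), sinusoidal_length = 64L,
                         pe_additive = FALSE,
                         head = c("per_second", "segment")) {
  pe <- match.arg(pe)
  head <- match.arg(head)
  if (d_model %% n_heads != 0) {
    stop("configuration error: d_model must be divisible by n_heads", call. = FALSE)
  }
  if (n_encoder_layers < 1) stop("need at least one encoder layer", call. = FALSE)
  if (pe == "learnable" && is.null(cae)) {
    stop("configuration error: learnable positional encoding requires a cae_config",
         call. = FALSE)
  }
  structure(list(n_encoder_layers = as.integer(n_encoder_layers),
                 d_model = as.integer(d_model), n_heads = as.integer(n_heads),
                 d_ff = as.integer(d_ff), dropout_rate = dropout_rate,
                 sequence_length = as.integer(sequence_length), pe = pe,
                 cae = if (pe == "learnable") cae else NULL,
                 sinusoidal_length = as.integer(sinusoidal_length),
                 pe_additive = isTRUE(pe_additive), head = head),
            class = "model_config")
}

#' Scaled dot-product attention
#'
#' `Attention(Q, K, V) = softmax(Q K^T / sqrt(d_k)) V`, softmax taken over
#' each query's row so every weight row is a probability distribution over
#' the keys.
#'
#' @param Q,K Query/key matrices sharing depth `d_k`.
#' @param V Value matrix sharing its time extent with `K`.
#' @return A list with `output` (`nrow(Q) x ncol(V)`) and `weights`
#'   (row-stochastic `nrow(Q) x nrow(K)`).
#' @export
scaled_dot_product_attention <- function(Q, K, V) {
  Q <- as.matrix(Q); K <- as.matrix(K); V <- as.matrix(V)
  if (ncol(Q) != ncol(K)) stop("shape error: Q and K depths differ", call. = FALSE)
  if (nrow(K) != nrow(V)) stop("shape error: K and V time extents differ", call. = FALSE)
  A <- softmax_rows(Q %*% t(K) / sqrt(ncol(K)))
  list(output = A %*% V, weights = A)
}

init_attn <- function(d) {
  list(Wq = glorot(d, d), Wk = glorot(d, d), Wv = glorot(d, d),
       Wo = glorot(d, d), bq = numeric(d), bk = numeric(d), bv = numeric(d),
       bo = numeric(d))
}

init_encoder_layer <- function(d, d_ff) {
  list(attn = init_attn(d),
       ln1 = list(g = rep(1, d), b = numeric(d)),
       ffn = list(W1 = glorot(d, d_ff), b1 = numeric(d_ff),
                  W2 = glorot(d_ff, d), b2 = numeric(d)),
       ln2 = list(g = rep(1, d), b = numeric(d)))
}

#' Multi-head self-attention over one sequence
#'
#' Projects `x` to per-head queries, keys and values of depth
#' `d_model / n_heads`, applies scaled dot-product attention per head,
#' concatenates the head outputs and projects back to `d_model`.
#'
#' @param x A `time x d_model` matrix.
#' @param params Projection parameters (`Wq`, `Wk`, `Wv`, `Wo` of shape
#'   `d_model x d_model` plus bias vectors `bq`, `bk`, `bv`, `bo`), e.g.
#'   `model$params$layers[[1]]$attn` of a built model.
#' @param n_heads Number of heads; must divide `d_model`.
#' @return A `time x d_model` matrix.
#' @export
multi_head_attention <- function(x, params, n_heads = 1L) {
  x <- as.matrix(x)
  d <- ncol(x)
  if (d %% n_heads != 0) {
    stop("configuration error: d_model must be divisible by n_heads", call. = FALSE)
  }
  f <- mha_forward(x, params, n_heads, 1L, nrow(x))
  f$y
}

# batched multi-head attention on stacked rows; caches per-head attention
# weights for backprop
mha_forward <- function(H, ap, h, B, T) {
  d <- ncol(H)
  dk <- d %/% h
  Q <- sweep(H %*% ap$Wq, 2, ap$bq, `+`)
  K <- sweep(H %*% ap$Wk, 2, ap$bk, `+`)
  V <- sweep(H %*% ap$Wv, 2, ap$bv, `+`)
  O <- matrix(0, nrow(H), d)
  A <- vector("list", B * h)
  for (s in seq_len(B)) {
    rs <- ((s - 1L) * T + 1L):(s * T)
    for (hh in seq_len(h)) {
      cs <- ((hh - 1L) * dk + 1L):(hh * dk)
      Aw <- softmax_rows(Q[rs, cs, drop = FALSE] %*%
                           t(K[rs, cs, drop = FALSE]) / sqrt(dk))
      O[rs, cs] <- Aw %*% V[rs, cs, drop = FALSE]
      A[[(s - 1L) * h + hh]] <- Aw
    }
  }
  y <- sweep(O %*% ap$Wo, 2, ap$bo, `+`)
  list(y = y, cache = list(H = H, Q = Q, K = K, V = V, O = O, A = A,
                           h = h, B = B, T = T, dk = dk))
}

mha_backward <- function(dy, cache, ap) {
  h <- cache$h; B <- cache$B; T <- cache$T; dk <- cache$dk
  dO <- dy %*% t(ap$Wo)
  dWo <- crossprod(cache$O, dy)
  dbo <- colSums(dy)
  dQ <- matrix(0, nrow(dy), ncol(dy))
  dK <- dQ; dV <- dQ
  for (s in seq_len(B)) {
    rs <- ((s - 1L) * T + 1L):(s * T)
    for (hh in seq_len(h)) {
      cs <- ((hh - 1L) * dk + 1L):(hh * dk)
      Aw <- cache$A[[(s - 1L) * h + hh]]
      dOj <- dO[rs, cs, drop = FALSE]
      dA <- dOj %*% t(cache$V[rs, cs, drop = FALSE])
      dV[rs, cs] <- crossprod(Aw, dOj)
      tmp <- dA * Aw
      dS <- (tmp - Aw * rowSums(tmp)) / sqrt(dk)
      dQ[rs, cs] <- dS %*% cache$K[rs, cs, drop = FALSE]
      dK[rs, cs] <- crossprod(dS, cache$Q[rs, cs, drop = FALSE])
    }
  }
  dH <- dQ %*% t(ap$Wq) + dK %*% t(ap$Wk) + dV %*% t(ap$Wv)
  list(dx = dH,
       g = list(Wq = crossprod(cache$H, dQ), Wk = crossprod(cache$H, dK),
                Wv = crossprod(cache$H, dV), Wo = dWo,
                bq = colSums(dQ), bk = colSums(dK), bv = colSums(dV),
                bo = dbo))
}

encoder_layer_fwd <- function(H, lp, h, B, T, p_drop) {
  mh <- mha_forward(H, lp$attn, h, B, T)
  d1 <- dropout_forward(mh$y, p_drop)
  l1 <- ln_forward(H + d1$y, lp$ln1$g, lp$ln1$b)
  Z1 <- sweep(l1$y %*% lp$ffn$W1, 2, lp$ffn$b1, `+`)
  A1 <- pmax(Z1, 0)
  Z2 <- sweep(A1 %*% lp$ffn$W2, 2, lp$ffn$b2, `+`)
  d2 <- dropout_forward(Z2, p_drop)
  l2 <- ln_forward(l1$y + d2$y, lp$ln2$g, lp$ln2$b)
  list(y = l2$y,
       cache = list(mha = mh$cache, m1 = d1$mask, l1 = l1, l1y = l1$y,
                    A1 = A1, m2 = d2$mask, l2 = l2))
}

encoder_layer_bwd <- function(dy, cache, lp) {
  l2b <- ln_backward(dy, cache$l2, lp$ln2$g)
  dZ2 <- dropout_backward(l2b$dx, cache$m2)
  dA1 <- dZ2 %*% t(lp$ffn$W2)
  dW2 <- crossprod(cache$A1, dZ2)
  db2 <- colSums(dZ2)
  dZ1 <- dA1 * (cache$A1 > 0)
  dW1 <- crossprod(cache$l1y, dZ1)
  db1 <- colSums(dZ1)
  dl1y <- l2b$dx + dZ1 %*% t(lp$ffn$W1)
  l1b <- ln_backward(dl1y, cache$l1, lp$ln1$g)
  dattn <- dropout_backward(l1b$dx, cache$m1)
  mb <- mha_backward(dattn, cache$mha, lp$attn)
  list(dx = l1b$dx + mb$dx,
       g = list(attn = mb$g,
                ln1 = list(g = l1b$dg, b = l1b$db),
                ffn = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2),
                ln2 = list(g = l2b$dg, b = l2b$db)))
}

#' One transformer encoder layer (self-attention + feedforward)
#'
#' Post-norm layout: `x` plus dropout of the multi-head attention output is
#' layer-normalized, then the position-wise feedforward
#' (`d_model -> d_ff -> d_model`, ReLU) is applied with its own residual
#' connection and normalization.
#'
#' @param x A `time x d_model` matrix.
#' @param params One element of `model$params$layers` (attn/ln1/ffn/ln2).
#' @param n_heads Attention heads.
#' @param dropout_rate,training Dropout configuration; with
#'   `training = FALSE` the layer is deterministic.
#' @return A `time x d_model` matrix.
#' @export
encoder_layer_forward <- function(x, params, n_heads = 1L, dropout_rate = 0,
                                  training = FALSE) {
  x <- as.matrix(x)
  p <- if (training) dropout_rate else 0
  encoder_layer_fwd(x, params, n_heads, 1L, nrow(x), p)$y
}

#' Build a per-second apnea detection model
#'
#' Composes the input embedding (pointwise linear lift of the scalar SpO2
#' value to `d_model`), the configured positional stage, the encoder stack
#' and the classification head, with all weights Glorot-initialized.
#'
#' @param config A [model_config()].
#' @param seed Optional integer seed; two builds with the same seed have
#'   identical initial parameters.
#' @return An object of class `spo2_model` with elements `config`, `params`
#'   and `n_params` (total trainable-parameter count).
#' @export
build_model <- function(config = model_config(), seed = NULL) {
  stopifnot(inherits(config, "model_config"))
  with_seed(seed, {
    d <- config$d_model
    params <- list(embed = list(W = glorot(1, d, dim = c(1, d)), b = numeric(d)))
    if (config$pe == "learnable") params$cae <- cae_init(config$cae)
    params$layers <- lapply(seq_len(config$n_encoder_layers),
                            function(i) init_encoder_layer(d, config$d_ff))
    params$head <- list(W = glorot(d, 1, dim = c(d, 1)), b = 0)
    structure(list(config = config, params = params,
                   n_params = count_params(params)),
              class = "spo2_model")
  })
}

#' @export
print.spo2_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<spo2_model: %d encoder layers, d_model %d, %d heads, pe=%s, seq_len %d, %d trainable parameters>\n",
              cfg$n_encoder_layers, cfg$d_model, cfg$n_heads, cfg$pe,
              cfg$sequence_length, x$n_params))
  invisible(x)
}

# Full forward pass over a batch. X: B x T matrix of normalized values.
model_forward <- function(model, X, training = FALSE) {
  cfg <- model$config
  P <- model$params
  X <- as.matrix(X)
  B <- nrow(X)
  T <- ncol(X)
  p_drop <- if (training) cfg$dropout_rate else 0
  cache <- list(B = B, T = T)

  if (cfg$pe == "learnable") {
    r <- matrix(0, B, T)
    cae_caches <- vector("list", B)
    for (s in seq_len(B)) {
      cf <- cae_fwd(X[s, ], cfg$cae, P$cae, p_drop)
      r[s, ] <- cf$y
      cae_caches[[s]] <- cf$cache
    }
    x_in <- if (cfg$pe_additive) X + r else r
    cache$cae <- cae_caches
  } else {
    x_in <- X
  }

  v <- as.vector(t(x_in)) # sample-major stacking
  H <- sweep(cbind(v) %*% P$embed$W, 2, P$embed$b, `+`)
  if (cfg$pe == "constant") {
    H <- H + rep(constant_pe(T), B)
  } else if (cfg$pe == "sinusoidal") {
    tab <- sinusoidal_pe(max(T, cfg$sinusoidal_length), cfg$d_model)
    H <- H + tab[rep(seq_len(T), B), , drop = FALSE]
  }
  cache$v <- v

  layer_caches <- vector("list", cfg$n_encoder_layers)
  for (l in seq_len(cfg$n_encoder_layers)) {
    lf <- encoder_layer_fwd(H, P$layers[[l]], cfg$n_heads, B, T, p_drop)
    H <- lf$y
    layer_caches[[l]] <- lf$cache
  }
  cache$layers <- layer_caches
  cache$H_final <- H

  if (cfg$head == "per_second") {
    logits <- drop(H %*% P$head$W) + P$head$b
    probs <- matrix(sigmoid(logits), B, T, byrow = TRUE)
  } else {
    pool <- rowsum(H, group = rep(seq_len(B), each = T)) / T
    cache$pool <- pool
    logits <- drop(pool %*% P$head$W) + P$head$b
    probs <- sigmoid(logits)
  }
  list(probs = probs, logits = logits, cache = cache)
}

# dlogits: length B*T (per_second, sample-major) or B (segment head)
model_backward <- function(model, dlogits, cache) {
  cfg <- model$config
  P <- model$params
  B <- cache$B
  T <- cache$T
  g <- list()

  if (cfg$head == "per_second") {
    dl <- cbind(dlogits)
    g$head <- list(W = crossprod(cache$H_final, dl), b = sum(dl))
    dH <- dl %*% t(P$head$W)
  } else {
    dl <- cbind(dlogits)
    g$head <- list(W = crossprod(cache$pool, dl), b = sum(dl))
    dpool <- dl %*% t(P$head$W)
    dH <- dpool[rep(seq_len(B), each = T), , drop = FALSE] / T
  }

  g$layers <- vector("list", cfg$n_encoder_layers)
  for (l in rev(seq_len(cfg$n_encoder_layers))) {
    lb <- encoder_layer_bwd(dH, cache$layers[[l]], P$layers[[l]])
    g$layers[[l]] <- lb$g
    dH <- lb$dx
  }

  dv <- drop(dH %*% t(P$embed$W)) # d/dv of v %*% W
  g$embed <- list(W = crossprod(cbind(cache$v), dH), b = colSums(dH))

  if (cfg$pe == "learnable") {
    dr <- matrix(dv, B, T, byrow = TRUE)
    cae_g <- NULL
    for (s in seq_len(B)) {
      cb <- cae_bwd(dr[s, ], cache$cae[[s]], cfg$cae, P$cae)
      cae_g <- if (is.null(cae_g)) cb$grads else tree_add(cae_g, cb$grads)
    }
    g$cae <- cae_g
  }
  # reorder to match params element order for the optimizer walk
  g[names(P)]
}

tree_add <- function(a, b) {
  if (is.list(a)) {
    for (nm in seq_along(a)) a[[nm]] <- tree_add(a[[nm]], b[[nm]])
    a
  } else {
    a + b
  }
}

# forward + loss + gradients for one batch (per-second head).
# Y: B x T 0/1 matrix; w_pos/w_neg optional class weights.
model_loss_backward <- function(model, X, Y, w_pos = 1, w_neg = 1,
                                training = TRUE) {
  fw <- model_forward(model, X, training = training)
  if (model$config$head == "per_second") {
    y <- as.vector(t(Y))
  } else {
    y <- as.integer(apply(Y, 1, max)) # window positive iff any apnea second
  }
  p <- clamp_prob(as.vector(if (is.matrix(fw$probs)) t(fw$probs) else fw$probs))
  w <- ifelse(y == 1, w_pos, w_neg)
  wsum <- sum(w)
  loss <- -sum(w * (y * log(p) + (1 - y) * log(1 - p))) / wsum
  dlogits <- w * (p - y) / wsum
  grads <- model_backward(model, dlogits, fw$cache)
  list(loss = loss, grads = grads, probs = fw$probs)
}

#' Score a batch of segments
#'
#' @param object A trained or freshly built [build_model()] model.
#' @param newdata A `batch x time` matrix of normalized SpO2 values (or a
#'   single numeric vector for one segment).
#' @param ... Unused.
#' @return A `batch x time` matrix of apnea probabilities (per-second head)
#'   or a length-`batch` vector (segment head).
#' @export
predict.spo2_model <- function(object, newdata, ...) {
  if (!is.matrix(newdata)) newdata <- matrix(newdata, nrow = 1)
  model_forward(object, newdata, training = FALSE)$probs
}

#' Per-second apnea probabilities for a whole record
#'
#' Windows the record, scores every window, and reassembles per-second
#' scores in record order. Seconds covered by several overlapping windows
#' are averaged; trailing seconds not covered by any full window are `NA`.
#'
#' @param model A [build_model()] model with the per-second head.
#' @param record A clean [patient_record()].
#' @param window_s Window length; defaults to the model's sequence length.
#' @param stride_s Hop between windows; defaults to `window_s`.
#' @param batch_size Windows scored per forward pass.
#' @return Numeric vector of probabilities aligned to the record's seconds.
#' @export
predict_per_second <- function(model, record, window_s = NULL,
                               stride_s = NULL, batch_size = 256L) {
  if (model$config$head != "per_second") {
    stop("per-second prediction requires the per-second head", call. = FALSE)
  }
  window_s <- window_s %||% model$config$sequence_length
  stride_s <- stride_s %||% window_s
  if (anyNA(record$spo2)) stop("record has missing samples: run drop_missing() first", call. = FALSE)
  n <- length(record$spo2)
  if (n < window_s) {
    stop(sprintf("prediction error: record %s (%d s) is shorter than one %d s window",
                 record$patient_id, n, window_s), call. = FALSE)
  }
  segs <- window_record(record, window_s, stride_s)
  ssum <- numeric(n)
  scount <- numeric(n)
  for (chunk in split(seq_along(segs), ceiling(seq_along(segs) / batch_size))) {
    X <- do.call(rbind, lapply(segs[chunk], function(s) s$values))
    pr <- model_forward(model, X, training = FALSE)$probs
    for (i in seq_along(chunk)) {
      idx <- segs[[chunk[i]]]$start_s + seq_len(window_s)
      ssum[idx] <- ssum[idx] + pr[i, ]
      scount[idx] <- scount[idx] + 1
    }
  }
  out <- ssum / scount
  out[scount == 0] <- NA_real_
  out
}

#' Save / load a model
#'
#' The model (weights + configuration) is serialized with R's native RDS
#' format; a human-readable JSON sidecar of the configuration is written
#' alongside.
#'
#' @param model A [build_model()] model.
#' @param path Destination `.rds` path.
#' @return `path` (save) or the model (load).
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  cfg <- model$config
  cfg$cae <- unclass(cfg$cae)
  jsonlite::write_json(unclass(cfg), paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  readRDS(path)
}
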