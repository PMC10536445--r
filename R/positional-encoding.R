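# The three positional-information mechanisms the model ablates:
# constant normalized-index, sinusoidal, and a learnable encoding built
# from a 1-D convolutional autoencoder (CAE).

#' Constant (normalized-index) positional encoding
#'
#' `PE(i) = i / (n - 1)` for `i = 0, ..., n - 1`; a length-1 sequence maps
#' to `0` (the min == max convention of the normalization).
#'
#' @param n Sequence length, at least 1.
#' @return Numeric vector of length `n` in `[0, 1]`.
#' @export
constant_pe <- function(n) {
  if (!is.numeric(n) || length(n) != 1 || n < 1) {
    stop("`n` must be a single integer >= 1", call. = FALSE)
  }
  if (n == 1) return(0)
  (seq_len(n) - 1) / (n - 1)
}

#' Sinusoidal positional encoding table
#'
#' Builds the `length x d_model` matrix with
#' `PE(pos, 2i) = sin(pos / 10000^(2i / d_model))` and
#' `PE(pos, 2i+1) = cos(pos / 10000^(2i / d_model))`, positions 0-based down
#' the rows. The defaults (64 x 32) are the canonical table size this
#' model family uses for 1 Hz oximetry.
#'
#' @param length Number of positions (rows), at least 1.
#' @param d_model Encoding depth (columns); must be even.
#' @return A `length x d_model` numeric matrix with entries in `[-1, 1]`.
#' @export
sinusoidal_pe <- function(length = 64L, d_model = 32L) {
  stopifnot(length >= 1)
  if (d_model %% 2 != 0) stop("`d_model` must be even", call. = FALSE)
  pos <- seq_len(length) - 1
  i2 <- 2 * (seq_len(d_model / 2) - 1)
  ang <- outer(pos, 1 / 10000^(i2 / d_model))
  pe <- matrix(0, length, d_model)
  pe[, seq(1, d_model, by = 2)] <- sin(ang)
  pe[, seq(2, d_model, by = 2)] <- cos(ang)
  pe
}

#' Add a positional encoding to an input embedding
#'
#' `Z_i = inputE(x_i) + PE(i)`. A vector encoding (the constant variant)
#' broadcasts across the embedding depth; a matrix encoding must match the
#' embedding depth and is truncated to the input's time extent.
#'
#' @param input_embedding A `time x depth` numeric matrix.
#' @param pe A numeric vector (length >= time) or matrix (rows >= time,
#'   columns == depth).
#' @return A `time x depth` matrix.
#' @export
additive_combine <- function(input_embedding, pe) {
  x <- as.matrix(input_embedding)
  n <- nrow(x)
  if (is.matrix(pe)) {
    if (ncol(pe) != ncol(x)) {
      stop("shape error: encoding depth does not match embedding depth", call. = FALSE)
    }
    if (nrow(pe) < n) stop("shape error: encoding shorter than input", call. = FALSE)
    x + pe[seq_len(n), , drop = FALSE]
  } else {
    if (length(pe) < n) stop("shape error: encoding shorter than input", call. = FALSE)
    x + pe[seq_len(n)] # recycles down columns: broadcast across depth
  }
}

#' Configuration of the learnable convolutional-autoencoder encoding
#'
#' The encoder is a stack of strided convolutions (kernel 7, stride 2,
#' ReLU, dropout in between); the decoder mirrors it with transposed
#' convolutions (ReLU) and a final kernel-7 stride-1 convolution that emits
#' a reconstruction of the same length as the input. Kernel size 7 and the
#' strides are fixed design points; layer depth and filter counts are
#' configurable.
#'
#' @param filters Encoder filter counts, one per downsampling layer.
#' @param kernel_size,down_stride,final_kernel,final_stride Convolution
#'   geometry (defaults 7/2/7/1).
#' @param dropout_rate Dropout probability applied between encoder layers
#'   during training.
#' @return A list of class `cae_config`.
#' @export
cae_config <- function(filters = c(32L, 16L), kernel_size = 7L,
                       down_stride = 2L, final_kernel = 7L, final_stride = 1L,
                       dropout_rate = 0.1) {
  stopifnot(length(filters) >= 1, all(filters >= 1), kernel_size >= 1,
            down_stride >= 1, dropout_rate >= 0, dropout_rate < 1)
  structure(list(filters = as.integer(filters),
                 kernel_size = as.integer(kernel_size),
                 down_stride = as.integer(down_stride),
                 final_kernel = as.integer(final_kernel),
                 final_stride = as.integer(final_stride),
                 dropout_rate = dropout_rate),
            class = "cae_config")
}

#' Bottleneck time extent of the autoencoder
#'
#' Each stride-`s` same-padded convolution divides the length by `s`,
#' rounding up; the latent length after all encoder layers is the iterated
#' ceiling.
#'
#' @param input_length Input sequence length.
#' @param config A [cae_config()].
#' @return Integer latent length.
#' @export
cae_latent_length <- function(input_length, config = cae_config()) {
  l <- input_length
  for (i in seq_along(config$filters)) l <- ceiling(l / config$down_stride)
  as.integer(l)
}

# Decoder channel plan: transposed convs walk back through the encoder
# filters, then the final conv maps to 1 channel.
cae_channels <- function(config) {
  f <- config$filters
  enc_in <- c(1L, f[-length(f)])
  dec_out <- rev(f)
  dec_in <- c(f[length(f)], dec_out[-length(dec_out)])
  list(enc_in = enc_in, enc_out = f, dec_in = dec_in, dec_out = dec_out)
}

#' Initialize CAE weights
#'
#' @param config A [cae_config()].
#' @param seed Optional integer seed for reproducible initialization.
#' @return A nested list of weight arrays (Glorot-uniform, zero biases).
#' @export
cae_init <- function(config = cae_config(), seed = NULL) {
  with_seed(seed, {
    ch <- cae_channels(config)
    k <- config$kernel_size
    down <- lapply(seq_along(ch$enc_out), function(i) {
      list(W = glorot(k * ch$enc_in[i], k * ch$enc_out[i],
                      dim = c(k * ch$enc_in[i], ch$enc_out[i])),
           b = numeric(ch$enc_out[i]))
    })
    up <- lapply(seq_along(ch$dec_out), function(i) {
      list(W = glorot(k * ch$dec_in[i], k * ch$dec_out[i],
                      dim = c(k * ch$dec_out[i], ch$dec_in[i])),
           b = numeric(ch$dec_out[i]))
    })
    fin <- list(W = glorot(config$final_kernel * ch$dec_out[length(ch$dec_out)],
                           config$final_kernel,
                           dim = c(config$final_kernel * ch$dec_out[length(ch$dec_out)], 1L)),
                b = numeric(1L))
    list(down = down, up = up, fin = fin)
  })
}

# forward with caches for backprop; x is a numeric vector (one sequence)
cae_fwd <- function(x, config, weights, p_drop = 0) {
  k <- config$kernel_size
  a <- cbind(as.numeric(x))
  lens <- integer(0)
  down_caches <- list()
  for (i in seq_along(weights$down)) {
    lens <- c(lens, nrow(a))
    cv <- conv1d_forward(a, weights$down[[i]]$W, weights$down[[i]]$b,
                         config$down_stride, k)
    r <- pmax(cv$y, 0)
    dp <- dropout_forward(r, p_drop)
    down_caches[[i]] <- list(conv = cv, relu = r > 0, mask = dp$mask)
    a <- dp$y
  }
  up_caches <- list()
  n_down <- length(weights$down)
  for (i in seq_along(weights$up)) {
    target <- lens[n_down - i + 1L]
    ct <- convt1d_forward(a, weights$up[[i]]$W, weights$up[[i]]$b,
                          config$down_stride, target, k)
    a <- pmax(ct$y, 0)
    up_caches[[i]] <- list(conv = ct, relu = ct$y > 0)
  }
  fv <- conv1d_forward(a, weights$fin$W, weights$fin$b,
                       config$final_stride, config$final_kernel)
  list(y = as.numeric(fv$y),
       cache = list(down = down_caches, up = up_caches, fin = fv))
}

cae_bwd <- function(dy, cache, config, weights) {
  g <- list(down = vector("list", length(weights$down)),
            up = vector("list", length(weights$up)))
  fb <- conv1d_backward(cbind(as.numeric(dy)), cache$fin, weights$fin$W)
  g$fin <- list(W = fb$dW, b = fb$db)
  da <- fb$dx
  for (i in rev(seq_along(weights$up))) {
    dz <- da * cache$up[[i]]$relu
    cb <- convt1d_backward(dz, cache$up[[i]]$conv, weights$up[[i]]$W)
    g$up[[i]] <- list(W = cb$dW, b = cb$db)
    da <- cb$dx
  }
  for (i in rev(seq_along(weights$down))) {
    dz <- dropout_backward(da, cache$down[[i]]$mask) * cache$down[[i]]$relu
    cb <- conv1d_backward(dz, cache$down[[i]]$conv, weights$down[[i]]$W)
    g$down[[i]] <- list(W = cb$dW, b = cb$db)
    da <- cb$dx
  }
  list(grads = g, dx = as.numeric(da))
}

#' Run the convolutional autoencoder over one sequence
#'
#' Reconstructs a 1-D sequence of exactly the input length. With
#' `training = FALSE` (no dropout) the output is deterministic.
#'
#' @param segment_values Numeric vector (one normalized segment).
#' @param config A [cae_config()].
#' @param weights Weights from [cae_init()] (or as trained inside a model).
#' @param training Apply dropout between encoder layers.
#' @return Numeric vector of `length(segment_values)`.
#' @export
cae_forward <- function(segment_values, config = cae_config(),
                        weights = cae_init(config), training = FALSE) {
  n_down <- length(config$filters)
  if (length(segment_values) < config$down_stride^n_down) {
    stop("configuration error: sequence too short for the strided encoder", call. = FALSE)
  }
  p <- if (training) config$dropout_rate else 0
  cae_fwd(segment_values, config, weights, p)$y
}
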