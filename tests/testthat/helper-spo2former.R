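# Shared fixtures and independent oracles for the test suite.

# Brute-force pairwise ROC AUC: probability a random positive outscores a
# random negative, ties counted one half. Deliberately O(n_pos * n_neg) and
# independent of the package's implementation.
pairwise_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# A tiny model configuration that exercises every component quickly.
tiny_config <- function(pe = "none", T_ = 12L, ...) {
  model_config(n_encoder_layers = 2L, d_model = 8L, n_heads = 2L, d_ff = 12L,
               dropout_rate = 0, sequence_length = T_, pe = pe,
               cae = cae_config(filters = c(4L, 3L), dropout_rate = 0), ...)
}

# Hand-rolled segments for a purely positional task: the signal contains a
# dip at a position that carries no label information, while the label
# depends on the timestep index alone. Order-blind models cannot beat
# chance here.
make_positional_segments <- function(n, T_ = 60L, boundary = 40L, seed = 1L) {
  spo2former:::with_seed(seed, lapply(seq_len(n), function(i) {
    v <- 0.8 + stats::rnorm(T_, 0, 0.05)
    s0 <- sample(T_ - 10L, 1L)
    v[s0:(s0 + 9L)] <- v[s0:(s0 + 9L)] - 0.5
    list(values = minmax_normalize(v),
         labels = as.integer(seq_len(T_) > boundary),
         patient_id = "POS", start_s = 0L, length_s = T_)
  }))
}

# Toy separable per-second dataset: apnea seconds carry values near 0,
# normal seconds values near 1.
make_separable_segments <- function(n, T_ = 20L, seed = 1L) {
  spo2former:::with_seed(seed, lapply(seq_len(n), function(i) {
    lab <- as.integer(stats::runif(T_) < 0.3)
    v <- ifelse(lab == 1, stats::runif(T_, 0, 0.2), stats::runif(T_, 0.8, 1))
    list(values = v, labels = lab, patient_id = "TOY", start_s = 0L,
         length_s = T_)
  }))
}
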