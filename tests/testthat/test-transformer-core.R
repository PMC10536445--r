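test_that("scaled dot-product attention handles the degenerate and worked cases", {
  # softmax of a singleton
  r <- scaled_dot_product_attention(matrix(1, 1, 2), matrix(2, 1, 2),
                                    matrix(c(5, 7), 1, 2))
  expect_equal(r$weights, matrix(1, 1, 1))
  expect_equal(r$output, matrix(c(5, 7), 1, 2))

  # identical keys -> uniform weights, rows equal the column means of V
  Q <- matrix(runif(6), 3, 2)
  K <- matrix(rep(c(0.3, 0.7), each = 3), 3, 2)
  V <- matrix(runif(6), 3, 2)
  r2 <- scaled_dot_product_attention(Q, K, V)
  expect_equal(r2$weights, matrix(1 / 3, 3, 3))
  expect_equal(r2$output, matrix(colMeans(V), 3, 2, byrow = TRUE))

  # hand-derived 2x2 example
  r3 <- scaled_dot_product_attention(diag(2), diag(2),
                                     matrix(c(1, 3, 2, 4), 2, 2))
  expect_equal(r3$output, matrix(c(1.6604, 2.3396, 2.6604, 3.3396), 2, 2),
               tolerance = 1e-4)

  expect_error(scaled_dot_product_attention(matrix(0, 2, 3), matrix(0, 2, 2),
                                            matrix(0, 2, 2)), "shape")
})

test_that("attention weights are convex combinations and shift-invariant", {
  spo2former:::with_seed(13, {
    for (i in 1:100) {
      t1 <- sample(2:8, 1); t2 <- sample(2:8, 1); d <- sample(2:6, 1)
      Q <- matrix(rnorm(t1 * d), t1, d)
      K <- matrix(rnorm(t2 * d), t2, d)
      V <- matrix(rnorm(t2 * 3), t2, 3)
      r <- scaled_dot_product_attention(Q, K, V)
      expect_true(all(r$weights >= 0))
      expect_equal(rowSums(r$weights), rep(1, t1), tolerance = 1e-6)
      lo <- apply(V, 2, min); hi <- apply(V, 2, max)
      expect_true(all(sweep(r$output, 2, lo, `-`) >= -1e-12))
      expect_true(all(sweep(r$output, 2, hi, `-`) <= 1e-12))
    }
    # adding a constant to every logit row leaves the weights unchanged
    Q <- matrix(rnorm(8), 4, 2); K <- matrix(rnorm(8), 4, 2)
    V <- matrix(rnorm(8), 4, 2)
    a <- scaled_dot_product_attention(Q, K, V)
    shift <- 3.7 * sqrt(2)                    # constant row offset in QK^T
    b <- spo2former:::softmax_rows(Q %*% t(K) / sqrt(2) + shift)
    expect_equal(a$weights, b, tolerance = 1e-12)
  })
})

test_that("multi-head attention reduces to single-head and respects shapes", {
  d <- 6
  x <- matrix(rnorm(5 * d), 5, d)
  id <- list(Wq = diag(d), Wk = diag(d), Wv = diag(d), Wo = diag(d),
             bq = numeric(d), bk = numeric(d), bv = numeric(d), bo = numeric(d))
  expect_equal(multi_head_attention(x, id, n_heads = 1),
               scaled_dot_product_attention(x, x, x)$output)

  p <- spo2former:::with_seed(3, spo2former:::init_attn(d))
  p$Wo <- p$Wo * 0
  out <- multi_head_attention(x, p, n_heads = 2)
  expect_equal(out, matrix(0, 5, d))

  p2 <- spo2former:::with_seed(4, spo2former:::init_attn(d))
  expect_equal(dim(multi_head_attention(x, p2, n_heads = 3)), dim(x))
  expect_error(multi_head_attention(x, p2, n_heads = 4), "divisible")
})

test_that("encoder layers keep shape, are deterministic, and are permutation-equivariant", {
  d <- 8
  lp <- spo2former:::with_seed(5, spo2former:::init_encoder_layer(d, 12))
  x <- matrix(rnorm(10 * d), 10, d)
  y1 <- encoder_layer_forward(x, lp, n_heads = 2)
  expect_equal(dim(y1), dim(x))
  expect_identical(y1, encoder_layer_forward(x, lp, n_heads = 2))

  perm <- sample(10)
  y2 <- encoder_layer_forward(x[perm, ], lp, n_heads = 2)
  expect_equal(y2, y1[perm, ], tolerance = 1e-5)
})

test_that("build_model contracts: shapes, probability range, seeding, parameter counts", {
  cfg <- model_config(sequence_length = 120)
  m <- build_model(cfg, seed = 1)
  X <- matrix(runif(32 * 120), 32, 120)
  pr <- predict(m, X)
  expect_equal(dim(pr), c(32, 120))
  expect_true(all(pr > 0 & pr < 1))

  m2 <- build_model(cfg, seed = 1)
  expect_identical(m$params, m2$params)

  # parameter count is independent of sequence length for fixed tables
  for (pe in c("none", "constant", "sinusoidal")) {
    n60 <- build_model(model_config(pe = pe, sequence_length = 60), seed = 2)$n_params
    n360 <- build_model(model_config(pe = pe, sequence_length = 360), seed = 2)$n_params
    expect_identical(n60, n360)
  }
  expect_error(model_config(d_model = 30, n_heads = 4), "divisible")
  expect_error(model_config(pe = "learnable", cae = NULL), "cae_config")
})

test_that("full model with pe=none is permutation-equivariant; positional variants break it", {
  T_ <- 16L
  X <- matrix(runif(3 * T_), 3, T_)
  perm <- spo2former:::with_seed(8, sample(T_))
  dev <- function(pe) {
    m <- build_model(tiny_config(pe = pe, T_ = T_), seed = 9)
    a <- predict(m, X)
    b <- predict(m, X[, perm, drop = FALSE])
    max(abs(b - a[, perm, drop = FALSE]))
  }
  expect_lt(dev("none"), 1e-5)
  expect_gt(dev("constant"), 1e-5)
  expect_gt(dev("sinusoidal"), 1e-5)
})

test_that("analytic gradients agree with finite differences through every component", {
  ns <- asNamespace("spo2former")
  m <- build_model(tiny_config(pe = "learnable"), seed = 7)
  spo2former:::with_seed(42, {
    X <- matrix(runif(3 * 12), 3, 12)
    Y <- matrix(rbinom(36, 1, 0.3), 3, 12)
  })
  fb <- ns$model_loss_backward(m, X, Y, training = FALSE)

  paths <- list()
  walk <- function(x, path) {
    if (is.list(x)) {
      for (nm in names(x)) walk(x[[nm]], c(path, nm))
    } else {
      paths[[length(paths) + 1]] <<- path
    }
  }
  walk(m$params, character(0))
  get_p <- function(tree, path) Reduce(`[[`, path, tree)
  set_p <- function(tree, path, val) {
    if (length(path) == 1) tree[[path]] <- val
    else tree[[path[1]]] <- set_p(tree[[path[1]]], path[-1], val)
    tree
  }

  eps <- 1e-5
  spo2former:::with_seed(11, {
    for (path in paths) {
      arr <- get_p(m$params, path)
      g <- get_p(fb$grads, path)
      for (i in sample(length(arr), min(2, length(arr)))) {
        m2 <- m
        a <- arr; a[i] <- arr[i] + eps
        m2$params <- set_p(m2$params, path, a)
        up <- ns$model_loss_backward(m2, X, Y, training = FALSE)$loss
        a[i] <- arr[i] - eps
        m2$params <- set_p(m2$params, path, a)
        dn <- ns$model_loss_backward(m2, X, Y, training = FALSE)$loss
        fd <- (up - dn) / (2 * eps)
        expect_equal(g[i], fd, tolerance = 1e-3,
                     label = paste(c(path, i), collapse = "/"))
      }
    }
  })
  # gradient flow: the classification loss reaches the CAE weights
  expect_gt(sqrt(sum(unlist(fb$grads$cae)^2)), 0)
})

test_that("predict_per_second tiles, averages overlaps, and flags unscored seconds", {
  m <- build_model(tiny_config(pe = "learnable", T_ = 20L), seed = 3)
  rec <- simulate_record(sim_params(duration_s = 130, target_ahi = 0, seed = 2))

  s1 <- predict_per_second(m, rec, window_s = 20, stride_s = 20)
  expect_length(s1, 130)
  expect_equal(sum(!is.na(s1)), 120) # trailing 10 s uncovered
  expect_identical(s1, predict_per_second(m, rec, window_s = 20, stride_s = 20))

  # overlap-count bookkeeping oracle: score each window independently
  s2 <- predict_per_second(m, rec, window_s = 20, stride_s = 10)
  segs <- window_record(rec, 20, 10)
  ssum <- numeric(130); cnt <- numeric(130)
  for (sg in segs) {
    idx <- sg$start_s + 1:20
    ssum[idx] <- ssum[idx] + as.vector(predict(m, sg$values))
    cnt[idx] <- cnt[idx] + 1
  }
  oracle <- ssum / cnt; oracle[cnt == 0] <- NA
  expect_equal(s2, oracle)
  expect_true(all(cnt[11:120] == 2)) # interior seconds averaged over two windows

  expect_error(predict_per_second(m, rec, window_s = 200), "shorter")
})

test_that("models survive a save/load round trip", {
  m <- build_model(tiny_config(pe = "sinusoidal"), seed = 6)
  path <- file.path(withr::local_tempdir(), "model.rds")
  save_model(m, path)
  expect_true(file.exists(paste0(path, ".json")))
  m2 <- load_model(path)
  X <- matrix(runif(2 * 12), 2, 12)
  expect_identical(predict(m, X), predict(m2, X))
})
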