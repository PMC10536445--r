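test_that("kfold_partition yields near-equal disjoint covering folds, deterministically", {
  folds <- kfold_partition(100, k = 5, seed = 1)
  expect_length(folds, 5)
  vals <- lapply(folds, `[[`, "val")
  expect_equal(vapply(vals, length, integer(1)), rep(20L, 5))
  expect_setequal(unlist(vals), 1:100)
  for (f in folds) {
    expect_length(intersect(f$train, f$val), 0)
    expect_setequal(c(f$train, f$val), 1:100)
  }

  sizes <- sort(vapply(kfold_partition(101, 5, seed = 2), function(f) length(f$val),
                       integer(1)), decreasing = TRUE)
  expect_equal(sizes, c(21L, 20L, 20L, 20L, 20L))

  expect_identical(kfold_partition(50, 5, seed = 9), kfold_partition(50, 5, seed = 9))
  expect_error(kfold_partition(3, 5), "fewer items")
})

test_that("confusion_from_scores tallies with apnea positive and >= threshold", {
  cm <- confusion_from_scores(c(1, 1, 0, 0), c(0.9, 0.2, 0.8, 0.1), 0.5)
  expect_equal(unclass(cm)[c("tp", "fn", "fp", "tn")],
               list(tp = 1L, fn = 1L, fp = 1L, tn = 1L), ignore_attr = TRUE)

  cm0 <- confusion_from_scores(rep(0, 5), rep(0, 5), 0.5)
  expect_equal(cm0$tn, 5)
  expect_equal(cm0$tp + cm0$fp + cm0$fn, 0)

  cmt <- confusion_from_scores(c(0, 1, 0), c(0, 0.3, 0.9), 0)
  expect_equal(cmt$tp + cmt$fp, 3) # score >= 0 predicts everything positive

  expect_error(confusion_from_scores(c(0, 1), c(0.5)), "same length")
})

test_that("compute_metrics reproduces the worked example and its conventions", {
  m <- compute_metrics(list(tp = 3, fp = 1, fn = 1, tn = 5))
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$recall, 0.75)
  expect_equal(m$precision, 0.75)
  expect_equal(m$f1, 0.75)
  expect_equal(m$specificity, 5 / 6)

  perfect <- compute_metrics(list(tp = 4, fp = 0, fn = 0, tn = 6))
  expect_equal(unlist(perfect[c("accuracy", "recall", "precision",
                                "specificity", "f1")]),
               rep(1, 5), ignore_attr = TRUE)

  degenerate <- compute_metrics(list(tp = 0, fp = 0, fn = 3, tn = 2))
  expect_equal(degenerate$recall, 0)
  expect_equal(degenerate$precision, 0)
  expect_equal(degenerate$f1, 0)

  expect_error(compute_metrics(list(tp = 0, fp = 0, fn = 0, tn = 0)), "empty")
})

test_that("metric identities hold on random confusion matrices", {
  spo2former:::with_seed(17, {
    for (i in 1:30) {
      cm <- list(tp = sample(0:40, 1), fp = sample(0:40, 1),
                 fn = sample(0:40, 1), tn = sample(0:40, 1))
      if (sum(unlist(cm)) == 0) next
      m <- compute_metrics(cm)
      P <- cm$tp + cm$fn; N <- cm$tn + cm$fp
      if (P > 0 && N > 0) {
        expect_equal(m$accuracy, (m$recall * P + m$specificity * N) / (P + N))
      }
      if (m$precision + m$recall > 0) {
        hm <- 2 * m$precision * m$recall / (m$precision + m$recall)
        expect_equal(m$f1, hm)
        expect_lte(m$f1, (m$precision + m$recall) / 2 + 1e-12)
      }
    }
  })
})

test_that("roc_auc matches the pairwise oracle, handles ties, and rejects one-class input", {
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1)
  expect_equal(roc_auc(c(0, 1, 0, 1), rep(0.5, 4)), 0.5)
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8)), 0.75)
  expect_error(roc_auc(c(1, 1), c(0.2, 0.4)), "single class")

  spo2former:::with_seed(23, {
    for (i in 1:60) {
      n <- sample(4:50, 1)
      lab <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
      sc <- round(runif(n), sample(1:3, 1)) # coarse rounding forces ties
      expect_equal(roc_auc(lab, sc), pairwise_auc(lab, sc))
    }
    # invariance under strictly increasing transforms
    lab <- sample(0:1, 40, replace = TRUE, prob = c(0.7, 0.3))
    lab[1:2] <- c(0, 1)
    sc <- runif(40)
    expect_equal(roc_auc(lab, sc), roc_auc(lab, qlogis(sc * 0.98 + 0.01)))
    expect_equal(roc_auc(lab, sc), roc_auc(lab, sc^3 + 2))
  })
})

test_that("extract_events applies run-length, minimum-duration and merge rules", {
  ev <- extract_events(c(rep(0, 5), rep(1, 12), rep(0, 3)))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$start_s, 5)
  expect_equal(ev$duration_s, 12)

  expect_equal(nrow(extract_events(rep(c(0, 1), c(3, 5)), min_duration_s = 10)), 0)

  two <- extract_events(c(rep(1, 11), rep(0, 100), rep(1, 15)))
  expect_equal(two$duration_s, c(11, 15))
  expect_equal(two$start_s, c(0, 111))

  merged <- extract_events(c(rep(1, 6), 0, 0, rep(1, 6)), min_duration_s = 10,
                           merge_gap_s = 2)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$duration_s, 14)
})

test_that("event extraction on ground-truth labels recovers the simulated event list", {
  for (s in c(3, 14)) {
    r <- simulate_record(sim_params(duration_s = 7200, target_ahi = 25, seed = s))
    ev <- extract_events(r$labels, min_duration_s = min(r$events$duration_s))
    expect_equal(ev$start_s, r$events$start_s)
    expect_equal(ev$duration_s, r$events$duration_s)
  }
})

test_that("estimate_ahi divides events by hours", {
  ev5 <- data.frame(start_s = 1:5, duration_s = rep(10, 5), kind = "apnea")
  expect_equal(estimate_ahi(ev5, 1), 5)
  expect_equal(estimate_ahi(ev5[0, ], 2), 0)
  expect_equal(estimate_ahi(rbind(ev5, ev5[1, ]), 0.5), 12)
  expect_error(estimate_ahi(ev5, 0), "positive")
})

test_that("training learns a separable toy task and is seed-reproducible", {
  tr <- make_separable_segments(60, T_ = 20, seed = 5)
  va <- make_separable_segments(20, T_ = 20, seed = 6)
  m <- build_model(tiny_config(pe = "none", T_ = 20L), seed = 2)
  tc <- train_config(initial_lr = 1e-2, max_epochs = 4, batch_size = 16, seed = 3)
  fit <- train_model(m, tr, va, tc)
  h <- fit$history
  expect_equal(nrow(h), 4)
  expect_lt(h$train_loss[4], h$train_loss[1])
  expect_gt(h$val_acc[4], 0.85)

  fit2 <- train_model(build_model(tiny_config(pe = "none", T_ = 20L), seed = 2),
                      tr, va, tc)
  expect_identical(tail(fit$history$val_loss, 1), tail(fit2$history$val_loss, 1))

  expect_error(train_model(m, list(), va, tc), "empty training set")
})

test_that("plateau schedule multiplies the learning rate by exactly the decay factor", {
  # constant inputs whose train and validation base rates disagree: fitting
  # the training labels cannot improve the validation loss, so it plateaus
  # and the schedule must fire
  seg <- function(rate) {
    list(values = rep(0.5, 20),
         labels = rep(c(1L, 0L), c(round(20 * rate), 20 - round(20 * rate))),
         patient_id = "C", start_s = 0L, length_s = 20L)
  }
  m <- build_model(tiny_config(pe = "none", T_ = 20L), seed = 1)
  tc <- train_config(initial_lr = 1e-5, max_epochs = 6,
                     plateau_patience_epochs = 2, seed = 1)
  fit <- train_model(m, rep(list(seg(0.65)), 15), rep(list(seg(0.35)), 5), tc)
  lr <- fit$history$lr
  expect_true(all(diff(lr) <= 0))
  drops <- which(diff(lr) < 0)
  expect_gt(length(drops), 0)
  for (d in drops) expect_equal(lr[d + 1] / lr[d], 0.2)
  expect_equal(lr[drops[1] + 1], 1e-5 * 0.2)
})

test_that("per_patient_report aggregates consistently and applies the AHI >= 5 rule", {
  m <- build_model(tiny_config(pe = "none", T_ = 20L), seed = 2)
  recs <- list(
    simulate_record(sim_params(duration_s = 400, target_ahi = 0, seed = 1), "A"),
    simulate_record(sim_params(duration_s = 400, target_ahi = 30, seed = 2), "B"),
    patient_record("SHORT", c(96, 97, 95), c(0L, 0L, 0L))
  )
  rep_ <- suppressWarnings(per_patient_report(m, recs, window_s = 20))
  expect_equal(nrow(rep_), 3)
  expect_true(rep_$skipped[3])
  expect_false(any(rep_$skipped[1:2]))
  expect_equal(rep_$osa_true[1:2], c(FALSE, TRUE))

  # per-second metrics equal compute_metrics of the patient's own confusion
  sc <- predict_per_second(m, recs[[2]], window_s = 20)
  ok <- !is.na(sc)
  mm <- compute_metrics(confusion_from_scores(recs[[2]]$labels[ok], sc[ok], 0.5))
  expect_equal(rep_$accuracy[2], mm$accuracy)
  expect_equal(rep_$f1[2], mm$f1)
  expect_equal(rep_$osa_predicted[1:2], rep_$estimated_ahi[1:2] >= 5)
})
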