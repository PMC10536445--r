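# Training protocol, per-second metrics, and per-patient OSA screening.

#' Training configuration
#'
#' Defaults are the canonical protocol for this model family: Adam with an initial learning
#' rate of 1e-5, batches of 32 windows, and a reduce-on-plateau schedule
#' that multiplies the learning rate by 0.2 when the validation loss stops
#' improving.
#'
#' @param batch_size Windows per optimization step (default 32).
#' @param initial_lr Initial Adam learning rate (default `1e-5`).
#' @param lr_plateau_factor Multiplier applied to the learning rate on a
#'   plateau, in (0, 1) (default 0.2).
#' @param plateau_patience_epochs Epochs without validation-loss improvement
#'   before the learning rate is reduced.
#' @param plateau_min_delta Minimum decrease in validation loss that counts
#'   as an improvement.
#' @param max_epochs Training epochs (default 40).
#' @param k_folds Folds for [kfold_partition()] (default 5).
#' @param holdout_fraction Fraction kept aside for final testing.
#' @param class_weighting `"off"` (unweighted loss, the default) or
#'   `"balanced"` (inverse-frequency weights on the training labels).
#' @param threshold Decision threshold on the apnea probability.
#' @param seed Integer seed covering shuffling and dropout.
#' @return A list of class `train_config`.
#' @export
train_config <- function(batch_size = 32L, initial_lr = 1e-5,
                         lr_plateau_factor = 0.2,
                         plateau_patience_epochs = 5L,
                         plateau_min_delta = 1e-4,
                         max_epochs = 40L, k_folds = 5L,
                         holdout_fraction = 0.2,
                         class_weighting = c("off", "balanced"),
                         threshold = 0.5, seed = 1L) {
  class_weighting <- match.arg(class_weighting)
  stopifnot(batch_size >= 1, lr_plateau_factor > 0, lr_plateau_factor < 1,
            k_folds >= 2, holdout_fraction > 0, holdout_fraction < 1,
            max_epochs >= 1)
  structure(list(batch_size = as.integer(batch_size), initial_lr = initial_lr,
                 lr_plateau_factor = lr_plateau_factor,
                 plateau_patience_epochs = as.integer(plateau_patience_epochs),
                 plateau_min_delta = plateau_min_delta,
                 max_epochs = as.integer(max_epochs),
                 k_folds = as.integer(k_folds),
                 holdout_fraction = holdout_fraction,
                 class_weighting = class_weighting, threshold = threshold,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' K-fold cross-validation partition
#'
#' @param items An integer count, or a vector/list whose length defines the
#'   collection size.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed; the partition is deterministic given the seed.
#' @return A list of `k` elements, each `list(train = idx, val = idx)`;
#'   validation folds are disjoint, cover all indices, and differ in size
#'   by at most one.
#' @export
kfold_partition <- function(items, k = 5L, seed = 1L) {
  n <- if (length(items) == 1 && is.numeric(items)) as.integer(items) else length(items)
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  if (n < k) stop("partition error: fewer items than folds", call. = FALSE)
  with_seed(seed, {
    ord <- sample.int(n)
    fold <- rep(seq_len(k), length.out = n)
    lapply(seq_len(k), function(f) {
      val <- sort(ord[fold == f])
      list(train = setdiff(seq_len(n), val), val = val)
    })
  })
}

#' Train a model with Adam and plateau learning-rate decay
#'
#' Minimizes per-timestep binary cross-entropy over shuffled batches,
#' monitors the validation loss each epoch, and multiplies the learning
#' rate by `lr_plateau_factor` whenever it fails to improve by at least
#' `plateau_min_delta` for `plateau_patience_epochs` consecutive epochs.
#' Fully seeded: identical seeds and data give identical results.
#'
#' @param model A [build_model()] model.
#' @param train_segments,val_segments Lists of segments from
#'   [window_record()], all of the model's sequence length.
#' @param config A [train_config()].
#' @param verbose Print one line per epoch.
#' @return A list with `model` (trained) and `history` (data frame with
#'   per-epoch `epoch`, `train_loss`, `train_acc`, `val_loss`, `val_acc`,
#'   `lr`).
#' @export
train_model <- function(model, train_segments, val_segments,
                        config = train_config(), verbose = FALSE) {
  if (length(train_segments) == 0) stop("training error: empty training set", call. = FALSE)
  tr <- segments_to_matrices(train_segments)
  va <- segments_to_matrices(val_segments)
  if (ncol(tr$X) != model$config$sequence_length) {
    stop("segments do not match the model's sequence length", call. = FALSE)
  }
  n <- nrow(tr$X)
  w_pos <- w_neg <- 1
  if (config$class_weighting == "balanced") {
    n_pos <- sum(tr$Y)
    n_tot <- length(tr$Y)
    if (n_pos > 0 && n_pos < n_tot) {
      w_pos <- n_tot / (2 * n_pos)
      w_neg <- n_tot / (2 * (n_tot - n_pos))
    }
  }
  state <- adam_init(model$params)
  lr <- config$initial_lr
  best <- Inf
  wait <- 0L
  hist <- vector("list", config$max_epochs)

  with_seed(config$seed, {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      tl <- 0
      tacc <- 0
      for (b in batches) {
        fb <- model_loss_backward(model, tr$X[b, , drop = FALSE],
                                  tr$Y[b, , drop = FALSE], w_pos, w_neg)
        st <- adam_step(model$params, fb$grads, state, lr)
        model$params <- st$params
        state <- st$state
        tl <- tl + fb$loss * length(b)
        yb <- if (model$config$head == "per_second") tr$Y[b, , drop = FALSE]
              else apply(tr$Y[b, , drop = FALSE], 1, max)
        tacc <- tacc + mean((fb$probs >= 0.5) == (yb == 1)) * length(b)
      }
      ev <- evaluate_loss(model, va$X, va$Y, w_pos, w_neg)
      hist[[epoch]] <- data.frame(epoch = epoch, train_loss = tl / n,
                                  train_acc = tacc / n, val_loss = ev$loss,
                                  val_acc = ev$acc, lr = lr)
      if (verbose) {
        message(sprintf("epoch %d: train %.4f val %.4f (acc %.3f) lr %g",
                        epoch, tl / n, ev$loss, ev$acc, lr))
      }
      if (ev$loss < best - config$plateau_min_delta) {
        best <- ev$loss
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$plateau_patience_epochs) {
          lr <- lr * config$lr_plateau_factor
          wait <- 0L
        }
      }
    }
  })
  list(model = model, history = do.call(rbind, hist))
}

evaluate_loss <- function(model, X, Y, w_pos = 1, w_neg = 1) {
  fw <- model_forward(model, X, training = FALSE)
  if (model$config$head == "per_second") {
    y <- as.vector(t(Y))
    p <- as.vector(t(fw$probs))
  } else {
    y <- as.integer(apply(Y, 1, max))
    p <- as.vector(fw$probs)
  }
  pc <- clamp_prob(p)
  w <- ifelse(y == 1, w_pos, w_neg)
  list(loss = -sum(w * (y * log(pc) + (1 - y) * log(1 - pc))) / sum(w),
       acc = mean((p >= 0.5) == (y == 1)))
}

#' Confusion matrix from scores at a threshold
#'
#' Apnea is the positive class; a sample is predicted positive when its
#' score is greater than or equal to the threshold.
#'
#' @param labels 0/1 vector of ground-truth labels.
#' @param scores Probability scores, same length.
#' @param threshold Decision threshold (default 0.5).
#' @return A list of class `confusion_matrix` with counts `tp`, `fp`,
#'   `fn`, `tn`.
#' @export
confusion_from_scores <- function(labels, scores, threshold = 0.5) {
  if (length(labels) != length(scores)) {
    stop("labels and scores must have the same length", call. = FALSE)
  }
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1", call. = FALSE)
  pred <- scores >= threshold
  structure(list(tp = sum(pred & labels == 1), fp = sum(pred & labels == 0),
                 fn = sum(!pred & labels == 1), tn = sum(!pred & labels == 0)),
            class = "confusion_matrix")
}

#' Confusion-derived classification metrics
#'
#' Accuracy, recall (sensitivity), precision, specificity and F1 from the
#' four confusion counts. Zero-denominator convention: recall, precision
#' and specificity are 0 when their denominator is 0, and F1 is 0 when
#' precision + recall is 0.
#'
#' @param cm A [confusion_from_scores()] result or a list with `tp`, `fp`,
#'   `fn`, `tn`.
#' @return A list of class `metrics_report` (`auc` is `NA` here; see
#'   [roc_auc()]).
#' @export
compute_metrics <- function(cm) {
  tp <- cm$tp; fp <- cm$fp; fn <- cm$fn; tn <- cm$tn
  total <- tp + fp + fn + tn
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  safe_div <- function(a, b) if (b == 0) 0 else a / b
  recall <- safe_div(tp, tp + fn)
  precision <- safe_div(tp, tp + fp)
  structure(list(
    accuracy = (tp + tn) / total,
    recall = recall,
    precision = precision,
    specificity = safe_div(tn, tn + fp),
    f1 = if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall),
    auc = NA_real_
  ), class = "metrics_report")
}

#' Area under the ROC curve
#'
#' The probability that a randomly chosen apnea second receives a higher
#' score than a randomly chosen normal second, ties counted one half
#' (equivalently the trapezoidal area under the TPR-vs-FPR curve over all
#' thresholds).
#'
#' @param labels 0/1 vector containing at least one of each class.
#' @param scores Numeric scores, same length.
#' @return A number in `[0, 1]`.
#' @export
roc_auc <- function(labels, scores) {
  if (length(labels) != length(scores)) {
    stop("labels and scores must have the same length", call. = FALSE)
  }
  if (length(unique(labels[!is.na(scores)])) < 2) {
    stop("AUC is undefined: labels contain a single class", call. = FALSE)
  }
  as.numeric(pROC::auc(pROC::roc(response = labels, predictor = scores,
                                 levels = c(0, 1), direction = "<",
                                 quiet = TRUE)))
}

#' Reconstruct discrete events from per-second predictions
#'
#' Maximal runs of consecutive positive seconds become events; runs shorter
#' than `min_duration_s` (default 10 s, the standard minimum duration of a
#' scored respiratory event) are discarded. Runs separated by at most
#' `merge_gap_s` negative seconds are merged first.
#'
#' @param per_second_predictions 0/1 (or logical) vector.
#' @param min_duration_s Minimum event duration in seconds.
#' @param merge_gap_s Gaps of at most this many seconds between runs are
#'   bridged before the duration filter.
#' @return A data frame with `start_s` (0-based), `duration_s`, `kind`.
#' @export
extract_events <- function(per_second_predictions, min_duration_s = 10L,
                           merge_gap_s = 0L) {
  v <- as.integer(per_second_predictions)
  stopifnot(all(v %in% c(0L, 1L)))
  if (merge_gap_s > 0 && length(v) > 0) {
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    inner <- which(r$values == 0 & r$lengths <= merge_gap_s &
                     seq_along(r$values) > 1 &
                     seq_along(r$values) < length(r$values))
    for (i in inner) v[starts[i]:ends[i]] <- 1L
  }
  r <- rle(v)
  ends <- cumsum(r$lengths)
  keep <- r$values == 1L & r$lengths >= min_duration_s
  data.frame(start_s = (ends - r$lengths)[keep],
             duration_s = r$lengths[keep],
             kind = rep("apnea", sum(keep)))
}

#' Apnea-hypopnea index from an event list
#'
#' @param events Event data frame (one row per event).
#' @param recording_hours Recording duration in hours (> 0).
#' @return Events per hour.
#' @export
estimate_ahi <- function(events, recording_hours) {
  if (!is.numeric(recording_hours) || recording_hours <= 0) {
    stop("recording_hours must be positive", call. = FALSE)
  }
  nrow(events) / recording_hours
}

#' Per-patient evaluation and OSA screening
#'
#' For each patient: per-second scores over the whole record, confusion
#' metrics and ROC AUC against the per-second labels, an estimated AHI from
#' the thresholded predictions (events reconstructed with
#' [extract_events()]), and an OSA call at the AHI >= 5 rule. Records
#' shorter than one window are skipped with a warning and reported with
#' `skipped = TRUE`.
#'
#' @param model A trained per-second model.
#' @param records List of clean [patient_record()]s (records still holding
#'   missing samples are cleaned with [drop_missing()] first).
#' @param window_s,stride_s Windowing for [predict_per_second()].
#' @param threshold Decision threshold.
#' @param min_duration_s Minimum reconstructed event duration.
#' @return A data frame, one row per patient.
#' @export
per_patient_report <- function(model, records, window_s = NULL,
                               stride_s = NULL, threshold = 0.5,
                               min_duration_s = 10L) {
  window_s <- window_s %||% model$config$sequence_length
  rows <- lapply(records, function(rec) {
    if (anyNA(rec$spo2)) rec <- drop_missing(rec)
    true_ahi <- rec$target_ahi %||%
      (if (!is.null(rec$events)) nrow(rec$events) / (length(rec$spo2) / 3600) else NA_real_)
    base <- data.frame(patient_id = rec$patient_id, skipped = FALSE,
                       n_scored = NA_real_, accuracy = NA_real_,
                       sensitivity = NA_real_, precision = NA_real_,
                       specificity = NA_real_, f1 = NA_real_, auc = NA_real_,
                       estimated_ahi = NA_real_, true_ahi = true_ahi,
                       osa_predicted = NA, osa_true = if (is.na(true_ahi)) NA else true_ahi >= 5)
    if (length(rec$spo2) < window_s) {
      warning(sprintf("patient %s skipped: record shorter than one window",
                      rec$patient_id))
      base$skipped <- TRUE
      return(base)
    }
    scores <- predict_per_second(model, rec, window_s, stride_s)
    ok <- !is.na(scores) # trailing unscored seconds are excluded
    lab <- rec$labels[ok]
    sc <- scores[ok]
    m <- compute_metrics(confusion_from_scores(lab, sc, threshold))
    base$n_scored <- sum(ok)
    base$accuracy <- m$accuracy
    base$sensitivity <- m$recall
    base$precision <- m$precision
    base$specificity <- m$specificity
    base$f1 <- m$f1
    base$auc <- if (length(unique(lab)) == 2) roc_auc(lab, sc) else NA_real_
    ev <- extract_events(as.integer(sc >= threshold), min_duration_s)
    base$estimated_ahi <- estimate_ahi(ev, sum(ok) / 3600)
    base$osa_predicted <- base$estimated_ahi >= 5
    base
  })
  do.call(rbind, rows)
}
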