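# Synthetic overnight oximetry with annotated desaturation events.
#
# The simulator emulates what a pulse oximeter sees during obstructive
# apnea: a stable baseline near 95-98% SpO2, intermittent desaturations of
# 3-4% lasting tens of seconds (rate set by a target AHI), measurement
# noise, a slow baseline drift, and optional missing samples and artifact
# spikes.

#' Simulation parameters for a synthetic oximetry record
#'
#' @param duration_s Record length in seconds (1 Hz sampling); at least 60.
#' @param baseline_mean Baseline SpO2 percent (default 97).
#' @param baseline_sd Standard deviation of the slow AR(1) baseline drift,
#'   in percent; the drift is truncated at 3 standard deviations.
#' @param target_ahi Target apnea-hypopnea index, events per hour.
#' @param desat_depth_range Min/max desaturation depth in percent below the
#'   local baseline (default `c(3, 4)`, the standard scoring criterion).
#' @param event_duration_range_s Min/max event duration in whole seconds.
#' @param desat_shape `"linear-recovery"` (piecewise-linear descent over the
#'   first third, linear recovery over the remainder) or
#'   `"exponential-recovery"`.
#' @param noise_sd Gaussian measurement noise, percent.
#' @param missing_rate Per-sample probability of a missing (`NA`) sample.
#' @param artifact_rate Per-sample probability of an implausible spike.
#' @param quantize Round SpO2 to integer percent, as many oximeters report.
#' @param seed Integer seed; records are fully reproducible.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(duration_s = 28800L, baseline_mean = 97,
                       baseline_sd = 0.5, target_ahi = 15,
                       desat_depth_range = c(3, 4),
                       event_duration_range_s = c(10L, 60L),
                       desat_shape = c("linear-recovery", "exponential-recovery"),
                       noise_sd = 0.3, missing_rate = 0, artifact_rate = 0,
                       quantize = FALSE, seed = 1L) {
  desat_shape <- match.arg(desat_shape)
  stopifnot(duration_s >= 60, target_ahi >= 0,
            all(desat_depth_range > 0), all(desat_depth_range < 100),
            event_duration_range_s[1] >= 1,
            missing_rate >= 0, missing_rate < 1,
            artifact_rate >= 0, artifact_rate < 1)
  structure(as.list(environment()), class = "sim_params")
}

# Non-overlapping event placement: draw candidate starts uniformly and
# reject any that come within `gap_s` of an accepted event.
place_events <- function(n_events, durations, duration_s, gap_s = 10L) {
  starts <- integer(0)
  accepted_d <- integer(0)
  attempts <- 0L
  max_attempts <- 200L * max(n_events, 1L)
  while (length(starts) < n_events && attempts < max_attempts) {
    attempts <- attempts + 1L
    i <- length(starts) + 1L
    d <- durations[i]
    s <- sample.int(duration_s - d + 1L, 1L) - 1L
    clash <- any(s < starts + accepted_d + gap_s & starts < s + d + gap_s)
    if (!clash) {
      starts <- c(starts, s)
      accepted_d <- c(accepted_d, d)
    }
  }
  if (length(starts) < n_events) {
    stop("simulation error: could not place the requested event load", call. = FALSE)
  }
  ord <- order(starts)
  data.frame(start_s = starts[ord], duration_s = durations[ord], kind = "apnea")
}

desat_profile <- function(d, depth, shape) {
  d1 <- max(1L, round(d / 3))
  tau <- seq_len(d)
  descent <- depth * pmin(tau, d1) / d1
  if (d == d1) return(descent)
  rec_tau <- pmax(tau - d1, 0)
  if (shape == "linear-recovery") {
    off <- ifelse(tau <= d1, descent, depth * (d - tau) / (d - d1))
  } else {
    off <- ifelse(tau <= d1, descent, depth * exp(-3 * rec_tau / (d - d1)))
  }
  off
}

#' Simulate one annotated overnight SpO2 record
#'
#' Events are placed without overlap (10 s refractory gap) at a Poisson rate
#' matching `target_ahi`; labels are 1 exactly on event seconds. Noise,
#' missing markers and artifact spikes are applied after labeling.
#'
#' @param params A [sim_params()] object.
#' @param patient_id Identifier for the generated record.
#' @return A [patient_record()] with event annotations and `target_ahi`
#'   metadata.
#' @export
simulate_record <- function(params = sim_params(), patient_id = "SIM01") {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  mean_dur <- mean(p$event_duration_range_s)
  if (p$target_ahi * mean_dur / 3600 > 0.9) {
    stop("simulation error: expected event seconds exceed the record duration",
         call. = FALSE)
  }
  with_seed(p$seed, {
    n <- as.integer(p$duration_s)
    n_events <- stats::rpois(1L, p$target_ahi * n / 3600)
    if (n_events > 0) {
      durations <- sample(seq(p$event_duration_range_s[1],
                              p$event_duration_range_s[2]), n_events,
                          replace = TRUE)
      events <- place_events(n_events, durations, n)
    } else {
      events <- data.frame(start_s = integer(0), duration_s = integer(0),
                           kind = character(0))
    }

    # slow AR(1) baseline drift, truncated at 3 sd
    rho <- 0.995
    innov <- stats::rnorm(n, 0, sqrt(1 - rho^2) * p$baseline_sd)
    drift <- stats::filter(innov, rho, method = "recursive")
    drift <- pmin(pmax(as.numeric(drift), -3 * p$baseline_sd), 3 * p$baseline_sd)
    spo2 <- pmin(p$baseline_mean + drift, 100)

    labels <- integer(n)
    if (nrow(events) > 0) {
      for (i in seq_len(nrow(events))) {
        d <- events$duration_s[i]
        depth <- stats::runif(1, p$desat_depth_range[1], p$desat_depth_range[2])
        idx <- events$start_s[i] + seq_len(d)
        spo2[idx] <- spo2[idx] - desat_profile(d, depth, p$desat_shape)
        labels[idx] <- 1L
      }
    }

    if (p$noise_sd > 0) spo2 <- spo2 + stats::rnorm(n, 0, p$noise_sd)
    spo2 <- pmin(pmax(spo2, 0), 100)
    if (p$quantize) spo2 <- round(spo2)

    rec <- patient_record(patient_id, spo2, labels, events = events,
                          target_ahi = p$target_ahi)
    if (p$missing_rate > 0 || p$artifact_rate > 0) {
      rec <- apply_artifacts(rec, p$missing_rate, p$artifact_rate)
    }
    rec
  })
}

# artifact machinery shared by simulate_record (in-stream) and
# inject_artifacts (own seed)
apply_artifacts <- function(record, missing_rate, artifact_rate) {
  n <- length(record$spo2)
  spo2 <- record$spo2
  env_min <- min(spo2, na.rm = TRUE)
  miss <- stats::runif(n) < missing_rate
  art <- (stats::runif(n) < artifact_rate) & !miss
  # spikes drop well below the clean envelope (sensor slippage reads low)
  spo2[art] <- pmax(0, env_min - stats::runif(sum(art), 5, 25))
  spo2[miss] <- NA_real_
  patient_record(record$patient_id, spo2, record$labels,
                 events = record$events, target_ahi = record$target_ahi)
}

#' Corrupt a record with missing samples and artifact spikes
#'
#' Independently per sample, the SpO2 value is replaced by a missing marker
#' (with probability `missing_rate`) or by an implausible spike below the
#' clean record's envelope (with probability `artifact_rate`). Labels are
#' untouched.
#'
#' @param record A [patient_record()].
#' @param missing_rate,artifact_rate Per-sample probabilities in `[0, 1)`.
#' @param seed Integer seed.
#' @return The corrupted `patient_record`.
#' @export
inject_artifacts <- function(record, missing_rate, artifact_rate, seed = 1L) {
  stopifnot(missing_rate >= 0, missing_rate < 1,
            artifact_rate >= 0, artifact_rate < 1)
  if (missing_rate == 0 && artifact_rate == 0) return(record)
  with_seed(seed, apply_artifacts(record, missing_rate, artifact_rate))
}

#' Simulate a cohort of patients with prescribed apnea burdens
#'
#' @param n_patients Number of patients; must equal `length(ahi_values)`.
#' @param ahi_values Target AHI (events/hour) per patient.
#' @param base_params A [sim_params()] whose fields other than `target_ahi`
#'   and `seed` apply to every patient.
#' @param seed Cohort seed; per-patient seeds are derived from it.
#' @return A list of [patient_record()]s with unique patient ids and the
#'   true AHI attached as metadata.
#' @export
simulate_cohort <- function(n_patients, ahi_values,
                            base_params = sim_params(), seed = 1L) {
  stopifnot(length(ahi_values) == n_patients, n_patients >= 1)
  ids <- sprintf("SIM%02d", seq_len(n_patients))
  if (anyDuplicated(ids)) stop("generation error: duplicate patient ids", call. = FALSE)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n_patients))
  lapply(seq_len(n_patients), function(i) {
    p <- base_params
    p$target_ahi <- ahi_values[i]
    p$seed <- seeds[i]
    simulate_record(p, patient_id = ids[i])
  })
}
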