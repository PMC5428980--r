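#' Synthetic actigraphy cohorts
#'
#' Generates minute-level, nonnegative integer activity-count signals with
#' circadian structure, so that the whole pipeline can be exercised without
#' any real recording.  A subject's expected count at minute \eqn{t} follows
#' a half-rectified sinusoid with a 1440-minute period (near-zero night
#' troughs), scaled by a subject-specific log-normal multiplier; on top of
#' the baseline, short activity bouts occur at random during active hours,
#' and Gaussian sensor noise (variance growing with the baseline) is added
#' before rounding and truncation at zero.  Between-subject heterogeneity is
#' the group-level control: the log-scale spread of the subject multiplier is
#' `subject_sdlog` for successes and `subject_sdlog + heterogeneity_delta`
#' for failures, emulating the more varied movement profiles of the failure
#' group.  With `heterogeneity_delta = 0` both groups are drawn from the same
#' distribution.
#'
#' @name synthetic_cohort
NULL

#' Cohort specification
#'
#' Parameters of the synthetic cohort generator.  Defaults emulate the study
#' conditions of a week-long wear protocol: 21 successes and 79 failures,
#' 7000 minutes per subject, and scales chosen so that mean minute counts
#' land near 290 counts/min.
#'
#' @param n_success,n_failure numbers of subjects per group.
#' @param signal_length samples (minutes) per subject; default 7000.
#' @param circadian_amplitude peak of the circadian baseline (counts/min);
#'   default 700.
#' @param bout_rate probability of an activity bout in an active minute;
#'   default 0.15.
#' @param noise_scale standard-deviation scale of the additive sensor noise
#'   (counts); default 50.
#' @param heterogeneity_delta extra log-scale between-subject spread for the
#'   failure group (0 = identical groups); default 0.6.
#' @param subject_sdlog baseline log-scale between-subject spread shared by
#'   both groups; default 0.1.
#' @param seed integer seed governing all randomness of the cohort.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_success = 21L, n_failure = 79L,
                        signal_length = 7000L,
                        circadian_amplitude = 700,
                        bout_rate = 0.15,
                        noise_scale = 50,
                        heterogeneity_delta = 0.6,
                        subject_sdlog = 0.1,
                        seed = 1L) {
  num1 <- function(x, nm, lo = 0) {
    if (length(x) != 1L || is.na(x) || !is.numeric(x) || x < lo)
      stop_config(nm, " must be a single number >= ", lo)
    x
  }
  spec <- list(
    n_success = as.integer(num1(n_success, "n_success")),
    n_failure = as.integer(num1(n_failure, "n_failure")),
    signal_length = as.integer(num1(signal_length, "signal_length")),
    circadian_amplitude = num1(circadian_amplitude, "circadian_amplitude"),
    bout_rate = num1(bout_rate, "bout_rate"),
    noise_scale = num1(noise_scale, "noise_scale"),
    heterogeneity_delta = num1(heterogeneity_delta, "heterogeneity_delta"),
    subject_sdlog = num1(subject_sdlog, "subject_sdlog"),
    seed = as.integer(num1(seed, "seed", lo = -Inf))
  )
  if (spec$bout_rate > 1) stop_config("bout_rate is a per-minute probability (<= 1)")
  structure(spec, class = "cohort_spec")
}

# Mean magnitude of an activity bout, in units of the circadian amplitude.
BOUT_MEAN_FACTOR <- 8 / 7

#' Generate one synthetic activity signal
#'
#' @param spec a [cohort_spec()].
#' @param multiplier subject-level log-normal scale multiplier (applied to
#'   the circadian amplitude and the bout rate).
#' @param phase circadian phase offset in minutes.
#' @param seed integer seed for this signal.
#' @return Integer-valued numeric vector of length `spec$signal_length`,
#'   all values >= 0.
#' @export
generate_signal <- function(spec, multiplier = 1, phase = 0, seed = 1L) {
  if (!inherits(spec, "cohort_spec")) stop_config("spec must be a cohort_spec")
  set.seed(as.integer(seed))
  t <- seq_len(spec$signal_length)
  circ <- pmax(0, sin(2 * pi * (t - phase) / 1440))
  base <- spec$circadian_amplitude * multiplier * circ
  rate <- min(1, spec$bout_rate * multiplier)
  bout_mean <- BOUT_MEAN_FACTOR * spec$circadian_amplitude * multiplier
  bouts <- ifelse(circ > 0 & runif(spec$signal_length) < rate,
                  rexp(spec$signal_length, rate = 1 / bout_mean), 0)
  noise <- rnorm(spec$signal_length, 0, spec$noise_scale * (0.2 + circ))
  round(pmax(0, base + bouts + noise))
}

#' Generate a labelled synthetic cohort
#'
#' Draws per-subject parameters (log-normal amplitude multiplier with
#' group-dependent spread, circadian phase jitter with SD 45 min), then one
#' signal per subject.  A single root seed drives everything; per-subject
#' signal seeds are drawn from the root stream, so the cohort is fully
#' reproducible.
#'
#' @param spec a [cohort_spec()].
#' @return List of [participant_record()] objects with ids `F001..` and
#'   `S001..` and the requested labels.
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) stop_config("spec must be a cohort_spec")
  set.seed(spec$seed)
  labels <- c(rep("failure", spec$n_failure), rep("success", spec$n_success))
  ids <- c(sprintf("F%03d", seq_len(spec$n_failure)),
           sprintf("S%03d", seq_len(spec$n_success)))
  n <- length(labels)
  sdlog <- spec$subject_sdlog + ifelse(labels == "failure", spec$heterogeneity_delta, 0)
  # mean-preserving log-normal: E[multiplier] = 1 in both groups, so the
  # heterogeneity control widens the spread without shifting group means
  multiplier <- rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  phase <- rnorm(n, 0, 45)
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    sig <- generate_signal(spec, multiplier = multiplier[i], phase = phase[i],
                           seed = seeds[i])
    out[[i]] <- participant_record(ids[i], sig, labels[i])
  }
  out
}

#' Weight trajectories consistent with given labels
#'
#' Draws (w1, w2, w3) triples (kg) that round-trip through
#' [assign_outcome_label()] to the requested labels: successes lose 15-25%
#' by `w2` and finish at 80-90% of `w1`; failures either miss the 15% target
#' at `w2` or, with probability 1/2, reach it and then regain above 90%;
#' indeterminate subjects reach the target but have no final weight.
#'
#' @param labels character vector of `"success"`, `"failure"`,
#'   `"indeterminate"` (may be named by participant id).
#' @param seed integer seed.
#' @return Data frame with columns `participant_id` (when `labels` is
#'   named, else `1..n`), `w1`, `w2`, `w3` (`NA` where unmeasured).
#' @export
generate_weight_trajectories <- function(labels, seed = 1L) {
  bad <- setdiff(unique(labels), c("success", "failure", "indeterminate"))
  if (length(bad)) stop_validation("unknown label token(s): ", paste(bad, collapse = ", "))
  set.seed(as.integer(seed))
  n <- length(labels)
  w1 <- round(rnorm(n, 110, 15), 1)
  w1 <- pmax(w1, 60)
  w2 <- w3 <- numeric(n)
  for (i in seq_len(n)) {
    if (labels[i] == "success") {
      w2[i] <- w1[i] * runif(1, 0.75, 0.849)
      w3[i] <- w1[i] * runif(1, 0.80, 0.899)
    } else if (labels[i] == "failure") {
      if (runif(1) < 0.5) {            # missed the intensive-phase target
        w2[i] <- w1[i] * runif(1, 0.86, 1.00)
        w3[i] <- NA_real_
      } else {                         # reached it, then regained
        w2[i] <- w1[i] * runif(1, 0.75, 0.849)
        w3[i] <- w1[i] * runif(1, 0.905, 1.05)
      }
    } else {                           # indeterminate: no final weight yet
      w2[i] <- w1[i] * runif(1, 0.75, 0.849)
      w3[i] <- NA_real_
    }
  }
  data.frame(participant_id = if (!is.null(names(labels))) names(labels)
             else as.character(seq_len(n)),
             w1 = w1, w2 = round(w2, 1), w3 = round(w3, 1),
             stringsAsFactors = FALSE)
}
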