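#' Baseline signal features
#'
#' The conventional features against which the windowed persistence pipeline
#' is benchmarked: signal power, normalized histogram entropy, mean activity,
#' and pairwise Pearson correlation between whole signals.
#'
#' @name baseline_features
NULL

#' Signal power
#'
#' Mean squared sample value (per-sample average energy, counts^2).  An
#' alternative convention (variance) can be selected for sensitivity checks.
#'
#' @param signal nonempty numeric vector.
#' @param definition `"mean_square"` (default) or `"variance"`.
#' @return Nonnegative scalar.
#' @export
#' @examples
#' signal_power(c(3, 4))  # 12.5
signal_power <- function(signal, definition = c("mean_square", "variance")) {
  check_signal(signal, min_length = 1L)
  definition <- match.arg(definition)
  if (definition == "mean_square") mean(signal^2) else stats::var(signal) * (length(signal) - 1) / length(signal)
}

#' Normalized histogram entropy
#'
#' Shannon entropy of the equal-width value histogram over `[min, max]`,
#' normalized by `log(bins)` so the result lies in `[0, 1]`.  A constant
#' signal occupies a single bin and has entropy 0.
#'
#' @param signal nonempty numeric vector.
#' @param bins integer number of histogram bins (>= 2); default 16.
#' @return Scalar in `[0, 1]`.
#' @export
#' @examples
#' signal_entropy(rep(c(0, 1), 50), bins = 2)  # 1
signal_entropy <- function(signal, bins = 16L) {
  check_signal(signal, min_length = 1L)
  if (length(bins) != 1L || is.na(bins) || bins != round(bins) || bins < 2)
    stop_config("bins must be a single integer >= 2")
  lo <- min(signal); hi <- max(signal)
  if (hi == lo) return(0)
  # right-closed equal-width bins; the minimum folds into the first bin
  idx <- pmin(pmax(ceiling((signal - lo) / (hi - lo) * bins), 1L), as.integer(bins))
  p <- tabulate(idx, nbins = as.integer(bins)) / length(signal)
  p <- p[p > 0]
  -sum(p * log(p)) / log(bins)
}

#' Mean activity
#'
#' Arithmetic mean of the samples (counts per minute for actigraphy input).
#'
#' @param signal nonempty numeric vector.
#' @return Scalar mean.
#' @export
signal_mean <- function(signal) {
  check_signal(signal, min_length = 1L)
  mean(signal)
}

#' Pearson correlation between two signals
#'
#' Sample Pearson correlation of two equal-length signals; the whole-signal
#' direct-comparison baseline.
#'
#' @param a,b numeric vectors of equal length (>= 2), neither constant.
#' @return Scalar in `[-1, 1]`.
#' @export
pearson_correlation <- function(a, b) {
  check_signal(a, min_length = 2L, what = "a")
  check_signal(b, min_length = 2L, what = "b")
  if (length(a) != length(b))
    stop_validation("signals must have equal length")
  if (sd(a) == 0 || sd(b) == 0)
    stop_validation("correlation is undefined for a constant signal")
  cor(a, b)
}

#' Per-participant baseline feature table
#'
#' @param records list of participant records (see [participant_record()]).
#' @param bins histogram bins for the entropy feature.
#' @return Data frame with columns `participant_id`, `power`, `entropy`,
#'   `mean`.
#' @export
baseline_features <- function(records, bins = 16L) {
  check_records(records)
  data.frame(
    participant_id = vapply(records, function(r) r$id, character(1)),
    power = vapply(records, function(r) signal_power(r$signal), numeric(1)),
    entropy = vapply(records, function(r) signal_entropy(r$signal, bins), numeric(1)),
    mean = vapply(records, function(r) signal_mean(r$signal), numeric(1)),
    stringsAsFactors = FALSE
  )
}
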