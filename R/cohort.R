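#' Cohort-level analysis
#'
#' Participants carry an outcome label ("success" = lost at least 15% of
#' starting body weight by the end of the intensive phase and finished the
#' program at no more than 90% of starting weight; "failure" otherwise;
#' "indeterminate" when the program is unfinished and neither rule applies).
#' Every unordered pair of labelled participants falls into one of three
#' strata — failure/failure (FF), failure/success (FS), success/success (SS)
#' — and a pairwise signal comparison (windowed persistence distance or
#' Pearson correlation) gives each pair a value.  Group summaries and
#' unpaired t tests quantify the separation between strata; a random-label
#' control checks that it vanishes under label shuffling.
#'
#' @name cohort_stats
NULL

#' Participant record
#'
#' @param id participant identifier (coerced to character).
#' @param signal numeric activity signal.
#' @param label `"success"`, `"failure"`, or `"indeterminate"`.
#' @return A list of class `participant_record`.
#' @export
participant_record <- function(id, signal, label = c("indeterminate", "success", "failure")) {
  label <- match.arg(label)
  check_signal(signal)
  structure(list(id = as.character(id), signal = as.numeric(signal), label = label),
            class = "participant_record")
}

check_records <- function(records) {
  if (!is.list(records) || length(records) == 0 ||
      !all(vapply(records, inherits, logical(1), "participant_record")))
    stop_validation("records must be a nonempty list of participant_record objects")
  ids <- vapply(records, function(r) r$id, character(1))
  if (anyDuplicated(ids))
    stop_validation("duplicate participant ids: ",
                    paste(unique(ids[duplicated(ids)]), collapse = ", "))
  invisible(records)
}

#' Outcome label from a weight trajectory
#'
#' Applies the program's labelling rule to weights (kg) at baseline (`w1`),
#' after the intensive weight-loss phase (`w2`), and at program end (`w3`,
#' possibly missing).  Failure: less than 15% loss at `w2` (i.e.
#' `w2 > 0.85 * w1`), or a completed program ending above 90% of starting
#' weight (`w3 > 0.90 * w1`).  Success: at least 15% loss at `w2` and
#' `w3 <= 0.90 * w1`.  A participant with at least 15% loss but no final
#' weight is indeterminate.
#'
#' @param w1,w2 positive weights; `w3` may be `NA` (not yet measured).
#' @return One of `"success"`, `"failure"`, `"indeterminate"` (vectorized).
#' @export
#' @examples
#' assign_outcome_label(100, 84, 88)   # success
#' assign_outcome_label(100, 90, NA)   # failure
#' assign_outcome_label(100, 80, 92)   # failure
#' assign_outcome_label(100, 84, NA)   # indeterminate
assign_outcome_label <- function(w1, w2, w3 = NA_real_) {
  n <- max(length(w1), length(w2), length(w3))
  w1 <- rep_len(as.numeric(w1), n)
  w2 <- rep_len(as.numeric(w2), n)
  w3 <- rep_len(as.numeric(w3), n)
  if (anyNA(w1) || anyNA(w2) || any(w1 <= 0) || any(w2 <= 0) || any(!is.na(w3) & w3 <= 0))
    stop_validation("weights must be positive (w3 may be NA)")
  out <- character(n)
  lost15 <- w2 <= 0.85 * w1
  out[!lost15] <- "failure"
  out[lost15 & !is.na(w3) & w3 <= 0.90 * w1] <- "success"
  out[lost15 & !is.na(w3) & w3 > 0.90 * w1] <- "failure"
  out[lost15 & is.na(w3)] <- "indeterminate"
  out
}

#' Enumerate labelled participant pairs
#'
#' Every unordered pair of definitely labelled participants, once, with its
#' stratum: `FF` (both failures), `FS` (mixed), `SS` (both successes).
#' Indeterminate participants are excluded with a warning.  With 79 failures
#' and 21 successes the counts are 3081 / 1659 / 210.
#'
#' @param records list of `participant_record` objects, or a named character
#'   vector of labels (names = ids).
#' @return Data frame with columns `id_a`, `id_b`, `group`.
#' @export
pair_groups <- function(records) {
  labels <- record_labels(records)
  drop <- labels == "indeterminate"
  if (any(drop)) {
    warning(sum(drop), " participant(s) with indeterminate labels excluded from pairing")
    labels <- labels[!drop]
  }
  if (length(labels) < 2)
    stop_validation("need at least two participants with definite labels")
  idx <- combn(length(labels), 2)
  la <- labels[idx[1, ]]; lb <- labels[idx[2, ]]
  group <- ifelse(la == "failure" & lb == "failure", "FF",
                  ifelse(la == "success" & lb == "success", "SS", "FS"))
  data.frame(id_a = names(labels)[idx[1, ]],
             id_b = names(labels)[idx[2, ]],
             group = group, stringsAsFactors = FALSE)
}

record_labels <- function(records) {
  if (is.character(records)) {
    labels <- records
    if (is.null(names(labels))) stop_validation("label vector must be named by participant id")
  } else {
    check_records(records)
    labels <- vapply(records, function(r) r$label, character(1))
    names(labels) <- vapply(records, function(r) r$id, character(1))
  }
  bad <- setdiff(unique(labels), c("success", "failure", "indeterminate"))
  if (length(bad))
    stop_validation("unknown label token(s): ", paste(bad, collapse = ", "))
  labels
}

#' Pairwise cohort comparison
#'
#' Compares every pair of labelled participants.  For the persistence
#' metrics the pairwise value is the mean of the window-by-window distance
#' signal between the two participants' diagram sequences; for
#' `metric = "correlation"` it is the whole-signal Pearson correlation.
#' Signals must share a common length (apply [apply_inclusion()] first);
#' diagram sequences are computed once per participant.
#'
#' @param records list of `participant_record` objects with definite labels
#'   (indeterminate records are excluded with a warning).
#' @param metric `"modified_hausdorff"` (default), `"hausdorff"`,
#'   `"wasserstein"`, or `"correlation"`.
#' @param q Wasserstein order.
#' @param window_length samples per window; default 20.
#' @return Data frame with columns `id_a`, `id_b`, `group`, `value`.
#' @export
pairwise_cohort_analysis <- function(records,
                                     metric = c("modified_hausdorff", "hausdorff",
                                                "wasserstein", "correlation"),
                                     q = 1, window_length = 20L) {
  metric <- match.arg(metric)
  check_records(records)
  labels <- record_labels(records)
  keep <- labels != "indeterminate"
  if (!all(keep)) {
    warning(sum(!keep), " participant(s) with indeterminate labels excluded")
    records <- records[keep]
  }
  lens <- vapply(records, function(r) length(r$signal), integer(1))
  if (length(unique(lens)) != 1)
    stop_validation("signals must have uniform length; apply_inclusion() crops them")
  pairs <- pair_groups(records)
  ids <- vapply(records, function(r) r$id, character(1))
  if (metric == "correlation") {
    sig <- lapply(records, function(r) r$signal)
    names(sig) <- ids
    value <- mapply(function(a, b) pearson_correlation(sig[[a]], sig[[b]]),
                    pairs$id_a, pairs$id_b, USE.NAMES = FALSE)
  } else {
    window_length <- check_window_length(window_length)
    seqs <- lapply(records, function(r)
      windowed_diagrams(r$signal, window_length, id = r$id))
    names(seqs) <- ids
    code <- match(metric, c("modified_hausdorff", "hausdorff", "wasserstein")) - 1L
    value <- mapply(function(a, b)
      mean(cpp_distance_signal(seqs[[a]]$diagrams, seqs[[b]]$diagrams, code, q)),
      pairs$id_a, pairs$id_b, USE.NAMES = FALSE)
  }
  pairs$value <- as.numeric(value)
  pairs
}

#' Per-group summary of pairwise values
#'
#' Unweighted mean and sample (n-1) standard deviation of the pair values in
#' each stratum present; a single-pair group reports `NA` for the SD, and
#' absent groups are simply not listed.
#'
#' @param pairs data frame from [pairwise_cohort_analysis()] (columns
#'   `group`, `value`).
#' @return Data frame with columns `group`, `n`, `mean`, `sd`, ordered
#'   FF, FS, SS.
#' @export
group_summary <- function(pairs) {
  if (!is.data.frame(pairs) || !all(c("group", "value") %in% names(pairs)))
    stop_validation("pairs must have 'group' and 'value' columns")
  groups <- intersect(c("FF", "FS", "SS"), unique(pairs$group))
  out <- do.call(rbind, lapply(groups, function(g) {
    v <- pairs$value[pairs$group == g]
    data.frame(group = g, n = length(v), mean = mean(v),
               sd = if (length(v) > 1) sd(v) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Unpaired two-sample t test
#'
#' Student's pooled-variance two-sample t test (the classical "unpaired t
#' test"), two-sided; the Welch variant is available via `variant`.  When
#' both samples are constant with equal means the statistic is taken as 0
#' with p = 1 by convention (and p = 0 for unequal constant means).
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @param variant `"student"` (default) or `"welch"`.
#' @return A list of class `ttest_result`: `statistic`, `df`, `p.value`,
#'   `variant`, `n` (the two sample sizes), `means`.
#' @export
#' @examples
#' unpaired_ttest(c(1, 2, 3), c(4, 5, 6))
unpaired_ttest <- function(x, y, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  if (!is.numeric(x) || !is.numeric(y) || length(x) < 2 || length(y) < 2)
    stop_validation("both samples must be numeric with at least 2 values")
  if (sd(x) == 0 && sd(y) == 0) {
    eq <- isTRUE(all.equal(mean(x), mean(y)))
    res <- list(statistic = if (eq) 0 else sign(mean(x) - mean(y)) * Inf,
                df = length(x) + length(y) - 2,
                p.value = if (eq) 1 else 0)
  } else {
    tt <- t.test(x, y, var.equal = (variant == "student"))
    res <- list(statistic = unname(tt$statistic), df = unname(tt$parameter),
                p.value = tt$p.value)
  }
  structure(c(res, list(variant = variant, n = c(length(x), length(y)),
                        means = c(mean(x), mean(y)))),
            class = "ttest_result")
}

#' @export
print.ttest_result <- function(x, ...) {
  cat(sprintf("Unpaired t test (%s): t = %.4g, df = %.4g, p = %.4g\n",
              x$variant, x$statistic, x$df, x$p.value))
  invisible(x)
}

#' Between-stratum t tests
#'
#' The three pairwise comparisons of stratum values: FF vs SS (the main
#' comparison), FF vs FS, and FS vs SS.  Pair values are treated as
#' independent observations even though pairs sharing a participant are
#' dependent — a deliberate replication of the standard pairwise-comparison
#' procedure; see the package vignette for the caveat.
#'
#' @param pairs data frame with `group` and `value` columns.
#' @param variant passed to [unpaired_ttest()].
#' @return Data frame with columns `comparison`, `t`, `df`, `p`.
#' @export
cohort_ttests <- function(pairs, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  vals <- split(pairs$value, pairs$group)
  comps <- list(c("FF", "SS"), c("FF", "FS"), c("FS", "SS"))
  rows <- lapply(comps, function(cp) {
    if (is.null(vals[[cp[1]]]) || is.null(vals[[cp[2]]]) ||
        length(vals[[cp[1]]]) < 2 || length(vals[[cp[2]]]) < 2)
      return(NULL)
    tt <- unpaired_ttest(vals[[cp[1]]], vals[[cp[2]]], variant)
    data.frame(comparison = paste(cp, collapse = "_vs_"),
               t = tt$statistic, df = tt$df, p = tt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop_validation("no stratum pair has at least 2 values per group")
  rownames(out) <- NULL
  out
}

#' Random-label ("blind") control
#'
#' Reassigns outcome labels at random and reruns the grouping and t tests,
#' averaging the p-values over trials.  Because pairwise signal distances do
#' not depend on labels, the pairwise values are computed once and only the
#' grouping is redone per trial.  By default each trial permutes the observed
#' labels, preserving the class sizes; set `preserve_sizes = FALSE` to redraw
#' each label independently with the observed success probability.
#'
#' @param records list of `participant_record` objects.
#' @param n_trials number of random relabellings; default 100.
#' @param seed integer seed controlling all randomness.
#' @param metric,q,window_length passed to [pairwise_cohort_analysis()].
#' @param variant t-test variant.
#' @param preserve_sizes keep the observed class sizes in every trial.
#' @param pairs optional precomputed result of [pairwise_cohort_analysis()]
#'   on `records`, to avoid recomputation.
#' @return Data frame with columns `comparison`, `mean_p`, `n_trials`.
#' @export
random_label_control <- function(records, n_trials = 100L, seed = 1L,
                                 metric = "modified_hausdorff", q = 1,
                                 window_length = 20L,
                                 variant = c("student", "welch"),
                                 preserve_sizes = TRUE, pairs = NULL) {
  variant <- match.arg(variant)
  if (length(n_trials) != 1L || is.na(n_trials) || n_trials < 1)
    stop_config("n_trials must be a positive integer")
  if (is.null(pairs))
    pairs <- pairwise_cohort_analysis(records, metric = metric, q = q,
                                      window_length = window_length)
  labels <- record_labels(records)
  labels <- labels[labels != "indeterminate"]
  ids <- names(labels)
  p_success <- mean(labels == "success")
  # values are label-independent: index them once by unordered pair
  key <- paste(pmin(pairs$id_a, pairs$id_b), pmax(pairs$id_a, pairs$id_b))
  value_by_pair <- pairs$value
  names(value_by_pair) <- key
  idx <- combn(length(ids), 2)
  pair_key <- paste(pmin(ids[idx[1, ]], ids[idx[2, ]]),
                    pmax(ids[idx[1, ]], ids[idx[2, ]]))
  v <- unname(value_by_pair[pair_key])
  set.seed(as.integer(seed))
  acc <- list()
  for (trial in seq_len(n_trials)) {
    lab <- if (preserve_sizes) sample(labels) else
      ifelse(runif(length(ids)) < p_success, "success", "failure")
    la <- lab[idx[1, ]]; lb <- lab[idx[2, ]]
    grp <- ifelse(la == "failure" & lb == "failure", "FF",
                  ifelse(la == "success" & lb == "success", "SS", "FS"))
    tests <- tryCatch(
      cohort_ttests(data.frame(group = grp, value = v, stringsAsFactors = FALSE),
                    variant),
      actiph_validation_error = function(e) NULL)
    if (!is.null(tests)) acc[[length(acc) + 1L]] <- tests
  }
  if (length(acc) == 0) stop_validation("no trial produced testable strata")
  all <- do.call(rbind, acc)
  out <- aggregate(p ~ comparison, data = all, FUN = mean)
  names(out) <- c("comparison", "mean_p")
  counts <- table(all$comparison)
  out$n_trials <- as.integer(counts[out$comparison])
  out[order(match(out$comparison, c("FF_vs_SS", "FF_vs_FS", "FS_vs_SS"))), ,
      drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Full cohort analysis
#'
#' Convenience wrapper chaining [pairwise_cohort_analysis()],
#' [group_summary()], and [cohort_ttests()].
#'
#' @inheritParams pairwise_cohort_analysis
#' @param variant t-test variant.
#' @return List with elements `pairs`, `summary`, `tests`, `metric`.
#' @export
cohort_analysis <- function(records,
                            metric = c("modified_hausdorff", "hausdorff",
                                       "wasserstein", "correlation"),
                            q = 1, window_length = 20L,
                            variant = c("student", "welch")) {
  metric <- match.arg(metric)
  variant <- match.arg(variant)
  pairs <- pairwise_cohort_analysis(records, metric = metric, q = q,
                                    window_length = window_length)
  list(pairs = pairs, summary = group_summary(pairs),
       tests = cohort_ttests(pairs, variant), metric = metric)
}
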