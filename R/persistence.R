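#' Persistence diagrams of discrete signals
#'
#' A signal is a finite real-valued sequence \eqn{f(1), \dots, f(n)} (here,
#' minute-level activity counts).  Its 0-dimensional sublevel-set persistence
#' diagram records, for every local minimum, the value at which a connected
#' component of the sublevel set is born and the value of the local maximum at
#' which it merges into an older component (the elder rule).  Ties between
#' equal sample values are broken by index, as if each value were perturbed by
#' an infinitesimal \eqn{\varepsilon i}; no numeric epsilon is ever added to
#' the data.  The construction frames the signal with sentinels
#' \eqn{f(0) = +\infty} and \eqn{f(n+1) = -\infty}, so a monotone increasing
#' ramp contributes one pair while a decreasing one contributes none.
#'
#' All indices are 1-based positions into the signal, matching the usual
#' time-series convention.
#'
#' @name persistence
NULL

new_persistence_diagram <- function(birth = numeric(), death = numeric(),
                                    min_index = integer(), max_index = integer()) {
  structure(
    data.frame(birth = as.numeric(birth), death = as.numeric(death),
               min_index = as.integer(min_index), max_index = as.integer(max_index)),
    class = c("persistence_diagram", "data.frame")
  )
}

#' Coerce to a persistence diagram
#'
#' Accepts a matrix or data frame with `birth` and `death` columns (or two
#' unnamed columns taken as birth and death) and returns a
#' `persistence_diagram` object.
#'
#' @param x matrix or data frame of diagram points.
#' @return A `persistence_diagram` (a data frame with columns `birth`,
#'   `death`, `min_index`, `max_index`; provenance indices are `NA` when
#'   unknown).
#' @export
as_persistence_diagram <- function(x) {
  if (inherits(x, "persistence_diagram")) return(x)
  m <- pd_matrix(x)
  if (is.data.frame(x) && all(c("min_index", "max_index") %in% names(x)))
    new_persistence_diagram(m[, 1], m[, 2], x$min_index, x$max_index)
  else if (is.matrix(x) && !is.null(colnames(x)) && all(c("min_index", "max_index") %in% colnames(x)))
    new_persistence_diagram(m[, 1], m[, 2], x[, "min_index"], x[, "max_index"])
  else
    new_persistence_diagram(m[, 1], m[, 2], rep(NA_integer_, nrow(m)), rep(NA_integer_, nrow(m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Internal: any diagram-like object -> numeric matrix with columns birth, death.
pd_matrix <- function(x) {
  if (inherits(x, "persistence_diagram") || is.data.frame(x)) {
    if (all(c("birth", "death") %in% names(x)))
      return(cbind(birth = as.numeric(x$birth), death = as.numeric(x$death)))
    x <- as.matrix(x)
  }
  if (is.matrix(x)) {
    if (!is.null(colnames(x)) && all(c("birth", "death") %in% colnames(x)))
      return(cbind(birth = as.numeric(x[, "birth"]), death = as.numeric(x[, "death"])))
    if (ncol(x) < 2 && nrow(x) > 0)
      stop_validation("a diagram matrix needs at least two columns (birth, death)")
    if (nrow(x) == 0) return(matrix(numeric(), 0, 2, dimnames = list(NULL, c("birth", "death"))))
    return(cbind(birth = as.numeric(x[, 1]), death = as.numeric(x[, 2])))
  }
  if (is.numeric(x) && length(x) == 2)  # a single point
    return(matrix(x, 1, 2, dimnames = list(NULL, c("birth", "death"))))
  if (is.null(x) || (is.numeric(x) && length(x) == 0))
    return(matrix(numeric(), 0, 2, dimnames = list(NULL, c("birth", "death"))))
  stop_validation("cannot interpret object of class '", class(x)[1], "' as a persistence diagram")
}

#' @export
print.persistence_diagram <- function(x, ...) {
  cat("Persistence diagram:", nrow(x), "point(s)\n")
  if (nrow(x) > 0) print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Tie-broken sample ordering
#'
#' The total order on sample positions `0..n+1` that underpins extremum
#' detection and pairing: position `i` precedes `j` when `f(i) < f(j)`, or
#' `f(i) = f(j)` and `i <= j`.  Positions `0` and `n+1` are sentinels with
#' values \eqn{+\infty} and \eqn{-\infty}.
#'
#' @param i,j sample positions in `0..length(signal)+1`.
#' @param signal numeric vector of finite values.
#' @return `TRUE` if `i` precedes (or equals) `j` in the tie-broken order.
#' @export
#' @examples
#' order_precedes(1, 2, c(5, 5))  # equal values: lower index first
order_precedes <- function(i, j, signal) {
  check_signal(signal)
  n <- length(signal)
  if (length(i) != 1L || length(j) != 1L || i != round(i) || j != round(j))
    stop_validation("i and j must be single integer positions")
  if (i < 0 || i > n + 1 || j < 0 || j > n + 1)
    stop_validation("positions must lie in 0..n+1 (0 and n+1 are sentinels)")
  val <- function(k) if (k == 0) Inf else if (k == n + 1) -Inf else signal[k]
  fi <- val(i); fj <- val(j)
  fi < fj || (fi == fj && i <= j)
}

#' Locate tie-broken local extrema
#'
#' Detects local minima and maxima of a signal under the tie-broken order,
#' with the \eqn{\pm\infty} sentinel convention at the boundaries: position
#' `i` is a minimum when it strictly precedes both neighbours, a maximum when
#' both neighbours strictly precede it.  The two sets always have the same
#' number of elements and alternate along the signal.
#'
#' @param signal numeric vector of finite values.
#' @return An object of class `extrema_set`: a list with integer vectors
#'   `minima` and `maxima` (1-based signal positions, each sorted ascending by
#'   the tie-broken `(value, index)` key) and the signal length `n`.
#' @export
#' @examples
#' find_extrema(c(0, 3, 1, 2))
find_extrema <- function(signal) {
  check_signal(signal)
  n <- length(signal)
  if (n == 0)
    return(structure(list(minima = integer(), maxima = integer(), n = 0L),
                     class = "extrema_set"))
  left <- c(Inf, signal[-n])
  right <- c(signal[-1], -Inf)
  # key(i) < key(i-1): ties lose against the left neighbour (lower index wins);
  # key(i) < key(i+1): ties win against the right neighbour.
  lt_left <- signal < left
  lt_right <- signal < right | signal == right
  minima <- which(lt_left & lt_right)
  maxima <- which(!lt_left & !lt_right)
  minima <- minima[order(signal[minima], minima)]
  maxima <- maxima[order(signal[maxima], maxima)]
  structure(list(minima = as.integer(minima), maxima = as.integer(maxima),
                 n = as.integer(n)),
            class = "extrema_set")
}

#' @export
print.extrema_set <- function(x, ...) {
  cat("Extrema set: r =", length(x$minima), "\n")
  cat("  minima (by key):", x$minima, "\n")
  cat("  maxima (by key):", x$maxima, "\n")
  invisible(x)
}

#' Pair extrema into a persistence diagram
#'
#' The inductive pairing rule: walk the maxima in ascending tie-broken order;
#' for the k-th maximum, among the not-yet-assigned minima lying strictly
#' below it, select the largest-key minimum such that no smaller-key candidate
#' sits strictly between the two positions.  The resulting pairs
#' \eqn{(f(a_{\sigma(k)}), f(b_k))} form the persistence diagram, and realize
#' the elder rule for the sublevel-set filtration.
#'
#' This is the literal reference implementation in R (quadratic in the number
#' of extrema, which is at most half the window length).
#' [compute_diagram()] runs the same algorithm in compiled code.
#'
#' @param signal numeric vector of finite values.
#' @param extrema an `extrema_set` for `signal`, from [find_extrema()].
#' @return A `persistence_diagram` with one point per minimum/maximum pair
#'   and provenance positions `min_index`, `max_index`.
#' @export
#' @examples
#' s <- c(0, 3, 1, 2)
#' pair_extrema(s, find_extrema(s))
pair_extrema <- function(signal, extrema) {
  check_signal(signal)
  if (!inherits(extrema, "extrema_set"))
    stop_validation("extrema must be an extrema_set from find_extrema()")
  a <- extrema$minima
  b <- extrema$maxima
  r <- length(a)
  if (length(b) != r)
    stop_validation("invalid extrema set: unequal numbers of minima and maxima")
  if (r == 0) return(new_persistence_diagram())
  key_lt <- function(vi, pi, vj, pj) vi < vj | (vi == vj & pi < pj)
  used <- logical(r)
  birth <- death <- numeric(r)
  mi <- ma <- integer(r)
  for (k in seq_len(r)) {
    bk <- b[k]; fbk <- signal[bk]
    cand <- which(!used & key_lt(signal[a], a, fbk, bk))
    if (length(cand) == 0)
      stop("internal error: empty candidate set in extrema pairing")
    chosen <- NA_integer_
    for (i in rev(cand)) {  # descending key order; first admissible = max
      lo <- min(a[i], bk); hi <- max(a[i], bk)
      js <- cand[cand < i]
      if (!any(a[js] > lo & a[js] < hi)) { chosen <- i; break }
    }
    used[chosen] <- TRUE
    birth[k] <- signal[a[chosen]]; death[k] <- fbk
    mi[k] <- a[chosen]; ma[k] <- bk
  }
  new_persistence_diagram(birth, death, mi, ma)
}

#' Persistence diagram of a signal
#'
#' Computes the 0-dimensional sublevel-set persistence diagram of a discrete
#' signal by the extrema-ordering and pairing construction (see
#' [find_extrema()] and [pair_extrema()]); the computation runs in compiled
#' code and is deterministic.  Empty and length-1 signals yield an empty
#' diagram, so windowed pipelines never fail on degenerate content.
#'
#' @param signal numeric vector of finite values (activity counts).
#' @return A `persistence_diagram`.
#' @export
#' @examples
#' compute_diagram(c(0, 3, 1, 2))
#' compute_diagram(numeric(0))
compute_diagram <- function(signal) {
  check_signal(signal)
  if (length(signal) == 0) return(new_persistence_diagram())
  m <- cpp_diagram(as.numeric(signal))
  new_persistence_diagram(m[, "birth"], m[, "death"], m[, "min_index"], m[, "max_index"])
}

#' Barcode representation of a diagram
#'
#' One `[birth, death]` interval per diagram point, sorted by birth then
#' death; the conversion is lossless up to point order.
#'
#' @param diagram a `persistence_diagram` (or anything [as_persistence_diagram()]
#'   accepts).
#' @return A numeric matrix with columns `birth` and `death`, one row per bar.
#' @export
#' @examples
#' diagram_to_barcode(compute_diagram(c(0, 3, 1, 2)))
diagram_to_barcode <- function(diagram) {
  m <- pd_matrix(diagram)
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}
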