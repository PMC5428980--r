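#' Distances between persistence diagrams
#'
#' Three ways to compare the diagrams of two windows.  The Hausdorff distance
#' takes the worst point-to-set Euclidean distance in either direction; the
#' modified Hausdorff semimetric replaces each directional supremum with an
#' average, trading the triangle inequality for robustness to outlying
#' points; the q-Wasserstein distance is the optimal-assignment cost with the
#' \eqn{L_\infty} ground metric, where any point may instead be retired to
#' its nearest diagonal point \eqn{y = x} at cost (death - birth)/2, so that
#' near-diagonal noise contributes little.
#'
#' Empty diagrams arise from monotone-decreasing windows.  Policy: two empty
#' diagrams are at distance 0; when exactly one side is empty, the Hausdorff
#' variants measure the nonempty side against the diagonal (supremum or
#' average of Euclidean point-to-diagonal distances), and the Wasserstein
#' distance needs no special case because diagonal augmentation already
#' covers it.
#'
#' @name diagram_distances
NULL

#' Ground distance between two diagram points
#'
#' @param a,b numeric length-2 vectors `(birth, death)`.
#' @param ground `"euclidean"` (used inside the Hausdorff variants) or
#'   `"chebyshev"` (the \eqn{L_\infty} norm used inside the Wasserstein
#'   distance).
#' @return Nonnegative scalar distance.
#' @export
#' @examples
#' diagram_point_distance(c(0, 0), c(3, 4))               # 5
#' diagram_point_distance(c(0, 0), c(3, 4), "chebyshev")  # 4
diagram_point_distance <- function(a, b, ground = c("euclidean", "chebyshev")) {
  ground <- match.arg(ground)
  if (length(a) != 2L || length(b) != 2L)
    stop_validation("diagram points are (birth, death) pairs")
  if (ground == "euclidean") sqrt(sum((a - b)^2)) else max(abs(a - b))
}

#' Directed average distance from one diagram to another
#'
#' The mean, over points of `A`, of the Euclidean distance to the nearest
#' point of `B` — the inner term of the modified Hausdorff semimetric.
#'
#' @param A,B nonempty persistence diagrams (or `(birth, death)` matrices).
#' @return Nonnegative scalar.
#' @export
directed_average_distance <- function(A, B) {
  a <- pd_matrix(A); b <- pd_matrix(B)
  if (nrow(a) == 0 || nrow(b) == 0)
    stop_validation("directed_average_distance requires nonempty diagrams")
  s <- 0
  for (i in seq_len(nrow(a))) {
    s <- s + sqrt(min((a[i, 1] - b[, 1])^2 + (a[i, 2] - b[, 2])^2))
  }
  s / nrow(a)
}

#' Modified Hausdorff semimetric between diagrams
#'
#' The maximum of the two directed average distances.  Symmetric and
#' nonnegative with `d(A, A) = 0`, but it does not satisfy the triangle
#' inequality (hence a semimetric).
#'
#' @inheritParams directed_average_distance
#' @return Nonnegative scalar.
#' @export
#' @examples
#' modified_hausdorff(rbind(c(0, 0), c(10, 0)), rbind(c(0, 0)))  # 5
modified_hausdorff <- function(A, B) {
  cpp_dmh(pd_matrix(A), pd_matrix(B))
}

#' Hausdorff distance between diagrams
#'
#' The maximum over both directions of the supremum of Euclidean
#' point-to-set distances; sensitive to single outlying points.
#'
#' @inheritParams directed_average_distance
#' @return Nonnegative scalar.
#' @export
#' @examples
#' hausdorff_distance(rbind(c(0, 0), c(10, 0)), rbind(c(0, 0)))  # 10
hausdorff_distance <- function(A, B) {
  cpp_hausdorff(pd_matrix(A), pd_matrix(B))
}

#' q-Wasserstein distance between diagrams
#'
#' Optimal matching between the two diagrams with diagonal augmentation:
#' every point may be matched either to a point of the other diagram (at
#' \eqn{L_\infty} cost) or to the diagonal (at cost (death - birth)/2).
#' Returns the q-norm of the optimal matching's costs, computed exactly by
#' the Hungarian algorithm.
#'
#' @inheritParams directed_average_distance
#' @param q Wasserstein order, a real `>= 1`; default 1.
#' @return Nonnegative scalar.
#' @export
#' @examples
#' wasserstein_distance(rbind(c(0, 2)), matrix(numeric(), 0, 2))  # 1
wasserstein_distance <- function(A, B, q = 1) {
  if (length(q) != 1L || is.na(q) || q < 1)
    stop_config("Wasserstein order q must be a single number >= 1")
  cpp_wasserstein(pd_matrix(A), pd_matrix(B), q)
}

#' Window-by-window distance signal
#'
#' Compares two diagram sequences window by window (first window against
#' first, second against second, ...), producing a new signal of distances
#' over time.  Two 350-window sequences yield a 350-point distance signal.
#'
#' @param seqA,seqB `diagram_sequence` objects of equal length and window
#'   length, from [windowed_diagrams()].
#' @param metric one of `"modified_hausdorff"` (default), `"hausdorff"`,
#'   `"wasserstein"`.
#' @param q Wasserstein order (ignored by the Hausdorff variants).
#' @return An object of class `distance_signal`: list with `values`
#'   (nonnegative numeric, one per window pair), `metric`, `window_length`,
#'   `id_a`, `id_b`.
#' @export
distance_signal <- function(seqA, seqB,
                            metric = c("modified_hausdorff", "hausdorff", "wasserstein"),
                            q = 1) {
  metric <- match.arg(metric)
  if (!inherits(seqA, "diagram_sequence") || !inherits(seqB, "diagram_sequence"))
    stop_validation("seqA and seqB must be diagram_sequence objects")
  if (length(seqA) != length(seqB))
    stop_validation("diagram sequences have different lengths (",
                    length(seqA), " vs ", length(seqB), ")")
  if (seqA$window_length != seqB$window_length)
    stop_validation("diagram sequences have different window lengths")
  if (length(q) != 1L || is.na(q) || q < 1)
    stop_config("Wasserstein order q must be a single number >= 1")
  code <- match(metric, c("modified_hausdorff", "hausdorff", "wasserstein")) - 1L
  vals <- cpp_distance_signal(seqA$diagrams, seqB$diagrams, code, q)
  structure(list(values = vals, metric = metric,
                 window_length = seqA$window_length,
                 id_a = seqA$id, id_b = seqB$id),
            class = "distance_signal")
}

#' @export
length.distance_signal <- function(x) length(x$values)

#' @export
print.distance_signal <- function(x, ...) {
  cat("Distance signal (", x$metric, "): ", length(x$values), " window(s), mean ",
      format(mean(x$values)), "\n", sep = "")
  invisible(x)
}

#' Mean of a distance signal
#'
#' The arithmetic mean over windows — the single number summarizing how far
#' apart two signals are, used as the pairwise value in cohort analyses.
#'
#' @param ds a `distance_signal` (or a nonempty numeric vector).
#' @return Scalar mean distance.
#' @export
mean_distance <- function(ds) {
  v <- if (inherits(ds, "distance_signal")) ds$values else ds
  if (!is.numeric(v) || length(v) == 0)
    stop_validation("mean_distance requires a nonempty distance signal")
  mean(v)
}
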