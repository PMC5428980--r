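#' Rectangular windowing of a signal
#'
#' Splits a signal into consecutive, non-overlapping windows of exactly
#' `window_length` samples (no tapering); a trailing partial window is
#' dropped.  A 7000-minute activity signal at the default window length of 20
#' yields 350 windows.
#'
#' @param signal numeric vector of finite values.
#' @param window_length integer number of samples per window (>= 2);
#'   default 20.
#' @return A list of numeric vectors, each of length `window_length`, in
#'   temporal order.  A warning is emitted when the signal is shorter than one
#'   window (empty result).
#' @export
#' @examples
#' length(segment_signal(rnorm(7000), 20))  # 350
segment_signal <- function(signal, window_length = 20L) {
  check_signal(signal)
  window_length <- check_window_length(window_length)
  nw <- length(signal) %/% window_length
  if (nw == 0) {
    warning("signal shorter than one window: returning zero windows")
    return(list())
  }
  lapply(seq_len(nw) - 1L, function(k) signal[(k * window_length + 1L):((k + 1L) * window_length)])
}

check_window_length <- function(window_length) {
  if (length(window_length) != 1L || is.na(window_length) ||
      window_length != round(window_length) || window_length < 2)
    stop_config("window_length must be a single integer >= 2")
  as.integer(window_length)
}

#' Per-window persistence diagrams
#'
#' Computes one persistence diagram per rectangular window of the signal.
#' Windows carry no state across boundaries: permuting whole windows permutes
#' the diagrams identically.
#'
#' @inheritParams segment_signal
#' @param id optional identifier of the source signal (participant id).
#' @return An object of class `diagram_sequence`: a list with `diagrams` (a
#'   list of per-window diagram matrices with columns `birth`, `death`,
#'   `min_index`, `max_index`; indices are window-local), `window_length`,
#'   `offsets` (0-based start offset of each window), and `id`.  Use
#'   [as_persistence_diagram()] on an element of `diagrams` for a typed
#'   diagram.
#' @export
#' @examples
#' ds <- windowed_diagrams(rnorm(100), window_length = 20)
#' length(ds)  # 5
windowed_diagrams <- function(signal, window_length = 20L, id = NULL) {
  check_signal(signal)
  window_length <- check_window_length(window_length)
  nw <- length(signal) %/% window_length
  if (nw == 0) warning("signal shorter than one window: empty diagram sequence")
  diagrams <- if (nw == 0) list() else cpp_windowed_diagrams(as.numeric(signal), window_length)
  structure(list(diagrams = diagrams,
                 window_length = window_length,
                 offsets = (seq_len(nw) - 1L) * window_length,
                 id = id),
            class = "diagram_sequence")
}

#' @export
length.diagram_sequence <- function(x) length(x$diagrams)

#' @export
print.diagram_sequence <- function(x, ...) {
  cat("Diagram sequence:", length(x$diagrams), "window(s) of length",
      x$window_length, if (!is.null(x$id)) paste0("[", x$id, "]"), "\n")
  invisible(x)
}
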