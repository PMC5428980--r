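#' Minute-level CSV input and inclusion filtering
#'
#' Armband recordings arrive as long-format CSV tables: one row per
#' participant-minute, with either three axis columns (transverse, forward,
#' longitudinal peak counts) or a single pre-summed `counts` column.  The
#' three axis counts are summed each minute into one movement profile per
#' participant; profiles shorter than the inclusion length (default 7000
#' minutes) are excluded, and the survivors are cropped to exactly that
#' length so every analyzed signal is the same size.
#'
#' @name io_cli
NULL

#' Read a minute-level activity CSV
#'
#' Accepts either the 3-axis schema (`participant_id`, `minute_index`,
#' `transverse`, `forward`, `longitudinal`) or the pre-summed schema
#' (`participant_id`, `minute_index`, `counts`); column names can be remapped
#' via `col_map`.  Validates numeric nonnegative counts, no duplicate
#' (participant, minute) rows, and per-participant minute indices that are
#' contiguous and ascending starting at 1; violations are reported with the
#' offending rows.
#'
#' @param path CSV file with a header row.
#' @param col_map optional named character vector renaming file columns to
#'   canonical names, e.g. `c(id = "participant_id", t = "transverse")`
#'   maps file column `id` to `participant_id`.
#' @return The validated data frame (canonical column names), with an
#'   attribute `schema` equal to `"axes"` or `"summed"`.
#' @export
read_minute_csv <- function(path, col_map = NULL) {
  if (!file.exists(path)) stop_validation("file not found: ", path)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(col_map)) {
    if (is.null(names(col_map))) stop_config("col_map must be a named character vector")
    m <- match(names(col_map), names(tab))
    if (anyNA(m))
      stop_config("col_map names not present in file: ",
                  paste(names(col_map)[is.na(m)], collapse = ", "))
    names(tab)[m] <- unname(col_map)
  }
  axes <- c("transverse", "forward", "longitudinal")
  need <- c("participant_id", "minute_index")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop_validation("missing required column(s): ", paste(miss, collapse = ", "))
  schema <- if (all(axes %in% names(tab))) "axes"
            else if ("counts" %in% names(tab)) "summed"
            else stop_validation("need either the three axis columns (",
                                 paste(axes, collapse = ", "), ") or a 'counts' column")
  count_cols <- if (schema == "axes") axes else "counts"
  for (cc in count_cols) {
    v <- tab[[cc]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))
      stop_validation("non-numeric values in column '", cc, "' (rows ",
                      paste(utils::head(bad, 5), collapse = ", "), ")")
    }
    if (anyNA(v) || any(v < 0)) {
      bad <- which(is.na(v) | v < 0)
      stop_validation("missing or negative counts in column '", cc, "' (rows ",
                      paste(utils::head(bad, 5), collapse = ", "), ")")
    }
  }
  if (!is.numeric(tab$minute_index) || anyNA(tab$minute_index))
    stop_validation("minute_index must be numeric and complete")
  key <- paste(tab$participant_id, tab$minute_index)
  if (anyDuplicated(key)) {
    bad <- which(duplicated(key))
    stop_validation("duplicate (participant, minute) rows: ",
                    paste(utils::head(bad, 5), collapse = ", "))
  }
  for (id in unique(tab$participant_id)) {
    m <- sort(tab$minute_index[tab$participant_id == id])
    if (!identical(as.integer(m), seq_len(length(m))))
      stop_validation("minute_index for participant '", id,
                      "' is not contiguous ascending from 1")
  }
  attr(tab, "schema") <- schema
  tab
}

#' Combine axis counts into per-participant signals
#'
#' For the 3-axis schema, sums the transverse, forward, and longitudinal
#' counts each minute; the pre-summed schema passes through.  Rows are
#' ordered by minute within participant.
#'
#' @param table validated table from [read_minute_csv()].
#' @return Named list of numeric signals, one per participant.
#' @export
combine_axes <- function(table) {
  if (!is.data.frame(table) || is.null(attr(table, "schema")))
    stop_validation("table must come from read_minute_csv()")
  counts <- if (attr(table, "schema") == "axes")
    table$transverse + table$forward + table$longitudinal
  else table$counts
  if (any(counts < 0)) stop_validation("negative counts")
  ord <- order(table$participant_id, table$minute_index)
  split(counts[ord], table$participant_id[ord])
}

#' Inclusion filtering and cropping
#'
#' Drops signals shorter than `min_length` samples and crops the survivors
#' to exactly `min_length`, yielding a uniform-length cohort.  Decisions are
#' reported via `message()`.
#'
#' @param signals named list of numeric signals.
#' @param min_length minimum (and final) signal length; default 7000.
#' @return List with `signals` (named list, each of length `min_length`) and
#'   `excluded` (data frame `participant_id`, `length`).
#' @export
apply_inclusion <- function(signals, min_length = 7000L) {
  if (!is.list(signals)) stop_validation("signals must be a (named) list")
  if (length(min_length) != 1L || is.na(min_length) || min_length < 1)
    stop_config("min_length must be a positive integer")
  lens <- vapply(signals, length, integer(1))
  keep <- lens >= min_length
  if (any(!keep))
    message(sum(!keep), " participant(s) excluded (< ", min_length, " minutes): ",
            paste(names(signals)[!keep], collapse = ", "))
  out <- lapply(signals[keep], function(s) s[seq_len(min_length)])
  if (length(out) == 0) warning("no signal satisfies the inclusion length")
  message(length(out), " participant(s) included at ", min_length, " minutes")
  list(signals = out,
       excluded = data.frame(participant_id = names(signals)[!keep],
                             length = unname(lens[!keep]),
                             stringsAsFactors = FALSE))
}

#' Read participant labels
#'
#' Two layouts are accepted: explicit labels (`participant_id,label` with
#' tokens success/failure/indeterminate) or weight trajectories
#' (`participant_id,w1,w2[,w3]`), from which labels are derived via
#' [assign_outcome_label()].
#'
#' @param path CSV file.
#' @return Named character vector of labels.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop_validation("file not found: ", path)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  if (!"participant_id" %in% names(tab))
    stop_validation("labels file needs a participant_id column")
  if (anyDuplicated(tab$participant_id)) {
    dup <- unique(tab$participant_id[duplicated(tab$participant_id)])
    stop_validation("duplicate participant ids in labels file: ",
                    paste(dup, collapse = ", "))
  }
  if ("label" %in% names(tab)) {
    bad <- setdiff(unique(tab$label), c("success", "failure", "indeterminate"))
    if (length(bad)) stop_validation("unknown label token(s): ", paste(bad, collapse = ", "))
    labels <- tab$label
  } else if (all(c("w1", "w2") %in% names(tab))) {
    w3 <- if ("w3" %in% names(tab)) tab$w3 else NA_real_
    labels <- assign_outcome_label(tab$w1, tab$w2, w3)
  } else {
    stop_validation("labels file needs either a 'label' column or 'w1','w2'[,'w3'] columns")
  }
  names(labels) <- as.character(tab$participant_id)
  labels
}

#' Assemble participant records
#'
#' Joins uniform-length signals with labels into the record list consumed by
#' the cohort functions; ids present in only one of the two inputs raise a
#' validation error.
#'
#' @param signals named list of numeric signals (see [apply_inclusion()]).
#' @param labels named character vector (see [read_labels()]).
#' @return List of [participant_record()] objects.
#' @export
records_from_tables <- function(signals, labels) {
  miss <- setdiff(names(signals), names(labels))
  if (length(miss)) stop_validation("no label for participant(s): ", paste(miss, collapse = ", "))
  lapply(names(signals), function(id)
    participant_record(id, signals[[id]], labels[[id]]))
}

#' Write a persistence diagram as CSV
#'
#' @param diagram a `persistence_diagram`.
#' @param path output file; columns `birth,death,min_index,max_index`.
#' @export
write_diagram_csv <- function(diagram, path) {
  d <- as_persistence_diagram(diagram)
  write.csv(as.data.frame(d), path, row.names = FALSE)
  invisible(path)
}

#' Run manifest
#'
#' A machine-readable record of a run — package version, R version,
#' configuration, seed, and MD5 digests of the input files — sufficient to
#' reproduce the outputs.
#'
#' @param config named list of configuration values (should include the
#'   seed).
#' @param inputs character vector of input file paths.
#' @param path optional file to write the manifest JSON to.
#' @return The manifest as a list (invisibly when `path` is given).
#' @export
run_manifest <- function(config = list(), inputs = character(), path = NULL) {
  man <- list(
    package = "actiph",
    version = as.character(utils::packageVersion("actiph")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = config,
    inputs = if (length(inputs))
      data.frame(path = inputs, md5 = unname(tools::md5sum(inputs)),
                 stringsAsFactors = FALSE)
    else NULL
  )
  if (!is.null(path)) {
    jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
    return(invisible(man))
  }
  man
}
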