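# Trial-bundle and result-table I/O. A trial bundle is a directory with
# metadata.json, forces.csv (time_s, LF_N, RF_N, LH_N, RH_N) and markers.csv
# (time_s, <marker>_{x,y,z}_m); synthetic bundles additionally carry the
# ground-truth events inside metadata.json.

FORCE_COLS <- c("time_s", "LF_N", "RF_N", "LH_N", "RH_N")

#' Write a trial bundle to disk
#'
#' @param trial an `eq_trial`.
#' @param path bundle directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_trial <- function(trial, path) {
  stopifnot(inherits(trial, "eq_trial"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  meta <- trial$meta
  if (!is.null(trial$ground_truth)) {
    meta$ground_truth <- list(
      events = lapply(trial$ground_truth$events, function(ev) {
        list(on = unname(ev[, "on"]), off = unname(ev[, "off"]))
      }),
      stride_starts = trial$ground_truth$stride_starts,
      stride_durations = trial$ground_truth$stride_durations
    )
  }
  jsonlite::write_json(meta, file.path(path, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  readr::write_csv(trial$forces, file.path(path, "forces.csv"))
  readr::write_csv(trial$markers, file.path(path, "markers.csv"))
  invisible(path)
}

check_time_column <- function(df, file) {
  if (!"time_s" %in% names(df)) {
    stop("format error in ", file, ": missing column time_s")
  }
  if (any(diff(df$time_s) <= 0)) {
    stop("format error in ", file, ": time_s is not strictly increasing")
  }
}

#' Read a trial bundle from disk
#'
#' Round-trips with [write_trial()] losslessly to the declared numeric
#' precision (1e-6 N / 1e-6 m). Missing files, missing columns and
#' non-monotonic time stamps raise format errors naming the offending
#' file/column.
#'
#' @param path bundle directory.
#' @return an `eq_trial`.
#' @export
read_trial <- function(path) {
  files <- file.path(path, c("metadata.json", "forces.csv", "markers.csv"))
  missing <- files[!file.exists(files)]
  if (length(missing) > 0) {
    stop("trial bundle incomplete, missing: ",
         paste(basename(missing), collapse = ", "))
  }
  meta <- jsonlite::read_json(files[1], simplifyVector = TRUE)
  forces <- readr::read_csv(files[2], show_col_types = FALSE,
                            progress = FALSE)
  absent <- setdiff(FORCE_COLS, names(forces))
  if (length(absent) > 0) {
    stop("format error in forces.csv: missing column ",
         paste(absent, collapse = ", "))
  }
  check_time_column(forces, "forces.csv")
  markers <- readr::read_csv(files[3], show_col_types = FALSE,
                             progress = FALSE)
  check_time_column(markers, "markers.csv")
  gt <- NULL
  if (!is.null(meta$ground_truth)) {
    g <- meta$ground_truth
    gt <- list(events = lapply(g$events, function(ev) {
      cbind(on = ev$on, off = ev$off)
    }),
    stride_starts = g$stride_starts,
    stride_durations = g$stride_durations)
    meta$ground_truth <- NULL
  }
  structure(list(meta = meta, forces = forces, markers = markers,
                 ground_truth = gt), class = "eq_trial")
}

RESULT_KEY <- c("horse_id", "gait", "condition", "stride_index", "variable")

#' Write a long-format result table
#'
#' Rows are sorted deterministically by (horse, gait, condition, stride,
#' variable); duplicate keys are an error.
#'
#' @param records tibble with columns `horse_id`, `gait`, `condition`,
#'   `stride_index`, `variable`, `value`, `units`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(records, path) {
  needed <- c(RESULT_KEY, "value", "units")
  stopifnot(all(needed %in% names(records)))
  key <- do.call(paste, c(records[RESULT_KEY], sep = "\r"))
  if (anyDuplicated(key)) {
    stop("duplicate (horse, gait, condition, stride, variable) keys in results")
  }
  extra <- setdiff(names(records), needed)
  records <- records[do.call(order, records[RESULT_KEY]),
                     c(needed, extra), drop = FALSE]
  readr::write_csv(records, path)
  invisible(path)
}

#' Read a long-format result table
#' @param path CSV path written by [write_results()].
#' @return tibble.
#' @export
read_results <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
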