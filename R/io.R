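#' Read spike trains from a text or CSV file
#'
#' Two plain-text layouts are supported: `"txt"`, one event time (seconds,
#' decimal) per line, giving a single train; and `"csv"`, a two-column
#' headered file `trial_id,time_s`, giving one train per trial id.
#'
#' @param path File to read.
#' @param format `"txt"` or `"csv"`; guessed from the extension when
#'   missing.
#' @param duration Recording duration, s; when `NULL` the maximum time is
#'   rounded up to the next integer second.
#' @return A list of [spike_train] objects (length one for `"txt"`).
#' @examples
#' f <- tempfile(fileext = ".txt")
#' writeLines(c("0.5", "1.0"), f)
#' read_spike_trains(f, duration = 2)
#' @export
read_spike_trains <- function(path, format = NULL, duration = NULL) {
  if (!file.exists(path)) rlang::abort(sprintf("file not found: %s", path))
  if (is.null(format)) {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "txt"
  }
  format <- match.arg(format, c("txt", "csv"))
  if (format == "txt") {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) rlang::abort(sprintf("empty spike file: %s", path))
    times <- suppressWarnings(as.numeric(lines))
    if (anyNA(times)) {
      rlang::abort(sprintf("non-numeric spike time at line %d of %s",
                           which(is.na(times))[1], path))
    }
    bad <- which(times <= 0)
    if (length(bad)) {
      rlang::abort(sprintf("non-positive spike time at line %d of %s",
                           bad[1], path))
    }
    if (is.unsorted(times, strictly = TRUE)) {
      rlang::abort(sprintf("unsorted or tied spike times in %s (line %d)",
                           path, which(diff(times) <= 0)[1] + 1L))
    }
    dur <- duration %||% ceiling(max(times))
    return(list(spike_train(times, dur)))
  }
  df <- utils::read.csv(path)
  need <- c("trial_id", "time_s")
  if (!all(need %in% names(df))) {
    rlang::abort(sprintf("csv spike file %s must have columns %s",
                         path, paste(need, collapse = ", ")))
  }
  if (!nrow(df)) rlang::abort(sprintf("empty spike file: %s", path))
  dur <- duration %||% ceiling(max(df$time_s))
  lapply(split(df$time_s, df$trial_id),
         function(tt) spike_train(sort(tt), dur))
}

#' Write spike trains
#'
#' Single trains are written one time per line (`"txt"`); a list of trains
#' is written as a headered `trial_id,time_s` CSV.  Times are printed with
#' nine decimal places, so a write/read round trip is lossless to 1 ns.
#'
#' @param trains A [spike_train] or list of them.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_spike_trains <- function(trains, path) {
  if (inherits(trains, "spike_train")) {
    writeLines(sprintf("%.9f", trains$times), path)
    return(invisible(path))
  }
  stopifnot(is.list(trains),
            all(vapply(trains, inherits, logical(1), "spike_train")))
  df <- dplyr::bind_rows(purrr::imap(trains, function(st, i) {
    tibble::tibble(trial_id = if (is.character(i)) i else as.integer(i),
                   time_s = sprintf("%.9f", st$times))
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a rate / bandwidth curve as CSV
#'
#' Rate curves become `time_s,rate_hz`; bandwidth curves
#' `time_s,bandwidth_s`; full BAKS fits `time_s,bandwidth_s,rate_hz`.
#' Deterministic fixed-decimal formatting (9 places).
#'
#' @param curve A `rate_curve`, `bandwidth_curve` or `baks_fit` tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  stopifnot(is.data.frame(curve))
  if (!nrow(curve)) rlang::abort("cannot write an empty curve.")
  cols <- c(time_s = "time")
  if ("bandwidth" %in% names(curve)) cols <- c(cols, bandwidth_s = "bandwidth")
  if ("rate" %in% names(curve)) cols <- c(cols, rate_hz = "rate")
  if (length(cols) < 2L) {
    rlang::abort("curve must have a `rate` or `bandwidth` column.")
  }
  df <- as.data.frame(lapply(cols, function(cn) sprintf("%.9f", curve[[cn]])))
  names(df) <- names(cols)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a curve CSV written by [write_curve()]
#'
#' @param path File to read.
#' @return A tibble with `time` plus `bandwidth` and/or `rate` columns.
#' @export
read_curve <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("file not found: %s", path))
  df <- utils::read.csv(path)
  out <- tibble::tibble(time = df$time_s)
  if ("bandwidth_s" %in% names(df)) out$bandwidth <- df$bandwidth_s
  if ("rate_hz" %in% names(df)) out$rate <- df$rate_hz
  out
}
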