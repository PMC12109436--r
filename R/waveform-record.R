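#' Construct a multichannel waveform record
#'
#' A waveform record is the lingua franca between every stage of the
#' pipeline: a tibble with a uniform `time_s` column, the four flow channels
#' (`q_upper`, `q_lower`, `q_rpa`, `q_lpa`, in L/min) and the five pressure
#' channels (`p_upper`, `p_lower`, `p_rpa`, `p_lpa`, `p_aortic`, in mmHg),
#' plus a sampling rate and free-form metadata carried as attributes.
#'
#' @param data Data frame with a `time_s` column and the nine channel
#'   columns.
#' @param sampling_rate Sampling rate in Hz; must match the spacing of
#'   `time_s`.
#' @param metadata Named list of provenance metadata (pump settings,
#'   protocol case, seed, `provenance` tag: one of `"simulated"`,
#'   `"filtered"`, `"external"`).
#'
#' @return A tibble of subclass `mfl_record`.
#' @export
mfl_record <- function(data, sampling_rate, metadata = list()) {
  data <- as_tibble(data)
  missing_cols <- setdiff(c("time_s", .ALL_CHANNELS), names(data))
  if (length(missing_cols) > 0) {
    .fj_abort(paste0("record is missing channel column(s): ",
                     paste(missing_cols, collapse = ", ")),
              "fontanjet_format_error")
  }
  data <- data[, c("time_s", .ALL_CHANNELS)]
  .check_uniform_time(data$time_s, sampling_rate)
  out <- new_tibble(data, class = "mfl_record", nrow = nrow(data))
  attr(out, "sampling_rate") <- sampling_rate
  attr(out, "units") <- c(
    setNames(rep("L/min", length(.FLOW_CHANNELS)), .FLOW_CHANNELS),
    setNames(rep("mmHg", length(.PRESSURE_CHANNELS)), .PRESSURE_CHANNELS)
  )
  attr(out, "metadata") <- metadata
  out
}

.check_uniform_time <- function(time_s, sampling_rate) {
  if (length(time_s) < 2L) {
    .fj_abort("record must contain at least two samples",
              "fontanjet_format_error")
  }
  dt <- diff(time_s)
  if (any(abs(dt - 1 / sampling_rate) > 1e-6 / sampling_rate + 1e-9)) {
    .fj_abort("time base is not uniform at the declared sampling rate",
              "fontanjet_format_error")
  }
  n <- length(time_s)
  if (abs(sampling_rate * (time_s[n] - time_s[1]) - (n - 1)) > 0.5) {
    .fj_abort("sampling_rate is inconsistent with the record extent",
              "fontanjet_format_error")
  }
  invisible(TRUE)
}

#' @rdname mfl_record
#' @param record An `mfl_record`.
#' @export
record_sampling_rate <- function(record) {
  attr(record, "sampling_rate", exact = TRUE)
}

#' @rdname mfl_record
#' @export
record_metadata <- function(record) {
  attr(record, "metadata", exact = TRUE) %||% list()
}

# cardiac period (s) carried by the record, falling back to 80 bpm
.record_period <- function(record) {
  hr <- record_metadata(record)$heart_rate %||% 80
  60 / hr
}

#' @export
print.mfl_record <- function(x, ...) {
  md <- record_metadata(x)
  cat(sprintf("<mfl_record> %d samples @ %g Hz (%.2f s), provenance: %s\n",
              nrow(x), record_sampling_rate(x),
              x$time_s[nrow(x)] - x$time_s[1],
              md$provenance %||% "unknown"))
  NextMethod()
}

#' Write or read a waveform record as annotated CSV
#'
#' The CSV dialect stores metadata in header lines beginning `#` as
#' `key=value` pairs (scalars only), followed by a regular CSV table whose
#' first column is `time_s`. Channel columns may appear in any order in a
#' file being read; the parsed record is always in canonical order. The
#' round trip `read_waveform_csv(write_waveform_csv(x))` reproduces `x` to
#' float precision.
#'
#' @param record An [mfl_record()].
#' @param path File path.
#' @return `write_waveform_csv()` returns `path` invisibly;
#'   `read_waveform_csv()` returns an [mfl_record()].
#' @export
write_waveform_csv <- function(record, path) {
  md <- record_metadata(record)
  md$sampling_rate <- record_sampling_rate(record)
  scalars <- md[vapply(md, function(v) is.atomic(v) && length(v) == 1L,
                       logical(1))]
  header <- sprintf("# %s=%s", names(scalars),
                    vapply(scalars, function(v) format(v, digits = 17),
                           character(1)))
  writeLines(header, path)
  readr::write_csv(as_tibble(as.data.frame(record)), path, append = TRUE,
                   col_names = TRUE)
  invisible(path)
}

#' @rdname write_waveform_csv
#' @export
read_waveform_csv <- function(path) {
  lines <- readLines(path)
  is_meta <- startsWith(lines, "#")
  meta_lines <- sub("^#\\s*", "", lines[is_meta & seq_along(lines) <=
                                          which(!is_meta)[1]])
  kv <- strsplit(meta_lines, "=", fixed = TRUE)
  metadata <- list()
  for (pair in kv) {
    if (length(pair) != 2L) next
    val <- pair[2]
    num <- suppressWarnings(as.numeric(val))
    metadata[[trimws(pair[1])]] <- if (!is.na(num)) num else val
  }
  if (is.null(metadata$sampling_rate)) {
    .fj_abort("waveform CSV lacks a sampling_rate metadata line",
              "fontanjet_format_error")
  }
  body <- readr::read_csv(I(lines[!is_meta]), show_col_types = FALSE)
  dup <- names(body)[duplicated(names(body))]
  if (length(dup) > 0) {
    .fj_abort(paste0("duplicate channel column(s): ",
                     paste(unique(dup), collapse = ", ")),
              "fontanjet_format_error")
  }
  fs <- metadata$sampling_rate
  metadata$sampling_rate <- NULL
  mfl_record(body, sampling_rate = fs, metadata = metadata)
}
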