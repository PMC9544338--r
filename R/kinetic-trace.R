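#' One well's fluorescence time series
#'
#' Container for a single plate-reader trace together with its assay type and
#' injection metadata. Times must be strictly increasing and the signal finite;
#' at least 8 samples are required (fewer cannot support any of the fits).
#'
#' @param times Numeric vector of read times, seconds, strictly increasing.
#' @param signal Numeric vector of fluorescence readings, AU, same length.
#' @param assay_kind One of `"association"`, `"binding_hydrolysis"`,
#'   `"displacement"`.
#' @param injection_index Index (1-based) of the first reading at or after the
#'   displacement injection. Required iff `assay_kind = "displacement"`.
#' @param well_id Optional well identifier (e.g. `"A1"`).
#' @param meta Optional named list of free-form string metadata.
#'
#' @return An object of class `kinetic_trace`.
#' @examples
#' tr <- kinetic_trace(seq(0, 70, 10), 100 + (0:7) * 3, "association")
#' length(tr$times)
#' @export
kinetic_trace <- function(times, signal,
                          assay_kind = c("association", "binding_hydrolysis",
                                         "displacement"),
                          injection_index = NULL, well_id = NULL,
                          meta = list()) {
  assay_kind <- match.arg(assay_kind)
  times <- as.numeric(times)
  signal <- as.numeric(signal)
  if (length(times) < 8L) stop_invalid("a trace needs at least 8 samples")
  if (length(signal) != length(times)) {
    stop_invalid("times and signal must have the same length")
  }
  if (any(!is.finite(times)) || any(diff(times) <= 0)) {
    stop_invalid("times must be finite and strictly increasing")
  }
  if (any(!is.finite(signal))) stop_invalid("signal must be finite")
  if (assay_kind == "displacement") {
    if (is.null(injection_index)) {
      stop_invalid("displacement traces require injection_index")
    }
    injection_index <- as.integer(injection_index)
    if (injection_index < 1L || injection_index > length(times)) {
      stop_invalid("injection_index out of range")
    }
  } else if (!is.null(injection_index)) {
    stop_invalid("injection_index is only valid for displacement traces")
  }
  structure(list(times = times, signal = signal, assay_kind = assay_kind,
                 injection_index = injection_index, well_id = well_id,
                 meta = meta),
            class = "kinetic_trace")
}

#' @export
print.kinetic_trace <- function(x, ...) {
  cat(sprintf("<kinetic_trace> %s, %d reads over [%g, %g] s%s\n",
              x$assay_kind, length(x$times), min(x$times), max(x$times),
              if (is.null(x$well_id)) "" else paste0(", well ", x$well_id)))
  invisible(x)
}

#' Restrict a trace to an initial time window
#'
#' Keeps readings with `times - times[1] <= window_s`. Used by the screening
#' metrics (10-min window by default there).
#'
#' @param trace A [kinetic_trace()].
#' @param window_s Window length in seconds, measured from the first read.
#' @param as_kind Optional assay kind to relabel the windowed trace with
#'   (screening traces are binding+hydrolysis reads fit with the association
#'   model over the window).
#' @return A `kinetic_trace` covering the window.
#' @export
trace_window <- function(trace, window_s, as_kind = NULL) {
  stopifnot(inherits(trace, "kinetic_trace"))
  keep <- trace$times - trace$times[1] <= window_s + 1e-9
  if (sum(keep) < 8L) stop_invalid("window retains fewer than 8 samples")
  kinetic_trace(trace$times[keep], trace$signal[keep],
                assay_kind = as_kind %||% trace$assay_kind,
                well_id = trace$well_id, meta = trace$meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and write long-format trace CSVs
#'
#' The on-disk format is the package's interchange format for plate-reader
#' data: a header `well,time_s,signal` and one row per read. A file may hold
#' any number of wells.
#'
#' @param traces A single `kinetic_trace` or a list of them.
#' @param path CSV file path.
#' @param assay_kind Assay kind to stamp on traces read back in.
#' @param injection_index Optional injection index (recycled) for displacement
#'   reads.
#' @return `write_traces_csv()` returns `path` invisibly; `read_traces_csv()`
#'   returns a named list of `kinetic_trace` objects.
#' @export
write_traces_csv <- function(traces, path) {
  if (inherits(traces, "kinetic_trace")) traces <- list(traces)
  rows <- lapply(seq_along(traces), function(i) {
    tr <- traces[[i]]
    data.frame(well = tr$well_id %||% paste0("W", i),
               time_s = tr$times, signal = tr$signal)
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_traces_csv
#' @export
read_traces_csv <- function(path, assay_kind = "association",
                            injection_index = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("well", "time_s", "signal")
  if (!all(need %in% names(df))) {
    stop_invalid("trace CSV must have columns well,time_s,signal")
  }
  out <- lapply(split(df, df$well), function(d) {
    d <- d[order(d$time_s), ]
    kinetic_trace(d$time_s, d$signal, assay_kind = assay_kind,
                  injection_index = injection_index, well_id = d$well[1])
  })
  out[unique(df$well)]
}
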