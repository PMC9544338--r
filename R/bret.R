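#' Dual-channel BRET time series
#'
#' Holds donor (nanoluciferase) and acceptor (Venus) luminescence channels,
#' the computed acceptor/donor ratio, and the reading index of the agonist
#' injection (plus optionally a later antagonist injection). Indices are
#' 1-based reading indices, matching the convention that windows are defined
#' in readings, not wall-clock time; the agonist injection index is the first
#' post-injection reading and at least 10 readings must precede it.
#'
#' @param times Reading times, seconds.
#' @param donor Donor-channel counts.
#' @param acceptor Acceptor-channel counts.
#' @param injection_index Index of the first reading after agonist injection
#'   (>= 11 so that 10 readings precede it).
#' @param second_injection_index Optional index of the first reading after a
#'   second (antagonist) injection.
#' @return An object of class `bret_series` (ratio not yet populated; see
#'   [compute_ratio()]).
#' @export
bret_series <- function(times, donor, acceptor, injection_index,
                        second_injection_index = NULL) {
  times <- as.numeric(times); donor <- as.numeric(donor)
  acceptor <- as.numeric(acceptor)
  n <- length(times)
  if (length(donor) != n || length(acceptor) != n) {
    stop_invalid("times, donor and acceptor must have the same length")
  }
  if (any(diff(times) <= 0)) stop_invalid("times must be strictly increasing")
  injection_index <- as.integer(injection_index)
  if (injection_index < 11L || injection_index > n) {
    stop_invalid("injection_index must leave >= 10 pre-injection readings")
  }
  if (!is.null(second_injection_index)) {
    second_injection_index <- as.integer(second_injection_index)
    if (second_injection_index <= injection_index ||
        second_injection_index > n) {
      stop_invalid("second_injection_index must follow injection_index")
    }
  }
  structure(list(times = times, donor = donor, acceptor = acceptor,
                 ratio = NULL, injection_index = injection_index,
                 second_injection_index = second_injection_index,
                 n_dropped = 0L),
            class = "bret_series")
}

#' @export
print.bret_series <- function(x, ...) {
  cat(sprintf("<bret_series> %d readings, agonist at %d%s%s\n",
              length(x$times), x$injection_index,
              if (is.null(x$second_injection_index)) "" else
                sprintf(", antagonist at %d", x$second_injection_index),
              if (is.null(x$ratio)) " (ratio not computed)" else ""))
  invisible(x)
}

#' Compute the acceptor/donor BRET ratio
#'
#' Populates `ratio[i] = acceptor[i] / donor[i]`. Readings with non-positive
#' donor counts are dropped (their count is recorded in `n_dropped` and
#' reported via a message), and the injection indices are shifted accordingly.
#'
#' @param series A [bret_series()].
#' @return The series with `ratio` populated.
#' @export
compute_ratio <- function(series) {
  stopifnot(inherits(series, "bret_series"))
  bad <- series$donor <= 0
  if (all(bad)) stop_invalid("all readings dropped: no positive donor counts")
  if (any(bad)) {
    message(sprintf("compute_ratio: dropped %d reading(s) with non-positive donor",
                    sum(bad)))
    shift1 <- sum(bad[seq_len(series$injection_index - 1L)])
    series$injection_index <- series$injection_index - shift1
    if (!is.null(series$second_injection_index)) {
      shift2 <- sum(bad[seq_len(series$second_injection_index - 1L)])
      series$second_injection_index <- series$second_injection_index - shift2
    }
    series$times <- series$times[!bad]
    series$donor <- series$donor[!bad]
    series$acceptor <- series$acceptor[!bad]
    series$n_dropped <- sum(bad)
    if (series$injection_index < 11L) {
      stop_invalid("fewer than 10 pre-injection readings remain after dropping")
    }
  }
  series$ratio <- series$acceptor / series$donor
  if (any(!is.finite(series$ratio))) stop_invalid("non-finite BRET ratio")
  series
}

ensure_ratio <- function(series) {
  if (is.null(series$ratio)) compute_ratio(series) else series
}

#' Basal BRET level
#'
#' Arithmetic mean of the ratio over the 10 readings immediately preceding
#' the agonist injection (the nonstimulated heterotrimer level).
#'
#' @param series A [bret_series()] (ratio computed on demand).
#' @return The basal mean ratio (numeric scalar).
#' @export
basal_bret <- function(series) {
  series <- ensure_ratio(series)
  i <- series$injection_index
  if (i < 11L) stop_invalid("need >= 10 pre-injection readings")
  mean(series$ratio[(i - 10L):(i - 1L)])
}

#' Plateau ratio of the agonist-induced BRET decrease
#'
#' `plateau_ratio` = mean of the final 10 stimulated readings divided by the
#' mean of the 10 readings before agonist injection. Values below 1 indicate
#' heterotrimer dissociation. When an antagonist injection is present, the
#' stimulated segment ends just before it and `recovered` flags whether the
#' last 10 readings overall returned to basal within `tolerance`
#' (default 5%).
#'
#' @param series A [bret_series()].
#' @param tolerance Relative tolerance for the recovery flag.
#' @return A list of class `bret_summary` with `basal`, `plateau_ratio`,
#'   `recovered` (`NA` when no second injection).
#' @export
plateau_ratio <- function(series, tolerance = 0.05) {
  series <- ensure_ratio(series)
  n <- length(series$ratio)
  i <- series$injection_index
  basal <- basal_bret(series)
  stim_end <- if (is.null(series$second_injection_index)) n else
    series$second_injection_index - 1L
  if (stim_end - 9L < i) {
    stop_invalid("stimulated window overlaps the pre-injection window")
  }
  plateau <- mean(series$ratio[(stim_end - 9L):stim_end])
  recovered <- NA
  if (!is.null(series$second_injection_index)) {
    if (n - 9L <= series$second_injection_index) {
      stop_invalid("need >= 10 readings after the second injection")
    }
    final <- mean(series$ratio[(n - 9L):n])
    recovered <- abs(final / basal - 1) < tolerance
  }
  structure(list(basal = basal, plateau_ratio = plateau / basal,
                 recovered = recovered),
            class = "bret_summary")
}

#' @export
print.bret_summary <- function(x, ...) {
  cat(sprintf("<bret_summary> basal = %.4g, plateau_ratio = %.4g%s\n",
              x$basal, x$plateau_ratio,
              if (is.na(x$recovered)) "" else
                sprintf(", recovered = %s", x$recovered)))
  invisible(x)
}

#' BRET series CSV + JSON sidecar round trip
#'
#' The CSV holds `time_s,donor,acceptor`; injection indices travel in a JSON
#' sidecar (`{"injection_index": i, "second_injection_index": j}`).
#'
#' @param series A [bret_series()].
#' @param path CSV path; the sidecar is `paste0(path, ".json")`.
#' @return `path` invisibly (write) or a `bret_series` (read).
#' @export
write_bret_csv <- function(series, path) {
  utils::write.csv(data.frame(time_s = series$times, donor = series$donor,
                              acceptor = series$acceptor),
                   path, row.names = FALSE, quote = FALSE)
  side <- list(injection_index = series$injection_index)
  if (!is.null(series$second_injection_index)) {
    side$second_injection_index <- series$second_injection_index
  }
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_bret_csv
#' @export
read_bret_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"))
  bret_series(df$time_s, df$donor, df$acceptor,
              injection_index = side$injection_index,
              second_injection_index = side$second_injection_index)
}
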