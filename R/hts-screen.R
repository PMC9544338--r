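#' A screening plate: plate map plus per-well traces
#'
#' @param plate_id Plate identifier string.
#' @param map A data.frame with columns `well`, `role` (one of `"dmso"`,
#'   `"compound"`, `"empty"`), `compound_id`, `concentration_uM`.
#' @param traces Named list of [kinetic_trace()] objects, names matching
#'   `map$well` (empty wells may lack traces).
#' @param grid_tol Relative tolerance for the shared-time-grid check.
#' @return An object of class `screen_plate`.
#' @export
screen_plate <- function(plate_id, map, traces, grid_tol = 1e-6) {
  need <- c("well", "role", "compound_id", "concentration_uM")
  if (!all(need %in% names(map))) {
    stop_invalid("plate map needs columns well, role, compound_id, concentration_uM")
  }
  if (!all(map$role %in% c("dmso", "compound", "empty"))) {
    stop_invalid("roles must be dmso, compound or empty")
  }
  active <- map$well[map$role != "empty"]
  missing <- setdiff(active, names(traces))
  if (length(missing)) {
    stop_invalid(paste("traces missing for wells:",
                       paste(utils::head(missing, 5), collapse = ", ")))
  }
  ref <- traces[[active[1]]]$times
  same <- vapply(active, function(w) {
    tw <- traces[[w]]$times
    length(tw) == length(ref) &&
      max(abs(tw - ref)) <= grid_tol * max(abs(ref), 1)
  }, logical(1))
  if (!all(same)) stop_invalid("all traces must share the same time grid")
  structure(list(plate_id = plate_id, map = map, traces = traces),
            class = "screen_plate")
}

#' @export
print.screen_plate <- function(x, ...) {
  cat(sprintf("<screen_plate> %s: %d wells (%d dmso, %d compound, %d empty)\n",
              x$plate_id, nrow(x$map), sum(x$map$role == "dmso"),
              sum(x$map$role == "compound"), sum(x$map$role == "empty")))
  invisible(x)
}

#' Per-well screening metrics
#'
#' Computes the two screening read-outs over an initial window (10 min by
#' default, matching the screen's reaction time): `k_bind` from
#' [fit_k_bind()] applied to the windowed trace, and `max_uptake`, the
#' maximal rise of the signal above the first read within the window (AU).
#' A failed or degenerate rate fit leaves `k_bind` as `NA` (the well is still
#' scored on `max_uptake`).
#'
#' @param trace A [kinetic_trace()] covering the window.
#' @param window_s Screening window, seconds (default 600).
#' @param opts A [fit_opts()] list for the rate fit.
#' @return A list with `k_bind` and `max_uptake`.
#' @export
compute_well_metrics <- function(trace, window_s = 600, opts = fit_opts()) {
  wtr <- trace_window(trace, window_s, as_kind = "association")
  max_uptake <- max(wtr$signal) - wtr$signal[1]
  k_bind <- tryCatch({
    fit <- fit_k_bind(wtr, opts)
    if (fit$converged) fit$params$k_bind else NA_real_
  }, error = function(e) NA_real_)
  list(k_bind = k_bind, max_uptake = max_uptake)
}

plate_metrics <- function(plate, window_s = 600, opts = fit_opts()) {
  active <- plate$map[plate$map$role != "empty", , drop = FALSE]
  m <- lapply(active$well, function(w) {
    compute_well_metrics(plate$traces[[w]], window_s, opts)
  })
  data.frame(well = active$well, role = active$role,
             compound_id = active$compound_id,
             k_bind = vapply(m, `[[`, numeric(1), "k_bind"),
             max_uptake = vapply(m, `[[`, numeric(1), "max_uptake"))
}

#' DMSO control statistics for one metric
#'
#' Plain (non-robust) mean and sample SD of the chosen metric over the
#' plate's usable DMSO wells, computed per plate. At least 8 usable control
#' wells are required.
#'
#' @param plate A [screen_plate()].
#' @param metric `"k_bind"` or `"max_uptake"`.
#' @param window_s,opts Passed to [compute_well_metrics()].
#' @param metrics Optional precomputed metric table (internal reuse).
#' @return A list with `mean`, `sd`, `n`.
#' @export
control_stats <- function(plate, metric = c("k_bind", "max_uptake"),
                          window_s = 600, opts = fit_opts(), metrics = NULL) {
  metric <- match.arg(metric)
  metrics <- metrics %||% plate_metrics(plate, window_s, opts)
  v <- metrics[[metric]][metrics$role == "dmso"]
  v <- v[is.finite(v)]
  if (length(v) < 8L) {
    stop_invalid("fewer than 8 usable DMSO control wells",
                 class = "gok_insufficient_controls")
  }
  list(mean = mean(v), sd = stats::sd(v), n = length(v))
}

#' Call screening hits against the DMSO controls
#'
#' For each compound well and each metric, computes the z-distance from the
#' plate's DMSO mean in units of the DMSO SD and calls a hit when
#' `|z| >= threshold` — 2 SD for `k_bind`, 3 SD for `max_uptake` by default
#' (inclusive boundary, two-sided: compounds may modulate either direction).
#'
#' @param plate A [screen_plate()].
#' @param window_s Screening window, seconds.
#' @param kbind_sd,uptake_sd SD thresholds for the two metrics.
#' @param opts A [fit_opts()] list.
#' @return A data.frame of class `hit_calls`, one row per compound well and
#'   metric, with columns `well`, `compound_id`, `metric`, `value`,
#'   `control_mean`, `control_sd`, `z`, `direction`, `threshold_sd`, `is_hit`.
#' @export
call_hits <- function(plate, window_s = 600, kbind_sd = 2, uptake_sd = 3,
                      opts = fit_opts()) {
  metrics <- plate_metrics(plate, window_s, opts)
  thresholds <- c(k_bind = kbind_sd, max_uptake = uptake_sd)
  rows <- list()
  for (metric in names(thresholds)) {
    cs <- control_stats(plate, metric, metrics = metrics)
    if (cs$sd == 0) {
      stop_invalid(sprintf("zero control variance for %s", metric),
                   class = "gok_zero_variance")
    }
    cw <- metrics[metrics$role == "compound", , drop = FALSE]
    v <- cw[[metric]]
    keep <- is.finite(v)
    z <- (v[keep] - cs$mean) / cs$sd
    rows[[metric]] <- data.frame(
      well = cw$well[keep], compound_id = cw$compound_id[keep],
      metric = metric, value = v[keep],
      control_mean = cs$mean, control_sd = cs$sd, z = z,
      direction = ifelse(z >= 0, "up", "down"),
      threshold_sd = thresholds[[metric]],
      # inclusive boundary (>=), robust to 1-ulp rounding of z
      is_hit = abs(z) >= thresholds[[metric]] * (1 - 1e-12))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("hit_calls", class(out))
  out
}

#' Write hit calls as TSV
#' @param hits A `hit_calls` data.frame from [call_hits()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Plate map CSV round trip
#' @param map Plate map data.frame (columns `well`, `role`, `compound_id`,
#'   `concentration_uM`).
#' @param path CSV path.
#' @return The map (read) or `path` invisibly (write).
#' @export
write_plate_map_csv <- function(map, path) {
  utils::write.csv(map, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_plate_map_csv
#' @export
read_plate_map_csv <- function(path) {
  map <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("well", "role", "compound_id", "concentration_uM")
  if (!all(need %in% names(map))) {
    stop_invalid("plate map CSV must have columns well,role,compound_id,concentration_uM")
  }
  map
}

#' One-way ANOVA dose dependence of a fitted rate
#'
#' Tests the significance of the concentration dependence of a rate across a
#' dose series (the rescue-quantification statistic): a fixed-effects one-way
#' ANOVA of the rate values on the dose factor, plus a monotone-trend flag
#' (per-dose means non-decreasing, as for a restoration, or non-increasing).
#'
#' @param doses Concentration label per observation (uM); coerced to a factor.
#' @param values Rate values, either a numeric vector (one per dose entry) or
#'   a list of converged `fit_result`s from which `which` is extracted.
#' @param which Rate to extract when `values` holds fit results.
#' @return A list with `F`, `p_value`, `df`, `means` (per-dose data.frame) and
#'   `monotone`.
#' @examples
#' dose_response(rep(c(0, 1, 10), each = 3),
#'               c(1.0, 1.1, 0.9, 2.1, 2.0, 2.2, 3.9, 4.1, 4.0))
#' @export
dose_response <- function(doses, values, which = c("k_hydr", "k_bind")) {
  which <- match.arg(which)
  if (is.list(values) && !is.numeric(values)) {
    values <- vapply(values, function(f) {
      stopifnot(inherits(f, "fit_result"))
      f$params[[which]]
    }, numeric(1))
  }
  if (length(doses) != length(values)) {
    stop_invalid("doses and values must have the same length")
  }
  g <- factor(doses, levels = unique(doses))
  counts <- table(g)
  if (length(counts) < 2L) stop_invalid("need at least 2 dose groups")
  if (any(counts < 2L)) {
    stop_invalid("every dose group needs at least 2 replicates")
  }
  fit <- stats::lm(values ~ g)
  # suppress the "essentially perfect fit" warning: that case is converted
  # into a zero-variance error below
  an <- suppressWarnings(stats::anova(fit))
  if (an$`Sum Sq`[2] <= 1e-12 * max(an$`Sum Sq`[1], 1e-300)) {
    stop_invalid("zero within-group variance: F undefined",
                 class = "gok_zero_variance")
  }
  means <- tapply(values, g, mean)
  mono <- all(diff(means) >= 0) || all(diff(means) <= 0)
  list(F = an$`F value`[1], p_value = an$`Pr(>F)`[1],
       df = unname(an$Df),
       means = data.frame(dose = names(means), mean = as.numeric(means),
                          n = as.integer(counts)),
       monotone = mono)
}
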