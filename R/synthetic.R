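#' Configuration for the synthetic-data generators
#'
#' The generators stand in for the raw plate-reader data (which is not
#' deposited with the study): 1 uM protein + 1 uM probe fluorescence traces
#' with Gaussian read noise, 384-well screening plates with DMSO control and
#' compound wells, and BRET ratio series with an agonist-induced decay. Every
#' generator is fully deterministic under a fixed `seed`.
#'
#' @param seed Integer RNG seed.
#' @param noise_sigma_frac Read-noise SD as a fraction of the amplitude `A`
#'   (default 0.02, i.e. 2% of full signal rise).
#' @param sample_interval_s Read interval, s. 2 s resolves the fastest
#'   (28-fold accelerated) mutant binding; 10 s suits WT-scale traces.
#' @param duration_s Trace duration, s.
#' @param true_params A [kinetic_params()] object (or per-well list for
#'   plates).
#' @param plate_layout List: `n_rows`, `n_cols`, `n_dmso`, `spikes` (a
#'   data.frame `well`, `metric`, `sd_units`), `calib_n` (size of the internal
#'   control set used to convert SD units into parameter shifts).
#' @param bret_profile List: `basal` ratio, fractional `decrease`, time
#'   constant `tau_s`, `interval_s`, `n_readings`, `injection_index`,
#'   optional `second_injection_index` and `recovery_tau_s`, channel
#'   `noise_frac`, `donor_counts`.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L, noise_sigma_frac = 0.02,
                             sample_interval_s = 10, duration_s = 600,
                             true_params = kinetic_params(k_bind = 0.01,
                                                          k_hydr = 0.01),
                             plate_layout = list(), bret_profile = list()) {
  if (!is.finite(noise_sigma_frac) || noise_sigma_frac < 0) {
    stop_invalid("noise_sigma_frac must be >= 0")
  }
  layout <- utils::modifyList(
    list(n_rows = 16L, n_cols = 24L, n_dmso = 32L,
         spikes = NULL, calib_n = 100L),
    plate_layout)
  bret <- utils::modifyList(
    list(basal = 0.5, decrease = 0.3, tau_s = 30, interval_s = 2,
         n_readings = 150L, injection_index = 20L,
         second_injection_index = NULL, recovery_tau_s = 30,
         noise_frac = 0.01, donor_counts = 1e5),
    bret_profile)
  structure(list(seed = as.integer(seed),
                 noise_sigma_frac = noise_sigma_frac,
                 sample_interval_s = sample_interval_s,
                 duration_s = duration_s, true_params = true_params,
                 plate_layout = layout, bret_profile = bret),
            class = "synthetic_config")
}

# run code under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, fn) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  fn()
}

#' Generate one synthetic fluorescence trace
#'
#' Forward-model signal (see the `simulate_*` functions) plus i.i.d. Gaussian
#' read noise with SD `noise_sigma_frac * A`.
#'
#' @param config A [synthetic_config()].
#' @param assay_kind `"association"`, `"binding_hydrolysis"` or
#'   `"displacement"` (the latter requires `true_params$t_inj`).
#' @return A [kinetic_trace()].
#' @export
generate_trace <- function(config,
                           assay_kind = c("association", "binding_hydrolysis",
                                          "displacement")) {
  stopifnot(inherits(config, "synthetic_config"))
  assay_kind <- match.arg(assay_kind)
  times <- seq(0, config$duration_s, by = config$sample_interval_s)
  clean <- switch(assay_kind,
                  association = simulate_association(config$true_params, times),
                  binding_hydrolysis =
                    simulate_binding_hydrolysis(config$true_params, times),
                  displacement = simulate_displacement(config$true_params, times))
  with_seed(config$seed, function() {
    noisy <- clean$signal +
      stats::rnorm(length(times), 0,
                   config$noise_sigma_frac * config$true_params$A)
    kinetic_trace(times, noisy, assay_kind = assay_kind,
                  injection_index = clean$injection_index,
                  meta = list(seed = as.character(config$seed)))
  })
}

well_names <- function(n_rows, n_cols) {
  as.vector(t(outer(LETTERS[seq_len(n_rows)], seq_len(n_cols), paste0)))
}

#' Generate a synthetic screening plate
#'
#' Builds a [screen_plate()] whose DMSO wells share `true_params` and whose
#' compound wells are neutral except for the requested spikes. Spike
#' magnitudes are given in units of the control SD of the corresponding
#' metric; the generator converts them into parameter shifts (on `k_bind` for
#' the rate metric, on the amplitude `A` for `max_uptake`) using metric SDs
#' measured on an internal seeded calibration set of simulated DMSO wells
#' analysed with [compute_well_metrics()]. Ground-truth spike labels are
#' stored in each trace's `meta` and in `attr(plate, "truth")`.
#'
#' @param config A [synthetic_config()]; `plate_layout$spikes` is a data.frame
#'   with columns `well`, `metric` (`"k_bind"`/`"max_uptake"`), `sd_units`.
#' @param opts [fit_opts()] used for the calibration fits.
#' @return A `screen_plate`; `attr(,"truth")` holds the spike table augmented
#'   with the applied parameter shifts and the calibration SDs.
#' @export
generate_plate <- function(config, opts = fit_opts()) {
  stopifnot(inherits(config, "synthetic_config"))
  l <- config$plate_layout
  wells <- well_names(l$n_rows, l$n_cols)
  spikes <- l$spikes
  if (!is.null(spikes)) {
    bad <- setdiff(spikes$well, wells)
    if (length(bad)) {
      stop_invalid(paste("spike wells not on the plate:",
                         paste(bad, collapse = ", ")))
    }
  }
  base <- config$true_params
  times <- seq(0, config$duration_s, by = config$sample_interval_s)
  sigma <- config$noise_sigma_frac * base$A

  with_seed(config$seed, function() {
    dmso <- sample(wells, l$n_dmso)
    if (!is.null(spikes) && any(spikes$well %in% dmso)) {
      stop_invalid("spike wells must be compound wells, not DMSO controls")
    }
    map <- data.frame(
      well = wells,
      role = ifelse(wells %in% dmso, "dmso", "compound"),
      compound_id = ifelse(wells %in% dmso, "DMSO",
                           sprintf("CMP%04d", seq_along(wells))),
      concentration_uM = ifelse(wells %in% dmso, 0, 12.5))

    # calibration: metric SDs across simulated control wells (only needed to
    # convert spike magnitudes from SD units into parameter shifts)
    clean <- simulate_binding_hydrolysis(base, times)$signal
    if (is.null(spikes)) {
      sd_kbind <- NA_real_
      sd_uptake <- NA_real_
    } else {
      calib <- replicate(l$calib_n, {
        tr <- kinetic_trace(times,
                            clean + stats::rnorm(length(times), 0, sigma),
                            assay_kind = "binding_hydrolysis")
        m <- compute_well_metrics(tr, window_s = config$duration_s,
                                  opts = opts)
        c(m$k_bind, m$max_uptake)
      })
      sd_kbind <- stats::sd(calib[1, ][is.finite(calib[1, ])])
      sd_uptake <- stats::sd(calib[2, ][is.finite(calib[2, ])])
    }

    truth <- if (is.null(spikes)) {
      data.frame(well = character(), metric = character(),
                 sd_units = numeric(), shift = numeric())
    } else {
      shift <- ifelse(spikes$metric == "k_bind",
                      spikes$sd_units * sd_kbind,
                      spikes$sd_units * sd_uptake)
      cbind(spikes, shift = shift)
    }

    traces <- stats::setNames(lapply(wells, function(w) {
      p <- base
      lab <- "neutral"
      if (!is.null(spikes) && w %in% spikes$well) {
        for (j in which(spikes$well == w)) {
          if (spikes$metric[j] == "k_bind") {
            p$k_bind <- max(p$k_bind + truth$shift[j], 1e-6)
          } else {
            p$A <- max(p$A + truth$shift[j], 1)
          }
        }
        lab <- "spiked"
      }
      cl <- simulate_binding_hydrolysis(p, times)$signal
      kinetic_trace(times, cl + stats::rnorm(length(times), 0, sigma),
                    assay_kind = "binding_hydrolysis", well_id = w,
                    meta = list(truth = lab))
    }), wells)

    plate <- screen_plate(sprintf("synthetic-%d", config$seed), map, traces)
    attr(plate, "truth") <- truth
    attr(plate, "calibration") <- list(sd_kbind = sd_kbind,
                                       sd_uptake = sd_uptake)
    plate
  })
}

#' Generate a synthetic BRET series
#'
#' Pre-injection constant basal ratio; after agonist injection an exponential
#' approach to `basal * (1 - decrease)`; optionally, after a second
#' (antagonist) injection, an exponential return to basal. Both channels get
#' independent multiplicative Gaussian noise.
#'
#' @param config A [synthetic_config()] (see `bret_profile`).
#' @return A [bret_series()] (ratio not yet computed).
#' @export
generate_bret <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  p <- config$bret_profile
  n <- p$n_readings
  times <- (seq_len(n) - 1) * p$interval_s
  i1 <- p$injection_index
  t1 <- times[i1]
  r <- rep(p$basal, n)
  post <- seq(i1, n)
  r[post] <- p$basal *
    (1 - p$decrease * (1 - exp(-(times[post] - t1) / p$tau_s)))
  if (!is.null(p$second_injection_index)) {
    i2 <- p$second_injection_index
    t2 <- times[i2]
    r_at <- r[i2]
    seg <- seq(i2, n)
    r[seg] <- p$basal + (r_at - p$basal) * exp(-(times[seg] - t2) /
                                                 p$recovery_tau_s)
  }
  with_seed(config$seed, function() {
    donor <- p$donor_counts * (1 + stats::rnorm(n, 0, p$noise_frac))
    acceptor <- p$donor_counts * r * (1 + stats::rnorm(n, 0, p$noise_frac))
    bret_series(times, donor, acceptor, injection_index = i1,
                second_injection_index = p$second_injection_index)
  })
}

#' Generate a synthetic dose-dependence rescue series
#'
#' Emulates a Zn-rescue concentration series: the true hydrolysis rate rises
#' geometrically by `fold_span` across the dose levels, and each replicate
#' observation carries multiplicative Gaussian noise (the effective
#' uncertainty of a fitted rate).
#'
#' @param seed RNG seed.
#' @param doses Dose labels (uM), lowest to highest.
#' @param base_rate Rate at the lowest dose, 1/s.
#' @param fold_span Total fold-increase across the series (1 = flat series).
#' @param n_replicates Replicates per dose.
#' @param noise_frac Relative SD of each observation.
#' @return A data.frame with columns `dose`, `value`.
#' @export
generate_rescue_series <- function(seed, doses = c(0, 3, 10, 30, 100),
                                   base_rate = 1e-4, fold_span = 10,
                                   n_replicates = 3, noise_frac = 0.05) {
  truth <- base_rate * fold_span ^ ((seq_along(doses) - 1) /
                                      (length(doses) - 1))
  with_seed(seed, function() {
    rows <- lapply(seq_along(doses), function(i) {
      data.frame(dose = doses[i],
                 value = truth[i] *
                   (1 + stats::rnorm(n_replicates, 0, noise_frac)))
    })
    do.call(rbind, rows)
  })
}
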