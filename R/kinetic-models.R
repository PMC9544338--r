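#' @name kinetic_models
#' @title Closed-form forward models for the three fluorescence assays
#'
#' @description
#' The package models the fluorescent-nucleotide assays with first-order
#' (pseudo-first-order) kinetics. For the nonhydrolyzable probe the bound
#' fraction follows a single observed exponential; for the hydrolyzable probe
#' a sequential two-step scheme free -> bound-GTP* -> bound-GDP* applies, the
#' hydrolyzed species remaining on the protein with relative brightness `rho`;
#' for the GDP-challenge displacement assay the bound probe decays
#' exponentially from its pre-injection plateau to a residual level.
#'
#' All three simulators return a [kinetic_trace()] evaluated on the supplied
#' time grid. Signals before the dead time `t0` sit at the initial value.
NULL

# bound-GTP* fraction of the sequential scheme at shifted time tt >= 0.
# Uses the analytic equal-rates limit k*t*exp(-k*t) when the two rates are
# within `tol` (relative) of each other, to avoid catastrophic cancellation.
bh_bound_gtp <- function(tt, k_bind, k_hydr, tol = 1e-6) {
  if (k_bind == 0) return(rep(0, length(tt)))
  if (abs(k_bind - k_hydr) < tol * max(k_bind, k_hydr)) {
    k <- (k_bind + k_hydr) / 2
    return(k * tt * exp(-k * tt))
  }
  k_bind / (k_hydr - k_bind) * (exp(-k_bind * tt) - exp(-k_hydr * tt))
}

# model signals on a shifted grid -----------------------------------------

model_association <- function(times, k_bind, F_free, A, t0 = 0) {
  tt <- pmax(times - t0, 0)
  F_free + A * (1 - exp(-k_bind * tt))
}

model_binding_hydrolysis <- function(times, k_bind, k_hydr, F_free, A, rho,
                                     t0 = 0, tol = 1e-6) {
  tt <- pmax(times - t0, 0)
  B <- bh_bound_gtp(tt, k_bind, k_hydr, tol = tol)
  C <- 1 - exp(-k_bind * tt) - B
  F_free + A * (B + rho * C)
}

model_displacement <- function(times, k_diss, F_pre, F_res, t_inj, d_inj = 1) {
  out <- rep(F_pre, length(times))
  post <- times >= t_inj
  out[post] <- d_inj *
    (F_res + (F_pre - F_res) * exp(-k_diss * (times[post] - t_inj)))
  out
}

#' Simulate probe association (nonhydrolyzable GTP analog)
#'
#' Single observed exponential rise,
#' `F(t) = F_free + A * (1 - exp(-k_bind * (t - t0)))` for `t >= t0`.
#' Although protein and probe are both at micromolar concentration (a
#' second-order encounter in reality), the assay is summarized by one observed
#' binding rate constant, so the pseudo-first-order form is used.
#'
#' @param params A [kinetic_params()] object.
#' @param times Time grid, seconds, strictly increasing, within `[0, Inf)`.
#' @return A [kinetic_trace()] with `assay_kind = "association"`.
#' @examples
#' p <- kinetic_params(k_bind = 0.01)
#' tr <- simulate_association(p, seq(0, 600, 10))
#' @export
simulate_association <- function(params, times) {
  validate_kinetic_params(params)
  check_grid(times)
  sig <- model_association(times, params$k_bind, params$F_free, params$A,
                           params$t0)
  kinetic_trace(times, sig, assay_kind = "association")
}

#' Simulate binding and hydrolysis of a hydrolyzable GTP analog
#'
#' Sequential first-order scheme free ->(k_bind) bound-GTP* ->(k_hydr)
#' bound-GDP* with unit total probe. With `B(t)` the bound-GTP* and `C(t)` the
#' bound-GDP* fraction, the signal is `F_free + A * (B + rho * C)`, which
#' rises and then decays towards `F_free + rho * A` when hydrolysis is active.
#' The analytic equal-rates limit `B = k t exp(-k t)` is used when
#' `|k_bind - k_hydr|` falls below `degeneracy_tol * max(k_bind, k_hydr)`.
#'
#' @inheritParams simulate_association
#' @param degeneracy_tol Relative rate-degeneracy tolerance for switching to
#'   the equal-rates branch.
#' @return A [kinetic_trace()] with `assay_kind = "binding_hydrolysis"`.
#' @export
simulate_binding_hydrolysis <- function(params, times, degeneracy_tol = 1e-6) {
  validate_kinetic_params(params)
  check_grid(times)
  sig <- model_binding_hydrolysis(times, params$k_bind, params$k_hydr,
                                  params$F_free, params$A, params$rho,
                                  params$t0, tol = degeneracy_tol)
  kinetic_trace(times, sig, assay_kind = "binding_hydrolysis")
}

#' Simulate GDP-challenge displacement of prebound probe
#'
#' The protein is preloaded with the nonhydrolyzable probe, giving a
#' pre-injection plateau `F_pre = F_free + A`. At `t_inj` an excess-GDP
#' solution is injected (diluting the well by `d_inj`), after which the signal
#' decays exponentially at `k_diss` to the residual level
#' `F_res = F_free + f_ret * A`. The retained fraction is implied by the rate
#' constants as the rebinding equilibrium `f_ret = k_bind / (k_bind + k_diss)`
#' (1 when both rates are zero), so `k_diss = 0` leaves the signal constant at
#' `d_inj * F_pre` and very fast dissociation drops it to `d_inj * F_free`.
#'
#' @inheritParams simulate_association
#' @return A [kinetic_trace()] with `assay_kind = "displacement"` and
#'   `injection_index` set to the first sample at or after `t_inj`.
#' @export
simulate_displacement <- function(params, times) {
  validate_kinetic_params(params)
  check_grid(times)
  if (!is.finite(params$t_inj) || params$t_inj < min(times) ||
      params$t_inj > max(times)) {
    stop_invalid("t_inj must lie inside the time grid")
  }
  f_ret <- retained_fraction_implied(params$k_bind, params$k_diss)
  F_pre <- params$F_free + params$A
  F_res <- params$F_free + f_ret * params$A
  sig <- model_displacement(times, params$k_diss, F_pre, F_res,
                            params$t_inj, params$d_inj)
  kinetic_trace(times, sig, assay_kind = "displacement",
                injection_index = which(times >= params$t_inj)[1])
}

retained_fraction_implied <- function(k_bind, k_diss) {
  if (k_bind + k_diss == 0) 1 else k_bind / (k_bind + k_diss)
}

check_grid <- function(times) {
  if (length(times) < 8L || any(!is.finite(times)) || any(diff(times) <= 0)) {
    stop_invalid("time grid must be >= 8 finite, strictly increasing values")
  }
  if (times[1] < 0) stop_invalid("time grid must be non-negative")
  invisible(times)
}
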