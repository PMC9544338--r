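#' Kinetic parameter set for the fluorescent nucleotide assays
#'
#' Bundles the forward-model parameters shared by the three assay types:
#' association of a nonhydrolyzable probe (BODIPY-GTPgammaS), sequential
#' binding + hydrolysis of BODIPY-GTP, and displacement of prebound probe by
#' excess GDP. All rates are observed first-order constants in 1/s; time is in
#' seconds throughout the package.
#'
#' @param k_bind Observed first-order binding (uptake) rate constant, 1/s, >= 0.
#' @param k_hydr First-order GTP hydrolysis rate constant, 1/s, >= 0.
#' @param k_diss First-order nucleotide dissociation rate constant after GDP
#'   challenge, 1/s, >= 0.
#' @param F_free Fluorescence of the fully unbound state, AU, >= 0. BODIPY
#'   probes are partially quenched when free in solution, so this is a flat,
#'   nonzero floor.
#' @param A Full-binding fluorescence amplitude (bound-GTP state minus
#'   `F_free`), AU, >= 0.
#' @param rho Brightness of protein-bound hydrolyzed probe (fluorophore-GDP)
#'   relative to the bound unhydrolyzed probe; dimensionless in [0, 1).
#' @param t0 Dead time between reagent mixing and the first read, s, >= 0.
#' @param t_inj Displacement-injection time, s (displacement assay only; `NA`
#'   otherwise).
#' @param d_inj Multiplicative dilution factor applied at `t_inj`,
#'   dimensionless in (0, 1]. The default 0.8 corresponds to injecting 5 ul
#'   into 20 ul (20/25).
#'
#' @return An object of class `kinetic_params` (a validated named list).
#' @examples
#' p <- kinetic_params(k_bind = 0.01, k_hydr = 0.01)
#' p$k_bind
#' @export
kinetic_params <- function(k_bind = 0, k_hydr = 0, k_diss = 0,
                           F_free = 100, A = 100, rho = 0.2,
                           t0 = 0, t_inj = NA_real_, d_inj = 0.8) {
  p <- list(k_bind = as.numeric(k_bind), k_hydr = as.numeric(k_hydr),
            k_diss = as.numeric(k_diss), F_free = as.numeric(F_free),
            A = as.numeric(A), rho = as.numeric(rho), t0 = as.numeric(t0),
            t_inj = as.numeric(t_inj), d_inj = as.numeric(d_inj))
  validate_kinetic_params(p)
  structure(p, class = "kinetic_params")
}

validate_kinetic_params <- function(p) {
  rates <- c(p$k_bind, p$k_hydr, p$k_diss)
  if (any(!is.finite(rates)) || any(rates < 0)) {
    stop_invalid("rates must be finite and non-negative")
  }
  if (!is.finite(p$F_free) || p$F_free < 0) stop_invalid("F_free must be >= 0")
  if (!is.finite(p$A) || p$A < 0) stop_invalid("A must be >= 0")
  if (!is.finite(p$rho) || p$rho < 0 || p$rho >= 1) {
    stop_invalid("rho must lie in [0, 1)")
  }
  if (!is.finite(p$t0) || p$t0 < 0) stop_invalid("t0 must be >= 0")
  if (!is.finite(p$d_inj) || p$d_inj <= 0 || p$d_inj > 1) {
    stop_invalid("d_inj must lie in (0, 1]")
  }
  invisible(p)
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("<kinetic_params>\n")
  cat(sprintf("  k_bind = %g /s, k_hydr = %g /s, k_diss = %g /s\n",
              x$k_bind, x$k_hydr, x$k_diss))
  cat(sprintf("  F_free = %g AU, A = %g AU, rho = %g, t0 = %g s\n",
              x$F_free, x$A, x$rho, x$t0))
  if (is.finite(x$t_inj)) {
    cat(sprintf("  t_inj = %g s, d_inj = %g\n", x$t_inj, x$d_inj))
  }
  invisible(x)
}

#' Serialize / deserialize kinetic parameters as JSON
#'
#' @param params A [kinetic_params()] object.
#' @param path File path to write to / read from.
#' @return `write_params_json()` returns `path` invisibly;
#'   `read_params_json()` returns a `kinetic_params` object.
#' @export
write_params_json <- function(params, path) {
  stopifnot(inherits(params, "kinetic_params"))
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_params_json
#' @export
read_params_json <- function(path) {
  raw <- jsonlite::read_json(path)
  raw <- lapply(raw, function(v) if (is.null(v)) NA_real_ else as.numeric(v))
  do.call(kinetic_params, raw)
}

# error helpers shared across the package --------------------------------

stop_invalid <- function(msg, class = "gok_invalid_input") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
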