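# Shared fixture builders. Everything is generated in code; no stored data.

wt_params <- function() kinetic_params(k_bind = 0.01, k_hydr = 0.01)

# noisy copy of a clean trace (caller manages the RNG seed)
noisy_trace <- function(clean, sigma, assay_kind = clean$assay_kind) {
  kinetic_trace(clean$times, clean$signal + rnorm(length(clean$times), 0, sigma),
                assay_kind = assay_kind,
                injection_index = clean$injection_index)
}

# displacement fixture with F_pre = 200, F_res = 120 (f_ret = 0.2 via
# k_bind/(k_bind + k_diss) = 0.005/0.025)
displacement_fixture_params <- function(k_diss = 0.02, d_inj = 1) {
  kinetic_params(k_bind = k_diss / 4, k_diss = k_diss, F_free = 100, A = 100,
                 t_inj = 300, d_inj = d_inj)
}

# deterministic screening plate: uptake metrics take exact target values.
# All traces share k (plus a small per-well spread so the k_bind control SD
# is nonzero) and the amplitude is scaled so max_uptake == u exactly at the
# last read of the noiseless exponential.
exact_uptake_plate <- function(dmso_uptake, compound_uptake) {
  times <- seq(0, 90, 10)
  q <- 1 - exp(-0.05 * 90)
  mk <- function(u, dk) {
    A <- u / (1 - exp(-(0.05 + dk) * 90))
    kinetic_trace(times, 100 + A * (1 - exp(-(0.05 + dk) * times)),
                  assay_kind = "binding_hydrolysis")
  }
  wells <- sprintf("W%02d", seq_along(c(dmso_uptake, compound_uptake)))
  u_all <- c(dmso_uptake, compound_uptake)
  dk <- seq_along(u_all) * 1e-4
  traces <- stats::setNames(Map(mk, u_all, dk), wells)
  map <- data.frame(well = wells,
                    role = rep(c("dmso", "compound"),
                               c(length(dmso_uptake), length(compound_uptake))),
                    compound_id = wells, concentration_uM = 12.5)
  screen_plate("exact", map, traces)
}

# small synthetic screening plate (48 wells) for pipeline tests; spike wells
# given as NA are assigned to the first compound wells of the seed's layout
small_plate <- function(seed = 3, spikes = NULL) {
  mk_cfg <- function(sp) synthetic_config(
    seed = seed, sample_interval_s = 10, duration_s = 600,
    true_params = kinetic_params(k_bind = 0.05, k_hydr = 1e-4),
    plate_layout = list(n_rows = 8L, n_cols = 6L, n_dmso = 16L,
                        spikes = sp, calib_n = 40L))
  if (!is.null(spikes) && anyNA(spikes$well)) {
    layout <- generate_plate(mk_cfg(NULL))
    free <- layout$map$well[layout$map$role == "compound"]
    spikes$well[is.na(spikes$well)] <- free[seq_len(sum(is.na(spikes$well)))]
  }
  plate <- generate_plate(mk_cfg(spikes))
  plate
}
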