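# gokinetics

Kinetic modelling and screening analytics for fluorescent GTPase assays of
heterotrimeric G-protein α subunits (Gα<sub>o</sub>, the GNAO1 gene product,
and its encephalopathy-associated mutants).

Plate-reader assays with BODIPY-labelled nucleotides report the catalytic
cycle of Gα as fluorescence: BODIPY-GTPγS binding as a rising exponential,
BODIPY-GTP binding-then-hydrolysis as a transient (the bound fluorophore-GDP
is dimmer than bound fluorophore-GTP), and excess-GDP challenge as a decay of
prebound probe. `gokinetics` provides the forward models, the nonlinear
least-squares fitters for the observed rate constants, the statistics of a
DMSO-referenced drug screen built on those read-outs, dose-dependence
(rescue) ANOVA, BRET heterotrimer-dissociation summaries, and seeded
synthetic-data generators that emulate every input — so the entire pipeline
is testable without instrument data.

## Models

With unit total probe, observed first-order rates (s⁻¹), baseline `F_free`,
amplitude `A` and relative bound-GDP brightness `ρ ∈ [0, 1)`:

* **Association** (nonhydrolyzable probe):
  `F(t) = F_free + A · (1 − e^{−k_bind (t − t₀)})`
* **Binding + hydrolysis** (sequential scheme free → bound-GTP\* → bound-GDP\*):
  `B(t) = k_bind/(k_hydr − k_bind) · (e^{−k_bind t} − e^{−k_hydr t})`,
  `C(t) = 1 − e^{−k_bind t} − B(t)`,
  `F(t) = F_free + A · (B + ρ C)`,
  with the analytic limit `B = k t e^{−k t}` at rate degeneracy.
* **Displacement** (GDP challenge at `t_inj`, dilution `d_inj`):
  `F(t) = d_inj · [F_res + (F_pre − F_res) e^{−k_diss (t − t_inj)}]`.

Fitted rates come with standard errors from the curvature of the
least-squares objective; derived quantities include fold changes with errors
propagated in quadrature, the dissociation-vs-uptake z comparison, and the
retained probe fraction after displacement.

The screen statistics follow the study conventions: per-well `k_bind` and
maximal GTP uptake over a 10-minute window, DMSO-well mean/SD per plate, and
inclusive two-sided hit thresholds of 2 SD (`k_bind`) and 3 SD (uptake).
BRET series are summarized by the basal ratio (mean of the 10 readings before
agonist injection) and the plateau ratio (mean of the last 10 stimulated
readings over basal).

## Worked example

```r
library(gokinetics)

# wild-type vs fast-binding mutant: BODIPY-GTPgammaS association
wt_cfg  <- synthetic_config(seed = 1, sample_interval_s = 2, duration_s = 598,
                            true_params = kinetic_params(k_bind = 0.01))
mut_cfg <- synthetic_config(seed = 2, sample_interval_s = 2, duration_s = 598,
                            true_params = kinetic_params(k_bind = 0.28))
fit_wt  <- fit_k_bind(generate_trace(wt_cfg, "association"))
fit_mut <- fit_k_bind(generate_trace(mut_cfg, "association"))
fit_wt
#> <fit_result> converged = TRUE, rss = 1108.42 over 300 points
#>   k_bind  = 0.0100165 +/- 0.000106
#>   F_free  = 100.307
#>   A       = 99.6795

fc <- fold_change(fit_mut, fit_wt, "k_bind")
sprintf("k_bind fold change (mutant/WT): %.1f +/- %.1f", fc$ratio, fc$se)
#> "k_bind fold change (mutant/WT): 28.9 +/- 1.1"
```

The fitted wild-type rate (0.0100 s⁻¹) recovers the programmed 0.01 s⁻¹
within its standard error, and the mutant/wild-type ratio recovers the
programmed 28-fold acceleration. A hydrolysis fit on a wild-type-paced
BODIPY-GTP trace uses the endpoint baseline convention:

```r
wt_gtp <- synthetic_config(seed = 3, sample_interval_s = 10, duration_s = 3600,
                           true_params = kinetic_params(k_bind = 0.01, k_hydr = 0.01))
fit_k_hydr(generate_trace(wt_gtp, "binding_hydrolysis"), "endpoint")
#> <fit_result> converged = TRUE, rss = 1453.55 over 361 points
#>   k_bind  = 0.00963031 +/- 0.000335
#>   k_hydr  = 0.0104856 +/- 0.000559
#>   A       = 105.141
```

and a BRET series with a programmed 30% agonist-induced decrease is
summarized as

```r
bret <- generate_bret(synthetic_config(seed = 4, bret_profile = list(
  decrease = 0.3, noise_frac = 0.01, n_readings = 200L,
  injection_index = 20L, tau_s = 20)))
plateau_ratio(bret)
#> <bret_summary> basal = 0.4985, plateau_ratio = 0.7013
```

## Command line

`exec/gokinetics` exposes `simulate`, `fit`, `screen` and `bret`
subcommands (`--seed`, `--out`, `--config`, plus per-command inputs); every
run writes a `run-manifest.json` and is byte-reproducible under a fixed seed:

```sh
Rscript exec/gokinetics simulate --seed 5 --out runs/demo
Rscript exec/gokinetics screen --plate-map runs/demo/plate_map.csv \
    --traces runs/demo/plate_traces.csv --out runs/demo
```

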