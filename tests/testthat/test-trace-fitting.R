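test_that("noiseless round trips recover the generating rates", {
  # association
  tr <- simulate_association(kinetic_params(k_bind = 0.05), seq(0, 300, 2))
  f <- fit_k_bind(tr)
  expect_true(f$converged)
  expect_lt(abs(f$params$k_bind - 0.05) / 0.05, 1e-6)
  expect_equal(f$derived$half_time_s, log(2) / f$params$k_bind)

  # sequential model, degenerate equal-rates branch (endpoint mode)
  trw <- simulate_binding_hydrolysis(wt_params(), seq(0, 3600, 10))
  fw <- fit_k_hydr(trw, "endpoint")
  expect_lt(abs(fw$params$k_bind - 0.01) / 0.01, 1e-4)
  expect_lt(abs(fw$params$k_hydr - 0.01) / 0.01, 1e-4)

  # separated rates with rho fitted
  trs <- simulate_binding_hydrolysis(
    kinetic_params(k_bind = 0.02, k_hydr = 0.005, rho = 0.35),
    seq(0, 3600, 10))
  fs <- fit_k_hydr(trs, "endpoint", fit_opts(fit_rho = TRUE))
  expect_lt(abs(fs$params$k_bind - 0.02) / 0.02, 1e-4)
  expect_lt(abs(fs$params$k_hydr - 0.005) / 0.005, 1e-4)
  expect_lt(abs(fs$params$rho - 0.35), 1e-3)

  # displacement
  trd <- simulate_displacement(displacement_fixture_params(), seq(0, 1200, 5))
  fd <- fit_k_diss(trd)
  expect_lt(abs(fd$params$k_diss - 0.02) / 0.02, 1e-6)
})

test_that("fit_k_bind rejects flat traces and reports sane errors", {
  flat <- kinetic_trace(seq(0, 90, 10), rep(100, 10), "association")
  expect_error(fit_k_bind(flat), class = "gok_degenerate_fit")
  # pure noise, no signal
  set.seed(2)
  noise <- kinetic_trace(seq(0, 590, 10), 100 + rnorm(60, 0, 1), "association")
  expect_error(fit_k_bind(noise), class = "gok_degenerate_fit")
  # wrong assay kind
  trw <- simulate_binding_hydrolysis(wt_params(), seq(0, 600, 10))
  expect_error(fit_k_bind(trw), class = "gok_invalid_input")
})

test_that("fit_k_bind recovers rates from noisy traces (Monte Carlo)", {
  tg <- seq(0, 598, 2)  # 300 samples over 10 min
  clean <- simulate_association(kinetic_params(k_bind = 0.01), tg)
  set.seed(7)
  res <- replicate(40, {
    f <- fit_k_bind(noisy_trace(clean, 2))
    c(f$params$k_bind, f$param_errors[["k_bind"]])
  })
  expect_lt(median(abs(res[1, ] - 0.01) / 0.01), 0.05)
  # noise consistency: reported SE within a factor 2 of the empirical SD
  ratio <- mean(res[2, ]) / sd(res[1, ])
  expect_gt(ratio, 0.5)
  expect_lt(ratio, 2)
})

test_that("fit_k_hydr honours baseline modes on hydrolysis-dead traces", {
  tg <- seq(0, 3600, 10)
  dead <- simulate_binding_hydrolysis(
    kinetic_params(k_bind = 0.05, k_hydr = 0), tg)

  fi <- fit_k_hydr(dead, "initial")
  expect_lte(fi$params$k_hydr, 1e-6)
  expect_equal(fi$params$F_free, dead$signal[1])

  # endpoint convention does not apply to a flat-top trace: it must either be
  # flagged as rejected or fit no better than the initial convention
  fe <- fit_k_hydr(dead, "endpoint")
  expect_true("endpoint baseline unverified" %in% fe$flags ||
                fe$rss >= fi$rss)

  # hard anchoring remains available and anchors the asymptote
  fh <- fit_k_hydr(dead, "endpoint", fit_opts(hard_endpoint_anchor = TRUE))
  expect_true(is.finite(fh$params$k_hydr))
})

test_that("fit_k_hydr flags an unresolved binding phase", {
  # trace much shorter than 2 / k_bind
  slow <- simulate_binding_hydrolysis(
    kinetic_params(k_bind = 0.002, k_hydr = 1e-5), seq(0, 400, 10))
  f <- fit_k_hydr(slow, "initial")
  expect_true("binding phase unresolved" %in% f$flags)
})

test_that("fit_k_diss derives the retained fraction and handles no decay", {
  # F_pre = 200, F_res = 120, F_free = 100 known => retained fraction 0.2
  trd <- simulate_displacement(displacement_fixture_params(), seq(0, 1500, 5))
  fd <- fit_k_diss(trd, fit_opts(F_free = 100))
  expect_equal(fd$derived$retained_fraction, 0.2, tolerance = 1e-4)
  # without F_free: F_res / F_pre
  fd2 <- fit_k_diss(trd)
  expect_equal(fd2$derived$retained_fraction, 120 / 200, tolerance = 1e-4)

  # constant post-injection signal: rate at lower bound, retained ~ 1
  pz <- kinetic_params(k_bind = 0.01, k_diss = 0, t_inj = 300, d_inj = 1)
  trz <- simulate_displacement(pz, seq(0, 1200, 10))
  fz <- fit_k_diss(trz)
  expect_lte(fz$params$k_diss, 1e-6)
  expect_equal(fz$derived$retained_fraction, 1, tolerance = 1e-6)
  expect_true("no decay" %in% fz$flags)

  # fewer than 8 post-injection readings
  short <- kinetic_trace(seq(0, 90, 10), c(rep(200, 5), 150, 140, 130, 120, 115),
                         "displacement", injection_index = 6)
  expect_error(fit_k_diss(short), class = "gok_invalid_input")
})

test_that("compare_rates implements the Welch-style z comparison", {
  mk_fit <- function(k, se, which) {
    p <- do.call(kinetic_params, stats::setNames(list(k), which))
    gokinetics:::new_fit_result(p, stats::setNames(se, which), 1, 100, which)
  }
  # identity: ratio 1, not significant
  cmp0 <- compare_rates(mk_fit(0.02, 0.001, "k_diss"),
                        mk_fit(0.02, 0.001, "k_bind"))
  expect_equal(cmp0$ratio, 1)
  expect_false(cmp0$exceeds)

  # closed-form z
  cmp <- compare_rates(mk_fit(0.1, 0.005, "k_diss"),
                       mk_fit(0.02, 0.001, "k_bind"))
  expect_equal(cmp$ratio, 5)
  expect_equal(cmp$z, (0.1 - 0.02) / sqrt(0.005^2 + 0.001^2))
  expect_equal(cmp$z, 15.689, tolerance = 1e-4)
  expect_true(cmp$exceeds)

  # zero / missing standard errors are undefined
  expect_error(compare_rates(mk_fit(0.1, 0, "k_diss"),
                             mk_fit(0.02, 0, "k_bind")),
               class = "gok_undefined_comparison")
})

test_that("fold_change propagates relative errors in quadrature", {
  mk_fit <- function(k, se) {
    gokinetics:::new_fit_result(kinetic_params(k_bind = k),
                                c(k_bind = se), 1, 100, "k_bind")
  }
  self <- mk_fit(0.04, 0.001)
  expect_identical(fold_change(self, self)$ratio, 1)

  fc <- fold_change(mk_fit(0.28, 0.28 * 0.03), mk_fit(0.01, 0.01 * 0.04))
  expect_equal(fc$ratio, 28)
  expect_equal(fc$rel_err, 0.05)

  wt_at_bound <- mk_fit(1e-8, 1e-9)
  expect_error(fold_change(self, wt_at_bound),
               class = "gok_division_unstable")
})

test_that("batch fitting produces one tidy row per trace", {
  tg <- seq(0, 600, 10)
  traces <- list(
    a = simulate_association(kinetic_params(k_bind = 0.02), tg),
    b = simulate_binding_hydrolysis(kinetic_params(k_bind = 0.05,
                                                   k_hydr = 1e-4), tg),
    d = simulate_displacement(
      kinetic_params(k_bind = 0.01, k_diss = 0.05, t_inj = 100, d_inj = 1), tg))
  traces$a$well_id <- "a"; traces$b$well_id <- "b"; traces$d$well_id <- "d"
  tab <- fit_traces(traces, baseline_mode = "initial")
  expect_equal(nrow(tab), 3)
  expect_equal(tab$well, c("a", "b", "d"))
  expect_equal(tab$k_bind[1], 0.02, tolerance = 1e-5)
  expect_equal(tab$k_diss[3], 0.05, tolerance = 1e-5)
  expect_true(all(tab$converged))
})

test_that("fit results serialize to JSON", {
  tr <- simulate_association(kinetic_params(k_bind = 0.05), seq(0, 300, 2))
  f <- fit_k_bind(tr)
  path <- withr::local_tempfile(fileext = ".json")
  write_fit_json(f, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$params$k_bind, f$params$k_bind)
  expect_true(back$converged)
  expect_equal(back$n_points, 151)
})
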