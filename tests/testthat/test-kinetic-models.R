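test_that("association model: limits, half-life, and shape", {
  times <- seq(0, 300, 2)

  # no binding: constant at F_free
  flat <- simulate_association(kinetic_params(k_bind = 0), times)
  expect_equal(flat$signal, rep(100, length(times)))

  # half-life of the exponential: F(ln 2 / k) = F_free + A/2
  p <- kinetic_params(k_bind = 0.01, F_free = 100, A = 100)
  tr <- simulate_association(p, c(0, 10, 20, 30, log(2) / 0.01, 200, 400, 800))
  expect_equal(tr$signal[5], 150)

  # monotone non-decreasing, plateau at F_free + A
  p2 <- kinetic_params(k_bind = 0.05)
  tr2 <- simulate_association(p2, times)
  expect_true(all(diff(tr2$signal) >= 0))
  expect_equal(tr2$signal[length(times)], 200, tolerance = 1e-6)
  expect_equal(tr2$assay_kind, "association")

  # invalid grids rejected
  expect_error(simulate_association(p2, c(0, 10, 10, 20, 30, 40, 50, 60)),
               class = "gok_invalid_input")
  expect_error(simulate_association(p2, rev(times)),
               class = "gok_invalid_input")
})

test_that("binding+hydrolysis model: limits and equal-rates branch", {
  times <- seq(0, 600, 2)

  # k_hydr = 0 reduces to the association model
  p <- kinetic_params(k_bind = 0.02, k_hydr = 0)
  expect_equal(simulate_binding_hydrolysis(p, times)$signal,
               simulate_association(p, times)$signal)

  # equal rates, rho = 0: peak at t = 1/k with B = exp(-1)
  pe <- kinetic_params(k_bind = 0.01, k_hydr = 0.01, rho = 0,
                       F_free = 100, A = 100)
  tg <- sort(unique(c(seq(0, 600, 5), 100)))
  tre <- simulate_binding_hydrolysis(pe, tg)
  expect_equal(tg[which.max(tre$signal)], 100)
  expect_equal(max(tre$signal), 100 + 100 * exp(-1), tolerance = 1e-9)

  # distinct rates: B peaks at ln(kb/kh)/(kb - kh) (visible with rho = 0);
  # with rho > 0 the trace decays to F_free + rho * A
  pd <- kinetic_params(k_bind = 0.02, k_hydr = 0.005, rho = 0)
  t_pk <- log(0.02 / 0.005) / (0.02 - 0.005)
  tgd <- sort(unique(c(seq(0, 3000, 1), t_pk)))
  trd <- simulate_binding_hydrolysis(pd, tgd)
  expect_equal(tgd[which.max(trd$signal)], t_pk)
  pr <- kinetic_params(k_bind = 0.02, k_hydr = 0.005, rho = 0.2)
  trr <- simulate_binding_hydrolysis(pr, tgd)
  expect_equal(trr$signal[length(tgd)], 100 + 0.2 * 100, tolerance = 1e-3)
})

test_that("displacement model: plateau, dilution, and decay", {
  p0 <- displacement_fixture_params()
  times <- seq(0, 1200, 5)

  # k_diss = 0: constant at d_inj * F_pre after injection
  pz <- kinetic_params(k_bind = 0.01, k_diss = 0, t_inj = 300, d_inj = 0.8)
  trz <- simulate_displacement(pz, times)
  expect_equal(unique(trz$signal[times >= 300]), 0.8 * 200)
  expect_equal(trz$injection_index, which(times >= 300)[1])

  # very fast dissociation: immediate drop towards d_inj * F_free
  pf <- kinetic_params(k_bind = 0.01, k_diss = 9.9, t_inj = 300, d_inj = 0.8)
  trf <- simulate_displacement(pf, times)
  late <- trf$signal[times > 302]
  expect_equal(unname(late[length(late)]),
               0.8 * (100 + 100 * 0.01 / 9.91), tolerance = 1e-3)

  # closed-form half-decay: F_pre=200, F_res=120 => F(t_inj + ln2/k) = 160
  tr <- simulate_displacement(p0, sort(unique(c(times, 300 + log(2) / 0.02))))
  i <- which(tr$times == 300 + log(2) / 0.02)
  expect_equal(tr$signal[i], 160)

  # constant before injection, monotone non-increasing after
  expect_equal(unique(tr$signal[tr$times < 300]), 200)
  expect_true(all(diff(tr$signal[tr$times >= 300]) <= 0))

  # t_inj outside the grid
  pbad <- kinetic_params(k_bind = 0.01, k_diss = 0.02, t_inj = 5000)
  expect_error(simulate_displacement(pbad, times),
               class = "gok_invalid_input")
})

test_that("parameter validation enforces the domain invariants", {
  expect_error(kinetic_params(k_bind = -1), class = "gok_invalid_input")
  expect_error(kinetic_params(rho = 1), class = "gok_invalid_input")
  expect_error(kinetic_params(d_inj = 0), class = "gok_invalid_input")
  expect_error(kinetic_params(A = -5), class = "gok_invalid_input")
  expect_error(kinetic_trace(1:10, 1:9, "association"),
               class = "gok_invalid_input")
  expect_error(kinetic_trace(1:7, 1:7, "association"),
               class = "gok_invalid_input")
  expect_error(kinetic_trace(1:10, 1:10, "association", injection_index = 3),
               class = "gok_invalid_input")
  expect_error(kinetic_trace(1:10, 1:10, "displacement"),
               class = "gok_invalid_input")
})

test_that("closed forms agree with the ODE oracle and conserve mass", {
  set.seed(42)
  times <- seq(0, 300, length.out = 121)
  for (i in 1:10) {
    kb <- 10^runif(1, -4, 0)
    kh <- if (i <= 2) kb * (1 + 1e-9) else 10^runif(1, -4, 0)
    p <- kinetic_params(k_bind = kb, k_hydr = kh, rho = runif(1, 0, 0.5))
    od <- ode_oracle(p, times, "binding_hydrolysis")
    cf <- simulate_binding_hydrolysis(p, times)
    expect_lt(max(abs(cf$signal - od$signal)), 1e-6 * p$A)
    expect_lt(max(abs(rowSums(od$species) - 1)), 1e-10)
  }
  pa <- kinetic_params(k_bind = 0.05)
  expect_lt(max(abs(simulate_association(pa, times)$signal -
                      ode_oracle(pa, times, "association")$signal)),
            1e-6 * pa$A)
  pd <- displacement_fixture_params()
  expect_lt(max(abs(simulate_displacement(pd, seq(0, 1200, 10))$signal -
                      ode_oracle(pd, seq(0, 1200, 10), "displacement")$signal)),
            1e-6 * pd$A)
})

test_that("output is continuous across the rate-degeneracy tolerance", {
  times <- seq(0, 600, 2)
  below <- kinetic_params(k_bind = 0.01, k_hydr = 0.01 * (1 + 9.9e-7))
  above <- kinetic_params(k_bind = 0.01, k_hydr = 0.01 * (1 + 1.01e-6))
  dev <- max(abs(simulate_binding_hydrolysis(below, times)$signal -
                   simulate_binding_hydrolysis(above, times)$signal))
  expect_lt(dev, 1e-6 * 100)
})

test_that("trace CSV round trip preserves wells and readings", {
  tr1 <- simulate_association(kinetic_params(k_bind = 0.02), seq(0, 300, 10))
  tr1$well_id <- "A1"
  tr2 <- simulate_association(kinetic_params(k_bind = 0.05), seq(0, 300, 10))
  tr2$well_id <- "B7"
  path <- withr::local_tempfile(fileext = ".csv")
  write_traces_csv(list(tr1, tr2), path)
  back <- read_traces_csv(path)
  expect_named(back, c("A1", "B7"))
  expect_equal(back$B7$signal, tr2$signal)
  expect_equal(back$A1$times, tr1$times)
})
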