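#' Fit options
#'
#' Options shared by the trace fitters. All fits are unweighted least squares
#' (plate-reader noise is approximately homoscedastic); rates are bounded to
#' `[lower_rate, upper_rate]` so that hydrolysis-dead mutants still yield a
#' finite, reportable `k_hydr`.
#'
#' @param fit_dead_time Fit the mixing dead time `t0` (for injector-started
#'   fast traces)? Default `FALSE` (fixed at 0).
#' @param fit_rho Fit the bound-GDP relative brightness `rho`? Default
#'   `FALSE`: `rho` is a property of the probe, calibrated once, and fitting
#'   it makes the sequential model swap-degenerate (exactly so at equal
#'   rates), which ruins the conditioning of `k_hydr`. Set `TRUE` to fit it
#'   (bounded to `[0, rho_max]`) on well-resolved traces.
#' @param rho Value used for `rho` when it is not fitted.
#' @param n_starts Number of log-spaced multi-start points (>= 3 recommended).
#' @param start_spread Multiplicative spread of the starts around the
#'   heuristic initial guess.
#' @param noise_floor Signal range below which a trace is declared flat
#'   (degenerate-fit error). `NULL` = 8x the robust read-noise estimate.
#' @param lower_rate,upper_rate Rate bounds, 1/s.
#' @param rho_max Upper bound for fitted `rho`.
#' @param degeneracy_tol Relative tolerance below which the equal-rates branch
#'   of the sequential model is used.
#' @param dilution_correction Divide post-injection displacement readings by
#'   `d_inj` before fitting? Default `FALSE` (i.e. fit with d_inj = 1).
#' @param d_inj Dilution factor used when `dilution_correction = TRUE`.
#' @param F_free Known free-probe fluorescence, used by [fit_k_diss()] to
#'   compute the retained fraction on the bound scale; `NULL` = unknown.
#' @param endpoint_n Number of final readings averaged to define the endpoint
#'   baseline level; `NULL` (default) uses the data-flat tail of the trace.
#' @param hard_endpoint_anchor If `TRUE`, `baseline_mode = "endpoint"`
#'   constrains the long-time asymptote `F_free + rho * A` to equal the
#'   endpoint level exactly. Default `FALSE`: the endpoint level only
#'   initializes the asymptote, which is then fitted — the hard constraint
#'   propagates the noise of the endpoint readings straight into `k_hydr`
#'   (about 15-40% variance inflation in simulation).
#' @param alpha Two-sided significance level for [compare_rates()].
#' @return A list of class `fit_opts`.
#' @export
fit_opts <- function(fit_dead_time = FALSE, fit_rho = FALSE, rho = 0.2,
                     n_starts = 3L, start_spread = 4,
                     noise_floor = NULL,
                     lower_rate = 1e-8, upper_rate = 10,
                     rho_max = 0.95, degeneracy_tol = 1e-6,
                     dilution_correction = FALSE, d_inj = 0.8,
                     F_free = NULL, endpoint_n = NULL,
                     hard_endpoint_anchor = FALSE, alpha = 0.05) {
  structure(list(fit_dead_time = fit_dead_time, fit_rho = fit_rho, rho = rho,
                 n_starts = max(3L, as.integer(n_starts)),
                 start_spread = start_spread, noise_floor = noise_floor,
                 lower_rate = lower_rate, upper_rate = upper_rate,
                 rho_max = rho_max, degeneracy_tol = degeneracy_tol,
                 dilution_correction = dilution_correction, d_inj = d_inj,
                 F_free = F_free,
                 endpoint_n = if (is.null(endpoint_n)) NULL else
                   as.integer(endpoint_n),
                 hard_endpoint_anchor = hard_endpoint_anchor,
                 alpha = alpha),
            class = "fit_opts")
}

new_fit_result <- function(params, param_errors, rss, n_points, free,
                           baseline_mode = NA_character_, converged = TRUE,
                           derived = list(), flags = character()) {
  structure(list(params = params, param_errors = param_errors, rss = rss,
                 n_points = n_points, free = free,
                 baseline_mode = baseline_mode, converged = converged,
                 derived = derived, flags = flags),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> converged = %s, rss = %.6g over %d points\n",
              x$converged, x$rss, x$n_points))
  for (nm in x$free) {
    se <- x$param_errors[nm]
    cat(sprintf("  %-7s = %.6g%s\n", nm, x$params[[nm]],
                if (is.finite(se)) sprintf(" +/- %.3g", se) else ""))
  }
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

# read-noise estimate robust to smooth trends
estimate_read_noise <- function(signal) {
  d <- diff(signal)
  stats::mad(d - stats::median(d)) / sqrt(2)
}

# centered moving average with shrinking windows at the edges
moving_average <- function(y, w) {
  n <- length(y)
  hw <- max(w %/% 2L, 1L)
  cs <- cumsum(c(0, y))
  lo <- pmax(seq_len(n) - hw, 1L)
  hi <- pmin(seq_len(n) + hw, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

log_bounds <- function(opts) c(log(opts$lower_rate), log(opts$upper_rate))

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# multi-start L-BFGS-B over log-rate space with a tightened polish run.
# fn takes the log-rate vector and returns rss; returns list(par, value, conv).
multistart_optim <- function(starts, fn, lower, upper) {
  best <- NULL
  for (s in starts) {
    res <- tryCatch(
      stats::optim(s, fn, method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(factr = 1e3, maxit = 500,
                                  ndeps = rep(1e-5, length(s)))),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value * (1 - 1e-10) ||
        (abs(res$value - best$value) <= 1e-10 * max(best$value, 1e-300) &&
         res$par[length(res$par)] < best$par[length(best$par)])) {
      best <- res
    }
  }
  if (is.null(best)) return(NULL)
  polish <- tryCatch(
    stats::optim(best$par, fn, method = "L-BFGS-B", lower = lower,
                 upper = upper,
                 control = list(factr = 1, maxit = 500,
                                ndeps = rep(1e-7, length(best$par)))),
    error = function(e) NULL)
  if (!is.null(polish) && polish$value <= best$value) best <- polish
  # derivative-free final polish: finite-difference gradients stall near the
  # degenerate-rates ridge of the sequential model
  if (length(best$par) == 1L) {
    op <- stats::optimize(function(x) fn(clamp(x, lower, upper)),
                          lower = max(best$par - 0.1, lower),
                          upper = min(best$par + 0.1, upper), tol = 1e-12)
    if (op$objective <= best$value) {
      best$par <- clamp(op$minimum, lower, upper)
      best$value <- op$objective
    }
  } else {
    nm <- tryCatch(
      stats::optim(best$par, function(p) fn(clamp(p, lower, upper)),
                   method = "Nelder-Mead",
                   control = list(reltol = 1e-15, maxit = 2000)),
      error = function(e) NULL)
    if (!is.null(nm) && nm$value <= best$value) {
      best$par <- clamp(nm$par, lower, upper)
      best$value <- nm$value
    }
  }
  # the derivative-free polish is the arbiter of convergence: L-BFGS-B line
  # search warnings near flat optima are not failures
  best$convergence <- if (is.finite(best$value)) 0L else 1L
  best
}

# non-negative-guarded linear least squares on a small basis; returns
# list(coef, rss, fitted). Columns that would go negative against `nonneg`
# are refit at zero.
guarded_lm <- function(X, y, nonneg = rep(FALSE, ncol(X))) {
  fit <- stats::lm.fit(X, y)
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  bad <- which(nonneg & beta < 0)
  if (length(bad)) {
    keep <- setdiff(seq_len(ncol(X)), bad)
    beta[] <- 0
    if (length(keep)) {
      sub <- stats::lm.fit(X[, keep, drop = FALSE], y)
      beta[keep] <- ifelse(is.na(sub$coefficients), 0, sub$coefficients)
      beta[keep][nonneg[keep] & beta[keep] < 0] <- 0
    }
  }
  fitted <- drop(X %*% beta)
  list(coef = beta, rss = sum((y - fitted)^2), fitted = fitted)
}

# covariance of free parameters from the numerical Hessian of an rss
# objective: cov = 2 * sigma2 * H^-1 with sigma2 = rss/(n - p).
rss_param_se <- function(fn, par, rss, n, p) {
  se <- rep(NA_real_, length(par))
  H <- tryCatch(stats::optimHess(par, fn), error = function(e) NULL)
  if (!is.null(H)) {
    sigma2 <- rss / max(n - p, 1)
    cov <- tryCatch(2 * sigma2 * solve(H), error = function(e) NULL)
    if (!is.null(cov)) {
      d <- diag(cov)
      se[d >= 0] <- sqrt(d[d >= 0])
    }
  }
  se
}

# ---------------------------------------------------------------------------

#' Fit the observed binding rate constant from an association trace
#'
#' Single-exponential fit `F(t) = F_free + A (1 - e^{-k_bind (t - t0)})` by
#' variable projection: the amplitudes `(F_free, A)` are profiled out by
#' linear least squares inside a bounded 1-D (or 2-D with dead time) search
#' over `log k_bind`, multi-started log-spaced around a time-to-half-plateau
#' heuristic; the lowest-RSS start wins.
#'
#' @param trace A [kinetic_trace()] with `assay_kind = "association"` (>= 8
#'   points).
#' @param opts A [fit_opts()] list.
#' @return A `fit_result` with fitted `k_bind`, `F_free`, `A` (and `t0` when
#'   `fit_dead_time`), standard errors from the local curvature of the
#'   objective, RSS, and derived `half_time_s`.
#' @examples
#' tr <- simulate_association(kinetic_params(k_bind = 0.02), seq(0, 600, 10))
#' fit_k_bind(tr)$params$k_bind
#' @export
fit_k_bind <- function(trace, opts = fit_opts()) {
  stopifnot(inherits(trace, "kinetic_trace"))
  if (trace$assay_kind != "association") {
    stop_invalid("fit_k_bind needs an association trace (see trace_window())")
  }
  t <- trace$times; y <- trace$signal; n <- length(y)
  rng <- diff(range(y))
  sig_hat <- estimate_read_noise(y)
  floor_ <- opts$noise_floor %||% (8 * sig_hat)
  if (rng <= floor_) {
    stop_invalid("flat trace: signal range below the noise floor",
                 class = "gok_degenerate_fit")
  }

  basis <- function(k, t0) cbind(1, 1 - exp(-k * pmax(t - t0, 0)))
  profile <- function(par) {
    k <- exp(par[1]); t0 <- if (length(par) > 1L) par[2] else 0
    guarded_lm(basis(k, t0), y, nonneg = c(TRUE, TRUE))$rss
  }

  # heuristic start: time to half plateau
  A0 <- max(y) - y[1]
  i_half <- which(y - y[1] >= A0 / 2)[1]
  t_half <- max(t[i_half] - t[1], diff(range(t)) / (2 * n))
  k0 <- clamp(log(2) / t_half, opts$lower_rate * 10, opts$upper_rate / 10)
  lb <- log_bounds(opts)
  facs <- opts$start_spread ^
    seq(-1, 1, length.out = opts$n_starts)
  starts <- lapply(clamp(log(k0 * facs), lb[1], lb[2]), function(lk) {
    if (opts$fit_dead_time) c(lk, 0) else lk
  })
  lower <- if (opts$fit_dead_time) c(lb[1], 0) else lb[1]
  upper <- if (opts$fit_dead_time) c(lb[2], diff(range(t)) / 4) else lb[2]

  best <- multistart_optim(starts, profile, lower, upper)
  if (is.null(best)) {
    return(new_fit_result(kinetic_params(k_bind = k0), c(k_bind = NA_real_),
                          Inf, n, "k_bind", converged = FALSE,
                          flags = "optimisation failed"))
  }
  k <- exp(best$par[1]); t0 <- if (opts$fit_dead_time) best$par[2] else 0
  lin <- guarded_lm(basis(k, t0), y, nonneg = c(TRUE, TRUE))
  F_free <- lin$coef[1]; A <- lin$coef[2]

  free <- c("k_bind", "F_free", "A", if (opts$fit_dead_time) "t0")
  p_free <- length(free)
  se_prof <- rss_param_se(profile, best$par, lin$rss, n, p_free)
  errs <- c(k_bind = unname(k * se_prof[1]), F_free = NA_real_, A = NA_real_)
  if (opts$fit_dead_time) errs["t0"] <- se_prof[2]

  params <- kinetic_params(k_bind = k, F_free = max(F_free, 0), A = max(A, 0),
                           t0 = t0, rho = opts$rho)
  new_fit_result(params, errs, lin$rss, n, free,
                 converged = best$convergence == 0,
                 derived = list(half_time_s = log(2) / k))
}

#' Fit binding and hydrolysis rates from a BODIPY-GTP trace
#'
#' Fits the sequential scheme (see [simulate_binding_hydrolysis()]) for
#' `k_bind`, `k_hydr`, the amplitude `A`, the relative brightness `rho` and
#' the baseline, with the study's two baseline conventions:
#'
#' * `baseline_mode = "endpoint"` — the convention for traces that hydrolyze
#'   to completion within the run: the final plateau defines the baseline.
#'   By default the endpoint level (mean over the data-flat tail) initializes
#'   the fitted asymptote `F_free + rho * A`, and the fit is flagged
#'   `"endpoint baseline unverified"` when hydrolysis is not complete within
#'   the trace (`k_hydr * duration < 3`), i.e. when the endpoint is not a
#'   post-hydrolysis plateau and the mode should be rejected. Set
#'   `opts$hard_endpoint_anchor = TRUE` to constrain the asymptote to the
#'   endpoint level exactly.
#' * `baseline_mode = "initial"` anchors `F_free` to the first reading; it is
#'   the documented default for hydrolysis-dead, flat-top traces, where the
#'   post-hydrolysis plateau is never reached (there `rho` must be held fixed
#'   at its calibrated value `opts$rho`, as `rho` and `k_hydr` are jointly
#'   unidentifiable without the plateau).
#'
#' `k_hydr` is reported even when it sits at the lower bound (mutant-like
#' traces), together with its standard error.
#'
#' @param trace A [kinetic_trace()] with `assay_kind = "binding_hydrolysis"`.
#' @param baseline_mode `"endpoint"` or `"initial"` (see above).
#' @param opts A [fit_opts()] list.
#' @return A `fit_result` with fitted rates, amplitudes, profile-curvature
#'   standard errors for the rates, RSS, and flags (e.g.
#'   `"binding phase unresolved"` when the trace is shorter than twice the
#'   fitted binding time constant).
#' @export
fit_k_hydr <- function(trace, baseline_mode = c("endpoint", "initial"),
                       opts = fit_opts()) {
  stopifnot(inherits(trace, "kinetic_trace"))
  baseline_mode <- match.arg(baseline_mode)
  if (trace$assay_kind != "binding_hydrolysis") {
    stop_invalid("fit_k_hydr needs a binding_hydrolysis trace")
  }
  t <- trace$times; y <- trace$signal; n <- length(y)
  fit_rho <- isTRUE(opts$fit_rho)
  rho_fix <- opts$rho
  # smoothed trace for all shape heuristics: raw extrema are noise-dominated
  w <- max(5L, n %/% 50L)
  sm <- moving_average(y, w)
  sig_hat <- estimate_read_noise(y)
  i_pk <- which.max(sm)
  # endpoint anchor width: default = the data-flat tail (readings whose
  # smoothed value is within noise of the final level), clamped to [5, n/2]
  en <- opts$endpoint_n
  if (is.null(en)) {
    sm_end <- mean(sm[max(1, n - w + 1L):n])
    thr <- max(3 * sig_hat / sqrt(w), 1e-12)
    off <- which(seq_len(n) > i_pk & abs(sm - sm_end) > thr)
    i_last <- if (length(off)) max(off) else i_pk
    en <- min(max(n - i_last, 5L), n %/% 2L)
  }
  F_end <- mean(y[max(1, n - en + 1L):n])
  F0 <- y[1]

  fractions <- function(k) {
    tt <- t - t[1]
    B <- bh_bound_gtp(tt, k[1], k[2], tol = opts$degeneracy_tol)
    C <- 1 - exp(-k[1] * tt) - B
    list(B = B, C = C)
  }
  hard <- isTRUE(opts$hard_endpoint_anchor)
  # linear sub-problem per baseline mode; returns rss (+ coefs on demand)
  solve_linear <- function(k) {
    fr <- fractions(k)
    if (baseline_mode == "endpoint" && hard) {
      if (fit_rho) {
        # y - F_end = A*B + (rho*A)*(C - 1)
        guarded_lm(cbind(fr$B, fr$C - 1), y - F_end, nonneg = c(TRUE, TRUE))
      } else {
        guarded_lm(cbind(fr$B + rho_fix * (fr$C - 1)), y - F_end,
                   nonneg = TRUE)
      }
    } else if (baseline_mode == "endpoint") {
      if (fit_rho) {
        guarded_lm(cbind(1, fr$B, fr$C), y, nonneg = c(TRUE, TRUE, TRUE))
      } else {
        guarded_lm(cbind(1, fr$B + rho_fix * fr$C), y, nonneg = c(TRUE, TRUE))
      }
    } else {
      if (fit_rho) {
        guarded_lm(cbind(fr$B, fr$C), y - F0, nonneg = c(TRUE, TRUE))
      } else {
        guarded_lm(cbind(fr$B + rho_fix * fr$C), y - F0, nonneg = TRUE)
      }
    }
  }
  profile <- function(lk) solve_linear(exp(lk))$rss

  # heuristic starts; the rise crossing uses the raw trace (smoothing blurs
  # injector-fast rises), the decay heuristics the smoothed one
  A0 <- max(sm[i_pk] - F0, max(y) - F0, 1e-12)
  i_half <- which(y - F0 >= A0 / 2)[1]
  t_half <- max(t[i_half] - t[1], diff(range(t)) / (2 * n))
  kb0 <- clamp(log(2) / t_half, opts$lower_rate * 10, opts$upper_rate / 10)
  tail_span <- max(t[n] - t[i_pk], diff(range(t)) / n)
  sm_last <- mean(sm[max(1, n - w + 1L):n])
  drop_ <- sm[i_pk] - sm_last
  if (drop_ > max(4 * sig_hat / sqrt(w), 0.05 * A0)) {
    # visible decay: half-time of the approach to the end level
    base <- if (baseline_mode == "endpoint") F_end else sm_last
    half <- base + (sm[i_pk] - base) / 2
    i_h <- which(seq_len(n) > i_pk & sm <= half)[1]
    t_dec <- if (is.na(i_h)) tail_span else max(t[i_h] - t[i_pk], tail_span / n)
    kh0 <- log(2) / t_dec
  } else {
    # flat-top trace: initial decay slope over the tail
    kh0 <- max(drop_, sig_hat / sqrt(w)) /
      max((1 - rho_fix) * A0 * tail_span, 1e-12)
  }
  kh0 <- clamp(kh0, opts$lower_rate * 10, opts$upper_rate / 10)
  lb <- log_bounds(opts)
  facs <- opts$start_spread ^ seq(-1, 1, length.out = opts$n_starts)
  starts <- lapply(facs, function(f) {
    clamp(log(c(kb0, kh0) * f), lb[1], lb[2])
  })
  # guard against the rate-swap basin of the sequential scheme
  starts <- c(starts, list(clamp(log(c(kh0, kb0)), lb[1], lb[2])))

  best <- multistart_optim(starts, profile, rep(lb[1], 2), rep(lb[2], 2))
  if (is.null(best)) {
    return(new_fit_result(kinetic_params(), c(k_bind = NA, k_hydr = NA),
                          Inf, n, c("k_bind", "k_hydr"), baseline_mode,
                          converged = FALSE, flags = "optimisation failed"))
  }
  k <- exp(best$par)
  # With rho free the sequential model is exactly swap-degenerate:
  # (k_bind, k_hydr, A, rho) and (k_hydr, k_bind, A', rho') produce identical
  # signals. Ties are broken in favour of the lower k_hydr.
  if (fit_rho && k[2] > k[1]) {
    rss_swap <- profile(log(rev(k)))
    if (rss_swap <= best$value * (1 + 1e-9) ||
        rss_swap - best$value <= 1e-9 * max(abs(best$value), 1)) {
      best$par <- log(rev(k))
      best$value <- rss_swap
      k <- rev(k)
    }
  }
  lin <- solve_linear(k)
  if (baseline_mode == "endpoint" && hard) {
    if (fit_rho) {
      A <- lin$coef[1]
      rho <- if (A > 0) clamp(lin$coef[2] / A, 0, opts$rho_max) else rho_fix
    } else {
      A <- lin$coef[1]; rho <- rho_fix
    }
    F_free <- max(F_end - rho * A, 0)
  } else if (baseline_mode == "endpoint") {
    F_free <- max(lin$coef[1], 0)
    if (fit_rho) {
      A <- lin$coef[2]
      rho <- if (A > 0) clamp(lin$coef[3] / A, 0, opts$rho_max) else rho_fix
    } else {
      A <- lin$coef[2]; rho <- rho_fix
    }
  } else {
    if (fit_rho) {
      A <- lin$coef[1]
      rho <- if (A > 0) clamp(lin$coef[2] / A, 0, opts$rho_max) else rho_fix
    } else {
      A <- lin$coef[1]; rho <- rho_fix
    }
    F_free <- max(F0, 0)
  }

  free <- c("k_bind", "k_hydr", "A", if (fit_rho) "rho")
  p_free <- length(free) + 1L  # + the baseline degree of freedom
  se_prof <- rss_param_se(profile, best$par, lin$rss, n, p_free)
  errs <- c(k_bind = unname(k[1] * se_prof[1]),
            k_hydr = unname(k[2] * se_prof[2]),
            A = NA_real_, rho = NA_real_)

  flags <- character()
  if (diff(range(t)) < 2 / k[1]) flags <- c(flags, "binding phase unresolved")
  if (baseline_mode == "endpoint" && k[2] * diff(range(t)) < 3) {
    # hydrolysis not complete within the trace: the endpoint is not a
    # post-hydrolysis plateau, so the endpoint convention does not apply
    flags <- c(flags, "endpoint baseline unverified")
  }

  params <- kinetic_params(k_bind = k[1], k_hydr = k[2],
                           F_free = F_free, A = max(A, 0), rho = rho)
  new_fit_result(params, errs, lin$rss, n, free, baseline_mode,
                 converged = best$convergence == 0,
                 derived = list(half_time_s = log(2) / k[1],
                                plateau = F_free + rho * max(A, 0)),
                 flags = flags)
}

#' Fit the dissociation rate from a GDP-challenge displacement trace
#'
#' Fits the post-injection readings with a single exponential decay
#' `F(t) = F_res + (F_pre - F_res) e^{-k_diss (t - t_inj)}` (variable
#' projection over `log k_diss`). The pre-injection plateau `F_pre` is the
#' mean of the readings before `injection_index`. When
#' `opts$dilution_correction` is set, post-injection readings are first
#' divided by `opts$d_inj`.
#'
#' The derived `retained_fraction` is `(F_res - F_free)/(F_pre - F_free)` when
#' `opts$F_free` is supplied, else `F_res / F_pre`. When the fitted rate sits
#' at the lower bound (no visible decay), `F_res` falls back to the mean of
#' the post-injection readings and the result is flagged `"no decay"`.
#'
#' @param trace A displacement [kinetic_trace()] with at least 8 post-injection
#'   readings.
#' @param opts A [fit_opts()] list.
#' @return A `fit_result` with fitted `k_diss`, `F_pre`, `F_res`, the derived
#'   `retained_fraction` and `half_time_s`.
#' @export
fit_k_diss <- function(trace, opts = fit_opts()) {
  stopifnot(inherits(trace, "kinetic_trace"))
  if (trace$assay_kind != "displacement" || is.null(trace$injection_index)) {
    stop_invalid("fit_k_diss needs a displacement trace with injection_index")
  }
  i0 <- trace$injection_index
  n_post <- length(trace$times) - i0 + 1L
  if (n_post < 8L) stop_invalid("need at least 8 post-injection readings")
  if (i0 < 2L) stop_invalid("need at least one pre-injection reading")
  F_pre <- mean(trace$signal[seq_len(i0 - 1L)])
  tau <- trace$times[i0:length(trace$times)] - trace$times[i0]
  y <- trace$signal[i0:length(trace$times)]
  if (opts$dilution_correction) y <- y / opts$d_inj
  n <- length(y)

  profile <- function(lk) {
    guarded_lm(cbind(1, exp(-exp(lk) * tau)), y, nonneg = c(TRUE, FALSE))$rss
  }
  drop0 <- y[1] - y[n]
  i_half <- which(y[1] - y <= drop0 / 2)
  t_half <- max(tau[utils::tail(i_half, 1)], tau[2] / 2)
  k0 <- clamp(log(2) / t_half, opts$lower_rate * 10, opts$upper_rate / 10)
  lb <- log_bounds(opts)
  facs <- opts$start_spread ^ seq(-1, 1, length.out = opts$n_starts)
  starts <- as.list(clamp(log(k0 * facs), lb[1], lb[2]))
  best <- multistart_optim(starts, profile, lb[1], lb[2])
  if (is.null(best)) {
    return(new_fit_result(kinetic_params(), c(k_diss = NA_real_), Inf, n,
                          "k_diss", converged = FALSE,
                          flags = "optimisation failed"))
  }
  k <- exp(best$par)
  lin <- guarded_lm(cbind(1, exp(-k * tau)), y, nonneg = c(TRUE, FALSE))
  F_res <- max(lin$coef[1], 0)
  flags <- character()
  # no visible decay: the exponential term is degenerate (any rate fits a
  # constant equally well), so report the rate at its lower bound
  rss_const <- sum((y - mean(y))^2)
  if (k <= 1e-6 || abs(lin$coef[2]) <= 1e-9 * max(abs(y)) ||
      lin$rss >= rss_const - 1e-12 * max(rss_const, 1)) {
    k <- opts$lower_rate
    F_res <- mean(y)
    lin <- guarded_lm(cbind(1, exp(-k * tau)), y, nonneg = c(TRUE, FALSE))
    flags <- c(flags, "no decay")
  }
  se_prof <- rss_param_se(profile, best$par, lin$rss, n, 3L)
  errs <- c(k_diss = unname(k * se_prof[1]),
            F_pre = NA_real_, F_res = NA_real_)
  rf <- if (!is.null(opts$F_free)) {
    (F_res - opts$F_free) / (F_pre - opts$F_free)
  } else {
    F_res / F_pre
  }
  params <- kinetic_params(k_diss = k, F_free = opts$F_free %||% 0,
                           A = max(F_pre - (opts$F_free %||% 0), 0),
                           rho = opts$rho)
  new_fit_result(params, errs, lin$rss, n, "k_diss",
                 converged = best$convergence == 0,
                 derived = list(retained_fraction = rf, F_pre = F_pre,
                                F_res = F_res, half_time_s = log(2) / k),
                 flags = flags)
}

#' Compare a dissociation rate with a binding rate
#'
#' Welch-style two-sided z comparison of `k_diss` against `k_bind` using the
#' two fitted standard errors:
#' `z = (k_diss - k_bind) / sqrt(se_diss^2 + se_bind^2)`. Used to test whether
#' probe dissociation outpaces uptake (the signature of the pathologic
#' mutants).
#'
#' @param diss A converged `fit_result` from [fit_k_diss()].
#' @param bind A converged `fit_result` from [fit_k_bind()].
#' @param alpha Two-sided significance level (default 0.05).
#' @return A list with `ratio` (`k_diss / k_bind`), `z`, `p_value`, and
#'   `exceeds` (`ratio > 1` and significant at `alpha`).
#' @export
compare_rates <- function(diss, bind, alpha = 0.05) {
  stopifnot(inherits(diss, "fit_result"), inherits(bind, "fit_result"))
  if (!diss$converged || !bind$converged) {
    stop_invalid("both fits must have converged")
  }
  kd <- diss$params$k_diss; kb <- bind$params$k_bind
  sd_ <- diss$param_errors[["k_diss"]]; sb <- bind$param_errors[["k_bind"]]
  if (!is.finite(sd_) || !is.finite(sb) || (sd_ == 0 && sb == 0)) {
    stop_invalid("comparison undefined: missing or zero standard errors",
                 class = "gok_undefined_comparison")
  }
  z <- (kd - kb) / sqrt(sd_^2 + sb^2)
  p <- 2 * stats::pnorm(-abs(z))
  list(ratio = kd / kb, z = z, p_value = p,
       exceeds = (kd / kb > 1) && (p < alpha), alpha = alpha)
}

#' Fold change of a fitted rate between two fits
#'
#' `ratio = mutant rate / wildtype rate` with the relative error propagated in
#' quadrature from the two fits' standard errors.
#'
#' @param mutant,wildtype Converged `fit_result` objects.
#' @param which One of `"k_bind"`, `"k_hydr"`, `"k_diss"`.
#' @return A list with `ratio`, `rel_err`, `se` (= `ratio * rel_err`) and
#'   `which`.
#' @export
fold_change <- function(mutant, wildtype,
                        which = c("k_bind", "k_hydr", "k_diss")) {
  which <- match.arg(which)
  stopifnot(inherits(mutant, "fit_result"), inherits(wildtype, "fit_result"))
  if (!mutant$converged || !wildtype$converged) {
    stop_invalid("both fits must have converged")
  }
  m <- mutant$params[[which]]; w <- wildtype$params[[which]]
  if (!is.finite(w) || w <= 1.01e-8) {
    stop_invalid("wildtype rate at the lower bound: fold change unstable",
                 class = "gok_division_unstable")
  }
  ratio <- m / w
  rm_ <- mutant$param_errors[[which]] / m
  rw <- wildtype$param_errors[[which]] / w
  rel <- if (is.finite(rm_) && is.finite(rw)) sqrt(rm_^2 + rw^2) else NA_real_
  list(ratio = ratio, rel_err = rel, se = ratio * rel, which = which)
}

#' Batch-fit a set of traces to a tidy table
#'
#' Applies the fitter matching each trace's `assay_kind` and collects one row
#' per well: rates, standard errors, RSS, baseline mode and flags. Fit
#' failures yield a row with `converged = FALSE`.
#'
#' @param traces A list of [kinetic_trace()] objects (e.g. from
#'   [read_traces_csv()]).
#' @param baseline_mode Baseline convention passed to [fit_k_hydr()].
#' @param opts A [fit_opts()] list.
#' @return A data.frame, one row per trace.
#' @export
fit_traces <- function(traces, baseline_mode = "endpoint", opts = fit_opts()) {
  rows <- lapply(seq_along(traces), function(i) {
    tr <- traces[[i]]
    well <- tr$well_id %||% paste0("W", i)
    fit <- tryCatch(switch(tr$assay_kind,
                           association = fit_k_bind(tr, opts),
                           binding_hydrolysis =
                             fit_k_hydr(tr, baseline_mode, opts),
                           displacement = fit_k_diss(tr, opts)),
                    error = function(e) NULL)
    if (is.null(fit)) {
      return(data.frame(well = well, assay_kind = tr$assay_kind,
                        k_bind = NA_real_, k_bind_se = NA_real_,
                        k_hydr = NA_real_, k_hydr_se = NA_real_,
                        k_diss = NA_real_, k_diss_se = NA_real_,
                        rss = NA_real_, n_points = length(tr$times),
                        baseline_mode = NA_character_, converged = FALSE,
                        flags = "fit error"))
    }
    data.frame(well = well, assay_kind = tr$assay_kind,
               k_bind = fit$params$k_bind,
               k_bind_se = fit$param_errors["k_bind"] %na%
                 NA_real_,
               k_hydr = fit$params$k_hydr,
               k_hydr_se = fit$param_errors["k_hydr"] %na% NA_real_,
               k_diss = fit$params$k_diss,
               k_diss_se = fit$param_errors["k_diss"] %na% NA_real_,
               rss = fit$rss, n_points = fit$n_points,
               baseline_mode = fit$baseline_mode,
               converged = fit$converged,
               flags = paste(fit$flags, collapse = ";"))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Serialize a fit result to JSON
#'
#' Writes parameters, standard errors, diagnostics and derived quantities.
#'
#' @param fit A `fit_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "fit_result"))
  jsonlite::write_json(
    list(params = unclass(fit$params),
         param_errors = as.list(fit$param_errors),
         rss = fit$rss, n_points = fit$n_points,
         baseline_mode = fit$baseline_mode, converged = fit$converged,
         derived = fit$derived, flags = as.list(fit$flags)),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

`%na%` <- function(x, alt) {
  v <- suppressWarnings(x[1])
  if (length(v) == 0 || is.null(v)) alt else unname(v)
}
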