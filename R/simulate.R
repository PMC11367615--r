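#' Time derivatives of the multi-hit repair system
#'
#' Reference (pure-R) right-hand side of the MHR ordinary differential
#' equations, in the form deSolve expects. [simulate_mhr()] normally uses
#' the compiled equivalent; this function is exported for inspection and
#' testing.
#'
#' The state is `(L_0, ..., L_kmax, Gamma)`. For interior populations
#' `dL_i/dt = alpha R (L_{i-1} - L_i) - c_r P_r L_i + c_r P_r L_{i+1} - c_e L_i`
#' with `P_r = exp(-mu_gamma * Gamma)`. `L_0` has no hit influx, no repair
#' outflow and no elimination; `L_kmax` receives no repair influx from above
#' and its hit outflow leaves the tracked system. The TBDE obeys
#' `dGamma/dt = R - gamma * Gamma`. `R` is the dose-rate in Gy/h.
#'
#' @param t Time, h.
#' @param state Numeric vector `(L_0, ..., L_kmax, Gamma)`.
#' @param params An [mhr_params()] object.
#' @param rate_gy_h Dose-rate at `t`, Gy/h (constant within a pulse segment).
#' @return A list whose first element is the derivative vector.
#' @export
mhr_derivative <- function(t, state, params, rate_gy_h) {
  n <- length(state)
  if (n < 3L) {
    stop("state must hold at least (L_0, L_1, Gamma)", call. = FALSE)
  }
  kmax <- n - 2L
  L <- state[seq_len(kmax + 1L)]
  G <- state[n]
  pr <- params$c_r * exp(-params$mu_gamma * G)
  aR <- params$alpha * rate_gy_h
  dL <- numeric(kmax + 1L)
  dL[1L] <- -aR * L[1L] + pr * L[2L]
  if (kmax > 1L) {
    i <- 2L:kmax
    dL[i] <- aR * (L[i - 1L] - L[i]) - pr * L[i] + pr * L[i + 1L] -
      params$c_e * L[i]
  }
  dL[kmax + 1L] <- aR * L[kmax] - aR * L[kmax + 1L] - pr * L[kmax + 1L] -
    params$c_e * L[kmax + 1L]
  list(c(dL, rate_gy_h - params$gamma * G))
}

# Piecewise-constant dose-rate segments of a protocol, in Gy/h.
# Returns data.frame(from, to, rate_gy_h) covering [0, horizon].
protocol_segments <- function(protocol, followup_h) {
  edges <- sort(unique(c(0, protocol$start_h, protocol$end_h)))
  horizon <- max(protocol$end_h) + followup_h
  edges <- c(edges[edges < horizon], horizon)
  from <- edges[-length(edges)]
  to <- edges[-1]
  mid <- (from + to) / 2
  data.frame(from = from, to = to,
             rate_gy_h = dose_rate_at(protocol, mid) * 60)
}

#' Simulate the multi-hit repair model
#'
#' Integrates the MHR system for a given parameter set and irradiation
#' protocol, starting from a fully clonogenic population (`L_0 = 1`, all
#' damaged populations and the TBDE at 0) and running until `followup_h`
#' hours after the last pulse ends.
#'
#' Integration uses `deSolve::ode` (lsoda, stiff-capable) with a compiled
#' right-hand side, split piecewise at pulse edges so the square dose-rate
#' pulse is represented exactly.
#'
#' @param params An [mhr_params()] object.
#' @param protocol An [irradiation()] protocol.
#' @param config An [sim_config()] object.
#' @param times Optional extra output times (h) to include in the trajectory.
#' @return An object of class `mhr_trajectory`: list with `times` (h),
#'   `populations` (matrix, columns `L0..Lkmax`), `tbde` (Gy), and the
#'   inputs. Small negative solver underflow is clamped to 0 on output.
#' @examples
#' tr <- simulate_mhr(mhr_params(0.26, 7.76, 0.83, 0.31, 0.31),
#'                    irradiation(6, 6))
#' surviving_fraction(tr)
#' @export
simulate_mhr <- function(params, protocol, config = sim_config(),
                         times = NULL) {
  stopifnot(inherits(params, "mhr_params"),
            inherits(protocol, "mhr_protocol"),
            inherits(config, "mhr_sim_config"))
  segs <- protocol_segments(protocol, config$followup_h)
  n_state <- config$k_max + 2L
  y <- c(1, numeric(n_state - 1L))
  names(y) <- c(paste0("L", 0:config$k_max), "tbde")

  out_t <- list()
  out_y <- list()
  extra <- if (is.null(times)) numeric(0) else sort(unique(times))
  if (length(extra) && (min(extra) < 0 ||
                        max(extra) > segs$to[nrow(segs)] + 1e-9)) {
    stop("requested output times fall outside the simulated span",
         call. = FALSE)
  }

  for (s in seq_len(nrow(segs))) {
    span <- segs$to[s] - segs$from[s]
    if (span <= 0) next
    active <- segs$rate_gy_h[s] > 0
    hmax <- if (active) config$max_step_s / 3600 else
      config$max_step_free_s / 3600
    # output grid: segment edges, any requested times, plus a modest
    # uniform grid so trajectories interpolate well
    grid <- unique(sort(c(
      segs$from[s], segs$to[s],
      extra[extra > segs$from[s] & extra < segs$to[s]],
      seq(segs$from[s], segs$to[s], length.out = min(101L, max(
        2L, ceiling(span / 0.05) + 1L)))
    )))
    sol <- deSolve::ode(
      y = y, times = grid, func = "mhr_deriv", parms = c(
        params$alpha, params$c_r, params$c_e, params$mu_gamma,
        params$gamma, segs$rate_gy_h[s]),
      dllname = "mhrcal", initfunc = "mhr_init",
      method = "lsoda", rtol = config$rel_tol, atol = config$abs_tol,
      hmax = min(hmax, span))
    if (attr(sol, "istate")[1] < 0) {
      stop(sprintf(
        "ODE integration failed in segment %d (params: %s; protocol: %s)",
        s, paste(signif(unlist(params), 4), collapse = ","),
        paste(signif(protocol$dose_gy, 4), collapse = "+")), call. = FALSE)
    }
    y <- sol[nrow(sol), -1]
    keep <- if (s < nrow(segs)) -nrow(sol) else TRUE  # avoid duplicate edges
    out_t[[s]] <- sol[keep, 1]
    out_y[[s]] <- sol[keep, -1, drop = FALSE]
  }

  tt <- unlist(out_t)
  yy <- do.call(rbind, out_y)
  pops <- pmax(yy[, seq_len(config$k_max + 1L), drop = FALSE], 0)
  structure(list(times = tt, populations = pops,
                 tbde = pmax(yy[, n_state], 0),
                 params = params, protocol = protocol, config = config),
            class = "mhr_trajectory")
}

#' @export
print.mhr_trajectory <- function(x, ...) {
  cat(sprintf(
    "MHR trajectory: %d time points over [0, %.3g] h, k_max = %d\n",
    length(x$times), max(x$times), ncol(x$populations) - 1L))
  cat(sprintf("  final L0 (surviving fraction): %.4g\n",
              surviving_fraction(x)))
  invisible(x)
}

#' Surviving fraction of a trajectory
#'
#' Only undamaged cells (`L_0`) retain proliferative capacity, so the
#' clonogenic surviving fraction equals `L_0` at the end of the simulation.
#'
#' @param traj An `mhr_trajectory` from [simulate_mhr()].
#' @return Surviving fraction in `[0, 1]`.
#' @export
surviving_fraction <- function(traj) {
  stopifnot(inherits(traj, "mhr_trajectory"), length(traj$times) > 0)
  min(max(traj$populations[length(traj$times), 1L], 0), 1)
}

#' Closed-form transient biological dose equivalent
#'
#' Analytic solution of `dGamma/dt = R - gamma * Gamma` for a single square
#' pulse of amplitude `R_max` lasting `t_rad` hours: a saturating rise
#' `(R/gamma) (1 - exp(-gamma t))` during the pulse and exponential decay
#' afterwards. Serves as an independent oracle for the integrated TBDE.
#'
#' @param R_max_gy_min Pulse amplitude, Gy/min.
#' @param gamma TBDE repair rate constant, 1/h; `gamma = 0` degenerates to
#'   linear accumulation then a constant.
#' @param t Time(s) since pulse start, h; vectorized.
#' @param t_rad_h Pulse duration, h.
#' @return `Gamma(t)` in Gy.
#' @export
tbde_closed_form <- function(R_max_gy_min, gamma, t, t_rad_h) {
  stopifnot(gamma >= 0, t_rad_h >= 0, all(t >= 0))
  R <- R_max_gy_min * 60  # Gy/h
  if (gamma == 0) {
    return(R * pmin(t, t_rad_h))
  }
  peak <- (R / gamma) * (1 - exp(-gamma * t_rad_h))
  ifelse(t <= t_rad_h,
         (R / gamma) * (1 - exp(-gamma * t)),
         peak * exp(-gamma * (t - t_rad_h)))
}

#' Simulated survival as a function of dose
#'
#' Convenience wrapper: one single-fraction simulation per dose at a common
#' dose-rate, each followed up `config$followup_h` hours after its pulse
#' ends (so protracted low-dose-rate irradiations are observed on their own
#' clock). A dose of 0 contributes the unirradiated survival of 1.
#'
#' @param params An [mhr_params()] object.
#' @param doses_gy Numeric vector of doses, Gy (>= 0).
#' @param dose_rate_gy_min Dose-rate, Gy/min.
#' @param config An [sim_config()].
#' @return Data frame with columns `dose_gy`, `dose_rate_gy_min`, `survival`.
#' @export
survival_curve <- function(params, doses_gy, dose_rate_gy_min,
                           config = sim_config()) {
  surv <- vapply(doses_gy, function(D) {
    if (D == 0) return(1)
    surviving_fraction(simulate_mhr(
      params, irradiation(D, dose_rate_gy_min), config))
  }, numeric(1))
  data.frame(dose_gy = doses_gy, dose_rate_gy_min = dose_rate_gy_min,
             survival = surv)
}
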