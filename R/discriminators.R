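#' Discriminator configuration
#'
#' Doses, dose-rates and thresholds for the nine theoretical dose-rate
#' discriminator conditions used to screen parameter sets:
#'
#' * I: survival at 2 Gy/min must be equal to or higher than at 20 Gy/min
#'   at every test dose.
#' * II: survival at 0.1 Gy/min must be strictly higher than at 2 Gy/min.
#' * III/IV: the log10-survival difference between 0.1 and 2 Gy/min must
#'   increase with dose (III: 6 vs 3 Gy; IV: 9 vs 6 Gy).
#' * V: at a very low dose-rate the log survival curve must be linear in
#'   dose (exponential limit).
#' * VI: a split course (2 x 3 Gy, 2 h apart) must survive strictly better
#'   than an acute 6 Gy.
#' * VII: simulated survival must lie within the error bars of the
#'   clonogenic data (evaluated only when data are supplied).
#' * VIII: log10 survival below 10 Gy must follow a linear-quadratic (LQ)
#'   shape with non-negative coefficients.
#' * IX: over a broader dose range, log10 survival must follow a
#'   linear-quadratic-linear (LQL) shape.
#'
#' @param doses_gy Test doses for I-IV, Gy (default 3, 6, 9).
#' @param rates_gy_min Dose-rates for I-IV, Gy/min (default 0.1, 2, 20).
#' @param low_rate_gy_min Dose-rate for the exponential-limit check V
#'   (default 0.01 Gy/min).
#' @param low_rate_doses_gy Dose grid for V (default 0..10 Gy).
#' @param frac_total_gy,frac_n,frac_gap_h Fractionation check VI: total dose
#'   (default 6 Gy) split into `frac_n` fractions (default 2) with
#'   `frac_gap_h` hours between fractions (default 2).
#' @param ref_rate_gy_min Reference (acute) dose-rate for VI, VIII, IX,
#'   Gy/min (default 6).
#' @param lq_doses_gy Dose grid for the LQ fit VIII (< 10 Gy; default 1..9).
#' @param lql_doses_gy Dose grid for the LQL fit IX (default 2.5..25).
#' @param lql_transition_grid_gy Candidate LQ-to-linear transition doses
#'   for IX (default 5..20).
#' @param r2_threshold Minimum coefficient of determination for the shape
#'   fits V, VIII, IX (default 0.99).
#' @param tol Numerical guard on the survival comparisons of conditions
#'   I-IV and VI (default 1e-9): a strict inequality must hold by more than
#'   `tol` so that solver noise at the integration-tolerance scale cannot
#'   flip a decision (degenerate dynamics, e.g. no repair, produce
#'   survivals equal up to that noise).
#' @return A `discriminator_config` object.
#' @export
discriminator_config <- function(doses_gy = c(3, 6, 9),
                                 rates_gy_min = c(0.1, 2, 20),
                                 low_rate_gy_min = 0.01,
                                 low_rate_doses_gy = 0:10,
                                 frac_total_gy = 6, frac_n = 2L,
                                 frac_gap_h = 2,
                                 ref_rate_gy_min = 6,
                                 lq_doses_gy = 1:9,
                                 lql_doses_gy = seq(2.5, 25, 2.5),
                                 lql_transition_grid_gy = seq(5, 20, 1),
                                 r2_threshold = 0.99, tol = 1e-9) {
  stopifnot(length(doses_gy) == 3, !is.unsorted(doses_gy),
            length(rates_gy_min) == 3, !is.unsorted(rates_gy_min),
            low_rate_gy_min > 0, frac_total_gy > 0, frac_n >= 2,
            frac_gap_h > 0, ref_rate_gy_min > 0,
            r2_threshold > 0, r2_threshold <= 1, tol >= 0)
  structure(list(doses_gy = doses_gy, rates_gy_min = rates_gy_min,
                 low_rate_gy_min = low_rate_gy_min,
                 low_rate_doses_gy = low_rate_doses_gy,
                 frac_total_gy = frac_total_gy, frac_n = as.integer(frac_n),
                 frac_gap_h = frac_gap_h,
                 ref_rate_gy_min = ref_rate_gy_min,
                 lq_doses_gy = lq_doses_gy, lql_doses_gy = lql_doses_gy,
                 lql_transition_grid_gy = lql_transition_grid_gy,
                 r2_threshold = r2_threshold, tol = tol),
            class = "discriminator_config")
}

# centered coefficient of determination
r_squared <- function(y, fitted) {
  sst <- sum((y - mean(y))^2)
  if (sst == 0) return(1)
  1 - sum((y - fitted)^2) / sst
}

#' Dose-rate ordering conditions (I-IV)
#'
#' Simulates survival at the configured doses and dose-rates and evaluates
#' the four dose-rate ordering conditions (see [discriminator_config()]).
#'
#' @param params An [mhr_params()] object.
#' @param config A [discriminator_config()].
#' @param sim An [sim_config()].
#' @return List with logical `pass` per condition `I..IV` and a `survival`
#'   matrix (dose x rate) of diagnostics.
#' @export
dose_rate_ordering <- function(params, config = discriminator_config(),
                               sim = sim_config()) {
  D <- config$doses_gy
  R <- config$rates_gy_min
  S <- sapply(R, function(r) survival_curve(params, D, r, sim)$survival)
  dimnames(S) <- list(paste0(D, "Gy"), paste0(R, "Gy/min"))
  if (any(S <= 0)) {
    return(list(pass = c(I = FALSE, II = FALSE, III = FALSE, IV = FALSE),
                survival = S, note = "non-positive survival"))
  }
  delta <- unname(log10(S[, 1]) - log10(S[, 2]))  # low vs mid rate, per dose
  eps <- config$tol
  list(pass = c(I = all(S[, 2] >= S[, 3] - eps),
                II = all(S[, 1] > S[, 2] + eps),
                III = delta[2] > delta[1] + eps,
                IV = delta[3] > delta[2] + eps),
       survival = S, log_difference = delta)
}

#' Low dose-rate exponential limit (condition V)
#'
#' At a very low dose-rate, sublethal damage is repaired during the
#' exposure and the survival curve must become exponential: a straight line
#' in log10 survival vs dose with non-positive slope.
#'
#' @inheritParams dose_rate_ordering
#' @return List with `pass`, the fitted `slope`, `r2` and the simulated
#'   curve.
#' @export
low_dose_rate_linearity <- function(params, config = discriminator_config(),
                                    sim = sim_config()) {
  sc <- survival_curve(params, config$low_rate_doses_gy,
                       config$low_rate_gy_min, sim)
  if (any(sc$survival <= 0)) {
    return(list(pass = FALSE, curve = sc, note = "non-positive survival"))
  }
  y <- log10(sc$survival)
  fit <- stats::lm(y ~ sc$dose_gy)
  r2 <- r_squared(y, stats::fitted(fit))
  slope <- unname(stats::coef(fit)[2])
  list(pass = r2 >= config$r2_threshold && slope <= 0,
       slope = slope, r2 = r2, curve = sc)
}

#' Fractionation sparing (condition VI)
#'
#' Compares an acute delivery of the total dose with a split course of
#' equal fractions separated by a recovery gap; repair between fractions
#' must make the fractionated survival strictly higher.
#'
#' @inheritParams dose_rate_ordering
#' @return List with `pass`, `s_acute`, `s_fractionated`.
#' @export
fractionation_sparing <- function(params, config = discriminator_config(),
                                  sim = sim_config()) {
  rate <- config$ref_rate_gy_min
  d_frac <- config$frac_total_gy / config$frac_n
  t_rad <- d_frac / (rate * 60)
  starts <- (seq_len(config$frac_n) - 1L) * (t_rad + config$frac_gap_h)
  s_acute <- surviving_fraction(simulate_mhr(
    params, irradiation(config$frac_total_gy, rate), sim))
  s_frac <- surviving_fraction(simulate_mhr(
    params, irradiation(rep(d_frac, config$frac_n), rate, starts), sim))
  list(pass = s_frac > s_acute + config$tol,
       s_acute = s_acute, s_fractionated = s_frac)
}

#' Experimental data coverage (condition VII)
#'
#' Simulated survival at each measured (dose, dose-rate) must lie within
#' one standard deviation of the measured mean.
#'
#' @param params An [mhr_params()] object.
#' @param data A [survival_dataset()]; `NULL` or empty marks the condition
#'   not evaluated.
#' @param sim An [sim_config()].
#' @return List with `pass` (`NA` when not evaluated) and a per-point
#'   diagnostic table.
#' @export
data_coverage <- function(params, data, sim = sim_config()) {
  if (is.null(data) || nrow(data) == 0) {
    return(list(pass = NA, note = "no survival data; not evaluated"))
  }
  d <- data[data$dose_gy > 0, , drop = FALSE]
  pred <- vapply(seq_len(nrow(d)), function(i) {
    surviving_fraction(simulate_mhr(
      params, irradiation(d$dose_gy[i], d$dose_rate_gy_min[i]), sim))
  }, numeric(1))
  inside <- pred >= d$survival_mean - d$survival_sd &
    pred <= d$survival_mean + d$survival_sd
  tab <- data.frame(d[, c("dose_gy", "dose_rate_gy_min")],
                    observed = d$survival_mean, sd = d$survival_sd,
                    simulated = pred, inside = inside)
  list(pass = all(inside), table = tab,
       note = if (!all(inside)) {
         paste0("outside error bars at ",
                paste(sprintf("%g Gy @ %g Gy/min", d$dose_gy[!inside],
                              d$dose_rate_gy_min[!inside]), collapse = "; "))
       })
}

# LQL fit: -log10 S = a*min(D,DT) + b*min(D,DT)^2 + s*max(D-DT,0),
# continuous piecewise LQ-then-linear; transition dose DT grid-searched.
fit_lql <- function(dose, y, transition_grid) {
  best <- list(r2 = -Inf)
  for (DT in transition_grid) {
    ua <- pmin(dose, DT)
    ub <- ua^2
    us <- pmax(dose - DT, 0)
    X <- cbind(ua, ub, us)
    fit <- stats::lm.fit(X, y)
    r2 <- r_squared(y, X %*% fit$coefficients)
    if (r2 > best$r2) {
      best <- list(r2 = r2, transition_gy = DT,
                   coef = stats::setNames(fit$coefficients,
                                          c("a", "b", "slope")))
    }
  }
  best
}

#' Survival-shape conditions (VIII-IX)
#'
#' VIII fits the origin-constrained linear-quadratic form
#' `-log10 S = a D + b D^2` below 10 Gy and requires a close fit with
#' non-negative coefficients. IX fits a continuous piecewise LQ-then-linear
#' (LQL) curve over a broader dose range, grid-searching the transition
#' dose, and requires a close fit.
#'
#' @inheritParams dose_rate_ordering
#' @return List with per-condition `pass`, fitted coefficients and R^2.
#' @export
shape_conditions <- function(params, config = discriminator_config(),
                             sim = sim_config()) {
  rate <- config$ref_rate_gy_min
  lq <- survival_curve(params, config$lq_doses_gy, rate, sim)
  lql <- survival_curve(params, config$lql_doses_gy, rate, sim)
  if (any(lq$survival <= 0) || any(lql$survival <= 0)) {
    return(list(pass = c(VIII = FALSE, IX = FALSE),
                note = "non-positive survival"))
  }
  y8 <- -log10(lq$survival)
  X <- cbind(D = lq$dose_gy, D2 = lq$dose_gy^2)
  f8 <- stats::lm.fit(X, y8)
  ab <- stats::setNames(f8$coefficients, c("a", "b"))
  r2_8 <- r_squared(y8, X %*% f8$coefficients)
  f9 <- fit_lql(lql$dose_gy, -log10(lql$survival),
                config$lql_transition_grid_gy)
  list(pass = c(VIII = r2_8 >= config$r2_threshold && all(ab >= 0),
                IX = f9$r2 >= config$r2_threshold),
       lq_coef = ab, lq_r2 = r2_8,
       lql_coef = f9$coef, lql_r2 = f9$r2,
       lql_transition_gy = f9$transition_gy)
}

#' Evaluate all discriminator conditions for one parameter set
#'
#' Runs conditions I-IX and combines them. Condition VII is evaluated only
#' when survival data are supplied; otherwise it is excluded from the
#' overall conjunction (the purely theoretical screen I-VI, VIII, IX).
#'
#' @param params An [mhr_params()] object.
#' @param data Optional [survival_dataset()] for condition VII.
#' @param config A [discriminator_config()].
#' @param sim An [sim_config()].
#' @return A `discriminator_report`: list with `conditions` (named logical,
#'   `NA` = not evaluated), `overall` (conjunction of evaluated conditions)
#'   and per-condition diagnostics.
#' @examples
#' \donttest{
#' rep <- evaluate_discriminators(
#'   mhr_params(0.26, 7.76, 0.83, 0.31, 0.31))
#' rep$overall
#' }
#' @export
evaluate_discriminators <- function(params, data = NULL,
                                    config = discriminator_config(),
                                    sim = sim_config()) {
  ord <- dose_rate_ordering(params, config, sim)
  low <- low_dose_rate_linearity(params, config, sim)
  fr <- fractionation_sparing(params, config, sim)
  cov <- data_coverage(params, data, sim)
  sh <- shape_conditions(params, config, sim)
  conditions <- c(ord$pass, V = low$pass, VI = fr$pass, VII = cov$pass,
                  sh$pass)
  structure(list(conditions = conditions,
                 overall = all(conditions, na.rm = TRUE),
                 details = list(ordering = ord, low_dose_rate = low,
                                fractionation = fr, coverage = cov,
                                shape = sh)),
            class = "discriminator_report")
}

#' @export
print.discriminator_report <- function(x, ...) {
  cat("Theoretical discriminator report\n")
  st <- ifelse(is.na(x$conditions), "not evaluated",
               ifelse(x$conditions, "pass", "FAIL"))
  for (i in seq_along(st)) {
    cat(sprintf("  %-4s %s\n", names(x$conditions)[i], st[i]))
  }
  cat(sprintf("  overall: %s\n", if (x$overall) "pass" else "FAIL"))
  invisible(x)
}

#' Filter a calibrated ensemble with the discriminators
#'
#' Applies [evaluate_discriminators()] to every ensemble member and keeps
#' those passing all evaluated conditions, reporting per-condition and
#' collective acceptance percentages.
#'
#' @param ensemble An `mhr_ensemble` from [calibrate_mhr()], or a data frame
#'   with columns `alpha, c_r, c_e, mu_gamma, gamma`.
#' @param data Optional [survival_dataset()] for condition VII.
#' @param config A [discriminator_config()].
#' @param sim An [sim_config()].
#' @return List with `kept` (data frame of surviving members), `flags`
#'   (logical matrix member x condition), and `acceptance_pct` (named
#'   vector: per-condition percentages plus `collective`).
#' @export
filter_ensemble <- function(ensemble, data = NULL,
                            config = discriminator_config(),
                            sim = sim_config()) {
  members <- if (inherits(ensemble, "mhr_ensemble")) {
    ensemble$members
  } else {
    as.data.frame(ensemble)
  }
  stopifnot(nrow(members) > 0)
  flags <- matrix(NA, nrow(members), 9,
                  dimnames = list(NULL, c("I", "II", "III", "IV", "V", "VI",
                                          "VII", "VIII", "IX")))
  overall <- logical(nrow(members))
  for (j in seq_len(nrow(members))) {
    rep_j <- evaluate_discriminators(
      mhr_params(members$alpha[j], members$c_r[j], members$c_e[j],
                 members$mu_gamma[j], members$gamma[j]),
      data, config, sim)
    flags[j, ] <- rep_j$conditions
    overall[j] <- rep_j$overall
  }
  evaluated <- colSums(!is.na(flags)) > 0
  acc <- c(ifelse(evaluated, colMeans(flags, na.rm = TRUE) * 100, NA),
           collective = mean(overall) * 100)
  list(kept = members[overall, , drop = FALSE], flags = flags,
       acceptance_pct = acc)
}
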