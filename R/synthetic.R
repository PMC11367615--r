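#' Synthetic-data specification
#'
#' Defines a ground-truth parameter set and the experimental designs to
#' emulate: a clonogenic survival design (doses, dose-rates, replicates,
#' multiplicative lognormal noise with a given coefficient of variation)
#' and a comet design (a single irradiation followed by sampling of cells
#' at several times). The defaults mirror the study conditions the package
#' targets: survival at 3 and 6 Gy delivered at 6 Gy/min, comet samples at
#' 15, 30, 60, 120, 240 and 360 minutes after a 6 Gy irradiation.
#'
#' @param truth An [mhr_params()] ground truth.
#' @param survival_doses_gy Survival design doses, Gy (default `c(3, 6)`).
#' @param survival_rates_gy_min Dose-rate(s), Gy/min (default 6).
#' @param n_reps Replicates per survival point (default 3).
#' @param cv Coefficient of variation of the multiplicative lognormal
#'   survival noise (default 0.2).
#' @param comet_dose_gy,comet_rate_gy_min Comet irradiation (defaults 6 Gy
#'   at 6 Gy/min).
#' @param comet_times_h Sampling times after irradiation, h (default
#'   15/30/60/120/240/360 min).
#' @param cells_per_time Cells sampled per comet time point (default 200);
#'   `Inf` returns the exact model distribution (no sampling noise).
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(truth,
                           survival_doses_gy = c(3, 6),
                           survival_rates_gy_min = 6,
                           n_reps = 3L, cv = 0.2,
                           comet_dose_gy = 6, comet_rate_gy_min = 6,
                           comet_times_h = c(15, 30, 60, 120, 240, 360) / 60,
                           cells_per_time = 200) {
  stopifnot(inherits(truth, "mhr_params"), cv >= 0, n_reps >= 1,
            length(survival_doses_gy) > 0, length(comet_times_h) > 0,
            all(cells_per_time >= 1))
  structure(list(truth = truth,
                 survival_doses_gy = survival_doses_gy,
                 survival_rates_gy_min = survival_rates_gy_min,
                 n_reps = as.integer(n_reps), cv = cv,
                 comet_dose_gy = comet_dose_gy,
                 comet_rate_gy_min = comet_rate_gy_min,
                 comet_times_h = comet_times_h,
                 cells_per_time = cells_per_time),
            class = "synthetic_spec")
}

#' Generate a synthetic clonogenic survival dataset
#'
#' Forward-simulates the ground truth at every design (dose, dose-rate) and
#' draws replicate survivals with multiplicative lognormal noise whose mean
#' is the model survival and whose coefficient of variation is `spec$cv`.
#' All values are strictly positive by construction.
#'
#' @param spec A [synthetic_spec()].
#' @param seed RNG seed.
#' @param sim An [sim_config()].
#' @return A [survival_dataset()] with replicate means, sds and counts.
#' @export
generate_survival <- function(spec, seed = 1L, sim = sim_config()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(seed)
  design <- expand.grid(dose_gy = spec$survival_doses_gy,
                        dose_rate_gy_min = spec$survival_rates_gy_min)
  sdlog <- sqrt(log(1 + spec$cv^2))
  rows <- lapply(seq_len(nrow(design)), function(i) {
    s <- surviving_fraction(simulate_mhr(
      spec$truth, irradiation(design$dose_gy[i],
                              design$dose_rate_gy_min[i]), sim))
    reps <- if (spec$cv == 0) rep(s, spec$n_reps) else
      s * stats::rlnorm(spec$n_reps, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    data.frame(dose_gy = design$dose_gy[i],
               dose_rate_gy_min = design$dose_rate_gy_min[i],
               survival_mean = mean(reps),
               survival_sd = if (spec$n_reps > 1) stats::sd(reps) else 0,
               n_reps = spec$n_reps)
  })
  d <- do.call(rbind, rows)
  survival_dataset(d$dose_gy, d$dose_rate_gy_min, pmin(d$survival_mean, 1.2),
                   d$survival_sd, d$n_reps)
}

#' Generate a synthetic comet dataset
#'
#' Forward-simulates the ground truth through the comet irradiation, takes
#' the normalized model population distribution at each sampling time, and
#' draws `cells_per_time` cells per time point by categorical (multinomial)
#' sampling. With `cells_per_time = Inf`, the exact model distribution is
#' returned (the infinite-cell limit).
#'
#' @inheritParams generate_survival
#' @return A [comet_dataset()] of binned proportions per time point.
#' @export
generate_comet <- function(spec, seed = 1L, sim = sim_config()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(seed)
  traj <- simulate_mhr(spec$truth,
                       irradiation(spec$comet_dose_gy,
                                   spec$comet_rate_gy_min),
                       sim, times = spec$comet_times_h)
  dist <- model_comet_distribution(traj, spec$comet_times_h)
  k <- ncol(dist)
  props <- if (is.infinite(spec$cells_per_time)) {
    dist
  } else {
    t(apply(dist, 1, function(p) {
      as.vector(stats::rmultinom(1, spec$cells_per_time, p)) /
        spec$cells_per_time
    }))
  }
  comet_dataset(time_h = rep(spec$comet_times_h, each = k),
                population = rep(0:(k - 1L), length(spec$comet_times_h)),
                proportion = as.vector(t(props)),
                dose_gy = spec$comet_dose_gy,
                dose_rate_gy_min = spec$comet_rate_gy_min)
}
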