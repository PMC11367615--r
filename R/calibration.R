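#' Configuration of the ensemble calibration
#'
#' Settings for the iterative approximate-Bayesian-computation style
#' calibration: an ensemble of `n` independent parameter sets is drawn from
#' uniform priors, and each set is evolved for `n_it` iterations by Gaussian
#' perturbation with greedy acceptance (a proposal is kept only if it
#' strictly reduces the objective error). A member stops early once its
#' error falls below `cutoff`.
#'
#' @param n Ensemble size (default 5000).
#' @param n_it Number of iterations (default 250).
#' @param cutoff Early-stop error threshold per member (default 1e-5).
#' @param prior_bounds Named list of `c(low, high)` per parameter. Defaults
#'   cover all published fitted values: `alpha` in `[0, 2]` 1/Gy, `c_r` in
#'   `[0, 50]` 1/h, `c_e` in `[0, 25]` 1/h, `mu_gamma` in `[0, 6]` 1/Gy,
#'   `gamma` in `[0, 6]` 1/h.
#' @param perturb_scale Gaussian proposal standard deviation as a fraction
#'   of each prior width (default 0.05).
#' @param seed RNG seed; member `j` derives its own stream from `seed + j`,
#'   so members are independent and embarrassingly parallel.
#' @return An `abc_config` object.
#' @export
abc_config <- function(n = 5000, n_it = 250, cutoff = 1e-5,
                       prior_bounds = list(
                         alpha = c(0, 2), c_r = c(0, 50), c_e = c(0, 25),
                         mu_gamma = c(0, 6), gamma = c(0, 6)),
                       perturb_scale = 0.05, seed = 1L) {
  stopifnot(n >= 1, n_it >= 1, cutoff > 0, perturb_scale > 0)
  nm <- c("alpha", "c_r", "c_e", "mu_gamma", "gamma")
  if (!setequal(names(prior_bounds), nm)) {
    stop("prior_bounds must name exactly: ", paste(nm, collapse = ", "),
         call. = FALSE)
  }
  prior_bounds <- prior_bounds[nm]
  for (b in prior_bounds) {
    if (length(b) != 2L || b[1] >= b[2]) {
      stop("each prior bound must be c(low, high) with low < high",
           call. = FALSE)
    }
  }
  structure(list(n = as.integer(n), n_it = as.integer(n_it), cutoff = cutoff,
                 prior_bounds = prior_bounds,
                 perturb_scale = perturb_scale, seed = as.integer(seed)),
            class = "abc_config")
}

#' Draw parameter sets from the uniform prior
#'
#' @param config An [abc_config()].
#' @param n Number of draws (default `config$n`).
#' @return Numeric matrix, one row per draw, columns
#'   `alpha, c_r, c_e, mu_gamma, gamma`; each entry i.i.d. uniform within
#'   its prior bounds. Reproducible under `config$seed`.
#' @export
sample_prior <- function(config, n = config$n) {
  stopifnot(inherits(config, "abc_config"))
  set.seed(config$seed)
  out <- vapply(config$prior_bounds, function(b) {
    stats::runif(n, b[1], b[2])
  }, numeric(n))
  matrix(out, nrow = n, dimnames = list(NULL, names(config$prior_bounds)))
}

# reflect x into [low, high]
reflect <- function(x, low, high) {
  w <- high - low
  r <- (x - low) %% (2 * w)
  low + ifelse(r > w, 2 * w - r, r)
}

#' Gaussian perturbation of a parameter set
#'
#' Adds independent zero-mean Gaussian noise to each parameter (standard
#' deviation `perturb_scale` times the prior width) and reflects the result
#' at the prior boundaries so proposals stay inside the search box.
#'
#' @param values Named numeric vector (or [mhr_params()]) to perturb.
#' @param config An [abc_config()].
#' @return Named numeric vector of the same shape, inside the prior box.
#' @export
perturb_params <- function(values, config) {
  stopifnot(inherits(config, "abc_config"))
  if (inherits(values, "mhr_params")) values <- unlist(values)
  nm <- names(config$prior_bounds)
  lo <- vapply(config$prior_bounds, `[`, numeric(1), 1L)
  hi <- vapply(config$prior_bounds, `[`, numeric(1), 2L)
  z <- stats::rnorm(length(nm), 0, config$perturb_scale * (hi - lo))
  out <- reflect(values[nm] + z, lo, hi)
  names(out) <- nm
  out
}

# Build an objective closure params-vector -> error for given data.
# One simulation per unique (dose, rate) protocol; the comet protocol is
# shared with a matching survival protocol when present.
build_objective <- function(survival = NULL, comet = NULL,
                            mode = c("combined", "clonogenic", "comet"),
                            xi = 1 / 30, config = sim_config()) {
  mode <- match.arg(mode)
  if (mode %in% c("clonogenic", "combined") &&
      (is.null(survival) || nrow(survival) == 0)) {
    stop("mode '", mode, "' requires survival data", call. = FALSE)
  }
  if (mode %in% c("comet", "combined") &&
      (is.null(comet) || nrow(comet) == 0)) {
    stop("mode '", mode, "' requires comet data", call. = FALSE)
  }
  use_surv <- mode != "comet"
  use_comet <- mode != "clonogenic"

  surv <- if (use_surv) survival[survival$dose_gy > 0, , drop = FALSE]
  cm_times <- cm_obs <- cm_dose <- cm_rate <- NULL
  if (use_comet) {
    cm_obs <- comet_matrix(comet, k_max = config$k_max)
    cm_times <- attr(cm_obs, "times_h")
    cm_dose <- attr(comet, "dose_gy")
    cm_rate <- attr(comet, "dose_rate_gy_min")
  }

  protos <- unique(rbind(
    if (use_surv) surv[, c("dose_gy", "dose_rate_gy_min")],
    if (use_comet) data.frame(dose_gy = cm_dose,
                              dose_rate_gy_min = cm_rate)))

  function(values) {
    nm <- c("alpha", "c_r", "c_e", "mu_gamma", "gamma")
    v <- unlist(values, use.names = TRUE)
    if (all(nm %in% names(v))) {
      v <- v[nm]
    } else if (length(v) == 5L) {
      v <- stats::setNames(v, nm)
    } else {
      stop("parameter vector must have the five named entries ",
           paste(nm, collapse = ", "), call. = FALSE)
    }
    p <- mhr_params(v[["alpha"]], v[["c_r"]], v[["c_e"]],
                    v[["mu_gamma"]], v[["gamma"]])
    sims <- lapply(seq_len(nrow(protos)), function(i) {
      is_cm <- use_comet && protos$dose_gy[i] == cm_dose &&
        protos$dose_rate_gy_min[i] == cm_rate
      simulate_mhr(p, irradiation(protos$dose_gy[i],
                                  protos$dose_rate_gy_min[i]),
                   config, times = if (is_cm) cm_times)
    })
    key <- function(d, r) match(TRUE, protos$dose_gy == d &
                                  protos$dose_rate_gy_min == r)
    e_cl <- 0
    if (use_surv) {
      pred <- vapply(seq_len(nrow(surv)), function(i) {
        surviving_fraction(sims[[key(surv$dose_gy[i],
                                     surv$dose_rate_gy_min[i])]])
      }, numeric(1))
      e_cl <- clonogenic_error(surv$survival_mean, pmax(pred, 1e-300))
    }
    e_cm <- 0
    if (use_comet) {
      pred <- model_comet_distribution(sims[[key(cm_dose, cm_rate)]],
                                       cm_times)
      e_cm <- comet_error(cm_obs, pred, times_h = cm_times)
    }
    switch(mode,
           clonogenic = e_cl,
           comet = e_cm,
           combined = combined_error(e_cl, e_cm, xi))
  }
}

#' Calibrate the model against survival and/or comet data
#'
#' Runs the iterative ensemble calibration: `n` parameter sets drawn from
#' the uniform prior, each independently refined for `n_it` iterations by
#' Gaussian perturbation with greedy error-decreasing acceptance. Proposals
#' whose simulation fails are rejected and the member continues. Member `j`
#' uses RNG seed `seed + j`, so a run is reproducible and members are
#' independent.
#'
#' @param survival A [survival_dataset()] (or `NULL`).
#' @param comet A [comet_dataset()] (or `NULL`).
#' @param mode Objective: `"combined"` (default), `"clonogenic"`, `"comet"`.
#' @param xi Comet weight in the combined objective (default 1/30).
#' @param config An [abc_config()].
#' @param sim An [sim_config()] used for all forward simulations.
#' @return An `mhr_ensemble`: list with `members` (data frame `member_id`,
#'   the five parameters, `final_error`), `traces` (matrix, one row per
#'   member, error after each iteration including the initial one;
#'   non-increasing by construction) and the configs.
#' @export
calibrate_mhr <- function(survival = NULL, comet = NULL,
                          mode = c("combined", "clonogenic", "comet"),
                          xi = 1 / 30, config = abc_config(),
                          sim = sim_config()) {
  mode <- match.arg(mode)
  objective <- build_objective(survival, comet, mode, xi, sim)
  init <- sample_prior(config)
  n <- config$n
  traces <- matrix(NA_real_, n, config$n_it + 1L)
  members <- init
  final_err <- numeric(n)

  for (j in seq_len(n)) {
    set.seed(config$seed + j)
    cur <- init[j, ]
    err <- tryCatch(objective(cur), error = function(e) Inf)
    traces[j, 1L] <- err
    for (it in seq_len(config$n_it)) {
      if (err < config$cutoff) {
        traces[j, (it + 1L):(config$n_it + 1L)] <- err
        break
      }
      prop <- perturb_params(cur, config)
      perr <- tryCatch(objective(prop), error = function(e) Inf)
      if (perr < err) {
        cur <- prop
        err <- perr
      }
      traces[j, it + 1L] <- err
    }
    members[j, ] <- cur
    final_err[j] <- err
  }

  structure(list(
    members = data.frame(member_id = seq_len(n), members,
                         final_error = final_err),
    traces = traces, mode = mode, xi = xi,
    config = config, sim = sim), class = "mhr_ensemble")
}

#' @export
print.mhr_ensemble <- function(x, ...) {
  cat(sprintf(
    "MHR calibration ensemble: %d members, %d iterations, mode '%s'\n",
    nrow(x$members), x$config$n_it, x$mode))
  cat(sprintf("  final error: median %.4g, best %.4g\n",
              stats::median(x$members$final_error),
              min(x$members$final_error)))
  invisible(x)
}

#' Posterior summaries of a calibrated ensemble
#'
#' Per-parameter normalized histograms (density scale, unit area) and
#' quantiles. Peaked distributions indicate well-determined parameters;
#' spread ones indicate that many repair dynamics explain the data equally
#' well.
#'
#' @param ensemble An `mhr_ensemble` (or a plain data frame / matrix of
#'   parameter draws).
#' @param bins Number of histogram bins (default 30).
#' @return A list per parameter with elements `histogram`
#'   (data frame `mid`, `density`), `quantiles` (2.5, 25, 50, 75, 97.5
#'   percent) and `iqr`.
#' @export
posterior_summaries <- function(ensemble, bins = 30) {
  draws <- if (inherits(ensemble, "mhr_ensemble")) {
    ensemble$members[, c("alpha", "c_r", "c_e", "mu_gamma", "gamma")]
  } else {
    as.data.frame(ensemble)
  }
  stopifnot(nrow(draws) > 0)
  lapply(draws, function(v) {
    rng <- range(v)
    if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
    br <- seq(rng[1], rng[2], length.out = bins + 1L)
    h <- graphics::hist(v, breaks = br, plot = FALSE)
    q <- stats::quantile(v, c(0.025, 0.25, 0.5, 0.75, 0.975), names = TRUE)
    list(histogram = data.frame(mid = h$mids, density = h$density),
         quantiles = q, iqr = unname(q[4] - q[2]))
  })
}
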