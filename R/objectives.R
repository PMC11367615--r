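#' Survival dataset constructor
#'
#' Clonogenic-survival measurements: per (dose, dose-rate), the mean and
#' standard deviation of the surviving fraction over replicates.
#'
#' @param dose_gy Doses, Gy (>= 0).
#' @param dose_rate_gy_min Dose-rates, Gy/min (> 0).
#' @param survival_mean Mean surviving fractions, in `(0, 1]` (a small
#'   overshoot above 1 from plating-efficiency normalization is tolerated).
#' @param survival_sd Standard deviations (>= 0; default 0).
#' @param n_reps Replicate counts (default 3).
#' @return A `survival_dataset` data frame.
#' @export
survival_dataset <- function(dose_gy, dose_rate_gy_min, survival_mean,
                             survival_sd = 0, n_reps = 3L) {
  n <- length(dose_gy)
  d <- data.frame(dose_gy = dose_gy,
                  dose_rate_gy_min = rep_len(dose_rate_gy_min, n),
                  survival_mean = survival_mean,
                  survival_sd = rep_len(survival_sd, n),
                  n_reps = rep_len(as.integer(n_reps), n))
  if (any(d$dose_gy < 0) || any(d$dose_rate_gy_min <= 0)) {
    stop("doses must be >= 0 and dose-rates > 0", call. = FALSE)
  }
  if (any(d$survival_mean <= 0) || any(d$survival_mean > 1 + 0.2)) {
    stop("survival means must lie in (0, 1] (up to small overshoot)",
         call. = FALSE)
  }
  if (any(d$survival_sd < 0)) stop("survival sd must be >= 0", call. = FALSE)
  class(d) <- c("survival_dataset", "data.frame")
  d
}

#' Comet objective function
#'
#' Sum of squared differences between observed and simulated comet
#' population distributions over all post-irradiation time points (`t > 0`;
#' the unirradiated control is excluded) and all populations.
#'
#' @param observed Matrix (time x population) of observed proportions, or a
#'   [comet_dataset()].
#' @param predicted Matrix of simulated proportions on the same time grid
#'   and populations (e.g. from [model_comet_distribution()]).
#' @param times_h Time grid, h; required when `observed` is a matrix without
#'   a `times_h` attribute.
#' @return Error (>= 0).
#' @export
comet_error <- function(observed, predicted, times_h = NULL) {
  if (inherits(observed, "comet_dataset")) {
    observed <- comet_matrix(observed, k_max = ncol(predicted) - 1L)
  }
  if (is.null(times_h)) times_h <- attr(observed, "times_h")
  if (is.null(times_h)) {
    stop("times_h required to identify the t = 0 control", call. = FALSE)
  }
  if (!all(dim(observed) == dim(predicted))) {
    stop("observed and predicted distributions differ in shape (",
         paste(dim(observed), collapse = "x"), " vs ",
         paste(dim(predicted), collapse = "x"), ")", call. = FALSE)
  }
  keep <- times_h > 0
  sum((observed[keep, , drop = FALSE] - predicted[keep, , drop = FALSE])^2)
}

#' Clonogenic objective function
#'
#' Sum of squared differences of log10 survival between observed and
#' simulated values per dose. The logarithmic scale keeps low-survival
#' (high-dose) points from being underweighted.
#'
#' @param observed Observed surviving fractions (> 0), or a
#'   [survival_dataset()] (its `survival_mean` column is used).
#' @param predicted Simulated surviving fractions, same length, > 0.
#' @return Error (>= 0).
#' @export
clonogenic_error <- function(observed, predicted) {
  if (inherits(observed, "survival_dataset")) {
    observed <- observed$survival_mean
  }
  stopifnot(length(observed) == length(predicted))
  bad <- which(observed <= 0 | predicted <= 0)
  if (length(bad)) {
    stop("non-positive survival at comparison point(s) ",
         paste(bad, collapse = ", "), "; log10 undefined", call. = FALSE)
  }
  sum((log10(observed) - log10(predicted))^2)
}

#' Combined objective function
#'
#' `eps_combined = eps_clonogenic + xi * eps_comet`. With 2 survival points
#' and 60 comet points, `xi = 1/30` weights every data point equally;
#' `xi = 1` weights the two assays equally.
#'
#' @param eps_clonogenic,eps_comet Component errors (>= 0).
#' @param xi Weighting constant (> 0).
#' @return Combined error.
#' @export
combined_error <- function(eps_clonogenic, eps_comet, xi = 1 / 30) {
  stopifnot(eps_clonogenic >= 0, eps_comet >= 0, xi > 0)
  eps_clonogenic + xi * eps_comet
}
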