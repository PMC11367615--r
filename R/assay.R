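#' Bin comet-assay tail intensities into hit populations
#'
#' Maps single-cell relative tail intensities onto the MHR hit populations
#' assuming tail intensity is linear in the number of hits: intensities in
#' `[0, w)` percent belong to `L_0`, `[w, 2w)` to `L_1`, and so on, with the
#' default bin width `w = 4` percent. Intensities at or above the top bin
#' clamp to `L_kmax` so normalization is preserved. Bins are half-open, so a
#' cell at exactly `w` percent belongs to `L_1`.
#'
#' @param intensity_pct Numeric vector of relative tail intensities, percent,
#'   in `[0, 100]`.
#' @param bin_width_pct Bin width in percent (default 4).
#' @param k_max Highest population index (default 9).
#' @return Named numeric vector of proportions `L0..Lkmax` summing to 1.
#' @examples
#' bin_tail_intensities(c(2, 6, 10, 50))
#' @export
bin_tail_intensities <- function(intensity_pct, bin_width_pct = 4,
                                 k_max = 9) {
  stopifnot(bin_width_pct > 0, k_max >= 1, length(intensity_pct) > 0)
  if (any(!is.finite(intensity_pct)) || any(intensity_pct < 0) ||
      any(intensity_pct > 100)) {
    stop("tail intensities must lie in [0, 100] percent", call. = FALSE)
  }
  idx <- pmin(floor(intensity_pct / bin_width_pct), k_max)
  prop <- tabulate(idx + 1L, nbins = k_max + 1L) / length(intensity_pct)
  names(prop) <- paste0("L", 0:k_max)
  prop
}

#' Model-side comet population distribution
#'
#' Extracts the simulated hit-population distribution at requested times and
#' renormalizes each row over the tracked populations (eliminated and
#' above-chain mass is unobservable in a comet sample), so model and
#' experimental distributions are compared on the same footing.
#'
#' @param traj An `mhr_trajectory` from [simulate_mhr()].
#' @param times_h Times (h) within the trajectory span.
#' @return Matrix with one row per time (rownames = times) and columns
#'   `L0..Lkmax`; rows sum to 1.
#' @export
model_comet_distribution <- function(traj, times_h) {
  stopifnot(inherits(traj, "mhr_trajectory"))
  if (any(times_h < min(traj$times) - 1e-9) ||
      any(times_h > max(traj$times) + 1e-9)) {
    stop("requested times outside the simulated span [",
         signif(min(traj$times), 4), ", ", signif(max(traj$times), 4), "] h",
         call. = FALSE)
  }
  k <- ncol(traj$populations)
  out <- vapply(seq_len(k), function(j) {
    stats::approx(traj$times, traj$populations[, j], xout = times_h,
                  rule = 2)$y
  }, numeric(length(times_h)))
  out <- matrix(out, nrow = length(times_h), ncol = k,
                dimnames = list(format(times_h), colnames(traj$populations)))
  sweep(out, 1, rowSums(out), "/")
}

#' Comet dataset constructor
#'
#' A binned comet dataset: per time point after irradiation, the proportion
#' of cells in each hit population. Proportions are renormalized per time
#' point.
#'
#' @param time_h Time after irradiation, h (one value per row).
#' @param population Population index in `0..k_max`.
#' @param proportion Proportion of cells (>= 0).
#' @param dose_gy,dose_rate_gy_min The irradiation the assay followed
#'   (stored as attributes; defaults 6 Gy at 6 Gy/min).
#' @return A `comet_dataset` data frame with columns
#'   `time_h`, `population`, `proportion`.
#' @export
comet_dataset <- function(time_h, population, proportion,
                          dose_gy = 6, dose_rate_gy_min = 6) {
  stopifnot(length(time_h) == length(population),
            length(time_h) == length(proportion))
  if (any(proportion < 0) || any(!is.finite(proportion))) {
    stop("proportions must be finite and >= 0", call. = FALSE)
  }
  if (any(population != floor(population)) || any(population < 0)) {
    stop("population indices must be non-negative integers", call. = FALSE)
  }
  d <- data.frame(time_h = time_h, population = as.integer(population),
                  proportion = proportion)
  for (tt in unique(d$time_h)) {
    i <- d$time_h == tt
    s <- sum(d$proportion[i])
    if (s <= 0) stop("all-zero proportions at time ", tt, " h", call. = FALSE)
    d$proportion[i] <- d$proportion[i] / s
  }
  attr(d, "dose_gy") <- dose_gy
  attr(d, "dose_rate_gy_min") <- dose_rate_gy_min
  class(d) <- c("comet_dataset", "data.frame")
  d
}

# comet dataset -> matrix (time x population), k_max columns inferred or given
comet_matrix <- function(data, k_max = NULL) {
  if (is.null(k_max)) k_max <- max(data$population)
  times <- sort(unique(data$time_h))
  m <- matrix(0, length(times), k_max + 1L,
              dimnames = list(format(times), paste0("L", 0:k_max)))
  for (r in seq_len(nrow(data))) {
    i <- match(data$time_h[r], times)
    m[i, data$population[r] + 1L] <- data$proportion[r]
  }
  attr(m, "times_h") <- times
  m
}
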