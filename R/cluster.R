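#' Calibrate the target-site retention threshold
#'
#' In the target-site hit-cluster simulation, each of `n_target` sites in a
#' cell nucleus can gain one hit per 0.5-Gy dose step with probability
#' `1 - q`. The expected number of hits per Gy is
#' `(1 / step_gy) * n_target * (1 - q)`; solving for the threshold gives
#' `q = 1 - hits_per_gy / ((1 / step_gy) * n_target)`.
#'
#' @param n_target Target sites per nucleus.
#' @param hits_per_gy Desired mean hit induction rate, hits/Gy (default 40,
#'   the expected double-strand break yield per Gy).
#' @param step_gy Dose decision step, Gy (default 0.5).
#' @return The threshold `q` in `[0, 1)`.
#' @examples
#' solve_threshold(200)    # 0.9
#' solve_threshold(1e4)    # 0.998
#' @export
solve_threshold <- function(n_target, hits_per_gy = 40, step_gy = 0.5) {
  stopifnot(n_target >= 1, hits_per_gy > 0, step_gy > 0)
  per_gy <- n_target / step_gy
  if (per_gy <= hits_per_gy) {
    stop("infeasible: ", n_target, " sites at ", 1 / step_gy,
         " steps/Gy cannot average ", hits_per_gy, " hits/Gy", call. = FALSE)
  }
  1 - hits_per_gy / per_gy
}

#' Cluster simulation configuration
#'
#' @param n_target Target sites per nucleus (e.g. 200 or 1e4).
#' @param dose_gy Total dose, Gy; must be (near) a multiple of `step_gy`.
#' @param q Per-step per-site retention threshold in `[0, 1]`; if `NULL`,
#'   calibrated from `hits_per_gy` via [solve_threshold()].
#' @param hits_per_gy Mean hit induction rate used when `q` is `NULL`
#'   (default 40).
#' @param step_gy Dose step, Gy (default 0.5).
#' @param n_cells Number of simulated cells.
#' @param seed RNG seed.
#' @return A `cluster_sim_config` object (includes derived `n_steps`).
#' @export
cluster_sim_config <- function(n_target, dose_gy, q = NULL,
                               hits_per_gy = 40, step_gy = 0.5,
                               n_cells = 1e4, seed = 1L) {
  stopifnot(n_target >= 1, dose_gy > 0, step_gy > 0, n_cells >= 1)
  n_steps <- round(dose_gy / step_gy)
  if (abs(n_steps * step_gy - dose_gy) > step_gy * 1e-6) {
    stop("dose_gy must be a multiple of step_gy", call. = FALSE)
  }
  if (is.null(q)) q <- solve_threshold(n_target, hits_per_gy, step_gy)
  stopifnot(q >= 0, q <= 1)
  structure(list(n_target = as.integer(n_target), dose_gy = dose_gy,
                 q = q, step_gy = step_gy, n_steps = as.integer(n_steps),
                 n_cells = as.integer(n_cells), seed = as.integer(seed)),
            class = "cluster_sim_config")
}

#' Monte Carlo simulation of per-site hit accumulation
#'
#' Delivers the dose in `step_gy` increments; at every step every target
#' site of every cell independently gains one hit with probability `1 - q`,
#' so a site's final hit count is Binomial(`n_steps`, `1 - q`) and expected
#' total hits grow linearly with dose.
#'
#' Two equivalent engines are provided. `"multinomial"` (default) draws,
#' per cell, the number of sites with each final hit count directly from
#' the multinomial distribution implied by the per-site binomial -- the
#' same process, vectorized. `"bernoulli"` runs the literal per-site
#' per-step loop and is intended for small problems and cross-checks.
#'
#' @param config A [cluster_sim_config()].
#' @param engine `"multinomial"` or `"bernoulli"`.
#' @return Integer matrix `counts` with one row per cell and one column per
#'   hit count `0..n_steps`: entry `[cell, k+1]` is the number of sites in
#'   that cell carrying exactly `k` hits.
#' @export
simulate_cluster_cells <- function(config,
                                   engine = c("multinomial", "bernoulli")) {
  stopifnot(inherits(config, "cluster_sim_config"))
  engine <- match.arg(engine)
  set.seed(config$seed)
  p <- 1 - config$q
  if (engine == "multinomial") {
    pk <- stats::dbinom(0:config$n_steps, config$n_steps, p)
    counts <- t(stats::rmultinom(config$n_cells, config$n_target, pk))
  } else {
    if (as.double(config$n_cells) * config$n_target > 1e8) {
      stop("bernoulli engine is for small problems; use 'multinomial'",
           call. = FALSE)
    }
    counts <- matrix(0L, config$n_cells, config$n_steps + 1L)
    for (cell in seq_len(config$n_cells)) {
      hits <- integer(config$n_target)
      for (s in seq_len(config$n_steps)) {
        hits <- hits + (stats::runif(config$n_target) > config$q)
      }
      counts[cell, ] <- tabulate(hits + 1L, nbins = config$n_steps + 1L)
    }
  }
  colnames(counts) <- paste0("k", 0:config$n_steps)
  counts
}

#' Summarize a cluster simulation
#'
#' A site with `k >= 1` accumulated hits is a cluster of size `k`. The
#' cluster histogram reports the mean number of size-`k` clusters per cell;
#' the population histogram assigns each cell to the MHR population `L_k`
#' given by its largest cluster (cells with no hits are in `L_0`, carrying
#' the interpretation that a cell in `L_k` has at least one repair-limiting
#' cluster of `k` hits).
#'
#' @param counts Count matrix from [simulate_cluster_cells()].
#' @return A `cluster_sim_result`: list with `cluster_histogram` (named
#'   mean clusters per cell for `k >= 1`), `population_histogram` (named
#'   fractions of cells in `L_0, L_1, ...`, summing to 1), `modal_population`
#'   (index of the population mode) and `n_cells`.
#' @export
summarize_clusters <- function(counts) {
  stopifnot(is.matrix(counts), nrow(counts) >= 1)
  n_steps <- ncol(counts) - 1L
  cluster_hist <- colMeans(counts[, -1L, drop = FALSE])
  names(cluster_hist) <- paste0("k", seq_len(n_steps))
  max_k <- apply(counts[, -1L, drop = FALSE] > 0, 1, function(z) {
    w <- which(z)
    if (length(w)) max(w) else 0L
  })
  pop <- tabulate(max_k + 1L, nbins = n_steps + 1L) / nrow(counts)
  names(pop) <- paste0("L", 0:n_steps)
  structure(list(cluster_histogram = cluster_hist,
                 population_histogram = pop,
                 modal_population = unname(which.max(pop)) - 1L,
                 n_cells = nrow(counts)),
            class = "cluster_sim_result")
}

#' @export
print.cluster_sim_result <- function(x, ...) {
  cat(sprintf("Cluster simulation summary (%d cells)\n", x$n_cells))
  cat(sprintf("  modal population: L%d\n", x$modal_population))
  nz <- x$population_histogram[x$population_histogram > 0]
  cat("  population fractions:",
      paste(sprintf("%s=%.3g", names(nz), nz), collapse = ", "), "\n")
  invisible(x)
}

#' Exact population distribution of the cluster model
#'
#' Analytic counterpart of the Monte Carlo: a site's hit count is
#' Binomial(`n_steps`, `1 - q`), so the largest cluster of a cell with
#' `n_target` independent sites has CDF `F(k)^n_target`, where `F` is the
#' binomial CDF. Differencing gives the exact probability that a cell
#' belongs to each population `L_k`.
#'
#' @param n_target Target sites per nucleus.
#' @param q Retention threshold.
#' @param n_steps Number of dose steps.
#' @return Named numeric vector `P(L_0), ..., P(L_n_steps)` summing to 1.
#' @examples
#' analytic_population_distribution(1e4, 0.998, 12)[2:4]
#' @export
analytic_population_distribution <- function(n_target, q, n_steps) {
  stopifnot(n_target >= 1, q >= 0, q <= 1, n_steps >= 1)
  cdf_max <- stats::pbinom(0:n_steps, n_steps, 1 - q)^n_target
  p <- diff(c(0, cdf_max))
  stats::setNames(p, paste0("L", 0:n_steps))
}
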