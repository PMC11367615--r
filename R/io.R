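#' Read and write survival CSV files
#'
#' Survival tables use RFC-4180 CSV with dot decimals and the columns
#' `dose_gy, dose_rate_gy_min, survival_mean, survival_sd, n_reps`.
#'
#' @param path File path.
#' @return `read_survival_csv` returns a [survival_dataset()].
#' @export
read_survival_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("dose_gy", "dose_rate_gy_min", "survival_mean", "survival_sd",
            "n_reps")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop("survival file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  for (col in need) {
    if (!is.numeric(d[[col]])) {
      stop("column '", col, "' is not numeric (check decimal separators)",
           call. = FALSE)
    }
  }
  bad <- which(d$survival_mean <= 0)
  if (length(bad)) {
    stop("non-positive survival_mean in row(s) ",
         paste(bad, collapse = ", "), " of ", path, call. = FALSE)
  }
  survival_dataset(d$dose_gy, d$dose_rate_gy_min, d$survival_mean,
                   d$survival_sd, d$n_reps)
}

#' @param data A [survival_dataset()].
#' @rdname read_survival_csv
#' @export
write_survival_csv <- function(data, path) {
  stopifnot(inherits(data, "survival_dataset"))
  utils::write.csv(as.data.frame(data), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read and write comet CSV files
#'
#' Binned comet tables have columns `time_h, population, proportion`; raw
#' per-cell tables have columns `time_h, tail_intensity_pct` and are binned
#' on read with [bin_tail_intensities()].
#'
#' @param path File path.
#' @param dose_gy,dose_rate_gy_min Irradiation metadata attached to the
#'   dataset (defaults 6 Gy at 6 Gy/min).
#' @param bin_width_pct,k_max Binning settings used for raw files.
#' @return A [comet_dataset()].
#' @export
read_comet_csv <- function(path, dose_gy = 6, dose_rate_gy_min = 6,
                           bin_width_pct = 4, k_max = 9) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (all(c("time_h", "population", "proportion") %in% names(d))) {
    return(comet_dataset(d$time_h, d$population, d$proportion,
                         dose_gy, dose_rate_gy_min))
  }
  if (all(c("time_h", "tail_intensity_pct") %in% names(d))) {
    rows <- lapply(sort(unique(d$time_h)), function(tt) {
      prop <- bin_tail_intensities(d$tail_intensity_pct[d$time_h == tt],
                                   bin_width_pct, k_max)
      data.frame(time_h = tt, population = 0:k_max, proportion = prop)
    })
    b <- do.call(rbind, rows)
    return(comet_dataset(b$time_h, b$population, b$proportion,
                         dose_gy, dose_rate_gy_min))
  }
  stop("comet file ", path, " must have columns (time_h, population, ",
       "proportion) or (time_h, tail_intensity_pct)", call. = FALSE)
}

#' @param data A [comet_dataset()].
#' @rdname read_comet_csv
#' @export
write_comet_csv <- function(data, path) {
  stopifnot(inherits(data, "comet_dataset"))
  utils::write.csv(as.data.frame(data), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read and write calibration ensembles
#'
#' Ensembles are stored as CSV (`member_id, alpha, c_r, c_e, mu_gamma,
#' gamma, final_error`, full precision) with an optional JSON sidecar of
#' run metadata (configuration, seed, data digest, package version,
#' timestamp).
#'
#' @param ensemble An `mhr_ensemble` or member data frame.
#' @param path CSV path; metadata is written to `<path>.json`.
#' @param metadata Logical: write the JSON sidecar (default TRUE for
#'   ensembles).
#' @return `read_ensemble` returns the member data frame.
#' @export
write_ensemble <- function(ensemble, path, metadata = TRUE) {
  members <- if (inherits(ensemble, "mhr_ensemble")) ensemble$members
  else as.data.frame(ensemble)
  utils::write.csv(format(members, digits = 17, scientific = TRUE,
                          trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  if (metadata && inherits(ensemble, "mhr_ensemble")) {
    meta <- list(
      package = "mhrcal",
      version = as.character(utils::packageVersion("mhrcal")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      mode = ensemble$mode, xi = ensemble$xi,
      abc = unclass(ensemble$config), sim = unclass(ensemble$sim))
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("member_id", "alpha", "c_r", "c_e", "mu_gamma", "gamma",
            "final_error")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop("ensemble file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  d
}

#' Read a YAML/JSON configuration file
#'
#' Recognized top-level keys: `params` (alpha, c_r, c_e, mu_gamma, gamma),
#' `fractions` (list of `{start_h, dose_gy, dose_rate_gy_min}`), `sim`
#' (arguments of [sim_config()]), `abc` (arguments of [abc_config()]) and
#' `discriminators` (arguments of [discriminator_config()]). Missing keys
#' fall back to package defaults (reported via message); unknown keys
#' produce a warning, not a failure.
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` file.
#' @return List with elements `params` ([mhr_params()] or `NULL`),
#'   `protocol` ([irradiation()] or `NULL`), `sim`, `abc`,
#'   `discriminators`.
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    # keep YAML 1.1 boolean-like scalars (notably the key "n") literal
    yaml::read_yaml(path, handlers = list(
      "bool#no" = function(x) x, "bool#yes" = function(x) x))
  }
  known <- c("params", "fractions", "sim", "abc", "discriminators")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    warning("ignoring unknown config key(s): ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  params <- NULL
  if (!is.null(raw$params)) {
    params <- do.call(mhr_params, raw$params[c("alpha", "c_r", "c_e",
                                               "mu_gamma", "gamma")])
  }
  protocol <- NULL
  if (!is.null(raw$fractions)) {
    fr <- raw$fractions
    if (!is.data.frame(fr)) fr <- do.call(rbind.data.frame, fr)
    protocol <- irradiation(fr$dose_gy, fr$dose_rate_gy_min,
                            if (is.null(fr$start_h)) 0 else fr$start_h)
  }
  defaulted <- setdiff(c("sim", "abc", "discriminators"), names(raw))
  if (length(defaulted)) {
    message("config ", path, ": using package defaults for ",
            paste(defaulted, collapse = ", "))
  }
  list(params = params, protocol = protocol,
       sim = do.call(sim_config, as.list(raw$sim)),
       abc = do.call(abc_config, as.list(raw$abc)),
       discriminators = do.call(discriminator_config,
                                as.list(raw$discriminators)))
}
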