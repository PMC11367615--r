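test_that("prior sampling is reproducible, in-bounds and uniform-ish", {
  cfg <- abc_config(n = 3, seed = 99)
  expect_identical(sample_prior(cfg), sample_prior(cfg))
  big <- sample_prior(abc_config(seed = 7), n = 1e4)
  for (nm in colnames(big)) {
    b <- cfg$prior_bounds[[nm]]
    expect_gte(min(big[, nm]), b[1])
    expect_lte(max(big[, nm]), b[2])
    # empirical extremes approach the bounds
    expect_lt(min(big[, nm]), b[1] + 0.01 * (b[2] - b[1]))
    expect_gt(max(big[, nm]), b[2] - 0.01 * (b[2] - b[1]))
  }
  # degenerate (narrow) bounds confine the draws
  narrow <- abc_config(prior_bounds = list(
    alpha = c(0.26, 0.26 + 1e-9), c_r = c(0, 50), c_e = c(0, 25),
    mu_gamma = c(0, 6), gamma = c(0, 6)), seed = 1)
  expect_equal(sample_prior(narrow, 100)[, "alpha"], rep(0.26, 100),
               tolerance = 1e-8)
})

test_that("perturbation is centred, bounded and vanishes with its scale", {
  cfg <- abc_config(seed = 3)
  x <- c(alpha = 1, c_r = 25, c_e = 12, mu_gamma = 3, gamma = 3)
  set.seed(17)
  moves <- t(replicate(1e4, perturb_params(x, cfg))) -
    matrix(x, 1e4, 5, byrow = TRUE)
  widths <- c(2, 50, 25, 6, 6)
  se <- cfg$perturb_scale * widths / sqrt(1e4)
  expect_true(all(abs(colMeans(moves)) < 4 * se))
  set.seed(18)
  out <- t(replicate(200, perturb_params(x, cfg)))
  lo <- c(0, 0, 0, 0, 0)
  hi <- c(2, 50, 25, 6, 6)
  expect_true(all(sweep(out, 2, lo, ">=")))
  expect_true(all(sweep(out, 2, hi, "<=")))
  tiny <- abc_config(perturb_scale = 1e-12, seed = 3)
  set.seed(19)
  expect_equal(perturb_params(x, tiny), x, tolerance = 1e-9)
})

test_that("greedy acceptance yields monotone error traces and improvement", {
  data <- survival_dataset(c(3, 6), 6, c(0.5, 0.2), c(0.05, 0.02))
  ens <- calibrate_mhr(survival = data, mode = "clonogenic",
                       config = abc_config(n = 12, n_it = 8, seed = 5))
  fin <- ens$traces[, ncol(ens$traces)]
  expect_true(all(apply(ens$traces, 1, function(r) all(diff(r) <= 1e-12))))
  expect_lte(median(fin), median(ens$traces[, 1]))
  expect_true(all(ens$members$final_error == fin))
  # members stay inside the prior box
  for (nm in names(ens$config$prior_bounds)) {
    b <- ens$config$prior_bounds[[nm]]
    expect_true(all(ens$members[[nm]] >= b[1] & ens$members[[nm]] <= b[2]))
  }
})

test_that("the cutoff early-stops members; a vanishing cutoff never does", {
  data <- survival_dataset(c(3, 6), 6, c(0.5, 0.2), c(0.05, 0.02))
  frozen <- calibrate_mhr(survival = data, mode = "clonogenic",
                          config = abc_config(n = 4, n_it = 6, seed = 5,
                                              cutoff = 1e10))
  # every member already satisfies a huge cutoff: traces stay flat
  expect_true(all(frozen$traces == frozen$traces[, 1]))
  free <- calibrate_mhr(survival = data, mode = "clonogenic",
                        config = abc_config(n = 4, n_it = 6, seed = 5,
                                            cutoff = 1e-300))
  expect_true(any(free$traces[, 7] < free$traces[, 1]))
})

test_that("clonogenic calibration recovers a one-parameter radiosensitivity", {
  # data generated from the exact exponential S = exp(-alpha D); other
  # parameters pinned by degenerate priors so alpha is the only unknown
  a_true <- 0.26
  data <- survival_dataset(c(3, 6), 6, exp(-a_true * c(3, 6)))
  # independent grid-search oracle over alpha
  grid <- seq(0.01, 2, 0.001)
  g_err <- vapply(grid, function(a) {
    sum((log10(exp(-a * c(3, 6))) - log10(data$survival_mean))^2)
  }, numeric(1))
  a_oracle <- grid[which.min(g_err)]
  expect_equal(a_oracle, a_true, tolerance = 1e-2)
  eps <- 1e-9
  cfg <- abc_config(n = 12, n_it = 40, seed = 8, prior_bounds = list(
    alpha = c(0, 2), c_r = c(0, eps), c_e = c(0, eps),
    mu_gamma = c(0, eps), gamma = c(0, eps)))
  ens <- calibrate_mhr(survival = data, mode = "clonogenic", config = cfg)
  best <- ens$members[which.min(ens$members$final_error), ]
  expect_equal(best$alpha, a_oracle, tolerance = 0.05)
})

test_that("posterior summaries behave on degenerate and uniform ensembles", {
  same <- data.frame(alpha = rep(0.5, 50), c_r = 5, c_e = 1,
                     mu_gamma = 2, gamma = 1)
  ps <- posterior_summaries(same)
  expect_equal(unname(ps$alpha$quantiles), rep(0.5, 5))
  expect_equal(ps$alpha$iqr, 0)
  # histogram integrates to 1
  h <- ps$c_r$histogram
  expect_equal(sum(h$density * diff(h$mid)[1]), 1, tolerance = 1e-6)
  flat <- as.data.frame(sample_prior(abc_config(seed = 12), 2e4))
  psf <- posterior_summaries(flat, bins = 10)
  counts <- psf$gamma$histogram$density
  # chi-square goodness of fit against uniform
  obs <- counts / sum(counts) * 2e4
  chi <- sum((obs - 2e3)^2 / 2e3)
  expect_lt(chi, qchisq(0.999, df = 9))
  expect_true(all(diff(psf$gamma$quantiles) >= 0))
})
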