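test_that("both worked-example parameter sets pass the theoretical screen", {
  for (p in list(fig_set_a(), fig_set_b())) {
    rep <- evaluate_discriminators(p)
    evaluated <- rep$conditions[!is.na(rep$conditions)]
    expect_true(all(evaluated),
                label = paste("conditions",
                              paste(names(evaluated)[!evaluated],
                                    collapse = ",")))
    expect_true(is.na(rep$conditions[["VII"]]))  # no data supplied
    expect_true(rep$overall)
  }
})

test_that("a no-repair model fails the dose-rate and fractionation screens", {
  rep <- evaluate_discriminators(no_repair_set())
  expect_true(rep$conditions[["I"]])    # equality allowed
  expect_false(rep$conditions[["II"]])  # no dose-rate effect without repair
  expect_false(rep$conditions[["VI"]])  # no sparing without repair
  expect_false(rep$overall)
})

test_that("without repair the low-dose-rate curve is exactly exponential", {
  p <- mhr_params(0.5, 0, 1, 0, 1)
  res <- low_dose_rate_linearity(p)
  expect_true(res$pass)
  expect_equal(res$r2, 1, tolerance = 1e-6)
  expect_equal(res$slope, -0.5 * log10(exp(1)), tolerance = 1e-4)
})

test_that("a pure-quadratic log-survival curve fails the linearity threshold", {
  D <- 0:10
  y <- -0.05 * D^2
  fit <- lm(y ~ D)
  r2 <- 1 - sum(residuals(fit)^2) / sum((y - mean(y))^2)
  expect_lt(r2, 0.99)
})

test_that("the LQ fit recovers exact linear-quadratic coefficients", {
  D <- 1:9
  y <- 0.04 * D + 0.01 * D^2
  f <- stats::lm.fit(cbind(D, D^2), y)
  expect_equal(unname(f$coefficients), c(0.04, 0.01), tolerance = 1e-10)
  # and a pure exponential is nested within LQ (b ~ 0)
  y2 <- 0.1 * D
  f2 <- stats::lm.fit(cbind(D, D^2), y2)
  expect_equal(unname(f2$coefficients[2]), 0, tolerance = 1e-12)
})

test_that("fractionation sparing holds for the worked example", {
  res <- fractionation_sparing(fig_set_a())
  expect_true(res$pass)
  expect_gt(res$s_fractionated, res$s_acute)
})

test_that("data coverage checks error bars and names offenders", {
  p <- fig_set_a()
  sim_s <- vapply(c(3, 6), function(D) {
    surviving_fraction(simulate_mhr(p, irradiation(D, 6)))
  }, numeric(1))
  ok <- survival_dataset(c(3, 6), 6, sim_s, 0.01)
  expect_true(data_coverage(p, ok)$pass)
  bad <- survival_dataset(c(3, 6), 6,
                          pmin(sim_s + c(0.3, 0), 1), c(0.01, 0.01))
  res <- data_coverage(p, bad)
  expect_false(res$pass)
  expect_match(res$note, "3 Gy")
  expect_true(is.na(data_coverage(p, NULL)$pass))
})

test_that("forward-consistent synthetic data passes coverage", {
  d <- truth_datasets(seed = 301)
  expect_true(data_coverage(fig_set_a(), d$survival)$pass)
})

test_that("ensemble filtering respects the intersection bound", {
  one <- data.frame(alpha = 0.26, c_r = 7.76, c_e = 0.83,
                    mu_gamma = 0.31, gamma = 0.31)
  res <- filter_ensemble(one)
  expect_equal(nrow(res$kept), 1)       # VII not evaluated, all others pass
  expect_true(is.na(res$acceptance_pct[["VII"]]))
  norep <- data.frame(alpha = c(0.3, 0.8), c_r = 0, c_e = c(0.5, 1),
                      mu_gamma = 0, gamma = c(0.5, 2))
  res2 <- filter_ensemble(norep)
  expect_equal(nrow(res2$kept), 0)
  expect_equal(unname(res2$acceptance_pct[["II"]]), 0)
  both <- rbind(one, one)
  res3 <- filter_ensemble(both)
  pct <- res3$acceptance_pct
  expect_true(all(pct[!is.na(pct)] >= 0 & pct[!is.na(pct)] <= 100))
  expect_lte(unname(pct[["collective"]]),
             min(pct[setdiff(names(pct), "collective")], na.rm = TRUE))
})
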