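test_that("dose_rate_at reproduces the square pulse, gaps and zero tails", {
  p <- irradiation(6, 6)  # 1 min pulse
  expect_equal(dose_rate_at(p, 0.5 / 60), 6)
  expect_equal(dose_rate_at(p, 2), 0)
  # half-open interval: rate is 0 exactly at pulse end
  expect_equal(dose_rate_at(p, 1 / 60), 0)
  split <- irradiation(c(3, 3), 6, c(0, 2 + 0.5 / 60))
  expect_equal(dose_rate_at(split, 1), 0)          # inside the gap
  expect_equal(dose_rate_at(split, 2 + 0.6 / 60), 6)  # second pulse
})

test_that("protocol validation rejects bad fractions", {
  expect_error(irradiation(-1, 6), "> 0")
  expect_error(irradiation(6, 0), "> 0")
  expect_error(irradiation(c(3, 3), 0.01, c(0, 1)), "overlap")
})

test_that("derivatives vanish without radiation or damage", {
  st <- c(1, numeric(10))  # L0 = 1, 9 damaged pops, Gamma
  d <- mhr_derivative(0, st, fig_set_a(), rate_gy_h = 0)[[1]]
  expect_equal(d, numeric(11))
})

test_that("with alpha = 0 only repair and elimination act", {
  p <- mhr_params(0, 5, 2, 0.3, 0.3)
  st <- c(0.5, 0.3, 0.2, 0)  # k_max = 2, Gamma = 0
  d <- mhr_derivative(1, st, p, rate_gy_h = 360)[[1]]
  # manual: pr = 5 at Gamma = 0
  expect_equal(d[1], 5 * 0.3)
  expect_equal(d[2], -5 * 0.3 + 5 * 0.2 - 2 * 0.3)
  expect_equal(d[3], -5 * 0.2 - 2 * 0.2)
  expect_equal(d[4], 360 - 0.3 * 0)
})

test_that("pure-birth chain matches the Poisson master equation", {
  # with c_r = c_e = 0 and constant R the hit chain is a Poisson counting
  # process with intensity alpha * R; compare against the independently
  # constructed master-equation generator matrix applied to a random state
  p <- mhr_params(0.4, 0, 0, 1.3, 0.7)
  kmax <- 5L
  lam <- 0.4 * 120  # alpha * R, 1/h
  A <- matrix(0, kmax + 1L, kmax + 1L)
  for (i in 0:kmax) {
    A[i + 1L, i + 1L] <- -lam
    if (i > 0) A[i + 1L, i] <- lam
  }
  set.seed(11)
  L <- runif(kmax + 1L)
  st <- c(L, 0.8)
  d <- mhr_derivative(0, st, p, rate_gy_h = 120)[[1]]
  expect_equal(d[seq_len(kmax + 1L)], as.vector(A %*% L), tolerance = 1e-12)
})

test_that("derivative rejects malformed state", {
  expect_error(mhr_derivative(0, c(1, 0), fig_set_a(), 0), "at least")
})

test_that("compiled and reference derivatives integrate identically", {
  p <- fig_set_b()
  cfg <- sim_config()
  traj <- simulate_mhr(p, irradiation(6, 6), cfg, times = c(0.5, 2, 8))
  # independent route: integrate the exported R derivative piecewise
  segs <- mhrcal:::protocol_segments(irradiation(6, 6), cfg$followup_h)
  y <- c(1, numeric(cfg$k_max + 1L))
  for (s in seq_len(nrow(segs))) {
    sol <- deSolve::ode(
      y, c(segs$from[s], segs$to[s]),
      function(t, y, parms) mhr_derivative(t, y, p, segs$rate_gy_h[s]),
      parms = NULL, rtol = 1e-10, atol = 1e-12)
    y <- sol[nrow(sol), -1]
  }
  n <- length(traj$times)
  expect_equal(unname(traj$populations[n, ]),
               unname(y[seq_len(cfg$k_max + 1L)]), tolerance = 1e-7)
  expect_equal(unname(traj$tbde[n]), unname(y[cfg$k_max + 2L]),
               tolerance = 1e-7)
})

test_that("no damage induction leaves the population untouched", {
  p <- mhr_params(0, 3, 1, 0.5, 0.5)
  traj <- simulate_mhr(p, irradiation(6, 6))
  expect_equal(max(abs(traj$populations[, 1] - 1)), 0, tolerance = 1e-9)
  expect_equal(surviving_fraction(traj), 1, tolerance = 1e-9)
})

test_that("without repair and elimination survival is the Poisson void probability", {
  for (a in c(0.1, 0.5, 1.0)) {
    for (D in c(2, 6, 10)) {
      p <- mhr_params(a, 0, 0, 0.5, 0.5)
      s <- surviving_fraction(simulate_mhr(p, irradiation(D, 6),
                                           sim_config(k_max = 15)))
      expect_equal(s, exp(-a * D), tolerance = 1e-5,
                   label = sprintf("S(alpha=%g, D=%g)", a, D))
    }
  }
})

test_that("integrated TBDE matches its closed form during and after the pulse", {
  p <- fig_set_a()
  t_rad <- 6 / (6 * 60)
  chk <- sort(c(seq(0.005, t_rad, length.out = 5),
                seq(0.2, 10, length.out = 15)))
  traj <- simulate_mhr(p, irradiation(6, 6), times = chk)
  idx <- vapply(chk, function(t) which.min(abs(traj$times - t)), integer(1))
  expect_lt(max(abs(traj$tbde[idx] -
                      tbde_closed_form(6, p$gamma, chk, t_rad))), 1e-6)
})

test_that("closed-form TBDE limits behave", {
  expect_equal(tbde_closed_form(6, 0.3, 0, 0.1), 0)
  # gamma = 0: linear accumulation then constant
  expect_equal(tbde_closed_form(6, 0, c(0.05, 0.1, 3), 0.1),
               c(18, 36, 36))
  # large gamma saturates at R / gamma
  expect_equal(tbde_closed_form(6, 500, 0.1, 0.1), 360 / 500,
               tolerance = 1e-3)
  # quadrature oracle for the rise phase
  g <- 0.7
  f <- function(u) 360 * exp(-g * (0.08 - u))
  expect_equal(tbde_closed_form(6, g, 0.08, 0.1),
               stats::integrate(f, 0, 0.08)$value, tolerance = 1e-8)
})

test_that("trajectories are non-negative and lose mass monotonically", {
  set.seed(21)
  cfg <- abc_config(n = 8, seed = 21)
  draws <- sample_prior(cfg, 8)
  for (j in seq_len(nrow(draws))) {
    p <- mhr_params(draws[j, 1], draws[j, 2], draws[j, 3], draws[j, 4],
                    draws[j, 5])
    traj <- simulate_mhr(p, irradiation(6, 2))
    expect_true(all(traj$populations >= -1e-8))
    expect_true(all(traj$tbde >= 0))
    total <- rowSums(traj$populations)
    expect_true(all(diff(total) <= 1e-7))
    expect_true(all(total <= 1 + 1e-8))
  }
})

test_that("with no elimination and a long chain total mass is conserved", {
  p <- mhr_params(0.3, 4, 0, 0.4, 0.4)
  traj <- simulate_mhr(p, irradiation(6, 6), sim_config(k_max = 20))
  expect_lt(max(traj$populations[, 21]), 1e-9)  # chain long enough
  expect_equal(sum(traj$populations[length(traj$times), ]), 1,
               tolerance = 1e-6)
})

test_that("chain truncation at k_max = 9 is converged for the worked examples", {
  for (p in list(fig_set_a(), fig_set_b())) {
    for (D in c(3, 6, 10)) {
      s9 <- surviving_fraction(simulate_mhr(p, irradiation(D, 6),
                                            sim_config(k_max = 9)))
      s12 <- surviving_fraction(simulate_mhr(p, irradiation(D, 6),
                                             sim_config(k_max = 12)))
      expect_lt(abs(s9 - s12), 1e-4)
    }
  }
})

test_that("faster repair does not reduce survival", {
  base <- fig_set_a()
  s <- vapply(c(2, 7.76, 20), function(cr) {
    surviving_fraction(simulate_mhr(
      mhr_params(base$alpha, cr, base$c_e, base$mu_gamma, base$gamma),
      irradiation(6, 6)))
  }, numeric(1))
  expect_true(all(diff(s) >= -1e-9))
})

test_that("a global pulse-resolution step cap gives the same answer", {
  p <- fig_set_a()
  t1 <- simulate_mhr(p, irradiation(6, 6), sim_config())
  t2 <- simulate_mhr(p, irradiation(6, 6), sim_config(max_step_free_s = 1))
  expect_equal(surviving_fraction(t1), surviving_fraction(t2),
               tolerance = 1e-7)
})
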