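test_that("noiseless exponential relaxations are recovered exactly", {
  t <- seq(0, 5, by = 0.05)
  tr <- data.frame(time = t, response = -0.5 * (1 - exp(-t / 0.8)) + 1)
  f <- fit_relaxation(tr, "exp")
  expect_true(f$converged)
  expect_equal(unname(coef(f)[c("A", "tau", "c")]), c(-0.5, 0.8, 1),
               tolerance = 1e-8)
})

test_that("exp+linear traces need the linear term", {
  t <- seq(0, 10, by = 0.05)
  tr <- data.frame(time = t, response = 1 * (1 - exp(-t / 2)) + 0.01 * t)
  f2 <- fit_relaxation(tr, "exp_linear")
  expect_equal(unname(coef(f2)), c(1, 2, 0, 0.01), tolerance = 1e-6)
  f1 <- fit_relaxation(tr, "exp")
  expect_gt(f1$residual_norm, f2$residual_norm)
})

test_that("degenerate and structureless traces are flagged, not fitted", {
  t <- seq(0, 5, by = 0.1)
  flat <- fit_relaxation(data.frame(time = t, response = rep(2, length(t))),
                         "exp")
  expect_false(flat$converged)
  expect_true(is.na(flat$tau))
  # alternating garbage with no exponential structure
  garbage <- fit_relaxation(data.frame(time = t,
                                       response = rep(c(1, -1),
                                                      length.out = length(t))),
                            "exp")
  expect_false(garbage$converged)
  expect_match(garbage$reason, "exponential")
  expect_error(fit_relaxation(data.frame(time = 1:4, response = 1:4), "exp"),
               "8 samples")
})

test_that("baseline offsets are absorbed into the constant term", {
  t <- seq(0, 4, by = 0.04)
  y <- 0.8 * (1 - exp(-t / 0.5))
  f0 <- fit_relaxation(data.frame(time = t, response = y), "exp")
  f7 <- fit_relaxation(data.frame(time = t, response = y + 7), "exp")
  expect_equal(f7$A, f0$A, tolerance = 1e-8)
  expect_equal(f7$tau, f0$tau, tolerance = 1e-8)
  expect_equal(f7$c - f0$c, 7, tolerance = 1e-8)
})

test_that("rate regression recovers k_ON, k_OFF and K_d from exact rates", {
  conc <- c(1, 3, 10)
  taus <- 1 / (0.3 * conc + 1.2)
  rr <- rate_regression(data.frame(concentration_uM = conc, tau = taus))
  expect_equal(rr$k_on, 0.3, tolerance = 1e-12)
  expect_equal(rr$k_off, 1.2, tolerance = 1e-12)
  expect_equal(rr$K_d, 4.0, tolerance = 1e-12)
  # K_d identity holds exactly by construction
  expect_identical(rr$K_d * rr$k_on, rr$k_off)
  # doubling both rates leaves K_d unchanged
  taus2 <- 1 / (0.6 * conc + 2.4)
  rr2 <- rate_regression(data.frame(concentration_uM = conc, tau = taus2))
  expect_equal(rr2$K_d, rr$K_d, tolerance = 1e-12)
})

test_that("concentration-independent rates yield a no-association error", {
  d <- data.frame(concentration_uM = c(1, 3, 10), tau = rep(0.5, 3))
  expect_error(rate_regression(d), "slope <= 0|no association")
  expect_error(rate_regression(data.frame(concentration_uM = c(1, 1, 1),
                                          tau = c(1, 2, 3))), "distinct")
})

test_that("washout k_OFF cross-check flags >2-fold disagreement", {
  conc <- c(1, 3, 10)
  taus <- 1 / (0.3 * conc + 1.2)
  ok <- rate_regression(data.frame(concentration_uM = conc, tau = taus),
                        washout = rep(1 / 1.2, 3))
  expect_false(ok$washout_discrepant)
  expect_equal(ok$k_off_washout, 1.2, tolerance = 1e-12)
  bad <- rate_regression(data.frame(concentration_uM = conc, tau = taus),
                         washout = rep(1 / 0.3, 3))
  expect_true(bad$washout_discrepant)
})

test_that("end-to-end: Q-model relaxations recover the binding rate constants", {
  sch <- two_state_scheme(k_on = 0.3, k_off = 1.2)
  concs <- c(1, 3, 10)
  taus <- vapply(concs, function(M) {
    tr <- simulate_relaxation(
      sch, data.frame(start = 0, agonist = 0, pam = 0, nam = M),
      times = seq(0.005, 4, by = 0.005), initial = c(1, 0),
      weights = c(R.N = 1))
    coef(fit_relaxation(tr, "exp"))[["tau"]]
  }, numeric(1))
  rr <- rate_regression(data.frame(concentration_uM = concs, tau = taus))
  expect_equal(rr$k_on, 0.3, tolerance = 0.05)
  expect_equal(rr$k_off, 1.2, tolerance = 0.05)
  expect_equal(rr$K_d, 4.0, tolerance = 0.05)
})

test_that("noisy synthetic traces still recover rates within tolerance", {
  tr <- generate_traces(k_on = 0.3, k_off = 1.2, concentrations = c(1, 3, 10),
                        noise = "additive-gaussian", noise_scale = 0.01,
                        seed = 77)
  taus <- vapply(tr$onset, function(x) coef(fit_relaxation(x, "exp"))[["tau"]],
                 numeric(1))
  rr <- rate_regression(
    data.frame(concentration_uM = c(1, 3, 10), tau = taus),
    washout = vapply(tr$washout, function(x) {
      coef(fit_relaxation(x, "exp"))[["tau"]]
    }, numeric(1)))
  expect_equal(rr$k_on, 0.3, tolerance = 0.15)
  expect_equal(rr$k_off, 1.2, tolerance = 0.15)
  expect_false(rr$washout_discrepant)
})

test_that("washout time constants are concentration independent", {
  tr <- generate_traces(k_on = 0.3, k_off = 1.2,
                        concentrations = c(1, 3, 10), noise = "none")
  taus <- vapply(tr$washout, function(x) {
    coef(fit_relaxation(x, "exp"))[["tau"]]
  }, numeric(1))
  expect_lt(diff(range(taus)) / mean(taus), 0.02)
  expect_equal(mean(taus), 1 / 1.2, tolerance = 1e-4)
})

test_that("racemization half-life is recovered and reported as ln2/k", {
  ser <- generate_racemization(half_life = 197, times = seq(0, 720, by = 36))
  f <- fit_racemization(ser)
  expect_true(f$determined)
  expect_equal(f$half_life, 197, tolerance = 0.001)
  expect_equal(f$asymptote, 0.5, tolerance = 1e-4)
  expect_identical(f$half_life, log(2) / f$rate)
  # definition check at another rate: k = 0.01 /min -> 69.31 min
  ser2 <- generate_racemization(half_life = log(2) / 0.01,
                                times = seq(0, 400, by = 20))
  expect_equal(fit_racemization(ser2)$half_life, 69.31, tolerance = 1e-3)
  # fixing a known racemic asymptote pins the same answer
  f_fix <- fit_racemization(ser, asymptote = 0.5)
  expect_equal(f_fix$half_life, 197, tolerance = 1e-4)
  expect_identical(f_fix$asymptote, 0.5)
})

test_that("a known asymptote sharpens noisy half-life estimates", {
  hl_free <- hl_fix <- numeric(12)
  for (i in 1:12) {
    s <- generate_racemization(197, times = seq(0, 1080, by = 36),
                               noise_scale = 0.05, seed = 40 + i)
    hl_free[i] <- fit_racemization(s)$half_life
    hl_fix[i] <- fit_racemization(s, asymptote = 0.5)$half_life
  }
  expect_lt(sd(hl_fix), sd(hl_free))
  expect_equal(mean(hl_fix), 197, tolerance = 0.1)
})

test_that("non-decaying racemization series are not determined", {
  flat <- data.frame(time_min = seq(0, 300, by = 30),
                     activity = rep(0.5, 11))
  f <- fit_racemization(flat)
  expect_false(f$determined)
  expect_true(is.na(f$half_life))
  expect_error(fit_racemization(data.frame(time_min = c(1, 2, 3, 4),
                                           activity = c(1, 1, 1, 1))),
               ">= 5")
})
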