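test_that("Hill equations honour their fixed points", {
  # modulator form: identity at zero, midpoint, saturation plateau
  expect_equal(hill_modulator(0, EC50 = 5, h = 2, Extent = 3), 1)
  expect_equal(hill_modulator(0.20, EC50 = 0.20, h = 1, Extent = -0.86),
               0.57)
  # submaximal NAM: at 10^4 x EC50 the residual is essentially 14% of control
  expect_equal(hill_modulator(1e4 * 0.20, EC50 = 0.20, h = 1, Extent = -0.86),
               1 - 0.86 * 1e4 / (1e4 + 1), tolerance = 1e-12)
  # agonist form
  expect_equal(hill_agonist(0, EC50 = 2, h = 1.7), 0)
  expect_equal(hill_agonist(2, EC50 = 2, h = 0.6), 0.5)
  expect_equal(hill_agonist(6, EC50 = 2, h = 1), 0.75)
  expect_error(hill_modulator(1, EC50 = -1, h = 1, Extent = 0.5), "EC50")
  expect_error(hill_modulator(1, EC50 = 1, h = 1, Extent = -1.5), "Extent")
})

test_that("both Hill forms are monotonic in concentration", {
  set.seed(7)
  conc <- 10^seq(-3, 3, length.out = 40)
  for (i in 1:25) {
    ec <- 10^runif(1, -2, 2); h <- runif(1, 0.3, 4)
    ext <- runif(1, -1, 4)
    ym <- hill_modulator(conc, ec, h, ext)
    expect_true(all(diff(ym) * sign(ext) >= 0))
    ya <- hill_agonist(conc, ec, h)
    expect_true(all(diff(ya) >= 0))
  }
})

test_that("noiseless Hill data are recovered to high relative accuracy", {
  conc <- 10^seq(-2, 2, length.out = 7)
  truth <- c(EC50 = 2, h = 1.2, Extent = 1.5)
  crc <- data.frame(replicate_id = 1, concentration_uM = conc,
                    response = hill_modulator(conc, 2, 1.2, 1.5))
  f <- fit_hill(crc, "modulator", probe_conc = NULL)[[1]]
  expect_true(f$converged)
  expect_equal(unname(coef(f)), unname(truth), tolerance = 1e-6)

  # agonist form, and fixed Hill slope
  crc_a <- data.frame(replicate_id = 1, concentration_uM = conc,
                      response = hill_agonist(conc, 0.7, 1))
  fa <- fit_hill(crc_a, "agonist", fix_h = 1)[[1]]
  expect_equal(unname(coef(fa)[["EC50"]]), 0.7, tolerance = 1e-8)
})

test_that("fit -> simulate -> fit round trip is idempotent on noiseless data", {
  conc <- c(0.3, 1, 3, 10, 30)
  crc <- data.frame(replicate_id = 1, concentration_uM = conc,
                    response = hill_modulator(conc, 3, 0.9, -0.7))
  f1 <- fit_hill(crc, "modulator", probe_conc = NULL)[[1]]
  crc2 <- data.frame(replicate_id = 1, concentration_uM = conc,
                     response = predict(f1, conc))
  f2 <- fit_hill(crc2, "modulator", probe_conc = NULL)[[1]]
  expect_equal(coef(f1), coef(f2), tolerance = 1e-9)
})

test_that("the fit matches a brute-force grid-search oracle", {
  crc <- generate_crc(list(EC50 = 2, h = 1, Extent = 1.5),
                      concentrations = c(0.3, 1, 3, 10, 30),
                      n_replicates = 1, noise = "multiplicative-lognormal",
                      noise_scale = 0.05, seed = 421)
  f <- fit_hill(crc, "modulator", probe_conc = NULL)[[1]]
  # oracle: log-spaced EC50 grid x Hill-slope grid, Extent solved linearly
  conc <- crc$concentration_uM; y <- crc$response
  ec_grid <- 10^seq(-3, 3, length.out = 2000)
  h_grid <- 10^seq(log10(0.3), log10(3), length.out = 61)
  best <- c(ssr = Inf, ec = NA, h = NA)
  for (h in h_grid) {
    ch <- conc^h
    for (i in seq_along(ec_grid)) {
      w <- ch / (ch + ec_grid[i]^h)
      ext <- sum(w * (y - 1)) / sum(w * w)
      ssr <- sum((y - 1 - ext * w)^2)
      if (ssr < best[["ssr"]]) best <- c(ssr = ssr, ec = ec_grid[i], h = h)
    }
  }
  step <- diff(log10(ec_grid[1:2]))
  expect_lt(abs(log10(coef(f)[["EC50"]]) - log10(best[["ec"]])), step * 1.5)
})

test_that("inactive-compound replicates are refused, not fitted", {
  conc <- c(0.3, 1, 3, 10, 30)
  flat <- data.frame(replicate_id = 1, concentration_uM = conc,
                     response = c(1.00, 0.99, 1.01, 0.97, 0.92))
  f <- fit_hill(flat, "modulator")[[1]]
  expect_true(f$refused)
  expect_false(f$converged)
  expect_match(f$reason, "30")
  # a clearly active replicate is fitted even with the rule on
  act <- data.frame(replicate_id = 1, concentration_uM = conc,
                    response = hill_modulator(conc, 2, 1, -0.8))
  expect_true(fit_hill(act, "modulator")[[1]]$converged)
  # too few concentrations
  short <- data.frame(replicate_id = 1, concentration_uM = c(1, 10),
                      response = c(0.9, 0.5))
  expect_true(fit_hill(short, "modulator")[[1]]$refused)
})

test_that("log-scale EC50 aggregation matches hand-computed t-intervals", {
  mkfit <- function(ec, ext = NA) {
    structure(list(converged = TRUE, refused = FALSE,
                   params = c(EC50 = ec, h = 1, Extent = ext)),
              class = "hill_fit")
  }
  # degenerate sample: zero CI width
  s0 <- aggregate_log_ec50(lapply(rep(2, 4), mkfit))
  expect_equal(s0$ec50, 2)
  expect_equal(unname(s0$ci), c(2, 2))
  # geometric mean of a symmetric log set
  expect_equal(aggregate_log_ec50(lapply(c(0.1, 1, 10), mkfit))$ec50, 1)
  # hand t-interval on log10({1,2,4}) = {0, 0.30103, 0.60206}, df = 2
  s <- aggregate_log_ec50(lapply(c(1, 2, 4), mkfit))
  lec <- log10(c(1, 2, 4))
  half <- qt(0.975, 2) * sd(lec) / sqrt(3)
  expect_equal(unname(s$ci),
               10^(mean(lec) + c(-1, 1) * half), tolerance = 1e-12)
  expect_error(aggregate_log_ec50(list(mkfit(1))), ">= 2")
  # order invariance
  s_rev <- aggregate_log_ec50(lapply(c(4, 2, 1), mkfit))
  expect_equal(s_rev$ec50, s$ec50)
  expect_equal(s_rev$ci, s$ci)
})

test_that("aggregation is invariant to uniform concentration rescaling", {
  crc <- generate_crc(list(EC50 = 2, h = 1, Extent = 2), n_replicates = 4,
                      noise_scale = 0.05, seed = 11)
  s1 <- aggregate_log_ec50(fit_hill(crc, "modulator", probe_conc = NULL))
  crc10 <- crc
  crc10$concentration_uM <- crc10$concentration_uM * 10
  s10 <- aggregate_log_ec50(fit_hill(crc10, "modulator", probe_conc = NULL))
  expect_equal(s10$ec50 / s1$ec50, 10, tolerance = 1e-4)
  expect_equal(log10(s10$ci) - log10(s1$ci), c(lower = 1, upper = 1),
               tolerance = 1e-4)
})

test_that("fold shift is the geometric mean of per-pair potency ratios", {
  mkfits <- function(ecs) {
    structure(lapply(seq_along(ecs), function(i) {
      structure(list(converged = TRUE, refused = FALSE, replicate_id = i,
                     params = c(EC50 = ecs[i], h = 1, Extent = NA)),
                class = "hill_fit")
    }), class = "hill_fits")
  }
  expect_equal(fold_shift(mkfits(c(2, 4)), mkfits(c(2, 4)))$fold, 1)
  expect_equal(fold_shift(mkfits(c(2, 4)), mkfits(c(1, 2)))$fold, 2)
  fs <- fold_shift(mkfits(c(1, 4)), mkfits(c(0.5, 1)))
  expect_equal(fs$fold, sqrt(8), tolerance = 1e-12)   # 2.83
  # unpaired replicates are an error
  bad <- mkfits(c(1, 2, 3))
  expect_error(fold_shift(mkfits(c(1, 2)), bad), "pair")
})

test_that("95% log-EC50 CIs achieve nominal coverage on seeded simulations", {
  n_sims <- 200
  truth <- list(EC50 = 2, h = 1, Extent = 1.5)
  hits <- 0
  fitted <- 0
  for (i in seq_len(n_sims)) {
    crc <- generate_crc(truth, n_replicates = 8, noise_scale = 0.05,
                        seed = 5000 + i)
    s <- aggregate_log_ec50(fit_hill(crc, "modulator", probe_conc = NULL))
    fitted <- fitted + 1
    if (s$ci[["lower"]] <= truth$EC50 && truth$EC50 <= s$ci[["upper"]]) {
      hits <- hits + 1
    }
  }
  expect_equal(fitted, n_sims)
  expect_gte(hits / n_sims, 0.90)
})
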