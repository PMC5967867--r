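test_that("state expansion follows the binding topology", {
  s1 <- default_scheme("MODEL1")
  expect_length(s1$states, 12)   # 4 base states x {free, N, P}
  s2 <- default_scheme("MODEL2")
  expect_length(s2$states, 16)   # 4 base states x {free, N, P, NP}
  expect_true(any(grepl("\\.NP$", s2$states)))
  expect_false(any(grepl("\\.NP$", s1$states)))
})

test_that("invalid rates and topologies are rejected with named fields", {
  expect_error(modulator_spec("N", "NAM", k_on = -1, k_off_reference = 1),
               "k_on")
  expect_error(modulator_spec("N", "NAM", k_on = 1, k_off_reference = 0),
               "k_off_reference")
  expect_error(modulator_spec("N", "NAM", 1, 1, state_dependence_factor = 0.5),
               "state_dependence_factor")
  expect_error(receptor_scheme("MODEL1", agonist_on = 0), "agonist_on")
  expect_error(build_q_matrix(default_scheme(), -1), "concentrations")
})

test_that("cycle closure derives the open-state dissociation rate", {
  # PAM with gating factor 5: the RA2 <-> O <-> O.P <-> RA2.P cycle closes
  # only if dissociation from the open state is k_off_reference / 5
  pam <- modulator_spec("P", "PAM", k_on = 1, k_off_reference = 2,
                        gating_factor = 5, state_dependence_factor = 1)
  sch <- receptor_scheme("MODEL1", pam = pam)
  q <- build_q_matrix(sch, agonist_conc = 10, pam_conc = 3)
  fwd <- q["RA2", "O"] * q["O", "O.P"] * q["O.P", "RA2.P"] * q["RA2.P", "RA2"]
  bwd <- q["RA2", "RA2.P"] * q["RA2.P", "O.P"] * q["O.P", "O"] * q["O", "RA2"]
  expect_equal(fwd / bwd, 1, tolerance = 1e-12)
  expect_equal(q["O.P", "O"], 2 / 5)
})

test_that("Q matrices are valid generators at arbitrary concentrations", {
  set.seed(41)
  for (i in 1:20) {
    sch <- random_scheme()
    q <- build_q_matrix(sch, agonist_conc = stats::runif(1, 0, 200),
                        pam_conc = stats::runif(1, 0, 20),
                        nam_conc = stats::runif(1, 0, 20))
    expect_lt(max(abs(rowSums(q))), 1e-12)
    off <- q; diag(off) <- 0
    expect_true(all(off >= 0))
  }
})

test_that("concentration scaling of association entries is exact", {
  sch <- two_state_scheme(k_on = 0.3)
  q <- build_q_matrix(sch, agonist_conc = 0, nam_conc = 10)
  expect_identical(unname(q["R", "R.N"]), 3.0)
  q0 <- build_q_matrix(sch, agonist_conc = 0, nam_conc = 0)
  expect_identical(unname(q0["R", "R.N"]), 0)
})

test_that("equilibrium solvers agree and conserve probability", {
  # symmetric two-state: equal forward/backward rates -> (0.5, 0.5)
  sch <- two_state_scheme(k_on = 1, k_off = 2)
  q <- build_q_matrix(sch, 0, nam_conc = 2)   # on = off = 2 /s
  expect_equal(as.numeric(solve_equilibrium_nullspace(q)), c(0.5, 0.5),
               tolerance = 1e-12)
  expect_equal(as.numeric(solve_equilibrium_ode(q, initial = c(1, 0))),
               c(0.5, 0.5), tolerance = 1e-9)

  # binding isotherm: K_d = 4 uM at 4 uM -> half occupancy
  sch2 <- two_state_scheme(k_on = 0.3, k_off = 1.2)
  q2 <- build_q_matrix(sch2, 0, nam_conc = 4)
  occ <- solve_equilibrium_nullspace(q2)
  expect_equal(unname(occ["R.N"]), 0.5, tolerance = 1e-12)
})

test_that("nullspace equilibrium matches long-time matrix-power propagation", {
  # three-state chain with known rates, brute-force propagation as oracle
  nam <- modulator_spec("N", "NAM", k_on = 0.5, k_off_reference = 1,
                        gating_factor = 1, state_dependence_factor = 2)
  sch <- receptor_scheme("MODEL1", agonist_on = 2, agonist_off = 3,
                         nam = nam, n_agonist_sites = 1, gating = FALSE)
  q <- build_q_matrix(sch, agonist_conc = 4, nam_conc = 2)
  # discrete-time uniformization: P = I + Q/lambda, pi = lim pi0 P^k
  lambda <- max(abs(diag(q))) * 2
  P <- diag(nrow(q)) + unclass(q) / lambda
  v <- c(1, rep(0, nrow(q) - 1))
  for (i in 1:4000) v <- as.vector(v %*% P)
  expect_equal(as.numeric(solve_equilibrium_nullspace(q)), v,
               tolerance = 1e-8)
})

test_that("permuting state order permutes the stationary distribution", {
  sch <- default_scheme("MODEL1")
  q <- build_q_matrix(sch, 100, 2, 0.5)
  occ <- solve_equilibrium_nullspace(q)
  perm <- sample(nrow(q))
  qp <- unclass(q)[perm, perm]
  class(qp) <- class(q)
  occp <- solve_equilibrium_nullspace(qp)
  expect_equal(as.numeric(occp), as.numeric(occ)[perm], tolerance = 1e-10)
})

test_that("equilibrium is independent of the starting occupancy", {
  sch <- default_scheme("MODEL2")
  q <- build_q_matrix(sch, 100, 3, 1)
  n <- nrow(q)
  starts <- list(c(1, rep(0, n - 1)), rep(1 / n, n),
                 c(rep(0, n - 1), 1))
  sols <- lapply(starts, function(s) {
    as.numeric(solve_equilibrium_ode(q, initial = s))
  })
  expect_equal(sols[[1]], sols[[2]], tolerance = 1e-8)
  expect_equal(sols[[1]], sols[[3]], tolerance = 1e-8)
})

test_that("microscopic reversibility holds for every built scheme", {
  set.seed(99)
  for (i in 1:15) {
    chk <- check_reversibility(random_scheme())
    expect_true(chk$reversible)
    expect_lt(chk$max_imbalance, 1e-9)
  }
})

test_that("readout sums conducting-state occupancy with optional weights", {
  sch <- default_scheme("MODEL1")
  occ <- structure(rep(0, 12), names = sch$states, class = "occupancy")
  expect_equal(response_readout(occ, sch), 0)
  occ[c("O", "O.P")] <- 0.2
  expect_equal(response_readout(occ, sch), 0.4)
  expect_equal(response_readout(occ, sch, weights = c(O = 2)), 0.4)
  # binding-only scheme: no open states without explicit weights
  s2 <- two_state_scheme()
  occ2 <- structure(c(0.3, 0.7), names = s2$states, class = "occupancy")
  expect_error(response_readout(occ2, s2), "open states")
  expect_equal(response_readout(occ2, s2, weights = c(R.N = 1)), 0.7)
})

test_that("saturating NAM leaves a nonzero residual below control", {
  sch <- default_scheme("MODEL1")
  ctrl <- equilibrium_response(sch, 100)
  inhib <- equilibrium_response(sch, 100, nam_conc = 1000)
  expect_gt(inhib, 0)
  expect_lt(inhib, ctrl)
  # residual near the NAM gating factor (14% of control)
  expect_equal(inhib / ctrl, sch$modulators[["N"]]$gating_factor,
               tolerance = 0.15)
})

test_that("relaxation simulation is flat at equilibrium and exponential on a jump", {
  s <- two_state_scheme(k_on = 0.3, k_off = 1.2)
  # constant-concentration protocol starting at equilibrium -> flat
  prot <- data.frame(start = 0, agonist = 0, pam = 0, nam = 4)
  tr <- simulate_relaxation(s, prot, times = seq(0.01, 2, by = 0.05),
                            weights = c(R.N = 1))
  expect_lt(diff(range(tr$response)), 1e-8)

  # jump 0 -> 10 uM: mono-exponential with rate k_on [M] + k_off = 4.2 /s
  tr2 <- simulate_relaxation(s, prot = data.frame(start = 0, agonist = 0,
                                                  pam = 0, nam = 10),
                             times = seq(0.001, 2, by = 0.01),
                             initial = c(1, 0), weights = c(R.N = 1))
  b_inf <- 10 / (10 + 4)
  k_hat <- -unname(coef(lm(log(b_inf - tr2$response) ~ tr2$time))[2])
  expect_equal(k_hat, 4.2, tolerance = 1e-5)

  # segment end values match the segment equilibrium
  prot3 <- data.frame(start = c(0, 3), agonist = 0, pam = 0, nam = c(10, 2))
  tr3 <- simulate_relaxation(s, prot3, times = c(seq(0.1, 2.9, by = 0.1),
                                                 seq(3.1, 18, by = 0.1)),
                             weights = c(R.N = 1))
  q_seg2 <- build_q_matrix(s, 0, nam_conc = 2)
  eq2 <- response_readout(solve_equilibrium_nullspace(q_seg2), s,
                          weights = c(R.N = 1))
  expect_equal(tr3$response[nrow(tr3)], eq2, tolerance = 1e-6)

  expect_error(simulate_relaxation(s, data.frame(), 1:3), "empty|columns")
})

test_that("ODE and nullspace equilibria agree across a randomized fuzz suite", {
  set.seed(2024)
  n_cases <- 100
  worst <- 0
  for (i in seq_len(n_cases)) {
    sch <- random_scheme()
    q <- build_q_matrix(sch, agonist_conc = exp(stats::runif(1, log(1), log(200))),
                        pam_conc = stats::runif(1, 0, 10),
                        nam_conc = stats::runif(1, 0, 10))
    pi_ns <- solve_equilibrium_nullspace(q)
    pi_ode <- solve_equilibrium_ode(q)
    expect_equal(sum(pi_ns), 1, tolerance = 1e-10)
    expect_true(all(pi_ns >= 0))
    worst <- max(worst, max(abs(pi_ns - pi_ode)))
  }
  expect_lt(worst, 1e-8)
})
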