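# shared fixtures: schemes and small generators used across test files

# binding-only two-state scheme (single base state + one modulator)
two_state_scheme <- function(k_on = 0.3, k_off = 1.2) {
  receptor_scheme(
    "MODEL1",
    nam = modulator_spec("N", "NAM", k_on = k_on, k_off_reference = k_off,
                         gating_factor = 1, state_dependence_factor = 1),
    n_agonist_sites = 0, gating = FALSE)
}

# randomized full scheme for fuzz suites; rates kept in ranges where the
# slowest relaxation is fast enough for the ODE route to converge
random_scheme <- function(topology = sample(c("MODEL1", "MODEL2"), 1)) {
  runif_log <- function(lo, hi) exp(stats::runif(1, log(lo), log(hi)))
  receptor_scheme(
    topology,
    agonist_on = runif_log(1, 20), agonist_off = runif_log(5, 100),
    beta = runif_log(1, 50), alpha = runif_log(50, 1000),
    nam = modulator_spec("N", "NAM", k_on = runif_log(0.5, 5),
                         k_off_reference = runif_log(0.1, 5),
                         gating_factor = stats::runif(1, 0.05, 0.5),
                         state_dependence_factor = runif_log(1, 50)),
    pam = modulator_spec("P", "PAM", k_on = runif_log(0.5, 5),
                         k_off_reference = runif_log(0.1, 5),
                         gating_factor = stats::runif(1, 2, 10),
                         state_dependence_factor = runif_log(1, 50)))
}

# NAM concentration grid wide enough to bracket shifted IC50s
nam_grid <- function() 10^seq(-2.5, 2, by = 0.5)
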