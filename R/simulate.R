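#' @keywords internal
#' Evaluate an expression under a temporary RNG seed, restoring state after.
.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
      stop("seed must be a single integer", call. = FALSE)
    }
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

.apply_noise <- function(values, noise = c("none", "multiplicative-lognormal",
                                           "additive-gaussian"),
                         noise_scale = 0) {
  noise <- match.arg(noise)
  if (noise_scale < 0) stop("noise_scale must be >= 0", call. = FALSE)
  if (noise == "none" || noise_scale == 0) return(values)
  n <- length(values)
  if (noise == "multiplicative-lognormal") {
    sdlog <- sqrt(log(1 + noise_scale^2))
    # meanlog chosen so the noise factor has expectation exactly 1
    values * stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  } else {
    values + stats::rnorm(n, sd = noise_scale)
  }
}

#' Generate a synthetic concentration-response table
#'
#' Simulates replicate concentration-response measurements from known Hill
#' truth, the design used throughout for parameter-recovery and coverage
#' testing: typically a five-point half-log concentration series with a
#' handful of replicates and multiplicative lognormal noise (proportional
#' scatter, as in voltage-clamp response amplitudes). With `noise = "none"`
#' the responses equal the Hill values exactly; with a fixed seed the output
#' is byte-identical across calls.
#'
#' @param truth Named list of Hill parameters: `EC50`, `h` and, for the
#'   modulator form, `Extent`.
#' @param concentrations Concentration design, uM (default five half-log
#'   points 0.3 to 30 uM).
#' @param n_replicates Number of replicates (default 8).
#' @param form `"modulator"` or `"agonist"`.
#' @param noise Noise model: `"none"`, `"multiplicative-lognormal"` (scale =
#'   coefficient of variation) or `"additive-gaussian"` (scale = SD).
#' @param noise_scale Noise scale (default 0.05, i.e. 5 percent CV).
#' @param seed Optional integer seed; RNG state is restored afterwards.
#' @return CRC table with columns `replicate_id`, `concentration_uM`,
#'   `response`.
#' @export
generate_crc <- function(truth, concentrations = c(0.3, 1, 3, 10, 30),
                         n_replicates = 8, form = c("modulator", "agonist"),
                         noise = "multiplicative-lognormal",
                         noise_scale = 0.05, seed = NULL) {
  form <- match.arg(form)
  if (!length(concentrations)) {
    stop("generate_crc: empty concentration design", call. = FALSE)
  }
  mu <- if (form == "modulator") {
    hill_modulator(concentrations, truth$EC50, truth$h, truth$Extent)
  } else {
    hill_agonist(concentrations, truth$EC50, truth$h)
  }
  .with_seed(seed, {
    out <- lapply(seq_len(n_replicates), function(r) {
      data.frame(replicate_id = r, concentration_uM = concentrations,
                 response = .apply_noise(mu, noise, noise_scale))
    })
    do.call(rbind, out)
  })
}

#' Generate synthetic two-state relaxation traces
#'
#' Emulates whole-cell modulation time-course records for a bimolecular
#' binding step: at each modulator concentration an onset trace relaxes
#' mono-exponentially with observed rate `k_on [M] + k_off` toward the
#' equilibrium bound fraction, and a washout trace decays at `k_off`. The
#' response is `baseline + amplitude * bound_fraction(t)`, so a NAM-like
#' truth uses a negative amplitude. Gaussian noise is additive (instrument
#' noise). With `noise = "none"` the observed rate matches the closed form
#' exactly.
#'
#' @param k_on Association rate, 1/(uM s).
#' @param k_off Dissociation rate, 1/s.
#' @param concentrations Modulator concentrations for the onset traces, uM.
#' @param times Sample times, s (default 0 to 5 s at 20 ms).
#' @param amplitude Response change at full occupancy (default -1).
#' @param baseline Response before modulator application (default 1).
#' @param noise,noise_scale,seed As in [generate_crc()] (default additive
#'   gaussian).
#' @return List with `onset` (one `"relaxation_trace"`-style data frame per
#'   concentration, each with attribute `concentration_uM` and `true_tau`)
#'   and `washout` (one trace per concentration, decaying from the bound
#'   level).
#' @export
generate_traces <- function(k_on, k_off, concentrations,
                            times = seq(0, 5, by = 0.02),
                            amplitude = -1, baseline = 1,
                            noise = "additive-gaussian", noise_scale = 0,
                            seed = NULL) {
  stopifnot(k_on > 0, k_off > 0, length(concentrations) > 0)
  .with_seed(seed, {
    onset <- lapply(concentrations, function(M) {
      kobs <- k_on * M + k_off
      b_inf <- M / (M + k_off / k_on)
      y <- baseline + amplitude * b_inf * (1 - exp(-kobs * times))
      tr <- data.frame(time = times,
                       response = .apply_noise(y, noise, noise_scale))
      attr(tr, "concentration_uM") <- M
      attr(tr, "true_tau") <- 1 / kobs
      class(tr) <- c("relaxation_trace", "data.frame")
      tr
    })
    washout <- lapply(concentrations, function(M) {
      b0 <- M / (M + k_off / k_on)
      y <- baseline + amplitude * b0 * exp(-k_off * times)
      tr <- data.frame(time = times,
                       response = .apply_noise(y, noise, noise_scale))
      attr(tr, "concentration_uM") <- M
      attr(tr, "true_tau") <- 1 / k_off
      class(tr) <- c("relaxation_trace", "data.frame")
      tr
    })
    list(onset = onset, washout = washout)
  })
}

#' Generate a synthetic first-order racemization series
#'
#' Activity of a purified enantiomer decaying to the racemic asymptote:
#' `y(t) = asymptote + (y0 - asymptote) * 2^(-t / half_life)`. At
#' `t = half_life` the value is midway between start and asymptote.
#'
#' @param half_life Racemization half-life, minutes.
#' @param asymptote Racemic activity level (default 0.5).
#' @param y0 Initial activity of the pure enantiomer (default 1).
#' @param times Sample times, minutes (default 0 to 600 in steps of 30).
#' @param noise,noise_scale,seed As in [generate_crc()].
#' @return Data frame with columns `time_min`, `activity`.
#' @export
generate_racemization <- function(half_life, asymptote = 0.5, y0 = 1,
                                  times = seq(0, 600, by = 30),
                                  noise = "multiplicative-lognormal",
                                  noise_scale = 0, seed = NULL) {
  stopifnot(half_life > 0, length(times) > 0)
  mu <- asymptote + (y0 - asymptote) * 2^(-times / half_life)
  .with_seed(seed, {
    data.frame(time_min = times,
               activity = .apply_noise(mu, noise, noise_scale))
  })
}

#' Generate a synthetic mutant panel
#'
#' Draws per-construct percent-of-control replicates around specified means,
#' the fixture generator for the mutant classifier: each construct is
#' described by a mean, SD and replicate count, and values are drawn from a
#' normal distribution (SD 0 gives the mean exactly).
#'
#' @param specs Data frame with columns `construct`, `mean`, `sd`, `n`.
#' @param seed Optional integer seed.
#' @return A `"mutant_panel"` data frame (columns `construct`,
#'   `replicate_id`, `percent_of_control`).
#' @export
generate_mutant_panel <- function(specs, seed = NULL) {
  need <- c("construct", "mean", "sd", "n")
  if (!is.data.frame(specs) || !all(need %in% names(specs))) {
    stop("generate_mutant_panel: specs needs columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(specs$sd < 0) || any(specs$n < 1)) {
    stop("generate_mutant_panel: sd must be >= 0 and n >= 1", call. = FALSE)
  }
  .with_seed(seed, {
    rows <- lapply(seq_len(nrow(specs)), function(i) {
      data.frame(construct = specs$construct[i],
                 replicate_id = seq_len(specs$n[i]),
                 percent_of_control = stats::rnorm(specs$n[i],
                                                   mean = specs$mean[i],
                                                   sd = specs$sd[i]))
    })
    out <- do.call(rbind, rows)
    class(out) <- c("mutant_panel", "data.frame")
    out
  })
}
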