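#' Fit an exponential relaxation to a modulation time course
#'
#' Fits the onset/offset of modulation with a single exponential,
#' `dI(t) = A (1 - exp(-t/tau)) + c`, or with an exponential plus a linear
#' component, `dI(t) = A (1 - exp(-t/tau)) + m t + c`, the form used when a
#' slow second phase of modulation rides on the primary relaxation. The fit
#' is separable least squares: for a candidate time constant the amplitude,
#' offset and slope are the exact linear solution, and tau is optimized over
#' a log-spaced decade grid spanning the trace duration followed by a local
#' refinement. This makes the fit deterministic and immune to poor starting
#' values.
#'
#' A trace without exponential structure (flat, or dominated by
#' non-exponential variation so that the model explains less than `min_r2`
#' of the variance) is flagged as not converged and its parameters withheld.
#'
#' @param trace A data frame with columns `time` (s) and `response`, e.g. a
#'   `"relaxation_trace"` from [simulate_relaxation()] or
#'   [generate_traces()]. At least 8 samples are required.
#' @param form `"exp"` or `"exp_linear"`.
#' @param min_r2 Minimum variance explained for the fit to count as
#'   converged (default 0.2).
#' @return Object of class `"kinetic_fit"` with `A`, `tau` (s), `c`, `m`
#'   (`NA` for the plain exponential), `residual_norm`, `r_squared`,
#'   `converged` and the fitted data.
#' @export
fit_relaxation <- function(trace, form = c("exp", "exp_linear"),
                           min_r2 = 0.2) {
  form <- match.arg(form)
  if (!is.data.frame(trace) || !all(c("time", "response") %in% names(trace))) {
    stop("fit_relaxation: trace needs columns 'time' and 'response'",
         call. = FALSE)
  }
  t <- trace$time - min(trace$time)
  y <- trace$response
  if (length(t) < 8) {
    stop("fit_relaxation: need at least 8 samples", call. = FALSE)
  }
  out <- list(form = form, A = NA_real_, tau = NA_real_, c = NA_real_,
              m = NA_real_, residual_norm = NA_real_, r_squared = NA_real_,
              converged = FALSE, reason = NA_character_,
              data = data.frame(time = t, response = y))
  tss <- sum((y - mean(y))^2)
  if (tss == 0) {
    out$reason <- "constant trace; amplitude 0, tau unidentifiable"
    class(out) <- "kinetic_fit"
    return(out)
  }
  span <- max(t) - min(t)
  dt <- min(diff(sort(unique(t))))
  ssr_for <- function(ltau) .relax_lin(t, y, exp(ltau), form)$ssr
  lgrid <- seq(log(dt / 4), log(span * 3), length.out = 60)
  ssrs <- vapply(lgrid, ssr_for, numeric(1))
  i0 <- which.min(ssrs)
  lo <- lgrid[max(1, i0 - 1)]; hi <- lgrid[min(length(lgrid), i0 + 1)]
  opt <- stats::optimize(ssr_for, interval = c(lo, hi), tol = 1e-10)
  tau <- exp(opt$minimum)
  sol <- .relax_lin(t, y, tau, form)
  r2 <- 1 - sol$ssr / tss
  out$residual_norm <- sqrt(sol$ssr)
  out$r_squared <- r2
  if (!is.finite(r2) || r2 < min_r2) {
    out$reason <- sprintf("no exponential structure (R^2 = %.3g)", r2)
    class(out) <- "kinetic_fit"
    return(out)
  }
  out$A <- sol$A; out$tau <- tau; out$c <- sol$c; out$m <- sol$m
  out$converged <- TRUE
  class(out) <- "kinetic_fit"
  out
}

# exact linear solve for (A, c[, m]) at fixed tau
.relax_lin <- function(t, y, tau, form) {
  b <- 1 - exp(-t / tau)
  X <- if (form == "exp_linear") cbind(b, 1, t) else cbind(b, 1)
  fit <- stats::lm.fit(X, y)
  cf <- fit$coefficients
  cf[is.na(cf)] <- 0
  list(A = cf[[1]], c = cf[[2]],
       m = if (form == "exp_linear") cf[[3]] else NA_real_,
       ssr = sum(fit$residuals^2))
}

#' @export
print.kinetic_fit <- function(x, ...) {
  if (!x$converged) {
    cat(sprintf("Relaxation fit (%s): not converged - %s\n", x$form, x$reason))
  } else if (x$form == "exp") {
    cat(sprintf("Relaxation fit (exp): A %.4g, tau %.4g s (rate %.4g /s), c %.4g; R^2 %.4f\n",
                x$A, x$tau, 1 / x$tau, x$c, x$r_squared))
  } else {
    cat(sprintf("Relaxation fit (exp+linear): A %.4g, tau %.4g s, m %.4g /s, c %.4g; R^2 %.4f\n",
                x$A, x$tau, x$m, x$c, x$r_squared))
  }
  invisible(x)
}

#' @export
coef.kinetic_fit <- function(object, ...) {
  c(A = object$A, tau = object$tau, c = object$c, m = object$m)
}

#' @export
predict.kinetic_fit <- function(object, newdata = NULL, ...) {
  if (!object$converged) stop("predict.kinetic_fit: fit did not converge",
                              call. = FALSE)
  t <- if (is.null(newdata)) object$data$time else {
    if (is.data.frame(newdata)) newdata$time else newdata
  }
  y <- object$A * (1 - exp(-t / object$tau)) + object$c
  if (object$form == "exp_linear") y <- y + object$m * t
  y
}

#' Extract k_ON, k_OFF and K_d from concentration-dependent relaxation rates
#'
#' Under the pseudo-first-order treatment of bimolecular binding, the
#' observed onset relaxation rate is linear in modulator concentration,
#' `1/tau = k_ON [M] + k_OFF`, while the washout rate is concentration
#' independent and equals `k_OFF` directly. This function regresses the
#' observed onset rates on concentration by ordinary least squares: the
#' slope is the association rate constant `k_ON` (1/(uM s)), the intercept
#' the dissociation rate `k_OFF` (1/s), and the kinetically determined
#' dissociation constant is `K_d = k_OFF / k_ON` (uM). Washout fits, when
#' supplied, provide an independent `k_OFF` estimate; a greater than 2-fold
#' disagreement between intercept and washout estimates is flagged.
#'
#' @param onset Data frame with columns `concentration_uM` and `tau` (s), one
#'   row per onset measurement (or a list of `"kinetic_fit"` objects plus a
#'   `concentration_uM` vector of the same length). At least 3 distinct
#'   concentrations are required.
#' @param washout Optional vector of washout time constants (s), or data
#'   frame with column `tau`.
#' @return Object of class `"rate_regression"` with `k_on`, `k_off`, `K_d`,
#'   `k_off_washout`, `r_squared`, `washout_discrepant` and the per-
#'   concentration observed rates.
#' @export
rate_regression <- function(onset, washout = NULL) {
  if (is.list(onset) && !is.data.frame(onset) &&
      all(vapply(onset, inherits, logical(1), "kinetic_fit"))) {
    stop("rate_regression: pass a data frame with columns concentration_uM ",
         "and tau (see also attr 'concentration_uM')", call. = FALSE)
  }
  if (!is.data.frame(onset) ||
      !all(c("concentration_uM", "tau") %in% names(onset))) {
    stop("rate_regression: onset needs columns 'concentration_uM' and 'tau'",
         call. = FALSE)
  }
  conc <- onset$concentration_uM
  if (length(unique(conc)) < 3) {
    stop("rate_regression: need >= 3 distinct onset concentrations",
         call. = FALSE)
  }
  if (any(onset$tau <= 0)) {
    stop("rate_regression: time constants must be > 0", call. = FALSE)
  }
  rate <- 1 / onset$tau
  fm <- stats::lm(rate ~ conc)
  k_on <- unname(stats::coef(fm)[2])
  k_off <- unname(stats::coef(fm)[1])
  if (!is.finite(k_on) || k_on <= 0) {
    stop("rate_regression: observed rates do not increase with concentration ",
         "(slope <= 0); no association rate, K_d undefined", call. = FALSE)
  }
  tss <- sum((rate - mean(rate))^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fm)^2) / tss else 1
  k_off_w <- NA_real_
  discrepant <- FALSE
  if (!is.null(washout)) {
    tw <- if (is.data.frame(washout)) washout$tau else washout
    if (any(tw <= 0)) stop("rate_regression: washout tau must be > 0",
                           call. = FALSE)
    k_off_w <- mean(1 / tw)
    if (k_off > 0 && k_off_w > 0) {
      discrepant <- max(k_off / k_off_w, k_off_w / k_off) > 2
    }
  }
  structure(
    list(k_on = k_on, k_off = k_off, K_d = k_off / k_on,
         k_off_washout = k_off_w, washout_discrepant = discrepant,
         r_squared = r2,
         observed = data.frame(concentration_uM = conc, rate = rate)),
    class = "rate_regression"
  )
}

#' @export
print.rate_regression <- function(x, ...) {
  cat(sprintf("Rate regression (1/tau = k_ON [M] + k_OFF, R^2 %.4f):\n",
              x$r_squared))
  cat(sprintf("  k_ON %.4g /(uM s), k_OFF %.4g /s  =>  K_d %.4g uM\n",
              x$k_on, x$k_off, x$K_d))
  if (!is.na(x$k_off_washout)) {
    cat(sprintf("  washout k_OFF %.4g /s%s\n", x$k_off_washout,
                if (x$washout_discrepant)
                  "  [WARNING: > 2-fold disagreement with intercept]" else ""))
  }
  invisible(x)
}

#' @export
coef.rate_regression <- function(object, ...) {
  c(k_on = object$k_on, k_off = object$k_off, K_d = object$K_d)
}

#' Fit first-order racemization of an enantiomer
#'
#' A purified enantiomer in aqueous solution interconverts with its mirror
#' image by a first-order reaction, so any activity proxy of enantiomeric
#' excess relaxes exponentially to the racemic asymptote:
#' `y(t) = y_inf + (y_0 - y_inf) exp(-k t)`. The fit is separable least
#' squares over a log-spaced rate grid with local refinement, and reports
#' the half-life `ln 2 / k` in minutes.
#'
#' @param series Data frame with columns `time_min` (increasing) and
#'   `activity` (any proxy proportional to enantiomeric excess plus a
#'   constant). At least 5 time points are required.
#' @param asymptote Optional known racemic activity level. The racemate is
#'   usually available as a reference compound, so its activity (the decay
#'   asymptote) can be measured directly; fixing it substantially sharpens
#'   the rate estimate. Default `NULL` (asymptote fitted).
#' @param min_r2 Minimum variance explained for a determined fit.
#' @return Object of class `"racemization_fit"` with `rate` (1/min),
#'   `half_life` (min), `asymptote`, `y0`, `determined` flag.
#' @export
fit_racemization <- function(series, asymptote = NULL, min_r2 = 0.5) {
  if (!is.data.frame(series) ||
      !all(c("time_min", "activity") %in% names(series))) {
    stop("fit_racemization: series needs columns 'time_min' and 'activity'",
         call. = FALSE)
  }
  t <- series$time_min
  y <- series$activity
  if (length(t) < 5) stop("fit_racemization: need >= 5 time points",
                          call. = FALSE)
  if (is.unsorted(t, strictly = TRUE)) {
    stop("fit_racemization: times must be strictly increasing", call. = FALSE)
  }
  out <- list(rate = NA_real_, half_life = NA_real_, asymptote = NA_real_,
              y0 = NA_real_, r_squared = NA_real_, determined = FALSE,
              reason = NA_character_, data = series)
  tss <- sum((y - mean(y))^2)
  if (tss == 0) {
    out$reason <- "flat series at the asymptote; rate not determined"
    class(out) <- "racemization_fit"
    return(out)
  }
  span <- max(t) - min(t)
  solve_at <- function(k) {
    e <- exp(-k * (t - min(t)))
    if (is.null(asymptote)) {
      fit <- stats::lm.fit(cbind(1, e), y)
      cf <- fit$coefficients
      list(asym = cf[[1]], amp = cf[[2]], ssr = sum(fit$residuals^2))
    } else {
      fit <- stats::lm.fit(cbind(e), y - asymptote)
      list(asym = asymptote, amp = fit$coefficients[[1]],
           ssr = sum(fit$residuals^2))
    }
  }
  ssr_for <- function(lk) solve_at(exp(lk))$ssr
  lgrid <- seq(log(0.05 / span), log(20 / min(diff(t))), length.out = 60)
  ssrs <- vapply(lgrid, ssr_for, numeric(1))
  i0 <- which.min(ssrs)
  opt <- stats::optimize(ssr_for,
                         interval = c(lgrid[max(1, i0 - 1)],
                                      lgrid[min(length(lgrid), i0 + 1)]),
                         tol = 1e-12)
  k <- exp(opt$minimum)
  sol <- solve_at(k)
  if (!is.null(asymptote)) {
    tss <- sum((y - asymptote)^2)   # variance against the known asymptote
  }
  r2 <- 1 - sol$ssr / tss
  out$r_squared <- r2
  if (!is.finite(r2) || r2 < min_r2 || sol$amp <= 0) {
    out$reason <- "series does not decay exponentially; rate not determined"
    class(out) <- "racemization_fit"
    return(out)
  }
  out$rate <- k
  out$half_life <- log(2) / k
  out$asymptote <- sol$asym
  out$y0 <- sol$asym + sol$amp
  out$determined <- TRUE
  class(out) <- "racemization_fit"
  out
}

#' @export
print.racemization_fit <- function(x, ...) {
  if (!x$determined) {
    cat("Racemization fit: not determined -", x$reason, "\n")
  } else {
    cat(sprintf("Racemization: first-order rate %.4g /min, half-life %.4g min (R^2 %.4f)\n",
                x$rate, x$half_life, x$r_squared))
    cat(sprintf("  initial activity %.4g decaying to racemic asymptote %.4g\n",
                x$y0, x$asymptote))
  }
  invisible(x)
}

#' @export
coef.racemization_fit <- function(object, ...) {
  c(rate = object$rate, half_life = object$half_life,
    asymptote = object$asymptote)
}
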