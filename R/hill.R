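#' Hill equation for modulator concentration-response
#'
#' Response ratio of the modulated to the unmodulated agonist response,
#' `I/I0 = 1 + Extent * M^h / (M^h + EC50^h)`. At `M = 0` the ratio is 1
#' (100 percent of control); at saturation it plateaus at `1 + Extent`.
#' Negative `Extent` (bounded below by -1) describes inhibition with a
#' residual current of `1 + Extent`; positive `Extent` describes
#' potentiation.
#'
#' @param M Modulator concentration(s), uM, `>= 0`.
#' @param EC50 Half-maximally effective modulator concentration, uM, `> 0`.
#' @param h Hill slope, `> 0`.
#' @param Extent Maximal fractional modulation; `1 + Extent >= 0`.
#' @return Response ratio(s) I/I0.
#' @examples
#' hill_modulator(0.20, EC50 = 0.20, h = 1, Extent = -0.86)   # midpoint: 0.57
#' @export
hill_modulator <- function(M, EC50, h, Extent) {
  .check_hill_params(EC50, h, Extent)
  if (any(M < 0)) stop("hill_modulator: M must be >= 0", call. = FALSE)
  frac <- ifelse(M == 0, 0, M^h / (M^h + EC50^h))
  1 + Extent * frac
}

#' Hill equation for agonist concentration-response
#'
#' Fraction of the maximal response, `I/Imax = A^h / (A^h + EC50^h)`:
#' 0 at zero agonist, 0.5 at `A = EC50`, approaching 1 at saturation.
#'
#' @param A Agonist concentration(s), uM, `>= 0`.
#' @param EC50 Half-maximally effective agonist concentration, uM, `> 0`.
#' @param h Hill slope, `> 0`.
#' @return Response fraction(s) I/Imax.
#' @export
hill_agonist <- function(A, EC50, h) {
  .check_hill_params(EC50, h, NULL)
  if (any(A < 0)) stop("hill_agonist: A must be >= 0", call. = FALSE)
  ifelse(A == 0, 0, A^h / (A^h + EC50^h))
}

.check_hill_params <- function(EC50, h, Extent) {
  if (!is.numeric(EC50) || any(!is.finite(EC50)) || any(EC50 <= 0)) {
    stop("Hill parameters: EC50 must be > 0", call. = FALSE)
  }
  if (!is.numeric(h) || any(!is.finite(h)) || any(h <= 0)) {
    stop("Hill parameters: h must be > 0", call. = FALSE)
  }
  if (!is.null(Extent) && (any(!is.finite(Extent)) || any(1 + Extent < 0))) {
    stop("Hill parameters: 1 + Extent must be >= 0", call. = FALSE)
  }
  invisible(TRUE)
}

.validate_crc <- function(crc) {
  need <- c("replicate_id", "concentration_uM", "response")
  if (!is.data.frame(crc) || !all(need %in% names(crc))) {
    stop("CRC table must be a data frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(crc$concentration_uM < 0)) {
    stop("CRC table: concentrations must be >= 0", call. = FALSE)
  }
  if (any(!is.finite(crc$response))) {
    stop("CRC table: responses must be finite", call. = FALSE)
  }
  invisible(crc)
}

#' Fit the Hill equation per replicate
#'
#' Nonlinear least-squares Hill fits of a tidy concentration-response table,
#' one fit per replicate, by Levenberg-Marquardt with multi-start
#' initialization. Fitting is parameterized internally in `log10(EC50)`,
#' which matches the convention of summarizing potency on the log scale and
#' stabilizes the optimizer. EC50 is started at the geometric mean of the
#' tested concentrations and at each tested concentration; the Hill slope is
#' started at 0.8, 1 and 1.5; the best residual wins, ties broken by the
#' smallest distance of log EC50 from the log median concentration.
#'
#' For the modulator form, a replicate whose response at the probe
#' concentration (default 30 uM, when tested) differs from control by less
#' than `refuse_frac` (default 15 percent) is refused rather than fitted,
#' the convention used for compounds with no measurable activity.
#' Non-converged replicates are flagged, never silently dropped.
#'
#' @param crc Data frame with columns `replicate_id`, `concentration_uM`,
#'   `response` (response ratio I/I0 for the modulator form, fraction I/Imax
#'   for the agonist form). Each replicate needs `>= 3` distinct non-zero
#'   concentrations.
#' @param form `"modulator"` or `"agonist"`.
#' @param fix_h Optional fixed Hill slope (e.g. `1`); if `NULL` (default) the
#'   slope is free.
#' @param probe_conc,refuse_frac Probe concentration (uM) and minimum
#'   fractional change from control for the modulator-form refusal rule. Set
#'   `probe_conc = NULL` to disable.
#' @return An object of class `"hill_fits"`: a list of per-replicate
#'   `"hill_fit"` objects, each with `params`, `converged`, `refused`,
#'   `residual_norm`, `replicate_id` and the data fitted.
#' @seealso [aggregate_log_ec50()], [fold_shift()]
#' @export
fit_hill <- function(crc, form = c("modulator", "agonist"), fix_h = NULL,
                     probe_conc = 30, refuse_frac = 0.15) {
  form <- match.arg(form)
  .validate_crc(crc)
  fits <- lapply(split(crc, crc$replicate_id), function(d) {
    .fit_hill_one(d, form, fix_h, probe_conc, refuse_frac)
  })
  structure(fits, class = "hill_fits", form = form)
}

.fit_hill_one <- function(d, form, fix_h, probe_conc, refuse_frac) {
  rid <- d$replicate_id[1]
  conc <- d$concentration_uM
  y <- d$response
  res <- list(replicate_id = rid, form = form, converged = FALSE,
              refused = FALSE, reason = NA_character_,
              params = c(EC50 = NA_real_, h = NA_real_, Extent = NA_real_),
              residual_norm = NA_real_,
              data = data.frame(concentration_uM = conc, response = y))
  pos <- conc > 0
  if (length(unique(conc[pos])) < 3) {
    res$refused <- TRUE
    res$reason <- "fewer than 3 distinct non-zero concentrations"
    class(res) <- "hill_fit"
    return(res)
  }
  if (form == "modulator" && !is.null(probe_conc)) {
    at_probe <- abs(conc - probe_conc) < 1e-8 * max(probe_conc, 1)
    if (any(at_probe) && all(abs(y[at_probe] - 1) <= refuse_frac)) {
      res$refused <- TRUE
      res$reason <- sprintf(
        "response at %g uM within %g%% of control; not fit",
        probe_conc, 100 * refuse_frac)
      class(res) <- "hill_fit"
      return(res)
    }
  }
  cp <- conc[pos]; yp <- y[pos]
  lstarts <- unique(c(mean(log10(cp)), log10(unique(cp))))
  hstarts <- if (is.null(fix_h)) c(0.8, 1, 1.5) else fix_h
  lmed <- stats::median(log10(cp))

  best <- NULL
  for (l0 in lstarts) {
    for (h0 in hstarts) {
      fit <- .try_hill_nls(cp, yp, form, l0, h0, fix_h)
      if (is.null(fit)) next
      if (is.null(best) ||
          fit$rss < best$rss - 1e-12 ||
          (abs(fit$rss - best$rss) <= 1e-12 &&
           abs(fit$lec - lmed) < abs(best$lec - lmed))) {
        best <- fit
      }
    }
  }
  if (is.null(best)) {
    res$reason <- "optimizer failed to converge from all starts"
    class(res) <- "hill_fit"
    return(res)
  }
  res$converged <- TRUE
  res$params <- c(EC50 = 10^best$lec, h = best$h,
                  Extent = if (form == "modulator") best$Extent else NA_real_)
  res$residual_norm <- sqrt(best$rss)
  class(res) <- "hill_fit"
  res
}

.try_hill_nls <- function(conc, y, form, l0, h0, fix_h) {
  d <- data.frame(conc = conc, y = y)
  lo_l <- min(log10(conc)) - 4
  hi_l <- max(log10(conc)) + 4
  out <- tryCatch({
    if (form == "modulator") {
      e0 <- y[which.max(conc)] - 1
      if (abs(e0) < 1e-3) e0 <- sign(e0 + 1e-9) * 0.1
      if (is.null(fix_h)) {
        fm <- minpack.lm::nlsLM(
          y ~ 1 + Extent * conc^h / (conc^h + (10^lec)^h), data = d,
          start = list(lec = l0, h = h0, Extent = e0),
          lower = c(lo_l, 0.05, -1), upper = c(hi_l, 10, Inf),
          control = minpack.lm::nls.lm.control(maxiter = 200))
        cf <- stats::coef(fm)
        list(lec = cf[["lec"]], h = cf[["h"]], Extent = cf[["Extent"]],
             rss = sum(stats::residuals(fm)^2))
      } else {
        fm <- minpack.lm::nlsLM(
          y ~ 1 + Extent * conc^fix_h / (conc^fix_h + (10^lec)^fix_h),
          data = d, start = list(lec = l0, Extent = e0),
          lower = c(lo_l, -1), upper = c(hi_l, Inf),
          control = minpack.lm::nls.lm.control(maxiter = 200))
        cf <- stats::coef(fm)
        list(lec = cf[["lec"]], h = fix_h, Extent = cf[["Extent"]],
             rss = sum(stats::residuals(fm)^2))
      }
    } else {
      if (is.null(fix_h)) {
        fm <- minpack.lm::nlsLM(
          y ~ conc^h / (conc^h + (10^lec)^h), data = d,
          start = list(lec = l0, h = h0),
          lower = c(lo_l, 0.05), upper = c(hi_l, 10),
          control = minpack.lm::nls.lm.control(maxiter = 200))
        cf <- stats::coef(fm)
        list(lec = cf[["lec"]], h = cf[["h"]], Extent = NA_real_,
             rss = sum(stats::residuals(fm)^2))
      } else {
        fm <- minpack.lm::nlsLM(
          y ~ conc^fix_h / (conc^fix_h + (10^lec)^fix_h), data = d,
          start = list(lec = l0),
          lower = lo_l, upper = hi_l,
          control = minpack.lm::nls.lm.control(maxiter = 200))
        cf <- stats::coef(fm)
        list(lec = cf[["lec"]], h = fix_h, Extent = NA_real_,
             rss = sum(stats::residuals(fm)^2))
      }
    }
  }, error = function(e) NULL, warning = function(w) NULL)
  out
}

#' @export
print.hill_fit <- function(x, ...) {
  if (x$refused) {
    cat(sprintf("Hill fit (replicate %s): not fit - %s\n",
                x$replicate_id, x$reason))
  } else if (!x$converged) {
    cat(sprintf("Hill fit (replicate %s): did not converge (%s)\n",
                x$replicate_id, x$reason))
  } else {
    p <- x$params
    if (x$form == "modulator") {
      cat(sprintf("Hill fit (replicate %s, modulator): EC50 %.4g uM, h %.3g, Extent %.3g (plateau %.3g%% of control)\n",
                  x$replicate_id, p[["EC50"]], p[["h"]], p[["Extent"]],
                  100 * (1 + p[["Extent"]])))
    } else {
      cat(sprintf("Hill fit (replicate %s, agonist): EC50 %.4g uM, h %.3g\n",
                  x$replicate_id, p[["EC50"]], p[["h"]]))
    }
  }
  invisible(x)
}

#' @export
coef.hill_fit <- function(object, ...) object$params

#' @export
predict.hill_fit <- function(object, newdata = NULL, ...) {
  if (!object$converged) stop("predict.hill_fit: fit did not converge",
                              call. = FALSE)
  conc <- if (is.null(newdata)) object$data$concentration_uM else {
    if (is.data.frame(newdata)) newdata$concentration_uM else newdata
  }
  p <- object$params
  if (object$form == "modulator") {
    hill_modulator(conc, p[["EC50"]], p[["h"]], p[["Extent"]])
  } else {
    hill_agonist(conc, p[["EC50"]], p[["h"]])
  }
}

#' @export
print.hill_fits <- function(x, ...) {
  cat(sprintf("%d Hill fits (%s form): %d converged, %d refused\n",
              length(x), attr(x, "form"),
              sum(vapply(x, function(f) f$converged, logical(1))),
              sum(vapply(x, function(f) f$refused, logical(1)))))
  for (f in x) print(f)
  invisible(x)
}

#' @export
coef.hill_fits <- function(object, ...) {
  t(vapply(object, function(f) f$params, numeric(3)))
}

#' Aggregate replicate EC50s on the log scale
#'
#' Summarizes converged per-replicate Hill fits the way modulator potencies
#' are conventionally reported: the mean and t-based confidence interval are
#' computed on `log10(EC50)` and back-transformed, so the reported EC50 is
#' the geometric mean with an asymmetric CI. The modulation extent is
#' summarized as arithmetic mean +/- SEM.
#'
#' @param fits A `"hill_fits"` object (or list of `"hill_fit"`); at least two
#'   converged fits are required.
#' @param level Confidence level (default 0.95).
#' @return An object of class `"hill_summary"` with `ec50` (geometric mean,
#'   uM), `ci` (lower, upper), `log10_ec50` mean and SD, `extent_mean`,
#'   `extent_sem` and `n`.
#' @export
aggregate_log_ec50 <- function(fits, level = 0.95) {
  ok <- Filter(function(f) isTRUE(f$converged), fits)
  n <- length(ok)
  if (n < 2) {
    stop("aggregate_log_ec50: need >= 2 converged fits (got ", n, ")",
         call. = FALSE)
  }
  lec <- vapply(ok, function(f) log10(f$params[["EC50"]]), numeric(1))
  ext <- vapply(ok, function(f) f$params[["Extent"]], numeric(1))
  m <- mean(lec)
  s <- stats::sd(lec)
  half <- stats::qt(1 - (1 - level) / 2, df = n - 1) * s / sqrt(n)
  structure(
    list(ec50 = 10^m, ci = c(lower = 10^(m - half), upper = 10^(m + half)),
         level = level, log10_ec50_mean = m, log10_ec50_sd = s,
         extent_mean = if (all(is.na(ext))) NA_real_ else mean(ext),
         extent_sem = if (all(is.na(ext)) || n < 2) NA_real_ else
           stats::sd(ext) / sqrt(n),
         n = n),
    class = "hill_summary"
  )
}

#' @export
print.hill_summary <- function(x, ...) {
  cat(sprintf("EC50 %.4g uM [%.4g, %.4g] (%d%% CI on log10 EC50, n = %d)\n",
              x$ec50, x$ci[["lower"]], x$ci[["upper"]],
              round(100 * x$level), x$n))
  if (!is.na(x$extent_mean)) {
    cat(sprintf("Extent %.3g +/- %.3g (mean +/- SEM); plateau %.3g%% of control\n",
                x$extent_mean, x$extent_sem, 100 * (1 + x$extent_mean)))
  }
  invisible(x)
}

#' @export
summary.hill_fits <- function(object, level = 0.95, ...) {
  aggregate_log_ec50(object, level = level)
}

#' Paired fold shift in potency
#'
#' For paired control/treated Hill fits from the same replicates (e.g.
#' agonist EC50 with and without a modulator, measured in the same cell),
#' computes the per-pair potency ratio `control EC50 / treated EC50` and
#' summarizes it as the geometric mean of per-pair ratios. A ratio above 1
#' means the treatment increased potency (left-shifted the curve). Also
#' reports whether the two groups' log-EC50 confidence intervals overlap.
#'
#' @param control_fits,treated_fits `"hill_fits"` objects whose replicate ids
#'   pair one-to-one.
#' @param level Confidence level for the group CIs (default 0.95).
#' @return Object of class `"fold_shift"` with `fold` (geometric mean of
#'   per-pair ratios), `pair_ratios`, the two `"hill_summary"` objects and
#'   `ci_overlap`.
#' @export
fold_shift <- function(control_fits, treated_fits, level = 0.95) {
  cids <- vapply(control_fits, function(f) as.character(f$replicate_id),
                 character(1))
  tids <- vapply(treated_fits, function(f) as.character(f$replicate_id),
                 character(1))
  if (!setequal(cids, tids) || anyDuplicated(cids) || anyDuplicated(tids)) {
    stop("fold_shift: control and treated fits must pair one-to-one by ",
         "replicate_id", call. = FALSE)
  }
  treated_fits <- treated_fits[match(cids, tids)]
  keep <- vapply(seq_along(control_fits), function(i) {
    isTRUE(control_fits[[i]]$converged) && isTRUE(treated_fits[[i]]$converged)
  }, logical(1))
  if (sum(keep) < 2) {
    stop("fold_shift: need >= 2 converged pairs", call. = FALSE)
  }
  cf <- control_fits[keep]; tf <- treated_fits[keep]
  ratios <- vapply(seq_along(cf), function(i) {
    cf[[i]]$params[["EC50"]] / tf[[i]]$params[["EC50"]]
  }, numeric(1))
  names(ratios) <- vapply(cf, function(f) as.character(f$replicate_id),
                          character(1))
  sc <- aggregate_log_ec50(cf, level = level)
  st <- aggregate_log_ec50(tf, level = level)
  overlap <- sc$ci[["lower"]] <= st$ci[["upper"]] &&
    st$ci[["lower"]] <= sc$ci[["upper"]]
  structure(
    list(fold = exp(mean(log(ratios))), pair_ratios = ratios,
         control = sc, treated = st, ci_overlap = overlap, level = level),
    class = "fold_shift"
  )
}

#' @export
print.fold_shift <- function(x, ...) {
  cat(sprintf("Fold shift in potency: %.3g (geometric mean of %d paired ratios)\n",
              x$fold, length(x$pair_ratios)))
  cat(sprintf("  control EC50 %.4g uM, treated EC50 %.4g uM; group %d%% CIs %s\n",
              x$control$ec50, x$treated$ec50, round(100 * x$level),
              if (x$ci_overlap) "overlap" else "do NOT overlap"))
  invisible(x)
}
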