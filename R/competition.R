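#' Simulate NAM concentration-response curves across fixed PAM backgrounds
#'
#' For every PAM concentration in `pam_concs`, computes the equilibrium
#' response of the receptor scheme over the NAM concentrations in
#' `nam_concs`, normalizing each PAM level to its own NAM-free response.
#' This mirrors how a shifted IC50 (IC50') is measured experimentally: the
#' inhibitor curve is expressed relative to the response in the fixed PAM
#' background, not to the global control. The result is deterministic.
#'
#' @param scheme A [receptor_scheme()].
#' @param nam_concs,pam_concs Non-empty concentration vectors, uM.
#' @param agonist_conc Agonist concentration, uM (use a maximally effective
#'   concentration, default 100).
#' @return A CRC table (`data.frame`) with columns `replicate_id`,
#'   `condition` (label `PAM=<conc>`), `pam_conc_uM`, `concentration_uM`
#'   (the NAM axis) and `response` (fraction of the NAM-free response at the
#'   same PAM level).
#' @export
simulate_crc_grid <- function(scheme, nam_concs, pam_concs,
                              agonist_conc = 100) {
  stopifnot(inherits(scheme, "receptor_scheme"))
  if (!length(nam_concs) || !length(pam_concs)) {
    stop("simulate_crc_grid: concentration lists must be non-empty",
         call. = FALSE)
  }
  out <- list()
  for (p in pam_concs) {
    base <- tryCatch(
      equilibrium_response(scheme, agonist_conc, pam_conc = p, nam_conc = 0),
      error = function(e) stop("simulate_crc_grid: solver failed at PAM = ",
                               p, " uM, NAM = 0 uM: ", conditionMessage(e),
                               call. = FALSE))
    resp <- vapply(nam_concs, function(nc) {
      tryCatch(
        equilibrium_response(scheme, agonist_conc, pam_conc = p,
                             nam_conc = nc),
        error = function(e) stop("simulate_crc_grid: solver failed at PAM = ",
                                 p, " uM, NAM = ", nc, " uM: ",
                                 conditionMessage(e), call. = FALSE))
    }, numeric(1))
    out[[length(out) + 1L]] <- data.frame(
      replicate_id = 1L,
      condition = sprintf("PAM=%g", p),
      pam_conc_uM = p,
      concentration_uM = nam_concs,
      response = resp / base)
  }
  do.call(rbind, out)
}

#' Closed-form competitive (Gaddum) reference curves
#'
#' The analytic one-site competition reference: a full-block NAM and a
#' binding-only competitor at a single shared site give fractional response
#' `1 - occ_N` with `occ_N = n / (1 + n + p)` where `n = [N]/K_N` and
#' `p = [P]/K_P`. The shifted midpoint obeys the Gaddum/Schild relation
#' `IC50' = K_N (1 + [P]/K_P)`, so the dose ratio minus one is linear in
#' `[P]` with slope `1/K_P`. Used as the independent oracle for
#' [dose_ratio_analysis()].
#'
#' @param k_n,k_p Dissociation constants of the NAM and competitor, uM.
#' @param nam_concs,pam_concs Concentration grids, uM.
#' @return A CRC table in the same format as [simulate_crc_grid()].
#' @export
simulate_crc_gaddum <- function(k_n, k_p, nam_concs, pam_concs) {
  stopifnot(k_n > 0, k_p > 0)
  out <- list()
  for (p in pam_concs) {
    pp <- p / k_p
    resp <- (1 + pp) / (1 + nam_concs / k_n + pp)
    out[[length(out) + 1L]] <- data.frame(
      replicate_id = 1L,
      condition = sprintf("PAM=%g", p),
      pam_conc_uM = p,
      concentration_uM = nam_concs,
      response = resp)
  }
  do.call(rbind, out)
}

#' Dose-ratio (Schild-type) analysis of modulator competition
#'
#' Discriminates a shared, mutually exclusive modulator site from
#' independent sites. The NAM IC50 is fitted per PAM level
#' ([fit_hill()], modulator form); the dose ratio is `IC50'/IC50` against
#' the PAM-free baseline; `(dose ratio - 1)` is regressed on `[PAM]` by
#' ordinary least squares. Competition at a single site produces a linear
#' relation through the origin with slope `1/K_P` (the Gaddum relation),
#' whereas independent, non-interacting sites leave the NAM curve in place
#' and the ratios pinned near 1.
#'
#' Verdicts: if the largest `|dose ratio - 1|` is within `flat_tol` the
#' verdict is `INDEPENDENT_SITES`; otherwise, if the regression has
#' `R^2 >= r2_threshold` and a slope confidence interval excluding zero, it
#' is `SHARED_SITE`; anything else is `INDETERMINATE`. The spread of fitted
#' Hill slopes across PAM levels is reported as a parallel-shift diagnostic
#' but does not gate the verdict.
#'
#' @param crc CRC table with columns `pam_conc_uM`, `concentration_uM`,
#'   `response`, `replicate_id` (from [simulate_crc_grid()],
#'   [simulate_crc_gaddum()] or experiment). Needs `>= 3` PAM levels
#'   including 0.
#' @param r2_threshold Minimum regression R-squared for a shared-site call
#'   (default 0.98).
#' @param flat_tol Maximum `|dose ratio - 1|` for an independent-sites call
#'   (default 0.10).
#' @param fix_h Optional fixed Hill slope for the per-level fits.
#' @return Object of class `"dose_ratio"`: per-level IC50', dose ratios,
#'   regression `slope` (1/uM), `intercept`, `r_squared`, `slope_ci`,
#'   `verdict` and the Hill-slope diagnostic.
#' @export
dose_ratio_analysis <- function(crc, r2_threshold = 0.98, flat_tol = 0.10,
                                fix_h = NULL) {
  if (!all(c("pam_conc_uM", "concentration_uM", "response") %in% names(crc))) {
    stop("dose_ratio_analysis: crc needs columns pam_conc_uM, ",
         "concentration_uM, response", call. = FALSE)
  }
  levels_p <- sort(unique(crc$pam_conc_uM))
  if (length(levels_p) < 3 || !any(levels_p == 0)) {
    stop("dose_ratio_analysis: need >= 3 PAM levels including 0",
         call. = FALSE)
  }
  per_level <- lapply(levels_p, function(p) {
    d <- crc[crc$pam_conc_uM == p, ]
    d$replicate_id <- 1L   # pooled fit per level
    # each level is expressed relative to its own NAM-free response, so the
    # analysis is invariant to uniform rescaling of the response axis
    zero <- d$concentration_uM == 0
    if (any(zero)) {
      d$response <- d$response / mean(d$response[zero])
      d <- d[!zero, , drop = FALSE]
    }
    fits <- fit_hill(d[, c("replicate_id", "concentration_uM", "response")],
                     form = "modulator", fix_h = fix_h, probe_conc = NULL)
    f <- fits[[1]]
    if (!f$converged) {
      stop("dose_ratio_analysis: concentration-response curve at PAM = ", p,
           " uM could not be fitted (", f$reason, ")", call. = FALSE)
    }
    f
  })
  ic50 <- vapply(per_level, function(f) f$params[["EC50"]], numeric(1))
  hvals <- vapply(per_level, function(f) f$params[["h"]], numeric(1))
  baseline <- ic50[levels_p == 0]
  ratio <- ic50 / baseline
  fm <- stats::lm(I(ratio - 1) ~ levels_p)
  slope <- unname(stats::coef(fm)[2])
  intercept <- unname(stats::coef(fm)[1])
  tss <- sum((ratio - mean(ratio))^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fm)^2) / tss else 1
  ci <- tryCatch(suppressWarnings(stats::confint(fm, "levels_p", 0.95)),
                 error = function(e) matrix(c(NA, NA), 1))
  slope_ci <- c(lower = ci[1, 1], upper = ci[1, 2])

  verdict <- if (max(abs(ratio - 1)) <= flat_tol) {
    "INDEPENDENT_SITES"
  } else if (is.finite(r2) && r2 >= r2_threshold &&
             all(is.finite(slope_ci)) && slope_ci[["lower"]] > 0) {
    "SHARED_SITE"
  } else {
    "INDETERMINATE"
  }
  structure(
    list(pam_concentrations = levels_p, ic50_prime = ic50,
         baseline_ic50 = baseline, dose_ratios = ratio,
         slope = slope, intercept = intercept, slope_ci = slope_ci,
         r_squared = r2, verdict = verdict,
         hill_slopes = hvals,
         hill_slope_spread = diff(range(hvals)),
         thresholds = c(r2 = r2_threshold, flat = flat_tol)),
    class = "dose_ratio"
  )
}

#' @export
print.dose_ratio <- function(x, ...) {
  cat("Dose-ratio analysis of modulator competition\n")
  tab <- data.frame(pam_uM = x$pam_concentrations,
                    ic50_prime_uM = signif(x$ic50_prime, 4),
                    dose_ratio = signif(x$dose_ratios, 4),
                    hill_slope = signif(x$hill_slopes, 3))
  print(tab, row.names = FALSE)
  cat(sprintf("(ratio - 1) vs [PAM]: slope %.4g /uM [%.4g, %.4g], intercept %.4g, R^2 %.4f\n",
              x$slope, x$slope_ci[["lower"]], x$slope_ci[["upper"]],
              x$intercept, x$r_squared))
  cat("Verdict:", x$verdict, "\n")
  invisible(x)
}

#' Independent-action prediction for co-applied modulators
#'
#' If two modulators act at independent sites with no interaction, the
#' response to their co-application (as percent of control) is predicted by
#' multiplying the extents of their independent actions:
#' `predicted = a * b / 100`. Deviation of the observed combination from
#' this null is evidence for interacting (e.g. shared) sites.
#'
#' @param modulation_a,modulation_b Independent modulations, percent of
#'   control (100 = no effect). Must be `>= 0`.
#' @return Predicted combined modulation, percent of control.
#' @examples
#' predict_independent_action(14, 230)   # 32.2% of control
#' @export
predict_independent_action <- function(modulation_a, modulation_b) {
  if (any(modulation_a < 0) || any(modulation_b < 0)) {
    stop("predict_independent_action: modulations must be >= 0 (percent of ",
         "control)", call. = FALSE)
  }
  modulation_a * modulation_b / 100
}

#' Compare observed combination responses with the independent-action null
#'
#' Paired comparison of per-replicate observed co-application responses with
#' their predicted independent-action values (a scalar prediction is
#' recycled). Reports the mean difference and a paired two-sided t test.
#' When the differences have zero variance the result is reported as
#' "no detectable difference" instead of a numeric p value.
#'
#' @param observed Per-replicate observed combined modulation, percent of
#'   control (`n >= 2`).
#' @param predicted Predicted combined modulation(s), percent of control;
#'   scalar or one per replicate.
#' @return Object of class `"combination_test"` with `mean_difference`,
#'   `statistic`, `df`, `p_value` and `no_detectable_difference`.
#' @export
compare_combination <- function(observed, predicted) {
  n <- length(observed)
  if (n < 2) stop("compare_combination: need >= 2 replicates", call. = FALSE)
  if (length(predicted) == 1L) predicted <- rep(predicted, n)
  if (length(predicted) != n) {
    stop("compare_combination: predicted must be scalar or match observed",
         call. = FALSE)
  }
  d <- observed - predicted
  md <- mean(d)
  if (stats::sd(d) == 0) {
    res <- list(mean_difference = md, statistic = if (md == 0) 0 else NA_real_,
                df = n - 1L, p_value = NA_real_,
                no_detectable_difference = md == 0, n = n)
  } else {
    tt <- stats::t.test(d)
    res <- list(mean_difference = md,
                statistic = unname(tt$statistic),
                df = unname(tt$parameter),
                p_value = tt$p.value,
                no_detectable_difference = FALSE, n = n)
  }
  structure(res, class = "combination_test")
}

#' @export
print.combination_test <- function(x, ...) {
  cat(sprintf("Observed vs independent-action prediction (n = %d pairs)\n",
              x$n))
  if (x$no_detectable_difference) {
    cat("  mean difference 0: no detectable difference\n")
  } else if (is.na(x$p_value)) {
    cat(sprintf("  mean difference %.4g%% with zero-variance differences\n",
                x$mean_difference))
  } else {
    cat(sprintf("  mean difference %.4g%%, paired t = %.4g (df = %d), p = %.3g\n",
                x$mean_difference, x$statistic, x$df, x$p_value))
  }
  invisible(x)
}
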