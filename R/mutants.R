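#' Normalize a mutant panel to per-replicate agonist-only controls
#'
#' Converts raw paired measurements (response in the presence of a fixed
#' modulator concentration, and the same cell's agonist-only response) into
#' percent-of-control values, the form in which mutant panels are compared
#' against wild type. Normalization is per replicate, so any common scaling
#' of both raw columns (expression level, day effects) cancels.
#'
#' @param raw Data frame with columns `construct`, `replicate_id`,
#'   `response_modulator` and `response_control` (same units).
#' @return A `"mutant_panel"` data frame with columns `construct`,
#'   `replicate_id` and `percent_of_control`.
#' @export
normalize_panel <- function(raw) {
  need <- c("construct", "replicate_id", "response_modulator",
            "response_control")
  if (!is.data.frame(raw) || !all(need %in% names(raw))) {
    stop("normalize_panel: raw needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!is.finite(raw$response_control) | raw$response_control <= 0)
  if (length(bad)) {
    stop("normalize_panel: non-positive agonist-only control for replicate(s) ",
         paste(sprintf("%s/%s", raw$construct[bad], raw$replicate_id[bad]),
               collapse = ", "), call. = FALSE)
  }
  out <- data.frame(
    construct = raw$construct,
    replicate_id = raw$replicate_id,
    percent_of_control = 100 * raw$response_modulator / raw$response_control)
  class(out) <- c("mutant_panel", "data.frame")
  out
}

.panel_ci <- function(x, level) {
  n <- length(x)
  m <- mean(x)
  half <- stats::qt(1 - (1 - level) / 2, df = n - 1) * stats::sd(x) / sqrt(n)
  c(mean = m, lower = m - half, upper = m + half, n = n)
}

#' Classify a mutant's modulator sensitivity against wild type
#'
#' Compares a mutant construct's modulated response (percent of its own
#' agonist-only control) with the wild type using t-based confidence
#' intervals at `level` (default 99 percent, the convention for mutant-panel
#' screens). Overlapping intervals give `UNCHANGED`. For non-overlapping
#' intervals the category depends on where the mutant mean lies relative to
#' the 100 percent line (no modulation) and the wild-type mean: on the
#' wild-type side but closer to 100 is `LOSS` (modulation attenuated),
#' farther from 100 is `AUGMENTED` (modulation strengthened), and on the
#' opposite side of 100 is `INVERTED` (a NAM acting as a PAM or vice versa).
#'
#' @param panel A `"mutant_panel"` (see [normalize_panel()]), or any data
#'   frame with columns `construct` and `percent_of_control`.
#' @param construct Label of the mutant to classify.
#' @param wild_type Label of the wild-type construct (default `"WT"`).
#' @param level Confidence level (default 0.99).
#' @return Object of class `"mutant_classification"` with `category`,
#'   mutant and wild-type means and CI bounds.
#' @seealso [classify_panel()] to classify every construct at once.
#' @export
classify_mutant <- function(panel, construct, wild_type = "WT",
                            level = 0.99) {
  if (!all(c("construct", "percent_of_control") %in% names(panel))) {
    stop("classify_mutant: panel needs columns construct, percent_of_control",
         call. = FALSE)
  }
  mu <- panel$percent_of_control[panel$construct == construct]
  wt <- panel$percent_of_control[panel$construct == wild_type]
  if (length(wt) < 2) {
    stop("classify_mutant: wild-type construct '", wild_type,
         "' needs n >= 2", call. = FALSE)
  }
  if (length(mu) < 2) {
    stop("classify_mutant: construct '", construct, "' needs n >= 2",
         call. = FALSE)
  }
  ci_m <- .panel_ci(mu, level)
  ci_w <- .panel_ci(wt, level)
  overlap <- ci_m[["lower"]] <= ci_w[["upper"]] &&
    ci_w[["lower"]] <= ci_m[["upper"]]
  category <- if (overlap) {
    "UNCHANGED"
  } else {
    wt_side <- sign(ci_w[["mean"]] - 100)
    mu_side <- sign(ci_m[["mean"]] - 100)
    if (wt_side == 0) {
      # wild type shows no modulation; any departure is a gain of effect
      "AUGMENTED"
    } else if (mu_side == -wt_side) {
      "INVERTED"
    } else if (abs(ci_m[["mean"]] - 100) < abs(ci_w[["mean"]] - 100)) {
      "LOSS"
    } else {
      "AUGMENTED"
    }
  }
  structure(
    list(construct = construct, wild_type = wild_type, category = category,
         level = level,
         mutant_mean = ci_m[["mean"]],
         mutant_ci = c(lower = ci_m[["lower"]], upper = ci_m[["upper"]]),
         mutant_n = ci_m[["n"]],
         wild_type_mean = ci_w[["mean"]],
         wild_type_ci = c(lower = ci_w[["lower"]], upper = ci_w[["upper"]]),
         wild_type_n = ci_w[["n"]]),
    class = "mutant_classification"
  )
}

#' @export
print.mutant_classification <- function(x, ...) {
  cat(sprintf("%s vs %s: %s\n", x$construct, x$wild_type, x$category))
  cat(sprintf("  mutant    %.4g%% [%.4g, %.4g] (n = %d)\n", x$mutant_mean,
              x$mutant_ci[["lower"]], x$mutant_ci[["upper"]], x$mutant_n))
  cat(sprintf("  wild type %.4g%% [%.4g, %.4g] (n = %d), %d%% CIs\n",
              x$wild_type_mean, x$wild_type_ci[["lower"]],
              x$wild_type_ci[["upper"]], x$wild_type_n,
              round(100 * x$level)))
  invisible(x)
}

#' Classify every construct in a mutant panel
#'
#' Applies [classify_mutant()] to each non-wild-type construct in the panel
#' and returns a tidy classification report.
#'
#' @inheritParams classify_mutant
#' @return Data frame with one row per construct: `construct`, `category`,
#'   means, CI bounds and n for mutant and wild type.
#' @export
classify_panel <- function(panel, wild_type = "WT", level = 0.99) {
  constructs <- setdiff(unique(panel$construct), wild_type)
  rows <- lapply(constructs, function(cn) {
    cl <- classify_mutant(panel, cn, wild_type = wild_type, level = level)
    data.frame(construct = cn, category = cl$category,
               mean = cl$mutant_mean,
               ci_lower = cl$mutant_ci[["lower"]],
               ci_upper = cl$mutant_ci[["upper"]],
               n = cl$mutant_n,
               wt_mean = cl$wild_type_mean,
               wt_ci_lower = cl$wild_type_ci[["lower"]],
               wt_ci_upper = cl$wild_type_ci[["upper"]],
               wt_n = cl$wild_type_n)
  })
  do.call(rbind, rows)
}
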