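#' Read a validated delimited table
#'
#' Reads a comma-separated, UTF-8, header-row table and validates it against
#' a column schema. Decimal separator is the period only: cells like
#' `"1,5"` in a numeric column are rejected with the offending row and
#' column named, as is any missing column.
#'
#' @param path File path.
#' @param schema Named character vector mapping required column names to
#'   types (`"numeric"`, `"integer"` or `"character"`). Extra columns are
#'   kept as read.
#' @return A data frame.
#' @export
read_table <- function(path, schema) {
  if (!file.exists(path)) stop("read_table: no such file: ", path,
                               call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE,
                        fileEncoding = "UTF-8")
  missing_cols <- setdiff(names(schema), names(df))
  if (length(missing_cols)) {
    stop("read_table: missing column(s) ", paste(missing_cols, collapse = ", "),
         " in ", path, call. = FALSE)
  }
  for (col in names(schema)) {
    type <- schema[[col]]
    if (type %in% c("numeric", "integer")) {
      raw <- df[[col]]
      conv <- suppressWarnings(as.numeric(raw))
      bad <- which(is.na(conv) & !(is.na(raw) | raw == "" | raw == "NA"))
      if (length(bad)) {
        stop("read_table: non-numeric value '", raw[bad[1]], "' at row ",
             bad[1], ", column '", col, "' in ", path, call. = FALSE)
      }
      df[[col]] <- if (type == "integer") as.integer(conv) else conv
    }
  }
  df
}

#' Write a delimited table at full numeric precision
#'
#' Writes a comma-separated, UTF-8 table with a header row, formatting
#' numeric columns with 17 significant digits so a write-read round trip is
#' lossless for doubles.
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_table <- function(df, path) {
  out <- df
  for (col in names(out)) {
    if (is.double(out[[col]])) {
      out[[col]] <- sprintf("%.17g", out[[col]])
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Default model configuration
#'
#' The documented default parameterization of the receptor scheme and
#' modulators as a nested list, suitable for serialization to YAML and for
#' round-tripping through [scheme_from_config()].
#'
#' @param topology `"MODEL1"` or `"MODEL2"`.
#' @return Nested list with a `schema_version` field.
#' @export
default_config <- function(topology = "MODEL1") {
  list(
    schema_version = 1L,
    topology = topology,
    agonist = list(k_on = 10, k_off = 50),
    gate = list(beta = 5, alpha = 500),
    n_agonist_sites = 2L,
    modulators = list(
      list(name = "N", role = "NAM", k_on = 1, k_off_reference = 0.2,
           gating_factor = 0.14, state_dependence_factor = 100),
      list(name = "P", role = "PAM", k_on = 1, k_off_reference = 2,
           gating_factor = 2.5, state_dependence_factor = 100)
    )
  )
}

#' Write the default configuration as YAML
#'
#' @param path Output path (default `"allomod-config.yaml"`).
#' @param topology `"MODEL1"` or `"MODEL2"`.
#' @return Invisibly, `path`.
#' @export
dump_default_config <- function(path = "allomod-config.yaml",
                                topology = "MODEL1") {
  writeLines(yaml::as.yaml(default_config(topology)), path)
  invisible(path)
}

#' Build a receptor scheme from a configuration list or YAML file
#'
#' @param config A nested configuration list (see [default_config()]) or the
#'   path of a YAML file containing one.
#' @return A [receptor_scheme()].
#' @export
scheme_from_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config) || is.null(config$topology)) {
    stop("scheme_from_config: config must name a topology", call. = FALSE)
  }
  if (!identical(as.integer(config$schema_version %||% 1L), 1L)) {
    stop("scheme_from_config: unsupported schema_version ",
         config$schema_version, call. = FALSE)
  }
  pam <- nam <- NULL
  for (m in config$modulators %||% list()) {
    spec <- modulator_spec(m$name, m$role, m$k_on, m$k_off_reference,
                           m$gating_factor %||% 1,
                           m$state_dependence_factor %||% 100)
    if (spec$role == "PAM") {
      if (!is.null(pam)) stop("scheme_from_config: more than one PAM",
                              call. = FALSE)
      pam <- spec
    } else {
      if (!is.null(nam)) stop("scheme_from_config: more than one NAM",
                              call. = FALSE)
      nam <- spec
    }
  }
  receptor_scheme(
    topology = config$topology,
    agonist_on = config$agonist$k_on %||% 10,
    agonist_off = config$agonist$k_off %||% 50,
    beta = config$gate$beta %||% 5,
    alpha = config$gate$alpha %||% 500,
    pam = pam, nam = nam,
    n_agonist_sites = config$n_agonist_sites %||% 2L
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.provenance <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  # the hash covers the scientific configuration, not where outputs land
  cfg <- config[setdiff(names(config), "outdir")]
  saveRDS(cfg[order(names(cfg))], tf)
  list(package = "allomod",
       version = as.character(utils::packageVersion("allomod")),
       config_md5 = unname(tools::md5sum(tf)),
       seed = config$seed %||% NA)
}

#' Run one pipeline stage from a configuration
#'
#' Executes exactly one analysis stage described by a configuration list and
#' writes its outputs (delimited tables and/or a JSON report carrying a
#' provenance record with a config hash and the seed) into `config$outdir`.
#' Rerunning with an identical configuration and seed reproduces the outputs
#' byte-identically. On failure, partial outputs are removed and an error is
#' raised.
#'
#' Stages: `"generate-crc"` (fields `truth`, `design`, `n_replicates`,
#' `noise`, `noise_scale`, `seed`), `"fit-hill"` (`input` CSV path, `form`,
#' optional `fix_h`), `"simulate-crc"` (`scheme` config or YAML path,
#' `nam_concs`, `pam_concs`, `agonist_conc`), `"dose-ratio"` (`input` CSV
#' path or `scheme` + grids), `"predict-combo"` (`modulation_a`,
#' `modulation_b`, optional `observed`), `"classify-mutants"` (`input` CSV
#' with construct/replicate_id/percent_of_control, `wild_type`, `level`),
#' `"dump-default-config"`.
#'
#' @param config Named list with at least `stage` and `outdir`.
#' @return Invisibly, a character vector of the files written.
#' @export
run <- function(config) {
  if (!is.list(config) || is.null(config$stage) || is.null(config$outdir)) {
    stop("run: config must be a list with 'stage' and 'outdir'", call. = FALSE)
  }
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(name, writer) {
    p <- file.path(config$outdir, name)
    writer(p)
    written <<- c(written, p)
    p
  }
  # YAML sequences of mixed int/real arrive as lists; flatten numeric fields
  for (fld in c("nam_concs", "pam_concs", "design", "observed")) {
    if (!is.null(config[[fld]])) config[[fld]] <- as.numeric(unlist(config[[fld]]))
  }
  ok <- FALSE
  on.exit(if (!ok) unlink(written), add = TRUE)
  prov <- .provenance(config)
  report <- list(stage = config$stage, provenance = prov)

  switch(
    config$stage,
    "generate-crc" = {
      crc <- generate_crc(truth = config$truth,
                          concentrations = config$design %||% c(0.3, 1, 3, 10, 30),
                          n_replicates = config$n_replicates %||% 8,
                          form = config$form %||% "modulator",
                          noise = config$noise %||% "multiplicative-lognormal",
                          noise_scale = config$noise_scale %||% 0.05,
                          seed = config$seed)
      emit("crc.csv", function(p) write_table(crc, p))
      report$truth <- config$truth
    },
    "fit-hill" = {
      crc <- read_table(config$input,
                        c(replicate_id = "character",
                          concentration_uM = "numeric",
                          response = "numeric"))
      fits <- fit_hill(crc, form = config$form %||% "modulator",
                       fix_h = config$fix_h)
      est <- as.data.frame(coef(fits))
      est$replicate_id <- rownames(est)
      est$converged <- vapply(fits, function(f) f$converged, logical(1))
      emit("hill-fits.csv", function(p) write_table(est, p))
      if (sum(est$converged) >= 2) {
        s <- aggregate_log_ec50(fits)
        report$summary <- list(ec50_uM = s$ec50, ci = unname(s$ci),
                               extent_mean = s$extent_mean, n = s$n)
      }
    },
    "simulate-crc" = {
      sch <- scheme_from_config(config$scheme)
      crc <- simulate_crc_grid(sch, config$nam_concs, config$pam_concs,
                               config$agonist_conc %||% 100)
      emit("crc-grid.csv", function(p) write_table(crc, p))
    },
    "dose-ratio" = {
      crc <- if (!is.null(config$input)) {
        read_table(config$input,
                   c(pam_conc_uM = "numeric", concentration_uM = "numeric",
                     response = "numeric"))
      } else {
        sch <- scheme_from_config(config$scheme)
        simulate_crc_grid(sch, config$nam_concs, config$pam_concs,
                          config$agonist_conc %||% 100)
      }
      dr <- dose_ratio_analysis(crc,
                                r2_threshold = config$r2_threshold %||% 0.98,
                                flat_tol = config$flat_tol %||% 0.10)
      report$result <- list(
        verdict = dr$verdict, slope_per_uM = dr$slope,
        intercept = dr$intercept, r_squared = dr$r_squared,
        pam_concentrations = dr$pam_concentrations,
        ic50_prime_uM = dr$ic50_prime, dose_ratios = dr$dose_ratios,
        thresholds = as.list(dr$thresholds))
    },
    "predict-combo" = {
      pred <- predict_independent_action(config$modulation_a,
                                         config$modulation_b)
      report$result <- list(predicted_percent = pred)
      if (!is.null(config$observed)) {
        ct <- compare_combination(config$observed, pred)
        report$result$mean_difference <- ct$mean_difference
        report$result$statistic <- ct$statistic
        report$result$p_value <- ct$p_value
      }
    },
    "classify-mutants" = {
      panel <- read_table(config$input,
                          c(construct = "character",
                            percent_of_control = "numeric"))
      cls <- classify_panel(panel, wild_type = config$wild_type %||% "WT",
                            level = config$level %||% 0.99)
      emit("classification.csv", function(p) write_table(cls, p))
      report$result <- list(categories = stats::setNames(cls$category,
                                                         cls$construct))
    },
    "dump-default-config" = {
      emit("allomod-config.yaml", function(p) {
        dump_default_config(p, topology = config$topology %||% "MODEL1")
      })
    },
    stop("run: unknown stage '", config$stage, "'", call. = FALSE)
  )
  emit("report.json", function(p) {
    jsonlite::write_json(report, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  })
  ok <- TRUE
  invisible(written)
}
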