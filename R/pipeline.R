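# Config-driven orchestration: harmonize -> meta-analyse -> IVW -> scale ->
# screen -> sensitivity rerun, one pass per configured exposure, producing
# publication-style report tables (a per-SD OR main table, a
# post-exclusion sensitivity table, and a per-SNP screen block).

#' Validate a pipeline run configuration
#'
#' Accepts a YAML/JSON file path or an equivalent list. All validation
#' errors are collected and reported together, not fail-fast.
#'
#' Expected structure:
#' \preformatted{
#' seed: 1                      # optional
#' output_dir: results/         # optional; no files written when absent
#' palindromic_policy: trust    # or strict
#' outcome_tables: [outcomes_uk.tsv, outcomes_aus.tsv]
#' exposures:
#'   - name: fasting_insulin
#'     sd: 0.60
#'     binary: false            # binary exposures require sd == 1
#'     instrument_file: fi_instruments.tsv
#'     exclude: [FTO]           # optional rsIDs / locus labels
#' }
#'
#' @param config a file path or a list.
#' @return a validated config of class `mr_run_config`.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop("config file not found: ", config, call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a file path",
                             call. = FALSE)

  errors <- character()
  known <- c("seed", "output_dir", "palindromic_policy", "outcome_tables",
             "exposures")
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0) {
    errors <- c(errors, paste0("unknown config key(s): ",
                               paste(unknown, collapse = ", ")))
  }

  if (is.null(config$palindromic_policy)) config$palindromic_policy <- "trust"
  if (!config$palindromic_policy %in% c("trust", "strict")) {
    errors <- c(errors, "palindromic_policy must be 'trust' or 'strict'")
  }
  if (!is.null(config$seed) &&
      (!is_number(config$seed) || config$seed != round(config$seed))) {
    errors <- c(errors, "seed must be an integer")
  }

  if (is.null(config$outcome_tables) || length(config$outcome_tables) == 0) {
    errors <- c(errors, "outcome_tables must list at least one file")
  } else {
    for (p in config$outcome_tables) {
      if (!file.exists(p)) errors <- c(errors,
                                       paste0("outcome table not found: ", p))
    }
  }

  if (is.null(config$exposures) || length(config$exposures) == 0) {
    errors <- c(errors, "exposures must list at least one entry")
  } else {
    nms <- vapply(config$exposures, function(e) e$name %||% NA_character_,
                  character(1))
    if (anyNA(nms)) errors <- c(errors, "every exposure needs a name")
    if (anyDuplicated(nms[!is.na(nms)])) {
      errors <- c(errors, "exposure names must be unique")
    }
    for (e in config$exposures) {
      id <- e$name %||% "(unnamed)"
      if (is.null(e$sd) || !is_number(e$sd) || e$sd <= 0) {
        errors <- c(errors, paste0("exposure ", id, ": sd must be > 0"))
      }
      if (isTRUE(e$binary) && !is.null(e$sd) && is_number(e$sd) && e$sd != 1) {
        errors <- c(errors,
                    paste0("exposure ", id,
                           ": binary exposures must have sd = 1 (log-odds scale)"))
      }
      if (is.null(e$instrument_file)) {
        errors <- c(errors, paste0("exposure ", id, ": instrument_file missing"))
      } else if (!file.exists(e$instrument_file)) {
        errors <- c(errors, paste0("exposure ", id,
                                   ": instrument file not found: ",
                                   e$instrument_file))
      }
    }
  }

  stop_if_errors(errors, "invalid pipeline configuration")
  structure(config, class = "mr_run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small stable content hash (31-base polynomial rolling hash over the
# deparsed config) for the run manifest; avoids a digest dependency.
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full MR pipeline from a configuration
#'
#' For each configured exposure: read and validate its instrument table,
#' apply a-priori exclusions, harmonize against the (meta-analysed when
#' multi-cohort) outcome associations, compute the IVW estimate scaled to a
#' per-SD odds ratio, screen individual SNPs at the Bonferroni threshold
#' 0.05 / n_snps, and rerun excluding any flagged SNPs with leave-one-out
#' diagnostics. Deterministic given the config and input tables.
#'
#' When `output_dir` is set, writes `main_table.tsv` (one row per exposure),
#' `sensitivity_table.tsv`, `snp_screen.tsv`, per-exposure
#' `scatter_<name>.tsv` and `leave_one_out_<name>.tsv`, and a JSON-lines
#' run manifest `manifest.jsonl`.
#'
#' @param config an `mr_run_config`, list, or config file path (validated
#'   via [validate_config()]).
#' @return an object of class `mr_analysis_report`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "mr_run_config")) config <- validate_config(config)

  outcomes <- do.call(rbind, lapply(config$outcome_tables, read_outcome_table))
  cohorts <- unique(outcomes$cohort)
  outcome_use <- if (length(cohorts) > 1) {
    meta_outcome_tables(outcomes)
  } else {
    outcomes
  }
  use_cohort <- unique(outcome_use$cohort)

  main_rows <- list()
  sens_rows <- list()
  screen_blocks <- list()
  scatter_blocks <- list()
  loo_blocks <- list()
  sens_reports <- list()

  for (e in config$exposures) {
    spec <- exposure_spec(e$name, e$sd, isTRUE(e$binary))
    instruments <- read_instrument_table(e$instrument_file)
    if (length(e$exclude %||% character()) > 0) {
      instruments <- exclude_variants(instruments, unlist(e$exclude))
    }
    h <- harmonize(instruments, outcome_use, cohort = use_cohort,
                   palindromic = config$palindromic_policy)
    est <- mr_ivw(h, spec)
    n_used <- est$n_snps

    alpha <- bonferroni_alpha(n_used)
    screen <- screen_snps(h, alpha)
    screen$exposure <- e$name
    flagged <- screen$rsid[screen$flagged]

    sens <- rerun_excluding(instruments, outcome_use, flagged, spec,
                            cohort = use_cohort,
                            palindromic = config$palindromic_policy)
    sens_reports[[e$name]] <- sens

    main_rows[[e$name]] <- data.frame(
      exposure = e$name, sd_scale = spec$sd_scale, n_snps = n_used,
      beta = est$beta, se = est$se, or_per_sd = est$or_per_sd,
      ci_low = est$ci_low, ci_high = est$ci_high, pvalue = est$pvalue,
      stringsAsFactors = FALSE
    )
    if (length(flagged) > 0) {
      r <- sens$rerun
      sens_rows[[e$name]] <- data.frame(
        exposure = e$name, sd_scale = spec$sd_scale,
        excluded = paste(flagged, collapse = ","), n_snps = r$n_snps,
        beta = r$beta, se = r$se, or_per_sd = r$or_per_sd,
        ci_low = r$ci_low, ci_high = r$ci_high, pvalue = r$pvalue,
        stringsAsFactors = FALSE
      )
    }
    screen_blocks[[e$name]] <- screen
    scatter_blocks[[e$name]] <- scatter_data(h)
    if (!is.null(sens$leave_one_out)) loo_blocks[[e$name]] <- sens$leave_one_out
  }

  report <- structure(list(
    main_table = do.call(rbind, c(main_rows, list(make.row.names = FALSE))),
    sensitivity_table = if (length(sens_rows)) {
      do.call(rbind, c(sens_rows, list(make.row.names = FALSE)))
    } else {
      NULL
    },
    snp_screen = do.call(rbind, c(screen_blocks, list(make.row.names = FALSE))),
    scatter = scatter_blocks,
    leave_one_out = loo_blocks,
    sensitivity_reports = sens_reports,
    config = config,
    config_hash = config_hash(unclass(config))
  ), class = "mr_analysis_report")

  if (!is.null(config$output_dir)) {
    write_report(report, config$output_dir)
  }
  report
}

write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv_file(report$main_table, file.path(dir, "main_table.tsv"))
  if (!is.null(report$sensitivity_table)) {
    write_tsv_file(report$sensitivity_table,
                   file.path(dir, "sensitivity_table.tsv"))
  }
  write_tsv_file(report$snp_screen, file.path(dir, "snp_screen.tsv"))
  for (nm in names(report$scatter)) {
    write_tsv_file(report$scatter[[nm]],
                   file.path(dir, paste0("scatter_", nm, ".tsv")))
  }
  for (nm in names(report$leave_one_out)) {
    write_tsv_file(report$leave_one_out[[nm]],
                   file.path(dir, paste0("leave_one_out_", nm, ".tsv")))
  }
  manifest <- file.path(dir, "manifest.jsonl")
  lines <- c(
    jsonlite::toJSON(list(event = "run", config_hash = report$config_hash,
                          package_version =
                            as.character(utils::packageVersion("mrivw")),
                          r_version = R.version.string,
                          timestamp = format(Sys.time(), tz = "UTC")),
               auto_unbox = TRUE),
    vapply(seq_len(nrow(report$main_table)), function(i) {
      row <- report$main_table[i, ]
      as.character(jsonlite::toJSON(as.list(row), auto_unbox = TRUE,
                                    digits = NA))
    }, character(1))
  )
  writeLines(lines, manifest)
  invisible(dir)
}

#' @export
print.mr_analysis_report <- function(x, ...) {
  cat("Associations per genetically predicted SD increase of each exposure\n")
  m <- x$main_table
  for (i in seq_len(nrow(m))) {
    cat(sprintf("  %-22s SD %-5g n=%2d  OR %s (%s to %s)  P = %s\n",
                m$exposure[i], m$sd_scale[i], m$n_snps[i],
                format_or(m$or_per_sd[i]), format_or(m$ci_low[i]),
                format_or(m$ci_high[i]), format_pvalue(m$pvalue[i])))
  }
  n_flag <- sum(x$snp_screen$flagged)
  cat(n_flag, "SNP(s) exceeded the Bonferroni screen threshold\n")
  if (!is.null(x$sensitivity_table)) {
    cat("Post-exclusion sensitivity estimates:\n")
    s <- x$sensitivity_table
    for (i in seq_len(nrow(s))) {
      cat(sprintf("  %-22s minus {%s}: OR %s (%s to %s)  P = %s\n",
                  s$exposure[i], s$excluded[i], format_or(s$or_per_sd[i]),
                  format_or(s$ci_low[i]), format_or(s$ci_high[i]),
                  format_pvalue(s$pvalue[i])))
    }
  }
  invisible(x)
}
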