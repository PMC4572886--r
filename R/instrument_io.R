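# Reading, validation, allele harmonization, QC filtering and subsetting of
# the summary-statistic tables every downstream stage consumes.
#
# Instrument tables carry per-SNP effects on an exposure (gamma_j, se);
# outcome tables carry per-SNP log odds ratios on disease (Gamma_j, se) for
# one or more cohorts. Both are plain TSV with a header row; '#' lines are
# ignored.

PALINDROMIC_PAIRS <- c("A/T", "T/A", "C/G", "G/C")

allele_pair <- function(a, b) paste(a, b, sep = "/")

validate_alleles <- function(df, errors) {
  for (col in c("effect_allele", "other_allele")) {
    bad <- which(!(df[[col]] %in% VALID_ALLELES))
    for (i in bad) {
      errors <- c(errors, sprintf("row %d: %s '%s' is not one of A/C/G/T",
                                  i, col, df[[col]][i]))
    }
  }
  same <- which(df$effect_allele == df$other_allele)
  for (i in same) {
    errors <- c(errors, sprintf("row %d: effect and other allele are both '%s'",
                                i, df$effect_allele[i]))
  }
  errors
}

#' Read an instrument table (per-SNP effects on an exposure)
#'
#' Expects columns `rsid`, `effect_allele`, `other_allele`, `beta_exposure`
#' (per-effect-allele effect in native exposure units), `se_exposure`, and
#' optionally `locus_label` (gene/locus tag used by exclusion rules).
#'
#' @param path path to a TSV file. Lines starting with `#` are ignored.
#' @return a data.frame of validated instrument records, row order preserved.
#' @export
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("rsid\teffect_allele\tother_allele\tbeta_exposure\tse_exposure",
#'              "rs1\tA\tG\t0.03\t0.005"), f)
#' read_instrument_table(f)
read_instrument_table <- function(path) {
  df <- read_tsv_file(path)
  required <- c("rsid", "effect_allele", "other_allele",
                "beta_exposure", "se_exposure")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("instrument table ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!"locus_label" %in% names(df)) df$locus_label <- NA_character_
  df <- df[, c(required, "locus_label")]
  if (nrow(df) == 0) return(df)

  errors <- character()
  errors <- validate_alleles(df, errors)
  for (col in c("beta_exposure", "se_exposure")) {
    bad <- which(!is_number(df[[col]]))
    for (i in bad) errors <- c(errors, sprintf("row %d: non-numeric %s", i, col))
  }
  bad_se <- which(is_number(df$se_exposure) & df$se_exposure <= 0)
  for (i in bad_se) {
    errors <- c(errors, sprintf("row %d: se_exposure must be > 0 (got %s)",
                                i, df$se_exposure[i]))
  }
  dup <- which(duplicated(df$rsid))
  for (i in dup) {
    errors <- c(errors, sprintf("row %d: duplicate rsid '%s'", i, df$rsid[i]))
  }
  stop_if_errors(errors, paste0("invalid instrument table ", path))
  df
}

#' Read an outcome table (per-SNP log odds ratios on disease)
#'
#' Expects columns `rsid`, `effect_allele`, `other_allele`, `cohort`, and
#' either `logor_outcome` + `se_outcome` or the published-summary form
#' `or_point` + `ci_low` + `ci_high` (converted via [se_from_ci()]).
#'
#' @param path path to a TSV file.
#' @return a data.frame with columns `rsid`, `effect_allele`, `other_allele`,
#'   `logor_outcome`, `se_outcome`, `cohort`.
#' @export
read_outcome_table <- function(path) {
  df <- read_tsv_file(path)
  base <- c("rsid", "effect_allele", "other_allele")
  missing <- setdiff(base, names(df))
  if (length(missing) > 0) {
    stop("outcome table ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!"cohort" %in% names(df)) df$cohort <- "COHORT1"

  has_beta <- all(c("logor_outcome", "se_outcome") %in% names(df))
  has_ci <- all(c("or_point", "ci_low", "ci_high") %in% names(df))
  if (!has_beta && !has_ci) {
    stop("outcome table ", path, " needs either logor_outcome/se_outcome ",
         "or or_point/ci_low/ci_high columns", call. = FALSE)
  }
  if (!has_beta) {
    conv <- se_from_ci(df$or_point, df$ci_low, df$ci_high)
    df$logor_outcome <- conv$logor
    df$se_outcome <- conv$se
  }
  df <- df[, c(base, "logor_outcome", "se_outcome", "cohort")]
  if (nrow(df) == 0) return(df)

  errors <- character()
  errors <- validate_alleles(df, errors)
  for (col in c("logor_outcome", "se_outcome")) {
    bad <- which(!is_number(df[[col]]))
    for (i in bad) errors <- c(errors, sprintf("row %d: non-numeric %s", i, col))
  }
  bad_se <- which(is_number(df$se_outcome) & df$se_outcome <= 0)
  for (i in bad_se) {
    errors <- c(errors, sprintf("row %d: se_outcome must be > 0 (got %s)",
                                i, df$se_outcome[i]))
  }
  dup <- which(duplicated(df[, c("rsid", "cohort")]))
  for (i in dup) {
    errors <- c(errors, sprintf("row %d: duplicate (rsid, cohort) ('%s', '%s')",
                                i, df$rsid[i], df$cohort[i]))
  }
  stop_if_errors(errors, paste0("invalid outcome table ", path))
  df
}

#' Read a per-variant genotype quality-control table
#'
#' Columns mirror the QC record: `rsid`, `call_rate`, `maf`, `hwe_p_cases`,
#' `hwe_p_controls`, `imputed` (logical or 0/1), `imputation_r2`.
#'
#' @param path path to a TSV file.
#' @return a validated data.frame.
#' @export
read_qc_table <- function(path) {
  df <- read_tsv_file(path)
  required <- c("rsid", "call_rate", "maf", "hwe_p_cases", "hwe_p_controls",
                "imputed", "imputation_r2")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("QC table ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df$imputed <- as.logical(df$imputed)
  validate_qc_records(df)
  df[, required]
}

validate_qc_records <- function(df) {
  errors <- character()
  check_range <- function(col, lo, hi) {
    bad <- which(!is_number(df[[col]]) | df[[col]] < lo | df[[col]] > hi)
    for (i in bad) {
      errors <<- c(errors, sprintf("row %d: %s outside [%g, %g]", i, col, lo, hi))
    }
  }
  check_range("call_rate", 0, 1)
  check_range("maf", 0, 0.5)
  check_range("hwe_p_cases", 0, 1)
  check_range("hwe_p_controls", 0, 1)
  check_range("imputation_r2", 0, 1)
  bad <- which(is.na(df$imputed))
  for (i in bad) errors <- c(errors, sprintf("row %d: imputed is not logical", i))
  stop_if_errors(errors, "invalid QC records")
  invisible(df)
}

#' Harmonize instrument and outcome tables to a common effect allele
#'
#' Joins per-SNP exposure and outcome associations by rsID and aligns their
#' effect alleles. When the two tables carry exactly swapped allele labels
#' the outcome log-OR is negated (`action = "swapped"`); incompatible allele
#' pairs are retained with `action = "dropped_mismatch"` and never enter
#' estimation. Every record is then oriented so that the effect allele is
#' the exposure-increasing allele (`beta_exposure >= 0`), flipping the
#' outcome sign in tandem; the combined causal estimate is invariant to this
#' convention, which exists so scatter and leave-one-out plots read
#' naturally.
#'
#' Palindromic SNPs (A/T, C/G) are strand-ambiguous from labels alone. Under
#' `palindromic = "trust"` (default) they are matched by label like any other
#' SNP, appropriate for curated instrument lists whose strands were resolved
#' upstream; `"strict"` drops them (`action = "dropped_palindromic"`).
#'
#' Instruments absent from the outcome table are reported via a warning, not
#' silently dropped; zero overlap is an error.
#'
#' @param instruments data.frame from [read_instrument_table()].
#' @param outcomes data.frame from [read_outcome_table()].
#' @param cohort cohort label to select from `outcomes`; may be `NULL` when
#'   the outcome table holds a single cohort.
#' @param palindromic `"trust"` or `"strict"`.
#' @return a data.frame with columns `rsid`, `effect_allele`, `other_allele`,
#'   `beta_exposure`, `se_exposure`, `logor_outcome`, `se_outcome`,
#'   `harmonization_action`. Only `as_is`/`swapped` rows are used by
#'   estimation functions.
#' @export
harmonize <- function(instruments, outcomes, cohort = NULL,
                      palindromic = c("trust", "strict")) {
  palindromic <- match.arg(palindromic)
  if (nrow(instruments) == 0 || nrow(outcomes) == 0) {
    stop("harmonize() requires nonempty instrument and outcome tables",
         call. = FALSE)
  }
  if (!is.null(cohort)) {
    outcomes <- outcomes[outcomes$cohort == cohort, , drop = FALSE]
    if (nrow(outcomes) == 0) {
      stop("no outcome records for cohort '", cohort, "'", call. = FALSE)
    }
  } else if (length(unique(outcomes$cohort)) > 1) {
    stop("outcome table holds multiple cohorts; pass `cohort` or ",
         "meta-analyse first with meta_outcome_tables()", call. = FALSE)
  }

  idx <- match(instruments$rsid, outcomes$rsid)
  absent <- instruments$rsid[is.na(idx)]
  if (length(absent) == nrow(instruments)) {
    stop("no instrument rsIDs overlap the outcome table", call. = FALSE)
  }
  if (length(absent) > 0) {
    warning("instrument SNP(s) absent from outcome table and dropped: ",
            paste(absent, collapse = ", "), call. = FALSE)
  }
  keep <- !is.na(idx)
  ins <- instruments[keep, , drop = FALSE]
  out <- outcomes[idx[keep], , drop = FALSE]

  n <- nrow(ins)
  action <- character(n)
  logor <- out$logor_outcome
  for (i in seq_len(n)) {
    pair_i <- allele_pair(ins$effect_allele[i], ins$other_allele[i])
    if (palindromic == "strict" && pair_i %in% PALINDROMIC_PAIRS) {
      action[i] <- "dropped_palindromic"
      next
    }
    same <- out$effect_allele[i] == ins$effect_allele[i] &&
      out$other_allele[i] == ins$other_allele[i]
    swap <- out$effect_allele[i] == ins$other_allele[i] &&
      out$other_allele[i] == ins$effect_allele[i]
    if (same) {
      action[i] <- "as_is"
    } else if (swap) {
      action[i] <- "swapped"
      logor[i] <- -logor[i]
    } else {
      action[i] <- "dropped_mismatch"
    }
  }

  h <- data.frame(
    rsid = ins$rsid,
    effect_allele = ins$effect_allele,
    other_allele = ins$other_allele,
    beta_exposure = ins$beta_exposure,
    se_exposure = ins$se_exposure,
    logor_outcome = logor,
    se_outcome = out$se_outcome,
    harmonization_action = action,
    stringsAsFactors = FALSE
  )
  if ("locus_label" %in% names(instruments)) {
    h$locus_label <- ins$locus_label
  }

  # Orient so the effect allele is the exposure-increasing allele.
  flip <- h$beta_exposure < 0 & h$harmonization_action %in% c("as_is", "swapped")
  if (any(flip)) {
    ea <- h$effect_allele[flip]
    h$effect_allele[flip] <- h$other_allele[flip]
    h$other_allele[flip] <- ea
    h$beta_exposure[flip] <- -h$beta_exposure[flip]
    h$logor_outcome[flip] <- -h$logor_outcome[flip]
  }
  rownames(h) <- NULL
  h
}

#' Rows of a harmonized table that enter estimation
#' @param harmonized output of [harmonize()].
#' @return the subset with `harmonization_action` in `as_is`/`swapped`.
#' @export
harmonized_kept <- function(harmonized) {
  if (is.null(harmonized$harmonization_action)) return(harmonized)
  harmonized[harmonized$harmonization_action %in% c("as_is", "swapped"), ,
             drop = FALSE]
}

#' Apply genotype quality-control thresholds
#'
#' A variant passes iff all of:
#' \itemize{
#'   \item call rate >= 0.95 with MAF >= 0.05, or call rate >= 0.99 with
#'     MAF < 0.05;
#'   \item Hardy-Weinberg p-value in cases > 1e-12 (strict inequality);
#'   \item Hardy-Weinberg p-value in controls > 1e-7 (strict inequality);
#'   \item if imputed, imputation R^2 >= 0.6.
#' }
#' Call-rate/MAF thresholds are inclusive, HWE thresholds strict, mirroring
#' the usual array-QC convention for these rules.
#'
#' @param records data.frame of QC records (see [read_qc_table()]).
#' @return list with `pass` (character rsIDs) and `fail` (data.frame of
#'   `rsid`, `reason`, naming the first violated rule).
#' @export
qc_filter <- function(records) {
  validate_qc_records(records)
  n <- nrow(records)
  reason <- rep(NA_character_, n)

  rule1 <- (records$call_rate >= 0.95 & records$maf >= 0.05) |
    (records$call_rate >= 0.99 & records$maf < 0.05)
  reason[is.na(reason) & !rule1] <- "call_rate_maf"
  reason[is.na(reason) & !(records$hwe_p_cases > 1e-12)] <- "hwe_cases"
  reason[is.na(reason) & !(records$hwe_p_controls > 1e-7)] <- "hwe_controls"
  reason[is.na(reason) & records$imputed & records$imputation_r2 < 0.6] <-
    "imputation_r2"

  fail <- !is.na(reason)
  list(
    pass = records$rsid[!fail],
    fail = data.frame(rsid = records$rsid[fail], reason = reason[fail],
                      stringsAsFactors = FALSE)
  )
}

#' Remove instruments by rsID or locus label
#'
#' Used for a-priori exclusions (e.g. dropping a BMI-mediated locus from an
#' insulin instrument set) and for sensitivity reruns. Names that match
#' nothing raise a warning, not an error.
#'
#' @param instruments instrument data.frame.
#' @param exclusion character vector of rsIDs and/or locus labels.
#' @return the reduced data.frame, with attribute `n_removed`.
#' @export
#' @examples
#' ins <- data.frame(rsid = c("rs1", "rs2"), effect_allele = "A",
#'                   other_allele = "G", beta_exposure = 0.1,
#'                   se_exposure = 0.01, locus_label = c("FTO", "TCF7L2"))
#' exclude_variants(ins, "FTO")
exclude_variants <- function(instruments, exclusion) {
  exclusion <- as.character(exclusion)
  if (length(exclusion) == 0) {
    out <- instruments
    attr(out, "n_removed") <- 0L
    return(out)
  }
  locus <- if ("locus_label" %in% names(instruments)) {
    instruments$locus_label
  } else {
    rep(NA_character_, nrow(instruments))
  }
  hit <- instruments$rsid %in% exclusion | (!is.na(locus) & locus %in% exclusion)
  matched <- unique(c(instruments$rsid[instruments$rsid %in% exclusion],
                      locus[!is.na(locus) & locus %in% exclusion]))
  unmatched <- setdiff(exclusion, matched)
  if (length(unmatched) > 0) {
    warning("exclusion name(s) matched no variant: ",
            paste(unmatched, collapse = ", "), call. = FALSE)
  }
  out <- instruments[!hit, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(hit)
  message(sum(hit), " variant(s) removed by exclusion list")
  out
}

#' Write an instrument table as TSV
#' @param df instrument data.frame.
#' @param path output path.
#' @param comments character vector written as '#' header lines (e.g. seed
#'   provenance).
#' @return the path, invisibly.
#' @export
write_instrument_table <- function(df, path, comments = character()) {
  write_tsv_file(df, path, comments)
}

#' Write an outcome table as TSV
#' @inheritParams write_instrument_table
#' @export
write_outcome_table <- function(df, path, comments = character()) {
  write_tsv_file(df, path, comments)
}
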