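# Sensitivity analyses around the IVW estimate: Bonferroni-corrected
# per-SNP outlier screening, exclusion reruns, leave-one-out diagnostics,
# and data export for scatter/forest plots. Individual SNPs strongly
# associated with the disease may act through pleiotropic pathways; the
# screen flags them, the rerun shows whether the combined estimate depends
# on them.

#' Bonferroni-corrected significance threshold
#'
#' @param n_tests number of tests in the family (>= 1).
#' @param family_alpha family-wise error rate (default 0.05).
#' @return `family_alpha / n_tests`.
#' @export
#' @examples
#' bonferroni_alpha(49)                 # per-SNP screen over 49 instruments
#' format_pvalue(bonferroni_alpha(55))  # "9.1x10^-4"
bonferroni_alpha <- function(n_tests, family_alpha = 0.05) {
  if (!is_number(n_tests) || n_tests < 1 || n_tests != round(n_tests)) {
    stop("n_tests must be a positive integer", call. = FALSE)
  }
  if (!is_number(family_alpha) || family_alpha <= 0 || family_alpha >= 1) {
    stop("family_alpha must be in (0, 1)", call. = FALSE)
  }
  family_alpha / n_tests
}

#' Screen individual SNPs for association with the outcome
#'
#' Two-sided normal p-value `2 pnorm(-|logor / se|)` per SNP, flagged when
#' below the Bonferroni threshold. The p-value depends on the association
#' through |z| only, so it is invariant to allele re-orientation.
#'
#' @param harmonized harmonized data.frame (only `as_is`/`swapped` rows are
#'   screened).
#' @param alpha significance threshold, typically from [bonferroni_alpha()].
#' @return data.frame with `rsid`, `logor_outcome`, `se_outcome`, `pvalue`,
#'   `alpha`, `flagged`.
#' @export
screen_snps <- function(harmonized, alpha) {
  if (!is_number(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must be in (0, 1)", call. = FALSE)
  }
  h <- harmonized_kept(harmonized)
  p <- 2 * pnorm(-abs(h$logor_outcome / h$se_outcome))
  data.frame(
    rsid = h$rsid,
    logor_outcome = h$logor_outcome,
    se_outcome = h$se_outcome,
    pvalue = p,
    alpha = alpha,
    flagged = p < alpha,
    stringsAsFactors = FALSE
  )
}

#' Re-estimate after excluding named or flagged variants
#'
#' Runs the full harmonize + IVW pipeline twice — on the complete
#' instrument set and on the set minus `exclude` — and attaches
#' leave-one-out diagnostics for the baseline. Both estimates are retained
#' so the report can show whether the exclusions change the association.
#'
#' @param instruments instrument data.frame.
#' @param outcomes outcome data.frame (single cohort or meta-analysed).
#' @param exclude character vector of rsIDs / locus labels to drop.
#' @param spec an [exposure_spec()].
#' @param cohort optional cohort label passed to [harmonize()].
#' @param palindromic palindromic-SNP policy passed to [harmonize()].
#' @return an object of class `sensitivity_report`: list with `baseline`
#'   (`mr_estimate`), `excluded_rsids`, `rerun` (`mr_estimate`), and
#'   `leave_one_out` (data.frame).
#' @export
rerun_excluding <- function(instruments, outcomes, exclude, spec,
                            cohort = NULL, palindromic = "trust") {
  h_base <- harmonize(instruments, outcomes, cohort = cohort,
                      palindromic = palindromic)
  baseline <- mr_ivw(h_base, spec)

  reduced <- exclude_variants(instruments, exclude)
  excluded_rsids <- setdiff(instruments$rsid, reduced$rsid)
  if (nrow(reduced) == 0) {
    stop("exclusion removes every instrument; nothing to estimate",
         call. = FALSE)
  }
  rerun <- if (length(excluded_rsids) == 0) {
    baseline
  } else {
    mr_ivw(harmonize(reduced, outcomes, cohort = cohort,
                     palindromic = palindromic), spec)
  }

  loo <- if (nrow(harmonized_kept(h_base)) >= 2) {
    leave_one_out(h_base)
  } else {
    NULL
  }

  structure(
    list(baseline = baseline, excluded_rsids = excluded_rsids,
         rerun = rerun, leave_one_out = loo),
    class = "sensitivity_report"
  )
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat("Baseline ")
  print(x$baseline)
  cat("Excluded: ",
      if (length(x$excluded_rsids)) paste(x$excluded_rsids, collapse = ", ")
      else "(none)", "\n", sep = "")
  cat("Rerun    ")
  print(x$rerun)
  invisible(x)
}

#' Leave-one-out IVW estimates
#'
#' Recomputes the combined estimate omitting each SNP in turn. A single SNP
#' whose omission moves the estimate far more than any other is a candidate
#' pleiotropic outlier.
#'
#' @param harmonized harmonized data.frame with at least 2 usable SNPs.
#' @return data.frame with `dropped_rsid`, `beta`, `se` (per exposure unit).
#' @export
leave_one_out <- function(harmonized) {
  h <- harmonized_kept(harmonized)
  if (nrow(h) < 2) {
    stop("leave-one-out needs at least 2 harmonized SNPs", call. = FALSE)
  }
  ratios <- wald_ratio(h)
  out <- lapply(seq_len(nrow(ratios)), function(i) {
    est <- ivw_estimate(ratios[-i, , drop = FALSE])
    data.frame(dropped_rsid = ratios$rsid[i], beta = est$beta, se = est$se,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Per-SNP scatter data for pleiotropy plots
#'
#' Exports (gamma_j, Gamma_j, se) pairs so SNP-exposure vs SNP-outcome
#' effects can be plotted with the IVW slope; rendering itself is left to
#' the caller.
#'
#' @param harmonized harmonized data.frame.
#' @return data.frame with `rsid`, `beta_exposure`, `se_exposure`,
#'   `logor_outcome`, `se_outcome`.
#' @export
scatter_data <- function(harmonized) {
  h <- harmonized_kept(harmonized)
  h[, c("rsid", "beta_exposure", "se_exposure", "logor_outcome", "se_outcome")]
}
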