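# Fixed-effect inverse-variance meta-analysis of per-SNP outcome
# associations across cohorts, applied before MR estimation so the causal
# estimate uses the combined case-control evidence.

#' Fixed-effect inverse-variance meta-analysis of log odds ratios
#'
#' With weights w_i = se_i^-2: pooled log-OR = sum(w_i logor_i) / sum(w_i),
#' pooled se = sum(w_i)^-1/2. Cochran's Q is returned for information and
#' never used to filter.
#'
#' @param logor numeric vector of per-cohort log odds ratios for one SNP.
#' @param se their standard errors (all > 0).
#' @return list with `logor`, `se`, `q_stat`, `q_df`, `n_cohorts`.
#' @export
#' @examples
#' fixed_effect_meta(c(0.1, 0.3), c(0.05, 0.05))
fixed_effect_meta <- function(logor, se) {
  if (length(logor) == 0) stop("empty meta-analysis input", call. = FALSE)
  if (length(logor) != length(se)) stop("logor/se length mismatch", call. = FALSE)
  if (any(!is_number(se) | se <= 0)) stop("all se must be > 0", call. = FALSE)
  w <- se^-2
  pooled <- sum(w * logor) / sum(w)
  list(
    logor = pooled,
    se = 1 / sqrt(sum(w)),
    q_stat = sum(w * (logor - pooled)^2),
    q_df = length(logor) - 1L,
    n_cohorts = length(logor)
  )
}

#' Meta-analyse per-SNP outcome associations across cohorts
#'
#' Aligns every cohort's record for a given rsID to the orientation of the
#' first cohort carrying it (exactly swapped allele labels flip the log-OR
#' sign; incompatible labels are an error), then pools with
#' [fixed_effect_meta()]. SNPs present in a single cohort pass through with
#' their original estimate. Contributing cohorts are recorded per SNP, and
#' per-SNP heterogeneity (Cochran's Q) is attached as the
#' `"heterogeneity"` attribute for inspection.
#'
#' @param outcomes an outcome data.frame holding one or more cohorts
#'   (see [read_outcome_table()]).
#' @param meta_label cohort label given to the pooled records.
#' @return an outcome data.frame with `cohort = meta_label` and an extra
#'   `contributors` column.
#' @export
meta_outcome_tables <- function(outcomes, meta_label = "META") {
  if (nrow(outcomes) == 0) stop("empty outcome table", call. = FALSE)
  rsids <- unique(outcomes$rsid)
  rows <- vector("list", length(rsids))
  het <- vector("list", length(rsids))
  for (k in seq_along(rsids)) {
    sub <- outcomes[outcomes$rsid == rsids[k], , drop = FALSE]
    ref_ea <- sub$effect_allele[1]
    ref_oa <- sub$other_allele[1]
    logor <- sub$logor_outcome
    for (i in seq_len(nrow(sub))) {
      same <- sub$effect_allele[i] == ref_ea && sub$other_allele[i] == ref_oa
      swap <- sub$effect_allele[i] == ref_oa && sub$other_allele[i] == ref_ea
      if (swap) {
        logor[i] <- -logor[i]
      } else if (!same) {
        stop("conflicting allele labels for ", rsids[k], " across cohorts: ",
             ref_ea, "/", ref_oa, " vs ",
             sub$effect_allele[i], "/", sub$other_allele[i], call. = FALSE)
      }
    }
    m <- fixed_effect_meta(logor, sub$se_outcome)
    rows[[k]] <- data.frame(
      rsid = rsids[k],
      effect_allele = ref_ea,
      other_allele = ref_oa,
      logor_outcome = m$logor,
      se_outcome = m$se,
      cohort = meta_label,
      contributors = paste(sub$cohort, collapse = ","),
      stringsAsFactors = FALSE
    )
    het[[k]] <- data.frame(rsid = rsids[k], q_stat = m$q_stat, q_df = m$q_df)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "heterogeneity") <- do.call(rbind, het)
  out
}
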