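# Shared fixtures: tiny instrument/outcome tables built in code, a fast
# small-scale simulation design, and TSV writers into tempfiles.

make_instruments <- function(n = 4, beta = NULL, se = NULL,
                             ea = NULL, oa = NULL, locus = NULL) {
  data.frame(
    rsid = sprintf("rs%d", seq_len(n)),
    effect_allele = ea %||% rep(c("A", "C", "G", "T"), length.out = n),
    other_allele = oa %||% rep(c("G", "T", "A", "C"), length.out = n),
    beta_exposure = beta %||% seq(0.02, by = 0.01, length.out = n),
    se_exposure = se %||% rep(0.005, n),
    locus_label = locus %||% rep(NA_character_, n),
    stringsAsFactors = FALSE
  )
}

make_outcomes <- function(instruments, logor = NULL, se = NULL,
                          cohort = "UK") {
  n <- nrow(instruments)
  data.frame(
    rsid = instruments$rsid,
    effect_allele = instruments$effect_allele,
    other_allele = instruments$other_allele,
    logor_outcome = logor %||% rep(0.05, n),
    se_outcome = se %||% rep(0.02, n),
    cohort = cohort,
    stringsAsFactors = FALSE
  )
}

# harmonized table straight from ratio-level quantities
make_harmonized <- function(beta_exposure, logor, se_outcome,
                            se_exposure = rep(0.001, length(beta_exposure))) {
  data.frame(
    rsid = sprintf("rs%d", seq_along(beta_exposure)),
    effect_allele = "A", other_allele = "G",
    beta_exposure = beta_exposure, se_exposure = se_exposure,
    logor_outcome = logor, se_outcome = se_outcome,
    harmonization_action = "as_is",
    stringsAsFactors = FALSE
  )
}

write_tmp_tsv <- function(df, comments = character()) {
  path <- tempfile(fileext = ".tsv")
  con <- file(path, "wt")
  if (length(comments)) writeLines(paste0("# ", comments), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  path
}

# small, fast design for unit tests (full-scale defaults are exercised in
# the acceptance suite)
small_design <- function(seed = 42, ...) {
  simulation_design(n_snps = 6, n_exposure_cohort = 3000, n_cases = 250,
                    n_controls = 1200, seed = seed, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
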