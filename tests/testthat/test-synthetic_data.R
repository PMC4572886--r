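# Deterministic two-sample simulator with known ground truth.

test_that("simulation_design validates and derives its fields", {
  d <- simulation_design(seed = 5)
  expect_equal(d$n_snps, 36)
  expect_equal(length(d$allele_freqs), 36)
  expect_true(all(d$allele_freqs > 0.01 & d$allele_freqs < 0.5))
  expect_equal(d$n_cases, 1287)
  expect_equal(d$n_controls, 8273)
  # per-SNP gamma sized so the set explains instrument_r2 of variance
  var_explained <- sum(2 * d$allele_freqs * (1 - d$allele_freqs) *
                         (d$gamma_true / d$exposure_sd)^2)
  expect_equal(var_explained, d$instrument_r2, tolerance = 1e-12)
  expect_false(any(paste0(d$effect_allele, d$other_allele) %in%
                     c("AT", "TA", "CG", "GC")))
  expect_error(simulation_design(allele_freqs = c(0.6, 0.2), n_snps = 2),
               "allele_freqs")
  expect_error(simulation_design(confounder_effect_on_exposure = 1),
               "must be < 1")
})

test_that("generators are deterministic and leave the session RNG alone", {
  d <- small_design(seed = 8)
  set.seed(999)
  before <- .Random.seed
  a <- simulate_exposure_cohort(d)
  expect_identical(.Random.seed, before)
  b <- simulate_exposure_cohort(d)
  expect_identical(a$instruments, b$instruments)
  expect_identical(a$panel$genotypes, b$panel$genotypes)

  # byte-identical written tables
  f1 <- tempfile(); f2 <- tempfile()
  write_instrument_table(a$instruments, f1, comments = "seed: 8")
  write_instrument_table(b$instruments, f2, comments = "seed: 8")
  expect_identical(readLines(f1), readLines(f2))

  o1 <- simulate_case_control(d, seed = 9)
  o2 <- simulate_case_control(d, seed = 9)
  expect_identical(o1, o2)
  expect_false(identical(o1$logor_outcome,
                         simulate_case_control(d, seed = 10)$logor_outcome))
})

test_that("exposure GWAS summaries match lm() per SNP", {
  d <- small_design(seed = 14)
  sim <- simulate_exposure_cohort(d)
  for (j in c(1, 4)) {
    fit <- summary(lm(sim$panel$exposure ~ sim$panel$genotypes[, j]))
    expect_equal(sim$instruments$beta_exposure[j],
                 fit$coefficients[2, 1], tolerance = 1e-10)
    expect_equal(sim$instruments$se_exposure[j],
                 fit$coefficients[2, 2], tolerance = 1e-10)
  }
})

test_that("null instruments give calibrated z-scores, strong ones recover gamma", {
  # gamma = 0: ~5% of SNPs reach |z| > 1.96
  d0 <- simulation_design(n_snps = 60, gamma_true = rep(0, 60),
                          n_exposure_cohort = 2000, n_cases = 50,
                          n_controls = 200, seed = 44)
  sim <- simulate_exposure_cohort(d0)
  z <- sim$instruments$beta_exposure / sim$instruments$se_exposure
  expect_lt(mean(abs(z) > 1.96), 0.18)

  # single strong SNP at large n: estimate within 3 se of truth
  d1 <- simulation_design(n_snps = 1, allele_freqs = 0.3, gamma_true = 0.08,
                          n_exposure_cohort = 50000, n_cases = 50,
                          n_controls = 200, seed = 45)
  sim <- simulate_exposure_cohort(d1)
  expect_lt(abs(sim$instruments$beta_exposure - 0.08),
            3 * sim$instruments$se_exposure)
})

test_that("case-control generator fills quotas or fails with advice", {
  d <- small_design(seed = 50)
  out <- simulate_case_control(d, seed = 51, cohort = "AUS")
  expect_equal(out$cohort, rep("AUS", d$n_snps))
  expect_true(all(out$se_outcome > 0))

  rare <- simulation_design(n_snps = 2, n_exposure_cohort = 100,
                            n_cases = 50, n_controls = 10,
                            baseline_logodds = -12, seed = 52)
  expect_error(simulate_case_control(rare, max_batches = 3L),
               "baseline_logodds")
})

test_that("a planted pleiotropic SNP is flagged more often than clean SNPs", {
  pleio <- c(0.5, rep(0, 5))
  d <- simulation_design(n_snps = 6, pleiotropy_betas = pleio,
                         n_exposure_cohort = 3000, n_cases = 600,
                         n_controls = 3000, causal_beta = 0, seed = 61)
  flags <- matrix(FALSE, 8, 6)
  for (r in 1:8) {
    out <- simulate_case_control(d, seed = 100 + r)
    ins <- simulate_exposure_cohort(d, seed = 200 + r)$instruments
    h <- harmonize(ins, out)
    flags[r, ] <- screen_snps(h, bonferroni_alpha(6))$flagged
  }
  expect_gt(sum(flags[, 1]), max(colSums(flags[, -1])))
})

test_that("trait panel plants only the requested genetic links", {
  d <- small_design(seed = 70)
  alpha <- bonferroni_alpha(55)

  # all links disabled: no trait associates with the score
  null_panel <- simulate_trait_panel(d, n = 3000, exposure_link = FALSE)
  score <- build_unweighted_score(null_panel$genotypes,
                                  null_panel$increasing)
  res <- scan_confounders(score, null_panel$traits, null_panel$trait_types,
                          alpha)
  expect_false(any(res$significant))

  # FI link enabled: the FI-score scan flags fasting insulin alone
  fi_panel <- simulate_trait_panel(d, n = 3000,
                                   exposure_trait = "fasting_insulin")
  score <- build_unweighted_score(fi_panel$genotypes, fi_panel$increasing)
  res <- scan_confounders(score, fi_panel$traits, fi_panel$trait_types,
                          alpha)
  expect_identical(res$trait_name[res$significant], "fasting_insulin")

  # secretion panel with the secretion -> glucose link flags both
  sec_panel <- simulate_trait_panel(d, n = 5000,
                                    exposure_trait = "insulin_secretion",
                                    secretion_fg_link = TRUE,
                                    fg_link_r2 = 0.02)
  score <- build_unweighted_score(sec_panel$genotypes, sec_panel$increasing)
  res <- scan_confounders(score, sec_panel$traits, sec_panel$trait_types,
                          alpha)
  expect_setequal(res$trait_name[res$significant],
                  c("insulin_30min", "fasting_glucose"))
})

test_that("two-sample wrapper splits cohorts and keeps streams independent", {
  d <- small_design(seed = 80)
  sim <- simulate_two_sample(d, cohorts = c("UK", "AUS"))
  expect_setequal(unique(sim$outcomes$cohort), c("UK", "AUS"))
  expect_equal(nrow(sim$outcomes), 2 * d$n_snps)
  expect_equal(nrow(sim$instruments), d$n_snps)
  # downstream: meta + IVW runs end to end
  meta <- meta_outcome_tables(sim$outcomes)
  est <- mr_ivw(harmonize(sim$instruments, meta, cohort = "META"),
                exposure_spec("x", d$exposure_sd))
  expect_true(is.finite(est$beta))
})
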