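# Reading, validation, allele harmonization, QC filtering, exclusions.

test_that("instrument tables round-trip through TSV with validation", {
  ins <- make_instruments(18)
  path <- write_tmp_tsv(ins, comments = "seed: 1")
  got <- read_instrument_table(path)
  expect_equal(got$rsid, ins$rsid)
  expect_equal(got$beta_exposure, ins$beta_exposure)

  # header-only file -> empty table
  empty <- write_tmp_tsv(ins[0, ])
  expect_equal(nrow(read_instrument_table(empty)), 0)

  # invalid rows are rejected with their row numbers
  bad <- ins
  bad$se_exposure[3] <- 0
  expect_error(read_instrument_table(write_tmp_tsv(bad)), "row 3")
  bad <- ins
  bad$rsid[5] <- bad$rsid[2]
  expect_error(read_instrument_table(write_tmp_tsv(bad)), "row 5.*duplicate")
  bad <- ins
  bad$effect_allele[1] <- "N"
  expect_error(read_instrument_table(write_tmp_tsv(bad)), "row 1")
  expect_error(read_instrument_table(write_tmp_tsv(ins[, -4])), "beta_exposure")
})

test_that("outcome tables accept log-OR or published OR/CI columns", {
  ins <- make_instruments(3)
  out <- make_outcomes(ins, logor = c(0.1, -0.2, 0), se = c(0.05, 0.04, 0.03))
  got <- read_outcome_table(write_tmp_tsv(out))
  expect_equal(got$logor_outcome, out$logor_outcome)

  pub <- data.frame(rsid = "rs1", effect_allele = "A", other_allele = "G",
                    or_point = 2.34, ci_low = 1.06, ci_high = 5.14,
                    cohort = "META")
  got <- read_outcome_table(write_tmp_tsv(pub))
  expect_equal(got$logor_outcome, log(2.34))
  expect_equal(got$se_outcome, (log(5.14) - log(1.06)) / (2 * qnorm(0.975)),
               tolerance = 1e-12)

  dup <- rbind(out, out[1, ])
  expect_error(read_outcome_table(write_tmp_tsv(dup)), "duplicate")
})

test_that("harmonize matches the allele-pair policy table", {
  # independent enumeration of the policy over every ordered outcome pair
  alleles <- c("A", "C", "G", "T")
  pairs <- expand.grid(ea = alleles, oa = alleles, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ea != pairs$oa, ]
  expected_action <- function(ins_ea, ins_oa, out_ea, out_oa, policy) {
    if (policy == "strict" &&
        paste0(ins_ea, ins_oa) %in% c("AT", "TA", "CG", "GC")) {
      return("dropped_palindromic")
    }
    if (out_ea == ins_ea && out_oa == ins_oa) return("as_is")
    if (out_ea == ins_oa && out_oa == ins_ea) return("swapped")
    "dropped_mismatch"
  }

  for (policy in c("trust", "strict")) {
    for (ins_pair in list(c("A", "G"), c("A", "T"), c("C", "G"))) {
      for (k in seq_len(nrow(pairs))) {
        ins <- make_instruments(1, ea = ins_pair[1], oa = ins_pair[2],
                                beta = 0.03)
        out <- data.frame(rsid = "rs1", effect_allele = pairs$ea[k],
                          other_allele = pairs$oa[k], logor_outcome = 0.10,
                          se_outcome = 0.02, cohort = "UK")
        h <- harmonize(ins, out, palindromic = policy)
        want <- expected_action(ins_pair[1], ins_pair[2],
                                pairs$ea[k], pairs$oa[k], policy)
        expect_equal(h$harmonization_action, want,
                     label = paste(policy, ins_pair[1], ins_pair[2], "vs",
                                   pairs$ea[k], pairs$oa[k]))
        if (want == "swapped") expect_equal(h$logor_outcome, -0.10)
        if (want == "as_is") expect_equal(h$logor_outcome, 0.10)
      }
    }
  }
})

test_that("harmonize orients records to the exposure-increasing allele", {
  ins <- make_instruments(2, beta = c(0.03, -0.04), ea = c("A", "C"),
                          oa = c("G", "T"))
  out <- make_outcomes(ins, logor = c(0.10, 0.20))
  h <- harmonize(ins, out)
  expect_true(all(h$beta_exposure >= 0))
  # the negated instrument flipped alleles and outcome sign together
  expect_equal(h$effect_allele[2], "T")
  expect_equal(h$logor_outcome[2], -0.20)
})

test_that("harmonize reports missing SNPs and errors on zero overlap", {
  ins <- make_instruments(3)
  out <- make_outcomes(ins[1:2, ])
  expect_warning(h <- harmonize(ins, out), "rs3")
  expect_equal(nrow(h), 2)
  expect_error(suppressWarnings(harmonize(ins, make_outcomes(make_instruments(
    2, ea = "A", oa = "G"))[0, ])), "nonempty")
  out_disjoint <- make_outcomes(ins)
  out_disjoint$rsid <- paste0("rs", 100:102)
  expect_error(harmonize(ins, out_disjoint), "overlap")
})

test_that("harmonize is idempotent and sign-convention invariant", {
  set.seed(7)
  ins <- make_instruments(10, beta = rnorm(10, 0, 0.05))
  out <- make_outcomes(ins, logor = rnorm(10, 0, 0.1),
                       se = runif(10, 0.01, 0.1))
  h1 <- harmonize(ins, out)

  # feeding the harmonized table back as instrument + outcome changes nothing
  h2 <- harmonize(h1[, names(ins)[names(ins) != "locus_label"]],
                  data.frame(h1[, c("rsid", "effect_allele", "other_allele",
                                    "logor_outcome", "se_outcome")],
                             cohort = "UK"))
  expect_equal(h2$beta_exposure, h1$beta_exposure)
  expect_equal(h2$logor_outcome, h1$logor_outcome)
  expect_true(all(h2$harmonization_action == "as_is"))

  # negating all exposure betas and swapping allele labels leaves the MR
  # estimate untouched
  flipped <- ins
  flipped$beta_exposure <- -flipped$beta_exposure
  tmp <- flipped$effect_allele
  flipped$effect_allele <- flipped$other_allele
  flipped$other_allele <- tmp
  spec <- exposure_spec("x", 0.6)
  e1 <- mr_ivw(h1, spec)
  e2 <- mr_ivw(harmonize(flipped, out), spec)
  expect_equal(e2$beta, e1$beta, tolerance = 1e-12)
  expect_equal(e2$se, e1$se, tolerance = 1e-12)
})

test_that("qc_filter applies the quoted thresholds and partitions input", {
  rec <- function(cr, maf, hc = 0.5, hw = 0.5, imp = FALSE, r2 = 1) {
    data.frame(rsid = "x", call_rate = cr, maf = maf, hwe_p_cases = hc,
               hwe_p_controls = hw, imputed = imp, imputation_r2 = r2)
  }
  expect_equal(qc_filter(rec(0.96, 0.10))$pass, "x")
  f <- qc_filter(rec(0.96, 0.01))
  expect_equal(f$fail$reason, "call_rate_maf")
  f <- qc_filter(rec(0.99, 0.01))
  expect_equal(f$pass, "x")
  # HWE thresholds are strict inequalities
  expect_equal(qc_filter(rec(0.96, 0.1, hc = 1e-12))$fail$reason, "hwe_cases")
  expect_equal(qc_filter(rec(0.96, 0.1, hw = 1e-7))$fail$reason, "hwe_controls")
  expect_equal(qc_filter(rec(0.96, 0.1, imp = TRUE, r2 = 0.59))$fail$reason,
               "imputation_r2")
  expect_equal(qc_filter(rec(0.96, 0.1, imp = TRUE, r2 = 0.6))$pass, "x")

  # partition property over a random batch
  set.seed(1)
  n <- 200
  batch <- data.frame(
    rsid = sprintf("rs%d", 1:n),
    call_rate = runif(n, 0.9, 1), maf = runif(n, 0, 0.5),
    hwe_p_cases = 10^runif(n, -14, 0), hwe_p_controls = 10^runif(n, -9, 0),
    imputed = runif(n) < 0.5, imputation_r2 = runif(n)
  )
  res <- qc_filter(batch)
  expect_equal(length(res$pass) + nrow(res$fail), n)
  expect_length(intersect(res$pass, res$fail$rsid), 0)
})

test_that("exclude_variants removes by rsid or locus label", {
  ins <- make_instruments(19, locus = c("DGKB", "TFB1M",
                                        rep(NA_character_, 17)))
  expect_message(red <- exclude_variants(ins, c("DGKB", "TFB1M")),
                 "2 variant")
  expect_equal(nrow(red), 17)

  ins18 <- make_instruments(18)
  suppressMessages(red <- exclude_variants(ins18, "rs7"))
  expect_equal(nrow(red), 17)
  expect_false("rs7" %in% red$rsid)

  suppressMessages(same <- exclude_variants(ins18, character()))
  expect_equal(nrow(same), 18)
  expect_warning(suppressMessages(exclude_variants(ins18, "rs_nothing")),
                 "matched no variant")
})
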