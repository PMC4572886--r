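# Individual-level simulator for two-sample summary-statistic MR with known
# ground truth.
#
# Data-generating model, per individual i and SNP j:
#   g_ij ~ Binomial(2, f_j)                          (Hardy-Weinberg, no LD)
#   X_i  = sum_j gamma_j g_ij + a U_i + e_i          (continuous exposure)
#   logit P(D_i = 1) = b0 + beta_causal X_i + d U_i + sum_j rho_j g_ij
# with U, e standard normal. U is a shared confounder of exposure and
# disease; rho_j are optional direct (pleiotropic) SNP effects on disease.
# The exposure GWAS cohort and the case-control outcome cohort are sampled
# from independent RNG streams, so SNP-exposure and SNP-outcome estimation
# errors are uncorrelated — a genuine two-sample design.
#
# Defaults emulate an insulin-trait MR at realistic scale: 36 independent
# SNPs with allele frequencies in (0.1, 0.4) jointly explaining 2% of
# exposure variance (mean per-SNP F about 28 at n = 50,000), exposure SD
# 0.60 in native units, 1,287 cases and 8,273 controls in the outcome GWAS.

#' Define a two-sample MR simulation design
#'
#' All downstream generators are deterministic functions of
#' `(design, seed)`. Per-SNP allele frequencies, allele labels and true
#' exposure effects are fixed at design creation (using `seed`) unless
#' supplied explicitly.
#'
#' @param n_snps number of independent instrument SNPs.
#' @param allele_freqs effect-allele frequencies in (0.01, 0.5); drawn
#'   uniformly from (0.1, 0.4) when `NULL`.
#' @param gamma_true per-SNP effects on the exposure, native units; when
#'   `NULL`, set so the SNPs jointly explain `instrument_r2` of the
#'   exposure variance, split equally.
#' @param instrument_r2 total exposure variance explained by the SNPs.
#' @param exposure_sd exposure standard deviation in native units (default
#'   0.60, a log-insulin-like scale).
#' @param causal_beta true causal log-odds of disease per native exposure
#'   unit.
#' @param confounder_effect_on_exposure confounder loading on the exposure,
#'   in exposure SDs per confounder SD.
#' @param confounder_effect_on_outcome confounder effect on disease
#'   log-odds per confounder SD.
#' @param pleiotropy_betas optional per-SNP direct effects on disease
#'   log-odds (default all zero).
#' @param n_exposure_cohort exposure GWAS sample size.
#' @param n_cases,n_controls outcome GWAS case-control sizes.
#' @param baseline_logodds disease log-odds at exposure 0 and confounder 0.
#' @param seed integer seed recorded in the design and used as the default
#'   for every generator.
#' @return an object of class `simulation_design`.
#' @export
#' @examples
#' d <- simulation_design(n_snps = 6, n_exposure_cohort = 2000,
#'                        n_cases = 100, n_controls = 600, seed = 7)
simulation_design <- function(n_snps = 36,
                              allele_freqs = NULL,
                              gamma_true = NULL,
                              instrument_r2 = 0.02,
                              exposure_sd = 0.60,
                              causal_beta = 0.85,
                              confounder_effect_on_exposure = 0.3,
                              confounder_effect_on_outcome = 0.3,
                              pleiotropy_betas = NULL,
                              n_exposure_cohort = 50000,
                              n_cases = 1287,
                              n_controls = 8273,
                              baseline_logodds = -2,
                              seed = 1L) {
  stopifnot(n_snps >= 1, n_cases >= 1, n_controls >= 1,
            n_exposure_cohort >= 10, exposure_sd > 0,
            instrument_r2 > 0, instrument_r2 < 1)
  seed <- as.integer(seed)

  if (is.null(allele_freqs)) {
    allele_freqs <- with_local_seed(seed, runif(n_snps, 0.1, 0.4))
  }
  if (length(allele_freqs) != n_snps ||
      any(allele_freqs <= 0.01 | allele_freqs >= 0.5)) {
    stop("allele_freqs must have length n_snps with values in (0.01, 0.5)",
         call. = FALSE)
  }
  if (is.null(gamma_true)) {
    # equal variance share per SNP on the standardized scale, then rescaled
    gamma_true <- exposure_sd *
      sqrt((instrument_r2 / n_snps) / (2 * allele_freqs * (1 - allele_freqs)))
  }
  if (length(gamma_true) != n_snps) {
    stop("gamma_true must have length n_snps", call. = FALSE)
  }
  if (is.null(pleiotropy_betas)) pleiotropy_betas <- numeric(n_snps)
  if (length(pleiotropy_betas) != n_snps) {
    stop("pleiotropy_betas must have length n_snps", call. = FALSE)
  }

  a <- confounder_effect_on_exposure
  resid_var <- 1 - instrument_r2 - a^2
  if (resid_var <= 0) {
    stop("instrument_r2 + confounder_effect_on_exposure^2 must be < 1",
         call. = FALSE)
  }

  # fixed non-palindromic allele labels so harmonization is exercised
  pairs <- rbind(c("A", "G"), c("G", "A"), c("C", "T"), c("T", "C"),
                 c("A", "C"), c("C", "A"), c("G", "T"), c("T", "G"))
  pick <- with_local_seed(seed + 1L, sample.int(nrow(pairs), n_snps,
                                                replace = TRUE))

  structure(list(
    n_snps = n_snps,
    rsid = sprintf("rs%06d", seq_len(n_snps)),
    effect_allele = pairs[pick, 1],
    other_allele = pairs[pick, 2],
    allele_freqs = allele_freqs,
    gamma_true = gamma_true,
    instrument_r2 = instrument_r2,
    exposure_sd = exposure_sd,
    causal_beta = causal_beta,
    confounder_effect_on_exposure = confounder_effect_on_exposure,
    confounder_effect_on_outcome = confounder_effect_on_outcome,
    pleiotropy_betas = pleiotropy_betas,
    n_exposure_cohort = n_exposure_cohort,
    n_cases = n_cases,
    n_controls = n_controls,
    baseline_logodds = baseline_logodds,
    resid_sd = sqrt(resid_var),
    seed = seed
  ), class = "simulation_design")
}

#' @export
print.simulation_design <- function(x, ...) {
  cat(sprintf(paste0(
    "Two-sample MR simulation design (seed %d)\n",
    "  %d SNPs, instrument R^2 = %.3f, exposure SD = %g\n",
    "  causal log-odds per exposure unit = %g (OR per SD = %.3f)\n",
    "  exposure GWAS n = %d; outcome GWAS %d cases / %d controls\n"),
    x$seed, x$n_snps, x$instrument_r2, x$exposure_sd, x$causal_beta,
    exp(x$causal_beta * x$exposure_sd), x$n_exposure_cohort,
    x$n_cases, x$n_controls))
  invisible(x)
}

# Binomial(2, f_j) genotype matrix, one column per SNP.
sim_genotypes <- function(n, freqs) {
  matrix(rbinom(n * length(freqs), 2, rep(freqs, each = n)),
         nrow = n, ncol = length(freqs))
}

# Exposure and confounder for one cohort under the design's model.
sim_exposure_values <- function(design, genotypes) {
  n <- nrow(genotypes)
  u <- rnorm(n)
  e <- rnorm(n)
  x <- as.vector(genotypes %*% design$gamma_true) +
    design$exposure_sd * design$confounder_effect_on_exposure * u +
    design$exposure_sd * design$resid_sd * e
  list(exposure = x, confounder = u)
}

# Per-SNP marginal simple linear regressions of x on each genotype column,
# vectorised over SNPs (equivalent to lm(x ~ g) per SNP).
marginal_linear_gwas <- function(genotypes, x) {
  n <- nrow(genotypes)
  gc <- sweep(genotypes, 2, colMeans(genotypes))
  xc <- x - mean(x)
  sxx <- colSums(gc^2)
  sxy <- as.vector(crossprod(gc, xc))
  beta <- sxy / sxx
  rss <- sum(xc^2) - beta * sxy
  se <- sqrt(pmax(rss, 0) / (n - 2) / sxx)
  list(beta = beta, se = se)
}

# Per-SNP logistic regression of case status on dosage (glm.fit per SNP).
marginal_logistic_gwas <- function(genotypes, status) {
  J <- ncol(genotypes)
  beta <- se <- numeric(J)
  for (j in seq_len(J)) {
    fit <- glm.fit(cbind(1, genotypes[, j]), status, family = binomial())
    beta[j] <- fit$coefficients[2]
    covmat <- chol2inv(fit$qr$qr[1:2, 1:2, drop = FALSE])
    se[j] <- sqrt(covmat[2, 2])
  }
  list(beta = beta, se = se)
}

#' Simulate the exposure GWAS cohort and its instrument summary table
#'
#' Draws an individual-level cohort under the design's model and collapses
#' it to per-SNP marginal regression estimates of the SNP-exposure effects,
#' in the instrument table schema.
#'
#' @param design a [simulation_design()].
#' @param seed RNG seed (defaults to the design's).
#' @return list with `panel` (list: `genotypes`, `exposure`, `confounder`)
#'   and `instruments` (data.frame in the instrument TSV schema, with the
#'   seed recorded in the `"seed"` attribute).
#' @export
simulate_exposure_cohort <- function(design, seed = design$seed) {
  stopifnot(inherits(design, "simulation_design"))
  with_local_seed(seed, {
    G <- sim_genotypes(design$n_exposure_cohort, design$allele_freqs)
    vals <- sim_exposure_values(design, G)
    gwas <- marginal_linear_gwas(G, vals$exposure)
    instruments <- data.frame(
      rsid = design$rsid,
      effect_allele = design$effect_allele,
      other_allele = design$other_allele,
      beta_exposure = gwas$beta,
      se_exposure = gwas$se,
      locus_label = NA_character_,
      stringsAsFactors = FALSE
    )
    attr(instruments, "seed") <- seed
    list(panel = list(genotypes = G, exposure = vals$exposure,
                      confounder = vals$confounder),
         instruments = instruments)
  })
}

#' Simulate a case-control outcome GWAS and its summary table
#'
#' Draws population batches under the design's disease model until the
#' case and control quotas are met, then estimates per-SNP log odds ratios
#' by logistic regression of case status on dosage.
#'
#' @param design a [simulation_design()].
#' @param seed RNG seed; use a seed distinct from the exposure cohort's to
#'   preserve two-sample independence.
#' @param cohort cohort label written to the outcome table.
#' @param max_batches bound on population batches drawn while filling the
#'   case quota.
#' @return an outcome data.frame (schema of [read_outcome_table()]) with
#'   the seed in the `"seed"` attribute.
#' @export
simulate_case_control <- function(design, seed = design$seed + 1L,
                                  cohort = "UK", max_batches = 25L) {
  stopifnot(inherits(design, "simulation_design"))
  with_local_seed(seed, {
    p0 <- plogis(design$baseline_logodds)
    batch_n <- ceiling(1.3 * max(design$n_cases / max(p0, 0.005),
                                 design$n_controls / max(1 - p0, 0.005)))
    case_g <- list(); control_g <- list()
    n_case <- 0L; n_control <- 0L
    for (b in seq_len(max_batches)) {
      G <- sim_genotypes(batch_n, design$allele_freqs)
      vals <- sim_exposure_values(design, G)
      eta <- design$baseline_logodds +
        design$causal_beta * vals$exposure +
        design$confounder_effect_on_outcome * vals$confounder +
        as.vector(G %*% design$pleiotropy_betas)
      y <- rbinom(batch_n, 1, plogis(eta))
      if (n_case < design$n_cases) {
        take <- which(y == 1)[seq_len(min(sum(y == 1),
                                          design$n_cases - n_case))]
        if (length(take)) {
          case_g[[length(case_g) + 1]] <- G[take, , drop = FALSE]
          n_case <- n_case + length(take)
        }
      }
      if (n_control < design$n_controls) {
        take <- which(y == 0)[seq_len(min(sum(y == 0),
                                          design$n_controls - n_control))]
        if (length(take)) {
          control_g[[length(control_g) + 1]] <- G[take, , drop = FALSE]
          n_control <- n_control + length(take)
        }
      }
      if (n_case >= design$n_cases && n_control >= design$n_controls) break
    }
    if (n_case < design$n_cases || n_control < design$n_controls) {
      stop("could not fill the case-control quotas within ", max_batches,
           " batches; raise baseline_logodds or lower n_cases/n_controls",
           call. = FALSE)
    }
    G <- rbind(do.call(rbind, case_g), do.call(rbind, control_g))
    status <- rep(c(1L, 0L), c(design$n_cases, design$n_controls))
    gwas <- marginal_logistic_gwas(G, status)
    out <- data.frame(
      rsid = design$rsid,
      effect_allele = design$effect_allele,
      other_allele = design$other_allele,
      logor_outcome = gwas$beta,
      se_outcome = gwas$se,
      cohort = cohort,
      stringsAsFactors = FALSE
    )
    attr(out, "seed") <- seed
    out
  })
}

#' Simulate an individual-level confounder-scan trait panel
#'
#' Emulates a population cohort carrying the 11 traits scanned against
#' genetic scores: nine quantitative (age, age at menarche, age at
#' menopause, BMI, fasting glucose, fasting insulin, 30-minute insulin,
#' physical activity, energy intake) and two binary (education, smoking).
#' Traits are independent of genotype except where a link is planted: the
#' designated exposure trait receives the SNPs' genetic component scaled to
#' `design$instrument_r2` of its variance, and, optionally, fasting glucose
#' receives a secondary secretion-score component (`secretion_fg_link`,
#' variance share `fg_link_r2`) — emulating insulin-secretion variants that
#' also shape glucose levels.
#'
#' @param design a [simulation_design()].
#' @param seed RNG seed.
#' @param n panel size.
#' @param exposure_trait which trait the design's SNPs instrument:
#'   `"fasting_insulin"` or `"insulin_secretion"` (measured as 30-minute
#'   insulin, column `insulin_30min`).
#' @param exposure_link plant the SNPs -> exposure-trait effect (disable
#'   for a fully null panel).
#' @param secretion_fg_link also link the secretion score to fasting
#'   glucose.
#' @param fg_link_r2 variance share of fasting glucose explained by the
#'   secretion score when linked.
#' @return list with `genotypes`, `traits` (data.frame, 11 columns),
#'   `trait_types` (named vector), and `increasing` (per-SNP
#'   trait-increasing orientation flags for score building).
#' @export
simulate_trait_panel <- function(design, seed = design$seed + 2L, n = 10000,
                                 exposure_trait = c("fasting_insulin",
                                                    "insulin_secretion"),
                                 exposure_link = TRUE,
                                 secretion_fg_link = FALSE,
                                 fg_link_r2 = 0.01) {
  stopifnot(inherits(design, "simulation_design"))
  exposure_trait <- match.arg(exposure_trait)
  with_local_seed(seed, {
    G <- sim_genotypes(n, design$allele_freqs)
    gscore <- as.vector(G %*% design$gamma_true)
    gstd <- (gscore - mean(gscore)) / stats::sd(gscore)

    linked_trait <- function(mean, sd, r2) {
      mean + gstd * sd * sqrt(r2) + rnorm(n, 0, sd * sqrt(1 - r2))
    }
    plain <- function(mean, sd) rnorm(n, mean, sd)

    r2 <- design$instrument_r2
    traits <- data.frame(
      age = plain(45, 7),
      age_menarche = plain(13, 1.5),
      age_menopause = plain(50, 4),
      bmi = plain(26.4, 4.81),
      fasting_glucose = if (secretion_fg_link) {
        linked_trait(4.8, 0.65, fg_link_r2)
      } else {
        plain(4.8, 0.65)
      },
      fasting_insulin = if (exposure_link &&
                            exposure_trait == "fasting_insulin") {
        linked_trait(3.9, 0.60, r2)
      } else {
        plain(3.9, 0.60)
      },
      insulin_30min = if (exposure_link &&
                          exposure_trait == "insulin_secretion") {
        linked_trait(5.6, 0.58, r2)
      } else {
        plain(5.6, 0.58)
      },
      physical_activity = plain(0, 1),
      energy_intake = plain(8.4, 2.0),
      education = rbinom(n, 1, 0.5),
      smoking = rbinom(n, 1, 0.3)
    )
    trait_types <- c(
      age = "quantitative", age_menarche = "quantitative",
      age_menopause = "quantitative", bmi = "quantitative",
      fasting_glucose = "quantitative", fasting_insulin = "quantitative",
      insulin_30min = "quantitative", physical_activity = "quantitative",
      energy_intake = "quantitative", education = "binary",
      smoking = "binary"
    )
    list(genotypes = G, traits = traits, trait_types = trait_types,
         increasing = design$gamma_true > 0, seed = seed)
  })
}

#' Simulate one full two-sample data set
#'
#' Convenience wrapper drawing the exposure cohort and one or more
#' case-control cohorts from independent RNG streams derived from `seed`.
#' Multi-cohort outcome sizes split the design's case/control quotas as
#' evenly as possible.
#'
#' @param design a [simulation_design()].
#' @param seed base seed.
#' @param cohorts character vector of outcome cohort labels.
#' @return list with `instruments` (data.frame) and `outcomes` (data.frame
#'   stacking all cohorts).
#' @export
simulate_two_sample <- function(design, seed = design$seed,
                                cohorts = "UK") {
  seeds <- derive_seeds(seed, 1 + length(cohorts))
  exp_cohort <- simulate_exposure_cohort(design, seeds[1])
  k <- length(cohorts)
  case_split <- diff(round(seq(0, design$n_cases, length.out = k + 1)))
  control_split <- diff(round(seq(0, design$n_controls, length.out = k + 1)))
  outs <- lapply(seq_along(cohorts), function(i) {
    d <- design
    d$n_cases <- max(1L, case_split[i])
    d$n_controls <- max(1L, control_split[i])
    simulate_case_control(d, seeds[1 + i], cohort = cohorts[i])
  })
  list(instruments = exp_cohort$instruments, outcomes = do.call(rbind, outs))
}

#' Monte-Carlo calibration study of the IVW estimator
#'
#' Repeats the full generate -> harmonize -> IVW pipeline `n_reps` times
#' under a design and records, per replicate, the combined estimate, its
#' 95% CI coverage of the design's true causal effect, and the two-sided
#' p-value. Used to check consistency, CI coverage and type-I error of the
#' estimator under known ground truth.
#'
#' @param design a [simulation_design()].
#' @param n_reps number of replicates.
#' @param seed base seed; each replicate consumes two derived sub-seeds.
#' @return data.frame with one row per replicate: `rep`, `beta_hat`, `se`,
#'   `covered` (logical, CI covers `design$causal_beta`), `pvalue`,
#'   `or_per_sd`.
#' @export
mr_calibration_study <- function(design, n_reps, seed = design$seed) {
  seeds <- derive_seeds(seed, 2L * n_reps)
  rows <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    ins <- simulate_exposure_cohort(design, seeds[2 * r - 1])$instruments
    out <- simulate_case_control(design, seeds[2 * r], cohort = "UK")
    h <- harmonize(ins, out, cohort = "UK")
    est <- ivw_estimate(wald_ratio(h))
    lo <- est$beta - Z975 * est$se
    hi <- est$beta + Z975 * est$se
    rows[[r]] <- data.frame(
      rep = r, beta_hat = est$beta, se = est$se,
      covered = lo <= design$causal_beta & design$causal_beta <= hi,
      pvalue = 2 * pnorm(-abs(est$beta / est$se)),
      or_per_sd = exp(est$beta * design$exposure_sd)
    )
  }
  do.call(rbind, rows)
}
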