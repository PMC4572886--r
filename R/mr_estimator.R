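# Core causal estimator: per-SNP Wald ratios combined by the fixed-effect
# inverse-variance weighted (IVW) method, reported as an odds ratio per SD
# of the genetically predicted exposure.
#
# For SNP j with exposure effect gamma_j (se sigma_gj) and outcome log-OR
# Gamma_j (se sigma_Gj), the Wald ratio is Gamma_j / gamma_j with
# first-order standard error sigma_Gj / |gamma_j|. The IVW estimate is the
# precision-weighted mean of the ratios, algebraically identical to the
# slope of a weighted through-origin regression of Gamma on gamma with
# weights sigma_Gj^-2. First-order weights only (the uncertainty in
# gamma_j is not propagated) and no heterogeneity inflation, matching the
# classical fixed-effect summary-data estimator.

#' Per-SNP Wald ratio estimates
#'
#' @param harmonized a harmonized data.frame (see [harmonize()]); rows whose
#'   `harmonization_action` is not `as_is`/`swapped` are excluded.
#' @return data.frame with `rsid`, `ratio` (causal log-odds per exposure
#'   unit) and `se_ratio`.
#' @export
#' @examples
#' h <- data.frame(rsid = "rs1", beta_exposure = 0.04, se_exposure = 0.004,
#'                 logor_outcome = 0.02, se_outcome = 0.01)
#' wald_ratio(h)
wald_ratio <- function(harmonized) {
  h <- harmonized_kept(harmonized)
  if (nrow(h) == 0) stop("no harmonized SNPs available", call. = FALSE)
  zero <- h$beta_exposure == 0
  if (any(zero)) {
    stop("zero exposure effect for SNP(s): ",
         paste(h$rsid[zero], collapse = ", "),
         "; Wald ratio undefined", call. = FALSE)
  }
  data.frame(
    rsid = h$rsid,
    ratio = h$logor_outcome / h$beta_exposure,
    se_ratio = h$se_outcome / abs(h$beta_exposure),
    stringsAsFactors = FALSE
  )
}

#' Inverse-variance weighted combination of Wald ratios
#'
#' Fixed-effect precision-weighted mean: with w_j = se_ratio_j^-2,
#' beta = sum(w_j ratio_j) / sum(w_j) and se = sum(w_j)^-1/2.
#'
#' @param ratios data.frame from [wald_ratio()] (columns `ratio`,
#'   `se_ratio`).
#' @return list with `beta` (combined causal log-odds per exposure unit),
#'   `se`, and `n_snps`.
#' @export
ivw_estimate <- function(ratios) {
  if (is.null(ratios) || nrow(ratios) == 0) {
    stop("ivw_estimate() needs at least one Wald ratio", call. = FALSE)
  }
  if (any(ratios$se_ratio <= 0)) {
    stop("all se_ratio must be > 0", call. = FALSE)
  }
  w <- ratios$se_ratio^-2
  beta <- sum(w * ratios$ratio) / sum(w)
  list(beta = beta, se = 1 / sqrt(sum(w)), n_snps = nrow(ratios))
}

#' Declare an exposure's reporting scale
#'
#' Continuous exposures are reported per standard deviation in native units
#' (e.g. BMI 4.81 kg/m^2, fasting glucose 0.65 mmol/L, fasting insulin
#' 0.60 ln(pmol/L)); binary exposures such as type 2 diabetes are reported
#' per unit increase in genetically predicted log-odds, i.e. `sd_scale = 1`.
#'
#' @param name exposure name.
#' @param sd_scale standard deviation in native exposure units; must be 1
#'   for binary exposures.
#' @param binary_exposure logical.
#' @return an `exposure_spec` list.
#' @export
#' @examples
#' exposure_spec("fasting_insulin", 0.60)
#' exposure_spec("type_2_diabetes", 1, binary_exposure = TRUE)
exposure_spec <- function(name, sd_scale, binary_exposure = FALSE) {
  if (!is_number(sd_scale) || sd_scale <= 0) {
    stop("sd_scale must be a positive number", call. = FALSE)
  }
  if (binary_exposure && sd_scale != 1) {
    stop("binary exposures are reported per unit log-odds; sd_scale must be 1",
         call. = FALSE)
  }
  structure(list(name = name, sd_scale = sd_scale,
                 binary_exposure = binary_exposure),
            class = "exposure_spec")
}

#' Scale a combined estimate to a per-SD odds ratio report
#'
#' Converts (beta, se) on the per-exposure-unit scale into the reported
#' odds ratio per genetically predicted SD increase:
#' `or_per_sd = exp(beta * s)` with 95% CI `exp((beta +/- 1.959964 se) * s)`
#' and a two-sided normal p-value `2 pnorm(-|beta / se|)` (invariant to the
#' scaling).
#'
#' @param beta combined causal log-odds per exposure unit.
#' @param se its standard error.
#' @param spec an [exposure_spec()].
#' @param n_snps number of SNPs combined.
#' @return an object of class `mr_estimate`.
#' @export
scale_and_report <- function(beta, se, spec, n_snps = NA_integer_) {
  stopifnot(inherits(spec, "exposure_spec"))
  if (!is_number(se) || se <= 0) stop("se must be > 0", call. = FALSE)
  s <- spec$sd_scale
  est <- list(
    exposure = spec$name,
    beta = beta,
    se = se,
    sd_scale = s,
    or_per_sd = exp(beta * s),
    ci_low = exp((beta - Z975 * se) * s),
    ci_high = exp((beta + Z975 * se) * s),
    pvalue = 2 * pnorm(-abs(beta / se)),
    n_snps = n_snps
  )
  structure(est, class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf(
    "MR estimate for %s (%d SNPs)\n  OR per genetically predicted SD (SD = %g): %s (%s to %s), P = %s\n",
    x$exposure, x$n_snps, x$sd_scale, format_or(x$or_per_sd),
    format_or(x$ci_low), format_or(x$ci_high), format_pvalue(x$pvalue)))
  invisible(x)
}

#' One-call IVW analysis of a harmonized table
#'
#' Convenience wrapper: [wald_ratio()] then [ivw_estimate()] then
#' [scale_and_report()].
#'
#' @inheritParams wald_ratio
#' @param spec an [exposure_spec()].
#' @return an `mr_estimate`.
#' @export
mr_ivw <- function(harmonized, spec) {
  est <- ivw_estimate(wald_ratio(harmonized))
  scale_and_report(est$beta, est$se, spec, n_snps = est$n_snps)
}

#' Recover a log odds ratio and its standard error from a published OR/CI
#'
#' `logor = ln(or_point)`; `se = (ln(ci_high) - ln(ci_low)) / (2 * 1.959964)`.
#' A degenerate interval (`ci_low == ci_high`) yields `se = 0` and is
#' flagged in the `degenerate` column. Vectorised.
#'
#' @param or_point odds ratio point estimate(s).
#' @param ci_low,ci_high 95% confidence bounds; must satisfy
#'   `0 < ci_low <= or_point <= ci_high`.
#' @return data.frame with `logor`, `se`, `degenerate`.
#' @export
#' @examples
#' se_from_ci(2.34, 1.06, 5.14)
se_from_ci <- function(or_point, ci_low, ci_high) {
  bad <- !(is_number(or_point) & is_number(ci_low) & is_number(ci_high)) |
    ci_low <= 0 | ci_low > or_point | or_point > ci_high
  if (any(bad)) {
    stop("se_from_ci() requires 0 < ci_low <= or_point <= ci_high ",
         "(violated at position ", which(bad)[1], ")", call. = FALSE)
  }
  se <- (log(ci_high) - log(ci_low)) / (2 * Z975)
  data.frame(logor = log(or_point), se = se, degenerate = se == 0)
}
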