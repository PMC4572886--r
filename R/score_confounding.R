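# Genetic-score confounder scans. An unweighted score (count of
# trait-increasing alleles over the instrument SNPs) is regressed against a
# panel of candidate confounders; under valid instruments the score should
# associate with its own trait and nothing else. Quantitative traits use
# linear regression, binary traits logistic regression, both unadjusted
# with the score as sole predictor.

#' Build an unweighted genetic score from a dosage matrix
#'
#' Each SNP contributes its trait-increasing allele dosage; SNPs whose
#' recorded effect allele is trait-decreasing are counted as `2 - dosage`.
#' With hard genotypes the score is an integer in \[0, 2 * n_snps\].
#'
#' @param dosages individuals x SNPs matrix of effect-allele dosages in
#'   \[0, 2\].
#' @param increasing logical per-SNP flag: `TRUE` when the effect allele is
#'   the trait-increasing allele (taken from the harmonized orientation).
#' @param missing_policy `"error"` (default) or `"mean_impute"`, which
#'   replaces missing dosages by the SNP's mean dosage (2 x allele
#'   frequency) before summing.
#' @return numeric vector of per-individual scores.
#' @export
#' @examples
#' g <- matrix(c(2, 0, 1, 1), nrow = 2)
#' build_unweighted_score(g, increasing = c(TRUE, FALSE))
build_unweighted_score <- function(dosages,
                                   increasing = rep(TRUE, ncol(dosages)),
                                   missing_policy = c("error", "mean_impute")) {
  missing_policy <- match.arg(missing_policy)
  dosages <- as.matrix(dosages)
  if (length(increasing) != ncol(dosages)) {
    stop("`increasing` must have one flag per SNP column", call. = FALSE)
  }
  if (anyNA(dosages)) {
    if (missing_policy == "error") {
      stop("missing dosages present; use missing_policy = \"mean_impute\" ",
           "or complete the genotypes", call. = FALSE)
    }
    means <- colMeans(dosages, na.rm = TRUE)
    for (j in seq_len(ncol(dosages))) {
      nas <- is.na(dosages[, j])
      dosages[nas, j] <- means[j]
    }
  }
  if (any(dosages < 0 | dosages > 2)) {
    stop("dosages must lie in [0, 2]", call. = FALSE)
  }
  oriented <- sweep(dosages, 2, ifelse(increasing, 0, 2), function(g, base) {
    abs(base - g)
  })
  # abs(0 - g) = g for increasing SNPs, abs(2 - g) = 2 - g otherwise
  rowSums(oriented)
}

#' Scan a genetic score against a panel of candidate confounders
#'
#' Fits one unadjusted regression per trait: `lm(trait ~ score)` for
#' quantitative traits, `glm(trait ~ score, binomial)` for binary traits.
#' A binary trait with a single observed class is skipped with a warning.
#'
#' @param score numeric vector from [build_unweighted_score()].
#' @param traits data.frame of traits, one row per individual.
#' @param trait_types named character vector mapping every trait column to
#'   `"quantitative"` or `"binary"`.
#' @param alpha significance threshold for the whole scan, typically
#'   [bonferroni_alpha()] over the full score x trait family.
#' @return data.frame with one row per trait: `trait_name`, `test_type`,
#'   `estimate` (trait units, or log-odds, per score allele), `se`,
#'   `pvalue`, `n`, `alpha_used`, `significant`.
#' @export
scan_confounders <- function(score, traits, trait_types, alpha) {
  if (!is_number(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must be in (0, 1)", call. = FALSE)
  }
  missing_types <- setdiff(names(traits), names(trait_types))
  if (length(missing_types) > 0) {
    stop("no declared type for trait(s): ",
         paste(missing_types, collapse = ", "), call. = FALSE)
  }
  if (length(score) != nrow(traits)) {
    stop("score length must match trait panel rows", call. = FALSE)
  }

  rows <- list()
  for (trait in names(traits)) {
    type <- match.arg(trait_types[[trait]], c("quantitative", "binary"))
    y <- traits[[trait]]
    ok <- !is.na(y) & !is.na(score)
    yk <- y[ok]
    sk <- score[ok]
    if (type == "binary") {
      if (length(unique(yk)) < 2) {
        warning("binary trait '", trait, "' has a single class; skipped",
                call. = FALSE)
        next
      }
      fit <- summary(glm(yk ~ sk, family = binomial()))$coefficients
    } else {
      fit <- summary(lm(yk ~ sk))$coefficients
    }
    est <- fit["sk", 1]
    se <- fit["sk", 2]
    p <- fit["sk", 4]
    rows[[trait]] <- data.frame(
      trait_name = trait,
      test_type = if (type == "binary") "logistic" else "linear",
      estimate = est, se = se, pvalue = p, n = length(yk),
      alpha_used = alpha, significant = p < alpha,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
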