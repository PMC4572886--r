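# Internal helpers: TSV dialect, display formatting, local RNG.

VALID_ALLELES <- c("A", "C", "G", "T")

#' Read a tab-separated table, skipping '#' comment lines
#' @noRd
read_tsv_file <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
             stringsAsFactors = FALSE, check.names = TRUE)
}

#' Write a tab-separated table with optional '#' header comments
#' @noRd
write_tsv_file <- function(df, path, comments = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(comments) > 0) {
    writeLines(paste0("# ", comments), con)
  }
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run code with a temporary RNG state seeded by `seed`
#'
#' Restores the caller's .Random.seed afterwards so simulations never
#' perturb the session RNG stream.
#' @noRd
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Derive independent sub-seeds from a base seed
#'
#' Separate stages (exposure cohort, each outcome cohort, trait panel)
#' consume distinct sub-seeds so their sampling errors are independent by
#' construction, as in a genuine two-sample design.
#' @noRd
derive_seeds <- function(seed, n) {
  with_local_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Format an odds ratio (or CI bound) for display
#'
#' @param x numeric vector.
#' @return character vector, two decimal places.
#' @export
#' @examples
#' format_or(exp(0.85))
format_or <- function(x) {
  sprintf("%.2f", x)
}

#' Format a p-value (or alpha level) in journal table style
#'
#' Two significant figures; values below 10^-3 are shown in
#' scientific "m.mx10^-k" notation, others as bare decimals without a
#' leading zero (".03", ".003").
#'
#' @param p numeric vector of probabilities.
#' @return character vector.
#' @export
#' @examples
#' format_pvalue(0.05 / 55)  # "9.1x10^-4"
#' format_pvalue(0.0348)     # ".03"
format_pvalue <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    if (pi >= 0.995) return("> .99")
    if (pi >= 0.01) return(sub("^0", "", sprintf("%.2f", pi)))
    if (pi >= 0.001) return(sub("^0", "", sprintf("%.3f", pi)))
    pi <- signif(pi, 2)
    expo <- floor(log10(pi))
    mant <- pi / 10^expo
    sprintf("%.1fx10^%d", mant, expo)
  }, character(1))
}

#' Stop with a collected list of row-level validation messages
#' @noRd
stop_if_errors <- function(errors, context) {
  if (length(errors) > 0) {
    stop(context, ":\n", paste0("  - ", errors, collapse = "\n"), call. = FALSE)
  }
}

is_number <- function(x) is.numeric(x) & !is.na(x)
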