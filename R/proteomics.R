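#' Spectral-count quantification for a two-sample comparison
#'
#' Label-free quantification of a metastatic versus parental run: each
#' sample's spectral counts are scaled so that its library size (total
#' counts) equals the mean library size across the two samples, the scaled
#' quantitative values are floored at 1.0, and the fold change is the
#' floored metastatic value over the floored parental value. The floor keeps
#' fold changes finite for proteins seen in only one sample.
#'
#' Fisher's exact test (two-sided) is applied to the raw integer counts
#' against the library totals, never to the floored values, and the
#' p-values are corrected by the Benjamini-Hochberg step-up method.
#'
#' @param counts data.frame with columns `protein`, `count_metastatic`,
#'   `count_parental` (non-negative integers). Multiple runs per class
#'   should be summed before calling.
#' @param min_quant floor applied to normalized quantitative values
#'   (default 1.0).
#' @return data.frame with columns `protein`, `count_metastatic`,
#'   `count_parental`, `qvalue_met`, `qvalue_par`, `fold_change`, `pvalue`,
#'   `p_adj`.
#' @export
quantify_spectral_counts <- function(counts, min_quant = 1.0) {
  counts <- as.data.frame(counts)
  need <- c("protein", "count_metastatic", "count_parental")
  missing <- setdiff(need, names(counts))
  if (length(missing) > 0L) {
    stop("count table lacks column(s): ", paste(missing, collapse = ", "))
  }
  counts$protein <- trimws(toupper(as.character(counts$protein)))
  if (anyDuplicated(counts$protein)) stop("duplicate protein identifiers")
  cm <- counts$count_metastatic
  cp <- counts$count_parental
  if (any(cm < 0 | cp < 0) || any(cm != round(cm) | cp != round(cp))) {
    stop("spectral counts must be non-negative integers")
  }
  lib_m <- sum(cm)
  lib_p <- sum(cp)
  if (lib_m == 0 || lib_p == 0) stop("a sample has zero total spectral counts")
  target <- mean(c(lib_m, lib_p))
  qm <- pmax(cm * target / lib_m, min_quant)
  qp <- pmax(cp * target / lib_p, min_quant)
  pv <- vapply(seq_along(cm), function(i) {
    fisher_count_test(c(cm[i], cp[i]), c(lib_m, lib_p))
  }, numeric(1L))
  data.frame(
    protein = counts$protein,
    count_metastatic = cm,
    count_parental = cp,
    qvalue_met = qm,
    qvalue_par = qp,
    fold_change = qm / qp,
    pvalue = pv,
    p_adj = stepup_correct(pv),
    stringsAsFactors = FALSE
  )
}

#' Fisher's exact test for one protein's spectral counts
#'
#' Two-sided exact test on the 2x2 table contrasting a protein's counts
#' with the remainder of each library.
#'
#' @param protein_counts length-2 integer vector (metastatic, parental).
#' @param library_totals length-2 totals for the two samples.
#' @return Two-sided p-value.
#' @export
fisher_count_test <- function(protein_counts, library_totals) {
  stopifnot(length(protein_counts) == 2L, length(library_totals) == 2L)
  if (any(library_totals <= 0)) stop("library totals must be positive")
  if (any(protein_counts > library_totals)) {
    stop("protein count exceeds its library total")
  }
  tab <- matrix(
    c(protein_counts, library_totals - protein_counts),
    nrow = 2L, byrow = TRUE
  )
  # fisher.test can return 1 + eps from summing tied table probabilities
  min(stats::fisher.test(tab, alternative = "two.sided")$p.value, 1)
}

#' Benjamini-Hochberg step-up correction
#'
#' Step-up adjusted p-values: from the largest p downward, each adjusted
#' value is `min(p * n / rank, next larger adjusted value)`, clipped at 1.
#' Output order matches input order.
#'
#' @param pvalues numeric vector of p-values in [0, 1].
#' @return Adjusted p-values, same length and order.
#' @export
stepup_correct <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1 | is.na(pvalues))) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Differential proteins from a quantified spectral-count table
#'
#' Applies the corrected-p and fold thresholds to the output of
#' [quantify_spectral_counts()]: up-regulated when `p_adj < p_max` and
#' `fold_change >= fc_min`, down-regulated when `p_adj < p_max` and
#' `1 / fold_change >= fc_min`.
#'
#' @param quant output of [quantify_spectral_counts()].
#' @param p_max corrected p-value threshold (default 0.05).
#' @param fc_min minimal linear fold change (default 2).
#' @param model label for the resulting set.
#' @return A [differential_set()].
#' @export
differential_proteins <- function(quant, p_max = 0.05, fc_min = 2.0, model = "model") {
  quant <- as.data.frame(quant)
  if (is.null(quant$p_adj)) stop("quant table lacks p_adj; run quantify_spectral_counts()")
  if (fc_min <= 1) stop("fc_min must exceed 1")
  pass <- quant$p_adj < p_max
  up <- pass & quant$fold_change >= fc_min
  down <- pass & (1 / quant$fold_change) >= fc_min
  differential_set(quant$protein[up], quant$protein[down], model = model)
}

#' Read a spectral-count table from TSV
#' @param path TSV with header `protein`, `count_metastatic`, `count_parental`.
#' @return data.frame as read, identifiers upper-cased.
#' @export
read_spectral_counts <- function(path) {
  if (!file.exists(path)) stop("count file not found: ", path)
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  x$protein <- trimws(toupper(as.character(x$protein)))
  x
}
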