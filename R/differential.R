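#' Validate a per-feature statistics table
#'
#' A feature-statistics table holds one row per feature with the log2 fold
#' change (metastatic over parental) and the p-value of differential
#' expression, whatever upstream method produced them.
#'
#' @param stats data.frame with columns `feature`, `log2fc`, `pvalue`.
#' @return The table with `feature` upper-cased, invisibly usable downstream.
#' @export
feature_stats <- function(stats) {
  stats <- as.data.frame(stats)
  need <- c("feature", "log2fc", "pvalue")
  missing <- setdiff(need, names(stats))
  if (length(missing) > 0L) {
    stop("feature table lacks column(s): ", paste(missing, collapse = ", "))
  }
  stats$feature <- trimws(toupper(as.character(stats$feature)))
  if (anyDuplicated(stats$feature)) {
    stop(
      "duplicate feature(s): ",
      paste(unique(stats$feature[duplicated(stats$feature)]), collapse = ", ")
    )
  }
  bad <- !is.finite(stats$log2fc)
  if (any(bad)) {
    stop("non-finite log2fc for feature(s): ", paste(stats$feature[bad], collapse = ", "))
  }
  if (any(stats$pvalue < 0 | stats$pvalue > 1 | is.na(stats$pvalue))) {
    stop("pvalue outside [0, 1]")
  }
  stats
}

#' Differential feature set for one cell-line model
#'
#' @param up,down character vectors of up-/down-regulated feature
#'   identifiers; they must not overlap.
#' @param model label for the model (e.g. `"HOS/143B"`).
#' @return An object of class `differential_set`.
#' @export
differential_set <- function(up, down, model = "model") {
  up <- unique(toupper(up))
  down <- unique(toupper(down))
  both <- intersect(up, down)
  if (length(both) > 0L) {
    stop("features in both up and down sets: ", paste(both, collapse = ", "))
  }
  structure(list(model = model, up = up, down = down), class = "differential_set")
}

#' @export
print.differential_set <- function(x, ...) {
  cat(sprintf(
    "<differential_set '%s': %d up, %d down>\n",
    x$model, length(x$up), length(x$down)
  ))
  invisible(x)
}

#' Threshold-based differential selection
#'
#' Applies the two-criterion rule used throughout the pipeline: a feature is
#' called up-regulated when its p-value is below `p_max` and its linear fold
#' change is at least `fc_min`, and down-regulated symmetrically on the
#' reciprocal fold. The fold threshold is inclusive (2-fold or greater) by
#' default; set `strict_fold = TRUE` for a strict inequality.
#'
#' @param stats a [feature_stats()] table.
#' @param p_max p-value threshold (default 0.05).
#' @param fc_min minimal linear fold change (default 2), must exceed 1.
#' @param strict_fold require fold strictly greater than `fc_min`.
#' @param model label passed to the result.
#' @return A [differential_set()].
#' @export
select_differential <- function(stats, p_max = 0.05, fc_min = 2.0,
                                strict_fold = FALSE, model = "model") {
  stats <- feature_stats(stats)
  if (nrow(stats) == 0L) stop("empty feature table")
  if (fc_min <= 1) stop("fc_min must exceed 1")
  lfc_min <- log2(fc_min)
  pass_p <- stats$pvalue < p_max
  if (strict_fold) {
    up <- pass_p & stats$log2fc > lfc_min
    down <- pass_p & -stats$log2fc > lfc_min
  } else {
    up <- pass_p & stats$log2fc >= lfc_min
    down <- pass_p & -stats$log2fc >= lfc_min
  }
  differential_set(stats$feature[up], stats$feature[down], model = model)
}

#' Restrict a statistics table to a feature panel
#'
#' Used for focused analyses such as the glycogene panel: keeps only the
#' rows whose feature appears on the panel, in panel order.
#'
#' @param stats a [feature_stats()] table.
#' @param panel character vector of panel feature identifiers.
#' @return The subset table; empty (with a warning) when nothing overlaps.
#' @export
subset_panel <- function(stats, panel) {
  stats <- feature_stats(stats)
  if (length(panel) == 0L) stop("panel is empty")
  panel <- unique(trimws(toupper(panel)))
  idx <- match(panel, stats$feature)
  idx <- idx[!is.na(idx)]
  if (length(idx) == 0L) {
    warning("no panel feature found in the table")
  }
  out <- stats[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan a protein sequence for N-glycosylation sequons
#'
#' Reports the 1-based positions of every Asn-Xaa-Ser/Thr tripeptide
#' (overlapping matches included). Xaa may be any residue including proline
#' by default; `exclude_proline = TRUE` applies the common refinement that
#' skips Asn-Pro-Ser/Thr.
#'
#' @param seq single amino-acid sequence (character scalar, 20-letter
#'   alphabet, case insensitive).
#' @param exclude_proline drop sequons with proline at the Xaa position.
#' @return Integer vector of sequon start positions, strictly increasing.
#' @export
scan_sequons <- function(seq, exclude_proline = FALSE) {
  stopifnot(is.character(seq), length(seq) == 1L)
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  aa <- c(
    "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"
  )
  bad <- which(!(chars %in% aa))
  if (length(bad) > 0L) {
    stop(sprintf("invalid amino-acid character '%s' at position %d", chars[bad[1L]], bad[1L]))
  }
  n <- length(chars)
  if (n < 3L) return(integer(0))
  p <- seq_len(n - 2L)
  hit <- chars[p] == "N" & chars[p + 2L] %in% c("S", "T")
  if (exclude_proline) hit <- hit & chars[p + 1L] != "P"
  p[hit]
}

#' Scan all sequences of a FASTA file for sequons
#'
#' @param path FASTA file of amino-acid sequences.
#' @param exclude_proline see [scan_sequons()].
#' @return Named list of position vectors, one per sequence record.
#' @export
scan_sequons_fasta <- function(path, exclude_proline = FALSE) {
  seqs <- read_fasta(path)
  lapply(seqs, scan_sequons, exclude_proline = exclude_proline)
}
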