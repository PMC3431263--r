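#' Collapse an RPPA antibody table to one value per protein
#'
#' Reverse phase protein arrays often carry several antibodies against the
#' same protein. For each protein the antibody with the largest absolute
#' log2 expression difference is retained (ties broken by antibody name),
#' preserving the direction of the strongest signal.
#'
#' @param table data.frame with columns `antibody`, `protein`, `log2diff`
#'   (metastatic minus parental log2 expression).
#' @return data.frame with one row per protein: `protein`, `antibody`,
#'   `log2diff`, ordered by protein.
#' @export
collapse_antibodies <- function(table) {
  table <- as.data.frame(table)
  need <- c("antibody", "protein", "log2diff")
  missing <- setdiff(need, names(table))
  if (length(missing) > 0L) {
    stop("RPPA table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(table) == 0L) stop("empty RPPA table")
  if (anyDuplicated(table$antibody)) stop("duplicate antibody identifiers")
  table$protein <- trimws(toupper(as.character(table$protein)))
  ord <- order(table$protein, -abs(table$log2diff), table$antibody)
  table <- table[ord, , drop = FALSE]
  out <- table[!duplicated(table$protein), c("protein", "antibody", "log2diff")]
  rownames(out) <- NULL
  out
}

#' Call up-regulated proteins from per-protein log2 differences
#'
#' A protein is called up-regulated when its log2 expression difference is
#' strictly greater than `threshold`. The default 0.3 corresponds to a
#' linear fold change of 2^0.3 = 1.23, a deliberately permissive cut for
#' the compressed dynamic range of RPPA.
#'
#' @param values named numeric vector (names = proteins) or the data.frame
#'   from [collapse_antibodies()].
#' @param threshold log2 difference cut, must be positive (default 0.3).
#' @return List with `up` (protein character vector), `threshold`, and
#'   `fold_equivalent` (the linear fold 2^threshold).
#' @export
call_upregulated <- function(values, threshold = 0.3) {
  if (threshold <= 0) stop("threshold must be positive")
  if (is.data.frame(values)) {
    v <- stats::setNames(values$log2diff, values$protein)
  } else {
    v <- values
  }
  if (is.null(names(v))) stop("values must be named by protein")
  list(
    up = names(v)[v > threshold],
    threshold = threshold,
    fold_equivalent = 2^threshold
  )
}

#' Counts for the RPPA pathway enrichment test
#'
#' Bundles the six counts of the hypergeometric pathway test: of `N` panel
#' proteins, `K` are called up-regulated; `n` belong to the pathway of
#' interest, of which `k` are up-regulated; `m` and `M` are the not-up
#' complements within the pathway and on the panel.
#'
#' @param k up-regulated proteins in the pathway.
#' @param K up-regulated proteins on the panel.
#' @param n all proteins in the pathway.
#' @param N all proteins on the panel.
#' @return An object of class `hypergeom_input` with fields k, K, m, M, n, N.
#' @export
hypergeom_input <- function(k, K, n, N) {
  inp <- list(k = k, K = K, m = n - k, M = N - K, n = n, N = N)
  if (any(unlist(inp) < 0)) stop("negative count: need k <= n and K <= N")
  if (inp$k > inp$K) stop("violated identity: k <= K (pathway up-calls exceed panel up-calls)")
  if (inp$n > inp$N) stop("violated identity: n <= N (pathway larger than panel)")
  if (inp$m > inp$M) stop("violated identity: m <= M (pathway not-up exceed panel not-up)")
  structure(inp, class = "hypergeom_input")
}

#' Hypergeometric pathway up-regulation test
#'
#' Tests whether a pathway's proteins are preferentially up-regulated on an
#' RPPA panel. Under the null of no preferential up-regulation, the number
#' of up-regulated proteins among the `n` pathway proteins follows the
#' hypergeometric distribution with probability mass
#' `P(X = i) = C(K, i) C(M, n - i) / C(N, n)`; the reported p-value is the
#' upper tail `P(X >= k)`, summed term by term in log space.
#'
#' @param inp a [hypergeom_input()].
#' @return Upper-tail p-value in [0, 1].
#' @export
pathway_hypergeom_test <- function(inp) {
  stopifnot(inherits(inp, "hypergeom_input"))
  i <- seq.int(inp$k, min(inp$K, inp$n))
  if (length(i) == 0L) return(1)
  log_pmf <- lchoose(inp$K, i) + lchoose(inp$M, inp$n - i) - lchoose(inp$N, inp$n)
  min(max(sum(exp(log_pmf)), 0), 1)
}

#' Summarize an RPPA panel against a pathway
#'
#' End-to-end RPPA validation for one pathway: collapse antibodies, call
#' up-regulated proteins, count the pathway overlap and run the
#' hypergeometric test. Fractions are reported as percentages (the pathway
#' up-regulated fraction k/n versus the panel-wide fraction K/N).
#'
#' @param table RPPA antibody table (see [collapse_antibodies()]).
#' @param pathway_proteins character vector of pathway member proteins.
#' @param threshold log2 up-call threshold (default 0.3).
#' @return List with the collapsed table, the [hypergeom_input()] counts,
#'   `pct_up_pathway` (100 k/n), `pct_up_panel` (100 K/N),
#'   `fold_equivalent`, and `pvalue`.
#' @export
rppa_pathway_summary <- function(table, pathway_proteins, threshold = 0.3) {
  collapsed <- collapse_antibodies(table)
  call <- call_upregulated(collapsed, threshold = threshold)
  pathway_proteins <- intersect(unique(toupper(pathway_proteins)), collapsed$protein)
  if (length(pathway_proteins) == 0L) stop("no pathway protein on the panel")
  inp <- hypergeom_input(
    k = length(intersect(call$up, pathway_proteins)),
    K = length(call$up),
    n = length(pathway_proteins),
    N = nrow(collapsed)
  )
  list(
    collapsed = collapsed,
    counts = inp,
    pct_up_pathway = 100 * inp$k / inp$n,
    pct_up_panel = 100 * inp$K / inp$N,
    fold_equivalent = call$fold_equivalent,
    pvalue = pathway_hypergeom_test(inp)
  )
}

#' Read an RPPA antibody table from TSV
#' @param path TSV with header `antibody`, `protein`, `log2diff`.
#' @return data.frame, protein identifiers upper-cased.
#' @export
read_rppa <- function(path) {
  if (!file.exists(path)) stop("RPPA file not found: ", path)
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  x$protein <- trimws(toupper(as.character(x$protein)))
  x
}
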