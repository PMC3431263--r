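#' Read a per-feature statistics table from TSV
#'
#' Expects a header with columns `feature`, `log2fc`, `pvalue`.
#'
#' @param path TSV file.
#' @return A validated [feature_stats()] table.
#' @export
read_feature_stats <- function(path) {
  if (!file.exists(path)) stop("stats file not found: ", path)
  feature_stats(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Write a per-feature statistics table to TSV
#' @param stats a [feature_stats()] table.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_feature_stats <- function(stats, path) {
  utils::write.table(feature_stats(stats), path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Read a feature panel (one identifier per line)
#' @param path text file, `#` comments allowed.
#' @return Character vector of upper-cased identifiers.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  unique(toupper(lines))
}

#' Read amino-acid sequences from FASTA
#'
#' Uses Biostrings when available, otherwise a plain-text fallback.
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    set <- Biostrings::readAAStringSet(path)
    out <- as.character(set)
    names(out) <- sub("\\s.*$", "", names(set))
    return(out)
  }
  lines <- readLines(path, warn = FALSE)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("not a FASTA file: ", path)
  id <- cumsum(hdr)
  seqs <- vapply(
    split(lines[!hdr], id[!hdr]),
    function(x) paste(x, collapse = ""), character(1L)
  )
  names(seqs) <- sub("^>\\s*(\\S+).*$", "\\1", lines[hdr])
  seqs
}

#' Read a pathway collection from a GMT file
#'
#' Standard GMT: one pathway per line, tab-separated fields
#' `name<TAB>description<TAB>member1<TAB>member2...`.
#'
#' @param path GMT file.
#' @param background feature universe; defaults to the union of all pathway
#'   members.
#' @return A [pathway_collection()].
#' @export
read_gmt <- function(path, background = NULL) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short) > 0L) {
    stop(sprintf("malformed GMT line %d: fewer than 3 fields", short[1L]))
  }
  pw <- lapply(fields, function(f) unique(toupper(f[-(1:2)])))
  names(pw) <- vapply(fields, `[[`, character(1L), 1L)
  pathway_collection(pw, background = background)
}

#' Write a pathway collection to GMT
#' @param coll a [pathway_collection()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(coll, path) {
  lines <- vapply(names(coll$pathways), function(nm) {
    paste(c(nm, "na", coll$pathways[[nm]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}
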