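#' Pathway collection
#'
#' Named feature sets over a common background universe. The background is
#' the reference list used for enrichment; by default it is the union of
#' all pathway members, but it should normally be set to all nodes of the
#' interaction network so that enrichment is judged against everything the
#' topological scorer could have returned.
#'
#' @param pathways named list of character vectors (members).
#' @param background feature universe; pathway members outside an explicit
#'   background are trimmed.
#' @return An object of class `pathway_collection`.
#' @export
pathway_collection <- function(pathways, background = NULL) {
  if (length(pathways) == 0L) stop("empty pathway collection")
  if (is.null(names(pathways)) || any(!nzchar(names(pathways)))) {
    stop("pathways must be named")
  }
  if (anyDuplicated(names(pathways))) stop("duplicate pathway names")
  pathways <- lapply(pathways, function(p) unique(toupper(p)))
  if (is.null(background)) {
    background <- sort(unique(unlist(pathways, use.names = FALSE)))
  } else {
    background <- unique(toupper(background))
    pathways <- lapply(pathways, intersect, background)
  }
  sizes <- lengths(pathways)
  if (any(sizes < 2L)) {
    stop(
      "pathway(s) with fewer than 2 members in background: ",
      paste(names(pathways)[sizes < 2L], collapse = ", ")
    )
  }
  structure(
    list(pathways = pathways, background = background),
    class = "pathway_collection"
  )
}

#' @export
print.pathway_collection <- function(x, ...) {
  cat(sprintf(
    "<pathway_collection: %d pathways over %d background features>\n",
    length(x$pathways), length(x$background)
  ))
  invisible(x)
}

#' Hypergeometric pathway over-representation
#'
#' For each pathway, the upper-tail hypergeometric probability of observing
#' at least the seen overlap between the query set and the pathway, drawing
#' `|query|` features from the background. P-values are corrected across
#' pathways by Benjamini-Hochberg, and pathways are ranked by p-value with
#' lexicographic name tie-breaking so top-10 lists are reproducible.
#'
#' @param query character vector of features (e.g. a differential set or
#'   the significant topological nodes); silently intersected with the
#'   background, the intersection must be non-empty.
#' @param coll a [pathway_collection()].
#' @param fdr_max FDR significance cut (default 0.05).
#' @return data.frame ordered by rank with columns `pathway`, `size`,
#'   `overlap`, `p`, `fdr`, `rank`, `significant`.
#' @export
enrich <- function(query, coll, fdr_max = 0.05) {
  stopifnot(inherits(coll, "pathway_collection"))
  query <- intersect(unique(toupper(query)), coll$background)
  if (length(query) == 0L) stop("query has no feature in the background")
  N <- length(coll$background)
  q <- length(query)
  overlap <- vapply(coll$pathways, function(p) length(intersect(p, query)), integer(1L))
  size <- lengths(coll$pathways)
  p <- stats::phyper(overlap - 1L, size, N - size, q, lower.tail = FALSE)
  fdr <- stats::p.adjust(p, method = "BH")
  nm <- names(coll$pathways)
  ord <- order(p, nm)
  out <- data.frame(
    pathway = nm[ord],
    size = size[ord],
    overlap = overlap[ord],
    p = p[ord],
    fdr = fdr[ord],
    rank = seq_along(ord),
    significant = fdr[ord] < fdr_max,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Common pathways between two models' enrichment tables
#'
#' Names appearing among the significant rows of the top `top_k` ranks of
#' both tables, ordered by the sum of their two ranks (ties by name).
#'
#' @param a,b enrichment tables from [enrich()].
#' @param top_k how many top-ranked rows to consider per model (default 10).
#' @param require_significant only consider rows flagged significant.
#' @return Character vector of common pathway names (possibly empty).
#' @export
common_pathways <- function(a, b, top_k = 10L, require_significant = TRUE) {
  pick <- function(tab) {
    tab <- tab[tab$rank <= top_k, , drop = FALSE]
    if (require_significant) tab <- tab[tab$significant, , drop = FALSE]
    tab
  }
  ta <- pick(a)
  tb <- pick(b)
  common <- intersect(ta$pathway, tb$pathway)
  if (length(common) == 0L) return(character(0))
  rsum <- ta$rank[match(common, ta$pathway)] + tb$rank[match(common, tb$pathway)]
  common[order(rsum, common)]
}

#' Random-gene-set false discovery calibration
#'
#' Measures how often given target pathways surface among the top-ranked
#' enrichment results when the whole analysis -- topological scoring
#' followed by enrichment of the significant nodes -- is run on randomly
#' drawn gene sets instead of real differential profiles. A pathway that
#' keeps appearing for random input is being favored by the machinery, not
#' by the data.
#'
#' @param net an [interaction_network()].
#' @param coll a [pathway_collection()].
#' @param target_pathways pathway names whose false discovery rate to report.
#' @param n_sets number of random sets (default 10).
#' @param set_size genes per random set (default 300).
#' @param top_k rank window counting as a discovery (default 10).
#' @param require_significant also require the significance flag for a
#'   discovery (default TRUE): with zero overlap every p is 1 and rank
#'   degenerates to name order, which would count alphabetically early
#'   pathways as discoveries.
#' @param exclude features excluded from sampling (e.g. the real
#'   differentially expressed genes).
#' @param n_resamples,alpha passed to [score_nodes()].
#' @param rng_seed integer seed.
#' @return List with `fdr` (named per-target fraction of sets where the
#'   target ranked in the top `top_k`) and `hits` (logical matrix, sets x
#'   targets).
#' @export
random_set_fdr <- function(net, coll, target_pathways, n_sets = 10L,
                           set_size = 300L, top_k = 10L, exclude = character(0),
                           n_resamples = 100L, alpha = 0.05, rng_seed = NULL,
                           require_significant = TRUE) {
  stopifnot(inherits(net, "interaction_network"), inherits(coll, "pathway_collection"))
  target_pathways <- as.character(target_pathways)
  universe <- setdiff(network_nodes(net), toupper(exclude))
  if (set_size > length(universe)) {
    stop("set_size exceeds the available background universe")
  }
  with_rng_seed(rng_seed, {
    hits <- matrix(FALSE, n_sets, length(target_pathways),
      dimnames = list(NULL, target_pathways)
    )
    for (i in seq_len(n_sets)) {
      rset <- sample(universe, set_size)
      scores <- score_nodes(net, rset,
        n_resamples = n_resamples, alpha = alpha,
        rng_seed = sample.int(.Machine$integer.max, 1L)
      )
      sig <- scores$node[scores$significant]
      if (length(intersect(sig, coll$background)) == 0L) next
      tab <- enrich(sig, coll)
      keep <- tab$rank <= top_k
      if (require_significant) keep <- keep & tab$significant
      top <- tab$pathway[keep]
      hits[i, ] <- target_pathways %in% top
    }
    list(fdr = colMeans(hits), hits = hits)
  })
}
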