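# Run expr with a reproducible RNG state, restoring the caller's stream.
with_rng_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Logarithmic degree bins: nodes of degree d fall in bin floor(log2(d)),
# isolated nodes in their own bin. Returns an integer bin id per node.
degree_bins <- function(degrees) {
  bin <- integer(length(degrees))
  pos <- degrees > 0
  bin[pos] <- floor(log2(degrees[pos])) + 1L
  bin
}

# Draw one degree-matched replacement set: for every seed, a distinct node
# from the same degree bin (falling back to the nearest non-empty bin when
# a bin is exhausted within the resample).
sample_degree_matched <- function(seed_idx, bin, bin_members) {
  chosen <- integer(length(seed_idx))
  taken <- logical(length(bin))
  bins_avail <- as.integer(names(bin_members))
  for (i in seq_along(seed_idx)) {
    b <- bin[seed_idx[i]]
    cand <- bin_members[[as.character(b)]]
    cand <- cand[!taken[cand]]
    if (length(cand) == 0L) {
      ord <- bins_avail[order(abs(bins_avail - b))]
      for (b2 in ord) {
        cand <- bin_members[[as.character(b2)]]
        cand <- cand[!taken[cand]]
        if (length(cand) > 0L) break
      }
      if (length(cand) == 0L) stop("degree-matched resampling exhausted the network")
    }
    pick <- cand[sample.int(length(cand), 1L)]
    chosen[i] <- pick
    taken[pick] <- TRUE
  }
  chosen
}

#' Topological significance scoring of network nodes
#'
#' Scores every network node by its shortest-path participation among a set
#' of differential seed nodes, judged against a degree-matched resampling
#' null. The observed statistic for node v is the total number of shortest
#' paths, over all unordered seed pairs, whose interior contains v (ties all
#' counted; pairs with v as an endpoint excluded, so seed nodes are scored
#' against the remaining seeds). The null redraws, `n_resamples` times, one
#' node per seed from the same logarithmic degree bin (boundaries at powers
#' of two) and recomputes the statistic, so a node is rewarded only for
#' connectivity specific to the seed set, not for being a global hub: a hub
#' connects degree-matched random seed sets just as well, which is what
#' penalizes it.
#'
#' The empirical p-value uses the standard permutation pseudocount,
#' `p = (1 + #\{null >= observed\}) / (n_resamples + 1)`, so p is never zero
#' and is bounded below by `1/(n_resamples + 1)`. No multiplicity correction
#' is applied; significance is a flat cut at `alpha`.
#'
#' @param net an [interaction_network()].
#' @param seeds character vector of seed identifiers; members absent from
#'   the network are dropped with a message, and at least two must remain.
#' @param n_resamples number of degree-matched null resamples (>= 10).
#' @param alpha significance level (default 0.05).
#' @param rng_seed integer seed making the resampling reproducible.
#' @return data.frame with one row per network node: `node`, `degree`,
#'   `is_seed`, `observed`, `null_mean`, `null_sd`, `pvalue`, `significant`.
#' @export
score_nodes <- function(net, seeds, n_resamples = 100L, alpha = 0.05,
                        rng_seed = NULL) {
  stopifnot(inherits(net, "interaction_network"))
  if (n_resamples < 10L) stop("n_resamples must be at least 10")
  nodes <- network_nodes(net)
  seeds <- unique(toupper(seeds))
  missing <- setdiff(seeds, nodes)
  if (length(missing) > 0L) {
    message(sprintf("score_nodes: %d seed(s) absent from the network, dropped", length(missing)))
    seeds <- setdiff(seeds, missing)
  }
  if (length(seeds) < 2L) stop("fewer than 2 seeds present in the network")
  n <- length(nodes)
  adj <- adjacency_index(net)
  degrees <- lengths(adj)
  bin <- degree_bins(degrees)
  bin_members <- split(seq_len(n), bin)

  # BFS results are cached per source node: null resamples revisit sources.
  bfs_cache <- vector("list", n)
  get_bfs <- function(idx) {
    for (s in idx) {
      if (is.null(bfs_cache[[s]])) bfs_cache[[s]] <<- bfs_paths(adj, n, s)
    }
    bfs_cache[idx]
  }

  seed_idx <- match(seeds, nodes)
  obs <- seed_pair_path_counts(get_bfs(seed_idx), seed_idx, n)$paths_through

  with_rng_seed(rng_seed, {
    null_ge <- numeric(n) # count of resamples with null stat >= observed
    null_sum <- numeric(n)
    null_sq <- numeric(n)
    for (r in seq_len(n_resamples)) {
      rs <- sample_degree_matched(seed_idx, bin, bin_members)
      stat <- seed_pair_path_counts(get_bfs(rs), rs, n)$paths_through
      null_ge <- null_ge + (stat >= obs)
      null_sum <- null_sum + stat
      null_sq <- null_sq + stat^2
    }
    null_mean <- null_sum / n_resamples
    null_var <- pmax(null_sq / n_resamples - null_mean^2, 0)
    pvalue <- (1 + null_ge) / (n_resamples + 1)
    data.frame(
      node = nodes,
      degree = degrees,
      is_seed = nodes %in% seeds,
      observed = obs,
      null_mean = null_mean,
      null_sd = sqrt(null_var * n_resamples / max(n_resamples - 1, 1)),
      pvalue = pvalue,
      significant = pvalue < alpha,
      stringsAsFactors = FALSE
    )
  })
}

#' Hidden nodes among the topologically significant ones
#'
#' A hidden node is topologically significant with respect to a model's
#' differential profile while absent from the profile itself -- the
#' signature of regulators acting through post-translational mechanisms or
#' outside the measured subproteome.
#'
#' @param scores output of [score_nodes()].
#' @param direct the model's [differential_set()] (the directly measured
#'   differential features).
#' @return List with `hidden` (character vector), `significant` (character
#'   vector), and `hidden_fraction` (share of significant nodes that are
#'   hidden; 0 when nothing is significant).
#' @export
hidden_nodes <- function(scores, direct) {
  stopifnot(is.data.frame(scores), inherits(direct, "differential_set"))
  sig <- scores$node[scores$significant]
  hid <- setdiff(sig, union(direct$up, direct$down))
  list(
    hidden = hid,
    significant = sig,
    hidden_fraction = if (length(sig) == 0L) 0 else length(hid) / length(sig)
  )
}
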