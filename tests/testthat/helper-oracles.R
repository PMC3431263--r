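# Independent oracles used to freeze expected values. Each one recomputes a
# quantity by brute force or closed form, never through the code path it
# checks.

# Two-sided Fisher exact p by enumerating every 2x2 table with the observed
# margins and summing the probabilities <= the observed table's.
oracle_fisher_2x2 <- function(a, b, c, d) {
  r1 <- a + b
  c1 <- a + c
  n <- a + b + c + d
  prob <- function(x) {
    stats::dhyper(x, c1, n - c1, r1)
  }
  p_obs <- prob(a)
  xs <- max(0, r1 + c1 - n):min(r1, c1)
  sum(prob(xs)[prob(xs) <= p_obs * (1 + 1e-7)])
}

# Literal step-up definition: sort descending, cumulative minimum of
# p * n / rank, mapped back to input order.
oracle_stepup <- function(p) {
  n <- length(p)
  ord <- order(p, decreasing = TRUE)
  adj <- pmin(cummin(p[ord] * n / (n:1)), 1)
  out <- numeric(n)
  out[ord] <- adj
  out
}

# Upper-tail hypergeometric by direct summed PMF with choose().
oracle_hyper_upper <- function(k, K, M, n) {
  i <- k:min(K, n)
  if (length(i) == 0L || k > min(K, n)) return(if (k <= 0) 1 else 0)
  sum(choose(K, i) * choose(M, n - i) / choose(K + M, n))
}

# Upper-tail hypergeometric by enumerating every query of size q from a
# small background and counting queries with overlap >= observed.
oracle_hyper_enumerate <- function(background, pathway, q, min_overlap) {
  combos <- utils::combn(background, q, simplify = FALSE)
  mean(vapply(combos, function(s) length(intersect(s, pathway)) >= min_overlap, logical(1L)))
}

# Exhaustive shortest-path profile: enumerate all shortest paths between
# every unordered seed pair with igraph and count interior visits.
oracle_path_profile <- function(graph, seeds, nodes = igraph::V(graph)$name) {
  paths_through <- stats::setNames(numeric(length(nodes)), nodes)
  covered <- stats::setNames(numeric(length(nodes)), nodes)
  k <- length(seeds)
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      asp <- suppressWarnings(igraph::all_shortest_paths(
        graph,
        from = seeds[i], to = seeds[j]
      )$vpaths)
      if (length(asp) == 0L) next
      interior <- unlist(lapply(asp, function(p) {
        nm <- names(p)
        if (length(nm) <= 2L) character(0) else nm[-c(1L, length(nm))]
      }))
      if (length(interior) == 0L) next
      tab <- table(interior)
      paths_through[names(tab)] <- paths_through[names(tab)] + as.numeric(tab)
      covered[names(tab)] <- covered[names(tab)] + 1
    }
  }
  list(paths_through = paths_through, seed_pairs_covered = covered)
}

# Plain BFS distances (no igraph), for checking shortest_path_lengths.
oracle_bfs_dist <- function(edges, nodes, src) {
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (r in seq_len(nrow(edges))) {
    a <- edges[r, 1L]
    b <- edges[r, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  dist <- stats::setNames(rep(Inf, length(nodes)), nodes)
  dist[src] <- 0
  queue <- src
  while (length(queue) > 0L) {
    v <- queue[1L]
    queue <- queue[-1L]
    for (w in adj[[v]]) {
      if (is.infinite(dist[w])) {
        dist[w] <- dist[v] + 1
        queue <- c(queue, w)
      }
    }
  }
  dist
}

# Independent re-implementation of the topological scorer for tiny
# networks: same resampling contract (so an identical rng_seed yields the
# same null draws), but the statistic comes from exhaustive shortest-path
# enumeration instead of BFS sigma counting.
oracle_score_nodes <- function(net, seeds, n_resamples, rng_seed) {
  g <- net$graph
  nodes <- igraph::V(g)$name
  deg <- igraph::degree(g)
  bin <- ifelse(deg > 0, floor(log2(deg)) + 1, 0)
  members <- split(seq_along(nodes), bin)
  stat_for <- function(seed_names) {
    oracle_path_profile(g, seed_names, nodes)$paths_through
  }
  obs <- stat_for(seeds)
  set.seed(rng_seed)
  ge <- numeric(length(nodes))
  seed_idx <- match(seeds, nodes)
  bins_avail <- as.integer(names(members))
  for (r in seq_len(n_resamples)) {
    taken <- logical(length(nodes))
    chosen <- integer(length(seed_idx))
    for (i in seq_along(seed_idx)) {
      b <- bin[seed_idx[i]]
      cand <- members[[as.character(b)]]
      cand <- cand[!taken[cand]]
      if (length(cand) == 0L) {
        for (b2 in bins_avail[order(abs(bins_avail - b))]) {
          cand <- members[[as.character(b2)]]
          cand <- cand[!taken[cand]]
          if (length(cand) > 0L) break
        }
      }
      pick <- cand[sample.int(length(cand), 1L)]
      chosen[i] <- pick
      taken[pick] <- TRUE
    }
    ge <- ge + (stat_for(nodes[chosen]) >= obs)
  }
  list(observed = unname(obs), pvalue = unname((1 + ge) / (n_resamples + 1)))
}

# Small deterministic Erdos-Renyi-style edge list for distance tests.
random_edge_graph <- function(n, p, seed) {
  set.seed(seed)
  nodes <- sprintf("N%02d", seq_len(n))
  pairs <- utils::combn(nodes, 2L)
  keep <- stats::runif(ncol(pairs)) < p
  list(nodes = nodes, edges = t(pairs[, keep, drop = FALSE]))
}
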