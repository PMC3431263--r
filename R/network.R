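#' Interaction network container
#'
#' An `interaction_network` is a thin wrapper around an undirected, simple
#' [igraph][igraph::igraph-package] graph. Node identifiers are upper-cased
#' gene/protein symbols so that features coming from different omic layers
#' (microarray symbols, proteomic accessions mapped to symbols, RPPA
#' antibody targets) join without case mismatches. The graph carries no edge
#' weights, directions or interaction types: the topological score uses
#' connectivity only.
#'
#' @param edges two-column character matrix or data.frame of endpoints.
#' @param name label for the network.
#' @return An object of class `interaction_network` with elements `graph`
#'   (igraph), `name`, and `dropped_self_loops` (count removed on
#'   construction).
#' @examples
#' net <- interaction_network(cbind(c("a", "b"), c("b", "c")))
#' network_nodes(net)
#' @export
interaction_network <- function(edges, name = "network") {
  edges <- as.matrix(edges)
  if (ncol(edges) < 2L) stop("edge table needs two endpoint columns")
  ends <- cbind(trimws(toupper(edges[, 1L])), trimws(toupper(edges[, 2L])))
  if (any(ends == "")) stop("empty node identifier in edge list")
  self <- ends[, 1L] == ends[, 2L]
  n_self <- sum(self)
  if (n_self > 0L) ends <- ends[!self, , drop = FALSE]
  g <- igraph::graph_from_edgelist(ends, directed = FALSE)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  structure(
    list(graph = g, name = name, dropped_self_loops = n_self),
    class = "interaction_network"
  )
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf(
    "<interaction_network '%s': %d nodes, %d edges>\n",
    x$name, igraph::vcount(x$graph), igraph::ecount(x$graph)
  ))
  invisible(x)
}

#' Nodes and edges of an interaction network
#' @param net an `interaction_network`.
#' @return `network_nodes()`: character vector of node identifiers.
#' @export
network_nodes <- function(net) {
  stopifnot(inherits(net, "interaction_network"))
  igraph::V(net$graph)$name
}

#' @rdname network_nodes
#' @return `network_edges()`: two-column character matrix, each row an
#'   unordered edge with endpoints sorted alphabetically.
#' @export
network_edges <- function(net) {
  stopifnot(inherits(net, "interaction_network"))
  el <- igraph::as_edgelist(net$graph)
  if (nrow(el) == 0L) return(el)
  swap <- el[, 1L] > el[, 2L]
  el[swap, ] <- el[swap, c(2L, 1L)]
  el[order(el[, 1L], el[, 2L]), , drop = FALSE]
}

#' Load an interaction network from an edge-list file
#'
#' Reads a TSV edge list (`nodeA<TAB>nodeB`, `#` comments allowed) or a SIF
#' file (`nodeA<TAB>relation<TAB>nodeB`; the relation column is ignored).
#' Duplicate edges are collapsed, self-loops dropped with a message, and
#' identifiers upper-cased.
#'
#' @param path path to the edge-list file.
#' @param delimiter field separator, default tab.
#' @param format `"auto"` (SIF assumed when every data line has exactly
#'   three fields), `"edgelist"`, or `"sif"`.
#' @param name network label; defaults to the file name.
#' @return An [interaction_network()].
#' @export
load_network <- function(path, delimiter = "\t", format = c("auto", "edgelist", "sif"),
                         name = basename(path)) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("network file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- seq_along(keep)[keep]
  if (length(lines) == 0L) stop("network file is empty: ", path)
  fields <- strsplit(lines, delimiter, fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 2L)
  if (length(bad) > 0L) {
    stop(sprintf(
      "malformed edge line %d in '%s': fewer than 2 fields", lineno[bad[1L]], path
    ))
  }
  if (format == "auto") format <- if (all(nf == 3L)) "sif" else "edgelist"
  a <- vapply(fields, `[[`, character(1L), 1L)
  b <- if (format == "sif") {
    vapply(fields, `[[`, character(1L), 3L)
  } else {
    vapply(fields, `[[`, character(1L), 2L)
  }
  net <- interaction_network(cbind(a, b), name = name)
  if (net$dropped_self_loops > 0L) {
    message(sprintf("load_network: dropped %d self-loop(s)", net$dropped_self_loops))
  }
  net
}

#' Write a network back to a TSV edge list
#' @param net an `interaction_network`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  el <- network_edges(net)
  utils::write.table(el, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

# Internal: integer adjacency list (1-based indices) for fast BFS.
adjacency_index <- function(net) {
  g <- net$graph
  adj <- igraph::as_adj_list(g, mode = "all")
  lapply(adj, as.integer)
}

# Internal: BFS from one source over an integer adjacency list.
# Returns dist (Inf where unreachable) and sigma, the number of distinct
# shortest paths from src to each node (double to avoid integer overflow).
bfs_paths <- function(adj, n, src) {
  dist <- rep(Inf, n)
  sigma <- numeric(n)
  dist[src] <- 0
  sigma[src] <- 1
  frontier <- src
  d <- 0
  while (length(frontier) > 0L) {
    d <- d + 1
    deg <- lengths(adj[frontier])
    nbrs <- unlist(adj[frontier], use.names = FALSE)
    if (length(nbrs) == 0L) break
    contrib <- rep.int(sigma[frontier], deg)
    unvisited <- dist[nbrs] > d # Inf, or d itself is impossible pre-update
    nbrs <- nbrs[unvisited]
    contrib <- contrib[unvisited]
    if (length(nbrs) == 0L) break
    sums <- rowsum(contrib, nbrs)
    idx <- as.integer(rownames(sums))
    dist[idx] <- d
    sigma[idx] <- sums[, 1L]
    frontier <- idx
  }
  list(dist = dist, sigma = sigma)
}

#' Pairwise shortest-path lengths between node sets
#'
#' Unweighted geodesic distances (minimum edge counts) between every source
#' and every target. Unreachable pairs are `Inf`.
#'
#' @param net an `interaction_network`.
#' @param sources,targets character vectors of node identifiers (case
#'   insensitive). Unknown nodes are an error.
#' @return Numeric matrix with sources as rows and targets as columns.
#' @export
shortest_path_lengths <- function(net, sources, targets = sources) {
  stopifnot(inherits(net, "interaction_network"))
  sources <- toupper(sources)
  targets <- toupper(targets)
  nodes <- network_nodes(net)
  unknown <- setdiff(c(sources, targets), nodes)
  if (length(unknown) > 0L) {
    stop("unknown node(s): ", paste(unknown, collapse = ", "))
  }
  igraph::distances(net$graph, v = sources, to = targets)
}

# Internal engine shared by path_profile() and score_nodes(): given BFS
# results from every seed, accumulate per node the number of seed pairs
# with >= 1 shortest path through it and the total shortest-path count
# through it. A node on a pair's endpoint is excluded from that pair.
seed_pair_path_counts <- function(bfs_list, seed_idx, n) {
  paths_through <- numeric(n)
  covered <- numeric(n)
  k <- length(seed_idx)
  for (i in seq_len(k - 1L)) {
    di <- bfs_list[[i]]$dist
    si <- bfs_list[[i]]$sigma
    for (j in (i + 1L):k) {
      dij <- di[seed_idx[j]]
      if (!is.finite(dij)) next
      dj <- bfs_list[[j]]$dist
      sj <- bfs_list[[j]]$sigma
      on_path <- di + dj == dij
      on_path[c(seed_idx[i], seed_idx[j])] <- FALSE
      on_path[is.na(on_path)] <- FALSE
      cnt <- si[on_path] * sj[on_path]
      paths_through[on_path] <- paths_through[on_path] + cnt
      covered[on_path] <- covered[on_path] + 1
    }
  }
  list(paths_through = paths_through, seed_pairs_covered = covered)
}

#' Shortest-path participation profile of a node
#'
#' Counts, over all unordered pairs of seed nodes, the shortest paths whose
#' interior passes through `node`. All tied shortest paths of minimal length
#' are counted, not an arbitrary representative. Pairs having `node` as an
#' endpoint are excluded, so a seed node can itself be profiled against the
#' remaining seeds.
#'
#' @param net an `interaction_network`.
#' @param node node identifier to profile.
#' @param seeds character vector of at least two seed identifiers.
#' @return List with `node`, `seed_pairs_covered` (pairs with at least one
#'   shortest path through the node) and `paths_through` (total shortest
#'   paths through the node).
#' @export
path_profile <- function(net, node, seeds) {
  stopifnot(inherits(net, "interaction_network"))
  node <- toupper(node)
  seeds <- unique(toupper(seeds))
  nodes <- network_nodes(net)
  unknown <- setdiff(c(node, seeds), nodes)
  if (length(unknown) > 0L) {
    stop("unknown node(s): ", paste(unknown, collapse = ", "))
  }
  if (length(seeds) < 2L) stop("insufficient seeds: need at least 2")
  n <- length(nodes)
  adj <- adjacency_index(net)
  seed_idx <- match(seeds, nodes)
  bfs_list <- lapply(seed_idx, function(s) bfs_paths(adj, n, s))
  res <- seed_pair_path_counts(bfs_list, seed_idx, n)
  v <- match(node, nodes)
  list(
    node = node,
    seed_pairs_covered = res$seed_pairs_covered[v],
    paths_through = res$paths_through[v]
  )
}
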