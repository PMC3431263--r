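#' Configuration for a synthetic two-model scenario
#'
#' Describes a fully synthetic study of two isogenic metastatic/parental
#' cell-line models sharing hidden biology: a scale-free interaction
#' network, a pathway collection with a few planted pathways common to both
#' models, per-model differential expression tables whose seed features
#' overlap only weakly between models, spectral-count tables with spiked
#' proteins, and an RPPA layer with pathway-enriched up-regulation. The
#' planted mechanism is the one the direct-versus-topological contrast
#' requires: each planted pathway contains hidden regulator nodes, and the
#' models' differential seeds are network neighbors of those regulators
#' rather than pathway members themselves, so direct enrichment sees
#' nothing while topological scoring recovers the regulators and, through
#' them, the pathways. Each model's up-seeds are split into one group per
#' planted pathway and that pathway's regulators are wired to the whole
#' group, in both models, so regulator connectivity is seed-specific.
#'
#' Effects switch off at their neutral values (`expr_lfc = 0`,
#' `spike_fold = 1`, `rppa_effect = 0`), which turns the corresponding
#' layer into a pure null for calibration checks.
#'
#' @param n_nodes,n_edges network size (preferential attachment, connected).
#' @param n_pathways,pathway_size collection shape.
#' @param n_planted number of planted pathways shared by both models.
#' @param n_hidden_regulators hidden regulator nodes per planted pathway.
#' @param seeds_per_model differential seed features per model and
#'   direction.
#' @param seed_overlap_fraction fraction of seeds shared between the two
#'   models, per direction.
#' @param expr_lfc mean absolute log2 fold change planted on seed features.
#' @param count_depth expected total spectral counts per sample.
#' @param spike_fold linear fold applied to spiked proteins in the
#'   metastatic sample.
#' @param dispersion negative-binomial dispersion of the counts (variance
#'   `mu + dispersion * mu^2`).
#' @param rppa_n_proteins,rppa_n_antibodies RPPA panel shape.
#' @param rppa_effect log2 shift planted on RPPA pathway-member proteins.
#' @param rppa_n_extra_up additional non-pathway panel proteins planted up.
#' @param rng_seed integer seed governing the whole scenario.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(n_nodes = 400L, n_edges = 1200L,
                            n_pathways = 20L, pathway_size = 10L,
                            n_planted = 3L, n_hidden_regulators = 5L,
                            seeds_per_model = 24L, seed_overlap_fraction = 0.1,
                            expr_lfc = 2.0, count_depth = 20000L,
                            spike_fold = 5.0, dispersion = 0.2,
                            rppa_n_proteins = 120L, rppa_n_antibodies = 242L,
                            rppa_effect = 0.8, rppa_n_extra_up = 12L,
                            rng_seed = 11L) {
  cfg <- as.list(environment())
  if (cfg$pathway_size < 3L) stop("pathway_size must be at least 3")
  if (cfg$seed_overlap_fraction < 0 || cfg$seed_overlap_fraction > 1) {
    stop("seed_overlap_fraction must lie in [0, 1]")
  }
  if (cfg$spike_fold < 1) stop("spike_fold must be at least 1")
  if (cfg$dispersion <= 0) stop("dispersion must be positive")
  if (cfg$n_hidden_regulators < 1L) stop("need at least one hidden regulator")
  if (cfg$n_planted > cfg$n_pathways) stop("more planted pathways than pathways")
  if (cfg$rppa_n_antibodies < cfg$rppa_n_proteins) {
    stop("need at least one antibody per RPPA protein")
  }
  structure(cfg, class = "scenario_config")
}

#' Generate a connected scale-free interaction network
#'
#' Preferential attachment: nodes arrive one at a time and attach to an
#' existing node with probability proportional to degree + 1 (giving a
#' spanning tree), then the remaining edges are added between
#' degree-weighted endpoint pairs. The result has exactly the requested
#' node and edge counts and a heavy-tailed degree distribution.
#'
#' @param cfg a [scenario_config()] (only `n_nodes`, `n_edges`, `rng_seed`
#'   are used), or pass the sizes directly.
#' @param n_nodes,n_edges,rng_seed overrides of the config values.
#' @return An [interaction_network()].
#' @export
generate_network <- function(cfg = scenario_config(), n_nodes = cfg$n_nodes,
                             n_edges = cfg$n_edges, rng_seed = cfg$rng_seed) {
  if (n_nodes < 2L) stop("need at least 2 nodes")
  if (n_edges < n_nodes - 1L) stop("too few edges for a connected graph")
  if (n_edges > n_nodes * (n_nodes - 1L) / 2) stop("more edges than node pairs")
  names <- sprintf("G%04d", seq_len(n_nodes))
  with_rng_seed(rng_seed, {
    deg <- integer(n_nodes)
    from <- integer(n_edges)
    to <- integer(n_edges)
    # tree phase
    for (v in 2:n_nodes) {
      u <- sample.int(v - 1L, 1L, prob = deg[seq_len(v - 1L)] + 1)
      from[v - 1L] <- u
      to[v - 1L] <- v
      deg[u] <- deg[u] + 1L
      deg[v] <- deg[v] + 1L
    }
    seen <- new.env(hash = TRUE, parent = emptyenv())
    for (i in seq_len(n_nodes - 1L)) {
      assign(paste(from[i], to[i]), TRUE, envir = seen)
    }
    e <- n_nodes - 1L
    while (e < n_edges) {
      a <- sample.int(n_nodes, 1L, prob = deg + 1)
      b <- sample.int(n_nodes, 1L, prob = deg + 1)
      if (a == b) next
      key <- paste(min(a, b), max(a, b))
      if (exists(key, envir = seen, inherits = FALSE)) next
      assign(key, TRUE, envir = seen)
      e <- e + 1L
      from[e] <- min(a, b)
      to[e] <- max(a, b)
      deg[a] <- deg[a] + 1L
      deg[b] <- deg[b] + 1L
    }
    interaction_network(cbind(names[from], names[to]), name = "synthetic")
  })
}

# Split a seed budget into shared + model-specific draws from a pool.
draw_model_seeds <- function(pool, per_model, overlap_fraction) {
  n_shared <- round(overlap_fraction * per_model)
  n_own <- per_model - n_shared
  need <- n_shared + 2L * n_own
  if (length(pool) < need) stop("pathway capacity too small for the requested seeds")
  picked <- sample(pool, need)
  shared <- picked[seq_len(n_shared)]
  a <- c(shared, picked[n_shared + seq_len(n_own)])
  b <- c(shared, picked[n_shared + n_own + seq_len(n_own)])
  list(a = a, b = b, shared = shared)
}

#' Generate a full synthetic two-model scenario
#'
#' Builds every input layer of the pipeline plus a ground-truth record.
#' See [scenario_config()] for the planted structure.
#'
#' @param cfg a [scenario_config()].
#' @return List of class `scenario` with elements `network`,
#'   `pathways` (a [pathway_collection()]), `stats` (named list of two
#'   [feature_stats()] tables), `counts` (named list of two spectral-count
#'   tables), `rppa` (named list of two antibody tables), `truth` (planted
#'   pathways, hidden regulators, per-model seed sets, spiked proteins,
#'   RPPA up truth), and `config`.
#' @export
generate_scenario <- function(cfg = scenario_config()) {
  stopifnot(inherits(cfg, "scenario_config"))
  net <- generate_network(cfg)
  nodes <- network_nodes(net)
  models <- c("modelA", "modelB")

  with_rng_seed(cfg$rng_seed + 1L, {
    # hidden regulators and planted pathways; regulators are drawn from the
    # low-degree half of the network so their connectivity is specific to
    # the seeds, not inherited from a pre-existing hub role
    n_reg <- cfg$n_planted * cfg$n_hidden_regulators
    deg <- igraph::degree(net$graph)
    low <- nodes[deg <= stats::median(deg)]
    regulators <- sample(low, n_reg)
    reg_by_pathway <- split(regulators, rep(seq_len(cfg$n_planted), each = cfg$n_hidden_regulators))
    other <- setdiff(nodes, regulators)
    pathways <- vector("list", cfg$n_pathways)
    names(pathways) <- sprintf("PW%02d", seq_len(cfg$n_pathways))
    for (i in seq_len(cfg$n_planted)) {
      fill <- sample(other, cfg$pathway_size - cfg$n_hidden_regulators)
      pathways[[i]] <- c(reg_by_pathway[[i]], fill)
    }
    if (cfg$n_pathways > cfg$n_planted) {
      for (i in seq.int(cfg$n_planted + 1L, cfg$n_pathways)) {
        pathways[[i]] <- sample(other, cfg$pathway_size)
      }
    }
    planted_names <- names(pathways)[seq_len(cfg$n_planted)]

    # seeds: neighbors-to-be of the hidden regulators, never pathway members
    pathway_members <- unique(unlist(pathways, use.names = FALSE))
    pool <- setdiff(nodes, pathway_members)
    up <- draw_model_seeds(pool, cfg$seeds_per_model, cfg$seed_overlap_fraction)
    pool_dn <- setdiff(pool, c(up$a, up$b))
    dn <- draw_model_seeds(pool_dn, cfg$seeds_per_model, cfg$seed_overlap_fraction)
    seeds <- list(
      modelA = list(up = up$a, down = dn$a),
      modelB = list(up = up$b, down = dn$b)
    )

    # wiring: each model's up seeds are partitioned into one group per
    # planted pathway, and every regulator of a pathway is wired to all of
    # its group's seeds in both models. Grouping keeps each regulator's
    # connectivity specific to a coherent seed subset; wiring every
    # regulator to most seeds would make the two models' seed sets each
    # other's degree-matched twins and wash out the null contrast.
    grp <- rep(seq_len(cfg$n_planted), length.out = cfg$seeds_per_model)
    extra <- list()
    for (m in models) {
      groups <- split(seeds[[m]]$up, grp)
      for (i in seq_len(cfg$n_planted)) {
        for (h in reg_by_pathway[[i]]) {
          extra[[length(extra) + 1L]] <- cbind(h, groups[[i]])
        }
      }
    }
    net <- interaction_network(
      rbind(network_edges(net), do.call(rbind, extra)),
      name = "synthetic"
    )

    coll <- pathway_collection(pathways, background = nodes)

    # expression layer
    stats <- lapply(models, function(m) {
      lfc <- stats::rnorm(length(nodes), 0, 0.2)
      pv <- stats::runif(length(nodes))
      if (cfg$expr_lfc > 0) {
        iu <- match(seeds[[m]]$up, nodes)
        id <- match(seeds[[m]]$down, nodes)
        lfc[iu] <- cfg$expr_lfc + stats::rnorm(length(iu), 0, 0.25)
        lfc[id] <- -cfg$expr_lfc + stats::rnorm(length(id), 0, 0.25)
        pv[c(iu, id)] <- stats::runif(length(iu) + length(id), 1e-6, 1e-3)
      }
      feature_stats(data.frame(feature = nodes, log2fc = lfc, pvalue = pv))
    })
    names(stats) <- models

    # spectral-count layer: spiked proteins are the model's seed features
    counts <- lapply(models, function(m) {
      w <- stats::rgamma(length(nodes), shape = 1.2)
      mu <- cfg$count_depth * w / sum(w)
      fold <- rep(1, length(nodes))
      if (cfg$spike_fold > 1) {
        fold[match(seeds[[m]]$up, nodes)] <- cfg$spike_fold
        fold[match(seeds[[m]]$down, nodes)] <- 1 / cfg$spike_fold
      }
      size <- 1 / cfg$dispersion
      data.frame(
        protein = nodes,
        count_metastatic = stats::rnbinom(length(nodes), mu = mu * fold, size = size),
        count_parental = stats::rnbinom(length(nodes), mu = mu, size = size),
        stringsAsFactors = FALSE
      )
    })
    names(counts) <- models

    # RPPA layer: panel contains the first planted pathway's members
    validation_members <- pathways[[1L]]
    panel <- c(
      validation_members,
      sample(setdiff(nodes, validation_members), cfg$rppa_n_proteins - length(validation_members))
    )
    rppa_up_truth <- c(
      validation_members,
      sample(setdiff(panel, validation_members), min(cfg$rppa_n_extra_up, cfg$rppa_n_proteins - length(validation_members)))
    )
    if (cfg$rppa_effect <= 0) rppa_up_truth <- character(0)
    n_extra_ab <- cfg$rppa_n_antibodies - cfg$rppa_n_proteins
    ab_protein <- c(panel, sample(panel, n_extra_ab, replace = TRUE))
    rppa <- lapply(models, function(m) {
      base <- stats::setNames(stats::rnorm(cfg$rppa_n_proteins, 0, 0.08), panel)
      base[rppa_up_truth] <- cfg$rppa_effect + stats::rnorm(length(rppa_up_truth), 0, 0.08)
      data.frame(
        antibody = sprintf("AB%03d", seq_len(cfg$rppa_n_antibodies)),
        protein = ab_protein,
        log2diff = base[ab_protein] + stats::rnorm(cfg$rppa_n_antibodies, 0, 0.03),
        stringsAsFactors = FALSE
      )
    })
    names(rppa) <- models

    structure(list(
      network = net,
      pathways = coll,
      stats = stats,
      counts = counts,
      rppa = rppa,
      truth = list(
        planted_pathways = planted_names,
        hidden_regulators = regulators,
        model_seeds = seeds,
        spiked_proteins = lapply(seeds, function(s) if (cfg$spike_fold > 1) s else list(up = character(0), down = character(0))),
        rppa_up_truth = rppa_up_truth,
        rppa_panel = panel
      ),
      config = cfg
    ), class = "scenario")
  })
}

#' Write a scenario to plain-text files
#'
#' Emits `network.tsv`, `pathways.gmt`, per-model `stats_<model>.tsv` and
#' `counts_<model>.tsv`, per-model `rppa_<model>.tsv`, and `truth.json`.
#'
#' @param scn a [generate_scenario()] result.
#' @param outdir output directory, created if needed.
#' @return `outdir`, invisibly.
#' @export
write_scenario <- function(scn, outdir) {
  stopifnot(inherits(scn, "scenario"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_network(scn$network, file.path(outdir, "network.tsv"))
  write_gmt(scn$pathways, file.path(outdir, "pathways.gmt"))
  for (m in names(scn$stats)) {
    write_feature_stats(scn$stats[[m]], file.path(outdir, sprintf("stats_%s.tsv", m)))
    utils::write.table(scn$counts[[m]], file.path(outdir, sprintf("counts_%s.tsv", m)),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    utils::write.table(scn$rppa[[m]], file.path(outdir, sprintf("rppa_%s.tsv", m)),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  jsonlite::write_json(scn$truth, file.path(outdir, "truth.json"), auto_unbox = TRUE)
  invisible(outdir)
}
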