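# Enrichment that degrades to NULL instead of erroring on an empty query:
# the pipeline reports "no features" rather than aborting a whole stage.
enrich_or_null <- function(query, coll, ...) {
  if (length(intersect(toupper(query), coll$background)) == 0L) return(NULL)
  enrich(query, coll, ...)
}

common_or_empty <- function(a, b, top_k = 10L) {
  if (is.null(a) || is.null(b)) return(character(0))
  common_pathways(a, b, top_k = top_k)
}

#' Direct-layer analysis of two or more models
#'
#' Threshold selection on each model's feature statistics, per-direction
#' pathway enrichment, the common-pathway lists, and the pairwise
#' concordance report (first model pair).
#'
#' @param models named list (>= 2) of [feature_stats()] tables.
#' @param coll a [pathway_collection()].
#' @param p_max,fc_min thresholds for [select_differential()].
#' @param top_k rank window for [common_pathways()].
#' @return List with `differential` (per-model [differential_set()]),
#'   `enrichment` (per model, `up`/`down` tables or NULL when a set is
#'   empty), `common` (`up`/`down` name vectors for the first model pair),
#'   and `concordance` (a [compare_sets()] report, or NULL when every set
#'   is empty).
#' @export
run_direct <- function(models, coll, p_max = 0.05, fc_min = 2.0, top_k = 10L) {
  if (length(models) < 2L) stop("need at least 2 models")
  if (is.null(names(models))) names(models) <- paste0("model", seq_along(models))
  diffsets <- lapply(names(models), function(m) {
    select_differential(models[[m]], p_max = p_max, fc_min = fc_min, model = m)
  })
  names(diffsets) <- names(models)
  enr <- lapply(diffsets, function(ds) {
    list(
      up = enrich_or_null(ds$up, coll),
      down = enrich_or_null(ds$down, coll)
    )
  })
  m1 <- names(models)[1L]
  m2 <- names(models)[2L]
  empty_all <- all(vapply(diffsets, function(d) length(d$up) + length(d$down) == 0L, logical(1L)))
  list(
    differential = diffsets,
    enrichment = enr,
    common = list(
      up = common_or_empty(enr[[m1]]$up, enr[[m2]]$up, top_k),
      down = common_or_empty(enr[[m1]]$down, enr[[m2]]$down, top_k)
    ),
    concordance = if (empty_all) NULL else compare_sets(diffsets[[m1]], diffsets[[m2]])
  )
}

#' Topological-layer analysis of two or more models
#'
#' For each model and direction, runs [score_nodes()] with the model's
#' differential features as seeds, enriches the significant topological
#' nodes, computes per-model hidden fractions, the common-pathway lists,
#' and the concordance between the models' significant-node sets.
#'
#' @param diffsets named list (>= 2) of [differential_set()] objects.
#' @param net an [interaction_network()].
#' @param coll a [pathway_collection()].
#' @param n_resamples,alpha passed to [score_nodes()].
#' @param top_k rank window for [common_pathways()].
#' @param rng_seed integer seed (one stream drives all scoring runs).
#' @return List with `scores` (per model, `up`/`down` score tables),
#'   `significant` (per model, per-direction node vectors), `enrichment`,
#'   `common` (`up`/`down`), `hidden` (per model: hidden node set and
#'   fraction over both directions), and `concordance`.
#' @export
run_topological <- function(diffsets, net, coll, n_resamples = 100L,
                            alpha = 0.05, top_k = 10L, rng_seed = NULL) {
  if (length(diffsets) < 2L) stop("need at least 2 models")
  if (is.null(names(diffsets))) names(diffsets) <- paste0("model", seq_along(diffsets))
  nodes <- network_nodes(net)
  feats <- unique(unlist(lapply(diffsets, function(d) c(d$up, d$down))))
  cover <- length(intersect(feats, nodes)) / max(length(feats), 1L)
  if (cover < 0.5) {
    warning(sprintf("network covers only %.0f%% of the differential features", 100 * cover))
  }
  with_rng_seed(rng_seed, {
    res <- lapply(names(diffsets), function(m) {
      ds <- diffsets[[m]]
      out <- list()
      for (dir in c("up", "down")) {
        seeds <- intersect(ds[[dir]], nodes)
        if (length(seeds) < 2L) {
          stop(sprintf("model %s: no usable %s-seed intersection with the network", m, dir))
        }
        out[[dir]] <- score_nodes(net, seeds,
          n_resamples = n_resamples, alpha = alpha,
          rng_seed = sample.int(.Machine$integer.max, 1L)
        )
      }
      out
    })
    names(res) <- names(diffsets)
    sig <- lapply(res, function(r) lapply(r, function(s) s$node[s$significant]))
    enr <- lapply(sig, function(s) {
      list(up = enrich_or_null(s$up, coll), down = enrich_or_null(s$down, coll))
    })
    hidden <- lapply(names(diffsets), function(m) {
      direct <- union(diffsets[[m]]$up, diffsets[[m]]$down)
      all_sig <- union(sig[[m]]$up, sig[[m]]$down)
      hid <- setdiff(all_sig, direct)
      list(
        hidden = hid,
        hidden_fraction = if (length(all_sig) == 0L) 0 else length(hid) / length(all_sig)
      )
    })
    names(hidden) <- names(diffsets)
    m1 <- names(diffsets)[1L]
    m2 <- names(diffsets)[2L]
    node_sets <- lapply(names(diffsets), function(m) {
      differential_set(sig[[m]]$up, setdiff(sig[[m]]$down, sig[[m]]$up), model = m)
    })
    names(node_sets) <- names(diffsets)
    list(
      scores = res,
      significant = sig,
      enrichment = enr,
      common = list(
        up = common_or_empty(enr[[m1]]$up, enr[[m2]]$up, top_k),
        down = common_or_empty(enr[[m1]]$down, enr[[m2]]$down, top_k)
      ),
      hidden = hidden,
      concordance = compare_sets(node_sets[[m1]], node_sets[[m2]])
    )
  })
}

run_stage <- function(name, fun) {
  tryCatch(
    list(status = "ok", result = fun()),
    error = function(e) list(status = "error", message = conditionMessage(e), result = NULL)
  )
}

#' Run the full two-model pipeline on a synthetic scenario
#'
#' Generates (or accepts) a scenario, then runs the direct layer, the
#' topological layer, the random-gene-set FDR calibration, and the RPPA
#' pathway test, collecting everything into a single report. Stage
#' failures are recorded per stage rather than aborting the run.
#'
#' @param cfg a [scenario_config()], or a path to a YAML file with the
#'   config fields.
#' @param scenario optionally, a pre-built [generate_scenario()] result
#'   (overrides `cfg`).
#' @param n_resamples,alpha topological scoring parameters.
#' @param fdr_sets,fdr_set_size random-set calibration size (kept small by
#'   default; the calibration scales to the scenario, not to a genome).
#' @param top_k rank window for common-pathway calls.
#' @return List of class `pipeline_report` with elements `config`,
#'   `stages` (per-stage status), `direct`, `topological`, `random_fdr`,
#'   `rppa`, and `summary` (flat named numbers: set sizes, concordances,
#'   hidden fractions, common-pathway counts, RPPA p-values).
#' @export
run_full <- function(cfg = scenario_config(), scenario = NULL,
                     n_resamples = 100L, alpha = 0.05,
                     fdr_sets = 5L, fdr_set_size = 30L, top_k = 10L) {
  if (is.character(cfg)) cfg <- do.call(scenario_config, yaml::read_yaml(cfg))
  stopifnot(inherits(cfg, "scenario_config"))
  scn <- if (is.null(scenario)) generate_scenario(cfg) else scenario
  stages <- list()

  stages$direct <- run_stage("direct", function() {
    run_direct(scn$stats, scn$pathways, top_k = top_k)
  })
  direct <- stages$direct$result

  stages$topological <- run_stage("topological", function() {
    if (is.null(direct)) stop("direct stage failed")
    run_topological(direct$differential, scn$network, scn$pathways,
      n_resamples = n_resamples, alpha = alpha, top_k = top_k,
      rng_seed = cfg$rng_seed + 2L
    )
  })
  topo <- stages$topological$result

  stages$random_fdr <- run_stage("random_fdr", function() {
    exclude <- if (is.null(direct)) character(0) else {
      unique(unlist(lapply(direct$differential, function(d) c(d$up, d$down))))
    }
    random_set_fdr(scn$network, scn$pathways,
      target_pathways = scn$truth$planted_pathways,
      n_sets = fdr_sets, set_size = fdr_set_size, top_k = top_k,
      exclude = exclude, n_resamples = n_resamples, alpha = alpha,
      rng_seed = cfg$rng_seed + 3L
    )
  })

  stages$rppa <- run_stage("rppa", function() {
    validation <- scn$pathways$pathways[[scn$truth$planted_pathways[1L]]]
    lapply(scn$rppa, rppa_pathway_summary, pathway_proteins = validation)
  })

  summary <- list()
  if (!is.null(direct)) {
    for (m in names(direct$differential)) {
      summary[[paste0("n_up_", m)]] <- length(direct$differential[[m]]$up)
      summary[[paste0("n_down_", m)]] <- length(direct$differential[[m]]$down)
    }
    summary$direct_common_up <- length(direct$common$up)
    summary$direct_common_down <- length(direct$common$down)
    if (!is.null(direct$concordance)) {
      summary$direct_overall_pct <- direct$concordance$overall_pct
    }
  }
  if (!is.null(topo)) {
    summary$topo_common_up <- length(topo$common$up)
    summary$topo_common_down <- length(topo$common$down)
    summary$topo_overall_pct <- topo$concordance$overall_pct
    for (m in names(topo$hidden)) {
      summary[[paste0("hidden_fraction_", m)]] <- topo$hidden[[m]]$hidden_fraction
    }
  }
  if (stages$random_fdr$status == "ok") {
    summary$random_set_fdr <- stages$random_fdr$result$fdr
  }
  if (stages$rppa$status == "ok") {
    for (m in names(stages$rppa$result)) {
      summary[[paste0("rppa_p_", m)]] <- stages$rppa$result[[m]]$pvalue
    }
  }

  structure(list(
    config = unclass(cfg),
    stages = lapply(stages, function(s) s[c("status", "message")[c(TRUE, s$status != "ok")]]),
    direct = direct,
    topological = topo,
    random_fdr = stages$random_fdr$result,
    rppa = stages$rppa$result,
    summary = summary,
    provenance = list(
      package_version = as.character(utils::packageVersion("hiddenpath")),
      rng_seed = cfg$rng_seed,
      timestamp = NULL
    )
  ), class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  for (nm in names(x$stages)) {
    cat(sprintf("  stage %-12s %s\n", nm, x$stages[[nm]]$status))
  }
  s <- x$summary
  flat <- unlist(s)
  for (nm in names(flat)) cat(sprintf("  %-28s %s\n", nm, format(flat[[nm]], digits = 4)))
  invisible(x)
}

#' Write a pipeline report to JSON
#'
#' Serializes the summary, stage statuses, config and provenance (not the
#' full intermediate tables) to a JSON file.
#'
#' @param report a [run_full()] report.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "pipeline_report"))
  jsonlite::write_json(
    list(
      config = report$config,
      stages = report$stages,
      summary = report$summary,
      provenance = report$provenance
    ),
    path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
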