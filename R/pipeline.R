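# End-to-end workflow: ensembles -> metrics -> geometry/statistics ->
# tabular report.

#' Analysis configuration
#'
#' Collects the tunable constants of the full workflow with the
#' conventional defaults: 100 surrogates per ensemble kind, top-15% hubs,
#' 1 mm profile bins, a 21-point density grid from 0.05 to 1, alpha 0.01.
#'
#' @param n_surrogates Ensemble size per kind (0 skips ensembles and all
#'   normalized sections).
#' @param tol,max_iter Strength-restoration controls.
#' @param hub_fraction Hub fraction for hub analyses.
#' @param resolution Louvain resolution.
#' @param empirical_restarts,surrogate_restarts Louvain restarts for
#'   empirical graphs and for each ensemble member.
#' @param densities Density grid for binary efficiency sweeps.
#' @param bin_width Profile bin width, mm.
#' @param alpha Significance level after correction.
#' @param n_perm Permutations for permutation tests.
#' @return A named list of class `analysis_config`.
#' @export
analysis_config <- function(n_surrogates = 100,
                            tol = 1e-3,
                            max_iter = 1000,
                            hub_fraction = 0.15,
                            resolution = 1,
                            empirical_restarts = 100,
                            surrogate_restarts = 10,
                            densities = seq(0.05, 1, length.out = 21),
                            bin_width = 1,
                            alpha = 0.01,
                            n_perm = 999) {
  structure(
    list(
      n_surrogates = n_surrogates, tol = tol, max_iter = max_iter,
      hub_fraction = hub_fraction, resolution = resolution,
      empirical_restarts = empirical_restarts,
      surrogate_restarts = surrogate_restarts, densities = densities,
      bin_width = bin_width, alpha = alpha, n_perm = n_perm
    ),
    class = "analysis_config"
  )
}

#' Binary efficiency versus network density, with surrogate normalisation
#'
#' Thresholds the weighted graph to each density, computes global
#' efficiency for the empirical graph and every surrogate ensemble member,
#' and normalizes the empirical value by each ensemble mean. Per density,
#' the empirical value's two-sided rank p within each ensemble and a
#' permutation test between the geometric and random ensemble
#' distributions are reported.
#'
#' @param w Symmetric weight matrix (or [spatial_graph()]).
#' @param densities Densities in (0, 1\].
#' @param ensembles Named list of `surrogate_ensemble`s (typically
#'   `geometric` and `random`); may be empty.
#' @param n_perm,seed Permutation-test controls.
#' @return Tibble: one row per density with `efficiency`, per-ensemble
#'   means, ratios, rank p-values and the cross-ensemble permutation p.
#' @export
efficiency_sweep <- function(w, densities, ensembles = list(), n_perm = 999,
                             seed = 1L) {
  if (inherits(w, "spatial_graph")) w <- w$weights
  if (length(densities) == 0) {
    return(tibble(density = numeric(), efficiency = numeric()))
  }
  if (any(densities <= 0 | densities > 1)) {
    stop_invalid("densities must lie in (0, 1]")
  }
  rows <- lapply(seq_along(densities), function(di) {
    d <- densities[di]
    e_emp <- global_efficiency(threshold_to_density(w, d))
    row <- tibble(density = d, efficiency = e_emp)
    ens_vals <- list()
    for (nm in names(ensembles)) {
      vals <- map_dbl(
        ensembles[[nm]]$matrices,
        function(m) global_efficiency(threshold_to_density(m, d))
      )
      ens_vals[[nm]] <- vals
      n_e <- length(vals)
      p_rank <- 2 * min(
        (1 + sum(vals >= e_emp)) / (n_e + 1),
        (1 + sum(vals <= e_emp)) / (n_e + 1)
      )
      row[[paste0("mean_", nm)]] <- mean(vals)
      row[[paste0("ratio_", nm)]] <- normalized_metric_ratio(e_emp, vals)
      row[[paste0("p_rank_", nm)]] <- min(p_rank, 1)
    }
    if (all(c("geometric", "random") %in% names(ens_vals))) {
      row$p_geo_vs_rand <- permutation_test(
        ens_vals$geometric, ens_vals$random,
        n_perm = n_perm, seed = as.integer(seed) + di
      )$p_value
    }
    row
  })
  bind_rows(rows)
}

q_analysis <- function(w, ensembles, config, seed) {
  emp <- louvain_partition(w,
    seed = seed, resolution = config$resolution,
    n_restarts = config$empirical_restarts
  )
  out <- list(
    empirical_partition = emp,
    q = tibble(q_empirical = emp$Q)
  )
  if (length(ensembles)) {
    parts <- list()
    for (nm in names(ensembles)) {
      pl <- imap(
        ensembles[[nm]]$matrices,
        function(m, i) {
          louvain_partition(m,
            seed = seed + i, resolution = config$resolution,
            n_restarts = config$surrogate_restarts
          )
        }
      )
      parts[[nm]] <- pl
      qs <- map_dbl(pl, "Q")
      out$q[[paste0("q_", nm, "_mean")]] <- mean(qs)
      out$q[[paste0("q_", nm, "_sd")]] <- sd(qs)
      out$q[[paste0("ratio_", nm)]] <- normalized_metric_ratio(emp$Q, qs)
      out$q[[paste0("p_", nm)]] <-
        (1 + sum(qs >= emp$Q)) / (length(qs) + 1)
      out[[paste0("q_values_", nm)]] <- qs
    }
    if (!is.null(parts$geometric)) {
      cons <- consensus_partition(parts$geometric, emp, w = w)
      out$geo_consensus <- cons
      out$q$geo_consensus_agreement <- partition_agreement(cons, emp)
    }
    out$surrogate_partitions <- parts
  }
  out
}

hub_analysis <- function(graph, ensembles, config, seed) {
  w <- graph$weights
  fd <- graph$fiber_distances
  strengths <- node_strengths(w)
  ec <- eigenvector_centrality(w)
  hubs_s <- identify_hubs(strengths, config$hub_fraction, "strength")
  hubs_e <- identify_hubs(ec, config$hub_fraction, "eigenvector")
  dn <- mean_neighbor_fiber_distance(w, fd)
  com_hub <- com_distances(graph$coordinates, graph$volumes, hubs_s)
  com_all <- com_distances(graph$coordinates, graph$volumes)
  feeders_e <- setdiff(seq_len(nrow(w)), hubs_e$indices)
  res <- list(
    hubs_strength = hubs_s,
    hubs_eigenvector = hubs_e,
    division_table = hub_strength_by_division(strengths, hubs_s, graph$division),
    summary = tibble(
      hub_com_distance = mean(com_hub),
      nonhub_com_distance = mean(com_all[-hubs_s$indices]),
      hub_dneighbors = mean(dn[hubs_e$indices], na.rm = TRUE),
      feeder_dneighbors = mean(dn[feeders_e], na.rm = TRUE)
    )
  )
  if (length(ensembles)) {
    for (nm in names(ensembles)) {
      mats <- ensembles[[nm]]$matrices
      per_surr <- lapply(mats, function(m) {
        hs <- identify_hubs(node_strengths(m), config$hub_fraction, "strength")
        he <- identify_hubs(eigenvector_centrality(m), config$hub_fraction, "eigenvector")
        dnm <- mean_neighbor_fiber_distance(m, fd)
        list(
          com = com_distances(graph$coordinates, graph$volumes, hs),
          hub_dn = dnm[he$indices],
          feed_dn = dnm[setdiff(seq_len(nrow(m)), he$indices)]
        )
      })
      surr_com <- unlist(lapply(per_surr, `[[`, "com"))
      surr_hub_dn <- unlist(lapply(per_surr, `[[`, "hub_dn"))
      surr_feed_dn <- unlist(lapply(per_surr, `[[`, "feed_dn"))
      res$summary[[paste0("hub_com_distance_", nm)]] <- mean(surr_com)
      res$summary[[paste0("hub_dneighbors_", nm)]] <- mean(surr_hub_dn, na.rm = TRUE)
      res$summary[[paste0("feeder_dneighbors_", nm)]] <- mean(surr_feed_dn, na.rm = TRUE)
      res[[paste0("com_test_", nm)]] <- tukey_range_test(list(
        empirical_hubs = com_hub,
        surrogate_hubs = surr_com
      ))
      res[[paste0("dneighbors_test_", nm)]] <- tukey_range_test(list(
        empirical_hubs = dn[hubs_e$indices],
        empirical_feeders = dn[feeders_e],
        surrogate_hubs = surr_hub_dn,
        surrogate_feeders = surr_feed_dn
      ))
    }
  }
  res
}

#' Run the full geometric-surrogate analysis workflow
#'
#' For every input graph: builds geometric and random surrogate ensembles,
#' computes modularity (raw, surrogate-normalized, consensus modules),
#' participation, hub organisation (center-of-mass peripherality, neighbor
#' fiber distances, division composition), binned weight-distance profiles
#' and binary efficiency sweeps; when a reference graph is designated,
#' edge-weight agreement (overall and per division pair), module-assignment
#' agreement and profile significance versus the reference are added. The
#' run is a pure function of (graphs, config, seed).
#'
#' @param graphs Named list of [spatial_graph()]s (>= 1).
#' @param reference Name of the reference graph for cross-graph
#'   comparisons, or `NULL`.
#' @param config An [analysis_config()].
#' @param seed Master seed; all per-graph and per-surrogate seeds derive
#'   from it.
#' @return An `analysis_report`: nested list of tibbles (see
#'   [write_report()]), with the resolved config and seeds embedded.
#' @export
run_analysis <- function(graphs, reference = NULL,
                         config = analysis_config(), seed = 1L) {
  if (!is.list(graphs) || length(graphs) == 0 || is.null(names(graphs))) {
    stop_invalid("graphs must be a nonempty named list of spatial_graph objects")
  }
  if (!all(map_lgl(graphs, inherits, "spatial_graph"))) {
    stop_invalid("graphs must be spatial_graph objects")
  }
  if (!is.null(reference) && !reference %in% names(graphs)) {
    stop_invalid("reference graph '", reference, "' not among the inputs")
  }
  seed <- as.integer(seed)
  per_graph <- list()
  for (gi in seq_along(graphs)) {
    name <- names(graphs)[gi]
    graph <- graphs[[gi]]
    gseed <- seed + 1000L * gi
    ensembles <- list()
    trend <- fit_trend(graph)
    if (config$n_surrogates > 0) {
      ensembles$geometric <- build_ensemble(graph,
        n = config$n_surrogates,
        kind = "geometric", base_seed = gseed, tol = config$tol,
        max_iter = config$max_iter, model = trend
      )
      ensembles$random <- build_ensemble(graph,
        n = config$n_surrogates,
        kind = "random", base_seed = gseed + 500000L, tol = config$tol,
        max_iter = config$max_iter
      )
    }
    qres <- q_analysis(graph$weights, ensembles, config, gseed)
    hubres <- hub_analysis(graph, ensembles, config, gseed)
    prof <- binned_weight_profile(
      zscore_log_weights(graph), graph$fiber_distances, config$bin_width
    )
    eff <- efficiency_sweep(graph, config$densities, ensembles,
      n_perm = config$n_perm, seed = gseed
    )
    cpl <- bind_rows(lapply(config$densities, function(d) {
      mutate(
        clustering_and_path_length(threshold_to_density(graph$weights, d)),
        density = d, .before = 1
      )
    }))
    participation <- node_centralities(graph, qres$empirical_partition)
    per_graph[[name]] <- list(
      trend = trend,
      ensembles = ensembles,
      modularity = qres,
      hubs = hubres,
      profile = prof,
      efficiency = eff,
      clustering_path = cpl,
      centralities = participation,
      seed = gseed
    )
  }
  comparison <- NULL
  if (!is.null(reference)) {
    ref_graph <- graphs[[reference]]
    others <- setdiff(names(graphs), reference)
    weight_cmp <- bind_rows(lapply(others, function(nm) {
      mutate(
        division_weight_agreement(
          graphs[[nm]]$weights, ref_graph$weights,
          ref_graph$division, ref_graph$hemisphere
        ),
        graph = nm, .before = 1
      )
    }))
    ref_part <- per_graph[[reference]]$modularity$empirical_partition
    module_cmp <- bind_rows(lapply(others, function(nm) {
      aligned <- align_labels(
        per_graph[[nm]]$modularity$empirical_partition, ref_part
      )
      tibble(
        graph = nm,
        agreement_with_reference = partition_agreement(aligned, ref_part)
      )
    }))
    profile_cmp <- NULL
    if (length(others) >= 2) {
      profile_cmp <- compare_profiles(
        lapply(others, function(nm) per_graph[[nm]]$profile),
        per_graph[[reference]]$profile,
        alpha = config$alpha
      )
    }
    comparison <- list(
      weight_agreement = weight_cmp,
      module_agreement = module_cmp,
      profile_comparison = profile_cmp
    )
  }
  structure(
    list(
      graphs = per_graph,
      comparison = comparison,
      reference = reference,
      config = config,
      seed = seed,
      package_version = as.character(utils::packageVersion("geonull"))
    ),
    class = "analysis_report"
  )
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf(
    "<analysis_report> %d graph(s)%s, seed %d\n",
    length(x$graphs),
    if (!is.null(x$reference)) paste0(", reference '", x$reference, "'") else "",
    x$seed
  ))
  for (nm in names(x$graphs)) {
    q <- x$graphs[[nm]]$modularity$q
    cat(sprintf(
      "  %s: Q = %.3f%s\n", nm, q$q_empirical,
      if (!is.null(q$ratio_geometric)) {
        sprintf(
          " (Q/Q_geo = %.3f, Q/Q_rand = %.3f)",
          q$ratio_geometric, q$ratio_random
        )
      } else {
        ""
      }
    ))
  }
  invisible(x)
}

report_payload <- function(report) {
  per_graph <- lapply(report$graphs, function(g) {
    out <- list(
      trend = list(
        cubic_coeffs = g$trend$cubic_coeffs,
        spread_coeffs = g$trend$spread_coeffs,
        n_edges_fit = g$trend$n_edges_fit,
        excluded_zero_edges = g$trend$excluded_zero_edges
      ),
      modularity = g$modularity$q,
      empirical_partition = g$modularity$empirical_partition$assignment,
      hub_summary = g$hubs$summary,
      hub_divisions = g$hubs$division_table,
      hub_indices_strength = g$hubs$hubs_strength$indices,
      hub_indices_eigenvector = g$hubs$hubs_eigenvector$indices,
      profile = as_tibble(g$profile),
      efficiency = g$efficiency,
      clustering_path = g$clustering_path,
      centralities = g$centralities,
      seed = g$seed
    )
    for (nm in grep("^(com_test_|dneighbors_test_)", names(g$hubs), value = TRUE)) {
      out[[nm]] <- g$hubs[[nm]]
    }
    if (length(g$ensembles)) {
      out$ensemble_diagnostics <- bind_rows(lapply(g$ensembles, tidy))
      out$geo_consensus_partition <- g$modularity$geo_consensus$assignment
    }
    out
  })
  list(
    graphs = per_graph,
    comparison = report$comparison,
    reference = report$reference,
    config = unclass(report$config),
    seed = report$seed,
    package_version = report$package_version
  )
}

#' Serialize an analysis report
#'
#' Writes `report.json` (full numeric precision; the serialization is a
#' pure function of the report, so identical runs give identical bytes)
#' plus per-graph TSV tables for the profile, efficiency and centrality
#' tibbles.
#'
#' @param report An `analysis_report`.
#' @param dir Output directory.
#' @return Invisibly, the path to `report.json`.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "analysis_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, "report.json")
  write_json(report_payload(report), path,
    auto_unbox = TRUE, digits = NA,
    null = "null", dataframe = "columns"
  )
  for (nm in names(report$graphs)) {
    g <- report$graphs[[nm]]
    for (tbl in c("profile", "efficiency", "clustering_path", "centralities")) {
      write.table(as.data.frame(g[[tbl]]),
        file.path(dir, paste0(nm, "_", tbl, ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE
      )
    }
  }
  invisible(path)
}
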