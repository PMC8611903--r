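# ggplot2 views of the main result types.

#' Plot the weight-distance relationship and fitted trend
#'
#' Scatter of log-weights versus fiber distance for the positive edges,
#' with the fitted cubic trend and the +/- 1 spread band.
#'
#' @param graph A [spatial_graph()].
#' @param model Optional `trend_model` (fitted on the fly otherwise).
#' @param max_edges Edges to draw (subsampled deterministically when the
#'   graph has more).
#' @return A ggplot object.
#' @export
plot_weight_distance <- function(graph, model = NULL, max_edges = 5000) {
  ed <- edge_table(graph)
  model <- model %||% fit_trend(graph)
  if (nrow(ed) > max_edges) {
    ed <- ed[round(seq(1, nrow(ed), length.out = max_edges)), ]
  }
  grid <- tibble(
    f = seq(min(ed$fiber_distance_mm), max(ed$fiber_distance_mm),
      length.out = 200
    )
  )
  grid$g <- predict_trend(model, grid$f)
  grid$h <- predict_spread(model, grid$f)
  ggplot(ed, aes(x = .data$fiber_distance_mm, y = log(.data$weight))) +
    geom_point(alpha = 0.2, size = 0.5) +
    geom_ribbon(
      data = grid,
      aes(
        x = .data$f, ymin = .data$g - .data$h, ymax = .data$g + .data$h,
        y = NULL
      ),
      fill = "steelblue", alpha = 0.3
    ) +
    geom_line(data = grid, aes(x = .data$f, y = .data$g), color = "steelblue") +
    labs(
      x = "fiber distance (mm)", y = "log weight",
      title = "Weight-distance relationship and cubic trend"
    )
}

#' @method autoplot binned_profile
#' @export
autoplot.binned_profile <- function(object, ...) {
  dat <- as_tibble(object) |>
    mutate(mid = (.data$bin_lo + .data$bin_hi) / 2)
  ggplot(dat, aes(x = .data$mid, y = .data$mean)) +
    geom_hline(yintercept = 0, linetype = 2, color = "grey60") +
    geom_pointrange(aes(
      ymin = .data$mean - .data$sd,
      ymax = .data$mean + .data$sd
    )) +
    labs(
      x = "fiber distance bin (mm)", y = "log-weight z-score",
      title = "Binned weight-distance profile"
    )
}

#' @method autoplot surrogate_ensemble
#' @export
autoplot.surrogate_ensemble <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$iterations, y = .data$strength_error)) +
    geom_point(aes(color = .data$converged)) +
    scale_y_log10() +
    labs(
      x = "restoration sweeps", y = "max relative strength error",
      title = sprintf("%s ensemble convergence", object$kind)
    )
}

#' Efficiency-density curves from a sweep
#'
#' @param sweep Tibble from [efficiency_sweep()].
#' @return A ggplot object showing raw and surrogate-normalized global
#'   efficiency against density.
#' @export
plot_efficiency_sweep <- function(sweep) {
  value_cols <- intersect(
    c("efficiency", "ratio_geometric", "ratio_random"), names(sweep)
  )
  long <- pivot_longer(sweep,
    cols = dplyr::all_of(value_cols),
    names_to = "curve", values_to = "value"
  )
  ggplot(long, aes(x = .data$density, y = .data$value, color = .data$curve)) +
    geom_line() +
    geom_point(size = 0.8) +
    labs(
      x = "network density", y = "global efficiency (raw or ratio)",
      title = "Binary global efficiency vs density"
    )
}

#' Spatial scatter of hubs and modules
#'
#' Simple 2-D projections of node positions colored by module and sized by
#' hub membership.
#'
#' @param graph A [spatial_graph()].
#' @param partition Optional `module_partition` for coloring.
#' @param hubs Optional `hub_set` for sizing.
#' @param plane Projection plane: "axial" (x-y), "sagittal" (y-z) or
#'   "coronal" (x-z).
#' @return A ggplot object.
#' @export
plot_node_map <- function(graph, partition = NULL, hubs = NULL,
                          plane = c("axial", "sagittal", "coronal")) {
  plane <- match.arg(plane)
  axes <- switch(plane,
    axial = c(1, 2),
    sagittal = c(2, 3),
    coronal = c(1, 3)
  )
  dat <- tibble(
    a = graph$coordinates[, axes[1]],
    b = graph$coordinates[, axes[2]],
    module = if (!is.null(partition)) {
      factor(as_membership_vec(partition, nrow(graph$weights)))
    } else {
      factor(1)
    },
    hub = if (!is.null(hubs)) {
      seq_len(nrow(graph$weights)) %in% hubs$indices
    } else {
      FALSE
    }
  )
  lab <- list(
    axial = c("x (mm)", "y (mm)"), sagittal = c("y (mm)", "z (mm)"),
    coronal = c("x (mm)", "z (mm)")
  )[[plane]]
  ggplot(dat, aes(x = .data$a, y = .data$b, color = .data$module)) +
    geom_point(aes(size = .data$hub), alpha = 0.8) +
    scale_size_manual(values = c(`FALSE` = 1, `TRUE` = 3)) +
    coord_equal() +
    labs(x = lab[1], y = lab[2], title = paste(plane, "node map"))
}
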