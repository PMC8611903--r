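# Synthetic spatially embedded benchmark graphs with known ground truth.
#
# The generator emulates the statistical structure of mesoscale mouse
# connectomes: ~286 bilaterally mirrored regions in an ellipsoidal brain,
# near-fully-connected, log-weights declining with fiber distance along a
# cubic trend with heteroscedastic residuals, plus optional planted module
# and peripheral-hub signals with known ground truth.

#' Specification for a synthetic benchmark graph
#'
#' Defaults describe a mouse-brain-like network: 286 regions in a
#' 5.7 x 4.1 x 3.3 mm semi-axis ellipsoid, fiber distances a tortuous
#' (tau = 1.3), jittered version of the Euclidean distances, and a cubic
#' log-weight trend declining ~7 natural-log units across the distance
#' range so that, with unit residual noise, weights span roughly five
#' orders of magnitude.
#'
#' @param n_nodes Even node count (bilateral pairing), default 286.
#' @param semi_axes Ellipsoid semi-axes (x right, y anterior, z superior),
#'   mm.
#' @param tau Tortuosity multiplier on Euclidean distances (>= 1).
#' @param jitter Lognormal SD of multiplicative fiber-distance jitter.
#' @param trend_coeffs Cubic coefficients of the log-weight trend g
#'   (increasing powers of distance, natural log).
#' @param sigma Residual noise SD in log-weight units at the reference
#'   distance scale.
#' @param sigma_gradient Linear increase of the residual SD with distance:
#'   `sd(f) = sigma * (0.75 + sigma_gradient * f / f_ref)` with
#'   `f_ref = 2 * tau * max(semi_axes)`; 0 gives homoscedastic noise.
#' @param modules Planted module signal: "none", "intrinsic" (boost the
#'   Louvain modules of the unplanted graph — spatially coherent, as real
#'   brain modules are) or "random" (spatially random bilateral modules).
#' @param n_modules Module count for `modules = "random"`.
#' @param module_boost Intra-module log-weight boost beta_m (natural log).
#' @param hub_fraction Fraction of nodes planted as peripheral hubs (0
#'   disables planting).
#' @param hub_boost Hub-edge log-weight boost beta_h.
#' @param hub_profile "distance" (default) boosts hub edges by
#'   `beta_h * (0.5 + f / fbar)`, concentrating the extra weight on
#'   long-range connections as tracer-measured hubs do; "uniform" adds a
#'   flat `beta_h`.
#' @param volume_meanlog,volume_sdlog Lognormal region-volume parameters.
#' @param seed Master seed; every draw derives from it.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_nodes = 286,
                           semi_axes = c(5.7, 4.1, 3.3),
                           tau = 1.3,
                           jitter = 0.1,
                           trend_coeffs = c(0, -0.63, 0.014, -0.0002074),
                           sigma = 1,
                           sigma_gradient = 0.5,
                           modules = c("none", "intrinsic", "random"),
                           n_modules = 4,
                           module_boost = 1,
                           hub_fraction = 0,
                           hub_boost = 1,
                           hub_profile = c("distance", "uniform"),
                           volume_meanlog = log(1.5),
                           volume_sdlog = 0.6,
                           seed = 1L) {
  modules <- match.arg(modules)
  hub_profile <- match.arg(hub_profile)
  if (n_nodes %% 2 != 0 || n_nodes < 4) stop_invalid("n_nodes must be even and >= 4")
  if (tau < 1) stop_invalid("tortuosity tau must be >= 1")
  if (sigma < 0 || jitter < 0) stop_invalid("noise SDs must be nonnegative")
  if (module_boost < 0 || hub_boost < 0) stop_invalid("boosts must be nonnegative")
  structure(
    list(
      n_nodes = as.integer(n_nodes), semi_axes = semi_axes, tau = tau,
      jitter = jitter, trend_coeffs = trend_coeffs, sigma = sigma,
      sigma_gradient = sigma_gradient, modules = modules,
      n_modules = as.integer(n_modules), module_boost = module_boost,
      hub_fraction = hub_fraction, hub_boost = hub_boost,
      hub_profile = hub_profile, volume_meanlog = volume_meanlog,
      volume_sdlog = volume_sdlog, seed = as.integer(seed)
    ),
    class = "synthetic_spec"
  )
}

# symmetric standard-normal matrix, zero diagonal
sym_noise <- function(n) {
  e <- matrix(rnorm(n * n), n)
  e <- (e + t(e)) / sqrt(2)
  diag(e) <- 0
  e
}

#' Sample bilaterally mirrored node layout
#'
#' Half the nodes are rejection-sampled uniformly in the right
#' half-ellipsoid (x > 0, off the midsagittal plane); the other half are
#' their mirror images across x = 0. Volumes are lognormal; homolog pairs
#' are the mirror partners. Divisions are 12 anterior-to-posterior slabs of
#' equal node count, mirrored across hemispheres.
#'
#' @param spec A [synthetic_spec()].
#' @return List: `coordinates`, `volumes`, `region_ids`, `hemisphere`,
#'   `division`, `homolog`.
#' @export
generate_nodes <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_nodes
  half <- n %/% 2L
  ax <- spec$semi_axes
  with_seed(spec$seed, {
    pts <- matrix(NA_real_, half, 3)
    got <- 0
    while (got < half) {
      p <- runif(3, -1, 1)
      if (sum(p^2) <= 1 && p[1] > 0.02) {
        got <- got + 1
        pts[got, ] <- p * ax
      }
    }
    vols_half <- rlnorm(half, spec$volume_meanlog, spec$volume_sdlog)
    coords <- rbind(pts, pts * rep(c(-1, 1, 1), each = half))
    divisions_half <- paste0(
      "division_",
      sprintf("%02d", as.integer(cut(rank(pts[, 2], ties.method = "first"),
        breaks = 12, labels = FALSE
      )))
    )
    list(
      coordinates = coords,
      volumes = c(vols_half, vols_half),
      region_ids = c(
        sprintf("region_%03d_R", seq_len(half)),
        sprintf("region_%03d_L", seq_len(half))
      ),
      hemisphere = rep(c("R", "L"), each = half),
      division = c(divisions_half, divisions_half),
      homolog = c(seq_len(half) + half, seq_len(half))
    )
  })
}

#' Synthetic fiber distances
#'
#' `f_ij = tau * ||x_i - x_j|| * exp(jitter * eta_ij)` with symmetric
#' standard-normal `eta`, floored at the Euclidean distance so fiber paths
#' are never shorter than straight lines.
#'
#' @param coords N x 3 coordinates, mm.
#' @param tau Tortuosity (>= 1).
#' @param jitter Lognormal jitter SD.
#' @param seed Integer seed.
#' @return Symmetric fiber-distance matrix, zero diagonal.
#' @export
fiber_distances <- function(coords, tau = 1.3, jitter = 0.1, seed = 1L) {
  if (tau < 1) stop_invalid("tau must be >= 1")
  eu <- as.matrix(dist(coords))
  fd <- with_seed(as.integer(seed), tau * eu * exp(jitter * sym_noise(nrow(eu))))
  fd <- pmax(fd, eu)
  diag(fd) <- 0
  fd
}

#' Synthetic weights from a distance trend
#'
#' `log w_ij = g(f_ij) + sd(f_ij) * eps_ij` with symmetric standard-normal
#' noise; the resulting graph is fully connected with approximately
#' log-normal weights declining along the cubic trend.
#'
#' @param f Fiber-distance matrix.
#' @param trend_coeffs Cubic coefficients of g (increasing powers).
#' @param sigma,sigma_gradient Residual noise scale and its linear
#'   distance gradient (see [synthetic_spec()]).
#' @param f_ref Reference distance for the noise gradient.
#' @param seed Integer seed.
#' @return Symmetric positive weight matrix, zero diagonal.
#' @export
generate_weights <- function(f, trend_coeffs, sigma = 1, sigma_gradient = 0.5,
                             f_ref = max(f), seed = 1L) {
  check_symmetric(f, what = "fiber_distances")
  n <- nrow(f)
  lw <- eval_poly(trend_coeffs, f)
  sd_f <- sigma * (0.75 + sigma_gradient * f / f_ref)
  w <- with_seed(as.integer(seed), exp(lw + sd_f * sym_noise(n)))
  diag(w) <- 0
  dimnames(w) <- dimnames(f)
  w
}

#' Plant a module signal into a weight matrix
#'
#' Boosts intra-module log-weights by `beta_m` (multiplicative in weight
#' space, preserving log-normality).
#'
#' @param w Symmetric weight matrix.
#' @param partition Module assignment (vector or `module_partition`).
#' @param beta_m Intra-module log-weight boost.
#' @return Boosted symmetric matrix.
#' @export
plant_modules <- function(w, partition, beta_m = 1) {
  check_symmetric(w, what = "weights")
  memb <- as_membership_vec(partition, nrow(w))
  out <- w * exp(beta_m * outer(memb, memb, "=="))
  diag(out) <- 0
  out
}

#' Plant peripheral hubs into a weight matrix
#'
#' Selects the `round(fraction * N)` nodes farthest from the
#' volume-weighted brain center of mass and boosts the log-weights of
#' their incident edges (doubly for hub-hub edges). The default "distance"
#' profile adds `beta_h * (0.5 + f/fbar)` per incident hub — concentrating
#' the planted strength on long-range edges, the signature of peripheral
#' tracer hubs; "uniform" adds a flat `beta_h`.
#'
#' @param w Symmetric weight matrix.
#' @param coords N x 3 coordinates.
#' @param volumes Node volumes (center-of-mass weights).
#' @param f Fiber-distance matrix (needed for the "distance" profile).
#' @param fraction Hub fraction, default 0.15.
#' @param beta_h Log-weight boost.
#' @param profile "distance" (default) or "uniform".
#' @return List: `weights` (boosted matrix), `hubs` (a `hub_set` of the
#'   planted nodes).
#' @export
plant_peripheral_hubs <- function(w, coords, volumes, f = NULL,
                                  fraction = 0.15, beta_h = 1,
                                  profile = c("distance", "uniform")) {
  profile <- match.arg(profile)
  check_symmetric(w, what = "weights")
  n <- nrow(w)
  dcom <- com_distances(coords, volumes)
  k <- round(fraction * n)
  planted <- sort(order(-dcom, seq_len(n))[seq_len(k)])
  incid <- matrix(0, n, n)
  incid[planted, ] <- incid[planted, ] + 1
  incid[, planted] <- incid[, planted] + 1
  boost <- if (profile == "uniform") {
    beta_h * incid
  } else {
    if (is.null(f)) stop_invalid("the distance profile needs fiber distances")
    fbar <- mean(f[upper.tri(f)])
    beta_h * incid * (0.5 + f / fbar)
  }
  out <- w * exp(boost)
  diag(out) <- 0
  list(
    weights = out,
    hubs = structure(
      list(
        indices = planted, fraction = fraction, measure = "planted",
        threshold_value = if (k > 0) sort(dcom, decreasing = TRUE)[k] else Inf
      ),
      class = "hub_set"
    )
  )
}

#' Generate a complete synthetic benchmark with ground truth
#'
#' Composes node layout, fiber distances, trend-driven weights and the
#' optional planted module/hub signals into a [spatial_graph()] plus a
#' ground-truth record. Fully reproducible from the spec's seed. With
#' `modules = "intrinsic"` the planted partition is the Louvain partition
#' of the unplanted graph, whose boost then reinforces the network's own
#' spatially coherent community structure.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Optional directory; when given, the fixture TSV files and a
#'   ground-truth JSON are written there.
#' @return List with `graph` (a `spatial_graph`) and `truth` (list:
#'   `partition`, `hubs`, `trend_coeffs`, `seed`; empty fields when
#'   nothing is planted).
#' @export
make_benchmark <- function(spec = synthetic_spec(), dir = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  nodes <- generate_nodes(spec)
  fd <- fiber_distances(nodes$coordinates,
    tau = spec$tau, jitter = spec$jitter,
    seed = spec$seed + 1L
  )
  w <- generate_weights(fd, spec$trend_coeffs,
    sigma = spec$sigma,
    sigma_gradient = spec$sigma_gradient,
    f_ref = 2 * spec$tau * max(spec$semi_axes),
    seed = spec$seed + 2L
  )
  truth <- list(
    partition = NULL, hubs = NULL,
    trend_coeffs = spec$trend_coeffs, seed = spec$seed
  )
  if (spec$modules == "intrinsic") {
    part <- louvain_partition(w, seed = spec$seed + 3L, n_restarts = 20)
    w <- plant_modules(w, part, spec$module_boost)
    truth$partition <- part
  } else if (spec$modules == "random") {
    half <- spec$n_nodes %/% 2
    memb_half <- with_seed(
      spec$seed + 3L,
      sample(rep(seq_len(spec$n_modules), length.out = half))
    )
    part <- module_partition(c(memb_half, memb_half))
    w <- plant_modules(w, part, spec$module_boost)
    truth$partition <- part
  }
  if (spec$hub_fraction > 0) {
    planted <- plant_peripheral_hubs(w, nodes$coordinates, nodes$volumes,
      f = fd, fraction = spec$hub_fraction,
      beta_h = spec$hub_boost, profile = spec$hub_profile
    )
    w <- planted$weights
    truth$hubs <- planted$hubs
  }
  graph <- spatial_graph(
    weights = w, fiber_distances = fd,
    coordinates = nodes$coordinates, volumes = nodes$volumes,
    region_ids = nodes$region_ids, hemisphere = nodes$hemisphere,
    division = nodes$division, homolog = nodes$homolog
  )
  if (!is.null(dir)) {
    write_spatial_graph(graph, dir, prefix = "benchmark")
    truth_json <- list(
      partition = if (!is.null(truth$partition)) truth$partition$assignment,
      hub_indices = if (!is.null(truth$hubs)) truth$hubs$indices,
      trend_coeffs = truth$trend_coeffs,
      seed = truth$seed
    )
    write_json(truth_json, file.path(dir, "benchmark_truth.json"),
      auto_unbox = TRUE, digits = NA, null = "null"
    )
  }
  list(graph = graph, truth = truth)
}
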