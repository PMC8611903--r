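# Labeled-TSV I/O for spatial graphs.
#
# Dialect: dense numeric TSV, UTF-8, '.' decimal, mandatory header row and
# leading region_id column for matrices; parcellation TSV with columns
# region_id, name, division, hemisphere, homolog_id, x_mm, y_mm, z_mm,
# volume_mm3.

write_labeled_matrix <- function(M, path) {
  df <- data.frame(region_id = rownames(M), format(M, digits = 17, trim = TRUE),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  write.table(df, path,
    sep = "\t", quote = FALSE, row.names = FALSE,
    fileEncoding = "UTF-8"
  )
}

read_labeled_matrix <- function(path, what = basename(path)) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop_invalid(what, ": expected region_id column plus matrix")
  ids <- as.character(df[[1]])
  M <- as.matrix(df[, -1, drop = FALSE])
  mode(M) <- "numeric"
  if (any(is.na(M))) stop_invalid(what, " contains NA/NaN entries")
  if (nrow(M) != ncol(M)) stop_invalid(what, " is not square")
  if (!identical(ids, colnames(M))) {
    stop_invalid(what, ": row and column labels disagree")
  }
  rownames(M) <- ids
  M
}

#' Read a spatial graph from labeled TSV files
#'
#' Expects a weight matrix, fiber-distance matrix and parcellation table in
#' the package's TSV dialect (see [write_spatial_graph()]). Matrix rows and
#' columns are reordered to parcellation order if they arrive permuted;
#' asymmetries beyond 1e-9 and dimension mismatches are rejected with the
#' offending entries named.
#'
#' @param weights_path,distances_path Paths to dense labeled TSV matrices.
#' @param parcellation_path Path to the parcellation TSV.
#' @return A [spatial_graph()].
#' @export
read_spatial_graph <- function(weights_path, distances_path, parcellation_path) {
  parc <- read_parcellation(parcellation_path)
  align_to_parc <- function(M, what) {
    if (nrow(M) != nrow(parc)) {
      stop_invalid(sprintf(
        "%s has %d regions but parcellation has %d", what, nrow(M), nrow(parc)
      ))
    }
    if (!setequal(rownames(M), parc$region_id)) {
      stop_invalid(what, " region labels do not match the parcellation")
    }
    ord <- match(parc$region_id, rownames(M))
    M <- M[ord, ord]
    check_symmetric(M, tol = 1e-9, what = what)
    (M + t(M)) / 2 # exact symmetry downstream
  }
  W <- align_to_parc(read_labeled_matrix(weights_path, "weight matrix"), "weight matrix")
  FD <- align_to_parc(
    read_labeled_matrix(distances_path, "fiber-distance matrix"),
    "fiber-distance matrix"
  )
  homolog <- match(parc$homolog_id, parc$region_id)
  if (any(is.na(homolog))) stop_invalid("homolog_id values that resolve to no region")
  spatial_graph(
    weights = W, fiber_distances = FD,
    coordinates = as.matrix(parc[, c("x_mm", "y_mm", "z_mm")]),
    volumes = parc$volume_mm3, region_ids = parc$region_id,
    hemisphere = parc$hemisphere, division = parc$division, homolog = homolog
  )
}

#' Write a spatial graph as labeled TSV files
#'
#' @param graph A [spatial_graph()].
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix, default "graph".
#' @return Invisibly, a named character vector of the three file paths
#'   (`weights`, `distances`, `parcellation`).
#' @export
write_spatial_graph <- function(graph, dir, prefix = "graph") {
  stopifnot(inherits(graph, "spatial_graph"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    weights = file.path(dir, paste0(prefix, "_weights.tsv")),
    distances = file.path(dir, paste0(prefix, "_distances.tsv")),
    parcellation = file.path(dir, paste0(prefix, "_parcellation.tsv"))
  )
  write_labeled_matrix(graph$weights, paths[["weights"]])
  write_labeled_matrix(graph$fiber_distances, paths[["distances"]])
  parc <- data.frame(
    region_id = graph$region_ids,
    name = graph$region_ids,
    division = graph$division,
    hemisphere = graph$hemisphere,
    homolog_id = graph$region_ids[graph$homolog],
    x_mm = format(graph$coordinates[, 1], digits = 17, trim = TRUE),
    y_mm = format(graph$coordinates[, 2], digits = 17, trim = TRUE),
    z_mm = format(graph$coordinates[, 3], digits = 17, trim = TRUE),
    volume_mm3 = format(graph$volumes, digits = 17, trim = TRUE),
    stringsAsFactors = FALSE
  )
  write.table(parc, paths[["parcellation"]],
    sep = "\t", quote = FALSE,
    row.names = FALSE, fileEncoding = "UTF-8"
  )
  invisible(paths)
}

#' Read a parcellation table
#'
#' @param path Parcellation TSV with columns region_id, name, division,
#'   hemisphere, homolog_id, x_mm, y_mm, z_mm, volume_mm3.
#' @return A tibble, one row per region, validated (unique ids, homologs
#'   resolving to the opposite hemisphere).
#' @export
read_parcellation <- function(path) {
  parc <- as_tibble(read.delim(path, check.names = FALSE, stringsAsFactors = FALSE))
  needed <- c(
    "region_id", "name", "division", "hemisphere", "homolog_id",
    "x_mm", "y_mm", "z_mm", "volume_mm3"
  )
  missing_cols <- setdiff(needed, names(parc))
  if (length(missing_cols)) {
    stop_invalid("parcellation lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  parc$region_id <- as.character(parc$region_id)
  parc$homolog_id <- as.character(parc$homolog_id)
  if (anyDuplicated(parc$region_id)) stop_invalid("duplicate region_id values")
  hom <- match(parc$homolog_id, parc$region_id)
  if (any(is.na(hom))) stop_invalid("homolog_id values that resolve to no region")
  if (any(parc$hemisphere[hom] == parc$hemisphere)) {
    stop_invalid("homolog_id must point to the opposite hemisphere")
  }
  parc
}

#' Export a thresholded binary graph as an edge list
#'
#' @param adjacency Binary symmetric adjacency with region-id dimnames.
#' @param path Output TSV path (two label columns).
#' @return Invisibly, the edge-list tibble.
#' @export
write_edge_list <- function(adjacency, path) {
  check_symmetric(adjacency, what = "adjacency")
  ids <- rownames(adjacency) %||% as.character(seq_len(nrow(adjacency)))
  iu <- which(upper.tri(adjacency) & adjacency > 0, arr.ind = TRUE)
  el <- tibble(from = ids[iu[, 1]], to = ids[iu[, 2]])
  write.table(el, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(el)
}
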