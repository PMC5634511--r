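#' Monthly water balance (runoff) per cell
#'
#' Runoff available for routing is rainfall minus actual evapotranspiration,
#' floored at zero: cells where evapotranspiration exceeds rainfall contribute
#' no water.
#'
#' @param precip precipitation, mm (vector or matrix, non-negative).
#' @param aet actual evapotranspiration, mm (same shape, non-negative).
#' @return runoff in mm, same shape as the inputs.
#' @export
#' @examples
#' water_balance(100, 40)  # 60
#' water_balance(30, 50)   # 0
water_balance <- function(precip, aet) {
  if (any(precip < 0)) stop("precip must be non-negative")
  if (any(aet < 0)) stop("aet must be non-negative")
  pmax(precip - aet, 0)
}

#' Fraction of a cell tagged as impacted by people or livestock
#'
#' The human part assumes each person contaminates 3.65 m^2 of ground per
#' year, so a cell's human-impacted fraction is `population * 3.65 /
#' cell_area`, capped at 1. All pasture land counts as polluted whenever the
#' cell's cattle headcount is positive. The two parts combine by capped sum.
#'
#' @param population persons per cell (non-negative).
#' @param cattle cattle head count per cell (non-negative).
#' @param pasture_frac pasture fraction of the cell, in `[0, 1]`.
#' @param cell_area cell area in m^2 (positive).
#' @param footprint_m2 contaminated ground per person, m^2 (default 3.65).
#' @return contaminated fraction in `[0, 1]`, same shape as the inputs.
#' @export
#' @examples
#' contaminated_fraction(1, 0, 0, 100)        # 0.0365
#' contaminated_fraction(10, 5, 0.5, 100)     # 0.865
contaminated_fraction <- function(population, cattle, pasture_frac, cell_area,
                                  footprint_m2 = 3.65) {
  if (any(cell_area <= 0)) stop("cell_area must be positive")
  if (any(population < 0) || any(cattle < 0)) stop("counts must be non-negative")
  if (any(pasture_frac < 0) || any(pasture_frac > 1)) stop("pasture_frac must be in [0, 1]")
  human <- pmin(1, population * footprint_m2 / cell_area)
  pasture <- ifelse(cattle > 0, pasture_frac, 0)
  pmin(1, human + pasture)
}

#' Route runoff downstream, tracking water from tagged source cells
#'
#' For each cell in topological order, the total accumulated water is its own
#' runoff volume plus the totals of all immediate upstream neighbors; tagged
#' water accumulates identically but each cell contributes only
#' `source_frac` of its own runoff. Volumes are in mm * m^2.
#'
#' @param network a `flow_network`.
#' @param runoff per-cell runoff, mm (matrix or vector in cell order).
#' @param source_frac per-cell tagged fraction in `[0, 1]`.
#' @return list with numeric vectors `total` and `tagged` (per cell,
#'   column-major cell order); `tagged <= total` everywhere.
#' @export
accumulate_flow <- function(network, runoff, source_frac) {
  runoff <- as.vector(runoff); source_frac <- as.vector(source_frac)
  n <- length(network$downstream)
  if (length(runoff) != n || length(source_frac) != n)
    stop("runoff and source_frac must have one value per cell")
  if (any(runoff < 0)) stop("runoff must be non-negative")
  if (any(source_frac < 0 | source_frac > 1)) stop("source_frac must be in [0, 1]")
  # cheap acyclicity guarantee: a cycle admits no consistent topological order
  pos <- integer(n); pos[network$topo_order] <- seq_len(n)
  dn <- network$downstream
  if (!all(is.na(dn) | pos < pos[ifelse(is.na(dn), 1L, dn)]))
    stop("network is cyclic or topo_order is inconsistent with downstream pointers")
  area <- network$cell_size^2
  total <- runoff * area
  tagged <- runoff * area * source_frac
  down <- network$downstream
  for (cell in network$topo_order) {
    d <- down[cell]
    if (!is.na(d)) {
      total[d] <- total[d] + total[cell]
      tagged[d] <- tagged[d] + tagged[cell]
    }
  }
  list(total = total, tagged = tagged)
}

#' Water-source index from accumulated volumes
#'
#' The index at a cell is the percent of its accumulated water that fell as
#' rain on tagged land: `100 * tagged / total`. Cells with no accumulated
#' water have index 0 (no water implies no influence).
#'
#' @param tagged,total accumulated volumes from [accumulate_flow()].
#' @return index in percent, `[0, 100]`, same shape as the inputs.
#' @export
index_from_accumulation <- function(tagged, total) {
  if (any(tagged > total * (1 + 1e-9) + 1e-12))
    stop("invariant violation: tagged accumulation exceeds total")
  out <- ifelse(total > 0, 100 * tagged / total, 0)
  pmin(pmax(out, 0), 100)
}

#' Compute routed upstream human-activity and tree-cover indices
#'
#' Full routing stage: water balance from the grid's precipitation and
#' evapotranspiration, contamination tagging from population/cattle/pasture,
#' tree tagging from tree-cover fraction, accumulation over the D8 network,
#' and conversion to percent indices.
#'
#' @param grid a `landscape_grid`.
#' @param network optional precomputed `flow_network` (derived if missing).
#' @return object of class `routed_indices`: list with matrices `total_water`
#'   (mm * m^2), `human_index` and `tree_index` (percent), and the `network`.
#' @export
route_indices <- function(grid, network = NULL) {
  if (is.null(network)) network <- derive_flow_network(grid)
  runoff <- water_balance(grid$precip, grid$aet)
  human_frac <- contaminated_fraction(grid$population, grid$cattle,
                                      grid$pasture_frac, grid$cell_size^2)
  acc_h <- accumulate_flow(network, runoff, human_frac)
  acc_t <- accumulate_flow(network, runoff, grid$tree_frac)
  dims <- c(grid$n_rows, grid$n_cols)
  structure(list(
    total_water = matrix(acc_h$total, dims[1], dims[2]),
    human_index = matrix(index_from_accumulation(acc_h$tagged, acc_h$total),
                         dims[1], dims[2]),
    tree_index = matrix(index_from_accumulation(acc_t$tagged, acc_t$total),
                        dims[1], dims[2]),
    network = network), class = "routed_indices")
}

#' @export
print.routed_indices <- function(x, ...) {
  cat(sprintf("<routed_indices> %d x %d cells; human index %.1f..%.1f%%, tree index %.1f..%.1f%%\n",
              nrow(x$human_index), ncol(x$human_index),
              min(x$human_index), max(x$human_index),
              min(x$tree_index), max(x$tree_index)))
  invisible(x)
}

#' Brute-force upstream-enumeration oracle for one cell's index
#'
#' Computes the water-source index at a single cell by explicitly enumerating
#' its full upstream set (reverse traversal of the network) and summing
#' contributions, independently of the topological-order accumulation. Used
#' to verify the routing pipeline on small grids.
#'
#' @param network a `flow_network`.
#' @param runoff per-cell runoff, mm.
#' @param source_frac per-cell tagged fraction.
#' @param cell cell index (column-major).
#' @return index in percent.
#' @export
upstream_index_oracle <- function(network, runoff, source_frac, cell) {
  runoff <- as.vector(runoff); source_frac <- as.vector(source_frac)
  cells <- c(cell, upstream_cells(network, cell))
  area <- network$cell_size^2
  total <- sum(runoff[cells]) * area
  tagged <- sum(runoff[cells] * source_frac[cells]) * area
  if (total <= 0) return(0)
  100 * tagged / total
}

#' Average routed indices within a window around cluster coordinates
#'
#' Emulates linking environmental rasters to displaced survey coordinates:
#' each index is averaged over all cells whose centers lie within a square
#' window (default 10 km side) centered on the cluster's reported
#' coordinates.
#'
#' @param indices a `routed_indices`.
#' @param clusters data.frame with `cluster_id` and reported coordinates
#'   (`x_reported`, `y_reported`; falls back to `x_true`/`y_true`).
#' @param window window side length in meters (default 10000).
#' @return data.frame with `cluster_id`, `human_index`, `tree_index`,
#'   `n_cells` (cells averaged).
#' @export
aggregate_at_cluster <- function(indices, clusters, window = 10000) {
  net <- indices$network
  xs <- if ("x_reported" %in% names(clusters)) clusters$x_reported else clusters$x_true
  ys <- if ("y_reported" %in% names(clusters)) clusters$y_reported else clusters$y_true
  nr <- net$n_rows; nc <- net$n_cols; cs <- net$cell_size
  cx <- (rep(seq_len(nc), each = nr) - 0.5) * cs
  cy <- (rep(seq_len(nr), nc) - 0.5) * cs
  half <- window / 2
  hi <- as.vector(indices$human_index)
  ti <- as.vector(indices$tree_index)
  out <- lapply(seq_along(xs), function(i) {
    sel <- abs(cx - xs[i]) <= half & abs(cy - ys[i]) <= half
    if (!any(sel))
      stop(sprintf("window around cluster %s contains no grid cells",
                   clusters$cluster_id[i]))
    data.frame(cluster_id = clusters$cluster_id[i],
               human_index = mean(hi[sel]), tree_index = mean(ti[sel]),
               n_cells = sum(sel))
  })
  do.call(rbind, out)
}
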