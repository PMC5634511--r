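#' Derive the D8 drainage network from a landscape grid
#'
#' Each cell drains to the single 8-neighbor with the steepest descent, where
#' descent is (elevation drop) / (center-to-center distance), i.e. diagonal
#' neighbors are down-weighted by sqrt(2). Edge cells with no lower neighbor
#' are outlets. Ties are broken by a fixed neighbor precedence: N, NE, E, SE,
#' S, SW, W, NW (the first neighbor in that order wins).
#'
#' Cells are indexed column-major like an R matrix (`cell = row + (col-1) *
#' n_rows`). Because every downstream pointer is strictly downhill, sorting
#' cells by decreasing elevation yields a valid topological order, which is
#' stored on the network.
#'
#' @param grid a `landscape_grid` (or a list with `elevation`, `cell_size`).
#' @return an object of class `flow_network`: list with `downstream` (integer
#'   cell index of the downstream neighbor, `NA` for outlets), `topo_order`
#'   (cell permutation, upstream before downstream), `n_rows`, `n_cols`,
#'   `cell_size`.
#' @export
derive_flow_network <- function(grid) {
  elev <- grid$elevation
  nr <- nrow(elev); nc <- ncol(elev)
  # neighbor precedence for tie-breaks: N, NE, E, SE, S, SW, W, NW
  dr <- c(-1, -1, 0, 1, 1, 1, 0, -1)
  dc <- c(0, 1, 1, 1, 0, -1, -1, -1)
  dist <- ifelse(dr != 0 & dc != 0, sqrt(2), 1) * grid$cell_size
  n <- nr * nc
  down <- rep(NA_integer_, n)
  best <- rep(0, n)
  rows <- rep(seq_len(nr), nc)
  cols <- rep(seq_len(nc), each = nr)
  for (k in seq_along(dr)) {
    r2 <- rows + dr[k]; c2 <- cols + dc[k]
    ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
    nb <- as.integer(r2 + (c2 - 1) * nr)
    slope <- rep(-Inf, n)
    slope[ok] <- (elev[cbind(rows[ok], cols[ok])] - elev[nb[ok]]) / dist[k]
    take <- ok & slope > best + 0  # strictly steeper than current best
    down[take] <- nb[take]
    best[take] <- slope[take]
  }
  interior <- rows > 1 & rows < nr & cols > 1 & cols < nc
  if (any(interior & is.na(down))) {
    bad <- which(interior & is.na(down))[1]
    stop(sprintf("pit detected at cell %d (row %d, col %d): run pit_fill() first",
                 bad, rows[bad], cols[bad]))
  }
  structure(list(downstream = down,
                 topo_order = order(elev, decreasing = TRUE),
                 n_rows = nr, n_cols = nc, cell_size = grid$cell_size),
            class = "flow_network")
}

#' Validate a flow network
#'
#' Checks, by explicit traversal, that following downstream pointers from any
#' cell terminates at an outlet within `n_cells` steps (acyclicity), and that
#' `topo_order` places every cell before its downstream neighbor.
#'
#' @param network a `flow_network`.
#' @return `TRUE` invisibly; stops with a message on violation.
#' @export
validate_flow_network <- function(network) {
  n <- length(network$downstream)
  down <- network$downstream
  for (start in seq_len(n)) {
    c0 <- start
    for (step in seq_len(n + 1)) {
      if (is.na(down[c0])) break
      c0 <- down[c0]
      if (step > n) stop(sprintf("cycle detected starting from cell %d", start))
    }
  }
  pos <- integer(n)
  pos[network$topo_order] <- seq_len(n)
  ok <- is.na(down) | pos[seq_len(n)] < pos[ifelse(is.na(down), 1L, down)]
  if (!all(ok)) stop("topo_order is inconsistent with downstream pointers")
  invisible(TRUE)
}

#' @export
print.flow_network <- function(x, ...) {
  cat(sprintf("<flow_network> %d x %d cells, %d outlets\n",
              x$n_rows, x$n_cols, sum(is.na(x$downstream))))
  invisible(x)
}

# Full upstream cell set of `cell` (excluding itself), by reverse traversal.
upstream_cells <- function(network, cell) {
  n <- length(network$downstream)
  inflow <- split(seq_len(n), factor(network$downstream, levels = seq_len(n)))
  seen <- logical(n)
  frontier <- inflow[[cell]]
  out <- integer(0)
  while (length(frontier)) {
    frontier <- frontier[!seen[frontier]]
    seen[frontier] <- TRUE
    out <- c(out, frontier)
    frontier <- unlist(inflow[frontier], use.names = FALSE)
  }
  out
}
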