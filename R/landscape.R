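#' Configuration defaults for the synthetic landscape generator
#'
#' Returns the list of tunable settings consumed by [generate_landscape()].
#' Every field layer is built from Gaussian-smoothed white noise so that the
#' landscape has realistic spatial autocorrelation; `sd = 0` for a layer makes
#' it spatially constant.
#'
#' @param relief vertical relief of the random elevation component, meters.
#' @param tilt deterministic down-slope toward the first row, meters per cell;
#'   guarantees a preferred drainage direction before pit filling.
#' @param smooth_sigma Gaussian smoothing radius for all layers, in cells.
#' @param precip_mean,precip_sd monthly precipitation, mm.
#' @param aet_mean,aet_sd monthly actual evapotranspiration, mm.
#' @param tree_mean mean tree-cover fraction (on the logit scale the smoothed
#'   noise is added around `qlogis(tree_mean)`).
#' @param tree_scale logit-scale spatial variability of tree cover.
#' @param pasture_mean mean share of the non-treed part of a cell that is
#'   pasture.
#' @param pop_log_mean,pop_log_sd log-scale mean/sd of the expected persons
#'   per cell (population is Poisson around a log-normal intensity).
#' @param cattle_log_mean,cattle_log_sd same for cattle on pasture cells.
#' @return a named list of settings.
#' @export
landscape_config <- function(relief = 80, tilt = 1.5, smooth_sigma = 3,
                             precip_mean = 120, precip_sd = 40,
                             aet_mean = 60, aet_sd = 15,
                             tree_mean = 0.35, tree_scale = 1.5,
                             pasture_mean = 0.3,
                             pop_log_mean = log(20), pop_log_sd = 1.5,
                             cattle_log_mean = log(10), cattle_log_sd = 1) {
  as.list(environment())
}

# Separable Gaussian blur with replicate padding; sigma in cells.
blur_field <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  conv <- function(v) {
    vp <- c(rep(v[1], r), v, rep(v[length(v)], r))
    out <- stats::filter(vp, k, sides = 2)
    as.numeric(out[(r + 1):(r + length(v))])
  }
  m1 <- apply(m, 2, conv)
  t(apply(m1, 1, conv))
}

# Smoothed standard-normal field (unit variance after smoothing).
noise_field <- function(n_rows, n_cols, sigma) {
  z <- blur_field(matrix(rnorm(n_rows * n_cols), n_rows, n_cols), sigma)
  s <- sd(as.vector(z))
  if (s > 0) z <- z / s
  z
}

#' Fill elevation pits so every cell drains to the grid edge
#'
#' Planchon-Darboux relaxation: raises interior cells to the lowest level
#' from which a strictly descending path (by at least `eps` per step) to the
#' boundary exists. After filling, the steepest-descent (D8) network is
#' acyclic with all outlets on the grid edge.
#'
#' @param elevation numeric matrix, meters.
#' @param eps minimum drop per cell step, meters.
#' @return elevation matrix with pits raised.
#' @export
pit_fill <- function(elevation, eps = 1e-6) {
  nr <- nrow(elevation); nc <- ncol(elevation)
  if (nr < 2 || nc < 2) stop("elevation grid must be at least 2x2")
  w <- matrix(Inf, nr, nc)
  w[1, ] <- elevation[1, ]; w[nr, ] <- elevation[nr, ]
  w[, 1] <- elevation[, 1]; w[, nc] <- elevation[, nc]
  shift <- function(m, dr, dc) {
    out <- matrix(Inf, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  deltas <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
                 c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  repeat {
    nb <- matrix(Inf, nr, nc)
    for (d in deltas) nb <- pmin(nb, shift(w, d[1], d[2]))
    w_new <- pmax(elevation, pmin(w, nb + eps))
    w_new[1, ] <- w[1, ]; w_new[nr, ] <- w[nr, ]
    w_new[, 1] <- w[, 1]; w_new[, nc] <- w[, nc]
    if (identical(w_new, w)) break
    w <- w_new
  }
  w
}

#' Generate a synthetic landscape grid
#'
#' Builds the per-cell environmental state the routing stage consumes:
#' elevation (smoothed noise plus a deterministic tilt, then pit-filled),
#' monthly precipitation and actual evapotranspiration, tree-cover and
#' pasture fractions, and population and cattle counts. Stands in for the
#' global raster layers (climate, land cover, population, livestock) a
#' real analysis would download.
#'
#' @param n_rows,n_cols grid dimensions (each at least 2).
#' @param cell_size cell edge length in meters (default 1000 m).
#' @param config settings list from [landscape_config()].
#' @param seed integer seed; identical seed and config give an identical grid.
#' @return an object of class `landscape_grid`: a list with scalar fields
#'   `n_rows`, `n_cols`, `cell_size` and matrix layers `elevation`, `precip`,
#'   `aet`, `tree_frac`, `pasture_frac`, `population`, `cattle`.
#' @export
#' @examples
#' g <- generate_landscape(10, 10, seed = 1)
#' range(g$tree_frac)
generate_landscape <- function(n_rows = 50, n_cols = 50, cell_size = 1000,
                               config = landscape_config(), seed) {
  if (missing(seed)) stop("a seed is required")
  if (n_rows < 2 || n_cols < 2) stop("grid dimensions must be at least 2x2")
  if (cell_size <= 0) stop("cell_size must be positive")
  cfg <- utils::modifyList(landscape_config(), config)
  with_seed(substream_seed(seed, "landscape"), {
    n <- n_rows * n_cols
    elev <- cfg$relief * noise_field(n_rows, n_cols, cfg$smooth_sigma) +
      cfg$tilt * (row(matrix(0, n_rows, n_cols)) - 1)
    elev <- pit_fill(elev)
    precip <- pmax(cfg$precip_mean +
                     cfg$precip_sd * noise_field(n_rows, n_cols, cfg$smooth_sigma), 0)
    aet <- pmax(cfg$aet_mean +
                  cfg$aet_sd * noise_field(n_rows, n_cols, cfg$smooth_sigma), 0)
    tree <- plogis(qlogis(cfg$tree_mean) +
                     cfg$tree_scale * noise_field(n_rows, n_cols, cfg$smooth_sigma))
    pshare <- plogis(qlogis(cfg$pasture_mean) +
                       1.5 * noise_field(n_rows, n_cols, cfg$smooth_sigma))
    pasture <- pshare * (1 - tree)
    pop_lam <- exp(cfg$pop_log_mean + cfg$pop_log_sd *
                     noise_field(n_rows, n_cols, cfg$smooth_sigma))
    population <- matrix(stats::rpois(n, as.vector(pop_lam)), n_rows, n_cols)
    cat_lam <- exp(cfg$cattle_log_mean + cfg$cattle_log_sd *
                     noise_field(n_rows, n_cols, cfg$smooth_sigma))
    cattle <- matrix(stats::rpois(n, as.vector(cat_lam)), n_rows, n_cols)
    cattle[pasture < 0.05] <- 0L
    structure(list(n_rows = n_rows, n_cols = n_cols, cell_size = cell_size,
                   elevation = elev, precip = precip, aet = aet,
                   tree_frac = tree, pasture_frac = pasture,
                   population = population, cattle = cattle),
              class = "landscape_grid")
  })
}

#' @export
print.landscape_grid <- function(x, ...) {
  cat(sprintf("<landscape_grid> %d x %d cells, %g m cell size\n",
              x$n_rows, x$n_cols, x$cell_size))
  cat(sprintf("  elevation %.1f..%.1f m, precip %.0f..%.0f mm, tree cover %.2f..%.2f\n",
              min(x$elevation), max(x$elevation), min(x$precip), max(x$precip),
              min(x$tree_frac), max(x$tree_frac)))
  invisible(x)
}

#' Place survey clusters on a landscape
#'
#' Clusters sit at cell centers. The urban flag is drawn per cluster with
#' probability `urban_fraction`; urban clusters are sampled with probability
#' proportional to cell population (plus one), rural clusters uniformly, so
#' urban clusters sit on more populated cells in expectation. Cells are used
#' at most once.
#'
#' @param grid a `landscape_grid`.
#' @param n_clusters number of clusters (at most the number of cells).
#' @param urban_fraction probability a cluster is urban, in `[0, 1]`.
#' @param seed integer seed.
#' @return data.frame with `cluster_id`, `row`, `col`, `x_true`, `y_true`
#'   (meters, cell-center coordinates), `urban` (0/1), `population`.
#' @export
place_clusters <- function(grid, n_clusters, urban_fraction, seed) {
  stopifnot(inherits(grid, "landscape_grid"))
  if (n_clusters < 1) stop("n_clusters must be at least 1")
  n_cells <- grid$n_rows * grid$n_cols
  if (n_clusters > n_cells) stop("n_clusters exceeds the number of grid cells")
  if (urban_fraction < 0 || urban_fraction > 1) stop("urban_fraction must be in [0, 1]")
  with_seed(substream_seed(seed, "clusters"), {
    urban <- rbinom(n_clusters, 1, urban_fraction)
    pop <- as.vector(grid$population)
    avail <- rep(TRUE, n_cells)
    cells <- integer(n_clusters)
    for (i in order(urban, decreasing = TRUE)) {  # urban first (weighted)
      idx <- which(avail)
      w <- if (urban[i] == 1) pop[idx] + 1 else rep(1, length(idx))
      cells[i] <- if (length(idx) == 1) idx else sample(idx, 1, prob = w)
      avail[cells[i]] <- FALSE
    }
    r <- ((cells - 1) %% grid$n_rows) + 1
    cc <- ((cells - 1) %/% grid$n_rows) + 1
    data.frame(cluster_id = seq_len(n_clusters), row = r, col = cc,
               x_true = (cc - 0.5) * grid$cell_size,
               y_true = (r - 0.5) * grid$cell_size,
               urban = urban, population = pop[cells])
  })
}

#' Apply DHS-style random coordinate displacement to clusters
#'
#' Emulates the anonymization applied to published survey-cluster GPS
#' positions: coordinates are displaced in a uniform random direction, up to
#' 2 km for urban clusters and up to 5 km for rural clusters, with a further
#' 1 percent of rural clusters displaced up to 10 km.
#'
#' @param clusters data.frame from [place_clusters()] (needs `x_true`,
#'   `y_true`, `urban`).
#' @param seed integer seed.
#' @param urban_max,rural_max,rural_far_max displacement caps in meters.
#' @param far_prob probability a rural cluster uses the far cap.
#' @param bounds optional `c(xmax, ymax)`: reported coordinates are clipped
#'   to the box `[0, xmax] x [0, ymax]`, mirroring the real rule that
#'   displaced points stay inside the survey area. Clipping projects onto a
#'   convex region containing the true point, so it never increases the
#'   realized displacement.
#' @return the input data.frame with `x_reported`, `y_reported` and
#'   `displacement` (realized meters) added.
#' @export
displace_coordinates <- function(clusters, seed,
                                 urban_max = 2000, rural_max = 5000,
                                 rural_far_max = 10000, far_prob = 0.01,
                                 bounds = NULL) {
  stopifnot(all(c("x_true", "y_true", "urban") %in% names(clusters)))
  n <- nrow(clusters)
  with_seed(substream_seed(seed, "displacement"), {
    far <- rbinom(n, 1, far_prob) == 1
    cap <- ifelse(clusters$urban == 1, urban_max,
                  ifelse(far, rural_far_max, rural_max))
    # the far 1% of rural clusters land beyond the ordinary rural cap
    lo <- ifelse(clusters$urban == 0 & far, rural_max, 0)
    radius <- runif(n, lo, cap)
    angle <- runif(n, 0, 2 * pi)
    x <- clusters$x_true + radius * cos(angle)
    y <- clusters$y_true + radius * sin(angle)
    if (!is.null(bounds)) {
      x <- pmin(pmax(x, 0), bounds[1])
      y <- pmin(pmax(y, 0), bounds[2])
    }
    clusters$x_reported <- x
    clusters$y_reported <- y
    clusters$displacement <- sqrt((x - clusters$x_true)^2 + (y - clusters$y_true)^2)
    clusters
  })
}
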