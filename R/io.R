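#' Write / read a grid layer as an ESRI ASCII raster
#'
#' Plain-text raster exchange format: a six-line header (ncols, nrows,
#' xllcorner, yllcorner, cellsize, NODATA_value) followed by rows of values,
#' northernmost row first. Row 1 of the matrix is treated as the southern
#' edge (y = 0), matching the package's cell-center coordinate convention.
#'
#' @param m numeric matrix (rows = south to north).
#' @param path output file.
#' @param cell_size cell edge, meters.
#' @param nodata value written for `NA`s.
#' @return `read_esri_ascii()` returns a list with `matrix` and `cell_size`.
#' @export
write_esri_ascii <- function(m, path, cell_size, nodata = -9999) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", ncol(m)),
               sprintf("nrows %d", nrow(m)),
               "xllcorner 0", "yllcorner 0",
               sprintf("cellsize %g", cell_size),
               sprintf("NODATA_value %g", nodata)), con)
  mm <- m
  mm[is.na(mm)] <- nodata
  # ASCII grids store the northern row first
  for (r in rev(seq_len(nrow(mm))))
    writeLines(paste(format(mm[r, ], trim = TRUE, digits = 10), collapse = " "), con)
  invisible(path)
}

#' @rdname write_esri_ascii
#' @export
read_esri_ascii <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(tolower(lines[1:6]), "\\s+")
  keyval <- setNames(vapply(hdr, function(x) as.numeric(x[2]), numeric(1)),
                     vapply(hdr, `[`, "", 1))
  nr <- as.integer(keyval[["nrows"]]); nc <- as.integer(keyval[["ncols"]])
  vals <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  m <- matrix(vals, nr, nc, byrow = TRUE)[rev(seq_len(nr)), , drop = FALSE]
  m[m == keyval[["nodata_value"]]] <- NA
  list(matrix = m, cell_size = keyval[["cellsize"]])
}

#' Write all layers of a landscape grid to a directory
#'
#' One ESRI ASCII file per layer (`elevation.asc`, `precip.asc`, ...).
#'
#' @param grid a `landscape_grid`.
#' @param dir output directory (created if needed).
#' @return `read_landscape()` returns a `landscape_grid`.
#' @export
write_landscape <- function(grid, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (layer in c("elevation", "precip", "aet", "tree_frac", "pasture_frac",
                  "population", "cattle"))
    write_esri_ascii(grid[[layer]], file.path(dir, paste0(layer, ".asc")),
                     grid$cell_size)
  invisible(dir)
}

#' @rdname write_landscape
#' @export
read_landscape <- function(dir) {
  layers <- c("elevation", "precip", "aet", "tree_frac", "pasture_frac",
              "population", "cattle")
  out <- lapply(layers, function(l)
    read_esri_ascii(file.path(dir, paste0(l, ".asc"))))
  g <- setNames(lapply(out, `[[`, "matrix"), layers)
  g$n_rows <- nrow(g$elevation); g$n_cols <- ncol(g$elevation)
  g$cell_size <- out[[1]]$cell_size
  structure(g, class = "landscape_grid")
}

#' Export a flow network as a two-column cell-to-downstream table
#'
#' @param network a `flow_network`.
#' @param path CSV path; `downstream` is empty (NA) for outlets.
#' @export
write_flow_network <- function(network, path) {
  write.csv(data.frame(cell = seq_along(network$downstream),
                       downstream = network$downstream),
            path, row.names = FALSE, na = "")
  invisible(path)
}

#' Serialize a fitted model
#'
#' `write_fit_json()` stores coefficients, odds ratios, variance components,
#' ICCs and sample sizes as JSON; `write_fit_csv()` writes the odds-ratio
#' table (one row per term) as CSV.
#'
#' @param fit a `ws_fit`.
#' @param path output path.
#' @export
write_fit_json <- function(fit, path) {
  ic <- icc(fit)
  jsonlite::write_json(list(
    coefficients = fit$coefficients,
    sigma_cluster = fit$sigma_cluster,
    sigma_household = fit$sigma_household,
    icc_cluster = ic[["icc_cluster"]],
    icc_household = ic[["icc_household"]],
    loglik = fit$loglik,
    n_children = fit$n_children, n_households = fit$n_households,
    n_clusters = fit$n_clusters),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fit_json
#' @export
write_fit_csv <- function(fit, path) {
  write.csv(fit$coefficients, path, row.names = FALSE)
  invisible(path)
}
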