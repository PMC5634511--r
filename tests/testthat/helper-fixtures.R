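# Shared fixtures, all built in code at test time.

# Hand-built linear chain network: cell i drains to i+1, cell n is the outlet.
make_chain_network <- function(n, cell_size = 1) {
  structure(list(downstream = c(seq_len(n - 1) + 1L, NA_integer_),
                 topo_order = seq_len(n),
                 n_rows = n, n_cols = 1L, cell_size = cell_size),
            class = "flow_network")
}

# Deterministic tilted-plane landscape: elevation rises with row index,
# spatially constant climate; useful when the flow field must be known.
make_tilted_grid <- function(n_rows = 5, n_cols = 5, cell_size = 1000,
                             precip = 100, aet = 40, seed = 1) {
  generate_landscape(n_rows, n_cols, cell_size,
                     config = landscape_config(relief = 0, tilt = 1,
                                               precip_mean = precip, precip_sd = 0,
                                               aet_mean = aet, aet_sd = 0),
                     seed = seed)
}

# Routed cluster environment from a full landscape run; memoised because
# several test files reuse the same one.
.env_cache <- new.env(parent = emptyenv())
make_cluster_env <- function(seed = 11, n_clusters = 500, urban_fraction = 0.35,
                             n_rows = 50, n_cols = 50) {
  key <- paste(seed, n_clusters, urban_fraction, n_rows, n_cols, sep = "|")
  if (!is.null(.env_cache[[key]])) return(.env_cache[[key]])
  g <- generate_landscape(n_rows, n_cols, seed = seed)
  cl <- place_clusters(g, n_clusters, urban_fraction, seed = seed)
  cl <- displace_coordinates(cl, seed = seed,
                             bounds = c(n_cols * g$cell_size, n_rows * g$cell_size))
  idx <- aggregate_at_cluster(route_indices(g), cl, 10000)
  clim <- standardize_climate(cluster_climate(g, cl, seed = seed))
  env <- data.frame(cluster_id = idx$cluster_id,
                    human_index = idx$human_index,
                    tree_index = idx$tree_index,
                    precip_lag_z = clim$precip_lag_z,
                    precip_change = clim$precip_change_z,
                    temp_lag_z = clim$temp_lag_z,
                    temp_change = clim$temp_change_z)
  out <- list(grid = g, clusters = cl, env = env, indices = idx)
  .env_cache[[key]] <- out
  out
}

# Analysis table simulated from known generating parameters.
make_table <- function(seed, params = generating_params(), fix = NULL) {
  fx <- make_cluster_env(n_clusters = params$n_clusters,
                         urban_fraction = params$urban_fraction)
  sv <- simulate_survey(fx$clusters, params, fx$env, seed = seed)
  build_table(sv, fx$env)
}

# Wide binomial check: x successes in n trials at rate p, 99% central interval
expect_binomial_99 <- function(x, n, p) {
  bounds <- qbinom(c(0.005, 0.995), n, p)
  expect_gte(x, bounds[1])
  expect_lte(x, bounds[2])
}
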