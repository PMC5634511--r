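#' Default end-to-end run configuration
#'
#' A single nested list drives the full pipeline: landscape settings, cluster
#' placement, the survey generating parameters, the environmental aggregation
#' window, which subgroup analyses to run, and whether to fit the
#' age-band/tree-quartile variant. The resolved configuration is written next
#' to every run's outputs, and serializes losslessly through YAML.
#'
#' @param seed root seed for all substreams.
#' @return a `run_config` list.
#' @export
default_run_config <- function(seed = 1) {
  structure(list(
    seed = seed,
    landscape = c(list(n_rows = 50, n_cols = 50, cell_size = 1000),
                  landscape_config()),
    clusters = list(n_clusters = 500, urban_fraction = 0.35),
    window_m = 10000,
    params = unclass(generating_params()),
    subgroups = c("urban", "improved_water", "human_activity"),
    quartile_variant = TRUE,
    quad_points = 7), class = "run_config")
}

#' Validate a run configuration
#'
#' Returns every violation found (not just the first); an empty character
#' vector means the configuration is valid.
#'
#' @param config a `run_config` list.
#' @return character vector of findings.
#' @export
validate_config <- function(config) {
  f <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) f <<- c(f, msg)
  chk(is.numeric(config$seed) && length(config$seed) == 1, "seed: must be a single number")
  ls <- config$landscape
  chk(!is.null(ls$n_rows) && ls$n_rows >= 2, "landscape$n_rows: must be >= 2")
  chk(!is.null(ls$n_cols) && ls$n_cols >= 2, "landscape$n_cols: must be >= 2")
  chk(!is.null(ls$cell_size) && ls$cell_size > 0, "landscape$cell_size: must be positive")
  cl <- config$clusters
  chk(!is.null(cl$n_clusters) && cl$n_clusters >= 1, "clusters$n_clusters: must be >= 1")
  chk(!is.null(cl$urban_fraction) && cl$urban_fraction >= 0 && cl$urban_fraction <= 1,
      "clusters$urban_fraction: must be in [0, 1]")
  if (!is.null(ls$n_rows) && !is.null(ls$n_cols) && !is.null(cl$n_clusters))
    chk(cl$n_clusters <= ls$n_rows * ls$n_cols,
        "clusters$n_clusters: exceeds the number of grid cells")
  chk(config$window_m > 0, "window_m: must be positive")
  p <- config$params
  chk(length(p$beta) == 12, "params$beta: must have 12 coefficients")
  chk(!is.null(p$sigma_cluster) && p$sigma_cluster >= 0,
      "params$sigma_cluster: must be non-negative")
  chk(!is.null(p$sigma_household) && p$sigma_household >= 0,
      "params$sigma_household: must be non-negative")
  for (pr in c("quintile_probs_urban", "quintile_probs_rural"))
    chk(length(p[[pr]]) == 5 && all(p[[pr]] >= 0) && abs(sum(p[[pr]]) - 1) < 1e-8,
        sprintf("params$%s: must be 5 probabilities summing to 1", pr))
  for (pr in c("edu_prob_urban", "edu_prob_rural", "water_prob_urban",
               "water_prob_rural", "san_prob_urban", "san_prob_rural"))
    chk(!is.null(p[[pr]]) && p[[pr]] >= 0 && p[[pr]] <= 1,
        sprintf("params$%s: must be in [0, 1]", pr))
  chk(all(config$subgroups %in% c("urban", "improved_water", "human_activity")),
      "subgroups: unknown subgroup name")
  f
}

#' Run the full pipeline: generate, route, assemble, fit, effects
#'
#' Executes every stage in order under one root seed: synthetic landscape and
#' drainage network; routed watershed indices; cluster placement,
#' displacement, and environmental aggregation at the reported coordinates;
#' climate standardization; survey simulation from the three-level logit;
#' covariate assembly; the full-sample fit plus the configured subgroup fits
#' and the quartile variant; and the policy marginal-effects table. Identical
#' config and seed give an identical report.
#'
#' @param config a `run_config` (see [default_run_config()]).
#' @param out_dir optional directory; when given, all tables (CSV/JSON), the
#'   resolved config (YAML) and the summary are written there.
#' @return a `run_report` list: `config`, `tables` (cluster index table,
#'   analysis table head counts), `fits` (full + subgroups + variant),
#'   `policy`, `prevalence`, sample sizes, and `paths` when `out_dir` is set.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir = NULL) {
  findings <- validate_config(config)
  if (length(findings))
    stop("invalid configuration:\n  - ", paste(findings, collapse = "\n  - "))
  seed <- config$seed
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  ls <- config$landscape
  grid <- stage("generate", generate_landscape(
    ls$n_rows, ls$n_cols, ls$cell_size,
    config = ls[setdiff(names(ls), c("n_rows", "n_cols", "cell_size"))],
    seed = seed))
  indices <- stage("route", route_indices(grid))
  clusters <- stage("clusters", place_clusters(
    grid, config$clusters$n_clusters, config$clusters$urban_fraction, seed))
  clusters <- stage("displace", displace_coordinates(
    clusters, seed,
    bounds = c(ls$n_cols * ls$cell_size, ls$n_rows * ls$cell_size)))
  idx_tab <- stage("aggregate",
                   aggregate_at_cluster(indices, clusters, config$window_m))
  climate <- stage("climate",
                   standardize_climate(cluster_climate(grid, clusters, seed)))
  env <- data.frame(cluster_id = idx_tab$cluster_id,
                    human_index = idx_tab$human_index,
                    tree_index = idx_tab$tree_index,
                    precip_lag_z = climate$precip_lag_z,
                    precip_change = climate$precip_change_z,
                    temp_lag_z = climate$temp_lag_z,
                    temp_change = climate$temp_change_z)
  params <- do.call(generating_params, config$params)
  survey <- stage("simulate", simulate_survey(clusters, params, env, seed))
  tab <- stage("assemble", build_table(survey, env))

  message(sprintf("run_pipeline: %d children in %d households in %d clusters",
                  nrow(tab), length(unique(tab$household_id)),
                  length(unique(tab$cluster_id))))
  fits <- list(full = stage("fit", fit_three_level_logit(
    tab, quad_points = config$quad_points)))
  for (sg in config$subgroups)
    fits[[sg]] <- stage(paste0("fit_", sg),
                        subgroup_fit(tab, sg, quad_points = config$quad_points))
  if (isTRUE(config$quartile_variant))
    fits$quartile_variant <- stage("fit_quartile",
                                   quartile_variant_fit(tab, quad_points = config$quad_points))
  policy <- stage("effects", policy_table(fits$full))

  report <- structure(list(
    config = config,
    cluster_indices = idx_tab,
    prevalence = mean(tab$diarrhea),
    n_children = nrow(tab),
    n_households = length(unique(tab$household_id)),
    n_clusters = length(unique(tab$cluster_id)),
    fits = fits, policy = policy), class = "run_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    yaml::write_yaml(unclass_config(config), file.path(out_dir, "config.yaml"))
    write.csv(tab, file.path(out_dir, "analysis_table.csv"), row.names = FALSE)
    write.csv(idx_tab, file.path(out_dir, "cluster_indices.csv"), row.names = FALSE)
    write.csv(clusters, file.path(out_dir, "clusters.csv"), row.names = FALSE)
    write_fit_csv(fits$full, file.path(out_dir, "fit_full.csv"))
    write_fit_json(fits$full, file.path(out_dir, "fit_full.json"))
    write.csv(policy, file.path(out_dir, "policy_table.csv"), row.names = FALSE)
    summary <- list(prevalence = report$prevalence,
                    n_children = report$n_children,
                    n_households = report$n_households,
                    n_clusters = report$n_clusters,
                    sigma_cluster = fits$full$sigma_cluster,
                    sigma_household = fits$full$sigma_household,
                    icc = as.list(icc(fits$full)))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    report$paths <- file.path(out_dir, c("config.yaml", "analysis_table.csv",
                                         "cluster_indices.csv", "clusters.csv",
                                         "fit_full.csv", "fit_full.json",
                                         "policy_table.csv", "summary.json"))
  }
  report
}

# strip classes so YAML round-trips to plain lists
unclass_config <- function(config) {
  out <- unclass(config)
  out$params <- lapply(unclass(out$params), function(x)
    if (is.numeric(x) && !is.null(names(x))) as.list(x) else x)
  out
}

#' Read / write a run configuration as YAML
#'
#' @param config a `run_config`.
#' @param path file path.
#' @return `read_run_config()` returns a `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass_config(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$params$beta <- unlist(raw$params$beta)
  for (f in c("quintile_probs_urban", "quintile_probs_rural", "age_range"))
    raw$params[[f]] <- unlist(raw$params[[f]], use.names = FALSE)
  raw$subgroups <- unlist(raw$subgroups)
  structure(raw, class = "run_config")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d children, %d households, %d clusters; prevalence %.3f\n",
              x$n_children, x$n_households, x$n_clusters, x$prevalence))
  cat("fits:", paste(names(x$fits), collapse = ", "), "\n")
  invisible(x)
}
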