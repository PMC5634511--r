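#' Default WHO/JMP improved-source mapping
#'
#' Ships the dichotomization of drinking-water sources and sanitation
#' facility types into improved vs unimproved, following the standard WHO/JMP
#' service-ladder definitions. The mapping is an assumption of the package
#' (surveys differ in labels) and is fully overridable: pass an edited copy to
#' [recode_jmp()], or round-trip it through YAML with [write_jmp_mapping()].
#'
#' @return nested list: `water` and `sanitation`, each with character vectors
#'   `improved` and `unimproved`.
#' @export
jmp_default_mapping <- function() {
  list(
    water = list(
      improved = c("piped into dwelling", "piped to yard/plot",
                   "public tap/standpipe", "tubewell or borehole",
                   "protected dug well", "protected spring", "rainwater",
                   "bottled water"),
      unimproved = c("unprotected dug well", "unprotected spring",
                     "tanker truck", "cart with small tank", "surface water")),
    sanitation = list(
      improved = c("flush to piped sewer system", "flush to septic tank",
                   "flush to pit latrine", "ventilated improved pit latrine",
                   "pit latrine with slab", "composting toilet"),
      unimproved = c("flush to somewhere else", "pit latrine without slab",
                     "bucket", "hanging toilet", "open defecation",
                     "shared facility")))
}

#' Recode a water or sanitation category to a binary improved flag
#'
#' @param category character vector of source/facility labels.
#' @param type `"water"` or `"sanitation"`.
#' @param mapping mapping list (default [jmp_default_mapping()]).
#' @return integer vector of 0/1 flags (1 = improved).
#' @export
#' @examples
#' recode_jmp("surface water", "water")        # 0
#' recode_jmp("piped into dwelling", "water")  # 1
recode_jmp <- function(category, type = c("water", "sanitation"),
                       mapping = jmp_default_mapping()) {
  type <- match.arg(type)
  m <- mapping[[type]]
  unknown <- setdiff(unique(category[!is.na(category)]),
                     c(m$improved, m$unimproved))
  if (length(unknown))
    stop(sprintf("unknown %s category: %s. Valid categories: %s",
                 type, paste(unknown, collapse = ", "),
                 paste(c(m$improved, m$unimproved), collapse = "; ")))
  # NA labels stay NA (missing covariate, handled by listwise deletion)
  ifelse(is.na(category), NA_integer_, as.integer(category %in% m$improved))
}

#' Write / read a JMP mapping as YAML
#'
#' @param mapping mapping list as from [jmp_default_mapping()].
#' @param path file path.
#' @return `read_jmp_mapping()` returns the mapping list.
#' @export
write_jmp_mapping <- function(mapping, path) {
  yaml::write_yaml(mapping, path)
  invisible(path)
}

#' @rdname write_jmp_mapping
#' @export
read_jmp_mapping <- function(path) {
  m <- yaml::read_yaml(path)
  lapply(m, function(x) lapply(x, as.character))
}

#' Standardize a numeric vector to a z-score over the analysis sample
#'
#' @param x numeric vector with positive variance.
#' @return `(x - mean(x)) / sd(x)`.
#' @export
zscore <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) stop("cannot standardize: zero variance")
  (x - mean(x)) / s
}

#' Standardize per-cluster climate terms over the analysis sample
#'
#' Converts the raw one-month-lag climate values and month-over-month changes
#' (from [cluster_climate()]) to z-scores computed over all clusters pooled,
#' which is how the analysis model scales them. Requires at least two
#' clusters and nonzero variance in each column.
#'
#' @param climate data.frame with `precip_lag`, `precip_change`, `temp_lag`,
#'   `temp_change`.
#' @return the input with columns `precip_lag_z`, `precip_change_z` (exposed
#'   to the model as `precip_change`), `temp_lag_z`, `temp_change_z` added;
#'   each has mean ~0 and SD ~1.
#' @export
standardize_climate <- function(climate) {
  if (nrow(climate) < 2) stop("need at least 2 clusters to standardize")
  climate$precip_lag_z <- zscore(climate$precip_lag)
  climate$precip_change_z <- zscore(climate$precip_change)
  climate$temp_lag_z <- zscore(climate$temp_lag)
  climate$temp_change_z <- zscore(climate$temp_change)
  climate
}

#' Assemble the child-level analysis table
#'
#' Joins cluster-level environment values (watershed indices and standardized
#' climate terms) onto the simulated survey, recodes water and sanitation
#' labels to improved flags via the WHO/JMP mapping, enforces referential
#' integrity (every child in a known household, every household in exactly
#' one cluster with environment values), and drops rows with any missing
#' model covariate, reporting the count.
#'
#' @param survey child-level data.frame from [simulate_survey()].
#' @param cluster_environment data.frame with `cluster_id`, `human_index`,
#'   `tree_index`, `precip_lag_z`, `precip_change`, `temp_lag_z`,
#'   `temp_change`.
#' @param mapping JMP mapping (default [jmp_default_mapping()]).
#' @return data.frame with one row per child and the model columns:
#'   `diarrhea`, `age`, `household_id`, `cluster_id`, `urban`, `wealth_high`,
#'   `edu_secondary`, `improved_sanitation`, `improved_water`,
#'   `precip_lag_z`, `precip_change`, `temp_lag_z`, `temp_change`,
#'   `human_index`, `tree_index`. Attribute `"n_dropped"` records listwise
#'   deletions.
#' @export
build_table <- function(survey, cluster_environment,
                        mapping = jmp_default_mapping()) {
  need <- c("cluster_id", "human_index", "tree_index", "precip_lag_z",
            "precip_change", "temp_lag_z", "temp_change")
  miss <- setdiff(need, names(cluster_environment))
  if (length(miss)) stop("cluster_environment lacks columns: ",
                         paste(miss, collapse = ", "))
  orphans <- setdiff(unique(survey$cluster_id), cluster_environment$cluster_id)
  if (length(orphans))
    stop("survey references clusters with no environment values: ",
         paste(orphans, collapse = ", "))
  hh_cl <- unique(survey[, c("household_id", "cluster_id")])
  if (anyDuplicated(hh_cl$household_id))
    stop("household(s) assigned to more than one cluster")
  env <- cluster_environment[match(survey$cluster_id,
                                   cluster_environment$cluster_id), ]
  tab <- data.frame(
    diarrhea = survey$diarrhea,
    age = survey$age,
    household_id = survey$household_id,
    cluster_id = survey$cluster_id,
    urban = survey$urban,
    wealth_high = survey$wealth_high,
    edu_secondary = survey$edu_secondary,
    improved_sanitation = recode_jmp(survey$sanitation_type, "sanitation", mapping),
    improved_water = recode_jmp(survey$water_source, "water", mapping),
    precip_lag_z = env$precip_lag_z,
    precip_change = env$precip_change,
    temp_lag_z = env$temp_lag_z,
    temp_change = env$temp_change,
    human_index = env$human_index,
    tree_index = env$tree_index)
  complete <- stats::complete.cases(tab)
  n_dropped <- sum(!complete)
  if (n_dropped > 0)
    message(sprintf("build_table: dropped %d row(s) with missing covariates",
                    n_dropped))
  out <- tab[complete, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  out
}
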