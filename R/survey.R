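#' Generating parameters for the synthetic survey
#'
#' Bundles everything the survey simulator needs: the 12 fixed-effect
#' coefficients of the three-level diarrhea logit (intercept, child age in
#' months, household wealth in the top two quintiles, maternal secondary
#' education, improved sanitation, improved water, lagged precipitation and
#' temperature z-scores with their month-over-month changes, and the two
#' upstream watershed indices in percent), the random-intercept standard
#' deviations at the cluster and household levels, sample-size settings, and
#' the stratum-specific covariate distributions.
#'
#' Default variance components are obtained by inverting the latent-scale
#' intra-class correlations 0.05 (cluster) and 0.18 (household, cumulative)
#' with logistic residual variance pi^2/3, giving sigma_cluster ~ 0.448 and
#' sigma_household ~ 0.722. The improved-water probabilities default to the
#' urban/rural contrast of 63 percent vs 22 percent; other covariate
#' probabilities are plausible DHS-like values. Children's ages are uniform
#' on 0-59 months (all children under five).
#'
#' @param beta named numeric vector of the 12 fixed effects, in model order.
#' @param sigma_cluster,sigma_household random-intercept SDs (non-negative).
#' @param n_clusters,households_per_cluster,children_per_household counts.
#' @param urban_fraction probability a cluster is urban.
#' @param quintile_probs_urban,quintile_probs_rural wealth-quintile
#'   probabilities (length 5, summing to 1); "wealthy" means quintile 4 or 5.
#' @param edu_prob_urban,edu_prob_rural probability of maternal secondary
#'   education or higher.
#' @param water_prob_urban,water_prob_rural probability of an improved
#'   drinking-water source.
#' @param san_prob_urban,san_prob_rural probability of improved sanitation.
#' @param age_range child age range in months (inclusive).
#' @param beta_tree_unimproved extra tree-cover slope applied only to
#'   children in households without improved water; 0 by default. A
#'   generator-only knob for designed experiments on subgroup contrasts, not
#'   part of the analysis model.
#' @return object of class `generating_params` (a named list).
#' @export
generating_params <- function(
    beta = c(intercept = -1.8, age = -0.008, wealth_high = -0.30,
             edu_secondary = -0.35, improved_sanitation = -0.20,
             improved_water = -0.25, precip_lag_z = -0.10,
             precip_change = 0.08, temp_lag_z = 0.12, temp_change = 0.05,
             human_index = 0.004, tree_index = -0.006),
    sigma_cluster = sqrt(0.05 * (pi^2 / 3) / (1 - 0.18)),
    sigma_household = sqrt(0.13 * (pi^2 / 3) / (1 - 0.18)),
    n_clusters = 500, households_per_cluster = 5, children_per_household = 2,
    urban_fraction = 0.35,
    quintile_probs_urban = c(0.08, 0.12, 0.20, 0.28, 0.32),
    quintile_probs_rural = c(0.28, 0.25, 0.20, 0.15, 0.12),
    edu_prob_urban = 0.45, edu_prob_rural = 0.20,
    water_prob_urban = 0.63, water_prob_rural = 0.22,
    san_prob_urban = 0.50, san_prob_rural = 0.20,
    age_range = c(0, 59),
    beta_tree_unimproved = 0) {
  p <- as.list(environment())
  stopifnot(length(p$beta) == 12, !is.null(names(p$beta)))
  if (p$sigma_cluster < 0 || p$sigma_household < 0)
    stop("random-intercept SDs must be non-negative")
  structure(p, class = "generating_params")
}

#' Previous calendar month with January wrapping to December
#'
#' @param month integer month(s) in 1..12.
#' @return integer month(s): `month - 1`, with 1 mapping to 12.
#' @export
lag_month <- function(month) {
  if (any(month < 1 | month > 12)) stop("month must be in 1..12")
  ifelse(month == 1, 12L, as.integer(month) - 1L)
}

# canonical order of the model's fixed-effect terms
model_terms <- function() {
  c("age", "wealth_high", "edu_secondary", "improved_sanitation",
    "improved_water", "precip_lag_z", "precip_change", "temp_lag_z",
    "temp_change", "human_index", "tree_index")
}

#' Simulate a DHS-like clustered child survey with binary diarrhea outcomes
#'
#' For every cluster a random intercept v ~ N(0, sigma_cluster) is drawn, for
#' every household u ~ N(0, sigma_household); household covariates (wealth
#' quintile, maternal education, water source, sanitation) come from the
#' stratum-specific distributions in `params`; child age is uniform on the
#' configured range. Each child's outcome is Bernoulli with probability the
#' inverse logit of the generating linear predictor.
#'
#' Water and sanitation are emitted as category labels (drawn within the
#' improved/unimproved groups of the WHO/JMP mapping); downstream assembly
#' recodes them, mirroring a real survey workflow.
#'
#' @param clusters data.frame with `cluster_id` and `urban`.
#' @param params a [generating_params()] object.
#' @param environment_tbl data.frame with one row per cluster: `cluster_id`,
#'   `human_index`, `tree_index`, `precip_lag_z`, `precip_change`,
#'   `temp_lag_z`, `temp_change`. Values enter the linear predictor as-is.
#' @param seed integer seed.
#' @return data.frame with one row per child: identifiers (`cluster_id`,
#'   `household_id`, `child_id`), `urban`, child `age` (months), household
#'   covariates (`wealth_quintile`, `water_source`, `sanitation_type`, plus
#'   the binary `wealth_high`, `edu_secondary`), and `diarrhea` (0/1).
#'   Attributes `"true_prob"` (per-child generating probabilities) and
#'   `"random_effects"` support diagnostics and tests.
#' @export
simulate_survey <- function(clusters, params, environment_tbl, seed) {
  stopifnot(inherits(params, "generating_params"))
  missing_env <- setdiff(clusters$cluster_id, environment_tbl$cluster_id)
  if (length(missing_env))
    stop("no environment values for cluster(s): ",
         paste(missing_env, collapse = ", "))
  K <- nrow(clusters)
  J <- params$households_per_cluster
  I <- params$children_per_household
  n_hh <- K * J
  n <- n_hh * I
  env <- environment_tbl[match(clusters$cluster_id, environment_tbl$cluster_id), ]
  jmp <- jmp_default_mapping()
  with_seed(substream_seed(seed, "survey"), {
    v <- rnorm(K, 0, params$sigma_cluster)
    u <- rnorm(n_hh, 0, params$sigma_household)
    hh_cl <- rep(seq_len(K), each = J)          # cluster index per household
    urban_hh <- clusters$urban[hh_cl]
    quintile <- vapply(seq_len(n_hh), function(j) {
      pr <- if (urban_hh[j] == 1) params$quintile_probs_urban
            else params$quintile_probs_rural
      sample.int(5, 1, prob = pr)
    }, integer(1))
    wealth_high <- as.integer(quintile >= 4)
    edu <- rbinom(n_hh, 1, ifelse(urban_hh == 1, params$edu_prob_urban,
                                  params$edu_prob_rural))
    wat <- rbinom(n_hh, 1, ifelse(urban_hh == 1, params$water_prob_urban,
                                  params$water_prob_rural))
    san <- rbinom(n_hh, 1, ifelse(urban_hh == 1, params$san_prob_urban,
                                  params$san_prob_rural))
    water_source <- ifelse(wat == 1,
                           sample(jmp$water$improved, n_hh, replace = TRUE),
                           sample(jmp$water$unimproved, n_hh, replace = TRUE))
    sanitation_type <- ifelse(san == 1,
                              sample(jmp$sanitation$improved, n_hh, replace = TRUE),
                              sample(jmp$sanitation$unimproved, n_hh, replace = TRUE))
    ch_hh <- rep(seq_len(n_hh), each = I)       # household index per child
    ch_cl <- hh_cl[ch_hh]
    age <- round(runif(n, params$age_range[1], params$age_range[2]))
    b <- params$beta
    eta <- b[["intercept"]] +
      b[["age"]] * age +
      b[["wealth_high"]] * wealth_high[ch_hh] +
      b[["edu_secondary"]] * edu[ch_hh] +
      b[["improved_sanitation"]] * san[ch_hh] +
      b[["improved_water"]] * wat[ch_hh] +
      b[["precip_lag_z"]] * env$precip_lag_z[ch_cl] +
      b[["precip_change"]] * env$precip_change[ch_cl] +
      b[["temp_lag_z"]] * env$temp_lag_z[ch_cl] +
      b[["temp_change"]] * env$temp_change[ch_cl] +
      b[["human_index"]] * env$human_index[ch_cl] +
      b[["tree_index"]] * env$tree_index[ch_cl] +
      params$beta_tree_unimproved * env$tree_index[ch_cl] * (1 - wat[ch_hh]) +
      v[ch_cl] + u[ch_hh]
    p <- plogis(eta)
    out <- data.frame(
      cluster_id = clusters$cluster_id[ch_cl],
      household_id = paste0(clusters$cluster_id[ch_cl], "_h",
                            rep(rep(seq_len(J), each = I), K)),
      child_id = seq_len(n),
      urban = urban_hh[ch_hh],
      age = age,
      wealth_quintile = quintile[ch_hh],
      wealth_high = wealth_high[ch_hh],
      edu_secondary = edu[ch_hh],
      water_source = water_source[ch_hh],
      sanitation_type = sanitation_type[ch_hh],
      diarrhea = rbinom(n, 1, p))
    attr(out, "true_prob") <- p
    attr(out, "random_effects") <- list(cluster = v, household = u)
    out
  })
}

#' Long-term monthly climate and survey-month terms per cluster
#'
#' Builds cluster-level long-term monthly mean precipitation and temperature
#' climatologies (seasonal sinusoids around the cluster cell's landscape
#' values, with an elevation lapse on temperature), draws a survey month per
#' cluster, and returns the one-month-lag values and month-over-month changes
#' the analysis model uses. January's lag wraps to December.
#'
#' @param grid a `landscape_grid`.
#' @param clusters data.frame from [place_clusters()] (`cluster_id`, `row`,
#'   `col`).
#' @param seed integer seed.
#' @return data.frame with `cluster_id`, `survey_month`, `precip_lag`,
#'   `precip_change`, `temp_lag`, `temp_change` (raw units: mm and deg C).
#' @export
cluster_climate <- function(grid, clusters, seed) {
  with_seed(substream_seed(seed, "climate"), {
    K <- nrow(clusters)
    base_p <- grid$precip[cbind(clusters$row, clusters$col)]
    base_t <- 26 - 0.0065 * grid$elevation[cbind(clusters$row, clusters$col)]
    phase <- runif(K, 0, 2 * pi)     # wet-season timing varies in space
    amp_p <- runif(K, 0.2, 0.6)
    amp_t <- runif(K, 1, 4)
    m <- sample.int(12, K, replace = TRUE)
    month_val <- function(base, amp, month, phase, mult) {
      s <- sin(2 * pi * month / 12 + phase)
      if (mult) pmax(0, base * (1 + amp * s)) else base + amp * s
    }
    lag_m <- lag_month(m)
    p_now <- month_val(base_p, amp_p, m, phase, TRUE)
    p_lag <- month_val(base_p, amp_p, lag_m, phase, TRUE)
    t_now <- month_val(base_t, amp_t, m, phase, FALSE)
    t_lag <- month_val(base_t, amp_t, lag_m, phase, FALSE)
    data.frame(cluster_id = clusters$cluster_id, survey_month = m,
               precip_lag = p_lag, precip_change = p_now - p_lag,
               temp_lag = t_lag, temp_change = t_now - t_lag)
  })
}
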