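# Linear predictor at the design-column means (random effects at zero,
# their distribution median), optionally overriding one column.
eta_at_means <- function(fit, override = NULL) {
  x <- fit$xbar
  if (!is.null(override)) x[names(override)] <- override
  sum(x * fit$beta)
}

me_result <- function(variable, baseline, delta, se, scenario = NA_real_) {
  data.frame(variable = variable, scenario_size = scenario,
             baseline_probability = baseline, delta_probability = delta,
             percent_reduction = 100 * abs(delta) / baseline,
             ci_low = delta - qnorm(0.975) * se,
             ci_high = delta + qnorm(0.975) * se,
             row.names = NULL)
}

#' Marginal effect at means of a binary covariate
#'
#' The discrete change in predicted diarrhea probability when the variable
#' moves from 0 to 1 with all other covariates at their sample means (binary
#' covariates at their sample proportions) and both random intercepts at
#' zero: `delta = invlogit(eta | x_v = 1) - invlogit(eta | x_v = 0)`. The 95
#' percent interval is by the delta method through the fitted coefficient
#' covariance.
#'
#' @param fit a `ws_fit`.
#' @param variable name of a binary fixed effect in the fit.
#' @return one-row data.frame: `variable`, `scenario_size` (NA for binary),
#'   `baseline_probability` (at means), `delta_probability`,
#'   `percent_reduction` (100 |delta| / baseline), `ci_low`, `ci_high`.
#' @export
me_binary <- function(fit, variable) {
  if (!variable %in% names(fit$beta))
    stop(sprintf("variable '%s' is not a fixed effect in the fit", variable))
  eta1 <- eta_at_means(fit, setNames(1, variable))
  eta0 <- eta_at_means(fit, setNames(0, variable))
  p1 <- plogis(eta1); p0 <- plogis(eta0)
  delta <- p1 - p0
  x1 <- fit$xbar; x1[variable] <- 1
  x0 <- fit$xbar; x0[variable] <- 0
  grad <- p1 * (1 - p1) * x1 - p0 * (1 - p0) * x0
  se <- sqrt(drop(t(grad) %*% fit$vcov %*% grad))
  me_result(variable, plogis(eta_at_means(fit)), delta, se)
}

#' Scenario marginal effect of a continuous covariate
#'
#' Approximates the change in diarrhea probability for a stated increase in
#' a continuous covariate by the instantaneous rate of change at the means:
#' `delta = beta_v * p * (1 - p) * increase` with `p` the at-means
#' probability (random effects at zero). For the upstream tree-cover index
#' the standard scenarios are additive increases of 10, 20 and 30 percentage
#' points; the effect is linear in the scenario size by construction.
#'
#' @param fit a `ws_fit`.
#' @param variable name of a continuous fixed effect.
#' @param increase scenario size, in the covariate's own units (percentage
#'   points for the watershed indices).
#' @return one-row data.frame as in [me_binary()], with `scenario_size` set.
#' @export
me_continuous_scenario <- function(fit, variable, increase) {
  if (!variable %in% names(fit$beta))
    stop(sprintf("variable '%s' is not a fixed effect in the fit", variable))
  bv <- fit$beta[[variable]]
  pbar <- plogis(eta_at_means(fit))
  delta <- bv * pbar * (1 - pbar) * increase
  # d delta / d beta_m = increase * [ 1{m=v} p(1-p) + b_v (1-2p) p(1-p) xbar_m ]
  grad <- increase * bv * (1 - 2 * pbar) * pbar * (1 - pbar) * fit$xbar
  grad[variable] <- grad[variable] + increase * pbar * (1 - pbar)
  se <- sqrt(drop(t(grad) %*% fit$vcov %*% grad))
  me_result(variable, pbar, delta, se, scenario = increase)
}

#' Policy comparison table of marginal effects
#'
#' One row per binary policy variable (moving it from 0 to 1) plus one row
#' per tree-cover increase scenario, sorted by absolute effect size. This is
#' the package's analogue of comparing wealth, education, improved
#' sanitation, improved water and tree-cover restoration as interventions.
#'
#' @param fit a `ws_fit`.
#' @param binary_vars binary fixed effects to include.
#' @param scenario_var continuous variable for the scenarios.
#' @param scenarios increases in the scenario variable's units.
#' @return data.frame of marginal effects, one row per option, ordered by
#'   decreasing `|delta_probability|`.
#' @export
policy_table <- function(fit,
                         binary_vars = c("wealth_high", "edu_secondary",
                                         "improved_sanitation", "improved_water"),
                         scenario_var = "tree_index",
                         scenarios = c(10, 20, 30)) {
  rows <- lapply(intersect(binary_vars, names(fit$beta)),
                 function(v) me_binary(fit, v))
  if (!is.null(scenario_var) && scenario_var %in% names(fit$beta))
    rows <- c(rows, lapply(scenarios,
                           function(s) me_continuous_scenario(fit, scenario_var, s)))
  out <- do.call(rbind, rows)
  out <- out[order(-abs(out$delta_probability)), , drop = FALSE]
  rownames(out) <- NULL
  out
}
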