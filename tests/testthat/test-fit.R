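# compact synthetic table with explicit grouping, bypassing the landscape
sim_table <- function(seed, K, J, I, beta, sv, su, x_fun = NULL) {
  set.seed(seed)
  n <- K * J * I
  cl <- rep(seq_len(K), each = J * I)
  hh <- rep(seq_len(K * J), each = I)
  tab <- data.frame(
    cluster_id = cl, household_id = hh,
    age = round(runif(n, 0, 59)),
    wealth_high = rbinom(K * J, 1, 0.3)[hh],
    edu_secondary = rbinom(K * J, 1, 0.4)[hh],
    improved_sanitation = rbinom(K * J, 1, 0.5)[hh],
    improved_water = rbinom(K * J, 1, 0.4)[hh],
    precip_lag_z = rnorm(K)[cl], precip_change = rnorm(K)[cl],
    temp_lag_z = rnorm(K)[cl], temp_change = rnorm(K)[cl],
    human_index = runif(K, 0, 60)[cl], tree_index = runif(K, 0, 80)[cl],
    urban = rbinom(K, 1, 0.4)[cl])
  X <- cbind(1, as.matrix(tab[, model_spec()$terms]))
  eta <- drop(X %*% beta) + rnorm(K, 0, sv)[cl] + rnorm(K * J, 0, su)[hh]
  tab$diarrhea <- rbinom(n, 1, plogis(eta))
  tab
}

default_beta <- c(-1.8, -0.008, -0.3, -0.35, -0.2, -0.25, -0.1, 0.08, 0.12,
                  0.05, 0.004, -0.006)

test_that("with singleton groups and zero variance the fit collapses to
           ordinary logistic regression", {
  tab <- sim_table(1, K = 1500, J = 1, I = 1, beta = default_beta,
                   sv = 0, su = 0)
  fit <- fit_three_level_logit(tab)
  gl <- glm(diarrhea ~ age + wealth_high + edu_secondary + improved_sanitation +
              improved_water + precip_lag_z + precip_change + temp_lag_z +
              temp_change + human_index + tree_index, binomial, tab)
  expect_lt(max(abs(fit$beta - coef(gl))), 1e-4)
  expect_lt(fit$sigma_cluster, 1e-3)
  expect_lt(fit$sigma_household, 1e-3)
  expect_lt(max(abs(fit$coefficients$se - summary(gl)$coefficients[, 2])), 1e-4)
})

test_that("estimates agree with an independent Laplace fit when groups are
           large enough for Laplace to be sound", {
  skip_if_not_installed("glmmTMB")
  set.seed(5)
  K <- 80; J <- 8; I <- 6; n <- K * J * I
  cl <- rep(1:K, each = J * I); hh <- rep(1:(K * J), each = I)
  x1 <- rnorm(n); x2 <- rbinom(n, 1, 0.4)
  eta <- -1.2 + 0.5 * x1 - 0.6 * x2 + rnorm(K, 0, 0.6)[cl] + rnorm(K * J, 0, 0.8)[hh]
  y <- rbinom(n, 1, plogis(eta))
  tab <- data.frame(diarrhea = y, cluster_id = cl, household_id = hh,
                    x1 = x1, x2 = x2,
                    cl_f = factor(cl), hh_f = factor(hh))
  fit <- fit_three_level_logit(tab, model_spec(terms = c("x1", "x2")))
  tmb <- glmmTMB::glmmTMB(diarrhea ~ x1 + x2 + (1 | cl_f) + (1 | hh_f),
                          family = stats::binomial(), data = tab)
  expect_lt(max(abs(fit$beta - glmmTMB::fixef(tmb)$cond)), 0.05)
  # the quadrature likelihood at its optimum dominates the Laplace value
  expect_gte(fit$loglik, as.numeric(stats::logLik(tmb)) - 1e-6)
})

test_that("the fit is invariant to row order and to ID relabeling", {
  tab <- sim_table(3, K = 60, J = 4, I = 2, beta = default_beta,
                   sv = 0.45, su = 0.72)
  f1 <- fit_three_level_logit(tab)
  set.seed(9)
  perm <- sample(nrow(tab))
  tab2 <- tab[perm, ]
  f2 <- fit_three_level_logit(tab2)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-8)
  expect_equal(f1$sigma_household, f2$sigma_household, tolerance = 1e-8)
  tab3 <- tab
  tab3$cluster_id <- paste0("K", tab$cluster_id + 1000)
  tab3$household_id <- paste0("H", tab$household_id * 7)
  f3 <- fit_three_level_logit(tab3)
  expect_equal(f1$beta, f3$beta, tolerance = 1e-8)
})

test_that("the optimized likelihood dominates the generating parameters", {
  tab <- sim_table(4, K = 100, J = 5, I = 2, beta = default_beta,
                   sv = 0.45, su = 0.72)
  fit <- fit_three_level_logit(tab)
  ll_truth <- loglik_three_level(tab, beta = default_beta,
                                 sigma_cluster = 0.45, sigma_household = 0.72)
  expect_gte(fit$loglik, ll_truth - 1e-6)
})

test_that("odds-ratio intervals are the exponentiated Wald intervals", {
  tab <- sim_table(6, K = 80, J = 4, I = 2, beta = default_beta,
                   sv = 0.3, su = 0.5)
  fit <- fit_three_level_logit(tab)
  co <- fit$coefficients
  expect_equal(co$or_low, exp(co$estimate - qnorm(0.975) * co$se), tolerance = 1e-12)
  expect_equal(co$or_high, exp(co$estimate + qnorm(0.975) * co$se), tolerance = 1e-12)
  expect_equal(co$odds_ratio, exp(co$estimate), tolerance = 1e-12)
})

test_that("degenerate outcomes are refused with informative errors", {
  tab <- sim_table(7, K = 20, J = 2, I = 2, beta = default_beta, sv = 0, su = 0)
  tab$diarrhea <- 0
  expect_error(fit_three_level_logit(tab), "single class")
  tab2 <- sim_table(8, K = 1, J = 5, I = 2, beta = default_beta, sv = 0, su = 0)
  expect_error(fit_three_level_logit(tab2), "2 clusters")
})

test_that("latent-scale ICCs follow the pi^2/3 convention", {
  fake <- function(sv, su) structure(list(sigma_cluster = sv,
                                          sigma_household = su),
                                     class = "ws_fit")
  expect_equal(icc(fake(0, 0)), c(icc_cluster = 0, icc_household = 0))
  expect_equal(icc(fake(sqrt(pi^2 / 3), 0)),
               c(icc_cluster = 0.5, icc_household = 0.5))
  # cumulative household ICC includes the cluster variance
  both <- icc(fake(0.448, 0.722))
  expect_gt(both[["icc_household"]], both[["icc_cluster"]])
  noncum <- icc(fake(0.448, 0.722), cumulative = FALSE)
  expect_equal(noncum[["icc_household"]] + both[["icc_cluster"]],
               both[["icc_household"]])
  # ICC recovery at scale is exercised in the acceptance suite
})

test_that("subgroup fits partition the sample and drop within-group constants", {
  tab <- sim_table(10, K = 120, J = 4, I = 2, beta = default_beta,
                   sv = 0.3, su = 0.5)
  sg <- subgroup_fit(tab, "urban")
  expect_identical(sum(sg$sizes), nrow(tab))
  expect_identical(sg$fits$urban$n_children + sg$fits$rural$n_children, nrow(tab))
  expect_message(sw <- subgroup_fit(tab, "improved_water"), "improved_water")
  expect_false("improved_water" %in% sw$fits$improved_water$coefficients$term)
  sa <- subgroup_fit(tab, "human_activity")
  expect_equal(sa$split_value, mean(tab$human_index))
  tab$urban <- 1
  expect_error(subgroup_fit(tab, "urban"), "empty subgroup")
})

test_that("the quartile/age-band variant recodes as documented", {
  tab <- sim_table(11, K = 150, J = 4, I = 2,
                   beta = c(-1.6, -0.008, -0.3, -0.35, -0.2, -0.25, -0.1, 0.08,
                            0.12, 0.05, 0.004, -0.02),
                   sv = 0.3, su = 0.5)
  fit <- quartile_variant_fit(tab)
  terms <- fit$coefficients$term
  expect_true(all(c("age_1yr", "age_4yr", "tree_q2", "tree_q4") %in% terms))
  expect_false(any(c("age", "tree_index") %in% terms))
  # a monotone negative tree effect orders the quartile odds ratios
  or <- fit$coefficients
  expect_lt(or$odds_ratio[or$term == "tree_q4"], 1)
  expect_lt(or$odds_ratio[or$term == "tree_q4"],
            or$odds_ratio[or$term == "tree_q2"])
  # all children in the reference age band: the band dummies vanish
  tab$age <- tab$age %% 12
  fit0 <- fit_three_level_logit(tab, model_spec(age_bands = TRUE))
  expect_false(any(grepl("^age", fit0$coefficients$term)))
  # degenerate quartiles are refused
  tab$tree_index <- 5
  expect_error(fit_three_level_logit(tab, model_spec(tree_quartiles = TRUE)),
               "not distinct")
})
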