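# hand-built fit objects give exact control over beta, vcov and xbar
fake_fit <- function(beta, xbar, vcov = NULL) {
  p <- length(beta)
  if (is.null(vcov)) vcov <- matrix(0, p, p, dimnames = list(names(beta), names(beta)))
  structure(list(beta = beta, xbar = xbar, vcov = vcov), class = "ws_fit")
}

test_that("binary marginal effect equals the difference of the two at-means
           predictions", {
  f <- fake_fit(beta = c(intercept = 0, v = -0.4),
                xbar = c(intercept = 1, v = 0))
  me <- me_binary(f, "v")
  expect_equal(me$delta_probability, plogis(-0.4) - 0.5, tolerance = 1e-12)
  expect_equal(me$baseline_probability, 0.5)
  # exact identity on a real fitted model, via independent prediction
  tab <- local({
    set.seed(2)
    n <- 1200
    d <- data.frame(cluster_id = rep(1:100, each = 12),
                    household_id = rep(1:600, each = 2),
                    x = rbinom(n, 1, 0.4), w = rnorm(n))
    d$diarrhea <- rbinom(n, 1, plogis(-1 + 0.6 * d$x - 0.3 * d$w))
    d
  })
  fit <- fit_three_level_logit(tab, model_spec(terms = c("x", "w")))
  me2 <- me_binary(fit, "x")
  x1 <- fit$xbar; x1["x"] <- 1
  x0 <- fit$xbar; x0["x"] <- 0
  oracle <- plogis(sum(x1 * fit$beta)) - plogis(sum(x0 * fit$beta))
  expect_equal(me2$delta_probability, oracle, tolerance = 1e-12)
  expect_error(me_binary(fit, "nope"), "not a fixed effect")
})

test_that("zero coefficients and zero scenarios produce zero effects", {
  f <- fake_fit(beta = c(intercept = -2, v = 0, t = 0),
                xbar = c(intercept = 1, v = 0.5, t = 20))
  expect_equal(me_binary(f, "v")$delta_probability, 0)
  expect_equal(me_continuous_scenario(f, "t", 0)$delta_probability, 0)
  expect_equal(me_continuous_scenario(f, "t", 10)$delta_probability, 0)
})

test_that("scenario effects follow the instantaneous-rate arithmetic and are
           linear in the scenario size", {
  f <- fake_fit(beta = c(intercept = qlogis(0.1), t = -0.01),
                xbar = c(intercept = 1, t = 0))
  me10 <- me_continuous_scenario(f, "t", 10)
  expect_equal(me10$delta_probability, -0.01 * 0.1 * 0.9 * 10, tolerance = 1e-12)
  me30 <- me_continuous_scenario(f, "t", 30)
  expect_equal(me30$delta_probability, 3 * me10$delta_probability, tolerance = 1e-12)
})

test_that("delta-method intervals degenerate to a point under zero variance
           and always bracket the estimate", {
  f <- fake_fit(beta = c(intercept = -1, v = -0.5),
                xbar = c(intercept = 1, v = 0.3))
  me <- me_binary(f, "v")  # vcov is all zero
  expect_equal(me$ci_low, me$delta_probability)
  expect_equal(me$ci_high, me$delta_probability)
  V <- diag(c(0.01, 0.04))
  dimnames(V) <- list(c("intercept", "v"), c("intercept", "v"))
  f2 <- fake_fit(beta = c(intercept = -1, v = -0.5),
                 xbar = c(intercept = 1, v = 0.3), vcov = V)
  me2 <- me_binary(f2, "v")
  expect_lt(me2$ci_low, me2$delta_probability)
  expect_gt(me2$ci_high, me2$delta_probability)
  # percent reduction is recomputable from delta and baseline
  expect_equal(me2$percent_reduction,
               100 * abs(me2$delta_probability) / me2$baseline_probability,
               tolerance = 1e-10)
})

test_that("for small coefficients the binary effect matches the
           instantaneous-rate approximation to second order", {
  for (b in c(0.05, 0.02, 0.01)) {
    f <- fake_fit(beta = c(intercept = -2, v = b), xbar = c(intercept = 1, v = 0))
    exact <- me_binary(f, "v")$delta_probability
    pbar <- plogis(-2 + 0 * b)
    approx <- b * plogis(sum(f$beta * f$xbar)) * (1 - plogis(sum(f$beta * f$xbar)))
    expect_lt(abs(exact - approx), b^2)  # second-order bound
  }
})

test_that("the policy table has one row per option, sorted by effect size", {
  V <- diag(0.01, 7)
  nm <- c("intercept", "wealth_high", "edu_secondary", "improved_sanitation",
          "improved_water", "human_index", "tree_index")
  dimnames(V) <- list(nm, nm)
  f <- fake_fit(beta = setNames(c(-2, -0.6, -0.8, -0.25, -0.45, 0.004, -0.004), nm),
                xbar = setNames(c(1, 0.3, 0.3, 0.4, 0.4, 20, 30), nm), vcov = V)
  pt <- policy_table(f)
  expect_identical(nrow(pt), 4L + 3L)
  expect_true(all(diff(abs(pt$delta_probability)) <= 1e-12))
  expect_setequal(pt$scenario_size[pt$variable == "tree_index"], c(10, 20, 30))
  # all-zero coefficients: every delta is zero
  f0 <- fake_fit(beta = setNames(rep(0, 7), nm), xbar = f$xbar)
  expect_true(all(policy_table(f0)$delta_probability == 0))
})
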