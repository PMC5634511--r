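#' Specification of the three-level diarrhea model
#'
#' Fixed-effect terms in canonical order (age in months; binary wealth,
#' education, sanitation, water; standardized lagged climate and changes; the
#' two upstream watershed indices in percent), with random intercepts at the
#' household-within-cluster and cluster levels. Variant flags swap the
#' continuous age for year-band dummies and the continuous tree-cover index
#' for quartile dummies; a flag is mutually exclusive with its continuous
#' term.
#'
#' @param terms character vector of fixed-effect column names (after the
#'   intercept), in order.
#' @param age_bands if `TRUE`, age enters as year-band dummies (reference:
#'   first year of life).
#' @param tree_quartiles if `TRUE`, tree cover enters as quartile dummies
#'   (reference: below the 25th percentile).
#' @return object of class `model_spec`.
#' @export
model_spec <- function(terms = model_terms(), age_bands = FALSE,
                       tree_quartiles = FALSE) {
  structure(list(terms = terms, age_bands = age_bands,
                 tree_quartiles = tree_quartiles), class = "model_spec")
}

# Gauss-Hermite nodes/log-weights rescaled for a standard normal integrand.
ghq_normal <- function(Q) {
  g <- pracma::gaussHermite(Q)
  list(z = sqrt(2) * g$x, lw = log(g$w) - 0.5 * log(pi))
}

# Design matrix (with intercept) for a spec, applying variant recodes.
build_design <- function(table, spec) {
  terms <- spec$terms
  tab <- table
  if (spec$age_bands) {
    if (any(table$age < 0 | table$age > 59)) stop("age must be in [0, 59] months")
    band <- pmin(table$age %/% 12, 4)
    for (b in 1:4) tab[[paste0("age_", b, "yr")]] <- as.integer(band == b)
    terms <- c(paste0("age_", 1:4, "yr"), setdiff(terms, "age"))
  }
  if (spec$tree_quartiles) {
    qs <- quantile(table$tree_index, c(0.25, 0.5, 0.75), names = FALSE)
    if (any(duplicated(qs)))
      stop("degenerate tree-cover quartiles: cut points are not distinct")
    # half-open bins [q25, q50), [q50, q75), [q75, Inf); reference < q25
    qn <- findInterval(table$tree_index, qs, left.open = FALSE) + 1L
    for (b in 2:4) tab[[paste0("tree_q", b)]] <- as.integer(qn == b)
    terms <- c(setdiff(terms, "tree_index"), paste0("tree_q", 2:4))
  }
  miss <- setdiff(terms, names(tab))
  if (length(miss)) stop("table lacks model columns: ", paste(miss, collapse = ", "))
  # a variant dummy can be structurally empty (e.g. every child in the
  # reference age band); such columns are dropped, not treated as covariates
  empty <- vapply(terms, function(tm)
    grepl("^(age_[1-4]yr|tree_q[2-4])$", tm) && all(tab[[tm]] == 0), logical(1))
  terms <- terms[!empty]
  X <- cbind(intercept = 1, as.matrix(tab[, terms, drop = FALSE]))
  storage.mode(X) <- "double"
  X
}

#' Fit the three-level random-intercept logistic model
#'
#' Maximizes the marginal likelihood of the logit model for child-level
#' binary outcomes with nested random intercepts at the household and cluster
#' levels. Both intercepts are integrated out with a nested Gauss-Hermite
#' product rule (default 7 nodes per level; group sizes are small, so
#' non-adaptive quadrature is accurate — see the package vignette), and the
#' likelihood is maximized with `nlminb` using the analytic gradient.
#' Standard errors come from the numerically differentiated observed
#' information; 95 percent odds-ratio intervals are Wald intervals on the
#' coefficient scale, exponentiated.
#'
#' The fit is invariant to row order: rows are sorted internally by cluster
#' and household.
#'
#' @param table analysis table from [build_table()] (or any data.frame with
#'   the model specification's columns plus `diarrhea`, `household_id`,
#'   `cluster_id`).
#' @param spec a [model_spec()].
#' @param quad_points Gauss-Hermite nodes per level.
#' @param control list passed to [nlminb()]'s control.
#' @return object of class `ws_fit`: list with `coefficients` (data.frame of
#'   term, estimate, se, odds ratio and 95 percent bounds), `beta`, `vcov`
#'   (fixed-effect block), `sigma_cluster`, `sigma_household`, `loglik`,
#'   `n_children`, `n_households`, `n_clusters`, `xbar` (design-column means,
#'   used for at-means effects), `spec`, `convergence`.
#' @export
fit_three_level_logit <- function(table, spec = model_spec(), quad_points = 7,
                                  control = list(eval.max = 2000, iter.max = 1000,
                                                 rel.tol = 1e-8)) {
  y <- table$diarrhea
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1")
  if (length(unique(y)) < 2)
    stop("outcome has a single class: model is not estimable (complete separation)")
  if (length(unique(table$cluster_id)) < 2) stop("need at least 2 clusters")
  X <- build_design(table, spec)
  # sort by cluster then household for grouped likelihood evaluation
  ord <- order(table$cluster_id, table$household_id)
  X <- X[ord, , drop = FALSE]
  y <- as.integer(y[ord])
  hh_f <- factor(paste(table$cluster_id, table$household_id, sep = "\r")[ord])
  hh <- as.integer(hh_f) - 1L
  cl_of_hh <- as.integer(factor(tapply(as.character(table$cluster_id)[ord],
                                       hh_f, `[`, 1)[levels(hh_f)])) - 1L
  n_cl <- length(unique(cl_of_hh))
  p <- ncol(X)
  qv <- ghq_normal(quad_points); qu <- ghq_normal(quad_points)

  b0 <- suppressWarnings(coef(glm.fit(X, y, family = binomial())))
  if (any(!is.finite(b0)) || any(abs(b0) > 15))
    stop("starting logistic fit is degenerate (possible complete separation)")

  # With one child per household and one household per cluster the random
  # intercepts are not identifiable (they are confounded with the child-level
  # logistic noise; only the link shape would change along a flat likelihood
  # ridge). The model then collapses, exactly, to ordinary logistic
  # regression with both variance components zero.
  if (length(levels(hh_f)) == length(y) && n_cl == length(y))
    return(collapse_glm_fit(X, y, spec, quad_points))

  # optimize on a standardized design (unit-SD, centered columns) for
  # conditioning; estimates and covariance are transformed back exactly
  mX <- colMeans(X)
  sX <- apply(X, 2, sd)
  sc <- which(colnames(X) != "intercept" & sX > 0)
  Xs <- X
  Xs[, sc] <- sweep(sweep(X[, sc, drop = FALSE], 2, mX[sc]), 2, sX[sc], "/")
  A <- diag(p)                       # beta_orig = A %*% beta_scaled
  A[1, sc] <- -mX[sc] / sX[sc]
  diag(A)[sc] <- 1 / sX[sc]
  b0s <- suppressWarnings(coef(glm.fit(Xs, y, family = binomial())))
  th0 <- c(b0s, 0.3, 0.3)

  cache <- new.env(parent = emptyenv())
  evalfg <- function(th) {
    if (!identical(cache$th, th)) {
      cache$val <- ll3_nested_cpp(th, Xs, y, hh, cl_of_hh, n_cl,
                                  qv$z, qv$lw, qu$z, qu$lw, TRUE)
      cache$th <- th
    }
    cache$val
  }
  # variance components are boxed at a latent-scale SD of 5 (an ICC of 0.88
  # with both at the bound): values beyond are substantively meaningless for
  # clustered prevalence data and lie outside the quadrature's accurate range
  lower <- c(rep(-Inf, p), 0, 0)
  upper <- c(rep(Inf, p), 5, 5)
  for (attempt in 1:4) {  # warm restarts clear occasional line-search stalls
    opt <- nlminb(th0, function(th) evalfg(th)$nll,
                  function(th) evalfg(th)$gradient,
                  lower = lower, upper = upper, control = control)
    g_at <- evalfg(opt$par)$gradient
    free <- c(rep(TRUE, p), opt$par[p + 1] > 1e-6, opt$par[p + 2] > 1e-6)
    ok <- opt$convergence == 0 ||
      max(abs(g_at[free])) <= 1e-2 * (1 + abs(opt$objective))
    if (ok) break
    th0 <- opt$par
  }
  if (!ok)
    stop("three-level fit did not converge: ", opt$message,
         sprintf(" (nll = %.6g, max |grad| = %.3g)", opt$objective,
                 max(abs(g_at[free]))))

  # observed information by central differences of the analytic gradient
  # (on the standardized scale); variance parameters at the zero boundary
  # are profiled out of the covariance
  idx <- which(free)
  Hm <- matrix(0, length(idx), length(idx))
  for (m in seq_along(idx)) {
    j <- idx[m]
    h <- 1e-5 * (1 + abs(opt$par[j]))
    tp <- opt$par; tp[j] <- tp[j] + h
    tm <- opt$par; tm[j] <- max(tm[j] - h, lower[j])
    gp <- ll3_nested_cpp(tp, Xs, y, hh, cl_of_hh, n_cl, qv$z, qv$lw, qu$z, qu$lw, TRUE)$gradient
    gm <- ll3_nested_cpp(tm, Xs, y, hh, cl_of_hh, n_cl, qv$z, qv$lw, qu$z, qu$lw, TRUE)$gradient
    Hm[m, ] <- (gp[idx] - gm[idx]) / (tp[j] - tm[j])
  }
  Hm <- (Hm + t(Hm)) / 2
  Vs_free <- tryCatch(solve(Hm), error = function(e) {
    warning("observed information is singular; using pseudo-inverse")
    s <- svd(Hm)
    pos <- s$d > max(s$d) * 1e-10
    s$v[, pos, drop = FALSE] %*% diag(1 / s$d[pos], sum(pos)) %*%
      t(s$u[, pos, drop = FALSE])
  })
  Vs <- matrix(0, p + 2, p + 2)
  Vs[idx, idx] <- Vs_free
  Afull <- diag(p + 2)
  Afull[1:p, 1:p] <- A
  V <- Afull %*% Vs %*% t(Afull)
  se_all <- sqrt(pmax(diag(V), 0))
  se_all[(p + 1):(p + 2)][!free[(p + 1):(p + 2)]] <- NA_real_

  beta <- setNames(drop(A %*% opt$par[1:p]), colnames(X))
  se <- se_all[1:p]
  zc <- qnorm(0.975)
  coefs <- data.frame(term = colnames(X), estimate = beta, se = se,
                      z = beta / se,
                      odds_ratio = exp(beta),
                      or_low = exp(beta - zc * se),
                      or_high = exp(beta + zc * se),
                      row.names = NULL)
  vb <- matrix(NA_real_, p, p, dimnames = list(colnames(X), colnames(X)))
  vb[,] <- V[1:p, 1:p]
  structure(list(coefficients = coefs, beta = beta, vcov = vb,
                 sigma_cluster = opt$par[p + 1], sigma_household = opt$par[p + 2],
                 se_sigma = se_all[(p + 1):(p + 2)],
                 loglik = -opt$objective,
                 n_children = length(y), n_households = length(levels(hh_f)),
                 n_clusters = n_cl,
                 xbar = colMeans(X), spec = spec, quad_points = quad_points,
                 convergence = list(code = opt$convergence, message = opt$message,
                                    iterations = opt$iterations,
                                    max_grad = max(abs(g_at[free])))),
            class = "ws_fit")
}

# Exact collapse limit: ordinary logistic regression packaged as a ws_fit.
collapse_glm_fit <- function(X, y, spec, quad_points) {
  gl <- glm.fit(X, y, family = binomial())
  beta <- setNames(coef(gl), colnames(X))
  mu <- gl$fitted.values
  w <- mu * (1 - mu)
  V <- solve(crossprod(X * sqrt(w)))
  dimnames(V) <- list(colnames(X), colnames(X))
  se <- sqrt(diag(V))
  zc <- qnorm(0.975)
  structure(list(
    coefficients = data.frame(term = colnames(X), estimate = beta, se = se,
                              z = beta / se, odds_ratio = exp(beta),
                              or_low = exp(beta - zc * se),
                              or_high = exp(beta + zc * se), row.names = NULL),
    beta = beta, vcov = V, sigma_cluster = 0, sigma_household = 0,
    se_sigma = c(NA_real_, NA_real_),
    loglik = sum(y * log(mu) + (1 - y) * log1p(-mu)),
    n_children = length(y), n_households = length(y), n_clusters = length(y),
    xbar = colMeans(X), spec = spec, quad_points = quad_points,
    convergence = list(code = 0L,
                       message = "singleton groups: exact collapse to ordinary logit",
                       iterations = gl$iter, max_grad = 0)), class = "ws_fit")
}

#' @export
print.ws_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Three-level random-intercept logit: %d children, %d households, %d clusters\n",
              x$n_children, x$n_households, x$n_clusters))
  cat(sprintf("log-likelihood %.3f; sigma_cluster %.4f, sigma_household %.4f\n",
              x$loglik, x$sigma_cluster, x$sigma_household))
  ic <- icc(x)
  cat(sprintf("latent-scale ICC: cluster %.4f, household (cumulative) %.4f\n\n",
              ic[["icc_cluster"]], ic[["icc_household"]]))
  print(format(x$coefficients, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Marginal log-likelihood of a fitted or hypothesized parameter vector
#'
#' Evaluates the same quadrature likelihood the fitter maximizes, at
#' arbitrary parameter values. Useful for checking that the optimum
#' dominates the generating parameters.
#'
#' @param table analysis table.
#' @param spec a [model_spec()].
#' @param beta fixed-effect vector (including intercept, in design order).
#' @param sigma_cluster,sigma_household random-intercept SDs.
#' @param quad_points nodes per level.
#' @return the marginal log-likelihood (a scalar).
#' @export
loglik_three_level <- function(table, spec = model_spec(), beta,
                               sigma_cluster, sigma_household, quad_points = 7) {
  X <- build_design(table, spec)
  ord <- order(table$cluster_id, table$household_id)
  X <- X[ord, , drop = FALSE]
  y <- as.integer(table$diarrhea[ord])
  hh_f <- factor(paste(table$cluster_id, table$household_id, sep = "\r")[ord])
  hh <- as.integer(hh_f) - 1L
  cl_of_hh <- as.integer(factor(tapply(as.character(table$cluster_id)[ord],
                                       hh_f, `[`, 1)[levels(hh_f)])) - 1L
  qv <- ghq_normal(quad_points); qu <- ghq_normal(quad_points)
  -ll3_nested_cpp(c(beta, sigma_cluster, sigma_household), X, y, hh, cl_of_hh,
                  length(unique(cl_of_hh)), qv$z, qv$lw, qu$z, qu$lw, FALSE)$nll
}

#' Latent-scale intra-class correlations of a fitted model
#'
#' Uses the logistic residual variance pi^2/3. With the cumulative
#' convention (default), the household figure includes the cluster variance —
#' the correlation between two children of the same household, which exceeds
#' the cluster ICC (the correlation between children of different households
#' in one cluster):
#' `icc_cluster = s_k^2 / T`, `icc_household = (s_k^2 + s_jk^2) / T`,
#' `T = s_k^2 + s_jk^2 + pi^2/3`. The non-cumulative convention reports
#' `s_jk^2 / T` for the household level instead.
#'
#' @param fit a `ws_fit`.
#' @param cumulative household ICC convention (default `TRUE`).
#' @return named numeric vector `icc_cluster`, `icc_household`.
#' @export
icc <- function(fit, cumulative = TRUE) {
  vk <- fit$sigma_cluster^2
  vj <- fit$sigma_household^2
  tot <- vk + vj + pi^2 / 3
  c(icc_cluster = vk / tot,
    icc_household = if (cumulative) (vk + vj) / tot else vj / tot)
}

#' Fit the same model to two complementary subgroups
#'
#' Splits the analysis table by one of the rules the subgroup analyses use —
#' urban vs rural, improved vs unimproved household water, or high vs low
#' upstream human activity (above vs below the sample mean of the provided
#' table, typically the rural subset) — and fits the identical specification
#' to each side. Covariates that are constant within a subgroup (for
#' example `improved_water` after splitting on it) are dropped from that
#' subgroup's design with a message.
#'
#' @param table analysis table.
#' @param split one of `"urban"`, `"improved_water"`, `"human_activity"`.
#' @param spec a [model_spec()].
#' @param ... passed to [fit_three_level_logit()].
#' @return list with `fits` (named list of two `ws_fit`), `sizes`, `split`,
#'   and `split_value` (the mean used, for `"human_activity"`).
#' @export
subgroup_fit <- function(table, split = c("urban", "improved_water", "human_activity"),
                         spec = model_spec(), ...) {
  split <- match.arg(split)
  split_value <- NA_real_
  if (split == "urban") {
    flag <- table$urban == 1
    labels <- c("urban", "rural")
  } else if (split == "improved_water") {
    flag <- table$improved_water == 1
    labels <- c("improved_water", "unimproved_water")
  } else {
    split_value <- mean(table$human_index)
    flag <- table$human_index >= split_value
    labels <- c("high_activity", "low_activity")
  }
  if (!any(flag) || all(flag))
    stop(sprintf("split '%s' leaves an empty subgroup", split))
  fit_one <- function(sub) {
    keep <- vapply(spec$terms, function(tm) length(unique(sub[[tm]])) > 1,
                   logical(1))
    if (!all(keep))
      message("dropping constant covariate(s) in subgroup: ",
              paste(spec$terms[!keep], collapse = ", "))
    sp <- spec; sp$terms <- spec$terms[keep]
    fit_three_level_logit(sub, sp, ...)
  }
  fits <- list(fit_one(table[flag, , drop = FALSE]),
               fit_one(table[!flag, , drop = FALSE]))
  names(fits) <- labels
  list(fits = fits, sizes = setNames(c(sum(flag), sum(!flag)), labels),
       split = split, split_value = split_value)
}

#' Alternative specification: age bands and tree-cover quartiles
#'
#' Refits the model with age as year-band dummies (reference: under 12
#' months) and upstream tree cover as quartile dummies (reference: below the
#' 25th percentile; half-open bins at the cut points).
#'
#' @param table analysis table.
#' @param ... passed to [fit_three_level_logit()].
#' @return a `ws_fit`.
#' @export
quartile_variant_fit <- function(table, ...) {
  fit_three_level_logit(table, model_spec(age_bands = TRUE,
                                          tree_quartiles = TRUE), ...)
}
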