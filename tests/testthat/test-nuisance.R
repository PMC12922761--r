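test_that("identity-link fitting matches the least-squares normal equations", {
  set.seed(11)
  n <- 80
  df <- tibble::tibble(x1 = rnorm(n), x2 = rbinom(n, 1, 0.5))
  y <- 0.3 + 0.5 * df$x1 - 0.2 * df$x2 + rnorm(n, 0, 0.3)
  spec <- regression_spec(~ x1 + x2, link = "identity")
  fit <- fit_weighted_regression(df, y, spec)
  X <- cbind(1, df$x1, df$x2)
  beta <- solve(crossprod(X), crossprod(X, y))
  expect_equal(unname(fit$coef), drop(beta), tolerance = 1e-10)
  expect_equal(fit$predict(df), drop(X %*% beta), tolerance = 1e-10)
})

test_that("duplicating a row is equivalent to doubling its weight", {
  set.seed(12)
  df <- tibble::tibble(x = rbinom(30, 1, 0.5))
  y <- rbinom(30, 1, plogis(-0.3 + 0.8 * df$x))
  spec <- regression_spec(~x)
  w <- rep(1, 30); w[7] <- 2
  f_w <- fit_weighted_regression(df, y, spec, weights = w)
  f_d <- fit_weighted_regression(df[c(1:30, 7), ], y[c(1:30, 7)], spec)
  expect_equal(f_w$coef, f_d$coef, tolerance = 1e-8)
})

test_that("saturated fits reproduce weighted stratum means exactly", {
  set.seed(13)
  df <- tibble::tibble(x = rbinom(50, 1, 0.5))
  y <- rbinom(50, 1, 0.3 + 0.3 * df$x)
  w <- runif(50, 0.5, 2)
  fit <- fit_weighted_regression(df, y, regression_spec(~x, flavor = "saturated"),
                                 weights = w)
  for (v in 0:1) {
    expect_equal(fit$predict(tibble::tibble(x = v)),
                 sum(w[df$x == v] * y[df$x == v]) / sum(w[df$x == v]),
                 tolerance = 1e-12)
  }
  # a saturated logistic glm agrees with the stratum means to solver precision
  fit_glm <- fit_weighted_regression(df, y, regression_spec(~x), weights = w)
  expect_equal(fit_glm$predict(tibble::tibble(x = 0:1)),
               fit$predict(tibble::tibble(x = 0:1)), tolerance = 1e-8)
})

test_that("the fluctuation solver finds the exact score root", {
  # already-solved offsets: epsilon = 0
  y <- c(1, 0, 1, 0)
  off <- qlogis(rep(0.5, 4))
  fl <- solve_fluctuation(y, off)
  expect_lt(abs(fl$epsilon), 1e-9)
  expect_true(fl$converged)

  # closed form: intercept-only with common offset moves logit(0.4) to logit(2/3)
  fl2 <- solve_fluctuation(c(1, 0, 1), rep(qlogis(0.4), 3))
  expect_equal(fl2$epsilon, qlogis(2 / 3) - qlogis(0.4), tolerance = 1e-9)
  expect_lt(abs(fl2$residual), 1e-12)

  # all responses at the bound: clamped with a warning
  expect_warning(fl3 <- solve_fluctuation(c(1, 1), rep(0, 2), eps_max = 10),
                 "clamped")
  expect_equal(fl3$epsilon, 10)
  expect_false(fl3$converged)

  expect_error(solve_fluctuation(numeric(0), numeric(0)), "Empty")
})

test_that("IA nuisance estimation reduces cleanly on fully observed data", {
  set.seed(14)
  n <- 300
  df <- tibble::tibble(y = rbinom(n, 1, 0.4), a = rbinom(n, 1, 0.5),
                       l_o = rbinom(n, 1, 0.5), l_m1 = rbinom(n, 1, 0.5),
                       l_m2 = rbinom(n, 1, 0.5))
  tab <- as_observed_table(df, toy_roles(2))
  fit <- estimate_nuisances_ia(tab, specs_saturated(toy_roles(2), trunc = 0.01), 1)
  # degenerate indicators stay at exactly 1 (no truncation cap)
  expect_true(all(fit$pi_rl == 1))
  expect_true(all(fit$pi_ra == 1))
  # the exposure model is the ordinary saturated propensity
  key <- paste(df$l_o, df$l_m1, df$l_m2)
  for (s in unique(key)) {
    expect_equal(fit$pi_a[key == s][1], mean(df$a[key == s] == 1),
                 tolerance = 1e-12)
  }
})

test_that("saturated IA/IB nuisances equal empirical conditional frequencies", {
  tab <- random_table(400, seed = 15)
  roles <- attr(tab, "roles")
  sp <- specs_saturated(roles)
  fit <- estimate_nuisances_ia(tab, sp, 1)
  df <- tibble::as_tibble(tab)
  r_l <- as.integer(df$r_l_m1 == 1 & df$r_l_m2 == 1)
  expect_equal(fit$pi_rl[df$l_o == 1][1], mean(r_l[df$l_o == 1]),
               tolerance = 1e-12)

  ctab <- coarsen_monotone(tab)
  fib <- estimate_nuisances_ib(ctab, sp, 1)
  cdf <- tibble::as_tibble(ctab)
  expect_equal(fib$pi_rlk[[1]][cdf$l_o == 0][1],
               mean(cdf$r_l_m1[cdf$l_o == 0]), tolerance = 1e-12)
  # level 2 conditions on level-1 observation and its value
  sub <- cdf$r_l_m1 == 1 & !is.na(cdf$l_m1) & cdf$l_m1 == 1 & cdf$l_o == 0
  pred <- fib$pi_rlk[[2]][sub][1]
  expect_equal(pred, mean(cdf$r_l_m2[sub]), tolerance = 1e-12)
  # IB refuses non-monotone input
  expect_error(estimate_nuisances_ib(tab, sp, 1), "monotone")
})

test_that("parametric nuisances on simulated data respect the truncation bounds", {
  dgp <- scenario_dgp("II")
  sim <- simulate_scenario(dgp, 1500, seed = 16)
  sp <- nuisance_specs(dgp$roles, flavor = "glm", trunc = 0.01)
  fit <- estimate_nuisances_ia(sim$data, sp, 1)
  expect_true(all(fit$prob_range >= 0.01 - 1e-12))
  expect_true(all(fit$prob_range <= 0.99 + 1e-12))
  expect_named(fit$n_trunc, c("pi_rl", "pi_ra", "pi_a"))
})

test_that("the flexible-learner hook accepts a gam-style fitter", {
  skip_if_not_installed("mgcv")
  set.seed(17)
  n <- 400
  df <- tibble::tibble(x = runif(n))
  y <- rbinom(n, 1, plogis(sin(3 * df$x)))
  spec <- regression_spec(~x, flavor = "custom", fit_fun = function(data, formula, weights) {
    mgcv::gam(.y ~ s(x), family = stats::binomial(), data = data,
              weights = weights)
  })
  fit <- fit_weighted_regression(df, y, spec)
  p <- fit$predict(df)
  expect_true(all(p > 0 & p < 1))
  # the smooth should track the truth better than a constant
  expect_lt(mean((p - plogis(sin(3 * df$x)))^2), var(y))
})
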