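test_that("influence values vanish on a degenerate fit and average to zero after targeting", {
  # all predictions equal to the (constant) outcome: every term is zero
  roles <- toy_roles(1)
  df <- tibble::tibble(y = rep(1, 5), a = c(1, 1, 0, 1, 0),
                       l_o = c(0, 1, 0, 1, 0), l_m1 = c(0, 1, 1, 0, NA))
  tab <- as_observed_table(df, roles)
  n <- 5
  fake <- list(r_l = tab$r_l_m1, r_a = tab$r_a, r = tab$r_a * tab$r_l_m1,
               pi_a = rep(0.5, n), pi_ra = rep(0.8, n), pi_rl = rep(0.8, n),
               t1_star = rep(1, n), t0_star = rep(1, n))
  iv <- eif_ia(tab, fake, psi = 1, a = 1)
  expect_equal(as.numeric(iv), rep(0, n))
  expect_error(eif_ia(tab, list(), 1, 1), "t1_star")

  # score equation holds after targeting, with parametric nuisances too
  dgp <- scenario_dgp("II")
  sim <- simulate_scenario(dgp, 1500, seed = 41)
  f_glm <- tmle_a(sim$data, a = 1,
                  specs = nuisance_specs(dgp$roles, flavor = "glm"))
  expect_lt(abs(mean(f_glm$if_values)), 1e-8)
  f_b <- tmle_b(sim$data, a = 1,
                specs = nuisance_specs(dgp$roles, flavor = "glm"))
  expect_lt(abs(mean(f_b$if_values)), 1e-8)

  # plug-ins carry no such guarantee: recompute their influence-type values
  # under a misspecified outcome model and see a nonzero mean
  sp_mis <- misspecify(nuisance_specs(dgp$roles, flavor = "saturated"),
                       "misspec-outcome")
  f_ice <- ice(sim$data, a = 1, specs = sp_mis, mode = "IA")
  f_sat <- tmle_a(sim$data, a = 1, specs = specs_saturated(dgp$roles))
  expect_gt(abs(f_ice$psi - f_sat$psi), 1e-3)
})

test_that("the IA influence function matches the numerical pathwise derivative", {
  law <- small_law_q1()
  roles <- toy_roles(1)
  tab <- law_to_table(law, roles)
  fit <- tmle_a(tab, a = 1, specs = specs_saturated(roles))
  nuis <- fit$diagnostics$nuisance
  iv <- eif_ia(tab, nuis, fit$psi, 1)

  emp <- empirical_law(tab)
  num <- gateaux_numeric(emp, roles, function(l) psi_ia_plugin(l, 1))
  # match each record's influence value to its state's derivative
  cols <- setdiff(names(emp), "prob")
  key_emp <- do.call(paste, c(as.data.frame(emp)[cols], sep = "/"))
  key_tab <- do.call(paste, c(as.data.frame(tibble::as_tibble(tab))[cols],
                              sep = "/"))
  num_per_record <- num[match(key_tab, key_emp)]
  expect_lt(max(abs(as.numeric(iv) - num_per_record)), 1e-6)
  # and the influence values integrate to zero under the law
  expect_lt(abs(sum(emp$prob * num)), 1e-6)
})

test_that("the IB influence function matches the numerical pathwise derivative", {
  law <- small_law_q2()
  roles <- toy_roles(2)
  tab <- coarsen_monotone(law_to_table(law, roles))
  fit <- tmle_b(tab, a = 1, specs = specs_saturated(roles))
  nuis <- fit$diagnostics$nuisance
  iv <- eif_ib(tab, nuis, fit$psi, 1)

  emp <- empirical_law(tab)
  num <- gateaux_numeric(emp, roles, function(l) psi_ib_plugin(l, 1), t = 2e-6)
  cols <- setdiff(names(emp), "prob")
  key_emp <- do.call(paste, c(as.data.frame(emp)[cols], sep = "/"))
  key_tab <- do.call(paste, c(as.data.frame(tibble::as_tibble(tab))[cols],
                              sep = "/"))
  num_per_record <- num[match(key_tab, key_emp)]
  expect_lt(max(abs(as.numeric(iv) - num_per_record)), 1e-6)
})

test_that("IB influence values collapse to IA for a single covariate", {
  dgp <- scenario_dgp("II")
  sim <- simulate_scenario(dgp, 1000, seed = 43)
  tab1 <- drop_lm2(sim$data)
  sp <- specs_saturated(attr(tab1, "roles"))
  fa <- tmle_a(tab1, a = 1, specs = sp)
  fb <- tmle_b(tab1, a = 1, specs = sp, ordering = "l_m1")
  expect_equal(as.numeric(fb$if_values), as.numeric(fa$if_values),
               tolerance = 1e-12)
})

test_that("influence-function variance follows the mean-square convention", {
  iv <- rep(0.3, 10)
  v <- if_variance(iv)
  expect_equal(v$sigma2, 0.09)
  expect_equal(v$se, sqrt(0.09 / 10))
  x <- c(-1.2, 0.4, 0.8, -0.1, 0.05)
  expect_equal(if_variance(x)$sigma2, mean(x^2))
  ci <- if_variance(x, psi = 0.5)$ci
  expect_equal(ci, 0.5 + c(-1, 1) * qnorm(0.975) * sqrt(mean(x^2) / 5))
})

test_that("the bootstrap is deterministic, honest about failures, and covers", {
  set.seed(44)
  df <- tibble::tibble(x = rnorm(60, mean = 2))
  # constant estimator: degenerate interval at the constant
  b0 <- bootstrap_ci(df, function(d) 0.7, b = 60, seed = 1)
  expect_equal(unname(b0$ci), c(0.7, 0.7))
  expect_equal(b0$se, 0)

  b1 <- bootstrap_ci(df, function(d) mean(d$x), b = 200, seed = 5)
  b2 <- bootstrap_ci(df, function(d) mean(d$x), b = 200, seed = 5)
  expect_identical(b1, b2)
  expect_error(bootstrap_ci(df, function(d) mean(d$x), b = 10), "at least 50")
  expect_error(
    bootstrap_ci(df, function(d) if (runif(1) < 0.5) stop("boom") else 1,
                 b = 100, seed = 6), "resamples")

  # classical coverage of the percentile interval for a sample mean
  hits <- 0
  reps <- 150
  set.seed(45)
  for (i in seq_len(reps)) {
    d <- tibble::tibble(x = rnorm(40))
    ci <- bootstrap_ci(d, function(dd) mean(dd$x), b = 200, seed = i)$ci
    hits <- hits + (ci[1] <= 0 && 0 <= ci[2])
  }
  expect_gt(hits / reps, 0.85)
  expect_lt(hits / reps, 0.995)
})

test_that("IF-based and bootstrap standard errors agree on a well-specified fixture", {
  dgp <- scenario_dgp("II")
  sim <- simulate_scenario(dgp, 2500, seed = 46)
  sp <- nuisance_specs(dgp$roles, flavor = "saturated", trunc = 0.01)
  f <- tmle_a(sim$data, a = 1, specs = sp)
  roles <- dgp$roles
  bs <- bootstrap_ci(tibble::as_tibble(sim$data),
                     function(d) tmle_a(as_observed_table(d, roles),
                                        a = 1, specs = sp)$psi,
                     b = 300, seed = 47)
  expect_lt(abs(bs$se / f$se - 1), 0.2)
  f_boot <- add_bootstrap_ci(f, tibble::as_tibble(sim$data),
                             function(d) tmle_a(as_observed_table(d, roles),
                                                a = 1, specs = sp)$psi,
                             b = 60, seed = 48)
  expect_equal(f_boot$ci_method, "boot")
  expect_length(f_boot$diagnostics$if_ci, 2)
})
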