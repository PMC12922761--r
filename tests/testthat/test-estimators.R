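test_that("complete-data TMLE reduces to stratum means and the g-formula", {
  # no covariates: mean outcome among the exposed-at-a
  set.seed(21)
  roles0 <- variable_roles("y", "a", l_o = character())
  df <- tibble::tibble(y = rbinom(100, 1, 0.4), a = rbinom(100, 1, 0.5))
  fit <- tmle_complete(df, roles0, a = 1, specs = specs_saturated(roles0))
  expect_equal(fit$psi, mean(df$y[df$a == 1]), tolerance = 1e-12)

  # one binary covariate: saturated TMLE equals the empirical g-formula
  roles1 <- variable_roles("y", "a", l_o = "l_o")
  df2 <- tibble::tibble(y = rbinom(300, 1, 0.4), a = rbinom(300, 1, 0.5),
                        l_o = rbinom(300, 1, 0.5))
  fit2 <- tmle_complete(df2, roles1, a = 1, specs = specs_saturated(roles1))
  gform <- sum(vapply(0:1, function(l) {
    mean(df2$y[df2$a == 1 & df2$l_o == l]) * mean(df2$l_o == l)
  }, numeric(1)))
  expect_equal(fit2$psi, gform, tolerance = 1e-12)
  expect_lt(abs(mean(fit2$if_values)), 1e-10)
  expect_error(tmle_complete(tibble::tibble(y = 1, a = NA_real_), roles0),
               "fully observed")
})

test_that("TMLE-A collapses to the complete-data TMLE when nothing is missing", {
  set.seed(22)
  n <- 400
  df <- tibble::tibble(y = rbinom(n, 1, 0.4), a = rbinom(n, 1, 0.5),
                       l_o = rbinom(n, 1, 0.5), l_m1 = rbinom(n, 1, 0.5),
                       l_m2 = rbinom(n, 1, 0.5))
  roles <- toy_roles(2)
  tab <- as_observed_table(df, roles)
  for (sp in list(specs_saturated(roles),
                  nuisance_specs(roles, flavor = "glm", trunc = 0))) {
    fa <- tmle_a(tab, a = 1, specs = sp)
    fc <- tmle_complete(df, roles, a = 1, specs = sp)
    expect_psi_equal(fa, fc, tol = 1e-12)
    expect_equal(as.numeric(fa$if_values), as.numeric(fc$if_values),
                 tolerance = 1e-10)
  }
})

test_that("saturated TMLE-A has zero fluctuations and equals the IA plug-in", {
  dgp <- scenario_dgp("II")
  sim <- simulate_scenario(dgp, 2000, seed = 23)
  fit <- tmle_a(sim$data, a = 1, specs = specs_saturated(dgp$roles))
  expect_lt(max(abs(fit$diagnostics$epsilon)), 1e-10)
  expect_equal(fit$psi, psi_ia_plugin(empirical_law(sim$data), 1),
               tolerance = 1e-10)
})

test_that("saturated TMLE-B equals the IB plug-in on the coarsened empirical law", {
  dgp <- scenario_dgp("III")
  sim <- simulate_scenario(dgp, 2000, seed = 24)
  fit <- tmle_b(sim$data, a = 1, specs = specs_saturated(dgp$roles))
  expect_lt(max(abs(fit$diagnostics$epsilon)), 1e-10)
  law <- empirical_law(coarsen_monotone(sim$data))
  expect_equal(fit$psi, psi_ib_plugin(law, 1), tolerance = 1e-10)
})

test_that("TMLE-B with a single covariate is exactly TMLE-A", {
  dgp <- scenario_dgp("II")
  sim <- simulate_scenario(dgp, 1500, seed = 25)
  tab1 <- drop_lm2(sim$data)
  roles1 <- attr(tab1, "roles")
  for (sp in list(specs_saturated(roles1),
                  nuisance_specs(roles1, flavor = "glm", trunc = 0.01))) {
    fa <- tmle_a(tab1, a = 1, specs = sp)
    fb <- tmle_b(tab1, a = 1, specs = sp, ordering = "l_m1")
    expect_psi_equal(fa, fb, tol = 1e-12)
    expect_equal(as.numeric(fb$if_values), as.numeric(fa$if_values),
                 tolerance = 1e-12)
  }
})

test_that("saturated ICE and IPW reproduce the plug-in functionals", {
  dgp <- scenario_dgp("II")
  sim <- simulate_scenario(dgp, 1500, seed = 26)
  sp <- specs_saturated(dgp$roles)
  law <- empirical_law(sim$data)
  expect_equal(ice(sim$data, a = 1, specs = sp, mode = "IA")$psi,
               psi_ia_plugin(law, 1), tolerance = 1e-10)
  law_b <- empirical_law(coarsen_monotone(sim$data))
  expect_equal(ice(sim$data, a = 1, specs = sp, mode = "IB")$psi,
               psi_ib_plugin(law_b, 1), tolerance = 1e-10)
  # saturated IPW also collapses to the plug-in
  expect_equal(ipw(sim$data, a = 1, specs = sp, mode = "IA")$psi,
               psi_ia_plugin(law, 1), tolerance = 1e-10)
})

test_that("IPW matches hand-computed Horvitz-Thompson weights", {
  # complete data, constant propensity: psi = mean(1{A=a} Y) / P(A=a)
  set.seed(27)
  roles0 <- variable_roles("y", "a", l_o = character())
  df <- tibble::tibble(y = rbinom(200, 1, 0.4), a = rbinom(200, 1, 0.3))
  f <- ipw(as_observed_table(df, roles0), a = 1,
           specs = specs_saturated(roles0), mode = "IA")
  expect_equal(f$psi, mean((df$a == 1) * df$y) / mean(df$a == 1),
               tolerance = 1e-12)

  # 4-record worked fixture, one binary covariate
  roles1 <- variable_roles("y", "a", l_o = "l_o")
  d4 <- tibble::tibble(y = c(1, 0, 1, 1), a = c(1, 1, 0, 1),
                       l_o = c(0, 0, 1, 1))
  f4 <- ipw(as_observed_table(d4, roles1), a = 1,
            specs = specs_saturated(roles1), mode = "IA")
  # pi_a(l_o=0) = 1, pi_a(l_o=1) = 1/2; records 1, 2, 4 contribute
  expect_equal(f4$psi, (1 / 1 + 0 / 1 + 1 / 0.5) / 4, tolerance = 1e-12)
  expect_equal(f4$diagnostics$weight_range, c(1, 2))
})

test_that("MI with nothing missing degenerates to the complete-data TMLE", {
  set.seed(28)
  roles <- toy_roles(1)
  df <- tibble::tibble(y = rbinom(150, 1, 0.4), a = rbinom(150, 1, 0.5),
                       l_o = rbinom(150, 1, 0.5), l_m1 = rbinom(150, 1, 0.5))
  sp <- specs_saturated(roles)
  f_mi <- mi_then_tmle(df, roles, a = 1, specs = sp, m = 3, seed = 1)
  f_c <- tmle_complete(df, roles, a = 1, specs = sp)
  expect_psi_equal(f_mi, f_c, tol = 1e-12)
  expect_equal(f_mi$diagnostics$between, 0)

  # with real missingness, imputation fills everything and pooling works
  df$a[1:30] <- NA; df$l_m1[10:45] <- NA
  f2 <- mi_then_tmle(df, roles, a = 1, specs = sp, m = 4, maxit = 3,
                     seed = 2, mi_flavor = "saturated")
  expect_gt(f2$diagnostics$between, 0)
  expect_true(f2$ci[1] < f2$psi & f2$psi < f2$ci[2])
  # same seed, same answer
  f3 <- mi_then_tmle(df, roles, a = 1, specs = sp, m = 4, maxit = 3,
                     seed = 2, mi_flavor = "saturated")
  expect_equal(f2$psi, f3$psi, tolerance = 1e-15)
})

test_that("estimates and targeted predictions respect the outcome bounds", {
  for (seed in c(31, 32)) {
    tab <- random_table(250, seed = seed)
    roles <- attr(tab, "roles")
    for (sp in list(specs_saturated(roles, trunc = 0.01),
                    nuisance_specs(roles, flavor = "glm", trunc = 0.01))) {
      for (f in list(tmle_a(tab, a = 1, specs = sp),
                     tmle_b(tab, a = 1, specs = sp),
                     ice(tab, a = 1, specs = sp, mode = "IA"))) {
        expect_gte(f$psi, 0); expect_lte(f$psi, 1)
      }
    }
  }
})

test_that("causal contrasts combine influence functions", {
  dgp <- scenario_dgp("II")
  sim <- simulate_scenario(dgp, 1200, seed = 33)
  sp <- specs_saturated(dgp$roles)
  f1 <- tmle_a(sim$data, a = 1, specs = sp)
  f0 <- tmle_a(sim$data, a = 0, specs = sp)
  ct <- contrast_fits(f1, f0)
  expect_equal(ct$estimate, f1$psi - f0$psi)
  expect_true(ct$conf.low < ct$estimate & ct$estimate < ct$conf.high)
  cv <- contrast_vs_observed(f0, sim$data$y)
  expect_equal(cv$estimate, mean(sim$data$y) - f0$psi)
  expect_true(is.finite(cv$std.error))
})

test_that("tidy, glance and autoplot expose the fit", {
  dgp <- scenario_dgp("II")
  sim <- simulate_scenario(dgp, 800, seed = 34)
  f <- tmle_a(sim$data, a = 1, specs = specs_saturated(dgp$roles))
  td <- tidy(f)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$estimate, f$psi)
  expect_true(td$conf.low <= f$psi & f$psi <= td$conf.high)
  gl <- glance(f)
  expect_equal(gl$n, 800)
  expect_lt(abs(gl$mean_if), 1e-8)
  expect_s3_class(autoplot(f), "ggplot")
  path <- withr::local_tempfile(fileext = ".json")
  write_result_json(f, path)
  parsed <- jsonlite::read_json(path)
  expect_equal(parsed$estimate, f$psi)
  expect_equal(parsed$ci_method, "if")
})
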