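#' Structural-equation data-generating processes for the simulation study
#'
#' Builds the generator behind the package's Monte-Carlo study: a binary
#' outcome `y`, a partially observed binary exposure `a`, a fully observed
#' confounder `l_o` and two partially observed confounders `l_m1`, `l_m2`,
#' with latent Bernoulli(1/2) common causes `u1` (of `l_o`, `l_m`), `u2`
#' (of `l_m`, `y`), `u3` (of `l_o`, `y`), `u_ar` (of `a`, `r_a`) and `u_al`
#' (of `a`, the covariate observation indicators). All structural equations
#' are logistic. The three scenarios differ only in the missingness block:
#'
#' * **I** — a single indicator `r` governs `(a, l_m1, l_m2)` jointly and
#'   depends on `l_o` only (missing at random; with `mar_y = TRUE` it also
#'   depends on `y`, the most general mechanism the MAR assumption allows).
#' * **II** — `r_a` depends on `a`, `l_m1`, `l_m2` and the latent `u_ar`;
#'   a joint covariate indicator depends on `l_o` and `u_al` (the
#'   outcome-independent MNAR mechanism with exposure-driven exposure
#'   missingness).
#' * **III** — as II, but `l_m1` and `l_m2` have separate indicators and
#'   the observation of `l_m2` additionally depends on `l_m1` (the
#'   block-conditional MNAR mechanism).
#'
#' Default coefficients are calibrated by exact enumeration so that joint
#' missingness sits in the 20–30% band, exposure prevalence is non-extreme,
#' and `E(Y^{a=1})` is close to 0.29; every coefficient can be overridden.
#'
#' @param scenario `"I"`, `"II"` or `"III"`.
#' @param coefs Named list of named numeric vectors overriding the default
#'   structural equations (element `"(Intercept)"` plus one element per
#'   parent variable, on the logit scale).
#' @param mar_y Scenario I only: let the missingness indicator depend on the
#'   outcome as well as `l_o`.
#'
#' @return An object of class `scenario_dgp`.
#' @examples
#' dgp <- scenario_dgp("II")
#' sim <- simulate_scenario(dgp, n = 500, seed = 7)
#' summarize_missingness(sim$data)
#' @export
scenario_dgp <- function(scenario = c("I", "II", "III"), coefs = NULL,
                         mar_y = FALSE) {
  scenario <- match.arg(scenario)
  eqs <- dgp_default_eqs(scenario, mar_y)
  if (!is.null(coefs)) {
    bad <- setdiff(names(coefs), names(eqs))
    if (length(bad)) abort(paste0("Unknown equation(s): ", paste(bad, collapse = ", ")))
    for (v in names(coefs)) {
      eqs[[v]] <- replace_coefs(eqs[[v]], coefs[[v]])
    }
  }
  latents <- c("u1", "u2", "u3", "u_ar", "u_al")
  indicators <- switch(scenario,
    I = "r",
    II = c("r_a", "r_l"),
    III = c("r_a", "r_l_m1", "r_l_m2"))
  structure(
    list(scenario = scenario, mar_y = mar_y, eqs = eqs, latents = latents,
         indicators = indicators, q = 2L,
         roles = variable_roles(outcome = "y", exposure = "a", l_o = "l_o",
                                l_m = c("l_m1", "l_m2"))),
    class = "scenario_dgp")
}

replace_coefs <- function(eq, new) {
  bad <- setdiff(names(new), names(eq))
  if (length(bad)) abort(paste0("Unknown coefficient(s): ", paste(bad, collapse = ", ")))
  eq[names(new)] <- new
  eq
}

# Calibrated once against the enumerated law (see the methods vignette):
# missing-any fractions ~ I 0.26, II 0.25, III 0.27; P(A=1) ~ 0.50;
# E(Y^{a=1}) ~ 0.30, E(Y^{a=0}) ~ 0.20.
dgp_default_eqs <- function(scenario, mar_y) {
  eqs <- list(
    u1   = c("(Intercept)" = 0),
    u2   = c("(Intercept)" = 0),
    u3   = c("(Intercept)" = 0),
    u_ar = c("(Intercept)" = 0),
    u_al = c("(Intercept)" = 0),
    l_o  = c("(Intercept)" = -0.2, u1 = 0.8, u3 = 0.6),
    l_m1 = c("(Intercept)" = -0.3, u1 = 0.7, u2 = 0.7),
    l_m2 = c("(Intercept)" = 0.1, u1 = -0.6, u2 = 0.5),
    a    = c("(Intercept)" = -0.9, l_o = 0.5, l_m1 = 0.6, l_m2 = -0.4,
             u_ar = 0.5, u_al = 0.4),
    y    = c("(Intercept)" = -2.55, a = 0.6, l_o = 0.5, l_m1 = 0.7,
             l_m2 = -0.5, u2 = 0.6, u3 = 0.5)
  )
  miss <- switch(scenario,
    I = if (mar_y) {
      list(r = c("(Intercept)" = 1.7, l_o = -0.5, y = -0.6))
    } else {
      list(r = c("(Intercept)" = 1.5, l_o = -0.7))
    },
    II = list(
      r_a = c("(Intercept)" = 2.9, a = -0.5, l_m1 = -0.5, l_m2 = -0.4,
              u_ar = -0.5),
      r_l = c("(Intercept)" = 2.6, l_o = -0.6, u_al = -0.5)),
    III = list(
      r_a    = c("(Intercept)" = 2.9, a = -0.5, l_m1 = -0.5, l_m2 = -0.4,
                 u_ar = -0.5),
      r_l_m1 = c("(Intercept)" = 3.4, l_o = -0.6, u_al = -0.5),
      r_l_m2 = c("(Intercept)" = 3.3, l_o = -0.5, l_m1 = -0.8, u_al = -0.4)))
  c(eqs, miss)
}

#' @export
print.scenario_dgp <- function(x, ...) {
  cat("<scenario_dgp> scenario", x$scenario,
      if (x$scenario == "I" && x$mar_y) "(outcome-dependent R)" else "", "\n")
  for (v in names(x$eqs)) {
    cat(sprintf("  %-7s ~ logit(%s)\n", v,
                paste(sprintf("%+.2f%s", x$eqs[[v]],
                              ifelse(names(x$eqs[[v]]) == "(Intercept)", "",
                                     paste0("*", names(x$eqs[[v]])))),
                      collapse = " ")))
  }
  invisible(x)
}

lin_pred <- function(eq, values) {
  out <- rep(eq[["(Intercept)"]], nrow(values))
  for (p in setdiff(names(eq), "(Intercept)")) {
    out <- out + eq[[p]] * values[[p]]
  }
  out
}

#' Simulate one dataset from a scenario generator
#'
#' Draws the latent common causes, covariates, exposure and outcome from the
#' structural equations, draws the missingness indicators according to the
#' scenario's mechanism, and masks values accordingly. Counterfactual
#' outcomes `Y^0`, `Y^1` are generated with common exogenous noise (so
#' consistency `Y = Y^A` holds record by record) and returned for truth
#' tracking; they are never part of the observed table.
#'
#' @param dgp A [scenario_dgp()].
#' @param n Number of records.
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#' @return A list of class `scenario_sim`: `data` (masked [as_observed_table()]
#'   tibble), `potential` (tibble with `y0`, `y1`), and `shadow` (the
#'   unmasked observed variables plus indicators, for masking checks).
#' @export
simulate_scenario <- function(dgp, n, seed = NULL) {
  stopifnot(inherits(dgp, "scenario_dgp"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  vals <- tibble::tibble(.rows = n)
  for (v in setdiff(names(dgp$eqs), c("y", dgp$indicators))) {
    vals[[v]] <- rbinom(n, 1, plogis(lin_pred(dgp$eqs[[v]], vals)))
  }
  # common exogenous uniform for factual and counterfactual outcomes
  ey <- runif(n)
  y_under <- function(a_val) {
    va <- vals
    va$a <- a_val
    as.integer(ey < plogis(lin_pred(dgp$eqs$y, va)))
  }
  y0 <- y_under(0L)
  y1 <- y_under(1L)
  vals$y <- ifelse(vals$a == 1, y1, y0)
  for (v in dgp$indicators) {
    vals[[v]] <- rbinom(n, 1, plogis(lin_pred(dgp$eqs[[v]], vals)))
  }
  ind <- expand_indicators(dgp, vals)
  shadow <- dplyr::bind_cols(
    vals[c("y", "a", "l_o", "l_m1", "l_m2")], ind)
  masked <- shadow
  masked$a[ind$r_a == 0] <- NA
  masked$l_m1[ind$r_l_m1 == 0] <- NA
  masked$l_m2[ind$r_l_m2 == 0] <- NA
  structure(
    list(data = as_observed_table(masked, dgp$roles),
         potential = tibble::tibble(y0 = y0, y1 = y1),
         shadow = shadow),
    class = "scenario_sim")
}

# map scenario-specific indicator variables onto one indicator per
# partially observable column
expand_indicators <- function(dgp, vals) {
  switch(dgp$scenario,
    I = tibble::tibble(r_a = vals$r, r_l_m1 = vals$r, r_l_m2 = vals$r),
    II = tibble::tibble(r_a = vals$r_a, r_l_m1 = vals$r_l,
                        r_l_m2 = vals$r_l),
    III = tibble::tibble(r_a = vals$r_a, r_l_m1 = vals$r_l_m1,
                         r_l_m2 = vals$r_l_m2))
}

#' Exactly enumerate the law implied by a scenario generator
#'
#' Tabulates the full joint probability mass function of the observed
#' variables and observation indicators by exact marginalization over the
#' latent common causes (all variables are Bernoulli, so the state space is
#' tiny). The result is the package's ground-truth object: identification
#' oracles evaluate their functionals on it by exact summation.
#'
#' @param dgp A [scenario_dgp()].
#' @return A `discrete_law` tibble: one row per full-data state
#'   `(l_o, l_m1, l_m2, a, y, r_a, r_l_m1, r_l_m2)` with its probability.
#'   Values of `a` / `l_m` are *not* masked here; use [observed_law()] for
#'   the coarsened observed-data law.
#' @export
enumerate_law <- function(dgp) {
  stopifnot(inherits(dgp, "scenario_dgp"))
  vars <- names(dgp$eqs)
  if (length(vars) > 20) abort("State space exceeds the enumeration cap.")
  grid <- do.call(tidyr::expand_grid,
                  setNames(rep(list(c(0L, 1L)), length(vars)), vars))
  prob <- rep(1, nrow(grid))
  for (v in vars) {
    p <- plogis(lin_pred(dgp$eqs[[v]], grid))
    prob <- prob * ifelse(grid[[v]] == 1, p, 1 - p)
  }
  grid$prob <- prob
  ind <- expand_indicators(dgp, grid)
  states <- dplyr::bind_cols(grid[c("l_o", "l_m1", "l_m2", "a", "y")], ind)
  states$prob <- grid$prob
  states <- states |>
    dplyr::group_by(dplyr::across(-"prob")) |>
    dplyr::summarise(prob = sum(.data$prob), .groups = "drop")
  new_discrete_law(states, dgp$roles)
}

#' Construct a discrete law
#'
#' A discrete law is a finite probability mass function over full- or
#' observed-data states, stored as a tibble with a `prob` column and carrying
#' the variable roles. Probabilities must be nonnegative and sum to one.
#'
#' @param states Tibble of states with a `prob` column.
#' @param roles A [variable_roles()] object describing the columns.
#' @return A `discrete_law` tibble.
#' @export
new_discrete_law <- function(states, roles) {
  states <- tibble::as_tibble(states)
  stopifnot("prob" %in% names(states))
  if (any(states$prob < -1e-12)) abort("Negative probability in law.")
  if (abs(sum(states$prob) - 1) > 1e-8) {
    abort("Law probabilities must sum to 1.")
  }
  structure(states, roles = roles,
            class = c("discrete_law", class(tibble::tibble())))
}

#' Coarsen a full-data law to the observed-data law
#'
#' Masks exposure and covariate values on states where the corresponding
#' indicator is zero (setting them to `NA`) and aggregates states that become
#' indistinguishable. This is the distribution of the observed data `O`.
#'
#' @param law A full-data `discrete_law` (e.g. from [enumerate_law()]).
#' @return A `discrete_law` over observed-data states.
#' @export
observed_law <- function(law) {
  roles <- attr(law, "roles")
  out <- tibble::as_tibble(law)
  out[[roles$exposure]][out[[r_col(roles$exposure)]] == 0] <- NA
  for (v in roles$l_m) out[[v]][out[[r_col(v)]] == 0] <- NA
  out <- out |>
    dplyr::group_by(dplyr::across(-"prob")) |>
    dplyr::summarise(prob = sum(.data$prob), .groups = "drop")
  new_discrete_law(out, roles)
}

#' Empirical law of an observed-data table
#'
#' The empirical distribution (relative frequencies of observed-data states)
#' as a `discrete_law`; with saturated nuisance models the targeted
#' estimators coincide with the identification functionals evaluated on this
#' law, which the test-suite exploits.
#'
#' @param table An `obs_table`.
#' @return A `discrete_law`.
#' @export
empirical_law <- function(table) {
  roles <- attr(table, "roles")
  cols <- c(roles$outcome, roles$exposure, roles$l_o, roles$l_m,
            r_col(c(roles$exposure, roles$l_m)))
  out <- tibble::as_tibble(table)[cols] |>
    dplyr::count(dplyr::across(dplyr::everything())) |>
    dplyr::mutate(prob = .data$n / sum(.data$n)) |>
    dplyr::select(-"n")
  new_discrete_law(out, roles)
}

#' True average potential outcome of a scenario generator
#'
#' Intervenes `A := a` in the outcome equation and returns `E(Y^a)`, either
#' by exact enumeration over the latent causes and covariates (default) or
#' by Monte Carlo with a reported simulation standard error.
#'
#' @param dgp A [scenario_dgp()].
#' @param a Exposure level (0 or 1).
#' @param method `"enumerate"` (exact) or `"mc"`.
#' @param n_mc Monte-Carlo draws when `method = "mc"`.
#' @param seed Seed for the Monte-Carlo path.
#' @return The mean counterfactual outcome; for `"mc"` the result carries an
#'   `mc_se` attribute.
#' @export
true_potential_mean <- function(dgp, a, method = c("enumerate", "mc"),
                                n_mc = 1e6, seed = NULL) {
  stopifnot(inherits(dgp, "scenario_dgp"))
  if (!a %in% c(0, 1)) abort("`a` must be an exposure level (0 or 1).")
  method <- match.arg(method)
  if (method == "enumerate") {
    pre <- setdiff(names(dgp$eqs), c("y", dgp$indicators, "a"))
    grid <- do.call(tidyr::expand_grid,
                    setNames(rep(list(c(0L, 1L)), length(pre)), pre))
    prob <- rep(1, nrow(grid))
    for (v in pre) {
      p <- plogis(lin_pred(dgp$eqs[[v]], grid))
      prob <- prob * ifelse(grid[[v]] == 1, p, 1 - p)
    }
    # A itself depends on the same ancestors; intervening removes its draw
    grid$a <- a
    sum(prob * plogis(lin_pred(dgp$eqs$y, grid)))
  } else {
    if (!is.null(seed)) set.seed(seed)
    vals <- tibble::tibble(.rows = n_mc)
    for (v in setdiff(names(dgp$eqs), c("y", dgp$indicators))) {
      vals[[v]] <- rbinom(n_mc, 1, plogis(lin_pred(dgp$eqs[[v]], vals)))
    }
    vals$a <- a
    ya <- rbinom(n_mc, 1, plogis(lin_pred(dgp$eqs$y, vals)))
    structure(mean(ya), mc_se = sd(ya) / sqrt(n_mc))
  }
}

#' Save or load a scenario generator as a YAML configuration
#'
#' Serializes the scenario label and every structural-equation coefficient
#' to a plain YAML file, so alternative parameterizations can be versioned
#' and reloaded (for fixture reuse or to drop in published coefficient
#' sets).
#'
#' @param dgp A [scenario_dgp()].
#' @param path YAML file path.
#' @return `dgp_save()` returns `path` invisibly; `dgp_load()` returns a
#'   `scenario_dgp`.
#' @export
dgp_save <- function(dgp, path) {
  stopifnot(inherits(dgp, "scenario_dgp"))
  yaml::write_yaml(list(scenario = dgp$scenario, mar_y = dgp$mar_y,
                        eqs = lapply(dgp$eqs, as.list)), path)
  invisible(path)
}

#' @rdname dgp_save
#' @export
dgp_load <- function(path) {
  cfg <- yaml::read_yaml(path)
  coefs <- lapply(cfg$eqs, function(e) unlist(e))
  scenario_dgp(cfg$scenario, coefs = coefs, mar_y = isTRUE(cfg$mar_y))
}
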