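#' Configure a Monte-Carlo study
#'
#' Bundles the design of a simulation experiment: scenario generator
#' settings, sample size, replicate count, the estimator roster, and which
#' nuisance-model specification regimes to run. The three regimes mirror
#' the robustness experiment: all models correct, outcome models
#' misspecified, exposure model misspecified.
#'
#' @param scenario `"I"`, `"II"` or `"III"` (selects the default estimator
#'   roster; the generator itself is passed to [run_study()]).
#' @param n Records per simulated dataset.
#' @param reps Number of replicates.
#' @param estimators Character vector from `"cc"`, `"mi"`, `"ice_a"`,
#'   `"ipw_a"`, `"tmle_a"`, `"ice_b"`, `"ipw_b"`, `"tmle_b"`, `"oracle"`;
#'   defaults to the roster matching the scenario (A-estimators for I-II,
#'   B-estimators for III).
#' @param modes Subset of `"all-correct"`, `"misspec-outcome"`,
#'   `"misspec-exposure"`.
#' @param a Exposure level of interest.
#' @param flavor Nuisance flavor for the correctly specified models
#'   (`"saturated"` is exactly correct on the all-binary generator).
#' @param trunc Probability truncation for the nuisance fits.
#' @param mi_m,mi_maxit Imputation count and chained-equation sweeps for the
#'   MI estimator.
#' @param ci `"if"` (influence-function / Rubin intervals where available)
#'   or `"boot"` (percentile bootstrap for every estimator).
#' @param boot_b Bootstrap resamples when `ci = "boot"`.
#' @param ordering Covariate ordering for the B-estimators.
#' @param seed Master seed; replicate seeds are derived from it, so results
#'   do not depend on execution order.
#' @param truth Optional known value of `E(Y^a)` (otherwise computed by
#'   [true_potential_mean()]).
#' @return A `study_config` list.
#' @export
study_config <- function(scenario = c("II", "I", "III"), n = 2500,
                         reps = 1000, estimators = NULL,
                         modes = c("all-correct", "misspec-outcome",
                                   "misspec-exposure"),
                         a = 1, flavor = "saturated", trunc = 0.01,
                         mi_m = 10, mi_maxit = 5,
                         ci = c("if", "boot"), boot_b = 200,
                         ordering = NULL, seed = 1, truth = NULL) {
  scenario <- match.arg(scenario)
  ci <- match.arg(ci)
  modes <- match.arg(modes, several.ok = TRUE)
  estimators <- estimators %||% switch(scenario,
    I = c("cc", "mi", "ice_a", "ipw_a", "tmle_a"),
    II = c("cc", "mi", "ice_a", "ipw_a", "tmle_a"),
    III = c("cc", "mi", "ice_b", "ipw_b", "tmle_b"))
  known <- c("cc", "mi", "ice_a", "ipw_a", "tmle_a", "ice_b", "ipw_b",
             "tmle_b", "oracle")
  bad <- setdiff(estimators, known)
  if (length(bad)) abort(paste0("Unknown estimator(s): ", paste(bad, collapse = ", ")))
  stopifnot(reps >= 1, n >= 10)
  structure(list(scenario = scenario, n = n, reps = reps,
                 estimators = estimators, modes = modes, a = a,
                 flavor = flavor, trunc = trunc, mi_m = mi_m,
                 mi_maxit = mi_maxit, ci = ci, boot_b = boot_b,
                 ordering = ordering, seed = seed, truth = truth),
            class = "study_config")
}

#' Distort nuisance specifications for a robustness experiment
#'
#' Returns a modified specification set implementing one of the
#' misspecification regimes: `"misspec-outcome"` replaces the outcome and
#' downstream sequential regressions by main-effects logistic models that
#' omit the partially observed confounders; `"misspec-exposure"` does the
#' same to the exposure model only. Models not named by the regime are left
#' untouched, so each regime isolates one set of nuisance functions.
#'
#' @param specs A [nuisance_specs()] set (must carry `roles`).
#' @param mode One of `"all-correct"`, `"misspec-outcome"`,
#'   `"misspec-exposure"`.
#' @return A `nuisance_specs` set.
#' @export
misspecify <- function(specs, mode = c("all-correct", "misspec-outcome",
                                       "misspec-exposure")) {
  mode <- match.arg(mode)
  roles <- specs$roles
  if (is.null(roles)) abort("`specs` does not carry variable roles.")
  if (mode == "all-correct") return(specs)
  lo <- roles$l_o
  if (mode == "misspec-outcome") {
    specs$outcome <- regression_spec(one_sided(c(roles$exposure, lo)),
                                     flavor = "glm")
    specs$seqk <- lapply(specs$seqk, function(s) {
      regression_spec(one_sided(lo), flavor = "glm")
    })
    specs$seq0 <- regression_spec(one_sided(lo), flavor = "glm")
  } else {
    specs$exposure <- regression_spec(one_sided(lo), flavor = "glm")
  }
  specs
}

run_one_estimator <- function(est, data, sp, config, imps, truth) {
  a <- config$a
  fit <- switch(est,
    cc = cc_tmle(data, a = a, specs = sp),
    mi = mi_then_tmle(data, a = a, specs = sp, imputations = imps),
    ice_a = ice(data, a = a, specs = sp, mode = "IA"),
    ipw_a = ipw(data, a = a, specs = sp, mode = "IA"),
    tmle_a = tmle_a(data, a = a, specs = sp),
    ice_b = ice(data, a = a, specs = sp, mode = "IB",
                ordering = config$ordering),
    ipw_b = ipw(data, a = a, specs = sp, mode = "IB",
                ordering = config$ordering),
    tmle_b = tmle_b(data, a = a, specs = sp, ordering = config$ordering),
    oracle = new_psi_fit(truth, "oracle", "truth", a, nrow(data),
                         se = 0.01, ci = truth + c(-1, 1) * 0.01,
                         ci_method = "fixed"))
  if (config$ci == "boot" && est != "oracle") {
    closure <- function(d) run_one_estimator(est, as_observed_table(
      d, attr(data, "roles")), sp,
      modifyList(config, list(ci = "if")), NULL, truth)
    # MI inside the bootstrap re-imputes each resample
    if (est == "mi") closure <- function(d) {
      mi_then_tmle(as_observed_table(d, attr(data, "roles")), a = a,
                   specs = sp, m = config$mi_m, maxit = config$mi_maxit)
    }
    bs <- bootstrap_ci(tibble::as_tibble(data),
                       function(d) closure(d)$psi, b = config$boot_b)
    fit$ci <- bs$ci; fit$se <- bs$se; fit$ci_method <- "boot"
  }
  fit
}

#' Run a Monte-Carlo study
#'
#' For each replicate: simulate a dataset from the generator, and apply
#' every configured estimator under every specification regime, recording
#' the point estimate and confidence interval. Metrics follow the usual
#' reporting convention: bias, empirical standard error and 95% coverage
#' probability, all multiplied by 100, each with its Monte-Carlo standard
#' error. Replicate seeds are derived from the master seed.
#'
#' @param config A [study_config()].
#' @param dgp The [scenario_dgp()] generator to simulate from (defaults to
#'   `scenario_dgp(config$scenario)`).
#' @return A tibble of class `study_metrics` (one row per estimator x
#'   regime) with attributes `truth`, `config` and `estimates` (the
#'   replicate-level results).
#' @export
run_study <- function(config, dgp = scenario_dgp(config$scenario)) {
  stopifnot(inherits(config, "study_config"), inherits(dgp, "scenario_dgp"))
  truth <- config$truth %||% true_potential_mean(dgp, config$a)
  roles <- dgp$roles
  base_specs <- nuisance_specs(roles, flavor = config$flavor,
                               trunc = config$trunc)
  spec_by_mode <- lapply(setNames(config$modes, config$modes),
                         function(m) misspecify(base_specs, m))
  rows <- vector("list", config$reps)
  for (r in seq_len(config$reps)) {
    seed_r <- (config$seed * 1000003 + r * 7919) %% 2147483629
    sim <- simulate_scenario(dgp, config$n, seed = seed_r)
    imps <- NULL
    if ("mi" %in% config$estimators) {
      imps <- mi_impute(sim$data, m = config$mi_m, maxit = config$mi_maxit,
                        seed = seed_r + 13, mi_flavor = "saturated")
    }
    out <- list()
    for (mode in config$modes) {
      sp <- spec_by_mode[[mode]]
      for (est in config$estimators) {
        # MI's imputation models are not part of the misspecification
        # regimes, so it is evaluated once (under the first regime)
        if (est == "mi" && mode != config$modes[1]) next
        fit <- tryCatch(
          run_one_estimator(est, sim$data, sp, config, imps, truth),
          error = function(e) NULL)
        out[[paste(mode, est)]] <- tibble::tibble(
          rep = r, mode = mode, estimator = est,
          psi = if (is.null(fit)) NA_real_ else fit$psi,
          ci_lo = if (is.null(fit)) NA_real_ else fit$ci[1],
          ci_hi = if (is.null(fit)) NA_real_ else fit$ci[2])
      }
    }
    rows[[r]] <- dplyr::bind_rows(out)
  }
  est_tbl <- dplyr::bind_rows(rows)

  fail <- est_tbl |>
    dplyr::group_by(.data$mode, .data$estimator) |>
    dplyr::summarise(frac = mean(is.na(.data$psi)), .groups = "drop")
  if (any(fail$frac > 0.05)) {
    worst <- fail[which.max(fail$frac), ]
    abort(paste0("More than 5% of replicates failed for ", worst$estimator,
                 " (", worst$mode, "): ", round(100 * worst$frac, 1), "%."))
  }

  metrics <- est_tbl |>
    dplyr::filter(!is.na(.data$psi)) |>
    dplyr::group_by(.data$mode, .data$estimator) |>
    dplyr::summarise(
      n_rep = dplyr::n(),
      bias100 = 100 * (mean(.data$psi) - truth),
      se100 = 100 * sd(.data$psi),
      cp100 = 100 * mean(.data$ci_lo <= truth & truth <= .data$ci_hi),
      bias_mcse100 = 100 * sd(.data$psi) / sqrt(dplyr::n()),
      se_mcse100 = 100 * sd(.data$psi) / sqrt(2 * (dplyr::n() - 1)),
      cp_mcse100 = 100 * sqrt(pmax(mean(
        .data$ci_lo <= truth & truth <= .data$ci_hi, na.rm = TRUE) *
          (1 - mean(.data$ci_lo <= truth & truth <= .data$ci_hi,
                    na.rm = TRUE)), 0) / dplyr::n()),
      .groups = "drop") |>
    dplyr::left_join(fail, by = c("mode", "estimator")) |>
    dplyr::rename(fail_frac = "frac")
  structure(metrics, truth = truth, config = config, estimates = est_tbl,
            class = c("study_metrics", class(metrics)))
}

#' @export
print.study_metrics <- function(x, ...) {
  cat("<study_metrics> truth E(Y^a) =", round(attr(x, "truth"), 4),
      "| bias/SE/CP x 100\n")
  NextMethod()
}
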