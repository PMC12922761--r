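#' Read an analysis configuration file
#'
#' A YAML file describing an analysis: variable roles, the exposure level,
#' the covariate ordering, estimator settings and a seed. Used by the
#' command-line interface and handy for scripted analyses. Recognized keys:
#'
#' ```yaml
#' roles:
#'   outcome: y
#'   exposure: a
#'   l_o: [l_o]
#'   l_m: [l_m1, l_m2]
#'   exposure_level: 1
#'   missing_codes: ["", "NA"]
#' estimator: tmle-a        # tmle-a, tmle-b, ice, ipw, cc-tmle, mi-tmle
#' ordering: [l_m1, l_m2]
#' flavor: glm              # or saturated
#' trunc: 0.01
#' ci: boot                 # boot or if
#' boot_reps: 1000
#' mi: {m: 25, maxit: 10}
#' seed: 1
#' ```
#'
#' @param path Path to the YAML file.
#' @return A named list with a `roles` element of class `variable_roles`.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$roles)) abort("Config must contain a 'roles' block.")
  r <- cfg$roles
  for (f in c("outcome", "exposure")) {
    if (is.logical(r[[f]])) {
      abort(paste0("YAML parsed roles$", f, " as a boolean; quote column ",
                   "names like \"y\" or \"n\" in the config."))
    }
  }
  cfg$roles <- variable_roles(
    outcome = r$outcome, exposure = r$exposure,
    l_o = as.character(r$l_o %||% character()),
    l_m = as.character(r$l_m %||% character()),
    exposure_level = r$exposure_level %||% 1,
    missing_codes = as.character(r$missing_codes %||% c("", "NA")))
  cfg
}

#' Run a configured analysis on a dataset
#'
#' Dispatches to the estimator named in the configuration, with bootstrap
#' or influence-function intervals as configured.
#'
#' @param data A data frame or `obs_table`.
#' @param cfg A configuration list from [read_config()].
#' @return A [psi_fit].
#' @export
run_config <- function(data, cfg) {
  roles <- cfg$roles
  tab <- resolve_table(data, roles)
  a <- roles$exposure_level
  flavor <- cfg$flavor %||% "glm"
  specs <- nuisance_specs(roles, flavor = flavor,
                          trunc = cfg$trunc %||% 0.01)
  ordering <- cfg$ordering
  est <- cfg$estimator %||% "tmle-a"
  run <- function(d) switch(est,
    "tmle-a" = tmle_a(d, a = a, specs = specs),
    "tmle-b" = tmle_b(d, a = a, specs = specs, ordering = ordering),
    "ice" = ice(d, a = a, specs = specs,
                mode = if (is.null(ordering)) "IA" else "IB",
                ordering = ordering),
    "ipw" = ipw(d, a = a, specs = specs,
                mode = if (is.null(ordering)) "IA" else "IB",
                ordering = ordering),
    "cc-tmle" = cc_tmle(d, a = a, specs = specs),
    "mi-tmle" = mi_then_tmle(d, a = a, specs = specs,
                             m = cfg$mi$m %||% 25,
                             maxit = cfg$mi$maxit %||% 10,
                             seed = cfg$seed),
    abort(paste0("Unknown estimator '", est, "'.")))
  fit <- run(tab)
  if (identical(cfg$ci, "boot")) {
    fit <- add_bootstrap_ci(
      fit, tibble::as_tibble(tab),
      function(d) run(as_observed_table(d, roles)),
      b = cfg$boot_reps %||% 1000, seed = cfg$seed)
  }
  fit
}
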