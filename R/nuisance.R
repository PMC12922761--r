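#' Specify a nuisance regression
#'
#' A small container for how one nuisance function is estimated: a
#' right-hand-side formula over available columns, a link, and an estimator
#' flavor. Flavors:
#'
#' * `"glm"` — parametric working model fit by (quasi-)likelihood; the
#'   default, with main effects of the conditioning set.
#' * `"saturated"` — exact weighted stratum means over the discrete
#'   right-hand-side variables (the nonparametric MLE); used for the
#'   oracle/saturation tests and for all-binary data.
#' * `"custom"` — a flexible-learner hook: `fit_fun(data, formula, weights)`
#'   must return a `predict(newdata)`-able object on the response scale.
#'   A spline-based additive model (e.g. `mgcv::gam`) is a natural choice.
#'
#' @param rhs One-sided formula giving the predictors, e.g. `~ l_o + l_m1`.
#' @param link `"logit"` (default; response in `[0, 1]`) or `"identity"`.
#' @param flavor `"glm"`, `"saturated"` or `"custom"`.
#' @param fit_fun Fitting function for `flavor = "custom"`.
#' @return A `regression_spec` object.
#' @export
regression_spec <- function(rhs, link = c("logit", "identity"),
                            flavor = c("glm", "saturated", "custom"),
                            fit_fun = NULL) {
  link <- match.arg(link)
  flavor <- match.arg(flavor)
  stopifnot(inherits(rhs, "formula"), length(rhs) == 2)
  if (flavor == "custom" && !is.function(fit_fun)) {
    abort("flavor = 'custom' requires a fit_fun(data, formula, weights).")
  }
  structure(list(rhs = rhs, link = link, flavor = flavor, fit_fun = fit_fun),
            class = "regression_spec")
}

rhs_vars <- function(spec) all.vars(spec$rhs)

one_sided <- function(vars) {
  if (!length(vars)) return(~1)
  as.formula(paste("~", paste(vars, collapse = " + ")))
}

#' Default nuisance specifications for an analysis
#'
#' Builds the full set of nuisance regressions the estimators need, with
#' main effects of the conditioning set stated in each definition (the
#' conditioning sets themselves are fixed by the identifying functionals;
#' only the functional form is the analyst's choice):
#'
#' * `outcome` — `Y ~ A + L` among the fully observed,
#' * `exposure` — `1{A=a} ~ L` among the fully observed,
#' * `miss_a` — `R_A ~ L` among records with observed covariates,
#' * `miss_l` — joint `R_L ~ L_O` (assumption set IA),
#' * `miss_lk[[k]]` — `R_Lk ~ L_M1..L_M,k-1 + L_O` (assumption set IB),
#' * `seq0` — the downstream regression on `L_O` (IA),
#' * `seqk[[k]]` — the level-k sequential regression on
#'   `L_M1..L_M,k-1 + L_O` (IB).
#'
#' @param roles A [variable_roles()] object.
#' @param flavor Default estimator flavor for every spec (see
#'   [regression_spec()]).
#' @param trunc Probability truncation bound: estimated exposure/missingness
#'   probabilities are clipped to `[trunc, 1 - trunc]` before inverting
#'   (set to 0 for exact oracle checks). Degenerate indicators that are
#'   constant in the fitting sample are kept at their exact constant.
#' @param ... Named `regression_spec` overrides for any of the components
#'   above (for `miss_lk` / `seqk`, a list of specs of length `q`).
#' @return A `nuisance_specs` list.
#' @export
nuisance_specs <- function(roles, flavor = "glm", trunc = 0.01, ...) {
  lo <- roles$l_o; lm <- roles$l_m
  q <- length(lm)
  sp <- function(vars) regression_spec(one_sided(vars), flavor = flavor)
  defaults <- list(
    outcome  = sp(c(roles$exposure, lo, lm)),
    exposure = sp(c(lo, lm)),
    miss_a   = sp(c(lo, lm)),
    miss_l   = sp(lo),
    miss_lk  = lapply(seq_len(q), function(k) sp(c(lo, lm[seq_len(k - 1)]))),
    seq0     = sp(lo),
    seqk     = lapply(seq_len(q), function(k) sp(c(lo, lm[seq_len(k - 1)]))),
    trunc    = trunc,
    roles    = roles
  )
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(defaults))
  if (length(bad)) abort(paste0("Unknown spec component(s): ", paste(bad, collapse = ", ")))
  structure(modifyList(defaults, overrides), class = "nuisance_specs")
}

#' Saturated nuisance specifications
#'
#' Convenience wrapper: [nuisance_specs()] with `flavor = "saturated"` and
#' no probability truncation. On discrete data these are correctly
#' specified by construction, and the targeted estimators then coincide
#' with the identification functionals on the empirical law.
#'
#' @inheritParams nuisance_specs
#' @return A `nuisance_specs` list.
#' @export
specs_saturated <- function(roles, trunc = 0) {
  nuisance_specs(roles, flavor = "saturated", trunc = trunc)
}

#' Fit a weighted regression with an optional offset
#'
#' The single fitting primitive behind every nuisance function: solves the
#' weighted quasi-likelihood score equations for the requested link
#' (`logit` via `glm(quasibinomial)`, which also accepts fractional
#' pseudo-outcomes in `[0, 1]`; `identity` via weighted least squares), or
#' computes exact weighted stratum means for the `"saturated"` flavor.
#'
#' @param data Data frame of predictors.
#' @param y Numeric response vector (within the link range).
#' @param spec A [regression_spec()].
#' @param weights Nonnegative observation weights (default 1); duplicating a
#'   row is equivalent to doubling its weight.
#' @param offset Optional offset on the link scale.
#' @return A `wreg_fit` with elements `predict(newdata)` (response scale),
#'   `coef`, and `converged`.
#' @export
fit_weighted_regression <- function(data, y, spec, weights = NULL,
                                    offset = NULL) {
  n <- nrow(data)
  weights <- weights %||% rep(1, n)
  if (any(weights < 0)) abort("Weights must be nonnegative.")
  if (all(weights == 0) || n == 0) {
    abort("Zero effective sample for nuisance regression.")
  }
  if (spec$link == "logit" && (any(y < 0) || any(y > 1))) {
    abort("Response outside [0, 1] for logit link.")
  }

  if (spec$flavor == "saturated") {
    if (!is.null(offset)) abort("Saturated fits do not support offsets.")
    return(fit_saturated(data, y, spec, weights))
  }
  if (spec$flavor == "custom") {
    obj <- spec$fit_fun(data = cbind(data, .y = y), formula = update(spec$rhs, .y ~ .),
                        weights = weights)
    return(structure(list(
      predict = function(newdata) as.numeric(predict(obj, newdata = newdata,
                                                     type = "response")),
      coef = NULL, converged = TRUE, flavor = "custom"), class = "wreg_fit"))
  }

  df <- data[intersect(rhs_vars(spec), names(data))]
  df$.y <- y; df$.w <- weights
  df$.off <- offset %||% rep(0, n)
  fam <- if (spec$link == "logit") quasibinomial() else gaussian()
  fml <- update(spec$rhs, .y ~ .)
  fit <- withCallingHandlers(
    glm(fml, family = fam, data = df, weights = .w, offset = .off,
        control = list(epsilon = 1e-12, maxit = 200)),
    warning = function(w) invokeRestart("muffleWarning"))
  converged <- fit$converged || fit$deviance < 1e-8  # perfect fit trips IRLS
  if (!converged) {
    warn("Nuisance regression did not converge (possible separation).")
  }
  structure(list(
    predict = function(newdata) {
      newdata$.off <- 0  # offsets are for fitting; predictions are offset-free
      as.numeric(predict(fit, newdata = newdata, type = "response"))
    },
    coef = coef(fit), converged = converged, flavor = "glm"),
    class = "wreg_fit")
}

fit_saturated <- function(data, y, spec, weights) {
  vars <- rhs_vars(spec)
  if (!length(vars)) {
    m <- sum(weights * y) / sum(weights)
    return(structure(list(
      predict = function(newdata) rep(m, nrow(newdata)),
      coef = c(mean = m), converged = TRUE, flavor = "saturated"),
      class = "wreg_fit"))
  }
  key <- do.call(paste, c(data[vars], sep = "\r"))
  sums <- rowsum(weights * y, key)
  ns <- rowsum(weights, key)
  mu <- drop(sums / ns)
  names(mu) <- rownames(sums)
  structure(list(
    predict = function(newdata) {
      unname(mu[match(do.call(paste, c(newdata[vars], sep = "\r")),
                      names(mu))])
    },
    coef = mu, converged = TRUE, flavor = "saturated"),
    class = "wreg_fit")
}

#' Solve a one-dimensional intercept fluctuation
#'
#' Every targeting step updates an initial fit on the logit scale by a
#' scalar `epsilon` solving the weighted score equation
#' `sum_i w_i (y_i - expit(offset_i + epsilon)) = 0` — equivalently, the
#' intercept of a weighted logistic regression with offset. A bracketed
#' root search is used (robust where IRLS on an intercept-only offset model
#' can fail); when all responses sit at a bound and no finite root exists,
#' the result is clamped at `±eps_max` with a warning.
#'
#' @param y Responses in `[0, 1]` (outcomes or pseudo-outcomes).
#' @param offset Offsets on the logit scale.
#' @param weights Positive observational weights (default 1).
#' @param eps_max Search bound for the fluctuation parameter.
#' @return A list (`fluctuation_result`): `epsilon`, `converged`, `residual`
#'   (weighted mean score at the solution).
#' @export
solve_fluctuation <- function(y, offset, weights = NULL, eps_max = 10) {
  weights <- weights %||% rep(1, length(y))
  stopifnot(length(offset) == length(y), length(weights) == length(y))
  if (!length(y)) abort("Empty fluctuation subset (positivity failure).")
  if (any(weights <= 0)) abort("Fluctuation weights must be positive.")
  score <- function(eps) sum(weights * (y - plogis(offset + eps))) / sum(weights)
  s_lo <- score(-eps_max); s_hi <- score(eps_max)
  if (s_hi > 0 || s_lo < 0) {
    eps <- if (s_hi > 0) eps_max else -eps_max
    warn(paste0("Fluctuation has no finite root; clamped at ", eps, "."))
    return(structure(list(epsilon = eps, converged = FALSE,
                          residual = score(eps)),
                     class = "fluctuation_result"))
  }
  if (s_lo == 0 && s_hi == 0) {
    return(structure(list(epsilon = 0, converged = TRUE, residual = 0),
                     class = "fluctuation_result"))
  }
  root <- uniroot(score, c(-eps_max, eps_max), tol = 1e-14)
  structure(list(epsilon = root$root, converged = TRUE,
                 residual = score(root$root)),
            class = "fluctuation_result")
}

clip01 <- function(p, eps = 1e-6) pmin(pmax(p, eps), 1 - eps)

# Fit an observation-probability model and return truncated predictions.
# A response that is constant in the fitting sample yields that exact
# constant (no truncation): this is what makes the estimators collapse to
# their complete-data counterparts when nothing is missing.
fit_prob <- function(data_fit, y_fit, spec, data_pred, trunc, what,
                     need = NULL) {
  need <- need %||% rep(TRUE, nrow(data_pred))
  if (length(unique(y_fit)) == 1) {
    p <- rep(y_fit[1], nrow(data_pred))
    return(list(p = p, fit = NULL, n_trunc = 0L))
  }
  fit <- fit_weighted_regression(data_fit, y_fit, spec)
  p <- fit$predict(data_pred)
  if (anyNA(p[need])) {
    positivity_error(what, "unseen covariate stratum")
  }
  n_trunc <- sum(p[need] < trunc | p[need] > 1 - trunc)
  list(p = pmin(pmax(p, trunc), 1 - trunc), fit = fit, n_trunc = n_trunc)
}

#' Estimate nuisance functions under assumption set IA
#'
#' Fits, in order: the covariate observation model `P(R_L=1 | L_O)` on all
#' records; the exposure observation model `P(R_A=1 | L, R_L=1)` among
#' records with observed covariates; the exposure model `P(A=a | R=1, L)`
#' among fully observed records; and the initial outcome regression
#' `E(Y | A, R=1, L)` among fully observed records, evaluated at `A = a`.
#' The joint covariate indicator is `R_L = prod_k R_Lk` (covariates are
#' treated as observed only when all of them are), and `R = R_A R_L`.
#'
#' @param table An `obs_table`.
#' @param specs A [nuisance_specs()] set.
#' @param a Exposure level of interest.
#' @return A `nuisance_fit` (mode `"IA"`) with per-record prediction vectors
#'   `pi_rl`, `pi_ra`, `pi_a`, `t1_0` (the latter three defined where
#'   `R_L = 1`), indicator vectors, and truncation diagnostics.
#' @export
estimate_nuisances_ia <- function(table, specs, a) {
  roles <- attr(table, "roles")
  df <- tibble::as_tibble(table)
  n <- nrow(df)
  r_l <- as.integer(Reduce(`&`, lapply(r_col(roles$l_m),
                                       function(rc) df[[rc]] == 1),
                           rep(TRUE, n)))
  r_a <- df[[r_col(roles$exposure)]]
  r <- r_l * r_a
  if (!any(r == 1 & df[[roles$exposure]] == a, na.rm = TRUE)) {
    positivity_error("P(A = a, R = 1)", "whole sample")
  }
  trunc <- specs$trunc
  idx_rl <- which(r_l == 1); idx_r <- which(r == 1)

  p_rl <- fit_prob(df, r_l, specs$miss_l, df, trunc, "P(R_L = 1 | L_O)")
  p_ra <- fit_prob(df[idx_rl, ], r_a[idx_rl], specs$miss_a, df, trunc,
                   "P(R_A = 1 | L, R_L = 1)", need = r_l == 1)
  ya <- as.integer(df[[roles$exposure]] == a)
  p_a <- fit_prob(df[idx_r, ], ya[idx_r], specs$exposure, df, trunc,
                  "P(A = a | R = 1, L)", need = r_l == 1)

  t1_fit <- fit_weighted_regression(df[idx_r, ], df[[roles$outcome]][idx_r],
                                    specs$outcome)
  df_a <- df; df_a[[roles$exposure]] <- a
  t1_0 <- t1_fit$predict(df_a)
  if (any(is.na(t1_0[idx_rl]))) {
    positivity_error("E(Y | A = a, R = 1, L)", "unseen covariate stratum")
  }

  mask <- function(p, keep) { p[!keep] <- NA; p }
  structure(list(
    mode = "IA", a = a, roles = roles, trunc = trunc,
    r_l = r_l, r_a = r_a, r = r,
    pi_rl = p_rl$p,
    pi_ra = mask(p_ra$p, r_l == 1),
    pi_a = mask(p_a$p, r_l == 1),
    t1_0 = mask(t1_0, r_l == 1),
    n_trunc = c(pi_rl = p_rl$n_trunc, pi_ra = p_ra$n_trunc,
                pi_a = p_a$n_trunc),
    prob_range = range(c(p_rl$p, p_ra$p[r_l == 1], p_a$p[r == 1]))),
    class = "nuisance_fit")
}

#' Estimate nuisance functions under assumption set IB
#'
#' For the block-conditional functional with monotone-coarsened covariates
#' in the given ordering: for each `k`, fits
#' `P(R_Lk = 1 | Rbar_L,k-1 = 1, L_M1..L_M,k-1, L_O)` among records with the
#' first `k - 1` covariates observed; then the exposure observation model
#' among records with all covariates observed, the exposure model and the
#' initial outcome regression among fully observed records. The table must
#' already be monotone in `ordering` (see [coarsen_monotone()]).
#'
#' @inheritParams estimate_nuisances_ia
#' @param ordering Permutation of the `l_m` columns (the coarsening order).
#' @return A `nuisance_fit` (mode `"IB"`) with a list `pi_rlk` of `q`
#'   prediction vectors, cumulative products `wprod`, `pi_ra`, `pi_a`,
#'   `tq_0`, cumulative indicators `c_k`, and diagnostics.
#' @export
estimate_nuisances_ib <- function(table, specs, a, ordering = NULL) {
  roles <- attr(table, "roles")
  ordering <- ordering %||% roles$l_m
  df <- tibble::as_tibble(table)
  n <- nrow(df); q <- length(ordering)
  if (!q) abort("IB estimation requires at least one partially observed covariate.")
  rl <- vapply(ordering, function(v) as.integer(df[[r_col(v)]]), integer(n))
  c_k <- matrix(0L, n, q)
  c_prev <- rep(1L, n)
  for (k in seq_len(q)) {
    if (any(rl[, k] == 1 & c_prev == 0)) {
      abort("Table is not monotone in `ordering`; apply coarsen_monotone() first.")
    }
    c_k[, k] <- rl[, k] * c_prev
    c_prev <- c_k[, k]
  }
  r_a <- df[[r_col(roles$exposure)]]
  complete <- c_k[, q] == 1 & r_a == 1
  if (!any(complete & df[[roles$exposure]] == a, na.rm = TRUE)) {
    positivity_error("P(A = a, R_A = 1, all L_M observed)", "whole sample")
  }
  trunc <- specs$trunc

  pi_rlk <- vector("list", q)
  wprod <- matrix(NA_real_, n, q)
  n_trunc <- integer(q)
  cum <- rep(1, n)
  for (k in seq_len(q)) {
    idx_fit <- if (k == 1) seq_len(n) else which(c_k[, k - 1] == 1)
    if (!length(idx_fit)) positivity_error(paste0("R_L", k), "empty stratum")
    keep <- if (k == 1) rep(TRUE, n) else c_k[, k - 1] == 1
    pk <- fit_prob(df[idx_fit, ], rl[idx_fit, k], specs$miss_lk[[k]], df,
                   trunc, paste0("P(R_L", k, " = 1 | history)"), need = keep)
    p <- pk$p
    p[!keep] <- NA
    pi_rlk[[k]] <- p
    cum <- cum * p
    wprod[, k] <- cum
    n_trunc[k] <- pk$n_trunc
  }

  idx_cq <- which(c_k[, q] == 1); idx_full <- which(complete)
  p_ra <- fit_prob(df[idx_cq, ], r_a[idx_cq], specs$miss_a, df, trunc,
                   "P(R_A = 1 | L, all L_M observed)", need = c_k[, q] == 1)
  ya <- as.integer(df[[roles$exposure]] == a)
  p_a <- fit_prob(df[idx_full, ], ya[idx_full], specs$exposure, df, trunc,
                  "P(A = a | R = 1, L)", need = c_k[, q] == 1)
  tq_fit <- fit_weighted_regression(df[idx_full, ],
                                    df[[roles$outcome]][idx_full],
                                    specs$outcome)
  df_a <- df; df_a[[roles$exposure]] <- a
  tq_0 <- tq_fit$predict(df_a)
  if (any(is.na(tq_0[idx_cq]))) {
    positivity_error("E(Y | A = a, R = 1, L)", "unseen covariate stratum")
  }

  mask <- function(p, keep) { p[!keep] <- NA; p }
  structure(list(
    mode = "IB", a = a, roles = roles, trunc = trunc, ordering = ordering,
    q = q, c_k = c_k, r_a = r_a, complete = as.integer(complete),
    pi_rlk = pi_rlk, wprod = wprod,
    pi_ra = mask(p_ra$p, c_k[, q] == 1),
    pi_a = mask(p_a$p, c_k[, q] == 1),
    tq_0 = mask(tq_0, c_k[, q] == 1),
    n_trunc = c(setNames(n_trunc, paste0("pi_rl", seq_len(q))),
                pi_ra = p_ra$n_trunc, pi_a = p_a$n_trunc),
    prob_range = range(c(wprod[c_k[, q] == 1, q],
                         p_ra$p[c_k[, q] == 1], p_a$p[complete]))),
    class = "nuisance_fit")
}
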