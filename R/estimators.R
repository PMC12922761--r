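#' @title Estimator results
#' @description Every estimator returns a `psi_fit`: the point estimate of
#'   the average potential outcome, per-record influence values (when the
#'   estimator admits them), the influence-function variance, a confidence
#'   interval tagged with its method, and diagnostics (fluctuation
#'   parameters, truncation counts, weight extremes). Use [tidy()] /
#'   [glance()] to extract tibbles.
#' @name psi_fit
NULL

new_psi_fit <- function(psi, estimator, assumption, a, n,
                        if_values = NULL, ci_method = NULL, se = NA_real_,
                        sigma2 = NA_real_, ci = c(NA_real_, NA_real_),
                        diagnostics = list()) {
  if (!is.null(if_values)) {
    v <- if_variance(if_values)
    sigma2 <- v$sigma2; se <- v$se
    ci <- psi + c(-1, 1) * qnorm(0.975) * se
    ci_method <- ci_method %||% "if"
  }
  structure(list(psi = psi, estimator = estimator, assumption = assumption,
                 a = a, n = n, if_values = if_values, sigma2 = sigma2,
                 se = se, ci = ci, ci_method = ci_method,
                 diagnostics = diagnostics),
            class = "psi_fit")
}

#' @export
print.psi_fit <- function(x, ...) {
  cat(sprintf("<psi_fit> %s (%s)  E(Y^%s) = %.4f", x$estimator,
              x$assumption, format(x$a), x$psi))
  if (!is.na(x$se)) {
    cat(sprintf("  se = %.4f  95%% CI [%.4f, %.4f] (%s)",
                x$se, x$ci[1], x$ci[2], x$ci_method))
  }
  cat("\n")
  invisible(x)
}

resolve_table <- function(data, roles) {
  if (inherits(data, "obs_table")) data else as_observed_table(data, roles)
}

#' Complete-data TMLE of the average potential outcome
#'
#' The standard targeted estimator for fully observed data: an initial
#' outcome regression `E(Y | A, L)` is updated by an intercept fluctuation
#' with weight `1 / P(A = a | L)` among the exposed-at-`a`, and the estimate
#' is the mean updated prediction at `A = a`. Used directly on complete
#' data, and as the second stage of the complete-case and
#' multiple-imputation pathways.
#'
#' @param data A data frame with no missing cells in the role columns.
#' @param roles A [variable_roles()] object (taken from `data` when it is an
#'   `obs_table`).
#' @param a Exposure level of interest.
#' @param specs A [nuisance_specs()] set (components `outcome`, `exposure`,
#'   `trunc` are used).
#' @return A [psi_fit].
#' @export
tmle_complete <- function(data, roles = attr(data, "roles"),
                          a = roles$exposure_level,
                          specs = nuisance_specs(roles)) {
  df <- tibble::as_tibble(data)
  used <- c(roles$outcome, roles$exposure, roles$l_o, roles$l_m)
  if (anyNA(df[used])) {
    abort("tmle_complete() requires fully observed data; use cc_tmle() or an estimator that models missingness.")
  }
  n <- nrow(df)
  ya <- as.integer(df[[roles$exposure]] == a)
  if (!any(ya == 1)) positivity_error("P(A = a)", "whole sample")
  p_a <- fit_prob(df, ya, specs$exposure, df, specs$trunc, "P(A = a | L)")
  q_fit <- fit_weighted_regression(df, df[[roles$outcome]], specs$outcome)
  df_a <- df; df_a[[roles$exposure]] <- a
  q0 <- q_fit$predict(df_a)
  if (anyNA(q0)) positivity_error("E(Y | A = a, L)", "unseen covariate stratum")

  idx <- which(ya == 1)
  fl <- solve_fluctuation(df[[roles$outcome]][idx],
                          qlogis(clip01(q0[idx])), 1 / p_a$p[idx])
  q_star <- plogis(qlogis(clip01(q0)) + fl$epsilon)
  psi <- mean(q_star)
  iv <- ya / p_a$p * (df[[roles$outcome]] - q_star) + q_star - psi
  new_psi_fit(psi, "tmle_complete", "complete-data", a, n, if_values = iv,
              diagnostics = list(epsilon = fl$epsilon,
                                 n_trunc = p_a$n_trunc,
                                 weight_range = range(1 / p_a$p[idx])))
}

#' Complete-case analysis paired with the complete-data TMLE
#'
#' Drops every record missing the exposure or any partially observed
#' covariate and applies [tmle_complete()] to the remainder. Valid under
#' MCAR; included as the baseline the simulation study shows to be biased
#' under all three of its missingness mechanisms.
#'
#' @inheritParams tmle_complete
#' @return A [psi_fit] (field `n` is the complete-case count).
#' @export
cc_tmle <- function(data, roles = attr(data, "roles"),
                    a = roles$exposure_level,
                    specs = nuisance_specs(roles)) {
  tab <- resolve_table(data, roles)
  roles <- attr(tab, "roles")
  keep <- complete_ind(tab, roles)
  cc <- tibble::as_tibble(tab)[keep,
                               c(roles$outcome, roles$exposure, roles$l_o, roles$l_m)]
  fit <- tmle_complete(cc, roles, a, specs)
  fit$estimator <- "cc_tmle"
  fit$diagnostics$n_dropped <- sum(!keep)
  fit
}

#' TMLE-A: targeted estimator under assumption set IA
#'
#' Implements the two-stage targeted maximum likelihood estimator for the
#' functional identified when exposure missingness may depend on the
#' exposure and the partially observed confounders, while confounder
#' missingness is MAR relative to `L_O`:
#'
#' 1. estimate the missingness, exposure and initial outcome regressions
#'    ([estimate_nuisances_ia()]);
#' 2. fluctuate the outcome regression among `(A = a, R_A = 1, R_L = 1)`
#'    with weight `1 / (pi_A pi_RA pi_RL)`;
#' 3. regress the updated predictions on `L_O` among `R_L = 1` and
#'    fluctuate again with weight `1 / pi_RL`;
#' 4. average the final predictions over the whole sample.
#'
#' The estimator is multiply robust (consistent when either the outcome
#' regressions, or the exposure-and-missingness models, or the pair
#' `T_1`/`pi_RL` are correctly specified) and solves the influence-function
#' estimating equation, so the influence values ([eif_ia()]) have sample
#' mean zero and provide the asymptotic variance.
#'
#' @inheritParams tmle_complete
#' @param specs A [nuisance_specs()] set.
#' @return A [psi_fit] with influence values and Wald CI.
#' @export
tmle_a <- function(data, roles = attr(data, "roles"),
                   a = roles$exposure_level,
                   specs = nuisance_specs(roles)) {
  tab <- resolve_table(data, roles)
  roles <- attr(tab, "roles")
  df <- tibble::as_tibble(tab)
  n <- nrow(df)
  fit <- estimate_nuisances_ia(tab, specs, a)

  idx_fl1 <- which(fit$r == 1 & df[[roles$exposure]] == a)
  off1 <- qlogis(clip01(fit$t1_0))
  w1 <- 1 / (fit$pi_a * fit$pi_ra * fit$pi_rl)
  fl1 <- solve_fluctuation(df[[roles$outcome]][idx_fl1], off1[idx_fl1],
                           w1[idx_fl1])
  t1_star <- plogis(off1 + fl1$epsilon)  # defined where R_L = 1

  idx_rl <- which(fit$r_l == 1)
  t0_fit <- fit_weighted_regression(df[idx_rl, ], t1_star[idx_rl],
                                    specs$seq0)
  t0_0 <- t0_fit$predict(df)
  if (anyNA(t0_0)) positivity_error("E(T_1 | L_O, R_L = 1)", "unseen stratum")
  off0 <- qlogis(clip01(t0_0))
  fl0 <- solve_fluctuation(t1_star[idx_rl], off0[idx_rl],
                           1 / fit$pi_rl[idx_rl])
  t0_star <- plogis(off0 + fl0$epsilon)

  psi <- mean(t0_star)
  fit$t1_star <- t1_star
  fit$t0_star <- t0_star
  iv <- eif_ia(tab, fit, psi, a)
  new_psi_fit(psi, "tmle_a", "IA", a, n, if_values = iv,
              diagnostics = list(
                epsilon = c(t1 = fl1$epsilon, t0 = fl0$epsilon),
                n_trunc = fit$n_trunc,
                weight_range = range(w1[idx_fl1]),
                nuisance = fit))
}

#' TMLE-B: targeted estimator under the block-conditional assumption set
#'
#' The sequential-regression targeted estimator for the functional whose
#' covariate factors respect an analyst-chosen ordering of the partially
#' observed confounders (covariate `k`'s missingness may depend on the
#' earlier-ordered, partially observed covariates). Monotone coarsening in
#' the ordering is enforced automatically (with a recorded count) before
#' estimation. The top-level outcome regression is fluctuated among the
#' fully observed with weight `1 / (pi_A pi_RA prod_k pi_RLk)`; then,
#' recursively for `k = q, ..., 1`, the level-`k` predictions are regressed
#' on the earlier covariates and fluctuated with weight
#' `1 / prod_{j<=k} pi_RLj`. With `q = 1` the algorithm reduces exactly to
#' [tmle_a()].
#'
#' @inheritParams tmle_a
#' @param ordering Permutation of the `l_m` columns; defaults to the
#'   declared order (see [default_ordering()] for the missingness-based
#'   heuristic).
#' @return A [psi_fit] with influence values ([eif_ib()]) and Wald CI.
#' @export
tmle_b <- function(data, roles = attr(data, "roles"),
                   a = roles$exposure_level,
                   specs = nuisance_specs(roles), ordering = NULL) {
  tab <- resolve_table(data, roles)
  roles <- attr(tab, "roles")
  ordering <- ordering %||% roles$l_m
  tab <- coarsen_monotone(tab, ordering)
  n_coarsened <- attr(tab, "n_coarsened")
  roles <- attr(tab, "roles")
  df <- tibble::as_tibble(tab)
  n <- nrow(df); q <- length(ordering)
  fit <- estimate_nuisances_ib(tab, specs, a, ordering)

  idx_fl <- which(fit$complete == 1 & df[[roles$exposure]] == a)
  off_q <- qlogis(clip01(fit$tq_0))
  w_q <- 1 / (fit$pi_a * fit$pi_ra * fit$wprod[, q])
  fl_q <- solve_fluctuation(df[[roles$outcome]][idx_fl], off_q[idx_fl],
                            w_q[idx_fl])
  epsilons <- c(tq = fl_q$epsilon)

  # tk_star[[k + 1]] holds the targeted level-k predictions (k = q..0)
  tk_star <- vector("list", q + 1)
  tk_star[[q + 1]] <- plogis(off_q + fl_q$epsilon)
  for (k in rev(seq_len(q))) {
    idx_ck <- which(fit$c_k[, k] == 1)
    tk_fit <- fit_weighted_regression(df[idx_ck, ],
                                      tk_star[[k + 1]][idx_ck],
                                      specs$seqk[[k]])
    tkm1_0 <- tk_fit$predict(df)
    keep <- if (k == 1) rep(TRUE, n) else fit$c_k[, k - 1] == 1
    if (any(is.na(tkm1_0[keep]))) {
      positivity_error(paste0("sequential regression at level ", k - 1),
                       "unseen stratum")
    }
    off_k <- qlogis(clip01(tkm1_0))
    fl_k <- solve_fluctuation(tk_star[[k + 1]][idx_ck], off_k[idx_ck],
                              1 / fit$wprod[idx_ck, k])
    tk_star[[k]] <- ifelse(keep, plogis(off_k + fl_k$epsilon), NA_real_)
    epsilons <- c(epsilons, setNames(fl_k$epsilon, paste0("t", k - 1)))
  }

  psi <- mean(tk_star[[1]])
  fit$tk_star <- tk_star
  iv <- eif_ib(tab, fit, psi, a, ordering)
  new_psi_fit(psi, "tmle_b", "IB", a, n, if_values = iv,
              diagnostics = list(
                epsilon = epsilons, n_trunc = fit$n_trunc,
                weight_range = range(w_q[idx_fl]),
                n_coarsened = n_coarsened, ordering = ordering,
                nuisance = fit))
}

#' Iterated-conditional-expectation (sequential regression) plug-in
#'
#' The pure outcome-modelling estimator for either identifying functional:
#' nested regressions evaluated at `A = a` and averaged, with no weighting
#' and no targeting step. Most efficient when the outcome regressions are
#' correct, but inconsistent when they are misspecified (it has no second
#' chance through the missingness models), and it does not solve an
#' influence-function equation, so inference is by bootstrap only.
#'
#' @inheritParams tmle_b
#' @param mode `"IA"` (joint covariate observation indicator) or `"IB"`
#'   (block-conditional recursion in `ordering`).
#' @return A [psi_fit] without influence values (use [bootstrap_ci()]).
#' @export
ice <- function(data, roles = attr(data, "roles"),
                a = roles$exposure_level, specs = nuisance_specs(roles),
                mode = c("IA", "IB"), ordering = NULL) {
  mode <- match.arg(mode)
  tab <- resolve_table(data, roles)
  roles <- attr(tab, "roles")
  df <- tibble::as_tibble(tab)
  n <- nrow(df)
  df_a <- df; df_a[[roles$exposure]] <- a

  if (mode == "IA") {
    r_l <- as.integer(Reduce(`&`, lapply(r_col(roles$l_m),
                                         function(rc) df[[rc]] == 1),
                             rep(TRUE, n)))
    r <- r_l * df[[r_col(roles$exposure)]]
    t1_fit <- fit_weighted_regression(df[r == 1, ],
                                      df[[roles$outcome]][r == 1],
                                      specs$outcome)
    t1 <- t1_fit$predict(df_a)
    idx_rl <- which(r_l == 1)
    if (anyNA(t1[idx_rl])) positivity_error("E(Y | A = a, R = 1, L)", "unseen stratum")
    t0_fit <- fit_weighted_regression(df[idx_rl, ], t1[idx_rl], specs$seq0)
    t0 <- t0_fit$predict(df)
    if (anyNA(t0)) positivity_error("E(T_1 | L_O, R_L = 1)", "unseen stratum")
    psi <- mean(t0)
    return(new_psi_fit(psi, "ice_a", "IA", a, n))
  }

  ordering <- ordering %||% roles$l_m
  tab <- coarsen_monotone(tab, ordering)
  roles <- attr(tab, "roles")
  df <- tibble::as_tibble(tab)
  df_a <- df; df_a[[roles$exposure]] <- a
  q <- length(ordering)
  rl <- vapply(ordering, function(v) as.integer(df[[r_col(v)]]), integer(n))
  c_k <- apply(rl, 1, cumprod)
  c_k <- if (q == 1) matrix(c_k, ncol = 1) else t(c_k)
  complete <- c_k[, q] == 1 & df[[r_col(roles$exposure)]] == 1
  tq_fit <- fit_weighted_regression(df[complete, ],
                                    df[[roles$outcome]][complete],
                                    specs$outcome)
  tk <- tq_fit$predict(df_a)
  if (anyNA(tk[c_k[, q] == 1])) positivity_error("E(Y | A = a, R = 1, L)", "unseen stratum")
  for (k in rev(seq_len(q))) {
    idx_ck <- which(c_k[, k] == 1)
    fitk <- fit_weighted_regression(df[idx_ck, ], tk[idx_ck], specs$seqk[[k]])
    tk <- fitk$predict(df)
    keep <- if (k == 1) rep(TRUE, n) else c_k[, k - 1] == 1
    if (any(is.na(tk[keep]))) {
      positivity_error(paste0("sequential regression at level ", k - 1),
                       "unseen stratum")
    }
  }
  new_psi_fit(mean(tk), "ice_b", "IB", a, n)
}

#' Inverse-probability-weighted (Horvitz-Thompson) estimator
#'
#' Weights each fully observed record at the exposure level of interest by
#' the inverse of its estimated exposure-and-observation probability — the
#' leading term of the corresponding influence function. Consistent when
#' the exposure and missingness models are correct; inconsistent when the
#' exposure model is misspecified. Inference is by bootstrap.
#'
#' @inheritParams ice
#' @return A [psi_fit] without influence values; diagnostics report the
#'   weight extremes.
#' @export
ipw <- function(data, roles = attr(data, "roles"),
                a = roles$exposure_level, specs = nuisance_specs(roles),
                mode = c("IA", "IB"), ordering = NULL) {
  mode <- match.arg(mode)
  tab <- resolve_table(data, roles)
  roles <- attr(tab, "roles")
  if (mode == "IA") {
    fit <- estimate_nuisances_ia(tab, specs, a)
    denom <- fit$pi_a * fit$pi_ra * fit$pi_rl
    ind <- fit$r == 1 & tibble::as_tibble(tab)[[roles$exposure]] == a
    label <- "ipw_a"; assumption <- "IA"
  } else {
    ordering <- ordering %||% roles$l_m
    tab <- coarsen_monotone(tab, ordering)
    roles <- attr(tab, "roles")
    fit <- estimate_nuisances_ib(tab, specs, a, ordering)
    q <- fit$q
    denom <- fit$pi_a * fit$pi_ra * fit$wprod[, q]
    ind <- fit$complete == 1 & tibble::as_tibble(tab)[[roles$exposure]] == a
    label <- "ipw_b"; assumption <- "IB"
  }
  ind[is.na(ind)] <- FALSE
  if (any(denom[ind] <= 0)) positivity_error("IPW denominator", "zero probability")
  y <- tibble::as_tibble(tab)[[roles$outcome]]
  w <- ifelse(ind, 1 / denom, 0)
  psi <- mean(w * y)
  new_psi_fit(psi, label, assumption, a, nrow(tab),
              diagnostics = list(weight_range = range(w[ind]),
                                 sum_weights = sum(w),
                                 n_trunc = fit$n_trunc))
}

#' Multiple imputation paired with the complete-data TMLE
#'
#' Fully-conditional-specification (chained-equations) imputation of the
#' missing exposure and covariates, followed by [tmle_complete()] on each
#' completed dataset and Rubin's-rules pooling (between + within variance,
#' with a Barnard-Rubin style t reference). Valid when the data are missing
#' at random; the simulation study exhibits its bias under the
#' outcome-independent MNAR mechanisms.
#'
#' @inheritParams tmle_complete
#' @param m Number of imputations (default 25).
#' @param maxit Chained-equation sweeps per imputation (default 10).
#' @param seed Seed controlling the imputation draws.
#' @param mi_flavor `"glm"` — logistic (binary) / linear (continuous)
#'   imputation models with approximate posterior draws of the
#'   coefficients; `"saturated"` — exact beta-binomial posterior draws
#'   within covariate strata (all-binary data only).
#' @param imputations Optional precomputed result of [mi_impute()] (lets a
#'   simulation harness share one set of imputations across analyses).
#' @return A [psi_fit] with Rubin's-rules CI; diagnostics carry `m` and the
#'   between/within variance split.
#' @export
mi_then_tmle <- function(data, roles = attr(data, "roles"),
                         a = roles$exposure_level,
                         specs = nuisance_specs(roles), m = 25, maxit = 10,
                         seed = NULL, mi_flavor = c("glm", "saturated"),
                         imputations = NULL) {
  tab <- resolve_table(data, roles)
  roles <- attr(tab, "roles")
  if (is.null(imputations)) {
    imputations <- mi_impute(tab, roles, m = m, maxit = maxit, seed = seed,
                             mi_flavor = mi_flavor)
  }
  m <- length(imputations)
  if (m < 2 && attr(imputations, "any_missing")) {
    abort("Multiple imputation requires m >= 2.")
  }
  fits <- lapply(imputations, tmle_complete, roles = roles, a = a,
                 specs = specs)
  qs <- vapply(fits, function(f) f$psi, numeric(1))
  ws <- vapply(fits, function(f) f$se^2, numeric(1))
  qbar <- mean(qs); W <- mean(ws); B <- if (m > 1) var(qs) else 0
  Tv <- W + (1 + 1 / m) * B
  if (B > 0) {
    df_rub <- (m - 1) * (1 + W / ((1 + 1 / m) * B))^2
  } else {
    df_rub <- Inf
  }
  ci <- qbar + c(-1, 1) * qt(0.975, df_rub) * sqrt(Tv)
  new_psi_fit(qbar, "mi_tmle", "MAR", a, nrow(tab), se = sqrt(Tv),
              sigma2 = Tv * nrow(tab), ci = ci, ci_method = "rubin",
              diagnostics = list(m = m, within = W, between = B,
                                 df = df_rub))
}

#' Chained-equations imputation of missing exposure and covariates
#'
#' @inheritParams mi_then_tmle
#' @return List of `m` completed tibbles (attribute `any_missing` records
#'   whether anything needed imputing).
#' @export
mi_impute <- function(data, roles = attr(data, "roles"), m = 25, maxit = 10,
                      seed = NULL, mi_flavor = c("glm", "saturated")) {
  mi_flavor <- match.arg(mi_flavor)
  tab <- resolve_table(data, roles)
  roles <- attr(tab, "roles")
  df <- tibble::as_tibble(tab)[c(roles$outcome, roles$exposure, roles$l_o,
                                 roles$l_m)]
  targets <- names(df)[vapply(df, anyNA, logical(1))]
  if (!is.null(seed)) set.seed(seed)
  if (!length(targets)) {
    out <- rep(list(df), max(m, 1))
    attr(out, "any_missing") <- FALSE
    return(out)
  }
  obs_idx <- lapply(targets, function(v) which(!is.na(df[[v]])))
  names(obs_idx) <- targets
  for (v in targets) {
    if (!length(obs_idx[[v]])) {
      abort(paste0("Imputation model failure: '", v, "' has no observed values."))
    }
  }
  out <- vector("list", m)
  mis_idx <- lapply(targets, function(v) which(is.na(df[[v]])))
  names(mis_idx) <- targets
  for (j in seq_len(m)) {
    imp <- as.list(df)  # plain vectors: cheap in the chained sweeps
    for (v in targets) {  # initialize from the observed marginal
      imp[[v]][mis_idx[[v]]] <- sample(df[[v]][obs_idx[[v]]],
                                       length(mis_idx[[v]]), replace = TRUE)
    }
    for (it in seq_len(maxit)) {
      for (v in targets) {
        imp[[v]] <- mi_draw(imp, v, obs_idx[[v]], mis_idx[[v]], mi_flavor)
      }
    }
    out[[j]] <- tibble::as_tibble(imp)
  }
  attr(out, "any_missing") <- TRUE
  out
}

mi_draw <- function(imp, v, idx_obs, idx_mis, mi_flavor) {
  if (!length(idx_mis)) return(imp[[v]])
  others <- setdiff(names(imp), v)
  binary <- all(imp[[v]][idx_obs] %in% c(0, 1))
  if (mi_flavor == "saturated") {
    if (!binary) abort(paste0("Saturated imputation needs binary '", v, "'."))
    key_all <- do.call(paste, c(imp[others], sep = "\r"))
    key_obs <- key_all[idx_obs]
    key_mis <- key_all[idx_mis]
    s <- rowsum(imp[[v]][idx_obs], key_obs)
    n <- rowsum(rep(1, length(idx_obs)), key_obs)
    # Jeffreys-posterior draw per stratum; empty strata fall back to pooled
    p <- rbeta(length(s), 0.5 + s, 0.5 + n - s)
    pm <- p[match(key_mis, rownames(s))]
    pm[is.na(pm)] <- mean(imp[[v]][idx_obs])
    imp[[v]][idx_mis] <- rbinom(length(idx_mis), 1, pm)
    return(imp[[v]])
  }
  fml <- as.formula(paste(v, "~", paste(others, collapse = " + ")))
  dat <- as.data.frame(imp)
  if (binary) {
    fit <- withCallingHandlers(
      glm(fml, data = dat[idx_obs, ], family = binomial()),
      warning = function(w) invokeRestart("muffleWarning"))
    beta <- draw_coef(fit, v)
    X <- model.matrix(delete.response(terms(fit)), dat[idx_mis, , drop = FALSE])
    imp[[v]][idx_mis] <- rbinom(length(idx_mis), 1,
                                plogis(drop(X %*% beta)))
  } else {
    fit <- lm(fml, data = dat[idx_obs, ])
    res_df <- max(fit$df.residual, 1)
    sigma <- sqrt(sum(fit$residuals^2) / stats::rchisq(1, res_df))
    beta <- draw_coef(fit, v, dispersion = sigma^2)
    X <- model.matrix(delete.response(terms(fit)), dat[idx_mis, , drop = FALSE])
    imp[[v]][idx_mis] <- drop(X %*% beta) + rnorm(length(idx_mis), 0, sigma)
  }
  imp[[v]]
}

draw_coef <- function(fit, v, dispersion = NULL) {
  bh <- coef(fit)
  if (anyNA(bh)) abort(paste0("Imputation model failure for '", v,
                              "': collinear predictors."))
  V <- if (is.null(dispersion)) vcov(fit) else {
    stats::summary.lm(fit)$cov.unscaled * dispersion
  }
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) abort(paste0("Imputation model failure for '", v, "'."))
  bh + drop(t(ch) %*% rnorm(length(bh)))
}

#' Causal contrasts from two fitted average potential outcomes
#'
#' Computes `psi_1 - psi_0` with an influence-function delta-method
#' standard error when both fits carry influence values (e.g. two TMLE
#' fits on the same data), and `E(Y) - psi_0` against the observed outcome
#' mean.
#'
#' @param fit1,fit0 [psi_fit] objects fitted on the same records.
#' @param y For `contrast_vs_observed()`, the observed outcome vector.
#' @return A one-row tibble with estimate, SE and Wald CI.
#' @export
contrast_fits <- function(fit1, fit0) {
  est <- fit1$psi - fit0$psi
  if (!is.null(fit1$if_values) && !is.null(fit0$if_values)) {
    iv <- fit1$if_values - fit0$if_values
    v <- if_variance(iv)
    tibble::tibble(contrast = "psi(a1) - psi(a0)", estimate = est,
                   std.error = v$se, conf.low = est - qnorm(0.975) * v$se,
                   conf.high = est + qnorm(0.975) * v$se)
  } else {
    tibble::tibble(contrast = "psi(a1) - psi(a0)", estimate = est,
                   std.error = NA_real_, conf.low = NA_real_,
                   conf.high = NA_real_)
  }
}

#' @rdname contrast_fits
#' @export
contrast_vs_observed <- function(fit0, y) {
  est <- mean(y) - fit0$psi
  if (!is.null(fit0$if_values)) {
    iv <- (y - mean(y)) - fit0$if_values
    v <- if_variance(iv)
    tibble::tibble(contrast = "E(Y) - psi(a0)", estimate = est,
                   std.error = v$se, conf.low = est - qnorm(0.975) * v$se,
                   conf.high = est + qnorm(0.975) * v$se)
  } else {
    tibble::tibble(contrast = "E(Y) - psi(a0)", estimate = est,
                   std.error = NA_real_, conf.low = NA_real_,
                   conf.high = NA_real_)
  }
}
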