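#' Influence values for the targeted estimators
#'
#' Evaluate the per-record efficient influence function of the identifying
#' functional at the fitted (post-targeting) nuisance estimates. For the
#' IA functional the influence function is
#'
#' ```
#' I(A=a, R_A=1, R_L=1) / (pi_A pi_RA pi_RL) * (Y - T1)
#'   + I(R_L=1) / pi_RL * (T1 - T0) + T0 - psi
#' ```
#'
#' and for the block-conditional (IB) functional the leading term uses the
#' full product of observation probabilities, followed by the telescoping
#' level-k terms `I(Rbar_Lk = 1) / prod_{j<=k} pi_RLj * (Ttilde_k -
#' Ttilde_{k-1})` and `Ttilde_0 - psi`. After targeting, the sample mean of
#' these values is zero up to solver tolerance; their second moment
#' estimates the asymptotic variance.
#'
#' @param table The `obs_table` the fit was computed on.
#' @param fit A `nuisance_fit` carrying the targeted predictions
#'   (`t1_star`/`t0_star` for IA, `tk_star` for IB), as produced inside
#'   [tmle_a()] / [tmle_b()].
#' @param psi The point estimate.
#' @param a Exposure level.
#' @param ordering For `eif_ib()`, the coarsening ordering used.
#' @return Numeric vector of per-record influence values (class
#'   `influence_vector`, attribute `assumption`).
#' @export
eif_ia <- function(table, fit, psi, a) {
  roles <- attr(table, "roles")
  if (is.null(fit$t1_star) || is.null(fit$t0_star)) {
    abort("`fit` lacks targeted predictions t1_star/t0_star.")
  }
  df <- tibble::as_tibble(table)
  y <- df[[roles$outcome]]
  ind1 <- fit$r == 1 & df[[roles$exposure]] == a
  ind1[is.na(ind1)] <- FALSE
  t1 <- ifelse(ind1, (y - fit$t1_star) /
                 (fit$pi_a * fit$pi_ra * fit$pi_rl), 0)
  t2 <- ifelse(fit$r_l == 1,
               (fit$t1_star - fit$t0_star) / fit$pi_rl, 0)
  t2[is.na(t2)] <- 0
  iv <- t1 + t2 + fit$t0_star - psi
  structure(iv, assumption = "IA", class = "influence_vector")
}

#' @rdname eif_ia
#' @export
eif_ib <- function(table, fit, psi, a, ordering = NULL) {
  roles <- attr(table, "roles")
  if (is.null(fit$tk_star)) abort("`fit` lacks targeted predictions tk_star.")
  df <- tibble::as_tibble(table)
  y <- df[[roles$outcome]]
  q <- fit$q
  ind <- fit$complete == 1 & df[[roles$exposure]] == a
  ind[is.na(ind)] <- FALSE
  iv <- ifelse(ind, (y - fit$tk_star[[q + 1]]) /
                 (fit$pi_a * fit$pi_ra * fit$wprod[, q]), 0)
  iv[is.na(iv)] <- 0
  for (k in seq_len(q)) {
    tk <- ifelse(fit$c_k[, k] == 1,
                 (fit$tk_star[[k + 1]] - fit$tk_star[[k]]) / fit$wprod[, k],
                 0)
    tk[is.na(tk)] <- 0
    iv <- iv + tk
  }
  iv <- iv + fit$tk_star[[1]] - psi
  structure(iv, assumption = "IB", class = "influence_vector")
}

#' Influence-function variance and Wald interval
#'
#' The asymptotic variance of a targeted estimator is estimated by the
#' empirical second moment of the influence values (the mean-square
#' convention; at the TMLE solution the mean is zero so this matches the
#' variance), giving `se = sqrt(sigma2 / n)` and a 95% Wald interval.
#'
#' @param iv Influence values.
#' @param psi Optional point estimate for the interval.
#' @return List with `sigma2`, `se`, and (when `psi` is given) `ci`.
#' @export
if_variance <- function(iv, psi = NULL) {
  n <- length(iv)
  sigma2 <- mean(iv^2)
  se <- sqrt(sigma2 / n)
  out <- list(sigma2 = sigma2, se = se)
  if (!is.null(psi)) out$ci <- psi + c(-1, 1) * qnorm(0.975) * se
  out
}

#' Nonparametric bootstrap confidence interval
#'
#' Resamples records with replacement, refits the estimator on each
#' resample (all nuisance models included), and returns the percentile
#' interval and the resampling standard error. This is the recommended
#' interval when nuisance functions are modelled parametrically; the
#' influence-function interval is the default for flexible learners.
#' Failed resamples (e.g. empty-stratum positivity errors) are skipped and
#' counted; more than 5% failures aborts.
#'
#' @param data The analysis dataset (resampling unit: the record).
#' @param estimator A function of a resampled data frame returning either a
#'   [psi_fit] or a numeric estimate.
#' @param b Number of resamples (>= 50).
#' @param seed Seed; the same seed reproduces the interval exactly.
#' @param conf Confidence level.
#' @return List: `ci` (percentile), `se` (resample SD), `estimates`,
#'   `n_fail`.
#' @export
bootstrap_ci <- function(data, estimator, b = 1000, seed = NULL,
                         conf = 0.95) {
  if (b < 50) abort("Use at least 50 bootstrap resamples.")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(data)
  est <- rep(NA_real_, b)
  for (i in seq_len(b)) {
    idx <- sample.int(n, n, replace = TRUE)
    est[i] <- tryCatch({
      fit <- estimator(data[idx, , drop = FALSE])
      if (inherits(fit, "psi_fit")) fit$psi else as.numeric(fit)
    }, error = function(e) NA_real_)
  }
  n_fail <- sum(is.na(est))
  if (n_fail > 0.05 * b) {
    abort(paste0("Bootstrap failed on ", n_fail, " of ", b, " resamples."))
  }
  alpha <- (1 - conf) / 2
  ok <- est[!is.na(est)]
  list(ci = unname(quantile(ok, c(alpha, 1 - alpha), type = 7)),
       se = sd(ok), estimates = est, n_fail = n_fail)
}

#' Attach a bootstrap interval to a fitted estimate
#'
#' @param fit A [psi_fit].
#' @param data The dataset `fit` was computed on.
#' @param estimator The estimator closure to refit per resample.
#' @inheritParams bootstrap_ci
#' @return `fit` with `ci`, `se` and `ci_method = "boot"` replaced; the IF
#'   interval (if any) is kept in `diagnostics$if_ci`.
#' @export
add_bootstrap_ci <- function(fit, data, estimator, b = 1000, seed = NULL,
                             conf = 0.95) {
  bs <- bootstrap_ci(data, estimator, b = b, seed = seed, conf = conf)
  fit$diagnostics$if_ci <- fit$ci
  fit$diagnostics$boot_n_fail <- bs$n_fail
  fit$ci <- bs$ci
  fit$se <- bs$se
  fit$ci_method <- "boot"
  fit
}
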