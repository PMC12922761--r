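# Shared fixture builders: everything is generated in code at test time.

toy_roles <- function(q = 2) {
  variable_roles(outcome = "y", exposure = "a", l_o = "l_o",
                 l_m = if (q >= 1) paste0("l_m", seq_len(q)) else character())
}

# A small random partially observed table (binary everything, MCAR masks).
random_table <- function(n = 60, seed = 1, q = 2, p_miss = 0.25) {
  set.seed(seed)
  df <- tibble::tibble(
    y = rbinom(n, 1, 0.4),
    a = rbinom(n, 1, 0.5),
    l_o = rbinom(n, 1, 0.5))
  for (k in seq_len(q)) df[[paste0("l_m", k)]] <- rbinom(n, 1, 0.5)
  df$a[runif(n) < p_miss] <- NA
  for (k in seq_len(q)) {
    v <- paste0("l_m", k)
    df[[v]][runif(n) < p_miss] <- NA
  }
  as_observed_table(df, toy_roles(q))
}

# Expand a discrete law with rational probabilities (counts / N) into a
# dataset whose empirical law equals the law exactly.
law_to_table <- function(law, roles) {
  stopifnot(all(abs(law$count - round(law$count)) < 1e-9))
  idx <- rep(seq_len(nrow(law)), law$count)
  df <- tibble::as_tibble(law[idx, setdiff(names(law), c("count", "prob"))])
  as_observed_table(df, roles)
}

# A small q = 1 observed-data law with rational masses, satisfying IA
# (missingness independent of everything: MCAR within the law).
small_law_q1 <- function(counts_seed = 4, N = 64) {
  set.seed(counts_seed)
  grid <- tidyr::expand_grid(y = 0:1, a = 0:1, l_o = 0:1, l_m1 = 0:1,
                             r_a = 0:1, r_l_m1 = 0:1)
  grid$a[grid$r_a == 0] <- NA
  grid$l_m1[grid$r_l_m1 == 0] <- NA
  grid <- dplyr::distinct(grid)
  grid$count <- sample(1:6, nrow(grid), replace = TRUE)
  grid$prob <- grid$count / sum(grid$count)
  grid
}

# A q = 2 observed-data law with monotone missingness patterns and rational
# masses; every conditional stratum holds both outcome values, so no
# regression hits the [0, 1] boundary.
small_law_q2 <- function(counts_seed = 8) {
  set.seed(counts_seed)
  grid <- tidyr::expand_grid(y = 0:1, a = 0:1, l_o = 0:1, l_m1 = 0:1,
                             l_m2 = 0:1, r_a = 0:1, r_l_m1 = 0:1,
                             r_l_m2 = 0:1)
  grid <- grid[grid$r_l_m2 <= grid$r_l_m1, ]  # monotone patterns only
  grid$a[grid$r_a == 0] <- NA
  grid$l_m1[grid$r_l_m1 == 0] <- NA
  grid$l_m2[grid$r_l_m2 == 0] <- NA
  grid <- dplyr::distinct(grid)
  grid$count <- sample(1:6, nrow(grid), replace = TRUE)
  grid$prob <- grid$count / sum(grid$count)
  grid
}

# restrict a simulated scenario dataset to a single partially observed
# covariate (drops l_m2), for the q = 1 reduction checks
drop_lm2 <- function(tab) {
  df <- tibble::as_tibble(tab)[c("y", "a", "l_o", "l_m1")]
  as_observed_table(df, toy_roles(q = 1))
}

expect_psi_equal <- function(f1, f2, tol = 1e-12) {
  testthat::expect_lt(abs(f1$psi - f2$psi), tol)
}

# compare table contents, ignoring class/metadata attributes
strip_table <- function(t) {
  out <- as.data.frame(tibble::as_tibble(t))
  attr(out, "roles") <- NULL
  attr(out, "n_coarsened") <- NULL
  out
}
expect_same_table <- function(a, b) {
  testthat::expect_identical(strip_table(a), strip_table(b))
}

# numerical Gateaux derivative of a plug-in functional at the empirical law:
# d/dt Psi((1-t) P + t delta_o) at t = 0, by central differences
gateaux_numeric <- function(law, roles, psi_fun, t = 1e-5) {
  vapply(seq_len(nrow(law)), function(i) {
    perturb <- function(tt) {
      l2 <- law
      l2$prob <- (1 - tt) * l2$prob
      l2$prob[i] <- l2$prob[i] + tt
      psi_fun(new_discrete_law(l2, roles))
    }
    (perturb(t) - perturb(-t)) / (2 * t)
  }, numeric(1))
}

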