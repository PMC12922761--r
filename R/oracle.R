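#' Identification oracles on enumerable discrete laws
#'
#' The three identifying functionals evaluated by exact summation on a
#' finite [new_discrete_law()]. These serve as ground-truth oracles: on any
#' law satisfying the corresponding assumption set they equal the
#' counterfactual mean exactly, and every estimator in the package can be
#' checked against them (with saturated nuisance models, TMLE/ICE/IPW
#' reproduce these functionals on the empirical law).
#'
#' * `psi_mar_plugin()` evaluates the MAR functional
#'   `E[beta(L)/gamma(L) * R / P(R=1 | L_O, Y)]`, where
#'   `beta(L) = sum_y y p(L_M, a | L_O, y, R=1) p(y | L_O)` and `gamma(L)`
#'   is the same sum without the leading `y`. It treats `(A, L_M)` as
#'   jointly observed (`R = R_A * prod_k R_Lk`).
#' * `psi_ia_plugin()` evaluates
#'   `sum_l E(Y | A=a, R_A=1, R_L=1, L=l) p(l_M | l_O, R_L=1) p(l_O)`,
#'   valid when exposure missingness may depend on `(A, L_M)` but covariate
#'   missingness is MAR relative to `L_O`.
#' * `psi_ib_plugin()` evaluates the block-conditional functional
#'   `sum_l E(Y | A=a, R_A=1, Rbar_Lq=1, L=l) prod_k p(l_Mk | l_O,
#'   lbar_M,k-1, Rbar_Lk = 1_k) p(l_O)`, whose covariate factors respect the
#'   analyst-chosen ordering.
#'
#' Positivity is checked lazily: only conditioning strata that actually
#' receive positive weight are required to have positive mass, and a
#' violation raises an error naming the stratum.
#'
#' @param law A `discrete_law` (full-data or observed-data representation;
#'   the functionals only read states compatible with their conditioning
#'   events).
#' @param a Exposure level of interest.
#' @param ordering For `psi_ib_plugin()`, permutation of the `l_m` columns
#'   defining the block-conditional factorization; defaults to the declared
#'   order.
#' @return The value of the identifying functional (a scalar in
#'   `[min(y), max(y)]`).
#' @name identification-oracles
NULL

law_roles <- function(law) {
  roles <- attr(law, "roles")
  if (is.null(roles)) abort("Law carries no variable roles.")
  roles
}

complete_ind <- function(x, roles) {
  out <- x[[r_col(roles$exposure)]] == 1
  for (v in roles$l_m) out <- out & x[[r_col(v)]] == 1
  out
}

positivity_error <- function(what, strata) {
  abort(paste0("Positivity violated: ", what, " has zero mass in stratum ",
               strata, "."), class = "tmlemiss_positivity_error")
}

group_mass <- function(law, cols) {
  law |>
    dplyr::group_by(dplyr::across(dplyr::all_of(cols))) |>
    dplyr::summarise(mass = sum(.data$prob), .groups = "drop")
}

#' @rdname identification-oracles
#' @export
psi_ia_plugin <- function(law, a) {
  roles <- law_roles(law)
  lo <- roles$l_o; lm <- roles$l_m
  law <- tibble::as_tibble(law)

  w <- group_mass(law, lo) |> dplyr::filter(.data$mass > 0)
  names(w)[names(w) == "mass"] <- "w"

  if (length(lm)) {
    rl1 <- law[Reduce(`&`, lapply(r_col(lm), function(rc) law[[rc]] == 1)), ]
    pk <- rl1 |>
      group_mass(c(lo, lm)) |>
      dplyr::group_by(dplyr::across(dplyr::all_of(lo))) |>
      dplyr::mutate(p = .data$mass / sum(.data$mass)) |>
      dplyr::ungroup() |>
      dplyr::select(-"mass")
    w <- dplyr::left_join(w, pk, by = lo)
    if (anyNA(w$p)) {
      bad <- w[is.na(w$p), lo, drop = FALSE][1, ]
      positivity_error("P(R_L = 1 | L_O)", paste(lo, unlist(bad), collapse = ", "))
    }
    w$w <- w$w * w$p
    w$p <- NULL
  }
  psi_weighted_outcome(law, w, a, roles)
}

#' @rdname identification-oracles
#' @export
psi_ib_plugin <- function(law, a, ordering = NULL) {
  roles <- law_roles(law)
  lo <- roles$l_o; lm <- roles$l_m
  ordering <- ordering %||% lm
  if (!setequal(ordering, lm) || length(ordering) != length(lm)) {
    abort("`ordering` must be a permutation of the l_m columns.")
  }
  law <- tibble::as_tibble(law)

  w <- group_mass(law, lo) |> dplyr::filter(.data$mass > 0)
  names(w)[names(w) == "mass"] <- "w"

  for (k in seq_along(ordering)) {
    vk <- ordering[k]
    cond <- c(lo, ordering[seq_len(k - 1)])
    sub <- law[Reduce(`&`, lapply(r_col(ordering[seq_len(k)]),
                                  function(rc) law[[rc]] == 1)), ]
    pk <- sub |>
      group_mass(c(cond, vk)) |>
      dplyr::group_by(dplyr::across(dplyr::all_of(cond))) |>
      dplyr::mutate(p = .data$mass / sum(.data$mass)) |>
      dplyr::ungroup() |>
      dplyr::select(-"mass")
    w <- dplyr::left_join(w, pk, by = cond)
    if (anyNA(w$p)) {
      bad <- w[is.na(w$p), cond, drop = FALSE][1, ]
      positivity_error(paste0("P(R_L", k, " = 1 | history)"),
                       paste(cond, unlist(bad), collapse = ", "))
    }
    w$w <- w$w * w$p
    w$p <- NULL
  }
  psi_weighted_outcome(law, w, a, roles)
}

# sum_l w(l) E(Y | A = a, all indicators = 1, L = l)
psi_weighted_outcome <- function(law, w, a, roles) {
  lo <- roles$l_o; lm <- roles$l_m
  sub <- law[complete_ind(law, roles) & law[[roles$exposure]] == a, ]
  mu <- sub |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(lo, lm)))) |>
    dplyr::summarise(num = sum(.data$prob * .data[[roles$outcome]]),
                     den = sum(.data$prob), .groups = "drop") |>
    dplyr::filter(.data$den > 0) |>
    dplyr::mutate(mu = .data$num / .data$den) |>
    dplyr::select(dplyr::all_of(c(lo, lm)), "mu")
  w <- dplyr::left_join(w, mu, by = c(lo, lm))
  bad <- is.na(w$mu) & w$w > 0
  if (any(bad)) {
    b <- w[bad, c(lo, lm), drop = FALSE][1, ]
    positivity_error("P(A = a, all observed | L)",
                     paste(c(lo, lm), unlist(b), collapse = ", "))
  }
  sum(w$w * w$mu, na.rm = TRUE)
}

#' @rdname identification-oracles
#' @export
psi_mar_plugin <- function(law, a) {
  roles <- law_roles(law)
  lo <- roles$l_o; lm <- roles$l_m
  ycol <- roles$outcome; acol <- roles$exposure
  law <- tibble::as_tibble(law)
  law$.r <- as.integer(complete_ind(law, roles))

  # p(y | l_o)
  p_y_lo <- law |>
    group_mass(c(lo, ycol)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(lo))) |>
    dplyr::mutate(p_y = .data$mass / sum(.data$mass)) |>
    dplyr::ungroup() |>
    dplyr::select(-"mass")

  # P(R = 1 | l_o, y); assumption-4 positivity on every populated stratum
  p_r <- law |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(lo, ycol)))) |>
    dplyr::summarise(p_r = sum(.data$prob * .data$.r) / sum(.data$prob),
                     mass = sum(.data$prob), .groups = "drop")
  viol <- p_r$mass > 0 & p_r$p_r <= 0
  if (any(viol)) {
    b <- p_r[viol, c(lo, ycol), drop = FALSE][1, ]
    positivity_error("P(R = 1 | L_O, Y)",
                     paste(c(lo, ycol), unlist(b), collapse = ", "))
  }

  # J(y', l_o, l_m) = p(L_M = l_m, A = a | L_O = l_o, Y = y', R = 1)
  num <- group_mass(law[law$.r == 1 & law[[acol]] == a, ], c(lo, ycol, lm))
  den <- group_mass(law[law$.r == 1, ], c(lo, ycol))
  names(den)[names(den) == "mass"] <- "den"
  jtab <- dplyr::left_join(num, den, by = c(lo, ycol)) |>
    dplyr::mutate(j = .data$mass / .data$den) |>
    dplyr::select(dplyr::all_of(c(lo, ycol, lm)), "j")

  # beta/gamma per complete state, summing J * p(y'|l_o) over y'
  bg <- dplyr::left_join(jtab, p_y_lo, by = c(lo, ycol)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(lo, lm)))) |>
    dplyr::summarise(beta = sum(.data$j * .data$p_y * .data[[ycol]]),
                     gamma = sum(.data$j * .data$p_y), .groups = "drop")

  states <- law[law$.r == 1 & law$prob > 0, ] |>
    dplyr::left_join(bg, by = c(lo, lm)) |>
    dplyr::left_join(p_r[c(lo, ycol, "p_r")], by = c(lo, ycol))
  if (any(is.na(states$gamma) | states$gamma <= 0)) {
    b <- states[is.na(states$gamma) | states$gamma <= 0,
                c(lo, lm), drop = FALSE][1, ]
    positivity_error("gamma(L) (joint density of (L_M, a) given (L_O, Y, R=1))",
                     paste(c(lo, lm), unlist(b), collapse = ", "))
  }
  sum(states$prob * states$beta / states$gamma / states$p_r)
}
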