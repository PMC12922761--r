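#' Declare variable roles for a partially observed causal dataset
#'
#' Analyses in this package revolve around a rectangular dataset holding a
#' fully observed outcome `Y`, a partially observed exposure `A`, fully
#' observed covariates `L_O`, and partially observed covariates
#' `L_M = (L_M1, ..., L_Mq)`. A roles object names which column plays which
#' part, fixes the analyst-chosen ordering of the partially observed
#' covariates (the ordering matters for the block-conditional estimators:
#' a covariate that may affect the missingness of another must come first),
#' and records which strings encode missing cells in CSV files.
#'
#' @param outcome Name of the outcome column. Must be fully observed and, in
#'   this version, binary 0/1.
#' @param exposure Name of the (possibly partially observed) exposure column.
#' @param l_o Character vector of fully observed covariate columns.
#' @param l_m Character vector of partially observed covariate columns, in
#'   the analyst's chosen order `L_M1, ..., L_Mq`. May be empty only for
#'   estimators that do not model covariate missingness.
#' @param exposure_level Exposure level `a` whose average potential outcome
#'   `E(Y^a)` is targeted. Supplied explicitly, never inferred.
#' @param missing_codes Strings treated as missing cells when reading CSV.
#'
#' @return An object of class `variable_roles`.
#' @examples
#' roles <- variable_roles(outcome = "y", exposure = "a",
#'                         l_o = "l_o", l_m = c("l_m1", "l_m2"))
#' @export
variable_roles <- function(outcome, exposure, l_o, l_m = character(),
                           exposure_level = 1,
                           missing_codes = c("", "NA")) {
  stopifnot(is.character(outcome), length(outcome) == 1,
            is.character(exposure), length(exposure) == 1,
            is.character(l_o), is.character(l_m))
  cols <- c(outcome, exposure, l_o, l_m)
  if (anyDuplicated(cols)) {
    abort("outcome, exposure, l_o and l_m columns must be disjoint.")
  }
  structure(
    list(outcome = outcome, exposure = exposure, l_o = l_o, l_m = l_m,
         exposure_level = exposure_level, missing_codes = missing_codes),
    class = "variable_roles"
  )
}

#' @export
print.variable_roles <- function(x, ...) {
  cat("<variable_roles>\n")
  cat("  outcome :", x$outcome, "\n")
  cat("  exposure:", x$exposure, " (a =", x$exposure_level, ")\n")
  cat("  L_O     :", paste(x$l_o, collapse = ", "), "\n")
  cat("  L_M     :", if (length(x$l_m)) paste(x$l_m, collapse = " < ") else "(none)", "\n")
  invisible(x)
}

r_col <- function(var) {
  if (!length(var)) return(character(0))  # paste0 would yield "r_"
  paste0("r_", var)
}

#' Build an observed-data table from a data frame
#'
#' Derives the observation indicators `R_A` and `R_Lk` from `NA` cells,
#' validates the invariants of the observed-data structure
#' `O = (L_O, R_L1, ..., R_Lq, R_A, R_L1 L_M1, ..., R_A A, Y)`, and returns a
#' tibble carrying the roles as metadata. Existing indicator columns named
#' `r_<variable>` are validated against the data rather than re-derived.
#'
#' @param data A data frame with the role columns.
#' @param roles A [variable_roles()] object.
#'
#' @return A tibble of class `obs_table` with one `r_<name>` indicator column
#'   per partially observable variable.
#' @export
as_observed_table <- function(data, roles) {
  stopifnot(inherits(roles, "variable_roles"))
  data <- tibble::as_tibble(data)
  needed <- c(roles$outcome, roles$exposure, roles$l_o, roles$l_m)
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols)) {
    abort(paste0("Role column(s) not found in data: ",
                 paste(missing_cols, collapse = ", ")))
  }

  y <- data[[roles$outcome]]
  if (anyNA(y)) {
    abort(paste0("Outcome '", roles$outcome, "' has missing values in rows: ",
                 paste(head(which(is.na(y)), 10), collapse = ", ")))
  }
  if (!all(y %in% c(0, 1))) {
    abort(paste0("Outcome '", roles$outcome,
                 "' must be binary 0/1 in this version."))
  }
  for (lo in roles$l_o) {
    if (anyNA(data[[lo]])) {
      abort(paste0("Fully observed covariate '", lo, "' contains NA; ",
                   "move it to l_m or fix the data."))
    }
  }

  for (v in c(roles$exposure, roles$l_m)) {
    rc <- r_col(v)
    if (rc %in% names(data)) {
      if (!all(data[[rc]] %in% c(0, 1))) {
        abort(paste0("Indicator '", rc, "' must be 0/1."))
      }
      if (any(data[[rc]] == 1 & is.na(data[[v]]))) {
        abort(paste0("'", v, "' is NA on rows where ", rc, " = 1."))
      }
      data[[v]][data[[rc]] == 0] <- NA
    } else {
      data[[rc]] <- as.integer(!is.na(data[[v]]))
    }
  }

  structure(data, roles = roles, class = c("obs_table", class(data)))
}

#' @export
print.obs_table <- function(x, ...) {
  roles <- attr(x, "roles")
  cat("<obs_table> n =", nrow(x), "| q =", length(roles$l_m),
      "partially observed covariate(s)\n")
  NextMethod()
}

#' Read a partially observed dataset from CSV
#'
#' Reads an RFC-4180 CSV, converts the configured missing-value codes to
#' `NA`, and derives observation indicators via [as_observed_table()]. A
#' missing outcome cell is a hard error (the methods require a fully
#' observed outcome); an entirely missing covariate column is *not* an
#' error here — positivity failures belong to the estimators.
#'
#' @param path Path to a CSV file.
#' @param roles A [variable_roles()] object; `roles$missing_codes` are
#'   treated as absent cells.
#' @return An `obs_table` tibble.
#' @export
read_dataset <- function(path, roles) {
  stopifnot(file.exists(path))
  data <- readr::read_csv(path, na = roles$missing_codes,
                          show_col_types = FALSE, progress = FALSE)
  as_observed_table(data, roles)
}

#' Write an observed-data table back to CSV
#'
#' Inverse of [read_dataset()] for the supported dialect: masked cells are
#' written as `"NA"`, indicator columns are dropped (they are re-derivable).
#'
#' @param table An `obs_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(table, path) {
  roles <- attr(table, "roles")
  keep <- setdiff(names(table), r_col(c(roles$exposure, roles$l_m)))
  readr::write_csv(tibble::as_tibble(table)[keep], path, na = "NA")
  invisible(path)
}

#' Enforce monotone coarsening of the partially observed covariates
#'
#' The block-conditional identifying functional conditions on the joint
#' patterns of the leading observation indicators, so its estimators treat
#' `L_Mk` as missing whenever any earlier-ordered `L_Mj` (j < k) is missing.
#' This transform applies that rule: it zeroes `r_l[k]` (and masks the value)
#' whenever an earlier indicator is zero, leaving everything else unchanged.
#' It is idempotent and never increases the number of observed cells.
#'
#' @param table An `obs_table`.
#' @param ordering Permutation of the `l_m` columns to use as the coarsening
#'   order; defaults to the order declared in the roles.
#' @return An `obs_table`, coarsened; attribute `n_coarsened` counts cells
#'   that were masked.
#' @export
coarsen_monotone <- function(table, ordering = NULL) {
  roles <- attr(table, "roles")
  ordering <- ordering %||% roles$l_m
  if (!setequal(ordering, roles$l_m) || length(ordering) != length(roles$l_m)) {
    abort("`ordering` must be a permutation of the declared l_m columns.")
  }
  n_masked <- 0L
  if (length(ordering) >= 2) {
    prev_ok <- rep(TRUE, nrow(table))
    for (k in seq_along(ordering)) {
      v <- ordering[k]; rc <- r_col(v)
      newly <- table[[rc]] == 1 & !prev_ok
      n_masked <- n_masked + sum(newly)
      table[[rc]][newly] <- 0L
      table[[v]][newly] <- NA
      prev_ok <- prev_ok & table[[rc]] == 1
    }
  }
  # reordering the roles keeps downstream estimators aligned with the order
  roles$l_m <- ordering
  attr(table, "roles") <- roles
  attr(table, "n_coarsened") <- n_masked
  table
}

#' Summarize missingness structure of an observed-data table
#'
#' @param table An `obs_table`.
#' @return A list of class `missingness_summary`: `fractions` (per-variable
#'   missing fraction, plus `any` = fraction missing the exposure or any
#'   `L_M`), `patterns` (counts of joint missingness patterns over
#'   `(A, L_M1, ..., L_Mq)`), and `monotone` (`TRUE` iff
#'   [coarsen_monotone()] is a no-op in the declared ordering).
#' @export
summarize_missingness <- function(table) {
  roles <- attr(table, "roles")
  vars <- c(roles$exposure, roles$l_m)
  rcs <- r_col(vars)
  fractions <- vapply(rcs, function(rc) mean(1 - table[[rc]]), numeric(1))
  names(fractions) <- vars
  ind <- as.matrix(tibble::as_tibble(table)[rcs])
  fractions <- c(fractions, any = mean(rowSums(1 - ind) > 0))

  pat <- apply(ind, 1, function(z) {
    miss <- vars[z == 0]
    if (!length(miss)) "(complete)" else paste(miss, collapse = "+")
  })
  patterns <- tibble::as_tibble(table(pattern = pat))
  names(patterns)[2] <- "count"

  monotone <- TRUE
  if (length(roles$l_m) >= 2) {
    rl <- as.matrix(tibble::as_tibble(table)[r_col(roles$l_m)])
    cum_ok <- t(apply(rl == 1, 1, cumall_lgl))
    monotone <- all((rl == 1) == cum_ok)
  }
  structure(list(fractions = fractions, patterns = patterns,
                 monotone = monotone, n = nrow(table)),
            class = "missingness_summary")
}

cumall_lgl <- function(x) cumprod(as.integer(x)) == 1

#' @export
print.missingness_summary <- function(x, ...) {
  cat("<missingness_summary> n =", x$n, "\n")
  cat("  missing fractions:\n")
  for (v in names(x$fractions)) {
    cat(sprintf("    %-12s %.3f\n", v, x$fractions[[v]]))
  }
  cat("  monotone in declared ordering:", x$monotone, "\n")
  print(x$patterns)
  invisible(x)
}

#' Default ordering of partially observed covariates
#'
#' When no causal ordering is supplied for the block-conditional estimators,
#' covariates are placed in order of increasing missingness fraction, which
#' minimizes the number of cells sacrificed by monotone coarsening and tends
#' to improve efficiency. A substantive constraint — a covariate believed to
#' affect the observation status of another must precede it — always
#' overrides this heuristic, so a warning reminds the analyst.
#'
#' @param table An `obs_table`.
#' @param quiet Suppress the reminder warning.
#' @return Character vector: the `l_m` columns, reordered.
#' @export
default_ordering <- function(table, quiet = FALSE) {
  roles <- attr(table, "roles")
  fr <- vapply(roles$l_m, function(v) mean(1 - table[[r_col(v)]]), numeric(1))
  ord <- roles$l_m[order(fr)]
  if (!quiet) {
    warn(paste0("Ordering L_M by increasing missingness (",
                paste(ord, collapse = " < "),
                "); a causal ordering constraint, if any, must override this."))
  }
  ord
}
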