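#' Tidy a fitted average-potential-outcome estimate
#'
#' @param x A [psi_fit].
#' @param ... Unused.
#' @return A one-row tibble: estimator, assumption set, exposure level,
#'   estimate, standard error, confidence bounds and CI method.
#' @export
tidy.psi_fit <- function(x, ...) {
  tibble::tibble(
    estimator = x$estimator, assumption = x$assumption, a = x$a,
    estimate = x$psi, std.error = x$se,
    conf.low = x$ci[1], conf.high = x$ci[2],
    ci_method = x$ci_method %||% NA_character_)
}

#' Glance at a fitted estimate
#'
#' @param x A [psi_fit].
#' @param ... Unused.
#' @return A one-row tibble with sample size, influence-function variance,
#'   fluctuation parameters and truncation counts.
#' @export
glance.psi_fit <- function(x, ...) {
  d <- x$diagnostics
  tibble::tibble(
    n = x$n, sigma2 = x$sigma2,
    max_abs_eps = if (!is.null(d$epsilon)) max(abs(d$epsilon)) else NA_real_,
    n_trunc = if (!is.null(d$n_trunc)) sum(d$n_trunc) else NA_integer_,
    max_weight = if (!is.null(d$weight_range)) d$weight_range[2] else NA_real_,
    mean_if = if (!is.null(x$if_values)) mean(x$if_values) else NA_real_)
}

#' Histogram of the estimated influence values
#'
#' A quick diagnostic: heavy tails signal near-positivity-violations
#' (extreme inverse weights); the vertical line marks the sample mean,
#' which is ~0 for targeted estimators.
#'
#' @param object A [psi_fit] carrying influence values.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.psi_fit <- function(object, bins = 50, ...) {
  if (is.null(object$if_values)) {
    abort("This fit carries no influence values (bootstrap-only estimator).")
  }
  df <- tibble::tibble(phi = as.numeric(object$if_values))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$phi)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey40") +
    ggplot2::geom_vline(xintercept = mean(df$phi), colour = "red",
                        linetype = 2) +
    ggplot2::labs(x = "influence value", y = "records",
                  title = paste0(object$estimator, ": influence values"))
}

#' Plot Monte-Carlo study metrics
#'
#' Bias (x100) per estimator and specification regime with +/- 2
#' Monte-Carlo standard-error bars; the dashed line is zero bias.
#'
#' @param object A `study_metrics` tibble from [run_study()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.study_metrics <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimator, y = .data$bias100)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$bias100 - 2 * .data$bias_mcse100,
      ymax = .data$bias100 + 2 * .data$bias_mcse100)) +
    ggplot2::facet_wrap(~mode) +
    ggplot2::labs(y = "bias x 100", x = NULL,
                  title = "Monte-Carlo bias by estimator and regime") +
    ggplot2::theme_bw()
}

#' Serialize a fitted estimate to JSON
#'
#' Writes the tidy summary plus key diagnostics (CI method tag included) to
#' a JSON file; requires the `jsonlite` package.
#'
#' @param x A [psi_fit].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_result_json <- function(x, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    abort("write_result_json() requires the jsonlite package.")
  }
  out <- c(as.list(tidy(x)), as.list(glance(x)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
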