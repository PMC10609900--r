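#' Build a forest-plot table from MR fits
#'
#' Flattens a set of exposure-outcome MR results into one row per
#' pair, ready for tabulation or [plot_forest()]. Binary outcomes are
#' rendered on the odds-ratio scale (estimate and CI exponentiated);
#' continuous outcomes stay on the beta scale. Row order is stable:
#' exposures then outcomes, in first-appearance order.
#'
#' @param results A data frame with columns `exposure`, `outcome`, and
#'   `fit` (a list column of `mr_result` objects), e.g. built with
#'   `tibble::tibble(exposure = ..., outcome = ..., fit = list(...))`.
#' @return A tibble with `exposure_label`, `outcome_label`, `k`,
#'   `beta`, `ci_low`, `ci_high`, `pvalue`, `scale`.
#' @export
forest_table <- function(results) {
  results <- tibble::as_tibble(results)
  if (nrow(results) == 0) {
    return(tibble::tibble(
      exposure_label = character(), outcome_label = character(),
      k = integer(), beta = double(), ci_low = double(),
      ci_high = double(), pvalue = double(), scale = character()
    ))
  }
  stopifnot(all(c("exposure", "outcome", "fit") %in% names(results)))
  rows <- purrr::pmap_dfr(results, function(exposure, outcome, fit, ...) {
    stopifnot(inherits(fit, "mr_result"))
    binary <- identical(fit$trait_type, "binary")
    tr <- if (binary) exp else identity
    tibble::tibble(
      exposure_label = as.character(exposure),
      outcome_label = as.character(outcome),
      k = fit$k,
      beta = tr(fit$beta), ci_low = tr(fit$ci_low), ci_high = tr(fit$ci_high),
      pvalue = fit$pvalue,
      scale = if (binary) "odds_ratio" else "beta"
    )
  })
  rows$exposure_label <- factor(rows$exposure_label,
                                levels = unique(rows$exposure_label))
  rows$outcome_label <- factor(rows$outcome_label,
                               levels = unique(rows$outcome_label))
  rows <- dplyr::arrange(rows, .data$exposure_label, .data$outcome_label)
  rows$exposure_label <- as.character(rows$exposure_label)
  rows$outcome_label <- as.character(rows$outcome_label)
  rows
}

#' Format a forest table for printing
#'
#' Betas and CI bounds to 3 decimals, odds ratios to 2, p-values in
#' scientific notation with 2 significant digits.
#'
#' @param rows A tibble from [forest_table()].
#' @return A tibble of formatted strings with an `estimate` column
#'   `"est [lo, hi]"`.
#' @export
format_forest <- function(rows) {
  fmt1 <- function(x, scale) {
    ifelse(scale == "odds_ratio", sprintf("%.2f", x), sprintf("%.3f", x))
  }
  tibble::tibble(
    exposure = rows$exposure_label,
    outcome = rows$outcome_label,
    k = rows$k,
    estimate = paste0(fmt1(rows$beta, rows$scale), " [",
                      fmt1(rows$ci_low, rows$scale), ", ",
                      fmt1(rows$ci_high, rows$scale), "]"),
    scale = rows$scale,
    p = sprintf("%.1e", rows$pvalue)
  )
}

#' Forest plot of MR estimates
#'
#' Point estimates with CI whiskers, one row per exposure-outcome
#' pair, and a null reference line at 0 (beta scale) or 1 (odds-ratio
#' scale). Mixed scales are split into facets. Layout is deterministic
#' given the rows.
#'
#' @param rows A tibble from [forest_table()].
#' @param path Optional output file; when given the plot is also saved
#'   there (format from the extension) and a JSON sidecar
#'   `<path>.json` records the plotted rows.
#' @param width,height Device size in inches when saving.
#' @return A ggplot object, invisibly when `path` is given.
#' @export
plot_forest <- function(rows, path = NULL, width = 7, height = 4.5) {
  if (nrow(rows) == 0) {
    abort("no rows to plot", class = "caffemr_usage_error")
  }
  rows <- dplyr::mutate(
    rows,
    label = factor(paste(.data$exposure_label, "→", .data$outcome_label),
                   levels = rev(unique(paste(.data$exposure_label, "→",
                                             .data$outcome_label)))),
    null = ifelse(.data$scale == "odds_ratio", 1, 0)
  )
  p <- ggplot2::ggplot(rows, ggplot2::aes(x = .data$beta, y = .data$label)) +
    ggplot2::geom_vline(ggplot2::aes(xintercept = .data$null),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high),
      height = 0.2
    ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "MR estimate (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
  if (length(unique(rows$scale)) > 1) {
    p <- p + ggplot2::facet_wrap(~scale, scales = "free_x")
  } else if (rows$scale[1] == "odds_ratio") {
    p <- p + ggplot2::labs(x = "Odds ratio (95% CI)")
  }
  if (!is.null(path)) {
    ggplot2::ggsave(path, p, width = width, height = height)
    jsonlite::write_json(
      rows[, c("exposure_label", "outcome_label", "k", "beta",
               "ci_low", "ci_high", "pvalue", "scale")],
      paste0(path, ".json"), digits = NA, dataframe = "rows"
    )
    return(invisible(p))
  }
  p
}

#' Forest plot of a single MR fit's per-variant estimates
#'
#' Shows each variant's Wald ratio with its CI and the pooled IVW
#' estimate beneath.
#'
#' @param object An `mr_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mr_result <- function(object, ...) {
  z <- qnorm(1 - object$alpha / 2)
  pv <- tibble::tibble(
    label = object$per_variant$rsid,
    beta = object$per_variant$theta,
    lo = object$per_variant$theta - z * object$per_variant$se_theta,
    hi = object$per_variant$theta + z * object$per_variant$se_theta,
    pooled = FALSE
  )
  pooled <- tibble::tibble(label = paste0("Pooled (", object$method, ")"),
                           beta = object$beta, lo = object$ci_low,
                           hi = object$ci_high, pooled = TRUE)
  d <- dplyr::bind_rows(pv, pooled)
  d$label <- factor(d$label, levels = rev(d$label))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$beta, y = .data$label,
                                  shape = .data$pooled)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                            height = 0.2) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 18),
                                guide = "none") +
    ggplot2::labs(x = "Wald ratio / pooled estimate (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
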