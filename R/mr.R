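#' Per-variant Wald ratio estimates
#'
#' For each retained harmonized pair, the Wald ratio is the
#' variant-outcome association divided by the variant-exposure
#' association, `theta = beta_outcome / beta_exposure`. Its standard
#' error is, by default, the first-order approximation
#' `se_outcome / |beta_exposure|` (the standard error of the
#' variant-outcome association divided by the variant-exposure
#' association); the delta-method second-order form
#' `sqrt(se_out^2/bx^2 + by^2 se_x^2 / bx^4)` additionally propagates
#' uncertainty in the exposure association.
#'
#' @param pairs A tibble of harmonized pairs from [harmonize()] (rows
#'   with `action == "dropped"` are ignored), or any data frame with
#'   `rsid`, `beta_exposure`, `se_exposure`, `beta_outcome`,
#'   `se_outcome`.
#' @param se_method `"first_order"` (default) or `"second_order"`.
#' @param weak_f Instrument-strength threshold: a warning is issued
#'   when any `|beta_exposure| / se_exposure` falls below it
#'   (default 3).
#' @return A tibble with `rsid`, `theta`, `se_theta`, `se_method` plus
#'   the input association columns.
#' @export
#' @examples
#' pairs <- tibble::tibble(
#'   rsid = "rs0", beta_exposure = 0.5, se_exposure = 0.05,
#'   beta_outcome = 0.5, se_outcome = 0.1
#' )
#' wald_ratios(pairs) # theta 1, se 0.2
wald_ratios <- function(pairs, se_method = c("first_order", "second_order"),
                        weak_f = 3) {
  se_method <- match.arg(se_method)
  pairs <- tibble::as_tibble(pairs)
  if ("action" %in% names(pairs)) {
    pairs <- pairs[pairs$action != "dropped", , drop = FALSE]
  }
  bx <- pairs$beta_exposure
  if (any(abs(bx) < 1e-12)) {
    abort(paste0("undefined Wald ratio: zero exposure beta for ",
                 paste(pairs$rsid[abs(bx) < 1e-12], collapse = ", ")),
          class = "caffemr_undefined_ratio_error")
  }
  f <- abs(bx) / pairs$se_exposure
  if (any(is.finite(f) & f < weak_f)) {
    warn(paste0("weak instrument(s) (|beta|/se < ", weak_f, "): ",
                paste(pairs$rsid[is.finite(f) & f < weak_f], collapse = ", ")))
  }
  theta <- pairs$beta_outcome / bx
  se_theta <- if (se_method == "first_order") {
    pairs$se_outcome / abs(bx)
  } else {
    sqrt(pairs$se_outcome^2 / bx^2 +
           pairs$beta_outcome^2 * pairs$se_exposure^2 / bx^4)
  }
  dplyr::bind_cols(
    tibble::tibble(rsid = pairs$rsid, theta = theta, se_theta = se_theta,
                   se_method = se_method),
    pairs[, setdiff(names(pairs), c("rsid", "se_method"))]
  )
}

# Shared pooling core. method: "fixed", "random_multiplicative",
# "random_additive". Returns an mr_result.
ivw_pool <- function(estimates, method, alpha, trait_type = "continuous",
                     se_method = NULL) {
  estimates <- tibble::as_tibble(estimates)
  if (nrow(estimates) == 0) {
    abort("no estimates to pool", class = "caffemr_usage_error")
  }
  if (any(estimates$se_theta <= 0)) {
    abort("se_theta must be > 0", class = "caffemr_validation_error")
  }
  theta <- estimates$theta
  se <- estimates$se_theta
  k <- length(theta)
  w <- 1 / se^2
  beta_fe <- sum(w * theta) / sum(w)
  se_fe <- sqrt(1 / sum(w))
  q <- sum(w * (theta - beta_fe)^2)
  df <- k - 1L
  tau2 <- NA_real_
  dispersion <- NA_real_

  if (k == 1 && method != "fixed") {
    inform("single variant: pooled result is the Wald estimate itself")
  }
  if (method == "fixed" || k == 1) {
    beta <- beta_fe
    se_pooled <- se_fe
  } else if (method == "random_multiplicative") {
    dispersion <- max(1, q / df)
    beta <- beta_fe
    se_pooled <- se_fe * sqrt(dispersion)
  } else if (method == "random_additive") {
    tau2 <- max(0, (q - df) / (sum(w) - sum(w^2) / sum(w)))
    w_star <- 1 / (se^2 + tau2)
    beta <- sum(w_star * theta) / sum(w_star)
    se_pooled <- sqrt(1 / sum(w_star))
  } else {
    abort(paste0("unknown method: ", method), class = "caffemr_usage_error")
  }

  z_crit <- qnorm(1 - alpha / 2)
  z <- beta / se_pooled
  res <- list(
    beta = beta, se = se_pooled,
    ci_low = beta - z_crit * se_pooled,
    ci_high = beta + z_crit * se_pooled,
    z = z, pvalue = 2 * pnorm(-abs(z)),
    q = q, df = df, tau2 = tau2, dispersion = dispersion,
    method = method, k = k, alpha = alpha,
    trait_type = trait_type,
    se_method = se_method %||%
      (if ("se_method" %in% names(estimates)) estimates$se_method[1] else NA_character_),
    per_variant = estimates
  )
  class(res) <- "mr_result"
  res
}

#' Fixed-effect inverse-variance-weighted pooling
#'
#' Pools per-variant Wald ratios with weights `1/se^2`:
#' `beta = sum(w theta) / sum(w)`, `se = sqrt(1/sum(w))`, and Cochran's
#' `Q = sum(w (theta - beta)^2)` on `k - 1` degrees of freedom.
#' Confidence bounds and the two-sided p-value use the normal
#' reference distribution.
#'
#' @param estimates A tibble of Wald estimates from [wald_ratios()]
#'   (needs `theta` and `se_theta`).
#' @param alpha Confidence level complement (default 0.05 for 95% CI).
#' @param trait_type `"continuous"` or `"binary"`; binary results gain
#'   an odds-ratio view in [glance.mr_result()] and [forest_table()].
#' @return An `mr_result` object; see [tidy.mr_result()] and
#'   [glance.mr_result()].
#' @export
#' @examples
#' est <- tibble::tibble(theta = c(1, 3), se_theta = c(0.5, 0.5))
#' glance(ivw_fixed(est)) # beta 2, se 0.3536, Q 8
ivw_fixed <- function(estimates, alpha = 0.05, trait_type = "continuous") {
  ivw_pool(estimates, "fixed", alpha, trait_type)
}

#' Random-effects inverse-variance-weighted pooling
#'
#' Two random-effects flavors are provided because "random-effects IVW"
#' is ambiguous with very few variants. The multiplicative model keeps
#' the fixed-effect point estimate and inflates its standard error by
#' `sqrt(max(1, Q/(k-1)))` (the dispersion, floored at 1 so the
#' random-effects SE is never smaller than the fixed-effect SE). The
#' additive model is DerSimonian-Laird:
#' `tau2 = max(0, (Q - (k-1)) / (sum(w) - sum(w^2)/sum(w)))` with
#' fixed-effect weights, then re-weighting by `1/(se^2 + tau2)`. With a
#' single variant both return the Wald estimate unchanged.
#'
#' @inheritParams ivw_fixed
#' @param flavor `"multiplicative"` (default) or `"additive_dl"`.
#' @return An `mr_result` object.
#' @export
ivw_random <- function(estimates, flavor = c("multiplicative", "additive_dl"),
                       alpha = 0.05, trait_type = "continuous") {
  flavor <- match.arg(flavor)
  method <- if (flavor == "multiplicative") "random_multiplicative" else "random_additive"
  ivw_pool(estimates, method, alpha, trait_type)
}

#' Run a two-sample MR analysis end to end
#'
#' Harmonizes the two tables, computes per-variant Wald ratios for the
#' retained pairs, pools them by random-effects IVW (default
#' multiplicative; see [ivw_random()]), and returns the pooled result
#' together with the per-variant report and harmonization audit.
#'
#' @param exposure,outcome Association tibbles (see
#'   [association_table()]).
#' @param method `"random_multiplicative"` (default),
#'   `"random_additive"`, or `"fixed"`.
#' @inheritParams wald_ratios
#' @inheritParams ivw_fixed
#' @inheritParams harmonize
#' @param trait_type Outcome trait type; defaults to the outcome
#'   table's `trait_type` when uniformly recorded, else
#'   `"continuous"`.
#' @return An `mr_result`: pooled `beta`, `se`, `ci_low`, `ci_high`,
#'   `z`, `pvalue`, heterogeneity `q`/`df`/`tau2`/`dispersion`,
#'   `method`, `k`, plus `per_variant` (Wald estimates joined with
#'   harmonization actions) and `audit`.
#' @export
#' @examples
#' exp <- caffeine_instruments("plasma_caffeine")
#' out <- exp
#' out$beta <- 0.1 * exp$beta # outcome exactly proportional: theta = 0.1
#' out$se <- c(0.001, 0.001)
#' fit <- run_mr(exp, out)
#' glance(fit)
run_mr <- function(exposure, outcome,
                   method = c("random_multiplicative", "random_additive",
                              "fixed"),
                   se_method = c("first_order", "second_order"),
                   alpha = 0.05,
                   palindrome_policy = c("infer_by_eaf", "drop"),
                   eaf_ambiguity_band = 0.08,
                   trait_type = NULL, weak_f = 3) {
  method <- match.arg(method)
  se_method <- match.arg(se_method)
  palindrome_policy <- match.arg(palindrome_policy)
  pairs <- harmonize(exposure, outcome,
                     palindrome_policy = palindrome_policy,
                     eaf_ambiguity_band = eaf_ambiguity_band)
  retained <- pairs[pairs$action != "dropped", , drop = FALSE]
  if (nrow(retained) < 1) {
    abort("no instruments retained after harmonization",
          class = "caffemr_no_instruments_error")
  }
  if (is.null(trait_type)) {
    tt <- unique(outcome$trait_type)
    tt <- tt[!is.na(tt)]
    trait_type <- if (length(tt) == 1) tt else "continuous"
  }
  wald <- wald_ratios(retained, se_method = se_method, weak_f = weak_f)
  res <- ivw_pool(wald, method = method, alpha = alpha,
                  trait_type = trait_type, se_method = se_method)
  res$audit <- harmonization_audit(pairs)
  res$dropped <- pairs[pairs$action == "dropped", , drop = FALSE]
  res
}

#' @export
print.mr_result <- function(x, ...) {
  cat("Two-sample MR (IVW, ", x$method, ")\n", sep = "")
  cat(sprintf("  k = %d variants; beta = %.4f (se %.4f), %g%% CI [%.4f, %.4f]\n",
              x$k, x$beta, x$se, 100 * (1 - x$alpha), x$ci_low, x$ci_high))
  cat(sprintf("  p = %.3g; Q = %.3f on %d df\n", x$pvalue, x$q, x$df))
  if (identical(x$trait_type, "binary")) {
    cat(sprintf("  OR = %.3f [%.3f, %.3f]\n",
                exp(x$beta), exp(x$ci_low), exp(x$ci_high)))
  }
  invisible(x)
}

#' Tidy the per-variant report of an MR fit
#'
#' @param x An `mr_result`.
#' @param ... Unused.
#' @return A tibble with one row per variant: Wald ratio, SE, and (for
#'   [run_mr()] fits) the harmonization action taken.
#' @export
tidy.mr_result <- function(x, ...) {
  tibble::as_tibble(x$per_variant)
}

#' One-row summary of an MR fit
#'
#' @param x An `mr_result`.
#' @param ... Unused.
#' @return A one-row tibble: `beta`, `se`, `ci_low`, `ci_high`, `z`,
#'   `pvalue`, `q`, `df`, `tau2`, `dispersion`, `method`, `k`,
#'   `alpha`; binary outcomes add `or`, `or_ci_low`, `or_ci_high`.
#' @export
glance.mr_result <- function(x, ...) {
  out <- tibble::tibble(
    beta = x$beta, se = x$se, ci_low = x$ci_low, ci_high = x$ci_high,
    z = x$z, pvalue = x$pvalue, q = x$q, df = x$df, tau2 = x$tau2,
    dispersion = x$dispersion, method = x$method, k = x$k, alpha = x$alpha
  )
  if (identical(x$trait_type, "binary")) {
    out$or <- exp(x$beta)
    out$or_ci_low <- exp(x$ci_low)
    out$or_ci_high <- exp(x$ci_high)
  }
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
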