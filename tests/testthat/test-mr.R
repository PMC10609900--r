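# Independent oracle: with first-order Wald SEs, fixed-effect IVW
# equals the least-squares slope through the origin of beta_outcome on
# beta_exposure weighted by 1/se_outcome^2. Implemented via lm(), never
# through the package's own pooling code.
ivw_regression_oracle <- function(beta_x, beta_y, se_y) {
  fit <- lm(beta_y ~ 0 + beta_x, weights = 1 / se_y^2)
  list(beta = unname(coef(fit)[1]),
       se = sqrt(1 / sum(beta_x^2 / se_y^2)))
}

test_that("Wald ratios match the ratio formula and both SE forms", {
  # zero outcome beta: theta 0, first-order se = se_y / |beta_x|
  p0 <- tibble::tibble(rsid = "rs4410790", beta_exposure = 0.109,
                       se_exposure = 0.015, beta_outcome = 0,
                       se_outcome = 0.005)
  w0 <- wald_ratios(p0)
  expect_equal(w0$theta, 0)
  expect_equal(w0$se_theta, 0.005 / 0.109, tolerance = 1e-12)
  expect_equal(round(w0$se_theta, 6), 0.045872)

  p1 <- tibble::tibble(rsid = "rs_x", beta_exposure = 0.5, se_exposure = 0.01,
                       beta_outcome = 0.5, se_outcome = 0.1)
  w1 <- wald_ratios(p1)
  expect_equal(w1$theta, 1)
  expect_equal(w1$se_theta, 0.2)

  # frozen from direct arithmetic: theta = -0.002/0.109; first-order
  # 0.0005/0.109; second-order sqrt(0.0005^2/0.109^2 + 0.002^2*0.015^2/0.109^4)
  p2 <- tibble::tibble(rsid = "rs_y", beta_exposure = 0.109,
                       se_exposure = 0.015, beta_outcome = -0.002,
                       se_outcome = 0.0005)
  expect_equal(round(wald_ratios(p2)$theta, 6), -0.018349)
  expect_equal(round(wald_ratios(p2)$se_theta, 6), 0.004587)
  expect_equal(round(wald_ratios(p2, se_method = "second_order")$se_theta, 6),
               0.005236)

  # zero exposure beta is an explicit error; weak instruments warn
  pz <- tibble::tibble(rsid = "rs_z", beta_exposure = 0, se_exposure = 0.01,
                       beta_outcome = 0.1, se_outcome = 0.1)
  expect_error(wald_ratios(pz), class = "caffemr_undefined_ratio_error")
  pw <- tibble::tibble(rsid = "rs_w", beta_exposure = 0.01, se_exposure = 0.01,
                       beta_outcome = 0.1, se_outcome = 0.1)
  expect_warning(wald_ratios(pw), "weak instrument")
})

test_that("fixed-effect IVW matches hand-computed meta-analysis", {
  # k = 1 identity under every method
  single <- tibble::tibble(theta = 2, se_theta = 0.3)
  for (fit in list(ivw_fixed(single),
                   suppressMessages(ivw_random(single, "multiplicative")),
                   suppressMessages(ivw_random(single, "additive_dl")))) {
    expect_equal(fit$beta, 2)
    expect_equal(fit$se, 0.3)
    expect_equal(fit$q, 0)
  }

  # w = 4 each: beta 2, se sqrt(1/8), Q = 4*1 + 4*1 = 8
  est <- tibble::tibble(theta = c(1, 3), se_theta = c(0.5, 0.5))
  fe <- ivw_fixed(est)
  expect_equal(fe$beta, 2)
  expect_equal(fe$se, sqrt(1 / 8))
  expect_equal(round(fe$se, 6), 0.353553)
  expect_equal(fe$q, 8)
  expect_equal(fe$df, 1)

  # homogeneous estimates: Q = 0 regardless of weights
  hom <- ivw_fixed(tibble::tibble(theta = c(2, 2), se_theta = c(0.1, 0.4)))
  expect_equal(hom$beta, 2)
  expect_equal(hom$q, 0)

  expect_error(ivw_fixed(tibble::tibble(theta = double(),
                                        se_theta = double())),
               class = "caffemr_usage_error")
})

test_that("random-effects flavors match hand computation and floor at the fixed SE", {
  est <- tibble::tibble(theta = c(1, 3), se_theta = c(0.5, 0.5))
  mult <- ivw_random(est, "multiplicative")
  expect_equal(mult$beta, 2)
  expect_equal(mult$dispersion, 8)
  expect_equal(mult$se, sqrt(1 / 8) * sqrt(8)) # = 1
  expect_equal(mult$se, 1)

  # DL: tau2 = (8 - 1) / (8 - 32/8) = 1.75; w* = 1/2 each; se = 1
  dl <- ivw_random(est, "additive_dl")
  expect_equal(dl$tau2, 1.75)
  expect_equal(dl$beta, 2)
  expect_equal(dl$se, 1)

  # identical estimates: dispersion floored at 1, equals fixed
  same <- tibble::tibble(theta = c(2, 2), se_theta = c(0.3, 0.3))
  expect_equal(ivw_random(same, "multiplicative")$se, ivw_fixed(same)$se)
  expect_equal(ivw_random(same, "multiplicative")$dispersion, 1)

  # k = 2 equal SEs: the two flavors provably coincide
  for (seed in 1:20) {
    est2 <- withr::with_seed(seed, tibble::tibble(
      theta = rnorm(2), se_theta = rep(runif(1, 0.1, 1), 2)
    ))
    expect_equal(ivw_random(est2, "multiplicative")$se,
                 ivw_random(est2, "additive_dl")$se, tolerance = 1e-12)
    expect_equal(ivw_random(est2, "multiplicative")$beta,
                 ivw_random(est2, "additive_dl")$beta, tolerance = 1e-12)
  }
})

test_that("IVW agrees with metafor on random instances", {
  skip_if_not_installed("metafor")
  for (seed in 1:10) {
    est <- withr::with_seed(seed, tibble::tibble(
      theta = rnorm(5, 0.2, 0.5), se_theta = runif(5, 0.05, 0.5)
    ))
    fe <- ivw_fixed(est)
    ref_fe <- metafor::rma(yi = est$theta, sei = est$se_theta, method = "FE")
    expect_equal(fe$beta, as.numeric(ref_fe$beta), tolerance = 1e-10)
    expect_equal(fe$se, ref_fe$se, tolerance = 1e-10)
    expect_equal(fe$q, ref_fe$QE, tolerance = 1e-10)

    dl <- ivw_random(est, "additive_dl")
    ref_dl <- metafor::rma(yi = est$theta, sei = est$se_theta, method = "DL")
    expect_equal(dl$tau2, ref_dl$tau2, tolerance = 1e-10)
    expect_equal(dl$beta, as.numeric(ref_dl$beta), tolerance = 1e-10)
    expect_equal(dl$se, ref_dl$se, tolerance = 1e-10)
  }
})

test_that("confidence intervals, p-values, and the odds-ratio view", {
  null <- ivw_fixed(tibble::tibble(theta = 0, se_theta = 1))
  expect_equal(null$ci_low, -1.959964, tolerance = 1e-6)
  expect_equal(null$ci_high, 1.959964, tolerance = 1e-6)
  expect_equal(null$pvalue, 1)

  z2 <- ivw_fixed(tibble::tibble(theta = 1, se_theta = 0.5))
  expect_equal(z2$z, 2)
  expect_equal(round(z2$pvalue, 4), 0.0455)

  # the printed odds-ratio form: beta -0.1744 -> OR 0.84 [0.75, 0.94]
  bin <- ivw_fixed(tibble::tibble(theta = -0.1744, se_theta = 0.0576),
                   trait_type = "binary")
  g <- glance(bin)
  expect_equal(round(g$or, 3), 0.840)
  expect_equal(round(g$or_ci_low, 2), 0.75)
  expect_equal(round(g$or_ci_high, 2), 0.94)
  expect_false("or" %in% names(glance(ivw_fixed(
    tibble::tibble(theta = -0.1744, se_theta = 0.0576)
  ))))

  # alpha controls CI width
  wide <- ivw_fixed(tibble::tibble(theta = 0, se_theta = 1), alpha = 0.10)
  expect_equal(wide$ci_high, qnorm(0.95), tolerance = 1e-10)
})

test_that("fixed IVW equals the weighted least-squares oracle on random instances", {
  for (seed in 1:50) {
    d <- withr::with_seed(seed, {
      k <- sample(2:8, 1)
      tibble::tibble(
        rsid = sprintf("rs%d", seq_len(k)),
        beta_exposure = runif(k, 0.05, 0.5) * sample(c(-1, 1), k, TRUE),
        se_exposure = runif(k, 0.005, 0.05),
        beta_outcome = rnorm(k, 0, 0.1),
        se_outcome = runif(k, 0.002, 0.05)
      )
    })
    fit <- suppressWarnings(ivw_fixed(wald_ratios(d)))
    oracle <- ivw_regression_oracle(d$beta_exposure, d$beta_outcome,
                                    d$se_outcome)
    expect_equal(fit$beta, oracle$beta, tolerance = 1e-10)
    expect_equal(fit$se, oracle$se, tolerance = 1e-10)
  }
})

test_that("Wald and IVW results are invariant to joint allele flips", {
  for (seed in 1:10) {
    exp <- random_assoc_table(k = 4, seed = seed)
    out <- withr::with_seed(seed + 500,
                            outcome_from_exposure(exp, theta = 0.4,
                                                  noise_sd = 0.02))
    base <- glance(suppressWarnings(run_mr(exp, out, method = "fixed")))
    flipped <- glance(suppressWarnings(
      run_mr(swap_alleles(exp), swap_alleles(out), method = "fixed")
    ))
    expect_equal(flipped$beta, base$beta, tolerance = 1e-12)
    expect_equal(flipped$se, base$se, tolerance = 1e-12)
    expect_equal(flipped$q, base$q, tolerance = 1e-10)
  }
})

test_that("pooled estimate is scale-equivariant in the exposure betas", {
  exp <- random_assoc_table(k = 4, seed = 3)
  out <- withr::with_seed(42, outcome_from_exposure(exp, theta = 0.4,
                                                    noise_sd = 0.02))
  base <- glance(suppressWarnings(run_mr(exp, out, method = "fixed")))
  for (c_mult in c(0.5, 2, 10)) {
    scaled <- exp
    scaled$beta <- scaled$beta * c_mult
    scaled$se <- scaled$se * c_mult # keep instrument strength constant
    res <- glance(suppressWarnings(run_mr(scaled, out, method = "fixed")))
    expect_equal(res$beta, base$beta / c_mult, tolerance = 1e-10)
  }
})

test_that("run_mr composes harmonization, Wald ratios, and pooling", {
  plasma <- caffeine_instruments("plasma_caffeine")

  # exact proportionality: pooled beta = theta to numerical precision
  out <- plasma
  out$beta <- 0.25 * plasma$beta
  out$se <- c(1e-5, 1e-5)
  out$pvalue <- pmax(2 * pnorm(-abs(out$beta / out$se)),
                     .Machine$double.xmin)
  out <- association_table(out, trait_id = "outcome")
  fit <- run_mr(plasma, out)
  expect_equal(fit$beta, 0.25, tolerance = 1e-10)
  expect_equal(fit$q, 0, tolerance = 1e-6)
  expect_equal(fit$k, 2)
  expect_true(all(c("rsid", "theta", "se_theta", "se_method",
                    "beta_exposure", "se_exposure", "beta_outcome",
                    "se_outcome", "action") %in% names(tidy(fit))))

  # single-variant tables: pooled result equals that variant's Wald ratio
  single <- suppressMessages(run_mr(plasma[1, ], out[1, ]))
  expect_equal(single$beta, out$beta[1] / plasma$beta[1], tolerance = 1e-12)
  expect_equal(single$se, out$se[1] / abs(plasma$beta[1]), tolerance = 1e-12)

  # null generative case: the 95% CI covers 0 in the vast majority of
  # seeded replicates (exact coverage is checked at scale elsewhere)
  covered <- vapply(1:20, function(s) {
    sim <- sim_summary_stats(k = 2, theta = 0, seed = s)
    g <- glance(run_mr(sim$exposure, sim$outcome, method = "fixed"))
    abs(g$beta) < 1.959964 * g$se
  }, logical(1))
  expect_gte(sum(covered), 16)

  # no shared instruments is an explicit error
  lonely <- plasma
  lonely$rsid <- c("rs_other1", "rs_other2")
  expect_error(suppressMessages(run_mr(plasma, lonely)),
               class = "caffemr_no_instruments_error")
})
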