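# Two-sided normal p-value, floored at the smallest normal double so
# that extreme z does not underflow to an invalid p = 0.
p_from_z <- function(beta, se) {
  pmax(2 * pnorm(-abs(beta / se)), .Machine$double.xmin)
}

# Derive a component sub-seed from a master seed so that adding a new
# draw to one component never perturbs another. Kept below 2^31.
sub_seed <- function(seed, offset) {
  (as.integer(seed) + 1009L * as.integer(offset)) %% .Machine$integer.max
}

#' Simulate two-sample GWAS summary statistics with a known causal effect
#'
#' The standard summary-level MR generative model: each variant j has a
#' true exposure effect `bx_j` drawn uniformly from `beta_x_range`; the
#' observed exposure beta is `N(bx_j, se_x_j)` and the observed outcome
#' beta is `N(theta * bx_j + alpha_j, se_y_j)`, where
#' `alpha_j ~ N(0, pleiotropy_sd^2)` is a direct (pleiotropic) effect —
#' zero gives valid instruments. Standard errors come from the
#' single-SNP regression approximation `se^2 = 1 / (2 f (1-f) n)` for a
#' unit-variance trait with effect-allele frequency `f`. The two tables
#' share rsids and allele orientation, emulating pre-harmonized
#' non-overlapping samples.
#'
#' Defaults mirror the caffeine analysis: two variants with exposure
#' effects in the 0.10-0.15 range, an exposure GWAS of about 10,000
#' individuals (plasma caffeine metabolite meta-analysis scale), and a
#' large outcome GWAS of several hundred thousand (kidney-trait
#' consortium scale).
#'
#' @param k Number of variants (default 2).
#' @param theta True causal effect of exposure on outcome (default 0).
#' @param beta_x_range Range for the true exposure effects (default
#'   `c(0.10, 0.15)`, spanning the instrument effect sizes at the
#'   *AHR*/*CYP1A2* loci).
#' @param n_exposure,n_outcome Sample sizes of the two GWAS (defaults
#'   9876 and 400000).
#' @param pleiotropy_sd SD of per-variant direct effects (default 0,
#'   i.e. valid instruments).
#' @param eaf_range Range for effect-allele frequencies (default
#'   `c(0.2, 0.8)`; degenerate frequencies 0/1 are rejected).
#' @param seed Optional integer seed; given the seed and the
#'   configuration the output is bit-reproducible.
#' @return A list with `exposure` and `outcome` association tibbles and
#'   a `truth` list carrying `theta` and all latent values.
#' @export
#' @examples
#' sim <- sim_summary_stats(k = 2, theta = 0.5, seed = 7)
#' glance(run_mr(sim$exposure, sim$outcome))
sim_summary_stats <- function(k = 2, theta = 0,
                              beta_x_range = c(0.10, 0.15),
                              n_exposure = 9876, n_outcome = 400000,
                              pleiotropy_sd = 0,
                              eaf_range = c(0.2, 0.8), seed = NULL) {
  stopifnot(k >= 1, n_exposure >= 2, n_outcome >= 2, pleiotropy_sd >= 0)
  if (eaf_range[1] <= 0 || eaf_range[2] >= 1) {
    abort("eaf_range must lie strictly inside (0, 1)",
          class = "caffemr_validation_error")
  }
  draw <- function() {
    eaf <- runif(k, eaf_range[1], eaf_range[2])
    bx_true <- runif(k, beta_x_range[1], beta_x_range[2])
    se_x <- sqrt(1 / (2 * eaf * (1 - eaf) * n_exposure))
    se_y <- sqrt(1 / (2 * eaf * (1 - eaf) * n_outcome))
    alpha_j <- rnorm(k, 0, pleiotropy_sd)
    bx_hat <- rnorm(k, bx_true, se_x)
    by_hat <- rnorm(k, theta * bx_true + alpha_j, se_y)
    # Non-palindromic allele pairs, shared orientation across tables.
    pair_pool <- list(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"))
    pairs <- pair_pool[sample.int(4, k, replace = TRUE)]
    list(eaf = eaf, bx_true = bx_true, se_x = se_x, se_y = se_y,
         alpha = alpha_j, bx_hat = bx_hat, by_hat = by_hat, pairs = pairs)
  }
  d <- if (is.null(seed)) draw() else withr::with_seed(sub_seed(seed, 1), draw())

  rsid <- sprintf("rs_sim%03d", seq_len(k))
  ea <- vapply(d$pairs, `[`, character(1), 1)
  oa <- vapply(d$pairs, `[`, character(1), 2)
  mk <- function(beta, se, n, trait_id) {
    association_table(tibble::tibble(
      rsid = rsid, effect_allele = ea, other_allele = oa,
      beta = beta, se = se, pvalue = p_from_z(beta, se),
      eaf = d$eaf, n = n, gene_label = paste0("locus", seq_len(k))
    ), trait_id = trait_id, trait_type = "continuous", strict = TRUE)
  }
  list(
    exposure = mk(d$bx_hat, d$se_x, n_exposure, "sim_exposure"),
    outcome = mk(d$by_hat, d$se_y, n_outcome, "sim_outcome"),
    truth = list(theta = theta, beta_x_true = d$bx_true, alpha = d$alpha,
                 eaf = d$eaf, se_x = d$se_x, se_y = d$se_y, seed = seed)
  )
}

#' Simulate a metabolizer-compensation cohort
#'
#' A mechanistic, individual-level model of why plasma-caffeine and
#' caffeine-intake MR analyses can disagree in sign. Genotypes at L
#' clearance loci raise log caffeine clearance
#' (`c_i = sum_l delta_l g_il + e_c`); individuals behaviorally titrate
#' intake toward a target stimulant effect, so log intake tracks
#' clearance with compensation strength `kappa`
#' (`I_i = mu + kappa c_i + e_I`); steady-state log plasma level is
#' intake minus clearance (`P_i = I_i - c_i`, exactly, row-wise); and
#' the outcome combines a plasma effect and an intake effect
#' (`Y_i = gamma_p P_i + gamma_i I_i + e_Y`). Faster metabolizers
#' (higher clearance) thus have higher intake but, for `kappa < 1`,
#' lower plasma levels — the same variant is a positive instrument for
#' intake and a negative one for plasma.
#'
#' @param n Cohort size.
#' @param loci A data frame with columns `eaf` (allele frequency in
#'   (0,1)) and `delta` (per-allele effect on log clearance). Defaults
#'   to two loci with frequencies 0.36 and 0.73, matching the caffeine
#'   instruments' allele frequencies, and clearance effects 0.15 and
#'   0.20.
#' @param kappa Behavioral compensation strength in `[0, 1]`: 0 = no
#'   titration, 1 = full titration to constant plasma exposure.
#' @param gamma_p Outcome effect per unit log plasma caffeine.
#' @param gamma_i Outcome effect per unit log caffeine intake.
#' @param sd_c,sd_i,sd_y Noise SDs (> 0) for clearance, intake, and
#'   outcome.
#' @param mu Baseline log intake.
#' @param seed Optional integer seed (bit-reproducible output).
#' @return A `cohort_sim` object: list with `genotypes` (n x L dosage
#'   matrix), `data` (tibble with `log_clearance`, `log_intake`,
#'   `log_plasma`, `outcome`), and `config`.
#' @export
sim_cohort <- function(n,
                       loci = tibble::tibble(eaf = c(0.36, 0.73),
                                             delta = c(0.15, 0.20)),
                       kappa = 0.5, gamma_p = -0.2, gamma_i = 0,
                       sd_c = 0.3, sd_i = 0.3, sd_y = 1,
                       mu = 0, seed = NULL) {
  loci <- tibble::as_tibble(loci)
  stopifnot(n >= 2, all(c("eaf", "delta") %in% names(loci)),
            kappa >= 0, kappa <= 1,
            sd_c > 0, sd_i > 0, sd_y > 0)
  if (any(loci$eaf <= 0 | loci$eaf >= 1)) {
    abort("locus eafs must lie strictly in (0, 1)",
          class = "caffemr_validation_error")
  }
  L <- nrow(loci)
  gen <- function(s, expr) {
    if (is.null(seed)) expr() else withr::with_seed(sub_seed(seed, s), expr())
  }
  g <- gen(1, function() {
    matrix(rbinom(n * L, 2, rep(loci$eaf, each = n)), nrow = n, ncol = L)
  })
  e_c <- gen(2, function() rnorm(n, 0, sd_c))
  e_i <- gen(3, function() rnorm(n, 0, sd_i))
  e_y <- gen(4, function() rnorm(n, 0, sd_y))
  log_clearance <- as.vector(g %*% loci$delta) + e_c
  log_intake <- mu + kappa * log_clearance + e_i
  log_plasma <- log_intake - log_clearance
  outcome <- gamma_p * log_plasma + gamma_i * log_intake + e_y
  colnames(g) <- sprintf("locus%d", seq_len(L))
  structure(list(
    genotypes = g,
    data = tibble::tibble(log_clearance = log_clearance,
                          log_intake = log_intake,
                          log_plasma = log_plasma,
                          outcome = outcome),
    config = list(n = n, loci = loci, kappa = kappa, gamma_p = gamma_p,
                  gamma_i = gamma_i, sd_c = sd_c, sd_i = sd_i, sd_y = sd_y,
                  mu = mu, seed = seed)
  ), class = "cohort_sim")
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat(sprintf("Metabolizer-compensation cohort: n = %d, %d loci, kappa = %g\n",
              x$config$n, nrow(x$config$loci), x$config$kappa))
  invisible(x)
}

#' Run a per-locus GWAS on a simulated cohort
#'
#' Simple linear regression of the chosen trait on allele dosage, one
#' locus at a time, within a subsample — pass disjoint subsamples for
#' the exposure and outcome GWAS to emulate the two-sample design.
#' Monomorphic loci in the subsample are dropped with a message.
#'
#' @param sim A `cohort_sim` from [sim_cohort()].
#' @param trait `"log_plasma"`, `"log_intake"`, or `"outcome"`.
#' @param subsample Integer indices of individuals to use (default
#'   all).
#' @return An association tibble (alleles are synthetic placeholders
#'   `A`/`G`; `eaf` is the sample dosage frequency).
#' @export
cohort_gwas <- function(sim, trait = c("log_plasma", "log_intake", "outcome"),
                        subsample = NULL) {
  trait <- match.arg(trait)
  stopifnot(inherits(sim, "cohort_sim"))
  idx <- subsample %||% seq_len(nrow(sim$genotypes))
  if (length(idx) < 3) {
    abort("subsample must contain at least 3 individuals",
          class = "caffemr_usage_error")
  }
  y <- sim$data[[trait]][idx]
  n <- length(idx)
  rows <- purrr::map_dfr(seq_len(ncol(sim$genotypes)), function(l) {
    g <- sim$genotypes[idx, l]
    vg <- var(g)
    if (vg == 0) {
      inform(sprintf("locus%d monomorphic in subsample; dropped", l))
      return(NULL)
    }
    beta <- cov(g, y) / vg
    resid <- y - mean(y) - beta * (g - mean(g))
    se <- sqrt(sum(resid^2) / (n - 2) / ((n - 1) * vg))
    tibble::tibble(
      rsid = colnames(sim$genotypes)[l],
      effect_allele = "A", other_allele = "G",
      beta = beta, se = se,
      pvalue = p_from_z(beta, se),
      eaf = mean(g) / 2, n = n,
      gene_label = colnames(sim$genotypes)[l]
    )
  })
  if (nrow(rows) == 0) {
    abort("all loci monomorphic in subsample",
          class = "caffemr_no_instruments_error")
  }
  association_table(rows, trait_id = trait, trait_type = "continuous",
                    strict = TRUE)
}

#' Closed-form MR estimands under the compensation model
#'
#' Under [sim_cohort()]'s generative model, a clearance allele with
#' effect `delta` shifts log plasma by `delta (kappa - 1)`, log intake
#' by `delta kappa`, and the outcome by
#' `delta (gamma_p (kappa - 1) + gamma_i kappa)`. The Wald ratio
#' therefore converges, independently of `delta`, to
#' `gamma_p + gamma_i kappa/(kappa - 1)` when instrumenting plasma and
#' to `gamma_p (kappa - 1)/kappa + gamma_i` when instrumenting intake.
#' With `gamma_i = 0` these are `gamma_p` and
#' `gamma_p (kappa - 1)/kappa`: opposite signs for `0 < kappa < 1`,
#' the qualitative pattern seen when plasma-caffeine and
#' caffeine-intake analyses of the same kidney trait disagree.
#'
#' @param kappa Compensation strength in `(0, 1)`; at the boundary the
#'   corresponding instrument is null (weak) and the estimand is
#'   undefined (`NaN` with a warning).
#' @param gamma_p,gamma_i Outcome effects per unit log plasma / log
#'   intake.
#' @return A one-row tibble with `plasma_mr` and `intake_mr`.
#' @export
#' @examples
#' expected_mr_estimates(kappa = 0.5, gamma_p = -0.2, gamma_i = 0)
expected_mr_estimates <- function(kappa, gamma_p, gamma_i) {
  stopifnot(kappa >= 0, kappa <= 1)
  plasma_mr <- if (kappa == 1) {
    warn("kappa = 1: genotype has no effect on plasma; plasma-instrumented estimand undefined")
    NaN
  } else {
    gamma_p + gamma_i * kappa / (kappa - 1)
  }
  intake_mr <- if (kappa == 0) {
    warn("kappa = 0: genotype has no effect on intake; intake-instrumented estimand undefined")
    NaN
  } else {
    gamma_p * (kappa - 1) / kappa + gamma_i
  }
  tibble::tibble(plasma_mr = plasma_mr, intake_mr = intake_mr)
}

#' Kidney phenotype derivations
#'
#' The standard phenotype constructions for kidney-trait GWAS:
#' blood urea nitrogen (mg/dL) is blood urea (mg/dL) times 2.8;
#' the urinary albumin-to-creatinine ratio (mg/g) is
#' `100 * albumin (mg/L) / creatinine (mg/dL)`; and estimated
#' glomerular filtration rate is winsorized to
#' `[15, 200] mL/min/1.73m^2` before natural-log transformation.
#'
#' @param urea_mgdl Blood urea in mg/dL.
#' @param albumin_mgL Urinary albumin in mg/L.
#' @param creatinine_mgdl Urinary creatinine in mg/dL.
#' @param egfr Estimated GFR in mL/min/1.73m^2.
#' @return A tibble with `bun`, `uacr`, `log_egfr_winsorized` (columns
#'   present for the inputs supplied). All inputs must be positive.
#' @export
#' @examples
#' derive_phenotypes(urea_mgdl = 10, albumin_mgL = 30,
#'                   creatinine_mgdl = 100, egfr = 250)
derive_phenotypes <- function(urea_mgdl = NULL, albumin_mgL = NULL,
                              creatinine_mgdl = NULL, egfr = NULL) {
  check_pos <- function(x, nm) {
    if (!is.null(x) && (any(!is.finite(x)) || any(x <= 0))) {
      abort(paste0(nm, " must be positive and finite"),
            class = "caffemr_validation_error")
    }
  }
  check_pos(urea_mgdl, "urea_mgdl")
  check_pos(albumin_mgL, "albumin_mgL")
  check_pos(creatinine_mgdl, "creatinine_mgdl")
  check_pos(egfr, "egfr")
  if (xor(is.null(albumin_mgL), is.null(creatinine_mgdl))) {
    abort("albumin_mgL and creatinine_mgdl must be supplied together",
          class = "caffemr_usage_error")
  }
  out <- list()
  if (!is.null(urea_mgdl)) out$bun <- 2.8 * urea_mgdl
  if (!is.null(albumin_mgL)) out$uacr <- 100 * albumin_mgL / creatinine_mgdl
  if (!is.null(egfr)) out$log_egfr_winsorized <- log(pmin(pmax(egfr, 15), 200))
  if (length(out) == 0) {
    abort("supply at least one input", class = "caffemr_usage_error")
  }
  tibble::as_tibble(out)
}
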