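# Shared fixture builders for the test suite. All fixtures are built in
# code; no binary data.

# A valid association tibble with k random non-palindromic SNVs.
random_assoc_table <- function(k = 5, trait_id = "trait", seed = NULL) {
  build <- function() {
    pairs <- list(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                  c("G", "A"), c("C", "T"))
    idx <- sample(seq_along(pairs), k, replace = TRUE)
    tibble::tibble(
      rsid = sprintf("rs%05d", sample.int(99999, k)),
      effect_allele = vapply(pairs[idx], `[`, character(1), 1),
      other_allele = vapply(pairs[idx], `[`, character(1), 2),
      beta = rnorm(k, 0, 0.2),
      se = runif(k, 0.01, 0.1),
      pvalue = runif(k, 1e-12, 1),
      eaf = runif(k, 0.05, 0.95),
      n = sample(1000:100000, k),
      gene_label = sample(c("AHR", "CYP1A2"), k, replace = TRUE)
    )
  }
  df <- if (is.null(seed)) build() else withr::with_seed(seed, build())
  association_table(df, trait_id = trait_id, trait_type = "continuous")
}

# Swap effect/other alleles of selected rows and negate beta, flip eaf —
# the same association reported against the opposite allele.
swap_alleles <- function(x, rows = seq_len(nrow(x))) {
  ea <- x$effect_allele[rows]
  x$effect_allele[rows] <- x$other_allele[rows]
  x$other_allele[rows] <- ea
  x$beta[rows] <- -x$beta[rows]
  x$eaf[rows] <- 1 - x$eaf[rows]
  x
}

# Recode selected rows onto the complementary strand (labels only).
strand_flip_alleles <- function(x, rows = seq_len(nrow(x))) {
  comp <- function(a) chartr("ACGT", "TGCA", a)
  x$effect_allele[rows] <- comp(x$effect_allele[rows])
  x$other_allele[rows] <- comp(x$other_allele[rows])
  x
}

# Build an outcome table from an exposure table with outcome betas
# theta * beta_x plus optional noise, and given outcome SEs.
outcome_from_exposure <- function(exposure, theta, se_out = 0.01,
                                  noise_sd = 0, trait_id = "outcome_sim") {
  out <- exposure
  out$beta <- theta * exposure$beta + rnorm(nrow(exposure), 0, noise_sd)
  out$se <- rep_len(se_out, nrow(exposure))
  out$pvalue <- pmax(2 * pnorm(-abs(out$beta / out$se)),
                     .Machine$double.xmin)
  association_table(out, trait_id = trait_id, trait_type = "continuous")
}
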