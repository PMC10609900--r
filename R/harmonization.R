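#' Normalize allele representation of variant associations
#'
#' Uppercases both alleles and validates that each is a single base
#' A/C/G/T. No reordering is performed; the operation is idempotent.
#'
#' @param x An association tibble (or any data frame with
#'   `effect_allele` and `other_allele` columns).
#' @return `x` with normalized alleles.
#' @export
normalize_variant <- function(x) {
  x <- tibble::as_tibble(x)
  x$effect_allele <- toupper(as.character(x$effect_allele))
  x$other_allele <- toupper(as.character(x$other_allele))
  bad <- !(x$effect_allele %in% c("A", "C", "G", "T")) |
    !(x$other_allele %in% c("A", "C", "G", "T"))
  if (any(bad)) {
    abort(paste0("non-ACGT allele(s) in row(s): ",
                 paste(which(bad), collapse = ", ")),
          class = "caffemr_validation_error")
  }
  x
}

complement_base <- function(a) chartr("ACGT", "TGCA", a)

is_palindromic <- function(a1, a2) a1 == complement_base(a2)

#' Harmonize one exposure/outcome association pair
#'
#' Places the exposure and outcome associations for the same variant on
#' a common effect allele. Identical allele pairs in the same order
#' need no action; a swapped pair negates the outcome beta and reflects
#' its frequency (`swap_flip`); a complementary-strand representation
#' is recoded first (`strand_flip`, `strand_flip_and_swap`).
#' Palindromic variants (A/T or C/G) cannot be oriented from alleles
#' alone: under `palindrome_policy = "drop"` they are dropped, under
#' `"infer_by_eaf"` they are oriented by comparing the two effect-allele
#' frequencies, and dropped when either frequency lies within
#' `eaf_ambiguity_band` of 0.5 (or is missing). Incompatible allele
#' sets are dropped with reason `allele_mismatch`.
#'
#' @param exposure,outcome One-row association tibbles for the same
#'   rsid.
#' @param palindrome_policy `"infer_by_eaf"` (default) or `"drop"`.
#' @param eaf_ambiguity_band Half-width around 0.5 within which a
#'   palindromic variant's frequency is considered uninformative
#'   (default 0.08).
#' @return A one-row tibble with columns `rsid`, `effect_allele`,
#'   `other_allele`, `beta_exposure`, `se_exposure`, `beta_outcome`,
#'   `se_outcome`, `eaf_exposure`, `eaf_outcome`, `action`,
#'   `drop_reason`. `action` is one of `none`, `swap_flip`,
#'   `strand_flip`, `strand_flip_and_swap`, `dropped`.
#' @export
#' @examples
#' exp <- association_table(data.frame(
#'   rsid = "rs4410790", effect_allele = "T", other_allele = "C",
#'   beta = 0.109, se = 0.015, pvalue = 1.8e-10, eaf = 0.36
#' ))
#' out <- association_table(data.frame(
#'   rsid = "rs4410790", effect_allele = "C", other_allele = "T",
#'   beta = 0.01, se = 0.002, pvalue = 1e-6, eaf = 0.62
#' ))
#' harmonize_pair(exp, out) # action "swap_flip", beta_outcome -0.01
harmonize_pair <- function(exposure, outcome,
                           palindrome_policy = c("infer_by_eaf", "drop"),
                           eaf_ambiguity_band = 0.08) {
  palindrome_policy <- match.arg(palindrome_policy)
  exposure <- normalize_variant(exposure)
  outcome <- normalize_variant(outcome)
  if (nrow(exposure) != 1 || nrow(outcome) != 1) {
    abort("harmonize_pair() expects one-row tables; use harmonize() for tables",
          class = "caffemr_usage_error")
  }
  if (!identical(exposure$rsid, outcome$rsid)) {
    abort(paste0("rsid mismatch: ", exposure$rsid, " vs ", outcome$rsid),
          class = "caffemr_usage_error")
  }

  ex_ea <- exposure$effect_allele
  ex_oa <- exposure$other_allele
  out_ea <- outcome$effect_allele
  out_oa <- outcome$other_allele

  res <- tibble::tibble(
    rsid = exposure$rsid,
    effect_allele = ex_ea,
    other_allele = ex_oa,
    beta_exposure = exposure$beta,
    se_exposure = exposure$se,
    beta_outcome = outcome$beta,
    se_outcome = outcome$se,
    eaf_exposure = exposure$eaf %||% NA_real_,
    eaf_outcome = outcome$eaf %||% NA_real_,
    action = "none",
    drop_reason = NA_character_
  )
  drop <- function(reason) {
    res$action <- "dropped"
    res$drop_reason <- reason
    res
  }
  flip_outcome <- function(res) {
    res$beta_outcome <- -res$beta_outcome
    if (!is.na(res$eaf_outcome)) res$eaf_outcome <- 1 - res$eaf_outcome
    res
  }

  if (is_palindromic(ex_ea, ex_oa)) {
    # Outcome alleles must be the same palindromic pair (possibly reversed);
    # anything else is a mismatch.
    if (!setequal(c(out_ea, out_oa), c(ex_ea, ex_oa))) {
      return(drop("allele_mismatch"))
    }
    if (palindrome_policy == "drop") {
      return(drop("palindromic"))
    }
    eaf_x <- res$eaf_exposure
    eaf_y <- res$eaf_outcome
    if (is.na(eaf_x) || is.na(eaf_y)) {
      return(drop("palindromic_missing_eaf"))
    }
    # Alleles cannot resolve strand for palindromes; orient by which
    # side of 0.5 each cohort's frequency falls. First match the
    # outcome's labels to the exposure's, then let frequency agreement
    # decide whether a strand flip (which, for a palindrome, swaps the
    # alleles again) is additionally needed.
    labels_swapped <- out_ea != ex_ea
    eaf_y_matched <- if (labels_swapped) 1 - eaf_y else eaf_y
    if (abs(eaf_x - 0.5) < eaf_ambiguity_band ||
        abs(eaf_y_matched - 0.5) < eaf_ambiguity_band) {
      return(drop("palindromic_ambiguous_eaf"))
    }
    same_side <- (eaf_x - 0.5) * (eaf_y_matched - 0.5) > 0
    if (xor(labels_swapped, !same_side)) res <- flip_outcome(res)
    res$action <- if (labels_swapped && same_side) {
      "swap_flip"
    } else if (!labels_swapped && !same_side) {
      "strand_flip_and_swap"
    } else if (labels_swapped && !same_side) {
      "strand_flip"
    } else {
      "none"
    }
    return(res)
  }

  if (out_ea == ex_ea && out_oa == ex_oa) {
    res$action <- "none"
  } else if (out_ea == ex_oa && out_oa == ex_ea) {
    res <- flip_outcome(res)
    res$action <- "swap_flip"
  } else if (complement_base(out_ea) == ex_ea &&
             complement_base(out_oa) == ex_oa) {
    res$action <- "strand_flip"
  } else if (complement_base(out_ea) == ex_oa &&
             complement_base(out_oa) == ex_ea) {
    res <- flip_outcome(res)
    res$action <- "strand_flip_and_swap"
  } else {
    res <- drop("allele_mismatch")
  }
  res
}

#' Harmonize exposure and outcome association tables
#'
#' Pairs every rsid present in both tables via [harmonize_pair()] and
#' compiles an audit of actions taken, drop reasons, instruments
#' missing from the outcome table (no proxy search is attempted), and
#' post-orientation frequency discrepancies exceeding `freq_warn`.
#'
#' @param exposure,outcome Association tibbles.
#' @inheritParams harmonize_pair
#' @param freq_warn Absolute effect-allele frequency difference, after
#'   orientation, above which a pair is flagged in the audit
#'   (default 0.2). Flagged pairs are retained; cross-cohort frequency
#'   drift is common.
#' @return A tibble of harmonized pairs (one row per shared rsid,
#'   including dropped ones) with the audit as attribute `"audit"`;
#'   retrieve it with [harmonization_audit()].
#' @export
harmonize <- function(exposure, outcome,
                      palindrome_policy = c("infer_by_eaf", "drop"),
                      eaf_ambiguity_band = 0.08, freq_warn = 0.2) {
  palindrome_policy <- match.arg(palindrome_policy)
  shared <- intersect(exposure$rsid, outcome$rsid)
  missing <- setdiff(exposure$rsid, outcome$rsid)
  pairs <- purrr::map_dfr(shared, function(id) {
    harmonize_pair(exposure[exposure$rsid == id, ],
                   outcome[outcome$rsid == id, ],
                   palindrome_policy = palindrome_policy,
                   eaf_ambiguity_band = eaf_ambiguity_band)
  })
  if (length(shared) == 0) {
    pairs <- harmonized_prototype()
  }
  flagged <- pairs[!is.na(pairs$eaf_exposure) & !is.na(pairs$eaf_outcome) &
                     pairs$action != "dropped" &
                     abs(pairs$eaf_exposure - pairs$eaf_outcome) > freq_warn, ]
  audit <- list(
    n_exposure = nrow(exposure),
    n_outcome = nrow(outcome),
    n_shared = length(shared),
    n_retained = sum(pairs$action != "dropped"),
    actions = table(pairs$action),
    drop_reasons = table(pairs$drop_reason[pairs$action == "dropped"]),
    missing_from_outcome = missing,
    eaf_discrepancy = flagged[, c("rsid", "eaf_exposure", "eaf_outcome")]
  )
  if (length(missing) > 0) {
    inform(paste0("instrument(s) absent from outcome table (no proxy search): ",
                  paste(missing, collapse = ", ")))
  }
  attr(pairs, "audit") <- audit
  pairs
}

harmonized_prototype <- function() {
  tibble::tibble(
    rsid = character(), effect_allele = character(),
    other_allele = character(), beta_exposure = double(),
    se_exposure = double(), beta_outcome = double(), se_outcome = double(),
    eaf_exposure = double(), eaf_outcome = double(),
    action = character(), drop_reason = character()
  )
}

#' Retrieve the harmonization audit
#'
#' @param pairs The result of [harmonize()].
#' @return A list with input/retained counts, an action table, drop
#'   reasons, instruments missing from the outcome GWAS, and flagged
#'   frequency discrepancies.
#' @export
harmonization_audit <- function(pairs) {
  audit <- attr(pairs, "audit")
  if (is.null(audit)) {
    abort("no audit attached; pass the result of harmonize()",
          class = "caffemr_usage_error")
  }
  audit
}

#' Write a harmonization audit as JSON
#'
#' @param audit A list from [harmonization_audit()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_audit <- function(audit, path) {
  out <- audit
  out$actions <- as.list(out$actions)
  out$drop_reasons <- as.list(out$drop_reasons)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
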