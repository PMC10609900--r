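#' Build a validated association table
#'
#' An association table holds one row per variant for a single trait:
#' the per-allele effect estimate (`beta`), its standard error (`se`),
#' the two-sided p-value, and the allele pair the effect is reported
#' against. Alleles are restricted to single-base A/C/G/T (the
#' instruments in this design are all SNVs; indels are rejected) and
#' are normalized to upper case. Effect-allele frequency (`eaf`) and
#' sample size (`n`) are optional because public outcome GWAS extracts
#' often omit them; operations that need them check for themselves.
#'
#' @param x A data frame with at least `rsid`, `effect_allele`,
#'   `other_allele`, `beta`, `se`, `pvalue`; optionally `eaf`, `n`,
#'   `gene_label`, `chrom`, `pos`.
#' @param trait_id Trait identifier recorded on every row (overrides an
#'   existing `trait_id` column when supplied).
#' @param trait_type `"continuous"` or `"binary"` (binary means `beta`
#'   is a per-allele log-odds).
#' @param strict If `TRUE`, any invalid row aborts; otherwise invalid
#'   rows are dropped with a warning and row-level diagnostics are
#'   attached as the `"diagnostics"` attribute.
#'
#' @return A tibble with the canonical columns; attribute
#'   `"diagnostics"` holds a tibble of rejected rows (row index, field,
#'   problem).
#' @export
#' @examples
#' association_table(
#'   data.frame(
#'     rsid = "rs4410790", effect_allele = "t", other_allele = "c",
#'     beta = 0.109, se = 0.015, pvalue = 1.8e-10, eaf = 0.36
#'   ),
#'   trait_id = "plasma_caffeine"
#' )
association_table <- function(x, trait_id = NULL, trait_type = NULL,
                              strict = FALSE) {
  x <- tibble::as_tibble(x)
  required <- c("rsid", "effect_allele", "other_allele", "beta", "se", "pvalue")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "association table is missing required column(s): ",
      paste(missing_cols, collapse = ", ")
    ), class = "caffemr_config_error")
  }
  for (col in setdiff(assoc_cols, names(x))) {
    x[[col]] <- if (col %in% c("rsid", "trait_id", "trait_type", "gene_label")) {
      NA_character_
    } else {
      NA_real_
    }
  }
  if (!is.null(trait_id)) x$trait_id <- trait_id
  if (!is.null(trait_type)) {
    trait_type <- match.arg(trait_type, c("continuous", "binary"))
    x$trait_type <- trait_type
  }
  x$effect_allele <- toupper(as.character(x$effect_allele))
  x$other_allele <- toupper(as.character(x$other_allele))
  for (col in c("beta", "se", "pvalue", "eaf", "n")) {
    x[[col]] <- as.numeric(x[[col]])
  }

  diag <- validate_association_rows(x)
  if (nrow(diag) > 0) {
    if (strict) {
      abort(paste0(
        "invalid association rows: ",
        paste(unique(paste0("row ", diag$row, " (", diag$problem, ")")),
              collapse = "; ")
      ), class = "caffemr_validation_error")
    }
    warn(paste0(nrow(diag), " invalid value(s) in ",
                length(unique(diag$row)), " row(s) dropped; ",
                "see attr(x, 'diagnostics')"))
    x <- x[-unique(diag$row), , drop = FALSE]
  }
  dup <- x$rsid[duplicated(x$rsid)]
  if (length(dup) > 0) {
    abort(paste0("duplicate rsid(s) in association table: ",
                 paste(unique(dup), collapse = ", ")),
          class = "caffemr_validation_error")
  }
  x <- dplyr::relocate(x, dplyr::all_of(assoc_cols))
  attr(x, "diagnostics") <- diag
  x
}

# Row-level range/type checks; returns tibble(row, field, problem).
validate_association_rows <- function(x) {
  probs <- list()
  flag <- function(rows, field, problem) {
    if (any(rows)) {
      probs[[length(probs) + 1L]] <<- tibble::tibble(
        row = which(rows), field = field, problem = problem
      )
    }
  }
  flag(is.na(x$rsid) | x$rsid == "", "rsid", "missing rsid")
  ok_base <- function(a) !is.na(a) & a %in% c("A", "C", "G", "T")
  flag(!ok_base(x$effect_allele), "effect_allele", "allele not a single base A/C/G/T")
  flag(!ok_base(x$other_allele), "other_allele", "allele not a single base A/C/G/T")
  same <- ok_base(x$effect_allele) & ok_base(x$other_allele) &
    x$effect_allele == x$other_allele
  flag(same, "other_allele", "effect and other allele identical")
  flag(!is.finite(x$beta), "beta", "beta not finite")
  flag(!is.finite(x$se) | x$se <= 0, "se", "se must be > 0")
  flag(!is.finite(x$pvalue) | x$pvalue <= 0 | x$pvalue > 1,
       "pvalue", "pvalue must lie in (0, 1]")
  flag(!is.na(x$eaf) & (x$eaf < 0 | x$eaf > 1), "eaf", "eaf outside [0, 1]")
  flag(!is.na(x$n) & x$n < 2, "n", "n must be >= 2")
  if (length(probs) == 0) {
    tibble::tibble(row = integer(), field = character(), problem = character())
  } else {
    dplyr::arrange(dplyr::bind_rows(probs), .data$row)
  }
}

#' Read GWAS summary statistics from a delimited text file
#'
#' Reads the canonical tab-separated dialect (header `rsid`,
#' `effect_allele`, `other_allele`, `beta`, `se`, `pvalue`, `eaf`, `n`)
#' or any foreign dialect via `column_map`, so consortium exports with
#' different headers need no preprocessing.
#'
#' @param path Path to a delimited text file with a header row.
#' @param column_map Named character vector mapping canonical field
#'   names to the file's column names, e.g.
#'   `c(rsid = "SNP", beta = "Effect")`. Unmapped canonical fields are
#'   taken from identically named columns when present.
#' @param delimiter Field delimiter (default tab).
#' @inheritParams association_table
#' @return A validated association tibble (see [association_table()]).
#' @export
read_associations <- function(path, column_map = NULL, delimiter = "\t",
                              trait_id = NULL, trait_type = NULL,
                              strict = FALSE) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "caffemr_io_error")
  }
  raw <- readr::read_delim(path, delim = delimiter, show_col_types = FALSE,
                           progress = FALSE)
  if (!is.null(column_map)) {
    bad <- setdiff(unname(column_map), names(raw))
    if (length(bad) > 0) {
      abort(paste0("column_map refers to column(s) absent from ", path, ": ",
                   paste(bad, collapse = ", ")),
            class = "caffemr_config_error")
    }
    for (field in names(column_map)) {
      raw[[field]] <- raw[[column_map[[field]]]]
    }
    raw <- raw[, unique(c(names(column_map),
                          intersect(assoc_cols, names(raw)))), drop = FALSE]
  }
  association_table(raw, trait_id = trait_id, trait_type = trait_type,
                    strict = strict)
}

#' Write an association table to tab-separated text
#'
#' Writes the canonical header so that
#' `read_associations(write_associations(x, path))` reproduces `x`
#' field-for-field; missing optional values round-trip as empty fields.
#'
#' @param x An association tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_associations <- function(x, path) {
  x <- tibble::as_tibble(x)
  keep <- intersect(assoc_cols, names(x))
  readr::write_tsv(x[, keep, drop = FALSE], path, na = "")
  invisible(path)
}

#' Genetic instruments for the caffeine exposures
#'
#' Loads the packaged instrument set used throughout the caffeine to
#' kidney-function analysis: the strongest cis-signal at the *AHR* and
#' *CYP1A2* loci for each exposure GWAS. Plasma caffeine level is
#' instrumented by rs4410790 (*AHR*) and rs2472297 (*CYP1A2*); caffeine
#' intake by rs4410790 (*AHR*) and rs2470893 (*CYP1A2*). Note that
#' rs4410790 is reported against opposite effect alleles in the two
#' exposure GWAS (T for plasma caffeine, C for intake) -- harmonization
#' against any outcome GWAS must resolve this.
#'
#' @param exposure `"plasma_caffeine"` or `"caffeine_intake"`.
#' @return An association tibble with two rows.
#' @export
#' @examples
#' caffeine_instruments("plasma_caffeine")
caffeine_instruments <- function(exposure = c("plasma_caffeine",
                                              "caffeine_intake")) {
  exposure <- match.arg(exposure)
  path <- system.file("extdata", "caffeine_instruments.tsv",
                      package = "caffemr", mustWork = TRUE)
  all <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  association_table(all[all$exposure == exposure,
                        setdiff(names(all), "exposure")],
                    trait_id = exposure, trait_type = "continuous",
                    strict = TRUE)
}
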