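#' Define a gene region for cis-instrument assignment
#'
#' Coordinates are 1-based and inclusive; the flanking `window` extends
#' the region symmetrically, giving the closed interval
#' `[start - window, end + window]`. The default 100 kb window reflects
#' common practice for cis-instrument selection around candidate genes
#' such as *AHR* and *CYP1A2*.
#'
#' @param gene_label Gene name used to label assigned variants.
#' @param chrom Chromosome, as a string.
#' @param start,end 1-based inclusive gene boundaries, `start <= end`.
#' @param window Flanking distance in bases (default 100000).
#' @return A one-row tibble; bind rows to build a region set.
#' @export
gene_region <- function(gene_label, chrom, start, end, window = 1e5) {
  if (any(start > end)) {
    abort("gene region start must be <= end", class = "caffemr_validation_error")
  }
  if (any(window < 0)) {
    abort("window must be >= 0", class = "caffemr_validation_error")
  }
  tibble::tibble(gene_label = as.character(gene_label),
                 chrom = as.character(chrom),
                 start = as.numeric(start), end = as.numeric(end),
                 window = as.numeric(window))
}

#' Read gene regions from a BED-like TSV
#'
#' Expects four columns (chrom, start, end, gene_label), headered or
#' not. BED files use 0-based half-open starts; set
#' `zero_based = TRUE` to convert to the 1-based inclusive convention
#' used internally.
#'
#' @param path Path to a 4-column TSV.
#' @param zero_based If `TRUE`, starts are incremented by one on read.
#' @param window Flanking distance applied to every region.
#' @return A region tibble as from [gene_region()].
#' @export
read_gene_regions <- function(path, zero_based = FALSE, window = 1e5) {
  first <- readr::read_lines(path, n_max = 1)
  has_header <- grepl("chrom", first, ignore.case = TRUE)
  raw <- readr::read_tsv(path,
                         col_names = if (has_header) TRUE else
                           c("chrom", "start", "end", "gene_label"),
                         skip = 0, show_col_types = FALSE, progress = FALSE)
  if (has_header) names(raw)[1:4] <- c("chrom", "start", "end", "gene_label")
  if (zero_based) raw$start <- raw$start + 1
  gene_region(raw$gene_label, raw$chrom, raw$start, raw$end, window = window)
}

#' Assign variants to gene-region loci
#'
#' Labels each variant with the gene region whose windowed interval
#' `[start - window, end + window]` (same chromosome) contains its
#' position. Variants outside every window are labeled `"none"`. A
#' table whose `gene_label` is already fully populated passes through
#' unchanged, so pre-annotated instrument sets need no coordinates.
#'
#' @param x An association tibble; needs `chrom` and `pos` columns
#'   unless `gene_label` is pre-filled.
#' @param regions A region tibble from [gene_region()] /
#'   [read_gene_regions()].
#' @return `x` with `gene_label` filled.
#' @export
assign_loci <- function(x, regions) {
  x <- tibble::as_tibble(x)
  if ("gene_label" %in% names(x) && !anyNA(x$gene_label)) {
    return(x)
  }
  if (!all(c("chrom", "pos") %in% names(x))) {
    abort("variants lack coordinates (chrom, pos) and gene_label is not pre-filled",
          class = "caffemr_usage_error")
  }
  lab <- vapply(seq_len(nrow(x)), function(i) {
    hit <- regions$chrom == as.character(x$chrom[i]) &
      x$pos[i] >= regions$start - regions$window &
      x$pos[i] <= regions$end + regions$window
    if (sum(hit) > 1) {
      abort(paste0("variant ", x$rsid[i], " falls inside ", sum(hit),
                   " overlapping gene windows"),
            class = "caffemr_ambiguity_error")
    }
    if (any(hit)) regions$gene_label[hit] else "none"
  }, character(1))
  x$gene_label <- lab
  x
}

#' Read an LD matrix of squared correlations
#'
#' Square TSV with rsids as both header row and first column. The
#' matrix must be symmetric with unit diagonal and entries in `[0, 1]`.
#'
#' @param path Path to the TSV.
#' @return A named numeric matrix of r-squared values.
#' @export
read_ld_matrix <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  rsids <- as.character(raw[[1]])
  m <- as.matrix(raw[, -1, drop = FALSE])
  dimnames(m) <- list(rsids, colnames(raw)[-1])
  validate_ld_matrix(m)
  m
}

validate_ld_matrix <- function(m) {
  if (nrow(m) != ncol(m) || !identical(rownames(m), colnames(m))) {
    abort("LD matrix must be square with matching rsid row/column names",
          class = "caffemr_validation_error")
  }
  if (any(m < 0 | m > 1)) {
    abort("LD r-squared entries must lie in [0, 1]",
          class = "caffemr_validation_error")
  }
  if (any(abs(diag(m) - 1) > 1e-8)) {
    abort("LD matrix diagonal must be exactly 1",
          class = "caffemr_validation_error")
  }
  if (any(abs(m - t(m)) > 1e-8)) {
    abort("LD matrix must be symmetric", class = "caffemr_validation_error")
  }
  invisible(m)
}

#' Select cis-instruments: strongest signal per locus
#'
#' Drops variants with `pvalue > p_threshold`, then keeps the smallest-p
#' variant in each locus (`gene_label`). With an LD matrix, additional
#' variants at a locus are retained greedily in ascending p order when
#' their r-squared with every already-kept variant is below `r2_max`;
#' without one, exactly one variant survives per locus. Ties on p are
#' broken by larger `|beta|/se`, then lexicographic rsid, so selection
#' does not depend on input row order. Variants labeled `"none"` are
#' excluded.
#'
#' @param x An association tibble with `gene_label` populated (see
#'   [assign_loci()]).
#' @param p_threshold Significance cutoff (default genome-wide,
#'   5e-8).
#' @param ld Optional r-squared matrix covering the locus variants.
#' @param r2_max LD-pruning threshold used when `ld` is given
#'   (default 0.1).
#' @return The selected subset, ordered by locus then p.
#' @export
select_instruments <- function(x, p_threshold = 5e-8, ld = NULL,
                               r2_max = 0.1) {
  x <- tibble::as_tibble(x)
  if (!"gene_label" %in% names(x) || anyNA(x$gene_label)) {
    abort("gene_label must be populated before instrument selection",
          class = "caffemr_usage_error")
  }
  cand <- x[x$pvalue <= p_threshold & x$gene_label != "none", , drop = FALSE]
  cand <- cand[order(cand$gene_label, cand$pvalue,
                     -abs(cand$beta) / cand$se, cand$rsid), , drop = FALSE]
  if (nrow(cand) == 0) {
    abort("no instruments pass the selection criteria",
          class = "caffemr_no_instruments_error")
  }
  keep <- unlist(lapply(split(seq_len(nrow(cand)), cand$gene_label), function(idx) {
    if (is.null(ld)) {
      return(idx[1])
    }
    ids <- cand$rsid[idx]
    missing <- setdiff(ids, rownames(ld))
    if (length(missing) > 0) {
      abort(paste0("LD matrix lacks variant(s): ",
                   paste(missing, collapse = ", ")),
            class = "caffemr_config_error")
    }
    kept <- idx[1]
    for (i in idx[-1]) {
      if (all(ld[cand$rsid[i], cand$rsid[kept]] < r2_max)) {
        kept <- c(kept, i)
      }
    }
    kept
  }), use.names = FALSE)
  out <- cand[sort(keep), , drop = FALSE]
  out[order(out$gene_label, out$pvalue, out$rsid), , drop = FALSE]
}
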