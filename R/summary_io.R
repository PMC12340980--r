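# Canonical column set for GWAS summary-statistic tables. `snp`,
# `effect_allele`, `other_allele`, `beta`, `se` and `pval` are mandatory;
# the rest may be missing and are filled with NA.
.canonical_cols <- c("snp", "chrom", "pos", "effect_allele", "other_allele",
                     "eaf", "beta", "se", "pval", "n")
.mandatory_cols <- c("snp", "effect_allele", "other_allele", "beta", "se", "pval")

#' Read GWAS summary statistics from a delimited text file
#'
#' Reads a header-ed TSV or CSV (delimiter auto-detected) of per-SNP
#' association statistics, renames columns to the canonical scheme
#' (`snp, chrom, pos, effect_allele, other_allele, eaf, beta, se, pval, n`),
#' and validates every row. Rows violating the record invariants (non-positive
#' standard error, p-value outside (0, 1], malformed or identical alleles,
#' allele frequency outside \[0, 1\], duplicated SNP identifier) are dropped
#' with a warning giving the count.
#'
#' @param path path to a delimited text file with a header row.
#' @param column_map optional named character vector mapping canonical names
#'   to the file's headers, e.g. `c(snp = "rsid", pval = "p")`. Unmapped
#'   canonical columns are looked up under their own names.
#' @param delim optional delimiter; by default tab and comma are auto-detected.
#' @return validated `data.frame` with the canonical columns.
#' @export
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' write.table(
#'   data.frame(snp = c("rs1", "rs2"), effect_allele = "A", other_allele = "G",
#'              beta = c(0.1, -0.2), se = 0.05, pval = c(1e-6, 1e-4)),
#'   f, sep = "\t", quote = FALSE, row.names = FALSE)
#' read_summary_stats(f)
read_summary_stats <- function(path, column_map = NULL, delim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- data.table::fread(path, sep = delim %||% "auto", header = TRUE,
                         data.table = FALSE, showProgress = FALSE)
  if (!is.null(column_map)) {
    bad_map <- setdiff(names(column_map), .canonical_cols)
    if (length(bad_map)) stop("unknown canonical names in column_map: ",
                              paste(bad_map, collapse = ", "))
    missing_src <- setdiff(unname(column_map), names(x))
    if (length(missing_src)) stop("mapped columns absent from file: ",
                                  paste(missing_src, collapse = ", "))
    idx <- match(unname(column_map), names(x))
    names(x)[idx] <- names(column_map)
  }
  absent <- setdiff(.mandatory_cols, names(x))
  if (length(absent)) {
    stop("mandatory summary-statistic columns missing: ",
         paste(absent, collapse = ", "))
  }
  for (col in setdiff(.canonical_cols, names(x))) x[[col]] <- NA
  validate_summary_stats(x[.canonical_cols])
}

#' Validate a table of GWAS summary statistics
#'
#' Coerces a data frame to the canonical column types and drops rows that
#' violate the per-record invariants: `se > 0`, `0 < pval <= 1`, single-base
#' alleles in A/C/G/T with `effect_allele != other_allele`, `eaf` in
#' \[0, 1\] when present, and unique SNP identifiers (later duplicates are
#' dropped). A warning reports how many rows were removed.
#'
#' @param x data frame with at least the mandatory canonical columns.
#' @return validated `data.frame` with all canonical columns.
#' @export
validate_summary_stats <- function(x) {
  absent <- setdiff(.mandatory_cols, names(x))
  if (length(absent)) {
    stop("mandatory summary-statistic columns missing: ",
         paste(absent, collapse = ", "))
  }
  for (col in setdiff(.canonical_cols, names(x))) x[[col]] <- NA
  x <- x[.canonical_cols]
  x$snp <- as.character(x$snp)
  x$chrom <- as.character(x$chrom)
  x$pos <- suppressWarnings(as.integer(x$pos))
  x$effect_allele <- toupper(as.character(x$effect_allele))
  x$other_allele <- toupper(as.character(x$other_allele))
  for (col in c("eaf", "beta", "se", "pval", "n")) {
    x[[col]] <- suppressWarnings(as.numeric(x[[col]]))
  }

  ok_allele <- x$effect_allele %in% c("A", "C", "G", "T") &
    x$other_allele %in% c("A", "C", "G", "T") &
    x$effect_allele != x$other_allele
  ok <- !is.na(x$snp) &
    ok_allele &
    is.finite(x$beta) &
    is.finite(x$se) & x$se > 0 &
    is.finite(x$pval) & x$pval > 0 & x$pval <= 1 &
    (is.na(x$eaf) | (x$eaf >= 0 & x$eaf <= 1))
  ok[is.na(ok)] <- FALSE
  dup <- duplicated(x$snp)
  drop <- !ok | (ok & dup)
  if (any(drop)) {
    warning(sum(drop), " of ", nrow(x),
            " summary-statistic rows dropped (invalid fields or duplicated SNP ids)")
  }
  out <- x[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write summary statistics in the canonical TSV format
#'
#' @param x validated summary-statistic table.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# strand-ambiguous allele pair (A/T or C/G)?
is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Construct a harmonized exposure/outcome instrument set
#'
#' Low-level constructor used by [harmonize()] and by the simulation and test
#' code; vectors must be allele-aligned already, i.e. `beta_out[j]` refers to
#' the same effect allele as `beta_exp[j]`.
#'
#' @param beta_exp,se_exp per-SNP effects on the exposure and their SEs.
#' @param beta_out,se_out aligned per-SNP effects on the outcome and SEs.
#' @param snp optional SNP identifiers.
#' @param n_flipped,n_dropped_palindromic,n_dropped_mismatch harmonization
#'   bookkeeping counters.
#' @return object of class `harmonized_set`.
#' @export
harmonized_set <- function(beta_exp, se_exp, beta_out, se_out,
                           snp = paste0("snp", seq_along(beta_exp)),
                           n_flipped = 0L, n_dropped_palindromic = 0L,
                           n_dropped_mismatch = 0L) {
  J <- length(beta_exp)
  if (J < 1) stop("harmonized set must contain at least one SNP")
  stopifnot(length(se_exp) == J, length(beta_out) == J, length(se_out) == J,
            length(snp) == J)
  if (any(se_exp <= 0) || any(se_out <= 0)) stop("standard errors must be > 0")
  structure(
    list(snp = as.character(snp), beta_exp = as.numeric(beta_exp),
         se_exp = as.numeric(se_exp), beta_out = as.numeric(beta_out),
         se_out = as.numeric(se_out),
         n_flipped = as.integer(n_flipped),
         n_dropped_palindromic = as.integer(n_dropped_palindromic),
         n_dropped_mismatch = as.integer(n_dropped_mismatch)),
    class = "harmonized_set"
  )
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat("Harmonized instrument set: ", length(x$snp), " SNPs",
      " (", x$n_flipped, " flipped, ",
      x$n_dropped_palindromic, " palindromic dropped, ",
      x$n_dropped_mismatch, " allele-mismatch dropped)\n", sep = "")
  invisible(x)
}

#' @export
`[.harmonized_set` <- function(x, i) {
  harmonized_set(x$beta_exp[i], x$se_exp[i], x$beta_out[i], x$se_out[i],
                 snp = x$snp[i])
}

#' @export
length.harmonized_set <- function(x) length(x$snp)

#' Harmonize exposure and outcome summary statistics
#'
#' Matches SNPs between two validated summary-statistic tables by identifier
#' and aligns the outcome effects to the exposure's effect allele. When the
#' outcome lists the alleles in swapped order its beta is negated (and eaf
#' complemented). Palindromic (A/T, C/G) variants cannot be oriented from the
#' allele strings alone: they are kept only when both tables report an allele
#' frequency, both frequencies are informative (`min(eaf, 1 - eaf)` below
#' `palindromic_eaf_limit`), and the frequencies agree on orientation;
#' otherwise they are dropped. Variants whose alleles match in neither order
#' are dropped as mismatches.
#'
#' @param exposure,outcome validated summary-statistic tables (see
#'   [validate_summary_stats()]).
#' @param palindromic_eaf_limit allele-frequency informativeness bound for
#'   palindromic SNPs (default 0.42).
#' @return a [harmonized_set()] with flip/drop counters.
#' @export
harmonize <- function(exposure, outcome, palindromic_eaf_limit = 0.42) {
  stopifnot(palindromic_eaf_limit > 0, palindromic_eaf_limit <= 0.5)
  common <- intersect(exposure$snp, outcome$snp)
  if (!length(common)) {
    stop("no overlapping SNPs between exposure and outcome tables: ",
         "no usable instruments")
  }
  e <- exposure[match(common, exposure$snp), , drop = FALSE]
  o <- outcome[match(common, outcome$snp), , drop = FALSE]

  same <- o$effect_allele == e$effect_allele & o$other_allele == e$other_allele
  swap <- o$effect_allele == e$other_allele & o$other_allele == e$effect_allele
  matched <- same | swap
  beta_out <- ifelse(swap, -o$beta, o$beta)
  eaf_out <- ifelse(swap, 1 - o$eaf, o$eaf)

  pal <- is_palindromic(e$effect_allele, e$other_allele)
  pal_ok <- !is.na(e$eaf) & !is.na(eaf_out) &
    pmin(e$eaf, 1 - e$eaf) < palindromic_eaf_limit &
    pmin(eaf_out, 1 - eaf_out) < palindromic_eaf_limit &
    ((e$eaf < 0.5) == (eaf_out < 0.5))
  drop_pal <- matched & pal & !pal_ok
  keep <- matched & !drop_pal
  if (!any(keep)) {
    stop("all ", length(common),
         " overlapping SNPs dropped during harmonization: no usable instruments")
  }
  harmonized_set(
    beta_exp = e$beta[keep], se_exp = e$se[keep],
    beta_out = beta_out[keep], se_out = o$se[keep], snp = common[keep],
    n_flipped = sum(swap & keep),
    n_dropped_palindromic = sum(drop_pal),
    n_dropped_mismatch = sum(!matched)
  )
}
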