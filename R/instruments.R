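#' Instrument-selection thresholds
#'
#' Bundle of the four instrument-selection settings: the exposure association
#' p-value cut-off, the LD-clumping window and r-squared bound, and the
#' minimum per-SNP F statistic. Defaults are the conventional settings for
#' summary-level MR with sub-genome-wide instruments: `p < 1e-5`,
#' 10,000-kb window, r-squared 0.001, `F > 10`. Both the p and F cuts are
#' strict inequalities.
#'
#' @param p_max exposure association p-value threshold (keep `pval < p_max`).
#' @param clump_window_kb clumping window in kilobases.
#' @param clump_r2_max pairwise r-squared above which the weaker SNP of a
#'   linked pair is removed.
#' @param f_min minimum instrument-strength F statistic (keep `F > f_min`).
#' @return a list of class `selection_thresholds`.
#' @export
selection_thresholds <- function(p_max = 1e-5, clump_window_kb = 10000,
                                 clump_r2_max = 0.001, f_min = 10) {
  stopifnot(p_max > 0, p_max < 1, clump_window_kb >= 0,
            clump_r2_max >= 0, clump_r2_max <= 1, f_min >= 0)
  structure(list(p_max = p_max, clump_window_kb = clump_window_kb,
                 clump_r2_max = clump_r2_max, f_min = f_min),
            class = "selection_thresholds")
}

#' Filter summary statistics on the association p-value
#'
#' @param records validated summary-statistic table.
#' @param p_max threshold; rows with `pval < p_max` are kept (strict), in
#'   their original order.
#' @return filtered table.
#' @export
filter_by_pvalue <- function(records, p_max = 1e-5) {
  stopifnot(p_max > 0)
  records[records$pval < p_max, , drop = FALSE]
}

#' Per-SNP instrument-strength F statistic
#'
#' Computed as the squared z score, `(beta / se)^2`, the form usable whenever
#' an effect and standard error are reported.
#'
#' @param beta,se per-SNP effect(s) on the exposure and standard error(s).
#' @return numeric vector of F values.
#' @seealso [f_statistic_af()] for the variance-explained form.
#' @export
f_statistic <- function(beta, se) {
  if (any(!is.finite(se)) || any(se <= 0)) stop("se must be > 0")
  (beta / se)^2
}

#' F statistic from variance explained
#'
#' Alternative instrument-strength measure `(n - 2) * R2 / (1 - R2)` with
#' `R2 = 2 * eaf * (1 - eaf) * beta^2`, valid for a standardized continuous
#' trait; usable only when allele frequency and sample size are reported.
#'
#' @param beta per-SNP effect(s) in SD units of the trait.
#' @param eaf effect-allele frequency in (0, 1).
#' @param n GWAS sample size.
#' @return numeric vector of F values.
#' @export
f_statistic_af <- function(beta, eaf, n) {
  stopifnot(all(eaf > 0 & eaf < 1), all(n > 2))
  r2 <- 2 * eaf * (1 - eaf) * beta^2
  if (any(r2 >= 1)) stop("variance explained >= 1; effects are not on a standardized scale")
  (n - 2) * r2 / (1 - r2)
}

#' Filter instruments on strength
#'
#' @param records validated summary-statistic table.
#' @param f_min minimum F; rows with `(beta/se)^2 > f_min` are kept (strict).
#' @return filtered table.
#' @export
filter_by_f <- function(records, f_min = 10) {
  records[f_statistic(records$beta, records$se) > f_min, , drop = FALSE]
}

#' Pairwise LD lookup
#'
#' Wraps a long-format table of pairwise r-squared values (columns `snp_a`,
#' `snp_b`, `r2`) into a symmetric lookup. Absent pairs are treated as
#' unlinked (r-squared 0); `r2(a, a)` is 1 by definition.
#'
#' @param pairs data frame with columns `snp_a`, `snp_b`, `r2`.
#' @return object of class `ld_source`.
#' @export
ld_source <- function(pairs) {
  stopifnot(all(c("snp_a", "snp_b", "r2") %in% names(pairs)))
  r2 <- as.numeric(pairs$r2)
  if (any(!is.finite(r2)) || any(r2 < 0) || any(r2 > 1)) {
    stop("r2 values must lie in [0, 1]")
  }
  a <- as.character(pairs$snp_a)
  b <- as.character(pairs$snp_b)
  key <- paste(pmin(a, b), pmax(a, b), sep = "\r")
  structure(list(r2 = stats::setNames(r2, key)), class = "ld_source")
}

#' Read a pairwise LD table from file
#'
#' @param path delimited text file with columns `snp_a`, `snp_b`, `r2`.
#' @return an [ld_source()].
#' @export
read_ld_table <- function(path) {
  ld_source(data.table::fread(path, data.table = FALSE, showProgress = FALSE))
}

#' Query pairwise r-squared
#'
#' @param ld an [ld_source()], or `NULL` meaning all pairs unlinked.
#' @param a single SNP id.
#' @param b vector of SNP ids.
#' @return numeric vector of r-squared values, one per element of `b`.
#' @export
ld_r2 <- function(ld, a, b) {
  out <- rep(0, length(b))
  out[b == a] <- 1
  if (!is.null(ld)) {
    stopifnot(inherits(ld, "ld_source"))
    key <- paste(pmin(a, b), pmax(a, b), sep = "\r")
    hit <- ld$r2[key]
    out[!is.na(hit) & b != a] <- hit[!is.na(hit) & b != a]
  }
  out
}

#' Greedy LD clumping
#'
#' Standard index-SNP clumping: repeatedly take the remaining SNP with the
#' smallest p-value as an index SNP and remove every other remaining SNP on
#' the same chromosome within `clump_window_kb` of it whose r-squared with
#' the index exceeds `clump_r2_max`. The retained index SNPs are returned
#' sorted by chromosome and position, forming an approximately independent
#' instrument set.
#'
#' @param records validated summary-statistic table with non-missing `chrom`
#'   and `pos`.
#' @param ld an [ld_source()] (or `NULL` for no linkage information, in which
#'   case every pair is treated as unlinked and all SNPs are retained).
#' @param thresholds a [selection_thresholds()].
#' @return the retained rows of `records`, sorted by position.
#' @export
clump <- function(records, ld = NULL, thresholds = selection_thresholds()) {
  if (!nrow(records)) return(records)
  if (any(is.na(records$chrom)) || any(is.na(records$pos))) {
    stop("clumping requires chrom and pos for every SNP; ",
         "supply pre-clumped input otherwise")
  }
  window_bp <- thresholds$clump_window_kb * 1000
  alive <- rep(TRUE, nrow(records))
  keep <- integer(0)
  for (i in order(records$pval)) {
    if (!alive[i]) next
    keep <- c(keep, i)
    alive[i] <- FALSE
    near <- alive & records$chrom == records$chrom[i] &
      abs(records$pos - records$pos[i]) <= window_bp
    if (any(near)) {
      r2 <- ld_r2(ld, records$snp[i], records$snp[near])
      alive[which(near)[r2 > thresholds$clump_r2_max]] <- FALSE
    }
  }
  out <- records[keep, , drop = FALSE]
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove blacklisted SNPs
#'
#' Exclusion-list mechanism for instruments tied to known confounders
#' (assembled by the user, e.g. from phenome-wide lookups).
#'
#' @param records validated summary-statistic table.
#' @param blacklist character vector of SNP ids to remove.
#' @return filtered table; a message reports the number removed.
#' @export
exclude_snps <- function(records, blacklist = character()) {
  hit <- records$snp %in% blacklist
  message(sum(hit), " SNP(s) removed by exclusion list")
  records[!hit, , drop = FALSE]
}

#' Read a SNP exclusion list
#'
#' @param path plain-text file, one SNP id per line.
#' @return character vector.
#' @export
read_snp_blacklist <- function(path) {
  x <- readLines(path, warn = FALSE)
  x[nzchar(trimws(x))]
}

#' Full instrument-selection chain
#'
#' Applies, in order: the association p-value filter, greedy LD clumping,
#' the instrument-strength F filter, and the exclusion list. The chain is
#' idempotent: re-running it on its own output changes nothing.
#'
#' @param records validated summary-statistic table for the exposure.
#' @param thresholds a [selection_thresholds()].
#' @param ld optional [ld_source()]; when `NULL`, clumping is skipped (all
#'   pairs treated as unlinked). Clumping also requires `chrom`/`pos`.
#' @param blacklist character vector of SNP ids to exclude.
#' @return the selected instrument rows.
#' @export
select_instruments <- function(records, thresholds = selection_thresholds(),
                               ld = NULL, blacklist = character()) {
  out <- filter_by_pvalue(records, thresholds$p_max)
  if (nrow(out) && !is.null(ld)) out <- clump(out, ld, thresholds)
  if (nrow(out)) out <- filter_by_f(out, thresholds$f_min)
  if (length(blacklist)) out <- exclude_snps(out, blacklist)
  out
}
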