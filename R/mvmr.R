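#' Construct a multivariable harmonized set
#'
#' Container for multivariable MR input: J SNPs by K exposures, with every
#' effect aligned to a common effect allele per SNP. Requires `J >= K + 1`
#' (otherwise the regression is under-identified) and no exposure column that
#' is all zero.
#'
#' @param snp SNP identifiers (length J).
#' @param beta_exp J-by-K matrix of exposure effects (columns named by
#'   exposure).
#' @param se_exp J-by-K matrix of their standard errors, all positive.
#' @param beta_out,se_out length-J outcome effects and standard errors.
#' @return object of class `multi_harmonized_set`.
#' @export
multi_harmonized_set <- function(snp, beta_exp, se_exp, beta_out, se_out) {
  beta_exp <- as.matrix(beta_exp)
  se_exp <- as.matrix(se_exp)
  J <- nrow(beta_exp)
  K <- ncol(beta_exp)
  if (J < K + 1) {
    stop("under-identified multivariable set: ", J, " SNPs for ", K,
         " exposures (need J >= K + 1)")
  }
  stopifnot(length(snp) == J, all(dim(se_exp) == c(J, K)),
            length(beta_out) == J, length(se_out) == J)
  if (any(se_exp <= 0) || any(se_out <= 0)) stop("standard errors must be > 0")
  zero_col <- apply(beta_exp == 0, 2, all)
  if (any(zero_col)) {
    stop("exposure column(s) with all-zero effects: ",
         paste(colnames(beta_exp)[zero_col] %||% which(zero_col), collapse = ", "))
  }
  if (is.null(colnames(beta_exp))) {
    colnames(beta_exp) <- colnames(se_exp) <- paste0("exposure", seq_len(K))
  }
  structure(list(snp = as.character(snp), beta_exp = beta_exp, se_exp = se_exp,
                 beta_out = as.numeric(beta_out), se_out = as.numeric(se_out)),
            class = "multi_harmonized_set")
}

#' Assemble a multivariable MR instrument set
#'
#' Builds the joint instrument set for multivariable MR: the union of SNPs
#' passing the per-exposure p-value and F filters for at least one exposure,
#' restricted to SNPs present in every exposure table and the outcome table
#' (missing SNPs are dropped with a message), jointly clumped on the smallest
#' per-SNP p-value across exposures, and allele-aligned to the first
#' exposure's effect allele. Palindromic SNPs, which cannot be oriented
#' across tables from alleles alone, are dropped here.
#'
#' @param exposures named list of at least two validated summary-statistic
#'   tables.
#' @param outcome validated outcome summary-statistic table.
#' @param thresholds a [selection_thresholds()].
#' @param ld optional [ld_source()] for the joint clumping.
#' @param blacklist SNP ids to exclude.
#' @return a [multi_harmonized_set()].
#' @export
build_multi_set <- function(exposures, outcome,
                            thresholds = selection_thresholds(),
                            ld = NULL, blacklist = character()) {
  if (length(exposures) < 2) stop("multivariable MR needs at least 2 exposures")
  if (is.null(names(exposures))) {
    names(exposures) <- paste0("exposure", seq_along(exposures))
  }
  cand <- lapply(exposures, function(tb) {
    filter_by_f(filter_by_pvalue(tb, thresholds$p_max), thresholds$f_min)
  })
  ids <- unique(unlist(lapply(cand, function(tb) tb$snp), use.names = FALSE))
  ids <- setdiff(ids, blacklist)
  if (!length(ids)) stop("no candidate instruments for any exposure")

  present <- Reduce(`&`, lapply(exposures, function(tb) ids %in% tb$snp)) &
    ids %in% outcome$snp
  if (any(!present)) {
    message(sum(!present), " candidate SNP(s) absent from some table; dropped")
  }
  ids <- ids[present]

  ref <- exposures[[1]][match(ids, exposures[[1]]$snp), , drop = FALSE]
  p_min <- Reduce(pmin, lapply(exposures, function(tb) tb$pval[match(ids, tb$snp)]))
  clump_in <- data.frame(snp = ids, chrom = ref$chrom, pos = ref$pos,
                         pval = p_min, stringsAsFactors = FALSE)
  ids <- clump(clump_in, ld, thresholds)$snp
  ref <- exposures[[1]][match(ids, exposures[[1]]$snp), , drop = FALSE]

  align <- function(tb) {
    r <- tb[match(ids, tb$snp), , drop = FALSE]
    same <- r$effect_allele == ref$effect_allele & r$other_allele == ref$other_allele
    swap <- r$effect_allele == ref$other_allele & r$other_allele == ref$effect_allele
    list(beta = ifelse(swap, -r$beta, r$beta), se = r$se, ok = same | swap)
  }
  al_exp <- lapply(exposures, align)
  al_out <- align(outcome)
  ok <- Reduce(`&`, lapply(al_exp, `[[`, "ok")) & al_out$ok &
    !is_palindromic(ref$effect_allele, ref$other_allele)
  if (any(!ok)) {
    message(sum(!ok), " SNP(s) dropped during multivariable harmonization ",
            "(allele mismatch or palindromic)")
  }
  multi_harmonized_set(
    snp = ids[ok],
    beta_exp = do.call(cbind, stats::setNames(
      lapply(al_exp, function(a) a$beta[ok]), names(exposures))),
    se_exp = do.call(cbind, stats::setNames(
      lapply(al_exp, function(a) a$se[ok]), names(exposures))),
    beta_out = al_out$beta[ok], se_out = al_out$se[ok]
  )
}

#' Multivariable IVW estimator
#'
#' Weighted multiple regression of the outcome effects on all K exposure
#' effect columns with no intercept and weights `1 / se_out^2`, estimating
#' each exposure's direct effect conditional on the others. Coefficient SEs
#' carry multiplicative overdispersion `max(1, sqrt(Q / (J - K)))`; p-values
#' use a normal reference. With K = 1 this reduces to the univariable
#' random-effects IVW.
#'
#' @param set a [multi_harmonized_set()].
#' @return data frame of stacked `mr_estimate` rows (method `mvmr_ivw`), one
#'   per exposure, with the residual heterogeneity attached as attributes
#'   `"q"` and `"q_df"`.
#' @export
mvmr_ivw <- function(set) {
  X <- set$beta_exp
  J <- nrow(X)
  K <- ncol(X)
  qr_x <- qr(X)
  if (qr_x$rank < K) {
    stop("collinear exposure effect columns: ",
         paste(colnames(X)[qr_x$pivot[(qr_x$rank + 1):K]], collapse = ", "))
  }
  w <- 1 / set$se_out^2
  fit <- stats::lm(set$beta_out ~ 0 + X, weights = w)
  res <- stats::residuals(fit)
  q <- sum(w * res^2)
  sigma <- sqrt(q / (J - K))
  piv <- order(fit$qr$pivot)
  se <- sqrt(diag(chol2inv(qr.R(fit$qr))[piv, piv, drop = FALSE])) *
    max(1, sigma)
  coefs <- stats::coef(fit)
  out <- do.call(rbind, lapply(seq_len(K), function(k) {
    new_mr_estimate("mvmr_ivw", unname(coefs[k]), unname(se[k]), J,
                    exposure = colnames(X)[k])
  }))
  rownames(out) <- NULL
  attr(out, "q") <- q
  attr(out, "q_df") <- J - K
  out
}
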