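#' Cochran's Q heterogeneity statistic
#'
#' Weighted sum of squared deviations of the per-SNP Wald ratios from the
#' fitted causal model, with IVW weights `beta_exp^2 / se_out^2`. In the
#' `"ivw"` context the fit is the fixed-effect IVW estimate (`df = J - 1`);
#' in the `"egger"` context it is the Egger regression line (`df = J - 2`).
#' The p-value is the upper tail of the chi-square reference.
#'
#' @param set a [harmonized_set()] (at least 2 SNPs for IVW, 3 for Egger).
#' @param context `"ivw"` or `"egger"`.
#' @return list of class `q_statistic` with `q`, `df`, `pval`, `context`.
#' @export
cochrans_q <- function(set, context = c("ivw", "egger")) {
  context <- match.arg(context)
  J <- length(set$beta_exp)
  if (context == "ivw") {
    if (J < 2) stop("Cochran's Q (IVW) requires at least 2 SNPs")
    est <- mr_ivw(set, "fixed")
    q <- attr(est, "q")
    df <- J - 1
  } else {
    f <- .egger_fit(set)
    q <- f$q
    df <- f$df
  }
  structure(list(q = q, df = as.integer(df),
                 pval = stats::pchisq(q, df, lower.tail = FALSE),
                 context = context),
            class = "q_statistic")
}

#' @export
print.q_statistic <- function(x, ...) {
  cat(sprintf("Cochran's Q (%s): Q = %.3f, df = %d, p = %.4g\n",
              x$context, x$q, x$df, x$pval))
  invisible(x)
}

#' Horizontal-pleiotropy (Egger intercept) test
#'
#' Tests for directional horizontal pleiotropy via the MR-Egger intercept:
#' under valid instruments the weighted regression of outcome on exposure
#' effects passes through the origin, so a non-zero intercept signals that
#' instruments affect the outcome through pathways other than the exposure.
#' An intercept p-value above 0.05 is conventionally read as no evidence of
#' horizontal pleiotropy.
#'
#' @param set a [harmonized_set()] with at least 3 SNPs.
#' @return list with `intercept`, `intercept_se`, `pval`.
#' @export
pleiotropy_test <- function(set) {
  e <- mr_egger(set)
  list(intercept = e$intercept, intercept_se = e$intercept_se,
       pval = e$intercept_pval)
}

#' Leave-one-out sensitivity analysis
#'
#' Re-estimates the IVW causal effect with each instrument excluded in turn.
#' An exclusion is flagged when it changes the sign of the estimate or moves
#' the 95% CI across the null relative to the full-set estimate, i.e. when a
#' single SNP drives the result.
#'
#' @param set a [harmonized_set()] with at least 3 SNPs.
#' @param model IVW effects model used for every re-estimate.
#' @return data frame of class `loo_result` with one row per excluded SNP
#'   (`snp`, `beta`, `se`, `pval`, `or`, `ci_low`, `ci_high`, `flagged`); the
#'   full-set estimate is attached as attribute `"full"`.
#' @export
leave_one_out <- function(set, model = c("fixed", "random")) {
  model <- match.arg(model)
  J <- length(set$beta_exp)
  if (J < 3) stop("leave-one-out analysis requires at least 3 SNPs")
  full <- mr_ivw(set, model)
  rows <- do.call(rbind, lapply(seq_len(J), function(j) {
    est <- mr_ivw(set[-j], model)
    data.frame(snp = set$snp[j], n_snp = J - 1L, beta = est$beta, se = est$se,
               pval = est$pval, or = est$or, ci_low = est$ci_low,
               ci_high = est$ci_high, stringsAsFactors = FALSE)
  }))
  rows$flagged <- sign(rows$beta) != sign(full$beta) |
    (rows$ci_low > 1 | rows$ci_high < 1) != .excludes_null(full)
  attr(rows, "full") <- full
  class(rows) <- c("loo_result", "data.frame")
  rows
}

#' Model-selection rule for reporting
#'
#' Encodes the reporting convention used with the diagnostic pair: when the
#' IVW heterogeneity test is non-significant (`p > 0.05`) results are
#' presented under the fixed-effects model, otherwise under random effects;
#' when the Egger-intercept test is non-significant the IVW estimate is the
#' headline result, otherwise MR-Egger is reported instead.
#'
#' @param q a `q_statistic` (IVW context) or its numeric p-value.
#' @param pleio_pval p-value of the Egger-intercept test.
#' @return list with `effects_model` (`"fixed"`/`"random"`) and
#'   `headline_method` (`"ivw"`/`"egger"`).
#' @export
select_model <- function(q, pleio_pval) {
  q_pval <- if (inherits(q, "q_statistic")) q$pval else q
  stopifnot(is.numeric(q_pval), is.numeric(pleio_pval))
  list(effects_model = if (q_pval > 0.05) "fixed" else "random",
       headline_method = if (pleio_pval > 0.05) "ivw" else "egger")
}

#' Funnel-plot table
#'
#' Plot-ready per-SNP table of Wald ratios against their precision, for
#' visual asymmetry checks (the content of a funnel plot, left to the user's
#' plotting layer).
#'
#' @param set a [harmonized_set()].
#' @return data frame with `snp`, `ratio`, `se_ratio`, `precision`.
#' @export
funnel_table <- function(set) {
  se_ratio <- set$se_out / abs(set$beta_exp)
  data.frame(snp = set$snp, ratio = set$beta_out / set$beta_exp,
             se_ratio = se_ratio, precision = 1 / se_ratio,
             stringsAsFactors = FALSE)
}

#' Scatter-plot table
#'
#' Per-SNP exposure and outcome effects with the fitted IVW and Egger lines
#' attached as attribute `"lines"` (columns `method`, `intercept`, `slope`),
#' ready for a scatter plot of the instrument effects.
#'
#' @param set a [harmonized_set()] with at least 3 SNPs.
#' @return data frame with `snp`, `beta_exp`, `se_exp`, `beta_out`, `se_out`.
#' @export
scatter_table <- function(set) {
  out <- data.frame(snp = set$snp, beta_exp = set$beta_exp,
                    se_exp = set$se_exp, beta_out = set$beta_out,
                    se_out = set$se_out, stringsAsFactors = FALSE)
  egger <- mr_egger(set)
  attr(out, "lines") <- data.frame(
    method = c("ivw_fixed", "egger"),
    intercept = c(0, egger$intercept),
    slope = c(mr_ivw(set, "fixed")$beta, egger$slope$beta),
    stringsAsFactors = FALSE
  )
  out
}
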