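`%||%` <- function(a, b) if (is.null(a)) b else a

# 97.5% standard-normal quantile used for all 95% intervals
.z95 <- function() stats::qnorm(0.975)

#' Construct a single causal-effect estimate
#'
#' Internal constructor shared by all estimators. The p-value uses a standard
#' normal reference unless `df` is given, in which case a t reference is used
#' (MR-Egger). The odds ratio and its 95% CI are derived with [beta_to_or()].
#'
#' @param method estimator label.
#' @param beta,se causal log-scale effect and its standard error.
#' @param n_snp number of instruments used.
#' @param df optional degrees of freedom for a t reference.
#' @param exposure,outcome optional trait labels carried through to output.
#' @return one-row data frame of class `mr_estimate`.
#' @keywords internal
new_mr_estimate <- function(method, beta, se, n_snp, df = NULL,
                            exposure = NA_character_, outcome = NA_character_) {
  stopifnot(is.finite(beta), is.finite(se), se >= 0)
  if (se == 0) {
    pval <- if (beta == 0) 1 else 0
  } else {
    z <- beta / se
    pval <- if (is.null(df)) 2 * stats::pnorm(-abs(z)) else 2 * stats::pt(-abs(z), df = df)
  }
  ci <- beta_to_or(beta, se)
  out <- data.frame(
    method = method, exposure = exposure, outcome = outcome,
    n_snp = as.integer(n_snp), beta = beta, se = se, pval = pval,
    or = ci$or, ci_low = ci$ci_low, ci_high = ci$ci_high,
    stringsAsFactors = FALSE, row.names = NULL
  )
  class(out) <- c("mr_estimate", "data.frame")
  out
}

# does the 95% CI of a log-scale estimate exclude zero?
.excludes_null <- function(est) est$ci_low > 1 | est$ci_high < 1
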