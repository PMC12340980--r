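#' Total-effect IVW estimate with diagnostic-driven effects model
#'
#' IVW estimate of a harmonized exposure/outcome set, using the fixed-effects
#' model when the IVW heterogeneity test is non-significant (`p > 0.05`) and
#' the random-effects model otherwise. Used for the total effect and for each
#' leg of the mediation chain.
#'
#' @param set a [harmonized_set()].
#' @return one-row `mr_estimate`; the chosen model is in the `method` column
#'   and the heterogeneity statistic is attached as attribute `"q_stat"`.
#' @export
total_effect <- function(set) {
  if (length(set$beta_exp) < 2) {
    est <- mr_ivw(set, "fixed")
    return(est)
  }
  q <- cochrans_q(set, "ivw")
  model <- if (q$pval > 0.05) "fixed" else "random"
  est <- mr_ivw(set, model)
  attr(est, "q_stat") <- q
  est
}

#' Two-step mediation decomposition
#'
#' Product-of-coefficients decomposition of a total causal effect into the
#' path through one mediator and the residual direct effect. With `b1` the
#' exposure-to-mediator effect and `b2` the mediator-to-outcome effect, the
#' mediated (indirect) effect is `b1 * b2`, the direct effect is
#' `total - b1 * b2`, and the mediated proportion is
#' `100 * b1 * b2 / total` percent. The two MR legs come from separate,
#' non-overlapping GWAS samples and are treated as independent.
#'
#' Interval methods for the mediated effect:
#' * `"delta"` (default): first-order delta method,
#'   `Var(b1 b2) = b1^2 se2^2 + b2^2 se1^2`; the proportion's variance adds
#'   the total-effect term `(b1 b2 * se_total / total^2)^2`.
#' * `"montecarlo"`: resamples `b1` and `b2` from normal sampling
#'   distributions (seeded) and takes quantile intervals; the proportion
#'   interval additionally resamples the total effect.
#'
#' Proportions outside \[0, 100\] are reported as-is; a zero total effect
#' leaves the proportion undefined (`NA` with a warning).
#'
#' @param b1,se1 exposure-to-mediator effect and SE (log scale).
#' @param b2,se2 mediator-to-outcome effect and SE.
#' @param total,se_total total exposure-to-outcome effect and SE.
#' @param alpha two-sided interval level (default 0.05 for 95% CIs).
#' @param label optional chain label carried to the output row.
#' @param ci_method `"delta"` or `"montecarlo"`.
#' @param n_mc,seed Monte-Carlo resampling size and seed.
#' @return one-row data frame of class `mediation_decomposition`.
#' @export
#' @examples
#' two_step_mediation(b1 = log(1.125), se1 = 0.037, b2 = log(1.822),
#'                    se2 = 0.288, total = log(1.291), se_total = 0.094)
two_step_mediation <- function(b1, se1, b2, se2, total, se_total,
                               alpha = 0.05, label = NA_character_,
                               ci_method = c("delta", "montecarlo"),
                               n_mc = 10000L, seed = 20240101L) {
  ci_method <- match.arg(ci_method)
  stopifnot(se1 >= 0, se2 >= 0, se_total >= 0)
  z <- stats::qnorm(1 - alpha / 2)
  mediation <- b1 * b2
  direct <- total - mediation
  se_med <- sqrt(b1^2 * se2^2 + b2^2 * se1^2)

  if (total == 0) {
    warning("total effect is zero; mediated proportion undefined")
    prop <- prop_lo <- prop_hi <- NA_real_
    se_prop <- NA_real_
  } else {
    prop <- 100 * mediation / total
    se_prop <- 100 * sqrt((se_med / total)^2 + (mediation * se_total / total^2)^2)
    prop_lo <- prop - z * se_prop
    prop_hi <- prop + z * se_prop
  }
  med_lo <- mediation - z * se_med
  med_hi <- mediation + z * se_med

  if (ci_method == "montecarlo") {
    qs <- c(alpha / 2, 1 - alpha / 2)
    withr::with_seed(seed, {
      m <- stats::rnorm(n_mc, b1, se1) * stats::rnorm(n_mc, b2, se2)
      med_ci <- stats::quantile(m, qs, names = FALSE)
      if (total != 0) {
        t_draw <- stats::rnorm(n_mc, total, se_total)
        prop_ci <- stats::quantile(100 * m / t_draw, qs, names = FALSE)
        prop_lo <- prop_ci[1]
        prop_hi <- prop_ci[2]
      }
    })
    med_lo <- med_ci[1]
    med_hi <- med_ci[2]
  }

  out <- data.frame(
    label = label, total = total, se_total = se_total,
    b1 = b1, se1 = se1, b2 = b2, se2 = se2,
    direct = direct, mediation = mediation, se_mediation = se_med,
    med_ci_low = med_lo, med_ci_high = med_hi,
    proportion = prop, se_proportion = se_prop,
    prop_ci_low = prop_lo, prop_ci_high = prop_hi,
    ci_method = ci_method, stringsAsFactors = FALSE
  )
  class(out) <- c("mediation_decomposition", "data.frame")
  out
}

#' Replay mediation chains from published per-leg estimates
#'
#' Runs [two_step_mediation()] on a fixture of per-chain total, step-1 and
#' step-2 estimates (see [make_table1_fixture()]), one row per chain.
#'
#' @param fixture data frame with columns `chain`, `role`
#'   (`total`/`step1`/`step2`), `beta`, `se`.
#' @param ... further arguments passed to [two_step_mediation()].
#' @return stacked `mediation_decomposition` rows, one per chain.
#' @export
mediate_chains <- function(fixture = make_table1_fixture(), ...) {
  rows <- lapply(unique(fixture$chain), function(ch) {
    f <- fixture[fixture$chain == ch, , drop = FALSE]
    pick <- function(role) f[f$role == role, , drop = FALSE]
    t_ <- pick("total"); s1 <- pick("step1"); s2 <- pick("step2")
    stopifnot(nrow(t_) == 1, nrow(s1) == 1, nrow(s2) == 1)
    two_step_mediation(s1$beta, s1$se, s2$beta, s2$se, t_$beta, t_$se,
                       label = ch, ...)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Screen candidate mediators with two-step MR
#'
#' For each candidate mediator, estimates the exposure-to-mediator effect
#' (IVW over the exposure's instruments) and the mediator-to-outcome effect
#' (IVW over the mediator's own instruments, selected with the same
#' thresholds). Mediators with both legs significant at `alpha` are retained
#' and decomposed with [two_step_mediation()] against the exposure-to-outcome
#' total effect. A mediated path whose sign opposes the total effect is
#' reported as-is, with a negative proportion. No multiplicity correction is
#' applied by default; `fdr = TRUE` switches both legs' p-values to
#' Benjamini-Hochberg adjusted values across the mediator panel.
#'
#' @param exposure validated exposure summary-statistic table.
#' @param mediators named list of validated mediator tables.
#' @param outcome validated outcome summary-statistic table.
#' @param thresholds a [selection_thresholds()].
#' @param ld optional [ld_source()].
#' @param blacklist SNP ids to exclude.
#' @param alpha per-leg significance level for retention.
#' @param fdr use BH-adjusted per-leg p-values.
#' @param exposure_label,outcome_label labels used in the chain names.
#' @return `mediation_decomposition` rows for the retained mediators; the
#'   complete per-mediator screen (attribute `"screen"`) and the total-effect
#'   estimate (attribute `"total"`) are attached.
#' @export
screen_mediators <- function(exposure, mediators, outcome,
                             thresholds = selection_thresholds(),
                             ld = NULL, blacklist = character(),
                             alpha = 0.05, fdr = FALSE,
                             exposure_label = "exposure",
                             outcome_label = "outcome") {
  if (is.null(names(mediators))) {
    names(mediators) <- paste0("mediator_", seq_along(mediators))
  }
  exp_iv <- select_instruments(exposure, thresholds, ld, blacklist)
  if (!nrow(exp_iv)) stop("no instruments survive selection for the exposure")
  tot <- total_effect(harmonize(exp_iv, outcome))

  legs <- lapply(names(mediators), function(nm) {
    l1 <- tryCatch(total_effect(harmonize(exp_iv, mediators[[nm]])),
                   error = function(e) NULL)
    l2 <- tryCatch({
      iv <- select_instruments(mediators[[nm]], thresholds, ld, blacklist)
      if (nrow(iv) < 2) NULL else total_effect(harmonize(iv, outcome))
    }, error = function(e) NULL)
    list(nm = nm, l1 = l1, l2 = l2)
  })

  num <- function(x, fld) if (is.null(x)) NA_real_ else x[[fld]]
  screen <- data.frame(
    mediator = vapply(legs, `[[`, "", "nm"),
    b1 = vapply(legs, function(l) num(l$l1, "beta"), 0),
    se1 = vapply(legs, function(l) num(l$l1, "se"), 0),
    p1 = vapply(legs, function(l) num(l$l1, "pval"), 0),
    n_snp1 = vapply(legs, function(l) if (is.null(l$l1)) NA_integer_ else l$l1$n_snp, 0L),
    b2 = vapply(legs, function(l) num(l$l2, "beta"), 0),
    se2 = vapply(legs, function(l) num(l$l2, "se"), 0),
    p2 = vapply(legs, function(l) num(l$l2, "pval"), 0),
    n_snp2 = vapply(legs, function(l) if (is.null(l$l2)) NA_integer_ else l$l2$n_snp, 0L),
    stringsAsFactors = FALSE
  )
  p1 <- if (fdr) stats::p.adjust(screen$p1, "BH") else screen$p1
  p2 <- if (fdr) stats::p.adjust(screen$p2, "BH") else screen$p2
  screen$retained <- !is.na(p1) & !is.na(p2) & p1 < alpha & p2 < alpha

  kept <- which(screen$retained)
  out <- if (length(kept)) {
    do.call(rbind, lapply(kept, function(i) {
      two_step_mediation(screen$b1[i], screen$se1[i], screen$b2[i],
                         screen$se2[i], tot$beta, tot$se, alpha = alpha,
                         label = paste(exposure_label, screen$mediator[i],
                                       outcome_label, sep = "—"))
    }))
  } else {
    two_step_mediation(0, 0, 0, 0, 1, 0)[0, , drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "screen") <- screen
  attr(out, "total") <- tot
  out
}

#' Reverse-direction MR check
#'
#' Estimates the outcome-to-exposure effect by IVW, using instruments
#' selected from the outcome trait's own summary statistics, to check that
#' the causal direction assumed by the forward analysis is not reversed. A
#' non-significant reverse estimate (`pval > 0.05`) is flagged as
#' directionally consistent. Fewer than two surviving reverse instruments
#' make the check non-assessable (non-fatal).
#'
#' @param outcome_as_exposure validated table of the outcome trait (used here
#'   as the exposure of the reverse analysis).
#' @param exposure_as_outcome validated table of the original exposure trait.
#' @param thresholds a [selection_thresholds()].
#' @param ld optional [ld_source()].
#' @param blacklist SNP ids to exclude.
#' @return list of class `reverse_mr` with `assessable`, `estimate` (an
#'   `mr_estimate` or `NULL`), `directionally_consistent`, `reason`.
#' @export
reverse_mr <- function(outcome_as_exposure, exposure_as_outcome,
                       thresholds = selection_thresholds(),
                       ld = NULL, blacklist = character()) {
  iv <- tryCatch(select_instruments(outcome_as_exposure, thresholds, ld, blacklist),
                 error = function(e) NULL)
  if (is.null(iv) || nrow(iv) < 2) {
    return(structure(list(assessable = FALSE, estimate = NULL,
                          directionally_consistent = NA,
                          reason = "fewer than 2 reverse instruments"),
                     class = "reverse_mr"))
  }
  est <- tryCatch(total_effect(harmonize(iv, exposure_as_outcome)),
                  error = function(e) NULL)
  if (is.null(est)) {
    return(structure(list(assessable = FALSE, estimate = NULL,
                          directionally_consistent = NA,
                          reason = "reverse harmonization failed"),
                     class = "reverse_mr"))
  }
  structure(list(assessable = TRUE, estimate = est,
                 directionally_consistent = est$pval > 0.05, reason = NA_character_),
            class = "reverse_mr")
}
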