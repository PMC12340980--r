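#' Settings for bootstrap-based estimators
#'
#' The weighted-median and mode-based estimators obtain their standard errors
#' by parametric bootstrap; the mode estimators additionally need a kernel
#' bandwidth. `seed` makes the bootstrap reproducible and is applied locally
#' (the caller's RNG state is untouched).
#'
#' @param bandwidth_factor positive multiplier on the modified-Silverman
#'   bandwidth of the mode estimators (1 = default bandwidth).
#' @param n_boot number of parametric-bootstrap replicates.
#' @param seed integer seed for the bootstrap draws.
#' @return list of class `mode_settings`.
#' @export
mode_settings <- function(bandwidth_factor = 1, n_boot = 1000, seed = 20240101L) {
  stopifnot(bandwidth_factor > 0, n_boot >= 1)
  structure(list(bandwidth_factor = bandwidth_factor,
                 n_boot = as.integer(n_boot), seed = as.integer(seed)),
            class = "mode_settings")
}

#' Convert a log-scale effect to an odds ratio with 95% CI
#'
#' @param beta log-scale causal effect (log odds ratio for a binary outcome).
#' @param se its standard error (`>= 0`).
#' @return data frame with columns `or`, `ci_low`, `ci_high`, where
#'   `or = exp(beta)` and the bounds are `exp(beta -/+ z * se)` with z the
#'   97.5% normal quantile.
#' @export
#' @examples
#' beta_to_or(0.255, 0.09)
beta_to_or <- function(beta, se) {
  stopifnot(all(se >= 0))
  z <- .z95()
  data.frame(or = exp(beta), ci_low = exp(beta - z * se),
             ci_high = exp(beta + z * se))
}

#' Wald ratio for a single instrument
#'
#' Per-SNP causal estimate `beta_out / beta_exp`. The default standard error
#' is first order, `se_out / |beta_exp|`, ignoring the sampling error of the
#' exposure effect; `second_order = TRUE` adds the exposure-side term.
#'
#' @param beta_exp,se_exp SNP effect on the exposure and its SE.
#' @param beta_out,se_out SNP effect on the outcome and its SE.
#' @param second_order use the second-order SE including `se_exp`.
#' @return one-row `mr_estimate`.
#' @export
wald_ratio <- function(beta_exp, se_exp, beta_out, se_out, second_order = FALSE) {
  if (beta_exp == 0) stop("Wald ratio undefined: exposure effect is zero")
  beta <- beta_out / beta_exp
  se <- if (second_order) {
    sqrt(se_out^2 / beta_exp^2 + beta_out^2 * se_exp^2 / beta_exp^4)
  } else {
    se_out / abs(beta_exp)
  }
  new_mr_estimate("wald_ratio", beta, se, 1L)
}

#' Inverse-variance weighted estimator
#'
#' The primary two-sample MR estimator: the weighted average of per-SNP Wald
#' ratios with weights `beta_exp^2 / se_out^2`, algebraically identical to
#' weighted least squares of `beta_out` on `beta_exp` through the origin with
#' weights `1 / se_out^2`. The fixed-effect SE is `1 / sqrt(sum(w))`; the
#' random-effects (multiplicative overdispersion) SE scales it by
#' `max(1, sqrt(Q / (J - 1)))` with Q Cochran's heterogeneity statistic, so
#' the random-effects model can never be more precise than the fixed one.
#' A single-SNP set degenerates to the Wald ratio.
#'
#' @param set a [harmonized_set()].
#' @param model `"fixed"` or `"random"`.
#' @return one-row `mr_estimate`; Cochran's Q is attached as attribute `"q"`.
#' @export
mr_ivw <- function(set, model = c("fixed", "random")) {
  model <- match.arg(model)
  J <- length(set$beta_exp)
  if (all(set$beta_exp == 0)) stop("all exposure effects are zero")
  if (J == 1) return(wald_ratio(set$beta_exp, set$se_exp, set$beta_out, set$se_out))
  w <- set$beta_exp^2 / set$se_out^2
  beta <- sum(set$beta_exp * set$beta_out / set$se_out^2) / sum(w)
  se_fixed <- 1 / sqrt(sum(w))
  q <- sum((set$beta_out - beta * set$beta_exp)^2 / set$se_out^2)
  se <- if (model == "random") se_fixed * max(1, sqrt(q / (J - 1))) else se_fixed
  est <- new_mr_estimate(paste0("ivw_", model), beta, se, J)
  attr(est, "q") <- q
  est
}

# weighted Egger regression shared by mr_egger() and cochrans_q();
# orients each SNP so the exposure effect is non-negative
.egger_fit <- function(set) {
  J <- length(set$beta_exp)
  if (J < 3) stop("MR-Egger requires at least 3 SNPs")
  flip <- set$beta_exp < 0
  bx <- abs(set$beta_exp)
  by <- ifelse(flip, -set$beta_out, set$beta_out)
  w <- 1 / set$se_out^2
  fit <- stats::lm(by ~ bx, weights = w)
  res <- stats::residuals(fit)
  q <- sum(w * res^2)
  sigma <- sqrt(q / (J - 2))
  # (X' W X)^{-1} from the QR factor of sqrt(w) X
  piv <- order(fit$qr$pivot)
  cov_unscaled <- chol2inv(qr.R(fit$qr))[piv, piv, drop = FALSE]
  se <- sqrt(diag(cov_unscaled)) * max(1, sigma)
  list(coef = stats::coef(fit), se = se, q = q, df = J - 2)
}

#' MR-Egger regression
#'
#' Weighted regression of the (orientation-normalized) outcome effects on the
#' exposure effects with a free intercept and weights `1 / se_out^2`. The
#' slope estimates the causal effect under the InSIDE assumption; a non-zero
#' intercept indicates directional horizontal pleiotropy. Standard errors use
#' multiplicative overdispersion bounded below by 1, and p-values use a t
#' reference with `J - 2` degrees of freedom.
#'
#' @param set a [harmonized_set()] with at least 3 SNPs.
#' @return list of class `egger_estimate` with elements `slope` (an
#'   `mr_estimate`), `intercept`, `intercept_se`, `intercept_pval`, and the
#'   Egger heterogeneity statistic `q` with its `df`.
#' @export
mr_egger <- function(set) {
  f <- .egger_fit(set)
  J <- f$df + 2
  slope <- new_mr_estimate("egger", unname(f$coef[2]), unname(f$se[2]), J, df = f$df)
  icpt <- unname(f$coef[1])
  icpt_se <- unname(f$se[1])
  icpt_p <- if (icpt_se == 0) {
    if (icpt == 0) 1 else 0
  } else {
    2 * stats::pt(-abs(icpt / icpt_se), df = f$df)
  }
  structure(list(slope = slope, intercept = icpt, intercept_se = icpt_se,
                 intercept_pval = icpt_p, q = f$q, q_df = f$df),
            class = "egger_estimate")
}

# interpolated weighted median with the midpoint cumulative-weight convention
weighted_median_point <- function(x, w) {
  ord <- order(x)
  x <- x[ord]
  w <- w[ord] / sum(w)
  cw <- cumsum(w) - w / 2
  if (cw[1] >= 0.5) return(x[1])
  if (cw[length(cw)] <= 0.5) return(x[length(x)])
  k <- which(cw >= 0.5)[1]
  x[k - 1] + (x[k] - x[k - 1]) * (0.5 - cw[k - 1]) / (cw[k] - cw[k - 1])
}

# parametric bootstrap SE: redraw both effect vectors from their sampling
# distributions and recompute the statistic; seeded locally
.boot_se <- function(set, statistic, settings) {
  J <- length(set$beta_exp)
  withr::with_seed(settings$seed, {
    reps <- vapply(seq_len(settings$n_boot), function(i) {
      be <- stats::rnorm(J, set$beta_exp, set$se_exp)
      bo <- stats::rnorm(J, set$beta_out, set$se_out)
      statistic(be, bo)
    }, numeric(1))
    stats::sd(reps)
  })
}

#' Weighted-median estimator
#'
#' Consistent when at least half the weight comes from valid instruments.
#' Wald ratios are ordered and the estimate is the linear interpolation of
#' the ordered ratios at cumulative normalized weight 0.5 (midpoint
#' convention), with IVW weights `beta_exp^2 / se_out^2`. The SE comes from a
#' parametric bootstrap that redraws both effect vectors.
#'
#' @param set a [harmonized_set()] with at least 3 SNPs.
#' @param settings a [mode_settings()] (bootstrap size and seed).
#' @return one-row `mr_estimate`.
#' @export
mr_weighted_median <- function(set, settings = mode_settings()) {
  if (length(set$beta_exp) < 3) stop("weighted median requires at least 3 SNPs")
  point <- weighted_median_point(set$beta_out / set$beta_exp,
                                 set$beta_exp^2 / set$se_out^2)
  se <- .boot_se(set, function(be, bo) {
    weighted_median_point(bo / be, be^2 / set$se_out^2)
  }, settings)
  new_mr_estimate("weighted_median", point, se, length(set$beta_exp))
}

# kernel-density mode of the Wald ratios on a fixed 512-point grid;
# ties in the grid argmax resolve to the smaller value
mode_point <- function(x, w, bandwidth_factor = 1) {
  if (length(unique(x)) == 1L) return(x[1])
  cand <- c(stats::sd(x), stats::IQR(x) / 1.349)
  cand <- cand[cand > 0]
  h <- bandwidth_factor * 0.9 * min(cand) * length(x)^(-1 / 5)
  grid <- seq(min(x) - 3 * h, max(x) + 3 * h, length.out = 512L)
  dens <- as.vector(stats::dnorm(outer(grid, x, "-") / h) %*% (w / sum(w)))
  grid[which.max(dens)]
}

#' Mode-based estimators (simple and weighted)
#'
#' The estimate is the mode of a normal-kernel density of the per-SNP Wald
#' ratios, located by grid search over 512 points spanning the ratio range
#' plus three bandwidths. The bandwidth is the modified Silverman rule
#' `0.9 * min(sd, IQR/1.349) * J^(-1/5)` times `bandwidth_factor`. The simple
#' mode weights ratios equally; the weighted mode uses inverse-variance
#' weights `1 / s_j^2` with `s_j = se_out / |beta_exp|` the first-order ratio
#' SE. Standard errors by parametric bootstrap. If all ratios coincide the
#' common ratio is returned directly.
#'
#' @param set a [harmonized_set()] with at least 3 SNPs.
#' @param weighted use inverse-variance ratio weights.
#' @param settings a [mode_settings()].
#' @return one-row `mr_estimate` with method `simple_mode` or `weighted_mode`.
#' @export
mr_mode <- function(set, weighted = FALSE, settings = mode_settings()) {
  J <- length(set$beta_exp)
  if (J < 3) stop("mode-based estimation requires at least 3 SNPs")
  ratio_w <- function(be) if (weighted) be^2 / set$se_out^2 else rep(1, J)
  point <- mode_point(set$beta_out / set$beta_exp, ratio_w(set$beta_exp),
                      settings$bandwidth_factor)
  se <- .boot_se(set, function(be, bo) {
    mode_point(bo / be, ratio_w(be), settings$bandwidth_factor)
  }, settings)
  new_mr_estimate(if (weighted) "weighted_mode" else "simple_mode",
                  point, se, J)
}

#' Run the five standard estimators on one harmonized set
#'
#' Convenience wrapper returning a tidy, forest-plot-ready table with one row
#' per method: IVW (fixed or random effects), MR-Egger slope, weighted
#' median, simple mode and weighted mode.
#'
#' @param set a [harmonized_set()] with at least 3 SNPs.
#' @param settings a [mode_settings()].
#' @param ivw_model effects model for the IVW row.
#' @return data frame of stacked `mr_estimate` rows.
#' @export
mr_all <- function(set, settings = mode_settings(),
                   ivw_model = c("fixed", "random")) {
  ivw_model <- match.arg(ivw_model)
  rows <- rbind(
    mr_ivw(set, ivw_model),
    mr_egger(set)$slope,
    mr_weighted_median(set, settings),
    mr_mode(set, weighted = FALSE, settings = settings),
    mr_mode(set, weighted = TRUE, settings = settings)
  )
  rownames(rows) <- NULL
  rows
}
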