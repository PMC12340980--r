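# resolve a summary-stats argument that may be a path or a data frame
.as_sumstats <- function(x, column_map = NULL) {
  if (is.character(x) && length(x) == 1) {
    read_summary_stats(x, column_map = column_map)
  } else {
    validate_summary_stats(as.data.frame(x))
  }
}

#' Configuration of a full two-phase analysis run
#'
#' Bundles every input of the workflow: exposure/outcome (and optionally
#' mediator) summary statistics as file paths or data frames, the
#' instrument-selection thresholds, the bootstrap settings of the auxiliary
#' estimators, optional LD information and SNP exclusion list, and an output
#' directory for the tidy result tables.
#'
#' @param exposures named list of exposure tables or file paths.
#' @param outcome outcome table or file path.
#' @param mediators optional named list of mediator tables or file paths.
#' @param thresholds a [selection_thresholds()].
#' @param settings a [mode_settings()] (bootstrap SEs; also the run seed).
#' @param ld optional [ld_source()], pairwise-r2 data frame, or file path.
#' @param blacklist optional character vector of SNP ids or file path.
#' @param column_map optional named vector passed to [read_summary_stats()].
#' @param out_dir optional directory; when set, result tables are written as
#'   TSV files.
#' @return list of class `run_config` with all tables loaded and validated.
#' @export
run_config <- function(exposures, outcome, mediators = NULL,
                       thresholds = selection_thresholds(),
                       settings = mode_settings(), ld = NULL,
                       blacklist = NULL, column_map = NULL, out_dir = NULL) {
  if (is.null(names(exposures)) || any(!nzchar(names(exposures)))) {
    stop("exposures must be a named list")
  }
  exposures <- lapply(exposures, .as_sumstats, column_map = column_map)
  outcome <- .as_sumstats(outcome, column_map)
  if (!is.null(mediators)) {
    if (is.null(names(mediators))) {
      names(mediators) <- paste0("mediator_", seq_along(mediators))
    }
    mediators <- lapply(mediators, .as_sumstats, column_map = column_map)
  }
  if (is.character(ld)) ld <- read_ld_table(ld)
  if (is.data.frame(ld)) ld <- ld_source(ld)
  if (is.character(blacklist) && length(blacklist) == 1 && file.exists(blacklist)) {
    blacklist <- read_snp_blacklist(blacklist)
  }
  structure(list(exposures = exposures, outcome = outcome,
                 mediators = mediators, thresholds = thresholds,
                 settings = settings, ld = ld,
                 blacklist = blacklist %||% character(),
                 out_dir = out_dir),
            class = "run_config")
}

.rbind_rows <- function(lst) {
  if (length(lst)) do.call(rbind, c(lst, list(make.row.names = FALSE))) else NULL
}

.write_tsv <- function(x, dir, name) {
  if (is.null(dir) || is.null(x) || !nrow(x)) return(invisible(NULL))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.table(x, file.path(dir, name), sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

# provenance columns stamped on every emitted row
.provenance <- function(config, sel = NULL) {
  th <- config$thresholds
  data.frame(p_max = th$p_max, clump_window_kb = th$clump_window_kb,
             clump_r2_max = th$clump_r2_max, f_min = th$f_min,
             effects_model = sel$effects_model %||% NA_character_,
             headline_method = sel$headline_method %||% NA_character_)
}

#' Phase 1: exposure-wide MR with diagnostics and multivariable follow-up
#'
#' For each exposure: instrument selection, harmonization against the
#' outcome, the five estimators (IVW under the heterogeneity-selected effects
#' model, MR-Egger, weighted median, simple and weighted mode), the
#' diagnostic suite (Cochran's Q for both contexts, Egger-intercept test,
#' leave-one-out), and the reporting rule of [select_model()]. Exposures
#' whose headline estimate has `p < 0.05` are flagged positive; when two or
#' more are positive, multivariable IVW is run on them jointly. Exposures
#' with no surviving instruments are skipped with a message, not an error.
#' No multiplicity correction is applied across exposures.
#'
#' @param config a [run_config()].
#' @return (invisibly) list with `estimates`, `diagnostics`, `loo`,
#'   `snps_used`, `mvmr`, `positives`, `skipped`; the same tables are written
#'   to `config$out_dir` when set.
#' @export
run_phase1 <- function(config) {
  stopifnot(inherits(config, "run_config"))
  estimates <- list(); diagnostics <- list(); loo_all <- list()
  snps_used <- list(); skipped <- character(); positives <- character()

  for (label in names(config$exposures)) {
    iv <- tryCatch(
      select_instruments(config$exposures[[label]], config$thresholds,
                         config$ld, config$blacklist),
      error = function(e) NULL)
    if (is.null(iv) || nrow(iv) == 0) {
      message("exposure '", label, "' skipped: no instruments survive selection")
      skipped <- c(skipped, label)
      next
    }
    set <- tryCatch(harmonize(iv, config$outcome), error = function(e) NULL)
    if (is.null(set) || length(set) < 2) {
      message("exposure '", label, "' skipped: fewer than 2 harmonized instruments")
      skipped <- c(skipped, label)
      next
    }

    q_ivw <- cochrans_q(set, "ivw")
    pl <- if (length(set) >= 3) pleiotropy_test(set) else NULL
    sel <- select_model(q_ivw, pl$pval %||% 1)
    ivw_est <- mr_ivw(set, sel$effects_model)
    est <- if (length(set) >= 3) {
      egger <- mr_egger(set)
      rbind(ivw_est, egger$slope,
            mr_weighted_median(set, config$settings),
            mr_mode(set, weighted = FALSE, settings = config$settings),
            mr_mode(set, weighted = TRUE, settings = config$settings))
    } else {
      ivw_est
    }
    est$exposure <- label
    est$outcome <- "outcome"
    headline <- if (sel$headline_method == "ivw" || length(set) < 3) {
      ivw_est
    } else {
      egger$slope
    }
    if (headline$pval < 0.05) positives <- c(positives, label)

    estimates[[label]] <- cbind(est, .provenance(config, sel))
    diagnostics[[label]] <- data.frame(
      exposure = label, n_snp = length(set),
      q = q_ivw$q, q_df = q_ivw$df, q_pval = q_ivw$pval,
      egger_intercept = pl$intercept %||% NA_real_,
      intercept_se = pl$intercept_se %||% NA_real_,
      intercept_pval = pl$pval %||% NA_real_,
      effects_model = sel$effects_model,
      headline_method = sel$headline_method,
      headline_pval = headline$pval,
      positive = headline$pval < 0.05,
      n_flipped = set$n_flipped,
      n_dropped_palindromic = set$n_dropped_palindromic,
      stringsAsFactors = FALSE)
    if (length(set) >= 3) {
      loo <- leave_one_out(set, sel$effects_model)
      loo$exposure <- label
      loo_all[[label]] <- as.data.frame(loo)
    }
    snps_used[[label]] <- data.frame(
      exposure = label, snp = set$snp, beta_exp = set$beta_exp,
      se_exp = set$se_exp, beta_out = set$beta_out, se_out = set$se_out,
      stringsAsFactors = FALSE)
  }

  mvmr <- NULL
  if (length(positives) >= 2) {
    mvmr <- tryCatch({
      ms <- build_multi_set(config$exposures[positives], config$outcome,
                            config$thresholds, config$ld, config$blacklist)
      cbind(mvmr_ivw(ms), .provenance(config))
    }, error = function(e) {
      message("multivariable MR not run: ", conditionMessage(e))
      NULL
    })
  }

  out <- list(
    estimates = .rbind_rows(estimates),
    diagnostics = .rbind_rows(diagnostics),
    loo = .rbind_rows(loo_all),
    snps_used = .rbind_rows(snps_used),
    mvmr = mvmr, positives = positives, skipped = skipped
  )
  .write_tsv(out$estimates, config$out_dir, "estimates.tsv")
  .write_tsv(out$diagnostics, config$out_dir, "diagnostics.tsv")
  .write_tsv(out$loo, config$out_dir, "loo.tsv")
  .write_tsv(out$snps_used, config$out_dir, "snps_used.tsv")
  .write_tsv(out$mvmr, config$out_dir, "mvmr.tsv")
  invisible(out)
}

#' Format decompositions as the standard mediation results table
#'
#' Renames the columns of stacked `mediation_decomposition` rows to the
#' conventional reporting schema: chain label, total effect, the two step
#' effects, direct effect, mediated effect with CI, and mediated proportion
#' (percent) with CI.
#'
#' @param dec rows from [two_step_mediation()]/[mediate_chains()]/
#'   [screen_mediators()].
#' @return data frame in the reporting schema.
#' @export
format_mediation_table <- function(dec) {
  data.frame(
    chain = dec$label, total_effect = dec$total,
    direct_effect_1 = dec$b1, direct_effect_2 = dec$b2,
    direct_effect = dec$direct, mediation_effect = dec$mediation,
    mediation_ci_low = dec$med_ci_low, mediation_ci_high = dec$med_ci_high,
    mediated_proportion_pct = dec$proportion,
    proportion_ci_low = dec$prop_ci_low,
    proportion_ci_high = dec$prop_ci_high,
    stringsAsFactors = FALSE
  )
}

#' Phase 2: reverse-direction checks and mediator screening
#'
#' For each positive exposure from phase 1: a reverse-direction MR check
#' (outcome as exposure), then the two-step mediation screen across all
#' configured mediators, emitting one decomposition row per retained
#' exposure-mediator-outcome chain in the standard reporting schema. Skipped
#' with a message when no mediators are configured.
#'
#' @param config a [run_config()] with mediators.
#' @param positives exposure labels to carry into mediation (default: all
#'   configured exposures; normally the `positives` element of
#'   [run_phase1()]'s result).
#' @return (invisibly) list with `mediation` (reporting-schema table),
#'   `decompositions` (raw rows), `screens` (per-exposure screen tables) and
#'   `reverse` (per-exposure reverse-MR summary); written to
#'   `config$out_dir` when set.
#' @export
run_phase2 <- function(config, positives = names(config$exposures)) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$mediators) || !length(config$mediators)) {
    message("no mediators configured; phase 2 skipped")
    return(invisible(NULL))
  }
  dec_all <- list(); screens <- list(); rev_rows <- list()
  for (label in positives) {
    rev <- reverse_mr(config$outcome, config$exposures[[label]],
                      config$thresholds, config$ld, config$blacklist)
    rev_rows[[label]] <- data.frame(
      exposure = label, assessable = rev$assessable,
      reverse_beta = if (rev$assessable) rev$estimate$beta else NA_real_,
      reverse_pval = if (rev$assessable) rev$estimate$pval else NA_real_,
      directionally_consistent = rev$directionally_consistent,
      stringsAsFactors = FALSE)
    dec <- screen_mediators(config$exposures[[label]], config$mediators,
                            config$outcome, config$thresholds, config$ld,
                            config$blacklist, exposure_label = label,
                            outcome_label = "outcome")
    screens[[label]] <- cbind(exposure = label, attr(dec, "screen"))
    if (nrow(dec)) dec_all[[label]] <- as.data.frame(dec)
  }
  decompositions <- .rbind_rows(dec_all)
  out <- list(
    mediation = if (!is.null(decompositions)) format_mediation_table(decompositions),
    decompositions = decompositions,
    screens = .rbind_rows(screens),
    reverse = .rbind_rows(rev_rows)
  )
  .write_tsv(out$mediation, config$out_dir, "mediation.tsv")
  .write_tsv(out$screens, config$out_dir, "mediator_screen.tsv")
  .write_tsv(out$reverse, config$out_dir, "reverse_mr.tsv")
  invisible(out)
}
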