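# non-palindromic ordered allele pairs (effect, other); palindromic pairs
# are A/T and C/G
.nonpal_pairs <- matrix(c("A", "C", "A", "G", "C", "A", "C", "T",
                          "G", "A", "G", "T", "T", "C", "T", "G"),
                        ncol = 2, byrow = TRUE)
.pal_pairs <- matrix(c("A", "T", "T", "A", "C", "G", "G", "C"),
                     ncol = 2, byrow = TRUE)

#' Configuration of a synthetic three-source GWAS scenario
#'
#' Describes a structural exposure-mediator-outcome model and the three
#' independent GWAS that measure it. Per SNP j among the exposure's J
#' instruments, the true per-allele effects are `gamma_j` on the exposure,
#' `b1 * gamma_j` on the (focal) mediator, and
#' `(d + b1 * b2) * gamma_j + alpha_j` on the outcome, where `alpha_j` is a
#' direct (pleiotropic) SNP-outcome effect. Each mediator additionally
#' carries `n_snp_med` instruments of its own with effects
#' `delta_j ~ N(0, delta_sd^2)` on the mediator and `b2 * delta_j` on the
#' outcome (zero for null mediators); without such mediator-specific
#' instruments the mediator-to-outcome leg of two-step MR would not be
#' identifiable. Null mediators have no causal path (`b1 = b2 = 0`) but keep
#' their own instruments, so screening against them has well-defined type-I
#' behaviour.
#'
#' Defaults emulate a trace-element/microbiome/disease design: a moderately
#' sized continuous-exposure GWAS, a ~7,700-sample mediator GWAS, a large
#' binary-outcome GWAS, 20 instruments per trait, and the worked-example
#' copper-chain effects (`b1 = 0.118`, `b2 = 0.600`, `d = 0.185`).
#'
#' @param n_snp number J of exposure instruments (>= 3).
#' @param n_exp,n_med,n_out GWAS sample sizes (>= 100).
#' @param maf_range minor-allele-frequency interval within (0, 0.5].
#' @param gamma_sd SD of the true instrument effects on the exposure.
#' @param b1 true exposure-to-mediator effect (focal mediator).
#' @param b2 true mediator-to-outcome effect (log-odds scale).
#' @param d true direct exposure-to-outcome effect.
#' @param pleiotropy_mean,pleiotropy_sd mean and SD of the direct SNP-outcome
#'   effects `alpha_j` (0/0 = no pleiotropy).
#' @param n_null_mediators number of additional no-path mediator traits.
#' @param n_snp_med mediator-specific instruments per mediator.
#' @param delta_sd SD of the mediator-specific instrument effects.
#' @param include_palindromic also sample strand-ambiguous allele pairs
#'   (default `FALSE`), for exercising harmonization.
#' @param seed integer seed; the whole simulation is a deterministic
#'   function of the configuration.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_snp = 20L, n_exp = 64979L, n_med = 7738L,
                              n_out = 184190L, maf_range = c(0.05, 0.5),
                              gamma_sd = 0.05, b1 = 0.118, b2 = 0.600,
                              d = 0.185, pleiotropy_mean = 0,
                              pleiotropy_sd = 0, n_null_mediators = 0L,
                              n_snp_med = n_snp, delta_sd = 0.25,
                              include_palindromic = FALSE, seed = 20240101L) {
  stopifnot(n_snp >= 3, n_snp_med >= 3,
            n_exp >= 100, n_med >= 100, n_out >= 100,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            gamma_sd > 0, delta_sd >= 0, pleiotropy_sd >= 0,
            n_null_mediators >= 0)
  structure(list(n_snp = as.integer(n_snp), n_exp = as.integer(n_exp),
                 n_med = as.integer(n_med), n_out = as.integer(n_out),
                 maf_range = maf_range, gamma_sd = gamma_sd,
                 b1 = b1, b2 = b2, d = d,
                 pleiotropy_mean = pleiotropy_mean,
                 pleiotropy_sd = pleiotropy_sd,
                 n_null_mediators = as.integer(n_null_mediators),
                 n_snp_med = as.integer(n_snp_med), delta_sd = delta_sd,
                 include_palindromic = isTRUE(include_palindromic),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate GWAS summary statistics for an exposure/mediator/outcome triplet
#'
#' Generates summary statistics directly (no individual-level genotypes):
#' per SNP, the standard error in a study of n samples is the analytic
#' per-allele regression SE for a unit-variance trait,
#' `1 / sqrt(2 p (1 - p) n)` with p the allele frequency, and the observed
#' beta is drawn from a normal around the true effect with that SE,
#' independently in each study (two-sample designs have no overlapping
#' samples). P-values are two-sided normal. Every trait table reports all
#' SNPs (exposure instruments plus every mediator's instruments) in the
#' canonical summary-statistic format with consistent allele orientation.
#'
#' @param config a [simulation_config()].
#' @return list of class `mr_simulation` with elements `exposure` (table),
#'   `mediators` (named list of tables; the focal mediator first, then any
#'   null mediators), `outcome` (table), `truth` (a `simulation_truth`:
#'   generating parameters, per-SNP effects, instrument id lists and the
#'   implied total/mediated effects and mediated proportion), and `config`.
#' @export
simulate_triplet <- function(config = simulation_config()) {
  cfg <- config
  stopifnot(inherits(cfg, "simulation_config"))
  withr::with_seed(cfg$seed, {
    n_med_traits <- 1L + cfg$n_null_mediators
    J <- cfg$n_snp
    Jm <- cfg$n_snp_med
    n_total <- J + n_med_traits * Jm

    snp <- sprintf("rs%06d", seq_len(n_total))
    chrom <- as.character(rep_len(1:22, n_total))
    # 25-Mb spacing keeps SNPs sharing a chromosome outside any clumping
    # window of up to 10 Mb
    occ <- stats::ave(seq_len(n_total), chrom, FUN = seq_along)
    pos <- as.integer(1e6 + (occ - 1) * 25e6)
    maf <- stats::runif(n_total, cfg$maf_range[1], cfg$maf_range[2])
    pairs <- if (cfg$include_palindromic) {
      rbind(.nonpal_pairs, .pal_pairs)
    } else {
      .nonpal_pairs
    }
    pick <- sample.int(nrow(pairs), n_total, replace = TRUE)

    gamma <- stats::rnorm(J, 0, cfg$gamma_sd)
    alpha <- stats::rnorm(J, cfg$pleiotropy_mean, cfg$pleiotropy_sd)
    deltas <- lapply(seq_len(n_med_traits),
                     function(m) stats::rnorm(Jm, 0, cfg$delta_sd))
    b1v <- c(cfg$b1, rep(0, cfg$n_null_mediators))
    b2v <- c(cfg$b2, rep(0, cfg$n_null_mediators))

    med_block <- function(m) {
      # effects of every mediator-instrument block on mediator trait m
      unlist(lapply(seq_len(n_med_traits), function(mm) {
        if (mm == m) deltas[[mm]] else rep(0, Jm)
      }))
    }
    true_exp <- c(gamma, rep(0, n_med_traits * Jm))
    true_med <- lapply(seq_len(n_med_traits),
                       function(m) c(b1v[m] * gamma, med_block(m)))
    true_out <- c((cfg$d + cfg$b1 * cfg$b2) * gamma + alpha,
                  unlist(lapply(seq_len(n_med_traits),
                                function(m) b2v[m] * deltas[[m]])))

    make_tab <- function(true, n_study) {
      se <- 1 / sqrt(2 * maf * (1 - maf) * n_study)
      beta <- stats::rnorm(n_total, true, se)
      pval <- pmax(2 * stats::pnorm(-abs(beta / se)), .Machine$double.xmin)
      data.frame(snp = snp, chrom = chrom, pos = pos,
                 effect_allele = pairs[pick, 1], other_allele = pairs[pick, 2],
                 eaf = maf, beta = beta, se = se, pval = pval, n = n_study,
                 stringsAsFactors = FALSE)
    }

    mediator_names <- c("mediator_1",
                        if (cfg$n_null_mediators > 0)
                          paste0("null_", seq_len(cfg$n_null_mediators)))
    mediator_snps <- lapply(seq_len(n_med_traits), function(m) {
      snp[J + (m - 1) * Jm + seq_len(Jm)]
    })
    names(mediator_snps) <- mediator_names

    truth <- structure(list(
      gamma = gamma, alpha = alpha, deltas = stats::setNames(deltas, mediator_names),
      b1 = cfg$b1, b2 = cfg$b2, d = cfg$d,
      true_total = cfg$d + cfg$b1 * cfg$b2,
      true_mediation = cfg$b1 * cfg$b2,
      true_proportion = 100 * cfg$b1 * cfg$b2 / (cfg$d + cfg$b1 * cfg$b2),
      exposure_snps = snp[seq_len(J)], mediator_snps = mediator_snps
    ), class = "simulation_truth")

    structure(list(
      exposure = make_tab(true_exp, cfg$n_exp),
      mediators = stats::setNames(
        lapply(seq_len(n_med_traits), function(m) make_tab(true_med[[m]], cfg$n_med)),
        mediator_names),
      outcome = make_tab(true_out, cfg$n_out),
      truth = truth, config = cfg
    ), class = "mr_simulation")
  })
}

#' Write a simulated triplet to disk
#'
#' Emits the canonical TSV tables (`exposure.tsv`, `outcome.tsv`, one
#' `mediator_<name>.tsv` per mediator) plus the generating truth as
#' `truth.json`.
#'
#' @param sim an `mr_simulation` from [simulate_triplet()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_triplet <- function(sim, dir) {
  stopifnot(inherits(sim, "mr_simulation"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_summary_stats(sim$exposure, file.path(dir, "exposure.tsv"))
  write_summary_stats(sim$outcome, file.path(dir, "outcome.tsv"))
  for (nm in names(sim$mediators)) {
    write_summary_stats(sim$mediators[[nm]],
                        file.path(dir, paste0("mediator_", nm, ".tsv")))
  }
  jsonlite::write_json(sim$truth[setdiff(names(sim$truth), "deltas")],
                       file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Worked-example fixture: published trace-element mediation chains
#'
#' Per-leg causal estimates for three published mediation chains linking
#' serum copper and carotene to Alzheimer's disease through gut-microbiome
#' pathway or taxon abundances: copper acting through lipid IVA biosynthesis
#' (GCST90027490), and carotene acting through the pentose phosphate pathway
#' (GCST90027506) and through *Paraprevotella* abundance (GCST90027699).
#' Each leg is given as its reported odds ratio with 95% CI; the log-scale
#' `beta` is `ln(or)` and the `se` is recovered from the CI width,
#' `(ln(ci_high) - ln(ci_low)) / (2 z)`. Replaying the fixture through
#' [mediate_chains()] reproduces the published decomposition (mediated
#' effects 0.071, 0.263, 0.331; mediated proportions about 27.6%, 25.5%,
#' 32.1%).
#'
#' @return data frame with columns `chain`, `role`
#'   (`total`/`step1`/`step2`), `from`, `to`, `or`, `or_low`, `or_high`,
#'   `beta`, `se`.
#' @export
make_table1_fixture <- function() {
  rows <- rbind(
    c("copper-GCST90027490", "total", "copper", "AD", 1.291, 1.075, 1.551),
    c("copper-GCST90027490", "step1", "copper", "GCST90027490", 1.125, 1.046, 1.210),
    c("copper-GCST90027490", "step2", "GCST90027490", "AD", 1.822, 1.036, 3.206),
    c("carotene-GCST90027506", "total", "carotene", "AD", 2.805, 1.054, 7.466),
    c("carotene-GCST90027506", "step1", "carotene", "GCST90027506", 0.593, 0.374, 0.939),
    c("carotene-GCST90027506", "step2", "GCST90027506", "AD", 0.604, 0.375, 0.974),
    c("carotene-GCST90027699", "total", "carotene", "AD", 2.805, 1.054, 7.466),
    c("carotene-GCST90027699", "step1", "carotene", "GCST90027699", 0.530, 0.281, 0.999),
    c("carotene-GCST90027699", "step2", "GCST90027699", "AD", 0.593, 0.389, 0.906)
  )
  out <- data.frame(chain = rows[, 1], role = rows[, 2], from = rows[, 3],
                    to = rows[, 4], or = as.numeric(rows[, 5]),
                    or_low = as.numeric(rows[, 6]),
                    or_high = as.numeric(rows[, 7]),
                    stringsAsFactors = FALSE)
  out$beta <- log(out$or)
  out$se <- (log(out$or_high) - log(out$or_low)) / (2 * .z95())
  out
}

#' Simulate LD blocks for clumping tests
#'
#' Assigns SNPs to blocks on one chromosome: within a block, every pair gets
#' an r-squared drawn uniformly from `r2_range`; between blocks r-squared is
#' 0. SNPs within a block are `within_kb` apart and consecutive blocks start
#' `between_kb` apart, so blocks can be placed inside or beyond a clumping
#' window by choice of spacing.
#'
#' @param n_blocks number of blocks.
#' @param block_size SNPs per block (scalar or length-`n_blocks` vector).
#' @param r2_range range of within-block r-squared values.
#' @param within_kb spacing between consecutive SNPs of a block, in kb.
#' @param between_kb spacing between block start positions, in kb.
#' @param chrom chromosome label for all SNPs.
#' @param seed integer seed.
#' @return list with `ld` (an [ld_source()]) and `map` (data frame `snp`,
#'   `chrom`, `pos`, `block`).
#' @export
simulate_ld_blocks <- function(n_blocks = 3, block_size = 5,
                               r2_range = c(0.2, 1), within_kb = 100,
                               between_kb = 20000, chrom = "1",
                               seed = 20240101L) {
  size <- rep_len(block_size, n_blocks)
  withr::with_seed(seed, {
    map <- do.call(rbind, lapply(seq_len(n_blocks), function(b) {
      data.frame(
        snp = sprintf("blk%d_snp%d", b, seq_len(size[b])),
        chrom = chrom,
        pos = as.integer(1e6 + (b - 1) * between_kb * 1000 +
                           (seq_len(size[b]) - 1) * within_kb * 1000),
        block = b, stringsAsFactors = FALSE
      )
    }))
    pairs <- do.call(rbind, lapply(seq_len(n_blocks), function(b) {
      ids <- map$snp[map$block == b]
      if (length(ids) < 2) return(NULL)
      cmb <- utils::combn(ids, 2)
      data.frame(snp_a = cmb[1, ], snp_b = cmb[2, ],
                 r2 = stats::runif(ncol(cmb), r2_range[1], r2_range[2]),
                 stringsAsFactors = FALSE)
    }))
    if (is.null(pairs)) {
      pairs <- data.frame(snp_a = character(), snp_b = character(),
                          r2 = numeric())
    }
    list(ld = ld_source(pairs), map = map)
  })
}
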