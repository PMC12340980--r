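# build a canonical summary-stat table from effect vectors
make_records <- function(beta, se,
                         snp = sprintf("rs%03d", seq_along(beta)),
                         pval = 2 * pnorm(-abs(beta / se)),
                         effect_allele = "A", other_allele = "G",
                         chrom = "1", pos = seq_along(beta) * 1e6,
                         eaf = 0.3, n = 10000) {
  data.frame(snp = snp, chrom = chrom, pos = as.integer(pos),
             effect_allele = effect_allele, other_allele = other_allele,
             eaf = eaf, beta = beta, se = se, pval = pval, n = n,
             stringsAsFactors = FALSE)
}

# harmonized set straight from the four effect vectors
make_set <- function(beta_exp, se_exp, beta_out, se_out) {
  harmonized_set(beta_exp, se_exp, beta_out, se_out)
}

# swap outcome alleles and negate beta (allele-orientation flip)
swap_alleles <- function(tab) {
  ea <- tab$effect_allele
  tab$effect_allele <- tab$other_allele
  tab$other_allele <- ea
  tab$beta <- -tab$beta
  if (!all(is.na(tab$eaf))) tab$eaf <- 1 - tab$eaf
  tab
}

# the calibration regime: strong instruments, homogeneous null, no pleiotropy
calibration_config <- function(seed) {
  simulation_config(n_snp = 100, n_snp_med = 3, n_exp = 4e5, n_med = 7738,
                    n_out = 2e5, maf_range = c(0.1, 0.5), gamma_sd = 0.15,
                    b1 = 0, b2 = 0, d = 0.1, seed = seed)
}

# the mediation parameter-recovery regime: the copper-chain effect sizes
recovery_config <- function(seed, ...) {
  b1 <- log(1.125); b2 <- log(1.822)
  args <- list(n_snp = 50, n_snp_med = 50, n_exp = 2e5, n_med = 7738,
               n_out = 2e5, maf_range = c(0.1, 0.5), gamma_sd = 0.15,
               delta_sd = 0.25, b1 = b1, b2 = b2,
               d = log(1.291) - b1 * b2, seed = seed)
  do.call(simulation_config, utils::modifyList(args, list(...)))
}
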