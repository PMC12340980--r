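---
title: "Methods: two-sample, multivariable and mediation MR in mrmediate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample, multivariable and mediation MR in mrmediate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmediate)
```

## The causal model

Mendelian randomization (MR) uses genetic variants as instrumental
variables: because alleles are assigned at conception, a SNP that robustly
associates with an exposure can stand in for a randomized nudge to that
exposure, provided it affects the outcome only through the exposure (no
horizontal pleiotropy) and shares no confounders with it. In the
*two-sample* setting the SNP–exposure and SNP–outcome associations come from
separate, non-overlapping GWAS and are combined at the summary level.

`mrmediate` works with the structural chain

> exposure → mediator → outcome,

plus a direct exposure → outcome path. On the log-odds scale (binary
outcome) the total effect decomposes as `τ = d + b₁·b₂`, where `b₁` is the
exposure→mediator effect, `b₂` the mediator→outcome effect and `d` the
residual direct effect. Two-step mediation MR estimates `b₁` and `b₂` by two
separate univariable MR analyses and multiplies them (product of
coefficients). All three legs use different GWAS cohorts, so their sampling
errors are treated as independent.

## Instrument selection

Four filters, applied in order by `select_instruments()`:

1. **Association**: keep SNPs with exposure `p < p_max` (default `1e-5`,
   strict). The sub-genome-wide default is conventional for exposures with
   few genome-wide-significant hits.
2. **LD clumping** (`clump()`): greedy index-SNP pruning — repeatedly take
   the smallest-p remaining SNP, drop all remaining SNPs on the same
   chromosome within `clump_window_kb` (default 10,000 kb) whose pairwise
   `r²` with it exceeds `clump_r2_max` (default 0.001). The threshold is
   read as the standard *exclusion* rule (retain an approximately
   independent set); the literal opposite reading — keeping only highly
   correlated SNPs — would be statistically incoherent. LD comes from a
   user-supplied pairwise table (`ld_source()`); absent pairs count as
   unlinked. No reference-panel LD computation is in scope.
3. **Strength**: per-SNP `F = (β/σ)² > f_min` (default 10, strict), the
   squared z-score form usable from β and SE alone. The variance-explained
   form `(n−2)R²/(1−R²)` with `R² = 2·eaf·(1−eaf)·β²` is available
   (`f_statistic_af()`) when allele frequency and sample size are present,
   but is not the default because those fields are often missing.
4. **Exclusion list**: confounder-associated SNPs are removed via a plain
   id list. Screening instruments against phenome-wide databases is an
   irreproducible manual step; only the mechanism is provided.

The chain is idempotent, and clumping with `r²_max = 1` or window 0 is a
no-op — properties the test suite checks.

## Harmonization

`harmonize()` matches SNPs by identifier (summary sources use rsIDs
consistently; chromosome/position reconciliation and liftover are out of
scope) and aligns outcome effects to the exposure's effect allele, negating
the outcome beta (and complementing its allele frequency) when the alleles
are listed in swapped order. Palindromic pairs (A/T, C/G) cannot be oriented
from allele strings; they are kept only when both sides report an allele
frequency, both frequencies are informative (`min(eaf, 1−eaf) < 0.42`), and
the frequencies agree on orientation — otherwise dropped and counted. With
missing frequencies palindromic SNPs are always dropped while non-palindromic
alignment proceeds on alleles alone. The 0.42 bound is the conservative
convention; at `eaf = 0.5` orientation is maximally ambiguous and the SNP is
always dropped.

## Estimators

Let `r_j = β_Yj/β_Xj` be the Wald ratios and `w_j = β_Xj²/σ_Yj²` the IVW
weights (first-order: exposure-side noise ignored; a second-order Wald SE is
available but off by default).

* **IVW** (`mr_ivw()`): `β̂ = Σ w_j r_j / Σ w_j`, identical to weighted
  least squares of `β_Y` on `β_X` through the origin with weights `1/σ_Y²`.
  Fixed-effects SE `(Σ w_j)^{−1/2}`; the random-effects model multiplies it
  by `max(1, √(Q/(J−1)))` — multiplicative overdispersion bounded below by
  one, so heterogeneity can only widen the interval. A single SNP
  degenerates to the Wald ratio. Normal reference for p-values.
* **MR-Egger** (`mr_egger()`): SNPs are first oriented so every `β_Xj ≥ 0`
  (both betas negated where needed), then `β_Y` is regressed on `β_X` with a
  free intercept and weights `1/σ_Y²`. Slope and intercept SEs carry
  `max(1, √(Q_egger/(J−2)))`; p-values use a t reference with `J−2` df. A
  non-zero intercept estimates the average directional pleiotropy — note
  that "directional" is defined relative to the exposure-increasing
  orientation, which is why pleiotropy that is symmetric with respect to
  arbitrary allele coding cancels out of the intercept.
* **Weighted median** (`mr_weighted_median()`): order the ratios, form
  midpoint cumulative weights `(Σ_{i≤k} w_i − w_k/2)/Σ w_i` (stable sort for
  ties), and linearly interpolate at 0.5. Consistent when ≥50% of the weight
  is valid.
* **Modes** (`mr_mode()`): normal-kernel density of the ratios with the
  modified Silverman bandwidth `φ·0.9·min(sd, IQR/1.349)·J^{−1/5}`
  (`φ = 1` by default), evaluated on a fixed 512-point grid spanning the
  ratio range ± 3 bandwidths; the estimate is the grid argmax, with ties
  resolved to the smaller value so the search is deterministic. The simple
  mode weights ratios equally; the weighted mode uses `1/s_j²` with
  `s_j = σ_Yj/|β_Xj|`. If every ratio coincides, that common value is
  returned directly.
* Bootstrap SEs (median and modes): parametric — both effect vectors are
  redrawn from normal sampling distributions `n_boot` times (default 1000)
  under a fixed seed (default 20240101), making stochastic SEs reproducible;
  the caller's RNG state is left untouched.

Scale equivariance (rescaling all `β_X` by `c` divides every estimate by
`c`), sign equivariance in `β_Y`, and order invariance are enforced by
property tests.

## Multivariable MR

`mvmr_ivw()` regresses `β_Y` on the J×K matrix of exposure effects with no
intercept and weights `1/σ_Y²`; coefficient SEs carry
`max(1, √(Q/(J−K)))`. The instrument set (`build_multi_set()`) is the union
of SNPs passing the per-exposure p and F filters, restricted to SNPs present
in all tables, jointly clumped on the smallest per-exposure p-value, and
aligned to the first exposure's effect allele (palindromic SNPs are dropped
here, since cross-table orientation cannot use frequencies safely).
`J ≥ K+1` is required; rank-deficient exposure matrices abort with the
offending columns named. With K = 1 the estimator reduces exactly to
univariable random-effects IVW. An Egger-style MVMR intercept and
conditional F statistics are out of scope.

## Sensitivity suite and reporting rule

`cochrans_q()` computes `Q = Σ w_j (r_j − fit_j)²` against the IVW fit
(`df = J−1`) or the Egger line (`df = J−2`), with an upper-tail chi-square
p-value. `pleiotropy_test()` is the Egger intercept triple.
`leave_one_out()` re-estimates IVW dropping each SNP in turn and flags
exclusions that change the estimate's sign or move the 95% CI across the
null. `select_model()` encodes the reporting convention: fixed effects when
the Q test is non-significant at 0.05, random effects otherwise; IVW as the
headline estimate when the intercept test is non-significant, MR-Egger
otherwise. The heterogeneity decision consumes the IVW-context Q by default
(both contexts are computed). Funnel- and scatter-plot content is emitted as
plot-ready tables (`funnel_table()`, `scatter_table()`); no graphics are
rendered.

## Mediation

`two_step_mediation()` enforces the exact identities
`mediation = b₁·b₂`, `direct = τ − mediation`,
`proportion·τ = 100·mediation`. The mediated-effect variance uses the
first-order delta method `b₁²·se₂² + b₂²·se₁²`; the proportion's variance
adds the total-effect term `(b₁b₂·se_τ/τ²)²`, treating the legs as
independent (three distinct cohorts). The published example this package
replays prints interval bounds that are not recoverable from its printed
per-leg intervals by any first-order formula (its proportion interval is
its mediated-effect interval divided by the total effect), so interval
conventions differ across reports; the delta method is the package default
and a seeded Monte-Carlo alternative (`ci_method = "montecarlo"`) is
provided for comparison. Proportions outside [0, 100] are reported as-is —
a mediated path can oppose the total effect — and a zero total effect
leaves the proportion `NA` with a warning.

`screen_mediators()` runs both legs for every candidate mediator (step 1
over the exposure's instruments, step 2 over the mediator's own
instruments, selected with the same thresholds) and retains mediators with
both legs significant at 0.05. No multiplicity correction is applied by
default, matching common practice in published mediator screens; a
Benjamini–Hochberg switch (`fdr = TRUE`) is available. `reverse_mr()`
estimates the outcome→exposure direction from the outcome trait's own
instruments; fewer than two reverse instruments make the check
non-assessable rather than an error.

## The synthetic-data generator

`simulate_triplet()` generates GWAS *summary statistics directly* — no
individual-level genotypes. Per SNP with allele frequency `p` in a study of
`n` samples, the SE is the analytic per-allele regression SE for a
unit-variance trait, `1/√(2p(1−p)n)`, and the observed beta is drawn
normally around the truth with that SE, independently per study (no sample
overlap, matching a three-cohort design). A mini individual-level
regression oracle in the test suite confirms the SE formula to within 5%.
P-values are two-sided normal, floored at the smallest positive normalized
double so that extremely strong associations survive validation.

Structure: `J` exposure instruments with effects `γ_j ~ N(0, γ_sd²)`
propagate as `β_med = b₁γ_j` and `β_out = (d + b₁b₂)γ_j + α_j`, where
`α_j ~ N(a, τ_p²)` is optional direct (pleiotropic) SNP→outcome effect.
**Each mediator additionally carries its own instruments**
(`δ_j ~ N(0, δ_sd²)`, outcome effect `b₂δ_j`): without mediator-specific
instruments the mediator→outcome leg is not identifiable — using the
exposure's SNPs for step 2 returns `(d + b₁b₂)/b₁`, not `b₂`, exactly the
confounded-leg failure two-step designs must avoid. Null mediators keep
their instruments but have `b₁ = b₂ = 0`, giving mediator screens a
well-defined type-I behaviour. Allele pairs are non-palindromic by default
(`include_palindromic = TRUE` injects strand-ambiguous pairs to exercise
harmonization), and co-chromosomal SNPs are spaced 25 Mb apart so default
clumping windows never connect them; `simulate_ld_blocks()` supplies
configurable LD structure for clumping tests.

Default configuration: 20 instruments per trait, exposure GWAS n = 64,979,
mediator n = 7,738, outcome n = 184,190, MAF 0.05–0.5, `γ_sd = 0.05`,
`δ_sd = 0.25`, and the copper-chain effects `b₁ = 0.118`, `b₂ = 0.600`,
`d = 0.185` — the scale of the trace-element/microbiome/disease design the
package's worked example comes from (selected instrument counts of order
10–30, a modest continuous-exposure cohort, a small microbiome cohort, a
large case-control outcome).

## Calibration and recovery regimes

Two fixed regimes are used by the tests and the acceptance script, chosen
as the conditions under which the diagnostics' null models genuinely hold:

* **Calibration** (IVW coverage, Egger type-I, Q rejection): J = 100,
  n_exp = 4×10⁵, n_out = 2×10⁵, MAF 0.1–0.5, `γ_sd = 0.15` (median
  instrument F ≈ 800), `d = 0.1`, no pleiotropy. The first-order IVW
  weights neglect exposure-side noise; the neglected variance fraction is
  ≈ `d²·(σ_X/σ_Y)²`, so the regime keeps it at ~1%. This is a real
  approximation property of ratio-based two-sample MR: with equal sample
  sizes and `d = 0.2` the Q test over-rejects (≈9% at nominal 5%) even
  though the data are perfectly homogeneous — worth remembering when
  interpreting Q on strong effects.
* **Recovery** (mediated proportion): J = 50 exposure + 50 mediator
  instruments, n_exp = n_out = 2×10⁵, n_med = 7,738, `δ_sd = 0.25` (so
  mediator instruments clear the selection threshold with little winner's
  curse), chain effects set to the copper-chain values, true proportion
  27.67%.

Problem sizes (500 replicates for coverage and recovery, 1000 for the
type-I rates) balance Monte-Carlo error (±1–2 percentage points on a rate)
against desk-scale runtimes of a few seconds.

## What passing tests do and do not show

The generator draws clean normal summary statistics with correct SEs,
consistent alleles, known truth, and no LD unless injected. Real summary
data differ in ways the tests deliberately do not emulate: winner's curse
at genome-wide thresholds, sample overlap between cohorts, LD-induced
correlation among instruments, population stratification, mis-specified or
missing allele frequencies, liability-scale subtleties for binary traits,
and batch differences across consortia. Passing calibration here validates
the estimators and their implementation under their own assumptions — it
does not certify any particular real-data analysis. Likewise the worked
example replays published per-leg estimates through the decomposition
algebra; it does not re-derive those estimates from cohort data.

## Numerical conventions

* Strict inequalities on the p and F selection cuts, matching the
  `p < 1e-5` / `F > 10` notation.
* 95% intervals use the normal 97.5% quantile (1.959964); Egger uses t
  quantiles only for p-values, intervals stay normal for comparability
  across methods.
* Mode grid: 512 points, argmax ties to the smaller value; bandwidth falls
  back to the available non-zero spread measure when sd or IQR degenerate,
  and to the common ratio when all ratios coincide.
* Weighted-median ties keep input order (stable sort).
* Bootstrap and Monte-Carlo seeds are explicit arguments with fixed
  defaults; `withr::with_seed()` isolates them from the caller's RNG.
* Overdispersion factors are floored at 1 everywhere (no super-efficiency).
* Degenerate inputs fail loudly and early: zero exposure effect in a Wald
  ratio, under-identified or collinear MVMR sets, empty SNP intersections,
  all-dropped harmonization.

## Known limitations

Single mediators only (no joint multi-mediator decomposition or
MVMR-based controlled direct effects); no MR-PRESSO/radial/Steiger
variants; no proxy-SNP substitution or strand inference from a reference
genome; LD must be supplied, not computed; the mediated-proportion delta
interval can behave poorly when the total effect is near zero (the
proportion itself is then unstable — the package reports it as-is rather
than truncating).
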