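---
title: "Methods: cross-trait causal inference from paired GWAS summary statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-trait causal inference from paired GWAS summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crosstrait)
```

## The question the package answers

Observational studies often report that two late-life diseases travel
together — for example coronary artery disease (CAD) and late-onset
Alzheimer's disease (LOAD) — but co-occurrence in cohorts cannot
separate a causal effect from confounding, reverse causation, or a
shared genetic locus with trait-specific mechanisms. `crosstrait`
implements three complementary summary-statistic analyses that attack
this question with genetics alone:

1. **Two-sample Mendelian randomization (MR)**: genetic variants
   robustly associated with the exposure serve as instrumental
   variables; because alleles are assorted at meiosis, their
   downstream associations with the outcome are protected from the
   usual environmental confounding.
2. **Cross-trait LD score regression**: a genome-wide estimate of the
   correlation of genetic effects between the traits, using millions
   of variants rather than a handful of instruments, and robust to
   overlapping study participants.
3. **A four-model Bayesian regional scan**: at a locus associated with
   both traits, it distinguishes one shared causal variant from two
   distinct, merely co-located ones — the difference between a common
   mechanism and a genomic coincidence.

The paired-GWAS simulators are first-class components: they generate
each analysis's inputs under a known truth, so every estimator in the
package is validated by parameter recovery rather than by fiat.

## Harmonization and instrument selection

Two GWAS report effects per copy of an *effect allele*, and nothing
guarantees the two studies chose the same allele or even the same DNA
strand. `harmonize()` re-expresses the outcome effect per copy of the
exposure's effect allele by trying, in order, label identity, label
swap (negate the effect, complement the frequency), strand complement
(A↔T, C↔G), and complement-plus-swap. Palindromic variants (A/T,
C/G) are unresolvable from labels alone, so they are aligned by
effect-allele frequency and **dropped** when either study's frequency
falls within 0.5 ± 0.08. The window is configurable; 0.08 is the
conservative value in widespread use, chosen here once and not tuned —
at 0.5 ± 0.08 the frequency signal is too weak to call strand reliably
in studies of this size. Anything irreconcilable is dropped with the
explicit reason `allele-mismatch`; the harmonization report makes
silent sign errors — the classic MR failure mode — impossible by
construction.

Instruments come from `select_instruments()`: either all variants at
genome-wide significance (p ≤ 5×10⁻⁸) or a Benjamini–Hochberg
5%-FDR set. Variants with minor allele frequency below 0.05 are
flagged but never removed, because sensitivity sets in this field
deliberately retain low-frequency instruments. Instruments missing
from the outcome study can be replaced by `find_proxy()` with an LD
proxy at r² ≥ 0.80 from a user-supplied haplotype panel; among equal
candidates the physically nearest, then lexicographically first, rsid
is taken — a deterministic rule documented because published analyses
rarely state one.

## The MR estimators

For instrument *i* with exposure effect β̂_Xi (se σ_Xi) and harmonized
outcome effect β̂_Yi (se σ_Yi), the Wald ratio is θ̂_i = β̂_Yi / β̂_Xi
with first-order standard error σ_Yi/|β̂_Xi| (default) or the
second-order delta-method form
√(σ_Yi²/β̂_Xi² + β̂_Yi² σ_Xi²/β̂_Xi⁴). First-order is the default
because exposure instruments are by construction strongly associated
(tiny σ_Xi), making the second term negligible; both are available
since the choice is occasionally visible in heterogeneity statistics.

`ivw_fixed()` pools ratios with weights w_i = 1/se(θ̂_i)²:

- θ̂ = Σw_iθ̂_i / Σw_i, se(θ̂) = (Σw_i)^{−1/2};
- exp(θ̂) is the outcome odds ratio per log-odds unit of the exposure;
- Cochran's Q = Σw_i(θ̂_i − θ̂)² is chi-square with k−1 df under
  homogeneity.

Fixed-effect pooling is the headline estimator; heterogeneity is
treated as a diagnostic to be *explained* (by finding the invalid
instrument) rather than absorbed into a random-effects variance.

`leave_one_out()` refits the pool k times with one instrument removed.
The *dominant outlier* is the variant whose removal reduces Q the
most, flagged whenever the full-set heterogeneity is significant
(p ≤ 0.05). Whether its removal leaves no residual heterogeneity is
reported separately (`resolved`) rather than folded into the flag:
when all remaining instruments are valid, the residual heterogeneity
p-value is uniform, so conditioning the flag itself on residual
p > 0.05 would randomly suppress a correct detection in 5% of
datasets. A locus like *APOE* — one variant with a direct outcome
effect an order of magnitude beyond the causal signal — produces the
full signature: biased pool, enormous Q, and a flagged variant whose
exclusion restores both homogeneity and the unbiased estimate.

`egger()` regresses β̂_Yi on β̂_Xi by weighted least squares
(weights 1/σ_Yi²) with a free intercept, after orienting every
instrument so β̂_Xi > 0 (the method's defining convention — the
intercept is only interpretable on the oriented scale). The slope is a
causal estimate valid under the InSIDE assumption even when
instruments are pleiotropic; the intercept estimates average
directional pleiotropy. Inference uses the t distribution with k−2 df.
With the intercept constrained to zero the estimator collapses to IVW
exactly, a relationship the test suite verifies against `lm()`.

`mr_power()` uses the standard normal-approximation for a binary
outcome: power = Φ(−z_{1−α/2}+x) + Φ(−z_{1−α/2}−x) with
x = |log OR|·√(N R² φ(1−φ)), N the outcome sample size, φ its case
fraction and R² the variance in exposure liability explained by the
instruments. Both tails are kept so power equals α exactly at the
null. The smallest OR detectable at 80% power is found by numerical
inversion.

## Cross-trait LD score regression

Under a polygenic model, the expected squared z-score of variant *j*
grows linearly in its LD score ℓ_j (the sum of r² with neighbouring
variants): E[z²_j] = 1 + n h² ℓ_j / m. Confounding (stratification,
relatedness) shifts the intercept, not the slope, so regressing z² on
nℓ/m separates heritability from bias. For two traits,
E[z_{1j} z_{2j}] = √(n₁n₂) ρ_g ℓ_j / m + ρ N_s/√(n₁n₂): the slope
estimates genetic covariance and the intercept absorbs sample
overlap — which is why the genetic correlation
r_g = cov_g/√(h²₁h²₂) is trustworthy even when the two
meta-analyses share participants.

Numerical choices:

- **Two-pass weighting.** A first pass with 1/ℓ weights yields
  plug-in fitted variances v_tj = intercept₀ + n_t ĥ²₀ ℓ_j/m and
  covariance c_j; the second pass uses heteroskedasticity weights
  1/(ℓ_j v²_j) for the single-trait fits and 1/(ℓ_j(v_{1j}v_{2j}+c_j²))
  for the cross fit — the exact sampling variances of z² and z₁z₂
  under bivariate normality. Using the *fitted* intercepts in the
  plug-ins makes the estimator exactly self-consistent: regressing a
  trait on itself returns r_g = 1 identically.
- **Chi-square cap.** z² values are capped at 80 before fitting
  (configurable), the usual guard against single enormous loci
  steering a genome-wide regression.
- **Block jackknife.** All standard errors come from one joint
  delete-one-block jackknife (default 200 contiguous blocks) over the
  three regressions simultaneously, so the correlation between ĥ²₁,
  ĥ²₂ and the covariance propagates into se(r_g). r_g is reported
  unclamped with a flag when |r_g| > 1, never silently truncated.

LD scores are an input — read from file, or computed from a haplotype
panel by summing r² within a 1 Mb window (the customary physical proxy
for 1 cM when no genetic map is supplied).

## The four-model regional scan

For one region with per-variant effects for both traits, five
hypotheses are compared: no association (0), a causal variant for
trait 1 only (1), trait 2 only (2), one variant shared by both traits
(3), or two distinct variants, one per trait (4). Each variant's
evidence is a Wakefield approximate Bayes factor,
ABF = √(V/(V+w))·exp(z²w/(2(V+w))) with V = se² and prior effect
variance w, and the model evidences are prior-weighted sums:
E₁ = π₁ΣA_i, E₂ = π₂ΣB_i, E₃ = π₁₂ΣA_iB_i, and
E₄ = π₁π₂Σ_{i≠j}A_iB_j, computed via the identity
(ΣA)(ΣB) − ΣA_iB_i. Defaults π₁ = π₂ = 10⁻⁴, π₁₂ = 10⁻⁵,
w = 0.04 (prior sd 0.2 on the log-odds scale) follow the established
single-variant colocalization literature; all are configurable, and
posterior conclusions at strongly associated loci are insensitive to
them because the Bayes factors dominate the priors by many orders of
magnitude.

Everything is evaluated on the log scale with log-sum-exp (and a
log-space subtraction for E₄), so a LOAD-scale signal of z ≈ 60
(p ≈ 10⁻⁵⁷⁵, far below double-precision underflow) is handled
exactly; the signal table likewise derives −log₁₀p from `pnorm(log.p
= TRUE)`. The evidence sums assume at most one causal variant per
trait per model and ignore LD between variants, as in the model family
this scan belongs to; regions are user-specified intervals
(`parse_region_spec("chr19:44,744,147-46,101,600")`), not an automatic
genome segmentation.

## What the simulators emulate — and what they do not

`simulate_mr_study()` draws exposure effects uniform in magnitude on
[0.03, 0.3] (per-allele odds ratios ≈ 1.03–1.35, the observed range
for CAD instruments), standard errors from the binary-trait
approximation se = 1/√(2p(1−p)·N·φ(1−φ)), and outcome effects
γ·β_X + α + noise. Defaults echo the motivating study design: k = 52
instruments, exposure study 60,801/123,504 cases/controls, outcome
study 17,008/37,154, and an outlier direct effect of log 3.2 — the
effect-size scale of an *APOE* ε4 heterozygote on LOAD. Allele labels
are randomly swapped and strand-flipped on the outcome side so the
harmonizer is always exercised.

`simulate_ldsc_panel()` draws z-pairs directly from the bivariate
model above with exponential-tailed LD scores (mean 10) and an
overlap intercept N_s ρ/√(n₁n₂); recovery tests use m = 5,000
variants with n = 2,000 — chosen so the per-variant signal
(E[z²] ≈ 2–3) matches the regime of a real million-variant
regression while keeping a full jackknife under a second.
`simulate_region()` draws regional z-vectors from MVN(Rλ, R) with
first-order autoregressive LD (adjacent r = 0.5 by default) and
places distinct causal variants in opposite thirds of the region so
their r² < 0.1. `simulate_haplotypes()` uses Markovian allele copying
(copy probability e^{−decay}) and can plant a four-variant block in
which a frequency-0.08 allele occurs only on one half of the
haplotypes — D′ = 1 with r² ≈ 0.087, the rare-on-common signature
that makes D′ and r² tell opposite stories at loci like *APOE*.

Every simulator takes a seed, draws from a private RNG stream
(restoring the caller's), and serializes a `truth_record`; recovery
tests read truth only from that record.

Deliberate simplifications: summary statistics are simulated directly
(no genotypes, no liability-scale phenotype model); MR instruments are
mutually independent (no residual LD between instruments); LD-score
draws are independent across variants given ℓ (real z-scores are
locally correlated, which the block jackknife accommodates but the
generator does not produce); winner's curse in instrument selection is
not modelled. Passing recovery tests therefore demonstrates estimator
correctness under the stated models, not robustness to every
pathology of real consortium data.

## Degenerate inputs and tie-breaks

- Wald ratios refuse β_X = 0; such variants must be excluded upstream.
- Heterogeneity is undefined for k < 2, leave-one-out for k < 3, Egger
  for k < 3 or for constant oriented exposure effects.
- Monomorphic panel variants give an explicit undefined-LD error.
- Constant LD scores make the slope unidentifiable — an error, not NA.
- A single-variant region has pp4 = 0 exactly (no i ≠ j pair).
- The workflow aborts with a diagnostic when fewer than 3 instruments
  survive harmonization, and logs every excluded variant with stage
  and reason so that selected = analysed + excluded always holds.

## Problem sizes used in the shipped checks

The package's own verification runs entirely on synthetic data at
these scales, chosen to mirror the study design while completing in
minutes: 1,000 random instrument sets for the IVW/Q oracle match; 500
replicates at k = 52 for causal-effect recovery and heterogeneity
calibration; 100 replicates each for outlier flagging and for the
three regional-scan configurations (m = 50 variants); one m = 5,000
LD-score regression with 200 jackknife blocks. The acceptance script
(`scripts/acceptance.R`) regenerates all of these from a single
command-line seed.

## Known limitations

Reproducing the published numbers for a specific pair of consortium
studies requires those consortia's variant-level tables, which are
redistributed under their own terms and therefore not shipped here;
the corresponding checks name the files they expect and fail visibly
until the user supplies them. The LD-score module fits the standard
unpartitioned model only. The regional scan's single-causal-variant
assumption is shared with the method family it implements; loci with
allelic heterogeneity within one trait are outside its scope, as are
multivariable MR, weighted-median/mode estimators, genome builds
liftover, imputation, and indel instruments.
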