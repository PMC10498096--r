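---
title: "Trumpet plots: models, conventions, and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trumpet plots: models, conventions, and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trumpetr)
```

## The problem

Genome-wide association studies (GWAS) of common variants and exome/genome
sequencing studies of rare variants together sketch the effect-size
architecture of a complex trait: most significant variants are common with
small effects, and a minority are rare with large effects. Plotting per-variant
effect size against allele frequency — frequency on a log10 axis so the rare
end is not crushed against zero — makes this architecture visible at a glance
as a trumpet-shaped scatter. `trumpetr` builds these plots and everything they
need: validated summary-statistics input, a canonical allele orientation,
reduction to independent significant variants, analytic power curves, and
static and interactive renderings, plus a simulator so all of it can be
exercised and tested without external data.

This vignette explains the models, conventions, numerical choices, and known
limitations. It states no empirical result that the package's test suite or
`scripts/acceptance.R` does not itself compute.

## Input records and validation

A `sumstats` table holds one row per variant: identifier, chromosome and
1-based position, effect and other allele, effect-allele frequency (EAF),
effect size on the beta scale, standard error, p-value, and optional
per-variant sample size, gene, trait, and source (`gwas` or `exome`, so
exome-style rare-variant records can be carried alongside array-based GWAS
records and distinguished downstream). Effects must be per-allele regression
coefficients; for binary traits this is the log odds ratio, and odds ratios
must be log-transformed before ingestion — the package deliberately does not
guess the scale.

Validation is total: each input row is either loaded or rejected with a
reason, and the counts always sum to the input row count. The invariants are
`0 < eaf < 1` (a frequency of exactly 0 or 1 is monomorphic: `2f(1-f) = 0`
breaks both the power model and orientation flipping, so such rows are
rejected rather than patched), `se > 0`, `0 < p ≤ 1`, distinct alleles, and
unique variant ids. One repair is applied rather than a rejection: an input
p-value of exactly 0 (common in files that underflowed) is clamped to the
smallest positive double with a warning, so `-log10(p)` stays finite.
Alleles are upper-cased; no strand flipping or palindrome resolution is
attempted, since this is a single-study tool rather than a meta-analysis
harmonizer.

## Allele orientation

Two canonical orientations are supported, selected per table or plot:

* **Signed minor-allele** (default and recommended): every record reports the
  minor allele, frequencies fall in (0, 0.5], effects keep their sign. A
  record with `eaf > 0.5` is flipped: alleles swapped, `eaf := 1 - eaf`,
  `beta := -beta`.
* **Positive-effect**: every record reports the trait-increasing allele,
  effects are non-negative, frequencies span (0, 1).

Both transforms are idempotent, preserve `se`, `p`, and `n`, and preserve the
per-variant variance contribution `2f(1-f)β²` — which is why statistical
power is orientation-invariant and the two plot conventions are two views of
the same data. Ties are deterministic by fiat: `eaf = 0.5` is never flipped
under the minor-allele convention, and `beta = 0` (undefined sign) is never
flipped under the positive-effect convention. The minor allele is defined
from the study's own EAF, not from a reference panel: a single-study plot
should reflect the study's frequencies, and requiring a panel would add an
input the plot does not otherwise need.

## The power model

The package adopts the standard single-variant GWAS formulation: the additive
1-degree-of-freedom Wald/score chi-square test, which under the alternative is
non-central chi-square with non-centrality

* quantitative trait, phenotype variance standardized to 1:
  λ = n · 2f(1−f) · β²;
* binary trait, β on the log-odds scale:
  λ = 2f(1−f) · β² · n_cases·n_controls / n,
  the usual log-OR variance approximation
  var(β̂) = n / (2f(1−f) · n_cases · n_controls).

Power at threshold α is P(χ²₁(λ) > q) with q the central χ²₁ critical value.
At β = 0 this is exactly α. The model assumes exact genotypes and no LD,
winner's curse, or imputation-quality adjustment — it is the power of the
test that produced the summary statistics, not a discovery-pipeline forecast.

The minimum-detectable-effect curve inverts this relationship: for a target
power p the non-centrality λ*(α, p) is found once per level by a monotone
root-find on the non-central chi-square survival function (bracketed from
[0, 10q] with geometric expansion, tolerance 10⁻¹⁰ in power — tight enough
that curves are reproducible across platforms), and then
β_min(f) = sqrt(λ* / (n_eff · 2f(1−f))). Curves are evaluated on a log10-
spaced frequency grid (default 200 points from 10⁻⁵ to 0.5) so they render
smoothly at the rare end where the plot axis is logarithmic. Because λ* is
increasing in the level, curves for higher power sit uniformly above lower
ones and never cross; because β_min ∝ n^(−1/2), doubling the sample size
scales every curve by 1/√2.

The default curve parameters — N = 351,550, α = 5×10⁻⁸, levels 0.5 / 0.7 /
0.9, frequency axis from 10⁻⁵ — are a typical large-biobank GWAS
configuration and are all user-settable. Whether such a figure should use the
quantitative or the binary formulation is a user decision; both are
implemented and the choice is explicit in `power_spec()`.

`empirical_power()` is the package's own independent check on this algebra:
it simulates genotypes Binomial(2, f) and phenotypes (quantitative:
β·g + Normal noise scaled so total variance is 1, matching the analytic
convention; binary: a logistic model with the intercept set by the case
fraction), runs the Wald (quantitative) or score (binary) test per replicate,
and reports the rejection fraction. The quantitative convention implies the
constraint 2f(1−f)β² < 1 (an effect cannot explain more than the full
phenotypic variance), which is enforced with an error. Note one deliberate
asymmetry: the analytic λ uses the total phenotypic variance, while a real
regression sees the residual variance 1 − 2f(1−f)β²; the two agree to first
order and the discrepancy is quadratic in the (small) per-variant variance
explained, which is why validation grids use per-variant effects in the
realistic small-h² regime.

## Independent significant variants

Variants near a causal site are significant through LD alone, so trumpet
plots are most interpretable when restricted to distinct association
signals. Two reductions are implemented, both operating on summary statistics
plus an LD reference (`ld_reference`): a symmetric signed allelic correlation
matrix keyed by variant id, computable from a genotype dosage matrix
(`ld_from_genotypes()`) or read from TSV. Correlations are assumed oriented
to the table's effect alleles; re-orienting a variant flips the sign of its
row and column, which is irrelevant to r²-based clumping but matters to
stepwise selection.

**Clumping** is the classic greedy pass: restrict to candidates with minor
allele frequency above `maf_min` (default 0.01) and p below `p_threshold`
(default 5×10⁻⁸); repeatedly take the unassigned candidate with the smallest
p-value as a lead and absorb unassigned same-chromosome candidates within
`window_bp` of the lead (default 100 kb, measured lead-to-candidate, not
chained) whose r² with the lead is at least `r2_threshold` (default 0.1; the
commonly used value, exposed as a parameter). Absorption requires the window
and r² conditions *jointly*: a distant variant in high LD is a separate
signal as far as a window-bounded method can tell. P-value ties break by
distance-to-lead then lexicographic id, so output is independent of input row
order. The result is a partition of the significant set — checked
exhaustively in the tests.

**Stepwise conditional/joint selection** approximates a joint multi-variant
model from marginal statistics. Marginal effects are standardized to the
correlation scale, b = z/√n with z = β/se; for a selected set S with LD
submatrix R_S, joint standardized effects are R_S⁻¹ b_S, and a candidate c is
scored by its conditional z,
(z_c − R_{c,S} R_S⁻¹ z_S) / sqrt(1 − R_{c,S} R_S⁻¹ R_{S,c}).
Selection starts at the smallest marginal p and adds the best candidate while
its conditional p clears the threshold. Joint estimates are back-transformed
to the input beta scale (β_joint = b_joint · se·√n, se_joint =
sqrt(diag(R_S⁻¹)) · se). Three numerical guards keep the linear algebra
honest: the procedure runs per chromosome with correlations beyond
`window_bp` treated as zero (a banded approximation matching the local range
of LD); candidates with max r² to S above `collinearity_r2_cap` (default
0.9) are skipped; and a candidate whose addition would push the selected-set
LD matrix past condition number 10⁸ is skipped with a warning naming it.
With an identity LD matrix the procedure provably reduces to marginal
thresholding with joint = marginal estimates, which the tests assert
exactly. When the LD matrix and the summary statistics come from the same
cohort, the joint betas reproduce individual-level multiple regression — the
acceptance tests verify this against `lm()` on simulated cohorts.

## Plot construction

`build_plot_data()` resolves a harmonized table into render-ready geometry:

* x = EAF on a log10 axis (ticks at powers of ten); y = beta.
* Point **area** interpolates linearly in |β| between configurable bounds —
  area rather than radius, because perceived size tracks area. When all |β|
  are equal the midpoint size is used.
* Colour encodes −log10(p) on a continuous viridis scale, capped by default
  at 50 so that genome-wide p-values spanning hundreds of orders of magnitude
  do not flatten the scale.
* `min_effect_display` drops records with |β| strictly below the threshold
  (so a variant at exactly the threshold is kept). The static default is 0;
  the interactive renderer defaults to 0.05 to keep self-contained HTML files
  small. Filtering is the only thing that changes the point count, and
  retained + dropped always equals the input count.
* Points with EAF below the axis minimum are clipped to the axis edge with a
  warning rather than dropped — rare singletons are the most interesting part
  of the plot and silently losing them would defeat its purpose.
* In signed mode, power curves are mirrored to ±β_min, giving the two-sided
  trumpet; a table whose orientation contradicts the spec (e.g. eaf > 0.5 in
  signed mode) is a fatal error reporting the offending count.

`render_static()` draws via ggplot2 to SVG/PDF/PNG. `render_interactive()`
writes a deterministic, dependency-free HTML file: the layout is computed in
R, embedded as JSON in a stable order and number format, and drawn
client-side into an SVG with a tooltip showing exactly the configured hover
fields (variant id, effect, gene, p-value, trait). Re-rendering identical
plot data is byte-identical, which makes end-to-end artifact determinism
testable.

## The simulator

The generator exists so that every method above can be tested against known
truth. It emulates:

* **Frequencies**: common, array-like variants with minor allele frequency
  log10-uniform on [−2, −0.3]; rare, exome-like variants log10-uniform on
  [−5, −2], tagged `source = "exome"`, given gene labels, and emitted LD-free
  (singleton-like loss-of-function records in sequencing studies are
  effectively private haplotypes).
* **Effects**: a causal subset (exactly `round(causal_fraction · m)` variants,
  so architecture is reproducible) with β | causal ∼ N(0, τ²/(2f(1−f))^γ).
  γ = 0 gives frequency-independent effects; γ = 1 equalizes expected
  per-variant variance explained (E[2f(1−f)β²] = τ², asserted by simulation
  in the tests); the default γ = 0.5 is the middle of the standard
  architecture family and produces the characteristic trumpet without
  asserting any specific trait's genetics. Defaults τ = 0.02,
  causal fraction 0.3, and N = 351,550 were chosen so that, at the default
  sample size, common causal variants are mostly well-powered and rare
  variants are significant only in their large-effect tail — the regime the
  plot is designed to show.
* **LD**: common variants sit in blocks (default: 5 variants at genotype
  correlation 0.7) laid out round-robin across 20 chromosome labels, 300 kb
  apart within a chromosome so distinct blocks never share a clumping
  window. All members of a block share one frequency — LD partners have
  similar frequencies in real data, and it makes the within-block
  correlation target exactly attainable.
* **Summary statistics**: se = 1/sqrt(n·2f(1−f)) (standardized phenotype),
  emitted β = β_true + N(0, se²), p from the two-sided Wald z — so emitted
  (β, se, p) are mutually consistent by construction. About half the common
  records are emitted on the major-allele orientation to exercise
  harmonization.
* **Cohorts** (`simulate_cohort()`): individual-level genotypes for the
  common variants via a Gaussian copula — exchangeable latent normals per
  block, thresholded to Binomial(2, f) margins, two haplotypes per
  genotype. The latent correlation is calibrated by numerically inverting
  the threshold-bivariate-normal relation (`integrate` + `uniroot`); if the
  achieved allele correlation misses the target by more than 0.02 a warning
  reports both. The phenotype is G·β_true plus Gaussian noise scaled to unit
  total variance. `cohort_sumstats()` then produces the marginal scan that
  serves as the individual-level oracle for the selection methods.

What the generator does **not** emulate: winner's curse beyond plain
sampling noise, imputation error, population stratification, binary-liability
phenotypes (quantitative only), selection-driven frequency–effect coupling
beyond the γ family, and — deliberately — LD-induced correlation in the
*emitted summary statistics*' noise: emitted marginal effects are independent
across variants given truth, which keeps the generative law transparent.
Methods that need LD-consistent marginals (the stepwise oracle tests) use
`simulate_cohort()` + `cohort_sumstats()`, where LD contamination arises
naturally from the genotypes. Passing tests therefore demonstrate algorithmic
correctness under a clean architecture, not robustness to every artifact of
real summary statistics.

## Measuring the trumpet shape

The tests summarize "is the emitted architecture trumpet-shaped?" as: among
genome-wide-significant variants, median |β| strictly decreases across ten
equal-width bins of log10 frequency, comparing bins holding at least 20
variants. Equal-width *log* bins rather than equal-count deciles are the
right ruler here: the plot's axis is logarithmic, and on that axis adjacent
bins span comparable ratios of the detection threshold, so the expected
decline per bin is roughly uniform. Equal-count deciles concentrate at the
common end of the spectrum, where adjacent deciles differ by only a few
percent in threshold and a ~200-variant median cannot resolve the decline
reliably. The 20-variant density rule excludes bins whose median would be
estimated from a handful of rare points.

## Problem sizes and numerical conventions used in validation

The shipped validation uses: a 3 (frequency) × 3 (effect, including 0) × 2
(sample size) grid at two significance thresholds with 10,000 Monte-Carlo
replicates per cell for the power model; 1,000 random draws for inverse-power
consistency at tolerance 10⁻⁸ (symmetry in f ↔ 1−f is asserted at the same
10⁻⁸, which is also the floating-point limit of forming 1−f at rare f);
20 simulated cohorts of 2,000 individuals with one 8-variant LD block and two
causal variants for the selection-versus-regression oracle; 10,000+ random
records for harmonization invariants; and a 20,000-variant simulation
(16,000 common + 4,000 rare) at the default study parameters for the
end-to-end trumpet reproduction. These sizes give each stochastic assertion
a comfortable noise margin (3 binomial standard deviations unless stated)
while keeping the default test run fast.

Other numerical conventions, collected: root-find tolerance 10⁻¹⁰ in power
with geometric bracket expansion; clump tie-breaks by (p, distance, id);
stepwise LD banding at the clump window; collinearity cap r² = 0.9 and
condition-number cap 10⁸; p = 0 clamped to the smallest positive double;
monomorphic frequencies rejected; artifact numbers written with explicit
format so identical runs are byte-identical.

## Limitations

* Power formulas assume the additive 1-df test with exact genotypes; power
  for burden tests, interactions, or family designs is out of scope.
* Stepwise selection is a windowed approximation to full conditional/joint
  analysis; it is validated against in-sample multiple regression, not
  against any external implementation, and out-of-sample LD references will
  add the usual reference-panel noise.
* The simulator is a testing substrate, not a population-genetics model: no
  coalescent realism, no selection, no binary liability.
* The interactive renderer favours determinism and zero dependencies over
  figure-library polish; very large tables belong in the static rendering or
  behind the display filter.
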