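---
title: "Methods: mixed-model mapping and tandem-duplication genotyping in inbred island populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mixed-model mapping and tandem-duplication genotyping in inbred island populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdgwas)
```

`tdgwas` implements the computational core of a trait-mapping study in a
small, recently bottlenecked population of selfing (inbred) plant lines:
replicated ionome phenotypes are cleaned and collapsed to accession means,
a kinship-corrected linear mixed model scans biallelic variants for
association, tandem duplications are genotyped from read depth and their
breakpoint junctions classified, and population-genetic summaries prepare
inputs for downstream genealogy inference. A seeded synthetic-data
generator with full ground truth makes every stage testable end to end.
This vignette records the models, the defaults and their units, the
numerical choices, and the design decisions that were genuinely open.

## Phenotype model and quality control

Leaf elemental contents (boron, with chromium and titanium as
soil-contamination sentinels, all in µg/g dry weight) are measured on
replicate plants laid out in a randomized block design. Cleaning happens in
two single-pass steps:

1. **Contamination filter.** For each channel a z-score is computed once,
   over all rows, with the sample (n−1) standard deviation; any replicate
   plant with |z| > 3 on any channel is removed. The filter is deliberately
   single-pass — z-scores are not recomputed after removals — because
   iterative re-filtering is a different (and unstated) procedure that
   removes progressively more points. A constant channel has zero SD and
   contributes z = 0. Whether z-scores should be computed per tray or
   globally was open; globally is assumed.
2. **Replicate floor.** Accessions left with fewer than three replicates
   are dropped entirely. Removal before this point is per plant, not per
   accession.

**BLUEs.** Block effects are removed by fitting
`value ~ 0 + accession + (1 | block)` by REML with **lme4** — accession
fixed, block random — and reporting the accession fixed effects on the
original scale. For a balanced complete design these equal raw accession
means; they differ (and are better) exactly when the design is unbalanced,
e.g. after outlier removal. With a single block, or a completely confounded
design, the function warns and falls back to ordinary least squares with
block as a sum-contrast fixed effect.

**Broad-sense heritability.** `H² = var_line / (var_line + var_residual)`
from a one-way random-effects fit (`value ~ (1 | accession)`, REML,
components truncated at zero). H² is invariant to affine rescaling of the
measurements and reaches 1 when replicates agree exactly within accessions.

## The association scan

Genotypes are haploid-coded per inbred line (0/1; heterozygotes are not
modelled). Calls with read depth not above 3 or genotype quality not above
20 are set to missing ("greater than three" and "above 20" are read
strictly: DP ≥ 4, GQ ≥ 21). Variants are then kept when their minor allele
frequency, computed on non-missing calls, is at least 5% and their
missingness is below 10%. The MAF filter direction deserves a note: the
source protocol phrase reads "minor allele frequency below 5%", which as
written would retain only rare variants; retaining MAF ≥ 5% is the standard
reading, is consistent with reported post-filter variant counts, and is what
the package does (the threshold is a plain argument either way).

The kinship matrix is the centered relatedness matrix `K = W Wᵀ / p`,
where `W` holds mean-centered, mean-imputed variant columns and `p` is the
variant count.

Each marker is tested in

y = intercept + covariates + x·β + u + ε,  u ~ N(0, σ²_g K),  ε ~ N(0, σ²_e I)

fit by **exact per-marker REML**: on the eigenbasis of `K` the profile REML
criterion is a one-dimensional function of the variance ratio
δ = σ²_e/σ²_g, optimized by Brent search on log δ over [1e-5, 1e5] with
tolerance 1e-8. Per-marker exact fitting (rather than a null-model
approximation) is affordable at the sample sizes this package targets
(tens to a few hundred lines) and keeps the estimator's definition
unambiguous. The Wald statistic (β/se)² is referred to χ²₁, the
large-sample mixed-model convention; at small n this is mildly
anti-conservative relative to a t reference, which is why the calibration
properties below are stated at n in the low hundreds. β is the per-allele
effect; for contrasts between homozygous inbred classes the package reports
2β (`effect_size_homozygous()`).

With `K = I` the model degenerates to ordinary least squares exactly — used
as a unit test — and the naive `ols_scan()` is kept as the uncorrected
baseline: on structured data its genomic-control λ inflates severely while
the mixed model stays near 1.

**Conditional scans** append the mean-imputed genotype columns of chosen
lead markers as fixed covariates and drop those markers from the report;
a regional signal explained by a single haplotype disappears under
conditioning on it.

**Thresholds and λ.** Bonferroni cut α/m at α = 0.05; Benjamini–Hochberg
step-up cut at q = 0.10 (largest p(i) ≤ i·q/m, reported as absent when no
index qualifies). Genomic control converts p-values to χ²₁ quantiles and
divides the observed median by the χ²₁ median, computed by inverse CDF
(≈ 0.4549), never hard-coded.

**Group tests.** Two-group comparisons (e.g. carriers versus non-carriers)
use the Mann–Whitney–Wilcoxon test: exact two-sided p when both groups have
at most 20 observations and no ties, otherwise the tie-corrected normal
approximation with continuity correction.

## Copy-number genotyping from read depth

Per-base depth over a candidate region is summarized in 800 bp windows
every 400 bp. A trailing partial window of at most half a window is merged
into its predecessor (the tiling example in the unit tests pins this rule
down; the alternative strict-inequality reading contradicts the documented
window enumeration). Window means are divided by the pooled per-base mean
of the two 3 kb flanks just outside the breakpoints — pooling the flanks
was an open choice; the mean is the default and a median is available — and
the copy number is the median ratio over windows lying **fully** inside the
breakpoints, rounded half-up (ratios in [1.5, 2.5) give CN 2). Partial
windows are excluded because they straddle the breakpoint and dilute the
ratio. Normalization makes calls invariant to overall sequencing depth.
`detect_depth_changepoints()` is a deliberately simple screen — maximal
runs of ≥ 3 consecutive windows above 1.5× the global median window depth —
standing in for split-read SV discovery, which is out of scope.

## Breakpoint junction classification

A tandem duplication of `reference[dup_start..dup_end]` creates a junction
where the end of copy 1 meets the start of copy 2. The classifier locates
two exact, case-insensitive anchors in the junction-spanning sequence: the
`flank_probe` (default 50) reference bases ending at `dup_end` and the
`flank_probe` bases starting at `dup_start` (`N` never matches). Their
relative placement decides the call:

* anchors overlapping by `k ≥ 1` bases → **microhomology** of length `k`
  (the motif is shared by both breakpoint ends of the reference — the
  alignment-overlap signature of microhomology-mediated repair);
* intervening unmatched bases → **novel insertion** (the bases are
  reported);
* exact adjacency → **blunt** junction.

Ties are impossible under this geometry: a junction read either carries the
shared motif once (overlap) or not, so the "longest homology, zero insert"
preference is structural rather than a tie-break rule. The synthetic
constructor builds all three junction types with recorded truth; for
microhomology it edits the reference so the motif both ends copy 1 and
starts copy 2, and the junction read carries the motif exactly once. The
constructor/classifier pair round-trips over a thousand random motifs and
inserts of 1–50 bp in the test suite.

## Population-genetic preprocessing

* **Watterson's θ** per site: `S / (a_n · L)` with `a_n = Σ 1/i`. Inbred
  accessions contribute one haplotype each, so n is the number of lines —
  matching the haploid model used downstream.
* **Missingness-corrected mutation rate**: `μ = μ₀ (1 − missing/total)`
  with μ₀ = 7×10⁻⁹ per bp per generation, in 10 Mb windows every 50 kb,
  truncated (not dropped) at chromosome ends so ends are never rateless.
  `total` counts biallelic SNPs with ≤ 10% missingness; `missing` counts
  those among them failing the completeness rule (any absent call, or DP
  not above 3 or GQ not above 25 — note the GQ cut here is deliberately 25,
  distinct from the scan's 20). Which variants count as "missing" was open;
  sites failing the stated completeness rule are counted.
* **Outcrossing-scaled maps**: in a selfer with outcrossing rate c,
  effective recombination is reduced; genetic distances are multiplied by c
  (at the default c = 0.05, divided by twenty). Scaling composes
  (a then b equals a·b) and preserves monotonicity.
* **Genealogy input export**: SHAPEIT-style haps/sample/map files, one
  haplotype row per line, restricted to sites passing the completeness
  rule; tandem-duplication breakpoints enter as biallelic pseudo-variants
  coded 1 for carriers, inserted in position order, with collisions against
  real sites rejected by name. Tree building itself is out of scope — the
  module stops at verified input files that parse back exactly.

## The synthetic-data generator

The generator emulates the statistical structure the estimators must cope
with, not the biology that produced it:

* **Population**: a finite-island (Balding–Nichols) construction. The
  number of segregating sites is drawn Poisson(θ·a_n·L) around the
  configured per-site diversity target (default θ = 10⁻³ over a 100 kb
  region — a low-diversity, post-bottleneck regime), island-wide
  frequencies follow the neutral 1/i spectrum, and subpopulation
  frequencies are Beta-dispersed with differentiation F (default 0.3,
  strong structure; default 3 subpopulations). Candidate sites are drawn
  until the target number segregate in the sample, so realized Watterson's
  θ is centred on the target by construction. Genotypes are homozygous
  0/1 per line; heterozygotes never occur. Per-call DP (Poisson, mean 30)
  and GQ are emitted so quality filters have real targets; missing calls
  (default 2%) receive low DP/GQ.
* **Traits**: B = intercept (20 µg/g DW) + genetic value + block effect +
  residual, four replicates per accession across four blocks. When a target
  H² is set, the residual variance is solved from the realized genetic
  variance so that var_g/(var_g + var_block + var_residual) equals it — the
  quantity the one-way repeatability fit estimates under this layout. Block
  effects are treated as fixed design effects: the handful of draws is
  centred and rescaled to exactly the nominal block SD (default 2 µg/g),
  otherwise the χ²-noise of 3 degrees of freedom would dominate the
  variance partition the generator promises. Soil-contamination outliers
  hit Cr and Ti jointly with a 15× multiplicative shift (far beyond 6
  sample SDs) at rate 2%, giving the |z| > 3 filter unambiguous targets.
* **Depth**: negative binomial per base (variance μ + d·μ²), Poisson at
  d = 0, with expected depth `depth_mean × copies` inside the duplication.
* **Limitations**: sites are exchangeable given the structure — there is no
  linkage disequilibrium along the chromosome, no site-frequency-spectrum
  realism beyond the 1/i shape, no selection, and no read-level error
  model. Passing tests therefore demonstrate estimator correctness and
  calibration under confounded structure, not robustness to LD patterns or
  sequencing artifacts of real data.

All generators are pure functions of (configuration, seed); child seeds for
sub-generators are derived deterministically.

## Pipeline, problem sizes and determinism

`validate_config()` fills a nested configuration with the defaults above,
rejects unknown keys, checks numeric domains, and logs every deviation.
`run_pipeline()` chains simulate → QC/BLUEs → scan → CN/junction → popgen,
writes each stage's tables (VCF, TSV, FASTA, YAML, haps/sample/map) and a
manifest with the seed and a configuration hash; identical configuration
and seed reproduce every output byte for byte. Stage-input mismatches are
rejected before any computation.

The test suite exercises calibration at deliberately modest problem sizes
chosen to make the checks sharp yet quick: null calibration of λ over 50
structured scans of 100 lines × ~400 variants; copy-number recovery over
500 Poisson 30× regions; H² = 0.75 recovery over 100 simulations of 150
accessions × 4 replicates; end-to-end causal-variant recovery over 100
seeded pipeline runs of 200 lines. Oracle equivalence of the mixed model is
checked against a brute-force variance-ratio grid search at n ≤ 10, where
the GLS algebra can be enumerated directly.

## Known limitations

* The Wald χ²₁ reference is anti-conservative below roughly a hundred
  samples; a t-type reference would differ there (documented, not
  implemented, to keep the convention unambiguous).
* Copy-number calls assume a single duplicated segment between known
  breakpoints and are not guaranteed beyond CN 3; breakpoint discovery
  itself is only a screen.
* Bayesian chip-heritability, genealogy/ARG inference, coalescent dating,
  de novo assembly and structure prediction are out of scope; the package
  produces verified inputs where those tools would take over.
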