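---
title: "Polygenic score calculation and ancestry QC: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polygenic score calculation and ancestry QC: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgsdesk)
```

# The scoring model

For each individual $j$ and score with $N$ variants, the score is the
weighted dosage sum

$$\mathrm{PGS}_j = \sum_{i}^{N} \beta_i \, D_{ij},$$

with $\beta_i$ the published effect-allele weight and $D_{ij} \in [0,2]$ the
imputed effect-allele dosage. The VCF stores the ALT-allele dosage (`DS`
field, falling back to the `GT` hard call); when the score's effect allele
matches REF instead of ALT, the effect dosage is $2 - D_{\mathrm{alt}}$.
Everything else in the scoring engine is bookkeeping around which variants
are allowed to contribute:

* **Strand flips.** In the default `resolve` mode, a score variant whose
  alleles match the VCF record only after complementation (A↔T, C↔G) is
  used as `FLIPPED` / `FLIPPED_SWAPPED`. The cost of this automation is
  that palindromic pairs (A/T, G/C) become undecidable — complementation
  maps them onto themselves — so they are excluded outright, *even when
  they would match directly*: a direct match is indistinguishable from a
  flipped swap. `strict` mode disables flip resolution and retains
  palindromic variants.
* **Indels** match exactly or not at all; complementation is not defined
  for them, and they never count as palindromic.
* **Scores without an other allele** are matched against ALT then REF
  only; flips are not attempted because a single base cannot be oriented.
* **Imputation quality.** Variants carrying an `R2`/`ER2` INFO value below
  `min_r2` (default 0.3) are excluded. Sites without any quality value —
  typically genotyped rather than imputed sites — pass the filter: an
  absent measurement is not evidence of poor imputation. Dosages outside
  $[0,2]$ are treated as a hard data error rather than clamped, because
  they indicate the field does not mean what we assume.
* **Missing dosages.** A variant with a missing dosage in *any* sample is
  excluded for *all* samples. The alternative (skipping it only for the
  affected sample) silently gives incomplete samples systematically lower
  scores; an opt-out (`missing_global = FALSE`) exists for single-sample
  use.

Per score, the *coverage* is the fraction of its variants that survived
matching and filtering, classified strictly: above 0.75 `HIGH`, below 0.25
`LOW`, the closed interval between them `MEDIUM` (the boundary values fall
in `MEDIUM` by a literal reading of "above"/"below"). Every variant's fate
is recorded with a reason code, so a coverage number can always be
decomposed.

## Determinism and chunking

Genomes are tiled into fixed-size chunks (default 20 Mb; chunk $k$ spans
$[(k-1)S+1,\,kS]$), each chunk is scored independently from the tabix
index of the weight repository and the region read of the VCF, and the
final score is the sum of chunk partial sums. Contributions are
accumulated in sorted $(\mathrm{chrom}, \mathrm{pos}, \mathrm{other},
\mathrm{effect})$ order within a chunk and chunks are merged in genomic
order, so the result is bit-identical across worker counts. Across
*different* chunk sizes the summation grouping changes, which perturbs the
result at the level of floating-point regrouping only; the tests bound
this at $10^{-9}$ relative.

## The weight repository

All scores are merged into one table keyed by
$(\mathrm{chrom}, \mathrm{pos}, \mathrm{other}, \mathrm{effect})$ — both
alleles are part of the key so that split multi-allelic sites occupy
separate rows — with one weight column per score and `.` for absence,
bgzip-compressed and tabix-indexed. Weights are printed with 17
significant digits, which round-trips IEEE doubles exactly; interval
queries through the index are therefore bit-identical to a linear scan.
Chromosome names are normalized (leading `chr` stripped, `X/Y/MT`
upper-cased) on every input path. Genome builds are recorded from file
metadata when present but never lifted over; a mismatch is the user's to
resolve.

# Ancestry estimation

The reference panel is a labelled genotype matrix (the HGDP-style panels
used in production, or the simulator's panels in the tests). SNPs with
minor allele frequency below 1% are dropped; genotypes are standardized
under Hardy–Weinberg scaling ($\mathrm{centre}\ 2p$, $\mathrm{scale}\
\sqrt{2p(1-p)}$) and the top `n_pcs` (default 10) principal components are
extracted. Study samples are standardized with the *reference* frequencies,
missing genotypes are mean-imputed (zero after centring), and coordinates
are obtained by projection onto the reference loadings.

## Projection shrinkage

Naive projection of new samples onto PCs estimated from $n$ reference
samples and $p \gg n$ SNPs is biased toward the origin: with noise variance
1 after standardization and $\gamma = p/n$, a sample eigenvalue $\ell$
above the Marchenko–Pastur edge $(1+\sqrt\gamma)^2$ corresponds to a
population spike $\lambda$ with

$$\lambda = \tfrac12\!\left[(\ell + 1 - \gamma) + \sqrt{(\ell+1-\gamma)^2 - 4\ell}\right],
\qquad
\cos^2\theta = \frac{1 - \gamma/(\lambda-1)^2}{1 + \gamma/(\lambda-1)},$$

and an out-of-sample projection is shrunk by
$\rho = \cos\theta\,\sqrt{\lambda/\ell}$ relative to the in-sample scores.
`project_samples()` divides each PC by $\rho$ (PCs below the edge carry no
signal and are left untouched, with $\rho$ floored at 0.1 for numerical
safety). On the package's default simulated panel the predicted
$\rho \approx 0.87$ agrees with held-out measurement to three digits. This
correction plays the role that Procrustes re-alignment plays in
sequence-oriented projection tools; without it, study samples land
systematically inside their reference cluster's radius and off its centre.
Projecting a reference sample's own genotypes is exact only with
`correct = FALSE`, since the correction is by construction an out-of-sample
rescaling.

## Classification

A sample's distances to all reference samples are computed over the first
`n_pcs` PCs (plain Euclidean; squared distance would give the same
neighbour ranking but different vote weights). The `k = 20` nearest
references vote with weight $1/(d + 10^{-12})$ — the epsilon makes a
zero-distance match dominate without dividing by zero — and the sample
receives the top population only if its weighted vote fraction strictly
exceeds 0.75; otherwise it is `UNCLASSIFIED`. Ties at the $k$-th distance
keep the first references in input order, so exactly $k$ neighbours always
vote and results are deterministic. Scores annotated with source-GWAS
populations then exclude mismatching and unclassified samples from their
summary statistics (never from the score matrix itself — exclusion is a
reporting decision, not a data deletion). A score with no population
annotation restricts nothing beyond the unclassified rule.

# The simulator, and what passing its tests does not show

`simulate_panel()` draws ancestral frequencies $p \sim U(0.05, 0.95)$ and
per-population frequencies from the Balding–Nichols model
$\mathrm{Beta}\!\left(p\frac{1-F}{F},\,(1-p)\frac{1-F}{F}\right)$, giving
pairwise Hudson $F_{st} \approx F$ between populations. Reference genotypes
are $\mathrm{Binomial}(2, p_{\mathrm{pop}})$; study dosages add truncated
Gaussian noise (sd 0.05) to genotypes to mimic imputation uncertainty and
are rounded to the 3 decimals written in the VCF, so the in-memory truth
equals the parsed file exactly. Per-variant imputation quality is drawn
high ($U(0.7,1)$) except for a configurable fraction below the 0.3
threshold. Defaults describe the conditions the test-suite benchmarks
assume: 7 populations at $F_{st} = 0.08$, 50 reference samples per
population, 2000 SNPs over 3 chromosomes — a desk-scale stand-in for the
938-sample HGDP panel. `simulate_scores()` layers score files on top
(random effect-allele orientation, optional strand-flipped entries, absent
positions, palindromic-only selections) together with a naive oracle score
matrix honouring every exclusion rule.

The generator deliberately omits linkage disequilibrium, within-population
substructure and real allele-frequency spectra. Two consequences matter for
interpreting green tests. First, real panels have correlated SNPs, so the
effective dimensionality and the PC noise floor differ; the shrinkage
correction's spiked-model assumptions hold only approximately there.
Second — and this one is visible in the acceptance suite — real HGDP super
populations are internally substructured (AFR spans Yoruba to San), which
spreads each reference cluster. A 50/50 admixed sample between two such
spread clusters usually acquires a mixed neighbourhood and falls below the
75% vote threshold. Between two *homogeneous* Balding–Nichols clusters,
the admixed sample's own binomial sampling noise almost always leaves it
slightly nearer one parent cluster, all 20 neighbours come from that
cluster, and the sample is confidently (mis)labelled: at the default
conditions only ~25–40% of simulated F1 admixtures come back
`UNCLASSIFIED`, across the whole $F_{st}$ range 0.03–0.12. The
corresponding acceptance expectation (a majority unclassified) therefore
fails honestly under this generator; the classifier itself is verified
separately against a brute-force K-NN oracle and recovers pure-population
labels at ≥99%.

# Numerical and design choices

* Sub-scores and final scores are plain double accumulation in a fixed
  order; no compensated summation (errors observed are $\sim 10^{-15}$
  relative at desk scale).
* Duplicate variant keys within one scoring file keep the first occurrence
  and warn; nothing in the published format defines which duplicate is
  authoritative.
* If several VCF records at one position match the same score variant
  (which should not occur after multi-allelic splitting), the first in
  file order is used, with a warning.
* When both a quality filter and a missing dosage would exclude a variant,
  the audit records `EXCLUDED_LOW_R2`; the quality check is cheaper and
  runs first. The score value is 0 either way.
* A score with zero coverage reports the value 0.0 with an explicit
  warning, so a structural zero cannot be read as a real score.
* Test problem sizes (hundreds of variants, tens of samples, 20-dataset
  sweeps; a 350-sample reference panel with 2000 SNPs for the ancestry
  benchmark) were chosen so the full suite exercises every code path —
  including region-indexed chunk streaming at 1 Mb granularity — while
  remaining comfortable to run locally.
* The convex-hull projection check uses 100 reference samples per
  population: the hull is estimated from the reference points themselves,
  and a hull over a few dozen points covers well under 95% of its own
  distribution's mass regardless of the projection's quality.

# Limitations

Phasing, imputation and genotype-probability (`GP`) handling are out of
scope: the package consumes imputed dosages. BGEN/PGEN inputs are not
read. Scores are applied, never trained. Mean-imputing a missing dosage by
allele frequency (as some tools offer) is deliberately not implemented —
the global missing-variant exclusion replaces it. Ancestry calls are
single-label; admixture proportions are not estimated, and as discussed
above, samples between reference clusters are flagged rather than
resolved.
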