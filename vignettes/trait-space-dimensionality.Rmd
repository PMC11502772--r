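---
title: "Methods: dimensionality and structure of sparse trait spaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dimensionality and structure of sparse trait spaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traitdims)
```

## The model

The package analyses a species × trait matrix `X` (n species, p traits, on
the log10, per-trait standardised scale) in which most entries are missing.
The object of interest is not `X` itself but the p × p Pearson correlation
matrix `R` of its columns and the spectrum of that matrix.

**Pairwise-complete correlations.** Each entry `R[i, j]` is estimated over
the species with both traits i and j observed, so every entry can rest on a
different species set. This makes maximal use of sparse data at a known
cost: `R` is not guaranteed positive semi-definite. The per-pair sample
sizes are carried alongside the coefficients (`pairwise_correlation()`),
and any pair below a configurable floor (`min_n`, default 3, the
mathematical minimum for a defined correlation — large compilations will
want a much higher floor) is an error rather than a silent NaN.

**Spectral dimensionality.** Eigendecomposing a unit-diagonal correlation
matrix is PCA on the correlation scale; the trace identity Σλ = p holds
regardless of definiteness and is enforced to 1e-8 in the tests. Two
summaries are derived from the spectrum:

* the **Kaiser count** — the number of eigenvalues strictly greater
  than 1, i.e. dimensions carrying more variance than a single
  standardised trait (ties at exactly 1 are excluded);
* the **effective number of dimensions** —
  `END = 1 / Σ (λ_i / Σλ)²`, the inverse Simpson diversity of the relative
  spectrum. END is continuous where the Kaiser count is coarse: it equals 1
  when all traits are perfectly correlated and p when all are independent,
  and it is invariant to uniform rescaling of the spectrum.

**The uncorrelated-trait null.** "Did adding these traits add a
dimension?" is calibrated against the change END undergoes when one
genuinely independent standard-normal trait is appended
(`null_uncorrelated_end()`, default 500 replicates with a recorded seed
and Monte Carlo standard error). Observed changes are then expressed as a
percentage of that reference (`proportional_increase()`); the percentage is
signed and may exceed 100 (more than one effective dimension gained) or be
negative (the additions concentrated the spectrum).

**Loading angles.** Trait relationships inside the reduced space are
summarised as angles between the traits' loading vectors over the retained
dimensions: association +1 maps to 0°, 0 to 90°, −1 to 180°. Two
conventions are implemented (see *Design choices*). Whole tables are
compared by correlating the upper-triangle angles of the traits shared by
two spaces (`compare_angle_tables()`, two-sided t-test on k − 2 degrees of
freedom).

**Phylogenetically-informed PCA.** On complete cases, with a phylogeny
whose tips match the species, the Brownian-motion generalised
least-squares machinery replaces the sample moments: ancestral mean
`a = (1ᵀC⁻¹1)⁻¹1ᵀC⁻¹X`, evolutionary covariance
`(X − 1a)ᵀC⁻¹(X − 1a)/(n − 1)`, where `C` is the matrix of shared
root-to-tip branch lengths. The default rescales to a correlation matrix
before eigendecomposition so the spectrum is comparable with the
non-phylogenetic spaces (trace p, Kaiser and END apply unchanged). On a
star tree with equal depths `C ∝ I` and the result coincides with ordinary
PCA to 1e-8 (tested). The assumptions are the usual ones: Brownian
evolution with a single rate matrix, no transformation of `C` (no
lambda/OU), non-singular `C`.

## Preprocessing

Raw trait values (all strictly positive, in registry units) are log10
transformed and standardised per trait over observed entries. The log base
is irrelevant to every downstream correlation; the standardisation uses the
population-SD convention (√n denominator), again irrelevant to
correlations, fixed only so transformed values are deterministic.

The outlier rule deletes observed entries with |z| > 4 on the standardised
log scale, re-standardises, and iterates to a fixpoint (max 10 passes), so
a second application removes nothing. The threshold is configurable; 4 is
conservative (about 0.6 expected deletions per 10,000 standard-normal
values). Whether outliers should be removed before or after per-species
averaging is left to the caller: `species_means()` is a separate utility,
and the two orders can be composed either way.

## The synthetic compilation

The generator exists so that every downstream stage has a testable input
with known truth. It emulates, in order of fidelity:

* **Block-correlated traits.** Twelve traits in four blocks — size
  (`ph`, `ssd`, `sm`, `Dr`, `Lr`), leaf economics (`la`, `ln`, `sla`),
  collaboration (`SRL`, `D`), conservation (`RTD`, `RN`) — with
  within-block correlation 0.7 and zero between blocks. This is the
  qualitative four-dimensional structure of the empirical space, with the
  two root-size traits deliberately placed in the size block (the
  hypothesis under test). The implied population spectrum is
  {3.8, 2.4, 1.7, 1.7, 0.3 × 8}: four Kaiser dimensions, END ≈ 5.6 for the
  ten-trait subset.
* **Heterogeneous completeness.** Defaults anchor the documented empirical
  values (seed mass 58.48%, plant height 34.16%, root tissue density
  3.46%, root nitrogen 3.13%) with plausible intermediates for the rest.
  Because the empirical study never estimated a correlation from fewer
  than 257 shared species, simulations far below the empirical n would
  otherwise enter a qualitatively different (much noisier) estimation
  regime; the default therefore floors each trait's expected observation
  count at 250 (`default_completeness(n, min_count = 250)`). At
  n ≈ 39,000 the floor is inactive and the fractions are exactly the
  anchored ones. The analysis scripts and tests use n = 3,000–10,000; the
  floor keeps the per-pair sample sizes of those runs in the empirical
  regime.
* **Co-observation structure.** Real compilations are built from separate
  databases, so traits of the same family are measured together and
  well-studied species are measured for everything. The `stratified`
  mechanism multiplies a lognormal per-species attention factor
  (sdlog 1.395, making cross-block overlaps about 7× the independence
  expectation — the excess implied by the documented minimum overlap) with
  a per-block campaign factor (sdlog 1.05), then calibrates each trait's
  inclusion probability numerically so realised completeness matches the
  request. A plain MCAR mechanism is also provided.
* **Strata and phylogeny.** Growth-form labels at the documented
  proportions (49.47% woody / 32.04% herbaceous / 18.29% unknown), and a
  unit-rate pure-birth tree for the phylogenetic variants. The tree is
  independent of the trait values unless traits are simulated with
  `simulate_bm_traits()`.

What the generator does **not** emulate: record-level structure (multiple
observations per species, unit heterogeneity), taxonomic noise,
value-dependent (MNAR) missingness, non-normal trait distributions, and
any phylogenetic signal in the default trait draw. Passing tests therefore
show that the machinery recovers known structure under realistic sparsity
— not that the empirical data satisfies these idealisations.

## Numerical choices

* **Eigen order and signs.** Eigenvalues descending; exact ties broken by
  the trait index of the eigenvector's dominant entry; within each
  eigenvector the largest-magnitude entry is made positive. Signs of
  eigenvectors are mathematically arbitrary, but the Pearson angle variant
  is *not* invariant to them (below), so a fixed convention is part of the
  method's definition here, not just cosmetics.
* **Indefinite spectra.** Negative eigenvalues from pairwise deletion are
  kept in the reported spectrum (preserving Σλ = p) and clipped to zero
  only where a square root or a proportion is required: loadings and END.
  The clipped mass is reported (`clipped_negative_mass`), and END can be
  computed from the raw spectrum with `clip = FALSE`.
* **Angle boundaries.** The association is clamped to [−1, 1] before
  `acos`, and values within 1e-12 of ±1 are snapped so identical
  (opposite) vectors give exactly 0° (180°).
* **Degenerate inputs.** Zero-variance loading vectors under the Pearson
  convention, all-zero vectors, asymmetric correlation inputs (beyond
  1e-10), non-PSD simulation targets, trait pairs under the `min_n` floor,
  and empty complete-case sets are all errors with diagnostic messages,
  never silent NA propagation.
* **Seeds.** Every stochastic entry point takes an integer seed;
  `run_space_suite()` fans one global seed out to per-space null seeds via
  a deterministic label hash (`derive_seed()`, kept below 2³¹), and each
  record stores the seed it used. Re-running with the same configuration
  reproduces every number bit-for-bit (tested).

## Design choices that were genuinely open

* **Loadings.** Reported as eigenvector × √λ — the correlation between
  trait and dimension — with `loading_type = "eigenvector"` available,
  since published loading tables do not always state the convention.
* **Pearson versus cosine angles.** The figure-caption definition
  (correlation of loading vectors) is the default. But loading vectors are
  short (as many entries as retained dimensions, typically 2–4) and
  uncentred; centring them costs a degree of freedom and breaks sign-flip
  invariance. Empirically (analysis stage 3), the cosine convention gives
  angle correlations ≥ 0.99 across root-size inclusion levels of the same
  trait set (≥ 0.89 including cross-set comparisons) where the Pearson
  convention ranges 0.67–1.00 on the same spaces, and cosine angles
  between independent blocks sit near 90° where Pearson ones can
  exceed 120°.
  The cosine variant also satisfies an exact identity: over *all*
  dimensions of a complete-data space, cos(angle) reproduces the original
  correlation matrix (tested to 1e-8). The Monte-Carlo property tests
  therefore assert the geometry on the cosine convention; the published
  angle/correlation pairs are themselves mutually inconsistent with a
  single convention, and both are first-class here.
* **Null-trait coverage.** The simulated uncorrelated trait is observed
  for every species (the literal published procedure); a `completeness`
  argument subsamples it to a realistic coverage instead, since a fully
  observed column is mildly conservative relative to the sparse real
  columns.
* **Phylogenetic mode.** `"correlation"` by default for comparability
  across the twelve spaces; `"covariance"` (the reference
  implementation's default) provided. No lambda transformation.
* **Null replicates for the phylogenetic estimator.** The PPCA refit is
  the expensive step, so `analysis/05_phylo.R` uses a single replicate per
  space, as the empirical robustness analysis did; the function accepts
  any `reps`.

## Problem sizes

The test suite and the acceptance checks run the generator at
n = 1,500–3,000 species (40 seeds for the Kaiser-retention rate, 10 for
the END dichotomy, 100–200 null replicates; 200-tip trees and 50 seeds for
the Brownian-motion recovery), and the analysis scripts at n = 10,000 with
the full 500-replicate nulls. These sizes were chosen so each property is
measured comfortably inside its Monte Carlo error; all of them scale
linearly in n and reps if larger runs are wanted.

## Known limitations

* Pairwise-complete correlation matrices are not guaranteed consistent
  (entries estimated from different species sets can be jointly
  impossible); indefiniteness is reported, not repaired, and no
  imputation-based alternative is offered.
* The Pearson angle convention depends on the eigenvector sign convention;
  comparisons should never mix conventions (and `compare_angle_tables()`
  refuses to).
* The phylogenetic estimator requires complete cases and a non-singular
  phylogenetic covariance; near-zero internal branches can make `C`
  ill-conditioned.
* Growth-form stratified analyses inherit whatever overlap the stratum
  leaves; sparse strata legitimately fail per space (recorded, not fatal).
* The generator's defaults are a stylised stand-in for one particular
  compilation; conclusions about other trait sets need their own block
  structure and completeness profile.
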