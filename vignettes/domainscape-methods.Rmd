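---
title: "domainscape: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{domainscape: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the statistical machinery inside `domainscape`, the
assumptions it rests on, and the choices made where the underlying
procedures are conventionally under-specified.  It states no empirical
result that the package's tests do not themselves compute.

## 1. The broad-domain HMM

Broad repressive marks such as H3K9me2 form megabase-scale domains with
modest per-bin enrichment, so peak callers built for sharp marks are a poor
fit.  `domainscape` models the genome as a two-state hidden Markov chain
over fixed 2-kb bins: a *depleted* state emitting counts as Poisson(λ_d)
and an *enriched* state emitting Poisson(λ_e), λ_e > λ_d.

**Preprocessing order.**  Raw bin counts are (1) depth-normalised by
`× 30,000,000 / library size`, (2) rounded to integers, (3) capped at
`max_count = 150`.  Normalising *before* capping is deliberate: the cap is
meant to neutralise artifact pileups on a common count scale, so it must be
applied after libraries are made comparable.  The cap value is the
conventional setting for this class of caller; it matters because tandem
repeats (pericentromeric satellite, rDNA) accumulate reads far above any
biological domain level and would otherwise hijack the enriched state.

**Emission model.**  Poisson emissions on rounded, capped, normalised
counts.  Poisson is the minimal count model consistent with an explicit
outlier cap; biological overdispersion beyond Poisson is largely absorbed
by the cap and by the domain-scale (not bin-scale) decoding target.  A
negative-binomial emission would add a dispersion parameter per state but
changes nothing structural; it was not needed to meet any validation
property and is left out to keep the fit deterministic and fast.

**Fitting.**  Baum–Welch with a fixed, data-driven initialisation — λ_d at
the 25th and λ_e at the 90th percentile of non-zero bins, self-transitions
0.9, uniform initial-state probabilities — so the fit has no random
component.  Convergence: relative log-likelihood change below 1e-6, at most
500 iterations.  The log-likelihood trace is retained and is asserted
monotone in the tests.  States are re-ordered after fitting so state 2
always carries the larger mean; a fit whose two means collapse (within
1e-6 relative) is flagged *degenerate*.  Only complete bins enter fitting
and decoding; the partial terminal bin of a chromosome is counted in I/O
but never modelled.

**Cross-chromosome pooling.**  Parameters are fitted per chromosome and
then arithmetically averaged over non-degenerate fits (transition rows
renormalised); decoding uses the pooled parameters everywhere.  The reason
is identifiability: on a chromosome with almost no true domains the
enriched state has nothing stable to attach to.  The failure mode is
concrete and reproduced in the acceptance suite: when such a chromosome
carries a capped satellite array, the local EM's enriched state converges
onto the capped bins (λ_e ≈ 150).  Under that fit a genuine domain bin with
counts near 30 is *more* likely under the background state
(30·log(λ_e/λ_d) < λ_e − λ_d once λ_e exceeds ≈ 128 at λ_d ≈ 2), so the
true domains are decoded as depleted and essentially no domain bp is
called.  The pooled parameters, dominated by domain-rich chromosomes, call
the same domains cleanly.  This is also why the satellite/domain balance in
the pooling test uses a 400-kb array: a smaller array puts the local
enriched mean exactly at the likelihood crossover, where EM splits the
domain bins between states and the contrast between local and pooled
decoding is undefined rather than diagnostic.

**Decoding.**  Forward–backward posteriors; a bin is enriched when the
enriched-state posterior is at least `posterior_threshold = 0.9`.  The
threshold is intentionally strict: broad-domain analysis wants contiguous
regions, and 0.9 suppresses isolated single-bin excursions (a property the
tests check exactly against brute-force path enumeration).  Maximal
enriched runs are merged into domains; no gap-bridging is applied, because
the chain's transition stickiness already smooths over single noisy bins.

**Input controls.**  Domain calling operates on treatment tracks only.  No
input-subtraction term appears in the procedure this caller follows, and
adding one would change the meaning of λ_d; the cap plays the
artifact-suppression role an input track would otherwise play.

## 2. Differential domain loss

For each reference-condition domain, reads are counted in both conditions
(border bins pro-rated), scaled to a common 10 M depth, and tested:
*lost* requires a fold change `ref/target ≥ 4` **and** a lower-tail Poisson
probability `P(X ≤ target | λ = ref) ≤ 1e-4`.  Both thresholds follow the
established differential-enrichment convention for this analysis; the
Poisson tail uses the floor of the (non-integer) normalised target count,
which makes the rule monotone in the target count — a property the tests
verify.  Domains with zero reference reads are untestable and stay
`unassigned` with a warning.  Reference domains that overlap (≥ 1 bp) an
independently called target-condition domain and are not lost become
`conserved`.

## 3. Compartment scores

Raw intrachromosomal matrices are balanced by symmetric diagonal scaling
(`d_i ← d_i / sqrt(rowsum_i)` iterated), which converges on symmetric
non-negative matrices to the same fixed point Knight–Ruiz targets; rows
with fewer than 10 non-zero contacts are masked first, the tolerance is a
1e-8 maximum relative row-sum deviation, and non-convergence within 3000
iterations is a hard error with the residual reported.  Balanced values are
divided by the mean balanced contact at each genomic distance
(observed/expected); distances with no unmasked pairs stay masked.

The compartment score is the first principal component of the Pearson
correlation matrix of O/E columns over scorable bins, scaled by the square
root of the leading eigenvalue.  The eigenvalue scaling (rather than a
unit-norm eigenvector) keeps score magnitudes comparable across chromosomes
of different bin counts and produces the small per-bin magnitudes typical
of published compartment tracks; it is a convention choice and does not
affect signs or orderings.  The sign of a principal component is arbitrary,
so each chromosome is oriented by correlation against a caller-supplied
reference (gene density on real data; the planted A-label indicator in
tests).  An exactly zero or undefined correlation is an error asking for a
different reference, not a silent guess.  Sex chromosomes are excluded from
scoring.  Scores computed on 100-kb bins can be carried onto other grids
(e.g. 80-kb ChIP bins) by coverage-weighted projection (`project_bins`).

Per-bin compartment changes are classed by score sign (`A->A`, `B->B`,
`A->B`, `B->A`); a score of exactly zero counts as B, which is immaterial
in practice since scores are continuous.

## 4. Recovery timing

RPKM of 10-kb bins is z-scaled per sample over autosomal bins with the
population (divide-by-n) standard deviation; the choice of population vs
sample SD is numerically irrelevant at genome bin counts but is fixed for
determinism.  A bin is *early* / *middle* / *late* when its z-score rises
by `delta = 0.3` or more (relative to 0 h) at 32 h / 48 h / 72 h, testing
times in that order so the earliest qualifying time defines the class;
*none* otherwise.  When several thresholds are met the earliest wins — the
alternative (latest wins) would make the classes non-nested in time and is
hard to defend.  Class-mean curves are compared only among bins whose
untreated z lies in [0.5, 0.7] so that classes end at matched mark levels.
The two-proportion chi-square used for class-enrichment tests is the
pooled-variance statistic; the Yates continuity correction is **off** by
default (exposed as a flag) so that the statistic equals the textbook
chi-square that the tests cross-check to 1e-10.

## 5. Gene selection and integration

Promoter windows are the symmetric `[TSS − 500, TSS + 500)`; the TSS comes
from BED6 strand (start for `+`, end − 1 for `-`).  The RPKM bounds (> 1 in
inhibitor-treated wild type, < 1 in the treated knockout, < 1 for H3K9me3
everywhere) are strict inequalities; inclusive bounds would differ only on
a measure-zero set of exact-1 values.  Selection is a pure conjunction of
the four criteria, so relaxing any one (e.g. the H3K9me3 ceiling) can only
grow the set — a monotonicity property the tests assert.

The integration join is per 100-kb bin over bins scored in both conditions.
Grouping edges default to −0.01/0/0.01 for score changes and
−0.5/−0.25/0 for domain-fraction changes: only the focal cuts (≥ 0.01,
< −0.5) are established convention; the interior edges are this package's
defaults and are configurable and labelled in output.  Group means are
compared by Tukey's HSD on an equal-variance ANOVA, with the focal group
additionally contrasted against all remaining bins.  The compartment shift
at upregulated genes uses the bin containing the TSS, a random background
of equal size drawn with a recorded seed from the non-upregulated genes,
and a one-tailed equal-variance two-sample t test (upregulated >
background).

## 6. The synthetic world

The generator emulates a small slice of a mammalian genome so every stage
can be validated against planted truth:

* **Slice-plus-library convention.**  Chromosomes (default 3 × 20 Mb) are a
  contiguous slice of a ~2.7-Gb genome sequenced at `library_size = 30 M`
  reads.  Bin counts are drawn at per-bin rates (λ_d = 2, λ_e = 30 per 2-kb
  bin) while `total_reads` carries the library size.  This keeps RPKM and
  the ×30 M normalisation on the realistic scale — a promoter planted at
  λ = 120 per 2 kb has RPKM ≈ 2, background ≈ 0.03 — which is what makes
  the literature's "RPKM 1" thresholds meaningful at desk scale.  Scaling
  the slice's total counts instead would inflate RPKM ~45-fold and no fixed
  threshold could be realistic.
* **Compartments.**  Alternating A/B blocks with exponential lengths (mean
  2 Mb, floored at one 100-kb bin; the first block is capped at 60 % of the
  chromosome so both compartments always occur, as on real chromosomes).
  Contacts decay as `max(d,1)^(-α)` with α = 1 and a same-compartment boost
  1 + δ, δ = 0.5, ~100 expected contacts at one-bin distance; counts are
  Poisson and symmetric.
* **Domains.**  Placed with target coverage 0.45 in A and 0.85 in B
  (minimum 10 bins, mean 20, per-domain strength jitter ±30 %), mirroring
  the B-compartment preference of broad H3K9me2.  Per-condition retention
  probabilities emulate compartment-dependent removal: the G9a/GLP
  inhibitor leaves B domains more intact than A; the inhibitor-plus-Setdb1
  knockout strips A almost completely.  Retention draws are independent
  between conditions — a simplification; nested retention (knockout losses
  a superset of inhibitor losses) would be more mechanistic but changes no
  tested property.
* **Satellite.**  One 100-kb pericentromeric-style array per chromosome
  (Poisson rate 200 per 2-kb bin, saturating the 150 cap).  Real assemblies
  contain few such bins, which is why the default array is small: a large
  array would also dominate the z-scale of the recovery analysis in a way
  real (mostly satellite-free) assemblies do not.
* **Coupling.**  B bins whose planted domain coverage drops by more than
  0.5 in a condition flip to A with probability 0.8; genes whose promoter
  mark or covering domain is lost are upregulated with probability
  `p_up_null + coupling_up` (0.02 + 0.78), log2 fold changes ~N(4, 1);
  setting `coupling_up = 0` yields the null world used for p-value
  calibration.
* **Recovery.**  Bins overlapping inhibitor-resistant (residual) domains
  recover first (onset 24 h); other bins with recoverable domain material
  draw middle (40 h) / late (64 h) / never onsets; recovery follows a
  logistic ramp (~8 h width).  Bins with only one-fifth of a 10-kb bin
  recoverable sit on domain edges and are intrinsically borderline against
  a 0.3 z threshold; they are planted as `ambiguous` and excluded from
  accuracy scoring, since no classifier can be right about them by
  definition.  Strength jitter is disabled in the recovery tracks so
  classes separate by onset, not by plateau.

**What a green test does and does not establish.**  The generator plants
exactly the structures the pipeline looks for: Poisson counts, block
compartments, step-function domains.  Passing tests demonstrate that the
implementation recovers planted truth under its own model assumptions and
that every decision rule matches its independent oracle; they do not
demonstrate robustness to mappability bias, copy-number variation,
replicate disagreement, overdispersion beyond the cap, or TAD-scale Hi-C
structure, none of which are simulated.

## 7. Numerical choices and degenerate inputs

* Baum–Welch: tolerance 1e-6 (relative), ≤ 500 iterations, fixed
  percentile initialisation; emission means floored at 1e-10 inside the
  likelihood so an all-zero state cannot produce 0/0.
* Balancing: tolerance 1e-8, ≤ 3000 iterations; zero row sums on kept bins
  (reducible matrices) are a hard error.
* All-zero tracks, zero-variance z-scaling inputs, empty domain sets,
  constant O/E matrices, and orientation references uncorrelated with PC1
  are hard errors, not silent results.
* Reads are assigned to bins by midpoint (`floor((start+end)/2)`), with
  border midpoints going to the right-hand half-open bin — unbiased for
  reads spanning bin borders.
* All internal coordinates are 0-based half-open; BED/bedGraph conventions
  are preserved on disk; contact matrices travel as per-chromosome sparse
  COO text with a `#bin_size=... chrom=...` header.
* Every random draw in the generator flows from one master seed through
  deterministic per-stream sub-seeds (all below 2^31), so outputs are
  byte-reproducible.

## 8. Known limitations

* The Poisson emission model understates biological overdispersion; the
  count cap compensates only at the high end.
* Compartment scores from correlation-matrix PC1 are unreliable on very
  short chromosomes (fewer than ~20 scorable bins) and near masked runs.
* The recovery classifier is a thresholded difference, not a kinetic fit;
  bins with noisy baselines near the threshold will flicker between
  classes, which is why borderline synthetic bins are labelled ambiguous.
* Differential loss assumes count proportionality between conditions after
  a single global depth factor; copy-number differences would violate it.
* The 80-kb/100-kb grid reconciliation is a coverage-weighted projection;
  it slightly smooths scores at block boundaries.
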