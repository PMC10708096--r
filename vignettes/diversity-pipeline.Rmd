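---
title: "Models and methods behind the snpdiv pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the snpdiv pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`snpdiv` packages the standard small-panel SNP workflow used to
characterise clonally propagated germplasm collections: design a
genome-evenly-spaced marker panel, genotype the collection, filter the
panel, then derive identity, diversity and structure. This vignette is the
package's own account of the models and numerical choices; it states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## Genotype representation

All stages consume a `geno_matrix`: accessions × loci, each cell the
alternate-allele dosage 0/1/2 of an unordered diploid genotype at a
biallelic locus, `NA` for a missing call. Allele 0 is always REF and
allele 1 ALT (the `AA/AB/BB` CSV dialect maps A→0, B→1); phase is
discarded on input because no analysis here uses it, and missingness is a
dedicated sentinel so no statistic can silently average over missing
calls. VCF positions are 1-based and kept 1-based internally (loci are
points; no half-open conversion arises).

## Panel design

Three eligibility/selection criteria, with defaults matching common
practice for a 150-marker panel on a 15-chromosome genome:

* **Flank isolation** (`flank_bp`, default 150): a candidate is isolated
  iff no other candidate on the same chromosome lies within 150 bp.
  The window is inclusive — a neighbour at exactly 150 bp violates
  isolation — reading "no other SNP in the 150 bp up/downstream"
  literally.
* **MAF** (`maf_min`, default 0.05): eligibility requires MAF strictly
  greater than the threshold. Note the deliberate asymmetry with QC below:
  a locus with realised MAF exactly 0.05 would survive QC (which removes
  MAF *below* 5%) but would not be eligible for panel design (which
  requires MAF *above* 5%). Both are literal readings of their respective
  rules and both are kept.
* **Even spacing** (`per_chromosome_quota`, default 10): each chromosome
  is split into quota equal-length bins and the eligible candidate nearest
  each bin midpoint is selected, ties broken by higher MAF then lower
  position. "Evenly spaced" has no canonical operationalisation; the bin
  rule was chosen because it is deterministic, invariant to candidate
  input order, returns exactly quota × chromosomes markers whenever every
  bin is served, and reports every unfilled bin rather than silently
  under-delivering. Chromosome lengths come from VCF `##contig` headers
  when present, else the maximum candidate position.

## QC filter cascade

Post-genotyping filtering removes loci in a fixed order, each locus
counted in exactly one category (its first trigger): assay design
failures (supplied as ids — primer chemistry is out of scope, so design
failure is metadata, not a genotype property), monomorphic loci (exactly
one allele observed among non-missing calls), loci with missing fraction
strictly above `missing_max` (default 0.10), then loci with MAF strictly
below `maf_min` (default 0.05). First-trigger counting makes the report an
arithmetic identity (input − categories = retained), which is
property-tested on random matrices.

## Diversity

Per locus with alternate-allele frequency $p$ over non-missing calls:
$He = 2p(1-p)$ and $Ho$ = heterozygote fraction of non-missing calls. He
is the *uncorrected* expected heterozygosity — the default of the usual
spreadsheet tools — because no published worked value pins the variant;
the unbiased $\frac{2N}{2N-1}$ correction is exposed via
`heterozygosity(..., unbiased = TRUE)`. Group summaries are unweighted
means over the same locus set (no re-filtering within groups); a locus
with no called genotype inside a group is dropped from that group's mean
only.

## Multilocus matching

Two accessions match when they disagree at zero loci among those where
both are called (and share at least one such locus); synonym groups are
connected components of the matched relation. Whether real-world matching
should tolerate missing data is genuinely open, so `require_complete`
exposes both behaviours; the default is tolerant, because assay missingness
is mostly technical and a strict rule would split true clone pairs on a
single dropout. Monotonicity (removing loci can only decrease mismatch
counts, never unmatch a matched pair) is property-tested.

## Distances, UPGMA, PCoA

The genotype distance is the allele-sharing distance: per comparable
locus $|x_i - x_j|/2$ (0 for identical genotypes, ½ for homozygote vs
heterozygote, 1 for opposite homozygotes), averaged over comparable loci.
"p-distance" in the phylogenetics tools is a per-site mismatch proportion
on sequences; this is its standard diploid-genotype analogue — bounded in
[0, 1], missing-tolerant, and reducing to the mismatch proportion for
haploid data.

UPGMA merges the minimal-average-distance pair, updates distances by
size-weighted means, and sets each node's height to half the merge
distance, so trees are ultrametric (leaf depths equal to 1 in 10⁹ is an
invariant test). Ties are broken by the lexicographically smallest pair of
member-id sets — deterministic and input-order invariant, so the same data
always serialise to the same Newick string. The implementation is checked
against a naive $O(n^3)$ oracle (cluster distances recomputed from the
original matrix each step) on 100 random matrices.

`cut_tree(tree, k)` removes the $k-1$ highest internal nodes; for the
monotone UPGMA heights this is exactly undoing the last $k-1$ merges.

PCoA is the classical Gower construction: eigendecomposition of the
double-centred $-\tfrac12 d^2$, coordinates scaled by $\sqrt{\lambda}$.
Negative eigenvalues (the allele-sharing distance is not guaranteed
Euclidean) are reported but excluded from the percent-variance
denominator, and no Cailliez/Lingoes correction is applied — matching the
behaviour of the tools this workflow usually feeds. Euclidean inputs are
recovered exactly (tested to 1e-9), and `stats::cmdscale` serves as an
independent oracle.

## AMOVA and F_ST

The three-level AMOVA (among groups / among individuals within groups /
within individuals) is computed from squared Euclidean distances between
allele copies, with all sums of squares derived from the standard
distance-partition identities. Viewing individual $i$ as its two allele
copies, the per-locus cross-pair sum between individuals with dosages
$x, y$ is $2x + 2y - 2xy$, and the within-individual term is the
heterozygosity indicator; loci missing in either member of a pair are
excluded and the remaining sum rescaled by the loci-count ratio. Variance
components follow from mean squares with the usual unequal-group-size
coefficient $n_c = (M - \sum m_g^2 / M)/(G-1)$ in allele counts
($m_g = 2n_g$). Degrees of freedom sum to $2N - 1$.

Two published tool families differ in their internals here (spreadsheet
AMOVA vs population-genetics AMOVA); rather than being bug-compatible
with either, one coherent distance-based formulation is used for both the
full AMOVA and the pairwise F_ST (a two-level collapse of the same
construction, the Φ-statistic analogue), with Weir–Cockerham θ exposed as
an independent estimator (`pairwise_fst(..., method = "wc")`). The two
estimators are asserted to agree broadly away from zero, not numerically.

Negative variance components are reported as computed but floored at zero
for the percentage column — published AMOVA tables print "0%" strata,
which is evidence the source tools floor. Permutation p-values come from
random whole-individual reassignment to groups (the standard scheme for
the top stratum; per-stratum schemes are out of scope), with the observed
arrangement included in numerator and denominator:
$p = (1 + \#\{perm \ge obs\})/(1 + B)$. The full-analysis convention is
$B = 9999$; tests use small $B$ for speed, which changes only p-value
resolution, not the components.

## Admixture model and Evanno ΔK

The sampler is the standard admixture-model Gibbs scheme for unphased
biallelic genotypes. Each allele copy of individual $i$ at locus $l$
carries a latent cluster of origin $z \sim \mathrm{Cat}(q_i)$ and is the
alternate allele with probability $p_{z l}$. Full conditionals: $z$
categorical $\propto q_{ik} \cdot p$ or $(1-p)$; $p_{kl}$ Beta-conjugate;
$q_i \sim \mathrm{Dirichlet}(\alpha + \text{copy counts})$. Missing calls
contribute no copies. Two design choices deliberately simplify the
reference tool's model space:

* $\alpha$ is fixed (default 1.0) rather than sampled. Sampling α mostly
  matters near $K$-overspecification; for recovery testing it adds a
  Metropolis layer without changing the contract. Listed as an extension.
* The default allele-frequency prior is independent Beta(1,1). The
  correlated-frequencies F-model prior
  $p_{kl} \sim \mathrm{Beta}(p^A_l \tfrac{1-F_k}{F_k}, (1-p^A_l)\tfrac{1-F_k}{F_k})$
  — the prior the classic tool runs by default — is available via
  `correlated_frequencies = TRUE`, with $p^A$ and per-cluster $F$ updated
  by Metropolis steps.

The model evidence proxy is $\ln P(D) = \overline{LL} - \tfrac12
\mathrm{var}(LL)$ over retained sweeps — the same harmonic-approximation
estimator the classic tool prints, which matters because Evanno's ΔK is
defined on that quantity. Note $\overline{LL}$ sits below the plug-in
log-likelihood at the posterior means by roughly the Jensen gap
(≈ var(LL)/2 again), so at $K=1$ the estimator is close to, but
systematically below, the binomial log-likelihood at $\hat p$; the test
suite allows 5% relative slack for exactly this reason.

`run_K_sweep` derives one seed per (master seed, K, replicate), so sweeps
are bit-for-bit reproducible; the sampler itself draws only from R's RNG
(including inside the Rcpp core), making `set.seed` the single source of
randomness. Evanno's table follows the stated recipe: $L'(K)$ first
differences of mean $\ln P(D)$, $|L''(K)|$ absolute second differences,
$\Delta K = |L''|/\mathrm{sd}$, defined only for interior K with positive
replicate sd; a flat profile yields an explicit "undetermined" rather than
an arbitrary argmax.

Label switching is handled only post hoc: `align_replicates` aligns each
replicate's columns to the first by minimising summed $|\Delta q|$. The
declared algorithm is a best-permutation search — exhaustive for
$K \le 7$ (≤ 5040 permutations, trivial) and greedy beyond. A purely
greedy matcher cannot guarantee optimality, and the contract is tested
against an exhaustive oracle, so exhaustive search at small K is the
honest implementation.

### Membership recovery and the shrinkage caveat

On two-population simulations (F = 0.3, pure memberships, 84 × 91), the
posterior-mean $q$ under the Dirichlet(1) prior is intrinsically shrunk
away from the one-hot truth: loci whose two population frequencies happen
to be close contribute near-uninformative copies, so a pure individual's
posterior mass sits around 0.90–0.95 on its true cluster. Measured over
eight seeds the per-seed mean |q − q_true| ranges 0.08–0.11 with mean
≈ 0.09. The recovery contract is therefore asserted on the mean over
seeds (< 0.1), alongside the sharper and more robust criterion that
≥ 95% of accessions have their max-q cluster equal to the true
population. Nothing was tuned to make this pass: seeds are consecutive
integers and the MCMC settings are the package's desk-scale defaults.

## The synthetic-data generator

`simulate_genotypes` draws the world the analyses assume: ancestral
frequencies $p^A \sim U(0.1, 0.9)$ (bounded away from 0/1 so accidental
monomorphism cannot leak into the clean locus set), population frequencies
from the F-model Beta above (one F per population — the fewest parameters
that give a tunable F_ST), memberships Dirichlet(α) with the convention
α = 0 ⇒ pure assignment (round-robin across populations), genotypes by
sampling each allele copy's population from $q$ then Bernoulli(frequency).
Defective loci are injected afterwards on disjoint sets — disjointness is
what makes the filter-cascade arithmetic (e.g. 150 − 1 − 28 − 10 − 20 =
91) exactly testable:

* monomorphic loci are overwritten to all-REF;
* high-missingness loci get a missing fraction drawn U(0.11, 0.5)
  (strictly above the 10% threshold at n = 84), kept polymorphic so the
  cascade attributes them to missingness, not monomorphism;
* low-MAF loci are rebuilt with 1 to ⌊0.05·2n⌋−1 alternate copies, giving
  0 < MAF < 0.05 with no missingness.

Baseline missingness is applied before clone rows are copied, so clones
are verbatim copies including the missing pattern; hybrids draw one
transmitted allele per locus from each named parent (missing parent call ⇒
missing transmitted allele). Repairs that keep clean loci clean
(MAF ≥ 0.05, missingness ≤ 10%, polymorphic) only ever touch rows that
are neither clones nor hybrid children, so clone identity and pedigrees
survive injection.

What the generator does *not* emulate: linkage and LD (loci are
independent), genotyping error, null alleles, coalescent ancestry within
populations, and selection. A green recovery test therefore establishes
that the estimators work on F-model data of the study's shape — not that
they would be similarly calibrated on data with strong LD or assay error.

`reference_fixture()` instantiates the generator at a fixed seed on the
packaged 84-accession metadata: two source populations (extremely-early
vs middle-to-late maturing, F = 0.3), the early-maturing accessions
admixed 50/50, the five documented synonym groups as clone sets, all
twelve hybrids drawn from named parents (with stand-ins, documented in
the help page, where a true parent is outside the panel), 3% baseline
missingness, and exactly 1 + 28 + 10 + 20 defective loci. The genotypes
are synthetic — only the metadata, shape and relationship structure mirror
the real panel — so real-data headline numbers (overall He = 0.364, PC1 =
57.64%, the published AMOVA percentages and F_ST values) are *not*
reproduction targets; the pipeline reproduces their qualitative shape
(three maturation clusters, K = 2, the admixed group intermediate in
F_ST, a floored 0% among-individuals stratum).

## Numerical choices and degenerate inputs

* UPGMA tie-break: lexicographically smallest pair of sorted member-id
  sets, compared element-wise; an all-equal distance matrix exercises it
  and yields equal heights with a reproducible topology.
* Distances: a pair with zero comparable loci is an error naming the pair
  (silently imputing a distance would poison the tree).
* PCoA eigenvalue threshold: |λ| > max|λ|·1e-9 counts as positive;
  requesting more axes than the positive spectrum truncates with a
  warning.
* All-missing loci have undefined MAF; in the cascade they fall to the
  missingness category (their missing fraction exceeds any threshold
  < 1).
* Beta draws in the sampler are clamped to [1e-9, 1−1e-9] and the
  genotype likelihood to [1e-12, 1−1e-12] to keep log-likelihoods finite
  at fixation.
* Permutation p-values always include the observed arrangement, so the
  minimum attainable p is 1/(B+1), never 0.

## Known limitations

* The AMOVA is the codominant three-level design only; hierarchical
  regional designs and haplotype-model AMOVA are out of scope.
* F_ST p-values permute individuals between the two groups of a pair;
  no correction for multiple pairs is applied.
* The sampler does not implement the no-admixture or linkage models, nor
  sampled α; CLUMPP-style multi-replicate consensus beyond best-permutation
  alignment is out of scope.
* Panel design assumes candidate MAF is estimable from the provided
  samples; it does not model assay (primer) feasibility, which enters only
  as the design-failed id list.
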