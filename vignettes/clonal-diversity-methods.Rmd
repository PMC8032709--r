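---
title: "Methods: somatic-SNV consensus filtering and clonal-lineage inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: somatic-SNV consensus filtering and clonal-lineage inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonediv)
```

## Scope and model

`clonediv` analyses intra-cultivar (clonal) genetic diversity from somatic
single-nucleotide variants. The data model assumes a clonally propagated,
highly heterozygous crop: every accession descends from one founder
genotype, differences among accessions arise only from somatic mutations
(and occasional loss of heterozygosity), and the reference genome is
effectively homozygous at every site, so the founder's heterozygous sites
appear as cultivar-level SNPs in all clones while somatic events appear as
clone-distinguishing SNVs.

The canonical design the package targets is a panel of four resequenced
clonal accessions — two with a long propagation history in one region
(MB53, MB59), one transferred recently (C225) and one never transferred
(C143) — followed by a custom genotyping chip applied to a cohort of around
two hundred accessions.

## The consensus filter

Somatic variants are overwhelmingly heterozygous, which is exactly the
genotype class most prone to false positives. The retention logic therefore
stacks several independent defences:

* **Three-caller intersection.** A variant is kept only when three callers
  report the same site key (chrom, pos, ref, alt) *and* the same genotype in
  every clone. We read "identified by all three callers" as agreement on the
  call, not mere positional overlap: a positional-only rule would let one
  caller's genotype error through on the strength of the other two.
* **Depth window** DP ∈ [15, 150]: the lower bound controls binomial noise
  in VAF, the upper bound removes collapsed repeats.
* **VAF genotype windows** VAF(Ref) ≤ 0.025, VAF(Het) ∈ [0.25, 0.75],
  VAF(Hom) ≥ 0.95. The gap zones (0.025, 0.25) and (0.75, 0.95) are
  `ambiguous`; a site with any ambiguous clone fails as a whole (the filter
  operates on sites, not on individual genotypes). The heterozygous window
  is a deliberate chimerism dial: with the L1 meristem layer contributing
  about 40 % of somatic tissue, an L2-confined heterozygous mutation has
  expected VAF 0.5 × 0.6 = 0.3 (inside the window) while an L1-confined one
  has 0.5 × 0.4 = 0.2 (outside). Losing L1-only mutations is accepted as a
  trade-off for a low false-positive rate.
* **Bias tests.** Strand bias: two-sided Fisher exact test on the 2×2
  ref/alt × forward/reverse table. Read-position ("distance") bias:
  two-sided Wilcoxon rank-sum test comparing alt- versus ref-supporting
  read offsets (exact for small untied samples, normal approximation with
  continuity correction otherwise). Sites with p ≤ 1e-4 in either test are
  *discarded*. The significance level is stated as "P ≤ 0.0001" in the
  conventions this filter follows; discarding at the boundary (≤ rather
  than <) is our choice — retaining significantly biased sites would defeat
  the purpose of the test. A clone with no alt-supporting (or no
  ref-supporting) reads carries no positional signal; the bias test is
  treated as inapplicable there rather than failed.
* **Read edit-distance budget**: one mismatch per 25 bases,
  `edit ≤ floor(length / 25)`; a zero-length read has no budget and fails.

Every failing site carries machine-readable reasons (`depth_low`,
`vaf_ambiguous`, `strand_bias`, ...), and pass/fail partitions the input —
both properties are enforced by tests.

## Variant classes

For a four-clone panel, `classify_site()` maps each per-clone genotype
vector to: **SNP** (one shared non-reference genotype), **SC_het** (one
heterozygous clone, three homozygous-reference), **SC_ref** (one
homozygous-reference clone, three sharing a heterozygous genotype),
**SC_hom** (one homozygous-alternative clone, the other three sharing one
state), **Sh_het/Sh_hom** (2+2 splits into two states, the focal pair being
the one carrying the more alternative state), and **complex** otherwise.
Two design points were genuinely open:

* For SC_hom we require the three background clones to share *one* state;
  a mixed background (e.g. het, het, hom_ref) is `complex`. Every worked
  pattern in the source material shows two states per site, and a strict
  rule is auditable; it may undercount relative to a permissive reading.
* Two-state 3+1 patterns that match no named class (e.g. one het against
  three hom_alt) are `complex` rather than force-fitted.

The classifier is verified against an exhaustive, independently written rule
table over all 3^4 = 81 genotype patterns.

## Panel design

Chip markers must be assayable: only heterozygous-alternative variants
(`SC_het`, `Sh_het`) qualify, and each candidate's ~600 bp window must be
free of neighbouring variants near the target and near both window ends
(primer/probe annealing zones). The clearance distance is not documented in
the source conventions; we default to 50 bp, exposed as `clear_window_bp`,
with an exclusive boundary (a neighbour exactly at the distance passes).
SC quotas are balanced across focal clones; Sh markers are prioritised when
their focal pair separates the two propagation lineages; chromosome spread
is implemented as a greedy round-robin (a soft constraint — the stated
intent is spread, not an algorithm).

## Genotype collapsing and the median-joining network

Multilocus genotypes (MLGs) collapse identical marker profiles. Under the
default `match_any` missing policy a missing entry matches any state and the
genotype's consensus profile is filled from new members — a greedy,
input-order-deterministic merge; `strict` requires identical missingness.
Multi-sample genotypes are named A, B, C, ... by descending frequency;
singletons keep their sample name.

The network treats each marker as one multistate character with states
{0, 1, 2}; distances are Hamming steps, and a 0↔2 difference counts as
**one** step by default (character-state semantics, matching how unphased
multistate columns are handled by standard network software); a
`dosage_steps` flag counts it as two. The ε-relaxed minimum spanning
network keeps an edge (u, v) iff d(u, v) ≤ bottleneck(u, v) + ε, where the
bottleneck (minimax-path) distance is computed as the single-linkage
cophenetic height — the component-merge level of Kruskal's algorithm.
Median (Steiner) vectors are the per-marker majority profiles of connected
triples, admitted only when they shorten the triple's local connection,
iterated to closure; obsolete medians (degree ≤ 2 whose removal does not
lengthen any observed-to-observed shortest path) are pruned. Ties break on
node name order, so the network is deterministic. With ε = 0 and medians
disabled the construction reduces to the classical minimum spanning
network, and tests verify MST containment against a greedy oracle plus
median placement against exhaustive Steiner search on small cases.

## Trees, ordination, AMOVA

Genotypes are coded to sequences (0→R, 1→H, 2→A, missing→?) with an
all-R outgroup representing the reference genotype. p-distances use
pairwise deletion; the heterozygous code is a *distinct state* (R↔A is one
difference, like any mismatch) — the alternative (treating H as an
ambiguity) would halve hom↔hom distances and is not what sequence-coded
genotype analyses conventionally do. Neighbor-joining is delegated to
`ape::nj`; negative branch lengths (an NJ artifact) are clamped to zero
with the deficit moved to the sibling branch. Bootstrap supports resample
markers with replacement (default 200 replicates) and report, for each
internal edge of the full-data tree, the percentage of replicates
containing that bipartition.

Codominant genotypic distance is the standard squared rule per locus —
(dosage difference)², i.e. 0/1/4 — summed over pairwise non-missing loci;
it equals squared Euclidean distance on dosage vectors, so the PCoA of it
(Gower double-centering, eigendecomposition via `cmdscale`) is exact.
AMOVA uses the method-of-moments decomposition:
SS_total = Σ d²/N over all pairs, SS_within = Σ_g (Σ d² within g)/n_g,
df = (G−1, N−G), n0 = (N − Σn_g²/N)/(G−1), Vw = SS_w/df_w,
Va = (SS_a/df_a − Vw)/n0, and Φ_PT = Va/(Va+Vw). Negative Va estimates are
reported raw alongside a zero-clamped Φ_PT. The p-value permutes
individuals among groups with sizes fixed (the Φ_PT null of the standard
codominant-distance software; we read that software's "bootstrap
iterations" as these permutations) and is computed as (count+1)/(n_perm+1)
with 900 permutations by default. Tests check the SS decomposition to
1e-9, hand-computed closed-form cases, scale invariance, and agreement of
the permutation p with exhaustive enumeration at small N.

## The synthetic-data generator

The generator *defines* the study conditions the package is validated
under; its defaults are fixed once:

* Four clones, two lineages; terminal branch years 75/70 (long
  propagation), 30 (recent transfer), 100 (never transferred); 20-year
  shared branches per lineage. Mutations are planted per branch as
  Poisson(μ × branch-years × site-space) — a clock-like accumulation model;
  μ defaults to 1e-4 per site per year so a 10,000-site space yields a few
  hundred SNVs, matching the sparse-variant regime of real intra-cultivar
  data at desk scale.
* A founder-heterozygous fraction (default 5 %) supplies the SNP
  background and the substrate for loss-of-heterozygosity events (rate
  2e-4 per het site per year, resolving to either homozygote with equal
  probability) — these produce the reference- and homozygous-class SC-SNVs
  and the rare homozygous Sh-SNVs.
* Transitions are drawn with probability 4.1/5.1; depth is Poisson(30);
  125 bp reads; per-base error 0.002; mutations are chimeric for L1 with
  probability 0.1 and for L2 with probability 0.2 (both-layer otherwise).
* Three callers drop true sites independently (FN 0.05) and inject
  caller-private false positives (1e-2 per free site) — so consensus
  intersection removes essentially all FPs, which the precision tests
  confirm.
* The chip cohort has two lineage founder profiles separated at 4
  diagnostic markers (the Sh-SNV role), about six derived genotypes per
  lineage at low marker distance, and rare per-sample singleton mutations;
  107 samples per lineage × 41 markers by default.

What the generator does *not* emulate: alignment and mapping artifacts,
linked error modes shared across callers, copy-number variation, sample
contamination, and realistic missing-data structure (missingness is
uniform). Passing tests therefore demonstrate correctness of the analysis
logic under the stated statistical model, not robustness to every failure
mode of real resequencing data.

## Numerical choices and degenerate inputs

Problem sizes used by the test suite and the acceptance script were chosen
to give stable Monte-Carlo behaviour at desk scale: 10,000-site simulations
for end-to-end checks, 200 bootstrap replicates, 900 AMOVA permutations,
2,000 permutations when comparing against exhaustive enumeration. Seeds are
explicit everywhere; every stochastic operation restores the caller's RNG
state, and the pipeline fans one global seed out through stage-specific
offsets so toggling a stage does not perturb the others. Degenerate inputs
fail loudly with typed conditions: zero-depth observations, all-zero
contingency tables, empty offset lists, all-missing samples or markers,
unsatisfiable panel quotas (with the shortfall named), fewer than three
taxa for NJ, and multiallelic VCF records (the pipeline is biallelic-SNV
only) are all explicit errors, not silent NAs.

## Known limitations

* The SC_hom strictness and the 0↔2 one-step convention (both discussed
  above) are judgment calls exposed as flags where feasible.
* The median-joining closure caps inferred medians (default 200) as a
  safety valve; pathological inputs could hit the cap and yield a valid
  but non-minimal network.
* AMOVA is two-level (among/within groups); hierarchical designs are out
  of scope.
* The generator's caller model treats false negatives as site drops; it
  does not simulate genotype miscalls within a reported site.
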