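# clonediv

Clonal genetic diversity analysis from somatic single-nucleotide variants
(SNVs).

## The problem

Grapevine cultivars (and clonally propagated perennial crops in general) are
multiplied vegetatively, so all plants of a cultivar share one ancestral
genotype. The only natural source of new genetic variation within a cultivar
is the somatic mutation: a heterozygous change that arises in a meristem,
is inherited by daughter vines through cuttings, and accumulates along each
propagation lineage. These variants are rare (hundreds per genome, against
millions of cultivar-level SNPs that separate the cultivar from the reference
genome), which makes them both hard to call reliably and extremely
informative: shared mutated positions are fingerprints of a clone's
propagation history.

`clonediv` implements the complete analysis chain for this problem, for
researchers and breeders working on intra-cultivar diversity:

1. **Consensus variant filtering** — retain only variants called identically
   by three independent callers, then apply stringent site filters: total
   depth DP in [15, 150]; variant allele frequency (VAF = alt reads / DP)
   windows VAF(Ref) ≤ 0.025, VAF(Het) ∈ [0.25, 0.75], VAF(Hom) ≥ 0.95 (gap
   zones are ambiguous and fail the site); two-sided Fisher exact strand-bias
   and Wilcoxon read-position-bias tests at α = 1e-4; one read edit per 25
   bases. The heterozygous window is tuned to chimerism: a mutation confined
   to the L2 cell layer (~60 % of somatic tissue) has expected VAF
   0.5 × 0.6 = 0.3 and is kept, while an L1-confined mutation
   (0.5 × 0.4 = 0.2) is deliberately excluded.
2. **Variant classification** — cultivar-level **SNPs** (all clones share one
   non-reference genotype) versus clone-distinguishing **SNVs**:
   single-clone SC-SNVs (heterozygous / reference / homozygous subclasses by
   the genotype pattern relative to the reference genome) and shared Sh-SNVs
   (a 2+2 genotype split between clone pairs), plus genomic-region annotation
   and transition/transversion summaries.
3. **Panel design** — select a genotyping-chip marker panel (default 42
   SC + 6 Sh markers) from heterozygous-alternative SNVs with variant-free
   flanking windows, balanced across focal clones and spread over
   chromosomes.
4. **Clonal-lineage inference** — collapse a samples × markers dosage matrix
   (0/1/2) into multilocus genotypes; build a median-joining network
   (ε-relaxed minimum spanning network plus inferred median vectors);
   neighbor-joining trees on uncorrected p-distances with bootstrap supports
   and a reference-genotype outgroup; principal coordinates analysis; and
   AMOVA on codominant squared genotypic distances (per locus
   (dosage_a − dosage_b)², i.e. 0/1/4) with

   Φ_PT = V_a / (V_a + V_w),

   the among-lineage fraction of molecular variance, tested by permuting
   individuals among groups.

A first-class synthetic-data generator emulates the whole study design —
four resequenced clones at ~30× with planted mutations (transition excess
ts/tv ≈ 4.1, chimeric L1/L2 VAF structure, loss-of-heterozygosity events),
three callers with independent error profiles, and a 200+ sample two-lineage
genotyping cohort — so every stage is testable against known truth.

## Worked example

```r
library(clonediv)

cfg   <- sim_config(seed = 7)                    # ~30x, ts/tv 4.1, 3 callers
gen   <- simulate_genealogy(4, cfg)              # MB53/MB59 vs C225/C143
truth <- plant_mutations(gen, cfg, n_sites = 10000)
obs   <- simulate_read_counts(truth, cfg)
calls <- simulate_callers(truth, cfg)

filt <- consensus_filter(calls, obs)             # 3-caller consensus + filters
cls  <- partition_variants(filt$retained$calls)
cls$summary$class_counts
#>     SNP  SC_het  SC_ref  SC_hom  Sh_het  Sh_hom complex
#>     406     176       9      18      30       2       0
```

641 of 717 consensus sites survive the site filters (most losses are
ambiguous-VAF chimeric sites, by design), and the retained SNVs keep the
planted transition excess (ts/tv = 3.93). The genotyping stage:

```r
cohort <- simulate_chip_cohort(gen, n_samples_per_lineage = 107,
                               n_markers = 41, missing_rate = 0.01, seed = 7)
mlg <- collapse_genotypes(cohort$genotypes)
length(mlg$genotypes)                            # 11 multilocus genotypes

gm <- cohort$genotypes; gm[is.na(gm)] <- 0L
amova_phipt(codominant_distance_matrix(gm), cohort$groups,
            n_perm = 900, seed = 7)
#> AMOVA (codominant squared distances)
#>         source  df    SS       MS
#>   Among groups   1 259.9 259.9112
#>  Within groups 212 182.1   0.8588
#>          Total 213 442.0       NA
#> Va = 2.4211  Vw = 0.8588  n0 = 107.000
#> Phi_PT = 0.738 (raw 0.738), p = 0.00111 (900 permutations)
```

The two planted lineages are strongly differentiated (Φ_PT = 0.74,
p ≈ 0.001): the lineage-diagnostic markers dominate the molecular variance.
`median_joining()`, `bootstrap_supports()` + `root_with_outgroup()` and
`pcoa()` complete the picture; `run_pipeline(pipeline_config(...))`
orchestrates all stages end-to-end with one seed and writes VCF / TSV /
FASTA / Newick / NEXUS artifacts plus a checksummed run manifest.

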