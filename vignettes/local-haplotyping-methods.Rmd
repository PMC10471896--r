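---
title: "Local haplotyping from linkage profiles: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local haplotyping from linkage profiles: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Genome-wide association studies point at a region; they do not explain
the web of linkage inside it. In a trait-associated interval spanning
dozens to thousands of SNPs, enumerating haplotypes as unique
combinations of *all* SNPs explodes combinatorially — every rare private
variant spawns a new haplotype, and group sizes collapse below anything
analysable. `localhap` takes the linkage-based route: it reduces the
variant dimension first, by clustering SNPs whose allelic states travel
together through the population, and only then defines haplotypes as
combinations of those clusters.

The pipeline has three stages:

1. **Marker Groups.** Each SNP is represented by its *linkage profile* —
   its row of the pairwise R² matrix against every other SNP in the
   region. SNPs are clustered in this profile space with DBSCAN;
   clusters become Marker Groups (MGs), and unclustered SNPs are noise.
2. **Haplotype groups.** Each individual is collapsed onto one allelic
   state (hom-ref / het / hom-alt) per MG — the arithmetic mode across
   the MG's member SNPs. Individuals sharing a complete MG-allele vector
   form a combination; combinations with at least `min_hap` individuals
   (default 9) are labelled `A`, `B`, … by descending frequency.
3. **Interpretation.** Haplotype groups are connected to phenotype and
   categorical metadata through descriptive summaries, a clustering tree
   over the epsilon grid, and a composite dashboard built around an
   UpSet-style haplotype × MG matrix.

## The LD statistic

`compute_ld_matrix()` uses the squared Pearson correlation of genotype
dosages (composite r²) over pairwise-complete observations. This is the
statistic plink's `--r2 square` emits for unphased data, which is the
dialect `read_ld_matrix()` accepts, so an externally computed matrix and
the internal one are interchangeable. Pairs that are undefined —
a monomorphic member, or fewer than two complete observations — are set
to 0 rather than NA so the clustering feature space stays finite; the
count of such pairs is reported. No D′, no phased haplotype r²: phasing
is out of scope and the method never needs it.

## DBSCAN over linkage profiles

The feature vector of a SNP is its full R² row, including the self-R²
of 1; since that diagonal contribution is shared by all rows at
different coordinates, it adds the locus' own column difference like
any other column and the profile geometry stays bounded in [0, 1] per
coordinate. Distances are Euclidean. DBSCAN semantics are pinned down
explicitly because they are the reproducibility surface of the whole
method:

* a point's neighbourhood includes itself, so a core point needs
  `min_points` neighbours *counting itself*;
* clusters are the connected components of core points at radius
  epsilon;
* border points (non-core with at least one core neighbour) join the
  cluster of their lowest-index core neighbour, indices being genomic
  order — the classic order-dependence of DBSCAN made deterministic by
  fixing the order to the genome;
* clusters are relabelled `MG1`, `MG2`, … by descending size, ties
  broken by the smallest minimum member position.

Defaults: `min_points = 5`, epsilon grid `0.2, 0.4, 0.6, 0.8, 1.0`.
The grid spans the geometry of R²-bounded profiles — below ~0.2
essentially only duplicated profiles co-cluster, and by 1.0 distinct
LD blocks in a typical region have merged — and the clustering tree,
not any automatic criterion, is the instrument for choosing within it.
A k-nearest-neighbour distance plot is deliberately not provided: it
summarises all points into one outlier-sensitive curve, whereas the
tree shows what each cluster does as epsilon moves.

## Mode collapse and tie-breaking

The MG allele of an individual is the arithmetic mode of its non-missing
dosages across the MG's SNPs. Two deterministic tie rules close the
gaps the mode leaves open: a tied count (e.g. dosages `{0, 0, 2, 2}`)
resolves towards the dosage nearest the MG-wide mean dosage (computed
over all individuals and member SNPs), and a residual tie takes the
lower dosage. The first rule is data-driven — it sides with the MG's
overall allele balance; the second is an arbitrary but fixed
convention. Individuals missing every SNP of an MG are unresolved, and
any unresolved MG excludes the individual from combination counting
entirely: haplotypes are defined as complete combinations, never
partial matches.

Invariant-MG removal happens *after* the `min_hap` filter: invariance is
judged across the labelled rows only. The label space is `A`–`Z`; more
than 26 qualifying combinations keeps the 26 largest with a warning.
Heterozygous MG alleles are never merged into a homozygous class, however
rare.

## The association score

The per-SNP phenotype association is a weighted difference of allele
pools, assuming additive heterozygote effects: the reference pool takes
hom-ref individuals at weight 2 and hets at weight 1, the alternate pool
takes hom-alt at weight 2 and hets at weight 1, and the score is the
alt-pool weighted mean minus the ref-pool weighted mean, in phenotype
units. The weights are allele counts: a homozygote carries two copies,
a het one of each, which is the reading under which "homozygotes count
double" and "additive heterozygote effects" are the same statement. The
identical formula applies to MG alleles. It is a descriptive statistic —
no p-values, no mixed models — and the tests pin its exact symmetries:
ref/alt swap negates it, location shifts leave it unchanged, scaling is
equivariant.

Missing data: an individual without phenotype is excluded from
association computations everywhere; a missing genotype excludes the
individual at that locus only.

Haplotype-level panels show distributions (boxplot convention: median
and quartiles) and the tables report means — the dashboard renders the
distribution, the export carries both. `isolate_groups` restricts the
*phenotype* statistics to individuals from the named metadata labels
while group sizes and metadata compositions continue to describe all
members, so the restriction can never silently shrink a haplotype.

## The clustering tree

`build_clustering_tree()` connects clusters at consecutive epsilon
levels by shared members — loci in MG mode, individuals in haplotype
mode — with an explicit sink node (`NOISE` / `UNASSIGNED`) per level.
The sink makes the haplotype-mode tree conservative: out-edge weights
from every node sum exactly to its size, which the tests assert. Edges
carry raw member counts (no proportion threshold); node colour encodes
the mean member-SNP association score (MG mode) or mean member
phenotype (haplotype mode). Mean rather than extreme was chosen for the
node statistic because a cluster-level colour should reflect the bulk
of its members; the statistic lives in one accessor and is trivially
swappable.

## The dashboard and the embedding

Every dashboard panel is a view over a tabular export: the figure and
its TSV side-cars are produced from the same tables in the same call,
so any number on screen can be traced to a file. The central matrix
encodes allelic state by glyph fill (open = hom-ref, half = het,
filled = hom-alt); rows are haplotypes in label order, columns MGs in
numeric order, and the flanking panels share those axes. `plot_left`
switches the MG panel between allele-state frequencies and SNP genomic
positions; `plot_right` between per-MG SNP association distributions
and intra-MG linkage boxplots. The intra-MG linkage panel shows the
raw distribution of off-diagonal R² among member SNPs; its spread is
what the field loosely calls the sphericity of a block — no scalar
sphericity index is defined here, the distribution itself is shown.

The SNP UMAP (`umap_snps()`) embeds LD-profile rows in 2-D with
`n_neighbors = min(15, n_loci - 1)`, `min_dist = 0.1`, PCA
initialisation and single-threaded SGD under a fixed seed (default 42),
making coordinates bit-reproducible. UMAP hyperparameters here are
presentation choices, not inference: nothing downstream consumes the
embedding.

## The synthetic-population generator

`generate_population()` is first-class, tested code: it emits exactly
the dialects the readers parse, plus a ground-truth record, so the
whole pipeline is validated end-to-end without external data.

The generative model: each individual draws two haplotype-template
copies from the template frequencies; with probability `inbreeding`
(default 0.98) the copies are identical by descent. The default mimics
a predominantly selfing crop panel — the setting local haplotyping is
most used in — where haplotype groups are essentially homozygous
template classes and heterozygotes are rare but present, which
exercises the mode and het-weighting rules without drowning the
planted structure in diploid combinations. Within a planted block,
each SNP copies the block allele of each copy with a per-copy flip
probability q solved in closed form from the flip-noise model:
with t = (1 − 2q)² and V = 2p(1 − p)(1 + F) the variance of the summed
copy alleles at block allele frequency p and inbreeding F, the
SNP–SNP dosage correlation is r = tV / ((1 − t)/2 + tV), and q is
chosen so r² equals the target R². The calibration is verified
empirically in the tests: over 20 seeds at target 0.9 the realised
mean within-block R² stays inside ±0.05.

Defaults are the reference design used throughout the tests and the
acceptance script: 200 individuals; three blocks of 20 SNPs at R² 0.9
spanning 5 kb each; 15 unlinked noise SNPs with allele frequencies
uniform in [0.1, 0.9]; template frequencies 0.5/0.3/0.2; phenotype
effects 0, +2, −1 with noise sd 0.5 (an individual's expectation is the
mean of its two copies' effects, so homozygote group means equal the
planted effects); one metadata label per template with 10%
contamination. Phenotype effect sizes of ±1–2 residual sd are the
regime where a GWAS follow-up is plausible in the first place.

What the generator does *not* emulate: recombination gradients within
blocks, allele-frequency spectra from demography, genotyping error
beyond the flip noise, linkage between blocks, population structure
confounded with phenotype. Passing the planted-recovery tests therefore
shows the machinery is correct under the method's own assumptions — it
does not certify behaviour on real panels where blocks bleed into each
other, and the clustering tree exists precisely because real regions
need that judgement.

## Numerical and degenerate-input conventions

* LD matrices are validated to [−1e-9, 1 + 1e-9], symmetrised at
  tolerance 1e-6 (hard error beyond), then clamped to [0, 1].
* Undefined LD pairs → 0, with a reported count; an all-monomorphic
  region is a hard error.
* Half-calls and irregular genotype strings are missing, never imputed.
* A region yielding zero biallelic SNPs errors naming the region; a
  result with zero labelled haplotypes refuses to render the dashboard
  and says which knobs (epsilon, `min_hap`) to move.
* All exported text is written at full precision; write→read round
  trips are asserted to 1e-9.

## Problem sizes

The validation suite runs the reference design (75 SNPs × 200–300
individuals) and randomised oracle checks up to 200 loci / 500
individuals — sizes chosen so the full suite completes in a few minutes
while covering the combinatorial corners (ties, overflow, empty pools,
all-noise clusterings). The algorithms are quadratic in loci (LD matrix,
DBSCAN) and linear in individuals; regions of a few thousand SNPs
remain practical.

## Known limitations

* Border-point assignment inherits DBSCAN's order dependence; it is
  deterministic here (genomic order) but a border SNP equidistant to
  two MGs is a convention, not a discovery.
* The association score is descriptive; with structured populations it
  absorbs stratification like any unadjusted difference of means.
* Polyploids, multi-allelic sites, and structural variants are out of
  scope; the dosage model is strictly biallelic-diploid.
* `min_hap` interacts with sample size: the default 9 is an absolute
  count, so small panels may need to lower it, and the warning on an
  empty haplotype table says so.
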