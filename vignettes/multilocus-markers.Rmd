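---
title: "Multi-locus marker panels: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-locus marker panels: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthopanel)
```

# What this package models

`orthopanel` implements the analysis core of a reduced-complexity,
capture-based monitoring framework for species-rich insect groups: a few
hundred conserved nuclear loci (ultraconserved elements, UCEs, plus the two
ends of universal single-copy orthologs, USCOs) are enriched by
hybridisation capture across an entire fauna and used simultaneously for

* species identification and phylogeny benchmarking (monophyly scoring),
* per-individual genetic diversity (percent heterozygous exonic sites),
* association of species-level diversity with ecological traits and
  threat status, and
* within-species spatial structure from SNPs.

Every stage consumes standard formats (FASTA, VCF, BED, Newick, TSV) and is
paired with a synthetic-cohort generator that plants known ground truth, so
the whole pipeline is testable by parameter recovery without any sequencing
data.

# Probe-panel design

Candidate conserved loci arrive as per-locus alignments across a panel of
reference genomes labelled by suborder-level clade (grasshopper-like vs.
cricket-like). The filter cascade, in order of application, keeps a UCE
candidate iff:

1. it is captured in at least `min_genomes` genomes (default 6; the
   outgroup genome counts toward this total — the alternative reading would
   only shift the effective threshold by one and is configurable by setting
   `min_genomes`);
2. its alignment is at least `min_locus_len` = 120 bp;
3. at most `max_variable_frac` = 50% of its comparable columns are
   variable; and
4. its maximum pairwise p-distance within each clade is at most
   `max_within_clade_div` = 10%.

Each rejection records the *first* failing rule, which makes filter
attrition auditable. USCO candidates skip rules 3–4 (their conservation is
vouched for by single-copy orthology) and apply only the genome-count rule.

Two counting conventions matter downstream and are fixed here once:

* **Variable-column denominator.** A column counts only when at least two
  rows carry a non-gap residue; this avoids scoring missing data as
  variation in trimmed alignments.
* **Divergence = uncorrected p-distance** (fraction of mismatching
  comparable columns), matching the distance used for orthology assignment,
  so one definition serves both modules.

Probes tile loci in non-overlapping, fixed-length 170-bp windows; a
terminal remainder shorter than one probe is dropped (probes are
fixed-length by synthesis constraint), so a locus yields
`floor(L / 170)` tiles. USCOs are probed at their first and last 120 bp;
because the two ends of a gene are usually separated by hundreds of bases
of intron, *each end-probe is registered as an independent locus* in the
panel manifest. A USCO shorter than 240 bp degrades to a single probe with
a warning rather than an error, keeping a panel run total. Mito/rDNA
alignments reuse the same tiling operator on their consensus.

# Orthology assignment

A captured region is matched to its targeted locus by aligning the probe to
the region (global alignment with affine gaps, both strands, best strand
kept) and computing the percent p-distance over gap-free columns. The
region is assigned iff at least 3 samples mapped to it and the distance is
*strictly below* 30; exactly 30.0 is rejected. The distance is uncorrected
(no multiple-hit correction); the corrected alternative would only matter
near the threshold, and the threshold itself is the operative convention.

On synthetic panels built with within-clade divergence 5%, between-clade
divergence 15% and paralogs carrying 35 extra substitutions per 100 sites,
true orthologs fall well below the threshold and paralog copies well above
it; the acceptance suite measures the resulting classification accuracy
(≥ 0.95 required, observed 1.0 at the default settings).

# Alignment-level QC

Three filters run in a fixed order:

1. **Row missingness** — sequences with more than 40% gaps/Ns are dropped
   (a row at exactly 40% is kept; the rule is strict `>`). Gap `-`, `N` and
   `?` all count as missing because trimmed alignments mix them.
2. **Occupancy** — loci present in at least one-third of the samples are
   kept, *then* samples missing at least 20% of the kept loci are dropped.
   Loci-first ordering is deliberate (and configurable): filtering samples
   first would let a few badly captured samples drag down locus occupancy.
   "Missing data" for the sample rule is measured as the fraction of
   missing *loci* by default; a fraction-of-characters alternative is
   selectable via `qc_config(sample_missing_unit = "characters")`.
3. **Paralog screen** — a stand-in rule, flagged as such in its output
   metadata: within each taxonomy-level group (order, then family, then
   genus; each round on the previous round's survivors) with ≥ 3 rows,
   each row's p-distance to the group's majority-rule consensus is
   computed, and rows above `median + 5 × MAD` are removed. The MAD is
   floored at 0.5 percentage points: in near-identical groups the raw MAD
   is ~0 and any single substitution would otherwise flag a row. The
   multiplier 5 is intentionally permissive — genuine paralogs carry tens
   of percent of extra divergence, and the screen should not amputate
   ordinary allelic variation. On synthetic loci (2% background divergence,
   planted paralogs at +35%) the screen recovers ≥ 90% of planted paralogs
   with ≤ 5% false removals.

Concatenation pads absent samples with `-` and emits 1-based inclusive
column ranges per locus, the de-facto partition-file convention. Tree
inference itself (model selection, ML search, bootstrap) is out of scope;
trees are inputs to the benchmarking module.

# Per-individual diversity

The diversity statistic is the percentage of heterozygous exonic positions:
heterozygous biallelic SNP calls passing depth ≥ 6 and site QUAL ≥ 100
(both inclusive), inside the exon mask, divided by the number of masked
positions covered by at least 6 reads *in that individual*, × 100. Three
conventions are fixed:

* the denominator is per-individual (the statistic is "within
  individuals"; a cohort-level denominator would mix capture efficiencies);
* numerator and denominator share the same depth threshold, so raising
  `min_depth` is monotone in both;
* quality means the site QUAL field, not genotype GQ.

Species-level diversity is the arithmetic mean over individuals, and
cross-marker comparisons (nuclear vs. mitochondrial vs. ribosomal, or
diversity vs. sampled area) use ordinary least squares.

# Monophyly benchmarking

A species is monophyletic on an unrooted topology iff some edge bipartition
separates exactly its tips from everything else. The implementation
computes each edge's tip-side set by a postorder sweep and compares against
the species' tip set and its complement, which makes the check
rooting-invariant by construction and gives soft-polytomy semantics (a
polytomy that *could* resolve the species into a clade does not count; its
tips must already form one side of a branch). Species with a single sample
are reported as excluded singletons and never enter the counts. Marker-set
comparisons restrict all reports to the species scored in *every* marker
tree before counting, so coverage differences cannot masquerade as
resolution differences. Node-support values are carried for reporting but
never affect status.

The tests cross-check this implementation on hundreds of random trees
against an independent route (rooting at an outside tip and asking `ape`
for rooted monophyly).

# Trait association

Correlated trait variables are pruned greedily: while any pair exceeds
|r| > 0.7 (the published workflow states the action, not the cutoff; 0.7
is the conventional collinearity threshold and is exposed as an argument),
the member of the worst pair with the higher mean absolute correlation is
dropped, with ties broken by column order — fully deterministic.

The diversity model is a Gaussian GLM with identity link on the *natural
log of the polymorphic-site proportion*. The log scale is the package's
default because a log response back-transforms an intercept of about −5.4
to a heterozygosity of ~0.45%, a biologically plausible magnitude, whereas
an identity response on raw percentages would let predictions go negative;
`response_transform = "identity"` is available. Ordinal predictors
(including the IUCN category, coded LC=1 < NT=2 < VU=3 < EN=4 < CR=5)
enter as numeric scores — a single coefficient per variable. Museum
specimens are excluded from association runs via a row flag.

Threatened (VU+EN+CR) vs. non-threatened (LC+NT) diversity uses a
two-sided Wilcoxon rank-sum test: exact by enumeration when the smaller
group has ≤ 10 observations and there are no ties, normal approximation
with continuity correction otherwise; fully tied data return p = 1.
The trait PCA is centred and standardised, so eigenvalues sum to the
number of variables; constant columns are excluded with a warning.

# Spatial structure

SNP filtering keeps biallelic sites with QUAL ≥ 100 and call rate ≥ 0.85,
then drops individuals below 0.85 call rate over the kept sites. The
published "maximum missing rate of 0.85%" is read as a vcftools-style
*call-rate threshold of 0.85* — the literal reading (at most 0.85%
missing) would discard nearly every site at typical sample sizes of ~20;
both readings are implemented
(`structure_config(missing_reading = "percent_missing")`) and the choice
is recorded in the config object.

Clustering runs k-means (best of 50 restarts under a fixed seed stream)
for each k in 2–10 on the leading principal components explaining ≥ 80%
of variance (genotypes 0/1/2, missing entries mean-imputed per SNP,
zero-variance SNPs excluded); clustering on components stabilises the
Euclidean distances that both k-means and the silhouette use, and a
raw-matrix mode is available. The chosen k maximises the average
silhouette width; ties break to the smallest k and are flagged. No
neutrality test is applied to the SNPs — the input filter is quality and
completeness only. Cluster-to-geography interpretation is a join against
an input region column, not a spatial statistic.

# The synthetic cohort: what it emulates and what it does not

The generator defines the study conditions for every test:

* **Sequence evolution** is a single-parameter symmetric (Jukes–Cantor-like)
  model: a site mutates with probability q, uniformly to one of the three
  other bases. It is the simplest model with a closed-form identity
  expectation (`expected_p_distance()`), which is what the calibration
  tests need. Copies diverge from a shared root via clade ancestors
  (between-clade rate) and per-genome branches (within-clade rate);
  paralogs take extra divergence at the root. Defaults: within-clade 5%,
  between-clade 15%, paralog extra 35% — chosen so that ortholog and
  paralog distance distributions sit on the two sides of the 30% threshold
  as the real capture data's distributions do.
* **Trees** are coalescent species trees with shallow within-species
  subtrees. Monophyly violations are planted constructively: one tip of a
  donor species is pruned and regrafted as sister to another species'
  whole clade, which breaks exactly the donor — so any violation count,
  odd or even, is plantable and the truth set is exact by construction.
* **Genotype calls**: heterozygosity is i.i.d. per exonic site with
  probability θ; depth is negative-binomial (mean 30, dispersion 5),
  capturing capture-efficiency overdispersion without modelling it
  mechanistically; QUAL is proportional to depth (30 per read). The
  per-species θ defaults (0.001–0.01) bracket the range implied by a
  log-scale intercept of ≈ −5.4, i.e. heterozygosities of a few tenths of
  a percent; no empirical distribution of θ is claimed.
* **SNP matrices**: per-SNP ancestral frequencies are uniform on
  \[0.1, 0.9\]; each planted cluster shifts them by a uniform offset in
  \[−d, d\] with d = 0.4 by default, clipped away from fixation;
  genotypes are binomial(2) draws; missingness is uniform at 2%.
* **Trait tables**: log diversity-proportion = −5.4 − 0.11 × riparian
  score + N(0, 0.3); all other ordinal traits are drawn independently of
  diversity, so the GLM's null calibration can be measured on them.

What the generator deliberately does **not** emulate: read-level errors and
mapping artefacts, indels, linkage between SNPs, numts/heteroplasmy,
intragenomic rDNA variation, spatially autocorrelated sampling, and
correlated ecological traits. Passing tests therefore demonstrate that the
*estimators and filters* recover what they are pointed at under clean,
correctly specified noise — not that the upstream wet-lab and mapping
stages are error-free, and not that real traits are independent.

Internally all coordinates are 0-based half-open; conversion to 1-based
happens only at VCF emission (and partition files are 1-based inclusive by
convention). One master seed drives everything; each stage derives a child
seed deterministically, so outputs are byte-identical under a fixed config
and adding a stage never perturbs another stage's stream.

# Problem sizes and numerical choices

The test and acceptance workloads are sized for a laptop-class run: 500
random trees of ≤ 12 tips for the monophyly oracle; 50-kb exomes for
heterozygosity recovery (binomial standard error ≈ 0.014 percentage points
at θ = 0.001); 40-locus panels for classifier accuracy; 200 replicates of
100 species for GLM recovery and null calibration; 30 individuals × 500
SNPs for cluster recovery. Tolerances are statistical, not tuned: 3
binomial standard errors for proportions, 2 Monte-Carlo standard errors
for the GLM mean, exact equality for enumerable quantities (probe counts,
exact Wilcoxon p, planted violation sets).

# Known limitations

* The paralog screen is a heuristic stand-in; with real data an
  assembly-aware filter should be preferred where available, and the
  screen's output is labelled accordingly.
* The monophyly check is exact but quadratic-ish in tree size per species;
  it is meant for hundreds of tips, not millions.
* The exact Wilcoxon enumeration applies only to small untied groups, as
  in the published workflow; ties always route to the approximation.
* `cluster_agreement()` matches labels by exhaustive permutation and is
  limited to ≤ 8 clusters.
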