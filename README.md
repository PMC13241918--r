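# orthopanel

Multi-locus nuclear marker panels for conservation genomics of species-rich
insect groups.

Red Lists rank species by demography and range, but within-species genetic
diversity — the raw material of adaptation — is rarely measured at the scale
of a whole fauna. A practical compromise is a reduced-complexity panel of a
few hundred conserved nuclear loci (ultraconserved elements, UCEs, and the
two 120-bp ends of universal single-copy orthologs, USCOs) enriched by
hybridisation capture across every species of an order. One dataset then
serves three purposes at once: species identification and phylogeny
benchmarking, per-individual heterozygosity as a standardised diversity
metric, and within-species spatial structure from SNPs.

`orthopanel` implements the analysis core of that framework for R users:

* **Panel design** — harvest candidate conserved loci from a genome-panel
  alignment, apply the filter cascade (captured in ≥ 6 genomes, length
  ≥ 120 bp, ≤ 50% variable columns, ≤ 10% within-clade p-distance), tile
  non-overlapping 170-bp probes and extract USCO end-probes, and emit a
  locus manifest.
* **Orthology assignment** — classify captured regions by probe-to-region
  alignment distance (assigned iff p-distance < 30% and ≥ 3 samples
  mapped).
* **Locus QC** — drop sequences > 40% missing, keep loci in ≥ 1/3 of
  samples and samples < 20% missing, screen paralogs by consensus-distance
  outliers over order → family → genus rounds, and build a partitioned
  supermatrix.
* **Diversity** — the per-individual statistic
  `pct_polymorphic = 100 × n_het / L_covered`, where `n_het` counts
  heterozygous biallelic exonic SNPs with depth ≥ 6 and QUAL ≥ 100 and
  `L_covered` is the exonic length covered by ≥ 6 reads in that
  individual; species means; cross-marker regressions.
* **Monophyly benchmarking** — bipartition-based species monophyly on
  labelled trees (rooting-invariant, polytomy-aware, singletons excluded)
  and marker-set comparisons on shared species.
* **Trait association** — correlation pruning, a Gaussian GLM of
  log diversity-proportion on ordinal ecological traits, the two-sided
  Wilcoxon test of threatened (VU+EN+CR) vs. non-threatened (LC+NT)
  species, and trait PCA.
* **Spatial structure** — SNP filtering (QUAL ≥ 100, call rate ≥ 0.85 at
  SNP and individual level), genotype PCA, and k-means with the number of
  clusters selected by the highest average silhouette width.
* **Synthetic cohorts** — a generator that plants known ground truth
  (divergences, paralogs, monophyly violations, heterozygosity, clusters,
  a riparian effect on log-diversity) so every stage is testable by
  parameter recovery.

## Worked example

Simulate a cohort and run every stage (`seed = 20` reproduces the numbers
below exactly):

```r
library(orthopanel)
cfg <- sim_config(seed = 20, n_loci_uce = 30, n_loci_usco = 8,
                  paralog_frac = 0.2, n_species = 20,
                  n_monophyly_violations = 3)

# 1. panel design from the genome panel
panel <- simulate_genome_panel(cfg)
loci <- lapply(names(panel$alignments), function(id)
  list(id = id, type = panel$truth$type[match(id, panel$truth$locus_id)],
       seqs = panel$alignments[[id]],
       clades = attr(panel$alignments[[id]], "clades")))
flt <- filter_candidates(loci, panel_config())
usco_kept <- Filter(function(l) l$type == "USCO", flt$kept)
probes <- do.call(rbind, lapply(usco_kept, function(l)
  usco_end_probes(l$seqs[[1]], locus_id = l$id)))
man <- build_panel_manifest(Filter(function(l) l$type == "UCE", flt$kept),
                            probes)
man$counts
#>   UCE  USCO total
#>    30    16    46
```

All 30 UCE candidates pass the cascade and each of the 8 orthologs
contributes its two end-probes as independent loci: 30 + 16 = 46 targeted
loci. (With the published panel's inputs — 290 UCEs and 54 orthologs — the
same arithmetic gives 290 + 108 = 398.)

```r
# 2. monophyly benchmark on a tree with 3 planted violations
tsim <- simulate_labeled_trees(cfg)
count_monophyletic(tsim$tree, tsim$tip_map, marker = "nuclear")
#> Monophyly report [nuclear]
#>   17 of 20 species with >= 2 samples monophyletic; 0 singleton species excluded

# 3. per-individual diversity (planted theta = 0.005)
sc <- simulate_site_calls(cfg, "sp001")
pct_polymorphic(sc$calls, sc$depth, sc$exons,
                sample_id = sc$sample_id, species = "sp001")
#>   sample_id species n_het_sites covered_exon_len pct_polymorphic
#> 1  sp001_s1   sp001         247            49605       0.4979337
```

The benchmark recovers exactly the 3 planted violations (17 of 20
monophyletic), and the diversity estimate (0.498%) sits on the planted
heterozygosity of 0.5%: 247 heterozygous sites over 49,605 exonic bases
covered at ≥ 6 reads.

```r
# 4. trait association (planted riparian effect -0.11 on log diversity)
tt <- simulate_trait_table(sim_config(seed = 20, n_species = 100))
fit_diversity_glm(tt)
#> Gaussian GLM of log(polymorphic-site proportion) on 100 species
#>                      term  estimate std_error  t_value   p_value
#> 1             (Intercept) -5.214390   0.12781 -40.7986 1.024e-60
#> ...
#> 4      riparian_indicator -0.105553   0.02833  -3.7261 3.354e-04
#> ...
wilcoxon_threatened(tt)$p_value
#> [1] 0.098194794

# 5. spatial structure (3 planted clusters, divergence 0.4)
gm <- simulate_snp_matrix(cfg)
select_k_kmeans(gm$genotypes, structure_config(seed = 20))
#> Silhouette-selected k-means clustering
#>   chosen k: 3
#>   mean silhouette by k:
#>     2     3     4     5     6     7     8     9    10
#> 0.174 0.234 0.167 0.121 0.070 0.071 0.065 0.069 0.070
```

The riparian coefficient is recovered (−0.106 ± 0.028 against a planted
−0.11; the only significant term), threat status shows no association
(p = 0.098), and the silhouette scan peaks at the planted k = 3 with
perfect label agreement.

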