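#' Configuration of the synthetic cohort generator
#'
#' Bundles every knob of the synthetic-data generator into one validated
#' object. The generator emulates the statistical structure a capture-based
#' multi-locus dataset is assumed to have: a small panel of reference genomes
#' from two suborder-level clades carrying conserved loci (with a fraction of
#' planted paralogs), labelled phylogenies with a known number of species-
#' monophyly violations, per-individual exonic genotype calls with planted
#' heterozygosity and negative-binomial read depth, SNP matrices with planted
#' clusters, and species trait tables with a planted riparian effect on
#' log-diversity.
#'
#' @param seed master integer seed; per-stage child seeds are derived from it
#'   deterministically (see [child_seed()]), so the same config always yields
#'   byte-identical outputs.
#' @param n_genomes number of reference genomes in the panel.
#' @param clade_labels character vector of length `n_genomes` assigning each
#'   genome to one of two clades (defaults alternate "caelifera"/"ensifera").
#' @param n_loci_uce,n_loci_usco number of conserved loci of each type.
#' @param locus_len_range length-2 integer range (bp) of planted locus lengths.
#' @param within_clade_div,between_clade_div expected substitutions/site
#'   separating copies within and between clades, in \[0, 1\].
#' @param paralog_frac fraction of loci that also receive a duplicated
#'   (paralogous) copy.
#' @param paralog_extra_div extra substitutions/site carried by paralog copies.
#' @param n_species,tips_per_species species count and tips per species for
#'   the labelled trees (`tips_per_species` may be a single count or a
#'   length-2 range sampled uniformly per species).
#' @param n_monophyly_violations number of species planted non-monophyletic.
#' @param theta_per_species per-site heterozygosity probability, recycled over
#'   species, each in \[0, 0.5\].
#' @param exon_len total exonic length (bp) simulated per individual.
#' @param depth_mean,depth_dispersion negative-binomial read-depth mean and
#'   dispersion (size) parameters.
#' @param qual_per_read variant quality contributed per supporting read; site
#'   QUAL is `qual_per_read * depth`.
#' @param n_clusters,cluster_divergence,n_per_cluster,n_snps planted cluster
#'   count, allele-frequency divergence among clusters, individuals per
#'   cluster and SNP count for the genotype matrix.
#' @param missing_rate genotype missingness applied uniformly at random.
#' @param beta_riparian effect of the riparian score on log-diversity in the
#'   trait table.
#' @param trait_noise_sd residual s.d. of log-diversity.
#' @param trait_intercept intercept of log-diversity (log proportion scale).
#' @return an object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(seed = 1, n_loci_uce = 5, n_loci_usco = 2)
#' cfg$n_genomes
#' @export
sim_config <- function(seed = 1L,
                       n_genomes = 6L,
                       clade_labels = NULL,
                       n_loci_uce = 40L,
                       n_loci_usco = 10L,
                       locus_len_range = c(400L, 1200L),
                       within_clade_div = 0.05,
                       between_clade_div = 0.15,
                       paralog_frac = 0,
                       paralog_extra_div = 0.35,
                       n_species = 20L,
                       tips_per_species = c(2L, 4L),
                       n_monophyly_violations = 0L,
                       theta_per_species = 0.005,
                       exon_len = 50000L,
                       depth_mean = 30,
                       depth_dispersion = 5,
                       qual_per_read = 30,
                       n_clusters = 3L,
                       cluster_divergence = 0.4,
                       n_per_cluster = 10L,
                       n_snps = 500L,
                       missing_rate = 0.02,
                       beta_riparian = -0.11,
                       trait_noise_sd = 0.3,
                       trait_intercept = -5.4) {
  if (is.null(clade_labels)) {
    clade_labels <- rep(c("caelifera", "ensifera"), length.out = n_genomes)
  }
  cfg <- list(
    seed = as.integer(seed), n_genomes = as.integer(n_genomes),
    clade_labels = as.character(clade_labels),
    n_loci_uce = as.integer(n_loci_uce), n_loci_usco = as.integer(n_loci_usco),
    locus_len_range = as.integer(locus_len_range),
    within_clade_div = within_clade_div, between_clade_div = between_clade_div,
    paralog_frac = paralog_frac, paralog_extra_div = paralog_extra_div,
    n_species = as.integer(n_species),
    tips_per_species = as.integer(tips_per_species),
    n_monophyly_violations = as.integer(n_monophyly_violations),
    theta_per_species = theta_per_species,
    exon_len = as.integer(exon_len),
    depth_mean = depth_mean, depth_dispersion = depth_dispersion,
    qual_per_read = qual_per_read,
    n_clusters = as.integer(n_clusters),
    cluster_divergence = cluster_divergence,
    n_per_cluster = as.integer(n_per_cluster), n_snps = as.integer(n_snps),
    missing_rate = missing_rate,
    beta_riparian = beta_riparian, trait_noise_sd = trait_noise_sd,
    trait_intercept = trait_intercept
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(
    length(cfg$seed) == 1L, !is.na(cfg$seed),
    cfg$n_genomes >= 1L,
    length(cfg$clade_labels) == cfg$n_genomes,
    length(unique(cfg$clade_labels)) <= 2L,
    cfg$n_loci_uce >= 0L, cfg$n_loci_usco >= 0L,
    length(cfg$locus_len_range) == 2L,
    cfg$locus_len_range[1] >= 2L,
    cfg$locus_len_range[2] >= cfg$locus_len_range[1],
    cfg$within_clade_div >= 0, cfg$within_clade_div <= 1,
    cfg$between_clade_div >= 0, cfg$between_clade_div <= 1,
    cfg$paralog_frac >= 0, cfg$paralog_frac <= 1,
    cfg$paralog_extra_div >= 0, cfg$paralog_extra_div <= 1,
    cfg$n_species >= 1L,
    all(cfg$tips_per_species >= 1L),
    cfg$n_monophyly_violations >= 0L,
    cfg$n_monophyly_violations <= cfg$n_species - 1L,
    all(cfg$theta_per_species >= 0), all(cfg$theta_per_species <= 0.5),
    cfg$exon_len >= 1L,
    cfg$depth_mean > 0, cfg$depth_dispersion > 0, cfg$qual_per_read >= 0,
    cfg$n_clusters >= 1L, cfg$n_per_cluster >= 1L, cfg$n_snps >= 1L,
    cfg$cluster_divergence >= 0, cfg$cluster_divergence <= 1,
    cfg$missing_rate >= 0, cfg$missing_rate <= 1,
    cfg$trait_noise_sd >= 0
  )
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat("  seed:", x$seed, "\n")
  cat("  genomes:", x$n_genomes, "(",
      paste(table(x$clade_labels), names(table(x$clade_labels)),
            collapse = ", "), ")\n")
  cat("  loci:", x$n_loci_uce, "UCE +", x$n_loci_usco, "USCO;",
      "paralog fraction", x$paralog_frac, "\n")
  cat("  trees:", x$n_species, "species,",
      x$n_monophyly_violations, "planted violations\n")
  cat("  calls: theta", paste(x$theta_per_species, collapse = "/"),
      "over", x$exon_len, "exonic bp, depth NB(",
      x$depth_mean, ",", x$depth_dispersion, ")\n")
  cat("  SNPs:", x$n_snps, "sites,", x$n_clusters, "clusters,",
      "divergence", x$cluster_divergence, "\n")
  invisible(x)
}
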