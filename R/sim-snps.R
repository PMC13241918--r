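#' Simulate a genotype matrix with planted clusters
#'
#' Each SNP gets a shared ancestral allele frequency drawn uniformly on
#' \[0.1, 0.9\]; each planted cluster perturbs it by an offset drawn uniformly
#' on \[-d, d\] with d = `cluster_divergence`, clipped to \[0.02, 0.98\].
#' Genotypes are binomial(2, p) draws of alternate-allele counts; missingness
#' is applied uniformly at random at `missing_rate`. Per-SNP quality scores
#' are emitted so the structure module's quality filter can operate.
#'
#' @param config a [sim_config()]; uses `n_clusters`, `n_per_cluster`,
#'   `n_snps`, `cluster_divergence`, `missing_rate`, `qual_per_read`,
#'   `depth_mean`.
#' @return a list with elements
#'   \describe{
#'     \item{genotypes}{integer matrix individuals x SNPs of 0/1/2 alternate-
#'       allele counts with `NA` for missing entries;}
#'     \item{qual}{numeric per-SNP quality;}
#'     \item{biallelic}{logical per-SNP flag (all `TRUE` here);}
#'     \item{truth}{integer vector of planted cluster labels per individual.}
#'   }
#' @examples
#' gm <- simulate_snp_matrix(sim_config(seed = 4, n_snps = 50))
#' table(gm$truth)
#' @export
simulate_snp_matrix <- function(config) {
  validate_sim_config(config)
  set.seed(child_seed(config$seed, "snp_matrix"))

  k <- config$n_clusters
  n <- k * config$n_per_cluster
  m <- config$n_snps
  d <- config$cluster_divergence

  p0 <- runif(m, 0.1, 0.9)
  pk <- matrix(0, nrow = k, ncol = m)
  for (j in seq_len(k)) {
    pk[j, ] <- pmin(pmax(p0 + runif(m, -d, d), 0.02), 0.98)
  }

  truth <- rep(seq_len(k), each = config$n_per_cluster)
  geno <- matrix(0L, nrow = n, ncol = m,
                 dimnames = list(sprintf("ind%03d", seq_len(n)),
                                 sprintf("snp%04d", seq_len(m))))
  for (i in seq_len(n)) {
    geno[i, ] <- rbinom(m, 2L, pk[truth[i], ])
  }
  if (config$missing_rate > 0) {
    miss <- runif(n * m) < config$missing_rate
    geno[matrix(miss, nrow = n)] <- NA_integer_
  }
  qual <- config$qual_per_read * rnbinom(m, size = config$depth_dispersion,
                                         mu = config$depth_mean)
  list(genotypes = geno, qual = qual,
       biallelic = rep(TRUE, m), truth = truth)
}

#' Write a genotype matrix as TSV
#'
#' Individuals in rows, SNPs in columns, `NA` for missing genotypes; per-SNP
#' quality written as a companion two-column TSV.
#'
#' @param gm result of [simulate_snp_matrix()].
#' @param geno_path,qual_path output file paths.
#' @return `geno_path`, invisibly.
#' @export
write_snp_matrix <- function(gm, geno_path, qual_path = NULL) {
  write.table(gm$genotypes, geno_path, sep = "\t", quote = FALSE,
              row.names = TRUE, col.names = NA)
  if (!is.null(qual_path)) {
    write.table(data.frame(snp = colnames(gm$genotypes), qual = gm$qual),
                qual_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(geno_path)
}
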