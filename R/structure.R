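#' Spatial-structure analysis configuration
#'
#' @param min_qual minimum SNP quality (inclusive).
#' @param biallelic_only keep biallelic SNPs only.
#' @param min_call_rate_snp minimum per-SNP call rate (inclusive `>=`).
#' @param min_call_rate_individual minimum per-individual call rate over the
#'   kept SNPs (individuals strictly below are dropped).
#' @param missing_reading how the published "maximum missing rate of 0.85"
#'   threshold is read: `"call_rate"` (the vcftools convention, keep sites
#'   with >= 85% calls; default) or `"percent_missing"` (at most 0.85%
#'   missing — so strict it discards nearly everything at typical sample
#'   sizes; provided for comparison).
#' @param k_range integer range of cluster numbers to scan (min >= 2).
#' @param n_init k-means restarts per k.
#' @param var_explained fraction of variance the leading principal
#'   components used for clustering must explain.
#' @param seed RNG seed for the k-means restarts.
#' @return a `structure_config` list.
#' @export
structure_config <- function(min_qual = 100, biallelic_only = TRUE,
                             min_call_rate_snp = 0.85,
                             min_call_rate_individual = 0.85,
                             missing_reading = c("call_rate",
                                                 "percent_missing"),
                             k_range = 2:10, n_init = 50L,
                             var_explained = 0.8, seed = 1L) {
  missing_reading <- match.arg(missing_reading)
  if (missing_reading == "percent_missing") {
    min_call_rate_snp <- 1 - 0.0085
    min_call_rate_individual <- 1 - 0.0085
  }
  stopifnot(min_call_rate_snp >= 0, min_call_rate_snp <= 1,
            min_call_rate_individual >= 0, min_call_rate_individual <= 1,
            min(k_range) >= 2L, n_init >= 1L,
            var_explained > 0, var_explained <= 1)
  structure(list(min_qual = min_qual, biallelic_only = isTRUE(biallelic_only),
                 min_call_rate_snp = min_call_rate_snp,
                 min_call_rate_individual = min_call_rate_individual,
                 missing_reading = missing_reading,
                 k_range = as.integer(k_range), n_init = as.integer(n_init),
                 var_explained = var_explained, seed = as.integer(seed)),
            class = "structure_config")
}

#' Filter a genotype matrix for structure analysis
#'
#' Keeps biallelic SNPs with quality at or above `min_qual` and call rate at
#' or above `min_call_rate_snp`; then drops individuals whose call rate over
#' the kept SNPs is below `min_call_rate_individual`.
#'
#' @param genotypes individuals x SNPs integer matrix (0/1/2, `NA` missing).
#' @param qual per-SNP quality vector.
#' @param biallelic per-SNP logical (defaults to all `TRUE`).
#' @param config a [structure_config()].
#' @return list with `genotypes` (filtered matrix), `kept_snps`,
#'   `kept_individuals`.
#' @export
filter_snps <- function(genotypes, qual, biallelic = NULL,
                        config = structure_config()) {
  m <- ncol(genotypes)
  if (is.null(biallelic)) biallelic <- rep(TRUE, m)
  stopifnot(length(qual) == m, length(biallelic) == m)
  call_rate <- colMeans(!is.na(genotypes))
  keep_snp <- qual >= config$min_qual & call_rate >= config$min_call_rate_snp
  if (config$biallelic_only) keep_snp <- keep_snp & biallelic
  g <- genotypes[, keep_snp, drop = FALSE]
  if (ncol(g) == 0L) {
    stop("no SNP passes the filters; consider relaxing min_qual or ",
         "min_call_rate_snp")
  }
  ind_rate <- rowMeans(!is.na(g))
  keep_ind <- ind_rate >= config$min_call_rate_individual
  g <- g[keep_ind, , drop = FALSE]
  if (nrow(g) == 0L) {
    stop("no individual passes the call-rate filter")
  }
  list(genotypes = g, kept_snps = colnames(genotypes)[keep_snp],
       kept_individuals = rownames(genotypes)[keep_ind])
}

#' PCA of a genotype matrix
#'
#' Genotypes coded as 0/1/2 alternate-allele counts; missing entries are
#' mean-imputed per SNP; zero-variance SNPs are excluded; centred (not
#' scaled) PCA.
#'
#' @param genotypes individuals x SNPs matrix.
#' @return list with `scores`, `prop_variance`, `n_snps_used`.
#' @export
genotype_pca <- function(genotypes) {
  stopifnot(nrow(genotypes) >= 3L)
  g <- apply(genotypes, 2L, function(col) {
    col[is.na(col)] <- mean(col, na.rm = TRUE)
    col
  })
  v <- apply(g, 2L, stats::var)
  g <- g[, v > 0, drop = FALSE]
  pc <- prcomp(g, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  list(scores = pc$x, prop_variance = ev / sum(ev), n_snps_used = ncol(g))
}

#' Select the number of k-means clusters by average silhouette width
#'
#' Runs k-means (best of `n_init` restarts, fixed seed stream) for every k
#' in `k_range` on the leading principal components explaining at least
#' `var_explained` of the variance (or on the raw matrix with
#' `use_pca = FALSE`), scores each partition by the average silhouette
#' width on Euclidean distances, and returns the k attaining the maximum;
#' ties break to the smallest k. Values of k with too few individuals
#' (n <= k) are skipped.
#'
#' @param genotypes individuals x SNPs matrix (or any numeric matrix with
#'   `use_pca = FALSE`).
#' @param config a [structure_config()].
#' @param use_pca cluster on leading PCA scores (default) or on the matrix
#'   as supplied.
#' @return a `cluster_result` list: `chosen_k`, `assignments` (named integer
#'   vector), `silhouette` (named numeric, mean width per k), `scores` (the
#'   PCA scores used, or `NULL`), `tie` (logical: was the maximum tied).
#' @export
select_k_kmeans <- function(genotypes, config = structure_config(),
                            use_pca = TRUE) {
  if (use_pca) {
    pc <- genotype_pca(genotypes)
    ncomp <- max(which(cumsum(pc$prop_variance) >= config$var_explained)[1], 2L)
    ncomp <- min(ncomp, ncol(pc$scores))
    x <- pc$scores[, seq_len(ncomp), drop = FALSE]
    scores <- pc$scores
  } else {
    x <- as.matrix(genotypes)
    scores <- NULL
  }
  n <- nrow(x)
  d <- dist(x)
  sil <- setNames(rep(NA_real_, length(config$k_range)),
                  as.character(config$k_range))
  parts <- list()
  set.seed(config$seed)
  for (k in config$k_range) {
    if (n <= k) next
    km <- kmeans(x, centers = k, nstart = config$n_init, iter.max = 100L)
    sw <- cluster::silhouette(km$cluster, d)
    sil[as.character(k)] <- mean(sw[, "sil_width"])
    parts[[as.character(k)]] <- km$cluster
  }
  if (all(is.na(sil))) stop("no k in range is feasible for n = ", n)
  best <- max(sil, na.rm = TRUE)
  winners <- config$k_range[!is.na(sil) & sil >= best - 1e-12]
  chosen <- min(winners)
  assignments <- parts[[as.character(chosen)]]
  names(assignments) <- rownames(x)
  out <- list(chosen_k = chosen, assignments = assignments,
              silhouette = sil, scores = scores,
              tie = length(winners) > 1L)
  class(out) <- "cluster_result"
  out
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("Silhouette-selected k-means clustering\n")
  cat("  chosen k:", x$chosen_k,
      if (x$tie) "(tie broken to smallest k)", "\n")
  cat("  mean silhouette by k:\n")
  print(round(x$silhouette, 3))
  invisible(x)
}

#' Best label agreement between two partitions
#'
#' Fraction of individuals on which two cluster labelings agree, maximised
#' over all permutations of the labels of `b` (label-permutation-invariant
#' match; exact over all k! permutations, intended for small k).
#'
#' @param a,b integer vectors of cluster labels.
#' @return agreement fraction in \[0, 1\].
#' @export
cluster_agreement <- function(a, b) {
  stopifnot(length(a) == length(b))
  la <- sort(unique(a)); lb <- sort(unique(b))
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  if (length(lb) > 8L) stop("too many clusters for exact permutation match")
  best <- 0
  for (p in perms(lb)) {
    mapped <- setNames(p, lb)[as.character(b)]
    best <- max(best, mean(a == mapped))
  }
  best
}
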