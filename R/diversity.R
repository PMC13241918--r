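#' Genotype-call filter configuration
#'
#' @param min_depth minimum read depth (inclusive); used both for call
#'   filtering and for the covered-length denominator.
#' @param min_qual minimum site QUAL (inclusive).
#' @param biallelic_only keep only biallelic SNPs.
#' @return a `call_filter_config` list.
#' @export
call_filter_config <- function(min_depth = 6L, min_qual = 100,
                               biallelic_only = TRUE) {
  stopifnot(min_depth >= 1L, min_qual >= 0)
  structure(list(min_depth = as.integer(min_depth), min_qual = min_qual,
                 biallelic_only = isTRUE(biallelic_only)),
            class = "call_filter_config")
}

in_mask <- function(chrom, pos, exons) {
  ok <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(exons))) {
    ok <- ok | (chrom == exons$chrom[i] &
                  pos >= exons$start[i] & pos < exons$end[i])
  }
  ok
}

#' Filter genotype calls for diversity estimation
#'
#' Keeps records that are biallelic SNPs (when `biallelic_only`), fall inside
#' the exon mask, and meet the depth and quality minima (both inclusive:
#' depth 6 and QUAL 100 pass at the defaults). Malformed records (missing
#' depth or quality) are skipped with a warning.
#'
#' @param calls data.frame of call records (`chrom`, `pos` 0-based, `ref`,
#'   `alt`, `genotype`, `depth`, `qual`, `biallelic`), e.g. from
#'   [read_vcf_calls()] or [simulate_site_calls()].
#' @param exons exon mask data.frame (`chrom`, `start`, `end`, 0-based
#'   half-open).
#' @param config a [call_filter_config()].
#' @return the filtered call data.frame.
#' @export
filter_calls <- function(calls, exons, config = call_filter_config()) {
  if (nrow(calls) == 0) return(calls)
  malformed <- is.na(calls$depth) | is.na(calls$qual)
  if (any(malformed)) {
    warning(sum(malformed), " malformed call record(s) skipped")
    calls <- calls[!malformed, , drop = FALSE]
  }
  keep <- calls$depth >= config$min_depth & calls$qual >= config$min_qual &
    in_mask(calls$chrom, calls$pos, exons)
  if (config$biallelic_only) keep <- keep & calls$biallelic
  calls[keep, , drop = FALSE]
}

is_het <- function(gt) {
  parts <- strsplit(gt, "[/|]")
  vapply(parts, function(p) length(p) == 2L && p[1] != p[2], logical(1L))
}

#' Per-individual percentage of polymorphic (heterozygous) sites
#'
#' The diversity statistic: heterozygous filtered exonic calls divided by the
#' number of masked positions covered at `min_depth` or more reads, times
#' 100. The same depth threshold governs numerator and denominator.
#'
#' @param calls call records for one individual (see [filter_calls()]).
#' @param depth_track data.frame (`chrom`, `pos` 0-based, `depth`) covering
#'   the masked positions.
#' @param exons exon mask data.frame.
#' @param config a [call_filter_config()].
#' @param sample_id,species identifiers carried into the result.
#' @return one-row data.frame with `sample_id`, `species`, `n_het_sites`,
#'   `covered_exon_len`, `pct_polymorphic`; `NULL` (with a warning) when no
#'   masked position reaches the depth threshold.
#' @examples
#' # 2 het sites over 400 covered bp -> 0.5%
#' @export
pct_polymorphic <- function(calls, depth_track, exons,
                            config = call_filter_config(),
                            sample_id = NA_character_,
                            species = NA_character_) {
  dt <- depth_track[in_mask(depth_track$chrom, depth_track$pos, exons), ,
                    drop = FALSE]
  covered <- sum(dt$depth >= config$min_depth)
  if (covered == 0L) {
    warning("no masked position covered at depth >= ", config$min_depth,
            "; estimate undefined for ", sample_id)
    return(NULL)
  }
  filtered <- filter_calls(calls, exons, config)
  n_het <- sum(is_het(filtered$genotype))
  data.frame(sample_id = sample_id, species = species,
             n_het_sites = n_het, covered_exon_len = covered,
             pct_polymorphic = 100 * n_het / covered,
             stringsAsFactors = FALSE)
}

#' Mean diversity per species
#'
#' Arithmetic mean of the per-individual percentages, with the number of
#' individuals contributing.
#'
#' @param estimates data.frame of rows from [pct_polymorphic()].
#' @return data.frame `species`, `mean_pct_polymorphic`, `n`.
#' @export
species_mean <- function(estimates) {
  stopifnot(nrow(estimates) >= 1L)
  agg <- aggregate(pct_polymorphic ~ species, data = estimates, FUN = mean)
  n <- aggregate(pct_polymorphic ~ species, data = estimates, FUN = length)
  data.frame(species = agg$species,
             mean_pct_polymorphic = agg$pct_polymorphic,
             n = n$pct_polymorphic, stringsAsFactors = FALSE)
}

#' Ordinary least-squares regression between two diversity measures
#'
#' Used to compare diversity estimates across marker classes (e.g. nuclear
#' vs. mitochondrial) or against the area occupied by the samples. Classical
#' t-based p-value for the slope.
#'
#' @param x,y numeric vectors (n >= 3).
#' @return list with `slope`, `intercept`, `r_squared`, `p_value`, `n`.
#' @export
diversity_regression <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  stopifnot(length(x) >= 3L)
  if (sd(x) == 0) stop("zero variance in x; regression undefined")
  fit <- lm(y ~ x)
  s <- summary(fit)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = s$r.squared,
       p_value = s$coefficients[2, 4], n = length(x))
}

#' @importFrom stats aggregate
NULL
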