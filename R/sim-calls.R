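#' Simulate per-individual genotype calls over an exon mask
#'
#' Emulates the substrate of the per-individual diversity statistic: exonic
#' positions are heterozygous independently with probability `theta`, read
#' depth is drawn per site from a negative binomial (mean `depth_mean`,
#' dispersion `depth_dispersion`), and the site quality is
#' `qual_per_read * depth`. The exon mask is a set of disjoint intervals
#' (0-based, half-open) totalling `exon_len` bp on a single synthetic contig.
#'
#' Only variant (heterozygous) sites become call records; the depth track
#' covers every masked position so that the covered-length denominator can be
#' computed downstream.
#'
#' @param config a [sim_config()].
#' @param species species id used to pick `theta` (recycled over
#'   `theta_per_species`) and to seed the stream, so different individuals
#'   of one species share theta but not noise.
#' @param sample_id sample identifier written into the output.
#' @param theta optional override of the per-site heterozygosity probability.
#' @return a list with elements
#'   \describe{
#'     \item{calls}{data.frame of heterozygous records: `chrom`, `pos`
#'       (0-based), `ref`, `alt`, `genotype` ("0/1"), `depth`, `qual`,
#'       `biallelic`;}
#'     \item{exons}{data.frame `chrom`, `start`, `end` (0-based half-open);}
#'     \item{depth}{data.frame `chrom`, `pos` (0-based), `depth` for every
#'       masked position;}
#'     \item{theta, sample_id, species}{the generating parameters.}
#'   }
#' @examples
#' sc <- simulate_site_calls(sim_config(seed = 2, exon_len = 2000), "sp001")
#' nrow(sc$calls)
#' @export
simulate_site_calls <- function(config, species, sample_id = paste0(species, "_s1"),
                                theta = NULL) {
  validate_sim_config(config)
  sp_index <- if (grepl("[0-9]+$", species))
    as.integer(sub(".*?([0-9]+)$", "\\1", species)) else 1L
  if (is.null(theta)) {
    th <- rep(config$theta_per_species, length.out = max(sp_index, 1L))
    theta <- th[[max(sp_index, 1L)]]
  }
  set.seed(child_seed(config$seed, paste0("site_calls_", sample_id)))

  # carve exon_len into exon intervals of ~200-600 bp along one contig
  exon_lens <- integer(0)
  remaining <- config$exon_len
  while (remaining > 0L) {
    l <- min(remaining, sample(200:600, 1L))
    exon_lens <- c(exon_lens, l)
    remaining <- remaining - l
  }
  gaps <- sample(100:400, length(exon_lens), replace = TRUE)
  starts <- cumsum(c(0L, exon_lens[-length(exon_lens)] + gaps[-length(gaps)]))
  exons <- data.frame(chrom = "contig1", start = starts,
                      end = starts + exon_lens)

  pos <- unlist(Map(function(s, e) seq.int(s, e - 1L), exons$start, exons$end))
  n <- length(pos)
  depth <- rnbinom(n, size = config$depth_dispersion, mu = config$depth_mean)
  het <- runif(n) < theta

  ref <- sample(DNA_BASES, n, replace = TRUE)
  alt <- vapply(ref[het], function(b) sample(setdiff(DNA_BASES, b), 1L),
                character(1L))
  n_het <- sum(het)
  calls <- data.frame(
    chrom = rep("contig1", n_het), pos = pos[het], ref = ref[het],
    alt = alt, genotype = rep("0/1", n_het), depth = depth[het],
    qual = config$qual_per_read * depth[het],
    biallelic = rep(TRUE, n_het), stringsAsFactors = FALSE)

  list(calls = calls, exons = exons,
       depth = data.frame(chrom = "contig1", pos = pos, depth = depth),
       theta = theta, sample_id = sample_id, species = species)
}

#' Write simulated site calls as VCF v4.2, BED mask and depth track
#'
#' The VCF carries QUAL and `DP` in INFO and a single unphased diploid
#' genotype column; positions are converted from the internal 0-based
#' convention to 1-based at emission. The exon mask stays 0-based half-open
#' (the BED convention), and the depth track is a BED-graph-style TSV.
#'
#' @param sc result of [simulate_site_calls()].
#' @param vcf_path,bed_path,depth_path output file paths (`bed_path` and
#'   `depth_path` optional).
#' @return `vcf_path`, invisibly.
#' @export
write_site_calls <- function(sc, vcf_path, bed_path = NULL, depth_path = NULL) {
  con <- file(vcf_path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=orthopanel",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           sc$sample_id)), con)
  if (nrow(sc$calls) > 0) {
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t%g\tPASS\tDP=%d\tGT:DP\t%s:%d",
                       sc$calls$chrom, sc$calls$pos + 1L, sc$calls$ref,
                       sc$calls$alt, sc$calls$qual, sc$calls$depth,
                       sc$calls$genotype, sc$calls$depth), con)
  }
  if (!is.null(bed_path)) {
    write.table(sc$exons, bed_path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(depth_path)) {
    write.table(sc$depth, depth_path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(vcf_path)
}

#' Read genotype call records from a VCF file
#'
#' Thin wrapper over [vcfR::read.vcfR()] returning the flat call data.frame
#' the diversity module consumes. Positions are converted to the internal
#' 0-based convention; a record is flagged biallelic when ALT holds exactly
#' one allele and both REF and ALT are single bases.
#'
#' @param vcf_path VCF file.
#' @return data.frame with columns `chrom`, `pos` (0-based), `ref`, `alt`,
#'   `genotype`, `depth`, `qual`, `biallelic`.
#' @export
read_vcf_calls <- function(vcf_path) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      genotype = character(0), depth = integer(0),
                      qual = numeric(0), biallelic = logical(0)))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  dp_fmt <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  dp_info <- suppressWarnings(as.integer(sub(".*DP=([0-9]+).*", "\\1", fix$INFO)))
  depth <- ifelse(is.na(dp_fmt[, 1]), dp_info, dp_fmt[, 1])
  alt <- fix$ALT
  biallelic <- !grepl(",", alt) & nchar(fix$REF) == 1L &
    nchar(alt) == 1L & alt %in% DNA_BASES
  data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS) - 1L,
             ref = fix$REF, alt = alt, genotype = unname(gt[, 1]),
             depth = as.integer(depth),
             qual = suppressWarnings(as.numeric(fix$QUAL)),
             biallelic = biallelic, stringsAsFactors = FALSE)
}

#' Read a BED exon mask
#'
#' @param bed_path BED file (0-based, half-open).
#' @return data.frame `chrom`, `start`, `end`.
#' @export
read_bed_mask <- function(bed_path) {
  b <- read.table(bed_path, sep = "\t", stringsAsFactors = FALSE)[, 1:3]
  names(b) <- c("chrom", "start", "end")
  b
}
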