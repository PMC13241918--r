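#' Ortholog-assignment configuration
#'
#' A captured genomic region is assigned to its targeted locus when the
#' probe-to-region alignment distance is strictly below `max_distance`
#' percent and at least `min_samples_mapped` samples mapped to the region.
#'
#' @param max_distance assignment threshold in percent (strict `<`).
#' @param min_samples_mapped minimum mapping support.
#' @return an `assign_config` list.
#' @export
assign_config <- function(max_distance = 30, min_samples_mapped = 3L) {
  stopifnot(max_distance >= 0, max_distance <= 100, min_samples_mapped >= 0L)
  structure(list(max_distance = max_distance,
                 min_samples_mapped = as.integer(min_samples_mapped)),
            class = "assign_config")
}

#' Uncorrected pairwise p-distance in percent
#'
#' 100 x (mismatching comparable columns) / (comparable columns), where a
#' comparable column carries a non-gap residue in both rows. Symmetric, zero
#' for identical rows, uncorrected for multiple hits.
#'
#' @param a,b two aligned sequences of equal length (strings).
#' @return percent distance; `NA` with a warning when no column is
#'   comparable.
#' @examples
#' p_distance("ACGTACGTAC", "ACGTACGTTT")  # 20
#' @export
p_distance <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  x <- seq_to_bases(toupper(a))
  y <- seq_to_bases(toupper(b))
  comparable <- !(x %in% MISSING_CHARS) & !(y %in% MISSING_CHARS)
  n <- sum(comparable)
  if (n == 0L) {
    warning("no comparable columns; distance undefined")
    return(NA_real_)
  }
  100 * sum(x[comparable] != y[comparable]) / n
}

#' Globally align a probe to a candidate region
#'
#' Needleman-Wunsch global alignment with affine gap costs via
#' [Biostrings::pairwiseAlignment()]. Both strands of the region are tried
#' and the alignment giving the lower p-distance is returned — hybridisation
#' capture is strand-agnostic.
#'
#' @param probe,region nucleotide sequences (strings).
#' @param match,mismatch,gap_open,gap_extend alignment scores.
#' @return list with `probe_aln`, `region_aln` (gapped strings), `strand`
#'   ("+"/"-") and `distance` (percent p-distance).
#' @export
align_pair <- function(probe, region, match = 1, mismatch = -1,
                       gap_open = 5, gap_extend = 2) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch)
  one <- function(subject, strand) {
    al <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(probe), Biostrings::DNAString(subject),
      type = "global", substitutionMatrix = mat,
      gapOpening = gap_open, gapExtension = gap_extend)
    pa <- as.character(Biostrings::alignedPattern(al))
    ra <- as.character(Biostrings::alignedSubject(al))
    list(probe_aln = pa, region_aln = ra, strand = strand,
         distance = suppressWarnings(p_distance(pa, ra)))
  }
  fwd <- one(region, "+")
  rev <- one(as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(region))), "-")
  if (is.na(rev$distance) ||
      (!is.na(fwd$distance) && fwd$distance <= rev$distance)) fwd else rev
}

#' Classify a candidate region as ortholog or reject it
#'
#' Assigned iff mapping support reaches `min_samples_mapped` and the
#' alignment p-distance is strictly below `max_distance` (a distance of
#' exactly the threshold is rejected). The support rule is checked first;
#' an undefined distance rejects on distance with a flag.
#'
#' @param probe_aln,region_aln a pre-aligned probe/region pair (equal-length
#'   gapped strings); alternatively pass unaligned sequences with
#'   `aligned = FALSE` to route through [align_pair()].
#' @param n_samples_mapped mapping support count of the region.
#' @param config an [assign_config()].
#' @param aligned set `FALSE` to align first.
#' @return list with `status` ("assigned", "rejected_distance" or
#'   "rejected_support"), `distance` (percent) and `reason`.
#' @examples
#' classify_region("ACGTACGTAC", "ACGTACGTAC", n_samples_mapped = 3)$status
#' @export
classify_region <- function(probe_aln, region_aln, n_samples_mapped,
                            config = assign_config(), aligned = TRUE) {
  if (!aligned) {
    al <- align_pair(probe_aln, region_aln)
    probe_aln <- al$probe_aln
    region_aln <- al$region_aln
  }
  d <- suppressWarnings(p_distance(probe_aln, region_aln))
  if (n_samples_mapped < config$min_samples_mapped) {
    return(list(status = "rejected_support", distance = d,
                reason = sprintf("support %d < %d", n_samples_mapped,
                                 config$min_samples_mapped)))
  }
  if (is.na(d)) {
    return(list(status = "rejected_distance", distance = NA_real_,
                reason = "distance undefined (no comparable columns)"))
  }
  if (d < config$max_distance) {
    list(status = "assigned", distance = d, reason = NA_character_)
  } else {
    list(status = "rejected_distance", distance = d,
         reason = sprintf("distance %.2f >= %g", d, config$max_distance))
  }
}
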