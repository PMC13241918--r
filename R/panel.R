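#' Probe-panel design configuration
#'
#' Thresholds of the conserved-locus filter cascade: probes are fixed-length
#' 170-mers tiled without overlap; single-copy-ortholog loci are represented
#' by their two 120-bp ends; candidate loci must be recovered in at least
#' `min_genomes` genomes, be at least `min_locus_len` bp long, show at most
#' `max_variable_frac` variable alignment columns and at most
#' `max_within_clade_div` maximum pairwise p-distance within either suborder
#' clade.
#'
#' @param probe_len tiling probe length in bp.
#' @param end_probe_len end-probe length in bp for single-copy orthologs.
#' @param min_genomes minimum number of genomes a locus must be captured in.
#' @param min_locus_len minimum locus length in bp.
#' @param max_variable_frac maximum fraction of variable alignment columns.
#' @param max_within_clade_div maximum within-clade pairwise p-distance
#'   (fraction).
#' @return a `panel_config` list.
#' @export
panel_config <- function(probe_len = 170L, end_probe_len = 120L,
                         min_genomes = 6L, min_locus_len = 120L,
                         max_variable_frac = 0.50,
                         max_within_clade_div = 0.10) {
  stopifnot(probe_len >= 1L, end_probe_len >= 1L, min_genomes >= 1L,
            min_locus_len >= 0L,
            max_variable_frac >= 0, max_variable_frac <= 1,
            max_within_clade_div >= 0, max_within_clade_div <= 1)
  structure(list(probe_len = as.integer(probe_len),
                 end_probe_len = as.integer(end_probe_len),
                 min_genomes = as.integer(min_genomes),
                 min_locus_len = as.integer(min_locus_len),
                 max_variable_frac = max_variable_frac,
                 max_within_clade_div = max_within_clade_div),
            class = "panel_config")
}

strip_gaps <- function(s) gsub("-", "", s, fixed = TRUE)

#' Tile a sequence into non-overlapping fixed-length probes
#'
#' Probes start at offsets 0, `probe_len`, 2*`probe_len`, ... in the ungapped
#' sequence; a terminal remainder shorter than `probe_len` is dropped, so the
#' probe count is `floor(length / probe_len)`.
#'
#' @param sequence ungapped nucleotide sequence (a single string); gaps, if
#'   present, are removed first.
#' @param probe_len probe length in bp.
#' @param locus_id optional locus id carried into the output.
#' @return data.frame with columns `locus_id`, `offset` (0-based), `length`,
#'   `role` ("tile"), `sequence`; zero rows for an empty sequence.
#' @examples
#' nrow(tile_probes(strrep("ACGT", 100), 170))  # 2 probes from 400 bp
#' @export
tile_probes <- function(sequence, probe_len = 170L, locus_id = NA_character_) {
  probe_len <- as.integer(probe_len)
  sequence <- strip_gaps(sequence)
  L <- nchar(sequence)
  n <- L %/% probe_len
  if (n == 0L) {
    return(data.frame(locus_id = character(0), offset = integer(0),
                      length = integer(0), role = character(0),
                      sequence = character(0), stringsAsFactors = FALSE))
  }
  offs <- (seq_len(n) - 1L) * probe_len
  data.frame(locus_id = locus_id, offset = offs, length = probe_len,
             role = "tile",
             sequence = substring(sequence, offs + 1L, offs + probe_len),
             stringsAsFactors = FALSE)
}

#' Extract the two end-probes of a single-copy ortholog
#'
#' Emits the first and last `end_probe_len` bp of the sequence; because the
#' two ends of an ortholog are generally separated by long introns, each end
#' probe is treated as an independent locus downstream (see
#' [build_panel_manifest()]). Sequences shorter than twice the probe length
#' yield a single truncated probe with a warning rather than failing, keeping
#' a panel run total.
#'
#' @param sequence ungapped nucleotide sequence.
#' @param end_probe_len end-probe length in bp.
#' @param locus_id optional locus id.
#' @return data.frame as in [tile_probes()] with roles "end5"/"end3".
#' @examples
#' usco_end_probes(strrep("ACGT", 100))$offset  # 0 and 280
#' @export
usco_end_probes <- function(sequence, end_probe_len = 120L,
                            locus_id = NA_character_) {
  end_probe_len <- as.integer(end_probe_len)
  sequence <- strip_gaps(sequence)
  L <- nchar(sequence)
  if (L < 2L * end_probe_len) {
    warning("sequence ", locus_id, " shorter than two end-probes (", L,
            " bp); emitting a single probe")
    len <- min(L, end_probe_len)
    return(data.frame(locus_id = locus_id, offset = 0L, length = len,
                      role = "end5", sequence = substring(sequence, 1L, len),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    locus_id = locus_id,
    offset = c(0L, L - end_probe_len),
    length = end_probe_len,
    role = c("end5", "end3"),
    sequence = c(substring(sequence, 1L, end_probe_len),
                 substring(sequence, L - end_probe_len + 1L, L)),
    stringsAsFactors = FALSE)
}

aln_matrix <- function(seqs) {
  stopifnot(length(unique(nchar(seqs))) == 1L)
  do.call(rbind, strsplit(toupper(seqs), "", fixed = TRUE))
}

#' Fraction of variable columns in a locus alignment
#'
#' A column is comparable when at least two rows carry a non-gap residue, and
#' variable when those residues include at least two distinct states. The
#' returned value is variable / comparable — gap-only or single-residue
#' columns do not count as variation.
#'
#' @param seqs character vector of >= 2 aligned sequences (equal length).
#' @return fraction in \[0, 1\]; `NA` when no column is comparable.
#' @export
variable_site_fraction <- function(seqs) {
  stopifnot(length(seqs) >= 2L)
  m <- aln_matrix(seqs)
  res <- !(m %in% MISSING_CHARS)
  dim(res) <- dim(m)
  comparable <- colSums(res) >= 2L
  if (!any(comparable)) return(NA_real_)
  variable <- vapply(which(comparable), function(j) {
    length(unique(m[res[, j], j])) >= 2L
  }, logical(1L))
  sum(variable) / sum(comparable)
}

#' Maximum pairwise p-distance within each clade of a locus alignment
#'
#' For every clade with at least two member sequences, returns the maximum
#' uncorrected pairwise p-distance (fraction, see [p_distance()]); clades
#' with fewer than two members are omitted.
#'
#' @param seqs named character vector of aligned sequences.
#' @param clades character vector of clade labels, parallel to `seqs` (or
#'   taken from `attr(seqs, "clades")`).
#' @return named numeric vector, one entry per scored clade.
#' @export
within_clade_divergence <- function(seqs, clades = attr(seqs, "clades")) {
  stopifnot(!is.null(clades), length(clades) == length(seqs))
  out <- c()
  for (cl in unique(clades)) {
    idx <- which(clades == cl)
    if (length(idx) < 2L) next
    dmax <- 0
    for (i in idx) for (j in idx) {
      if (j <= i) next
      d <- p_distance(seqs[[i]], seqs[[j]]) / 100
      if (!is.na(d)) dmax <- max(dmax, d)
    }
    out[cl] <- dmax
  }
  out
}

#' Apply the conserved-locus filter cascade to candidate loci
#'
#' A UCE-type candidate is kept iff it is present in at least `min_genomes`
#' genomes, its alignment is at least `min_locus_len` columns long, its
#' variable-site fraction does not exceed `max_variable_frac`, and every
#' within-clade maximum p-distance is at most `max_within_clade_div`.
#' USCO-type candidates skip the variability and divergence clauses (their
#' conservation is asserted by single-copy orthology) and apply only the
#' genome-count rule. Each rejection records the first failing rule, checked
#' in the order `min_genomes`, `min_locus_len`, `max_variable_frac`,
#' `max_within_clade_div`.
#'
#' @param loci list of candidate loci; each element a list with fields `id`,
#'   `type` ("UCE"/"USCO"/"MITO"/"RDNA"), `seqs` (named aligned sequences)
#'   and `clades` (per-sequence labels; defaults to `attr(seqs, "clades")`).
#' @param config a [panel_config()].
#' @return list with `kept` (the surviving loci) and `rejected` (data.frame
#'   `id`, `type`, `reason`).
#' @export
filter_candidates <- function(loci, config = panel_config()) {
  kept <- list()
  rej <- list()
  for (lc in loci) {
    clades <- lc$clades %||% attr(lc$seqs, "clades")
    reason <- NA_character_
    n_genomes <- length(lc$seqs)
    len <- nchar(lc$seqs[[1]])
    if (n_genomes < config$min_genomes) {
      reason <- "min_genomes"
    } else if (identical(lc$type, "UCE")) {
      if (len < config$min_locus_len) {
        reason <- "min_locus_len"
      } else {
        vf <- variable_site_fraction(lc$seqs)
        if (!is.na(vf) && vf > config$max_variable_frac) {
          reason <- "max_variable_frac"
        } else {
          wcd <- within_clade_divergence(lc$seqs, clades)
          if (length(wcd) && any(wcd > config$max_within_clade_div)) {
            reason <- "max_within_clade_div"
          }
        }
      }
    }
    if (is.na(reason)) {
      kept[[length(kept) + 1L]] <- lc
    } else {
      rej[[length(rej) + 1L]] <- data.frame(id = lc$id, type = lc$type,
                                            reason = reason,
                                            stringsAsFactors = FALSE)
    }
  }
  list(kept = kept,
       rejected = if (length(rej)) do.call(rbind, rej) else
         data.frame(id = character(0), type = character(0),
                    reason = character(0)))
}

#' Build the panel manifest of targeted loci
#'
#' One row per targeted locus: each kept UCE contributes one locus; each
#' single-copy-ortholog end-probe is registered as an independent locus
#' (the two ends of one gene are separated by intronic sequence and behave
#' as unlinked capture targets). Mito/rDNA tiles, when supplied, contribute
#' one locus per source alignment.
#'
#' @param uce_loci list of kept UCE candidates (fields `id`, `type`).
#' @param usco_probes data.frame of end-probes from [usco_end_probes()]
#'   (fields `locus_id`, `role`).
#' @param other_loci optional additional loci (fields `id`, `type`).
#' @return list with `manifest` (data.frame `locus_id`, `type`, `source_id`)
#'   and `counts` (named integer vector by type plus `total`).
#' @examples
#' # 290 UCE + 54 two-end orthologs -> 398 targeted loci
#' @export
build_panel_manifest <- function(uce_loci = list(), usco_probes = NULL,
                                 other_loci = list()) {
  rows <- list()
  for (lc in uce_loci) {
    rows[[length(rows) + 1L]] <- data.frame(
      locus_id = lc$id, type = lc$type %||% "UCE", source_id = lc$id,
      stringsAsFactors = FALSE)
  }
  if (!is.null(usco_probes) && nrow(usco_probes) > 0) {
    rows[[length(rows) + 1L]] <- data.frame(
      locus_id = paste0(usco_probes$locus_id, "_", usco_probes$role),
      type = "USCO", source_id = usco_probes$locus_id,
      stringsAsFactors = FALSE)
  }
  for (lc in other_loci) {
    rows[[length(rows) + 1L]] <- data.frame(
      locus_id = lc$id, type = lc$type, source_id = lc$id,
      stringsAsFactors = FALSE)
  }
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(locus_id = character(0), type = character(0),
               source_id = character(0))
  if (anyDuplicated(manifest$locus_id)) {
    stop("duplicate locus ids in panel manifest: ",
         paste(unique(manifest$locus_id[duplicated(manifest$locus_id)]),
               collapse = ", "))
  }
  counts <- table(manifest$type)
  counts <- c(setNames(as.integer(counts), names(counts)),
              total = nrow(manifest))
  list(manifest = manifest, counts = counts)
}

#' Write probes to FASTA with `locusID|role|offset` headers
#'
#' @param probes data.frame from [tile_probes()]/[usco_end_probes()].
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_probe_fasta <- function(probes, path) {
  seqs <- setNames(probes$sequence,
                   sprintf("%s|%s|%d", probes$locus_id, probes$role,
                           probes$offset))
  write_fasta(seqs, path)
}
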