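#' Locus/sample quality-control configuration
#'
#' @param max_seq_missing per-sequence missing fraction above which a row is
#'   dropped (strict `>`).
#' @param min_locus_occupancy minimum fraction of samples a locus must be
#'   present in (inclusive `>=`).
#' @param max_sample_missing sample missing-locus fraction at or above which
#'   a sample is dropped (samples with *less than* this fraction missing are
#'   kept).
#' @param paralog_levels ordered taxonomy levels for the paralog screen,
#'   coarse to fine.
#' @param paralog_z_threshold outlier multiplier on the MAD in the paralog
#'   screen.
#' @param sample_missing_unit whether sample missingness is measured as the
#'   fraction of missing loci (`"loci"`, default) or of missing characters
#'   over the concatenated matrix (`"characters"`).
#' @return a `qc_config` list.
#' @export
qc_config <- function(max_seq_missing = 0.40, min_locus_occupancy = 1 / 3,
                      max_sample_missing = 0.20,
                      paralog_levels = c("order", "family", "genus"),
                      paralog_z_threshold = 5,
                      sample_missing_unit = c("loci", "characters")) {
  stopifnot(max_seq_missing >= 0, max_seq_missing <= 1,
            min_locus_occupancy >= 0, min_locus_occupancy <= 1,
            max_sample_missing >= 0, max_sample_missing <= 1,
            length(paralog_levels) >= 1L, paralog_z_threshold > 0)
  structure(list(max_seq_missing = max_seq_missing,
                 min_locus_occupancy = min_locus_occupancy,
                 max_sample_missing = max_sample_missing,
                 paralog_levels = paralog_levels,
                 paralog_z_threshold = paralog_z_threshold,
                 sample_missing_unit = match.arg(sample_missing_unit)),
            class = "qc_config")
}

#' Per-sequence missing fraction of an aligned matrix
#'
#' Gaps (`-`), `N` and `?` all count as missing.
#'
#' @param mat named character vector of aligned sequences.
#' @return numeric vector of missing fractions, named by sample.
#' @export
missing_fraction <- function(mat) {
  vapply(mat, function(s) {
    b <- seq_to_bases(s)
    sum(b %in% MISSING_CHARS) / length(b)
  }, numeric(1L))
}

#' Drop overly gappy sequences from a locus alignment
#'
#' Rows whose missing fraction (gaps + Ns over columns) exceeds
#' `max_seq_missing` are removed; a row at exactly the threshold is kept.
#'
#' @param mat named character vector of aligned sequences.
#' @param config a [qc_config()].
#' @return the filtered alignment, with attribute `removed` naming dropped
#'   rows.
#' @export
drop_gappy_sequences <- function(mat, config = qc_config()) {
  mf <- missing_fraction(mat)
  drop <- mf > config$max_seq_missing
  out <- mat[!drop]
  attr(out, "removed") <- names(mat)[drop]
  out
}

#' Occupancy filter over a set of locus alignments
#'
#' Loci present in at least `min_locus_occupancy` of the samples are kept
#' first; then samples whose missing-locus fraction over the kept loci is
#' `>= max_sample_missing` are removed (the keep rule is strict: less than
#' the threshold missing). With `sample_missing_unit = "characters"` the
#' sample criterion uses missing characters over the would-be supermatrix
#' instead of missing loci.
#'
#' @param matrices named list of locus alignments (named character vectors).
#' @param samples character vector of the full sample universe.
#' @param config a [qc_config()].
#' @return list with `kept_loci`, `kept_samples` and `matrices` (the kept
#'   alignments restricted to kept samples).
#' @export
occupancy_filter <- function(matrices, samples, config = qc_config()) {
  stopifnot(length(samples) >= 1L)
  occ <- vapply(matrices, function(m) {
    length(intersect(names(m), samples)) / length(samples)
  }, numeric(1L))
  kept_loci <- names(matrices)[occ >= config$min_locus_occupancy]

  if (length(kept_loci) == 0L) {
    warning("no locus passes the occupancy filter")
    return(list(kept_loci = character(0), kept_samples = character(0),
                matrices = list()))
  }
  kept_mats <- matrices[kept_loci]
  if (config$sample_missing_unit == "loci") {
    miss <- vapply(samples, function(s) {
      mean(!vapply(kept_mats, function(m) s %in% names(m), logical(1L)))
    }, numeric(1L))
  } else {
    ncols <- vapply(kept_mats, function(m) nchar(m[[1]]), numeric(1L))
    miss <- vapply(samples, function(s) {
      miss_chars <- sum(vapply(seq_along(kept_mats), function(i) {
        m <- kept_mats[[i]]
        if (s %in% names(m)) missing_fraction(m[s])[[1]] * ncols[i]
        else ncols[i]
      }, numeric(1L)))
      miss_chars / sum(ncols)
    }, numeric(1L))
  }
  kept_samples <- samples[miss < config$max_sample_missing]
  if (length(kept_samples) == 0L) warning("no sample passes the missingness filter")
  out_mats <- lapply(kept_mats, function(m) m[intersect(names(m), kept_samples)])
  list(kept_loci = kept_loci, kept_samples = kept_samples,
       matrices = out_mats)
}

#' Majority-rule consensus of an aligned matrix
#'
#' Per column, the most frequent non-missing residue (ties broken by
#' alphabetical order); columns with no residue become `-`.
#'
#' @param mat named character vector of aligned sequences.
#' @return a single consensus string.
#' @export
consensus_majority <- function(mat) {
  m <- aln_matrix(mat)
  cons <- apply(m, 2L, function(col) {
    col <- col[!(col %in% MISSING_CHARS)]
    if (length(col) == 0L) return("-")
    tab <- sort(table(col), decreasing = TRUE)
    names(tab)[tab == max(tab)][1L]
  })
  paste(cons, collapse = "")
}

#' One round of the consensus-distance paralog screen
#'
#' Stand-in for a reference-based paralog filter: within each taxonomic
#' group at the given level with at least three rows, each row's p-distance
#' to the group's majority-rule consensus is computed, and rows whose
#' distance exceeds `median + threshold * MAD` of the group's distances are
#' removed. Groups with fewer than three rows are skipped. Because the rule
#' is a robust-outlier heuristic rather than a published algorithm, outputs
#' carry a `method = "consensus-distance stand-in"` attribute.
#'
#' @param mat named character vector of aligned sequences.
#' @param grouping named character vector mapping sample -> group label at
#'   this level.
#' @param threshold outlier multiplier on the MAD.
#' @return the filtered alignment with attributes `removed` (data.frame
#'   `sample`, `group`, `distance`, `cutoff`) and `method`.
#' @export
paralog_filter_round <- function(mat, grouping,
                                 threshold = qc_config()$paralog_z_threshold) {
  removed <- list()
  keep <- rep(TRUE, length(mat))
  names(keep) <- names(mat)
  for (g in unique(grouping[names(mat)])) {
    members <- names(mat)[grouping[names(mat)] == g]
    if (length(members) < 3L) next
    cons <- consensus_majority(mat[members])
    d <- vapply(mat[members], function(s)
      suppressWarnings(p_distance(s, cons)), numeric(1L))
    med <- median(d, na.rm = TRUE)
    # floor the MAD at half a percentage point: near-identical groups have
    # MAD ~ 0 and would otherwise flag any row with a single difference
    md <- max(mad(d, na.rm = TRUE), 0.5)
    cutoff <- med + threshold * md
    bad <- members[!is.na(d) & d > cutoff]
    keep[bad] <- FALSE
    if (length(bad)) {
      removed[[length(removed) + 1L]] <- data.frame(
        sample = bad, group = g, distance = unname(d[bad]), cutoff = cutoff,
        stringsAsFactors = FALSE)
    }
  }
  out <- mat[keep]
  attr(out, "removed") <- if (length(removed)) do.call(rbind, removed) else
    data.frame(sample = character(0), group = character(0),
               distance = numeric(0), cutoff = numeric(0))
  attr(out, "method") <- "consensus-distance stand-in"
  out
}

#' Consecutive paralog-screen rounds at successive taxonomy levels
#'
#' Applies [paralog_filter_round()] at each level in `config$paralog_levels`
#' (coarse to fine, conventionally order, family, genus), each round on the
#' previous round's survivors.
#'
#' @param mat named character vector of aligned sequences.
#' @param taxonomy data.frame with a `sample` column plus one column per
#'   level in `config$paralog_levels`.
#' @param config a [qc_config()].
#' @return filtered alignment with attribute `removed` (rows removed across
#'   all rounds, with a `level` column).
#' @export
paralog_filter_rounds <- function(mat, taxonomy, config = qc_config()) {
  all_removed <- list()
  for (lev in config$paralog_levels) {
    grouping <- setNames(as.character(taxonomy[[lev]]), taxonomy$sample)
    mat2 <- paralog_filter_round(mat, grouping, config$paralog_z_threshold)
    rem <- attr(mat2, "removed")
    if (nrow(rem)) {
      rem$level <- lev
      all_removed[[length(all_removed) + 1L]] <- rem
    }
    mat <- mat2
  }
  attr(mat, "removed") <- if (length(all_removed))
    do.call(rbind, all_removed) else
      data.frame(sample = character(0), group = character(0),
                 distance = numeric(0), cutoff = numeric(0),
                 level = character(0))
  attr(mat, "method") <- "consensus-distance stand-in"
  mat
}

#' Concatenate locus alignments into a supermatrix
#'
#' Samples absent from a locus are padded with the missing symbol; per-locus
#' column ranges are reported 1-based inclusive, the de-facto partition-file
#' convention.
#'
#' @param matrices named list of locus alignments.
#' @param samples sample universe (defaults to the union over loci).
#' @param missing_char padding symbol.
#' @return list with `supermatrix` (named character vector) and `partitions`
#'   (data.frame `locus`, `start`, `end`).
#' @export
concat_supermatrix <- function(matrices, samples = NULL, missing_char = "-") {
  if (is.null(samples)) {
    samples <- unique(unlist(lapply(matrices, names)))
  }
  ncols <- vapply(matrices, function(m) nchar(m[[1]]), integer(1L))
  ends <- cumsum(ncols)
  starts <- ends - ncols + 1L
  partitions <- data.frame(locus = names(matrices), start = starts,
                           end = ends, row.names = NULL,
                           stringsAsFactors = FALSE)
  super <- vapply(samples, function(s) {
    paste(vapply(seq_along(matrices), function(i) {
      m <- matrices[[i]]
      if (s %in% names(m)) m[[s]] else strrep(missing_char, ncols[i])
    }, character(1L)), collapse = "")
  }, character(1L))
  list(supermatrix = super, partitions = partitions)
}

#' Write a RAxML-style partition file
#'
#' @param partitions data.frame from [concat_supermatrix()].
#' @param path output path.
#' @param model substitution-model tag to print.
#' @return `path`, invisibly.
#' @export
write_partitions <- function(partitions, path, model = "DNA") {
  writeLines(sprintf("%s, %s = %d-%d", model, partitions$locus,
                     partitions$start, partitions$end), path)
  invisible(path)
}
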