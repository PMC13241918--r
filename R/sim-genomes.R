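#' Simulate a reference genome panel with planted conserved loci
#'
#' Generates one sequence per genome, each carrying every planted locus
#' (UCE or USCO type) separated by random spacer sequence, plus optional
#' paralogous copies. Locus copies evolve from a common ancestor under a
#' single-parameter symmetric substitution model: a shared root sequence is
#' diverged into two clade ancestors (each at `between_clade_div / 2`), and
#' each genome copy then mutates from its clade ancestor at
#' `within_clade_div / 2` per site, so expected pairwise distances match
#' [expected_p_distance()] at the configured divergences. A fraction
#' `paralog_frac` of loci additionally receives one duplicated copy per genome
#' carrying `paralog_extra_div` extra substitutions.
#'
#' @param config a [sim_config()].
#' @return a list with elements
#'   \describe{
#'     \item{genomes}{named character vector, one sequence per genome;}
#'     \item{truth}{data.frame with one row per planted copy: `locus_id`,
#'       `type`, `genome`, `clade`, `start`, `end` (0-based, half-open),
#'       `paralog` (logical);}
#'     \item{alignments}{list of per-locus alignments, each a named character
#'       vector of the orthologous copies (gap-free, equal length), with
#'       attribute `clades`;}
#'     \item{paralog_seqs}{list of per-locus named character vectors of
#'       paralogous copies (empty when `paralog_frac = 0`).}
#'   }
#' @examples
#' panel <- simulate_genome_panel(sim_config(seed = 1, n_loci_uce = 3,
#'                                           n_loci_usco = 1))
#' head(panel$truth)
#' @export
simulate_genome_panel <- function(config) {
  validate_sim_config(config)
  set.seed(child_seed(config$seed, "genome_panel"))

  n_loci <- config$n_loci_uce + config$n_loci_usco
  types <- c(rep("UCE", config$n_loci_uce), rep("USCO", config$n_loci_usco))
  locus_ids <- sprintf("%s-%03d", tolower(types),
                       c(seq_len(config$n_loci_uce),
                         seq_len(config$n_loci_usco)))
  genomes_id <- sprintf("genome%02d", seq_len(config$n_genomes))
  clades <- config$clade_labels
  names(clades) <- genomes_id

  is_paralog_locus <- rep(FALSE, n_loci)
  n_par <- round(config$paralog_frac * n_loci)
  if (n_par > 0) is_paralog_locus[sample.int(n_loci, n_par)] <- TRUE

  q_within <- config$within_clade_div / 2
  q_between <- config$between_clade_div / 2

  alignments <- vector("list", n_loci)
  paralog_seqs <- vector("list", n_loci)
  names(alignments) <- names(paralog_seqs) <- locus_ids
  copies <- vector("list", n_loci)  # per locus: named list genome -> seqs

  for (i in seq_len(n_loci)) {
    len <- sample(seq(config$locus_len_range[1], config$locus_len_range[2]), 1L)
    root <- seq_to_bases(random_sequence(len))
    clade_anc <- lapply(unique(clades), function(cl) mutate_sequence(root, q_between))
    names(clade_anc) <- unique(clades)

    ortho <- vapply(genomes_id, function(g) {
      bases_to_seq(mutate_sequence(clade_anc[[clades[[g]]]], q_within))
    }, character(1L))
    alignments[[i]] <- structure(ortho, clades = clades)

    par <- character(0)
    if (is_paralog_locus[i]) {
      par_anc <- mutate_sequence(root, config$paralog_extra_div)
      par <- vapply(genomes_id, function(g) {
        bases_to_seq(mutate_sequence(
          mutate_sequence(par_anc, q_between), q_within))
      }, character(1L))
    }
    paralog_seqs[[i]] <- par
    copies[[i]] <- list(ortho = ortho, par = par)
  }

  # lay loci down on each genome with random spacers; record coordinates
  truth <- list()
  genomes <- setNames(character(length(genomes_id)), genomes_id)
  for (g in genomes_id) {
    parts <- character(0)
    pos <- 0L
    for (i in seq_len(n_loci)) {
      spacer <- random_sequence(sample(50:200, 1L))
      parts <- c(parts, spacer)
      pos <- pos + nchar(spacer)
      s <- copies[[i]]$ortho[[g]]
      parts <- c(parts, s)
      truth[[length(truth) + 1L]] <- data.frame(
        locus_id = locus_ids[i], type = types[i], genome = g,
        clade = unname(clades[[g]]), start = pos, end = pos + nchar(s),
        paralog = FALSE, stringsAsFactors = FALSE)
      pos <- pos + nchar(s)
      if (is_paralog_locus[i]) {
        spacer <- random_sequence(sample(50:200, 1L))
        parts <- c(parts, spacer)
        pos <- pos + nchar(spacer)
        p <- copies[[i]]$par[[g]]
        parts <- c(parts, p)
        truth[[length(truth) + 1L]] <- data.frame(
          locus_id = locus_ids[i], type = types[i], genome = g,
          clade = unname(clades[[g]]), start = pos, end = pos + nchar(p),
          paralog = TRUE, stringsAsFactors = FALSE)
        pos <- pos + nchar(p)
      }
    }
    genomes[[g]] <- paste(parts, collapse = "")
  }

  list(genomes = genomes, truth = do.call(rbind, truth),
       alignments = alignments, paralog_seqs = paralog_seqs)
}

#' Write a genome panel (or any named sequences) to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read sequences from FASTA as a named character vector
#'
#' @param path FASTA file path.
#' @return named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}
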