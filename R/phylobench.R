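#' Monophyly status of one species on a labelled tree
#'
#' A species is monophyletic on an unrooted topology iff some bipartition
#' (edge) separates exactly its tips from all others; with soft-polytomy
#' semantics a species is monophyletic when its tips form exactly one side
#' of some branch. The check is rooting-invariant: every edge's tip-side set
#' is compared against the species' tip set and its complement. Species with
#' a single tip are reported as `excluded_singleton` (benchmark counts use
#' species with at least two samples only).
#'
#' @param tree an [ape::phylo] tree (rooted or unrooted; polytomies allowed).
#' @param tip_map data.frame with columns `tip`, `species`.
#' @param species species id to score.
#' @return "monophyletic", "non-monophyletic" or "excluded_singleton".
#' @examples
#' tr <- ape::read.tree(text = "((a1,a2),(b1,b2));")
#' map <- data.frame(tip = c("a1", "a2", "b1", "b2"),
#'                   species = c("A", "A", "B", "B"))
#' is_monophyletic(tr, map, "A")
#' @export
is_monophyletic <- function(tree, tip_map, species) {
  sp_tips <- tip_map$tip[tip_map$species == species]
  sp_tips <- intersect(sp_tips, tree$tip.label)
  if (length(sp_tips) == 0L) stop("species ", species, " absent from tree")
  if (length(sp_tips) == 1L) return("excluded_singleton")
  n <- length(tree$tip.label)
  if (length(sp_tips) == n) return("monophyletic")
  target <- sort(match(sp_tips, tree$tip.label))
  for (part in edge_tip_sets(tree)) {
    if (identical(part, target) ||
        identical(setdiff(seq_len(n), part), target)) {
      return("monophyletic")
    }
  }
  "non-monophyletic"
}

## tip-index set below each edge (postorder accumulation); each internal
## edge defines the bipartition {set, complement}
edge_tip_sets <- function(tree) {
  n <- length(tree$tip.label)
  nodes <- n + seq_len(tree$Nnode)
  below <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) below[[i]] <- i
  # fixed-point sweep handles any edge ordering and polytomies
  repeat {
    changed <- FALSE
    for (nd in nodes) {
      kids <- tree$edge[tree$edge[, 1] == nd, 2]
      if (!is.null(below[[nd]])) next
      if (all(!vapply(below[kids], is.null, logical(1L)))) {
        below[[nd]] <- sort(unlist(below[kids]))
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  lapply(tree$edge[, 2], function(child) below[[child]])
}

#' Count monophyletic species on a labelled tree
#'
#' Applies [is_monophyletic()] to every species in the map that appears on
#' the tree; species with one tip are excluded from the monophyly counts.
#'
#' @param tree an [ape::phylo] tree.
#' @param tip_map data.frame with columns `tip`, `species`.
#' @param marker optional marker-set label carried into the report.
#' @return a `monophyly_report` list with `status` (named character vector
#'   per species), `n_monophyletic`, `n_non_monophyletic`, `n_singleton`,
#'   `n_scored` and `marker`.
#' @examples
#' tr <- ape::read.tree(text = "((a1,b1),(a2,b2));")
#' map <- data.frame(tip = c("a1", "a2", "b1", "b2"),
#'                   species = c("A", "A", "B", "B"))
#' count_monophyletic(tr, map)$n_non_monophyletic
#' @export
count_monophyletic <- function(tree, tip_map, marker = NA_character_) {
  tip_map <- tip_map[tip_map$tip %in% tree$tip.label, , drop = FALSE]
  species <- unique(tip_map$species)
  status <- vapply(species, function(sp) is_monophyletic(tree, tip_map, sp),
                   character(1L))
  out <- list(status = status,
              n_monophyletic = sum(status == "monophyletic"),
              n_non_monophyletic = sum(status == "non-monophyletic"),
              n_singleton = sum(status == "excluded_singleton"),
              n_scored = sum(status != "excluded_singleton"),
              marker = marker)
  class(out) <- "monophyly_report"
  out
}

#' @export
print.monophyly_report <- function(x, ...) {
  cat("Monophyly report", if (!is.na(x$marker)) paste0("[", x$marker, "]"),
      "\n")
  cat(" ", x$n_monophyletic, "of", x$n_scored,
      "species with >= 2 samples monophyletic;",
      x$n_singleton, "singleton species excluded\n")
  invisible(x)
}

#' Compare marker sets on their shared scored species
#'
#' Restricts every report to the species scored (at least two tips, present)
#' in *all* marker trees, then reports per-marker monophyletic counts on
#' that common set — the fair comparison across marker sets of unequal
#' species coverage.
#'
#' @param reports named list of `monophyly_report` objects (>= 2).
#' @return list with `shared_species`, `table` (data.frame per species x
#'   marker of statuses) and `counts` (named integer vector of monophyletic
#'   counts per marker on the shared set).
#' @export
compare_markers <- function(reports) {
  stopifnot(length(reports) >= 2L)
  scored <- lapply(reports, function(r)
    names(r$status)[r$status != "excluded_singleton"])
  shared <- Reduce(intersect, scored)
  if (length(shared) == 0L) warning("no species scored in every marker set")
  tab <- data.frame(species = shared, stringsAsFactors = FALSE)
  for (m in names(reports)) tab[[m]] <- unname(reports[[m]]$status[shared])
  counts <- vapply(reports, function(r)
    sum(r$status[shared] == "monophyletic"), integer(1L))
  list(shared_species = shared, table = tab, counts = counts)
}
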