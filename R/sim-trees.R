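#' Simulate a labelled phylogeny with planted monophyly violations
#'
#' Builds a coalescent species tree (via [ape::rcoal()]), expands each species
#' tip into a shallow within-species subtree, and then makes exactly
#' `n_monophyly_violations` species non-monophyletic. Each violation prunes
#' one tip of a distinct donor species and regrafts it as sister to another
#' species' entire clade; this breaks only the donor (the recipient clade's
#' subtending edge is preserved), so any violation count up to
#' `n_species - 1` can be planted, including odd counts.
#'
#' @param config a [sim_config()]; uses `n_species`, `tips_per_species` (a
#'   single count or a length-2 range sampled per species) and
#'   `n_monophyly_violations`.
#' @return a list with elements
#'   \describe{
#'     \item{tree}{an [ape::phylo] tree whose tip labels are sample ids;}
#'     \item{tip_map}{data.frame with columns `tip`, `species`;}
#'     \item{violations}{character vector of the planted non-monophyletic
#'       species (sorted).}
#'   }
#' @examples
#' sim <- simulate_labeled_trees(sim_config(seed = 3, n_species = 8,
#'                                          n_monophyly_violations = 2))
#' sim$violations
#' @export
simulate_labeled_trees <- function(config) {
  validate_sim_config(config)
  if (config$n_species < 2L) stop("need at least 2 species")
  set.seed(child_seed(config$seed, "labeled_trees"))

  sp_ids <- sprintf("sp%03d", seq_len(config$n_species))
  sp_tree <- ape::rcoal(config$n_species, tip.label = sp_ids)
  # normalise depth so within-species subtrees are shallow in comparison
  sp_tree$edge.length <- sp_tree$edge.length /
    max(ape::node.depth.edgelength(sp_tree))

  tpr <- config$tips_per_species
  n_tips_sp <- if (length(tpr) == 1L) rep(tpr, config$n_species) else
    sample(seq(tpr[1], tpr[2]), config$n_species, replace = TRUE)

  tree <- sp_tree
  tip_map <- data.frame(tip = character(0), species = character(0),
                        stringsAsFactors = FALSE)
  for (i in seq_len(config$n_species)) {
    k <- n_tips_sp[i]
    labs <- sprintf("%s_t%d", sp_ids[i], seq_len(k))
    tip_map <- rbind(tip_map, data.frame(tip = labs, species = sp_ids[i],
                                         stringsAsFactors = FALSE))
    if (k == 1L) {
      tree$tip.label[tree$tip.label == sp_ids[i]] <- labs
    } else {
      # grow a shallow cherry-chain below the species tip
      tree$tip.label[tree$tip.label == sp_ids[i]] <- labs[1]
      for (j in 2:k) {
        at <- which(tree$tip.label == labs[j - 1])
        elen <- tree$edge.length[tree$edge[, 2] == at]
        tree <- phytools::bind.tip(tree, labs[j], edge.length = 0.02,
                                   where = at,
                                   position = min(0.01, elen / 2))
      }
    }
  }

  violations <- character(0)
  if (config$n_monophyly_violations > 0L) {
    eligible <- sp_ids[n_tips_sp >= 2L]
    if (length(eligible) < config$n_monophyly_violations)
      stop("not enough species with >= 2 tips to plant violations")
    donors <- sample(eligible, config$n_monophyly_violations)
    for (don in donors) {
      don_tips <- tip_map$tip[tip_map$species == don]
      moved <- sample(don_tips, 1L)
      recipients <- setdiff(sp_ids, donors)
      if (length(recipients) == 0L) recipients <- setdiff(sp_ids, don)
      rec <- sample(recipients, 1L)
      rec_tips <- intersect(tip_map$tip[tip_map$species == rec],
                            tree$tip.label)
      tree <- ape::drop.tip(tree, moved)
      node <- if (length(rec_tips) == 1L) {
        which(tree$tip.label == rec_tips)
      } else {
        ape::getMRCA(tree, rec_tips)
      }
      edge_len <- tree$edge.length[tree$edge[, 2] == node]
      tree <- phytools::bind.tip(tree, moved, edge.length = 0.02,
                                 where = node, position = edge_len / 2)
    }
    violations <- sort(donors)
  }

  list(tree = tree, tip_map = tip_map, violations = violations)
}

#' Write a labelled tree and its tip-to-species map
#'
#' Emits Newick (via [ape::write.tree()]) plus a two-column TSV map.
#'
#' @param sim result of [simulate_labeled_trees()].
#' @param tree_path,map_path output file paths.
#' @return `tree_path`, invisibly.
#' @export
write_labeled_tree <- function(sim, tree_path, map_path) {
  ape::write.tree(sim$tree, file = tree_path)
  write.table(sim$tip_map, map_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(tree_path)
}

#' Read a labelled tree and its tip-to-species map
#'
#' @param tree_path Newick file.
#' @param map_path TSV with columns `tip`, `species`.
#' @return list with `tree` (phylo) and `tip_map` (data.frame).
#' @export
read_labeled_tree <- function(tree_path, map_path) {
  list(tree = ape::read.tree(tree_path),
       tip_map = read.table(map_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE))
}
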