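# Shared fixtures and independent oracles used across test files.

# Independent monophyly oracle: root the tree at a tip outside the species
# and ask ape whether the species' tips form a clade. Unrooted monophyly
# holds iff the rooted check passes for an outside outgroup.
oracle_monophyletic <- function(tree, tips) {
  out <- setdiff(tree$tip.label, tips)[1]
  rooted <- ape::root(tree, outgroup = out, resolve.root = TRUE)
  ape::is.monophyletic(rooted, tips)
}

# Exact two-sided rank-sum p by full enumeration of all group assignments,
# using the same two-sided rule as stats::wilcox.test (doubled one-sided
# tail, capped at 1). Independent of wilcox.test's pwilcox machinery.
enumerate_wilcox_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  vals <- c(x, y)
  r <- rank(vals)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n1 + n2, n1)
  u_all <- apply(combos, 2, function(idx) {
    sum(r[idx]) - n1 * (n1 + 1) / 2
  })
  mu <- n1 * n2 / 2
  one_sided <- if (u_obs > mu) mean(u_all >= u_obs) else mean(u_all <= u_obs)
  min(2 * one_sided, 1)
}

# A small labelled tree with two clean species and one broken one.
toy_labeled_tree <- function() {
  tree <- ape::read.tree(
    text = "(((a1:1,a2:1):1,(c1:1,(b1:1,c2:1):0.5):1):1,(b2:1,b3:1):1);")
  map <- data.frame(tip = c("a1", "a2", "b1", "b2", "b3", "c1", "c2"),
                    species = c("A", "A", "B", "B", "B", "C", "C"),
                    stringsAsFactors = FALSE)
  list(tree = tree, tip_map = map)
}

# Build a candidate locus list entry.
make_locus <- function(id, seqs, type = "UCE",
                       clades = rep(c("caelifera", "ensifera"),
                                    length.out = length(seqs))) {
  if (is.null(names(seqs))) names(seqs) <- paste0("g", seq_along(seqs))
  names(clades) <- names(seqs)
  list(id = id, type = type, seqs = seqs, clades = clades)
}
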