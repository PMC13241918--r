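test_that("is_monophyletic scores clean and broken species correctly", {
  tr <- ape::read.tree(text = "((a1,a2),(b1,b2));")
  map <- data.frame(tip = c("a1", "a2", "b1", "b2"),
                    species = c("A", "A", "B", "B"))
  expect_identical(is_monophyletic(tr, map, "A"), "monophyletic")
  tr2 <- ape::read.tree(text = "((a1,b1),(a2,b2));")
  expect_identical(is_monophyletic(tr2, map, "A"), "non-monophyletic")
  # singleton species are excluded
  map1 <- data.frame(tip = c("a1", "a2", "b1", "b2"),
                     species = c("A", "A", "B", "C"))
  expect_identical(is_monophyletic(tr, map1, "B"), "excluded_singleton")
  expect_error(is_monophyletic(tr, map, "Z"), "absent")
  # a species spanning one full side of the root is monophyletic
  fx <- toy_labeled_tree()
  expect_identical(is_monophyletic(fx$tree, fx$tip_map, "A"), "monophyletic")
  expect_identical(is_monophyletic(fx$tree, fx$tip_map, "B"),
                   "non-monophyletic")
  expect_identical(is_monophyletic(fx$tree, fx$tip_map, "C"),
                   "non-monophyletic")
})

test_that("monophyly status matches the rooted-outgroup oracle on random trees", {
  set.seed(61)
  for (rep in 1:120) {
    n <- sample(5:12, 1)
    tr <- ape::rtree(n)
    n_sp <- sample(2:4, 1)
    map <- data.frame(tip = tr$tip.label,
                      species = sample(paste0("S", seq_len(n_sp)), n,
                                       replace = TRUE),
                      stringsAsFactors = FALSE)
    for (sp in unique(map$species)) {
      tips <- map$tip[map$species == sp]
      status <- is_monophyletic(tr, map, sp)
      if (length(tips) == 1L) {
        expect_identical(status, "excluded_singleton")
      } else if (length(tips) == n) {
        expect_identical(status, "monophyletic")
      } else {
        expect_identical(status == "monophyletic",
                         oracle_monophyletic(tr, tips))
      }
    }
  }
})

test_that("monophyly status is invariant under rerooting", {
  set.seed(67)
  tr <- ape::rtree(10)
  map <- data.frame(tip = tr$tip.label,
                    species = rep(c("A", "B"), each = 5),
                    stringsAsFactors = FALSE)
  base <- vapply(c("A", "B"), function(sp)
    is_monophyletic(tr, map, sp), "")
  for (tip in tr$tip.label[1:5]) {
    rerooted <- ape::root(tr, outgroup = tip, resolve.root = TRUE)
    for (sp in c("A", "B")) {
      expect_identical(is_monophyletic(rerooted, map, sp), base[[sp]])
    }
  }
  unrooted <- ape::unroot(tr)
  for (sp in c("A", "B")) {
    expect_identical(is_monophyletic(unrooted, map, sp), base[[sp]])
  }
})

test_that("count_monophyletic recovers planted violations exactly", {
  cfg <- sim_config(seed = 71, n_species = 20, tips_per_species = c(2L, 4L),
                    n_monophyly_violations = 3L)
  sim <- simulate_labeled_trees(cfg)
  rep <- count_monophyletic(sim$tree, sim$tip_map)
  found <- sort(names(rep$status)[rep$status == "non-monophyletic"])
  expect_identical(found, sim$violations)
  expect_identical(rep$n_monophyletic, 17L)
  # counts are conserved
  expect_identical(rep$n_monophyletic + rep$n_non_monophyletic,
                   rep$n_scored)
  expect_identical(rep$n_scored + rep$n_singleton, length(rep$status))
  # zero planted violations: every multi-tip species monophyletic
  clean <- simulate_labeled_trees(sim_config(seed = 73, n_species = 12))
  crep <- count_monophyletic(clean$tree, clean$tip_map)
  expect_identical(crep$n_non_monophyletic, 0L)
})

test_that("compare_markers restricts to species scored in every marker", {
  cfg <- sim_config(seed = 79, n_species = 15, tips_per_species = 3L,
                    n_monophyly_violations = 2L)
  simA <- simulate_labeled_trees(cfg)
  repA <- count_monophyletic(simA$tree, simA$tip_map, marker = "nuclear")
  # marker B: same tree with one extra violated species dropped to observe
  # count arithmetic; identical trees first
  repA2 <- count_monophyletic(simA$tree, simA$tip_map, marker = "coi")
  cmp_same <- compare_markers(list(nuclear = repA, coi = repA2))
  expect_identical(unname(cmp_same$counts["nuclear"]),
                   unname(cmp_same$counts["coi"]))
  # marker with an extra planted violation scores one fewer on the common set
  cfgB <- sim_config(seed = 79, n_species = 15, tips_per_species = 3L,
                     n_monophyly_violations = 3L)
  simB <- simulate_labeled_trees(cfgB)
  repB <- count_monophyletic(simB$tree, simB$tip_map, marker = "mito")
  cmp <- compare_markers(list(nuclear = repA, mito = repB))
  expect_identical(length(cmp$shared_species), 15L)
  expect_identical(unname(cmp$counts["nuclear"] - cmp$counts["mito"]),
                   length(setdiff(simB$violations, simA$violations)) -
                     length(setdiff(simA$violations, simB$violations)))
  # a species absent from one marker is absent from the whole table
  mapless <- simA$tip_map[simA$tip_map$species != "sp001", ]
  treeless <- ape::drop.tip(simA$tree,
                            simA$tip_map$tip[simA$tip_map$species == "sp001"])
  repC <- count_monophyletic(treeless, mapless, marker = "rdna")
  cmp2 <- compare_markers(list(nuclear = repA, rdna = repC))
  expect_false("sp001" %in% cmp2$shared_species)
  expect_false("sp001" %in% cmp2$table$species)
})

test_that("labelled trees survive a Newick/TSV round trip", {
  sim <- simulate_labeled_trees(sim_config(seed = 83, n_species = 6,
                                           n_monophyly_violations = 1L))
  td <- withr::local_tempdir()
  tp <- file.path(td, "t.nwk"); mp <- file.path(td, "t.tsv")
  write_labeled_tree(sim, tp, mp)
  back <- read_labeled_tree(tp, mp)
  expect_identical(sort(back$tree$tip.label), sort(sim$tree$tip.label))
  expect_identical(back$tip_map, sim$tip_map)
  r1 <- count_monophyletic(sim$tree, sim$tip_map)
  r2 <- count_monophyletic(back$tree, back$tip_map)
  expect_identical(r1$status[order(names(r1$status))],
                   r2$status[order(names(r2$status))])
})
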