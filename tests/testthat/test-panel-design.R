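test_that("tile_probes tiles without overlap and drops the remainder", {
  s340 <- strrep("ACGT", 85)        # 340 bp
  p <- tile_probes(s340, 170)
  expect_identical(p$offset, c(0L, 170L))
  expect_identical(nrow(tile_probes(strrep("A", 169), 170)), 0L)
  p511 <- tile_probes(paste0(strrep("ACGT", 127), "ACG"), 170)  # 511 bp
  expect_identical(nrow(p511), 3L)
  # conservation: probes disjoint, total length <= sequence length
  expect_true(all(diff(p511$offset) >= 170))
  expect_lte(sum(p511$length), 511)
  # probes reassemble the prefix of the source
  expect_identical(paste(p$sequence, collapse = ""), s340)
  expect_identical(nrow(tile_probes("", 170)), 0L)
})

test_that("usco_end_probes extracts both ends as independent probes", {
  s400 <- strrep("ACGT", 100)
  p <- usco_end_probes(s400, 120)
  expect_identical(p$offset, c(0L, 280L))
  expect_identical(p$role, c("end5", "end3"))
  expect_identical(p$sequence[1], substr(s400, 1, 120))
  expect_identical(p$sequence[2], substr(s400, 281, 400))
  # abutting boundary case at exactly 2x the probe length
  p240 <- usco_end_probes(strrep("AC", 120), 120)
  expect_identical(p240$offset, c(0L, 120L))
  # short sequences degrade to a single probe with a warning
  expect_warning(p1 <- usco_end_probes(strrep("A", 200), 120),
                 "single probe")
  expect_identical(nrow(p1), 1L)
})

test_that("variable_site_fraction counts gap-aware variable columns", {
  expect_equal(variable_site_fraction(c("ACGTACGTAC", "ACGTACGTAC")), 0)
  # 10 columns, 6 with two states
  a <- "AAAAAAAAAA"
  b <- "TTTTTTAAAA"
  expect_equal(variable_site_fraction(c(a, b)), 0.6)
  # gapped columns with < 2 residues are not comparable
  expect_equal(variable_site_fraction(c("AC-TA", "ACG-A", "ACGTA")), 0)
  expect_true(is.na(suppressWarnings(
    variable_site_fraction(c("----", "NNNN")))))
  # two iid uniform sequences differ at ~3/4 of columns
  set.seed(42)
  x <- paste(sample(c("A", "C", "G", "T"), 1000, TRUE), collapse = "")
  y <- paste(sample(c("A", "C", "G", "T"), 1000, TRUE), collapse = "")
  se <- sqrt(0.75 * 0.25 / 1000)
  expect_lt(abs(variable_site_fraction(c(x, y)) - 0.75), 3 * se)
})

test_that("within_clade_divergence equals the brute-force pair maximum", {
  seqs <- c(g1 = "ACGTACGTAC", g2 = "ACGTACGTTT", g3 = "ACGAACGTAC",
            g4 = "TTTTACGTAC")
  clades <- c("cae", "cae", "cae", "ens")
  wcd <- within_clade_divergence(seqs, clades)
  expect_named(wcd, "cae")  # singleton clade omitted
  pairs <- combn(3, 2)
  brute <- max(apply(pairs, 2, function(ij)
    p_distance(seqs[[ij[1]]], seqs[[ij[2]]]) / 100))
  expect_equal(unname(wcd["cae"]), brute)
  # identical members give zero
  expect_equal(unname(within_clade_divergence(
    c(a = "ACGT", b = "ACGT"), c("cae", "cae"))["cae"]), 0)
  # 5 mismatches over 100 comparable columns -> 0.05
  x <- strrep("A", 100)
  y <- paste0(strrep("C", 5), strrep("A", 95))
  expect_equal(unname(within_clade_divergence(
    c(x, y), c("cae", "cae"))["cae"]), 0.05)
})

test_that("filter_candidates applies the cascade with first-failure reasons", {
  cfg <- panel_config()
  ok_seqs <- setNames(rep(strrep("ACGT", 40), 6), paste0("g", 1:6))
  loci <- list(
    make_locus("u1", ok_seqs),
    make_locus("u2", ok_seqs[1:5]),                       # 5 genomes
    make_locus("u3", setNames(rep(strrep("AC", 59), 6),   # 118 bp
                              paste0("g", 1:6))),
    make_locus("u4", setNames(c(strrep("A", 200), strrep("C", 200),
                                rep(strrep("A", 200), 4)),
                              paste0("g", 1:6)),
               clades = rep(c("cae", "ens"), 3)))
  res <- filter_candidates(loci, cfg)
  expect_identical(vapply(res$kept, `[[`, "", "id"), "u1")
  expect_identical(res$rejected$reason[res$rejected$id == "u2"],
                   "min_genomes")
  expect_identical(res$rejected$reason[res$rejected$id == "u3"],
                   "min_locus_len")
  # u4: g1 vs g3 fully divergent within clade "cae" -> divergence clause,
  # but 100% variable sites fails first in the cascade
  expect_identical(res$rejected$reason[res$rejected$id == "u4"],
                   "max_variable_frac")
})

test_that("USCO candidates bypass the variability and divergence clauses", {
  divergent <- setNames(c(strrep("A", 200), strrep("C", 200),
                          rep(strrep("A", 200), 3)), paste0("g", 1:5))
  res <- filter_candidates(list(make_locus("s1", divergent, type = "USCO")),
                           panel_config(min_genomes = 5))
  expect_length(res$kept, 1L)
})

test_that("tightening any panel threshold never enlarges the kept set", {
  cfg <- sim_config(seed = 31, n_loci_uce = 20, n_loci_usco = 0,
                    within_clade_div = 0.09)
  panel <- simulate_genome_panel(cfg)
  loci <- lapply(names(panel$alignments), function(id) {
    make_locus(id, panel$alignments[[id]],
               clades = attr(panel$alignments[[id]], "clades"))
  })
  base_cfg <- panel_config(max_within_clade_div = 0.10)
  kept_ids <- function(cfg) vapply(filter_candidates(loci, cfg)$kept,
                                   `[[`, "", "id")
  base <- kept_ids(base_cfg)
  for (tighter in list(panel_config(max_within_clade_div = 0.05),
                       panel_config(max_variable_frac = 0.2),
                       panel_config(min_locus_len = 600),
                       panel_config(min_genomes = 7))) {
    expect_true(all(kept_ids(tighter) %in% base))
  }
})

test_that("filter_candidates agrees with an independent brute-force re-check", {
  cfg <- sim_config(seed = 33, n_loci_uce = 15, n_loci_usco = 0,
                    within_clade_div = 0.08)
  panel <- simulate_genome_panel(cfg)
  loci <- lapply(names(panel$alignments), function(id) {
    make_locus(id, panel$alignments[[id]],
               clades = attr(panel$alignments[[id]], "clades"))
  })
  pcfg <- panel_config(min_genomes = 6, min_locus_len = 120,
                       max_variable_frac = 0.5, max_within_clade_div = 0.10)
  res <- filter_candidates(loci, pcfg)
  kept_ids <- vapply(res$kept, `[[`, "", "id")
  for (lc in loci) {
    seqs <- lc$seqs
    keep <- length(seqs) >= 6 && nchar(seqs[[1]]) >= 120 &&
      variable_site_fraction(seqs) <= 0.5 &&
      all(within_clade_divergence(seqs, lc$clades) <= 0.10)
    expect_identical(lc$id %in% kept_ids, keep)
  }
})

test_that("the panel manifest counts loci by type and forbids duplicates", {
  uce <- lapply(1:3, function(i) make_locus(paste0("u", i),
                                            c(a = "ACGT", b = "ACGT")))
  usco <- do.call(rbind, lapply(1:2, function(i)
    usco_end_probes(strrep("ACGT", 100), locus_id = paste0("s", i))))
  man <- build_panel_manifest(uce, usco)
  expect_identical(unname(man$counts["total"]), 7L)
  expect_identical(unname(man$counts["UCE"]), 3L)
  expect_identical(unname(man$counts["USCO"]), 4L)
  expect_identical(sum(man$counts[c("UCE", "USCO")]),
                   unname(man$counts["total"]))
  empty <- build_panel_manifest()
  expect_identical(unname(empty$counts["total"]), 0L)
  expect_error(build_panel_manifest(c(uce, uce)), "duplicate")
})
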