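test_that("drop_gappy_sequences removes rows above 40% missing, keeps 40%", {
  mk <- function(n_missing) paste0(strrep("-", n_missing),
                                   strrep("A", 100 - n_missing))
  mat <- c(s41 = mk(41), s40 = mk(40), s0 = mk(0))
  out <- drop_gappy_sequences(mat, qc_config())
  expect_identical(names(out), c("s40", "s0"))
  expect_identical(attr(out, "removed"), "s41")
  # all-clean matrix is untouched
  clean <- c(a = strrep("A", 10), b = strrep("C", 10))
  expect_identical(unclass(drop_gappy_sequences(clean))[1:2], clean)
  # gaps, N and ? all count as missing
  expect_identical(unname(missing_fraction(c(x = "A-N?AAAAAA"))), 0.3)
})

test_that("occupancy_filter keeps loci at exactly one-third occupancy", {
  samples <- paste0("s", 1:9)
  mk_locus <- function(present) setNames(rep(strrep("A", 10),
                                             length(present)), present)
  mats <- list(l3 = mk_locus(samples[1:3]),   # exactly 1/3
               l2 = mk_locus(samples[1:2]),   # below
               l9 = mk_locus(samples))
  out <- occupancy_filter(mats, samples, qc_config())
  expect_identical(sort(out$kept_loci), c("l3", "l9"))
  # sample missing exactly 20% of kept loci is removed (keep rule is < 20%)
  mats5 <- c(lapply(1:4, function(i) mk_locus(samples)),
             list(mk_locus(samples[-1])))
  names(mats5) <- paste0("k", 1:5)
  out5 <- occupancy_filter(mats5, samples, qc_config())
  expect_false("s1" %in% out5$kept_samples)  # 1/5 = 20% missing
  # fully occupied set is the identity
  full <- list(a = mk_locus(samples), b = mk_locus(samples))
  outf <- occupancy_filter(full, samples, qc_config())
  expect_identical(outf$kept_loci, c("a", "b"))
  expect_identical(outf$kept_samples, samples)
  # empty survivor set warns
  expect_warning(occupancy_filter(list(l1 = mk_locus(samples[1:2])),
                                  samples, qc_config()), "occupancy")
})

test_that("the consensus-distance paralog screen removes a planted outlier", {
  set.seed(19)
  base <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  jitter_seq <- function(s, k) {
    b <- strsplit(s, "")[[1]]
    idx <- sample(length(b), k)
    b[idx] <- vapply(b[idx], function(x)
      sample(setdiff(c("A", "C", "G", "T"), x), 1), "")
    paste(b, collapse = "")
  }
  rows <- vapply(1:9, function(i) jitter_seq(base, 6), "")
  names(rows) <- paste0("s", 1:9)
  rows["s9"] <- jitter_seq(base, 105)  # planted paralog at +35%
  grouping <- setNames(rep("acrididae", 9), names(rows))
  out <- paralog_filter_round(rows, grouping, threshold = 5)
  expect_identical(attr(out, "removed")$sample, "s9")
  expect_identical(attr(out, "method"), "consensus-distance stand-in")
  # identical rows: nothing removed
  same <- setNames(rep(base, 5), paste0("t", 1:5))
  expect_length(paralog_filter_round(same, setNames(rep("g", 5),
                                                    names(same))), 5L)
  # groups under 3 rows are skipped
  two <- same[1:2]
  expect_length(paralog_filter_round(two, setNames(rep("g", 2),
                                                   names(two))), 2L)
})

test_that("repeating the paralog rounds is a fixed point after no removals", {
  set.seed(23)
  base <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
  rows <- setNames(rep(base, 6), paste0("s", 1:6))
  taxonomy <- data.frame(sample = names(rows), order = "orthoptera",
                         family = rep(c("f1", "f2"), 3),
                         genus = paste0("g", 1:6),
                         stringsAsFactors = FALSE)
  once <- paralog_filter_rounds(rows, taxonomy)
  twice <- paralog_filter_rounds(unclass(once)[names(once)], taxonomy)
  expect_identical(names(once), names(twice))
  expect_identical(nrow(attr(twice, "removed")), 0L)
})

test_that("paralog screen recovers planted paralogs on synthetic loci", {
  # one locus, 12 samples of one genus; 2 planted paralog rows
  set.seed(29)
  base <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  mut <- function(s, rate) {
    b <- strsplit(s, "")[[1]]
    hit <- runif(length(b)) < rate
    b[hit] <- vapply(b[hit], function(x)
      sample(setdiff(c("A", "C", "G", "T"), x), 1), "")
    paste(b, collapse = "")
  }
  n_rep <- 20
  recovered <- 0; false_removed <- 0
  for (r in seq_len(n_rep)) {
    rows <- vapply(1:12, function(i) mut(base, 0.02), "")
    names(rows) <- paste0("s", 1:12)
    paralogs <- c("s11", "s12")
    for (p in paralogs) rows[p] <- mut(rows[p], 0.35)
    taxonomy <- data.frame(sample = names(rows), order = "o", family = "f",
                           genus = "g", stringsAsFactors = FALSE)
    out <- paralog_filter_rounds(rows, taxonomy)
    rem <- attr(out, "removed")$sample
    recovered <- recovered + sum(paralogs %in% rem)
    false_removed <- false_removed + sum(!rem %in% paralogs)
  }
  expect_gte(recovered / (2 * n_rep), 0.90)
  expect_lte(false_removed / (10 * n_rep), 0.05)
})

test_that("concat_supermatrix records 1-based inclusive partitions and pads", {
  mats <- list(locus1 = c(s1 = strrep("A", 100), s2 = strrep("C", 100)),
               locus2 = c(s1 = strrep("G", 50)))
  out <- concat_supermatrix(mats)
  expect_identical(out$partitions$start, c(1L, 101L))
  expect_identical(out$partitions$end, c(100L, 150L))
  expect_identical(nchar(out$supermatrix[["s1"]]), 150L)
  expect_identical(substr(out$supermatrix[["s2"]], 101, 150),
                   strrep("-", 50))
  expect_identical(sum(out$partitions$end - out$partitions$start + 1L),
                   sum(vapply(mats, function(m) nchar(m[[1]]), 0L)))
  pf <- tempfile()
  write_partitions(out$partitions, pf)
  expect_identical(readLines(pf)[1], "DNA, locus1 = 1-100")
})
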