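#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif rbinom rnbinom median mad lm glm wilcox.test
#'   prcomp kmeans dist cor coef complete.cases setNames sd as.formula gaussian
#' @importFrom utils write.table read.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

DNA_BASES <- c("A", "C", "G", "T")
MISSING_CHARS <- c("-", "N", "n", "?")

#' Derive a deterministic child seed from a master seed
#'
#' One master seed drives the whole synthetic cohort; each stage (genomes,
#' trees, calls, SNPs, traits) draws from its own child stream so that adding
#' a stage never perturbs the others. The child seed is a deterministic hash
#' of the master seed and a stage label, kept below 2^31.
#'
#' @param seed master integer seed.
#' @param stage character stage label.
#' @return an integer seed.
#' @export
child_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 7919 + h * 104729) %% 2147483647L)
}

## mutate each site independently with probability `rate`, always to a
## different base (single-parameter symmetric model)
mutate_sequence <- function(bases, rate) {
  if (rate <= 0) return(bases)
  hit <- runif(length(bases)) < rate
  if (any(hit)) {
    bases[hit] <- vapply(bases[hit], function(b) {
      sample(setdiff(DNA_BASES, b), 1L)
    }, character(1L))
  }
  bases
}

random_sequence <- function(len) {
  paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
}

seq_to_bases <- function(s) strsplit(s, "", fixed = TRUE)[[1L]]
bases_to_seq <- function(b) paste(b, collapse = "")

#' Expected p-distance between two copies mutated from a common ancestor
#'
#' Under the symmetric single-parameter model (each site substituted with
#' probability q, uniformly to one of the three other bases) two copies drawn
#' independently at rates q1 and q2 from the same ancestor match at a site
#' with probability (1-q1)(1-q2) + q1*q2/3.
#'
#' @param q1,q2 per-copy substitution probabilities.
#' @return expected pairwise p-distance (fraction of differing sites).
#' @export
expected_p_distance <- function(q1, q2 = q1) {
  1 - ((1 - q1) * (1 - q2) + q1 * q2 / 3)
}
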