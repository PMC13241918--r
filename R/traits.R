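#' Greedy pruning of correlated trait variables
#'
#' While any pair of numeric columns has |Pearson r| above the threshold,
#' drops the member of the worst (highest |r|) pair with the higher mean
#' absolute correlation against all remaining variables; ties break by
#' column order (the later column is dropped). Constant columns are dropped
#' up front with a warning.
#'
#' @param table data.frame of numeric variables (ordered factors are coerced
#'   to their integer codes).
#' @param threshold absolute-correlation cutoff (default 0.7).
#' @return character vector of retained column names.
#' @export
prune_correlated <- function(table, threshold = 0.7) {
  num <- as.data.frame(lapply(table, function(col) {
    if (is.ordered(col) || is.factor(col)) as.numeric(col) else col
  }))
  num <- num[vapply(num, is.numeric, logical(1L))]
  stopifnot(ncol(num) >= 2L)
  const <- vapply(num, function(col) sd(col, na.rm = TRUE) == 0, logical(1L))
  if (any(const)) {
    warning("dropping constant column(s): ",
            paste(names(num)[const], collapse = ", "))
    num <- num[!const]
  }
  vars <- names(num)
  repeat {
    if (length(vars) < 2L) break
    r <- abs(cor(num[vars], use = "pairwise.complete.obs"))
    diag(r) <- 0
    if (max(r) <= threshold) break
    worst <- which(r == max(r), arr.ind = TRUE)[1L, ]
    mean_abs <- rowMeans(r)
    cand <- vars[worst]
    drop <- if (mean_abs[worst[1]] > mean_abs[worst[2]]) cand[1]
      else if (mean_abs[worst[2]] > mean_abs[worst[1]]) cand[2]
      else cand[which.max(match(cand, vars))]  # tie: later column goes
    vars <- setdiff(vars, drop)
  }
  vars
}

#' Gaussian GLM of species diversity on ecological traits
#'
#' Fits `response ~ traits` with a Gaussian family and identity link, where
#' the response is by default the natural log of the polymorphic-site
#' *proportion* (`mean_pct_polymorphic / 100`). Ordinal predictors enter as
#' numeric scores; IUCN categories are coded LC=1 < NT=2 < VU=3 < EN=4 <
#' CR=5. Species flagged `museum_specimen` are excluded. Per-term Wald t
#' statistics and p-values are returned.
#'
#' @param table trait table (see [simulate_trait_table()] for the column
#'   dictionary); must contain `mean_pct_polymorphic`.
#' @param predictors character vector of predictor columns (defaults to all
#'   trait score columns present).
#' @param response_transform "log" (log proportion, default) or "identity"
#'   (raw percent).
#' @return a `glm_result` list with `coefficients` (data.frame `term`,
#'   `estimate`, `std_error`, `t_value`, `p_value`), `fit` (the glm object),
#'   `response_transform`, `n`.
#' @export
fit_diversity_glm <- function(table,
                              predictors = NULL,
                              response_transform = c("log", "identity")) {
  response_transform <- match.arg(response_transform)
  if ("museum_specimen" %in% names(table)) {
    table <- table[!table$museum_specimen, , drop = FALSE]
  }
  default_preds <- c("iucn_category", "habitat_specialisation",
                     "riparian_indicator", "dry_meadow_indicator",
                     "dispersal_potential", "thermophilic_preference",
                     "elevation_level")
  if (is.null(predictors)) {
    predictors <- intersect(default_preds, names(table))
  }
  dat <- table
  for (p in predictors) {
    if (is.ordered(dat[[p]]) || is.factor(dat[[p]]))
      dat[[p]] <- as.numeric(dat[[p]])
  }
  stopifnot(nrow(dat) >= length(predictors) + 2L)
  dat$.response <- if (response_transform == "log") {
    log(dat$mean_pct_polymorphic / 100)
  } else {
    dat$mean_pct_polymorphic
  }
  fml <- as.formula(paste(".response ~", paste(predictors, collapse = " + ")))
  fit <- glm(fml, data = dat, family = gaussian())
  if (any(is.na(coef(fit)))) {
    stop("singular design; aliased terms: ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "))
  }
  cf <- summary(fit)$coefficients
  out <- list(coefficients = data.frame(term = rownames(cf),
                                        estimate = cf[, 1],
                                        std_error = cf[, 2],
                                        t_value = cf[, 3],
                                        p_value = cf[, 4],
                                        row.names = NULL,
                                        stringsAsFactors = FALSE),
              fit = fit, response_transform = response_transform,
              n = nrow(dat))
  class(out) <- "glm_result"
  out
}

#' @export
print.glm_result <- function(x, ...) {
  cat("Gaussian GLM of", if (x$response_transform == "log")
    "log(polymorphic-site proportion)" else "% polymorphic sites",
    "on", x$n, "species\n")
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Wilcoxon test of diversity between threatened and non-threatened species
#'
#' Two-sided rank-sum test of `mean_pct_polymorphic` between threatened
#' (VU + EN + CR) and non-threatened (LC + NT) species. Exact p by full
#' enumeration when the smaller group has at most 10 observations and there
#' are no ties; the normal approximation (with continuity correction)
#' otherwise — [stats::wilcox.test()] semantics. Museum specimens are
#' excluded.
#'
#' @param table trait table with `iucn_category` and `mean_pct_polymorphic`.
#' @return list with `statistic` (rank-sum W of the threatened group),
#'   `p_value`, `n_threatened`, `n_non_threatened`, `exact` (logical).
#' @export
wilcoxon_threatened <- function(table) {
  if ("museum_specimen" %in% names(table)) {
    table <- table[!table$museum_specimen, , drop = FALSE]
  }
  threatened <- table$iucn_category %in% c("VU", "EN", "CR")
  x <- table$mean_pct_polymorphic[threatened]
  y <- table$mean_pct_polymorphic[!threatened]
  if (length(x) == 0L || length(y) == 0L) {
    stop("both threatened and non-threatened groups must be non-empty")
  }
  if (length(unique(c(x, y))) == 1L) {
    # fully tied data carry no ranking information
    return(list(statistic = length(x) * length(y) / 2, p_value = 1,
                n_threatened = length(x), n_non_threatened = length(y),
                exact = FALSE))
  }
  exact <- min(length(x), length(y)) <= 10L &&
    !anyDuplicated(c(x, y))
  wt <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided",
                                     exact = exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n_threatened = length(x), n_non_threatened = length(y),
       exact = exact)
}

#' PCA of species traits and diversity
#'
#' Centred, standardised principal component analysis of the numeric trait
#' columns (ordered factors coerced to scores); constant columns are
#' excluded with a warning. With standardised input the eigenvalues sum to
#' the number of variables.
#'
#' @param table trait table.
#' @param columns columns to include (defaults to all trait scores plus
#'   `mean_pct_polymorphic`).
#' @return list with `scores` (species x components), `loadings`
#'   (variables x components), `eigenvalues`, `prop_variance`.
#' @export
pca_traits <- function(table, columns = NULL) {
  if (is.null(columns)) {
    columns <- intersect(c("iucn_category", "habitat_specialisation",
                           "riparian_indicator", "dry_meadow_indicator",
                           "dispersal_potential", "thermophilic_preference",
                           "elevation_level", "mean_pct_polymorphic"),
                         names(table))
  }
  num <- as.data.frame(lapply(table[columns], function(col) {
    if (is.ordered(col) || is.factor(col)) as.numeric(col) else col
  }))
  stopifnot(ncol(num) >= 2L, nrow(num) >= 3L)
  const <- vapply(num, function(col) sd(col) == 0, logical(1L))
  if (any(const)) {
    warning("excluding constant column(s): ",
            paste(names(num)[const], collapse = ", "))
    num <- num[!const]
  }
  pc <- prcomp(num, center = TRUE, scale. = TRUE)
  ev <- pc$sdev^2
  list(scores = pc$x, loadings = pc$rotation, eigenvalues = ev,
       prop_variance = ev / sum(ev))
}
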