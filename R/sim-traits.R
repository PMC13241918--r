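#' Simulate a species trait table with a planted riparian effect
#'
#' Produces one row per species with ordinal ecological scores in the style
#' of the Fauna Indicativa trait database (small integer supports) plus an
#' IUCN threat category, and a per-species genetic-diversity value generated
#' as
#' \deqn{\log(\mathrm{diversity\ proportion}) = \alpha + \beta_{rip} \cdot
#'   \mathrm{riparian} + \varepsilon,\quad
#'   \varepsilon \sim N(0, \sigma^2)}
#' so that a Gaussian GLM on the log proportion recovers `beta_riparian`.
#' Other traits are drawn independently of diversity. The diversity column
#' `mean_pct_polymorphic` is reported in percent (100 x proportion).
#'
#' @param config a [sim_config()]; uses `n_species`, `beta_riparian`,
#'   `trait_noise_sd`, `trait_intercept`.
#' @param species_diversities optional named numeric vector of per-species
#'   diversity percentages; when supplied it overrides the planted model and
#'   the table simply joins the traits to these values.
#' @return data.frame with columns `species`, `iucn_category` (ordered factor
#'   LC < NT < VU < EN < CR), `habitat_specialisation`, `riparian_indicator`,
#'   `dry_meadow_indicator`, `dispersal_potential`, `thermophilic_preference`,
#'   `elevation_level`, `museum_specimen` (logical) and
#'   `mean_pct_polymorphic`. The planted coefficients are stored in attribute
#'   `truth`.
#' @examples
#' tt <- simulate_trait_table(sim_config(seed = 5, n_species = 30))
#' head(tt)
#' @export
simulate_trait_table <- function(config, species_diversities = NULL) {
  validate_sim_config(config)
  set.seed(child_seed(config$seed, "trait_table"))
  n <- config$n_species
  sp <- sprintf("sp%03d", seq_len(n))

  iucn_levels <- c("LC", "NT", "VU", "EN", "CR")
  tab <- data.frame(
    species = sp,
    iucn_category = factor(sample(iucn_levels, n, replace = TRUE,
                                  prob = c(0.45, 0.15, 0.2, 0.12, 0.08)),
                           levels = iucn_levels, ordered = TRUE),
    habitat_specialisation = sample(0:3, n, replace = TRUE),
    riparian_indicator = sample(0:3, n, replace = TRUE),
    dry_meadow_indicator = sample(0:3, n, replace = TRUE),
    dispersal_potential = sample(1:4, n, replace = TRUE),
    thermophilic_preference = sample(0:3, n, replace = TRUE),
    elevation_level = sample(1:5, n, replace = TRUE),
    museum_specimen = FALSE,
    stringsAsFactors = FALSE)

  if (is.null(species_diversities)) {
    logprop <- config$trait_intercept +
      config$beta_riparian * tab$riparian_indicator +
      rnorm(n, 0, config$trait_noise_sd)
    tab$mean_pct_polymorphic <- 100 * exp(logprop)
  } else {
    tab$mean_pct_polymorphic <- unname(species_diversities[sp])
  }
  attr(tab, "truth") <- list(intercept = config$trait_intercept,
                             beta_riparian = config$beta_riparian,
                             noise_sd = config$trait_noise_sd)
  tab
}
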