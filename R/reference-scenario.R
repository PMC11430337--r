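#' Synthetic reference economic inputs
#'
#' A complete, realistic set of valuation inputs for the worked examples
#' and the test surface, in the structure the model consumes: Swedish-style
#' annual direct post-stroke costs (2016 SEK) by disability level and year
#' since stroke, EQ-5D-style utilities by mRS score, CPI adjustment to
#' 2022 and SEK-to-EUR conversion, 3% annual discounting. The values are
#' synthetic stand-ins chosen to be of realistic magnitude; they are this
#' package's own reference scenario, not any published cost study's
#' figures.
#'
#' @return An [econ_params()].
#' @export
synthetic_econ_params <- function() {
  econ_params(
    cost_year1 = c(mrs02 = 100000, mrs3 = 280000, mrs4 = 450000, mrs5 = 600000),
    cost_year2 = c(mrs02 = 60000, mrs3 = 180000, mrs4 = 320000, mrs5 = 450000),
    utility = c(mrs0 = 0.95, mrs1 = 0.91, mrs2 = 0.78, mrs3 = 0.55,
                mrs4 = 0.31, mrs5 = 0.05),
    discount_rate_annual = 0.03,
    cpi_factor = 1.15,      # 2016 -> 2022 consumer prices
    fx_sek_to_eur = 0.095,  # 2022 average-style SEK/EUR
    fx_eur_to_usd = 1.08
  )
}

#' Synthetic reference pipeline configuration
#'
#' Bundles the synthetic two-arm trial ([synthetic_trial_spec()]) with the
#' synthetic economic inputs ([synthetic_econ_params()]) into a ready
#' [run_pipeline()] configuration. Subgroup attribute columns (`b_nihss`,
#' `ott_hours`, `rehab`) are attached per patient so the subgroup filters
#' are exercisable; they are independent of outcome by construction.
#'
#' @param seed Integer seed driving data generation and PSA.
#' @param psa_iter PSA iterations (0 disables).
#' @param n_per_arm Passed to [synthetic_trial_spec()].
#' @return A config list for [run_pipeline()].
#' @export
synthetic_reference_config <- function(seed = 2024L, psa_iter = 0,
                                       n_per_arm = c(intervention = 287L,
                                                     comparator = 261L)) {
  spec <- synthetic_trial_spec(seed = seed, n_per_arm = n_per_arm)
  panel <- generate_cohort(spec)
  # per-patient attributes for subgroup filters (independent of trajectory)
  set.seed(seed + 1L)
  ids <- unique(panel$patient_id)
  attrs <- tibble::tibble(
    patient_id = ids,
    b_nihss = sample(8:14, length(ids), replace = TRUE),
    ott_hours = stats::rnorm(length(ids), mean = 50, sd = 17),
    rehab = stats::runif(length(ids)) < 0.45
  )
  panel <- dplyr::left_join(panel, attrs, by = "patient_id")
  list(
    mode = "panel",
    panel = panel,
    econ = synthetic_econ_params(),
    subgroups = list(
      nihss_10_14 = list(b_nihss_min = 10, b_nihss_max = 14),
      onset_gt_48h = list(ott_gt_48 = TRUE),
      rehab_first_3m = list(rehab = TRUE)
    ),
    sensitivity = list(dsa = TRUE, psa_iter = psa_iter),
    seed = seed
  )
}
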