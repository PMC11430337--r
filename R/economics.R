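#' Economic valuation parameters
#'
#' Collects the inputs that turn a cohort trace into discounted costs and
#' QALYs: annual per-state direct costs in the source currency (SEK, 2016
#' price year) reported for the grouped state mRS 0--2 and for mRS 3, 4
#' and 5, separately for the first and second year after stroke; the
#' weights that split the grouped mRS 0--2 cost onto the model states
#' mRS 0--1 and mRS 2; per-score utilities for raw mRS 0..5; the annual
#' discount rate; the CPI and currency factors that bring costs to 2022
#' EUR; and an optional per-cycle treatment acquisition cost charged to
#' the intervention arm.
#'
#' @param cost_year1,cost_year2 Named numeric vectors with elements
#'   `mrs02`, `mrs3`, `mrs4`, `mrs5`: annual cost in source currency for
#'   the first/second year after stroke. Death carries zero cost.
#' @param utility Named numeric vector `mrs0`..`mrs5` of utilities in
#'   \[0, 1\]; death has utility 0.
#' @param discount_rate_annual Annual discount rate; default 0.03.
#' @param cost_split_weights Length-2 weights `(w01, w2)` allocating the
#'   grouped mRS 0--2 cost to mRS 0--1 and mRS 2; must sum to 1. Default
#'   `c(1/3, 2/3)`: the milder state is assumed to incur one third.
#' @param cpi_factor Source-year to 2022 consumer-price multiplier.
#' @param fx_sek_to_eur SEK to EUR conversion rate.
#' @param fx_eur_to_usd EUR to USD rate; default 1.08, used only when
#'   mirroring results in USD.
#' @param treatment_cost_per_cycle Cost (2022 EUR) added to the
#'   intervention arm during treatment cycles; default 0.
#' @param treatment_cycles Cycles carrying the treatment cost; default 1
#'   (the 3-month course).
#' @param qaly_convention `"per_cycle"` (default) or `"per_year"`; see
#'   [accumulate()].
#' @param death_cost Annual cost attached to the death state; default 0
#'   (costs accrued before death are already counted in the living
#'   states), configurable only for sensitivity exploration.
#' @return An `econ_params` object.
#' @export
econ_params <- function(cost_year1, cost_year2, utility,
                        discount_rate_annual = 0.03,
                        cost_split_weights = c(1 / 3, 2 / 3),
                        cpi_factor = 1, fx_sek_to_eur = 1,
                        fx_eur_to_usd = 1.08,
                        treatment_cost_per_cycle = 0,
                        treatment_cycles = 1L,
                        qaly_convention = c("per_cycle", "per_year"),
                        death_cost = 0) {
  qaly_convention <- match.arg(qaly_convention)
  cost_states <- c("mrs02", "mrs3", "mrs4", "mrs5")
  for (cv in list(cost_year1, cost_year2)) {
    if (!all(cost_states %in% names(cv))) {
      rlang::abort("Costs must be named mrs02, mrs3, mrs4, mrs5.",
                   class = "strokecea_config_error")
    }
    if (any(cv < 0)) {
      rlang::abort("Costs must be non-negative.", class = "strokecea_validation_error")
    }
  }
  if (!all(paste0("mrs", 0:5) %in% names(utility))) {
    rlang::abort("Utilities must be named mrs0..mrs5.", class = "strokecea_config_error")
  }
  if (any(utility < 0 | utility > 1)) {
    rlang::abort("Utilities must lie in [0, 1].", class = "strokecea_validation_error")
  }
  if (abs(sum(cost_split_weights) - 1) > 1e-12) {
    rlang::abort("cost_split_weights must sum to 1.", class = "strokecea_validation_error")
  }
  if (discount_rate_annual < 0 || cpi_factor <= 0 || fx_sek_to_eur <= 0 ||
      fx_eur_to_usd <= 0) {
    rlang::abort("Discount rate must be >= 0 and CPI/FX factors > 0.",
                 class = "strokecea_validation_error")
  }
  structure(
    list(cost_year1 = cost_year1[cost_states], cost_year2 = cost_year2[cost_states],
         utility = utility[paste0("mrs", 0:5)],
         discount_rate_annual = discount_rate_annual,
         cost_split_weights = cost_split_weights,
         cpi_factor = cpi_factor, fx_sek_to_eur = fx_sek_to_eur,
         fx_eur_to_usd = fx_eur_to_usd,
         treatment_cost_per_cycle = treatment_cost_per_cycle,
         treatment_cycles = as.integer(treatment_cycles),
         qaly_convention = qaly_convention,
         death_cost = death_cost),
    class = "econ_params"
  )
}

#' Adjust a source-currency amount to 2022 EUR and USD
#'
#' Applies the consumer-price index of the source country and the
#' SEK-to-EUR rate; USD is mirrored at the fixed EUR 1 = USD 1.08.
#'
#' @param amount Non-negative amount in source currency (2016 SEK).
#' @param params An [econ_params()].
#' @return Named numeric vector `c(eur = , usd = )`.
#' @export
adjust_cost <- function(amount, params) {
  if (any(amount < 0)) {
    rlang::abort("Cost amounts must be non-negative.",
                 class = "strokecea_validation_error")
  }
  eur <- amount * params$cpi_factor * params$fx_sek_to_eur
  c(eur = eur, usd = eur * params$fx_eur_to_usd)
}

#' Split the grouped mRS 0--2 cost onto the model states
#'
#' The cost source reports one figure for mRS 0--2; the model needs
#' separate costs for mRS 0--1 and mRS 2. By default one third of the
#' grouped cost is attributed to mRS 0--1 and two thirds to mRS 2.
#'
#' @param c02 Grouped annual cost for mRS 0--2 (non-negative).
#' @param weights Length-2 weights summing to 1.
#' @return Named vector `c(mrs01 = , mrs2 = )`.
#' @export
split_mrs02_cost <- function(c02, weights = c(1 / 3, 2 / 3)) {
  if (c02 < 0) {
    rlang::abort("c02 must be non-negative.", class = "strokecea_validation_error")
  }
  if (abs(sum(weights) - 1) > 1e-12) {
    rlang::abort("Split weights must sum to 1.", class = "strokecea_validation_error")
  }
  c(mrs01 = weights[1] * c02, mrs2 = weights[2] * c02)
}

#' Per-cycle state cost vector in 2022 EUR
#'
#' Annual state costs for the given year since stroke, CPI/FX adjusted to
#' 2022 EUR, split onto the six model states and prorated to the 3-month
#' cycle (annual cost / 4). The death entry is zero by assumption.
#'
#' @param year_index 1 (cycles 1--4) or 2 (cycles 5--8).
#' @param params An [econ_params()].
#' @return Length-6 numeric vector of per-cycle costs (EUR 2022), in model
#'   state order.
#' @export
state_cost_vector <- function(year_index, params) {
  stopifnot(year_index %in% c(1L, 2L))
  cv <- if (year_index == 1L) params$cost_year1 else params$cost_year2
  split <- split_mrs02_cost(cv[["mrs02"]], params$cost_split_weights)
  annual_sek <- c(split[["mrs01"]], split[["mrs2"]],
                  cv[["mrs3"]], cv[["mrs4"]], cv[["mrs5"]],
                  params$death_cost)
  annual_eur <- annual_sek * params$cpi_factor * params$fx_sek_to_eur
  stats::setNames(annual_eur / 4, model_states())
}

#' Utility vector over the merged state space
#'
#' The merged functional-recovery state gets the average of the mRS 0 and
#' mRS 1 utilities; death has utility zero.
#'
#' @param params An [econ_params()].
#' @return Length-6 numeric vector of utilities in model state order.
#' @export
merged_utility_vector <- function(params) {
  u <- params$utility
  stats::setNames(
    c((u[["mrs0"]] + u[["mrs1"]]) / 2, u[["mrs2"]], u[["mrs3"]], u[["mrs4"]],
      u[["mrs5"]], 0),
    model_states()
  )
}

#' Discount factor at the end of a model cycle
#'
#' `(1 + r)^(-t)` with `t = cycle_index * 0.25` years.
#'
#' @param cycle_index Cycle index (0 gives factor 1).
#' @param params An [econ_params()] (uses `discount_rate_annual`).
#' @return Numeric discount factor(s).
#' @export
discount_factor <- function(cycle_index, params) {
  (1 + params$discount_rate_annual)^(-(cycle_index * 0.25))
}

#' Value a cohort trace: total discounted cost and QALYs
#'
#' For each cycle c = 1..8 the cohort occupying a state at the cycle's
#' start earns that cycle's state cost and utility, discounted by the
#' factor at cycle c. Year-1 costs apply to cycles 1--4, year-2 costs to
#' cycles 5--8. Under the `per_cycle` QALY convention each cycle
#' contributes the full occupancy-weighted utility; under `per_year` the
#' same sum is scaled by the 0.25-year cycle length. A per-cycle treatment
#' cost is added (discounted) for the intervention arm's treatment cycles.
#'
#' @param trace A `cohort_trace` from [run_cohort()].
#' @param params An [econ_params()].
#' @param arm Arm label; defaults to the trace's.
#' @param is_intervention Whether this arm carries the treatment cost.
#' @param half_cycle_correction If `TRUE`, each cycle is valued at the mean
#'   of its start and end occupancy instead of its start occupancy.
#'   Default `FALSE`.
#' @return An `arm_result`: list with `total_cost_eur`, `total_cost_usd`,
#'   `total_qaly`, `arm` and a per-cycle `breakdown` tibble.
#' @export
accumulate <- function(trace, params, arm = NULL, is_intervention = FALSE,
                       half_cycle_correction = FALSE) {
  stopifnot(inherits(trace, "cohort_trace"), inherits(params, "econ_params"))
  arm <- arm %||% attr(trace, "arm")
  occ <- trace_matrix(trace)
  if (half_cycle_correction) {
    occ <- (occ[1:8, , drop = FALSE] + occ[2:9, , drop = FALSE]) / 2
  }
  cycles <- 1:8
  df <- discount_factor(cycles, params)
  u <- merged_utility_vector(params)
  cost_c <- vapply(cycles, function(c) {
    year <- if (c <= 4L) 1L else 2L
    sum(occ[c, ] * state_cost_vector(year, params))
  }, numeric(1))
  treat_c <- ifelse(is_intervention & cycles %in% seq_len(params$treatment_cycles),
                    params$treatment_cost_per_cycle, # already in 2022 EUR
                    0)
  qaly_c <- vapply(cycles, function(c) sum(occ[c, ] * u), numeric(1))
  qscale <- if (params$qaly_convention == "per_year") 0.25 else 1
  breakdown <- tibble::tibble(
    cycle = cycles,
    discount = df,
    cost_eur = df * (cost_c + treat_c),
    qaly = df * qaly_c * qscale
  )
  total_cost <- sum(breakdown$cost_eur)
  structure(
    list(total_cost_eur = total_cost,
         total_cost_usd = total_cost * params$fx_eur_to_usd,
         total_qaly = sum(breakdown$qaly),
         arm = arm, breakdown = breakdown),
    class = "arm_result"
  )
}

#' @export
print.arm_result <- function(x, ...) {
  cat(sprintf("Arm %s: cost EUR %.2f (USD %.2f), QALY %.4f over 2 years\n",
              x$arm %||% "?", x$total_cost_eur, x$total_cost_usd, x$total_qaly))
  invisible(x)
}
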