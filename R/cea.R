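#' Incremental cost-effectiveness comparison of two arms
#'
#' Computes incremental cost and QALYs of the intervention over the
#' comparator, the ICER (undefined when the QALY difference is zero), the
#' cost-effectiveness-plane quadrant, and the dominance classification:
#' quadrant II (cheaper, more effective) means the intervention dominates;
#' quadrant IV (dearer, less effective) means it is dominated; quadrants I
#' and III are trade-offs requiring a willingness-to-pay threshold.
#'
#' @param intervention,comparator `arm_result` objects from [accumulate()].
#' @return A `ce_result`: list with both arm results, `delta_cost_eur`,
#'   `delta_qaly`, `icer` (EUR/QALY, `NA` if undefined), `quadrant`
#'   (`"I"`, `"II"`, `"III"`, `"IV"`, `"indifferent"`) and `dominance`
#'   (`"intervention_dominant"`, `"comparator_dominant"`, `"trade-off"`,
#'   `"indifferent"`).
#' @export
compare_arms <- function(intervention, comparator) {
  stopifnot(inherits(intervention, "arm_result"), inherits(comparator, "arm_result"))
  dc <- intervention$total_cost_eur - comparator$total_cost_eur
  dq <- intervention$total_qaly - comparator$total_qaly
  icer <- if (dq != 0) dc / dq else NA_real_
  quadrant <- if (dq > 0 && dc > 0) "I"
  else if (dq > 0 && dc < 0) "II"
  else if (dq < 0 && dc < 0) "III"
  else if (dq < 0 && dc > 0) "IV"
  else if (dq == 0 && dc == 0) "indifferent"
  else if (dq == 0) if (dc < 0) "II" else "IV" # cost sign decides
  else if (dc == 0) if (dq > 0) "II" else "IV"
  dominance <- switch(quadrant,
    II = "intervention_dominant",
    IV = "comparator_dominant",
    indifferent = "indifferent",
    "trade-off"
  )
  structure(
    list(intervention = intervention, comparator = comparator,
         delta_cost_eur = dc, delta_qaly = dq, icer = icer,
         quadrant = quadrant, dominance = dominance),
    class = "ce_result"
  )
}

#' Net monetary benefit
#'
#' `NMB = WTP x QALY - cost`; a positive incremental NMB means the
#' intervention is cost-effective at that willingness-to-pay.
#'
#' @param arm An `arm_result`.
#' @param wtp Willingness-to-pay threshold, EUR per QALY.
#' @return NMB in EUR.
#' @export
nmb <- function(arm, wtp) {
  wtp * arm$total_qaly - arm$total_cost_eur
}

#' @export
tidy.ce_result <- function(x, ...) {
  tibble::tibble(
    arm = c(x$intervention$arm %||% "intervention", x$comparator$arm %||% "comparator"),
    role = c("intervention", "comparator"),
    cost_eur = c(x$intervention$total_cost_eur, x$comparator$total_cost_eur),
    cost_usd = c(x$intervention$total_cost_usd, x$comparator$total_cost_usd),
    qaly = c(x$intervention$total_qaly, x$comparator$total_qaly)
  )
}

#' @export
glance.ce_result <- function(x, ...) {
  tibble::tibble(
    delta_cost_eur = x$delta_cost_eur, delta_qaly = x$delta_qaly,
    icer = x$icer, quadrant = x$quadrant, dominance = x$dominance
  )
}

#' @export
print.ce_result <- function(x, ...) {
  cat(sprintf(
    "Incremental cost EUR %.2f, incremental QALY %.4f, ICER %s, quadrant %s (%s)\n",
    x$delta_cost_eur, x$delta_qaly,
    if (is.na(x$icer)) "undefined" else sprintf("%.2f EUR/QALY", x$icer),
    x$quadrant, x$dominance))
  invisible(x)
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Re-evaluates the model with each parameter set to its low and high
#' bound in turn, all others at base values, and ranks parameters by the
#' swing (absolute difference of the two outcomes). Rows where the low and
#' high outcomes fall in different cost-effectiveness-plane quadrants are
#' flagged, because the ICER's sign is not comparable across quadrants.
#'
#' @param model_fn Function taking a named list of parameter overrides and
#'   returning a `ce_result`.
#' @param param_bounds Tibble with columns `parameter`, `base`, `low`,
#'   `high` (see [dsa_bounds()]).
#' @param outcome `"icer"` (default) or `"inmb"` (incremental net monetary
#'   benefit at `wtp`).
#' @param wtp Willingness-to-pay used when `outcome = "inmb"`.
#' @return A `tornado_table` tibble: parameter, outcome at low/high bound,
#'   swing, base outcome, quadrant flags; sorted by decreasing swing.
#' @export
one_way_dsa <- function(model_fn, param_bounds,
                        outcome = c("icer", "inmb"), wtp = 30000) {
  outcome <- match.arg(outcome)
  extract <- function(ce) {
    if (outcome == "icer") ce$icer
    else wtp * ce$delta_qaly - ce$delta_cost_eur
  }
  base_ce <- model_fn(list())
  rows <- purrr::pmap(param_bounds, function(parameter, base, low, high, ...) {
    run_at <- function(v) {
      ov <- stats::setNames(list(v), parameter)
      tryCatch(model_fn(ov), error = function(e) e)
    }
    ce_lo <- run_at(low); ce_hi <- run_at(high)
    failed <- inherits(ce_lo, "error") || inherits(ce_hi, "error")
    if (failed) {
      tibble::tibble(parameter = parameter, low = low, high = high,
                     outcome_low = NA_real_, outcome_high = NA_real_,
                     swing = NA_real_, quadrant_low = NA_character_,
                     quadrant_high = NA_character_, mixed_quadrants = NA,
                     error = paste(c(if (inherits(ce_lo, "error")) conditionMessage(ce_lo),
                                     if (inherits(ce_hi, "error")) conditionMessage(ce_hi)),
                                   collapse = "; "))
    } else {
      o_lo <- extract(ce_lo); o_hi <- extract(ce_hi)
      tibble::tibble(parameter = parameter, low = low, high = high,
                     outcome_low = o_lo, outcome_high = o_hi,
                     swing = abs(o_hi - o_lo),
                     quadrant_low = ce_lo$quadrant, quadrant_high = ce_hi$quadrant,
                     mixed_quadrants = ce_lo$quadrant != ce_hi$quadrant,
                     error = NA_character_)
    }
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::arrange(dplyr::desc(.data$swing))
  structure(out, outcome = outcome, base_outcome = extract(base_ce), wtp = wtp,
            class = c("tornado_table", class(out)))
}

#' Default DSA bounds for the economic parameters
#'
#' One row per scalar economic input (utilities by mRS score, annual state
#' costs by year, discount rate, the mRS 0--1 share of the grouped cost),
#' with bounds at +/-20% of the base value (utilities capped at 1, the
#' share capped at 1).
#'
#' @param params An [econ_params()].
#' @param rel Relative half-width of the bounds; default 0.2.
#' @return Tibble with columns `parameter`, `base`, `low`, `high`.
#' @export
dsa_bounds <- function(params, rel = 0.2) {
  vals <- c(
    stats::setNames(as.list(params$utility), paste0("utility.", names(params$utility))),
    stats::setNames(as.list(params$cost_year1), paste0("cost_year1.", names(params$cost_year1))),
    stats::setNames(as.list(params$cost_year2), paste0("cost_year2.", names(params$cost_year2))),
    list(discount_rate_annual = params$discount_rate_annual,
         cost_split_w01 = params$cost_split_weights[1])
  )
  tibble::tibble(
    parameter = names(vals),
    base = unlist(vals),
    low = unlist(vals) * (1 - rel),
    high = pmin(unlist(vals) * (1 + rel),
                ifelse(grepl("^utility|^cost_split", names(vals)), 1, Inf))
  )
}

# internal: apply named overrides (dsa_bounds naming scheme) to econ_params
apply_overrides <- function(params, overrides) {
  for (nm in names(overrides)) {
    v <- overrides[[nm]]
    if (grepl("^utility\\.", nm)) {
      params$utility[[sub("^utility\\.", "", nm)]] <- v
    } else if (grepl("^cost_year1\\.", nm)) {
      params$cost_year1[[sub("^cost_year1\\.", "", nm)]] <- v
    } else if (grepl("^cost_year2\\.", nm)) {
      params$cost_year2[[sub("^cost_year2\\.", "", nm)]] <- v
    } else if (nm == "discount_rate_annual") {
      params$discount_rate_annual <- v
    } else if (nm == "cost_split_w01") {
      params$cost_split_weights <- c(v, 1 - v)
    } else {
      rlang::abort(sprintf("Unknown parameter override '%s'.", nm),
                   class = "strokecea_config_error")
    }
  }
  do.call(econ_params, unclass(params))
}

#' Probabilistic sensitivity analysis by Monte Carlo simulation
#'
#' Draws all uncertain parameters jointly from their distributions
#' (beta for utilities, gamma for costs, Dirichlet for transition rows
#' when counts are supplied) and re-runs the full valuation for each
#' draw. One master seed generates a deterministic per-draw substream, so
#' results do not depend on evaluation order.
#'
#' @param model_fn Function taking a `draw` list (elements `params`, an
#'   [econ_params()], and optionally `schedules`, per-arm cycle schedules)
#'   and returning a `ce_result`.
#' @param sampler A function `(i)` returning the draw list for substream
#'   `i`; build one with [psa_sampler()].
#' @param n_iter Number of Monte Carlo iterations.
#' @param seed Master seed.
#' @return A `psa_sample` tibble: `iter`, `delta_cost_eur`, `delta_qaly`,
#'   `quadrant`; attribute `seed`. A draw whose evaluation fails is kept as
#'   a row with `quadrant = "error"` and `NA` increments (and a warning),
#'   never silently dropped.
#' @export
psa <- function(model_fn, sampler, n_iter, seed) {
  stopifnot(n_iter >= 1)
  set.seed(seed)
  substreams <- sample.int(.Machine$integer.max, n_iter)
  rows <- purrr::map(seq_len(n_iter), function(i) {
    set.seed(substreams[i])
    ce <- tryCatch(model_fn(sampler(i)), error = function(e) e)
    if (inherits(ce, "error")) {
      tibble::tibble(iter = i, delta_cost_eur = NA_real_,
                     delta_qaly = NA_real_, quadrant = "error")
    } else {
      tibble::tibble(iter = i, delta_cost_eur = ce$delta_cost_eur,
                     delta_qaly = ce$delta_qaly, quadrant = ce$quadrant)
    }
  })
  out <- dplyr::bind_rows(rows)
  n_err <- sum(out$quadrant == "error")
  if (n_err > 0) {
    rlang::warn(sprintf(
      "%d of %d PSA draws failed to evaluate and are recorded with quadrant 'error'.",
      n_err, n_iter))
  }
  structure(out, seed = seed, class = c("psa_sample", class(out)))
}

#' Build the default PSA parameter sampler
#'
#' Returns a function drawing one joint parameter set: each utility from a
#' beta distribution moment-matched to its base value (standard deviation
#' = `utility_cv` x mean, truncated to keep a proper beta), each annual
#' state cost from a gamma distribution with coefficient of variation
#' `cost_cv`, and, when base cycle schedules with at-risk counts are
#' supplied, each live row of each per-cycle transition matrix from a
#' Dirichlet centred on the estimated row. The Dirichlet concentration for
#' row i is `n_i * p_ij` with `n_i` the patients observed in state i at
#' the start of the cycle's source interval (0.5 replaces zero cells), so
#' sampled rows are simplex-valid by construction and their spread matches
#' the data's information content. The two model cycles inside one 6-month
#' observation interval share a single draw, preserving the model's
#' equal-cycles assumption. The sampler must be called inside a seeded
#' substream (see [psa()]).
#'
#' @param params Base [econ_params()].
#' @param transition_info Optional named list (`intervention`,
#'   `comparator`), each `list(schedule = <cycle_schedule>, row_counts =
#'   <8 x 6 matrix>)` of base schedules and per-cycle at-risk counts; see
#'   [cycle_row_counts()].
#' @param cost_cv Coefficient of variation for cost draws; default 0.2.
#' @param utility_cv Coefficient of variation for utility draws; default 0.1.
#' @return Function `(i)` returning `list(params = , schedules = or NULL)`.
#' @export
psa_sampler <- function(params, transition_info = NULL,
                        cost_cv = 0.2, utility_cv = 0.1) {
  stopifnot(inherits(params, "econ_params"))
  if (cost_cv <= 0 || utility_cv <= 0) {
    rlang::abort("Coefficients of variation must be positive.",
                 class = "strokecea_validation_error")
  }
  draw_beta <- function(m) {
    s <- utility_cv * m
    s <- min(s, 0.95 * sqrt(m * (1 - m))) # keep within beta-feasible variance
    if (m <= 0 || m >= 1 || s == 0) return(m)
    nu <- m * (1 - m) / s^2 - 1
    stats::rbeta(1, m * nu, (1 - m) * nu)
  }
  draw_gamma <- function(m) {
    if (m == 0) return(0)
    shape <- 1 / cost_cv^2
    stats::rgamma(1, shape = shape, scale = m / shape)
  }
  draw_dirichlet_row <- function(alpha) {
    g <- stats::rgamma(length(alpha), shape = alpha, scale = 1)
    g / sum(g)
  }
  draw_schedule <- function(info) {
    base <- info$schedule
    stopifnot(inherits(base, "cycle_schedule"))
    mats <- vector("list", 8L)
    key <- paste(base$provenance$t_start, base$provenance$t_end)
    for (k in 1:8) {
      if (k > 1 && key[k] == key[k - 1]) { # second cycle of a 6-month interval
        mats[[k]] <- mats[[k - 1]]
        next
      }
      P <- base$matrices[[k]]$probs
      draw <- matrix(0, N_STATES, N_STATES)
      for (i in seq_len(N_STATES - 1L)) {
        n_i <- info$row_counts[k, i]
        if (n_i <= 0) {
          draw[i, ] <- P[i, ]
        } else {
          alpha <- P[i, ] * n_i
          alpha[alpha == 0] <- 0.5
          draw[i, ] <- draw_dirichlet_row(alpha)
        }
      }
      draw[DEATH, DEATH] <- 1
      mats[[k]] <- transition_matrix(draw, time_step = 3, arm = base$arm)
    }
    structure(list(matrices = mats, arm = base$arm, provenance = base$provenance,
                   repair_norms = base$repair_norms),
              class = "cycle_schedule")
  }
  function(i) {
    p <- params
    p$utility[] <- vapply(p$utility, draw_beta, numeric(1))
    p$cost_year1[] <- vapply(p$cost_year1, draw_gamma, numeric(1))
    p$cost_year2[] <- vapply(p$cost_year2, draw_gamma, numeric(1))
    p <- do.call(econ_params, p)
    schedules <- NULL
    if (!is.null(transition_info)) {
      schedules <- purrr::map(transition_info, draw_schedule)
    }
    list(params = p, schedules = schedules)
  }
}

#' Per-cycle at-risk counts for transition uncertainty
#'
#' For each model cycle, the number of patients observed in each state at
#' the start of the observation interval that cycle's matrix derives from.
#' These act as Dirichlet sample sizes in [psa_sampler()].
#'
#' @param data Panel tibble.
#' @param arm Arm label.
#' @param schedule Visit schedule.
#' @param use_month1 Must match the [build_cycle_schedule()] call.
#' @return An 8 x 6 matrix of counts (cycles by states).
#' @export
cycle_row_counts <- function(data, arm, schedule = visit_schedule(),
                             use_month1 = FALSE) {
  iv_of_cycle <- c(
    list(if (use_month1) c(1, 3) else c(schedule[1], 3), c(3, 6)),
    rep(list(c(6, 12)), 2), rep(list(c(12, 18)), 2), rep(list(c(18, 24)), 2)
  )
  t(vapply(iv_of_cycle, function(iv) {
    rowSums(count_transitions(data, arm, iv, schedule)$counts)
  }, numeric(N_STATES)))
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of PSA draws with
#' strictly positive incremental net monetary benefit
#' (`wtp x delta_qaly - delta_cost > 0`); ties count as not
#' cost-effective. At WTP = 0 this is the fraction of cost-saving draws.
#'
#' @param sample A `psa_sample` from [psa()].
#' @param wtp_grid Numeric vector of WTP thresholds (EUR/QALY); default 0
#'   to 100,000 in steps of 1,000.
#' @return A `ceac_curve` tibble: `wtp`, `prob_cost_effective`.
#' @export
ceac <- function(sample, wtp_grid = seq(0, 100000, by = 1000)) {
  if (anyNA(sample$delta_qaly)) {
    rlang::warn("Failed PSA draws count as not cost-effective in the CEAC.")
  }
  prob <- vapply(wtp_grid, function(w) {
    inmb <- w * sample$delta_qaly - sample$delta_cost_eur
    mean(!is.na(inmb) & inmb > 0)
  }, numeric(1))
  out <- tibble::tibble(wtp = wtp_grid, prob_cost_effective = prob)
  structure(out, class = c("ceac_curve", class(out)))
}

#' @export
autoplot.ceac_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$wtp, y = .data$prob_cost_effective)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay (EUR/QALY)",
                  y = "Probability cost-effective",
                  title = "Cost-effectiveness acceptability curve") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.tornado_table <- function(object, ...) {
  base <- attr(object, "base_outcome")
  dat <- tidyr::pivot_longer(object, c("outcome_low", "outcome_high"),
                             names_to = "bound", values_to = "outcome")
  dat$parameter <- factor(dat$parameter, levels = rev(object$parameter))
  ggplot2::ggplot(dat, ggplot2::aes(y = .data$parameter)) +
    ggplot2::geom_segment(ggplot2::aes(x = base, xend = .data$outcome,
                                       yend = .data$parameter, colour = .data$bound),
                          linewidth = 4) +
    ggplot2::geom_vline(xintercept = base, linetype = 2) +
    ggplot2::labs(x = attr(object, "outcome"), y = NULL,
                  title = "One-way sensitivity analysis") +
    ggplot2::theme_minimal()
}

#' CE-plane scatter of PSA draws
#'
#' @param sample A `psa_sample`.
#' @param ce Optional base-case `ce_result` to mark.
#' @return A ggplot object.
#' @export
autoplot.psa_sample <- function(object, ce = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$delta_qaly,
                                            y = .data$delta_cost_eur)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.6, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = 0) + ggplot2::geom_vline(xintercept = 0) +
    ggplot2::labs(x = "Incremental QALY", y = "Incremental cost (EUR)",
                  title = "Cost-effectiveness plane") +
    ggplot2::theme_minimal()
  if (!is.null(ce)) {
    p <- p + ggplot2::annotate("point", x = ce$delta_qaly, y = ce$delta_cost_eur,
                               colour = "red", size = 2)
  }
  p
}
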