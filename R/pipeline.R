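#' Write / read economic parameters as YAML
#'
#' @param params An [econ_params()].
#' @param path File path.
#' @return `write_econ_params()` returns `path` invisibly;
#'   `read_econ_params()` returns an `econ_params`.
#' @export
write_econ_params <- function(params, path) {
  stopifnot(inherits(params, "econ_params"))
  yaml::write_yaml(purrr::map(unclass(params), function(x) {
    if (is.numeric(x) && !is.null(names(x))) as.list(x) else x
  }), path, precision = 15)
  invisible(path)
}

#' @rdname write_econ_params
#' @export
read_econ_params <- function(path) {
  obj <- yaml::read_yaml(path)
  for (nm in c("cost_year1", "cost_year2", "utility", "cost_split_weights")) {
    if (!is.null(obj[[nm]])) obj[[nm]] <- unlist(obj[[nm]])
  }
  do.call(econ_params, obj)
}

#' Initial state distribution of one arm at the first visit
#'
#' The cohort's state distribution at model start (day 10/discharge),
#' tabulated from the panel's first-visit assessments.
#'
#' @param data Panel tibble.
#' @param arm Arm label.
#' @param schedule Visit schedule (the first entry defines the first visit).
#' @return Length-6 probability vector in model state order.
#' @export
initial_distribution <- function(data, arm, schedule = visit_schedule()) {
  first <- data[data$arm == arm & data$visit_month == schedule[1], , drop = FALSE]
  if (nrow(first) == 0) {
    rlang::abort(sprintf("Arm '%s' has no observations at the first visit.", arm),
                 class = "strokecea_validation_error")
  }
  s <- mrs_to_state(first$mrs)
  tabulate(s, nbins = N_STATES) / length(s)
}

# internal: apply a subgroup filter to a panel
apply_subgroup <- function(data, filter) {
  if (is.null(filter)) return(data)
  known <- c("b_nihss_min", "b_nihss_max", "ott_gt_48", "rehab")
  unknown <- setdiff(names(filter), known)
  if (length(unknown) > 0) {
    rlang::abort(sprintf("Unknown subgroup filter field(s): %s.",
                         paste(unknown, collapse = ", ")),
                 class = "strokecea_config_error")
  }
  need_col <- function(col) {
    if (!col %in% names(data)) {
      rlang::abort(sprintf("Subgroup filter needs panel column '%s'.", col),
                   class = "strokecea_config_error")
    }
  }
  keep <- rep(TRUE, nrow(data))
  if (!is.null(filter$b_nihss_min)) { need_col("b_nihss"); keep <- keep & data$b_nihss >= filter$b_nihss_min }
  if (!is.null(filter$b_nihss_max)) { need_col("b_nihss"); keep <- keep & data$b_nihss <= filter$b_nihss_max }
  if (isTRUE(filter$ott_gt_48)) { need_col("ott_hours"); keep <- keep & data$ott_hours > 48 }
  if (!is.null(filter$rehab)) { need_col("rehab"); keep <- keep & data$rehab == filter$rehab }
  data[keep, , drop = FALSE]
}

#' Run the full cost-utility pipeline
#'
#' From a single configuration, runs base case and subgroups: estimates
#' (or loads) per-arm cycle schedules, runs the cohort traces, values them
#' and compares arms; optionally runs the one-way DSA and the Monte Carlo
#' PSA with CEAC per population. A failing population is recorded with its
#' error and does not abort the others.
#'
#' @param config A named list (or path to a YAML file) with fields:
#' * `mode`: `"panel"` or `"schedule_file"`;
#' * `panel`: panel tibble or CSV path (panel mode);
#' * `schedule_files`: named list (`intervention`, `comparator`) of cycle
#'   schedule YAML paths, and `initial_dist`: named list of length-6
#'   distributions (schedule_file mode);
#' * `econ`: an [econ_params()] or a YAML path;
#' * `subgroups`: optional named list of filters
#'   (`b_nihss_min`, `b_nihss_max`, `ott_gt_48`, `rehab`) — panel mode only;
#' * `sensitivity`: list with `dsa` (logical), `psa_iter` (0 disables),
#'   `wtp_grid`, `cost_cv`, `utility_cv`;
#' * `seed`: integer, mandatory;
#' * `use_month1`: see [build_cycle_schedule()];
#' * `half_cycle_correction`: logical, default `FALSE`; see [accumulate()];
#' * `output_dir`: optional directory for CSV/figure exports.
#' @return A `run_report`: list with `populations` (per population: name,
#'   `ce` result, `trace` per arm, `tornado`, `psa`, `ceac`, or `error`),
#'   `summary` tibble (see [summarize_table()]), `config`, `seed`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) {
    rlang::abort("config$seed is mandatory.", class = "strokecea_config_error")
  }
  mode <- match.arg(config$mode, c("panel", "schedule_file"))
  econ <- config$econ
  if (is.character(econ)) econ <- read_econ_params(econ)
  stopifnot(inherits(econ, "econ_params"))
  sens <- config$sensitivity %||% list()
  wtp_grid <- sens$wtp_grid %||% seq(0, 100000, by = 1000)
  schedule <- config$schedule %||% visit_schedule()
  use_month1 <- isTRUE(config$use_month1)
  arms <- c("intervention", "comparator")

  populations <- list()
  if (mode == "panel") {
    panel <- config$panel
    if (is.character(panel)) panel <- read_panel(panel)
    subgroups <- config$subgroups %||% list()
    # validate subgroup fields before any computation
    for (sg in subgroups) apply_subgroup(panel[0, , drop = FALSE], sg)
    pops <- c(list(base_case = NULL), subgroups)
  } else {
    pops <- list(base_case = NULL)
  }

  for (pop_name in names(pops)) {
    res <- tryCatch({
      if (mode == "panel") {
        d <- apply_subgroup(panel, pops[[pop_name]])
        scheds <- purrr::map(stats::setNames(arms, arms), function(a) {
          build_cycle_schedule(d, a, schedule, use_month1 = use_month1)
        })
        inits <- purrr::map(stats::setNames(arms, arms), function(a) {
          initial_distribution(d, a, schedule)
        })
        transition_info <- purrr::map(stats::setNames(arms, arms), function(a) {
          list(schedule = scheds[[a]],
               row_counts = cycle_row_counts(d, a, schedule, use_month1))
        })
      } else {
        scheds <- purrr::map(config$schedule_files, read_cycle_schedule)[arms]
        inits <- purrr::map(config$initial_dist, unlist)[arms]
        transition_info <- NULL
      }
      traces <- purrr::map(stats::setNames(arms, arms), function(a) {
        run_cohort(inits[[a]], scheds[[a]], arm = a)
      })
      value_arms <- function(params, schedules = NULL) {
        tr <- traces
        if (!is.null(schedules)) {
          tr <- purrr::map(stats::setNames(arms, arms), function(a) {
            run_cohort(inits[[a]], schedules[[a]], arm = a)
          })
        }
        hcc <- isTRUE(config$half_cycle_correction)
        compare_arms(
          accumulate(tr$intervention, params, is_intervention = TRUE,
                     half_cycle_correction = hcc),
          accumulate(tr$comparator, params, half_cycle_correction = hcc)
        )
      }
      ce <- value_arms(econ)
      tornado <- NULL
      if (isTRUE(sens$dsa %||% TRUE)) {
        tornado <- one_way_dsa(
          function(overrides) value_arms(apply_overrides(econ, overrides)),
          dsa_bounds(econ, rel = sens$dsa_rel %||% 0.2)
        )
      }
      psa_res <- NULL; ceac_res <- NULL
      n_iter <- sens$psa_iter %||% 0
      if (n_iter > 0) {
        sampler <- psa_sampler(
          econ, transition_info = transition_info,
          cost_cv = sens$cost_cv %||% 0.2,
          utility_cv = sens$utility_cv %||% 0.1
        )
        psa_res <- psa(function(draw) value_arms(draw$params, draw$schedules),
                       sampler, n_iter = n_iter, seed = config$seed)
        ceac_res <- ceac(psa_res, wtp_grid)
      }
      list(name = pop_name, ce = ce, traces = traces, tornado = tornado,
           psa = psa_res, ceac = ceac_res, error = NULL)
    }, error = function(e) {
      list(name = pop_name, ce = NULL, traces = NULL, tornado = NULL,
           psa = NULL, ceac = NULL, error = conditionMessage(e))
    })
    populations[[pop_name]] <- res
  }

  report <- structure(
    list(populations = populations, config = config, seed = config$seed),
    class = "run_report"
  )
  report$summary <- summarize_table(report)
  if (!is.null(config$output_dir)) export_report(report, config$output_dir)
  report
}

#' Summary table of a pipeline run
#'
#' One row per population per arm, in the conventional cost-utility layout:
#' cost, incremental cost, QALY, incremental QALY, ICER (EUR/QALY), with
#' incremental columns on the intervention row only. Base case first.
#'
#' @param report A `run_report` from [run_pipeline()].
#' @return A tibble with columns `population`, `strategy`, `cost_eur`,
#'   `incremental_cost_eur`, `qaly`, `incremental_qaly`, `icer`.
#' @export
summarize_table <- function(report) {
  stopifnot(inherits(report, "run_report"))
  rows <- purrr::map(report$populations, function(p) {
    if (is.null(p$ce)) return(NULL)
    ce <- p$ce
    tibble::tibble(
      population = p$name,
      strategy = c("comparator", "intervention"),
      cost_eur = c(ce$comparator$total_cost_eur, ce$intervention$total_cost_eur),
      incremental_cost_eur = c(NA_real_, ce$delta_cost_eur),
      qaly = c(ce$comparator$total_qaly, ce$intervention$total_qaly),
      incremental_qaly = c(NA_real_, ce$delta_qaly),
      icer = c(NA_real_, ce$icer)
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) > 0 && "base_case" %in% out$population) {
    out <- dplyr::arrange(out, .data$population != "base_case")
  }
  out
}

# internal: write all report artefacts under a directory
export_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(report$summary, file.path(dir, "summary.csv"))
  for (p in report$populations) {
    if (!is.null(p$error)) next
    for (a in names(p$traces)) {
      readr::write_csv(tibble::as_tibble(p$traces[[a]]),
                       file.path(dir, sprintf("trace_%s_%s.csv", p$name, a)))
    }
    if (!is.null(p$tornado)) {
      readr::write_csv(tibble::as_tibble(p$tornado),
                       file.path(dir, sprintf("tornado_%s.csv", p$name)))
    }
    if (!is.null(p$psa)) {
      readr::write_csv(tibble::as_tibble(p$psa),
                       file.path(dir, sprintf("psa_%s.csv", p$name)))
      readr::write_csv(tibble::as_tibble(p$ceac),
                       file.path(dir, sprintf("ceac_%s.csv", p$name)))
    }
  }
  invisible(dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("Cost-utility run (seed %s): %d population(s)\n", x$seed,
              length(x$populations)))
  print(x$summary, n = Inf)
  invisible(x)
}
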