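#' Model health states
#'
#' The model collapses the 7-point modified Rankin Scale (mRS) into six
#' health states: mRS 0--1 (functional recovery), mRS 2, 3, 4, 5, and death
#' (mRS 6). Death is absorbing. State order here fixes the row/column order
#' of every transition matrix and cohort trace in the package.
#'
#' @return Character vector of the six state labels, in model order.
#' @export
model_states <- function() {
  c("mrs01", "mrs2", "mrs3", "mrs4", "mrs5", "dead")
}

N_STATES <- 6L
DEATH <- 6L

#' Map raw mRS scores to model state indices
#'
#' Raw mRS values 0 and 1 both map to the merged functional-recovery state;
#' 6 maps to death.
#'
#' @param mrs Integer vector of raw mRS scores in 0..6.
#' @return Integer vector of state indices in 1..6.
#' @export
mrs_to_state <- function(mrs) {
  if (any(is.na(mrs)) || any(mrs < 0 | mrs > 6) || any(mrs != floor(mrs))) {
    rlang::abort("mRS scores must be integers in 0..6.", class = "strokecea_domain_error")
  }
  as.integer(ifelse(mrs <= 1, 1L, mrs))
}

#' Map model state indices back to representative mRS scores
#'
#' The merged state mrs01 is written out as mRS 0; all other states keep
#' their mRS value (death = 6).
#'
#' @param state Integer vector of state indices in 1..6.
#' @return Integer vector of mRS scores.
#' @export
state_to_mrs <- function(state) {
  as.integer(ifelse(state == 1L, 0L, state))
}

#' Default assessment schedule
#'
#' Assessment times in months: day 10/discharge (coded 0.33), then months
#' 1, 3, 6, 12, 18 and 24. The last visit equals the 2-year model horizon.
#'
#' @param visit_times Strictly increasing numeric vector of visit times in
#'   months; the last entry must equal 24 (the model horizon).
#' @return Validated numeric vector of visit times.
#' @export
visit_schedule <- function(visit_times = c(0.33, 1, 3, 6, 12, 18, 24)) {
  if (!is.numeric(visit_times) || length(visit_times) < 2L) {
    rlang::abort("visit_times must be a numeric vector with at least two visits.",
                 class = "strokecea_config_error")
  }
  if (any(diff(visit_times) <= 0)) {
    rlang::abort("visit_times must be strictly increasing.",
                 class = "strokecea_config_error")
  }
  if (utils::tail(visit_times, 1) != 24) {
    rlang::abort("The last visit must equal the 24-month model horizon.",
                 class = "strokecea_config_error")
  }
  visit_times
}

# internal: check a vector is a probability distribution over the 6 states
check_distribution <- function(p, what = "distribution") {
  if (length(p) != N_STATES || any(p < 0) || abs(sum(p) - 1) > 1e-8) {
    rlang::abort(
      sprintf("%s must be 6 non-negative values summing to 1.", what),
      class = "strokecea_validation_error"
    )
  }
  invisible(p)
}

# internal: validate a 6x6 row-stochastic matrix with absorbing death row
check_stochastic <- function(P, tol = 1e-8, what = "transition matrix") {
  if (!is.matrix(P) || !all(dim(P) == N_STATES)) {
    rlang::abort(sprintf("%s must be a 6x6 matrix.", what),
                 class = "strokecea_validation_error")
  }
  rs <- rowSums(P)
  bad <- which(abs(rs - 1) > tol | apply(P < -tol, 1, any))
  if (length(bad) > 0) {
    rlang::abort(
      sprintf("%s row %d is not a probability distribution (sum = %.12g).",
              what, bad[1], rs[bad[1]]),
      class = "strokecea_validation_error"
    )
  }
  if (any(abs(P[DEATH, ] - c(rep(0, N_STATES - 1L), 1)) > tol)) {
    rlang::abort(
      sprintf("%s death row must be [0,0,0,0,0,1]: death is absorbing.", what),
      class = "strokecea_validation_error"
    )
  }
  invisible(P)
}
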