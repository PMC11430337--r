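#' Count observed transitions over one inter-visit interval
#'
#' Tabulates, for one arm, how many patients moved from each health state
#' at the interval's start visit to each state at its end visit. Patients
#' missing either assessment are excluded (their number is recorded in the
#' result). Observing a patient leave the death state is a data-integrity
#' error.
#'
#' @param data Panel tibble (columns `patient_id`, `arm`, `visit_month`,
#'   `mrs`).
#' @param arm Arm label to count.
#' @param interval Numeric length-2: start and end visit times in months;
#'   both must be visits of `schedule`.
#' @param schedule Visit schedule the panel was collected on.
#' @return A `count_matrix`: list with `counts` (6x6 integer matrix),
#'   `interval`, `arm`, `n_excluded`.
#' @export
count_transitions <- function(data, arm, interval, schedule = visit_schedule()) {
  if (length(interval) != 2L || !all(interval %in% schedule) ||
      interval[2] <= interval[1]) {
    rlang::abort("interval endpoints must be increasing visit times of the schedule.",
                 class = "strokecea_config_error")
  }
  d <- data[data$arm == arm & data$visit_month %in% interval, , drop = FALSE]
  wide <- tidyr::pivot_wider(
    d[, c("patient_id", "visit_month", "mrs")],
    names_from = "visit_month", values_from = "mrs"
  )
  t0 <- as.character(interval[1]); t1 <- as.character(interval[2])
  for (col in c(t0, t1)) if (!col %in% names(wide)) wide[[col]] <- NA_real_
  complete <- !is.na(wide[[t0]]) & !is.na(wide[[t1]])
  from <- mrs_to_state(wide[[t0]][complete])
  to <- mrs_to_state(wide[[t1]][complete])
  if (any(from == DEATH & to != DEATH)) {
    rlang::abort(
      sprintf("Patient %s leaves the death state over (%s, %s) months.",
              wide$patient_id[complete][which(from == DEATH & to != DEATH)[1]],
              t0, t1),
      class = "strokecea_integrity_error"
    )
  }
  counts <- matrix(0L, N_STATES, N_STATES,
                   dimnames = list(model_states(), model_states()))
  for (k in seq_along(from)) counts[from[k], to[k]] <- counts[from[k], to[k]] + 1L
  structure(
    list(counts = counts, interval = interval, arm = arm,
         n_excluded = sum(!complete)),
    class = "count_matrix"
  )
}

#' Maximum-likelihood transition probabilities from counts
#'
#' Row-normalises a transition count matrix. Rows with no observations get
#' the identity row (the cohort fraction in an unobserved state stays put),
#' with a warning; the death row is forced to the absorbing unit vector.
#'
#' @param c A `count_matrix` from [count_transitions()].
#' @return A `transition_matrix`: list with `probs` (6x6), `time_step`
#'   (months), `arm`.
#' @export
counts_to_probability <- function(c) {
  stopifnot(inherits(c, "count_matrix"))
  P <- matrix(0, N_STATES, N_STATES,
              dimnames = dimnames(c$counts))
  rs <- rowSums(c$counts)
  empty <- integer(0)
  for (i in seq_len(N_STATES)) {
    if (rs[i] > 0) {
      P[i, ] <- c$counts[i, ] / rs[i]
    } else {
      P[i, i] <- 1
      if (i != DEATH) empty <- c(empty, i)
    }
  }
  P[DEATH, ] <- c(rep(0, N_STATES - 1L), 1)
  if (length(empty) > 0) {
    rlang::warn(sprintf(
      "No observations leaving state(s) %s over (%s, %s) months; identity row used.",
      paste(model_states()[empty], collapse = ", "),
      c$interval[1], c$interval[2]))
  }
  transition_matrix(P, time_step = diff(c$interval), arm = c$arm)
}

#' Construct a transition matrix object
#'
#' @param P 6x6 row-stochastic matrix with absorbing death row.
#' @param time_step Time step of the matrix, in months.
#' @param arm Optional arm label.
#' @return A `transition_matrix`.
#' @export
transition_matrix <- function(P, time_step, arm = NULL) {
  dimnames(P) <- list(model_states(), model_states())
  check_stochastic(P, tol = 1e-10)
  structure(list(probs = P, time_step = time_step, arm = arm),
            class = "transition_matrix")
}

#' Convert a transition matrix to a hazard (rate) matrix
#'
#' Computes the generator Q = log(P) / dt (principal matrix logarithm, dt
#' in years). Empirical matrices are often not exactly embeddable: small
#' negative off-diagonal rates in the principal log are repaired by zeroing
#' them and adding the removed mass to the diagonal, so rows still sum to
#' zero; the total perturbation is returned. A matrix whose spectrum does
#' not admit a real principal logarithm raises an embeddability error.
#'
#' @param p A `transition_matrix`.
#' @return A `rate_matrix`: list with `rates` (per year, rows sum to 0,
#'   death row all zero), `repair_norm` (sum of removed negative mass, per
#'   year), `arm`.
#' @export
probability_to_rate <- function(p) {
  stopifnot(inherits(p, "transition_matrix"))
  dt_years <- p$time_step / 12
  ev <- eigen(p$probs, only.values = TRUE)$values
  if (any(Re(ev) <= 0 & abs(Im(ev)) < 1e-12)) {
    rlang::abort(
      "Matrix has an eigenvalue on the closed negative real axis: no real principal logarithm exists. Estimate on a finer time step or pool intervals.",
      class = "strokecea_embeddability_error"
    )
  }
  L <- principal_logm(p$probs)
  Q <- L / dt_years
  # repair: zero negative off-diagonal rates, return mass to the diagonal
  off <- Q; diag(off) <- 0
  neg <- pmin(off, 0)
  repair_norm <- sum(abs(neg))
  off <- pmax(off, 0)
  Q <- off
  diag(Q) <- -rowSums(off)
  Q[DEATH, ] <- 0
  dimnames(Q) <- list(model_states(), model_states())
  structure(list(rates = Q, repair_norm = repair_norm, arm = p$arm),
            class = "rate_matrix")
}

# principal matrix logarithm, robust to defective matrices.
# Route 1: eigendecomposition (pracma::logm). Empirical transition matrices
# with several identical (e.g. identity) rows can be defective, where the
# eigenvector solve is singular; route 2 then applies inverse scaling and
# squaring: repeated Denman-Beavers square roots until the matrix is close
# to I, a truncated Mercator series for log(I + X), and doubling back.
principal_logm <- function(P, tol = 1e-8) {
  L <- tryCatch(suppressWarnings(pracma::logm(P)), error = function(e) NULL)
  ok <- function(L) {
    !is.null(L) && all(is.finite(Re(L))) && max(abs(Im(L))) < tol &&
      max(abs(as.matrix(Matrix::expm(Matrix::Matrix(Re(L)))) - P)) < tol
  }
  if (ok(L)) return(Re(L))
  L <- tryCatch(logm_iss(P), error = function(e) NULL)
  if (ok(L)) return(Re(L))
  rlang::abort(
    "No accurate real principal matrix logarithm found: the matrix appears non-embeddable.",
    class = "strokecea_embeddability_error"
  )
}

# Denman-Beavers iteration for the principal matrix square root
sqrtm_db <- function(A, maxit = 100L, tol = 1e-14) {
  Y <- A; Z <- diag(nrow(A))
  for (i in seq_len(maxit)) {
    Y1 <- 0.5 * (Y + solve(Z))
    Z1 <- 0.5 * (Z + solve(Y))
    if (max(abs(Y1 - Y)) < tol) return(Y1)
    Y <- Y1; Z <- Z1
  }
  Y
}

logm_iss <- function(P, maxroots = 40L) {
  I <- diag(nrow(P))
  A <- P
  k <- 0L
  while (max(abs(A - I)) > 0.25 && k < maxroots) {
    A <- sqrtm_db(A)
    k <- k + 1L
  }
  X <- A - I
  L <- matrix(0, nrow(P), ncol(P))
  term <- I
  for (j in 1:40) { # Mercator series, ||X|| < 0.25 so terms decay fast
    term <- term %*% X
    L <- L + ((-1)^(j + 1) / j) * term
  }
  L * 2^k
}

#' Convert a hazard matrix to a transition matrix over a cycle
#'
#' P = exp(Q * cycle_length). Tiny negative entries from the matrix
#' exponential are clamped to zero and the row renormalised provided the
#' clamping moves the row sum by less than 1e-9.
#'
#' @param q A `rate_matrix` (per year).
#' @param cycle_length_years Cycle length in years; default 0.25 (3 months).
#' @return A `transition_matrix` with `time_step = cycle_length_years * 12`.
#' @export
rate_to_probability <- function(q, cycle_length_years = 0.25) {
  stopifnot(inherits(q, "rate_matrix"), cycle_length_years > 0)
  P <- as.matrix(Matrix::expm(Matrix::Matrix(q$rates * cycle_length_years)))
  clamped <- pmin(pmax(P, 0), 1)
  if (any(abs(rowSums(clamped) - 1) > 1e-9)) {
    rlang::abort("Matrix exponential row sums deviate from 1 by more than 1e-9.",
                 class = "strokecea_numeric_error")
  }
  P <- clamped / rowSums(clamped)
  P[DEATH, ] <- c(rep(0, N_STATES - 1L), 1)
  transition_matrix(P, time_step = cycle_length_years * 12, arm = q$arm)
}

#' Build the per-cycle transition schedule for one arm
#'
#' Produces the eight 3-month transition matrices the Markov engine
#' consumes, from panel data on the default assessment schedule:
#' * cycle 1 (months 0--3): the observed first-visit -> month-3 transition,
#'   used on its native step (optionally the month-1 -> month-3 transition
#'   re-timed through hazards, see `use_month1`);
#' * cycle 2 (months 3--6): the observed month-3 -> month-6 transition;
#' * cycles 3--8: each observed 6-month interval (6--12, 12--18, 18--24) is
#'   converted to hazards and re-expressed on the 3-month cycle, and the
#'   resulting matrix is used for both cycles inside that interval.
#'
#' @param data Panel tibble.
#' @param arm Arm label.
#' @param schedule Visit schedule; must include months 3, 6, 12, 18, 24.
#' @param use_month1 If `TRUE`, derive cycle 1 from the month-1 -> month-3
#'   transition rescaled to 3 months via hazards instead of the
#'   first-visit -> month-3 transition. Default `FALSE`.
#' @return A `cycle_schedule`: list with `matrices` (8 `transition_matrix`
#'   objects), `arm`, `provenance` (tibble: cycle, interval, method),
#'   `repair_norms`.
#' @export
build_cycle_schedule <- function(data, arm, schedule = visit_schedule(),
                                 use_month1 = FALSE) {
  need <- c(3, 6, 12, 18, 24)
  if (!all(need %in% schedule)) {
    rlang::abort("Schedule must include months 3, 6, 12, 18 and 24.",
                 class = "strokecea_config_error")
  }
  first_visit <- schedule[1]
  est <- function(interval) {
    counts_to_probability(count_transitions(data, arm, interval, schedule))
  }
  # Hazard halving with an embeddability fallback: sparse empirical
  # matrices (e.g. a one-patient row) can be singular or have negative
  # real eigenvalues, so no principal logarithm exists. The matrix is then
  # shrunk toward the identity, P(eps) = (1-eps) P + eps I, by the
  # smallest eps on a doubling ladder that restores embeddability; the
  # shrinkage is reported with the repair norms.
  halve <- function(tm) {
    for (eps in c(0, 1e-8, 1e-6, 1e-4, 1e-3, 2e-3, 5e-3, 0.01, 0.02, 0.05)) {
      P <- (1 - eps) * tm$probs + eps * diag(N_STATES)
      tm_eps <- transition_matrix(P, time_step = tm$time_step, arm = tm$arm)
      q <- tryCatch(probability_to_rate(tm_eps),
                    strokecea_embeddability_error = function(e) NULL)
      if (!is.null(q)) {
        if (eps > 0) {
          rlang::warn(sprintf(
            "Interval matrix shrunk toward identity by eps = %g to admit a hazard representation.",
            eps))
        }
        return(list(p = rate_to_probability(q, 0.25),
                    repair = q$repair_norm, shrink = eps))
      }
    }
    rlang::abort(
      "Interval matrix admits no hazard representation even after shrinkage.",
      class = "strokecea_embeddability_error"
    )
  }
  matrices <- vector("list", 8L)
  prov <- list()
  repair_norms <- numeric(0)
  if (use_month1) {
    h <- halve(est(c(1, 3)))
    matrices[[1]] <- h$p
    repair_norms <- c(repair_norms, cycle1 = h$repair)
    prov[[1]] <- tibble::tibble(cycle = 1L, t_start = 1, t_end = 3,
                                method = "hazard_rescaled")
  } else {
    matrices[[1]] <- est(c(first_visit, 3))
    prov[[1]] <- tibble::tibble(cycle = 1L, t_start = first_visit, t_end = 3,
                                method = "direct")
  }
  matrices[[2]] <- est(c(3, 6))
  prov[[2]] <- tibble::tibble(cycle = 2L, t_start = 3, t_end = 6, method = "direct")
  six_month <- list(c(6, 12), c(12, 18), c(18, 24))
  for (k in seq_along(six_month)) {
    iv <- six_month[[k]]
    h <- halve(est(iv))
    for (j in 1:2) {
      cyc <- 2L + 2L * (k - 1L) + j
      matrices[[cyc]] <- h$p
      prov[[cyc]] <- tibble::tibble(cycle = cyc, t_start = iv[1], t_end = iv[2],
                                    method = "hazard_half")
    }
    repair_norms <- c(repair_norms,
                      stats::setNames(h$repair, paste0("interval_", iv[1], "_", iv[2])),
                      stats::setNames(h$shrink, paste0("shrink_", iv[1], "_", iv[2])))
  }
  structure(
    list(matrices = matrices, arm = arm,
         provenance = dplyr::bind_rows(prov), repair_norms = repair_norms),
    class = "cycle_schedule"
  )
}

#' Construct a cycle schedule directly from matrices
#'
#' For supplying externally derived per-cycle transition inputs (e.g. a
#' published model's inputs) without panel data.
#'
#' @param matrices List of 8 row-stochastic 6x6 matrices (or
#'   `transition_matrix` objects), one per 3-month cycle.
#' @param arm Arm label.
#' @return A `cycle_schedule`.
#' @export
cycle_schedule <- function(matrices, arm = NULL) {
  if (length(matrices) != 8L) {
    rlang::abort("A cycle schedule needs exactly 8 matrices (2 years / 3 months).",
                 class = "strokecea_config_error")
  }
  matrices <- purrr::map(matrices, function(m) {
    if (inherits(m, "transition_matrix")) m else transition_matrix(m, time_step = 3, arm = arm)
  })
  structure(
    list(matrices = matrices, arm = arm,
         provenance = tibble::tibble(cycle = 1:8, t_start = NA_real_,
                                     t_end = NA_real_, method = "supplied"),
         repair_norms = numeric(0)),
    class = "cycle_schedule"
  )
}

#' Write / read a cycle schedule as YAML
#'
#' Serialises the eight per-cycle matrices (row-major nested lists) with
#' the arm label, so the Markov engine can run from a file without panel
#' data.
#'
#' @param sched A `cycle_schedule`.
#' @param path File path.
#' @return `write_cycle_schedule()` returns `path` invisibly;
#'   `read_cycle_schedule()` returns a `cycle_schedule`.
#' @export
write_cycle_schedule <- function(sched, path) {
  stopifnot(inherits(sched, "cycle_schedule"))
  obj <- list(
    arm = sched$arm,
    cycle_length_months = 3,
    matrices = purrr::map(sched$matrices, function(m) {
      apply(unname(m$probs), 1, as.list, simplify = FALSE)
    })
  )
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname write_cycle_schedule
#' @export
read_cycle_schedule <- function(path) {
  obj <- yaml::read_yaml(path)
  mats <- purrr::map(obj$matrices, function(m) {
    do.call(rbind, purrr::map(m, unlist))
  })
  cycle_schedule(mats, arm = obj$arm)
}

#' @export
tidy.cycle_schedule <- function(x, ...) {
  purrr::imap(x$matrices, function(m, cyc) {
    tibble::tibble(
      cycle = cyc,
      from = rep(model_states(), times = N_STATES),
      to = rep(model_states(), each = N_STATES),
      probability = as.vector(m$probs)
    )
  }) |> dplyr::bind_rows()
}
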