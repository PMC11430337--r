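make_panel <- function(rows) {
  # rows: list of c(id, arm, month, mrs)
  tibble::tibble(
    patient_id = purrr::map_chr(rows, 1),
    arm = purrr::map_chr(rows, 2),
    visit_month = as.numeric(purrr::map_chr(rows, 3)),
    mrs = as.numeric(purrr::map_chr(rows, 4))
  )
}

test_that("count_transitions enumerates observed state pairs", {
  d <- make_panel(list(
    c("A", "comparator", "3", "3"), c("A", "comparator", "6", "2"),
    c("B", "comparator", "3", "3"), c("B", "comparator", "6", "6"),
    c("C", "comparator", "3", "2"), c("C", "comparator", "6", "2"),
    c("D", "comparator", "3", "4") # month 6 missing -> excluded
  ))
  cm <- count_transitions(d, "comparator", c(3, 6))
  expect_equal(cm$counts["mrs3", "mrs2"], 1L)
  expect_equal(cm$counts["mrs3", "dead"], 1L)
  expect_equal(cm$counts["mrs2", "mrs2"], 1L)
  expect_equal(sum(cm$counts), 3L)
  expect_equal(cm$n_excluded, 1L)

  all_stay <- make_panel(list(
    c("A", "x", "3", "3"), c("A", "x", "6", "3"),
    c("B", "x", "3", "3"), c("B", "x", "6", "3"),
    c("C", "x", "3", "3"), c("C", "x", "6", "3")
  ))
  cm2 <- count_transitions(all_stay, "x", c(3, 6))
  expect_equal(cm2$counts["mrs3", "mrs3"], 3L)
  expect_equal(sum(cm2$counts), 3L)
})

test_that("count_transitions rejects bad intervals and resurrection", {
  d <- make_panel(list(c("A", "x", "3", "6"), c("A", "x", "6", "3")))
  expect_error(count_transitions(d, "x", c(3, 6)),
               class = "strokecea_integrity_error")
  expect_error(count_transitions(d, "x", c(3, 5)),
               class = "strokecea_config_error")
})

test_that("counts_to_probability row-normalises and patches empty rows", {
  cm <- count_transitions(
    make_panel(list(
      c("A", "x", "3", "3"), c("A", "x", "6", "2"),
      c("B", "x", "3", "3"), c("B", "x", "6", "3")
    )), "x", c(3, 6))
  cm$counts["mrs01", ] <- c(2L, 2L, 0L, 0L, 0L, 0L)
  p <- suppressWarnings(counts_to_probability(cm))
  expect_equal(unname(p$probs["mrs01", ]), c(0.5, 0.5, 0, 0, 0, 0))
  expect_equal(unname(p$probs["mrs3", ]), c(0, 0.5, 0.5, 0, 0, 0))
  expect_warning(counts_to_probability(cm), regexp = "identity row")
  # unobserved rows (mrs2, mrs4, mrs5) stay put
  expect_equal(unname(p$probs["mrs4", "mrs4"]), 1)
  expect_equal(unname(p$probs["dead", ]), c(0, 0, 0, 0, 0, 1))
})

test_that("probability_to_rate recovers a closed-form single-exit hazard", {
  # exit intensity 0.4/yr observed over half a year: P(exit) = 1 - exp(-0.2)
  P <- single_exit_P(1 - exp(-0.2))
  q <- probability_to_rate(transition_matrix(P, time_step = 6))
  expect_equal(q$rates[5, 6], 0.4, tolerance = 1e-8)
  expect_equal(q$repair_norm, 0, tolerance = 1e-10)
  expect_true(all(abs(rowSums(q$rates)) < 1e-10))

  # identity matrix has a zero generator
  q0 <- probability_to_rate(transition_matrix(identity_P(), time_step = 6))
  expect_equal(max(abs(q0$rates)), 0, tolerance = 1e-12)
})

test_that("negative off-diagonal rates are repaired mass-preservingly", {
  P <- recovery_P()
  q <- probability_to_rate(transition_matrix(P, time_step = 6))
  Q <- q$rates
  off <- Q; diag(off) <- 0
  expect_true(all(off >= 0))
  expect_true(all(abs(rowSums(Q)) < 1e-10))
  expect_true(all(Q[6, ] == 0))
  expect_gte(q$repair_norm, 0)
})

test_that("rate_to_probability inverts the hazard map", {
  # zero generator -> identity
  q0 <- probability_to_rate(transition_matrix(identity_P(), time_step = 6))
  expect_equal(unname(rate_to_probability(q0, 0.25)$probs), diag(6),
               tolerance = 1e-10)

  # single-exit intensity 0.4/yr over a 3-month cycle: 1 - exp(-0.1)
  Q <- matrix(0, 6, 6); Q[5, 6] <- 0.4; Q[5, 5] <- -0.4
  q <- structure(list(rates = Q, repair_norm = 0, arm = NULL), class = "rate_matrix")
  P3 <- rate_to_probability(q, 0.25)$probs
  expect_equal(P3[5, 6], 1 - exp(-0.1), tolerance = 1e-10)

  # inverse pair on an embeddable matrix
  P <- embeddable_P6()
  tm <- transition_matrix(P, time_step = 6)
  back <- rate_to_probability(probability_to_rate(tm), cycle_length_years = 0.5)
  expect_equal(unname(back$probs), unname(P), tolerance = 1e-8)
})

test_that("half-interval matrices square back to the observed 6-month matrix", {
  for (P in list(embeddable_P6(), single_exit_P(0.3))) {
    tm <- transition_matrix(P, time_step = 6)
    P3 <- rate_to_probability(probability_to_rate(tm), 0.25)$probs
    expect_lt(max(abs(P3 %*% P3 - P)), 1e-6)
  }
})

test_that("build_cycle_schedule lays out 8 cycles with duplicated half-intervals", {
  spec <- homogeneous_spec(recovery_P(), n = 500L, seed = 5L)
  d <- generate_cohort(spec)
  s <- build_cycle_schedule(d, "comparator")
  expect_length(s$matrices, 8)
  expect_equal(s$provenance$cycle, 1:8)
  expect_equal(s$provenance$method,
               c("direct", "direct", rep("hazard_half", 6)))
  # the two cycles inside each 6-month interval share one matrix
  for (k in c(3, 5, 7)) {
    expect_identical(s$matrices[[k]]$probs, s$matrices[[k + 1]]$probs)
  }
  # every produced matrix is row-stochastic with absorbing death
  for (m in s$matrices) {
    expect_true(all(abs(rowSums(m$probs) - 1) < 1e-10))
    expect_true(all(m$probs >= 0 & m$probs <= 1))
    expect_equal(unname(m$probs[6, ]), c(0, 0, 0, 0, 0, 1))
  }
})

test_that("identity-dynamics data recover an identity schedule", {
  spec <- homogeneous_spec(identity_P(), n = 50L, seed = 2L,
                           init = c(0.2, 0.2, 0.2, 0.2, 0.2, 0))
  d <- generate_cohort(spec)
  s <- suppressWarnings(build_cycle_schedule(d, "intervention"))
  for (m in s$matrices) expect_equal(unname(m$probs), diag(6), tolerance = 1e-10)
})

test_that("a homogeneous generator is recovered within sampling error", {
  # truly time-homogeneous dynamics: one generator Q drives every interval,
  # observed at the trial's irregular spacings. The estimation chain should
  # recover the corresponding interval matrices within binomial error.
  P3 <- rate_to_probability(
    probability_to_rate(transition_matrix(recovery_P(), time_step = 6)), 0.25)$probs
  Q <- probability_to_rate(transition_matrix(P3, time_step = 3))
  pstep <- function(months) rate_to_probability(Q, months / 12)$probs
  P6 <- pstep(6)
  arm <- list(
    matrices = list(pstep(0.67), pstep(2), P3, P6, P6, P6),
    init = c(0.05, 0.1, 0.3, 0.35, 0.2, 0)
  )
  spec <- generative_spec(
    arms = list(intervention = arm, comparator = arm),
    n_per_arm = c(intervention = 2000L, comparator = 2000L), seed = 77L
  )
  d <- generate_cohort(spec)
  s <- build_cycle_schedule(d, "intervention")

  # >= 95% of live-row entries within 3 binomial SEs of truth
  check_vs <- function(Phat, Ptrue, row_n, label) {
    hits <- unlist(lapply(1:5, function(i) {
      se <- binom_se(Ptrue[i, ], row_n[i])
      abs(Phat[i, ] - Ptrue[i, ]) <= 3 * se + 1e-9
    }))
    expect_gte(mean(hits), 0.95)
  }
  # directly observed cycles against the exact interval truths
  n1 <- rowSums(count_transitions(d, "intervention", c(0.33, 3))$counts)
  check_vs(s$matrices[[1]]$probs, pstep(2.67), n1, "cycle 1 (day10 -> m3)")
  n2 <- rowSums(count_transitions(d, "intervention", c(3, 6))$counts)
  check_vs(s$matrices[[2]]$probs, P3, n2, "cycle 2")
  # hazard-derived cycles: squaring the derived 3-month matrix must land
  # within binomial error of the observed 6-month truth
  for (iv in list(c(6, 12), c(12, 18), c(18, 24))) {
    k <- 3 + 2 * (iv[1] / 6 - 1)
    nk <- rowSums(count_transitions(d, "intervention", iv)$counts)
    Phat6 <- s$matrices[[k]]$probs %*% s$matrices[[k]]$probs
    check_vs(Phat6, P6, nk, sprintf("interval %d-%d", iv[1], iv[2]))
  }
})

test_that("cycle schedules round-trip through YAML", {
  spec <- homogeneous_spec(recovery_P(), n = 120L, seed = 8L)
  d <- generate_cohort(spec)
  s <- build_cycle_schedule(d, "comparator")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_cycle_schedule(s, path)
  s2 <- read_cycle_schedule(path)
  for (k in 1:8) {
    expect_equal(unname(s2$matrices[[k]]$probs), unname(s$matrices[[k]]$probs),
                 tolerance = 1e-12)
  }
  expect_equal(s2$arm, "comparator")
})
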