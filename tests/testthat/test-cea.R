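test_that("a cheaper, more effective intervention lands in quadrant II and dominates", {
  # totals on the scale of a two-year stroke cost-utility comparison
  ce <- compare_arms(arm_stub(33266, 4.57, "active"), arm_stub(38346, 4.12, "control"))
  expect_equal(ce$delta_cost_eur, -5080)
  expect_equal(ce$delta_qaly, 0.45, tolerance = 1e-12)
  expect_equal(ce$quadrant, "II")
  expect_equal(ce$dominance, "intervention_dominant")
  # ICER from these (rounded) totals; negative in quadrant II
  expect_equal(ce$icer, -5080 / 0.45, tolerance = 1e-9)
  expect_equal(ce$icer, -11288.89, tolerance = 1e-6)
})

test_that("identical arms are indifferent with an undefined ICER", {
  ce <- compare_arms(arm_stub(1000, 2), arm_stub(1000, 2))
  expect_equal(ce$delta_cost_eur, 0)
  expect_equal(ce$delta_qaly, 0)
  expect_true(is.na(ce$icer))
  expect_equal(ce$quadrant, "indifferent")
  expect_equal(ce$dominance, "indifferent")
})

test_that("dominance classification agrees with a sign-enumeration oracle", {
  # oracle: classify purely from the signs of (delta cost, delta qaly)
  oracle <- function(dc, dq) {
    if (dc == 0 && dq == 0) return(c("indifferent", "indifferent"))
    if (dq > 0 && dc < 0) return(c("II", "intervention_dominant"))
    if (dq < 0 && dc > 0) return(c("IV", "comparator_dominant"))
    if (dq > 0 && dc > 0) return(c("I", "trade-off"))
    if (dq < 0 && dc < 0) return(c("III", "trade-off"))
    # one delta exactly zero: better-or-equal on both axes decides
    if (dc < 0 || dq > 0) return(c("II", "intervention_dominant"))
    c("IV", "comparator_dominant")
  }
  set.seed(123)
  n <- 10000
  dc <- sample(c(-1, 0, 1), n, replace = TRUE) * stats::rexp(n, 1 / 5000)
  dq <- sample(c(-1, 0, 1), n, replace = TRUE) * stats::rexp(n, 2)
  comp <- arm_stub(1000, 2)
  ok <- vapply(seq_len(n), function(k) {
    ce <- compare_arms(arm_stub(1000 + dc[k], 2 + dq[k]), comp)
    identical(c(ce$quadrant, ce$dominance),
              oracle(ce$delta_cost_eur, ce$delta_qaly))
  }, logical(1))
  expect_true(all(ok))
})

test_that("net monetary benefit is the WTP-weighted QALY minus cost", {
  expect_equal(nmb(arm_stub(4000, 1), 0), -4000)
  expect_equal(nmb(arm_stub(4000, 1), 10000), 6000)
  # incremental NMB positive at every non-negative WTP in quadrant II
  ce <- compare_arms(arm_stub(900, 3), arm_stub(1000, 2))
  wtp <- seq(0, 100000, by = 5000)
  expect_true(all(wtp * ce$delta_qaly - ce$delta_cost_eur > 0))
})

test_that("one-way DSA ranks swings and flags inert parameters", {
  # a toy model whose outcome reacts only to parameter 'a'
  model <- function(overrides) {
    a <- overrides$a %||% 10
    compare_arms(arm_stub(1000 - 50 * a, 2.5), arm_stub(1000, 2))
  }
  bounds <- tibble::tibble(
    parameter = c("b", "a"),
    base = c(1, 10), low = c(0.5, 5), high = c(1.5, 15)
  )
  tt <- one_way_dsa(model, bounds)
  expect_equal(tt$parameter, c("a", "b")) # sorted by swing, descending
  expect_equal(tt$swing[tt$parameter == "b"], 0)
  expect_true(all(tt$swing >= 0))
  # degenerate bounds: every swing zero
  tt0 <- one_way_dsa(model, tibble::tibble(parameter = c("a", "b"),
                                           base = c(10, 1), low = c(10, 1),
                                           high = c(10, 1)))
  expect_true(all(tt0$swing == 0))
  # swings invariant to the order bounds are supplied in
  tt_rev <- one_way_dsa(model, bounds[2:1, ])
  expect_equal(tt_rev$swing, tt$swing)
  expect_equal(tt_rev$parameter, tt$parameter)
})

test_that("DSA on the economic inputs keeps a dominant base case negative throughout", {
  spec <- homogeneous_spec(recovery_P(), n = 250L, seed = 15L)
  d <- generate_cohort(spec)
  # make the intervention arm strictly better: its cohort starts healthier
  s <- build_cycle_schedule(d, "comparator")
  tr_i <- run_cohort(c(0.3, 0.3, 0.2, 0.1, 0.1, 0), s)
  tr_c <- run_cohort(c(0.0, 0.1, 0.2, 0.3, 0.4, 0), s)
  econ <- toy_econ()
  model <- function(overrides) {
    p <- strokecea:::apply_overrides(econ, overrides)
    compare_arms(accumulate(tr_i, p, arm = "i", is_intervention = TRUE),
                 accumulate(tr_c, p, arm = "c"))
  }
  tt <- one_way_dsa(model, dsa_bounds(econ))
  expect_true(all(is.na(tt$error)))
  expect_true(all(tt$outcome_low < 0 & tt$outcome_high < 0))
  expect_false(any(tt$mixed_quadrants))
})

test_that("PSA is reproducible, degenerate at zero variance, and simplex-valid", {
  spec <- homogeneous_spec(recovery_P(), n = 250L, seed = 16L)
  d <- generate_cohort(spec)
  scheds <- purrr::map(list(intervention = "intervention", comparator = "comparator"),
                       function(a) build_cycle_schedule(d, a))
  tinfo <- purrr::imap(scheds, function(s, a) {
    list(schedule = s, row_counts = cycle_row_counts(d, a))
  })
  inits <- purrr::map(list(intervention = "intervention", comparator = "comparator"),
                      function(a) initial_distribution(d, a))
  econ <- toy_econ()
  model <- function(draw) {
    sch <- draw$schedules %||% scheds
    compare_arms(
      accumulate(run_cohort(inits$intervention, sch$intervention), draw$params,
                 arm = "i", is_intervention = TRUE),
      accumulate(run_cohort(inits$comparator, sch$comparator), draw$params, arm = "c")
    )
  }
  sampler <- psa_sampler(econ, transition_info = tinfo)
  s1 <- psa(model, sampler, n_iter = 40, seed = 99)
  s2 <- psa(model, sampler, n_iter = 40, seed = 99)
  expect_identical(as.data.frame(s1), as.data.frame(s2)) # same seed, same draws
  s3 <- psa(model, sampler, n_iter = 40, seed = 100)
  expect_false(identical(s1$delta_cost_eur, s3$delta_cost_eur))

  # sampled transition rows live on the simplex
  set.seed(1)
  draw <- sampler(1)
  for (sch in draw$schedules) {
    for (m in sch$matrices) {
      expect_true(all(abs(rowSums(m$probs) - 1) < 1e-10))
      expect_true(all(m$probs >= 0))
    }
  }

  # with no transition counts and near-zero parameter CVs the draws
  # concentrate on the base case
  tight <- psa_sampler(econ, cost_cv = 1e-6, utility_cv = 1e-6)
  s4 <- psa(model, tight, n_iter = 10, seed = 5)
  base <- model(list(params = econ))
  expect_lt(max(abs(s4$delta_cost_eur - base$delta_cost_eur)), 1)
  expect_lt(max(abs(s4$delta_qaly - base$delta_qaly)), 1e-4)
})

test_that("CEAC follows its definition on a two-atom sample", {
  # 50/50 between (+1 QALY, -100 EUR) and (-1 QALY, +100 EUR)
  sample <- structure(
    tibble::tibble(iter = 1:2,
                   delta_cost_eur = c(-100, 100),
                   delta_qaly = c(1, -1),
                   quadrant = c("II", "IV")),
    class = c("psa_sample", class(tibble::tibble()))
  )
  curve <- ceac(sample, wtp_grid = c(0, 50, 100, 150, 1000))
  # draw 1 is cost-effective at every wtp (NMB = wtp + 100 > 0);
  # draw 2 never is (NMB = -wtp - 100 < 0)
  expect_equal(curve$prob_cost_effective, rep(0.5, 5))
  expect_equal(curve$prob_cost_effective[curve$wtp == 0],
               mean(sample$delta_cost_eur < 0))
})

test_that("CEAC is identically 1 on quadrant-II draws and 0 on quadrant-IV draws", {
  qii <- structure(tibble::tibble(iter = 1:5, delta_cost_eur = -(1:5) * 10,
                                  delta_qaly = (1:5) / 10, quadrant = "II"),
                   class = c("psa_sample", class(tibble::tibble())))
  qiv <- structure(tibble::tibble(iter = 1:5, delta_cost_eur = (1:5) * 10,
                                  delta_qaly = -(1:5) / 10, quadrant = "IV"),
                   class = c("psa_sample", class(tibble::tibble())))
  expect_true(all(ceac(qii)$prob_cost_effective == 1))
  expect_true(all(ceac(qiv)$prob_cost_effective == 0))
  # ties count as not cost-effective
  tie <- structure(tibble::tibble(iter = 1L, delta_cost_eur = 0, delta_qaly = 0,
                                  quadrant = "indifferent"),
                   class = c("psa_sample", class(tibble::tibble())))
  expect_true(all(ceac(tie)$prob_cost_effective == 0))
})
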