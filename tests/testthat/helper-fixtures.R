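# shared fixtures: small matrices, specs and econ params built in code

STATES <- model_states()

# identity transition matrix on the 6-state space
identity_P <- function() diag(6)

# single-exit matrix: state mrs5 leaves to death with probability p,
# everything else stays put
single_exit_P <- function(p) {
  P <- diag(6)
  P[5, 5] <- 1 - p
  P[5, 6] <- p
  P
}

# a well-behaved (embeddable) recovery-flavoured matrix used across tests
recovery_P <- function() {
  matrix(c(
    0.88, 0.06, 0.03, 0.02, 0.00, 0.01,
    0.20, 0.65, 0.10, 0.03, 0.01, 0.01,
    0.08, 0.22, 0.55, 0.10, 0.03, 0.02,
    0.02, 0.08, 0.22, 0.55, 0.10, 0.03,
    0.01, 0.03, 0.08, 0.20, 0.63, 0.05,
    0,    0,    0,    0,    0,    1
  ), 6, 6, byrow = TRUE)
}

# an exactly embeddable 6-month matrix: the exponential of a valid generator
embeddable_P6 <- function() {
  Q <- matrix(c(
    -0.30, 0.15, 0.08, 0.04, 0.01, 0.02,
     0.50, -0.80, 0.20, 0.06, 0.02, 0.02,
     0.15, 0.55, -1.05, 0.25, 0.06, 0.04,
     0.04, 0.15, 0.55, -1.00, 0.20, 0.06,
     0.02, 0.06, 0.15, 0.50, -0.83, 0.10,
     0, 0, 0, 0, 0, 0
  ), 6, 6, byrow = TRUE)
  as.matrix(Matrix::expm(Matrix::Matrix(Q * 0.5)))
}

# generative spec with the same matrix on every interval
homogeneous_spec <- function(P, n = 200L, seed = 42L,
                             init = c(0.05, 0.1, 0.3, 0.35, 0.2, 0),
                             missingness = 0) {
  arm <- list(matrices = replicate(6, P, simplify = FALSE), init = init)
  generative_spec(
    arms = list(intervention = arm, comparator = arm),
    n_per_arm = c(intervention = n, comparator = n),
    seed = seed, missingness = missingness
  )
}

# minimal econ params with transparent round numbers
toy_econ <- function(...) {
  econ_params(
    cost_year1 = c(mrs02 = 12000, mrs3 = 8000, mrs4 = 16000, mrs5 = 24000),
    cost_year2 = c(mrs02 = 6000, mrs3 = 4000, mrs4 = 8000, mrs5 = 12000),
    utility = c(mrs0 = 0.9, mrs1 = 0.8, mrs2 = 0.7, mrs3 = 0.6,
                mrs4 = 0.4, mrs5 = 0.2),
    ...
  )
}

# constant-matrix cycle schedule
const_schedule <- function(P, arm = NULL) {
  cycle_schedule(replicate(8, P, simplify = FALSE), arm = arm)
}

# arm_result stub with given totals (for CEA logic tests)
arm_stub <- function(cost, qaly, arm = "x") {
  structure(list(total_cost_eur = cost, total_cost_usd = cost * 1.08,
                 total_qaly = qaly, arm = arm,
                 breakdown = tibble::tibble()),
            class = "arm_result")
}

# binomial standard error for a transition probability estimate
binom_se <- function(p, n) sqrt(pmax(p * (1 - p), 1e-12) / pmax(n, 1))
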