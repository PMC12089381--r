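test_that("transition matrix equals hand-tallied sliding-window counts", {
  s <- c(1, 1, 2, 2, 1, 2, 2, 2, 1, 1, 2, 1)   # 12-frame toy sequence
  m <- estimate_transition_matrix(s, 1)
  # hand count: from 1: 1->1 x2, 1->2 x3; from 2: 2->1 x3, 2->2 x3
  expect_equal(m$C, matrix(c(2, 3, 3, 3), 2, 2, byrow = TRUE))
  expect_equal(m$T, matrix(c(2 / 5, 3 / 5, 1 / 2, 1 / 2), 2, 2,
                           byrow = TRUE))
  expect_equal(rowSums(m$T), c(1, 1))
  # deterministic alternation
  alt <- estimate_transition_matrix(rep(1:2, 50), 1)
  expect_equal(alt$T, matrix(c(0, 1, 1, 0), 2, 2))
  expect_error(estimate_transition_matrix(c(1, 1, 1, 2), 1), "no outgoing")
})

test_that("estimator agrees with an independent cross-tabulation oracle", {
  set.seed(5)
  s <- sample(1:4, 5000, replace = TRUE,
              prob = c(0.4, 0.3, 0.2, 0.1))
  for (tau in c(1, 3, 10)) {
    m <- estimate_transition_matrix(s, tau)
    # oracle: base-R table on (s_t, s_{t+tau}) pairs
    n <- length(s)
    tab <- table(factor(s[1:(n - tau)], 1:4),
                 factor(s[(tau + 1):n], 1:4))
    oracle <- unclass(tab / rowSums(tab))
    expect_lt(max(abs(m$T - oracle)), 1e-12)
  }
})

test_that("first-order rates are T/tau with unit bookkeeping", {
  Tm <- matrix(c(0.8, 0.2, 0.3, 0.7), 2, 2, byrow = TRUE)
  model <- structure(list(T = Tm, tau = 10, n_states = 2), class = "phos_msm")
  k <- transition_rates(model)
  expect_equal(k[1, 2], 0.02)
  expect_true(is.na(k[1, 1]))
  model0 <- structure(list(T = Tm, tau = 0), class = "phos_msm")
  expect_error(transition_rates(model0), "positive")
})

test_that("rates from a known generator match the matrix-exponential oracle", {
  skip_if_not_installed("Matrix")
  K <- driven_cycle_rates(0, k0 = 0.02)
  gen <- generate_markov_cycle(K, 2e5, seed = 3)
  tau <- 5
  Q <- K; diag(Q) <- -rowSums(K)
  T_true <- as.matrix(Matrix::expm(Q * tau))
  m <- estimate_transition_matrix(as.integer(gen), tau)
  expect_lt(max(abs(m$T - T_true)), 0.01)
  k <- transition_rates(m)
  # first-order rates agree with the generator up to O(tau) error
  expect_lt(max(abs(k[cbind(1:4, c(2, 3, 4, 1))] -
                    K[cbind(1:4, c(2, 3, 4, 1))])), 0.01)
})

test_that("cycle affinity has the documented invariances and sign", {
  K <- driven_cycle_rates(-2 * RT300)      # ratio product e^2
  expect_equal(attr(generate_markov_cycle(K, 10, seed = 1), "affinity"),
               -2 * RT300)
  k <- K; diag(k) <- NA
  expect_equal(delta_mu_cycle(k, 300), -2 * RT300, tolerance = 1e-12)
  expect_equal(delta_mu_cycle(2 * k, 300), delta_mu_cycle(k, 300))
  # detailed-balanced rates: zero affinity
  kb <- driven_cycle_rates(0); diag(kb) <- NA
  expect_equal(delta_mu_cycle(kb, 300), 0)
  # zero rate on a cycle edge is an error with diagnostics
  k0 <- k; k0[2, 3] <- 0
  expect_error(delta_mu_cycle(k0), "cycle edge")
})

test_that("analytic-oracle pipeline recovers the stored affinity", {
  for (dmu in c(0, -2 * RT300, -5)) {
    K <- driven_cycle_rates(dmu, k0 = 0.05)
    gen <- generate_markov_cycle(K, 1e5, seed = 17)
    est <- estimate_dmu_cycle(as.integer(gen), tau = 2, n_boot = 30,
                              seed = 2)
    expect_lt(abs(est$value - attr(gen, "affinity")), 2 * max(est$sem, 0.05))
  }
})

test_that("implied timescales follow the eigenvalue closed form", {
  # symmetric 2-state chain: second eigenvalue 1 - 2p
  p <- 0.2
  Tm <- matrix(c(1 - p, p, p, 1 - p), 2, 2)
  ev <- eigen(Tm)$values
  model <- structure(list(T = Tm, tau = 3, eigenvalues = ev, n_states = 2),
                     class = "phos_msm")
  its <- implied_timescales(model)
  expect_equal(its$timescale, -3 / log(1 - 2 * p))
  # lambda = exp(-1) at tau = 1 gives t = 1
  m2 <- structure(list(T = diag(2), tau = 1,
                       eigenvalues = c(1, exp(-1)), n_states = 2),
                  class = "phos_msm")
  expect_equal(implied_timescales(m2)$timescale, 1)
  # negative eigenvalue: modulus used, flagged oscillatory
  m3 <- structure(list(T = diag(2), tau = 1,
                       eigenvalues = c(1, -0.5), n_states = 2),
                  class = "phos_msm")
  its3 <- implied_timescales(m3)
  expect_equal(its3$timescale, -1 / log(0.5))
  expect_true(its3$oscillatory)
})

test_that("CK test validates Markov data and flags a semi-Markov chain", {
  set.seed(8)
  # exact Markov chain
  Tm <- matrix(c(0.95, 0.05, 0.1, 0.9), 2, 2, byrow = TRUE)
  s <- integer(20000); s[1] <- 1
  for (i in 2:length(s)) s[i] <- sample(1:2, 1, prob = Tm[s[i - 1], ])
  ck <- ck_test(s, tau = 2, n_values = c(1, 2, 4), n_boot = 50)
  expect_gt(attr(ck, "pass"), 0.9)
  # n = 1: estimated equals predicted identically
  ck1 <- ck[ck$n == 1, ]
  expect_equal(ck1$estimated, ck1$predicted, tolerance = 1e-12)
  # semi-Markov counterexample: deterministic dwell of length 8 in state 1
  dwell <- 8
  s2 <- integer(0)
  while (length(s2) < 20000) {
    s2 <- c(s2, rep(1, dwell), rep(2, 1 + rgeom(1, 0.5)))
  }
  s2 <- s2[1:20000]
  ck2 <- ck_test(s2, tau = 2, n_values = c(1, 2, 4), n_boot = 50)
  expect_lt(attr(ck2, "pass"), attr(ck, "pass"))
  expect_lt(attr(ck2, "pass"), 0.85)
})

test_that("block bootstrap returns closed-form SEM for iid means", {
  set.seed(13)
  x <- rnorm(4000)
  bt <- bootstrap_observable(x + 10, mean, n_boot = 200, block_len = 10,
                             seed = 1)
  # SEM of the mean of n/block iid blocks ~ sd/sqrt(n)
  expect_lt(abs(bt$sem - sd(x) / sqrt(4000)) / (sd(x) / sqrt(4000)), 0.25)
  expect_equal(unname(bt$mean), mean(x) + 10, tolerance = 0.01)
  # constant estimator: zero SEM; single replicate: error
  expect_equal(bootstrap_observable(x, function(s) 42, n_boot = 5,
                                    block_len = 10)$sem, 0)
  expect_error(bootstrap_observable(x, mean, n_boot = 1, block_len = 10),
               "at least 2")
  expect_error(bootstrap_observable(1:5, mean, n_boot = 5, block_len = 10),
               "shorter")
})

test_that("two-state assignment recovers a telegraph process with TBSA", {
  set.seed(30)
  # telegraph distance trace: bound ~ 0.6 nm, unbound ~ 3 nm, with noise
  state <- integer(5000); state[1] <- 1
  for (i in 2:5000) state[i] <- if (runif(1) < 0.02) 3 - state[i - 1]
                                else state[i - 1]
  d <- ifelse(state == 1, 0.6, 3) + rnorm(5000, 0, 0.15)
  lab <- assign_two_states(d, cutoff = 1.5, soft_margin = 0.2)
  expect_gt(mean(lab == (state == 1)), 0.99)
  lab2 <- assign_two_states(matrix(d), method = "vamp_linear", lag = 5)
  expect_gt(mean(lab2 == (state == 1)), 0.99)
  # all-bound input refused
  expect_error(assign_two_states(rep(0.5, 100)), "single-state")
})

test_that("uncertain frames are relabeled by their firm neighbours", {
  # soft probability 0.5 sandwiched between firm bound frames -> bound
  p <- c(1, 1, 0.5, 1, 1)
  lab <- phosdyn:::tbsa_filter(p >= 0.5, p)
  expect_true(lab[3])
  # uncertain run between different firm states splits at the midpoint
  p2 <- c(1, 0.5, 0.5, 0.5, 0.5, 0)
  lab2 <- phosdyn:::tbsa_filter(p2 >= 0.5, p2)
  expect_equal(lab2, c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  # leading uncertain frames take the first firm state
  p3 <- c(0.5, 0.5, 0, 0)
  expect_equal(phosdyn:::tbsa_filter(p3 >= 0.5, p3), rep(FALSE, 4))
})

test_that("cycle-state mapping follows the bound/chemistry convention", {
  bound <- c(FALSE, TRUE, TRUE, FALSE)
  chem <- c(0, 0, 1, 1)
  expect_equal(as.integer(build_cycle_trajectory(bound, chem)), 1:4)
  expect_error(build_cycle_trajectory(c(TRUE, FALSE), 0), "length mismatch")
  # constant inputs give a constant state
  expect_equal(unique(as.integer(build_cycle_trajectory(rep(TRUE, 5),
                                                        rep(1, 5)))), 3L)
  # alternating binding at fixed Ser alternates 1 <-> 2
  alt <- build_cycle_trajectory(rep(c(FALSE, TRUE), 10), rep(0, 20))
  expect_equal(sort(unique(as.integer(alt))), 1:2)
})
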