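theta4 <- function(b = c(0.39, 0.53, 0.03, 0.0), t = c(0.5, 0.3, 0.2),
                   p_late = 0.6) spread_params(b, t, p_late)

test_that("node transition probability is the noisy-OR of incoming arcs", {
  g <- default_graph()
  th <- theta4()
  # no involved parents: base probability alone
  expect_equal(node_transition_prob("I", c(0, 0, 0, 0), th, g), 0.39)
  # one involved parent: 1 - (1 - b)(1 - t)
  th2 <- spread_params(c(0.1, 0.5, 0.1, 0.1), c(0.5, 0.2, 0.2), 0.5)
  expect_equal(node_transition_prob("II", c(1, 0, 0, 0), th2, g), 0.75)
  # zero base probability and healthy parents: cannot become involved
  th0 <- spread_params(c(0, 0.5, 0.5, 0.5), c(0.5, 0.5, 0.5), 0.5)
  expect_equal(node_transition_prob("I", c(0, 0, 0, 0), th0, g), 0)
  # involvement persists: asking about an involved level is a contract error
  expect_error(node_transition_prob("I", c(1, 0, 0, 0), th, g), "involved")
})

test_that("transition matrix has the product form with exact no-healing zeros", {
  g <- default_graph()
  th <- theta4()
  A <- transition_matrix(g, th)
  expect_equal(A["0000", "1000"], 0.39 * 0.47 * 0.97 * 1.0)
  expect_equal(A["1111", "1111"], 1)
  zero <- spread_params(rep(0, 4), rep(0, 3), 0.5)
  expect_equal(unname(transition_matrix(g, zero)), diag(16))
  expect_error(transition_matrix(g, replace(th, 1, 1.2)), "\\[0, 1\\]")

  bits <- enumerate_states(g)
  set.seed(42)
  for (i in 1:50) {
    A <- transition_matrix(g, random_theta(g))
    expect_lt(max(abs(rowSums(A) - 1)), 1e-12)
    for (x in c(1, 6, 16)) {
      healed <- bits[, bits[x, ] == 1, drop = FALSE]
      if (ncol(healed))
        expect_identical(unname(A[x, rowSums(healed) < sum(bits[x, ])]),
                         rep(0, sum(rowSums(healed) < sum(bits[x, ]))))
    }
  }
})

test_that("observation matrix factorises over levels", {
  g <- default_graph()
  B <- observation_matrix(observation_model(0.81, 0.63), g)
  expect_equal(B["0000", "0000"], 0.63^4)
  expect_lt(max(abs(rowSums(B) - 1)), 1e-12)
  perfect <- observation_matrix(observation_model(1, 1), g)
  expect_equal(unname(perfect), diag(16))
  # single involved level reads positive with the sensitivity
  g1 <- lnl_graph("A", list())
  B1 <- observation_matrix(observation_model(0.81, 0.63), g1)
  expect_equal(B1["1", "1"], 0.81)
})

test_that("binomial time prior has the stated pmf", {
  expect_equal(unname(binomial_time_prior(10, 0)$weights),
               c(1, rep(0, 10)))
  expect_equal(unname(binomial_time_prior(10, 1)$weights),
               c(rep(0, 10), 1))
  expect_equal(unname(binomial_time_prior(2, 0.5)$weights),
               c(0.25, 0.5, 0.25))
  expect_equal(sum(binomial_time_prior(7, 0.37)$weights), 1)
})

test_that("state distribution matches exhaustive trajectory enumeration", {
  g <- default_graph()
  th <- theta4()
  p0 <- state_distribution(th, 0, g)
  expect_equal(unname(p0), c(1, rep(0, 15)))
  A <- transition_matrix(g, th)
  expect_equal(state_distribution(th, 1, g), A["0000", ])

  toy <- toy_graphs()$chain2
  tv <- 0.35
  th2 <- spread_params(c(0.3, 0.2), tv, 0.5, toy$g)
  dist <- oracle_dist_at_times(c(0.3, 0.2), toy$arcs_fun(tv), 3)
  expect_equal(unname(state_distribution(th2, 3, toy$g)), dist[4, ],
               tolerance = 1e-12)
})

test_that("time-marginalised distribution is the prior-weighted mixture", {
  toy <- toy_graphs()$chain2
  th <- spread_params(c(0.3, 0.2), 0.35, 0.5, toy$g)
  # degenerate priors reduce to the fixed-time distributions
  expect_equal(
    marginal_state_distribution(th, "early", toy$g,
                                time_settings(t_max = 1, p_early = 0)),
    state_distribution(th, 0, toy$g))
  expect_equal(
    marginal_state_distribution(th, "early", toy$g,
                                time_settings(t_max = 1, p_early = 1)),
    state_distribution(th, 1, toy$g))
  # binomial(10, 0.3) mixture against the explicit weighted oracle
  w <- dbinom(0:10, 10, 0.3)
  dist <- oracle_dist_at_times(c(0.3, 0.2), toy$arcs_fun(0.35), 10)
  expect_equal(unname(marginal_state_distribution(th, "early", toy$g,
                                                  time_settings(10, 0.3))),
               as.vector(w %*% dist), tolerance = 1e-12)
  expect_equal(sum(marginal_state_distribution(th, "late", toy$g)), 1)
})

test_that("per-level occupancy never decreases with time", {
  g <- default_graph()
  bits <- enumerate_states(g)
  set.seed(7)
  for (i in 1:20) {
    th <- random_theta(g)
    occ <- sapply(0:8, function(t) {
      p <- state_distribution(th, t, g)
      as.vector(p %*% bits)
    })
    expect_true(all(diff(t(occ)) >= -1e-12))
  }
})

test_that("patient likelihood marginalises states, times and unknowns", {
  g <- default_graph()
  th <- theta4()
  perfect <- observation_model(1, 1)
  at0 <- time_settings(t_max = 1, p_early = 0)
  expect_equal(patient_likelihood(th, c(I = 0, II = 0, III = 0, IV = 0),
                                  "early", g, perfect, at0), 1)
  expect_equal(patient_likelihood(th, c(I = 0, II = 1, III = 0, IV = 0),
                                  "early", g, perfect, at0), 0)
  expect_equal(patient_likelihood(th, rep(NA, 4), "early", g), 1)

  toy <- toy_graphs()$chain2
  th2 <- spread_params(c(0.3, 0.2), 0.35, 0.5, toy$g)
  w <- dbinom(0:4, 4, 0.3)
  want <- oracle_patient_likelihood(c(0.3, 0.2), toy$arcs_fun(0.35), w,
                                    c(1, 0), 0.81, 0.63)
  expect_equal(patient_likelihood(th2, c(1, 0), "early", toy$g,
                                  observation_model(0.81, 0.63),
                                  time_settings(4, 0.3)),
               want, tolerance = 1e-12)
})

test_that("cohort log-likelihood is additive and guards the zero case", {
  g <- default_graph()
  th <- theta4(p_late = 0.6)
  expect_equal(cohort_log_likelihood(th, simulate_cohort(n_early = 3,
                                                         n_late = 0,
                                                         seed = 1)[0, ]), 0)
  cohort <- simulate_cohort(n_early = 6, n_late = 4, seed = 2)
  single <- cohort[3, , drop = FALSE]
  rep5 <- do.call(rbind, replicate(5, single, simplify = FALSE))
  rep5$patient_id <- paste0("D", 1:5)
  expect_equal(cohort_log_likelihood(th, rep5, g),
               5 * cohort_log_likelihood(th, single, g))
  per_patient <- sapply(seq_len(nrow(cohort)), function(i)
    log(patient_likelihood(th, unname(unlist(cohort[i, paste0("lvl_", g$levels)])),
                           cohort$stage_class[i], g)))
  expect_equal(cohort_log_likelihood(th, cohort, g), sum(per_patient),
               tolerance = 1e-12)
  # an impossible diagnosis yields -Inf, not an exception
  pos <- single
  pos[paste0("lvl_", g$levels)] <- c(1, 0, 0, 0)
  expect_identical(
    cohort_log_likelihood(th, pos, g, observation_model(1, 1),
                          time_settings(t_max = 1, p_early = 0)),
    -Inf)
})
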