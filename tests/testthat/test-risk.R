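test_that("state posterior is a normalised Bayes inversion", {
  g <- default_graph()
  set.seed(14)
  for (i in 1:50) {
    th <- random_theta(g)
    z <- sample(c(0L, 1L, NA_integer_), 4, replace = TRUE)
    post <- state_posterior(th, z, sample(c("early", "late"), 1), g)
    expect_lt(abs(sum(post) - 1), 1e-12)
    expect_true(all(post >= 0))
  }

  # perfect observation pins the posterior to the observed pattern
  th <- default_generator_theta()
  post <- state_posterior(th, c(I = 0, II = 1, III = 0, IV = 0), "early", g,
                          observation_model(1, 1))
  expect_equal(unname(post["0100"]), 1)

  # an uninformative test (sens = 1 - spec) returns the prior marginal
  g1 <- lnl_graph("A", list())
  th1 <- spread_params(0.3, p_late = 0.6, graph = g1)
  prior <- marginal_state_distribution(th1, "early", g1)
  for (z in 0:1)
    expect_equal(state_posterior(th1, z, "early", g1,
                                 observation_model(0.7, 0.3)),
                 prior, tolerance = 1e-12)

  # impossible diagnosis is signalled as undefined
  expect_error(state_posterior(spread_params(0, p_late = 0.5, graph = g1),
                               1, "early", g1, observation_model(1, 1),
                               time_settings(1, 0)),
               "undefined")
})

test_that("microscopic risk matches the exhaustive Bayes oracle", {
  toy <- toy_graphs()$chain2
  th <- spread_params(c(0.3, 0.2), 0.35, 0.5, toy$g)
  w <- dbinom(0:4, 4, 0.3)
  tc <- time_settings(4, 0.3)
  for (z in list(c(0, 0), c(1, 0), c(0, 1), c(NA, 1))) {
    for (lv in 1:2) {
      expect_equal(
        microscopic_risk(th, toy$g$levels[lv], z, "early", toy$g,
                         observation_model(0.81, 0.63), tc),
        oracle_risk(c(0.3, 0.2), toy$arcs_fun(0.35), w, z, 0.81, 0.63, lv),
        tolerance = 1e-10)
    }
  }
  # joint query: both levels involved simultaneously
  expect_equal(
    microscopic_risk(th, toy$g$levels, c(1, 0), "early", toy$g,
                     observation_model(0.81, 0.63), tc),
    oracle_risk(c(0.3, 0.2), toy$arcs_fun(0.35), w, c(1, 0), 0.81, 0.63,
                1:2),
    tolerance = 1e-10)
})

test_that("risk respects observed involvement and upstream conditioning", {
  g <- default_graph()
  th <- default_generator_theta()
  # a level seen positive under a perfect test is involved with certainty
  expect_equal(microscopic_risk(th, "II", c(I = 0, II = 1, III = 0, IV = 0),
                                "early", g, observation_model(1, 1)), 1)
  # seeing disease upstream raises the downstream risk
  set.seed(15)
  for (i in 1:20) {
    th_i <- random_theta(g, lo = 0.05, hi = 0.95)
    r_n0 <- microscopic_risk(th_i, "III", c(0, 0, 0, 0), "early", g)
    r_ii <- microscopic_risk(th_i, "III", c(0, 1, 0, 0), "early", g)
    expect_gt(r_ii, r_n0)
  }
  # a coin-flip test makes every diagnosis uninformative
  bits <- enumerate_states(g)
  prior_marg <- as.vector(marginal_state_distribution(th, "early", g) %*%
                            bits)
  flip <- observation_model(0.5, 0.5)
  for (z in list(c(0, 0, 0, 0), c(1, 1, 0, 0))) {
    risks <- sapply(g$levels, function(lv)
      microscopic_risk(th, lv, z, "early", g, flip))
    expect_equal(unname(risks), prior_marg, tolerance = 1e-12)
  }
})

test_that("Bayesian network risk matches brute-force BN enumeration", {
  toy <- toy_graphs()$chain2
  th <- spread_params(c(0.3, 0.2), 0.35, graph = toy$g)
  for (z in list(c(0, 0), c(1, 0), c(0, 1), c(1, 1), c(NA, 1))) {
    for (lv in 1:2) {
      expect_equal(
        bn_risk(th, toy$g$levels[lv], z, toy$g,
                observation_model(0.81, 0.63)),
        oracle_bn_risk(c(0.3, 0.2), toy$arcs_fun(0.35), z, 0.81, 0.63, lv),
        tolerance = 1e-10)
    }
  }
  # with no spread at all, a one-level N0 risk is exactly zero
  g1 <- lnl_graph("A", list())
  expect_equal(bn_risk(spread_params(0, graph = g1), "A", 0, g1), 0)
})

test_that("the BN is the one-step limit under the topological kernel", {
  g <- default_graph()
  set.seed(16)
  point1 <- time_settings(t_max = 1, p_early = 1)
  for (i in 1:10) {
    th <- random_theta(g, lo = 0.05, hi = 0.95)
    th["p_late"] <- 1
    expect_equal(unname(state_distribution(th, 1, g, order = "topological")),
                 unname(bn_state_prior(g, th)), tolerance = 1e-12)
    z <- sample(0:1, 4, replace = TRUE)
    for (lv in g$levels) {
      expect_equal(
        microscopic_risk(th, lv, z, "early", g, time = point1,
                         order = "topological"),
        bn_risk(th, lv, z, g), tolerance = 1e-10)
    }
  }
  # the parallel kernel does NOT reproduce the BN once inter-level spread
  # is active: the within-step cascade is what the BN encodes
  th <- default_generator_theta()
  th["p_late"] <- 1
  r_par <- microscopic_risk(th, "III", c(0, 1, 0, 0), "early", g,
                            time = point1)
  expect_gt(abs(r_par - bn_risk(th, "III", c(0, 1, 0, 0), g)), 1e-3)
})

test_that("risk tables evaluate queries per draw with summaries", {
  g <- default_graph()
  th <- default_generator_theta()
  queries <- canonical_queries(g, stage = "early")
  expect_equal(nrow(queries), 16)

  one <- matrix(th, nrow = 1, dimnames = list(NULL, names(th)))
  rt1 <- risk_table(one, queries[queries$level == "III", ])
  direct <- sapply(which(queries$level == "III"), function(q)
    microscopic_risk(th, "III", queries$diagnosis[[q]], "early", g))
  expect_equal(rt1$mean, unname(direct))
  expect_true(all(is.na(rt1$sd)))  # spread undefined from one draw
  expect_equal(rt1$q16, rt1$mean)

  two <- rbind(one, one)
  rt2 <- risk_table(two, queries[1:2, ])
  expect_length(rt2$draws[[1]], 2)
  expect_equal(rt2$draws[[1]][1], rt2$draws[[1]][2])
  expect_equal(rt2$mean[1], rt2$draws[[1]][1])
  expect_true(all(rt2$mean >= 0 & rt2$mean <= 1))
})
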