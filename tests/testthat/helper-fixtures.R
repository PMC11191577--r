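# Shared fixtures, built once per test run. The 108-patient cohort mirrors
# the default study composition (66 early / 42 late at the default
# generating parameters); the shared fit uses a short but converged chain
# so several files can interrogate the same posterior.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, build(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

shared_cohort108 <- function() {
  fixture("cohort108", function()
    simulate_cohort(default_generator_theta(), n_early = 66, n_late = 42,
                    seed = 5))
}

shared_fit108 <- function() {
  fixture("fit108", function()
    lymph_hmm(shared_cohort108(), n_steps = 200, burn_in = 150, thin = 8,
              seed = 5))
}

thin_draws <- function(samples, n) {
  draws <- if (inherits(samples, "posterior_samples")) samples$draws
           else samples
  draws[unique(round(seq(1, nrow(draws), length.out = n))), , drop = FALSE]
}

random_theta <- function(graph, lo = 0, hi = 1) {
  spread_params(b = runif(length(graph$levels), lo, hi),
                t = runif(nrow(graph$arcs), lo, hi),
                p_late = runif(1, lo, hi), graph = graph)
}
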