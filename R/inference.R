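#' Log prior over spread parameters
#'
#' Uniform over the unit hypercube: 0 when every component lies in
#' `[0, 1]` (boundaries included), `-Inf` otherwise. With no further prior
#' information the posterior is shaped by the cohort likelihood alone.
#'
#' @param theta Numeric parameter vector.
#' @return 0 or `-Inf`.
#' @export
log_prior <- function(theta) {
  if (anyNA(theta) || any(theta < 0) || any(theta > 1)) -Inf else 0
}

#' Sample the posterior over spread parameters
#'
#' Draws from `p(theta | cohort)` with the affine-invariant ensemble
#' ("stretch move") sampler: an ensemble of walkers is evolved jointly, each
#' walker proposing a move along the line through itself and a randomly
#' chosen companion from the complementary half of the ensemble. The method
#' is invariant under affine reparameterisation and needs no proposal-scale
#' tuning beyond the single stretch parameter `a`.
#'
#' For the default model the parameter vector is
#' `(b_1..b_V, t_rs per arc, p_late)`; `model = "bn"` drops the time
#' parameter and targets the one-pass Bayesian network likelihood instead.
#'
#' @param cohort Cohort table (see [simulate_cohort()] / [read_cohort()]).
#' @param graph An `lnl_graph`.
#' @param obs An [observation_model()].
#' @param time [time_settings()].
#' @param model `"hmm"` (default) or `"bn"`.
#' @param n_walkers Ensemble size; default 6 per parameter (minimum 2 per
#'   parameter plus 2 for an ergodic stretch move).
#' @param n_steps Post burn-in ensemble steps to retain.
#' @param burn_in Ensemble steps discarded before retention.
#' @param thin Keep every `thin`-th retained step.
#' @param seed Integer seed; the run is fully reproducible given it.
#' @param a Stretch scale (> 1).
#' @param init_range Walkers start uniform in this interval per coordinate,
#'   away from the prior boundary.
#' @return Object of class `posterior_samples`: list with `draws`
#'   (`n_samples x n_parameters` matrix, columns named), `parameter_names`,
#'   and `meta` (seed, walkers, steps, burn-in, thinning, acceptance
#'   fraction, integrated autocorrelation time per parameter).
#' @export
sample_posterior <- function(cohort, graph = default_graph(),
                             obs = observation_model(),
                             time = time_settings(),
                             model = c("hmm", "bn"),
                             n_walkers = NULL, n_steps = 600, burn_in = 300,
                             thin = 1, seed = 1, a = 2,
                             init_range = c(0.1, 0.9)) {
  model <- match.arg(model)
  if (nrow(cohort) < 1L) stop("empty cohort: at least one patient is required")
  pnames <- param_names(graph, time_param = model == "hmm")
  d <- length(pnames)
  if (is.null(n_walkers)) n_walkers <- max(2L * d + 2L, 6L * d)
  if (n_walkers < 2L * d + 2L || n_walkers %% 2L != 0L)
    stop("n_walkers must be even and at least 2 * n_parameters + 2")
  loglik <- make_cohort_loglik(cohort, graph, obs, time, model = model)
  logpost <- function(th) {
    lp <- log_prior(th)
    if (!is.finite(lp)) return(-Inf)
    names(th) <- pnames
    lp + loglik(th)
  }

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  walkers <- matrix(stats::runif(n_walkers * d, init_range[1], init_range[2]),
                    n_walkers, d)
  lp <- apply(walkers, 1L, logpost)
  if (all(!is.finite(lp)))
    stop("no walker initialization has finite posterior probability; ",
         "the cohort may contain zero-likelihood patients")

  n_total <- burn_in + n_steps
  keep_steps <- seq.int(burn_in + thin, n_total, by = thin)
  kept <- array(NA_real_, c(length(keep_steps), n_walkers, d))
  chain_mean <- matrix(NA_real_, n_total, d)  # for autocorrelation estimate
  accepted <- 0L
  half <- n_walkers / 2L
  sets <- list(seq_len(half), half + seq_len(half))
  ki <- 0L
  for (step in seq_len(n_total)) {
    for (h in 1:2) {
      idx <- sets[[h]]
      other <- sets[[3L - h]]
      partners <- other[sample.int(half, half, replace = TRUE)]
      z <- ((a - 1) * stats::runif(half) + 1)^2 / a
      prop <- walkers[partners, , drop = FALSE] +
        z * (walkers[idx, , drop = FALSE] - walkers[partners, , drop = FALSE])
      lp_prop <- apply(prop, 1L, logpost)
      log_ratio <- (d - 1) * log(z) + lp_prop - lp[idx]
      acc <- log(stats::runif(half)) < log_ratio
      acc[!is.finite(lp_prop)] <- FALSE
      walkers[idx[acc], ] <- prop[acc, , drop = FALSE]
      lp[idx[acc]] <- lp_prop[acc]
      accepted <- accepted + sum(acc)
    }
    chain_mean[step, ] <- colMeans(walkers)
    if (step %in% keep_steps) {
      ki <- ki + 1L
      kept[ki, , ] <- walkers
    }
  }
  draws <- matrix(aperm(kept, c(2L, 1L, 3L)),
                  nrow = length(keep_steps) * n_walkers, ncol = d)
  colnames(draws) <- pnames
  iact <- apply(chain_mean[-seq_len(burn_in), , drop = FALSE], 2L, iact_sokal)
  structure(
    list(draws = draws, parameter_names = pnames,
         meta = list(seed = seed, n_walkers = n_walkers, n_steps = n_steps,
                     burn_in = burn_in, thin = thin, model = model,
                     acceptance = accepted / (n_total * n_walkers),
                     iact = stats::setNames(iact, pnames))),
    class = "posterior_samples"
  )
}

# Integrated autocorrelation time with Sokal's adaptive window (c = 5).
iact_sokal <- function(x, c = 5) {
  n <- length(x)
  x <- x - mean(x)
  if (stats::sd(x) == 0 || n < 10L) return(NA_real_)
  acf_est <- stats::acf(x, lag.max = min(n - 1L, 10L * floor(sqrt(n))),
                        plot = FALSE, demean = FALSE)$acf[, 1L, 1L]
  tau <- 2 * cumsum(acf_est) - 1
  window <- which(seq_along(tau) - 1L >= c * tau)
  if (length(window) == 0L) return(tau[length(tau)])
  tau[window[1L]]
}

posterior_draws <- function(samples) {
  if (inherits(samples, "posterior_samples")) return(samples$draws)
  if (is.matrix(samples)) return(samples)
  if (is.data.frame(samples)) return(as.matrix(samples))
  stop("samples must be a posterior_samples object or a draws matrix")
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat("Posterior samples:", nrow(x$draws), "draws of",
      ncol(x$draws), "parameters\n")
  cat("  model:", x$meta$model,
      " walkers:", x$meta$n_walkers,
      " acceptance:", sprintf("%.2f", x$meta$acceptance), "\n")
  print(summarize_posterior(x), digits = 3)
  invisible(x)
}

#' Posterior summary table
#'
#' Mean, standard deviation and the 16th/84th percentile interval of every
#' parameter's marginal posterior (the one-sigma-equivalent asymmetric
#' interval conventionally quoted for these spread probabilities).
#'
#' @param samples A `posterior_samples` object or draws matrix.
#' @return Data frame with one row per parameter and columns `mean`, `sd`,
#'   `q16`, `q84`.
#' @export
summarize_posterior <- function(samples) {
  draws <- posterior_draws(samples)
  if (nrow(draws) < 2L) stop("need at least two draws to summarize")
  data.frame(
    parameter = colnames(draws),
    mean = colMeans(draws),
    sd = apply(draws, 2L, stats::sd),
    q16 = apply(draws, 2L, stats::quantile, probs = 0.16, names = FALSE),
    q84 = apply(draws, 2L, stats::quantile, probs = 0.84, names = FALSE),
    row.names = NULL
  )
}

#' Pairwise posterior parameter correlations
#'
#' Pearson correlations between the marginal draws of every parameter pair;
#' a parameter with zero posterior variance yields `NA` entries (undefined,
#' not zero) off the diagonal.
#'
#' @param samples A `posterior_samples` object or draws matrix (>= 3 draws).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
parameter_correlations <- function(samples) {
  draws <- posterior_draws(samples)
  if (nrow(draws) < 3L) stop("need at least three draws")
  sds <- apply(draws, 2L, stats::sd)
  cc <- suppressWarnings(stats::cor(draws))
  cc[sds == 0, ] <- NA_real_
  cc[, sds == 0] <- NA_real_
  diag(cc) <- 1
  cc
}
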