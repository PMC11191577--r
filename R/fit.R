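#' Fit the lymphatic progression model
#'
#' The main entry point: learns the posterior over per-arc spread
#' probabilities (and the late-stage time parameter) from a cohort of
#' per-level imaging diagnoses via MCMC, and returns a fitted-model object
#' whose methods answer the clinical question -- how likely is occult
#' involvement of each lymph node level, given what was seen on imaging and
#' the T-stage?
#'
#' @param cohort Cohort table with one row per patient: `t_stage` (1-4) and
#'   a 0/1/NA diagnosis per level in columns `lvl_<level>`; see
#'   [read_cohort()] for the CSV schema or [simulate_cohort()] for
#'   synthetic cohorts.
#' @param graph Lymphatic drainage graph, default the I-II-III-IV chain.
#' @param sensitivity,specificity Fixed imaging operating point (MRI
#'   defaults 0.81 / 0.63; these are not learned).
#' @param t_max,p_early Temporal settings, see [time_settings()].
#' @param model `"hmm"` (default) or `"bn"` for the one-pass
#'   Bayesian-network variant.
#' @param seed Integer seed making the fit reproducible.
#' @param ... Sampler settings forwarded to [sample_posterior()].
#' @return Object of class `lymph_hmm` with methods `print`, `summary`,
#'   `coef` (posterior means), `predict` (occult-involvement risk),
#'   `simulate`, `plot`, `residuals` and `logLik`.
#' @examples
#' cohort <- simulate_cohort(n_early = 40, n_late = 25, seed = 3)
#' fit <- lymph_hmm(cohort, n_steps = 80, burn_in = 40, seed = 3)
#' coef(fit)
#' predict(fit, diagnosis = c(I = 0, II = 1, III = 0, IV = 0),
#'         stage = "early")
#' @export
lymph_hmm <- function(cohort, graph = default_graph(),
                      sensitivity = 0.81, specificity = 0.63,
                      t_max = 10, p_early = 0.3,
                      model = c("hmm", "bn"), seed = 1, ...) {
  model <- match.arg(model)
  cohort <- validate_cohort(cohort, graph)
  obs <- observation_model(sensitivity, specificity)
  time <- time_settings(t_max, p_early)
  samples <- sample_posterior(cohort, graph, obs, time, model = model,
                              seed = seed, ...)
  theta_hat <- colMeans(samples$draws)
  ll <- if (model == "hmm") {
    cohort_log_likelihood(theta_hat, cohort, graph, obs, time)
  } else {
    make_cohort_loglik(cohort, graph, obs, time, model = "bn")(theta_hat)
  }
  structure(
    list(call = match.call(), graph = graph, obs = obs, time = time,
         model = model, samples = samples, n_patients = nrow(cohort),
         stage_counts = table(cohort_stage(cohort)),
         cohort = cohort, loglik = ll, seed = seed),
    class = "lymph_hmm"
  )
}

#' @export
print.lymph_hmm <- function(x, ...) {
  cat("Lymphatic progression model (",
      if (x$model == "hmm") "hidden Markov" else "Bayesian network",
      ")\n", sep = "")
  cat("  cohort:", x$n_patients, "patients (",
      x$stage_counts[["early"]], "early /",
      x$stage_counts[["late"]], "late )\n")
  cat("  log-likelihood at posterior mean:", sprintf("%.2f", x$loglik), "\n")
  cat("  posterior means:\n")
  print(round(coef(x), 3))
  invisible(x)
}

#' @export
coef.lymph_hmm <- function(object, ...) colMeans(object$samples$draws)

#' @export
logLik.lymph_hmm <- function(object, ...) {
  structure(object$loglik, df = ncol(object$samples$draws),
            nobs = object$n_patients, class = "logLik")
}

#' @export
summary.lymph_hmm <- function(object, ...) {
  out <- list(
    model = object$model,
    n_patients = object$n_patients,
    stage_counts = object$stage_counts,
    posterior = summarize_posterior(object$samples),
    correlations = parameter_correlations(object$samples),
    acceptance = object$samples$meta$acceptance,
    iact = object$samples$meta$iact,
    loglik = object$loglik
  )
  class(out) <- "summary.lymph_hmm"
  out
}

#' @export
print.summary.lymph_hmm <- function(x, ...) {
  cat("Lymphatic progression model --", x$n_patients, "patients,",
      "log-likelihood", sprintf("%.2f", x$loglik), "\n\n")
  cat("Posterior marginals (mean, sd, 16th/84th percentiles):\n")
  print(x$posterior, digits = 3, row.names = FALSE)
  cat("\nSampler: acceptance", sprintf("%.2f", x$acceptance),
      "; max integrated autocorrelation time",
      sprintf("%.1f", max(x$iact, na.rm = TRUE)), "steps\n")
  off <- abs(x$correlations)
  diag(off) <- 0
  i <- which(off == max(off, na.rm = TRUE), arr.ind = TRUE)[1L, ]
  cat("Strongest parameter correlation:",
      rownames(x$correlations)[i[1L]], "~",
      colnames(x$correlations)[i[2L]],
      sprintf("(%.2f)\n", x$correlations[i[1L], i[2L]]))
  invisible(x)
}

#' Predict occult-involvement risk from a fitted model
#'
#' @param object A fitted `lymph_hmm`.
#' @param diagnosis Observed per-level status 0/1/NA (named by level or in
#'   graph order).
#' @param stage `"early"` or `"late"`.
#' @param level Level label(s) to query; default every level separately.
#'   A character vector element containing `+` (e.g. `"I+II"`) queries
#'   joint involvement of the listed levels.
#' @param type `"mean"` for posterior-mean risks, `"draws"` for the full
#'   per-draw risk distribution (one column per query).
#' @param ... Unused.
#' @return Named numeric vector of risks (`type = "mean"`) or a matrix of
#'   per-draw risks (`type = "draws"`).
#' @export
predict.lymph_hmm <- function(object, diagnosis, stage = "early",
                              level = object$graph$levels,
                              type = c("mean", "draws"), ...) {
  type <- match.arg(type)
  z <- parse_query_diagnosis(diagnosis, object$graph)
  draws <- object$samples$draws
  risk_fun <- function(th, lv) {
    if (object$model == "bn") {
      bn_risk(th, lv, z, object$graph, object$obs)
    } else {
      microscopic_risk(th, lv, z, stage, object$graph, object$obs,
                       object$time)
    }
  }
  res <- sapply(level, function(lab) {
    lv <- strsplit(lab, "\\+")[[1]]
    apply(draws, 1L, risk_fun, lv = lv)
  })
  res <- matrix(res, nrow = nrow(draws), dimnames = list(NULL, level))
  if (type == "draws") res else colMeans(res)
}

#' Simulate cohorts from a fitted model
#'
#' Draws synthetic cohorts at the posterior-mean parameters, with the same
#' stage mix as the training cohort by default.
#'
#' @param object A fitted `lymph_hmm` (HMM variant).
#' @param nsim Number of cohorts.
#' @param seed Integer seed.
#' @param n_early,n_late Cohort composition; defaults mirror the training
#'   cohort.
#' @param ... Unused.
#' @return A list of `nsim` cohort tables (a single table when
#'   `nsim = 1`).
#' @export
simulate.lymph_hmm <- function(object, nsim = 1, seed = 1,
                               n_early = object$stage_counts[["early"]],
                               n_late = object$stage_counts[["late"]], ...) {
  if (object$model != "hmm")
    stop("cohort simulation requires the time-resolved (hmm) model")
  theta_hat <- coef(object)
  out <- lapply(seq_len(nsim), function(i)
    simulate_cohort(theta_hat, n_early, n_late, seed = seed + i - 1L,
                    graph = object$graph, obs = object$obs,
                    time = object$time))
  if (nsim == 1L) out[[1L]] else out
}

#' Pattern-frequency residuals
#'
#' Observed minus model-predicted frequency of every complete diagnosis
#' pattern in the training cohort (at the posterior-mean parameters,
#' stage-mixed as in the cohort): a coarse goodness-of-fit diagnostic on
#' the observable scale.
#'
#' @param object A fitted `lymph_hmm`.
#' @param ... Unused.
#' @return Data frame with `pattern`, `observed`, `predicted`, `residual`.
#' @export
residuals.lymph_hmm <- function(object, ...) {
  theta_hat <- coef(object)
  B <- observation_matrix(object$obs, object$graph)
  stage <- cohort_stage(object$cohort)
  w_early <- mean(stage == "early")
  pred <- w_early * as.vector(
    marginal_state_distribution(theta_hat, "early", object$graph,
                                object$time) %*% B)
  if (w_early < 1)
    pred <- pred + (1 - w_early) * as.vector(
      marginal_state_distribution(theta_hat, "late", object$graph,
                                  object$time) %*% B)
  Z <- cohort_diagnosis_matrix(object$cohort, object$graph)
  obs_pat <- apply(Z, 1L, paste0, collapse = "")
  observed <- as.vector(table(factor(obs_pat, levels = colnames(B)))) /
    nrow(object$cohort)
  data.frame(pattern = colnames(B), observed = observed, predicted = pred,
             residual = observed - pred, row.names = NULL)
}

#' Plot posterior marginals of a fitted model
#'
#' One histogram per parameter (base graphics), the visual summary usually
#' shown on the diagonal of a corner plot.
#'
#' @param x A fitted `lymph_hmm`.
#' @param ... Passed to [graphics::hist()].
#' @export
plot.lymph_hmm <- function(x, ...) {
  draws <- x$samples$draws
  d <- ncol(draws)
  op <- graphics::par(mfrow = c(ceiling(d / 3), 3), mar = c(4, 3, 2, 1))
  on.exit(graphics::par(op))
  for (j in seq_len(d)) {
    graphics::hist(draws[, j], breaks = 30, main = colnames(draws)[j],
                   xlab = "", xlim = c(0, 1), col = "grey70", border = NA,
                   ...)
    graphics::abline(v = mean(draws[, j]), lwd = 2)
  }
  invisible(x)
}
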