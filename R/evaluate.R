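#' Threefold cross-validation
#'
#' Splits the cohort at random into three near-equal folds (stratified by
#' stage class so each fold preserves the early/late mix), fits the model on
#' every pair of folds, and evaluates the held-out fold's log-likelihood at
#' the training posterior mean. The full cohort is fitted as well and its
#' whole-dataset log-likelihood reported.
#'
#' @param cohort Cohort table.
#' @param graph An `lnl_graph`.
#' @param obs An [observation_model()].
#' @param time [time_settings()].
#' @param seed Integer seed controlling both the fold assignment and the
#'   per-fold samplers (sub-seeds are derived deterministically).
#' @param ... Sampler settings forwarded to [sample_posterior()]
#'   (`n_walkers`, `n_steps`, `burn_in`, ...).
#' @return Object of class `cv_report`: list with `folds` (assignment
#'   vector), `fits` (per-fold posterior summaries), `heldout_loglik`,
#'   `train_loglik_per_patient`, `full_fit` and `full_loglik`.
#' @export
threefold_cv <- function(cohort, graph = default_graph(),
                         obs = observation_model(), time = time_settings(),
                         seed = 1, ...) {
  if (nrow(cohort) < 3L) stop("cohort must contain at least 3 patients")
  folds <- assign_folds(cohort, k = 3L, seed = seed)
  if (any(tabulate(folds, 3L) == 0L)) stop("empty cross-validation fold")
  fits <- vector("list", 3L)
  heldout <- train_ll <- numeric(3L)
  for (f in 1:3) {
    train <- cohort[folds != f, , drop = FALSE]
    test <- cohort[folds == f, , drop = FALSE]
    samples <- sample_posterior(train, graph, obs, time,
                                seed = seed + f, ...)
    theta_hat <- colMeans(samples$draws)
    fits[[f]] <- summarize_posterior(samples)
    heldout[f] <- cohort_log_likelihood(theta_hat, test, graph, obs, time)
    train_ll[f] <- cohort_log_likelihood(theta_hat, train, graph, obs, time)
  }
  full <- sample_posterior(cohort, graph, obs, time, seed = seed, ...)
  theta_full <- colMeans(full$draws)
  structure(
    list(folds = folds,
         fold_sizes = tabulate(folds, 3L),
         fits = fits,
         heldout_loglik = heldout,
         heldout_n = tabulate(folds, 3L),
         train_loglik_per_patient = train_ll / (nrow(cohort) - tabulate(folds, 3L)),
         full_fit = summarize_posterior(full),
         full_samples = full,
         full_loglik = cohort_log_likelihood(theta_full, cohort, graph,
                                             obs, time)),
    class = "cv_report"
  )
}

# stage-stratified near-equal partition; extras go to the currently
# smallest folds so total sizes differ by at most one
assign_folds <- function(cohort, k = 3L, seed = 1) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  folds <- integer(nrow(cohort))
  sizes <- integer(k)
  for (s in unique(cohort_stage(cohort))) {
    idx <- which(cohort_stage(cohort) == s)
    idx <- idx[sample.int(length(idx))]
    base <- length(idx) %/% k
    extra <- length(idx) %% k
    take <- rep(base, k)
    if (extra > 0L) {
      receivers <- order(sizes, seq_len(k))[seq_len(extra)]
      take[receivers] <- take[receivers] + 1L
    }
    pos <- 1L
    for (f in seq_len(k)) {
      if (take[f] > 0L) {
        folds[idx[pos:(pos + take[f] - 1L)]] <- f
        pos <- pos + take[f]
      }
      sizes[f] <- sizes[f] + take[f]
    }
  }
  folds
}

#' @export
print.cv_report <- function(x, ...) {
  cat("Threefold cross-validation\n")
  cat("  fold sizes:", paste(x$fold_sizes, collapse = "/"), "\n")
  cat("  held-out log-likelihood:",
      paste(sprintf("%.2f", x$heldout_loglik), collapse = ", "), "\n")
  cat("  whole-dataset log-likelihood:",
      sprintf("%.2f", x$full_loglik), "\n")
  invisible(x)
}

#' Beta distribution from an observed prevalence
#'
#' Conjugate posterior of a proportion under a uniform prior: `k` positives
#' out of `n` give `Beta(k + 1, n - k + 1)`. Used as the data-driven
#' reference against which model-predicted pattern probabilities are
#' compared.
#'
#' @param k Number of positives (0 <= k <= n).
#' @param n Total count.
#' @return Named numeric vector `c(alpha, beta)`.
#' @export
prevalence_beta <- function(k, n) {
  stopifnot(k >= 0, n >= 0, k <= n)
  c(alpha = k + 1, beta = n - k + 1)
}

#' Predicted pattern probability versus cohort prevalence
#'
#' For each complete diagnosis pattern, compares the model-predicted
#' probability of observing that pattern in a random cohort member (per
#' posterior draw, mixing the stage-specific predictions with the cohort's
#' stage proportions) with the beta distribution implied by the pattern's
#' prevalence in the cohort. The comparison is on observable quantities, so
#' model and data are measured on the same scale.
#'
#' @param samples `posterior_samples` or draws matrix.
#' @param cohort Cohort table the prevalences are computed from.
#' @param patterns Character vector of diagnosis patterns over levels in
#'   graph order (e.g. `"0100"`); defaults to every pattern observed in the
#'   cohort.
#' @inheritParams threefold_cv
#' @return List, one element per pattern: `draws` (predicted probability per
#'   posterior draw), `alpha`, `beta`, `k`, `n`.
#' @export
predicted_vs_prevalence <- function(samples, cohort, patterns = NULL,
                                    graph = default_graph(),
                                    obs = observation_model(),
                                    time = time_settings()) {
  draws <- posterior_draws(samples)
  Z <- cohort_diagnosis_matrix(cohort, graph)
  observed_patterns <- apply(Z, 1L, paste0, collapse = "")
  if (is.null(patterns)) patterns <- sort(unique(observed_patterns))
  stage <- cohort_stage(cohort)
  w_early <- mean(stage == "early")
  B <- observation_matrix(obs, graph)
  n <- nrow(cohort)
  out <- vector("list", length(patterns))
  names(out) <- patterns
  # predicted P(pattern) per draw: stage-mixture of pi_stage %*% B
  pred <- matrix(0, nrow(draws), 2L^length(graph$levels))
  for (i in seq_len(nrow(draws))) {
    th <- draws[i, ]
    p_obs <- w_early *
      as.vector(marginal_state_distribution(th, "early", graph, time) %*% B)
    if (w_early < 1)
      p_obs <- p_obs + (1 - w_early) *
        as.vector(marginal_state_distribution(th, "late", graph, time) %*% B)
    pred[i, ] <- p_obs
  }
  colnames(pred) <- colnames(B)
  for (pat in patterns) {
    if (!pat %in% colnames(pred)) stop("unknown pattern: ", pat)
    k <- sum(observed_patterns == pat)
    ab <- prevalence_beta(k, n)
    out[[pat]] <- list(draws = pred[, pat], alpha = unname(ab["alpha"]),
                       beta = unname(ab["beta"]), k = k, n = n)
  }
  out
}

#' Compare HMM and Bayesian-network risk distributions
#'
#' Evaluates each query's risk at every draw of both sample sets and
#' summarises how close the two risk histograms are: mean difference and
#' the overlap coefficient (integral of the pointwise minimum of the two
#' normalised histograms on a shared 100-bin grid over `[0, 1]`).
#'
#' @param samples_hmm Posterior samples for the progression HMM.
#' @param samples_bn Posterior samples for the one-pass Bayesian network
#'   (no `p_late` column needed).
#' @param queries Query data frame as in [risk_table()].
#' @inheritParams risk_table
#' @param order Within-step update schedule for the HMM risks, see
#'   [transition_matrix()]; `"topological"` with a point-mass-at-one time
#'   prior makes the two models coincide exactly.
#' @return Data frame with one row per query: `mean_hmm`, `mean_bn`,
#'   `mean_diff`, `overlap`.
#' @export
compare_bn_hmm <- function(samples_hmm, samples_bn, queries,
                           graph = default_graph(),
                           obs = observation_model(),
                           time = time_settings(),
                           order = "parallel") {
  dh <- posterior_draws(samples_hmm)
  db <- posterior_draws(samples_bn)
  if (nrow(dh) == 0L || nrow(db) == 0L)
    stop("both sample sets must be non-empty")
  out <- queries
  out$mean_hmm <- out$mean_bn <- out$mean_diff <- out$overlap <- NA_real_
  for (q in seq_len(nrow(queries))) {
    lv <- strsplit(as.character(queries$level[q]), "\\+")[[1]]
    z <- parse_query_diagnosis(queries$diagnosis[[q]], graph)
    st <- as.character(queries$stage[q])
    r_hmm <- apply(dh, 1L, function(th)
      microscopic_risk(th, lv, z, st, graph, obs, time, order = order))
    r_bn <- apply(db, 1L, function(th) bn_risk(th, lv, z, graph, obs))
    out$mean_hmm[q] <- mean(r_hmm)
    out$mean_bn[q] <- mean(r_bn)
    out$mean_diff[q] <- mean(r_hmm) - mean(r_bn)
    out$overlap[q] <- histogram_overlap(r_hmm, r_bn)
  }
  out
}

#' Overlap coefficient of two samples on [0, 1]
#'
#' Bins both samples on a shared 100-bin grid over the unit interval,
#' normalises each histogram to total mass one, and returns the sum of the
#' binwise minima: 1 for identical distributions, 0 for disjoint support.
#'
#' @param x,y Numeric samples in `[0, 1]`.
#' @param bins Number of bins.
#' @return Overlap coefficient in `[0, 1]`.
#' @export
histogram_overlap <- function(x, y, bins = 100L) {
  breaks <- seq(0, 1, length.out = bins + 1L)
  hx <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE,
                              all.inside = TRUE), bins)
  hy <- tabulate(findInterval(y, breaks, rightmost.closed = TRUE,
                              all.inside = TRUE), bins)
  sum(pmin(hx / sum(hx), hy / sum(hy)))
}
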