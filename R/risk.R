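#' Posterior over hidden states given a diagnosis
#'
#' Bayes inversion of the observation model against the time-marginalised
#' state distribution: `P(x | z)` proportional to `P(z | x) P(x)`. This is
#' the quantity that turns an imaging read into a statement about occult
#' disease.
#'
#' @inheritParams patient_likelihood
#' @return Probability vector over the `2^V` states (sums to 1).
#' @export
state_posterior <- function(theta, diagnosis, stage = "early",
                            graph = default_graph(),
                            obs = observation_model(),
                            time = time_settings(),
                            prior = NULL, order = "parallel") {
  pi_m <- marginal_state_distribution(theta, stage, graph, time, prior, order)
  f <- diagnosis_likelihoods(diagnosis, obs, graph)
  w <- pi_m * f
  tot <- sum(w)
  if (tot <= 0)
    stop("diagnosis has probability zero under these parameters; ",
         "the state posterior is undefined")
  w / tot
}

#' Risk of occult involvement of one or more levels
#'
#' Posterior probability that the named level(s) are truly involved --
#' including microscopic disease invisible to imaging -- given the observed
#' diagnosis pattern and T-stage class. With several levels the joint risk
#' (all of them involved simultaneously) is returned.
#'
#' @param level Level label, or vector of labels for a joint query.
#' @inheritParams state_posterior
#' @return A probability.
#' @examples
#' theta <- spread_params(c(0.39, 0.53, 0.03, 0.01), c(0.5, 0.3, 0.2), 0.6)
#' microscopic_risk(theta, "III",
#'                  diagnosis = c(I = 0, II = 1, III = 0, IV = 0),
#'                  stage = "early")
#' @export
microscopic_risk <- function(theta, level, diagnosis, stage = "early",
                             graph = default_graph(),
                             obs = observation_model(),
                             time = time_settings(),
                             prior = NULL, order = "parallel") {
  post <- state_posterior(theta, diagnosis, stage, graph, obs, time, prior, order)
  sum(post[states_with_levels(level, graph)])
}

states_with_levels <- function(level, graph) {
  v <- match(level, graph$levels)
  if (anyNA(v)) stop("unknown level(s): ",
                     paste(level[is.na(v)], collapse = ", "))
  bits <- enumerate_states(graph)
  rowSums(bits[, v, drop = FALSE]) == length(v)
}

#' One-pass Bayesian network prior over states
#'
#' The predecessor model of the progression HMM: each level is involved with
#' probability `p_v = 1 - (1 - b_v) prod_r (1 - t_rv)` over its *involved*
#' parents, evaluated in topological order, giving the joint
#' `P(x) = prod_v [p_v if x_v else 1 - p_v]`. There is no time axis.
#'
#' This joint is exactly the distribution obtained by a single
#' `order = "topological"` step of [transition_matrix()] from the
#' all-healthy state; a single *parallel* step reproduces it only when all
#' inter-level transition probabilities vanish.
#'
#' @param graph An `lnl_graph`.
#' @param theta Parameter vector with `b` and `t` components (any `p_late`
#'   entry is ignored).
#' @return Probability vector over states.
#' @export
bn_state_prior <- function(graph, theta) {
  check_theta(theta)
  bits <- enumerate_states(graph)
  pr <- rep(1, nrow(bits))
  for (v in seq_len(ncol(bits))) {
    # each state's involve-probability conditions on its own parent bits
    esc <- rep(1 - theta_b(theta, graph)[v], nrow(bits))
    into <- which(graph$arcs$to == graph$levels[v])
    for (k in into) {
      r <- match(graph$arcs$from[k], graph$levels)
      esc <- esc * (1 - theta_t(theta, graph)[k] * bits[, r])
    }
    pv <- 1 - esc
    pr <- pr * ifelse(bits[, v] == 1L, pv, 1 - pv)
  }
  stats::setNames(pr, rownames(bits))
}

#' Risk of occult involvement under the Bayesian network model
#'
#' Same Bayes conditioning as [microscopic_risk()], but with the one-pass
#' Bayesian network prior [bn_state_prior()] in place of the
#' time-marginalised HMM distribution.
#'
#' @param theta_bn Parameter vector with `b` and `t` components (no time
#'   parameter required).
#' @inheritParams microscopic_risk
#' @return A probability.
#' @export
bn_risk <- function(theta_bn, level, diagnosis, graph = default_graph(),
                    obs = observation_model()) {
  pr <- bn_state_prior(graph, theta_bn)
  f <- diagnosis_likelihoods(diagnosis, obs, graph)
  w <- pr * f
  tot <- sum(w)
  if (tot <= 0)
    stop("diagnosis has probability zero under these parameters; ",
         "the state posterior is undefined")
  sum((w / tot)[states_with_levels(level, graph)])
}

#' Risk table over posterior draws
#'
#' Evaluates the occult-involvement risk of a set of queries at every
#' posterior draw, returning both per-draw histogram values and summary
#' statistics. Queried with the four canonical conditioning patterns (N0,
#' "II only", "II and III", "III only") against each level, this reproduces
#' the layout of the published risk tables.
#'
#' @param samples A `posterior_samples` object (or plain draws matrix with
#'   parameter-name columns).
#' @param queries Data frame with columns `level` (label, or several labels
#'   separated by `+` for a joint query), `diagnosis` (list column of 0/1/NA
#'   vectors, or a character pattern like `"0100"` over levels in order),
#'   and `stage`.
#' @inheritParams microscopic_risk
#' @return Object of class `risk_table`: the query data frame augmented with
#'   `mean`, `sd`, `q16`, `q84` (all probabilities) and a list column
#'   `draws` of per-draw risks.
#' @export
risk_table <- function(samples, queries, graph = default_graph(),
                       obs = observation_model(), time = time_settings(),
                       order = "parallel") {
  draws <- posterior_draws(samples)
  if (nrow(draws) == 0L) stop("samples must contain at least one draw")
  out <- queries
  res <- vector("list", nrow(queries))
  for (q in seq_len(nrow(queries))) {
    lv <- strsplit(as.character(queries$level[q]), "\\+")[[1]]
    z <- parse_query_diagnosis(queries$diagnosis[[q]], graph)
    st <- as.character(queries$stage[q])
    res[[q]] <- apply(draws, 1L, function(th)
      microscopic_risk(th, lv, z, st, graph, obs, time, order = order))
  }
  out$mean <- vapply(res, mean, 0)
  out$sd <- vapply(res, stats::sd, 0)
  out$q16 <- vapply(res, stats::quantile, 0, probs = 0.16, names = FALSE)
  out$q84 <- vapply(res, stats::quantile, 0, probs = 0.84, names = FALSE)
  out$draws <- res
  class(out) <- c("risk_table", class(queries))
  out
}

parse_query_diagnosis <- function(diagnosis, graph) {
  if (is.character(diagnosis) && length(diagnosis) == 1L &&
      nchar(diagnosis) == length(graph$levels)) {
    ch <- strsplit(diagnosis, "")[[1]]
    return(ifelse(ch == "?", NA_integer_, as.integer(ch)))
  }
  diagnosis
}

#' @export
print.risk_table <- function(x, digits = 2, ...) {
  df <- as.data.frame(x)[, setdiff(names(x), "draws"), drop = FALSE]
  df$diagnosis <- vapply(x$diagnosis, function(z)
    paste(ifelse(is.na(z), "?", z), collapse = ""), "")
  for (col in c("mean", "sd", "q16", "q84"))
    df[[col]] <- sprintf(paste0("%.", digits, "f%%"), 100 * df[[col]])
  print(df, row.names = FALSE)
  invisible(x)
}

#' Canonical conditioning patterns
#'
#' The four diagnosis patterns used in the published risk comparison: N0
#' (all levels negative), level II only, levels II and III, level III only;
#' unlisted levels are observed negative.
#'
#' @param graph An `lnl_graph` with levels I-IV.
#' @param stage Stage class attached to every query.
#' @return A query data frame suitable for [risk_table()], one row per
#'   (level, pattern) pair.
#' @export
canonical_queries <- function(graph = default_graph(), stage = "early") {
  pats <- list(
    "N0" = c(I = 0, II = 0, III = 0, IV = 0),
    "II only" = c(I = 0, II = 1, III = 0, IV = 0),
    "II and III" = c(I = 0, II = 1, III = 1, IV = 0),
    "III only" = c(I = 0, II = 0, III = 1, IV = 0)
  )
  grid <- expand.grid(level = graph$levels, pattern = names(pats),
                      stringsAsFactors = FALSE)
  data.frame(
    level = grid$level,
    pattern = grid$pattern,
    diagnosis = I(pats[grid$pattern]),
    stage = stage,
    stringsAsFactors = FALSE
  )
}
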