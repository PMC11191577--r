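#' Spread parameter vector
#'
#' Bundles the learnable parameters of the progression model: one base
#' probability per level (per-step chance of direct seeding from the primary
#' tumor), one transition probability per lymphatic arc (per-step chance of
#' spread from an involved upstream level), and the late-stage binomial
#' time-prior parameter `p_late`.
#'
#' @param b Numeric vector of base probabilities, one per level (in graph
#'   level order).
#' @param t Numeric vector of arc transition probabilities, one per arc (in
#'   graph arc order). May be empty for an arcless graph.
#' @param p_late Late T-stage binomial success probability, or `NULL` for a
#'   time-free (Bayesian network) parameter set.
#' @param graph The `lnl_graph` the parameters refer to.
#' @return Named numeric vector in canonical `param_names()` order.
#' @examples
#' spread_params(b = c(0.39, 0.53, 0.03, 0.01), t = c(0.5, 0.3, 0.2),
#'               p_late = 0.6)
#' @export
spread_params <- function(b, t = numeric(0), p_late = NULL,
                          graph = default_graph()) {
  theta <- c(b, t, p_late)
  names(theta) <- param_names(graph, time_param = !is.null(p_late))
  check_theta(theta)
  theta
}

check_theta <- function(theta) {
  if (anyNA(theta) || any(theta < 0) || any(theta > 1))
    stop("all spread parameters must lie in [0, 1]")
  invisible(theta)
}

theta_b <- function(theta, graph) unname(theta[unname(graph$tumor_params)])
theta_t <- function(theta, graph) unname(theta[graph$arcs$param])

#' One-step infection probability of a healthy level
#'
#' The chance that a currently healthy level `v` becomes involved in the next
#' time step: it escapes infection only if both the direct route from the
#' tumor and every route from an already-involved upstream level fail
#' independently, so
#' `P(involved) = 1 - (1 - b_v) * prod_r (1 - t_rv)` over involved parents
#' `r` (a noisy-OR of the incoming arcs).
#'
#' @param level Level label.
#' @param state Current hidden state (0/1 vector over levels or state index).
#' @param theta Parameter vector from [spread_params()].
#' @param graph An `lnl_graph`.
#' @return A probability.
#' @export
node_transition_prob <- function(level, state, theta, graph = default_graph()) {
  check_theta(theta)
  bits <- as_state_bits(state, graph)
  v <- match(level, graph$levels)
  if (is.na(v)) stop("unknown level: ", level)
  if (bits[v] == 1L)
    stop("level ", level, " is already involved; involvement persists")
  esc <- 1 - theta[[graph$tumor_params[[level]]]]
  into <- graph$arcs[graph$arcs$to == level, , drop = FALSE]
  for (k in seq_len(nrow(into))) {
    r <- match(into$from[k], graph$levels)
    if (bits[r] == 1L) esc <- esc * (1 - theta[[into$param[k]]])
  }
  1 - esc
}

# P[x, v] = probability level v is involved at t+1 given state x at t:
# 1 if already involved, else the noisy-OR of tumor and involved-parent arcs.
involvement_step_probs <- function(graph, theta, bits = enumerate_states(graph)) {
  V <- length(graph$levels)
  b <- theta_b(theta, graph)
  tt <- theta_t(theta, graph)
  P <- matrix(0, nrow(bits), V)
  for (v in seq_len(V)) {
    esc <- rep(1 - b[v], nrow(bits))
    into <- which(graph$arcs$to == graph$levels[v])
    for (k in into) {
      r <- match(graph$arcs$from[k], graph$levels)
      esc <- esc * (1 - tt[k] * bits[, r])
    }
    P[, v] <- ifelse(bits[, v] == 1L, 1, 1 - esc)
  }
  P
}

#' Hidden-state transition matrix
#'
#' The `2^V x 2^V` one-step kernel of the progression process. All levels
#' update in parallel: involved levels stay involved (no healing), each
#' healthy level becomes involved independently with its noisy-OR
#' probability given the current state. Reversions have probability exactly
#' zero and the all-involved state is absorbing.
#'
#' With `order = "topological"` the levels instead update one at a time in
#' topological order within the step, so spread acquired earlier in the
#' sweep can propagate onward within the same step; a single such step from
#' the all-healthy state reproduces the one-pass Bayesian network prior
#' exactly (see [bn_state_prior()]).
#'
#' @param graph An `lnl_graph`.
#' @param theta Parameter vector (the `p_late` entry, if present, is
#'   ignored here).
#' @param order `"parallel"` (default) or `"topological"` within-step update
#'   schedule.
#' @return Row-stochastic matrix with state-pattern dimnames.
#' @examples
#' A <- transition_matrix(lnl_graph(c("I", "II")),
#'                        spread_params(c(0.3, 0.2), 0.5, 0.6,
#'                                      lnl_graph(c("I", "II"))))
#' rowSums(A)
#' @export
transition_matrix <- function(graph, theta, order = c("parallel", "topological")) {
  order <- match.arg(order)
  check_theta(theta)
  bits <- enumerate_states(graph)
  if (order == "topological") {
    A <- diag(nrow(bits))
    for (lev in graph$topo_order) A <- A %*% single_level_kernel(graph, theta, lev, bits)
    dimnames(A) <- list(rownames(bits), rownames(bits))
    return(A)
  }
  P <- involvement_step_probs(graph, theta, bits)
  A <- matrix(1, nrow(bits), nrow(bits))
  for (v in seq_len(ncol(bits))) {
    yv <- bits[, v]
    A <- A * (P[, v] %o% yv + (1 - P[, v]) %o% (1 - yv))
  }
  dimnames(A) <- list(rownames(bits), rownames(bits))
  A
}

# kernel that updates only `level`, conditioning on the current state
single_level_kernel <- function(graph, theta, level, bits) {
  n <- nrow(bits)
  v <- match(level, graph$levels)
  P <- involvement_step_probs(graph, theta, bits)[, v]
  A <- matrix(0, n, n)
  flip <- bitwXor(0:(n - 1L), 2L^(v - 1L))  # partner state with bit v toggled
  for (x in seq_len(n)) {
    if (bits[x, v] == 1L) {
      A[x, x] <- 1
    } else {
      A[x, x] <- 1 - P[x]
      A[x, flip[x] + 1L] <- P[x]
    }
  }
  A
}

#' Imaging observation model
#'
#' Probability model linking true involvement to the imaging diagnosis of
#' each level: a truly involved level is read positive with probability
#' `sensitivity`, a truly healthy level is read negative with probability
#' `specificity`. Defaults are the MRI values for head and neck cancer used
#' throughout (sensitivity 0.81, specificity 0.63).
#'
#' @param sensitivity,specificity Probabilities in `[0, 1]`.
#' @return An object of class `lnl_observation`.
#' @export
observation_model <- function(sensitivity = 0.81, specificity = 0.63) {
  stopifnot(sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1)
  structure(list(sensitivity = sensitivity, specificity = specificity),
            class = "lnl_observation")
}

#' Full observation matrix
#'
#' `P(diagnosis pattern z | hidden state x)` for all pairs of the `2^V`
#' involvement patterns and the `2^V` complete diagnosis patterns, assuming
#' levels are read independently.
#'
#' @param obs An [observation_model()].
#' @param graph An `lnl_graph`.
#' @return Row-stochastic `2^V x 2^V` matrix (rows: hidden states, columns:
#'   diagnosis patterns).
#' @export
observation_matrix <- function(obs = observation_model(),
                               graph = default_graph()) {
  bits <- enumerate_states(graph)
  B <- matrix(1, nrow(bits), nrow(bits))
  for (v in seq_len(ncol(bits))) {
    p_pos <- ifelse(bits[, v] == 1L, obs$sensitivity, 1 - obs$specificity)
    zv <- bits[, v]
    B <- B * (p_pos %o% zv + (1 - p_pos) %o% (1 - zv))
  }
  dimnames(B) <- list(rownames(bits), rownames(bits))
  B
}

#' Per-state likelihood of a (possibly partial) diagnosis
#'
#' `P(observed findings | hidden state x)` for every state. Levels whose
#' status is `NA` (not assessed) contribute a factor of one, i.e. are
#' marginalised out rather than imputed negative.
#'
#' @param diagnosis Vector over levels with values 0 (negative), 1
#'   (positive) or `NA` (unknown); may be named by level.
#' @param obs An [observation_model()].
#' @param graph An `lnl_graph`.
#' @return Numeric vector of length `2^V`.
#' @export
diagnosis_likelihoods <- function(diagnosis, obs = observation_model(),
                                  graph = default_graph()) {
  z <- as_diagnosis(diagnosis, graph)
  bits <- enumerate_states(graph)
  f <- rep(1, nrow(bits))
  for (v in seq_len(ncol(bits))) {
    if (is.na(z[v])) next
    p_pos <- ifelse(bits[, v] == 1L, obs$sensitivity, 1 - obs$specificity)
    f <- f * if (z[v] == 1L) p_pos else 1 - p_pos
  }
  f
}

as_diagnosis <- function(diagnosis, graph) {
  V <- length(graph$levels)
  if (!is.null(names(diagnosis))) {
    z <- rep(NA_integer_, V)
    if (!all(names(diagnosis) %in% graph$levels))
      stop("diagnosis names must be level labels")
    z[match(names(diagnosis), graph$levels)] <- as.integer(diagnosis)
  } else {
    if (length(diagnosis) != V)
      stop("diagnosis must have one entry per level")
    z <- as.integer(diagnosis)
  }
  if (!all(z %in% c(0L, 1L, NA_integer_)))
    stop("diagnosis entries must be 0, 1 or NA")
  z
}

#' Binomial diagnosis-time prior
#'
#' Distribution over the unobserved number of progression steps elapsed when
#' the patient is diagnosed: `P(T = t) = C(t_max, t) p^t (1-p)^(t_max-t)`
#' for `t = 0..t_max`.
#'
#' @param t_max Maximum number of time steps (integer >= 1).
#' @param p Binomial success probability.
#' @return Object of class `time_prior`: list with `t_max` and `weights`
#'   (named by `t`).
#' @export
binomial_time_prior <- function(t_max, p) {
  stopifnot(t_max >= 1, p >= 0, p <= 1)
  w <- stats::dbinom(0:t_max, size = t_max, prob = p)
  structure(list(t_max = as.integer(t_max),
                 weights = stats::setNames(w, 0:t_max)),
            class = "time_prior")
}

#' Time-evolution settings
#'
#' The fixed part of the temporal model: the number of time steps `t_max`
#' shared by both stages and the early-stage binomial parameter `p_early`,
#' which is held fixed to anchor the time scale (only the late-stage
#' parameter `p_late` is learned).
#'
#' @param t_max Maximum number of progression steps.
#' @param p_early Binomial parameter of the early (T1-T2) time prior.
#' @return List of class `time_settings`.
#' @export
time_settings <- function(t_max = 10, p_early = 0.3) {
  stopifnot(t_max >= 1, p_early >= 0, p_early <= 1)
  structure(list(t_max = as.integer(t_max), p_early = p_early),
            class = "time_settings")
}

stage_time_prior <- function(theta, stage, time) {
  stage <- match.arg(stage, c("early", "late"))
  p <- if (stage == "early") time$p_early else theta[["p_late"]]
  binomial_time_prior(time$t_max, p)
}

#' Hidden-state distribution after t steps
#'
#' Evolves the point mass on the all-healthy state through `t` applications
#' of the transition kernel: at diagnosis time 0 the patient's levels are
#' all healthy with probability 1.
#'
#' @param theta Parameter vector.
#' @param t Non-negative integer number of steps.
#' @param graph An `lnl_graph`.
#' @param order Within-step update schedule, see [transition_matrix()].
#' @return Probability vector over the `2^V` states.
#' @export
state_distribution <- function(theta, t, graph = default_graph(),
                               order = "parallel") {
  stopifnot(t >= 0)
  A <- transition_matrix(graph, theta, order = order)
  pi_t <- c(1, rep(0, nrow(A) - 1L))
  for (i in seq_len(t)) pi_t <- as.vector(pi_t %*% A)
  stats::setNames(pi_t, rownames(A))
}

#' Time-marginalised hidden-state distribution
#'
#' The state distribution at diagnosis, averaging the t-step distributions
#' over the stage-appropriate binomial time prior:
#' `sum_t P(T = t) * e_0 A^t`.
#'
#' @param theta Parameter vector (must contain `p_late` when
#'   `stage = "late"` and no explicit `prior` is given).
#' @param stage `"early"` or `"late"` T-stage class.
#' @param graph An `lnl_graph`.
#' @param time [time_settings()].
#' @param prior Optional explicit [binomial_time_prior()]-style prior
#'   overriding the stage rule.
#' @param order Within-step update schedule, see [transition_matrix()].
#' @return Probability vector over states (sums to 1).
#' @export
marginal_state_distribution <- function(theta, stage = "early",
                                        graph = default_graph(),
                                        time = time_settings(),
                                        prior = NULL,
                                        order = "parallel") {
  if (is.null(prior)) prior <- stage_time_prior(theta, stage, time)
  A <- transition_matrix(graph, theta, order = order)
  pi_t <- c(1, rep(0, nrow(A) - 1L))
  out <- prior$weights[[1L]] * pi_t
  for (t in seq_len(prior$t_max)) {
    pi_t <- as.vector(pi_t %*% A)
    out <- out + prior$weights[[t + 1L]] * pi_t
  }
  stats::setNames(out, rownames(A))
}

#' Likelihood of one patient's diagnosis
#'
#' `P(observed diagnosis | theta, stage)`: the time-marginalised state
#' distribution pushed through the observation model, with unknown level
#' statuses marginalised out.
#'
#' @inheritParams marginal_state_distribution
#' @param diagnosis Per-level status 0/1/`NA`, see [diagnosis_likelihoods()].
#' @param obs An [observation_model()].
#' @return A probability.
#' @export
patient_likelihood <- function(theta, diagnosis, stage = "early",
                               graph = default_graph(),
                               obs = observation_model(),
                               time = time_settings(),
                               prior = NULL, order = "parallel") {
  pi_m <- marginal_state_distribution(theta, stage, graph, time, prior, order)
  sum(pi_m * diagnosis_likelihoods(diagnosis, obs, graph))
}

#' Cohort log-likelihood
#'
#' Sum of log patient likelihoods over a cohort table. A patient whose
#' diagnosis has probability zero under `theta` makes the result `-Inf`;
#' an empty cohort has log-likelihood 0.
#'
#' @param theta Parameter vector.
#' @param cohort A cohort table (see [simulate_cohort()] / [read_cohort()]).
#' @inheritParams patient_likelihood
#' @return A number `<= 0` (possibly `-Inf`).
#' @export
cohort_log_likelihood <- function(theta, cohort, graph = default_graph(),
                                  obs = observation_model(),
                                  time = time_settings(), order = "parallel") {
  ll <- make_cohort_loglik(cohort, graph, obs, time, order)
  ll(theta)
}

# Aggregates patients into unique (stage, pattern) cells once, returning a
# fast closure theta -> log-likelihood for repeated MCMC evaluation.
make_cohort_loglik <- function(cohort, graph = default_graph(),
                               obs = observation_model(),
                               time = time_settings(), order = "parallel",
                               model = c("hmm", "bn")) {
  model <- match.arg(model)
  if (nrow(cohort) == 0L) return(function(theta) 0)
  Z <- cohort_diagnosis_matrix(cohort, graph)
  key <- apply(Z, 1L, paste, collapse = ",")
  stage <- cohort_stage(cohort)
  cell <- if (model == "hmm") paste(stage, key) else key
  tab <- table(cell)
  first <- match(names(tab), cell)
  counts <- as.vector(tab)
  # per-state likelihood factors for each unique pattern, 2^V x K
  f_mat <- vapply(first, function(i) diagnosis_likelihoods(Z[i, ], obs, graph),
                  numeric(graph$n_states))
  cell_stage <- stage[first]
  function(theta) {
    check_theta(theta)
    if (model == "bn") {
      pr <- bn_state_prior(graph, theta)
      lik <- as.vector(pr %*% f_mat)
    } else {
      lik <- numeric(length(counts))
      for (s in unique(cell_stage)) {
        idx <- cell_stage == s
        pi_m <- marginal_state_distribution(theta, s, graph, time, order = order)
        lik[idx] <- as.vector(pi_m %*% f_mat[, idx, drop = FALSE])
      }
    }
    if (any(lik <= 0)) return(-Inf)
    sum(counts * log(lik))
  }
}

cohort_diagnosis_matrix <- function(cohort, graph) {
  cols <- paste0("lvl_", graph$levels)
  missing <- setdiff(cols, names(cohort))
  if (length(missing))
    stop("cohort is missing level columns: ", paste(missing, collapse = ", "))
  Z <- as.matrix(cohort[, cols, drop = FALSE])
  storage.mode(Z) <- "integer"
  colnames(Z) <- graph$levels
  Z
}

cohort_stage <- function(cohort) {
  if ("stage_class" %in% names(cohort)) {
    s <- as.character(cohort$stage_class)
  } else if ("t_stage" %in% names(cohort)) {
    s <- ifelse(cohort$t_stage <= 2, "early", "late")
  } else {
    stop("cohort must carry stage_class or t_stage")
  }
  if (!all(s %in% c("early", "late")))
    stop("stage_class must be 'early' or 'late'")
  s
}
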