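# Independent brute-force oracles: everything here works by explicit
# enumeration of states / trajectories with scalar loops, sharing no code
# path with the package's matrix implementation.

# states in index order (first level = least significant bit)
oracle_states <- function(V) {
  as.matrix(expand.grid(rep(list(0:1), V)))
}

# arcs: list of list(from = i, to = j, t = value) with integer level positions
oracle_node_p <- function(v, x, b, arcs) {
  esc <- 1 - b[v]
  for (a in arcs) if (a$to == v && x[a$from] == 1) esc <- esc * (1 - a$t)
  1 - esc
}

oracle_step_prob <- function(x, y, b, arcs) {
  p <- 1
  for (v in seq_along(x)) {
    if (x[v] == 1) {
      p <- p * (if (y[v] == 1) 1 else 0)
    } else {
      pv <- oracle_node_p(v, x, b, arcs)
      p <- p * (if (y[v] == 1) pv else 1 - pv)
    }
    if (p == 0) return(0)
  }
  p
}

# P(state at time t) for t = 0..t_max by exhaustive trajectory enumeration
oracle_dist_at_times <- function(b, arcs, t_max) {
  S <- oracle_states(length(b))
  n <- nrow(S)
  out <- matrix(0, t_max + 1L, n)
  rec <- function(xi, t, prob) {
    out[t + 1L, xi] <<- out[t + 1L, xi] + prob
    if (t == t_max) return(invisible())
    for (yi in seq_len(n)) {
      sp <- oracle_step_prob(S[xi, ], S[yi, ], b, arcs)
      if (sp > 0) rec(yi, t + 1L, prob * sp)
    }
  }
  rec(1L, 0L, 1)
  out
}

oracle_obs_factor <- function(x, z, sens, spec) {
  f <- 1
  for (v in seq_along(x)) {
    if (is.na(z[v])) next
    p_pos <- if (x[v] == 1) sens else 1 - spec
    f <- f * (if (z[v] == 1) p_pos else 1 - p_pos)
  }
  f
}

oracle_patient_likelihood <- function(b, arcs, weights, z, sens, spec) {
  S <- oracle_states(length(b))
  dist <- oracle_dist_at_times(b, arcs, length(weights) - 1L)
  lik <- 0
  for (t in seq_along(weights)) {
    for (xi in seq_len(nrow(S))) {
      lik <- lik + weights[t] * dist[t, xi] *
        oracle_obs_factor(S[xi, ], z, sens, spec)
    }
  }
  lik
}

# posterior risk that all levels in `lv` (integer positions) are involved
oracle_risk <- function(b, arcs, weights, z, sens, spec, lv) {
  S <- oracle_states(length(b))
  dist <- oracle_dist_at_times(b, arcs, length(weights) - 1L)
  post <- numeric(nrow(S))
  for (xi in seq_len(nrow(S))) {
    marg <- sum(weights * dist[, xi])
    post[xi] <- marg * oracle_obs_factor(S[xi, ], z, sens, spec)
  }
  post <- post / sum(post)
  sum(post[apply(S, 1L, function(x) all(x[lv] == 1))])
}

oracle_bn_prior <- function(b, arcs) {
  S <- oracle_states(length(b))
  pr <- numeric(nrow(S))
  for (xi in seq_len(nrow(S))) {
    x <- S[xi, ]
    p <- 1
    for (v in seq_along(x)) {
      pv <- oracle_node_p(v, x, b, arcs)
      p <- p * (if (x[v] == 1) pv else 1 - pv)
    }
    pr[xi] <- p
  }
  pr
}

oracle_bn_risk <- function(b, arcs, z, sens, spec, lv) {
  S <- oracle_states(length(b))
  post <- oracle_bn_prior(b, arcs) *
    apply(S, 1L, oracle_obs_factor, z = z, sens = sens, spec = spec)
  post <- post / sum(post)
  sum(post[apply(S, 1L, function(x) all(x[lv] == 1))])
}

# small test-graph catalogue shared across files: package graph plus the
# matching oracle arc list
toy_graphs <- function() {
  list(
    single = list(g = lnl_graph("A", list()),
                  arcs = list()),
    chain2 = list(g = lnl_graph(c("A", "B"), list(c("A", "B"))),
                  arcs_fun = function(tv) list(list(from = 1, to = 2, t = tv[1]))),
    chain3 = list(g = lnl_graph(c("A", "B", "C"),
                                list(c("A", "B"), c("B", "C"))),
                  arcs_fun = function(tv) list(
                    list(from = 1, to = 2, t = tv[1]),
                    list(from = 2, to = 3, t = tv[2]))),
    vee3 = list(g = lnl_graph(c("A", "B", "C"),
                              list(c("A", "C"), c("B", "C"))),
                arcs_fun = function(tv) list(
                  list(from = 1, to = 3, t = tv[1]),
                  list(from = 2, to = 3, t = tv[2])))
  )
}
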