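#' Lymphatic drainage graph
#'
#' Constructs the directed graph along which metastases spread: every lymph
#' node level (LNL) receives one arc from the primary tumor, carrying a base
#' probability `b_v` of direct seeding per time step, and arcs between levels
#' carry transition probabilities `t_rs` of spread from an involved upstream
#' level `r` to its downstream neighbour `s`.
#'
#' Arc parameters are named by level position: the tumor arc into the v-th
#' level is `b<v>` and the arc from the r-th to the s-th level is `t<r><s>`,
#' so the default four-level chain has parameters
#' `b1, b2, b3, b4, t12, t23, t34`.
#'
#' @param levels Character vector of ordered LNL labels.
#' @param arcs List of length-2 character vectors `c(source, target)` giving
#'   directed arcs between levels. Must form a DAG with no self-loops.
#' @return An object of class `lnl_graph`: a list with elements `levels`,
#'   `tumor_params` (named by level), `arcs` (data frame with `from`, `to`,
#'   `param`), and `n_states`.
#' @examples
#' g <- lnl_graph(c("I", "II"), list(c("I", "II")))
#' g$arcs$param  # "t12"
#' @export
lnl_graph <- function(levels = c("I", "II", "III", "IV"),
                      arcs = list(c("I", "II"), c("II", "III"), c("III", "IV"))) {
  levels <- as.character(levels)
  if (length(levels) < 1L || anyDuplicated(levels))
    stop("levels must be a non-empty vector of unique labels")
  arc_df <- if (length(arcs)) {
    data.frame(
      from = vapply(arcs, `[`, "", 1L),
      to = vapply(arcs, `[`, "", 2L),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(from = character(), to = character(), stringsAsFactors = FALSE)
  }
  if (!all(c(arc_df$from, arc_df$to) %in% levels))
    stop("every arc endpoint must be a declared level")
  if (any(arc_df$from == arc_df$to)) stop("self-loops are not allowed")
  if (anyDuplicated(paste(arc_df$from, arc_df$to))) stop("duplicate arc")
  arc_df$param <- if (nrow(arc_df)) {
    paste0("t", match(arc_df$from, levels), match(arc_df$to, levels))
  } else {
    character(0)
  }

  g <- structure(
    list(
      levels = levels,
      tumor_params = stats::setNames(paste0("b", seq_along(levels)), levels),
      arcs = arc_df,
      n_states = 2L^length(levels)
    ),
    class = "lnl_graph"
  )
  # reject cycles; also fixes the topological evaluation order
  g$topo_order <- topological_order(g)
  g
}

#' @export
print.lnl_graph <- function(x, ...) {
  cat("Lymphatic drainage graph:", length(x$levels), "levels,",
      nrow(x$arcs), "level arcs\n")
  cat("  levels:", paste(x$levels, collapse = ", "), "\n")
  cat("  parameters:", paste(param_names(x), collapse = ", "), "\n")
  invisible(x)
}

#' Default four-level graph
#'
#' The chain I -> II -> III -> IV with tumor arcs into every level: the
#' standard cervical drainage pattern for oral tongue primaries, with
#' parameters `b1..b4` and `t12, t23, t34`.
#'
#' @return An `lnl_graph` with levels I-IV.
#' @export
default_graph <- function() lnl_graph()

topological_order <- function(graph) {
  n <- length(graph$levels)
  indeg <- stats::setNames(integer(n), graph$levels)
  for (to in graph$arcs$to) indeg[to] <- indeg[to] + 1L
  order <- character(0)
  ready <- graph$levels[indeg == 0L]
  while (length(ready)) {
    # take the earliest declared level first so the order is deterministic
    v <- ready[order(match(ready, graph$levels))][1L]
    ready <- setdiff(ready, v)
    order <- c(order, v)
    kids <- graph$arcs$to[graph$arcs$from == v]
    for (k in kids) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) ready <- c(ready, k)
    }
  }
  if (length(order) != n) stop("level arcs must form an acyclic graph")
  order
}

#' Parameter names of a graph
#'
#' Full learnable parameter layout: one base probability per level, one
#' transition probability per arc and, for the hidden Markov model, the late
#' T-stage time-prior parameter `p_late` (dropped when `time_param = FALSE`,
#' e.g. for the one-pass Bayesian-network variant).
#'
#' @param graph An `lnl_graph`.
#' @param time_param Include the `p_late` slot?
#' @return Character vector of parameter names in canonical order.
#' @export
param_names <- function(graph, time_param = TRUE) {
  c(unname(graph$tumor_params), graph$arcs$param, if (time_param) "p_late")
}

#' Enumerate hidden involvement states
#'
#' All `2^V` joint involvement patterns of the `V` levels, ordered by integer
#' index with the first level as least-significant bit. State 0 is
#' all-healthy, state `2^V - 1` all-involved.
#'
#' @param graph An `lnl_graph`.
#' @return Integer 0/1 matrix with `2^V` rows (one per state, in index
#'   order), one column per level, row names giving the bit pattern in level
#'   order (e.g. `"0100"` = only the second level involved).
#' @examples
#' enumerate_states(lnl_graph(c("I", "II")))
#' @export
enumerate_states <- function(graph) {
  V <- length(graph$levels)
  idx <- 0:(2L^V - 1L)
  bits <- vapply(seq_len(V),
                 function(v) bitwAnd(bitwShiftR(idx, v - 1L), 1L),
                 integer(length(idx)))
  bits <- matrix(bits, nrow = length(idx), ncol = V,
                 dimnames = list(apply(matrix(bits, ncol = V), 1L,
                                       paste0, collapse = ""),
                                 graph$levels))
  bits
}

#' Test monotone progression between two states
#'
#' Involvement never regresses: state `y` is reachable from `x` only if every
#' level involved in `x` is still involved in `y` (the subset partial order
#' on involvement patterns).
#'
#' @param x,y States given either as 0/1 vectors over levels or as integer
#'   state indices.
#' @param graph An `lnl_graph` (needed when indices are supplied).
#' @return `TRUE` iff `y` is a (possibly trivial) progression of `x`.
#' @export
is_progression <- function(x, y, graph = default_graph()) {
  x <- as_state_bits(x, graph)
  y <- as_state_bits(y, graph)
  all(y[x == 1L] == 1L)
}

as_state_bits <- function(x, graph) {
  V <- length(graph$levels)
  if (length(x) == 1L && (is.numeric(x) || is.integer(x)) && (x > 1L || V == 1L)) {
    # an index, not a 1-level pattern: disambiguated by length for V > 1
  }
  if (length(x) == V && all(x %in% c(0L, 1L))) return(as.integer(x))
  if (length(x) == 1L && x >= 0 && x < 2L^V)
    return(as.integer(bitwAnd(bitwShiftR(as.integer(x), 0:(V - 1L)), 1L)))
  stop("state must be a 0/1 vector over levels or a valid state index")
}

state_index <- function(bits) sum(bits * 2L^(seq_along(bits) - 1L))
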