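#' Built-in toy models
#'
#' Small hand-checkable networks used throughout the test-suite and useful
#' for exploring engine semantics:
#' * `constant` — `A = A`: every state is a fixed point.
#' * `negation_oscillator` — `A = !A`: period-2 cycle under synchronous
#'   updating.
#' * `two_node_feedback` — `A = !B; B = A`: period-4 synchronous cycle.
#' * `feedforward_chain` — `A = A; B = A; C = B`: signal propagates one
#'   node per iteration.
#' * `temporal_toy` — a tautologically ON source feeding `ALL`/`ANY`
#'   windows of width 3: starting all-zero, the `ANY` target first fires at
#'   iteration 2 and the `ALL` target at iteration 4.
#' * `clamped_input` — `IN = IN; OUT = IN`: exercise knockout/overexpression
#'   clamps on `IN`.
#'
#' @return Named list of `network_model` objects.
#' @examples
#' detect_attractor(named_fixtures()$negation_oscillator,
#'                  sim_config(iterations = 16, repetitions = 1,
#'                             update_scheme = "synchronous"))
#' @export
named_fixtures <- function() {
  lapply(list(
    constant = "A = A",
    negation_oscillator = "A = !A",
    two_node_feedback = c("A = !B", "B = A"),
    feedforward_chain = c("A = A", "B = A", "C = B"),
    temporal_toy = c("w = 3", "SRC = SRC | !SRC",
                     "DALL = ALL(SRC, w)", "DANY = ANY(SRC, w)"),
    clamped_input = c("IN = IN", "OUT = IN")
  ), parse_model)
}

#' Random Boolean network fixture
#'
#' Draws a model whose rules are 2-level OR-of-AND forms over sampled
#' regulators (with NOT applied to individual literals), optionally
#' replacing literals with temporal window terms. The shallow rule shape
#' keeps truth tables cheap to enumerate, so generated models can be
#' cross-checked against brute-force state-transition oracles. Deterministic
#' in `seed`; the global RNG state is left untouched.
#'
#' @param n_nodes Number of nodes (>= 1).
#' @param density Expected regulators per node scale in \[0, 1\]; 0 yields
#'   pure self-referential rules (`A = A`).
#' @param temporal_fraction Probability that a literal becomes a window
#'   term.
#' @param max_width Maximum window width for temporal literals.
#' @param seed Integer seed.
#' @return A validated `network_model`.
#' @export
random_model <- function(n_nodes, density = 0.3, temporal_fraction = 0,
                         max_width = 3L, seed = 1L) {
  stopifnot(n_nodes >= 1L, density >= 0, density <= 1,
            temporal_fraction >= 0, temporal_fraction <= 1, max_width >= 1L)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  nodes <- sprintf("N%02d", seq_len(n_nodes))
  literal <- function() {
    reg <- sample(nodes, 1L)
    e <- if (stats::runif(1) < temporal_fraction) {
      w <- sample.int(max_width, 1L)
      if (stats::runif(1) < 0.5) bn_all(reg, w) else bn_any(reg, w)
    } else bn_atom(reg)
    if (stats::runif(1) < 0.3) bn_not(e) else e
  }
  rules <- lapply(nodes, function(nm) {
    k <- stats::rbinom(1L, max(0L, n_nodes - 1L), density)
    if (k == 0L) return(bn_atom(nm))  # self-referential constant
    terms <- lapply(seq_len(min(k, 3L)), function(i) {
      lits <- lapply(seq_len(sample.int(3L, 1L)), function(j) literal())
      if (length(lits) == 1L) lits[[1L]] else nary("and", lits)
    })
    if (length(terms) == 1L) terms[[1L]] else nary("or", terms)
  })
  text <- vapply(seq_along(nodes), function(i)
    sprintf("%s = %s", nodes[i], deparse_expr(rules[[i]])), character(1))
  parse_model(text)
}
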