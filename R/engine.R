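#' Simulation configuration
#'
#' @param iterations Number of discrete time steps per repetition. Must be at
#'   least the model's maximum window width. The reference protocol for the
#'   bundled disease model is 5000.
#' @param repetitions Number of independent stochastic repetitions (25 in the
#'   reference protocol; irrelevant for synchronous updating, which is
#'   deterministic).
#' @param update_scheme `"asynchronous"` (default): every iteration draws a
#'   fresh uniformly random permutation of the nodes and updates them one at
#'   a time, each update seeing the freshest current values; `"synchronous"`:
#'   all nodes update simultaneously from the previous state;
#'   `"asynchronous_single"`: one randomly chosen node updates per iteration
#'   (exposed for sensitivity checks). Temporal window terms always read
#'   end-of-iteration history, never the partially updated sweep.
#' @param seed Integer master seed; per-repetition streams are derived from
#'   it deterministically, so identical seeds give bit-identical ensembles.
#' @param attractor_window_fraction Trailing fraction of the run over which
#'   activation is averaged (default 0.5).
#' @param perturbations Named character vector: names are node names, values
#'   `"knockout"` (clamp to 0) or `"overexpress"` (clamp to 1). Clamps hold
#'   at every recorded iteration, including the initial state.
#' @param initial_state Named 0/1 vector; unnamed nodes start at 0. `NULL`
#'   for the all-zero state.
#' @return A `sim_config` list.
#' @export
sim_config <- function(iterations = 5000L, repetitions = 25L,
                       update_scheme = c("asynchronous", "synchronous",
                                         "asynchronous_single"),
                       seed = 1L,
                       attractor_window_fraction = 0.5,
                       perturbations = character(),
                       initial_state = NULL) {
  update_scheme <- match.arg(update_scheme)
  stopifnot(iterations >= 1L, repetitions >= 1L,
            attractor_window_fraction > 0, attractor_window_fraction <= 1)
  if (length(perturbations)) {
    stopifnot(is.character(perturbations), !is.null(names(perturbations)),
              all(perturbations %in% c("knockout", "overexpress")))
  }
  structure(list(iterations = as.integer(iterations),
                 repetitions = as.integer(repetitions),
                 update_scheme = update_scheme,
                 seed = as.integer(seed),
                 attractor_window_fraction = attractor_window_fraction,
                 perturbations = perturbations,
                 initial_state = initial_state),
            class = "sim_config")
}

# Compile an expression to the postfix bytecode of the C++ stack machine.
compile_expr <- function(expr, node_index, parameters) {
  switch(expr$type,
    atom = c(1L, node_index[[expr$node]] - 1L),
    not  = c(compile_expr(expr$child, node_index, parameters), 2L),
    and  = c(unlist(lapply(expr$children, compile_expr, node_index, parameters)),
             3L, length(expr$children)),
    or   = c(unlist(lapply(expr$children, compile_expr, node_index, parameters)),
             4L, length(expr$children)),
    all  = c(5L, node_index[[expr$node]] - 1L,
             resolve_width(expr$width, parameters)),
    any  = c(6L, node_index[[expr$node]] - 1L,
             resolve_width(expr$width, parameters))
  )
}

compile_model <- function(model) {
  nodes <- model_nodes(model)
  node_index <- stats::setNames(seq_along(nodes), nodes)
  lapply(model$rules, function(r) compile_expr(r$expr, node_index,
                                               model$parameters))
}

clamp_vector <- function(nodes, perturbations) {
  clamp <- rep(-1L, length(nodes))
  if (length(perturbations)) {
    unknown <- setdiff(names(perturbations), nodes)
    if (length(unknown))
      stop("perturbation targets not in model: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    clamp[match(names(perturbations), nodes)] <-
      ifelse(perturbations == "knockout", 0L, 1L)
  }
  clamp
}

initial_vector <- function(nodes, initial_state) {
  init <- rep(0L, length(nodes))
  if (!is.null(initial_state)) {
    stopifnot(!is.null(names(initial_state)),
              all(names(initial_state) %in% nodes),
              all(initial_state %in% c(0, 1)))
    init[match(names(initial_state), nodes)] <- as.integer(initial_state)
  }
  init
}

#' Simulate a Boolean network
#'
#' Runs the discrete-time dynamics of a (possibly temporal) Boolean model.
#' Under asynchronous updating each iteration draws a fresh random
#' permutation of the nodes, so every node updates exactly once per
#' iteration and the lag-`i` window terms remain well defined. Knockout
#' (overexpression) clamps force a node to 0 (1) in the initial state, after
#' every individual update and in all recorded history.
#'
#' @param model A `network_model`.
#' @param config A [sim_config()].
#' @return A `trajectory_ensemble`: list with `states`, an integer array
#'   indexed `[repetition, iteration, node]`; `nodes`, the node order; and
#'   `config`.
#' @examples
#' osc <- parse_model(c("A = !B", "B = A"))
#' tr <- simulate_network(osc, sim_config(iterations = 8, repetitions = 1,
#'                                        update_scheme = "synchronous"))
#' tr$states[1, , ]
#' @export
simulate_network <- function(model, config = sim_config()) {
  validate_model(model)
  stopifnot(inherits(config, "sim_config"))
  w <- model_max_width(model)
  if (config$iterations < w)
    stop(sprintf("iterations (%d) must be >= the model's maximum window width (%d)",
                 config$iterations, w), call. = FALSE)
  nodes <- model_nodes(model)
  scheme <- match(config$update_scheme,
                  c("synchronous", "asynchronous", "asynchronous_single")) - 1L
  states <- .simulate_cpp(compile_model(model),
                          config$iterations, config$repetitions, scheme,
                          as.double(config$seed),
                          clamp_vector(nodes, config$perturbations),
                          initial_vector(nodes, config$initial_state))
  dimnames(states) <- list(NULL, NULL, nodes)
  structure(list(states = states, nodes = nodes, config = config),
            class = "trajectory_ensemble")
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  d <- dim(x$states)
  cat(sprintf("<trajectory_ensemble> %d repetitions x %d iterations x %d nodes (%s, seed %d)\n",
              d[1], d[2], d[3], x$config$update_scheme, x$config$seed))
  invisible(x)
}

#' Evaluate a single Boolean expression
#'
#' Reference evaluator over the AST, matching the engine's semantics: atoms
#' read `current`; `ALL(X, w)` is 1 iff `X` was 1 at every one of the `w`
#' most recent completed iterations, `ANY(X, w)` iff at least one; history
#' states that do not exist yet (start of a run) count as 0.
#'
#' @param expr A `bn_expr`.
#' @param current Named 0/1 vector of current node values.
#' @param history Named list of 0/1 vectors, one per node, oldest first
#'   (may be empty).
#' @param parameters Named integer vector resolving symbolic window widths.
#' @return 0 or 1.
#' @export
evaluate_expr <- function(expr, current, history = list(),
                          parameters = integer()) {
  window_vals <- function(node, width) {
    w <- resolve_width(width, parameters)
    h <- history[[node]]
    if (is.null(h)) h <- integer()
    got <- rev(h)[seq_len(min(w, length(h)))]
    c(got, rep(0L, w - length(got)))  # missing history counts as 0
  }
  v <- switch(expr$type,
    atom = {
      if (!expr$node %in% names(current))
        stop("unresolved node '", expr$node, "'", call. = FALSE)
      current[[expr$node]]
    },
    not  = 1L - evaluate_expr(expr$child, current, history, parameters),
    and  = min(vapply(expr$children, evaluate_expr, numeric(1),
                      current, history, parameters)),
    or   = max(vapply(expr$children, evaluate_expr, numeric(1),
                      current, history, parameters)),
    all  = as.integer(all(window_vals(expr$node, expr$width) == 1L)),
    any  = as.integer(any(window_vals(expr$node, expr$width) == 1L))
  )
  as.integer(v)
}

#' Per-node activation over the trailing attractor window
#'
#' The long-run readout of a simulation: for each node, the fraction of ON
#' states over the trailing window of each repetition, averaged across
#' repetitions.
#'
#' @param traj A `trajectory_ensemble`.
#' @param window_fraction Trailing fraction of iterations to average over;
#'   defaults to the value in the trajectory's config.
#' @return An `activation_summary`: list with `mean` (named numeric in
#'   \[0,1\]), `window` (first and last iteration averaged),
#'   `repetition_means` (repetitions x nodes matrix) and `config`.
#' @export
summarize_activation <- function(traj, window_fraction = NULL) {
  stopifnot(inherits(traj, "trajectory_ensemble"))
  if (is.null(window_fraction))
    window_fraction <- traj$config$attractor_window_fraction
  stopifnot(window_fraction > 0, window_fraction <= 1)
  T <- dim(traj$states)[2]
  if (T < 1L) stop("empty trajectory", call. = FALSE)
  from <- max(1L, T - as.integer(floor(T * window_fraction)) + 1L)
  rep_means <- apply(traj$states[, from:T, , drop = FALSE], c(1, 3), mean)
  structure(list(mean = colMeans(rep_means),
                 window = c(from, T),
                 repetition_means = rep_means,
                 config = traj$config),
            class = "activation_summary")
}

#' @export
print.activation_summary <- function(x, ...) {
  cat(sprintf("<activation_summary> %d nodes, window %d..%d\n",
              length(x$mean), x$window[1], x$window[2]))
  print(round(x$mean, 3))
  invisible(x)
}

#' Classify the long-run behaviour of a model
#'
#' Under synchronous updating the dynamics are deterministic, and the
#' extended state (the last `W` recorded states, `W` = maximum window width)
#' is Markov, so exact cycle detection applies: the report gives
#' `fixed_point` (period 1) or `simple_cycle` with the minimal period. If no
#' recurrence occurs within the configured iterations, non-convergence is
#' reported in the `converged` field rather than raised. Under asynchronous
#' updating the long-run set is stochastic; the report is
#' `complex_or_stochastic` together with a stationarity gap — the maximum
#' over nodes of |mean over first half of the summary window - mean over
#' second half| — as a convergence diagnostic.
#'
#' @param model A `network_model`.
#' @param config A [sim_config()].
#' @return An `attractor_report` with fields `kind`, `period` (for the
#'   deterministic kinds), `transient` (iteration at which the cycle is
#'   entered), `stationarity_gap`, `converged`.
#' @export
detect_attractor <- function(model, config = sim_config()) {
  traj <- simulate_network(model, config)
  if (config$update_scheme == "synchronous") {
    W <- max(1L, model_max_width(model))
    n <- length(traj$nodes)
    T <- config$iterations
    init <- clamp_vector(traj$nodes, config$perturbations)
    free <- init < 0L
    init[free] <- initial_vector(traj$nodes, config$initial_state)[free]
    rec <- traj$states[1, , , drop = FALSE]
    dim(rec) <- c(T, n)
    seqs <- rbind(init, rec)  # rows 1..T+1 are states 0..T
    seen <- new.env(hash = TRUE, parent = emptyenv())
    for (t in 0:T) {
      lo <- t - W + 1L
      block <- if (lo < 0L)
        c(rep(0L, -lo * n), t(seqs[seq(1L, t + 1L), , drop = FALSE]))
      else t(seqs[seq(lo + 1L, t + 1L), , drop = FALSE])
      key <- paste(block, collapse = "")
      prev <- seen[[key]]
      if (!is.null(prev)) {
        period <- t - prev
        return(structure(list(kind = if (period == 1L) "fixed_point"
                                     else "simple_cycle",
                              period = period, transient = prev,
                              stationarity_gap = 0,
                              converged = TRUE),
                         class = "attractor_report"))
      }
      seen[[key]] <- t
    }
    return(structure(list(kind = "simple_cycle", period = NA_integer_,
                          transient = NA_integer_,
                          stationarity_gap = NA_real_, converged = FALSE),
                     class = "attractor_report"))
  }
  structure(list(kind = "complex_or_stochastic", period = NULL,
                 transient = NA_integer_,
                 stationarity_gap = stationarity_gap(traj),
                 converged = TRUE),
            class = "attractor_report")
}

#' Stationarity gap of a trajectory ensemble
#'
#' Maximum over nodes of the absolute difference between the mean activation
#' in the first and second halves of the summary window, averaged over
#' repetitions. Values near 0 indicate the ensemble has reached its
#' stationary regime.
#'
#' @param traj A `trajectory_ensemble`.
#' @param window_fraction Trailing fraction, defaulting to the config value.
#' @return Non-negative numeric scalar.
#' @export
stationarity_gap <- function(traj, window_fraction = NULL) {
  if (is.null(window_fraction))
    window_fraction <- traj$config$attractor_window_fraction
  T <- dim(traj$states)[2]
  from <- max(1L, T - as.integer(floor(T * window_fraction)) + 1L)
  mid <- from + (T - from) %/% 2L
  m1 <- apply(traj$states[, from:mid, , drop = FALSE], 3, mean)
  m2 <- apply(traj$states[, (mid + 1L):T, , drop = FALSE], 3, mean)
  max(abs(m1 - m2))
}

#' @export
print.attractor_report <- function(x, ...) {
  cat("<attractor_report>", x$kind)
  if (!is.null(x$period) && !is.na(x$period))
    cat(sprintf(", period %d (entered at iteration %d)", x$period, x$transient))
  if (!is.null(x$stationarity_gap) && !is.na(x$stationarity_gap))
    cat(sprintf(", stationarity gap %.4g", x$stationarity_gap))
  if (!x$converged) cat(" [no recurrence within the configured iterations]")
  cat("\n")
  invisible(x)
}

#' Export a trajectory ensemble as tabular text
#'
#' Long format: one row per (repetition, iteration, node) with the recorded
#' 0/1 value.
#'
#' @param traj A `trajectory_ensemble`.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  d <- dim(traj$states)
  df <- data.frame(repetition = rep(seq_len(d[1]), times = d[2] * d[3]),
                   iteration = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
                   node = rep(traj$nodes, each = d[1] * d[2]),
                   value = as.vector(traj$states))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
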