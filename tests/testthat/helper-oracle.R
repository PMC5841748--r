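# Independent reference implementations used to cross-check the compiled
# engine. Deliberately naive: direct recursion over the AST and explicit
# state-transition enumeration, sharing no code with the simulation path.

# Evaluate one expression. `state` is a named 0/1 vector (current values);
# `hist` a matrix with one row per completed iteration (oldest first) and
# one named column per node; absent rows count as 0.
oracle_eval <- function(expr, state, hist, params) {
  window <- function(node, width, need_all) {
    w <- if (is.character(width)) params[[width]] else width
    vals <- rep(0L, w)
    n_have <- min(w, nrow(hist))
    if (n_have > 0)
      vals[seq_len(n_have)] <- hist[nrow(hist) - seq_len(n_have) + 1L, node]
    if (need_all) as.integer(sum(vals) == w) else as.integer(sum(vals) > 0)
  }
  switch(expr$type,
    atom = as.integer(state[[expr$node]]),
    not  = 1L - oracle_eval(expr$child, state, hist, params),
    and  = {
      v <- 1L
      for (ch in expr$children) v <- v * oracle_eval(ch, state, hist, params)
      v
    },
    or   = {
      v <- 0L
      for (ch in expr$children)
        if (oracle_eval(ch, state, hist, params)) v <- 1L
      v
    },
    all  = window(expr$node, expr$width, TRUE),
    any  = window(expr$node, expr$width, FALSE)
  )
}

# Synchronous trajectory: rows are iterations 1..T (matching the engine's
# recorded states); `init` is iteration 0.
oracle_sync_traj <- function(model, init, iterations) {
  nodes <- names(model$rules)
  hist <- matrix(init, nrow = 1, dimnames = list(NULL, nodes))
  for (t in seq_len(iterations)) {
    prev <- hist[nrow(hist), ]
    nxt <- vapply(model$rules, function(r)
      oracle_eval(r$expr, prev, hist, model$parameters), integer(1))
    hist <- rbind(hist, nxt)
  }
  unname(hist[-1, , drop = FALSE])
}

# Exact attractor of a temporal-free model under synchronous updating,
# found by walking the state-transition graph from `init`.
oracle_sync_attractor <- function(model, init, max_steps = 4096L) {
  nodes <- names(model$rules)
  state <- stats::setNames(as.integer(init), nodes)
  seen <- list()
  empty_hist <- matrix(integer(), 0, length(nodes),
                       dimnames = list(NULL, nodes))
  for (step in 0:max_steps) {
    key <- paste(state, collapse = "")
    if (!is.null(seen[[key]]))
      return(list(period = step - seen[[key]], transient = seen[[key]]))
    seen[[key]] <- step
    state <- vapply(model$rules, function(r)
      oracle_eval(r$expr, state, empty_hist, model$parameters), integer(1))
  }
  stop("oracle: no recurrence found")
}

all_binary_states <- function(n) {
  m <- as.matrix(expand.grid(rep(list(0:1), n)))
  dimnames(m) <- NULL
  m
}

# Evaluate the MathML condition of an SBML-qual function term against a
# named 0/1 input vector (independent reader used to check exports).
mathml_eval <- function(node, inputs) {
  name <- xml2::xml_name(node)
  if (name == "math") return(mathml_eval(xml2::xml_child(node), inputs))
  stopifnot(name == "apply")
  children <- xml2::xml_children(node)
  op <- xml2::xml_name(children[[1]])
  args <- children[-1]
  switch(op,
    eq = {
      ci <- xml2::xml_text(args[[1]])
      as.integer(inputs[[ci]] == as.numeric(xml2::xml_text(args[[2]])))
    },
    not = 1L - mathml_eval(args[[1]], inputs),
    and = as.integer(all(vapply(args, mathml_eval, integer(1), inputs) == 1L)),
    or  = as.integer(any(vapply(args, mathml_eval, integer(1), inputs) == 1L)),
    stop("unexpected MathML operator: ", op)
  )
}
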