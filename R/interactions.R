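#' Extract the signed interaction list of a model
#'
#' A regulator of node `T` is any node appearing in `T`'s rule, either as a
#' current-time atom or inside a temporal window term. The sign of an
#' occurrence is the parity of NOT operators enclosing it: an even number of
#' negations gives an activating edge, odd gives an inhibitory one. A node
#' occurring under both parities contributes two interactions; duplicate
#' (regulator, target, sign) triples are collapsed. Self-references (a node
#' in its own rule) count as interactions.
#'
#' @param model A `network_model`.
#' @return A data.frame with columns `regulator`, `target`, `sign`
#'   (`"activating"`/`"inhibitory"`), ordered by (target, regulator, sign).
#' @examples
#' m <- parse_model(c("A = !B", "B = A"))
#' extract_interactions(m)
#' @export
extract_interactions <- function(model) {
  validate_model(model)
  rows <- lapply(model$rules, function(rule) {
    occ <- expr_occurrences(rule$expr, negated = FALSE)
    if (!nrow(occ)) return(NULL)
    occ <- unique(occ)
    data.frame(regulator = occ$node,
               target = rule$target,
               sign = ifelse(occ$negated, "inhibitory", "activating"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out))
    out <- data.frame(regulator = character(), target = character(),
                      sign = character(), stringsAsFactors = FALSE)
  out <- out[order(out$target, out$regulator, out$sign), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# All (node, negation-parity) occurrences in an expression.
expr_occurrences <- function(expr, negated) {
  switch(expr$type,
    atom = data.frame(node = expr$node, negated = negated,
                      stringsAsFactors = FALSE),
    all  = ,
    any  = data.frame(node = expr$node, negated = negated,
                      stringsAsFactors = FALSE),
    not  = expr_occurrences(expr$child, !negated),
    and  = ,
    or   = do.call(rbind, lapply(expr$children, expr_occurrences, negated))
  )
}

#' Write an interaction list as tab-separated text
#'
#' @param interactions Output of [extract_interactions()].
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_interactions <- function(interactions, path) {
  utils::write.table(interactions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
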