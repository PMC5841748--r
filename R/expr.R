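#' Boolean expression constructors
#'
#' A rule's right-hand side is an abstract syntax tree built from six node
#' types: plain atoms (the regulator's current value), negation, n-ary
#' conjunction/disjunction, and the two temporal window operators.
#' `bn_all(x, w)` is true iff node `x` was active in *every* one of the `w`
#' most recent completed iterations; `bn_any(x, w)` iff it was active in at
#' least one of them. The width `w` may be a positive integer or the name of
#' a model parameter resolved at simulation time.
#'
#' @param node Node name (character scalar).
#' @param child,... Sub-expressions.
#' @param width Positive integer or parameter name.
#' @return An object of class `bn_expr`.
#' @examples
#' bn_and(bn_atom("NFkB"), bn_not(bn_any("IL10", "downreg_cell")))
#' @name bn_expr
NULL

new_expr <- function(type, fields) {
  structure(c(list(type = type), fields), class = "bn_expr")
}

#' @rdname bn_expr
#' @export
bn_atom <- function(node) {
  stopifnot(is.character(node), length(node) == 1L, nzchar(node))
  new_expr("atom", list(node = node))
}

#' @rdname bn_expr
#' @export
bn_not <- function(child) {
  stopifnot(inherits(child, "bn_expr"))
  new_expr("not", list(child = child))
}

nary <- function(type, children) {
  stopifnot(length(children) >= 2L,
            all(vapply(children, inherits, logical(1), "bn_expr")))
  new_expr(type, list(children = children))
}

#' @rdname bn_expr
#' @export
bn_and <- function(...) nary("and", list(...))

#' @rdname bn_expr
#' @export
bn_or <- function(...) nary("or", list(...))

check_width <- function(width) {
  if (is.numeric(width)) {
    if (length(width) != 1L || width != as.integer(width) || width < 1L)
      stop("window width must be a positive integer", call. = FALSE)
    as.integer(width)
  } else if (is.character(width) && length(width) == 1L && nzchar(width)) {
    width
  } else stop("window width must be a positive integer or a parameter name",
              call. = FALSE)
}

#' @rdname bn_expr
#' @export
bn_all <- function(node, width) {
  new_expr("all", list(node = node, width = check_width(width)))
}

#' @rdname bn_expr
#' @export
bn_any <- function(node, width) {
  new_expr("any", list(node = node, width = check_width(width)))
}

#' Structural equality of expressions
#'
#' Two ASTs are equal iff they have identical shape, node references,
#' operator types and window widths. Child order matters (serialization is
#' order-preserving); no logical simplification is attempted.
#'
#' @param a,b `bn_expr` objects.
#' @return Logical scalar.
#' @export
expr_equal <- function(a, b) {
  if (a$type != b$type) return(FALSE)
  switch(a$type,
    atom = a$node == b$node,
    not  = expr_equal(a$child, b$child),
    and  = ,
    or   = length(a$children) == length(b$children) &&
           all(mapply(expr_equal, a$children, b$children)),
    all  = ,
    any  = a$node == b$node && identical(a$width, b$width)
  )
}

#' Nodes referenced by an expression
#'
#' @param expr A `bn_expr`.
#' @return Character vector of distinct node names (atoms and window terms).
#' @export
expr_nodes <- function(expr) {
  switch(expr$type,
    atom = expr$node,
    not  = expr_nodes(expr$child),
    and  = ,
    or   = unique(unlist(lapply(expr$children, expr_nodes))),
    all  = ,
    any  = expr$node
  )
}

# Parameter names (non-integer widths) used by an expression.
expr_params <- function(expr) {
  switch(expr$type,
    atom = character(),
    not  = expr_params(expr$child),
    and  = ,
    or   = unique(unlist(lapply(expr$children, expr_params))),
    all  = ,
    any  = if (is.character(expr$width)) expr$width else character()
  )
}

# Maximum window width of an expression given a parameter table.
expr_max_width <- function(expr, parameters) {
  switch(expr$type,
    atom = 0L,
    not  = expr_max_width(expr$child, parameters),
    and  = ,
    or   = max(vapply(expr$children, expr_max_width, integer(1), parameters)),
    all  = ,
    any  = resolve_width(expr$width, parameters)
  )
}

resolve_width <- function(width, parameters) {
  if (is.character(width)) {
    if (!width %in% names(parameters))
      stop("unresolved parameter '", width, "'", call. = FALSE)
    width <- parameters[[width]]
  }
  w <- as.integer(width)
  if (is.na(w) || w < 1L)
    stop("window width must resolve to a positive integer", call. = FALSE)
  w
}

#' Render an expression in the model language
#'
#' Minimal parenthesisation under the precedence NOT > AND > OR.
#'
#' @param expr A `bn_expr`.
#' @return Character scalar.
#' @export
deparse_expr <- function(expr) {
  prec <- function(e) switch(e$type, or = 1L, and = 2L, not = 3L, 4L)
  wrap <- function(e, parent_prec) {
    s <- deparse_expr(e)
    if (prec(e) < parent_prec) paste0("(", s, ")") else s
  }
  switch(expr$type,
    atom = expr$node,
    not  = paste0("!", wrap(expr$child, 4L)),
    and  = paste(vapply(expr$children, wrap, character(1), 3L), collapse = " & "),
    or   = paste(vapply(expr$children, wrap, character(1), 2L), collapse = " | "),
    all  = sprintf("ALL(%s, %s)", expr$node, expr$width),
    any  = sprintf("ANY(%s, %s)", expr$node, expr$width)
  )
}

#' @export
print.bn_expr <- function(x, ...) {
  cat(deparse_expr(x), "\n")
  invisible(x)
}

#' @export
format.bn_expr <- function(x, ...) deparse_expr(x)
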