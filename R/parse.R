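#' Parse a Boolean network model from its text representation
#'
#' The model language has one statement per line. A statement is either a
#' rule `NODE = expression` or a parameter assignment `name = integer`.
#' Expressions combine node names with `!` (NOT), `&` (AND), `|` (OR),
#' parentheses, and the temporal window operators `ALL(NODE, w)` /
#' `ANY(NODE, w)` where `w` is a positive integer or a parameter name.
#' Precedence is NOT > AND > OR. `#` starts a comment; pragma comments of
#' the form `#@ key: value...` carry metadata — `input`/`output` list node
#' roles, `animal` flags rules whose support comes from animal rather than
#' human data, and `title` names the model.
#'
#' @param text Character vector of lines, or a single string with newlines.
#' @return A validated `network_model`: a list with `rules` (named list of
#'   rules, each with `target`, `expr`, `role`, `provenance`), `parameters`
#'   (named integer vector) and `metadata`.
#' @seealso [serialize_model()], [read_model()], [extract_interactions()]
#' @examples
#' m <- parse_model(c("B = 1", "A = !A2 & ANY(A2, B)", "A2 = A"))
#' m$parameters
#' @export
parse_model <- function(text) {
  stopifnot(is.character(text))
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))

  rules <- list()
  parameters <- integer()
  metadata <- list(title = NULL)
  roles <- list(input = character(), output = character())
  animal <- character()

  for (i in seq_along(lines)) {
    raw <- lines[[i]]
    pragma <- regmatches(raw, regexec("^\\s*#@\\s*([a-z]+)\\s*:\\s*(.*)$", raw))[[1]]
    if (length(pragma) == 3L) {
      key <- pragma[[2]]; val <- trimws(pragma[[3]])
      if (key == "title") metadata$title <- val
      else if (key %in% c("input", "output"))
        roles[[key]] <- c(roles[[key]], strsplit(val, "\\s+")[[1]])
      else if (key == "animal") animal <- c(animal, strsplit(val, "\\s+")[[1]])
      next
    }
    line <- sub("#.*$", "", raw)
    if (!nzchar(trimws(line))) next

    toks <- tokenize_line(line, i)
    st <- new.env(parent = emptyenv())
    st$toks <- toks; st$pos <- 1L; st$line <- i

    name <- expect_token(st, "name")
    expect_token(st, "=")
    # a lone integer on the right-hand side is a parameter assignment
    if (tok_type(st) == "int" && tok_type(st, ahead = 1L) == "eof") {
      value <- as.integer(take_token(st)$text)
      if (value < 1L)
        parse_error(st, sprintf("parameter '%s' must be a positive integer", name))
      if (name %in% names(parameters))
        parse_error(st, sprintf("duplicate parameter '%s'", name))
      parameters[[name]] <- value
      next
    }
    expr <- parse_or(st)
    if (tok_type(st) != "eof")
      parse_error(st, sprintf("unexpected '%s' after expression", tok_text(st)))
    if (name %in% names(rules))
      parse_error(st, sprintf("duplicate rule for node '%s'", name))
    rules[[name]] <- list(target = name, expr = expr,
                          role = "internal", provenance = NULL)
  }

  for (nm in roles$input)
    if (nm %in% names(rules)) rules[[nm]]$role <- "input"
  for (nm in roles$output)
    if (nm %in% names(rules)) rules[[nm]]$role <- "output"
  for (nm in animal)
    if (nm %in% names(rules)) rules[[nm]]$provenance <- "animal"

  validate_model(new_network_model(rules, parameters, metadata))
}

new_network_model <- function(rules, parameters, metadata = list()) {
  structure(list(rules = rules,
                 parameters = parameters,
                 metadata = metadata),
            class = "network_model")
}

#' @export
print.network_model <- function(x, ...) {
  roles <- vapply(x$rules, `[[`, character(1), "role")
  cat(sprintf("<network_model> %d nodes (%d input, %d internal, %d output), %d parameters\n",
              length(x$rules), sum(roles == "input"), sum(roles == "internal"),
              sum(roles == "output"), length(x$parameters)))
  if (!is.null(x$metadata$title)) cat("  title:", x$metadata$title, "\n")
  invisible(x)
}

#' Node names of a model, in rule order
#' @param model A `network_model`.
#' @return Character vector.
#' @export
model_nodes <- function(model) names(model$rules)

#' Validate a network model
#'
#' Checks closure (every referenced node has a rule), parameter resolution,
#' positive window widths and rule uniqueness. Called by [parse_model()];
#' exported for models built programmatically.
#'
#' @param model A `network_model`.
#' @return The model, invisibly unchanged, or an error.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "network_model"))
  nodes <- names(model$rules)
  if (anyDuplicated(nodes)) stop("duplicate rules: ",
    paste(unique(nodes[duplicated(nodes)]), collapse = ", "), call. = FALSE)
  for (rule in model$rules) {
    refs <- expr_nodes(rule$expr)
    missing <- setdiff(refs, nodes)
    if (length(missing))
      stop(sprintf("rule for '%s' references undefined node(s): %s",
                   rule$target, paste(missing, collapse = ", ")), call. = FALSE)
    for (p in expr_params(rule$expr))
      if (!p %in% names(model$parameters))
        stop(sprintf("rule for '%s' uses unresolved parameter '%s'",
                     rule$target, p), call. = FALSE)
    expr_max_width(rule$expr, model$parameters)  # errors on non-positive width
  }
  model
}

#' Maximum temporal window width of a model
#' @param model A `network_model`.
#' @return Integer (0 for temporal-free models).
#' @export
model_max_width <- function(model) {
  if (!length(model$rules)) return(0L)
  max(vapply(model$rules, function(r) expr_max_width(r$expr, model$parameters),
             integer(1)))
}

#' Does the model contain temporal window operators?
#' @param model A `network_model`.
#' @return Logical scalar.
#' @export
model_is_temporal <- function(model) model_max_width(model) > 0L

#' Serialize a model back to its text representation
#'
#' Emits the title pragma, parameter assignments, role and provenance
#' pragmas, then one rule per line in rule order. `parse_model()` of the
#' result reconstructs a structurally identical model.
#'
#' @param model A `network_model`.
#' @return Character vector of lines.
#' @export
serialize_model <- function(model) {
  out <- character()
  if (!is.null(model$metadata$title))
    out <- c(out, paste0("#@ title: ", model$metadata$title))
  roles <- vapply(model$rules, `[[`, character(1), "role")
  if (any(roles == "input"))
    out <- c(out, paste0("#@ input: ",
                         paste(names(roles)[roles == "input"], collapse = " ")))
  if (any(roles == "output"))
    out <- c(out, paste0("#@ output: ",
                         paste(names(roles)[roles == "output"], collapse = " ")))
  animal <- vapply(model$rules,
                   function(r) identical(r$provenance, "animal"), logical(1))
  if (any(animal))
    out <- c(out, paste0("#@ animal: ",
                         paste(names(model$rules)[animal], collapse = " ")))
  if (length(model$parameters))
    out <- c(out, sprintf("%s = %d", names(model$parameters), model$parameters))
  c(out, vapply(model$rules,
                function(r) sprintf("%s = %s", r$target, deparse_expr(r$expr)),
                character(1), USE.NAMES = FALSE))
}

#' Read / write a model file
#'
#' @param path File path (UTF-8 text in the model language).
#' @param model A `network_model`.
#' @return `read_model()`: a validated `network_model`. `write_model()`: the
#'   path, invisibly.
#' @export
read_model <- function(path) parse_model(readLines(path, warn = FALSE))

#' @rdname read_model
#' @export
write_model <- function(model, path) {
  writeLines(serialize_model(model), path)
  invisible(path)
}

#' Structural equality of two models
#'
#' Equal iff they hold the same nodes in the same order, structurally equal
#' expressions, equal roles and equal parameter tables.
#'
#' @param a,b `network_model` objects.
#' @return Logical scalar.
#' @export
model_equal <- function(a, b) {
  if (!identical(names(a$rules), names(b$rules))) return(FALSE)
  if (length(a$parameters) != length(b$parameters) ||
      !identical(sort(names(a$parameters)), sort(names(b$parameters))) ||
      !identical(a$parameters[sort(names(a$parameters))],
                 b$parameters[sort(names(b$parameters))])) return(FALSE)
  all(vapply(names(a$rules), function(nm) {
    ra <- a$rules[[nm]]; rb <- b$rules[[nm]]
    ra$role == rb$role && expr_equal(ra$expr, rb$expr)
  }, logical(1)))
}

## ---- tokenizer / recursive-descent internals --------------------------

TOKEN_RE <- "^([A-Za-z_][A-Za-z0-9_]*|[0-9]+|[()=!&|,])"

tokenize_line <- function(line, lineno) {
  toks <- list()
  col <- 1L
  rest <- line
  repeat {
    ws <- regmatches(rest, regexpr("^\\s*", rest))
    col <- col + nchar(ws)
    rest <- substring(rest, nchar(ws) + 1L)
    if (!nzchar(rest)) break
    m <- regmatches(rest, regexpr(TOKEN_RE, rest))
    if (!length(m))
      stop(sprintf("syntax error at line %d, column %d: unexpected character '%s'",
                   lineno, col, substring(rest, 1L, 1L)), call. = FALSE)
    type <- if (grepl("^[0-9]", m)) "int"
            else if (grepl("^[A-Za-z_]", m)) "name"
            else m
    toks[[length(toks) + 1L]] <- list(text = m, type = type, col = col)
    col <- col + nchar(m)
    rest <- substring(rest, nchar(m) + 1L)
  }
  toks[[length(toks) + 1L]] <- list(text = "<end of line>", type = "eof", col = col)
  toks
}

tok_type <- function(st, ahead = 0L) st$toks[[st$pos + ahead]]$type
tok_text <- function(st) st$toks[[st$pos]]$text

take_token <- function(st) {
  t <- st$toks[[st$pos]]
  st$pos <- st$pos + 1L
  t
}

parse_error <- function(st, msg) {
  stop(sprintf("syntax error at line %d, column %d: %s",
               st$line, st$toks[[st$pos]]$col, msg), call. = FALSE)
}

expect_token <- function(st, type) {
  if (tok_type(st) != type)
    parse_error(st, sprintf("expected %s, found '%s'",
                            if (type == "name") "a name" else paste0("'", type, "'"),
                            tok_text(st)))
  take_token(st)$text
}

parse_or <- function(st) {
  terms <- list(parse_and(st))
  while (tok_type(st) == "|") {
    take_token(st)
    terms[[length(terms) + 1L]] <- parse_and(st)
  }
  if (length(terms) == 1L) terms[[1L]] else nary("or", terms)
}

parse_and <- function(st) {
  factors <- list(parse_unary(st))
  while (tok_type(st) == "&") {
    take_token(st)
    factors[[length(factors) + 1L]] <- parse_unary(st)
  }
  if (length(factors) == 1L) factors[[1L]] else nary("and", factors)
}

parse_unary <- function(st) {
  if (tok_type(st) == "!") {
    take_token(st)
    return(bn_not(parse_unary(st)))
  }
  parse_primary(st)
}

parse_primary <- function(st) {
  type <- tok_type(st)
  if (type == "(") {
    take_token(st)
    e <- parse_or(st)
    expect_token(st, ")")
    return(e)
  }
  if (type == "name") {
    name <- take_token(st)$text
    if (name %in% c("ALL", "ANY") && tok_type(st) == "(") {
      take_token(st)
      node <- expect_token(st, "name")
      expect_token(st, ",")
      wt <- tok_type(st)
      if (!wt %in% c("name", "int"))
        parse_error(st, "expected a window width (integer or parameter name)")
      width <- take_token(st)$text
      if (wt == "int") {
        width <- as.integer(width)
        if (width < 1L) parse_error(st, "window width must be positive")
      }
      expect_token(st, ")")
      return(if (name == "ALL") bn_all(node, width) else bn_any(node, width))
    }
    return(bn_atom(name))
  }
  parse_error(st, sprintf("expected an expression, found '%s'", tok_text(st)))
}
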