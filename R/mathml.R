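# Namespace URIs used throughout the package.
MATHML_NS <- "http://www.w3.org/1998/Math/MathML"
CELLML_1_0_NS <- "http://www.cellml.org/cellml/1.0#"
CELLML_1_1_NS <- "http://www.cellml.org/cellml/1.1#"
UNCERTAINTY_NS <- "http://www.cellml.org/uncertainty-1#"
SEDML_NS <- "http://sed-ml.org/"

# Operators accepted inside <apply>.  Anything else is a parse error, never
# silent acceptance.
SUPPORTED_OPERATORS <- c(
  "plus", "minus", "times", "divide", "power", "root",
  "exp", "ln", "log", "abs", "min", "max",
  "sin", "cos", "tan", "arcsin", "arccos", "arctan",
  "sinh", "cosh", "tanh", "floor", "ceiling",
  "eq", "neq", "lt", "leq", "gt", "geq",
  "and", "or", "not", "xor",
  "diff"
)

# ---------------------------------------------------------------------------
# Expression constructors.  An expression is an immutable list with a `kind`
# field; class "mathml_expr" hangs printing and equality helpers off it.

new_expr <- function(kind, fields) {
  structure(c(list(kind = kind), fields), class = "mathml_expr")
}

#' Construct a numeric constant with units
#'
#' CellML requires every constant to carry a units name (possibly
#' `"dimensionless"`); the constructor enforces that rule.
#'
#' @param value Numeric scalar.
#' @param units Units name, e.g. `"m"` or `"dimensionless"`.
#' @return A `mathml_expr` node of kind `"cn"`.
#' @export
mml_constant <- function(value, units) {
  if (missing(units) || is.null(units) || !nzchar(units)) {
    stop("units error: constant ", value, " lacks a units annotation", call. = FALSE)
  }
  stopifnot(is.numeric(value), length(value) == 1L)
  new_expr("cn", list(value = as.numeric(value), units = as.character(units)))
}

#' Construct a variable reference
#'
#' @param variable Variable name.
#' @param component Component name, or `NA` for a contextual/bound name.
#' @return A `mathml_expr` node of kind `"ci"`.
#' @export
mml_var <- function(variable, component = NA_character_) {
  new_expr("ci", list(component = as.character(component),
                      variable = as.character(variable)))
}

#' Construct an operator application
#'
#' @param operator Operator name from the supported Content MathML subset.
#' @param operands List of operand expressions.
#' @return A `mathml_expr` node of kind `"apply"`.
#' @export
mml_apply <- function(operator, operands) {
  if (!operator %in% SUPPORTED_OPERATORS) {
    stop("parse error: unsupported operator <", operator, ">", call. = FALSE)
  }
  new_expr("apply", list(operator = operator, operands = operands))
}

#' Construct a piecewise expression
#'
#' @param cases List of `list(condition =, value =)` pairs, tried in order.
#' @param otherwise Optional fall-through expression.
#' @return A `mathml_expr` node of kind `"piecewise"`.
#' @export
mml_piecewise <- function(cases, otherwise = NULL) {
  new_expr("piecewise", list(cases = cases, otherwise = otherwise))
}

#' Construct a lambda (anonymous function)
#'
#' @param bound_vars Character vector of bound variable names.
#' @param body Body expression.
#' @return A `mathml_expr` node of kind `"lambda"`.
#' @export
mml_lambda <- function(bound_vars, body) {
  new_expr("lambda", list(bound_vars = as.character(bound_vars), body = body))
}

#' Construct a vector literal
#'
#' Used both for realisation vectors and for tuples of target variables.
#'
#' @param elements List of element expressions.
#' @return A `mathml_expr` node of kind `"vector"`.
#' @export
mml_vector <- function(elements) {
  new_expr("vector", list(elements = elements))
}

#' Construct a csymbol application
#'
#' @param definition_url The csymbol `definitionURL`, preserved verbatim.
#' @param operands List of operand expressions.
#' @return A `mathml_expr` node of kind `"csymbol"`.
#' @export
mml_csymbol_apply <- function(definition_url, operands = list()) {
  new_expr("csymbol", list(definition_url = as.character(definition_url),
                           operands = operands))
}

is_expr <- function(x) inherits(x, "mathml_expr")

#' @export
print.mathml_expr <- function(x, ...) {
  cat(deparse_expr(x), "\n")
  invisible(x)
}

# Compact human-readable rendering used in print and error context.
deparse_expr <- function(e) {
  switch(e$kind,
    cn = paste0(format(e$value), "{", e$units, "}"),
    ci = if (is.na(e$component)) e$variable else paste0(e$component, ".", e$variable),
    apply = paste0(e$operator, "(",
                   paste(vapply(e$operands, deparse_expr, ""), collapse = ", "), ")"),
    piecewise = paste0("piecewise(",
                       paste(vapply(e$cases, function(cs)
                         paste0(deparse_expr(cs$condition), " -> ", deparse_expr(cs$value)),
                         ""), collapse = "; "),
                       if (!is.null(e$otherwise)) paste0("; else ", deparse_expr(e$otherwise)),
                       ")"),
    lambda = paste0("lambda(", paste(e$bound_vars, collapse = ","), "). ",
                    deparse_expr(e$body)),
    vector = paste0("vector[", length(e$elements), "]"),
    csymbol = paste0("csymbol<", e$definition_url, ">(",
                     paste(vapply(e$operands, deparse_expr, ""), collapse = ", "), ")"),
    stop("unknown expression kind: ", e$kind)
  )
}

# ---------------------------------------------------------------------------
# Parsing

local_name <- function(node) sub("^.*:", "", xml2::xml_name(node))

# Fetch an attribute by local name regardless of namespace prefix.
attr_any_ns <- function(node, name) {
  at <- xml2::xml_attrs(node)
  if (length(at) == 0L) return(NA_character_)
  hit <- grepl(paste0("^([A-Za-z_][\\w.-]*:)?", name, "$"), names(at), perl = TRUE)
  if (!any(hit)) return(NA_character_)
  unname(at[which(hit)[1L]])
}

element_children <- function(node) {
  kids <- xml2::xml_children(node)
  kids[vapply(kids, function(k) xml2::xml_type(k) == "element", TRUE)]
}

parse_context <- function(node) {
  paste0(" at ", xml2::xml_path(node))
}

#' Parse a Content MathML fragment into an expression tree
#'
#' Accepts the subset of Content MathML 2.0 used by CellML models and the
#' uncertainty csymbol extension: `math`, `apply`, `lambda`, `vector`,
#' `piecewise`, `ci`, `cn` and `csymbol`.  `csymbol` elements preserve their
#' `definitionURL` verbatim; the CellML `units` attribute on `cn` (from either
#' the CellML 1.0 or 1.1 namespace) is captured and required.
#'
#' @param node An `xml2` element, or a string of XML.
#' @return A `mathml_expr` tree.
#' @export
parse_mathml <- function(node) {
  if (is.character(node)) node <- xml2::read_xml(node)
  nm <- local_name(node)
  switch(nm,
    math = {
      kids <- element_children(node)
      if (length(kids) != 1L) {
        stop("parse error: <math> with ", length(kids),
             " children; parse each child separately", parse_context(node), call. = FALSE)
      }
      parse_mathml(kids[[1L]])
    },
    cn = parse_cn(node),
    ci = mml_var(trimws(xml2::xml_text(node))),
    csymbol = mml_csymbol_apply(xml2::xml_attr(node, "definitionURL")),
    apply = parse_apply(node),
    piecewise = parse_piecewise(node),
    lambda = parse_lambda(node),
    vector = mml_vector(lapply(element_children(node), parse_mathml)),
    pi = mml_constant(pi, "dimensionless"),
    exponentiale = mml_constant(exp(1), "dimensionless"),
    stop("parse error: unsupported element <", nm, ">", parse_context(node),
         call. = FALSE)
  )
}

parse_cn <- function(node) {
  units <- attr_any_ns(node, "units")
  if (is.na(units)) {
    stop("units error: <cn> without a units attribute", parse_context(node),
         call. = FALSE)
  }
  type <- xml2::xml_attr(node, "type")
  txt <- xml2::xml_text(node)
  value <- if (!is.na(type) && type == "e-notation") {
    # mantissa and exponent are the text nodes around <sep/>
    parts <- trimws(vapply(xml2::xml_contents(node), xml2::xml_text, ""))
    parts <- parts[nzchar(parts)]
    if (length(parts) != 2L) {
      stop("parse error: malformed e-notation <cn>", parse_context(node),
           call. = FALSE)
    }
    as.numeric(parts[1L]) * 10^as.numeric(parts[2L])
  } else {
    as.numeric(trimws(txt))
  }
  if (is.na(value)) {
    stop("parse error: non-numeric <cn> content '", txt, "'", parse_context(node),
         call. = FALSE)
  }
  mml_constant(value, units)
}

parse_apply <- function(node) {
  kids <- element_children(node)
  if (length(kids) == 0L) {
    stop("parse error: empty <apply>", parse_context(node), call. = FALSE)
  }
  head <- kids[[1L]]
  rest <- kids[-1L]
  head_nm <- local_name(head)

  if (head_nm == "csymbol") {
    url <- xml2::xml_attr(head, "definitionURL")
    return(mml_csymbol_apply(url, lapply(rest, parse_mathml)))
  }
  if (head_nm == "diff") {
    bvar_idx <- which(vapply(rest, local_name, "") == "bvar")
    if (length(bvar_idx) != 1L) {
      stop("parse error: <diff> requires exactly one <bvar>", parse_context(node),
           call. = FALSE)
    }
    bvar_kids <- element_children(rest[[bvar_idx]])
    target <- rest[-bvar_idx]
    if (length(bvar_kids) != 1L || length(target) != 1L) {
      stop("parse error: malformed <diff>", parse_context(node), call. = FALSE)
    }
    return(mml_apply("diff", list(parse_mathml(bvar_kids[[1L]]),
                                  parse_mathml(target[[1L]]))))
  }
  if (!head_nm %in% SUPPORTED_OPERATORS) {
    stop("parse error: unsupported operator <", head_nm, ">", parse_context(node),
         call. = FALSE)
  }
  # <degree>/<logbase> qualifiers become a leading operand for root/log.
  operands <- list()
  for (k in rest) {
    knm <- local_name(k)
    if (knm %in% c("degree", "logbase")) {
      inner <- element_children(k)
      if (length(inner) != 1L) {
        stop("parse error: malformed <", knm, ">", parse_context(node), call. = FALSE)
      }
      operands <- c(list(parse_mathml(inner[[1L]])), operands)
    } else {
      operands <- c(operands, list(parse_mathml(k)))
    }
  }
  mml_apply(head_nm, operands)
}

parse_piecewise <- function(node) {
  cases <- list()
  otherwise <- NULL
  for (k in element_children(node)) {
    knm <- local_name(k)
    inner <- element_children(k)
    if (knm == "piece") {
      if (length(inner) != 2L) {
        stop("parse error: <piece> needs value and condition", parse_context(node),
             call. = FALSE)
      }
      cases <- c(cases, list(list(value = parse_mathml(inner[[1L]]),
                                  condition = parse_mathml(inner[[2L]]))))
    } else if (knm == "otherwise") {
      if (length(inner) != 1L) {
        stop("parse error: malformed <otherwise>", parse_context(node), call. = FALSE)
      }
      otherwise <- parse_mathml(inner[[1L]])
    } else {
      stop("parse error: unexpected <", knm, "> in <piecewise>", parse_context(node),
           call. = FALSE)
    }
  }
  mml_piecewise(cases, otherwise)
}

parse_lambda <- function(node) {
  bound <- character()
  body <- NULL
  for (k in element_children(node)) {
    if (local_name(k) == "bvar") {
      inner <- element_children(k)
      if (length(inner) != 1L || local_name(inner[[1L]]) != "ci") {
        stop("parse error: malformed lambda <bvar>", parse_context(node), call. = FALSE)
      }
      bound <- c(bound, trimws(xml2::xml_text(inner[[1L]])))
    } else {
      if (!is.null(body)) {
        stop("parse error: lambda with multiple bodies", parse_context(node),
             call. = FALSE)
      }
      body <- parse_mathml(k)
    }
  }
  if (length(bound) == 0L || is.null(body)) {
    stop("parse error: lambda needs bound variables and a body",
         parse_context(node), call. = FALSE)
  }
  mml_lambda(bound, body)
}

# ---------------------------------------------------------------------------
# Serialization (used by write_cellml and round-trip tests)

fmt_num <- function(x) sprintf("%.17g", x)

#' Serialize an expression tree to Content MathML
#'
#' Inverse of [parse_mathml()]: `parse_mathml(serialize_mathml(e))` is
#' structurally identical to `e`.  Constants carry their units through the
#' `cellml:units` attribute; callers embedding the output must declare the
#' `cellml` prefix (as [write_cellml()] does on each `<math>` block).
#'
#' @param expr A `mathml_expr`.
#' @return A character scalar of XML (no `<math>` wrapper).
#' @export
serialize_mathml <- function(expr) {
  stopifnot(is_expr(expr))
  switch(expr$kind,
    cn = paste0('<cn cellml:units="', expr$units, '">', fmt_num(expr$value), "</cn>"),
    ci = paste0("<ci>", expr$variable, "</ci>"),
    csymbol = {
      head <- paste0('<csymbol definitionURL="', expr$definition_url, '"/>')
      if (length(expr$operands) == 0L) head
      else paste0("<apply>", head,
                  paste(vapply(expr$operands, serialize_mathml, ""), collapse = ""),
                  "</apply>")
    },
    apply = serialize_apply(expr),
    piecewise = paste0(
      "<piecewise>",
      paste(vapply(expr$cases, function(cs)
        paste0("<piece>", serialize_mathml(cs$value),
               serialize_mathml(cs$condition), "</piece>"), ""), collapse = ""),
      if (!is.null(expr$otherwise))
        paste0("<otherwise>", serialize_mathml(expr$otherwise), "</otherwise>"),
      "</piecewise>"),
    lambda = paste0(
      "<lambda>",
      paste(vapply(expr$bound_vars, function(v)
        paste0("<bvar><ci>", v, "</ci></bvar>"), ""), collapse = ""),
      serialize_mathml(expr$body), "</lambda>"),
    vector = paste0("<vector>",
                    paste(vapply(expr$elements, serialize_mathml, ""), collapse = ""),
                    "</vector>"),
    stop("cannot serialize kind ", expr$kind)
  )
}

serialize_apply <- function(expr) {
  op <- expr$operator
  ops <- expr$operands
  if (op == "diff") {
    return(paste0("<apply><diff/><bvar>", serialize_mathml(ops[[1L]]),
                  "</bvar>", serialize_mathml(ops[[2L]]), "</apply>"))
  }
  if (op %in% c("root", "log") && length(ops) == 2L) {
    qual <- if (op == "root") "degree" else "logbase"
    return(paste0("<apply><", op, "/><", qual, ">", serialize_mathml(ops[[1L]]),
                  "</", qual, ">", serialize_mathml(ops[[2L]]), "</apply>"))
  }
  paste0("<apply><", op, "/>",
         paste(vapply(ops, serialize_mathml, ""), collapse = ""), "</apply>")
}

# ---------------------------------------------------------------------------
# Environments and evaluation

#' Create an evaluation environment
#'
#' Bindings map names to real values.  A name can be a bare variable name (for
#' canonical model variables and lambda bound variables) or a
#' `"component.variable"` key.  Looking up an unbound name is an error, never a
#' default value.
#'
#' @param bindings Named numeric vector or list of initial bindings.
#' @return An object of class `eval_env`.
#' @export
env_new <- function(bindings = numeric()) {
  b <- as.list(bindings)
  structure(list(bindings = b), class = "eval_env")
}

#' Bind values in an environment (functional update)
#'
#' @param env An `eval_env`.
#' @param bindings Named numeric vector or list.
#' @return A new `eval_env` with the bindings added/overridden.
#' @export
env_bind <- function(env, bindings) {
  b <- env$bindings
  nb <- as.list(bindings)
  b[names(nb)] <- nb
  structure(list(bindings = b), class = "eval_env")
}

env_lookup <- function(env, ref) {
  b <- env$bindings
  if (!is.na(ref$component)) {
    key <- paste0(ref$component, ".", ref$variable)
    v <- b[[key]]
    if (!is.null(v)) return(v)
  }
  v <- b[[ref$variable]]
  if (is.null(v)) {
    stop("unbound variable '", deparse_expr(ref), "' during evaluation",
         call. = FALSE)
  }
  v
}

#' Evaluate an expression to a real number
#'
#' Relational and logical operators evaluate to `1`/`0`; piecewise conditions
#' treat any nonzero value as true and evaluate the first case whose condition
#' holds, falling back to `otherwise`.
#'
#' @param expr A `mathml_expr` (not a lambda or vector literal).
#' @param env An `eval_env` binding every free variable of `expr`.
#' @return A numeric scalar.
#' @export
evaluate <- function(expr, env = env_new()) {
  k <- expr$kind
  if (k == "cn") return(expr$value)
  if (k == "ci") return(env_lookup(env, expr))
  if (k == "apply") {
    op <- expr$operator
    if (op == "diff") {
      key <- paste0("d(", expr$operands[[2L]]$variable, ")/d(",
                    expr$operands[[1L]]$variable, ")")
      v <- env$bindings[[key]]
      if (is.null(v)) stop("unbound derivative ", key, call. = FALSE)
      return(v)
    }
    vals <- vapply(expr$operands, evaluate, 0, env = env)
    return(eval_operator(op, vals, expr))
  }
  if (k == "piecewise") {
    for (cs in expr$cases) {
      if (evaluate(cs$condition, env) != 0) return(evaluate(cs$value, env))
    }
    if (is.null(expr$otherwise)) {
      stop("piecewise with no true case and no otherwise: ", deparse_expr(expr),
           call. = FALSE)
    }
    return(evaluate(expr$otherwise, env))
  }
  stop("cannot evaluate a ", k, " node directly: ", deparse_expr(expr),
       call. = FALSE)
}

eval_operator <- function(op, v, expr) {
  r <- switch(op,
    plus = sum(v),
    minus = if (length(v) == 1L) -v else v[1L] - v[2L],
    times = prod(v),
    divide = v[1L] / v[2L],
    power = v[1L]^v[2L],
    root = if (length(v) == 1L) sqrt(v) else v[2L]^(1 / v[1L]),
    exp = exp(v),
    ln = {
      if (v <= 0) stop("domain error: ln of non-positive value in ",
                       deparse_expr(expr), call. = FALSE)
      log(v)
    },
    log = {
      x <- if (length(v) == 1L) v else v[2L]
      base <- if (length(v) == 1L) 10 else v[1L]
      if (x <= 0) stop("domain error: log of non-positive value in ",
                       deparse_expr(expr), call. = FALSE)
      log(x, base = base)
    },
    abs = abs(v),
    min = min(v),
    max = max(v),
    sin = sin(v), cos = cos(v), tan = tan(v),
    arcsin = asin(v), arccos = acos(v), arctan = atan(v),
    sinh = sinh(v), cosh = cosh(v), tanh = tanh(v),
    floor = floor(v), ceiling = ceiling(v),
    eq = as.numeric(v[1L] == v[2L]),
    neq = as.numeric(v[1L] != v[2L]),
    lt = as.numeric(v[1L] < v[2L]),
    leq = as.numeric(v[1L] <= v[2L]),
    gt = as.numeric(v[1L] > v[2L]),
    geq = as.numeric(v[1L] >= v[2L]),
    and = as.numeric(all(v != 0)),
    or = as.numeric(any(v != 0)),
    not = as.numeric(v == 0),
    xor = as.numeric(sum(v != 0) %% 2 == 1),
    stop("unsupported operator in evaluation: ", op, call. = FALSE)
  )
  if (is.na(r)) {
    stop("domain error evaluating ", deparse_expr(expr), call. = FALSE)
  }
  r
}

#' Apply a lambda to argument values
#'
#' @param fn A `mathml_expr` of kind `"lambda"`.
#' @param args Numeric vector of argument values, one per bound variable.
#' @param env Outer environment visible for other symbols.
#' @return A numeric scalar.
#' @export
apply_lambda <- function(fn, args, env = env_new()) {
  stopifnot(is_expr(fn), fn$kind == "lambda")
  if (length(args) != length(fn$bound_vars)) {
    stop("arity mismatch: lambda of ", length(fn$bound_vars),
         " bound variables applied to ", length(args), " arguments", call. = FALSE)
  }
  evaluate(fn$body, env_bind(env, stats::setNames(as.list(args), fn$bound_vars)))
}

#' Free variables of an expression
#'
#' Bound variables of enclosing lambdas (and `diff` bound variables are kept —
#' the integration variable is a genuine dependency) are excluded.
#'
#' @param expr A `mathml_expr`.
#' @return Character vector of variable keys (bare or `component.variable`),
#'   with set semantics.
#' @export
free_variables <- function(expr) {
  unique(free_vars_rec(expr, character()))
}

free_vars_rec <- function(expr, bound) {
  switch(expr$kind,
    cn = character(),
    ci = {
      key <- if (is.na(expr$component)) expr$variable
             else paste0(expr$component, ".", expr$variable)
      if (expr$variable %in% bound || key %in% bound) character() else key
    },
    apply = unlist(lapply(expr$operands, free_vars_rec, bound = bound)),
    piecewise = c(
      unlist(lapply(expr$cases, function(cs)
        c(free_vars_rec(cs$condition, bound), free_vars_rec(cs$value, bound)))),
      if (!is.null(expr$otherwise)) free_vars_rec(expr$otherwise, bound)),
    lambda = free_vars_rec(expr$body, c(bound, expr$bound_vars)),
    vector = unlist(lapply(expr$elements, free_vars_rec, bound = bound)),
    csymbol = unlist(lapply(expr$operands, free_vars_rec, bound = bound)),
    stop("unknown kind ", expr$kind)
  )
}

# Rewrite every ci reference using `fn(component, variable) -> new bare name`,
# skipping lambda-bound names.  Used to canonicalize model math.
rewrite_vars <- function(expr, fn, bound = character()) {
  switch(expr$kind,
    cn = expr,
    ci = {
      if (expr$variable %in% bound) expr
      else mml_var(fn(expr$component, expr$variable))
    },
    apply = mml_apply(expr$operator,
                      lapply(expr$operands, rewrite_vars, fn = fn, bound = bound)),
    piecewise = mml_piecewise(
      lapply(expr$cases, function(cs)
        list(condition = rewrite_vars(cs$condition, fn, bound),
             value = rewrite_vars(cs$value, fn, bound))),
      if (!is.null(expr$otherwise)) rewrite_vars(expr$otherwise, fn, bound)),
    lambda = mml_lambda(expr$bound_vars,
                        rewrite_vars(expr$body, fn, c(bound, expr$bound_vars))),
    vector = mml_vector(lapply(expr$elements, rewrite_vars, fn = fn, bound = bound)),
    csymbol = mml_csymbol_apply(expr$definition_url,
                                lapply(expr$operands, rewrite_vars, fn = fn,
                                       bound = bound)),
    stop("unknown kind ", expr$kind)
  )
}
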