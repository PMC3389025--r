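# CellML document I/O and the uncertainty csymbol dialect.
#
# Uncertainty is asserted in ordinary <math> blocks with three csymbol
# operators rooted at http://www.cellml.org/uncertainty-1# :
#   uncertainParameterWithDistribution(target(s), distribution)
#   distributionFromDensity(lambda)        -- symbolic p.d.f.
#   distributionFromRealisations(vector)   -- empirical realisations

UNCERTAIN_PARAM_URL <- paste0(UNCERTAINTY_NS, "uncertainParameterWithDistribution")
DENSITY_URL <- paste0(UNCERTAINTY_NS, "distributionFromDensity")
REALISATIONS_URL <- paste0(UNCERTAINTY_NS, "distributionFromRealisations")

#' Density specification for an uncertain parameter
#'
#' @param pdf A lambda `mathml_expr` with exactly one bound variable, mapping
#'   a real to the probability density at that value.
#' @return An object of class `density_spec`.
#' @export
density_spec <- function(pdf) {
  stopifnot(is_expr(pdf), pdf$kind == "lambda")
  if (length(pdf$bound_vars) != 1L) {
    stop("density p.d.f. must be a lambda of exactly one bound variable",
         call. = FALSE)
  }
  if (pdf$body$kind == "cn" && !identical(pdf$body$units, "dimensionless")) {
    warning("probability density values should be annotated 'dimensionless', not '",
            pdf$body$units, "'", call. = FALSE)
  }
  structure(list(pdf = pdf), class = "density_spec")
}

#' Realisations specification for one or more uncertain parameters
#'
#' @param values Numeric vector (univariate) or matrix with one realisation
#'   per row (`k >= 2` columns for a joint tuple).  All values must be finite.
#' @return An object of class `realisations_spec`.
#' @export
realisations_spec <- function(values) {
  m <- if (is.matrix(values)) values else matrix(as.numeric(values), ncol = 1L)
  if (nrow(m) == 0L) stop("realisations vector must be non-empty", call. = FALSE)
  if (!all(is.finite(m))) {
    stop("every realisation must evaluate to a finite real value", call. = FALSE)
  }
  structure(list(values = m), class = "realisations_spec")
}

#' Uncertainty assertion binding targets to a distribution
#'
#' @param targets List of variable-reference expressions (length >= 1).
#' @param spec A [density_spec()] or [realisations_spec()].
#' @return An object of class `uncertainty_assertion`.
#' @export
uncertainty_assertion <- function(targets, spec) {
  stopifnot(length(targets) >= 1L,
            all(vapply(targets, function(t) is_expr(t) && t$kind == "ci", TRUE)))
  if (inherits(spec, "density_spec") && length(targets) != 1L) {
    stop("a density distribution may be attached to exactly one target ",
         "(multivariate densities are not supported)", call. = FALSE)
  }
  if (inherits(spec, "realisations_spec") &&
      ncol(spec$values) != length(targets)) {
    stop("realisation tuple length ", ncol(spec$values),
         " does not match the ", length(targets), " target variable(s)",
         call. = FALSE)
  }
  structure(list(targets = targets, spec = spec), class = "uncertainty_assertion")
}

# ---------------------------------------------------------------------------
# Extraction of assertions from parsed math

#' Extract uncertainty assertions from parsed math expressions
#'
#' Recognizes applications of `uncertainParameterWithDistribution` whose
#' second operand applies `distributionFromDensity` or
#' `distributionFromRealisations`; all other expressions pass through as
#' ordinary math.  Assertions are returned in document order.
#'
#' @param exprs List of parsed `mathml_expr` statements.
#' @return List with `assertions` (list of [uncertainty_assertion()]) and
#'   `remaining` (the non-uncertainty expressions).
#' @export
extract_uncertainty <- function(exprs) {
  assertions <- list()
  remaining <- list()
  for (e in exprs) {
    if (is_expr(e) && e$kind == "csymbol") {
      assertions <- c(assertions, list(parse_assertion(e)))
    } else {
      remaining <- c(remaining, list(e))
    }
  }
  list(assertions = assertions, remaining = remaining)
}

parse_assertion <- function(e) {
  if (!identical(e$definition_url, UNCERTAIN_PARAM_URL)) {
    if (startsWith(e$definition_url %||% "", UNCERTAINTY_NS)) {
      stop("unknown uncertainty operator suffix '",
           sub(UNCERTAINTY_NS, "", e$definition_url, fixed = TRUE),
           "' (expected uncertainParameterWithDistribution, ",
           "distributionFromDensity or distributionFromRealisations)",
           call. = FALSE)
    }
    stop("unsupported csymbol definitionURL '", e$definition_url,
         "' at statement level", call. = FALSE)
  }
  if (length(e$operands) != 2L) {
    stop("uncertainParameterWithDistribution takes two arguments, got ",
         length(e$operands), call. = FALSE)
  }
  tgt <- e$operands[[1L]]
  targets <- if (tgt$kind == "ci") {
    list(tgt)
  } else if (tgt$kind == "vector") {
    if (!all(vapply(tgt$elements, function(x) x$kind == "ci", TRUE))) {
      stop("target vector must contain only variable references", call. = FALSE)
    }
    tgt$elements
  } else {
    stop("first argument of uncertainParameterWithDistribution must be a ",
         "variable or a vector of variables", call. = FALSE)
  }

  dist <- e$operands[[2L]]
  if (dist$kind != "csymbol") {
    stop("second argument of uncertainParameterWithDistribution must be a ",
         "distribution construct", call. = FALSE)
  }
  spec <- if (identical(dist$definition_url, DENSITY_URL)) {
    if (length(dist$operands) != 1L) {
      stop("distributionFromDensity takes a single argument, got ",
           length(dist$operands), call. = FALSE)
    }
    pdf <- dist$operands[[1L]]
    if (pdf$kind != "lambda" || length(pdf$bound_vars) != 1L) {
      stop("distributionFromDensity argument must be a lambda of one bound ",
           "variable", call. = FALSE)
    }
    density_spec(pdf)
  } else if (identical(dist$definition_url, REALISATIONS_URL)) {
    if (length(dist$operands) != 1L || dist$operands[[1L]]$kind != "vector") {
      stop("distributionFromRealisations takes a single vector argument",
           call. = FALSE)
    }
    realisations_spec(eval_realisations(dist$operands[[1L]], length(targets)))
  } else if (startsWith(dist$definition_url %||% "", UNCERTAINTY_NS)) {
    stop("unknown uncertainty operator suffix '",
         sub(UNCERTAINTY_NS, "", dist$definition_url, fixed = TRUE), "'",
         call. = FALSE)
  } else {
    stop("unsupported distribution csymbol '", dist$definition_url, "'",
         call. = FALSE)
  }
  uncertainty_assertion(targets, spec)
}

# Realisation elements are constant expressions evaluated once at load.
eval_realisations <- function(vec, k) {
  elems <- vec$elements
  if (length(elems) == 0L) stop("realisations vector must be non-empty", call. = FALSE)
  kinds <- vapply(elems, function(x) x$kind, "")
  if (all(kinds != "vector")) {
    if (k != 1L) {
      stop("scalar realisations given for ", k, " target variables; each ",
           "element must be a vector of length ", k, call. = FALSE)
    }
    return(vapply(elems, function(x) evaluate(x, env_new()), 0))
  }
  if (!all(kinds == "vector")) {
    stop("realisations vector mixes scalars and tuples", call. = FALSE)
  }
  lens <- vapply(elems, function(x) length(x$elements), 0L)
  if (any(lens != k)) {
    stop("realisation tuple length ", lens[which(lens != k)[1L]],
         " does not match the ", k, " target variable(s)", call. = FALSE)
  }
  t(vapply(elems, function(x)
    vapply(x$elements, function(el) evaluate(el, env_new()), 0), numeric(k)))
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a

# ---------------------------------------------------------------------------
# Model assembly: connection resolution, canonical naming, validation

# Union-find over "component|variable" keys.
uf_new <- function(keys) stats::setNames(keys, keys)
uf_find <- function(uf, k) {
  while (uf[[k]] != k) k <- uf[[k]]
  k
}
uf_union <- function(uf, a, b) {
  ra <- uf_find(uf, a)
  rb <- uf_find(uf, b)
  if (ra != rb) uf[[rb]] <- ra
  uf
}

assemble_model <- function(name, units, components, connections,
                           source_path = NA_character_) {
  var_rows <- do.call(rbind, lapply(components, function(cp) {
    if (nrow(cp$variables) == 0L) return(NULL)
    data.frame(component = cp$name, variable = cp$variables$name,
               units = cp$variables$units,
               initial_value = cp$variables$initial_value,
               stringsAsFactors = FALSE)
  }))
  if (is.null(var_rows)) {
    var_rows <- data.frame(component = character(), variable = character(),
                           units = character(), initial_value = character(),
                           stringsAsFactors = FALSE)
  }
  key <- function(comp, var) paste0(comp, "|", var)
  keys <- if (nrow(var_rows) == 0L) character() else
    key(var_rows$component, var_rows$variable)
  if (anyDuplicated(keys)) {
    stop("variable redefinition: ", keys[duplicated(keys)][1L], call. = FALSE)
  }
  uf <- uf_new(keys)
  for (cn in connections) {
    for (pair in cn$pairs) {
      k1 <- key(cn$component_1, pair[1L])
      k2 <- key(cn$component_2, pair[2L])
      if (!k1 %in% keys || !k2 %in% keys) {
        stop("unresolved connection: ", k1, " <-> ", k2, call. = FALSE)
      }
      uf <- uf_union(uf, k1, k2)
    }
  }
  roots <- vapply(keys, function(k) uf_find(uf, k), "")
  # Canonical display name: the bare variable name when it is unambiguous
  # across connection groups, else "component.variable" of the group root.
  root_var <- sub("^.*\\|", "", roots)
  root_comp <- sub("\\|.*$", "", roots)
  canon_of_root <- character()
  for (r in unique(roots)) {
    v <- sub("^.*\\|", "", r)
    other_groups <- unique(roots[root_var == v])
    canon_of_root[[r]] <- if (length(other_groups) == 1L) v
                          else paste0(sub("\\|.*$", "", r), ".", v)
  }
  var_rows$canonical <- unname(canon_of_root[roots])
  canon_map <- stats::setNames(var_rows$canonical, keys)

  resolver_for <- function(comp) {
    function(component, variable) {
      comp_use <- if (is.na(component)) comp else component
      k <- key(comp_use, variable)
      cv <- canon_map[[k]]
      if (is.null(cv)) {
        stop("variable '", variable, "' referenced in math of component '",
             comp, "' is not declared", call. = FALSE)
      }
      cv
    }
  }

  assignments <- list()
  assertions <- list()
  for (cp in components) {
    res <- resolver_for(cp$name)
    for (e in cp$math) {
      e2 <- rewrite_vars(e, res)
      if (e2$kind == "csymbol") {
        assertions <- c(assertions, list(parse_assertion(e2)))
      } else if (e2$kind == "apply" && e2$operator == "eq" &&
                 length(e2$operands) == 2L) {
        lhs <- e2$operands[[1L]]
        rhs <- e2$operands[[2L]]
        if (lhs$kind == "ci") {
          assignments <- c(assignments, list(list(
            kind = "algebraic", var = lhs$variable, rhs = rhs)))
        } else if (lhs$kind == "apply" && lhs$operator == "diff") {
          assignments <- c(assignments, list(list(
            kind = "rate", var = lhs$operands[[2L]]$variable,
            bound = lhs$operands[[1L]]$variable, rhs = rhs)))
        } else {
          stop("unsupported assignment left-hand side: ", deparse_expr(lhs),
               call. = FALSE)
        }
      } else {
        stop("unsupported statement in component '", cp$name, "': ",
             deparse_expr(e2), call. = FALSE)
      }
    }
  }

  assigned <- vapply(assignments, function(a) a$var, "")
  if (anyDuplicated(assigned)) {
    stop("variable '", assigned[duplicated(assigned)][1L],
         "' is the target of two assignments", call. = FALSE)
  }
  target_names <- unlist(lapply(assertions, function(a)
    vapply(a$targets, function(t) t$variable, "")))
  if (anyDuplicated(target_names)) {
    stop("variable '", target_names[duplicated(target_names)][1L],
         "' is the target of two uncertainty assertions", call. = FALSE)
  }
  both <- intersect(assigned, target_names)
  if (length(both) > 0L) {
    stop("variable '", both[1L], "' is the target of both an assignment and ",
         "an uncertainty assertion", call. = FALSE)
  }
  missing_tgt <- setdiff(target_names, var_rows$canonical)
  if (length(missing_tgt) > 0L) {
    stop("uncertainty target '", missing_tgt[1L], "' is not a declared variable",
         call. = FALSE)
  }

  structure(list(name = name, units = units, components = components,
                 connections = connections, var_table = var_rows,
                 assignments = assignments, uncertainty = assertions,
                 source_path = source_path),
            class = "cellml_model")
}

#' @export
print.cellml_model <- function(x, ...) {
  cat("<cellml_model '", x$name, "': ", length(x$components), " component(s), ",
      nrow(x$var_table), " variable(s), ", length(x$assignments),
      " assignment(s), ", length(x$uncertainty), " uncertainty assertion(s)>\n",
      sep = "")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Loading

#' Load a CellML model
#'
#' Reads a single-document CellML 1.0 or 1.1 model: components, variables,
#' connections and math are parsed, connections are collapsed into canonical
#' logical variables, and uncertainty csymbol constructs are extracted into
#' assertion records (removed from the plain assignment list).  `import`
#' elements are a hard error.
#'
#' @param path Path to the CellML file.
#' @return A `cellml_model` object.
#' @export
load_cellml <- function(path) {
  doc <- xml2::read_xml(path)
  root <- xml2::xml_root(doc)
  ns_uri <- xml2::xml_ns(doc)
  if (local_name(root) != "model" ||
      !any(ns_uri %in% c(CELLML_1_0_NS, CELLML_1_1_NS))) {
    stop("not a CellML 1.0/1.1 model document: ", path, call. = FALSE)
  }
  name <- xml2::xml_attr(root, "name") %||% "model"

  units <- character()
  components <- list()
  connections <- list()
  for (node in element_children(root)) {
    nm <- local_name(node)
    if (nm == "import") {
      stop("CellML import elements are not supported (single-document models only)",
           call. = FALSE)
    } else if (nm == "units") {
      units <- c(units, as.character(node))
    } else if (nm == "component") {
      components <- c(components, list(parse_component(node)))
    } else if (nm == "connection") {
      connections <- c(connections, list(parse_connection(node)))
    }
    # other elements (documentation, RDF) are ignored
  }
  names(components) <- vapply(components, function(cp) cp$name, "")
  assemble_model(name, units, components, connections, source_path = path)
}

parse_component <- function(node) {
  cname <- xml2::xml_attr(node, "name")
  vars <- data.frame(name = character(), units = character(),
                     initial_value = character(), stringsAsFactors = FALSE)
  math <- list()
  for (k in element_children(node)) {
    nm <- local_name(k)
    if (nm == "variable") {
      vn <- xml2::xml_attr(k, "name")
      vu <- xml2::xml_attr(k, "units")
      if (is.na(vu)) {
        stop("units error: variable '", vn, "' in component '", cname,
             "' lacks a units attribute", call. = FALSE)
      }
      vars <- rbind(vars, data.frame(
        name = vn, units = vu,
        initial_value = xml2::xml_attr(k, "initial_value"),
        stringsAsFactors = FALSE))
    } else if (nm == "math") {
      math <- c(math, lapply(element_children(k), parse_mathml))
    }
  }
  list(name = cname, variables = vars, math = math)
}

parse_connection <- function(node) {
  comp1 <- comp2 <- NA_character_
  pairs <- list()
  for (k in element_children(node)) {
    nm <- local_name(k)
    if (nm == "map_components") {
      comp1 <- xml2::xml_attr(k, "component_1")
      comp2 <- xml2::xml_attr(k, "component_2")
    } else if (nm == "map_variables") {
      pairs <- c(pairs, list(c(xml2::xml_attr(k, "variable_1"),
                               xml2::xml_attr(k, "variable_2"))))
    }
  }
  if (is.na(comp1) || is.na(comp2)) {
    stop("connection without map_components", call. = FALSE)
  }
  list(component_1 = comp1, component_2 = comp2, pairs = pairs)
}

# ---------------------------------------------------------------------------
# Writing

#' Write a CellML model
#'
#' Emits CellML 1.1 XML; uncertainty assertions are serialized through the
#' csymbol constructs, so `load_cellml(write_cellml(m, p))` is structurally
#' equal to `m`.
#'
#' @param model A `cellml_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cellml <- function(model, path) {
  stopifnot(inherits(model, "cellml_model"))
  comp_xml <- vapply(model$components, function(cp) {
    vars <- cp$variables
    var_xml <- if (nrow(vars) == 0L) "" else paste(vapply(seq_len(nrow(vars)),
      function(i) paste0(
        '<variable name="', vars$name[i], '" units="', vars$units[i], '"',
        if (!is.na(vars$initial_value[i]))
          paste0(' initial_value="', vars$initial_value[i], '"'),
        "/>"), ""), collapse = "\n    ")
    math_xml <- if (length(cp$math) == 0L) "" else paste0(
      '\n    <math xmlns="', MATHML_NS, '" xmlns:cellml="', CELLML_1_1_NS, '">\n      ',
      paste(vapply(cp$math, serialize_mathml, ""), collapse = "\n      "),
      "\n    </math>")
    paste0('  <component name="', cp$name, '">\n    ', var_xml, math_xml,
           "\n  </component>")
  }, "")
  conn_xml <- vapply(model$connections, function(cn) paste0(
    "  <connection>\n    <map_components component_1=\"", cn$component_1,
    "\" component_2=\"", cn$component_2, "\"/>\n",
    paste(vapply(cn$pairs, function(p) paste0(
      '    <map_variables variable_1="', p[1L], '" variable_2="', p[2L], '"/>'),
      ""), collapse = "\n"),
    "\n  </connection>"), "")
  xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<model name="', model$name, '" xmlns="', CELLML_1_1_NS,
    '" xmlns:cellml="', CELLML_1_1_NS, '">\n',
    paste(model$units, collapse = "\n"), "\n",
    paste(comp_xml, collapse = "\n"), "\n",
    paste(conn_xml, collapse = "\n"), "\n",
    "</model>\n")
  doc <- xml2::read_xml(xml)  # well-formedness check before touching disk
  ok <- tryCatch({
    xml2::write_xml(doc, path)
    TRUE
  }, error = function(e) {
    stop("I/O error writing CellML to '", path, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(path)
}

# ---------------------------------------------------------------------------
# Classification

#' Classify the variables of a model for simulation
#'
#' Partitions every declared (canonical) variable into exactly one of:
#' `states` (appear under `diff` on an assignment left-hand side), `bound`
#' (the differentiation variable), `uncertain` (targets of uncertainty
#' assertions), `constants` (a numeric `initial_value` or an assignment with
#' no free variables) and `algebraic` (assigned an expression).
#'
#' @param model A `cellml_model`.
#' @return A list of character vectors
#'   `list(states, constants, uncertain, algebraic, bound)`.
#' @export
classify_variables <- function(model) {
  stopifnot(inherits(model, "cellml_model"))
  vt <- model$var_table
  all_vars <- unique(vt$canonical)

  states <- unique(vapply(Filter(function(a) a$kind == "rate",
                                 model$assignments), function(a) a$var, ""))
  bound <- unique(vapply(Filter(function(a) a$kind == "rate",
                                model$assignments), function(a) a$bound, ""))
  if (length(bound) > 1L) {
    stop("differentiation with respect to more than one bound variable: ",
         paste(bound, collapse = ", "), call. = FALSE)
  }
  uncertain <- unlist(lapply(model$uncertainty, function(a)
    vapply(a$targets, function(t) t$variable, "")))
  if (is.null(uncertain)) uncertain <- character()

  alg_assign <- Filter(function(a) a$kind == "algebraic", model$assignments)
  alg_vars <- vapply(alg_assign, function(a) a$var, character(1L))
  constants <- character()
  algebraic <- character()
  for (a in alg_assign) {
    fv <- free_variables(a$rhs)
    if (length(fv) == 0L) constants <- c(constants, a$var)
    else algebraic <- c(algebraic, a$var)
  }

  # numeric initial_value (and no equation) => constant
  iv_num <- suppressWarnings(as.numeric(vt$initial_value))
  for (i in seq_len(nrow(vt))) {
    cv <- vt$canonical[i]
    if (cv %in% c(states, bound, uncertain, constants, algebraic)) next
    if (!is.na(vt$initial_value[i]) && !is.na(iv_num[i])) {
      constants <- c(constants, cv)
    }
  }
  constants <- unique(constants)

  leftover <- setdiff(all_vars, c(states, bound, uncertain, constants, algebraic))
  if (length(leftover) > 0L) {
    stop("underdetermined model: variable(s) ",
         paste(leftover, collapse = ", "),
         " have no defining assignment and are not uncertain or bound",
         call. = FALSE)
  }

  # algebraic-loop check (DAE systems are not supported)
  topo_sort_algebraic(alg_assign[vapply(alg_assign, function(a)
    a$var %in% algebraic, TRUE)])

  list(states = states, constants = constants, uncertain = unique(uncertain),
       algebraic = algebraic, bound = bound)
}

# Topological sort of algebraic assignments by rhs dependencies among
# themselves; a cycle is an algebraic-loop error.
topo_sort_algebraic <- function(assigns) {
  if (length(assigns) == 0L) return(assigns)
  vars <- vapply(assigns, function(a) a$var, "")
  deps <- lapply(assigns, function(a) intersect(free_variables(a$rhs), vars))
  ordered <- list()
  done <- character()
  remaining <- seq_along(assigns)
  while (length(remaining) > 0L) {
    ready <- remaining[vapply(remaining, function(i)
      all(deps[[i]] %in% done), TRUE)]
    if (length(ready) == 0L) {
      stop("algebraic-loop error: cyclic dependency among ",
           paste(vars[remaining], collapse = ", "),
           " (DAE systems are not supported)", call. = FALSE)
    }
    for (i in ready) {
      ordered <- c(ordered, list(assigns[[i]]))
      done <- c(done, vars[i])
    }
    remaining <- setdiff(remaining, ready)
  }
  ordered
}

# Structural model equality (round-trip testing helper).
model_equal <- function(m1, m2) {
  if (!identical(m1$name, m2$name)) return(FALSE)
  if (length(m1$components) != length(m2$components)) return(FALSE)
  for (nm in names(m1$components)) {
    c1 <- m1$components[[nm]]
    c2 <- m2$components[[nm]]
    if (is.null(c2)) return(FALSE)
    v1 <- c1$variables[order(c1$variables$name), , drop = FALSE]
    v2 <- c2$variables[order(c2$variables$name), , drop = FALSE]
    if (!isTRUE(all.equal(v1$name, v2$name)) ||
        !isTRUE(all.equal(v1$units, v2$units))) return(FALSE)
  }
  if (length(m1$assignments) != length(m2$assignments)) return(FALSE)
  for (i in seq_along(m1$assignments)) {
    if (!identical(m1$assignments[[i]], m2$assignments[[i]])) return(FALSE)
  }
  if (length(m1$uncertainty) != length(m2$uncertainty)) return(FALSE)
  for (i in seq_along(m1$uncertainty)) {
    a1 <- m1$uncertainty[[i]]
    a2 <- m2$uncertainty[[i]]
    if (!identical(vapply(a1$targets, function(t) t$variable, ""),
                   vapply(a2$targets, function(t) t$variable, ""))) return(FALSE)
    if (!identical(class(a1$spec), class(a2$spec))) return(FALSE)
    if (inherits(a1$spec, "density_spec")) {
      if (!identical(a1$spec$pdf, a2$spec$pdf)) return(FALSE)
    } else {
      if (!isTRUE(all.equal(a1$spec$values, a2$spec$values))) return(FALSE)
    }
  }
  TRUE
}
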