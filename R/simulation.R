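# Compile a model into an executable ODE-IV evaluation plan and integrate
# time courses with an adaptive Dormand-Prince Runge-Kutta 4(5) method.
# (No ODE solver package is assumed; the integrator is self-contained.)

#' Time-course specification
#'
#' @param initial_time Time at which initial values hold.
#' @param output_start First reported time (`>= initial_time`).
#' @param output_end Last reported time (`>= output_start`).
#' @param number_of_points Number of reporting intervals; the output grid has
#'   `number_of_points + 1` uniformly spaced entries (a single row when
#'   `output_start == output_end`).
#' @param solver List of solver controls: `method` (only `"rk45"`), `rel_tol`,
#'   `abs_tol`, `max_step`.
#' @return An object of class `time_course_spec`.
#' @export
time_course_spec <- function(initial_time = 0, output_start = 0,
                             output_end = 10, number_of_points = 100L,
                             solver = list()) {
  if (!(initial_time <= output_start && output_start <= output_end)) {
    stop("require initial_time <= output_start <= output_end", call. = FALSE)
  }
  if (number_of_points < 1L) {
    stop("number_of_points must be >= 1", call. = FALSE)
  }
  sv <- utils::modifyList(list(method = "rk45", rel_tol = 1e-8,
                               abs_tol = 1e-10, max_step = Inf), solver)
  structure(list(initial_time = initial_time, output_start = output_start,
                 output_end = output_end,
                 number_of_points = as.integer(number_of_points), solver = sv),
            class = "time_course_spec")
}

#' Compile a model into an evaluation plan
#'
#' Resolves the variable classification, topologically orders the algebraic
#' assignments, folds constants, and records the rate expression of every
#' state plus how each state's initial value is obtained (a number, a
#' constant, or an uncertain parameter slot).  The resulting rate evaluation
#' is side-effect free.
#'
#' @param model A `cellml_model`.
#' @return An object of class `evaluation_plan`.
#' @export
compile_plan <- function(model) {
  cls <- classify_variables(model)
  rates <- Filter(function(a) a$kind == "rate", model$assignments)
  rate_exprs <- stats::setNames(lapply(rates, function(a) a$rhs),
                                vapply(rates, function(a) a$var, ""))
  alg <- Filter(function(a) a$kind == "algebraic", model$assignments)
  const_assign <- alg[vapply(alg, function(a) a$var %in% cls$constants, TRUE)]
  alg <- alg[vapply(alg, function(a) a$var %in% cls$algebraic, TRUE)]
  alg <- topo_sort_algebraic(alg)

  constants <- numeric()
  for (a in const_assign) constants[[a$var]] <- evaluate(a$rhs, env_new())
  vt <- model$var_table
  iv_num <- suppressWarnings(as.numeric(vt$initial_value))
  for (i in seq_len(nrow(vt))) {
    cv <- vt$canonical[i]
    if (cv %in% cls$constants && !cv %in% names(constants) &&
        !is.na(iv_num[i])) {
      constants[[cv]] <- iv_num[i]
    }
  }

  # How each state gets its initial value.
  initial <- list()
  for (s in cls$states) {
    rows <- vt[vt$canonical == s & !is.na(vt$initial_value), , drop = FALSE]
    if (nrow(rows) == 0L) {
      stop("underdetermined model: state '", s, "' has no initial value",
           call. = FALSE)
    }
    iv <- rows$initial_value[1L]
    ivn <- suppressWarnings(as.numeric(iv))
    initial[[s]] <- if (!is.na(ivn)) {
      list(kind = "number", value = ivn)
    } else {
      # initial_value names another variable; resolve to its canonical form
      ref_rows <- vt[vt$component == rows$component[1L] & vt$variable == iv, ,
                     drop = FALSE]
      ref <- if (nrow(ref_rows) > 0L) ref_rows$canonical[1L] else iv
      if (!ref %in% c(cls$constants, cls$uncertain)) {
        stop("state '", s, "' initial value references '", iv,
             "', which is neither a constant nor an uncertain parameter",
             call. = FALSE)
      }
      list(kind = "ref", ref = ref)
    }
  }

  structure(list(states = cls$states, rate_exprs = rate_exprs,
                 algebraic = alg, constants = constants,
                 parameter_slots = cls$uncertain,
                 bound_var = if (length(cls$bound)) cls$bound else character(),
                 initial = initial),
            class = "evaluation_plan")
}

#' @export
print.evaluation_plan <- function(x, ...) {
  cat("<evaluation_plan: ", length(x$states), " state(s), ",
      length(x$algebraic), " algebraic, ", length(x$constants), " constant(s), ",
      length(x$parameter_slots), " parameter slot(s)>\n", sep = "")
  invisible(x)
}

plan_env <- function(plan, draw_values) {
  missing_slots <- setdiff(plan$parameter_slots, names(draw_values))
  if (length(missing_slots) > 0L) {
    stop("parameter draw does not fill slot(s): ",
         paste(missing_slots, collapse = ", "), call. = FALSE)
  }
  env_bind(env_new(plan$constants), draw_values)
}

eval_algebraic <- function(plan, env) {
  for (a in plan$algebraic) {
    env <- env_bind(env, stats::setNames(list(evaluate(a$rhs, env)), a$var))
  }
  env
}

# Dormand-Prince 5(4) tableau.
DP_A <- list(
  c(1 / 5),
  c(3 / 40, 9 / 40),
  c(44 / 45, -56 / 15, 32 / 9),
  c(19372 / 6561, -25360 / 2187, 64448 / 6561, -212 / 729),
  c(9017 / 3168, -355 / 33, 46732 / 5247, 49 / 176, -5103 / 18656),
  c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84))
DP_C <- c(1 / 5, 3 / 10, 4 / 5, 8 / 9, 1, 1)
DP_B5 <- c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84, 0)
DP_B4 <- c(5179 / 57600, 0, 7571 / 16695, 393 / 640, -92097 / 339200,
           187 / 2100, 1 / 40)

# Integrate dy/dt = f(t, y) from t0 to t1 with adaptive step control.
rk45_integrate <- function(f, t0, y0, t1, rel_tol, abs_tol, max_step) {
  if (t1 <= t0 || length(y0) == 0L) return(y0)
  t <- t0
  y <- y0
  h <- min(max_step, (t1 - t0) / 10)
  k1 <- f(t, y)
  for (step in seq_len(100000L)) {
    if (t >= t1 - 1e-14 * max(1, abs(t1))) return(y)
    h <- min(h, t1 - t)
    ks <- matrix(0, nrow = 7L, ncol = length(y))
    ks[1L, ] <- k1
    for (i in seq_len(6L)) {
      yi <- y + h * drop(DP_A[[i]] %*% ks[seq_len(i), , drop = FALSE])
      ks[i + 1L, ] <- f(t + DP_C[i] * h, yi)
    }
    y5 <- y + h * drop(DP_B5 %*% ks)
    y4 <- y + h * drop(DP_B4 %*% ks)
    sc <- abs_tol + rel_tol * pmax(abs(y), abs(y5))
    err <- sqrt(mean(((y5 - y4) / sc)^2))
    if (!is.finite(err)) {
      stop("integration error: non-finite state at t = ", fmt_num(t),
           call. = FALSE)
    }
    if (err <= 1) {
      t <- t + h
      y <- y5
      k1 <- ks[7L, ]  # FSAL
    }
    fac <- if (err > 0) 0.9 * err^(-0.2) else 5
    h <- h * min(5, max(0.2, fac))
    h <- min(h, max_step)
    if (h < 1e-14 * max(1, abs(t))) {
      stop("integration error: step-size underflow at t = ", fmt_num(t),
           call. = FALSE)
    }
  }
  stop("integration error: step limit exceeded; last good time t = ",
       fmt_num(t), call. = FALSE)
}

#' Run a single time course
#'
#' Integrates the plan's ODE system for one parameter draw and reports the
#' states (and algebraic variables) on the uniform output grid.
#'
#' @param plan An [compile_plan()] result.
#' @param draw A `parameter_draw` filling every parameter slot (may be an
#'   empty draw when the model has no uncertain parameters).
#' @param spec A [time_course_spec()].
#' @return An object of class `trajectory`: `times`, a `values` matrix
#'   (time x variable, bound variable first), and the `draw` used.
#' @export
run_time_course <- function(plan, draw = NULL, spec = time_course_spec()) {
  stopifnot(inherits(plan, "evaluation_plan"))
  draw_values <- if (is.null(draw)) numeric() else draw$values
  env0 <- plan_env(plan, draw_values)

  y0 <- vapply(plan$states, function(s) {
    iv <- plan$initial[[s]]
    if (iv$kind == "number") iv$value else env_lookup(env0, mml_var(iv$ref))
  }, 0)

  bv <- if (length(plan$bound_var)) plan$bound_var else ".t"
  deriv <- function(t, y) {
    env <- env_bind(env0, c(stats::setNames(as.list(y), plan$states),
                            stats::setNames(list(t), bv)))
    env <- eval_algebraic(plan, env)
    vapply(plan$states, function(s) evaluate(plan$rate_exprs[[s]], env), 0)
  }

  times <- if (spec$output_start == spec$output_end) {
    spec$output_start
  } else {
    seq(spec$output_start, spec$output_end,
        length.out = spec$number_of_points + 1L)
  }

  sv <- spec$solver
  y <- rk45_integrate(deriv, spec$initial_time, y0, times[1L],
                      sv$rel_tol, sv$abs_tol, sv$max_step)
  alg_vars <- vapply(plan$algebraic, function(a) a$var, "")
  cols <- c(if (length(plan$bound_var)) plan$bound_var, plan$states, alg_vars)
  values <- matrix(NA_real_, nrow = length(times), ncol = length(cols),
                   dimnames = list(NULL, cols))
  record <- function(i, t, y) {
    env <- env_bind(env0, c(stats::setNames(as.list(y), plan$states),
                            stats::setNames(list(t), bv)))
    env <- eval_algebraic(plan, env)
    row <- c(if (length(plan$bound_var)) t, y,
             vapply(alg_vars, function(v) env_lookup(env, mml_var(v)), 0))
    values[i, ] <<- row
  }
  record(1L, times[1L], y)
  if (length(times) > 1L) {
    for (i in 2L:length(times)) {
      y <- rk45_integrate(deriv, times[i - 1L], y, times[i],
                          sv$rel_tol, sv$abs_tol, sv$max_step)
      record(i, times[i], y)
    }
  }
  structure(list(times = times, values = values, draw = draw),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory: ", length(x$times), " time point(s) x ",
      ncol(x$values), " variable(s)>\n", sep = "")
  invisible(x)
}
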