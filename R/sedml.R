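# SED-ML Level 1 subset: models, uniform time courses (plus the
# SamplingSensitivityAnalysis extension), tasks, identity data generators
# and report outputs.  The extension is recognized through the attribute
# numberOfSamples in the namespace http://www.cellml.org/uncertainty-1# on
# the simulation element (a samplingSensitivityAnalysis element name is also
# accepted).

#' Load a SED-ML experiment description
#'
#' @param path Path to a SED-ML Level 1 XML file.
#' @return An object of class `sedml_experiment` with fields `models`,
#'   `simulations`, `tasks`, `data_generators`, `outputs` and `path`.
#' @export
load_sedml <- function(path) {
  doc <- xml2::read_xml(path)
  root <- xml2::xml_root(doc)
  if (local_name(root) != "sedML") {
    stop("not a SED-ML document: ", path, call. = FALSE)
  }
  models <- list()
  simulations <- list()
  tasks <- list()
  dgs <- list()
  outputs <- list()
  for (sect in element_children(root)) {
    nm <- local_name(sect)
    for (node in element_children(sect)) {
      knm <- local_name(node)
      id <- xml2::xml_attr(node, "id")
      if (nm == "listOfModels" && knm == "model") {
        models[[id]] <- list(id = id, source = xml2::xml_attr(node, "source"),
                             language = xml2::xml_attr(node, "language"))
      } else if (nm == "listOfSimulations") {
        simulations[[id]] <- parse_sedml_simulation(node, knm)
      } else if (nm == "listOfTasks" && knm == "task") {
        tasks[[id]] <- list(id = id,
                            model = xml2::xml_attr(node, "modelReference"),
                            simulation = xml2::xml_attr(node, "simulationReference"))
      } else if (nm == "listOfDataGenerators" && knm == "dataGenerator") {
        dgs[[id]] <- parse_data_generator(node)
      } else if (nm == "listOfOutputs" && knm == "report") {
        outputs[[id]] <- parse_report_output(node)
      }
    }
  }
  exp <- structure(list(models = models, simulations = simulations,
                        tasks = tasks, data_generators = dgs,
                        outputs = outputs, path = path),
                   class = "sedml_experiment")
  validate_sedml(exp)
  exp
}

parse_sedml_simulation <- function(node, knm) {
  id <- xml2::xml_attr(node, "id")
  num_attr <- function(name, default = NA_real_) {
    v <- attr_any_ns(node, name)
    if (is.na(v)) default else as.numeric(v)
  }
  sim <- list(id = id,
              initial_time = num_attr("initialTime", 0),
              output_start = num_attr("outputStartTime", 0),
              output_end = num_attr("outputEndTime"),
              number_of_points = as.integer(num_attr("numberOfPoints", 100)))
  alg <- Filter(function(k) local_name(k) == "algorithm", element_children(node))
  sim$algorithm <- if (length(alg) > 0L) xml2::xml_attr(alg[[1L]], "kisaoID")
                   else NA_character_
  n_samples <- attr_any_ns(node, "numberOfSamples")
  if (knm == "samplingSensitivityAnalysis" || !is.na(n_samples)) {
    if (is.na(n_samples)) {
      stop("validation error: samplingSensitivityAnalysis simulation '", id,
           "' lacks the numberOfSamples attribute", call. = FALSE)
    }
    sim$type <- "SamplingSensitivityAnalysis"
    sim$number_of_samples <- as.integer(as.numeric(n_samples))
    if (is.na(sim$number_of_samples) || sim$number_of_samples < 1L) {
      stop("validation error: numberOfSamples must be an integer >= 1, got '",
           n_samples, "'", call. = FALSE)
    }
  } else if (knm == "uniformTimeCourse") {
    sim$type <- "UniformTimeCourse"
  } else {
    stop("unsupported simulation element <", knm, ">", call. = FALSE)
  }
  sim
}

# Data generators are restricted to a single-variable identity map.
parse_data_generator <- function(node) {
  id <- xml2::xml_attr(node, "id")
  vars <- list()
  for (sect in element_children(node)) {
    if (local_name(sect) == "listOfVariables") {
      for (v in element_children(sect)) {
        vars <- c(vars, list(list(
          id = xml2::xml_attr(v, "id"),
          task = xml2::xml_attr(v, "taskReference"),
          target = xml2::xml_attr(v, "target") %||% xml2::xml_attr(v, "symbol"))))
      }
    }
  }
  if (length(vars) != 1L) {
    stop("data generator '", id, "' must reference exactly one variable ",
         "(identity generators only)", call. = FALSE)
  }
  list(id = id, task = vars[[1L]]$task, variable = sedml_target_variable(vars[[1L]]$target))
}

# Accept either a bare variable name, an xpath-ish CellML target, or the
# SED-ML time symbol urn.
sedml_target_variable <- function(target) {
  if (is.na(target)) stop("data generator variable lacks target/symbol", call. = FALSE)
  if (grepl("^urn:sedml:symbol:time$", target)) return("time")
  m <- regmatches(target, regexec("@name='([^']+)'\\]?$", target))[[1L]]
  if (length(m) == 2L) return(m[2L])
  target
}

parse_report_output <- function(node) {
  id <- xml2::xml_attr(node, "id")
  datasets <- list()
  for (sect in element_children(node)) {
    if (local_name(sect) == "listOfDataSets") {
      for (ds in element_children(sect)) {
        datasets <- c(datasets, list(list(
          id = xml2::xml_attr(ds, "id"),
          label = xml2::xml_attr(ds, "label"),
          data_generator = xml2::xml_attr(ds, "dataReference"))))
      }
    }
  }
  list(id = id, datasets = datasets)
}

validate_sedml <- function(exp) {
  for (tk in exp$tasks) {
    if (is.null(exp$models[[tk$model]])) {
      stop("validation error: task '", tk$id, "' references undeclared model '",
           tk$model, "'", call. = FALSE)
    }
    if (is.null(exp$simulations[[tk$simulation]])) {
      stop("validation error: task '", tk$id,
           "' references undeclared simulation '", tk$simulation, "'",
           call. = FALSE)
    }
  }
  for (dg in exp$data_generators) {
    if (!is.null(dg$task) && !is.na(dg$task) && is.null(exp$tasks[[dg$task]])) {
      stop("validation error: data generator '", dg$id,
           "' references undeclared task '", dg$task, "'", call. = FALSE)
    }
  }
  invisible(exp)
}

#' @export
print.sedml_experiment <- function(x, ...) {
  cat("<sedml_experiment: ", length(x$models), " model(s), ",
      length(x$simulations), " simulation(s), ", length(x$tasks), " task(s)>\n",
      sep = "")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Execution

sim_to_time_course <- function(sim, solver = list()) {
  time_course_spec(initial_time = sim$initial_time,
                   output_start = sim$output_start,
                   output_end = sim$output_end,
                   number_of_points = sim$number_of_points,
                   solver = solver)
}

#' Run a SED-ML experiment
#'
#' Executes every task.  A `UniformTimeCourse` draws one parameter set and one
#' trajectory; a `SamplingSensitivityAnalysis` draws `numberOfSamples`
#' independent parameter sets, each with a full trajectory, from a single
#' random stream seeded with `master_seed` (so a run with
#' `numberOfSamples = 1` is bit-identical to the single time course at the
#' same seed).  On a per-sample failure the whole ensemble fails, reporting
#' the sample index and the number of completed samples.
#'
#' @param exp A [load_sedml()] result.
#' @param master_seed Integer seed for all sampling in the run.
#' @param model_dir Directory against which relative model sources resolve
#'   (defaults to the SED-ML file's directory).
#' @param models Optional named list of pre-loaded `cellml_model` objects
#'   keyed by model id, overriding file loading.
#' @param settings A [quadrature_settings()] for density sampling.
#' @param solver Solver overrides for [time_course_spec()].
#' @return Named list (by task id) of `ensemble_result` objects.
#' @export
run_experiment <- function(exp, master_seed, model_dir = NULL, models = NULL,
                           settings = quadrature_settings(), solver = list()) {
  stopifnot(inherits(exp, "sedml_experiment"))
  if (is.null(model_dir)) {
    model_dir <- if (!is.null(exp$path) && !is.na(exp$path)) dirname(exp$path) else "."
  }
  results <- list()
  for (tk in exp$tasks) {
    mref <- exp$models[[tk$model]]
    model <- if (!is.null(models) && !is.null(models[[tk$model]])) {
      models[[tk$model]]
    } else {
      src <- mref$source
      if (!file.exists(src)) src <- file.path(model_dir, mref$source)
      if (!file.exists(src)) {
        stop("unresolvable model reference '", tk$model, "' (source '",
             mref$source, "')", call. = FALSE)
      }
      load_cellml(src)
    }
    sim <- exp$simulations[[tk$simulation]]
    n <- if (identical(sim$type, "SamplingSensitivityAnalysis"))
      sim$number_of_samples else 1L
    plan <- compile_plan(model)
    tc <- sim_to_time_course(sim, solver)
    rng <- rng_stream(master_seed)
    samples <- vector("list", n)
    for (i in seq_len(n)) {
      samples[[i]] <- tryCatch({
        draw <- draw_parameter_set(model$uncertainty, env_new(), rng, settings)
        list(draw = draw, trajectory = run_time_course(plan, draw, tc))
      }, error = function(e) {
        stop("ensemble failed at sample ", i, " of ", n, " (",
             i - 1L, " completed): ", conditionMessage(e), call. = FALSE)
      })
    }
    results[[tk$id]] <- structure(
      list(samples = samples, master_seed = as.integer(master_seed),
           task = tk$id, simulation_type = sim$type,
           variables = colnames(samples[[1L]]$trajectory$values)),
      class = "ensemble_result")
  }
  results
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat("<ensemble_result '", x$task, "': ", length(x$samples), " sample(s), ",
      length(x$variables), " variable(s)>\n", sep = "")
  invisible(x)
}

#' Write ensemble results as CSV reports
#'
#' Writes a long-format values file (`sample_index, time, variable, value`)
#' and a companion draws file (`sample_index, parameter, value`; path derived
#' by inserting `_draws` before the extension) with deterministic row order:
#' sample, then time, then variable in trajectory column order.
#'
#' @param result An `ensemble_result`.
#' @param path Output CSV path for the values file.
#' @param variables Optional subset of variables to report.
#' @return Invisibly, `c(values = path, draws = draws_path)`.
#' @export
write_report <- function(result, path, variables = NULL) {
  stopifnot(inherits(result, "ensemble_result"))
  if (length(result$samples) == 0L) {
    stop("empty ensemble: nothing to report", call. = FALSE)
  }
  vars <- variables %||% result$variables
  rows <- lapply(seq_along(result$samples), function(i) {
    tr <- result$samples[[i]]$trajectory
    vv <- tr$values[, vars, drop = FALSE]
    data.frame(sample_index = i,
               time = rep(tr$times, times = length(vars)),
               variable = rep(vars, each = length(tr$times)),
               value = as.vector(vv),
               stringsAsFactors = FALSE)
  })
  values_df <- do.call(rbind, rows)
  # order: sample, time, variable column order
  values_df <- values_df[order(values_df$sample_index,
                               values_df$time,
                               match(values_df$variable, vars)), ]
  utils::write.csv(values_df, path, row.names = FALSE)

  draw_rows <- lapply(seq_along(result$samples), function(i) {
    dv <- result$samples[[i]]$draw$values
    if (length(dv) == 0L) return(NULL)
    data.frame(sample_index = i, parameter = names(dv), value = unname(dv),
               stringsAsFactors = FALSE)
  })
  draws_path <- sub("(\\.[A-Za-z0-9]+)?$", "_draws.csv",
                    sub("\\.csv$", "", path))
  draws_df <- do.call(rbind, draw_rows)
  if (is.null(draws_df)) {
    draws_df <- data.frame(sample_index = integer(), parameter = character(),
                           value = numeric())
  }
  utils::write.csv(draws_df, draws_path, row.names = FALSE)
  invisible(c(values = path, draws = draws_path))
}

#' Summarize an ensemble at one output time
#'
#' @param result An `ensemble_result`.
#' @param variable Reported variable name.
#' @param time A time on the output grid.
#' @return List with `mean`, `sd` and `quantiles` (2.5/25/50/75/97.5%).
#' @export
summarize_endpoint <- function(result, variable, time) {
  stopifnot(inherits(result, "ensemble_result"))
  if (!variable %in% result$variables) {
    stop("variable '", variable, "' is not reported by this ensemble",
         call. = FALSE)
  }
  times <- result$samples[[1L]]$trajectory$times
  idx <- which(abs(times - time) <= 1e-9 * max(1, abs(time)))
  if (length(idx) == 0L) {
    stop("time ", time, " is not on the output grid", call. = FALSE)
  }
  vals <- vapply(result$samples, function(s)
    s$trajectory$values[idx[1L], variable], 0)
  list(mean = mean(vals),
       sd = stats::sd(vals),
       quantiles = stats::quantile(vals, c(0.025, 0.25, 0.5, 0.75, 0.975),
                                   names = TRUE))
}

#' Plot ensemble trajectories in the (x, y) plane
#'
#' Qualitative path plot: one curve per sample.
#'
#' @param result An `ensemble_result`.
#' @param x,y Variable names for the two axes.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `result`.
#' @export
plot_ensemble_paths <- function(result, x = "x", y = "y", ...) {
  stopifnot(inherits(result, "ensemble_result"))
  xs <- lapply(result$samples, function(s) s$trajectory$values[, x])
  ys <- lapply(result$samples, function(s) s$trajectory$values[, y])
  graphics::plot(range(unlist(xs)), range(unlist(ys)), type = "n",
                 xlab = x, ylab = y, ...)
  for (i in seq_along(xs)) graphics::lines(xs[[i]], ys[[i]], col = i)
  invisible(result)
}

#' Scatter plot of ensemble endpoints at a fixed time
#'
#' @inheritParams plot_ensemble_paths
#' @param time Grid time at which to take the endpoint.
#' @return Invisibly, a two-column matrix of endpoints.
#' @export
plot_endpoint_scatter <- function(result, x = "x", y = "y", time, ...) {
  stopifnot(inherits(result, "ensemble_result"))
  times <- result$samples[[1L]]$trajectory$times
  idx <- which(abs(times - time) <= 1e-9 * max(1, abs(time)))[1L]
  pts <- t(vapply(result$samples, function(s)
    c(s$trajectory$values[idx, x], s$trajectory$values[idx, y]), numeric(2L)))
  graphics::plot(pts[, 1L], pts[, 2L], xlab = x, ylab = y, ...)
  invisible(pts)
}
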