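# Fixture generation: the two-spring mixture posterior that supplies the
# realisation vector for the initial y velocity, the projectile example model
# (uncertain initial position and velocity, constant acceleration), and the
# two SED-ML experiment documents.

#' Configuration of the two-spring mixture model
#'
#' An object is launched by one of two springs, chosen with equal
#' probability.  Each spring imparts a normally distributed initial velocity
#' with unknown per-spring mean and variance.  Priors: mean ~ N(9, 0.5^2);
#' variance ~ Exponential(rate 20).  The observed data are 40 velocities,
#' twenty equal to 6 and twenty equal to 12, with spring labels unknown.
#'
#' @param mixture_weight Probability of spring 1.
#' @param prior_mean_mu,prior_sd_mu Normal prior on each per-spring mean.
#' @param variance_prior_rate Rate of the exponential prior on each
#'   per-spring variance.
#' @param data Observed velocity data.
#' @param burn_in Discarded initial iterations.
#' @param retained Retained posterior draws.
#' @param rw_step Random-walk step (log-variance scale) of the Metropolis
#'   update.
#' @param log_var_floor Lower bound on log variance.  The all-6s/all-12s
#'   dataset makes the variance posterior improper (a locked component has a
#'   sum of squares of exactly zero), so the chain's log variance would drift
#'   to minus infinity; proposals below the floor are rejected.  Every
#'   reported summary is insensitive to the bound.
#' @return An object of class `spring_mixture_config`.
#' @export
spring_mixture_config <- function(mixture_weight = 0.5,
                                  prior_mean_mu = 9,
                                  prior_sd_mu = 0.5,
                                  variance_prior_rate = 20,
                                  data = c(rep(6, 20), rep(12, 20)),
                                  burn_in = 1000L,
                                  retained = 1000L,
                                  rw_step = 0.5,
                                  log_var_floor = -60) {
  structure(list(mixture_weight = mixture_weight,
                 prior_mean_mu = prior_mean_mu, prior_sd_mu = prior_sd_mu,
                 variance_prior_rate = variance_prior_rate,
                 data = data, burn_in = as.integer(burn_in),
                 retained = as.integer(retained), rw_step = rw_step,
                 log_var_floor = log_var_floor),
            class = "spring_mixture_config")
}

#' Generate the spring calibration dataset
#'
#' Deterministic: twenty values of 6 followed by twenty values of 12 (the
#' default), or whatever `config$data` holds.
#'
#' @param config A [spring_mixture_config()].
#' @return Numeric vector.
#' @export
generate_spring_data <- function(config = spring_mixture_config()) {
  config$data
}

#' Metropolis-within-Gibbs sampler for the two-spring mixture posterior
#'
#' Gibbs updates for the latent spring labels (Bernoulli posterior
#' proportional to `weight * N(y_i | mu_k, sigma2_k)`) and for each mean
#' (conjugate normal given the labels); random-walk Metropolis on the log
#' variance under the exponential prior.  A component with zero assigned
#' points falls back to a prior-only update, never an error.
#'
#' @param config A [spring_mixture_config()].
#' @param rng An [rng_stream()].
#' @return An object of class `mcmc_chain`: matrices `mu` and `sigma2`
#'   (`retained x 2`), integer label matrix `s` (`retained x n`), and
#'   `diagnostics` with Metropolis acceptance rates.
#' @export
run_mixture_mcmc <- function(config = spring_mixture_config(), rng) {
  y <- config$data
  n <- length(y)
  w <- config$mixture_weight
  m0 <- config$prior_mean_mu
  v0 <- config$prior_sd_mu^2
  rate <- config$variance_prior_rate
  total <- config$burn_in + config$retained

  mu <- c(m0, m0) + 0.1 * c(-1, 1)
  lv <- rep(log(1 / rate), 2L)  # prior mean variance
  s <- ifelse(rng_uniform(rng, n) < w, 1L, 2L)

  keep_mu <- matrix(NA_real_, config$retained, 2L)
  keep_s2 <- matrix(NA_real_, config$retained, 2L)
  keep_s <- matrix(NA_integer_, config$retained, n)
  acc <- c(0L, 0L)
  prop <- c(0L, 0L)

  for (it in seq_len(total)) {
    sig2 <- exp(lv)
    # labels
    l1 <- log(w) + stats::dnorm(y, mu[1L], sqrt(sig2[1L]), log = TRUE)
    l2 <- log(1 - w) + stats::dnorm(y, mu[2L], sqrt(sig2[2L]), log = TRUE)
    p1 <- 1 / (1 + exp(l2 - l1))
    s <- ifelse(rng_uniform(rng, n) < p1, 1L, 2L)
    # means (conjugate normal)
    z <- rng_normal(rng, 2L)
    for (k in 1:2) {
      idx <- s == k
      nk <- sum(idx)
      prec <- 1 / v0 + nk / sig2[k]
      mean_k <- (m0 / v0 + sum(y[idx]) / sig2[k]) / prec
      mu[k] <- mean_k + z[k] / sqrt(prec)
    }
    # variances (random-walk Metropolis on log scale)
    zp <- rng_normal(rng, 2L)
    up <- rng_uniform(rng, 2L)
    for (k in 1:2) {
      idx <- s == k
      nk <- sum(idx)
      ss <- if (nk > 0L) sum((y[idx] - mu[k])^2) else 0
      logpost <- function(l) {
        # likelihood + Exp(rate) prior + log-scale Jacobian
        -(nk / 2) * l - ss / (2 * exp(l)) - rate * exp(l) + l
      }
      lp <- lv[k] + config$rw_step * zp[k]
      prop[k] <- prop[k] + 1L
      if (lp >= config$log_var_floor &&
          log(up[k]) < logpost(lp) - logpost(lv[k])) {
        lv[k] <- lp
        acc[k] <- acc[k] + 1L
      }
    }
    if (it > config$burn_in) {
      j <- it - config$burn_in
      keep_mu[j, ] <- mu
      keep_s2[j, ] <- exp(lv)
      keep_s[j, ] <- s
    }
  }
  structure(list(mu = keep_mu, sigma2 = keep_s2, s = keep_s,
                 diagnostics = list(acceptance = acc / prop)),
            class = "mcmc_chain")
}

#' @export
print.mcmc_chain <- function(x, ...) {
  cat("<mcmc_chain: ", nrow(x$mu), " retained draw(s); Metropolis acceptance ",
      paste(sprintf("%.2f", x$diagnostics$acceptance), collapse = "/"), ">\n",
      sep = "")
  invisible(x)
}

#' Posterior-predictive velocity draws
#'
#' Each draw picks a retained chain state uniformly, picks a spring with the
#' mixture weight, and draws a normal velocity from that spring's posterior
#' parameters.  Three uniform deviates are consumed per draw (state index,
#' spring, normal deviate).
#'
#' @param chain An [run_mixture_mcmc()] result.
#' @param config The [spring_mixture_config()] used.
#' @param rng An [rng_stream()].
#' @param n Number of draws (`> 0`).
#' @return Numeric vector of length `n`; the chosen spring of each draw is
#'   attached as integer attribute `"spring"`.
#' @export
posterior_predictive_realisations <- function(chain, config, rng, n) {
  stopifnot(inherits(chain, "mcmc_chain"))
  if (n <= 0L) stop("n must be positive", call. = FALSE)
  m <- nrow(chain$mu)
  if (m == 0L) stop("empty chain", call. = FALSE)
  out <- numeric(n)
  spring <- integer(n)
  for (i in seq_len(n)) {
    u <- rng_uniform(rng, 3L)
    j <- min(m, floor(u[1L] * m) + 1L)
    k <- if (u[2L] < config$mixture_weight) 1L else 2L
    out[i] <- chain$mu[j, k] + sqrt(chain$sigma2[j, k]) * stats::qnorm(u[3L])
    spring[i] <- k
  }
  attr(out, "spring") <- spring
  out
}

# ---------------------------------------------------------------------------
# Example model construction

# lambda x. (1/(sd*sqrt(2*pi))) * exp(-(x - mean)^2 / (2*sd^2)),
# written with dimensionless constants (probability densities are
# dimensionless by the units rule).
normal_density_lambda <- function(mean, sd = 1) {
  dimless <- function(v) mml_constant(v, "dimensionless")
  x <- mml_var("x")
  centered <- if (mean == 0) x else mml_apply("minus", list(x, dimless(mean)))
  quad <- mml_apply("divide", list(
    mml_apply("power", list(centered, dimless(2))),
    dimless(2 * sd^2)))
  coef <- mml_apply("divide", list(
    dimless(1),
    mml_apply("root", list(mml_apply("times", list(
      dimless(2 * sd^2), mml_constant(pi, "dimensionless")))))))
  mml_lambda("x", mml_apply("times", list(
    coef, mml_apply("exp", list(mml_apply("minus", list(quad)))))))
}

#' Build the projectile example model
#'
#' Motion of an object in two spatial dimensions under constant acceleration,
#' with uncertain initial position and velocity: the initial `x` and `y`
#' positions and the initial `x` velocity carry symbolic normal densities
#' (N(0,1), N(0,1) and N(10,1) respectively), while the initial `y` velocity
#' carries the supplied realisation vector (the spring-mixture posterior
#' predictive).  States: `x`, `y`, `vx`, `vy` with `dx/dt = vx`,
#' `dy/dt = vy`, `dvx/dt = ax`, `dvy/dt = ay`.
#'
#' @param realisations Non-empty numeric vector of initial `y` velocity
#'   realisations.
#' @param accelerations Named numeric vector `c(ax =, ay =)` in m s^-2.
#' @return A `cellml_model`.
#' @export
build_example_model <- function(realisations,
                                accelerations = c(ax = 0, ay = -9.81)) {
  stopifnot(length(realisations) >= 1L, all(is.finite(realisations)))
  ax <- unname(accelerations[["ax"]])
  ay <- unname(accelerations[["ay"]])

  units <- c(
    paste0('<units name="m_per_s" xmlns="', CELLML_1_1_NS, '">',
           '<unit units="metre"/><unit units="second" exponent="-1"/></units>'),
    paste0('<units name="m_per_s2" xmlns="', CELLML_1_1_NS, '">',
           '<unit units="metre"/><unit units="second" exponent="-2"/></units>'))

  vars <- data.frame(
    name = c("t", "x", "y", "vx", "vy", "x0", "y0", "vx0", "vy0", "ax", "ay"),
    units = c("second", "metre", "metre", "m_per_s", "m_per_s",
              "metre", "metre", "m_per_s", "m_per_s", "m_per_s2", "m_per_s2"),
    initial_value = c(NA, "x0", "y0", "vx0", "vy0", NA, NA, NA, NA,
                      fmt_num(ax), fmt_num(ay)),
    stringsAsFactors = FALSE)

  rate <- function(state, rhs_var) {
    mml_apply("eq", list(
      mml_apply("diff", list(mml_var("t"), mml_var(state))),
      mml_var(rhs_var)))
  }
  assert_density <- function(target, mean) {
    mml_csymbol_apply(UNCERTAIN_PARAM_URL, list(
      mml_var(target),
      mml_csymbol_apply(DENSITY_URL, list(normal_density_lambda(mean)))))
  }
  realisation_vec <- mml_vector(lapply(realisations, function(v)
    mml_constant(v, "m_per_s")))
  assert_realisations <- mml_csymbol_apply(UNCERTAIN_PARAM_URL, list(
    mml_var("vy0"),
    mml_csymbol_apply(REALISATIONS_URL, list(realisation_vec))))

  math <- list(
    rate("x", "vx"), rate("y", "vy"), rate("vx", "ax"), rate("vy", "ay"),
    assert_density("x0", 0), assert_density("y0", 0),
    assert_density("vx0", 10), assert_realisations)

  comp <- list(name = "projectile", variables = vars, math = math)
  assemble_model("uncertain_projectile", units,
                 stats::setNames(list(comp), "projectile"), list())
}

#' Build the two SED-ML experiment documents
#'
#' One single-run uniform time course and one sampling sensitivity analysis,
#' both over `t` in [0, 10] s against the fixture model.
#'
#' @param number_of_samples `numberOfSamples` of the sensitivity document.
#' @param model_source Model file name referenced by both documents.
#' @param number_of_points Reporting intervals of the time courses.
#' @return List with character XML fields `single_run` and `sensitivity`.
#' @export
build_sedml_documents <- function(number_of_samples,
                                  model_source = "uncertain_projectile.cellml",
                                  number_of_points = 100L) {
  stopifnot(number_of_samples >= 1L)
  doc <- function(sim_extra, sim_id) {
    dg <- function(var, tgt) paste0(
      '    <dataGenerator id="dg_', var, '">\n',
      '      <listOfVariables>\n',
      '        <variable id="v_', var, '" taskReference="task1" target="', tgt,
      '"/>\n',
      '      </listOfVariables>\n',
      '    </dataGenerator>')
    ds <- function(var) paste0(
      '        <dataSet id="ds_', var, '" label="', var,
      '" dataReference="dg_', var, '"/>')
    vars <- c("time", "x", "y", "vx", "vy")
    vars_dg <- c("urn:sedml:symbol:time", "x", "y", "vx", "vy")
    dgs <- paste(mapply(dg, vars, vars_dg), collapse = "\n")
    paste0(
      '<?xml version="1.0" encoding="UTF-8"?>\n',
      '<sedML xmlns="', SEDML_NS, '" xmlns:uncert="', UNCERTAINTY_NS,
      '" level="1" version="1">\n',
      '  <listOfSimulations>\n',
      '    <uniformTimeCourse id="', sim_id, '" initialTime="0"',
      ' outputStartTime="0" outputEndTime="10" numberOfPoints="',
      number_of_points, '"', sim_extra, '>\n',
      '      <algorithm kisaoID="KISAO:0000032"/>\n',
      '    </uniformTimeCourse>\n',
      '  </listOfSimulations>\n',
      '  <listOfModels>\n',
      '    <model id="model1" language="urn:sedml:language:cellml" source="',
      model_source, '"/>\n',
      '  </listOfModels>\n',
      '  <listOfTasks>\n',
      '    <task id="task1" modelReference="model1" simulationReference="',
      sim_id, '"/>\n',
      '  </listOfTasks>\n',
      '  <listOfDataGenerators>\n', dgs, '\n  </listOfDataGenerators>\n',
      '  <listOfOutputs>\n',
      '    <report id="report1">\n',
      '      <listOfDataSets>\n',
      paste(vapply(vars, ds, ""), collapse = "\n"), '\n',
      '      </listOfDataSets>\n',
      '    </report>\n',
      '  </listOfOutputs>\n',
      '</sedML>\n')
  }
  list(single_run = doc("", "sim_single"),
       sensitivity = doc(paste0(' uncert:numberOfSamples="',
                                as.integer(number_of_samples), '"'),
                         "sim_sampling"))
}

#' Emit the complete fixture bundle
#'
#' Runs the mixture MCMC, builds the example model with the
#' posterior-predictive realisations, and writes the CellML model plus both
#' SED-ML documents into a directory.  Fully deterministic from one seed.
#'
#' @param dir Output directory (created if needed).
#' @param seed Master seed.
#' @param number_of_samples `numberOfSamples` of the sensitivity document.
#' @param n_realisations Realisation vector length placed in the model.
#' @param config A [spring_mixture_config()].
#' @return Invisibly, named character vector of the written paths.
#' @export
write_fixture_bundle <- function(dir, seed = 1L, number_of_samples = 100L,
                                 n_realisations = 1000L,
                                 config = spring_mixture_config()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rng <- rng_stream(seed)
  chain <- run_mixture_mcmc(config, rng)
  real <- posterior_predictive_realisations(chain, config, rng, n_realisations)
  model <- build_example_model(as.numeric(real))
  model_path <- file.path(dir, "uncertain_projectile.cellml")
  write_cellml(model, model_path)
  docs <- build_sedml_documents(number_of_samples)
  single_path <- file.path(dir, "single_run.sedml")
  sens_path <- file.path(dir, "sensitivity.sedml")
  writeLines(docs$single_run, single_path)
  writeLines(docs$sensitivity, sens_path)
  invisible(c(model = model_path, single_run = single_path,
              sensitivity = sens_path))
}
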