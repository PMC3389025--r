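test_that("rng streams are reproducible and isolated from the global RNG", {
  a <- rng_stream(123L)
  b <- rng_stream(123L)
  expect_identical(rng_uniform(a, 10L), rng_uniform(b, 10L))
  set.seed(77)
  before <- runif(1)
  set.seed(77)
  invisible(rng_uniform(rng_stream(5L), 100L))
  expect_identical(runif(1), before)
})

test_that("cdf_value matches closed-form normal CDFs", {
  cdf <- numeric_cdf(density_spec(std_normal_lambda()))
  expect_equal(cdf_value(cdf, 0), 0.5, tolerance = 1e-6)
  expect_equal(cdf_value(cdf, Inf), 1, tolerance = 1e-6)
  expect_equal(cdf_value(cdf, -Inf), 0, tolerance = 1e-6)
  # frozen from the error-function oracle: pnorm(11, 10, 1) = Phi(1)
  cdf10 <- numeric_cdf(density_spec(std_normal_lambda(mean = 10)))
  expect_equal(cdf_value(cdf10, 11), 0.841345, tolerance = 1e-5)
})

test_that("cdf is monotone and invalid densities are rejected", {
  for (spec in list(density_spec(std_normal_lambda(3, 2)),
                    density_spec(uniform_lambda(-1, 2)),
                    density_spec(exponential_lambda(0.5)))) {
    cdf <- numeric_cdf(spec)
    expect_lt(abs(cdf$normalization - 1), 1e-3)
    ys <- seq(-8, 8, length.out = 41)
    Fs <- vapply(ys, function(y) cdf_value(cdf, y), 0)
    expect_true(all(diff(Fs) >= -1e-8))
  }
  # integrates to 2: not a density; must be rejected, not renormalized
  double_mass <- mml_lambda("x", mml_apply("times", list(
    dimless(2), std_normal_lambda()$body)))
  expect_error(numeric_cdf(density_spec(double_mass)), "normalization tolerance")
  # negative lobes are not a density either
  signed <- mml_lambda("x", mml_apply("minus", list(std_normal_lambda()$body)))
  expect_error(numeric_cdf(density_spec(signed)), "negative|normalization")
})

test_that("invert_cdf recovers quantiles and the inverse property holds", {
  cdf <- numeric_cdf(density_spec(std_normal_lambda()))
  expect_equal(invert_cdf(cdf, 0.5), 0, tolerance = 1e-5)
  # frozen from the normal quantile oracle qnorm(0.975)
  expect_equal(invert_cdf(cdf, 0.975), 1.959964, tolerance = 1e-4)
  unif <- numeric_cdf(density_spec(uniform_lambda(0, 1)))
  expect_equal(invert_cdf(unif, 0.25), 0.25, tolerance = 1e-5)
  for (x in seq(-2.5, 2.5, by = 0.5)) {
    expect_equal(invert_cdf(cdf, cdf_value(cdf, x)), x, tolerance = 1e-4)
  }
  expo <- numeric_cdf(density_spec(exponential_lambda(2)))
  for (x in c(0.05, 0.3, 1, 2.5)) {
    expect_equal(invert_cdf(expo, cdf_value(expo, x)), x, tolerance = 1e-4)
  }
})

test_that("flat zero-density plateaus resolve to the smallest minimiser", {
  # mass 1/2 on [0,1] and 1/2 on [2,3]; F = 0.5 on all of [1,2]
  x <- mml_var("x")
  blocky <- mml_lambda("x", mml_piecewise(
    list(
      list(condition = mml_apply("and", list(
        mml_apply("geq", list(x, dimless(0))),
        mml_apply("leq", list(x, dimless(1))))),
        value = dimless(0.5)),
      list(condition = mml_apply("and", list(
        mml_apply("geq", list(x, dimless(2))),
        mml_apply("leq", list(x, dimless(3))))),
        value = dimless(0.5))),
    otherwise = dimless(0)))
  cdf <- numeric_cdf(density_spec(blocky))
  expect_equal(invert_cdf(cdf, 0.5), 1, tolerance = 1e-3)
})

test_that("seeded density draws pass KS tests against closed-form CDFs", {
  n <- 2000L
  crit <- 1.628 / sqrt(n)  # alpha = 0.01 asymptotic KS critical value
  cases <- list(
    list(spec = density_spec(std_normal_lambda()), cdf = stats::pnorm),
    list(spec = density_spec(uniform_lambda(0, 1)),
         cdf = function(q) stats::punif(q, 0, 1)),
    list(spec = density_spec(exponential_lambda(1)),
         cdf = function(q) stats::pexp(q, 1)))
  for (i in seq_along(cases)) {
    rng <- rng_stream(1000L + i)
    x <- sample_density(cases[[i]]$spec, env_new(), rng, n = n)
    D <- as.numeric(stats::ks.test(x, cases[[i]]$cdf)$statistic)
    expect_lt(D, crit)
  }
})

test_that("density sampling is deterministic and consumes one deviate per draw", {
  spec <- density_spec(std_normal_lambda())
  x1 <- sample_density(spec, env_new(), rng_stream(9L), n = 5L)
  x2 <- sample_density(spec, env_new(), rng_stream(9L), n = 5L)
  expect_identical(x1, x2)
  # the draw is the quantile of the stream's uniforms, in order
  z <- rng_uniform(rng_stream(9L), 5L)
  cdf <- numeric_cdf(spec)
  expect_equal(x1, vapply(z, function(zi) invert_cdf(cdf, zi), 0),
               tolerance = 1e-12)
})

test_that("realisation sampling is uniform over indices and keeps tuples whole", {
  single <- realisations_spec(7)
  expect_identical(as.numeric(sample_realisations(single, rng_stream(1L), 20L)),
                   rep(7, 20))
  two <- realisations_spec(c(0, 1))
  x <- sample_realisations(two, rng_stream(2L), 10000L)
  f <- mean(x == 0)
  expect_gte(f, 0.47)  # binomial 99% interval at n = 10000
  expect_lte(f, 0.53)
  pairs <- realisations_spec(rbind(c(1, 10), c(2, 20)))
  draws <- sample_realisations(pairs, rng_stream(3L), 500L)
  ok <- apply(draws, 1L, function(r)
    identical(unname(r), c(1, 10)) || identical(unname(r), c(2, 20)))
  expect_true(all(ok))
})

test_that("draw_parameter_set samples assertions in order with provenance", {
  m <- small_example_model()
  d1 <- draw_parameter_set(m$uncertainty, env_new(), rng_stream(31L))
  d2 <- draw_parameter_set(m$uncertainty, env_new(), rng_stream(31L))
  expect_identical(d1, d2)
  expect_identical(names(d1$values), c("x0", "y0", "vx0", "vy0"))
  expect_length(d1$provenance, 4L)
  expect_identical(d1$provenance[[4L]]$kind, "realisations")
  expect_true(d1$provenance[[4L]]$index >= 1L)
  empty <- draw_parameter_set(list(), env_new(), rng_stream(31L))
  expect_length(empty$values, 0L)
})
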