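test_that("the fixture documents load as the two simulation types", {
  paths <- small_fixture_bundle()
  single <- load_sedml(paths[["single_run"]])
  sens <- load_sedml(paths[["sensitivity"]])
  s1 <- single$simulations[[1L]]
  expect_identical(s1$type, "UniformTimeCourse")
  expect_equal(s1$output_end, 10)
  s2 <- sens$simulations[[1L]]
  expect_identical(s2$type, "SamplingSensitivityAnalysis")
  expect_identical(s2$number_of_samples, 4L)
  expect_length(single$tasks, 1L)
})

test_that("numberOfSamples is validated", {
  docs <- build_sedml_documents(2L)
  bad <- sub('uncert:numberOfSamples="2"', 'uncert:numberOfSamples="0"',
             docs$sensitivity, fixed = TRUE)
  path <- tempfile(fileext = ".sedml")
  writeLines(bad, path)
  expect_error(load_sedml(path), "numberOfSamples must be an integer >= 1")
  missing <- sub('<uniformTimeCourse id="sim_sampling"',
                 '<samplingSensitivityAnalysis id="sim_sampling"',
                 sub(' uncert:numberOfSamples="2"', "", docs$sensitivity,
                     fixed = TRUE), fixed = TRUE)
  missing <- sub("</uniformTimeCourse>", "</samplingSensitivityAnalysis>",
                 missing, fixed = TRUE)
  writeLines(missing, path)
  expect_error(load_sedml(path), "lacks the numberOfSamples attribute")
  dangling <- sub('modelReference="model1"', 'modelReference="nope"',
                  docs$single_run, fixed = TRUE)
  writeLines(dangling, path)
  expect_error(load_sedml(path), "undeclared model")
})

test_that("ensembles have the declared sample count and are seed-deterministic", {
  paths <- small_fixture_bundle()
  sens <- load_sedml(paths[["sensitivity"]])
  r1 <- run_experiment(sens, master_seed = 5L)$task1
  expect_length(r1$samples, 4L)
  r2 <- run_experiment(sens, master_seed = 5L)$task1
  expect_identical(
    lapply(r1$samples, function(s) s$trajectory$values),
    lapply(r2$samples, function(s) s$trajectory$values))
  r3 <- run_experiment(sens, master_seed = 6L)$task1
  expect_false(identical(r1$samples[[1L]]$draw$values,
                         r3$samples[[1L]]$draw$values))
})

test_that("SamplingSensitivityAnalysis with one sample equals the plain time course", {
  paths <- small_fixture_bundle()
  dir <- dirname(paths[["model"]])
  docs <- build_sedml_documents(1L, number_of_points = 20L)
  p1 <- file.path(dir, "n1_sens.sedml")
  p2 <- file.path(dir, "n1_single.sedml")
  writeLines(docs$sensitivity, p1)
  writeLines(docs$single_run, p2)
  # fewer points on the single doc too, for a like-for-like comparison
  single <- sub('numberOfPoints="100"', 'numberOfPoints="20"',
                readLines(p2))
  writeLines(single, p2)
  rs <- run_experiment(load_sedml(p1), master_seed = 17L)$task1
  ru <- run_experiment(load_sedml(p2), master_seed = 17L)$task1
  expect_identical(rs$samples[[1L]]$draw$values, ru$samples[[1L]]$draw$values)
  expect_identical(rs$samples[[1L]]$trajectory$values,
                   ru$samples[[1L]]$trajectory$values)
})

test_that("reports have the contracted shape and order", {
  paths <- small_fixture_bundle()
  sens <- load_sedml(paths[["sensitivity"]])
  res <- run_experiment(sens, master_seed = 8L,
                        solver = list(rel_tol = 1e-8))$task1
  out <- tempfile(fileext = ".csv")
  written <- write_report(res, out, variables = c("x", "y", "vx", "vy"))
  values <- utils::read.csv(written[["values"]])
  # 4 samples x 101 grid points x 4 variables
  expect_identical(nrow(values), 4L * 101L * 4L)
  expect_identical(names(values), c("sample_index", "time", "variable", "value"))
  draws <- utils::read.csv(written[["draws"]])
  expect_identical(nrow(draws), 4L * 4L)  # 4 uncertain parameters per sample
  expect_identical(unique(draws$parameter), c("x0", "y0", "vx0", "vy0"))
  empty <- structure(list(samples = list(), variables = character()),
                     class = "ensemble_result")
  expect_error(write_report(empty, out), "empty ensemble")
})

test_that("endpoint summaries behave at the grid and reject off-grid times", {
  paths <- small_fixture_bundle()
  sens <- load_sedml(paths[["sensitivity"]])
  res <- run_experiment(sens, master_seed = 4L)$task1
  s <- summarize_endpoint(res, "x", 10)
  vals <- vapply(res$samples, function(smp)
    smp$trajectory$values[101L, "x"], 0)
  expect_equal(s$mean, mean(vals))
  expect_equal(unname(s$quantiles[["50%"]]), unname(stats::median(vals)))
  # t is reported and constant across samples at a grid point
  st <- summarize_endpoint(res, "t", 5)
  expect_equal(st$sd, 0)
  expect_error(summarize_endpoint(res, "x", 10.123), "not on the output grid")
  expect_error(summarize_endpoint(res, "nope", 10), "not reported")
})
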