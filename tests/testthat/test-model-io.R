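test_that("the example model loads with four uncertainty assertions", {
  m <- small_example_model()
  path <- tempfile(fileext = ".cellml")
  write_cellml(m, path)
  m2 <- load_cellml(path)
  expect_length(m2$uncertainty, 4L)
  targets <- vapply(m2$uncertainty, function(a) a$targets[[1L]]$variable, "")
  expect_identical(targets, c("x0", "y0", "vx0", "vy0"))
  kinds <- vapply(m2$uncertainty, function(a) class(a$spec)[1L], "")
  expect_identical(kinds, c("density_spec", "density_spec", "density_spec",
                            "realisations_spec"))
})

test_that("round-trip write/load preserves structure and realisation order", {
  real <- c(6.25, 11.75, 6.5, 12.01, 5.99)
  m <- build_example_model(real)
  path <- tempfile(fileext = ".cellml")
  write_cellml(m, path)
  m2 <- load_cellml(path)
  expect_true(cellsamp:::model_equal(m, m2))
  got <- m2$uncertainty[[4L]]$spec$values[, 1L]
  expect_identical(got, real)
  # idempotence: a second round trip changes nothing
  path2 <- tempfile(fileext = ".cellml")
  write_cellml(m2, path2)
  expect_true(cellsamp:::model_equal(m2, load_cellml(path2)))
})

test_that("plain models load with empty uncertainty and resolve connections", {
  path <- write_temp_cellml(plain_two_component_cellml())
  m <- load_cellml(path)
  expect_length(m$uncertainty, 0L)
  cls <- classify_variables(m)
  expect_identical(cls$states, "n")
  expect_identical(cls$bound, "t")
  # k and kp collapse into one logical constant
  expect_length(cls$constants, 1L)
  plan <- compile_plan(m)
  tr <- run_time_course(plan, NULL, time_course_spec(0, 0, 2, 10))
  expect_equal(unname(tr$values[nrow(tr$values), "n"]), exp(-0.5 * 2), tolerance = 1e-7)
})

test_that("malformed uncertainty constructs are rejected", {
  bogus <- sub("distributionFromDensity",
               "bogus",
               serialize_mathml(small_example_model()$components[[1L]]$math[[5L]]))
  xml <- paste0(
    '<?xml version="1.0"?>\n<model name="m" xmlns="', CELLML11,
    '" xmlns:cellml="', CELLML11, '">\n<component name="c">\n',
    '<variable name="x0" units="metre"/>\n',
    '<math xmlns="', MML, '" xmlns:cellml="', CELLML11, '">', bogus,
    "</math>\n</component>\n</model>\n")
  expect_error(load_cellml(write_temp_cellml(xml)), "unknown uncertainty operator suffix 'bogus'")

  # density takes a single argument
  expect_error(
    extract_uncertainty(list(mml_csymbol_apply(
      cellsamp:::UNCERTAIN_PARAM_URL,
      list(mml_var("v"), mml_csymbol_apply(
        cellsamp:::DENSITY_URL,
        list(std_normal_lambda(), std_normal_lambda())))))),
    "single argument")
  # density cannot target a vector of variables
  expect_error(
    extract_uncertainty(list(mml_csymbol_apply(
      cellsamp:::UNCERTAIN_PARAM_URL,
      list(mml_vector(list(mml_var("a"), mml_var("b"))),
           mml_csymbol_apply(cellsamp:::DENSITY_URL,
                             list(std_normal_lambda())))))),
    "exactly one target")
  # realisations mixing scalars and pairs / tuple length mismatches
  two_targets <- mml_vector(list(mml_var("a"), mml_var("b")))
  realise <- function(elements) {
    mml_csymbol_apply(cellsamp:::UNCERTAIN_PARAM_URL, list(
      two_targets,
      mml_csymbol_apply(cellsamp:::REALISATIONS_URL,
                        list(mml_vector(elements)))))
  }
  mixed <- realise(list(dimless(1),
                        mml_vector(list(dimless(1), dimless(2)))))
  expect_error(extract_uncertainty(list(mixed)), "mixes scalars and tuples")
  triple <- realise(list(mml_vector(list(dimless(1), dimless(2), dimless(3)))))
  expect_error(extract_uncertainty(list(triple)), "does not match")
})

test_that("extraction preserves document order and is a clean partition", {
  m <- small_example_model()
  math <- m$components[[1L]]$math
  res <- extract_uncertainty(math)
  expect_length(res$assertions, 4L)
  expect_length(res$remaining, 4L)
  expect_identical(
    vapply(res$assertions, function(a) a$targets[[1L]]$variable, ""),
    c("x0", "y0", "vx0", "vy0"))
})

test_that("classification detects degenerate models", {
  loop <- paste0(
    '<?xml version="1.0"?>\n<model name="m" xmlns="', CELLML11,
    '" xmlns:cellml="', CELLML11, '">\n<component name="c">\n',
    '<variable name="x" units="dimensionless"/>\n',
    '<variable name="y" units="dimensionless"/>\n',
    '<math xmlns="', MML, '" xmlns:cellml="', CELLML11, '">',
    "<apply><eq/><ci>x</ci><ci>y</ci></apply>",
    "<apply><eq/><ci>y</ci><ci>x</ci></apply>",
    "</math>\n</component>\n</model>\n")
  expect_error(classify_variables(load_cellml(write_temp_cellml(loop))),
               "algebraic-loop")

  underdet <- sub("<apply><eq/><ci>y</ci><ci>x</ci></apply>", "", loop,
                  fixed = TRUE)
  expect_error(classify_variables(load_cellml(write_temp_cellml(underdet))),
               "underdetermined")

  empty <- paste0('<?xml version="1.0"?>\n<model name="m" xmlns="', CELLML11,
                  '"/>')
  cls <- classify_variables(load_cellml(write_temp_cellml(empty)))
  expect_true(all(lengths(cls) == 0L))
})

test_that("imports and unwritable paths are hard errors", {
  imp <- paste0('<?xml version="1.0"?>\n<model name="m" xmlns="', CELLML11,
                '"><import xlink:href="other.cellml" ',
                'xmlns:xlink="http://www.w3.org/1999/xlink"/></model>')
  expect_error(load_cellml(write_temp_cellml(imp)), "import")
  expect_error(write_cellml(small_example_model(),
                            file.path(tempfile(), "nope", "m.cellml")),
               "I/O error")
})
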