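# Shared builders for small in-code fixtures.

MML <- "http://www.w3.org/1998/Math/MathML"
CELLML11 <- "http://www.cellml.org/cellml/1.1#"

# Wrap a MathML fragment with namespaces so parse_mathml can read it standalone.
mml_xml <- function(fragment) {
  paste0('<math xmlns="', MML, '" xmlns:cellml="', CELLML11, '">',
         fragment, "</math>")
}

dimless <- function(v) mml_constant(v, "dimensionless")

# lambda x. standard normal density at x, built from expression nodes.
std_normal_lambda <- function(mean = 0, sd = 1) {
  x <- mml_var("x")
  centered <- if (mean == 0) x else mml_apply("minus", list(x, dimless(mean)))
  mml_lambda("x", mml_apply("times", list(
    dimless(1 / (sd * sqrt(2 * pi))),
    mml_apply("exp", list(mml_apply("minus", list(
      mml_apply("divide", list(
        mml_apply("power", list(centered, dimless(2))),
        dimless(2 * sd^2))))))))))
}

# lambda x. 1 on [lo, hi], 0 elsewhere.
uniform_lambda <- function(lo = 0, hi = 1) {
  x <- mml_var("x")
  inside <- mml_apply("and", list(
    mml_apply("geq", list(x, dimless(lo))),
    mml_apply("leq", list(x, dimless(hi)))))
  mml_lambda("x", mml_piecewise(
    list(list(condition = inside, value = dimless(1 / (hi - lo)))),
    otherwise = dimless(0)))
}

# lambda x. rate * exp(-rate x) for x >= 0.
exponential_lambda <- function(rate = 1) {
  x <- mml_var("x")
  neg_rx <- mml_apply("minus", list(mml_apply("times", list(dimless(rate), x))))
  dens <- mml_apply("times", list(dimless(rate), mml_apply("exp", list(neg_rx))))
  cond <- mml_apply("geq", list(x, dimless(0)))
  mml_lambda("x", mml_piecewise(list(list(condition = cond, value = dens)),
                                otherwise = dimless(0)))
}

# A minimal plain CellML document (no uncertainty), two connected components.
plain_two_component_cellml <- function() {
  paste0(
    '<?xml version="1.0"?>\n',
    '<model name="decay" xmlns="', CELLML11, '" xmlns:cellml="', CELLML11, '">\n',
    '  <component name="main">\n',
    '    <variable name="t" units="second"/>\n',
    '    <variable name="n" units="dimensionless" initial_value="1"/>\n',
    '    <variable name="k" units="dimensionless"/>\n',
    '    <math xmlns="', MML, '" xmlns:cellml="', CELLML11, '">\n',
    '      <apply><eq/><apply><diff/><bvar><ci>t</ci></bvar><ci>n</ci></apply>',
    '<apply><minus/><apply><times/><ci>k</ci><ci>n</ci></apply></apply></apply>\n',
    '    </math>\n',
    '  </component>\n',
    '  <component name="params">\n',
    '    <variable name="kp" units="dimensionless"/>\n',
    '    <math xmlns="', MML, '" xmlns:cellml="', CELLML11, '">\n',
    '      <apply><eq/><ci>kp</ci><cn cellml:units="dimensionless">0.5</cn></apply>\n',
    '    </math>\n',
    '  </component>\n',
    '  <connection>\n',
    '    <map_components component_1="main" component_2="params"/>\n',
    '    <map_variables variable_1="k" variable_2="kp"/>\n',
    '  </connection>\n',
    '</model>\n')
}

write_temp_cellml <- function(xml) {
  path <- tempfile(fileext = ".cellml")
  writeLines(xml, path)
  path
}

# Small example model shared across tests (20 realisations keeps I/O fast).
small_example_model <- function(realisations = seq(5.5, 12.5, length.out = 20)) {
  build_example_model(realisations)
}

# Fixture bundle on disk, built once per test run.
.bundle_cache <- new.env(parent = emptyenv())
small_fixture_bundle <- function() {
  if (is.null(.bundle_cache$paths)) {
    dir <- file.path(tempdir(), "cellsamp-fixture-bundle")
    cfg <- spring_mixture_config(burn_in = 200L, retained = 200L)
    .bundle_cache$paths <- write_fixture_bundle(
      dir, seed = 20260909L, number_of_samples = 4L, n_realisations = 50L,
      config = cfg)
  }
  .bundle_cache$paths
}
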