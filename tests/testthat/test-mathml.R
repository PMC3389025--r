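test_that("parsing maps MathML structures onto expression nodes", {
  e <- parse_mathml(mml_xml(
    '<apply><plus/><cn cellml:units="m">1</cn><cn cellml:units="m">2</cn></apply>'))
  expect_identical(e$kind, "apply")
  expect_identical(e$operator, "plus")
  expect_identical(e$operands[[1L]], mml_constant(1, "m"))
  expect_identical(e$operands[[2L]], mml_constant(2, "m"))

  cs <- parse_mathml(mml_xml(paste0(
    '<apply><csymbol definitionURL="http://www.cellml.org/uncertainty-1#',
    'distributionFromDensity"/><ci>v</ci></apply>')))
  expect_identical(cs$kind, "csymbol")
  expect_identical(cs$definition_url,
                   "http://www.cellml.org/uncertainty-1#distributionFromDensity")

  pw <- parse_mathml(mml_xml(paste0(
    '<piecewise><piece><cn cellml:units="dimensionless">1</cn>',
    '<apply><lt/><ci>x</ci><cn cellml:units="dimensionless">0</cn></apply>',
    '</piece><otherwise><cn cellml:units="dimensionless">2</cn></otherwise>',
    '</piecewise>')))
  expect_length(pw$cases, 1L)
  expect_identical(pw$otherwise, mml_constant(2, "dimensionless"))

  en <- parse_mathml(mml_xml(
    '<cn cellml:units="second" type="e-notation">1<sep/>-3</cn>'))
  expect_equal(en$value, 1e-3)
})

test_that("unsupported elements and missing units are reported, not accepted", {
  expect_error(
    parse_mathml(mml_xml('<apply><factorial/><ci>n</ci></apply>')),
    "unsupported operator")
  expect_error(parse_mathml(mml_xml("<cn>1</cn>")), "units error")
  expect_error(parse_mathml(mml_xml("<matrix/>")), "unsupported element")
  expect_error(mml_apply("gamma", list()), "unsupported operator")
})

test_that("evaluation covers arithmetic, piecewise and error contracts", {
  env <- env_new(c(x = 0))
  expect_equal(evaluate(mml_apply("times", list(dimless(2), dimless(3)))), 6)
  # closed form 1/sqrt(2*pi), independent of the lambda machinery
  expect_equal(apply_lambda(std_normal_lambda(), 0), 1 / sqrt(2 * pi),
               tolerance = 1e-12)
  pw <- mml_piecewise(
    list(list(condition = mml_apply("lt", list(mml_var("x"), dimless(0))),
              value = dimless(-1))),
    otherwise = dimless(1))
  expect_equal(evaluate(pw, env), 1)
  expect_equal(evaluate(pw, env_new(c(x = -2))), -1)
  expect_error(evaluate(mml_piecewise(list(list(
    condition = mml_apply("lt", list(mml_var("x"), dimless(0))),
    value = dimless(-1))), otherwise = NULL), env), "no true case")
  expect_error(evaluate(mml_var("ghost"), env), "unbound variable")
  expect_error(evaluate(mml_apply("ln", list(dimless(-1)))), "domain error")
  # relational/logical results are 1/0 reals
  expect_identical(evaluate(mml_apply("geq", list(dimless(2), dimless(2)))), 1)
  expect_identical(evaluate(mml_apply("and", list(dimless(1), dimless(0)))), 0)
})

test_that("lambda application binds positionally and checks arity", {
  idf <- mml_lambda("x", mml_var("x"))
  expect_equal(apply_lambda(idf, 5), 5)
  sq <- mml_lambda("x", mml_apply("power", list(mml_var("x"), dimless(2))))
  expect_equal(apply_lambda(sq, -3), 9)
  expect_error(apply_lambda(idf, c(1, 2)), "arity mismatch")
  # outer environment stays visible for free symbols
  shifted <- mml_lambda("x", mml_apply("plus", list(mml_var("x"), mml_var("a"))))
  expect_equal(apply_lambda(shifted, 1, env_new(c(a = 10))), 11)
})

test_that("free_variables has set semantics and respects lambda binding", {
  expect_identical(free_variables(dimless(1)), character())
  lam <- mml_lambda("x", mml_apply("plus", list(mml_var("x"), mml_var("a"))))
  expect_identical(free_variables(lam), "a")
  dup <- mml_apply("plus", list(mml_var("v", "c"), mml_var("v", "c")))
  expect_identical(free_variables(dup), "c.v")
})

test_that("serialize/parse round-trips structurally identical trees", {
  exprs <- list(
    mml_apply("plus", list(mml_constant(1.5, "m"), mml_constant(-2e-7, "m"))),
    std_normal_lambda(10),
    uniform_lambda(0, 1),
    mml_vector(list(dimless(1), dimless(2), dimless(3))),
    mml_apply("root", list(dimless(3), dimless(8))),
    mml_apply("log", list(dimless(2), dimless(8))),
    mml_apply("eq", list(
      mml_apply("diff", list(mml_var("t"), mml_var("x"))), mml_var("vx"))),
    mml_csymbol_apply(paste0("http://www.cellml.org/uncertainty-1#",
                             "uncertainParameterWithDistribution"),
                      list(mml_var("v"),
                           mml_csymbol_apply(paste0(
                             "http://www.cellml.org/uncertainty-1#",
                             "distributionFromDensity"),
                             list(std_normal_lambda())))))
  for (e in exprs) {
    reparsed <- parse_mathml(mml_xml(serialize_mathml(e)))
    expect_identical(reparsed, parse_mathml(mml_xml(serialize_mathml(reparsed))))
  }
})

test_that("evaluate agrees with a brute-force oracle on random trees", {
  # independent oracle: direct recursion onto R arithmetic
  oracle <- function(e, bindings) {
    switch(e$kind,
      cn = e$value,
      ci = bindings[[e$variable]],
      apply = {
        v <- vapply(e$operands, oracle, 0, bindings = bindings)
        switch(e$operator,
          plus = sum(v), times = prod(v),
          minus = if (length(v) == 1L) -v else v[1L] - v[2L],
          divide = v[1L] / v[2L], exp = exp(v), sin = sin(v), cos = cos(v),
          abs = abs(v), stop("oracle: ", e$operator))
      },
      stop("oracle: ", e$kind))
  }
  set.seed(1234)
  gen <- function(depth) {
    if (depth <= 0 || runif(1) < 0.3) {
      if (runif(1) < 0.5) dimless(round(runif(1, -3, 3), 3))
      else mml_var(sample(c("a", "b"), 1L))
    } else {
      op <- sample(c("plus", "times", "minus", "divide", "exp", "sin", "cos", "abs"), 1L)
      nops <- if (op %in% c("exp", "sin", "cos", "abs")) 1L
              else sample(2:3, 1L)
      if (op %in% c("minus", "divide")) nops <- 2L
      mml_apply(op, lapply(seq_len(nops), function(i) gen(depth - 1L)))
    }
  }
  env <- env_new(c(a = 0.7, b = -1.3))
  for (i in 1:200) {
    e <- gen(4L)
    expect_identical(evaluate(e, env), oracle(e, list(a = 0.7, b = -1.3)))
  }
})
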