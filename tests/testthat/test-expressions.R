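test_that("evaluation follows standard mathematics and piecewise semantics", {
  expect_equal(evaluate_expr(parse_expr("x*y"), list(x = 2, y = 3)), 6)
  expect_equal(evaluate_expr(parse_expr("piecewise(1, t < 5, 0)"),
                             list(t = 7)), 0)
  expect_equal(evaluate_expr(parse_expr("exp(-k*t)"), list(k = 1, t = 1)),
               exp(-1))
  expect_true(evaluate_expr(parse_expr("(x < 1) & (y >= 0)"),
                            list(x = 0, y = 0)))
  # purity: repeated evaluation is bit-identical
  e <- parse_expr("exp(-k*t) + ln(k) * piecewise(2, t > 0.5, 0)")
  env <- list(k = 1.7, t = 0.9)
  expect_identical(evaluate_expr(e, env), evaluate_expr(e, env))
})

test_that("evaluation errors name the problem", {
  expect_error(evaluate_expr(parse_expr("k9 * x"), list(x = 1)), "k9")
  expect_error(evaluate_expr(parse_expr("1/x"), list(x = 0)),
               "evaluation error")
  expect_error(evaluate_expr(parse_expr("ln(x)"), list(x = -1)),
               "evaluation error")
  expect_error(parse_expr("factorial(x)"), "unsupported")
  expect_error(parse_expr("x +* y"), "syntax")
})

test_that("boolean-to-numeric conversion agrees with boolean evaluation", {
  expect_equal(evaluate_expr(boolean_to_numeric(
    parse_expr("(x < 1) & (y < 1)")), list(x = 0, y = 0)), 1)
  expect_equal(evaluate_expr(boolean_to_numeric(quote(!TRUE)), list()), 0)

  # property: random boolean expressions over three symbols agree with their
  # numeric encodings (true <-> 1) on many random environments
  set.seed(401)
  syms <- c("x", "y", "z")
  rand_bool <- function(depth) {
    if (depth <= 0 || stats::runif(1) < 0.35) {
      op <- sample(c("<", "<=", ">", ">=", "==", "!="), 1)
      return(call(op, as.symbol(sample(syms, 1)),
                  sample(c(-1, 0, 0.5, 1), 1)))
    }
    switch(sample(3, 1),
           call("&", rand_bool(depth - 1), rand_bool(depth - 1)),
           call("|", rand_bool(depth - 1), rand_bool(depth - 1)),
           call("!", rand_bool(depth - 1)))
  }
  for (rep in 1:40) {
    e <- rand_bool(3)
    en <- boolean_to_numeric(e)
    for (k in 1:25) {
      env <- as.list(stats::setNames(stats::runif(3, -2, 2), syms))
      expect_identical(as.numeric(evaluate_expr(e, env)),
                       evaluate_expr(en, env))
    }
  }
})

test_that("trigger margins are positive exactly when the trigger is true", {
  set.seed(402)
  exprs <- list(parse_expr("x < 0.5"), parse_expr("(x > 0) & (y < 1)"),
                parse_expr("!(x >= y)"), parse_expr("(x < 0) | (y > 0.5)"))
  for (e in exprs) {
    me <- sbkernel:::trigger_margin_expr(e)
    for (k in 1:50) {
      env <- list(x = stats::runif(1, -1, 1), y = stats::runif(1, -1, 1))
      b <- evaluate_expr(e, env)
      m <- evaluate_expr(me, env)
      if (m != 0) expect_identical(b, m > 0)
    }
  }
})
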