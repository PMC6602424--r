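test_that("compiled right-hand side equals N v for pure reaction networks", {
  m <- math_model(list(mm_variable("A", 3), mm_variable("B", 0)),
                  list(mm_parameter("k", 2)),
                  list(mm_reaction("r1", c(A = 1), c(B = 1),
                                   kinetic_law = "k*A")))
  sys <- compile_system(NULL, m)
  expect_equal(sys$rhs(0, sys$x0, sys$p0), c(-6, 6))

  m2 <- math_model(list(mm_variable("A", 1), mm_variable("B", 1),
                        mm_variable("C", 0)),
                   list(mm_parameter("k", 1)),
                   list(mm_reaction("r1", c(A = 2, B = 1), c(C = 1),
                                    kinetic_law = "k*A^2*B")))
  sys2 <- compile_system(NULL, m2)
  expect_equal(unname(sys2$N[, 1]), c(-2, -1, 1))

  # rhs == N v on random states (and compile is deterministic)
  set.seed(17)
  r <- random_mass_action(4, 5, seed = 21)
  sa <- compile_system(r$diagram, r$model)
  sb <- compile_system(r$diagram, r$model)
  expect_identical(sa$layout, sb$layout)
  for (i in 1:20) {
    x <- stats::setNames(stats::runif(length(sa$x0), 0, 5), sa$layout)
    expect_identical(sa$rhs(0, x, sa$p0), sb$rhs(0, x, sb$p0))
    expect_equal(sa$rhs(0, x, sa$p0),
                 as.numeric(sa$N %*% sa$rates(0, x, sa$p0)))
  }
})

test_that("stochastic compilation rejects incompatible models", {
  lg <- canonical("logistic")
  expect_error(compile_system(lg$diagram, lg$model, "stochastic"),
               "rate rule")
  m <- math_model(list(mm_variable("A", 1), mm_variable("B", 0)),
                  list(mm_parameter("k", 1)),
                  list(mm_reaction("r1", c(A = 0.5), c(B = 1),
                                   kinetic_law = "k*A")))
  expect_error(compile_system(NULL, m, "stochastic"), "non-integer")
})

test_that("constraints become halting events with negated triggers", {
  m <- canonical("constraint_demo")$model
  m2 <- constraints_to_events(m)
  expect_length(m2$constraints, 0L)
  expect_length(m2$events, 1L)
  expect_true(m2$events[[1]]$halt)
  expect_match(m2$events[[1]]$message, "0.25")
  # no constraints: unchanged
  d <- canonical("decay")$model
  expect_identical(constraints_to_events(d), d)
  # two constraints: two halt events, order preserved
  m3 <- math_model(list(mm_variable("x", 1)),
                   constraints = list(mm_constraint("c1", "x < 5", "one"),
                                      mm_constraint("c2", "x > 0", "two")))
  m4 <- constraints_to_events(m3)
  expect_identical(vapply(m4$events, `[[`, "", "message"), c("one", "two"))
})

test_that("fast reactions become algebraic relations plus pool dynamics", {
  m <- canonical("fast_equilibrium_demo")$model
  m2 <- fast_to_algebraic(m)
  expect_length(m2$reactions, 1L)           # only the slow inflow remains
  kinds <- vapply(m2$rules, `[[`, "", "kind")
  expect_equal(sum(kinds == "algebraic"), 2L)  # law = 0 and pool definition
  expect_equal(sum(kinds == "rate"), 1L)       # pool total ODE
  dyn <- vapply(m2$variables, `[[`, "", "dynamics")
  expect_identical(unname(dyn[c("A", "B")]), c("algebraic", "algebraic"))

  # quasi-equilibrium trajectory: kf A = kr B and T = T0 + v0 t
  sys <- compile_system(NULL, m2)
  tr <- simulate_ode(sys, ode_settings(t_end = 3, rel_tol = 1e-8, n_out = 31))
  Tt <- 3 + tr$times
  expect_equal(unname(tr$states[, "A"]), Tt / 3, tolerance = 1e-6)
  expect_equal(unname(tr$states[, "B"]), 2 * Tt / 3, tolerance = 1e-6)

  # no fast reactions: identity
  d <- canonical("decay")$model
  expect_identical(fast_to_algebraic(d), d)
  # unsupported kinetic form
  bad <- math_model(list(mm_variable("A", 1), mm_variable("B", 0)),
                    list(mm_parameter("V", 1), mm_parameter("K", 1)),
                    list(mm_reaction("f1", c(A = 1), c(B = 1),
                                     kinetic_law = "V*A/(K + A)",
                                     fast = TRUE, reversible = FALSE)))
  expect_error(fast_to_algebraic(bad), "unsupported transformation")
})

test_that("flattening merges connected variables and keeps dynamics", {
  mm <- canonical("decay_chain_modular")
  fl <- flatten(mm)
  expect_length(fl$model$variables, 3L)    # A, shared B, C
  expect_length(fl$model$reactions, 2L)
  expect_true(all(c("M1__A", "M1__B", "M2__C") %in%
                    names(fl$model$variables)))
  expect_length(validate_model(fl$diagram, fl$model), 0L)
  # no port nodes remain
  expect_false(any(vapply(fl$diagram$nodes, function(n)
    n$kind == "port", logical(1))))

  # single module: identity up to namespacing
  single <- compose(list(M = canonical("decay")$model))
  fs <- flatten(single)
  expect_identical(names(fs$model$variables), "M__A")
  sys0 <- compiled_fixture("decay")
  sys1 <- compile_system(fs$diagram, fs$model)
  expect_equal(unname(sys1$rhs(0, sys1$x0, sys1$p0)),
               unname(sys0$rhs(0, sys0$x0, sys0$p0)))

  # two ode-governed variables without a master is a composition error
  mA <- read_text(c("J1: A -> B; k*A", "A = 1", "B = 0", "k = 1"))$model
  mB <- read_text(c("J2:  -> B; v", "B = 0", "v = 1"))$model
  bad <- compose(list(M1 = mA, M2 = mB),
                 list(connection("undirected", c("M1.B", "M2.B"))))
  expect_error(flatten(bad), "master")
  # with a master it flattens
  okm <- compose(list(M1 = mA, M2 = mB),
                 list(connection("undirected", c("M1.B", "M2.B"),
                                 master = "M1.B")))
  expect_length(flatten(okm)$model$variables, 2L)
})

test_that("directed connections rewrite the consumer symbol", {
  producer <- read_text(c("J1: A -> ; k*A", "A = 2", "k = 1"))$model
  consumer <- read_text(c("y' = 3*u", "var y = 0", "const u = 0"))$model
  mm <- compose(list(P = producer, C = consumer),
                list(connection("directed", c("P.A", "C.u"), factor = 2)))
  fl <- flatten(mm)
  expect_false("C__u" %in% names(fl$model$variables))
  rl <- fl$model$rules[[1]]
  # consumer rate rule now reads 3 * (2 * P__A)
  env <- list(P__A = 2)
  expect_equal(evaluate_expr(rl$expression, env), 12)
})
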