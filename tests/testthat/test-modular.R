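test_that("composition validates modules and connection endpoints", {
  mA <- canonical("decay")$model
  mB <- read_text(c("J2: B -> ; k2*B", "B = 1", "k2 = 1"))$model
  mm <- compose(list(M1 = mA, M2 = mB),
                list(connection("undirected", c("M1.A", "M2.B"),
                                master = "M1.A")))
  expect_s3_class(mm, "ModularModel")
  expect_error(compose(list(M1 = mA),
                       list(connection("directed", c("M1.A", "M1.nope")))),
               "nope")
  expect_error(compose(list(M1 = mA),
                       list(connection("directed", c("MX.A", "M1.A")))),
               "MX")
  # zero connections: independent co-simulation is fine
  mm0 <- compose(list(M1 = mA, M2 = mB))
  tr <- simulate_agents(mm0, schedule_settings(h_ex = 0.5, t_end = 1,
                                               n_out = 11))
  expect_identical(colnames(tr$states), c("M1__A", "M2__B"))
})

test_that("a single module co-simulates identically to direct simulation", {
  mm <- compose(list(M = canonical("decay")$model))
  tr <- simulate_agents(mm, schedule_settings(h_ex = 0.25, t_end = 1,
                                              n_out = 11,
                                              ode = list(rel_tol = 1e-10)))
  sys <- compiled_fixture("decay")
  ref <- simulate_ode(sys, ode_settings(t_end = 1, n_out = 11,
                                        rel_tol = 1e-10))
  expect_equal(unname(tr$states[, "M__A"]), unname(ref$states[, "A"]),
               tolerance = 1e-9)
})

test_that("the scheduler converges to the flattened model as h_ex shrinks", {
  mm <- canonical("decay_chain_modular")
  fl <- flatten(mm)
  sysf <- compile_system(fl$diagram, fl$model)
  ref <- simulate_ode(sysf, ode_settings(t_end = 4, n_out = 41,
                                         rel_tol = 1e-10, abs_tol = 1e-12))
  devs <- vapply(c(0.04, 0.02, 0.01), function(h) {
    tr <- simulate_agents(mm, schedule_settings(h_ex = h, t_end = 4,
                                                n_out = 41,
                                                ode = list(rel_tol = 1e-10,
                                                           abs_tol = 1e-12)))
    max(abs(tr$states[, colnames(ref$states)] - ref$states))
  }, 0)
  expect_lt(devs[3], 0.01)          # first-order coupling error at h = 0.01
  expect_true(all(diff(devs) < 0))  # monotone in the exchange step
})

test_that("quantities conserved in the flattened model survive scheduling", {
  mm <- canonical("decay_chain_modular")
  h <- 0.05
  tr <- simulate_agents(mm, schedule_settings(h_ex = h, t_end = 4, n_out = 41,
                                              ode = list(rel_tol = 1e-10)))
  tot <- rowSums(tr$states[, c("M1__A", "M1__B", "M2__C")])
  expect_lt(diff(range(tot)), 5 * h)   # O(h_ex) bound; reconciliation keeps
  # boundary values exact, interior grid points carry the holding error
  bidx <- which(abs((tr$times / h) - round(tr$times / h)) < 1e-9)
  expect_lt(diff(range(tot[bidx])), 1e-7)
})

test_that("scheduler runs are deterministic, including stochastic modules", {
  mA <- read_text(c("J1: A -> B; k1*A", "A = 40", "B = 0", "k1 = 1"))$model
  mB <- read_text(c("J2: B -> ; k2*B", "B = 0", "k2 = 0.5"))$model
  mm <- compose(list(M1 = mA, M2 = mB),
                list(connection("undirected", c("M1.B", "M2.B"),
                                master = "M1.B")),
                engines = c(M1 = "stochastic"))
  st <- schedule_settings(h_ex = 0.1, t_end = 2, n_out = 21, seed = 7)
  t1 <- simulate_agents(mm, st)
  t2 <- simulate_agents(mm, st)
  expect_identical(t1$states, t2$states)
  # stochastic module states remain integers at boundaries (floor + carry)
  expect_true(all(t1$states[, "M1__A"] == round(t1$states[, "M1__A"])))
})
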