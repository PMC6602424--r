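test_that("stoichiometric relations express derivatives in fluxes", {
  m <- read_text(c("J1: A -> B; k*A", "A = 1", "B = 0", "k = 1"))$model
  rel <- stoichiometric_analysis(m)
  expect_identical(attr(rel$relations$A, "text"), "dA/dt = -J1")
  expect_identical(attr(rel$relations$B, "text"), "dB/dt = +J1")

  m2 <- read_text(c("J1: 2 A + B -> C; k*A^2*B", "A = 1", "B = 1", "C = 0",
                    "k = 1"))$model
  rel2 <- stoichiometric_analysis(m2)
  expect_equal(rel2$relations$A$coefficient, -2)

  empty <- math_model(list(mm_variable("A", 1)))
  expect_length(stoichiometric_analysis(empty)$relations, 0L)

  mixed <- math_model(list(mm_variable("A", 1)), list(mm_parameter("k", 1)),
                      list(mm_reaction("r", c(A = 1), numeric(0),
                                       kinetic_law = "k*A")),
                      rules = list(mm_rule("rate", "A", "1")))
  expect_error(stoichiometric_analysis(mixed), "structure error")
})

test_that("conservation analysis is exact with a clean partition", {
  ab <- read_text(c("J1: A <-> B; kf*A - kr*B", "A = 1", "B = 0",
                    "kf = 1", "kr = 1"))$model
  d <- conservation_analysis(ab)
  expect_equal(nrow(d$conservation), 1L)
  expect_equal(unname(d$conservation[1, ]), c(1, 1))
  expect_identical(d$independent, "A")

  em <- canonical("enzyme_mm")$model
  d2 <- conservation_analysis(em)
  expect_equal(nrow(d2$N_R), 2L)                       # rank(N) = 2
  expect_equal(nrow(d2$conservation), 2L)
  # vectors span {E + ES, S + ES + P}: check both pools are in the span
  expect_identical(unname(d2$conservation %*% d2$N),
                   matrix(0, 2, ncol(d2$N)))           # left null space
  for (m in list(c(E = 1, S = 0, ES = 1, P = 0),
                 c(E = 0, S = 1, ES = 1, P = 1))) {
    cf <- qr.solve(t(d2$conservation[, names(m)]), m)
    expect_equal(unname(t(d2$conservation[, names(m)]) %*% cf), cbind(m),
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
  # N = L N_R holds exactly (bit-identical values)
  expect_identical(unname(d2$L %*% d2$N_R), unname(d2$N))

  open <- read_text(c("J1:  -> A; v", "J2: A -> ; k*A", "A = 0",
                      "v = 1", "k = 1"))$model
  expect_equal(nrow(conservation_analysis(open)$conservation), 0L)
})

test_that("conservation vectors hold along simulated trajectories", {
  # cross-module property on random mass-action networks
  for (seed in c(2, 5, 9)) {
    r <- random_mass_action(4, 4, seed = seed)
    sys <- compile_system(r$diagram, r$model)
    tr <- simulate_ode(sys, ode_settings(t_end = 5, rel_tol = 1e-10,
                                         abs_tol = 1e-12,
                                         solver = "stiff_multistep"))
    expect_lt(max_conservation_drift(tr, r$model), 1e-6)
  }
})

test_that("steady-state sensitivities match closed forms", {
  tsp <- compiled_fixture("two_step_pathway")
  xs <- steady_state(tsp)
  sens <- steady_state_sensitivity(tsp, xs, c("k1", "k2", "absent"))
  # S* = k1 S0/(k1+k2); at k1=k2=1, S0=2: dS*/dk2 = -1/2, dS*/dk1 = +1/2
  expect_equal(unname(sens["S", "k2"]), -0.5, tolerance = 1e-5)
  expect_equal(unname(sens["S", "k1"]), 0.5, tolerance = 1e-5)
  expect_equal(unname(sens["S", "absent"]), 0)
})

test_that("metabolic control analysis matches closed forms and theorems", {
  tsp <- compiled_fixture("two_step_pathway")
  # symmetric case: equal control
  rep1 <- mca(tsp, steady_state(tsp))
  expect_equal(unname(rep1$flux_control[1, ]), c(0.5, 0.5), tolerance = 1e-6)
  # asymmetric case: C^J = (k2, k1)/(k1+k2)
  p <- c(k1 = 2, k2 = 1)
  xs <- steady_state(tsp, p0 = p)
  rep2 <- mca(tsp, xs, p0 = p)
  expect_equal(unname(rep2$flux_control[1, ]), c(1, 2) / 3, tolerance = 1e-4)

  # finite-difference oracle: d ln J / d ln k by re-solving the steady state
  flux_at <- function(p) {
    x <- steady_state(tsp, p0 = p)
    tsp$rates(0, x, replace(tsp$p0, names(p), p))
  }
  for (i in 1:2) {
    kn <- names(p)[i]
    up <- p; up[kn] <- up[kn] * (1 + 1e-4)
    dn <- p; dn[kn] <- dn[kn] * (1 - 1e-4)
    fd <- (log(flux_at(up)[1]) - log(flux_at(dn)[1])) / (2e-4)
    expect_equal(unname(rep2$flux_control[1, i]), fd, tolerance = 1e-4)
  }

  # summation theorems on a conservation-carrying open pathway
  chain <- compile_system(NULL, three_step_chain())
  repc <- mca(chain, steady_state(chain))
  expect_equal(unname(rowSums(repc$flux_control)), rep(1, 3),
               tolerance = 1e-6)
  expect_equal(unname(rowSums(repc$conc_control)), rep(0, 2),
               tolerance = 1e-6)

  # zero flux is an undefined scaling
  em <- compiled_fixture("enzyme_mm")       # closed: all fluxes die out
  xs_em <- steady_state(em)
  expect_error(mca(em, xs_em), "zero steady-state flux")
})
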