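# stochastic tolerances are 3 standard errors of the ensemble mean

se_of <- function(ens, var) sqrt(ens$var[nrow(ens$var), var] /
                                   ens$n_replicates)

test_that("the direct method matches the pure-death analytic mean", {
  dec <- compiled_fixture("decay", "stochastic")
  ens <- simulate_direct(dec, ssa_settings(t_end = 1, n_replicates = 1000,
                                           seed = 101), x0 = c(A = 100))
  m <- ens$mean[nrow(ens$mean), "A"]
  expect_lt(abs(m - 100 * exp(-1)), 3 * se_of(ens, "A"))
  # copy numbers stay nonnegative integers
  ens2 <- simulate_direct(dec, ssa_settings(t_end = 1, n_replicates = 5,
                                            seed = 5, keep_replicates = TRUE),
                          x0 = c(A = 50))
  for (r in ens2$replicates) {
    expect_true(all(r >= 0))
    expect_true(all(r == round(r)))
  }
})

test_that("the immigration-death process reaches its Poisson mean", {
  im <- compiled_fixture("immigration_death", "stochastic")
  ens <- simulate_direct(im, ssa_settings(t_end = 10, n_replicates = 800,
                                          seed = 102))
  m <- ens$mean[nrow(ens$mean), "X"]
  expect_lt(abs(m - 10), 3 * se_of(ens, "X"))
})

test_that("zero propensities leave the state constant with no events", {
  dec <- compiled_fixture("decay", "stochastic")
  ens <- simulate_direct(dec, ssa_settings(t_end = 1, n_replicates = 3,
                                           seed = 1), x0 = c(A = 10),
                         p0 = c(k = 0))
  expect_true(all(ens$mean[, "A"] == 10))
  expect_true(all(ens$event_counts == 0))
})

test_that("the next-reaction method is distributionally exact", {
  dec <- compiled_fixture("decay", "stochastic")
  ens <- simulate_next_reaction(dec, ssa_settings(t_end = 1,
                                                  n_replicates = 1000,
                                                  seed = 103),
                                x0 = c(A = 100))
  m <- ens$mean[nrow(ens$mean), "A"]
  expect_lt(abs(m - 100 * exp(-1)), 3 * se_of(ens, "A"))
})

test_that("direct and next-reaction agree on first two moments", {
  sys <- compile_system(NULL, three_reaction_model(), "stochastic")
  n <- 2000
  e1 <- simulate_direct(sys, ssa_settings(t_end = 5, n_replicates = n,
                                          seed = 104))
  e2 <- simulate_next_reaction(sys, ssa_settings(t_end = 5, n_replicates = n,
                                                 seed = 105))
  for (v in c("A", "B")) {
    se <- sqrt(e1$var[nrow(e1$var), v] / n + e2$var[nrow(e2$var), v] / n)
    expect_lt(abs(e1$mean[nrow(e1$mean), v] - e2$mean[nrow(e2$mean), v]),
              3 * se)
    # second moment (variance) within a generous normal-approx band
    vr1 <- e1$var[nrow(e1$var), v]; vr2 <- e2$var[nrow(e2$var), v]
    se_var <- sqrt(2 / (n - 1)) * max(vr1, vr2)
    expect_lt(abs(vr1 - vr2), 4 * se_var)
  }
})

test_that("the dependency graph couples reactions through shared species", {
  m <- read_text(c("J1: A -> B; k1*A", "J2: B -> C; k2*B",
                   "A = 5", "B = 0", "C = 0", "k1 = 1", "k2 = 1"))
  sys <- compile_system(m$diagram, m$model, "stochastic")
  dep <- dependency_graph(sys)
  expect_identical(dep[[1]], c(1L, 2L))  # firing J1 changes B, input of J2
  expect_identical(dep[[2]], 2L)         # firing J2 does not affect J1
})

test_that("tau-leaping approximates the exact method and tightens with tau", {
  dim_sys <- compiled_fixture("dimerization", "stochastic")
  exact <- simulate_direct(dim_sys, ssa_settings(t_end = 1,
                                                 n_replicates = 2000,
                                                 seed = 106))
  target <- exact$mean[nrow(exact$mean), "A"]
  bias <- vapply(c(0.1, 0.001), function(tau) {
    e <- simulate_tau_leap(dim_sys, ssa_settings(t_end = 1,
                                                 n_replicates = 2000,
                                                 seed = 107, tau = tau))
    abs(e$mean[nrow(e$mean), "A"] - target)
  }, 0)
  expect_gt(bias[1], bias[2])   # coarse leap is more biased
  e_fine <- simulate_tau_leap(dim_sys, ssa_settings(t_end = 1,
                                                    n_replicates = 1000,
                                                    seed = 108, tau = 0.001))
  se <- sqrt(e_fine$var[nrow(e_fine$var), "A"] / 1000 +
               exact$var[nrow(exact$var), "A"] / 2000)
  expect_lt(abs(e_fine$mean[nrow(e_fine$mean), "A"] - target), 4 * se)
  expect_error(simulate_tau_leap(dim_sys, ssa_settings(t_end = 1, tau = 0)),
               "tau")
})

test_that("a fixed seed reproduces the whole ensemble bit-identically", {
  dec <- compiled_fixture("decay", "stochastic")
  st <- ssa_settings(t_end = 1, n_replicates = 20, seed = 42,
                     keep_replicates = TRUE)
  for (f in list(simulate_direct, simulate_next_reaction)) {
    a <- f(dec, st, x0 = c(A = 50))
    b <- f(dec, st, x0 = c(A = 50))
    expect_identical(a$replicates, b$replicates)
    expect_identical(a$event_counts, b$event_counts)
  }
})

test_that("the ensemble mean tracks the ODE limit at large copy numbers", {
  dec <- canonical("decay")
  ode_sys <- compile_system(dec$diagram, dec$model)
  ssa_sys <- compile_system(dec$diagram, dec$model, "stochastic")
  tr <- simulate_ode(ode_sys, ode_settings(t_end = 1, rel_tol = 1e-10,
                                           n_out = 11),
                     x0 = c(A = 1000))
  ens <- simulate_direct(ssa_sys, ssa_settings(t_end = 1, n_out = 11,
                                               n_replicates = 400,
                                               seed = 109), x0 = c(A = 1000))
  for (i in c(6, 11)) {
    se <- sqrt(ens$var[i, "A"] / 400)
    expect_lt(abs(ens$mean[i, "A"] - tr$states[i, "A"]), 3 * se)
  }
})

test_that("negative propensities and non-integer starts are rejected", {
  dec <- compiled_fixture("decay", "stochastic")
  expect_error(simulate_direct(dec, ssa_settings(t_end = 1, seed = 1),
                               x0 = c(A = 10), p0 = c(k = -1)),
               "negative propensity")
  expect_error(simulate_direct(dec, ssa_settings(t_end = 1, seed = 1),
                               x0 = c(A = 1.5)), "integer")
})
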