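decay_problem <- function(ex = decay_experiment()) {
  fit_problem(canonical("decay"),
              data.frame(id = "k", lower = 0.01, upper = 10), list(ex))
}

test_that("the objective is zero at the truth and positive elsewhere", {
  prob <- decay_problem()
  expect_lt(fit_objective(prob, c(k = 1)), 1e-12)
  expect_gt(fit_objective(prob, c(k = 2)), 0.1)
  # relative observations: scale factor is profiled out analytically
  ex <- decay_experiment()
  ex$data$A <- 3.7 * ex$data$A
  prob_rel <- fit_problem(canonical("decay"),
                          data.frame(id = "k", lower = 0.01, upper = 10),
                          list(experiment_data(ex$data, relative = "A")))
  expect_lt(fit_objective(prob_rel, c(k = 1)), 1e-12)
  # steady-state experiments compare at the computed steady state
  ss <- experiment_data(data.frame(S = 1), kind = "steady_state")
  prob_ss <- fit_problem(canonical("two_step_pathway"),
                         data.frame(id = "k2", lower = 0.1, upper = 10),
                         list(ss))
  expect_lt(fit_objective(prob_ss, c(k2 = 1)), 1e-12)
  expect_gt(fit_objective(prob_ss, c(k2 = 2)), 0.05)
})

test_that("problem construction validates bounds and observed symbols", {
  expect_error(fit_problem(canonical("decay"),
                           data.frame(id = "k", lower = 0, upper = Inf),
                           list(decay_experiment())), "finite")
  expect_error(fit_problem(canonical("decay"),
                           data.frame(id = "zz", lower = 0, upper = 1),
                           list(decay_experiment())), "zz")
  bad <- decay_experiment()
  names(bad$data)[2] <- "Q"
  bad$observed <- "Q"
  expect_error(fit_problem(canonical("decay"),
                           data.frame(id = "k", lower = 0, upper = 1),
                           list(bad)), "Q")
})

test_that("SRES recovers parameters from noiseless data", {
  prob <- decay_problem()
  res <- fit_sres(prob, lambda = 20, mu = 4, generations = 25, seed = 11)
  expect_lt(abs(res$best[["k"]] - 1), 1e-3)
  expect_true(all(diff(res$trace) <= 0))        # monotone best-so-far
  # seeded determinism
  res2 <- fit_sres(prob, lambda = 20, mu = 4, generations = 25, seed = 11)
  expect_identical(res$best, res2$best)
  expect_identical(res$trace, res2$trace)
  # generations = 0: best of the initial population, lambda evaluations
  res0 <- fit_sres(prob, lambda = 12, mu = 3, generations = 0, seed = 3)
  expect_equal(res0$evaluations, 12L)
  expect_length(res0$trace, 1L)
  expect_error(fit_sres(prob, lambda = 3, mu = 5), "lambda")
})

test_that("PSO recovers parameters and honours its contracts", {
  prob <- decay_problem()
  res <- fit_pso(prob, swarm = 15, iterations = 40, seed = 21)
  expect_lt(abs(res$best[["k"]] - 1), 1e-3)
  expect_true(all(diff(res$trace) <= 0))
  res2 <- fit_pso(prob, swarm = 15, iterations = 40, seed = 21)
  expect_identical(res$best, res2$best)
  res0 <- fit_pso(prob, swarm = 10, iterations = 0, seed = 4)
  expect_equal(res0$evaluations, 10L)
  expect_error(fit_pso(prob, swarm = 0), "swarm")
})

test_that("PSO minimizes a plain quadratic embedded as a mock objective", {
  # sphere function via a rate-rule model whose steady state is irrelevant:
  # fit two initial values against zero observations
  m <- read_text(c("var u = 0", "var v = 0", "u' = 0", "v' = 0"))
  ex <- experiment_data(data.frame(time = 1, u = 0.3, v = -0.2))
  prob <- fit_problem(m, data.frame(id = c("u", "v"), lower = c(-2, -2),
                                    upper = c(2, 2)), list(ex))
  res <- fit_pso(prob, swarm = 20, iterations = 60, seed = 5)
  expect_lt(res$objective, 1e-4)
  expect_equal(unname(res$best), c(0.3, -0.2), tolerance = 0.05)
})

test_that("two-parameter pathway recovery reaches percent-level accuracy", {
  truth <- c(k1 = 1.4, k2 = 0.6)
  prob <- fit_problem(canonical("two_step_pathway"),
                      data.frame(id = c("k1", "k2"), lower = c(0.05, 0.05),
                                 upper = c(5, 5)),
                      list(two_step_experiment(truth[1], truth[2])))
  res <- fit_sres(prob, lambda = 30, mu = 5, generations = 40, seed = 31)
  expect_lt(max(abs(res$best - truth) / truth), 0.01)
})

test_that("the reported objective is the re-evaluated objective of the best", {
  prob <- decay_problem()
  res <- fit_sres(prob, lambda = 12, mu = 3, generations = 5, seed = 9)
  expect_equal(res$objective, fit_objective(prob, res$best), tolerance = 1e-12)
})
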