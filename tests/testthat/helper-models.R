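# shared builders for the test-suite; fixtures are generated in code

# noiseless (or 1%-noisy) decay observations A(t) = exp(-k t), k = 1
decay_experiment <- function(times = seq(0.2, 3, by = 0.2), noise_sd = 0,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  y <- exp(-times)
  if (noise_sd > 0) y <- y * (1 + stats::rnorm(length(y), 0, noise_sd))
  experiment_data(data.frame(time = times, A = y))
}

# noiseless two-step-pathway observations S(t) with parameters (k1, k2)
two_step_experiment <- function(k1 = 1.4, k2 = 0.6,
                                times = seq(0.25, 4, by = 0.25)) {
  sstar <- 2 * k1 / (k1 + k2)
  S <- sstar * (1 - exp(-(k1 + k2) * times))
  experiment_data(data.frame(time = times, S = S))
}

compiled_fixture <- function(name, engine = "ode") {
  m <- canonical(name)
  compile_system(m$diagram, m$model, engine)
}

# three-reaction open network used for cross-method stochastic checks:
# birth, conversion, death
three_reaction_model <- function() {
  math_model(
    list(mm_variable("A", 0), mm_variable("B", 0)),
    list(mm_parameter("b", 5), mm_parameter("c", 0.3),
         mm_parameter("d", 0.4)),
    list(mm_reaction("Rb", numeric(0), c(A = 1), kinetic_law = "b"),
         mm_reaction("Rc", c(A = 1), c(B = 1), kinetic_law = "c*A"),
         mm_reaction("Rd", c(B = 1), numeric(0), kinetic_law = "d*B")))
}

# open three-step linear pathway with nonzero steady-state fluxes
three_step_chain <- function() {
  math_model(
    list(mm_variable("X1", 0), mm_variable("X2", 0)),
    list(mm_parameter("v0", 2), mm_parameter("q1", 1.3),
         mm_parameter("q2", 0.7)),
    list(mm_reaction("R0", numeric(0), c(X1 = 1), kinetic_law = "v0"),
         mm_reaction("R1", c(X1 = 1), c(X2 = 1), kinetic_law = "q1*X1"),
         mm_reaction("R2", c(X2 = 1), numeric(0), kinetic_law = "q2*X2")))
}

max_conservation_drift <- function(traj, model) {
  cons <- conservation_analysis(model)
  if (!nrow(cons$conservation)) return(0)
  tot <- traj$states[, rownames(cons$N), drop = FALSE] %*%
    t(cons$conservation)
  max(apply(tot, 2L, function(z) diff(range(z))))
}
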