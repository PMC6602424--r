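# Parameter estimation against time-course / steady-state experiments with
# exact or relative observations, by two global stochastic optimizers: a
# stochastic-ranking (mu, lambda) evolution strategy and global-best particle
# swarm optimization.  Both are seeded-deterministic and keep a monotone
# best-so-far trace.

#' Experimental observations
#'
#' @param data Data frame.  For `kind = "time_course"` the first column must
#'   be `time`; remaining columns are observed symbols (NA = missing cell).
#'   For `kind = "steady_state"` there is no time column.
#' @param kind `"time_course"` or `"steady_state"`.
#' @param weights Named numeric weights per observed symbol (default 1).
#' @param relative Character vector of symbols observed only up to a scale
#'   factor; they are compared after per-symbol least-squares scaling of the
#'   simulated series.
#' @param name Experiment label.
#' @export
experiment_data <- function(data, kind = c("time_course", "steady_state"),
                            weights = NULL, relative = character(0),
                            name = "experiment") {
  kind <- match.arg(kind)
  if (kind == "time_course") {
    stopifnot("time" %in% names(data))
    if (anyDuplicated(data$time)) stop("duplicate time points", call. = FALSE)
    data <- data[order(data$time), , drop = FALSE]
  }
  obs <- setdiff(names(data), "time")
  w <- stats::setNames(rep(1, length(obs)), obs)
  if (!is.null(weights)) w[names(weights)] <- weights
  if (any(w <= 0)) stop("weights must be positive", call. = FALSE)
  structure(list(kind = kind, data = data, observed = obs, weights = w,
                 relative = relative, name = name),
            class = "ExperimentData")
}

#' Read a time-course (or steady-state) table
#'
#' Reads a delimited table, comma by default with tab auto-detected.  For
#' time courses the first column is time; blank cells are kept as missing
#' observations.  Non-numeric cells and duplicate times are errors.
#'
#' @param path File path.
#' @param steady_state If `TRUE` the table has no time column and describes
#'   steady-state observations.
#' @param ... Passed to [experiment_data()] (`weights`, `relative`, `name`).
#' @return An `ExperimentData`.
#' @export
read_timecourse <- function(path, steady_state = FALSE, ...) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  for (j in seq_along(df)) {
    if (is.character(df[[j]])) {
      conv <- suppressWarnings(as.numeric(df[[j]]))
      bad <- which(!is.na(df[[j]]) & nzchar(trimws(df[[j]])) & is.na(conv))
      if (length(bad))
        stop("non-numeric cell in column '", names(df)[j], "', row ",
             bad[[1L]], ": '", df[[j]][bad[[1L]]], "'", call. = FALSE)
      df[[j]] <- conv
    }
  }
  if (!steady_state) {
    names(df)[1L] <- "time"
    if (anyDuplicated(df$time))
      stop("duplicate time value in '", path, "'", call. = FALSE)
  }
  experiment_data(df, kind = if (steady_state) "steady_state"
                  else "time_course", ...)
}

#' Define a parameter-estimation problem
#'
#' @param model `list(diagram=, model=)`, a `MathModel`, or a
#'   `CompiledSystem`.
#' @param free Data frame with columns `id`, `lower`, `upper`: the free
#'   parameters and their finite box bounds.  Ids may name parameters or
#'   variables (the latter fit initial values).
#' @param experiments List of [experiment_data()] objects.
#' @param objective `"sse"` or `"weighted_sse"` (weights from the data).
#' @param sim One [ode_settings()]-style list of overrides used for every
#'   experiment simulation (`rel_tol`, `abs_tol`, `solver`).
#' @param init_overrides Optional per-experiment named lists of initial-value
#'   overrides (list parallel to `experiments`).
#' @export
fit_problem <- function(model, free, experiments,
                        objective = c("weighted_sse", "sse"),
                        sim = list(), init_overrides = NULL) {
  objective <- match.arg(objective)
  sys <- if (inherits(model, "CompiledSystem")) model else
    compile_system(if (!inherits(model, "MathModel")) model$diagram,
                   if (inherits(model, "MathModel")) model else model$model,
                   engine = "ode")
  stopifnot(is.data.frame(free),
            all(c("id", "lower", "upper") %in% names(free)))
  if (!all(is.finite(free$lower) & is.finite(free$upper)))
    stop("parameter bounds must be finite", call. = FALSE)
  if (!all(free$lower < free$upper))
    stop("lower bounds must be below upper bounds", call. = FALSE)
  known <- c(sys$par_layout, sys$layout)
  missing <- setdiff(free$id, known)
  if (length(missing))
    stop("free parameter(s) not in the model: ",
         paste(missing, collapse = ", "), call. = FALSE)
  for (ex in experiments) {
    stopifnot(inherits(ex, "ExperimentData"))
    bad <- setdiff(ex$observed, sys$layout)
    if (length(bad))
      stop("experiment '", ex$name, "' observes unknown symbol(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(system = sys, free = free, experiments = experiments,
                 objective = objective, sim = sim,
                 init_overrides = init_overrides),
            class = "FitProblem")
}

#' Objective value of a parameter vector
#'
#' Sum over experiments of weighted squared residuals between simulation and
#' observations.  Relative observations are compared after the closed-form
#' least-squares scale `c = sum(w y yhat) / sum(w yhat^2)` per (experiment,
#' symbol); steady-state experiments are compared at the computed steady
#' state.  A failed simulation yields `Inf` (penalty), with the failure
#' message attached as an attribute.
#'
#' @param problem A [fit_problem()].
#' @param theta Named (or `free`-ordered) parameter vector within bounds.
#' @export
fit_objective <- function(problem, theta) {
  sys <- problem$system
  if (is.null(names(theta))) names(theta) <- problem$free$id
  pover <- theta[names(theta) %in% sys$par_layout]
  xover <- theta[names(theta) %in% sys$layout]
  total <- 0
  for (k in seq_along(problem$experiments)) {
    ex <- problem$experiments[[k]]
    xo <- xover
    ov <- if (!is.null(problem$init_overrides))
      problem$init_overrides[[k]] else NULL
    if (length(ov)) xo[names(ov)] <- unlist(ov)
    if (ex$kind == "steady_state") {
      xs <- tryCatch(steady_state(sys, guess = if (length(xo)) xo,
                                  p0 = if (length(pover)) pover),
                     error = function(e) e)
      if (inherits(xs, "error"))
        return(structure(Inf, failure = conditionMessage(xs)))
      sim <- matrix(xs[ex$observed], 1L,
                    dimnames = list(NULL, ex$observed))
      obs_rows <- 1L
    } else {
      tt <- ex$data$time
      t0 <- min(0, tt[1L])
      args <- utils::modifyList(
        list(t_end = max(tt), t0 = t0,
             times = sort(unique(c(t0, tt))), rel_tol = 1e-8,
             abs_tol = 1e-10),
        problem$sim)
      st <- do.call(ode_settings, args)
      tr <- tryCatch(simulate_ode(sys, st,
                                  x0 = if (length(xo)) xo,
                                  p0 = if (length(pover)) pover),
                     error = function(e) e)
      if (inherits(tr, "error"))
        return(structure(Inf, failure = conditionMessage(tr)))
      if (!is.null(tr$halt) || length(tr$times) < length(st$times))
        return(structure(Inf, failure = "simulation halted early"))
      sim <- tr$states[match(tt, tr$times), ex$observed, drop = FALSE]
      obs_rows <- seq_along(tt)
    }
    for (s in ex$observed) {
      y <- ex$data[[s]][obs_rows]
      keep <- !is.na(y)
      if (!any(keep)) next
      yhat <- sim[keep, s]
      w <- if (problem$objective == "weighted_sse") ex$weights[[s]] else 1
      if (s %in% ex$relative) {
        denom <- sum(w * yhat^2)
        cc <- if (denom > 0) sum(w * y[keep] * yhat) / denom else 0
        yhat <- cc * yhat
      }
      total <- total + sum(w * (y[keep] - yhat)^2)
    }
  }
  total
}

.fit_result <- function(best, fbest, trace, evals, seed, problem) {
  # contract: reported objective is the re-evaluated objective of `best`
  fchk <- fit_objective(problem, best)
  structure(list(best = best, objective = as.numeric(fchk), trace = trace,
                 evaluations = evals, seed = seed),
            class = "FitResult")
}

#' @export
print.FitResult <- function(x, ...) {
  cat("FitResult: objective", format(x$objective), "after", x$evaluations,
      "evaluations\n")
  print(round(x$best, 6))
  invisible(x)
}

#' Stochastic-ranking evolution strategy
#'
#' A (mu, lambda) evolution strategy with log-normal self-adaptive step sizes.
#' Offspring are ranked by a stochastic-ranking bubble sort: when at least one
#' of a compared pair violates the box bounds, the pair is ordered by
#' objective with probability `pf` and by the (squared) bound violation
#' otherwise.  Out-of-bounds candidates are evaluated at the clamped point
#' and penalized through the ranking.  The best-so-far never worsens.
#'
#' @param problem A [fit_problem()].
#' @param lambda Offspring per generation (default `7 * mu`).
#' @param mu Parents.
#' @param generations Number of generations (0 = evaluate the initial
#'   population only).
#' @param pf Rank-pressure probability.
#' @param seed RNG seed (fixed seed = identical result).
#' @return A `FitResult` (best vector, re-evaluated best objective, monotone
#'   best-so-far trace, evaluation count, seed).
#' @export
fit_sres <- function(problem, lambda = 7L * mu, mu = 15L, generations = 100L,
                     pf = 0.45, seed = 1L) {
  if (lambda < mu) stop("population lambda must be at least mu", call. = FALSE)
  set.seed(seed)
  lo <- problem$free$lower; hi <- problem$free$upper
  n <- length(lo)
  ids <- problem$free$id
  clamp <- function(x) pmin(pmax(x, lo), hi)
  phi <- function(x) sum(pmax(0, lo - x)^2 + pmax(0, x - hi)^2)
  evalf <- function(x) fit_objective(problem, stats::setNames(clamp(x), ids))
  tau <- 1 / sqrt(2 * sqrt(n)); tau2 <- 1 / sqrt(2 * n)
  sigma0 <- (hi - lo) / sqrt(n)

  # initial population
  X <- matrix(stats::runif(lambda * n, lo, hi), n, lambda)
  S <- matrix(sigma0, n, lambda)
  f <- apply(X, 2L, evalf)
  g <- apply(X, 2L, phi)     # zero: uniform sampling respects bounds
  evals <- lambda
  rank_order <- function(f, g) {
    idx <- seq_along(f)
    for (sweep in seq_along(idx)) {
      swapped <- FALSE
      for (i in seq_len(length(idx) - 1L)) {
        a <- idx[i]; b <- idx[i + 1L]
        both_feasible <- g[a] == 0 && g[b] == 0
        by_f <- both_feasible || stats::runif(1L) < pf
        worse <- if (by_f) f[a] > f[b] else g[a] > g[b]
        if (worse) { idx[i] <- b; idx[i + 1L] <- a; swapped <- TRUE }
      }
      if (!swapped) break
    }
    idx
  }
  ord <- rank_order(f, g)
  P <- X[, ord[seq_len(mu)], drop = FALSE]
  PS <- S[, ord[seq_len(mu)], drop = FALSE]
  feas <- ord[g[ord] == 0]
  best_idx <- if (length(feas)) feas[[1L]] else ord[[1L]]
  best <- clamp(X[, best_idx]); fbest <- f[best_idx]
  trace <- fbest

  for (gen in seq_len(generations)) {
    X <- matrix(0, n, lambda); S <- matrix(0, n, lambda)
    for (j in seq_len(lambda)) {
      pidx <- sample.int(mu, 1L)
      g0 <- stats::rnorm(1L)
      S[, j] <- pmin(PS[, pidx] * exp(tau2 * g0 + tau * stats::rnorm(n)),
                     hi - lo)
      X[, j] <- P[, pidx] + S[, j] * stats::rnorm(n)
    }
    f <- apply(X, 2L, evalf)
    g <- apply(X, 2L, phi)
    evals <- evals + lambda
    ord <- rank_order(f, g)
    P <- X[, ord[seq_len(mu)], drop = FALSE]
    PS <- S[, ord[seq_len(mu)], drop = FALSE]
    feas <- ord[g[ord] == 0]
    cand <- if (length(feas)) feas[[1L]] else ord[[1L]]
    if (f[cand] < fbest) { fbest <- f[cand]; best <- clamp(X[, cand]) }
    trace <- c(trace, fbest)
  }
  .fit_result(stats::setNames(best, ids), fbest, trace, evals, seed, problem)
}

#' Particle swarm optimization (global best)
#'
#' Velocities are clamped to the width of the bound box; particles leaving
#' the box are reflected back and their velocity reversed in the offending
#' coordinates.  The best-so-far never worsens and the run is reproducible
#' under a fixed seed.
#'
#' @param problem A [fit_problem()].
#' @param swarm Swarm size.
#' @param w Inertia weight.
#' @param c1,c2 Cognitive and social acceleration coefficients.
#' @param iterations Number of iterations (0 = evaluate the initial swarm).
#' @param seed RNG seed.
#' @return A `FitResult`.
#' @export
fit_pso <- function(problem, swarm = 30L, w = 0.72, c1 = 1.49, c2 = 1.49,
                    iterations = 200L, seed = 1L) {
  if (swarm < 1L) stop("swarm size must be positive", call. = FALSE)
  set.seed(seed)
  lo <- problem$free$lower; hi <- problem$free$upper
  n <- length(lo)
  ids <- problem$free$id
  vmax <- hi - lo
  evalf <- function(x) fit_objective(problem, stats::setNames(x, ids))
  X <- matrix(stats::runif(swarm * n, lo, hi), n, swarm)
  V <- matrix(stats::runif(swarm * n, -vmax / 2, vmax / 2), n, swarm)
  f <- apply(X, 2L, evalf)
  evals <- swarm
  Pb <- X; fPb <- f
  gb <- which.min(f)
  best <- X[, gb]; fbest <- f[gb]
  trace <- fbest
  for (it in seq_len(iterations)) {
    for (j in seq_len(swarm)) {
      r1 <- stats::runif(n); r2 <- stats::runif(n)
      V[, j] <- w * V[, j] + c1 * r1 * (Pb[, j] - X[, j]) +
        c2 * r2 * (best - X[, j])
      V[, j] <- pmin(pmax(V[, j], -vmax), vmax)
      x <- X[, j] + V[, j]
      # reflect at the bounds
      for (rep in 1:3) {
        below <- x < lo; above <- x > hi
        if (!any(below | above)) break
        x[below] <- 2 * lo[below] - x[below]
        x[above] <- 2 * hi[above] - x[above]
        V[below | above, j] <- -V[below | above, j]
      }
      x <- pmin(pmax(x, lo), hi)
      X[, j] <- x
      fx <- evalf(x)
      evals <- evals + 1L
      if (fx < fPb[j]) { Pb[, j] <- x; fPb[j] <- fx }
      if (fx < fbest) { best <- x; fbest <- fx }
    }
    trace <- c(trace, fbest)
  }
  .fit_result(stats::setNames(best, ids), fbest, trace, evals, seed, problem)
}

#' Export a fit result as JSON plus a CSV objective trace
#' @param result A `FitResult`.
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @export
write_fit_result <- function(result, dir = ".", prefix = "fit") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(list(best = as.list(result$best),
                            objective = result$objective,
                            evaluations = result$evaluations,
                            seed = result$seed),
                       file.path(dir, paste0(prefix, "_result.json")),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(data.frame(iteration = seq_along(result$trace) - 1L,
                              best_objective = result$trace),
                   file.path(dir, paste0(prefix, "_trace.csv")),
                   row.names = FALSE)
  invisible(dir)
}
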