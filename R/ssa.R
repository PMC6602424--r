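# Exact stochastic simulation of the reaction network as a continuous-time
# Markov chain: Gillespie's direct method, the Gibson-Bruck next-reaction
# method (reaction dependency graph + indexed priority queue with time
# rescaling), and fixed-step tau-leaping.  Kinetic laws are interpreted
# verbatim as propensities; no combinatorial rescaling is applied.

#' Settings for stochastic simulation
#'
#' @param t_end Final time.
#' @param t0 Initial time.
#' @param n_out Number of uniform output grid points (state sampled
#'   last-value-carried-forward).
#' @param times Explicit output times.
#' @param n_replicates Number of independent realizations.
#' @param seed Master seed; each replicate runs on its own child stream, so a
#'   fixed seed makes the whole ensemble bit-reproducible.
#' @param tau Fixed leap size (tau-leaping only).
#' @param keep_replicates Keep every replicate's sampled trajectory.
#' @export
ssa_settings <- function(t_end, t0 = 0, n_out = 101L, times = NULL,
                         n_replicates = 1L, seed = 1L, tau = NULL,
                         keep_replicates = FALSE) {
  stopifnot(t_end > t0, n_replicates >= 1L)
  if (is.null(times)) times <- seq(t0, t_end, length.out = n_out)
  structure(list(t0 = t0, t_end = t_end, times = times,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed), tau = tau,
                 keep_replicates = keep_replicates),
            class = "SsaSettings")
}

#' @keywords internal
.ssa_prepare <- function(system, x0, p0) {
  if (system$engine != "stochastic")
    stop("system was compiled for engine '", system$engine,
         "'; compile with engine = 'stochastic'", call. = FALSE)
  if (length(system$events))
    stop("stochastic engines do not support events/constraints", call. = FALSE)
  x <- system$x0
  p <- system$p0
  if (!is.null(x0)) x[names(x0)] <- x0
  if (!is.null(p0)) p[names(p0)] <- p0
  ode_idx <- which(system$dynamics == "ode")
  if (any(abs(x[ode_idx] - round(x[ode_idx])) > 1e-9))
    stop("stochastic simulation requires an integer initial state",
         call. = FALSE)
  x[ode_idx] <- round(x[ode_idx])
  list(x = x, p = p)
}

# shared ensemble runner: `realize(x, p)` returns list(times=, states=,
# counts=) of one replicate sampled on the grid
#' @keywords internal
.ssa_ensemble <- function(system, settings, realize, x0, p0) {
  init <- .ssa_prepare(system, x0, p0)
  grid <- settings$times
  nvar <- length(system$layout)
  nrep <- settings$n_replicates
  set.seed(settings$seed)
  child_seeds <- sample.int(.Machine$integer.max - 1L, nrep)
  sum_x <- matrix(0, length(grid), nvar)
  sum_x2 <- matrix(0, length(grid), nvar)
  counts <- matrix(0, nrep, length(system$reaction_ids),
                   dimnames = list(NULL, system$reaction_ids))
  reps <- if (settings$keep_replicates) vector("list", nrep) else NULL
  for (r in seq_len(nrep)) {
    set.seed(child_seeds[[r]])
    one <- realize(init$x, init$p)
    sum_x <- sum_x + one$states
    sum_x2 <- sum_x2 + one$states^2
    counts[r, ] <- one$counts
    if (settings$keep_replicates) reps[[r]] <- one$states
  }
  mean_x <- sum_x / nrep
  var_x <- if (nrep > 1) (sum_x2 - nrep * mean_x^2) / (nrep - 1) else
    matrix(NA_real_, length(grid), nvar)
  colnames(mean_x) <- colnames(var_x) <- system$layout
  structure(list(times = grid, mean = mean_x, var = var_x,
                 n_replicates = nrep, event_counts = counts,
                 replicates = reps, seed = settings$seed),
            class = "EnsembleResult")
}

#' @export
print.EnsembleResult <- function(x, ...) {
  cat("EnsembleResult:", x$n_replicates, "replicates,",
      length(x$times), "grid points,", ncol(x$mean), "variables\n")
  invisible(x)
}

# sample a jump trajectory on the grid, last value carried forward
#' @keywords internal
.grid_sampler <- function(grid, nvar) {
  states <- matrix(0, length(grid), nvar)
  gi <- 1L
  list(
    advance = function(t_next, x) {
      # record x at all grid points strictly before t_next
      while (gi <= length(grid) && grid[gi] < t_next - 1e-15) {
        states[gi, ] <<- x
        gi <<- gi + 1L
      }
    },
    finish = function(x) {
      while (gi <= length(grid)) { states[gi, ] <<- x; gi <<- gi + 1L }
      states
    })
}

#' @keywords internal
.check_propensities <- function(a, system, x, t) {
  bad <- which(a < 0)
  if (length(bad))
    stop("model error: negative propensity for reaction '",
         system$reaction_ids[bad[1L]], "' at t = ", format(t), ", state ",
         paste(sprintf("%s=%g", system$layout, x), collapse = ", "),
         call. = FALSE)
  a
}

#' Gillespie direct method
#'
#' Statistically exact realizations of the reaction-network CTMC.  Waiting
#' times are exponential in the total propensity; the firing reaction is
#' chosen proportionally to its propensity.
#'
#' @param system A `CompiledSystem` compiled with `engine = "stochastic"`.
#' @param settings An [ssa_settings()].
#' @param x0,p0 Optional named overrides.
#' @return An `EnsembleResult` (grid, ensemble mean/variance, realized event
#'   counts, optionally per-replicate states).
#' @export
simulate_direct <- function(system, settings, x0 = NULL, p0 = NULL) {
  N <- system$N
  nr <- ncol(N)
  realize <- function(x, p) {
    t <- settings$t0
    smp <- .grid_sampler(settings$times, length(x))
    cnt <- numeric(nr)
    repeat {
      a <- .check_propensities(system$rates(t, x, p), system, x, t)
      a0 <- sum(a)
      if (a0 <= 0 || t >= settings$t_end) break
      dt <- stats::rexp(1L, a0)
      if (t + dt > settings$t_end) { t <- settings$t_end; break }
      j <- findInterval(stats::runif(1L) * a0, cumsum(a),
                        left.open = TRUE) + 1L
      t <- t + dt
      smp$advance(t, x)
      x <- x + N[, j]
      cnt[j] <- cnt[j] + 1L
    }
    list(states = smp$finish(x), counts = cnt)
  }
  .ssa_ensemble(system, settings, realize, x0, p0)
}

## ---- indexed priority queue for the next-reaction method ----

#' @keywords internal
.ipq_new <- function(keys) {
  n <- length(keys)
  e <- new.env(parent = emptyenv())
  e$key <- keys
  e$heap <- seq_len(n)     # heap positions -> reaction index
  e$pos <- seq_len(n)      # reaction index -> heap position
  swap <- function(i, j) {
    hi <- e$heap[i]; hj <- e$heap[j]
    e$heap[i] <- hj; e$heap[j] <- hi
    e$pos[hj] <- i; e$pos[hi] <- j
  }
  up <- function(i) {
    while (i > 1L) {
      par <- i %/% 2L
      if (e$key[e$heap[i]] < e$key[e$heap[par]]) { swap(i, par); i <- par }
      else break
    }
  }
  down <- function(i) {
    repeat {
      l <- 2L * i; r <- l + 1L; m <- i
      if (l <= n && e$key[e$heap[l]] < e$key[e$heap[m]]) m <- l
      if (r <= n && e$key[e$heap[r]] < e$key[e$heap[m]]) m <- r
      if (m == i) break
      swap(i, m); i <- m
    }
  }
  for (i in rev(seq_len(n %/% 2L))) down(i)
  e$update <- function(j, newkey) {
    old <- e$key[j]
    e$key[j] <- newkey
    if (newkey < old) up(e$pos[j]) else down(e$pos[j])
  }
  e$top <- function() e$heap[1L]
  e
}

#' Reaction dependency graph
#'
#' Edge j -> k when firing reaction j changes a species that reaction k's
#' propensity depends on.  Every reaction also depends on itself.
#'
#' @param system A `CompiledSystem`.
#' @return List of integer vectors, one per reaction.
#' @export
dependency_graph <- function(system) {
  model <- system$model
  reacts <- model$reactions
  inputs <- lapply(reacts, function(r)
    intersect(expr_symbols(r$kinetic_law), system$layout))
  affects <- lapply(seq_along(reacts), function(j)
    system$layout[system$N[, j] != 0])
  lapply(seq_along(reacts), function(j)
    which(vapply(seq_along(reacts), function(k)
      k == j || length(intersect(affects[[j]], inputs[[k]])) > 0,
      logical(1))))
}

#' Gibson-Bruck next-reaction method
#'
#' Distributionally identical to the direct method; keeps tentative absolute
#' firing times in an indexed priority queue and rescales the times of
#' dependent reactions when their propensity changes, so each step costs
#' O(log R + out-degree).
#'
#' @inheritParams simulate_direct
#' @export
simulate_next_reaction <- function(system, settings, x0 = NULL, p0 = NULL) {
  N <- system$N
  nr <- ncol(N)
  dep <- dependency_graph(system)
  realize <- function(x, p) {
    t <- settings$t0
    smp <- .grid_sampler(settings$times, length(x))
    cnt <- numeric(nr)
    a <- .check_propensities(system$rates(t, x, p), system, x, t)
    tau <- ifelse(a > 0, t + stats::rexp(nr) / a, Inf)
    q <- .ipq_new(tau)
    repeat {
      mu <- q$top()
      tmu <- q$key[mu]
      if (!is.finite(tmu) || tmu > settings$t_end) break
      smp$advance(tmu, x)
      t <- tmu
      x <- x + N[, mu]
      cnt[mu] <- cnt[mu] + 1L
      a_new <- .check_propensities(system$rates(t, x, p), system, x, t)
      for (al in dep[[mu]]) {
        if (al == mu) {
          q$update(al, if (a_new[al] > 0) t + stats::rexp(1L) / a_new[al]
                       else Inf)
        } else if (a_new[al] != a[al]) {
          old_tau <- q$key[al]
          nt <- if (a_new[al] > 0) {
            if (a[al] > 0 && is.finite(old_tau))
              t + (a[al] / a_new[al]) * (old_tau - t)
            else t + stats::rexp(1L) / a_new[al]
          } else Inf
          q$update(al, nt)
        }
      }
      a <- a_new
    }
    list(states = smp$finish(x), counts = cnt)
  }
  .ssa_ensemble(system, settings, realize, x0, p0)
}

#' Fixed-step tau-leaping
#'
#' Poisson-increment approximation with reject-and-halve negativity handling:
#' a leap that would drive any copy number negative is rejected and retried
#' at half the step.  Converges in mean to the exact methods as tau tends
#' to 0.
#'
#' @inheritParams simulate_direct
#' @export
simulate_tau_leap <- function(system, settings, x0 = NULL, p0 = NULL) {
  if (is.null(settings$tau) || settings$tau <= 0)
    stop("tau-leaping requires settings$tau > 0", call. = FALSE)
  N <- system$N
  nr <- ncol(N)
  realize <- function(x, p) {
    t <- settings$t0
    smp <- .grid_sampler(settings$times, length(x))
    cnt <- numeric(nr)
    while (t < settings$t_end - 1e-15) {
      a <- .check_propensities(system$rates(t, x, p), system, x, t)
      if (sum(a) <= 0) break
      h <- min(settings$tau, settings$t_end - t)
      repeat {
        k <- stats::rpois(nr, a * h)
        xn <- x + as.numeric(N %*% k)
        if (all(xn >= 0)) break
        h <- h / 2
        if (h < 1e-12)
          stop("tau-leap step underflow (state pinned at a boundary)",
               call. = FALSE)
      }
      t <- t + h
      smp$advance(t, x)
      x <- xn
      cnt <- cnt + k
    }
    list(states = smp$finish(x), counts = cnt)
  }
  .ssa_ensemble(system, settings, realize, x0, p0)
}

#' Export an ensemble summary as CSV
#'
#' Writes time, per-variable ensemble mean and variance columns.
#' @param ens An `EnsembleResult`.
#' @param path Output file.
#' @export
write_ensemble_csv <- function(ens, path) {
  df <- data.frame(time = ens$times,
                   stats::setNames(as.data.frame(ens$mean),
                                   paste0("mean_", colnames(ens$mean))),
                   stats::setNames(as.data.frame(ens$var),
                                   paste0("var_", colnames(ens$var))))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
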