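# Deterministic simulation engines: fixed-step Euler, adaptive embedded
# Dormand-Prince (DOPRI5, with its classical dense-output polynomial), and a
# stiff variable-order multistep route delegated to deSolve's lsodar
# (Adams-Moulton/BDF with root finding).  All engines share one event
# machinery: triggers fire on the false-to-true transition, are located by
# bisection on the continuous solution to 1e-9 time units, assignments are
# applied and integration restarts; halting events truncate the trajectory.

#' Settings for deterministic simulation
#'
#' @param t_end Final time (must exceed `t0`).
#' @param t0 Initial time.
#' @param n_out Number of uniform output points (ignored when `times` given).
#' @param times Explicit output times (ascending).
#' @param rel_tol,abs_tol Local error tolerances for the adaptive solvers.
#' @param initial_step Initial step (Dormand-Prince) or the fixed step
#'   (Euler; default `(t_end - t0)/1000`).
#' @param max_step Maximum step size.
#' @param solver `"euler"`, `"dormand_prince"` or `"stiff_multistep"`.
#' @export
ode_settings <- function(t_end, t0 = 0, n_out = 201L, times = NULL,
                         rel_tol = 1e-6, abs_tol = 1e-9,
                         initial_step = NULL, max_step = Inf,
                         solver = c("dormand_prince", "euler",
                                    "stiff_multistep")) {
  solver <- match.arg(solver)
  stopifnot(t_end > t0, rel_tol > 0, abs_tol > 0)
  if (is.null(times)) times <- seq(t0, t_end, length.out = n_out)
  stopifnot(all(diff(times) > 0))
  structure(list(t0 = t0, t_end = t_end, times = times, rel_tol = rel_tol,
                 abs_tol = abs_tol, initial_step = initial_step,
                 max_step = max_step, solver = solver),
            class = "OdeSettings")
}

# DOPRI5 tableau
.DP_C <- c(0, 1/5, 3/10, 4/5, 8/9, 1, 1)
.DP_A <- list(
  NULL,
  c(1/5),
  c(3/40, 9/40),
  c(44/45, -56/15, 32/9),
  c(19372/6561, -25360/2187, 64448/6561, -212/729),
  c(9017/3168, -355/33, 46732/5247, 49/176, -5103/18656),
  c(35/384, 0, 500/1113, 125/192, -2187/6784, 11/84))
.DP_E <- c(71/57600, 0, -71/16695, 71/1920, -17253/339200, 22/525, -1/40)
.DP_D <- c(-12715105075/11282082432, 0, 87487479700/32700410799,
           -10690763975/1880347072, 701980252875/199316789632,
           -1453857185/822651844, 69997945/29380423)

# one Dormand-Prince step; returns new state, error estimate and the dense
# output closure over [t, t+h]
#' @keywords internal
.dp_step <- function(f, t, x, p, h, k1 = NULL) {
  n <- length(x)
  K <- matrix(0, n, 7L)
  K[, 1L] <- if (is.null(k1)) f(t, x, p) else k1
  for (s in 2:7) {
    a <- .DP_A[[s]]
    xs <- x + h * as.numeric(K[, seq_along(a), drop = FALSE] %*% a)
    K[, s] <- f(t + .DP_C[s] * h, xs, p)
  }
  x1 <- x + h * as.numeric(K[, 1:6, drop = FALSE] %*% .DP_A[[7L]][1:6])
  # K7 is f at (t+h, x1) thanks to FSAL structure of the tableau row
  K[, 7L] <- f(t + h, x1, p)
  errv <- h * as.numeric(K %*% .DP_E)
  ydiff <- x1 - x
  bspl <- h * K[, 1L] - ydiff
  rc <- list(x, ydiff, bspl, ydiff - h * K[, 7L] - bspl,
             h * as.numeric(K %*% .DP_D))
  dense <- function(tq) {
    th <- (tq - t) / h
    th1 <- 1 - th
    rc[[1L]] + th * (rc[[2L]] + th1 * (rc[[3L]] + th * (rc[[4L]] +
      th1 * rc[[5L]])))
  }
  list(x1 = x1, err = errv, dense = dense, k_end = K[, 7L])
}

#' Simulate a compiled system deterministically
#'
#' Integrates the ODE/DAE system on `[t0, t_end]`, locating events on the
#' continuous solution, applying their assignments and restarting.  Output
#' values are produced by dense interpolation of the accepted steps, never by
#' forcing integration steps onto the output grid.  A halting event (e.g. a
#' converted constraint) truncates the trajectory and records its message.
#'
#' @param system A `CompiledSystem` compiled for the ode engine.
#' @param settings An [ode_settings()].
#' @param x0,p0 Optional named overrides of initial state / parameters.
#' @return A [trajectory()].
#' @export
simulate_ode <- function(system, settings, x0 = NULL, p0 = NULL) {
  stopifnot(inherits(system, "CompiledSystem"))
  if (system$engine != "ode")
    stop("system was compiled for engine '", system$engine, "'", call. = FALSE)
  x <- system$x0
  p <- system$p0
  if (!is.null(x0)) x[names(x0)] <- x0
  if (!is.null(p0)) p[names(p0)] <- p0
  .integrate(system, settings, x, p)
}

#' @keywords internal
.integrate <- function(sys, st, x, p) {
  f_raw <- system_rhs(sys)
  f <- function(t, x, p) {
    d <- f_raw(t, x, p)
    if (any(!is.finite(d)))
      stop("numeric error: non-finite right-hand side at t = ", format(t),
           "; state: ", paste(sprintf("%s=%.6g", sys$layout, x),
                              collapse = ", "), call. = FALSE)
    d
  }
  grid <- st$times
  nvar <- length(sys$layout)
  t <- st$t0
  x <- solve_algebraic(sys, t, x, p)
  ev <- sys$events
  nev <- length(ev)
  trig <- vapply(ev, function(e) e$trigger(t, x, p), logical(1)) %||% logical(0)

  out_t <- numeric(0)
  out_x <- matrix(0, 0, nvar)
  ev_t <- numeric(0); ev_id <- character(0)
  halt <- NULL
  pending <- list()

  emit <- function(tq, xq) {
    out_t[[length(out_t) + 1L]] <<- tq
    out_x <<- rbind(out_x, sys$observer(tq, xq, p))
  }
  gi <- 1L
  emit_upto <- function(tlim, dense) {
    while (gi <= length(grid) && grid[gi] <= tlim + 1e-12) {
      xq <- dense(grid[gi])
      if (length(sys$alg_idx)) xq <- solve_algebraic(sys, grid[gi], xq, p)
      emit(grid[gi], xq)
      gi <<- gi + 1L
    }
  }

  apply_vals <- function(vals) {
    for (tg in names(vals)) {
      if (tg %in% sys$layout) x[[tg]] <<- vals[[tg]]
      else if (tg %in% sys$par_layout) p[[tg]] <<- vals[[tg]]
    }
    if (length(sys$alg_idx)) x <<- solve_algebraic(sys, t, x, p)
  }
  fire <- function(j) {
    e <- ev[[j]]
    d <- if (is.numeric(e$delay)) e$delay else e$delay_fun(t, x, p)
    if (d <= 0) {
      vals <- e$values(t, x, p)
      apply_vals(vals)
      ev_t[[length(ev_t) + 1L]] <<- t; ev_id[[length(ev_id) + 1L]] <<- e$id
      if (e$halt) halt <<- list(time = t, message = e$message)
    } else {
      pending[[length(pending) + 1L]] <<- list(
        time = t + d, j = j,
        vals = if (e$use_trigger_time_values) e$values(t, x, p) else NULL)
    }
  }
  cascade <- function() {
    for (iter in seq_len(100L)) {
      if (!is.null(halt) || !nev) return(invisible())
      newtrig <- vapply(ev, function(e) e$trigger(t, x, p), logical(1))
      fired <- which(!trig & newtrig)
      trig <<- newtrig
      if (!length(fired)) return(invisible())
      for (j in fired) { fire(j); if (!is.null(halt)) return(invisible()) }
    }
    stop("event cascade did not settle after 100 rounds at t = ", format(t),
         call. = FALSE)
  }
  run_pending <- function() {
    while (length(pending) && is.null(halt)) {
      times_p <- vapply(pending, `[[`, 0, "time")
      due <- which(times_p <= t + 1e-12)
      if (!length(due)) break
      k <- due[1L]
      pd <- pending[[k]]; pending[[k]] <<- NULL
      e <- ev[[pd$j]]
      vals <- pd$vals %||% e$values(t, x, p)
      apply_vals(vals)
      ev_t[[length(ev_t) + 1L]] <<- t; ev_id[[length(ev_id) + 1L]] <<- e$id
      if (e$halt) { halt <<- list(time = t, message = e$message); break }
      cascade()
      if (!is.null(halt)) break
    }
  }
  next_break <- function() {
    tp <- if (length(pending)) min(vapply(pending, `[[`, 0, "time")) else Inf
    min(st$t_end, tp)
  }
  locate <- function(j, ta, tb, dense) {
    # earliest false->true time of event j in (ta, tb], to 1e-9 time units
    lo <- ta; hi <- tb
    while (hi - lo > 1e-10) {
      mid <- (lo + hi) / 2
      xm <- dense(mid)
      if (length(sys$alg_idx)) xm <- solve_algebraic(sys, mid, xm, p)
      if (ev[[j]]$trigger(mid, xm, p)) hi <- mid else lo <- mid
    }
    hi
  }
  handle_step_events <- function(t0s, t1s, x1, dense) {
    # returns TRUE when an event interrupted the step at some te < t1s
    newtrig <- vapply(ev, function(e) e$trigger(t1s, x1, p), logical(1))
    fired <- which(!trig & newtrig)
    if (!length(fired)) { trig <<- newtrig; return(FALSE) }
    te_j <- vapply(fired, locate, 0, ta = t0s, tb = t1s, dense = dense)
    te <- min(te_j)
    js <- fired[te_j <= te + 1e-12]
    emit_upto(te - 1e-12, dense)
    t <<- te
    xq <- dense(te)
    if (length(sys$alg_idx)) xq <- solve_algebraic(sys, te, xq, p)
    x <<- xq
    trig <<- vapply(ev, function(e) e$trigger(t, x, p), logical(1))
    for (j in js) { trig[j] <<- TRUE; fire(j); if (!is.null(halt)) break }
    if (is.null(halt)) cascade()
    TRUE
  }
  finish <- function() {
    if (!is.null(halt)) {
      if (!length(out_t) || out_t[[length(out_t)]] < halt$time - 1e-12)
        emit(halt$time, x)
    }
    trajectory(out_t, {
      colnames(out_x) <- sys$layout
      out_x
    }, events = data.frame(time = ev_t, id = ev_id, stringsAsFactors = FALSE),
    halt = halt)
  }

  ## dispatch on solver
  if (st$solver %in% c("euler", "dormand_prince")) {
    adaptive <- st$solver == "dormand_prince"
    h <- st$initial_step %||%
      (if (adaptive) (st$t_end - st$t0) / 100 else (st$t_end - st$t0) / 1000)
    emit_upto(t, function(tq) x)
    k1 <- NULL
    repeat {
      if (!is.null(halt)) break
      run_pending()
      if (!is.null(halt)) break
      brk <- next_break()
      if (t >= st$t_end - 1e-12) break
      hs <- min(h, brk - t, st$max_step)
      if (hs < 1e-14 * max(1, abs(t)))
        stop("stiffness error: step size underflow at t = ", format(t),
             "; try solver = 'stiff_multistep'", call. = FALSE)
      if (adaptive) {
        step <- .dp_step(f, t, x, p, hs, k1)
        sc <- st$abs_tol + st$rel_tol * pmax(abs(x), abs(step$x1))
        err <- sqrt(mean((step$err / sc)^2))
        if (!is.finite(err)) err <- 2
        if (err > 1) {
          h <- hs * max(0.2, 0.9 * err^(-0.2))
          k1 <- NULL
          next
        }
        h <- hs * min(5, max(0.2, 0.9 * (err + 1e-16)^(-0.2)))
        dense <- step$dense
        x1 <- step$x1
      } else {
        k <- f(t, x, p)
        x1 <- x + hs * k
        t0s <- t; x0s <- x
        dense <- function(tq) x0s + (tq - t0s) * k
      }
      t1s <- t + hs
      if (nev && handle_step_events(t, t1s, x1, dense)) { k1 <- NULL; next }
      if (!is.null(halt)) break
      emit_upto(t1s, dense)
      t <- t1s
      x <- x1
      k1 <- if (adaptive && abs(t - brk) > 1e-12) step$k_end else NULL
      if (t >= brk - 1e-12 && brk < st$t_end - 1e-12) run_pending()
    }
    return(finish())
  }

  ## stiff multistep via deSolve::lsodar (Adams/BDF with root finding)
  emit_upto(t, function(tq) x)
  repeat {
    if (!is.null(halt)) break
    run_pending()
    if (!is.null(halt)) break
    brk <- next_break()
    if (t >= st$t_end - 1e-12) break
    seg <- sort(unique(c(t, grid[grid > t + 1e-12 & grid < brk - 1e-12], brk)))
    func <- function(tt, y, parms) list(f(tt, y, p))
    rootf <- if (nev)
      function(tt, y, parms)
        vapply(ev, function(e) e$margin(tt, y, p), 0)
    else NULL
    out <- deSolve::lsodar(y = x, times = seg, func = func, parms = NULL,
                           rtol = st$rel_tol, atol = st$abs_tol,
                           rootfunc = rootf, hmax = st$max_step)
    troot <- attr(out, "troot")
    rows_t <- out[, 1L]
    rows_x <- out[, -1L, drop = FALSE]
    stopped <- !is.null(troot) && length(troot) &&
      rows_t[length(rows_t)] < brk - 1e-12
    lastrow <- nrow(out)
    # emit the grid points the solver reached
    for (ri in seq_len(lastrow)) {
      if (gi <= length(grid) && abs(rows_t[ri] - grid[gi]) <= 1e-9) {
        xq <- rows_x[ri, ]
        if (length(sys$alg_idx)) xq <- solve_algebraic(sys, rows_t[ri], xq, p)
        emit(grid[gi], xq)
        gi <- gi + 1L
      }
    }
    t_new <- rows_t[lastrow]
    x <- rows_x[lastrow, ]
    names(x) <- sys$layout
    if (length(sys$alg_idx)) x <- solve_algebraic(sys, t_new, x, p)
    if (stopped) {
      tprev <- t
      t <- t_new
      newtrig <- vapply(ev, function(e) e$trigger(t, x, p), logical(1))
      fired <- which(!trig & newtrig)
      trig <- newtrig
      if (length(fired)) {
        for (j in fired) { fire(j); if (!is.null(halt)) break }
        if (is.null(halt)) cascade()
      } else if (t - tprev < 1e-11) {
        # sitting on a root without a boolean flip: nudge past it
        nud <- deSolve::lsoda(y = x, times = c(t, t + max(1e-9, 1e-9 * abs(t))),
                              func = func, parms = NULL,
                              rtol = st$rel_tol, atol = st$abs_tol)
        t <- nud[nrow(nud), 1L]
        x <- nud[nrow(nud), -1L]
        names(x) <- sys$layout
      }
    } else {
      t <- brk
      if (nev) trig <- vapply(ev, function(e) e$trigger(t, x, p), logical(1))
      run_pending()
    }
  }
  finish()
}

#' Steady state of a compiled system
#'
#' Damped Newton iteration with finite-difference Jacobian on the
#' conservation-respecting system (each conserved pool contributes the
#' constraint `m . x = m . x0` in place of a redundant balance row), falling
#' back to integrating to large times when Newton stalls.
#'
#' @param system A `CompiledSystem` (ode engine).
#' @param guess Optional named initial guess (defaults to the initial state).
#' @param tol Convergence tolerance on the max-norm of the right-hand side.
#' @param p0 Optional named parameter overrides.
#' @return Named steady-state vector over the full layout.
#' @export
steady_state <- function(system, guess = NULL, tol = 1e-9, p0 = NULL) {
  sys <- system
  p <- sys$p0
  if (!is.null(p0)) p[names(p0)] <- p0
  x <- sys$x0
  if (!is.null(guess)) x[names(guess)] <- guess
  f <- system_rhs(sys)
  ode_idx <- which(sys$dynamics == "ode")
  if (!length(ode_idx)) return(sys$observer(0, x, p))

  cons <- tryCatch(conservation_analysis(sys$model), error = function(e) NULL)
  m_rows <- list()
  if (!is.null(cons) && nrow(cons$conservation)) {
    sp <- rownames(cons$N)
    tot0 <- as.numeric(cons$conservation %*% x[sp])
    for (k in seq_len(nrow(cons$conservation)))
      m_rows[[k]] <- list(dep = cons$dependent[[k]],
                          m = cons$conservation[k, ], sp = sp,
                          total = tot0[[k]])
  }
  resid <- function(x) {
    r <- f(0, x, p)[ode_idx]
    names(r) <- sys$layout[ode_idx]
    for (mr in m_rows)
      r[[mr$dep]] <- sum(mr$m * x[mr$sp]) - mr$total
    r
  }
  newton <- function(x) {
    z <- x[ode_idx]
    r <- resid(x)
    for (it in seq_len(100L)) {
      if (max(abs(r)) < tol) return(list(x = x, ok = TRUE))
      J <- matrix(0, length(z), length(z))
      for (k in seq_along(z)) {
        h <- max(1e-7, 1e-7 * abs(z[[k]]))
        xp <- x; xp[ode_idx][k] <- xp[ode_idx][k] + h
        J[, k] <- (resid(xp) - r) / h
      }
      step <- tryCatch(solve(J, -r), error = function(e) NULL)
      if (is.null(step)) return(list(x = x, ok = FALSE))
      lam <- 1
      improved <- FALSE
      while (lam > 1e-8) {
        xn <- x; xn[ode_idx] <- z + lam * step
        rn <- tryCatch(resid(xn), error = function(e) NULL)
        if (!is.null(rn) && max(abs(rn)) < max(abs(r))) {
          x <- xn; z <- x[ode_idx]; r <- rn; improved <- TRUE; break
        }
        lam <- lam / 2
      }
      if (!improved) return(list(x = x, ok = FALSE))
    }
    list(x = x, ok = max(abs(r)) < tol)
  }
  res <- tryCatch(newton(x), error = function(e) list(x = x, ok = FALSE))
  if (!res$ok) {
    # integrate towards the attractor, then polish
    tend <- 100
    xcur <- x
    for (round in seq_len(4L)) {
      traj <- tryCatch(
        .integrate(sys, ode_settings(t_end = tend, n_out = 11L,
                                     rel_tol = 1e-8, abs_tol = 1e-10,
                                     solver = "stiff_multistep"), xcur, p),
        error = function(e) NULL)
      if (!is.null(traj)) {
        xcur[sys$layout] <- traj$states[nrow(traj$states), sys$layout]
        res <- tryCatch(newton(xcur), error = function(e) list(x = xcur, ok = FALSE))
        if (res$ok) break
        if (max(abs(resid(xcur))) < tol) { res <- list(x = xcur, ok = TRUE); break }
      }
      tend <- tend * 100
    }
  }
  if (!res$ok)
    stop("convergence error: no steady state found (residual ",
         format(max(abs(resid(res$x)))), ")", call. = FALSE)
  xs <- res$x
  if (length(sys$alg_idx)) xs <- solve_algebraic(sys, 0, xs, p)
  out <- sys$observer(0, xs, p)
  names(out) <- sys$layout
  out
}
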