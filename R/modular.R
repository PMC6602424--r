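# Modular model composition.  Two execution routes: flattening (see
# flatten()) and agent-based co-simulation, where each module runs its own
# engine and a fixed-step scheduler exchanges the values of connected
# variables at window boundaries (zero-order hold within a window, so the
# coupling error is first order in the exchange step).

#' Create a connection between module variables
#'
#' @param kind `"undirected"` (the variables are one shared quantity) or
#'   `"directed"` (first endpoint produces, the rest consume).
#' @param endpoints Character vector `"module.symbol"` (at least two).
#' @param master For undirected connections: the endpoint whose initial value
#'   wins; required when more than one endpoint is actively integrated.
#' @param factor Conversion factor applied producer -> consumer (directed
#'   connections only; undirected connections require factor 1).
#' @export
connection <- function(kind = c("undirected", "directed"), endpoints,
                       master = NULL, factor = 1) {
  kind <- match.arg(kind)
  parse_ep <- function(s) {
    parts <- strsplit(s, ".", fixed = TRUE)[[1L]]
    if (length(parts) != 2L)
      stop("connection endpoint must be 'module.symbol': '", s, "'",
           call. = FALSE)
    list(parts[[1L]], parts[[2L]])
  }
  eps <- lapply(endpoints, parse_ep)
  if (length(eps) < 2L) stop("a connection needs at least two endpoints",
                             call. = FALSE)
  structure(list(kind = kind, endpoints = eps,
                 master = if (!is.null(master)) parse_ep(master),
                 factor = factor),
            class = "Connection")
}

#' Compose modules into a modular model
#'
#' @param modules Named list; each element is `list(diagram=, model=)` or a
#'   bare `MathModel`.
#' @param connections List of [connection()] objects.
#' @param engines Named character vector module -> engine kind (`"ode"` or
#'   `"stochastic"`); defaults to `"ode"`.
#' @return A validated `ModularModel`.
#' @export
compose <- function(modules, connections = list(), engines = NULL) {
  stopifnot(length(names(modules)) == length(modules),
            all(nzchar(names(modules))))
  modules <- lapply(modules, function(m) {
    if (inherits(m, "MathModel")) list(diagram = NULL, model = m) else m
  })
  for (nm in names(modules)) {
    d <- validate_model(modules[[nm]]$diagram, modules[[nm]]$model)
    if (length(d))
      stop("module '", nm, "' is invalid:\n  ", paste(d, collapse = "\n  "),
           call. = FALSE)
  }
  for (ci in seq_along(connections)) {
    cn <- connections[[ci]]
    for (ep in c(cn$endpoints, list(cn$master))) {
      if (is.null(ep)) next
      if (!(ep[[1L]] %in% names(modules)))
        stop("connection ", ci, ": unknown module '", ep[[1L]], "'",
             call. = FALSE)
      m <- modules[[ep[[1L]]]]$model
      if (!(ep[[2L]] %in% model_symbols(m)))
        stop("connection ", ci, ": module '", ep[[1L]],
             "' has no symbol '", ep[[2L]], "'", call. = FALSE)
    }
  }
  eng <- stats::setNames(rep("ode", length(modules)), names(modules))
  if (!is.null(engines)) eng[names(engines)] <- engines
  structure(list(modules = modules, connections = connections, engines = eng),
            class = "ModularModel")
}

#' @export
print.ModularModel <- function(x, ...) {
  cat("ModularModel:", length(x$modules), "modules (",
      paste(names(x$modules), collapse = ", "), "),",
      length(x$connections), "connection(s)\n")
  invisible(x)
}

#' Scheduler settings for agent-based co-simulation
#'
#' @param h_ex Exchange step: the scheduler pushes connected values at
#'   multiples of `h_ex`.
#' @param t_end,t0 Time span.
#' @param n_out Output grid size (uniform).
#' @param ode Named list of [ode_settings()] overrides for ODE modules
#'   (`rel_tol`, `abs_tol`, `solver`).
#' @param seed Seed driving stochastic modules.
#' @export
schedule_settings <- function(h_ex, t_end, t0 = 0, n_out = 101L,
                              ode = list(), seed = 1L) {
  stopifnot(h_ex > 0, h_ex <= t_end - t0)
  structure(list(h_ex = h_ex, t0 = t0, t_end = t_end, n_out = n_out,
                 ode = ode, seed = as.integer(seed)),
            class = "ScheduleSettings")
}

# topological order of modules along directed connections, name order within
# ties; cycle -> error
#' @keywords internal
.module_order <- function(mm) {
  mods <- sort(names(mm$modules))
  edges <- list()
  for (cn in mm$connections) {
    if (cn$kind != "directed") next
    from <- cn$endpoints[[1L]][[1L]]
    for (ep in cn$endpoints[-1L])
      edges[[length(edges) + 1L]] <- c(from, ep[[1L]])
  }
  order <- character(0)
  remaining <- mods
  while (length(remaining)) {
    has_in <- vapply(remaining, function(m)
      any(vapply(edges, function(e)
        e[[2L]] == m && e[[1L]] %in% remaining, logical(1))), logical(1))
    ready <- remaining[!has_in]
    if (!length(ready))
      stop("directed connections form a cycle among modules: ",
           paste(remaining, collapse = ", "), call. = FALSE)
    order <- c(order, ready)
    remaining <- setdiff(remaining, ready)
  }
  order
}

#' Agent-based co-simulation of a modular model
#'
#' Time advances in exchange windows of length `h_ex`.  Within a window every
#' module integrates independently with its own engine, holding incoming
#' connected values constant; at window boundaries the scheduler reconciles
#' shared (undirected) variables by summing the modules' increments and pushes
#' producer values to consumers in topological order of the directed
#' connections (ties broken by module name).  When a real-valued reconciled
#' value is pushed into a stochastic module it is floored and the remainder
#' carried to the next boundary.
#'
#' @param mm A `ModularModel` from [compose()].
#' @param settings A [schedule_settings()].
#' @return A [trajectory()] over the namespaced variables (`module__symbol`);
#'   merged variables appear once, under the master's name.
#' @export
simulate_agents <- function(mm, settings) {
  stopifnot(inherits(mm, "ModularModel"))
  ns <- function(mod, sym) paste0(mod, "__", sym)
  mods <- names(mm$modules)
  sys <- lapply(mods, function(m)
    compile_system(mm$modules[[m]]$diagram, mm$modules[[m]]$model,
                   engine = mm$engines[[m]]))
  names(sys) <- mods
  xs <- lapply(sys, function(s) s$x0)
  ps <- lapply(sys, function(s) s$p0)

  # resolve connection bookkeeping (same master rules as flatten)
  shared <- list()   # undirected: list(value, endpoints, master)
  directed <- list()
  drop_cols <- character(0)
  for (ci in seq_along(mm$connections)) {
    cn <- mm$connections[[ci]]
    if (cn$kind == "undirected") {
      if ((cn$factor %||% 1) != 1)
        stop("composition error: undirected connections require conversion ",
             "factor 1", call. = FALSE)
      governed <- vapply(cn$endpoints, function(ep)
        is_ode_governed(mm$modules[[ep[[1L]]]]$model, ep[[2L]]), logical(1))
      master <- cn$master
      if (is.null(master)) {
        if (sum(governed) > 1L)
          stop("composition error: connection ", ci, " joins more than one ",
               "ode-governed variable without a designated master",
               call. = FALSE)
        master <- if (any(governed)) cn$endpoints[[which(governed)[1L]]]
                  else cn$endpoints[[1L]]
      }
      mv <- xs[[master[[1L]]]][[master[[2L]]]]
      shared[[length(shared) + 1L]] <-
        list(value = mv, endpoints = cn$endpoints, master = master, carry = 0)
      for (ep in cn$endpoints)
        if (!identical(ep, master))
          drop_cols <- c(drop_cols, ns(ep[[1L]], ep[[2L]]))
    } else {
      for (ep in cn$endpoints[-1L])
        drop_cols <- c(drop_cols, ns(ep[[1L]], ep[[2L]]))
      directed[[length(directed) + 1L]] <-
        list(producer = cn$endpoints[[1L]], consumers = cn$endpoints[-1L],
             factor = cn$factor %||% 1, carry = numeric(length(cn$endpoints) - 1L))
    }
  }
  order <- .module_order(mm)

  carry_store <- new.env(parent = emptyenv())
  set_value <- function(mod, symv, value, key = NULL) {
    # floor + remainder carry when pushing a real into a stochastic module
    if (mm$engines[[mod]] == "stochastic" && symv %in% sys[[mod]]$layout &&
        !is.null(key) && value != round(value)) {
      tot <- value + (carry_store[[key]] %||% 0)
      iv <- floor(tot + 1e-9)
      carry_store[[key]] <- tot - iv
      value <- iv
    }
    if (symv %in% sys[[mod]]$layout) xs[[mod]][[symv]] <<- value
    else ps[[mod]][[symv]] <<- value
  }
  push_boundary <- function(initial = FALSE) {
    # reconcile shared variables: master value + sum of module increments
    # (at t0 there is nothing to reconcile: copies take the master's value)
    for (k in seq_along(shared)) {
      sh <- shared[[k]]
      delta <- 0
      if (!initial) {
        for (ep in sh$endpoints) {
          cur <- if (ep[[2L]] %in% sys[[ep[[1L]]]]$layout)
            xs[[ep[[1L]]]][[ep[[2L]]]] else ps[[ep[[1L]]]][[ep[[2L]]]]
          delta <- delta + (cur - sh$value)
        }
      }
      newv <- sh$value + delta
      shared[[k]]$value <<- newv
      for (ei in seq_along(sh$endpoints)) {
        ep <- sh$endpoints[[ei]]
        set_value(ep[[1L]], ep[[2L]], newv, key = paste0("s", k, "_", ei))
      }
    }
    # push directed values in topological module order
    for (mod in order) {
      for (k in seq_along(directed)) {
        dc <- directed[[k]]
        if (dc$producer[[1L]] != mod) next
        pv <- if (dc$producer[[2L]] %in% sys[[mod]]$layout)
          xs[[mod]][[dc$producer[[2L]]]] else ps[[mod]][[dc$producer[[2L]]]]
        for (ei in seq_along(dc$consumers)) {
          ep <- dc$consumers[[ei]]
          set_value(ep[[1L]], ep[[2L]], dc$factor * pv,
                    key = paste0("d", k, "_", ei))
        }
      }
    }
  }

  grid <- seq(settings$t0, settings$t_end, length.out = settings$n_out)
  nb <- ceiling((settings$t_end - settings$t0) / settings$h_ex - 1e-9)
  bounds <- settings$t0 + settings$h_ex * seq_len(nb)
  bounds[nb] <- settings$t_end
  cols <- unlist(lapply(mods, function(m) ns(m, sys[[m]]$layout)))
  cols <- setdiff(cols, drop_cols)
  out <- matrix(NA_real_, length(grid), length(cols),
                dimnames = list(NULL, cols))

  set.seed(settings$seed)
  wseeds <- matrix(sample.int(.Machine$integer.max - 1L, nb * length(mods)),
                   nb, length(mods), dimnames = list(NULL, mods))
  record <- function(idx, tq) {
    for (m in mods) {
      v <- sys[[m]]$observer(tq, xs[[m]], ps[[m]])
      names(v) <- ns(m, sys[[m]]$layout)
      keep <- intersect(names(v), cols)
      out[idx, keep] <<- v[keep]
    }
    # merged variables: report the reconciled shared value
    for (sh in shared)
      out[idx, ns(sh$master[[1L]], sh$master[[2L]])] <<-
        xs[[sh$master[[1L]]]][[sh$master[[2L]]]]
  }
  push_boundary(initial = TRUE)   # align copies/consumers at t0
  t <- settings$t0
  if (abs(grid[1L] - t) < 1e-12) record(1L, t)
  for (w in seq_len(nb)) {
    tb <- bounds[[w]]
    gidx <- which(grid > t + 1e-12 & grid <= tb + 1e-12)
    inner <- sort(unique(c(grid[gidx], tb)))
    for (mi in seq_along(mods)) {
      m <- mods[[mi]]
      if (mm$engines[[m]] == "stochastic") {
        st <- ssa_settings(t_end = tb, t0 = t, times = inner,
                           n_replicates = 1L, seed = wseeds[w, m],
                           keep_replicates = TRUE)
        res <- tryCatch(simulate_direct(sys[[m]], st, x0 = xs[[m]],
                                        p0 = ps[[m]]),
                        error = function(e)
                          stop("module '", m, "': ", conditionMessage(e),
                               call. = FALSE))
        states <- res$replicates[[1L]]
      } else {
        odeargs <- utils::modifyList(
          list(t_end = tb, t0 = t, times = inner), settings$ode)
        st <- do.call(ode_settings, odeargs)
        tr <- tryCatch(simulate_ode(sys[[m]], st, x0 = xs[[m]], p0 = ps[[m]]),
                       error = function(e)
                         stop("module '", m, "': ", conditionMessage(e),
                              call. = FALSE))
        states <- tr$states[match(inner, tr$times), , drop = FALSE]
      }
      colnames(states) <- sys[[m]]$layout
      for (gq in gidx) {
        ridx <- match(grid[gq], inner)
        v <- states[ridx, ]
        names(v) <- ns(m, sys[[m]]$layout)
        keep <- intersect(names(v), cols)
        out[gq, keep] <- v[keep]
      }
      xs[[m]][sys[[m]]$layout] <- states[nrow(states), ]
    }
    t <- tb
    push_boundary()
    # boundary grid points show the reconciled values
    bq <- which(abs(grid - tb) <= 1e-12)
    if (length(bq)) record(bq[[1L]], tb)
  }
  trajectory(grid, out)
}
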