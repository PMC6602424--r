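# Preprocessors and the compiler: turn a (Diagram, MathModel) pair into a
# CompiledSystem whose right-hand side, rates, triggers and residuals are
# generated, parsed and byte-compiled R functions -- the in-memory analogue
# of generating simulator source code from the model description.

## ---- stoichiometry ----

#' Stoichiometric matrix of a model
#'
#' Rows are the species (ode variables that participate in at least one
#' reaction, in declaration order), columns the reactions.  Entries are
#' products minus reactants.
#'
#' @param model A `MathModel`.
#' @param reactions Optional subset of reactions (defaults to all).
#' @param species Optional explicit row species.
#' @return Numeric matrix with dimnames.
#' @export
stoich_matrix <- function(model, reactions = model$reactions, species = NULL) {
  if (is.null(species)) {
    touched <- unique(unlist(lapply(reactions, function(r)
      c(names(r$reactants), names(r$products)))))
    species <- names(model$variables)[
      names(model$variables) %in% touched &
        vapply(model$variables, function(v) v$dynamics == "ode", logical(1))]
  }
  N <- matrix(0, length(species), length(reactions),
              dimnames = list(species, vapply(reactions, `[[`, "", "id")))
  for (j in seq_along(reactions)) {
    r <- reactions[[j]]
    for (s in names(r$reactants))
      if (s %in% species) N[s, j] <- N[s, j] - r$reactants[[s]]
    for (s in names(r$products))
      if (s %in% species) N[s, j] <- N[s, j] + r$products[[s]]
  }
  N
}

## ---- simple preprocessors ----

#' Convert constraints to halting events
#'
#' Each constraint becomes a discrete event whose trigger is the negated
#' condition and whose action halts the simulation, carrying the constraint
#' message.  The constraint list of the returned model is empty.
#'
#' @param model A `MathModel`.
#' @return The transformed model.
#' @export
constraints_to_events <- function(model) {
  for (cn in model$constraints) {
    trig <- call("!", cn$condition)
    model$events[[length(model$events) + 1L]] <-
      mm_event(paste0(cn$id, "_halt"), trig, halt = TRUE,
               message = if (nzchar(cn$message)) cn$message
                         else paste0("constraint '", cn$id, "' violated"))
  }
  model$constraints <- list()
  model
}

#' Replace fast reactions by algebraic equilibrium relations
#'
#' Each reaction flagged `fast` is assumed at quasi-equilibrium.  Supported
#' form: reversible mass action, i.e. a kinetic law that is a top-level
#' difference `forward - backward`.  The reaction is removed and replaced by
#' the algebraic relation `law = 0`; the species it touches become algebraic
#' variables, and one new total variable per conserved pool of the fast
#' subnetwork keeps the slow dynamics (rate rule summing the slow reactions'
#' net inflow into the pool).
#'
#' @param model A `MathModel`.
#' @return The transformed model.
#' @export
fast_to_algebraic <- function(model) {
  fast <- Filter(function(r) isTRUE(r$fast), model$reactions)
  if (!length(fast)) return(model)
  for (r in fast) {
    law <- r$kinetic_law
    while (is.call(law) && identical(law[[1L]], as.symbol("("))) law <- law[[2L]]
    if (!(is.call(law) && identical(law[[1L]], as.symbol("-")) &&
          length(law) == 3L) || !isTRUE(r$reversible))
      stop("unsupported transformation: fast reaction '", r$id,
           "' is not reversible mass action (kinetic law must be a ",
           "difference 'forward - backward')", call. = FALSE)
  }
  slow <- Filter(function(r) !isTRUE(r$fast), model$reactions)
  Nf <- stoich_matrix(model, reactions = fast)
  fast_species <- rownames(Nf)
  if (rat_eliminate(Nf)$rank != length(fast))
    stop("unsupported transformation: fast reactions are structurally ",
         "dependent", call. = FALSE)

  # conserved pools of the fast subnetwork
  cons <- left_null_basis(Nf)   # rows = conservation vectors over fast species
  # residuals: one per fast reaction (law = 0)
  for (r in fast)
    model$rules[[length(model$rules) + 1L]] <-
      mm_rule("algebraic", expression = r$kinetic_law)
  # pool totals: new ode variable + defining residual + slow-inflow rate rule
  if (nrow(cons)) {
    Ns <- stoich_matrix(model, reactions = slow, species = fast_species)
    for (k in seq_len(nrow(cons))) {
      m <- cons[k, ]
      tot_id <- paste0("total_", paste(fast_species[m != 0], collapse = "_"))
      tot0 <- sum(m * vapply(fast_species, function(s)
        model$variables[[s]]$initial_value, 0))
      model$variables[[tot_id]] <- mm_variable(tot_id, tot0, dynamics = "ode")
      # residual: tot - sum(m_i * x_i) = 0
      acc <- NULL
      for (i in seq_along(fast_species)) {
        if (m[i] == 0) next
        term <- if (m[i] == 1) as.symbol(fast_species[i]) else
          call("*", m[i], as.symbol(fast_species[i]))
        acc <- if (is.null(acc)) term else call("+", acc, term)
      }
      model$rules[[length(model$rules) + 1L]] <-
        mm_rule("algebraic", expression = call("-", as.symbol(tot_id), acc))
      # rate rule: net slow inflow into the pool
      inflow <- NULL
      for (j in seq_along(slow)) {
        coef <- sum(m * Ns[, j])
        if (coef == 0) next
        term <- if (coef == 1) call("(", slow[[j]]$kinetic_law) else
          call("*", coef, call("(", slow[[j]]$kinetic_law))
        inflow <- if (is.null(inflow)) term else call("+", inflow, term)
      }
      model$rules[[length(model$rules) + 1L]] <-
        mm_rule("rate", target = tot_id, expression = inflow %||% quote(0))
    }
  }
  for (s in fast_species) model$variables[[s]]$dynamics <- "algebraic"
  model$reactions <- model$reactions[
    !vapply(model$reactions, function(r) isTRUE(r$fast), logical(1))]
  model
}

## ---- flattening ----

#' Flatten a modular model into a single-namespace model
#'
#' Symbols of module `M` are renamed `M__symbol`.  Undirected connections
#' merge the connected variables into one, keeping the master's id and initial
#' value; directed connections remove the consumer variable and rewrite its
#' symbol to `factor * producer`.  The result passes [validate_model()].
#'
#' @param mm A `ModularModel` (see [compose()]).
#' @return `list(diagram=, model=)`.
#' @export
flatten <- function(mm) {
  stopifnot(inherits(mm, "ModularModel"))
  ns <- function(mod, sym) paste0(mod, "__", sym)

  # rename all symbols per module
  renamed <- list()
  for (mod in names(mm$modules)) {
    m <- mm$modules[[mod]]$model
    map <- stats::setNames(
      lapply(setdiff(model_symbols(m), m$time_symbol),
             function(s) as.symbol(ns(mod, s))),
      setdiff(model_symbols(m), m$time_symbol))
    renamed[[mod]] <- rename_model(m, map, prefix = paste0(mod, "__"))
  }

  # resolve connections: build a symbol substitution per module
  subs <- stats::setNames(vector("list", length(mm$modules)), names(mm$modules))
  drop_vars <- character(0)
  master_ids <- list()
  for (ci in seq_along(mm$connections)) {
    cn <- mm$connections[[ci]]
    eps <- cn$endpoints
    if (cn$kind == "undirected") {
      if ((cn$factor %||% 1) != 1)
        stop("composition error: undirected connections require conversion ",
             "factor 1", call. = FALSE)
      governed <- vapply(eps, function(ep)
        is_ode_governed(mm$modules[[ep[[1L]]]]$model, ep[[2L]]), logical(1))
      master <- cn$master
      if (is.null(master)) {
        if (sum(governed) > 1L)
          stop("composition error: connection ", ci, " joins more than one ",
               "ode-governed variable without a designated master",
               call. = FALSE)
        master <- if (any(governed)) eps[[which(governed)[1L]]] else eps[[1L]]
      }
      mid <- ns(master[[1L]], master[[2L]])
      for (ep in eps) {
        eid <- ns(ep[[1L]], ep[[2L]])
        if (eid == mid) next
        subs[[ep[[1L]]]][[eid]] <- as.symbol(mid)
        drop_vars <- c(drop_vars, eid)
        master_ids[[eid]] <- mid
      }
    } else {  # directed
      prod_ep <- eps[[1L]]
      pid <- ns(prod_ep[[1L]], prod_ep[[2L]])
      f <- cn$factor %||% 1
      for (ep in eps[-1L]) {
        eid <- ns(ep[[1L]], ep[[2L]])
        if (is_ode_governed(mm$modules[[ep[[1L]]]]$model, ep[[2L]]))
          stop("composition error: directed connection feeds ode-governed ",
               "variable '", eid, "'", call. = FALSE)
        repl <- if (f == 1) as.symbol(pid) else call("*", f, as.symbol(pid))
        subs[[ep[[1L]]]][[eid]] <- repl
        drop_vars <- c(drop_vars, eid)
        master_ids[[eid]] <- pid
      }
    }
  }

  # apply substitutions and merge
  all_vars <- list(); all_pars <- list(); all_reacts <- list()
  all_rules <- list(); all_events <- list(); all_constraints <- list()
  for (mod in names(mm$modules)) {
    m <- renamed[[mod]]
    if (length(subs[[mod]])) {
      smap <- subs[[mod]]
      # the merged-away variables disappear; remaining references follow smap
      m$variables[intersect(names(m$variables), names(smap))] <- NULL
      m$parameters[intersect(names(m$parameters), names(smap))] <- NULL
      m <- rename_model(m, smap, prefix = NULL)
    }
    for (v in m$variables) {
      if (v$id %in% drop_vars) next
      if (!is.null(all_vars[[v$id]]))
        stop("composition error: name collision on '", v$id, "'", call. = FALSE)
      all_vars[[v$id]] <- v
    }
    for (p in m$parameters) {
      if (!is.null(all_pars[[p$id]]))
        stop("composition error: name collision on '", p$id, "'", call. = FALSE)
      all_pars[[p$id]] <- p
    }
    all_reacts <- c(all_reacts, m$reactions)
    all_rules <- c(all_rules, m$rules)
    all_events <- c(all_events, m$events)
    all_constraints <- c(all_constraints, m$constraints)
  }
  model <- math_model(unname(all_vars), unname(all_pars), unname(all_reacts),
                      all_rules, all_events, all_constraints)
  diags <- validate_model(NULL, model)
  if (length(diags))
    stop("flatten produced an invalid model:\n  ",
         paste(diags, collapse = "\n  "), call. = FALSE)
  list(diagram = diagram_from_model(paste0(collapse = "_", names(mm$modules)),
                                    model),
       model = model)
}

# variable is actively driven by its module's dynamics
#' @keywords internal
is_ode_governed <- function(model, sym) {
  v <- model$variables[[sym]]
  if (is.null(v) || v$dynamics != "ode") return(FALSE)
  in_react <- any(vapply(model$reactions, function(r)
    sym %in% c(names(r$reactants), names(r$products)), logical(1)))
  in_rate <- any(vapply(model$rules, function(r)
    r$kind == "rate" && identical(r$target, sym), logical(1)))
  in_react || in_rate
}

# rename every symbol of a model through `map` (symbol -> replacement
# expression); element ids of variables/parameters get the same mapping, and
# reaction/event/rule ids get `prefix` when given.
#' @keywords internal
rename_model <- function(model, map, prefix = NULL) {
  map_id <- function(id) {
    r <- map[[id]]
    if (is.null(r)) id else if (is.symbol(r)) as.character(r) else
      stop("cannot use expression substitution for id '", id, "'")
  }
  pre <- function(id) if (is.null(prefix)) id else paste0(prefix, id)
  vars <- lapply(model$variables, function(v) { v$id <- map_id(v$id); v })
  pars <- lapply(model$parameters, function(p) { p$id <- map_id(p$id); p })
  reacts <- lapply(model$reactions, function(r) {
    r$id <- pre(r$id)
    names(r$reactants) <- vapply(names(r$reactants) %||% character(0),
                                 map_id, "")
    names(r$products) <- vapply(names(r$products) %||% character(0),
                                map_id, "")
    r$modifiers <- vapply(r$modifiers, map_id, "") %||% character(0)
    r$kinetic_law <- substitute_symbols(r$kinetic_law, map)
    r
  })
  rules <- lapply(model$rules, function(rl) {
    if (!is.null(rl$target)) rl$target <- map_id(rl$target)
    rl$expression <- substitute_symbols(rl$expression, map)
    rl
  })
  events <- lapply(model$events, function(ev) {
    ev$id <- pre(ev$id)
    ev$trigger <- substitute_symbols(ev$trigger, map)
    names(ev$assignments) <- vapply(names(ev$assignments) %||% character(0),
                                    map_id, "")
    ev$assignments <- lapply(ev$assignments, substitute_symbols, map = map)
    if (!is.numeric(ev$delay)) ev$delay <- substitute_symbols(ev$delay, map)
    ev
  })
  cons <- lapply(model$constraints, function(cn) {
    cn$id <- pre(cn$id)
    cn$condition <- substitute_symbols(cn$condition, map)
    cn
  })
  math_model(unname(vars), unname(pars), unname(reacts), rules, events, cons,
             time_symbol = model$time_symbol)
}

## ---- compilation ----

#' Compile a model into an executable system
#'
#' Generates, parses and byte-compiles R functions for the ODE right-hand
#' side, reaction rates/propensities, assigned-variable observer, event
#' triggers and algebraic residuals.  For a pure reaction network the
#' right-hand side equals `N %*% v(x, t)`.  Layouts (state and parameter
#' order) follow declaration order and are deterministic.
#'
#' Remaining constraints are converted to halting events (see
#' [constraints_to_events()]) as part of compilation.
#'
#' @param diagram Optional `Diagram` (checked with the model when given).
#' @param model A `MathModel`, already flattened.
#' @param engine `"ode"` or `"stochastic"`.
#' @return A `CompiledSystem`.
#' @export
compile_system <- function(diagram = NULL, model, engine = c("ode", "stochastic")) {
  engine <- match.arg(engine)
  diags <- validate_model(diagram, model)
  if (length(diags))
    stop("cannot compile an invalid model:\n  ",
         paste(diags, collapse = "\n  "), call. = FALSE)
  model <- constraints_to_events(model)

  vars <- names(model$variables)
  pars <- names(model$parameters)
  dyn <- vapply(model$variables, `[[`, "", "dynamics")
  rate_targets <- unlist(lapply(model$rules, function(r)
    if (r$kind == "rate") r$target else NULL)) %||% character(0)
  alg_rules <- Filter(function(r) r$kind == "algebraic", model$rules)
  alg_idx <- which(dyn == "algebraic")

  # a species may be governed by reactions or by a rate rule, not both
  for (r in model$reactions)
    for (s in intersect(c(names(r$reactants), names(r$products)), rate_targets))
      stop("species '", s, "' is governed by both reaction '", r$id,
           "' and a rate rule", call. = FALSE)

  if (engine == "stochastic") {
    if (length(rate_targets))
      stop("engine-compatibility error: stochastic engine does not support ",
           "rate rules (targets: ", paste(rate_targets, collapse = ", "), ")",
           call. = FALSE)
    if (length(alg_idx))
      stop("engine-compatibility error: stochastic engine does not support ",
           "algebraic variables", call. = FALSE)
    for (r in model$reactions) {
      st <- c(r$reactants, r$products)
      if (any(st != round(st)))
        stop("engine-compatibility error: reaction '", r$id,
             "' has non-integer stoichiometry", call. = FALSE)
    }
  }
  if (length(alg_rules) != length(alg_idx))
    stop("algebraic system is not square: ", length(alg_rules),
         " residual(s) for ", length(alg_idx), " algebraic variable(s)",
         call. = FALSE)

  N <- stoich_matrix(model, species = vars)   # full: zero rows for non-species
  preamble <- .codegen_preamble(model, vars, pars)

  law_lines <- vapply(seq_along(model$reactions), function(j)
    paste0(".v", j, " <- ", expr_to_text(model$reactions[[j]]$kinetic_law)),
    "")
  deriv_terms <- vapply(seq_along(vars), function(i) {
    v <- vars[[i]]
    if (dyn[[i]] %in% c("constant", "assigned", "algebraic")) return("0")
    rr <- Filter(function(r) r$kind == "rate" && identical(r$target, v),
                 model$rules)
    if (length(rr)) return(paste0("(", expr_to_text(rr[[1L]]$expression), ")"))
    js <- which(N[i, ] != 0)
    if (!length(js)) return("0")
    paste(vapply(js, function(j)
      paste0("(", format(N[i, j], digits = 17), ")*.v", j), ""),
      collapse = " + ")
  }, "")

  mk <- function(body_lines, result) {
    # dot-prefixed arguments cannot collide with model identifiers
    txt <- paste0("function(.t, .x, .p) {\n",
                  paste(c(preamble, body_lines), collapse = "\n"),
                  "\n", result, "\n}")
    f <- eval(parse(text = txt)[[1L]], .sbk_eval_parent())
    compiler::cmpfun(f)
  }
  rhs_core <- mk(law_lines, paste0("c(", paste(deriv_terms, collapse = ", "), ")"))
  rates <- mk(law_lines,
              if (length(model$reactions))
                paste0("c(", paste(paste0(".v", seq_along(model$reactions)),
                                   collapse = ", "), ")")
              else "numeric(0)")
  observer <- mk(character(0),
                 paste0("c(", paste(vars, collapse = ", "), ")"))
  residual <- if (length(alg_rules))
    mk(character(0), paste0("c(", paste(vapply(alg_rules, function(r)
      paste0("(", expr_to_text(r$expression), ")"), ""), collapse = ", "), ")"))
  else NULL

  events <- lapply(model$events, function(ev) {
    list(id = ev$id,
         trigger = mk(character(0),
                      paste0("isTRUE(", expr_to_text(ev$trigger), ")")),
         margin = mk(character(0),
                     expr_to_text(trigger_margin_expr(ev$trigger))),
         values = if (length(ev$assignments))
           mk(character(0),
              paste0("c(", paste(vapply(names(ev$assignments), function(tg)
                paste0(tg, " = (",
                       expr_to_text(ev$assignments[[tg]]), ")"), ""),
                collapse = ", "), ")"))
         else function(t, x, p) numeric(0),
         targets = names(ev$assignments) %||% character(0),
         delay = ev$delay,
         delay_fun = if (!is.numeric(ev$delay))
           mk(character(0), expr_to_text(ev$delay)) else NULL,
         use_trigger_time_values = ev$use_trigger_time_values,
         halt = isTRUE(ev$halt), message = ev$message)
  })

  x0 <- vapply(model$variables, `[[`, 0, "initial_value")
  p0 <- vapply(model$parameters, `[[`, 0, "value")
  structure(list(layout = vars, par_layout = pars, dynamics = dyn,
                 x0 = stats::setNames(x0, vars),
                 p0 = stats::setNames(p0, pars),
                 N = N, rhs = rhs_core, rates = rates, observer = observer,
                 residual = residual, alg_idx = alg_idx,
                 events = events, engine = engine,
                 reaction_ids = vapply(model$reactions, `[[`, "", "id"),
                 model = model, diagram = diagram),
            class = "CompiledSystem")
}

# shared preamble: unpack state/parameters, bind time, apply assignment rules
#' @keywords internal
.codegen_preamble <- function(model, vars, pars) {
  lines <- character(0)
  for (i in seq_along(vars))
    lines <- c(lines, paste0(vars[[i]], " <- .x[[", i, "L]]"))
  for (i in seq_along(pars))
    lines <- c(lines, paste0(pars[[i]], " <- .p[[", i, "L]]"))
  lines <- c(lines, paste0(model$time_symbol, " <- .t"))
  asg <- Filter(function(r) r$kind == "assignment", model$rules)
  for (r in .topo_sort_rules(asg))
    lines <- c(lines, paste0(r$target, " <- ", expr_to_text(r$expression)))
  lines
}

# order assignment rules so each target is computed before it is used
#' @keywords internal
.topo_sort_rules <- function(rules) {
  if (length(rules) <= 1L) return(rules)
  targets <- vapply(rules, `[[`, "", "target")
  deps <- lapply(rules, function(r) intersect(expr_symbols(r$expression),
                                              targets))
  ordered <- list(); done <- character(0); left <- seq_along(rules)
  while (length(left)) {
    ready <- left[vapply(left, function(i)
      all(deps[[i]] %in% done), logical(1))]
    if (!length(ready))
      stop("cyclic assignment rules among: ",
           paste(targets[left], collapse = ", "), call. = FALSE)
    for (i in ready) {
      ordered[[length(ordered) + 1L]] <- rules[[i]]
      done <- c(done, targets[[i]])
    }
    left <- setdiff(left, ready)
  }
  ordered
}

#' @export
print.CompiledSystem <- function(x, ...) {
  cat("CompiledSystem (", x$engine, "): ", length(x$layout), " state variables, ",
      length(x$par_layout), " parameters, ", length(x$reaction_ids),
      " reactions, ", length(x$events), " events\n", sep = "")
  invisible(x)
}

# Solve the algebraic subsystem for the algebraic state entries at (t, x, p)
# by damped Newton with finite-difference Jacobian.
#' @keywords internal
solve_algebraic <- function(sys, t, x, p, tol = 1e-12) {
  if (!length(sys$alg_idx)) return(x)
  idx <- sys$alg_idx
  g <- function(z) { x[idx] <- z; sys$residual(t, x, p) }
  z <- x[idx]
  f <- g(z)
  for (it in seq_len(60L)) {
    if (max(abs(f)) < tol) break
    J <- matrix(0, length(f), length(z))
    for (k in seq_along(z)) {
      h <- max(1e-8, 1e-8 * abs(z[k]))
      zp <- z; zp[k] <- zp[k] + h
      J[, k] <- (g(zp) - f) / h
    }
    step <- tryCatch(solve(J, -f), error = function(e)
      stop("algebraic system is singular at t = ", t, call. = FALSE))
    lam <- 1
    repeat {
      znew <- z + lam * step
      fnew <- g(znew)
      if (max(abs(fnew)) < max(abs(f)) || lam < 1e-6) break
      lam <- lam / 2
    }
    z <- znew; f <- fnew
  }
  if (max(abs(f)) > 1e-8)
    stop("algebraic constraints could not be satisfied at t = ", t,
         " (residual ", format(max(abs(f))), ")", call. = FALSE)
  x[idx] <- z
  x
}

# full rhs including algebraic projection (used by integrators)
#' @keywords internal
system_rhs <- function(sys) {
  if (!length(sys$alg_idx)) return(sys$rhs)
  function(t, x, p) {
    x <- solve_algebraic(sys, t, x, p)
    sys$rhs(t, x, p)
  }
}
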