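# The meta-model: a compartmentalized attributed graph (Diagram) plus the
# executable mathematical overlay (MathModel).  Database cross-references are
# carried only as free-form annotation strings.

#' Create a model variable
#'
#' @param id Identifier.
#' @param initial_value Finite numeric initial value (amount).
#' @param units Free-form unit label; never converted.
#' @param dynamics One of `"ode"`, `"assigned"`, `"algebraic"`, `"constant"`.
#'   `"constant"` covers boundary/fixed species and plain state constants.
#' @param compartment Optional compartment id.
#' @return A `Variable` list.
#' @export
mm_variable <- function(id, initial_value = 0, units = "", dynamics = "ode",
                        compartment = NULL) {
  dynamics <- match.arg(dynamics, c("ode", "assigned", "algebraic", "constant"))
  structure(list(id = id, initial_value = initial_value, units = units,
                 dynamics = dynamics, compartment = compartment),
            class = "Variable")
}

#' Create a model parameter
#' @param id Identifier.
#' @param value Numeric value.
#' @param units Free-form unit label.
#' @export
mm_parameter <- function(id, value, units = "") {
  structure(list(id = id, value = value, units = units), class = "Parameter")
}

#' Create a reaction
#'
#' @param id Identifier.
#' @param reactants,products Named numeric vectors: species id -> positive
#'   stoichiometry.  Empty vectors describe source/sink reactions.
#' @param modifiers Character vector of modifier species ids.
#' @param kinetic_law Quoted expression (or string, parsed) for the rate.
#' @param fast Logical: quasi-equilibrium reaction (see
#'   [fast_to_algebraic()]).
#' @param reversible Logical flag (semantics only; the law carries the math).
#' @export
mm_reaction <- function(id, reactants = numeric(0), products = numeric(0),
                        modifiers = character(0), kinetic_law,
                        fast = FALSE, reversible = FALSE) {
  if (is.character(kinetic_law)) kinetic_law <- parse_expr(kinetic_law)
  structure(list(id = id, reactants = reactants, products = products,
                 modifiers = modifiers, kinetic_law = kinetic_law,
                 fast = fast, reversible = reversible),
            class = "Reaction")
}

#' Create a rule
#' @param kind `"assignment"`, `"rate"` or `"algebraic"`.
#' @param target Target symbol (absent/NULL for algebraic rules).
#' @param expression Quoted expression or string.
#' @export
mm_rule <- function(kind, target = NULL, expression) {
  kind <- match.arg(kind, c("assignment", "rate", "algebraic"))
  if (is.character(expression)) expression <- parse_expr(expression)
  structure(list(kind = kind, target = target, expression = expression),
            class = "Rule")
}

#' Create an event
#'
#' Events fire on the false-to-true transition of their trigger; triggers
#' already true at the initial time do not fire (SBML convention).
#'
#' @param id Identifier.
#' @param trigger Boolean expression (quoted or string).
#' @param assignments Named list: target symbol -> value expression.
#' @param delay Nonnegative number or expression; assignments execute
#'   `delay` after the trigger fires.
#' @param use_trigger_time_values If `TRUE` (default) assignment values are
#'   computed at trigger time, else at execution time.
#' @param halt If `TRUE` the event stops the simulation (used by
#'   [constraints_to_events()]).
#' @param message Optional message recorded when a halt event fires.
#' @export
mm_event <- function(id, trigger, assignments = list(), delay = 0,
                     use_trigger_time_values = TRUE, halt = FALSE,
                     message = "") {
  if (is.character(trigger)) trigger <- parse_expr(trigger)
  if (is.character(delay)) delay <- parse_expr(delay)
  assignments <- lapply(assignments, function(a)
    if (is.character(a)) parse_expr(a) else a)
  structure(list(id = id, trigger = trigger, assignments = assignments,
                 delay = delay,
                 use_trigger_time_values = use_trigger_time_values,
                 halt = halt, message = message),
            class = "Event")
}

#' Create a constraint
#' @param id Identifier.
#' @param condition Boolean expression that must stay true.
#' @param message Message reported when the constraint is violated.
#' @export
mm_constraint <- function(id, condition, message = "") {
  if (is.character(condition)) condition <- parse_expr(condition)
  structure(list(id = id, condition = condition, message = message),
            class = "Constraint")
}

#' Create a mathematical model
#'
#' @param variables List of [mm_variable()] objects.
#' @param parameters List of [mm_parameter()] objects.
#' @param reactions List of [mm_reaction()] objects.
#' @param rules List of [mm_rule()] objects.
#' @param events List of [mm_event()] objects.
#' @param constraints List of [mm_constraint()] objects.
#' @param time_symbol Symbol bound to simulation time in expressions.
#' @return A `MathModel`.
#' @export
math_model <- function(variables = list(), parameters = list(),
                       reactions = list(), rules = list(), events = list(),
                       constraints = list(), time_symbol = "time") {
  named <- function(xs) stats::setNames(xs, vapply(xs, `[[`, "", "id"))
  structure(list(variables = named(variables), parameters = named(parameters),
                 reactions = named(reactions), rules = rules, events = events,
                 constraints = constraints, time_symbol = time_symbol),
            class = "MathModel")
}

#' Create a diagram node
#' @param id Identifier.
#' @param kind One of species, reaction, compartment, module, port, annotation.
#' @param attributes Key -> value list.
#' @param math_ref Optional id of the bound MathModel element.
#' @export
dg_node <- function(id, kind, attributes = list(), math_ref = NULL) {
  kind <- match.arg(kind, c("species", "reaction", "compartment", "module",
                            "port", "annotation"))
  structure(list(id = id, kind = kind, attributes = attributes,
                 math_ref = math_ref), class = "Node")
}

#' Create a diagram edge
#' @param id Identifier.
#' @param source,target Node ids.
#' @param role One of reactant, product, modifier, connection.
#' @param stoichiometry Positive number (reactant/product roles only).
#' @export
dg_edge <- function(id, source, target, role, stoichiometry = NULL) {
  role <- match.arg(role, c("reactant", "product", "modifier", "connection"))
  structure(list(id = id, source = source, target = target, role = role,
                 stoichiometry = stoichiometry), class = "Edge")
}

#' Create a diagram
#' @param name Identifier.
#' @param nodes List of [dg_node()] objects.
#' @param edges List of [dg_edge()] objects.
#' @param compartments Named character map: node id -> parent compartment id.
#' @param annotations Key -> string list (free-form; holds database refs).
#' @export
diagram <- function(name, nodes = list(), edges = list(),
                    compartments = character(0), annotations = list()) {
  named <- function(xs) stats::setNames(xs, vapply(xs, `[[`, "", "id"))
  structure(list(name = name, nodes = named(nodes), edges = named(edges),
                 compartments = compartments, annotations = annotations),
            class = "Diagram")
}

# Derive the standard bipartite diagram (species/reaction nodes, stoichiometry
# edges) from a MathModel, so builders only have to supply the math.
#' @keywords internal
diagram_from_model <- function(name, model) {
  nodes <- list()
  edges <- list()
  for (v in model$variables)
    nodes[[length(nodes) + 1L]] <- dg_node(v$id, "species", math_ref = v$id)
  k <- 0L
  for (r in model$reactions) {
    nodes[[length(nodes) + 1L]] <- dg_node(r$id, "reaction", math_ref = r$id)
    for (s in names(r$reactants)) {
      k <- k + 1L
      edges[[length(edges) + 1L]] <-
        dg_edge(paste0("e", k), s, r$id, "reactant", r$reactants[[s]])
    }
    for (s in names(r$products)) {
      k <- k + 1L
      edges[[length(edges) + 1L]] <-
        dg_edge(paste0("e", k), r$id, s, "product", r$products[[s]])
    }
    for (s in r$modifiers) {
      k <- k + 1L
      edges[[length(edges) + 1L]] <- dg_edge(paste0("e", k), s, r$id, "modifier")
    }
  }
  diagram(name, nodes, edges)
}

#' All symbols a model declares
#' @keywords internal
model_symbols <- function(model) {
  c(names(model$variables), names(model$parameters), model$time_symbol)
}

#' Validate a diagram and mathematical model
#'
#' Checks every structural invariant of the meta-model and returns a character
#' vector of diagnostics, empty when the pair is well-formed.  Diagnostics name
#' the offending element and the violated rule; validation never throws.
#'
#' @param diagram A `Diagram` (or `NULL` to check only the model).
#' @param model A `MathModel`.
#' @return Character vector of diagnostics (empty if valid).
#' @export
validate_model <- function(diagram = NULL, model) {
  diags <- character(0)
  say <- function(...) diags[[length(diags) + 1L]] <<- paste0(...)

  ## ---- diagram invariants ----
  if (!is.null(diagram)) {
    ids <- vapply(diagram$nodes, `[[`, "", "id")
    dup <- unique(ids[duplicated(ids)])
    for (d in dup) say("diagram: duplicate node id '", d, "'")
    for (e in diagram$edges) {
      for (end in c(e$source, e$target))
        if (!(end %in% ids))
          say("edge '", e$id, "': endpoint '", end, "' is not a node")
      if (e$role %in% c("reactant", "product") &&
          e$source %in% ids && e$target %in% ids) {
        kinds <- sort(c(diagram$nodes[[e$source]]$kind,
                        diagram$nodes[[e$target]]$kind))
        if (!identical(kinds, c("reaction", "species")))
          say("edge '", e$id, "': ", e$role,
              " edges must join a species and a reaction node")
        if (!is.null(e$stoichiometry) && !(e$stoichiometry > 0))
          say("edge '", e$id, "': stoichiometry must be positive")
      }
    }
    # compartment nesting must be a forest (acyclic)
    comp <- diagram$compartments
    for (start in names(comp)) {
      seen <- character(0)
      cur <- start
      while (!is.null(cur) && cur %in% names(comp)) {
        if (cur %in% seen) {
          say("compartment nesting cycle involving '", start, "'")
          break
        }
        seen <- c(seen, cur)
        cur <- comp[[cur]]
      }
    }
    for (n in diagram$nodes) {
      if (n$kind == "port" &&
          length(n$attributes$variable) != 1L)
        say("port node '", n$id, "' must carry exactly one variable reference")
    }
  }

  ## ---- math model invariants ----
  syms <- model_symbols(model)
  dupsym <- unique(syms[duplicated(syms)])
  for (d in dupsym) say("model: symbol '", d, "' declared more than once")

  check_refs <- function(expr, where) {
    for (s in setdiff(expr_symbols(expr), syms))
      say(where, ": undeclared symbol '", s, "'")
  }
  for (v in model$variables)
    if (!is.finite(v$initial_value))
      say("variable '", v$id, "': initial value is not finite")
  for (r in model$reactions) {
    check_refs(r$kinetic_law, paste0("reaction '", r$id, "' kinetic law"))
    for (s in c(names(r$reactants), names(r$products), r$modifiers))
      if (!(s %in% names(model$variables)))
        say("reaction '", r$id, "': species '", s, "' is not a variable")
  }
  targets <- character(0)
  for (rule in model$rules) {
    if (rule$kind %in% c("assignment", "rate")) {
      if (is.null(rule$target))
        say("rule of kind '", rule$kind, "' has no target")
      else {
        if (rule$target %in% targets)
          say("symbol '", rule$target, "' is the target of more than one rule")
        targets <- c(targets, rule$target)
        if (!(rule$target %in% syms))
          say("rule target '", rule$target, "' is not declared")
      }
    } else if (!is.null(rule$target)) {
      say("algebraic rule must not name a target")
    }
    check_refs(rule$expression, paste0(rule$kind, " rule"))
  }
  for (ev in model$events) {
    check_refs(ev$trigger, paste0("event '", ev$id, "' trigger"))
    ok <- tryCatch({trigger_margin_expr(ev$trigger); TRUE},
                   error = function(e) FALSE)
    if (!ok) say("event '", ev$id, "': trigger is not a boolean expression")
    for (tg in names(ev$assignments)) {
      if (!(tg %in% syms) || tg == model$time_symbol)
        say("event '", ev$id, "': assignment target '", tg,
            "' is not a variable or parameter")
      if (tg %in% names(model$variables) &&
          model$variables[[tg]]$dynamics == "assigned")
        say("event '", ev$id, "': cannot assign to rule-assigned variable '",
            tg, "'")
      check_refs(ev$assignments[[tg]],
                 paste0("event '", ev$id, "' assignment to '", tg, "'"))
    }
    if (is.numeric(ev$delay) && ev$delay < 0)
      say("event '", ev$id, "': delay must be nonnegative")
  }
  for (cn in model$constraints) {
    check_refs(cn$condition, paste0("constraint '", cn$id, "'"))
    ok <- tryCatch({trigger_margin_expr(cn$condition); TRUE},
                   error = function(e) FALSE)
    if (!ok) say("constraint '", cn$id, "': condition is not boolean")
  }
  # consistency between dynamics flags and rules
  for (v in model$variables) {
    if (v$dynamics == "assigned") {
      has <- any(vapply(model$rules, function(r)
        r$kind == "assignment" && identical(r$target, v$id), logical(1)))
      if (!has) say("variable '", v$id,
                    "' is 'assigned' but has no assignment rule")
    }
  }
  diags
}

#' @export
print.MathModel <- function(x, ...) {
  cat("MathModel:", length(x$variables), "variables,",
      length(x$parameters), "parameters,",
      length(x$reactions), "reactions,",
      length(x$rules), "rules,",
      length(x$events), "events,",
      length(x$constraints), "constraints\n")
  invisible(x)
}

#' @export
print.Diagram <- function(x, ...) {
  cat("Diagram '", x$name, "': ", length(x$nodes), " nodes, ",
      length(x$edges), " edges\n", sep = "")
  invisible(x)
}
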