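# SBML Level 3 core subset reader/writer on top of xml2.
#
# Supported: compartments (constant), species (amount or concentration
# initialization; boundary/constant flags), parameters, reactions with
# MathML-core kinetic laws and local parameters (globalized as
# `<reaction>_<parameter>`), assignment/rate/algebraic rules, initial
# assignments (folded into initial values at load), events (trigger, delay,
# event assignments, useValuesFromTriggerTime) and constraints.  Extension
# packages (comp, fbc, ...), function definitions, priorities, delay
# csymbols and other MathML constructs outside the operator whitelist raise
# an import error naming each offending element; nothing is dropped
# silently.  The canonical state is amount: concentration-initialized
# species are converted through their compartment size at load time.

.SBML_NS <- "http://www.sbml.org/sbml/level3/version2/core"
.MATHML_NS <- "http://www.w3.org/1998/Math/MathML"
.TIME_URL <- "http://www.sbml.org/sbml/symbols/time"

#' Read an SBML Level 3 core subset document
#'
#' @param source File path, XML string, or raw vector.
#' @return `list(diagram=, model=)`.
#' @export
read_sbml <- function(source) {
  doc <- xml2::read_xml(source)
  root <- xml2::xml_name(doc)
  if (root != "sbml") stop("not an SBML document (root element '", root, "')",
                           call. = FALSE)
  bad <- character(0)
  complain <- function(...) bad[[length(bad) + 1L]] <<- paste0(...)

  nss <- xml2::xml_ns(doc)
  pkg_ns <- nss[!(nss %in% c(.SBML_NS, .MATHML_NS))]
  for (u in unique(pkg_ns)) {
    short <- sub(".*/(comp|fbc|layout|qual|groups|multi|distrib)/.*", "\\1", u)
    if (grepl("sbml", u))
      complain("unsupported SBML package namespace '",
               if (nchar(short) < nchar(u)) short else u, "'")
  }
  lvl <- xml2::xml_attr(doc, "level")
  if (!is.na(lvl) && lvl != "3")
    complain("unsupported SBML level ", lvl, " (subset is Level 3 core)")

  mnode <- xml2::xml_find_first(doc, "./*[local-name()='model']")
  if (inherits(mnode, "xml_missing")) stop("SBML document has no <model>",
                                           call. = FALSE)
  if (!is.na(xml2::xml_attr(mnode, "conversionFactor")))
    complain("unsupported attribute conversionFactor on <model>")
  find_all <- function(node, path) xml2::xml_find_all(node, path)
  lof <- function(list_name, item) find_all(mnode, paste0(
    "./*[local-name()='", list_name, "']/*[local-name()='", item, "']"))
  if (length(lof("listOfFunctionDefinitions", "functionDefinition")))
    complain("unsupported construct: functionDefinition")

  att <- function(n, a, default = NA_character_) {
    v <- xml2::xml_attr(n, a)
    if (is.na(v)) default else v
  }
  num_att <- function(n, a, default = NA_real_) {
    v <- att(n, a)
    if (is.na(v)) default else as.numeric(v)
  }
  bool_att <- function(n, a, default = FALSE) {
    v <- att(n, a)
    if (is.na(v)) default else identical(v, "true")
  }
  math_of <- function(n) {
    mn <- xml2::xml_find_first(n, "./*[local-name()='math']")
    if (inherits(mn, "xml_missing")) return(NULL)
    tryCatch(.mathml_to_expr(xml2::xml_children(mn)[[1L]]),
             error = function(e) { complain(conditionMessage(e)); quote(0) })
  }

  comps <- list(); comp_sizes <- numeric(0)
  for (n in lof("listOfCompartments", "compartment")) {
    id <- att(n, "id")
    if (!bool_att(n, "constant", TRUE))
      complain("unsupported: non-constant compartment '", id, "'")
    comp_sizes[[id]] <- num_att(n, "size", 1)
  }

  parameters <- list()
  param_const <- character(0)
  for (n in lof("listOfParameters", "parameter")) {
    id <- att(n, "id")
    parameters[[id]] <- mm_parameter(id, num_att(n, "value", 0),
                                     units = att(n, "units", ""))
    param_const[[id]] <- att(n, "constant", "true")
  }

  variables <- list()
  for (n in lof("listOfSpecies", "species")) {
    id <- att(n, "id")
    comp <- att(n, "compartment")
    amt <- num_att(n, "initialAmount")
    if (is.na(amt)) {
      conc <- num_att(n, "initialConcentration")
      size <- if (!is.na(comp) && comp %in% names(comp_sizes))
        comp_sizes[[comp]] else 1
      amt <- if (is.na(conc)) 0 else conc * size
    }
    dyn <- if (bool_att(n, "boundaryCondition") || bool_att(n, "constant"))
      "constant" else "ode"
    variables[[id]] <- mm_variable(id, amt, units = att(n, "units", ""),
                                   dynamics = dyn,
                                   compartment = if (!is.na(comp)) comp)
  }

  reactions <- list()
  for (n in lof("listOfReactions", "reaction")) {
    id <- att(n, "id")
    refs <- function(kind) {
      out <- numeric(0)
      for (sr in find_all(n, paste0("./*[local-name()='", kind,
                                    "']/*[local-name()='speciesReference']")))
        out[[att(sr, "species")]] <- num_att(sr, "stoichiometry", 1)
      out
    }
    mods <- vapply(find_all(n, paste0(
      "./*[local-name()='listOfModifiers']",
      "/*[local-name()='modifierSpeciesReference']")),
      function(sr) att(sr, "species"), "")
    kl <- xml2::xml_find_first(n, "./*[local-name()='kineticLaw']")
    law <- quote(0)
    if (!inherits(kl, "xml_missing")) {
      law <- math_of(kl) %||% quote(0)
      for (lp in find_all(kl, paste0(
        "./*[local-name()='listOfLocalParameters']",
        "/*[local-name()='localParameter']"))) {
        lid <- att(lp, "id")
        gid <- paste0(id, "_", lid)
        if (gid %in% names(parameters))
          complain("local parameter '", lid, "' of reaction '", id,
                   "' collides with global id '", gid, "'")
        parameters[[gid]] <- mm_parameter(gid, num_att(lp, "value", 0))
        law <- substitute_symbols(law,
                                  stats::setNames(list(as.symbol(gid)), lid))
      }
    }
    reactions[[length(reactions) + 1L]] <-
      mm_reaction(id, reactants = refs("listOfReactants"),
                  products = refs("listOfProducts"),
                  modifiers = as.character(mods), kinetic_law = law,
                  fast = bool_att(n, "fast"),
                  reversible = bool_att(n, "reversible", TRUE))
  }

  rules <- list()
  rule_targets <- character(0)
  n_alg <- 0L
  for (n in find_all(mnode, "./*[local-name()='listOfRules']/*")) {
    kind <- switch(xml2::xml_name(n),
                   assignmentRule = "assignment", rateRule = "rate",
                   algebraicRule = "algebraic", NA_character_)
    if (is.na(kind)) { complain("unsupported rule <", xml2::xml_name(n), ">")
      next }
    tg <- att(n, "variable")
    rules[[length(rules) + 1L]] <-
      mm_rule(kind, target = if (!is.na(tg)) tg, expression = math_of(n))
    if (!is.na(tg)) rule_targets <- c(rule_targets,
                                      stats::setNames(kind, tg))
    if (kind == "algebraic") n_alg <- n_alg + 1L
  }
  # promote non-constant rule-target parameters to variables
  for (tg in names(rule_targets)) {
    if (tg %in% names(parameters)) {
      variables[[tg]] <- mm_variable(tg, parameters[[tg]]$value,
                                     units = parameters[[tg]]$units,
                                     dynamics = "ode")
      parameters[[tg]] <- NULL
    }
    if (tg %in% names(variables) && rule_targets[[tg]] == "assignment")
      variables[[tg]]$dynamics <- "assigned"
  }
  # species determined by algebraic rules: the first otherwise-undetermined
  # non-constant variables, in declaration order
  if (n_alg > 0L) {
    participants <- unique(unlist(lapply(reactions, function(r)
      c(names(r$reactants), names(r$products)))))
    free <- names(variables)[vapply(names(variables), function(v)
      variables[[v]]$dynamics == "ode" && !(v %in% participants) &&
        !(v %in% names(rule_targets)), logical(1))]
    if (length(free) < n_alg)
      complain("cannot match ", n_alg, " algebraic rule(s) to undetermined ",
               "variables")
    for (v in utils::head(free, n_alg)) variables[[v]]$dynamics <- "algebraic"
  }

  # initial assignments folded into initial values
  for (n in lof("listOfInitialAssignments", "initialAssignment")) {
    sym <- att(n, "symbol")
    e <- math_of(n)
    env <- c(lapply(variables, `[[`, "initial_value"),
             lapply(parameters, `[[`, "value"),
             as.list(comp_sizes), list(time = 0))
    val <- tryCatch(evaluate_expr(e, env), error = function(err) {
      complain("initialAssignment for '", sym, "': ", conditionMessage(err))
      0
    })
    if (sym %in% names(variables)) variables[[sym]]$initial_value <- val
    else if (sym %in% names(parameters)) parameters[[sym]]$value <- val
    else if (sym %in% names(comp_sizes)) comp_sizes[[sym]] <- val
    else complain("initialAssignment for unknown symbol '", sym, "'")
  }

  events <- list()
  for (n in lof("listOfEvents", "event")) {
    id <- att(n, "id", paste0("E", length(events) + 1L))
    if (length(find_all(n, ".//*[local-name()='priority']")))
      complain("unsupported construct: event priority in '", id, "'")
    trig_n <- xml2::xml_find_first(n, "./*[local-name()='trigger']")
    trig <- if (!inherits(trig_n, "xml_missing")) math_of(trig_n) else TRUE
    delay_n <- xml2::xml_find_first(n, "./*[local-name()='delay']")
    delay <- if (!inherits(delay_n, "xml_missing")) math_of(delay_n) else 0
    if (is.numeric(delay) || is.null(delay)) delay <- as.numeric(delay %||% 0)
    asg <- list()
    for (ea in find_all(n, paste0("./*[local-name()='listOfEventAssignments']",
                                  "/*[local-name()='eventAssignment']")))
      asg[[att(ea, "variable")]] <- math_of(ea)
    events[[length(events) + 1L]] <-
      mm_event(id, trig, asg, delay = delay,
               use_trigger_time_values =
                 bool_att(n, "useValuesFromTriggerTime", TRUE))
  }

  constraints <- list()
  for (n in lof("listOfConstraints", "constraint")) {
    msg_n <- xml2::xml_find_first(n, "./*[local-name()='message']")
    constraints[[length(constraints) + 1L]] <-
      mm_constraint(att(n, "id", paste0("C", length(constraints) + 1L)),
                    math_of(n),
                    message = if (!inherits(msg_n, "xml_missing"))
                      trimws(xml2::xml_text(msg_n)) else "")
  }

  for (cid in names(comp_sizes))
    parameters[[cid]] <- mm_parameter(cid, comp_sizes[[cid]])
  # event-targeted parameters stay parameters (marked non-constant on write)

  if (length(bad))
    stop("SBML import error:\n  ", paste(unique(bad), collapse = "\n  "),
         call. = FALSE)

  dup <- names(variables)[names(variables) %in% names(parameters)]
  if (length(dup))
    stop("SBML import error: duplicate id '", dup[[1L]], "'", call. = FALSE)

  model <- math_model(unname(variables), unname(parameters),
                      unname(reactions), rules, events, constraints)
  dg <- diagram_from_model(att(mnode, "id", "model"), model)
  dg$compartments <- stats::setNames(rep("", length(comp_sizes)),
                                     names(comp_sizes))
  diags <- validate_model(dg, model)
  if (length(diags))
    stop("SBML import produced an invalid model:\n  ",
         paste(diags, collapse = "\n  "), call. = FALSE)
  list(diagram = dg, model = model)
}

## ---- MathML ----

#' @keywords internal
.mathml_to_expr <- function(n) {
  name <- xml2::xml_name(n)
  kids <- xml2::xml_children(n)
  if (name == "ci") return(as.symbol(trimws(xml2::xml_text(n))))
  if (name == "csymbol") {
    if (identical(xml2::xml_attr(n, "definitionURL"), .TIME_URL))
      return(as.symbol("time"))
    stop("unsupported csymbol '", trimws(xml2::xml_text(n)), "'",
         call. = FALSE)
  }
  if (name == "cn") {
    type <- xml2::xml_attr(n, "type")
    if (!is.na(type) && type == "rational") {
      parts <- as.numeric(trimws(strsplit(xml2::xml_text(n), "\n")[[1L]]))
      parts <- parts[!is.na(parts)]
      return(parts[[1L]] / parts[[2L]])
    }
    if (!is.na(type) && type == "e-notation") {
      parts <- as.numeric(trimws(strsplit(xml2::xml_text(n), "\n")[[1L]]))
      parts <- parts[!is.na(parts)]
      return(parts[[1L]] * 10^parts[[2L]])
    }
    return(as.numeric(trimws(xml2::xml_text(n))))
  }
  if (name == "true") return(TRUE)
  if (name == "false") return(FALSE)
  if (name == "pi") return(pi)
  if (name == "exponentiale") return(exp(1))
  if (name == "piecewise") {
    args <- list(quote(piecewise))
    for (k in kids) {
      kk <- xml2::xml_children(k)
      if (xml2::xml_name(k) == "piece") {
        args[[length(args) + 1L]] <- .mathml_to_expr(kk[[1L]])
        args[[length(args) + 1L]] <- .mathml_to_expr(kk[[2L]])
      } else if (xml2::xml_name(k) == "otherwise") {
        args[[length(args) + 1L]] <- .mathml_to_expr(kk[[1L]])
      }
    }
    return(as.call(args))
  }
  if (name != "apply")
    stop("unsupported MathML element <", name, ">", call. = FALSE)
  op <- xml2::xml_name(kids[[1L]])
  plain <- Filter(function(k)
    !(xml2::xml_name(k) %in% c("logbase", "degree")), kids[-1L])
  args <- lapply(plain, .mathml_to_expr)
  fold <- function(sym) {
    if (length(args) == 0L) return(if (sym == "+") 0 else 1)
    Reduce(function(a, b) call(sym, a, b), args)
  }
  switch(op,
    plus = fold("+"), times = fold("*"),
    minus = if (length(args) == 1L) call("-", args[[1L]]) else
      call("-", args[[1L]], args[[2L]]),
    divide = call("/", args[[1L]], args[[2L]]),
    power = call("^", args[[1L]], args[[2L]]),
    exp = call("exp", args[[1L]]),
    ln = call("ln", args[[1L]]),
    abs = call("abs", args[[1L]]),
    floor = call("floor", args[[1L]]),
    ceiling = call("ceiling", args[[1L]]),
    min = as.call(c(list(quote(min)), args)),
    max = as.call(c(list(quote(max)), args)),
    log = {
      base_n <- xml2::xml_find_first(n, "./*[local-name()='logbase']")
      base <- if (inherits(base_n, "xml_missing")) 10 else
        .mathml_to_expr(xml2::xml_children(base_n)[[1L]])
      if (!identical(as.numeric(base), 10))
        stop("unsupported logarithm base ", deparse(base), call. = FALSE)
      call("log10", args[[1L]])
    },
    root = {
      deg_n <- xml2::xml_find_first(n, "./*[local-name()='degree']")
      deg <- if (inherits(deg_n, "xml_missing")) 2 else
        .mathml_to_expr(xml2::xml_children(deg_n)[[1L]])
      if (!identical(as.numeric(deg), 2))
        stop("unsupported root degree ", deparse(deg), call. = FALSE)
      call("sqrt", args[[1L]])
    },
    lt = call("<", args[[1L]], args[[2L]]),
    leq = call("<=", args[[1L]], args[[2L]]),
    gt = call(">", args[[1L]], args[[2L]]),
    geq = call(">=", args[[1L]], args[[2L]]),
    eq = call("==", args[[1L]], args[[2L]]),
    neq = call("!=", args[[1L]], args[[2L]]),
    and = if (length(args)) Reduce(function(a, b) call("&", a, b), args)
          else TRUE,
    or = if (length(args)) Reduce(function(a, b) call("|", a, b), args)
         else FALSE,
    not = call("!", args[[1L]]),
    stop("unsupported MathML operator <", op, ">", call. = FALSE))
}

# expression -> MathML string (no namespace prefix; parent provides xmlns)
#' @keywords internal
.expr_to_mathml <- function(e, time_symbol = "time") {
  esc <- function(s) gsub("<", "&lt;", gsub("&", "&amp;", s, fixed = TRUE),
                          fixed = TRUE)
  rec <- function(e) {
    if (is.numeric(e)) {
      if (e == round(e) && abs(e) < 1e15)
        return(paste0("<cn type=\"integer\"> ",
                      format(e, scientific = FALSE), " </cn>"))
      return(paste0("<cn> ", format(e, digits = 17, scientific = FALSE),
                    " </cn>"))
    }
    if (isTRUE(e)) return("<true/>")
    if (isFALSE(e)) return("<false/>")
    if (is.symbol(e)) {
      s <- as.character(e)
      if (s == time_symbol)
        return(paste0("<csymbol encoding=\"text\" definitionURL=\"",
                      .TIME_URL, "\"> ", s, " </csymbol>"))
      return(paste0("<ci> ", esc(s), " </ci>"))
    }
    if (!is.call(e)) stop("cannot serialize ", deparse(e), call. = FALSE)
    op <- as.character(e[[1L]])
    if (op == "(") return(rec(e[[2L]]))
    args <- lapply(as.list(e)[-1L], rec)
    wrap <- function(opel, qualifier = NULL)
      paste0("<apply> <", opel, "/> ", qualifier,
             paste(unlist(args), collapse = " "), " </apply>")
    switch(op,
      "+" = wrap("plus"), "*" = wrap("times"), "/" = wrap("divide"),
      "-" = wrap("minus"), "^" = wrap("power"),
      "exp" = wrap("exp"), "ln" = wrap("ln"),
      "log" = wrap("ln"), "sqrt" = wrap("root"),
      "log10" = paste0("<apply> <log/> <logbase> <cn type=\"integer\"> 10 ",
                       "</cn> </logbase> ", args[[1L]], " </apply>"),
      "abs" = wrap("abs"), "floor" = wrap("floor"),
      "ceiling" = wrap("ceiling"),
      "min" = wrap("min"), "max" = wrap("max"),
      "<" = wrap("lt"), "<=" = wrap("leq"), ">" = wrap("gt"),
      ">=" = wrap("geq"), "==" = wrap("eq"), "!=" = wrap("neq"),
      "&" = wrap("and"), "&&" = wrap("and"),
      "|" = wrap("or"), "||" = wrap("or"), "!" = wrap("not"),
      "piecewise" = {
        a <- as.list(e)[-1L]
        np <- length(a) %/% 2L
        parts <- character(0)
        for (k in seq_len(np))
          parts <- c(parts, paste0("<piece> ", rec(a[[2L * k - 1L]]), " ",
                                   rec(a[[2L * k]]), " </piece>"))
        if (length(a) %% 2L == 1L)
          parts <- c(parts, paste0("<otherwise> ", rec(a[[length(a)]]),
                                   " </otherwise>"))
        paste0("<piecewise> ", paste(parts, collapse = " "), " </piecewise>")
      },
      stop("cannot serialize operator '", op, "' to MathML", call. = FALSE))
  }
  paste0("<math xmlns=\"", .MATHML_NS, "\"> ", rec(e), " </math>")
}

#' Write a model as SBML Level 3 core
#'
#' The inverse of [read_sbml()]: reading the output reproduces the model
#' element-wise.  Modular models cannot be exported directly; flatten first.
#'
#' @param x `list(diagram=, model=)` or a `MathModel`.
#' @param path Optional file path.
#' @return XML as a single string (invisibly when `path` is given).
#' @export
write_sbml <- function(x, path = NULL) {
  if (inherits(x, "ModularModel"))
    stop("export error: modular models cannot be written as core SBML; ",
         "flatten() first", call. = FALSE)
  model <- if (inherits(x, "MathModel")) x else x$model
  dg <- if (inherits(x, "MathModel")) NULL else x$diagram
  diags <- validate_model(dg, model)
  if (length(diags))
    stop("cannot export an invalid model:\n  ",
         paste(diags, collapse = "\n  "), call. = FALSE)
  esc <- function(s) gsub("<", "&lt;", gsub("&", "&amp;", s, fixed = TRUE),
                          fixed = TRUE)
  num <- function(v) format(v, digits = 17, scientific = FALSE)
  comp_ids <- if (!is.null(dg)) names(dg$compartments) else character(0)
  ev_targets <- unique(unlist(lapply(model$events, function(e)
    names(e$assignments)))) %||% character(0)
  L <- character(0)
  add <- function(...) L[[length(L) + 1L]] <<- paste0(...)
  add("<?xml version=\"1.0\" encoding=\"UTF-8\"?>")
  add("<sbml xmlns=\"", .SBML_NS, "\" level=\"3\" version=\"2\">")
  add("  <model id=\"", esc(if (!is.null(dg)) dg$name else "model"), "\">")
  if (length(comp_ids)) {
    add("    <listOfCompartments>")
    for (cid in comp_ids)
      add("      <compartment id=\"", cid, "\" size=\"",
          num(model$parameters[[cid]]$value %||% 1),
          "\" constant=\"true\"/>")
    add("    </listOfCompartments>")
  }
  if (length(model$variables)) {
    add("    <listOfSpecies>")
    for (v in model$variables)
      add("      <species id=\"", v$id, "\"",
          if (!is.null(v$compartment)) paste0(" compartment=\"",
                                              v$compartment, "\""),
          " initialAmount=\"", num(v$initial_value), "\"",
          if (nzchar(v$units)) paste0(" units=\"", esc(v$units), "\""),
          " hasOnlySubstanceUnits=\"true\"",
          " boundaryCondition=\"", if (v$dynamics == "constant") "true"
                                   else "false", "\"",
          " constant=\"false\"/>")
    add("    </listOfSpecies>")
  }
  pars <- Filter(function(p) !(p$id %in% comp_ids), model$parameters)
  if (length(pars)) {
    add("    <listOfParameters>")
    for (p in pars)
      add("      <parameter id=\"", p$id, "\" value=\"", num(p$value), "\"",
          if (nzchar(p$units)) paste0(" units=\"", esc(p$units), "\""),
          " constant=\"", if (p$id %in% ev_targets) "false" else "true",
          "\"/>")
    add("    </listOfParameters>")
  }
  if (length(model$rules)) {
    add("    <listOfRules>")
    for (r in model$rules) {
      el <- switch(r$kind, assignment = "assignmentRule", rate = "rateRule",
                   algebraic = "algebraicRule")
      add("      <", el,
          if (!is.null(r$target)) paste0(" variable=\"", r$target, "\""), ">")
      add("        ", .expr_to_mathml(r$expression, model$time_symbol))
      add("      </", el, ">")
    }
    add("    </listOfRules>")
  }
  if (length(model$constraints)) {
    add("    <listOfConstraints>")
    for (cn in model$constraints) {
      add("      <constraint id=\"", cn$id, "\">")
      add("        ", .expr_to_mathml(cn$condition, model$time_symbol))
      if (nzchar(cn$message))
        add("        <message><p xmlns=\"http://www.w3.org/1999/xhtml\">",
            esc(cn$message), "</p></message>")
      add("      </constraint>")
    }
    add("    </listOfConstraints>")
  }
  if (length(model$reactions)) {
    add("    <listOfReactions>")
    for (r in model$reactions) {
      add("      <reaction id=\"", r$id, "\" reversible=\"",
          if (isTRUE(r$reversible)) "true" else "false", "\"",
          if (isTRUE(r$fast)) " fast=\"true\"", ">")
      refs <- function(tag, st) {
        if (!length(st)) return()
        add("        <", tag, ">")
        for (s in names(st))
          add("          <speciesReference species=\"", s,
              "\" stoichiometry=\"", num(st[[s]]), "\" constant=\"true\"/>")
        add("        </", tag, ">")
      }
      refs("listOfReactants", r$reactants)
      refs("listOfProducts", r$products)
      if (length(r$modifiers)) {
        add("        <listOfModifiers>")
        for (s in r$modifiers)
          add("          <modifierSpeciesReference species=\"", s, "\"/>")
        add("        </listOfModifiers>")
      }
      add("        <kineticLaw>")
      add("          ", .expr_to_mathml(r$kinetic_law, model$time_symbol))
      add("        </kineticLaw>")
      add("      </reaction>")
    }
    add("    </listOfReactions>")
  }
  if (length(model$events)) {
    add("    <listOfEvents>")
    for (e in model$events) {
      add("      <event id=\"", e$id, "\" useValuesFromTriggerTime=\"",
          if (e$use_trigger_time_values) "true" else "false", "\">")
      add("        <trigger initialValue=\"false\" persistent=\"true\">")
      add("          ", .expr_to_mathml(e$trigger, model$time_symbol))
      add("        </trigger>")
      if (!identical(e$delay, 0)) {
        add("        <delay>")
        add("          ", .expr_to_mathml(
          if (is.numeric(e$delay)) e$delay else e$delay, model$time_symbol))
        add("        </delay>")
      }
      if (length(e$assignments)) {
        add("        <listOfEventAssignments>")
        for (tg in names(e$assignments)) {
          add("          <eventAssignment variable=\"", tg, "\">")
          add("            ", .expr_to_mathml(e$assignments[[tg]],
                                              model$time_symbol))
          add("          </eventAssignment>")
        }
        add("        </listOfEventAssignments>")
      }
      add("      </event>")
    }
    add("    </listOfEvents>")
  }
  add("  </model>")
  add("</sbml>")
  txt <- paste(L, collapse = "\n")
  xml2::read_xml(txt)  # well-formedness check
  if (!is.null(path)) { writeLines(txt, path); return(invisible(txt)) }
  txt
}
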