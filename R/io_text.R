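# Human-readable text format for models (one statement per line).
#
#   model name
#   compartment cell = 1
#   const k1 = 0.5            parameter
#   var A in cell = 10        variable (ode); `alg` = algebraic, `fix` = constant
#   A = 10                    auto-classified: species if A reacts, else parameter
#   J1: A + 2 B -> C; k1*A*B  reaction (`<->` reversible, `fast J1: ...` fast;
#                             `$A` marks a boundary/constant species)
#   x := expr                 assignment rule
#   x' = expr                 rate rule
#   0 = expr                  algebraic rule
#   at E1 (x < 0.5) delay 2: y = 1, z = 0      event (delay/valuesAtExecution
#                                              optional; id optional on input)
#   constraint C1 (x < 5): message text
#   module M1 ... end         modular models, plus top-level:
#   connect M1.B = M2.B master M1.B
#   connect M1.A -> M2.x factor 2
#   engine M1 = stochastic
#
# Comments start with `#` or `//`.  Parsing either yields exactly one model
# (or ModularModel) or fails with a line-numbered error.

.ID_RE <- "[A-Za-z_][A-Za-z0-9_]*"

#' Read a model from the text format
#'
#' @param source A file path, or a character vector of lines (a single string
#'   containing newlines is split).
#' @return `list(diagram=, model=)`, or a `ModularModel` when the source
#'   contains `module` blocks.
#' @export
read_text <- function(source) {
  lines <- if (length(source) == 1L && !grepl("\n", source) &&
               file.exists(source)) readLines(source, warn = FALSE)
  else unlist(strsplit(source, "\n", fixed = TRUE))
  raw <- sub("//.*$", "", sub("#.*$", "", lines))
  raw <- trimws(raw)

  perr <- function(i, ...) stop("text format, line ", i, ": ", ...,
                                call. = FALSE)

  # split into module blocks / top-level lines
  blocks <- list(); top <- integer(0)
  i <- 1L
  while (i <= length(raw)) {
    ln <- raw[[i]]
    if (grepl(paste0("^module\\s+", .ID_RE, "$"), ln)) {
      nm <- sub("^module\\s+", "", ln)
      j <- i + 1L
      while (j <= length(raw) && raw[[j]] != "end") j <- j + 1L
      if (j > length(raw)) perr(i, "module '", nm, "' has no matching 'end'")
      blocks[[nm]] <- seq(i + 1L, j - 1L)
      i <- j + 1L
    } else {
      if (nzchar(ln)) top <- c(top, i)
      i <- i + 1L
    }
  }

  if (!length(blocks)) {
    return(.parse_scope(raw, which(nzchar(raw)), perr))
  }

  # modular model: top-level lines are connect / engine / model only
  connections <- list(); engines <- character(0); name <- "modular_model"
  for (i in top) {
    ln <- raw[[i]]
    if (grepl("^model\\s+", ln)) { name <- sub("^model\\s+", "", ln); next }
    if (grepl("^engine\\s+", ln)) {
      m <- regmatches(ln, regexec(paste0(
        "^engine\\s+(", .ID_RE, ")\\s*=\\s*(ode|stochastic)$"), ln))[[1L]]
      if (!length(m)) perr(i, "malformed engine statement")
      engines[[m[[2L]]]] <- m[[3L]]
      next
    }
    if (grepl("^connect\\s+", ln)) {
      connections[[length(connections) + 1L]] <- .parse_connect(ln, i, perr)
      next
    }
    perr(i, "only 'connect', 'engine' and 'model' are allowed outside modules")
  }
  modules <- lapply(names(blocks), function(nm)
    .parse_scope(raw, blocks[[nm]][nzchar(raw[blocks[[nm]]])], perr,
                 name = nm))
  names(modules) <- names(blocks)
  compose(modules, connections,
          engines = if (length(engines)) engines)
}

#' @keywords internal
.parse_connect <- function(ln, i, perr) {
  body <- trimws(sub("^connect\\s+", "", ln))
  ep_re <- paste0(.ID_RE, "\\.", .ID_RE)
  if (grepl("->", body, fixed = TRUE)) {
    factor <- 1
    fm <- regmatches(body, regexec("\\bfactor\\s+([0-9.eE+-]+)\\s*$", body))[[1L]]
    if (length(fm)) {
      factor <- as.numeric(fm[[2L]])
      body <- trimws(sub("\\bfactor\\s+[0-9.eE+-]+\\s*$", "", body))
    }
    parts <- trimws(strsplit(body, "->", fixed = TRUE)[[1L]])
    if (length(parts) != 2L) perr(i, "malformed directed connection")
    consumers <- trimws(strsplit(parts[[2L]], ",", fixed = TRUE)[[1L]])
    eps <- c(parts[[1L]], consumers)
    if (!all(grepl(paste0("^", ep_re, "$"), eps)))
      perr(i, "connection endpoints must be module.symbol")
    connection("directed", eps, factor = factor)
  } else {
    master <- NULL
    mm <- regmatches(body, regexec(paste0("\\bmaster\\s+(", ep_re, ")\\s*$"),
                                   body))[[1L]]
    if (length(mm)) {
      master <- mm[[2L]]
      body <- trimws(sub(paste0("\\bmaster\\s+", ep_re, "\\s*$"), "", body))
    }
    eps <- trimws(strsplit(body, "=", fixed = TRUE)[[1L]])
    if (length(eps) < 2L || !all(grepl(paste0("^", ep_re, "$"), eps)))
      perr(i, "malformed undirected connection")
    connection("undirected", eps, master = master)
  }
}

# split on top-level commas (ignoring commas inside parentheses)
#' @keywords internal
.split_commas <- function(s) {
  out <- character(0); depth <- 0L; start <- 1L
  chars <- strsplit(s, "")[[1L]]
  for (k in seq_along(chars)) {
    ch <- chars[[k]]
    if (ch == "(") depth <- depth + 1L
    else if (ch == ")") depth <- depth - 1L
    else if (ch == "," && depth == 0L) {
      out <- c(out, substr(s, start, k - 1L)); start <- k + 1L
    }
  }
  trimws(c(out, substr(s, start, nchar(s))))
}

# parse one reaction side "A + 2 B" -> named stoichiometry vector;
# `$X` terms are returned in attr "boundary"
#' @keywords internal
.parse_side <- function(s, i, perr) {
  s <- trimws(s)
  out <- numeric(0); boundary <- character(0)
  if (!nzchar(s)) return(structure(out, boundary = boundary))
  for (term in trimws(strsplit(s, "+", fixed = TRUE)[[1L]])) {
    m <- regmatches(term, regexec(paste0(
      "^(?:([0-9]+(?:\\.[0-9]+)?(?:/[0-9]+)?)\\s*\\*?\\s*)?(\\$)?(",
      .ID_RE, ")$"), term, perl = TRUE))[[1L]]
    if (!length(m)) perr(i, "cannot parse species term '", term, "'")
    st <- if (nzchar(m[[2L]])) {
      if (grepl("/", m[[2L]], fixed = TRUE)) {
        pq <- as.numeric(strsplit(m[[2L]], "/", fixed = TRUE)[[1L]])
        pq[[1L]] / pq[[2L]]
      } else as.numeric(m[[2L]])
    } else 1
    sp <- m[[4L]]
    out[[sp]] <- if (is.na(out[sp])) st else out[[sp]] + st
    if (nzchar(m[[3L]])) boundary <- c(boundary, sp)
  }
  structure(out, boundary = boundary)
}

#' @keywords internal
.parse_scope <- function(raw, idx, perr, name = NULL) {
  reactions <- list(); rules <- list(); events <- list(); constraints <- list()
  init <- list()          # id -> value
  marker <- character(0)  # id -> const/var/alg/fix/compartment
  compartment_of <- character(0)
  boundary <- character(0)
  ev_n <- 0L; cn_n <- 0L
  decl_order <- character(0)
  note <- function(id) if (!(id %in% decl_order)) decl_order <<- c(decl_order, id)

  for (i in idx) {
    ln <- raw[[i]]
    if (grepl("^model\\s+", ln)) {
      if (is.null(name)) name <- sub("^model\\s+", "", ln)
      next
    }
    ## declarations with markers
    m <- regmatches(ln, regexec(paste0(
      "^(const|var|alg|fix|species|compartment)\\s+(", .ID_RE,
      ")(?:\\s+in\\s+(", .ID_RE, "))?\\s*=\\s*(\\S+)$"), ln,
      perl = TRUE))[[1L]]
    if (length(m)) {
      id <- m[[3L]]
      val <- suppressWarnings(as.numeric(m[[5L]]))
      if (is.na(val)) perr(i, "'", id, "': value is not a number")
      marker[[id]] <- if (m[[2L]] == "species") "var" else m[[2L]]
      if (nzchar(m[[4L]])) compartment_of[[id]] <- m[[4L]]
      init[[id]] <- val
      note(id)
      next
    }
    ## events
    if (grepl("^at\\b", ln)) {
      m <- regmatches(ln, regexec(paste0(
        "^at(?:\\s+(", .ID_RE, "))?\\s*\\((.*?)\\)\\s*",
        "(?:delay\\s+(\\S+)\\s*)?(valuesAtExecution\\s*)?:\\s*(.*)$"),
        ln, perl = TRUE))[[1L]]
      if (!length(m)) perr(i, "malformed event ('at (cond): x = v, ...')")
      ev_n <- ev_n + 1L
      id <- if (nzchar(m[[2L]])) m[[2L]] else paste0("E", ev_n)
      trig <- tryCatch(parse_expr(m[[3L]]),
                       error = function(e) perr(i, conditionMessage(e)))
      delay <- if (nzchar(m[[4L]])) {
        d <- suppressWarnings(as.numeric(m[[4L]]))
        if (is.na(d)) tryCatch(parse_expr(m[[4L]]),
                               error = function(e) perr(i, conditionMessage(e)))
        else d
      } else 0
      uttv <- !nzchar(m[[5L]])
      asg <- list()
      for (a in .split_commas(m[[6L]])) {
        if (!nzchar(a)) next
        am <- regmatches(a, regexec(paste0("^(", .ID_RE, ")\\s*=\\s*(.+)$"),
                                    a))[[1L]]
        if (!length(am)) perr(i, "malformed event assignment '", a, "'")
        asg[[am[[2L]]]] <- tryCatch(parse_expr(am[[3L]]),
                                    error = function(e)
                                      perr(i, conditionMessage(e)))
      }
      events[[length(events) + 1L]] <-
        mm_event(id, trig, asg, delay = delay,
                 use_trigger_time_values = uttv)
      next
    }
    ## constraints
    if (grepl("^constraint\\b", ln)) {
      m <- regmatches(ln, regexec(paste0(
        "^constraint(?:\\s+(", .ID_RE, "))?\\s*\\((.*?)\\)\\s*:\\s*(.*)$"),
        ln, perl = TRUE))[[1L]]
      if (!length(m)) perr(i, "malformed constraint")
      cn_n <- cn_n + 1L
      id <- if (nzchar(m[[2L]])) m[[2L]] else paste0("C", cn_n)
      constraints[[length(constraints) + 1L]] <-
        mm_constraint(id, tryCatch(parse_expr(m[[3L]]),
                                   error = function(e)
                                     perr(i, conditionMessage(e))),
                      message = m[[4L]])
      next
    }
    ## reactions:  [fast] ID: lhs (->|<->) rhs ; law
    m <- regmatches(ln, regexec(paste0(
      "^(fast\\s+)?(", .ID_RE, ")\\s*:\\s*([^;]*?)(<->|->)([^;]*);\\s*(.+)$"),
      ln))[[1L]]
    if (length(m)) {
      lhs <- .parse_side(m[[4L]], i, perr)
      rhs <- .parse_side(m[[6L]], i, perr)
      boundary <- c(boundary, attr(lhs, "boundary"), attr(rhs, "boundary"))
      law <- tryCatch(parse_expr(m[[7L]]),
                      error = function(e) perr(i, conditionMessage(e)))
      reactions[[length(reactions) + 1L]] <-
        mm_reaction(m[[3L]], reactants = c(unclass(lhs)),
                    products = c(unclass(rhs)),
                    kinetic_law = law, fast = nzchar(m[[2L]]),
                    reversible = m[[5L]] == "<->")
      for (s in c(names(lhs), names(rhs))) note(s)
      next
    }
    ## rules
    if (grepl("^0\\s*=", ln)) {
      rules[[length(rules) + 1L]] <-
        mm_rule("algebraic",
                expression = tryCatch(parse_expr(sub("^0\\s*=", "", ln)),
                                      error = function(e)
                                        perr(i, conditionMessage(e))))
      next
    }
    m <- regmatches(ln, regexec(paste0("^(", .ID_RE, ")'\\s*=\\s*(.+)$"),
                                ln))[[1L]]
    if (length(m)) {
      rules[[length(rules) + 1L]] <-
        mm_rule("rate", target = m[[2L]],
                expression = tryCatch(parse_expr(m[[3L]]),
                                      error = function(e)
                                        perr(i, conditionMessage(e))))
      note(m[[2L]])
      next
    }
    m <- regmatches(ln, regexec(paste0("^(", .ID_RE, ")\\s*:=\\s*(.+)$"),
                                ln))[[1L]]
    if (length(m)) {
      rules[[length(rules) + 1L]] <-
        mm_rule("assignment", target = m[[2L]],
                expression = tryCatch(parse_expr(m[[3L]]),
                                      error = function(e)
                                        perr(i, conditionMessage(e))))
      note(m[[2L]])
      next
    }
    ## bare initial value
    m <- regmatches(ln, regexec(paste0("^(", .ID_RE, ")\\s*=\\s*(\\S+)$"),
                                ln))[[1L]]
    if (length(m)) {
      val <- suppressWarnings(as.numeric(m[[3L]]))
      if (is.na(val)) perr(i, "'", m[[2L]], "': value is not a number")
      init[[m[[2L]]]] <- val
      note(m[[2L]])
      next
    }
    perr(i, paste0("cannot parse statement '", ln, "'"))
  }

  ## classification
  participants <- unique(unlist(lapply(reactions, function(r)
    c(names(r$reactants), names(r$products)))))
  rule_targets <- unique(unlist(lapply(rules, function(r) r$target)))
  asg_targets <- unique(unlist(lapply(rules, function(r)
    if (r$kind == "assignment") r$target)))
  is_var <- function(id) {
    mk <- marker[id]
    if (!is.na(mk) && mk %in% c("var", "alg", "fix")) return(TRUE)
    if (!is.na(mk)) return(FALSE)           # const / compartment
    id %in% c(participants, rule_targets)
  }
  ids <- unique(c(decl_order, participants, rule_targets))
  variables <- list(); parameters <- list()
  compartments <- character(0)
  for (id in ids) {
    mk <- marker[id]
    v0 <- init[[id]] %||% 0
    if (!is.na(mk) && mk == "compartment") {
      parameters[[length(parameters) + 1L]] <- mm_parameter(id, v0)
      compartments[[id]] <- ""
    } else if (is_var(id)) {
      dyn <- if (!is.na(mk) && mk == "alg") "algebraic"
      else if ((!is.na(mk) && mk == "fix") || id %in% boundary) "constant"
      else if (id %in% asg_targets) "assigned"
      else "ode"
      variables[[length(variables) + 1L]] <-
        mm_variable(id, v0, dynamics = dyn,
                    compartment = if (!is.na(compartment_of[id]))
                      compartment_of[[id]])
    } else {
      parameters[[length(parameters) + 1L]] <- mm_parameter(id, v0)
    }
  }
  # infer modifiers: species referenced by the law but not consumed/produced
  var_ids <- vapply(variables, `[[`, "", "id")
  reactions <- lapply(reactions, function(r) {
    r$modifiers <- setdiff(intersect(expr_symbols(r$kinetic_law), var_ids),
                           c(names(r$reactants), names(r$products)))
    r
  })
  model <- math_model(variables, parameters, reactions, rules, events,
                      constraints)
  dg <- diagram_from_model(name %||% "model", model)
  dg$compartments <- compartments
  list(diagram = dg, model = model)
}

#' Write a model in the text format
#'
#' The inverse of [read_text()]: `read_text(write_text(m))` reproduces the
#' model element-wise (same ids, stoichiometries, expression trees).
#'
#' @param x `list(diagram=, model=)`, a `MathModel`, or a `ModularModel`.
#' @param path Optional file to write.
#' @return The text, invisibly when `path` is given.
#' @export
write_text <- function(x, path = NULL) {
  txt <- if (inherits(x, "ModularModel")) {
    chunks <- character(0)
    for (nm in names(x$modules)) {
      body <- .write_scope(x$modules[[nm]]$model, x$modules[[nm]]$diagram,
                           indent = "  ")
      chunks <- c(chunks, paste0("module ", nm), body, "end", "")
    }
    for (cn in x$connections) {
      ep <- vapply(cn$endpoints, function(e) paste0(e[[1L]], ".", e[[2L]]), "")
      chunks <- c(chunks, if (cn$kind == "undirected")
        paste0("connect ", paste(ep, collapse = " = "),
               if (!is.null(cn$master))
                 paste0(" master ", cn$master[[1L]], ".", cn$master[[2L]]))
      else
        paste0("connect ", ep[[1L]], " -> ",
               paste(ep[-1L], collapse = ", "),
               if ((cn$factor %||% 1) != 1) paste0(" factor ",
                                                   format(cn$factor))))
    }
    for (nm in names(x$engines))
      if (x$engines[[nm]] != "ode")
        chunks <- c(chunks, paste0("engine ", nm, " = ", x$engines[[nm]]))
    paste(chunks, collapse = "\n")
  } else {
    model <- if (inherits(x, "MathModel")) x else x$model
    dg <- if (inherits(x, "MathModel")) NULL else x$diagram
    paste(.write_scope(model, dg), collapse = "\n")
  }
  txt <- paste0(txt, "\n")
  if (!is.null(path)) { writeLines(txt, path, sep = ""); return(invisible(txt)) }
  txt
}

#' @keywords internal
.write_scope <- function(model, dg = NULL, indent = "") {
  num <- function(v) format(v, digits = 15)
  out <- character(0)
  add <- function(s) out[[length(out) + 1L]] <<- paste0(indent, s)
  if (!is.null(dg))
    for (cid in names(dg$compartments))
      add(paste0("compartment ", cid, " = ",
                 num(model$parameters[[cid]]$value %||% 1)))
  comp_ids <- if (!is.null(dg)) names(dg$compartments) else character(0)
  for (v in model$variables) {
    kw <- switch(v$dynamics, ode = "var", assigned = "var",
                 algebraic = "alg", constant = "fix")
    add(paste0(kw, " ", v$id,
               if (!is.null(v$compartment)) paste0(" in ", v$compartment),
               " = ", num(v$initial_value)))
  }
  for (p in model$parameters)
    if (!(p$id %in% comp_ids))
      add(paste0("const ", p$id, " = ", num(p$value)))
  side <- function(st) paste(vapply(names(st), function(s)
    paste0(if (st[[s]] != 1) paste0(format(st[[s]]), " "), s), ""),
    collapse = " + ")
  for (r in model$reactions)
    add(paste0(if (isTRUE(r$fast)) "fast ", r$id, ": ", side(r$reactants),
               " ", if (isTRUE(r$reversible)) "<->" else "->", " ",
               side(r$products), "; ", expr_to_text(r$kinetic_law)))
  for (rl in model$rules)
    add(switch(rl$kind,
               assignment = paste0(rl$target, " := ",
                                   expr_to_text(rl$expression)),
               rate = paste0(rl$target, "' = ", expr_to_text(rl$expression)),
               algebraic = paste0("0 = ", expr_to_text(rl$expression))))
  for (ev in model$events) {
    has_delay <- !identical(ev$delay, 0)
    add(paste0("at ", ev$id, " (", expr_to_text(ev$trigger), ")",
               if (has_delay) paste0(" delay ",
                                     if (is.numeric(ev$delay)) num(ev$delay)
                                     else gsub(" ", "",
                                               expr_to_text(ev$delay),
                                               fixed = TRUE)),
               if (!ev$use_trigger_time_values) " valuesAtExecution",
               ": ",
               paste(vapply(names(ev$assignments), function(tg)
                 paste0(tg, " = ", expr_to_text(ev$assignments[[tg]])), ""),
                 collapse = ", ")))
  }
  for (cn in model$constraints)
    add(paste0("constraint ", cn$id, " (", expr_to_text(cn$condition), "): ",
               cn$message))
  out
}
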