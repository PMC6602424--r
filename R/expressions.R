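# Expression layer: kinetic laws, triggers, rule right-hand sides.
#
# Expressions are plain R `language` objects restricted to a fixed operator
# whitelist (a practical MathML core).  Anything outside the whitelist is
# rejected at parse/import time, never silently dropped.

.SBK_BINARY_OPS <- c("+", "-", "*", "/", "^")
.SBK_COMPARE_OPS <- c("<", "<=", ">", ">=", "==", "!=")
.SBK_BOOL_OPS <- c("&", "|", "&&", "||", "!")
.SBK_FUNS <- c("exp", "ln", "log", "log10", "min", "max", "abs", "piecewise",
               "sqrt", "floor", "ceiling")

#' Parse an expression from text
#'
#' Parses a mathematical expression in the kernel's grammar: arithmetic
#' (`+ - * / ^`), `exp`, `ln`, `log10`, `min`, `max`, `abs`, `sqrt`,
#' `piecewise(value1, condition1, ..., otherwise)`, comparison and boolean
#' operators, numeric literals and symbols.
#'
#' @param text A single string.
#' @return A quoted expression (R language object).
#' @export
parse_expr <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  e <- tryCatch(str2lang(text),
                error = function(err) stop("expression syntax error in '", text,
                                           "': ", conditionMessage(err),
                                           call. = FALSE))
  check_expr(e)
  strip_parens(e)
}

# normalize an AST by removing explicit parenthesis calls; deparse re-inserts
# the parentheses needed for printing, so this is loss-free
#' @keywords internal
strip_parens <- function(e) {
  if (is.call(e)) {
    if (identical(e[[1L]], as.symbol("("))) return(strip_parens(e[[2L]]))
    for (i in seq_along(e)[-1L]) e[[i]] <- strip_parens(e[[i]])
  }
  e
}

#' @keywords internal
check_expr <- function(e) {
  if (is.numeric(e) || is.logical(e) || is.symbol(e)) return(invisible(TRUE))
  if (is.call(e)) {
    op <- as.character(e[[1L]])
    if (op == "(") return(check_expr(e[[2L]]))
    allowed <- c(.SBK_BINARY_OPS, .SBK_COMPARE_OPS, .SBK_BOOL_OPS, .SBK_FUNS)
    if (!(op %in% allowed))
      stop("unsupported operator or function '", op, "' in expression: ",
           expr_to_text(e), call. = FALSE)
    for (i in seq_along(e)[-1L]) check_expr(e[[i]])
    return(invisible(TRUE))
  }
  stop("unsupported expression element: ", deparse(e), call. = FALSE)
}

#' Deparse an expression to text
#' @param e A quoted expression.
#' @return A single string.
#' @export
expr_to_text <- function(e) paste(deparse(e, width.cutoff = 500L), collapse = " ")

#' Free symbols of an expression
#'
#' @param e A quoted expression.
#' @return Character vector of symbol names (functions excluded).
#' @export
expr_symbols <- function(e) {
  syms <- character(0)
  walk <- function(x) {
    if (is.symbol(x)) {
      syms[[length(syms) + 1L]] <<- as.character(x)
    } else if (is.call(x)) {
      for (i in seq_along(x)[-1L]) walk(x[[i]])
    }
  }
  walk(e)
  unique(syms)
}

# piecewise(v1, c1, v2, c2, ..., [otherwise]); first true condition wins.
#' Piecewise selection
#'
#' `piecewise(v1, c1, v2, c2, ..., otherwise)` returns the first value whose
#' condition is true, the trailing `otherwise` if none is, and `NaN` when no
#' condition holds and no otherwise is given.
#' @param ... Alternating value/condition arguments, optional trailing default.
#' @export
piecewise <- function(...) {
  args <- list(...)
  n <- length(args)
  npairs <- n %/% 2L
  for (i in seq_len(npairs)) {
    if (isTRUE(args[[2L * i]])) return(args[[2L * i - 1L]])
  }
  if (n %% 2L == 1L) args[[n]] else NaN
}

# natural log alias used by both I/O formats
#' @rdname piecewise
#' @param x numeric
#' @export
ln <- function(x) log(x)

#' Evaluate an expression in an environment of symbol bindings
#'
#' Pure evaluation: the same bindings always give the same value.  Unbound
#' symbols, division by zero and logs of non-positive numbers raise errors
#' naming the offending subexpression.
#'
#' @param e Quoted expression (or number).
#' @param env Named list or environment mapping symbols to finite numerics.
#' @return A numeric or logical scalar.
#' @export
evaluate_expr <- function(e, env = list()) {
  if (is.list(env)) env <- list2env(env, parent = .sbk_eval_parent())
  else if (is.environment(env) &&
           !identical(parent.env(env), .sbk_eval_parent())) {
    # caller-supplied environment: keep it, but make helpers reachable
    env <- list2env(as.list(env), parent = .sbk_eval_parent())
  }
  free <- expr_symbols(e)
  missing <- free[!vapply(free, exists, logical(1), envir = env)]
  if (length(missing))
    stop("unbound symbol(s) in expression '", expr_to_text(e), "': ",
         paste(missing, collapse = ", "), call. = FALSE)
  val <- suppressWarnings(eval(e, env))
  if (is.numeric(val) && !all(is.finite(val)))
    stop("evaluation error: '", expr_to_text(e),
         "' is not finite (division by zero or log of a non-positive number?)",
         call. = FALSE)
  val
}

.sbk_eval_env <- new.env(parent = baseenv())

.sbk_eval_parent <- function() {
  if (!exists("piecewise", envir = .sbk_eval_env, inherits = FALSE)) {
    assign("piecewise", piecewise, envir = .sbk_eval_env)
    assign("ln", ln, envir = .sbk_eval_env)
  }
  .sbk_eval_env
}

#' Convert a boolean expression to an equivalent numeric expression
#'
#' Encodes booleans as 0/1: a comparison `a < b` becomes
#' `piecewise(1, a < b, 0)`, `and` becomes a product, `or` a saturating sum
#' (`min(x + y, 1)`), `not` becomes `1 - x`.  On every environment the numeric
#' form evaluates to 1 exactly when the boolean form is true.
#'
#' @param e Quoted expression.
#' @return Quoted numeric-valued expression.
#' @export
boolean_to_numeric <- function(e) {
  if (isTRUE(e)) return(1)
  if (isFALSE(e)) return(0)
  if (!is.call(e)) return(e)
  op <- as.character(e[[1L]])
  if (op == "(") return(boolean_to_numeric(e[[2L]]))
  if (op %in% .SBK_COMPARE_OPS)
    return(as.call(list(quote(piecewise), 1, e, 0)))
  if (op %in% c("&", "&&")) {
    a <- boolean_to_numeric(e[[2L]]); b <- boolean_to_numeric(e[[3L]])
    return(call("*", a, b))
  }
  if (op %in% c("|", "||")) {
    a <- boolean_to_numeric(e[[2L]]); b <- boolean_to_numeric(e[[3L]])
    return(call("min", call("+", a, b), 1))
  }
  if (op == "!")
    return(call("-", 1, boolean_to_numeric(e[[2L]])))
  # non-boolean call: recurse into arguments (e.g. piecewise conditions stay)
  out <- e
  for (i in seq_along(e)[-1L]) out[[i]] <- boolean_to_numeric(e[[i]])
  out
}

# Continuous margin of a boolean trigger: positive iff the trigger is true,
# crosses zero where the trigger flips.  Used for event root location.
#' @keywords internal
trigger_margin_expr <- function(e) {
  if (isTRUE(e)) return(1)
  if (isFALSE(e)) return(-1)
  if (!is.call(e)) stop("trigger is not a boolean expression: ", deparse(e))
  op <- as.character(e[[1L]])
  if (op == "(") return(trigger_margin_expr(e[[2L]]))
  if (op %in% c("<", "<=")) return(call("-", e[[3L]], e[[2L]]))
  if (op %in% c(">", ">=")) return(call("-", e[[2L]], e[[3L]]))
  if (op == "==") return(call("-", 0, call("abs", call("-", e[[2L]], e[[3L]]))))
  if (op == "!=") return(call("abs", call("-", e[[2L]], e[[3L]])))
  if (op %in% c("&", "&&"))
    return(call("min", trigger_margin_expr(e[[2L]]), trigger_margin_expr(e[[3L]])))
  if (op %in% c("|", "||"))
    return(call("max", trigger_margin_expr(e[[2L]]), trigger_margin_expr(e[[3L]])))
  if (op == "!") return(call("-", 0, trigger_margin_expr(e[[2L]])))
  stop("trigger is not a boolean expression: ", expr_to_text(e), call. = FALSE)
}

# Substitute symbols by expressions throughout an AST.
#' @keywords internal
substitute_symbols <- function(e, map) {
  if (is.symbol(e)) {
    nm <- as.character(e)
    if (!is.null(map[[nm]])) return(map[[nm]])
    return(e)
  }
  if (is.call(e)) {
    for (i in seq_along(e)[-1L]) e[[i]] <- substitute_symbols(e[[i]], map)
    return(e)
  }
  e
}

# TRUE when two expressions are structurally equal after removing parentheses.
#' @keywords internal
expr_equal <- function(a, b) {
  strip <- function(x) {
    if (is.call(x) && identical(x[[1L]], as.symbol("("))) return(strip(x[[2L]]))
    if (is.call(x)) for (i in seq_along(x)[-1L]) x[[i]] <- strip(x[[i]])
    x
  }
  identical(strip(a), strip(b))
}
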