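# Structural and steady-state analyses: stoichiometric relations, exact
# mass-conservation decomposition (N = L N_R), steady-state sensitivities via
# the implicit-function theorem on the reduced system, and metabolic control
# analysis.  Structural computations are exact (rational elimination);
# derivatives are central finite differences.

#' Stoichiometric analysis
#'
#' Returns the stoichiometric matrix and the linear relations between species
#' derivatives and reaction fluxes, `dx/dt = N v`, as symbolic records.
#'
#' @param model A `MathModel` describing a pure reaction network (no rate
#'   rules on reacting species).
#' @return `list(N=, relations=)`; `relations` is a named list mapping each
#'   species to a data frame with columns `flux` and `coefficient`, plus a
#'   `text` attribute with the printed equation.
#' @export
stoichiometric_analysis <- function(model) {
  .check_pure_network(model)
  N <- stoich_matrix(model)
  relations <- list()
  for (s in rownames(N)) {
    js <- which(N[s, ] != 0)
    rel <- data.frame(flux = colnames(N)[js], coefficient = N[s, js],
                      stringsAsFactors = FALSE)
    txt <- if (nrow(rel) == 0) paste0("d", s, "/dt = 0") else
      paste0("d", s, "/dt = ",
             paste(vapply(seq_len(nrow(rel)), function(k) {
               cf <- rel$coefficient[k]
               paste0(if (cf < 0) "-" else "+",
                      if (abs(cf) != 1) paste0(abs(cf), "*") else "",
                      rel$flux[k])
             }, ""), collapse = " "))
    attr(rel, "text") <- txt
    relations[[s]] <- rel
  }
  list(N = N, relations = relations)
}

#' @keywords internal
.check_pure_network <- function(model) {
  rate_targets <- unlist(lapply(model$rules, function(r)
    if (r$kind == "rate") r$target else NULL)) %||% character(0)
  for (r in model$reactions) {
    bad <- intersect(c(names(r$reactants), names(r$products)), rate_targets)
    if (length(bad))
      stop("structure error: species '", bad[[1L]],
           "' is governed by both reactions and a rate rule", call. = FALSE)
  }
  invisible(TRUE)
}

# integer-scaled basis of the left null space of N (rows are conservation
# vectors m with m^T N = 0), via exact rational elimination
#' @keywords internal
left_null_basis <- function(N) {
  S <- nrow(N)
  indep <- integer(0)
  dep <- integer(0)
  for (i in seq_len(S)) {
    cand <- N[c(indep, i), , drop = FALSE]
    if (rat_eliminate(cand)$rank > length(indep)) indep <- c(indep, i)
    else dep <- c(dep, i)
  }
  if (!length(dep))
    return(matrix(0, 0, S, dimnames = list(NULL, rownames(N))))
  out <- matrix(0, length(dep), S, dimnames = list(NULL, rownames(N)))
  NR <- N[indep, , drop = FALSE]
  for (k in seq_along(dep)) {
    d <- dep[[k]]
    cf <- rat_solve(t(NR), as.numeric(N[d, ]))
    m <- numeric(S)
    m[indep] <- -cf
    m[d] <- 1
    r <- .to_rational(m)
    out[k, ] <- integer_scale(r$num, r$den)
  }
  out
}

#' Mass-conservation decomposition
#'
#' Decomposes the stoichiometric matrix into its linearly independent rows and
#' a link matrix, `N = L N_R`, in exact rational arithmetic, and returns the
#' integer-scaled conservation vectors (left null-space basis) together with
#' the independent/dependent species partition.  Species are processed in
#' declaration order, so the partition is deterministic.
#'
#' @param model A `MathModel` (pure reaction network).
#' @return A `ConservationDecomposition`: list with `N`, `N_R`, `L`
#'   (`N = L %*% N_R` exactly), `conservation` (matrix, one vector per row),
#'   `independent`, `dependent` (species ids).
#' @export
conservation_analysis <- function(model) {
  .check_pure_network(model)
  N <- stoich_matrix(model)
  S <- nrow(N)
  indep <- integer(0); dep <- integer(0)
  for (i in seq_len(S)) {
    if (rat_eliminate(N[c(indep, i), , drop = FALSE])$rank > length(indep))
      indep <- c(indep, i)
    else dep <- c(dep, i)
  }
  NR <- N[indep, , drop = FALSE]
  L <- matrix(0, S, length(indep),
              dimnames = list(rownames(N), rownames(N)[indep]))
  for (k in seq_along(indep)) L[indep[[k]], k] <- 1
  cons <- matrix(0, length(dep), S, dimnames = list(NULL, rownames(N)))
  for (k in seq_along(dep)) {
    d <- dep[[k]]
    cf <- rat_solve(t(NR), as.numeric(N[d, ]))
    L[d, ] <- cf
    m <- numeric(S); m[indep] <- -cf; m[d] <- 1
    r <- .to_rational(m)
    cons[k, ] <- integer_scale(r$num, r$den)
  }
  structure(list(N = N, N_R = NR, L = L, conservation = cons,
                 independent = rownames(N)[indep],
                 dependent = rownames(N)[dep]),
            class = "ConservationDecomposition")
}

#' @export
print.ConservationDecomposition <- function(x, ...) {
  cat("ConservationDecomposition: rank", nrow(x$N_R), "of",
      nrow(x$N), "species;", nrow(x$conservation), "conservation vector(s)\n")
  invisible(x)
}

# central-difference step
.fd_step <- function(v) max(1e-6, 1e-6 * abs(v))

# unscaled elasticity matrix d v_i / d x_j over the N species, by central
# differences at (x*, p)
#' @keywords internal
elasticity_unscaled <- function(sys, xstar, p, species) {
  t0 <- 0
  R <- length(sys$reaction_ids)
  E <- matrix(0, R, length(species),
              dimnames = list(sys$reaction_ids, species))
  for (s in species) {
    h <- .fd_step(xstar[[s]])
    xp <- xstar; xp[[s]] <- xp[[s]] + h
    xm <- xstar; xm[[s]] <- xm[[s]] - h
    E[, s] <- (sys$rates(t0, xp, p) - sys$rates(t0, xm, p)) / (2 * h)
  }
  E
}

#' Steady-state sensitivity analysis
#'
#' Sensitivities of the steady state with respect to parameters via the
#' implicit-function relation on the conservation-reduced system:
#' `d x*/d p = -J_R^{-1} dF_R/dp`, lifted back through the link matrix.
#' Derivatives are central finite differences with step
#' `max(1e-6, 1e-6 |p|)`.
#'
#' @param model A `MathModel` or `CompiledSystem`.
#' @param xstar Named steady-state vector (full layout); see
#'   [steady_state()].
#' @param parameters Character vector of parameter ids.
#' @param p0 Optional named parameter overrides (the values at which the
#'   steady state was computed).
#' @return Matrix (species x parameters) of `d x*/d p`.
#' @export
steady_state_sensitivity <- function(model, xstar, parameters, p0 = NULL) {
  sys <- if (inherits(model, "CompiledSystem")) model else
    compile_system(NULL, model, "ode")
  cons <- conservation_analysis(sys$model)
  species <- rownames(cons$N)
  indep <- cons$independent
  L <- cons$L
  p <- sys$p0
  if (!is.null(p0)) p[names(p0)] <- p0
  f_indep <- function(x, p) sys$rhs(0, x, p)[match(indep, sys$layout)]

  # reduced Jacobian d f_I / d x_I with dependents following through L
  JR <- matrix(0, length(indep), length(indep),
               dimnames = list(indep, indep))
  for (k in seq_along(indep)) {
    s <- indep[[k]]
    h <- .fd_step(xstar[[s]])
    shift <- function(sgn) {
      x <- xstar
      dx <- numeric(length(species)); names(dx) <- species
      dx[indep[k]] <- sgn * h
      x[species] <- x[species] + as.numeric(L %*% dx[indep])
      x
    }
    JR[, k] <- (f_indep(shift(1), p) - f_indep(shift(-1), p)) / (2 * h)
  }
  sens <- matrix(0, length(species), length(parameters),
                 dimnames = list(species, parameters))
  for (pm in parameters) {
    if (!(pm %in% names(p))) next   # absent parameter: zero column
    h <- .fd_step(p[[pm]])
    pp <- p; pp[[pm]] <- pp[[pm]] + h
    pmn <- p; pmn[[pm]] <- pmn[[pm]] - h
    dF <- (f_indep(xstar, pp) - f_indep(xstar, pmn)) / (2 * h)
    dI <- tryCatch(solve(JR, -dF), error = function(e)
      stop("singularity error: reduced Jacobian is singular", call. = FALSE))
    sens[, pm] <- as.numeric(L %*% dI)
  }
  sens
}

#' Metabolic control analysis
#'
#' Computes scaled elasticities, flux control coefficients and concentration
#' control coefficients at a steady state, from the standard matrix relations
#' on the conservation-reduced system.  The summation theorems (rows of
#' `C^J` sum to 1, rows of `C^S` sum to 0) are asserted to 1e-6 before the
#' report is returned.
#'
#' @param model A `MathModel` or `CompiledSystem`.
#' @param xstar Named steady-state vector; see [steady_state()].
#' @param unscaled Also return the unscaled matrices.
#' @param p0 Optional named parameter overrides.
#' @return An `McaReport`: list with `elasticities` (reaction x species,
#'   scaled), `flux_control` (flux x reaction), `conc_control`
#'   (species x reaction), `steady_state`, `fluxes`.
#' @export
mca <- function(model, xstar, unscaled = FALSE, p0 = NULL) {
  sys <- if (inherits(model, "CompiledSystem")) model else
    compile_system(NULL, model, "ode")
  cons <- conservation_analysis(sys$model)
  species <- rownames(cons$N)
  p <- sys$p0
  if (!is.null(p0)) p[names(p0)] <- p0
  v <- sys$rates(0, xstar, p)
  names(v) <- sys$reaction_ids
  zero <- which(abs(v) < 1e-12)
  if (length(zero))
    stop("undefined-scaling error: zero steady-state flux through reaction '",
         sys$reaction_ids[zero[1L]], "'", call. = FALSE)

  Eu <- elasticity_unscaled(sys, xstar, p, species)        # R x S
  NR <- cons$N_R; L <- cons$L
  M <- NR %*% Eu %*% L                                     # reduced Jacobian
  Gamma <- tryCatch(-L %*% solve(M, NR), error = function(e)
    stop("singularity error: reduced Jacobian is singular at the steady state",
         call. = FALSE))                                   # S x R, unscaled
  CJu <- diag(length(v)) + Eu %*% Gamma                    # R x R, unscaled
  xs <- xstar[species]
  Dv <- diag(v, nrow = length(v))
  Dvi <- diag(1 / v, nrow = length(v))
  CJ <- Dvi %*% CJu %*% Dv
  CS <- diag(1 / xs, nrow = length(xs)) %*% Gamma %*% Dv
  eps <- Dvi %*% Eu %*% diag(xs, nrow = length(xs))
  dimnames(CJ) <- list(sys$reaction_ids, sys$reaction_ids)
  dimnames(CS) <- list(species, sys$reaction_ids)
  dimnames(eps) <- list(sys$reaction_ids, species)

  if (max(abs(rowSums(CJ) - 1)) > 1e-6)
    stop("flux control summation theorem violated (max deviation ",
         format(max(abs(rowSums(CJ) - 1))), ")", call. = FALSE)
  if (nrow(CS) && max(abs(rowSums(CS))) > 1e-6)
    stop("concentration control summation theorem violated (max deviation ",
         format(max(abs(rowSums(CS)))), ")", call. = FALSE)

  out <- list(elasticities = eps, flux_control = CJ, conc_control = CS,
              steady_state = xs, fluxes = v)
  if (unscaled)
    out <- c(out, list(elasticities_unscaled = Eu, flux_control_unscaled = CJu,
                       conc_control_unscaled = Gamma))
  structure(out, class = "McaReport")
}

#' @export
print.McaReport <- function(x, ...) {
  cat("McaReport at steady state\nFlux control coefficients:\n")
  print(round(x$flux_control, 6))
  invisible(x)
}

#' Export an analysis report as CSV matrices and JSON
#'
#' @param report An `McaReport` or `ConservationDecomposition`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @export
write_report <- function(report, dir = ".", prefix = "report") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mats <- Filter(is.matrix, report)
  for (nm in names(mats))
    utils::write.csv(mats[[nm]], file.path(dir, paste0(prefix, "_", nm, ".csv")))
  jsonlite::write_json(lapply(report, function(x)
    if (is.matrix(x)) as.data.frame(x) else x),
    file.path(dir, paste0(prefix, ".json")), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
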