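# Deterministic fixture models: a canonical catalogue (stored as
# human-readable text-format files under inst/extdata/catalogue, the single
# source of truth parsed by read_text) and a seeded random mass-action
# network generator, so every engine and analysis is testable without any
# external download.

#' Names of the canonical fixture models
#' @export
canonical_names <- function() {
  dir <- system.file("extdata", "catalogue", package = "sbkernel")
  sort(sub("\\.txt$", "", list.files(dir, pattern = "\\.txt$")))
}

#' Load a canonical fixture model
#'
#' The catalogue covers the standard textbook systems used throughout the
#' test-suite: `decay` (first-order decay), `logistic`, `two_step_pathway`
#' (linear pathway with closed-form steady state), `enzyme_mm`
#' (mass-action enzyme mechanism), `robertson` (classic stiff system),
#' `dimerization` (stochastic dimerization with explicit combinatorial
#' propensities), `immigration_death` (birth-death process),
#' `decay_chain` and its modular split `decay_chain_modular`,
#' `event_demo`, `constraint_demo` and `fast_equilibrium_demo`.
#'
#' @param name Catalogue name.
#' @return `list(diagram=, model=)`, or a `ModularModel` for modular entries.
#' @export
canonical <- function(name) {
  path <- system.file("extdata", "catalogue", paste0(name, ".txt"),
                      package = "sbkernel")
  if (!nzchar(path))
    stop("unknown fixture '", name, "'; available: ",
         paste(canonical_names(), collapse = ", "), call. = FALSE)
  read_text(path)
}

#' Generate a random mass-action network
#'
#' Connected mass-action reaction network with stoichiometries in \{1, 2\},
#' rate constants log-uniform on [0.1, 10] and no autocatalysis (a species
#' never appears on both sides of one reaction), so states stay nonnegative
#' for mass-action dynamics.  Deterministic under the seed.
#'
#' @param n_species,n_reactions Sizes (both at least 1).
#' @param seed RNG seed.
#' @return `list(diagram=, model=)`.
#' @export
random_mass_action <- function(n_species, n_reactions, seed = 1L) {
  if (n_species < 1L || n_reactions < 1L)
    stop("n_species and n_reactions must be at least 1", call. = FALSE)
  set.seed(seed)
  sp <- paste0("S", seq_len(n_species))
  pick <- function(pool, k, prefer = character(0)) {
    # favour not-yet-used species so the network touches everything
    pool2 <- c(intersect(prefer, pool), setdiff(pool, prefer))
    w <- c(rep(3, length(intersect(prefer, pool))),
           rep(1, length(setdiff(pool, prefer))))
    pool2[sample.int(length(pool2), k, prob = w)]
  }
  used <- character(0)
  unused <- sp
  reactions <- list()
  rate_ids <- character(0)
  for (j in seq_len(n_reactions)) {
    # at least one reactant from the already-connected component (after the
    # first reaction), preferring unused species elsewhere
    anchor <- if (length(used)) sample(used, 1L) else sample(sp, 1L)
    kind <- sample.int(5L, 1L)
    others <- setdiff(sp, anchor)
    reactants <- switch(kind,
      stats::setNames(1, anchor),                       # A -> ...
      stats::setNames(1, anchor),
      stats::setNames(2, anchor),                       # 2A -> ...
      if (length(others)) stats::setNames(c(1, 1), c(anchor,
        pick(others, 1L, unused))) else stats::setNames(1, anchor),
      stats::setNames(1, anchor))
    pool <- setdiff(sp, names(reactants))
    products <- if (!length(pool)) numeric(0) else switch(kind,
      stats::setNames(1, pick(pool, 1L, unused)),
      if (length(pool) >= 2L)
        stats::setNames(c(1, 1), pick(pool, 2L, unused))
      else stats::setNames(1, pool),
      stats::setNames(1, pick(pool, 1L, unused)),
      stats::setNames(1, pick(pool, 1L, unused)),
      numeric(0))                                        # A -> (sink)
    kid <- paste0("k", j)
    rate_ids <- c(rate_ids, kid)
    law <- NULL
    for (s in names(reactants)) {
      term <- if (reactants[[s]] == 2) call("^", as.symbol(s), 2)
      else as.symbol(s)
      law <- if (is.null(law)) term else call("*", law, term)
    }
    law <- if (is.null(law)) as.symbol(kid) else call("*", as.symbol(kid), law)
    reactions[[j]] <- mm_reaction(paste0("R", j), reactants, products,
                                  kinetic_law = law)
    used <- unique(c(used, names(reactants), names(products)))
    unused <- setdiff(sp, used)
  }
  kvals <- exp(stats::runif(n_reactions, log(0.1), log(10)))
  variables <- lapply(sp, function(s) mm_variable(s, 10))
  parameters <- lapply(seq_len(n_reactions), function(j)
    mm_parameter(rate_ids[[j]], kvals[[j]]))
  model <- math_model(variables, parameters, reactions)
  dg <- diagram_from_model(paste0("random_", seed), model)
  diags <- validate_model(dg, model)
  if (length(diags))
    stop("random network generation produced an invalid model: ",
         paste(diags, collapse = "; "), call. = FALSE)
  list(diagram = dg, model = model)
}
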