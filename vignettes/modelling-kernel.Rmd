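---
title: "A reaction-network modelling kernel: models, engines and analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A reaction-network modelling kernel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sbkernel)
```

## The model representation

`sbkernel` holds a biochemical model in two coupled layers.  The *diagram*
is a compartmentalized attributed graph: species, reaction, compartment,
module and port nodes joined by reactant/product/modifier edges, with
free-form annotation strings standing in for database cross-references.
The *mathematical model* is the executable overlay: variables (amounts),
parameters, reactions with kinetic-law expressions, assignment/rate/algebraic
rules, discrete events and constraints.  `validate_model()` checks every
structural invariant (unique ids, acyclic compartment nesting, symbol
resolution, one rule per variable, boolean triggers, finite initial values)
and returns diagnostics rather than throwing, so a user interface or script
can report all problems at once.

Expressions are abstract syntax trees over a fixed operator whitelist —
arithmetic, `exp`/`ln`/`log10`/`sqrt`, `min`/`max`/`abs`, `piecewise`,
comparisons and boolean connectives.  Anything outside the whitelist is
rejected at parse or import time; nothing is dropped silently.  `piecewise`
selects the first true branch, matching the MathML convention.

**Amounts, not concentrations.**  The canonical state of every species is an
amount.  Species initialized by concentration in SBML are converted through
their compartment size at import, and compartment sizes are ordinary
constant parameters thereafter.  One canonical form lets the deterministic
and stochastic engines share a single state layout; the cost is that this
subset does not model dynamically resized compartments.

## File formats

The SBML reader/writer covers a Level 3 core subset: compartments
(constant), species, parameters, reactions with MathML-core kinetic laws and
local parameters, rules, initial assignments (folded into initial values at
load), events and constraints.  Extension packages (`comp`, `fbc`, ...),
function definitions, event priorities and MathML outside the whitelist
raise an import error listing each offending element.  Hierarchical
composition is deliberately expressed only in the text format, which keeps
the XML surface small while leaving modular semantics fully testable.

The bundled text format is a line-oriented, human-readable language
(`J1: A + 2 B -> C; k1*A*B`, `x' = ...`, `at E1 (A <= 0.5): y = 1`,
`module ... end`, `connect M1.B = M2.B master M1.B`).  Both formats satisfy
the same contract: writing and re-reading reproduces the model element-wise
(ids, stoichiometries, expression trees), and the test-suite enforces this
over the whole fixture catalogue, in both formats and across them.

## Compilation and preprocessing

`compile_system()` turns a flat model into executable code: it generates,
parses and byte-compiles plain R functions for the right-hand side, the
reaction-rate/propensity vector, the assigned-variable observer, event
triggers and margins, and algebraic residuals.  For a pure reaction network
the generated right-hand side is exactly `N %*% v(x, t)` with the
stoichiometric matrix `N`; state and parameter layouts follow declaration
order and are deterministic, so two compilations of the same model are
interchangeable.

Preprocessors bring a model into the form an engine expects:

* `constraints_to_events()` replaces each constraint by an event whose
  trigger is the negated condition and whose action halts the simulation,
  carrying the constraint message.
* `fast_to_algebraic()` treats reactions flagged *fast* as being at
  quasi-equilibrium.  Support is restricted to reversible mass action
  (kinetic law of the form `forward - backward`), the one case with a
  well-defined closed algebraic form: the reaction becomes the residual
  `law = 0`, its species become algebraic variables, and each conserved pool
  of the fast subnetwork gains a total variable whose rate rule sums the
  slow reactions' net inflow.
* `boolean_to_numeric()` encodes booleans as 0/1 (products for *and*,
  saturating sums for *or*, `1 - x` for *not*), verified equivalent to the
  boolean form by a randomized property test.
* `flatten()` resolves a modular model into a single namespace
  (`module__symbol`; collisions are errors, never silent renames).
  Undirected connections merge the connected variables into one — the
  designated master supplies the identity and initial value, and a master is
  required whenever more than one endpoint is actively integrated, because
  nothing in the model says which initial value should win otherwise.
  Directed connections delete the consumer variable and rewrite its symbol
  to `factor * producer`.

## Deterministic engines

Three solvers sit behind one contract.  Fixed-step Euler and an adaptive
embedded Dormand–Prince pair (with the classical fifth-order dense-output
polynomial) are implemented in the package; the stiff variable-order
multistep route delegates the integrator core to `deSolve`'s
`lsodar`/`lsoda` (the Adams-Moulton/BDF family), while event location and
restart semantics remain the kernel's own.  Re-deriving a Butcher tableau or
a BDF implementation would add risk without adding science; the engine
architecture — preprocessing, code generation, event handling — is the
contribution here.

Events fire on the false-to-true transition of their trigger; triggers
already true at the initial time do not fire.  Transitions are detected on
the continuous solution and located by bisection to 1e-9 time units, the
assignments applied (optionally after a delay, with values captured at
trigger or at execution time), and integration restarted.  Simultaneous
events fire in declaration order, and events raised by other events'
assignments cascade within the same time point (bounded at 100 rounds).
Output values always come from dense interpolation of accepted steps —
integration steps are never forced onto the output grid, so the output grid
cannot perturb the solution.

Algebraic variables (from algebraic rules or the fast-reaction
transformation) are solved by a damped Newton iteration inside every
right-hand-side evaluation and at every output point — an index-1
projection approach that is entirely adequate at the scale of the supported
transformation, and deliberately far short of general DAE index reduction.

`steady_state()` runs a damped Newton iteration with finite-difference
Jacobian on the conservation-respecting system: each conserved pool replaces
a redundant balance row with `m . x = m . x0`, which keeps the Jacobian
nonsingular for closed networks.  If Newton stalls it integrates towards
the attractor (time horizons growing from 100 by factors of 100) and
polishes; failure of both routes is a convergence error carrying the
residual.

## Stochastic engines

The reaction network is interpreted as a continuous-time Markov chain whose
hazards are the kinetic laws *verbatim*: the kernel applies no combinatorial
rescaling (`k*A*(A-1)/2` versus `k*A^2`), because silently rewriting a
user's propensity is a correctness trap; the fixture catalogue states its
propensities explicitly.  Three methods are provided: Gillespie's direct
method; the Gibson–Bruck next-reaction method with a reaction dependency
graph and an indexed priority queue (binary heap) of tentative firing
times, rescaled on propensity change, so a step costs O(log R + degree);
and fixed-step tau-leaping with Poisson increments and reject-and-halve
handling of would-be-negative states.  Adaptive tau selection and hybrid
partitioning are out of scope.

Replicates run on per-replicate child streams: the master seed draws one
child seed per replicate, so ensembles are bit-reproducible under a fixed
seed and replicates are independent by construction.  Grid output is
last-value-carried-forward, the natural sampling of a jump process.

## Modular models and the scheduler

Beyond flattening, a modular model can be co-simulated: `simulate_agents()`
advances time in exchange windows of length `h_ex`.  Within a window each
module integrates independently with its own engine, holding incoming
connected values constant (zero-order hold — the coupling error is first
order in `h_ex`, which the tests verify by comparing against the flattened
model at three step sizes).  At a boundary the scheduler reconciles each
shared variable by summing the modules' increments — a choice that makes
quantities conserved in the flattened model exactly conserved at boundary
times — and pushes producer values to consumers in topological order of the
directed connections, ties broken by module name, so the update order is
deterministic.  A real-valued value pushed into a stochastic module is
floored with the remainder carried to the next boundary, preserving flux on
average.  The exchange grid is fixed rather than adaptive; that is the
documented choice, and the step-size study quantifies its cost.

## Parameter estimation

`fit_objective()` sums weighted squared residuals over experiments.
Relative (scale-free) observations are compared after the closed-form
least-squares scale per experiment and symbol — profiling the scale out
analytically keeps the search space small, which is why a free scale
parameter was rejected.  Steady-state experiments are compared at the
computed steady state.  A failed simulation scores `+Inf`, so optimizers
simply rank such candidates last.  Residuals are summed raw across
experiments of different sizes; re-weighting by experiment size is the
user's decision via the weight columns, not the kernel's.

Two global optimizers are implemented in full:

* `fit_sres()` — a (mu, lambda) evolution strategy with log-normal
  self-adaptive step sizes and the stochastic-ranking bubble sort: pairs
  with a bound violation are ordered by objective with probability
  `pf = 0.45`, by violation otherwise.  Defaults `mu = 15`,
  `lambda = 7 mu` follow the common literature settings.
* `fit_pso()` — global-best particle swarm with inertia `w = 0.72` and
  acceleration coefficients `c1 = c2 = 1.49`, velocity clamped to the box
  width, reflection at the bounds.

Both are deterministic under a fixed seed, keep a monotone best-so-far
trace, re-evaluate the reported best (so the stored objective is never a
stale cache), and with `generations = 0` / `iterations = 0` return the best
of the initial population after exactly `lambda` (swarm-size) evaluations.
The objective is a pure function of the parameter vector, so evaluations
within a generation may be computed in any order — the sequential loop here
is an implementation choice, not a semantic one.

## Structural and steady-state analyses

All structural computations run in exact rational arithmetic (an in-package
fraction-matrix elimination): `conservation_analysis()` returns the
decomposition `N = L N_R` *exactly*, the integer-scaled conservation vectors
(left null-space basis) and the deterministic independent/dependent species
partition, with species processed in declaration order.  Exactness matters
because the conservation invariant `m . x(t) = const` is asserted to 1e-6
along simulated trajectories, including on randomly generated mass-action
networks, and a floating-point basis would turn that sharp test to mush.

`steady_state_sensitivity()` applies the implicit-function theorem on the
reduced system, `d x*/d p = -J_R^{-1} dF_R/dp`, lifted back through `L`;
derivatives are central differences with step `max(1e-6, 1e-6 |p|)`.
Forward-sensitivity ODEs would be the alternative; central differences on
the steady-state equations are simpler, and accurate to the 1e-4 the control
coefficients are checked at.  `mca()` computes scaled elasticities and the
flux/concentration control matrices from the standard reduced-system
relations and *asserts the summation theorems* (rows of `C^J` sum to 1,
rows of `C^S` to 0, both to 1e-6) before returning — a report that violates
the theorems is an error, not a result.  Scaled (logarithmic) form is the
default; `unscaled = TRUE` adds the raw matrices.

## Fixtures: what the generator emulates, and what it does not

The canonical catalogue lives as text-format files under
`inst/extdata/catalogue/` — one human-readable source of truth that the
package itself parses — and covers the closed-form systems the engines are
tested against: exponential decay (`e^{-1}` at unit time), the logistic
equation, a two-step pathway with steady state `k1 S0/(k1+k2)` and flux
control coefficients `(k2, k1)/(k1+k2)`, a mass-action enzyme mechanism
with two conserved moieties, the Robertson stiff system, a dimerization
process with explicit combinatorial propensities, an immigration-death
process with Poisson stationary law, a decay chain in monolithic and
modular form, and event/constraint/fast-equilibrium demonstrations.

`random_mass_action()` generates connected mass-action networks with
stoichiometries in \{1, 2\}, rate constants log-uniform on [0.1, 10], and no
autocatalysis, so mass-action dynamics keep states nonnegative.  These
networks emulate the *structural* variety of small biochemical models —
they are not calibrated to any organism, carry no regulation, no
Michaelis–Menten saturation, no separation of time scales and no
measurement model.  Tests passing on them demonstrate correctness of the
algorithms (conservation, compilation, integration), not predictive power
on real data.

## Numerical choices and problem sizes

Defaults: relative tolerance 1e-6 and absolute tolerance 1e-9 for adaptive
integration (closed-form checks in the test-suite tighten this to 1e-8/1e-12
where they assert 1e-6 accuracy); event bisection to 1e-10 in time;
algebraic Newton to residual 1e-12; steady-state residual tolerance 1e-9.
The test-suite and the acceptance script use ensembles of 1000–5000
replicates for stochastic means (compared at three standard errors),
50 random networks of 4 species and 5 reactions for the conservation sweep,
and 20 seeded repetitions for the noisy-recovery study — sizes chosen so the
statistical bands are sharp while a full run stays comfortably on a laptop
scale.

## Known limitations

No delay differential equations, no PDE or population engines, no dynamic
flux-balance coupling; DAE support stops at the rapid-equilibrium form; the
SBML subset excludes packages, function definitions and event priorities;
stochastic simulation excludes events, rules and non-integer stoichiometry;
identifiability and confidence intervals for fitted parameters are out of
scope.  The SBML reader matches algebraic rules to otherwise-undetermined
variables in declaration order — a heuristic that is exact for this subset
but would need explicit pairing for exotic hand-written documents.
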