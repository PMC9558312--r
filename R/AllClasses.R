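#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Titratable lambda-group
#'
#' A group of atoms whose partial charges depend on the protonation state of
#' one titratable residue, in the multisite representation: one
#' lambda-coordinate per physical protonation state, with the sum of the
#' coordinates constrained to 1.  A residue with a single titratable site is
#' the two-state special case (protonated state / deprotonated state).
#'
#' @slot atomIds integer indices (into the system's atom table) of the member
#'   atoms.
#' @slot stateCharges numeric matrix, one row per member atom and one column
#'   per protonation state; entry `[i, k]` is the partial charge (e) of member
#'   atom i when the group is fully in state k (lambda_k = 1).
#' @slot stateNames character, one name per state (e.g. `c("HSP","HSD","HSE")`).
#' @slot protonatedState integer, index of the fully protonated reference
#'   state.  Its coordinate carries no pH potential.
#' @slot pKaRefs numeric, one reference pKa per state; the entry for the
#'   protonated state is `NA`.  For deprotonated states these are microscopic
#'   reference pKas.
#' @slot lambda numeric, current value of each lambda-coordinate.  Unbounded:
#'   the bias, pH and correction potentials confine the coordinates, no hard
#'   clamping is applied.
#' @slot constrainedSum numeric(1), target of the simplex constraint
#'   (always 1).
#' @slot name character(1) label used in trajectory headers.
#' @seealso [LambdaGroup()], [TitratableSystem-class]
#' @export
setClass("LambdaGroup",
  representation(
    atomIds = "integer",
    stateCharges = "matrix",
    stateNames = "character",
    protonatedState = "integer",
    pKaRefs = "numeric",
    lambda = "numeric",
    constrainedSum = "numeric",
    name = "character"
  )
)

setValidity("LambdaGroup", function(object) {
  msg <- character()
  ns <- ncol(object@stateCharges)
  if (ns < 2L)
    msg <- c(msg, "a lambda-group needs at least 2 protonation states")
  if (nrow(object@stateCharges) != length(object@atomIds))
    msg <- c(msg, "stateCharges must have one row per member atom")
  if (length(object@stateNames) != ns)
    msg <- c(msg, "need one state name per state")
  if (length(object@pKaRefs) != ns)
    msg <- c(msg, "need one reference pKa per state (NA for the protonated state)")
  if (length(object@protonatedState) != 1L ||
      object@protonatedState < 1L || object@protonatedState > ns)
    msg <- c(msg, "protonatedState must index one of the states")
  else {
    dep <- setdiff(seq_len(ns), object@protonatedState)
    if (any(!is.finite(object@pKaRefs[dep])))
      msg <- c(msg, "deprotonated states need finite reference pKas")
  }
  if (length(object@lambda) != ns)
    msg <- c(msg, "need one lambda value per state")
  if (!isTRUE(all.equal(object@constrainedSum, 1)))
    msg <- c(msg, "constrainedSum must be 1")
  if (anyDuplicated(object@atomIds))
    msg <- c(msg, "duplicated member atom ids")
  if (length(msg)) msg else TRUE
})

#' Construct a lambda-group
#'
#' @param atomIds integer atom indices of the member atoms.
#' @param stateCharges numeric matrix `[n_atoms x n_states]` of per-state
#'   partial charges (e).  For a single-site residue supply two columns:
#'   protonated and deprotonated.
#' @param pKaRefs numeric reference pKas, one per state, `NA` for the
#'   protonated state.  A vector of length `n_states - 1` is also accepted and
#'   taken to be the pKas of the deprotonated states in column order.
#' @param protonatedState index of the fully protonated state (default 1).
#' @param stateNames optional state labels.
#' @param lambda initial coordinate values (default: fully protonated).
#' @param name group label.
#' @return A [LambdaGroup-class] object.
#' @examples
#' ## aspartate-like site: neutral when protonated, -1 e when not
#' LambdaGroup(1L, cbind(0, -1), pKaRefs = 3.65)
#' @export
LambdaGroup <- function(atomIds, stateCharges, pKaRefs,
                        protonatedState = 1L, stateNames = NULL,
                        lambda = NULL, name = "site") {
  stateCharges <- as.matrix(stateCharges)
  ns <- ncol(stateCharges)
  protonatedState <- as.integer(protonatedState)
  if (length(pKaRefs) == ns - 1L) {
    full <- rep(NA_real_, ns)
    full[-protonatedState] <- pKaRefs
    pKaRefs <- full
  }
  if (is.null(stateNames)) {
    stateNames <- colnames(stateCharges)
    if (is.null(stateNames))
      stateNames <- paste0("state", seq_len(ns))
  }
  if (is.null(lambda)) {
    lambda <- rep(0, ns)
    lambda[protonatedState] <- 1
  }
  new("LambdaGroup", atomIds = as.integer(atomIds),
      stateCharges = unname(stateCharges), stateNames = stateNames,
      protonatedState = protonatedState, pKaRefs = as.numeric(pKaRefs),
      lambda = as.numeric(lambda), constrainedSum = 1, name = name)
}

#' Collective buffer particles
#'
#' Buffer particles absorb the net charge released or taken up by titrating
#' sites.  All buffers carry the identical charge at all times,
#' `qMin + collectiveLambda * (qMax - qMin)`, and the single collective
#' coordinate is coupled to the titratable sites through the charge
#' constraint, keeping the cell neutral.
#'
#' @slot atomIds integer indices of the buffer atoms.
#' @slot qMin,qMax numeric(1), charge range of one buffer (defaults -0.5 e
#'   and +0.5 e).
#' @slot collectiveLambda numeric(1), current collective coordinate in
#'   `[0, 1]`.
#' @export
setClass("BufferSet",
  representation(atomIds = "integer", qMin = "numeric", qMax = "numeric",
                 collectiveLambda = "numeric"))

setValidity("BufferSet", function(object) {
  msg <- character()
  if (length(object@atomIds) < 1L) msg <- c(msg, "empty buffer set")
  if (object@qMax <= object@qMin) msg <- c(msg, "qMax must exceed qMin")
  lam <- object@collectiveLambda
  if (length(lam) != 1L || !is.finite(lam))
    msg <- c(msg, "collectiveLambda must be a single finite number")
  else if (lam < -1e-9 || lam > 1 + 1e-9)
    msg <- c(msg, "collectiveLambda outside [0, 1]: buffer charge would leave [qMin, qMax]")
  if (length(msg)) msg else TRUE
})

#' @param atomIds integer indices of the buffer atoms.
#' @param qMin,qMax per-buffer charge range (e).
#' @param collectiveLambda initial collective coordinate.
#' @return A [BufferSet-class] object.
#' @rdname BufferSet-class
#' @export
BufferSet <- function(atomIds, qMin = -0.5, qMax = 0.5,
                      collectiveLambda = 0.5) {
  new("BufferSet", atomIds = as.integer(atomIds), qMin = qMin, qMax = qMax,
      collectiveLambda = collectiveLambda)
}

setClassUnion("BufferSetOrNULL", c("BufferSet", "NULL"))

#' A titratable toy system
#'
#' The central container: point-charge atoms, titratable lambda-groups,
#' optional collective buffers, and the electrostatics settings.  Atoms that
#' belong to no group and no buffer keep their fixed `charge`; member atoms of
#' a group get the state-weighted interpolated charge; buffer atoms share the
#' collective buffer charge.
#'
#' @slot atoms data.frame with columns `x`, `y`, `z` (nm), `mass` (amu) and
#'   `charge` (e; the fixed charge of atoms outside any group/buffer).
#' @slot groups list of [LambdaGroup-class].
#' @slot buffers a [BufferSet-class] or `NULL`.
#' @slot scheme electrostatics kernel: `"plain"` (direct sum) or
#'   `"reaction-field"`.
#' @slot cutoff pair cutoff in nm (`Inf` = none; required finite for
#'   reaction-field).
#' @slot epsilonR relative dielectric permittivity.
#' @slot box periodic cubic box edge lengths (nm, length 3) or `NULL` for
#'   open boundaries (minimum-image convention when periodic).
#' @slot temperature reference temperature (K).
#' @slot totalChargeTarget target total charge (e) enforced by the charge
#'   constraint when buffers are present.
#' @slot frozen logical(1): if `TRUE` the atoms do not move and only the
#'   lambda degrees of freedom are dynamic.
#' @slot restraintK harmonic position-restraint force constant
#'   (kJ mol^-1 nm^-2, 0 = none) applied to every mobile atom about its
#'   initial position; keeps toy fixtures bounded in the absence of
#'   Lennard-Jones repulsion.
#' @seealso [TitratableSystem()], [interpolatedCharges()], [coulombEnergy()]
#' @export
setClass("TitratableSystem",
  representation(
    atoms = "data.frame",
    groups = "list",
    buffers = "BufferSetOrNULL",
    scheme = "character",
    cutoff = "numeric",
    epsilonR = "numeric",
    box = "numericOrNULL",
    temperature = "numeric",
    totalChargeTarget = "numeric",
    frozen = "logical",
    restraintK = "numeric"
  )
)

setValidity("TitratableSystem", function(object) {
  msg <- character()
  at <- object@atoms
  need <- c("x", "y", "z", "mass", "charge")
  if (!all(need %in% names(at)))
    return(sprintf("atoms must have columns %s", paste(need, collapse = ", ")))
  if (any(!is.finite(as.matrix(at[need]))))
    msg <- c(msg, "non-finite atom fields")
  if (any(at$mass <= 0)) msg <- c(msg, "atom masses must be positive")
  n <- nrow(at)
  used <- integer()
  for (g in object@groups) {
    if (!is(g, "LambdaGroup")) msg <- c(msg, "groups must be LambdaGroup objects")
    else {
      if (any(g@atomIds < 1L | g@atomIds > n))
        msg <- c(msg, "group refers to atoms outside the system")
      used <- c(used, g@atomIds)
    }
  }
  if (!is.null(object@buffers)) {
    if (any(object@buffers@atomIds < 1L | object@buffers@atomIds > n))
      msg <- c(msg, "buffer refers to atoms outside the system")
    used <- c(used, object@buffers@atomIds)
  }
  if (anyDuplicated(used))
    msg <- c(msg, "an atom is assigned to more than one lambda-group/buffer set")
  if (!object@scheme %in% c("plain", "reaction-field"))
    msg <- c(msg, "scheme must be 'plain' or 'reaction-field'")
  if (object@scheme == "reaction-field" && !is.finite(object@cutoff))
    msg <- c(msg, "reaction-field needs a finite cutoff")
  if (!is.null(object@box)) {
    if (length(object@box) != 3L || any(object@box <= 0))
      msg <- c(msg, "box must be three positive edge lengths")
    else if (is.finite(object@cutoff) && object@cutoff > min(object@box) / 2)
      msg <- c(msg, "cutoff exceeds half the box: minimum image invalid")
  }
  if (object@epsilonR <= 0) msg <- c(msg, "epsilonR must be positive")
  if (object@temperature <= 0) msg <- c(msg, "temperature must be positive")
  if (object@restraintK < 0) msg <- c(msg, "restraintK must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a titratable system
#'
#' @param atoms data.frame with columns `x`, `y`, `z`, `mass`, `charge`.
#' @param groups list of [LambdaGroup-class] objects (or a single group).
#' @param buffers optional [BufferSet-class].
#' @param scheme `"plain"` or `"reaction-field"`.
#' @param cutoff pair cutoff, nm (`Inf` = none).
#' @param epsilonR relative permittivity (reaction-field dielectric; the
#'   continuum beyond the cutoff is treated as a perfect conductor,
#'   epsilon_RF = Inf).
#' @param box periodic cubic box (length-3 numeric) or `NULL` for open
#'   boundaries.
#' @param temperature reference temperature, K.
#' @param totalChargeTarget target total charge, e.
#' @param frozen freeze atomic positions (lambda-only dynamics).
#' @param restraintK harmonic position-restraint constant for mobile atoms.
#' @return A [TitratableSystem-class] object.
#' @examples
#' atoms <- data.frame(x = 0, y = 0, z = 0, mass = 12, charge = 0)
#' sys <- TitratableSystem(atoms, LambdaGroup(1L, cbind(0, -1), pKaRefs = 4))
#' interpolatedCharges(sys)
#' @export
TitratableSystem <- function(atoms, groups = list(), buffers = NULL,
                             scheme = c("plain", "reaction-field"),
                             cutoff = Inf, epsilonR = 1, box = NULL,
                             temperature = 300, totalChargeTarget = 0,
                             frozen = TRUE, restraintK = 0) {
  if (is(groups, "LambdaGroup")) groups <- list(groups)
  scheme <- match.arg(scheme)
  atoms <- as.data.frame(atoms)
  if (is.null(atoms$charge)) atoms$charge <- 0
  if (is.null(atoms$mass)) atoms$mass <- 12
  new("TitratableSystem", atoms = atoms, groups = groups, buffers = buffers,
      scheme = scheme, cutoff = cutoff, epsilonR = epsilonR, box = box,
      temperature = temperature, totalChargeTarget = totalChargeTarget,
      frozen = frozen, restraintK = restraintK)
}

#' Result of one electrostatic evaluation
#'
#' @slot energy total Coulomb energy, kJ/mol.
#' @slot forces per-atom force matrix `[n x 3]`, kJ/(mol nm).
#' @slot phi per-atom electrostatic potential `Phi(R_i, lambda)`,
#'   kJ/(mol e); `phi[i]` is the derivative of the energy with respect to
#'   charge i.
#' @slot charges the per-atom charges the evaluation used (e); consumed by
#'   [lambdaGradients()] to detect stale potentials.
#' @slot nEvaluations number of full electrostatic-potential computations
#'   performed (1 for charge interpolation).
#' @export
setClass("ElectrostaticsResult",
  representation(energy = "numeric", forces = "matrix", phi = "numeric",
                 charges = "numeric", nEvaluations = "integer"))

#' Fitted polynomial correction potential V^MM
#'
#' A polynomial in the free simplex coordinates of one lambda-group (the
#' coordinate of the protonated state is eliminated through the constraint
#' sum(lambda) = 1).  For a two-state group this is a univariate polynomial in
#' the deprotonation coordinate; for an n-state group it is a multivariate
#' polynomial in n - 1 coordinates.  Evaluable and differentiable on the
#' extended range lambda in [-0.1, 1.1] used by the calibration grid.
#'
#' @slot coefficients numeric coefficients, one per monomial.
#' @slot exponents integer matrix `[n_terms x arity]`; row t holds the powers
#'   of each free coordinate in monomial t.
#' @slot arity number of free coordinates (`n_states - 1`).
#' @slot order maximum total degree.
#' @seealso [evalVmm()], [fitVmm()]
#' @export
setClass("VmmPolynomial",
  representation(coefficients = "numeric", exponents = "matrix",
                 arity = "integer", order = "integer"))

setValidity("VmmPolynomial", function(object) {
  msg <- character()
  if (nrow(object@exponents) != length(object@coefficients))
    msg <- c(msg, "one exponent row per coefficient required")
  if (ncol(object@exponents) != object@arity)
    msg <- c(msg, "exponent columns must match arity")
  if (length(msg)) msg else TRUE
})

#' Construct a V^MM polynomial
#'
#' @param coefficients numeric coefficients.
#' @param exponents integer exponent matrix `[n_terms x arity]`.  For
#'   `arity = 1` a plain vector of powers is accepted; if omitted entirely the
#'   coefficients are taken to belong to powers `1..length(coefficients)` of a
#'   single coordinate.
#' @return A [VmmPolynomial-class].
#' @examples
#' ## V = -3 * x  (constant gradient -3 along the deprotonation coordinate)
#' evalVmm(0.3, VmmPolynomial(-3, 1))
#' @export
VmmPolynomial <- function(coefficients, exponents = NULL) {
  coefficients <- as.numeric(coefficients)
  if (is.null(exponents))
    exponents <- matrix(seq_along(coefficients), ncol = 1L)
  if (is.null(dim(exponents)))
    exponents <- matrix(as.integer(exponents), ncol = 1L)
  storage.mode(exponents) <- "integer"
  ord <- if (nrow(exponents)) max(rowSums(exponents)) else 0L
  new("VmmPolynomial", coefficients = coefficients, exponents = exponents,
      arity = ncol(exponents), order = as.integer(ord))
}

setClassUnion("VmmPolynomialOrNULL", c("VmmPolynomial", "NULL"))

#' Lambda-potential settings
#'
#' Parameters of the analytic lambda-dependent terms applied to every
#' lambda-coordinate: the double-well biasing potential (barrier height at
#' lambda = 0.5) and the smooth-step pH potential (steepness `k1`, kink
#' position `x0`).
#'
#' @slot barrier bias barrier height, kJ/mol (default 5.0, the all-atom
#'   setting; coarse-grained-like runs use 7.5).
#' @slot k1 steepness of the smooth step (dimensionless, default 50).
#' @slot x0 kink position of the smooth step (default 0.1; the step rises
#'   between `x0` and `1 - x0`).
#' @export
setClass("LambdaPotentialSettings",
  representation(barrier = "numeric", k1 = "numeric", x0 = "numeric"),
  prototype(barrier = 5.0, k1 = 50, x0 = 0.1))

setValidity("LambdaPotentialSettings", function(object) {
  msg <- character()
  if (object@barrier < 0) msg <- c(msg, "barrier must be >= 0")
  if (object@k1 <= 0) msg <- c(msg, "k1 must be positive")
  if (object@x0 <= 0 || object@x0 >= 0.5) msg <- c(msg, "x0 must lie in (0, 0.5)")
  if (length(msg)) msg else TRUE
})

#' @param barrier bias barrier height, kJ/mol.
#' @param k1,x0 smooth-step parameters of the pH potential.
#' @rdname LambdaPotentialSettings-class
#' @export
LambdaPotentialSettings <- function(barrier = 5.0, k1 = 50, x0 = 0.1) {
  new("LambdaPotentialSettings", barrier = barrier, k1 = k1, x0 = x0)
}

#' Integrator settings
#'
#' @slot dt integration step, ps (default 0.002).
#' @slot nSteps number of steps.
#' @slot atomT,atomTau atom thermostat temperature (K) and coupling time (ps);
#'   `Inf` coupling time disables the thermostat.
#' @slot lambdaT,lambdaTau same for the separate lambda thermostat (defaults
#'   300 K, 2.0 ps).
#' @slot lambdaMass fictitious mass of each lambda-particle, amu (default 5).
#' @slot outputInterval trajectory output spacing, ps (default 1.0).
#' @slot seed RNG seed.
#' @export
setClass("IntegratorSpec",
  representation(dt = "numeric", nSteps = "integer",
                 atomT = "numeric", atomTau = "numeric",
                 lambdaT = "numeric", lambdaTau = "numeric",
                 lambdaMass = "numeric", outputInterval = "numeric",
                 seed = "integer"),
  prototype(dt = 0.002, nSteps = 1000L, atomT = 300, atomTau = 0.5,
            lambdaT = 300, lambdaTau = 2.0, lambdaMass = 5,
            outputInterval = 1.0, seed = 1L))

setValidity("IntegratorSpec", function(object) {
  msg <- character()
  if (object@dt <= 0) msg <- c(msg, "dt must be positive")
  if (object@atomTau <= 0 || object@lambdaTau <= 0)
    msg <- c(msg, "thermostat time constants must be positive")
  if (object@lambdaMass <= 0) msg <- c(msg, "lambdaMass must be positive")
  if (object@outputInterval < object@dt)
    msg <- c(msg, "outputInterval must be at least dt")
  if (length(msg)) msg else TRUE
})

#' @param dt,nSteps,atomT,atomTau,lambdaT,lambdaTau,lambdaMass,outputInterval,seed
#'   see the class slots.
#' @rdname IntegratorSpec-class
#' @export
IntegratorSpec <- function(nSteps = 1000L, dt = 0.002, atomT = 300,
                           atomTau = 0.5, lambdaT = 300, lambdaTau = 2.0,
                           lambdaMass = 5, outputInterval = 1.0, seed = 1L) {
  new("IntegratorSpec", dt = dt, nSteps = as.integer(nSteps), atomT = atomT,
      atomTau = atomTau, lambdaT = lambdaT, lambdaTau = lambdaTau,
      lambdaMass = lambdaMass, outputInterval = outputInterval,
      seed = as.integer(seed))
}

#' Linear constraints on the lambda-coordinates
#'
#' Rows of `C` are the constraint gradients over the stacked coordinate
#' vector (all group coordinates in group-major order, then the collective
#' buffer coordinate if present): one simplex row per group
#' (sum_k lambda_{i,k} = 1) and, with buffers, one global charge row.  All
#' rows are linear, so the constraint is solved in closed form by Lagrange
#' multipliers each step.
#'
#' @slot Cmat constraint coefficient matrix `[n_constraints x n_coordinates]`.
#' @slot target right-hand-side vector.
#' @slot masses fictitious masses of the coordinates (mass-weighted
#'   least-squares correction).
#' @slot tolerance satisfaction tolerance (default 1e-10).
#' @seealso [constraintSet()], [solveConstraints()]
#' @export
setClass("ConstraintSet",
  representation(Cmat = "matrix", target = "numeric", masses = "numeric",
                 tolerance = "numeric"))

setValidity("ConstraintSet", function(object) {
  msg <- character()
  if (length(object@target) != nrow(object@Cmat))
    msg <- c(msg, "one target per constraint row required")
  if (length(object@masses) != ncol(object@Cmat))
    msg <- c(msg, "one mass per coordinate required")
  if (any(object@masses <= 0)) msg <- c(msg, "masses must be positive")
  if (length(msg)) msg else TRUE
})

#' Lambda trajectory
#'
#' Time series of the lambda-coordinates written at the output interval.
#'
#' @slot time output times, ps.
#' @slot lambdas matrix `[n_frames x n_coordinates]`, group-major column
#'   order; the collective buffer coordinate, when present, is the last
#'   column, named `"buffer"`.
#' @slot coordinateNames column labels (`<group>.<state>`).
#' @slot pH solvent pH of the run.
#' @slot seed RNG seed of the run.
#' @slot replica replica index.
#' @slot energies optional per-frame energy table (data.frame; may have 0
#'   rows) with columns `time`, `potential`, `kineticAtoms`, `kineticLambda`.
#' @export
setClass("LambdaTrajectory",
  representation(time = "numeric", lambdas = "matrix",
                 coordinateNames = "character", pH = "numeric",
                 seed = "integer", replica = "integer",
                 energies = "data.frame"))

#' Thermodynamic-integration scan result
#'
#' Mean force-field gradients with respect to the free simplex coordinates of
#' one lambda-group, on a grid that extends beyond the physical range on both
#' sides (default -0.1 to 1.1 in steps of 0.05).
#'
#' @slot grid matrix `[n_points x arity]` of free-coordinate values.
#' @slot meanGradients matrix `[n_points x arity]`;
#'   `<d V / d x_k>` time averages, kJ/mol.
#' @slot stderr matching standard errors (0 for deterministic frozen-atom
#'   scans).
#' @slot nSamples samples retained per grid point.
#' @slot equilibrationFraction discarded prefix fraction.
#' @slot group index of the scanned group.
#' @seealso [tiScan()], [fitVmm()], [tiFreeEnergy()]
#' @export
setClass("TiScanResult",
  representation(grid = "matrix", meanGradients = "matrix", stderr = "matrix",
                 nSamples = "integer", equilibrationFraction = "numeric",
                 group = "integer"))

setValidity("TiScanResult", function(object) {
  msg <- character()
  if (!all(dim(object@grid) == dim(object@meanGradients)))
    msg <- c(msg, "grid and meanGradients dimensions differ")
  if (min(object@grid) >= 0 || max(object@grid) <= 1)
    msg <- c(msg, "grid must extend beyond the physical range on both sides")
  if (length(msg)) msg else TRUE
})

#' Titration campaign result
#'
#' Per-pH deprotonated fractions (replica means and standard errors) and
#' Henderson-Hasselbalch fits, for every reportable species: the site itself
#' for a two-state group; the macroscopic fraction plus one microscopic
#' fraction per deprotonated tautomer for a multisite group.
#'
#' @slot fractions data.frame with columns `pH`, `species`, `S`, `sem`,
#'   `framesUsed`, `framesExcluded`, `nReplicas`.
#' @slot fits data.frame with columns `species`, `pKa`, `ci95` (95 percent
#'   confidence half-width of the nonlinear fit), `se`, `nPoints`.
#' @slot thresholds classification thresholds (protonated below the first,
#'   deprotonated above the second).
#' @slot nReplicas replicas per pH value.
#' @slot pHValues the pH grid.
#' @seealso [titrationCampaign()], [fitHH()]
#' @export
setClass("TitrationResult",
  representation(fractions = "data.frame", fits = "data.frame",
                 thresholds = "numeric", nReplicas = "integer",
                 pHValues = "numeric"))
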