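# S4 classes for the design/analysis/simulation pipeline.

setClassUnion("numericOrNULL", c("numeric", "NULL"))
setClassUnion("listOrNULL", c("list", "NULL"))
setClassUnion("functionOrNULL", c("function", "NULL"))

#' Dimensional reaction-diffusion linearization
#'
#' Diffusivities and Jacobian entries of a two-species reaction-diffusion
#' system evaluated at a homogeneous steady state, in physical units.
#'
#' @slot Du,Dv diffusivities of u and v (> 0, same units).
#' @slot fu,fv,gu,gv Jacobian entries at the steady state (1/time).
#' @slot L optional 1D domain length (length units, \code{NA} when absent).
#' @export
setClass("DimensionalRD",
  representation(Du = "numeric", Dv = "numeric",
                 fu = "numeric", fv = "numeric",
                 gu = "numeric", gv = "numeric", L = "numeric"),
  prototype(L = NA_real_))

setValidity("DimensionalRD", function(object) {
  vals <- c(object@Du, object@Dv, object@fu, object@fv, object@gu, object@gv)
  if (!all(is.finite(vals))) return("all diffusivities and Jacobian entries must be finite")
  if (object@Du <= 0 || object@Dv <= 0) return("Du and Dv must be positive")
  TRUE
})

#' @param Du,Dv,fu,fv,gu,gv,L see the class slots.
#' @rdname DimensionalRD-class
#' @export
dimensionalRD <- function(Du, Dv, fu, fv, gu, gv, L = NA_real_) {
  new("DimensionalRD", Du = as.numeric(Du), Dv = as.numeric(Dv),
      fu = as.numeric(fu), fv = as.numeric(fv),
      gu = as.numeric(gu), gv = as.numeric(gv), L = as.numeric(L))
}

#' Nondimensional reaction-diffusion summary
#'
#' The reduced linearization in which the activator has unit self-activation
#' and unit diffusivity: F = |g_u| f_v / f_u^2 measures how strongly the
#' activator drives the inhibitor, G = |g_v| / f_u the inhibitor's
#' self-damping, and D = D_v / D_u the diffusion ratio. The Turing conditions
#' reduce to F > G > 1 together with D large enough.
#'
#' @slot F,G,D nondimensional groups (dimensionless, all > 0).
#' @slot signType \code{"pure"} or \code{"cross"}.
#' @slot timeScale,lengthScale the scales 1/f_u and sqrt(D_u/f_u) used in the
#'   reduction.
#' @export
setClass("NondimRD",
  representation(F = "numeric", G = "numeric", D = "numeric",
                 signType = "character",
                 timeScale = "numeric", lengthScale = "numeric"))

setValidity("NondimRD", function(object) {
  if (object@F <= 0 || object@G <= 0) return("F and G must be positive")
  if (object@D <= 0) return("D must be positive")
  if (!object@signType %in% c("pure", "cross"))
    return("signType must be 'pure' or 'cross'")
  TRUE
})

#' Outcome of the Turing instability conditions
#'
#' @slot stableWithoutDiffusion trace/determinant stability at wavenumber zero.
#' @slot diffusionDriven whether diffusion destabilises the steady state.
#' @slot band squared-wavenumber interval (k2minus, k2plus) with positive
#'   growth, or \code{numeric(0)} when closed.
#' @slot Dc critical diffusion ratio (NA when the sign structure admits none).
#' @slot Lc minimum 1D domain length for mode n = 1 (NA when no band).
#' @slot admissibleModes integers n with k_minus < n*pi/L < k_plus (empty when
#'   L not supplied).
#' @slot marginal TRUE when any inequality holds with equality to tolerance.
#' @slot inequalities named logical vector for the four conditions.
#' @export
setClass("TuringReport",
  representation(stableWithoutDiffusion = "logical",
                 diffusionDriven = "logical",
                 band = "numeric",
                 Dc = "numeric", Lc = "numeric",
                 admissibleModes = "integer",
                 marginal = "logical",
                 inequalities = "logical"))

setValidity("TuringReport", function(object) {
  if (length(object@band) == 2) {
    if (!(object@band[1] < object@band[2]) || any(object@band <= 0))
      return("nonempty band requires 0 < k2minus < k2plus")
  } else if (length(object@band) != 0) {
    return("band must have length 0 or 2")
  }
  if (isTRUE(object@diffusionDriven) && !isTRUE(object@stableWithoutDiffusion))
    return("diffusionDriven requires stableWithoutDiffusion")
  TRUE
})

#' Dispersion relation sample
#'
#' Dominant real part of the linear growth rate over a grid of squared
#' wavenumbers.
#'
#' @slot kSquared grid of k^2 values.
#' @slot growthRate Re of the dominant eigenvalue at each k^2.
#' @slot kMax k^2 achieving the largest growth rate on the grid.
#' @export
setClass("DispersionResult",
  representation(kSquared = "numeric", growthRate = "numeric",
                 kMax = "numeric"))

#' Level-set parameter region
#'
#' A target Turing space Omega = \{p in box : S(p) > 0\} described by a scalar
#' level-set function over named parameters, together with the (F, G)
#' parameterisation the kinetic family attaches to each point. When no
#' parameterisation is given the canonical level-set family F = S + 2,
#' G = 2 is assumed.
#'
#' @slot S function taking a data.frame with columns \code{paramNames} and
#'   returning the level-set values.
#' @slot paramNames ordered parameter names.
#' @slot box numeric matrix with rows "min" and "max" and one column per
#'   parameter (finite bounds used for suprema).
#' @slot gridResolution points per axis for the initial scan.
#' @slot Ffun,Gfun optional functions of the same signature as S giving the
#'   nondimensional groups F and G at each parameter point.
#' @export
setClass("LevelSetRegion",
  representation(S = "function", paramNames = "character", box = "matrix",
                 gridResolution = "integer",
                 Ffun = "functionOrNULL", Gfun = "functionOrNULL"))

setValidity("LevelSetRegion", function(object) {
  if (!is.numeric(object@box) || nrow(object@box) != 2 ||
      ncol(object@box) != length(object@paramNames))
    return("box must be a 2 x n numeric matrix (rows: min, max)")
  if (!all(is.finite(object@box))) return("box bounds must be finite")
  if (any(object@box[1, ] >= object@box[2, ])) return("box must have min < max")
  if (object@gridResolution < 3L) return("gridResolution must be >= 3")
  TRUE
})

#' Polynomial kinetic system
#'
#' Two-species polynomial kinetics f(u,v), g(u,v) with steady state (U, V),
#' an optional subtracted cubic term C (u - U)^3 in f (which selects stripes
#' over spots as C grows without touching the linearization), and an optional
#' saturation guard replacing the quadratic term of the phase-switching
#' family by q u^2 / (1 + eps^2 u^2).
#'
#' @slot fTerms,gTerms data.frames with columns \code{coef}, \code{pu},
#'   \code{pv}: each row is coef * u^pu * v^pv.
#' @slot cubic cubic coefficient C (>= 0).
#' @slot steadyState numeric (U, V), both > 0.
#' @slot signType one of \code{"pure"}, \code{"cross"}, \code{"none"}.
#' @slot family construction family label.
#' @slot alpha exponent of the u^alpha v (cross) / u^alpha (pure) monomial.
#' @slot eta level-set offset used in the construction (fixed to 1).
#' @slot params named list of parameter bindings used to generate the system.
#' @slot targetJacobian declared 2 x 2 Jacobian at the steady state.
#' @slot guardEps saturation-guard epsilon (0 = guard off).
#' @slot guardCoef coefficient of the guarded quadratic term.
#' @export
setClass("KineticSystem",
  representation(fTerms = "data.frame", gTerms = "data.frame",
                 cubic = "numeric", steadyState = "numeric",
                 signType = "character", family = "character",
                 alpha = "numeric", eta = "numeric",
                 params = "list", targetJacobian = "matrix",
                 guardEps = "numeric", guardCoef = "numeric"),
  prototype(cubic = 0, alpha = 2, eta = 1, params = list(),
            guardEps = 0, guardCoef = 0,
            targetJacobian = matrix(NA_real_, 2, 2)))

setValidity("KineticSystem", function(object) {
  for (tm in list(object@fTerms, object@gTerms)) {
    if (!all(c("coef", "pu", "pv") %in% names(tm)))
      return("fTerms/gTerms need columns coef, pu, pv")
  }
  if (length(object@steadyState) != 2 || any(object@steadyState <= 0))
    return("steadyState must be two positive values")
  if (object@cubic < 0) return("cubic coefficient C must be >= 0")
  ss <- object@steadyState
  res <- abs(c(evalKinetics(object, ss[1], ss[2])$f,
               evalKinetics(object, ss[1], ss[2])$g))
  tol <- 1e-12 * max(1, sum(abs(object@fTerms$coef)), sum(abs(object@gTerms$coef)))
  if (object@guardEps > 0) tol <- tol + 4 * abs(object@guardCoef) * object@guardEps^2
  if (any(res > tol))
    return(sprintf("steady state residual %.3e exceeds tolerance", max(res)))
  TRUE
})

#' Rectangular simulation grid
#'
#' Node-centred uniform grid: x_i = i * hx for i = 0..nx-1 with the first and
#' last nodes on the boundary; \code{ny = 1} denotes a 1D interval.
#'
#' @slot nx,ny node counts (nx >= 3; ny = 1 for 1D, otherwise >= 3).
#' @slot Lx,Ly physical extents.
#' @export
setClass("Grid2D",
  representation(nx = "integer", ny = "integer", Lx = "numeric", Ly = "numeric"))

setValidity("Grid2D", function(object) {
  if (object@nx < 3L) return("nx must be >= 3")
  if (object@ny != 1L && object@ny < 3L) return("ny must be 1 (1D) or >= 3")
  if (object@Lx <= 0) return("Lx must be positive")
  if (object@ny > 1L && object@Ly <= 0) return("Ly must be positive in 2D")
  TRUE
})

#' A scalar parameter as a field over the grid
#'
#' @slot name parameter symbol the field binds (e.g. "C", "a", "S", "U").
#' @slot values scalar per grid node (nx x ny matrix, or vector in 1D), or a
#'   single scalar recycled over the grid.
#' @slot schedule optional time program (see \code{\link{timeSquareWave}});
#'   \code{NULL} for a static field.
#' @export
setClass("ParamField",
  representation(name = "character", values = "numeric", dim = "integer",
                 schedule = "listOrNULL"),
  prototype(schedule = NULL))

setValidity("ParamField", function(object) {
  if (!all(is.finite(object@values))) return("field values must be finite")
  TRUE
})

#' Segmentation of an image or grid into labelled regions
#'
#' @slot labels integer region id per node (nx x ny matrix layout).
#' @slot thresholds intensity thresholds used (normalised to [0, 1]).
#' @slot nLevels number of requested levels.
#' @export
setClass("SegmentMap",
  representation(labels = "matrix", thresholds = "numeric", nLevels = "integer"))

setValidity("SegmentMap", function(object) {
  if (any(is.na(object@labels))) return("labels must cover every node")
  TRUE
})

#' Simulation result
#'
#' @slot u,v final fields (nx x ny matrices; single-column in 1D).
#' @slot tFinal simulated time reached.
#' @slot converged TRUE when both stopping conditions were met (sup-norm of
#'   the time derivative below tolerance and t >= tMin).
#' @slot positivityOk TRUE when no monitored state dipped below zero.
#' @slot history optional snapshots (list of list(t, u, v)).
#' @slot seed RNG seed used.
#' @slot config echo of the configuration list.
#' @slot nSteps accepted time steps.
#' @slot derivSup final sup-norm of du/dt, dv/dt.
#' @export
setClass("SimResult",
  representation(u = "matrix", v = "matrix", tFinal = "numeric",
                 converged = "logical", positivityOk = "logical",
                 history = "list", seed = "numeric", config = "list",
                 nSteps = "numeric", derivSup = "numeric"))

#' Pattern classification report
#'
#' @slot amplitude max - min of u.
#' @slot classification one of homogeneous, spots, stripes, mixed.
#' @slot nModes 1D mode index (NA in 2D).
#' @slot phase in_phase / out_of_phase / indeterminate.
#' @slot perSegment optional per-segment sub-reports.
#' @slot diagnostics component count, median circularity, tolerances used.
#' @export
setClass("PatternReport",
  representation(amplitude = "numeric", classification = "character",
                 nModes = "numeric", phase = "character",
                 perSegment = "list", diagnostics = "list"),
  prototype(nModes = NA_real_, phase = "indeterminate",
            perSegment = list(), diagnostics = list()))

setValidity("PatternReport", function(object) {
  ok <- c("homogeneous", "spots", "stripes", "mixed")
  if (!object@classification %in% ok)
    return("classification must be homogeneous/spots/stripes/mixed")
  if (!object@phase %in% c("in_phase", "out_of_phase", "indeterminate"))
    return("phase must be in_phase/out_of_phase/indeterminate")
  TRUE
})

#' Heterogeneous kinetics: a family bound to parameter fields
#'
#' @slot family one of "cross", "pure", "switching", "steadyState".
#' @slot params named list of scalars or \linkS4class{ParamField}s; fields may
#'   carry time schedules.
#' @export
setClass("HeteroKinetics",
  representation(family = "character", params = "list"))

setValidity("HeteroKinetics", function(object) {
  if (!object@family %in% c("cross", "pure", "switching", "steadyState"))
    return("unknown kinetic family")
  TRUE
})
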