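# Generics and simple accessors.

#' Evaluate the Turing instability conditions
#'
#' @param x a \linkS4class{DimensionalRD} or \linkS4class{NondimRD} object.
#' @param L optional 1D domain length used to fill the admissible modes; for
#'   \code{DimensionalRD} objects the slot value is used when \code{L} is
#'   missing.
#' @param tol relative tolerance below which an inequality is flagged as an
#'   equality (marginal case).
#' @return a \linkS4class{TuringReport}.
#' @export
setGeneric("checkTuring", function(x, L = NULL, tol = 1e-9, ...) standardGeneric("checkTuring"))

#' Self-verification of a constructed kinetic system
#'
#' Recomputes the steady-state residuals and the Jacobian (5-point central
#' differences, exact for polynomial kinetics up to rounding) and compares
#' them with the declared targets.
#'
#' @param sys a \linkS4class{KineticSystem}.
#' @param tol residual threshold for a pass (default 1e-10); systems carrying
#'   a saturation guard are allowed an additional O(eps^2) Jacobian drift,
#'   which the report records.
#' @return list with residuals, numeric Jacobian, max Jacobian deviation,
#'   sign classification, recorded guard drift and a \code{pass} flag.
#' @export
setGeneric("verifyKinetics", function(sys, tol = 1e-10) standardGeneric("verifyKinetics"))

#' Serialize a turingkit object to JSON
#'
#' @param x object to serialize.
#' @param path optional file path; when omitted the JSON string is returned.
#' @param ... unused.
#' @export
setGeneric("exportJSON", function(x, path = NULL, ...) standardGeneric("exportJSON"))

#' @describeIn NondimRD-class derived quantity F' = F - 1.
#' @param x object.
#' @export
setGeneric("FPrime", function(x) standardGeneric("FPrime"))
#' @describeIn NondimRD-class derived quantity G' = G - 1.
#' @export
setGeneric("GPrime", function(x) standardGeneric("GPrime"))
setMethod("FPrime", "NondimRD", function(x) x@F - 1)
setMethod("GPrime", "NondimRD", function(x) x@G - 1)

#' @describeIn KineticSystem-class steady state (U, V).
#' @param object a KineticSystem.
#' @export
setGeneric("steadyState", function(object) standardGeneric("steadyState"))
setMethod("steadyState", "KineticSystem", function(object) object@steadyState)

#' @describeIn KineticSystem-class sign structure ("pure", "cross", "none").
#' @export
setGeneric("signType", function(object) standardGeneric("signType"))
setMethod("signType", "KineticSystem", function(object) object@signType)
setMethod("signType", "NondimRD", function(object) object@signType)

#' @describeIn KineticSystem-class cubic coefficient C.
#' @export
setGeneric("cubicCoef", function(object) standardGeneric("cubicCoef"))
setMethod("cubicCoef", "KineticSystem", function(object) object@cubic)

# --- show methods -----------------------------------------------------------

setMethod("show", "NondimRD", function(object) {
  cat(sprintf("NondimRD (%s kinetics): F = %.6g, G = %.6g, D = %.6g\n",
              object@signType, object@F, object@G, object@D))
  cat(sprintf("  F' = %.6g, G' = %.6g; scales [t] = %.4g, [x] = %.4g\n",
              object@F - 1, object@G - 1, object@timeScale, object@lengthScale))
})

setMethod("show", "TuringReport", function(object) {
  cat("TuringReport\n")
  cat("  stable without diffusion:", object@stableWithoutDiffusion, "\n")
  cat("  diffusion-driven instability:", object@diffusionDriven, "\n")
  if (length(object@band) == 2)
    cat(sprintf("  band (k^2): [%.6g, %.6g]\n", object@band[1], object@band[2]))
  else cat("  band: empty\n")
  cat(sprintf("  Dc = %.6g, Lc = %.6g, marginal = %s\n",
              object@Dc, object@Lc, object@marginal))
  if (length(object@admissibleModes))
    cat("  admissible modes:", paste(object@admissibleModes, collapse = ", "), "\n")
})

setMethod("show", "KineticSystem", function(object) {
  ss <- object@steadyState
  cat(sprintf("KineticSystem (%s family, %s sign structure)\n",
              object@family, object@signType))
  cat("  f(u,v) =", renderPoly(object@fTerms, object@cubic, ss[1], object@guardEps,
                               object@guardCoef), "\n")
  cat("  g(u,v) =", renderPoly(object@gTerms, 0, ss[1], 0, 0), "\n")
  cat(sprintf("  steady state (U, V) = (%.6g, %.6g)\n", ss[1], ss[2]))
})

setMethod("show", "Grid2D", function(object) {
  if (object@ny == 1L)
    cat(sprintf("Grid2D: 1D interval [0, %g], %d nodes (h = %.4g)\n",
                object@Lx, object@nx, object@Lx / (object@nx - 1)))
  else
    cat(sprintf("Grid2D: [0, %g] x [0, %g], %d x %d nodes\n",
                object@Lx, object@Ly, object@nx, object@ny))
})

setMethod("show", "SimResult", function(object) {
  cat(sprintf("SimResult: t = %.4g, converged = %s, positivity ok = %s\n",
              object@tFinal, object@converged, object@positivityOk))
  cat(sprintf("  amplitude(u) = %.4g over %d x %d nodes, %d steps\n",
              diff(range(object@u)), nrow(object@u), ncol(object@u),
              as.integer(object@nSteps)))
})

setMethod("show", "PatternReport", function(object) {
  cat(sprintf("PatternReport: %s (amplitude %.4g, phase %s",
              object@classification, object@amplitude, object@phase))
  if (!is.na(object@nModes)) cat(sprintf(", %d mode(s)", as.integer(object@nModes)))
  cat(")\n")
  if (length(object@perSegment))
    cat("  per-segment:", paste(sprintf("%s: %s", names(object@perSegment),
        vapply(object@perSegment, function(r) r@classification, "")),
        collapse = "; "), "\n")
})

setMethod("show", "LevelSetRegion", function(object) {
  cat("LevelSetRegion over", paste(object@paramNames, collapse = ", "), "\n")
  cat("  box:", paste(sprintf("%s in [%g, %g]", object@paramNames,
      object@box[1, ], object@box[2, ]), collapse = "; "), "\n")
})
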