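# JSON serialization of the main objects.

.writeOrReturn <- function(obj, path) {
  if (is.null(path))
    return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null"))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @describeIn exportJSON monomial-basis coefficients, steady state, cubic
#'   coefficient and sign type; round-trips through
#'   \code{\link{kineticsFromJSON}}.
#' @export
setMethod("exportJSON", "KineticSystem", function(x, path = NULL, ...) {
  obj <- list(
    family = x@family, signType = x@signType, alpha = x@alpha, eta = x@eta,
    steadyState = as.list(setNames(x@steadyState, c("U", "V"))),
    C = x@cubic,
    fTerms = x@fTerms, gTerms = x@gTerms,
    params = x@params,
    guard = if (x@guardEps > 0) list(eps = x@guardEps, coef = x@guardCoef)
      else NULL,
    render = list(
      f = renderPoly(x@fTerms, x@cubic, x@steadyState[1], x@guardEps, x@guardCoef),
      g = renderPoly(x@gTerms)))
  .writeOrReturn(obj, path)
})

#' Rebuild a kinetic system from its JSON serialization
#'
#' @param json path to a JSON file or a JSON string produced by
#'   \code{exportJSON}.
#' @return a \linkS4class{KineticSystem}.
#' @export
kineticsFromJSON <- function(json) {
  obj <- if (file.exists(json)) jsonlite::read_json(json, simplifyVector = TRUE)
    else jsonlite::fromJSON(json)
  sys <- kineticSystem(
    fTerms = as.data.frame(obj$fTerms), gTerms = as.data.frame(obj$gTerms),
    steadyState = c(obj$steadyState$U, obj$steadyState$V),
    C = obj$C, signType = obj$signType, family = obj$family,
    params = as.list(obj$params), alpha = obj$alpha)
  if (!is.null(obj$guard)) {
    sys@guardEps <- obj$guard$eps
    sys@guardCoef <- obj$guard$coef
  }
  sys
}

#' @describeIn exportJSON inequalities, Dc, Lc, band, marginality and
#'   admissible modes.
#' @export
setMethod("exportJSON", "TuringReport", function(x, path = NULL, ...) {
  obj <- list(
    inequalities = as.list(x@inequalities),
    stable_without_diffusion = x@stableWithoutDiffusion,
    diffusion_driven = x@diffusionDriven,
    Dc = if (is.finite(x@Dc)) x@Dc else NULL,
    Lc = if (is.finite(x@Lc)) x@Lc else NULL,
    band = if (length(x@band)) as.numeric(x@band) else list(),
    marginal = x@marginal,
    admissible_modes = if (length(x@admissibleModes))
      as.integer(x@admissibleModes) else list())
  .writeOrReturn(obj, path)
})

#' @describeIn exportJSON amplitude, classification, modes, phase and
#'   per-segment sub-reports.
#' @export
setMethod("exportJSON", "PatternReport", function(x, path = NULL, ...) {
  asList <- function(r) list(
    amplitude = r@amplitude, classification = r@classification,
    n_modes = if (is.finite(r@nModes)) r@nModes else NULL,
    phase = r@phase, diagnostics = r@diagnostics)
  obj <- asList(x)
  if (length(x@perSegment)) obj$per_segment <- lapply(x@perSegment, asList)
  .writeOrReturn(obj, path)
})
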