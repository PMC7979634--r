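# Linear Turing analysis: sign structures, instability conditions,
# nondimensional reduction, critical diffusion ratio, wavenumber band,
# minimum domain length, dispersion relation, and suprema over regions.

#' Classify the Jacobian sign structure
#'
#' Turing-capable two-species Jacobians (with the convention f_u > 0) come in
#' two sign patterns: pure kinetics (+,-;+,-), for which the morphogen peaks
#' coincide, and cross kinetics (+,+;-,-), for which they are out of phase.
#'
#' @param J 2x2 numeric Jacobian.
#' @param tol entries with |x| < tol are treated as zero; such marginal cases
#'   classify as "none" and are flagged via the \code{"marginal"} attribute.
#' @return \code{"pure"}, \code{"cross"} or \code{"none"}, with a logical
#'   attribute \code{"marginal"}.
#' @export
classifySignStructure <- function(J, tol = 1e-9) {
  J <- as.matrix(J)
  if (!all(is.finite(J)) || any(dim(J) != c(2, 2)))
    stop("J must be a finite 2x2 matrix")
  marginal <- any(abs(J) < tol)
  s <- sign(J) * (abs(J) >= tol)
  out <- "none"
  if (!marginal && s[1, 1] > 0) {
    if (s[1, 2] < 0 && s[2, 1] > 0 && s[2, 2] < 0) out <- "pure"
    if (s[1, 2] > 0 && s[2, 1] < 0 && s[2, 2] < 0) out <- "cross"
  }
  structure(out, marginal = marginal)
}

#' Critical diffusion ratio
#'
#' Smallest diffusion ratio D = D_v/D_u at which the unstable wavenumber band
#' opens for the nondimensional system: Dc = (sqrt(F - G) + sqrt(F))^2.
#'
#' @param F,G nondimensional Jacobian magnitudes (see
#'   \linkS4class{NondimRD}); requires F > G.
#' @export
criticalDiffusion <- function(F, G) {
  if (!is.finite(F) || !is.finite(G)) stop("F and G must be finite")
  if (F <= G)
    stop("criticalDiffusion requires F > G (no Turing instability otherwise)")
  (sqrt(F - G) + sqrt(F))^2
}

# Vectorized Dc that tolerates the closed-region boundary F = G (where the
# band degenerates and Dc -> F); NA where F < G.
.DcVec <- function(F, G) {
  d <- F - G
  out <- ifelse(d >= 0, (sqrt(pmax(d, 0)) + sqrt(F))^2, NA_real_)
  out
}

#' Unstable wavenumber band
#'
#' Positive roots in k^2 of D k^4 - (D - G) k^2 + (F - G) = 0, the
#' nondimensional marginal-stability quadratic. Growth is positive exactly
#' strictly inside the band.
#'
#' @param F,G,D nondimensional groups.
#' @return numeric of length 2 (k2minus, k2plus), or \code{numeric(0)} when
#'   the discriminant is negative or no positive root exists. A degenerate
#'   band (repeated root) is returned as two equal values.
#' @export
wavenumberBand <- function(F, G, D) {
  disc <- (D - G)^2 - 4 * D * (F - G)
  if (disc < 0) return(numeric(0))
  r <- ((D - G) + c(-1, 1) * sqrt(disc)) / (2 * D)
  if (r[2] <= 0) return(numeric(0))
  r[1] <- max(r[1], 0)
  r
}

.kplus2Vec <- function(F, G, D) {
  disc <- (D - G)^2 - 4 * D * (F - G)
  kp <- ((D - G) + sqrt(pmax(disc, 0))) / (2 * D)
  kp[disc < 0 | kp <= 0] <- NA_real_
  kp
}

#' Minimum 1D domain length
#'
#' The smallest interval [0, L] on which the first cosine mode (k = pi/L)
#' enters the unstable band: Lc = pi / k_plus.
#'
#' @param F,G,D nondimensional groups.
#' @export
minDomainLength <- function(F, G, D) {
  band <- wavenumberBand(F, G, D)
  if (length(band) == 0)
    stop("no unstable band at this (F, G, D): no pattern, Lc undefined")
  pi / sqrt(band[2])
}

#' Dispersion relation of the nondimensional linearization
#'
#' For each squared wavenumber, the dominant Re eigenvalue of
#' \code{[[1 - k^2, sigma], [-sigma F, -G - D k^2]]} with sigma = +1 for cross
#' and -1 for pure kinetics (both sign structures share the same spectrum).
#'
#' @param F,G,D nondimensional groups.
#' @param kSquared grid of k^2 values (>= 0).
#' @param signType "cross" or "pure" (spectrum is identical; kept for the
#'   eigenvector phase).
#' @return a \linkS4class{DispersionResult}.
#' @export
dispersion <- function(F, G, D, kSquared, signType = c("cross", "pure")) {
  signType <- match.arg(signType)
  if (any(kSquared < 0)) stop("kSquared values must be >= 0")
  gr <- growthRate(F, G, D, kSquared)
  new("DispersionResult", kSquared = as.numeric(kSquared),
      growthRate = gr, kMax = kSquared[which.max(gr)])
}

# Dominant Re eigenvalue; vectorized over k2 (and over F, G for region scans).
growthRate <- function(F, G, D, k2) {
  tr <- (1 - k2) + (-G - D * k2)
  det <- (1 - k2) * (-G - D * k2) + F
  disc <- tr^2 - 4 * det
  ifelse(disc >= 0, (tr + sqrt(pmax(disc, 0))) / 2, tr / 2)
}

#' Wavelength of the fastest-growing mode
#'
#' 2 pi / k at the maximiser of the dispersion relation; used to size grids.
#' @param F,G,D nondimensional groups.
#' @export
patternWavelength <- function(F, G, D) {
  band <- wavenumberBand(F, G, D)
  if (length(band) == 0) return(NA_real_)
  opt <- optimize(function(k2) growthRate(F, G, D, k2),
                  interval = c(band[1], band[2]), maximum = TRUE)
  2 * pi / sqrt(opt$maximum)
}

# --- Turing condition reports ----------------------------------------------

.turingReportCore <- function(Du, Dv, fu, fv, gu, gv, L, tol) {
  tr <- fu + gv
  det <- fu * gv - fv * gu
  lhs6 <- Dv * fu + Du * gv
  rhs6 <- if (det > 0) 2 * sqrt(Du * Dv * det) else NA_real_
  scale <- max(abs(c(fu, fv, gu, gv, 1)))
  cond <- c(trace = tr < 0,
            det = det > 0,
            diffusion = det > 0 && lhs6 > rhs6,
            band = FALSE)
  marginal <- (abs(tr) <= tol * scale) || (abs(det) <= tol * scale^2) ||
    (det > 0 && abs(lhs6 - rhs6) <= tol * max(abs(lhs6), abs(rhs6), 1))

  disc <- lhs6^2 - 4 * Du * Dv * det
  band <- numeric(0)
  if (disc >= 0) {
    r <- (lhs6 + c(-1, 1) * sqrt(disc)) / (2 * Du * Dv)
    if (r[2] > 0 && r[1] < r[2]) band <- pmax(r, 0)
    if (length(band) == 2 && band[1] <= 0) band[1] <- .Machine$double.eps * band[2]
  }
  if (length(band) == 2 && band[1] >= band[2]) band <- numeric(0)

  modes <- integer(0)
  if (!is.null(L) && is.finite(L) && length(band) == 2) {
    kk <- sqrt(band)
    nlo <- floor(kk[1] * L / pi) + 1L
    nhi <- ceiling(kk[2] * L / pi) - 1L
    if (nhi >= nlo) modes <- seq.int(max(nlo, 1L), nhi)
    cond["band"] <- length(modes) > 0
  } else {
    cond["band"] <- NA
  }

  # critical diffusion ratio through the nondimensional reduction (defined
  # only for admissible sign structures with fu > 0)
  Dc <- NA_real_
  Lc <- NA_real_
  if (fu > 0 && det > 0) {
    Fn <- abs(gu) * abs(fv) / fu^2
    Gn <- abs(gv) / fu
    if (Fn > Gn) Dc <- (sqrt(Fn - Gn) + sqrt(Fn))^2
  }
  if (length(band) == 2 && band[2] > 0) Lc <- pi / sqrt(band[2])

  stable <- unname(cond["trace"] && cond["det"])
  driven <- unname(stable && cond["diffusion"] && length(band) == 2)
  new("TuringReport",
      stableWithoutDiffusion = stable,
      diffusionDriven = driven,
      band = band, Dc = Dc, Lc = Lc,
      admissibleModes = as.integer(modes),
      marginal = marginal, inequalities = cond)
}

#' @describeIn checkTuring dimensional form: evaluates the four classical
#'   inequalities (stability without diffusion, positive determinant,
#'   diffusion-driven destabilisation, and a domain admitting an unstable
#'   mode when L is given).
#' @export
setMethod("checkTuring", "DimensionalRD", function(x, L = NULL, tol = 1e-9) {
  if (is.null(L)) L <- if (is.finite(x@L)) x@L else NULL
  .turingReportCore(x@Du, x@Dv, x@fu, x@fv, x@gu, x@gv, L, tol)
})

#' @describeIn checkTuring nondimensional form (f_u = 1, D_u = 1).
#' @export
setMethod("checkTuring", "NondimRD", function(x, L = NULL, tol = 1e-9) {
  sgn <- if (x@signType == "cross") 1 else -1
  .turingReportCore(1, x@D, 1, sgn, -sgn * x@F, -x@G, L, tol)
})

#' @describeIn checkTuring convenience for a constructed
#'   \linkS4class{KineticSystem} at diffusion ratio \code{D}.
#' @param D diffusion ratio (KineticSystem method only).
#' @export
setMethod("checkTuring", "KineticSystem", function(x, L = NULL, tol = 1e-9, D = NULL) {
  if (is.null(D)) stop("supply the diffusion ratio D")
  J <- kineticsJacobian(x)
  .turingReportCore(1, D, J[1, 1], J[1, 2], J[2, 1], J[2, 2], L, tol)
})

#' Nondimensional reduction of a dimensional linearization
#'
#' Rescales time by 1/f_u and length by sqrt(D_u/f_u), collapsing the
#' linearization onto the three groups F = |g_u| |f_v| / f_u^2,
#' G = |g_v| / f_u, D = D_v / D_u.
#'
#' @param sys a \linkS4class{DimensionalRD}.
#' @return a \linkS4class{NondimRD}.
#' @export
nondimensionalize <- function(sys) {
  stopifnot(is(sys, "DimensionalRD"))
  if (sys@fu <= 0)
    stop("nondimensionalization uses the convention f_u > 0")
  st <- as.character(classifySignStructure(
    matrix(c(sys@fu, sys@gu, sys@fv, sys@gv), 2, 2)))
  if (st == "none")
    stop("Jacobian sign structure is neither pure nor cross")
  new("NondimRD",
      F = abs(sys@gu) * abs(sys@fv) / sys@fu^2,
      G = abs(sys@gv) / sys@fu,
      D = sys@Dv / sys@Du,
      signType = st,
      timeScale = 1 / sys@fu,
      lengthScale = sqrt(sys@Du / sys@fu))
}

# --- suprema over level-set regions ----------------------------------------

.regionQuantity <- function(region, quantity, D = NULL) {
  Ffun <- region@Ffun
  Gfun <- region@Gfun
  if (is.null(Ffun)) Ffun <- function(p) region@S(p) + 2
  if (is.null(Gfun)) Gfun <- function(p) rep(2, nrow(p))
  switch(quantity,
    S = function(p) region@S(p),
    F = function(p) Ffun(p),
    Dc = function(p) .DcVec(Ffun(p), Gfun(p)),
    Lc = function(p) {
      if (is.null(D)) stop("quantity 'Lc' needs the diffusion ratio D")
      pi / sqrt(.kplus2Vec(Ffun(p), Gfun(p), D))
    },
    stop("quantity must be one of S, F, Dc, Lc"))
}

#' Supremum of an analysis quantity over a level-set region
#'
#' Scans the closed region \{S(p) >= 0\} intersected with the bounding box on
#' a dense grid, then refines by repeatedly zooming a finer grid onto the
#' incumbent maximiser. Deterministic for a fixed resolution.
#'
#' @param region a \linkS4class{LevelSetRegion}.
#' @param quantity one of \code{"Dc"}, \code{"Lc"}, \code{"F"}, \code{"S"}.
#' @param D diffusion ratio (required for \code{"Lc"}).
#' @param resolution points per axis for the initial scan (defaults to the
#'   region's \code{gridResolution}).
#' @param refine number of zoom refinement rounds.
#' @return list with \code{value}, \code{arg} (named parameter point) and
#'   \code{quantity}.
#' @export
supOverRegion <- function(region, quantity = c("Dc", "Lc", "F", "S"),
                          D = NULL, resolution = NULL, refine = 4L) {
  stopifnot(is(region, "LevelSetRegion"))
  quantity <- match.arg(quantity)
  qfun <- .regionQuantity(region, quantity, D)
  if (is.null(resolution)) resolution <- region@gridResolution
  pn <- region@paramNames
  lo <- region@box[1, ]; hi <- region@box[2, ]

  scan <- function(lo, hi, res) {
    axes <- lapply(seq_along(pn), function(i) seq(lo[i], hi[i], length.out = res))
    p <- do.call(expand.grid, setNames(axes, pn))
    inside <- region@S(p) >= -1e-12
    if (!any(inside)) return(NULL)
    p <- p[inside, , drop = FALSE]
    q <- qfun(p)
    ok <- is.finite(q)
    if (!any(ok)) return(NULL)
    p <- p[ok, , drop = FALSE]; q <- q[ok]
    i <- which.max(q)
    list(value = q[i], arg = as.numeric(p[i, ]))
  }

  best <- scan(lo, hi, resolution)
  if (is.null(best))
    stop("region is empty (or the quantity undefined) within the bounding box")
  span <- (hi - lo) / (resolution - 1)
  for (r in seq_len(refine)) {
    lo2 <- pmax(lo, best$arg - 2 * span)
    hi2 <- pmin(hi, best$arg + 2 * span)
    cand <- scan(lo2, hi2, 41L)
    if (!is.null(cand) && cand$value >= best$value) best <- cand
    span <- (hi2 - lo2) / 40
  }
  list(value = best$value, arg = setNames(best$arg, pn), quantity = quantity)
}
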