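# Construction of polynomial kinetic systems realizing a prescribed Jacobian
# at a prescribed steady state, and their self-verification.

.terms <- function(coef, pu, pv) {
  keep <- coef != 0
  data.frame(coef = coef[keep], pu = pu[keep], pv = pv[keep])
}

# Evaluate f and g (including cubic and saturation guard) at u, v (vectors).
evalKinetics <- function(sys, u, v) {
  evalTerms <- function(tm) {
    out <- 0
    for (j in seq_len(nrow(tm)))
      out <- out + tm$coef[j] * u^tm$pu[j] * v^tm$pv[j]
    out + numeric(length(u))
  }
  f <- evalTerms(sys@fTerms)
  if (sys@cubic != 0) f <- f - sys@cubic * (u - sys@steadyState[1])^3
  if (sys@guardEps > 0)
    f <- f + sys@guardCoef * u^2 / (1 + sys@guardEps^2 * u^2)
  list(f = f, g = evalTerms(sys@gTerms))
}

# Analytic Jacobian of the polynomial part (guard handled analytically too).
kineticsJacobian <- function(sys, at = sys@steadyState) {
  u <- at[1]; v <- at[2]
  dTerms <- function(tm, wrt) {
    out <- 0
    for (j in seq_len(nrow(tm))) {
      if (wrt == "u" && tm$pu[j] > 0)
        out <- out + tm$coef[j] * tm$pu[j] * u^(tm$pu[j] - 1) * v^tm$pv[j]
      if (wrt == "v" && tm$pv[j] > 0)
        out <- out + tm$coef[j] * tm$pv[j] * u^tm$pu[j] * v^(tm$pv[j] - 1)
    }
    out
  }
  fu <- dTerms(sys@fTerms, "u") - 3 * sys@cubic * (u - sys@steadyState[1])^2
  if (sys@guardEps > 0) {
    e2 <- sys@guardEps^2
    fu <- fu + sys@guardCoef * 2 * u / (1 + e2 * u^2)^2
  }
  matrix(c(fu, dTerms(sys@gTerms, "u"),
           dTerms(sys@fTerms, "v"), dTerms(sys@gTerms, "v")), 2, 2)
}

#' Construct a raw kinetic system from monomial terms
#'
#' Low-level constructor; the \code{build*} family functions are the intended
#' entry points. Validity enforces that (U, V) is an exact root of f and g.
#'
#' @param fTerms,gTerms data.frames with columns coef, pu, pv.
#' @param steadyState numeric (U, V).
#' @param C cubic coefficient of the subtracted C (u - U)^3 term in f.
#' @param signType,family,params,alpha metadata (see
#'   \linkS4class{KineticSystem}).
#' @param targetJacobian declared Jacobian target used by
#'   \code{\link{verifyKinetics}}; computed analytically when missing.
#' @export
kineticSystem <- function(fTerms, gTerms, steadyState = c(1, 1), C = 0,
                          signType = "none", family = "custom",
                          params = list(), alpha = 2,
                          targetJacobian = NULL) {
  sys <- new("KineticSystem", fTerms = fTerms, gTerms = gTerms,
             cubic = as.numeric(C), steadyState = as.numeric(steadyState),
             signType = signType, family = family, params = params,
             alpha = as.numeric(alpha), eta = 1)
  if (is.null(targetJacobian)) targetJacobian <- kineticsJacobian(sys)
  sys@targetJacobian <- targetJacobian
  validObject(sys)
  sys
}

#' Construct kinetics with a prescribed (F, G) Jacobian
#'
#' Solves the coefficient constraints f(1,1) = g(1,1) = 0 with
#' f_u = 1, |f_v| = 1, |g_u| = F, g_v = -G on the monomial ansatz
#' f = a1 + b1 u + c1 u^alpha v (cross) or f = a1 + b1 u^alpha + c1 u v
#' (pure), g = a2 + b2 v + c2 u v.
#'
#' @param F,G target nondimensional groups (F, G > 0).
#' @param signType "cross" (f_v = +1, g_u = -F) or "pure" (f_v = -1,
#'   g_u = +F).
#' @param alpha exponent of the quadratic-order monomial (>= 2; positivity of
#'   the constant coefficient requires it).
#' @param C cubic coefficient (>= 0).
#' @param params parameter bindings recorded on the object.
#' @return a \linkS4class{KineticSystem} with Jacobian
#'   \code{[[1, sigma], [-sigma F, -G]]}.
#' @export
buildFromFG <- function(F, G, signType = c("cross", "pure"), alpha = 2, C = 0,
                        params = list()) {
  signType <- match.arg(signType)
  stopifnot(is.finite(F), is.finite(G), alpha >= 2)
  if (signType == "cross") {
    f <- .terms(coef = c(alpha - 2, 1 - alpha, 1),
                pu = c(0, 1, alpha), pv = c(0, 0, 1))
    g <- .terms(coef = c(G, F - G, -F), pu = c(0, 0, 1), pv = c(0, 1, 1))
    J <- matrix(c(1, -F, 1, -G), 2, 2)
  } else {
    f <- .terms(coef = c(1 - 2 / alpha, 2 / alpha, -1),
                pu = c(0, alpha, 1), pv = c(0, 0, 1))
    g <- .terms(coef = c(G, -(F + G), F), pu = c(0, 0, 1), pv = c(0, 1, 1))
    J <- matrix(c(1, F, -1, -G), 2, 2)
  }
  kineticSystem(f, g, steadyState = c(1, 1), C = C, signType = signType,
                family = signType, params = c(params, list(F = F, G = G)),
                alpha = alpha, targetJacobian = J)
}

#' Cross-kinetics level-set family
#'
#' f = -u + u^2 v, g = 2 + S v - (S + 2) u v: Turing-unstable (for large
#' enough D and L) exactly where S > 0, with u and v out of phase. Realises
#' F' = S + 1, G' = 1.
#'
#' @param S level-set value at the chosen parameter point.
#' @param alpha,C see \code{\link{buildFromFG}}.
#' @export
buildCross <- function(S, alpha = 2, C = 0) {
  stopifnot(is.finite(S))
  sys <- buildFromFG(S + 2, 2, "cross", alpha = alpha, C = C,
                     params = list(S = S))
  sys@family <- "cross"
  sys
}

#' Pure-kinetics level-set family
#'
#' f = u^2 - u v, g = 2 - (S + 4) v + (S + 2) u v: same Turing space as
#' \code{\link{buildCross}} but with u and v in phase.
#'
#' @inheritParams buildCross
#' @export
buildPure <- function(S, alpha = 2, C = 0) {
  stopifnot(is.finite(S))
  sys <- buildFromFG(S + 2, 2, "pure", alpha = alpha, C = C,
                     params = list(S = S))
  sys@family <- "pure"
  sys
}

#' Phase-switching family for the hyperbolic region
#'
#' f = -u + (4 - a) u^2 + (a - 3) u^2 v,
#' g = (b^2 + 1) + (3 - a) u v + (a - 4 - b^2) v. The Jacobian at (1, 1) is
#' \code{[[1, a - 3], [-(a - 3), -(b^2 + 1)]]}: pure for a < 3, cross for
#' a > 3, so the morphogen phase flips between the two branches of the
#' region. At a = 3 the u equation reduces to u^2 - u and blows up in finite
#' time; constructing it is refused unless the saturation guard is enabled or
#' \code{allowBlowUp = TRUE}.
#'
#' @param a,b region parameters.
#' @param C cubic coefficient.
#' @param saturate replace the (4 - a) u^2 term by
#'   (4 - a) u^2 / (1 + eps^2 u^2) (bounds growth; shifts the steady state
#'   and Jacobian by O(eps^2), which \code{\link{verifyKinetics}} records).
#' @param satEps guard epsilon.
#' @param allowBlowUp permit a = 3 without the guard.
#' @export
buildPhaseSwitching <- function(a, b, C = 0, saturate = FALSE, satEps = 0.05,
                                allowBlowUp = FALSE) {
  stopifnot(is.finite(a), is.finite(b))
  if (abs(a - 3) < 1e-12 && !saturate && !allowBlowUp)
    stop("a = 3 gives du/dt = u^2 - u + ... which blows up in finite time; ",
         "enable the saturation guard or allowBlowUp to proceed")
  fq <- if (saturate) 0 else (4 - a)
  f <- .terms(coef = c(-1, fq, a - 3), pu = c(1, 2, 2), pv = c(0, 0, 1))
  g <- .terms(coef = c(b^2 + 1, 3 - a, a - 4 - b^2),
              pu = c(0, 1, 0), pv = c(0, 1, 1))
  J <- matrix(c(1, -(a - 3), a - 3, -(b^2 + 1)), 2, 2)
  sys <- new("KineticSystem", fTerms = f, gTerms = g, cubic = as.numeric(C),
             steadyState = c(1, 1),
             signType = if (a < 3) "pure" else if (a > 3) "cross" else "none",
             family = "switching", params = list(a = a, b = b),
             alpha = 2, eta = 1, targetJacobian = J,
             guardEps = if (saturate) satEps else 0,
             guardCoef = if (saturate) (4 - a) else 0)
  validObject(sys)
  sys
}

#' Add (or replace) the spot/stripe-selecting cubic term
#'
#' Subtracts C (u - U)^3 from f. The term has zero value, slope and curvature
#' at the steady state, so the linear analysis is untouched; as C grows the
#' cubic nonlinearity dominates the quadratic one and simulations favour
#' stripes/labyrinths over spots.
#'
#' @param sys a \linkS4class{KineticSystem}.
#' @param C cubic coefficient (>= 0; negative values promote blow-up and are
#'   rejected).
#' @export
withCubic <- function(sys, C) {
  stopifnot(is(sys, "KineticSystem"))
  if (C < 0) stop("C must be >= 0 (a negative cubic promotes blow-up)")
  sys@cubic <- as.numeric(C)
  validObject(sys)
  sys
}

#' Cross-kinetics with an arbitrary positive steady state
#'
#' Solves the construction constraints around (U, V) instead of (1, 1), with
#' F' = S + 1 and G' = 1, on the ansatz f = a1 + b1 u + c1 u^2 v - C(u - U)^3,
#' g = a2 + b2 v + c2 u v:
#' a1 = V - U, b1 = (U - 2V)/U, c1 = 1/U^2, a2 = 2V,
#' b2 = (S U + 2U - 2V)/V, c2 = -(S + 2)/V. The Jacobian at (U, V) is
#' \code{[[1, 1], [-(S + 2), -2]]}.
#'
#' @param U,V steady state (> 0).
#' @param S level-set value.
#' @param C cubic coefficient.
#' @export
buildAtSteadyState <- function(U, V, S, C = 0) {
  if (U <= 0 || V <= 0) stop("U and V must be positive")
  f <- .terms(coef = c(V - U, (U - 2 * V) / U, 1 / U^2),
              pu = c(0, 1, 2), pv = c(0, 0, 1))
  g <- .terms(coef = c(2 * V, (S * U + 2 * U - 2 * V) / V, -(S + 2) / V),
              pu = c(0, 0, 1), pv = c(0, 1, 1))
  J <- matrix(c(1, -(S + 2), 1, -2), 2, 2)
  kineticSystem(f, g, steadyState = c(U, V), C = C, signType = "cross",
                family = "steadyState", params = list(U = U, V = V, S = S),
                targetJacobian = J)
}

#' @describeIn verifyKinetics numeric verification by 5-point central
#'   differences.
#' @export
setMethod("verifyKinetics", "KineticSystem", function(sys, tol = 1e-10) {
  ss <- sys@steadyState
  res <- evalKinetics(sys, ss[1], ss[2])
  h <- 1e-3
  d5 <- function(fn) {
    # 5-point stencil: exact for polynomials of degree <= 4
    du <- (-fn(ss[1] + 2 * h, ss[2]) + 8 * fn(ss[1] + h, ss[2]) -
             8 * fn(ss[1] - h, ss[2]) + fn(ss[1] - 2 * h, ss[2])) / (12 * h)
    dv <- (-fn(ss[1], ss[2] + 2 * h) + 8 * fn(ss[1], ss[2] + h) -
             8 * fn(ss[1], ss[2] - h) + fn(ss[1], ss[2] - 2 * h)) / (12 * h)
    c(du, dv)
  }
  J <- rbind(d5(function(u, v) evalKinetics(sys, u, v)$f),
             d5(function(u, v) evalKinetics(sys, u, v)$g))
  target <- sys@targetJacobian
  dev <- if (all(is.finite(target))) max(abs(J - target)) else NA_real_
  guardDrift <- if (sys@guardEps > 0)
    4 * abs(sys@guardCoef) * sys@guardEps^2 else 0
  effTol <- tol + 10 * guardDrift
  sgn <- classifySignStructure(J)
  pass <- abs(res$f) < effTol && abs(res$g) < effTol &&
    (is.na(dev) || dev < effTol)
  list(fResidual = abs(res$f), gResidual = abs(res$g),
       jacobian = J, jacobianDeviation = dev,
       signType = as.character(sgn), marginal = attr(sgn, "marginal"),
       guardDrift = guardDrift, pass = pass)
})

#' Recommend a diffusion ratio and domain size for a region
#'
#' \code{Drecommended} is the supremum over the closed region of the critical
#' diffusion ratio for the region's (F, G) parameterisation (for the
#' canonical level-set family this is sup (sqrt(S) + sqrt(S + 2))^2);
#' \code{Dconservative} is the simpler bound 4 sup F, which always exceeds
#' Dc; \code{LcSup} is the supremum of the minimum domain length at the
#' working diffusion ratio.
#'
#' @param region a \linkS4class{LevelSetRegion}.
#' @param D diffusion ratio at which to evaluate the minimum domain length
#'   (defaults to \code{Dconservative}).
#' @param resolution scan resolution.
#' @return list with Drecommended, Dconservative, LcSup, and the achieving
#'   parameter points.
#' @export
recommendDiffusion <- function(region, D = NULL, resolution = NULL) {
  supDc <- supOverRegion(region, "Dc", resolution = resolution)
  supF <- supOverRegion(region, "F", resolution = resolution)
  Dcons <- 4 * supF$value
  Dwork <- if (is.null(D)) Dcons else D
  supLc <- supOverRegion(region, "Lc", D = Dwork, resolution = resolution)
  supS <- supOverRegion(region, "S", resolution = resolution)
  list(Drecommended = supDc$value, DrecommendedAt = supDc$arg,
       Dconservative = Dcons, supS = supS$value,
       LcSup = supLc$value, LcSupAt = supLc$arg, D = Dwork,
       marginal = supS$value <= 0)
}

# Human-readable polynomial rendering used by show() and reports.
renderPoly <- function(terms, C = 0, U = 1, guardEps = 0, guardCoef = 0) {
  mono <- function(pu, pv) {
    s <- c(if (pu == 1) "u" else if (pu > 1) sprintf("u^%d", pu),
           if (pv == 1) "v" else if (pv > 1) sprintf("v^%d", pv))
    paste(s, collapse = " ")
  }
  parts <- character(0)
  for (j in seq_len(nrow(terms))) {
    cf <- terms$coef[j]
    m <- mono(terms$pu[j], terms$pv[j])
    txt <- if (m == "") sprintf("%.6g", cf)
      else if (cf == 1) m else if (cf == -1) paste0("-", m)
      else sprintf("%.6g %s", cf, m)
    parts <- c(parts, txt)
  }
  if (guardEps > 0 && guardCoef != 0)
    parts <- c(parts, sprintf("%.6g u^2/(1 + %.3g u^2)", guardCoef, guardEps^2))
  if (C != 0)
    parts <- c(parts, sprintf("-%.6g (u - %.6g)^3", C, U))
  if (!length(parts)) return("0")
  out <- parts[1]
  for (p in parts[-1])
    out <- if (startsWith(p, "-")) paste(out, "-", substring(p, 2))
      else paste(out, "+", p)
  out
}
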