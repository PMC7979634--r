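# Level-set parameter regions and shipped presets.

#' Construct a level-set parameter region
#'
#' @param S function of a data.frame (columns named by \code{paramNames})
#'   returning the level-set values; the Turing space is \{S > 0\}.
#' @param paramNames ordered parameter names.
#' @param box finite per-parameter bounds: a 2 x n matrix (rows min, max) or a
#'   list of length-2 numeric ranges.
#' @param gridResolution points per axis used by \code{\link{supOverRegion}}.
#' @param Ffun,Gfun optional parameterisation of the nondimensional groups at
#'   each point; default is the canonical level-set family F = S + 2, G = 2.
#' @return a \linkS4class{LevelSetRegion}.
#' @export
levelSetRegion <- function(S, paramNames, box, gridResolution = 401L,
                           Ffun = NULL, Gfun = NULL) {
  if (is.list(box)) box <- vapply(box, function(b) as.numeric(b[1:2]), numeric(2))
  box <- as.matrix(box)
  rownames(box) <- c("min", "max")
  colnames(box) <- paramNames
  new("LevelSetRegion", S = S, paramNames = paramNames, box = box,
      gridResolution = as.integer(gridResolution), Ffun = Ffun, Gfun = Gfun)
}

#' Circular parameter region preset
#'
#' The unit disc S(a, b) = 1 - a^2 - b^2 with the direct parameterisation
#' F = 2 - a^2, G = 1 + b^2 (so F' = 1 - a^2, G' = b^2). The supremum of the
#' critical diffusion ratio over the closed disc is (1 + sqrt(2))^2, attained
#' at the origin.
#'
#' @param gridResolution points per axis for suprema scans.
#' @export
circleRegion <- function(gridResolution = 401L) {
  levelSetRegion(
    S = function(p) 1 - p$a^2 - p$b^2,
    paramNames = c("a", "b"),
    box = list(a = c(-1, 1), b = c(-1, 1)),
    gridResolution = gridResolution,
    Ffun = function(p) 2 - p$a^2,
    Gfun = function(p) 1 + p$b^2)
}

#' Non-contiguous hyperbolic parameter region preset
#'
#' The two-branch region (a - 3)^2 - b^2 >= 1 with a, b > 0, restricted to a
#' finite box, with F = (a - 3)^2 and G = b^2 + 1. The left branch (a < 3)
#' carries pure kinetics and the right branch (a > 3) cross kinetics in the
#' phase-switching family.
#'
#' @param aMax,bMax box bounds.
#' @param gridResolution points per axis for suprema scans.
#' @export
hyperbolicRegion <- function(aMax = 6, bMax = 4, gridResolution = 401L) {
  levelSetRegion(
    S = function(p) (p$a - 3)^2 - p$b^2 - 1,
    paramNames = c("a", "b"),
    box = list(a = c(0, aMax), b = c(0, bMax)),
    gridResolution = gridResolution,
    Ffun = function(p) (p$a - 3)^2,
    Gfun = function(p) p$b^2 + 1)
}
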