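# Classification of simulated patterns: amplitude/homogeneity, 1D mode
# counting, 2D spots-versus-stripes via connected-component shape
# statistics, morphogen phase relation, and per-segment reports.

#' Pattern amplitude
#'
#' max - min of a field over the grid; the patterned/homogeneous decision is
#' a threshold on this quantity.
#' @param field numeric vector or matrix.
#' @export
amplitude <- function(field) {
  if (!all(is.finite(field))) stop("field must be finite")
  diff(range(field))
}

#' Count 1D pattern modes
#'
#' The cosine mode cos(n pi x / L) compatible with zero-flux boundaries has
#' exactly n sign changes about its mean, so modes are counted as sign
#' changes of field - mean(field), which (unlike peak counting) registers a
#' half-cosine boundary peak as mode one. Excursions below \code{ampFloor}
#' are ignored.
#'
#' @param field 1D field.
#' @param hetTol amplitude below which the field counts as homogeneous
#'   (returns 0).
#' @param ampFloor excursion floor; default a tenth of the amplitude.
#' @export
countModes1D <- function(field, hetTol = 0.05, ampFloor = NULL) {
  field <- as.numeric(field)
  if (amplitude(field) < hetTol) return(0L)
  s <- field - mean(field)
  if (is.null(ampFloor)) ampFloor <- 0.1 * amplitude(field)
  s <- s[abs(s) >= ampFloor]
  if (length(s) < 2) return(0L)
  sum(diff(sign(s)) != 0)
}

#' Phase relation between the two morphogens
#'
#' Pearson correlation of the centred fields: pure-kinetics patterns are in
#' phase (peaks aligned), cross-kinetics patterns out of phase.
#'
#' @param u,v same-shape fields.
#' @param phaseTol |correlation| needed for a call.
#' @param hetTol amplitude below which the phase is indeterminate.
#' @return "in_phase", "out_of_phase" or "indeterminate", with the
#'   correlation as attribute \code{"correlation"}.
#' @export
phaseRelation <- function(u, v, phaseTol = 0.5, hetTol = 0.05) {
  stopifnot(length(u) == length(v))
  if (amplitude(u) < hetTol || amplitude(v) < hetTol)
    return(structure("indeterminate", correlation = NA_real_))
  r <- cor(as.numeric(u) - mean(u), as.numeric(v) - mean(v))
  out <- if (!is.finite(r)) "indeterminate"
    else if (r >= phaseTol) "in_phase"
    else if (r <= -phaseTol) "out_of_phase"
    else "indeterminate"
  structure(out, correlation = r)
}

# Connected components of a logical matrix (8-connectivity) with area,
# perimeter (boundary pixel count), bounding box. Labelling via EBImage.
.componentStats <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  n <- max(lab)
  if (n == 0) return(data.frame(area = numeric(0), perimeter = numeric(0),
                                circ = numeric(0), w = numeric(0),
                                h = numeric(0)))
  # boundary pixels: in-component pixels with a 4-neighbour outside (or on
  # the image edge)
  pad <- matrix(0L, nrow(lab) + 2, ncol(lab) + 2)
  pad[2:(nrow(lab) + 1), 2:(ncol(lab) + 1)] <- lab
  core <- pad[2:(nrow(lab) + 1), 2:(ncol(lab) + 1)]
  nb <- (pad[1:nrow(lab), 2:(ncol(lab) + 1)] == core) &
        (pad[3:(nrow(lab) + 2), 2:(ncol(lab) + 1)] == core) &
        (pad[2:(nrow(lab) + 1), 1:ncol(lab)] == core) &
        (pad[2:(nrow(lab) + 1), 3:(ncol(lab) + 2)] == core)
  boundary <- core > 0 & !nb
  idx <- which(lab > 0, arr.ind = TRUE)
  labs <- lab[lab > 0]
  area <- tabulate(labs, n)
  per <- tabulate(lab[boundary], n)
  w <- tapply(idx[, 1], labs, function(z) diff(range(z)) + 1)
  h <- tapply(idx[, 2], labs, function(z) diff(range(z)) + 1)
  per <- pmax(per, 1)
  data.frame(area = area, perimeter = per,
             circ = pmin(4 * pi * area / per^2, 1),
             w = as.numeric(w), h = as.numeric(h))
}

#' Classify a 2D field as spots, stripes, mixed or homogeneous
#'
#' Thresholds the field at its mean, labels connected components of the high
#' phase (8-connectivity) and computes per-component circularity
#' 4 pi A / P^2 (clamped at 1). Spots: median circularity >= spotTol and no
#' component spanning the domain; stripes: median circularity < stripeTol or
#' a component extending beyond three pattern wavelengths; mixed otherwise.
#' The decision is invariant under positive affine rescaling of the field
#' and under 90-degree rotation.
#'
#' @param field 2D matrix.
#' @param hetTol homogeneity amplitude threshold.
#' @param spotTol,stripeTol circularity thresholds.
#' @param wavelength expected pattern wavelength in node units (optional;
#'   enables the elongation rule).
#' @param thresholdAt threshold level (defaults to the field mean).
#' @return a \linkS4class{PatternReport}.
#' @export
classify2D <- function(field, hetTol = 0.05, spotTol = 0.6, stripeTol = 0.4,
                       wavelength = NULL, thresholdAt = NULL) {
  stopifnot(is.matrix(field))
  amp <- amplitude(field)
  dg <- list(hetTol = hetTol, spotTol = spotTol, stripeTol = stripeTol)
  if (amp < hetTol)
    return(new("PatternReport", amplitude = amp,
               classification = "homogeneous", diagnostics = dg))
  if (is.null(thresholdAt)) thresholdAt <- mean(field)
  stats <- .componentStats(field > thresholdAt)
  # ignore fragments too small to have a shape
  stats <- stats[stats$area >= 4, , drop = FALSE]
  if (nrow(stats) == 0)
    return(new("PatternReport", amplitude = amp,
               classification = "homogeneous", diagnostics = dg))
  medCirc <- median(stats$circ)
  spans <- any(stats$w >= nrow(field)) || any(stats$h >= ncol(field))
  elongated <- if (!is.null(wavelength))
    any(pmax(stats$w, stats$h) > 3 * wavelength) else FALSE
  cls <- if (medCirc >= spotTol && !spans) "spots"
    else if (medCirc < stripeTol || elongated || spans) "stripes"
    else "mixed"
  dg$nComponents <- nrow(stats)
  dg$medianCircularity <- medCirc
  dg$spans <- spans
  new("PatternReport", amplitude = amp, classification = cls,
      diagnostics = dg)
}

#' Classify a simulation result
#'
#' 1D results get a mode count; 2D results the spots/stripes call; both get
#' the u-v phase relation.
#'
#' @param result a \linkS4class{SimResult}.
#' @param hetTol,spotTol,stripeTol,phaseTol classifier tolerances.
#' @param wavelength optional expected wavelength in node units.
#' @return a \linkS4class{PatternReport}.
#' @export
classifyPattern <- function(result, hetTol = 0.05, spotTol = 0.6,
                            stripeTol = 0.4, phaseTol = 0.5,
                            wavelength = NULL) {
  stopifnot(is(result, "SimResult"))
  phase <- phaseRelation(result@u, result@v, phaseTol, hetTol)
  if (ncol(result@u) == 1L) {
    amp <- amplitude(result@u)
    n <- countModes1D(result@u, hetTol)
    cls <- if (amp < hetTol) "homogeneous"
      else "spots"  # 1D heterogeneity: peaks/troughs; reported via nModes
    rpt <- new("PatternReport", amplitude = amp, classification = cls,
               nModes = as.numeric(n), phase = as.character(phase),
               diagnostics = list(hetTol = hetTol,
                                  correlation = attr(phase, "correlation")))
  } else {
    rpt <- classify2D(result@u, hetTol, spotTol, stripeTol, wavelength)
    rpt@phase <- as.character(phase)
    rpt@diagnostics$correlation <- attr(phase, "correlation")
  }
  rpt
}

#' Classify independently within each segment of a prepattern
#'
#' Runs the 2D classifier on each labelled region (components clipped at the
#' segment boundary; the threshold uses the segment's own mean), so mixed
#' prepatterns can be checked region by region. Segments smaller than four
#' squared pattern wavelengths are flagged low-confidence.
#'
#' @param u field to classify (matrix in grid layout).
#' @param seg a \linkS4class{SegmentMap} aligned to the grid.
#' @param v optional second field for per-segment phase.
#' @param hetTol,spotTol,stripeTol classifier tolerances.
#' @param wavelength optional wavelength in node units (enables both the
#'   elongation rule and the confidence flag).
#' @return a \linkS4class{PatternReport} whose \code{perSegment} holds one
#'   sub-report per label.
#' @export
classifyBySegment <- function(u, seg, v = NULL, hetTol = 0.05, spotTol = 0.6,
                              stripeTol = 0.4, wavelength = NULL) {
  stopifnot(is(seg, "SegmentMap"), all(dim(u) == dim(seg@labels)))
  labs <- sort(unique(as.vector(seg@labels)))
  per <- list()
  for (lb in labs) {
    mask <- seg@labels == lb
    sub <- u
    segMean <- mean(u[mask])
    # clip components at the segment boundary by pushing the outside below
    # the threshold
    sub[!mask] <- segMean - 2 * max(abs(u - segMean))
    subAmp <- amplitude(u[mask])
    r <- if (subAmp < hetTol)
      new("PatternReport", amplitude = subAmp, classification = "homogeneous")
    else {
      rr <- classify2D(sub, hetTol, spotTol, stripeTol, wavelength,
                       thresholdAt = segMean)
      rr@amplitude <- subAmp
      rr
    }
    if (!is.null(v)) r@phase <- as.character(
      phaseRelation(u[mask], v[mask], hetTol = hetTol))
    if (!is.null(wavelength))
      r@diagnostics$lowConfidence <- sum(mask) < 4 * wavelength^2
    per[[as.character(lb)]] <- r
  }
  top <- classify2D(u, hetTol, spotTol, stripeTol, wavelength)
  top@perSegment <- per
  if (!is.null(v)) top@phase <- as.character(phaseRelation(u, v, hetTol = hetTol))
  top
}
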