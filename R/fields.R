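# Spatiotemporal parameter heterogeneity: grids, smoothed spatial steps,
# temporal square-wave schedules, image-derived prepatterns and synthetic
# fixture images.

#' Construct a simulation grid
#'
#' @param nx,ny node counts (ny = 1 for a 1D interval).
#' @param Lx,Ly physical extents.
#' @return a \linkS4class{Grid2D}.
#' @export
makeGrid <- function(nx, Lx, ny = 1L, Ly = 0) {
  new("Grid2D", nx = as.integer(nx), ny = as.integer(ny),
      Lx = as.numeric(Lx), Ly = as.numeric(Ly))
}

gridCoords <- function(grid) {
  x <- seq(0, grid@Lx, length.out = grid@nx)
  y <- if (grid@ny == 1L) 0 else seq(0, grid@Ly, length.out = grid@ny)
  list(x = x, y = y)
}

gridSpacing <- function(grid) {
  hx <- grid@Lx / (grid@nx - 1)
  hy <- if (grid@ny == 1L) NA_real_ else grid@Ly / (grid@ny - 1)
  c(hx = hx, hy = hy)
}

#' Construct a parameter field
#'
#' @param name parameter symbol the field binds.
#' @param values scalar, vector (1D) or nx x ny matrix of per-node values.
#' @param schedule optional time program from \code{\link{timeSquareWave}} or
#'   \code{\link{piecewiseSchedule}}.
#' @return a \linkS4class{ParamField}.
#' @export
paramField <- function(name, values, schedule = NULL) {
  dm <- if (is.matrix(values)) dim(values) else c(length(values), 1L)
  new("ParamField", name = name, values = as.numeric(values),
      dim = as.integer(dm),
      schedule = if (is.null(schedule)) NULL else unclass(schedule))
}

fieldValues <- function(field, grid = NULL) {
  v <- field@values
  if (length(v) == 1L && !is.null(grid)) v <- rep(v, grid@nx * max(grid@ny, 1L))
  v
}

#' Smoothed spatial step (tanh profile)
#'
#' value = low + (high - low) (1 + tanh((coord - center)/width)) / 2 along the
#' chosen axis; monotone, attaining (low + high)/2 at the center. width = 1
#' gives the sharp-but-smooth interface used for stripe/spot half-domains.
#'
#' @param grid a \linkS4class{Grid2D}.
#' @param axis "x" or "y".
#' @param center interface position.
#' @param width transition width (> 0), in the same units as the axis.
#' @param low,high limiting values.
#' @param name parameter symbol to bind (default "C").
#' @return a \linkS4class{ParamField}.
#' @export
tanhStep <- function(grid, axis = c("x", "y"), center, width = 1,
                     low = 0, high = 2, name = "C") {
  axis <- match.arg(axis)
  if (width <= 0) stop("width must be > 0")
  co <- gridCoords(grid)
  coord <- if (axis == "x") co$x else co$y
  prof <- low + (high - low) * (1 + tanh((coord - center) / width)) / 2
  vals <- if (grid@ny == 1L) matrix(prof, ncol = 1L)
    else if (axis == "x") matrix(prof, grid@nx, grid@ny)
    else matrix(rep(prof, each = grid@nx), grid@nx, grid@ny)
  paramField(name, vals)
}

#' Temporal square-wave schedule
#'
#' Alternates between two value sets in epochs of length period/2, starting
#' (at t = 0) from the first set, matching a Heaviside-of-cosine switch
#' H(cos(2 pi t / period)) that is 1 on the first half-period.
#'
#' @param period full oscillation period (> 0); with period 6000 the
#'   parameters switch every 3000 time units.
#' @param phaseValues list of two value sets (scalars, vectors or field
#'   matrices): the first is active on [0, period/2), the second on
#'   [period/2, period), and so on (right-open intervals).
#' @return a schedule object usable as the \code{schedule} of a
#'   \code{\link{paramField}}.
#' @export
timeSquareWave <- function(period, phaseValues) {
  if (period <= 0) stop("period must be > 0")
  stopifnot(length(phaseValues) == 2L)
  structure(list(type = "square", period = period,
                 phases = lapply(phaseValues, as.numeric)),
            class = "rdSchedule")
}

#' Piecewise-constant schedule
#'
#' @param times strictly increasing switch times (the first epoch starts at
#'   t = 0).
#' @param valuesList value sets per epoch, one more than \code{times}; the
#'   last set holds for all later times.
#' @export
piecewiseSchedule <- function(times, valuesList) {
  if (length(times) && any(diff(times) <= 0))
    stop("schedule times must be strictly increasing")
  stopifnot(length(valuesList) == length(times) + 1L)
  structure(list(type = "piecewise", times = as.numeric(times),
                 phases = lapply(valuesList, as.numeric)),
            class = "rdSchedule")
}

#' Evaluate a schedule at a time point
#'
#' Epoch intervals are right-open: the value returned at a switch time is the
#' new epoch's.
#'
#' @param schedule an \code{rdSchedule}.
#' @param t time.
#' @export
scheduleValues <- function(schedule, t) {
  if (schedule$type == "square") {
    k <- floor(2 * t / schedule$period) %% 2
    schedule$phases[[k + 1L]]
  } else {
    i <- findInterval(t, schedule$times, left.open = FALSE) + 1L
    schedule$phases[[min(i, length(schedule$phases))]]
  }
}

# Switch times strictly inside (0, T].
scheduleSwitchTimes <- function(schedule, T) {
  if (is.null(schedule)) return(numeric(0))
  if (schedule$type == "square") {
    half <- schedule$period / 2
    n <- floor(T / half)
    if (n < 1) numeric(0) else seq_len(n) * half
  } else {
    schedule$times[schedule$times > 0 & schedule$times <= T]
  }
}

# --- images -----------------------------------------------------------------

#' Read a grayscale image (PNG or PGM)
#'
#' @param path file path; format chosen by extension.
#' @param convert collapse RGB input to luminance; without it multi-channel
#'   input is an error.
#' @return numeric matrix in image convention (row 1 = top), intensities in
#'   [0, 1].
#' @export
readGrayImage <- function(path, convert = FALSE) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "pgm") return(readPGM(path))
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) {
    if (!convert)
      stop("multi-channel image; pass convert = TRUE to reduce to luminance")
    img <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  }
  img
}

#' Read a PGM (P2 ascii or P5 binary) grayscale image
#'
#' @param path file path.
#' @return numeric matrix (row 1 = top), intensities normalised to [0, 1].
#' @export
readPGM <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readToken <- function() {
    tok <- ""
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0 || ch == "") stop("unexpected end of PGM header")
      if (ch == "#") { repeat { c2 <- readChar(con, 1L, useBytes = TRUE)
        if (!length(c2) || c2 == "\n") break }; next }
      if (grepl("[[:space:]]", ch)) { if (nzchar(tok)) return(tok) else next }
      tok <- paste0(tok, ch)
    }
  }
  magic <- readToken()
  if (!magic %in% c("P2", "P5")) stop("not a PGM (P2/P5) file")
  w <- as.integer(readToken()); h <- as.integer(readToken())
  maxv <- as.integer(readToken())
  if (magic == "P5") {
    raw <- readBin(con, "integer", n = w * h, size = 1L, signed = FALSE)
    m <- matrix(raw, nrow = h, ncol = w, byrow = TRUE)
  } else {
    txt <- readLines(con, warn = FALSE)
    vals <- as.integer(unlist(strsplit(paste(txt, collapse = " "), "[[:space:]]+")))
    vals <- vals[!is.na(vals)]
    if (length(vals) < w * h) stop("truncated PGM data")
    m <- matrix(vals[seq_len(w * h)], nrow = h, ncol = w, byrow = TRUE)
  }
  m / maxv
}

#' Write a plain-text PGM (P2) grayscale image
#'
#' @param img numeric matrix; values in [0, 1] are scaled to maxval, larger
#'   values are taken as already being on [0, maxval].
#' @param path output path.
#' @param maxval maximum gray value.
#' @export
writePGM <- function(img, path, maxval = 255L) {
  m <- img
  if (max(m) <= 1) m <- m * maxval
  m <- round(m)
  lines <- c("P2", sprintf("%d %d", ncol(m), nrow(m)), as.character(maxval),
             apply(m, 1, paste, collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' Segment a grayscale image by intensity thresholds
#'
#' Labels run from 0 for the brightest class to nLevels - 1 for the darkest
#' (so on a portrait-style prepattern: 0 = white, 1 = grey, 2 = black).
#'
#' @param image numeric matrix (image convention, row 1 = top); intensities
#'   on [0, 1] (thresholds given above 1 are interpreted on a 0-255 scale).
#' @param nLevels number of classes.
#' @param thresholds strictly increasing cut points, length nLevels - 1;
#'   default: k-quantiles of the intensity distribution.
#' @param grid optional \linkS4class{Grid2D}: resample to the grid by
#'   nearest neighbour, with image row 1 mapped to y = Ly.
#' @return a \linkS4class{SegmentMap} (labels in grid layout when a grid is
#'   given, otherwise image layout transposed to nx x ny with x = columns of
#'   the image and y increasing upwards).
#' @export
imageToSegments <- function(image, nLevels, thresholds = NULL, grid = NULL) {
  if (length(dim(image)) != 2L)
    stop("image must be a single-channel matrix (see readGrayImage(convert=))")
  if (max(image) > 1) image <- image / 255
  if (is.null(thresholds)) {
    thresholds <- quantile(image, probs = seq_len(nLevels - 1) / nLevels,
                           names = FALSE)
  }
  if (any(thresholds > 1)) thresholds <- thresholds / 255
  if (length(thresholds) != nLevels - 1L || any(diff(thresholds) <= 0))
    stop("need nLevels - 1 strictly increasing thresholds")
  lab <- (nLevels - 1L) - matrix(findInterval(image, thresholds),
                                 nrow(image), ncol(image))
  counts <- tabulate(lab + 1L, nbins = nLevels)
  if (any(counts == 0))
    warning("empty segmentation level(s): ",
            paste(which(counts == 0) - 1L, collapse = ", "))
  labGrid <- imageToFieldLayout(lab, grid)
  new("SegmentMap", labels = labGrid, thresholds = thresholds,
      nLevels = as.integer(nLevels))
}

# Image (row 1 = top) -> field layout (nx x ny, y increasing upward),
# nearest-neighbour resampling when a grid is given.
imageToFieldLayout <- function(img, grid = NULL) {
  nr <- nrow(img); nc <- ncol(img)
  if (is.null(grid)) {
    # flip rows so column index = x, row index = y upward, then transpose
    return(t(img[nr:1, , drop = FALSE]))
  }
  co <- gridCoords(grid)
  col <- pmin(pmax(round(co$x / grid@Lx * (nc - 1)) + 1L, 1L), nc)
  ny <- max(grid@ny, 1L)
  yy <- if (grid@ny == 1L) 0 else co$y
  Ly <- if (grid@ny == 1L) 1 else grid@Ly
  row <- pmin(pmax(round((1 - yy / Ly) * (nr - 1)) + 1L, 1L), nr)
  m <- img[row, col, drop = FALSE]
  t(m[seq_len(ny), , drop = FALSE])
}

#' Map segment labels to parameter fields
#'
#' @param seg a \linkS4class{SegmentMap}.
#' @param mapping named list: names are labels ("0", "1", ...), values are
#'   named numeric vectors of parameter values, e.g.
#'   \code{list("0" = c(C = 0, a = 1), "1" = c(C = 0.4, a = 6))}. Every label
#'   present in the map must be covered.
#' @return named list of \linkS4class{ParamField}s, one per parameter.
#' @export
segmentsToParams <- function(seg, mapping) {
  labs <- sort(unique(as.vector(seg@labels)))
  missing <- setdiff(as.character(labs), names(mapping))
  if (length(missing))
    stop("mapping misses label(s): ", paste(missing, collapse = ", "))
  pnames <- unique(unlist(lapply(mapping, names)))
  out <- list()
  for (pn in pnames) {
    vals <- matrix(NA_real_, nrow(seg@labels), ncol(seg@labels))
    for (lb in labs) {
      mv <- mapping[[as.character(lb)]]
      if (!pn %in% names(mv))
        stop("mapping for label ", lb, " misses parameter ", pn)
      vals[seg@labels == lb] <- mv[[pn]]
    }
    out[[pn]] <- paramField(pn, vals)
  }
  out
}

#' Preset label mapping for mixed spot/stripe/inverse prepatterns
#'
#' Three-level portrait-style mapping: black regions get spots (C = 1,
#' a = 1), white regions stripes (C = 0, a = 1), grey regions inverse
#' (out-of-phase) patterns (C = 0.4, a = 6). Labels: 0 = white, 1 = grey,
#' 2 = black.
#' @export
mixedPatternMapping <- function() {
  list("0" = c(C = 0, a = 1), "1" = c(C = 0.4, a = 6), "2" = c(C = 1, a = 1))
}

#' Preset label mapping for the prepattern-preserving recipe
#'
#' Outer (white) region Turing-unstable with spots (S = 1, C = 0), grey
#' border labyrinthine (S = 1, C = 2), inner detailed region pinned to the
#' heterogeneous state (S = -1, C = 20). Labels: 0 = white, 1 = grey,
#' 2 = dark interior.
#' @export
prepatternMapping <- function() {
  list("0" = c(S = 1, C = 0), "1" = c(S = 1, C = 2), "2" = c(S = -1, C = 20))
}

#' Inverse-intensity steady-state field
#'
#' U(x) = low + (high - low) (1 - I(x)) for normalised intensity I: white
#' pixels map to \code{low}, the darkest (I = 0) to \code{high}.
#'
#' @param image numeric matrix, intensities in [0, 1] (image convention).
#' @param low,high steady-state values (> 0).
#' @param grid optional grid for resampling.
#' @return a \linkS4class{ParamField} named "U".
#' @export
intensityToSteadyState <- function(image, low = 1, high = 11, grid = NULL) {
  if (low <= 0 || high <= 0) stop("low and high must be positive")
  if (max(image) > 1) image <- image / 255
  vals <- imageToFieldLayout(low + (high - low) * (1 - image), grid)
  paramField("U", vals)
}

#' Deterministic synthetic fixture image
#'
#' Draws rectangles and discs of given intensity classes on a uniform
#' background; later shapes overwrite earlier ones (draw order resolves
#' overlaps). A stand-in generator for photographic prepatterns, used by the
#' image-pipeline tests; no image assets are shipped.
#'
#' @param width,height image size in pixels.
#' @param background background intensity (0-255).
#' @param shapes list of shapes: \code{list(type = "rect", x = c(x0, x1),
#'   y = c(y0, y1), intensity = )} with x, y in pixels from the top-left
#'   corner, or \code{list(type = "disc", center = c(cx, cy), radius = ,
#'   intensity = )}.
#' @return numeric matrix (image convention, row 1 = top), values 0-255.
#' @export
makeFixtureImage <- function(width, height, background = 255, shapes = list()) {
  img <- matrix(background, nrow = height, ncol = width)
  cx <- matrix(rep(seq_len(width), each = height), height, width)
  cy <- matrix(rep(seq_len(height), width), height, width)
  for (sh in shapes) {
    if (sh$type == "rect") {
      rows <- pmax(1, sh$y[1]):pmin(height, sh$y[2])
      cols <- pmax(1, sh$x[1]):pmin(width, sh$x[2])
      img[rows, cols] <- sh$intensity
    } else if (sh$type == "disc") {
      mask <- (cx - sh$center[1])^2 + (cy - sh$center[2])^2 <= sh$radius^2
      img[mask] <- sh$intensity
    } else stop("unknown shape type: ", sh$type)
  }
  img
}
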