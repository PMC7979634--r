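# Shared fixtures: small grids and short-horizon configurations for unit
# tests (the full stopping protocol is exercised in the acceptance suite),
# plus constructed 2D fields with known shape classes.

quickConfig <- function(D, grid, seed = 1L, tEnd = 200, ...) {
  simConfig(D = D, grid = grid, seed = seed, tMin = tEnd, tMax = tEnd, ...)
}

# sinusoidal stripe field on an n x n grid
stripeField <- function(n = 80, waves = 3) {
  x <- seq(0, waves * 2 * pi, length.out = n)
  outer(sin(x), rep(1, n))
}

# lattice of Gaussian bumps on [-1, 1]^2
bumpField <- function(n = 80, spacing = 0.4, width = 0.005) {
  cx <- seq(-1, 1, length.out = n)
  centers <- seq(-0.8, 0.8, by = spacing)
  f <- matrix(0, n, n)
  for (a in centers) for (b in centers)
    f <- f + outer(cx, cx, function(x, y) exp(-((x - a)^2 + (y - b)^2) / width))
  f
}

# dominant eigenvalue of the dimensional linearization at a given k^2
dimGrowth <- function(Du, Dv, fu, fv, gu, gv, k2) {
  M <- matrix(c(fu - Du * k2, fv, gu, gv - Dv * k2), 2, 2, byrow = TRUE)
  max(Re(eigen(M, only.values = TRUE)$values))
}
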