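# Linear Turing analysis: sign structures, instability conditions, critical
# diffusion, wavenumber band, minimum domain, dispersion, region suprema.

test_that("Jacobian sign structures classify as pure, cross or none", {
  expect_equal(as.character(classifySignStructure(
    matrix(c(1, -3, 1, -2), 2, 2))), "cross")
  expect_equal(as.character(classifySignStructure(
    matrix(c(1, 3, -1, -2), 2, 2))), "pure")
  # f_u <= 0 is outside the convention
  expect_equal(as.character(classifySignStructure(
    matrix(c(-1, 1, 1, -2), 2, 2))), "none")
  # near-zero entry flags marginality and refuses a call
  m <- classifySignStructure(matrix(c(1, -3, 1e-12, -2), 2, 2))
  expect_equal(as.character(m), "none")
  expect_true(attr(m, "marginal"))
  expect_error(classifySignStructure(matrix(c(1, NA, 1, -2), 2, 2)), "finite")
})

test_that("critical diffusion ratio matches closed form and a bisection oracle", {
  expect_equal(criticalDiffusion(2, 1), (1 + sqrt(2))^2, tolerance = 1e-12)
  expect_equal(criticalDiffusion(9, 1), 17 + 12 * sqrt(2), tolerance = 1e-12)
  expect_error(criticalDiffusion(2, 2), "F > G")
  # oracle: bisection on D for where the max growth rate crosses zero
  maxGrowth <- function(F, G, D)
    optimize(function(k2) turingkit:::growthRate(F, G, D, k2),
             c(0, 5), maximum = TRUE)$objective
  for (fg in list(c(9, 1), c(2, 1), c(5, 2.5))) {
    lo <- fg[2] + 1e-6; hi <- 200
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      if (maxGrowth(fg[1], fg[2], mid) > 0) hi <- mid else lo <- mid
    }
    expect_equal(criticalDiffusion(fg[1], fg[2]), (lo + hi) / 2,
                 tolerance = 1e-6)
  }
})

test_that("wavenumber band endpoints agree with dispersion sign changes", {
  band <- wavenumberBand(2, 1, 8)
  expect_equal(band, c((7 - sqrt(17)) / 16, (7 + sqrt(17)) / 16),
               tolerance = 1e-12)
  for (k2b in band) {
    inside <- turingkit:::growthRate(2, 1, 8, k2b + c(-1, 1) * 1e-6)
    lower <- abs(k2b - band[1]) < 1e-12
    expect_true(if (lower) inside[1] < 0 && inside[2] > 0
                else inside[1] > 0 && inside[2] < 0)
  }
  # degenerate band exactly at D = Dc
  Dc <- criticalDiffusion(2, 1)
  bd <- wavenumberBand(2, 1, Dc)
  expect_length(bd, 2)
  expect_equal(bd[1], bd[2], tolerance = 1e-9)
  # closed band below Dc
  expect_length(wavenumberBand(2, 1, 4), 0)
})

test_that("minimum domain length matches the band and its large-D limit", {
  expect_equal(minDomainLength(2, 1, 8), 4 * pi / sqrt(7 + sqrt(17)),
               tolerance = 1e-12)
  expect_equal(minDomainLength(2, 1, 1e9), pi, tolerance = 1e-4)
  expect_error(minDomainLength(2, 1, 5), "band")
})

test_that("dispersion growth matches direct eigenvalues and the S boundary", {
  # det = F - G = 0 at the region boundary: neutral at k = 0
  d <- dispersion(2, 2, 8, 0)
  expect_equal(d@growthRate, 0, tolerance = 1e-12)
  # det < 0: unstable to spatially constant modes
  expect_gt(dispersion(1.5, 2, 8, 0)@growthRate, 0)
  # interior of the band grows; direct eigenvalue oracle
  k2 <- 0.43
  M <- matrix(c(1 - k2, 1, -2, -1 - 8 * k2), 2, 2, byrow = TRUE)
  lam <- max(Re(eigen(M)$values))
  got <- dispersion(2, 1, 8, k2)@growthRate
  expect_gt(got, 0)
  expect_equal(got, lam, tolerance = 1e-12)
})

test_that("dimensional Turing report matches an eigenvalue sweep oracle", {
  sys <- dimensionalRD(Du = 1, Dv = 20, fu = 1, fv = 1, gu = -3, gv = -2)
  rpt <- checkTuring(sys)
  expect_true(rpt@stableWithoutDiffusion)
  expect_true(rpt@diffusionDriven)
  expect_length(rpt@band, 2)
  # oracle: positive growth exactly inside the reported band
  k2grid <- seq(1e-4, 2 * rpt@band[2], length.out = 400)
  gr <- vapply(k2grid, function(k2) dimGrowth(1, 20, 1, 1, -3, -2, k2), 0)
  inBand <- k2grid > rpt@band[1] & k2grid < rpt@band[2]
  expect_true(all(gr[inBand] > 0))
  expect_true(all(gr[!inBand & abs(k2grid - rpt@band[1]) > 1e-3 &
                     abs(k2grid - rpt@band[2]) > 1e-3] < 0))
})

test_that("equal diffusivities cannot be diffusion-driven unstable", {
  rpt <- checkTuring(dimensionalRD(1, 1, 1, 1, -3, -2))
  expect_true(rpt@stableWithoutDiffusion)
  expect_false(rpt@diffusionDriven)
})

test_that("an equality in the diffusion condition flags marginality", {
  # choose Dv so that Dv fu + Du gv = 2 sqrt(Du Dv det) exactly
  Dv <- (sqrt(2) + sqrt(3))^2
  rpt <- checkTuring(dimensionalRD(1, Dv, 1, 1, -3, -1))
  expect_true(rpt@marginal)
})

test_that("admissible modes are the integers whose wavenumber is in-band", {
  rpt <- checkTuring(dimensionalRD(1, 20, 1, 1, -3, -2), L = 10)
  kk <- sqrt(rpt@band)
  ns <- 1:50
  expect_equal(rpt@admissibleModes,
               ns[ns * pi / 10 > kk[1] & ns * pi / 10 < kk[2]])
})

test_that("nondimensionalization reproduces (F, G, D) and rescaled growth", {
  nd <- nondimensionalize(dimensionalRD(1, 16, fu = 2, fv = 4, gu = -3, gv = -4))
  expect_equal(nd@F, 3); expect_equal(nd@G, 2); expect_equal(nd@D, 16)
  expect_equal(nd@signType, "cross")
  expect_equal(FPrime(nd), 2); expect_equal(GPrime(nd), 1)
  expect_equal(nd@timeScale, 0.5)
  expect_equal(nd@lengthScale, sqrt(1 / 2))
  # oracle: lambda_dim(k^2) = fu * lambda_nondim(k^2 * Du / fu)
  for (k2 in c(0.1, 0.5, 1.2)) {
    lamDim <- dimGrowth(1, 16, 2, 4, -3, -4, k2)
    lamNon <- turingkit:::growthRate(3, 2, 16, k2 * nd@lengthScale^2)
    expect_equal(lamDim, lamNon / nd@timeScale, tolerance = 1e-10)
  }
  # identity on already-nondimensional input
  nd2 <- nondimensionalize(dimensionalRD(1, 12, 1, 1, -2.5, -1.5))
  expect_equal(c(nd2@F, nd2@G, nd2@D), c(2.5, 1.5, 12))
  # pure structure
  nd3 <- nondimensionalize(dimensionalRD(1, 10, 1, -1, 2, -1.5))
  expect_equal(c(nd3@F, nd3@G), c(2, 1.5))
  expect_equal(nd3@signType, "pure")
  expect_error(nondimensionalize(dimensionalRD(1, 10, -1, 1, 1, -2)), "f_u")
  expect_error(nondimensionalize(dimensionalRD(1, 10, 1, 1, 3, -2)),
               "neither pure nor cross")
})

test_that("dimensional and nondimensional reports agree for random systems", {
  set.seed(42)
  for (i in 1:40) {
    fu <- runif(1, 0.2, 3)
    fv <- runif(1, 0.2, 3) * sample(c(-1, 1), 1)
    gu <- -sign(fv) * runif(1, 0.2, 4)
    gv <- -runif(1, 0.1, 4)
    Du <- runif(1, 0.5, 2); Dv <- Du * runif(1, 1, 40)
    dim <- checkTuring(dimensionalRD(Du, Dv, fu, fv, gu, gv))
    nd <- checkTuring(nondimensionalize(dimensionalRD(Du, Dv, fu, fv, gu, gv)))
    expect_equal(dim@stableWithoutDiffusion, nd@stableWithoutDiffusion)
    expect_equal(dim@diffusionDriven, nd@diffusionDriven)
  }
})

test_that("band membership and dispersion sign agree over random parameters", {
  set.seed(7)
  for (i in 1:200) {
    G <- runif(1, 1.05, 3)
    F <- G + runif(1, 0.05, 3)
    D <- criticalDiffusion(F, G) * runif(1, 1.1, 4)
    band <- wavenumberBand(F, G, D)
    expect_length(band, 2)
    gIn <- turingkit:::growthRate(F, G, D, band + c(1e-6, -1e-6))
    gOut <- turingkit:::growthRate(F, G, D, band + c(-1e-6, 1e-6))
    expect_true(all(gIn > -1e-9))
    expect_true(all(gOut < 1e-9))
  }
})

test_that("growth is marginal (max zero) exactly at D = Dc", {
  set.seed(11)
  for (i in 1:50) {
    G <- runif(1, 1.05, 3)
    F <- G + runif(1, 0.1, 3)
    Dc <- criticalDiffusion(F, G)
    m <- optimize(function(k2) turingkit:::growthRate(F, G, Dc, k2),
                  c(0, 3), maximum = TRUE)$objective
    expect_lt(abs(m), 1e-8)
  }
})

test_that("the discretized linearization converges to the dispersion at O(h^2)", {
  F <- 3; G <- 2; D <- 15; L <- 20
  # (a) the full spectrum of the finite-difference linearization equals the
  # dispersion evaluated at the operator's discrete wavenumbers
  n <- 48
  Lap <- as.matrix(diffusionMatrix(makeGrid(n, L)))
  A <- rbind(cbind(Lap + diag(n), diag(n)),
             cbind(-F * diag(n), D * Lap - G * diag(n)))
  h <- L / (n - 1)
  kh2 <- vapply(0:(n - 1), function(m) {
    k <- m * pi / L
    2 * (1 - cos(k * h)) / h^2
  }, 0)
  predicted <- unlist(lapply(kh2, function(z) {
    M <- matrix(c(1 - z, 1, -F, -G - D * z), 2, 2, byrow = TRUE)
    Re(eigen(M, only.values = TRUE)$values)
  }))
  got <- Re(eigen(A, only.values = TRUE)$values)
  expect_equal(sort(got), sort(predicted), tolerance = 1e-8)
  # (b) per-mode error against the continuum dispersion shrinks ~4x per
  # halving of h
  modeErr <- function(n) {
    h <- L / (n - 1)
    max(vapply(2:5, function(m) {
      k <- m * pi / L
      kh2 <- 2 * (1 - cos(k * h)) / h^2
      abs(turingkit:::growthRate(F, G, D, kh2) -
            turingkit:::growthRate(F, G, D, k^2))
    }, 0))
  }
  errs <- vapply(c(24, 48, 96), modeErr, 0)
  expect_gt(errs[1] / errs[2], 3.5)
  expect_gt(errs[2] / errs[3], 3.5)
})

test_that("suprema over level-set regions hit the analytic optima", {
  circ <- circleRegion(gridResolution = 201L)
  sDc <- supOverRegion(circ, "Dc")
  expect_equal(sDc$value, (1 + sqrt(2))^2, tolerance = 1e-6)
  expect_lt(max(abs(sDc$arg)), 1e-2)
  sF <- supOverRegion(circ, "F")
  expect_equal(sF$value, 2, tolerance = 1e-9)
  sLc <- supOverRegion(circ, "Lc", D = 8)
  expect_equal(sLc$value, 4 * pi / sqrt(7 + sqrt(17)), tolerance = 1e-4)
  hyp <- hyperbolicRegion(gridResolution = 201L)
  sH <- supOverRegion(hyp, "Dc")
  expect_equal(sH$value, 17 + 12 * sqrt(2), tolerance = 1e-4)
  expect_lte(sH$value, 50)
  # empty region
  empty <- levelSetRegion(function(p) -1 - p$a^2, "a", list(a = c(-1, 1)))
  expect_error(supOverRegion(empty, "S"), "empty")
})

test_that("Turing report serializes to the documented JSON keys", {
  rpt <- checkTuring(dimensionalRD(1, 20, 1, 1, -3, -2), L = 10)
  j <- jsonlite::fromJSON(as.character(exportJSON(rpt)))
  expect_true(all(c("inequalities", "Dc", "Lc", "band", "marginal",
                    "admissible_modes") %in% names(j)))
  expect_equal(j$band, rpt@band, tolerance = 1e-12)
})
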