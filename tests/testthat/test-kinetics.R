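# Kinetic construction: the level-set families, phase switching, cubic
# augmentation, arbitrary steady states, self-verification, and the D/L
# recommendations.

test_that("the cross family realizes the prescribed Jacobian", {
  sys <- buildCross(1)
  g <- sys@gTerms
  expect_equal(g$coef[g$pu == 0 & g$pv == 0], 2)
  expect_equal(g$coef[g$pu == 0 & g$pv == 1], 1)
  expect_equal(g$coef[g$pu == 1 & g$pv == 1], -3)
  # f is fixed for every S
  for (S in c(-1, 0, 1, 3)) {
    f <- buildCross(S)@fTerms
    expect_equal(f$coef[f$pu == 1 & f$pv == 0], -1)
    expect_equal(f$coef[f$pu == 2 & f$pv == 1], 1)
  }
  v <- verifyKinetics(sys)
  expect_true(v$pass)
  expect_equal(v$signType, "cross")
  expect_equal(v$jacobian, matrix(c(1, -3, 1, -2), 2, 2), tolerance = 1e-10)
})

test_that("the pure family solves the constraints with in-phase structure", {
  sys <- buildPure(1)
  g <- sys@gTerms
  expect_equal(g$coef[g$pu == 0 & g$pv == 0], 2)
  expect_equal(g$coef[g$pu == 0 & g$pv == 1], -5)
  expect_equal(g$coef[g$pu == 1 & g$pv == 1], 3)
  v <- verifyKinetics(sys)
  expect_true(v$pass)
  expect_equal(v$signType, "pure")
  expect_equal(v$jacobian, matrix(c(1, 3, -1, -2), 2, 2), tolerance = 1e-10)
  # (1,1) is a root for any S; det = S, trace = -1
  for (S in c(-0.5, 0.7, 2)) {
    s2 <- buildPure(S)
    r <- turingkit:::evalKinetics(s2, 1, 1)
    expect_equal(abs(r$f) + abs(r$g), 0, tolerance = 1e-14)
    J <- verifyKinetics(s2)$jacobian
    expect_equal(det(J), S, tolerance = 1e-9)
    expect_equal(sum(diag(J)), -1, tolerance = 1e-9)
  }
})

test_that("alpha > 2 re-solves the coefficients and keeps the Jacobian", {
  for (al in c(3, 4)) {
    sys <- buildCross(1, alpha = al)
    f <- sys@fTerms
    expect_equal(f$coef[f$pu == 0 & f$pv == 0], al - 2)
    expect_equal(f$coef[f$pu == 1 & f$pv == 0], 1 - al)
    expect_equal(f$coef[f$pu == al & f$pv == 1], 1)
    expect_true(verifyKinetics(sys)$pass)
  }
})

test_that("the phase-switching family flips sign structure at a = 3", {
  s1 <- buildPhaseSwitching(1, 1)
  g <- s1@gTerms
  expect_equal(g$coef[g$pu == 0 & g$pv == 0], 2)
  expect_equal(g$coef[g$pu == 1 & g$pv == 1], 2)
  expect_equal(g$coef[g$pu == 0 & g$pv == 1], -4)
  v1 <- verifyKinetics(s1)
  expect_true(v1$pass)
  expect_equal(v1$signType, "pure")
  expect_equal(v1$jacobian, matrix(c(1, 2, -2, -2), 2, 2), tolerance = 1e-10)

  s6 <- buildPhaseSwitching(6, 1)
  f <- s6@fTerms
  expect_equal(f$coef[f$pu == 1 & f$pv == 0], -1)
  expect_equal(f$coef[f$pu == 2 & f$pv == 0], -2)
  expect_equal(f$coef[f$pu == 2 & f$pv == 1], 3)
  v6 <- verifyKinetics(s6)
  expect_true(v6$pass)
  expect_equal(v6$signType, "cross")
  expect_equal(v6$jacobian, matrix(c(1, -3, 3, -2), 2, 2), tolerance = 1e-10)

  expect_error(buildPhaseSwitching(3, 1), "blows up")
  # sign structure across the two branches, any b
  set.seed(3)
  for (i in 1:20) {
    a <- runif(1, 0.1, 2.9); b <- runif(1, 0.1, 3)
    expect_equal(verifyKinetics(buildPhaseSwitching(a, b))$signType, "pure")
    a2 <- runif(1, 3.1, 6)
    expect_equal(verifyKinetics(buildPhaseSwitching(a2, b))$signType, "cross")
  }
})

test_that("the saturation guard permits a = 3 and records the O(eps^2) drift", {
  sys <- buildPhaseSwitching(3, 1, saturate = TRUE, satEps = 0.05)
  v <- verifyKinetics(sys)
  expect_true(v$pass)
  expect_gt(v$guardDrift, 0)
  expect_lt(v$jacobianDeviation, 10 * v$guardDrift + 1e-10)
})

test_that("the cubic term changes nothing at linear order", {
  base <- buildCross(1)
  expect_identical(withCubic(base, 0)@fTerms, base@fTerms)
  expect_error(withCubic(base, -1), ">= 0")
  set.seed(5)
  for (C in runif(6, 0, 20)) {
    aug <- withCubic(base, C)
    expect_equal(verifyKinetics(aug)$jacobian, verifyKinetics(base)$jacobian,
                 tolerance = 1e-13)
    rb <- checkTuring(base, D = 9)
    ra <- checkTuring(aug, D = 9)
    expect_equal(ra@band, rb@band)
    expect_equal(ra@diffusionDriven, rb@diffusionDriven)
  }
})

test_that("arbitrary steady states reproduce the coefficient formulas", {
  sys <- buildAtSteadyState(2, 1, 1)
  f <- sys@fTerms; g <- sys@gTerms
  getc <- function(tm, pu, pv) {
    z <- tm$coef[tm$pu == pu & tm$pv == pv]
    if (length(z)) z else 0
  }
  expect_equal(getc(f, 0, 0), -1)   # a1 = V - U
  expect_equal(getc(f, 1, 0), 0)    # b1 = (U - 2V)/U
  expect_equal(getc(f, 2, 1), 0.25) # c1 = U^-2
  expect_equal(getc(g, 0, 0), 2)    # a2 = 2V
  expect_equal(getc(g, 0, 1), 4)    # b2 = (SU + 2U - 2V)/V
  expect_equal(getc(g, 1, 1), -3)   # c2 = -(S + 2)/V
  r <- turingkit:::evalKinetics(sys, 2, 1)
  expect_equal(abs(r$f) + abs(r$g), 0, tolerance = 1e-14)
  v <- verifyKinetics(sys)
  expect_true(v$pass)
  expect_equal(v$jacobian, matrix(c(1, -3, 1, -2), 2, 2), tolerance = 1e-10)
  # (U, V) = (1, 1) reduces to the cross family
  expect_equal(buildAtSteadyState(1, 1, 1.5)@gTerms, buildCross(1.5)@gTerms)
  expect_error(buildAtSteadyState(-1, 1, 1), "positive")
})

test_that("an S < 0 steady-state system is a saddle (k = 0 unstable, no band)", {
  sys <- buildAtSteadyState(11, 1, -1)
  f <- sys@fTerms; g <- sys@gTerms
  expect_equal(f$coef[f$pu == 0 & f$pv == 0], -10)
  expect_equal(f$coef[f$pu == 1 & f$pv == 0], 9 / 11)
  expect_equal(g$coef[g$pu == 0 & g$pv == 1], 9)
  expect_equal(g$coef[g$pu == 1 & g$pv == 1], -1)
  rpt <- checkTuring(sys, D = 20)
  expect_false(rpt@stableWithoutDiffusion)
  expect_false(rpt@diffusionDriven)
  expect_gt(dispersion(1, 2, 20, 0)@growthRate, 0)  # det = S < 0 at k = 0
})

test_that("every family keeps trace -1 and determinant S at the steady state", {
  set.seed(9)
  for (S in runif(100, -2, 5)) {
    builder <- sample(1:3, 1)
    sys <- switch(builder, buildCross(S), buildPure(S),
                  buildAtSteadyState(runif(1, 0.3, 4), runif(1, 0.3, 4), S))
    J <- verifyKinetics(sys)$jacobian
    expect_equal(sum(diag(J)), -1, tolerance = 1e-9)
    expect_equal(det(J), S, tolerance = 1e-8)
  }
})

test_that("a corrupted coefficient fails self-verification", {
  sys <- buildCross(1)
  sys@gTerms$coef[1] <- sys@gTerms$coef[1] + 0.1
  v <- verifyKinetics(sys)
  expect_false(v$pass)
  expect_gt(v$gResidual, 0.05)
})

test_that("the Turing band opens exactly on the designed region", {
  set.seed(21)
  regions <- list(circle = circleRegion(), hyper = hyperbolicRegion())
  for (nm in names(regions)) {
    reg <- regions[[nm]]
    Drec <- supOverRegion(reg, "Dc")$value
    lo <- reg@box[1, ]; hi <- reg@box[2, ]
    pts <- data.frame(a = runif(300, lo[1], hi[1]), b = runif(300, lo[2], hi[2]))
    S <- reg@S(pts)
    keep <- abs(S) > 1e-6
    pts <- pts[keep, ]; S <- S[keep]
    F <- reg@Ffun(pts); G <- reg@Gfun(pts)
    for (i in seq_len(min(100, nrow(pts)))) {
      band <- wavenumberBand(F[i], G[i], Drec + 1e-9)
      if (S[i] > 0) {
        expect_length(band, 2)
      } else {
        # either no band or k = 0 already unstable (saddle, det < 0)
        ok <- length(band) == 0 ||
          turingkit:::growthRate(F[i], G[i], Drec, 0) > 0
        expect_true(ok)
        if (F[i] < G[i])
          expect_gt(turingkit:::growthRate(F[i], G[i], Drec, 0), 0)
      }
    }
  }
})

test_that("diffusion and domain recommendations match the printed rules", {
  rec <- recommendDiffusion(circleRegion(gridResolution = 201L))
  expect_equal(rec$Drecommended, (1 + sqrt(2))^2, tolerance = 1e-5)
  expect_equal(rec$Dconservative, 8, tolerance = 1e-9)
  expect_equal(rec$LcSup, 4 * pi / sqrt(7 + sqrt(17)), tolerance = 1e-4)
  # canonical level-set family: D = 4 (2 + sup S) and (sqrt S + sqrt(S+2))^2
  disc <- levelSetRegion(function(p) 1 - p$a^2 - p$b^2, c("a", "b"),
                         list(a = c(-1, 1), b = c(-1, 1)),
                         gridResolution = 201L)
  rec2 <- recommendDiffusion(disc)
  expect_equal(rec2$Dconservative, 12, tolerance = 1e-6)
  expect_equal(rec2$Drecommended, (sqrt(1) + sqrt(3))^2, tolerance = 1e-5)
  # degenerate region S == 0 on a tiny box
  flat <- levelSetRegion(function(p) rep(0, nrow(p)), "a", list(a = c(-1, 1)),
                         gridResolution = 51L)
  rec3 <- recommendDiffusion(flat)
  expect_equal(rec3$Drecommended, 2, tolerance = 1e-9)
  expect_true(rec3$marginal)
})

test_that("kinetic systems round-trip through JSON", {
  for (sys in list(buildCross(1.5, C = 2), buildPhaseSwitching(6, 1),
                   buildAtSteadyState(2, 1, 1))) {
    back <- kineticsFromJSON(as.character(exportJSON(sys)))
    expect_equal(back@fTerms, sys@fTerms)
    expect_equal(back@gTerms, sys@gTerms)
    expect_equal(back@steadyState, sys@steadyState)
    expect_equal(cubicCoef(back), cubicCoef(sys))
    expect_equal(signType(back), signType(sys))
  }
})
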