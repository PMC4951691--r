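test_that("scattering ASCII reader handles comments, commas and bad rows", {
  spec <- simulationSpec(seed = 1, qGrid = c(0.05, 4, 100))
  curve <- makeSphereCurve(4.52, spec = spec)
  tf <- tempfile(fileext = ".dat")
  writeScattering(curve, tf)
  back <- readScattering(tf)
  expect_equal(qValues(back), qValues(curve), tolerance = 1e-8)
  expect_equal(intensities(back), intensities(curve), tolerance = 1e-6)

  # comma-delimited with extra comments
  tf2 <- tempfile(fileext = ".dat")
  writeLines(c("# instrument: synthetic", "# q,I",
               sprintf("%.6f,%.6e", curve@q, curve@I)), tf2)
  expect_equal(intensities(readScattering(tf2)),
               intensities(curve), tolerance = 1e-6)

  # one NaN row is dropped with a warning
  tf3 <- tempfile(fileext = ".dat")
  rows <- sprintf("%.6f %.6e", curve@q, curve@I)
  rows[50] <- "NaN NaN"
  writeLines(rows, tf3)
  expect_warning(c3 <- readScattering(tf3), "non-finite")
  expect_length(qValues(c3), 99)

  tf4 <- tempfile(fileext = ".dat")
  writeLines(sprintf("%.4f %.4f", 1:5 / 10, rep(1, 5)), tf4)
  expect_error(readScattering(tf4), "fewer than 10")

  tf5 <- tempfile(fileext = ".dat")
  writeLines(sprintf("%.4f %.4f", c(1:8, 8, 7) / 10, rep(1, 10)), tf5)
  expect_error(readScattering(tf5), "not strictly increasing")

  # Angstrom input converts to 1/nm on request
  tf6 <- tempfile(fileext = ".dat")
  writeLines(sprintf("%.6f %.6e", curve@q / 10, curve@I), tf6)
  expect_equal(qValues(readScattering(tf6, qUnits = "ang")),
               qValues(curve), tolerance = 1e-4)
})

test_that("Guinier fit is exact for Guinier-limit data and scale invariant", {
  gl <- guinierLimitCurve(Rg = 3.5)
  fit <- guinierFit(gl)
  expect_true(fit@converged)
  expect_lt(abs(fit@Rg - 3.5) / 3.5, 1e-3)
  expect_equal(fit@I0, 1, tolerance = 1e-6)
  expect_gte(fit@nPoints, 5)
  # multiplying I by c > 0 leaves Rg unchanged and scales I0 by c
  scaled <- ScatteringCurve(gl@q, 7.3 * gl@I)
  fitS <- guinierFit(scaled)
  expect_equal(fitS@Rg, fit@Rg, tolerance = 1e-12)
  expect_equal(fitS@I0, 7.3 * fit@I0, tolerance = 1e-9)
})

test_that("Guinier fit errors when the window cannot be populated", {
  # curve truncated above qRg = 0.7: the 0.759-1.294 window is empty
  q <- seq(0.02, 0.2, length.out = 40)
  trunc <- ScatteringCurve(q, exp(-q^2 * 3.5^2 / 3))
  expect_error(guinierFit(trunc), "window")
  # flat curve has no Guinier region at all
  flat <- ScatteringCurve(seq(0.05, 1, length.out = 50), rep(2, 50))
  expect_error(guinierFit(flat), "slope")
})

test_that("sphere and coil fits carry the known window biases", {
  # Guinier's law is exact only at q -> 0; over the fixed 0.759-1.294 qRg
  # window a hard sphere reads high by ~2.6% and a Gaussian coil low by
  # ~11%. These frozen values pin the estimator's documented behaviour.
  sph <- makeSphereCurve(4.52, spec = simulationSpec(seed = 1))
  fitS <- guinierFit(sph)
  expect_equal(fitS@Rg, 3.5965, tolerance = 1e-3)
  expect_gt(fitS@Rg, sqrt(3 / 5) * 4.52)          # systematic overestimate
  coil <- makeDebyeCoilCurve(3.5, spec = simulationSpec(seed = 1))
  fitC <- guinierFit(coil)
  expect_equal(fitC@Rg, 3.1201, tolerance = 1e-3)
  expect_lt(fitC@Rg, 3.5)                         # systematic underestimate
})

test_that("noisy sphere curves are recovered within the estimator's scatter", {
  errs <- vapply(1:100, function(seed) {
    sp <- simulationSpec(seed = seed, noiseModel = "relative", sigma = 0.02)
    fit <- guinierFit(makeSphereCurve(4.52, spec = sp))
    abs(fit@Rg - sqrt(3 / 5) * 4.52) / (sqrt(3 / 5) * 4.52)
  }, numeric(1))
  # median reflects the +2.6% window bias plus noise scatter
  expect_lt(median(errs), 0.04)
})

test_that("weighted fits use the provided uncertainties", {
  sp <- simulationSpec(seed = 7, noiseModel = "relative", sigma = 0.02)
  noisy <- makeSphereCurve(4.52, spec = sp)
  expect_length(intensityErrors(noisy), length(qValues(noisy)))
  fit <- guinierFit(noisy)
  expect_true(fit@converged)
  expect_gt(fit@RgSE, 0)
})

test_that("the dimensionless Kratky of a Guinier-limit curve peaks at sqrt(3)", {
  gl <- guinierLimitCurve(Rg = 3.5)
  fit <- guinierFit(gl)
  prof <- dimensionlessKratky(gl, fit)
  # closed form: x^2 exp(-x^2/3) is maximal at x = sqrt(3), height 3/e
  expect_equal(prof@peak$x, sqrt(3), tolerance = 0.03)
  expect_equal(prof@peak$y, 3 / exp(1), tolerance = 1e-3)
  expect_true(all(prof@y >= 0))
  expect_identical(shapeClass(prof), "globular_compact")
})

test_that("Kratky shape rules separate sphere, coil and hybrid", {
  spec <- simulationSpec(seed = 1)
  sph <- makeSphereCurve(4.52, spec = spec)
  coil <- makeDebyeCoilCurve(3.5, spec = spec)
  kS <- dimensionlessKratky(sph, guinierFit(sph))
  expect_identical(shapeClass(kS), "globular_compact")
  kC <- dimensionlessKratky(coil, guinierFit(coil))
  expect_identical(shapeClass(kC), "extended")
  # Debye asymptote: with the exact Rg and I0 on the axes, the
  # dimensionless Kratky ordinate plateaus at 2
  exactFit <- new("GuinierResult", Rg = 3.5, RgSE = 0, I0 = 1, I0SE = 0,
                  window = c(0.2, 0.37), qRgWindow = c(0.759, 1.294),
                  nPoints = 15, r2 = 1, converged = TRUE, iterations = 1)
  kTrue <- dimensionlessKratky(coil, exactFit)
  expect_equal(mean(kTrue@y[kTrue@x > 5]), 2, tolerance = 0.02)
  hyb <- makeHybridCurve(sph, coil, 0.6, spec)
  kH <- dimensionlessKratky(hyb, guinierFit(hyb))
  expect_identical(shapeClass(kH), "compact_plus_flexible")
  # the hybrid keeps a real peak but its tail stays high
  expect_gt(kH@tailLevel, 0.5 * kH@peak$y)
})

test_that("Kratky classification is invariant to rescaling and regridding", {
  for (maker in list(function(sp) makeSphereCurve(4.52, spec = sp),
                     function(sp) makeDebyeCoilCurve(3.5, spec = sp))) {
    c400 <- maker(simulationSpec(seed = 1))
    cls <- shapeClass(dimensionlessKratky(c400, guinierFit(c400)))
    scaled <- ScatteringCurve(c400@q, 250 * c400@I)
    expect_identical(
      shapeClass(dimensionlessKratky(scaled, guinierFit(scaled))), cls)
    c800 <- maker(simulationSpec(seed = 1, qGrid = c(0.05, 4, 800)))
    expect_identical(
      shapeClass(dimensionlessKratky(c800, guinierFit(c800))), cls)
  }
})

test_that("Kratky handles degenerate intensities and short curves", {
  q <- seq(0.05, 4, length.out = 60)
  I <- c(exp(-q[1:6]^2 * 4), rep(0, 54))
  curve <- ScatteringCurve(q, I)
  fakeFit <- new("GuinierResult", Rg = 3.5, RgSE = 0, I0 = 1, I0SE = 0,
                 window = c(0.05, 0.3), qRgWindow = c(0.175, 1.05),
                 nPoints = 6, r2 = 1, converged = TRUE, iterations = 1)
  prof <- dimensionlessKratky(curve, fakeFit)
  expect_true(all(prof@y[curve@I == 0] == 0))
  # a curve that never reaches the tail band is inconclusive
  qShort <- seq(0.05, 0.5, length.out = 30)
  short <- ScatteringCurve(qShort, exp(-qShort^2 * 3.5^2 / 3))
  profShort <- dimensionlessKratky(short, fakeFit)
  expect_identical(shapeClass(profShort), "inconclusive")
})
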