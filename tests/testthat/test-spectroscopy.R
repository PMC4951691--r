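test_that("Stern-Volmer fit recovers KSV exactly on a noiseless line", {
  qc <- seq(0, 0.3, length.out = 10)
  ser <- makeQuenchingSeries(5, qc, simulationSpec(seed = 1))
  fit <- sternVolmerFit(ser)
  expect_equal(fit$KSV, 5, tolerance = 1e-12)
  expect_identical(fit$verdict, "linear")
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  # a missing [Q] = 0 point is prepended with F0/F = 1
  noZero <- TitrationSeries(qc[-1], 1 + 5 * qc[-1], kind = "quenching")
  expect_equal(sternVolmerFit(noZero)$KSV, 5, tolerance = 1e-12)
  expect_error(sternVolmerFit(TitrationSeries(qc, 1 + qc, kind = "generic")),
               "quenching")
})

test_that("KSV is invariant to rescaling the raw fluorescence intensities", {
  qc <- seq(0, 0.3, length.out = 12)
  F0 <- 1000; Fq <- F0 / (1 + 7 * qc)
  ratio1 <- TitrationSeries(qc, F0 / Fq, kind = "quenching")
  ratio2 <- TitrationSeries(qc, (3.7 * F0) / (3.7 * Fq), kind = "quenching")
  expect_equal(sternVolmerFit(ratio1)$KSV, sternVolmerFit(ratio2)$KSV,
               tolerance = 1e-12)
})

test_that("two accessibility populations give a nonlinear verdict", {
  qc <- seq(0, 0.3, length.out = 15)
  # equal mixture of KSV = 3 and KSV = 15: downward-curved F0/F
  y <- 1 / (0.5 / (1 + 3 * qc) + 0.5 / (1 + 15 * qc))
  fit <- sternVolmerFit(TitrationSeries(qc, y, kind = "quenching"))
  expect_identical(fit$verdict, "nonlinear")
  # ratios below 1 are physically suspect
  below <- TitrationSeries(qc, 1 - 0.5 * qc, kind = "quenching")
  expect_warning(sternVolmerFit(below), "below 1")
})

test_that("unfolded fraction interpolates between the baselines", {
  x <- seq(0, 6, length.out = 13)
  bN <- c(intercept = -10, slope = 0.2)
  bD <- c(intercept = -2, slope = 0.1)
  yN <- bN[["intercept"]] + bN[["slope"]] * x
  yD <- bD[["intercept"]] + bD[["slope"]] * x
  expect_equal(yValues(unfoldedFraction(TitrationSeries(x, yN), bN, bD)),
               rep(0, 13))
  expect_equal(yValues(unfoldedFraction(TitrationSeries(x, yD), bN, bD)),
               rep(1, 13))
  expect_equal(yValues(unfoldedFraction(TitrationSeries(x, (yN + yD) / 2),
                                        bN, bD)),
               rep(0.5, 13))
  expect_error(unfoldedFraction(TitrationSeries(x, yN), bN, bN),
               "coincide")
  # noise pushing f_d outside [0, 1] flags but does not clip
  wob <- yN + c(-0.5, rep(0, 12))
  out <- unfoldedFraction(TitrationSeries(x, wob), bN, bD)
  expect_true("outside_unit_interval" %in% out@flags)
  expect_lt(min(yValues(out)), 0)
})

test_that("unfolded fraction round-trips a two-state signal", {
  sp <- simulationSpec(seed = 4, xGrid = c(0, 5, 21))
  fd <- makeUnfoldingSeries("two_state", list(dG0 = 5, m = 2), spec = sp)
  bN <- c(intercept = 0, slope = 0); bD <- c(intercept = 1, slope = 0)
  # embed into a sloped signal and recover fd through the baselines
  x <- xValues(fd)
  yN <- -12 + 0.3 * x; yD <- -3 + 0.1 * x
  y <- yN + (yD - yN) * yValues(fd)
  back <- unfoldedFraction(TitrationSeries(x, y),
                           c(intercept = -12, slope = 0.3),
                           c(intercept = -3, slope = 0.1))
  expect_equal(yValues(back), yValues(fd), tolerance = 1e-10)
})

test_that("unfolding model comparison separates sigmoid from line", {
  sp <- simulationSpec(seed = 1, xGrid = c(0, 5, 20))
  two <- fitUnfolding(makeUnfoldingSeries("two_state",
                                          list(dG0 = 5, m = 2), spec = sp))
  expect_identical(two@verdict, "cooperative")
  expect_identical(two@model, "two_state")
  expect_equal(two@parameters$two_state$m, 2, tolerance = 1e-4)
  expect_equal(two@parameters$two_state$Cm, 2.5, tolerance = 1e-4)

  lin <- fitUnfolding(makeUnfoldingSeries("linear",
                                          list(slope = -0.12, intercept = 1),
                                          spec = sp))
  expect_identical(lin@verdict, "weakly_cooperative_or_linear")
  expect_identical(lin@model, "linear")

  flat <- fitUnfolding(TitrationSeries(0:9, rep(2, 10),
                                       kind = "chemical_unfolding"))
  expect_true("degenerate" %in% flat@flags)
  expect_true(is.na(flat@verdict))

  expect_error(fitUnfolding(TitrationSeries(1:5, 1:5,
                                            kind = "chemical_unfolding")),
               "at least 6")
})

test_that("verdicts are error-free at zero noise in both directions", {
  for (seed in 1:30) {
    sp <- simulationSpec(seed = seed, xGrid = c(0, 5, 20))
    expect_identical(
      fitUnfolding(makeUnfoldingSeries("two_state", list(dG0 = 5, m = 2),
                                       spec = sp))@verdict,
      "cooperative")
    expect_identical(
      fitUnfolding(makeUnfoldingSeries("linear",
                                       list(slope = -0.1, intercept = 1),
                                       spec = sp))@verdict,
      "weakly_cooperative_or_linear")
  }
})

test_that("the m-value estimator is unbiased at 1% noise", {
  # 1% of the unit signal range, 20 points: the signed relative error
  # averages out across seeds even though single fits scatter by a few %
  relErr <- vapply(1:50, function(seed) {
    sp <- simulationSpec(seed = seed, noiseModel = "absolute", sigma = 0.01,
                         xGrid = c(0, 5, 20))
    fit <- fitUnfolding(makeUnfoldingSeries("two_state",
                                            list(dG0 = 5, m = 2),
                                            spec = sp))
    (fit@parameters$two_state$m - 2) / 2
  }, numeric(1))
  expect_lt(abs(mean(relErr)), 0.02)
})

test_that("the thermal two-state variant detects a van 't Hoff sigmoid", {
  Tc <- seq(20, 90, length.out = 20)
  Tk <- Tc + 273.15
  K <- exp(80 / 1.9872e-3 * (1 / 330 - 1 / Tk))
  y <- K / (1 + K)
  fit <- fitUnfolding(TitrationSeries(Tc, y, kind = "thermal_unfolding"))
  expect_identical(fit@verdict, "cooperative")
  expect_equal(fit@parameters$two_state$Tm, 330 - 273.15, tolerance = 0.1)
})

test_that("lambda-max tracking interpolates band maxima across a series", {
  grid <- 310:400
  gauss <- function(centre) exp(-(grid - centre)^2 / (2 * 15^2))
  sp1 <- list(x = 0, wavelength = grid, intensity = gauss(344))
  sp2 <- list(x = 1, wavelength = grid, intensity = gauss(344))
  ser <- lambdaMaxSeries(list(sp1, sp2))
  expect_equal(yValues(ser), c(344, 344), tolerance = 0.1)
  # identical spectra give identical maxima
  expect_identical(yValues(ser)[1], yValues(ser)[2])

  # red-shifting stack: 344 -> 352 nm, handed on to the unfolding fit
  urea <- seq(0, 7, length.out = 16)
  centres <- 344 + 8 / (1 + exp(-(urea - 3.5) * 1.5))
  stack <- lapply(seq_along(urea), function(i)
    list(x = urea[i], wavelength = grid, intensity = gauss(centres[i])))
  lamSer <- lambdaMaxSeries(stack)
  expect_true(all(diff(yValues(lamSer)) > 0))
  fit <- fitUnfolding(lamSer)
  expect_identical(fit@verdict, "cooperative")

  # maximum on the spectrum edge flags the series
  edgeSp <- list(x = 0, wavelength = grid, intensity = gauss(405))
  edgeSer <- lambdaMaxSeries(list(edgeSp))
  expect_true("edge_maximum" %in% edgeSer@flags)
})
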