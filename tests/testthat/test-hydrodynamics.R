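test_that("partition coefficient maps the elution volume onto [0, 1]", {
  expect_equal(partitionCoefficient(8, 8, 20), 0)
  expect_equal(partitionCoefficient(20, 8, 20), 1)
  # an analyte at V0 + 0.422 (Vt - V0) has Kav = 0.422
  expect_equal(partitionCoefficient(8 + 0.422 * 12, 8, 20), 0.422)
  expect_warning(k <- partitionCoefficient(22, 8, 20), "outside")
  expect_gt(k, 1)
  expect_error(partitionCoefficient(10, 20, 8), "Vt must exceed V0")
})

test_that("SEC calibration recovers a generating line and flags bad input", {
  # two standards: the fitted line passes through both exactly
  std2 <- data.frame(name = c("a", "b"), Ve = c(10, 14), Rh = c(5, 2))
  cal2 <- calibrateSEC(std2, V0 = 8, Vt = 20)
  est <- secEstimate(cal2@standards$Kav[1], cal2)
  expect_equal(est$Rh, 5, tolerance = 1e-12)

  # five standards generated from a known line, zero noise
  truth <- data.frame(name = letters[1:5], Rh = c(5.2, 4.1, 3.2, 2.4, 1.8))
  run <- makeSECRun(truth, analyteRh = 3.0, V0 = 8, Vt = 20,
                    line = c(slope = -0.8, intercept = 0.9),
                    spec = simulationSpec(seed = 1))
  cal <- calibrateSEC(run$standards, V0 = 8, Vt = 20)
  expect_equal(unname(cal@fitRh["slope"]), -0.8, tolerance = 1e-10)
  expect_equal(unname(cal@fitRh["intercept"]), 0.9, tolerance = 1e-10)
  expect_equal(unname(cal@fitRh["r2"]), 1, tolerance = 1e-10)

  # noisy calibrations: OLS recovers the slope without bias across seeds
  slopes <- vapply(1:50, function(s) {
    r <- makeSECRun(truth, 3.0, 8, 20, c(slope = -0.8, intercept = 0.9),
                    simulationSpec(seed = s, noiseModel = "absolute",
                                   sigma = 0.1))
    unname(calibrateSEC(r$standards, 8, 20)@fitRh["slope"])
  }, numeric(1))
  expect_lt(abs(median(slopes) - (-0.8)), 0.05)

  expect_error(calibrateSEC(std2[1, ], 8, 20), "at least 2")
  degen <- data.frame(name = c("a", "b", "c"), Ve = c(12, 12, 12),
                      Rh = c(5, 3, 2))
  expect_error(calibrateSEC(degen, 8, 20), "degenerate")
})

test_that("SEC estimation inverts the calibration and round-trips", {
  truth <- data.frame(name = letters[1:5], Rh = c(5.2, 4.1, 3.2, 2.4, 1.8))
  line <- c(slope = -0.8, intercept = 0.9)
  run <- makeSECRun(truth, analyteRh = 3.0, V0 = 8, Vt = 20, line = line,
                    spec = simulationSpec(seed = 1))
  cal <- calibrateSEC(run$standards, V0 = 8, Vt = 20)
  # a Kav chosen so that log10(Rh) = 0.5 inverts to 10^0.5 nm
  kHalf <- line[["slope"]] * 0.5 + line[["intercept"]]
  expect_equal(secEstimate(kHalf, cal)$Rh, 10^0.5, tolerance = 1e-10)
  # noiseless round trip: partition_coefficient -> estimate -> truth
  kAn <- partitionCoefficient(run$analyteVe, 8, 20)
  expect_equal(secEstimate(kAn, cal)$Rh, 3.0, tolerance = 1e-10)
  expect_warning(secEstimate(0.99, cal), "extrapolating")
})

test_that("Siegel-Monte mass reproduces the hand calculation and is linear", {
  # hand unit tracking: 4.2e-13 s * 6.02214076e23 /mol * 6 pi * 1e-3 Pa s
  #   * 3.4e-9 m / 0.27 = 60.04 kg/mol
  handDa <- 1000 * 4.2e-13 * 6.02214076e23 * 6 * pi * 1e-3 * 3.4e-9 / 0.27
  m <- siegelMonteMass(4.2, 3.4)
  expect_equal(m, handDa, tolerance = 1e-12)
  expect_equal(m / 1000, 60.04, tolerance = 1e-4)
  # exactly linear in s and in Rh
  expect_equal(siegelMonteMass(8.4, 3.4), 2 * m)
  expect_equal(siegelMonteMass(4.2, 6.8), 2 * m)
  # halving (1 - nu2 rho) doubles the mass
  expect_equal(siegelMonteMass(4.2, 3.4,
                               SolventModel(buoyancyProduct = 0.865)),
               2 * m, tolerance = 1e-12)
  expect_error(siegelMonteMass(4.2, 3.4, SolventModel(buoyancyProduct = 1)))
  expect_error(siegelMonteMass(-1, 3.4))
})

test_that("conformer scaling laws are monotone power laws per state", {
  states <- scalingLaws()$state
  # strictly increasing in mass for every state
  for (st in states) {
    rh <- conformerRh(c(1e4, 3e4, 1e5, 3e5), st)
    expect_true(all(diff(rh) > 0))
  }
  # power-law property: Rh(2M)/Rh(M) = 2^slope
  sl <- scalingLaws()
  for (i in seq_len(nrow(sl)))
    expect_equal(conformerRh(2e5, sl$state[i]) / conformerRh(1e5, sl$state[i]),
                 2^sl$slope[i], tolerance = 1e-12)
  # expanded states grow faster than the native state
  expect_gt(sl$slope[sl$state == "urea_unfolded"],
            sl$slope[sl$state == "native"])
  expect_error(conformerRh(5e4, "liquid_crystal"), "unknown")
})

test_that("a 55.1 kDa dimer sits near 3 nm native and 3.4 nm molten globule", {
  mDimer <- 2 * 27551.7
  expect_equal(conformerRh(mDimer, "native"), 3.1296, tolerance = 1e-4)
  expect_equal(conformerRh(mDimer, "molten_globule"), 3.3928,
               tolerance = 1e-4)
})

test_that("Q-factor and its uncertainty propagation are correct", {
  expect_equal(qFactor(3.5, 3.4)$q, 1.0294118, tolerance = 1e-7)
  expect_equal(qFactor(2.2, 2.2)$q, 1)
  # uniform solid sphere: Rg = sqrt(3/5) R, Rh = R
  R <- 7.3
  expect_equal(qFactor(sqrt(3 / 5) * R, R)$q, sqrt(0.6), tolerance = 1e-12)
  # quadrature: 1.0294 * sqrt((0.1/3.5)^2 + (0.2/3.4)^2) = 0.06732
  expect_equal(qFactor(3.5, 3.4, 0.1, 0.2)$se, 0.067319, tolerance = 1e-5)
  expect_true(is.na(qFactor(3.5, 3.4)$se))
})

test_that("Q bands report all members and decision-zone neighbours", {
  r103 <- qClassify(1.03)
  expect_identical(r103$members, "pre_molten_globule")
  expect_true("molten_globule" %in% r103$adjacent)
  # the sphere point lies inside three overlapping bands
  expect_setequal(qClassify(0.775)$members,
                  c("sphere", "globular", "molten_globule"))
  expect_identical(qClassify(1.51)$members, "random_coil")
  expect_error(qClassify(-1), "positive")
})

test_that("gradient sedimentation interpolates linearly between standards", {
  std <- data.frame(name = c("a", "b"), position = c(10, 20), s = c(3, 7))
  expect_equal(sedimentationFromGradient(10, std)$s, 3, tolerance = 1e-12)
  expect_equal(sedimentationFromGradient(15, std)$s, 5, tolerance = 1e-12)
  expect_warning(out <- sedimentationFromGradient(25, std), "extrapolating")
  expect_true(out$extrapolated)
  bad <- data.frame(name = c("a", "b", "c"), position = c(10, 25, 20),
                    s = c(3, 5, 7))
  expect_error(sedimentationFromGradient(15, bad), "monotone")

  # noisy gradient: recovery within the least-squares scatter across seeds
  truth <- data.frame(name = letters[1:4], s = c(2.8, 4.3, 5.1, 7.6))
  errs <- vapply(1:20, function(seed) {
    tab <- makeGradientRun(truth, c(slope = 2, intercept = 5),
                           simulationSpec(seed = seed,
                                          noiseModel = "absolute",
                                          sigma = 0.1))
    target <- 5 + 2 * 4.2  # position of a 4.2 S sample on the true line
    abs(sedimentationFromGradient(target, tab)$s - 4.2)
  }, numeric(1))
  expect_lt(median(errs), 0.2)
})

test_that("the Kirkwood double sum converges to the coil Q-factor", {
  q4 <- idealCoilQFactor(1e4)
  q5 <- idealCoilQFactor(1e5)
  expect_equal(q4, 1.48803, tolerance = 1e-4)   # frozen from the sum
  expect_gt(q5, q4)                             # converges from below
  expect_lt(abs(q5 - 1.51) / 1.51, 0.01)
})

test_that("hydroRecord derives the Q-factor and validates inputs", {
  hr <- hydroRecord(Rh = 3.4, RhSE = 0.2, Rg = 3.5, RgSE = 0.1, s = 4.2,
                    massEstimates = data.frame(
                      method = c("siegel_monte", "sequence_theoretical"),
                      value = c(60036.6, 55103.4)))
  expect_equal(hr@qFactor, 3.5 / 3.4)
  expect_error(hydroRecord(Rh = -1))
})
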