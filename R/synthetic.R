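## Synthetic-data generators: every input the analysis consumes, produced
## from the analytic models the analysis assumes, with seed-deterministic
## noise so generator -> analyzer round trips are exact at sigma = 0.

# Derive an independent, reproducible stream per (seed, generator name).
.withGeneratorSeed <- function(spec, name, expr) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)) * 131) %% 1000003L
  derived <- (as.integer(spec@seed) %% 1000003L) * 2011L + h
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(derived %% 2147483647L)
  force(expr)
}

.applyNoise <- function(values, spec) {
  switch(spec@noiseModel,
         none = values,
         relative = values + rnorm(length(values), 0,
                                   spec@sigma * abs(values)),
         absolute = values + rnorm(length(values), 0, spec@sigma))
}

.noiseSigma <- function(values, spec) {
  switch(spec@noiseModel,
         none = numeric(0),
         relative = spec@sigma * abs(values),
         absolute = rep(spec@sigma, length(values)))
}

.qGrid <- function(spec) seq(spec@qGrid[1L], spec@qGrid[2L],
                             length.out = spec@qGrid[3L])

.xGrid <- function(spec) seq(spec@xGrid[1L], spec@xGrid[2L],
                             length.out = spec@xGrid[3L])

#' Scattering curve of a homogeneous sphere
#'
#' `I(q) = I0 [3 (sin(qR) - qR cos(qR)) / (qR)^3]^2` plus the spec'd
#' noise. The forward limit is I0 and the radius of gyration is
#' `sqrt(3/5) R`. This is the analytic oracle for the compact
#' (peaked-Kratky) pattern.
#'
#' @param R Sphere radius, nm.
#' @param I0 Forward scattering.
#' @param spec A [SimulationSpec-class].
#' @return A [ScatteringCurve-class].
#' @export
#' @examples
#' makeSphereCurve(4.52, spec = simulationSpec(seed = 1))
makeSphereCurve <- function(R, I0 = 1, spec = simulationSpec()) {
  stopifnot(R > 0, is(spec, "SimulationSpec"))
  q <- .qGrid(spec)
  u <- q * R
  model <- I0 * (3 * (sin(u) - u * cos(u)) / u^3)^2
  I <- .withGeneratorSeed(spec, "sphere", .applyNoise(model, spec))
  ScatteringCurve(q, I, sigma = .noiseSigma(model, spec),
                  metadata = list(model = "sphere", R = R, I0 = I0))
}

#' Scattering curve of a Gaussian (Debye) coil
#'
#' `I(q) = I0 * 2 (exp(-x) + x - 1) / x^2` with `x = (q Rg)^2`, the Debye
#' function - the analytic oracle for the extended, plateau-Kratky
#' pattern (the dimensionless Kratky ordinate tends to 2 at large qRg).
#'
#' @param Rg Radius of gyration, nm.
#' @inheritParams makeSphereCurve
#' @return A [ScatteringCurve-class].
#' @export
makeDebyeCoilCurve <- function(Rg, I0 = 1, spec = simulationSpec()) {
  stopifnot(Rg > 0, is(spec, "SimulationSpec"))
  q <- .qGrid(spec)
  x <- (q * Rg)^2
  model <- I0 * 2 * (exp(-x) + x - 1) / x^2
  I <- .withGeneratorSeed(spec, "coil", .applyNoise(model, spec))
  ScatteringCurve(q, I, sigma = .noiseSigma(model, spec),
                  metadata = list(model = "debye_coil", Rg = Rg, I0 = I0))
}

#' Intensity mixture of a compact and a coil component
#'
#' `I = w * I_sphere + (1 - w) * I_coil` on a shared q grid, plus noise -
#' the model of a partially folded protein with a compact domain linked to
#' a disordered one.
#'
#' @param spherePart,coilPart [ScatteringCurve-class] objects on the same
#'   q grid (noiseless components are the usual input).
#' @param w Weight of the sphere component in `[0, 1]`.
#' @param spec A [SimulationSpec-class] (supplies the noise only).
#' @return A [ScatteringCurve-class].
#' @export
makeHybridCurve <- function(spherePart, coilPart, w,
                            spec = simulationSpec()) {
  stopifnot(is(spherePart, "ScatteringCurve"),
            is(coilPart, "ScatteringCurve"), w >= 0, w <= 1)
  if (length(spherePart@q) != length(coilPart@q) ||
      any(abs(spherePart@q - coilPart@q) > 1e-12))
    stop("sphere and coil components must share the same q grid")
  model <- w * spherePart@I + (1 - w) * coilPart@I
  I <- .withGeneratorSeed(spec, "hybrid", .applyNoise(model, spec))
  ScatteringCurve(spherePart@q, I, sigma = .noiseSigma(model, spec),
                  metadata = list(model = "hybrid", w = w))
}

#' Synthetic SEC calibration run
#'
#' Generates elution volumes for a set of standards (and one analyte) from
#' a known linear law `Kav = slope * log10(Rh) + intercept`, mapping Kav to
#' `Ve = V0 + (Vt - V0) Kav` and adding the spec'd noise to Ve. At zero
#' noise, [calibrateSEC()] plus [secEstimate()] recover the generating Rh
#' exactly.
#'
#' @param standardsTruth data.frame with columns `name`, `Rh` (nm) and
#'   optionally `mass` (Da).
#' @param analyteRh True analyte Rh, nm.
#' @param V0,Vt Column volumes, mL.
#' @param line Named numeric `c(slope = , intercept = )` of Kav vs
#'   log10(Rh).
#' @param spec A [SimulationSpec-class].
#' @return List with `standards` (data.frame name, Ve, Rh, mass),
#'   `analyteVe`, and `extrapolated` (TRUE when the analyte lies outside
#'   the standards' Rh span).
#' @export
makeSECRun <- function(standardsTruth, analyteRh, V0, Vt,
                       line = c(slope = -0.8, intercept = 0.9),
                       spec = simulationSpec()) {
  stopifnot(is.data.frame(standardsTruth),
            all(c("name", "Rh") %in% colnames(standardsTruth)),
            Vt > V0, analyteRh > 0)
  kav <- function(Rh) line[["slope"]] * log10(Rh) + line[["intercept"]]
  veAll <- V0 + (Vt - V0) * kav(c(standardsTruth$Rh, analyteRh))
  veAll <- .withGeneratorSeed(spec, "sec", .applyNoise(veAll, spec))
  n <- nrow(standardsTruth)
  standards <- data.frame(name = standardsTruth$name,
                          Ve = veAll[seq_len(n)],
                          Rh = standardsTruth$Rh,
                          stringsAsFactors = FALSE)
  if ("mass" %in% colnames(standardsTruth))
    standards$mass <- standardsTruth$mass
  extrapolated <- analyteRh < min(standardsTruth$Rh) ||
    analyteRh > max(standardsTruth$Rh)
  if (extrapolated)
    warning("analyte Rh outside the standards' span (extrapolation fixture)")
  list(standards = standards, analyteVe = veAll[n + 1L],
       extrapolated = extrapolated)
}

#' Synthetic sucrose-gradient run
#'
#' Positions generated from the linear migration law
#' `position = intercept + slope * s` plus noise.
#'
#' @param sTruth data.frame with columns `name` and `s` (Svedberg).
#' @param line Named numeric `c(slope = , intercept = )`.
#' @param spec A [SimulationSpec-class].
#' @return data.frame with columns `name`, `position`, `s`.
#' @export
makeGradientRun <- function(sTruth, line = c(slope = 2, intercept = 5),
                            spec = simulationSpec()) {
  stopifnot(is.data.frame(sTruth),
            all(c("name", "s") %in% colnames(sTruth)))
  pos <- line[["intercept"]] + line[["slope"]] * sTruth$s
  pos <- .withGeneratorSeed(spec, "gradient", .applyNoise(pos, spec))
  data.frame(name = sTruth$name, position = pos, s = sTruth$s,
             stringsAsFactors = FALSE)
}

#' Synthetic Stern-Volmer quenching series
#'
#' `F0/F = 1 + KSV [Q]` plus noise.
#'
#' @param KSV Stern-Volmer constant, 1/M.
#' @param qConc Quencher concentrations, M (increasing, typically starting
#'   at 0).
#' @param spec A [SimulationSpec-class].
#' @return A [TitrationSeries-class] of kind `quenching`.
#' @export
makeQuenchingSeries <- function(KSV, qConc, spec = simulationSpec()) {
  stopifnot(KSV >= 0)
  model <- 1 + KSV * qConc
  y <- .withGeneratorSeed(spec, "quenching", .applyNoise(model, spec))
  TitrationSeries(qConc, y, kind = "quenching",
                  yUncertainty = .noiseSigma(model, spec))
}

#' Synthetic unfolding titration
#'
#' Either an exact two-state transition (linear-extrapolation free energy
#' `dG = dG0 - m x`, with optional linear baselines; the signal passes
#' through the baseline midpoint at `Cm = dG0/m`) or a pure line, plus
#' noise. The default baselines (0 and 1, zero slopes) produce an
#' unfolded-fraction-like signal.
#'
#' @param model `two_state` or `linear`.
#' @param params For `two_state`: list with `dG0` (kcal/mol), `m`
#'   (kcal/mol/M) and optional `aN`, `bN`, `aD`, `bD` baselines. For
#'   `linear`: list with `slope`, `intercept`.
#' @param x Denaturant grid, M; defaults to the spec's x grid.
#' @param spec A [SimulationSpec-class].
#' @param RT Thermal energy, kcal/mol.
#' @return A [TitrationSeries-class] of kind `chemical_unfolding`.
#' @export
makeUnfoldingSeries <- function(model = c("two_state", "linear"),
                                params, x = NULL,
                                spec = simulationSpec(),
                                RT = defaultSettings()$unfolding$RT) {
  model <- match.arg(model)
  if (is.null(x)) x <- .xGrid(spec)
  if (model == "two_state") {
    p <- modifyList(list(aN = 0, bN = 0, aD = 1, bD = 0), params)
    y <- .twoStateChemical(x, p$dG0, p$m, p$aN, p$bN, p$aD, p$bD, RT)
  } else {
    y <- params$intercept + params$slope * x
  }
  yn <- .withGeneratorSeed(spec, "unfolding", .applyNoise(y, spec))
  TitrationSeries(x, yn, kind = "chemical_unfolding",
                  yUncertainty = .noiseSigma(y, spec))
}

#' Random sequence with target composition
#'
#' Draws a sequence whose realised order-promoting and proline fractions
#' match the targets to within one residue: `round(prolineFraction * n)`
#' prolines, `round(orderFraction * n)` residues drawn uniformly from the
#' order-promoting set, the rest drawn uniformly from the non-proline
#' disorder-promoting residues, then shuffled.
#'
#' @param length Sequence length.
#' @param orderFraction Target order-promoting fraction.
#' @param prolineFraction Target proline fraction (counted inside the
#'   disorder-promoting budget; `orderFraction + prolineFraction <= 1`).
#' @param spec A [SimulationSpec-class].
#' @return A single-entry [Biostrings::AAStringSet].
#' @export
#' @examples
#' makeSequence(100, 0.3, 0.08, simulationSpec(seed = 1))
makeSequence <- function(length, orderFraction, prolineFraction = 0,
                         spec = simulationSpec()) {
  stopifnot(length >= 1, orderFraction >= 0, prolineFraction >= 0,
            orderFraction + prolineFraction <= 1)
  nOrder <- round(orderFraction * length)
  nPro <- round(prolineFraction * length)
  nRest <- length - nOrder - nPro
  res <- .withGeneratorSeed(spec, "sequence", {
    pool <- c(sample(.orderResidues, nOrder, replace = TRUE),
              rep("P", nPro),
              sample(setdiff(.disorderResidues, "P"), max(nRest, 0),
                     replace = TRUE))
    sample(pool, length(pool))
  })
  Biostrings::AAStringSet(setNames(paste(res, collapse = ""), "synthetic"))
}
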