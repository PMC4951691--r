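## S4 container classes for the package's domain objects.

#' CompositionProfile: residue-class statistics of a protein sequence
#'
#' Holds the sequence-derived disorder indicators of one protein: residue
#' composition, the order-promoting/disorder-promoting split, proline
#' content, average-mass molecular mass, mean absolute net charge per
#' residue and the rescaled mean Kyte-Doolittle hydrophobicity. Created by
#' [compositionProfile()].
#'
#' @slot identifier Sequence identifier.
#' @slot length Number of residues.
#' @slot perResidueFraction Named numeric, fraction of each residue type.
#' @slot orderFraction Fraction of residues in \{I, C, L, V, W, Y, F\}.
#' @slot disorderFraction Fraction in the complementary 13-residue set.
#' @slot prolineFraction Fraction of prolines.
#' @slot molecularMass Average molecular mass in Da (residues + one water).
#' @slot meanNetCharge Absolute net charge per residue at the profile pH.
#' @slot meanHydrophobicity Windowed, rescaled Kyte-Doolittle mean in
#'   `[0, 1]`.
#' @export
setClass("CompositionProfile",
  representation(
    identifier = "character",
    length = "numeric",
    perResidueFraction = "numeric",
    orderFraction = "numeric",
    disorderFraction = "numeric",
    prolineFraction = "numeric",
    molecularMass = "numeric",
    meanNetCharge = "numeric",
    meanHydrophobicity = "numeric"
  ),
  validity = function(object) {
    msg <- character(0)
    fr <- c(object@orderFraction, object@disorderFraction,
            object@prolineFraction, object@perResidueFraction)
    if (any(fr < -1e-12 | fr > 1 + 1e-12))
      msg <- c(msg, "all fractions must lie in [0, 1]")
    if (abs(sum(object@perResidueFraction) - 1) > 1e-9)
      msg <- c(msg, "per-residue fractions must sum to 1")
    if (abs(object@orderFraction + object@disorderFraction - 1) > 1e-9)
      msg <- c(msg, "order and disorder fractions must sum to 1")
    if (object@molecularMass <= 0)
      msg <- c(msg, "molecular mass must be positive")
    if (length(msg)) msg else TRUE
  }
)

#' SolventModel: solvent constants for hydrodynamic mass relations
#'
#' @slot viscosity Solvent viscosity eta in Pa s.
#' @slot buoyancyProduct Product nu2 * rho (partial specific volume times
#'   solvent density), dimensionless; 0.73 for a standard protein in water.
#' @slot avogadro Avogadro's number in 1/mol.
#' @export
setClass("SolventModel",
  representation(viscosity = "numeric", buoyancyProduct = "numeric",
                 avogadro = "numeric"),
  prototype(viscosity = 0.001, buoyancyProduct = 0.73,
            avogadro = 6.02214076e23),
  validity = function(object) {
    msg <- character(0)
    if (object@viscosity <= 0) msg <- c(msg, "viscosity must be positive")
    if (object@buoyancyProduct <= 0 || object@buoyancyProduct >= 1)
      msg <- c(msg, "buoyancy product must lie in (0, 1)")
    if (length(msg)) msg else TRUE
  }
)

#' @describeIn SolventModel-class Constructor.
#' @param viscosity,buoyancyProduct,avogadro See slots.
#' @export
SolventModel <- function(viscosity = 0.001, buoyancyProduct = 0.73,
                         avogadro = 6.02214076e23) {
  new("SolventModel", viscosity = viscosity,
      buoyancyProduct = buoyancyProduct, avogadro = avogadro)
}

#' SECCalibration: fitted size-exclusion column calibration
#'
#' Ordinary least-squares lines of the partition coefficient Kav against
#' log10(Rh) and/or log10(mass) over a set of (usually globular) standards.
#' Created by [calibrateSEC()], consumed by [secEstimate()].
#'
#' @slot V0 Void volume in mL.
#' @slot Vt Total (bed) volume in mL.
#' @slot standards data.frame of the standards with their computed Kav.
#' @slot fitRh Named numeric `(slope, intercept, r2)` of Kav vs log10(Rh),
#'   or NA when too few standards carry an Rh.
#' @slot fitMass Same for Kav vs log10(mass in Da).
#' @slot diagnostics List of per-fit residual vectors.
#' @export
setClass("SECCalibration",
  representation(V0 = "numeric", Vt = "numeric", standards = "data.frame",
                 fitRh = "numeric", fitMass = "numeric",
                 diagnostics = "list"),
  validity = function(object) {
    if (object@Vt <= object@V0) "Vt must exceed V0" else TRUE
  }
)

#' HydroRecord: the hydrodynamic observables of one analyte
#'
#' A light record bundling the hydrodynamic radius, radius of gyration,
#' sedimentation coefficient, mass estimates (with method provenance) and
#' the Q-factor of a single analyte. Created by [hydroRecord()].
#'
#' @slot Rh,RhSE Hydrodynamic radius and its uncertainty, nm.
#' @slot Rg,RgSE Radius of gyration and its uncertainty, nm.
#' @slot s Sedimentation coefficient in Svedberg (1 S = 1e-13 s).
#' @slot massEstimates data.frame with columns `method`
#'   (sec_apparent, siegel_monte, sequence_theoretical, dls) and `value` (Da).
#' @slot qFactor,qFactorSE Q = Rg/Rh and its propagated uncertainty.
#' @export
setClass("HydroRecord",
  representation(Rh = "numeric", RhSE = "numeric", Rg = "numeric",
                 RgSE = "numeric", s = "numeric",
                 massEstimates = "data.frame",
                 qFactor = "numeric", qFactorSE = "numeric"),
  validity = function(object) {
    msg <- character(0)
    for (nm in c("Rh", "Rg", "s"))
      if (!is.na(slot(object, nm)) && slot(object, nm) <= 0)
        msg <- c(msg, paste(nm, "must be positive when present"))
    if (!is.na(object@qFactor) && !is.na(object@Rh) && !is.na(object@Rg) &&
        abs(object@qFactor - object@Rg / object@Rh) > 1e-9)
      msg <- c(msg, "qFactor must equal Rg/Rh when both radii are present")
    if (length(msg)) msg else TRUE
  }
)

#' ScatteringCurve: a one-dimensional SAXS profile
#'
#' @slot q Momentum transfer grid, strictly increasing, in 1/nm.
#' @slot I Intensities (arbitrary units), finite.
#' @slot sigma Optional per-point intensity errors (length 0 when absent).
#' @slot metadata Free-form list.
#' @export
setClass("ScatteringCurve",
  representation(q = "numeric", I = "numeric", sigma = "numeric",
                 metadata = "list"),
  prototype(sigma = numeric(0), metadata = list()),
  validity = function(object) {
    msg <- character(0)
    if (length(object@q) != length(object@I))
      msg <- c(msg, "q and I must have equal length")
    if (length(object@sigma) &&
        length(object@sigma) != length(object@q))
      msg <- c(msg, "sigma must be empty or match q in length")
    if (any(!is.finite(object@q)) || any(object@q <= 0))
      msg <- c(msg, "q must be positive and finite")
    if (any(diff(object@q) <= 0))
      msg <- c(msg, "q must be strictly increasing")
    if (any(!is.finite(object@I)))
      msg <- c(msg, "intensities must be finite")
    if (length(msg)) msg else TRUE
  }
)

#' @describeIn ScatteringCurve-class Constructor.
#' @param q,I,sigma,metadata See slots.
#' @export
ScatteringCurve <- function(q, I, sigma = numeric(0), metadata = list()) {
  new("ScatteringCurve", q = as.numeric(q), I = as.numeric(I),
      sigma = as.numeric(sigma), metadata = metadata)
}

#' GuinierResult: the outcome of an iterative Guinier fit
#'
#' @slot Rg,RgSE Fitted radius of gyration and standard error, nm.
#' @slot I0,I0SE Fitted forward scattering and standard error.
#' @slot window Fitted q window `(qmin, qmax)` in 1/nm.
#' @slot qRgWindow The same window in qRg units.
#' @slot nPoints Number of points in the final window.
#' @slot r2 Coefficient of determination of the ln(I) vs q^2 line.
#' @slot converged TRUE when the window iteration reached a fixed point.
#' @slot iterations Number of window iterations used.
#' @export
setClass("GuinierResult",
  representation(Rg = "numeric", RgSE = "numeric", I0 = "numeric",
                 I0SE = "numeric", window = "numeric",
                 qRgWindow = "numeric", nPoints = "numeric", r2 = "numeric",
                 converged = "logical", iterations = "numeric"),
  validity = function(object) {
    if (object@nPoints < 5) "a Guinier window needs at least 5 points"
    else TRUE
  }
)

#' KratkyProfile: a dimensionless Kratky transform
#'
#' Holds x = qRg and y = (qRg)^2 I/I0 together with the detected interior
#' peak, the mean tail level over the configured high-x band, and the shape
#' class assigned by [kratkyClassify()].
#'
#' @slot x qRg grid (increasing).
#' @slot y Dimensionless Kratky ordinate.
#' @slot peak List with `x`, `y`, `prominence` when a qualifying interior
#'   maximum exists, empty otherwise.
#' @slot tailLevel Mean y over the tail band (NA when not covered).
#' @slot shapeClass One of `globular_compact`, `compact_plus_flexible`,
#'   `extended`, or `inconclusive`.
#' @slot settings The kratky settings used.
#' @export
setClass("KratkyProfile",
  representation(x = "numeric", y = "numeric", peak = "list",
                 tailLevel = "numeric", shapeClass = "character",
                 settings = "list"),
  validity = function(object) {
    if (length(object@x) != length(object@y))
      "x and y must have equal length"
    else if (any(diff(object@x) <= 0)) "x must be increasing"
    else TRUE
  }
)

#' TitrationSeries: a spectroscopic signal against a titrant
#'
#' @slot x Titrant axis (quencher M, denaturant M, or temperature),
#'   strictly increasing.
#' @slot y Signal (intensity ratio, ellipticity, lambda-max, anisotropy,
#'   unfolded fraction, ...).
#' @slot kind Signal kind tag, e.g. `quenching`, `chemical_unfolding`,
#'   `thermal_unfolding`, `lambda_max`, `unfolded_fraction`, `anisotropy`.
#' @slot yUncertainty Optional per-point uncertainty (length 0 when absent).
#' @slot flags Character vector of quality flags.
#' @export
setClass("TitrationSeries",
  representation(x = "numeric", y = "numeric", kind = "character",
                 yUncertainty = "numeric", flags = "character"),
  prototype(yUncertainty = numeric(0), flags = character(0)),
  validity = function(object) {
    msg <- character(0)
    if (length(object@x) != length(object@y))
      msg <- c(msg, "x and y must have equal length")
    if (any(diff(object@x) <= 0))
      msg <- c(msg, "x must be strictly increasing")
    if (length(object@yUncertainty) &&
        length(object@yUncertainty) != length(object@x))
      msg <- c(msg, "yUncertainty must be empty or match x in length")
    if (length(msg)) msg else TRUE
  }
)

#' @describeIn TitrationSeries-class Constructor.
#' @param x,y,kind,yUncertainty See slots.
#' @export
TitrationSeries <- function(x, y, kind = "generic",
                            yUncertainty = numeric(0)) {
  new("TitrationSeries", x = as.numeric(x), y = as.numeric(y), kind = kind,
      yUncertainty = as.numeric(yUncertainty))
}

#' UnfoldingFit: two-state versus linear unfolding model comparison
#'
#' @slot model Winning model, `two_state` or `linear`.
#' @slot parameters Named list of the fitted parameters of both models:
#'   for the two-state model `dG0` (kcal/mol), `m` (kcal/mol/M),
#'   `Cm = dG0/m` (M) and the four baseline coefficients; for the linear
#'   model `slope` and `intercept`.
#' @slot aicc Named numeric of AICc values, one per candidate model.
#' @slot verdict `cooperative` or `weakly_cooperative_or_linear` (NA
#'   character when degenerate).
#' @slot flags Quality flags (e.g. `two_state_not_converged`, `degenerate`).
#' @slot fitted Fitted values of the winning model.
#' @export
setClass("UnfoldingFit",
  representation(model = "character", parameters = "list",
                 aicc = "numeric", verdict = "character",
                 flags = "character", fitted = "numeric"),
  prototype(flags = character(0))
)

#' EvidenceBundle: the per-probe evidence entering the state classifier
#'
#' All channels are optional (NA / empty when absent); [classifyState()]
#' requires at least two populated channels for a full-confidence verdict.
#'
#' @slot chClass `native_side` or `unfolded_side` from [chClassify()].
#' @slot qValue The measured Q-factor.
#' @slot qClasses Band labels from [qClassify()] (members).
#' @slot rhStateDeviations Named numeric from [rhStateDeviations()].
#' @slot kratkyClass Shape class from [kratkyClassify()].
#' @slot unfoldingVerdicts Character vector of [fitUnfolding()] verdicts.
#' @slot ansAffinity TRUE when the protein shows high ANS affinity.
#' @slot trpLambdaMax Tryptophan emission maximum in nm.
#' @export
setClass("EvidenceBundle",
  representation(chClass = "character", qValue = "numeric",
                 qClasses = "character", rhStateDeviations = "numeric",
                 kratkyClass = "character", unfoldingVerdicts = "character",
                 ansAffinity = "logical", trpLambdaMax = "numeric"),
  prototype(chClass = NA_character_, qValue = NA_real_,
            qClasses = character(0), rhStateDeviations = numeric(0),
            kratkyClass = NA_character_, unfoldingVerdicts = character(0),
            ansAffinity = NA, trpLambdaMax = NA_real_)
)

#' @describeIn EvidenceBundle-class Constructor; any argument may be left
#'   at its empty default.
#' @param chClass,qValue,qClasses,rhStateDeviations,kratkyClass See slots.
#' @param unfoldingVerdicts,ansAffinity,trpLambdaMax See slots.
#' @export
evidenceBundle <- function(chClass = NA_character_, qValue = NA_real_,
                           qClasses = character(0),
                           rhStateDeviations = numeric(0),
                           kratkyClass = NA_character_,
                           unfoldingVerdicts = character(0),
                           ansAffinity = NA, trpLambdaMax = NA_real_) {
  new("EvidenceBundle", chClass = chClass, qValue = qValue,
      qClasses = qClasses, rhStateDeviations = rhStateDeviations,
      kratkyClass = kratkyClass, unfoldingVerdicts = unfoldingVerdicts,
      ansAffinity = ansAffinity, trpLambdaMax = trpLambdaMax)
}

#' ConformationalAssessment: the integrated conformational-state verdict
#'
#' @slot primaryState Highest-scoring state among `native_globular`,
#'   `molten_globule`, `pre_molten_globule`, `extended_coil`.
#' @slot compatibleStates data.frame of states with positive score, ranked,
#'   scores normalised to sum to 1.
#' @slot rationale Human-readable evidence statements, one per channel.
#' @slot confidence `strong`, `moderate` or `weak`.
#' @slot nChannels Number of evidence channels that voted.
#' @export
setClass("ConformationalAssessment",
  representation(primaryState = "character", compatibleStates = "data.frame",
                 rationale = "character", confidence = "character",
                 nChannels = "numeric"),
  validity = function(object) {
    msg <- character(0)
    if (nrow(object@compatibleStates) &&
        abs(sum(object@compatibleStates$score) - 1) > 1e-9)
      msg <- c(msg, "state scores must sum to 1")
    if (!length(object@rationale))
      msg <- c(msg, "rationale must be non-empty")
    if (length(msg)) msg else TRUE
  }
)

#' SimulationSpec: seed, noise model and grids for the synthetic generators
#'
#' @slot seed Integer seed; every generator derives an independent stream
#'   from (seed, generator name), so fixtures do not share randomness.
#' @slot noiseModel `none`, `relative` (sigma as a fraction of the model
#'   value) or `absolute`.
#' @slot sigma Noise scale (fraction for `relative`, signal units for
#'   `absolute`).
#' @slot qGrid `c(min, max, n)` for scattering curves, 1/nm.
#' @slot xGrid `c(min, max, n)` for titration series.
#' @export
setClass("SimulationSpec",
  representation(seed = "numeric", noiseModel = "character",
                 sigma = "numeric", qGrid = "numeric", xGrid = "numeric"),
  validity = function(object) {
    msg <- character(0)
    if (!object@noiseModel %in% c("none", "relative", "absolute"))
      msg <- c(msg, "unknown noise model")
    if (object@sigma < 0) msg <- c(msg, "sigma must be >= 0")
    if (length(msg)) msg else TRUE
  }
)

#' @describeIn SimulationSpec-class Constructor. The default q grid
#'   (0.05-4.0 1/nm, 400 points) matches a typical beamline range.
#' @param seed,noiseModel,sigma,qGrid,xGrid See slots.
#' @export
simulationSpec <- function(seed = 1L, noiseModel = "none", sigma = 0,
                           qGrid = c(0.05, 4.0, 400),
                           xGrid = c(0, 5, 20)) {
  new("SimulationSpec", seed = as.numeric(seed), noiseModel = noiseModel,
      sigma = sigma, qGrid = qGrid, xGrid = xGrid)
}
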