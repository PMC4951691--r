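## The hydrodynamic chain: SEC calibration, Rh / apparent-mass estimation,
## sucrose-gradient sedimentation, Siegel-Monte mass, per-state Rh scaling
## laws, and the Q-factor.

# Unit conversions used throughout (inputs/outputs are stated per function).
.SVEDBERG <- 1e-13   # s per Svedberg
.NM <- 1e-9          # m per nm

#' SEC partition coefficient
#'
#' `Kav = (Ve - V0) / (Vt - V0)`. An elution volume outside `[V0, Vt]` is
#' physically suspect; the value is still returned (outside `[0, 1]`) with
#' a warning.
#'
#' @param Ve Elution volume, mL.
#' @param V0 Void volume, mL.
#' @param Vt Total (bed) volume, mL.
#' @return The partition coefficient (dimensionless).
#' @export
#' @examples
#' partitionCoefficient(12.2, 8, 20)
partitionCoefficient <- function(Ve, V0, Vt) {
  if (Vt <= V0) stop("Vt must exceed V0")
  k <- (Ve - V0) / (Vt - V0)
  if (any(k < 0 | k > 1))
    warning("elution volume outside [V0, Vt]; Kav outside [0, 1]")
  k
}

.olsLine <- function(x, y) {
  fit <- lm(y ~ x)
  s <- suppressWarnings(summary(fit))  # noiseless fixtures fit perfectly
  list(slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
       r2 = s$r.squared, residuals = unname(residuals(fit)))
}

#' Calibrate a size-exclusion column
#'
#' Computes Kav for each standard and fits ordinary least-squares lines of
#' Kav against log10(Rh) and against log10(mass), whichever properties at
#' least two standards carry. Globular standards make both relations linear;
#' a non-globular analyte then reveals itself by disagreeing between the
#' two inversions.
#'
#' @param standards data.frame with columns `name`, `Ve` (mL) and at least
#'   one of `Rh` (nm), `mass` (Da). NA properties are allowed per standard.
#' @param V0,Vt Void and total column volumes, mL.
#' @return A [SECCalibration-class] object.
#' @export
#' @examples
#' std <- data.frame(name = c("a", "b", "c"), Ve = c(10, 12, 14),
#'                   Rh = c(4.5, 3.1, 2.1), mass = c(158000, 44000, 13700))
#' calibrateSEC(std, V0 = 8, Vt = 20)
calibrateSEC <- function(standards, V0, Vt) {
  if (Vt <= V0) stop("Vt must exceed V0")
  stopifnot(is.data.frame(standards), all(c("name", "Ve") %in%
                                            colnames(standards)))
  standards$Kav <- partitionCoefficient(standards$Ve, V0, Vt)
  fitFor <- function(prop) {
    if (!prop %in% colnames(standards)) return(NULL)
    ok <- is.finite(standards[[prop]]) & is.finite(standards$Kav)
    if (sum(ok) < 2L) return(NULL)
    if (diff(range(standards$Kav[ok])) < 1e-12)
      stop("degenerate calibration: all standards elute at the same Kav")
    .olsLine(log10(standards[[prop]][ok]), standards$Kav[ok])
  }
  fr <- fitFor("Rh")
  fm <- fitFor("mass")
  if (is.null(fr) && is.null(fm))
    stop("need at least 2 standards with Rh or mass to calibrate")
  asNum <- function(f) if (is.null(f)) c(slope = NA_real_,
                                         intercept = NA_real_, r2 = NA_real_)
    else c(slope = f$slope, intercept = f$intercept, r2 = f$r2)
  new("SECCalibration", V0 = V0, Vt = Vt, standards = standards,
      fitRh = asNum(fr), fitMass = asNum(fm),
      diagnostics = list(residualsRh = if (!is.null(fr)) fr$residuals,
                         residualsMass = if (!is.null(fm)) fm$residuals))
}

#' Estimate Rh and apparent mass from a partition coefficient
#'
#' Inverts the fitted calibration lines at `k`. An analyte outside the
#' calibrated Kav range triggers an extrapolation warning. The apparent mass
#' assumes the analyte shares the standards' (globular) conformation - for
#' expanded proteins it overestimates the true mass, which is precisely the
#' diagnostic this pipeline exploits.
#'
#' @param k Partition coefficient of the analyte.
#' @param calib A [SECCalibration-class].
#' @return List with `Rh` (nm, NA when not calibrated) and `mass` (Da,
#'   NA when not calibrated).
#' @export
secEstimate <- function(k, calib) {
  stopifnot(is(calib, "SECCalibration"))
  rng <- range(calib@standards$Kav, na.rm = TRUE)
  if (k < rng[1L] || k > rng[2L])
    warning(sprintf("Kav = %.3f outside calibrated range [%.3f, %.3f]; extrapolating",
                    k, rng[1L], rng[2L]))
  invert <- function(fit) {
    if (anyNA(fit)) return(NA_real_)
    10^((k - fit[["intercept"]]) / fit[["slope"]])
  }
  list(Rh = invert(calib@fitRh), mass = invert(calib@fitMass))
}

#' Molecular mass from the Siegel-Monte relation
#'
#' `M = s * N0 * 6 pi eta Rh / (1 - nu2 rho)`, combining the sedimentation
#' coefficient and the hydrodynamic radius into a solution mass that does
#' not assume globularity. With the defaults (eta = 0.001 Pa s,
#' nu2 rho = 0.73) and s in Svedberg, Rh in nm, the result is in Da.
#'
#' @param s Sedimentation coefficient, Svedberg (1 S = 1e-13 s).
#' @param Rh Hydrodynamic radius, nm.
#' @param solvent A [SolventModel-class].
#' @return Molecular mass in Da.
#' @export
#' @examples
#' siegelMonteMass(4.2, 3.4) / 1000  # about 60 kDa
siegelMonteMass <- function(s, Rh, solvent = SolventModel()) {
  stopifnot(is(solvent, "SolventModel"))
  if (any(s <= 0) || any(Rh <= 0)) stop("s and Rh must be positive")
  # kg/mol -> g/mol (Da)
  1000 * (s * .SVEDBERG) * solvent@avogadro *
    (6 * pi * solvent@viscosity * (Rh * .NM)) /
    (1 - solvent@buoyancyProduct)
}

#' Expected Rh of a conformational state at a given mass
#'
#' Evaluates the empirical per-state compaction law
#' `log10(Rh[A]) = slope * log10(M[Da]) + intercept` (see [scalingLaws()])
#' and returns the radius in nm. The exponents grow from the native state
#' to the chemically unfolded states, so more expanded conformations
#' expand faster with mass.
#'
#' @param mass Molecular mass, Da.
#' @param state One of `native`, `molten_globule`, `pre_molten_globule`,
#'   `urea_unfolded`, `gdmcl_unfolded`.
#' @param coefficients Coefficient table, see [scalingLaws()].
#' @return Expected hydrodynamic radius in nm.
#' @export
#' @examples
#' conformerRh(2 * 27551.7, "native")          # about 3.1 nm
#' conformerRh(2 * 27551.7, "molten_globule")  # about 3.4 nm
conformerRh <- function(mass, state, coefficients = scalingLaws()) {
  if (any(mass <= 0)) stop("mass must be positive")
  i <- match(state, coefficients$state)
  if (anyNA(i)) stop("unknown conformational state: ",
                     paste(state[is.na(i)], collapse = ", "))
  # law is in Angstrom; convert to nm
  10^(coefficients$slope[i] * log10(mass) + coefficients$intercept[i]) / 10
}

#' Q-factor (Rg/Rh)
#'
#' The ratio of the radius of gyration to the hydrodynamic radius is a
#' compactness diagnostic: sqrt(3/5) = 0.775 for a homogeneous sphere,
#' about 0.8 for globular proteins, near 1 for pre-molten globules and
#' 1.51 for an ideal random coil. Uncertainties, when given, are propagated
#' in quadrature.
#'
#' @param Rg Radius of gyration, nm.
#' @param Rh Hydrodynamic radius, nm.
#' @param RgSE,RhSE Optional 1-sigma uncertainties.
#' @return List with `q` and `se` (NA when no uncertainties given).
#' @export
#' @examples
#' qFactor(3.5, 3.4)$q  # 1.03
qFactor <- function(Rg, Rh, RgSE = NA_real_, RhSE = NA_real_) {
  if (Rg <= 0 || Rh <= 0) stop("Rg and Rh must be positive")
  q <- Rg / Rh
  se <- if (is.na(RgSE) && is.na(RhSE)) NA_real_ else {
    rgTerm <- if (is.na(RgSE)) 0 else (RgSE / Rg)^2
    rhTerm <- if (is.na(RhSE)) 0 else (RhSE / Rh)^2
    q * sqrt(rgTerm + rhTerm)
  }
  list(q = q, se = se)
}

#' Classify a Q-factor against the per-state bands
#'
#' Returns every band containing Q (the bands overlap by design) plus the
#' bands whose nearest edge lies within `adjacency` of Q - the "decision
#' zone" cases a Kratky plot is then used to resolve.
#'
#' @param Q Q-factor value.
#' @param adjacency Adjacency distance in Q units (default from settings).
#' @param bands Band table, see [qBands()].
#' @param settings Settings list.
#' @return List with `members` and `adjacent` character vectors of state
#'   labels.
#' @export
#' @examples
#' qClassify(1.03)   # member: pre_molten_globule; adjacent: molten_globule
#' qClassify(0.775)  # sphere, globular and molten_globule all contain it
qClassify <- function(Q, adjacency = NULL, bands = qBands(),
                      settings = defaultSettings()) {
  if (Q <= 0) stop("Q must be positive")
  if (is.null(adjacency)) adjacency <- settings$qAdjacency
  inBand <- Q >= bands$lower & Q <= bands$upper
  edgeDist <- pmin(abs(Q - bands$lower), abs(Q - bands$upper))
  near <- !inBand & edgeDist <= adjacency
  list(members = bands$state[inBand], adjacent = bands$state[near])
}

#' Sedimentation coefficient from a sucrose-gradient run
#'
#' Migration in a zonal sucrose gradient is linear in s over the usual
#' protein range, so the sample's s is obtained from a least-squares linear
#' map of the standards' positions to their known s, evaluated at the
#' sample's position. Position may be a fraction index or % sucrose - the
#' map is linear either way.
#'
#' @param samplePosition Gradient coordinate of the sample.
#' @param standards data.frame with columns `position` and `s` (Svedberg);
#'   positions must be monotone in s.
#' @return List with `s` (Svedberg), the fitted `slope`/`intercept`, `r2`,
#'   and `extrapolated` flag.
#' @export
sedimentationFromGradient <- function(samplePosition, standards) {
  stopifnot(is.data.frame(standards),
            all(c("position", "s") %in% colnames(standards)))
  if (nrow(standards) < 2L) stop("need at least 2 gradient standards")
  o <- order(standards$s)
  d <- diff(standards$position[o])
  if (!(all(d > 0) || all(d < 0)))
    stop("standard positions are not monotone in s")
  fit <- .olsLine(standards$position, standards$s)
  extrapolated <- samplePosition < min(standards$position) ||
    samplePosition > max(standards$position)
  if (extrapolated)
    warning("sample position outside the standards' span; extrapolating")
  list(s = fit$slope * samplePosition + fit$intercept,
       slope = fit$slope, intercept = fit$intercept, r2 = fit$r2,
       extrapolated = extrapolated)
}

#' Theoretical Q-factor of an ideal Gaussian coil (Kirkwood double sum)
#'
#' Computes Rg/Rh for an ideal (theta-solvent) Gaussian chain of `nBeads`
#' beads with bond length `bond`: `Rg = b sqrt(N/6)` and the Kirkwood
#' hydrodynamic radius `1/Rh = (1/N^2) sum_{i != j} <1/r_ij>` with
#' `<1/r_ij> = sqrt(6/pi) / (b sqrt(|i-j|))`. Converges to about 1.5 from
#' below as N grows; the commonly quoted theoretical coil value is 1.51.
#'
#' @param nBeads Number of beads (>= 100; use >= 1e4 for a converged
#'   value).
#' @param bond Bond length (cancels in the ratio).
#' @return The dimensionless Q-factor.
#' @export
#' @examples
#' idealCoilQFactor(1e4)
idealCoilQFactor <- function(nBeads = 1e5, bond = 1) {
  nBeads <- as.integer(nBeads)
  if (nBeads < 100L) stop("nBeads must be >= 100")
  Rg <- bond * sqrt(nBeads / 6)
  k <- seq_len(nBeads - 1L)
  invRh <- sqrt(6 / pi) / bond * (2 / nBeads^2) * sum((nBeads - k) / sqrt(k))
  Rg * invRh
}

#' Assemble a HydroRecord
#'
#' Bundles the hydrodynamic observables of one analyte; the Q-factor is
#' computed (with propagated uncertainty) when both radii are present.
#'
#' @param Rh,RhSE Hydrodynamic radius and uncertainty, nm.
#' @param Rg,RgSE Radius of gyration and uncertainty, nm.
#' @param s Sedimentation coefficient, Svedberg.
#' @param massEstimates data.frame with columns `method` and `value` (Da).
#' @return A [HydroRecord-class].
#' @export
hydroRecord <- function(Rh = NA_real_, RhSE = NA_real_, Rg = NA_real_,
                        RgSE = NA_real_, s = NA_real_,
                        massEstimates = data.frame(method = character(0),
                                                   value = numeric(0))) {
  qf <- if (!is.na(Rh) && !is.na(Rg))
    qFactor(Rg, Rh, RgSE, RhSE) else list(q = NA_real_, se = NA_real_)
  new("HydroRecord", Rh = Rh, RhSE = RhSE, Rg = Rg, RgSE = RgSE, s = s,
      massEstimates = massEstimates, qFactor = qf$q, qFactorSE = qf$se)
}
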