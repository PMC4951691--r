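## Residue-level constant tables and tunable analysis settings.
## Everything numeric that a user might legitimately override lives here.

# Average (not monoisotopic) residue masses in Da, ExPASy/ProtParam-style.
.residueMasses <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)

.waterMass <- 18.01528

# Kyte-Doolittle hydropathy scale (raw, later rescaled to [0, 1]).
.kdScale <- c(
  I =  4.5, V =  4.2, L =  3.8, F =  2.8, C =  2.5, M =  1.9, A =  1.8,
  G = -0.4, T = -0.7, S = -0.8, W = -0.9, Y = -1.3, P = -1.6, H = -3.2,
  E = -3.5, Q = -3.5, D = -3.5, N = -3.5, K = -3.9, R = -4.5
)

# Residue classes: the bulky/order-promoting set and its complement, the
# disorder-promoting set. Together they partition the 20-letter alphabet.
.orderResidues <- c("I", "C", "L", "V", "W", "Y", "F")
.disorderResidues <- c("A", "G", "R", "D", "H", "Q", "T", "K", "N", "M",
                       "S", "E", "P")

# Side-chain and terminal pKa values (EMBOSS set) for the
# Henderson-Hasselbalch charge model used at pH != 7.
.pKaTable <- c(
  C = 8.5, D = 3.9, E = 4.1, H = 6.5, K = 10.8, R = 12.5, Y = 10.1,
  Nterm = 8.6, Cterm = 3.6
)

#' Empirical hydrodynamic-radius scaling laws per conformational state
#'
#' Per-state coefficients of the empirical compaction relations
#' `log10(Rh[A]) = slope * log10(M[Da]) + intercept` linking the
#' hydrodynamic radius of a protein to its molecular mass for the native,
#' molten-globule, pre-molten-globule, urea-unfolded and GdmCl-unfolded
#' states. The literature carries more than one published coefficient set;
#' this one reproduces the canonical expectations used throughout the
#' package (e.g. about 3 nm for a 55 kDa native globule and about 3.4 nm
#' for a molten-globule dimer of the same mass). Pass a modified copy to
#' [conformerRh()] to use a different set.
#'
#' @return A data.frame with columns `state`, `slope` and `intercept`.
#' @export
#' @examples
#' scalingLaws()
scalingLaws <- function() {
  data.frame(
    state = c("native", "molten_globule", "pre_molten_globule",
              "urea_unfolded", "gdmcl_unfolded"),
    slope = c(0.369, 0.334, 0.392, 0.493, 0.526),
    intercept = c(-0.254, -0.053, -0.188, -0.649, -0.691),
    stringsAsFactors = FALSE
  )
}

#' Q-factor bands per conformational state
#'
#' Membership bands of the Q-factor (Rg/Rh) used by [qClassify()]:
#' a compact homogeneous sphere sits at sqrt(3/5) = 0.775, globular
#' proteins close to 0.8, molten globules between 0.70 and 0.93,
#' pre-molten globules close to 1, and an ideal random coil at 1.51.
#' Bands overlap by construction; the classifier module disambiguates
#' using the Kratky shape.
#'
#' @return A data.frame with columns `state`, `lower` and `upper`.
#' @export
#' @examples
#' qBands()
qBands <- function() {
  data.frame(
    state = c("sphere", "globular", "molten_globule",
              "pre_molten_globule", "random_coil"),
    lower = c(0.765, 0.76, 0.70, 0.93, 1.35),
    upper = c(0.785, 0.86, 0.93, 1.15, Inf),
    stringsAsFactors = FALSE
  )
}

#' Default analysis settings
#'
#' Central registry of the tunable thresholds and constants used across the
#' package. Override individual entries by passing a modified copy to the
#' functions that accept a `settings` argument, or load overrides from a
#' YAML file with [loadSettings()].
#'
#' Components:
#' \describe{
#'   \item{chBoundary}{Charge-hydropathy boundary `<R>_b = slope * <H> +
#'     intercept` separating natively folded from natively unfolded
#'     proteins in the Uversky plane.}
#'   \item{qAdjacency}{Distance (in Q units) within which a non-member band
#'     is still reported as adjacent by [qClassify()].}
#'   \item{kratky}{Savitzky-Golay smoothing window/order, peak prominence
#'     floor (fraction of max), tail band in qRg units, and the
#'     peak-fraction threshold separating `globular_compact` from
#'     `compact_plus_flexible`.}
#'   \item{guinier}{Default qRg fit window, hard ceiling, minimum points
#'     and maximum window iterations.}
#'   \item{unfolding}{AICc margin required to call a transition
#'     cooperative, and the thermal-energy RT in kcal/mol (298.15 K).}
#'   \item{sternVolmer}{Significance level for the curvature test and the
#'     tolerance below 1 that triggers the static-quenching warning.}
#'   \item{classifier}{Per-channel weights and the tie-break priority
#'     order.}
#' }
#'
#' @return A named list of settings.
#' @export
#' @examples
#' s <- defaultSettings()
#' s$kratky$peakFraction
defaultSettings <- function() {
  list(
    chBoundary = c(slope = 2.785, intercept = -1.151),
    qAdjacency = 0.1,
    kratky = list(
      sgWindow = 11, sgOrder = 3,
      prominenceFloor = 0.05,
      tailBand = c(2.5, 4.0),
      peakFraction = 0.5
    ),
    guinier = list(
      window = c(0.759, 1.294),
      qRgCeiling = 1.3,
      minPoints = 5,
      maxIterations = 50
    ),
    unfolding = list(deltaAICc = 4, RT = 0.59249),
    sternVolmer = list(curvatureAlpha = 0.01, belowOneTolerance = 0.02),
    classifier = list(
      weights = c(kratky = 1, rhDeviation = 1, q = 1, unfolding = 1,
                  ch = 1, ans = 1, lambdaMax = 1),
      priority = c("kratky", "rhDeviation", "q", "unfolding", "ch",
                   "ans", "lambdaMax"),
      strongTop = 0.5, strongMargin = 0.15, weakMargin = 0.1
    )
  )
}

#' Load settings overrides from a YAML file
#'
#' Reads a YAML file and merges it (recursively) over [defaultSettings()],
#' so a file only needs to state the entries it changes.
#'
#' @param path Path to a YAML file.
#' @return A settings list as from [defaultSettings()].
#' @export
loadSettings <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read settings files")
  overrides <- yaml::read_yaml(path)
  mergeList <- function(base, extra) {
    for (name in names(extra)) {
      if (is.list(base[[name]]) && is.list(extra[[name]]))
        base[[name]] <- mergeList(base[[name]], extra[[name]])
      else
        base[[name]] <- extra[[name]]
    }
    base
  }
  mergeList(defaultSettings(), overrides)
}
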