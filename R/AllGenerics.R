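## Accessor generics and show methods.

#' @name accessors
#' @title Accessors for moltenscope containers
#' @description Small accessor generics so user code never reaches into
#'   slots directly.
#' @param object A moltenscope S4 object.
#' @return The corresponding component.
NULL

#' @rdname accessors
#' @export
setGeneric("qValues", function(object) standardGeneric("qValues"))
#' @rdname accessors
#' @export
setMethod("qValues", "ScatteringCurve", function(object) object@q)

#' @rdname accessors
#' @export
setGeneric("intensities", function(object) standardGeneric("intensities"))
#' @rdname accessors
#' @export
setMethod("intensities", "ScatteringCurve", function(object) object@I)

#' @rdname accessors
#' @export
setGeneric("intensityErrors",
           function(object) standardGeneric("intensityErrors"))
#' @rdname accessors
#' @export
setMethod("intensityErrors", "ScatteringCurve", function(object) object@sigma)

#' @rdname accessors
#' @export
setGeneric("xValues", function(object) standardGeneric("xValues"))
#' @rdname accessors
#' @export
setMethod("xValues", "TitrationSeries", function(object) object@x)
#' @rdname accessors
#' @export
setMethod("xValues", "KratkyProfile", function(object) object@x)

#' @rdname accessors
#' @export
setGeneric("yValues", function(object) standardGeneric("yValues"))
#' @rdname accessors
#' @export
setMethod("yValues", "TitrationSeries", function(object) object@y)
#' @rdname accessors
#' @export
setMethod("yValues", "KratkyProfile", function(object) object@y)

#' @rdname accessors
#' @export
setGeneric("seriesKind", function(object) standardGeneric("seriesKind"))
#' @rdname accessors
#' @export
setMethod("seriesKind", "TitrationSeries", function(object) object@kind)

#' @rdname accessors
#' @export
setGeneric("radiusOfGyration",
           function(object) standardGeneric("radiusOfGyration"))
#' @rdname accessors
#' @export
setMethod("radiusOfGyration", "GuinierResult",
          function(object) c(Rg = object@Rg, se = object@RgSE))

#' @rdname accessors
#' @export
setGeneric("forwardScattering",
           function(object) standardGeneric("forwardScattering"))
#' @rdname accessors
#' @export
setMethod("forwardScattering", "GuinierResult",
          function(object) c(I0 = object@I0, se = object@I0SE))

#' @rdname accessors
#' @export
setGeneric("shapeClass", function(object) standardGeneric("shapeClass"))
#' @rdname accessors
#' @export
setMethod("shapeClass", "KratkyProfile", function(object) object@shapeClass)

#' @rdname accessors
#' @export
setGeneric("primaryState", function(object) standardGeneric("primaryState"))
#' @rdname accessors
#' @export
setMethod("primaryState", "ConformationalAssessment",
          function(object) object@primaryState)

#' @rdname accessors
#' @export
setGeneric("stateScores", function(object) standardGeneric("stateScores"))
#' @rdname accessors
#' @export
setMethod("stateScores", "ConformationalAssessment",
          function(object) object@compatibleStates)

#' @rdname accessors
#' @export
setGeneric("assessmentConfidence",
           function(object) standardGeneric("assessmentConfidence"))
#' @rdname accessors
#' @export
setMethod("assessmentConfidence", "ConformationalAssessment",
          function(object) object@confidence)

#' @rdname accessors
#' @export
setGeneric("molecularMass", function(object) standardGeneric("molecularMass"))
#' @rdname accessors
#' @export
setMethod("molecularMass", "CompositionProfile",
          function(object) object@molecularMass)

#' @rdname accessors
#' @export
setGeneric("orderFraction", function(object) standardGeneric("orderFraction"))
#' @rdname accessors
#' @export
setMethod("orderFraction", "CompositionProfile",
          function(object) object@orderFraction)

#' @rdname accessors
#' @export
setGeneric("disorderFraction",
           function(object) standardGeneric("disorderFraction"))
#' @rdname accessors
#' @export
setMethod("disorderFraction", "CompositionProfile",
          function(object) object@disorderFraction)

#' @rdname accessors
#' @export
setGeneric("prolineFraction",
           function(object) standardGeneric("prolineFraction"))
#' @rdname accessors
#' @export
setMethod("prolineFraction", "CompositionProfile",
          function(object) object@prolineFraction)

setMethod("show", "CompositionProfile", function(object) {
  cat("CompositionProfile:", object@identifier, "\n")
  cat(sprintf("  %d residues, %.1f Da\n", object@length,
              object@molecularMass))
  cat(sprintf("  order %.1f%% | disorder %.1f%% | proline %.1f%%\n",
              100 * object@orderFraction, 100 * object@disorderFraction,
              100 * object@prolineFraction))
  cat(sprintf("  <R> = %.4f, <H> = %.4f\n", object@meanNetCharge,
              object@meanHydrophobicity))
})

setMethod("show", "ScatteringCurve", function(object) {
  cat(sprintf("ScatteringCurve: %d points, q in [%.3g, %.3g] 1/nm%s\n",
              length(object@q), min(object@q), max(object@q),
              if (length(object@sigma)) ", with errors" else ""))
})

setMethod("show", "GuinierResult", function(object) {
  cat(sprintf(
    "GuinierResult: Rg = %.3f +/- %.3f nm, I0 = %.4g +/- %.2g\n",
    object@Rg, object@RgSE, object@I0, object@I0SE))
  cat(sprintf("  window qRg [%.3f, %.3f], %d points, R2 = %.4f, %s\n",
              object@qRgWindow[1], object@qRgWindow[2], object@nPoints,
              object@r2,
              if (object@converged) "converged" else "NOT converged"))
})

setMethod("show", "KratkyProfile", function(object) {
  cat(sprintf("KratkyProfile: %d points, shape = %s\n", length(object@x),
              object@shapeClass))
  if (length(object@peak))
    cat(sprintf("  peak at qRg = %.3f (y = %.3f, prominence = %.3f)\n",
                object@peak$x, object@peak$y, object@peak$prominence))
  cat(sprintf("  tail level = %.3f\n", object@tailLevel))
})

setMethod("show", "TitrationSeries", function(object) {
  cat(sprintf("TitrationSeries (%s): %d points, x in [%.3g, %.3g]\n",
              object@kind, length(object@x), min(object@x), max(object@x)))
})

setMethod("show", "SECCalibration", function(object) {
  cat(sprintf("SECCalibration: V0 = %.2f mL, Vt = %.2f mL, %d standards\n",
              object@V0, object@Vt, nrow(object@standards)))
  if (!anyNA(object@fitRh))
    cat(sprintf("  Kav vs log10(Rh):   slope %.4f, intercept %.4f, R2 %.4f\n",
                object@fitRh["slope"], object@fitRh["intercept"],
                object@fitRh["r2"]))
  if (!anyNA(object@fitMass))
    cat(sprintf("  Kav vs log10(mass): slope %.4f, intercept %.4f, R2 %.4f\n",
                object@fitMass["slope"], object@fitMass["intercept"],
                object@fitMass["r2"]))
})

setMethod("show", "HydroRecord", function(object) {
  cat("HydroRecord:\n")
  if (!is.na(object@Rh))
    cat(sprintf("  Rh = %.2f +/- %.2f nm\n", object@Rh, object@RhSE))
  if (!is.na(object@Rg))
    cat(sprintf("  Rg = %.2f +/- %.2f nm\n", object@Rg, object@RgSE))
  if (!is.na(object@s)) cat(sprintf("  s  = %.2f S\n", object@s))
  if (!is.na(object@qFactor))
    cat(sprintf("  Q  = %.3f +/- %.3f\n", object@qFactor, object@qFactorSE))
  if (nrow(object@massEstimates)) {
    cat("  mass estimates:\n")
    for (i in seq_len(nrow(object@massEstimates)))
      cat(sprintf("    %-20s %.1f kDa\n", object@massEstimates$method[i],
                  object@massEstimates$value[i] / 1000))
  }
})

setMethod("show", "UnfoldingFit", function(object) {
  cat(sprintf("UnfoldingFit: model = %s, verdict = %s\n", object@model,
              object@verdict))
  if (!is.null(object@parameters$two_state)) {
    p <- object@parameters$two_state
    cat(sprintf("  two-state: dG0 = %.2f kcal/mol, m = %.2f kcal/mol/M, Cm = %.2f M\n",
                p$dG0, p$m, p$Cm))
  }
  if (length(object@aicc))
    cat("  AICc:", paste(sprintf("%s %.1f", names(object@aicc),
                                 object@aicc), collapse = ", "), "\n")
  if (length(object@flags)) cat("  flags:", object@flags, "\n")
})

setMethod("show", "EvidenceBundle", function(object) {
  cat("EvidenceBundle with channels:\n")
  if (!is.na(object@chClass)) cat("  charge-hydropathy:", object@chClass, "\n")
  if (!is.na(object@qValue)) cat(sprintf("  Q-factor: %.3f (%s)\n",
      object@qValue, paste(object@qClasses, collapse = ", ")))
  if (length(object@rhStateDeviations))
    cat("  Rh deviation minimal at:",
        names(which.min(object@rhStateDeviations)), "\n")
  if (!is.na(object@kratkyClass)) cat("  Kratky:", object@kratkyClass, "\n")
  if (length(object@unfoldingVerdicts))
    cat("  unfolding:", paste(object@unfoldingVerdicts, collapse = ", "), "\n")
  if (!is.na(object@ansAffinity)) cat("  high ANS affinity:",
                                      object@ansAffinity, "\n")
  if (!is.na(object@trpLambdaMax))
    cat(sprintf("  Trp lambda-max: %.1f nm\n", object@trpLambdaMax))
})

setMethod("show", "ConformationalAssessment", function(object) {
  cat(sprintf("ConformationalAssessment: %s (%s confidence, %d channels)\n",
              object@primaryState, object@confidence, object@nChannels))
  for (i in seq_len(nrow(object@compatibleStates)))
    cat(sprintf("  %-20s %.3f\n", object@compatibleStates$state[i],
                object@compatibleStates$score[i]))
  cat("rationale:\n")
  for (r in object@rationale) cat("  -", r, "\n")
})
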