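## Evidence integration: additive per-channel voting over the four
## conformational states, with a traceable rationale.

.states <- c("native_globular", "molten_globule", "pre_molten_globule",
             "extended_coil")

# Map the hydrodynamic scaling-law / Q-band labels onto classifier states.
.stateAlias <- c(
  native = "native_globular", sphere = "native_globular",
  globular = "native_globular",
  molten_globule = "molten_globule",
  pre_molten_globule = "pre_molten_globule",
  random_coil = "extended_coil",
  urea_unfolded = "extended_coil", gdmcl_unfolded = "extended_coil"
)

#' Relative deviation of an observed Rh from each state's expectation
#'
#' For each conformational state of the scaling-law table, computes
#' `|Rh_obs - Rh_state(mass)| / Rh_state(mass)`. The state with the
#' smallest deviation is the scaling law the observed radius agrees with
#' best - e.g. a molten-globule dimer when the observed Rh matches the
#' molten-globule law evaluated at twice the monomer mass.
#'
#' @param mass Molecular mass, Da.
#' @param RhObs Observed hydrodynamic radius, nm.
#' @param coefficients Scaling-law table, see [scalingLaws()].
#' @return Named numeric of relative deviations (all >= 0).
#' @export
#' @examples
#' which.min(rhStateDeviations(55103.4, 3.4))  # molten_globule
rhStateDeviations <- function(mass, RhObs, coefficients = scalingLaws()) {
  if (mass <= 0 || RhObs <= 0) stop("mass and RhObs must be positive")
  expected <- vapply(coefficients$state,
                     function(st) conformerRh(mass, st, coefficients),
                     numeric(1))
  abs(RhObs - expected) / expected
}

# Each channel emits a unit vote split over the states it supports.
.channelVotes <- function(bundle) {
  zero <- setNames(numeric(length(.states)), .states)
  votes <- list()
  note <- character(0)
  vote <- function(states, share = 1 / length(states)) {
    v <- zero
    v[states] <- share
    v
  }
  if (!is.na(bundle@chClass)) {
    votes$ch <- if (bundle@chClass == "native_side")
      vote(c("native_globular", "molten_globule"))
    else vote(c("pre_molten_globule", "extended_coil"))
    note["ch"] <- sprintf(
      "charge-hydropathy plane: %s (supports %s)", bundle@chClass,
      if (bundle@chClass == "native_side")
        "a compact, foldable sequence" else "an expanded state")
  }
  if (length(bundle@qClasses)) {
    st <- unique(unname(.stateAlias[bundle@qClasses]))
    votes$q <- vote(st)
    note["q"] <- sprintf("Q-factor%s band membership: %s",
                         if (!is.na(bundle@qValue))
                           sprintf(" %.2f", bundle@qValue) else "",
                         paste(bundle@qClasses, collapse = ", "))
  }
  if (length(bundle@rhStateDeviations)) {
    best <- names(which.min(bundle@rhStateDeviations))
    votes$rhDeviation <- vote(unname(.stateAlias[best]))
    note["rhDeviation"] <- sprintf(
      "observed Rh closest to the %s scaling law (%.1f%% off)", best,
      100 * min(bundle@rhStateDeviations))
  }
  if (!is.na(bundle@kratkyClass)) {
    votes$kratky <- switch(bundle@kratkyClass,
      globular_compact = vote("native_globular"),
      compact_plus_flexible = vote("molten_globule"),
      extended = vote(c("pre_molten_globule", "extended_coil")),
      NULL)
    if (!is.null(votes$kratky))
      note["kratky"] <- sprintf("Kratky shape: %s", bundle@kratkyClass)
  }
  if (length(bundle@unfoldingVerdicts)) {
    per <- 1 / length(bundle@unfoldingVerdicts)
    v <- zero
    for (verdict in bundle@unfoldingVerdicts) {
      v <- v + if (identical(verdict, "cooperative"))
        vote("native_globular", share = per)
      else vote(c("molten_globule", "pre_molten_globule",
                  "extended_coil"), share = per / 3)
    }
    votes$unfolding <- v
    note["unfolding"] <- sprintf(
      "unfolding cooperativity: %s",
      paste(bundle@unfoldingVerdicts, collapse = ", "))
  }
  if (!is.na(bundle@ansAffinity) && isTRUE(bundle@ansAffinity)) {
    votes$ans <- vote("molten_globule")
    note["ans"] <- "high ANS affinity: exposed hydrophobic surface"
  }
  if (!is.na(bundle@trpLambdaMax)) {
    lam <- bundle@trpLambdaMax
    votes$lambdaMax <- if (lam <= 330) vote("native_globular")
    else if (lam < 350) vote("molten_globule")
    else vote(c("pre_molten_globule", "extended_coil"))
    note["lambdaMax"] <- sprintf(
      "Trp emission maximum %.0f nm: %s", lam,
      if (lam <= 330) "buried fluorophores"
      else if (lam < 350) "partially buried fluorophores"
      else "solvent-exposed fluorophores")
  }
  list(votes = votes, notes = note)
}

#' Integrate an evidence bundle into a conformational-state verdict
#'
#' Linear additive voting: each populated evidence channel distributes one
#' (weighted) vote over the conformational states it supports, the scores
#' are normalised to sum to 1, and the highest-scoring state becomes the
#' primary state. Ties are broken by channel priority (Kratky first, since
#' the Kratky shape is what separates a molten globule from a pre-molten
#' globule when the Q-factor sits between their bands). Confidence is
#' `strong` when the top score is at least 0.5 with a margin of at least
#' 0.15 over the runner-up, `weak` when the margin is below 0.1 (or fewer
#' than two channels voted), `moderate` otherwise.
#'
#' @param bundle An [EvidenceBundle-class].
#' @param settings Settings list (channel weights, priority, confidence
#'   thresholds).
#' @return A [ConformationalAssessment-class].
#' @export
#' @examples
#' b <- evidenceBundle(chClass = "native_side", qValue = 1.03,
#'                     qClasses = qClassify(1.03)$members,
#'                     rhStateDeviations = rhStateDeviations(55103.4, 3.4),
#'                     kratkyClass = "compact_plus_flexible",
#'                     unfoldingVerdicts = "weakly_cooperative_or_linear",
#'                     ansAffinity = TRUE, trpLambdaMax = 344)
#' primaryState(classifyState(b))
classifyState <- function(bundle, settings = defaultSettings()) {
  stopifnot(is(bundle, "EvidenceBundle"))
  cs <- settings$classifier
  cv <- .channelVotes(bundle)
  nChannels <- length(cv$votes)
  if (nChannels == 0L) stop("evidence bundle is empty")
  total <- setNames(numeric(length(.states)), .states)
  for (ch in names(cv$votes)) {
    w <- if (ch %in% names(cs$weights)) cs$weights[[ch]] else 1
    total <- total + w * cv$votes[[ch]]
  }
  scores <- total / sum(total)
  ranked <- sort(scores[scores > 0], decreasing = TRUE)
  top <- max(scores)
  tied <- names(scores)[abs(scores - top) < 1e-12]
  primary <- tied[1L]
  if (length(tied) > 1L) {
    # break the tie with the highest-priority channel voting for a tied state
    for (ch in cs$priority) {
      v <- cv$votes[[ch]]
      if (is.null(v)) next
      hit <- tied[v[tied] > 0]
      if (length(hit)) { primary <- hit[1L]; break }
    }
  }
  margin <- if (length(ranked) > 1L) ranked[1L] - ranked[2L] else 1
  confidence <- if (nChannels < 2L || margin < cs$weakMargin) "weak"
  else if (top >= cs$strongTop && margin >= cs$strongMargin) "strong"
  else "moderate"
  rationale <- unname(cv$notes)
  if (nChannels < 2L)
    rationale <- c(rationale,
                   "partial assessment: fewer than two evidence channels")
  new("ConformationalAssessment",
      primaryState = primary,
      compatibleStates = data.frame(state = names(ranked),
                                    score = unname(ranked),
                                    stringsAsFactors = FALSE),
      rationale = rationale,
      confidence = confidence,
      nChannels = nChannels)
}

#' Write a conformational assessment to JSON
#'
#' @param assessment A [ConformationalAssessment-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeAssessment <- function(assessment, path) {
  stopifnot(is(assessment, "ConformationalAssessment"))
  jsonlite::write_json(
    list(primary_state = assessment@primaryState,
         confidence = assessment@confidence,
         n_channels = assessment@nChannels,
         compatible_states = assessment@compatibleStates,
         rationale = assessment@rationale),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
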