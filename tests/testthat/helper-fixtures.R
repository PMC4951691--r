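# Shared fixture builders; all fixtures are generated in code.

writeFastaTemp <- function(entries) {
  tf <- tempfile(fileext = ".fasta")
  lines <- unlist(lapply(names(entries), function(n)
    c(paste0(">", n), entries[[n]])))
  writeLines(lines, tf)
  tf
}

# A Guinier-limit (pure exponential) curve: the one family for which the
# Guinier law is exact at all q.
guinierLimitCurve <- function(Rg = 3.5, I0 = 1,
                              q = seq(0.05, 4, length.out = 400)) {
  ScatteringCurve(q, I0 * exp(-q^2 * Rg^2 / 3))
}

# Evidence bundle reproducing the molten-globule-like evidence pattern:
# native-side CH plot, Q just above the MG band, Rh matching the MG
# scaling law at the dimer mass, hybrid Kratky, non-cooperative unfolding,
# high ANS affinity, intermediate Trp emission maximum.
mgLikeBundle <- function() {
  evidenceBundle(
    chClass = "native_side",
    qValue = 1.03,
    qClasses = qClassify(1.03)$members,
    rhStateDeviations = rhStateDeviations(2 * 27551.7, 3.4),
    kratkyClass = "compact_plus_flexible",
    unfoldingVerdicts = "weakly_cooperative_or_linear",
    ansAffinity = TRUE,
    trpLambdaMax = 344)
}
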