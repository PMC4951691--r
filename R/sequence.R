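## Sequence-derived disorder indicators: residue-class composition, mass,
## mean net charge, rescaled hydropathy, and charge-hydropathy placement.

.canonical <- names(.residueMasses)

# Coerce character / AAString / single-sequence AAStringSet to one
# upper-case residue string and validate against the canonical alphabet.
.asResidues <- function(x, lenient = FALSE) {
  if (is(x, "AAStringSet")) {
    if (length(x) != 1L)
      stop("expected a single sequence; got ", length(x))
    x <- x[[1L]]
  }
  if (is(x, "AAString")) x <- as.character(x)
  if (!is.character(x) || length(x) != 1L)
    stop("sequence must be a single character string, AAString or ",
         "single-entry AAStringSet")
  res <- strsplit(toupper(x), "", fixed = TRUE)[[1L]]
  if (!length(res)) stop("sequence is empty")
  bad <- which(!res %in% .canonical)
  if (length(bad)) {
    if (lenient) {
      warning(sprintf("dropping %d non-canonical residue(s): %s",
                      length(bad),
                      paste(sprintf("%s@%d", res[bad], bad),
                            collapse = ", ")))
      res <- res[-bad]
      if (!length(res)) stop("no canonical residues left after filtering")
    } else {
      stop(sprintf("non-canonical residue '%s' at position %d",
                   res[bad[1L]], bad[1L]))
    }
  }
  res
}

#' Read protein sequences from a FASTA file
#'
#' Reads a (multi-record) FASTA file into an [Biostrings::AAStringSet],
#' upper-casing the residues and validating them against the 20 canonical
#' one-letter codes. In strict mode (default) a non-canonical residue is an
#' error naming the offending record and position; in lenient mode the
#' residue is dropped with a warning.
#'
#' @param path Path to a FASTA file.
#' @param lenient Drop non-canonical residues instead of erroring.
#' @return An `AAStringSet`, one entry per FASTA record, in file order.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">x", "IVW"), tf)
#' readProteinFasta(tf)
readProteinFasta <- function(path, lenient = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readAAStringSet(path)
  if (!length(set)) stop("no FASTA records in ", path)
  out <- character(length(set))
  for (i in seq_along(set)) {
    res <- tryCatch(.asResidues(as.character(set[[i]]), lenient = lenient),
                    error = function(e)
                      stop(sprintf("record '%s': %s", names(set)[i],
                                   conditionMessage(e)), call. = FALSE))
    out[i] <- paste(res, collapse = "")
  }
  Biostrings::AAStringSet(setNames(out, names(set)))
}

#' Residue-class composition profile of a protein sequence
#'
#' Computes the sequence statistics used as disorder indicators: residue
#' fractions, the split into order-promoting (I, C, L, V, W, Y, F) and
#' disorder-promoting (the remaining 13) residues, proline content, the
#' average-mass molecular mass (residue masses plus one water), the mean
#' absolute net charge per residue at `pH` and the windowed, rescaled
#' Kyte-Doolittle hydrophobicity. The two residue classes partition the
#' alphabet, so their fractions always sum to one.
#'
#' @param x A sequence: character string, `AAString`, or single-entry
#'   `AAStringSet`.
#' @param pH pH for the mean net charge (default 7, the counting
#'   convention of the charge-hydropathy plot).
#' @param window Sliding-window width for the hydropathy mean; sequences
#'   shorter than the window get `NA` hydrophobicity.
#' @param identifier Identifier stored in the profile (taken from the
#'   `AAStringSet` name when available).
#' @return A [CompositionProfile-class] object.
#' @export
#' @examples
#' p <- compositionProfile("IVWCFLY")
#' orderFraction(p)  # 1
compositionProfile <- function(x, pH = 7, window = 5,
                               identifier = NULL) {
  if (is.null(identifier))
    identifier <- if (is(x, "AAStringSet") && !is.null(names(x)))
      names(x)[1L] else "sequence"
  res <- .asResidues(x)
  n <- length(res)
  counts <- table(factor(res, levels = .canonical))
  frac <- as.numeric(counts) / n
  names(frac) <- .canonical
  hyd <- if (n >= window)
    meanHydrophobicity(paste(res, collapse = ""), window = window)
  else NA_real_
  new("CompositionProfile",
      identifier = identifier,
      length = n,
      perResidueFraction = frac,
      orderFraction = sum(frac[.orderResidues]),
      disorderFraction = sum(frac[.disorderResidues]),
      prolineFraction = frac[["P"]],
      molecularMass = sum(.residueMasses[res]) + .waterMass,
      meanNetCharge = meanNetCharge(paste(res, collapse = ""), pH = pH),
      meanHydrophobicity = hyd)
}

#' Mean absolute net charge per residue
#'
#' At pH 7 (the convention of the charge-hydropathy plot) the charge is the
#' simple count `|#(K, R) - #(D, E)| / N`, ignoring histidine and the
#' termini. At any other pH a Henderson-Hasselbalch per-residue model is
#' used with the EMBOSS pKa table (side chains C, D, E, H, K, R, Y plus the
#' two termini).
#'
#' @param x A sequence (see [compositionProfile()]) or a
#'   [CompositionProfile-class] (returns the stored value).
#' @param pH pH in `[0, 14]`.
#' @return Mean absolute net charge per residue (dimensionless).
#' @export
#' @examples
#' meanNetCharge("KKDD")     # 0
#' meanNetCharge("KKKKDDAA") # 0.25
setGeneric("meanNetCharge", function(x, pH = 7) standardGeneric("meanNetCharge"))

#' @rdname meanNetCharge
#' @export
setMethod("meanNetCharge", "CompositionProfile",
          function(x, pH = 7) x@meanNetCharge)

#' @rdname meanNetCharge
#' @export
setMethod("meanNetCharge", "ANY", function(x, pH = 7) {
  stopifnot(pH >= 0, pH <= 14)
  res <- .asResidues(x)
  n <- length(res)
  if (isTRUE(all.equal(pH, 7))) {
    pos <- sum(res %in% c("K", "R"))
    neg <- sum(res %in% c("D", "E"))
    return(abs(pos - neg) / n)
  }
  hh <- function(pKa, acid) {
    if (acid) -1 / (1 + 10^(pKa - pH)) else 1 / (1 + 10^(pH - pKa))
  }
  counts <- table(factor(res, levels = .canonical))
  q <- counts[["K"]] * hh(.pKaTable[["K"]], FALSE) +
    counts[["R"]] * hh(.pKaTable[["R"]], FALSE) +
    counts[["H"]] * hh(.pKaTable[["H"]], FALSE) +
    counts[["D"]] * hh(.pKaTable[["D"]], TRUE) +
    counts[["E"]] * hh(.pKaTable[["E"]], TRUE) +
    counts[["C"]] * hh(.pKaTable[["C"]], TRUE) +
    counts[["Y"]] * hh(.pKaTable[["Y"]], TRUE) +
    hh(.pKaTable[["Nterm"]], FALSE) + hh(.pKaTable[["Cterm"]], TRUE)
  abs(q) / n
})

#' Mean rescaled Kyte-Doolittle hydrophobicity
#'
#' The Kyte-Doolittle scale is rescaled to `[0, 1]` via
#' `(v - min) / (max - min)`, averaged over every sliding window of
#' `window` residues, and the window means are averaged. This is the
#' canonical recipe of the charge-hydropathy plot abscissa.
#'
#' @inheritParams meanNetCharge
#' @param window Window width in residues (default 5).
#' @return Mean hydrophobicity in `[0, 1]`.
#' @export
#' @examples
#' meanHydrophobicity(strrep("I", 10))  # rescaled KD value of Ile, = 1
setGeneric("meanHydrophobicity",
           function(x, window = 5) standardGeneric("meanHydrophobicity"))

#' @rdname meanHydrophobicity
#' @export
setMethod("meanHydrophobicity", "CompositionProfile",
          function(x, window = 5) x@meanHydrophobicity)

#' @rdname meanHydrophobicity
#' @export
setMethod("meanHydrophobicity", "ANY", function(x, window = 5) {
  res <- .asResidues(x)
  n <- length(res)
  if (n < window)
    stop(sprintf("sequence (%d residues) shorter than window (%d)",
                 n, window))
  kd <- (.kdScale[res] - min(.kdScale)) / (max(.kdScale) - min(.kdScale))
  # mean over all sliding windows, then over windows; a plain convolution
  wm <- vapply(seq_len(n - window + 1L),
               function(i) mean(kd[i:(i + window - 1L)]), numeric(1))
  mean(wm)
})

#' Charge-hydropathy (Uversky-plot) classification
#'
#' Places a sequence in the charge-hydropathy plane and classifies it
#' against the linear boundary `<R>_b = slope * <H> + intercept`
#' (default 2.785 <H> - 1.151) separating natively folded from natively
#' unfolded proteins. Points below the boundary (`<R> < <R>_b`) fall on the
#' native side; points exactly on it are assigned to the native side so the
#' classification is total.
#'
#' @param profile A [CompositionProfile-class], or a numeric mean net
#'   charge when `hydrophobicity` is given.
#' @param hydrophobicity Mean hydrophobicity, only when `profile` is
#'   numeric.
#' @param settings Settings list, see [defaultSettings()].
#' @return A list with `side` (`native_side` or `unfolded_side`) and
#'   `distance`, the signed perpendicular distance to the boundary
#'   (positive on the native side).
#' @export
#' @examples
#' chClassify(0.05, hydrophobicity = 0.5)
chClassify <- function(profile, hydrophobicity = NULL,
                       settings = defaultSettings()) {
  if (is(profile, "CompositionProfile")) {
    R <- profile@meanNetCharge
    H <- profile@meanHydrophobicity
  } else {
    R <- as.numeric(profile)
    H <- as.numeric(hydrophobicity)
  }
  if (anyNA(c(R, H))) stop("both <R> and <H> must be populated")
  cb <- settings$chBoundary
  Rb <- cb[["slope"]] * H + cb[["intercept"]]
  # signed perpendicular distance to the line R = slope*H + intercept
  distance <- (Rb - R) / sqrt(1 + cb[["slope"]]^2)
  side <- if (distance >= 0) "native_side" else "unfolded_side"
  list(side = side, distance = unname(distance),
       boundaryCharge = unname(Rb))
}
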