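## SAXS analysis: Guinier fit in a fixed qRg window, dimensionless Kratky
## transform, and the qualitative shape classification used to separate
## globular, hybrid (compact + flexible) and extended particles.

#' Read a 1-D SAXS curve from ASCII
#'
#' Accepts 2- or 3-column (q, I and optionally sigma) whitespace- or comma-delimited
#' text with `#` comment lines. Rows with non-finite values are dropped
#' with a warning. q is expected in 1/nm; use `qUnits = "ang"` to convert
#' from 1/Angstrom (never guessed from the data).
#'
#' @param path Path to the file.
#' @param qUnits `"nm"` (default) or `"ang"`.
#' @return A [ScatteringCurve-class].
#' @export
readScattering <- function(path, qUnits = c("nm", "ang")) {
  qUnits <- match.arg(qUnits)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) stop("no data rows in ", path)
  sep <- if (any(grepl(",", lines[1L], fixed = TRUE))) "," else ""
  tab <- read.table(text = lines, sep = sep, header = FALSE,
                    fill = TRUE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("expected 2 or 3 columns, got ", ncol(tab))
  tab <- tab[, seq_len(min(3L, ncol(tab))), drop = FALSE]
  tab <- as.data.frame(lapply(tab, function(v) suppressWarnings(as.numeric(v))))
  ok <- rowSums(!is.finite(as.matrix(tab))) == 0L
  if (any(!ok)) {
    warning(sprintf("dropping %d row(s) with non-finite values", sum(!ok)))
    tab <- tab[ok, , drop = FALSE]
  }
  if (nrow(tab) < 10L) stop("fewer than 10 usable points in ", path)
  q <- tab[[1L]]
  if (any(diff(q) <= 0)) stop("q values are not strictly increasing")
  if (qUnits == "ang") q <- q * 10
  ScatteringCurve(q = q, I = tab[[2L]],
                  sigma = if (ncol(tab) >= 3L) tab[[3L]] else numeric(0),
                  metadata = list(source = path, qUnits = "nm"))
}

#' Write a scattering curve to ASCII
#'
#' @param curve A [ScatteringCurve-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeScattering <- function(curve, path) {
  stopifnot(is(curve, "ScatteringCurve"))
  tab <- data.frame(q = curve@q, I = curve@I)
  if (length(curve@sigma)) tab$sigma <- curve@sigma
  header <- sprintf("# q[1/nm] I(q)%s",
                    if (length(curve@sigma)) " sigma" else "")
  writeLines(header, path)
  write.table(format(tab, digits = 10), path, append = TRUE,
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# One weighted ln(I) ~ q^2 regression on the index set; sigma on ln scale
# is sigma/I, so the weights are (I/sigma)^2.
.guinierLine <- function(q, I, sigma, idx) {
  qq <- q[idx]^2
  lnI <- log(I[idx])
  w <- if (length(sigma)) (I[idx] / sigma[idx])^2 else NULL
  fit <- lm(lnI ~ qq, weights = w)
  sm <- suppressWarnings(summary(fit))  # noiseless curves fit perfectly
  slope <- unname(coef(fit)[2L])
  list(fit = fit, slope = slope, intercept = unname(coef(fit)[1L]),
       slopeSE = sm$coefficients[2L, 2L],
       interceptSE = sm$coefficients[1L, 2L],
       r2 = sm$r.squared)
}

#' Iterative Guinier fit
#'
#' Fits `ln I = ln I0 - q^2 Rg^2 / 3` by (weighted, when errors are
#' present) least squares, iterating the fit window: the first fit uses the
#' lowest-q decade of the curve, the window is then recomputed as the
#' points with `qRg` inside `window` using the current Rg, and the fit is
#' repeated until the point set is stable (or `maxIterations`). On an
#' oscillating fixed cycle the smaller window is kept and the result is
#' flagged as not converged. The default window is the conventional
#' low-angle range `0.759 <= qRg <= 1.294`.
#'
#' Note that the Guinier law is exact only in the q -> 0 limit: for a hard
#' sphere fitted over this window the estimate carries a known systematic
#' bias of about +2.6%, and for a Gaussian coil about -11% (see the
#' methods vignette); the fit is still the field's canonical estimator.
#'
#' @param curve A [ScatteringCurve-class].
#' @param window qRg window `c(min, max)`.
#' @param settings Settings list (minimum points, iteration cap).
#' @return A [GuinierResult-class].
#' @export
#' @examples
#' spec <- simulationSpec(seed = 1)
#' g <- guinierFit(makeSphereCurve(4.52, spec = spec))
#' radiusOfGyration(g)
guinierFit <- function(curve, window = NULL, settings = defaultSettings()) {
  stopifnot(is(curve, "ScatteringCurve"))
  gs <- settings$guinier
  if (is.null(window)) window <- gs$window
  if (window[2L] > gs$qRgCeiling + 1e-9)
    warning(sprintf("window upper bound %.3f exceeds the qRg ceiling %.3f",
                    window[2L], gs$qRgCeiling))
  q <- curve@q; I <- curve@I; sigma <- curve@sigma
  usable <- which(I > 0)
  if (length(usable) < gs$minPoints)
    stop("too few points with positive intensity")
  idx <- usable[q[usable] <= 10 * min(q[usable])]
  if (length(idx) < gs$minPoints)
    idx <- usable[seq_len(min(gs$minPoints, length(usable)))]
  seen <- list()
  converged <- FALSE
  iterations <- 0L
  repeat {
    iterations <- iterations + 1L
    line <- .guinierLine(q, I, sigma, idx)
    if (line$slope >= 0)
      stop("non-negative Guinier slope: Rg^2 <= 0 (no Guinier region)")
    Rg <- sqrt(-3 * line$slope)
    newIdx <- usable[q[usable] * Rg >= window[1L] &
                       q[usable] * Rg <= window[2L]]
    if (length(newIdx) < gs$minPoints)
      stop(sprintf("Guinier window [%.3f, %.3f] qRg contains %d point(s); need %d",
                   window[1L], window[2L], length(newIdx), gs$minPoints))
    if (identical(newIdx, idx)) { converged <- TRUE; break }
    cyc <- vapply(seen, identical, logical(1), y = newIdx)
    if (any(cyc)) {
      # oscillation between windows: keep the smaller one, flag it
      if (length(newIdx) < length(idx)) idx <- newIdx
      line <- .guinierLine(q, I, sigma, idx)
      Rg <- sqrt(-3 * line$slope)
      break
    }
    if (iterations >= gs$maxIterations) break
    seen[[length(seen) + 1L]] <- idx
    idx <- newIdx
  }
  RgSE <- 3 * line$slopeSE / (2 * Rg)
  I0 <- exp(line$intercept)
  new("GuinierResult", Rg = Rg, RgSE = RgSE, I0 = I0,
      I0SE = I0 * line$interceptSE,
      window = range(q[idx]), qRgWindow = range(q[idx]) * Rg,
      nPoints = length(idx), r2 = line$r2, converged = converged,
      iterations = iterations)
}

#' Dimensionless Kratky transform
#'
#' Computes `x = q Rg`, `y = x^2 I(q) / I0` from a curve and its Guinier
#' fit. The interior peak is detected on a Savitzky-Golay-smoothed copy as
#' the global interior maximum whose prominence (height above the lowest
#' smoothed level between the peak and the high-x end) exceeds the
#' configured floor. The tail level is the mean y over the configured
#' high-x band (NA, and an `inconclusive` class, when the curve does not
#' reach it). For a particle obeying the Guinier law exactly the peak sits
#' at `x = sqrt(3)` with height `3/e`.
#'
#' @param curve A [ScatteringCurve-class].
#' @param guinier The curve's [GuinierResult-class].
#' @param settings Settings list (smoothing, prominence floor, tail band,
#'   peak fraction).
#' @return A [KratkyProfile-class] with `shapeClass` already assigned by
#'   [kratkyClassify()].
#' @export
dimensionlessKratky <- function(curve, guinier,
                                settings = defaultSettings()) {
  stopifnot(is(curve, "ScatteringCurve"), is(guinier, "GuinierResult"))
  if (!guinier@converged)
    warning("Guinier fit did not converge; Kratky axis may be misscaled")
  if (guinier@I0 <= 0) stop("I0 must be positive")
  ks <- settings$kratky
  x <- curve@q * guinier@Rg
  y <- x^2 * curve@I / guinier@I0
  n <- length(x)
  sgWin <- min(ks$sgWindow, if (n %% 2L) n else n - 1L)
  ySm <- if (n > sgWin && sgWin > ks$sgOrder)
    signal::sgolayfilt(y, p = ks$sgOrder, n = sgWin) else y
  interior <- 2L:(n - 1L)
  iPeak <- interior[which.max(ySm[interior])]
  prominence <- ySm[iPeak] - min(ySm[iPeak:n])
  peak <- if (prominence >= ks$prominenceFloor * max(ySm))
    list(x = x[iPeak], y = y[iPeak], prominence = prominence)
  else list()
  inTail <- x >= ks$tailBand[1L] & x <= ks$tailBand[2L]
  tailLevel <- if (max(x) >= ks$tailBand[2L] && any(inTail))
    mean(y[inTail]) else NA_real_
  prof <- new("KratkyProfile", x = x, y = y, peak = peak,
              tailLevel = tailLevel, shapeClass = "unclassified",
              settings = ks)
  prof@shapeClass <- kratkyClassify(prof, settings = settings)
  prof
}

#' Classify a Kratky profile by shape
#'
#' Pattern rules: a qualifying interior peak whose tail level stays below
#' `peakFraction * y_peak` is a compact globule (`globular_compact`); a
#' peak whose tail remains at or above that fraction indicates a compact
#' core plus a flexible/disordered part (`compact_plus_flexible`); no
#' qualifying peak means a chain-like, `extended` profile. A profile that
#' does not cover the tail band is `inconclusive`.
#'
#' @param profile A [KratkyProfile-class].
#' @param settings Settings list.
#' @return The shape class, one of `globular_compact`,
#'   `compact_plus_flexible`, `extended`, `inconclusive`.
#' @export
kratkyClassify <- function(profile, settings = defaultSettings()) {
  stopifnot(is(profile, "KratkyProfile"))
  ks <- settings$kratky
  if (is.na(profile@tailLevel)) return("inconclusive")
  if (!length(profile@peak)) return("extended")
  if (profile@tailLevel >= ks$peakFraction * profile@peak$y)
    "compact_plus_flexible"
  else
    "globular_compact"
}
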