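## Titration analytics: Stern-Volmer quenching, unfolded fraction,
## lambda-max tracking, and the cooperative-vs-linear unfolding model
## comparison.

.GAS_KCAL <- 1.9872e-3  # kcal / (mol K)

.aicc <- function(fit, n) {
  k <- attr(stats::logLik(fit), "df")
  if (n - k - 1 <= 0) return(Inf)  # too few points to support the model
  AIC(fit) + 2 * k * (k + 1) / (n - k - 1)
}

#' Stern-Volmer quenching fit
#'
#' Fits `F0/F = 1 + KSV [Q]` with the intercept fixed at 1 (the model's
#' definition; set `freeIntercept = TRUE` for diagnostics). A `[Q] = 0`
#' point with `F0/F = 1` is prepended when absent. Linearity - the
#' signature of a single fluorophore-accessibility population - is assessed
#' by testing the quadratic curvature term of an unconstrained fit;
#' downward curvature (two populations with different accessibility) yields
#' a `nonlinear` verdict. Ratios below 1 beyond the configured tolerance
#' trigger a warning (static-quenching artefact or data error).
#'
#' @param series A [TitrationSeries-class] of kind `quenching`; x is the
#'   quencher concentration (M), y is F0/F.
#' @param freeIntercept Fit the intercept instead of fixing it at 1.
#' @param settings Settings list.
#' @return List with `KSV` (1/M), `KSVSE`, `intercept`, `r2`, and
#'   `verdict` (`linear` / `nonlinear`).
#' @export
#' @examples
#' s <- makeQuenchingSeries(5, seq(0, 0.3, length.out = 10),
#'                          simulationSpec(seed = 1))
#' sternVolmerFit(s)$KSV
sternVolmerFit <- function(series, freeIntercept = FALSE,
                           settings = defaultSettings()) {
  stopifnot(is(series, "TitrationSeries"))
  if (series@kind != "quenching")
    stop("series kind must be 'quenching', got '", series@kind, "'")
  x <- series@x; y <- series@y
  if (x[1L] > 0) { x <- c(0, x); y <- c(1, y) }
  if (length(x) < 5L) stop("need at least 5 points")
  tol <- settings$sternVolmer$belowOneTolerance
  if (any(y < 1 - tol))
    warning("F0/F below 1 beyond tolerance: static-quenching artefact ",
            "or data error")
  if (freeIntercept) {
    fit <- lm(y ~ x)
    ksv <- unname(coef(fit)[2L]); icpt <- unname(coef(fit)[1L])
    ksvSE <- suppressWarnings(summary(fit))$coefficients[2L, 2L]
  } else {
    fit <- lm(I(y - 1) ~ 0 + x)
    ksv <- unname(coef(fit)[1L]); icpt <- 1
    ksvSE <- suppressWarnings(summary(fit))$coefficients[1L, 2L]
  }
  pred <- icpt + ksv * x
  ssRes <- sum((y - pred)^2)
  ssTot <- sum((y - mean(y))^2)
  r2 <- if (ssTot > 0) 1 - ssRes / ssTot else 1
  # curvature test: significant quadratic term => more than one population
  quad <- lm(y ~ x + I(x^2))
  pQuad <- suppressWarnings(summary(quad))$coefficients
  pQuad <- if (nrow(pQuad) >= 3L) pQuad[3L, 4L] else NA_real_
  verdict <- if (is.finite(pQuad) &&
                 pQuad < settings$sternVolmer$curvatureAlpha)
    "nonlinear" else "linear"
  list(KSV = ksv, KSVSE = ksvSE, intercept = icpt, r2 = r2,
       verdict = verdict)
}

.evalBaseline <- function(b, x) {
  if (is.null(names(b)) || !all(c("intercept", "slope") %in% names(b)))
    stop("baselines must be named numeric c(intercept = , slope = )")
  b[["intercept"]] + b[["slope"]] * x
}

.fitBaseline <- function(x, y, range) {
  ok <- x >= range[1L] & x <= range[2L]
  if (sum(ok) < 2L) stop("baseline range contains fewer than 2 points")
  fit <- lm(y[ok] ~ x[ok])
  c(intercept = unname(coef(fit)[1L]), slope = unname(coef(fit)[2L]))
}

#' Unfolded fraction from a titration signal
#'
#' `f_d(x) = (y(x) - yN(x)) / (yD(x) - yN(x))` given linear native and
#' denatured baselines, supplied as `c(intercept = , slope = )` or fitted
#' from flanking x-ranges. Noise can push f_d slightly outside `[0, 1]`;
#' values are not clipped but the series is flagged.
#'
#' @param series A [TitrationSeries-class].
#' @param nativeBaseline,denaturedBaseline Named numeric
#'   `c(intercept = , slope = )`, or NULL to fit from the ranges.
#' @param nativeRange,denaturedRange x-ranges `c(lo, hi)` used to fit the
#'   baselines when not supplied directly.
#' @return A [TitrationSeries-class] of kind `unfolded_fraction` (flag
#'   `outside_unit_interval` set when applicable).
#' @export
unfoldedFraction <- function(series, nativeBaseline = NULL,
                             denaturedBaseline = NULL,
                             nativeRange = NULL, denaturedRange = NULL) {
  stopifnot(is(series, "TitrationSeries"))
  x <- series@x; y <- series@y
  if (is.null(nativeBaseline))
    nativeBaseline <- .fitBaseline(x, y, nativeRange)
  if (is.null(denaturedBaseline))
    denaturedBaseline <- .fitBaseline(x, y, denaturedRange)
  yN <- .evalBaseline(nativeBaseline, x)
  yD <- .evalBaseline(denaturedBaseline, x)
  gap <- yD - yN
  if (max(abs(gap)) < 1e-12 * max(abs(y), 1))
    stop("native and denatured baselines coincide")
  fd <- (y - yN) / gap
  out <- TitrationSeries(x, fd, kind = "unfolded_fraction")
  if (any(fd < 0) || any(fd > 1))
    out@flags <- "outside_unit_interval"
  out
}

.twoStateChemical <- function(x, dG0, m, aN, bN, aD, bD, RT) {
  K <- exp((m * x - dG0) / RT)
  (aN + bN * x + (aD + bD * x) * K) / (1 + K)
}

.twoStateThermal <- function(Tk, dH, Tm, aN, bN, aD, bD) {
  K <- exp(dH / .GAS_KCAL * (1 / Tm - 1 / Tk))
  (aN + bN * Tk + (aD + bD * Tk) * K) / (1 + K)
}

#' Cooperative versus linear unfolding model comparison
#'
#' Fits two candidate models to an unfolding titration and compares them by
#' AICc. For chemical unfolding the two-state model is the linear
#' extrapolation method, `dG([D]) = dG0 - m [D]`, with linear native and
#' denatured baselines:
#' `y = (aN + bN x + (aD + bD x) K) / (1 + K)`, `K = exp((m x - dG0)/RT)`.
#' For thermal unfolding a van 't Hoff two-state form in `(dHvh, Tm)` is
#' used. The alternative is a straight line. The verdict is `cooperative`
#' only when the two-state model wins by more than the configured AICc
#' margin (default 4), its m-value (or dHvh) is positive, and the fitted
#' midpoint lies inside the sampled x-range; otherwise
#' `weakly_cooperative_or_linear` - the monotonic, sigmoid-free behaviour
#' characteristic of molten-globule-like proteins. A constant signal is
#' flagged `degenerate` with no verdict; a two-state fit that fails to
#' converge falls back to the linear model with a flag.
#'
#' @param series A [TitrationSeries-class] of kind `chemical_unfolding`,
#'   `thermal_unfolding`, `unfolded_fraction`, `lambda_max` or
#'   `anisotropy` (anything except `quenching`; non-thermal kinds use the
#'   chemical model). x in M (chemical) or degrees C (thermal).
#' @param settings Settings list (AICc margin, RT).
#' @return An [UnfoldingFit-class].
#' @export
#' @examples
#' s <- makeUnfoldingSeries("two_state", list(dG0 = 5, m = 2),
#'                          spec = simulationSpec(seed = 1))
#' fitUnfolding(s)@verdict
fitUnfolding <- function(series, settings = defaultSettings()) {
  stopifnot(is(series, "TitrationSeries"))
  if (series@kind == "quenching")
    stop("quenching series go through sternVolmerFit()")
  x <- series@x; y <- series@y
  n <- length(x)
  if (n < 6L) stop("need at least 6 points to compare unfolding models")
  if (sd(y) < 1e-12 * max(abs(y), 1))
    return(new("UnfoldingFit", model = "linear",
               parameters = list(), aicc = numeric(0),
               verdict = NA_character_, flags = "degenerate",
               fitted = y))
  thermal <- series@kind == "thermal_unfolding"
  linFit <- lm(y ~ x)
  aiccLin <- .aicc(linFit, n)
  RT <- settings$unfolding$RT

  # heuristic starts: baselines from the ends, midpoint from the signal mid
  aN0 <- y[1L]; aD0 <- y[n]
  mid <- (aN0 + aD0) / 2
  Cm0 <- x[which.min(abs(y - mid))]
  Cm0 <- min(max(Cm0, x[2L]), x[n - 1L])
  tsFit <- NULL
  if (thermal) {
    Tk <- x + 273.15
    df <- data.frame(Tk = Tk, y = y)
    for (dH0 in c(50, 20, 100)) {
      tsFit <- tryCatch(
        minpack.lm::nlsLM(
          y ~ .twoStateThermal(Tk, dH, Tm, aN, bN, aD, bD), data = df,
          start = list(dH = dH0, Tm = Cm0 + 273.15, aN = aN0, bN = 0,
                       aD = aD0, bD = 0),
          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (!is.null(tsFit)) break
    }
  } else {
    df <- data.frame(x = x, y = y)
    for (m0 in c(2, 1, 5)) {
      tsFit <- tryCatch(
        minpack.lm::nlsLM(
          y ~ .twoStateChemical(x, dG0, m, aN, bN, aD, bD, RT), data = df,
          start = list(dG0 = m0 * Cm0, m = m0, aN = aN0, bN = 0,
                       aD = aD0, bD = 0),
          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (!is.null(tsFit)) break
    }
  }

  linPars <- list(slope = unname(coef(linFit)[2L]),
                  intercept = unname(coef(linFit)[1L]))
  if (is.null(tsFit)) {
    return(new("UnfoldingFit", model = "linear",
               parameters = list(linear = linPars),
               aicc = c(linear = aiccLin),
               verdict = "weakly_cooperative_or_linear",
               flags = "two_state_not_converged",
               fitted = unname(predict(linFit))))
  }
  cf <- as.list(coef(tsFit))
  if (thermal) {
    steepness <- cf$dH
    midpoint <- cf$Tm - 273.15
    tsPars <- list(dHvh = cf$dH, Tm = midpoint, aN = cf$aN, bN = cf$bN,
                   aD = cf$aD, bD = cf$bD)
  } else {
    steepness <- cf$m
    midpoint <- cf$dG0 / cf$m
    tsPars <- list(dG0 = cf$dG0, m = cf$m, Cm = midpoint, aN = cf$aN,
                   bN = cf$bN, aD = cf$aD, bD = cf$bD)
  }
  aiccTS <- .aicc(tsFit, n)
  wins <- (aiccLin - aiccTS) > settings$unfolding$deltaAICc
  interior <- midpoint > min(x) && midpoint < max(x)
  cooperative <- wins && steepness > 0 && interior
  verdict <- if (cooperative) "cooperative" else
    "weakly_cooperative_or_linear"
  model <- if (cooperative) "two_state" else "linear"
  new("UnfoldingFit", model = model,
      parameters = list(two_state = tsPars, linear = linPars),
      aicc = c(two_state = aiccTS, linear = aiccLin),
      verdict = verdict, flags = character(0),
      fitted = if (cooperative) unname(predict(tsFit))
               else unname(predict(linFit)))
}

#' Emission-maximum series from a stack of spectra
#'
#' Extracts the wavelength of maximum intensity from each spectrum by
#' parabolic interpolation through the grid maximum and its neighbours,
#' and assembles the values into a titration series over the stack's
#' x-coordinates (e.g. urea concentration). A maximum sitting on a spectrum
#' edge cannot be interpolated; the grid value is used and the series is
#' flagged.
#'
#' @param spectra List of spectra, each a list with elements `x` (the
#'   titration coordinate), `wavelength` and `intensity`.
#' @return A [TitrationSeries-class] of kind `lambda_max` (flag
#'   `edge_maximum` when applicable).
#' @export
lambdaMaxSeries <- function(spectra) {
  stopifnot(is.list(spectra), length(spectra) >= 1L)
  edge <- FALSE
  one <- function(sp) {
    w <- sp$wavelength; I <- sp$intensity
    i <- which.max(I)
    if (i == 1L || i == length(I)) { edge <<- TRUE; return(w[i]) }
    # vertex of the parabola through the three points around the maximum
    fit <- lm(I[(i - 1L):(i + 1L)] ~ poly(w[(i - 1L):(i + 1L)], 2,
                                          raw = TRUE))
    a <- coef(fit)[3L]; b <- coef(fit)[2L]
    if (!is.finite(a) || a >= 0) return(w[i])
    unname(-b / (2 * a))
  }
  lam <- vapply(spectra, one, numeric(1))
  xs <- vapply(spectra, function(sp) sp$x, numeric(1))
  out <- TitrationSeries(xs, lam, kind = "lambda_max")
  if (edge) out@flags <- "edge_maximum"
  out
}
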