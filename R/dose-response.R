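## Monotone sigmoidal dose-response curves x_S^CA over physiological ranges.
##
## Each curve maps a nutrient concentration (glucose in mM, or pH) to a
## normalized sensitivity x in [0, 1], calibrated by least squares on
## discrete anchor points and rescaled so the curve spans exactly [0, 1]
## over its physiological range. The direction (increasing vs decreasing)
## is carried by the anchors: x encodes the strength of the edge's effect,
## so an edge driven by acidity has x rising as pH falls; the activating or
## inhibiting sign of the edge is applied only in the PN equation.

.stimulusRange <- function(stimulus) {
  switch(stimulus,
         glucose = .GLUCOSE_RANGE,
         pH = .PH_RANGE,
         stop("no concentration range defined for stimulus '", stimulus, "'",
              call. = FALSE))
}

#' DoseResponseCurve: a monotone normalized sensitivity function
#'
#' A four-parameter logistic fitted to anchor points and renormalized so
#' that its infimum over the range is 0 and its supremum 1.
#'
#' @slot stimulus stimulus name (glucose or pH).
#' @slot activity cell-activity name the curve feeds.
#' @slot range numeric length-2, the physiological concentration range.
#' @slot anchors data.frame(concentration, normalized_response) used in
#'   the fit (ties averaged).
#' @slot par named numeric: \code{lo}, \code{hi} (asymptotes), \code{mid}
#'   (midpoint), \code{k} (signed steepness).
#' @slot direction \code{"increasing"} or \code{"decreasing"}.
#' @slot sse residual sum of squares at the anchors.
#' @export
setClass("DoseResponseCurve", representation(
  stimulus = "character", activity = "character",
  range = "numeric", anchors = "data.frame",
  par = "numeric", direction = "character", sse = "numeric"
))

setValidity("DoseResponseCurve", function(object) {
  msg <- character()
  if (length(object@range) != 2L || object@range[1] >= object@range[2])
    msg <- c(msg, "range must be an increasing length-2 interval")
  if (!all(c("lo", "hi", "mid", "k") %in% names(object@par)))
    msg <- c(msg, "par must contain lo, hi, mid, k")
  if (!object@direction %in% c("increasing", "decreasing"))
    msg <- c(msg, "direction must be increasing or decreasing")
  if (length(msg)) msg else TRUE
})

#' @describeIn DoseResponseCurve-class brief description
#' @param object A \code{DoseResponseCurve}.
#' @export
setMethod("show", "DoseResponseCurve", function(object) {
  cat(sprintf("DoseResponseCurve %s -> %s: %s over [%g, %g], %d anchors, sse %.2e\n",
              object@stimulus, object@activity, object@direction,
              object@range[1], object@range[2], nrow(object@anchors),
              object@sse))
})

## raw 4PL before range-normalization
.logistic4 <- function(c, p) {
  p[["lo"]] + (p[["hi"]] - p[["lo"]]) / (1 + exp(-p[["k"]] * (c - p[["mid"]])))
}

## normalized curve value: inf 0 / sup 1 over [range]
.curveValue <- function(conc, range, p) {
  f <- .logistic4(conc, p)
  f0 <- .logistic4(range[1], p)
  f1 <- .logistic4(range[2], p)
  mn <- min(f0, f1); mx <- max(f0, f1)
  if (mx - mn < 1e-12) return(rep(0, length(conc)))
  (f - mn) / (mx - mn)
}

#' Fit a monotone sigmoid to dose-response anchor points
#'
#' Least-squares fit of a four-parameter logistic, constrained to the
#' monotone direction implied by the anchors, then rescaled so the curve
#' spans [0, 1] exactly over the physiological range. Anchors sharing a
#' concentration are averaged first; a sequence that is not monotone after
#' averaging is rejected. The optimisation uses a small set of fixed
#' deterministic starting points, so refitting the same anchors always
#' yields the same curve.
#'
#' @param anchors data.frame with columns \code{concentration} and
#'   \code{normalized_response} (responses in [0, 1]).
#' @param range length-2 physiological concentration interval; defaults to
#'   the stimulus's standard range (glucose [0, 5] mM, pH [6.5, 7.4]).
#' @param stimulus,activity labels stored on the curve.
#' @return A [DoseResponseCurve-class].
#' @examples
#' a <- data.frame(concentration = c(0, 0.5, 1, 5),
#'                 normalized_response = c(0, 0.7, 0.9, 1))
#' crv <- fitCurve(a, range = c(0, 5), stimulus = "glucose", activity = "Agg")
#' evalCurve(crv, c(0, 5))  # 0, 1
#' @export
fitCurve <- function(anchors, range = NULL, stimulus = "glucose",
                     activity = "Agg") {
  if (is.null(range)) range <- .stimulusRange(stimulus)
  range <- as.numeric(range)
  if (!all(c("concentration", "normalized_response") %in% names(anchors)))
    stop("anchors need columns concentration and normalized_response",
         call. = FALSE)
  a <- stats::aggregate(normalized_response ~ concentration,
                        data = anchors, FUN = mean)
  a <- a[order(a$concentration), c("concentration", "normalized_response")]
  if (nrow(a) < 2L)
    stop("need at least 2 anchors with distinct concentrations", call. = FALSE)
  if (any(a$concentration < range[1] - 1e-9 | a$concentration > range[2] + 1e-9))
    stop("anchor concentrations must lie inside the physiological range",
         call. = FALSE)
  if (any(a$normalized_response < -1e-9 | a$normalized_response > 1 + 1e-9))
    stop("anchor responses must lie in [0, 1]", call. = FALSE)
  d <- diff(a$normalized_response)
  if (all(d >= 0) && any(d > 0)) direction <- "increasing"
  else if (all(d <= 0) && any(d < 0)) direction <- "decreasing"
  else stop("anchor sequence is not consistent with a monotone curve",
            call. = FALSE)
  sgn <- if (direction == "increasing") 1 else -1

  obj <- function(p) {
    names(p) <- c("lo", "hi", "mid", "k")
    if (p[["k"]] * sgn <= 0) return(1e6)          # keep the fitted direction
    if (p[["hi"]] <= p[["lo"]]) return(1e6)
    pred <- .curveValue(a$concentration, range, p)
    sum((pred - a$normalized_response)^2)
  }
  span <- diff(range)
  starts <- list(
    c(lo = 0, hi = 1, mid = mean(range), k = sgn * 8 / span),
    c(lo = 0, hi = 1, mid = range[1] + 0.25 * span, k = sgn * 4 / span),
    c(lo = 0, hi = 1, mid = range[1] + 0.1 * span, k = sgn * 16 / span)
  )
  best <- NULL
  for (s in starts) {
    fit <- stats::optim(s, obj, method = "Nelder-Mead",
                        control = list(maxit = 4000, reltol = 1e-12))
    ## polish from the first solution
    fit <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                        control = list(maxit = 4000, reltol = 1e-12))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  p <- best$par
  names(p) <- c("lo", "hi", "mid", "k")
  new("DoseResponseCurve", stimulus = stimulus, activity = activity,
      range = range, anchors = a, par = p, direction = direction,
      sse = best$value)
}

#' Evaluate a dose-response curve
#'
#' Concentrations outside the physiological range are clamped to the
#' nearest endpoint with a warning, so that the returned sensitivity is
#' always in [0, 1] as the PN equation requires.
#'
#' @param curve A [DoseResponseCurve-class].
#' @param concentration numeric vector of concentrations.
#' @param rounded report at 4-decimal resolution (default TRUE).
#' @return Numeric vector of sensitivities in [0, 1].
#' @export
evalCurve <- function(curve, concentration, rounded = TRUE) {
  stopifnot(is(curve, "DoseResponseCurve"))
  conc <- as.numeric(concentration)
  out <- conc < curve@range[1] | conc > curve@range[2]
  if (any(out)) {
    warning(sprintf("%d concentration(s) outside [%g, %g] for %s->%s clamped",
                    sum(out), curve@range[1], curve@range[2],
                    curve@stimulus, curve@activity), call. = FALSE)
    conc <- pmin(pmax(conc, curve@range[1]), curve@range[2])
  }
  x <- .curveValue(conc, curve@range, curve@par)
  x <- pmin(pmax(x, 0), 1)
  if (rounded) round(x, 4) else x
}

#' Read a dose-response anchor table
#'
#' CSV with header
#' \code{stimulus,activity,concentration,normalized_response}; one curve
#' per (stimulus, activity) pair. Only the nutrient stimuli glucose and pH
#' carry concentration-based curves (cytokine x-values come from the
#' inflammation submodel).
#'
#' @param path CSV path.
#' @return Validated data.frame.
#' @export
loadAnchorTable <- function(path) {
  if (!file.exists(path)) stop("no such anchor table: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("stimulus", "activity", "concentration", "normalized_response")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("anchor table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!all(df$stimulus %in% c("glucose", "pH")))
    stop("anchor tables only cover the nutrient stimuli glucose and pH",
         call. = FALSE)
  if (!all(df$activity %in% c(.PN_ACTIVITIES, .INFL_ACTIVITIES)))
    stop("unknown activity in anchor table", call. = FALSE)
  df
}

#' Fit the full set of dose-response curves from an anchor table
#'
#' @param anchorTable data.frame as returned by [loadAnchorTable()].
#' @return Named list of [DoseResponseCurve-class] objects, keyed
#'   \code{"stimulus:activity"}.
#' @export
fitCurveSet <- function(anchorTable) {
  keys <- unique(paste(anchorTable$stimulus, anchorTable$activity, sep = ":"))
  curves <- lapply(keys, function(k) {
    parts <- strsplit(k, ":", fixed = TRUE)[[1]]
    sub <- anchorTable[anchorTable$stimulus == parts[1] &
                       anchorTable$activity == parts[2], ]
    fitCurve(sub, range = .stimulusRange(parts[1]),
             stimulus = parts[1], activity = parts[2])
  })
  names(curves) <- keys
  curves
}

#' The default dose-response curve set
#'
#' Fits the shipped anchor tables covering all nutrient edges of the
#' PN-system and the inflammation submodel. Fitting is deterministic, so
#' repeated calls return identical curves; results are cached per session.
#'
#' @return Named list of [DoseResponseCurve-class] objects.
#' @export
defaultCurves <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- fitCurveSet(loadAnchorTable(defaultTablePath("anchors_default")))
    cache
  }
})
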