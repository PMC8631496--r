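## Evaluation of the PN equation for every cell activity x cell state.

## multiplicity of an edge across cell-state networks: nutrient edges enter
## all four state networks, cytokine edges only the two states positive for
## that cytokine
.edgeMultiplicity <- function(stimulus) {
  vapply(stimulus, function(s)
    sum(vapply(.CELL_STATES, function(act) s %in% act, logical(1))),
    numeric(1))
}

## system-wide sums entering the PN equation, honoring the global-sum mode
.systemSums <- function(rel, globalSumMode) {
  w <- if (globalSumMode == "per_state_repeats")
    .edgeMultiplicity(rel$stimulus) else rep(1, nrow(rel))
  act <- rel$sign == "activating"
  sumAlpha <- sum(rel$theta[act] * w[act])
  betaByActivity <- vapply(unique(rel$activity), function(a) {
    i <- !act & rel$activity == a
    sum(rel$theta[i] * w[i])
  }, numeric(1))
  list(sumAlpha = sumAlpha, betaByActivity = betaByActivity)
}

#' Evaluate the PN equation for one cell activity and cell state
#'
#' Computes the PN-activity
#' \deqn{\omega_{CA,CS} = \frac{1+\sum\theta_\alpha}{\sum\theta_\alpha}
#'   \frac{S_\alpha}{1+S_\alpha}\left(1-
#'   \frac{\sum\theta^{CA}_{S,\beta}}{\sum\theta^{CA}_{S,\alpha}+\sum\theta^{CA}_{S,\beta}}
#'   \frac{1+\sum\theta^{CA}_\beta}{\sum\theta^{CA}_\beta}
#'   \frac{S_\beta}{1+S_\beta}\right)}
#' where \eqn{S_\alpha = \sum \theta x} over the activating edges of the
#' (activity, state) network and \eqn{S_\beta} the analogous inhibiting
#' sum; \eqn{\sum\theta_\alpha} runs over all activating edges of the whole
#' PN-system and \eqn{\sum\theta^{CA}_\beta} over all inhibiting edges
#' converging on the same activity regardless of cell state. A network with
#' no activating edge yields 0 (with a warning); an activity with no
#' inhibiting edge anywhere has a vanishing inhibition term. The result is
#' clamped to [0, 1].
#'
#' @param system A [PNSystem-class].
#' @param activity one of [pnActivities()].
#' @param state one of [cellStates()].
#' @param x named numeric of stimulus sensitivities in [0, 1]; must cover
#'   every stimulus of the (activity, state) network.
#' @param thetaMode \code{"individual"} uses the calibrated weighting
#'   factors; \code{"invariant_0.01"} replaces every weighting factor by
#'   0.01 (the comparison mode).
#' @param rounded report at 4-decimal resolution (default TRUE).
#' @return PN-activity in [0, 1].
#' @examples
#' sys <- defaultPNSystem()
#' pnEvaluate(sys, "Agg", "noninflamed", c(glucose = 1, pH = 0))
#' @export
pnEvaluate <- function(system, activity, state, x,
                       thetaMode = c("individual", "invariant_0.01"),
                       rounded = TRUE) {
  stopifnot(is(system, "PNSystem"))
  thetaMode <- match.arg(thetaMode)
  activity <- match.arg(activity, .PN_ACTIVITIES)
  state <- match.arg(state, names(.CELL_STATES))
  rel <- system@relationships
  if (thetaMode == "invariant_0.01") rel$theta <- .THETA_FLOOR

  sums <- .systemSums(rel, system@globalSumMode)
  stim <- .CELL_STATES[[state]]
  net <- rel[rel$activity == activity & rel$stimulus %in% stim, , drop = FALSE]
  missing <- setdiff(net$stimulus, names(x))
  if (length(missing))
    stop("no x value provided for edge(s): ",
         paste0(missing, "->", activity, collapse = ", "), call. = FALSE)
  xs <- as.numeric(x[net$stimulus])
  if (anyNA(xs) || any(xs < -1e-9 | xs > 1 + 1e-9))
    stop("stimulus sensitivities x must lie in [0, 1]", call. = FALSE)

  aIdx <- net$sign == "activating"
  if (!any(aIdx)) {
    warning(sprintf("network %s/%s has no activating edge; omega = 0",
                    activity, state), call. = FALSE)
    return(if (rounded) 0 else 0)
  }
  sumAlphaGlobal <- sums$sumAlpha
  sAlpha <- sum(net$theta[aIdx] * xs[aIdx])
  A <- ((1 + sumAlphaGlobal) / sumAlphaGlobal) * (sAlpha / (1 + sAlpha))

  sumBetaCA <- unname(sums$betaByActivity[activity])
  if (length(sumBetaCA) != 1L || is.na(sumBetaCA)) sumBetaCA <- 0
  thNetA <- sum(net$theta[aIdx])
  thNetB <- sum(net$theta[!aIdx])
  B <- 0
  if (thNetB > 0 && sumBetaCA > 0) {
    sBeta <- sum(net$theta[!aIdx] * xs[!aIdx])
    B <- (thNetB / (thNetA + thNetB)) *
      ((1 + sumBetaCA) / sumBetaCA) * (sBeta / (1 + sBeta))
  }
  omega <- min(max(A * (1 - B), 0), 1)
  if (rounded) round(omega, 4) else omega
}

#' PN-activity profiles for all cell states and activities
#'
#' Evaluates the PN equation for the 4 cell states x 5 activities of the
#' PN-system under a nutrient environment. Nutrient sensitivities come from
#' the dose-response curves evaluated at the environment's glucose and pH;
#' cytokine sensitivities are taken from the inflammation submodel (or can
#' be supplied directly).
#'
#' @param system A [PNSystem-class].
#' @param env A [NutrientEnvironment-class].
#' @param curves named curve list from [fitCurveSet()]/[defaultCurves()];
#'   must cover every nutrient edge of the PN-system.
#' @param cytokineXValues optional named numeric \code{c(IL1B=, TNFA=)} in
#'   [0, 1]; when NULL it is computed by [inflammationState()] under the
#'   same \code{thetaMode}.
#' @param thetaMode \code{"individual"} or \code{"invariant_0.01"}; the
#'   invariant mode replaces every weighting factor by 0.01 before
#'   evaluating (the systematic-weighting comparison experiment).
#' @return data.frame with columns \code{environment}, \code{cell_state},
#'   \code{activity}, \code{omega} (4 decimals), \code{theta_mode}.
#' @examples
#' prof <- profileAll(defaultPNSystem(), nutrientPreset("optimal"),
#'                    defaultCurves())
#' head(prof)
#' @export
profileAll <- function(system, env, curves, cytokineXValues = NULL,
                       thetaMode = c("individual", "invariant_0.01")) {
  stopifnot(is(system, "PNSystem"), is(env, "NutrientEnvironment"))
  thetaMode <- match.arg(thetaMode)
  rel <- system@relationships
  nutrient <- unique(rel[rel$stimulus %in% c("glucose", "pH"),
                         c("stimulus", "activity")])
  keys <- paste(nutrient$stimulus, nutrient$activity, sep = ":")
  miss <- setdiff(keys, names(curves))
  if (length(miss))
    stop("no dose-response curve for edge(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (is.null(cytokineXValues)) {
    needCyt <- intersect(unique(rel$stimulus), c("IL1B", "TNFA"))
    cytokineXValues <- c(IL1B = 0, TNFA = 0)
    if (length(needCyt)) {
      st <- inflammationState(system, env, curves, thetaMode = thetaMode)
      cytokineXValues <- cytokineX(st)
    }
  }
  xFor <- function(activity, stimuli) {
    vals <- vapply(stimuli, function(s) {
      if (s %in% c("glucose", "pH")) {
        key <- paste(s, activity, sep = ":")
        conc <- if (s == "glucose") env@glucose else env@pH
        evalCurve(curves[[key]], conc, rounded = FALSE)
      } else {
        v <- cytokineXValues[[s]]
        if (is.null(v) || is.na(v))
          stop("no cytokine x value for ", s, call. = FALSE)
        v
      }
    }, numeric(1))
    names(vals) <- stimuli
    vals
  }
  grid <- expand.grid(cell_state = names(.CELL_STATES),
                      activity = .PN_ACTIVITIES,
                      stringsAsFactors = FALSE)
  grid <- grid[order(match(grid$cell_state, names(.CELL_STATES))), ]
  omega <- mapply(function(st, ac) {
    stim <- intersect(.CELL_STATES[[st]],
                      rel$stimulus[rel$activity == ac])
    pnEvaluate(system, ac, st, xFor(ac, stim), thetaMode = thetaMode,
               rounded = FALSE)
  }, grid$cell_state, grid$activity)
  data.frame(environment = env@label,
             cell_state = grid$cell_state,
             activity = grid$activity,
             omega = round(as.numeric(omega), 4),
             theta_mode = thetaMode,
             row.names = NULL,
             stringsAsFactors = FALSE)
}
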