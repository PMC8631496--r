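## Inflammation submodel: global cytokine mRNA activities from the
## nutrient environment, protein synthesis/decay dynamics and the linear
## map from normalized activity to the percentage of immunopositive cells.

#' Parameters of a cytokine submodel
#'
#' @param cytokine \code{"IL1B"} or \code{"TNFA"}.
#' @return List with \code{halfLife} (hours; IL1B 2 h, TNFA 1 h) and
#'   \code{immunoRange} (percent; IL1B 10-59, TNFA 9-36).
#' @export
cytokineParams <- function(cytokine = c("IL1B", "TNFA")) {
  cytokine <- match.arg(cytokine)
  .CYTOKINE_DEFAULTS[[cytokine]]
}

#' Normalized cytokine mRNA activity under a nutrient environment
#'
#' Evaluates the single-network regulatory equation for a cytokine's mRNA
#' expression: with \eqn{S = \sum \theta x} over the submodel's activating
#' edges, \eqn{\omega = \frac{1+\sum\theta_\alpha}{\sum\theta_\alpha}
#' \frac{S}{1+S}} (times an inhibition factor when inhibiting edges are
#' present), clamped to [0, 1]. The weighting factors are the
#' inflammation-submodel thetas derived with the PN-system scaling factor;
#' they may exceed 1 because the cytokine activities are not part of the
#' PN-system.
#'
#' @param system A [PNSystem-class] whose inflammation slot holds the
#'   cytokine relationships.
#' @param cytokine \code{"IL1B"} or \code{"TNFA"}.
#' @param env A [NutrientEnvironment-class].
#' @param curves curve list covering the submodel's nutrient edges
#'   (keys \code{"glucose:IL1B_mRNA"} etc.).
#' @param thetaMode \code{"individual"} or \code{"invariant_0.01"}.
#' @param rounded report at 4-decimal resolution (default TRUE).
#' @return Normalized activity in [0, 1].
#' @export
cytokineOmega <- function(system, cytokine = c("IL1B", "TNFA"), env, curves,
                          thetaMode = c("individual", "invariant_0.01"),
                          rounded = TRUE) {
  stopifnot(is(system, "PNSystem"), is(env, "NutrientEnvironment"))
  cytokine <- match.arg(cytokine)
  thetaMode <- match.arg(thetaMode)
  activity <- paste0(cytokine, "_mRNA")
  net <- system@inflammation[system@inflammation$activity == activity, ,
                             drop = FALSE]
  if (nrow(net) == 0L)
    stop("system has no inflammation-submodel relationships for ", cytokine,
         call. = FALSE)
  if (thetaMode == "invariant_0.01") net$theta <- .THETA_FLOOR
  xs <- vapply(seq_len(nrow(net)), function(i) {
    key <- paste(net$stimulus[i], activity, sep = ":")
    if (is.null(curves[[key]]))
      stop("no dose-response curve for edge ", key, call. = FALSE)
    conc <- switch(net$stimulus[i], glucose = env@glucose, pH = env@pH,
                   stop("inflammation submodel edges must be nutrient-driven",
                        call. = FALSE))
    evalCurve(curves[[key]], conc, rounded = FALSE)
  }, numeric(1))
  aIdx <- net$sign == "activating"
  if (!any(aIdx)) {
    warning("cytokine network has no activating edge; omega = 0", call. = FALSE)
    return(0)
  }
  thA <- sum(net$theta[aIdx])
  sA <- sum(net$theta[aIdx] * xs[aIdx])
  omega <- ((1 + thA) / thA) * (sA / (1 + sA))
  if (any(!aIdx)) {
    thB <- sum(net$theta[!aIdx])
    sB <- sum(net$theta[!aIdx] * xs[!aIdx])
    omega <- omega * (1 - (thB / (thA + thB)) *
                        ((1 + thB) / thB) * (sB / (1 + sB)))
  }
  omega <- min(max(omega, 0), 1)
  if (rounded) round(omega, 4) else omega
}

#' One synthesis/decay step of a cytokine protein pool
#'
#' Exponential decay at the cytokine's half-life plus synthesis
#' proportional to the current normalized mRNA activity:
#' \deqn{P_{t+dt} = P_t \, 2^{-dt/t_{1/2}} + k_{syn}\,\omega.}
#' The 1-hour default time step matches the agent-based model clock and
#' equals the shortest implemented half-life (TNF-a).
#'
#' @param protein current normalized protein level (non-negative).
#' @param omega normalized mRNA activity in [0, 1].
#' @param halfLife protein half-life in hours (IL1B 2, TNFA 1).
#' @param dt time step in hours (default 1).
#' @param kSyn synthesis proportionality constant (normalized units,
#'   default 1).
#' @return Updated protein level.
#' @examples
#' proteinStep(1, 0, halfLife = 1)  # 0.5 after one half-life
#' proteinStep(1, 0, halfLife = 2)  # 2^(-1/2)
#' @export
proteinStep <- function(protein, omega, halfLife, dt = 1, kSyn = 1) {
  if (!is.numeric(dt) || length(dt) != 1L || is.na(dt) || dt <= 0)
    stop("time step dt must be positive", call. = FALSE)
  if (any(protein < 0)) stop("protein level must be non-negative", call. = FALSE)
  protein * 2^(-dt / halfLife) + kSyn * omega
}

#' Protein trajectory under constant mRNA activity
#'
#' @inheritParams proteinStep
#' @param nSteps number of steps to simulate.
#' @param p0 initial protein level.
#' @return Numeric vector of length \code{nSteps} (levels after each step).
#' @export
proteinTrajectory <- function(omega, halfLife, nSteps, dt = 1, kSyn = 1,
                              p0 = 0) {
  out <- numeric(nSteps)
  p <- p0
  for (i in seq_len(nSteps)) {
    p <- proteinStep(p, omega, halfLife, dt = dt, kSyn = kSyn)
    out[i] <- p
  }
  out
}

#' Steady-state protein level under constant mRNA activity
#'
#' Limit of the geometric series of [proteinStep()]:
#' \eqn{P^\ast = k_{syn}\,\omega / (1 - 2^{-dt/t_{1/2}})}.
#'
#' @inheritParams proteinStep
#' @return Steady-state level.
#' @export
proteinSteadyState <- function(omega, halfLife, dt = 1, kSyn = 1) {
  kSyn * omega / (1 - 2^(-dt / halfLife))
}

#' Percentage of immunopositive cells for a cytokine activity
#'
#' Affine map anchored at the published immunopositivity range endpoints:
#' \eqn{pct = low + \omega\,(high - low)}, so a fully silent network still
#' yields the non-degenerated floor (10\% for IL1B, 9\% for TNF-a) and a
#' saturated one the degenerated ceiling (59\% / 36\%).
#'
#' @param cytokine \code{"IL1B"} or \code{"TNFA"}.
#' @param omega normalized activity; values outside [0, 1] are clamped.
#' @param range optional length-2 override of the percent range.
#' @return Percent of immunopositive cells.
#' @examples
#' pctImmunopositive("IL1B", c(0, 1))   # 10, 59
#' pctImmunopositive("TNFA", 0.5)       # 22.5
#' @export
pctImmunopositive <- function(cytokine = c("IL1B", "TNFA"), omega,
                              range = NULL) {
  cytokine <- match.arg(cytokine)
  if (is.null(range)) range <- .CYTOKINE_DEFAULTS[[cytokine]]$immunoRange
  stopifnot(length(range) == 2L, range[1] >= 0, range[1] < range[2],
            range[2] <= 100)
  omega <- pmin(pmax(as.numeric(omega), 0), 1)
  range[1] + omega * (range[2] - range[1])
}

#' Full inflammation state for a nutrient environment
#'
#' Computes both cytokines' normalized mRNA activities, simulates the
#' protein pools to (near) steady state, maps the activities to
#' immunopositivity percentages, and derives the x-values that the
#' second/third-level cell-activity networks consume. With the default
#' \code{carrier = "protein"} the x-value is the protein level normalized
#' by its maximal steady state (the level a saturated network would
#' sustain), which keeps x in [0, 1]; \code{carrier = "mRNA"} uses the
#' mRNA activity directly.
#'
#' @param system A [PNSystem-class].
#' @param env A [NutrientEnvironment-class].
#' @param curves curve list covering the submodel's nutrient edges.
#' @param thetaMode \code{"individual"} or \code{"invariant_0.01"}.
#' @param carrier \code{"protein"} (default) or \code{"mRNA"}.
#' @param nSteps protein simulation steps (default 100 h, far beyond both
#'   half-lives).
#' @param dt time step in hours.
#' @param kSyn synthesis constant.
#' @return An [InflammationState-class].
#' @examples
#' st <- inflammationState(defaultPNSystem(), nutrientPreset("optimal"),
#'                         defaultCurves())
#' pctImmunopositiveCells(st)
#' @export
inflammationState <- function(system, env, curves,
                              thetaMode = c("individual", "invariant_0.01"),
                              carrier = c("protein", "mRNA"),
                              nSteps = 100, dt = 1, kSyn = 1) {
  thetaMode <- match.arg(thetaMode)
  carrier <- match.arg(carrier)
  omega <- protein <- pct <- xval <- c(IL1B = NA_real_, TNFA = NA_real_)
  for (cy in c("IL1B", "TNFA")) {
    hl <- .CYTOKINE_DEFAULTS[[cy]]$halfLife
    om <- cytokineOmega(system, cy, env, curves, thetaMode = thetaMode,
                        rounded = FALSE)
    traj <- proteinTrajectory(om, hl, nSteps = nSteps, dt = dt, kSyn = kSyn)
    pmax_ <- proteinSteadyState(1, hl, dt = dt, kSyn = kSyn)
    omega[[cy]] <- om
    protein[[cy]] <- traj[nSteps] / pmax_   # normalized by saturated steady state
    pct[[cy]] <- pctImmunopositive(cy, om)
    xval[[cy]] <- if (carrier == "protein")
      min(max(traj[nSteps] / pmax_, 0), 1) else om
  }
  new("InflammationState", omegaMRNA = omega, protein = protein,
      pctImmunopositive = pct, cytokineX = xval, environment = env@label)
}
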