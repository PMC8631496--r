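## Central S4 classes and controlled vocabularies.

## Controlled vocabularies -------------------------------------------------

#' Names of the five cell activities of the PN-system
#' @keywords internal
.PN_ACTIVITIES <- c("Agg", "ColI", "ColII", "MMP3", "ADAMTS4")

#' Cell activities handled only by the inflammation submodel
#' @keywords internal
.INFL_ACTIVITIES <- c("IL1B_mRNA", "TNFA_mRNA")

## stimulus -> order; glucose/pH are user-defined first-order stimuli,
## cytokines are second-order stimuli produced by the inflammation submodel
.STIMULI <- c(glucose = "first", pH = "first", IL1B = "second", TNFA = "second")

## cell state -> the stimuli acting on that state's networks
.CELL_STATES <- list(
  noninflamed   = c("glucose", "pH"),
  IL1B_pos      = c("glucose", "pH", "IL1B"),
  TNFA_pos      = c("glucose", "pH", "TNFA"),
  IL1B_TNFA_pos = c("glucose", "pH", "IL1B", "TNFA")
)

.GLUCOSE_RANGE <- c(0, 5)    # mM
.PH_RANGE <- c(6.5, 7.4)     # pH units

## cytokine protein half-lives (h) and immunopositivity ranges (%)
.CYTOKINE_DEFAULTS <- list(
  IL1B = list(halfLife = 2, immunoRange = c(10, 59)),
  TNFA = list(halfLife = 1, immunoRange = c(9, 36))
)

## floor weighting factor: approximates a linear coupling between x and omega
.THETA_FLOOR <- 0.01

#' Enumerate the four pro-inflammatory cell states
#'
#' @return Character vector of the four cell-state labels, from non-inflamed
#'   to double immunopositive.
#' @export
cellStates <- function() names(.CELL_STATES)

#' Stimuli acting on the networks of a given cell state
#'
#' Non-inflamed cells respond to the two nutrient stimuli only; cells
#' immunopositive for a cytokine are additionally exposed to that cytokine,
#' and double-positive cells to all four stimuli.
#'
#' @param state One of [cellStates()].
#' @return Character vector of stimulus names.
#' @export
activeStimuli <- function(state) {
  state <- match.arg(state, names(.CELL_STATES))
  .CELL_STATES[[state]]
}

#' Cell-activity names of the PN-system
#' @return Character vector of the five mRNA-expression activity names.
#' @export
pnActivities <- function() .PN_ACTIVITIES

## PNSystem ---------------------------------------------------------------

#' PNSystem: a calibrated parallel-networks system
#'
#' Holds the stimulus to cell-activity (S-CA) relationship table of the
#' PN-system (one row per unique directed edge) together with the
#' inflammation-submodel relationships, the scaling factor used to derive
#' the weighting factors, and the convention used for the system-wide
#' activating sum of the PN equation.
#'
#' @slot relationships data.frame of PN-system edges with columns
#'   \code{stimulus}, \code{activity}, \code{sign}, \code{significant},
#'   \code{epsilon}, \code{effort}, \code{theta}.
#' @slot inflammation data.frame of inflammation-submodel edges, same
#'   columns; their \code{theta} may exceed 1.
#' @slot scalingFactor numeric, the maximal cellular effort over all
#'   significant PN-system edges.
#' @slot scalingSource character \code{"stimulus->activity"} naming the edge
#'   that attains the maximum.
#' @slot globalSumMode \code{"unique_edges"} (default) or
#'   \code{"per_state_repeats"}; see [pnEvaluate()].
#' @export
setClass("PNSystem", representation(
  relationships = "data.frame",
  inflammation  = "data.frame",
  scalingFactor = "numeric",
  scalingSource = "character",
  globalSumMode = "character"
))

setValidity("PNSystem", function(object) {
  rel <- object@relationships
  msg <- character()
  need <- c("stimulus", "activity", "sign", "significant", "theta")
  if (!all(need %in% names(rel)))
    return(paste("relationships must have columns:", paste(need, collapse = ", ")))
  if (nrow(rel) == 0L) msg <- c(msg, "at least one PN-system relationship required")
  if (anyDuplicated(rel[c("stimulus", "activity")]))
    msg <- c(msg, "duplicated (stimulus, activity) edge in PN-system")
  if (!any(rel$sign == "activating"))
    msg <- c(msg, "PN-system needs at least one activating edge")
  if (any(rel$theta < .THETA_FLOOR - 1e-12 | rel$theta > 1 + 1e-12))
    msg <- c(msg, "PN-system weighting factors must lie in [0.01, 1]")
  infl <- object@inflammation
  if (nrow(infl) > 0L && anyDuplicated(infl[c("stimulus", "activity")]))
    msg <- c(msg, "duplicated (stimulus, activity) edge in inflammation submodel")
  if (length(object@globalSumMode) != 1L ||
      !object@globalSumMode %in% c("unique_edges", "per_state_repeats"))
    msg <- c(msg, "globalSumMode must be 'unique_edges' or 'per_state_repeats'")
  if (length(msg)) msg else TRUE
})

#' @describeIn PNSystem-class compact description of the calibrated system
#' @param object A \code{PNSystem}.
#' @export
setMethod("show", "PNSystem", function(object) {
  rel <- object@relationships
  cat("PNSystem with", nrow(rel), "S-CA relationships (",
      sum(rel$significant), "significant ) over",
      length(unique(rel$activity)), "cell activities\n")
  cat("  scaling factor:", format(object@scalingFactor),
      "(", object@scalingSource, ")\n")
  if (nrow(object@inflammation))
    cat("  inflammation submodel:", nrow(object@inflammation), "edges\n")
  cat("  global activating-sum mode:", object@globalSumMode, "\n")
})

#' Relationship table of a PNSystem
#'
#' @param object A \code{PNSystem}.
#' @param submodel \code{"pn"} for the PN-system edges (default),
#'   \code{"inflammation"} for the inflammation-submodel edges, or
#'   \code{"all"} for both stacked.
#' @return data.frame of S-CA relationships with derived effort and theta.
#' @export
relationships <- function(object, submodel = c("pn", "inflammation", "all")) {
  stopifnot(is(object, "PNSystem"))
  submodel <- match.arg(submodel)
  switch(submodel,
    pn = object@relationships,
    inflammation = object@inflammation,
    all = rbind(object@relationships, object@inflammation))
}

#' Scaling factor of a calibrated PNSystem
#'
#' @param object A \code{PNSystem}.
#' @return The maximal cellular effort among significant PN-system edges,
#'   with attribute \code{source} naming the edge attaining it.
#' @export
scalingFactor <- function(object) {
  stopifnot(is(object, "PNSystem"))
  structure(object@scalingFactor, source = object@scalingSource)
}

## NutrientEnvironment -----------------------------------------------------

#' NutrientEnvironment: a glucose/pH micro-environment
#'
#' @slot glucose glucose concentration in mM, within [0, 5].
#' @slot pH extracellular pH, within [6.5, 7.4].
#' @slot label free-text label (e.g. preset name).
#' @export
setClass("NutrientEnvironment", representation(
  glucose = "numeric", pH = "numeric", label = "character"
))

setValidity("NutrientEnvironment", function(object) {
  msg <- character()
  if (length(object@glucose) != 1L || is.na(object@glucose) ||
      object@glucose < .GLUCOSE_RANGE[1] || object@glucose > .GLUCOSE_RANGE[2])
    msg <- c(msg, sprintf("glucose must be a single value in [%g, %g] mM",
                          .GLUCOSE_RANGE[1], .GLUCOSE_RANGE[2]))
  if (length(object@pH) != 1L || is.na(object@pH) ||
      object@pH < .PH_RANGE[1] || object@pH > .PH_RANGE[2])
    msg <- c(msg, sprintf("pH must be a single value in [%g, %g]",
                          .PH_RANGE[1], .PH_RANGE[2]))
  if (length(msg)) msg else TRUE
})

#' Construct a nutrient environment
#'
#' @param glucose glucose concentration in mM (0-5).
#' @param pH extracellular pH (6.5-7.4).
#' @param label optional label.
#' @return A validated \code{NutrientEnvironment}.
#' @examples
#' nutrientEnvironment(5, 7.1, "optimal")
#' @export
nutrientEnvironment <- function(glucose, pH, label = "custom") {
  new("NutrientEnvironment", glucose = as.numeric(glucose),
      pH = as.numeric(pH), label = as.character(label))
}

#' @describeIn NutrientEnvironment-class print glucose and pH
#' @param object A \code{NutrientEnvironment}.
#' @export
setMethod("show", "NutrientEnvironment", function(object) {
  cat(sprintf("NutrientEnvironment '%s': glucose %g mM, pH %g\n",
              object@label, object@glucose, object@pH))
})

#' Glucose concentration of an environment
#' @param object A \code{NutrientEnvironment}.
#' @return Numeric scalar (mM).
#' @export
glucose <- function(object) object@glucose

#' pH of an environment
#' @param object A \code{NutrientEnvironment}.
#' @return Numeric scalar.
#' @export
pH <- function(object) object@pH

## InflammationState -------------------------------------------------------

#' InflammationState: normalized cytokine activities of an environment
#'
#' @slot omegaMRNA named numeric, normalized IL1B/TNFA mRNA activities
#'   in [0, 1].
#' @slot protein named numeric, normalized cytokine protein level after the
#'   simulated synthesis/decay steps.
#' @slot pctImmunopositive named numeric, percent of immunopositive cells
#'   per cytokine (within the published ranges).
#' @slot cytokineX named numeric, the x-values in [0, 1] carried into the
#'   second/third-level cell-activity networks.
#' @slot environment label of the nutrient environment used.
#' @export
setClass("InflammationState", representation(
  omegaMRNA = "numeric", protein = "numeric",
  pctImmunopositive = "numeric", cytokineX = "numeric",
  environment = "character"
))

setValidity("InflammationState", function(object) {
  msg <- character()
  for (s in c("omegaMRNA", "protein", "pctImmunopositive", "cytokineX")) {
    v <- slot(object, s)
    if (!all(c("IL1B", "TNFA") %in% names(v)))
      msg <- c(msg, paste(s, "must be named with IL1B and TNFA"))
  }
  if (any(object@omegaMRNA < -1e-9 | object@omegaMRNA > 1 + 1e-9))
    msg <- c(msg, "omegaMRNA must lie in [0, 1]")
  if (any(object@protein < -1e-9))
    msg <- c(msg, "protein levels must be non-negative")
  if (length(msg)) msg else TRUE
})

#' @describeIn InflammationState-class summary of cytokine activities
#' @param object An \code{InflammationState}.
#' @export
setMethod("show", "InflammationState", function(object) {
  cat(sprintf("InflammationState (%s)\n", object@environment))
  for (cy in c("IL1B", "TNFA"))
    cat(sprintf("  %s: omega = %.4f, protein = %.4f, immunopositive = %.2f%%\n",
                cy, object@omegaMRNA[[cy]], object@protein[[cy]],
                object@pctImmunopositive[[cy]]))
})

#' Immunopositivity percentages of an inflammation state
#' @param object An \code{InflammationState}.
#' @return Named numeric (percent) for IL1B and TNFA.
#' @export
pctImmunopositiveCells <- function(object) object@pctImmunopositive

#' Normalized cytokine mRNA activities
#' @param object An \code{InflammationState}.
#' @return Named numeric in [0, 1] for IL1B and TNFA.
#' @export
omegaMRNA <- function(object) object@omegaMRNA

#' Cytokine x-values carried into inflamed cell-activity networks
#' @param object An \code{InflammationState}.
#' @return Named numeric in [0, 1] for IL1B and TNFA.
#' @export
cytokineX <- function(object) object@cytokineX
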