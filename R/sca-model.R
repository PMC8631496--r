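## Calibration of S-CA weighting factors from x-fold mRNA changes.

#' Cellular effort of an x-fold mRNA change
#'
#' Maps a fold-change \eqn{\epsilon > 0} relative to control (= 1) to a
#' symmetric magnitude of regulation: \eqn{f(\epsilon) = \epsilon} for
#' up-regulation (\eqn{\epsilon \ge 1}) and \eqn{f(\epsilon) = 1/\epsilon}
#' for down-regulation (\eqn{0 < \epsilon < 1}), so that a 2-fold increase
#' and a halving carry the same effort. The term implies no intracellular
#' mechanism; it is a normalization device.
#'
#' @param epsilon numeric vector of strictly positive fold-changes.
#' @return Numeric vector of efforts, all \eqn{\ge 1}.
#' @examples
#' cellularEffort(c(0.06, 1, 0.37))  # 16.6667, 1, 2.7027
#' @export
cellularEffort <- function(epsilon) {
  epsilon <- as.numeric(epsilon)
  if (length(epsilon) == 0L || anyNA(epsilon) || any(epsilon <= 0))
    stop("fold-changes (epsilon) must be strictly positive", call. = FALSE)
  ifelse(epsilon >= 1, epsilon, 1 / epsilon)
}

## internal: validate a raw relationship data.frame (shared by the file
## loader and the in-memory constructor)
.validateRelationshipDF <- function(df, where = "relationship table") {
  need <- c("stimulus", "activity", "sign", "significant", "epsilon")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(where, " is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(df) == 0L)
    stop(where, " contains no relationships", call. = FALSE)
  df$stimulus <- as.character(df$stimulus)
  df$activity <- as.character(df$activity)
  df$sign <- as.character(df$sign)
  df$significant <- as.logical(df$significant)
  df$epsilon <- as.numeric(df$epsilon)
  allAct <- c(.PN_ACTIVITIES, .INFL_ACTIVITIES)
  for (i in seq_len(nrow(df))) {
    rowid <- sprintf("%s row %d (%s -> %s)", where, i, df$stimulus[i], df$activity[i])
    if (!df$stimulus[i] %in% names(.STIMULI))
      stop("unknown stimulus in ", rowid, call. = FALSE)
    if (!df$activity[i] %in% allAct)
      stop("unknown activity in ", rowid, call. = FALSE)
    if (!df$sign[i] %in% c("activating", "inhibiting"))
      stop("sign must be 'activating' or 'inhibiting' in ", rowid, call. = FALSE)
    if (is.na(df$significant[i]))
      stop("significant flag missing in ", rowid, call. = FALSE)
    if (df$significant[i] && (is.na(df$epsilon[i]) || df$epsilon[i] <= 0))
      stop("significant relationship needs a strictly positive epsilon in ",
           rowid, call. = FALSE)
  }
  df[, need]
}

#' Read an S-CA relationship table
#'
#' Parses a delimited table with header
#' \code{stimulus,activity,sign,significant,epsilon}. Fold-changes
#' (\code{epsilon}) may be empty for non-significant rows; significant rows
#' must carry a strictly positive value. Weighting factors are not derived
#' here; see [calibrateSystem()].
#'
#' @param path path to a CSV file.
#' @return data.frame with the five validated columns.
#' @seealso [defaultTablePath()] for the shipped default tables.
#' @export
loadRelationshipTable <- function(path) {
  if (!file.exists(path)) stop("no such relationship table: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .validateRelationshipDF(df, where = basename(path))
}

#' Scaling factor from a set of relationships
#'
#' The maximal cellular effort over all significant relationships; dividing
#' every effort by it maps the weighting factors into (0, 1], with the
#' maximal edge landing exactly on 1.
#'
#' @param rel data.frame of relationships (columns as in
#'   [loadRelationshipTable()]).
#' @return Numeric scalar with attribute \code{source} =
#'   \code{"stimulus->activity"} of the edge attaining the maximum.
#' @export
deriveScalingFactor <- function(rel) {
  rel <- .validateRelationshipDF(rel, where = "relationships")
  sig <- rel[rel$significant, , drop = FALSE]
  if (nrow(sig) == 0L)
    stop("cannot derive a scaling factor: no significant relationship",
         call. = FALSE)
  eff <- cellularEffort(sig$epsilon)
  k <- which.max(eff)
  structure(eff[k], source = paste0(sig$stimulus[k], "->", sig$activity[k]))
}

#' Derive weighting factors for a set of relationships
#'
#' Significant edges get \eqn{\theta = f(\epsilon) / \vartheta} rounded to
#' 4 decimals (round-half-even) and floored at 0.01; non-significant edges
#' are fixed at \eqn{\theta = 0.01}, which approximates a linear coupling
#' between the stimulus sensitivity x and the resulting PN-activity.
#'
#' @param rel data.frame of relationships.
#' @param scaling positive scaling factor (see [deriveScalingFactor()]).
#' @return \code{rel} with added \code{effort} and \code{theta} columns.
#' @export
deriveTheta <- function(rel, scaling) {
  if (!is.numeric(scaling) || length(scaling) != 1L || is.na(scaling) ||
      scaling <= 0)
    stop("scaling factor must be a single positive number", call. = FALSE)
  rel <- .validateRelationshipDF(rel, where = "relationships")
  rel$effort <- NA_real_
  rel$theta <- .THETA_FLOOR
  sig <- which(rel$significant)
  if (length(sig)) {
    rel$effort[sig] <- cellularEffort(rel$epsilon[sig])
    rel$theta[sig] <- pmax(round(rel$effort[sig] / scaling, 4), .THETA_FLOOR)
  }
  rel
}

#' Calibrate a parallel-networks system from relationship tables
#'
#' Derives the scaling factor from the PN-system rows only (the maximal
#' cellular effort, attained by pH->MMP3 for the shipped defaults) and uses
#' it to derive weighting factors for both the PN-system and the
#' inflammation submodel. Submodel weighting factors may exceed 1 because
#' the cytokine mRNA activities are not part of the PN-system.
#'
#' @param pn data.frame of PN-system relationships (activities among
#'   [pnActivities()]).
#' @param inflammation optional data.frame of inflammation-submodel
#'   relationships (activities \code{IL1B_mRNA}/\code{TNFA_mRNA}).
#' @param globalSumMode convention for the system-wide activating sum of
#'   the PN equation: \code{"unique_edges"} counts every (stimulus,
#'   activity) edge once (default); \code{"per_state_repeats"} counts each
#'   edge once per cell state whose networks contain it.
#' @return A validated [PNSystem-class] object.
#' @examples
#' sys <- defaultPNSystem()
#' scalingFactor(sys)     # 28.7, attained by pH->MMP3
#' @export
calibrateSystem <- function(pn, inflammation = NULL,
                            globalSumMode = c("unique_edges", "per_state_repeats")) {
  globalSumMode <- match.arg(globalSumMode)
  pn <- .validateRelationshipDF(pn, where = "PN-system table")
  bad <- setdiff(unique(pn$activity), .PN_ACTIVITIES)
  if (length(bad))
    stop("PN-system table contains non-PN activities: ",
         paste(bad, collapse = ", "), call. = FALSE)
  scal <- deriveScalingFactor(pn)
  pn <- deriveTheta(pn, as.numeric(scal))
  infl <- if (is.null(inflammation) || nrow(inflammation) == 0L) {
    cbind(pn[0, ], effort = numeric(0), theta = numeric(0))[, c(names(pn))]
  } else {
    inflammation <- .validateRelationshipDF(inflammation,
                                            where = "inflammation table")
    bad <- setdiff(unique(inflammation$activity), .INFL_ACTIVITIES)
    if (length(bad))
      stop("inflammation table contains non-submodel activities: ",
           paste(bad, collapse = ", "), call. = FALSE)
    deriveTheta(inflammation, as.numeric(scal))
  }
  new("PNSystem", relationships = pn, inflammation = infl,
      scalingFactor = as.numeric(scal),
      scalingSource = attr(scal, "source"),
      globalSumMode = globalSumMode)
}

#' Build a PNSystem from relationships with pre-derived weighting factors
#'
#' Low-level constructor for systems whose \code{theta} column is already
#' set (e.g. synthetic networks in property tests). No calibration is
#' performed.
#'
#' @param relationships data.frame with at least \code{stimulus},
#'   \code{activity}, \code{sign}, \code{significant}, \code{theta}.
#' @param inflammation optional submodel data.frame of the same shape.
#' @param scalingFactor numeric scalar recorded on the object.
#' @param globalSumMode see [calibrateSystem()].
#' @return A validated [PNSystem-class].
#' @export
makePNSystem <- function(relationships, inflammation = NULL,
                         scalingFactor = NA_real_,
                         globalSumMode = c("unique_edges", "per_state_repeats")) {
  globalSumMode <- match.arg(globalSumMode)
  fill <- function(df) {
    if (is.null(df$epsilon)) df$epsilon <- NA_real_
    if (is.null(df$effort)) df$effort <- NA_real_
    df
  }
  relationships <- fill(relationships)
  if (is.null(inflammation))
    inflammation <- relationships[0, ]
  else inflammation <- fill(inflammation)
  new("PNSystem", relationships = relationships, inflammation = inflammation,
      scalingFactor = as.numeric(scalingFactor),
      scalingSource = "user", globalSumMode = globalSumMode)
}

#' Export the derived weighting-factor table
#'
#' Writes a CSV mirroring the published parameter-table layout: stimulus,
#' activity, sign, significance, epsilon, cellular effort f(epsilon) and
#' theta (4 decimals).
#'
#' @param system A [PNSystem-class].
#' @param path output CSV path.
#' @return The exported data.frame, invisibly.
#' @export
exportThetaTable <- function(system, path) {
  stopifnot(is(system, "PNSystem"))
  df <- relationships(system, "all")
  df$submodel <- rep(c("pn", "inflammation"),
                     c(nrow(system@relationships), nrow(system@inflammation)))
  df$effort <- round(df$effort, 4)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(df)
}

#' Path to a shipped default parameter table
#'
#' @param name one of \code{"table1_pn"} (PN-system S-CA relationships),
#'   \code{"table3_inflammation"} (inflammation submodel) or
#'   \code{"anchors_default"} (dose-response anchor points).
#' @return File path inside the installed package.
#' @export
defaultTablePath <- function(name = c("table1_pn", "table3_inflammation",
                                      "anchors_default")) {
  name <- match.arg(name)
  p <- system.file("extdata", "tables", paste0(name, ".csv"),
                   package = "pnDisc", mustWork = TRUE)
  p
}

#' The calibrated default system
#'
#' Loads the shipped PN-system and inflammation relationship tables and
#' calibrates the weighting factors (scaling factor 28.7 attained by the
#' pH->MMP3 edge).
#'
#' @param globalSumMode see [calibrateSystem()].
#' @return A [PNSystem-class].
#' @export
defaultPNSystem <- function(globalSumMode = "unique_edges") {
  calibrateSystem(loadRelationshipTable(defaultTablePath("table1_pn")),
                  loadRelationshipTable(defaultTablePath("table3_inflammation")),
                  globalSumMode = globalSumMode)
}
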