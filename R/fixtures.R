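## Synthetic fixture generation: relationship tables with known
## ground-truth weighting factors and monotone anchor tables, so the whole
## calibration path is testable against values computed independently of
## the calibration code.

#' Generate synthetic relationship and anchor tables with known truth
#'
#' Draws synthetic S-CA edges over the real stimulus/activity vocabulary
#' with fold-changes in the requested ranges, and computes the expected
#' calibration result (effort, scaling factor, theta) by direct arithmetic
#' inside the generator: effort is \code{eps} or \code{1/eps}, the scaling
#' factor the maximal effort among significant edges, theta the rounded
#' floored ratio -- the same rules the calibration is specified to follow,
#' computed here without calling it. Anchor tables are monotone logistic
#' samples with optional noise (noise is projected back to a monotone
#' sequence so the tables always stay fit-consistent).
#'
#' @param nEdges number of PN-system edges to draw (1..20).
#' @param epsActivating range of fold-changes for activating edges (> 1).
#' @param epsInhibiting range of fold-changes for inhibiting edges (in
#'   (0, 1)).
#' @param pSignificant probability that an edge is significant.
#' @param nAnchors anchors per dose-response curve.
#' @param noise standard deviation of anchor noise (response units).
#' @param seed RNG seed; fixed seed gives identical tables.
#' @return List with \code{relationships} (columns of
#'   [loadRelationshipTable()] plus ground-truth \code{truthEffort},
#'   \code{truthTheta}), \code{scalingTruth}, and \code{anchors}.
#' @export
generateFixtureTables <- function(nEdges = 10L, epsActivating = c(1.5, 30),
                                  epsInhibiting = c(0.05, 0.9),
                                  pSignificant = 0.8, nAnchors = 5L,
                                  noise = 0, seed = 1L) {
  nEdges <- as.integer(nEdges)
  if (nEdges < 1L) stop("at least one edge must be requested", call. = FALSE)
  pairs <- expand.grid(stimulus = names(.STIMULI), activity = .PN_ACTIVITIES,
                       stringsAsFactors = FALSE)
  if (nEdges > nrow(pairs))
    stop("at most ", nrow(pairs), " unique PN-system edges exist", call. = FALSE)
  set.seed(seed)
  idx <- sample.int(nrow(pairs), nEdges)
  rel <- pairs[idx, ]
  rel$sign <- sample(c("activating", "inhibiting"), nEdges, replace = TRUE)
  ## guarantee the PN-system invariant of at least one activating edge
  rel$sign[1] <- "activating"
  rel$significant <- stats::runif(nEdges) < pSignificant
  if (!any(rel$significant)) rel$significant[1] <- TRUE
  rel$epsilon <- ifelse(rel$sign == "activating",
                        stats::runif(nEdges, epsActivating[1], epsActivating[2]),
                        stats::runif(nEdges, epsInhibiting[1], epsInhibiting[2]))
  rel$epsilon[!rel$significant] <- NA_real_
  ## ground truth by direct arithmetic (no calibration code involved)
  eps <- rel$epsilon
  truthEffort <- ifelse(rel$significant,
                        ifelse(eps >= 1, eps, 1 / eps), NA_real_)
  scalingTruth <- max(truthEffort, na.rm = TRUE)
  truthTheta <- ifelse(rel$significant,
                       pmax(round(truthEffort / scalingTruth, 4), 0.01),
                       0.01)
  rel$truthEffort <- truthEffort
  rel$truthTheta <- truthTheta
  rownames(rel) <- NULL

  ## monotone anchor tables for every nutrient edge drawn
  nut <- rel[rel$stimulus %in% c("glucose", "pH"), , drop = FALSE]
  anchors <- do.call(rbind, lapply(seq_len(nrow(nut)), function(i) {
    rng <- if (nut$stimulus[i] == "glucose") .GLUCOSE_RANGE else .PH_RANGE
    conc <- seq(rng[1], rng[2], length.out = nAnchors)
    mid <- stats::runif(1, rng[1] + 0.2 * diff(rng), rng[2] - 0.2 * diff(rng))
    k <- stats::runif(1, 4, 12) / diff(rng) *
      sample(c(-1, 1), 1)
    resp <- 1 / (1 + exp(-k * (conc - mid)))
    resp <- (resp - min(resp)) / (max(resp) - min(resp))
    if (noise > 0) {
      resp <- resp + stats::rnorm(nAnchors, 0, noise)
      resp <- pmin(pmax(resp, 0), 1)
      resp <- if (resp[nAnchors] >= resp[1]) cummax(resp) else cummin(resp)
    }
    data.frame(stimulus = nut$stimulus[i], activity = nut$activity[i],
               concentration = conc, normalized_response = resp)
  }))
  rownames(anchors) <- NULL
  list(relationships = rel, scalingTruth = scalingTruth, anchors = anchors)
}

#' Write fixture tables to CSV files
#'
#' Writes the relationship table (without the ground-truth columns, so the
#' file is a valid [loadRelationshipTable()] input) and the anchor table.
#' Deterministic per seed: identical arguments give byte-identical files.
#'
#' @param fixtures list from [generateFixtureTables()].
#' @param dir output directory.
#' @return Named character vector of the two file paths.
#' @export
writeFixtureTables <- function(fixtures, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  relPath <- file.path(dir, "fixture_relationships.csv")
  ancPath <- file.path(dir, "fixture_anchors.csv")
  rel <- fixtures$relationships[c("stimulus", "activity", "sign",
                                  "significant", "epsilon")]
  utils::write.csv(rel, relPath, row.names = FALSE, quote = FALSE, na = "")
  utils::write.csv(fixtures$anchors, ancPath, row.names = FALSE,
                   quote = FALSE)
  c(relationships = relPath, anchors = ancPath)
}
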