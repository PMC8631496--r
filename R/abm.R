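## 3D agent-based multicellular model: agent placement, nucleation,
## globally-shortest-distance cluster growth, state classification and
## replicate summaries.

#' ABMWorld: agents of a 1 mm^3 nucleus pulposus sub-volume
#'
#' @slot positions n x 3 matrix of agent centres in micrometres within
#'   \code{[0, domain]^3}.
#' @slot domain edge length of the cubic domain in micrometres (default
#'   1000, i.e. 1 mm^3).
#' @slot minDist minimal centre-to-centre distance (the 10 um cell
#'   diameter; agents must not overlap).
#' @slot seed RNG seed used to build the world.
#' @slot nucleation list with integer agent ids \code{IL1B} and
#'   \code{TNFA} used as cluster nucleation points.
#' @slot il1b,tnfa logical vectors: immunopositivity flags per agent.
#' @slot growthLog list of data.frames (\code{id}, \code{dist}) recording,
#'   per cytokine, each grown agent and the globally shortest distance at
#'   which it was added.
#' @export
setClass("ABMWorld", representation(
  positions = "matrix", domain = "numeric", minDist = "numeric",
  seed = "integer", nucleation = "list",
  il1b = "logical", tnfa = "logical", growthLog = "list"
))

setValidity("ABMWorld", function(object) {
  msg <- character()
  p <- object@positions
  if (ncol(p) != 3L) msg <- c(msg, "positions must be an n x 3 matrix")
  if (any(p < 0 | p > object@domain))
    msg <- c(msg, "agent positions must lie inside the domain")
  n <- nrow(p)
  if (length(object@il1b) != n || length(object@tnfa) != n)
    msg <- c(msg, "immunopositivity flags must have one entry per agent")
  if (length(msg)) msg else TRUE
})

#' @describeIn ABMWorld-class summary of agents and flags
#' @param object An \code{ABMWorld}.
#' @export
setMethod("show", "ABMWorld", function(object) {
  n <- nrow(object@positions)
  cat(sprintf("ABMWorld: %d agents in [0, %g]^3 um (min distance %g um)\n",
              n, object@domain, object@minDist))
  cat(sprintf("  IL1B+ %d, TNFA+ %d, double %d\n",
              sum(object@il1b), sum(object@tnfa),
              sum(object@il1b & object@tnfa)))
})

#' Number of agents in a world
#' @param object An [ABMWorld-class].
#' @return Integer count.
#' @export
nAgents <- function(object) nrow(object@positions)

#' Agent positions
#' @param object An [ABMWorld-class].
#' @return n x 3 numeric matrix (micrometres).
#' @export
agentPositions <- function(object) object@positions

## pairs (i < j) of agents closer than minDist, decoded straight from the
## packed dist vector (pair (i, j) sits at k = f(i) + j - i with
## f(i) = (i-1)(2n-i)/2 pairs having first index < i)
.closePairs <- function(pos, minDist) {
  n <- nrow(pos)
  k <- which(stats::dist(pos) < minDist)
  if (length(k) == 0L) return(cbind(i = integer(), j = integer()))
  f <- cumsum(c(0, (n - 1):1))[seq_len(n)]
  i <- findInterval(k - 0.5, f)
  j <- k - f[i] + i
  cbind(i = i, j = j)
}

#' Place non-overlapping agents uniformly in a cubic domain
#'
#' Samples uniform random positions and resamples colliding agents until
#' all centre-to-centre distances are at least \code{minDist} (the cell
#' diameter). At the default density (4,000 cells of 10 um in 1 mm^3 the
#' cells occupy well under 1\% of the volume) only a handful of repair
#' rounds are needed. Deterministic for a fixed seed.
#'
#' @param n number of agents (default 4000).
#' @param domain cube edge length in micrometres (default 1000).
#' @param minDist minimal centre distance in micrometres (default 10).
#' @param seed integer RNG seed.
#' @param maxRounds bound on resampling rounds before giving up.
#' @return An [ABMWorld-class] with no immunopositive agents yet.
#' @export
placeAgents <- function(n = 4000, domain = 1000, minDist = 10, seed = 1L,
                        maxRounds = 200L) {
  stopifnot(n >= 1, domain > 0, minDist >= 0)
  ## quick density sanity check: sphere packing must be loose
  if (n * (4 / 3) * pi * (minDist / 2)^3 > 0.2 * domain^3)
    stop("requested density too high for rejection placement", call. = FALSE)
  set.seed(seed)
  pos <- matrix(stats::runif(3 * n, 0, domain), n, 3)
  round <- 0L
  repeat {
    bad <- unique(.closePairs(pos, minDist)[, "j"])
    if (length(bad) == 0L) break
    round <- round + 1L
    if (round > maxRounds)
      stop("could not place agents without overlap after ", maxRounds,
           " rounds", call. = FALSE)
    pos[bad, ] <- stats::runif(3 * length(bad), 0, domain)
  }
  colnames(pos) <- c("x", "y", "z")
  new("ABMWorld", positions = pos, domain = domain, minDist = minDist,
      seed = as.integer(seed), nucleation = list(),
      il1b = logical(n), tnfa = logical(n),
      growthLog = list(IL1B = data.frame(id = integer(), dist = numeric()),
                       TNFA = data.frame(id = integer(), dist = numeric())))
}

#' Select nucleation points for the immunopositive clusters
#'
#' Randomly selects disjoint agents as nucleation points (default 30 of
#' 4,000: 15 IL1B and 15 TNF-a clusters) and marks them immunopositive.
#' Uses the current RNG stream, so calling directly after [placeAgents()]
#' keeps the whole world a deterministic function of the placement seed.
#'
#' @param world An [ABMWorld-class].
#' @param nIl1b,nTnfa number of nucleation points per cytokine.
#' @return The world with nucleation ids stored and flags set.
#' @export
seedNucleation <- function(world, nIl1b = 15L, nTnfa = 15L) {
  stopifnot(is(world, "ABMWorld"))
  n <- nAgents(world)
  if (nIl1b + nTnfa > n)
    stop("more nucleation points than agents", call. = FALSE)
  ids <- sample.int(n, nIl1b + nTnfa)
  world@nucleation <- list(IL1B = sort(ids[seq_len(nIl1b)]),
                           TNFA = sort(ids[nIl1b + seq_len(nTnfa)]))
  world@il1b[world@nucleation$IL1B] <- TRUE
  world@tnfa[world@nucleation$TNFA] <- TRUE
  world
}

#' Grow an immunopositive cluster set to a target size
#'
#' Iteratively marks the not-yet-positive agent with the globally shortest
#' Euclidean distance to any already-positive agent (for this cytokine),
#' until exactly \code{target} agents carry the flag. Ties are broken by
#' the lowest agent id. Growth per cytokine is independent: an agent may
#' acquire both flags, which later classifies it as double positive.
#'
#' @param world An [ABMWorld-class] with nucleation already seeded.
#' @param cytokine \code{"IL1B"} or \code{"TNFA"}.
#' @param target total number of positive agents wanted (must be at least
#'   the number of nucleation points and at most the number of agents).
#' @return The world with updated flags and growth log.
#' @export
growClusters <- function(world, cytokine = c("IL1B", "TNFA"), target) {
  stopifnot(is(world, "ABMWorld"))
  cytokine <- match.arg(cytokine)
  n <- nAgents(world)
  target <- as.integer(target)
  if (target > n)
    stop("target exceeds the number of agents", call. = FALSE)
  marked <- if (cytokine == "IL1B") world@il1b else world@tnfa
  if (!any(marked))
    stop("no nucleation points for ", cytokine,
         "; call seedNucleation() first", call. = FALSE)
  if (target < sum(marked))
    stop("target smaller than the current positive count", call. = FALSE)
  pos <- world@positions
  ## dmin[i]: distance from unmarked agent i to the nearest marked agent
  dmin <- rep(Inf, n)
  um <- which(!marked)
  for (j in which(marked)) {
    dj <- sqrt((pos[um, 1] - pos[j, 1])^2 + (pos[um, 2] - pos[j, 2])^2 +
                 (pos[um, 3] - pos[j, 3])^2)
    dmin[um] <- pmin(dmin[um], dj)
  }
  nGrow <- target - sum(marked)
  addId <- integer(nGrow); addDist <- numeric(nGrow)
  for (g in seq_len(nGrow)) {
    j <- which.min(dmin)              # lowest id on ties
    addId[g] <- j; addDist[g] <- dmin[j]
    marked[j] <- TRUE
    dmin[j] <- Inf
    um <- which(!marked)
    dj <- sqrt((pos[um, 1] - pos[j, 1])^2 + (pos[um, 2] - pos[j, 2])^2 +
                 (pos[um, 3] - pos[j, 3])^2)
    dmin[um] <- pmin(dmin[um], dj)
  }
  if (cytokine == "IL1B") world@il1b <- marked else world@tnfa <- marked
  world@growthLog[[cytokine]] <- rbind(world@growthLog[[cytokine]],
                                       data.frame(id = addId, dist = addDist))
  world
}

#' Classify agents into the four pro-inflammatory cell states
#'
#' @param world An [ABMWorld-class] after both growth passes.
#' @return One-row data.frame with counts (\code{n}, \code{nIl1bOnly},
#'   \code{nTnfaOnly}, \code{nDouble}, \code{nNoninflamed}, plus the
#'   per-cytokine totals) and the corresponding percentages.
#' @export
classifyStates <- function(world) {
  stopifnot(is(world, "ABMWorld"))
  n <- nAgents(world)
  double <- world@il1b & world@tnfa
  df <- data.frame(
    n = n,
    nIl1bOnly = sum(world@il1b & !world@tnfa),
    nTnfaOnly = sum(world@tnfa & !world@il1b),
    nDouble = sum(double),
    nNoninflamed = sum(!world@il1b & !world@tnfa),
    nIl1bTotal = sum(world@il1b),
    nTnfaTotal = sum(world@tnfa)
  )
  df$pctIl1bOnly <- 100 * df$nIl1bOnly / n
  df$pctTnfaOnly <- 100 * df$nTnfaOnly / n
  df$pctDouble <- 100 * df$nDouble / n
  df$pctIl1bTotal <- 100 * df$nIl1bTotal / n
  df$pctTnfaTotal <- 100 * df$nTnfaTotal / n
  df
}

#' One complete agent-based run
#'
#' Places agents, seeds nucleation points, grows both cytokine cluster
#' sets to \code{round(pct/100 * n)} agents and classifies the outcome.
#'
#' @param pctIl1b,pctTnfa target percentages of immunopositive cells
#'   (from [inflammationState()]).
#' @param n number of agents (default 4000).
#' @param domain cube edge (um).
#' @param minDist minimal centre distance (um).
#' @param nIl1b,nTnfa nucleation points per cytokine (default 15 each).
#' @param seed RNG seed for this run.
#' @return List with the final \code{world} ([ABMWorld-class]) and its
#'   \code{summary} row (see [classifyStates()]).
#' @export
runABM <- function(pctIl1b, pctTnfa, n = 4000, domain = 1000, minDist = 10,
                   nIl1b = 15L, nTnfa = 15L, seed = 1L) {
  world <- placeAgents(n = n, domain = domain, minDist = minDist, seed = seed)
  world <- seedNucleation(world, nIl1b = nIl1b, nTnfa = nTnfa)
  world <- growClusters(world, "IL1B", target = round(pctIl1b / 100 * n))
  world <- growClusters(world, "TNFA", target = round(pctTnfa / 100 * n))
  s <- classifyStates(world)
  s$seed <- seed
  list(world = world, summary = s)
}

#' Replicate agent-based runs
#'
#' Runs [runABM()] with seeds \code{baseSeed .. baseSeed + nRuns - 1}. The
#' per-cytokine totals are deterministic given the percentages; the double
#' positive count varies with the random geometry.
#'
#' @inheritParams runABM
#' @param nRuns number of replicate runs (default 10).
#' @param baseSeed seed of the first run.
#' @param keepWorlds keep the full worlds (default FALSE, summaries only).
#' @return data.frame with one summary row per run; when
#'   \code{keepWorlds = TRUE} the worlds are attached as attribute
#'   \code{"worlds"}.
#' @export
replicateRuns <- function(pctIl1b, pctTnfa, n = 4000, nRuns = 10L,
                          baseSeed = 1L, domain = 1000, minDist = 10,
                          nIl1b = 15L, nTnfa = 15L, keepWorlds = FALSE) {
  seeds <- as.integer(baseSeed) + seq_len(nRuns) - 1L
  worlds <- vector("list", nRuns)
  rows <- lapply(seq_along(seeds), function(i) {
    r <- runABM(pctIl1b, pctTnfa, n = n, domain = domain, minDist = minDist,
                nIl1b = nIl1b, nTnfa = nTnfa, seed = seeds[i])
    if (keepWorlds) worlds[[i]] <<- r$world
    r$summary
  })
  out <- do.call(rbind, rows)
  if (keepWorlds) attr(out, "worlds") <- worlds
  out
}

#' Descriptive statistics over replicate runs
#'
#' Mean, standard deviation and t-based 95\% confidence interval per
#' summary column across runs. With a single run the CI is undefined and
#' reported as NA (with a warning).
#'
#' @param runs data.frame from [replicateRuns()].
#' @param level confidence level (default 0.95).
#' @return data.frame with one row per summarized quantity.
#' @export
summarizeReplicates <- function(runs, level = 0.95) {
  stopifnot(is.data.frame(runs), nrow(runs) >= 1L)
  cols <- setdiff(names(runs), "seed")
  nr <- nrow(runs)
  if (nr < 2L)
    warning("fewer than 2 runs: confidence intervals are undefined",
            call. = FALSE)
  rows <- lapply(cols, function(cl) {
    v <- runs[[cl]]
    m <- mean(v)
    s <- if (nr >= 2L) stats::sd(v) else NA_real_
    half <- if (nr >= 2L)
      stats::qt(1 - (1 - level) / 2, df = nr - 1L) * s / sqrt(nr)
    else NA_real_
    data.frame(quantity = cl, mean = m, sd = s,
               ciLow = m - half, ciHigh = m + half, nRuns = nr)
  })
  do.call(rbind, rows)
}

#' Snapshot of an agent world as a plain table
#'
#' @param world An [ABMWorld-class].
#' @return data.frame with columns \code{id}, \code{x_um}, \code{y_um},
#'   \code{z_um}, \code{il1b}, \code{tnfa}, \code{state}.
#' @export
worldSnapshot <- function(world) {
  stopifnot(is(world, "ABMWorld"))
  p <- world@positions
  state <- ifelse(world@il1b & world@tnfa, "IL1B_TNFA_pos",
           ifelse(world@il1b, "IL1B_pos",
           ifelse(world@tnfa, "TNFA_pos", "noninflamed")))
  data.frame(id = seq_len(nrow(p)), x_um = p[, 1], y_um = p[, 2],
             z_um = p[, 3], il1b = world@il1b, tnfa = world@tnfa,
             state = state)
}

#' Plot an agent world (2D projection)
#'
#' Simple x/y projection of the 3D world, colour-coded by state: red IL1B
#' positive, purple TNF-a positive, green double positive, grey
#' non-inflamed.
#'
#' @param world An [ABMWorld-class].
#' @param file optional PNG output path; when NULL plots to the active
#'   device.
#' @return Invisibly, the snapshot data.frame used for plotting.
#' @export
plotWorld <- function(world, file = NULL) {
  snap <- worldSnapshot(world)
  cols <- c(noninflamed = "grey80", IL1B_pos = "red2",
            TNFA_pos = "purple3", IL1B_TNFA_pos = "green3")
  if (!is.null(file)) grDevices::png(file, width = 800, height = 800)
  graphics::plot(snap$x_um, snap$y_um, col = cols[snap$state], pch = 19,
                 cex = 0.4, xlab = "x [um]", ylab = "y [um]",
                 main = "Immunopositive cell clusters (x/y projection)")
  graphics::legend("topright", legend = names(cols), col = cols, pch = 19,
                   cex = 0.8)
  if (!is.null(file)) grDevices::dev.off()
  invisible(snap)
}
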