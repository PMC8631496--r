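# Independent oracles used across the suite. These are deliberately naive
# transcriptions (scalar loops, brute-force scans) that share no code with
# the package internals.

# Literal transcription of the parallel-networks activation equation.
# edges: data.frame(stimulus, activity, sign, theta) for the whole system.
oracle_pn <- function(edges, activity, state_stimuli, x,
                      mode = "unique_edges") {
  all_states <- list(c("glucose", "pH"),
                     c("glucose", "pH", "IL1B"),
                     c("glucose", "pH", "TNFA"),
                     c("glucose", "pH", "IL1B", "TNFA"))
  mult <- function(s) {
    m <- 0
    for (a in all_states) if (s %in% a) m <- m + 1
    m
  }
  sum_alpha <- 0
  sum_beta_ca <- 0
  for (r in seq_len(nrow(edges))) {
    w <- if (mode == "per_state_repeats") mult(edges$stimulus[r]) else 1
    if (edges$sign[r] == "activating")
      sum_alpha <- sum_alpha + w * edges$theta[r]
    else if (edges$activity[r] == activity)
      sum_beta_ca <- sum_beta_ca + w * edges$theta[r]
  }
  th_a <- th_b <- s_a <- s_b <- 0
  any_act <- FALSE
  for (r in seq_len(nrow(edges))) {
    if (edges$activity[r] != activity) next
    if (!(edges$stimulus[r] %in% state_stimuli)) next
    th <- edges$theta[r]
    xv <- x[[edges$stimulus[r]]]
    if (edges$sign[r] == "activating") {
      any_act <- TRUE
      th_a <- th_a + th
      s_a <- s_a + th * xv
    } else {
      th_b <- th_b + th
      s_b <- s_b + th * xv
    }
  }
  if (!any_act) return(0)
  A <- ((1 + sum_alpha) / sum_alpha) * (s_a / (1 + s_a))
  B <- 0
  if (th_b > 0 && sum_beta_ca > 0)
    B <- (th_b / (th_a + th_b)) * ((1 + sum_beta_ca) / sum_beta_ca) *
      (s_b / (1 + s_b))
  min(max(A * (1 - B), 0), 1)
}

# Random small network (1-4 unique edges, at least one activating) with
# pre-set weighting factors, as a raw data.frame.
random_small_network <- function() {
  pairs <- expand.grid(stimulus = c("glucose", "pH", "IL1B", "TNFA"),
                       activity = c("Agg", "ColI", "ColII", "MMP3", "ADAMTS4"),
                       stringsAsFactors = FALSE)
  nE <- sample(1:4, 1)
  rel <- pairs[sample(nrow(pairs), nE), , drop = FALSE]
  rel$sign <- sample(c("activating", "inhibiting"), nE, replace = TRUE)
  rel$sign[sample.int(nE, 1)] <- "activating"
  rel$significant <- TRUE
  rel$epsilon <- NA_real_
  rel$theta <- round(runif(nE, 0.01, 1), 4)
  rownames(rel) <- NULL
  rel
}

# Brute-force globally-nearest-neighbour cluster growth: at every step
# rescan all unmarked agents against all marked agents.
brute_growth <- function(pos, seed_ids, target) {
  n <- nrow(pos)
  marked <- rep(FALSE, n)
  marked[seed_ids] <- TRUE
  ids <- integer(0)
  dists <- numeric(0)
  while (sum(marked) < target) {
    best_d <- Inf
    best_i <- NA_integer_
    for (i in which(!marked)) {
      mi <- which(marked)
      di <- Inf
      for (j in mi) {
        dj <- sqrt(sum((pos[i, ] - pos[j, ])^2))
        if (dj < di) di <- dj
      }
      if (di < best_d) {           # strict: first (lowest id) wins ties
        best_d <- di
        best_i <- i
      }
    }
    marked[best_i] <- TRUE
    ids <- c(ids, best_i)
    dists <- c(dists, best_d)
  }
  list(ids = ids, dists = dists, marked = which(marked))
}

# Build a tiny calibrated system around the default tables without
# touching package internals.
default_system_cached <- local({
  sys <- NULL
  function() {
    if (is.null(sys)) sys <<- defaultPNSystem()
    sys
  }
})

default_curves_cached <- function() defaultCurves()
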