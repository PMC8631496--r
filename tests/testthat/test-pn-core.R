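test_that("PN equation saturates and vanishes at its trivial limits", {
  sys <- default_system_cached()
  # all sensitivities zero -> no activation at all
  x0 <- c(glucose = 0, pH = 0, IL1B = 0, TNFA = 0)
  for (ac in pnActivities())
    expect_identical(pnEvaluate(sys, ac, "IL1B_TNFA_pos", x0), 0)

  # single activating edge carrying the full system weight saturates at 1
  single <- makePNSystem(data.frame(
    stimulus = "pH", activity = "MMP3", sign = "activating",
    significant = TRUE, epsilon = NA_real_, theta = 1))
  expect_identical(pnEvaluate(single, "MMP3", "noninflamed", c(pH = 1)), 1)
})

test_that("PN evaluation matches an independent transcription of the equation", {
  sys <- default_system_cached()
  edges <- relationships(sys)[c("stimulus", "activity", "sign", "theta")]
  # hand-picked corner: optimal glucose, fully acidic insensitivity
  x <- c(glucose = 1, pH = 0)
  expect_equal(pnEvaluate(sys, "Agg", "noninflamed", x, rounded = FALSE),
               oracle_pn(edges, "Agg", c("glucose", "pH"), as.list(x)),
               tolerance = 1e-14)

  # randomized small networks, both global-sum conventions
  set.seed(42)
  for (mode in c("unique_edges", "per_state_repeats")) {
    for (rep in 1:150) {
      rel <- random_small_network()
      s <- makePNSystem(rel, globalSumMode = mode)
      st <- sample(cellStates(), 1)
      ac <- sample(unique(rel$activity), 1)
      x <- runif(4)
      names(x) <- c("glucose", "pH", "IL1B", "TNFA")
      got <- suppressWarnings(
        pnEvaluate(s, ac, st, x, rounded = FALSE))
      want <- oracle_pn(rel, ac, activeStimuli(st), as.list(x), mode = mode)
      expect_equal(got, want, tolerance = 1e-12)
      expect_true(got >= 0 && got <= 1)
    }
  }
})

test_that("PN activity is monotone in the stimulus sensitivities", {
  set.seed(7)
  for (rep in 1:40) {
    rel <- random_small_network()
    s <- makePNSystem(rel)
    ac <- sample(unique(rel$activity), 1)
    st <- "IL1B_TNFA_pos"                 # all stimuli active
    x <- runif(4); names(x) <- c("glucose", "pH", "IL1B", "TNFA")
    base <- suppressWarnings(pnEvaluate(s, ac, st, x, rounded = FALSE))
    for (i in seq_len(nrow(rel))) {
      if (rel$activity[i] != ac) next
      x2 <- x
      x2[rel$stimulus[i]] <- min(1, x[rel$stimulus[i]] + 0.2)
      v <- suppressWarnings(pnEvaluate(s, ac, st, x2, rounded = FALSE))
      if (rel$sign[i] == "activating") expect_gte(v, base - 1e-12)
      else expect_lte(v, base + 1e-12)
    }
  }
})

test_that("invariant 0.01 weighting approximates a linear coupling", {
  single <- makePNSystem(data.frame(
    stimulus = "pH", activity = "Agg", sign = "activating",
    significant = TRUE, epsilon = NA_real_, theta = 0.01))
  xs <- seq(0, 1, by = 0.05)
  om <- vapply(xs, function(v)
    pnEvaluate(single, "Agg", "noninflamed", c(pH = v), rounded = FALSE),
    numeric(1))
  # deviation from the straight line through the endpoints stays tiny
  line <- om[length(om)] * xs
  expect_lt(max(abs(om - line)), 0.005)
})

test_that("degenerate networks are handled totally", {
  sys <- default_system_cached()
  # a network without activating edges yields 0 with a warning
  inhOnly <- makePNSystem(data.frame(
    stimulus = c("pH", "TNFA"), activity = c("MMP3", "Agg"),
    sign = c("activating", "inhibiting"), significant = TRUE,
    epsilon = NA_real_, theta = c(0.5, 0.3)))
  expect_warning(v <- pnEvaluate(inhOnly, "Agg", "TNFA_pos", c(TNFA = 1)),
                 "no activating")
  expect_identical(v, 0)
  # missing x coverage is a configuration error naming the edge
  expect_error(pnEvaluate(sys, "Agg", "noninflamed", c(glucose = 1)),
               "pH->Agg")
})

test_that("profiles cover 4 states x 5 activities and honor theta mode", {
  sys <- default_system_cached()
  curves <- default_curves_cached()
  env <- nutrientPreset("optimal")
  prof <- profileAll(sys, env, curves, cytokineXValues = c(IL1B = .5, TNFA = .5))
  expect_identical(nrow(prof), 20L)
  expect_setequal(unique(prof$cell_state), cellStates())
  expect_setequal(unique(prof$activity), pnActivities())
  expect_true(all(prof$omega >= 0 & prof$omega <= 1))

  inv <- profileAll(sys, env, curves, cytokineXValues = c(IL1B = .5, TNFA = .5),
                    thetaMode = "invariant_0.01")
  expect_identical(unique(inv$theta_mode), "invariant_0.01")
  # with every theta at 0.01 the same x-inputs give state-similar profiles
  spread <- function(p) max(tapply(p$omega, p$activity,
                                   function(v) diff(range(v))))
  expect_lt(spread(inv), spread(prof))

  # missing curve coverage is reported with the edge name
  expect_error(profileAll(sys, env, curves[-1],
                          cytokineXValues = c(IL1B = 0, TNFA = 0)),
               "glucose:")
})
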