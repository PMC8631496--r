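test_that("agent placement is uniform, non-overlapping and deterministic", {
  w1 <- placeAgents(400, seed = 42)
  w2 <- placeAgents(400, seed = 42)
  expect_identical(agentPositions(w1), agentPositions(w2))
  expect_false(identical(agentPositions(w1),
                         agentPositions(placeAgents(400, seed = 43))))
  # exhaustive pair scan: no two centres closer than the cell diameter
  expect_gte(min(dist(agentPositions(w1))), 10)
  expect_true(all(agentPositions(w1) >= 0 & agentPositions(w1) <= 1000))
  expect_error(placeAgents(4000, domain = 40), "density")
})

test_that("nucleation marks disjoint seed sets per cytokine", {
  w <- placeAgents(400, seed = 1)
  w <- seedNucleation(w, 3, 3)
  expect_length(w@nucleation$IL1B, 3L)
  expect_length(w@nucleation$TNFA, 3L)
  expect_length(intersect(w@nucleation$IL1B, w@nucleation$TNFA), 0L)
  expect_identical(which(w@il1b), w@nucleation$IL1B)
  expect_error(growClusters(placeAgents(50, seed = 1), "IL1B", 10),
               "nucleation")
})

test_that("cluster growth follows the globally shortest distance rule", {
  w <- placeAgents(400, seed = 5)
  w <- seedNucleation(w, 3, 3)

  # target equal to the seed count: no growth at all
  w0 <- growClusters(w, "IL1B", 3)
  expect_identical(which(w0@il1b), w@nucleation$IL1B)
  expect_identical(nrow(w0@growthLog$IL1B), 0L)

  # one growth step adds the global nearest neighbour of the seed set
  w1 <- growClusters(w, "IL1B", 4)
  added <- setdiff(which(w1@il1b), w@nucleation$IL1B)
  pos <- agentPositions(w)
  ref <- brute_growth(pos, w@nucleation$IL1B, 4)
  expect_identical(added, ref$ids)
  expect_equal(w1@growthLog$IL1B$dist, ref$dists)

  # full growth reproduces the brute-force oracle, per step and as a set
  target <- 60L
  wg <- growClusters(w, "IL1B", target)
  refg <- brute_growth(pos, w@nucleation$IL1B, target)
  expect_identical(wg@growthLog$IL1B$id, refg$ids)
  expect_equal(wg@growthLog$IL1B$dist, refg$dists)
  expect_identical(which(wg@il1b), refg$marked)

  expect_error(growClusters(w, "IL1B", 401), "exceeds")
  expect_error(growClusters(w1, "IL1B", 2), "smaller")
})

test_that("state classification partitions all agents and conserves targets", {
  pctI <- 16; pctT <- 12; n <- 400
  r <- runABM(pctI, pctT, n = n, nIl1b = 3, nTnfa = 3, seed = 9)
  s <- r$summary
  expect_identical(s$nIl1bTotal, as.integer(round(pctI / 100 * n)))
  expect_identical(s$nTnfaTotal, as.integer(round(pctT / 100 * n)))
  expect_identical(s$nIl1bOnly + s$nTnfaOnly + s$nDouble + s$nNoninflamed,
                   s$n)
  expect_identical(s$nIl1bOnly + s$nDouble, s$nIl1bTotal)
  expect_identical(s$nTnfaOnly + s$nDouble, s$nTnfaTotal)

  # identical seed sets grown to identical targets overlap fully
  w <- placeAgents(200, seed = 2)
  ids <- sample(200, 3)
  w@nucleation <- list(IL1B = sort(ids), TNFA = sort(ids))
  w@il1b[ids] <- TRUE
  w@tnfa[ids] <- TRUE
  w <- growClusters(w, "IL1B", 40)
  w <- growClusters(w, "TNFA", 40)
  expect_identical(classifyStates(w)$nDouble, 40L)

  # disjoint far-apart clusters have no double positives: grow nothing
  w2 <- placeAgents(100, seed = 3)
  w2 <- seedNucleation(w2, 2, 2)
  w2 <- growClusters(w2, "IL1B", 2)
  w2 <- growClusters(w2, "TNFA", 2)
  expect_identical(classifyStates(w2)$nDouble, 0L)
})

test_that("replicate runs are seed-deterministic with fixed per-run totals", {
  runs <- replicateRuns(16, 12, n = 400, nRuns = 4, baseSeed = 21,
                        nIl1b = 3, nTnfa = 3)
  expect_identical(nrow(runs), 4L)
  expect_identical(unique(runs$nIl1bTotal), 64L)
  expect_identical(unique(runs$nTnfaTotal), 48L)
  expect_identical(runs$seed, 21:24)
  again <- replicateRuns(16, 12, n = 400, nRuns = 4, baseSeed = 21,
                         nIl1b = 3, nTnfa = 3)
  expect_identical(runs, again)

  s <- summarizeReplicates(runs)
  expect_true(all(c("mean", "sd", "ciLow", "ciHigh") %in% names(s)))
  # independent textbook t-interval on the same values
  v <- runs$nDouble
  half <- qt(0.975, df = 3) * sd(v) / sqrt(4)
  row <- s[s$quantity == "nDouble", ]
  expect_equal(row$mean, mean(v))
  expect_equal(row$ciLow, mean(v) - half)
  expect_equal(row$ciHigh, mean(v) + half)

  # identical replicates give a zero-width interval
  twin <- rbind(runs[1, ], runs[1, ])
  s2 <- summarizeReplicates(twin)
  expect_equal(s2$ciLow, s2$ciHigh)
  expect_warning(summarizeReplicates(runs[1, ]), "fewer than 2")
})

test_that("world snapshots expose positions and the four states", {
  r <- runABM(16, 12, n = 200, nIl1b = 3, nTnfa = 3, seed = 4)
  snap <- worldSnapshot(r$world)
  expect_identical(nrow(snap), 200L)
  expect_true(all(snap$state %in% c("noninflamed", "IL1B_pos", "TNFA_pos",
                                    "IL1B_TNFA_pos")))
  expect_identical(sum(snap$state == "IL1B_TNFA_pos"),
                   r$summary$nDouble)
  f <- withr::local_tempfile(fileext = ".png")
  plotWorld(r$world, file = f)
  expect_true(file.exists(f))
})
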