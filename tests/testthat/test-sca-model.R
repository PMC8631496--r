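test_that("cellular effort is the reciprocal-symmetric fold-change magnitude", {
  expect_equal(round(cellularEffort(0.06), 4), 16.6667)
  expect_equal(cellularEffort(1), 1)
  expect_equal(round(cellularEffort(0.37), 4), 2.7027)
  expect_equal(cellularEffort(c(2, 0.5)), c(2, 2))

  # symmetry f(eps) == f(1/eps) and f >= 1 over random fold-changes
  set.seed(11)
  eps <- exp(runif(200, -4, 4))
  expect_equal(cellularEffort(eps), cellularEffort(1 / eps))
  expect_true(all(cellularEffort(eps) >= 1))

  expect_error(cellularEffort(0), "positive")
  expect_error(cellularEffort(-2), "positive")
  expect_error(cellularEffort(NA_real_), "positive")
})

test_that("scaling factor is the maximal effort among significant edges", {
  pn <- loadRelationshipTable(defaultTablePath("table1_pn"))
  s <- deriveScalingFactor(pn)
  expect_equal(as.numeric(s), 28.7)
  expect_equal(attr(s, "source"), "pH->MMP3")

  # TNFA->MMP3 (effort 26.85) is present but does not attain the maximum
  expect_true(any(pn$stimulus == "TNFA" & pn$activity == "MMP3"))
  expect_gt(as.numeric(s), cellularEffort(26.85) - 1e-9)

  single <- data.frame(stimulus = "pH", activity = "Agg", sign = "activating",
                       significant = TRUE, epsilon = 2)
  s1 <- deriveScalingFactor(single)
  expect_equal(as.numeric(s1), 2)
  expect_equal(deriveTheta(single, s1)$theta, 1)

  ns <- data.frame(stimulus = "pH", activity = "Agg", sign = "activating",
                   significant = FALSE, epsilon = NA_real_)
  expect_error(deriveScalingFactor(ns), "no significant")
})

test_that("theta derivation reproduces the published weighting factors", {
  sys <- default_system_cached()
  rel <- relationships(sys)

  th <- function(st, ac) rel$theta[rel$stimulus == st & rel$activity == ac]
  expect_identical(th("TNFA", "MMP3"), 0.9355)
  expect_identical(th("glucose", "Agg"), 0.01)     # non-significant floor
  expect_identical(th("pH", "Agg"), 0.0942)
  expect_identical(th("pH", "ColII"), 0.0553)
  expect_identical(th("pH", "MMP3"), 1)
  expect_identical(th("pH", "ADAMTS4"), 0.1986)
  expect_identical(th("IL1B", "Agg"), 0.0774)
  expect_identical(th("IL1B", "MMP3"), 0.3763)
  expect_identical(th("TNFA", "ColI"), 0.1124)
  expect_identical(th("TNFA", "ColII"), 0.5807)
  expect_identical(th("TNFA", "ADAMTS4"), 0.201)

  # inflammation submodel reuses the PN scaling and may exceed 1
  infl <- relationships(sys, "inflammation")
  expect_identical(infl$theta[infl$stimulus == "pH" &
                              infl$activity == "IL1B_mRNA"], 2.8223)
  expect_true(all(infl$theta[!infl$significant] == 0.01))

  # exactly one PN-system edge attains theta = 1
  expect_identical(sum(rel$theta == 1), 1L)
  # theta is monotone non-decreasing in effort at fixed scaling
  sig <- rel[rel$significant, ]
  o <- order(sig$effort)
  expect_true(all(diff(sig$theta[o]) >= 0))

  expect_error(deriveTheta(rel, -1), "positive")
})

test_that("relationship tables are parsed and validated", {
  pn <- loadRelationshipTable(defaultTablePath("table1_pn"))
  infl <- loadRelationshipTable(defaultTablePath("table3_inflammation"))
  expect_identical(nrow(pn), 20L)
  expect_identical(nrow(infl), 4L)
  expect_true(all(pn$epsilon[pn$significant] > 0))

  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines("stimulus,activity,sign,significant,epsilon", tmp)
  expect_error(loadRelationshipTable(tmp), "no relationships")

  writeLines(c("stimulus,activity,sign,significant,epsilon",
               "pH,Agg,activating,TRUE,0"), tmp)
  expect_error(loadRelationshipTable(tmp), "positive epsilon")

  writeLines(c("stimulus,activity,sign,significant,epsilon",
               "lactate,Agg,activating,TRUE,2"), tmp)
  expect_error(loadRelationshipTable(tmp), "unknown stimulus")

  writeLines(c("stimulus,activity,sign,significant,epsilon",
               "pH,Agg,up,TRUE,2"), tmp)
  expect_error(loadRelationshipTable(tmp), "sign")
})

test_that("calibrated systems respect structural invariants", {
  sys <- default_system_cached()
  rel <- relationships(sys)
  expect_true(all(rel$theta >= 0.01 & rel$theta <= 1))
  expect_false(anyDuplicated(rel[c("stimulus", "activity")]) > 0)
  expect_true(any(rel$sign == "activating"))
  # round-trip through the export format
  tmp <- withr::local_tempfile(fileext = ".csv")
  out <- exportThetaTable(sys, tmp)
  back <- read.csv(tmp)
  expect_equal(back$theta, out$theta)
  expect_equal(back$stimulus, out$stimulus)
})
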