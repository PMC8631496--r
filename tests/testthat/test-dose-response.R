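test_that("fitted curves hit the range endpoints and follow anchor direction", {
  up <- fitCurve(data.frame(concentration = c(0, 5),
                            normalized_response = c(0, 1)),
                 range = c(0, 5), stimulus = "glucose", activity = "Agg")
  expect_equal(evalCurve(up, 0), 0)
  expect_equal(evalCurve(up, 5), 1)
  expect_identical(up@direction, "increasing")

  dn <- fitCurve(data.frame(concentration = c(6.5, 7.4),
                            normalized_response = c(1, 0)),
                 range = c(6.5, 7.4), stimulus = "pH", activity = "MMP3")
  expect_identical(dn@direction, "decreasing")
  expect_equal(evalCurve(dn, 6.5), 1)
  expect_equal(evalCurve(dn, 7.4), 0)
})

test_that("all shipped curves are bounded, monotone and close to their anchors", {
  curves <- default_curves_cached()
  expect_length(curves, 14L)
  for (crv in curves) {
    grid <- seq(crv@range[1], crv@range[2], length.out = 1000)
    x <- evalCurve(crv, grid, rounded = FALSE)
    expect_true(all(x >= 0 & x <= 1))
    d <- diff(x)
    sgn <- if (crv@direction == "increasing") 1 else -1
    expect_true(all(sgn * d >= -1e-12))
    # fit tolerance at the anchor concentrations
    fit <- evalCurve(crv, crv@anchors$concentration, rounded = FALSE)
    expect_lt(max(abs(fit - crv@anchors$normalized_response)), 0.05)
  }
})

test_that("refitting identical anchors is deterministic", {
  a <- data.frame(concentration = c(0, 0.5, 1, 5),
                  normalized_response = c(0, 0.7, 0.9, 1))
  c1 <- fitCurve(a, c(0, 5), "glucose", "Agg")
  c2 <- fitCurve(a, c(0, 5), "glucose", "Agg")
  expect_identical(c1@par, c2@par)
  expect_identical(evalCurve(c1, seq(0, 5, 0.25)), evalCurve(c2, seq(0, 5, 0.25)))
})

test_that("out-of-range concentrations clamp with a warning", {
  crv <- default_curves_cached()[["glucose:Agg"]]
  expect_warning(v <- evalCurve(crv, 7), "clamped")
  expect_identical(v, evalCurve(crv, 5))
  expect_warning(v0 <- evalCurve(crv, -1), "clamped")
  expect_identical(v0, evalCurve(crv, 0))
})

test_that("non-monotone or degenerate anchor sets are rejected", {
  bad <- data.frame(concentration = c(0, 2, 5),
                    normalized_response = c(0, 1, 0.2))
  expect_error(fitCurve(bad, c(0, 5)), "monotone")
  expect_error(fitCurve(data.frame(concentration = 1,
                                   normalized_response = 0.5), c(0, 5)),
               "at least 2")
  # ties at the same concentration are averaged before the monotone check
  tied <- data.frame(concentration = c(0, 2, 2, 5),
                     normalized_response = c(0, 0.4, 0.6, 1))
  expect_s4_class(fitCurve(tied, c(0, 5)), "DoseResponseCurve")
})

test_that("least-squares fit at least matches a brute-force logistic grid", {
  a <- data.frame(concentration = c(1, 2.5, 4),
                  normalized_response = c(0.2, 0.55, 0.95))
  crv <- fitCurve(a, c(0, 5), "glucose", "ColII")

  # exhaustive 2-parameter logistic grid (midpoint step 0.001, steepness
  # grid), same range-normalization as the fitted family
  mids <- seq(0, 5, by = 0.001)
  best <- Inf
  for (k in seq(0.2, 6, by = 0.05)) {
    f <- function(c, m) 1 / (1 + exp(-k * (c - m)))
    f0 <- f(0, mids); f1 <- f(5, mids)
    sse <- rep(0, length(mids))
    for (i in seq_len(nrow(a))) {
      g <- (f(a$concentration[i], mids) - pmin(f0, f1)) / abs(f1 - f0)
      sse <- sse + (g - a$normalized_response[i])^2
    }
    best <- min(best, min(sse))
  }
  expect_lte(crv@sse, best + 1e-6)
})

test_that("anchor tables are validated on load", {
  tab <- loadAnchorTable(defaultTablePath("anchors_default"))
  expect_true(all(tab$stimulus %in% c("glucose", "pH")))
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("stimulus,activity,concentration,normalized_response",
               "IL1B,Agg,1,0.5"), tmp)
  expect_error(loadAnchorTable(tmp), "nutrient")
})
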