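# Synthetic-cohort generator: determinism, sizing, stationarity guards,
# condition effects and artifact injection.

test_that("identical spec and seed give bitwise-identical recordings", {
  sp <- defaultCoupling()
  a <- simulateRecording(sp, rf = 17.3, window = 5, seed = 11)
  b <- simulateRecording(sp, rf = 17.3, window = 5, seed = 11)
  expect_identical(a@channels, b@channels)
  expect_identical(breathIndex(a), breathIndex(b))
  c <- simulateRecording(sp, rf = 17.3, window = 5, seed = 12)
  expect_false(identical(a@channels, c@channels))
})

test_that("sample count is round(rf * window), event-indexed", {
  rec <- simulateRecording(defaultCoupling(), rf = 20, window = 5, seed = 1)
  expect_equal(nBreaths(rec), 100L)
  expect_equal(channelNames(rec), teChannels())
  expect_equal(breathIndex(rec), 0:99)
  expect_equal(nBreaths(simulateRecording(defaultCoupling(), rf = 12,
                                          window = 5, seed = 1)), 60L)
})

test_that("non-stationary or too-short specs are rejected with diagnostics", {
  expect_error(
    couplingSpec(edges = data.frame(source = c("HR", "RF"),
                                    target = c("RF", "HR"),
                                    lag = c(1, 1), strength = c(0.9, 0.9)),
                 ar = 0.95),
    "not stationary")
  expect_error(
    couplingSpec(edges = data.frame(source = "HR", target = "RF",
                                    lag = 1, strength = 1.4)),
    "strength")
  sp <- couplingSpec(edges = data.frame(source = "HR", target = "RF",
                                        lag = 5, strength = 0.5))
  expect_error(simulateRecording(sp, rf = 0.8, window = 5, seed = 1),
               "too short")
})

test_that("generated variance stays near the analytic stationary level", {
  sp <- defaultCoupling()
  rec <- simulateRecording(sp, rf = 20, window = 50, seed = 3)
  arVar <- (sp@noiseSd / sp@scale)^2 / (1 - sp@ar^2) * sp@scale^2
  ratio <- apply(rec@channels, 2, var) / arVar
  expect_true(all(is.finite(ratio)))
  expect_true(all(ratio < 3))
})

test_that("estimated TE on a planted edge grows with coupling strength", {
  mean50 <- function(strength) {
    tes <- vapply(1:50, function(s) {
      sp <- if (strength == 0) couplingSpec()
            else couplingSpec(edges = data.frame(source = "HR", target = "RF",
                                                 lag = 5, strength = strength))
      rec <- simulateRecording(sp, rf = 20, window = 5, seed = s)
      transferEntropy(channelValues(rec, "HR"), channelValues(rec, "RF"))
    }, numeric(1))
    mean(tes)
  }
  m0 <- mean50(0); m4 <- mean50(0.4); m8 <- mean50(0.8)
  expect_lt(m0, m4)
  expect_lt(m4, m8)
})

test_that("default cohort has the full crossover layout and is reproducible", {
  spec <- cohortSpec(seed = 21)
  co <- generateCohort(spec)
  expect_length(co$recordings, 12 * 3 * 2)
  expect_equal(nrow(co$table), 12 * 3)
  co2 <- generateCohort(spec)
  expect_identical(co$table, co2$table)
  expect_identical(co$recordings[["P05.HY1.exercise"]]@channels,
                   co2$recordings[["P05.HY1.exercise"]]@channels)
  # table-only generation draws identical flags (separate substream)
  co3 <- generateCohort(spec, recordings = FALSE)
  expect_identical(co$table, co3$table)
  expect_length(co3$recordings, 0)
})

test_that("zero symptom slope recovers the intercept rate over many cohorts", {
  p0 <- 0.35
  spec0 <- function(s) cohortSpec(
    nParticipants = 6,
    symptomIntercepts = qlogis(c(CTR = p0, HY1 = p0, HY2 = p0)),
    symptomSlope = 0, seed = s)
  flags <- unlist(lapply(1:500, function(s)
    generateCohort(spec0(s), recordings = FALSE)$table$symptom))
  expect_equal(mean(flags), p0, tolerance = 0.02 / p0)
})

test_that("zero condition multiplier yields pure AR channels at the null edge rate", {
  spec <- cohortSpec(nParticipants = 6,
                     conditionMultipliers = c(CTR = 1, HY1 = 0, HY2 = 0.9),
                     seed = 77)
  co <- generateCohort(spec)
  counts <- vapply(sprintf("P%02d", 1:6), function(p) {
    net <- participantNetwork(co$recordings[[paste0(p, ".HY1.rest")]],
                              seed = childSeed(77, match(p, sprintf("P%02d", 1:6))))
    sum(teWeights(net) > 0)
  }, numeric(1))
  # 42 independent null pairs at the nominal 5% level
  expect_gt(mean(counts), 0.05 * 42 - 1.5)
  expect_lt(mean(counts), 0.05 * 42 + 1.5)
})

test_that("artifact injection counts, returns truth indices, and is invertible at rate 0", {
  x <- rnorm(100)
  r0 <- injectArtifacts(x, rate = 0, seed = 5)
  expect_identical(r0$values, x)
  expect_length(r0$indices, 0)
  r5 <- injectArtifacts(x, rate = 0.05, seed = 5)
  expect_length(r5$indices, 5L)
  expect_equal(r5$values[-r5$indices], x[-r5$indices])
  expect_error(injectArtifacts(x, rate = 0.3), "rate")
})

test_that("10-MAD spikes are recovered by the Hampel defaults in >=95% of trials", {
  hitRates <- vapply(1:200, function(s) {
    sp <- defaultCoupling()
    rec <- simulateRecording(sp, rf = 20, window = 5, seed = s)
    x <- channelValues(rec, "HR")
    art <- injectArtifacts(x, rate = 0.05, magnitude = 10, seed = s)
    mask <- detectOutliers(art$values)
    mean(art$indices %in% which(mask))
  }, numeric(1))
  expect_gte(mean(hitRates == 1), 0.95)
})
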