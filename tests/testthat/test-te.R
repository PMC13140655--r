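# Transfer-entropy estimator: analytic value, brute-force oracle equivalence,
# invariances, degenerate inputs and the lag scan.

test_that("deterministic binary mapping y[t+5] = x[t] carries 1 bit", {
  set.seed(101)
  n <- 5000
  x <- sample(0:1, n + 5, replace = TRUE)
  y <- c(sample(0:1, 5, replace = TRUE), x[1:n])
  x <- x[1:(n + 5)]
  expect_equal(transferEntropy(x, y), 1, tolerance = 0.02)
  # reverse direction is analytically 0; estimate must be near 0
  expect_lt(transferEntropy(y, x), 0.01)
})

test_that("estimator equals the brute-force plug-in oracle on discrete toys", {
  set.seed(7)
  for (alpha in 2:4) {
    for (rep in 1:5) {
      n <- sample(40:200, 1)
      lag <- sample(1:5, 1)
      x <- sample(0:(alpha - 1), n, replace = TRUE)
      y <- sample(0:(alpha - 1), n, replace = TRUE)
      cfg <- teConfig(lag = lag, nBins = alpha)
      expect_equal(transferEntropy(x, y, cfg), teOracle(x, y, lag),
                   tolerance = 1e-12)
    }
  }
  # coupled toy with a lagged copy structure, alphabet 2
  x <- rep(c(0, 1, 1, 0, 1), 8)
  y <- c(x[4:40], 0, 1, 0)
  expect_equal(transferEntropy(x, y, teConfig(lag = 3, nBins = 2)),
               teOracle(x, y, 3), tolerance = 1e-12)
})

test_that("quantile binning is invariant under strictly monotone transforms", {
  set.seed(12)
  x <- rnorm(150)
  y <- rnorm(150)
  cfg <- teConfig(lag = 2)
  base <- transferEntropy(x, y, cfg)
  expect_identical(transferEntropy(exp(x), y, cfg), base)
  expect_identical(transferEntropy(x, 3 * y - 7, cfg), base)
  expect_identical(transferEntropy(atan(x), exp(y), cfg), base)
  expect_identical(discretizeSeries(x, cfg), discretizeSeries(exp(x), cfg))
})

test_that("TE is non-negative and shrinks with sample size under independence", {
  meanTe <- function(n) {
    mean(vapply(1:200, function(s) {
      set.seed(s)
      transferEntropy(rnorm(n), rnorm(n))
    }, numeric(1)))
  }
  m100 <- meanTe(100)
  m1000 <- meanTe(1000)
  expect_gte(m100, 0)
  expect_lt(m1000, m100)
})

test_that("degenerate and undersized inputs are handled explicitly", {
  expect_warning(te <- transferEntropy(rep(1, 100), rnorm(100)), "constant")
  expect_identical(te, 0)
  expect_warning(te2 <- transferEntropy(rnorm(100), rep(2, 100)), "constant")
  expect_identical(te2, 0)
  expect_error(transferEntropy(rnorm(20), rnorm(20)), "at least 30")
  expect_error(transferEntropy(rnorm(100), rnorm(99)), "equal length")
})

test_that("adaptive partitioning mode gives a usable non-negative estimate", {
  set.seed(31)
  n <- 300
  x <- sample(0:1, n + 5, replace = TRUE)
  y <- c(sample(0:1, 5, replace = TRUE), x[1:n])
  x <- x[1:(n + 5)]
  cfg <- teConfig(partition = "adaptive")
  expect_equal(transferEntropy(x, y, cfg), 1, tolerance = 0.1)
  expect_gte(transferEntropy(rnorm(200), rnorm(200), cfg), 0)
})

test_that("lag scan finds the plateau and the planted lag", {
  # constant profile -> plateau at 1 (zero successive change)
  set.seed(55)
  x <- sample(0:1, 400, replace = TRUE)
  y <- sample(0:1, 400, replace = TRUE)
  sc <- lagScan(x, y, teConfig(nBins = 2))
  expect_length(sc$teValues, 5)
  expect_true(sc$plateauLag %in% sc$lags)
  # coupling injected at lag 3: argmax of the profile is 3 in >= 90% of seeds
  hit <- vapply(1:100, function(s) {
    sp <- couplingSpec(edges = data.frame(source = "HR", target = "RF",
                                          lag = 3, strength = 0.8))
    rec <- simulateRecording(sp, rf = 20, window = 25, seed = s)  # n = 500
    sc <- lagScan(channelValues(rec, "HR"), channelValues(rec, "RF"))
    which.max(sc$teValues) == 3
  }, logical(1))
  expect_gte(mean(hit), 0.9)
})

test_that("plateau detection follows the relative-change rule exactly", {
  # monotone profile with 50% jumps everywhere never satisfies the tolerance
  with_mocked_bindings(
    transferEntropy = local({
      vals <- c(0.1, 0.15, 0.225, 0.3375, 0.50625)
      function(source, target, config) vals[config$lag]
    }),
    {
      sc <- lagScan(rnorm(50), rnorm(50))
      expect_equal(sc$plateauLag, 5L)
    }
  )
  with_mocked_bindings(
    transferEntropy = function(source, target, config) 0.25,
    {
      sc <- lagScan(rnorm(50), rnorm(50))
      expect_equal(sc$plateauLag, 1L)
    }
  )
})
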