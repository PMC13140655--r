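# Network assembly, centrality, rankings and (weighted) Jaccard similarity.

test_that("participant networks are 7x7, zero-diagonal and label-preserving", {
  rec <- simulateRecording(defaultCoupling(), rf = 16, window = 5, seed = 8,
                           participantId = "P01", condition = "HY2",
                           phase = "exercise")
  net <- participantNetwork(rec, nShuffles = 40, seed = 8)
  w <- teWeights(net)
  expect_equal(dim(w), c(7L, 7L))
  expect_true(all(diag(w) == 0))
  expect_true(all(w >= 0))
  expect_identical(teNodes(net), teChannels())
  expect_identical(condition(net), "HY2")
  expect_identical(phase(net), "exercise")
  expect_identical(teWeights(participantNetwork(rec, nShuffles = 40, seed = 8)), w)
})

test_that("independent channels give roughly the nominal number of spurious edges", {
  counts <- vapply(1:60, function(s) {
    rec <- simulateRecording(couplingSpec(), rf = 16, window = 5, seed = s)
    sum(teWeights(participantNetwork(rec, seed = s)) > 0)
  }, numeric(1))
  expect_gt(mean(counts), 0.05 * 42 - 1.3)
  expect_lt(mean(counts), 0.05 * 42 + 1.6)
})

test_that("a single strong edge is recovered and ranks among the largest entries", {
  sp <- couplingSpec(edges = data.frame(source = "HR", target = "RF",
                                        lag = 5, strength = 0.8))
  found <- top <- logical(100)
  for (s in 1:100) {
    rec <- simulateRecording(sp, rf = 20, window = 5, seed = s)
    w <- teWeights(participantNetwork(rec, seed = s))
    found[s] <- w["HR", "RF"] > 0
    top[s] <- w["HR", "RF"] >= sort(w, decreasing = TRUE)[3]
  }
  expect_gte(mean(found), 0.95)
  expect_gte(mean(top), 0.9)
})

test_that("group median pools element-wise with zeros included", {
  a <- fullTEMatrix(0); b <- fullTEMatrix(0); c <- fullTEMatrix(0)
  wa <- teWeights(a); wa["HR", "RF"] <- 0.4
  ms <- list(toyTEMatrix(wa, nodes = teChannels()), b, c)
  med <- groupMedianNetwork(ms)
  expect_identical(participantId(med), "group")
  expect_equal(teWeights(med)["HR", "RF"], 0)  # absent in the majority
  # identical inputs reproduce themselves
  expect_equal(teWeights(groupMedianNetwork(list(a, a))), teWeights(a))
  # even count uses the midpoint of the central values
  mk <- function(v) { w <- teWeights(fullTEMatrix(0)); w["VE", "VT"] <- v
                      toyTEMatrix(w, nodes = teChannels()) }
  med4 <- groupMedianNetwork(lapply(c(0.1, 0.2, 0.7, 0.8), mk))
  expect_equal(teWeights(med4)["VE", "VT"], 0.45)
  # mixed labels are rejected
  other <- fullTEMatrix(0, condition = "HY1")
  expect_error(groupMedianNetwork(list(a, other)), "conditions")
})

test_that("degree profiles satisfy the conservation identities", {
  w <- matrix(0, 3, 3)
  w[1, 2] <- 0.2; w[2, 3] <- 0.3; w[3, 1] <- 0.5
  m <- toyTEMatrix(w)
  d <- weightedDegrees(m)
  expect_equal(unname(d$outdegree), c(0.2, 0.3, 0.5))
  expect_equal(unname(d$indegree), c(0.5, 0.2, 0.3))
  expect_equal(d$totalTe, 1.0)
  expect_equal(totalTE(m), 1.0)
  # conservation on random matrices
  set.seed(42)
  for (i in 1:100) {
    w <- matrix(runif(49), 7, 7); diag(w) <- 0
    d <- weightedDegrees(toyTEMatrix(w, nodes = teChannels()))
    expect_equal(sum(d$indegree), sum(d$outdegree))
    expect_equal(sum(d$indegree), d$totalTe)
  }
  z <- weightedDegrees(fullTEMatrix(0))
  expect_true(all(z$indegree == 0) && all(z$outdegree == 0) && z$totalTe == 0)
})

test_that("node ranking is a stable descending sort with fixed-order ties", {
  w <- matrix(0, 3, 3); w[1, 2] <- 0.2; w[2, 3] <- 0.3; w[3, 1] <- 0.5
  d <- weightedDegrees(toyTEMatrix(w))
  expect_equal(rankNodes(d, "ID"), c("A", "C", "B"))
  expect_equal(rankNodes(d, "OD"), c("C", "B", "A"))
  dEq <- weightedDegrees(fullTEMatrix(0.1))
  expect_equal(rankNodes(dEq, "ID"), teChannels())
  expect_setequal(rankNodes(weightedDegrees(fullTEMatrix(0.3)), "OD"),
                  teChannels())
})

test_that("jsi follows binary set arithmetic", {
  w <- function(edges) {
    m <- matrix(0, 3, 3)
    for (e in edges) m[e[1], e[2]] <- e[3]
    toyTEMatrix(m)
  }
  a <- w(list(c(1, 2, 0.5), c(2, 3, 0.1)))
  b <- w(list(c(2, 3, 0.9), c(3, 1, 0.2)))
  expect_equal(jsi(a, a), 1)
  expect_equal(jsi(a, b), 1 / 3)
  expect_equal(jsi(w(list(c(1, 2, 1))), w(list(c(2, 1, 1)))), 0)
  expect_equal(jsi(w(list()), w(list())), 1)
})

test_that("wjsi implements sum-min over sum-max with its conventions", {
  w3 <- function(v12, v13, v21) {
    m <- matrix(0, 3, 3); m[1, 2] <- v12; m[1, 3] <- v13; m[2, 1] <- v21
    toyTEMatrix(m)
  }
  a <- w3(0.2, 0.5, 0)
  b <- w3(0.4, 0.1, 0)
  expect_equal(wjsi(a, b), 0.3 / 0.9)
  expect_equal(wjsi(a, a), 1)
  expect_equal(wjsi(w3(0, 0, 0), w3(0, 0, 0)), 1)
  expect_equal(wjsi(w3(1, 0, 0), w3(0, 0, 1)), 0)
  # symmetry and scaling behaviour
  expect_equal(wjsi(a, b), wjsi(b, a))
  ca <- teMatrix(2.5 * teWeights(a), nodes = teNodes(a))
  expect_equal(wjsi(ca, ca), 1)
  expect_equal(wjsi(a, ca), 1 / 2.5)
  # wjsi equals jsi on 0/1 matrices
  set.seed(9)
  for (i in 1:50) {
    m1 <- matrix(rbinom(49, 1, 0.4), 7, 7); diag(m1) <- 0
    m2 <- matrix(rbinom(49, 1, 0.4), 7, 7); diag(m2) <- 0
    t1 <- toyTEMatrix(m1, nodes = teChannels())
    t2 <- toyTEMatrix(m2, nodes = teChannels())
    expect_equal(wjsi(t1, t2), jsi(t1, t2))
  }
  # removing a shared edge strictly decreases wjsi
  shared <- w3(0.3, 0.4, 0.2)
  dropped <- w3(0, 0.4, 0.2)
  expect_lt(wjsi(dropped, shared), wjsi(shared, shared))
  # node-order mismatch is an error
  other <- toyTEMatrix(matrix(0, 3, 3), nodes = c("X", "Y", "Z"))
  expect_error(wjsi(a, other), "node order")
  expect_error(jsi(a, other), "node order")
})

test_that("the nine-comparison schema evaluates a full 3x2 network set", {
  nets <- list()
  set.seed(14)
  for (cond in conditionLevels()) for (ph in phaseLevels()) {
    w <- matrix(runif(49, 0, 0.5), 7, 7); diag(w) <- 0
    nets[[paste(cond, ph, sep = ".")]] <-
      toyTEMatrix(w, nodes = teChannels(), condition = cond, phase = ph)
  }
  s <- similarityTable(nets)
  expect_named(s, comparisonSchema()$name)
  expect_true(all(s >= 0 & s <= 1))
  expect_equal(unname(s["restExercise.CTR"]),
               wjsi(nets[["CTR.rest"]], nets[["CTR.exercise"]]))
  expect_error(similarityTable(nets[-1]), "every condition")
})
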