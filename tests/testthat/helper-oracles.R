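# Independent oracles used across the suite. Kept deliberately naive: direct
# tabulation / definition-level sums, no shared code with the package paths
# they check.

# Brute-force plug-in transfer entropy from raw (discrete) values: tabulate
# every (y[t+lag], y[t], x[t]) triplet and sum the definition term by term.
teOracle <- function(x, y, lag) {
  m <- length(x) - lag
  trip <- data.frame(yl = y[(1 + lag):(m + lag)], y = y[1:m], x = x[1:m])
  te <- 0
  for (yl in unique(trip$yl)) {
    for (yy in unique(trip$y)) {
      nY <- sum(trip$y == yy)
      nYlY <- sum(trip$yl == yl & trip$y == yy)
      if (nYlY == 0) next
      for (xx in unique(trip$x)) {
        n3 <- sum(trip$yl == yl & trip$y == yy & trip$x == xx)
        if (n3 == 0) next
        nYX <- sum(trip$y == yy & trip$x == xx)
        pJoint <- n3 / m
        pCondFull <- n3 / nYX
        pCondY <- nYlY / nY
        te <- te + pJoint * log2(pCondFull / pCondY)
      }
    }
  }
  max(te, 0)
}

# Brute-force one-way repeated-measures sums of squares, straight from the
# textbook definitions with explicit loops.
rmAnovaOracle <- function(Y) {
  n <- nrow(Y); k <- ncol(Y)
  grand <- sum(Y) / (n * k)
  ssSub <- 0
  for (i in 1:n) ssSub <- ssSub + k * (mean(Y[i, ]) - grand)^2
  ssEff <- 0
  for (j in 1:k) ssEff <- ssEff + n * (mean(Y[, j]) - grand)^2
  ssTot <- 0
  for (i in 1:n) for (j in 1:k) ssTot <- ssTot + (Y[i, j] - grand)^2
  ssErr <- ssTot - ssSub - ssEff
  Fval <- (ssEff / (k - 1)) / (ssErr / ((n - 1) * (k - 1)))
  list(F = Fval, eta2p = ssEff / (ssEff + ssErr),
       ssEffect = ssEff, ssError = ssErr, ssSubjects = ssSub)
}

# Small TEMatrix builder for toys.
toyTEMatrix <- function(w, nodes = NULL, ...) {
  if (is.null(nodes)) nodes <- LETTERS[seq_len(nrow(w))]
  dimnames(w) <- list(nodes, nodes)
  teMatrix(w, nodes = nodes, ...)
}

# 7x7 TEMatrix from a flat off-diagonal filler.
fullTEMatrix <- function(fill = 0, ...) {
  k <- 7L
  w <- matrix(fill, k, k)
  diag(w) <- 0
  toyTEMatrix(w, nodes = teChannels(), ...)
}

# The reference WJSI table shipped with the package, as a matrix.
refWjsi <- function() {
  ref <- referenceSimilarities()
  as.matrix(ref[, setdiff(names(ref), "sex")])
}
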