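## Directed weighted network construction and comparison: per-participant
## significant-TE adjacency matrices, group medians, in/out-degree centrality,
## node rankings, and (weighted) Jaccard similarity.

#' Construct a TEMatrix
#'
#' @param weights square numeric matrix, `weights[i, j] = TE(node_i ->
#'   node_j)` in bits; non-negative with zero diagonal
#' @param nodes node names (default taken from dimnames or [teChannels()])
#' @param participantId participant label, or `"group"` for a group median
#' @param condition,phase experimental labels
#' @return a validated [TEMatrix-class]
#' @export
teMatrix <- function(weights, nodes = NULL, participantId = "sim",
                     condition = "CTR", phase = "rest") {
  if (is.null(nodes))
    nodes <- if (!is.null(rownames(weights))) rownames(weights)
             else teChannels()[seq_len(nrow(weights))]
  dimnames(weights) <- list(nodes, nodes)
  new("TEMatrix", nodes = nodes, weights = weights,
      participantId = participantId, condition = condition, phase = phase)
}

#' Map one participant's physiological network
#'
#' Runs the surrogate-thresholded transfer-entropy estimate for every ordered
#' channel pair of a (preprocessed) recording - 42 directed pairs for the 7
#' standard channels - and assembles the significant values into a directed
#' adjacency matrix with zero diagonal. Each pair uses its own deterministic
#' seed substream, so the whole network is reproducible from `seed`.
#'
#' @param recording a [BreathRecording-class]
#' @param config a [teConfig()]
#' @param nShuffles,percentile surrogate-test settings (see [surrogateTest()])
#' @param seed integer seed
#' @return a [TEMatrix-class] carrying the recording's labels
#' @export
participantNetwork <- function(recording, config = teConfig(),
                               nShuffles = 100L, percentile = 95,
                               seed = 1L) {
  ch <- channelNames(recording)
  k <- length(ch)
  w <- matrix(0, k, k, dimnames = list(ch, ch))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) next
      res <- tryCatch(
        surrogateTest(recording@channels[, i], recording@channels[, j],
                      config = config, nShuffles = nShuffles,
                      percentile = percentile,
                      seed = childSeed(seed, i, j)),
        error = function(e)
          stop(sprintf("TE estimation failed for pair %s -> %s: %s",
                       ch[i], ch[j], conditionMessage(e)), call. = FALSE))
      w[i, j] <- res$finalTe
    }
  }
  teMatrix(w, nodes = ch, participantId = participantId(recording),
           condition = condition(recording), phase = phase(recording))
}

#' Group median network
#'
#' Element-wise median of per-participant adjacency matrices (same condition
#' and phase). Zeroed, non-significant entries take part in the median, so an
#' edge absent in the majority of participants vanishes from the group
#' network; an even participant count uses the midpoint of the two central
#' values.
#'
#' @param matrices list of [TEMatrix-class] with identical node order and
#'   identical condition/phase labels
#' @return a [TEMatrix-class] with `participantId = "group"`
#' @export
groupMedianNetwork <- function(matrices) {
  stopifnot(length(matrices) >= 1L)
  nodes <- teNodes(matrices[[1L]])
  cond <- condition(matrices[[1L]])
  ph <- phase(matrices[[1L]])
  for (m in matrices) {
    if (!identical(teNodes(m), nodes))
      stop("all matrices must share the same node order")
    if (!identical(condition(m), cond) || !identical(phase(m), ph))
      stop("cannot pool matrices across different conditions or phases")
  }
  arr <- vapply(matrices, teWeights, matrix(0, length(nodes), length(nodes)))
  med <- apply(arr, c(1, 2), median)
  teMatrix(med, nodes = nodes, participantId = "group",
           condition = cond, phase = ph)
}

#' Weighted degree centrality
#'
#' In-degree `ID[j] = sum_i w[i, j]` (the network's influence on a node) and
#' out-degree `OD[i] = sum_j w[i, j]` (a node's influence on the network) of
#' the significant-TE adjacency matrix, in bits, plus the total TE (their
#' common sum).
#'
#' @param matrix a [TEMatrix-class]
#' @return a list of class `"DegreeProfile"` with `indegree`, `outdegree`
#'   (named per node) and `totalTe`
#' @export
weightedDegrees <- function(matrix) {
  w <- teWeights(matrix)
  structure(list(indegree = colSums(w), outdegree = rowSums(w),
                 totalTe = sum(w), nodes = teNodes(matrix)),
            class = "DegreeProfile")
}

#' @export
print.DegreeProfile <- function(x, ...) {
  cat("DegreeProfile (bits): total TE", format(x$totalTe, digits = 4), "\n")
  print(rbind(ID = x$indegree, OD = x$outdegree), digits = 3)
  invisible(x)
}

#' Rank nodes by degree
#'
#' Stable descending sort of the nodes by in- or out-degree; ties keep the
#' fixed channel order.
#'
#' @param profile a `"DegreeProfile"` from [weightedDegrees()]
#' @param by `"ID"` (in-degree) or `"OD"` (out-degree)
#' @return character vector: all nodes in descending-degree order
#' @export
rankNodes <- function(profile, by = c("ID", "OD")) {
  by <- match.arg(by)
  v <- if (by == "ID") profile$indegree else profile$outdegree
  profile$nodes[order(-v, seq_along(v))]
}

#' Total transfer entropy of a network
#'
#' Sum of all significant edge weights (bits); equals both the sum of
#' in-degrees and the sum of out-degrees.
#'
#' @param matrix a [TEMatrix-class]
#' @return total TE in bits
#' @export
totalTE <- function(matrix) sum(teWeights(matrix))

offDiagonal <- function(m) {
  w <- teWeights(m)
  w[row(w) != col(w)]
}

checkComparable <- function(a, b) {
  if (!identical(teNodes(a), teNodes(b)))
    stop("networks must share the same node order")
}

#' Jaccard similarity of two networks
#'
#' Binarizes both adjacency matrices (an edge is present iff its weight is
#' `> 0`) and returns the proportion of shared edges out of the union of
#' edges. Two empty networks are identical by convention (`1`).
#'
#' @param a,b [TEMatrix-class] objects with the same node order
#' @return JSI in \[0, 1\]
#' @export
jsi <- function(a, b) {
  checkComparable(a, b)
  ea <- offDiagonal(a) > 0
  eb <- offDiagonal(b) > 0
  uni <- sum(ea | eb)
  if (uni == 0L) return(1)
  sum(ea & eb) / uni
}

#' Weighted Jaccard similarity of two networks
#'
#' `sum_i min(a_i, b_i) / sum_i max(a_i, b_i)` over all off-diagonal entries
#' of the two adjacency matrices. Equals [jsi()] when both matrices are
#' 0/1-valued; two all-zero networks give `1` by convention.
#'
#' @param a,b [TEMatrix-class] objects with the same node order
#' @return WJSI in \[0, 1\]
#' @export
wjsi <- function(a, b) {
  checkComparable(a, b)
  wa <- offDiagonal(a)
  wb <- offDiagonal(b)
  denom <- sum(pmax(wa, wb))
  if (denom == 0) return(1)
  sum(pmin(wa, wb)) / denom
}

#' The nine standard network comparisons
#'
#' The fixed comparison schema used for individual-level similarity tables:
#' rest vs. exercise within each condition, plus the three condition pairs
#' within rest and within exercise.
#'
#' @return data.frame with columns `name`, `conditionA`, `phaseA`,
#'   `conditionB`, `phaseB`
#' @export
comparisonSchema <- function() {
  data.frame(
    name = c("restExercise.CTR", "restExercise.HY1", "restExercise.HY2",
             "CTR-HY1.rest", "CTR-HY1.exercise",
             "CTR-HY2.rest", "CTR-HY2.exercise",
             "HY1-HY2.rest", "HY1-HY2.exercise"),
    conditionA = c("CTR", "HY1", "HY2", "CTR", "CTR", "CTR", "CTR",
                   "HY1", "HY1"),
    phaseA = c("rest", "rest", "rest", "rest", "exercise", "rest",
               "exercise", "rest", "exercise"),
    conditionB = c("CTR", "HY1", "HY2", "HY1", "HY1", "HY2", "HY2",
                   "HY2", "HY2"),
    phaseB = c("exercise", "exercise", "exercise", "rest", "exercise",
               "rest", "exercise", "rest", "exercise"),
    stringsAsFactors = FALSE)
}

#' Individual-level similarity table
#'
#' Applies the [comparisonSchema()] to one participant's six networks
#' (3 conditions x 2 phases) and returns the nine WJSI values.
#'
#' @param networks named list of [TEMatrix-class], names
#'   `"<condition>.<phase>"` (e.g. `"CTR.rest"`)
#' @return named numeric vector of nine WJSI values
#' @export
similarityTable <- function(networks) {
  sch <- comparisonSchema()
  out <- numeric(nrow(sch))
  names(out) <- sch$name
  for (r in seq_len(nrow(sch))) {
    a <- networks[[paste(sch$conditionA[r], sch$phaseA[r], sep = ".")]]
    b <- networks[[paste(sch$conditionB[r], sch$phaseB[r], sep = ".")]]
    if (is.null(a) || is.null(b))
      stop("networks list must contain every condition.phase combination")
    out[r] <- wjsi(a, b)
  }
  out
}
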