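## Transfer-entropy estimation on event-sampled series: rank-based
## equal-frequency discretization (or per-axis adaptive partitioning), a
## plug-in estimator in bits, and a lag scan with plateau detection.

#' Transfer-entropy estimator configuration
#'
#' @param lag source-to-future lag in respiratory cycles (default 5, the
#'   fixed lag used for network mapping: ~15 s at typical resting breathing
#'   frequencies, inside the 5-25 s memory length of cardiorespiratory series)
#' @param partition discretization scheme: `"quantile"` (equal-frequency bins
#'   from ranks; default) or `"adaptive"` (recursive per-axis partitioning
#'   with a chi-square uniformity stop)
#' @param nBins number of bins per dimension in quantile mode (default 4,
#'   which keeps the plug-in estimator's small-sample bias manageable on
#'   5-min breath-by-breath windows of ~60-150 samples); if
#'   a series has no more distinct values than `nBins`, each distinct value
#'   becomes its own bin, so genuinely discrete series are used exactly
#' @param minTriplets minimum usable `(y[t+lag], y[t], x[t])` triplets
#'   (default 30)
#' @param plateauTol relative-change tolerance used by [lagScan()] plateau
#'   detection (default 0.10)
#' @return a list of class `"teConfig"`
#' @export
teConfig <- function(lag = 5L, partition = c("quantile", "adaptive"),
                     nBins = 4L, minTriplets = 30L, plateauTol = 0.10) {
  partition <- match.arg(partition)
  lag <- as.integer(lag)
  nBins <- as.integer(nBins)
  if (lag < 1L) stop("lag must be a positive integer")
  if (nBins < 2L) stop("nBins must be >= 2")
  structure(list(lag = lag, partition = partition, nBins = nBins,
                 minTriplets = as.integer(minTriplets),
                 plateauTol = plateauTol, logBase = 2),
            class = "teConfig")
}

#' Discretize a series for TE estimation
#'
#' Quantile mode assigns equal-frequency bins from ranks (ties share the rank
#' of their first occurrence, so tied values always fall in the lower bin and
#' the assignment is invariant under strictly monotone transforms). If the
#' series has at most `nBins` distinct values, each distinct value is its own
#' bin. Adaptive mode recursively splits each axis at the median of the data
#' in a segment while a chi-square test rejects uniformity of the two halves.
#'
#' @param x numeric series
#' @param config a [teConfig()]
#' @return integer bin indices in `1..nbins(x)`, with attribute `"nbins"`
#' @export
discretizeSeries <- function(x, config = teConfig()) {
  ux <- unique(x)
  if (length(ux) <= config$nBins) {
    b <- match(x, sort(ux))
    attr(b, "nbins") <- length(ux)
    return(b)
  }
  if (config$partition == "quantile") {
    n <- length(x)
    r <- rank(x, ties.method = "min")
    b <- as.integer(floor((r - 1) * config$nBins / n) + 1L)
    attr(b, "nbins") <- config$nBins
    return(b)
  }
  ## adaptive: recursive dyadic splitting of the 1-D support
  breaks <- adaptiveBreaks(sort(x), maxBins = config$nBins * 4L)
  b <- findInterval(x, breaks, left.open = TRUE) + 1L
  ## compact to consecutive ids
  b <- match(b, sort(unique(b)))
  attr(b, "nbins") <- max(b)
  b
}

## Darbellay-Vajda-flavoured 1-D recursion: split a sorted segment at its
## median when the counts of the two halves of its value range deviate from
## uniformity by a chi-square criterion; stop at small segments.
adaptiveBreaks <- function(xs, maxBins, minCount = 8L, alpha = 0.05) {
  recurse <- function(lo, hi, depth) {
    seg <- xs[xs > lo & xs <= hi]
    nSeg <- length(seg)
    if (nSeg < 2L * minCount || depth > ceiling(log2(maxBins))) return(numeric())
    mid <- median(seg)
    if (mid <= lo || mid >= hi) return(numeric())
    nl <- sum(seg <= mid)
    ## uniformity over the value range: expected split proportional to width
    pl <- (mid - lo) / (hi - lo)
    expL <- nSeg * pl
    expR <- nSeg - expL
    if (expL < 1 || expR < 1) return(numeric())
    chi2 <- (nl - expL)^2 / expL + ((nSeg - nl) - expR)^2 / expR
    if (chi2 <= stats::qchisq(1 - alpha, df = 1)) return(numeric())
    c(recurse(lo, mid, depth + 1L), mid, recurse(mid, hi, depth + 1L))
  }
  lo <- xs[1L] - 1
  hi <- xs[length(xs)]
  sort(recurse(lo, hi, 1L))
}

#' Transfer entropy between two event-sampled series
#'
#' Plug-in estimate of
#' \deqn{TE_{X \to Y} = \sum p(y_{t+\lambda}, y_t, x_t)
#'   \log_2 \frac{p(y_{t+\lambda} \mid y_t, x_t)}{p(y_{t+\lambda} \mid y_t)}}
#' with embedding dimension 1 for both histories and lag \eqn{\lambda} in
#' respiratory cycles, in bits. Probabilities come from the configured
#' discretization of each full series; empty cells contribute 0 and the
#' estimate is clipped at 0 from below. A constant source or target yields 0
#' with a warning (degenerate partition).
#'
#' @param source,target numeric series of equal length (source = the channel
#'   whose past is tested for predictive influence)
#' @param config a [teConfig()]
#' @return transfer entropy in bits, `>= 0`
#' @export
#' @examples
#' set.seed(1)
#' x <- sample(0:1, 500, replace = TRUE)
#' y <- c(sample(0:1, 5, replace = TRUE), x[1:495])  # y[t+5] = x[t]
#' transferEntropy(x, y)  # close to 1 bit
transferEntropy <- function(source, target, config = teConfig()) {
  n <- length(source)
  if (length(target) != n)
    stop("source and target must have equal length")
  if (any(!is.finite(source)) || any(!is.finite(target)))
    stop("series must be finite")
  m <- n - config$lag
  if (m < config$minTriplets)
    stop(sprintf("only %d usable triplets at lag %d; at least %d are required",
                 max(m, 0L), config$lag, config$minTriplets))
  if (length(unique(source)) < 2L || length(unique(target)) < 2L) {
    warning("constant source or target: degenerate partition, TE set to 0")
    return(0)
  }
  xb <- discretizeSeries(source, config)
  yb <- discretizeSeries(target, config)
  te_plugin_c(xb, yb, config$lag, attr(xb, "nbins"), attr(yb, "nbins"))
}

#' Scan lags and locate the TE plateau
#'
#' Computes TE at every lag `1..maxLag` and reports the smallest lag from
#' which the profile has flattened: the first lag `l` such that every
#' subsequent successive relative change `|TE(j+1) - TE(j)| / max(TE(j),
#' 1e-12)` stays below `config$plateauTol`. If the profile never settles, the
#' plateau lag is `maxLag`.
#'
#' @param source,target numeric series
#' @param config a [teConfig()]; its `lag` entry is ignored here
#' @param maxLag largest lag scanned (default 5 respiratory cycles)
#' @return list with `lags`, `teValues` (bits) and `plateauLag`
#' @export
lagScan <- function(source, target, config = teConfig(), maxLag = 5L) {
  lags <- seq_len(maxLag)
  te <- vapply(lags, function(l) {
    cfg <- config
    cfg$lag <- as.integer(l)
    transferEntropy(source, target, cfg)
  }, numeric(1))
  plateau <- as.integer(maxLag)
  if (maxLag > 1L) {
    rel <- abs(diff(te)) / pmax(te[-maxLag], 1e-12)
    flat <- rev(cumprod(rev(rel < config$plateauTol))) == 1  # all changes from l on
    if (any(flat)) plateau <- which(flat)[1L]
  } else plateau <- 1L
  list(lags = lags, teValues = te, plateauLag = plateau)
}
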