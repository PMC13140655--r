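## Breath-by-breath series cleaning: Hampel outlier detection, linear gap
## interpolation, and event-indexed analysis-window extraction.

#' Detect outliers with a rolling Hampel filter
#'
#' Flags sample `i` when `|x[i] - median(w_i)| > threshold * MAD(w_i)`, where
#' `w_i` is the window of `window` samples centred on `i` (shrunk at the series
#' edges). The MAD uses the usual Gaussian consistency constant 1.4826, so
#' `threshold = 3` corresponds to roughly a 3-sigma rule on clean data. The
#' inequality is strict, so a window whose MAD is zero (e.g. a constant
#' stretch) flags only samples that differ from the window median.
#'
#' @param object numeric series or [BreathRecording-class]
#' @param window odd window length, >= 3 (default 11)
#' @param threshold flag threshold in MAD multiples (default 3)
#' @return logical mask (series) or breaths x channels logical matrix
#'   (recording); `TRUE` marks an outlier
#' @rdname detectOutliers
#' @export
#' @examples
#' detectOutliers(c(5, 5, 5, 50, 5, 5, 5), window = 7)  # only the spike
setMethod("detectOutliers", "numeric", function(object, window = 11L,
                                                threshold = 3) {
  if (window < 3L || window %% 2L == 0L)
    stop("'window' must be an odd integer >= 3")
  if (threshold <= 0) stop("'threshold' must be positive")
  n <- length(object)
  if (n < 3L) {
    warning("series shorter than 3 samples; nothing flagged")
    return(rep(FALSE, n))
  }
  half <- window %/% 2L
  mask <- logical(n)
  for (i in seq_len(n)) {
    w <- object[max(1L, i - half):min(n, i + half)]
    med <- median(w)
    nw <- length(w)
    ## Gaussian-consistent MAD with the finite-sample correction n/(n - 0.8),
    ## without which short windows under-estimate sigma and over-flag
    s <- mad(w, center = med) * nw / (nw - 0.8)
    mask[i] <- abs(object[i] - med) > threshold * s
  }
  mask
})

#' @rdname detectOutliers
#' @export
setMethod("detectOutliers", "BreathRecording",
  function(object, window = 11L, threshold = 3) {
    apply(object@channels, 2L, detectOutliers,
          window = window, threshold = threshold)
  })

#' Interpolate masked samples
#'
#' Replaces masked samples by linear interpolation over the breath index
#' between the nearest unmasked neighbours; leading/trailing masked samples
#' take the nearest unmasked value. Output length is unchanged and always
#' finite.
#'
#' @param object numeric series or [BreathRecording-class]
#' @param mask logical, same length as the series (for a recording: a
#'   breaths x channels matrix as returned by [detectOutliers()])
#' @param index abscissa used for interpolation (defaults to the sample
#'   positions; for recordings, the stored breath index)
#' @param ... unused
#' @return the series/recording with masked samples replaced
#' @rdname interpolateGaps
#' @export
#' @examples
#' interpolateGaps(c(1, 2, 99, 4), c(FALSE, FALSE, TRUE, FALSE))  # 1 2 3 4
setMethod("interpolateGaps", "numeric",
  function(object, mask, index = seq_along(object), ...) {
    if (length(mask) != length(object))
      stop("mask must have the same length as the series")
    if (!any(mask)) return(object)
    if (all(mask)) stop("all samples masked: nothing to interpolate from")
    good <- which(!mask)
    if (length(good) == 1L) {
      object[mask] <- object[good]
      return(object)
    }
    object[mask] <- approx(x = index[good], y = object[good],
                           xout = index[mask], rule = 2)$y
    object
  })

#' @rdname interpolateGaps
#' @export
setMethod("interpolateGaps", "BreathRecording",
  function(object, mask, ...) {
    stopifnot(is.matrix(mask), dim(mask) == dim(object@channels))
    for (j in seq_len(ncol(mask)))
      object@channels[, j] <- interpolateGaps(object@channels[, j], mask[, j],
                                              index = object@breathIndex)
    object
  })

#' Clean a recording (detect + interpolate)
#'
#' Convenience wrapper running the Hampel filter and linear interpolation on
#' every channel of a recording. Channel parallelism is preserved and no
#' non-finite value is ever introduced.
#'
#' @param recording a [BreathRecording-class]
#' @param window,threshold Hampel settings, see [detectOutliers()]
#' @return the cleaned [BreathRecording-class]
#' @export
preprocessRecording <- function(recording, window = 11L, threshold = 3) {
  mask <- detectOutliers(recording, window = window, threshold = threshold)
  interpolateGaps(recording, mask)
}

#' Extract an event-indexed analysis window
#'
#' Slices all channels identically to `n = round(rfEstimate * duration)`
#' samples starting at 0-based breath `startBreath` (half-open slice
#' `[startBreath, startBreath + n)`). Windows are event-indexed (breaths), not
#' wall-clock-indexed, matching the breath-by-breath sampling model.
#'
#' @param object a [BreathRecording-class]
#' @param startBreath 0-based start offset in breaths
#' @param duration window duration in minutes
#' @param rfEstimate breathing-frequency estimate, breaths/min
#' @return a [BreathRecording-class] with `n` breaths; labels preserved
#' @rdname extractWindow
#' @export
setMethod("extractWindow", "BreathRecording",
  function(object, startBreath = 0L, duration = 5, rfEstimate) {
    n <- as.integer(round(rfEstimate * duration))
    if (n < 1L) stop("requested window is empty")
    avail <- nBreaths(object)
    if (startBreath < 0L) stop("startBreath must be >= 0")
    if (startBreath + n > avail)
      stop(sprintf("window needs %d breaths from offset %d but only %d are available (%d short)",
                   n, startBreath, avail, startBreath + n - avail))
    sel <- startBreath + seq_len(n)
    new("BreathRecording", participantId = object@participantId,
        condition = object@condition, phase = object@phase,
        channels = object@channels[sel, , drop = FALSE],
        breathIndex = object@breathIndex[sel])
  })
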