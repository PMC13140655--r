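#' Accessors for recordings and TE matrices
#'
#' Small accessor generics so downstream code never touches slots directly:
#' `nBreaths` (number of sampled respiratory cycles), `channelNames`,
#' `participantId`, `condition`, `phase`, `channelValues` (one channel's
#' series), `breathIndex`, `teWeights` (the directed adjacency matrix of
#' significant transfer-entropy values, bits) and `teNodes`.
#'
#' @param object a [BreathRecording] or [TEMatrix]
#' @param channel channel name, one of [teChannels()]
#' @return the accessed component
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nBreaths", function(object) standardGeneric("nBreaths"))
#' @rdname accessors
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))
#' @rdname accessors
#' @export
setGeneric("participantId", function(object) standardGeneric("participantId"))
#' @rdname accessors
#' @export
setGeneric("condition", function(object) standardGeneric("condition"))
#' @rdname accessors
#' @export
setGeneric("phase", function(object) standardGeneric("phase"))
#' @rdname accessors
#' @export
setGeneric("channelValues", function(object, channel) standardGeneric("channelValues"))
#' @rdname accessors
#' @export
setGeneric("breathIndex", function(object) standardGeneric("breathIndex"))
#' @rdname accessors
#' @export
setGeneric("teWeights", function(object) standardGeneric("teWeights"))
#' @rdname accessors
#' @export
setGeneric("teNodes", function(object) standardGeneric("teNodes"))

#' @rdname accessors
#' @export
setMethod("nBreaths", "BreathRecording", function(object) nrow(object@channels))
#' @rdname accessors
#' @export
setMethod("channelNames", "BreathRecording", function(object) colnames(object@channels))
#' @rdname accessors
#' @export
setMethod("participantId", "BreathRecording", function(object) object@participantId)
#' @rdname accessors
#' @export
setMethod("condition", "BreathRecording", function(object) object@condition)
#' @rdname accessors
#' @export
setMethod("phase", "BreathRecording", function(object) object@phase)
#' @rdname accessors
#' @export
setMethod("breathIndex", "BreathRecording", function(object) object@breathIndex)
#' @rdname accessors
#' @export
setMethod("channelValues", "BreathRecording", function(object, channel) {
  if (!channel %in% colnames(object@channels))
    stop("unknown channel '", channel, "'")
  object@channels[, channel]
})

#' @rdname accessors
#' @export
setMethod("teWeights", "TEMatrix", function(object) object@weights)
#' @rdname accessors
#' @export
setMethod("teNodes", "TEMatrix", function(object) object@nodes)
#' @rdname accessors
#' @export
setMethod("participantId", "TEMatrix", function(object) object@participantId)
#' @rdname accessors
#' @export
setMethod("condition", "TEMatrix", function(object) object@condition)
#' @rdname accessors
#' @export
setMethod("phase", "TEMatrix", function(object) object@phase)

#' @rdname detectOutliers
#' @export
setGeneric("detectOutliers",
  function(object, window = 11L, threshold = 3)
    standardGeneric("detectOutliers"))

#' @rdname interpolateGaps
#' @export
setGeneric("interpolateGaps",
  function(object, mask, ...) standardGeneric("interpolateGaps"))

#' @rdname injectArtifacts
#' @export
setGeneric("injectArtifacts",
  function(object, rate, magnitude = 10, seed = 1L)
    standardGeneric("injectArtifacts"))

#' @rdname extractWindow
#' @export
setGeneric("extractWindow",
  function(object, startBreath = 0L, duration = 5, rfEstimate)
    standardGeneric("extractWindow"))
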