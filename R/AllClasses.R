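#' @import methods
#' @importFrom stats median mad quantile rnorm runif rbinom approx cor cor.test
#'   pchisq pf glm binomial logLik coef AIC BIC lm residuals plogis qlogis
#'   complete.cases var sd setNames pbinom
#' @importFrom utils read.csv write.csv packageVersion
#' @useDynLib breathTE, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Channel, condition and phase vocabularies
#'
#' The seven cardiorespiratory network nodes, in the fixed order used for
#' matrices and for deterministic tie-breaking: heart rate (HR), respiratory
#' frequency (RF), minute ventilation (VE), tidal volume (VT), oxygen
#' consumption (VO2), end-tidal O2 (PETO2) and CO2 (PETCO2) pressures.
#'
#' @return `teChannels()`: character vector of the 7 channel names.
#'   `conditionLevels()`: the condition vocabulary (`CTR`, `HY1`, `HY2`:
#'   normoxic control and the two normobaric-hypoxia levels).
#'   `phaseLevels()`: the phase vocabulary (`rest`, `exercise`).
#' @export
#' @examples
#' teChannels()
teChannels <- function() c("HR", "RF", "VE", "VT", "VO2", "PETO2", "PETCO2")

#' @rdname teChannels
#' @export
conditionLevels <- function() c("CTR", "HY1", "HY2")

#' @rdname teChannels
#' @export
phaseLevels <- function() c("rest", "exercise")

## ---------------------------------------------------------------------------
## CouplingSpec: ground-truth generative model for one multichannel recording
## ---------------------------------------------------------------------------

#' Ground-truth coupled-system specification
#'
#' S4 container for the lagged linear generative model behind one synthetic
#' recording; build it with [couplingSpec()]. Validity enforces named
#' per-channel parameters, strengths in \[0, 1\], positive integer lags and
#' stationarity (companion-matrix spectral radius below 1).
#'
#' @slot channels ordered channel names
#' @slot edges data.frame of directed couplings (`source`, `target`, `lag`,
#'   `strength`)
#' @slot ar,noiseSd,mean,scale named per-channel dynamics parameters
#' @seealso [couplingSpec()], [simulateRecording()]
#' @export
setClass("CouplingSpec",
  representation(
    channels = "character",
    edges    = "data.frame",   # source, target, lag, strength
    ar       = "numeric",      # per-channel AR(1) coefficient, in [0, 1)
    noiseSd  = "numeric",      # per-channel innovation SD, channel units
    mean     = "numeric",      # per-channel level, physiological units
    scale    = "numeric"       # per-channel dynamic scale (typical SD)
  )
)

setValidity("CouplingSpec", function(object) {
  msg <- character()
  ch <- object@channels
  if (length(ch) < 1L || anyDuplicated(ch) > 0L)
    msg <- c(msg, "channels must be non-empty and unique")
  for (slot in c("ar", "noiseSd", "mean", "scale")) {
    v <- slot(object, slot)
    if (!identical(names(v), ch))
      msg <- c(msg, sprintf("'%s' must be named exactly by the channels", slot))
  }
  e <- object@edges
  need <- c("source", "target", "lag", "strength")
  if (!all(need %in% names(e))) {
    msg <- c(msg, "edges must have columns source, target, lag, strength")
  } else if (nrow(e) > 0L) {
    if (!all(e$source %in% ch) || !all(e$target %in% ch))
      msg <- c(msg, "edge endpoints must be declared channels")
    if (any(e$lag < 1L) || any(e$lag != round(e$lag)))
      msg <- c(msg, "edge lags must be positive integers (no lag-0 self loops)")
    if (any(e$strength < 0) || any(e$strength > 1))
      msg <- c(msg, "edge strengths must lie in [0, 1]")
  }
  if (length(msg) == 0L) {
    if (any(object@ar < 0) || any(object@ar >= 1))
      msg <- c(msg, "ar coefficients must lie in [0, 1)")
    if (any(object@noiseSd <= 0)) msg <- c(msg, "noiseSd must be positive")
    if (any(object@scale <= 0)) msg <- c(msg, "scale must be positive")
    rho <- spectralRadius(object)
    if (!is.finite(rho) || rho >= 1)
      msg <- c(msg, sprintf(
        "coupling system is not stationary (spectral radius %.3f >= 1)", rho))
  }
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## CohortSpec: study design for a synthetic cohort
## ---------------------------------------------------------------------------

#' Synthetic study-cohort specification
#'
#' S4 container for a crossover design (participants x conditions x phases)
#' with condition-dependent coupling multipliers and a logistic symptom
#' model; build it with [cohortSpec()]. The seed fully determines every
#' generated recording and flag.
#'
#' @slot nParticipants,conditions,phases design dimensions
#' @slot rfMean,rfSd,windowMinutes breathing-frequency distribution and
#'   window length
#' @slot coupling baseline [CouplingSpec-class]
#' @slot conditionMultipliers,exerciseMultiplier,decoupledExercise
#'   condition/phase effects on the couplings
#' @slot symptomIntercepts,symptomSlope,headacheIntercepts logistic symptom
#'   model
#' @slot jitterBreaths,seed sampling-jitter flag and master seed
#' @seealso [cohortSpec()], [generateCohort()]
#' @export
setClass("CohortSpec",
  representation(
    nParticipants        = "integer",
    conditions           = "character",
    phases               = "character",
    rfMean               = "numeric",   # breaths / min
    rfSd                 = "numeric",
    windowMinutes        = "numeric",
    coupling             = "CouplingSpec",
    conditionMultipliers = "numeric",   # scales all edge strengths, per condition
    exerciseMultiplier   = "numeric",   # extra strength scaling in the exercise phase
    decoupledExercise    = "character", # conditions whose exercise edges are rewired
    symptomIntercepts    = "numeric",   # per-condition logit intercept
    symptomSlope         = "numeric",   # logit slope on ground-truth total coupling
    headacheIntercepts   = "numeric",
    jitterBreaths        = "logical",   # Gamma inter-breath-interval jitter flag
    seed                 = "integer"
  )
)

setValidity("CohortSpec", function(object) {
  msg <- character()
  if (object@nParticipants < 1L) msg <- c(msg, "nParticipants must be >= 1")
  if (length(object@conditions) < 1L) msg <- c(msg, "need >= 1 condition")
  if (!all(object@phases %in% phaseLevels()))
    msg <- c(msg, "phases must be drawn from phaseLevels()")
  if (object@rfMean <= 0 || object@rfSd < 0 || object@windowMinutes <= 0)
    msg <- c(msg, "rfMean, windowMinutes must be positive; rfSd non-negative")
  if (object@rfMean * object@windowMinutes < 30)
    msg <- c(msg, "rfMean * windowMinutes must give >= 30 samples for TE estimation")
  for (slot in c("conditionMultipliers", "symptomIntercepts", "headacheIntercepts")) {
    v <- slot(object, slot)
    if (!identical(sort(names(v)), sort(object@conditions)))
      msg <- c(msg, sprintf("'%s' must be named by the conditions", slot))
  }
  if (any(object@conditionMultipliers < 0))
    msg <- c(msg, "conditionMultipliers must be non-negative")
  if (!all(object@decoupledExercise %in% object@conditions))
    msg <- c(msg, "decoupledExercise must name declared conditions")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## BreathRecording: 7 parallel event-sampled channels + labels
## ---------------------------------------------------------------------------

#' One participant's breath-by-breath recording
#'
#' S4 container for the seven parallel event-sampled channels of one
#' recording window, with participant/condition/phase labels. Sampling is
#' event-based: one row per respiratory cycle, indexed by a strictly
#' increasing 0-based breath index shared by all channels.
#'
#' @slot participantId participant label
#' @slot condition one of [conditionLevels()]
#' @slot phase one of [phaseLevels()]
#' @slot channels numeric matrix, breaths x channels
#' @slot breathIndex 0-based integer breath index
#' @seealso [simulateRecording()], [readRecording()], [accessors]
#' @export
setClass("BreathRecording",
  representation(
    participantId = "character",
    condition     = "character",
    phase         = "character",
    channels      = "matrix",    # breaths x channels, channel names as colnames
    breathIndex   = "integer"    # 0-based, strictly increasing
  )
)

setValidity("BreathRecording", function(object) {
  msg <- character()
  m <- object@channels
  if (is.null(colnames(m)) || anyDuplicated(colnames(m)) > 0L)
    msg <- c(msg, "channels matrix must have unique column names")
  if (nrow(m) < 1L) msg <- c(msg, "recording must contain at least one breath")
  if (length(object@breathIndex) != nrow(m))
    msg <- c(msg, "breathIndex must align with the channel rows")
  else if (nrow(m) > 1L && any(diff(object@breathIndex) <= 0L))
    msg <- c(msg, "breathIndex must be strictly increasing")
  if (!object@condition %in% conditionLevels())
    msg <- c(msg, "condition must be one of conditionLevels()")
  if (!object@phase %in% phaseLevels())
    msg <- c(msg, "phase must be one of phaseLevels()")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## TEMatrix: directed, weighted, zero-diagonal adjacency of significant TE
## ---------------------------------------------------------------------------

#' Directed significant-TE adjacency matrix
#'
#' S4 container for one network: `weights[i, j]` holds the
#' surrogate-significant transfer entropy from node i to node j in bits
#' (zero where the surrogate test failed), with a zero diagonal. Build it
#' with [teMatrix()] or [participantNetwork()].
#'
#' @slot nodes node (channel) names, fixed order
#' @slot weights non-negative numeric matrix, zero diagonal
#' @slot participantId participant label, or `"group"` for pooled medians
#' @slot condition,phase experimental labels
#' @seealso [participantNetwork()], [weightedDegrees()], [wjsi()]
#' @export
setClass("TEMatrix",
  representation(
    nodes         = "character",
    weights       = "matrix",     # weights[i, j] = TE(node_i -> node_j), bits
    participantId = "character",  # or "group"
    condition     = "character",
    phase         = "character"
  )
)

setValidity("TEMatrix", function(object) {
  msg <- character()
  w <- object@weights
  k <- length(object@nodes)
  if (nrow(w) != k || ncol(w) != k)
    msg <- c(msg, "weights must be square with one row/column per node")
  if (!identical(rownames(w), object@nodes) ||
      !identical(colnames(w), object@nodes))
    msg <- c(msg, "weights dimnames must equal the node names")
  if (any(!is.finite(w))) msg <- c(msg, "weights must be finite")
  else {
    if (any(w < 0)) msg <- c(msg, "weights must be non-negative (bits)")
    if (any(diag(w) != 0)) msg <- c(msg, "diagonal must be zero (no self edges)")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "BreathRecording", function(object) {
  cat(sprintf("BreathRecording '%s' [%s / %s]: %d breaths x %d channels\n",
              object@participantId, object@condition, object@phase,
              nrow(object@channels), ncol(object@channels)))
  cat("  channels:", paste(colnames(object@channels), collapse = ", "), "\n")
})

setMethod("show", "TEMatrix", function(object) {
  nz <- sum(object@weights > 0)
  cat(sprintf("TEMatrix '%s' [%s / %s]: %d nodes, %d significant edges, total TE %.3f bits\n",
              object@participantId, object@condition, object@phase,
              length(object@nodes), nz, sum(object@weights)))
})

setMethod("show", "CouplingSpec", function(object) {
  cat(sprintf("CouplingSpec: %d channels, %d directed lagged couplings (spectral radius %.3f)\n",
              length(object@channels), nrow(object@edges), spectralRadius(object)))
})

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf("CohortSpec: %d participants x {%s} x {%s}, %g-min windows, seed %d\n",
              object@nParticipants, paste(object@conditions, collapse = ", "),
              paste(object@phases, collapse = ", "), object@windowMinutes,
              object@seed))
})
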