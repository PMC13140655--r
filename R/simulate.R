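## Synthetic-cohort generator: coupled lagged-autoregressive breath-sampled
## series with known ground-truth directed couplings, condition effects,
## artifacts and symptom labels.

#' Specify a ground-truth coupled system
#'
#' A `CouplingSpec` describes the linear lagged scheme that generates one
#' multichannel breath-by-breath recording:
#' \deqn{x_j[t] = \mu_j + a_j (x_j[t-1] - \mu_j) +
#'   \sum_{i \to j} s_{ij} (x_i[t-\lambda_{ij}] - \mu_i) \sigma_j/\sigma_i +
#'   \epsilon_j[t]}
#' i.e. each channel is AR(1) around its physiological level \eqn{\mu_j},
#' plus cross-channel couplings of strength \eqn{s_{ij} \in [0,1]} acting at a
#' lag of \eqn{\lambda_{ij} \ge 1} respiratory cycles, rescaled by the ratio of
#' channel scales so that strengths are comparable across channels. The implied
#' vector-autoregression must be stationary (spectral radius of the companion
#' matrix < 1), which is enforced at construction.
#'
#' @param channels ordered channel names (default [teChannels()])
#' @param edges data.frame with columns `source`, `target`, `lag`
#'   (respiratory cycles, positive integer) and `strength` (in \[0, 1\])
#' @param ar per-channel AR(1) coefficient in \[0, 1); recycled if scalar
#' @param noiseSd per-channel innovation SD in channel units; recycled
#' @param mean,scale per-channel level and dynamic scale in physiological
#'   units; recycled
#' @return a validated [CouplingSpec-class] object
#' @seealso [defaultCoupling()] for the package's reference cardiorespiratory
#'   topology, [simulateRecording()] to draw series from a spec.
#' @export
#' @examples
#' sp <- couplingSpec(edges = data.frame(source = "HR", target = "RF",
#'                                       lag = 5, strength = 0.8))
#' sp
couplingSpec <- function(channels = teChannels(),
                         edges = data.frame(source = character(),
                                            target = character(),
                                            lag = integer(),
                                            strength = numeric()),
                         ar = 0.5,
                         noiseSd = NULL,
                         mean = NULL,
                         scale = NULL) {
  k <- length(channels)
  defMean  <- c(HR = 80, RF = 16, VE = 12, VT = 0.75, VO2 = 0.35,
                PETO2 = 100, PETCO2 = 38)
  defScale <- c(HR = 5, RF = 2, VE = 2, VT = 0.08, VO2 = 0.05,
                PETO2 = 3, PETCO2 = 1.5)
  fill <- function(x, default) {
    if (is.null(x)) x <- default
    if (length(x) == 1L && k > 1L) x <- rep(x, k)
    if (is.null(names(x)) || !all(channels %in% names(x)))
      names(x) <- channels
    x[channels]
  }
  mean  <- fill(mean, if (all(channels %in% names(defMean))) defMean[channels] else 0)
  scale <- fill(scale, if (all(channels %in% names(defScale))) defScale[channels] else 1)
  ar    <- fill(ar, 0.5)
  noiseSd <- fill(noiseSd, 0.5 * scale)
  edges$lag <- as.integer(edges$lag)
  new("CouplingSpec", channels = channels, edges = edges, ar = ar,
      noiseSd = noiseSd, mean = mean, scale = scale)
}

#' Reference cardiorespiratory coupling topology
#'
#' The default ground truth used by [cohortSpec()]: a set of directed lagged
#' couplings among the 7 channels chosen to mimic the qualitative structure of
#' resting cardiorespiratory control (end-tidal gas pressures driving heart
#' rate, tidal volume driving respiratory frequency, ventilation driving
#' end-tidal O2, and so on), with moderate strengths so the system is well
#' inside the stationary regime.
#'
#' @return a [CouplingSpec-class]
#' @export
defaultCoupling <- function() {
  edges <- data.frame(
    source   = c("PETCO2", "PETO2", "VT", "PETCO2", "VE",    "VT",    "PETCO2", "HR",  "RF", "VE"),
    target   = c("HR",     "HR",    "RF", "RF",     "PETO2", "PETO2", "VT",     "VO2", "VE", "PETCO2"),
    lag      = c(5L,       5L,      4L,   5L,       4L,      5L,      5L,       4L,    5L,   5L),
    strength = c(0.45,     0.45,    0.4,  0.4,      0.45,    0.4,     0.4,      0.4,   0.45, 0.4)
  )
  couplingSpec(edges = edges, ar = 0.35)
}

#' Spectral radius of the implied vector autoregression
#'
#' Builds the companion matrix of the linear lagged system a [CouplingSpec]
#' describes (on standardized deviations from channel means, where the AR and
#' coupling coefficients act directly) and returns the modulus of its largest
#' eigenvalue. Values below 1 mean the generated series are stationary.
#'
#' @param spec a [CouplingSpec-class]
#' @return non-negative real; `< 1` for a stationary system
#' @export
spectralRadius <- function(spec) {
  ch <- spec@channels
  k <- length(ch)
  p <- max(1L, if (nrow(spec@edges)) max(spec@edges$lag) else 1L)
  A <- array(0, dim = c(k, k, p))
  A[cbind(seq_len(k), seq_len(k), 1L)] <- spec@ar
  if (nrow(spec@edges)) {
    for (r in seq_len(nrow(spec@edges))) {
      i <- match(spec@edges$target[r], ch)
      j <- match(spec@edges$source[r], ch)
      l <- spec@edges$lag[r]
      A[i, j, l] <- A[i, j, l] + spec@edges$strength[r]
    }
  }
  comp <- matrix(0, k * p, k * p)
  for (l in seq_len(p)) comp[seq_len(k), (l - 1L) * k + seq_len(k)] <- A[, , l]
  if (p > 1L)
    comp[k + seq_len(k * (p - 1L)), seq_len(k * (p - 1L))] <-
      diag(k * (p - 1L))
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

#' Counter-based seed substreams
#'
#' Expands one master seed into deterministic per-use substreams (per
#' recording, per channel pair, ...) by hashing the integer counters given in
#' `...`. The result is always below 2^31 - 1, hence a valid R seed. All
#' randomness in the generator, the surrogate tests and the pipeline derives
#' from the master seed through this function, so any element of a run can be
#' reproduced in isolation.
#'
#' @param seed master integer seed
#' @param ... integer counters identifying the substream
#' @return an integer seed
#' @export
#' @examples
#' childSeed(1, 3, 2, 1)
childSeed <- function(seed, ...) {
  h <- as.numeric(seed) %% 2147483647
  for (k in c(...)) {
    h <- (h * 69069 + as.numeric(k) + 1) %% 2147483647
  }
  as.integer(h)
}

#' Simulate one breath-by-breath recording
#'
#' Draws `n = round(rf * window)` samples of every channel from the lagged
#' linear scheme in `spec`, after discarding a burn-in of at least ten times
#' the maximum coupling lag so the series start in their stationary regime.
#' Sampling is event-indexed: one sample per respiratory cycle, so the
#' sampling rate equals the breathing frequency `rf`.
#'
#' @param spec a [CouplingSpec-class]; must be stationary
#' @param rf breathing frequency, breaths per minute (> 0)
#' @param window window length in minutes
#' @param seed integer; fully determines the output
#' @param participantId,condition,phase labels attached to the recording
#' @return a [BreathRecording-class] with `round(rf * window)` breaths
#' @export
#' @examples
#' rec <- simulateRecording(defaultCoupling(), rf = 20, window = 5, seed = 1)
#' nBreaths(rec)  # 100
simulateRecording <- function(spec, rf, window = 5, seed = 1L,
                              participantId = "sim", condition = "CTR",
                              phase = "rest") {
  stopifnot(is(spec, "CouplingSpec"))
  validObject(spec)
  if (rf <= 0) stop("breathing frequency 'rf' must be positive")
  n <- as.integer(round(rf * window))
  maxLag <- max(1L, if (nrow(spec@edges)) max(spec@edges$lag) else 1L)
  if (n <= maxLag)
    stop(sprintf("window of %d breaths is too short for the maximum coupling lag (%d)",
                 n, maxLag))
  burn <- max(10L * maxLag, 100L)
  total <- n + burn
  ch <- spec@channels
  k <- length(ch)

  set.seed(childSeed(seed))
  ## simulate standardized deviations z, then map to channel units
  z <- matrix(0, nrow = total, ncol = k, dimnames = list(NULL, ch))
  sdz <- spec@noiseSd / spec@scale
  eps <- matrix(rnorm(total * k), total, k) %*% diag(sdz, k)
  e <- spec@edges
  ei <- if (nrow(e)) match(e$target, ch) else integer()
  ej <- if (nrow(e)) match(e$source, ch) else integer()
  for (t in seq_len(total)) {
    zt <- eps[t, ]
    if (t > 1L) zt <- zt + spec@ar * z[t - 1L, ]
    if (nrow(e)) {
      ok <- which(e$lag < t)
      if (length(ok)) {
        contrib <- e$strength[ok] * z[cbind(t - e$lag[ok], ej[ok])]
        for (r in seq_along(ok)) zt[ei[ok[r]]] <- zt[ei[ok[r]]] + contrib[r]
      }
    }
    z[t, ] <- zt
  }
  x <- sweep(sweep(z[burn + seq_len(n), , drop = FALSE], 2, spec@scale, "*"),
             2, spec@mean, "+")
  new("BreathRecording", participantId = participantId, condition = condition,
      phase = phase, channels = x, breathIndex = seq_len(n) - 1L)
}

#' Specify a synthetic study cohort
#'
#' Describes a crossover design: `nParticipants` participants, each recorded
#' under every condition and phase. Condition multipliers scale all coupling
#' strengths (emulating condition-dependent connectivity); conditions listed in
#' `decoupledExercise` use a deterministically rewired edge set during the
#' exercise phase, so their rest and exercise networks differ structurally and
#' not just in strength. Symptom and headache flags are drawn from logistic
#' models on the ground-truth total coupling strength.
#'
#' @param nParticipants number of participants (default 12)
#' @param conditions condition labels (default `CTR`, `HY1`, `HY2`)
#' @param phases phase labels (default rest and exercise)
#' @param rfMean,rfSd breathing-frequency distribution across recordings,
#'   breaths/min
#' @param windowMinutes recording window length (default 5); `rfMean *
#'   windowMinutes` must give at least 30 samples
#' @param coupling baseline [CouplingSpec-class] (default [defaultCoupling()])
#' @param conditionMultipliers named non-negative multipliers on edge strengths
#' @param exerciseMultiplier extra strength multiplier in the exercise phase
#' @param decoupledExercise conditions whose exercise-phase edge set is rewired
#' @param symptomIntercepts,symptomSlope per-condition logit intercepts and a
#'   common slope on ground-truth total coupling for the symptom model
#' @param headacheIntercepts per-condition logit intercepts for headache
#' @param jitterBreaths if `TRUE`, inter-breath intervals are Gamma-jittered
#'   (recorded in `breathIndex` spacing metadata only; sampling stays
#'   event-indexed)
#' @param seed integer; fully determines the cohort
#' @return a validated [CohortSpec-class]
#' @export
cohortSpec <- function(nParticipants = 12L,
                       conditions = conditionLevels(),
                       phases = phaseLevels(),
                       rfMean = 16, rfSd = 3,
                       windowMinutes = 5,
                       coupling = defaultCoupling(),
                       conditionMultipliers = c(CTR = 1, HY1 = 0.5, HY2 = 0.9),
                       exerciseMultiplier = 1.1,
                       decoupledExercise = "HY1",
                       symptomIntercepts = qlogis(c(CTR = 4, HY1 = 6, HY2 = 8) / 12),
                       symptomSlope = 0,
                       headacheIntercepts = qlogis(c(CTR = 2, HY1 = 3, HY2 = 2) / 12),
                       jitterBreaths = FALSE,
                       seed = 1L) {
  keep <- intersect(names(conditionMultipliers), conditions)
  if (length(keep) < length(conditions) &&
      !all(conditions %in% names(conditionMultipliers)))
    conditionMultipliers <- setNames(rep(1, length(conditions)), conditions)
  new("CohortSpec",
      nParticipants = as.integer(nParticipants),
      conditions = conditions, phases = phases,
      rfMean = rfMean, rfSd = rfSd, windowMinutes = windowMinutes,
      coupling = coupling,
      conditionMultipliers = conditionMultipliers[conditions],
      exerciseMultiplier = exerciseMultiplier,
      decoupledExercise = decoupledExercise,
      symptomIntercepts = symptomIntercepts[conditions],
      symptomSlope = symptomSlope,
      headacheIntercepts = headacheIntercepts[conditions],
      jitterBreaths = isTRUE(jitterBreaths),
      seed = as.integer(seed))
}

## Deterministic rewiring used for "decoupled" exercise phases: every edge's
## target is shifted three places along the fixed channel order (skipping the
## source), so the exercise network shares few directed edges with rest while
## the implied system stays stationary.
rewireEdges <- function(edges, channels) {
  if (!nrow(edges)) return(edges)
  k <- length(channels)
  for (r in seq_len(nrow(edges))) {
    ti <- match(edges$target[r], channels)
    si <- match(edges$source[r], channels)
    nt <- (ti - 1L + 3L) %% k + 1L
    if (nt == si) nt <- nt %% k + 1L
    edges$target[r] <- channels[nt]
  }
  edges
}

## CouplingSpec for one condition x phase cell of a cohort
conditionCoupling <- function(spec, cond, ph) {
  base <- spec@coupling
  e <- base@edges
  mult <- spec@conditionMultipliers[[cond]]
  if (ph == "exercise") {
    mult <- mult * spec@exerciseMultiplier
    if (cond %in% spec@decoupledExercise)
      e <- rewireEdges(e, base@channels)
  }
  e$strength <- pmin(1, e$strength * mult)
  couplingSpec(channels = base@channels, edges = e, ar = base@ar,
               noiseSd = base@noiseSd, mean = base@mean, scale = base@scale)
}

#' Generate a synthetic cohort
#'
#' Draws every participant x condition x phase recording from the design in a
#' [CohortSpec-class], via deterministic per-recording seed substreams, and
#' assembles the cohort table skeleton: participant id, sex label, condition,
#' ground-truth total coupling strength, and Bernoulli symptom / headache
#' flags from the logistic symptom model.
#'
#' @param spec a [CohortSpec-class]
#' @param recordings if `FALSE`, skip simulating the series and return only
#'   the cohort table (useful for calibration studies of the symptom model);
#'   the table is identical either way because symptom draws use their own
#'   seed substream
#' @return list with elements `recordings` (named list of
#'   [BreathRecording-class], names `participant.condition.phase`), `table`
#'   (data.frame, one row per participant x condition) and `spec`
#' @export
#' @examples
#' co <- generateCohort(cohortSpec(nParticipants = 2, seed = 7))
#' length(co$recordings)  # 2 x 3 x 2 = 12
generateCohort <- function(spec, recordings = TRUE) {
  validObject(spec)
  recs <- list()
  rows <- list()
  nP <- spec@nParticipants
  sexes <- rep(c("F", "M"), length.out = nP)
  for (p in seq_len(nP)) {
    pid <- sprintf("P%02d", p)
    for (ci in seq_along(spec@conditions)) {
      cond <- spec@conditions[ci]
      truthTotal <- 0
      for (phi in seq_along(spec@phases)) {
        ph <- spec@phases[phi]
        cc <- conditionCoupling(spec, cond, ph)
        truthTotal <- truthTotal + sum(cc@edges$strength)
        if (recordings) {
          rfSeed <- childSeed(spec@seed, 1L, p, ci, phi)
          set.seed(rfSeed)
          rf <- max(8, rnorm(1, spec@rfMean, spec@rfSd))
          recs[[paste(pid, cond, ph, sep = ".")]] <-
            simulateRecording(cc, rf = rf, window = spec@windowMinutes,
                              seed = childSeed(spec@seed, 2L, p, ci, phi),
                              participantId = pid, condition = cond, phase = ph)
        }
      }
      truthTotal <- truthTotal / length(spec@phases)
      set.seed(childSeed(spec@seed, 3L, p, ci))
      pSym <- plogis(spec@symptomIntercepts[[cond]] +
                       spec@symptomSlope * truthTotal)
      pHead <- plogis(spec@headacheIntercepts[[cond]])
      rows[[length(rows) + 1L]] <- data.frame(
        participant = pid, sex = sexes[p], condition = cond,
        totalCouplingTruth = truthTotal,
        symptom = rbinom(1, 1, pSym) == 1,
        headache = rbinom(1, 1, pHead) == 1,
        stringsAsFactors = FALSE)
    }
  }
  list(recordings = recs, table = do.call(rbind, rows), spec = spec)
}

#' Inject outlier artifacts into a series or recording
#'
#' Replaces a `rate` fraction of samples (chosen uniformly at random) with
#' spikes at `value +/- magnitude * MAD` of the series, returning both the
#' corrupted data and the ground-truth artifact indices so outlier-detection
#' stages can be scored.
#'
#' @param object numeric series or [BreathRecording-class]
#' @param rate fraction of samples to corrupt, in \[0, 0.2)
#' @param magnitude spike size in multiples of the series MAD
#' @param seed integer seed
#' @return for a numeric series, `list(values, indices)`; for a recording,
#'   `list(recording, indices)` where `indices` is a per-channel list
#' @rdname injectArtifacts
#' @export
setMethod("injectArtifacts", "numeric", function(object, rate, magnitude = 10,
                                                 seed = 1L) {
  if (rate < 0 || rate >= 0.2)
    stop("artifact rate must lie in [0, 0.2)")
  n <- length(object)
  k <- as.integer(round(rate * n))
  if (k == 0L) return(list(values = object, indices = integer()))
  set.seed(childSeed(seed))
  idx <- sort(sample.int(n, k))
  s <- mad(object)
  if (s == 0) s <- max(abs(object), 1)
  sgn <- ifelse(runif(k) < 0.5, -1, 1)
  object[idx] <- object[idx] + sgn * magnitude * s
  list(values = object, indices = idx)
})

#' @rdname injectArtifacts
#' @export
setMethod("injectArtifacts", "BreathRecording",
  function(object, rate, magnitude = 10, seed = 1L) {
    ch <- colnames(object@channels)
    idxList <- list()
    for (j in seq_along(ch)) {
      r <- injectArtifacts(object@channels[, j], rate, magnitude,
                           seed = childSeed(seed, j))
      object@channels[, j] <- r$values
      idxList[[ch[j]]] <- r$indices
    }
    list(recording = object, indices = idxList)
  })
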