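## End-to-end pipeline: recordings (synthetic or from a manifest) ->
## preprocessing -> surrogate-thresholded TE networks -> group medians and
## degree rankings -> individual similarity table -> cohort statistics.

#' Pipeline configuration
#'
#' Collects every tunable of the pipeline in one validated list; a run writes
#' the resolved configuration beside its outputs. `readPipelineConfig` loads
#' the same structure from a YAML or JSON file.
#'
#' @param channels channel names (default [teChannels()])
#' @param lag,partition,nBins TE settings, see [teConfig()]
#' @param nShuffles,percentile surrogate settings, see [surrogateTest()]
#' @param hampelWindow,hampelThreshold preprocessing settings, see
#'   [detectOutliers()]
#' @param ggThreshold Mauchly p-value threshold for the Greenhouse-Geisser
#'   correction
#' @param outputDir where [runPipeline()] writes its bundle
#' @param seed integer master seed; all surrogate randomness derives from it
#'   through per-recording, per-pair substreams
#' @return list of class `"PipelineConfig"`
#' @export
pipelineConfig <- function(channels = teChannels(), lag = 5L,
                           partition = "quantile", nBins = 6L,
                           nShuffles = 100L, percentile = 95,
                           hampelWindow = 11L, hampelThreshold = 3,
                           ggThreshold = 0.05,
                           outputDir = "breathTE-output", seed = 1L) {
  cfg <- list(channels = channels, lag = as.integer(lag),
              partition = partition, nBins = as.integer(nBins),
              nShuffles = as.integer(nShuffles), percentile = percentile,
              hampelWindow = as.integer(hampelWindow),
              hampelThreshold = hampelThreshold,
              ggThreshold = ggThreshold, outputDir = outputDir,
              seed = as.integer(seed))
  validatePipelineConfig(cfg)
  structure(cfg, class = "PipelineConfig")
}

validatePipelineConfig <- function(cfg) {
  need <- c("channels", "lag", "partition", "nBins", "nShuffles",
            "percentile", "hampelWindow", "hampelThreshold", "ggThreshold",
            "outputDir", "seed")
  missing <- setdiff(need, names(cfg))
  if (length(missing))
    stop("pipeline config is missing field(s): ",
         paste(missing, collapse = ", "))
  teConfig(lag = cfg$lag, partition = cfg$partition, nBins = cfg$nBins)
  if (cfg$nShuffles < 20L) stop("nShuffles must be >= 20")
  if (cfg$hampelWindow < 3L || cfg$hampelWindow %% 2L == 0L)
    stop("hampelWindow must be an odd integer >= 3")
  invisible(TRUE)
}

#' @rdname pipelineConfig
#' @param path YAML (or JSON) configuration file
#' @export
readPipelineConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipelineConfig, raw)
}

#' Run the full analysis pipeline
#'
#' From a cohort of recordings to the complete output bundle: each recording
#' is Hampel-cleaned, its 42 directed channel pairs are estimated and
#' surrogate-thresholded into a per-recording network, group median networks
#' and in/out-degree rankings are computed per condition x phase, the nine
#' standard similarity comparisons are evaluated per participant, and the
#' cohort statistics are run (repeated-measures ANOVAs on the three WJSI
#' families, chi-square of symptom occurrence against control, McNemar tests
#' for headache, total-TE correlation matrix, and per-condition logistic
#' symptom regressions on rest and exercise total TE). Everything is
#' deterministic given `config$seed`; recordings that fail to load are
#' quarantined with a message and the run continues.
#'
#' @param config a [pipelineConfig()]
#' @param cohort a cohort as returned by [generateCohort()]; alternatively
#'   supply `manifestPath`
#' @param manifestPath path to a cohort manifest (see [writeCohort()]);
#'   recordings are read relative to its directory
#' @param writeOutputs if `TRUE` (default), write networks, tables and a JSON
#'   report plus the resolved config under `config$outputDir`
#' @return (invisibly) list with `networks`, `groupNetworks`, `rankings`,
#'   `similarities`, `totalTe`, `anova`, `symptomTests`, `correlations`,
#'   `regressions`, `failures`, `timings`
#' @export
runPipeline <- function(config, cohort = NULL, manifestPath = NULL,
                        writeOutputs = TRUE) {
  validatePipelineConfig(config)
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[[stage]] <<- t1 - t0
    t0 <<- t1
  }
  failures <- character()
  symptoms <- NULL

  if (is.null(cohort) && is.null(manifestPath))
    stop("supply either a cohort or a manifestPath")
  if (is.null(cohort)) {
    man <- readManifest(manifestPath)
    base <- dirname(manifestPath)
    recs <- list()
    for (r in seq_len(nrow(man))) {
      key <- paste(man$participant[r], man$condition[r], man$phase[r],
                   sep = ".")
      rec <- tryCatch(
        readRecording(file.path(base, man$file[r]),
                      participantId = man$participant[r],
                      condition = man$condition[r], phase = man$phase[r]),
        error = function(e) {
          failures <<- c(failures,
                         sprintf("%s: %s", key, conditionMessage(e)))
          NULL
        })
      if (!is.null(rec)) recs[[key]] <- rec
    }
    symptoms <- unique(man[, intersect(c("participant", "condition",
                                         "symptom", "headache"),
                                       names(man))])
    cohort <- list(recordings = recs, table = symptoms)
  } else if (!is.null(cohort$table)) {
    symptoms <- cohort$table
  }
  tick("load")

  tcfg <- teConfig(lag = config$lag, partition = config$partition,
                   nBins = config$nBins)
  allParticipants <- unique(vapply(cohort$recordings, participantId,
                                   character(1)))
  networks <- list()
  for (key in names(cohort$recordings)) {
    raw <- cohort$recordings[[key]]
    rec <- preprocessRecording(raw, window = config$hampelWindow,
                               threshold = config$hampelThreshold)
    networks[[key]] <- participantNetwork(
      rec, config = tcfg, nShuffles = config$nShuffles,
      percentile = config$percentile,
      seed = childSeed(config$seed,
                       match(participantId(raw), allParticipants),
                       match(condition(raw), conditionLevels()),
                       match(phase(raw), phaseLevels())))
  }
  tick("networks")

  keys <- names(networks)
  meta <- do.call(rbind, lapply(keys, function(k) {
    m <- networks[[k]]
    data.frame(key = k, participant = participantId(m),
               condition = condition(m), phase = phase(m),
               totalTe = totalTE(m), stringsAsFactors = FALSE)
  }))

  cells <- unique(meta[, c("condition", "phase")])
  groupNetworks <- list()
  rankings <- list()
  for (r in seq_len(nrow(cells))) {
    sel <- meta$condition == cells$condition[r] & meta$phase == cells$phase[r]
    gm <- groupMedianNetwork(networks[meta$key[sel]])
    cellName <- paste(cells$condition[r], cells$phase[r], sep = ".")
    groupNetworks[[cellName]] <- gm
    deg <- weightedDegrees(gm)
    rankings[[cellName]] <- list(ID = rankNodes(deg, "ID"),
                                 OD = rankNodes(deg, "OD"))
  }
  tick("groups")

  participants <- unique(meta$participant)
  simRows <- list()
  for (p in participants) {
    nets <- networks[meta$key[meta$participant == p]]
    names(nets) <- paste(meta$condition[meta$participant == p],
                         meta$phase[meta$participant == p], sep = ".")
    simRows[[p]] <- tryCatch(similarityTable(nets), error = function(e) NULL)
  }
  simRows <- simRows[!vapply(simRows, is.null, logical(1))]
  similarities <- if (length(simRows)) do.call(rbind, simRows) else NULL

  totalTe <- meta[, c("participant", "condition", "phase", "totalTe")]

  anova <- list()
  symptomTests <- list()
  correlations <- NULL
  regressions <- list()
  if (!is.null(similarities) && nrow(similarities) >= 3 &&
      all(comparisonSchema()$name %in% colnames(similarities))) {
    anova$restExercise <- rmAnovaGG(
      similarities[, c("restExercise.CTR", "restExercise.HY1",
                       "restExercise.HY2")], config$ggThreshold)
    anova$rest <- rmAnovaGG(
      similarities[, c("CTR-HY1.rest", "CTR-HY2.rest", "HY1-HY2.rest")],
      config$ggThreshold)
    anova$exercise <- rmAnovaGG(
      similarities[, c("CTR-HY1.exercise", "CTR-HY2.exercise",
                       "HY1-HY2.exercise")], config$ggThreshold)
  }

  teWide <- tryCatch({
    w <- matrix(NA_real_, length(participants), nrow(cells),
                dimnames = list(participants,
                                paste(cells$condition, cells$phase, sep = ".")))
    for (r in seq_len(nrow(meta)))
      w[meta$participant[r],
        paste(meta$condition[r], meta$phase[r], sep = ".")] <- meta$totalTe[r]
    w
  }, error = function(e) NULL)
  if (!is.null(teWide) && !anyNA(teWide) && nrow(teWide) >= 3)
    correlations <- tryCatch(correlationMatrix(teWide), error = function(e) {
      failures <<- c(failures, paste("correlation matrix:",
                                     conditionMessage(e)))
      NULL
    })

  if (!is.null(symptoms) && all(c("participant", "condition", "symptom")
                                %in% names(symptoms))) {
    getFlags <- function(cond, col)
      symptoms[[col]][symptoms$condition == cond][
        match(participants, symptoms$participant[symptoms$condition == cond])]
    ctrYes <- sum(getFlags("CTR", "symptom"), na.rm = TRUE)
    nP <- length(participants)
    for (cond in setdiff(unique(symptoms$condition), "CTR")) {
      symptomTests[[paste0("chiSq.", cond)]] <- tryCatch(
        chiSquareVsControl(ctrYes, sum(getFlags(cond, "symptom"),
                                       na.rm = TRUE), nP),
        error = function(e) conditionMessage(e))
      if ("headache" %in% names(symptoms))
        symptomTests[[paste0("mcnemar.headache.", cond)]] <-
          mcnemarTest(getFlags("CTR", "headache"), getFlags(cond, "headache"))
    }
    if (!is.null(teWide) && !anyNA(teWide)) {
      for (cond in unique(symptoms$condition)) {
        y <- getFlags(cond, "symptom")
        X <- teWide[, paste(cond, c("rest", "exercise"), sep = "."),
                    drop = FALSE]
        colnames(X) <- c("rest", "exercise")
        regressions[[cond]] <- tryCatch(
          logisticSymptomRegression(X, y), error = function(e)
            conditionMessage(e))
      }
    }
  }
  tick("stats")

  bundle <- list(networks = networks, groupNetworks = groupNetworks,
                 rankings = rankings, similarities = similarities,
                 totalTe = totalTe, anova = anova,
                 symptomTests = symptomTests, correlations = correlations,
                 regressions = regressions, failures = failures,
                 timings = timings, config = config)

  if (writeOutputs) {
    dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)
    netDir <- file.path(config$outputDir, "networks")
    dir.create(netDir, showWarnings = FALSE)
    for (key in names(networks))
      writeAdjacency(networks[[key]], file.path(netDir, paste0(key, ".csv")))
    for (cellName in names(groupNetworks)) {
      writeAdjacency(groupNetworks[[cellName]],
                     file.path(config$outputDir,
                               paste0("group.", cellName, ".csv")))
      writeGraphml(groupNetworks[[cellName]],
                   file.path(config$outputDir,
                             paste0("group.", cellName, ".graphml")))
    }
    if (!is.null(similarities))
      write.csv(data.frame(participant = rownames(similarities),
                           similarities, check.names = FALSE),
                file.path(config$outputDir, "similarities.csv"),
                row.names = FALSE)
    report <- list(
      package = as.character(packageVersion("breathTE")),
      seed = config$seed,
      rankings = rankings,
      anova = lapply(anova, function(a) unclass(a)),
      symptomTests = lapply(symptomTests, function(s)
        if (is.character(s)) s else unclass(s)[setdiff(names(s), "fit")]),
      regressions = lapply(regressions, function(s)
        if (is.character(s)) s else unclass(s)[setdiff(names(s), "fit")]),
      failures = failures, timings = as.list(timings))
    jsonlite::write_json(report,
                         file.path(config$outputDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    yaml::write_yaml(unclass(config),
                     file.path(config$outputDir, "config.yaml"))
  }
  invisible(bundle)
}
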