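## File I/O: delimited breath-by-breath recordings, cohort manifests,
## adjacency CSV (canonical interchange), edge-list JSON, GraphML, and
## diagram-data export. No operation mutates its inputs on disk.

recordingColumns <- function() c("breath_index", teChannels())

#' Write / read a breath-by-breath recording
#'
#' Recordings are exchanged as delimited text with one row per respiratory
#' cycle: a `breath_index` column followed by the seven channel columns.
#' `readRecording` accepts a `columnMap` (named character vector,
#' `c(standardName = "vendorName")`) so vendor exports with different
#' headers can be ingested; it validates presence, uniqueness and
#' numericness of every required column.
#'
#' @param recording a [BreathRecording-class]
#' @param path file path
#' @param columnMap optional named character vector mapping standard column
#'   names to the file's column names
#' @param participantId,condition,phase labels for the returned recording
#' @return `readRecording`: a [BreathRecording-class];
#'   `writeRecording`: the path, invisibly
#' @export
writeRecording <- function(recording, path) {
  df <- data.frame(breath_index = recording@breathIndex,
                   recording@channels, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeRecording
#' @export
readRecording <- function(path, columnMap = NULL, participantId = "unknown",
                          condition = "CTR", phase = "rest") {
  if (!file.exists(path)) stop("recording file not found: ", path)
  df <- read.csv(path, check.names = FALSE)
  if (anyDuplicated(names(df)))
    stop("duplicate columns in ", path, ": ",
         paste(unique(names(df)[duplicated(names(df))]), collapse = ", "))
  need <- recordingColumns()
  if (!is.null(columnMap)) {
    for (std in names(columnMap)) {
      if (!columnMap[[std]] %in% names(df))
        stop("mapped column '", columnMap[[std]], "' missing from ", path)
      names(df)[names(df) == columnMap[[std]]] <- std
    }
  }
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("missing required column(s) in ", path, ": ",
         paste(missing, collapse = ", "))
  for (cn in need) {
    if (!is.numeric(df[[cn]]))
      stop("non-numeric values in column '", cn, "' of ", path)
  }
  new("BreathRecording", participantId = participantId,
      condition = condition, phase = phase,
      channels = as.matrix(df[teChannels()]),
      breathIndex = as.integer(df$breath_index))
}

#' Write a synthetic cohort to disk
#'
#' One delimited recording file per participant x condition x phase plus a
#' JSON manifest (participant id, sex, condition, phase, relative file path,
#' symptom/headache flags).
#'
#' @param cohort result of [generateCohort()]
#' @param dir output directory (created if needed)
#' @return the manifest path, invisibly
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (nm in names(cohort$recordings)) {
    rec <- cohort$recordings[[nm]]
    file <- paste0(nm, ".csv")
    writeRecording(rec, file.path(dir, file))
    tr <- cohort$table[cohort$table$participant == participantId(rec) &
                         cohort$table$condition == condition(rec), ]
    rows[[nm]] <- data.frame(
      participant = participantId(rec), sex = tr$sex[1],
      condition = condition(rec), phase = phase(rec), file = file,
      symptom = tr$symptom[1], headache = tr$headache[1],
      stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname writeCohort
#' @param path manifest path
#' @export
readManifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  jsonlite::fromJSON(path)
}

#' Adjacency-matrix CSV interchange
#'
#' The canonical on-disk form of a [TEMatrix-class]: a CSV with node names as
#' header row and first column, preceded by commented metadata lines
#' (`# participant=...`), so the full object round-trips.
#'
#' @param matrix a [TEMatrix-class]
#' @param path file path
#' @return `readAdjacency`: a [TEMatrix-class]; `writeAdjacency`: the path,
#'   invisibly
#' @export
writeAdjacency <- function(matrix, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# participant=%s", participantId(matrix)),
               sprintf("# condition=%s", condition(matrix)),
               sprintf("# phase=%s", phase(matrix))), con)
  w <- teWeights(matrix)
  writeLines(paste(c("node", colnames(w)), collapse = ","), con)
  for (i in seq_len(nrow(w)))
    writeLines(paste(c(rownames(w)[i],
                       format(w[i, ], digits = 17, scientific = TRUE,
                              trim = TRUE)),
                     collapse = ","), con)
  invisible(path)
}

#' @rdname writeAdjacency
#' @export
readAdjacency <- function(path) {
  if (!file.exists(path)) stop("adjacency file not found: ", path)
  hdr <- readLines(path, n = 10L)
  meta <- hdr[startsWith(hdr, "# ")]
  getMeta <- function(key, default) {
    m <- grep(paste0("^# ", key, "="), meta, value = TRUE)
    if (length(m)) sub(paste0("^# ", key, "="), "", m[1]) else default
  }
  df <- read.csv(path, comment.char = "#", check.names = FALSE)
  w <- as.matrix(df[, -1L, drop = FALSE])
  rownames(w) <- df[[1L]]
  teMatrix(w, nodes = colnames(w),
           participantId = getMeta("participant", "unknown"),
           condition = getMeta("condition", "CTR"),
           phase = getMeta("phase", "rest"))
}

#' Edge-list JSON export
#'
#' Writes nodes, metadata and all positive-weight directed edges
#' (`source`, `target`, `te_bits`) as JSON; round-trips through
#' `readEdgeList`.
#'
#' @param matrix a [TEMatrix-class]
#' @param path file path
#' @return `readEdgeList`: a [TEMatrix-class]; `writeEdgeList`: the path,
#'   invisibly
#' @export
writeEdgeList <- function(matrix, path) {
  w <- teWeights(matrix)
  idx <- which(w > 0, arr.ind = TRUE)
  edges <- data.frame(source = rownames(w)[idx[, 1L]],
                      target = colnames(w)[idx[, 2L]],
                      te_bits = w[idx])
  jsonlite::write_json(
    list(nodes = teNodes(matrix),
         metadata = list(participant = participantId(matrix),
                         condition = condition(matrix),
                         phase = phase(matrix)),
         edges = edges),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeEdgeList
#' @export
readEdgeList <- function(path) {
  obj <- jsonlite::fromJSON(path)
  k <- length(obj$nodes)
  w <- matrix(0, k, k, dimnames = list(obj$nodes, obj$nodes))
  e <- obj$edges
  if (length(e) && nrow(e))
    w[cbind(match(e$source, obj$nodes), match(e$target, obj$nodes))] <- e$te_bits
  teMatrix(w, nodes = obj$nodes,
           participantId = obj$metadata$participant,
           condition = obj$metadata$condition, phase = obj$metadata$phase)
}

#' GraphML export
#'
#' Exports the network as GraphML via igraph: nodes carry `name`, `indegree`
#' and `outdegree` attributes (bits); only edges with positive TE are kept,
#' with the weight stored as `te_bits`.
#'
#' @param matrix a [TEMatrix-class]
#' @param path file path
#' @return the path, invisibly
#' @export
writeGraphml <- function(matrix, path) {
  w <- teWeights(matrix)
  g <- igraph::graph_from_adjacency_matrix(w, mode = "directed",
                                           weighted = "te_bits", diag = FALSE)
  deg <- weightedDegrees(matrix)
  igraph::V(g)$indegree <- unname(deg$indegree)
  igraph::V(g)$outdegree <- unname(deg$outdegree)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Node-size-proportional diagram data
#'
#' Exports the data needed to draw the usual network diagram - node sizes
#' proportional to in- or out-degree, edge widths proportional to TE - as
#' JSON (rendering itself is left to the caller).
#'
#' @param matrix a [TEMatrix-class]
#' @param by size nodes by `"ID"` (in-degree) or `"OD"` (out-degree)
#' @param path file path
#' @return the path, invisibly
#' @export
writeDiagramData <- function(matrix, by = c("ID", "OD"), path) {
  by <- match.arg(by)
  deg <- weightedDegrees(matrix)
  v <- if (by == "ID") deg$indegree else deg$outdegree
  sizes <- if (max(v) > 0) v / max(v) else v
  w <- teWeights(matrix)
  idx <- which(w > 0, arr.ind = TRUE)
  widths <- if (length(idx) && max(w) > 0) w[idx] / max(w) else numeric()
  jsonlite::write_json(
    list(sizedBy = by,
         nodes = data.frame(node = teNodes(matrix), degree = unname(v),
                            size = unname(sizes)),
         edges = data.frame(source = rownames(w)[idx[, 1L]],
                            target = colnames(w)[idx[, 2L]],
                            te_bits = w[idx], width = widths)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Reference individual-level similarity table
#'
#' The published individual-level weighted Jaccard similarities of a
#' 12-participant normobaric-hypoxia crossover study (three conditions:
#' normoxic control and simulated altitudes of ~2500 m and ~3500 m; rest and
#' isometric-exercise phases), in the nine-comparison schema of
#' [comparisonSchema()], shipped as plain text with the package. Used as the
#' worked example for the cohort statistics.
#'
#' @return data.frame with a `sex` column and the nine WJSI columns
#' @export
#' @examples
#' ref <- referenceSimilarities()
#' colMeans(ref[, -1])
referenceSimilarities <- function() {
  path <- system.file("extdata", "reference_similarity.csv",
                      package = "breathTE", mustWork = TRUE)
  read.csv(path, check.names = FALSE)
}

#' @rdname referenceSimilarities
#' @return `referenceSymptomCounts`: data.frame of per-condition symptom and
#'   headache counts (of `n` participants) from the same study
#' @export
referenceSymptomCounts <- function() {
  data.frame(condition = conditionLevels(),
             symptoms = c(4L, 6L, 8L),
             headache = c(2L, 3L, 2L),
             n = 12L)
}
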