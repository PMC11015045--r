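#' @include AllClasses.R
NULL

# Session on-disk format: a directory of plain-text files.
#   behavior.csv     time_s, position_cm, velocity_cms, lick_analog, pump, lap
#   events.csv       neuron_id + one column per frame (deconvolved events)
#   neurons.csv      neuron_id, projecting
#   session.json     geometry + frame rate + scenario, schema versioned
#   ground_truth.json generator specs and event times (synthetic sessions)
# Numeric columns are written at full precision (%.17g) so a write/read
# round trip is bit-identical.

fmtFull <- function(x) {
  if (is.double(x)) formatC(x, format = "g", digits = 17) else x
}

#' Write a session to a directory of plain-text files
#'
#' @param session a \linkS4class{SpatialSession}.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSession <- function(session, dir) {
  stopifnot(is(session, "SpatialSession"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  beh <- behaviorFrames(session)
  behOut <- as.data.frame(lapply(beh, fmtFull), stringsAsFactors = FALSE)
  utils::write.csv(behOut, file.path(dir, "behavior.csv"),
                   row.names = FALSE, quote = FALSE)
  ev <- eventMatrix(session)
  evOut <- data.frame(neuron_id = rownames(ev),
                      apply(ev, 2, fmtFull), check.names = FALSE,
                      stringsAsFactors = FALSE)
  colnames(evOut) <- c("neuron_id", sprintf("f%d", seq_len(ncol(ev))))
  utils::write.csv(evOut, file.path(dir, "events.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(neuron_id = rownames(ev),
                              projecting = projecting(session)),
                   file.path(dir, "neurons.csv"), row.names = FALSE,
                   quote = FALSE)
  md <- metadata(session)
  meta <- list(schema_version = "1.0", frame_rate_hz = md$frameRate,
               belt_length_cm = md$beltLength, n_bins = md$nBins,
               reward_zone = md$rewardZone,
               texture_boundaries = md$textureBoundaries,
               scenario = md$scenario)
  jsonlite::write_json(meta, file.path(dir, "session.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  gt <- groundTruth(session)
  if (!is.null(gt)) {
    jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                         digits = NA, na = "null", null = "null",
                         dataframe = "columns")
  }
  invisible(dir)
}

#' Read a session written by [writeSession()]
#'
#' @param dir session directory.
#' @return a \linkS4class{SpatialSession}.
#' @export
readSession <- function(dir) {
  need <- c("behavior.csv", "events.csv", "neurons.csv", "session.json")
  miss <- need[!file.exists(file.path(dir, need))]
  if (length(miss))
    stop("session directory ", dir, " lacks: ", paste(miss, collapse = ", "))
  beh <- utils::read.csv(file.path(dir, "behavior.csv"))
  evDf <- utils::read.csv(file.path(dir, "events.csv"), check.names = FALSE)
  ev <- as.matrix(evDf[, -1, drop = FALSE])
  rownames(ev) <- evDf$neuron_id
  dimnames(ev) <- list(evDf$neuron_id, NULL)
  neurons <- utils::read.csv(file.path(dir, "neurons.csv"))
  meta <- jsonlite::read_json(file.path(dir, "session.json"),
                              simplifyVector = TRUE)
  gt <- NULL
  gtPath <- file.path(dir, "ground_truth.json")
  if (file.exists(gtPath)) {
    gt <- jsonlite::read_json(gtPath, simplifyVector = TRUE)
    if (!is.null(gt$specs)) gt$specs <- as.data.frame(gt$specs)
    if (!is.null(gt$rewardedLaps)) gt$rewardedLaps <- as.logical(gt$rewardedLaps)
  }
  SpatialSession(ev, beh, frameRate = meta$frame_rate_hz,
                 projecting = neurons$projecting,
                 beltLength = meta$belt_length_cm,
                 nBins = as.integer(meta$n_bins),
                 rewardZone = meta$reward_zone,
                 textureBoundaries = meta$texture_boundaries,
                 groundTruth = gt, scenario = meta$scenario)
}

#' Generate and write a scenario session
#'
#' Convenience wrapper: simulate a scenario session and persist it with
#' its ground truth. A session is never written without its ground truth.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param scenario scenario name (see [scenarioSpecs()]).
#' @param dir output directory.
#' @return the simulated \linkS4class{SpatialSession}, invisibly.
#' @export
generateSession <- function(config, scenario, dir) {
  ses <- simulateSession(config, scenario)
  writeSession(ses, dir)
  invisible(ses)
}
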