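#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @import SummarizedExperiment
#' @useDynLib placecode, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Simulation configuration for synthetic sessions
#'
#' Holds the task geometry and generator parameters for one synthetic
#' head-fixed session on a circular treadmill belt: a 360 cm belt divided
#' into 45 spatial bins of 8 cm, a 30 cm hidden reward zone (default
#' `[240, 270)` cm), six texture-zone boundaries, and the behavioral and
#' neural sampling parameters.
#'
#' @slot beltLength belt circumference in cm (default 360).
#' @slot nBins number of spatial bins (default 45; bin width 8 cm).
#' @slot frameRate imaging frame rate in Hz (default 15.2).
#' @slot nLaps number of laps to simulate.
#' @slot rewardZone half-open `[start, end)` reward zone in cm.
#' @slot textureBoundaries ordered belt positions (cm) of the texture-zone
#'   edges.
#' @slot meanSpeed mean running speed in cm/s.
#' @slot slowdownFactor multiplicative speed factor applied from 60 cm
#'   before the reward zone start to the zone end; in (0, 1].
#' @slot lickRampStart distance (cm) before the reward zone over which the
#'   appetitive lick rate ramps up (default 30, the anticipation zone).
#' @slot lickBaseRate baseline appetitive lick rate (licks/s) away from
#'   the ramp.
#' @slot lickMaxRate peak appetitive lick rate (licks/s) at the reward
#'   zone start; set equal to `lickBaseRate` for spatially flat licking.
#' @slot nNeurons number of simulated neurons.
#' @slot fractionProjecting fraction of neurons labeled as projection
#'   neurons.
#' @slot seed integer RNG seed; behavior and neural substreams are derived
#'   from it deterministically, so the behavioral trace does not depend on
#'   `nNeurons`.
#' @export
setClass("SimConfig", representation(
  beltLength = "numeric",
  nBins = "integer",
  frameRate = "numeric",
  nLaps = "integer",
  rewardZone = "numeric",
  textureBoundaries = "numeric",
  meanSpeed = "numeric",
  slowdownFactor = "numeric",
  lickRampStart = "numeric",
  lickBaseRate = "numeric",
  lickMaxRate = "numeric",
  nNeurons = "integer",
  fractionProjecting = "numeric",
  seed = "integer"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@beltLength <= 0) msg <- c(msg, "beltLength must be positive")
  if (object@nBins < 1) msg <- c(msg, "nBins must be >= 1")
  if (object@frameRate <= 0) msg <- c(msg, "frameRate must be positive")
  if (object@nLaps < 1) msg <- c(msg, "nLaps must be >= 1")
  rz <- object@rewardZone
  if (length(rz) != 2) msg <- c(msg, "rewardZone must have length 2")
  if (length(rz) == 2 && (any(rz < 0) || any(rz > object@beltLength)))
    msg <- c(msg, "reward zone exceeds belt bounds")
  if (length(rz) == 2 && rz[2] <= rz[1])
    msg <- c(msg, "rewardZone end must exceed start")
  if (object@slowdownFactor <= 0 || object@slowdownFactor > 1)
    msg <- c(msg, "slowdownFactor must be in (0, 1]")
  if (object@fractionProjecting < 0 || object@fractionProjecting > 1)
    msg <- c(msg, "fractionProjecting must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct a simulation configuration
#'
#' @param beltLength,nBins,frameRate,nLaps,rewardZone,textureBoundaries
#'   task geometry; see \linkS4class{SimConfig}.
#' @param meanSpeed,slowdownFactor,lickRampStart,lickBaseRate,lickMaxRate
#'   behavioral generator parameters.
#' @param nNeurons,fractionProjecting,seed neural generator parameters.
#' @return a validated \linkS4class{SimConfig}.
#' @examples
#' cfg <- simConfig(nLaps = 5, nNeurons = 10, seed = 1)
#' cfg
#' @export
simConfig <- function(beltLength = 360, nBins = 45L, frameRate = 15.2,
                      nLaps = 20L, rewardZone = c(240, 270),
                      textureBoundaries = c(0, 60, 120, 180, 240, 300),
                      meanSpeed = 15, slowdownFactor = 0.55,
                      lickRampStart = 30, lickBaseRate = 0.5,
                      lickMaxRate = 3.5, nNeurons = 50L,
                      fractionProjecting = 0.3, seed = 1L) {
  new("SimConfig",
      beltLength = beltLength, nBins = as.integer(nBins),
      frameRate = frameRate, nLaps = as.integer(nLaps),
      rewardZone = rewardZone, textureBoundaries = textureBoundaries,
      meanSpeed = meanSpeed, slowdownFactor = slowdownFactor,
      lickRampStart = lickRampStart, lickBaseRate = lickBaseRate,
      lickMaxRate = lickMaxRate, nNeurons = as.integer(nNeurons),
      fractionProjecting = fractionProjecting, seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@beltLength, "cm belt,", object@nBins, "bins,",
      object@nLaps, "laps @", object@frameRate, "Hz\n")
  cat("  reward zone [", object@rewardZone[1], ",", object@rewardZone[2],
      ") cm;", object@nNeurons, "neurons (",
      round(100 * object@fractionProjecting), "% projecting ); seed",
      object@seed, "\n")
})

#' SpatialSession: one imaging session on the circular belt
#'
#' A \linkS4class{SummarizedExperiment} whose assay `"S"` is the
#' neurons x frames matrix of non-negative deconvolved calcium event
#' amplitudes, whose `colData` carries the frame-aligned behavior
#' (`time_s`, `position_cm`, `velocity_cms`, `lick_analog`, `pump`,
#' `lap`), and whose `rowData` carries per-neuron annotation (at least
#' `projecting`, a logical projection label). Session geometry (frame
#' rate, belt length, number of spatial bins, reward zone, texture
#' boundaries) and, for synthetic sessions, the generator ground truth
#' live in `metadata()`.
#'
#' @export
setClass("SpatialSession", contains = "SummarizedExperiment")

setValidity("SpatialSession", function(object) {
  msg <- character()
  if (!"S" %in% assayNames(object))
    msg <- c(msg, "assay 'S' (deconvolved events) is required")
  else if (any(assay(object, "S") < 0))
    msg <- c(msg, "assay 'S' must be non-negative")
  need <- c("time_s", "position_cm", "velocity_cms", "lick_analog",
            "pump", "lap")
  miss <- setdiff(need, colnames(colData(object)))
  if (length(miss))
    msg <- c(msg, paste("colData lacks columns:", paste(miss, collapse = ", ")))
  if (!"projecting" %in% colnames(rowData(object)))
    msg <- c(msg, "rowData lacks 'projecting'")
  for (f in c("frameRate", "beltLength", "nBins", "rewardZone",
              "textureBoundaries"))
    if (is.null(metadata(object)[[f]]))
      msg <- c(msg, paste("metadata lacks", f))
  if (length(msg) == 0) {
    t <- colData(object)$time_s
    if (length(t) > 1 && any(diff(t) <= 0))
      msg <- c(msg, "time_s must be strictly increasing")
    if (any(!is.finite(colData(object)$velocity_cms)))
      msg <- c(msg, "velocity must be finite")
    if (is.unsorted(colData(object)$lap))
      msg <- c(msg, "lap index must be non-decreasing")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SpatialSession
#'
#' @param events neurons x frames numeric matrix of non-negative
#'   deconvolved event amplitudes.
#' @param behavior data.frame of frame-aligned behavior with columns
#'   `time_s`, `position_cm`, `velocity_cms`, `lick_analog`, `pump`,
#'   `lap` (one row per imaging frame).
#' @param frameRate imaging frame rate in Hz.
#' @param projecting logical vector, one per neuron; which neurons carry
#'   the projection label.
#' @param beltLength,nBins,rewardZone,textureBoundaries session geometry.
#' @param groundTruth optional list of generator ground truth (synthetic
#'   sessions only).
#' @param scenario optional scenario name recorded in metadata.
#' @return a \linkS4class{SpatialSession}.
#' @export
SpatialSession <- function(events, behavior, frameRate,
                           projecting = rep(FALSE, nrow(events)),
                           beltLength = 360, nBins = 45L,
                           rewardZone = c(240, 270),
                           textureBoundaries = c(0, 60, 120, 180, 240, 300),
                           groundTruth = NULL, scenario = NULL) {
  events <- as.matrix(events)
  stopifnot(ncol(events) == nrow(behavior),
            length(projecting) == nrow(events))
  if (is.null(rownames(events)))
    rownames(events) <- sprintf("n%03d", seq_len(nrow(events)))
  se <- SummarizedExperiment(
    assays = list(S = events),
    rowData = DataFrame(projecting = as.logical(projecting),
                        row.names = rownames(events)),
    colData = DataFrame(behavior))
  metadata(se) <- list(frameRate = frameRate, beltLength = beltLength,
                       nBins = as.integer(nBins), rewardZone = rewardZone,
                       textureBoundaries = textureBoundaries,
                       groundTruth = groundTruth, scenario = scenario)
  new("SpatialSession", se)
}

setMethod("show", "SpatialSession", function(object) {
  md <- metadata(object)
  cat("SpatialSession:", nrow(object), "neurons x", ncol(object),
      "frames @", md$frameRate, "Hz\n")
  cat("  belt", md$beltLength, "cm /", md$nBins, "bins; reward zone [",
      md$rewardZone[1], ",", md$rewardZone[2], ") cm\n")
  cat("  laps:", length(unique(colData(object)$lap)),
      "; projecting neurons:", sum(rowData(object)$projecting), "/",
      nrow(object), "\n")
  if (!is.null(md$scenario)) cat("  scenario:", md$scenario, "\n")
  if (!is.null(md$groundTruth)) cat("  ground truth: available\n")
})
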