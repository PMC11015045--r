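#' @include AllClasses.R behavior.R spatial.R tuning.R glm.R decode.R stats.R
NULL

# ---------------------------------------------------------------------------
# Per-session orchestration: behavior -> spatial -> tuning -> glm ->
# decode, with stage-scoped error reporting, optional CSV artifacts, and
# cross-session population comparisons.
# ---------------------------------------------------------------------------

runStage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full per-session analysis pipeline
#'
#' Executes the analysis stages in order (behavior, spatial, tuning,
#' encoding model, decoding) and assembles a session report. Rerunning
#' with an identical session and seeds reproduces identical outputs. Any
#' stage failure aborts with a stage-named error; artifacts written
#' before the failure are preserved.
#'
#' @param session a \linkS4class{SpatialSession}.
#' @param outDir optional directory for CSV artifacts (place_cells.csv,
#'   tuning.csv, glm_results.csv, decoding.csv, lap_table.csv); a file
#'   manifest with MD5 checksums is included in the report.
#' @param seed master seed; each stochastic stage derives its own
#'   substream.
#' @param nShufflesPlace place-cell shuffle count.
#' @param nShufflesGlm encoding-model shuffle count per predictor group.
#' @param snr signal-to-noise ratio for response scaling.
#' @param glmNeurons neuron indices for the encoding model (`NULL` = all).
#' @param runGlm,runDecode stage toggles.
#' @param decodeZone positive-class zone for decoding.
#' @param minProjecting minimum projection-neuron count for the
#'   projection-population decoding comparison.
#' @return a list (session report): `success`, `lapTable`, `placeCells`,
#'   `speedTuning`, `lickModulation`, `encoding`, `conjunctive`,
#'   `decoding`, `summary` (per-population proportions), `manifest`.
#' @export
runSessionPipeline <- function(session, outDir = NULL, seed = 1,
                               nShufflesPlace = 1000, nShufflesGlm = 100,
                               snr = 1, glmNeurons = NULL, runGlm = TRUE,
                               runDecode = TRUE, decodeZone = "both",
                               minProjecting = 10) {
  stopifnot(is(session, "SpatialSession"))
  frames <- behaviorFrames(session)
  zones <- zoneSet(rewardZone(session), beltLength(session),
                   textureBoundaries(session))
  lapTab <- runStage("behavior", buildLapTable(frames, zones))
  success <- runStage("behavior", classifySessionSuccess(lapTab))
  pc <- runStage("spatial",
                 placeCellStats(session, nShuffles = nShufflesPlace,
                                seed = childSeed(seed, 1)))
  speed <- runStage("tuning", speedTuningClassify(session))
  lickm <- runStage("tuning", lickModulationClassify(session))
  enc <- conj <- NULL
  if (runGlm) {
    if (is.null(glmNeurons)) glmNeurons <- seq_len(nrow(session))
    enc <- runStage("glm",
                    encodeSession(session, snr = snr,
                                  nShuffles = nShufflesGlm,
                                  seed = childSeed(seed, 2),
                                  neurons = glmNeurons))
    conj <- runStage("glm", classifyConjunctive(enc))
  }
  dec <- NULL
  if (runDecode) {
    dec <- runStage("decode", {
      ds <- prepareDecoderDataset(session, zone = decodeZone)
      if (ds$singleClass) {
        list(skipped = TRUE, reason = "single-class labels")
      } else {
        all <- trainEvalZoneDecoder(ds)
        proj <- projecting(session)
        cmp <- if (sum(proj) > minProjecting)
          comparePopulationsDecoding(ds, which(proj), which(!proj),
                                     seed = childSeed(seed, 3))
        else list(skipped = TRUE,
                  reason = paste("<=", minProjecting,
                                 "projection neurons"))
        list(skipped = FALSE, all = all, projectionComparison = cmp)
      }
    })
  }
  pop <- factor(ifelse(projecting(session), "projecting",
                       "nonprojecting"),
                levels = c("projecting", "nonprojecting"))
  summaryTab <- data.frame(
    population = levels(pop),
    n = as.integer(table(pop)),
    place_cell_prop = as.numeric(tapply(pc$is_place_cell, pop, mean)),
    speed_excited_prop = as.numeric(
      tapply(speed$speed_class == "excited", pop, mean)),
    speed_inhibited_prop = as.numeric(
      tapply(speed$speed_class == "inhibited", pop, mean)),
    lick_excited_prop = as.numeric(
      tapply(lickm$lick_class == "excited", pop, mean)),
    lick_inhibited_prop = as.numeric(
      tapply(lickm$lick_class == "inhibited", pop, mean)))
  manifest <- NULL
  if (!is.null(outDir)) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    wr <- function(df, f) {
      utils::write.csv(as.data.frame(df), file.path(outDir, f),
                       row.names = FALSE)
      f
    }
    files <- c(wr(lapTab, "lap_table.csv"),
               wr(pc, "place_cells.csv"),
               wr(speed, "speed_tuning.csv"),
               wr(lickm, "lick_modulation.csv"))
    if (!is.null(enc)) files <- c(files, wr(enc, "glm_results.csv"))
    manifest <- data.frame(
      file = files,
      md5 = unname(tools::md5sum(file.path(outDir, files))))
  }
  list(success = success, lapTable = lapTab, placeCells = pc,
       speedTuning = speed, lickModulation = lickm, encoding = enc,
       conjunctive = conj, decoding = dec, summary = summaryTab,
       manifest = manifest)
}

#' Cross-session population comparisons
#'
#' Pools per-population counts over session reports and compares
#' proportions (place cells, tuning classes, conjunctive classes) between
#' projecting and non-projecting populations with the continuity-corrected
#' chi-squared test, plus a bootstrap CI on the spatial-information
#' median difference.
#'
#' @param reports list of [runSessionPipeline()] reports.
#' @param nBoot bootstrap resamples for the SI median difference.
#' @param seed RNG seed.
#' @return list with `counts` (pooled 2x2 tables), `tests` (chi-squared
#'   results per comparison), `siMedianDifference` (bootstrap estimate),
#'   and `pooledProportions`.
#' @export
comparePopulationsReport <- function(reports, nBoot = 5000, seed = 1) {
  stopifnot(length(reports) >= 1)
  pcAll <- do.call(rbind, lapply(reports, function(r)
    as.data.frame(r$placeCells[, c("SI", "is_place_cell", "projecting")])))
  tab <- function(flag, proj) {
    m <- matrix(c(sum(flag & proj), sum(!flag & proj),
                  sum(flag & !proj), sum(!flag & !proj)),
                2, byrow = TRUE,
                dimnames = list(c("projecting", "nonprojecting"),
                                c("yes", "no")))
    m
  }
  counts <- list(placeCells = tab(pcAll$is_place_cell, pcAll$projecting))
  tests <- list()
  tests$placeCells <- tryCatch(chiSquaredYates(counts$placeCells),
                               error = function(e) NULL)
  siProj <- pcAll$SI[pcAll$projecting & !is.na(pcAll$SI)]
  siNon <- pcAll$SI[!pcAll$projecting & !is.na(pcAll$SI)]
  siDiff <- if (length(siProj) && length(siNon))
    bootstrapMedianDifference(siNon, siProj, n = nBoot, seed = seed)
  else NULL
  pooled <- data.frame(
    population = c("projecting", "nonprojecting"),
    n = c(sum(pcAll$projecting), sum(!pcAll$projecting)),
    place_cell_prop = c(mean(pcAll$is_place_cell[pcAll$projecting]),
                        mean(pcAll$is_place_cell[!pcAll$projecting])))
  list(counts = counts, tests = tests, siMedianDifference = siDiff,
       pooledProportions = pooled)
}
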