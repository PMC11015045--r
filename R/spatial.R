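#' @include AllClasses.R utils-belt.R
NULL

# ---------------------------------------------------------------------------
# Spatial coding analysis: rate maps over 45 x 8 cm bins (movement frames
# only, velocity > 2 cm/s), Skaggs spatial information and sparsity,
# place-cell classification against a 1000x circular-shift + block-permute
# null, place-field extraction from the Savitzky-Golay-smoothed doubled
# map, field metrics (reliability, delta in-out, lap stability, circular
# COM), boundary-ratio permutation test, reward-zone field density, and
# in-field pass overdispersion.
# ---------------------------------------------------------------------------

#' Spatial rate map of one neuron
#'
#' Bins the belt into `nBins` equal bins and computes, over movement
#' frames only (velocity > `vMin`), the occupancy share `o` per bin
#' (normalized to sum 1) and the mean deconvolved event activity `a` per
#' bin. Unvisited bins have occupancy 0 and `a = NA` (stored as missing,
#' not silence; they contribute nothing to the information sums). The
#' occupancy-weighted overall mean activity and the movement firing rate
#' (frames with events > 0 per second of movement) are included.
#'
#' @param events numeric event trace for one neuron (length = frames).
#' @param frames behavior data.frame with `position_cm`, `velocity_cms`.
#' @param rate imaging frame rate in Hz.
#' @param beltLength belt circumference in cm.
#' @param nBins number of spatial bins.
#' @param vMin movement velocity threshold, cm/s.
#' @return list with `a`, `o`, `abar`, `firingRate`, `nBins`,
#'   `nMovementFrames`.
#' @export
computeRatemap <- function(events, frames, rate, beltLength = 360,
                           nBins = 45, vMin = 2) {
  stopifnot(length(events) == nrow(frames))
  mov <- frames$velocity_cms > vMin
  if (!any(mov)) stop("no movement frames (velocity > ", vMin, " cm/s)")
  bin <- positionBin(frames$position_cm[mov], beltLength, nBins)
  ev <- events[mov]
  cnt <- tabulate(bin, nBins)
  sums <- rep(0, nBins)
  s <- tapply(ev, factor(bin, levels = seq_len(nBins)), sum, default = 0)
  sums <- as.numeric(s)
  a <- ifelse(cnt > 0, sums / cnt, NA_real_)
  o <- cnt / sum(cnt)
  abar <- sum(o * a, na.rm = TRUE)
  list(a = a, o = o, abar = abar,
       firingRate = sum(ev > 0) / (sum(mov) / rate),
       nBins = nBins, nMovementFrames = sum(mov))
}

#' Skaggs spatial information of a rate map
#'
#' \deqn{SI = \sum_i o_i a_i \log_2(a_i / \bar a)} where \eqn{o_i} is the
#' occupancy at bin i, \eqn{a_i} the mean event activity there, and
#' \eqn{\bar a = \sum_i o_i a_i} the occupancy-weighted overall mean.
#' Bins with \eqn{a_i = 0} contribute 0; unvisited bins are excluded. The
#' information rate (bits/s) multiplies SI by the movement firing rate.
#'
#' @param ratemap a [computeRatemap()] result.
#' @return list with `SI` and `SIrate`; both `NA` for a silent neuron
#'   (\eqn{\bar a = 0}), which is non-place by convention.
#' @export
spatialInformation <- function(ratemap) {
  a <- ratemap$a
  o <- ratemap$o
  ok <- !is.na(a) & o > 0
  abar <- sum(o[ok] * a[ok])
  if (abar <= 0) return(list(SI = NA_real_, SIrate = NA_real_))
  pos <- ok & a > 0
  SI <- sum(o[pos] * a[pos] * log2(a[pos] / abar))
  list(SI = SI, SIrate = SI * ratemap$firingRate)
}

#' Sparsity of a rate map
#'
#' \deqn{Sparsity = (\sum_i o_i a_i)^2 / \sum_i o_i a_i^2}, in (0, 1];
#' 1 for perfectly uniform activity, small for activity confined to few
#' bins.
#'
#' @param ratemap a [computeRatemap()] result.
#' @return sparsity value, or `NA` for a silent neuron.
#' @export
sparsityIndex <- function(ratemap) {
  a <- ratemap$a
  o <- ratemap$o
  ok <- !is.na(a) & o > 0
  den <- sum(o[ok] * a[ok]^2)
  if (den <= 0) return(NA_real_)
  sum(o[ok] * a[ok])^2 / den
}

# internal: index vector realizing one shuffle (circular shift by `shift`
# frames, then permute the order of `nBlocks` contiguous blocks)
shuffleIndex <- function(nFrames, shift, blockIdxList, perm) {
  shifted <- ((seq_len(nFrames) - 1 + shift) %% nFrames) + 1L
  shifted[unlist(blockIdxList[perm], use.names = FALSE)]
}

# internal: near-equal contiguous block index list
makeBlocks <- function(nFrames, nBlocks) {
  bounds <- round(seq(0, nFrames, length.out = nBlocks + 1))
  lapply(seq_len(nBlocks), function(b) (bounds[b] + 1L):bounds[b + 1L])
}

#' Place-cell classification by circular-shift permutation test
#'
#' For every neuron, the observed spatial information is compared with a
#' null distribution of `nShuffles` SI values from position-shuffled
#' activity: each shuffle circularly shifts the event trace by at least
#' 500 frames (bounds adapted with a note for recordings of 1000 frames or
#' fewer), segments it into approximately twice-the-lap-count contiguous
#' blocks, and randomly permutes the block order before recomputing SI
#' against the unshuffled behavior. A neuron is a place cell when its SI
#' exceeds the 95th percentile of its own null. One RNG substream per
#' neuron is derived from `seed`, so verdicts are reproducible and
#' independent of neuron order.
#'
#' @param session a \linkS4class{SpatialSession}.
#' @param nShuffles number of shuffles per neuron.
#' @param seed integer seed for the shuffle RNG.
#' @param vMin movement velocity threshold, cm/s.
#' @param keepNull keep the full null matrix (neurons x shuffles) in the
#'   result's metadata.
#' @return a `DataFrame`, one row per neuron: `SI`, `SI_rate`, `sparsity`,
#'   `firing_rate`, `null_p95`, `is_place_cell`, `projecting`. When
#'   `keepNull`, `metadata(x)$nullSI` holds the null matrix.
#' @export
placeCellTest <- function(session, nShuffles = 1000, seed = 1, vMin = 2,
                          keepNull = FALSE) {
  frames <- behaviorFrames(session)
  ev <- eventMatrix(session)
  nFrames <- ncol(ev)
  rate <- frameRate(session)
  L <- beltLength(session)
  nBins <- nSpatialBins(session)
  if (nFrames <= 500) stop("recording too short for the shuffle null")
  nLaps <- length(unique(frames$lap))
  nBlocks <- max(2L, round(2 * nLaps))
  blocks <- makeBlocks(nFrames, nBlocks)
  mov <- frames$velocity_cms > vMin
  movIdx <- which(mov)
  bin <- positionBin(frames$position_cm[mov], L, nBins)
  cnt <- tabulate(bin, nBins)
  o <- cnt / sum(cnt)
  visited <- cnt > 0
  if (nFrames > 1000) {
    loShift <- 500L; hiShift <- nFrames - 500L
  } else {
    loShift <- max(1L, floor(nFrames * 0.1))
    hiShift <- nFrames - loShift
    message("placeCellTest: recording has ", nFrames,
            " frames; shuffle shift bounds adapted to [", loShift, ", ",
            hiShift, "]")
  }
  blockStarts <- vapply(blocks, function(b) b[1], integer(1))
  blockEnds <- vapply(blocks, function(b) b[length(b)], integer(1))
  nNeurons <- nrow(ev)
  SI <- SIrate <- sparsity <- firing <- nullP95 <- numeric(nNeurons)
  nullMat <- if (keepNull) matrix(NA_real_, nNeurons, nShuffles) else NULL
  for (j in seq_len(nNeurons)) {
    rm <- computeRatemap(ev[j, ], frames, rate, L, nBins, vMin)
    si <- spatialInformation(rm)
    SI[j] <- si$SI
    SIrate[j] <- si$SIrate
    sparsity[j] <- sparsityIndex(rm)
    firing[j] <- rm$firingRate
    set.seed(childSeed(seed, 10000 + j))
    shifts <- sample(loShift:hiShift, nShuffles, replace = TRUE)
    perms <- vapply(seq_len(nShuffles),
                    function(k) sample.int(nBlocks), integer(nBlocks))
    nulls <- .nullSpatialInformation(ev[j, ], movIdx, bin, nBins, o, cnt,
                                     blockStarts, blockEnds, perms,
                                     shifts)
    nullP95[j] <- stats::quantile(nulls, 0.95, names = FALSE)
    if (keepNull) nullMat[j, ] <- nulls
  }
  res <- DataFrame(neuron_id = rownames(ev), SI = SI, SI_rate = SIrate,
                   sparsity = sparsity, firing_rate = firing,
                   null_p95 = nullP95,
                   is_place_cell = !is.na(SI) & SI > nullP95,
                   projecting = projecting(session),
                   row.names = rownames(ev))
  if (keepNull) metadata(res)$nullSI <- nullMat
  res
}

# ---------------------------------------------------------------------------
# Peak finding with prominences and relative-height boundaries, matching
# the find_peaks/peak_widths semantics the field-extraction procedure is
# defined by: prominence from the lowest contour between a peak and the
# next higher samples; boundaries where the trace crosses
# height - relHeight * prominence, linearly interpolated.
# ---------------------------------------------------------------------------
findPeaksProminence <- function(x, relHeight = 0.8) {
  n <- length(x)
  if (n < 3) return(data.frame())
  idx <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  if (!length(idx)) return(data.frame())
  out <- lapply(idx, function(i) {
    # left base: minimum between i and the previous sample higher than x[i]
    li <- i
    lmin <- x[i]; lminIdx <- i
    while (li > 1 && x[li - 1] <= x[i]) {
      li <- li - 1L
      if (x[li] < lmin) { lmin <- x[li]; lminIdx <- li }
    }
    ri <- i
    rmin <- x[i]; rminIdx <- i
    while (ri < n && x[ri + 1] <= x[i]) {
      ri <- ri + 1L
      if (x[ri] < rmin) { rmin <- x[ri]; rminIdx <- ri }
    }
    base <- max(lmin, rmin)
    prom <- x[i] - base
    h <- x[i] - relHeight * prom
    # walk outward to the interpolated crossings, bounded by the bases
    l <- i
    while (l > lminIdx && x[l - 1] > h) l <- l - 1L
    leftIp <- if (l > lminIdx && x[l - 1] <= h)
      (l - 1) + (h - x[l - 1]) / (x[l] - x[l - 1]) else as.numeric(lminIdx)
    r <- i
    while (r < rminIdx && x[r + 1] > h) r <- r + 1L
    rightIp <- if (r < rminIdx && x[r + 1] <= h)
      r + (x[r] - h) / (x[r] - x[r + 1]) else as.numeric(rminIdx)
    data.frame(peak = i, height = x[i], prominence = prom,
               leftIp = leftIp, rightIp = rightIp,
               width = rightIp - leftIp)
  })
  do.call(rbind, out)
}

#' Extract the primary place field from a rate map
#'
#' The 45-bin rate map is replicated by a factor of two (circularity),
#' smoothed with a Savitzky-Golay filter (window 5, order 2), and
#' searched for peaks with minimum width 1 bin, prominence at least 1.5
#' standard deviations of the smoothed trace, and boundaries at 0.8
#' relative height (interpolated crossings). The most prominent peak is
#' the primary place field; fields extending into the replicated half are
#' translated back modulo `nBins`.
#'
#' @param ratemap a [computeRatemap()] result, or a numeric rate-map
#'   vector.
#' @param prominenceSd prominence threshold in SD units of the smoothed
#'   trace.
#' @param relHeight relative height at which field boundaries are taken.
#' @return list with `found`, and when found: `peakBin`, `startBin`,
#'   `endBin` (1-based, wrap-aware: `startBin > endBin` for fields
#'   crossing the origin), `bins` (member bin indices), `prominence`. A
#'   classified place cell without a qualifying peak keeps its flag but
#'   has no field.
#' @export
extractPlaceField <- function(ratemap, prominenceSd = 1.5,
                              relHeight = 0.8) {
  a <- if (is.list(ratemap)) ratemap$a else ratemap
  nBins <- length(a)
  a[is.na(a)] <- 0
  doubled <- rep(a, 2)
  sm <- signal::sgolayfilt(doubled, p = 2, n = 5)
  if (stats::sd(sm) < 1e-10 * (abs(mean(sm)) + 1))
    return(list(found = FALSE))   # flat map: no peak
  peaks <- findPeaksProminence(sm, relHeight = relHeight)
  if (!nrow(peaks)) return(list(found = FALSE))
  thr <- prominenceSd * stats::sd(sm)
  peaks <- peaks[peaks$prominence >= thr & peaks$width >= 1, , drop = FALSE]
  if (!nrow(peaks)) return(list(found = FALSE))
  best <- peaks[which.max(peaks$prominence), ]
  toBin <- function(i) ((as.integer(floor(i)) - 1L) %% nBins) + 1L
  peakBin <- toBin(best$peak)
  startBin <- toBin(ceiling(best$leftIp))
  endBin <- toBin(floor(best$rightIp))
  fieldLen <- (floor(best$rightIp) - ceiling(best$leftIp)) %% nBins + 1L
  bins <- ((startBin - 1L + seq_len(fieldLen) - 1L) %% nBins) + 1L
  list(found = TRUE, peakBin = peakBin, startBin = startBin,
       endBin = endBin, bins = bins, prominence = best$prominence,
       leftIp = best$leftIp, rightIp = best$rightIp)
}

#' Circular center of mass of a rate map
#'
#' Spatial bins are mapped to polar coordinates (angle = bin center,
#' radius = activity); the angle of the two-dimensional centroid is
#' transformed back to a belt position.
#'
#' @param ratemap a [computeRatemap()] result or rate-map vector.
#' @param beltLength belt circumference in cm.
#' @return COM position in cm, `NA` for a silent map.
#' @export
placeFieldCOM <- function(ratemap, beltLength = 360) {
  a <- if (is.list(ratemap)) ratemap$a else ratemap
  a[is.na(a)] <- 0
  if (sum(a) <= 0) return(NA_real_)
  theta <- 2 * pi * binCenters(beltLength, length(a)) / beltLength
  ang <- atan2(sum(a * sin(theta)), sum(a * cos(theta)))
  beltWrap(ang / (2 * pi) * beltLength, beltLength)
}

#' Per-lap spatially binned activity
#'
#' @param events event trace of one neuron.
#' @param frames behavior data.frame.
#' @param beltLength,nBins,vMin see [computeRatemap()].
#' @return laps x bins matrix of mean activity over movement frames
#'   (`NA` where a lap never visited a bin at movement speed).
#' @export
lapBinActivity <- function(events, frames, beltLength = 360, nBins = 45,
                           vMin = 2) {
  mov <- frames$velocity_cms > vMin
  laps <- sort(unique(frames$lap))
  bin <- positionBin(frames$position_cm, beltLength, nBins)
  out <- matrix(NA_real_, length(laps), nBins,
                dimnames = list(paste0("lap", laps), NULL))
  for (i in seq_along(laps)) {
    sel <- mov & frames$lap == laps[i]
    if (!any(sel)) next
    f <- factor(bin[sel], levels = seq_len(nBins))
    m <- tapply(events[sel], f, mean)
    out[i, ] <- as.numeric(m)
  }
  out
}

#' Place-field metrics: reliability, in-out contrast, stability, COM
#'
#' Reliability is the fraction of (active) laps whose maximum spatially
#' binned activity falls inside the field. Delta in-out is the mean
#' activity inside the field minus outside (movement frames). Lap
#' stability is the mean Pearson correlation between consecutive laps'
#' bin-activity vectors (all-pairs mean available as an option). COM is
#' the circular centroid of the session rate map.
#'
#' @param events event trace of one neuron.
#' @param frames behavior data.frame.
#' @param field an [extractPlaceField()] result with `found = TRUE`.
#' @param rate imaging frame rate in Hz.
#' @param beltLength,nBins,vMin see [computeRatemap()].
#' @param stabilityPairs `"consecutive"` (default) or `"all"`.
#' @return list with `reliability`, `deltaInOut`, `lapStability`,
#'   `COM_cm`, `nStabilityPairs`, `nActiveLaps`.
#' @export
fieldMetrics <- function(events, frames, field, rate, beltLength = 360,
                         nBins = 45, vMin = 2,
                         stabilityPairs = c("consecutive", "all")) {
  stopifnot(isTRUE(field$found))
  stabilityPairs <- match.arg(stabilityPairs)
  lapAct <- lapBinActivity(events, frames, beltLength, nBins, vMin)
  lapAct0 <- lapAct
  lapAct0[is.na(lapAct0)] <- 0
  active <- rowSums(lapAct0) > 0
  inField <- seq_len(nBins) %in% field$bins
  rel <- if (any(active)) {
    hits <- apply(lapAct0[active, , drop = FALSE], 1,
                  function(r) inField[which.max(r)])
    mean(hits)
  } else NA_real_
  mov <- frames$velocity_cms > vMin
  bin <- positionBin(frames$position_cm, beltLength, nBins)
  fin <- mov & inField[bin]
  fout <- mov & !inField[bin]
  delta <- mean(events[fin]) - mean(events[fout])
  pairs <- if (stabilityPairs == "consecutive") {
    cbind(seq_len(nrow(lapAct0) - 1), seq_len(nrow(lapAct0) - 1) + 1)
  } else {
    t(utils::combn(nrow(lapAct0), 2))
  }
  cors <- apply(pairs, 1, function(p) {
    x <- lapAct0[p[1], ]; y <- lapAct0[p[2], ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_
    else stats::cor(x, y)
  })
  rm <- computeRatemap(events, frames, rate, beltLength, nBins, vMin)
  list(reliability = rel, deltaInOut = delta,
       lapStability = mean(cors, na.rm = TRUE),
       nStabilityPairs = sum(!is.na(cors)),
       nActiveLaps = sum(active),
       COM_cm = placeFieldCOM(rm, beltLength))
}

#' Boundary-ratio permutation test for field starts and ends
#'
#' Position bins are segmented into texture-transition bins (within
#' `transitionHalfWidthBins` of a texture boundary) and middle bins. The
#' observed statistic is the ratio of field beginnings (resp. ends)
#' falling in transition bins over those in middle bins. The null is
#' built by `nPerm` iterations of circularly shifting each field's
#' beginning and end jointly (preserving field length) by a random
#' offset, and the exceedance percentile of the observed ratio within the
#' null is reported (cutoff of interest: 99.9th percentile).
#'
#' @param startBins,endBins integer bin indices (1-based) of field
#'   beginnings and ends, one per field.
#' @param textureBoundaries texture boundary positions in cm.
#' @param beltLength belt circumference in cm.
#' @param nBins number of position bins.
#' @param transitionHalfWidthBins half-width of a transition zone in bins.
#' @param nPerm permutation count.
#' @param seed RNG seed.
#' @return list with `startRatio`, `endRatio`, `nullStart`, `nullEnd`,
#'   `startPercentile`, `endPercentile`, `startAboveP999`,
#'   `endAboveP999`, `infiniteRatio` flag (zero middle-bin count).
#' @export
boundaryRatioTest <- function(startBins, endBins, textureBoundaries,
                              beltLength = 360, nBins = 45,
                              transitionHalfWidthBins = 1, nPerm = 1000,
                              seed = 1) {
  stopifnot(length(startBins) == length(endBins), length(startBins) >= 1)
  bBins <- positionBin(textureBoundaries, beltLength, nBins)
  offs <- -transitionHalfWidthBins:transitionHalfWidthBins
  transition <- unique(as.vector(outer(bBins - 1L, offs, "+")) %% nBins + 1L)
  isTrans <- seq_len(nBins) %in% transition
  ratio <- function(bins) {
    tr <- sum(isTrans[bins])
    mid <- length(bins) - tr
    if (mid == 0) Inf else tr / mid
  }
  obsS <- ratio(startBins)
  obsE <- ratio(endBins)
  set.seed(childSeed(seed, 0))
  nullS <- nullE <- numeric(nPerm)
  n <- length(startBins)
  for (k in seq_len(nPerm)) {
    d <- sample.int(nBins, n, replace = TRUE) - 1L
    nullS[k] <- ratio(((startBins - 1L + d) %% nBins) + 1L)
    nullE[k] <- ratio(((endBins - 1L + d) %% nBins) + 1L)
  }
  pS <- 100 * mean(nullS < obsS)
  pE <- 100 * mean(nullE < obsE)
  list(startRatio = obsS, endRatio = obsE, nullStart = nullS,
       nullEnd = nullE, startPercentile = pS, endPercentile = pE,
       startAboveP999 = obsS > stats::quantile(nullS, 0.999, names = FALSE),
       endAboveP999 = obsE > stats::quantile(nullE, 0.999, names = FALSE),
       infiniteRatio = !is.finite(obsS) || !is.finite(obsE))
}

#' Proportion of place fields near the reward zone
#'
#' A field is "near reward" when its COM lies in the anticipation zone
#' (30 cm before the reward zone) or the reward zone itself. The chance
#' level under an even COM distribution (zone length / belt length,
#' 60/360 for the defaults) is reported alongside.
#'
#' @param com_cm field COM positions in cm.
#' @param rewardZone `c(start, end)` in cm.
#' @param beltLength belt circumference in cm.
#' @param group optional factor splitting fields into populations.
#' @return data.frame with columns `group`, `n`, `proportion`, `chance`.
#' @export
rewardZoneFieldDensity <- function(com_cm, rewardZone = c(240, 270),
                                   beltLength = 360, group = NULL) {
  zone <- c(rewardZone[1] - 30, rewardZone[2])
  near <- inZone(com_cm, zone, beltLength)
  chance <- (beltWrap(zone[2] - zone[1], beltLength)) / beltLength
  if (is.null(group)) group <- factor(rep("all", length(com_cm)))
  group <- as.factor(group)
  do.call(rbind, lapply(levels(group), function(g) {
    sel <- group == g & !is.na(com_cm)
    data.frame(group = g, n = sum(sel),
               proportion = if (any(sel)) mean(near[sel]) else NA_real_,
               chance = chance)
  }))
}

#' Contiguous in-field passes
#'
#' A pass is a maximal run of consecutive movement frames whose position
#' bin lies inside the field, within one lap.
#'
#' @param frames behavior data.frame.
#' @param field an [extractPlaceField()] result.
#' @param beltLength,nBins,vMin see [computeRatemap()].
#' @return list of integer frame-index vectors, one per pass.
#' @export
extractFieldPasses <- function(frames, field, beltLength = 360, nBins = 45,
                               vMin = 2) {
  bin <- positionBin(frames$position_cm, beltLength, nBins)
  ok <- frames$velocity_cms > vMin & bin %in% field$bins
  # contiguous TRUE runs, breaking at lap boundaries
  grp <- cumsum(c(TRUE, diff(ok) != 0 | diff(frames$lap) != 0))
  idx <- which(ok)
  split(idx, grp[idx])
}

#' Overdispersion statistic from per-pass observations
#'
#' \deqn{z = (obs - exp) / \sqrt{exp}}; overdispersion is the variance of
#' z across passes (1 under Poisson pass statistics).
#'
#' @param obs per-pass observed activity.
#' @param exp expected activity (scalar).
#' @return list with `z` and `sigma2` (`NA` with fewer than 2 passes).
#' @export
overdispersionStat <- function(obs, exp) {
  stopifnot(exp > 0)
  z <- (obs - exp) / sqrt(exp)
  list(z = z, sigma2 = if (length(z) >= 2) stats::var(z) else NA_real_)
}

#' In-field pass overdispersion of one place cell
#'
#' The expected activity is the mean of all non-zero deconvolved events
#' inside the place field; the observed activity is the per-pass mean of
#' non-zero in-field events. Only passes with detected activity enter the
#' z distribution.
#'
#' @param events event trace of one neuron.
#' @param frames behavior data.frame.
#' @param field an [extractPlaceField()] result.
#' @param beltLength,nBins,vMin see [computeRatemap()].
#' @return list with `sigma2`, `z`, `obs`, `expected`, `nPasses`
#'   (qualifying passes); `sigma2 = NA` with fewer than 2.
#' @export
overdispersion <- function(events, frames, field, beltLength = 360,
                           nBins = 45, vMin = 2) {
  passes <- extractFieldPasses(frames, field, beltLength, nBins, vMin)
  inField <- unlist(passes, use.names = FALSE)
  nz <- events[inField]
  nz <- nz[nz > 0]
  if (!length(nz))
    return(list(sigma2 = NA_real_, z = numeric(0), obs = numeric(0),
                expected = NA_real_, nPasses = 0L))
  expVal <- mean(nz)
  obs <- vapply(passes, function(ix) {
    v <- events[ix]
    v <- v[v > 0]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  obs <- obs[!is.na(obs)]
  od <- overdispersionStat(obs, expVal)
  list(sigma2 = od$sigma2, z = od$z, obs = obs, expected = expVal,
       nPasses = length(obs))
}

#' Full per-neuron spatial analysis of a session
#'
#' Runs [placeCellTest()], then for each classified place cell extracts
#' the primary field and its metrics.
#'
#' @param session a \linkS4class{SpatialSession}.
#' @param nShuffles,seed,vMin see [placeCellTest()].
#' @return a `DataFrame`: place-cell statistics plus field geometry
#'   (`peak_bin`, `start_bin`, `end_bin`, `COM_cm`, `reliability`,
#'   `delta_in_out`, `lap_stability`, `near_reward`). Field columns are
#'   `NA` for non-place cells and for place cells without a qualifying
#'   peak (the flag is retained; such cells are excluded from
#'   field-geometry analyses).
#' @export
placeCellStats <- function(session, nShuffles = 1000, seed = 1, vMin = 2) {
  res <- placeCellTest(session, nShuffles = nShuffles, seed = seed,
                       vMin = vMin)
  frames <- behaviorFrames(session)
  ev <- eventMatrix(session)
  L <- beltLength(session)
  nBins <- nSpatialBins(session)
  rz <- rewardZone(session)
  n <- nrow(res)
  peak <- startB <- endB <- rep(NA_integer_, n)
  com <- reliab <- dio <- stab <- rep(NA_real_, n)
  nearR <- rep(NA, n)
  noField <- 0L
  for (j in which(res$is_place_cell)) {
    rm <- computeRatemap(ev[j, ], frames, frameRate(session), L, nBins,
                         vMin)
    fld <- extractPlaceField(rm)
    if (!fld$found) {
      noField <- noField + 1L
      next
    }
    m <- fieldMetrics(ev[j, ], frames, fld, frameRate(session), L, nBins,
                      vMin)
    peak[j] <- fld$peakBin
    startB[j] <- fld$startBin
    endB[j] <- fld$endBin
    com[j] <- m$COM_cm
    reliab[j] <- m$reliability
    dio[j] <- m$deltaInOut
    stab[j] <- m$lapStability
    nearR[j] <- inZone(m$COM_cm, c(rz[1] - 30, rz[2]), L)
  }
  if (noField > 0)
    message("placeCellStats: ", noField,
            " place cell(s) without a qualifying field peak")
  res$peak_bin <- peak
  res$start_bin <- startB
  res$end_bin <- endB
  res$COM_cm <- com
  res$reliability <- reliab
  res$delta_in_out <- dio
  res$lap_stability <- stab
  res$near_reward <- nearR
  res
}
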