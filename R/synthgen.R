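#' @include AllClasses.R utils-belt.R
NULL

# ---------------------------------------------------------------------------
# Synthetic session generator.
#
# Emulates the statistical structure the downstream analyses assume: lap-
# structured running that slows near a hidden reward zone, appetitive lick
# ramps in the 30 cm anticipation zone, consummatory lick bouts after the
# reward pump fires, and neurons whose Poisson event rates carry place,
# speed, and/or lick tuning (singly or conjunctively) with known ground
# truth. One RNG stream per session, split deterministically into behavior
# and neural substreams, so behavior is invariant to the neuron count.
# ---------------------------------------------------------------------------

#' Specify one simulated neuron's tuning
#'
#' Any subset of the three tunings may be active, supporting single-,
#' dual- and triple-conjunctive cells. Rates combine multiplicatively:
#' \deqn{\lambda(t) = \mathrm{baseline} \times g_{place}(pos)
#'   \times g_{speed}(v) \times g_{lick}(t)}
#' with \eqn{g_{place} = 1 + (gain-1)\exp(-d^2 / 2\sigma^2)} a circular
#' Gaussian on the belt, \eqn{g_{speed} = \exp(slope\,(v - 10))}
#' log-linear in velocity (approximately linear over the analyzed 2-30
#' cm/s range, so both the velocity-bin regression and the log-link
#' encoding model can recover it), and \eqn{g_{lick} = \exp(amp\,K(t))}
#' with K a causal exponential kernel triggered at appetitive lick
#' onsets. Rates are always non-negative; any negative values from
#' user-supplied gain functions are clipped to zero.
#'
#' @param neuron_id identifier.
#' @param projecting logical projection label.
#' @param baseline baseline event rate, events/frame.
#' @param place_center,place_width,place_gain circular-Gaussian place
#'   field: center (cm), SD (cm), peak rate multiple of baseline. NA for
#'   no place tuning.
#' @param speed_slope log-rate change per cm/s (sign gives
#'   excited/inhibited); NA for none.
#' @param lick_amp log-rate lick-kernel amplitude (positive =
#'   lick-excited, negative = lick-inhibited); NA for none.
#' @param lick_tau lick kernel decay constant, s (default 2, the kernel's nominal duration).
#' @return one-row data.frame.
#' @export
neuronSpec <- function(neuron_id, projecting = FALSE, baseline = 0.08,
                       place_center = NA_real_, place_width = NA_real_,
                       place_gain = NA_real_, speed_slope = NA_real_,
                       lick_amp = NA_real_, lick_tau = 2) {
  data.frame(neuron_id = neuron_id, projecting = projecting,
             baseline = baseline, place_center = place_center,
             place_width = place_width, place_gain = place_gain,
             speed_slope = speed_slope, lick_amp = lick_amp,
             lick_tau = lick_tau, stringsAsFactors = FALSE)
}

#' Scenario presets for the generator
#'
#' Builds the per-neuron tuning table for a named scenario:
#' \describe{
#'   \item{null}{no tuning anywhere (calibration of false-positive rates).}
#'   \item{place_only}{every neuron place-tuned, centers evenly tiling the
#'     belt.}
#'   \item{mixed_conjunctive}{a mixture of untuned, place, speed(+/-),
#'     lick(+/-), dual- and triple-conjunctive neurons.}
#'   \item{projection_enriched}{place tuning more frequent, and place
#'     fields biased toward the reward zone, among projecting neurons.}
#' }
#'
#' @param config a \linkS4class{SimConfig}.
#' @param scenario scenario name.
#' @return data.frame of neuron specs (one row per neuron) with a
#'   `tuning_class` column naming the generative class.
#' @export
scenarioSpecs <- function(config, scenario = c("mixed_conjunctive", "null",
                                               "place_only",
                                               "projection_enriched")) {
  scenario <- match.arg(scenario)
  n <- config@nNeurons
  L <- config@beltLength
  set.seed(childSeed(config@seed, 5000))
  proj <- seq_len(n) <= round(n * config@fractionProjecting)
  base <- rep(0.08, n)
  sp <- do.call(rbind, lapply(seq_len(n), function(i)
    neuronSpec(sprintf("n%03d", i), projecting = proj[i],
               baseline = base[i])))
  evenCenters <- function(k) (seq_len(k) - 0.5) / k * L
  altSign <- function(k) rep_len(c(1, -1), k)
  cls <- rep("untuned", n)
  if (scenario == "place_only") {
    sp$place_center <- evenCenters(n)
    sp$place_width <- 12
    sp$place_gain <- 6
    cls <- rep("place", n)
  } else if (scenario == "mixed_conjunctive") {
    # fixed composition: 30% untuned, 20% place, 10% speed, 10% lick,
    # 10% place+speed, 10% place+lick, 10% triple
    frac <- c(untuned = 0.3, place = 0.2, speed = 0.1, lick = 0.1,
              place_speed = 0.1, place_lick = 0.1, triple = 0.1)
    counts <- diff(round(cumsum(c(0, frac)) * n))
    cls <- rep(names(frac), counts)[seq_len(n)]
    hasPlace <- cls %in% c("place", "place_speed", "place_lick", "triple")
    hasSpeed <- cls %in% c("speed", "place_speed", "triple")
    hasLick <- cls %in% c("lick", "place_lick", "triple")
    tri <- cls == "triple"
    # golden-angle spacing: any contiguous class slice tiles the belt
    sp$place_center[hasPlace] <-
      beltWrap((seq_len(sum(hasPlace)) - 1) * 0.3819660113 * L, L)
    sp$place_width[hasPlace] <- 12
    sp$place_gain[hasPlace] <- ifelse(tri[hasPlace], 7, 6)
    sp$speed_slope[hasSpeed] <- ifelse(tri[hasSpeed], 0.18, 0.09) *
      altSign(sum(hasSpeed))
    amp <- altSign(sum(hasLick))
    sp$lick_amp[hasLick] <- ifelse(tri[hasLick], 4,
                                   ifelse(amp > 0, 1.5, -2))
    # triple-conjunctive cells: active, strongly and jointly tuned, and
    # lick-excited (suppressive lick coding of an already sparse trace is
    # information-limited for any encoding model)
    sp$baseline[tri] <- 0.2
  } else if (scenario == "projection_enriched") {
    pPlace <- ifelse(proj, 0.6, 0.25)
    hasPlace <- runif(n) < pPlace
    ctr <- runif(n, 0, L)
    # bias 60% of projecting place fields into anticipation + reward zone
    biased <- proj & hasPlace & runif(n) < 0.6
    ctr[biased] <- runif(sum(biased), config@rewardZone[1] - 30,
                         config@rewardZone[2])
    sp$place_center[hasPlace] <- beltWrap(ctr[hasPlace], L)
    sp$place_width[hasPlace] <- 12
    sp$place_gain[hasPlace] <- 6
    cls[hasPlace] <- "place"
  }
  sp$tuning_class <- cls
  sp
}

#' Simulate the behavioral trace of one session
#'
#' Produces an imaging-rate behavioral table for `nLaps` full belt
#' rotations: running speed with AR(1) log-normal fluctuations and
#' occasional rest bouts (sub-threshold speed, as head-fixed mice pause
#' between running stretches — this keeps lap durations aperiodic, which
#' the movement mask and the circular-shift nulls presuppose), slowed by
#' `slowdownFactor` from 60 cm before the reward zone to its end;
#' stochastic appetitive licking whose rate ramps up over the
#' `lickRampStart` cm before the zone; exactly one reward per lap at the
#' first in-zone lick, followed by a consummatory lick bout 0.6-1.2 s
#' after the pump; and an analog lick signal built by convolving the lick
#' impulse train with a short causal kernel plus noise, so the detector is
#' exercised on realistic input. Lick events are generated with a 0.4 s
#' refractory period so they remain individually resolvable at the
#' detector's 0.33 s minimum separation.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return list with `frames` (data.frame: time_s, position_cm,
#'   velocity_cms, lick_analog, pump, lap) and `truth` (list: lickTimes,
#'   lickFrames, appetitiveOnsets, pumpTimes, rewardedLaps,
#'   lapStartFrames).
#' @export
simulateBehavior <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  set.seed(childSeed(config@seed, 0))
  L <- config@beltLength
  fr <- config@frameRate
  dt <- 1 / fr
  rz <- config@rewardZone
  slowZone <- c(rz[1] - 60, rz[2])
  nLaps <- config@nLaps
  Tmax <- ceiling(nLaps * L / (config@meanSpeed * min(1, config@slowdownFactor)) *
                    fr * 2) + 100L
  pos <- numeric(Tmax); vel <- numeric(Tmax); lap <- integer(Tmax)
  pumpV <- integer(Tmax); lickFrame <- logical(Tmax)
  p <- 0; curLap <- 0L; eps <- 0
  restUntil <- -1   # rest-bout end time; mice pause between stretches
  lastLick <- -Inf
  rewarded <- logical(nLaps)
  lapStart <- integer(nLaps); lapStart[1] <- 1L
  pumpTimes <- numeric(0)
  pending <- numeric(0)     # scheduled consummatory lick times
  t <- 0; i <- 0L
  while (curLap < nLaps && i < Tmax) {
    i <- i + 1L
    eps <- 0.9 * eps + 0.2 * sqrt(1 - 0.81) * rnorm(1)
    if (t >= restUntil && runif(1) < dt / 40)
      restUntil <- t + stats::rlnorm(1, log(8), 0.8)
    v <- config@meanSpeed * exp(eps)
    if (inZone(p, slowZone, L)) v <- v * config@slowdownFactor
    if (t < restUntil) v <- 0.3 * exp(eps)
    v <- max(v, 0.1)
    # licking ---------------------------------------------------------------
    lick <- FALSE
    if (length(pending) && t >= pending[1]) {
      lick <- TRUE
      pending <- pending[-1]
    } else if (t - lastLick >= 0.4 && !length(pending)) {
      dToZone <- beltWrap(rz[1] - p, L)
      inRz <- inZone(p, rz, L)
      rate <- config@lickBaseRate
      if (dToZone > 0 && dToZone <= config@lickRampStart)
        rate <- config@lickBaseRate +
          (config@lickMaxRate - config@lickBaseRate) *
          (1 - dToZone / config@lickRampStart)
      if (inRz && !rewarded[curLap + 1L]) rate <- config@lickMaxRate
      if (inRz && rewarded[curLap + 1L]) rate <- config@lickBaseRate
      lick <- runif(1) < rate * dt
    }
    if (lick) {
      lickFrame[i] <- TRUE
      lastLick <- t
      if (inZone(p, rz, L) && !rewarded[curLap + 1L]) {
        rewarded[curLap + 1L] <- TRUE
        pumpV[i] <- 1L
        pumpTimes <- c(pumpTimes, t)
        onset <- t + runif(1, 0.6, 1.2)
        gaps <- runif(3 + rpois(1, 2), 0.42, 0.65)
        pending <- onset + cumsum(c(0, gaps))
      }
    }
    pos[i] <- p; vel[i] <- v; lap[i] <- curLap
    pNew <- p + v * dt
    if (pNew >= L) {
      curLap <- curLap + 1L
      if (curLap < nLaps) lapStart[curLap + 1L] <- i + 1L
    }
    p <- beltWrap(pNew, L)
    t <- t + dt
  }
  n <- i
  lickIdx <- which(lickFrame[seq_len(n)])
  time_s <- (seq_len(n) - 1) * dt
  # analog lick signal: impulse train convolved with a causal kernel
  kern <- c(1, 0.55, 0.3, 0.15)
  analog <- numeric(n)
  amp <- rnorm(length(lickIdx), 1, 0.05)
  for (k in seq_along(kern)) {
    idx <- lickIdx + k - 1L
    ok <- idx <= n
    analog[idx[ok]] <- analog[idx[ok]] + amp[ok] * kern[k]
  }
  analog <- analog + rnorm(n, 0, 0.02)
  frames <- data.frame(time_s = time_s, position_cm = pos[seq_len(n)],
                       velocity_cms = vel[seq_len(n)],
                       lick_analog = analog, pump = pumpV[seq_len(n)],
                       lap = lap[seq_len(n)])
  lickTimes <- time_s[lickIdx]
  gaps <- c(Inf, diff(lickTimes))
  truth <- list(lickTimes = lickTimes, lickFrames = lickIdx,
                appetitiveOnsets = lickTimes[gaps >= 3],
                pumpTimes = pumpTimes, rewardedLaps = rewarded,
                lapStartFrames = lapStart)
  list(frames = frames, truth = truth)
}

#' Simulate the deconvolved event raster for one session
#'
#' Per frame t, each neuron's rate is
#' \eqn{\lambda(t) = baseline \cdot g_{place} \cdot g_{speed} \cdot
#' g_{lick}}, clipped at zero, and events are drawn Poisson(\eqn{\lambda}).
#' The lick kernel is triggered at the generator's appetitive lick onsets.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param specs neuron spec table (see [neuronSpec()], [scenarioSpecs()]).
#' @param behavior behavioral frames data.frame (from [simulateBehavior()]).
#' @param onsetTimes appetitive lick onset times (s) driving lick-tuned
#'   neurons; taken from the generator's ground truth.
#' @return neurons x frames integer matrix of event counts, with
#'   `rownames` = neuron ids.
#' @export
simulateEvents <- function(config, specs, behavior, onsetTimes = numeric(0)) {
  stopifnot(nrow(specs) == config@nNeurons)
  set.seed(childSeed(config@seed, 1000003))
  n <- nrow(specs)
  Tn <- nrow(behavior)
  fr <- config@frameRate
  L <- config@beltLength
  pos <- behavior$position_cm
  v <- behavior$velocity_cms
  onsetFrames <- pmin(pmax(round(onsetTimes * fr) + 1L, 1L), Tn)
  lickDriveCache <- new.env()
  lickDrive <- function(tau) {
    key <- format(tau)
    if (!is.null(lickDriveCache[[key]])) return(lickDriveCache[[key]])
    klen <- ceiling(5 * tau * fr)
    kern <- exp(-(seq_len(klen) - 1) / (tau * fr))
    drive <- numeric(Tn)
    for (f in onsetFrames) {
      idx <- f:min(Tn, f + klen - 1L)
      drive[idx] <- drive[idx] + kern[seq_along(idx)]
    }
    drive <- pmin(drive, 1)  # saturate under overlapping onsets
    lickDriveCache[[key]] <- drive
    drive
  }
  ev <- matrix(0L, n, Tn, dimnames = list(specs$neuron_id, NULL))
  nClipped <- 0L
  for (j in seq_len(n)) {
    lam <- rep(specs$baseline[j], Tn)
    if (!is.na(specs$place_gain[j])) {
      d <- beltDistance(pos, specs$place_center[j], L)
      lam <- lam * (1 + (specs$place_gain[j] - 1) *
                      exp(-d^2 / (2 * specs$place_width[j]^2)))
    }
    if (!is.na(specs$speed_slope[j]))
      lam <- lam * exp(specs$speed_slope[j] * (v - 10))
    if (!is.na(specs$lick_amp[j]))
      lam <- lam * exp(specs$lick_amp[j] * lickDrive(specs$lick_tau[j]))
    neg <- lam < 0
    nClipped <- nClipped + sum(neg)
    lam[neg] <- 0
    ev[j, ] <- rpois(Tn, lam)
  }
  if (nClipped > 0)
    message("simulateEvents: clipped ", nClipped,
            " negative rate values to 0")
  ev
}

#' Simulate a complete synthetic session
#'
#' Combines [simulateBehavior()] and [simulateEvents()] into a
#' \linkS4class{SpatialSession} carrying the generator ground truth in its
#' metadata.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param scenario scenario preset name (see [scenarioSpecs()]); ignored
#'   when `specs` is supplied.
#' @param specs optional explicit neuron spec table.
#' @return a \linkS4class{SpatialSession} with `groundTruth()` set.
#' @examples
#' ses <- simulateSession(simConfig(nLaps = 4, nNeurons = 8, seed = 1),
#'                        scenario = "place_only")
#' ses
#' @export
simulateSession <- function(config, scenario = "mixed_conjunctive",
                            specs = NULL) {
  if (is.null(specs)) specs <- scenarioSpecs(config, scenario)
  beh <- simulateBehavior(config)
  ev <- simulateEvents(config, specs, beh$frames,
                       onsetTimes = beh$truth$appetitiveOnsets)
  SpatialSession(ev, beh$frames, frameRate = config@frameRate,
                 projecting = specs$projecting,
                 beltLength = config@beltLength, nBins = config@nBins,
                 rewardZone = config@rewardZone,
                 textureBoundaries = config@textureBoundaries,
                 groundTruth = c(beh$truth, list(specs = specs)),
                 scenario = scenario)
}
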