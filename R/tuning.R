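#' @include AllClasses.R utils-belt.R behavior.R
NULL

# ---------------------------------------------------------------------------
# Speed and lick tuning classification: linear regression of bin-averaged
# activity on 1 cm/s velocity bins with BH FDR across neurons, per-event
# Wilcoxon paired pre/post comparison at appetitive lick onsets, and the
# shifted-lick-trace population null.
# ---------------------------------------------------------------------------

#' Speed tuning classification
#'
#' Each neuron's mean deconvolved event activity is computed in 1 cm/s
#' velocity bins over `[2, 30)` cm/s and regressed linearly on the bin
#' centers. p-values are Benjamini-Hochberg adjusted across the session's
#' neurons; neurons with adjusted p < 0.05 are classified speed-excited
#' (positive slope) or speed-inhibited (negative slope). The Pearson
#' correlation between the full activity and velocity traces is reported
#' alongside.
#'
#' @param session a \linkS4class{SpatialSession}.
#' @param vRange velocity range `[lo, hi)` in cm/s covered by the 1 cm/s
#'   bins.
#' @param alpha significance level on the adjusted p-values.
#' @param minBins minimum occupied velocity bins required for the
#'   regression.
#' @param minOccupancyS minimum time (s) a velocity bin must be occupied
#'   to enter the regression; bins visited for less are treated as
#'   unoccupied (their single-frame means are dominated by noise).
#' @return a `DataFrame`, one row per neuron: `slope`, `intercept`, `r`,
#'   `p`, `p_adj`, `speed_class` in {excited, inhibited, none},
#'   `velocity_correlation`, `n_bins_used`.
#' @export
speedTuningClassify <- function(session, vRange = c(2, 30), alpha = 0.05,
                                minBins = 5, minOccupancyS = 1) {
  frames <- behaviorFrames(session)
  ev <- eventMatrix(session)
  v <- frames$velocity_cms
  edges <- seq(vRange[1], vRange[2])
  vbin <- findInterval(v, edges, rightmost.closed = FALSE)
  use <- vbin >= 1 & v < vRange[2]
  centers <- edges[-length(edges)] + 0.5
  occ <- tabulate(vbin[use], length(centers))
  occupied <- occ >= minOccupancyS * frameRate(session)
  use[use] <- occupied[vbin[use]]
  n <- nrow(ev)
  slope <- intercept <- r <- p <- vcor <- rep(NA_real_, n)
  nUsed <- integer(n)
  for (j in seq_len(n)) {
    m <- tapply(ev[j, use], factor(vbin[use], levels = seq_along(centers)),
                mean)
    ok <- !is.na(m)
    nUsed[j] <- sum(ok)
    vcor[j] <- suppressWarnings(stats::cor(ev[j, ], v))
    if (sum(ok) < minBins) next
    y <- as.numeric(m[ok])
    x <- centers[ok]
    if (stats::sd(y) == 0) {
      slope[j] <- 0; intercept[j] <- y[1]; r[j] <- 0; p[j] <- 1
      next
    }
    fit <- stats::lm(y ~ x)
    cf <- summary(fit)$coefficients
    slope[j] <- cf[2, 1]
    intercept[j] <- cf[1, 1]
    p[j] <- cf[2, 4]
    r[j] <- stats::cor(x, y)
  }
  pAdj <- rep(NA_real_, n)
  pAdj[!is.na(p)] <- stats::p.adjust(p[!is.na(p)], method = "BH")
  cls <- rep("none", n)
  sig <- !is.na(pAdj) & pAdj < alpha & slope != 0
  cls[sig & slope > 0] <- "excited"
  cls[sig & slope < 0] <- "inhibited"
  DataFrame(neuron_id = rownames(ev), slope = slope,
            intercept = intercept, r = r, p = p, p_adj = pAdj,
            speed_class = cls, velocity_correlation = vcor,
            n_bins_used = nUsed, row.names = rownames(ev))
}

#' Lick modulation classification
#'
#' For each appetitive lick onset, each neuron's mean activity in the
#' pre-onset window is paired with that in the post-onset window; the
#' pairs are compared with Wilcoxon's paired test (two-sided). Neurons
#' significant at p < `alpha` are lick-excited (positive post-pre
#' difference) or lick-inhibited (negative).
#'
#' @param session a \linkS4class{SpatialSession}.
#' @param onsets appetitive lick onset times in s; detected from the
#'   session's analog lick signal when `NULL`.
#' @param preS,postS window lengths before/after onset, s.
#' @param alpha significance level.
#' @param minEvents minimum usable onsets (complete windows).
#' @return a `DataFrame`, one row per neuron: `statistic`, `p`,
#'   `mean_pre`, `mean_post`, `lick_class`, `n_events`.
#' @export
lickModulationClassify <- function(session, onsets = NULL, preS = 2,
                                   postS = 2, alpha = 0.05,
                                   minEvents = 5) {
  frames <- behaviorFrames(session)
  rate <- frameRate(session)
  if (is.null(onsets)) {
    lk <- detectLickEvents(frames$lick_analog, rate,
                           pumpTimes = frames$time_s[frames$pump > 0])
    onsets <- lk$appetitiveOnsets
  }
  ev <- eventMatrix(session)
  nPre <- round(preS * rate)
  nPost <- round(postS * rate)
  fr <- round(onsets * rate) + 1L
  fr <- fr[fr - nPre >= 1 & fr + nPost - 1 <= ncol(ev)]
  n <- nrow(ev)
  stat <- p <- mpre <- mpost <- rep(NA_real_, n)
  cls <- rep("none", n)
  for (j in seq_len(n)) {
    if (length(fr) < minEvents) next
    pre <- vapply(fr, function(f) mean(ev[j, (f - nPre):(f - 1)]),
                  numeric(1))
    post <- vapply(fr, function(f) mean(ev[j, f:(f + nPost - 1)]),
                   numeric(1))
    mpre[j] <- mean(pre)
    mpost[j] <- mean(post)
    d <- post - pre
    if (all(d == 0)) next  # all-tied pairs: test undefined, class none
    wt <- suppressWarnings(stats::wilcox.test(post, pre, paired = TRUE,
                                              exact = FALSE))
    stat[j] <- unname(wt$statistic)
    p[j] <- wt$p.value
    if (!is.na(p[j]) && p[j] < alpha)
      cls[j] <- if (mean(d) > 0) "excited" else "inhibited"
  }
  DataFrame(neuron_id = rownames(ev), statistic = stat, p = p,
            mean_pre = mpre, mean_post = mpost, lick_class = cls,
            n_events = length(fr), row.names = rownames(ev))
}

#' Population null from randomly shifted lick traces
#'
#' The analog lick trace is circularly shifted `nShifts` times by
#' offsets uniform over the recording; after each shift, lick events and
#' appetitive onsets are re-detected and every neuron re-classified,
#' yielding a null distribution of population proportions of
#' lick-excited and lick-inhibited cells.
#'
#' @param session a \linkS4class{SpatialSession}.
#' @param nShifts number of random shifts.
#' @param seed RNG seed.
#' @param includeIdentity include shift 0 as the first entry (sanity
#'   case reproducing the observed proportions).
#' @param preS,postS,alpha passed to [lickModulationClassify()].
#' @return data.frame with one row per shift: `shift_frames`,
#'   `pct_excited`, `pct_inhibited`.
#' @export
lickShiftNull <- function(session, nShifts = 100, seed = 1,
                          includeIdentity = FALSE, preS = 2, postS = 2,
                          alpha = 0.05) {
  frames <- behaviorFrames(session)
  rate <- frameRate(session)
  nFrames <- nrow(frames)
  set.seed(childSeed(seed, 0))
  shifts <- sample.int(nFrames, nShifts, replace = TRUE)
  if (includeIdentity) shifts <- c(0L, shifts)
  pump <- frames$time_s[frames$pump > 0]
  out <- lapply(shifts, function(s) {
    shifted <- if (s == 0) frames$lick_analog else
      frames$lick_analog[((seq_len(nFrames) - 1 + s) %% nFrames) + 1]
    lk <- detectLickEvents(shifted, rate, pumpTimes = pump)
    cl <- lickModulationClassify(session, onsets = lk$appetitiveOnsets,
                                 preS = preS, postS = postS,
                                 alpha = alpha)
    data.frame(shift_frames = s,
               pct_excited = 100 * mean(cl$lick_class == "excited"),
               pct_inhibited = 100 * mean(cl$lick_class == "inhibited"))
  })
  do.call(rbind, out)
}
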