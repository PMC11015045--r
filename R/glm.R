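#' @include AllClasses.R utils-belt.R behavior.R
NULL

# ---------------------------------------------------------------------------
# Poisson encoding model with grouped-feature shuffle significance.
# Response: per-neuron events scaled by SNR and SD, Gaussian-smoothed
# (0.5 s window, SD 2 samples), averaged down to 3 Hz, non-zero samples
# mapped to quintile ranks. Design: 45 position indicators + velocity and
# appetitive-lick-bout regressors at 19 lags (-3..+3 s in 1/3 s steps).
# Significance: a predictor group is significant when at least 96 of 100
# refits with that group circularly shifted by 200-700 samples have
# strictly decreased test R^2.
# ---------------------------------------------------------------------------

# internal: centered Gaussian smoothing by zero-padded convolution
gaussSmooth <- function(x, windowSamples, sdSamples = 2) {
  m <- max(3L, as.integer(windowSamples))
  k <- stats::dnorm(seq_len(m) - (m + 1) / 2, sd = sdSamples)
  k <- k / sum(k)
  n <- length(x)
  half <- (m - 1) %/% 2
  xp <- c(rep(0, half), x, rep(0, m - 1 - half))
  out <- stats::filter(xp, k, sides = 1)
  as.numeric(out[(m - 1 + 1):(m - 1 + n)])
}

# internal: 3 Hz window index for frames at `rate`
dsWindow <- function(nFrames, rate, targetRate = 3) {
  floor((seq_len(nFrames) - 1) / rate * targetRate) + 1L
}

#' Map non-zero samples to quintile ranks
#'
#' @param x non-negative numeric vector.
#' @return vector with zeros untouched and non-zero samples replaced by
#'   their quintile rank 1..5 (ties share a rank).
#' @export
quintileMap <- function(x) {
  nz <- which(x > 0)
  if (!length(nz)) return(x)
  r <- rank(x[nz], ties.method = "average")
  x[nz] <- ceiling(5 * r / length(nz))
  x
}

#' Preprocess one neuron's events into the model response
#'
#' Applied in order: divide by the signal-to-noise ratio, divide by the
#' resulting standard deviation, Gaussian-smooth (0.5 s window, SD 2
#' samples), average down to 3 Hz, map non-zero samples to quintiles.
#'
#' @param events event trace at the imaging rate.
#' @param rate imaging frame rate in Hz.
#' @param snr signal-to-noise ratio of the deconvolution (configured for
#'   synthetic data).
#' @param targetRate model sampling rate, Hz.
#' @return list with `response` (at `targetRate`) and `flagged` (TRUE for
#'   an all-zero trace, excluded from modeling).
#' @export
preprocessResponse <- function(events, rate, snr = 1, targetRate = 3) {
  stopifnot(snr > 0)
  if (all(events == 0))
    return(list(response = rep(0, max(dsWindow(length(events), rate,
                                               targetRate))),
                flagged = TRUE))
  x <- events / snr
  x <- x / stats::sd(x)
  x <- gaussSmooth(x, windowSamples = round(0.5 * rate), sdSamples = 2)
  win <- dsWindow(length(x), rate, targetRate)
  y <- as.numeric(tapply(x, win, mean))
  list(response = quintileMap(pmax(y, 0)), flagged = FALSE)
}

# internal: circularly shift rows of a matrix/vector
rowShift <- function(x, s) {
  n <- if (is.matrix(x)) nrow(x) else length(x)
  idx <- ((seq_len(n) - 1 + s) %% n) + 1L
  if (is.matrix(x)) x[idx, , drop = FALSE] else x[idx]
}

#' Build the encoding-model design matrix at 3 Hz
#'
#' Position is median-downsampled to 3 Hz and encoded as 45 spatial-bin
#' indicators. Velocity is mean-normalized (divided by its mean),
#' mean-downsampled, and replicated at 19 lags spanning -3 s to +3 s in
#' 1/3 s steps (circular shifts within the session). The licking
#' regressor is the appetitive-lick-bout indicator (bouts farther than
#' 5 s from any reward dispensation), median-downsampled, at the same 19
#' lags.
#'
#' @param session a \linkS4class{SpatialSession}.
#' @param targetRate model sampling rate, Hz.
#' @param lagSpanS lag extent on each side, s.
#' @return list with `X` (samples x 83), `groups` (named list of column
#'   indices for position / velocity / licking), `n` (samples).
#' @export
buildDesignMatrix <- function(session, targetRate = 3, lagSpanS = 3) {
  frames <- behaviorFrames(session)
  rate <- frameRate(session)
  nFrames <- nrow(frames)
  if (nFrames / rate < 2 * lagSpanS)
    stop("session shorter than ", 2 * lagSpanS, " s; lags undefined")
  L <- beltLength(session)
  nBins <- nSpatialBins(session)
  # appetitive lick bouts: exclude bouts within 5 s of a reward
  pump <- frames$time_s[frames$pump > 0]
  lk <- detectLickEvents(frames$lick_analog, rate, pumpTimes = pump)
  boutInd <- rep(0, nFrames)
  if (length(lk$eventTimes)) {
    for (b in unique(lk$boutId)) {
      ts <- lk$eventTimes[lk$boutId == b]
      onset <- ts[1]
      if (length(pump) && any(onset > pump - 5 & onset < pump + 5)) next
      f0 <- round(onset * rate) + 1L
      f1 <- round(ts[length(ts)] * rate) + 1L
      boutInd[f0:min(f1, nFrames)] <- 1
    }
  }
  win <- dsWindow(nFrames, rate, targetRate)
  pos3 <- as.numeric(tapply(frames$position_cm, win, stats::median))
  v <- frames$velocity_cms
  v3 <- as.numeric(tapply(v / mean(v), win, mean))
  lick3 <- as.numeric(tapply(boutInd, win, stats::median))
  n <- length(pos3)
  posBin <- positionBin(pos3, L, nBins)
  Xpos <- matrix(0, n, nBins)
  Xpos[cbind(seq_len(n), posBin)] <- 1
  lags <- seq(-lagSpanS * targetRate, lagSpanS * targetRate)
  Xv <- vapply(lags, function(s) rowShift(v3, s), numeric(n))
  Xl <- vapply(lags, function(s) rowShift(lick3, s), numeric(n))
  X <- cbind(Xpos, Xv, Xl)
  colnames(X) <- c(sprintf("pos%02d", seq_len(nBins)),
                   sprintf("vel_lag%+d", lags),
                   sprintf("lick_lag%+d", lags))
  groups <- list(position = seq_len(nBins),
                 velocity = nBins + seq_along(lags),
                 licking = nBins + length(lags) + seq_along(lags))
  list(X = X, groups = groups, n = n)
}

#' Fit the Poisson encoding model and score it on held-out data
#'
#' Poisson log-link regression (no lambda penalty; fitted by IRLS with a
#' vanishingly small numerical ridge of 1e-8 so the intercept plus the 45
#' position indicators stay solvable) with a seeded random
#' train/validation/test row split (80%/10%/10%), matching the reference
#' splitter of the modeling library this procedure was defined with; a
#' contiguous-in-time split is available for sensitivity analyses of
#' autocorrelation leakage. The score is R^2 = 1 - SSE/SST of the predicted mean on
#' the test split (squared-correlation variant behind `scoreType`).
#'
#' @param y response (quintile-mapped, non-negative).
#' @param X design matrix.
#' @param split train/validation/test fractions.
#' @param contiguous use a contiguous-in-time split instead of the
#'   default seeded random split.
#' @param seed seed for the random split.
#' @param scoreType `"vexp"` (1 - SSE/SST) or `"cor2"`.
#' @param start optional warm-start coefficients.
#' @return list with `r2`, `coef`, `converged`, `testIdx`.
#' @export
fitPoissonGlm <- function(y, X, split = c(0.8, 0.1, 0.1),
                          contiguous = FALSE, seed = 1,
                          scoreType = c("vexp", "cor2"), start = NULL) {
  scoreType <- match.arg(scoreType)
  n <- length(y)
  ord <- if (contiguous) seq_len(n) else {
    # draw the split without disturbing the caller's RNG stream
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(childSeed(seed, 0))
    o <- sample.int(n)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    o
  }
  nTr <- floor(split[1] * n)
  nVal <- floor(split[2] * n)
  trainIdx <- ord[seq_len(nTr)]
  testIdx <- ord[(nTr + nVal + 1):n]
  if (sum(y[trainIdx] > 0) < 50)
    stop("fewer than 50 non-zero response samples in the training split")
  Xi <- cbind(`(Intercept)` = 1, X)
  fit <- .poissonIRLS(Xi[trainIdx, , drop = FALSE],
                      as.numeric(y[trainIdx]), start)
  if (isTRUE(fit$failed)) stop("IRLS solve failed on this design")
  cf <- drop(fit$coef)
  names(cf) <- colnames(Xi)
  mu <- exp(pmin(pmax(drop(Xi[testIdx, , drop = FALSE] %*% cf), -30), 30))
  yt <- y[testIdx]
  r2 <- if (scoreType == "vexp") {
    sst <- sum((yt - mean(yt))^2)
    if (sst == 0) NA_real_ else 1 - sum((yt - mu)^2) / sst
  } else {
    if (stats::sd(mu) == 0 || stats::sd(yt) == 0) NA_real_
    else stats::cor(yt, mu)^2
  }
  list(r2 = r2, coef = cf, converged = fit$converged, testIdx = testIdx)
}

#' Grouped-feature shuffle significance for one neuron
#'
#' For each predictor group, `nShuffles` models are refit with only that
#' group's columns circularly shifted by a random offset drawn uniformly
#' from 200..700 samples; the group is significant when at least
#' `minDecreases` of the refits have strictly decreased test R^2.
#'
#' @param y response.
#' @param design a [buildDesignMatrix()] result.
#' @param nShuffles shuffles per group.
#' @param seed RNG seed.
#' @param minDecreases decrease count required for significance.
#' @param shiftRange shift bounds in samples (adapted with a message for
#'   sessions shorter than the upper bound).
#' @param splitSeed seed for the train/validation/test split shared by
#'   the full and all shuffled fits.
#' @param ... passed to [fitPoissonGlm()].
#' @return list with `r2Full`, and per group: `deltaR2` (mean R^2 drop),
#'   `nDecreased`, `significant`, `shuffleR2` (matrix groups x shuffles).
#' @export
shuffleFeatureSignificance <- function(y, design, nShuffles = 100,
                                       seed = 1, minDecreases = 96,
                                       shiftRange = c(200, 700),
                                       splitSeed = 1, ...) {
  X <- design$X
  groups <- design$groups
  n <- nrow(X)
  if (n <= shiftRange[2] + 1) {
    shiftRange <- c(min(shiftRange[1], floor(n / 4)), floor(n / 2))
    message("shuffleFeatureSignificance: short session; shift bounds ",
            "adapted to [", shiftRange[1], ", ", shiftRange[2], "]")
  }
  full <- fitPoissonGlm(y, X, seed = splitSeed, ...)
  set.seed(childSeed(seed, 0))
  # pre-draw shifts (with spares for redraws after failed refits)
  shiftPool <- matrix(sample(shiftRange[1]:shiftRange[2],
                             length(groups) * nShuffles * 11,
                             replace = TRUE), nrow = length(groups))
  shufR2 <- matrix(NA_real_, length(groups), nShuffles,
                   dimnames = list(names(groups), NULL))
  nFailed <- 0L
  for (g in seq_along(groups)) {
    cols <- groups[[g]]
    k <- 0L
    drawn <- 0L
    while (k < nShuffles) {
      drawn <- drawn + 1L
      s <- shiftPool[g, drawn]
      X2 <- X
      X2[, cols] <- rowShift(X[, cols, drop = FALSE], s)
      r2 <- tryCatch(fitPoissonGlm(y, X2, start = full$coef,
                                    seed = splitSeed, ...)$r2,
                     error = function(e) NULL)
      if (is.null(r2)) {
        nFailed <- nFailed + 1L
        if (drawn >= ncol(shiftPool)) stop("too many failed shuffles")
        next
      }
      k <- k + 1L
      shufR2[g, k] <- r2
    }
  }
  if (nFailed > 0)
    message("shuffleFeatureSignificance: ", nFailed,
            " failed shuffle refit(s) redrawn")
  nDec <- rowSums(shufR2 < full$r2)
  list(r2Full = full$r2,
       deltaR2 = rowMeans(full$r2 - shufR2),
       nDecreased = nDec,
       significant = nDec >= minDecreases,
       shuffleR2 = shufR2)
}

#' Encoding analysis of a whole session
#'
#' Preprocesses every neuron's response, builds the shared design matrix,
#' fits the full Poisson model, and runs the grouped shuffle test; the
#' conjunctive class counts the significant groups (none / single / dual
#' / triple).
#'
#' @param session a \linkS4class{SpatialSession}.
#' @param snr signal-to-noise ratio used in response scaling.
#' @param nShuffles shuffles per predictor group.
#' @param seed RNG seed (one substream per neuron).
#' @param neurons optional subset of neuron indices to model.
#' @return a `DataFrame`, one row per modeled neuron: `r2`,
#'   `sig_position`, `sig_velocity`, `sig_licking`, per-group `delta_*`,
#'   `n_significant`, `conjunctive_class`, `projecting`, `flagged`
#'   (all-zero or failed preconditions; such neurons carry NAs).
#' @export
encodeSession <- function(session, snr = 1, nShuffles = 100, seed = 1,
                          neurons = seq_len(nrow(session))) {
  design <- buildDesignMatrix(session)
  ev <- eventMatrix(session)
  rate <- frameRate(session)
  rows <- lapply(neurons, function(j) {
    resp <- preprocessResponse(ev[j, ], rate, snr = snr)
    base <- data.frame(neuron_id = rownames(ev)[j],
                       r2 = NA_real_, sig_position = NA,
                       sig_velocity = NA, sig_licking = NA,
                       delta_position = NA_real_,
                       delta_velocity = NA_real_,
                       delta_licking = NA_real_,
                       n_significant = NA_integer_,
                       conjunctive_class = NA_character_,
                       projecting = projecting(session)[j],
                       flagged = TRUE)
    if (resp$flagged) return(base)
    y <- resp$response[seq_len(design$n)]
    res <- tryCatch(
      shuffleFeatureSignificance(y, design, nShuffles = nShuffles,
                                 seed = childSeed(seed, 900000 + j),
                                 splitSeed = childSeed(seed, 700000 + j)),
      error = function(e) NULL)
    if (is.null(res)) return(base)
    nSig <- sum(res$significant)
    base$r2 <- res$r2Full
    base$sig_position <- res$significant[["position"]]
    base$sig_velocity <- res$significant[["velocity"]]
    base$sig_licking <- res$significant[["licking"]]
    base$delta_position <- res$deltaR2[["position"]]
    base$delta_velocity <- res$deltaR2[["velocity"]]
    base$delta_licking <- res$deltaR2[["licking"]]
    base$n_significant <- nSig
    base$conjunctive_class <- c("none", "single", "dual",
                                "triple")[nSig + 1]
    base$flagged <- FALSE
    base
  })
  res <- DataFrame(do.call(rbind, rows))
  rownames(res) <- res$neuron_id
  res
}

#' Conjunctive-class summary across neurons
#'
#' @param results an [encodeSession()] result.
#' @return list with `classCounts` (class x population table),
#'   `proportions`, and `overlap` (counts per significant-group
#'   combination, the Venn-style breakdown).
#' @export
classifyConjunctive <- function(results) {
  ok <- !results$flagged & !is.na(results$conjunctive_class)
  r <- results[ok, ]
  pop <- factor(ifelse(r$projecting, "projecting", "nonprojecting"),
                levels = c("projecting", "nonprojecting"))
  cls <- factor(r$conjunctive_class,
                levels = c("none", "single", "dual", "triple"))
  counts <- table(class = cls, population = pop)
  combo <- paste0(ifelse(r$sig_position, "P", ""),
                  ifelse(r$sig_velocity, "V", ""),
                  ifelse(r$sig_licking, "L", ""))
  combo[combo == ""] <- "none"
  list(classCounts = counts,
       proportions = prop.table(counts, margin = 2),
       overlap = table(combo))
}
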