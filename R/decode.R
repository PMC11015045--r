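#' @include AllClasses.R utils-belt.R
NULL

# ---------------------------------------------------------------------------
# Linear decoding of reward / anticipation zone presence from population
# activity: per-neuron quantile normalization of non-zero events, movement
# filtering, 1 Hz accumulation, binary zone labels, a linear SVM
# (hinge loss, L2 penalty) cross-validated over lap parity (train even /
# test odd and vice versa, scores averaged), and size-matched population
# comparisons (100 random subsamples of the larger population).
# ---------------------------------------------------------------------------

# internal: circular mean of belt positions
circMeanPos <- function(pos, beltLength) {
  th <- 2 * pi * pos / beltLength
  beltWrap(atan2(mean(sin(th)), mean(cos(th))) / (2 * pi) * beltLength,
           beltLength)
}

#' Prepare the 1 Hz decoder dataset
#'
#' Non-zero deconvolved events are quantile-normalized per neuron
#' (empirical CDF rank in (0, 1], over the whole session), movement
#' frames (velocity > `vMin`) are accumulated into 1 s bins (activity
#' summed, position circularly averaged), and each sample is labeled by
#' zone membership of its position.
#'
#' @param session a \linkS4class{SpatialSession}.
#' @param zone positive-class definition: `"both"` (reward +
#'   anticipation), `"reward"`, or `"anticipation"`.
#' @param vMin movement threshold, cm/s.
#' @return list with `activity` (samples x neurons), `label` (0/1),
#'   `lap`, `parity`, `position_cm`, `singleClass` flag.
#' @export
prepareDecoderDataset <- function(session, zone = c("both", "reward",
                                                    "anticipation"),
                                  vMin = 2) {
  zone <- match.arg(zone)
  frames <- behaviorFrames(session)
  ev <- eventMatrix(session)
  L <- beltLength(session)
  rz <- rewardZone(session)
  zoneInt <- switch(zone,
                    both = c(rz[1] - 30, rz[2]),
                    reward = rz,
                    anticipation = c(rz[1] - 30, rz[1]))
  # per-neuron quantile normalization of non-zero events
  Q <- t(apply(ev, 1, function(x) {
    nz <- which(x > 0)
    if (!length(nz)) return(x)
    x[nz] <- rank(x[nz], ties.method = "average") / length(nz)
    x
  }))
  mov <- frames$velocity_cms > vMin
  sec <- floor(frames$time_s) + 1L
  keep <- mov
  secs <- sort(unique(sec[keep]))
  act <- matrix(0, length(secs), nrow(ev),
                dimnames = list(NULL, rownames(ev)))
  pos <- lap <- numeric(length(secs))
  for (i in seq_along(secs)) {
    sel <- keep & sec == secs[i]
    act[i, ] <- rowSums(Q[, sel, drop = FALSE])
    pos[i] <- circMeanPos(frames$position_cm[sel], L)
    lap[i] <- stats::median(frames$lap[sel])
  }
  label <- as.integer(inZone(pos, zoneInt, L))
  list(activity = act, label = label, lap = lap,
       parity = as.integer(lap) %% 2L, position_cm = pos,
       singleClass = length(unique(label)) < 2)
}

# internal: one decoding fold (linear SVM, hinge loss + L2 penalty)
decodeFold <- function(Xtr, ytr, Xte, yte, minNonZero = 10) {
  use <- colSums(Xtr > 0) >= minNonZero & colSums(Xte > 0) >= minNonZero
  if (!any(use) || length(unique(ytr)) < 2 || length(unique(yte)) < 2)
    return(list(accuracy = NA_real_, balanced = NA_real_,
                nUsed = sum(use), failed = TRUE))
  fit <- e1071::svm(Xtr[, use, drop = FALSE], factor(ytr, levels = 0:1),
                    kernel = "linear", scale = FALSE)
  pred <- stats::predict(fit, Xte[, use, drop = FALSE])
  acc <- mean(pred == yte)
  bal <- mean(c(mean(pred[yte == 0] == 0), mean(pred[yte == 1] == 1)))
  list(accuracy = acc, balanced = bal, nUsed = sum(use), failed = FALSE)
}

#' Train and evaluate the zone decoder with odd/even-lap cross-validation
#'
#' A linear max-margin classifier (hinge loss, L2 penalty) is trained on
#' even laps and tested on odd laps, and vice versa; the reported score
#' is the mean accuracy of the two folds. Neurons with fewer than
#' `minNonZero` non-zero time bins in either the train or test fold are
#' excluded from that fold. Balanced accuracy is reported alongside for
#' interpretation under class imbalance (no reweighting is applied).
#'
#' @param dataset a [prepareDecoderDataset()] result.
#' @param neurons optional column indices or logical mask selecting the
#'   population to decode from.
#' @param minNonZero per-fold non-zero bin inclusion threshold.
#' @return list with `score` (mean fold accuracy), `foldScores`,
#'   `balancedAccuracy`, `nUsed` per fold, `foldFailed` flags.
#' @export
trainEvalZoneDecoder <- function(dataset, neurons = NULL,
                                 minNonZero = 10) {
  if (dataset$singleClass)
    stop("labels are single-class; decoding skipped")
  X <- dataset$activity
  if (!is.null(neurons)) X <- X[, neurons, drop = FALSE]
  y <- dataset$label
  even <- dataset$parity == 0
  f1 <- decodeFold(X[even, , drop = FALSE], y[even],
                   X[!even, , drop = FALSE], y[!even], minNonZero)
  f2 <- decodeFold(X[!even, , drop = FALSE], y[!even],
                   X[even, , drop = FALSE], y[even], minNonZero)
  fs <- c(evenTrain = f1$accuracy, oddTrain = f2$accuracy)
  list(score = mean(fs, na.rm = TRUE), foldScores = fs,
       balancedAccuracy = mean(c(f1$balanced, f2$balanced), na.rm = TRUE),
       nUsed = c(f1$nUsed, f2$nUsed),
       foldFailed = c(f1$failed, f2$failed))
}

#' Compare decoding by two populations with size matching
#'
#' Scores population A with all of its neurons, and population B with 100
#' random subsamples matched to A's size (roles are swapped when A is the
#' larger), reporting A's score against the subsample mean.
#'
#' @param dataset a [prepareDecoderDataset()] result.
#' @param maskA,maskB disjoint logical masks or index vectors over
#'   neurons.
#' @param nSub number of size-matched subsamples.
#' @param seed RNG seed.
#' @param minNonZero per-fold inclusion threshold.
#' @return list with `scoreA`, `scoresB` (length `nSub`), `meanScoreB`,
#'   `nA`, `swapped`; or `list(skipped = TRUE, reason = ...)` when A has
#'   fewer than 2 neurons or labels are single-class.
#' @export
comparePopulationsDecoding <- function(dataset, maskA, maskB, nSub = 100,
                                       seed = 1, minNonZero = 10) {
  idxA <- if (is.logical(maskA)) which(maskA) else maskA
  idxB <- if (is.logical(maskB)) which(maskB) else maskB
  if (length(intersect(idxA, idxB)))
    stop("population masks must be disjoint")
  if (dataset$singleClass)
    return(list(skipped = TRUE, reason = "single-class labels"))
  if (length(idxA) > length(idxB)) {
    tmp <- idxA; idxA <- idxB; idxB <- tmp
    swapped <- TRUE
  } else swapped <- FALSE
  if (length(idxA) < 2)
    return(list(skipped = TRUE, reason = "fewer than 2 neurons in A"))
  scoreA <- trainEvalZoneDecoder(dataset, idxA, minNonZero)$score
  set.seed(childSeed(seed, 0))
  scoresB <- vapply(seq_len(nSub), function(k) {
    sub <- sample(idxB, length(idxA))
    trainEvalZoneDecoder(dataset, sub, minNonZero)$score
  }, numeric(1))
  list(skipped = FALSE, scoreA = scoreA, scoresB = scoresB,
       meanScoreB = mean(scoresB, na.rm = TRUE), nA = length(idxA),
       swapped = swapped)
}
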