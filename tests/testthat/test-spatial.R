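rate <- 15.2

# small helper: frames with uniform running and chosen event placement
uniformFrames <- function(nLaps = 4, perCm = 1) {
  pos <- rep(rep(seq(0, 359.5, by = 1 / perCm)), nLaps)
  n <- length(pos)
  data.frame(time_s = (seq_len(n) - 1) / rate, position_cm = pos,
             velocity_cms = 10, lick_analog = 0, pump = 0L,
             lap = rep(seq_len(nLaps) - 1L, each = n / nLaps))
}

test_that("rate maps match a brute-force binned group-mean oracle", {
  set.seed(3)
  fr <- uniformFrames(4)
  fr$velocity_cms <- runif(nrow(fr), 0, 20)
  ev <- rpois(nrow(fr), 0.3)
  rm1 <- computeRatemap(ev, fr, rate)
  mov <- fr$velocity_cms > 2
  bins <- positionBin(fr$position_cm, 360, 45)
  for (i in c(1, 17, 45)) {
    sel <- mov & bins == i
    expect_equal(rm1$a[i], mean(ev[sel]))
    expect_equal(rm1$o[i], sum(sel) / sum(mov))
  }
  expect_equal(sum(rm1$o), 1)
  expect_equal(rm1$firingRate, sum(ev[mov] > 0) / (sum(mov) / rate))
})

test_that("rate map computation demands movement frames", {
  fr <- uniformFrames(1)
  fr$velocity_cms <- 1
  expect_error(computeRatemap(rpois(nrow(fr), 0.1), fr, rate),
               "no movement")
})

test_that("spatial information reproduces hand-computed values", {
  mkMap <- function(o, a) list(a = a, o = o, firingRate = 2)
  # two bins, activity only in one: SI = 0.5*2*log2(2) = 1
  si <- spatialInformation(mkMap(c(0.5, 0.5), c(2, 0)))
  expect_equal(si$SI, 1)
  expect_equal(si$SIrate, 2)
  # constant activity: SI = 0
  expect_equal(spatialInformation(mkMap(rep(1 / 45, 45),
                                        rep(3, 45)))$SI, 0)
  # silent neuron: undefined
  expect_true(is.na(spatialInformation(mkMap(c(0.5, 0.5), c(0, 0)))$SI))
})

test_that("SI and sparsity match literal summation oracles on random maps", {
  set.seed(11)
  for (k in 1:20) {
    o <- runif(45); o <- o / sum(o)
    a <- rpois(45, 2) * runif(45)
    rm1 <- list(a = a, o = o, firingRate = 1)
    abar <- sum(o * a)
    siOracle <- 0
    for (i in 1:45) if (a[i] > 0)
      siOracle <- siOracle + o[i] * a[i] * log2(a[i] / abar)
    expect_equal(spatialInformation(rm1)$SI, siOracle, tolerance = 1e-12)
    spOracle <- sum(o * a)^2 / sum(o * a^2)
    expect_equal(sparsityIndex(rm1), spOracle, tolerance = 1e-12)
  }
})

test_that("sparsity is 1 for uniform maps and decreases for narrower fields", {
  o <- rep(1 / 45, 45)
  expect_equal(sparsityIndex(list(a = rep(2, 45), o = o)), 1)
  expect_equal(sparsityIndex(list(a = c(2, 0), o = c(0.5, 0.5))), 0.5)
  widths <- c(20, 12, 6, 3)
  sps <- vapply(widths, function(w) {
    a <- exp(-beltDistance(binCenters(360, 45), 180, 360)^2 / (2 * w^2))
    sparsityIndex(list(a = a, o = o))
  }, numeric(1))
  expect_true(all(diff(sps) < 0))
})

test_that("the circular shuffle preserves event mass and is a permutation", {
  idx <- placecode:::shuffleIndex(100, 37, placecode:::makeBlocks(100, 7),
                                  sample(7))
  expect_equal(sort(idx), 1:100)
  ev <- rpois(100, 1)
  expect_equal(sum(ev[idx]), sum(ev))
})

test_that("place-cell verdicts separate tuned from untuned neurons", {
  ses <- smallMixed()
  gt <- groundTruth(ses)$specs
  pc <- placeCellTest(ses, nShuffles = 300, seed = 21)
  purePlace <- gt$tuning_class == "place"
  untuned <- gt$tuning_class == "untuned"
  expect_gte(mean(pc$is_place_cell[purePlace]), 0.9)
  expect_lte(mean(pc$is_place_cell[untuned]), 0.2)
  # verdict equals the stated rule
  expect_equal(pc$is_place_cell, !is.na(pc$SI) & pc$SI > pc$null_p95)
})

test_that("field extraction finds bumps, wraps, and picks the most prominent", {
  o <- rep(1 / 45, 45)
  bump <- function(ctr, w, h = 1)
    h * exp(-beltDistance(binCenters(360, 45), ctr, 360)^2 / (2 * w^2))
  f1 <- extractPlaceField(bump(156, 16))   # bin 20
  expect_true(f1$found)
  expect_lte(abs(f1$peakBin - 20), 1)
  expect_true(f1$startBin < 20 && f1$endBin > 20)
  expect_true(20 %in% f1$bins)
  # bump straddling the origin: start numerically greater than end
  f2 <- extractPlaceField(bump(2, 12))
  expect_true(f2$found)
  expect_true(f2$peakBin %in% c(44, 45, 1, 2))
  expect_true(f2$startBin > f2$endBin)
  expect_true(1 %in% f2$bins)
  # two bumps: the more prominent one wins
  f3 <- extractPlaceField(bump(100, 10, 3) + bump(260, 10, 2))
  expect_true(f3$found)
  expect_lte(beltDistance((f3$peakBin - 0.5) * 8, 100, 360), 12)
  # flat map: no field, but no error
  expect_false(extractPlaceField(rep(1, 45))$found)
})

test_that("COM is the polar centroid mapped back to the belt", {
  a <- rep(0, 45); a[20] <- 2
  expect_equal(placeFieldCOM(a), binCenters(360, 45)[20])
  # hand polar computation on a two-bin map
  a2 <- rep(0, 45); a2[10] <- 1; a2[12] <- 1
  th <- 2 * pi * binCenters(360, 45)[c(10, 12)] / 360
  ang <- atan2(sum(sin(th)), sum(cos(th)))
  expect_equal(placeFieldCOM(a2), (ang %% (2 * pi)) / (2 * pi) * 360)
  expect_true(is.na(placeFieldCOM(rep(0, 45))))
})

test_that("field metrics hit their closed-form cases", {
  # construct 4 identical laps with activity concentrated in bins 19-21
  fr <- uniformFrames(4)
  bins <- positionBin(fr$position_cm, 360, 45)
  ev <- ifelse(bins %in% 19:21, 2, 0)
  field <- list(found = TRUE, peakBin = 20L, startBin = 18L,
                endBin = 22L, bins = 18:22)
  m <- fieldMetrics(ev, fr, field, rate)
  expect_equal(m$reliability, 1)
  expect_equal(m$lapStability, 1)   # identical lap vectors
  expect_gt(m$deltaInOut, 0)
  expect_equal(m$COM_cm, binCenters(360, 45)[20], tolerance = 1)
})

test_that("every spatial statistic is invariant to a belt translation", {
  ses <- tinyMixed()
  fr <- behaviorFrames(ses)
  ev <- eventMatrix(ses)[5, ]
  off <- 120
  fr2 <- fr
  fr2$position_cm <- beltWrap(fr$position_cm + off, 360)
  r1 <- computeRatemap(ev, fr, rate)
  r2 <- computeRatemap(ev, fr2, rate)
  shift <- off / 8
  expect_equal(r2$a, r1$a[((seq_len(45) - 1 - shift) %% 45) + 1])
  expect_equal(spatialInformation(r2)$SI, spatialInformation(r1)$SI)
  expect_equal(sparsityIndex(r2), sparsityIndex(r1))
  expect_equal(beltWrap(placeFieldCOM(r2) - off, 360), placeFieldCOM(r1),
               tolerance = 1e-8)
})

test_that("boundary ratio test calibrates on uniform fields and flags enrichment", {
  tb <- c(0, 60, 120, 180, 240, 300)
  set.seed(14)
  starts <- sample.int(45, 120, replace = TRUE)
  ends <- ((starts - 1 + sample(3:6, 120, TRUE)) %% 45) + 1
  br <- boundaryRatioTest(starts, ends, tb, nPerm = 500, seed = 3)
  expect_gt(br$startPercentile, 2.5)
  expect_lt(br$startPercentile, 97.5)
  # all starts exactly at boundary bins: maximal enrichment
  bBins <- positionBin(tb, 360, 45)
  starts2 <- rep(bBins, length.out = 60)
  ends2 <- ((starts2 - 1 + 4) %% 45) + 1
  br2 <- boundaryRatioTest(starts2, ends2, tb, nPerm = 1000, seed = 3)
  expect_true(br2$startAboveP999)
  expect_gt(br2$startPercentile, 99.9)
})

test_that("reward-zone field density reports proportion against chance", {
  # uniform COMs: proportion equals the zone measure
  com <- seq(0.5, 359.5, by = 1)
  rd <- rewardZoneFieldDensity(com)
  expect_equal(rd$proportion, 60 / 360)
  expect_equal(rd$chance, 1 / 6, tolerance = 1e-9)
  expect_equal(rewardZoneFieldDensity(rep(255, 10))$proportion, 1)
  # grouped: enriched group exceeds the uniform group
  g <- rep(c("a", "b"), each = 100)
  com2 <- c(runif(100, 220, 269), runif(100, 0, 360))
  rd2 <- rewardZoneFieldDensity(com2, group = g)
  expect_gt(rd2$proportion[rd2$group == "a"],
            rd2$proportion[rd2$group == "b"])
})

test_that("overdispersion follows Eq.-style z statistics", {
  # obs equal to exp on every pass: zero variance
  od0 <- overdispersionStat(rep(4, 20), 4)
  expect_equal(od0$sigma2, 0)
  # Poisson passes: variance near 1 (averaged over cells)
  set.seed(8)
  s2 <- replicate(40, overdispersionStat(rpois(200, 6), 6)$sigma2)
  expect_equal(mean(s2), 1, tolerance = 0.1)
  # doubling the per-pass variance at fixed mean increases sigma2
  set.seed(9)
  obs1 <- rnorm(500, 10, 1); obs2 <- rnorm(500, 10, sqrt(2))
  expect_gt(overdispersionStat(obs2, 10)$sigma2,
            overdispersionStat(obs1, 10)$sigma2)
  expect_error(overdispersionStat(1:3, 0), "exp > 0")
})

test_that("in-field passes segment by lap and fuel overdispersion", {
  fr <- uniformFrames(3)
  field <- list(found = TRUE, bins = 10:14, startBin = 10L, endBin = 14L)
  passes <- extractFieldPasses(fr, field)
  expect_length(passes, 3)   # one traversal per lap
  bins <- positionBin(fr$position_cm, 360, 45)
  expect_true(all(bins[unlist(passes)] %in% 10:14))
  ev <- ifelse(bins %in% 10:14, rpois(nrow(fr), 2), 0)
  od <- overdispersion(ev, fr, field)
  expect_equal(od$nPasses, 3L)
  expect_true(is.finite(od$sigma2))
  # fewer than 2 qualifying passes: undefined
  od1 <- overdispersion(rep(0, nrow(fr)), fr, field)
  expect_true(is.na(od1$sigma2))
})
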