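test_that("downsampling applies the mandated statistic per signal", {
  rawRate <- 100; target <- 10
  t <- seq(0, 2 - 1 / rawRate, by = 1 / rawRate)
  raw <- data.frame(time_s = t,
                    position_cm = rep(42, length(t)),
                    velocity_cms = sin(2 * pi * t),
                    lick_analog = sin(2 * pi * 7 * t),
                    pump = 0)
  raw$pump[15] <- 1   # single high raw sample within one target window
  out <- downsampleSignals(raw, target)
  expect_equal(nrow(out), 20)
  # median of a constant is the constant
  expect_true(all(out$position_cm == 42))
  # any-sample semantics for the pump
  win <- floor((t - t[1]) * target) + 1
  expect_equal(which(out$pump == 1), unique(win[15]))
  # per-window SD matches an independent computation
  oracle <- as.numeric(tapply(raw$lick_analog, win, sd))
  expect_equal(out$lick_analog, oracle)
  # per-window mean for velocity
  expect_equal(out$velocity_cms,
               as.numeric(tapply(raw$velocity_cms, win, mean)))
})

test_that("downsampling rejects upsampling and carries empty windows", {
  raw <- data.frame(time_s = seq(0, 1, by = 0.2), x = 1:6)
  expect_error(downsampleSignals(raw, 100), "below target")
})

test_that("Kalman velocity converges on a constant-speed ramp", {
  rate <- 15.2
  t <- seq(0, 20, by = 1 / rate)
  pos <- beltWrap(5 * t, 360)   # 5 cm/s, wrapping
  v <- estimateVelocity(pos, rate)
  burn <- t > 1
  expect_true(all(abs(v[burn] - 5) / 5 < 0.01))
  # stationary animal
  v0 <- estimateVelocity(rep(100, 200), rate)
  expect_lt(max(abs(v0[50:200])), 0.05)
  expect_error(estimateVelocity(c(1, NA, 3), rate), "non-finite")
})

test_that("Kalman velocity suppresses single-sample position artifacts", {
  rate <- 15.2
  t <- seq(0, 10, by = 1 / rate)
  pos <- 5 * t
  pos[76] <- pos[76] + 10   # one-sample glitch
  vK <- estimateVelocity(pos, rate)
  vFD <- c(0, diff(pos)) * rate  # finite-difference oracle spikes
  expect_gt(max(abs(vFD - 5)), 100)
  # bounded excursion, more than 10x below the raw spike, no sign flip
  expect_lt(max(abs(vK[20:length(vK)] - 5)), 10)
  expect_false(any(vK[20:length(vK)] < 0))
})

test_that("lick events, bouts, and onsets follow the detection rules", {
  rate <- 20
  mkTrace <- function(times, n = 200) {
    x <- rep(0, n)
    x[round(times * rate) + 1] <- 1
    x
  }
  # three pulses at 1, 2, 3 s: 3 events, 1 bout, 1 appetitive onset
  lk <- detectLickEvents(mkTrace(c(1, 2, 3)), rate, threshold = 0.5)
  expect_equal(lk$eventTimes, c(1, 2, 3))
  expect_equal(length(unique(lk$boutId)), 1)
  expect_equal(lk$appetitiveOnsets, 1)
  # two pulses 0.2 s apart merge under the 0.33 s separation rule
  lk2 <- detectLickEvents(mkTrace(c(1, 1.2)), rate, threshold = 0.5)
  expect_equal(length(lk2$eventTimes), 1)
  # consummatory onset: first event in (0.5, 5] s after the pump
  lk3 <- detectLickEvents(mkTrace(c(10.6, 12), n = 300), rate,
                          threshold = 0.5, pumpTimes = 10)
  expect_equal(lk3$consummatoryOnsets, 10.6)
  # an event 0.4 s after the pump is too early to be consummatory
  lk4 <- detectLickEvents(mkTrace(c(10.4), n = 300), rate,
                          threshold = 0.5, pumpTimes = 10)
  expect_length(lk4$consummatoryOnsets, 0)
  # all-zero trace: empty result, not an error
  lk5 <- detectLickEvents(rep(0, 100), rate, threshold = 0.5)
  expect_length(lk5$eventTimes, 0)
})

test_that("bouts split at 2 s gaps and onsets require 3 s silence", {
  rate <- 20
  x <- rep(0, 400)
  x[round(c(1, 2.5, 7, 8) * rate) + 1] <- 1
  lk <- detectLickEvents(x, rate, threshold = 0.5)
  expect_equal(length(unique(lk$boutId)), 2)
  # second bout starts 4.5 s after the previous event: appetitive
  expect_equal(lk$appetitiveOnsets, c(1, 7))
  # with only 2.5 s silence it is a bout start but not an onset
  x2 <- rep(0, 400)
  x2[round(c(1, 3.5, 4) * rate) + 1] <- 1
  lk2 <- detectLickEvents(x2, rate, threshold = 0.5)
  expect_equal(length(unique(lk2$boutId)), 2)
  expect_equal(lk2$appetitiveOnsets, 1)
})

test_that("lap table computes relative licking and success flags", {
  rate <- 10
  n <- 360
  frames <- data.frame(
    time_s = (seq_len(n) - 1) / rate,
    position_cm = rep(seq(0, 359), length.out = n),
    velocity_cms = 10, lick_analog = 0, pump = 0L,
    lap = rep(0L, n))
  zones <- zoneSet()
  # all licking inside the reward zone, rewarded: successful at 100%
  f1 <- frames
  f1$lick_analog[inZone(f1$position_cm, c(240, 270), 360)] <- 1
  f1$pump[250] <- 1L
  lt1 <- buildLapTable(f1, zones)
  expect_equal(lt1$rel_lick_reward, 1)
  expect_true(lt1$successful)
  # uniform licking: reward+anticipation share = 60/360, unsuccessful
  f2 <- frames
  f2$lick_analog <- 1
  f2$pump[250] <- 1L
  lt2 <- buildLapTable(f2, zones)
  expect_equal(lt2$rel_lick_rz_az, 60 / 360, tolerance = 0.01)
  expect_false(lt2$successful)
  # unrewarded lap with perfect zone licking is not successful
  f3 <- f1
  f3$pump[] <- 0L
  lt3 <- buildLapTable(f3, zones)
  expect_false(lt3$successful)
  # zero licking: relative licking defined as 0
  lt4 <- buildLapTable(frames, zones)
  expect_equal(lt4$rel_lick_rz_az, 0)
})

test_that("session success uses an inclusive 50% boundary", {
  mk <- function(nSucc, n = 10) data.frame(
    lap = seq_len(n) - 1, rewarded = TRUE,
    successful = seq_len(n) <= nSucc)
  expect_equal(classifySessionSuccess(mk(5))$label, "high")
  expect_equal(classifySessionSuccess(mk(4))$label, "low")
  r0 <- classifySessionSuccess(
    data.frame(lap = 0:9, rewarded = FALSE, successful = FALSE))
  expect_equal(r0$label, "low")
  expect_equal(r0$successRate, 0)
})

test_that("relative licking per bin sums to one on licked laps", {
  ses <- tinyMixed()
  rl <- relativeLickingByBin(behaviorFrames(ses))
  sums <- rowSums(rl)
  expect_true(all(abs(sums[sums > 0] - 1) < 1e-12))
})

test_that("event-triggered averages align and shrink like 1/sqrt(n)", {
  rate <- 10
  # constant trace: flat average at the constant
  eta <- eventTriggeredAverage(rep(3, 200), c(5, 10, 15), rate, 1, 1)
  expect_true(all(eta$mean == 3))
  expect_equal(eta$nEvents, 3L)
  # unit impulses at the events: single peak at offset 0
  tr <- rep(0, 400)
  ev <- c(10, 20, 30)
  tr[round(ev * rate) + 1] <- 1
  eta2 <- eventTriggeredAverage(tr, ev, rate, 1, 1)
  expect_equal(which.max(eta2$mean), which(eta2$offsets_s == 0))
  expect_equal(max(eta2$mean), 1)
  # white noise: average amplitude shrinks with event count
  set.seed(42)
  noise <- rnorm(20000)
  amp <- vapply(c(10, 160), function(k) {
    evs <- seq(10, 1900, length.out = k)
    sd(eventTriggeredAverage(noise, evs, rate, 1, 1)$mean)
  }, numeric(1))
  expect_gt(amp[1] / amp[2], 2.5)  # expected ratio 4
  # zero usable events
  eta3 <- eventTriggeredAverage(rep(0, 50), numeric(0), rate, 1, 1)
  expect_equal(eta3$nEvents, 0L)
})

test_that("motion energy is zero for static frames and flags motion", {
  static <- array(0.5, dim = c(8, 8, 20))
  expect_true(all(motionEnergy(static) == 0))
  # alternating black/white frames: steady-state z-scores near zero
  alt <- array(rep(c(0, 1), each = 64, length.out = 64 * 100),
               dim = c(8, 8, 100))
  z <- motionEnergy(alt)
  expect_true(all(abs(z[-1]) < 0.2))
  # moving square: energy elevated only while it moves
  stack <- array(0, dim = c(10, 10, 30))
  for (k in 10:15) stack[k - 8, , k] <- 1
  z2 <- motionEnergy(stack)
  expect_gt(min(z2[10:16]), max(z2[c(2:8, 20:30)]))
  expect_error(motionEnergy(array(0, dim = c(4, 4, 1))), "2 frames")
  expect_error(motionEnergy(static, mask = matrix(FALSE, 8, 8)), "mask")
  expect_error(motionEnergy(list(matrix(0, 2, 2), matrix(0, 3, 3))),
               "mismatched")
})
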