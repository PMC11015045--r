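test_that("behavior covers the requested laps with one reward per lap at most", {
  cfg <- simConfig(nLaps = 10, nNeurons = 2, seed = 5)
  beh <- simulateBehavior(cfg)
  expect_equal(length(unique(beh$frames$lap)), 10)
  expect_lte(sum(beh$frames$pump), 10)
  expect_true(all(diff(beh$frames$lap) %in% c(0, 1)))
  expect_true(all(beh$frames$position_cm >= 0 &
                    beh$frames$position_cm < 360))
})

test_that("rewarded laps replay from the lick/zone contingency", {
  cfg <- simConfig(nLaps = 12, nNeurons = 2, seed = 1)
  beh <- simulateBehavior(cfg)
  fr <- beh$frames
  # independent replay: a lap is rewarded iff some generated lick falls
  # inside the reward zone during that lap
  replay <- vapply(sort(unique(fr$lap)), function(l) {
    licks <- beh$truth$lickFrames[fr$lap[beh$truth$lickFrames] == l]
    any(inZone(fr$position_cm[licks], c(240, 270), 360))
  }, logical(1))
  expect_equal(replay, beh$truth$rewardedLaps)
  expect_equal(sum(fr$pump), sum(beh$truth$rewardedLaps))
})

test_that("without slowdown and with flat licking, speed is zone-independent", {
  cfg <- simConfig(nLaps = 20, nNeurons = 2, seed = 9,
                   slowdownFactor = 1, lickMaxRate = 0.5,
                   lickBaseRate = 0.5)
  fr <- simulateBehavior(cfg)$frames
  inRz <- inZone(fr$position_cm, c(180, 270), 360)
  mv <- fr$velocity_cms > 2
  vin <- mean(fr$velocity_cms[inRz & mv])
  vout <- mean(fr$velocity_cms[!inRz & mv])
  expect_lt(abs(vin - vout) / vout, 0.1)
})

test_that("appetitive lick density peaks in the anticipation and reward zones", {
  cfg <- simConfig(nLaps = 20, nNeurons = 2, seed = 4)
  beh <- simulateBehavior(cfg)
  fr <- beh$frames
  lickPos <- fr$position_cm[beh$truth$lickFrames]
  occ <- tabulate(positionBin(fr$position_cm, 360, 45), 45)
  dens <- tabulate(positionBin(lickPos, 360, 45), 45) / occ
  zoneBins <- positionBin(seq(210.1, 269.9, by = 4), 360, 45)
  expect_gt(mean(dens[unique(zoneBins)]),
            2 * mean(dens[-unique(zoneBins)]))
})

test_that("untuned neuron event counts match the Poisson baseline", {
  cfg <- simConfig(nLaps = 10, nNeurons = 3, seed = 6)
  beh <- simulateBehavior(cfg)
  specs <- do.call(rbind, lapply(1:3, function(i)
    neuronSpec(paste0("n", i), baseline = 0.1)))
  ev <- simulateEvents(cfg, specs, beh$frames)
  m <- rowMeans(ev)
  se <- sqrt(0.1 / ncol(ev))
  expect_true(all(abs(m - 0.1) < 3 * se))
  expect_true(all(ev >= 0))
})

test_that("a place-tuned neuron's binned activity peaks at its center", {
  cfg <- simConfig(nLaps = 12, nNeurons = 1, seed = 7)
  beh <- simulateBehavior(cfg)
  specs <- neuronSpec("p", place_center = 160, place_width = 15,
                      place_gain = 6)
  ev <- simulateEvents(cfg, specs, beh$frames)
  bin <- positionBin(beh$frames$position_cm, 360, 45)
  binned <- tapply(ev[1, ], bin, mean)
  peak <- as.integer(names(binned)[which.max(binned)])
  expect_lte(abs(peak - positionBin(160, 360, 45)), 1)
})

test_that("a lick-inhibited neuron is quieter after lick onsets", {
  cfg <- simConfig(nLaps = 15, nNeurons = 1, seed = 8)
  beh <- simulateBehavior(cfg)
  specs <- neuronSpec("li", baseline = 0.15, lick_amp = -2)
  ev <- simulateEvents(cfg, specs, beh$frames,
                       onsetTimes = beh$truth$appetitiveOnsets)
  eta <- eventTriggeredAverage(ev[1, ], beh$truth$appetitiveOnsets,
                               cfg@frameRate, preS = 2, postS = 2)
  pre <- mean(eta$mean[eta$offsets_s < 0])
  post <- mean(eta$mean[eta$offsets_s >= 0])
  expect_lt(post, pre)
})

test_that("generation is deterministic and behavior ignores neuron count", {
  cfg <- simConfig(nLaps = 5, nNeurons = 6, seed = 11)
  s1 <- simulateSession(cfg, "mixed_conjunctive")
  s2 <- simulateSession(cfg, "mixed_conjunctive")
  expect_identical(eventMatrix(s1), eventMatrix(s2))
  expect_identical(behaviorFrames(s1), behaviorFrames(s2))
  cfgMore <- simConfig(nLaps = 5, nNeurons = 12, seed = 11)
  expect_identical(behaviorFrames(simulateSession(cfgMore, "null")),
                   behaviorFrames(s1))
})

test_that("projection-enriched scenario enriches place tuning as configured", {
  cfg <- simConfig(nLaps = 5, nNeurons = 200, seed = 12)
  sp <- scenarioSpecs(cfg, "projection_enriched")
  fProj <- mean(!is.na(sp$place_gain[sp$projecting]))
  fNon <- mean(!is.na(sp$place_gain[!sp$projecting]))
  expect_gt(fProj, fNon)
})

test_that("invalid configurations are rejected", {
  expect_error(simConfig(rewardZone = c(340, 380)), "belt bounds")
  expect_error(simConfig(slowdownFactor = 0), "slowdownFactor")
  expect_error(simConfig(rewardZone = c(270, 240)), "exceed")
})
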