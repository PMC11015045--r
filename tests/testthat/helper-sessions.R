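# Shared synthetic sessions, built once per test run and memoized.
.sessionCache <- new.env(parent = emptyenv())

cachedSession <- function(key, maker) {
  if (is.null(.sessionCache[[key]])) .sessionCache[[key]] <- maker()
  .sessionCache[[key]]
}

tinyMixed <- function() cachedSession("tinyMixed", function()
  simulateSession(simConfig(nLaps = 8, nNeurons = 20, seed = 101),
                  "mixed_conjunctive"))

smallNull <- function() cachedSession("smallNull", function()
  simulateSession(simConfig(nLaps = 12, nNeurons = 60, seed = 102),
                  "null"))

smallMixed <- function() cachedSession("smallMixed", function()
  simulateSession(simConfig(nLaps = 20, nNeurons = 60, seed = 103),
                  "mixed_conjunctive"))

# a hand-built session: constant slow drift in position bin 7, no licks
parkedSession <- function(nFrames = 400, rate = 15.2) {
  behavior <- data.frame(
    time_s = (seq_len(nFrames) - 1) / rate,
    position_cm = rep(52, nFrames),          # bin 7: [48, 56)
    velocity_cms = rep(0.01, nFrames),
    lick_analog = rep(0, nFrames),
    pump = rep(0L, nFrames),
    lap = rep(0L, nFrames))
  ev <- matrix(rpois(2 * nFrames, 0.1), 2, nFrames,
               dimnames = list(c("a", "b"), NULL))
  SpatialSession(ev, behavior, frameRate = rate)
}

# a session whose first 20 neurons fire (almost) only inside the
# reward + anticipation zone and whose last 20 are untuned
separableSession <- function(seed = 31, nLaps = 25) {
  cachedSession(paste0("sep", seed, "_", nLaps), function() {
    cfg <- simConfig(nLaps = nLaps, nNeurons = 40, seed = seed)
    ctr <- seq(213, 267, length.out = 20)
    sp <- do.call(rbind, c(
      lapply(1:20, function(i)
        neuronSpec(paste0("z", i), projecting = TRUE, baseline = 0.02,
                   place_center = ctr[i], place_width = 8,
                   place_gain = 60)),
      lapply(1:20, function(i)
        neuronSpec(paste0("u", i), baseline = 0.25))))
    sp$tuning_class <- rep(c("zone", "untuned"), each = 20)
    simulateSession(cfg, specs = sp)
  })
}

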