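test_that("response preprocessing follows the printed order and flags silence", {
  rate <- 15.2
  expect_true(preprocessResponse(rep(0, 500), rate)$flagged)
  # constant non-zero events: all non-zero samples share one quintile
  r <- preprocessResponse(rep(2, 500), rate)
  nz <- r$response[r$response > 0]
  expect_true(length(unique(nz)) == 1)
  # random trace: quintiles hold balanced counts of the non-zero mass
  set.seed(2)
  r2 <- preprocessResponse(rpois(6000, 0.4) * runif(6000, 0.5, 2), rate)
  nz2 <- r2$response[r2$response > 0]
  counts <- table(nz2)
  expect_equal(length(counts), 5)
  expect_lte(diff(range(counts)), max(2, 0.02 * length(nz2)))
  # SNR scaling is absorbed by the SD normalization + rank mapping
  ev <- rpois(3000, 0.3)
  expect_equal(preprocessResponse(ev, rate, snr = 1)$response,
               preprocessResponse(ev, rate, snr = 4)$response)
})

test_that("quintile mapping is a rank map over non-zero entries", {
  x <- c(0, 5, 1, 0, 3, 9, 2)
  q <- quintileMap(x)
  expect_equal(q[x == 0], c(0, 0))
  expect_equal(order(q[x > 0]), order(x[x > 0]))
  expect_true(all(q[x > 0] %in% 1:5))
})

test_that("design matrix encodes position indicators and lag structure", {
  ses <- parkedSession()
  d <- buildDesignMatrix(ses)
  expect_equal(ncol(d$X), 45 + 19 + 19)
  # parked in bin 7: constant indicator at column 7
  expect_true(all(d$X[, 7] == 1))
  expect_true(all(d$X[, setdiff(1:45, 7)] == 0))
  # exactly one indicator per sample
  expect_true(all(rowSums(d$X[, 1:45]) == 1))
  # constant velocity: mean-normalized block is all ones at every lag
  expect_true(all(abs(d$X[, d$groups$velocity] - 1) < 1e-9))
  expect_equal(length(d$groups$licking), 19)
})

test_that("lick bouts within 5 s of a reward are excluded from the regressor", {
  rate <- 10
  n <- 1200
  behavior <- data.frame(
    time_s = (seq_len(n) - 1) / rate,
    position_cm = beltWrap(3 * (seq_len(n) - 1) / rate, 360),
    velocity_cms = 3, lick_analog = 0, pump = 0L, lap = 0L)
  behavior$lap <- floor(3 * behavior$time_s / 360)
  # bout A at 20 s (far from reward), bout B 2 s before the reward at 60 s
  behavior$lick_analog[round(c(20, 20.5, 58, 58.5) * rate) + 1] <- 1
  behavior$pump[round(60 * rate) + 1] <- 1L
  ev <- matrix(rpois(n, 0.1), 1, n, dimnames = list("a", NULL))
  ses <- SpatialSession(ev, behavior, frameRate = rate)
  d <- buildDesignMatrix(ses)
  lick0 <- d$X[, d$groups$licking[10]]   # lag-0 column
  t3 <- (seq_len(d$n) - 1) / 3
  expect_gt(sum(lick0[t3 > 19 & t3 < 22]), 0)
  expect_equal(sum(lick0[t3 > 57 & t3 < 60]), 0)
})

test_that("Poisson recovery: coefficients correlate with generating truth", {
  set.seed(31)
  n <- 8000; p <- 12
  X <- matrix(rnorm(n * p, sd = 0.5), n, p)
  beta <- rnorm(p, sd = 0.3)
  y <- rpois(n, exp(0.2 + X %*% beta))
  f <- fitPoissonGlm(y, X)
  expect_gt(cor(f$coef[-1], beta), 0.95)
  expect_true(f$converged)
  expect_lte(f$r2, 1)
})

test_that("test R2 sits at chance for noise and survives degenerate designs", {
  set.seed(32)
  n <- 3000
  X <- matrix(rnorm(n * 10), n, 10)
  y <- rpois(n, 1)
  f <- fitPoissonGlm(y, X)
  expect_lt(abs(f$r2), 0.05)
  # duplicated columns: prediction still finite
  X2 <- cbind(X, X[, 1], X[, 1])
  f2 <- fitPoissonGlm(y, X2)
  expect_true(is.finite(f2$r2))
  # precondition on non-zero training samples
  expect_error(fitPoissonGlm(rep(0, 3000), X), "non-zero")
})

test_that("shifting a block by the full period leaves R2 unchanged", {
  ses <- tinyMixed()
  d <- buildDesignMatrix(ses)
  r <- preprocessResponse(eventMatrix(ses)[2, ], frameRate(ses))
  y <- r$response[seq_len(d$n)]
  f1 <- fitPoissonGlm(y, d$X)
  X2 <- d$X
  cols <- d$groups$velocity
  X2[, cols] <- placecode:::rowShift(d$X[, cols, drop = FALSE], nrow(d$X))
  f2 <- fitPoissonGlm(y, X2)
  expect_equal(f2$r2, f1$r2, tolerance = 1e-12)
})

test_that("group shuffle verdicts are deterministic given seeds", {
  ses <- tinyMixed()
  d <- buildDesignMatrix(ses)
  r <- preprocessResponse(eventMatrix(ses)[4, ], frameRate(ses))
  y <- r$response[seq_len(d$n)]
  s1 <- suppressMessages(
    shuffleFeatureSignificance(y, d, nShuffles = 15, seed = 6))
  s2 <- suppressMessages(
    shuffleFeatureSignificance(y, d, nShuffles = 15, seed = 6))
  expect_identical(s1$shuffleR2, s2$shuffleR2)
  expect_identical(s1$significant, s2$significant)
  # shuffled R2 varies across shifts (shifts are genuinely redrawn)
  expect_gt(max(apply(s1$shuffleR2, 1, function(z) length(unique(z)))), 5)
})

test_that("conjunctive classes count significant groups", {
  mk <- function(p, v, l) S4Vectors::DataFrame(
    sig_position = p, sig_velocity = v, sig_licking = l,
    conjunctive_class = c("none", "single", "dual",
                          "triple")[p + v + l + 1],
    projecting = c(TRUE, FALSE, TRUE), flagged = FALSE,
    r2 = 0.1)
  res <- mk(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE),
            c(TRUE, TRUE, FALSE))
  cc <- classifyConjunctive(res)
  expect_equal(as.integer(cc$classCounts["triple", "projecting"]), 1L)
  expect_equal(as.integer(cc$classCounts["dual", "nonprojecting"]), 1L)
  expect_equal(as.integer(cc$classCounts["none", "projecting"]), 1L)
  expect_true("PVL" %in% names(cc$overlap))
})

test_that("session encoding flags silent neurons instead of modeling them", {
  ses <- tinyMixed()
  ev <- eventMatrix(ses)
  ev[3, ] <- 0
  s2 <- SpatialSession(ev, behaviorFrames(ses), frameRate(ses),
                       projecting = projecting(ses))
  enc <- suppressMessages(
    encodeSession(s2, nShuffles = 10, seed = 2, neurons = c(2, 3)))
  expect_false(enc$flagged[1])
  expect_true(enc$flagged[2])
  expect_true(is.na(enc$r2[2]))
})
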