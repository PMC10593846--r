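test_that("state path sampling follows the constructed sticky chain", {
  # single state: constant path and trivial transition matrix
  cfg1 <- simConfig(nRegions = 2, nStates = 1, stickiness = 0.9,
                    stateSpecs = list(list(regions = 1:2, freqHz = 10,
                                           amplitude = 1, phaseLagS = 0)),
                    durationS = 2, seed = 1)
  tr1 <- simulateStatePath(cfg1)
  expect_true(all(tr1$statePath == 1L))
  expect_equal(tr1$transitionMatrix, matrix(1, 1, 1))

  # empirical self-transition fraction matches stickiness
  cfg2 <- simConfig(nRegions = 4, nStates = 2, stickiness = 0.99,
                    durationS = 1e5 / 250, seed = 7)
  p <- simulateStatePath(cfg2)$statePath
  selfFrac <- mean(p[-1] == p[-length(p)])
  expect_lt(abs(selfFrac - 0.99), 0.005)

  # seeded reproducibility
  expect_identical(simulateStatePath(cfg2)$statePath,
                   simulateStatePath(cfg2)$statePath)

  expect_error(simConfig(nStates = 2, stickiness = 1), "stickiness")
  expect_error(simConfig(nStates = 2, stickiness = 0), "stickiness")
})

test_that("long-run occupancy converges to the stationary distribution", {
  cfg <- simConfig(nRegions = 6, nStates = 3, stickiness = 0.95,
                   durationS = 1e6 / 250, seed = 3)
  tr <- simulateStatePath(cfg)
  fo <- tabulate(tr$statePath, 3) / length(tr$statePath)
  # uniform off-diagonal mass => uniform stationary distribution
  expect_lt(0.5 * sum(abs(fo - 1 / 3)), 0.02)
})

test_that("rendered recordings carry the specified oscillatory structure", {
  # noiseless single 10 Hz state on two regions: spectral mass at 10 Hz
  cfg <- simConfig(nRegions = 3, nStates = 1, stickiness = 0.5,
                   stateSpecs = list(list(regions = 1:2, freqHz = 10,
                                          amplitude = 1, phaseLagS = 0)),
                   noiseSd = 0, durationS = 8, seed = 2)
  tr <- simulateStatePath(cfg)
  rec <- renderRecording(tr, cfg)
  x <- recData(rec)[1, ]
  pg <- Mod(stats::fft(x))^2
  freqs <- (seq_along(pg) - 1) * cfg$fs / length(pg)
  half <- freqs <= cfg$fs / 2
  expect_equal(freqs[half][which.max(pg[half])], 10, tolerance = 0.2)

  # zero phase lag => identical signals on the subset, so correlation 1
  expect_equal(cor(recData(rec)[1, ], recData(rec)[2, ]), 1, tolerance = 1e-12)
  # region outside the subset is silent when noiseSd = 0
  expect_equal(max(abs(recData(rec)[3, ])), 0)

  # zero amplitude everywhere: pure white noise with sample SD ~ noiseSd
  cfg0 <- simConfig(nRegions = 4, nStates = 2, stickiness = 0.9,
                    stateSpecs = list(
                      list(regions = 1:2, freqHz = 8, amplitude = 0, phaseLagS = 0),
                      list(regions = 3:4, freqHz = 15, amplitude = 0, phaseLagS = 0)),
                    noiseSd = 0.7, durationS = 40, seed = 5)
  rec0 <- renderRecording(simulateStatePath(cfg0), cfg0)
  expect_equal(sd(as.vector(recData(rec0))), 0.7, tolerance = 0.02)
})

test_that("task event tables honour the n-back design counts and timing", {
  ev <- simulateTaskEvents(taskConfig(), seed = 4)
  expect_s3_class(ev, "EventTable")
  expect_equal(nrow(ev), 240)
  expect_equal(sum(ev$condition == "0T"), 25)
  expect_equal(sum(ev$condition == "1T"), 23)
  expect_equal(sum(ev$condition == "2T"), 28)
  expect_equal(as.vector(table(ev$load)), c(80, 80, 80))
  # exactly blocksPerCondition blocks per load
  expect_equal(as.vector(table(unique(ev[, c("block", "load")])$load)), c(4, 4, 4))
  # consecutive onsets within a block differ by 1 s + 1.8 s
  gaps <- unlist(lapply(split(ev$onset_s, ev$block), diff))
  expect_equal(unique(round(gaps, 10)), 2.8)

  # minimal design
  mini <- simulateTaskEvents(taskConfig(nBlocks = 3, stimuliPerBlock = 2,
                                        blocksPerCondition = 1,
                                        targetCounts = c(1, 1, 1)), seed = 1)
  expect_equal(nrow(mini), 6)
  expect_equal(sum(mini$isTarget), 3)

  expect_error(taskConfig(targetCounts = c(90, 23, 28)), "exceed")
  expect_error(taskConfig(nBlocks = 10), "blocksPerCondition")
})

test_that("event-locked modulation raises occupancy of the boosted state", {
  task <- taskConfig(nBlocks = 12, stimuliPerBlock = 20, blocksPerCondition = 4,
                     targetCounts = c(25, 23, 28),
                     evokedStates = list(list(state = 2, latencyS = 0.2,
                                              windowS = 0.3, factor = 4)))
  cfg <- simConfig(nRegions = 4, nStates = 3, stickiness = 0.95,
                   durationS = 700, seed = 9)
  tr <- simulateStatePath(cfg, task = task)
  expect_gte(nrow(tr$events), 200)
  ep <- epochStates(oneHotGamma(tr$statePath, 3), tr$events, fs = cfg$fs)
  inWin <- ep@times >= 0.2 & ep@times < 0.5
  base <- ep@times < -0.03
  # baseline-corrected occupancy of the boosted state is positive in-window
  expect_gt(mean(ep@data[, inWin, 2]), 0.05)
  expect_gt(mean(ep@data[, inWin, 2]), mean(ep@data[, base, 2]) + 0.05)
})
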