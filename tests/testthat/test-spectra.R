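test_that("DPSS tapers are orthonormal with the usual sign convention", {
  V <- dpssTapers(256, nw = 4, k = 7)
  expect_equal(crossprod(V), diag(7), tolerance = 1e-8, ignore_attr = TRUE)
  expect_gt(sum(V[, 1]), 0)
})

test_that("gamma weighting reduces to the plain multitaper for a constant state", {
  set.seed(40)
  rec <- Recording(matrix(rnorm(3 * 4000), 3), 250)
  plain <- weightedMultitaper(rec, matrix(1, 4000, 1))
  two <- suppressWarnings(weightedMultitaper(rec, cbind(1, 0)[rep(1, 4000), ]))
  expect_equal(two@psd[1, , ], plain@psd[1, , ], tolerance = 1e-10)
  expect_equal(two@coh[1, , , ], plain@coh[1, , , ], tolerance = 1e-10)
  expect_true(all(is.na(two@psd[2, , ])))   # zero-weight state reported missing
})

test_that("spectral estimates localize a known oscillation and bound coherence", {
  set.seed(41)
  fs <- 250; n <- 6000
  t0 <- seq_len(n) / fs
  x <- sin(2 * pi * 10 * t0) + 0.1 * rnorm(n)
  y <- sin(2 * pi * 10 * t0 + 0.7) + 0.1 * rnorm(n)
  rec <- Recording(rbind(x, y, rnorm(n), rnorm(n)), fs)
  est <- weightedMultitaper(rec, matrix(1, n, 1))
  f <- frequencies(est)
  expect_equal(f[which.max(est@psd[1, , 1])], 10, tolerance = 0.5)

  # coherence invariants: bounds, symmetry, unit diagonal
  expect_true(all(est@coh >= 0 & est@coh <= 1))
  expect_equal(est@coh[1, , 1, 2], est@coh[1, , 2, 1])
  expect_true(all(est@coh[1, , 3, 3] == 1))

  # identical channels: coherence 1 at all frequencies
  rec2 <- Recording(rbind(x, x), fs)
  est2 <- weightedMultitaper(rec2, matrix(1, n, 1))
  expect_equal(min(est2@coh[1, , 1, 2]), 1, tolerance = 1e-6)

  # independent channels: mean coherence under the estimation noise floor,
  # ~ sqrt(pi / (4 m)) for m effective independent taper-window estimates
  m <- est@params$nWindows / 2 * est@params$nTapers
  floorC <- 2 * sqrt(pi / (4 * m))
  expect_lt(mean(est@coh[1, , 3, 4]), floorC)
})

test_that("state-weighted spectra decompose the unweighted estimate", {
  set.seed(42)
  b <- makeThreeStateBenchmark(nSamples = 20000, seed = 43)
  g <- oneHotGamma(b$truth$statePath, 3)
  est <- weightedMultitaper(b$recording, g)
  plain <- weightedMultitaper(b$recording, matrix(1, 20000, 1))
  w <- est@params$stateWeights / est@params$nWindows
  mix <- w[1] * est@psd[1, , ] + w[2] * est@psd[2, , ] + w[3] * est@psd[3, , ]
  expect_equal(mix, plain@psd[1, , ], tolerance = 1e-8)

  # each state's PSD peaks within 1 Hz of its generating frequency
  f <- frequencies(est)
  gen <- c(6, 10, 20)
  for (k in 1:3) {
    prof <- rowMeans(est@psd[k, , b$cfg$stateSpecs[[k]]$regions])
    expect_lte(abs(f[which.max(prof)] - gen[k]), 1)
  }
})

# helper: wrap a freq x (region-spectra per state) array as SpectralEstimate
syntheticEstimate <- function(psdList, freqs) {
  K <- length(psdList); R <- ncol(psdList[[1]])
  psd <- array(0, c(K, length(freqs), R))
  coh <- array(0, c(K, length(freqs), R, R))
  for (k in seq_len(K)) {
    psd[k, , ] <- psdList[[k]]
    for (f in seq_along(freqs)) coh[k, f, , ] <- diag(R)
  }
  new("SpectralEstimate", freqs = freqs, psd = psd, coh = coh,
      subjectId = "synth", params = list())
}

test_that("NNMF recovers exact low-rank structure and band-confined modes", {
  set.seed(44)
  # exact rank-2 non-negative matrix
  W0 <- matrix(runif(30 * 2), 30)
  H0 <- matrix(runif(2 * 40), 2)
  V <- W0 %*% H0
  r <- tdehmm:::nnmfUpdate(V, 2, maxIter = 5000, tol = 1e-14)
  expect_lt(r$residual, 1e-6)
  # residual trace is non-increasing and factors stay non-negative
  expect_true(all(diff(r$trace) <= 1e-12))
  expect_true(all(r$W >= 0) && all(r$H >= 0))

  # two disjoint spectral bands -> band-confined mode profiles
  freqs <- seq(1, 40, by = 0.5)
  bump <- function(lo, hi) as.numeric(freqs >= lo & freqs <= hi) *
    exp(-((freqs - (lo + hi) / 2)^2))
  theta <- bump(4, 8); alphab <- bump(8.5, 12)
  mk <- function(profile) vapply(1:5, function(r)
    profile * runif(1, 0.5, 2) + 1e-4, numeric(length(freqs)))
  est <- syntheticEstimate(list(mk(theta), mk(alphab)), freqs)
  modes <- nnmfModes(est, M = 2, what = "psd", seed = 3)
  W <- modes@W
  inTheta <- sum(W[freqs <= 8.2, 1]) / sum(W[, 1])
  inAlpha <- sum(W[freqs >= 8.2, 2]) / sum(W[, 2])
  expect_gte(inTheta, 0.9)
  expect_gte(inAlpha, 0.9)

  # nesting: M = 1 cannot beat M = 2 on the same matrix
  sm <- tdehmm:::spectraToMatrix(est, "psd")
  set.seed(5)
  r1 <- tdehmm:::nnmfUpdate(sm$V, 1, maxIter = 800, tol = 1e-12)
  set.seed(5)
  r2 <- tdehmm:::nnmfUpdate(sm$V, 2, maxIter = 800, tol = 1e-12)
  expect_gte(r1$residual, r2$residual - 1e-9)

  est@psd[1, 1, 1] <- -1
  expect_error(nnmfModes(est, M = 2), "negative")
})

test_that("mode projection and z-scored maps behave as inner products", {
  freqs <- 1:20
  psd <- matrix(runif(20 * 4), 20)
  est <- syntheticEstimate(list(psd), freqs)
  # delta mode: projection equals the bin value
  W <- cbind(as.numeric(freqs == 7))
  modes <- new("SpectralModes", W = W, H = matrix(1, 1, 1), freqs = freqs,
               featureInfo = data.frame(), residual = 0)
  pj <- projectModes(est, modes)
  expect_equal(pj$psdRaw[1, 1, ], psd[7, ], tolerance = 1e-12)

  # uniform PSD across regions: z-scored map identically 0
  estU <- syntheticEstimate(list(matrix(2, 20, 4)), freqs)
  pjU <- projectModes(estU, modes)
  expect_equal(pjU$psdMaps[1, 1, ], rep(0, 4))

  # two-band ground truth: the low state loads the low mode more, and vice versa
  bump <- function(c0) exp(-((freqs - c0)^2) / 2)
  est2 <- syntheticEstimate(list(vapply(1:4, function(i) bump(5), numeric(20)),
                                 vapply(1:4, function(i) bump(15), numeric(20))),
                            freqs)
  W2 <- cbind(bump(5), bump(15))
  modes2 <- new("SpectralModes", W = W2, H = matrix(1, 2, 1), freqs = freqs,
                featureInfo = data.frame(), residual = 0)
  pj2 <- projectModes(est2, modes2)
  expect_gt(mean(pj2$psdRaw[1, 1, ]), mean(pj2$psdRaw[2, 1, ]))
  expect_gt(mean(pj2$psdRaw[2, 2, ]), mean(pj2$psdRaw[1, 2, ]))
})

test_that("Gaussian-mixture thresholding separates and degrades gracefully", {
  set.seed(46)
  lo <- rnorm(700, 0.1, 0.01)
  hi <- rnorm(161, 0.6, 0.01)
  g <- gmmThreshold(c(lo, hi))
  expect_false(g$fallback)
  expect_identical(which(g$keep), 701:861)        # exactly the high cluster
  # parameter recovery at n = 861
  expect_lt(abs(sort(g$means)[1] - 0.1), 0.02)
  expect_lt(abs(sort(g$means)[2] - 0.6), 0.02)

  # all-equal values: fallback with warning
  expect_warning(gf <- gmmThreshold(rep(0.3, 50)), "degenerate")
  expect_true(gf$fallback)
  expect_false(any(gf$keep))

  expect_error(gmmThreshold(c(1, 2)), "connections")
})
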