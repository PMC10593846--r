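test_that("forward-backward matches exhaustive enumeration on small instances", {
  set.seed(10)
  for (i in 1:25) {
    K <- sample(2:3, 1); T <- sample(2:8, 1)
    inst <- randomHMMInstance(K, T)
    stc <- forwardBackward(inst$model, inst$X)
    logB <- tdehmm:::pointLogEmissions(inst$model, inst$X)
    o <- bruteForceHMM(logB, transitionMatrix(inst$model), inst$model@pi)
    expect_lt(max(abs(stateProbs(stc) - o$gamma)), 1e-12)
    expect_lt(abs(stc@logLik - o$loglik), 1e-10)
    expect_identical(viterbiPath(inst$model, inst$X), as.integer(o$best))
  }
})

test_that("degenerate forward-backward cases behave as symmetry dictates", {
  set.seed(11)
  X <- matrix(rnorm(40), 20, 2)
  # K = 1: gamma identically 1; loglik is the plain Gaussian log density sum
  S <- crossprod(matrix(rnorm(4), 2)) + diag(2)
  m1 <- HMMModel(pi = 1, A = matrix(1, 1, 1), Sigma = list(S))
  stc1 <- forwardBackward(m1, X)
  expect_true(all(stateProbs(stc1) == 1))
  expect_equal(stc1@logLik, sum(tdehmm:::mvn_logdens(X, c(0, 0), S)))
  expect_identical(viterbiPath(m1, X), rep(1L, 20))

  # uniform transitions + identical emissions: gamma = 1/K everywhere
  m2 <- HMMModel(pi = c(.5, .5), A = matrix(.5, 2, 2), Sigma = list(S, S))
  expect_equal(max(abs(stateProbs(forwardBackward(m2, X)) - 0.5)), 0, tolerance = 1e-12)

  # dominant emissions + near-uniform transitions: Viterbi = per-sample argmax
  S1 <- diag(2) * 0.01; S2 <- diag(2) * 100
  m3 <- HMMModel(pi = c(.5, .5), A = matrix(c(.5, .5, .5, .5), 2),
                 Sigma = list(S1, S2))
  X3 <- rbind(matrix(rnorm(20, sd = 0.05), 10, 2), matrix(rnorm(20, sd = 10), 10, 2))
  lb <- tdehmm:::pointLogEmissions(m3, X3)
  expect_identical(viterbiPath(m3, X3), max.col(lb, ties.method = "first"))
})

test_that("variational fit is deterministic, monotone, and recovers K = 1 covariance", {
  set.seed(12)
  X <- matrix(rnorm(600), 300, 2) %*% matrix(c(1, .5, 0, 1), 2)
  f1 <- fitHMM(X, K = 1, nRestarts = 2, seed = 5)
  f2 <- fitHMM(X, K = 1, nRestarts = 2, seed = 5)
  expect_identical(freeEnergy(f1$model), freeEnergy(f2$model))

  # K = 1 posterior covariance equals the prior-weighted sample covariance
  pr <- f1$model@priors
  Sexp <- (pr$S0 + crossprod(X)) / (pr$nu0 + nrow(X) - 2 - 1)
  Sexp <- Sexp + diag(1e-6 * mean(diag(Sexp)), 2)
  expect_equal(stateCovariances(f1$model)[[1]], Sexp, tolerance = 1e-10)

  # free energy never increases across full-batch iterations
  set.seed(13)
  b <- makeThreeStateBenchmark(nSamples = 6000, seed = 21)
  prep <- prepareData(b$recording, lags = -3:3, nComponents = 10)
  fit <- fitHMM(prep$scores, K = 3, nRestarts = 2, maxIter = 30, seed = 2)
  expect_true(all(diff(freeEnergy(fit$model)) <= 1e-6))

  # posterior validity invariants
  g <- stateProbs(fit$stc)
  expect_lt(max(abs(rowSums(g) - 1)), 1e-8)
  expect_lt(max(abs(rowSums(transitionMatrix(fit$model)) - 1)), 1e-10)
  for (S in stateCovariances(fit$model))
    expect_gt(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values), 0)

  expect_error(fitHMM(matrix(0, 0, 2), K = 2), "empty")
  expect_error(fitHMM(matrix(rnorm(10), 5, 2), K = 0), "K")
})

test_that("state recovery improves with recording length", {
  accs <- vapply(1:3, function(s) {
    vapply(c(5e3, 3e4), function(n) {
      b <- makeThreeStateBenchmark(nSamples = n, seed = 30 + s)
      prep <- prepareData(b$recording, lags = -7:7, nComponents = 20)
      fit <- suppressWarnings(fitHMM(prep$scores, K = 3, nRestarts = 2,
                                     maxIter = 40, seed = s))
      vp <- max.col(stateProbs(fit$stc), ties.method = "first")
      alignToPath(vp, b$truth$statePath[prep$indexMaps[[1]]], 3)$accuracy
    }, numeric(1))
  }, numeric(2))
  expect_gte(mean(accs[2, ]), mean(accs[1, ]))
  expect_gt(mean(accs[2, ]), 0.8)
})

test_that("stochastic subject-minibatch inference returns a valid model", {
  set.seed(14)
  recs <- lapply(1:4, function(s) {
    b <- makeThreeStateBenchmark(nSamples = 4000, seed = 40 + s)
    b$recording
  })
  prep <- prepareData(recs, lags = -3:3, nComponents = 8)
  fit <- fitHMM(prep$scores, K = 3, lengths = prep$lengths, nRestarts = 1,
                maxIter = 15, seed = 3, minibatch = 2)
  expect_s4_class(fit$model, "HMMModel")
  expect_lt(max(abs(rowSums(stateProbs(fit$stc)) - 1)), 1e-8)
})

test_that("state alignment recovers permutations of covariance sets", {
  set.seed(15)
  Sigmas <- lapply(1:3, function(k) {
    M <- matrix(rnorm(16), 4); crossprod(M) + diag(4)
  })
  A <- matrix(0.05, 3, 3); diag(A) <- 0.9
  ref <- HMMModel(pi = rep(1 / 3, 3), A = A, Sigma = Sigmas)
  expect_identical(alignStates(ref, ref), 1:3)

  rev3 <- HMMModel(pi = rep(1 / 3, 3), A = A, Sigma = Sigmas[3:1])
  expect_identical(alignStates(ref, rev3), 3:1)

  # noisy copies still match correctly
  noisy <- lapply(Sigmas[c(2, 3, 1)], function(S) {
    N <- matrix(rnorm(16, sd = 0.05), 4)
    S + crossprod(N)
  })
  other <- HMMModel(pi = rep(1 / 3, 3), A = A, Sigma = noisy)
  expect_identical(alignStates(ref, other), c(3L, 1L, 2L))

  bad <- HMMModel(pi = c(.5, .5), A = matrix(.5, 2, 2), Sigma = Sigmas[1:2])
  expect_error(alignStates(ref, bad), "K and P")
})
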