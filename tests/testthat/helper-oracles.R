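# Independent brute-force oracles and shared fixtures.

# Exhaustive-enumeration smoothing and decoding oracle: sums / maximizes over
# all K^T state paths. Only feasible for tiny T, K — that is the point.
bruteForceHMM <- function(logB, A, pi0) {
  T <- nrow(logB); K <- ncol(logB)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T)))
  lp <- apply(paths, 1, function(p) {
    v <- log(pi0[p[1]]) + logB[1, p[1]]
    if (T > 1) for (t in 2:T) v <- v + log(A[p[t - 1], p[t]]) + logB[t, p[t]]
    v
  })
  mx <- max(lp)
  w <- exp(lp - mx); w <- w / sum(w)
  gamma <- matrix(0, T, K)
  for (t in seq_len(T)) for (k in seq_len(K))
    gamma[t, k] <- sum(w[paths[, t] == k])
  # ties toward the lower index under R's lexicographic expand.grid ordering:
  # pick the first path attaining the max
  best <- paths[which(lp == mx)[1], ]
  list(gamma = gamma, loglik = log(sum(exp(lp - mx))) + mx, best = best)
}

randomHMMInstance <- function(K, T, P = 2) {
  A <- matrix(runif(K * K) + 0.1, K); A <- A / rowSums(A)
  pi0 <- runif(K) + 0.1; pi0 <- pi0 / sum(pi0)
  Sigma <- lapply(seq_len(K), function(k) {
    M <- matrix(rnorm(P * P), P); crossprod(M) + diag(P) * 0.5
  })
  list(model = HMMModel(pi = pi0, A = A, Sigma = Sigma),
       X = matrix(rnorm(T * P), T, P))
}

oneHotGamma <- function(path, K) {
  g <- matrix(0, length(path), K)
  g[cbind(seq_along(path), path)] <- 1
  g
}

# shared (expensive) fixture: the three-state benchmark fit, computed once
.fixtures <- new.env(parent = emptyenv())

benchmarkFit <- function() {
  if (is.null(.fixtures$bench)) {
    b <- makeThreeStateBenchmark(nSamples = 1e5, seed = 11)
    prep <- prepareData(b$recording, lags = -7:7, nComponents = 20)
    fit <- fitHMM(prep$scores, K = 3, lengths = prep$lengths,
                  nRestarts = 3, maxIter = 60, seed = 1)
    .fixtures$bench <- list(bench = b, prep = prep, fit = fit)
  }
  .fixtures$bench
}

# epochs of pure (unmodulated) simulated state paths: the null for GLM tests
nullEpochsDataset <- function(nSubjects, task, seedBase, K = 3,
                              stickiness = 0.95, fs = 250) {
  lastOnset <- (task$nBlocks) *
    (task$stimuliPerBlock * (task$stimulusDurationS + task$interTrialS) +
       task$interBlockGapS) + task$startS
  lapply(seq_len(nSubjects), function(s) {
    cfg <- simConfig(nRegions = 2, fs = fs, nStates = K,
                     stickiness = stickiness, durationS = lastOnset + 2,
                     seed = seedBase + s)
    ev <- simulateTaskEvents(task, seed = seedBase + 100 + s)
    truth <- simulateStatePath(cfg, seed = seedBase + s)
    epochStates(oneHotGamma(truth$statePath, K), ev, fs = fs)
  })
}
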