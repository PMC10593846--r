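#' Simulation configuration for Markov-switching oscillatory network data
#'
#' Describes a ground-truthed generative model of parcellated recordings: a
#' sticky Markov chain over `nStates` hidden network states, each expressed as
#' a narrow-band oscillation shared (with fixed phase lags) by a subset of
#' regions, plus additive white noise. Defaults emulate 42-region,
#' leakage-corrected recordings sampled at 250 Hz with ~70 ms state lifetimes.
#'
#' @param nRegions number of regions (default 42).
#' @param fs sampling rate in Hz (default 250).
#' @param nStates number of hidden states K (default 6).
#' @param stickiness per-sample self-transition probability, in (0,1).
#'   The default 0.945 gives mean state lifetimes near 70 ms at 250 Hz.
#' @param stateSpecs per-state list with elements `regions` (integer indices),
#'   `freqHz` (center frequency), `amplitude` (scalar or per-region), and
#'   `phaseLagS` (pairwise phase lag between consecutive subset regions, in
#'   seconds). `NULL` builds [defaultStateSpecs()].
#' @param noiseSd standard deviation of the additive white noise (default 0.5,
#'   i.e. oscillation power about twice the noise power on active regions).
#' @param nSubjects number of subjects.
#' @param durationS seconds of recording per subject.
#' @param seed integer seed owning all randomness downstream.
#' @return A validated list of class `SimConfig`.
#' @export
simConfig <- function(nRegions = 42, fs = 250, nStates = 6, stickiness = 0.945,
                      stateSpecs = NULL, noiseSd = 0.5, nSubjects = 1,
                      durationS = 60, seed = 1) {
  if (!(stickiness > 0 && stickiness < 1))
    stop("invalid config: stickiness must lie strictly in (0,1)")
  if (nStates < 1) stop("invalid config: nStates must be >= 1")
  if (is.null(stateSpecs)) stateSpecs <- defaultStateSpecs(nRegions, nStates)
  if (length(stateSpecs) != nStates)
    stop("invalid config: stateSpecs must have one entry per state")
  for (k in seq_along(stateSpecs)) {
    sp <- stateSpecs[[k]]
    if (any(sp$regions < 1L | sp$regions > nRegions))
      stop(sprintf("invalid config: state %d region subset outside [1, nRegions]", k))
    if (sp$freqHz >= fs / 2)
      stop(sprintf("invalid config: state %d center frequency %g >= Nyquist %g",
                   k, sp$freqHz, fs / 2))
  }
  structure(list(nRegions = as.integer(nRegions), fs = fs,
                 nStates = as.integer(nStates), stickiness = stickiness,
                 stateSpecs = stateSpecs, noiseSd = noiseSd,
                 nSubjects = as.integer(nSubjects), durationS = durationS,
                 seed = as.integer(seed)),
            class = c("SimConfig", "list"))
}

#' Default per-state oscillatory network specifications
#'
#' Partitions the regions into `nStates` contiguous subsets and assigns each
#' state a center frequency spread over the 4-24 Hz range (theta through
#' beta), unit amplitude, and a 5 ms pairwise phase lag.
#'
#' @param nRegions,nStates as in [simConfig()].
#' @param freqsHz per-state center frequencies; default equally spaced in
#'   4-24 Hz.
#' @param amplitude oscillation amplitude.
#' @param phaseLagS phase lag (seconds) between consecutive regions of a
#'   state's subset.
#' @return List of per-state specs.
#' @export
defaultStateSpecs <- function(nRegions, nStates,
                              freqsHz = seq(4, 24, length.out = nStates),
                              amplitude = 1, phaseLagS = 0.005) {
  groups <- split(seq_len(nRegions), sort(rep_len(seq_len(nStates), nRegions)))
  lapply(seq_len(nStates), function(k)
    list(regions = as.integer(groups[[((k - 1L) %% length(groups)) + 1L]]),
         freqHz = freqsHz[k], amplitude = amplitude, phaseLagS = phaseLagS))
}

#' Task configuration for the n-back-style event schedule
#'
#' Blocked stimulus schedule: `nBlocks` blocks of `stimuliPerBlock` stimuli,
#' with exactly `blocksPerCondition` blocks per working-memory load (0/1/2),
#' each stimulus shown for 1 s followed by a 1.8 s inter-trial period, and a
#' fixed per-load number of target trials (defaults 25/23/28 for loads
#' 0/1/2); the remaining trials are distractors.
#'
#' @param nBlocks total blocks (must equal `3 * blocksPerCondition`).
#' @param stimuliPerBlock stimuli per block.
#' @param blocksPerCondition blocks per load condition.
#' @param stimulusDurationS stimulus display duration, seconds.
#' @param interTrialS inter-trial period, seconds.
#' @param targetCounts length-3 integer vector: targets for loads 0, 1, 2.
#' @param evokedStates optional list of event-locked state modulations, each
#'   `list(state=, latencyS=, windowS=, factor=)`: within
#'   `[onset+latencyS, onset+latencyS+windowS)` the per-sample probability of
#'   `state` is multiplied by `factor` and the row renormalized.
#' @param interBlockGapS silent gap between blocks, seconds.
#' @param startS onset of the first stimulus, seconds.
#' @return A validated list of class `TaskConfig`.
#' @export
taskConfig <- function(nBlocks = 12, stimuliPerBlock = 20, blocksPerCondition = 4,
                       stimulusDurationS = 1, interTrialS = 1.8,
                       targetCounts = c(25, 23, 28), evokedStates = list(),
                       interBlockGapS = 4, startS = 2) {
  if (nBlocks != 3 * blocksPerCondition)
    stop("invalid config: nBlocks must equal 3 * blocksPerCondition")
  if (length(targetCounts) != 3) stop("invalid config: targetCounts must have length 3")
  perLoad <- blocksPerCondition * stimuliPerBlock
  if (any(targetCounts > perLoad))
    stop(sprintf("invalid config: targetCounts exceed the %d trials per load", perLoad))
  if (any(targetCounts < 0)) stop("invalid config: negative target count")
  structure(list(nBlocks = as.integer(nBlocks),
                 stimuliPerBlock = as.integer(stimuliPerBlock),
                 blocksPerCondition = as.integer(blocksPerCondition),
                 stimulusDurationS = stimulusDurationS, interTrialS = interTrialS,
                 targetCounts = as.integer(targetCounts),
                 evokedStates = evokedStates,
                 interBlockGapS = interBlockGapS, startS = startS),
            class = c("TaskConfig", "list"))
}

#' Condition labels used throughout the package
#' @return Character vector `0T, 0D, 1T, 1D, 2T, 2D`.
#' @export
conditionLevels <- function() c("0T", "0D", "1T", "1D", "2T", "2D")

#' Simulate an n-back-style event table
#'
#' Block load order is a seeded pseudo-random permutation with exactly
#' `blocksPerCondition` blocks per load; onsets within a block are spaced
#' `stimulusDurationS + interTrialS` apart; target trials are drawn without
#' replacement within each load to match `targetCounts`.
#'
#' @param cfg a [taskConfig()].
#' @param seed integer seed.
#' @return A `data.frame` (class `EventTable`) with columns `onset_s`,
#'   `condition` (factor with levels `0T,0D,1T,1D,2T,2D`), `block`, `load`,
#'   `isTarget`.
#' @export
simulateTaskEvents <- function(cfg, seed = 1) {
  stopifnot(inherits(cfg, "TaskConfig"))
  set.seed(seed)
  loadOrder <- sample(rep(0:2, each = cfg$blocksPerCondition))
  trialS <- cfg$stimulusDurationS + cfg$interTrialS
  blockLenS <- cfg$stimuliPerBlock * trialS + cfg$interBlockGapS
  rows <- lapply(seq_len(cfg$nBlocks), function(b) {
    start <- cfg$startS + (b - 1) * blockLenS
    data.frame(onset_s = start + (seq_len(cfg$stimuliPerBlock) - 1) * trialS,
               block = b, load = loadOrder[b])
  })
  ev <- do.call(rbind, rows)
  ev$isTarget <- FALSE
  for (ld in 0:2) {
    idx <- which(ev$load == ld)
    ev$isTarget[sample(idx, cfg$targetCounts[ld + 1])] <- TRUE
  }
  ev$condition <- factor(paste0(ev$load, ifelse(ev$isTarget, "T", "D")),
                         levels = conditionLevels())
  ev <- ev[, c("onset_s", "condition", "block", "load", "isTarget")]
  class(ev) <- c("EventTable", "data.frame")
  ev
}

# T x K multiplicative boost matrix from event-locked modulations
buildBoost <- function(nSamples, nStates, fs, events, evokedStates) {
  boost <- matrix(1, nSamples, nStates)
  for (m in evokedStates) {
    for (on in events$onset_s) {
      i0 <- round((on + m$latencyS) * fs) + 1L
      i1 <- round((on + m$latencyS + m$windowS) * fs)
      if (i1 < 1L || i0 > nSamples) next
      idx <- max(i0, 1L):min(i1, nSamples)
      boost[idx, m$state] <- boost[idx, m$state] * m$factor
    }
  }
  boost
}

#' Simulate a hidden state path (with optional event-locked modulation)
#'
#' Samples a sticky Markov chain whose transition matrix has `stickiness` on
#' the diagonal and the remaining mass spread uniformly off-diagonal. When a
#' task with `evokedStates` modulations is supplied, the per-sample state
#' probabilities are multiplied by the modulation factor inside each
#' post-onset window and renormalized, keeping the path a valid
#' (inhomogeneous) Markov chain.
#'
#' @param cfg a [simConfig()].
#' @param task optional [taskConfig()] carrying `evokedStates`.
#' @param events optional pre-generated event table; generated from `task`
#'   with `cfg$seed` when `task` is given and `events` is `NULL`.
#' @param seed integer seed; defaults to `cfg$seed`.
#' @return A list of class `GroundTruth`: `statePath` (1-based labels),
#'   `transitionMatrix`, `pi` (uniform), `events` (or `NULL`), `stateSpecs`,
#'   `fs`.
#' @export
simulateStatePath <- function(cfg, task = NULL, events = NULL, seed = cfg$seed) {
  stopifnot(inherits(cfg, "SimConfig"))
  K <- cfg$nStates
  A <- if (K == 1) matrix(1, 1, 1) else {
    off <- (1 - cfg$stickiness) / (K - 1)
    m <- matrix(off, K, K); diag(m) <- cfg$stickiness; m
  }
  pi0 <- rep(1 / K, K)
  nSamples <- round(cfg$durationS * cfg$fs)
  set.seed(seed)
  if (!is.null(task) && is.null(events)) events <- simulateTaskEvents(task, seed)
  boost <- if (!is.null(task) && length(task$evokedStates) && !is.null(events)) {
    lastNeeded <- max(round((max(events$onset_s) + 3) * cfg$fs), nSamples)
    if (lastNeeded > nSamples) nSamples <- lastNeeded
    buildBoost(nSamples, K, cfg$fs, events, task$evokedStates)
  } else matrix(0, 0, 0)
  u <- runif(nSamples)
  path <- markov_path_cpp(A, pi0, u, boost)
  structure(list(statePath = path, transitionMatrix = A, pi = pi0,
                 events = events, stateSpecs = cfg$stateSpecs, fs = cfg$fs),
            class = c("GroundTruth", "list"))
}

#' Render a recording from a ground-truth state path
#'
#' Each sample is the active state's oscillatory network signal plus white
#' noise. During a contiguous visit of state k, every region in the state's
#' subset carries a sinusoid at the state's center frequency with a random
#' initial phase drawn once per visit, per-region amplitudes, and the stated
#' pairwise phase lag between consecutive subset regions; regions outside the
#' subset carry noise only.
#'
#' @param truth result of [simulateStatePath()].
#' @param cfg the same [simConfig()].
#' @param subjectId subject label.
#' @param seed integer seed; defaults to `cfg$seed + 1` so the path and the
#'   rendering consume independent streams.
#' @return A [Recording-class].
#' @export
renderRecording <- function(truth, cfg, subjectId = "S01", seed = cfg$seed + 1L) {
  stopifnot(inherits(truth, "GroundTruth"), inherits(cfg, "SimConfig"))
  path <- truth$statePath
  T <- length(path)
  set.seed(seed)
  X <- matrix(rnorm(cfg$nRegions * T, sd = cfg$noiseSd), cfg$nRegions, T)
  visits <- rle(path)
  ends <- cumsum(visits$lengths)
  starts <- ends - visits$lengths + 1L
  for (v in seq_along(visits$values)) {
    sp <- cfg$stateSpecs[[visits$values[v]]]
    if (all(sp$amplitude == 0)) { runif(1); next }  # keep RNG stream aligned
    tt <- (starts[v]:ends[v]) / cfg$fs
    phase0 <- runif(1, 0, 2 * pi)
    amp <- rep_len(sp$amplitude, length(sp$regions))
    w <- 2 * pi * sp$freqHz
    for (j in seq_along(sp$regions)) {
      r <- sp$regions[j]
      X[r, starts[v]:ends[v]] <- X[r, starts[v]:ends[v]] +
        amp[j] * sin(w * (tt - (j - 1) * sp$phaseLagS) + phase0)
    }
  }
  Recording(X, cfg$fs, subjectId = subjectId)
}

#' Simulate a multi-subject dataset
#'
#' Per subject: a state path (optionally event-modulated), its rendered
#' recording, and an event table. Subject s uses seeds derived from
#' `cfg$seed + 1000 * s` so subjects are independent yet reproducible.
#'
#' @param cfg a [simConfig()].
#' @param task optional [taskConfig()].
#' @return List of per-subject lists with elements `recording`, `events`,
#'   `truth`.
#' @export
simulateDataset <- function(cfg, task = NULL) {
  lapply(seq_len(cfg$nSubjects), function(s) {
    base <- cfg$seed + 1000L * s
    events <- if (!is.null(task)) simulateTaskEvents(task, seed = base) else NULL
    truth <- simulateStatePath(cfg, task = task, events = events, seed = base + 1L)
    rec <- renderRecording(truth, cfg, subjectId = sprintf("S%02d", s), seed = base + 2L)
    list(recording = rec, events = events, truth = truth)
  })
}

#' Three-state oscillatory benchmark
#'
#' The package's standard recovery benchmark: 10 regions at 250 Hz switching
#' among three states with distinct oscillatory networks near 6, 10 and 20 Hz
#' (stickiness 0.98, so mean lifetimes of 200 ms), against which state
#' recovery, transition estimates and spectral peaks are scored.
#'
#' @param nSamples samples to simulate (default 1e5).
#' @param seed integer seed.
#' @param noiseSd noise standard deviation.
#' @return List with `recording`, `truth`, `cfg`.
#' @export
makeThreeStateBenchmark <- function(nSamples = 1e5, seed = 1, noiseSd = 0.5) {
  specs <- list(
    list(regions = 1:4,  freqHz = 6,  amplitude = 1, phaseLagS = 0.005),
    list(regions = 4:7,  freqHz = 10, amplitude = 1, phaseLagS = 0.005),
    list(regions = 7:10, freqHz = 20, amplitude = 1, phaseLagS = 0.005))
  cfg <- simConfig(nRegions = 10, fs = 250, nStates = 3, stickiness = 0.98,
                   stateSpecs = specs, noiseSd = noiseSd,
                   durationS = nSamples / 250, seed = seed)
  truth <- simulateStatePath(cfg)
  rec <- renderRecording(truth, cfg)
  list(recording = rec, truth = truth, cfg = cfg)
}
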