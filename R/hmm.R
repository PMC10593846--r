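# Variational-Bayes Gaussian HMM on reduced time-delay-embedded data.
#
# Conjugate model: Dirichlet rows on the transition matrix, Dirichlet initial
# distribution, inverse-Wishart state covariances (optionally Normal-inverse-
# Wishart when state means are freed). The E-step is exact forward-backward
# run on the expected-log parameters (compiled in src/); the M-step applies
# the closed-form conjugate updates. The reported free energy is the negative
# evidence lower bound and is non-increasing across full-batch iterations.

defaultPriors <- function(X, K, freeMeans = FALSE) {
  P <- ncol(X)
  list(alphaA = 1, alphaPi = 1,
       nu0 = P + 2,
       S0 = diag(apply(X, 2, stats::var), P),  # prior mean of Sigma ~ data variances
       kappa0 = if (freeMeans) 1e-3 else Inf,
       m0 = rep(0, P))
}

# expected log emission densities under q(Sigma_k) (and q(mu_k) if freed)
expectedLogEmissions <- function(post, X, freeMeans) {
  T <- nrow(X); P <- ncol(X); K <- length(post$nu)
  logB <- matrix(0, T, K)
  for (k in seq_len(K)) {
    R <- chol(post$S[[k]])
    logdetS <- 2 * sum(log(diag(R)))
    ElogdetLam <- sum(digamma((post$nu[k] + 1 - seq_len(P)) / 2)) +
      P * log(2) - logdetS
    Xc <- if (freeMeans) sweep(X, 2, post$m[k, ]) else X
    Z <- backsolve(R, t(Xc), transpose = TRUE)
    q <- post$nu[k] * colSums(Z^2)
    if (freeMeans) q <- q + P / post$kappa[k]
    logB[, k] <- -0.5 * P * log(2 * pi) + 0.5 * ElogdetLam - 0.5 * q
  }
  logB
}

pointLogEmissions <- function(model, X) {
  vapply(seq_len(model@K),
         function(k) mvn_logdens(X, model@mu[k, ], model@Sigma[[k]]),
         numeric(nrow(X)))
}

# forward-backward over concatenated subjects
fbSegments <- function(logB, logA, logpi, lengths) {
  K <- ncol(logB)
  gamma <- matrix(0, nrow(logB), K)
  xi <- matrix(0, K, K)
  piCounts <- rep(0, K)
  loglik <- 0
  off <- 0L
  for (len in lengths) {
    idx <- (off + 1L):(off + len)
    r <- fb_cpp(logB[idx, , drop = FALSE], logA, logpi)
    gamma[idx, ] <- r$gamma
    xi <- xi + r$xi
    piCounts <- piCounts + r$gamma[1, ]
    loglik <- loglik + r$loglik
    off <- off + len
  }
  list(gamma = gamma, xi = xi, piCounts = piCounts, loglik = loglik)
}

klDirichlet <- function(alpha, alpha0) {
  a0 <- rep_len(alpha0, length(alpha))
  lgamma(sum(alpha)) - sum(lgamma(alpha)) - lgamma(sum(a0)) + sum(lgamma(a0)) +
    sum((alpha - a0) * (digamma(alpha) - digamma(sum(alpha))))
}

# KL( Wishart(nu, S^-1) || Wishart(nu0, S0^-1) ), the precision-space view of
# the inverse-Wishart covariance posterior vs prior
klWishart <- function(S, nu, S0, nu0) {
  P <- nrow(S)
  Rq <- chol(S)
  logdetS <- 2 * sum(log(diag(Rq)))
  logdetS0 <- 2 * sum(log(diag(chol(S0))))
  ElogdetLam <- sum(digamma((nu + 1 - seq_len(P)) / 2)) + P * log(2) - logdetS
  logB <- function(logdet, n)
    (n / 2) * logdet - (n * P / 2) * log(2) - (P * (P - 1) / 4) * log(pi) -
      sum(lgamma((n + 1 - seq_len(P)) / 2))
  # tr(S0 S^-1)
  Sinv <- chol2inv(Rq)
  trTerm <- sum(S0 * Sinv)
  logB(logdetS, nu) - logB(logdetS0, nu0) +
    ((nu - nu0) / 2) * ElogdetLam - nu * P / 2 + (nu / 2) * trTerm
}

klTheta <- function(post, priors, freeMeans) {
  K <- length(post$nu)
  kl <- klDirichlet(post$alphaPi, priors$alphaPi)
  for (k in seq_len(K)) {
    kl <- kl + klDirichlet(post$alphaA[k, ], priors$alphaA)
    kl <- kl + klWishart(post$S[[k]], post$nu[k], priors$S0, priors$nu0)
    if (freeMeans) {
      Sinv <- chol2inv(chol(post$S[[k]]))
      mq <- post$m[k, ] - priors$m0
      kl <- kl + 0.5 * (priors$kappa0 * post$nu[k] * drop(mq %*% Sinv %*% mq) +
        nrow(post$S[[k]]) * (priors$kappa0 / post$kappa[k] - 1 +
                               log(post$kappa[k] / priors$kappa0)))
    }
  }
  kl
}

mStep <- function(X, gamma, xi, piCounts, priors, freeMeans) {
  K <- ncol(gamma); P <- ncol(X)
  Nk <- colSums(gamma)
  post <- list(
    alphaA = priors$alphaA + xi,
    alphaPi = priors$alphaPi + piCounts,
    nu = priors$nu0 + Nk,
    kappa = if (freeMeans) priors$kappa0 + Nk else rep(Inf, K),
    m = matrix(0, K, P),
    S = vector("list", K))
  for (k in seq_len(K)) {
    Sxx <- crossprod(X, X * gamma[, k])
    if (freeMeans) {
      sx <- colSums(X * gamma[, k])
      mk <- (priors$kappa0 * priors$m0 + sx) / post$kappa[k]
      post$m[k, ] <- mk
      post$S[[k]] <- priors$S0 + Sxx +
        priors$kappa0 * tcrossprod(priors$m0) - post$kappa[k] * tcrossprod(mk)
    } else {
      post$S[[k]] <- priors$S0 + Sxx
    }
    post$S[[k]] <- (post$S[[k]] + t(post$S[[k]])) / 2
  }
  post
}

expectedLogA <- function(alphaA) {
  t(apply(alphaA, 1, function(a) digamma(a) - digamma(sum(a))))
}

postToModel <- function(post, priors, freeEnergy, seed, reg = 1e-6) {
  K <- length(post$nu); P <- ncol(post$m)
  A <- post$alphaA / rowSums(post$alphaA)
  pi0 <- post$alphaPi / sum(post$alphaPi)
  Sigma <- lapply(seq_len(K), function(k) {
    S <- post$S[[k]] / (post$nu[k] - P - 1)   # inverse-Wishart mean
    S + diag(reg * mean(diag(S)), P)
  })
  HMMModel(pi = pi0, A = A, Sigma = Sigma, mu = post$m, priors = priors,
           freeEnergy = freeEnergy, seed = seed)
}

#' Fit a variational-Bayes Gaussian HMM
#'
#' Alternates exact forward-backward smoothing (E-step, run on expected-log
#' parameters) with conjugate Dirichlet / inverse-Wishart updates (M-step) on
#' concatenated multi-subject data. State means are fixed at zero by default —
#' on time-delay-embedded, standardized data all state identity lives in the
#' covariances — and can be freed with `freeMeans = TRUE`. Multiple random
#' restarts are run and the one with the lowest final free energy is kept.
#'
#' @param X samples x P matrix (concatenated reduced data).
#' @param K number of states.
#' @param lengths per-subject segment lengths summing to `nrow(X)`.
#' @param maxIter maximum full VB iterations per restart.
#' @param tol absolute free-energy change declaring convergence.
#' @param nRestarts random restarts (default 5).
#' @param seed integer seed; the whole fit is deterministic given it.
#' @param freeMeans estimate state means (default FALSE).
#' @param priors optional list overriding the weak conjugate defaults
#'   (`alphaA`, `alphaPi`, `nu0`, `S0`, `kappa0`, `m0`).
#' @param minibatch optional subject-minibatch size for stochastic inference:
#'   each iteration updates the posterior from a random subject subset with a
#'   decaying step size (Robbins-Monro); the free-energy trace is then only
#'   approximate and the monotonicity guarantee applies to full-batch runs.
#' @param verbose print per-iteration free energy.
#' @return List with `model` ([HMMModel-class]) and `stc`
#'   ([StateTimeCourse-class] from a final full E-step).
#' @export
fitHMM <- function(X, K, lengths = nrow(X), maxIter = 100, tol = 1e-6,
                   nRestarts = 5, seed = 1, freeMeans = FALSE, priors = NULL,
                   minibatch = NULL, verbose = FALSE) {
  X <- as.matrix(X)
  if (K < 1) stop("K must be >= 1")
  if (nrow(X) == 0) stop("empty data")
  if (sum(lengths) != nrow(X)) stop("lengths must sum to nrow(X)")
  K <- as.integer(K)
  priors <- utils::modifyList(defaultPriors(X, K, freeMeans), priors %||% list())
  set.seed(seed)

  runs <- lapply(seq_len(nRestarts), function(rst) {
    if (is.null(minibatch)) {
      vbRun(X, K, lengths, maxIter, tol, priors, freeMeans, verbose)
    } else {
      vbRunStochastic(X, K, lengths, maxIter, priors, freeMeans, minibatch)
    }
  })
  fe <- vapply(runs, function(r) r$freeEnergy[length(r$freeEnergy)], numeric(1))
  best <- runs[[which.min(fe)]]
  if (!best$converged)
    warning(sprintf("VB fit did not converge within %d iterations (free-energy change %.3g)",
                    maxIter, best$lastChange))
  model <- postToModel(best$post, priors, best$freeEnergy, seed)
  stc <- new("StateTimeCourse", gamma = best$gamma, xi = best$xi,
             subjectLengths = as.integer(lengths), logLik = best$loglik)
  list(model = model, stc = stc)
}

vbRun <- function(X, K, lengths, maxIter, tol, priors, freeMeans, verbose = FALSE) {
  T <- nrow(X)
  gamma <- rdirichlet_rows(T, K)
  xi <- matrix(0, K, K)
  off <- 0L
  for (len in lengths) {  # crude init xi from soft counts
    idx <- (off + 1L):(off + len)
    g <- gamma[idx, , drop = FALSE]
    xi <- xi + crossprod(g[-len, , drop = FALSE], g[-1, , drop = FALSE])
    off <- off + len
  }
  piCounts <- colSums(gamma[cumsum(lengths) - lengths + 1, , drop = FALSE])
  post <- mStep(X, gamma, xi, piCounts, priors, freeMeans)

  feTrace <- numeric(0)
  converged <- FALSE
  lastChange <- Inf
  e <- NULL
  for (it in seq_len(maxIter)) {
    kl <- klTheta(post, priors, freeMeans)
    logB <- expectedLogEmissions(post, X, freeMeans)
    ElogA <- expectedLogA(post$alphaA)
    Elogpi <- digamma(post$alphaPi) - digamma(sum(post$alphaPi))
    e <- fbSegments(logB, ElogA, Elogpi, lengths)
    fe <- -(e$loglik - kl)
    feTrace <- c(feTrace, fe)
    if (verbose) message(sprintf("iter %d: free energy %.6f", it, fe))
    post <- mStep(X, e$gamma, e$xi, e$piCounts, priors, freeMeans)
    if (it > 1) {
      lastChange <- feTrace[it - 1] - feTrace[it]
      if (abs(lastChange) < tol) { converged <- TRUE; break }
    }
  }
  list(post = post, gamma = e$gamma, xi = e$xi, loglik = e$loglik,
       freeEnergy = feTrace, converged = converged, lastChange = lastChange)
}

vbRunStochastic <- function(X, K, lengths, maxIter, priors, freeMeans, minibatch,
                            forget = 0.7, delay = 2) {
  nSubj <- length(lengths)
  size <- min(if (is.list(minibatch)) minibatch$size else minibatch, nSubj)
  starts <- cumsum(lengths) - lengths + 1L
  T <- nrow(X)
  gamma <- rdirichlet_rows(T, K)
  xi0 <- crossprod(gamma[-T, , drop = FALSE], gamma[-1, , drop = FALSE])
  post <- mStep(X, gamma, xi0, colSums(gamma[starts, , drop = FALSE]),
                priors, freeMeans)
  feTrace <- numeric(0)
  stats <- NULL
  for (it in seq_len(maxIter)) {
    batch <- sample(nSubj, size)
    idx <- unlist(lapply(batch, function(s) starts[s]:(starts[s] + lengths[s] - 1L)))
    Xb <- X[idx, , drop = FALSE]
    logB <- expectedLogEmissions(post, Xb, freeMeans)
    e <- fbSegments(logB, expectedLogA(post$alphaA),
                    digamma(post$alphaPi) - digamma(sum(post$alphaPi)),
                    lengths[batch])
    scale <- T / nrow(Xb)
    new <- list(xi = e$xi * scale,
                piCounts = e$piCounts * nSubj / size,
                Nk = colSums(e$gamma) * scale,
                Sxx = lapply(seq_len(K), function(k)
                  crossprod(Xb, Xb * e$gamma[, k]) * scale))
    rho <- (it + delay)^(-forget)
    stats <- if (is.null(stats)) new else list(
      xi = (1 - rho) * stats$xi + rho * new$xi,
      piCounts = (1 - rho) * stats$piCounts + rho * new$piCounts,
      Nk = (1 - rho) * stats$Nk + rho * new$Nk,
      Sxx = lapply(seq_len(K), function(k)
        (1 - rho) * stats$Sxx[[k]] + rho * new$Sxx[[k]]))
    post$alphaA <- priors$alphaA + stats$xi
    post$alphaPi <- priors$alphaPi + stats$piCounts
    post$nu <- priors$nu0 + stats$Nk
    post$S <- lapply(seq_len(K), function(k) {
      S <- priors$S0 + stats$Sxx[[k]]; (S + t(S)) / 2
    })
    feTrace <- c(feTrace, -(e$loglik * scale - klTheta(post, priors, freeMeans)))
  }
  # final full E-step for reporting
  logB <- expectedLogEmissions(post, X, freeMeans)
  e <- fbSegments(logB, expectedLogA(post$alphaA),
                  digamma(post$alphaPi) - digamma(sum(post$alphaPi)), lengths)
  list(post = post, gamma = e$gamma, xi = e$xi, loglik = e$loglik,
       freeEnergy = feTrace, converged = TRUE, lastChange = NA_real_)
}

#' Forward-backward posterior state probabilities
#'
#' Exact smoothing distribution (the state time course, "gamma") under point
#' parameters, with the log-likelihood accumulated from the forward-scaling
#' constants.
#'
#' @param model an [HMMModel-class].
#' @param X samples x P observation matrix.
#' @param lengths per-subject segment lengths.
#' @return A [StateTimeCourse-class].
#' @export
forwardBackward <- function(model, X, lengths = nrow(X)) {
  stopifnot(is(model, "HMMModel"))
  X <- as.matrix(X)
  if (ncol(X) != model@P) stop("observation dimension does not match model P")
  logB <- pointLogEmissions(model, X)
  e <- fbSegments(logB, log(model@A), log(model@pi), lengths)
  new("StateTimeCourse", gamma = e$gamma, xi = e$xi,
      subjectLengths = as.integer(lengths), logLik = e$loglik)
}

#' Viterbi decoding
#'
#' Most probable joint state path under point parameters; ties are broken
#' toward the lower state index.
#'
#' @inheritParams forwardBackward
#' @return Integer vector of 1-based state labels.
#' @export
viterbiPath <- function(model, X, lengths = nrow(X)) {
  stopifnot(is(model, "HMMModel"))
  X <- as.matrix(X)
  logB <- pointLogEmissions(model, X)
  logA <- log(model@A)
  logpi <- log(model@pi)
  out <- integer(nrow(X))
  off <- 0L
  for (len in lengths) {
    idx <- (off + 1L):(off + len)
    out[idx] <- viterbi_cpp(logB[idx, , drop = FALSE], logA, logpi)
    off <- off + len
  }
  out
}

#' Match the states of two fitted models
#'
#' Finds the state permutation that maximizes the summed similarity between
#' matched state covariances, where similarity is the Pearson correlation of
#' the vectorized matrix logarithms (a log-Euclidean, affine-robust comparison
#' of covariance geometry). The assignment is solved exactly by enumeration
#' for K <= 8 and greedily above.
#'
#' @param reference,other [HMMModel-class] objects with equal K and P.
#' @return Integer permutation `p` such that `other` state `p[i]` matches
#'   `reference` state `i`.
#' @export
alignStates <- function(reference, other) {
  if (reference@K != other@K || reference@P != other@P)
    stop("models must share K and P")
  K <- reference@K
  vr <- lapply(reference@Sigma, function(S) as.vector(spd_logm(S)))
  vo <- lapply(other@Sigma, function(S) as.vector(spd_logm(S)))
  sim <- outer(seq_len(K), seq_len(K),
               Vectorize(function(i, j) stats::cor(vr[[i]], vo[[j]])))
  if (K <= 8) {
    pm <- perms(K)
    scores <- apply(pm, 1, function(p) sum(sim[cbind(seq_len(K), p)]))
    as.integer(pm[which.max(scores), ])
  } else {
    p <- integer(K)
    avail <- seq_len(K)
    for (i in order(apply(sim, 1, max), decreasing = TRUE)) {
      j <- avail[which.max(sim[i, avail])]
      p[i] <- j
      avail <- setdiff(avail, j)
    }
    p
  }
}

#' Best label permutation against a reference path
#'
#' Utility for ground-truth scoring: finds the relabeling of an estimated
#' state path that maximizes per-sample agreement with a true path.
#'
#' @param estPath,truePath integer state paths of equal length.
#' @param K number of states.
#' @return List: `perm` (estimated label i plays true label `perm[i]`) and
#'   `accuracy` (fraction of samples agreeing after relabeling).
#' @export
alignToPath <- function(estPath, truePath, K) {
  stopifnot(length(estPath) == length(truePath), K <= 8)
  pm <- perms(K)
  acc <- apply(pm, 1, function(p) mean(p[estPath] == truePath))
  best <- which.max(acc)
  list(perm = as.integer(pm[best, ]), accuracy = acc[best])
}
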