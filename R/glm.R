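#' Build the trial-wise GLM design matrix
#'
#' Constant regressor plus one demeaned indicator per condition, so the
#' constant estimates the average response across all task conditions and each
#' condition regressor the deviation from it. Because the demeaned indicators
#' of an exhaustive condition set sum to zero the design is solved by
#' minimum-norm least squares; all condition-difference contrasts and the
#' constant remain estimable and unique.
#'
#' @param conditions factor (or character) of per-trial condition labels.
#' @param levels condition levels defining the columns; defaults to
#'   [conditionLevels()].
#' @return Design matrix (trials x (1 + nlevels)) with column names
#'   `constant`, then the levels.
#' @export
buildDesign <- function(conditions, levels = conditionLevels()) {
  conditions <- factor(conditions, levels = levels)
  if (anyNA(conditions)) stop("unknown condition label in events")
  X <- cbind(constant = 1,
             vapply(levels, function(l) as.numeric(conditions == l),
                    numeric(length(conditions))))
  X[, -1] <- sweep(X[, -1, drop = FALSE], 2,
                   colMeans(X[, -1, drop = FALSE]))
  X
}

#' Standard contrasts for the six n-back conditions
#'
#' The across-condition mean (constant), target-vs-distractor at each
#' working-memory load, and the load contrasts 1-0, 2-0, 2-1 pooling target
#' and distractor trials.
#'
#' @return Contrast matrix (contrasts x 7) with informative row names; every
#'   row except `mean` sums to zero.
#' @export
defaultContrasts <- function() {
  lv <- conditionLevels()  # 0T 0D 1T 1D 2T 2D
  C <- rbind(
    mean       = c(1, 0, 0, 0, 0, 0, 0),
    TvD_0back  = c(0, 1, -1, 0, 0, 0, 0),
    TvD_1back  = c(0, 0, 0, 1, -1, 0, 0),
    TvD_2back  = c(0, 0, 0, 0, 0, 1, -1),
    load_1v0   = c(0, -0.5, -0.5, 0.5, 0.5, 0, 0),
    load_2v0   = c(0, -0.5, -0.5, 0, 0, 0.5, 0.5),
    load_2v1   = c(0, 0, 0, -0.5, -0.5, 0.5, 0.5))
  colnames(C) <- c("constant", lv)
  C
}

#' First-level contrasts of parameter estimates (COPEs)
#'
#' Fits the trial-wise GLM independently at every (state, timepoint) of one
#' subject's epoched state course and applies the contrast matrix to the
#' coefficient estimates.
#'
#' @param epochs an [EpochedCourse-class] for one subject.
#' @param contrasts contrast matrix (contrasts x design columns); default
#'   [defaultContrasts()].
#' @param levels condition levels; default [conditionLevels()].
#' @return Array (states x timepoints x contrasts) with contrast dimnames.
#' @export
firstLevelCopes <- function(epochs, contrasts = defaultContrasts(),
                            levels = conditionLevels()) {
  stopifnot(is(epochs, "EpochedCourse"))
  cond <- factor(epochs@conditions, levels = levels)
  used <- levels[colSums(abs(contrasts[, -1, drop = FALSE])) > 0]
  missing <- used[!used %in% cond]
  if (length(missing))
    stop(sprintf("no trials for condition(s) %s", paste(missing, collapse = ", ")))
  X <- buildDesign(cond, levels)
  Xp <- pinv(X)
  d <- dim(epochs@data)                          # trials x time x K
  Y <- matrix(epochs@data, d[1], d[2] * d[3])    # trials x (time*K)
  beta <- Xp %*% Y                               # p x (time*K)
  cop <- contrasts %*% beta                      # nC x (time*K)
  out <- aperm(array(t(cop), c(d[2], d[3], nrow(contrasts))), c(2, 1, 3))
  dimnames(out) <- list(NULL, NULL, rownames(contrasts))
  out
}

#' Group-level sign-flip permutation test with max-statistic correction
#'
#' Second level of the two-level GLM: the observed statistic is the
#' across-subject mean COPE at every (state, timepoint, contrast). The null is
#' built by randomly sign-flipping whole subjects; each permutation records
#' the maximum of |statistic| over states and timepoints (per contrast), and a
#' point is significant when its observed |statistic| reaches the 97.5th
#' percentile of that max-null — a two-sided test at family-wise alpha 0.05,
#' corrected across time and states.
#'
#' @param copes array (subjects x states x timepoints x contrasts) of
#'   first-level COPEs.
#' @param nPerm number of permutations (default 1000).
#' @param alpha per-tail significance level (default 0.025; the threshold sits
#'   at the `1 - alpha` quantile of the max-|null|).
#' @param seed integer seed for the permutation sequence.
#' @return List of class `PermutationResult`: `observed` (states x time x
#'   contrasts mean COPE), `maxNull` (nPerm x contrasts), `threshold` (per
#'   contrast), `mask` (logical, same shape as observed), `nPerm`, `alpha`.
#' @export
maxStatPermutation <- function(copes, nPerm = 1000, alpha = 0.025, seed = 1) {
  d <- dim(copes)
  if (length(d) != 4) stop("copes must be subjects x states x time x contrasts")
  S <- d[1]
  if (S < 2) stop("at least 2 subjects are required for the group-level test")
  if (nPerm < 20) warning("fewer than 20 permutations: percentile threshold is unstable")
  M <- matrix(copes, S, prod(d[-1]))             # subjects x (K*T*C)
  observed <- array(colMeans(M), d[-1], dimnames = dimnames(copes)[-1])

  set.seed(seed)
  signs <- matrix(sample(c(-1, 1), nPerm * S, replace = TRUE), nPerm, S)
  stats <- abs(signs %*% M) / S                  # nPerm x (K*T*C)
  dim(stats) <- c(nPerm, d[2] * d[3], d[4])
  maxNull <- apply(stats, c(1, 3), max)          # nPerm x contrasts
  threshold <- apply(maxNull, 2, stats::quantile, probs = 1 - alpha, names = FALSE)
  mask <- sweep(abs(observed), 3, threshold, ">=") & abs(observed) > 0
  structure(list(observed = observed, maxNull = maxNull, threshold = threshold,
                 mask = mask, nPerm = nPerm, alpha = alpha),
            class = c("PermutationResult", "list"))
}

#' Run the full two-level evoked GLM
#'
#' Convenience wrapper: first-level COPEs per subject, then the group-level
#' sign-flip max-statistic permutation test.
#'
#' @param epochsList list of per-subject [EpochedCourse-class] objects.
#' @param contrasts contrast matrix; default [defaultContrasts()].
#' @param levels condition levels; default [conditionLevels()].
#' @inheritParams maxStatPermutation
#' @return A `PermutationResult` (see [maxStatPermutation()]) with the
#'   subject-level COPE array attached as `copes`.
#' @export
evokedGLM <- function(epochsList, contrasts = defaultContrasts(),
                      levels = conditionLevels(), nPerm = 1000,
                      alpha = 0.025, seed = 1) {
  copesBySubj <- lapply(epochsList, firstLevelCopes, contrasts = contrasts,
                        levels = levels)
  d <- dim(copesBySubj[[1]])
  copes <- array(NA_real_, c(length(copesBySubj), d),
                 dimnames = c(list(NULL), dimnames(copesBySubj[[1]])))
  for (s in seq_along(copesBySubj)) copes[s, , , ] <- copesBySubj[[s]]
  res <- maxStatPermutation(copes, nPerm = nPerm, alpha = alpha, seed = seed)
  res$copes <- copes
  res
}
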