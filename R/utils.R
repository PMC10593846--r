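# internal numerical helpers

# Moore-Penrose pseudoinverse via SVD
pinv <- function(X, tol = NULL) {
  s <- svd(X)
  if (is.null(tol)) tol <- max(dim(X)) * .Machine$double.eps * max(s$d)
  keep <- s$d > tol
  if (!any(keep)) return(matrix(0, ncol(X), nrow(X)))
  s$v[, keep, drop = FALSE] %*% (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

# one draw from a symmetric Dirichlet per row
rdirichlet_rows <- function(n, k, alpha = 1) {
  g <- matrix(stats::rgamma(n * k, shape = alpha), n, k)
  g / rowSums(g)
}

# multivariate normal log density with fixed mean, via Cholesky
mvn_logdens <- function(X, mu, Sigma) {
  P <- ncol(X)
  R <- tryCatch(chol(Sigma), error = function(e)
    stop("singular covariance in emission density", call. = FALSE))
  Xc <- sweep(X, 2, mu)
  Z <- backsolve(R, t(Xc), transpose = TRUE)   # R' Z = Xc'
  q <- colSums(Z^2)
  -0.5 * (P * log(2 * pi) + 2 * sum(log(diag(R))) + q)
}

# principal matrix logarithm of a symmetric positive-definite matrix
spd_logm <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  v <- pmax(e$values, .Machine$double.eps)
  e$vectors %*% (log(v) * t(e$vectors))
}

# all permutations of 1..n (n small)
perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- perms(n - 1L)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub), n - 1L)))
  }
  out
}

# z-score a vector; a constant vector maps to all zeros
zscore0 <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s < .Machine$double.eps) return(rep(0, length(x)))
  (x - mean(x)) / s
}

`%||%` <- function(a, b) if (is.null(a)) b else a
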