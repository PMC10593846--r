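test_that("symmetric orthogonalization removes zero-lag correlations", {
  # two strongly correlated channels
  set.seed(1)
  n <- 2000
  z <- rnorm(n)
  X <- rbind(z + 0.3 * rnorm(n), 0.9 * z + 0.44 * rnorm(n))
  expect_gt(abs(cor(X[1, ], X[2, ])), 0.8)
  out <- orthogonalizeSymmetric(Recording(X, 250))
  Y <- recData(out)
  expect_lt(abs(cor(Y[1, ], Y[2, ])), 1e-8)
  # row norms preserved
  Xc <- X - rowMeans(X)
  expect_equal(sqrt(rowSums(Y^2)), sqrt(rowSums(Xc^2)), tolerance = 1e-10)

  # already-orthogonal zero-mean rows are a fixed point
  t0 <- seq_len(1000)
  O <- rbind(sin(2 * pi * 5 * t0 / 1000), cos(2 * pi * 5 * t0 / 1000))
  fx <- recData(orthogonalizeSymmetric(Recording(O, 250)))
  expect_lt(max(abs(fx - O)), 1e-10)

  # duplicated region: explicit rank error
  expect_error(orthogonalizeSymmetric(Recording(rbind(z, z, rnorm(n)), 250)),
               "rank")
})

test_that("orthogonalization commutes with region permutation", {
  set.seed(2)
  X <- matrix(rnorm(4 * 500), 4)
  X[2, ] <- X[2, ] + 0.7 * X[1, ]
  perm <- c(3, 1, 4, 2)
  a <- recData(orthogonalizeSymmetric(Recording(X[perm, ], 100)))
  b <- recData(orthogonalizeSymmetric(Recording(X, 100)))[perm, ]
  expect_equal(a, b, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("time-delay embedding has the documented shape and layout", {
  set.seed(3)
  rec42 <- Recording(matrix(rnorm(42 * 200), 42), 250)
  emb <- buildEmbedded(rec42, -7:7)
  expect_equal(nrow(emb$matrix), 630)           # 42 regions x 15 lags
  expect_equal(length(emb$lags), 15)
  expect_equal(emb$indexMap, 8:193)

  # lag set {0} is the identity embedding
  rec <- Recording(matrix(rnorm(2 * 50), 2), 100)
  emb0 <- buildEmbedded(rec, 0)
  expect_equal(emb0$matrix, recData(rec), ignore_attr = TRUE)

  # hand-written oracle: 2 regions, 5 samples, lags -1..+1
  X <- rbind(1:5, 11:15)
  e <- buildEmbedded(Recording(X, 1), -1:1)
  expected <- rbind(c(1, 2, 3),     # region 1, lag -1
                    c(2, 3, 4),     # region 1, lag  0
                    c(3, 4, 5),     # region 1, lag +1
                    c(11, 12, 13),  # region 2, lag -1
                    c(12, 13, 14),
                    c(13, 14, 15))
  expect_equal(dim(e$matrix), c(6, 3))
  expect_equal(unname(e$matrix), expected)
  expect_equal(e$indexMap, 2:4)

  # lag-0 extraction returns the original interior samples exactly
  expect_equal(unname(lagZero(e)), X[, 2:4])

  expect_error(buildEmbedded(Recording(matrix(rnorm(10), 1), 10), -7:7), "short")
})

test_that("PCA reduction retains the 2x-regions rule and reconstructs", {
  set.seed(4)
  rec <- Recording(matrix(rnorm(42 * 400), 42), 250)
  prep <- prepareData(rec, lags = -7:7)
  expect_equal(ncol(prep$scores), 84)           # 2 * 42 components
  expect_equal(ncol(prep$pca$loadings), 84)

  # full-rank reconstruction is exact
  E <- buildEmbedded(Recording(matrix(rnorm(3 * 100), 3), 100), -1:1)$matrix
  p <- pcaReduce(E, nComponents = 9)
  Ehat <- p$loadings %*% p$scores + p$mean
  expect_lt(max(abs(Ehat - E)), 1e-8)
  # loadings orthonormal
  expect_lt(max(abs(crossprod(p$loadings) - diag(9))), 1e-8)
  # explained variance fractions are non-increasing
  expect_true(all(diff(p$explained) <= 1e-12))

  # rank-2 matrix: two components explain everything
  F2 <- matrix(rnorm(2 * 200), 2)
  L <- matrix(rnorm(6 * 2), 6)
  p2 <- pcaReduce(L %*% F2, 2)
  expect_equal(sum(p2$explained[1:2]), 1, tolerance = 1e-10)
  expect_error(pcaReduce(L %*% F2, 5), "rank")
})

test_that("variance retained by PCA is monotone in the component count", {
  set.seed(5)
  E <- matrix(rnorm(10 * 300), 10) * seq(1, 4, length.out = 10)
  v <- vapply(1:6, function(P) {
    p <- pcaReduce(E, P)
    sum(p$explained[seq_len(P)])
  }, numeric(1))
  expect_true(all(diff(v) > 0))
})
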