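test_that("singular value thresholding matches hand-computed cases", {
  X <- diag(c(3, 1))
  expect_equal(svt(X, 1), diag(c(2, 0)), tolerance = 1e-12)
  set.seed(3)
  Y <- matrix(rnorm(12), 3)
  expect_equal(svt(Y, 0), Y, tolerance = 1e-10)
  expect_equal(svt(Y, max(svd(Y)$d)), matrix(0, 3, 4))
  # non-expansive
  expect_lte(sqrt(sum(svt(Y, 0.5)^2)), sqrt(sum(Y^2)))
})

test_that("shrinkage is the elementwise soft threshold", {
  expect_equal(shrink(2.0, 0.5), 1.5)
  expect_equal(shrink(-0.3, 0.5), 0)
  set.seed(4)
  X <- matrix(rnorm(15), 3, 5)
  oracle <- X
  for (i in 1:3) for (j in 1:5)
    oracle[i, j] <- sign(X[i, j]) * max(abs(X[i, j]) - 0.4, 0)
  expect_equal(shrink(X, 0.4), oracle, tolerance = 1e-15)
  expect_lte(sqrt(sum(shrink(X, 0.2)^2)), sqrt(sum(X^2)))
})

test_that("pursuit recovers an exact low-rank matrix and handles zero input", {
  # well-posed aspect ratio: with enough rows the rank-1 factor is
  # incoherent and pursuit splits exactly
  set.seed(5)
  M <- tcrossprod(rnorm(30), rnorm(300))
  dec <- pcp(M)
  expect_true(dec$converged)
  expect_lte(dec$residual, 1e-7)
  expect_lt(sqrt(sum(dec$S^2)) / sqrt(sum(M^2)), 1e-4)
  expect_lt(sqrt(sum((dec$L - M)^2)) / sqrt(sum(M^2)), 1e-4)

  # planted spikes at the same aspect ratio: near-exact recovery
  set.seed(8)
  L_true <- tcrossprod(rnorm(30), rnorm(300))
  scale <- max(abs(L_true))
  S_true <- matrix(0, 30, 300)
  pos <- cbind(sample(1:30, 15, replace = TRUE), sample(1:300, 15))
  S_true[pos] <- 10 * scale * sample(c(-1, 1), 15, replace = TRUE)
  dec2 <- suppressWarnings(pcp(L_true + S_true, max_iter = 5000L))
  expect_lt(sqrt(sum((dec2$L - L_true)^2)) / sqrt(sum(L_true^2)), 1e-3)
  expect_true(all(abs(dec2$S[pos]) > 5 * scale))

  z <- pcp(matrix(0, 3, 50))
  expect_equal(z$L, matrix(0, 3, 50))
  expect_equal(z$S, matrix(0, 3, 50))
  expect_equal(z$iters, 1L)
})

test_that("planted sparse corruption is separated from the low-rank part", {
  # With only 3 rows the low-rank factor is maximally coherent, so the
  # convex program's optimum recovers the spike support exactly but the
  # low-rank part only up to a modest tilt (exact recovery guarantees do
  # not apply at this aspect ratio).
  set.seed(6)
  L_true <- tcrossprod(c(1, -0.5, 2), rnorm(300))
  scale <- max(abs(L_true))
  S_true <- matrix(0, 3, 300)
  pos <- cbind(sample(1:3, 5, replace = TRUE), sample(1:300, 5))
  S_true[pos] <- 10 * scale * sample(c(-1, 1), 5, replace = TRUE)
  dec <- suppressWarnings(pcp(L_true + S_true, max_iter = 20000L))
  # support recovery: every planted spike found above half its magnitude
  expect_true(all(abs(dec$S[pos]) > 5 * scale))
  # and nothing comparable elsewhere
  off <- abs(dec$S); off[pos] <- 0
  expect_true(all(off < 5 * scale))
  # the recovered background keeps rank 1 and the exact row direction
  sv <- svd(dec$L)
  expect_lt(sv$d[2] / sv$d[1], 1e-8)
  u_true <- c(1, -0.5, 2) / sqrt(sum(c(1, -0.5, 2)^2))
  expect_gt(abs(sum(sv$u[, 1] * u_true)), 0.99)
  expect_lt(sqrt(sum((dec$L - L_true)^2)) / sqrt(sum(L_true^2)), 0.5)
})

test_that("the default sparsity weight is one over the root of the larger dimension", {
  dec <- suppressWarnings(pcp(matrix(rnorm(900), 3, 300), max_iter = 1L))
  expect_equal(dec$lam, 1 / sqrt(300))
  expect_equal(dec$lam, 0.05774, tolerance = 1e-4)
})

test_that("the iteration is scale-equivariant", {
  set.seed(7)
  M <- tcrossprod(rnorm(3), rnorm(80)) + matrix(rnorm(240, sd = 0.01), 3)
  a <- suppressWarnings(pcp(M, lam = 0.1))
  b <- suppressWarnings(pcp(3.7 * M, lam = 0.1))
  expect_equal(b$iters, a$iters)
  expect_equal(b$L, 3.7 * a$L, tolerance = 1e-6)
  expect_equal(b$S, 3.7 * a$S, tolerance = 1e-6)
})
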