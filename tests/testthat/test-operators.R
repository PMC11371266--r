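# Forward models, constrained convolution stacks, spectral norms, and the
# weighted analysis operator.

test_that("identity and dense forward models expose exact spectral data", {
  H <- makeForwardModel("identity", c(8, 8))
  expect_equal(sqSpectralNorm(H), 1)
  expect_equal(sigmaMin(H), 1)
  x <- matrix(rnorm(64), 8, 8)
  expect_identical(applyOp(H, x), x)

  A <- diag(c(1, 2, 3))
  Hd <- makeForwardModel("dense", c(1, 3), list(matrix = A))
  expect_equal(sqSpectralNorm(Hd), 9)
  expect_equal(sigmaMin(Hd), 1)
  expect_error(makeForwardModel("dense", c(2, 2)), "matrix")
})

test_that("forward/adjoint pairs are consistent on random probes", {
  set.seed(11)
  A <- matrix(rnorm(20), 5, 4)
  Hd <- makeForwardModel("dense", c(2, 2), list(matrix = A))
  Hm <- makeForwardModel("masked_fourier", c(8, 8), list(Macc = 2), seed = 3)
  op <- convOperator(1, 3, 5, nLayers = 2, constraint = "zero_mean", seed = 2)
  opc <- convOperator(1, 2, 3, constraint = "none",
                      padding = "circular", seed = 4)
  for (i in 1:100) {
    x <- matrix(rnorm(64), 8, 8)
    # dense
    x4 <- matrix(rnorm(4), 2, 2); yv <- rnorm(5)
    ipd <- sum(applyOp(Hd, x4) * yv) - sum(x4 * applyOp(Hd, yv, adjoint = TRUE))
    expect_lt(abs(ipd), 1e-10 * (1 + abs(sum(applyOp(Hd, x4) * yv))))
    # masked Fourier (complex inner product, real part)
    yc <- matrix(complex(real = rnorm(64), imaginary = rnorm(64)), 8, 8)
    ipf <- Re(sum(applyOp(Hm, x) * Conj(yc))) -
      sum(x * applyOp(Hm, yc, adjoint = TRUE))
    expect_lt(abs(ipf), 1e-10 * (1 + abs(Re(sum(applyOp(Hm, x) * Conj(yc))))))
    # conv stacks, zero and circular padding
    u <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
    ipc <- sum(applyOp(op, x) * u) - sum(x * applyOp(op, u, adjoint = TRUE))
    expect_lt(abs(ipc), 1e-10 * (1 + abs(sum(applyOp(op, x) * u))))
    u2 <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
    ipc2 <- sum(applyOp(opc, x) * u2) - sum(x * applyOp(opc, u2, adjoint = TRUE))
    expect_lt(abs(ipc2), 1e-10 * (1 + abs(sum(applyOp(opc, x) * u2))))
  }
})

test_that("masked Fourier model selects floor(width/Macc) columns and is a
           partial isometry", {
  Hm <- makeForwardModel("masked_fourier", c(16, 32), list(Macc = 4),
                         seed = 5)
  expect_length(Hm@keptCols, 8)
  expect_true(is.na(sigmaMin(Hm)))
  expect_equal(sqSpectralNorm(Hm), 1)
  # linearity at zero
  expect_equal(max(Mod(applyOp(Hm, matrix(0, 16, 32)))), 0)
  # all columns kept: H^T H = Id on real inputs
  Hf <- makeForwardModel("masked_fourier", c(8, 8),
                         list(Macc = 1, centerFraction = 0.9))
  x <- matrix(rnorm(64), 8, 8)
  expect_lt(max(abs(applyOp(Hf, applyOp(Hf, x), adjoint = TRUE) - x)), 1e-10)
  expect_error(makeForwardModel("masked_fourier", c(4, 4), list(Macc = 8)),
               "Macc")
})

test_that("kernel constraint projections match their closed forms and are
           idempotent", {
  expect_equal(projectZeroMean(c(1, 2, 3)), c(-1, 0, 1))
  zm <- projectZeroMean(rnorm(9))
  expect_equal(projectZeroMean(zm), zm)
  expect_equal(projectZeroMean(rep(3, 4)), rep(0, 4))

  expect_equal(projectSimplex(c(-1, 1, 2)), c(0.25, 0.25, 0.5))
  expect_equal(projectSimplex(c(0, 0, 1)), c(0, 0, 1))
  expect_error(projectSimplex(c(0, 0, 0)), "zero")

  # 4-d banks: every 2-d kernel lands exactly on the constraint set
  set.seed(1)
  bank <- array(rnorm(5 * 5 * 4 * 2), c(5, 5, 4, 2))
  zb <- projectZeroMean(bank)
  expect_lt(max(abs(apply(zb, c(3, 4), sum))), 1e-9)
  sb <- projectSimplex(bank)
  expect_true(all(sb >= 0))
  expect_lt(max(abs(apply(sb, c(3, 4), sum) - 1)), 1e-9)
})

test_that("convolution stacks behave linearly and respect trivial kernels", {
  op <- identityConvOp()
  op2 <- setKernels(op, list(array(2, c(1, 1, 1, 1))))
  x <- matrix(rnorm(16), 4, 4)
  expect_equal(applyOp(op2, x)[, , 1], 2 * x)
  opz <- setKernels(convOperator(1, 2, 3, constraint = "none"),
                    list(array(0, c(3, 3, 2, 1))))
  expect_equal(max(abs(applyOp(opz, x))), 0)
  expect_error(applyOp(op, array(rnorm(32), c(4, 4, 2))), "channel mismatch")
})

test_that("power iteration matches a dense SVD oracle", {
  est <- estimateSqSpectralNorm(identity, identity, c(2, 2))
  expect_equal(as.numeric(est), 1, tolerance = 1e-6)
  set.seed(7)
  for (i in 1:5) {
    A <- matrix(rnorm(64 * 64), 64, 64)
    Hd <- makeForwardModel("dense", c(8, 8), list(matrix = A))
    est <- estimateSqSpectralNorm(function(v) applyOp(Hd, v),
                                  function(w) applyOp(Hd, w, adjoint = TRUE),
                                  c(8, 8), iters = 1000, tol = 1e-9)
    truth <- max(svd(A)$d)^2
    expect_lt(abs(est - truth) / truth, 1e-6)
  }
})

test_that("weighted analysis operator matches its contract and a dense
           construction", {
  set.seed(3)
  W <- convOperator(1, 2, 3, constraint = "zero_mean", seed = 5)
  x <- matrix(rnorm(16), 4, 4)
  ones <- onesAnalysis(W, c(4, 4))
  expect_equal(applyOp(ones, x), applyOp(W, x))
  zeroMask <- buildWeightedAnalysis(array(0, c(4, 4, 2)), W)
  expect_equal(max(abs(applyOp(zeroMask, x))), 0)
  # channel mismatch errors
  expect_error(buildWeightedAnalysis(array(1, c(4, 4, 3)), W), "channels")

  # random mask: adjoint consistency and dense-matrix oracle
  mask <- array(runif(4 * 4 * 2), c(4, 4, 2))
  L <- buildWeightedAnalysis(mask, W)
  for (i in 1:20) {
    xr <- matrix(rnorm(16), 4, 4)
    u <- array(rnorm(32), c(4, 4, 2))
    ip <- sum(applyOp(L, xr) * u) - sum(xr * applyOp(L, u, adjoint = TRUE))
    expect_lt(abs(ip), 1e-10 * (1 + abs(sum(applyOp(L, xr) * u))))
  }
  # independent dense construction: diag(mask_c) %*% W_c from raw kernels
  k <- W@layers[[1]]$kern
  for (c in 1:2) {
    Wc <- denseConvMatrix(k[, , c, 1], 4, 4)
    Lc <- diag(as.vector(mask[, , c])) %*% Wc
    got <- as.vector(applyOp(L, x)[, , c])
    expect_lt(max(abs(got - Lc %*% as.vector(x))), 1e-12)
  }
})
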