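# Shared fixtures and independent oracles used across the suite. Everything
# here is built in code at test time; no stored data.

relErr <- function(a, b) {
  sqrt(sum((a - b)^2)) / max(sqrt(sum(b^2)), .Machine$double.eps)
}

# a 1x1 unit-kernel ConvOperator: the identity analysis operator
identityConvOp <- function() {
  op <- convOperator(1L, 1L, 1L, 1L, constraint = "none")
  setKernels(op, list(array(1, c(1, 1, 1, 1))))
}

# dense matrix of a linear operator on h x w images, built by probing with
# unit vectors (used to hand problems to matrix-based oracles)
denseFromOperator <- function(applyFun, h, w, mOut) {
  n <- h * w
  A <- matrix(0, mOut, n)
  for (j in seq_len(n)) {
    e <- matrix(0, h, w); e[j] <- 1
    A[, j] <- as.vector(applyFun(e))
  }
  A
}

# independent dense construction of a zero-padded "same" correlation matrix
# from an explicit kernel (direct index arithmetic, no package conv code)
denseConvMatrix <- function(kern2d, h, w) {
  ks <- nrow(kern2d); r <- (ks - 1) / 2
  A <- matrix(0, h * w, h * w)
  for (i in 1:h) for (j in 1:w) {
    row <- i + (j - 1) * h
    for (di in -r:r) for (dj in -r:r) {
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= h && jj >= 1 && jj <= w)
        A[row, ii + (jj - 1) * h] <- A[row, ii + (jj - 1) * h] +
          kern2d[di + r + 1, dj + r + 1]
    }
  }
  A
}

# ADMM oracle for prox_{gamma ||L .||_1}(z) with a dense L: an independent
# algorithm (direct linear solves + soft thresholding) run to high accuracy
admmProxOracle <- function(L, z, gamma, rho = 1, iters = 3000, tol = 1e-12) {
  n <- ncol(L)
  zv <- as.vector(z)
  M <- diag(n) + rho * crossprod(L)
  R <- chol(M)
  x <- zv
  w <- as.vector(L %*% x)
  u <- rep(0, length(w))
  soft <- function(v, t) sign(v) * pmax(abs(v) - t, 0)
  for (k in seq_len(iters)) {
    x_old <- x
    x <- backsolve(R, forwardsolve(t(R), zv + rho * crossprod(L, w - u)))
    Lx <- as.vector(L %*% x)
    w <- soft(Lx + u, gamma / rho)
    u <- u + Lx - w
    if (sqrt(sum((x - x_old)^2)) < tol * max(1, sqrt(sum(x^2))) && k > 10)
      break
  }
  x
}

# small random MMR generator with spatially varying masks (no training)
randomMMRGen <- function(channels = 4L, ks = 3L, seed = 1L) {
  mmrMaskGenerator(channels = channels, kernelSize = ks, init = "random",
                   seed = seed)
}

randomSAFIGen <- function(channels = 4L, ks = 3L, seed = 1L) {
  safiMaskGenerator(channels = channels, kernelSize = ks, init = "random",
                    seed = seed)
}
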