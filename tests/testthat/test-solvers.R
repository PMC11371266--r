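# Tolerance schedules, dual prox, FBS, objective/majorization, and the two
# refinement loops.

test_that("tolerance schedules reproduce their closed forms with continuous
           branches", {
  expect_equal(evalTolerance("denoising", 5), 1e-5)
  expect_equal(evalTolerance("denoising", 1), 1e-3 * 0.01^(1 / 5))
  expect_equal(evalTolerance("denoising", 6), 1e-5)
  # branch continuity at k_out = 5
  expect_equal(evalTolerance("denoising", 5), 1e-3 * 0.01^(5 / 5))
  # general mode: eps_FBS shares the closed form, prox scales off it
  for (k in c(1, 3, 5, 7)) {
    base <- if (k <= 5) 1e-3 * 0.01^(k / 5) else 1e-5
    expect_equal(evalTolerance("general", k, which = "fbs"), base)
    expect_equal(evalTolerance("general", k, 10), 3 * base * (1 / 9)^(10 / 50))
    # continuity at k_FBS = 50: 3 eps (1/9) = eps / 3
    expect_equal(evalTolerance("general", k, 50), base / 3)
    expect_equal(evalTolerance("general", k, 51), base / 3)
  }
  expect_identical(evalTolerance("off", 3), -1)
  expect_error(evalTolerance("denoising", 0), "kOut")
})

test_that("dual prox equals soft thresholding for the identity operator", {
  L <- onesAnalysis(identityConvOp(), c(1, 3))
  z <- matrix(c(2, -0.5, 0.1), 1, 3)
  p <- proxWeightedL1(L, z, 1, epsProx = 1e-10, Kprox = 2000)
  expect_equal(as.vector(p$x), c(1, 0, 0), tolerance = 1e-6)
  # gamma = 0 is the prox of the zero function
  expect_equal(proxWeightedL1(L, z, 0)$x, z)
  expect_error(proxWeightedL1(L, z, -1), "nonnegative")
  set.seed(1)
  z2 <- matrix(rnorm(16), 4, 4)
  L2 <- onesAnalysis(identityConvOp(), c(4, 4))
  p2 <- proxWeightedL1(L2, z2, 0.3, epsProx = 1e-10, Kprox = 2000)
  expect_lt(max(abs(p2$x - sign(z2) * pmax(abs(z2) - 0.3, 0))), 1e-6)
})

test_that("dual prox matches an ADMM oracle for random dense analysis
           operators", {
  set.seed(2)
  for (i in 1:10) {
    W <- convOperator(1, 2, 3, constraint = "zero_mean", seed = i)
    mask <- array(runif(4 * 4 * 2, 0.2, 1), c(4, 4, 2))
    L <- buildWeightedAnalysis(mask, W)
    Ld <- denseFromOperator(function(v) applyOp(L, v), 4, 4, 32)
    z <- matrix(rnorm(16), 4, 4)
    # early stopping disabled: the oracle comparison needs the fully
    # converged dual, not the scheduled approximate solve
    p <- proxWeightedL1(L, z, 0.3, epsProx = -1, Kprox = 3000)
    xo <- admmProxOracle(Ld, z, 0.3)
    expect_lt(relErr(as.vector(p$x), xo), 1e-4)
  }
})

test_that("prox optimality: subgradient sign condition holds at convergence", {
  set.seed(3)
  W <- convOperator(1, 2, 3, constraint = "zero_mean", seed = 9)
  L <- onesAnalysis(W, c(6, 6))
  z <- matrix(rnorm(36), 6, 6)
  gamma <- 0.2
  p <- proxWeightedL1(L, z, gamma, epsProx = 1e-10, Kprox = 10000)
  # z - x = L^T u with u in gamma * dsign(Lx): check componentwise
  res <- z - p$x
  backproj <- applyOp(L, p$u, adjoint = TRUE)
  expect_lt(max(abs(res - backproj)), 1e-8)
  expect_true(all(abs(p$u) <= gamma + 1e-12))
  Lx <- applyOp(L, p$x)
  nz <- abs(Lx) > 1e-4
  expect_lt(max(abs(p$u[nz] - gamma * sign(Lx[nz])), 0), 1e-4)
})

test_that("FBS with lambda = 0 and identity model returns the data in one
           step; one outer step is the exact prox", {
  H <- makeForwardModel("identity", c(8, 8))
  set.seed(4)
  y <- matrix(rnorm(64), 8, 8)
  W <- convOperator(1, 2, 3, constraint = "zero_mean", seed = 2)
  L <- onesAnalysis(W, c(8, 8))
  cfg0 <- solverConfig(0, schedule = "denoising")
  out <- fbsSolve(H, y, L, 0, matrix(5, 8, 8), cfg0, kOut = 1)
  expect_equal(out$x, y)
  expect_equal(out$iters, 1L)
  # single step from an arbitrary start equals a long, tight dual solve
  lam <- 0.15
  cfg <- solverConfig(lam, schedule = "denoising")
  one <- fbsSolve(H, y, L, lam, matrix(rnorm(64), 8, 8), cfg, kOut = 6)
  ref <- proxWeightedL1(L, y, lam, epsProx = 1e-12, Kprox = 20000)
  expect_lt(relErr(one$x, ref$x), 1e-4)
})

test_that("FBS solves a small dense inverse problem to oracle accuracy", {
  set.seed(5)
  A <- diag(4) + 0.3 * matrix(rnorm(16), 4, 4)  # well-conditioned
  H <- makeForwardModel("dense", c(2, 2), list(matrix = A))
  xTrue <- matrix(rnorm(4), 2, 2)
  y <- applyOp(H, xTrue)
  W <- convOperator(1, 2, 3, constraint = "zero_mean", seed = 3)
  L <- onesAnalysis(W, c(2, 2))
  lam <- 0.05
  cfg <- solverConfig(lam, Kfbs = 2000, Kprox = 500, schedule = "general")
  out <- fbsSolve(H, y, L, lam, matrix(0, 2, 2), cfg, kOut = 8)
  # independent objective check against a fine grid around an ADMM-type
  # solution of the equivalent matrix problem
  Ld <- denseFromOperator(function(v) applyOp(L, v), 2, 2, 8)
  obj <- function(xv) 0.5 * sum((A %*% xv - as.vector(y))^2) +
    lam * sum(abs(Ld %*% xv))
  # subgradient descent oracle from several starts
  best <- Inf
  for (s in 1:3) {
    xv <- rnorm(4)
    step <- 0.1
    for (it in 1:20000) {
      gsub <- crossprod(A, A %*% xv - as.vector(y)) +
        lam * crossprod(Ld, sign(Ld %*% xv))
      xv <- xv - step / sqrt(it) * as.vector(gsub)
      best <- min(best, obj(xv))
    }
  }
  expect_lt(obj(as.vector(out$x)), best + 1e-5)
})

test_that("majorization upper-bounds the objective and is tight at the
           anchor", {
  set.seed(6)
  g <- randomMMRGen(channels = 3, ks = 3, seed = 4)
  H <- makeForwardModel("identity", c(8, 8))
  y <- matrix(rnorm(64), 8, 8)
  lam <- 0.3
  for (i in 1:200) {
    x <- matrix(rnorm(64), 8, 8); xk <- matrix(rnorm(64), 8, 8)
    f <- objectiveMMR(x, H, y, lam, g)
    gv <- majorizationValue(x, xk, H, y, lam, g)
    expect_gte(gv, f - 1e-10)
    ft <- objectiveMMR(xk, H, y, lam, g)
    expect_lt(abs(majorizationValue(xk, xk, H, y, lam, g) - ft),
              1e-10 * (1 + abs(ft)))
  }
  # psi linear (psi' constant c): first-order bound is exact everywhere
  gLin <- g
  gLin@profiles <- rep(list(concaveProfileDeriv(rep(0.7, 21), delta = 0.05)),
                       3)
  x <- matrix(rnorm(64), 8, 8); xk <- matrix(rnorm(64), 8, 8)
  expect_equal(majorizationValue(x, xk, H, y, lam, gLin),
               objectiveMMR(x, H, y, lam, gLin), tolerance = 1e-12)
  # x = 0 objective reduces to the fidelity (psi(0) = 0)
  expect_equal(objectiveMMR(matrix(0, 8, 8), H, y, lam, g),
               0.5 * sum(y^2))
})

test_that("MMR refinement: lambda = 0 returns the least-squares solution and
           constant-psi' masks converge immediately", {
  H <- makeForwardModel("identity", c(8, 8))
  y <- makePhantom(c(8, 8), "random_ellipses", seed = 3)
  g <- randomMMRGen(channels = 3, ks = 3, seed = 5)
  out0 <- mmrReconstruct(H, y, g, solverConfig(1e-12))
  expect_lt(relErr(out0$x, y), 1e-6)
  # psi' constant 1 with circular simplex B: masks are a fixed point
  gc1 <- mmrMaskGenerator(channels = 3, kernelSize = 3,
                          padding = "circular", seed = 6)
  gc1@profiles <- rep(list(concaveProfileDeriv(rep(1, 21), delta = 0.05)), 3)
  out1 <- mmrReconstruct(H, y, gc1, solverConfig(0.02, epsOut = 1e-6),
                         keepMasks = TRUE)
  # the all-ones mask is a fixed point of the mask map, so the refinement
  # reduces to re-solving the one convex plain weighted-L1 problem
  for (m in out1$trace@masks)
    expect_lt(max(abs(maskValues(m) - 1)), 1e-12)
  L1 <- onesAnalysis(gc1@W, c(8, 8))
  ref <- proxWeightedL1(L1, y, 0.02, epsProx = -1, Kprox = 5000)
  expect_lt(relErr(out1$x, ref$x), 1e-4)
})

test_that("MMR objective trace is non-increasing on denoising instances", {
  H <- makeForwardModel("identity", c(16, 16))
  set.seed(7)
  for (i in 1:3) {
    y <- addNoise(makePhantom(c(16, 16), "random_ellipses", seed = i),
                  25 / 255, seed = 100 + i)
    g <- randomMMRGen(channels = 4, ks = 3, seed = i)
    out <- mmrReconstruct(H, y, g, solverConfig(0.05))
    f <- out$trace@f
    expect_true(all(diff(f) <= 1e-6 * (1 + abs(f[-length(f)]))))
  }
})

test_that("SAFI iterates obey the update-operator norm bound and approach a
           fixed point", {
  H <- makeForwardModel("identity", c(16, 16))
  set.seed(8)
  y <- addNoise(makePhantom(c(16, 16), "random_ellipses", seed = 9),
                25 / 255, seed = 10)
  g <- randomSAFIGen(channels = 4, ks = 3, seed = 11)
  out <- safiReconstruct(H, y, g, solverConfig(0.05, epsOut = 1e-5),
                         keepIterates = TRUE)
  normY <- sqrt(sum(y^2))
  for (k in seq_along(out$iterates)[-1]) {
    expect_lte(sqrt(sum(out$iterates[[k]]^2)), 2 * normY + 1e-8)
  }
  # one extra refinement from the converged point (at the converged stage's
  # inner tolerance) moves it very little
  Lstar <- buildWeightedAnalysis(generateMask(g, out$x), g@W, c(16, 16))
  cfg <- solverConfig(0.05, epsOut = 1e-5)
  extra <- fbsSolve(H, y, Lstar, 0.05, out$x,
                    safir:::.resolveConfig(cfg, H), kOut = 10)
  expect_lt(relErr(extra$x, out$x), 10 * 1e-5)
})

test_that("box constraint set is respected by the refinement", {
  H <- makeForwardModel("identity", c(8, 8))
  y <- matrix(rnorm(64, mean = 0.5, sd = 0.5), 8, 8)
  g <- randomMMRGen(channels = 3, ks = 3, seed = 13)
  cfg <- solverConfig(0.02, X = list(kind = "box", lo = 0, hi = 1))
  out <- mmrReconstruct(H, y, g, cfg)
  expect_true(all(out$x >= 0 & out$x <= 1))
})
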