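# Unrolled denoiser, training loss gradients, the optimizer loop, and lambda
# fine-tuning.

test_that("unrolled denoiser is the identity at lambda = 0 and bitwise
           deterministic", {
  theta <- initTheta("mmr", channels = 2, kernelSize = 3, lamInit = 0,
                     seed = 1)
  y <- addNoise(makePhantom(c(8, 8), "random_ellipses", seed = 1), 0.1,
                seed = 2)
  expect_equal(unrolledDenoise(theta, y, 3, 5), y, tolerance = 1e-12)
  theta$lambda <- 0.05
  a <- unrolledDenoise(theta, y, 4, 6)
  b <- unrolledDenoise(theta, y, 4, 6)
  expect_identical(a, b)
  expect_false(identical(a, y))
})

test_that("a single unrolled refinement with many dual steps converges to
           the plain weighted-L1 prox", {
  theta <- initTheta("mmr", channels = 2, kernelSize = 3, lamInit = 0.08,
                     seed = 3)
  y <- addNoise(makePhantom(c(12, 12), "random_ellipses", seed = 4), 0.1,
                seed = 5)
  den <- unrolledDenoise(theta, y, 1, 400)
  W <- setKernels(convOperator(1, 2, 3, constraint = "zero_mean"), theta$W)
  L <- onesAnalysis(W, c(12, 12))
  ref <- proxWeightedL1(L, y, 0.08, epsProx = 1e-12, Kprox = 20000)
  expect_lt(relErr(den, ref$x), 1e-5)
})

test_that("training loss has its closed-form trivial values", {
  theta <- initTheta("mmr", channels = 2, kernelSize = 3, lamInit = 0,
                     seed = 2)
  clean <- makePatches(3, 8, seed = 6)
  # zero noise, lambda = 0: denoiser is the identity, loss 0
  expect_equal(trainingLoss(theta, clean, clean, 2, 3)$value, 0)
  noisy <- addNoise(clean, 0.1, seed = 7)
  expect_equal(trainingLoss(theta, clean, noisy, 2, 3)$value,
               0.5 * sum((noisy - clean)^2))
})

test_that("tape gradients match central finite differences on a tiny model", {
  set.seed(42)
  theta <- initTheta("mmr", channels = 2, kernelSize = 3, lamInit = 0.05,
                     seed = 9)
  for (c in 1:2)
    theta$sigma[[c]] <- monotoneProjection(1 - cumsum(abs(rnorm(21,
                                                                sd = 0.1))))
  theta$r <- c(1.3, 0.7)
  clean <- makePatches(2, 8, seed = 3)
  noisy <- addNoise(clean, 0.1, seed = 4)
  tl <- trainingLoss(theta, clean, noisy, 3, 4, grad = TRUE)
  h <- 1e-6
  fd <- function(set) {
    (trainingLoss(set(theta, h), clean, noisy, 3, 4)$value -
       trainingLoss(set(theta, -h), clean, noisy, 3, 4)$value) / (2 * h)
  }
  checkOne <- function(gotten, setter) {
    want <- fd(setter)
    expect_lt(abs(gotten - want) / max(abs(want), 1e-8), 1e-4)
  }
  checkOne(tl$grads$lambda, function(t, e) { t$lambda <- t$lambda + e; t })
  for (idx in c(1, 5, 9, 14)) {
    checkOne(tl$grads$W[[1]][idx],
             function(t, e) { t$W[[1]][idx] <- t$W[[1]][idx] + e; t })
    checkOne(tl$grads$B[[1]][idx],
             function(t, e) { t$B[[1]][idx] <- t$B[[1]][idx] + e; t })
  }
  for (idx in c(2, 5)) {
    checkOne(tl$grads$sigma[[1]][idx],
             function(t, e) { t$sigma[[1]][idx] <- t$sigma[[1]][idx] + e; t })
  }
  checkOne(tl$grads$r[1], function(t, e) { t$r[1] <- t$r[1] + e; t })
})

test_that("gradients stay finite across random tiny-model draws (both
           schemes)", {
  clean <- makePatches(1, 8, seed = 10)
  noisy <- addNoise(clean, 0.1, seed = 11)
  set.seed(12)
  for (i in 1:100) {
    scheme <- if (i %% 2 == 0) "mmr" else "safi"
    th <- initTheta(scheme, channels = 2, kernelSize = 3,
                    lamInit = runif(1, 1e-4, 0.2), seed = i)
    if (scheme == "mmr") {
      for (c in 1:2) th$sigma[[c]] <- monotoneProjection(rnorm(21))
      th$r <- runif(2, 0.3, 2)
    } else {
      for (nm in c("phi1", "phi2", "phi3"))
        for (c in 1:2) th[[nm]][[c]] <- rnorm(21, sd = 0.3)
    }
    tl <- trainingLoss(th, clean, noisy, sample(1:3, 1), sample(1:4, 1),
                       grad = TRUE)
    expect_true(is.finite(tl$value))
    allg <- unlist(tl$grads)
    expect_true(all(is.finite(allg)))
  }
})

test_that("training is reproducible and preserves parameter constraints at
           every step", {
  cfg <- trainingConfig("mmr", patchSize = 8L, nPatches = 64L,
                        batchSize = 16L, epochs = 1L, channels = 2L,
                        kernelSize = 3L, valImages = 2L, maxSteps = 4L,
                        seed = 5L)
  ck1 <- trainDenoiser(config = cfg)
  ck2 <- trainDenoiser(config = cfg)
  expect_identical(ck1$theta, ck2$theta)
  expect_identical(ck1$history$loss, ck2$history$loss)
  th <- ck1$theta
  expect_lt(max(abs(apply(th$W[[1]], c(3, 4), sum))), 1e-9)
  expect_true(all(th$B[[1]] >= 0))
  expect_lt(max(abs(apply(th$B[[1]], c(3, 4), sum) - 1)), 1e-9)
  for (c in seq_along(th$sigma)) {
    expect_identical(th$sigma[[c]][1], 1)
    expect_true(all(diff(th$sigma[[c]]) <= 1e-12))
  }
  # the optimizer actually moved the parameters
  th0 <- initTheta("mmr", 2L, 3L, 1L, cfg$lamInit, seed = cfg$seed)
  expect_false(identical(th$W, th0$W))
})

test_that("lambda tuning selects sensible values coarse-to-fine", {
  # single candidate grid
  W <- convOperator(1, 2, 3, constraint = "zero_mean", seed = 2)
  H <- makeForwardModel("identity", c(16, 16))
  refs <- lapply(1:2, function(i)
    makePhantom(c(16, 16), "random_ellipses", seed = i))
  l1rec <- function(y, lam) l1Reconstruct(H, y, W, lam,
                                          solverConfig(lam, Kout = 4))$x
  lamOne <- tuneLambda(l1rec, H, refs, refs, grid = 0.07, refine = FALSE)
  expect_equal(as.numeric(lamOne), 0.07)
  # noiseless validation data: less regularization cannot hurt fidelity
  grid <- c(0.001, 0.01, 0.1)
  lam <- tuneLambda(l1rec, H, refs, refs, grid, refine = FALSE)
  expect_equal(as.numeric(lam), 0.001)
  # coarse-to-fine lands within one fine step of an exhaustive search
  ys <- lapply(refs, function(r) addNoise(r, 25 / 255, seed = 31))
  coarse <- exp(seq(log(0.005), log(0.3), length.out = 4))
  lamCF <- tuneLambda(l1rec, H, ys, refs, coarse)
  dense <- exp(seq(log(0.005), log(0.3), length.out = 25))
  scores <- vapply(dense, function(l)
    mean(mapply(function(y, r) psnr(l1rec(y, l), r), ys, refs)), numeric(1))
  lamBest <- dense[which.max(scores)]
  expect_lt(abs(log(as.numeric(lamCF)) - log(lamBest)), log(dense[2] / dense[1]) * 4)
  expect_error(tuneLambda(l1rec, H, ys, refs, numeric(0)), "empty")
})
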