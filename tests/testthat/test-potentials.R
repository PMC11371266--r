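# Linear splines, clipping, the monotone projection, and the concave
# potentials psi / psi'.

test_that("linear spline interpolates knots exactly and extrapolates with the
           boundary slope", {
  s <- linearSpline(c(0, 1, 0), M = 1, delta = 1)
  expect_equal(evalLinearSpline(s, 0), 1)
  expect_equal(evalLinearSpline(s, 0.5), 0.5)
  expect_equal(evalLinearSpline(s, 2), -1)   # right slope d3 - d2 = -1
  expect_equal(evalLinearSpline(s, -2), -1)  # left slope by symmetry
  # exact at every knot for a random spline
  set.seed(2)
  d <- rnorm(9)
  s2 <- linearSpline(d, M = 4, delta = 0.25)
  expect_equal(evalLinearSpline(s2, seq(-1, 1, by = 0.25)), d)
})

test_that("clipInterval clamps, is idempotent and 1-Lipschitz", {
  expect_equal(clipInterval(-0.3, 0, 1), 0)
  expect_equal(clipInterval(0.4, 0, 1), 0.4)
  expect_equal(clipInterval(2, 0, 1), 1)
  expect_error(clipInterval(1, 2, 1), "empty")
  set.seed(3)
  v <- rnorm(1000, sd = 2)
  w <- rnorm(1000, sd = 2)
  cv <- clipInterval(v, -1, 1)
  expect_equal(clipInterval(cv, -1, 1), cv)
  expect_true(all(abs(cv - clipInterval(w, -1, 1)) <= abs(v - w) + 1e-15))
})

test_that("monotone projection matches hand calculations and its invariants", {
  expect_equal(monotoneProjection(c(5, 5, 5)), c(1, 1, 1))
  expect_equal(monotoneProjection(c(1, 0.5, 0.8)), c(1, 0.5, 0.5))
  expect_equal(monotoneProjection(c(5, -2, 7)), c(1, -6, -6))
  set.seed(4)
  for (i in 1:10000) {
    d <- rnorm(sample(2:8, 1), sd = 3)
    p <- monotoneProjection(d)
    expect_identical(p[1], 1)
    expect_true(all(diff(p) <= 0))
    expect_equal(monotoneProjection(p), p)
  }
})

test_that("psi' is clipped, non-increasing, and equals 1 at the origin", {
  p <- concaveProfileDeriv(c(1, -1), delta = 1)
  expect_equal(evalPsiPrime(p, 0), 1)
  expect_equal(evalPsiPrime(p, 0.25), 0.5)
  expect_equal(evalPsiPrime(p, 0.75), 0)
  expect_error(evalPsiPrime(p, -0.1), "nonnegative")
  set.seed(5)
  for (i in 1:100) {
    prof <- concaveProfileDeriv(rnorm(21, sd = 1), r = runif(1, 0.2, 3),
                                delta = 0.05)
    x <- sort(abs(rnorm(100, sd = 1)))
    v <- evalPsiPrime(prof, x)
    expect_true(all(v >= 0 & v <= 1))
    expect_true(all(diff(v) <= 1e-12))
    expect_equal(evalPsiPrime(prof, 0), 1)
  }
})

test_that("psi is the exact antiderivative: nonnegative, concave,
           and consistent with psi' by finite differences", {
  # constant integrand: psi(x) = x
  pOne <- concaveProfileDeriv(rep(1, 5), delta = 0.5)
  xs <- c(0, 0.3, 1, 2.7)
  expect_equal(evalPsi(pOne, xs), xs)
  # hand-integrated example: psi(1) = int_0^0.5 (1 - 2t) dt = 0.25
  p <- concaveProfileDeriv(c(1, -1), delta = 1)
  expect_equal(evalPsi(p, 1), 0.25)
  expect_equal(evalPsi(p, 0), 0)

  set.seed(6)
  for (i in 1:50) {
    prof <- concaveProfileDeriv(rnorm(21, sd = 0.8), r = runif(1, 0.3, 2),
                                delta = 0.05)
    x1 <- abs(rnorm(50)); x2 <- abs(rnorm(50)); a <- runif(50)
    # concavity (with sign convention psi concave increasing)
    lhs <- evalPsi(prof, a * x1 + (1 - a) * x2)
    rhs <- a * evalPsi(prof, x1) + (1 - a) * evalPsi(prof, x2)
    expect_true(all(lhs >= rhs - 1e-10))
    expect_true(all(evalPsi(prof, x1) >= 0))
    # derivative check away from kink points (knots and clip crossings)
    grid <- prof@sigma@delta / prof@r
    xs <- seq(0.013, 1.51, by = 0.037)
    dist <- abs(xs / grid - round(xs / grid))
    xs <- xs[dist * grid > 1e-3]
    h <- 1e-7
    fd <- (evalPsi(prof, xs + h) - evalPsi(prof, xs - h)) / (2 * h)
    dv <- evalPsiPrime(prof, xs)
    keep <- abs(dv) > 1e-8 & dv < 1 - 1e-8 & dv > 1e-8  # off the clip kinks
    expect_lt(max(abs(fd[keep] - dv[keep]), 0), 1e-6)
  }
})

test_that("sigmoid splines map through the logistic function into (0, 1)", {
  s0 <- sigmoidSpline(rep(0, 21), M = 10, delta = 0.1)
  expect_equal(evalSigmoidSpline(s0, c(-5, 0, 17)), rep(0.5, 3))
  # spline value ln 3 -> 0.75, -ln 3 -> 0.25
  sc <- sigmoidSpline(rep(log(3), 5), M = 2, delta = 0.5)
  expect_equal(evalSigmoidSpline(sc, 0.3), 0.75)
  sc2 <- sigmoidSpline(rep(-log(3), 5), M = 2, delta = 0.5)
  expect_equal(evalSigmoidSpline(sc2, -1.2), 0.25)
  set.seed(7)
  s <- sigmoidSpline(rnorm(21, sd = 2), M = 10, delta = 0.1)
  v <- evalSigmoidSpline(s, runif(200, -1, 1))
  expect_true(all(v > 0 & v < 1))
})
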