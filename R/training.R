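# Reduced-scale unrolled training of the denoisers and lambda fine-tuning.
# The denoiser D^{n1,1,n3} is the reconstruction scheme run for n1 outer
# refinements with a single FBS step and n3 dual prox iterations each, all
# tolerances disabled; training differentiates through every unrolled step
# with the reverse-mode tape in autodiff.R.

#' Training configuration
#'
#' Defaults follow the denoising training protocol at reduced scale: Adam with
#' learning rate 1e-3 dropped by 0.1 at epochs 5 and 10, batches of 128
#' patches reconstructed for a single `(n1, n3)` pair drawn uniformly from
#' `{4,5,6} x {1,...,10}` per batch, lambda initialized at 1e-4, and the
#' reduced model geometry (8 channels, one 5x5 layer, 16x16 patches). The
#' full-scale geometry (64 channels, two 7x7 layers, 40x40 patches) remains
#' configurable through the same fields.
#'
#' @param scheme `"mmr"` or `"safi"`.
#' @param sigma noise standard deviation (training noise level).
#' @param patchSize patch side length in pixels.
#' @param nPatches number of training patches.
#' @param batchSize patches per stochastic gradient step.
#' @param lr Adam learning rate.
#' @param epochs training epochs.
#' @param lrDropEpochs epochs at whose start the learning rate is multiplied
#'   by 0.1.
#' @param n1Range,n3Range unrolling depths sampled per batch.
#' @param channels,kernelSize,nLayers model geometry.
#' @param lamInit initial regularization strength.
#' @param valImages held-out validation patches for the per-epoch model
#'   selection.
#' @param maxSteps optional cap on the total number of optimizer steps.
#' @param seed RNG seed controlling initialization, shuffling and `(n1, n3)`
#'   draws.
#' @return a named list of settings for [trainDenoiser()].
#' @export
trainingConfig <- function(scheme = c("mmr", "safi"), sigma = 25 / 255,
                           patchSize = 16L, nPatches = 2000L,
                           batchSize = 128L, lr = 1e-3, epochs = 2L,
                           lrDropEpochs = c(5L, 10L), n1Range = 4:6,
                           n3Range = 1:10, channels = 8L, kernelSize = 5L,
                           nLayers = 1L, lamInit = 1e-4, valImages = 5L,
                           maxSteps = Inf, seed = 1L) {
  scheme <- match.arg(scheme)
  stopifnot(sigma > 0, nPatches >= 1, batchSize >= 1, epochs >= 1)
  list(scheme = scheme, sigma = sigma, patchSize = as.integer(patchSize),
       nPatches = as.integer(nPatches), batchSize = as.integer(batchSize),
       lr = lr, epochs = as.integer(epochs),
       lrDropEpochs = as.integer(lrDropEpochs), n1Range = as.integer(n1Range),
       n3Range = as.integer(n3Range), channels = as.integer(channels),
       kernelSize = as.integer(kernelSize), nLayers = as.integer(nLayers),
       lamInit = lamInit, valImages = as.integer(valImages),
       maxSteps = maxSteps, seed = as.integer(seed))
}

## ---- parameter container ---------------------------------------------------

#' Initialize learnable parameters
#'
#' Kernels are drawn uniformly in `[-1/sqrt(fan_in), 1/sqrt(fan_in)]` and
#' projected onto their constraint sets (analysis filters zero-mean, MMR
#' mixing kernels on the simplex). Spline coefficients start at zero — for the
#' MMR profiles this means sigma = (1, 0, ..., 0) on the half grid (M = 20,
#' step 0.05) with unit scales r, and for SAFI all activations are zero (M =
#' 10, step 0.1), so the initial masks equal 0.5 everywhere. Lambda starts at
#' `lamInit`.
#'
#' @param scheme `"mmr"` or `"safi"`.
#' @param channels,kernelSize,nLayers model geometry.
#' @param lamInit initial lambda.
#' @param seed RNG seed.
#' @return a parameter list (`theta`) consumed by [unrolledDenoise()],
#'   [trainingLoss()] and [thetaToGenerator()].
#' @export
initTheta <- function(scheme = c("mmr", "safi"), channels = 8L,
                      kernelSize = 5L, nLayers = 1L, lamInit = 1e-4,
                      seed = 1L) {
  scheme <- match.arg(scheme)
  getK <- function(op) lapply(op@layers, `[[`, "kern")
  W <- convOperator(1L, channels, kernelSize, nLayers, groups = 1L,
                    constraint = "zero_mean", seed = seed)
  th <- list(scheme = scheme, channels = as.integer(channels),
             kernelSize = as.integer(kernelSize),
             nLayers = as.integer(nLayers), W = getK(W), lambda = lamInit)
  if (scheme == "mmr") {
    B <- convOperator(channels, channels, kernelSize, nLayers,
                      groups = channels, constraint = "simplex",
                      seed = seed + 1L)
    th$B <- getK(B)
    th$M <- 20L; th$delta <- 0.05
    th$sigma <- rep(list(c(1, rep(0, th$M))), channels)
    th$r <- rep(1, channels)
  } else {
    th$Wt <- getK(convOperator(1L, channels, kernelSize, 1L,
                               constraint = "zero_mean", seed = seed + 1L))
    th$Bt <- getK(convOperator(channels, channels, kernelSize, 1L,
                               constraint = "none", seed = seed + 2L))
    th$Bh <- getK(convOperator(channels, channels, kernelSize, 1L,
                               constraint = "none", seed = seed + 3L))
    th$M <- 10L; th$delta <- 0.1
    zero <- rep(list(rep(0, 2L * th$M + 1L)), channels)
    th$phi1 <- zero; th$phi2 <- zero; th$phi3 <- zero
  }
  th
}

#' Convert a parameter list to a mask generator
#'
#' Builds the S4 mask generator holding the same kernels, spline coefficients
#' and scales as `theta` (with the constraint projections re-applied), for use
#' with the evaluation-mode solvers [mmrReconstruct()] / [safiReconstruct()].
#'
#' @param theta a parameter list from [initTheta()] or [trainDenoiser()].
#' @return an [MMRMaskGenerator] or [SAFIMaskGenerator].
#' @export
thetaToGenerator <- function(theta) {
  C <- theta$channels; ks <- theta$kernelSize; S <- theta$nLayers
  W <- setKernels(convOperator(1L, C, ks, S, constraint = "zero_mean"),
                  theta$W)
  if (theta$scheme == "mmr") {
    B <- setKernels(convOperator(C, C, ks, S, groups = C,
                                 constraint = "simplex"), theta$B)
    profiles <- lapply(seq_len(C), function(c)
      concaveProfileDeriv(theta$sigma[[c]], r = abs(theta$r[c]),
                          delta = theta$delta))
    new("MMRMaskGenerator", W = W, B = B, profiles = profiles)
  } else {
    Wt <- setKernels(convOperator(1L, C, ks, 1L, constraint = "zero_mean"),
                     theta$Wt)
    Bt <- setKernels(convOperator(C, C, ks, 1L), theta$Bt)
    Bh <- setKernels(convOperator(C, C, ks, 1L), theta$Bh)
    phi1 <- lapply(theta$phi1, linearSpline, M = theta$M, delta = theta$delta)
    phi2 <- lapply(theta$phi2, linearSpline, M = theta$M, delta = theta$delta)
    phi3 <- lapply(theta$phi3, sigmoidSpline, M = theta$M,
                   delta = theta$delta)
    new("SAFIMaskGenerator", W = W, Wt = Wt, Bt = Bt, Bh = Bh,
        phi1 = phi1, phi2 = phi2, phi3 = phi3)
  }
}

# per-layer conv metadata for a stack with given first-layer input channels
.stackMetas <- function(C, ks, S, G, CinFirst, B) {
  lapply(seq_len(S), function(l) {
    Cin <- if (l == 1L) CinFirst else C
    Gl <- if (Cin %% G == 0L) G else 1L
    list(ks = ks, Cin = Cin, Cout = C, G = Gl, B = B, pad = 0L)
  })
}

.tpStack <- function(tp, x, kernIds, metas, adjoint = FALSE) {
  idx <- if (adjoint) rev(seq_along(kernIds)) else seq_along(kernIds)
  for (l in idx) x <- .tpConv(tp, x, kernIds[[l]], metas[[l]], adjoint)
  x
}

# register all theta leaves as tape parameters; returns node-id structure
.registerTheta <- function(tp, theta) {
  reg <- function(x) .tpParam(tp, x)
  thN <- list(W = lapply(theta$W, reg), lambda = reg(theta$lambda))
  if (theta$scheme == "mmr") {
    thN$B <- lapply(theta$B, reg)
    thN$sigma <- lapply(theta$sigma, reg)
    thN$r <- lapply(seq_along(theta$r), function(c) reg(theta$r[c]))
  } else {
    thN$Wt <- lapply(theta$Wt, reg)
    thN$Bt <- lapply(theta$Bt, reg)
    thN$Bh <- lapply(theta$Bh, reg)
    thN$phi1 <- lapply(theta$phi1, reg)
    thN$phi2 <- lapply(theta$phi2, reg)
    thN$phi3 <- lapply(theta$phi3, reg)
  }
  thN
}

# mask subgraph: MMR Lambda = B^T clip01(sigma_c(r_c * (B |W x|)))
.maskTapeMMR <- function(tp, thN, theta, xId, B) {
  C <- theta$channels; ks <- theta$kernelSize; S <- theta$nLayers
  mW <- .stackMetas(C, ks, S, 1L, 1L, B)
  mB <- .stackMetas(C, ks, S, C, C, B)
  wx <- .tpStack(tp, xId, thN$W, mW)
  ba <- .tpStack(tp, .tpAbs(tp, wx), thN$B, mB)
  chans <- lapply(seq_len(C), function(ch) {
    sl <- .tpSliceCh(tp, ba, ch, C, B)
    sc <- .tpMul(tp, sl, .tpAbs(tp, thN$r[[ch]]))
    sp <- .tpSpline(tp, sc, thN$sigma[[ch]], 0, theta$delta)
    .tpClip(tp, sp, 0, 1)
  })
  s <- .tpCatCh(tp, chans, C, B)
  .tpStack(tp, s, thN$B, mB, adjoint = TRUE)
}

# mask subgraph: SAFI Lambda = sigmoid(spline3(Bh spline2(Bt spline1(Wt x))))
.maskTapeSAFI <- function(tp, thN, theta, xId, B) {
  C <- theta$channels; ks <- theta$kernelSize
  m1 <- .stackMetas(C, ks, 1L, 1L, 1L, B)
  mC <- .stackMetas(C, ks, 1L, 1L, C, B)
  t0 <- -theta$M * theta$delta
  perCh <- function(h, knots, sigmoid = FALSE) {
    chans <- lapply(seq_len(C), function(ch) {
      sl <- .tpSliceCh(tp, h, ch, C, B)
      sp <- .tpSpline(tp, sl, knots[[ch]], t0, theta$delta)
      if (sigmoid) .tpSigmoid(tp, sp) else sp
    })
    .tpCatCh(tp, chans, C, B)
  }
  h <- .tpStack(tp, xId, thN$Wt, m1)
  h <- perCh(h, thN$phi1)
  h <- .tpStack(tp, h, thN$Bt, mC)
  h <- perCh(h, thN$phi2)
  h <- .tpStack(tp, h, thN$Bh, mC)
  perCh(h, thN$phi3, sigmoid = TRUE)
}

# differentiable upper bound on ||W||_2^2 via a fixed-depth power iteration
.sqnormWTape <- function(tp, thN, theta, shape, iters = 12L) {
  C <- theta$channels; ks <- theta$kernelSize; S <- theta$nLayers
  mW1 <- .stackMetas(C, ks, S, 1L, 1L, 1L)
  h <- shape[1]; w <- shape[2]
  probe <- array(sin(seq_len(h * w)) + 0.1 * cos(3 * seq_len(h * w)),
                 dim = c(h, w, 1L))
  probe <- probe / sqrt(sum(probe^2))
  b <- .tpConst(tp, probe)
  a <- b
  for (i in seq_len(iters)) {
    a <- .tpStack(tp, .tpStack(tp, b, thN$W, mW1), thN$W, mW1, adjoint = TRUE)
    nrm <- .tpSqrt(tp, .tpSqnorm(tp, a))
    b <- .tpMul(tp, a, .tpInv(tp, nrm))
  }
  a <- .tpStack(tp, .tpStack(tp, b, thN$W, mW1), thN$W, mW1, adjoint = TRUE)
  .tpSqrt(tp, .tpSqnorm(tp, a))
}

# The unrolled denoising graph D^{n1, 1, n3}(y): n1 outer refinements, each a
# single FBS step (exact for the identity model: the gradient step lands on y)
# followed by n3 accelerated dual prox iterations, warm-started at u = L y;
# masks are regenerated from each new iterate. The dual step size uses the
# differentiable bound ||L||^2 <= max(Lambda)^2 ||W||^2 with a 1.01 safety
# factor.
.unrolledTape <- function(tp, thN, theta, yId, n1, n3, B) {
  C <- theta$channels; ks <- theta$kernelSize; S <- theta$nLayers
  yv <- .tpVal(tp, yId)
  shape <- dim(yv)[1:2]
  mW <- .stackMetas(C, ks, S, 1L, 1L, B)
  gamma <- .tpAbs(tp, thN$lambda)  # alpha = 1/||H||^2 = 1 for denoising
  sW <- .sqnormWTape(tp, thN, theta, shape)
  Wy <- .tpStack(tp, yId, thN$W, mW)
  maskId <- .tpConst(tp, array(1, dim = c(shape, C * B)))
  maskFn <- if (theta$scheme == "mmr") .maskTapeMMR else .maskTapeSAFI
  xId <- NULL
  for (k in seq_len(n1)) {
    m2 <- .tpMax(tp, .tpMul(tp, maskId, maskId))
    alphaD <- .tpInv(tp, .tpScale(tp, .tpMul(tp, m2, sW), 1.01))
    u <- v <- .tpMul(tp, maskId, Wy)
    t <- 1
    for (j in seq_len(n3)) {
      Ltv <- .tpStack(tp, .tpMul(tp, maskId, v), thN$W, mW, adjoint = TRUE)
      r <- .tpSub(tp, Ltv, yId)
      gstep <- .tpMul(tp, maskId, .tpStack(tp, r, thN$W, mW))
      uNew <- .tpClipSym(tp, .tpSub(tp, v, .tpMul(tp, gstep, alphaD)), gamma)
      tNew <- (j + 5) / 3
      cm <- (t - 1) / tNew
      v <- if (cm == 0) uNew else
        .tpSub(tp, .tpScale(tp, uNew, 1 + cm), .tpScale(tp, u, cm))
      u <- uNew; t <- tNew
    }
    xId <- .tpSub(tp, yId,
                  .tpStack(tp, .tpMul(tp, maskId, u), thN$W, mW,
                           adjoint = TRUE))
    if (k < n1) maskId <- maskFn(tp, thN, theta, xId, B)
  }
  xId
}

.asBatch <- function(x) {
  if (is.matrix(x)) array(x, dim = c(dim(x), 1L)) else x
}

#' Unrolled denoiser
#'
#' Applies the reconstruction scheme as a fixed differentiable computation:
#' `n1` outer refinements, one FBS step each (exact for denoising), `n3` dual
#' prox iterations, tolerances disabled. Deterministic given
#' `(theta, y, n1, n3)`; repeated calls return bitwise-identical output. With
#' `lambda = 0` the denoiser is the identity.
#'
#' @param theta parameter list (see [initTheta()]).
#' @param y noisy image matrix, or an `(H, W, B)` array batch.
#' @param n1 outer refinements (>= 1).
#' @param n3 dual prox iterations per refinement (>= 1).
#' @return denoised image (matrix) or batch (array), matching `y`.
#' @export
unrolledDenoise <- function(theta, y, n1, n3) {
  stopifnot(n1 >= 1, n3 >= 1)
  yb <- .asBatch(y)
  B <- dim(yb)[3]
  tp <- .tpNew()
  thN <- .registerTheta(tp, theta)
  yId <- .tpConst(tp, yb)
  xId <- .unrolledTape(tp, thN, theta, yId, n1, n3, B)
  out <- .tpVal(tp, xId)
  if (is.matrix(y)) out[, , 1] else out
}

# map tape gradients back onto the theta structure (zeros when unused)
.gradsToTheta <- function(theta, thN, grads) {
  pick <- function(id, proto) {
    g <- grads[[id]]
    if (is.null(g)) array(0, dim = dim(proto) %||% length(proto)) else g
  }
  out <- list(W = lapply(seq_along(thN$W), function(l)
    pick(thN$W[[l]], theta$W[[l]])),
    lambda = as.numeric(pick(thN$lambda, theta$lambda)))
  if (theta$scheme == "mmr") {
    out$B <- lapply(seq_along(thN$B), function(l)
      pick(thN$B[[l]], theta$B[[l]]))
    out$sigma <- lapply(seq_along(thN$sigma), function(c)
      as.numeric(pick(thN$sigma[[c]], theta$sigma[[c]])))
    out$r <- vapply(seq_along(thN$r), function(c)
      as.numeric(pick(thN$r[[c]], theta$r[c])), numeric(1))
  } else {
    for (nm in c("Wt", "Bt", "Bh")) {
      out[[nm]] <- lapply(seq_along(thN[[nm]]), function(l)
        pick(thN[[nm]][[l]], theta[[nm]][[l]]))
    }
    for (nm in c("phi1", "phi2", "phi3")) {
      out[[nm]] <- lapply(seq_along(thN[[nm]]), function(c)
        as.numeric(pick(thN[[nm]][[c]], theta[[nm]][[c]])))
    }
  }
  out
}

#' Unrolled training loss (and gradient)
#'
#' The empirical risk contribution `0.5 * sum_m ||D(noisy_m) - clean_m||^2`
#' of a batch for one `(n1, n3)` draw. With `grad = TRUE` the reverse-mode
#' tape also returns the exact gradient of the loss with respect to every
#' parameter in `theta` (structured like `theta`).
#'
#' @param theta parameter list.
#' @param clean,noisy matching image matrices or `(H, W, B)` batches.
#' @param n1,n3 unrolling depths.
#' @param grad also compute gradients.
#' @return list with `value` and (if requested) `grads`.
#' @export
trainingLoss <- function(theta, clean, noisy, n1, n3, grad = FALSE) {
  cb <- .asBatch(clean); nb <- .asBatch(noisy)
  stopifnot(all(dim(cb) == dim(nb)))
  B <- dim(nb)[3]
  tp <- .tpNew()
  thN <- .registerTheta(tp, theta)
  yId <- .tpConst(tp, nb)
  xId <- .unrolledTape(tp, thN, theta, yId, n1, n3, B)
  lossId <- .tpScale(tp, .tpSqnorm(tp, .tpSub(tp, xId, .tpConst(tp, cb))),
                     0.5)
  value <- as.numeric(.tpVal(tp, lossId))
  if (!is.finite(value)) stop("non-finite training loss")
  if (!grad) return(list(value = value))
  grads <- .tpBackward(tp, lossId)
  list(value = value, grads = .gradsToTheta(theta, thN, grads))
}

## ---- optimizer -------------------------------------------------------------

.projectTheta <- function(theta) {
  theta$W <- lapply(theta$W, projectZeroMean)
  if (theta$scheme == "mmr") {
    theta$B <- lapply(theta$B, projectSimplex)
    theta$sigma <- lapply(theta$sigma, monotoneProjection)
  } else {
    theta$Wt <- lapply(theta$Wt, projectZeroMean)
  }
  theta
}

.adamLeafNames <- function(theta) {
  nm <- c("W", "lambda")
  if (theta$scheme == "mmr") nm <- c(nm, "B", "sigma", "r")
  else nm <- c(nm, "Wt", "Bt", "Bh", "phi1", "phi2", "phi3")
  nm
}

# one Adam update of the (possibly nested) numeric fields named in leafNames
.adamStep <- function(theta, grads, state, lr, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  corr <- sqrt(1 - b2^state$t) / (1 - b1^state$t)
  upd <- function(x, g, key) {
    m <- state$m[[key]]; v <- state$v[[key]]
    if (is.null(m)) { m <- 0 * g; v <- 0 * g }
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    state$m[[key]] <<- m
    state$v[[key]] <<- v
    x - lr * corr * m / (sqrt(v) + eps)
  }
  for (nm in .adamLeafNames(theta)) {
    if (is.list(theta[[nm]])) {
      for (l in seq_along(theta[[nm]])) {
        theta[[nm]][[l]] <- upd(theta[[nm]][[l]], grads[[nm]][[l]],
                                paste0(nm, l))
      }
    } else {
      theta[[nm]] <- upd(theta[[nm]], grads[[nm]], nm)
    }
  }
  list(theta = theta, state = state)
}

#' Train a denoiser by unrolled stochastic optimization
#'
#' Minimizes the empirical risk over batches with Adam, drawing a fresh
#' `(n1, n3)` pair uniformly for every batch (a regularizing randomization of
#' the unrolling depth). After every step the constraint projections are
#' re-applied (zero-mean analysis kernels, simplex mixing kernels,
#' non-increasing profile knots starting at 1), so the feasibility invariants
#' hold exactly throughout training. After each epoch the model is evaluated
#' (PSNR of the deepest unrolled configuration) on held-out validation
#' patches, and the best-epoch parameters are returned. Fully reproducible
#' under a fixed seed.
#'
#' @param patches optional list with `clean` and `noisy` arrays
#'   `(size, size, n)`; generated from the config when `NULL`.
#' @param config a [trainingConfig()] list.
#' @return a checkpoint list with elements `theta` (best parameters), `scheme`,
#'   `sigma`, `history` (per-step losses, per-epoch validation PSNR), and
#'   `config`.
#' @export
trainDenoiser <- function(patches = NULL, config = trainingConfig()) {
  if (is.null(patches))
    patches <- patchSet(config$nPatches, config$patchSize, config$sigma,
                        config$seed + 17L)
  nTot <- dim(patches$clean)[3]
  theta <- initTheta(config$scheme, config$channels, config$kernelSize,
                     config$nLayers, config$lamInit, seed = config$seed)
  val <- patchSet(config$valImages, config$patchSize, config$sigma,
                  config$seed + 900001L)
  state <- new.env(parent = emptyenv())
  state$m <- list(); state$v <- list(); state$t <- 0L
  lr <- config$lr
  losses <- numeric(0)
  valPsnr <- numeric(0)
  best <- list(psnr = -Inf, theta = theta)
  set.seed(config$seed + 31L)
  nB <- max(1L, nTot %/% config$batchSize)
  step <- 0L
  for (ep in seq_len(config$epochs)) {
    if (ep %in% config$lrDropEpochs) lr <- lr * 0.1
    perm <- sample.int(nTot)
    for (bi in seq_len(nB)) {
      if (step >= config$maxSteps) break
      take <- perm[((bi - 1L) * config$batchSize + 1L):
                     min(bi * config$batchSize, nTot)]
      n1 <- sample(config$n1Range, 1L)
      n3 <- sample(config$n3Range, 1L)
      tl <- trainingLoss(theta, patches$clean[, , take, drop = FALSE],
                         patches$noisy[, , take, drop = FALSE],
                         n1, n3, grad = TRUE)
      if (!is.finite(tl$value))
        stop("non-finite loss at step ", step, " (n1 = ", n1, ", n3 = ", n3,
             ")")
      losses <- c(losses, tl$value / length(take))
      ad <- .adamStep(theta, tl$grads, state, lr)
      theta <- .projectTheta(ad$theta)
      step <- step + 1L
    }
    den <- unrolledDenoise(theta, val$noisy, max(config$n1Range),
                           max(config$n3Range))
    vp <- mean(vapply(seq_len(dim(den)[3]), function(i)
      psnr(den[, , i], val$clean[, , i]), numeric(1)))
    valPsnr <- c(valPsnr, vp)
    if (vp > best$psnr) best <- list(psnr = vp, theta = theta)
    if (step >= config$maxSteps) break
  }
  list(theta = best$theta, scheme = config$scheme, sigma = config$sigma,
       history = list(loss = losses, valPsnr = valPsnr, steps = step),
       config = config)
}

## ---- lambda fine-tuning ----------------------------------------------------

#' Plain L1-analysis reconstruction (all-ones mask baseline)
#'
#' Solves the single convex problem
#' `argmin 0.5 ||Hx - y||^2 + lambda ||W x||_1` (unweighted masks) by the same
#' nested solver, iterated to the outer tolerance. This is the non-adaptive
#' baseline that the mask-refinement schemes extend.
#'
#' @param H a [ForwardModel].
#' @param y measurements.
#' @param W analysis [ConvOperator].
#' @param lam regularization strength.
#' @param config a [SolverConfig]; `lam` is overridden by the `lam` argument.
#' @return list with `x` and the number of outer iterations used.
#' @export
l1Reconstruct <- function(H, y, W, lam, config = solverConfig(lam)) {
  config <- .resolveConfig(config, H)
  L <- onesAnalysis(W, H@shape)
  x <- matrix(0, H@shape[1], H@shape[2])
  iters <- 0L
  for (k in seq_len(config@Kout)) {
    fb <- fbsSolve(H, y, L, lam, x, config, kOut = k)
    e <- .relErr(fb$x, x)
    x <- fb$x
    iters <- k
    if (e < config@epsOut) break
  }
  list(x = x, iters = iters)
}

#' Fine-tune the regularization strength by coarse-to-fine grid search
#'
#' Evaluates the mean validation PSNR of the full fixed-point reconstruction
#' for every candidate lambda on the coarse grid, then refines once with a
#' 5-point geometric grid between the neighbors of the coarse argmax, and
#' returns the best lambda. This adapts a denoising-trained model to a new
#' forward operator without retraining.
#'
#' @param obj either a parameter list / checkpoint (`theta`) or a function
#'   `function(y, lam)` returning a reconstruction.
#' @param H a [ForwardModel].
#' @param ys list of validation measurements.
#' @param refs list of matching ground-truth images.
#' @param grid positive candidate lambdas (coarse grid).
#' @param Kout outer refinement cap for the evaluations.
#' @param refine perform the 5-point refinement pass (default TRUE).
#' @return the selected lambda, with the evaluated grids and scores attached
#'   as attribute `"search"`.
#' @export
tuneLambda <- function(obj, H, ys, refs, grid, Kout = 10L, refine = TRUE) {
  if (length(grid) == 0) stop("empty lambda grid")
  if (length(ys) == 0) stop("empty validation set")
  recon <- if (is.function(obj)) {
    function(y, lam) obj(y, lam)
  } else {
    gen <- thetaToGenerator(obj$theta %||% obj)
    fn <- if ((obj$scheme %||% obj$theta$scheme %||% "mmr") == "safi" ||
              is(gen, "SAFIMaskGenerator")) safiReconstruct else mmrReconstruct
    function(y, lam) fn(H, y, gen, solverConfig(lam, Kout = Kout))$x
  }
  score <- function(lam) {
    mean(vapply(seq_along(ys), function(i)
      psnr(recon(ys[[i]], lam), refs[[i]]), numeric(1)))
  }
  grid <- sort(grid)
  coarse <- vapply(grid, score, numeric(1))
  iBest <- which.max(coarse)
  lamBest <- grid[iBest]
  scoreBest <- coarse[iBest]
  fine <- numeric(0); fineScores <- numeric(0)
  if (refine && length(grid) > 1L) {
    lo <- if (iBest > 1L) grid[iBest - 1L] else grid[iBest] / 2
    hi <- if (iBest < length(grid)) grid[iBest + 1L] else grid[iBest] * 2
    fine <- exp(seq(log(lo), log(hi), length.out = 5L))
    fineScores <- vapply(fine, score, numeric(1))
    if (max(fineScores) > scoreBest) {
      lamBest <- fine[which.max(fineScores)]
      scoreBest <- max(fineScores)
    }
  }
  structure(lamBest, search = list(grid = grid, scores = coarse,
                                   fine = fine, fineScores = fineScores))
}
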