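# Attentive mask generators: the MMR masks Lambda_c(x) = B_c^T psi'_c(B_c
# |W_c x|) and the SAFI three-layer convolutional mask network.

#' Create an MMR mask generator
#'
#' Assembles the analysis stack W (zero-mean kernels), the depthwise simplex
#' mixing stack B, and one concave-potential derivative per channel. With
#' `init = "default"` the spline coefficients follow the training
#' initialization (sigma = 1 at the origin knot, zero elsewhere, scales r = 1),
#' which makes the initial masks close to constant. With `init = "random"` the
#' profiles are drawn with random decay rates so the masks vary spatially
#' without any training, which is useful for studying the solver itself.
#'
#' @param channels number of analysis channels N_C.
#' @param kernelSize odd kernel size.
#' @param nLayers stacked convolution layers S per operator.
#' @param M,delta grid of the profile splines (defaults 20 and 0.05).
#' @param init `"default"` (training initialization) or `"random"`.
#' @param padding convolution padding for W and B.
#' @param seed RNG seed for kernels and random profiles.
#' @return an [MMRMaskGenerator].
#' @export
mmrMaskGenerator <- function(channels = 8L, kernelSize = 5L, nLayers = 1L,
                             M = 20L, delta = 0.05,
                             init = c("default", "random"),
                             padding = c("zero", "circular"), seed = 1L) {
  init <- match.arg(init)
  padding <- match.arg(padding)
  W <- convOperator(1L, channels, kernelSize, nLayers, groups = 1L,
                    constraint = "zero_mean", padding = padding, seed = seed)
  B <- convOperator(channels, channels, kernelSize, nLayers,
                    groups = channels, constraint = "simplex",
                    padding = padding, seed = seed + 1L)
  set.seed(seed + 2L)
  profiles <- vector("list", channels)
  for (c in seq_len(channels)) {
    if (init == "default") {
      d <- c(1, rep(0, M))
      r <- 1
    } else {
      # random decay: sigma falls from 1 to 0 somewhere inside the grid
      tau <- runif(1, 0.5, 2) / (M * delta)
      d <- 1 - tau * seq(0, M * delta, by = delta) +
        rnorm(M + 1L, sd = 0.05)
      r <- runif(1, 0.5, 2)
    }
    profiles[[c]] <- concaveProfileDeriv(d, r = r, delta = delta)
  }
  new("MMRMaskGenerator", W = W, B = B, profiles = profiles)
}

#' Create a SAFI mask generator
#'
#' Assembles the analysis stack W and the three-layer mask network (Wt, Bt,
#' Bh with spline activations phi1, phi2 and sigmoid-spline outputs phi3).
#' With `init = "default"` all spline coefficients are zero, so every mask
#' entry equals 0.5 and the first problem is a uniformly weighted L1-analysis
#' problem. `init = "random"` draws small random spline coefficients.
#'
#' @param channels number of analysis channels N_C.
#' @param kernelSize odd kernel size.
#' @param nLayers stacked layers S for the analysis operator W.
#' @param M,delta grid of the activation splines (defaults 10 and 0.1).
#' @param init `"default"` or `"random"`.
#' @param padding convolution padding.
#' @param seed RNG seed.
#' @return a [SAFIMaskGenerator].
#' @export
safiMaskGenerator <- function(channels = 8L, kernelSize = 5L, nLayers = 1L,
                              M = 10L, delta = 0.1,
                              init = c("default", "random"),
                              padding = c("zero", "circular"), seed = 1L) {
  init <- match.arg(init)
  padding <- match.arg(padding)
  W <- convOperator(1L, channels, kernelSize, nLayers, groups = 1L,
                    constraint = "zero_mean", padding = padding, seed = seed)
  Wt <- convOperator(1L, channels, kernelSize, 1L, groups = 1L,
                     constraint = "zero_mean", padding = padding,
                     seed = seed + 1L)
  Bt <- convOperator(channels, channels, kernelSize, 1L, groups = 1L,
                     constraint = "none", padding = padding, seed = seed + 2L)
  Bh <- convOperator(channels, channels, kernelSize, 1L, groups = 1L,
                     constraint = "none", padding = padding, seed = seed + 3L)
  set.seed(seed + 4L)
  mk <- function(random) {
    lapply(seq_len(channels), function(c) {
      d <- if (random) rnorm(2L * M + 1L, sd = 0.3) else rep(0, 2L * M + 1L)
      linearSpline(d, M, delta)
    })
  }
  phi1 <- mk(init == "random")
  phi2 <- mk(init == "random")
  phi3 <- lapply(seq_len(channels), function(c) {
    d <- if (init == "random") rnorm(2L * M + 1L, sd = 0.3) else
      rep(0, 2L * M + 1L)
    sigmoidSpline(d, M, delta)
  })
  new("SAFIMaskGenerator", W = W, Wt = Wt, Bt = Bt, Bh = Bh,
      phi1 = phi1, phi2 = phi2, phi3 = phi3)
}

setMethod("nChannels", "MMRMaskGenerator", function(object)
  object@W@channels)
setMethod("nChannels", "SAFIMaskGenerator", function(object)
  object@W@channels)

# per-channel pointwise map over an (H, W, C) field
.perChannel <- function(a, fns, eval1) {
  out <- a
  for (c in seq_len(dim(a)[3])) out[, , c] <- eval1(fns[[c]], a[, , c])
  out
}

#' @describeIn generateMask MMR masks `B_c^T psi'_c(B_c |W_c x|)`; entries are
#'   nonnegative and bounded by the column sums of B (at most 1 up to padding
#'   slack since psi' <= 1).
setMethod("generateMask", "MMRMaskGenerator", function(object, x) {
  wx <- applyOp(object@W, x)
  ba <- .convStack(object@B, abs(wx))
  s <- .perChannel(ba, object@profiles, evalPsiPrime)
  maskField(.convStack(object@B, s, adjoint = TRUE))
})

#' @describeIn generateMask SAFI masks
#'   `phi3_c(Bh_c phi2(Bt phi1(Wt x)))`; entries are strictly inside (0, 1).
setMethod("generateMask", "SAFIMaskGenerator", function(object, x) {
  h <- applyOp(object@Wt, x)
  h <- .perChannel(h, object@phi1, evalLinearSpline)
  h <- .convStack(object@Bt, h)
  h <- .perChannel(h, object@phi2, evalLinearSpline)
  h <- .convStack(object@Bh, h)
  maskField(.perChannel(h, object@phi3, evalSigmoidSpline))
})

#' MMR mask (functional form)
#'
#' @param g an [MMRMaskGenerator].
#' @param x image matrix.
#' @return a [MaskField] with nonnegative entries.
#' @export
mmrMask <- function(g, x) generateMask(g, x)

#' SAFI mask (functional form)
#'
#' @param g a [SAFIMaskGenerator].
#' @param x image matrix.
#' @return a [MaskField] with entries in (0, 1).
#' @export
safiMask <- function(g, x) generateMask(g, x)

setMethod("show", "MMRMaskGenerator", function(object) {
  cat(sprintf("MMRMaskGenerator: %d channels, %dx%d kernels, %d layer(s)\n",
              object@W@channels, object@W@kernelSize, object@W@kernelSize,
              length(object@W@layers)))
})
setMethod("show", "SAFIMaskGenerator", function(object) {
  cat(sprintf("SAFIMaskGenerator: %d channels, %dx%d kernels\n",
              object@W@channels, object@W@kernelSize, object@W@kernelSize))
})
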