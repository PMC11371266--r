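# Forward measurement models, constrained convolution stacks, the weighted
# analysis operator, and spectral-norm estimation.

## ---- kernel constraint projections ----------------------------------------

#' Project kernels onto the zero-mean set
#'
#' Subtracts the mean from every 2-D kernel: `w -> w - (1^T w) / ks^2`. For a
#' 4-D kernel bank the projection is applied to each `(ks, ks)` slice.
#' Idempotent; the analysis filters W are kept in this set after every training
#' step.
#'
#' @param kernel numeric vector, matrix, or 4-D kernel bank.
#' @return the projected object, same shape.
#' @export
projectZeroMean <- function(kernel) {
  if (length(kernel) == 0L) stop("kernel must be nonempty")
  d <- dim(kernel)
  if (is.null(d) || length(d) <= 2L) return(kernel - mean(kernel))
  m <- apply(kernel, c(3, 4), mean)
  sweep_arr <- aperm(array(m, dim = c(d[3], d[4], d[1], d[2])), c(3, 4, 1, 2))
  kernel - sweep_arr
}

#' Project kernels onto the probability simplex (by magnitude normalization)
#'
#' Maps `b -> |b| / (1^T |b|)`: entrywise nonnegative and summing to one, the
#' constraint on the mixing kernels B of the MMR mask generator. For a 4-D bank
#' each `(ks, ks)` kernel is normalized separately. An all-zero kernel has no
#' direction and raises an error.
#'
#' @param kernel numeric vector, matrix, or 4-D kernel bank.
#' @return the projected object, same shape.
#' @export
projectSimplex <- function(kernel) {
  d <- dim(kernel)
  if (is.null(d) || length(d) <= 2L) {
    s <- sum(abs(kernel))
    if (s == 0) stop("invalid kernel: all entries are zero")
    return(abs(kernel) / s)
  }
  s <- apply(abs(kernel), c(3, 4), sum)
  if (any(s == 0)) stop("invalid kernel: all entries are zero")
  sweep_arr <- aperm(array(s, dim = c(d[3], d[4], d[1], d[2])), c(3, 4, 1, 2))
  abs(kernel) / sweep_arr
}

.applyConstraint <- function(kern, constraint) {
  switch(constraint,
    zero_mean = projectZeroMean(kern),
    simplex = projectSimplex(kern),
    none = kern,
    stop("unknown kernel constraint: ", constraint))
}

## ---- convolution stacks ----------------------------------------------------

#' Create a stacked constrained convolution operator
#'
#' Builds `nLayers` grouped "same" 2-D convolutions with `channels` output
#' channels each. Kernels are initialized uniformly in
#' `[-1/sqrt(fan_in), 1/sqrt(fan_in)]` from `seed` and then projected onto the
#' constraint set. The first layer maps `channelsIn` channels to `channels`
#' (with group count 1 whenever `channelsIn` is not divisible by `groups`);
#' subsequent layers map `channels` to `channels` with group count `groups`.
#'
#' @param channelsIn input channel count of the stack (1 for an image).
#' @param channels output channel count N_C.
#' @param kernelSize odd spatial kernel size.
#' @param nLayers number of stacked convolution layers S.
#' @param groups group count G; `G = channels` is depthwise, `G = 1` mixes all
#'   channels.
#' @param constraint `"zero_mean"`, `"simplex"`, or `"none"`.
#' @param padding `"zero"` (default) or `"circular"`.
#' @param seed RNG seed for the kernel initialization.
#' @return a [ConvOperator].
#' @export
convOperator <- function(channelsIn = 1L, channels = 8L, kernelSize = 5L,
                         nLayers = 1L, groups = 1L,
                         constraint = c("none", "zero_mean", "simplex"),
                         padding = c("zero", "circular"), seed = 1L) {
  constraint <- match.arg(constraint)
  padding <- match.arg(padding)
  channelsIn <- as.integer(channelsIn); channels <- as.integer(channels)
  kernelSize <- as.integer(kernelSize); nLayers <- as.integer(nLayers)
  groups <- as.integer(groups)
  if (kernelSize %% 2L != 1L) stop("kernelSize must be odd")
  if (channels %% groups != 0L) stop("channels must be divisible by groups")
  set.seed(seed)
  layers <- vector("list", nLayers)
  for (l in seq_len(nLayers)) {
    Cin <- if (l == 1L) channelsIn else channels
    G <- if (Cin %% groups == 0L) groups else 1L
    fanIn <- kernelSize^2 * (Cin %/% G)
    kern <- array(runif(kernelSize^2 * channels * (Cin %/% G),
                        -1 / sqrt(fanIn), 1 / sqrt(fanIn)),
                  dim = c(kernelSize, kernelSize, channels, Cin %/% G))
    kern <- .applyConstraint(kern, constraint)
    layers[[l]] <- list(kern = kern, Cin = Cin, Cout = channels, G = G)
  }
  new("ConvOperator", layers = layers, channelsIn = channelsIn,
      channels = channels, kernelSize = kernelSize, groups = groups,
      constraint = constraint, padding = padding)
}

#' Replace the kernels of a convolution stack
#'
#' Installs new kernel banks (one 4-D array per layer), re-applying the
#' operator's constraint projection so the validity invariants hold exactly.
#'
#' @param op a [ConvOperator].
#' @param kernels list of kernel banks, one per layer.
#' @return the updated [ConvOperator].
#' @export
setKernels <- function(op, kernels) {
  stopifnot(length(kernels) == length(op@layers))
  for (l in seq_along(kernels)) {
    k <- kernels[[l]]
    stopifnot(all(dim(k) == dim(op@layers[[l]]$kern)))
    op@layers[[l]]$kern <- .applyConstraint(k, op@constraint)
  }
  validObject(op)
  op
}

# Internal: run a batched field (H, W, C*B) through the stack.
# x: 3-d array with C*B slices; forward maps channelsIn -> channels,
# adjoint maps channels -> channelsIn (layers in reverse order).
.convStack <- function(op, x, adjoint = FALSE, B = 1L) {
  pad <- if (op@padding == "zero") 0L else 1L
  ks <- op@kernelSize
  layers <- if (adjoint) rev(op@layers) else op@layers
  for (ly in layers) {
    x <- cpp_conv2d(x, ly$kern, ks, ly$Cin, ly$Cout, ly$G, as.integer(B),
                    pad, adjoint)
  }
  x
}

.asField <- function(x) {
  if (is.matrix(x)) array(x, dim = c(dim(x), 1L)) else x
}

# collapse a single-channel (H, W, 1) field to a matrix without dropping
# spatial dimensions of extent one
.asImage <- function(a) {
  matrix(a[, , 1L], dim(a)[1], dim(a)[2])
}

#' @describeIn applyOp stacked convolution: image matrix (or single-channel
#'   array) to an `(H, W, C)` coefficient array; adjoint maps coefficients
#'   back to the image domain.
setMethod("applyOp", "ConvOperator", function(object, x, adjoint = FALSE) {
  x <- .asField(x)
  nc <- dim(x)[3]
  want <- if (adjoint) object@channels else object@channelsIn
  if (nc != want)
    stop("channel mismatch: got ", nc, ", operator expects ", want)
  out <- .convStack(object, x, adjoint = adjoint, B = 1L)
  if (adjoint && object@channelsIn == 1L) .asImage(out) else out
})

setMethod("nChannels", "ConvOperator", function(object) object@channels)

setMethod("show", "ConvOperator", function(object) {
  cat(sprintf(
    "ConvOperator: %d layer(s), %d -> %d channels, %dx%d kernels, G = %d\n",
    length(object@layers), object@channelsIn, object@channels,
    object@kernelSize, object@kernelSize, object@groups))
  cat(sprintf("  constraint: %s, padding: %s\n", object@constraint,
              object@padding))
})

## ---- spectral norm ---------------------------------------------------------

#' Estimate the squared spectral norm of a linear operator pair
#'
#' Power iteration on `A^T A` for an operator given by matching apply/adjoint
#' closures. Used to form the step sizes `1/||H||_2^2` and `1/||L||_2^2` of
#' the forward-backward solvers; callers multiply the estimate by a 1.01
#' safety factor so steps never exceed the admissible range.
#'
#' @param apply function mapping an image-domain object forward.
#' @param adjoint function mapping the output-domain object back.
#' @param shape integer (height, width) of the image domain.
#' @param iters maximum power iterations.
#' @param tol relative change tolerance on the estimate.
#' @param seed seed for the random start probe.
#' @param warmStart optional start vector (matrix) from a previous call.
#' @return the squared spectral norm estimate, with the final probe attached
#'   as attribute `"vector"` for warm-starting.
#' @export
estimateSqSpectralNorm <- function(apply, adjoint, shape, iters = 100L,
                                   tol = 1e-6, seed = 1L, warmStart = NULL) {
  if (is.null(warmStart)) {
    set.seed(seed)
    b <- matrix(rnorm(prod(shape)), shape[1], shape[2])
  } else {
    b <- warmStart
  }
  b <- b / sqrt(sum(b^2))
  est <- 0
  for (i in seq_len(iters)) {
    a <- adjoint(apply(b))
    nrm <- sqrt(sum(a^2))
    if (!is.finite(nrm)) stop("non-finite values in power iteration")
    if (nrm == 0) { est <- 0; break }
    estNew <- nrm  # ||A^T A b|| with ||b|| = 1 -> largest eigenvalue of A^T A
    b <- a / nrm
    if (i > 1L && abs(estNew - est) <= tol * max(estNew, .Machine$double.eps)) {
      est <- estNew
      break
    }
    est <- estNew
  }
  structure(est, vector = b)
}

## ---- forward models --------------------------------------------------------

#' Create a forward measurement model
#'
#' @param kind `"identity"` (denoising), `"masked_fourier"` (column-
#'   undersampled unitary 2-D Fourier transform, the single-coil MRI model), or
#'   `"dense"` (explicit matrix).
#' @param shape integer (height, width) of the image domain.
#' @param params for `"masked_fourier"`: `Macc` (acceleration factor, >= 1) and
#'   optional `centerFraction` (fraction of width always kept as a contiguous
#'   center block, default 0.08) or `keptCols` (explicit column indices); for
#'   `"dense"`: `matrix`.
#' @param seed seed for the random k-space column selection.
#' @return a [ForwardModel].
#' @details The masked Fourier model keeps `floor(width / Macc)` columns of
#'   the unitary 2-D Fourier transform (a contiguous centered block plus
#'   uniformly drawn remaining columns); measurements are represented as a
#'   full-size complex matrix with the unsampled columns zeroed. The adjoint
#'   zero-fills, applies the inverse unitary transform, and takes the real
#'   part. Spectral data: identity and masked Fourier have unit squared
#'   spectral norm (the rows are orthonormal); dense models use an exact SVD.
#' @export
makeForwardModel <- function(kind = c("identity", "masked_fourier", "dense"),
                             shape, params = list(), seed = 1L) {
  kind <- match.arg(kind)
  shape <- as.integer(shape)
  if (kind == "identity") {
    return(new("IdentityModel", shape = shape, sqSpectralNorm = 1,
               sigmaMin = 1))
  }
  if (kind == "dense") {
    A <- params$matrix
    if (is.null(A)) stop("dense model needs params$matrix")
    if (ncol(A) != prod(shape)) stop("matrix columns must match image size")
    sv <- svd(A, nu = 0, nv = 0)$d
    smin <- if (nrow(A) >= ncol(A)) min(sv) else NA_real_
    return(new("DenseModel", shape = shape, matrix = A,
               sqSpectralNorm = max(sv)^2, sigmaMin = smin))
  }
  Macc <- params$Macc
  if (is.null(Macc)) stop("masked_fourier model needs params$Macc")
  if (Macc > shape[2]) stop("Macc exceeds image width")
  if (!is.null(params$keptCols)) {
    # explicit indices, already in the unshifted transform ordering
    kept <- sort(as.integer(params$keptCols))
  } else {
    cf <- if (is.null(params$centerFraction)) 0.08 else params$centerFraction
    mask <- makeKspaceMask(shape, Macc, cf, seed)
    kept <- sort(.ifftshiftCols(which(mask[1, ] > 0), shape[2]))
  }
  smin <- if (length(kept) == shape[2]) 1 else NA_real_
  kept <- as.integer(kept)
  new("MaskedFourierModel", shape = shape, keptCols = kept,
      Macc = as.numeric(Macc), sqSpectralNorm = 1, sigmaMin = smin)
}

setMethod("sqSpectralNorm", "ForwardModel", function(object)
  object@sqSpectralNorm)
setMethod("sigmaMin", "ForwardModel", function(object) object@sigmaMin)
setMethod("sqSpectralNorm", "AnalysisOperator", function(object)
  object@sqnorm)

.checkImage <- function(model, x) {
  if (!is.matrix(x) || !all(dim(x) == model@shape))
    stop("image shape mismatch: expected ", paste(model@shape, collapse = "x"))
}

#' @describeIn applyOp identity model: returns `x` unchanged.
setMethod("applyOp", "IdentityModel", function(object, x, adjoint = FALSE) {
  .checkImage(object, x)
  x
})

#' @describeIn applyOp dense model: `H vec(x)` (vector), adjoint maps a
#'   measurement vector back to an image matrix.
setMethod("applyOp", "DenseModel", function(object, x, adjoint = FALSE) {
  if (adjoint) {
    if (length(x) != nrow(object@matrix)) stop("measurement length mismatch")
    matrix(crossprod(object@matrix, as.vector(x)), object@shape[1],
           object@shape[2])
  } else {
    .checkImage(object, x)
    as.vector(object@matrix %*% as.vector(x))
  }
})

#' @describeIn applyOp masked Fourier model: unitary 2-D FFT with unsampled
#'   columns zeroed (complex matrix); adjoint zero-fills, inverse-transforms
#'   and takes the real part.
setMethod("applyOp", "MaskedFourierModel", function(object, x,
                                                    adjoint = FALSE) {
  n <- prod(object@shape)
  if (adjoint) {
    if (!all(dim(x) == object@shape)) stop("measurement shape mismatch")
    z <- matrix(0 + 0i, object@shape[1], object@shape[2])
    z[, object@keptCols] <- x[, object@keptCols]
    Re(fft(z, inverse = TRUE)) / sqrt(n)
  } else {
    .checkImage(object, x)
    y <- fft(x) / sqrt(n)
    drop <- setdiff(seq_len(object@shape[2]), object@keptCols)
    y[, drop] <- 0 + 0i
    y
  }
})

setMethod("show", "ForwardModel", function(object) {
  cat(sprintf("%s on %dx%d images, ||H||^2 = %.4g, sigma_min = %s\n",
              class(object), object@shape[1], object@shape[2],
              object@sqSpectralNorm,
              ifelse(is.na(object@sigmaMin), "undefined",
                     format(object@sigmaMin))))
})

#' Apply a forward model (functional form)
#'
#' Thin wrapper over [applyOp()] matching the measurement-operator contract:
#' linear in `x`, with `adjoint = TRUE` applying the transpose.
#'
#' @inheritParams applyOp
#' @param model a [ForwardModel].
#' @return see [applyOp()].
#' @export
applyForward <- function(model, x, adjoint = FALSE)
  applyOp(model, x, adjoint)

## ---- weighted analysis operator -------------------------------------------

#' Mask field constructor
#'
#' @param values `(H, W, C)` array of nonnegative weights, or a matrix for a
#'   single channel.
#' @return a [MaskField].
#' @export
maskField <- function(values) {
  new("MaskField", values = .asField(values))
}

setMethod("maskValues", "MaskField", function(object) object@values)
setMethod("nChannels", "MaskField", function(object) dim(object@values)[3])
setMethod("show", "MaskField", function(object) {
  v <- object@values
  cat(sprintf("MaskField: %dx%d pixels, %d channels, range [%.4g, %.4g]\n",
              dim(v)[1], dim(v)[2], dim(v)[3], min(v), max(v)))
})

#' Build a weighted analysis operator
#'
#' Combines an analysis stack W with a mask field Lambda into the operator
#' `L x = (Lambda_c * (W_c x))_c` whose L1 norm is the spatially re-weighted
#' penalty of one refinement step. With an all-ones mask, L coincides with W
#' exactly. The squared spectral norm is estimated at construction and cached.
#'
#' @param mask a [MaskField] (or `(H, W, C)` array) of weights; must match the
#'   channel count of `W`.
#' @param W the analysis [ConvOperator].
#' @param shape image (height, width); defaults to the mask's spatial size.
#' @return an [AnalysisOperator].
#' @export
buildWeightedAnalysis <- function(mask, W, shape = NULL) {
  if (!is(mask, "MaskField")) mask <- maskField(mask)
  if (nChannels(mask) != W@channels)
    stop("mask channels (", nChannels(mask), ") must match operator channels (",
         W@channels, ")")
  if (is.null(shape)) shape <- dim(mask@values)[1:2]
  mv <- mask@values
  sq <- estimateSqSpectralNorm(
    function(x) mv * .convStack(W, .asField(x)),
    function(u) .asImage(.convStack(W, mv * u, adjoint = TRUE)),
    shape, seed = 7L)
  new("AnalysisOperator", base = W, weights = mask,
      sqnorm = as.numeric(sq))
}

#' All-ones analysis operator
#'
#' The unweighted operator `L = W` used in the first refinement step.
#'
#' @param W the analysis [ConvOperator].
#' @param shape image (height, width).
#' @return an [AnalysisOperator] with unit weights.
#' @export
onesAnalysis <- function(W, shape) {
  buildWeightedAnalysis(array(1, dim = c(shape, W@channels)), W, shape)
}

#' @describeIn applyOp weighted analysis operator: channel c of the output is
#'   `Lambda_c * (W_c x)`; the adjoint is `sum_c W_c^T (Lambda_c * u_c)`.
setMethod("applyOp", "AnalysisOperator", function(object, x, adjoint = FALSE) {
  mv <- object@weights@values
  if (adjoint) {
    if (!all(dim(x) == dim(mv))) stop("coefficient/mask shape mismatch")
    .asImage(.convStack(object@base, mv * x, adjoint = TRUE))
  } else {
    mv * .convStack(object@base, .asField(x))
  }
})

#' Weighted analysis apply (functional form)
#'
#' @inheritParams applyOp
#' @param L an [AnalysisOperator].
#' @return see [applyOp()].
#' @export
weightedAnalysisApply <- function(L, x, adjoint = FALSE) applyOp(L, x, adjoint)

setMethod("show", "AnalysisOperator", function(object) {
  cat(sprintf("AnalysisOperator: %d channels, ||L||^2 ~ %.4g\n",
              object@base@channels, object@sqnorm))
})
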