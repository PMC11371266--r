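# S4 classes for the operator algebra, the spline nonlinearities, and the
# mask generators. Validity methods enforce the structural invariants that the
# solvers rely on (kernel constraints, mask ranges, spline shapes).

#' @title Forward measurement models
#'
#' @description Virtual parent of the linear measurement operators H in the
#' inverse problem y = Hx + n. Concrete models are created with
#' [makeForwardModel()]: `IdentityModel` (denoising), `DenseModel` (an explicit
#' matrix), and `MaskedFourierModel` (column-undersampled unitary Fourier
#' transform, the single-coil MRI model).
#'
#' @slot shape integer vector (height, width) of the image domain.
#' @slot sqSpectralNorm squared spectral norm of H, used for step sizes.
#' @slot sigmaMin smallest singular value of H, or `NA_real_` when H is not
#'   invertible.
#' @name ForwardModel-class
#' @aliases ForwardModel
#' @exportClass ForwardModel
setClass("ForwardModel", representation("VIRTUAL",
  shape = "integer",
  sqSpectralNorm = "numeric",
  sigmaMin = "numeric"
))

#' @rdname ForwardModel-class
#' @exportClass IdentityModel
setClass("IdentityModel", contains = "ForwardModel")

#' @rdname ForwardModel-class
#' @slot matrix the dense measurement matrix (rows = measurements).
#' @exportClass DenseModel
setClass("DenseModel", contains = "ForwardModel",
  representation(matrix = "matrix"))

#' @rdname ForwardModel-class
#' @slot keptCols integer indices of the k-space columns that are sampled.
#' @slot Macc acceleration factor (columns kept proportional to 1/Macc).
#' @exportClass MaskedFourierModel
setClass("MaskedFourierModel", contains = "ForwardModel",
  representation(keptCols = "integer", Macc = "numeric"))

#' Stacked constrained convolution operator
#'
#' A composition of `nLayers` grouped "same" 2-D convolutions, the building
#' block of the analysis operator W, the nonnegative mixing operator B of the
#' MMR mask generator, and the layers of the SAFI mask network. Kernels can be
#' constrained to zero mean (analysis filters) or to the probability simplex
#' (nonnegative, sum one; row-normalized mixing).
#'
#' @slot layers list of layers; each layer is a list with elements `kern`
#'   (array `ks x ks x Cout x Cin/G`), `Cin`, `Cout`, `G`.
#' @slot channelsIn number of input channels of the stack.
#' @slot channels number of output channels.
#' @slot kernelSize odd spatial kernel size.
#' @slot groups group count G (G = channels is depthwise, G = 1 dense mixing).
#' @slot constraint one of `"zero_mean"`, `"simplex"`, `"none"`.
#' @slot padding one of `"zero"`, `"circular"`.
#' @exportClass ConvOperator
setClass("ConvOperator", representation(
  layers = "list",
  channelsIn = "integer",
  channels = "integer",
  kernelSize = "integer",
  groups = "integer",
  constraint = "character",
  padding = "character"
))

setValidity("ConvOperator", function(object) {
  for (ly in object@layers) {
    k <- ly$kern
    if (!all(is.finite(k))) return("non-finite kernel coefficients")
    if (object@constraint == "zero_mean") {
      s <- apply(k, c(3, 4), sum)
      if (any(abs(s) > 1e-9)) return("zero_mean kernels must sum to 0")
    } else if (object@constraint == "simplex") {
      if (any(k < 0)) return("simplex kernels must be nonnegative")
      s <- apply(k, c(3, 4), sum)
      if (any(abs(s - 1) > 1e-9)) return("simplex kernels must sum to 1")
    }
  }
  TRUE
})

#' Per-channel, per-pixel regularization weights
#'
#' Holds the mask field Lambda with one nonnegative weight per analysis channel
#' and pixel. MMR masks are nonnegative; SAFI masks additionally lie in [0, 1].
#'
#' @slot values array (height, width, channels) of weights.
#' @exportClass MaskField
setClass("MaskField", representation(values = "array"))

setValidity("MaskField", function(object) {
  v <- object@values
  if (length(dim(v)) != 3L) return("mask values must be a 3-d array")
  if (!all(is.finite(v))) return("mask values must be finite")
  if (any(v < 0)) return("mask values must be nonnegative")
  TRUE
})

#' Weighted analysis operator
#'
#' The linear operator L x = (Lambda_c * (W_c x))_c obtained by weighting each
#' channel of a convolutional analysis stack with a mask field. Its squared
#' spectral norm is estimated once at construction (power iteration) and cached
#' for the dual prox step size.
#'
#' @slot base the [ConvOperator] analysis stack W.
#' @slot weights the [MaskField] Lambda.
#' @slot sqnorm cached squared spectral norm estimate of L.
#' @exportClass AnalysisOperator
setClass("AnalysisOperator", representation(
  base = "ConvOperator",
  weights = "MaskField",
  sqnorm = "numeric"
))

#' Linear splines and shape-constrained nonlinearities
#'
#' `LinearSpline` is a degree-one spline on the uniform symmetric grid
#' `{-M*delta, ..., M*delta}` with `2M+1` knot values, extrapolated linearly
#' with the boundary-segment slope. `HalfLineSpline` lives on the nonnegative
#' half grid `{0, ..., M*delta}` with `M+1` knot values.
#'
#' @slot M half-grid count.
#' @slot delta positive grid step.
#' @slot d knot values.
#' @name splines
#' @aliases LinearSpline-class LinearSpline HalfLineSpline-class HalfLineSpline
#' @exportClass LinearSpline
setClass("LinearSpline", representation(M = "integer", delta = "numeric",
  d = "numeric"))

setValidity("LinearSpline", function(object) {
  if (object@delta <= 0) return("delta must be positive")
  if (length(object@d) != 2L * object@M + 1L) return("need 2M+1 knot values")
  if (!all(is.finite(object@d))) return("knot values must be finite")
  TRUE
})

#' @rdname splines
#' @exportClass HalfLineSpline
setClass("HalfLineSpline", representation(M = "integer", delta = "numeric",
  d = "numeric"))

setValidity("HalfLineSpline", function(object) {
  if (object@delta <= 0) return("delta must be positive")
  if (length(object@d) != object@M + 1L) return("need M+1 knot values")
  if (!all(is.finite(object@d))) return("knot values must be finite")
  TRUE
})

#' Derivative of a learned concave potential
#'
#' Parameterizes psi'(x) = clip_[0,1](sigma(r x)) with a non-increasing
#' half-line spline sigma satisfying sigma(0) = 1 and a positive scale r. The
#' antiderivative psi (with psi(0) = 0) is piecewise quadratic, nonnegative,
#' non-decreasing and concave; see [evalPsi()].
#'
#' @slot sigma a [HalfLineSpline] with non-increasing knots starting at 1.
#' @slot r positive scale applied to the argument.
#' @slot tab cached breakpoint table of the clipped integrand (built at
#'   construction; used by [evalPsi()]).
#' @exportClass ConcaveProfileDeriv
setClass("ConcaveProfileDeriv", representation(sigma = "HalfLineSpline",
  r = "numeric", tab = "list"))

setValidity("ConcaveProfileDeriv", function(object) {
  d <- object@sigma@d
  if (abs(d[1] - 1) > 1e-9) return("sigma(0) must equal 1")
  if (any(diff(d) > 1e-9)) return("sigma knots must be non-increasing")
  if (object@r <= 0) return("scale r must be positive")
  TRUE
})

#' Sigmoid-composed linear spline
#'
#' The output nonlinearity of the SAFI mask network: a logistic function
#' applied to a linear-spline value, so the result always lies in (0, 1).
#'
#' @slot spline the inner [LinearSpline].
#' @exportClass SigmoidSpline
setClass("SigmoidSpline", representation(spline = "LinearSpline"))

#' MMR mask generator
#'
#' Generates masks Lambda_c(x) = B_c^T psi'_c(B_c |W_c x|): the analysis stack
#' W (zero-mean kernels), a depthwise nonnegative mixing stack B (simplex
#' kernels), and one concave-potential derivative per channel.
#'
#' @slot W zero-mean [ConvOperator] (analysis filters).
#' @slot B simplex-constrained depthwise [ConvOperator].
#' @slot profiles list of [ConcaveProfileDeriv], one per channel.
#' @exportClass MMRMaskGenerator
setClass("MMRMaskGenerator", representation(W = "ConvOperator",
  B = "ConvOperator", profiles = "list"))

setValidity("MMRMaskGenerator", function(object) {
  if (object@B@constraint != "simplex") return("B must be simplex-constrained")
  if (length(object@profiles) != object@W@channels)
    return("need one concave profile per channel")
  TRUE
})

#' SAFI mask generator
#'
#' The three-layer convolutional mask network
#' `Lambda_c(x) = phi3_c(Bh_c phi2(Bt phi1(Wt x)))` whose outputs lie in
#' (0, 1). Spline activations are shared across all pixels of a channel.
#'
#' @slot W zero-mean [ConvOperator]: the analysis filters that the masks weight.
#' @slot Wt first mask-network layer (image to channels).
#' @slot Bt second layer (channels to channels).
#' @slot Bh third layer (channels to channels, one row block per channel).
#' @slot phi1,phi2 lists of [LinearSpline] activations, one per channel.
#' @slot phi3 list of [SigmoidSpline] output activations, one per channel.
#' @exportClass SAFIMaskGenerator
setClass("SAFIMaskGenerator", representation(W = "ConvOperator",
  Wt = "ConvOperator", Bt = "ConvOperator", Bh = "ConvOperator",
  phi1 = "list", phi2 = "list", phi3 = "list"))

setValidity("SAFIMaskGenerator", function(object) {
  nc <- object@W@channels
  if (length(object@phi1) != nc || length(object@phi2) != nc ||
      length(object@phi3) != nc)
    return("need one spline per channel in every activation layer")
  TRUE
})

#' Solver configuration
#'
#' Iteration caps, tolerances and constraint set for the nested solvers. The
#' tolerance schedule modes are `"denoising"` (identity forward model, inner
#' FBS capped at one step), `"general"` (arbitrary H), and `"off"` (the
#' training sentinel -1: never stop early, always run the iteration caps).
#'
#' @slot lam regularization strength lambda (> 0 for reconstruction).
#' @slot Kout outer refinement cap.
#' @slot Kfbs inner FBS cap (1 for identity H, 1000 otherwise).
#' @slot Kprox dual prox iteration cap.
#' @slot epsOut outer relative-change tolerance.
#' @slot schedule tolerance schedule mode.
#' @slot X constraint set: `list(kind = "all_space")` or
#'   `list(kind = "box", lo =, hi =)`.
#' @exportClass SolverConfig
setClass("SolverConfig", representation(
  lam = "numeric", Kout = "integer", Kfbs = "integer", Kprox = "integer",
  epsOut = "numeric", schedule = "character", X = "list"
))

setValidity("SolverConfig", function(object) {
  if (object@lam < 0) return("lambda must be nonnegative")
  if (object@Kout < 1L || object@Kfbs < 1L || object@Kprox < 1L)
    return("iteration caps must be >= 1")
  if (!object@schedule %in% c("auto", "denoising", "general", "off"))
    return("unknown tolerance schedule mode")
  TRUE
})

#' Per-iteration solve record
#'
#' Records, for each outer refinement k, the relative error
#' `e_k = ||x_{k+1} - x_k|| / ||x_k||`, the objective value, and the iteration
#' counts spent in the inner solvers. Optionally stores mask snapshots.
#'
#' @slot e relative errors per outer iteration.
#' @slot f objective values per outer iteration.
#' @slot iterations list of per-stage iteration counts.
#' @slot masks optional list of mask snapshots.
#' @exportClass SolveTrace
setClass("SolveTrace", representation(e = "numeric", f = "numeric",
  iterations = "list", masks = "list"))
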