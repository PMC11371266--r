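# Generics shared across operator and mask classes.

#' Apply a linear operator or its adjoint
#'
#' Applies a [ForwardModel], [ConvOperator] or [AnalysisOperator] to an image
#' (or, with `adjoint = TRUE`, applies the transpose to a measurement-domain or
#' coefficient-domain object). All operators satisfy the adjoint-consistency
#' identity `<A x, y> = <x, A^T y>` to near machine precision.
#'
#' @param object the operator.
#' @param x a matrix (image domain) or the operator's output-domain object
#'   when `adjoint = TRUE`.
#' @param adjoint apply the transpose instead.
#' @return the mapped object: a matrix, a complex matrix (masked Fourier), a
#'   numeric vector (dense model), or an `(H, W, C)` coefficient array.
#' @export
setGeneric("applyOp", function(object, x, adjoint = FALSE)
  standardGeneric("applyOp"))

#' Generate a spatial regularization mask from an image
#'
#' Evaluates the mask generator at an image: for [MMRMaskGenerator],
#' `Lambda_c(x) = B_c^T psi'_c(B_c |W_c x|)` (entrywise nonnegative); for
#' [SAFIMaskGenerator], the three-layer network output (entrywise in (0, 1)).
#'
#' @param object the mask generator.
#' @param x image matrix.
#' @return a [MaskField].
#' @export
setGeneric("generateMask", function(object, x) standardGeneric("generateMask"))

#' Squared spectral norm of an operator
#'
#' @param object a [ForwardModel] or [AnalysisOperator].
#' @return the (cached or exact) squared spectral norm, used as inverse step
#'   size in the forward-backward solvers.
#' @export
setGeneric("sqSpectralNorm", function(object) standardGeneric("sqSpectralNorm"))

#' Smallest singular value of a forward model
#'
#' @param object a [ForwardModel].
#' @return the smallest singular value, or `NA_real_` when undefined (e.g. a
#'   column-undersampled Fourier model).
#' @export
setGeneric("sigmaMin", function(object) standardGeneric("sigmaMin"))

#' Number of analysis channels
#'
#' @param object a [ConvOperator], [MaskField] or mask generator.
#' @return integer channel count.
#' @export
setGeneric("nChannels", function(object) standardGeneric("nChannels"))

#' Mask values as an array
#'
#' @param object a [MaskField].
#' @return the `(H, W, C)` array of weights.
#' @export
setGeneric("maskValues", function(object) standardGeneric("maskValues"))
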