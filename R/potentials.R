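# Shape-constrained scalar nonlinearities: degree-one splines on uniform
# grids, the saturating clip, the monotone (non-increasing) projection of
# half-line spline coefficients, and concave potential derivatives psi' with
# their exact piecewise-quadratic antiderivatives psi.

#' Construct a linear spline
#'
#' Degree-one spline on the symmetric uniform grid `{-M*delta, ..., M*delta}`
#' parameterized by its `2M+1` values at the knots; linear extrapolation with
#' the boundary-segment slope outside the grid.
#'
#' @param d knot values (length `2M+1`).
#' @param M half-grid count.
#' @param delta positive grid step.
#' @return a [LinearSpline].
#' @export
linearSpline <- function(d, M = (length(d) - 1L) %/% 2L, delta = 0.1) {
  new("LinearSpline", M = as.integer(M), delta = as.numeric(delta),
      d = as.numeric(d))
}

#' @rdname linearSpline
#' @description `halfLineSpline` is the analogue on the nonnegative half grid
#'   `{0, delta, ..., M*delta}` with `M+1` knot values, used for the
#'   non-increasing profiles sigma.
#' @export
halfLineSpline <- function(d, M = length(d) - 1L, delta = 0.05) {
  new("HalfLineSpline", M = as.integer(M), delta = as.numeric(delta),
      d = as.numeric(d))
}

# Shared piecewise-linear interpolation with clamped segment index: inside the
# grid this is exact hat-basis interpolation; outside, the clamped index
# reproduces linear extrapolation with the boundary-segment slope.
.splineInterp <- function(x, d, t0, delta) {
  K <- length(d)
  i <- pmin(pmax(floor((x - t0) / delta), 0), K - 2L)
  u <- (x - t0) / delta - i
  d[i + 1L] * (1 - u) + d[i + 2L] * u
}

#' Evaluate a linear spline
#'
#' Piecewise-linear interpolation of the knot values on the grid, exact at the
#' knots, with linear extrapolation using the boundary-segment slope outside.
#'
#' @param s a [LinearSpline] or [HalfLineSpline].
#' @param x numeric vector/array of evaluation points.
#' @return spline values, same shape as `x`.
#' @export
evalLinearSpline <- function(s, x) {
  t0 <- if (is(s, "HalfLineSpline")) 0 else -s@M * s@delta
  out <- .splineInterp(as.numeric(x), s@d, t0, s@delta)
  if (!is.null(dim(x))) dim(out) <- dim(x)
  out
}

#' Saturating clip to an interval
#'
#' Componentwise clamp to `[k1, k2]`; idempotent and 1-Lipschitz.
#'
#' @param a numeric vector or array.
#' @param k1,k2 interval bounds with `k1 <= k2` (`-Inf`/`Inf` allowed).
#' @return clipped values, same shape.
#' @export
clipInterval <- function(a, k1, k2) {
  if (k1 > k2) stop("clip interval is empty: k1 > k2")
  pmin(pmax(a, k1), k2)
}

#' Monotone (non-increasing) projection of half-line spline coefficients
#'
#' Maps unconstrained knot values `d` to `S clip_(-inf,0](D d) + 1`, where `D`
#' takes consecutive differences and `S` is the cumulative-sum matrix: the
#' result is non-increasing, starts at exactly 1, and is a fixed point for any
#' non-increasing input starting at 1. This is the constraint map for the
#' profiles sigma (so that psi' is non-increasing with psi'(0) = 1).
#'
#' @param d numeric vector of `M+1` knot values.
#' @return the projected knot values.
#' @export
monotoneProjection <- function(d) {
  if (length(d) < 2L) stop("need at least two knot values")
  1 + c(0, cumsum(pmin(diff(d), 0)))
}

#' Construct a concave potential derivative
#'
#' `psi'(x) = clip_[0,1](sigma(r x))` with a non-increasing half-line spline
#' `sigma` (knots projected with [monotoneProjection()], so `sigma(0) = 1`) and
#' a positive scale `r`. The induced potential psi (fixed by `psi(0) = 0`) is
#' piecewise quadratic, nonnegative, non-decreasing and concave.
#'
#' @param d unconstrained knot values of sigma (length `M+1`); projected
#'   internally.
#' @param r positive scale.
#' @param delta grid step of sigma.
#' @return a [ConcaveProfileDeriv].
#' @export
concaveProfileDeriv <- function(d, r = 1, delta = 0.05) {
  sig <- halfLineSpline(monotoneProjection(d), delta = delta)
  new("ConcaveProfileDeriv", sigma = sig, r = abs(as.numeric(r)),
      tab = .psiTableFromSigma(sig))
}

#' Evaluate psi' (mask profile)
#'
#' `psi'(x) = clip_[0,1](sigma(r x))` for `x >= 0`: non-increasing, bounded in
#' `[0, 1]`, and equal to 1 at `x = 0`.
#'
#' @param p a [ConcaveProfileDeriv].
#' @param x nonnegative numeric vector/array.
#' @return values in `[0, 1]`, same shape as `x`.
#' @export
evalPsiPrime <- function(p, x) {
  if (any(x < 0)) stop("psi' is defined for nonnegative arguments only")
  out <- clipInterval(evalLinearSpline(p@sigma, p@r * as.numeric(x)), 0, 1)
  if (!is.null(dim(x))) dim(out) <- dim(x)
  out
}

# Breakpoint table of the clipped integrand s(u) = clip_[0,1](sigma(u)) on
# u >= 0: knots of sigma plus the points where sigma crosses the levels 0/1,
# plus the tail crossing of the linear extrapolation; beyond the last
# breakpoint s is constant. Cumulative trapezoids give the exact integral.
.psiTableFromSigma <- function(sig) {
  M <- sig@M; delta <- sig@delta; d <- sig@d
  u <- seq(0, M * delta, by = delta)
  segs <- cbind(u0 = u[-length(u)], u1 = u[-1L],
                v0 = d[-length(d)], v1 = d[-1L])
  # extrapolation tail: one long segment carried to past any level crossing
  slope <- (d[M + 1L] - d[M]) / delta
  if (slope != 0) {
    # distance until the extrapolated line exits [0, 1]
    target <- if (slope > 0) 1 else 0
    tcross <- (target - d[M + 1L]) / slope
    uEnd <- M * delta + max(tcross, 0) + delta
    segs <- rbind(segs, c(M * delta, uEnd, d[M + 1L],
                          d[M + 1L] + slope * (uEnd - M * delta)))
  }
  pts <- numeric(0)
  for (i in seq_len(nrow(segs))) {
    u0 <- segs[i, 1]; u1 <- segs[i, 2]; v0 <- segs[i, 3]; v1 <- segs[i, 4]
    pts <- c(pts, u0, u1)
    for (lev in c(0, 1)) {
      if ((v0 - lev) * (v1 - lev) < 0) {
        pts <- c(pts, u0 + (lev - v0) / (v1 - v0) * (u1 - u0))
      }
    }
  }
  pts <- sort(unique(pts))
  raw <- .splineInterp(pts, d, 0, delta)
  val <- clipInterval(raw, 0, 1)
  cums <- c(0, cumsum(0.5 * (val[-1L] + val[-length(val)]) * diff(pts)))
  list(u = pts, s = val, I = cums, tailValue = val[length(val)])
}

#' Evaluate the concave potential psi
#'
#' Exact closed-form integral of the clipped piecewise-linear derivative:
#' `psi(x) = integral_0^x psi'(t) dt` with the convention `psi(0) = 0`.
#' Nonnegative, non-decreasing, concave, and piecewise quadratic.
#'
#' @param p a [ConcaveProfileDeriv].
#' @param x nonnegative numeric vector/array.
#' @return psi values, same shape as `x`.
#' @export
evalPsi <- function(p, x) {
  if (any(x < 0)) stop("psi is defined for nonnegative arguments only")
  tb <- if (length(p@tab)) p@tab else .psiTableFromSigma(p@sigma)
  u <- p@r * as.numeric(x)
  i <- findInterval(u, tb$u, rightmost.closed = FALSE)
  i <- pmin(pmax(i, 1L), length(tb$u))
  du <- u - tb$u[i]
  # within segment i the integrand is linear from s[i] with known next value;
  # past the last breakpoint it is constant tailValue
  nextIdx <- pmin(i + 1L, length(tb$u))
  segLen <- tb$u[nextIdx] - tb$u[i]
  slope <- ifelse(segLen > 0, (tb$s[nextIdx] - tb$s[i]) / segLen, 0)
  inside <- du <= segLen | segLen == 0
  part <- ifelse(inside,
                 tb$s[i] * du + 0.5 * slope * du^2,
                 tb$s[i] * segLen + 0.5 * slope * segLen^2 +
                   tb$tailValue * (du - segLen))
  out <- (tb$I[i] + part) / p@r
  if (!is.null(dim(x))) dim(out) <- dim(x)
  out
}

#' Construct a sigmoid-composed spline
#'
#' @param d inner spline knot values (length `2M+1`).
#' @param M half-grid count.
#' @param delta grid step.
#' @return a [SigmoidSpline].
#' @export
sigmoidSpline <- function(d, M = (length(d) - 1L) %/% 2L, delta = 0.1) {
  new("SigmoidSpline", spline = linearSpline(d, M, delta))
}

#' Evaluate a sigmoid-composed spline
#'
#' Logistic function applied to the inner linear-spline value; output strictly
#' inside (0, 1). This is the final activation of the SAFI mask network.
#'
#' @param s a [SigmoidSpline].
#' @param x numeric vector/array.
#' @return values in (0, 1), same shape as `x`.
#' @export
evalSigmoidSpline <- function(s, x) {
  out <- plogis(evalLinearSpline(s@spline, as.numeric(x)))
  if (!is.null(dim(x))) dim(out) <- dim(x)
  out
}

setMethod("show", "ConcaveProfileDeriv", function(object) {
  cat(sprintf(
    "ConcaveProfileDeriv: M = %d, delta = %.3g, r = %.3g, sigma in [%.3g, 1]\n",
    object@sigma@M, object@sigma@delta, object@r, min(object@sigma@d)))
})
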