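# Synthetic data: phantoms, natural-image-like training patches, Gaussian
# noise, k-space sampling masks, and simulated measurements. Every generator
# is a pure function of its arguments including the seed, so all tests and
# demos run without external downloads.

# Modified Shepp-Logan ellipse table (intensity, semi-axes a/b, center x0/y0,
# rotation in degrees) on the [-1, 1]^2 square; the standard ten-ellipse head
# phantom with rescaled intensities so values stay in [0, 1].
.sheppLoganTable <- function() {
  matrix(c(
     1.00, 0.6900, 0.9200,  0.00,  0.0000,   0,
    -0.80, 0.6624, 0.8740,  0.00, -0.0184,   0,
    -0.20, 0.1100, 0.3100,  0.22,  0.0000, -18,
    -0.20, 0.1600, 0.4100, -0.22,  0.0000,  18,
     0.10, 0.2100, 0.2500,  0.00,  0.3500,   0,
     0.10, 0.0460, 0.0460,  0.00,  0.1000,   0,
     0.10, 0.0460, 0.0460,  0.00, -0.1000,   0,
     0.10, 0.0460, 0.0230, -0.08, -0.6050,   0,
     0.10, 0.0230, 0.0230,  0.00, -0.6050,   0,
     0.10, 0.0230, 0.0460,  0.06, -0.6050,   0
  ), ncol = 6, byrow = TRUE,
  dimnames = list(NULL, c("A", "a", "b", "x0", "y0", "phi")))
}

# Rasterize a set of ellipses (rows of a table as above) on pixel centers of
# [-1, 1]^2; row 1 is the top of the image (y = +1).
.rasterEllipses <- function(shape, tab) {
  h <- shape[1]; w <- shape[2]
  xs <- (seq_len(w) - 0.5) / w * 2 - 1
  ys <- 1 - (seq_len(h) - 0.5) / h * 2
  X <- matrix(xs, h, w, byrow = TRUE)
  Y <- matrix(ys, h, w)
  img <- matrix(0, h, w)
  for (i in seq_len(nrow(tab))) {
    phi <- tab[i, "phi"] * pi / 180
    dx <- X - tab[i, "x0"]; dy <- Y - tab[i, "y0"]
    xr <- dx * cos(phi) + dy * sin(phi)
    yr <- -dx * sin(phi) + dy * cos(phi)
    inside <- (xr / tab[i, "a"])^2 + (yr / tab[i, "b"])^2 <= 1
    img <- img + tab[i, "A"] * inside
  }
  img
}

#' Generate a synthetic phantom image
#'
#' @param shape integer (height, width).
#' @param kind `"shepp_logan"` (the standard ten-ellipse head phantom,
#'   modified intensities), `"random_ellipses"` (3-8 random ellipses with
#'   random intensities on a mid-gray background), or `"piecewise_poly"`
#'   (random rectangular tiles of low-order polynomials with sharp
#'   boundaries).
#' @param seed RNG seed; the output is a pure function of `(shape, kind,
#'   seed)`.
#' @return image matrix with values in `[0, 1]`.
#' @export
makePhantom <- function(shape, kind = c("shepp_logan", "random_ellipses",
                                        "piecewise_poly"), seed = 1L) {
  kind <- match.arg(kind)
  shape <- as.integer(shape)
  if (any(shape < 1L)) stop("shape entries must be >= 1")
  h <- shape[1]; w <- shape[2]
  if (kind == "shepp_logan") {
    img <- .rasterEllipses(shape, .sheppLoganTable())
  } else if (kind == "random_ellipses") {
    set.seed(seed)
    ne <- sample(3:8, 1)
    tab <- cbind(A = runif(ne, -0.45, 0.45),
                 a = runif(ne, 0.1, 0.6), b = runif(ne, 0.1, 0.6),
                 x0 = runif(ne, -0.5, 0.5), y0 = runif(ne, -0.5, 0.5),
                 phi = runif(ne, -90, 90))
    img <- 0.5 + .rasterEllipses(shape, tab)
  } else {
    set.seed(seed)
    nt <- sample(2:4, 2, replace = TRUE)  # tile grid (rows, cols)
    rowBrk <- unique(round(seq(0, h, length.out = nt[1] + 1)))
    colBrk <- unique(round(seq(0, w, length.out = nt[2] + 1)))
    img <- matrix(0, h, w)
    for (i in seq_len(length(rowBrk) - 1)) {
      for (j in seq_len(length(colBrk) - 1)) {
        ri <- (rowBrk[i] + 1):rowBrk[i + 1]
        cj <- (colBrk[j] + 1):colBrk[j + 1]
        u <- matrix(seq(-1, 1, length.out = length(ri)), length(ri),
                    length(cj))
        v <- matrix(seq(-1, 1, length.out = length(cj)), length(ri),
                    length(cj), byrow = TRUE)
        cf <- runif(6, -0.4, 0.4)
        img[ri, cj] <- runif(1, 0.1, 0.9) + cf[1] * u + cf[2] * v +
          cf[3] * u * v + cf[4] * u^2 + cf[5] * v^2 + cf[6] * u^2 * v
      }
    }
  }
  clipInterval(img, 0, 1)
}

# 1/f-filtered white noise, normalized to unit standard deviation
.pinkNoise <- function(h, w) {
  z <- matrix(rnorm(h * w), h, w)
  fy <- c(0:(h %/% 2), -((h - h %/% 2 - 1):1)) / h
  fx <- c(0:(w %/% 2), -((w - w %/% 2 - 1):1)) / w
  fr <- sqrt(outer(fy^2, fx^2, "+"))
  fr[1, 1] <- Inf  # kill DC
  flt <- Re(fft(fft(z) / fr, inverse = TRUE)) / (h * w)
  flt / max(sd(flt), .Machine$double.eps)
}

#' Generate natural-image-like clean patches
#'
#' Each patch combines a random piecewise-constant ellipse field (sparse
#' gradients, sharp edges) with 1/f-filtered noise texture, clipped to
#' `[0, 1]`. The resulting gradient-magnitude distribution is heavy-tailed
#' (positive excess kurtosis), the salient statistic of natural images that
#' the learned regularizers exploit.
#'
#' @param n number of patches (0 gives an empty set).
#' @param size patch side length in pixels.
#' @param seed RNG seed.
#' @return array `(size, size, n)` of clean patches in `[0, 1]`.
#' @export
makePatches <- function(n, size, seed = 1L) {
  n <- as.integer(n); size <- as.integer(size)
  if (size < 1L) stop("size must be >= 1")
  out <- array(0, dim = c(size, size, max(n, 0L)))
  if (n < 1L) return(out)
  set.seed(seed)
  for (m in seq_len(n)) {
    ne <- sample(2:5, 1)
    tab <- cbind(A = runif(ne, -0.4, 0.4),
                 a = runif(ne, 0.15, 0.8), b = runif(ne, 0.15, 0.8),
                 x0 = runif(ne, -0.7, 0.7), y0 = runif(ne, -0.7, 0.7),
                 phi = runif(ne, -90, 90))
    base <- 0.5 + .rasterEllipses(c(size, size), tab)
    tex <- runif(1, 0.02, 0.12) * .pinkNoise(size, size)
    out[, , m] <- clipInterval(base + tex, 0, 1)
  }
  out
}

#' Add white Gaussian noise
#'
#' `x + N(0, sigma^2)` i.i.d. per entry, deterministic given the seed.
#'
#' @param x numeric matrix or array.
#' @param sigma noise standard deviation (>= 0).
#' @param seed RNG seed.
#' @return noisy object, same shape.
#' @export
addNoise <- function(x, sigma, seed = 1L) {
  if (sigma < 0) stop("sigma must be nonnegative")
  if (sigma == 0) return(x)
  set.seed(seed)
  x + array(rnorm(length(x), sd = sigma), dim = dim(x) %||% length(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Paired clean/noisy patch set
#'
#' Convenience wrapper combining [makePatches()] and [addNoise()] into the
#' training-set structure used by [trainDenoiser()].
#'
#' @param n number of patches.
#' @param size patch side length.
#' @param sigma noise standard deviation.
#' @param seed RNG seed (patches and noise draw from separate streams).
#' @return list with `clean`, `noisy` (arrays `(size, size, n)`), `sigma`,
#'   `seed`.
#' @export
patchSet <- function(n, size, sigma, seed = 1L) {
  clean <- makePatches(n, size, seed)
  noisy <- addNoise(clean, sigma, seed + 1000003L)
  list(clean = clean, noisy = noisy, sigma = sigma, seed = seed)
}

#' Generate a k-space column sampling mask
#'
#' Binary column mask with `floor(width / Macc)` selected columns: a
#' contiguous centered block of about `centerFraction * width` low-frequency
#' columns is always kept and the remaining columns are drawn uniformly
#' without replacement. The mask is stored in the centered (display)
#' convention with the zero frequency in the middle column;
#' [makeForwardModel()] converts to the unshifted transform ordering.
#'
#' @param shape integer (height, width).
#' @param Macc acceleration factor (>= 1).
#' @param centerFraction fraction of width always kept around the center;
#'   must satisfy `0 <= centerFraction < 1/Macc`.
#' @param seed RNG seed for the random column draw.
#' @return binary matrix of dimension `shape` (entries 0/1, constant along
#'   rows).
#' @export
makeKspaceMask <- function(shape, Macc, centerFraction = 0.08, seed = 1L) {
  shape <- as.integer(shape)
  w <- shape[2]
  if (Macc < 1) stop("Macc must be >= 1")
  if (centerFraction < 0 || centerFraction >= 1 / Macc)
    stop("infeasible centerFraction: need 0 <= centerFraction < 1/Macc")
  nKeep <- floor(w / Macc)
  nCenter <- min(max(1L, round(centerFraction * w)), nKeep)
  c0 <- floor(w / 2) + 1L
  centerCols <- seq(c0 - (nCenter - 1L) %/% 2L, length.out = nCenter)
  set.seed(seed)
  restPool <- setdiff(seq_len(w), centerCols)
  rest <- if (nKeep > nCenter) sample(restPool, nKeep - nCenter) else integer(0)
  kept <- sort(c(centerCols, rest))
  mask <- matrix(0, shape[1], w)
  mask[, kept] <- 1
  mask
}

# centered column index -> unshifted transform column index
.ifftshiftCols <- function(cols, w) {
  c0 <- floor(w / 2) + 1L
  ((as.integer(cols) - c0) %% w) + 1L
}

#' Simulate noisy measurements from a forward model
#'
#' Applies the model and adds white Gaussian noise: real-valued noise for
#' identity/dense models, independent Gaussian noise with standard deviation
#' `sigma` on the real and imaginary parts of the sampled k-space entries for
#' the masked Fourier model.
#'
#' @param model a [ForwardModel].
#' @param x ground-truth image.
#' @param sigma noise standard deviation (default `2e-3`, the single-coil
#'   MRI level).
#' @param seed RNG seed.
#' @return measurements in the model's output domain.
#' @export
simulateMeasurements <- function(model, x, sigma = 2e-3, seed = 1L) {
  y <- applyOp(model, x)
  if (sigma == 0) return(y)
  set.seed(seed)
  if (is(model, "MaskedFourierModel")) {
    kept <- model@keptCols
    nk <- length(kept) * nrow(y)
    noise <- matrix(rnorm(nk, sd = sigma) + 1i * rnorm(nk, sd = sigma),
                    nrow(y), length(kept))
    y[, kept] <- y[, kept] + noise
    y
  } else {
    y + rnorm(length(y), sd = sigma)
  }
}
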