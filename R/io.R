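# Image, array, configuration, checkpoint and trace I/O. Containers are
# R-native text formats: PNG (optionally TIFF) for images, JSON for
# checkpoints, k-space bundles, traces and run logs, YAML or JSON for run
# configuration.

#' Load a grayscale image
#'
#' Reads PNG (or TIFF when the `tiff` package is available) into a numeric
#' matrix in `[0, 1]`; integer bit depths are rescaled, RGB(A) images are
#' averaged over the color channels.
#'
#' @param path image file (`.png`, `.tif`, `.tiff`).
#' @return image matrix with values in `[0, 1]`.
#' @export
loadImage <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("reading TIFF requires the 'tiff' package")
      tiff::readTIFF(path)
    },
    stop("unsupported image format: .", ext))
  if (length(dim(img)) == 3L) img <- rowMeans(img[, , 1:min(3, dim(img)[3])],
                                              dims = 2L)
  clipInterval(img, 0, 1)
}

#' Save a grayscale image
#'
#' Writes a `[0, 1]` matrix as 8-bit PNG (or 16-bit TIFF by extension).
#' Values are clipped to `[0, 1]` before quantization.
#'
#' @param x image matrix.
#' @param path output file.
#' @return the path, invisibly.
#' @export
saveImage <- function(x, path) {
  x <- clipInterval(x, 0, 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(x, path, dpi = NULL),
    tif = , tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("writing TIFF requires the 'tiff' package")
      tiff::writeTIFF(x, path, bits.per.sample = 16L)
    },
    stop("unsupported image format: .", ext))
  invisible(path)
}

#' Load a run configuration
#'
#' Reads YAML or JSON and validates the keys against the known configuration
#' fields, erroring with the name of the first offending key.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return named list of settings.
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop("cannot read config: ", path)
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    stop("unsupported config format: .", ext))
  known <- c("scheme", "checkpoint", "lambda", "Kout", "Kprox", "Kfbs",
             "epsOut", "schedule", "sigma", "seed", "input", "output",
             "log", "forward", "Macc", "centerFraction", "patchSize",
             "nPatches", "batchSize", "lr", "epochs", "channels",
             "kernelSize", "nLayers", "lamInit", "valImages", "maxSteps",
             "n1Range", "n3Range")
  bad <- setdiff(names(cfg), known)
  if (length(bad) > 0)
    stop("invalid configuration key: '", bad[1], "'")
  cfg
}

#' Save / load a model checkpoint
#'
#' Checkpoints are JSON with full double precision: the parameter list
#' (kernels, spline coefficients, scales, lambda), the scheme tag, and
#' training metadata. On load, the constraint projections are re-applied so
#' the feasibility invariants (zero-mean / simplex kernels, non-increasing
#' profiles, positive scales) hold exactly even if the file was edited.
#'
#' @param checkpoint a checkpoint list (from [trainDenoiser()]) or a bare
#'   `theta` parameter list.
#' @param path output `.json` file.
#' @return `saveCheckpoint`: the path, invisibly. `loadCheckpoint`: the
#'   checkpoint list.
#' @export
saveCheckpoint <- function(checkpoint, path) {
  if (is.null(checkpoint$theta)) checkpoint <- list(theta = checkpoint,
                                                    scheme = checkpoint$scheme)
  payload <- list(
    scheme = checkpoint$scheme %||% checkpoint$theta$scheme,
    sigma = checkpoint$sigma,
    theta = .thetaSerialize(checkpoint$theta),
    history = checkpoint$history
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

.thetaSerialize <- function(theta) {
  ser <- function(x) {
    if (is.list(x)) return(lapply(x, ser))
    if (is.array(x)) list(dim = dim(x), data = as.numeric(x)) else x
  }
  ser(theta)
}

.thetaDeserialize <- function(obj) {
  des <- function(x) {
    if (is.list(x) && !is.null(x$dim) && !is.null(x$data))
      return(array(as.numeric(unlist(x$data)), dim = as.integer(unlist(x$dim))))
    if (is.list(x)) return(lapply(x, des))
    if (is.numeric(x)) as.numeric(x) else x
  }
  th <- des(obj)
  for (nm in c("channels", "kernelSize", "nLayers", "M"))
    if (!is.null(th[[nm]])) th[[nm]] <- as.integer(th[[nm]])
  if (!is.null(th$r)) th$r <- abs(as.numeric(unlist(th$r)))
  if (!is.null(th$sigma)) th$sigma <- lapply(th$sigma, as.numeric)
  th$lambda <- abs(as.numeric(th$lambda))
  th
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  if (!file.exists(path)) stop("cannot read checkpoint: ", path)
  payload <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  theta <- .thetaDeserialize(payload$theta)
  theta <- .projectTheta(theta)
  list(theta = theta, scheme = payload$scheme,
       sigma = if (is.null(payload$sigma)) NULL else
         as.numeric(payload$sigma),
       history = payload$history)
}

#' Save / load a k-space measurement bundle
#'
#' JSON container for a masked-Fourier measurement: the complex measurements
#' (real and imaginary parts), the kept-column indices, the acceleration
#' factor and the image shape. Round-trips exactly (full double precision).
#'
#' @param y complex measurement matrix (full grid, unsampled columns zero).
#' @param model the [MaskedFourierModel] that produced `y`.
#' @param path output `.json` file.
#' @return `saveKspace`: the path, invisibly. `loadKspace`: a list with `y`
#'   and the reconstructed `model`.
#' @export
saveKspace <- function(y, model, path) {
  payload <- list(shape = model@shape, Macc = model@Macc,
                  keptCols = model@keptCols,
                  re = Re(y), im = Im(y))
  jsonlite::write_json(payload, path, digits = NA)
  invisible(path)
}

#' @rdname saveKspace
#' @export
loadKspace <- function(path) {
  if (!file.exists(path)) stop("cannot read k-space bundle: ", path)
  p <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  shape <- as.integer(p$shape)
  y <- matrix(complex(real = p$re, imaginary = p$im), shape[1], shape[2])
  model <- makeForwardModel("masked_fourier", shape,
                            params = list(Macc = p$Macc,
                                          keptCols = as.integer(p$keptCols)))
  list(y = y, model = model)
}

#' Serialize a solve trace to JSON
#'
#' Writes the per-iteration relative errors, objective values and iteration
#' counts (plus optional final metrics) of a reconstruction run.
#'
#' @param trace a [SolveTrace].
#' @param path output `.json` file.
#' @param extra named list of additional fields (e.g. resolved config, seed,
#'   final PSNR/SSIM).
#' @return the path, invisibly.
#' @export
saveTrace <- function(trace, path, extra = list()) {
  payload <- c(list(e = trace@e, f = trace@f, iterations = trace@iterations),
               extra)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
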