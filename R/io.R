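#' Read an 8-bit grayscale image
#'
#' Reads a PNG or TIFF file into an integer matrix in \code{[0, 255]}.
#' Multi-channel inputs are rejected unless \code{toGray = TRUE}, in which
#' case the standard luminance weights (0.299, 0.587, 0.114) are applied.
#' 16-bit inputs are rejected unless \code{allow16bit = TRUE}, in which
#' case they are rescaled to the 8-bit range.
#'
#' @param path file path; format chosen by extension (.png, .tif/.tiff).
#' @param toGray convert RGB input by luminance weights instead of
#'   erroring.
#' @param allow16bit accept 16-bit input and rescale to \code{[0, 255]}.
#' @return integer matrix in \code{[0, 255]}.
#' @export
readGrayscale <- function(path, toGray = FALSE, allow16bit = FALSE) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path, info = TRUE)
    depth <- attr(img, "info")$bit.depth
  } else if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, info = TRUE)
    depth <- attr(img, "bits.per.sample")
  } else {
    stop("unsupported format '", ext, "': expected PNG or TIFF",
         call. = FALSE)
  }
  if (!is.null(depth) && length(depth) && max(depth) > 8 && !allow16bit)
    stop("16-bit input requires allow16bit = TRUE: ", path, call. = FALSE)
  if (length(dim(img)) == 3L) {
    if (dim(img)[3L] == 2L) {
      img <- img[, , 1L]           # gray + alpha: drop alpha
    } else if (toGray) {
      img <- 0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L]
    } else {
      stop("multi-channel image (use toGray = TRUE to convert): ", path,
           call. = FALSE)
    }
  }
  out <- matrix(as.integer(.roundHalfAway(as.vector(img) * 255)),
                nrow(img), ncol(img))
  out
}

#' Write an image as 8-bit PNG (or float TIFF)
#'
#' @param image numeric matrix; quantized to \code{[0, 255]} for PNG
#'   output. With \code{floatTiff = TRUE} the unquantized values divided
#'   by 255 are stored as 32-bit float TIFF, which avoids a second
#'   quantization when metrics are computed from the file.
#' @param path output path.
#' @param floatTiff write a 32-bit float TIFF instead of 8-bit PNG.
#' @return the path, invisibly.
#' @export
writeGrayscale <- function(image, path, floatTiff = FALSE) {
  .checkGray(image, "image")
  if (floatTiff) {
    tiff::writeTIFF(image / 255, path, bits.per.sample = 32L)
  } else {
    png::writePNG(quantizeImage(image) / 255, path)
  }
  invisible(path)
}

#' Export a pulse series as binary PNG frames
#'
#' Writes one PNG per iteration (pixels 0 or 255) for visual inspection
#' of the SCM dynamics.
#'
#' @param pulses a [PulseSeries-class].
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @return character vector of written paths, invisibly.
#' @export
writePulseFrames <- function(pulses, dir, prefix = "pulse") {
  stopifnot(is(pulses, "PulseSeries"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- pulses@pulses
  paths <- vapply(seq_len(dim(p)[3L]), function(n) {
    f <- file.path(dir, sprintf("%s_%02d.png", prefix, n))
    png::writePNG(p[, , n], f)
    f
  }, character(1))
  invisible(paths)
}

#' Read / write a fusion run configuration as YAML
#'
#' The YAML file mirrors all pipeline parameters
#' (\code{f, g, h, nMax, linkRadius, thetaUpdate, lp, cs1, cs2, window,
#' step}); missing keys fall back to the defaults. \code{cs1}/\code{cs2}
#' may be the string \code{"auto"} to apply the standard rules
#' \code{3 * nMax} and \code{5 * pi}.
#'
#' @param path YAML file path.
#' @return \code{readRunConfig} returns a list with components
#'   \code{fusion} (a [FusionConfig-class]), \code{window} and
#'   \code{step}.
#' @export
readRunConfig <- function(path) {
  y <- if (is.null(path)) list() else yaml::read_yaml(path)
  .buildRunConfig(y)
}

.buildRunConfig <- function(y) {
  getOr <- function(key, default) if (is.null(y[[key]])) default else y[[key]]
  nMax <- as.integer(getOr("nMax", 20L))
  cs1 <- getOr("cs1", "auto"); cs2 <- getOr("cs2", "auto")
  if (identical(cs1, "auto")) cs1 <- 3 * nMax
  if (identical(cs2, "auto")) cs2 <- 5 * pi
  scm <- ScmParams(f = getOr("f", 0.9), g = getOr("g", 0.3),
                   h = getOr("h", 20), nMax = nMax,
                   linkRadius = as.integer(getOr("linkRadius", 1L)),
                   thetaUpdate = getOr("thetaUpdate", "previous"))
  list(fusion = FusionConfig(scm = scm, lp = as.integer(getOr("lp", 1L)),
                             cs1 = as.numeric(cs1), cs2 = as.numeric(cs2)),
       window = as.integer(getOr("window", 8L)),
       step = as.integer(getOr("step", 1L)))
}

#' @rdname readRunConfig
#' @param config list as returned by \code{readRunConfig}.
#' @export
writeRunConfig <- function(config, path) {
  fc <- config$fusion
  yaml::write_yaml(list(
    f = fc@scm@f, g = fc@scm@g, h = fc@scm@h, nMax = fc@scm@nMax,
    linkRadius = fc@scm@linkRadius, thetaUpdate = fc@scm@thetaUpdate,
    lp = fc@lp, cs1 = fc@constants@cs1, cs2 = fc@constants@cs2,
    window = config$window, step = config$step), path)
  invisible(path)
}
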