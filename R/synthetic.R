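# Deterministic synthetic phantoms emulating complementary modalities:
# a CT-like image (bright high-contrast skull ring plus a few sharp dense
# blobs on a dark background) and an MR-like image (smooth textured soft-
# tissue interior fading to a dark rim). The two share one anatomy layout
# per seed, so a pair is co-registered by construction while its salient
# content lives in disjoint regions (rim vs interior).

# run expr under a pinned RNG without disturbing the caller's stream
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}

.noiseSeed <- function(seed, idx) (abs(seed) %% 10000019L) * 31L + idx

# anatomy layout shared by both modes of one seed
.phantomAnatomy <- function(seed) {
  .withSeed(seed, {
    a <- list(
      cx = stats::runif(1, -0.05, 0.05),
      cy = stats::runif(1, -0.05, 0.05),
      rx = stats::runif(1, 0.75, 0.9),
      ry = stats::runif(1, 0.75, 0.9)
    )
    a$blobAng <- stats::runif(3, 0, 2 * pi)
    a$blobFrac <- stats::runif(3, 0.15, 0.6)
    a$blobRad <- stats::runif(3, 0.04, 0.07)
    a$blobInt <- stats::runif(3, 200, 255)
    a$bumpAng <- stats::runif(4, 0, 2 * pi)
    a$bumpFrac <- stats::runif(4, 0, 0.55)
    a$bumpSigma <- stats::runif(4, 0.12, 0.28)
    a$bumpAmp <- stats::runif(4, 25, 60) * sample(c(-1, 1), 4, replace = TRUE)
    a$texOrient <- stats::runif(1, 0, pi)
    a$texFreq <- stats::runif(1, 4, 8)
    a$texPhase <- stats::runif(1, 0, 2 * pi)
    a
  })
}

.phantomGrid <- function(size) {
  xs <- seq(-1, 1, length.out = size)
  list(X = matrix(xs, size, size, byrow = TRUE),
       Y = matrix(xs, size, size))
}

# normalized elliptic radius: 1 on the head boundary
.ellipticRadius <- function(g, a) {
  sqrt(((g$X - a$cx) / a$rx)^2 + ((g$Y - a$cy) / a$ry)^2)
}

.renderCT <- function(g, a) {
  rho <- .ellipticRadius(g, a)
  img <- matrix(5, nrow(rho), ncol(rho))
  img[rho < 1] <- 40                      # dark soft-tissue interior
  img[rho >= 0.88 & rho <= 1] <- 230      # bright skull-like ring
  for (k in seq_along(a$blobAng)) {       # sharp dense blobs
    bx <- a$cx + a$rx * 0.8 * a$blobFrac[k] * cos(a$blobAng[k])
    by <- a$cy + a$ry * 0.8 * a$blobFrac[k] * sin(a$blobAng[k])
    hit <- (g$X - bx)^2 + (g$Y - by)^2 < a$blobRad[k]^2
    img[hit & rho < 0.88] <- a$blobInt[k]
  }
  img
}

.renderMR <- function(g, a) {
  rho <- .ellipticRadius(g, a)
  # smooth ramp from background (5) to soft tissue (100) across the rim,
  # so the salient MR gradients live in the textured interior, not the rim
  t <- pmin(pmax((1 - rho) / 0.2, 0), 1)
  s <- t * t * (3 - 2 * t)
  img <- 5 + 95 * s
  tissue <- matrix(0, nrow(rho), ncol(rho))
  for (k in seq_along(a$bumpAng)) {       # low-frequency soft-tissue blobs
    bx <- a$cx + a$rx * 0.8 * a$bumpFrac[k] * cos(a$bumpAng[k])
    by <- a$cy + a$ry * 0.8 * a$bumpFrac[k] * sin(a$bumpAng[k])
    d2 <- (g$X - bx)^2 + (g$Y - by)^2
    tissue <- tissue + a$bumpAmp[k] * exp(-d2 / (2 * a$bumpSigma[k]^2))
  }
  proj <- cos(a$texOrient) * g$X + sin(a$texOrient) * g$Y
  tissue <- tissue + 25 * sin(2 * pi * a$texFreq * proj + a$texPhase)
  img + s * tissue
}

#' Generate one synthetic phantom image
#'
#' Produces a deterministic 8-bit grayscale phantom of one of two
#' complementary modalities sharing an anatomy layout per seed:
#' \code{"ct_like"} (bright high-contrast ring plus sharp dense blobs on
#' a dark background) or \code{"mr_like"} (smooth textured soft-tissue
#' interior with a dark rim). Optional additive Gaussian noise (clipped
#' to \code{[0, 255]}) uses a mode-specific stream so the two modalities
#' carry independent noise.
#'
#' @param seed integer seed; fully determines the image.
#' @param size image side in pixels (>= 32).
#' @param mode \code{"ct_like"} or \code{"mr_like"}.
#' @param noiseSigma additive Gaussian noise scale in intensity units.
#' @return integer matrix in \code{[0, 255]}.
#' @examples
#' ct <- makePhantom(seed = 7, size = 64, mode = "ct_like")
#' @export
makePhantom <- function(seed, size = 128L, mode = c("ct_like", "mr_like"),
                        noiseSigma = 2) {
  mode <- match.arg(mode)
  size <- as.integer(size)
  if (size < 32L) stop("'size' must be >= 32", call. = FALSE)
  if (noiseSigma < 0) stop("'noiseSigma' must be >= 0", call. = FALSE)
  a <- .phantomAnatomy(seed)
  g <- .phantomGrid(size)
  img <- if (mode == "ct_like") .renderCT(g, a) else .renderMR(g, a)
  if (noiseSigma > 0) {
    idx <- if (mode == "ct_like") 1L else 2L
    img <- img + .withSeed(.noiseSeed(seed, idx),
                           matrix(stats::rnorm(size * size, 0, noiseSigma),
                                  size, size))
  }
  out <- pmin(pmax(.roundHalfAway(img), 0), 255)
  storage.mode(out) <- "integer"
  out
}

#' Generate a co-registered complementary phantom pair
#'
#' Both modalities are rendered from the same seed-determined anatomy
#' layout, so the pair is co-registered by construction.
#'
#' @inheritParams makePhantom
#' @return list with elements \code{ct}, \code{mr} (integer matrices) and
#'   \code{mask} (logical head-region mask shared by the pair).
#' @examples
#' pair <- makePair(seed = 3, size = 64)
#' @export
makePair <- function(seed, size = 128L, noiseSigma = 2) {
  a <- .phantomAnatomy(seed)
  g <- .phantomGrid(as.integer(size))
  list(ct = makePhantom(seed, size, "ct_like", noiseSigma),
       mr = makePhantom(seed, size, "mr_like", noiseSigma),
       mask = .ellipticRadius(g, a) <= 1)
}

#' Degenerate fixture images for unit testing
#'
#' A named collection of exactly constructed images exercising the
#' degenerate corners of the SCM and of the quality metrics: constants at
#' three levels, a single bright pixel, a two-level half/half image, a
#' four-level uniform image and a checkerboard.
#'
#' @param size image side in pixels (even).
#' @return named list of integer matrices in \code{[0, 255]}.
#' @examples
#' names(fixtureSuite(16))
#' @export
fixtureSuite <- function(size = 32L) {
  size <- as.integer(size)
  if (size < 2L || size %% 2L != 0L)
    stop("'size' must be an even integer >= 2", call. = FALSE)
  mk <- function(v) {
    m <- matrix(as.integer(v), size, size)
    m
  }
  single <- mk(0L)
  single[size %/% 2L, size %/% 2L] <- 255L
  half <- mk(0L)
  half[, (size %/% 2L + 1L):size] <- 255L
  quarter <- size %/% 2L
  uniform4 <- mk(0L)
  uniform4[1:quarter, (quarter + 1L):size] <- 85L
  uniform4[(quarter + 1L):size, 1:quarter] <- 170L
  uniform4[(quarter + 1L):size, (quarter + 1L):size] <- 255L
  checker <- 255L * ((row(mk(0L)) + col(mk(0L))) %% 2L)
  storage.mode(checker) <- "integer"
  list(const0 = mk(0L), const128 = mk(128L), const255 = mk(255L),
       singleBright = single, half01 = half, uniform4 = uniform4,
       checker = checker)
}
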