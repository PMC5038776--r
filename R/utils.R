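# Internal numeric helpers shared by the SCM, feature and metric code.

# round half away from zero (base round() is banker's rounding)
.roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

.checkGray <- function(x, what = "image") {
  if (!is.matrix(x) || !is.numeric(x))
    stop("'", what, "' must be a 2-D numeric matrix (single-channel)",
         call. = FALSE)
  if (anyNA(x) || any(!is.finite(x)))
    stop("'", what, "' contains non-finite values", call. = FALSE)
  invisible(x)
}

.checkSameShape <- function(a, b, whatA = "first", whatB = "second") {
  if (!identical(dim(a), dim(b)))
    stop("shape mismatch: ", whatA, " is ", paste(dim(a), collapse = "x"),
         " but ", whatB, " is ", paste(dim(b), collapse = "x"),
         call. = FALSE)
  invisible(NULL)
}

# symmetric (edge-inclusive mirror) padding by r pixels on all sides
.padMirror <- function(m, r) {
  nr <- nrow(m); nc <- ncol(m)
  if (r >= nr || r >= nc)
    stop("mirror padding radius ", r, " too large for a ", nr, "x", nc,
         " image", call. = FALSE)
  ri <- c(r:1, 1:nr, nr:(nr - r + 1L))
  ci <- c(r:1, 1:nc, nc:(nc - r + 1L))
  m[ri, ci, drop = FALSE]
}

# patch sum over the (2r+1)^2 window, mirror-padded; exact for integer input
.patchSum <- function(m, r) {
  p <- .padMirror(m, r)
  nr <- nrow(m); nc <- ncol(m)
  s <- matrix(0, nr, nc)
  for (dk in -r:r)
    for (dl in -r:r)
      s <- s + p[(1L + r + dk):(nr + r + dk), (1L + r + dl):(nc + r + dl)]
  s
}

# integral image with a zero border, for sliding-window sums
.integralImage <- function(x) {
  nr <- nrow(x); nc <- ncol(x)
  I <- matrix(0, nr + 1L, nc + 1L)
  I[-1L, -1L] <- t(apply(apply(x, 2L, cumsum), 1L, cumsum))
  I
}

# sums over all w x w windows at the given stride; returns a matrix whose
# [a, b] entry is the sum over the window with top-left corner
# (1+(a-1)*step, 1+(b-1)*step)
.windowSums <- function(x, w, step = 1L) {
  nr <- nrow(x); nc <- ncol(x)
  if (w > nr || w > nc)
    stop("window side ", w, " exceeds image size", call. = FALSE)
  I <- .integralImage(x)
  rows <- seq.int(1L, nr - w + 1L, by = step)
  cols <- seq.int(1L, nc - w + 1L, by = step)
  I[rows + w, cols + w, drop = FALSE] -
    I[rows, cols + w, drop = FALSE] -
    I[rows + w, cols, drop = FALSE] +
    I[rows, cols, drop = FALSE]
}

# per-window mean / unbiased variance / unbiased covariance stacks
.windowStats <- function(a, b = NULL, w, step = 1L) {
  n <- w * w
  Sa <- .windowSums(a, w, step)
  Saa <- .windowSums(a * a, w, step)
  mu <- Sa / n
  va <- (Saa - Sa * Sa / n) / (n - 1)
  va[va < 0] <- 0  # guard tiny negative round-off
  out <- list(mean = mu, var = va)
  if (!is.null(b)) {
    Sb <- .windowSums(b, w, step)
    Sab <- .windowSums(a * b, w, step)
    out$cov <- (Sab - Sa * Sb / n) / (n - 1)
  }
  out
}

# Sobel gradients with symmetric padding; returns gx (horizontal derivative,
# column direction), gy (vertical derivative, row direction)
.sobel <- function(m) {
  p <- .padMirror(m, 1L)
  nr <- nrow(m); nc <- ncol(m)
  sh <- function(dk, dl)
    p[(2L + dk):(nr + 1L + dk), (2L + dl):(nc + 1L + dl)]
  gx <- (sh(-1L, 1L) + 2 * sh(0L, 1L) + sh(1L, 1L)) -
        (sh(-1L, -1L) + 2 * sh(0L, -1L) + sh(1L, -1L))
  gy <- (sh(1L, -1L) + 2 * sh(1L, 0L) + sh(1L, 1L)) -
        (sh(-1L, -1L) + 2 * sh(-1L, 0L) + sh(-1L, 1L))
  list(gx = gx, gy = gy)
}
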