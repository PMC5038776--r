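# Six fusion-quality measures scoring a fused image U against its two
# co-registered sources A and B. All are reference-free in the sense that
# no ground-truth fused image is needed.

# mutual information in bits between two 8-bit images via the 256x256
# joint histogram; empty cells contribute 0
.miBits <- function(x, y) {
  n <- length(x)
  J <- matrix(tabulate(as.integer(x) * 256L + as.integer(y) + 1L,
                       nbins = 65536L), nrow = 256L)
  # column-major fill: J[y+1, x+1]
  px <- colSums(J) / n
  py <- rowSums(J) / n
  p <- J / n
  i <- which(p > 0, arr.ind = TRUE)
  sum(p[i] * log2(p[i] / (py[i[, 1L]] * px[i[, 2L]])))
}

#' Mutual-information fusion metric (QM)
#'
#' Total amount of information the fused image carries about the two
#' sources: \eqn{Q_M = MI(A, U) + MI(B, U)}, with each mutual information
#' computed from 256-bin joint histograms in bits.
#'
#' @param imageA,imageB,fused 8-bit grayscale matrices of equal shape;
#'   non-integer fused values are quantized to 8-bit for binning.
#' @return QM in bits.
#' @export
mutualInfoMetric <- function(imageA, imageB, fused) {
  .checkGray(imageA, "imageA"); .checkGray(imageB, "imageB")
  .checkGray(fused, "fused")
  .checkSameShape(imageA, imageB, "imageA", "imageB")
  .checkSameShape(imageA, fused, "imageA", "fused")
  u <- quantizeImage(fused)
  .miBits(quantizeImage(imageA), u) + .miBits(quantizeImage(imageB), u)
}

# gradient strength and orientation; orientation 0 where both derivatives
# vanish (flat patch has no orientation)
.edgeStrengthOrientation <- function(m) {
  s <- .sobel(m)
  g <- sqrt(s$gx^2 + s$gy^2)
  a <- atan(s$gy / s$gx)
  a[!is.finite(a)] <- 0
  list(g = g, alpha = a)
}

# preservation sigmoid, normalized so that perfect preservation scores 1
.presSigmoid <- function(x, gamma, kappa, sigma) {
  raw <- gamma / (1 + exp(kappa * (x - sigma)))
  top <- gamma / (1 + exp(kappa * (1 - sigma)))
  raw / top
}

#' Edge-preservation fusion metric (QE)
#'
#' Measures how much of the edge information of each source survives in
#' the fused image. Sobel gradients give per-pixel edge strength g and
#' orientation alpha; the relative strength
#' \eqn{G = \min(g_U, g_A)/\max(g_U, g_A)} and the orientation agreement
#' \eqn{\Lambda = ||\alpha_A - \alpha_U| - \pi/2| / (\pi/2)} (orientation
#' is modulo pi: an edge and its reverse are the same edge) are passed
#' through sigmoids with the classical constants
#' (\eqn{\Gamma_g = 0.9994, \kappa_g = -15, \sigma_g = 0.5};
#' \eqn{\Gamma_\alpha = 0.9879, \kappa_\alpha = -22, \sigma_\alpha = 0.8}),
#' each normalized to score exactly 1 at perfect preservation. The per-
#' pixel products for A and B are averaged with weights equal to the
#' source edge strengths.
#'
#' @inheritParams mutualInfoMetric
#' @return QE in \code{[0, 1]}; 0 when neither source has any edges.
#' @export
edgePreservationMetric <- function(imageA, imageB, fused) {
  .checkGray(imageA, "imageA"); .checkGray(imageB, "imageB")
  .checkGray(fused, "fused")
  .checkSameShape(imageA, imageB, "imageA", "imageB")
  .checkSameShape(imageA, fused, "imageA", "fused")
  eA <- .edgeStrengthOrientation(imageA)
  eB <- .edgeStrengthOrientation(imageB)
  eU <- .edgeStrengthOrientation(fused)
  qx <- function(src) {
    G <- ifelse(src$g > eU$g, eU$g / src$g,
                ifelse(src$g == eU$g, 1, src$g / eU$g))
    G[src$g == 0 & eU$g == 0] <- 1
    A <- abs(abs(src$alpha - eU$alpha) - pi / 2) / (pi / 2)
    .presSigmoid(G, 0.9994, -15, 0.5) * .presSigmoid(A, 0.9879, -22, 0.8)
  }
  wA <- eA$g; wB <- eB$g
  den <- sum(wA) + sum(wB)
  if (den == 0) return(0)
  sum(qx(eA) * wA + qx(eB) * wB) / den
}

#' Structural similarity of two image windows
#'
#' The standard SSIM form (luminance, contrast, structure) with
#' stabilizers \code{C1 = C2 = 2e-6}, intended for intensities normalized
#' to \code{[0, 1]}. Equal constant windows score 1 (the stabilized
#' degenerate case); a window and its negative score below 0 when their
#' covariance is negative.
#'
#' @param windowA,windowB equal-size numeric matrices on the
#'   \code{[0, 1]} scale.
#' @param c1,c2 stabilizing constants.
#' @return a single similarity score.
#' @export
localSSIM <- function(windowA, windowB, c1 = 2e-6, c2 = 2e-6) {
  .checkSameShape(windowA, windowB, "windowA", "windowB")
  ma <- mean(windowA); mb <- mean(windowB)
  va <- stats::var(as.vector(windowA)); vb <- stats::var(as.vector(windowB))
  cab <- stats::cov(as.vector(windowA), as.vector(windowB))
  ((2 * ma * mb + c1) * (2 * cab + c2)) /
    ((ma^2 + mb^2 + c1) * (va + vb + c2))
}

# SSIM over every w x w sliding window (stride step), vectorized
.ssimWindows <- function(a, b, w, step, c1 = 2e-6, c2 = 2e-6) {
  sa <- .windowStats(a, b, w = w, step = step)
  sb <- .windowStats(b, w = w, step = step)
  ((2 * sa$mean * sb$mean + c1) * (2 * sa$cov + c2)) /
    ((sa$mean^2 + sb$mean^2 + c1) * (sa$var + sb$var + c2))
}

# universal image quality index per window; degenerate 0/0 windows score
# 1 when the windows agree (equal means, both flat) and 0 otherwise
.uiqiWindows <- function(a, b, w, step, tol = 1e-12) {
  sa <- .windowStats(a, b, w = w, step = step)
  sb <- .windowStats(b, w = w, step = step)
  den <- (sa$var + sb$var) * (sa$mean^2 + sb$mean^2)
  num <- 4 * sa$cov * sa$mean * sb$mean
  q <- matrix(0, nrow(den), ncol(den))
  ok <- den > tol
  q[ok] <- num[ok] / den[ok]
  flatEqual <- !ok & sa$var < tol & sb$var < tol &
    abs(sa$mean - sb$mean) < 1e-9
  q[flatEqual] <- 1
  q
}

# local-variance salience weight lambda = s(A)/(s(A)+s(B)), 0.5 when flat
.salienceLambda <- function(va, vb) {
  tot <- va + vb
  lam <- matrix(0.5, nrow(va), ncol(va))
  pos <- tot > 0
  lam[pos] <- va[pos] / tot[pos]
  lam
}

#' SSIM-based fusion metric (QS)
#'
#' Sliding-window score driven by the local SSIM between the two sources
#' as a match measure: where \eqn{SSIM(A, B) \ge 0.75} the window scores
#' the salience-weighted combination
#' \eqn{\lambda\,SSIM(A,U) + (1-\lambda)\,SSIM(B,U)} with
#' \eqn{\lambda = s(A)/(s(A)+s(B))} the local-variance ratio; where the
#' sources disagree (\eqn{SSIM(A,B) < 0.75}) it scores the better of
#' \eqn{SSIM(A,U)} and \eqn{SSIM(B,U)}. QS is the mean over all windows.
#' Intensities are normalized to \code{[0, 1]} first so the stabilizers
#' \code{2e-6} are on the intended scale.
#'
#' @inheritParams mutualInfoMetric
#' @param window window side in pixels (default 8).
#' @param step window stride (default 1, overlapping windows).
#' @return QS score.
#' @export
ssimFusionMetric <- function(imageA, imageB, fused, window = 8L, step = 1L) {
  .checkSameShape(imageA, imageB, "imageA", "imageB")
  .checkSameShape(imageA, fused, "imageA", "fused")
  a <- imageA / 255; b <- imageB / 255; u <- fused / 255
  ssAB <- .ssimWindows(a, b, window, step)
  ssAU <- .ssimWindows(a, u, window, step)
  ssBU <- .ssimWindows(b, u, window, step)
  va <- .windowStats(a, w = window, step = step)$var
  vb <- .windowStats(b, w = window, step = step)$var
  lam <- .salienceLambda(va, vb)
  q <- ifelse(ssAB >= 0.75, lam * ssAU + (1 - lam) * ssBU,
              pmax(ssAU, ssBU))
  mean(q)
}

# saliency-weighted lambda-combination of local SSIMs (the building block
# of the fusion quality index); C(ws) = max of the two window variances
.weightedQualityIndex <- function(a, b, u, window, step) {
  ssAU <- .ssimWindows(a, u, window, step)
  ssBU <- .ssimWindows(b, u, window, step)
  va <- .windowStats(a, w = window, step = step)$var
  vb <- .windowStats(b, w = window, step = step)$var
  lam <- .salienceLambda(va, vb)
  combo <- lam * ssAU + (1 - lam) * ssBU
  cw <- pmax(va, vb)
  if (sum(cw) == 0) return(mean(combo))
  sum(cw * combo) / sum(cw)
}

#' Fusion quality index (QL)
#'
#' Product of two saliency-weighted quality factors: one on the images
#' themselves and one on their edge images (Sobel gradient magnitudes).
#' Each factor averages the salience-weighted SSIM combination
#' \eqn{\lambda\,SSIM(A,U) + (1-\lambda)\,SSIM(B,U)} over all windows,
#' weighting every window by its overall saliency
#' \eqn{C(w) = \max(s(A|w), s(B|w))}.
#'
#' @inheritParams ssimFusionMetric
#' @return QL score.
#' @export
fusionQualityIndex <- function(imageA, imageB, fused, window = 8L,
                               step = 1L) {
  .checkSameShape(imageA, imageB, "imageA", "imageB")
  .checkSameShape(imageA, fused, "imageA", "fused")
  a <- imageA / 255; b <- imageB / 255; u <- fused / 255
  gm <- function(m) {
    s <- .sobel(m)
    sqrt(s$gx^2 + s$gy^2)
  }
  .weightedQualityIndex(a, b, u, window, step) *
    .weightedQualityIndex(gm(a), gm(b), gm(u), window, step)
}

#' Fusion similarity metric (QT)
#'
#' Per window, universal-image-quality-index scores \eqn{Q(A,U|w)} and
#' \eqn{Q(B,U|w)} are blended by the spatial-similarity weight
#' \eqn{sim = \sigma_{AU} / (\sigma_{AU} + \sigma_{BU})} (the covariance
#' ratio, clipped to \code{[0, 1]}; 0.5 when both covariances vanish).
#' QT is the mean over all windows of
#' \eqn{sim\,Q(A,U) + (1 - sim)\,Q(B,U)}.
#'
#' @inheritParams ssimFusionMetric
#' @return QT score.
#' @export
fusionSimilarityMetric <- function(imageA, imageB, fused, window = 8L,
                                   step = 1L) {
  .checkSameShape(imageA, imageB, "imageA", "imageB")
  .checkSameShape(imageA, fused, "imageA", "fused")
  a <- imageA / 255; b <- imageB / 255; u <- fused / 255
  qAU <- .uiqiWindows(a, u, window, step)
  qBU <- .uiqiWindows(b, u, window, step)
  cAU <- .windowStats(a, u, w = window, step = step)$cov
  cBU <- .windowStats(b, u, w = window, step = step)$cov
  tot <- cAU + cBU
  sim <- matrix(0.5, nrow(tot), ncol(tot))
  nz <- tot != 0
  sim[nz] <- cAU[nz] / tot[nz]
  sim <- pmin(pmax(sim, 0), 1)
  mean(sim * qAU + (1 - sim) * qBU)
}

#' Standard deviation of an image (contrast)
#'
#' Sample standard deviation over all pixels with the \eqn{N - 1}
#' denominator; a plain global contrast measure.
#'
#' @param fused numeric image matrix with at least two pixels.
#' @return standard deviation in intensity units.
#' @export
stdMetric <- function(fused) {
  .checkGray(fused, "fused")
  if (length(fused) < 2L)
    stop("standard deviation needs more than one pixel", call. = FALSE)
  stats::sd(as.vector(fused))
}

#' Score a fused image with all six quality metrics
#'
#' @inheritParams ssimFusionMetric
#' @param fused numeric matrix or a [FusedImage-class].
#' @return a [MetricReport-class].
#' @examples
#' f <- fixtureSuite(16)
#' metricReport(f$half01, f$half01, f$half01)
#' @export
metricReport <- function(imageA, imageB, fused, window = 8L, step = 1L) {
  if (is(fused, "FusedImage")) fused <- fused@values
  new("MetricReport",
      qm = mutualInfoMetric(imageA, imageB, fused),
      qe = edgePreservationMetric(imageA, imageB, fused),
      qs = ssimFusionMetric(imageA, imageB, fused, window, step),
      ql = fusionQualityIndex(imageA, imageB, fused, window, step),
      qt = fusionSimilarityMetric(imageA, imageB, fused, window, step),
      std = stdMetric(fused),
      params = list(window = as.integer(window), step = as.integer(step),
                    c1 = 2e-6, c2 = 2e-6))
}

#' @describeIn metricReport convert a report to a plain named list
#' @param x a [MetricReport-class]
#' @param ... ignored
#' @export
setMethod("as.list", "MetricReport", function(x, ...) {
  list(qm = x@qm, qe = x@qe, qs = x@qs, ql = x@ql, qt = x@qt,
       std = x@std, params = x@params)
})

#' Write / read a metric report as JSON
#'
#' @param report a [MetricReport-class].
#' @param path file path.
#' @return \code{readMetricReport} returns a [MetricReport-class].
#' @export
writeMetricReport <- function(report, path) {
  jsonlite::write_json(as.list(report), path, auto_unbox = TRUE,
                       digits = I(17))
  invisible(path)
}

#' @rdname writeMetricReport
#' @export
readMetricReport <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("MetricReport", qm = as.numeric(x$qm), qe = as.numeric(x$qe),
      qs = as.numeric(x$qs), ql = as.numeric(x$ql), qt = as.numeric(x$qt),
      std = as.numeric(x$std), params = as.list(x$params))
}
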