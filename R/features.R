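#' Patchwise Shannon entropy of a pulse series
#'
#' For every pixel and every iteration, the binary Shannon entropy (bits)
#' of the \code{(2*lp+1) x (2*lp+1)} patch of the pulse image centred at
#' that pixel: with \eqn{P^1} the fraction of 1s in the patch and
#' \eqn{P^0 = 1 - P^1},
#' \deqn{H = -P^1 \log_2 P^1 - P^0 \log_2 P^0}
#' (with \eqn{0 \log_2 0 \equiv 0}). Homogeneous patches score exactly 0;
#' the maximum on a finite patch is attained at the occupancy nearest 1/2.
#' Borders use symmetric (mirror) padding, so homogeneous regions stay
#' exactly homogeneous. Stacked across iterations these entropies form the
#' per-pixel feature vector that characterizes the local gray-level
#' distribution of the source image.
#'
#' @param pulses a [PulseSeries-class].
#' @param lp patch half-width in pixels (default 1, i.e. 3x3 patches).
#' @return an [EntropyFeatureField-class] of dimension
#'   \code{rows x cols x nMax}.
#' @export
patchEntropySeries <- function(pulses, lp = 1L) {
  stopifnot(is(pulses, "PulseSeries"))
  lp <- as.integer(lp)
  if (lp < 1L) stop("'lp' must be >= 1", call. = FALSE)
  p <- pulses@pulses
  d <- dim(p)
  area <- (2L * lp + 1L)^2
  out <- array(0, dim = d)
  for (n in seq_len(d[3L])) {
    k <- .patchSum(p[, , n], lp)     # count of 1s, exact
    out[, , n] <- .binaryEntropy(k / area)
  }
  new("EntropyFeatureField", values = out)
}

# binary Shannon entropy in bits, 0*log2(0) := 0
.binaryEntropy <- function(p1) {
  p0 <- 1 - p1
  h <- matrix(0, nrow(p1), ncol(p1))
  i <- p1 > 0 & p1 < 1
  h[i] <- -p1[i] * log2(p1[i]) - p0[i] * log2(p0[i])
  h
}

#' Entropy-based patch similarity between two sources
#'
#' Per pixel, the Euclidean norm D of the difference between the two
#' entropy feature vectors, mapped to a similarity
#' \eqn{S^{En} = 1 - D / cs_1}. With the default
#' \code{cs1 = 3 * nMax} and entries bounded by 1 bit,
#' \eqn{D \le \sqrt{nMax}} so the similarity never falls below
#' \eqn{1 - \sqrt{nMax} / (3\,nMax)}.
#'
#' @param fieldA,fieldB [EntropyFeatureField-class] objects of equal shape.
#' @param cs1 normalizing constant (default \code{3 * nMax}).
#' @return a [SimilarityMap-class] of kind \code{"entropy"}.
#' @export
entropySimilarity <- function(fieldA, fieldB, cs1 = NULL) {
  stopifnot(is(fieldA, "EntropyFeatureField"),
            is(fieldB, "EntropyFeatureField"))
  .checkSameShape(fieldA@values, fieldB@values, "fieldA", "fieldB")
  nmax <- dim(fieldA@values)[3L]
  if (is.null(cs1)) cs1 <- 3 * nmax
  d2 <- rowSums((fieldA@values - fieldB@values)^2, dims = 2L)
  s <- 1 - sqrt(d2) / cs1
  new("SimilarityMap", values = s, kind = "entropy")
}

#' Differential excitation (Weber local descriptor) of a firing map
#'
#' The salience component of the Weber local descriptor, applied to the
#' raw firing times T: the summed neighbour-minus-centre differences over
#' the patch, divided by the centre value, passed through the arctangent
#' to keep the output in \eqn{(-\pi/2, \pi/2)}:
#' \deqn{\xi = \arctan\!\big(\sum_{patch} (T_{neigh} - T_{centre}) \,/\,
#'   \max(T_{centre}, \epsilon)\big)}
#' The sum is a Laplacian-like high-pass response; the ratio follows
#' Weber's law (a just-noticeable difference scales with background
#' intensity), making \eqn{\xi} invariant to positive rescaling of T
#' wherever the centre is nonzero. Zero-firing centres use a small
#' \code{eps} in the denominator, which saturates \eqn{\xi} toward
#' \eqn{\pm\pi/2} for nonzero responses.
#'
#' @param fmap a [FiringMap-class].
#' @param lp patch half-width (default 1).
#' @param eps denominator floor for zero-firing centres.
#' @return an [ExcitationField-class].
#' @export
differentialExcitation <- function(fmap, lp = 1L, eps = 1e-6) {
  stopifnot(is(fmap, "FiringMap"))
  lp <- as.integer(lp)
  if (lp < 1L) stop("'lp' must be >= 1", call. = FALSE)
  t <- fmap@times + 0  # double
  area <- (2L * lp + 1L)^2
  r <- .patchSum(t, lp) - area * t   # centre term contributes 0
  xi <- atan(r / pmax(t, eps))
  new("ExcitationField", values = xi)
}

#' WLD-based patch similarity between two sources
#'
#' \eqn{S^{WLD} = 1 - |\xi^A - \xi^B| / cs_2} per pixel. With the default
#' \code{cs2 = 5 * pi} and excitations confined to
#' \eqn{(-\pi/2, \pi/2)}, the similarity always exceeds
#' \eqn{1 - \pi / cs_2 = 0.8}.
#'
#' @param xiA,xiB [ExcitationField-class] objects of equal shape.
#' @param cs2 normalizing constant (default \code{5 * pi}).
#' @return a [SimilarityMap-class] of kind \code{"wld"}.
#' @export
wldSimilarity <- function(xiA, xiB, cs2 = 5 * pi) {
  stopifnot(is(xiA, "ExcitationField"), is(xiB, "ExcitationField"))
  .checkSameShape(xiA@values, xiB@values, "xiA", "xiB")
  s <- 1 - abs(xiA@values - xiB@values) / cs2
  new("SimilarityMap", values = s, kind = "wld")
}
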