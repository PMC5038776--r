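#' Local energy of a firing map
#'
#' Per pixel, the sum of squared firing times over the
#' \code{(2*lp+1) x (2*lp+1)} patch (mirror-padded at the borders).
#' The pixelwise comparison of the two sources' local energies decides
#' which source dominates each fused pixel.
#'
#' @param fmap a [FiringMap-class].
#' @param lp patch half-width (default 1).
#' @return an [EnergyMap-class].
#' @export
localEnergy <- function(fmap, lp = 1L) {
  stopifnot(is(fmap, "FiringMap"))
  lp <- as.integer(lp)
  if (lp < 1L) stop("'lp' must be >= 1", call. = FALSE)
  t <- fmap@times + 0
  new("EnergyMap", values = .patchSum(t * t, lp))
}

#' Combine the two similarity maps into the fusion weight
#'
#' The fusion weight is the pointwise product
#' \eqn{\omega = S^{En} \cdot S^{WLD}}, joining gray-level similarity
#' (entropy features) with structural similarity (differential
#' excitation). Under the default constants every weight lies in
#' (0.74, 1], so the energy-dominant source always contributes the
#' majority share.
#'
#' @param sEn a [SimilarityMap-class] of kind \code{"entropy"}.
#' @param sWld a [SimilarityMap-class] of kind \code{"wld"}.
#' @return a [WeightMap-class].
#' @export
combineWeights <- function(sEn, sWld) {
  stopifnot(is(sEn, "SimilarityMap"), is(sWld, "SimilarityMap"))
  if (sEn@kind != "entropy" || sWld@kind != "wld")
    stop("'sEn' must have kind \"entropy\" and 'sWld' kind \"wld\"",
         call. = FALSE)
  .checkSameShape(sEn@values, sWld@values, "sEn", "sWld")
  new("WeightMap", values = sEn@values * sWld@values)
}

#' Energy-gated weighted fusion of two source images
#'
#' Per pixel: where the local energy of A exceeds that of B,
#' \eqn{U = \omega I^A + (1-\omega) I^B}; elsewhere (including energy
#' ties) \eqn{U = (1-\omega) I^A + \omega I^B}. With \eqn{\omega \in
#' [0, 1]} each fused pixel is a convex combination of the two sources.
#' Output is kept in floating point; quantize with [quantizeImage()] when
#' writing an 8-bit file.
#'
#' @param imageA,imageB source intensity matrices (same scale and shape).
#' @param energyA,energyB [EnergyMap-class] objects for the two sources.
#' @param weights a [WeightMap-class].
#' @return numeric matrix of fused intensities.
#' @export
fusePixels <- function(imageA, imageB, energyA, energyB, weights) {
  .checkGray(imageA, "imageA"); .checkGray(imageB, "imageB")
  stopifnot(is(energyA, "EnergyMap"), is(energyB, "EnergyMap"),
            is(weights, "WeightMap"))
  .checkSameShape(imageA, imageB, "imageA", "imageB")
  .checkSameShape(imageA, energyA@values, "imageA", "energyA")
  .checkSameShape(imageA, energyB@values, "imageA", "energyB")
  .checkSameShape(imageA, weights@values, "imageA", "weights")
  w <- weights@values
  aDominant <- energyA@values > energyB@values
  u <- (1 - w) * imageA + w * imageB
  u[aDominant] <- (w * imageA + (1 - w) * imageB)[aDominant]
  u
}

#' Quantize a fused image to 8-bit
#'
#' Round half away from zero and clip to \code{[0, 255]}.
#'
#' @param values numeric matrix of intensities.
#' @return integer matrix in \code{[0, 255]}.
#' @export
quantizeImage <- function(values) {
  out <- pmin(pmax(.roundHalfAway(values), 0), 255)
  storage.mode(out) <- "integer"
  out
}

#' Full SCM-driven weighted fusion pipeline
#'
#' Runs the complete method on a pair of co-registered 8-bit grayscale
#' images: (1) both sources are normalized and driven through the SCM
#' with one shared parameter set; (2) patchwise pulse-train entropies
#' give the entropy similarity; (3) the firing maps give local energies
#' and WLD differential excitations, hence the WLD similarity; (4) the
#' fusion weight is the product of the two similarities; (5) the
#' energy-gated weighted rule produces the fused image. Fusion arithmetic
#' runs on the original 8-bit intensity scale; only the SCM consumes the
#' normalized copy. Fully deterministic.
#'
#' @param imageA,imageB 8-bit grayscale matrices (values in
#'   \code{[0, 255]}) of equal shape; assumed co-registered.
#' @param config a [FusionConfig-class]; the single config drives both
#'   SCM runs identically.
#' @param details if \code{TRUE}, also return the intermediate fields.
#' @return a [FusedImage-class]; with \code{details = TRUE}, a list with
#'   components \code{fused}, \code{pulsesA}, \code{pulsesB},
#'   \code{fmapA}, \code{fmapB}, \code{sEn}, \code{sWld},
#'   \code{weights}, \code{energyA}, \code{energyB}.
#' @examples
#' pair <- makePair(seed = 1, size = 64)
#' fused <- scmFuse(pair$ct, pair$mr)
#' range(mapValues(fused))
#' @export
scmFuse <- function(imageA, imageB, config = FusionConfig(),
                    details = FALSE) {
  .checkGray(imageA, "imageA"); .checkGray(imageB, "imageB")
  .checkSameShape(imageA, imageB, "imageA", "imageB")
  validObject(config)

  psA <- runSCM(normalizeImage(imageA), config@scm)
  psB <- runSCM(normalizeImage(imageB), config@scm)

  vA <- patchEntropySeries(psA, config@lp)
  vB <- patchEntropySeries(psB, config@lp)
  sEn <- entropySimilarity(vA, vB, config@constants@cs1)

  fmA <- firingMap(psA)
  fmB <- firingMap(psB)
  eA <- localEnergy(fmA, config@lp)
  eB <- localEnergy(fmB, config@lp)
  xiA <- differentialExcitation(fmA, config@lp)
  xiB <- differentialExcitation(fmB, config@lp)
  sWld <- wldSimilarity(xiA, xiB, config@constants@cs2)

  w <- combineWeights(sEn, sWld)
  u <- fusePixels(imageA, imageB, eA, eB, w)
  fused <- new("FusedImage", values = u, config = config)
  if (!details) return(fused)
  list(fused = fused, pulsesA = psA, pulsesB = psB, fmapA = fmA,
       fmapB = fmB, sEn = sEn, sWld = sWld, weights = w,
       energyA = eA, energyB = eB)
}
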