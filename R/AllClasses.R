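#' Parameters of the spiking cortical model
#'
#' Bundles the constants of the SCM neuron dynamics. Each neuron keeps a
#' leaky internal activity \eqn{F} (decay \code{f}) fed by the normalized
#' pixel intensity and by linking input from neighbouring pulses, and fires
#' when \eqn{F} exceeds a dynamic threshold \eqn{\Theta} (decay \code{g},
#' refractory kick \code{h} after each pulse).
#'
#' @slot f feeding decay constant, in (0, 1).
#' @slot g threshold decay constant, in (0, 1).
#' @slot h threshold refractory magnitude, positive; a large value silences
#'   a neuron for several iterations after it fires.
#' @slot nMax number of iterations to run (length of the pulse series).
#' @slot linkRadius radius in pixels of the linking neighbourhood; the
#'   linking kernel spans \code{(2*linkRadius+1)^2} pixels.
#' @slot thetaUpdate either \code{"previous"} (threshold at step n is
#'   driven by the pulse of step n-1, the printed index scheme) or
#'   \code{"current"} (threshold absorbs the pulse fired at step n, a
#'   common variant). \code{"previous"} is the default.
#'
#' @seealso [ScmParams()] for the user constructor, [runSCM()].
#' @export
setClass("ScmParams",
  representation(
    f = "numeric", g = "numeric", h = "numeric",
    nMax = "integer", linkRadius = "integer",
    thetaUpdate = "character"
  ),
  prototype(
    f = 0.9, g = 0.3, h = 20, nMax = 20L, linkRadius = 1L,
    thetaUpdate = "previous"
  )
)

setValidity("ScmParams", function(object) {
  msg <- character()
  if (length(object@f) != 1L || !is.finite(object@f) ||
      object@f <= 0 || object@f >= 1)
    msg <- c(msg, "'f' must be a single value in (0, 1)")
  if (length(object@g) != 1L || !is.finite(object@g) ||
      object@g <= 0 || object@g >= 1)
    msg <- c(msg, "'g' must be a single value in (0, 1)")
  if (length(object@h) != 1L || !is.finite(object@h) || object@h <= 0)
    msg <- c(msg, "'h' must be a single positive value")
  if (length(object@nMax) != 1L || is.na(object@nMax) || object@nMax < 1L)
    msg <- c(msg, "'nMax' must be >= 1")
  if (length(object@linkRadius) != 1L || is.na(object@linkRadius) ||
      object@linkRadius < 1L)
    msg <- c(msg, "'linkRadius' must be >= 1")
  if (!object@thetaUpdate %in% c("previous", "current"))
    msg <- c(msg, "'thetaUpdate' must be \"previous\" or \"current\"")
  if (length(msg)) msg else TRUE
})

#' Temporal series of binary pulse images from one SCM run
#'
#' @slot pulses integer array of dimension \code{c(rows, cols, nMax)} with
#'   entries 0/1; slice \code{[,,n]} is the pulse image of iteration n.
#' @export
setClass("PulseSeries", representation(pulses = "array"))

setValidity("PulseSeries", function(object) {
  p <- object@pulses
  if (length(dim(p)) != 3L)
    return("'pulses' must be a rows x cols x nMax array")
  if (!all(p == 0L | p == 1L))
    return("pulse values must be binary (0/1)")
  TRUE
})

#' Firing-mapping image: per-pixel firing counts
#'
#' The firing-mapping image (FMI) is the elementwise sum of the pulse
#' series: each pixel holds the number of iterations at which the
#' corresponding neuron fired, an integer in \code{[0, nMax]}.
#'
#' @slot times integer matrix of firing counts.
#' @slot nMax the iteration count of the generating run.
#' @export
setClass("FiringMap",
  representation(times = "matrix", nMax = "integer"))

setValidity("FiringMap", function(object) {
  t <- object@times
  if (!is.numeric(t)) return("'times' must be numeric")
  if (any(t < 0) || any(t > object@nMax))
    return("firing times must lie in [0, nMax]")
  if (any(t != round(t))) return("firing times must be integer-valued")
  TRUE
})

#' Per-pixel entropy feature vectors
#'
#' For every pixel, the binary Shannon entropy (bits) of its patch in each
#' pulse image, stacked across iterations into a length-\code{nMax} feature
#' vector.
#'
#' @slot values numeric array \code{c(rows, cols, nMax)}; entries in
#'   \code{[0, 1]} bits.
#' @export
setClass("EntropyFeatureField", representation(values = "array"))

setValidity("EntropyFeatureField", function(object) {
  v <- object@values
  if (length(dim(v)) != 3L)
    return("'values' must be a rows x cols x nMax array")
  if (any(v < 0) || any(v > 1 + 1e-12))
    return("binary patch entropies must lie in [0, 1] bits")
  TRUE
})

#' Differential-excitation field of a firing map
#'
#' Weber local descriptor salience: arctangent of the summed
#' neighbour-minus-centre firing-time differences over the centre value.
#'
#' @slot values numeric matrix with entries in \eqn{(-\pi/2, \pi/2)}
#'   (radians).
#' @export
setClass("ExcitationField", representation(values = "matrix"))

setValidity("ExcitationField", function(object) {
  v <- object@values
  if (any(abs(v) >= pi / 2)) return("excitations must lie in (-pi/2, pi/2)")
  TRUE
})

#' Patch-similarity map between two sources
#'
#' @slot values numeric matrix of similarity scores, each at most 1.
#' @slot kind \code{"entropy"} (feature-vector distance based) or
#'   \code{"wld"} (differential-excitation based).
#' @export
setClass("SimilarityMap",
  representation(values = "matrix", kind = "character"))

setValidity("SimilarityMap", function(object) {
  if (!object@kind %in% c("entropy", "wld"))
    return("'kind' must be \"entropy\" or \"wld\"")
  if (any(object@values > 1 + 1e-12)) return("similarities cannot exceed 1")
  TRUE
})

#' Local-energy map of a firing map
#'
#' Patch sum of squared firing times; gates which source dominates each
#' fused pixel.
#'
#' @slot values nonnegative numeric matrix.
#' @export
setClass("EnergyMap", representation(values = "matrix"))

setValidity("EnergyMap", function(object) {
  if (any(object@values < 0)) return("local energies must be nonnegative")
  TRUE
})

#' Per-pixel fusion weight map
#'
#' The pointwise product of the entropy-based and WLD-based similarity
#' maps; allocates the convex combination between the two sources.
#'
#' @slot values numeric matrix of weights.
#' @export
setClass("WeightMap", representation(values = "matrix"))

#' Normalizing constants of the two similarity measures
#'
#' @slot cs1 divisor of the entropy feature distance; default
#'   \code{3 * nMax}.
#' @slot cs2 divisor of the differential-excitation difference; default
#'   \code{5 * pi}.
#' @export
setClass("SimilarityConstants",
  representation(cs1 = "numeric", cs2 = "numeric"))

setValidity("SimilarityConstants", function(object) {
  if (length(object@cs1) != 1L || object@cs1 <= 0)
    return("'cs1' must be a single positive value")
  if (length(object@cs2) != 1L || object@cs2 <= 0)
    return("'cs2' must be a single positive value")
  TRUE
})

#' Complete configuration of one fusion run
#'
#' A single configuration drives the SCM runs on both sources identically.
#'
#' @slot scm an [ScmParams-class] object.
#' @slot lp patch half-width in pixels; all patch statistics (entropy,
#'   local energy, differential excitation) use
#'   \code{(2*lp+1) x (2*lp+1)} patches.
#' @slot constants a [SimilarityConstants-class] object.
#' @export
setClass("FusionConfig",
  representation(scm = "ScmParams", lp = "integer",
    constants = "SimilarityConstants"))

setValidity("FusionConfig", function(object) {
  if (length(object@lp) != 1L || is.na(object@lp) || object@lp < 1L)
    return("'lp' must be >= 1")
  TRUE
})

#' A fused image with its provenance
#'
#' @slot values numeric matrix on the source intensity scale (unquantized;
#'   use [quantizeImage()] before writing an 8-bit file).
#' @slot config the [FusionConfig-class] that produced it.
#' @export
setClass("FusedImage",
  representation(values = "matrix", config = "FusionConfig"))

#' Six fusion-quality scores for one (A, B, fused) triple
#'
#' @slot qm mutual-information score, bits.
#' @slot qe edge-preservation score, in \code{[0, 1]}.
#' @slot qs SSIM-based fusion score.
#' @slot ql fusion quality index.
#' @slot qt fusion similarity metric.
#' @slot std standard deviation of the fused image, intensity units.
#' @slot params list recording the window/parameter provenance.
#' @export
setClass("MetricReport",
  representation(qm = "numeric", qe = "numeric", qs = "numeric",
    ql = "numeric", qt = "numeric", std = "numeric", params = "list"))

setValidity("MetricReport", function(object) {
  sc <- c(object@qm, object@qe, object@qs, object@ql, object@qt, object@std)
  if (length(sc) != 6L || !all(is.finite(sc)))
    return("all six scores must be single finite numbers")
  if (object@std < 0) return("'std' must be nonnegative")
  TRUE
})
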