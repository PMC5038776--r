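#' @describeIn PulseSeries-class number of iterations in the series
#' @param object a PulseSeries
#' @export
setGeneric("nIterations", function(object) standardGeneric("nIterations"))

#' @rdname PulseSeries-class
#' @export
setGeneric("pulseArray", function(object) standardGeneric("pulseArray"))

#' @rdname FiringMap-class
#' @export
setGeneric("firingTimes", function(object) standardGeneric("firingTimes"))

#' Extract the numeric field of a map-like object
#'
#' Accessor for the 2-D (or 3-D, for feature fields) numeric payload of
#' the similarity, energy, weight, excitation, entropy-feature and fused
#' image classes.
#'
#' @param object one of the map-like S4 objects of this package.
#' @return a numeric matrix (or array for [EntropyFeatureField-class]).
#' @export
setGeneric("mapValues", function(object) standardGeneric("mapValues"))

setMethod("nIterations", "PulseSeries", function(object) dim(object@pulses)[3L])
setMethod("pulseArray", "PulseSeries", function(object) object@pulses)
setMethod("firingTimes", "FiringMap", function(object) object@times)

setMethod("mapValues", "SimilarityMap", function(object) object@values)
setMethod("mapValues", "EnergyMap", function(object) object@values)
setMethod("mapValues", "WeightMap", function(object) object@values)
setMethod("mapValues", "ExcitationField", function(object) object@values)
setMethod("mapValues", "EntropyFeatureField", function(object) object@values)
setMethod("mapValues", "FusedImage", function(object) object@values)
setMethod("mapValues", "FiringMap", function(object) object@times)

setMethod("show", "ScmParams", function(object) {
  cat("ScmParams: f =", object@f, ", g =", object@g, ", h =", object@h,
      ", nMax =", object@nMax, ", linkRadius =", object@linkRadius,
      ", thetaUpdate =", object@thetaUpdate, "\n")
})

setMethod("show", "PulseSeries", function(object) {
  d <- dim(object@pulses)
  cat("PulseSeries:", d[1L], "x", d[2L], "pixels,", d[3L], "iterations;",
      "total firings:", sum(object@pulses), "\n")
})

setMethod("show", "FiringMap", function(object) {
  cat("FiringMap:", nrow(object@times), "x", ncol(object@times),
      "; firing-time range [", min(object@times), ",", max(object@times),
      "] of nMax =", object@nMax, "\n")
})

setMethod("show", "SimilarityMap", function(object) {
  cat("SimilarityMap (", object@kind, "): ", nrow(object@values), " x ",
      ncol(object@values), "; range [",
      format(min(object@values), digits = 4), ", ",
      format(max(object@values), digits = 4), "]\n", sep = "")
})

setMethod("show", "FusedImage", function(object) {
  cat("FusedImage:", nrow(object@values), "x", ncol(object@values),
      "; intensity range [", format(min(object@values), digits = 5), ",",
      format(max(object@values), digits = 5), "]\n")
})

setMethod("show", "MetricReport", function(object) {
  cat("MetricReport\n")
  cat(sprintf("  QM  (mutual information, bits): %.4f\n", object@qm))
  cat(sprintf("  QE  (edge preservation):        %.4f\n", object@qe))
  cat(sprintf("  QS  (SSIM-based):               %.4f\n", object@qs))
  cat(sprintf("  QL  (fusion quality index):     %.4f\n", object@ql))
  cat(sprintf("  QT  (fusion similarity):        %.4f\n", object@qt))
  cat(sprintf("  STD (contrast):                 %.4f\n", object@std))
})
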