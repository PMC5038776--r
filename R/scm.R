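#' Construct SCM parameters
#'
#' User-level constructor with the standard defaults: feeding decay
#' \code{f = 0.9}, threshold decay \code{g = 0.3}, refractory magnitude
#' \code{h = 20}, \code{nMax = 20} iterations and a 3x3 linking
#' neighbourhood (\code{linkRadius = 1}).
#'
#' @param f,g decay constants, both in (0, 1).
#' @param h threshold refractory magnitude (> 0).
#' @param nMax number of SCM iterations.
#' @param linkRadius linking neighbourhood radius in pixels.
#' @param thetaUpdate \code{"previous"} (default) follows the printed
#'   index scheme in which the threshold at step n absorbs the pulse of
#'   step n-1; \code{"current"} lets the threshold absorb the pulse fired
#'   at step n itself.
#' @return an [ScmParams-class] object.
#' @examples
#' ScmParams()
#' ScmParams(nMax = 7L)
#' @export
ScmParams <- function(f = 0.9, g = 0.3, h = 20, nMax = 20L,
                      linkRadius = 1L, thetaUpdate = c("previous", "current")) {
  thetaUpdate <- match.arg(thetaUpdate)
  new("ScmParams", f = f, g = g, h = h, nMax = as.integer(nMax),
      linkRadius = as.integer(linkRadius), thetaUpdate = thetaUpdate)
}

#' Construct the full fusion configuration
#'
#' @param scm an [ScmParams-class] object.
#' @param lp patch half-width; all patch statistics use
#'   \code{(2*lp+1) x (2*lp+1)} patches. Default 1 (3x3).
#' @param cs1 entropy-similarity normalizer; \code{NULL} (default) applies
#'   the standard rule \code{3 * nMax}.
#' @param cs2 WLD-similarity normalizer; \code{NULL} (default) applies the
#'   standard rule \code{5 * pi}.
#' @return a [FusionConfig-class] object.
#' @examples
#' FusionConfig()
#' @export
FusionConfig <- function(scm = ScmParams(), lp = 1L, cs1 = NULL, cs2 = NULL) {
  if (is.null(cs1)) cs1 <- 3 * scm@nMax
  if (is.null(cs2)) cs2 <- 5 * pi
  new("FusionConfig", scm = scm, lp = as.integer(lp),
      constants = new("SimilarityConstants", cs1 = cs1, cs2 = cs2))
}

#' Normalize an 8-bit grayscale image to the unit interval
#'
#' The SCM consumes normalized intensities as feeding input; this is the
#' plain linear map \code{values / 255}.
#'
#' @param image 2-D numeric matrix with integer values in \code{[0, 255]}.
#' @return numeric matrix with values in \code{[0, 1]}, same shape.
#' @examples
#' normalizeImage(matrix(c(0, 51, 255, 128), 2, 2))
#' @export
normalizeImage <- function(image) {
  .checkGray(image)
  if (any(image < 0) || any(image > 255))
    stop("image values must lie in [0, 255]", call. = FALSE)
  image / 255
}

#' Inverse-square linking kernel
#'
#' Synaptic weight between a neuron and a linking neighbour at offset
#' \code{(dk, dl)} is \code{1 / (dk^2 + dl^2)}; the centre weight is 0
#' (no self-linking). The kernel is restricted to a square window of side
#' \code{2 * linkRadius + 1}.
#'
#' @param linkRadius neighbourhood radius in pixels (>= 1).
#' @return numeric matrix of side \code{2 * linkRadius + 1}.
#' @examples
#' linkingKernel(1)  # 4-neighbours 1, diagonals 0.5, centre 0
#' @export
linkingKernel <- function(linkRadius) {
  linkRadius <- as.integer(linkRadius)
  if (length(linkRadius) != 1L || is.na(linkRadius) || linkRadius < 1L)
    stop("'linkRadius' must be an integer >= 1", call. = FALSE)
  off <- seq.int(-linkRadius, linkRadius)
  d2 <- outer(off^2, off^2, `+`)
  w <- 1 / d2
  w[linkRadius + 1L, linkRadius + 1L] <- 0
  w
}

#' Run the spiking cortical model on a stimulus image
#'
#' Iterates the SCM dynamics for \code{nMax} steps. At step n (all
#' elementwise, with O the stimulus and W the linking kernel applied by
#' correlation to the previous pulse image, zero-padded at the borders):
#' \deqn{F[n] = f F[n-1] + O + O (W \star Y[n-1])}
#' \deqn{\Theta[n] = g \Theta[n-1] + h Y[n-1]}
#' \deqn{Y[n] = 1 \textrm{ where } F[n] > \Theta[n-1], \textrm{ else } 0}
#' with initial state \eqn{F = \Theta = Y = 0}, so every neuron with a
#' positive stimulus fires at the first step. The strict inequality is
#' kept strict: ties do not fire. With
#' \code{thetaUpdate = "current"} the threshold recursion uses
#' \eqn{Y[n]} instead of \eqn{Y[n-1]} (and Y is computed first).
#'
#' @param stimulus numeric matrix of normalized intensities in
#'   \code{[0, 1]} (see [normalizeImage()]).
#' @param params an [ScmParams-class] object.
#' @return a [PulseSeries-class] with \code{nMax} binary slices.
#' @examples
#' s <- normalizeImage(matrix(255, 1, 1))
#' ps <- runSCM(s, ScmParams(nMax = 7L))
#' pulseArray(ps)[1, 1, ]  # 1 1 0 0 0 1 1
#' @export
runSCM <- function(stimulus, params = ScmParams()) {
  .checkGray(stimulus, "stimulus")
  if (any(stimulus < 0) || any(stimulus > 1))
    stop("stimulus must be normalized to [0, 1]", call. = FALSE)
  validObject(params)
  nr <- nrow(stimulus); nc <- ncol(stimulus)
  r <- params@linkRadius
  W <- linkingKernel(r)
  off <- seq.int(-r, r)

  # linking input: correlation of the previous pulse image with W,
  # zero-padded; offsets accumulated in fixed row-major order so that the
  # floating-point summation order matches a per-pixel scalar loop exactly
  linkInput <- function(Y) {
    P <- matrix(0, nr + 2L * r, nc + 2L * r)
    P[(r + 1L):(r + nr), (r + 1L):(r + nc)] <- Y
    L <- matrix(0, nr, nc)
    for (dk in off)
      for (dl in off) {
        w <- W[dk + r + 1L, dl + r + 1L]
        if (w == 0) next
        L <- L + w * P[(1L + r + dk):(nr + r + dk),
                       (1L + r + dl):(nc + r + dl)]
      }
    L
  }

  F <- matrix(0, nr, nc)
  Theta <- matrix(0, nr, nc)
  Y <- matrix(0, nr, nc)
  pulses <- array(0L, dim = c(nr, nc, params@nMax))

  for (n in seq_len(params@nMax)) {
    F <- params@f * F + stimulus + stimulus * linkInput(Y)
    if (params@thetaUpdate == "previous") {
      thetaPrev <- Theta
      Theta <- params@g * Theta + params@h * Y
      Y <- (F > thetaPrev) + 0
    } else {
      Y <- (F > Theta) + 0
      Theta <- params@g * Theta + params@h * Y
    }
    pulses[, , n] <- as.integer(Y)
  }
  new("PulseSeries", pulses = pulses)
}

#' Firing-mapping image of a pulse series
#'
#' Sums the binary pulse series over the iteration axis, giving the number
#' of times each neuron fired — a compact per-pixel representation of
#' image structure.
#'
#' @param pulses a [PulseSeries-class].
#' @return a [FiringMap-class] with integer times in \code{[0, nMax]}.
#' @export
firingMap <- function(pulses) {
  stopifnot(is(pulses, "PulseSeries"))
  p <- pulses@pulses
  if (dim(p)[3L] < 1L) stop("empty pulse series", call. = FALSE)
  t <- rowSums(p, dims = 2L)
  storage.mode(t) <- "integer"
  new("FiringMap", times = t, nMax = dim(p)[3L])
}

#' Rescale a firing map to 8-bit for display
#'
#' Linear stretch of the firing times to \code{[0, 255]} (minimum to 0,
#' maximum to 255, round half away from zero). A constant map has a
#' degenerate range and maps to all zeros. For visualization only:
#' downstream computation always uses the raw firing times.
#'
#' @param fmap a [FiringMap-class].
#' @return integer matrix in \code{[0, 255]}.
#' @export
scaleFMI <- function(fmap) {
  stopifnot(is(fmap, "FiringMap"))
  t <- fmap@times
  rng <- max(t) - min(t)
  if (rng == 0) return(matrix(0L, nrow(t), ncol(t)))
  out <- .roundHalfAway(255 * (t - min(t)) / rng)
  storage.mode(out) <- "integer"
  out
}
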