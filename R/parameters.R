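#' @include AllClasses.R
NULL

.TYPE_LABELS <- c("A1", "A2", "B1", "B2", "B3", "B4", "NA")

#' Default chromatin type-to-type coupling matrix
#'
#' A symmetric 7x7 matrix over the type alphabet A1, A2, B1, B2, B3, B4
#' plus the neutral centromere type. The default profile encodes the
#' microphase-separation structure of the model qualitatively: homotypic
#' couplings are the most attractive, A-with-A and B-with-B cross terms
#' weaker, A-with-B weakest, and the neutral type couples to nothing.
#' Negative values are attractive under the sign convention
#' `E = alpha * f(r)` with `f in [0, 1]`. Published parameter sets can be
#' dropped in verbatim via [michromParameters()].
#'
#' @return Numeric 7x7 matrix with dimnames over the type alphabet.
#' @export
defaultTypeMatrix <- function() {
  m <- matrix(0, 7, 7, dimnames = list(.TYPE_LABELS, .TYPE_LABELS))
  A <- 1:2; B <- 3:6
  m[A, A] <- -0.2
  m[B, B] <- -0.2
  m[A, B] <- -0.05
  m[B, A] <- -0.05
  diag(m)[1:6] <- -0.4
  m[7, ] <- 0; m[, 7] <- 0
  m
}

#' Construct the energy-function parameter set
#'
#' All coefficients of the chromatin energy landscape, in reduced units
#' (bead diameter sigma = 1, thermal energy = 1; one bead = 50 kb by
#' default). Every functional form is the package's documented default
#' family — FENE + repulsive core connectivity, half-harmonic spherical
#' wall, sigmoidal contact kernel, three-coefficient genomic-distance decay
#' — and every coefficient can be overridden so published parameter sets
#' can be used verbatim.
#'
#' Defaults: `feneK = 30`, `feneR0 = 1.5`, `stericEpsilon = 1`,
#' `stericSigma = 1` (standard coarse-grained bead-spring practice);
#' `contactMu = 3.22`, `contactRc = 1.78` (the field-standard contact
#' kernel steepness and midpoint at 50-kb resolution);
#' `confinementRadius = 10`, `confinementK = 10`; `idealGamma` a mild
#' attractive decay `gamma(d) = g1/log(d) + g2/d + g3/d^2` with
#' `(-0.01, -0.1, 0)` acting on separations `dMin = 3` to `dMax = 500`
#' (nearest and next-nearest neighbours are handled by the connectivity
#' and steric terms); `loopChi = -1.5` (attractive).
#'
#' @param feneK,feneR0 FENE stiffness and maximum extension.
#' @param stericEpsilon,stericSigma repulsive-core scale and range.
#' @param confinementRadius,confinementK spherical wall radius and
#'   stiffness; the wall energy is `confinementK * (|r| - R)^2` outside the
#'   sphere, zero inside.
#' @param typeMatrix symmetric 7x7 coupling matrix (see
#'   [defaultTypeMatrix()]).
#' @param idealGamma length-3 numeric `(g1, g2, g3)`.
#' @param dMin,dMax genomic-separation window of the ideal-chromosome term.
#' @param loopChi loop interaction strength (negative = attractive).
#' @param contactMu,contactRc contact kernel steepness and midpoint.
#' @return A validated [MiChroMParameters-class] object.
#' @examples
#' p <- michromParameters(confinementRadius = 5)
#' p
#' @export
michromParameters <- function(feneK = 30, feneR0 = 1.5,
                              stericEpsilon = 1, stericSigma = 1,
                              confinementRadius = 10, confinementK = 10,
                              typeMatrix = defaultTypeMatrix(),
                              idealGamma = c(-0.01, -0.1, 0),
                              dMin = 3L, dMax = 500L,
                              loopChi = -1.5,
                              contactMu = 3.22, contactRc = 1.78) {
  tm <- unname(as.matrix(typeMatrix))
  new("MiChroMParameters",
      feneK = as.numeric(feneK), feneR0 = as.numeric(feneR0),
      stericEpsilon = as.numeric(stericEpsilon),
      stericSigma = as.numeric(stericSigma),
      confinementRadius = as.numeric(confinementRadius),
      confinementK = as.numeric(confinementK),
      typeMatrix = tm,
      idealGamma = as.numeric(idealGamma),
      dMin = as.integer(dMin), dMax = as.integer(dMax),
      loopChi = as.numeric(loopChi),
      contactMu = as.numeric(contactMu), contactRc = as.numeric(contactRc))
}

#' Genomic-distance kernel of the ideal-chromosome term
#'
#' `gamma(d) = g1/log(d) + g2/d + g3/d^2` for bead separation `d >= dMin`;
#' zero outside `[dMin, dMax]`.
#'
#' @param d integer vector of genomic separations (beads).
#' @param params a [MiChroMParameters-class].
#' @return Numeric vector of coefficients.
#' @export
gammaIdeal <- function(d, params) {
  g <- params@idealGamma
  out <- g[1L] / log(d) + g[2L] / d + g[3L] / d^2
  out[d < params@dMin | d > params@dMax] <- 0
  out
}

# Flatten parameters for the C++ kernels, with the gamma(d) lookup table.
.paramsForCpp <- function(params, nBeads = NULL) {
  dmax <- params@dMax
  gt <- numeric(dmax + 1L)
  if (dmax >= params@dMin) {
    dd <- params@dMin:dmax
    gt[dd + 1L] <- gammaIdeal(dd, params)
  }
  list(feneK = params@feneK, feneR0 = params@feneR0,
       stericEpsilon = params@stericEpsilon,
       stericSigma = params@stericSigma,
       confinementRadius = params@confinementRadius,
       confinementK = params@confinementK,
       contactMu = params@contactMu, contactRc = params@contactRc,
       loopChi = params@loopChi,
       dMin = params@dMin, dMax = params@dMax,
       gammaTable = gt,  # gammaTable[d + 1] = gamma(d)
       typeMatrix = params@typeMatrix)
}
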