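#' @import methods
#' @importFrom stats pnorm rnorm runif rpois sd prcomp lm coef var setNames
#' @importFrom utils read.csv write.csv combn head
NULL

#' Bead-type registry
#'
#' Ordered alphabet of coarse-grained bead types. Each type carries a
#' unique positive identity number \eqn{Z_I} (standing in for the element
#' number of atomistic representations), a category (\code{solute},
#' \code{lipid} or \code{solvent}) and an optional physicochemical class.
#' The construction order is frozen and defines channel order everywhere
#' downstream.
#'
#' @slot typeName character vector of unique bead type names.
#' @slot Z integer vector of unique positive identity numbers.
#' @slot category character vector, each one of \code{"solute"},
#'   \code{"lipid"}, \code{"solvent"}.
#' @slot physClass character vector, each one of \code{"polar"},
#'   \code{"charged"}, \code{"hbond"}, \code{"apolar"} or \code{NA}.
#'
#' @seealso [buildRegistry()], [buildChannelIndex()]
#' @export
setClass("BeadTypeRegistry",
  representation(
    typeName = "character",
    Z = "integer",
    category = "character",
    physClass = "character"
  )
)

setValidity("BeadTypeRegistry", function(object) {
  n <- length(object@typeName)
  msgs <- character(0)
  if (n == 0L) msgs <- c(msgs, "registry must contain at least one bead type")
  if (length(object@Z) != n || length(object@category) != n ||
      length(object@physClass) != n)
    msgs <- c(msgs, "slot lengths differ")
  if (anyDuplicated(object@typeName))
    msgs <- c(msgs, "duplicate bead type names")
  if (anyDuplicated(object@Z))
    msgs <- c(msgs, "duplicate Z identity numbers")
  if (length(object@Z) && any(object@Z <= 0L))
    msgs <- c(msgs, "Z identity numbers must be positive")
  if (!all(object@category %in% c("solute", "lipid", "solvent")))
    msgs <- c(msgs, "category must be solute, lipid or solvent")
  ok <- object@physClass %in% c("polar", "charged", "hbond", "apolar") |
    is.na(object@physClass)
  if (!all(ok))
    msgs <- c(msgs, "physClass must be polar/charged/hbond/apolar or NA")
  if (length(msgs)) msgs else TRUE
})

#' Canonical channel index
#'
#' Deterministic enumeration of the one-, two- and three-body interaction
#' channels of a molecular SLATM for a fixed registry: \eqn{N} one-body
#' channels, \eqn{N(N+1)/2} unordered type pairs, and
#' \eqn{N \cdot N(N+1)/2} (center, unordered neighbor pair) triplets,
#' all in lexicographic registry order.
#'
#' @slot oneBody character vector of type names (registry order).
#' @slot twoBody character matrix with columns \code{typeA}, \code{typeB}
#'   (registry order, \code{typeA} before-or-equal \code{typeB}).
#' @slot threeBody character matrix with columns \code{center},
#'   \code{typeJ}, \code{typeK}.
#' @slot tripletPolicy \code{"all"} or \code{"observed-only"}. Both
#'   enumerate the full triplet set here; under \code{"observed-only"}
#'   triplet channels never observed across a dataset are dropped at
#'   dataset assembly, before PCA.
#'
#' @seealso [buildChannelIndex()], [channelKeys()]
#' @export
setClass("ChannelIndex",
  representation(
    oneBody = "character",
    twoBody = "matrix",
    threeBody = "matrix",
    tripletPolicy = "character"
  )
)

setValidity("ChannelIndex", function(object) {
  n <- length(object@oneBody)
  msgs <- character(0)
  if (nrow(object@twoBody) != n * (n + 1) / 2)
    msgs <- c(msgs, "two-body channel count must be N(N+1)/2")
  if (nrow(object@threeBody) > n * n * (n + 1) / 2)
    msgs <- c(msgs, "three-body channel count exceeds N*N(N+1)/2")
  if (!object@tripletPolicy %in% c("all", "observed-only"))
    msgs <- c(msgs, "tripletPolicy must be 'all' or 'observed-only'")
  if (length(msgs)) msgs else TRUE
})

#' SLATM histogram parameters
#'
#' Kernel widths, bin widths and radial cutoff of the two- and three-body
#' histograms, plus the (overridable) prefactors and exponent of the
#' London and Axilrod-Teller-Muto weights. Units are Angstrom and radian.
#'
#' Defaults: \code{sigmaR} 0.3 A, \code{sigmaTheta} 0.2 rad, bin widths
#' 0.2 A and 0.2 rad, \code{rCutoff} 8.0 A; London weight
#' \eqn{w_{ij} = 1/2 \, Z_I Z_J R_{ij}^{-6}}; ATM weight
#' \eqn{v_{ijk} = 1/3 \, Z_I Z_J Z_K (1 + 3\cos\theta_1\cos\theta_2\cos\theta_3)
#' / (R_{ij} R_{ik} R_{jk})^3}.
#'
#' @slot sigmaR,sigmaTheta Gaussian kernel widths (A, rad).
#' @slot binWidthR,binWidthTheta histogram bin widths (A, rad).
#' @slot rCutoff radial cutoff (A) for center-neighbor distances.
#' @slot londonPrefactor,londonExponent,atmPrefactor weight parameters.
#' @seealso [slatmParams()]
#' @export
setClass("SlatmParams",
  representation(
    sigmaR = "numeric",
    sigmaTheta = "numeric",
    binWidthR = "numeric",
    binWidthTheta = "numeric",
    rCutoff = "numeric",
    londonPrefactor = "numeric",
    londonExponent = "numeric",
    atmPrefactor = "numeric"
  )
)

setValidity("SlatmParams", function(object) {
  msgs <- character(0)
  pos <- c(
    sigmaR = object@sigmaR, sigmaTheta = object@sigmaTheta,
    binWidthR = object@binWidthR, binWidthTheta = object@binWidthTheta,
    rCutoff = object@rCutoff
  )
  if (any(!is.finite(pos)) || any(pos <= 0))
    msgs <- c(msgs, "sigma, bin widths and cutoff must be positive finite")
  if (object@rCutoff <= object@binWidthR)
    msgs <- c(msgs, "rCutoff must exceed binWidthR")
  if (length(msgs)) msgs else TRUE
})

#' A single bead configuration
#'
#' Positions (Angstrom), per-bead type names, per-bead solute flags and an
#' optional orthorhombic box (lengths in Angstrom, length-3 numeric;
#' `numeric(0)` means open boundaries).
#'
#' @slot positions numeric matrix, n x 3, Angstrom.
#' @slot types character vector of registered type names.
#' @slot soluteFlags logical vector marking solute beads.
#' @slot box numeric(0) or length-3 orthorhombic box lengths (A).
#' @export
setClass("Configuration",
  representation(
    positions = "matrix",
    types = "character",
    soluteFlags = "logical",
    box = "numeric"
  )
)

setValidity("Configuration", function(object) {
  n <- nrow(object@positions)
  msgs <- character(0)
  if (ncol(object@positions) != 3L)
    msgs <- c(msgs, "positions must be an n x 3 matrix")
  if (length(object@types) != n || length(object@soluteFlags) != n)
    msgs <- c(msgs, "positions, types and soluteFlags lengths differ")
  if (n && !all(is.finite(object@positions)))
    msgs <- c(msgs, "coordinates must be finite")
  if (!length(object@box) %in% c(0L, 3L))
    msgs <- c(msgs, "box must be numeric(0) or length 3")
  if (length(object@box) == 3L && any(object@box <= 0))
    msgs <- c(msgs, "box lengths must be positive")
  if (length(msgs)) msgs else TRUE
})

#' Trajectory ensemble
#'
#' Ordered frames sharing bead count and types; coordinates are stored in
#' Angstrom (nm-based inputs are converted on ingest).
#'
#' @slot frames list of [Configuration-class] objects.
#' @slot frameIndices integer source frame indices.
#' @slot lengthUnitSource \code{"angstrom"} or \code{"nm"} (unit of the
#'   source file; internal storage is always Angstrom).
#' @export
setClass("TrajectoryEnsemble",
  representation(
    frames = "list",
    frameIndices = "integer",
    lengthUnitSource = "character"
  )
)

setValidity("TrajectoryEnsemble", function(object) {
  msgs <- character(0)
  if (length(object@frames) == 0L)
    msgs <- c(msgs, "ensemble must contain at least one frame")
  if (length(object@frameIndices) != length(object@frames))
    msgs <- c(msgs, "frameIndices length must match frame count")
  if (!object@lengthUnitSource %in% c("angstrom", "nm"))
    msgs <- c(msgs, "lengthUnitSource must be 'angstrom' or 'nm'")
  if (length(object@frames) > 1L) {
    # frames must agree on the solute (the averaged object); the
    # environment bead count may fluctuate frame to frame
    s1 <- object@frames[[1L]]@types[object@frames[[1L]]@soluteFlags]
    same <- vapply(object@frames, function(f) {
      identical(f@types[f@soluteFlags], s1)
    }, logical(1))
    if (!all(same))
      msgs <- c(msgs, "all frames must share solute bead count and types")
  }
  if (length(msgs)) msgs else TRUE
})

#' Atomic SLATM spectrum
#'
#' One bead's SLATM: one-body identity scalar, two-body radial histograms
#' (one per neighbor type) and three-body angular histograms (one per
#' unordered neighbor type pair). Two-body entries are nonnegative;
#' three-body entries may be negative (ATM sign).
#'
#' @slot centerType type name of the center bead.
#' @slot oneBody numeric scalar, the identity number Z of the center.
#' @slot twoBody numeric matrix, radial bins x N types (columns named).
#' @slot threeBody numeric matrix, angular bins x N(N+1)/2 pairs
#'   (columns named by pair key).
#' @slot params the [SlatmParams-class] used.
#' @export
setClass("AtomicSpectrum",
  representation(
    centerType = "character",
    oneBody = "numeric",
    twoBody = "matrix",
    threeBody = "matrix",
    params = "SlatmParams"
  )
)

setValidity("AtomicSpectrum", function(object) {
  msgs <- character(0)
  if (!all(is.finite(object@twoBody)) || !all(is.finite(object@threeBody)))
    msgs <- c(msgs, "histogram entries must be finite")
  if (length(object@twoBody) && min(object@twoBody) < 0)
    msgs <- c(msgs, "two-body entries must be nonnegative")
  if (length(msgs)) msgs else TRUE
})

#' Ensemble-averaged, solute-summed molecular SLATM
#'
#' Boltzmann-proxy time average over frames of each solute bead's atomic
#' spectrum, summed over the solute beads. Channels are keyed by the
#' [ChannelIndex-class]: one-body per type, two-body per unordered type
#' pair, three-body per (center type, unordered neighbor pair).
#'
#' @slot oneBody named numeric of length N (per-type count x Z).
#' @slot twoBody numeric matrix, radial bins x N(N+1)/2 pair channels.
#' @slot threeBody numeric matrix, angular bins x triplet channels.
#' @slot nFramesUsed number of frames entering the time average.
#' @slot soluteBeadCount number of solute beads summed.
#' @slot params the [SlatmParams-class] used.
#' @slot channelIndex the [ChannelIndex-class] fixing channel order.
#' @export
setClass("MolecularSLATM",
  representation(
    oneBody = "numeric",
    twoBody = "matrix",
    threeBody = "matrix",
    nFramesUsed = "integer",
    soluteBeadCount = "integer",
    params = "SlatmParams",
    channelIndex = "ChannelIndex"
  )
)

setValidity("MolecularSLATM", function(object) {
  msgs <- character(0)
  if (object@nFramesUsed < 1L) msgs <- c(msgs, "nFramesUsed must be >= 1")
  if (object@soluteBeadCount < 1L)
    msgs <- c(msgs, "soluteBeadCount must be >= 1")
  ci <- object@channelIndex
  if (length(object@oneBody) != length(ci@oneBody))
    msgs <- c(msgs, "one-body block does not match channel index")
  if (ncol(object@twoBody) != nrow(ci@twoBody))
    msgs <- c(msgs, "two-body block does not match channel index")
  if (ncol(object@threeBody) != nrow(ci@threeBody))
    msgs <- c(msgs, "three-body block does not match channel index")
  if (length(msgs)) msgs else TRUE
})

#' Collapsed per-channel feature vector
#'
#' One scalar per channel of the [ChannelIndex-class], obtained by
#' collapsing each histogram (see [collapseChannels()]); one-body channels
#' pass through unchanged.
#'
#' @slot values numeric vector of length D, named by channel key.
#' @slot reductionMode the collapse mode used.
#' @slot epsilon regularizer recorded for downstream log transforms.
#' @slot channelKeys character vector of channel keys (ordering).
#' @export
setClass("FeatureVector",
  representation(
    values = "numeric",
    reductionMode = "character",
    epsilon = "numeric",
    channelKeys = "character"
  )
)

setValidity("FeatureVector", function(object) {
  msgs <- character(0)
  if (length(object@values) != length(object@channelKeys))
    msgs <- c(msgs, "values and channelKeys lengths differ")
  if (length(object@values) && !all(is.finite(object@values)))
    msgs <- c(msgs, "feature values must be finite")
  if (length(msgs)) msgs else TRUE
})

#' Per-compound log-difference vector between two environments
#'
#' \eqn{\Delta_c = \ln(s_c^A + \epsilon) - \ln(s_c^B + \epsilon)} per
#' channel, anti-symmetric under swapping the environment labels.
#'
#' @slot values numeric vector of length D, named by channel key.
#' @slot compoundId compound identifier.
#' @slot envPair length-2 character, target then reference environment.
#' @slot reductionMode,epsilon provenance of the collapse and log.
#' @slot signedLog whether the signed-log transform was used.
#' @slot channelKeys channel key ordering.
#' @export
setClass("DifferenceVector",
  representation(
    values = "numeric",
    compoundId = "character",
    envPair = "character",
    reductionMode = "character",
    epsilon = "numeric",
    signedLog = "logical",
    channelKeys = "character"
  )
)

setValidity("DifferenceVector", function(object) {
  msgs <- character(0)
  if (length(object@values) != length(object@channelKeys))
    msgs <- c(msgs, "values and channelKeys lengths differ")
  if (length(object@values) && !all(is.finite(object@values)))
    msgs <- c(msgs, "difference values must be finite")
  if (length(object@envPair) != 2L)
    msgs <- c(msgs, "envPair must have exactly two labels")
  if (length(msgs)) msgs else TRUE
})

#' Fitted PCA model of the difference matrix
#'
#' Column means, eigenvalues (variances of the principal components),
#' unit-norm eigenvectors and training scores of a centered, unscaled PCA
#' of the n x D difference matrix. Sign-fixed so each eigenvector's
#' largest-magnitude entry is positive.
#'
#' @slot center D-vector of column means.
#' @slot eigenvalues retained eigenvalues, descending.
#' @slot rotation D x d matrix of eigenvectors (columns).
#' @slot scores n x d training score matrix Y = X V.
#' @slot explainedVarianceRatios eigenvalue / total variance.
#' @slot totalVariance sum of all D eigenvalues.
#' @slot seed integer seed recorded at fit time.
#' @export
setClass("PcaModel",
  representation(
    center = "numeric",
    eigenvalues = "numeric",
    rotation = "matrix",
    scores = "matrix",
    explainedVarianceRatios = "numeric",
    totalVariance = "numeric",
    seed = "integer"
  )
)

setValidity("PcaModel", function(object) {
  msgs <- character(0)
  d <- ncol(object@rotation)
  if (length(object@eigenvalues) != d ||
      length(object@explainedVarianceRatios) != d)
    msgs <- c(msgs, "eigenvalues/ratios must match retained components")
  if (d > 1L && any(diff(object@eigenvalues) > 1e-10))
    msgs <- c(msgs, "eigenvalues must be descending")
  if (any(object@explainedVarianceRatios < -1e-12) ||
      sum(object@explainedVarianceRatios) > 1 + 1e-8)
    msgs <- c(msgs, "explained ratios must lie in [0,1] and sum to <= 1")
  ortho <- crossprod(object@rotation)
  if (d && max(abs(ortho - diag(d))) > 1e-10)
    msgs <- c(msgs, "eigenvectors must be orthonormal")
  if (length(msgs)) msgs else TRUE
})

#' Synthetic study specification
#'
#' Parameters of the synthetic two-environment bead system: solutes of
#' 1-5 beads embedded in type-dependent radial shells of lipid/solvent
#' beads, two environment variants that differ only in the planted
#' channel's shell occupancy, and a planted selectivity target.
#'
#' @slot nCompounds number of compounds.
#' @slot beadsRange integer length-2, solute size range.
#' @slot soluteAlphabet solute bead types.
#' @slot envTypes environment bead types (shared by both environments).
#' @slot shellTable data.frame with columns \code{soluteType},
#'   \code{envType}, \code{count}, \code{radius}, \code{jitter}
#'   (counts are Poisson means; radii/jitter in Angstrom).
#' @slot plantedChannel length-2 character, the planted two-body channel
#'   (solute type, environment type).
#' @slot plantedEffect log-scale effect size; per-compound contrasts are
#'   drawn Uniform(-1, 1) x effect.
#' @slot noiseFraction noise SD on the target as a fraction of signal SD.
#' @slot beta linear coefficient linking contrast to the target.
#' @slot nFrames i.i.d. frames per compound per environment.
#' @slot seed master seed.
#' @export
setClass("SyntheticSpec",
  representation(
    nCompounds = "integer",
    beadsRange = "integer",
    soluteAlphabet = "character",
    envTypes = "character",
    shellTable = "data.frame",
    plantedChannel = "character",
    plantedEffect = "numeric",
    noiseFraction = "numeric",
    beta = "numeric",
    nFrames = "integer",
    seed = "integer"
  )
)

setValidity("SyntheticSpec", function(object) {
  msgs <- character(0)
  if (object@nCompounds < 1L) msgs <- c(msgs, "nCompounds must be >= 1")
  if (length(object@beadsRange) != 2L ||
      object@beadsRange[1L] < 1L ||
      object@beadsRange[2L] < object@beadsRange[1L])
    msgs <- c(msgs, "beadsRange must be an increasing positive pair")
  if (object@nFrames < 1L) msgs <- c(msgs, "nFrames must be >= 1")
  needed <- c("soluteType", "envType", "count", "radius", "jitter")
  if (!all(needed %in% names(object@shellTable)))
    msgs <- c(msgs, "shellTable missing required columns")
  else if (any(object@shellTable$radius >= 11))
    msgs <- c(msgs, "shell radii must stay inside the 11 A extraction shell")
  if (length(object@plantedChannel) != 2L)
    msgs <- c(msgs, "plantedChannel must be (solute type, env type)")
  if (length(msgs)) msgs else TRUE
})
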