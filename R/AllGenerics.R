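#' @rdname BeadTypeRegistry-class
#' @param x a \code{BeadTypeRegistry}.
#' @export
setGeneric("beadTypes", function(x) standardGeneric("beadTypes"))

#' @rdname BeadTypeRegistry-class
#' @export
setGeneric("beadZ", function(x) standardGeneric("beadZ"))

#' @rdname BeadTypeRegistry-class
#' @export
setGeneric("beadCategory", function(x) standardGeneric("beadCategory"))

#' @rdname BeadTypeRegistry-class
#' @export
setGeneric("nBeadTypes", function(x) standardGeneric("nBeadTypes"))

#' @rdname ChannelIndex-class
#' @param x a \code{ChannelIndex} (or object carrying one).
#' @param body which channel block: "one", "two", "three" or "all".
#' @export
setGeneric("channelKeys", function(x, body = "all") {
  standardGeneric("channelKeys")
})

#' @rdname ChannelIndex-class
#' @export
setGeneric("channelCounts", function(x) standardGeneric("channelCounts"))

#' Number of frames in an ensemble
#' @param x a \code{TrajectoryEnsemble}.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Collapsed feature values
#' @param x a \code{FeatureVector} or \code{DifferenceVector}.
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @describeIn BeadTypeRegistry-class registered type names.
setMethod("beadTypes", "BeadTypeRegistry", function(x) x@typeName)

#' @describeIn BeadTypeRegistry-class named Z identity numbers.
setMethod("beadZ", "BeadTypeRegistry", function(x) {
  setNames(x@Z, x@typeName)
})

#' @describeIn BeadTypeRegistry-class named categories.
setMethod("beadCategory", "BeadTypeRegistry", function(x) {
  setNames(x@category, x@typeName)
})

#' @describeIn BeadTypeRegistry-class number of registered types.
setMethod("nBeadTypes", "BeadTypeRegistry", function(x) {
  length(x@typeName)
})

#' @describeIn ChannelIndex-class channel keys of a block (or all,
#'   concatenated in one/two/three order).
setMethod("channelKeys", "ChannelIndex", function(x, body = "all") {
  one <- x@oneBody
  two <- paste(x@twoBody[, 1L], x@twoBody[, 2L], sep = ":")
  three <- paste0(
    x@threeBody[, 1L], ">",
    x@threeBody[, 2L], ":", x@threeBody[, 3L]
  )
  switch(match.arg(body, c("all", "one", "two", "three")),
    one = one, two = two, three = three,
    all = c(one, two, three)
  )
})

#' @describeIn ChannelIndex-class named counts of the three blocks.
setMethod("channelCounts", "ChannelIndex", function(x) {
  c(
    oneBody = length(x@oneBody),
    twoBody = nrow(x@twoBody),
    threeBody = nrow(x@threeBody)
  )
})

#' @describeIn TrajectoryEnsemble-class number of frames.
setMethod("nFrames", "TrajectoryEnsemble", function(x) length(x@frames))

#' @describeIn FeatureVector-class named channel scalars.
setMethod("featureValues", "FeatureVector", function(x) {
  setNames(x@values, x@channelKeys)
})

#' @describeIn DifferenceVector-class named channel differences.
setMethod("featureValues", "DifferenceVector", function(x) {
  setNames(x@values, x@channelKeys)
})

setMethod("show", "BeadTypeRegistry", function(object) {
  cat(sprintf(
    "BeadTypeRegistry with %d bead types\n", length(object@typeName)
  ))
  cat("  types:", paste(object@typeName, collapse = " "), "\n")
  cat(
    "  categories:",
    paste(sprintf(
      "%s=%d", names(table(object@category)), table(object@category)
    ), collapse = " "), "\n"
  )
})

setMethod("show", "ChannelIndex", function(object) {
  cc <- channelCounts(object)
  cat(sprintf(
    "ChannelIndex: %d one-body, %d two-body, %d three-body channels (policy '%s')\n",
    cc[["oneBody"]], cc[["twoBody"]], cc[["threeBody"]],
    object@tripletPolicy
  ))
})

setMethod("show", "SlatmParams", function(object) {
  cat(sprintf(
    paste0(
      "SlatmParams: sigma_r=%.3g A, sigma_theta=%.3g rad, ",
      "bins %.3g A / %.3g rad, r_cutoff=%.3g A\n"
    ),
    object@sigmaR, object@sigmaTheta, object@binWidthR,
    object@binWidthTheta, object@rCutoff
  ))
})

setMethod("show", "Configuration", function(object) {
  cat(sprintf(
    "Configuration: %d beads (%d solute), %s boundaries\n",
    nrow(object@positions), sum(object@soluteFlags),
    if (length(object@box)) "periodic" else "open"
  ))
})

setMethod("show", "TrajectoryEnsemble", function(object) {
  cat(sprintf(
    "TrajectoryEnsemble: %d frames, %d beads/frame (source unit: %s)\n",
    length(object@frames), nrow(object@frames[[1L]]@positions),
    object@lengthUnitSource
  ))
})

setMethod("show", "AtomicSpectrum", function(object) {
  cat(sprintf(
    "AtomicSpectrum for center type %s (Z=%g): %d radial x %d types, %d angular x %d pairs\n",
    object@centerType, object@oneBody,
    nrow(object@twoBody), ncol(object@twoBody),
    nrow(object@threeBody), ncol(object@threeBody)
  ))
})

setMethod("show", "MolecularSLATM", function(object) {
  cat(sprintf(
    "MolecularSLATM: %d solute beads averaged over %d frames; channels %d/%d/%d\n",
    object@soluteBeadCount, object@nFramesUsed,
    length(object@oneBody), ncol(object@twoBody), ncol(object@threeBody)
  ))
})

setMethod("show", "FeatureVector", function(object) {
  cat(sprintf(
    "FeatureVector: D=%d channels, mode '%s'\n",
    length(object@values), object@reductionMode
  ))
})

setMethod("show", "DifferenceVector", function(object) {
  cat(sprintf(
    "DifferenceVector '%s' (%s - %s): D=%d, |Delta|_2=%.4g\n",
    object@compoundId, object@envPair[1L], object@envPair[2L],
    length(object@values), sqrt(sum(object@values^2))
  ))
})

setMethod("show", "PcaModel", function(object) {
  d <- ncol(object@rotation)
  cat(sprintf(
    "PcaModel: n=%d, D=%d, d=%d components (%.1f%% variance)\n",
    nrow(object@scores), nrow(object@rotation), d,
    100 * sum(object@explainedVarianceRatios)
  ))
})

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf(
    "SyntheticSpec: %d compounds, %d-%d beads, %d frames, planted %s:%s (effect %.2g), seed %d\n",
    object@nCompounds, object@beadsRange[1L], object@beadsRange[2L],
    object@nFrames, object@plantedChannel[1L], object@plantedChannel[2L],
    object@plantedEffect, object@seed
  ))
})
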