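#' Collapse channel histograms to scalars
#'
#' Reduces each two-/three-body histogram of a molecular SLATM to one
#' scalar per channel; one-body channels pass through unchanged. Modes:
#' \describe{
#'   \item{total-mass}{\eqn{s_c = \sum_b h_{cb}} (default downstream).}
#'   \item{mean-mass}{\eqn{s_c = (\sum_b h_{cb}) / N_b}.}
#'   \item{weighted-coordinate}{\eqn{s_c = \sum_b h_{cb} u_b / \sum_b
#'     h_{cb}} with \eqn{u_b} the bin-center coordinate; 0 for empty
#'     channels.}
#' }
#'
#' @param mol a [MolecularSLATM-class].
#' @param mode collapse mode.
#' @return A [FeatureVector-class] of length D ordered by the channel
#'   index (one-body, two-body, three-body blocks).
#' @export
collapseChannels <- function(mol,
                             mode = c("total-mass", "mean-mass",
                                      "weighted-coordinate")) {
  stopifnot(is(mol, "MolecularSLATM"))
  mode <- match.arg(mode)
  collapse <- function(h, centers) {
    tot <- colSums(h)
    switch(mode,
      "total-mass" = tot,
      "mean-mass" = tot / nrow(h),
      "weighted-coordinate" = {
        num <- colSums(h * centers)
        ifelse(tot == 0, 0, num / tot)
      }
    )
  }
  two <- collapse(mol@twoBody, radialBinCenters(mol@params))
  three <- collapse(mol@threeBody, angularBinCenters(mol@params))
  keys <- channelKeys(mol@channelIndex)
  vals <- c(unname(mol@oneBody), unname(two), unname(three))
  new("FeatureVector",
    values = vals, reductionMode = mode, epsilon = NA_real_,
    channelKeys = keys
  )
}

# elementwise log transform used by logDifference; internal
.logTransform <- function(s, epsilon, signedLog) {
  if (signedLog) sign(s) * log(abs(s) + epsilon) else log(s + epsilon)
}

#' Log-difference vector between two environments
#'
#' Forms the per-compound structural order parameter
#' \eqn{\Delta_c = \ln(s_c^A + \epsilon) - \ln(s_c^B + \epsilon)}, where
#' A is the target environment and B the reference. The log compresses
#' the order-of-magnitude spread induced by the inverse-power weights;
#' the difference isolates what distinguishes the two liquids. The
#' result is anti-symmetric under swapping the environments.
#'
#' Three-body channels can be legitimately negative under total-/mean-
#' mass collapse (ATM sign). The default transform requires scalars
#' above \eqn{-\epsilon} and fails loudly otherwise; set
#' \code{signedLog = TRUE} to use the signed log
#' \eqn{\mathrm{sign}(s)\,\ln(|s| + \epsilon)} instead.
#'
#' @param fvA,fvB [FeatureVector-class] objects for the target (A) and
#'   reference (B) environments, sharing channel index and mode.
#' @param compoundId compound identifier (metadata).
#' @param envPair length-2 character naming the environments.
#' @param epsilon regularizer, default 1e-12 in the collapsed-scalar
#'   units.
#' @param signedLog use the signed-log transform (default FALSE).
#' @return A [DifferenceVector-class].
#' @export
logDifference <- function(fvA, fvB, compoundId = "compound",
                          envPair = c("A", "B"), epsilon = 1e-12,
                          signedLog = FALSE) {
  stopifnot(is(fvA, "FeatureVector"), is(fvB, "FeatureVector"))
  if (!identical(fvA@channelKeys, fvB@channelKeys))
    stop("feature vectors use different channel indices")
  if (!identical(fvA@reductionMode, fvB@reductionMode))
    stop("feature vectors use different reduction modes")
  if (epsilon <= 0) stop("epsilon must be positive")
  if (!signedLog) {
    bad <- fvA@values <= -epsilon | fvB@values <= -epsilon
    if (any(bad)) {
      stop(
        "channel scalar(s) at or below -epsilon (net-negative ",
        "three-body mass): ",
        paste(head(fvA@channelKeys[bad], 5L), collapse = ", "),
        if (sum(bad) > 5L) ", ..." else "",
        "; use signedLog = TRUE for the signed-log transform"
      )
    }
  }
  delta <- .logTransform(fvA@values, epsilon, signedLog) -
    .logTransform(fvB@values, epsilon, signedLog)
  new("DifferenceVector",
    values = delta, compoundId = as.character(compoundId),
    envPair = as.character(envPair),
    reductionMode = fvA@reductionMode, epsilon = epsilon,
    signedLog = signedLog, channelKeys = fvA@channelKeys
  )
}

#' Assemble per-compound difference vectors into a dataset
#'
#' Collapses each compound's molecular SLATM in the two environments,
#' forms log-difference vectors and stacks them into a channels x
#' compounds SummarizedExperiment. Under the channel index's
#' \code{"observed-only"} triplet policy, triplet channels whose
#' collapsed scalar is zero in every compound and both environments are
#' dropped here, before PCA.
#'
#' @param fvListA,fvListB lists of [FeatureVector-class], one per
#'   compound, for the target (A) and reference (B) environments.
#' @param channelIndex the shared [ChannelIndex-class].
#' @param compoundIds character vector of compound identifiers.
#' @param colData optional data.frame of per-compound metadata (e.g. the
#'   selectivity target), rows aligned with \code{compoundIds}.
#' @param envPair length-2 character naming the environments.
#' @param epsilon,signedLog passed to [logDifference()].
#' @return A \code{SummarizedExperiment} with assay \code{"delta"}
#'   (channels x compounds), rowData columns \code{channelKey} and
#'   \code{body}, and the dataset provenance in \code{metadata()}.
#' @export
assembleDataset <- function(fvListA, fvListB, channelIndex,
                            compoundIds = NULL, colData = NULL,
                            envPair = c("A", "B"), epsilon = 1e-12,
                            signedLog = FALSE) {
  n <- length(fvListA)
  if (n == 0L || length(fvListB) != n)
    stop("fvListA and fvListB must be nonempty and equally long")
  if (is.null(compoundIds)) compoundIds <- sprintf("compound%03d", seq_len(n))
  diffs <- lapply(seq_len(n), function(i) {
    logDifference(
      fvListA[[i]], fvListB[[i]], compoundId = compoundIds[i],
      envPair = envPair, epsilon = epsilon, signedLog = signedLog
    )
  })
  keys <- diffs[[1L]]@channelKeys
  delta <- vapply(diffs, function(d) d@values, numeric(length(keys)))
  dimnames(delta) <- list(keys, compoundIds)
  cc <- channelCounts(channelIndex)
  body <- rep(
    c("one", "two", "three"),
    times = c(cc[["oneBody"]], cc[["twoBody"]], cc[["threeBody"]])
  )
  keep <- rep(TRUE, length(keys))
  if (channelIndex@tripletPolicy == "observed-only") {
    sA <- vapply(fvListA, function(f) f@values, numeric(length(keys)))
    sB <- vapply(fvListB, function(f) f@values, numeric(length(keys)))
    observed <- rowSums(abs(sA)) > 0 | rowSums(abs(sB)) > 0
    keep <- body != "three" | observed
  }
  rd <- S4Vectors::DataFrame(channelKey = keys, body = body)
  cd <- if (is.null(colData)) {
    S4Vectors::DataFrame(compoundId = compoundIds)
  } else {
    S4Vectors::DataFrame(compoundId = compoundIds, colData)
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(delta = delta[keep, , drop = FALSE]),
    rowData = rd[keep, , drop = FALSE],
    colData = cd
  )
  S4Vectors::metadata(se) <- list(
    envPair = envPair, epsilon = epsilon, signedLog = signedLog,
    reductionMode = diffs[[1L]]@reductionMode,
    tripletPolicy = channelIndex@tripletPolicy,
    droppedChannels = keys[!keep]
  )
  se
}

#' Per-compound physicochemical descriptor table
#'
#' Builds the descriptor table used to interpret principal components:
#' counts of polar, charged and hydrogen-bond-like solute beads, solute
#' bead count, the l2 norm of each compound's difference vector, plus
#' any externally supplied columns (e.g. the selectivity target or a
#' water-octanol partitioning free energy). All count and norm
#' descriptors are normalized by the solute bead count, once.
#'
#' @param se dataset from [assembleDataset()].
#' @param soluteTypes list (one per compound) of solute bead type
#'   vectors.
#' @param registry a [BeadTypeRegistry-class] with physClass
#'   annotations.
#' @param extra optional data.frame of extra descriptor columns (already
#'   normalized as the caller intends), rows aligned with compounds.
#' @return data.frame, one row per compound.
#' @export
descriptorTable <- function(se, soluteTypes, registry, extra = NULL) {
  n <- ncol(se)
  if (length(soluteTypes) != n)
    stop("soluteTypes must have one entry per compound")
  pc <- setNames(registry@physClass, registry@typeName)
  countOf <- function(types, cls) sum(pc[types] %in% cls)
  beadCount <- vapply(soluteTypes, length, integer(1))
  tab <- data.frame(
    compoundId = colnames(se),
    beadCount = beadCount,
    polarFraction = vapply(
      soluteTypes, countOf, numeric(1), cls = "polar"
    ) / beadCount,
    chargedFraction = vapply(
      soluteTypes, countOf, numeric(1), cls = "charged"
    ) / beadCount,
    hbondFraction = vapply(
      soluteTypes, countOf, numeric(1), cls = "hbond"
    ) / beadCount,
    deltaNorm = sqrt(colSums(
      SummarizedExperiment::assay(se, "delta")^2
    )) / beadCount,
    row.names = NULL
  )
  if (!is.null(extra)) tab <- cbind(tab, extra)
  tab
}
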