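#' Boltzmann-proxy ensemble average of atomic spectra
#'
#' Approximates the Boltzmann-ensemble average of each solute bead's
#' atomic SLATM by a time average over trajectory frames: every frame is
#' first passed through [extractLocalEnvironment()], then each solute
#' bead's spectrum is computed and the arithmetic mean is taken
#' channel-wise and bin-wise across frames.
#'
#' @param traj a [TrajectoryEnsemble-class] with consistent solute beads.
#' @param params a [SlatmParams-class].
#' @param registry a [BeadTypeRegistry-class].
#' @param channelIndex optional [ChannelIndex-class] (consistency only).
#' @param radius local-environment retention radius (A), default 11.0.
#' @return List of averaged [AtomicSpectrum-class], one per solute bead
#'   (in bead order).
#' @export
ensembleAverage <- function(traj, params, registry, channelIndex = NULL,
                            radius = 11.0) {
  stopifnot(is(traj, "TrajectoryEnsemble"))
  nf <- length(traj@frames)
  if (nf == 0L) stop("empty trajectory")
  nSol <- sum(traj@frames[[1L]]@soluteFlags)
  if (nSol == 0L) stop("trajectory frames contain no solute beads")
  cache <- .slatmCache(params, registry)
  acc <- NULL
  for (f in traj@frames) {
    env <- .localEnvCore(
      f@positions, f@types, f@soluteFlags, f@box, radius
    )
    solIdx <- which(env$soluteFlags)
    if (length(solIdx) != nSol)
      stop("solute beads inconsistent across frames")
    tIdx <- match(env$types, cache$types)
    if (anyNA(tIdx)) {
      stop(
        "bead type(s) not in registry: ",
        paste(unique(env$types[is.na(tIdx)]), collapse = ", ")
      )
    }
    spectra <- lapply(solIdx, function(i) {
      .centerSpectraIdx(
        env$positions, tIdx, numeric(0), i, params, cache
      )
    })
    if (is.null(acc)) {
      acc <- spectra
    } else {
      for (s in seq_len(nSol)) {
        acc[[s]]$twoBody <- acc[[s]]$twoBody + spectra[[s]]$twoBody
        acc[[s]]$threeBody <- acc[[s]]$threeBody + spectra[[s]]$threeBody
      }
    }
  }
  solTypes <- traj@frames[[1L]]@types[traj@frames[[1L]]@soluteFlags]
  zmap <- setNames(as.numeric(registry@Z), registry@typeName)
  lapply(seq_len(nSol), function(s) {
    two <- acc[[s]]$twoBody / nf
    three <- acc[[s]]$threeBody / nf
    colnames(two) <- cache$types
    colnames(three) <- cache$pairKeys
    new("AtomicSpectrum",
      centerType = solTypes[s],
      oneBody = zmap[[solTypes[s]]],
      twoBody = two,
      threeBody = three,
      params = params
    )
  })
}

# exact params equality; internal
.sameParams <- function(a, b) {
  isTRUE(all.equal(
    c(a@sigmaR, a@sigmaTheta, a@binWidthR, a@binWidthTheta, a@rCutoff,
      a@londonPrefactor, a@londonExponent, a@atmPrefactor),
    c(b@sigmaR, b@sigmaTheta, b@binWidthR, b@binWidthTheta, b@rCutoff,
      b@londonPrefactor, b@londonExponent, b@atmPrefactor),
    tolerance = 0
  ))
}

#' Sum solute-bead spectra into a molecular SLATM
#'
#' Sums the (averaged) atomic spectra of all solute beads channel-wise:
#' the one-body block becomes per-type counts times Z; the two-body
#' contribution of a center of type I toward neighbors of type J
#' accumulates into the unordered pair channel \{I, J\}; a triplet
#' contribution accumulates into (center type, unordered neighbor pair).
#'
#' @param averagedSpectra list of [AtomicSpectrum-class] (the solute
#'   beads), all computed under identical parameters.
#' @param channelIndex a [ChannelIndex-class].
#' @param registry a [BeadTypeRegistry-class].
#' @param nFramesUsed number of frames behind the averages (metadata).
#' @return A [MolecularSLATM-class].
#' @export
molecularSum <- function(averagedSpectra, channelIndex, registry,
                         nFramesUsed = 1L) {
  if (!length(averagedSpectra))
    stop("at least one solute bead spectrum is required")
  p0 <- averagedSpectra[[1L]]@params
  same <- vapply(
    averagedSpectra, function(s) .sameParams(s@params, p0), logical(1)
  )
  if (!all(same))
    stop("spectra computed under different SLATM parameters")
  types <- registry@typeName
  zmap <- setNames(as.numeric(registry@Z), types)
  pairKeysAll <- channelKeys(channelIndex, "two")
  tripKeysAll <- channelKeys(channelIndex, "three")
  nbR <- nrow(averagedSpectra[[1L]]@twoBody)
  nbT <- nrow(averagedSpectra[[1L]]@threeBody)
  oneBody <- setNames(numeric(length(types)), types)
  twoBody <- matrix(0, nbR, length(pairKeysAll),
    dimnames = list(NULL, pairKeysAll)
  )
  threeBody <- matrix(0, nbT, length(tripKeysAll),
    dimnames = list(NULL, tripKeysAll)
  )
  for (sp in averagedSpectra) {
    ct <- sp@centerType
    oneBody[ct] <- oneBody[ct] + zmap[[ct]]
    for (j in colnames(sp@twoBody)) {
      key <- .pairKey(registry, ct, j)
      twoBody[, key] <- twoBody[, key] + sp@twoBody[, j]
    }
    tk <- paste0(ct, ">", colnames(sp@threeBody))
    keep <- tk %in% tripKeysAll
    if (!all(keep)) {
      nz <- colSums(abs(sp@threeBody[, !keep, drop = FALSE])) > 0
      if (any(nz))
        stop("triplet channel(s) missing from index: ",
             paste(tk[!keep][nz], collapse = ", "))
    }
    threeBody[, tk[keep]] <- threeBody[, tk[keep]] +
      sp@threeBody[, keep, drop = FALSE]
  }
  new("MolecularSLATM",
    oneBody = oneBody, twoBody = twoBody, threeBody = threeBody,
    nFramesUsed = as.integer(nFramesUsed),
    soluteBeadCount = length(averagedSpectra),
    params = p0, channelIndex = channelIndex
  )
}

#' Featurize a trajectory into a molecular SLATM
#'
#' Convenience wrapper: ensemble-average the solute beads' atomic
#' spectra over the frames and sum them into the molecular
#' representation.
#'
#' @inheritParams ensembleAverage
#' @param channelIndex a [ChannelIndex-class].
#' @return A [MolecularSLATM-class].
#' @export
featurizeEnsemble <- function(traj, params, registry, channelIndex,
                              radius = 11.0) {
  avg <- ensembleAverage(traj, params, registry, channelIndex, radius)
  molecularSum(avg, channelIndex, registry,
    nFramesUsed = length(traj@frames)
  )
}
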