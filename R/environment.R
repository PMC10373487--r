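# minimum-image displacement of points relative to a reference under an
# orthorhombic box; internal
.minimumImage <- function(disp, box) {
  if (!length(box)) return(disp)
  for (k in 1:3) {
    disp[, k] <- disp[, k] - box[k] * round(disp[, k] / box[k])
  }
  disp
}

#' Extract the local environment around the solute
#'
#' Recenters a frame on the solute centroid and keeps the solute beads
#' plus every bead whose minimum-image distance to any solute bead is at
#' most \code{radius} (inclusive boundary). When a box is present the
#' solute is first made whole by minimum-image unwrapping relative to its
#' first bead, and environment beads are imaged relative to the centroid;
#' the returned configuration is open-boundary (the retained cluster is
#' compact by construction). The default radius of 11 A follows the
#' 1.1 nm information shell used for condensed-phase featurization.
#'
#' @param frame a [Configuration-class] with at least one solute bead.
#' @param radius retention radius in Angstrom (default 11.0).
#' @return A [Configuration-class], centered and truncated.
#' @export
extractLocalEnvironment <- function(frame, radius = 11.0) {
  stopifnot(is(frame, "Configuration"), radius >= 0)
  env <- .localEnvCore(
    frame@positions, frame@types, frame@soluteFlags, frame@box, radius
  )
  configuration(env$positions, env$types, env$soluteFlags, numeric(0))
}

# plain-vector core of the extraction, shared with the featurization
# hot path; internal
.localEnvCore <- function(pos, types, flags, box, radius) {
  sol <- which(flags)
  if (!length(sol)) stop("frame contains no solute beads")
  solPos <- pos[sol, , drop = FALSE]
  if (length(box)) {
    ref <- solPos[rep(1L, nrow(solPos)), , drop = FALSE]
    solPos <- ref + .minimumImage(solPos - ref, box)
  }
  centroid <- colMeans(solPos)
  solPos <- sweep(solPos, 2L, centroid)
  envIdx <- setdiff(seq_len(nrow(pos)), sol)
  envPos <- sweep(pos[envIdx, , drop = FALSE], 2L, centroid)
  if (length(box)) envPos <- .minimumImage(envPos, box)
  keep <- logical(length(envIdx))
  if (length(envIdx)) {
    for (s in seq_len(nrow(solPos))) {
      d2 <- rowSums(sweep(envPos, 2L, solPos[s, ])^2)
      keep <- keep | d2 <= radius^2
      if (all(keep)) break
    }
  }
  idx <- c(sol, envIdx[keep])
  ord <- order(idx)
  idx <- idx[ord]
  allPos <- rbind(solPos, envPos[keep, , drop = FALSE])[ord, , drop = FALSE]
  list(
    positions = allPos, types = types[idx], soluteFlags = flags[idx]
  )
}

#' Select the k best-scoring frames
#'
#' Keeps the \code{k} frames with the smallest score (for instance the
#' distance of the solute to a target insertion depth), breaking ties by
#' earlier frame index, and preserves the original frame order among the
#' kept frames. Mirrors the practice of gathering equidistant snapshots
#' and retaining the subset closest to the target depth.
#'
#' @param traj a [TrajectoryEnsemble-class].
#' @param frameScores numeric vector, one score per frame (smaller is
#'   better).
#' @param k number of frames to keep.
#' @return A [TrajectoryEnsemble-class] with \code{k} frames.
#' @export
selectFrames <- function(traj, frameScores, k) {
  stopifnot(is(traj, "TrajectoryEnsemble"))
  n <- length(traj@frames)
  if (length(frameScores) != n)
    stop("frameScores length must equal the frame count")
  if (k < 1L || k > n)
    stop("k must lie in 1..", n)
  keep <- sort(order(frameScores)[seq_len(k)])
  trajectoryEnsemble(
    traj@frames[keep],
    frameIndices = traj@frameIndices[keep],
    lengthUnitSource = traj@lengthUnitSource
  )
}

#' Insertion-depth frame scores
#'
#' Helper producing the frame score used by [selectFrames()] for
#' membrane insertion studies: the absolute z-distance of the solute
#' centroid to a reference plane.
#'
#' @param traj a [TrajectoryEnsemble-class].
#' @param planeZ z-coordinate of the reference plane (A), default 0.
#' @return Numeric vector of per-frame scores.
#' @export
soluteDepthScores <- function(traj, planeZ = 0) {
  vapply(traj@frames, function(f) {
    sol <- which(f@soluteFlags)
    if (!length(sol)) stop("frame contains no solute beads")
    abs(mean(f@positions[sol, 3L]) - planeZ)
  }, numeric(1))
}
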