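#' SLATM parameters
#'
#' Constructor with the condensed-phase coarse-grained defaults:
#' Gaussian widths 0.3 A / 0.2 rad, bin widths 0.2 A / 0.2 rad and an
#' 8.0 A radial cutoff. The London and Axilrod-Teller-Muto weight
#' prefactors and the London exponent are overridable.
#'
#' @param sigmaR radial kernel width (A).
#' @param sigmaTheta angular kernel width (rad).
#' @param binWidthR radial bin width (A).
#' @param binWidthTheta angular bin width (rad).
#' @param rCutoff radial cutoff (A).
#' @param londonPrefactor prefactor of the two-body weight (default 1/2).
#' @param londonExponent inverse-power exponent (default 6).
#' @param atmPrefactor prefactor of the three-body weight (default 1/3).
#' @return A [SlatmParams-class].
#' @export
slatmParams <- function(sigmaR = 0.3, sigmaTheta = 0.2,
                        binWidthR = 0.2, binWidthTheta = 0.2,
                        rCutoff = 8.0,
                        londonPrefactor = 0.5, londonExponent = 6,
                        atmPrefactor = 1 / 3) {
  new("SlatmParams",
    sigmaR = sigmaR, sigmaTheta = sigmaTheta,
    binWidthR = binWidthR, binWidthTheta = binWidthTheta,
    rCutoff = rCutoff,
    londonPrefactor = londonPrefactor,
    londonExponent = londonExponent,
    atmPrefactor = atmPrefactor
  )
}

#' Radial and angular bin centers
#'
#' The radial axis is binned over \eqn{[0, r_{cutoff}]} with
#' \eqn{N_b^{(2)} = \lceil r_{cutoff} / w_r \rceil} bins; the angular
#' axis over \eqn{[0, \pi]} with \eqn{\lceil \pi / w_\theta \rceil} bins.
#'
#' @param params a [SlatmParams-class].
#' @return Numeric vector of bin centers.
#' @export
radialBinCenters <- function(params) {
  nb <- ceiling(params@rCutoff / params@binWidthR)
  (seq_len(nb) - 0.5) * params@binWidthR
}

#' @rdname radialBinCenters
#' @export
angularBinCenters <- function(params) {
  nb <- ceiling(pi / params@binWidthTheta)
  (seq_len(nb) - 0.5) * params@binWidthTheta
}

#' Discretized unit-mass Gaussian kernel
#'
#' Distributes a unit-mass Gaussian centered at \code{value} over uniform
#' bins. Each bin receives the exact Gaussian integral over its support
#' (CDF differences), so the profile sums to 1 whenever the kernel lies
#' inside the binned range, for every \code{sigma} including the narrow
#' (delta) limit. Optional reflective bounds fold the tails of kernels
#' near the ends of a bounded domain (used for the angular axis on
#' \eqn{[0, \pi]}) back into range, preserving unit mass.
#'
#' @param value kernel center.
#' @param sigma kernel width (> 0).
#' @param binCenters uniformly spaced bin centers.
#' @param binWidth bin width.
#' @param reflect optional length-2 numeric c(lower, upper) giving
#'   reflective domain bounds; \code{NULL} (default) truncates.
#' @return Numeric vector of bin masses, one per bin center.
#' @export
gaussianBinProfile <- function(value, sigma, binCenters, binWidth,
                               reflect = NULL) {
  stopifnot(sigma > 0, binWidth > 0)
  lo <- binCenters - binWidth / 2
  hi <- binCenters + binWidth / 2
  if (!is.null(reflect)) {
    # bins may overshoot the bounded domain (e.g. pi is not a multiple
    # of the bin width); integrate each bin over its intersection with
    # the domain so reflected mass is not double-counted
    lo <- pmin(pmax(lo, reflect[1L]), reflect[2L])
    hi <- pmin(pmax(hi, reflect[1L]), reflect[2L])
  }
  prof <- pnorm(hi, value, sigma) - pnorm(lo, value, sigma)
  if (!is.null(reflect)) {
    prof <- prof +
      pnorm(hi, 2 * reflect[1L] - value, sigma) -
      pnorm(lo, 2 * reflect[1L] - value, sigma) +
      pnorm(hi, 2 * reflect[2L] - value, sigma) -
      pnorm(lo, 2 * reflect[2L] - value, sigma)
  }
  prof
}

# vectorized profile matrix: bins x values; internal
# edges has length nbins+1; reflect as in gaussianBinProfile. Reflection
# terms are only evaluated for values near a domain end (beyond ~7 sigma
# they are below double precision).
.profileMatrix <- function(values, sigma, edges, reflect = NULL) {
  if (!is.null(reflect))
    edges <- pmin(pmax(edges, reflect[1L]), reflect[2L])
  nb <- length(edges) - 1L
  cdfAt <- function(v) {
    C <- pnorm(outer(edges, v, "-") / sigma)
    C[-1L, , drop = FALSE] - C[-(nb + 1L), , drop = FALSE]
  }
  M <- cdfAt(values)
  if (!is.null(reflect)) {
    nearLo <- values < reflect[1L] + 7 * sigma
    if (any(nearLo)) {
      M[, nearLo] <- M[, nearLo, drop = FALSE] +
        cdfAt(2 * reflect[1L] - values[nearLo])
    }
    nearHi <- values > reflect[2L] - 7 * sigma
    if (any(nearHi)) {
      M[, nearHi] <- M[, nearHi, drop = FALSE] +
        cdfAt(2 * reflect[2L] - values[nearHi])
    }
  }
  M
}

# per-(params, registry) precomputation shared across centers/frames;
# internal
.slatmCache <- function(params, registry) {
  types <- registry@typeName
  n <- length(types)
  nbR <- ceiling(params@rCutoff / params@binWidthR)
  nbT <- ceiling(pi / params@binWidthTheta)
  pairIdx <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
  pairIdx <- pairIdx[order(pairIdx[, 1L], pairIdx[, 2L]), , drop = FALSE]
  pairCol <- matrix(0L, n, n)
  pairCol[pairIdx] <- seq_len(nrow(pairIdx))
  pairCol <- pairCol + t(pairCol) - diag(diag(pairCol))
  list(
    types = types,
    n = n,
    z = as.numeric(registry@Z),
    nbR = nbR,
    nbT = nbT,
    edgesR = seq(0, nbR * params@binWidthR, by = params@binWidthR),
    edgesT = seq(0, nbT * params@binWidthTheta,
      by = params@binWidthTheta
    ),
    pairKeys = paste(
      types[pairIdx[, 1L]], types[pairIdx[, 2L]], sep = ":"
    ),
    nPairs = nrow(pairIdx),
    pairCol = pairCol
  )
}

# hot path: spectra of center i on plain vectors (tIdx: integer type
# indices); returns unnamed matrices (bins x n, bins x nPairs); internal
.centerSpectraIdx <- function(pos, tIdx, box, i, params, cache) {
  twoBody <- matrix(0, cache$nbR, cache$n)
  threeBody <- matrix(0, cache$nbT, cache$nPairs)
  disp <- pos - rep(pos[i, ], each = nrow(pos))
  disp <- .minimumImage(disp, box)
  d <- sqrt(rowSums(disp^2))
  d[i] <- Inf
  if (any(d < 1e-6)) {
    stop(
      "coincident beads (distance < 1e-6 A) around center ", i,
      ": corrupt geometry"
    )
  }
  nb <- which(d <= params@rCutoff)
  if (!length(nb)) {
    return(list(twoBody = twoBody, threeBody = threeBody))
  }
  zi <- cache$z[tIdx[i]]
  dn <- d[nb]
  tn <- tIdx[nb]

  w2 <- params@londonPrefactor * zi * cache$z[tn] *
    dn^(-params@londonExponent)
  G <- .profileMatrix(dn, params@sigmaR, cache$edgesR)
  for (tt in unique(tn)) {
    sel <- tn == tt
    twoBody[, tt] <- G[, sel, drop = FALSE] %*% w2[sel]
  }

  if (length(nb) >= 2L) {
    pr <- combn(length(nb), 2L)
    j <- nb[pr[1L, ]]
    k <- nb[pr[2L, ]]
    relj <- disp[j, , drop = FALSE]
    relk <- disp[k, , drop = FALSE]
    dj <- d[j]
    dk <- d[k]
    djk2 <- rowSums((relk - relj)^2)
    if (any(djk2 < 1e-12)) {
      stop(
        "coincident beads (distance < 1e-6 A) in the neighborhood of ",
        "center ", i, ": corrupt geometry"
      )
    }
    djk <- sqrt(djk2)
    cosC <- pmin(1, pmax(-1, rowSums(relj * relk) / (dj * dk)))
    cosJ <- pmin(1, pmax(-1,
      rowSums(-relj * (relk - relj)) / (dj * djk)
    ))
    cosK <- pmin(1, pmax(-1,
      rowSums(-relk * (relj - relk)) / (dk * djk)
    ))
    theta <- acos(cosC)
    w3 <- params@atmPrefactor * zi * cache$z[tIdx[j]] *
      cache$z[tIdx[k]] *
      (1 + 3 * cosC * cosJ * cosK) / (dj * dk * djk)^3
    Gt <- .profileMatrix(theta, params@sigmaTheta, cache$edgesT,
      reflect = c(0, pi)
    )
    cols <- cache$pairCol[cbind(tIdx[j], tIdx[k])]
    acc <- rowsum(t(Gt) * w3, group = cols)
    threeBody[, as.integer(rownames(acc))] <- t(acc)
  }

  list(twoBody = twoBody, threeBody = threeBody)
}

# per-center computation on a Configuration: two-body (bins x N types)
# and three-body (bins x N(N+1)/2 pair channels) histograms with named
# columns; internal
.centerSpectra <- function(config, i, params, registry, cache = NULL) {
  if (is.null(cache)) cache <- .slatmCache(params, registry)
  tIdx <- .typeIndex(registry, config@types)
  sp <- .centerSpectraIdx(
    config@positions, tIdx, config@box, i, params, cache
  )
  colnames(sp$twoBody) <- cache$types
  colnames(sp$threeBody) <- cache$pairKeys
  sp
}

#' Two-body radial spectrum of one bead
#'
#' Population of pairwise interactions between the center bead and all
#' beads of type \code{neighborType} within the radial cutoff, as a
#' function of distance: each neighbor contributes a unit-mass Gaussian
#' at \eqn{R_{ij}} scaled by the London weight
#' \eqn{w_{ij} = 1/2\, Z_I Z_J R_{ij}^{-6}}. The center is never its own
#' neighbor; neighbors beyond the cutoff contribute nothing.
#'
#' @param config a [Configuration-class].
#' @param centerIndex index of the center bead.
#' @param neighborType registered type name of the neighbors.
#' @param params a [SlatmParams-class].
#' @param registry a [BeadTypeRegistry-class].
#' @return Numeric radial histogram vector (length \eqn{N_b^{(2)}}).
#' @export
twoBodySpectrum <- function(config, centerIndex, neighborType, params,
                            registry) {
  stopifnot(
    centerIndex >= 1L, centerIndex <= nrow(config@positions)
  )
  .typeIndex(registry, neighborType)
  sp <- .centerSpectra(config, centerIndex, params, registry)
  unname(sp$twoBody[, neighborType])
}

#' Three-body angular spectrum of one bead
#'
#' Population of triplet interactions between the center bead and all
#' unordered pairs of in-cutoff neighbors of types \code{neighborPair},
#' as a function of the angle at the center: each pair contributes a
#' unit-mass Gaussian at \eqn{\theta_{jik}} (reflected at the domain ends
#' 0 and \eqn{\pi}) scaled by the Axilrod-Teller-Muto weight
#' \eqn{v_{ijk} = 1/3\, Z_I Z_J Z_K
#' (1 + 3\cos\theta_{jik}\cos\theta_{ijk}\cos\theta_{ikj}) /
#' (R_{ij} R_{ik} R_{jk})^3}. The averaging over interparticle distances
#' is carried by the distance factors inside the weight; there is no
#' separate distance binning. Both center-neighbor legs must lie within
#' the cutoff; the neighbor-neighbor distance is unconstrained. Collinear
#' triplets are handled analytically (cosines clamped to +-1); entries
#' may be negative.
#'
#' @inheritParams twoBodySpectrum
#' @param neighborPair length-2 character vector of neighbor types
#'   (unordered).
#' @return Numeric angular histogram vector.
#' @export
threeBodySpectrum <- function(config, centerIndex, neighborPair, params,
                              registry) {
  stopifnot(
    centerIndex >= 1L, centerIndex <= nrow(config@positions),
    length(neighborPair) == 2L
  )
  key <- .pairKey(registry, neighborPair[1L], neighborPair[2L])
  sp <- .centerSpectra(config, centerIndex, params, registry)
  unname(sp$threeBody[, key])
}

#' Full atomic SLATM of one bead
#'
#' Concatenates the one-body identity \eqn{Z_I} with every two-body
#' channel (N radial histograms) and every three-body channel
#' (N(N+1)/2 angular histograms) in the deterministic order of the
#' registry, with zero vectors where no neighbors exist.
#'
#' @inheritParams twoBodySpectrum
#' @param channelIndex optional [ChannelIndex-class] (consistency only;
#'   built from the registry if missing).
#' @return An [AtomicSpectrum-class].
#' @export
atomicSlatm <- function(config, centerIndex, params, registry,
                        channelIndex = NULL) {
  stopifnot(
    centerIndex >= 1L, centerIndex <= nrow(config@positions)
  )
  sp <- .centerSpectra(config, centerIndex, params, registry)
  zmap <- setNames(as.numeric(registry@Z), registry@typeName)
  new("AtomicSpectrum",
    centerType = config@types[centerIndex],
    oneBody = zmap[[config@types[centerIndex]]],
    twoBody = sp$twoBody,
    threeBody = sp$threeBody,
    params = params
  )
}
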