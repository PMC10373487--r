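# Independent, unoptimized reference implementation of the SLATM
# spectra: scalar loops, no shared code with the package internals.
# Conventions mirrored deliberately: bin-integrated Gaussian kernels,
# angular reflection at 0 and pi with bins intersected with [0, pi],
# London weight 1/2 Zi Zj R^-6, ATM weight
# 1/3 Zi Zj Zk (1 + 3 cos cos cos) / (Rij Rik Rjk)^3.

oracleProfile <- function(value, sigma, edges, angular = FALSE) {
  nb <- length(edges) - 1L
  out <- numeric(nb)
  for (b in seq_len(nb)) {
    lo <- edges[b]
    hi <- edges[b + 1L]
    if (angular) {
      lo <- min(max(lo, 0), pi)
      hi <- min(max(hi, 0), pi)
    }
    m <- pnorm(hi, value, sigma) - pnorm(lo, value, sigma)
    if (angular) {
      m <- m + pnorm(hi, -value, sigma) - pnorm(lo, -value, sigma)
      m <- m + pnorm(hi, 2 * pi - value, sigma) -
        pnorm(lo, 2 * pi - value, sigma)
    }
    out[b] <- m
  }
  out
}

oracleAtomicSlatm <- function(config, center, params, registry) {
  types <- registry@typeName
  zs <- setNames(as.numeric(registry@Z), types)
  n <- length(types)
  pos <- config@positions
  ct <- config@types
  nbR <- ceiling(params@rCutoff / params@binWidthR)
  nbT <- ceiling(pi / params@binWidthTheta)
  edgesR <- (0:nbR) * params@binWidthR
  edgesT <- (0:nbT) * params@binWidthTheta
  pairKeys <- character(0)
  for (a in seq_len(n)) {
    for (b in a:n) {
      pairKeys <- c(pairKeys, paste(types[a], types[b], sep = ":"))
    }
  }
  two <- matrix(0, nbR, n, dimnames = list(NULL, types))
  three <- matrix(0, nbT, length(pairKeys),
    dimnames = list(NULL, pairKeys)
  )
  nAll <- nrow(pos)
  distTo <- function(a, b) sqrt(sum((pos[a, ] - pos[b, ])^2))
  for (j in seq_len(nAll)) {
    if (j == center) next
    r <- distTo(center, j)
    if (r > params@rCutoff) next
    w <- 0.5 * zs[[ct[center]]] * zs[[ct[j]]] * r^(-6)
    two[, ct[j]] <- two[, ct[j]] +
      w * oracleProfile(r, params@sigmaR, edgesR)
  }
  for (j in seq_len(nAll)) {
    for (k in seq_len(nAll)) {
      if (j >= k || j == center || k == center) next
      rij <- distTo(center, j)
      rik <- distTo(center, k)
      if (rij > params@rCutoff || rik > params@rCutoff) next
      rjk <- distTo(j, k)
      cosC <- sum((pos[j, ] - pos[center, ]) * (pos[k, ] - pos[center, ])) /
        (rij * rik)
      cosJ <- sum((pos[center, ] - pos[j, ]) * (pos[k, ] - pos[j, ])) /
        (rij * rjk)
      cosK <- sum((pos[center, ] - pos[k, ]) * (pos[j, ] - pos[k, ])) /
        (rik * rjk)
      cosC <- min(1, max(-1, cosC))
      cosJ <- min(1, max(-1, cosJ))
      cosK <- min(1, max(-1, cosK))
      v <- (1 / 3) * zs[[ct[center]]] * zs[[ct[j]]] * zs[[ct[k]]] *
        (1 + 3 * cosC * cosJ * cosK) / (rij * rik * rjk)^3
      a <- ct[j]
      b <- ct[k]
      ia <- match(a, types)
      ib <- match(b, types)
      key <- if (ia <= ib) paste(a, b, sep = ":") else
        paste(b, a, sep = ":")
      three[, key] <- three[, key] +
        v * oracleProfile(acos(cosC), params@sigmaTheta, edgesT,
          angular = TRUE
        )
    }
  }
  list(twoBody = two, threeBody = three)
}

# random open-boundary configuration with a 2 A overlap floor
randomConfig <- function(nBeads, typePool, seed, halfWidth = 6) {
  set.seed(seed)
  pos <- matrix(NA_real_, nBeads, 3L)
  pos[1L, ] <- runif(3, -halfWidth, halfWidth)
  for (i in seq_len(nBeads)[-1L]) {
    repeat {
      cand <- runif(3, -halfWidth, halfWidth)
      d2 <- rowSums(
        sweep(pos[seq_len(i - 1L), , drop = FALSE], 2L, cand)^2
      )
      if (min(d2) >= 4) {
        pos[i, ] <- cand
        break
      }
    }
  }
  configuration(
    pos, sample(typePool, nBeads, replace = TRUE),
    soluteFlags = c(TRUE, rep(FALSE, nBeads - 1L))
  )
}

# small three-type registry reused across tests
testRegistry <- function() {
  buildRegistry(data.frame(
    type = c("T1", "Q0", "Nda"),
    category = c("solute", "solute", "lipid"),
    physClass = c("polar", "charged", NA)
  ))
}

maxRelDiff <- function(a, b) {
  scale <- max(abs(a), abs(b), 1e-300)
  max(abs(a - b)) / scale
}
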