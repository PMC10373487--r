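# coerce SE / matrix / DifferenceVector(s) to an n x D matrix; internal
.asSampleMatrix <- function(x) {
  if (is(x, "SummarizedExperiment")) {
    return(t(SummarizedExperiment::assay(x, "delta")))
  }
  if (is(x, "DifferenceVector")) {
    return(matrix(x@values, nrow = 1L, dimnames = list(
      x@compoundId, x@channelKeys
    )))
  }
  if (is.list(x) && length(x) && is(x[[1L]], "DifferenceVector")) {
    return(do.call(rbind, lapply(x, .asSampleMatrix)))
  }
  as.matrix(x)
}

#' Fit a PCA model of the difference matrix
#'
#' Centered, unscaled (no whitening) principal component analysis of the
#' n x D difference matrix, solving the eigenproblem of the sample
#' covariance via exact singular value decomposition. Eigenvectors are
#' sign-fixed so each one's largest-magnitude entry is positive, making
#' the fit reproducible; the seed is consumed and recorded so stochastic
#' decompositions could be swapped in without changing the interface.
#'
#' @param x n x D matrix (rows = compounds), a SummarizedExperiment from
#'   [assembleDataset()], or a list of [DifferenceVector-class].
#' @param d number of components to retain (<= min(n, D)).
#' @param seed integer seed, recorded in the model.
#' @return A [PcaModel-class].
#' @export
fitPca <- function(x, d, seed = 0L) {
  X <- .asSampleMatrix(x)
  n <- nrow(X)
  if (n < 2L) stop("PCA needs at least two samples")
  if (d < 1L || d > min(n, ncol(X)))
    stop("d must lie in 1..min(n, D)")
  set.seed(as.integer(seed))
  pr <- prcomp(X, center = TRUE, scale. = FALSE, rank. = d)
  totalVar <- sum(pr$sdev^2)
  if (totalVar <= 0)
    stop("matrix has zero total variance; PCA undefined")
  rot <- pr$rotation[, seq_len(d), drop = FALSE]
  sco <- pr$x[, seq_len(d), drop = FALSE]
  for (k in seq_len(d)) {
    imax <- which.max(abs(rot[, k]))
    if (rot[imax, k] < 0) {
      rot[, k] <- -rot[, k]
      sco[, k] <- -sco[, k]
    }
  }
  lam <- pr$sdev[seq_len(d)]^2
  new("PcaModel",
    center = pr$center,
    eigenvalues = lam,
    rotation = rot,
    scores = sco,
    explainedVarianceRatios = lam / totalVar,
    totalVariance = totalVar,
    seed = as.integer(seed)
  )
}

#' Project vectors onto a fitted PCA model
#'
#' Computes \eqn{Y = (x - \bar{x}) V}: training rows reproduce their
#' stored scores; the column-mean vector maps to the origin.
#'
#' @param model a [PcaModel-class].
#' @param x new data: matrix (rows = compounds), SummarizedExperiment,
#'   [DifferenceVector-class] or list thereof, sharing the training
#'   channel order.
#' @return n x d score matrix.
#' @export
projectScores <- function(model, x) {
  X <- .asSampleMatrix(x)
  if (ncol(X) != nrow(model@rotation))
    stop(
      "dimension mismatch: new vectors have ", ncol(X),
      " channels, model expects ", nrow(model@rotation)
    )
  sweep(X, 2L, model@center) %*% model@rotation
}

#' Scaled PC loadings
#'
#' The elements of eigenvector \eqn{v_k} magnified by the component's
#' standard deviation: \eqn{\ell_{kc} = v_{kc} \sqrt{\lambda_k}}. On
#' centered data these equal the covariances between channel c and score
#' k divided by \eqn{\sqrt{\lambda_k}}, i.e. they carry the channel's
#' contribution on the scale of the data, which is why interpretation
#' thresholds of magnitude 1 or more are meaningful here and not for raw
#' unit-norm loadings. Sorted by |scaled loading| descending; exact ties
#' break lexicographically by channel key.
#'
#' @param model a [PcaModel-class].
#' @param k component index (<= d).
#' @return data.frame with columns \code{channelKey}, \code{loading},
#'   \code{scaledLoading}.
#' @export
scaledLoadings <- function(model, k) {
  d <- ncol(model@rotation)
  if (k < 1L || k > d) stop("k must lie in 1..", d)
  v <- model@rotation[, k]
  keys <- rownames(model@rotation)
  if (is.null(keys)) keys <- sprintf("channel%05d", seq_along(v))
  ell <- v * sqrt(model@eigenvalues[k])
  ord <- order(-abs(ell), keys)
  data.frame(
    channelKey = keys[ord],
    loading = unname(v[ord]),
    scaledLoading = unname(ell[ord]),
    row.names = NULL
  )
}

#' Correlate a principal component with a descriptor
#'
#' Ordinary least squares of the descriptor on a single score vector;
#' returns the coefficient of determination and the slope sign (used to
#' decide which loading sign contributes to strong selectivity when the
#' target is a negative-is-better free-energy difference).
#'
#' @param scores numeric score vector (one component).
#' @param descriptor numeric descriptor vector, same length, n >= 3.
#' @return list with \code{r2}, \code{slope}, \code{slopeSign}.
#' @export
correlateScores <- function(scores, descriptor) {
  scores <- as.numeric(scores)
  descriptor <- as.numeric(descriptor)
  if (length(scores) != length(descriptor))
    stop("scores and descriptor lengths differ")
  if (length(scores) < 3L) stop("need at least 3 observations")
  if (var(descriptor) == 0) stop("descriptor has zero variance")
  if (var(scores) == 0) stop("score vector has zero variance")
  fit <- lm(descriptor ~ scores)
  slope <- unname(coef(fit)[2L])
  list(
    r2 = summary(fit)$r.squared,
    slope = slope,
    slopeSign = sign(slope)
  )
}

#' Dominant interaction channels of a component
#'
#' Channels whose scaled loading passes a threshold (default magnitude
#' 1.0): \code{sign = "negative"} keeps \eqn{\ell \le -t},
#' \code{"positive"} keeps \eqn{\ell \ge t}, \code{"both"} keeps
#' \eqn{|\ell| \ge t}; sorted by |scaled loading|.
#'
#' @inheritParams scaledLoadings
#' @param threshold positive magnitude threshold, default 1.0.
#' @param sign which loading sign to keep.
#' @return data.frame as [scaledLoadings()], filtered.
#' @export
dominantInteractions <- function(model, k, threshold = 1.0,
                                 sign = c("both", "negative",
                                          "positive")) {
  if (threshold <= 0) stop("threshold must be positive")
  sign <- match.arg(sign)
  tab <- scaledLoadings(model, k)
  keep <- switch(sign,
    negative = tab$scaledLoading <= -threshold,
    positive = tab$scaledLoading >= threshold,
    both = abs(tab$scaledLoading) >= threshold
  )
  tab[keep, , drop = FALSE]
}

# parse a channel key back into its constituent types; internal
.parseChannelKey <- function(key) {
  if (grepl(">", key, fixed = TRUE)) {
    parts <- strsplit(key, ">", fixed = TRUE)[[1L]]
    pair <- strsplit(parts[2L], ":", fixed = TRUE)[[1L]]
    list(body = "three", center = parts[1L], types = pair)
  } else if (grepl(":", key, fixed = TRUE)) {
    list(
      body = "two", center = NA_character_,
      types = strsplit(key, ":", fixed = TRUE)[[1L]]
    )
  } else {
    list(body = "one", center = NA_character_, types = key)
  }
}

#' Bead-interaction graph of dominant channels
#'
#' Projects a set of dominant channels onto a bead-type graph: a
#' two-body channel \{I, J\} adds edge I-J; a three-body channel
#' (I, \{J, K\}) adds the center-neighbor edges I-J and I-K (optionally
#' also the neighbor-neighbor edge J-K). Edge weights count occurrences
#' across the channel list; nodes carry the registry category and edges
#' a class (\code{solute-solute}, \code{solute-environment},
#' \code{environment} and a \code{solvent} flag) mirroring the usual
#' rendering (solute-solute edges highlighted, solvent edges dashed).
#'
#' @param channels character vector of channel keys (or a data.frame
#'   with a \code{channelKey} column, e.g. from
#'   [dominantInteractions()]).
#' @param channelIndex the [ChannelIndex-class] the keys belong to.
#' @param registry a [BeadTypeRegistry-class].
#' @param includeNeighborEdge also add the J-K leg of three-body
#'   channels (default FALSE).
#' @return An \pkg{igraph} graph (possibly empty); vertex attribute
#'   \code{category}; edge attributes \code{weight}, \code{provenance}
#'   (contributing channel keys, comma-separated), \code{class},
#'   \code{solvent}.
#' @export
buildInteractionGraph <- function(channels, channelIndex, registry,
                                  includeNeighborEdge = FALSE) {
  if (is.data.frame(channels)) channels <- channels$channelKey
  channels <- as.character(channels)
  valid <- channelKeys(channelIndex, "all")
  bad <- setdiff(channels, valid)
  if (length(bad))
    stop("channel key(s) not in index: ", paste(bad, collapse = ", "))
  cat2 <- setNames(registry@category, registry@typeName)
  edges <- list()
  addEdge <- function(a, b, key) {
    ia <- .typeIndex(registry, a)
    ib <- .typeIndex(registry, b)
    if (ia > ib) { tmp <- a; a <- b; b <- tmp }
    edges[[length(edges) + 1L]] <<- data.frame(
      from = a, to = b, key = key, stringsAsFactors = FALSE
    )
  }
  for (key in channels) {
    pk <- .parseChannelKey(key)
    if (pk$body == "two") {
      addEdge(pk$types[1L], pk$types[2L], key)
    } else if (pk$body == "three") {
      addEdge(pk$center, pk$types[1L], key)
      addEdge(pk$center, pk$types[2L], key)
      if (includeNeighborEdge) addEdge(pk$types[1L], pk$types[2L], key)
    }
  }
  if (!length(edges)) {
    g <- igraph::make_empty_graph(n = 0, directed = FALSE)
    return(g)
  }
  etab <- do.call(rbind, edges)
  agg <- stats::aggregate(
    key ~ from + to, data = etab,
    FUN = function(k) paste(k, collapse = ",")
  )
  agg$weight <- stats::aggregate(
    key ~ from + to, data = etab, FUN = length
  )$key
  verts <- unique(c(agg$from, agg$to))
  vdf <- data.frame(
    name = verts, category = unname(cat2[verts]),
    stringsAsFactors = FALSE
  )
  edgeClass <- function(a, b) {
    ca <- cat2[[a]]; cb <- cat2[[b]]
    if (ca == "solute" && cb == "solute") "solute-solute"
    else if (ca == "solute" || cb == "solute") "solute-environment"
    else "environment"
  }
  g <- igraph::graph_from_data_frame(
    data.frame(
      from = agg$from, to = agg$to, weight = agg$weight,
      provenance = agg$key,
      class = mapply(edgeClass, agg$from, agg$to),
      # 0/1 rather than logical: DOT/GraphML exports have no boolean
      solvent = as.integer(
        cat2[agg$from] == "solvent" | cat2[agg$to] == "solvent"
      ),
      stringsAsFactors = FALSE
    ),
    directed = FALSE, vertices = vdf
  )
  g
}

#' Two-dimensional selectivity map (biplot bundle)
#'
#' Min-max scales two components' scores to [-1, 1] per axis and
#' overlays the directions of the strongest two-body loadings: the
#' \code{nArrows} two-body channels with the largest combined scaled
#' loading on the two displayed axes, with arrow tips
#' \eqn{(\ell_a, \ell_b)} normalized so the longest arrow has unit
#' infinity-norm. Returns a plot-ready bundle, not an image.
#'
#' @param model a [PcaModel-class].
#' @param pcA,pcB the two component indices (distinct).
#' @param colorDescriptor optional numeric vector (one per training
#'   compound) carried into the point table.
#' @param nArrows number of two-body loading arrows (default 6).
#' @return list with data.frames \code{points} (\code{x}, \code{y},
#'   optional \code{color}) and \code{arrows} (\code{channelKey},
#'   \code{xend}, \code{yend}).
#' @export
chartMap <- function(model, pcA, pcB, colorDescriptor = NULL,
                     nArrows = 6L) {
  if (pcA == pcB) stop("pcA and pcB must differ")
  d <- ncol(model@rotation)
  if (max(pcA, pcB) > d || min(pcA, pcB) < 1L)
    stop("component indices must lie in 1..", d)
  if (nrow(model@scores) < 2L)
    stop("map needs at least two compounds")
  scaleAxis <- function(s) {
    rng <- range(s)
    if (diff(rng) == 0)
      stop("degenerate axis: component has zero score variance")
    2 * (s - rng[1L]) / diff(rng) - 1
  }
  pts <- data.frame(
    x = scaleAxis(model@scores[, pcA]),
    y = scaleAxis(model@scores[, pcB])
  )
  if (!is.null(colorDescriptor)) pts$color <- colorDescriptor
  keys <- rownames(model@rotation)
  isTwo <- grepl(":", keys, fixed = TRUE) &
    !grepl(">", keys, fixed = TRUE)
  la <- model@rotation[, pcA] * sqrt(model@eigenvalues[pcA])
  lb <- model@rotation[, pcB] * sqrt(model@eigenvalues[pcB])
  mag <- sqrt(la^2 + lb^2)
  cand <- which(isTwo)
  cand <- cand[order(-mag[cand], keys[cand])]
  top <- head(cand, nArrows)
  arrows <- data.frame(
    channelKey = keys[top],
    xend = unname(la[top]), yend = unname(lb[top]),
    row.names = NULL
  )
  if (nrow(arrows)) {
    m <- max(abs(c(arrows$xend, arrows$yend)))
    if (m > 0) {
      arrows$xend <- arrows$xend / m
      arrows$yend <- arrows$yend / m
    }
  }
  list(points = pts, arrows = arrows)
}

#' Place and classify a new compound on a 2-D selectivity map
#'
#' Projects a new difference vector onto two components and reports
#' which side of a linear decision boundary it falls on. The boundary is
#' a least-squares separating line fitted on the training scores with
#' labels coded +1 (selective) and -1 (non-selective); points exactly on
#' the boundary deterministically classify as non-selective. The fitted
#' coefficients are returned so an explicit boundary can be substituted.
#'
#' @param model a [PcaModel-class].
#' @param pcA,pcB the two component indices.
#' @param trainLabels character vector over the training compounds with
#'   values \code{"selective"} / \code{"non-selective"} (both classes
#'   present).
#' @param newX new compound(s): [DifferenceVector-class], list thereof,
#'   or matrix.
#' @return data.frame with one row per new compound: \code{scoreA},
#'   \code{scoreB}, \code{decision} (signed boundary value),
#'   \code{label}; the boundary coefficients are attached as attribute
#'   \code{"boundary"} (intercept, coefA, coefB).
#' @export
classifyNew <- function(model, pcA, pcB, trainLabels, newX) {
  lv <- c("non-selective", "selective")
  if (!all(trainLabels %in% lv))
    stop("trainLabels must be 'selective' or 'non-selective'")
  if (length(unique(trainLabels)) < 2L)
    stop("training labels contain a single class; boundary undefined")
  if (length(trainLabels) != nrow(model@scores))
    stop("one training label per training compound required")
  y <- ifelse(trainLabels == "selective", 1, -1)
  a <- model@scores[, pcA]
  b <- model@scores[, pcB]
  fit <- lm(y ~ a + b)
  cf <- coef(fit)
  cf[is.na(cf)] <- 0
  sc <- projectScores(model, newX)
  dec <- cf[1L] + cf[2L] * sc[, pcA] + cf[3L] * sc[, pcB]
  out <- data.frame(
    scoreA = sc[, pcA], scoreB = sc[, pcB],
    decision = unname(dec),
    label = ifelse(dec > 0, "selective", "non-selective"),
    row.names = NULL
  )
  attr(out, "boundary") <- setNames(
    unname(cf), c("intercept", "coefA", "coefB")
  )
  out
}

#' Training-set classification consistency
#'
#' Applies the fitted boundary of [classifyNew()] back to the training
#' scores; used to verify label recovery on separable constructions.
#'
#' @inheritParams classifyNew
#' @return character vector of predicted labels for the training rows.
#' @export
classifyTraining <- function(model, pcA, pcB, trainLabels) {
  y <- ifelse(trainLabels == "selective", 1, -1)
  if (length(unique(trainLabels)) < 2L)
    stop("training labels contain a single class; boundary undefined")
  a <- model@scores[, pcA]
  b <- model@scores[, pcB]
  fit <- lm(y ~ a + b)
  pred <- stats::fitted(fit)
  ifelse(pred > 0, "selective", "non-selective")
}
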