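# SlatmParams <-> plain list; internal
.paramsToList <- function(p) {
  list(
    sigmaR = p@sigmaR, sigmaTheta = p@sigmaTheta,
    binWidthR = p@binWidthR, binWidthTheta = p@binWidthTheta,
    rCutoff = p@rCutoff, londonPrefactor = p@londonPrefactor,
    londonExponent = p@londonExponent, atmPrefactor = p@atmPrefactor
  )
}

.paramsFromList <- function(x) do.call(slatmParams, x)

#' Write / read a molecular SLATM
#'
#' Columnar CSV (channel key, bin index, value; one-body channels use
#' bin 0) plus a JSON sidecar holding the SLATM parameters, the channel
#' index, the kernel convention (bin-integrated Gaussian, reflected at
#' the angular domain ends) and the frame/bead bookkeeping.
#'
#' @param mol a [MolecularSLATM-class].
#' @param path CSV output path; the sidecar is written next to it as
#'   \code{<path>.json}.
#' @return \code{path}, invisibly.
#' @export
writeMolecularSlatm <- function(mol, path) {
  ci <- mol@channelIndex
  oneKeys <- channelKeys(ci, "one")
  rows <- rbind(
    data.frame(
      channelKey = oneKeys, bin = 0L, value = unname(mol@oneBody)
    ),
    data.frame(
      channelKey = rep(colnames(mol@twoBody), each = nrow(mol@twoBody)),
      bin = rep(seq_len(nrow(mol@twoBody)), ncol(mol@twoBody)),
      value = as.vector(mol@twoBody)
    ),
    data.frame(
      channelKey = rep(
        colnames(mol@threeBody), each = nrow(mol@threeBody)
      ),
      bin = rep(seq_len(nrow(mol@threeBody)), ncol(mol@threeBody)),
      value = as.vector(mol@threeBody)
    )
  )
  write.csv(rows, path, row.names = FALSE)
  sidecar <- list(
    params = .paramsToList(mol@params),
    kernel = "bin-integrated gaussian; angular reflection at 0 and pi",
    nFramesUsed = mol@nFramesUsed,
    soluteBeadCount = mol@soluteBeadCount,
    tripletPolicy = ci@tripletPolicy,
    oneBody = ci@oneBody,
    twoBody = apply(ci@twoBody, 1L, paste, collapse = ","),
    threeBody = apply(ci@threeBody, 1L, paste, collapse = ",")
  )
  jsonlite::write_json(
    sidecar, paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname writeMolecularSlatm
#' @param path CSV path written by [writeMolecularSlatm()].
#' @return \code{readMolecularSlatm}: a [MolecularSLATM-class].
#' @export
readMolecularSlatm <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  params <- .paramsFromList(side$params)
  ci <- new("ChannelIndex",
    oneBody = side$oneBody,
    twoBody = do.call(rbind, strsplit(side$twoBody, ",", fixed = TRUE)),
    threeBody = do.call(
      rbind, strsplit(side$threeBody, ",", fixed = TRUE)
    ),
    tripletPolicy = side$tripletPolicy
  )
  colnames(ci@twoBody) <- c("typeA", "typeB")
  colnames(ci@threeBody) <- c("center", "typeJ", "typeK")
  tab <- read.csv(path, stringsAsFactors = FALSE)
  oneKeys <- channelKeys(ci, "one")
  pairKeys <- channelKeys(ci, "two")
  tripKeys <- channelKeys(ci, "three")
  nbR <- ceiling(params@rCutoff / params@binWidthR)
  nbT <- ceiling(pi / params@binWidthTheta)
  oneBody <- setNames(tab$value[tab$bin == 0L][
    match(oneKeys, tab$channelKey[tab$bin == 0L])
  ], oneKeys)
  grab <- function(keys, nb) {
    sub <- tab[tab$bin > 0L & tab$channelKey %in% keys, ]
    m <- matrix(0, nb, length(keys), dimnames = list(NULL, keys))
    m[cbind(sub$bin, match(sub$channelKey, keys))] <- sub$value
    m
  }
  new("MolecularSLATM",
    oneBody = oneBody,
    twoBody = grab(pairKeys, nbR),
    threeBody = grab(tripKeys, nbT),
    nFramesUsed = as.integer(side$nFramesUsed),
    soluteBeadCount = as.integer(side$soluteBeadCount),
    params = params, channelIndex = ci
  )
}

#' Write / read a feature or difference vector
#'
#' CSV (channel key, value) plus a JSON sidecar recording the reduction
#' mode, epsilon and (for difference vectors) compound and environment
#' labels.
#'
#' @param x a [FeatureVector-class] or [DifferenceVector-class].
#' @param path CSV output path.
#' @return \code{path}, invisibly.
#' @export
writeFeatureVector <- function(x, path) {
  write.csv(
    data.frame(channelKey = x@channelKeys, value = x@values),
    path, row.names = FALSE
  )
  side <- list(
    reductionMode = x@reductionMode,
    epsilon = if (is.finite(x@epsilon)) x@epsilon else NULL
  )
  if (is(x, "DifferenceVector")) {
    side$compoundId <- x@compoundId
    side$envPair <- x@envPair
    side$signedLog <- x@signedLog
    side$kind <- "difference"
  } else {
    side$kind <- "feature"
  }
  jsonlite::write_json(
    side, paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname writeFeatureVector
#' @export
readFeatureVector <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  if (identical(side$kind, "difference")) {
    new("DifferenceVector",
      values = tab$value, compoundId = side$compoundId,
      envPair = side$envPair, reductionMode = side$reductionMode,
      epsilon = side$epsilon, signedLog = isTRUE(side$signedLog),
      channelKeys = tab$channelKey
    )
  } else {
    new("FeatureVector",
      values = tab$value, reductionMode = side$reductionMode,
      epsilon = if (is.null(side$epsilon)) NA_real_
                else as.numeric(side$epsilon),
      channelKeys = tab$channelKey
    )
  }
}

#' Persist / restore a PCA model
#'
#' JSON metadata (eigenvalues, ratios, seed, dimensions) with the
#' center vector, rotation and scores as full-precision CSV files next
#' to it (\code{<stem>_center.csv}, \code{<stem>_rotation.csv},
#' \code{<stem>_scores.csv}).
#'
#' @param model a [PcaModel-class].
#' @param stem path stem (no extension).
#' @return \code{stem}, invisibly.
#' @export
writePcaModel <- function(model, stem) {
  jsonlite::write_json(
    list(
      eigenvalues = model@eigenvalues,
      explainedVarianceRatios = model@explainedVarianceRatios,
      totalVariance = model@totalVariance,
      seed = model@seed,
      n = nrow(model@scores), D = nrow(model@rotation),
      d = ncol(model@rotation)
    ),
    paste0(stem, ".json"), auto_unbox = TRUE, digits = I(17)
  )
  # %.17g round-trips doubles exactly through the CSV text form
  fmt <- function(df) {
    df[] <- lapply(df, function(col) {
      if (is.numeric(col)) sprintf("%.17g", col) else col
    })
    df
  }
  write.csv(
    fmt(data.frame(
      channelKey = rownames(model@rotation), center = model@center
    )),
    paste0(stem, "_center.csv"), row.names = FALSE
  )
  rotDf <- as.data.frame(model@rotation)
  rotDf <- cbind(channelKey = rownames(model@rotation), rotDf)
  write.csv(fmt(rotDf), paste0(stem, "_rotation.csv"), row.names = FALSE)
  scoDf <- as.data.frame(model@scores)
  scoDf <- cbind(compoundId = rownames(model@scores), scoDf)
  write.csv(fmt(scoDf), paste0(stem, "_scores.csv"), row.names = FALSE)
  invisible(stem)
}

#' @rdname writePcaModel
#' @export
readPcaModel <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  cen <- read.csv(paste0(stem, "_center.csv"), stringsAsFactors = FALSE)
  rot <- read.csv(paste0(stem, "_rotation.csv"), stringsAsFactors = FALSE)
  sco <- read.csv(paste0(stem, "_scores.csv"), stringsAsFactors = FALSE)
  rotM <- as.matrix(rot[, -1L, drop = FALSE])
  rownames(rotM) <- rot$channelKey
  scoM <- as.matrix(sco[, -1L, drop = FALSE])
  rownames(scoM) <- sco$compoundId
  new("PcaModel",
    center = setNames(cen$center, cen$channelKey),
    eigenvalues = meta$eigenvalues,
    rotation = rotM,
    scores = scoM,
    explainedVarianceRatios = meta$explainedVarianceRatios,
    totalVariance = meta$totalVariance,
    seed = as.integer(meta$seed)
  )
}

#' Export an interaction graph
#'
#' @param graph an \pkg{igraph} graph from [buildInteractionGraph()].
#' @param path output path; format from extension (\code{.graphml} or
#'   \code{.dot}).
#' @return \code{path}, invisibly.
#' @export
writeInteractionGraph <- function(graph, path) {
  ext <- tolower(tools::file_ext(path))
  fmt <- switch(ext,
    graphml = "graphml", dot = "dot", gv = "dot",
    stop("unsupported graph format: ", ext)
  )
  igraph::write_graph(graph, path, format = fmt)
  invisible(path)
}
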