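#' Build a bead-type registry
#'
#' Constructs the frozen bead-type alphabet from a table. The row order of
#' the table fixes the channel order used everywhere downstream. If no
#' \code{Z} column is supplied, identity numbers 1..N are assigned in
#' table order (uniqueness is all the representation requires).
#'
#' @param configTable data.frame with columns \code{type} (or
#'   \code{typeName}), \code{category}, optional \code{Z} and
#'   \code{physClass}.
#' @return A [BeadTypeRegistry-class].
#' @examples
#' reg <- buildRegistry(data.frame(
#'   type = c("T1", "Q0", "Nda"),
#'   category = c("solute", "solute", "lipid")
#' ))
#' nBeadTypes(reg)
#' @export
buildRegistry <- function(configTable) {
  stopifnot(is.data.frame(configTable))
  if (nrow(configTable) == 0L)
    stop("bead-type table must be nonempty")
  nm <- if ("type" %in% names(configTable)) configTable$type
        else configTable$typeName
  if (is.null(nm))
    stop("bead-type table needs a 'type' (or 'typeName') column")
  nm <- as.character(nm)
  if (anyDuplicated(nm))
    stop(
      "duplicate bead type names: ",
      paste(unique(nm[duplicated(nm)]), collapse = ", ")
    )
  n <- length(nm)
  z <- if ("Z" %in% names(configTable)) as.integer(configTable$Z)
       else seq_len(n)
  if (anyDuplicated(z))
    stop("duplicate explicit Z identity numbers")
  category <- if ("category" %in% names(configTable))
    as.character(configTable$category) else rep("solute", n)
  physClass <- if ("physClass" %in% names(configTable))
    as.character(configTable$physClass) else rep(NA_character_, n)
  new("BeadTypeRegistry",
    typeName = nm, Z = z, category = category, physClass = physClass
  )
}

#' The 14-type bead registry of the reference membrane study
#'
#' Convenience registry combining the reduced solute force field
#' \{T1..T5, Q0\} with the lipid/solvent bead types
#' \{Nda, P4, Qa, Na, C1, C3, POL, PQd\} describing cardiolipin and
#' phosphatidylglycerol membrane environments, water and ions: N = 14.
#'
#' @return A [BeadTypeRegistry-class] with 14 types.
#' @export
membraneStudyRegistry <- function() {
  buildRegistry(data.frame(
    type = c(
      "T1", "T2", "T3", "T4", "T5", "Q0",
      "Nda", "P4", "Qa", "Na", "C1", "C3", "POL", "PQd"
    ),
    category = c(
      rep("solute", 6L),
      rep("lipid", 6L), "solvent", "solvent"
    ),
    physClass = c(
      "polar", "polar", "hbond", "apolar", "apolar", "charged",
      rep(NA_character_, 8L)
    )
  ))
}

#' Enumerate the canonical channel index
#'
#' Enumerates one-body channels (registry order), two-body channels as
#' unordered type pairs with repetition (N(N+1)/2), and three-body
#' channels as (center type, unordered neighbor pair with repetition)
#' (N * N(N+1)/2), all lexicographically over registry order. Under
#' \code{tripletPolicy = "observed-only"} the full triplet set is still
#' enumerated here; triplet channels never observed across a dataset are
#' dropped at dataset assembly (see [assembleDataset()]), before PCA.
#'
#' @param registry a [BeadTypeRegistry-class].
#' @param tripletPolicy \code{"observed-only"} (default) or \code{"all"}.
#' @return A [ChannelIndex-class].
#' @examples
#' channelCounts(buildChannelIndex(membraneStudyRegistry()))
#' @export
buildChannelIndex <- function(registry,
                              tripletPolicy = c("observed-only", "all")) {
  stopifnot(is(registry, "BeadTypeRegistry"))
  tripletPolicy <- match.arg(tripletPolicy)
  types <- registry@typeName
  n <- length(types)
  pairIdx <- which(
    upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE
  )
  pairIdx <- pairIdx[order(pairIdx[, 1L], pairIdx[, 2L]), , drop = FALSE]
  twoBody <- cbind(
    typeA = types[pairIdx[, 1L]], typeB = types[pairIdx[, 2L]]
  )
  threeBody <- cbind(
    center = rep(types, each = nrow(twoBody)),
    typeJ = rep(twoBody[, 1L], times = n),
    typeK = rep(twoBody[, 2L], times = n)
  )
  new("ChannelIndex",
    oneBody = types, twoBody = twoBody, threeBody = threeBody,
    tripletPolicy = tripletPolicy
  )
}

#' Read a bead registry from a YAML or CSV config file
#'
#' YAML layout: a top-level \code{types} list whose entries carry
#' \code{type}, \code{category} and optionally \code{Z}, \code{physClass}.
#' CSV: the same columns.
#'
#' @param path file path (.yaml/.yml or .csv).
#' @return A [BeadTypeRegistry-class].
#' @export
readBeadRegistry <- function(path) {
  if (!file.exists(path)) stop("registry file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  tab <- if (ext %in% c("yaml", "yml")) {
    y <- yaml::read_yaml(path)
    entries <- if (!is.null(y$types)) y$types else y
    do.call(rbind, lapply(entries, function(e) {
      data.frame(
        type = e$type,
        Z = if (is.null(e$Z)) NA_integer_ else as.integer(e$Z),
        category = if (is.null(e$category)) "solute" else e$category,
        physClass = if (is.null(e$physClass)) NA_character_
                    else e$physClass
      )
    }))
  } else {
    read.csv(path, stringsAsFactors = FALSE)
  }
  if (all(is.na(tab$Z))) tab$Z <- NULL
  buildRegistry(tab)
}

#' Write a bead registry to YAML
#'
#' @param registry a [BeadTypeRegistry-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeBeadRegistry <- function(registry, path) {
  entries <- lapply(seq_along(registry@typeName), function(i) {
    e <- list(
      type = registry@typeName[i],
      Z = registry@Z[i],
      category = registry@category[i]
    )
    if (!is.na(registry@physClass[i])) e$physClass <- registry@physClass[i]
    e
  })
  yaml::write_yaml(list(types = entries), path)
  invisible(path)
}

# registry index lookup with validation; internal
.typeIndex <- function(registry, types) {
  idx <- match(types, registry@typeName)
  if (anyNA(idx)) {
    stop(
      "bead type(s) not in registry: ",
      paste(unique(types[is.na(idx)]), collapse = ", ")
    )
  }
  idx
}

# canonical unordered pair key "A:B" with A at-or-before B in registry
# order; internal
.pairKey <- function(registry, a, b) {
  ia <- .typeIndex(registry, a)
  ib <- .typeIndex(registry, b)
  swap <- ia > ib
  lo <- ifelse(swap, b, a)
  hi <- ifelse(swap, a, b)
  paste(lo, hi, sep = ":")
}

# triplet key "C>A:B"; internal
.tripletKey <- function(registry, center, a, b) {
  paste0(center, ">", .pairKey(registry, a, b))
}
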