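#' Construct a Configuration
#'
#' @param positions n x 3 numeric matrix, Angstrom.
#' @param types character vector of bead type names.
#' @param soluteFlags logical vector marking solute beads.
#' @param box optional length-3 orthorhombic box lengths (A).
#' @return A [Configuration-class].
#' @export
configuration <- function(positions, types,
                          soluteFlags = rep(FALSE, length(types)),
                          box = numeric(0)) {
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  dimnames(positions) <- NULL
  new("Configuration",
    positions = positions, types = as.character(types),
    soluteFlags = as.logical(soluteFlags), box = as.numeric(box)
  )
}

#' Construct a TrajectoryEnsemble from configurations
#'
#' @param frames list of [Configuration-class] objects.
#' @param frameIndices optional source frame indices.
#' @param lengthUnitSource unit of the source data.
#' @return A [TrajectoryEnsemble-class].
#' @export
trajectoryEnsemble <- function(frames, frameIndices = seq_along(frames),
                               lengthUnitSource = "angstrom") {
  new("TrajectoryEnsemble",
    frames = frames, frameIndices = as.integer(frameIndices),
    lengthUnitSource = lengthUnitSource
  )
}

# parse "1-3,5,7-8" into an integer vector; internal
.parseIndexRanges <- function(s) {
  parts <- strsplit(gsub("\\s", "", s), ",", fixed = TRUE)[[1L]]
  out <- integer(0)
  for (p in parts[nzchar(parts)]) {
    if (grepl("-", p, fixed = TRUE)) {
      ab <- as.integer(strsplit(p, "-", fixed = TRUE)[[1L]])
      out <- c(out, seq.int(ab[1L], ab[2L]))
    } else {
      out <- c(out, as.integer(p))
    }
  }
  sort(unique(out))
}

.formatIndexRanges <- function(idx) {
  idx <- sort(unique(as.integer(idx)))
  if (!length(idx)) return("")
  brk <- c(0L, which(diff(idx) != 1L), length(idx))
  paste(vapply(seq_len(length(brk) - 1L), function(i) {
    a <- idx[brk[i] + 1L]
    b <- idx[brk[i + 1L]]
    if (a == b) as.character(a) else paste0(a, "-", b)
  }, character(1)), collapse = ",")
}

# map raw bead names to registry types; internal
.mapBeadNames <- function(names, registry, nameMap) {
  mapped <- if (is.null(nameMap)) names else {
    out <- unname(nameMap[names])
    out[is.na(out) & names %in% registry@typeName] <-
      names[is.na(out) & names %in% registry@typeName]
    out
  }
  bad <- unique(names[is.na(mapped) | !(mapped %in% registry@typeName)])
  if (length(bad)) {
    stop(
      "bead name(s) with no registered type mapping: ",
      paste(bad, collapse = ", ")
    )
  }
  mapped
}

# read the self-contained multi-frame extended-XYZ dialect; internal
.readXYZ <- function(path, registry, nameMap) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  unitSeen <- NULL
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat)) stop("malformed XYZ frame header at line ", i)
    header <- lines[i + 1L]
    toks <- regmatches(
      header, gregexpr("[A-Za-z_]+=[^ ]+", header)
    )[[1L]]
    kv <- strsplit(toks, "=", fixed = TRUE)
    keys <- vapply(kv, `[`, character(1), 1L)
    vals <- vapply(kv, `[`, character(1), 2L)
    unit <- vals[match("unit", keys)]
    if (is.na(unit)) {
      stop(
        "XYZ header must declare the length unit, e.g. unit=angstrom ",
        "or unit=nm (frame starting at line ", i, ")"
      )
    }
    if (!unit %in% c("angstrom", "nm"))
      stop("unsupported XYZ unit flag: ", unit)
    unitSeen <- unit
    soluteStr <- vals[match("solute", keys)]
    soluteIdx <- if (is.na(soluteStr)) integer(0)
                 else .parseIndexRanges(soluteStr)
    boxStr <- vals[match("box", keys)]
    box <- if (is.na(boxStr)) numeric(0)
           else as.numeric(strsplit(boxStr, ",", fixed = TRUE)[[1L]])
    body <- lines[(i + 2L):(i + 1L + nat)]
    fields <- strsplit(trimws(body), "[[:space:]]+")
    rawTypes <- vapply(fields, `[`, character(1), 1L)
    xyz <- t(vapply(
      fields,
      function(f) as.numeric(f[2:4]),
      numeric(3)
    ))
    scale <- if (unit == "nm") 10 else 1
    types <- .mapBeadNames(rawTypes, registry, nameMap)
    flags <- seq_len(nat) %in% soluteIdx
    frames[[length(frames) + 1L]] <- configuration(
      xyz * scale, types, flags, box * scale
    )
    i <- i + 2L + nat
  }
  if (!length(frames)) stop("no frames found in ", path)
  trajectoryEnsemble(frames, lengthUnitSource = unitSeen)
}

# fixed-column GRO reader (nm); internal
.readGRO <- function(path, registry, nameMap, soluteSelection) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i + 1L <= length(lines)) {
    nat <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(nat)) break
    body <- lines[(i + 2L):(i + 1L + nat)]
    resName <- trimws(substr(body, 6L, 10L))
    atomName <- trimws(substr(body, 11L, 15L))
    x <- as.numeric(substr(body, 21L, 28L))
    y <- as.numeric(substr(body, 29L, 36L))
    z <- as.numeric(substr(body, 37L, 44L))
    boxLine <- strsplit(trimws(lines[i + 2L + nat]), "[[:space:]]+")[[1L]]
    box <- as.numeric(boxLine[1:3]) * 10
    types <- .mapBeadNames(atomName, registry, nameMap)
    flags <- .resolveSoluteSelection(soluteSelection, resName, nat)
    frames[[length(frames) + 1L]] <- configuration(
      cbind(x, y, z) * 10, types, flags, box
    )
    i <- i + 3L + nat
  }
  if (!length(frames)) stop("no frames found in ", path)
  trajectoryEnsemble(frames, lengthUnitSource = "nm")
}

.resolveSoluteSelection <- function(soluteSelection, resNames, nat) {
  if (is.null(soluteSelection)) return(rep(FALSE, nat))
  if (is.numeric(soluteSelection)) {
    return(seq_len(nat) %in% as.integer(soluteSelection))
  }
  resNames %in% soluteSelection
}

#' Load a trajectory ensemble
#'
#' Reads a coarse-grained trajectory into a [TrajectoryEnsemble-class]
#' with coordinates in Angstrom. Supported inputs:
#' \itemize{
#'   \item self-contained multi-frame extended-XYZ dialect (lines:
#'     bead count; header with \code{unit=nm|angstrom},
#'     \code{solute=<index ranges>}, optional \code{box=x,y,z}; then
#'     \code{type x y z} per bead);
#'   \item GRO topology (single- or multi-frame, nm);
#'   \item PDB topology, optionally with a DCD frame file.
#' }
#' XTC/TRR readers are not available in this toolchain; convert such
#' trajectories to DCD or to the extended-XYZ dialect first.
#'
#' @param topologyPath path to the XYZ/GRO/PDB file.
#' @param trajectoryPath optional DCD frame file (with a PDB/GRO
#'   topology).
#' @param registry a [BeadTypeRegistry-class].
#' @param nameMap optional named character vector mapping file bead names
#'   to registered type names (unmapped names already matching a
#'   registered type pass through).
#' @param soluteSelection residue name(s) (GRO/PDB) or explicit bead
#'   index vector marking the solute; ignored for the XYZ dialect, whose
#'   header carries the solute range.
#' @return A [TrajectoryEnsemble-class].
#' @export
readTrajectory <- function(topologyPath, trajectoryPath = NULL,
                           registry, nameMap = NULL,
                           soluteSelection = NULL) {
  if (!file.exists(topologyPath))
    stop("topology file not found: ", topologyPath)
  ext <- tolower(tools::file_ext(topologyPath))
  if (!is.null(trajectoryPath)) {
    text <- tolower(tools::file_ext(trajectoryPath))
    if (text %in% c("xtc", "trr")) {
      stop(
        "XTC/TRR frame files are not supported by this toolchain; ",
        "convert the trajectory to DCD or to the extended-XYZ dialect"
      )
    }
    if (text != "dcd") stop("unsupported frame file format: ", text)
  }
  base <- switch(ext,
    xyz = .readXYZ(topologyPath, registry, nameMap),
    gro = .readGRO(topologyPath, registry, nameMap, soluteSelection),
    pdb = .readPDB(topologyPath, registry, nameMap, soluteSelection),
    stop("unsupported topology format: ", ext)
  )
  if (is.null(trajectoryPath)) return(base)
  .readDCDFrames(trajectoryPath, base)
}

# PDB via bio3d (Angstrom); internal
.readPDB <- function(path, registry, nameMap, soluteSelection) {
  pdb <- bio3d::read.pdb(path)
  atomName <- trimws(pdb$atom$elety)
  resName <- trimws(pdb$atom$resid)
  nat <- length(atomName)
  types <- .mapBeadNames(atomName, registry, nameMap)
  flags <- .resolveSoluteSelection(soluteSelection, resName, nat)
  xyz <- matrix(pdb$xyz[1L, ], ncol = 3L, byrow = TRUE)
  trajectoryEnsemble(
    list(configuration(xyz, types, flags)),
    lengthUnitSource = "angstrom"
  )
}

# DCD frames (Angstrom) applied onto a 1-frame topology; internal
.readDCDFrames <- function(path, base) {
  traj <- bio3d::read.dcd(path, verbose = FALSE)
  tmpl <- base@frames[[1L]]
  frames <- lapply(seq_len(nrow(traj)), function(k) {
    configuration(
      matrix(traj[k, ], ncol = 3L, byrow = TRUE),
      tmpl@types, tmpl@soluteFlags, tmpl@box
    )
  })
  trajectoryEnsemble(frames, lengthUnitSource = "angstrom")
}

#' Write a trajectory in the extended-XYZ dialect
#'
#' Inverse of the XYZ branch of [readTrajectory()]; coordinates are
#' written in Angstrom at full precision so a load/write/load round-trip
#' preserves coordinates to well below 1e-9 A.
#'
#' @param traj a [TrajectoryEnsemble-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeTrajectoryXYZ <- function(traj, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (f in traj@frames) {
    nat <- nrow(f@positions)
    header <- "unit=angstrom"
    sol <- which(f@soluteFlags)
    if (length(sol))
      header <- paste0(header, " solute=", .formatIndexRanges(sol))
    if (length(f@box) == 3L) {
      header <- paste0(
        header, " box=", paste(sprintf("%.17g", f@box), collapse = ",")
      )
    }
    writeLines(as.character(nat), con)
    writeLines(header, con)
    writeLines(sprintf(
      "%s %.17g %.17g %.17g",
      f@types, f@positions[, 1L], f@positions[, 2L], f@positions[, 3L]
    ), con)
  }
  invisible(path)
}
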