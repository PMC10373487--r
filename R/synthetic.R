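# default shell model: dense, uniform solvation. Every solute bead is
# coordinated by every environment type, as in a condensed-phase
# liquid, so that every geometrically accessible channel is robustly
# populated in every frame. Sparse shells would leave three-body
# channels intermittently empty, and the log transform turns on/off
# occupancy into order-of-magnitude jumps that are not sampling noise;
# dense shells keep all non-planted channel differences shrinking as
# 1/sqrt(n_frames), which is what the generator must guarantee.
.defaultShellTable <- function() {
  solute <- c("T1", "T2", "T3", "T4", "T5", "Q0")
  rbind(
    data.frame(
      soluteType = solute, envType = "Nda",
      count = 3, radius = 5.0, jitter = 0.7
    ),
    data.frame(
      soluteType = solute, envType = "P4",
      count = 3, radius = 6.0, jitter = 0.7
    ),
    data.frame(
      soluteType = solute, envType = "POL",
      count = 3, radius = 7.0, jitter = 0.9
    )
  )
}

#' Synthetic study specification
#'
#' Defines the synthetic two-environment bead system used to validate
#' the full pipeline without molecular dynamics: solutes of 1-5 beads
#' from the reduced \{T1..T5, Q0\} alphabet, type-dependent radial
#' shells of lipid (Nda, P4) and solvent (POL) beads around each solute
#' bead, and two environment variants A and B that are identical except
#' that the planted channel's shell occupancy in A is multiplied by
#' \eqn{e^{e_i}} with a per-compound log contrast
#' \eqn{e_i \sim U(-1, 1) \times} \code{plantedEffect}. The planted
#' selectivity target is \eqn{y_i = \beta e_i + \mathcal{N}(0,
#' \sigma)} with \eqn{\sigma =} \code{noiseFraction} times the signal
#' standard deviation. Frames are i.i.d. draws, not dynamics: the
#' featurizer only requires an ensemble, and i.i.d. sampling gives exact
#' control of the planted structure.
#'
#' @param nCompounds number of compounds (default 200).
#' @param beadsRange solute size range (default 1-5).
#' @param soluteAlphabet solute bead types.
#' @param envTypes environment bead types.
#' @param shellTable shell model table (see [SyntheticSpec-class]).
#' @param plantedChannel planted two-body channel,
#'   (solute type, env type).
#' @param plantedEffect log-scale effect size (default 1).
#' @param noiseFraction target noise SD as a fraction of signal SD
#'   (default 0.25).
#' @param beta linear coefficient (default 1).
#' @param nFrames i.i.d. frames per compound per environment
#'   (default 50).
#' @param seed master seed.
#' @return A [SyntheticSpec-class].
#' @export
syntheticSpec <- function(nCompounds = 200L,
                          beadsRange = c(1L, 5L),
                          soluteAlphabet = c("T1", "T2", "T3", "T4",
                                             "T5", "Q0"),
                          envTypes = c("Nda", "P4", "POL"),
                          shellTable = .defaultShellTable(),
                          plantedChannel = c("Q0", "Nda"),
                          plantedEffect = 1,
                          noiseFraction = 0.25,
                          beta = 1,
                          nFrames = 50L,
                          seed = 1L) {
  new("SyntheticSpec",
    nCompounds = as.integer(nCompounds),
    beadsRange = as.integer(beadsRange),
    soluteAlphabet = soluteAlphabet,
    envTypes = envTypes,
    shellTable = shellTable,
    plantedChannel = plantedChannel,
    plantedEffect = plantedEffect,
    noiseFraction = noiseFraction,
    beta = beta,
    nFrames = as.integer(nFrames),
    seed = as.integer(seed)
  )
}

#' Registry implied by a synthetic specification
#'
#' Solute types are categorized by the reduced force field's
#' physicochemical classes (T1/T2 polar, T3 hydrogen-bond-like, T4/T5
#' apolar, Q0 charged); Nda and P4 are lipid headgroup beads and POL a
#' solvent bead. Z identities are 1..N in alphabet order.
#'
#' @param spec a [SyntheticSpec-class].
#' @return A [BeadTypeRegistry-class].
#' @export
syntheticRegistry <- function(spec) {
  phys <- c(
    T1 = "polar", T2 = "polar", T3 = "hbond",
    T4 = "apolar", T5 = "apolar", Q0 = "charged"
  )
  envCat <- c(Nda = "lipid", P4 = "lipid", Qa = "lipid", Na = "lipid",
              C1 = "lipid", C3 = "lipid", POL = "solvent",
              PQd = "solvent")
  types <- c(spec@soluteAlphabet, spec@envTypes)
  cats <- c(
    rep("solute", length(spec@soluteAlphabet)),
    ifelse(is.na(envCat[spec@envTypes]), "lipid", envCat[spec@envTypes])
  )
  buildRegistry(data.frame(
    type = types,
    category = cats,
    physClass = ifelse(
      is.na(phys[types]) | cats != "solute", NA_character_, phys[types]
    )
  ))
}

#' Generate one synthetic solute
#'
#' Builds a compound of 1-5 beads with generic coarse-grained geometry:
#' 4.7 A bond lengths and 120-degree angles along a planar zig-zag
#' chain, with an occasional single branch for sizes of four or more.
#' The first bead is anchored to the planted channel's solute type so
#' every compound carries the planted interaction; remaining types are
#' drawn from the solute alphabet. Deterministic per seed.
#'
#' @param spec a [SyntheticSpec-class].
#' @param compoundSeed integer seed for this compound.
#' @return list with \code{positions} (n x 3, A), \code{types},
#'   \code{bonds} (2-column index matrix).
#' @export
generateCompound <- function(spec, compoundSeed) {
  set.seed(as.integer(compoundSeed))
  nb <- sample(seq.int(spec@beadsRange[1L], spec@beadsRange[2L]), 1L)
  anchor <- spec@plantedChannel[1L]
  types <- c(
    anchor,
    if (nb > 1L) sample(spec@soluteAlphabet, nb - 1L, replace = TRUE)
  )
  bond <- 4.7
  # planar zig-zag: successive bond directions alternate +-60 degrees
  # from the x axis, giving 120-degree internal angles
  pos <- matrix(0, nb, 3L)
  if (nb > 1L) {
    for (i in 2:nb) {
      ang <- if (i %% 2L == 0L) pi / 6 else -pi / 6
      pos[i, ] <- pos[i - 1L, ] + bond * c(cos(ang), sin(ang), 0)
    }
  }
  bonds <- if (nb > 1L) cbind(1:(nb - 1L), 2:nb) else
    matrix(integer(0), 0L, 2L)
  if (nb >= 4L && runif(1) < 0.25) {
    # re-attach the last bead as a branch on bead 2, on the opposite
    # side of the chain (still 4.7 A / 120 degrees)
    ang <- if (2L %% 2L == 0L) -pi / 2 else pi / 2
    pos[nb, ] <- pos[2L, ] + bond * c(cos(ang), sin(ang), 0)
    bonds[nb - 1L, ] <- c(2L, nb)
  }
  list(positions = pos, types = types, bonds = bonds)
}

#' Sample one synthetic environment frame
#'
#' Draws the environment beads around a solute according to the shell
#' model: for each (solute bead, environment type) with a shell entry, a
#' Poisson-distributed number of beads is placed at
#' Normal(radius, jitter) distances in uniform random directions.
#' Environments A and B differ only in the planted channel's shell
#' occupancy (multiplied by \code{exp(logContrast)} in A). Placements
#' closer than 3.5 A to any existing bead are rejected and redrawn
#' (bounded retries); the floor approximates the excluded volume of a
#' ~4.7 A coarse-grained bead and, under the R^-6 London weight, bounds
#' a closest-approach contact at under ten times a shell contact, so
#' single contacts cannot dominate a channel's mass. If a bead cannot
#' be placed after its retry budget the whole frame is redrawn (the
#' generative model is the Poisson-shell draw conditioned on packing
#' feasibility); only repeated whole-frame failure is an error.
#'
#' @param solute compound from [generateCompound()].
#' @param envLabel \code{"A"} or \code{"B"}.
#' @param spec a [SyntheticSpec-class].
#' @param frameSeed integer seed for this frame.
#' @param logContrast the compound's planted log contrast \eqn{e_i}
#'   (applied in environment A only).
#' @return A [Configuration-class] (solute beads first, flagged).
#' @export
sampleEnvironment <- function(solute, envLabel, spec, frameSeed,
                              logContrast = 0) {
  if (!envLabel %in% c("A", "B")) stop("envLabel must be 'A' or 'B'")
  set.seed(as.integer(frameSeed))
  ns <- nrow(solute$positions)
  st <- spec@shellTable
  floor2 <- 3.5^2
  for (frameTry in seq_len(20L)) {
    pos <- solute$positions
    types <- solute$types
    feasible <- TRUE
    for (s in seq_len(ns)) {
      rows <- which(st$soluteType == types[s])
      for (r in rows) {
        lambda <- st$count[r]
        planted <- types[s] == spec@plantedChannel[1L] &&
          st$envType[r] == spec@plantedChannel[2L]
        if (planted && envLabel == "A")
          lambda <- lambda * exp(logContrast)
        nDraw <- rpois(1L, lambda)
        for (q in seq_len(nDraw)) {
          placed <- FALSE
          for (try in seq_len(1000L)) {
            dir <- rnorm(3L)
            dir <- dir / sqrt(sum(dir^2))
            rad <- rnorm(1L, st$radius[r], st$jitter[r])
            cand <- solute$positions[s, ] + rad * dir
            d2 <- rowSums(sweep(pos, 2L, cand)^2)
            if (min(d2) >= floor2) {
              pos <- rbind(pos, cand)
              types <- c(types, st$envType[r])
              placed <- TRUE
              break
            }
          }
          if (!placed) {
            feasible <- FALSE
            break
          }
        }
        if (!feasible) break
      }
      if (!feasible) break
    }
    if (feasible) {
      return(configuration(
        pos, types,
        soluteFlags = c(rep(TRUE, ns), rep(FALSE, length(types) - ns))
      ))
    }
  }
  stop("infeasible packing: could not place an environment bead")
}

#' Generate the full synthetic dataset
#'
#' Draws per-compound solutes, planted log contrasts
#' \eqn{e_i \sim U(-1,1) \times} effect, i.i.d. frames for both
#' environments, and the planted target
#' \eqn{y_i = \beta e_i + \mathcal{N}(0, \sigma)}. All per-compound and
#' per-frame seeds derive from the master seed, so identical seeds give
#' identical datasets.
#'
#' @param spec a [SyntheticSpec-class].
#' @return list with elements \code{registry}, \code{spec},
#'   \code{compounds} (per compound: \code{solute}, \code{ensembles}
#'   list with [TrajectoryEnsemble-class] \code{A} and \code{B}),
#'   \code{metadata} (data.frame with \code{compoundId}, \code{nBeads},
#'   \code{ddG}) and \code{truth} (\code{beta}, \code{channel},
#'   \code{contrasts}, \code{noiseSd}).
#' @export
generateDataset <- function(spec) {
  stopifnot(is(spec, "SyntheticSpec"))
  set.seed(spec@seed)
  n <- spec@nCompounds
  compoundSeeds <- sample.int(.Machine$integer.max - 1L, n)
  contrasts <- runif(n, -1, 1) * spec@plantedEffect
  frameSeeds <- matrix(
    sample.int(.Machine$integer.max - 1L, n * spec@nFrames * 2L),
    nrow = n
  )
  signal <- spec@beta * contrasts
  noiseSd <- if (n > 1L) spec@noiseFraction * sd(signal) else 0
  y <- signal + rnorm(n, 0, noiseSd)
  registry <- syntheticRegistry(spec)
  compounds <- vector("list", n)
  for (i in seq_len(n)) {
    solute <- generateCompound(spec, compoundSeeds[i])
    mkEnsemble <- function(label, offset) {
      frames <- lapply(seq_len(spec@nFrames), function(f) {
        sampleEnvironment(
          solute, label, spec,
          frameSeed = frameSeeds[i, offset + f],
          logContrast = contrasts[i]
        )
      })
      trajectoryEnsemble(frames)
    }
    compounds[[i]] <- list(
      solute = solute,
      ensembles = list(
        A = mkEnsemble("A", 0L),
        B = mkEnsemble("B", spec@nFrames)
      )
    )
  }
  ids <- sprintf("compound%03d", seq_len(n))
  list(
    registry = registry,
    spec = spec,
    compounds = setNames(compounds, ids),
    metadata = data.frame(
      compoundId = ids,
      nBeads = vapply(
        compounds, function(cp) nrow(cp$solute$positions), integer(1)
      ),
      ddG = y
    ),
    truth = list(
      beta = spec@beta,
      channel = paste(spec@plantedChannel, collapse = ":"),
      contrasts = contrasts,
      noiseSd = noiseSd
    )
  )
}

#' Write a synthetic dataset to disk
#'
#' Emits the same file layout the featurization pipeline consumes:
#' one extended-XYZ trajectory per compound per environment, the
#' registry as YAML, the metadata table as CSV and the planted-truth
#' record as JSON.
#'
#' @param dataset from [generateDataset()].
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeSyntheticDataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeBeadRegistry(dataset$registry, file.path(dir, "registry.yaml"))
  write.csv(
    dataset$metadata, file.path(dir, "metadata.csv"), row.names = FALSE
  )
  jsonlite::write_json(
    dataset$truth, file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA
  )
  for (id in names(dataset$compounds)) {
    for (env in c("A", "B")) {
      writeTrajectoryXYZ(
        dataset$compounds[[id]]$ensembles[[env]],
        file.path(dir, sprintf("%s_env%s.xyz", id, env))
      )
    }
  }
  invisible(dir)
}

#' Run the featurization + PCA pipeline on a synthetic dataset
#'
#' Featurizes every compound in both environments (ensemble average,
#' molecular sum, channel collapse), forms the log-difference dataset
#' and fits the PCA model. The signed-log transform is used because
#' three-body ATM scalars can legitimately be net negative.
#'
#' @param dataset from [generateDataset()].
#' @param params a [SlatmParams-class].
#' @param d retained components.
#' @param mode collapse mode (default total-mass).
#' @param radius local-environment radius (A).
#' @param epsilon log regularizer.
#' @param seed PCA seed.
#' @return list with \code{se} (the SummarizedExperiment), \code{model}
#'   (the [PcaModel-class]), \code{descriptors} (data.frame) and
#'   \code{channelIndex}.
#' @export
runSelectivityPipeline <- function(dataset, params = slatmParams(),
                                   d = 6L, mode = "total-mass",
                                   radius = 11.0, epsilon = 1e-12,
                                   seed = 0L) {
  registry <- dataset$registry
  ci <- buildChannelIndex(registry)
  featurize <- function(traj) {
    collapseChannels(
      featurizeEnsemble(traj, params, registry, ci, radius),
      mode = mode
    )
  }
  fvA <- lapply(dataset$compounds, function(cp) featurize(cp$ensembles$A))
  fvB <- lapply(dataset$compounds, function(cp) featurize(cp$ensembles$B))
  se <- assembleDataset(
    fvA, fvB, ci,
    compoundIds = names(dataset$compounds),
    colData = dataset$metadata[, c("nBeads", "ddG")],
    epsilon = epsilon, signedLog = TRUE
  )
  model <- fitPca(se, d = min(d, ncol(se) - 1L, nrow(se)), seed = seed)
  soluteTypes <- lapply(dataset$compounds, function(cp) cp$solute$types)
  desc <- descriptorTable(
    se, soluteTypes, registry,
    extra = data.frame(ddG = dataset$metadata$ddG)
  )
  list(se = se, model = model, descriptors = desc, channelIndex = ci)
}
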