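# small shell table keeping module tests fast
miniSpec <- function(seed = 5L, ...) {
  syntheticSpec(
    nCompounds = 2L, beadsRange = c(2L, 3L), nFrames = 5L,
    shellTable = data.frame(
      soluteType = c("Q0", "T1", "T2", "T3", "T4", "T5"),
      envType = "Nda",
      count = c(3, 1, 1, 1, 1, 1), radius = 5.0, jitter = 0.5
    ),
    envTypes = c("Nda", "P4", "POL"),
    seed = seed, ...
  )
}

test_that("compound generation is deterministic with CG geometry", {
  spec <- syntheticSpec()
  a <- generateCompound(spec, compoundSeed = 11L)
  b <- generateCompound(spec, compoundSeed = 11L)
  expect_identical(a, b)
  # across seeds the draws vary (single-bead compounds can coincide)
  many <- lapply(1:20, function(s) generateCompound(spec, s))
  expect_gt(length(unique(many)), 1L)
  # every bonded distance is the 4.7 A CG bond length
  for (seed in 1:20) {
    cp <- generateCompound(spec, compoundSeed = seed)
    nb <- nrow(cp$positions)
    expect_true(nb >= 1L && nb <= 5L)
    expect_equal(cp$types[1L], "Q0")     # planted-channel anchor
    if (nrow(cp$bonds)) {
      d <- sqrt(rowSums((
        cp$positions[cp$bonds[, 1L], , drop = FALSE] -
          cp$positions[cp$bonds[, 2L], , drop = FALSE]
      )^2))
      expect_true(all(abs(d - 4.7) < 1e-9))
    }
  }
  # single bead sits at the origin
  one <- syntheticSpec(beadsRange = c(1L, 1L))
  cp1 <- generateCompound(one, compoundSeed = 3L)
  expect_equal(cp1$positions, matrix(0, 1L, 3L))
})

test_that("environment sampling respects shells, planting and packing", {
  spec <- miniSpec()
  cp <- list(
    positions = matrix(0, 1L, 3L), types = "Q0",
    bonds = matrix(integer(0), 0L, 2L)
  )
  # zero-count shells give solute-only frames
  empty <- syntheticSpec(shellTable = data.frame(
    soluteType = "Q0", envType = "Nda",
    count = 0, radius = 5, jitter = 0.5
  ))
  f0 <- sampleEnvironment(cp, "A", empty, frameSeed = 1L)
  expect_equal(nrow(f0@positions), 1L)
  # determinism per frame seed
  fa <- sampleEnvironment(cp, "A", spec, frameSeed = 7L)
  fb <- sampleEnvironment(cp, "A", spec, frameSeed = 7L)
  expect_identical(fa@positions, fb@positions)
  # excluded volume: no two beads closer than 3.5 A
  d <- as.matrix(dist(fa@positions))
  diag(d) <- Inf
  expect_gte(min(d), 3.5)
  # planted multiplier raises the planted shell occupancy in A only
  spec2 <- miniSpec()
  nA <- mean(vapply(1:40, function(s) {
    sum(sampleEnvironment(
      cp, "A", spec2, frameSeed = s, logContrast = 1
    )@types == "Nda")
  }, numeric(1)))
  nB <- mean(vapply(1:40, function(s) {
    sum(sampleEnvironment(
      cp, "B", spec2, frameSeed = s, logContrast = 1
    )@types == "Nda")
  }, numeric(1)))
  expect_gt(nA / nB, 1.8)      # exp(1) = 2.72, attenuated by packing
  expect_error(
    sampleEnvironment(cp, "C", spec, frameSeed = 1L), "envLabel"
  )
})

test_that("a tight planted shell puts the radial mode at its radius", {
  shell <- syntheticSpec(
    beadsRange = c(1L, 1L),
    shellTable = data.frame(
      soluteType = "Q0", envType = "Nda",
      count = 10, radius = 5.0, jitter = 0.3
    )
  )
  cp <- list(
    positions = matrix(0, 1L, 3L), types = "Q0",
    bonds = matrix(integer(0), 0L, 2L)
  )
  frames <- lapply(1:30, function(s) {
    sampleEnvironment(cp, "A", shell, frameSeed = 100L + s)
  })
  reg <- syntheticRegistry(shell)
  ci <- buildChannelIndex(reg)
  mol <- featurizeEnsemble(
    trajectoryEnsemble(frames), slatmParams(), reg, ci
  )
  h <- mol@twoBody[, "Q0:Nda"]
  mode <- radialBinCenters(slatmParams())[which.max(h)]
  # R^-6 weighting pulls the mode slightly inward of 5.0 A
  expect_lt(abs(mode - 5.0), 0.5)
})

test_that("planted contrast is detectable above channel noise", {
  # unit log contrast on the planted channel, 50 frames per environment
  spec <- syntheticSpec(beadsRange = c(2L, 2L), seed = 9L)
  solute <- generateCompound(spec, compoundSeed = 4L)
  mkEns <- function(env) {
    trajectoryEnsemble(lapply(1:50, function(s) {
      sampleEnvironment(
        solute, env, spec, frameSeed = 5000L + s, logContrast = 1
      )
    }))
  }
  reg <- syntheticRegistry(spec)
  ci <- buildChannelIndex(reg)
  p <- slatmParams()
  sA <- featureValues(collapseChannels(
    featurizeEnsemble(mkEns("A"), p, reg, ci)
  ))
  sB <- featureValues(collapseChannels(
    featurizeEnsemble(mkEns("B"), p, reg, ci)
  ))
  d <- abs(sA - sB)
  planted <- d[["Q0:Nda"]]
  others <- d[setdiff(names(d), "Q0:Nda")]
  others <- others[others > 0]   # drop channels empty in both envs
  expect_gt(planted, 5 * median(others))
  # and the log difference recovers the planted unit contrast
  expect_equal(
    log(sA[["Q0:Nda"]]) - log(sB[["Q0:Nda"]]), 1, tolerance = 0.5
  )
})

test_that("dataset generation is seeded, noiseless when asked, schema-stable", {
  spec0 <- miniSpec(noiseFraction = 0)
  ds <- generateDataset(spec0)
  # noiseless target equals beta x contrast exactly
  expect_equal(ds$metadata$ddG, ds$truth$contrasts, tolerance = 1e-12)
  ds2 <- generateDataset(spec0)
  expect_identical(ds$metadata, ds2$metadata)
  expect_identical(
    ds$compounds[[1L]]$ensembles$A@frames[[1L]]@positions,
    ds2$compounds[[1L]]$ensembles$A@frames[[1L]]@positions
  )
  # different seed: different draws, same schema
  ds3 <- generateDataset(miniSpec(noiseFraction = 0, seed = 6L))
  expect_false(identical(ds$metadata$ddG, ds3$metadata$ddG))
  expect_identical(names(ds3), names(ds))
  expect_identical(names(ds3$metadata), names(ds$metadata))
  expect_identical(names(ds3$truth), names(ds$truth))
})

test_that("written datasets are ingestible with zero warnings", {
  dir <- withr::local_tempdir()
  ds <- generateDataset(miniSpec())
  expect_no_warning(writeSyntheticDataset(ds, dir))
  reg <- readBeadRegistry(file.path(dir, "registry.yaml"))
  expect_identical(beadTypes(reg), beadTypes(ds$registry))
  meta <- read.csv(file.path(dir, "metadata.csv"))
  expect_identical(meta$compoundId, ds$metadata$compoundId)
  truth <- jsonlite::read_json(
    file.path(dir, "truth.json"), simplifyVector = TRUE
  )
  expect_equal(truth$contrasts, ds$truth$contrasts, tolerance = 1e-9)
  for (id in names(ds$compounds)) {
    for (env in c("A", "B")) {
      path <- file.path(dir, sprintf("%s_env%s.xyz", id, env))
      expect_true(file.exists(path))
      traj <- NULL
      expect_no_warning(traj <- readTrajectory(path, registry = reg))
      expect_equal(nFrames(traj), 5L)
      src <- ds$compounds[[id]]$ensembles[[env]]
      expect_identical(
        traj@frames[[1L]]@types, src@frames[[1L]]@types
      )
      expect_lt(
        max(abs(
          traj@frames[[1L]]@positions - src@frames[[1L]]@positions
        )), 1e-9
      )
      expect_identical(
        traj@frames[[1L]]@soluteFlags, src@frames[[1L]]@soluteFlags
      )
    }
  }
})
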