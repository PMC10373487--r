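params <- slatmParams()

test_that("gaussian bin profile is a discretized unit-mass kernel", {
  centers <- radialBinCenters(params)
  # interior kernel integrates to 1 (checked against closed-form CDF)
  g <- gaussianBinProfile(4.0, 0.3, centers, 0.2)
  expect_equal(sum(g), 1, tolerance = 1e-6)
  edges <- seq(0, 8, by = 0.2)
  closedForm <- pnorm(edges[-1L], 4.0, 0.3) - pnorm(edges[-41L], 4.0, 0.3)
  expect_equal(g, closedForm, tolerance = 1e-12)
  # far-outside kernel leaves nothing behind
  far <- gaussianBinProfile(20, 0.3, centers, 0.2)
  expect_true(all(far < 1e-12))
  # narrow (delta) limit concentrates in the bin containing the value
  delta <- gaussianBinProfile(3.14, 1e-4, centers, 0.2)
  expect_equal(sum(delta), 1, tolerance = 1e-9)
  expect_equal(which.max(delta), which(abs(centers - 3.1) < 1e-9))
  expect_equal(max(delta), 1, tolerance = 1e-9)
})

test_that("angular reflection preserves unit mass at the domain ends", {
  centers <- angularBinCenters(params)
  atPi <- gaussianBinProfile(pi, 0.2, centers, 0.2, reflect = c(0, pi))
  expect_equal(sum(atPi), 1, tolerance = 1e-9)
  atZero <- gaussianBinProfile(0, 0.2, centers, 0.2, reflect = c(0, pi))
  expect_equal(sum(atZero), 1, tolerance = 1e-9)
})

test_that("two-body spectrum carries the London weight", {
  reg <- buildRegistry(data.frame(
    type = c("A", "B"), Z = c(2L, 3L), category = "solute"
  ))
  cfg <- configuration(rbind(c(0, 0, 0), c(4, 0, 0)), c("A", "B"))
  h <- twoBodySpectrum(cfg, 1L, "B", params, reg)
  expect_equal(sum(h), 0.5 * 2 * 3 * 4^-6, tolerance = 0.01)
  expect_equal(sum(h), 7.3242e-4, tolerance = 0.01)
  # no neighbors of the requested type -> zero vector
  expect_equal(
    twoBodySpectrum(cfg, 1L, "A", params, reg),
    numeric(length(radialBinCenters(params)))
  )
  # beyond the cutoff -> zero vector
  farCfg <- configuration(rbind(c(0, 0, 0), c(9, 0, 0)), c("A", "B"))
  expect_equal(sum(twoBodySpectrum(farCfg, 1L, "B", params, reg)), 0)
  # coincident beads signal corrupt geometry
  bad <- configuration(rbind(c(0, 0, 0), c(0, 0, 1e-8)), c("A", "B"))
  expect_error(twoBodySpectrum(bad, 1L, "B", params, reg), "coincident")
})

test_that("three-body spectrum carries the ATM weight and sign", {
  reg <- buildRegistry(data.frame(type = "X", category = "solute"))
  s <- 3
  equi <- configuration(
    rbind(c(0, 0, 0), c(s, 0, 0), c(s / 2, s * sqrt(3) / 2, 0)),
    rep("X", 3L)
  )
  h <- threeBodySpectrum(equi, 1L, c("X", "X"), params, reg)
  expect_equal(sum(h), (1 / 3) * 1.375 / 3^9, tolerance = 0.01)
  expect_equal(sum(h), 2.3283e-5, tolerance = 0.01)
  # mode sits at 60 degrees
  expect_equal(
    angularBinCenters(params)[which.max(h)], pi / 3, tolerance = 0.2
  )
  # collinear triplet through the center: negative ATM factor
  lin <- configuration(
    rbind(c(0, 0, 0), c(-2, 0, 0), c(2, 0, 0)), rep("X", 3L)
  )
  hl <- threeBodySpectrum(lin, 1L, c("X", "X"), params, reg)
  expect_equal(sum(hl), -2 / (3 * 4096), tolerance = 0.01)
  expect_equal(sum(hl), -1.6276e-4, tolerance = 0.01)
  # fewer than two in-cutoff neighbors -> zero vector
  lone <- configuration(
    rbind(c(0, 0, 0), c(2, 0, 0), c(40, 0, 0)), rep("X", 3L)
  )
  expect_equal(
    sum(threeBodySpectrum(lone, 1L, c("X", "X"), params, reg)), 0
  )
})

test_that("atomic SLATM composes per-channel calls and sizes blocks", {
  reg <- testRegistry()
  cfg <- configuration(
    rbind(c(0, 0, 0), c(3, 0, 0), c(0, 4, 0)),
    c("Q0", "T1", "Nda"),
    soluteFlags = c(TRUE, FALSE, FALSE)
  )
  sp <- atomicSlatm(cfg, 1L, params, reg)
  expect_equal(sp@oneBody, 2)            # Q0 has Z = 2 in registry order
  expect_equal(ncol(sp@twoBody), 3L)     # N two-body maps per center
  expect_equal(ncol(sp@threeBody), 6L)   # N(N+1)/2 three-body maps
  for (tt in beadTypes(reg)) {
    expect_equal(
      unname(sp@twoBody[, tt]),
      twoBodySpectrum(cfg, 1L, tt, params, reg)
    )
  }
  expect_equal(
    unname(sp@threeBody[, "T1:Nda"]),
    threeBodySpectrum(cfg, 1L, c("Nda", "T1"), params, reg)
  )
  # isolated bead: identity only, all histograms zero
  iso <- atomicSlatm(
    configuration(matrix(0, 1L, 3L), "T1"), 1L, params, reg
  )
  expect_equal(iso@oneBody, 1)
  expect_equal(sum(abs(iso@twoBody)), 0)
  expect_equal(sum(abs(iso@threeBody)), 0)
})

test_that("implementation matches the brute-force oracle", {
  reg <- testRegistry()
  for (s in 1:12) {
    n <- sample(3:15, 1L)
    cfg <- randomConfig(n, beadTypes(reg), seed = 1000 + s)
    center <- sample(n, 1L)
    got <- atomicSlatm(cfg, center, params, reg)
    want <- oracleAtomicSlatm(cfg, center, params, reg)
    expect_lt(maxRelDiff(got@twoBody, want$twoBody), 1e-8)
    expect_lt(maxRelDiff(got@threeBody, want$threeBody), 1e-8)
  }
})

test_that("spectra are invariant to translation, rotation, permutation", {
  reg <- testRegistry()
  cfg <- randomConfig(15, beadTypes(reg), seed = 42)
  ref <- atomicSlatm(cfg, 1L, params, reg)
  set.seed(43)
  for (rep in 1:3) {
    qr_ <- qr(matrix(rnorm(9), 3L))
    R <- qr.Q(qr_)
    if (det(R) < 0) R[, 1L] <- -R[, 1L]
    shift <- runif(3, -20, 20)
    moved <- configuration(
      sweep(cfg@positions %*% R, 2L, -shift), cfg@types, cfg@soluteFlags
    )
    got <- atomicSlatm(moved, 1L, params, reg)
    expect_lt(max(abs(got@twoBody - ref@twoBody)), 1e-9)
    expect_lt(max(abs(got@threeBody - ref@threeBody)), 1e-9)
  }
  perm <- sample(15)
  shuffled <- configuration(
    cfg@positions[perm, ], cfg@types[perm], cfg@soluteFlags[perm]
  )
  got <- atomicSlatm(shuffled, which(perm == 1L), params, reg)
  expect_lt(max(abs(got@twoBody - ref@twoBody)), 1e-9)
  expect_lt(max(abs(got@threeBody - ref@threeBody)), 1e-9)
})

test_that("out-of-range beads cannot touch the spectrum (locality)", {
  reg <- testRegistry()
  cfg <- randomConfig(8, beadTypes(reg), seed = 77)
  ref <- atomicSlatm(cfg, 1L, params, reg)
  # add a bead beyond r_cutoff + 5 sigma_r from the center
  faraway <- cfg@positions[1L, ] + c(params@rCutoff + 5 * 0.3 + 0.5, 0, 0)
  grown <- configuration(
    rbind(cfg@positions, faraway), c(cfg@types, "Nda"),
    c(cfg@soluteFlags, FALSE)
  )
  got <- atomicSlatm(grown, 1L, params, reg)
  expect_lt(max(abs(got@twoBody - ref@twoBody)), 1e-12)
  expect_lt(max(abs(got@threeBody - ref@threeBody)), 1e-12)
})

test_that("two-body mass decays strictly with distance (R^-6 law)", {
  reg <- buildRegistry(data.frame(type = c("A", "B"), category = "solute"))
  masses <- vapply(seq(2.5, 7.5, by = 0.5), function(r) {
    cfg <- configuration(rbind(c(0, 0, 0), c(r, 0, 0)), c("A", "B"))
    sum(twoBodySpectrum(cfg, 1L, "B", params, reg))
  }, numeric(1))
  expect_true(all(diff(masses) < 0))
})
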