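test_that("PCA recovers planted variance structure", {
  # rank-1 data: first component explains everything
  set.seed(1)
  dir <- c(3, 1, 2) / sqrt(14)
  X1 <- outer(rnorm(20), dir)
  m1 <- fitPca(X1, d = 2L, seed = 1L)
  expect_equal(m1@explainedVarianceRatios[1L], 1, tolerance = 1e-10)
  # seeded 2-D Gaussian with variances 4:1 -> ratios (0.8, 0.2)
  set.seed(2024)
  X2 <- cbind(rnorm(10000, sd = 2), rnorm(10000, sd = 1))
  m2 <- fitPca(X2, d = 2L, seed = 1L)
  expect_equal(
    unname(m2@explainedVarianceRatios), c(0.8, 0.2), tolerance = 0.02
  )
  expect_equal(sum(m2@explainedVarianceRatios), 1, tolerance = 1e-12)
  # full-rank reconstruction recovers the matrix
  set.seed(3)
  X3 <- matrix(rnorm(60), 12L, 5L)
  m3 <- fitPca(X3, d = 5L, seed = 1L)
  rec <- sweep(m3@scores %*% t(m3@rotation), 2L, -m3@center)
  expect_lt(max(abs(rec - X3)), 1e-10)
  # scores are column-centered
  expect_lt(max(abs(colMeans(m3@scores))), 1e-10)
  # constant matrix has no variance to decompose
  expect_error(
    fitPca(matrix(1, 5L, 3L), d = 1L), "zero total variance"
  )
})

test_that("scaled loadings reconstruct channel-score covariances", {
  set.seed(4)
  X <- matrix(rnorm(600), 100L, 6L) %*% diag(c(3, 2, 1, 1, 0.5, 0.2))
  m <- fitPca(X, d = 6L, seed = 1L)
  Xc <- sweep(X, 2L, m@center)
  n <- nrow(X)
  for (k in c(1L, 3L)) {
    covCk <- drop(crossprod(Xc, m@scores[, k])) / (n - 1L)
    expect_lt(
      max(abs(covCk - m@eigenvalues[k] * m@rotation[, k])), 1e-8
    )
  }
})

test_that("projection reproduces training scores and maps means to 0", {
  set.seed(5)
  X <- matrix(rnorm(80), 16L, 5L)
  rownames(X) <- sprintf("c%02d", 1:16)
  m <- fitPca(X, d = 3L, seed = 7L)
  expect_equal(projectScores(m, X), m@scores, tolerance = 1e-12)
  expect_lt(
    max(abs(projectScores(m, matrix(m@center, 1L)))), 1e-12
  )
  # oracle dense product for a held-out vector
  held <- rnorm(5)
  expect_equal(
    drop(projectScores(m, matrix(held, 1L))),
    drop((held - m@center) %*% m@rotation),
    tolerance = 1e-10
  )
  expect_error(projectScores(m, matrix(0, 1L, 4L)), "dimension mismatch")
})

test_that("identical seeds yield identical models", {
  set.seed(6)
  X <- matrix(rnorm(200), 20L)
  a <- fitPca(X, d = 4L, seed = 9L)
  b <- fitPca(X, d = 4L, seed = 9L)
  expect_identical(a@rotation, b@rotation)
  expect_identical(a@scores, b@scores)
  expect_identical(a@eigenvalues, b@eigenvalues)
})

mkToyModel <- function() {
  # hand-built 3-channel model: eigenvectors e2, e1; eigenvalues 4, 1
  rot <- cbind(c(0, 1, 0), c(1, 0, 0))
  rownames(rot) <- c("Q0:Nda", "T1:Nda", "Q0")
  new("PcaModel",
    center = c(0, 0, 0),
    eigenvalues = c(4, 1),
    rotation = rot,
    scores = matrix(rnorm(8), 4L, 2L),
    explainedVarianceRatios = c(4, 1) / 6,
    totalVariance = 6,
    seed = 0L
  )
}

test_that("scaled loadings are eigenvector entries times sqrt(lambda)", {
  m <- mkToyModel()
  # eigenvector 1 is e2 (channel T1:Nda) with lambda = 4
  tab1 <- scaledLoadings(m, 1L)
  expect_equal(tab1$scaledLoading[tab1$channelKey == "T1:Nda"], 2)
  expect_equal(tab1$scaledLoading[tab1$channelKey == "Q0:Nda"], 0)
  # lambda = 1: scaled equals raw loadings
  tab2 <- scaledLoadings(m, 2L)
  expect_equal(tab2$loading, tab2$scaledLoading)
  # ties order lexicographically by channel key
  ties <- tab2[tab2$scaledLoading == 0, "channelKey"]
  expect_equal(ties, sort(ties))
  expect_error(scaledLoadings(m, 3L), "k must lie")
})

test_that("dominant interactions filter by sign and threshold 1.0", {
  m <- mkToyModel()
  expect_equal(
    dominantInteractions(m, 1L)$channelKey, "T1:Nda"
  )
  expect_equal(nrow(dominantInteractions(m, 1L, sign = "negative")), 0L)
  # all below threshold -> empty
  expect_equal(nrow(dominantInteractions(m, 2L, threshold = 1.5)), 0L)
  # planted large negative loading is singled out
  m2 <- mkToyModel()
  m2@rotation[, 1L] <- c(0, -1, 0)
  expect_equal(
    dominantInteractions(m2, 1L, sign = "negative")$channelKey,
    "T1:Nda"
  )
  expect_equal(nrow(dominantInteractions(m2, 1L, sign = "positive")), 0L)
  expect_error(dominantInteractions(m, 1L, threshold = 0), "positive")
})

test_that("regression R2 matches its construction", {
  set.seed(8)
  x <- rnorm(5000)
  # var(noise) / var(2x) = 1/4 -> R2 = 0.8
  y <- 2 * x + rnorm(5000, sd = 1)
  r <- correlateScores(x, y)
  expect_equal(r$r2, 0.8, tolerance = 0.03)
  expect_equal(r$slopeSign, 1)
  # exact colinearity and exact orthogonality
  exact <- suppressWarnings(correlateScores(x, -3 * x))
  expect_equal(exact$r2, 1, tolerance = 1e-12)
  expect_equal(exact$slopeSign, -1)
  yo <- residuals(lm(y ~ x))
  expect_lt(correlateScores(x, yo)$r2, 1e-12)
  expect_error(correlateScores(x, rep(1, 5000)), "zero variance")
})

test_that("interaction graphs count pairwise projections of channels", {
  reg <- testRegistry()
  ci <- buildChannelIndex(reg, "all")
  g1 <- buildInteractionGraph("Q0:Nda", ci, reg)
  expect_equal(igraph::ecount(g1), 1L)
  expect_equal(igraph::E(g1)$weight, 1L)
  # three-body channels project onto their center-neighbor edges
  # (canonical triplet key: center>J:K with J before K in registry order)
  g2 <- buildInteractionGraph(
    c("Q0:Nda", "Nda>T1:Q0"), ci, reg
  )
  w <- igraph::E(g2)$weight
  names(w) <- apply(igraph::as_edgelist(g2), 1L, function(e) {
    paste(sort(e), collapse = "-")
  })
  expect_equal(unname(w[["Nda-Q0"]]), 2L)
  expect_equal(unname(w[["Nda-T1"]]), 1L)
  expect_equal(
    sort(igraph::V(g2)$category), c("lipid", "solute", "solute")
  )
  # empty input gives an empty graph; bad keys are refused
  expect_equal(igraph::ecount(
    buildInteractionGraph(character(0), ci, reg)
  ), 0L)
  expect_error(
    buildInteractionGraph("XX:YY", ci, reg), "not in index"
  )
  # optional neighbor-neighbor leg
  g3 <- buildInteractionGraph(
    "Nda>T1:Q0", ci, reg, includeNeighborEdge = TRUE
  )
  expect_equal(igraph::ecount(g3), 3L)
})

test_that("chart map scales scores to [-1, 1] and picks two-body arrows", {
  set.seed(9)
  sco <- matrix(rnorm(40), 20L, 2L)
  sco <- rbind(sco, -sco)              # symmetric about the origin
  rot <- qr.Q(qr(matrix(rnorm(36), 6L)))[, 1:2]
  rownames(rot) <- c("Q0", "Q0:Nda", "T1:Nda", "Q0>T1:Nda",
                     "Nda:Nda", "T1:T1")
  m <- new("PcaModel",
    center = rep(0, 6L), eigenvalues = c(2, 1), rotation = rot,
    scores = sco, explainedVarianceRatios = c(2, 1) / 4,
    totalVariance = 4, seed = 0L
  )
  bundle <- chartMap(m, 1L, 2L, colorDescriptor = rep(1, 40L),
                     nArrows = 3L)
  expect_true(all(abs(bundle$points$x) <= 1 + 1e-12))
  expect_true(all(abs(bundle$points$y) <= 1 + 1e-12))
  # symmetric data stays symmetric after scaling (row i pairs row i+20)
  expect_lt(
    max(abs(bundle$points$x[1:20] + bundle$points$x[21:40])), 1e-10
  )
  # arrows come from two-body channels only
  expect_true(all(grepl(":", bundle$arrows$channelKey)))
  expect_false(any(grepl(">", bundle$arrows$channelKey)))
  expect_equal(nrow(bundle$arrows), 3L)
  expect_error(chartMap(m, 1L, 1L), "must differ")
  degen <- m
  degen@scores[, 2L] <- 0
  expect_error(chartMap(degen, 1L, 2L), "degenerate axis")
})

test_that("classification recovers separable basins and breaks ties", {
  set.seed(10)
  n <- 40L
  # two linearly separable basins along the first score axis
  s1 <- c(rnorm(n / 2, -3, 0.3), rnorm(n / 2, 3, 0.3))
  s2 <- rnorm(n)
  D <- 4L
  rot <- qr.Q(qr(matrix(rnorm(D * D), D)))[, 1:2]
  rownames(rot) <- c("Q0", "Q0:Nda", "T1:Nda", "T1:T1")
  X <- cbind(s1, s2) %*% t(rot)
  m <- fitPca(X, d = 2L, seed = 1L)
  labels <- ifelse(m@scores[, 1L] < 0, "selective", "non-selective")
  pred <- classifyTraining(m, 1L, 2L, labels)
  expect_equal(mean(pred == labels), 1)
  # a new vector equal to a selective training compound
  i <- which(labels == "selective")[1L]
  out <- classifyNew(m, 1L, 2L, labels, matrix(X[i, ], 1L))
  expect_equal(out$label, "selective")
  expect_equal(
    c(out$scoreA, out$scoreB), unname(m@scores[i, 1:2]),
    tolerance = 1e-10
  )
  # the boundary is reported, the label rule is the strict sign of the
  # decision value, and an exactly-zero decision is non-selective
  bd <- attr(out, "boundary")
  expect_named(bd, c("intercept", "coefA", "coefB"))
  ctr <- classifyNew(m, 1L, 2L, labels, matrix(m@center, 1L))
  expect_equal(ctr$decision, unname(bd[["intercept"]]), tolerance = 1e-10)
  expect_equal(
    ctr$label, ifelse(ctr$decision > 0, "selective", "non-selective")
  )
  expect_error(
    classifyNew(m, 1L, 2L, rep("selective", n), matrix(X[1L, ], 1L)),
    "single class"
  )
})
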