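test_that("orthogonalization removes exactly the zero-lag linear component", {
  set.seed(20)
  s <- rnorm(500)
  # perfect leakage: residual is identically zero
  expect_lt(max(abs(pairwiseOrthogonalize(s, s))), 1e-12)
  # already-orthogonal input is untouched
  t0 <- rnorm(500)
  t0 <- t0 - mean(t0) - cov(s, t0) / var(s) * (s - mean(s))
  expect_lt(max(abs(pairwiseOrthogonalize(s, t0) - t0)), 1e-12)
  # planted mixture: the independent part is recovered
  ind <- rnorm(2400); s2 <- rnorm(2400)
  res <- pairwiseOrthogonalize(s2, 0.5 * s2 + ind)
  expect_gt(cor(res, ind), 0.99)
  # zero-variance seed flagged, test returned unchanged
  flat <- rep(1, 500)
  out <- pairwiseOrthogonalize(flat, t0)
  expect_true(isTRUE(attr(out, "flagged")))
  expect_identical(as.numeric(out), t0)
  expect_error(pairwiseOrthogonalize(s, s[-1]), "lengths differ")
  expect_error(pairwiseOrthogonalize(s[1:5], t0[1:5]), "10 samples")
})

test_that("post-orthogonalization correlation is numerically zero (property)", {
  set.seed(21)
  worst <- 0
  for (i in 1:100) {
    n <- sample(50:500, 1)
    s <- rnorm(n) * runif(1, 0.1, 10)
    x <- rnorm(n) + runif(1, -2, 2) * s
    worst <- max(worst, abs(cor(s, pairwiseOrthogonalize(s, x))))
  }
  expect_lt(worst, 1e-10)
})

test_that("magnetomyogram regression cleans planted envelope contamination", {
  set.seed(22)
  n <- 1000
  mmg <- abs(rnorm(n)) + 0.2
  envTrue <- abs(rnorm(n)) + 1
  # uncorrelated artifact: output is essentially the demeaned envelope
  out0 <- mmgRegress(envTrue, sample(mmg))
  expect_gt(cor(out0, envTrue), 0.99)
  expect_lt(abs(mean(out0)), 1e-10)
  # planted contamination is removed
  env <- envTrue + 0.8 * mmg
  cleaned <- mmgRegress(env, mmg)
  expect_gt(cor(cleaned, envTrue), cor(env, envTrue))
  expect_lt(abs(cor(cleaned, mmg)), 1e-10)
  # constant reference: demean only, flagged
  out <- mmgRegress(env, rep(2, n))
  expect_true(isTRUE(attr(out, "flagged")))
  expect_equal(as.numeric(out), env - mean(env))
})

test_that("artifact-driven high-gamma inflation is halved by mmg regression", {
  cfg <- smallConfig(nRegions = 4, nTrials = 20, trialLength = 3,
                     fs = 600, bands = defaultBands()["gammaHigh"],
                     seed = 3)
  clean <- simulateTrialDataset(cfg)$data
  # independent carriers isolate the shared-envelope pathway targeted by
  # envelope regression
  dirty <- injectMMGArtifact(clean, c(1, 2), amplitude = 6, seed = 4,
                             rate = 0.8, carrierShare = 0)
  gh <- defaultBands()$gammaHigh
  w <- windowSpec("w", 0, 3)
  rClean <- as.matrix(computeTile(clean, gh, gh, w))[1, 2]
  rRaw <- as.matrix(computeTile(dirty, gh, gh, w))[1, 2]
  rCorr <- as.matrix(computeTile(dirty, gh, gh, w, mmg = TRUE))[1, 2]
  expect_gt(rRaw, rClean + 0.1)            # injection inflates
  expect_gte((rRaw - rCorr) / (rRaw - rClean), 0.5)
})

test_that("trial-wise envelope correlation averages raw Pearson r", {
  set.seed(23)
  e <- matrix(abs(rnorm(8 * 200)) + 0.5, 8, 200)
  expect_equal(as.numeric(envelopeCorrelationTrialwise(e, e)), 1)
  e2 <- matrix(abs(rnorm(8 * 200)) + 0.5, 8, 200)
  expect_lt(abs(envelopeCorrelationTrialwise(e, e2)), 3 / sqrt(8 * 200))
  # zero-variance trials are dropped and counted
  e3 <- e2; e3[2, ] <- 1
  r <- envelopeCorrelationTrialwise(e, e3)
  expect_equal(attr(r, "droppedTrials"), 1L)
  expect_error(envelopeCorrelationTrialwise(e[1, , drop = FALSE],
                                            e2[1, , drop = FALSE]),
               "2 trials")
})

test_that("trial-averaged correlation isolates the task-locked component", {
  set.seed(24)
  nTr <- 30; n <- 300
  taskProfile <- 1 + sin(2 * pi * (0:(n - 1)) / n)
  # identical envelopes across trials: averaging changes nothing
  eA <- matrix(rep(taskProfile, nTr), nTr, byrow = TRUE)
  expect_equal(trialAveragedCorrelation(eA, eA),
               as.numeric(envelopeCorrelationTrialwise(eA, eA)))
  # task-locked profile + independent per-trial fluctuations: averaging
  # cancels the fluctuations, so the averaged r exceeds the trialwise r
  fluct <- function() matrix(rnorm(nTr * n, sd = 1.5), nTr)
  a <- eA + fluct(); b <- eA + fluct()
  expect_gt(trialAveragedCorrelation(a, b),
            as.numeric(envelopeCorrelationTrialwise(a, b)))
  # shared per-trial fluctuations plus small region-specific task-locked
  # responses: the trialwise estimator tracks the planted coupling, but
  # averaging cancels the (non-locked) shared fluctuations and leaves the
  # uncorrelated locked responses, collapsing the averaged correlation
  lockA <- matrix(rep(sin(2 * pi * 3 * (0:(n - 1)) / n), nTr), nTr,
                  byrow = TRUE)
  lockB <- matrix(rep(cos(2 * pi * 3 * (0:(n - 1)) / n), nTr), nTr,
                  byrow = TRUE)
  shared <- fluct()
  a2 <- shared + 0.5 * lockA + 0.3 * fluct()
  b2 <- shared + 0.5 * lockB + 0.3 * fluct()
  expect_gt(as.numeric(envelopeCorrelationTrialwise(a2, b2)), 0.6)
  expect_lt(abs(trialAveragedCorrelation(a2, b2)), 0.3)
})

test_that("within-band tiles localize planted coupling and stay symmetric", {
  bset <- quickBands()["alpha"]
  hits <- 0
  for (seed in 1:3) {
    W <- diag(5); W[1, 2] <- W[2, 1] <- 0.8
    cfg <- smallConfig(nRegions = 5, nTrials = 15, trialLength = 3,
                       bands = bset, seed = seed,
                       withinCoupling = list(alpha = W))
    sim <- simulateTrialDataset(cfg)
    tile <- suppressWarnings(
      computeTile(sim$data, bset$alpha, bset$alpha,
                  windowSpec("whole", 0, 3)))
    m <- as.matrix(tile)
    expect_identical(m, t(m))
    expect_true(all(diag(m) == 0))
    expect_true(all(abs(m) <= 1))
    up <- m[upper.tri(m)]
    if (which.max(up) == 1L) hits <- hits + 1  # (1,2) is first in order
  }
  expect_gte(hits, 2)
})

test_that("cross-band tiles stay directed where coupling is asymmetric", {
  bands <- quickBands()
  diffs <- numeric(3)
  for (seed in 1:3) {
    Cm <- matrix(0, 4, 4); Cm[1, 2] <- 0.8  # alpha(r1) -> beta(r2) only
    cfg <- smallConfig(nRegions = 4, nTrials = 15, trialLength = 3,
                       bands = bands, seed = 30 + seed,
                       crossCoupling = list("alpha:beta" = Cm))
    sim <- simulateTrialDataset(cfg)
    tile <- suppressWarnings(
      computeTile(sim$data, bands$alpha, bands$beta,
                  windowSpec("whole", 0, 3)))
    m <- as.matrix(tile)
    diffs[seed] <- m[1, 2] - m[2, 1]
  }
  expect_gt(mean(diffs), 0.2)
  expect_error(
    new("Tile", seedBand = bands$alpha, testBand = bands$alpha,
        matrix = matrix(c(0, 0.2, 0.1, 0), 2), window = windowSpec("w", 0, 1),
        symmetric = FALSE),
    "symmetric")
})

test_that("orthogonalization suppresses pairwise leakage", {
  # unidirectional leakage of region 1 into region 2: the case the
  # pairwise regression removes exactly in the seed-1 direction
  M <- diag(4); M[2, 1] <- 0.35
  cfg <- smallConfig(nRegions = 4, nTrials = 20, trialLength = 4,
                     bands = quickBands()["alpha"], seed = 31,
                     leakageMix = M, noiseSd = 0)
  sim <- simulateTrialDataset(cfg)
  a <- quickBands()$alpha
  w <- windowSpec("whole", 0, 4)
  xf <- suppressWarnings(bandpass(sim$data, a))
  fs <- samplingRate(xf)
  directedR <- function(x, seedIdx, testIdx, orth = TRUE) {
    rs <- vapply(seq_len(nTrials(x)), function(tr) {
      s <- trialData(x)[tr, seedIdx, ]
      t2 <- trialData(x)[tr, testIdx, ]
      if (orth) {
        # leakage appears as zero-lag correlation; regression removes it
        expect_lt(abs(cor(s, pairwiseOrthogonalize(s, t2))), 1e-10)
        t2 <- pairwiseOrthogonalize(s, t2)
      }
      es <- trialData(hilbertEnvelope(trialArray(matrix(s, 1), fs), a))
      et <- trialData(hilbertEnvelope(trialArray(matrix(t2, 1), fs), a))
      cor(as.vector(es), as.vector(et))
    }, 0)
    mean(rs)
  }
  rawR <- directedR(xf, 1, 2, orth = FALSE)
  corrR <- directedR(xf, 1, 2, orth = TRUE)
  nullR <- directedR(xf, 3, 4, orth = TRUE)   # unmixed, uncoupled pair
  # leakage inflates the raw estimate well beyond the null ...
  expect_gt(rawR, abs(nullR) + 0.15)
  # ... and the corrected direction returns to the null level
  expect_lt(abs(corrR), abs(nullR) + 0.05)
  # the symmetrized tile is strictly improved by orthogonalization
  mixed <- as.matrix(computeTile(sim$data, a, a, w))
  raw <- as.matrix(computeTile(sim$data, a, a, w, orthogonalize = FALSE))
  expect_lt(mixed[1, 2], raw[1, 2])
})

test_that("super-adjacency assembly enforces the tile inventory", {
  bands4 <- defaultBands()
  regions <- paste0("r", 1:78)
  mkTile <- function(a, b) {
    m <- matrix(runif(78 * 78, -0.4, 0.4), 78,
                dimnames = list(regions, regions))
    if (a@name == b@name) {
      m <- (m + t(m)) / 2; diag(m) <- 0
    }
    new("Tile", seedBand = a, testBand = b, matrix = m,
        window = windowSpec("whole", 0, 1),
        symmetric = a@name == b@name)
  }
  tiles <- list()
  for (i in 1:4) tiles[[i]] <- mkTile(bands4[[i]], bands4[[i]])
  for (i in 1:4) for (j in 1:4)
    if (i < j) tiles[[length(tiles) + 1]] <- mkTile(bands4[[i]],
                                                    bands4[[j]])
  expect_length(tiles, 10L)   # 4 within + 6 between
  sm <- assembleSM(tiles, bands4)
  expect_equal(dim(as.matrix(sm)), c(312L, 312L))
  # round trip reproduces every tile exactly
  back <- disassembleSM(sm)
  expect_length(back, 10L)
  for (k in seq_along(tiles))
    expect_equal(back[[k]]@matrix, tiles[[k]]@matrix)
  # block (b, a) is the transpose of block (a, b)
  m <- sm@matrix
  expect_identical(m[79:156, 1:78], t(m[1:78, 79:156]))
  expect_error(assembleSM(tiles[-1], bands4), "missing tile")
  expect_error(assembleSM(c(tiles, tiles[7]), bands4), "duplicate")
  # two bands make three distinct tiles
  b2 <- bands4[1:2]
  t2 <- list(mkTile(b2[[1]], b2[[1]]), mkTile(b2[[2]], b2[[2]]),
             mkTile(b2[[1]], b2[[2]]))
  expect_length(disassembleSM(assembleSM(t2, b2)), 3L)
})

test_that("pipeline output is invariant to sign flips and rescaling", {
  cfg <- smallConfig(nRegions = 3, nTrials = 8, trialLength = 3,
                     bands = quickBands()["alpha"], seed = 32)
  sim <- simulateTrialDataset(cfg)
  a <- quickBands()$alpha
  w <- windowSpec("whole", 0, 3)
  base <- suppressWarnings(as.matrix(computeTile(sim$data, a, a, w)))
  d <- trialData(sim$data)
  d[, 2, ] <- -d[, 2, ]            # global sign flip of one region
  d[, 3, ] <- 4.2 * d[, 3, ]       # positive rescaling of another
  mod <- trialArray(d, fs = samplingRate(sim$data))
  expect_equal(suppressWarnings(as.matrix(computeTile(mod, a, a, w))),
               base, tolerance = 1e-10, ignore_attr = TRUE)
})
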