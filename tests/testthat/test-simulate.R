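test_that("a fixed seed fixes every output bit for bit", {
  cfg <- smallConfig(seed = 11)
  a <- simulateTrialDataset(cfg)
  b <- simulateTrialDataset(cfg)
  expect_identical(trialData(a$data), trialData(b$data))
  expect_identical(a$truth@seed, b$truth@seed)
  c <- simulateTrialDataset(smallConfig(seed = 12))
  expect_false(identical(trialData(a$data), trialData(c$data)))
})

test_that("identity couplings give independent envelopes", {
  cfg <- smallConfig(nRegions = 4, nTrials = 12, trialLength = 4,
                     bands = quickBands()["alpha"], seed = 21,
                     noiseSd = 0)
  sim <- simulateTrialDataset(cfg)
  tile <- computeTile(sim$data, quickBands()$alpha, quickBands()$alpha,
                      windowSpec("whole", 0, 4), orthogonalize = FALSE)
  offdiag <- as.matrix(tile)[upper.tri(as.matrix(tile))]
  # N effective envelope samples ~ trials x (2 * cutoffHz * duration)
  nEff <- 12 * 2 * cfg@envelopeCutoffHz * 4
  expect_lt(max(abs(offdiag)), 3 / sqrt(nEff))
})

test_that("planted envelope coupling is recovered near the calibrated target", {
  # study-condition geometry (45 trials, 8.5 s @ 600 Hz), reduced regions
  bset <- defaultBands()["beta"]
  W <- diag(4); W[1, 2] <- W[2, 1] <- 0.6
  cfg <- simulationConfig(nRegions = 4, nTrials = 45, trialLength = 8.5,
                          fs = 600, bands = bset,
                          withinCoupling = list(beta = W),
                          modulation = data.frame(),
                          couplingSpace = "envelope", seed = 42)
  sim <- simulateTrialDataset(cfg)
  tile <- computeTile(sim$data, bset$beta, bset$beta,
                      windowSpec("whole", 0, 8.5))
  est <- as.matrix(tile)[1, 2]
  expect_lt(abs(est - 0.6), 0.1)
  # uncoupled pairs stay near zero
  expect_lt(abs(as.matrix(tile)[3, 4]), 0.15)
})

test_that("modulation gains imprint decrease then overshoot on the envelope", {
  mod <- data.frame(band = "beta", region = NA_integer_,
                    tStart = c(0, 2), tEnd = c(2, 4), gain = c(0.5, 1.5))
  cfg <- simulationConfig(nRegions = 2, nTrials = 15, trialLength = 6,
                          fs = 250, bands = defaultBands()["beta"],
                          modulation = mod, couplingSpace = "latent",
                          seed = 33)
  sim <- simulateTrialDataset(cfg)
  env <- hilbertEnvelope(bandpass(sim$data, defaultBands()$beta))
  avg <- apply(trialData(env)[, 1, , drop = FALSE], 3, mean)
  tt <- trialTimes(env)
  base <- mean(avg[tt >= 4.5 & tt < 5.8])
  stim <- mean(avg[tt >= 0.3 & tt < 2])
  reb <- mean(avg[tt >= 2.2 & tt < 4])
  expect_lt(stim, base)   # suppression during the gain-0.5 segment
  expect_gt(reb, base)    # overshoot during the gain-1.5 segment
})

test_that("non-PSD coupling requests fail with advice unless projected", {
  W <- diag(3)
  W[1, 2] <- W[2, 1] <- 0.9
  W[2, 3] <- W[3, 2] <- 0.9
  W[1, 3] <- W[3, 1] <- -0.9
  cfg <- smallConfig(nRegions = 3, nTrials = 2, trialLength = 2,
                     bands = quickBands()["alpha"],
                     withinCoupling = list(alpha = W))
  expect_error(simulateTrialDataset(cfg), "nearestPSD")
  expect_s4_class(simulateTrialDataset(cfg, nearestPSD = TRUE)$data,
                  "TrialArray")
})

test_that("leakage mixing reproduces the closed-form zero-lag correlation", {
  set.seed(4)
  n <- 1e5
  x <- trialArray(array(rnorm(3 * n), c(1, 3, n)), fs = 1000)
  M <- matrix(c(1, 0.4, 0.1, 0, 1, 0.3, 0.2, 0, 1), 3, 3)
  y <- applyLeakageMix(x, M)
  emp <- cor(t(matrix(trialData(y)[1, , ], nrow = 3)))
  expected <- cov2cor(M %*% t(M))
  expect_lt(max(abs(emp - expected)), 1e-2)
})

test_that("sensor simulation has the planted low-rank structure", {
  # single unit source, no noise -> rank-1 sensor data
  cfg <- smallConfig(nRegions = 1, nTrials = 2, trialLength = 2,
                     bands = quickBands()["alpha"], noiseSd = 0, seed = 2)
  ss <- simulateSensorDataset(cfg, list(nSensors = 24,
                                        sensorNoiseSd = 0))
  S <- matrix(trialData(ss$sensors)[1, , ], nrow = 24)
  sv <- svd(S)$d
  expect_lt(sv[2] / sv[1], 1e-8)
  # two uncorrelated sources -> exactly two dominant eigenvalues
  cfg2 <- smallConfig(nRegions = 2, nTrials = 2, trialLength = 3,
                      bands = quickBands()["alpha"], noiseSd = 0,
                      seed = 3)
  ss2 <- simulateSensorDataset(cfg2, list(nSensors = 24,
                                          sensorNoiseSd = 1e-4))
  S2 <- matrix(trialData(ss2$sensors)[1, , ], nrow = 24)
  ev <- eigen(cov(t(S2)), symmetric = TRUE, only.values = TRUE)$values
  expect_gt(ev[2] / ev[3], 100)   # two signal eigenvalues above noise
  # source outside the sphere is rejected
  expect_error(
    sphericalLeadfield(matrix(c(0, 0, 150), 1),
                       matrix(c(0, 0, 110, 0, 110, 0), 2, 3,
                              byrow = TRUE)),
    "outside")
})

test_that("artifact injection is controlled by amplitude and shares envelopes", {
  cfg <- smallConfig(nRegions = 3, nTrials = 6, trialLength = 2,
                     fs = 600, bands = defaultBands()["gammaHigh"],
                     seed = 6)
  x <- simulateTrialDataset(cfg)$data
  expect_identical(injectMMGArtifact(x, 1:2, amplitude = 0), x)
  expect_error(injectMMGArtifact(x, 1:2, amplitude = -1), "non-negative")
  expect_error(injectMMGArtifact(x, c(1, 9), amplitude = 1), "indices")
  y <- injectMMGArtifact(x, 1:2, amplitude = 5, seed = 7)
  env <- hilbertEnvelope(bandpass(y, mmgBand()))
  rs <- vapply(seq_len(nTrials(env)), function(tr)
    cor(trialData(env)[tr, 1, ], trialData(env)[tr, 2, ]), 0)
  expect_gte(mean(rs), 0.9)
})

test_that("cohort generator plants a group- and severity-dependent deficit", {
  cfg <- smallConfig(nRegions = 5, nTrials = 6, trialLength = 2.5,
                     bands = quickBands(), seed = 1)
  edges <- rbind(c(1, 2), c(2, 3))
  # null cohort: all subjects share the same generating couplings
  co0 <- simulateCohort(3, 3, config = cfg, deficitTile = "alpha",
                        deficitEdges = edges, deficitSize = 0,
                        severitySlope = 0, baseCoupling = 0.5, seed = 2)
  expect_equal(nrow(co0$cohort), 6L)
  expect_true(all(is.na(co0$cohort$severity[1:3])))
  expect_equal(sd(co0$cohort$severity[4:6]), 1)
  # an excessive deficit is rejected
  expect_error(
    simulateCohort(2, 2, config = cfg, deficitEdges = edges,
                   deficitSize = 2.5, severitySlope = 0,
                   baseCoupling = 0, seed = 3),
    "below -1")
  # planted deficit: controls exceed patients on deficit edges
  co <- simulateCohort(8, 8, config = cfg, deficitTile = "alpha",
                       deficitEdges = edges, deficitSize = 0.45,
                       severitySlope = 0.15, baseCoupling = 0.65,
                       seed = 4)
  cc <- suppressWarnings(computeCohortConnectivity(
    co$subjects, co$cohort, quickBands(),
    windowSpec("whole", 0, 2.5)))
  D <- effectOfDiagnosis(cc)
  a <- as.matrix(getTile(D, "alpha", "alpha"))
  planted <- mean(a[edges])
  others <- mean(a[upper.tri(a)]) * length(a[upper.tri(a)])
  others <- (others - sum(a[edges])) / (length(a[upper.tri(a)]) - 2)
  expect_gt(planted, others)
  expect_gt(planted, 0)
})

test_that("calibration map is monotone and invertible", {
  b <- quickBands()$alpha
  cal <- calibrateCoupling(b, fs = 250, duration = 3, nTrials = 6,
                           nRep = 3)
  expect_true(all(diff(cal$grid$envR) >= 0))
  mid <- cal$toEnvelope(0.5)
  expect_equal(cal$toEnvelope(cal$toLatent(mid)), mid, tolerance = 1e-9)
})
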