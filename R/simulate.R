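# Synthetic narrowband datasets with planted envelope couplings, task
# modulation, leakage mixing and high-frequency muscle artifact.

# run expr under a private RNG stream, restoring the caller's stream
withLocalSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# real Gaussian noise with a brick-wall band-limited spectrum, sd 1
fourierBandNoise <- function(n, fs, fLo, fHi) {
  f <- (seq_len(n) - 1) * fs / n
  half <- 2:(ceiling(n / 2))
  keep <- half[f[half] >= fLo & f[half] <= fHi]
  if (length(keep) < 2L)
    stop("band too narrow for the requested duration")
  X <- complex(n)
  X[keep] <- complex(real = stats::rnorm(length(keep)),
                     imaginary = stats::rnorm(length(keep)))
  X[n + 2L - keep] <- Conj(X[keep])
  x <- Re(stats::fft(X, inverse = TRUE)) / n
  x / stats::sd(x)
}

# samples x 2K basis of unit-variance band-limited [0, fc] oscillations
slowBasis <- function(n, fs, fc) {
  T <- n / fs
  K <- max(1L, ceiling(fc * T))
  t <- (seq_len(n) - 1) / fs
  F <- matrix(0, n, 2L * K)
  for (k in seq_len(K)) {
    F[, 2L * k - 1L] <- cos(2 * pi * k / T * t)
    F[, 2L * k] <- sin(2 * pi * k / T * t)
  }
  F / sqrt(K)  # coefficient draws N(0,1) then give unit process variance
}

#' @rdname SimulationConfig-class
#' @param nRegions,nTrials,trialLength,fs,bands,withinCoupling,crossCoupling,modulation,leakageMix,mmg,noiseSd,logEnvSd,envelopeCutoffHz,couplingSpace,seed
#'   see the class slots; unspecified couplings default to identity
#'   (within band) and zero (between bands).
#' @examples
#' cfg <- simulationConfig(nRegions = 4, nTrials = 5, trialLength = 3,
#'                         fs = 250, bands = defaultBands()[c("alpha", "beta")])
#' @export
simulationConfig <- function(nRegions = 78, nTrials = 45, trialLength = 9,
                             fs = 600, bands = defaultBands(),
                             withinCoupling = NULL, crossCoupling = NULL,
                             modulation = NULL, leakageMix = NULL,
                             mmg = NULL, noiseSd = 0.05, logEnvSd = 1,
                             envelopeCutoffHz = 1,
                             couplingSpace = c("envelope", "latent"),
                             seed = 1L) {
  couplingSpace <- match.arg(couplingSpace)
  bn <- vapply(bands, function(b) b@name, "")
  names(bands) <- bn
  if (is.null(withinCoupling))
    withinCoupling <- stats::setNames(
      replicate(length(bands), diag(nRegions), simplify = FALSE), bn)
  if (is.null(crossCoupling)) crossCoupling <- list()
  if (is.null(modulation)) modulation <- defaultTaskModulation(bn)
  modulation <- modulation[modulation$band %in% bn, , drop = FALSE]
  new("SimulationConfig", nRegions = as.numeric(nRegions),
      nTrials = as.numeric(nTrials), trialLength = as.numeric(trialLength),
      fs = as.numeric(fs), bands = bands, withinCoupling = withinCoupling,
      crossCoupling = crossCoupling, modulation = modulation,
      leakageMix = leakageMix, mmg = mmg, noiseSd = noiseSd,
      logEnvSd = logEnvSd, envelopeCutoffHz = envelopeCutoffHz,
      couplingSpace = couplingSpace, seed = as.numeric(seed))
}

#' Default task-locked amplitude modulation
#'
#' Piecewise gains emulating a visuomotor response: beta decrease during
#' the stimulus (0--2 s) with a rebound overshoot (2--4 s), alpha
#' decrease and gamma increase during the stimulus.
#'
#' @param bandNames band names to include.
#' @return A data frame with columns `band`, `region` (NA = all regions),
#'   `tStart`, `tEnd`, `gain`.
#' @export
defaultTaskModulation <- function(bandNames = names(defaultBands())) {
  m <- data.frame(
    band = c("beta", "beta", "alpha", "gammaLow", "gammaHigh"),
    region = NA_integer_,
    tStart = c(0, 2, 0, 0, 0),
    tEnd = c(2, 4, 2, 2, 2),
    gain = c(0.6, 1.4, 0.6, 1.2, 1.5))
  m[m$band %in% bandNames, , drop = FALSE]
}

# gain vector over trial time for one (band, region)
modulationGain <- function(modulation, bandName, region, times) {
  g <- rep(1, length(times))
  if (nrow(modulation) == 0L) return(g)
  rows <- modulation$band == bandName &
    (is.na(modulation$region) | modulation$region == region)
  for (i in which(rows)) {
    sel <- times >= modulation$tStart[i] & times < modulation$tEnd[i]
    g[sel] <- g[sel] * modulation$gain[i]
  }
  g
}

# cache for calibration curves
.calCache <- new.env(parent = emptyenv())

#' Monte-Carlo calibration of envelope coupling
#'
#' Maps the latent Gaussian-copula correlation `rho` of two log-normal
#' envelopes to the Pearson correlation actually measured between the
#' Hilbert envelopes of the resulting narrowband signals (mean trial-wise
#' correlation, the pipeline's estimator). The map is monotone; its
#' inverse converts requested envelope correlations into copula
#' correlations, making simulator targets interpretable on the measured
#' scale. Results are cached per parameter set.
#'
#' @param band a [BandSpec-class].
#' @param fs sampling rate, Hz.
#' @param duration correlated segment length per trial, s.
#' @param nTrials trials per replicate.
#' @param logEnvSd,envelopeCutoffHz generator parameters, see
#'   [SimulationConfig-class].
#' @param rhoGrid latent correlations at which to evaluate the map.
#' @param nRep Monte-Carlo replicates per grid point.
#' @return A list with `grid` (data frame `rho`, `envR`), `toEnvelope`
#'   (function rho -> envelope r) and `toLatent` (its inverse).
#' @export
calibrateCoupling <- function(band, fs, duration, nTrials = 20,
                              logEnvSd = 1, envelopeCutoffHz = 1,
                              rhoGrid = c(0, 0.2, 0.4, 0.6, 0.75, 0.9,
                                          0.97),
                              nRep = 10) {
  key <- paste(band@fLo, band@fHi, fs, round(duration, 4), nTrials,
               logEnvSd, envelopeCutoffHz, length(rhoGrid), nRep,
               sep = "|")
  if (!is.null(.calCache[[key]])) return(.calCache[[key]])
  n <- round(duration * fs)
  F <- slowBasis(n, fs, envelopeCutoffHz)
  envR <- withLocalSeed(20160515, vapply(rhoGrid, function(rho) {
    L <- chol(matrix(c(1, rho, rho, 1), 2) + diag(2) * 1e-12)
    mean(replicate(nRep, {
      rs <- numeric(nTrials)
      for (tr in seq_len(nTrials)) {
        Z <- (F %*% matrix(stats::rnorm(ncol(F) * 2), ncol = 2)) %*% L
        e <- exp(logEnvSd * Z)
        sig <- vapply(1:2, function(j)
          e[, j] * fourierBandNoise(n, fs, band@fLo, band@fHi), numeric(n))
        env <- envelopeOf(sig)
        rs[tr] <- stats::cor(env[, 1], env[, 2])
      }
      mean(rs)
    }))
  }, 0))
  # enforce monotonicity for a well-defined inverse
  envR <- cummax(envR)
  grid <- data.frame(rho = rhoGrid, envR = envR)
  toEnv <- stats::approxfun(rhoGrid, envR, rule = 2)
  toLat <- stats::approxfun(envR, rhoGrid, rule = 2, ties = "ordered")
  out <- list(grid = grid, toEnvelope = toEnv, toLatent = toLat)
  .calCache[[key]] <- out
  out
}

# assemble the latent node-correlation matrix (band-major blocks)
latentSigma <- function(config, nearestPSD = FALSE) {
  bn <- names(config@bands)
  B <- length(bn); R <- config@nRegions
  maps <- NULL
  if (config@couplingSpace == "envelope") {
    maps <- lapply(config@bands, function(b)
      calibrateCoupling(b, config@fs, config@trialLength,
                        nTrials = min(config@nTrials, 20),
                        logEnvSd = config@logEnvSd,
                        envelopeCutoffHz = config@envelopeCutoffHz))
    names(maps) <- bn
  }
  toLatent <- function(m, a, b) {
    if (is.null(maps)) return(m)
    s <- sign(m)
    # cross-band map: average of the two per-band inverse maps
    la <- maps[[a]]$toLatent(abs(m)); lb <- maps[[b]]$toLatent(abs(m))
    out <- s * (la + lb) / 2
    out[m == 0] <- 0
    out
  }
  S <- diag(B * R)
  lat <- list()
  for (i in seq_len(B)) {
    W <- config@withinCoupling[[bn[i]]]
    if (is.null(W)) W <- diag(R)
    Wl <- toLatent(W, bn[i], bn[i]); diag(Wl) <- 1
    idx <- (i - 1) * R + seq_len(R)
    S[idx, idx] <- (Wl + t(Wl)) / 2
    lat[[bn[i]]] <- S[idx, idx]
  }
  for (i in seq_len(B)) for (j in seq_len(B)) {
    if (i >= j) next
    key <- paste(bn[i], bn[j], sep = ":")
    Cm <- config@crossCoupling[[key]]
    if (is.null(Cm)) Cm <- matrix(0, R, R)
    Cl <- toLatent(Cm, bn[i], bn[j])
    ii <- (i - 1) * R + seq_len(R); jj <- (j - 1) * R + seq_len(R)
    S[ii, jj] <- Cl; S[jj, ii] <- t(Cl)
    lat[[key]] <- Cl
  }
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    if (!nearestPSD)
      stop("requested coupling matrix is not positive semi-definite; ",
           "rerun with nearestPSD = TRUE to project to the nearest ",
           "correlation matrix")
    S <- as.matrix(Matrix::nearPD(S, corr = TRUE)$mat)
  }
  list(sigma = S, latent = lat)
}

#' Simulate a regional trial dataset with planted envelope couplings
#'
#' Per band and region, an independent band-pass-filtered noise carrier
#' is amplitude-modulated by a log-normal envelope; envelopes across all
#' (band, region) nodes are drawn from a Gaussian copula implementing the
#' requested within-band and cross-band envelope correlations. Task
#' modulation gains multiply the envelopes, the regional signal is the
#' sum over bands plus white noise, and an optional leakage matrix mixes
#' regions instantaneously. An optional shared 120--150 Hz artifact is
#' injected last.
#'
#' @param config a [SimulationConfig-class].
#' @param nearestPSD project a non-positive-semi-definite coupling
#'   request to the nearest correlation matrix instead of failing.
#' @return A list with `data` (a regional [TrialArray-class]) and
#'   `truth` (a [GroundTruth-class]).
#' @examples
#' cfg <- simulationConfig(nRegions = 3, nTrials = 2, trialLength = 2,
#'                         fs = 250, bands = defaultBands()["alpha"],
#'                         couplingSpace = "latent", modulation = data.frame())
#' sim <- simulateTrialDataset(cfg)
#' @export
simulateTrialDataset <- function(config, nearestPSD = FALSE) {
  stopifnot(is(config, "SimulationConfig"))
  sig <- latentSigma(config, nearestPSD)   # calibration uses its own RNG
  set.seed(config@seed)
  bn <- names(config@bands)
  B <- length(bn); R <- config@nRegions
  n <- round(config@trialLength * config@fs)
  times <- (seq_len(n) - 1) / config@fs
  Rt <- chol(sig$sigma + diag(B * R) * 1e-10)
  F <- slowBasis(n, config@fs, config@envelopeCutoffHz)
  gains <- matrix(1, n, B * R)
  for (i in seq_len(B)) for (r in seq_len(R))
    gains[, (i - 1) * R + r] <-
      modulationGain(config@modulation, bn[i], r, times)
  data <- array(0, c(config@nTrials, R, n))
  for (tr in seq_len(config@nTrials)) {
    Z <- (F %*% matrix(stats::rnorm(ncol(F) * B * R), ncol = B * R)) %*% Rt
    E <- exp(config@logEnvSd * Z) * gains
    X <- matrix(0, n, R)
    for (i in seq_len(B)) {
      b <- config@bands[[i]]
      for (r in seq_len(R)) {
        carrier <- fourierBandNoise(n, config@fs, b@fLo, b@fHi)
        X[, r] <- X[, r] + E[, (i - 1) * R + r] * carrier
      }
    }
    if (config@noiseSd > 0)
      X <- X + matrix(stats::rnorm(n * R, sd = config@noiseSd), n, R)
    if (!is.null(config@leakageMix))
      X <- X %*% t(config@leakageMix)
    data[tr, , ] <- t(X)
  }
  out <- trialArray(data, config@fs, t0 = 0, seriesKind = "regional",
                    labels = paste0("region", seq_len(R)),
                    meta = list(bands = config@bands,
                                simSeed = config@seed))
  couplings <- c(config@withinCoupling, config@crossCoupling)
  artifact <- list()
  if (!is.null(config@mmg)) {
    out <- injectMMGArtifact(out, regions = config@mmg$regions,
                             amplitude = config@mmg$amplitude)
    artifact <- config@mmg
  }
  truth <- new("GroundTruth", couplings = couplings,
               latentCouplings = sig$latent,
               modulation = config@modulation, artifact = artifact,
               seed = config@seed, config = config)
  list(data = out, truth = truth)
}

#' Apply an instantaneous leakage mixing matrix
#'
#' Mixes regional signals as `X M'` sample by sample, emulating the
#' zero-lag linear cross-talk (signal leakage) introduced by an ill-posed
#' source reconstruction.
#'
#' @param x a [TrialArray-class].
#' @param M an invertible `regions x regions` mixing matrix.
#' @return A mixed [TrialArray-class].
#' @export
applyLeakageMix <- function(x, M) {
  stopifnot(is(x, "TrialArray"))
  R <- dim(x@data)[2]
  M <- as.matrix(M)
  if (!all(dim(M) == R)) stop("mixing matrix of wrong size")
  out <- x@data
  for (tr in seq_len(dim(out)[1])) {
    X <- t(matrix(x@data[tr, , ], nrow = R))
    out[tr, , ] <- t(X %*% t(M))
  }
  new("TrialArray", data = out, fs = x@fs, t0 = x@t0,
      seriesKind = x@seriesKind, labels = x@labels, meta = x@meta)
}

#' Inject a shared bilateral muscle (magnetomyogram) artifact
#'
#' Adds a high-frequency band-limited burst train to the listed regions.
#' Muscle activity is broadband at high frequencies, so the default
#' carriers span 60--150 Hz: they contaminate the high-gamma (50--100
#' Hz) range while their 120--150 Hz portion is captured by the
#' magnetomyogram reference band used for regression. The burst envelope
#' is identical across regions (muscle artifacts are typically
#' bilateral) while the carriers are independent, so the artifact
#' inflates high-frequency envelope correlation between the regions
#' without adding zero-lag signal correlation.
#'
#' @param x a [TrialArray-class] sampled fast enough to contain 150 Hz.
#' @param regions indices of affected series.
#' @param amplitude artifact scale (>= 0; 0 returns the input unchanged).
#' @param seed optional RNG seed.
#' @param rate expected bursts per second.
#' @param burstDuration burst length, s.
#' @param artifactBand two-element carrier frequency range, Hz.
#' @param carrierShare variance fraction of the carrier shared between
#'   regions (bilateral bursts share common motor drive); the shared
#'   zero-lag component is removed downstream by orthogonalization,
#'   while the shared burst envelope is what the magnetomyogram
#'   regression targets.
#' @return A [TrialArray-class] with the artifact added.
#' @export
injectMMGArtifact <- function(x, regions, amplitude, seed = NULL,
                              rate = 0.5, burstDuration = 0.4,
                              artifactBand = c(60, 150),
                              carrierShare = 0.9) {
  stopifnot(is(x, "TrialArray"))
  if (amplitude < 0) stop("'amplitude' must be non-negative")
  if (!all(regions %in% seq_len(dim(x@data)[2])))
    stop("invalid region indices")
  if (amplitude == 0) return(x)
  if (x@fs / 2 <= 150)
    stop("sampling rate too low for the 120-150 Hz artifact band")
  if (!is.null(seed)) set.seed(seed)
  n <- dim(x@data)[3]
  T <- n / x@fs
  wb <- round(burstDuration * x@fs)
  bump <- 0.5 * (1 - cos(2 * pi * seq_len(wb) / (wb + 1)))  # Hann
  out <- x@data
  for (tr in seq_len(dim(out)[1])) {
    env <- rep(0.1, n)
    nb <- max(1L, stats::rpois(1, rate * T))
    for (k in seq_len(nb)) {
      at <- sample.int(max(1L, n - wb), 1)
      idx <- at:(at + wb - 1L)
      env[idx] <- env[idx] + bump
    }
    shared <- fourierBandNoise(n, x@fs, artifactBand[1], artifactBand[2])
    for (r in regions) {
      own <- fourierBandNoise(n, x@fs, artifactBand[1], artifactBand[2])
      carrier <- sqrt(carrierShare) * shared +
        sqrt(1 - carrierShare) * own
      out[tr, r, ] <- out[tr, r, ] + amplitude * env * carrier
    }
  }
  meta <- x@meta
  meta$artifact <- list(regions = regions, amplitude = amplitude)
  new("TrialArray", data = out, fs = x@fs, t0 = x@t0,
      seriesKind = x@seriesKind, labels = x@labels, meta = meta)
}

#' Simulate a cohort with a planted connectivity deficit
#'
#' Generates per-subject regional datasets where patients' envelope
#' coupling on selected edges of one tile is reduced by
#' `deficitSize + severitySlope * severity`, with standardized severity
#' scores; controls are unaltered. Emulates a patient group with reduced
#' band-limited connectivity in a sub-network, scaling with symptom
#' severity.
#'
#' @param nControls,nPatients group sizes.
#' @param config base [SimulationConfig-class] shared by all subjects.
#' @param deficitTile band name (within-band tile) or
#'   `c(seedBand, testBand)` for a between-band tile.
#' @param deficitEdges two-column matrix of region index pairs.
#' @param deficitSize mean coupling reduction in patients.
#' @param severitySlope additional reduction per severity unit.
#' @param baseCoupling coupling planted on the edges for all subjects.
#' @param seed RNG seed (drives severity draws and per-subject seeds).
#' @return A list with `subjects` (list of [TrialArray-class]), `cohort`
#'   (data frame `subject_id`, `group`, `severity`) and `truth`
#'   (a [GroundTruth-class]; the planted deficit is described in its
#'   `artifact` slot).
#' @export
simulateCohort <- function(nControls = 23, nPatients = 23,
                           config = simulationConfig(),
                           deficitTile = "alpha",
                           deficitEdges = rbind(c(1, 2), c(1, 3),
                                                c(2, 3), c(3, 4)),
                           deficitSize = 0.3, severitySlope = 0.2,
                           baseCoupling = 0.5, seed = 1L) {
  stopifnot(is(config, "SimulationConfig"), deficitSize >= 0)
  deficitTile <- rep(deficitTile, length.out = 2)
  within <- deficitTile[1] == deficitTile[2]
  if (!all(deficitTile %in% names(config@bands)))
    stop("deficit tile names an unknown band")
  set.seed(seed)
  nSub <- nControls + nPatients
  severity <- as.numeric(scale(stats::rnorm(nPatients)))
  group <- c(rep("control", nControls), rep("patient", nPatients))
  subjects <- vector("list", nSub)
  for (i in seq_len(nSub)) {
    cfg <- config
    drop <- if (group[i] == "patient")
      deficitSize + severitySlope * severity[i - nControls] else 0
    val <- baseCoupling - drop
    if (any(val < -1))
      stop("deficit reduces coupling below -1")
    if (within) {
      W <- cfg@withinCoupling[[deficitTile[1]]]
      for (k in seq_len(nrow(deficitEdges))) {
        W[deficitEdges[k, 1], deficitEdges[k, 2]] <- val
        W[deficitEdges[k, 2], deficitEdges[k, 1]] <- val
      }
      cfg@withinCoupling[[deficitTile[1]]] <- W
    } else {
      key <- paste(deficitTile[1], deficitTile[2], sep = ":")
      Cm <- cfg@crossCoupling[[key]]
      if (is.null(Cm)) Cm <- matrix(0, config@nRegions, config@nRegions)
      for (k in seq_len(nrow(deficitEdges)))
        Cm[deficitEdges[k, 1], deficitEdges[k, 2]] <- val
      cfg@crossCoupling[[key]] <- Cm
    }
    cfg@seed <- (seed + 104729 * i) %% .Machine$integer.max
    subjects[[i]] <- simulateTrialDataset(cfg, nearestPSD = TRUE)$data
  }
  cohort <- data.frame(
    subject_id = sprintf("S%03d", seq_len(nSub)),
    group = group,
    severity = c(rep(NA_real_, nControls), severity),
    stringsAsFactors = FALSE)
  truth <- new("GroundTruth",
               couplings = c(config@withinCoupling, config@crossCoupling),
               latentCouplings = list(),
               modulation = config@modulation,
               artifact = list(deficitTile = deficitTile,
                               deficitEdges = deficitEdges,
                               deficitSize = deficitSize,
                               severitySlope = severitySlope,
                               baseCoupling = baseCoupling,
                               severity = severity),
               seed = as.numeric(seed), config = config)
  list(subjects = subjects, cohort = cohort, truth = truth)
}

#' Simulate a sensor-level dataset through an analytic forward model
#'
#' Generates regional source signals with [simulateTrialDataset()], plants
#' them at source positions inside a conducting sphere with tangential
#' orientations, and projects them to radial sensors through the analytic
#' dipole-in-sphere forward field, adding white sensor noise.
#'
#' @param config a [SimulationConfig-class] (its `nRegions` sets the
#'   source count; leakage mixing is ignored at source level).
#' @param leadfieldSpec list with optional entries `nSensors` (default
#'   32), `sphereRadius` (mm, default 100), `sensorRadius` (default 110),
#'   `sourceRadius` (default 70), `sourcePositions` (`sources x 3`),
#'   `orientations` (`sources x 3`, tangential), `sensorNoiseSd`
#'   (default 0.1).
#' @return A list with `sensors` (sensor [TrialArray-class]), `leadfield`
#'   (a [Leadfield-class]), `orientations`, `sources` (the source
#'   [TrialArray-class]) and `truth`.
#' @export
simulateSensorDataset <- function(config, leadfieldSpec = list()) {
  spec <- utils::modifyList(
    list(nSensors = 32, sphereRadius = 100, sensorRadius = 110,
         sourceRadius = 70, sourcePositions = NULL, orientations = NULL,
         sensorNoiseSd = 0.1), leadfieldSpec)
  sim <- simulateTrialDataset(
    `slot<-`(config, "leakageMix", value = NULL))
  R <- config@nRegions
  # RNG continues from the simulation stream seeded by config@seed
  pos <- spec$sourcePositions
  if (is.null(pos)) {
    pos <- matrix(stats::rnorm(R * 3), R, 3)
    pos <- pos / sqrt(rowSums(pos^2)) *
      (spec$sourceRadius * stats::runif(R, 0.5, 1)^(1 / 3))
  }
  ori <- spec$orientations
  if (is.null(ori)) {
    ori <- matrix(stats::rnorm(R * 3), R, 3)
    # project out the radial component -> tangential orientations
    radial <- pos / sqrt(rowSums(pos^2))
    ori <- ori - radial * rowSums(ori * radial)
    ori <- ori / sqrt(rowSums(ori^2))
  }
  sens <- fibonacciSphere(spec$nSensors) * spec$sensorRadius
  lf <- sphericalLeadfield(pos, sens, sphereRadius = spec$sphereRadius)
  L <- scalarGain(lf, ori)   # sensors x sources
  n <- dim(sim$data@data)[3]
  out <- array(0, c(dim(sim$data@data)[1], spec$nSensors, n))
  for (tr in seq_len(dim(out)[1])) {
    S <- matrix(sim$data@data[tr, , ], nrow = R)
    out[tr, , ] <- L %*% S +
      matrix(stats::rnorm(spec$nSensors * n, sd = spec$sensorNoiseSd),
             spec$nSensors, n)
  }
  sensors <- trialArray(out, config@fs, t0 = 0, seriesKind = "sensor",
                        labels = lf@sensorLabels)
  list(sensors = sensors, leadfield = lf, orientations = ori,
       sources = sim$data, truth = sim$truth)
}

# near-uniform points on the unit sphere (golden-angle spiral)
fibonacciSphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}
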