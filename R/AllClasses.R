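#' @import methods
NULL

#' Frequency band specification
#'
#' A named frequency band with lower and upper edges in Hz. Bands are the
#' layers of the multi-layer connectivity model: connectivity is estimated
#' within each band and between every ordered pair of bands.
#'
#' @slot name band label, e.g. `"alpha"`.
#' @slot fLo lower band edge in Hz.
#' @slot fHi upper band edge in Hz.
#' @export
setClass("BandSpec",
  representation(name = "character", fLo = "numeric", fHi = "numeric"),
  validity = function(object) {
    if (length(object@name) != 1L || !nzchar(object@name))
      return("'name' must be a single non-empty string")
    if (length(object@fLo) != 1L || length(object@fHi) != 1L)
      return("band edges must be scalars")
    if (!is.finite(object@fLo) || !is.finite(object@fHi))
      return("band edges must be finite")
    if (object@fLo <= 0) return("'fLo' must be > 0")
    if (object@fHi <= object@fLo) return("'fHi' must exceed 'fLo'")
    TRUE
  })

#' @param name band label.
#' @param fLo,fHi band edges in Hz, `0 < fLo < fHi`.
#' @return A [BandSpec-class] object.
#' @rdname BandSpec-class
#' @examples
#' bandSpec("alpha", 8, 13)
#' @export
bandSpec <- function(name, fLo, fHi) {
  new("BandSpec", name = as.character(name), fLo = as.numeric(fLo),
      fHi = as.numeric(fHi))
}

#' Canonical analysis bands
#'
#' The four-band model used throughout: alpha (8--13 Hz), beta (13--30 Hz),
#' low gamma (30--50 Hz) and high gamma (50--100 Hz).
#'
#' @return A named list of [BandSpec-class] objects.
#' @examples
#' names(defaultBands())
#' @export
defaultBands <- function() {
  list(alpha     = bandSpec("alpha", 8, 13),
       beta      = bandSpec("beta", 13, 30),
       gammaLow  = bandSpec("gammaLow", 30, 50),
       gammaHigh = bandSpec("gammaHigh", 50, 100))
}

#' Magnetomyogram band
#'
#' The 120--150 Hz band used to capture muscle (magnetomyogram) activity;
#' assumed above neural frequencies of interest.
#'
#' @return A [BandSpec-class] object.
#' @export
mmgBand <- function() bandSpec("mmg", 120, 150)

#' Trial-relative analysis window
#'
#' A half-open time interval `[tStart, tEnd)` in trial-relative seconds.
#' Half-open windows make abutting windows disjoint.
#'
#' @slot name window label.
#' @slot tStart,tEnd window limits in seconds, `tStart < tEnd`.
#' @export
setClass("WindowSpec",
  representation(name = "character", tStart = "numeric", tEnd = "numeric"),
  validity = function(object) {
    if (length(object@name) != 1L || !nzchar(object@name))
      return("'name' must be a single non-empty string")
    if (!is.finite(object@tStart) || !is.finite(object@tEnd))
      return("window limits must be finite")
    if (object@tStart >= object@tEnd) return("'tStart' must precede 'tEnd'")
    TRUE
  })

#' @param name window label.
#' @param tStart,tEnd window limits in trial-relative seconds.
#' @return A [WindowSpec-class] object.
#' @rdname WindowSpec-class
#' @examples
#' windowSpec("active", 0, 4)
#' @export
windowSpec <- function(name, tStart, tEnd) {
  new("WindowSpec", name = as.character(name), tStart = as.numeric(tStart),
      tEnd = as.numeric(tEnd))
}

#' Canonical task windows
#'
#' Windows used in the visuomotor paradigm: an active window (0--4 s,
#' spanning stimulus and post-stimulus rebound), a control window
#' (4.5--8.5 s), a whole-trial window (0--8.5 s) for group comparisons,
#' and the stimulus (0--2 s) / rebound (2--4 s) windows used for
#' amplitude statistics.
#'
#' @return A named list of [WindowSpec-class] objects.
#' @export
defaultWindows <- function() {
  list(active   = windowSpec("active", 0, 4),
       control  = windowSpec("control", 4.5, 8.5),
       whole    = windowSpec("whole", 0, 8.5),
       stimulus = windowSpec("stimulus", 0, 2),
       rebound  = windowSpec("rebound", 2, 4))
}

#' Multi-trial time series container
#'
#' The pipeline's central object: a dense `trials x series x samples`
#' array of real-valued signals at a fixed sampling rate, where a series
#' is a sensor, a voxel or a regional timecourse. Sample `k` (0-based)
#' of every trial lies at `t0 + k/fs` seconds.
#'
#' @slot data numeric array, `trials x series x samples`.
#' @slot fs sampling rate in Hz.
#' @slot t0 trial-relative time of the first sample in seconds.
#' @slot seriesKind one of `"sensor"`, `"voxel"`, `"regional"`.
#' @slot labels one identifier per series.
#' @slot meta free-form metadata list (bands, windows, cohort table,
#'   leadfield, edge-sample bookkeeping).
#' @export
setClass("TrialArray",
  representation(data = "array", fs = "numeric", t0 = "numeric",
                 seriesKind = "character", labels = "character",
                 meta = "list"),
  prototype(t0 = 0, seriesKind = "regional", meta = list()),
  validity = function(object) {
    d <- dim(object@data)
    if (length(d) != 3L)
      return("'data' must be a trials x series x samples array")
    if (d[1] < 1L) return("need at least 1 trial")
    if (d[2] < 1L) return("need at least 1 series")
    if (d[3] < 2L) return("need at least 2 samples")
    if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
      return("'fs' must be a single positive number")
    if (length(object@t0) != 1L || !is.finite(object@t0))
      return("'t0' must be a single finite number")
    if (!object@seriesKind %in% c("sensor", "voxel", "regional"))
      return("'seriesKind' must be sensor, voxel or regional")
    if (length(object@labels) != d[2])
      return(sprintf("expected %d series labels, got %d", d[2],
                     length(object@labels)))
    if (anyDuplicated(object@labels))
      return("series labels must be unique")
    if (anyNA(object@data) || any(!is.finite(object@data)))
      return("'data' contains non-finite values")
    TRUE
  })

#' @param data numeric `trials x series x samples` array (a matrix is
#'   treated as one trial, `series x samples`).
#' @param fs sampling rate in Hz.
#' @param t0 time of the first sample, seconds.
#' @param seriesKind `"sensor"`, `"voxel"` or `"regional"`.
#' @param labels series identifiers; defaults to `kind1, kind2, ...`.
#' @param meta metadata list.
#' @return A [TrialArray-class] object.
#' @rdname TrialArray-class
#' @examples
#' x <- trialArray(array(rnorm(2 * 3 * 100), c(2, 3, 100)), fs = 100)
#' nTrials(x); nSeries(x); nSamples(x)
#' @export
trialArray <- function(data, fs, t0 = 0, seriesKind = "regional",
                       labels = NULL, meta = list()) {
  if (is.matrix(data)) data <- array(data, c(1L, nrow(data), ncol(data)))
  if (is.null(labels))
    labels <- paste0(seriesKind, seq_len(dim(data)[2]))
  new("TrialArray", data = data, fs = as.numeric(fs), t0 = as.numeric(t0),
      seriesKind = seriesKind, labels = as.character(labels), meta = meta)
}

#' Amplitude-envelope container
#'
#' A [TrialArray-class] holding non-negative Hilbert envelopes of a
#' band-limited signal, together with the band it came from.
#'
#' @slot band the [BandSpec-class] the envelopes were computed in.
#' @export
setClass("EnvelopeArray", contains = "TrialArray",
  representation(band = "BandSpec"),
  validity = function(object) {
    if (any(object@data < 0)) return("envelope values must be non-negative")
    TRUE
  })

#' Forward-model gain tensor
#'
#' Free-orientation leadfield: for every source, the sensor-space field
#' pattern of a unit dipole along each cartesian axis.
#'
#' @slot gain numeric `sensors x sources x 3` array.
#' @slot sourcePositions `sources x 3` matrix, mm.
#' @slot sensorPositions `sensors x 3` matrix, mm.
#' @slot sensorLabels one label per sensor.
#' @export
setClass("Leadfield",
  representation(gain = "array", sourcePositions = "matrix",
                 sensorPositions = "matrix", sensorLabels = "character"),
  validity = function(object) {
    d <- dim(object@gain)
    if (length(d) != 3L || d[3] != 3L)
      return("'gain' must be sensors x sources x 3")
    if (any(!is.finite(object@gain))) return("'gain' must be finite")
    if (nrow(object@sourcePositions) != d[2])
      return("one position row per source required")
    if (nrow(object@sensorPositions) != d[1])
      return("one position row per sensor required")
    if (length(object@sensorLabels) != d[1])
      return("one label per sensor required")
    nrm <- apply(object@gain, 2, function(g) sqrt(sum(g^2)))
    if (any(nrm == 0)) return("all-zero source column triplet in 'gain'")
    TRUE
  })

#' One adjacency tile of the multi-layer model
#'
#' A `regions x regions` matrix of mean trial-wise envelope correlations
#' for one band (within-band, symmetric) or one ordered band pair
#' (between-band, directed). Within-band diagonals are not interpreted
#' and are set to 0; between-band diagonals (same region, two bands) are
#' retained as valid measurements.
#'
#' @slot seedBand,testBand the [BandSpec-class] pair.
#' @slot matrix the correlation matrix.
#' @slot window the [WindowSpec-class] the tile was computed in.
#' @slot symmetric `TRUE` iff seed and test band coincide.
#' @export
setClass("Tile",
  representation(seedBand = "BandSpec", testBand = "BandSpec",
                 matrix = "matrix", window = "WindowSpec",
                 symmetric = "logical"),
  validity = function(object) {
    m <- object@matrix
    if (nrow(m) != ncol(m)) return("tile matrix must be square")
    if (any(!is.finite(m))) return("tile matrix must be finite")
    if (any(abs(m) > 1 + 1e-12)) return("tile entries must lie in [-1, 1]")
    if (object@symmetric) {
      if (object@seedBand@name != object@testBand@name)
        return("symmetric tiles require seedBand == testBand")
      if (max(abs(m - t(m))) > 1e-12)
        return("symmetric tile matrix is not symmetric")
      if (any(diag(m) != 0))
        return("within-band tile diagonal must be 0")
    } else if (object@seedBand@name == object@testBand@name) {
      return("within-band tiles must be symmetric")
    }
    TRUE
  })

#' Multi-layer super-adjacency matrix
#'
#' The `(B*R) x (B*R)` block matrix combining all within-band tiles
#' (block diagonal) and between-band tiles (off-diagonal blocks); block
#' `(a, b)` above the diagonal holds the `a -> b` tile and block
#' `(b, a)` its transpose. `kind` distinguishes correlation matrices
#' from derived matrices (differences, group effects) whose entries
#' need not lie in `[-1, 1]`.
#'
#' @slot bands ordered list of [BandSpec-class] objects.
#' @slot regions region labels.
#' @slot matrix the assembled block matrix.
#' @slot window the [WindowSpec-class] (shared by all tiles).
#' @slot kind `"correlation"`, `"difference"` or `"effect"`.
#' @export
setClass("SuperAdjacency",
  representation(bands = "list", regions = "character", matrix = "matrix",
                 window = "WindowSpec", kind = "character"),
  prototype(kind = "correlation"),
  validity = function(object) {
    B <- length(object@bands); R <- length(object@regions)
    if (B < 1L) return("need at least one band")
    if (!all(vapply(object@bands, is, TRUE, "BandSpec")))
      return("'bands' must be a list of BandSpec")
    if (nrow(object@matrix) != B * R || ncol(object@matrix) != B * R)
      return("matrix dimension must equal bands * regions")
    if (any(!is.finite(object@matrix))) return("matrix must be finite")
    if (!object@kind %in% c("correlation", "difference", "effect"))
      return("'kind' must be correlation, difference or effect")
    if (object@kind == "correlation" &&
        any(abs(object@matrix) > 1 + 1e-12))
      return("correlation entries must lie in [-1, 1]")
    TRUE
  })

#' Per-subject connectivity with cohort annotations
#'
#' A stack of per-subject [SuperAdjacency-class] matrices plus the cohort
#' table (group labels and, for patients, symptom-severity scores).
#'
#' @slot sms list of [SuperAdjacency-class], one per subject.
#' @slot table data frame with columns `subject_id`, `group`
#'   (`"control"`/`"patient"`) and `severity`.
#' @export
setClass("CohortConnectivity",
  representation(sms = "list", table = "data.frame"),
  validity = function(object) {
    tb <- object@table
    need <- c("subject_id", "group", "severity")
    if (!all(need %in% names(tb)))
      return("table needs columns subject_id, group, severity")
    if (length(object@sms) != nrow(tb))
      return("one SuperAdjacency per table row required")
    if (!all(vapply(object@sms, is, TRUE, "SuperAdjacency")))
      return("'sms' must contain SuperAdjacency objects")
    if (anyDuplicated(tb$subject_id)) return("subject_ids must be unique")
    if (!all(tb$group %in% c("control", "patient")))
      return("group must be 'control' or 'patient'")
    dims <- vapply(object@sms, function(s) nrow(s@matrix), 0)
    if (length(unique(dims)) > 1L)
      return("all subject matrices must share dimensions")
    TRUE
  })

#' @param sms list of [SuperAdjacency-class], one per subject.
#' @param table cohort data frame (`subject_id`, `group`, `severity`).
#' @return A [CohortConnectivity-class] object.
#' @rdname CohortConnectivity-class
#' @export
cohortConnectivity <- function(sms, table) {
  if (is.null(table$severity)) table$severity <- NA_real_
  new("CohortConnectivity", sms = sms, table = table)
}

#' Element-wise permutation test result
#'
#' @slot observed observed statistic matrix.
#' @slot p element-wise permutation p-values, in `(0, 1]` with floor
#'   `1/(nPerm + 1)`.
#' @slot mask logical matrix after multiple-comparison correction.
#' @slot nPerm number of permutations.
#' @slot seed RNG seed used.
#' @slot correction `"fdr_bh"`, `"bonferroni"` or `"none"`.
#' @slot q correction level.
#' @export
setClass("PermutationResult",
  representation(observed = "matrix", p = "matrix", mask = "matrix",
                 nPerm = "numeric", seed = "numeric",
                 correction = "character", q = "numeric"),
  validity = function(object) {
    if (!identical(dim(object@observed), dim(object@p)) ||
        !identical(dim(object@p), dim(object@mask)))
      return("observed, p and mask must share dimensions")
    pm <- object@p[is.finite(object@p)]
    if (any(pm <= 0 | pm > 1)) return("p-values must lie in (0, 1]")
    floorp <- 1 / (object@nPerm + 1)
    if (any(pm < floorp - 1e-12))
      return("p-values below the permutation floor 1/(nPerm + 1)")
    if (!object@correction %in% c("fdr_bh", "bonferroni", "none"))
      return("unknown correction")
    if (any(object@mask & !is.finite(object@observed)))
      return("mask selects non-finite observed entries")
    TRUE
  })

#' Tile-correlation permutation test result
#'
#' Per-tile Pearson correlation between the effect-of-diagnosis and
#' effect-of-severity matrices, with two-tailed permutation p-values from
#' a dual (label-exchange + severity-shuffle) null.
#'
#' @slot r named per-tile correlations.
#' @slot p named per-tile two-tailed permutation p-values.
#' @slot alphaCorrected Bonferroni-corrected significance threshold
#'   (`0.05/(2 * nTiles)` by default).
#' @slot trendThreshold uncorrected trend threshold.
#' @slot nPerm,seed permutation count and RNG seed.
#' @export
setClass("TileCorrelationResult",
  representation(r = "numeric", p = "numeric", alphaCorrected = "numeric",
                 trendThreshold = "numeric", nPerm = "numeric",
                 seed = "numeric"),
  validity = function(object) {
    if (length(object@r) != length(object@p))
      return("r and p must have equal length")
    if (any(abs(object@r[is.finite(object@r)]) > 1))
      return("tile correlations must lie in [-1, 1]")
    if (any(object@p <= 0 | object@p > 1))
      return("p-values must lie in (0, 1]")
    TRUE
  })

#' Planted structure emitted by the simulator
#'
#' Records everything a recovery test needs: the coupling targets
#' actually used per tile (in envelope-correlation and latent-copula
#' space), the modulation profile, the artifact envelopes, and the seed.
#'
#' @slot couplings list of region x region target matrices keyed
#'   `"band"` or `"seedBand:testBand"` (envelope-correlation space).
#' @slot latentCouplings same keys, latent Gaussian-copula space.
#' @slot modulation data frame of piecewise amplitude gains.
#' @slot artifact list describing injected artifact (may be empty).
#' @slot seed RNG seed.
#' @slot config the generating [SimulationConfig-class].
#' @export
setClass("GroundTruth",
  representation(couplings = "list", latentCouplings = "list",
                 modulation = "data.frame", artifact = "list",
                 seed = "numeric", config = "ANY"))

#' Simulation configuration
#'
#' Parameters of the synthetic narrowband generator. Per band, each
#' region receives an independent band-pass-filtered noise carrier whose
#' amplitude is modulated by a log-normal envelope; envelopes across all
#' (band, region) nodes share a Gaussian copula whose correlation matrix
#' implements the requested within-band and cross-band couplings.
#' Defaults reproduce the study conditions: 78 regions, 45 trials of
#' 9 s at 600 Hz, the four canonical bands, and task-locked modulation
#' (beta decrease then rebound, gamma increase, alpha decrease).
#'
#' @slot nRegions,nTrials,trialLength,fs basic geometry (s, Hz).
#' @slot bands named list of [BandSpec-class].
#' @slot withinCoupling named list (per band) of symmetric unit-diagonal
#'   region x region target envelope-correlation matrices.
#' @slot crossCoupling named list (per `"a:b"` ordered band pair) of
#'   region x region target matrices.
#' @slot modulation data frame with columns `band`, `region` (NA = all),
#'   `tStart`, `tEnd`, `gain`: piecewise amplitude gain over trial time.
#' @slot leakageMix optional invertible region x region instantaneous
#'   mixing matrix (`NULL` for none).
#' @slot mmg optional list(`regions`, `amplitude`) describing a shared
#'   bilateral 120--150 Hz artifact.
#' @slot noiseSd additive white-noise standard deviation.
#' @slot logEnvSd standard deviation of the log-envelope.
#' @slot envelopeCutoffHz low-pass cutoff of envelope fluctuations.
#' @slot couplingSpace `"envelope"` (targets are measured envelope
#'   correlations, mapped to copula space by Monte-Carlo calibration) or
#'   `"latent"` (targets used directly as copula correlations).
#' @slot seed RNG seed.
#' @export
setClass("SimulationConfig",
  representation(nRegions = "numeric", nTrials = "numeric",
                 trialLength = "numeric", fs = "numeric", bands = "list",
                 withinCoupling = "list", crossCoupling = "list",
                 modulation = "data.frame", leakageMix = "ANY",
                 mmg = "ANY", noiseSd = "numeric", logEnvSd = "numeric",
                 envelopeCutoffHz = "numeric", couplingSpace = "character",
                 seed = "numeric"),
  validity = function(object) {
    if (object@nRegions < 1) return("need at least one region")
    if (object@nTrials < 1) return("need at least one trial")
    if (object@trialLength <= 0) return("'trialLength' must be positive")
    if (object@fs <= 0) return("'fs' must be positive")
    for (b in object@bands)
      if (b@fHi >= object@fs / 2)
        return(sprintf("band '%s' exceeds the Nyquist frequency", b@name))
    R <- object@nRegions
    for (nm in names(object@withinCoupling)) {
      W <- object@withinCoupling[[nm]]
      if (!all(dim(W) == R)) return("within-coupling matrix of wrong size")
      if (any(abs(W) > 1)) return("coupling targets must lie in [-1, 1]")
      if (max(abs(W - t(W))) > 1e-12)
        return(sprintf("within-coupling '%s' is not symmetric", nm))
      if (any(abs(diag(W) - 1) > 1e-12))
        return(sprintf("within-coupling '%s' needs a unit diagonal", nm))
    }
    for (nm in names(object@crossCoupling)) {
      Cm <- object@crossCoupling[[nm]]
      if (!all(dim(Cm) == R)) return("cross-coupling matrix of wrong size")
      if (any(abs(Cm) > 1)) return("coupling targets must lie in [-1, 1]")
    }
    if (!is.null(object@leakageMix)) {
      M <- object@leakageMix
      if (!all(dim(M) == R)) return("leakage matrix of wrong size")
      if (abs(det(M)) < 1e-12) return("leakage matrix must be invertible")
    }
    if (object@noiseSd < 0) return("'noiseSd' must be non-negative")
    if (object@logEnvSd <= 0) return("'logEnvSd' must be positive")
    if (!object@couplingSpace %in% c("envelope", "latent"))
      return("'couplingSpace' must be 'envelope' or 'latent'")
    TRUE
  })
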