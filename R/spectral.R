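# Band-pass filtering, Hilbert envelopes, time-frequency spectrograms and
# task-induced amplitude statistics.

# Windowed-sinc FIR length: enough taps that the (two-pass) stopband
# reaches > 40 dB within a quarter of the lower band edge. For wide
# (e.g. broadband-covariance) bands the transition is allowed to scale
# with bandwidth instead, keeping the filter short relative to the data.
# Always odd.
firTaps <- function(fLo, fHi, fs, maxTaps = NULL) {
  delta <- max(0.25 * fLo, 0.05 * (fHi - fLo))
  n <- ceiling(2.5 * fs / delta)
  if (!is.null(maxTaps)) n <- min(n, maxTaps)
  n <- max(n, 31L)
  if (n %% 2L == 0L) n <- n + 1L
  as.integer(n)
}

firCoefficients <- function(band, fs, maxTaps = NULL) {
  checkBandUsable(band, fs)
  n <- firTaps(band@fLo, band@fHi, fs, maxTaps)
  signal::fir1(n - 1L, c(band@fLo, band@fHi) / (fs / 2), type = "pass")
}

# forward-backward (zero-phase) FIR filtering of one vector
zeroPhaseFilter <- function(b, x) {
  n <- length(b)
  # reflect-pad to suppress startup transients, as filtfilt implementations do
  pad <- min(n, length(x) - 1L)
  xp <- c(2 * x[1] - x[pad:1 + 1], x, 2 * x[length(x)] - x[length(x) - 1:pad])
  y <- stats::filter(xp, b, method = "convolution", sides = 2)
  y <- as.numeric(y)
  y <- y[pad + seq_along(x)]
  y
}

#' Zero-phase band-pass filter
#'
#' Filters every trial and series of a [TrialArray-class] into a frequency
#' band using a windowed-sinc FIR filter applied symmetrically (zero
#' phase), so that envelope timing is preserved. The filter length (in
#' samples) is recorded in `metadata(x)$filterLength`; the first and last
#' filter-length samples carry edge transients and are excluded from
#' window statistics by default downstream.
#'
#' @param x a [TrialArray-class].
#' @param band a [BandSpec-class]; must lie below the Nyquist frequency.
#' @param maxTaps optional cap on the filter length.
#' @return A band-limited [TrialArray-class].
#' @examples
#' x <- trialArray(array(rnorm(600), c(1, 1, 600)), fs = 200)
#' y <- bandpass(x, bandSpec("alpha", 8, 13))
#' @export
bandpass <- function(x, band, maxTaps = NULL) {
  stopifnot(is(x, "TrialArray"), is(band, "BandSpec"))
  ns <- dim(x@data)[3]
  b <- firCoefficients(band, x@fs, maxTaps)
  n <- length(b)
  if (ns <= n)
    stop(sprintf(
      "band '%s' too narrow for trial length: %d samples available, need > %d (>= %.2f s at %g Hz)",
      band@name, ns, n, (n + 1) / x@fs, x@fs))
  if (ns < 3L * n)
    warning(sprintf(
      "trial length (%d samples) is below 3 filter lengths (%d) for band '%s'; edge effects may dominate",
      ns, 3L * n, band@name))
  out <- x@data
  for (tr in seq_len(dim(out)[1]))
    for (s in seq_len(dim(out)[2]))
      out[tr, s, ] <- zeroPhaseFilter(b, x@data[tr, s, ])
  meta <- x@meta
  meta$filterLength <- n
  meta$band <- band
  new("TrialArray", data = out, fs = x@fs, t0 = x@t0,
      seriesKind = x@seriesKind, labels = x@labels, meta = meta)
}

# analytic signal of each column of a matrix (FFT method)
analyticSignal <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X)
  F <- stats::mvfft(X)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::mvfft(F * h, inverse = TRUE) / n
}

# magnitude of the analytic signal, column-wise
envelopeOf <- function(X) Mod(analyticSignal(X))

#' Hilbert amplitude envelope
#'
#' Computes, per trial and series, the magnitude of the analytic signal
#' of a band-limited timecourse: the amplitude (Hilbert) envelope, which
#' tracks slow fluctuations of oscillatory power. The envelope of `-x`
#' equals the envelope of `x`.
#'
#' @param x a band-limited [TrialArray-class] (typically from
#'   [bandpass()]).
#' @param band optional [BandSpec-class] recorded in the result; defaults
#'   to the band noted by [bandpass()].
#' @return An [EnvelopeArray-class] with the same shape as `x`.
#' @examples
#' fs <- 200; t <- seq(0, 2, by = 1 / fs)[-1]
#' x <- trialArray(array(sin(2 * pi * 10 * t), c(1, 1, length(t))), fs)
#' env <- hilbertEnvelope(x)
#' @export
hilbertEnvelope <- function(x, band = NULL) {
  stopifnot(is(x, "TrialArray"))
  if (is.null(band)) band <- x@meta$band
  if (is.null(band)) band <- bandSpec("broadband", 1e-6, x@fs / 2 * 0.999)
  out <- x@data
  for (tr in seq_len(dim(out)[1])) {
    m <- matrix(x@data[tr, , ], nrow = dim(out)[2])  # series x samples
    out[tr, , ] <- t(envelopeOf(t(m)))
  }
  new("EnvelopeArray", data = out, fs = x@fs, t0 = x@t0,
      seriesKind = x@seriesKind, labels = x@labels, meta = x@meta,
      band = band)
}

#' Log-spaced overlapping spectrogram bands
#'
#' `nBands` bands spanning `fRange`, with log-spaced edges and 50%
#' overlap between neighbours: with `nBands + 2` log-spaced edge points
#' `e`, band `k` spans `(e[k], e[k + 2])`.
#'
#' @param nBands number of bands.
#' @param fRange two-element frequency range in Hz.
#' @return A list of [BandSpec-class] objects, ordered low to high.
#' @export
tfsBands <- function(nBands = 33, fRange = c(1, 150)) {
  e <- exp(seq(log(fRange[1]), log(fRange[2]), length.out = nBands + 2))
  lapply(seq_len(nBands), function(k)
    bandSpec(sprintf("tfs%02d", k), e[k], e[k + 2]))
}

#' Time-frequency spectrogram of one region
#'
#' Per band: filter, envelope, average over trials; rows are stacked low
#' to high frequency. Optionally expressed as fractional change against
#' the mean of a baseline window.
#'
#' @param x a [TrialArray-class].
#' @param region series index or label.
#' @param nBands,fRange spectrogram bands, see [tfsBands()].
#' @param baseline optional [WindowSpec-class]; when given, each row
#'   becomes `(env - mean(baseline)) / mean(baseline)`.
#' @return A list with elements `spectrogram` (`nBands x samples`
#'   matrix), `bands`, `centres` (geometric band centres, Hz), `time`
#'   (trial-relative seconds) and `baseline`.
#' @export
tfs <- function(x, region = 1L, nBands = 33, fRange = c(1, 150),
                baseline = NULL) {
  stopifnot(is(x, "TrialArray"))
  if (fRange[2] >= x@fs / 2)
    stop(sprintf("frequency range exceeds the Nyquist frequency (%g Hz)",
                 x@fs / 2))
  if (is.character(region)) region <- match(region, x@labels)
  stopifnot(is.finite(region), region >= 1, region <= dim(x@data)[2])
  bands <- tfsBands(nBands, fRange)
  ns <- dim(x@data)[3]
  maxTaps <- ns - 2L
  one <- trialArray(x@data[, region, , drop = FALSE], x@fs, x@t0,
                    x@seriesKind, x@labels[region])
  S <- matrix(NA_real_, nBands, ns)
  for (k in seq_along(bands)) {
    env <- hilbertEnvelope(bandpass(one, bands[[k]], maxTaps = maxTaps))
    S[k, ] <- colMeans(matrix(env@data, nrow = dim(env@data)[1]))
  }
  if (!is.null(baseline)) {
    idx <- windowIndices(x, baseline)
    b <- rowMeans(S[, idx, drop = FALSE])
    S <- (S - b) / b
  }
  list(spectrogram = S, bands = bands,
       centres = vapply(bands, function(b) sqrt(b@fLo * b@fHi), 0),
       time = x@t0 + (seq_len(ns) - 1) / x@fs, baseline = baseline)
}

# valid (edge-trimmed) sample indices given recorded filter length
validSampleIndices <- function(x, trimEdges = TRUE) {
  ns <- dim(x@data)[3]
  n <- x@meta$filterLength
  if (!trimEdges || is.null(n) || 2L * n >= ns) return(seq_len(ns))
  (n + 1L):(ns - n)
}

#' Fractional amplitude change between two windows
#'
#' On the trial-averaged envelope of each region,
#' `(mean(winA) - mean(winB)) / mean(winB)`. Used to contrast a stimulus
#' window against a rebound window (e.g. movement-related beta decrease
#' versus post-movement rebound). Edge samples flagged by the filter are
#' excluded by default.
#'
#' @param env an [EnvelopeArray-class].
#' @param winA,winB [WindowSpec-class] windows inside the trial.
#' @param trimEdges drop filter-length edge samples from the windows.
#' @return Named numeric vector, one fractional change per region.
#' @export
fractionalChange <- function(env, winA, winB, trimEdges = TRUE) {
  stopifnot(is(env, "EnvelopeArray"))
  valid <- validSampleIndices(env, trimEdges)
  ia <- intersect(windowIndices(env, winA), valid)
  ib <- intersect(windowIndices(env, winB), valid)
  if (length(ia) == 0L || length(ib) == 0L)
    stop("window contains no valid samples after edge trimming")
  avg <- apply(env@data, c(2, 3), mean)  # regions x samples
  a <- rowMeans(avg[, ia, drop = FALSE])
  b <- rowMeans(avg[, ib, drop = FALSE])
  if (any(b == 0)) stop("zero denominator in fractional change")
  out <- (a - b) / b
  names(out) <- env@labels
  out
}

#' Signed-rank test of task-induced amplitude change
#'
#' Per region, a two-sided Wilcoxon signed-rank test of the null that
#' subjects' fractional amplitude changes have median zero, Bonferroni
#' corrected across the regions actually analysed. Zero differences are
#' dropped (zero-exclusion convention) and their count recorded.
#'
#' @param changes `subjects x regions` matrix of fractional changes.
#' @param alpha family-wise significance level before correction.
#' @return A data frame with columns `region`, `p`, `significant` and
#'   `nZero`, plus attribute `bonferroniDivisor`.
#' @export
amplitudeChangeTest <- function(changes, alpha = 0.05) {
  changes <- as.matrix(changes)
  if (nrow(changes) < 6L)
    stop("need at least 6 subjects for the signed-rank test")
  R <- ncol(changes)
  labs <- colnames(changes)
  if (is.null(labs)) labs <- paste0("region", seq_len(R))
  p <- numeric(R); nz <- integer(R)
  for (r in seq_len(R)) {
    v <- changes[, r]
    nz[r] <- sum(v == 0)
    v <- v[v != 0]
    p[r] <- if (length(v) == 0L) 1 else
      suppressWarnings(stats::wilcox.test(v, mu = 0,
                                          alternative = "two.sided")$p.value)
  }
  out <- data.frame(region = labs, p = p, significant = p < alpha / R,
                    nZero = nz, stringsAsFactors = FALSE)
  attr(out, "bonferroniDivisor") <- R
  out
}
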