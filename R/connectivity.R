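# Leakage orthogonalization, artifact regression, trial-wise envelope
# correlation, tile computation and super-adjacency assembly.

#' Pairwise leakage orthogonalization
#'
#' Signal leakage between reconstructed sources manifests as zero-lag
#' correlation. The linear zero-lag component of the seed is removed
#' from the test signal by regression: `residual = test - beta * seed`
#' with the least-squares slope `beta`, leaving the residual uncorrelated
#' with the seed. Must be applied per window and per trial, since
#' task-induced variance changes modulate leakage magnitude.
#'
#' @param seed,test numeric vectors of equal length (>= 10 samples).
#' @return The residual; a zero-variance seed returns `test` unmodified
#'   with attribute `flagged = TRUE`.
#' @examples
#' s <- rnorm(100); t <- 0.5 * s + rnorm(100)
#' r <- pairwiseOrthogonalize(s, t)
#' abs(cor(s, r)) < 1e-10
#' @export
pairwiseOrthogonalize <- function(seed, test) {
  if (length(seed) != length(test)) stop("series lengths differ")
  if (length(seed) < 10L) stop("need at least 10 samples")
  vs <- stats::var(seed)
  if (vs == 0) {
    attr(test, "flagged") <- TRUE
    return(test)
  }
  beta <- stats::cov(seed, test) / vs
  test - beta * seed
}

#' Regress a muscle-artifact envelope out of an envelope
#'
#' Least-squares residual of an oscillatory envelope on an intercept and
#' the 120--150 Hz magnetomyogram envelope of the same window and trial.
#' The residual is uncorrelated with the artifact envelope, protecting
#' gamma-band connectivity from bilateral muscle bursts.
#'
#' @param env,mmgEnv numeric vectors of equal length.
#' @return The residual (demeaned); a constant `mmgEnv` returns the
#'   demeaned `env` with attribute `flagged = TRUE`.
#' @export
mmgRegress <- function(env, mmgEnv) {
  if (length(env) != length(mmgEnv)) stop("series lengths differ")
  if (stats::var(mmgEnv) == 0) {
    out <- env - mean(env)
    attr(out, "flagged") <- TRUE
    return(out)
  }
  beta <- stats::cov(mmgEnv, env) / stats::var(mmgEnv)
  env - mean(env) - beta * (mmgEnv - mean(mmgEnv))
}

#' Mean trial-wise envelope correlation
#'
#' Pearson correlation between two windowed envelopes, computed within
#' each trial separately and averaged arithmetically over trials (no
#' Fisher transform). Trials in which either envelope has zero variance
#' are dropped; the count is reported in attribute `droppedTrials`.
#'
#' @param seedEnv,testEnv `trials x samples` matrices of windowed
#'   envelopes.
#' @return Mean correlation in `[-1, 1]`.
#' @export
envelopeCorrelationTrialwise <- function(seedEnv, testEnv) {
  seedEnv <- as.matrix(seedEnv); testEnv <- as.matrix(testEnv)
  if (!all(dim(seedEnv) == dim(testEnv))) stop("envelope shapes differ")
  if (nrow(seedEnv) < 2L) stop("need at least 2 trials")
  if (ncol(seedEnv) < 10L) stop("need at least 10 samples per window")
  rs <- vapply(seq_len(nrow(seedEnv)), function(tr) {
    a <- seedEnv[tr, ]; b <- testEnv[tr, ]
    if (stats::var(a) == 0 || stats::var(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }, 0)
  dropped <- sum(is.na(rs))
  if (dropped == nrow(seedEnv)) stop("all trials had zero variance")
  out <- mean(rs, na.rm = TRUE)
  attr(out, "droppedTrials") <- dropped
  out
}

#' Correlation of trial-averaged envelopes
#'
#' Averages the envelopes over trials first, then computes a single
#' Pearson correlation on the averaged traces. This suppresses any
#' fluctuation not time-locked to the stimulus, so it reflects the
#' coordination of the task-locked response only, in contrast to the
#' trial-wise estimator.
#'
#' @param seedEnv,testEnv `trials x samples` matrices.
#' @return Pearson correlation of the two trial-averaged envelopes.
#' @export
trialAveragedCorrelation <- function(seedEnv, testEnv) {
  seedEnv <- as.matrix(seedEnv); testEnv <- as.matrix(testEnv)
  if (!all(dim(seedEnv) == dim(testEnv))) stop("envelope shapes differ")
  if (nrow(seedEnv) < 2L) stop("need at least 2 trials")
  a <- colMeans(seedEnv); b <- colMeans(testEnv)
  if (stats::var(a) == 0 || stats::var(b) == 0)
    stop("trial-averaged envelope has zero variance")
  stats::cor(a, b)
}

# windowed band-limited signals: list over trials of samples x regions
windowedBandSignals <- function(x, band, window) {
  xf <- bandpass(x, band, maxTaps = dim(x@data)[3] - 2L)
  idx <- windowIndices(xf, window)
  R <- dim(xf@data)[2]
  lapply(seq_len(dim(xf@data)[1]), function(tr)
    t(matrix(xf@data[tr, , idx], nrow = R)))
}

#' Compute one adjacency tile
#'
#' For every ordered region pair (seed, test): filter both regions into
#' their bands, extract the analysis window per trial, regress the seed
#' signal out of the test signal (zero-lag leakage correction, at the
#' band-limited signal level), compute Hilbert envelopes, optionally
#' regress out each region's 120--150 Hz magnetomyogram envelope, and
#' average the per-trial envelope Pearson correlation. Within-band tiles
#' are symmetrized by averaging the two directed estimates and their
#' diagonal set to 0; between-band tiles stay directed and keep their
#' diagonal (same region, two bands).
#'
#' @param x regional [TrialArray-class].
#' @param seedBand,testBand [BandSpec-class] objects.
#' @param window a [WindowSpec-class].
#' @param mmg regress out the magnetomyogram envelope (requires
#'   `fs > 300 Hz`).
#' @param orthogonalize apply leakage orthogonalization; the cross-band
#'   variant (seed band regressed from test band) mainly guards
#'   overlapping transition bands and can be disabled.
#' @return A [Tile-class].
#' @export
computeTile <- function(x, seedBand, testBand, window, mmg = FALSE,
                        orthogonalize = TRUE) {
  stopifnot(is(x, "TrialArray"), is(seedBand, "BandSpec"),
            is(testBand, "BandSpec"), is(window, "WindowSpec"))
  within <- seedBand@name == testBand@name
  R <- dim(x@data)[2]
  nTr <- dim(x@data)[1]
  Swin <- windowedBandSignals(x, seedBand, window)
  Twin <- if (within) Swin else windowedBandSignals(x, testBand, window)
  Menv <- NULL
  if (mmg) {
    mwin <- windowedBandSignals(x, mmgBand(), window)
    Menv <- lapply(mwin, envelopeOf)
  }
  # per trial, per seed region: envelopes of seed and of all orthogonalized
  # test residuals; accumulate the directed correlation matrix
  acc <- matrix(0, R, R)
  cnt <- matrix(0, R, R)
  for (tr in seq_len(nTr)) {
    S <- Swin[[tr]]; T <- Twin[[tr]]
    envS <- envelopeOf(S)
    if (mmg)
      for (r in seq_len(R)) envS[, r] <- mmgRegress(envS[, r],
                                                    Menv[[tr]][, r])
    for (s in seq_len(R)) {
      if (orthogonalize) {
        vs <- stats::var(S[, s])
        beta <- if (vs == 0) rep(0, R) else
          as.numeric(stats::cov(S[, s], T)) / vs
        Res <- T - outer(S[, s], beta)
      } else Res <- T
      envT <- envelopeOf(Res)
      if (mmg)
        for (r in seq_len(R)) envT[, r] <- mmgRegress(envT[, r],
                                                      Menv[[tr]][, r])
      es <- envS[, s]
      vS <- stats::var(es)
      vT <- apply(envT, 2, stats::var)
      ok <- vS > 0 & vT > 0
      if (any(ok)) {
        r_ <- as.numeric(stats::cor(es, envT[, ok, drop = FALSE]))
        acc[s, ok] <- acc[s, ok] + r_
        cnt[s, ok] <- cnt[s, ok] + 1
      }
    }
  }
  m <- acc / pmax(cnt, 1)
  m[cnt == 0] <- 0
  if (within) {
    m <- (m + t(m)) / 2
    diag(m) <- 0
  }
  m[m > 1] <- 1; m[m < -1] <- -1
  dimnames(m) <- list(x@labels, x@labels)
  new("Tile", seedBand = seedBand, testBand = testBand, matrix = m,
      window = window, symmetric = within)
}

#' Compute all tiles and assemble the super-adjacency matrix
#'
#' Convenience wrapper running [computeTile()] for every within-band and
#' ordered between-band pair, then [assembleSM()].
#'
#' @param x regional [TrialArray-class].
#' @param bands list of [BandSpec-class] (order defines the block order).
#' @param window a [WindowSpec-class].
#' @param ... passed to [computeTile()].
#' @return A [SuperAdjacency-class].
#' @export
computeSuperAdjacency <- function(x, bands, window, ...) {
  B <- length(bands)
  tiles <- list()
  for (i in seq_len(B))
    tiles[[length(tiles) + 1L]] <-
      computeTile(x, bands[[i]], bands[[i]], window, ...)
  for (i in seq_len(B)) for (j in seq_len(B)) {
    if (i >= j) next
    tiles[[length(tiles) + 1L]] <-
      computeTile(x, bands[[i]], bands[[j]], window, ...)
  }
  assembleSM(tiles, bands)
}

#' Assemble tiles into a super-adjacency matrix
#'
#' Expects exactly `B` within-band tiles and `B(B-1)/2` between-band
#' tiles over consistent regions. Within-band tiles form the block
#' diagonal; for an ordered pair `(a, b)` with `a` before `b` in the
#' band order, the block above the diagonal holds the `a -> b` tile and
#' the block below holds its transpose.
#'
#' @param tiles list of [Tile-class].
#' @param bands ordered list of [BandSpec-class].
#' @return A [SuperAdjacency-class].
#' @export
assembleSM <- function(tiles, bands) {
  B <- length(bands)
  bn <- vapply(bands, function(b) b@name, "")
  keyOf <- function(t) paste(t@seedBand@name, t@testBand@name, sep = ":")
  keys <- vapply(tiles, keyOf, "")
  if (anyDuplicated(keys))
    stop("duplicate tile for band pair ", keys[duplicated(keys)][1])
  need <- c(paste(bn, bn, sep = ":"),
            unlist(lapply(seq_len(B), function(i)
              if (i < B) paste(bn[i], bn[(i + 1):B], sep = ":"))))
  miss <- setdiff(need, keys)
  if (length(miss))
    stop("missing tile for band pair ", miss[1])
  extra <- setdiff(keys, need)
  if (length(extra))
    stop("unexpected tile for band pair ", extra[1])
  R <- nrow(tiles[[1]]@matrix)
  regions <- rownames(tiles[[1]]@matrix)
  if (is.null(regions)) regions <- paste0("region", seq_len(R))
  if (any(vapply(tiles, function(t) nrow(t@matrix), 0) != R))
    stop("tiles have inconsistent region counts")
  M <- matrix(0, B * R, B * R)
  for (t in tiles) {
    a <- match(t@seedBand@name, bn); b <- match(t@testBand@name, bn)
    ia <- (a - 1) * R + seq_len(R); ib <- (b - 1) * R + seq_len(R)
    M[ia, ib] <- t@matrix
    if (a != b) M[ib, ia] <- t(t@matrix)
  }
  new("SuperAdjacency", bands = bands, regions = regions, matrix = M,
      window = tiles[[1]]@window, kind = "correlation")
}

#' Disassemble a super-adjacency matrix into its distinct tiles
#'
#' @param sm a [SuperAdjacency-class].
#' @return A list of `B + B(B-1)/2` [Tile-class] objects (within-band
#'   tiles first, then ordered between-band tiles).
#' @export
disassembleSM <- function(sm) {
  stopifnot(is(sm, "SuperAdjacency"))
  bn <- bandNames(sm)
  B <- length(bn)
  tiles <- lapply(seq_len(B), function(i) getTile(sm, bn[i], bn[i]))
  for (i in seq_len(B)) for (j in seq_len(B)) {
    if (i >= j) next
    tiles[[length(tiles) + 1L]] <- getTile(sm, bn[i], bn[j])
  }
  tiles
}
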