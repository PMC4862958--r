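# Scalar LCMV beamforming: data covariance, Tikhonov regularization,
# closed-form orientation optimization, unit-gain projection, Gaussian
# regional aggregation and sign alignment.

#' Analytic dipole-in-sphere leadfield (radial sensors)
#'
#' Free-orientation forward fields for dipoles inside a homogeneous
#' conducting sphere, measured by radially oriented magnetometers. For a
#' sphere, volume currents contribute nothing to the radial field
#' component, which is therefore the free-space dipole expression
#' `B_r = ((q x p) . u) / |s - p|^3` (unit system arbitrary); radial
#' dipole components are magnetically silent, so only tangential source
#' components are visible.
#'
#' @param sourcePositions `sources x 3` matrix, mm, inside the sphere.
#' @param sensorPositions `sensors x 3` matrix, mm, outside the sphere.
#' @param sphereRadius conductor radius, mm.
#' @return A [Leadfield-class].
#' @export
sphericalLeadfield <- function(sourcePositions, sensorPositions,
                               sphereRadius = 100) {
  sourcePositions <- as.matrix(sourcePositions)
  sensorPositions <- as.matrix(sensorPositions)
  if (any(sqrt(rowSums(sourcePositions^2)) >= sphereRadius))
    stop("source position outside the conducting sphere")
  nSens <- nrow(sensorPositions); nSrc <- nrow(sourcePositions)
  gain <- array(0, c(nSens, nSrc, 3))
  u <- sensorPositions / sqrt(rowSums(sensorPositions^2))
  ax <- diag(3)
  for (j in seq_len(nSrc)) {
    p <- sourcePositions[j, ]
    d <- sweep(sensorPositions, 2, p)
    r3 <- rowSums(d^2)^1.5
    for (a in 1:3) {
      q <- ax[a, ]
      m <- c(q[2] * p[3] - q[3] * p[2],
             q[3] * p[1] - q[1] * p[3],
             q[1] * p[2] - q[2] * p[1])   # q x p
      gain[, j, a] <- (u %*% m) / r3
    }
  }
  # field units are arbitrary: scale so a typical source has unit gain norm
  nrm <- apply(gain, 2, function(g) sqrt(sum(g^2)))
  gain <- gain / stats::median(nrm)
  new("Leadfield", gain = gain, sourcePositions = sourcePositions,
      sensorPositions = sensorPositions,
      sensorLabels = paste0("sensor", seq_len(nSens)))
}

#' Collapse a free-orientation leadfield onto fixed orientations
#'
#' @param leadfield a [Leadfield-class].
#' @param orientations `sources x 3` matrix of unit orientation vectors.
#' @return `sensors x sources` scalar gain matrix.
#' @export
scalarGain <- function(leadfield, orientations) {
  stopifnot(is(leadfield, "Leadfield"))
  orientations <- as.matrix(orientations)
  d <- dim(leadfield@gain)
  if (nrow(orientations) != d[2] || ncol(orientations) != 3)
    stop("need one 3-vector orientation per source")
  L <- matrix(0, d[1], d[2])
  for (j in seq_len(d[2]))
    L[, j] <- leadfield@gain[, j, ] %*% orientations[j, ]
  L
}

#' Sensor data covariance
#'
#' Covariance over sensors of band-passed, window-concatenated,
#' per-channel-demeaned trial data. The broadband default (1--150 Hz
#' over the whole trial extent) follows the convention of computing
#' covariance on as much data as possible to minimize matrix error.
#'
#' @param x a sensor [TrialArray-class].
#' @param band covariance band, default 1--150 Hz.
#' @param window optional [WindowSpec-class]; default: whole trials.
#' @return Symmetric positive semi-definite `sensors x sensors` matrix.
#' @export
dataCovariance <- function(x, band = bandSpec("broad", 1, 150),
                           window = NULL) {
  stopifnot(is(x, "TrialArray"))
  checkBandUsable(band, x@fs)
  xf <- bandpass(x, band, maxTaps = dim(x@data)[3] - 2L)
  idx <- if (is.null(window)) seq_len(dim(xf@data)[3]) else
    windowIndices(xf, window)
  nSens <- dim(xf@data)[2]
  segs <- lapply(seq_len(dim(xf@data)[1]), function(tr)
    t(matrix(xf@data[tr, , idx], nrow = nSens)))
  X <- do.call(rbind, segs)
  if (nrow(X) < 2L * nSens)
    warning(sprintf(
      "covariance window provides %d samples for %d sensors; estimate may be unstable",
      nrow(X), nSens))
  C <- stats::cov(X)
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < max(ev) * .Machine$double.eps * nSens)
    attr(C, "rankDeficient") <- TRUE
  C
}

#' Tikhonov regularization of a covariance matrix
#'
#' `C_reg = C + fraction * lambda_max(C) * I`, shifting every eigenvalue
#' up by the stated fraction of the largest one. The conventional
#' fraction is 5%.
#'
#' @param C symmetric positive semi-definite matrix.
#' @param fraction non-negative regularization fraction.
#' @return The regularized matrix.
#' @examples
#' tikhonovRegularize(diag(3), 0.05)
#' @export
tikhonovRegularize <- function(C, fraction = 0.05) {
  if (fraction < 0) stop("'fraction' must be non-negative")
  C <- as.matrix(C)
  if (fraction == 0) return(C)
  lmax <- max(eigen((C + t(C)) / 2, symmetric = TRUE,
                    only.values = TRUE)$values)
  C + fraction * lmax * diag(nrow(C))
}

#' Optimal scalar-beamformer dipole orientation
#'
#' Returns the unit orientation maximizing the beamformer output SNR
#' ratio `(t(eta) L' Cinv L eta) / (t(eta) L' Cinv^2 L eta)`, solved in
#' closed form as a generalized eigenproblem (equivalent to a non-linear
#' search over orientations). The sign is fixed so the largest-magnitude
#' component is positive.
#'
#' @param L3 `sensors x 3` free-orientation gains of one source.
#' @param Creg regularized covariance matrix.
#' @return Unit 3-vector. A degenerate pencil falls back to the dominant
#'   right singular vector of `L3` with attribute `fallback = TRUE`.
#' @export
scalarOrientation <- function(L3, Creg) {
  L3 <- as.matrix(L3)
  stopifnot(ncol(L3) == 3)
  Ci <- solve(Creg)
  A <- crossprod(L3, Ci %*% L3)
  Bm <- crossprod(L3, Ci %*% (Ci %*% L3))
  A <- (A + t(A)) / 2; Bm <- (Bm + t(Bm)) / 2
  # solve the pencil on B's non-null subspace (a magnetically silent
  # orientation, e.g. the radial direction in a sphere, makes B singular)
  eb <- eigen(Bm, symmetric = TRUE)
  keep <- eb$values > 1e-10 * max(eb$values)
  eta <- if (!any(keep)) {
    v <- svd(L3)$v[, 1]
    attr(v, "fallback") <- TRUE
    v
  } else {
    W <- eb$vectors[, keep, drop = FALSE] %*%
      diag(1 / sqrt(eb$values[keep]), sum(keep))
    M <- crossprod(W, A %*% W)
    ei <- eigen((M + t(M)) / 2, symmetric = TRUE)
    k <- sum(keep)
    if (k > 1L &&
        (ei$values[1] - ei$values[k]) <= 1e-9 * abs(ei$values[1])) {
      # degenerate pencil: every orientation ties (e.g. C proportional
      # to I); fall back to the dominant singular vector of the gains
      v <- svd(L3)$v[, 1]
      attr(v, "fallback") <- TRUE
      v
    } else as.vector(W %*% ei$vectors[, 1])
  }
  fb <- attr(eta, "fallback")
  eta <- eta / sqrt(sum(eta^2))
  k <- which.max(abs(eta))
  if (eta[k] < 0) eta <- -eta
  if (isTRUE(fb)) attr(eta, "fallback") <- TRUE
  eta
}

# brute-force oracle over a unit-vector grid (testing aid)
#' @rdname scalarOrientation
#' @param nGrid number of random unit vectors searched.
#' @param seed RNG seed for the grid.
#' @export
scalarOrientationGrid <- function(L3, Creg, nGrid = 10000, seed = 1L) {
  Ci <- solve(Creg)
  A <- crossprod(L3, Ci %*% L3)
  Bm <- crossprod(L3, Ci %*% (Ci %*% L3))
  G <- withLocalSeed(seed, {
    G <- matrix(stats::rnorm(nGrid * 3), nGrid, 3)
    G / sqrt(rowSums(G^2))
  })
  snr <- rowSums((G %*% A) * G) / rowSums((G %*% Bm) * G)
  eta <- G[which.max(snr), ]
  k <- which.max(abs(eta))
  if (eta[k] < 0) eta <- -eta
  eta
}

#' Unit-gain LCMV projection
#'
#' For each source with scalar leadfield column `l`, forms the spatial
#' filter `w = Cinv l / (l' Cinv l)`, which satisfies the unit-gain
#' property `w' l = 1`, and projects the sensor data to source
#' timecourses.
#'
#' @param L `sensors x sources` scalar gain matrix (or a single column).
#' @param Creg regularized covariance matrix.
#' @param x sensor [TrialArray-class].
#' @return A voxel [TrialArray-class] (one series per source), with the
#'   filter matrix in `metadata()$weights`.
#' @export
lcmvProject <- function(L, Creg, x) {
  stopifnot(is(x, "TrialArray"))
  L <- as.matrix(L)
  if (nrow(L) != dim(x@data)[2])
    stop("leadfield rows must match sensor count")
  Ci <- tryCatch(solve(Creg), error = function(e)
    stop("covariance matrix is singular; apply tikhonovRegularize() first"))
  CiL <- Ci %*% L
  W <- sweep(CiL, 2, colSums(L * CiL), "/")   # sensors x sources
  nSrc <- ncol(L)
  out <- array(0, c(dim(x@data)[1], nSrc, dim(x@data)[3]))
  for (tr in seq_len(dim(out)[1])) {
    S <- matrix(x@data[tr, , ], nrow = dim(x@data)[2])
    out[tr, , ] <- crossprod(W, S)
  }
  trialArray(out, x@fs, x@t0, seriesKind = "voxel",
             labels = paste0("voxel", seq_len(nSrc)),
             meta = list(weights = W))
}

#' Gaussian distance weighting of voxel timecourses
#'
#' The weight applied to a voxel at distance `r` (mm) from the regional
#' centre of mass: `exp(-r^2 / 400)`, biasing the regional timecourse
#' towards the centre of the region. The half-maximum radius is
#' `sqrt(400 log 2) ~ 16.65 mm`.
#'
#' @param r distance(s) from the centre of mass, mm.
#' @return Weight(s) in `(0, 1]`.
#' @examples
#' regionWeight(20)  # exp(-1)
#' @export
regionWeight <- function(r) {
  if (any(r < 0)) stop("distances must be non-negative")
  exp(-r^2 / 400)
}

#' Aggregate voxel timecourses into a regional timecourse
#'
#' Weighted sum of voxel signals, each weighted by [regionWeight()] of
#' its distance to the regional centre of mass. Weights are not
#' renormalized (the downstream envelope correlation is scale
#' invariant); `normalize = TRUE` rescales them to sum to one.
#'
#' @param x voxel [TrialArray-class].
#' @param distances one distance (mm) per voxel.
#' @param normalize rescale weights to sum to one.
#' @return A regional [TrialArray-class] with a single series.
#' @export
regionalAggregate <- function(x, distances, normalize = FALSE) {
  stopifnot(is(x, "TrialArray"))
  if (length(distances) != dim(x@data)[2])
    stop("need one distance per voxel")
  w <- regionWeight(distances)
  if (normalize) w <- w / sum(w)
  out <- array(0, c(dim(x@data)[1], 1L, dim(x@data)[3]))
  for (tr in seq_len(dim(out)[1])) {
    S <- matrix(x@data[tr, , ], nrow = dim(x@data)[2])
    out[tr, 1L, ] <- crossprod(S, w)
  }
  trialArray(out, x@fs, x@t0, seriesKind = "regional",
             labels = "region")
}

#' Align arbitrary beamformer signs across regions
#'
#' Source orientation estimation leaves each reconstructed timecourse
#' with an arbitrary polarity. Each region's sign is chosen so that its
#' correlation with the first principal component of the regional set
#' (trials concatenated) is non-negative; deterministic given the data,
#' and idempotent. Zero-variance regions are left unflipped with a
#' warning.
#'
#' @param x regional [TrialArray-class].
#' @return A [TrialArray-class] with aligned signs; the flips applied
#'   are recorded in `metadata()$signFlips`.
#' @export
signAlign <- function(x) {
  stopifnot(is(x, "TrialArray"))
  R <- dim(x@data)[2]
  if (R < 1L) stop("need at least one region")
  X <- do.call(rbind, lapply(seq_len(dim(x@data)[1]), function(tr)
    t(matrix(x@data[tr, , ], nrow = R))))
  sds <- apply(X, 2, stats::sd)
  flips <- rep(1, R)
  ok <- sds > 0
  if (!all(ok))
    warning("constant (zero-variance) region left unflipped")
  if (any(ok)) {
    Xc <- scale(X[, ok, drop = FALSE], center = TRUE, scale = FALSE)
    sv <- svd(Xc, nu = 1, nv = 0)
    pc1 <- sv$u[, 1] * sv$d[1]
    cc <- as.numeric(stats::cor(X[, ok, drop = FALSE], pc1))
    # gauge fix: orient the reference with the majority of regions, so a
    # single region's input polarity cannot flip the whole set; ties are
    # broken by the strongest correlate
    s <- sum(sign(cc))
    if (s < 0 || (s == 0 && cc[which.max(abs(cc))] < 0)) cc <- -cc
    flips[ok] <- ifelse(cc >= 0, 1, -1)
  }
  out <- x@data
  for (r in which(flips < 0)) out[, r, ] <- -out[, r, ]
  meta <- x@meta
  meta$signFlips <- flips
  new("TrialArray", data = out, fs = x@fs, t0 = x@t0,
      seriesKind = x@seriesKind, labels = x@labels, meta = meta)
}
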