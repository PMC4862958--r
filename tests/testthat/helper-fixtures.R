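# Shared fixtures: everything is generated in code at test time.

quickBands <- function() defaultBands()[c("alpha", "beta")]

# single- or multi-trial pure tone container
toneArray <- function(freq, fs = 600, duration = 9, amplitude = 1,
                      trials = 1, phase = 0) {
  t <- (seq_len(round(duration * fs)) - 1) / fs
  x <- amplitude * sin(2 * pi * freq * t + phase)
  trialArray(array(rep(x, each = trials),
                   c(trials, 1, length(t))), fs = fs)
}

# small latent-space simulation config (no task modulation)
smallConfig <- function(nRegions = 4, nTrials = 8, trialLength = 3,
                        fs = 250, bands = quickBands(), seed = 1, ...) {
  simulationConfig(nRegions = nRegions, nTrials = nTrials,
                   trialLength = trialLength, fs = fs, bands = bands,
                   couplingSpace = "latent", modulation = data.frame(),
                   seed = seed, ...)
}

# valid random correlation-kind SuperAdjacency (symmetric diagonal
# blocks with zero diagonal, directed off-diagonal blocks)
randomSM <- function(bands, regions, window = windowSpec("whole", 0, 1),
                     scale = 0.3) {
  B <- length(bands); R <- length(regions)
  M <- matrix(stats::runif((B * R)^2, -scale, scale), B * R)
  for (i in seq_len(B)) {
    idx <- (i - 1) * R + seq_len(R)
    blk <- M[idx, idx]
    blk <- (blk + t(blk)) / 2
    diag(blk) <- 0
    M[idx, idx] <- blk
  }
  for (i in seq_len(B)) for (j in seq_len(B)) {
    if (i >= j) next
    ii <- (i - 1) * R + seq_len(R); jj <- (j - 1) * R + seq_len(R)
    M[jj, ii] <- t(M[ii, jj])
  }
  new("SuperAdjacency", bands = bands, regions = regions, matrix = M,
      window = window, kind = "correlation")
}

# matrix-level null cohort: iid noise SMs, random severity
nullCohort <- function(nControls, nPatients, bands, regions,
                       scale = 0.3) {
  n <- nControls + nPatients
  sms <- replicate(n, randomSM(bands, regions, scale = scale))
  tb <- data.frame(
    subject_id = sprintf("s%02d", seq_len(n)),
    group = c(rep("control", nControls), rep("patient", nPatients)),
    severity = c(rep(NA_real_, nControls), stats::rnorm(nPatients)),
    stringsAsFactors = FALSE)
  cohortConnectivity(sms, tb)
}

# textbook step-up rule, used as the independent FDR oracle
handFdrStepUp <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  below <- which(ps <= (seq_len(m) / m) * q)
  keep <- logical(m)
  if (length(below)) keep[o[seq_len(max(below))]] <- TRUE
  keep
}

# exhaustive sign-flip permutation p for one element (oracle)
enumSignFlipP <- function(v) {
  n <- length(v)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  null <- abs(signs %*% v) / n
  obs <- abs(mean(v))
  mean(null >= obs - 1e-12)
}
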