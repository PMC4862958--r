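# Accessors and show methods for the core classes.

#' @rdname TrialArray-class
#' @export
setMethod("trialData", "TrialArray", function(x) x@data)

#' @rdname TrialArray-class
#' @export
setMethod("samplingRate", "TrialArray", function(x) x@fs)

#' @rdname TrialArray-class
#' @export
setMethod("timeOrigin", "TrialArray", function(x) x@t0)

#' @rdname TrialArray-class
#' @export
setMethod("seriesKind", "TrialArray", function(x) x@seriesKind)

#' @rdname TrialArray-class
#' @export
setMethod("seriesLabels", "TrialArray", function(x) x@labels)

#' @rdname TrialArray-class
#' @export
setMethod("nTrials", "TrialArray", function(x) dim(x@data)[1])

#' @rdname TrialArray-class
#' @export
setMethod("nSeries", "TrialArray", function(x) dim(x@data)[2])

#' @rdname TrialArray-class
#' @export
setMethod("nSamples", "TrialArray", function(x) dim(x@data)[3])

#' @rdname TrialArray-class
#' @export
setMethod("trialTimes", "TrialArray", function(x)
  x@t0 + (seq_len(dim(x@data)[3]) - 1) / x@fs)

#' @rdname TrialArray-class
#' @export
setMethod("metadata", "TrialArray", function(x) x@meta)

#' @rdname TrialArray-class
#' @export
setReplaceMethod("metadata", "TrialArray", function(x, value) {
  x@meta <- value
  x
})

setMethod("show", "TrialArray", function(object) {
  d <- dim(object@data)
  cat(sprintf("%s of %d trial(s) x %d %s series x %d samples @ %g Hz\n",
              class(object), d[1], d[2], object@seriesKind, d[3],
              object@fs))
  cat(sprintf("  time: [%g, %g) s\n", object@t0,
              object@t0 + d[3] / object@fs))
  if (length(object@meta))
    cat("  metadata fields:", paste(names(object@meta), collapse = ", "),
        "\n")
  invisible(NULL)
})

setMethod("show", "BandSpec", function(object) {
  cat(sprintf("band '%s': %g-%g Hz\n", object@name, object@fLo,
              object@fHi))
})

setMethod("show", "WindowSpec", function(object) {
  cat(sprintf("window '%s': [%g, %g) s\n", object@name, object@tStart,
              object@tEnd))
})

#' @rdname SuperAdjacency-class
#' @export
setMethod("bandNames", "SuperAdjacency", function(x)
  vapply(x@bands, function(b) b@name, ""))

#' @rdname SuperAdjacency-class
#' @export
setMethod("regionLabels", "SuperAdjacency", function(x) x@regions)

#' @rdname SuperAdjacency-class
#' @export
setMethod("getTile", "SuperAdjacency", function(x, seedBand, testBand) {
  bn <- bandNames(x)
  a <- match(seedBand, bn); b <- match(testBand, bn)
  if (is.na(a) || is.na(b))
    stop("unknown band; available: ", paste(bn, collapse = ", "))
  R <- length(x@regions)
  ia <- (a - 1L) * R + seq_len(R)
  ib <- (b - 1L) * R + seq_len(R)
  m <- x@matrix[ia, ib, drop = FALSE]
  dimnames(m) <- list(x@regions, x@regions)
  new("Tile", seedBand = x@bands[[a]], testBand = x@bands[[b]], matrix = m,
      window = x@window, symmetric = a == b)
})

#' @rdname SuperAdjacency-class
#' @export
setMethod("as.matrix", "SuperAdjacency", function(x, ...) {
  m <- x@matrix
  lbl <- smLabels(x@bands, x@regions)
  dimnames(m) <- list(lbl, lbl)
  m
})

#' @rdname Tile-class
#' @param x a [Tile-class].
#' @param ... unused.
#' @export
setMethod("as.matrix", "Tile", function(x, ...) x@matrix)

#' @rdname PermutationResult-class
#' @export
setMethod("as.matrix", "PermutationResult", function(x, ...) x@observed)

# "band:region" labels in block order (band-major)
smLabels <- function(bands, regions) {
  unlist(lapply(bands, function(b) paste(b@name, regions, sep = ":")),
         use.names = FALSE)
}

setMethod("show", "Tile", function(object) {
  cat(sprintf("%s tile %s -> %s (%d regions, window '%s')\n",
              if (object@symmetric) "within-band" else "between-band",
              object@seedBand@name, object@testBand@name,
              nrow(object@matrix), object@window@name))
})

setMethod("show", "SuperAdjacency", function(object) {
  B <- length(object@bands); R <- length(object@regions)
  cat(sprintf(
    "SuperAdjacency (%s): %d bands x %d regions -> %d x %d, window '%s'\n",
    object@kind, B, R, B * R, B * R, object@window@name))
  cat(sprintf("  %d distinct tiles (%d within-band, %d between-band)\n",
              B + B * (B - 1) / 2, B, B * (B - 1) / 2))
})

setMethod("show", "CohortConnectivity", function(object) {
  tb <- object@table
  cat(sprintf("CohortConnectivity: %d subjects (%d controls, %d patients)\n",
              nrow(tb), sum(tb$group == "control"),
              sum(tb$group == "patient")))
})

setMethod("show", "PermutationResult", function(object) {
  cat(sprintf(
    "PermutationResult: %d x %d elements, %d permutations, %s at q = %g\n",
    nrow(object@p), ncol(object@p), object@nPerm, object@correction,
    object@q))
  cat(sprintf("  %d significant element(s)\n", sum(object@mask)))
})

setMethod("show", "TileCorrelationResult", function(object) {
  cat(sprintf(
    "TileCorrelationResult: %d tiles, %d permutations\n",
    length(object@r), object@nPerm))
  sig <- object@p < object@alphaCorrected
  trend <- !sig & object@p < object@trendThreshold
  df <- data.frame(r = round(object@r, 4), p = signif(object@p, 4),
                   flag = ifelse(sig, "**", ifelse(trend, "*", "")))
  rownames(df) <- names(object@r)
  print(df)
  cat(sprintf("  ** p < %g (corrected)   * p < %g (trend)\n",
              object@alphaCorrected, object@trendThreshold))
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(
    "SimulationConfig: %d regions, %d trials of %g s @ %g Hz, %d bands\n",
    object@nRegions, object@nTrials, object@trialLength, object@fs,
    length(object@bands)))
  cat(sprintf("  coupling space: %s; noise sd %g; seed %d\n",
              object@couplingSpace, object@noiseSd, object@seed))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d coupling tile(s), seed %d\n",
              length(object@couplings), object@seed))
})

setMethod("show", "Leadfield", function(object) {
  d <- dim(object@gain)
  cat(sprintf("Leadfield: %d sensors x %d sources (free orientation)\n",
              d[1], d[2]))
})

# shared internal helpers ----------------------------------------------

# sample indices of a half-open window [tStart, tEnd)
windowIndices <- function(x, window) {
  tt <- x@t0 + (seq_len(dim(x@data)[3]) - 1) / x@fs
  idx <- which(tt >= window@tStart & tt < window@tEnd - 1e-12)
  if (length(idx) == 0L)
    stop(sprintf("window '%s' [%g, %g) contains no samples",
                 window@name, window@tStart, window@tEnd))
  if (window@tStart < x@t0 - 1e-9 ||
      window@tEnd > x@t0 + dim(x@data)[3] / x@fs + 1e-9)
    stop(sprintf("window '%s' extends beyond the trial extent",
                 window@name))
  idx
}

checkBandUsable <- function(band, fs) {
  if (band@fHi >= fs / 2)
    stop(sprintf("band '%s' (%g-%g Hz) exceeds the Nyquist frequency %g Hz",
                 band@name, band@fLo, band@fHi, fs / 2))
  invisible(TRUE)
}
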