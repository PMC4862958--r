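# Task-contrast permutation statistics, group/severity effect matrices,
# tile correlation with dual permutation nulls, and edge selection.

#' Difference super-adjacency matrix (dSM)
#'
#' Element-wise difference `active - control` between two matched
#' super-adjacency matrices, one subject's task contrast.
#'
#' @param active,control [SuperAdjacency-class] objects with matching
#'   bands and regions.
#' @return A [SuperAdjacency-class] of kind `"difference"`.
#' @export
dsm <- function(active, control) {
  stopifnot(is(active, "SuperAdjacency"), is(control, "SuperAdjacency"))
  if (!identical(bandNames(active), bandNames(control)) ||
      !identical(active@regions, control@regions))
    stop("band/region labels do not match")
  new("SuperAdjacency", bands = active@bands, regions = active@regions,
      matrix = active@matrix - control@matrix,
      window = windowSpec(paste0(active@window@name, "-",
                                 control@window@name),
                          min(active@window@tStart, control@window@tStart),
                          max(active@window@tEnd, control@window@tEnd)),
      kind = "difference")
}

# coerce a list of SuperAdjacency (or matrices) to subjects x elements
stackMatrices <- function(xs) {
  ms <- lapply(xs, function(x)
    if (is(x, "SuperAdjacency")) x@matrix else as.matrix(x))
  d <- dim(ms[[1]])
  if (any(!vapply(ms, function(m) all(dim(m) == d), TRUE)))
    stop("matrices have inconsistent dimensions")
  list(stack = do.call(rbind, lapply(ms, as.vector)), dim = d)
}

#' Element-wise sign-flip permutation test of paired differences
#'
#' Tests, per matrix element, whether subjects' difference matrices
#' (e.g. active-minus-control dSMs) have zero mean. Exchanging the two
#' window labels of a subject is equivalent to flipping the sign of that
#' subject's difference, so the null is built by averaging sham
#' difference matrices with independent random per-subject sign flips.
#' Two-tailed p-values use the exact-test convention
#' `p = (1 + #(|null| >= |observed|)) / (nPerm + 1)`, followed by
#' Benjamini-Hochberg FDR control.
#'
#' @param dsms list of per-subject difference [SuperAdjacency-class]
#'   objects (or plain matrices).
#' @param nPerm number of sham matrices (default 20000).
#' @param seed RNG seed.
#' @param q FDR level for the significance mask.
#' @param correction `"fdr_bh"`, `"bonferroni"` or `"none"`.
#' @return A [PermutationResult-class].
#' @export
permWindowTest <- function(dsms, nPerm = 20000, seed = 1L, q = 0.05,
                           correction = c("fdr_bh", "bonferroni",
                                          "none")) {
  correction <- match.arg(correction)
  st <- stackMatrices(dsms)
  X <- st$stack
  nSub <- nrow(X)
  if (nSub < 2L) stop("need at least 2 subjects")
  if (nPerm < 100) warning("fewer than 100 permutations; p floor is coarse")
  obs <- colMeans(X)
  set.seed(seed)
  exceed <- numeric(ncol(X))
  chunk <- max(1L, floor(5e6 / ncol(X)))
  done <- 0L
  while (done < nPerm) {
    k <- min(chunk, nPerm - done)
    S <- matrix(sample(c(-1, 1), k * nSub, replace = TRUE), k, nSub)
    null <- (S %*% X) / nSub
    exceed <- exceed + colSums(abs(null) >=
                                 matrix(abs(obs), k, ncol(X),
                                        byrow = TRUE))
    done <- done + k
  }
  p <- (1 + exceed) / (nPerm + 1)
  mask <- switch(correction,
                 fdr_bh = fdrBH(p, q),
                 bonferroni = p < q / length(p),
                 none = p < q)
  dimFn <- function(v) matrix(v, st$dim[1], st$dim[2])
  new("PermutationResult", observed = dimFn(obs), p = dimFn(p),
      mask = dimFn(mask), nPerm = nPerm, seed = as.numeric(seed),
      correction = correction, q = q)
}

#' Benjamini-Hochberg false-discovery-rate mask
#'
#' Step-up FDR control at level `q`: `TRUE` for retained hypotheses.
#'
#' @param p numeric vector or matrix of p-values in `(0, 1]`.
#' @param q FDR level.
#' @return Logical mask with the shape of `p`.
#' @examples
#' fdrBH(c(0.001, 0.2, 0.9), 0.05)
#' @export
fdrBH <- function(p, q) {
  if (length(p) == 0L) return(logical(0))
  if (any(p <= 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in (0, 1]")
  mask <- stats::p.adjust(as.vector(p), method = "BH") <= q
  mask[is.na(mask)] <- FALSE
  if (is.matrix(p)) mask <- matrix(mask, nrow(p), ncol(p))
  mask
}

#' Effect of diagnosis
#'
#' Element-wise difference between the control-group mean and the
#' patient-group mean connectivity (controls minus patients).
#'
#' @param cohort a [CohortConnectivity-class].
#' @return A [SuperAdjacency-class] of kind `"effect"`.
#' @export
effectOfDiagnosis <- function(cohort) {
  stopifnot(is(cohort, "CohortConnectivity"))
  g <- cohort@table$group
  if (!any(g == "control") || !any(g == "patient"))
    stop("both groups must be non-empty")
  st <- stackMatrices(cohort@sms)
  d <- colMeans(st$stack[g == "control", , drop = FALSE]) -
    colMeans(st$stack[g == "patient", , drop = FALSE])
  proto <- cohort@sms[[1]]
  new("SuperAdjacency", bands = proto@bands, regions = proto@regions,
      matrix = matrix(d, st$dim[1], st$dim[2]), window = proto@window,
      kind = "effect")
}

#' Severity score from three clinical measures
#'
#' First principal component of the column-standardized measures,
#' combining three numeric severity instruments into a single score per
#' patient. Sign convention: positive loading on the first column.
#'
#' @param measures `patients x 3` numeric matrix or data frame.
#' @return Numeric score per patient, with the loadings in attribute
#'   `loadings` and the explained variance fraction in `varExplained`.
#' @export
severityPCA <- function(measures) {
  m <- as.matrix(measures)
  if (nrow(m) < 3L) stop("need at least 3 patients")
  if (any(apply(m, 2, stats::sd) == 0))
    stop("constant measure column; cannot standardize")
  pc <- stats::prcomp(m, center = TRUE, scale. = TRUE)
  s <- pc$x[, 1]
  if (pc$rotation[1, 1] < 0) {
    s <- -s
    pc$rotation[, 1] <- -pc$rotation[, 1]
  }
  out <- as.numeric(s)
  attr(out, "loadings") <- pc$rotation[, 1]
  attr(out, "varExplained") <- pc$sdev[1]^2 / sum(pc$sdev^2)
  out
}

#' Effect of severity
#'
#' Element-wise Pearson correlation, across patients, between symptom
#' severity and connectivity. Zero-variance elements are undefined; they
#' are set to 0 and counted in attribute `nUndefined` of the result's
#' matrix slot so downstream tests can exclude them.
#'
#' @param cohort a [CohortConnectivity-class] whose patients all carry a
#'   severity value.
#' @return A [SuperAdjacency-class] of kind `"effect"` (entries are
#'   correlations across patients; undefined elements are set to 0 and
#'   counted in attribute `nUndefined` of the result's matrix).
#' @export
effectOfSeverity <- function(cohort) {
  stopifnot(is(cohort, "CohortConnectivity"))
  pat <- cohort@table$group == "patient"
  if (sum(pat) < 4L) stop("need at least 4 patients with severity")
  sev <- cohort@table$severity[pat]
  if (anyNA(sev)) stop("every patient needs a severity value")
  st <- stackMatrices(cohort@sms[pat])
  r <- elementwiseCorrelation(sev, st$stack)
  nUndef <- sum(is.na(r))
  r[is.na(r)] <- 0
  proto <- cohort@sms[[1]]
  m <- matrix(r, st$dim[1], st$dim[2])
  attr(m, "nUndefined") <- nUndef
  new("SuperAdjacency", bands = proto@bands, regions = proto@regions,
      matrix = m, window = proto@window, kind = "effect")
}

# correlation of a vector with every column of a matrix (NA for
# zero-variance columns)
elementwiseCorrelation <- function(v, X) {
  vc <- v - mean(v)
  Xc <- sweep(X, 2, colMeans(X))
  num <- as.numeric(crossprod(vc, Xc))
  den <- sqrt(sum(vc^2) * colSums(Xc^2))
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

#' Element index sets of the distinct tiles
#'
#' For a band list and region count, returns for every distinct tile the
#' linear indices (into the `(B*R) x (B*R)` matrix) of its unique
#' elements: the strict upper triangle for symmetric (within-band)
#' tiles, and all elements except same-region pairs for directed
#' (between-band) tiles.
#'
#' @param bands ordered list of [BandSpec-class].
#' @param nRegions region count.
#' @return Named list (names `"band"` / `"seed:test"`) of integer index
#'   vectors.
#' @export
tileIndices <- function(bands, nRegions) {
  B <- length(bands); R <- nRegions
  bn <- vapply(bands, function(b) b@name, "")
  n <- B * R
  out <- list()
  for (i in seq_len(B)) {
    ia <- (i - 1) * R + seq_len(R)
    sel <- outer(ia, ia, function(a, b) (b - 1) * n + a)
    out[[bn[i]]] <- as.vector(sel[upper.tri(sel)])
  }
  for (i in seq_len(B)) for (j in seq_len(B)) {
    if (i >= j) next
    ia <- (i - 1) * R + seq_len(R); ja <- (j - 1) * R + seq_len(R)
    sel <- outer(ia, ja, function(a, b) (b - 1) * n + a)
    diag(sel) <- NA
    out[[paste(bn[i], bn[j], sep = ":")]] <-
      as.vector(sel[!is.na(sel)])
  }
  out
}

#' Tile-by-tile correlation of two matrices
#'
#' Pearson correlation, per tile, between the unique elements of two
#' equally shaped matrices (typically the effect-of-diagnosis and
#' effect-of-severity matrices).
#'
#' @param D,S matrices or [SuperAdjacency-class] objects of equal shape.
#' @param bands ordered band list (taken from `D` when it is a
#'   [SuperAdjacency-class]).
#' @param nRegions region count (likewise inferred when possible).
#' @return Named numeric vector of per-tile correlations.
#' @export
tileCorrelation <- function(D, S, bands = NULL, nRegions = NULL) {
  if (is(D, "SuperAdjacency")) {
    if (is.null(bands)) bands <- D@bands
    if (is.null(nRegions)) nRegions <- length(D@regions)
  }
  Dm <- if (is(D, "SuperAdjacency")) D@matrix else as.matrix(D)
  Sm <- if (is(S, "SuperAdjacency")) S@matrix else as.matrix(S)
  if (!all(dim(Dm) == dim(Sm))) stop("matrix shapes differ")
  if (is.null(bands) || is.null(nRegions))
    stop("band list and region count required for plain matrices")
  idx <- tileIndices(bands, nRegions)
  vapply(idx, function(ii) {
    d <- Dm[ii]; s <- Sm[ii]
    ok <- is.finite(d) & is.finite(s)
    if (sum(ok) < 3L) stop("tile with fewer than 3 usable elements")
    stats::cor(d[ok], s[ok])
  }, 0)
}

# sham effect-of-diagnosis for a permuted group assignment
shamDiagnosis <- function(stack, nControl) {
  idx <- sample.int(nrow(stack))
  ic <- idx[seq_len(nControl)]
  ip <- idx[-seq_len(nControl)]
  colMeans(stack[ic, , drop = FALSE]) - colMeans(stack[ip, , drop = FALSE])
}

#' Dual-permutation tile-correlation test
#'
#' Observed statistic: per-tile correlation between the
#' effect-of-diagnosis and effect-of-severity matrices. Each null
#' iteration independently (i) exchanges patient/control labels
#' (preserving group sizes) to build a sham diagnosis matrix and (ii)
#' shuffles the severity scores across patients to build a sham severity
#' matrix, then recomputes the tile correlations. Two-tailed p-values
#' use the exact-test convention with floor `1/(nPerm + 1)`.
#' Significance is Bonferroni corrected across tiles and tails:
#' `alpha / (2 * nTiles)` (0.0025 for 10 tiles at `alpha = 0.05`);
#' `alpha / 2` uncorrected is flagged as a trend.
#'
#' @param cohort a [CohortConnectivity-class].
#' @param nPerm iterations (default 10000).
#' @param seed RNG seed.
#' @param alpha nominal two-tailed level before correction.
#' @return A [TileCorrelationResult-class].
#' @export
permTileCorrelation <- function(cohort, nPerm = 10000, seed = 1L,
                                alpha = 0.05) {
  stopifnot(is(cohort, "CohortConnectivity"))
  if (nPerm < 1000)
    warning("fewer than 1000 iterations: p floor too coarse for the ",
            "corrected threshold")
  D <- effectOfDiagnosis(cohort)
  S <- effectOfSeverity(cohort)
  bands <- D@bands; R <- length(D@regions)
  obs <- tileCorrelation(D, S, bands, R)
  idx <- tileIndices(bands, R)
  st <- stackMatrices(cohort@sms)
  pat <- cohort@table$group == "patient"
  sev <- cohort@table$severity[pat]
  patStack <- st$stack[pat, , drop = FALSE]
  nControl <- sum(!pat)
  set.seed(seed)
  exceed <- numeric(length(obs))
  for (it in seq_len(nPerm)) {
    dSham <- shamDiagnosis(st$stack, nControl)
    sSham <- elementwiseCorrelation(sample(sev), patStack)
    rSham <- vapply(idx, function(ii) {
      ok <- is.finite(dSham[ii]) & is.finite(sSham[ii])
      stats::cor(dSham[ii][ok], sSham[ii][ok])
    }, 0)
    exceed <- exceed + (abs(rSham) >= abs(obs))
  }
  p <- (1 + exceed) / (nPerm + 1)
  names(p) <- names(obs)
  nTiles <- length(obs)
  new("TileCorrelationResult", r = obs, p = p,
      alphaCorrected = alpha / (2 * nTiles), trendThreshold = alpha / 2,
      nPerm = nPerm, seed = as.numeric(seed))
}

#' Select edges significant for both diagnosis and severity
#'
#' Within one tile (previously flagged by [permTileCorrelation()]), each
#' element is tested independently for an effect of diagnosis (group
#' label exchange null) and an effect of severity (severity shuffle
#' null), both two-tailed; elements with both permutation p-values below
#' `alpha` are returned with their effect sizes.
#'
#' @param cohort a [CohortConnectivity-class].
#' @param tile band name (within-band tile) or `"seed:test"` key.
#' @param alpha per-test threshold (default 0.01).
#' @param nPerm permutations per test.
#' @param seed RNG seed.
#' @return A data frame of selected elements (`row`, `col`, `seedRegion`,
#'   `testRegion`, `diagEffect`, `severityR`, `pDiag`, `pSeverity`);
#'   the full per-element table is in attribute `all`.
#' @export
edgeSelection <- function(cohort, tile, alpha = 0.01, nPerm = 10000,
                          seed = 1L) {
  stopifnot(is(cohort, "CohortConnectivity"))
  proto <- cohort@sms[[1]]
  idx <- tileIndices(proto@bands, length(proto@regions))
  if (!tile %in% names(idx))
    stop("unknown tile; available: ", paste(names(idx), collapse = ", "))
  ii <- idx[[tile]]
  st <- stackMatrices(cohort@sms)
  pat <- cohort@table$group == "patient"
  sev <- cohort@table$severity[pat]
  patStack <- st$stack[pat, ii, drop = FALSE]
  sub <- st$stack[, ii, drop = FALSE]
  nControl <- sum(!pat)
  dObs <- colMeans(sub[!pat, , drop = FALSE]) -
    colMeans(sub[pat, , drop = FALSE])
  sObs <- elementwiseCorrelation(sev, patStack)
  set.seed(seed)
  dExceed <- numeric(length(ii)); sExceed <- numeric(length(ii))
  for (it in seq_len(nPerm)) {
    dSham <- shamDiagnosis(sub, nControl)
    sSham <- elementwiseCorrelation(sample(sev), patStack)
    dExceed <- dExceed + (abs(dSham) >= abs(dObs))
    sExceed <- sExceed + (abs(sSham) >= abs(sObs))
  }
  pD <- (1 + dExceed) / (nPerm + 1)
  pS <- (1 + sExceed) / (nPerm + 1)
  n <- nrow(proto@matrix)
  rows <- ((ii - 1) %% n) + 1
  cols <- ((ii - 1) %/% n) + 1
  lbl <- smLabels(proto@bands, proto@regions)
  all <- data.frame(row = rows, col = cols,
                    seedRegion = lbl[rows], testRegion = lbl[cols],
                    diagEffect = dObs, severityR = sObs,
                    pDiag = pD, pSeverity = pS,
                    stringsAsFactors = FALSE)
  sel <- all[all$pDiag < alpha & all$pSeverity < alpha, , drop = FALSE]
  rownames(sel) <- NULL
  attr(sel, "all") <- all
  sel
}
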