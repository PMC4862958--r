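# On-disk dataset container, adjacency import/export and run
# configuration parsing.
#
# The container is a directory:
#   meta.json      required attributes (fs, t0, series_kind, labels, dims)
#                  plus optional bands, windows, extras
#   data.bin       float64 little-endian payload, trials x series x samples
#                  in R array (column-major) order
#   cohort.csv     optional cohort table (subject_id, group, severity)
#   leadfield.json + leadfield.bin  optional forward model

schemaVersion <- "1.0"

#' Write a dataset container
#'
#' Serializes a [TrialArray-class] and its attached metadata (bands,
#' windows, cohort table, leadfield) to a directory container with a
#' JSON header and raw little-endian float64 payload. The round trip
#' through [readDataset()] is bit-identical.
#'
#' @param x a [TrialArray-class].
#' @param path container directory to create.
#' @param overwrite overwrite an existing container.
#' @return `path`, invisibly.
#' @export
writeDataset <- function(x, path, overwrite = FALSE) {
  stopifnot(is(x, "TrialArray"))
  validObject(x)
  if (file.exists(path) && !overwrite)
    stop("'", path, "' exists; use overwrite = TRUE to replace it")
  if (file.exists(path)) unlink(path, recursive = TRUE)
  dir.create(path, recursive = TRUE)
  meta <- list(
    schema_version = schemaVersion,
    fs = x@fs, t0 = x@t0, series_kind = x@seriesKind,
    labels = as.list(x@labels), dims = as.list(dim(x@data)),
    byte_order = "little")
  m <- x@meta
  if (!is.null(m$bands))
    meta$bands <- lapply(m$bands, function(b)
      list(name = b@name, f_lo = b@fLo, f_hi = b@fHi))
  if (!is.null(m$windows))
    meta$windows <- lapply(m$windows, function(w)
      list(name = w@name, t_start = w@tStart, t_end = w@tEnd))
  keep <- setdiff(names(m), c("bands", "windows", "cohort", "leadfield"))
  if (length(keep)) {
    simple <- m[keep][vapply(m[keep], function(v)
      is.atomic(v) && length(v) < 100, TRUE)]
    if (length(simple)) meta$extras <- simple
  }
  meta$has_cohort <- !is.null(m$cohort)
  meta$has_leadfield <- !is.null(m$leadfield)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  con <- file(file.path(path, "data.bin"), "wb")
  writeBin(as.vector(x@data), con, size = 8L, endian = "little")
  close(con)
  if (isTRUE(meta$has_cohort))
    utils::write.csv(m$cohort, file.path(path, "cohort.csv"),
                     row.names = FALSE)
  if (isTRUE(meta$has_leadfield)) {
    lf <- m$leadfield
    stopifnot(is(lf, "Leadfield"))
    jsonlite::write_json(
      list(dims = as.list(dim(lf@gain)),
           source_positions = lf@sourcePositions,
           sensor_positions = lf@sensorPositions,
           sensor_labels = as.list(lf@sensorLabels)),
      file.path(path, "leadfield.json"), auto_unbox = TRUE, digits = NA)
    con <- file(file.path(path, "leadfield.bin"), "wb")
    writeBin(as.vector(lf@gain), con, size = 8L, endian = "little")
    close(con)
  }
  invisible(path)
}

#' Read a dataset container
#'
#' Loads and validates a container written by [writeDataset()]. Missing
#' required attributes raise a schema error naming the attribute;
#' non-finite payload values raise a validation error.
#'
#' @param path container directory.
#' @return A [TrialArray-class] with metadata attached.
#' @export
readDataset <- function(path) {
  mf <- file.path(path, "meta.json")
  if (!file.exists(mf)) stop("not a dataset container: missing meta.json")
  meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
  for (req in c("fs", "t0", "series_kind", "labels", "dims"))
    if (is.null(meta[[req]]))
      stop(sprintf("schema error: missing required attribute '%s'", req))
  dims <- as.integer(unlist(meta$dims))
  n <- prod(dims)
  con <- file(file.path(path, "data.bin"), "rb")
  payload <- readBin(con, what = "double", n = n, size = 8L,
                     endian = "little")
  close(con)
  if (length(payload) != n)
    stop("validation error: payload size does not match 'dims'")
  if (anyNA(payload) || any(!is.finite(payload)))
    stop("validation error: payload contains NaN/Inf values")
  m <- list()
  if (!is.null(meta$bands)) {
    bl <- meta$bands
    if (is.data.frame(bl))
      bl <- lapply(seq_len(nrow(bl)), function(i) as.list(bl[i, ]))
    m$bands <- lapply(bl, function(b) bandSpec(b$name, b$f_lo, b$f_hi))
    names(m$bands) <- vapply(m$bands, function(b) b@name, "")
  }
  if (!is.null(meta$windows)) {
    wl <- meta$windows
    if (is.data.frame(wl))
      wl <- lapply(seq_len(nrow(wl)), function(i) as.list(wl[i, ]))
    m$windows <- lapply(wl, function(w)
      windowSpec(w$name, w$t_start, w$t_end))
    names(m$windows) <- vapply(m$windows, function(w) w@name, "")
  }
  if (!is.null(meta$extras)) m <- c(m, as.list(meta$extras))
  cf <- file.path(path, "cohort.csv")
  if (file.exists(cf))
    m$cohort <- utils::read.csv(cf, stringsAsFactors = FALSE)
  lfj <- file.path(path, "leadfield.json")
  if (file.exists(lfj)) {
    lmeta <- jsonlite::read_json(lfj, simplifyVector = TRUE)
    ld <- as.integer(unlist(lmeta$dims))
    con <- file(file.path(path, "leadfield.bin"), "rb")
    g <- readBin(con, "double", n = prod(ld), size = 8L,
                 endian = "little")
    close(con)
    m$leadfield <- new("Leadfield", gain = array(g, ld),
                       sourcePositions = as.matrix(lmeta$source_positions),
                       sensorPositions = as.matrix(lmeta$sensor_positions),
                       sensorLabels = unlist(lmeta$sensor_labels))
  }
  trialArray(array(payload, dims), fs = meta$fs, t0 = meta$t0,
             seriesKind = meta$series_kind, labels = unlist(meta$labels),
             meta = m)
}

#' Export an adjacency matrix as delimited text
#'
#' Writes a [SuperAdjacency-class], [Tile-class] or plain matrix as CSV
#' with `band:region` row and column headers, at full double precision
#' (re-import reproduces values to better than 1e-12 relative error).
#'
#' @param x the matrix-like object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
exportAdjacency <- function(x, path) {
  m <- as.matrix(x)
  if (any(!is.finite(m))) stop("matrix must be finite")
  if (is.null(rownames(m)))
    dimnames(m) <- list(paste0("r", seq_len(nrow(m))),
                        paste0("c", seq_len(ncol(m))))
  if (is(x, "Tile"))
    dimnames(m) <- list(paste(x@seedBand@name, rownames(m), sep = ":"),
                        paste(x@testBand@name, colnames(m), sep = ":"))
  chr <- matrix(sprintf("%.17g", m), nrow(m))
  out <- cbind(rownames(m), chr)
  lines <- c(paste(c("", colnames(m)), collapse = ","),
             apply(out, 1, paste, collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Re-import an exported adjacency matrix
#'
#' @param path file written by [exportAdjacency()].
#' @return Numeric matrix with row/column names.
#' @export
importAdjacency <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, row.names = 1)
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("non-numeric entries in adjacency file")
  m
}

#' Read a YAML run configuration
#'
#' Parses bands, windows, permutation counts, thresholds and the seed
#' for [runPipeline()]. Unknown fields are preserved.
#'
#' @param path YAML file.
#' @return A list with parsed `bands` ([BandSpec-class]) and `windows`
#'   ([WindowSpec-class]) plus remaining fields.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$bands))
    cfg$bands <- lapply(cfg$bands, function(b)
      bandSpec(b$name, b$f_lo, b$f_hi))
  if (!is.null(cfg$windows))
    cfg$windows <- lapply(cfg$windows, function(w)
      windowSpec(w$name, w$t_start, w$t_end))
  for (f in c("q_fdr", "tile_alpha", "edge_alpha"))
    if (!is.null(cfg[[f]]) && (cfg[[f]] <= 0 || cfg[[f]] >= 1))
      stop(sprintf("threshold '%s' must lie in (0, 1)", f))
  for (f in c("n_perm_window", "n_perm_tile"))
    if (!is.null(cfg[[f]]) && cfg[[f]] < 1)
      stop(sprintf("'%s' must be >= 1", f))
  cfg
}

# minimal structured logger (stderr + optional file)
mlLog <- function(fmt, ..., file = getOption("meglayer.logfile")) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                  sprintf(fmt, ...))
  message(line)
  if (!is.null(file)) cat(line, "\n", file = file, append = TRUE)
  invisible(line)
}
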