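## Native on-disk container: a directory holding one little-endian float64
## binary array per recording period plus a JSON metadata sidecar. Chosen
## over an opaque single-file format for transparency and diff-ability; the
## schema is versioned so later revisions can stay readable.

NATIVE_SCHEMA_VERSION <- 1L

#' Write / read an EEGRecording in the native container format
#'
#' \code{writeNative} serializes a recording to a directory:
#' \code{metadata.json} (all metadata, events, history, bad channels) plus
#' \code{period_<i>.bin} raw float64 arrays (column-major channels x
#' samples). \code{readNative} reverses it; the round trip reproduces every
#' field bit-exactly, including \code{NA} missing-channel sentinels.
#'
#' @param recording an \linkS4class{EEGRecording}.
#' @param path directory to create/overwrite (writeNative) or read
#'   (readNative).
#' @return \code{writeNative}: \code{path}, invisibly. \code{readNative}:
#'   an \linkS4class{EEGRecording}.
#' @export
writeNative <- function(recording, path) {
  stopifnot(is(recording, "EEGRecording"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  meta <- list(
    schema_version = NATIVE_SCHEMA_VERSION,
    sampling_rate = recording@samplingRate,
    original_sampling_rate = recording@originalSamplingRate,
    channel_labels = recording@channelLabels,
    layout_name = recording@layoutName,
    ten_twenty_map = as.list(recording@tenTwentyMap),
    line_noise_hz = recording@lineNoiseHz,
    data_type = recording@dataType,
    bad_channels = recording@badChannels,
    n_periods = length(recording@periods),
    period_cols = vapply(recording@periods, ncol, integer(1)),
    events = recording@events,
    history = recording@history
  )
  jsonlite::write_json(meta, file.path(path, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "columns", pretty = TRUE)
  for (i in seq_along(recording@periods)) {
    con <- file(file.path(path, sprintf("period_%03d.bin", i)), "wb")
    writeBin(as.vector(recording@periods[[i]]), con, size = 8L, endian = "little")
    close(con)
  }
  invisible(path)
}

#' @rdname writeNative
#' @export
readNative <- function(path) {
  metaPath <- file.path(path, "metadata.json")
  if (!file.exists(metaPath))
    stop("native container format error: missing metadata.json in ", path)
  meta <- jsonlite::read_json(metaPath, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  req <- c("schema_version", "sampling_rate", "channel_labels", "data_type",
           "n_periods", "period_cols")
  miss <- setdiff(req, names(meta))
  if (length(miss))
    stop("native container format error: metadata block missing section(s): ",
         paste(miss, collapse = ", "))
  nch <- length(meta$channel_labels)
  nper <- as.integer(meta$n_periods)
  cols <- as.integer(unlist(meta$period_cols))
  periods <- vector("list", nper)
  for (i in seq_len(nper)) {
    f <- file.path(path, sprintf("period_%03d.bin", i))
    if (!file.exists(f))
      stop("native container format error: missing period array ", basename(f))
    expected <- nch * cols[i]
    con <- file(f, "rb")
    v <- readBin(con, "double", n = expected + 1L, size = 8L, endian = "little")
    close(con)
    if (length(v) != expected)
      stop(sprintf("native container format error: %s holds %d values, expected %d",
                   basename(f), length(v), expected))
    periods[[i]] <- matrix(v, nrow = nch, ncol = cols[i])
  }
  ev <- meta$events
  events <- if (is.null(ev) || length(ev$label %||% character(0)) == 0L) {
    emptyEvents()
  } else {
    data.frame(label = as.character(unlist(ev$label)),
               period = as.integer(unlist(ev$period)),
               sample = as.numeric(unlist(ev$sample)),
               applied_offset_samples = as.numeric(unlist(ev$applied_offset_samples)),
               stringsAsFactors = FALSE)
  }
  ttm <- unlist(meta$ten_twenty_map) %||% character(0)
  if (is.null(ttm)) ttm <- character(0)
  new("EEGRecording",
      periods = periods,
      samplingRate = as.numeric(meta$sampling_rate),
      channelLabels = as.character(meta$channel_labels),
      layoutName = as.character(meta$layout_name %||% "unknown"),
      tenTwentyMap = ttm,
      lineNoiseHz = as.numeric(meta$line_noise_hz %||% 60),
      dataType = as.character(meta$data_type),
      events = events,
      originalSamplingRate = as.numeric(meta$original_sampling_rate %||% meta$sampling_rate),
      badChannels = as.integer(unlist(meta$bad_channels) %||% integer(0)),
      history = meta$history %||% list())
}

#' Export / import a SegmentSet for third-party tools
#'
#' Writes the 3-D segment array as one raw float64 file
#' (\code{segments.bin}, column-major channels x samples x segments) plus a
#' JSON sidecar (\code{segments.json}: labels, per-sample timing, keep
#' flags, provenance). Only kept segments are exported. An all-rejected or
#' empty set writes nothing and warns.
#'
#' @param segset a \linkS4class{SegmentSet}.
#' @param path output directory.
#' @param keptOnly export only segments with \code{keepFlags} TRUE
#'   (default TRUE).
#' @return the path (invisibly), or \code{NULL} if nothing was written.
#' @export
exportSegments <- function(segset, path, keptOnly = TRUE) {
  stopifnot(is(segset, "SegmentSet"))
  idx <- if (keptOnly) which(segset@keepFlags) else seq_len(nSegments(segset))
  if (length(idx) == 0L) {
    warning("no segments to export; no file written")
    return(invisible(NULL))
  }
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  d <- segset@data[, , idx, drop = FALSE]
  side <- list(
    schema_version = NATIVE_SCHEMA_VERSION,
    dims = dim(d),
    channel_labels = segset@channelLabels,
    rel_time_ms = segset@relTimeMs,
    sampling_rate = segset@samplingRate,
    condition_label = segset@conditionLabel,
    keep_flags = segset@keepFlags[idx],
    source_period = segset@sourcePeriod[idx],
    source_start = segset@sourceStart[idx],
    skipped_events = segset@skippedEvents
  )
  jsonlite::write_json(side, file.path(path, "segments.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  con <- file(file.path(path, "segments.bin"), "wb")
  writeBin(as.vector(d), con, size = 8L, endian = "little")
  close(con)
  invisible(path)
}

#' @rdname exportSegments
#' @export
importSegments <- function(path) {
  sidePath <- file.path(path, "segments.json")
  if (!file.exists(sidePath))
    stop("segment container format error: missing segments.json in ", path)
  side <- jsonlite::read_json(sidePath, simplifyVector = TRUE)
  dims <- as.integer(side$dims)
  con <- file(file.path(path, "segments.bin"), "rb")
  v <- readBin(con, "double", n = prod(dims) + 1L, size = 8L, endian = "little")
  close(con)
  if (length(v) != prod(dims))
    stop("segment container format error: segments.bin size mismatch")
  new("SegmentSet",
      data = array(v, dim = dims),
      relTimeMs = as.numeric(side$rel_time_ms),
      keepFlags = as.logical(side$keep_flags),
      conditionLabel = as.character(side$condition_label %||% ""),
      sourcePeriod = as.integer(side$source_period),
      sourceStart = as.numeric(side$source_start),
      channelLabels = as.character(side$channel_labels),
      samplingRate = as.numeric(side$sampling_rate),
      skippedEvents = as.integer(side$skipped_events %||% 0L))
}
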