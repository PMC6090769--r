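## Config-driven batch orchestration: a declarative YAML run configuration
## selects an ordered menu of stages; every input file flows through them,
## per-file failures are caught and logged without halting the batch, and
## the run emits an "out" folder with summary CSVs and a full provenance
## ledger. Exit-code semantics (0 ok / 1 config error / 2 partial failure)
## live in the thin CLI wrapper (exec/eegbatch).

STAGE_ORDER <- c("format", "filter", "resample", "rereference", "detrend",
                 "segment", "psd", "itpc")

KNOWN_CONFIG_KEYS <- c("inputs", "out_dir", "overwrite", "seed", "data_type",
                       "offset_csv", "stages", "filter", "resample",
                       "rereference", "detrend", "segment", "psd", "itpc",
                       "save", "hooks")

## Named no-op extension points where external cleaners (robust-reference
## pipelines, ICA-based artifact removal, ...) can be registered without
## changing the menu architecture. A hook is fun(recording, fileId) ->
## recording, run after the named stage.
.hookRegistry <- new.env(parent = emptyenv())

#' Register or clear stage hooks
#'
#' @param point hook point, \code{"post_<stage>"} for any stage name.
#' @param fun function(recording, fileId) returning a (possibly modified)
#'   recording.
#' @return invisibly, the hook point.
#' @export
registerStageHook <- function(point, fun) {
  stopifnot(is.function(fun))
  hooks <- get0(point, envir = .hookRegistry, ifnotfound = list())
  assign(point, c(hooks, list(fun)), envir = .hookRegistry)
  invisible(point)
}

#' @rdname registerStageHook
#' @export
clearStageHooks <- function() {
  rm(list = ls(.hookRegistry), envir = .hookRegistry)
  invisible(NULL)
}

runHooks <- function(point, rec, fileId) {
  for (fun in get0(point, envir = .hookRegistry, ifnotfound = list()))
    rec <- fun(rec, fileId)
  rec
}

#' Read a run configuration file
#'
#' A single declarative YAML file describes a run: the inputs, the ordered
#' stage list, per-stage parameter blocks, per-module save flags, the
#' offset/override CSV, the out directory, the overwrite flag and the
#' seed. Unknown keys are rejected.
#'
#' @param path YAML file.
#' @return the configuration list.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), KNOWN_CONFIG_KEYS)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg
}

#' Validate a run configuration without executing it
#'
#' Returns findings rather than running anything: ordering violations and
#' unknown stages, a resampling target below twice the low-pass cutoff
#' (the aliasing guard), and requests whose results would be hard to
#' interpret (inter-trial phase coherence on baseline data, whose segments
#' are tied to no stimulus, is a warning).
#'
#' @param config configuration list (see \code{\link{readRunConfig}}).
#' @return data.frame with columns \code{level} ("error"/"warning") and
#'   \code{message}; zero rows means clean.
#' @export
validateConfig <- function(config) {
  findings <- list()
  add <- function(level, msg)
    findings[[length(findings) + 1L]] <<- data.frame(level = level, message = msg,
                                                     stringsAsFactors = FALSE)
  unknown <- setdiff(names(config), KNOWN_CONFIG_KEYS)
  if (length(unknown))
    add("error", paste("unknown configuration key(s):", paste(unknown, collapse = ", ")))
  stages <- unlist(config$stages)
  if (length(stages) == 0L) {
    add("error", "stage list is empty")
  } else {
    bad <- setdiff(stages, STAGE_ORDER)
    if (length(bad)) add("error", paste("unknown stage(s):", paste(bad, collapse = ", ")))
    pos <- match(stages, STAGE_ORDER)
    if (!anyNA(pos) && any(diff(pos) < 0))
      add("error", paste("stage order must follow",
                         paste(STAGE_ORDER, collapse = " -> ")))
    if (anyDuplicated(stages)) add("error", "duplicate stage names")
  }
  lp <- config$filter$lowpass
  tgt <- config$resample$target_hz
  if (!is.null(lp) && !is.null(tgt) && all(c("filter", "resample") %in% stages)) {
    if (!checkResampleVsLowpass(lp, tgt))
      add("error", sprintf("resampling target %g Hz is below twice the low-pass cutoff %g Hz (aliasing)",
                           tgt, lp))
  }
  if ("itpc" %in% stages && identical(config$data_type, "baseline"))
    add("warning", "ITPC requested on baseline data: segments are tied to no stimulus, so the meaning of such results would be questionable")
  if (any(c("psd", "itpc") %in% stages) && !"segment" %in% stages)
    add("warning", "analysis stages without a segment stage assume pre-segmented inputs")
  if (length(findings)) do.call(rbind, findings) else
    data.frame(level = character(0), message = character(0))
}

## classify one input path: "edf", "native", "segments"
classifyInput <- function(path) {
  if (dir.exists(path)) {
    if (file.exists(file.path(path, "metadata.json"))) return("native")
    if (file.exists(file.path(path, "segments.json"))) return("segments")
    stop("input directory ", path, " is neither a native container nor a segment container")
  }
  if (grepl("\\.edf$", path, ignore.case = TRUE)) return("edf")
  stop("unrecognized input: ", path)
}

## expand a directory input into individual file inputs
discoverInputs <- function(inputs) {
  inputs <- unlist(inputs)
  out <- character(0)
  for (p in inputs) {
    if (dir.exists(p) && !file.exists(file.path(p, "metadata.json")) &&
        !file.exists(file.path(p, "segments.json"))) {
      edfs <- list.files(p, pattern = "\\.edf$", ignore.case = TRUE, full.names = TRUE)
      subs <- list.dirs(p, recursive = FALSE)
      subs <- subs[file.exists(file.path(subs, "metadata.json")) |
                     file.exists(file.path(subs, "segments.json"))]
      out <- c(out, sort(c(edfs, subs)))
    } else {
      out <- c(out, p)
    }
  }
  out
}

segmentStage <- function(rec, segCfg) {
  reject <- segCfg$reject %||% "none"
  thr <- segCfg$amplitude_threshold_uv %||% 100
  segset <- switch(dataType(rec),
    baseline = {
      if (identical(reject, "amplitude_pre_mask")) {
        mask <- buildArtifactMask(rec, thr)
        segmentMasked(rec, mask, segCfg$segment_len_s %||% 1)
      } else {
        segmentBaseline(rec, segCfg$segment_len_s %||% 1)
      }
    },
    event_tagged = segmentEvents(rec, segCfg$event_labels %||% "standard",
                                 segCfg$start_ms %||% -100,
                                 segCfg$end_ms %||% 800),
    conditioned_baseline = segmentConditionedBaseline(rec,
                                 segCfg$onset_label, segCfg$offset_label,
                                 segCfg$segment_len_s %||% 1))
  if (identical(reject, "amplitude_post")) segset <- rejectAmplitude(segset, thr)
  if (identical(reject, "joint_probability"))
    segset <- rejectJointProbability(segset, segCfg$jp_z_threshold %||% 3)
  if (isTRUE(segCfg$within_segment_detrend)) segset <- detrendWithinSegment(segset)
  if (!is.null(segCfg$baseline_correct))
    segset <- baselineCorrect(segset, segCfg$baseline_correct[[1]],
                              segCfg$baseline_correct[[2]])
  if (!is.null(segCfg$subsegment))
    segset <- extractSubsegment(segset, segCfg$subsegment[[1]],
                                segCfg$subsegment[[2]])
  segset
}

#' Run a configured batch over all input files
#'
#' Validates the configuration (aborting before any file is touched on
#' errors), guards against unintentionally overwriting an existing out
#' directory, then flows every input file through the selected stages.
#' Per-file failures are caught and recorded in the ledger without halting
#' the batch. Writes \code{power_summary.csv}, \code{itpc_summary.csv}
#' (when the respective analyses ran), per-module intermediates for
#' modules with a TRUE save flag, and \code{run_ledger.json} +
#' \code{command_log.txt}.
#'
#' @param config configuration list (see \code{\link{readRunConfig}}).
#' @return invisibly, a list with the ledger, the number of failed files,
#'   and the out directory.
#' @export
runBatch <- function(config) {
  findings <- validateConfig(config)
  errs <- findings$message[findings$level == "error"]
  if (length(errs))
    stop("invalid configuration:\n  ", paste(errs, collapse = "\n  "))
  outDir <- config$out_dir %||% "out"
  if (file.exists(file.path(outDir, "run_ledger.json")) && !isTRUE(config$overwrite))
    stop("out directory '", outDir, "' already holds a run; ",
         "pass overwrite: true to replace it")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed %||% 1L)
  stages <- unlist(config$stages)
  saveFlags <- vapply(setdiff(stages, c("psd", "itpc")),
                      function(s) isTRUE(config$save[[s]]), logical(1))
  offsets <- if (!is.null(config$offset_csv)) readOffsetTable(config$offset_csv) else NULL
  files <- discoverInputs(config$inputs)
  logLines <- character(0)
  log <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    logLines <<- c(logLines, line)
    message(line)
  }
  perFile <- list()
  powerEntries <- list()
  itpcEntries <- list()
  nFailed <- 0L

  for (f in files) {
    fileId <- sub("\\.edf$", "", basename(f), ignore.case = TRUE)
    log("processing %s", fileId)
    notes <- character(0)
    rec <- NULL; segset <- NULL
    status <- tryCatch({
      withCallingHandlers({
        kind <- classifyInput(f)
        ovr <- if (!is.null(offsets)) offsets[match(fileId, offsets$file_id), ] else NULL
        if (kind == "edf") {
          rec <- importEDF(f,
                           layoutName = if (!is.null(ovr) && !is.na(ovr$layout_name %||% NA)) ovr$layout_name else "unknown",
                           lineNoiseHz = if (!is.null(ovr) && !is.na(ovr$line_noise_hz %||% NA)) ovr$line_noise_hz else 60,
                           dataType = if (!is.null(ovr) && !is.na(ovr$data_type %||% NA)) ovr$data_type else "baseline")
        } else if (kind == "native") {
          rec <- readNative(f)
        } else {
          segset <- importSegments(f)
        }
        if (!is.null(rec)) {
          if (!is.null(config$data_type) && !identical(config$data_type, "auto") &&
              !identical(config$data_type, dataType(rec)))
            rec <- setDataType(rec, config$data_type)
          if (!is.null(ovr) && !is.na(ovr$periods %||% NA) && nzchar(ovr$periods)) {
            sel <- as.integer(strsplit(as.character(ovr$periods), ";")[[1]])
            if (!identical(sel, seq_len(nPeriods(rec))))
              rec <- selectRecordingPeriods(rec, sel)
          }
          if (dataType(rec) %in% c("event_tagged", "conditioned_baseline") &&
              !is.null(offsets))
            rec <- applyEventOffsets(rec, offsets, fileId)
        }
        for (stage in stages) {
          if (stage %in% c("format")) next
          if (stage %in% c("filter", "resample", "rereference", "detrend")) {
            if (is.null(rec)) next     # pre-segmented input: notice below
            rec <- switch(stage,
              filter = filterRecording(rec,
                         highpass = config$filter$highpass,
                         lowpass = config$filter$lowpass,
                         notch = config$filter$notch,
                         notchWidth = config$filter$notch_width %||% 2),
              resample = resampleRecording(rec, config$resample$target_hz),
              rereference = rereferenceRecording(rec,
                         scheme = config$rereference$scheme %||% "average",
                         channels = unlist(config$rereference$channels)),
              detrend = detrendRecording(rec,
                         method = config$detrend$method %||% "mean",
                         qOverR = config$detrend$q_over_r %||% 1e-6))
            rec <- runHooks(paste0("post_", stage), rec, fileId)
            if (isTRUE(unname(saveFlags[stage])))
              writeNative(rec, file.path(outDir, stage, fileId))
          } else if (stage == "segment") {
            if (is.null(rec)) next
            segset <- segmentStage(rec, config$segment)
            if (isTRUE(unname(saveFlags["segment"])))
              exportSegments(segset, file.path(outDir, "segment", fileId),
                             keptOnly = FALSE)
          } else if (stage == "psd") {
            if (is.null(segset)) stop("psd stage reached without segments")
            meta <- fileMetaFor(rec, segset, fileId)
            if (sum(keepFlags(segset)) == 0L) {
              notes <- c(notes, "no kept segments; empty power entry")
              powerEntries[[fileId]] <- list(meta = meta, bands = NULL)
            } else {
              psd <- if (identical(config$psd$window, "multitaper"))
                computePsdMultitaper(segset, config$psd$n_tapers %||% 3)
              else
                computePsd(segset, config$psd$window %||% "rectangular")
              bands <- bandsFromConfig(config$psd$bands)
              powerEntries[[fileId]] <- list(meta = meta,
                                              bands = bandPower(psd, bands))
            }
          } else if (stage == "itpc") {
            if (is.null(segset)) stop("itpc stage reached without segments")
            if (!is.null(rec) && dataType(rec) != "event_tagged") {
              notes <- c(notes, "itpc skipped: data are not event-tagged")
              next
            }
            icfg <- config$itpc
            res <- computeItpc(segset,
                               subwindowMs = icfg$subwindow_ms %||% 256,
                               hopFraction = icfg$hop_fraction %||% 0.5)
            summ <- itpcSummary(res,
                                timeRangeMs = unlist(icfg$time_range_ms),
                                freqRangeHz = unlist(icfg$freq_range_hz),
                                channelGroup = unlist(icfg$channel_group))
            itpcEntries[[fileId]] <- list(
              file_id = fileId, summary = summ$summary,
              band = if (is.null(icfg$freq_range_hz)) "all" else
                paste(unlist(icfg$freq_range_hz), collapse = "-"),
              window_range_ms = unlist(icfg$time_range_ms) %||% c(NA, NA))
          }
        }
        "ok"
      },
      warning = function(w) {
        notes <<- c(notes, conditionMessage(w))
        invokeRestart("muffleWarning")
      },
      message = function(m) {
        notes <<- c(notes, trimws(conditionMessage(m)))
        invokeRestart("muffleMessage")
      })
    }, error = function(e) paste("ERROR:", conditionMessage(e)))
    if (!identical(status, "ok")) {
      nFailed <- nFailed + 1L
      log("  %s: %s", fileId, status)
    }
    perFile[[fileId]] <- list(
      modules_run = if (!is.null(rec)) vapply(processingHistory(rec),
                                              function(h) h$module, character(1)) else stages,
      parameters = if (!is.null(rec)) lapply(processingHistory(rec),
                                             function(h) h$parameters) else NULL,
      warnings = notes,
      segments_created = if (!is.null(segset)) nSegments(segset) else NULL,
      segments_kept = if (!is.null(segset)) sum(keepFlags(segset)) else NULL,
      bad_channels = if (!is.null(rec)) badChannels(rec) else NULL,
      error = if (identical(status, "ok")) NULL else status)
  }

  if (length(powerEntries))
    writePowerCsv(unname(powerEntries), file.path(outDir, "power_summary.csv"))
  if (length(itpcEntries))
    writeItpcCsv(unname(itpcEntries), file.path(outDir, "itpc_summary.csv"))
  ledger <- list(group_settings = config, per_file = perFile,
                 command_log = logLines)
  writeRunLedger(ledger, outDir)
  pruneModuleOutputs(outDir, saveFlags)
  invisible(list(ledger = ledger, n_failed = nFailed, out_dir = outDir))
}

fileMetaFor <- function(rec, segset, fileId) {
  if (is.null(rec)) {
    return(list(file_id = fileId, net_type = "", original_sampling_rate = samplingRate(segset),
                current_sampling_rate = samplingRate(segset),
                recording_periods_run = sort(unique(segset@sourcePeriod)),
                bad_channels = integer(0),
                n_segments_analyzed = sum(keepFlags(segset))))
  }
  list(file_id = fileId,
       net_type = layoutName(rec),
       original_sampling_rate = originalSamplingRate(rec),
       current_sampling_rate = samplingRate(rec),
       recording_periods_run = seq_len(nPeriods(rec)),
       bad_channels = badChannels(rec),
       n_segments_analyzed = sum(keepFlags(segset)))
}

bandsFromConfig <- function(bands) {
  if (is.null(bands)) {
    return(data.frame(name = c("delta", "theta", "alpha", "beta", "gamma"),
                      lo = c(1, 4, 6, 13, 30), hi = c(4, 6, 13, 30, 50),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(bands, function(b)
    data.frame(name = b$name, lo = b$lo, hi = b$hi, stringsAsFactors = FALSE)))
}
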