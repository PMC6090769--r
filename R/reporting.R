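## The run's "out" folder: group-level settings ledger, per-file
## provenance, and analysis summary CSVs. CSV dialect: UTF-8, comma
## separator, "." decimal, mandatory header; list-valued cells
## semicolon-joined; undefined power serialized as an empty cell.

joinList <- function(x) paste(x, collapse = ";")

#' Write the power summary CSV
#'
#' One row per file x channel x band with the acquisition context needed
#' to interpret the numbers: file_id, net_type, original_sampling_rate,
#' current_sampling_rate, recording_periods_run, bad_channels,
#' n_segments_analyzed, band, power_abs, power_norm, power_ln,
#' power_log10. A file with zero analyzed segments contributes a single
#' row with empty band and power cells.
#'
#' @param entries list of per-file entries, each a list with \code{meta}
#'   (list: file_id, net_type, original_sampling_rate,
#'   current_sampling_rate, recording_periods_run, bad_channels,
#'   n_segments_analyzed) and \code{bands} (data.frame from
#'   \code{\link{bandPower}}, or NULL).
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writePowerCsv <- function(entries, path) {
  rows <- lapply(entries, function(e) {
    m <- e$meta
    base <- data.frame(file_id = m$file_id,
                       net_type = m$net_type %||% "",
                       original_sampling_rate = m$original_sampling_rate,
                       current_sampling_rate = m$current_sampling_rate,
                       recording_periods_run = joinList(m$recording_periods_run %||% 1L),
                       bad_channels = joinList(m$bad_channels %||% integer(0)),
                       n_segments_analyzed = m$n_segments_analyzed %||% 0L,
                       stringsAsFactors = FALSE)
    if (is.null(e$bands) || nrow(e$bands) == 0L) {
      cbind(base, data.frame(channel = "", band = "", power_abs = NA_real_,
                             power_norm = NA_real_, power_ln = NA_real_,
                             power_log10 = NA_real_, stringsAsFactors = FALSE))
    } else {
      cbind(base[rep(1L, nrow(e$bands)), , drop = FALSE], e$bands,
            row.names = NULL)
    }
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$file_id, tab$channel, tab$band), , drop = FALSE]
  utils::write.csv(tab, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Write the ITPC summary CSV
#'
#' One row per file x channel, ordered by (file_id, channel):
#' file_id, channel, band, window_range_ms, itpc_max, itpc_mean.
#'
#' @param entries list of per-file entries, each a list with
#'   \code{file_id}, \code{summary} (data.frame from
#'   \code{\link{itpcSummary}}), \code{band} (label for the analyzed
#'   frequency range) and \code{window_range_ms} (length-2).
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeItpcCsv <- function(entries, path) {
  rows <- lapply(entries, function(e) {
    s <- e$summary
    data.frame(file_id = e$file_id,
               channel = s$channel,
               band = e$band %||% "all",
               window_range_ms = paste(e$window_range_ms %||% c(NA, NA), collapse = ".."),
               itpc_max = s$itpc_max,
               itpc_mean = s$itpc_mean,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$file_id, tab$channel), , drop = FALSE]
  utils::write.csv(tab, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Write the run ledger
#'
#' Writes the group-level settings snapshot, the per-file provenance map
#' (modules run, parameters, warnings and skip notices, segment counts,
#' bad channels, failures) and the text command log into the out folder.
#' The ledger is written even after a partial failure, so every input file
#' appears exactly once, with its error text when it failed.
#'
#' @param ledger list with \code{group_settings}, \code{per_file},
#'   \code{command_log} (character vector of log lines).
#' @param outDir the run's out directory.
#' @return character vector of the paths written, invisibly.
#' @export
writeRunLedger <- function(ledger, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  jsonPath <- file.path(outDir, "run_ledger.json")
  logPath <- file.path(outDir, "command_log.txt")
  jsonlite::write_json(list(group_settings = ledger$group_settings,
                            per_file = ledger$per_file),
                       jsonPath, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  writeLines(ledger$command_log %||% character(0), logPath)
  invisible(c(jsonPath, logPath))
}

#' Delete intermediates of modules not marked for saving
#'
#' Each module's per-file intermediate outputs live under
#' \code{out/<module>/}; modules whose save flag is FALSE have that
#' directory removed once the run finishes. Asking to prune a module whose
#' save flag is TRUE is refused.
#'
#' @param outDir the run's out directory.
#' @param saveFlags named logical vector, module name -> keep.
#' @param prune module names to prune; default all with flag FALSE.
#' @return character vector of deleted paths, invisibly.
#' @export
pruneModuleOutputs <- function(outDir, saveFlags, prune = NULL) {
  if (is.null(prune)) prune <- names(saveFlags)[!saveFlags]
  keepAsked <- intersect(prune, names(saveFlags)[saveFlags])
  if (length(keepAsked))
    stop("refusing to prune module(s) marked keep: ",
         paste(keepAsked, collapse = ", "))
  deleted <- character(0)
  for (m in prune) {
    d <- file.path(outDir, m)
    if (dir.exists(d)) {
      unlink(d, recursive = TRUE)
      deleted <- c(deleted, d)
    }
  }
  invisible(deleted)
}
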