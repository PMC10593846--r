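# Plain-text on-disk formats: TSV for arrays/tables with '#' header lines for
# metadata and provenance, YAML for configuration. Everything round-trips.

headerLines <- function(meta) {
  vapply(names(meta), function(k) sprintf("# %s=%s", k, meta[[k]]), character(1))
}

readHeader <- function(path) {
  lines <- readLines(path, n = 50)
  h <- grep("^# ", lines, value = TRUE)
  kv <- regmatches(h, regexec("^# ([^=]+)=(.*)$", h))
  out <- list()
  for (m in kv) if (length(m) == 3) out[[m[2]]] <- m[3]
  out
}

#' Write / read a Recording as TSV
#'
#' Samples x regions tab-separated values with `# key=value` header lines
#' carrying the sampling rate, subject id, and any provenance metadata.
#'
#' @param rec a [Recording-class].
#' @param path file path.
#' @param meta optional named list of extra header fields (e.g. provenance).
#' @return `writeRecording` returns `path` invisibly; `readRecording` returns
#'   a [Recording-class].
#' @export
writeRecording <- function(rec, path, meta = list()) {
  stopifnot(is(rec, "Recording"))
  hdr <- headerLines(c(list(fs = rec@fs, subject = rec@subjectId), meta))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  df <- as.data.frame(t(rec@data))
  names(df) <- rec@regionNames
  utils::write.table(format(df, digits = 15, trim = TRUE, scientific = TRUE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeRecording
#' @export
readRecording <- function(path) {
  meta <- readHeader(path)
  if (is.null(meta$fs)) stop(sprintf("%s: missing 'fs' header", path))
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
  Recording(t(as.matrix(df)), fs = as.numeric(meta$fs),
            regionNames = names(df), subjectId = meta$subject %||% "S01")
}

#' Write / read an event table as TSV
#'
#' Columns `onset_s`, `condition` (one of `0T,0D,1T,1D,2T,2D`), `block`.
#' Unknown condition labels raise an error naming the offending row.
#'
#' @param events an event table (`data.frame` with at least `onset_s`,
#'   `condition`, `block`).
#' @param path file path.
#' @param meta optional named list of extra header fields.
#' @return `writeEvents` returns `path` invisibly; `readEvents` an
#'   `EventTable` data.frame.
#' @export
writeEvents <- function(events, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(headerLines(meta), con)
  utils::write.table(events[, c("onset_s", "condition", "block")], con,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEvents
#' @export
readEvents <- function(path) {
  df <- utils::read.delim(path, comment.char = "#",
                          colClasses = c(onset_s = "numeric",
                                         condition = "character",
                                         block = "integer"))
  bad <- which(!df$condition %in% conditionLevels())
  if (length(bad))
    stop(sprintf("%s: unknown condition label '%s' at row %d",
                 path, df$condition[bad[1]], bad[1]))
  df$condition <- factor(df$condition, levels = conditionLevels())
  df$load <- as.integer(substr(as.character(df$condition), 1, 1))
  df$isTarget <- grepl("T$", df$condition)
  class(df) <- c("EventTable", "data.frame")
  df
}

#' Read a set of recordings and event tables
#'
#' Validates that the files parse, region counts agree across subjects, and
#' units are sane (positive sampling rate, non-negative onsets).
#'
#' @param recordingPaths character vector of recording TSV paths.
#' @param eventPaths optional character vector of event TSV paths (parallel to
#'   `recordingPaths`).
#' @return List with `recordings` and `events` lists.
#' @export
readInputs <- function(recordingPaths, eventPaths = NULL) {
  recs <- lapply(recordingPaths, readRecording)
  nr <- vapply(recs, function(r) nrow(r@data), integer(1))
  if (length(unique(nr)) != 1L)
    stop(sprintf("region counts differ across subjects: %s (files: %s)",
                 paste(nr, collapse = ", "),
                 paste(basename(recordingPaths), collapse = ", ")))
  evs <- NULL
  if (!is.null(eventPaths)) {
    evs <- lapply(eventPaths, readEvents)
    for (i in seq_along(evs))
      if (any(evs[[i]]$onset_s < 0))
        stop(sprintf("%s: negative onset_s", eventPaths[i]))
  }
  list(recordings = recs, events = evs)
}

#' Write a TSV table with provenance header
#'
#' @param df data.frame.
#' @param path file path.
#' @param meta named list of header fields (config hash, seeds, version).
#' @return `path`, invisibly.
#' @export
writeTable <- function(df, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(headerLines(meta), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
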