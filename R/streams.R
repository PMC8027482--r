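#' Uniformly sampled sensor stream
#'
#' A bundle of equally long channels from one instrument, sampled at a fixed
#' rate. Sample k sits at `t0_offset + (k - 1) / rate` on the instrument's
#' own clock; `t0_offset` is the recorded offset of that clock relative to
#' the master timeline (the paper logged these manually per instrument).
#'
#' @param instrument instrument name, e.g. "imu", "hr", "pole_force"
#' @param rate sampling rate, Hz
#' @param channels named list of equal-length numeric vectors
#' @param t0_offset clock offset vs the master timeline, s
#' @export
sensor_stream <- function(instrument, rate, channels, t0_offset = 0) {
  stopifnot(is.character(instrument), rate > 0, is.list(channels),
            length(channels) > 0, !is.null(names(channels)))
  n <- unique(vapply(channels, length, 0L))
  if (length(n) != 1) stop("all channels must have equal length")
  structure(list(instrument = instrument, rate = rate,
                 t0_offset = t0_offset, channels = channels),
            class = "sensor_stream")
}

#' @export
print.sensor_stream <- function(x, ...) {
  cat(sprintf("<sensor_stream> %s: %d samples @ %g Hz (%.1f s), offset %g s\n",
              x$instrument, stream_length(x), x$rate,
              stream_length(x) / x$rate, x$t0_offset))
  cat("  channels:", paste(names(x$channels), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname sensor_stream
#' @param stream a `sensor_stream`
#' @export
stream_length <- function(stream) length(stream$channels[[1]])

#' Sample times of a stream on its own clock
#' @param stream a `sensor_stream`
#' @export
stream_time <- function(stream) {
  stream$t0_offset + (seq_len(stream_length(stream)) - 1) / stream$rate
}

#' Write / read one sensor stream as CSV
#'
#' The file is plain CSV preceded by comment lines
#' `#instrument=`, `#rate=`, `#t0_offset=` so each file is self-describing.
#'
#' @param stream a `sensor_stream`
#' @param path file path
#' @export
write_stream_csv <- function(stream, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("#instrument=", stream$instrument),
               paste0("#rate=", format(stream$rate, digits = 15)),
               paste0("#t0_offset=", format(stream$t0_offset, digits = 15))),
             con)
  utils::write.csv(as.data.frame(stream$channels), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_stream_csv
#' @export
read_stream_csv <- function(path) {
  hdr <- readLines(path, n = 3)
  if (!all(startsWith(hdr, "#"))) stop("missing stream metadata header")
  meta <- strsplit(sub("^#", "", hdr), "=", fixed = TRUE)
  meta <- stats::setNames(vapply(meta, `[`, "", 2), vapply(meta, `[`, "", 1))
  dat <- utils::read.csv(path, comment.char = "#")
  sensor_stream(meta[["instrument"]], as.numeric(meta[["rate"]]),
                as.list(dat), as.numeric(meta[["t0_offset"]]))
}

#' Write a generated trial (all streams plus ground-truth sidecars) to CSVs
#' @param trial output of [generate_trial()]
#' @param dir output directory (created if needed)
#' @export
write_trial_csv <- function(trial, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(trial$streams))
    write_stream_csv(trial$streams[[nm]], file.path(dir, paste0(nm, ".csv")))
  utils::write.csv(trial$truth$cycles,
                   file.path(dir, "truth_cycles.csv"), row.names = FALSE)
  utils::write.csv(trial$truth$per_second,
                   file.path(dir, "truth_per_second.csv"), row.names = FALSE)
  invisible(dir)
}
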