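#' Depth-frame sequences
#'
#' A `depth_sequence` bundles an ordered stack of depth frames (unsigned
#' 16-bit depth values, 1 unit = 1 mm), one timestamp per frame (seconds),
#' and the rectangular chest region of interest (ROI) whose mean
#' frame-to-frame change yields the breathing motion signal.
#'
#' @param frames integer array with dim `c(rows, cols, n_frames)`; values in
#'   `[0, 65535]`.
#' @param timestamps numeric vector of per-frame acquisition times in
#'   seconds, strictly increasing, one per frame.
#' @param roi integer vector `c(row_start, row_stop, col_start, col_stop)`,
#'   1-based and inclusive, within the frame bounds.
#'
#' @return An object of class `depth_sequence`.
#' @export
#' @examples
#' fr <- array(1000L, dim = c(4, 4, 3))
#' depth_sequence(fr, timestamps = c(0, 0.1, 0.2), roi = c(2, 3, 2, 3))
depth_sequence <- function(frames, timestamps, roi) {
  abort_if(!is.array(frames) || length(dim(frames)) != 3,
           "frames must be a rows x cols x n_frames array")
  storage.mode(frames) <- "integer"
  abort_if(anyNA(frames) || min(frames) < 0L || max(frames) > 65535L,
           "frame values must be unsigned 16-bit (0..65535)")
  dm <- dim(frames)
  abort_if(length(timestamps) != dm[3],
           "need exactly one timestamp per frame")
  check_increasing(timestamps)
  roi <- as.integer(roi)
  abort_if(length(roi) != 4, "roi must be c(row_start, row_stop, col_start, col_stop)")
  abort_if(roi[1] < 1 || roi[2] > dm[1] || roi[3] < 1 || roi[4] > dm[2] ||
             roi[1] > roi[2] || roi[3] > roi[4],
           "roi must be a non-empty rectangle inside the frame bounds")
  structure(
    list(frames = frames, timestamps = as.numeric(timestamps), roi = roi),
    class = "depth_sequence"
  )
}

#' @export
print.depth_sequence <- function(x, ...) {
  dm <- dim(x$frames)
  cat(sprintf("<depth_sequence> %d frames of %dx%d px, %.1f s, ROI rows %d..%d cols %d..%d\n",
              dm[3], dm[1], dm[2], diff(range(x$timestamps)),
              x$roi[1], x$roi[2], x$roi[3], x$roi[4]))
  invisible(x)
}

#' @export
dim.depth_sequence <- function(x) dim(x$frames)

n_frames <- function(seq) dim(seq$frames)[3]

# Frame-stack file format ------------------------------------------------
#
# Raw little-endian uint16, row-major frames concatenated, plus a JSON
# sidecar {rows, cols, n_frames, roi, roi_indexing} and a timestamps CSV
# (frame_index, t_s). Byte-auditable and dependency-free.

#' Write and read raw depth-frame stacks
#'
#' The on-disk format is a single binary file of little-endian unsigned
#' 16-bit values (row-major within each frame, frames concatenated), a JSON
#' sidecar recording `rows`, `cols`, `n_frames` and the ROI, and a CSV of
#' per-frame timestamps with columns `frame_index`, `t_s`.
#'
#' @param seq a [depth_sequence()].
#' @param path path of the binary frame stack (e.g. `stack.bin`).
#' @param sidecar path of the JSON sidecar; defaults to `<path>.json`.
#' @param timestamps path of the timestamps CSV; defaults to
#'   `<path>.timestamps.csv`.
#' @return `write_depth_stack()` returns `path` invisibly;
#'   `read_depth_stack()` returns a [depth_sequence()] byte-identical to
#'   what was written.
#' @export
write_depth_stack <- function(seq, path,
                              sidecar = paste0(path, ".json"),
                              timestamps = paste0(path, ".timestamps.csv")) {
  abort_if(!inherits(seq, "depth_sequence"), "seq must be a depth_sequence")
  dm <- dim(seq$frames)
  # row-major within frame: transpose each frame before writing
  vals <- as.integer(aperm(seq$frames, c(2, 1, 3)))
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(vals, con, size = 2, endian = "little")
  meta <- list(rows = dm[1], cols = dm[2], n_frames = dm[3],
               roi = seq$roi, roi_indexing = "1-based inclusive",
               dtype = "uint16le")
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE)
  readr::write_csv(
    tibble::tibble(frame_index = seq_len(dm[3]) - 1L, t_s = seq$timestamps),
    timestamps
  )
  invisible(path)
}

#' @rdname write_depth_stack
#' @export
read_depth_stack <- function(path,
                             sidecar = paste0(path, ".json"),
                             timestamps = paste0(path, ".timestamps.csv")) {
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  rows <- as.integer(meta$rows); cols <- as.integer(meta$cols)
  nf <- as.integer(meta$n_frames)
  expected <- as.numeric(rows) * cols * nf * 2
  actual <- file.info(path)$size
  abort_if(is.na(actual) || actual != expected,
           sprintf("frame stack size mismatch: expected %.0f bytes (%dx%dx%d uint16), found %.0f",
                   expected, rows, cols, nf, actual))
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  vals <- readBin(con, what = "integer", n = rows * cols * nf,
                  size = 2, signed = FALSE, endian = "little")
  frames <- aperm(array(as.integer(vals), dim = c(cols, rows, nf)), c(2, 1, 3))
  ts <- readr::read_csv(timestamps, show_col_types = FALSE)
  abort_if(!all(c("frame_index", "t_s") %in% names(ts)),
           "timestamps CSV needs columns frame_index, t_s")
  abort_if(nrow(ts) != nf, "timestamps CSV row count does not match n_frames")
  ts <- dplyr::arrange(ts, .data$frame_index)
  abort_if(any(diff(ts$t_s) <= 0), "timestamps must be strictly increasing")
  depth_sequence(frames, ts$t_s, as.integer(unlist(meta$roi)))
}

# Annotations and signals ------------------------------------------------

apnea_types <- c("central", "obstructive", "mixed")

#' Read and write apnea event annotations
#'
#' Annotations are a CSV with mandatory header `start_s,end_s,type`;
#' `type` is one of `central`, `obstructive`, `mixed`. Events are returned
#' sorted by start time.
#'
#' @param path CSV file path.
#' @param events a data frame with columns `start_s`, `end_s`, `type`.
#' @return A tibble with columns `start_s`, `end_s`, `type`, sorted by
#'   `start_s`.
#' @export
read_annotations <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          start_s = readr::col_double(),
                          end_s = readr::col_double(),
                          type = readr::col_character()
                        ))
  as_annotations(df)
}

#' @rdname read_annotations
#' @export
write_annotations <- function(events, path) {
  events <- as_annotations(events)
  readr::write_csv(events, path)
  invisible(path)
}

#' @rdname read_annotations
#' @export
as_annotations <- function(events) {
  abort_if(!is.data.frame(events), "events must be a data frame")
  if (nrow(events) == 0) {
    return(tibble::tibble(start_s = numeric(), end_s = numeric(),
                          type = character()))
  }
  abort_if(!all(c("start_s", "end_s", "type") %in% names(events)),
           "annotations need columns start_s, end_s, type")
  bad <- setdiff(unique(events$type), apnea_types)
  abort_if(length(bad) > 0,
           sprintf("unknown event type(s) %s; allowed: %s",
                   paste(bad, collapse = ", "),
                   paste(apnea_types, collapse = ", ")))
  abort_if(any(events$start_s >= events$end_s),
           "each event must have start_s < end_s")
  dplyr::arrange(
    tibble::as_tibble(events[c("start_s", "end_s", "type")]),
    .data$start_s
  )
}

#' Read and write motion-signal CSVs
#'
#' Signal files carry two columns, `t_s` and `value` (header mandatory,
#' comma-separated, dot decimal).
#'
#' @param path CSV file path.
#' @param signal data frame with columns `t` and `value` (seconds, depth
#'   units).
#' @return `read_signal_csv()` returns a tibble with columns `t`, `value`;
#'   if the timestamps are uniform the sampling rate is attached as the
#'   `fs` attribute.
#' @export
read_signal_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          t_s = readr::col_double(),
                          value = readr::col_double()
                        ))
  abort_if(!all(c("t_s", "value") %in% names(df)),
           "signal CSV needs columns t_s, value")
  check_increasing(df$t_s)
  out <- tibble::tibble(t = df$t_s, value = df$value)
  dt <- diff(out$t)
  if (length(dt) > 0 && max(dt) - min(dt) < 1e-9) {
    attr(out, "fs") <- 1 / stats::median(dt)
    class(out) <- c("breathing_signal", class(out))
  }
  out
}

#' @rdname read_signal_csv
#' @export
write_signal_csv <- function(signal, path) {
  signal <- as_signal_df(signal)
  readr::write_csv(tibble::tibble(t_s = signal$t, value = signal$value), path)
  invisible(path)
}
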