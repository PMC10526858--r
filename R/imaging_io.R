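#' Recording metadata
#'
#' @param frame_interval_s sampling interval in seconds (> 0).
#' @param n_frames number of frames (>= 2).
#' @param exposure_s exposure time in seconds; informational only.
#' @param source free-text provenance.
#' @return An object of class `recording_meta`.
#' @export
recording_meta <- function(frame_interval_s, n_frames, exposure_s = 0.01,
                           source = "") {
  check_number(frame_interval_s, "frame_interval_s", min = 0, strict_min = TRUE)
  check_number(n_frames, "n_frames", min = 2, integerish = TRUE)
  structure(list(frame_interval_s = frame_interval_s,
                 n_frames = as.integer(n_frames),
                 exposure_s = exposure_s, source = as.character(source)),
            class = "recording_meta")
}

#' Per-ROI fluorescence trace matrix
#'
#' The central time-series container: a frames x ROIs matrix of
#' fluorescence intensities (arbitrary units) with ROI labels and recording
#' metadata.  Frame indices are 0-based throughout the package; times are
#' `frame_index * frame_interval_s` seconds.
#'
#' @param values numeric matrix, frames in rows, ROIs in columns.
#' @param roi_ids character vector of column labels.
#' @param meta a [recording_meta()]; its `n_frames` must equal `nrow(values)`.
#' @return An object of class `trace_matrix`.
#' @export
trace_matrix <- function(values, roi_ids = colnames(values), meta) {
  if (!is.matrix(values) || !is.numeric(values))
    stop_contract("'values' must be a numeric matrix")
  if (any(!is.finite(values)))
    stop_contract("trace values must all be finite")
  if (ncol(values) < 1L)
    stop_contract("trace matrix needs at least one ROI column")
  if (is.null(roi_ids)) roi_ids <- sprintf("roi_%03d", seq_len(ncol(values)))
  if (length(roi_ids) != ncol(values))
    stop_contract("roi_ids length (%d) != number of columns (%d)",
                  length(roi_ids), ncol(values))
  stopifnot(inherits(meta, "recording_meta"))
  if (nrow(values) != meta$n_frames)
    stop_contract("trace has %d rows but meta says %d frames",
                  nrow(values), meta$n_frames)
  colnames(values) <- roi_ids
  structure(list(values = values, roi_ids = as.character(roi_ids),
                 meta = meta), class = "trace_matrix")
}

#' @export
print.trace_matrix <- function(x, ...) {
  cat(sprintf("<trace_matrix> %d frames x %d ROIs, %.3g s/frame (%s)\n",
              nrow(x$values), ncol(x$values), x$meta$frame_interval_s,
              if (nzchar(x$meta$source)) x$meta$source else "unknown source"))
  invisible(x)
}

#' @export
plot.trace_matrix <- function(x, rois = seq_len(min(5L, ncol(x$values))),
                              offset = NULL, ...) {
  v <- x$values[, rois, drop = FALSE]
  if (is.null(offset)) offset <- 1.2 * diff(range(v))
  t_s <- (seq_len(nrow(v)) - 1L) * x$meta$frame_interval_s
  graphics::plot(range(t_s), c(0, offset * ncol(v)), type = "n",
                 xlab = "time (s)", ylab = "fluorescence (offset a.u.)", ...)
  for (j in seq_len(ncol(v)))
    graphics::lines(t_s, v[, j] - min(v[, j]) + (j - 1) * offset)
  invisible(x)
}

#' Per-ROI spike trains
#'
#' @param trains list of strictly increasing 0-based integer frame indices,
#'   one element per ROI.
#' @param n_frames number of frames in the recording.
#' @param frame_interval_s sampling interval, seconds.
#' @return An object of class `spike_train_set`.
#' @export
spike_train_set <- function(trains, n_frames, frame_interval_s) {
  if (!is.list(trains) || length(trains) < 1L)
    stop_contract("'trains' must be a non-empty list")
  check_number(n_frames, "n_frames", min = 1, integerish = TRUE)
  check_number(frame_interval_s, "frame_interval_s", min = 0,
               strict_min = TRUE)
  trains <- lapply(trains, function(tr) {
    tr <- as.integer(tr)
    if (length(tr) && (any(tr < 0L) || any(tr >= n_frames)))
      stop_contract("spike frame index outside [0, %d)", n_frames)
    if (length(tr) > 1L && any(diff(tr) <= 0L))
      stop_contract("spike trains must be strictly increasing")
    tr
  })
  if (is.null(names(trains)))
    names(trains) <- sprintf("roi_%03d", seq_along(trains))
  structure(list(trains = trains, n_frames = as.integer(n_frames),
                 frame_interval_s = frame_interval_s),
            class = "spike_train_set")
}

#' @export
print.spike_train_set <- function(x, ...) {
  n <- lengths(x$trains)
  cat(sprintf(
    "<spike_train_set> %d ROIs, %d frames (%.3g s/frame); %d spikes total, %d active ROIs\n",
    length(n), x$n_frames, x$frame_interval_s, sum(n), sum(n > 0)))
  invisible(x)
}

#' Set of regions of interest
#'
#' @param centroids numeric matrix of (row, col) pixel centroids.
#' @param masks list of integer vectors of linear pixel indices (column-major).
#' @param radii numeric vector of nominal radii in pixels.
#' @return An object of class `roi_set`.
#' @export
roi_set <- function(centroids, masks, radii = NA_real_) {
  stopifnot(is.matrix(centroids), ncol(centroids) == 2L, is.list(masks),
            nrow(centroids) == length(masks))
  if (any(lengths(masks) == 0L))
    stop_contract("every ROI mask must be non-empty")
  structure(list(centroids = centroids, masks = masks,
                 radii = rep_len(radii, length(masks))), class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set> %d ROIs, median area %.0f px\n",
              length(x$masks), median(lengths(x$masks))))
  invisible(x)
}

#' @export
length.roi_set <- function(x) length(x$masks)

sidecar_path <- function(path) paste0(path, ".meta.json")

#' Write / read trace matrices as CSV
#'
#' Traces are written as a comma-separated table with a mandatory header of
#' ROI ids, one row per frame, dot decimal, UTF-8.  A JSON sidecar
#' (`<path>.meta.json`) carries `frame_interval_s`, `exposure_s`,
#' `n_frames` and `source`, so that a write/read cycle restores the object
#' to 1e-9 relative accuracy.
#'
#' @param tm a [trace_matrix()].
#' @param path CSV file path.
#' @return `write_traces` returns `path` invisibly; `read_traces` a
#'   [trace_matrix()].
#' @export
write_traces <- function(tm, path) {
  stopifnot(inherits(tm, "trace_matrix"))
  df <- as.data.frame(tm$values)
  colnames(df) <- tm$roi_ids
  write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    tm$meta[c("frame_interval_s", "n_frames", "exposure_s", "source")],
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_traces
#' @param meta a [recording_meta()]; if `NULL`, read from the JSON sidecar.
#' @export
read_traces <- function(path, meta = NULL) {
  if (!file.exists(path)) stop_contract("no such file: %s", path)
  lines <- readLines(path)
  if (length(lines) < 2L)
    stop_contract("trace CSV must have a header and at least 2 data rows")
  header <- strsplit(lines[[1L]], ",", fixed = TRUE)[[1L]]
  header <- gsub('^"|"$', "", header)
  body <- strsplit(lines[-1L], ",", fixed = TRUE)
  ncols <- length(header)
  vals <- matrix(NA_real_, length(body), ncols)
  for (i in seq_along(body)) {
    row <- body[[i]]
    if (length(row) != ncols)
      stop_contract("parse error at data row %d: %d fields, expected %d",
                    i, length(row), ncols)
    num <- suppressWarnings(as.numeric(row))
    if (any(is.na(num)))
      stop_contract("parse error at data row %d: non-numeric or missing value",
                    i)
    vals[i, ] <- num
  }
  if (nrow(vals) < 2L)
    stop_contract("trace CSV must contain at least 2 frames")
  if (is.null(meta)) {
    sp <- sidecar_path(path)
    if (!file.exists(sp))
      stop_contract("no metadata: supply 'meta' or provide sidecar %s", sp)
    m <- jsonlite::read_json(sp, simplifyVector = TRUE)
    meta <- recording_meta(frame_interval_s = m$frame_interval_s,
                           n_frames = nrow(vals),
                           exposure_s = if (!is.null(m$exposure_s))
                             m$exposure_s else 0.01,
                           source = if (!is.null(m$source)) m$source else path)
  }
  if (meta$n_frames != nrow(vals))
    meta$n_frames <- nrow(vals)
  trace_matrix(vals, roi_ids = header, meta = meta)
}

#' Write / read spike trains as CSV
#'
#' Schema: `roi_id, frame_index, time_s, peak_over_sigma` (the last column
#' is `NA` for trains without detector scores, e.g. simulated ground
#' truth).  Frame indices are 0-based.
#'
#' @param spikes a [spike_train_set()].
#' @param path CSV file path.
#' @export
write_spikes <- function(spikes, path) {
  stopifnot(inherits(spikes, "spike_train_set"))
  scores <- attr(spikes, "peak_over_sigma")
  rows <- lapply(seq_along(spikes$trains), function(i) {
    tr <- spikes$trains[[i]]
    if (!length(tr)) return(NULL)
    data.frame(roi_id = names(spikes$trains)[i], frame_index = tr,
               time_s = tr * spikes$frame_interval_s,
               peak_over_sigma = if (!is.null(scores)) scores[[i]]
                                 else NA_real_)
  })
  df <- do.call(rbind, c(rows, list(
    data.frame(roi_id = character(0), frame_index = integer(0),
               time_s = numeric(0), peak_over_sigma = numeric(0)))))
  write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    list(n_frames = spikes$n_frames,
         frame_interval_s = spikes$frame_interval_s,
         roi_ids = names(spikes$trains)),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_spikes
#' @param n_frames,frame_interval_s,roi_ids recording geometry; if `NULL`,
#'   read from the JSON sidecar.
#' @export
read_spikes <- function(path, n_frames = NULL, frame_interval_s = NULL,
                        roi_ids = NULL) {
  if (!file.exists(path)) stop_contract("no such file: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("roi_id", "frame_index")
  if (!all(need %in% names(df)))
    stop_contract("spike CSV must have columns: %s", paste(need, collapse = ", "))
  sp <- sidecar_path(path)
  if ((is.null(n_frames) || is.null(frame_interval_s)) && file.exists(sp)) {
    m <- jsonlite::read_json(sp, simplifyVector = TRUE)
    if (is.null(n_frames)) n_frames <- m$n_frames
    if (is.null(frame_interval_s)) frame_interval_s <- m$frame_interval_s
    if (is.null(roi_ids)) roi_ids <- m$roi_ids
  }
  if (is.null(n_frames) || is.null(frame_interval_s))
    stop_contract("supply n_frames and frame_interval_s or provide sidecar %s",
                  sp)
  if (is.null(roi_ids)) roi_ids <- sort(unique(df$roi_id))
  trains <- lapply(roi_ids, function(id)
    sort(unique(as.integer(df$frame_index[df$roi_id == id]))))
  names(trains) <- roi_ids
  spike_train_set(trains, n_frames = n_frames,
                  frame_interval_s = frame_interval_s)
}

#' Write / read image stacks as multi-page TIFF
#'
#' Stacks are grayscale, 16-bit, one page per frame; integer intensities in
#' \[0, 65535\] round-trip losslessly.  The frame interval travels in a
#' JSON sidecar or is supplied explicitly on read.
#'
#' @param stack height x width x frames numeric array of non-negative
#'   integers (<= 65535).
#' @param path TIFF file path.
#' @param frame_interval_s sampling interval in seconds, stored in the
#'   sidecar.
#' @export
write_movie <- function(stack, path, frame_interval_s = 0.2) {
  stopifnot(is.array(stack), length(dim(stack)) == 3L)
  if (any(stack < 0) || any(stack > 65535))
    stop_contract("stack intensities must lie in [0, 65535]")
  frames <- lapply(seq_len(dim(stack)[3]),
                   function(t) stack[, , t] / 65535)
  tiff::writeTIFF(frames, path, bits.per.sample = 16L)
  jsonlite::write_json(
    list(frame_interval_s = frame_interval_s, n_frames = dim(stack)[3]),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_movie
#' @return `read_movie` returns a list with `stack` (height x width x
#'   frames array of non-negative intensities) and `meta`, a
#'   [recording_meta()].
#' @export
read_movie <- function(path, frame_interval_s = NULL) {
  if (!file.exists(path)) stop_contract("no such file: %s", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e)
                      stop_contract("unreadable TIFF '%s': %s", path,
                                    conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 2L)
    stop_contract("movie must have at least 2 frames, got %d", length(pages))
  if (length(dim(pages[[1L]])) == 3L)
    stop_contract("RGB input not supported; convert to grayscale")
  h <- nrow(pages[[1L]]); w <- ncol(pages[[1L]])
  stack <- array(0, dim = c(h, w, length(pages)))
  for (t in seq_along(pages)) {
    if (!identical(dim(pages[[t]]), c(h, w)))
      stop_contract("frame %d has mismatched dimensions", t)
    stack[, , t] <- round(pages[[t]] * 65535)
  }
  if (is.null(frame_interval_s)) {
    sp <- sidecar_path(path)
    if (file.exists(sp)) {
      m <- jsonlite::read_json(sp, simplifyVector = TRUE)
      frame_interval_s <- m$frame_interval_s
    } else {
      stop_contract("supply frame_interval_s or provide sidecar %s", sp)
    }
  }
  list(stack = stack,
       meta = recording_meta(frame_interval_s = frame_interval_s,
                             n_frames = length(pages), source = path))
}
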