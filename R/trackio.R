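#' @include AllClasses.R
NULL

#' Construct acquisition metadata
#'
#' @param pixelSize pixel size, micrometers per pixel.
#' @param exposure exposure time per frame, seconds.
#' @param darkInterval dark time between exposures, seconds (0 for
#'   continuous acquisition).
#' @param nFrames number of frames in the movie.
#' @param label free-text label.
#' @return an [AcquisitionMetadata-class] object.
#' @examples
#' meta <- AcquisitionMetadata(pixelSize = 0.11, exposure = 0.2,
#'                             darkInterval = 0.8, nFrames = 100)
#' frameInterval(meta)  # 1 s
#' @export
AcquisitionMetadata <- function(pixelSize = 0.1, exposure = 0.2,
                                darkInterval = 0, nFrames = 0L,
                                label = "") {
  new("AcquisitionMetadata", pixelSize = as.numeric(pixelSize),
      exposure = as.numeric(exposure),
      darkInterval = as.numeric(darkInterval),
      nFrames = as.integer(nFrames), label = as.character(label))
}

#' Construct a TrackSet from a localization table
#'
#' Rows are sorted by (`track_id`, `frame`); missing optional columns are
#' filled (`t` from the frame interval, `intensity`/`sigma` with NA).
#'
#' @param data data.frame with columns `track_id`, `frame`, `x`, `y` and
#'   optionally `t`, `intensity`, `sigma`. Coordinates in micrometers,
#'   frames 0-based.
#' @param meta an [AcquisitionMetadata-class].
#' @return a validated [TrackSet-class].
#' @export
TrackSet <- function(data, meta) {
  stopifnot(is.data.frame(data), is(meta, "AcquisitionMetadata"))
  mandatory <- c("track_id", "frame", "x", "y")
  miss <- setdiff(mandatory, names(data))
  if (length(miss))
    stop("track table is missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  if (!"t" %in% names(data))
    data$t <- data$frame * frameInterval(meta)
  if (!"intensity" %in% names(data))
    data$intensity <- rep(NA_real_, nrow(data))
  if (!"sigma" %in% names(data)) data$sigma <- rep(NA_real_, nrow(data))
  data <- data[, .TRACK_COLS, drop = FALSE]
  data$frame <- as.integer(data$frame)
  for (col in c("t", "x", "y", "intensity", "sigma"))
    data[[col]] <- as.numeric(data[[col]])
  data <- data[order(data$track_id, data$frame), , drop = FALSE]
  rownames(data) <- NULL
  new("TrackSet", data = data, meta = meta)
}

#' Read a track table from CSV
#'
#' Expects a header with columns `track_id`, `frame`, `x`, `y` and optional
#' `t`, `intensity`, `sigma`. Coordinates must already be in micrometers
#' (0-based frames). When `t` is absent it is reconstructed as
#' `frame * (exposure + darkInterval)`.
#'
#' @param path path to a CSV file.
#' @param meta an [AcquisitionMetadata-class] describing the acquisition.
#' @return a validated [TrackSet-class]; a header-only file yields an empty
#'   TrackSet.
#' @seealso [writeTracks()]
#' @export
readTracks <- function(path, meta) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  TrackSet(d, meta)
}

#' Write a track table to CSV
#'
#' Deterministic output: columns in canonical order, rows sorted by
#' (`track_id`, `frame`), numbers serialized with 6 significant digits.
#'
#' @param ts a [TrackSet-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @seealso [readTracks()]
#' @export
writeTracks <- function(ts, path) {
  stopifnot(is(ts, "TrackSet"))
  d <- ts@data
  for (col in c("t", "x", "y", "intensity", "sigma"))
    d[[col]] <- signif(d[[col]], 6)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an image stack as a multi-page 16-bit TIFF
#'
#' @param stack 3D numeric array (rows, columns, frames) of nonnegative
#'   counts, or a single matrix.
#' @param path output path.
#' @param maxCount full-scale count mapped to the 16-bit maximum; defaults
#'   to 65535 so integer counts round-trip exactly.
#' @return `path`, invisibly.
#' @export
writeStack <- function(stack, path, maxCount = 65535) {
  if (is.matrix(stack)) stack <- array(stack, c(dim(stack), 1))
  stopifnot(length(dim(stack)) == 3, all(stack >= 0))
  pages <- lapply(seq_len(dim(stack)[3]),
                  function(k) pmin(stack[, , k] / maxCount, 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}

#' Read a multi-page TIFF into a 3D array of counts
#'
#' @param path path to a TIFF file.
#' @param maxCount full-scale count corresponding to the 16-bit maximum.
#' @return 3D numeric array (rows, columns, frames).
#' @export
readStack <- function(path, maxCount = 65535) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  arr <- array(0, c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- round(pages[[k]] * maxCount)
  arr
}

#' Write an analysis report as JSON
#'
#' @param report a named list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeReport <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
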