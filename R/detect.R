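#' @include AllClasses.R trackio.R
NULL

#' Spot-detection parameters
#'
#' @param bandpassLow sigma (px) of the small Gaussian in the
#'   difference-of-Gaussians bandpass.
#' @param bandpassHigh sigma (px) of the large Gaussian; must exceed
#'   `bandpassLow`.
#' @param threshold absolute intensity threshold on the bandpassed image.
#'   See [estimateNoiseSigma()] for a noise-relative helper.
#' @param minSeparation minimum distance between accepted maxima, px.
#' @param fitWindow side of the square window for the subpixel Gaussian
#'   fit, px; odd and >= 5.
#' @return a validated list of class `DetectionParams`.
#' @export
DetectionParams <- function(bandpassLow = 1, bandpassHigh = 4, threshold,
                            minSeparation = 4, fitWindow = 7) {
  if (bandpassLow >= bandpassHigh)
    stop("bandpassLow must be < bandpassHigh")
  if (fitWindow < 5 || fitWindow %% 2 != 1)
    stop("fitWindow must be odd and >= 5")
  structure(list(bandpassLow = bandpassLow, bandpassHigh = bandpassHigh,
                 threshold = threshold, minSeparation = minSeparation,
                 fitWindow = fitWindow),
            class = "DetectionParams")
}

#' Track-linking parameters
#'
#' @param maxDisp maximum displacement per frame interval, um; candidate
#'   links longer than this are rejected.
#' @param memory gap-closing memory in frames. The default 0 disables gap
#'   closing: closing gaps inflates apparent dwell times and biases the
#'   survival analysis downstream, so enable it knowingly.
#' @return a validated list of class `LinkParams`.
#' @export
LinkParams <- function(maxDisp, memory = 0L) {
  if (maxDisp <= 0) stop("maxDisp must be > 0")
  if (memory < 0) stop("memory must be >= 0")
  structure(list(maxDisp = maxDisp, memory = as.integer(memory)),
            class = "LinkParams")
}

.bandpass <- function(img, low, high) {
  EBImage::gblur(img, sigma = low) - EBImage::gblur(img, sigma = high)
}

#' Estimate the noise level of a bandpassed frame
#'
#' Robust sigma (median absolute deviation, scaled) of the
#' difference-of-Gaussians image, for setting a noise-relative detection
#' threshold such as `5 * estimateNoiseSigma(frame)`.
#'
#' @param frame image matrix (one frame).
#' @param bandpassLow,bandpassHigh DoG sigmas, px.
#' @return numeric scalar.
#' @export
estimateNoiseSigma <- function(frame, bandpassLow = 1, bandpassHigh = 4) {
  stats::mad(.bandpass(frame, bandpassLow, bandpassHigh))
}

# symmetric 2D Gaussian + offset least-squares fit in a window;
# returns NULL on divergence
.fitGaussian2D <- function(win, cx0, cy0) {
  cx0 <- unname(cx0); cy0 <- unname(cy0)
  nr <- nrow(win); nc <- ncol(win)
  xv <- rep(seq_len(nc), each = nr)
  yv <- rep(seq_len(nr), nc)
  z <- as.vector(win)
  b0 <- stats::median(z)
  a0 <- max(z) - b0
  if (a0 <= 0) return(NULL)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      z ~ A * exp(-((xv - x0)^2 + (yv - y0)^2) / (2 * s^2)) + b,
      start = list(A = a0, x0 = cx0, y0 = cy0, s = 1.5, b = b0),
      lower = c(A = 0, x0 = 1, y0 = 1, s = 0.3, b = -Inf),
      upper = c(A = Inf, x0 = nc, y0 = nr, s = max(nr, nc), b = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  cf <- stats::coef(fit)
  if (!all(is.finite(cf))) return(NULL)
  cf
}

#' Detect and localize spots in an image stack
#'
#' Per frame: a difference-of-Gaussians bandpass highlights spots above the
#' background, local maxima above `threshold` are kept with a minimum
#' separation, and each candidate is refined by least-squares fitting of a
#' symmetric 2D Gaussian with constant offset in a small window, giving
#' subpixel positions (converted to um) and integrated intensities.
#' Candidates whose fit diverges are discarded and counted in the
#' `discarded` attribute.
#'
#' @param stack 3D array (rows, cols, frames) or a single matrix.
#' @param params a [DetectionParams()] list.
#' @param meta an [AcquisitionMetadata-class] (pixel size).
#' @return data.frame with columns `frame` (0-based), `x`, `y` (um, origin
#'   at the image center), `intensity` (integrated counts above offset);
#'   attribute `discarded` counts divergent fits. Blank frames contribute
#'   no rows.
#' @seealso [linkTracks()], [simulateMovie()]
#' @export
detectSpots <- function(stack, params, meta) {
  stopifnot(inherits(params, "DetectionParams"),
            is(meta, "AcquisitionMetadata"))
  if (is.matrix(stack)) stack <- array(stack, c(dim(stack), 1))
  nr <- dim(stack)[1]; nc <- dim(stack)[2]; nF <- dim(stack)[3]
  ps <- meta@pixelSize
  ox <- -nc * ps / 2; oy <- -nr * ps / 2
  half <- (params$fitWindow - 1) / 2
  out <- vector("list", nF)
  discarded <- 0L
  for (f in seq_len(nF)) {
    img <- stack[, , f]
    bp <- .bandpass(img, params$bandpassLow, params$bandpassHigh)
    # 8-neighborhood local maxima above threshold (image interior only)
    cand <- which(bp > params$threshold, arr.ind = TRUE)
    cand <- cand[cand[, 1] > 1 & cand[, 1] < nr &
                 cand[, 2] > 1 & cand[, 2] < nc, , drop = FALSE]
    if (!nrow(cand)) next
    isMax <- vapply(seq_len(nrow(cand)), function(i) {
      r <- cand[i, 1]; c <- cand[i, 2]
      bp[r, c] >= max(bp[(r - 1):(r + 1), (c - 1):(c + 1)])
    }, logical(1))
    cand <- cand[isMax, , drop = FALSE]
    if (!nrow(cand)) next
    # enforce min separation, brightest first
    o <- order(bp[cand], decreasing = TRUE)
    cand <- cand[o, , drop = FALSE]
    keep <- rep(TRUE, nrow(cand))
    for (i in seq_len(nrow(cand))) {
      if (!keep[i]) next
      if (i < nrow(cand)) {
        j <- (i + 1):nrow(cand)
        d2 <- (cand[j, 1] - cand[i, 1])^2 + (cand[j, 2] - cand[i, 2])^2
        keep[j][d2 < params$minSeparation^2] <- FALSE
      }
    }
    cand <- cand[keep, , drop = FALSE]
    rows <- lapply(seq_len(nrow(cand)), function(i) {
      r <- cand[i, 1]; c <- cand[i, 2]
      r0 <- max(1, r - half); r1 <- min(nr, r + half)
      c0 <- max(1, c - half); c1 <- min(nc, c + half)
      cf <- .fitGaussian2D(img[r0:r1, c0:c1], c - c0 + 1, r - r0 + 1)
      if (is.null(cf)) return(NULL)
      data.frame(frame = f - 1L,
                 x = ox + (c0 - 1 + cf[["x0"]] - 0.5) * ps,
                 y = oy + (r0 - 1 + cf[["y0"]] - 0.5) * ps,
                 intensity = 2 * pi * cf[["A"]] * cf[["s"]]^2)
    })
    bad <- vapply(rows, is.null, logical(1))
    discarded <- discarded + sum(bad)
    if (any(!bad)) out[[f]] <- do.call(rbind, rows[!bad])
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res))
    res <- data.frame(frame = integer(), x = numeric(), y = numeric(),
                      intensity = numeric())
  attr(res, "discarded") <- discarded
  res
}

#' Link detections into tracks by greedy nearest-neighbor assignment
#'
#' Between consecutive frames, all candidate (track, detection) pairs
#' within the distance cutoff are sorted by distance (ties broken by track
#' then detection index) and assigned greedily, so linking is fully
#' deterministic. Unmatched detections start new tracks; tracks unmatched
#' for more than `memory` frames are terminated. With `memory > 0` the
#' cutoff for a gap of g frames is `maxDisp * g`.
#'
#' @param detections data.frame with columns `frame`, `x`, `y` and
#'   optionally `intensity` (as from [detectSpots()]).
#' @param params a [LinkParams()] list.
#' @param meta an [AcquisitionMetadata-class].
#' @return a [TrackSet-class]; empty input yields an empty TrackSet.
#' @export
linkTracks <- function(detections, params, meta) {
  stopifnot(inherits(params, "LinkParams"), is(meta, "AcquisitionMetadata"))
  if (!"intensity" %in% names(detections))
    detections$intensity <- rep(NA_real_, nrow(detections))
  empty <- data.frame(track_id = integer(), frame = integer(),
                      x = numeric(), y = numeric(), intensity = numeric())
  if (!nrow(detections)) return(TrackSet(empty, meta))
  detections <- detections[order(detections$frame), , drop = FALSE]
  frames <- sort(unique(detections$frame))
  nextId <- 1L
  active <- data.frame(id = integer(), lastFrame = integer(),
                       x = numeric(), y = numeric())
  rows <- vector("list", length(frames))
  for (fi in seq_along(frames)) {
    f <- frames[fi]
    det <- detections[detections$frame == f, , drop = FALSE]
    assigned <- rep(NA_integer_, nrow(det))
    if (nrow(active)) {
      gap <- f - active$lastFrame
      elig <- which(gap >= 1 & gap <= params$memory + 1L)
      if (length(elig)) {
        pairs <- expand.grid(ti = elig, di = seq_len(nrow(det)))
        pairs$dist <- sqrt((active$x[pairs$ti] - det$x[pairs$di])^2 +
                           (active$y[pairs$ti] - det$y[pairs$di])^2)
        pairs$cut <- params$maxDisp * gap[match(pairs$ti, seq_len(nrow(active)))]
        pairs <- pairs[pairs$dist <= pairs$cut, , drop = FALSE]
        pairs <- pairs[order(pairs$dist, pairs$ti, pairs$di), , drop = FALSE]
        usedT <- logical(nrow(active)); usedD <- logical(nrow(det))
        for (r in seq_len(nrow(pairs))) {
          ti <- pairs$ti[r]; di <- pairs$di[r]
          if (usedT[ti] || usedD[di]) next
          usedT[ti] <- TRUE; usedD[di] <- TRUE
          assigned[di] <- active$id[ti]
          active$lastFrame[ti] <- f
          active$x[ti] <- det$x[di]; active$y[ti] <- det$y[di]
        }
      }
    }
    newIdx <- which(is.na(assigned))
    if (length(newIdx)) {
      ids <- nextId + seq_along(newIdx) - 1L
      nextId <- nextId + length(newIdx)
      assigned[newIdx] <- ids
      active <- rbind(active,
                      data.frame(id = ids, lastFrame = f,
                                 x = det$x[newIdx], y = det$y[newIdx]))
    }
    active <- active[f - active$lastFrame <= params$memory, , drop = FALSE]
    rows[[fi]] <- data.frame(track_id = assigned, frame = det$frame,
                             x = det$x, y = det$y,
                             intensity = det$intensity)
  }
  TrackSet(do.call(rbind, rows), meta)
}

#' Render a kymograph by maximum-intensity projection
#'
#' For each frame, the stack is projected along the chosen spatial axis by
#' maximum intensity; the retained axis forms the rows and time the
#' columns of the output.
#'
#' @param stack 3D array (rows, cols, frames).
#' @param axis `"y"` to project along rows (retain x) or `"x"` to project
#'   along columns (retain y).
#' @return matrix (retained axis x frames).
#' @export
renderKymograph <- function(stack, axis = c("y", "x")) {
  axis <- match.arg(axis)
  if (is.matrix(stack)) stack <- array(stack, c(dim(stack), 1))
  nF <- dim(stack)[3]
  proj <- if (axis == "y") {
    vapply(seq_len(nF), function(f) apply(stack[, , f], 2, max),
           numeric(dim(stack)[2]))
  } else {
    vapply(seq_len(nF), function(f) apply(stack[, , f], 1, max),
           numeric(dim(stack)[1]))
  }
  matrix(proj, ncol = nF)
}
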