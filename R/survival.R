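#' @include AllClasses.R trackio.R
NULL

#' Classify bound segments within tracks
#'
#' A molecule is called bound over a maximal run of at least `nMin`
#' consecutive frames whose localizations all lie within `rMax` of the
#' run's centroid. Runs are grown greedily from the left: the run is
#' extended while every member stays within `rMax` of the updated centroid.
#' The paper's workflow presumes a bound/diffusing call without defining
#' one; the defaults (rMax = 0.22 um, about two pixels at 0.11 um/px, and
#' nMin = 3 frames) follow common SMT practice and should be reported with
#' any result (both are recorded in downstream provenance).
#'
#' @param ts a [TrackSet-class].
#' @param rMax maximum distance from the run centroid, um.
#' @param nMin minimum run length, frames.
#' @return data.frame with columns `track_id`, `start_frame`, `end_frame`,
#'   `dwell` (s, `(length - 1) * frame interval`) and `censored` (TRUE for
#'   runs reaching the last movie frame).
#' @seealso [buildSurvival()]
#' @export
classifyBound <- function(ts, rMax = 0.22, nMin = 3L) {
  stopifnot(is(ts, "TrackSet"))
  if (!is.finite(rMax) || rMax <= 0) stop("rMax must be > 0")
  dt <- frameInterval(ts)
  lastFrame <- acqMeta(ts)@nFrames - 1L
  d <- tracks(ts)
  segs <- list()
  for (tr in split(d, d$track_id, drop = TRUE)) {
    n <- nrow(tr)
    i <- 1L
    while (i <= n - nMin + 1L) {
      j <- i
      while (j + 1L <= n && tr$frame[j + 1L] == tr$frame[j] + 1L) {
        cand <- i:(j + 1L)
        cx <- mean(tr$x[cand]); cy <- mean(tr$y[cand])
        if (all((tr$x[cand] - cx)^2 + (tr$y[cand] - cy)^2 <= rMax^2))
          j <- j + 1L
        else break
      }
      len <- j - i + 1L
      if (len >= nMin) {
        segs[[length(segs) + 1L]] <- data.frame(
          track_id = tr$track_id[1], start_frame = tr$frame[i],
          end_frame = tr$frame[j], dwell = (len - 1L) * dt,
          censored = tr$frame[j] >= lastFrame)
        i <- j + 1L
      } else {
        i <- i + 1L
      }
    }
  }
  if (!length(segs))
    return(data.frame(track_id = integer(), start_frame = integer(),
                      end_frame = integer(), dwell = numeric(),
                      censored = logical()))
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  out
}

#' Build the bound-molecule survival distribution
#'
#' The raw survival is the fraction of bound segments whose dwell is at
#' least t, on a grid of multiples of the frame interval. The curve is then
#' normalized to the bound fraction C_eq, computed as total bound
#' detections (frames spent bound, summed over segments) over all
#' detections in all movie frames, so that the first grid point equals
#' C_eq. Censored segments (runs reaching the movie end) are counted up to
#' their observed dwell.
#'
#' @param segments data.frame from [classifyBound()] (columns `track_id`,
#'   `start_frame`, `end_frame`, `dwell`).
#' @param ts the [TrackSet-class] the segments came from (supplies the
#'   frame interval and the total detection count).
#' @param normalization `"bound_fraction"` (default) scales the first grid
#'   point to C_eq; `"raw"` leaves the counting fractions.
#' @return a [SurvivalCurve-class].
#' @seealso [correctPhotobleaching()], [fitDwellModels()]
#' @export
buildSurvival <- function(segments, ts,
                          normalization = c("bound_fraction", "raw")) {
  normalization <- match.arg(normalization)
  stopifnot(is(ts, "TrackSet"))
  if (!nrow(segments)) stop("no bound segments: nothing to build")
  dt <- frameInterval(ts)
  n0 <- nrow(segments)
  boundDetections <- sum(segments$end_frame - segments$start_frame + 1)
  Ceq <- min(1, boundDetections / nrow(tracks(ts)))
  K <- max(1L, round(max(segments$dwell) / dt))
  times <- seq_len(K) * dt
  counts <- vapply(times, function(t0) sum(segments$dwell >= t0 - 1e-9),
                   numeric(1))
  Sraw <- counts / n0
  S <- if (normalization == "bound_fraction") Ceq * Sraw / Sraw[1] else Sraw
  new("SurvivalCurve", times = times, S = S, counts = counts,
      n0 = as.integer(n0), normalization = normalization,
      correction = "none", Ceq = Ceq, dt = dt,
      provenance = list())
}

#' Build a survival curve directly from dwell-time samples
#'
#' Convenience constructor for simulation studies and model-selection
#' benchmarks: counts how many dwells are at least t on a grid of
#' multiples of `dt` and scales the first point to `Ceq`.
#'
#' @param dwells numeric vector of dwell times (s), all > 0.
#' @param dt frame interval (s).
#' @param Ceq bound fraction to normalize to.
#' @param maxTime truncate the grid here (default: the longest dwell).
#' @param minCount drop trailing grid points supported by fewer than this
#'   many dwells (tail counts of 1-2 carry almost no information on the
#'   log scale).
#' @return a [SurvivalCurve-class] with `normalization = "bound_fraction"`.
#' @export
survivalFromDwells <- function(dwells, dt, Ceq = 1,
                               maxTime = max(dwells), minCount = 5) {
  stopifnot(length(dwells) >= 1, all(dwells > 0), dt > 0)
  K <- max(1L, floor(maxTime / dt + 1e-9))
  times <- seq_len(K) * dt
  counts <- vapply(times, function(t0) sum(dwells >= t0 - 1e-9), numeric(1))
  keep <- counts >= max(1, minCount)
  times <- times[keep]; counts <- counts[keep]
  S <- Ceq * counts / counts[1]
  new("SurvivalCurve", times = times, S = S, counts = counts,
      n0 = length(dwells), normalization = "bound_fraction",
      correction = "none", Ceq = Ceq, dt = dt, provenance = list())
}

#' Per-frame detection counts of a TrackSet
#'
#' Number of localizations in each movie frame; the input for the
#' intrinsic photobleaching correction.
#'
#' @param ts a [TrackSet-class].
#' @return integer vector of length `nFrames` (frames 0-based).
#' @export
detectionCounts <- function(ts) {
  stopifnot(is(ts, "TrackSet"))
  nF <- acqMeta(ts)@nFrames
  tabulate(tracks(ts)$frame + 1L, nbins = nF)
}

#' Correct a survival curve for photobleaching
#'
#' Three alternative corrections, whose outcomes can differ strongly:
#'
#' * `intrinsic` — a single exponential is fitted to the target's own
#'   per-frame detection counts versus cumulative exposure count, and the
#'   survival is divided by that decay. Tends to underestimate bleaching
#'   for stably bound proteins.
#' * `whole_reference` — the survival is divided pointwise by the
#'   normalized survival of a stable reference protein (e.g. histone H3).
#'   Applied to the reference itself this yields a perfectly flat curve,
#'   and it tends to overestimate bleaching (it erases genuinely mobile
#'   sub-fractions of the reference).
#' * `immobile_fraction` — the reference survival is fitted with a
#'   tri-exponential; the slowest component, normalized to 1 at t = 0, is
#'   taken as the bleaching curve and divided out. A compromise that keeps
#'   a stable plateau while preserving unstable components.
#'
#' The bleaching time base is cumulative exposure count, not wall time, so
#' time-lapse dark intervals are handled correctly. After division the
#' curve is rescaled so its first point does not exceed C_eq.
#'
#' @param curve a [SurvivalCurve-class] to correct.
#' @param method one of `"intrinsic"`, `"whole_reference"`,
#'   `"immobile_fraction"`.
#' @param reference for `intrinsic`, a numeric vector of per-frame
#'   detection counts (see [detectionCounts()]); for the other two methods
#'   a reference [SurvivalCurve-class] whose grid extends at least as far
#'   as the target's.
#' @return a corrected [SurvivalCurve-class] with provenance recorded.
#' @export
correctPhotobleaching <- function(curve,
                                  method = c("intrinsic", "whole_reference",
                                             "immobile_fraction"),
                                  reference) {
  method <- match.arg(method)
  stopifnot(is(curve, "SurvivalCurve"))
  prov <- curve@provenance
  t <- curve@times
  if (method == "intrinsic") {
    if (missing(reference) || !is.numeric(reference))
      stop("intrinsic correction needs per-frame detection counts")
    f <- seq_along(reference) - 1  # cumulative exposure count per frame
    ok <- reference > 0
    if (sum(ok) < 3) stop("too few frames with detections to fit decay")
    # counts are Poisson-ish, so weight the log-linear fit by counts
    fit <- stats::lm(log(reference[ok]) ~ f[ok], weights = reference[ok])
    kb <- max(0, -stats::coef(fit)[2])  # decay per exposure
    B <- exp(-kb * (t / curve@dt))
    prov$bleach_per_exposure <- kb
  } else {
    if (missing(reference) || !is(reference, "SurvivalCurve"))
      stop(method, " correction needs a reference SurvivalCurve")
    if (max(reference@times) < max(t) - 1e-9)
      stop("reference grid is shorter than the target grid")
    if (method == "whole_reference") {
      Sref <- stats::approx(reference@times, reference@S, xout = t)$y
      B <- Sref / Sref[1]
    } else {
      # tail points carried by <5 surviving segments are noise-dominated
      # on the log scale and destabilize the tri-exponential fit
      solid <- reference@counts >= min(5, max(reference@counts))
      triexp <- .fitExpComponents(reference@times[solid],
                                  reference@S[solid],
                                  k = 3, w = reference@counts[solid])
      # components are weighed by their contribution at the first observed
      # time (an amplitude at t = 0 is meaningless for a spike component
      # with tau below the frame interval); components carrying < 5% are
      # treated as spurious for the bleaching estimate (tri-exp fits of a
      # near-single-exponential reference are degenerate and sprout stray
      # components)
      cw <- triexp$A * exp(-reference@times[1] / triexp$tau)
      cw <- cw / sum(cw)
      usable <- which(cw >= 0.05)
      tauSorted <- sort(triexp$tau[usable], decreasing = TRUE)
      tauSlow <- tauSorted[1]
      if (length(tauSorted) > 1 && tauSlow < 2 * tauSorted[2])
        prov$warning <- sprintf(
          "slowest reference tau (%.3g s) not separated from next (%.3g s)",
          tauSlow, tauSorted[2])
      prov$reference_taus <- triexp$tau
      prov$reference_fractions <- cw
      prov$tau_bleach <- tauSlow
      B <- exp(-t / tauSlow)
    }
  }
  S <- curve@S / B
  if (S[1] > curve@Ceq && S[1] > 0) S <- S * (curve@Ceq / S[1])
  prov$correction_method <- method
  new("SurvivalCurve", times = t, S = S, counts = curve@counts,
      n0 = curve@n0, normalization = curve@normalization,
      correction = method, Ceq = curve@Ceq, dt = curve@dt,
      provenance = prov)
}
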