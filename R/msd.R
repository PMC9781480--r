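#' @include AllClasses.R trackio.R
NULL

# per-track sums of squared displacements at frame lags 1..maxLag;
# overlapping windows, tolerant of frame gaps
.msdSums <- function(frame, x, y, maxLag) {
  ss <- numeric(maxLag)
  cnt <- numeric(maxLag)
  for (L in seq_len(maxLag)) {
    j <- match(frame + L, frame)
    ok <- !is.na(j)
    if (!any(ok)) next
    dx <- x[j[ok]] - x[ok]
    dy <- y[j[ok]] - y[ok]
    ss[L] <- sum(dx^2 + dy^2)
    cnt[L] <- sum(ok)
  }
  list(ss = ss, cnt = cnt)
}

#' Compute the mean squared displacement
#'
#' Time-averaged MSD over overlapping windows, per track, with the
#' ensemble curve formed as the count-weighted average over tracks (2D:
#' squared x plus squared y displacement). Lags run up to
#' `min(maxLag, track length - 1)` frames.
#'
#' @param x a [TrackSet-class] (ensemble MSD; a single-track set yields
#'   `source = "single_track"`).
#' @param maxLag maximum lag, frames (>= 1).
#' @return an [MSDCurve-class].
#' @seealso [fitDiffusion()], [fitAlphaRc()], [trackDiffusion()]
#' @export
computeMSD <- function(x, maxLag = 20) {
  stopifnot(is(x, "TrackSet"))
  if (maxLag < 1) stop("maxLag must be >= 1")
  d <- tracks(x)
  if (!nrow(d)) stop("empty TrackSet")
  dt <- frameInterval(x)
  ss <- numeric(maxLag); cnt <- numeric(maxLag)
  for (tr in split(d, d$track_id, drop = TRUE)) {
    if (nrow(tr) < 2) next
    part <- .msdSums(tr$frame, tr$x, tr$y, maxLag)
    ss <- ss + part$ss
    cnt <- cnt + part$cnt
  }
  keep <- cnt >= 1
  if (!any(keep)) stop("no displacement pairs at any lag")
  new("MSDCurve", lags = (seq_len(maxLag) * dt)[keep],
      msd = (ss / pmax(cnt, 1))[keep], counts = cnt[keep],
      source = if (nTracks(x) == 1) "single_track" else "ensemble")
}

#' Fit the apparent diffusion coefficient from the initial MSD slope
#'
#' Weighted linear fit `msd = 4 D tau + b` (2D convention) over the first
#' `nPoints` lags; the intercept absorbs the localization error
#' (`b ~ 4 sigma^2`). D is floored at 1e-4 um^2/s; a negative fitted
#' slope returns the floor with a flag.
#'
#' @param msd an [MSDCurve-class] with at least `nPoints` lags.
#' @param nPoints number of initial lags to fit (>= 2).
#' @return list with `D` (um^2/s), `offset` (um^2), `flagged` (logical,
#'   TRUE when the slope was non-positive and D was floored).
#' @export
fitDiffusion <- function(msd, nPoints = 4) {
  stopifnot(is(msd, "MSDCurve"))
  if (nPoints < 2) stop("nPoints must be >= 2")
  n <- min(nPoints, length(msd@lags))
  if (n < 2) stop("need at least 2 lags")
  i <- seq_len(n)
  fit <- stats::lm(msd@msd[i] ~ msd@lags[i], weights = msd@counts[i])
  slope <- unname(stats::coef(fit)[2])
  b <- unname(stats::coef(fit)[1])
  flagged <- slope <= 0
  D <- max(slope / 4, 1e-4)
  list(D = D, offset = b, flagged = flagged)
}

#' Fit the anomalous exponent and confinement radius of an MSD curve
#'
#' The anomalous exponent alpha is the slope of log msd versus log tau
#' over a configurable lag range (default lags 2-10, avoiding the
#' noise-dominated first lag and the plateau). The confined-motion model
#' `MSD(t) = R_c^2 (1 - exp(-4 D t / R_c^2))` is fitted by least squares
#' over all lags for the confinement radius R_c and diffusion coefficient.
#' Motion is classified from alpha with a dead band:
#' alpha in \[0.9, 1.1\] is Brownian, above super-diffusive, below
#' sub-diffusive. A non-convergent confinement fit reports `Rc = Inf`
#' with the flag `"rc_unbounded"`.
#'
#' @param msd an [MSDCurve-class] with at least 8 lags.
#' @param alphaLags integer range `c(first, last)` of lag indices for the
#'   log-log slope.
#' @return a [ConfinementFit-class].
#' @export
fitAlphaRc <- function(msd, alphaLags = c(2, 10)) {
  stopifnot(is(msd, "MSDCurve"))
  nl <- length(msd@lags)
  if (nl < 8) stop("need at least 8 lags, got ", nl)
  idx <- max(1, alphaLags[1]):min(nl, alphaLags[2])
  pos <- msd@msd[idx] > 0
  if (sum(pos) < 2) {
    alpha <- 0  # immobile: no measurable growth
  } else {
    af <- stats::lm(log(msd@msd[idx][pos]) ~ log(msd@lags[idx][pos]))
    alpha <- unname(stats::coef(af)[2])
  }
  rcFit <- tryCatch({
    fit <- minpack.lm::nlsLM(
      m ~ rc2 * (1 - exp(-4 * D * tau / rc2)),
      data = list(m = msd@msd, tau = msd@lags),
      start = list(rc2 = max(msd@msd) * 1.05,
                   D = max(msd@msd[1] / (4 * msd@lags[1]), 1e-4)),
      lower = c(rc2 = 1e-8, D = 1e-8),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- stats::coef(fit)
    list(Rc = sqrt(cf[["rc2"]]), D = cf[["D"]], flags = character())
  }, error = function(e) list(Rc = Inf, D = NA_real_,
                              flags = "rc_unbounded"))
  cls <- if (alpha > 1.1) "super_diffusive"
         else if (alpha < 0.9) "sub_diffusive" else "brownian"
  new("ConfinementFit", D = rcFit$D, Rc = rcFit$Rc, alpha = alpha,
      motionClass = cls, flags = rcFit$flags)
}

#' Population-average confinement radius
#'
#' Fraction-weighted average of sub-population confinement radii, used to
#' reconcile a whole-population R_c with previously reported bound and
#' unbound sub-population values.
#'
#' @param fractions numeric, nonnegative sub-population fractions summing
#'   to 1.
#' @param rcs numeric, confinement radii (um), same length.
#' @return numeric, the weighted radius (um).
#' @examples
#' populationRc(c(0.5, 0.5), c(0.13, 0.5))  # 0.315
#' @export
populationRc <- function(fractions, rcs) {
  if (length(fractions) != length(rcs))
    stop("fractions and rcs must have the same length")
  if (any(fractions < 0)) stop("fractions must be >= 0")
  if (abs(sum(fractions) - 1) > 1e-6)
    stop("fractions must sum to 1 (got ", sum(fractions), ")")
  sum(fractions * rcs)
}

#' Spherical sampling volume of a confinement radius
#'
#' @param rc confinement radius, um (>= 0).
#' @return volume `(4/3) pi rc^3`, um^3.
#' @examples
#' samplingVolume(0.3)  # ~0.113 um^3
#' samplingVolume(1.0)  # ~4.19 um^3, a diploid yeast nucleus
#' @export
samplingVolume <- function(rc) {
  if (any(rc < 0)) stop("rc must be >= 0")
  (4 / 3) * pi * rc^3
}

#' Time for a translocating complex to move one localization precision
#'
#' How long a processive enzyme (replisome, elongating polymerase) must
#' translocate along a straight DNA template before its progress exceeds
#' the localization precision and becomes detectable.
#'
#' @param speedKbpMin translocation speed, kbp/min.
#' @param precisionNm localization precision, nm.
#' @param risePerBpNm axial rise per base pair, nm (B-DNA: 0.34).
#' @return time in seconds: `precision / (speed * 1000/60 * rise)`.
#' @examples
#' translocationDetectTime(1.6, 30)  # ~3.3 s for a replisome
#' @export
translocationDetectTime <- function(speedKbpMin, precisionNm,
                                    risePerBpNm = 0.34) {
  if (any(c(speedKbpMin, precisionNm, risePerBpNm) <= 0))
    stop("all inputs must be > 0")
  precisionNm / (speedKbpMin * 1000 / 60 * risePerBpNm)
}

#' Per-track apparent diffusion coefficients
#'
#' Convenience wrapper: computes the MSD of every track with at least
#' `minLags + 1` localizations and fits the initial slope with
#' [fitDiffusion()].
#'
#' @param ts a [TrackSet-class].
#' @param nPoints initial lags for the linear fit.
#' @param minLags minimum number of lags a track must support.
#' @return named numeric vector of D (um^2/s), one per eligible track.
#' @export
trackDiffusion <- function(ts, nPoints = 4, minLags = 5) {
  stopifnot(is(ts, "TrackSet"))
  d <- tracks(ts)
  dt <- frameInterval(ts)
  out <- c()
  for (tr in split(d, d$track_id, drop = TRUE)) {
    if (nrow(tr) < minLags + 1) next
    part <- .msdSums(tr$frame, tr$x, tr$y, minLags)
    if (any(part$cnt < 1)) next
    curve <- new("MSDCurve", lags = seq_len(minLags) * dt,
                 msd = part$ss / part$cnt, counts = part$cnt,
                 source = "single_track")
    out[as.character(tr$track_id[1])] <- fitDiffusion(curve, nPoints)$D
  }
  out
}

# ---- log10-D Gaussian mixture --------------------------------------------

.em1d <- function(z, k, mu0, sd0, w0, maxIter = 500, tol = 1e-8) {
  n <- length(z)
  mu <- mu0; sd <- pmax(sd0, 1e-4); w <- w0 / sum(w0)
  ll <- -Inf
  for (it in seq_len(maxIter)) {
    dens <- vapply(seq_len(k),
                   function(j) w[j] * stats::dnorm(z, mu[j], sd[j]),
                   numeric(n))
    dens <- matrix(dens, n, k)
    rowsum_ <- rowSums(dens)
    rowsum_[rowsum_ < 1e-300] <- 1e-300
    llNew <- sum(log(rowsum_))
    resp <- dens / rowsum_
    nk <- colSums(resp)
    nk[nk < 1e-12] <- 1e-12
    w <- nk / n
    mu <- colSums(resp * z) / nk
    sd <- sqrt(colSums(resp * (z - rep(mu, each = n))^2) / nk)
    sd <- pmax(sd, 1e-4)
    if (is.finite(ll) && abs(llNew - ll) < tol) { ll <- llNew; break }
    ll <- llNew
  }
  list(mu = mu, sd = sd, w = w, logLik = ll)
}

#' Gaussian-mixture decomposition of log10 diffusion coefficients
#'
#' Fits 1- to `kMax`-component Gaussian mixtures to the distribution of
#' log10(D) by expectation-maximization (initialized by a quantile split,
#' 5 restarts with jittered means, fixed seed) and selects the number of
#' components by BIC, identifying the sub-fractions of bound, intermediate
#' and freely diffusing molecules. A candidate k requires at least
#' `10 * k` tracks; candidates with too few tracks are excluded from
#' selection.
#'
#' @param D numeric vector of per-track diffusion coefficients (um^2/s);
#'   see [trackDiffusion()]. Values are floored at 1e-4 before the log.
#' @param kMax maximum number of components (1-3 typical).
#' @param nRestarts EM restarts per k.
#' @param seed RNG seed for restart jitter.
#' @return a [DiffusionStates-class], components ordered slow to fast.
#' @export
fitLogDMixture <- function(D, kMax = 3, nRestarts = 5, seed = 0) {
  z <- log10(pmax(D, 1e-4))
  n <- length(z)
  if (n < 2) stop("need at least 2 diffusion coefficients")
  # k = 1 is always estimable; k >= 2 requires at least 10 tracks per
  # component
  ks <- unique(c(1L, seq_len(kMax)[10 * seq_len(kMax) <= n]))
  results <- list()
  bic <- c()
  for (k in ks) {
    qs <- stats::quantile(z, probs = (seq_len(k) - 0.5) / k, names = FALSE)
    grp <- cut(z, breaks = stats::quantile(z, probs = seq(0, 1, 1 / k)),
               include.lowest = TRUE, labels = FALSE)
    sd0 <- vapply(seq_len(k),
                  function(j) stats::sd(z[grp == j]), numeric(1))
    sd0[!is.finite(sd0) | sd0 < 1e-3] <- max(stats::sd(z) / k, 1e-3)
    best <- NULL
    starts <- .withSeed(seed, {
      c(list(qs),
        lapply(seq_len(max(0, nRestarts - 1)), function(i)
          qs + stats::rnorm(k, 0, stats::sd(z) / 2)))
    })
    for (mu0 in starts) {
      fit <- .em1d(z, k, sort(mu0), sd0, rep(1 / k, k))
      if (is.null(best) || fit$logLik > best$logLik) best <- fit
    }
    o <- order(best$mu)
    results[[as.character(k)]] <-
      list(mu = best$mu[o], sd = best$sd[o], w = best$w[o],
           logLik = best$logLik)
    bic[as.character(k)] <- (3 * k - 1) * log(n) - 2 * best$logLik
  }
  kBest <- as.integer(names(bic)[which.min(bic)])
  r <- results[[as.character(kBest)]]
  new("DiffusionStates", k = kBest, weights = unname(r$w),
      means = unname(r$mu), sds = unname(r$sd),
      BIC = unname(bic[as.character(kBest)]), bicTable = bic,
      logLik = r$logLik)
}
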