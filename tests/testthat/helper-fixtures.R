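# shared fixtures for the test suite; everything is generated in code

# metadata for a simple continuous acquisition
fixtureMeta <- function(nFrames = 10L, dt = 0.2, pixelSize = 0.1) {
  AcquisitionMetadata(pixelSize = pixelSize, exposure = dt,
                      darkInterval = 0, nFrames = nFrames)
}

# a TrackSet built from explicit coordinates
fixtureTrackSet <- function(df, meta = fixtureMeta(max(df$frame) + 1L)) {
  TrackSet(df, meta)
}

# random valid TrackSet for round-trip properties
randomTrackSet <- function(nTracks = 5, maxLen = 12, meta = fixtureMeta(50L)) {
  rows <- lapply(seq_len(nTracks), function(id) {
    len <- sample(2:maxLen, 1)
    start <- sample(0:(50L - maxLen - 1L), 1)
    data.frame(track_id = id, frame = start + seq_len(len) - 1L,
               x = cumsum(rnorm(len, 0, 0.1)),
               y = cumsum(rnorm(len, 0, 0.1)),
               intensity = runif(len, 100, 2000))
  })
  TrackSet(do.call(rbind, rows), meta)
}

# survival curve evaluated from a closed-form S(t) (synthetic, noiseless);
# C_eq defaults to the first grid value, as buildSurvival would produce
analyticCurve <- function(Sfun, dt = 0.25, tmax = 40, Ceq = NULL,
                          n0 = 1000L, correction = "none") {
  t <- seq(dt, tmax, by = dt)
  if (is.null(Ceq)) Ceq <- min(1, Sfun(t[1]))
  new("SurvivalCurve", times = t, S = Sfun(t), counts = rep(n0, length(t)),
      n0 = n0, normalization = "bound_fraction", correction = correction,
      Ceq = Ceq, dt = dt, provenance = list())
}

# dwell sampling for the model-selection benchmarks: 60/40 two-state
# exponential mixture, pure exponential, Pareto, or exponential+Pareto
sampleDwells <- function(family, n, dt = 0.25) {
  switch(family,
    exp_1 = rexp(n, 1 / 5),
    exp_2 = ifelse(runif(n) < 0.6, rexp(n, 1 / 2), rexp(n, 1 / 10)),
    power_law = dt * runif(n)^(-1 / 0.5),
    power_plus_exp = ifelse(runif(n) < 0.6, rexp(n, 1 / 1.5),
                            dt * runif(n)^(-1 / 0.5)),
    stop("unknown family"))
}

# the two-state bound-segment benchmark observed through per-exposure
# photobleaching and frame discretization (see the methods vignette);
# dt = 0.5 s is the time-lapse regime (0.2 s exposure + 0.3 s dark)
sampleBoundSegments <- function(n, tauNS = 2, tauS = 10, fNS = 0.6,
                                bleachProb = 0.02, dt = 0.5, nMin = 3) {
  nDraw <- ceiling(3 * n)
  state <- runif(nDraw) < fNS
  L <- rexp(nDraw, ifelse(state, 1 / tauNS, 1 / tauS))
  m <- floor(L / dt + runif(nDraw))        # frames spanned by the sojourn
  g <- rgeom(nDraw, bleachProb) + 1        # exposures until bleaching
  dwell <- (pmin(m, g) - 1) * dt
  dwell <- dwell[dwell >= (nMin - 1) * dt - 1e-9]
  stopifnot(length(dwell) >= n)
  dwell[seq_len(n)]
}

# matching immobile (bleaching-only) reference segments
sampleBleachSegments <- function(n, bleachProb = 0.02, dt = 0.5,
                                 nMin = 3) {
  g <- rgeom(n, bleachProb) + 1
  dwell <- (g - 1) * dt
  dwell[dwell >= (nMin - 1) * dt - 1e-9]
}

# one replicate of the two-state recovery study: returns
# c(tauNS, tauS, fNS) as recovered by the immobile-fraction-corrected
# bi-exponential fit
recoverTwoState <- function(seed, tauNS = 2, tauS = 10, nSegments = 3000,
                            nReference = 10000, bleachProb = 0.02,
                            dt = 0.5) {
  set.seed(seed)
  dw <- sampleBoundSegments(nSegments, tauNS = tauNS, tauS = tauS,
                            fNS = 0.6, bleachProb = bleachProb, dt = dt)
  curve <- survivalFromDwells(dw, dt, Ceq = 0.5, minCount = 50)
  ref <- survivalFromDwells(sampleBleachSegments(nReference, bleachProb, dt),
                            dt, Ceq = 1,
                            maxTime = max(survTimes(curve)) + dt,
                            minCount = 1)
  corr <- suppressWarnings(
    correctPhotobleaching(curve, "immobile_fraction", ref))
  fits <- suppressWarnings(
    fitDwellModels(corr, families = c("exp_1", "exp_2"), seed = 0))
  pw <- fitParams(fits@fits[["exp_2"]])
  o <- order(pw$tau)
  c(pw$tau[o], (pw$A / sum(pw$A))[o][1])
}
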