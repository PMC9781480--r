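test_that("a stationary track gives one bound segment with the right dwell", {
  meta <- fixtureMeta(nFrames = 20L, dt = 0.2)
  ts <- TrackSet(data.frame(track_id = 1, frame = 0:9, x = 0, y = 0), meta)
  segs <- classifyBound(ts, rMax = 0.2, nMin = 3)
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$dwell, 1.8)           # (10 - 1) x 0.2 s
  expect_false(segs$censored)             # movie continues to frame 19

  metaShort <- fixtureMeta(nFrames = 10L, dt = 0.2)
  ts2 <- TrackSet(data.frame(track_id = 1, frame = 0:9, x = 0, y = 0),
                  metaShort)
  expect_true(classifyBound(ts2, 0.2, 3)$censored)
  expect_error(classifyBound(ts, rMax = 0), "rMax")
})

test_that("fast Brownian tracks are rarely misclassified as bound", {
  p <- SimulationParams(nMolecules = 100,
                        states = list(MotionState("diffusing", D = 1)),
                        nucleusRadius = 2, frameExposure = 0.2,
                        nFrames = 30L, localizationSigma = 0, seed = 9)
  sim <- simulateTracks(p)
  segs <- classifyBound(sim$tracks, rMax = 0.2, nMin = 3)
  # independent Monte-Carlo oracle for the false-positive probability of
  # one window: three consecutive Brownian points within rMax of their
  # centroid (free diffusion, no boundary: conservative upper range)
  set.seed(10)
  sd1 <- sqrt(2 * 1 * 0.2)
  hits <- replicate(20000, {
    pts <- rbind(c(0, 0), matrix(rnorm(4, 0, sd1), 2, 2, byrow = TRUE))
    pts[2, ] <- pts[1, ] + pts[2, ]
    pts[3, ] <- pts[2, ] + pts[3, ]
    ctr <- colMeans(pts)
    all(sqrt(rowSums((pts - rep(ctr, each = 3))^2)) <= 0.2)
  })
  pWindow <- mean(hits)
  expect_lt(pWindow, 0.02)           # misclassification is rare per window
  nWindows <- sum(pmax(tabulate(factor(tracks(sim$tracks)$track_id)) - 2, 0))
  # classifier rate agrees with the oracle (greedy runs, so allow 2x)
  expect_lt(nrow(segs), 2 * pWindow * nWindows + 3 * sqrt(pWindow * nWindows))
  # and no spuriously long "binding" events appear
  expect_true(all(segs$end_frame - segs$start_frame + 1 <= 5))
})

test_that("alternating stationary and mobile stretches segment correctly", {
  meta <- fixtureMeta(nFrames = 30L, dt = 0.2)
  # 5 stationary, 5 mobile (1 um jumps), 5 stationary elsewhere
  d <- data.frame(track_id = 1, frame = 0:14,
                  x = c(rep(0, 5), seq(1, 5), rep(8, 5)),
                  y = 0)
  segs <- classifyBound(TrackSet(d, meta), rMax = 0.2, nMin = 3)
  expect_equal(nrow(segs), 2L)
  expect_equal(segs$start_frame, c(0L, 10L))
  expect_equal(segs$end_frame, c(4L, 14L))
})

test_that("survival counting matches the quoted normalization formula", {
  meta <- fixtureMeta(nFrames = 10L, dt = 1)
  # 8 detections total: one particle bound 4 frames + 4 diffuse detections
  d <- rbind(data.frame(track_id = 1, frame = 0:3, x = 0, y = 0),
             data.frame(track_id = 2, frame = 0:3,
                        x = c(0, 5, 10, 15), y = 0))
  ts <- TrackSet(d, meta)
  segs <- classifyBound(ts, rMax = 0.2, nMin = 3)
  curve <- buildSurvival(segs, ts)
  expect_equal(boundFraction(curve), 0.5)  # 4 bound / 8 detections

  # raw counting: segments with dwells 1, 2, 3 frame-intervals
  segs <- data.frame(track_id = 1:3, start_frame = 0,
                     end_frame = c(1, 2, 3), dwell = c(1, 2, 3),
                     censored = FALSE)
  raw <- buildSurvival(segs, ts, normalization = "raw")
  expect_equal(survProb(raw), c(1, 2 / 3, 1 / 3))
  expect_equal(survTimes(raw), c(1, 2, 3))

  # everything bound for the whole movie: C_eq = 1 and flat S
  dAll <- data.frame(track_id = rep(1:2, each = 10), frame = rep(0:9, 2),
                     x = 0, y = 0)
  tsAll <- TrackSet(dAll, meta)
  curveAll <- buildSurvival(classifyBound(tsAll, 0.2, 3), tsAll)
  expect_equal(boundFraction(curveAll), 1)
  expect_true(all(abs(survProb(curveAll) - 1) < 1e-12))

  expect_error(buildSurvival(segs[0, ], ts), "no bound segments")
})

test_that("survival counts equal a naive quadratic recount", {
  set.seed(33)
  meta <- fixtureMeta(nFrames = 100L, dt = 0.5)
  ts <- TrackSet(data.frame(track_id = 1, frame = 0:9, x = 0, y = 0), meta)
  for (rep in 1:20) {
    n <- sample(5:60, 1)
    segs <- data.frame(track_id = seq_len(n), start_frame = 0,
                       end_frame = 1, dwell = 0.5 * sample(1:40, n, TRUE),
                       censored = FALSE)
    curve <- buildSurvival(segs, ts, normalization = "raw")
    # independent O(n^2) oracle
    oracle <- vapply(survTimes(curve), function(t0) {
      hits <- 0
      for (i in seq_len(n)) if (segs$dwell[i] >= t0 - 1e-9) hits <- hits + 1
      hits / n
    }, numeric(1))
    expect_equal(survProb(curve), oracle)
  }
})

test_that("whole-reference correction of the reference against itself is flat", {
  ref <- analyticCurve(function(t) 0.8 * exp(-t / 4))
  corr <- correctPhotobleaching(ref, "whole_reference", ref)
  expect_lt(max(abs(survProb(corr) - boundFraction(ref))), 1e-9)
  expect_equal(corr@correction, "whole_reference")
})

test_that("immobile-fraction correction divides out the slowest reference component", {
  ref <- analyticCurve(function(t) 0.5 * exp(-t / 1) + 0.5 * exp(-t / 20),
                       dt = 0.5, tmax = 60, n0 = 5000L)
  target <- analyticCurve(function(t) exp(-t / 20), dt = 0.5, tmax = 60,
                          n0 = 5000L)
  corr <- correctPhotobleaching(target, "immobile_fraction", ref)
  expect_lt(max(abs(survProb(corr) - survProb(corr)[1])), 1e-6)
  expect_equal(corr@provenance$tau_bleach, 20, tolerance = 1e-4)
})

test_that("a separation warning is recorded when reference components are close", {
  ref <- analyticCurve(function(t) 0.5 * exp(-t / 6) + 0.5 * exp(-t / 10),
                       dt = 0.5, tmax = 60, n0 = 5000L)
  target <- analyticCurve(function(t) exp(-t / 10), dt = 0.5, tmax = 60,
                          n0 = 5000L)
  corr <- correctPhotobleaching(target, "immobile_fraction", ref)
  expect_match(corr@provenance$warning, "not separated")
})

test_that("intrinsic correction flattens a bleaching-only survival", {
  p <- SimulationParams(nMolecules = 10000,
                        states = list(MotionState("bound_specific", D = 0)),
                        nFrames = 120L, localizationSigma = 0.01,
                        bleachProbPerExposure = 0.05, seed = 10)
  sim <- simulateTracks(p)
  segs <- classifyBound(sim$tracks, rMax = 0.22, nMin = 3)
  curve <- buildSurvival(segs, sim$tracks)
  corr <- correctPhotobleaching(curve, "intrinsic", detectionCounts(sim$tracks))
  # flat within the counting-noise confidence band: z-score each grid
  # point's log-deviation against binomial noise, relative to the first
  # informative point (the end of the minimum-dwell plateau)
  i0 <- max(which(corr@counts == corr@counts[1]))
  keep <- which(corr@counts >= 30)
  keep <- keep[keep >= i0]
  rel <- log(survProb(corr)[keep] / survProb(corr)[i0])
  Sraw <- corr@counts[keep] / corr@n0
  z <- abs(rel) / sqrt((1 - Sraw + 1 / corr@n0) / corr@counts[keep])
  expect_lt(max(z), 4)
  expect_equal(corr@provenance$bleach_per_exposure, -log(0.95),
               tolerance = 0.05)
})

test_that("correction preconditions are enforced", {
  target <- analyticCurve(function(t) exp(-t / 5), tmax = 40)
  short <- analyticCurve(function(t) exp(-t / 5), tmax = 10)
  expect_error(correctPhotobleaching(target, "whole_reference", short),
               "shorter")
  expect_error(correctPhotobleaching(target, "intrinsic", short),
               "detection counts")
})

test_that("immobile-fraction corrected bi-exponential recovers both residence times", {
  # two bound states tau 2 s / 30 s, bleach 0.02 per exposure, immobile
  # reference co-simulated, 3000 segments per replicate; the median over
  # seeded replicates is compared (a single replicate sits at ~2 sigma of
  # the estimator's sampling noise, see the methods vignette)
  est <- t(vapply(1:5, function(s) recoverTwoState(s, tauNS = 2, tauS = 30),
                  numeric(3)))
  med <- apply(est, 2, median)
  expect_equal(med[1], 2, tolerance = 0.15)
  expect_equal(med[2], 30, tolerance = 0.15)
})
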