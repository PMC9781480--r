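test_that("a lossless immobile system yields full-length constant tracks", {
  p <- SimulationParams(nMolecules = 5,
                        states = list(MotionState("bound_specific", D = 0)),
                        nFrames = 10L, localizationSigma = 0,
                        bleachProbPerExposure = 0, seed = 1)
  sim <- simulateTracks(p)
  d <- tracks(sim$tracks)
  expect_equal(nTracks(sim$tracks), 5)
  lens <- tapply(d$frame, d$track_id, length)
  expect_true(all(lens == 10))
  spread <- tapply(d$x, d$track_id, function(z) diff(range(z)))
  expect_true(all(spread == 0))
})

test_that("observed track length under bleaching is geometric with mean 1/p", {
  p <- SimulationParams(nMolecules = 10000,
                        states = list(MotionState("bound_specific", D = 0)),
                        nFrames = 200L, localizationSigma = 0,
                        bleachProbPerExposure = 0.1, seed = 2)
  sim <- simulateTracks(p)
  lens <- tabulate(factor(tracks(sim$tracks)$track_id))
  expect_equal(mean(lens), 10, tolerance = 0.05)
})

test_that("symmetric switching spends half the time bound", {
  # the occupancy fraction is motion-independent, so both states are
  # immobile to keep the check cheap at 5e4 molecule-seconds
  st <- list(MotionState("diffusing", D = 0),
             MotionState("bound_nonspecific", D = 0))
  Q <- matrix(c(0, 1, 1, 0), 2, 2)
  p <- SimulationParams(nMolecules = 500, states = st, switchRates = Q,
                        nucleusRadius = 1, frameExposure = 0.2,
                        nFrames = 500L, seed = 3)
  sim <- simulateTracks(p)
  expect_equal(unname(sim$truth@trueFractions["bound_nonspecific"]), 0.5,
               tolerance = 0.03)
})

test_that("true bound dwells are exponential with rate k_off", {
  st <- list(MotionState("diffusing", D = 0.5),
             MotionState("bound_nonspecific", D = 0))
  Q <- matrix(c(0, 2, 1, 0), 2, 2, byrow = TRUE)  # k_on 2/s, k_off 1/s
  p <- SimulationParams(nMolecules = 120, states = st, switchRates = Q,
                        nucleusRadius = 1, frameExposure = 0.5,
                        nFrames = 200L, localizationSigma = 0, seed = 4)
  sim <- simulateTracks(p)
  Tend <- (200 - 1) * 0.5
  dw <- sim$truth@dwells
  paths <- sim$truth@statePath
  complete <- dw$dwell[paths$tEnd[grepl("^bound", paths$state)] < Tend - 1e-9]
  expect_gt(length(complete), 5000)
  ks <- suppressWarnings(ks.test(complete, "pexp", 1))
  expect_gt(ks$p.value, 0.01)
})

test_that("all emitted positions lie inside the nucleus sphere", {
  p <- SimulationParams(nMolecules = 50,
                        states = list(MotionState("diffusing", D = 1)),
                        nucleusRadius = 1, frameExposure = 0.05,
                        nFrames = 100L, localizationSigma = 0, seed = 5)
  sim <- simulateTracks(p)
  d <- tracks(sim$tracks)
  expect_true(all(d$x^2 + d$y^2 <= 1 + 1e-12))
})

test_that("identical seed gives bit-identical tracks; no bleaching keeps all molecules", {
  p <- SimulationParams(nMolecules = 30,
                        states = list(MotionState("diffusing", D = 0.3)),
                        nFrames = 40L, seed = 7)
  a <- simulateTracks(p)
  b <- simulateTracks(p)
  expect_identical(tracks(a$tracks), tracks(b$tracks))
  expect_equal(nTracks(a$tracks), 30)
})

test_that("defocalization removes molecules whose axial position escapes", {
  p <- SimulationParams(nMolecules = 200,
                        states = list(MotionState("diffusing", D = 1)),
                        nucleusRadius = 1, frameExposure = 0.1,
                        nFrames = 50L, depthOfField = 0.4,
                        localizationSigma = 0, seed = 8)
  sim <- simulateTracks(p)
  lens <- tabulate(factor(tracks(sim$tracks)$track_id))
  # with a 0.4 um slab inside a 1 um nucleus most tracks must be short
  expect_lt(nrow(tracks(sim$tracks)), 200 * 50)
  expect_lt(mean(lens), 10)
})

test_that("invalid simulation parameters are rejected", {
  st <- list(MotionState("diffusing", D = 0.5))
  expect_error(SimulationParams(10, st, nFrames = 1L), "nFrames")
  expect_error(SimulationParams(10, st, bleachProbPerExposure = 1.5),
               "bleachProb")
  expect_error(SimulationParams(10, st, nucleusRadius = -1), "nucleusRadius")
  expect_error(MotionState("diffusing", D = -1), "D must")
})

test_that("movie rendering: background, argmax and integrated intensity", {
  meta <- fixtureMeta(nFrames = 3L)
  empty <- TrackSet(data.frame(track_id = integer(), frame = integer(),
                               x = numeric(), y = numeric()), meta)
  mov <- simulateMovie(empty, psfSigma = 0.12, background = 7,
                       photonsPerMolecule = 1000, dims = c(32, 32),
                       noise = FALSE)
  expect_true(all(mov == 7))

  one <- TrackSet(data.frame(track_id = 1, frame = 0:2,
                             x = 0.43, y = -0.52), meta)
  mov <- simulateMovie(one, psfSigma = 0.12, background = 0,
                       photonsPerMolecule = 1000, dims = c(64, 64),
                       noise = FALSE)
  ps <- 0.1; ox <- -64 * ps / 2
  for (f in 1:3) {
    pk <- which(mov[, , f] == max(mov[, , f]), arr.ind = TRUE)[1, ]
    # pixel containing x=0.43: col index such that x in [ox+(c-1)ps, ox+c ps)
    expect_equal(unname(pk["col"]), floor((0.43 - ox) / ps) + 1)
    expect_equal(unname(pk["row"]), floor((-0.52 - ox) / ps) + 1)
  }
  # spot fully inside the frame: integral matches the photon budget
  expect_equal(sum(mov[, , 1]), 1000, tolerance = 0.02)
  expect_error(simulateMovie(one, psfSigma = 0), "psfSigma")
})
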