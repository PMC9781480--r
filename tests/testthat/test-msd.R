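test_that("MSD of degenerate motions matches closed forms", {
  meta <- fixtureMeta(nFrames = 30L, dt = 0.2)
  # stationary: zero at all lags
  still <- TrackSet(data.frame(track_id = 1, frame = 0:19, x = 1, y = -1),
                    meta)
  m <- computeMSD(still, maxLag = 5)
  expect_true(all(m@msd == 0))
  expect_equal(m@source, "single_track")

  # deterministic drift: msd = v^2 tau^2, alpha = 2
  v <- 0.3
  drift <- TrackSet(data.frame(track_id = 1, frame = 0:19,
                               x = v * 0.2 * (0:19), y = 0), meta)
  m <- computeMSD(drift, maxLag = 10)
  expect_equal(m@msd, v^2 * m@lags^2)
  cf <- fitAlphaRc(m)
  expect_equal(cf@alpha, 2, tolerance = 1e-6)
  expect_equal(cf@motionClass, "super_diffusive")

  expect_error(computeMSD(still, maxLag = 0), "maxLag")
})

test_that("ensemble Brownian MSD matches 4 D tau and the localization offset", {
  p <- SimulationParams(nMolecules = 100,
                        states = list(MotionState("diffusing", D = 1)),
                        nucleusRadius = Inf, frameExposure = 0.01,
                        nFrames = 100L, localizationSigma = 0, seed = 4)
  m <- computeMSD(simulateTracks(p)$tracks, maxLag = 10)
  expect_equal(m@msd[1:5], 4 * 1 * m@lags[1:5], tolerance = 0.03)

  # with localization noise the linear fit intercept approximates 4 sigma^2
  p2 <- SimulationParams(nMolecules = 500,
                         states = list(MotionState("diffusing", D = 0.5)),
                         nucleusRadius = Inf, frameExposure = 0.02,
                         nFrames = 40L, localizationSigma = 0.04, seed = 5)
  m2 <- computeMSD(simulateTracks(p2)$tracks, maxLag = 8)
  fit <- fitDiffusion(m2, nPoints = 4)
  expect_equal(fit$D, 0.5, tolerance = 0.1)
  expect_equal(fit$offset, 4 * 0.04^2, tolerance = 0.25)
})

test_that("MSD matches a brute-force double loop on random tracks", {
  set.seed(44)
  meta <- fixtureMeta(nFrames = 40L, dt = 0.1)
  for (rep in 1:5) {
    ts <- randomTrackSet(nTracks = 4, maxLen = 15, meta = meta)
    m <- computeMSD(ts, maxLag = 6)
    d <- tracks(ts)
    for (li in seq_along(m@lags)) {
      L <- round(m@lags[li] / 0.1)
      tot <- 0; cnt <- 0
      for (id in unique(d$track_id)) {
        tr <- d[d$track_id == id, ]
        for (i in seq_len(nrow(tr))) for (j in seq_len(nrow(tr))) {
          if (tr$frame[j] - tr$frame[i] == L) {
            tot <- tot + (tr$x[j] - tr$x[i])^2 + (tr$y[j] - tr$y[i])^2
            cnt <- cnt + 1
          }
        }
      }
      expect_equal(m@msd[li], tot / cnt)
      expect_equal(m@counts[li], cnt)
    }
  }
})

test_that("the diffusion fit handles exact lines and immobile tracks", {
  lags <- (1:10) * 0.1
  line <- new("MSDCurve", lags = lags, msd = 4 * lags + 0.01,
              counts = rep(100, 10), source = "ensemble")
  fit <- fitDiffusion(line)
  expect_equal(fit$D, 1)
  expect_equal(fit$offset, 0.01)
  expect_false(fit$flagged)

  set.seed(6)
  still <- new("MSDCurve", lags = lags,
               msd = pmax(rnorm(10, 0.0004, 1e-5) - (1:10) * 2e-5, 0),
               counts = rep(100, 10), source = "ensemble")
  fit <- fitDiffusion(still)
  expect_equal(fit$D, 1e-4)
  expect_true(fit$flagged)
})

test_that("confinement self-fit is exact and sphere confinement is recovered", {
  lags <- (1:20) * 0.01
  exact <- new("MSDCurve", lags = lags,
               msd = 0.3^2 * (1 - exp(-4 * 0.5 * lags / 0.3^2)),
               counts = rep(100, 20), source = "ensemble")
  cf <- fitAlphaRc(exact)
  expect_equal(cf@Rc, 0.3, tolerance = 1e-3)
  expect_equal(cf@D, 0.5, tolerance = 1e-3)
  expect_equal(cf@motionClass, "sub_diffusive")

  p <- SimulationParams(nMolecules = 200,
                        states = list(MotionState("diffusing", D = 0.5,
                                                  confinementRadius = 0.3)),
                        nucleusRadius = Inf, frameExposure = 0.01,
                        nFrames = 100L, localizationSigma = 0.01, seed = 7)
  m <- computeMSD(simulateTracks(p)$tracks, maxLag = 20)
  cf <- fitAlphaRc(m)
  expect_equal(cf@Rc, 0.3, tolerance = 0.15)
  expect_lt(cf@alpha, 0.9)

  pu <- SimulationParams(nMolecules = 200,
                         states = list(MotionState("diffusing", D = 0.5)),
                         nucleusRadius = Inf, frameExposure = 0.01,
                         nFrames = 100L, localizationSigma = 0, seed = 8)
  cfu <- fitAlphaRc(computeMSD(simulateTracks(pu)$tracks, maxLag = 20))
  expect_gt(cfu@alpha, 0.9)
  expect_lt(cfu@alpha, 1.1)
  expect_equal(cfu@motionClass, "brownian")
  expect_true(cfu@Rc > 1 || "rc_unbounded" %in% cfu@flags)
})

test_that("confined R_c is insensitive to localization noise well below R_c", {
  rcs <- vapply(c(0, 0.03), function(sig) {
    p <- SimulationParams(nMolecules = 150,
                          states = list(MotionState("diffusing", D = 0.5,
                                                    confinementRadius = 0.3)),
                          nucleusRadius = Inf, frameExposure = 0.01,
                          nFrames = 100L, localizationSigma = sig, seed = 9)
    fitAlphaRc(computeMSD(simulateTracks(p)$tracks, maxLag = 20))@Rc
  }, numeric(1))
  expect_equal(rcs[2], rcs[1], tolerance = 0.1)
})

test_that("population R_c reproduces the reported reconciliation", {
  expect_equal(populationRc(c(0.5, 0.5), c(0.13, 0.5)), 0.315)
  expect_equal(populationRc(1, 0.42), 0.42)
  expect_equal(populationRc(c(0.25, 0.75), c(0.1, 0.5)), 0.4)
  # permutation invariance
  expect_equal(populationRc(c(0.3, 0.7), c(0.1, 0.4)),
               populationRc(c(0.7, 0.3), c(0.4, 0.1)))
  expect_error(populationRc(c(0.5, 0.6), c(0.1, 0.2)), "sum to 1")
  expect_error(populationRc(c(1, 0), 0.1), "length")
})

test_that("sampling volumes match the reported nuclear numbers", {
  expect_equal(samplingVolume(0.3), 0.113, tolerance = 0.002)
  expect_equal(samplingVolume(1), 4.19, tolerance = 0.002)
  expect_equal(samplingVolume(0), 0)
  expect_error(samplingVolume(-1), "rc")
})

test_that("translocation detection time matches the replisome example", {
  expect_equal(translocationDetectTime(1.6, 30), 3.31, tolerance = 0.002)
  expect_equal(translocationDetectTime(1.6, 60),
               2 * translocationDetectTime(1.6, 30))
  expect_equal(translocationDetectTime(3.9, 30), 1.36, tolerance = 0.003)
  expect_error(translocationDetectTime(0, 30), "> 0")
})

test_that("log-D mixture recovers three states and respects eligibility", {
  set.seed(5)
  D <- 10^c(rnorm(500, -2, 0.25), rnorm(500, -0.7, 0.25),
            rnorm(500, 0.3, 0.25))
  st <- fitLogDMixture(D, kMax = 3, seed = 0)
  expect_equal(st@k, 3L)
  expect_equal(st@means, c(-2, -0.7, 0.3), tolerance = 0.05)
  expect_equal(sum(st@weights), 1)

  # 5 tracks: only the single component is eligible
  st1 <- fitLogDMixture(10^rnorm(5, -1, 0.2), kMax = 3, seed = 0)
  expect_equal(st1@k, 1L)
  expect_equal(names(st1@bicTable), "1")

  # weights always sum to 1, for any k, on arbitrary data
  for (i in 1:5) {
    st <- fitLogDMixture(10^rnorm(60, -1, 0.5), kMax = 3, seed = i)
    expect_equal(sum(st@weights), 1)
  }
})

test_that("the EM mixture agrees with an independent mixture fitter", {
  withr::local_package("mclust")
  set.seed(15)
  z <- c(rnorm(400, -2, 0.25), rnorm(400, 0, 0.25))
  st <- fitLogDMixture(10^z, kMax = 2, seed = 0)
  mc <- Mclust(z, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(st@means, sort(unname(mc$parameters$mean)), tolerance = 0.02)
  expect_equal(st@k, 2L)
})

test_that("per-track diffusion coefficients separate bound from mobile tracks", {
  st <- list(MotionState("bound_specific", D = 0),
             MotionState("diffusing", D = 1))
  p <- SimulationParams(nMolecules = 60, states = st,
                        nucleusRadius = Inf, frameExposure = 0.01,
                        nFrames = 60L, localizationSigma = 0.01, seed = 12)
  sim <- simulateTracks(p)
  Ds <- trackDiffusion(sim$tracks)
  expect_equal(length(Ds), 60L)
  truthBound <- grepl("bound", sim$truth@statePath$state[
    match(as.integer(names(Ds)), sim$truth@statePath$molecule)])
  expect_gt(min(Ds[!truthBound]), max(c(Ds[truthBound], 0.05)))
})
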