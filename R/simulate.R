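#' @include AllClasses.R trackio.R
NULL

#' Construct a motion state
#'
#' @param label `"bound_specific"`, `"bound_nonspecific"` or `"diffusing"`.
#' @param D diffusion coefficient, um^2/s (0 for an immobile bound state).
#' @param confinementRadius confinement sphere radius in um; `Inf` for
#'   motion bounded only by the nucleus.
#' @return a [MotionState-class].
#' @export
MotionState <- function(label = "diffusing", D = 0, confinementRadius = Inf) {
  new("MotionState", label = label, D = as.numeric(D),
      confinementRadius = as.numeric(confinementRadius))
}

#' Construct simulation parameters
#'
#' @param nMolecules number of molecules.
#' @param states list of [MotionState-class] objects.
#' @param switchRates nStates x nStates matrix of switching rates (1/s);
#'   entry (i, j) is the rate from state i to state j. Defaults to no
#'   switching.
#' @param nucleusRadius confinement radius of the whole compartment, um.
#' @param frameExposure exposure per frame, s.
#' @param darkInterval dark period between exposures, s.
#' @param nFrames number of frames (>= 2).
#' @param localizationSigma per-axis localization error sd, um.
#' @param bleachProbPerExposure bleaching probability per exposure in
#'   \[0, 1\]. Applied per exposure (not per second): dark intervals do not
#'   illuminate the fluorophore.
#' @param depthOfField axial detection slab thickness, um (`Inf` disables
#'   defocalization loss).
#' @param seed RNG seed.
#' @return a validated [SimulationParams-class].
#' @seealso [simulateTracks()]
#' @export
SimulationParams <- function(nMolecules, states,
                             switchRates = matrix(0, length(states),
                                                  length(states)),
                             nucleusRadius = 1, frameExposure = 0.2,
                             darkInterval = 0, nFrames = 100L,
                             localizationSigma = 0.02,
                             bleachProbPerExposure = 0,
                             depthOfField = Inf, seed = 0L) {
  new("SimulationParams",
      nMolecules = as.integer(nMolecules), states = states,
      switchRates = switchRates, nucleusRadius = as.numeric(nucleusRadius),
      frameExposure = as.numeric(frameExposure),
      darkInterval = as.numeric(darkInterval), nFrames = as.integer(nFrames),
      localizationSigma = as.numeric(localizationSigma),
      bleachProbPerExposure = as.numeric(bleachProbPerExposure),
      depthOfField = as.numeric(depthOfField), seed = as.integer(seed))
}

# uniform point in a sphere of radius R (origin if R is not finite)
.runifSphere <- function(R) {
  if (!is.finite(R)) return(c(0, 0, 0))
  repeat {
    p <- stats::runif(3, -R, R)
    if (sum(p^2) <= R^2) return(p)
  }
}

# fold a radial distance into [0, R] by reflection at the boundary
.foldRadius <- function(n, R) R - abs(n %% (2 * R) - R)

# reflect a 3D position into the sphere (center, R); no-op if inside
.reflectInto <- function(pos, center, R) {
  if (!is.finite(R)) return(pos)
  r <- pos - center
  n <- sqrt(sum(r^2))
  if (n <= R || n == 0) return(pos)
  center + r * (.foldRadius(n, R) / n)
}

# one diffusive propagation over `delta` seconds with reflecting
# boundaries; subdivided so the rms step stays well below the tightest
# boundary radius (reflection assumes steps small vs the sphere)
.diffuseStep <- function(pos, delta, D, confCenter, Rc, Rn) {
  rMin <- min(Rc, Rn)
  nSub <- if (is.finite(rMin))
    max(1L, ceiling(sqrt(2 * D * delta) / (rMin / 5))) else 1L
  dsub <- delta / nSub
  for (i in seq_len(nSub)) {
    pos <- pos + stats::rnorm(3, 0, sqrt(2 * D * dsub))
    pos <- .reflectInto(pos, confCenter, Rc)
    pos <- .reflectInto(pos, c(0, 0, 0), Rn)
  }
  pos
}

# stationary distribution of the CTMC with generator built from `rates`
.ctmcStationary <- function(rates) {
  ns <- nrow(rates)
  if (ns == 1) return(1)
  Q <- rates
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  if (all(Q == 0)) return(rep(1 / ns, ns))
  # solve pi Q = 0, sum(pi) = 1
  A <- rbind(t(Q), rep(1, ns))
  b <- c(rep(0, ns), 1)
  p <- stats::lsfit(A, b, intercept = FALSE)$coefficients
  p <- pmax(p, 0)
  p / sum(p)
}

#' Simulate ground-truth single-molecule tracks
#'
#' Molecules switch between motion states as a continuous-time Markov chain
#' with exact exponential waiting times; between frames they take isotropic
#' Gaussian steps with per-axis variance 2 D dt, reflected at the
#' confinement boundary (the nucleus sphere, and the state's confinement
#' sphere centered where the state was entered). The axial coordinate is
#' simulated explicitly (1D Brownian motion) solely to drive defocalization:
#' a molecule is removed permanently the first time its axial position
#' leaves +/- depthOfField/2. Photobleaching is Bernoulli per exposure;
#' the bleaching exposure is the last observed frame. Gaussian localization
#' error is added to the emitted x, y only.
#'
#' @param params a [SimulationParams-class].
#' @param pixelSize pixel size recorded in the output metadata, um/px
#'   (cosmetic for track-level analyses; used when rendering movies).
#' @return a list with elements `tracks` (a [TrackSet-class]) and `truth`
#'   (a [GroundTruth-class]).
#' @examples
#' p <- SimulationParams(nMolecules = 5,
#'                       states = list(MotionState("diffusing", D = 0.5)),
#'                       nFrames = 20L, seed = 1)
#' sim <- simulateTracks(p)
#' nTracks(sim$tracks)
#' @export
simulateTracks <- function(params, pixelSize = 0.1) {
  stopifnot(is(params, "SimulationParams"))
  validObject(params)
  set.seed(params@seed)
  ns <- length(params@states)
  labels <- vapply(params@states, function(s) s@label, character(1))
  stateNames <- if (anyDuplicated(labels))
    paste0(labels, "_", seq_len(ns)) else labels
  Ds <- vapply(params@states, function(s) s@D, numeric(1))
  Rcs <- vapply(params@states, function(s) s@confinementRadius, numeric(1))
  isBound <- grepl("^bound", labels)
  dt <- params@frameExposure + params@darkInterval
  nF <- params@nFrames
  Tend <- (nF - 1) * dt
  frameTimes <- (seq_len(nF) - 1) * dt
  rates <- params@switchRates
  diag(rates) <- 0
  outRate <- rowSums(rates)
  pInit <- .ctmcStationary(rates)
  p <- params@bleachProbPerExposure
  dofHalf <- params@depthOfField / 2
  Rn <- params@nucleusRadius

  locRows <- vector("list", params@nMolecules)
  pathRows <- vector("list", params@nMolecules)
  bleachFrame <- rep(NA_integer_, params@nMolecules)
  stateTime <- numeric(ns)

  for (m in seq_len(params@nMolecules)) {
    # realized state path over [0, Tend]
    s <- sample.int(ns, 1, prob = pInit)
    tEv <- 0
    evState <- integer(0); evStart <- numeric(0); evEnd <- numeric(0)
    while (tEv < Tend) {
      w <- if (outRate[s] > 0) stats::rexp(1, outRate[s]) else Inf
      t1 <- min(tEv + w, Tend)
      evState <- c(evState, s); evStart <- c(evStart, tEv)
      evEnd <- c(evEnd, t1)
      tEv <- t1
      if (tEv < Tend)
        s <- sample.int(ns, 1, prob = rates[s, ])
    }
    stateTime[evState] <- stateTime[evState] + (evEnd - evStart)

    # number of exposures observed before bleaching (geometric, mean 1/p)
    nObsMax <- if (p > 0) stats::rgeom(1, p) + 1L else nF
    if (p > 0 && nObsMax < nF) bleachFrame[m] <- nObsMax  # first dark frame

    # positions at frame times
    pos <- .runifSphere(Rn)
    framePos <- matrix(NA_real_, 3, nF)
    framePos[, 1] <- pos
    confCenter <- pos
    kNext <- 2L  # next frame index (1-based) to record
    for (e in seq_along(evState)) {
      st <- evState[e]
      D <- Ds[st]
      Rc <- Rcs[st]
      confCenter <- pos  # confinement anchored where the state is entered
      # breakpoints: frame times inside (evStart, evEnd]
      while (kNext <= nF && frameTimes[kNext] <= evEnd[e] + 1e-12) {
        tPrev <- max(evStart[e], frameTimes[kNext - 1L])
        delta <- frameTimes[kNext] - tPrev
        if (D > 0 && delta > 0)
          pos <- .diffuseStep(pos, delta, D, confCenter, Rc, Rn)
        framePos[, kNext] <- pos
        kNext <- kNext + 1L
      }
      # advance to the end of the sojourn (between frames)
      if (e < length(evState) && D > 0) {
        delta <- evEnd[e] - max(evStart[e], frameTimes[kNext - 1L])
        if (delta > 0)
          pos <- .diffuseStep(pos, delta, D, confCenter, Rc, Rn)
      }
    }

    # emission: bleaching and defocalization truncate the observed track
    lastObs <- min(nObsMax, nF)
    if (is.finite(dofHalf)) {
      out <- which(abs(framePos[3, seq_len(lastObs)]) > dofHalf)
      if (length(out)) lastObs <- out[1] - 1L
    }
    if (lastObs >= 1) {
      k <- seq_len(lastObs)
      sig <- params@localizationSigma
      locRows[[m]] <- data.frame(
        track_id = m,
        frame = k - 1L,
        t = frameTimes[k],
        x = framePos[1, k] + if (sig > 0) stats::rnorm(lastObs, 0, sig) else 0,
        y = framePos[2, k] + if (sig > 0) stats::rnorm(lastObs, 0, sig) else 0,
        intensity = NA_real_, sigma = sig)
    }
    pathRows[[m]] <- data.frame(molecule = m, state = stateNames[evState],
                                tStart = evStart, tEnd = evEnd)
  }

  loc <- do.call(rbind, locRows[!vapply(locRows, is.null, logical(1))])
  if (is.null(loc))
    loc <- data.frame(track_id = integer(), frame = integer(), t = numeric(),
                      x = numeric(), y = numeric(), intensity = numeric(),
                      sigma = numeric())
  meta <- AcquisitionMetadata(pixelSize = pixelSize,
                              exposure = params@frameExposure,
                              darkInterval = params@darkInterval,
                              nFrames = nF, label = "simulated")
  ts <- TrackSet(loc, meta)

  statePath <- do.call(rbind, pathRows)
  boundRows <- statePath[grepl("^bound", statePath$state), , drop = FALSE]
  dwells <- data.frame(molecule = boundRows$molecule,
                       state = boundRows$state,
                       dwell = boundRows$tEnd - boundRows$tStart)
  fr <- stateTime / sum(stateTime)
  names(fr) <- stateNames
  names(Ds) <- stateNames
  truth <- new("GroundTruth", statePath = statePath, dwells = dwells,
               bleachFrame = bleachFrame, trueD = Ds, trueFractions = fr)
  list(tracks = ts, truth = truth)
}

#' Canonical two-state binding benchmark parameters
#'
#' A three-state system (diffusing, non-specifically bound, specifically
#' bound) in the time-lapse imaging regime: molecules diffuse at
#' 0.5 um^2/s inside a 1 um nucleus, bind at a total on-rate of 1/s split
#' 60/40 between a non-specific state (residence 2 s) and a specific
#' state (residence 10 s), and photobleach with probability 0.02 per
#' exposure (time-lapse regime: 0.2 s exposures with 0.3 s dark
#' intervals, so bleaching is slow on the wall clock). These are the
#' reference conditions used by the package's parameter-recovery
#' benchmarks.
#'
#' @param seed RNG seed.
#' @param nMolecules number of molecules.
#' @param tauNS,tauS bound residence times, s.
#' @param fNS fraction of binding events that are non-specific.
#' @param bleachProb bleaching probability per exposure.
#' @return a [SimulationParams-class].
#' @seealso [immobileReferenceParams()] for the matching photobleaching
#'   reference.
#' @export
twoStateBindingParams <- function(seed = 0, nMolecules = 1800,
                                  tauNS = 2, tauS = 10, fNS = 0.6,
                                  bleachProb = 0.02) {
  states <- list(MotionState("diffusing", D = 0.5),
                 MotionState("bound_nonspecific", D = 0),
                 MotionState("bound_specific", D = 0))
  konTotal <- 1
  rates <- matrix(0, 3, 3)
  rates[1, 2] <- konTotal * fNS
  rates[1, 3] <- konTotal * (1 - fNS)
  rates[2, 1] <- 1 / tauNS
  rates[3, 1] <- 1 / tauS
  SimulationParams(nMolecules = nMolecules, states = states,
                   switchRates = rates, nucleusRadius = 1,
                   frameExposure = 0.2, darkInterval = 0.3,
                   nFrames = 300L, localizationSigma = 0.02,
                   bleachProbPerExposure = bleachProb,
                   depthOfField = Inf, seed = seed)
}

#' Immobile reference parameters for photobleaching correction
#'
#' A single permanently bound, immobile state (a stable histone stand-in)
#' under the same acquisition and bleaching regime as
#' [twoStateBindingParams()]: its observed survival decays by
#' photobleaching alone, making it the reference for the whole-reference
#' and immobile-fraction corrections.
#'
#' @param seed RNG seed.
#' @param nMolecules number of molecules.
#' @param bleachProb bleaching probability per exposure.
#' @return a [SimulationParams-class].
#' @export
immobileReferenceParams <- function(seed = 0, nMolecules = 1500,
                                    bleachProb = 0.02) {
  SimulationParams(nMolecules = nMolecules,
                   states = list(MotionState("bound_specific", D = 0)),
                   nucleusRadius = 1, frameExposure = 0.2,
                   darkInterval = 0.3, nFrames = 300L,
                   localizationSigma = 0.02,
                   bleachProbPerExposure = bleachProb,
                   depthOfField = Inf, seed = seed)
}

#' Render a synthetic movie from tracks
#'
#' Each frame is the sum of 2D Gaussian spots centered at the track
#' positions, integrated over pixel areas, plus a uniform background, with
#' optional Poisson shot noise. The image origin is placed so that (0, 0)
#' um maps to the image center; x runs along columns, y along rows.
#'
#' @param ts a [TrackSet-class]; pixel size is taken from its metadata.
#' @param psfSigma Gaussian PSF sigma, um.
#' @param background uniform background, counts per pixel.
#' @param photonsPerMolecule integrated counts per molecule per frame.
#' @param dims image size `c(rows, cols)` in pixels.
#' @param noise logical, add Poisson shot noise.
#' @return 3D array (rows, cols, frames) of counts.
#' @seealso [writeStack()], [detectSpots()]
#' @export
simulateMovie <- function(ts, psfSigma = 0.12, background = 5,
                          photonsPerMolecule = 1000, dims = c(64, 64),
                          noise = TRUE) {
  stopifnot(is(ts, "TrackSet"))
  if (psfSigma <= 0) stop("psfSigma must be > 0")
  meta <- acqMeta(ts)
  ps <- meta@pixelSize
  nr <- dims[1]; nc <- dims[2]
  nF <- max(meta@nFrames, if (nrow(ts@data)) max(ts@data$frame) + 1L else 1L)
  ox <- -nc * ps / 2  # um coordinate of the left edge of column 1
  oy <- -nr * ps / 2
  stack <- array(background, c(nr, nc, nF))
  d <- ts@data
  win <- ceiling(5 * psfSigma / ps)
  for (i in seq_len(nrow(d))) {
    f <- d$frame[i] + 1L
    # pixel indices whose area the spot meaningfully covers
    cx <- (d$x[i] - ox) / ps + 0.5  # center in pixel units (col)
    cy <- (d$y[i] - oy) / ps + 0.5
    cols <- max(1, floor(cx - win)):min(nc, ceiling(cx + win))
    rows <- max(1, floor(cy - win)):min(nr, ceiling(cy + win))
    if (!length(cols) || !length(rows)) next
    edgeX <- ox + (c(cols, cols[length(cols)] + 1) - 1) * ps
    edgeY <- oy + (c(rows, rows[length(rows)] + 1) - 1) * ps
    px <- diff(stats::pnorm(edgeX, d$x[i], psfSigma))
    py <- diff(stats::pnorm(edgeY, d$y[i], psfSigma))
    stack[rows, cols, f] <- stack[rows, cols, f] +
      photonsPerMolecule * outer(py, px)
  }
  if (noise) {
    stack[] <- stats::rpois(length(stack), stack)
  }
  stack
}
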