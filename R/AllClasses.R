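#' @import methods
NULL

#' Acquisition metadata for a tracking movie
#'
#' Describes the imaging regime a track table or image stack was acquired
#' under: camera pixel size, laser/camera exposure, and the dark interval
#' between exposures used in time-lapse imaging of long-binding events.
#' The frame interval (time between successive frames) is
#' `exposure + darkInterval`.
#'
#' @slot pixelSize numeric, pixel size in micrometers per pixel.
#' @slot exposure numeric, exposure time per frame in seconds.
#' @slot darkInterval numeric, dark (non-illuminated) time between exposures
#'   in seconds; 0 for continuous acquisition.
#' @slot nFrames integer, number of frames in the movie.
#' @slot label character, free-text label (e.g. protein / dye / regime).
#'
#' @seealso [AcquisitionMetadata()] for the constructor,
#'   [frameInterval()] for the derived frame interval.
#' @export
setClass("AcquisitionMetadata",
  representation(
    pixelSize    = "numeric",
    exposure     = "numeric",
    darkInterval = "numeric",
    nFrames      = "integer",
    label        = "character"
  ),
  prototype(
    pixelSize = 0.1, exposure = 0.2, darkInterval = 0,
    nFrames = 0L, label = ""
  )
)

setValidity("AcquisitionMetadata", function(object) {
  msg <- character()
  if (length(object@pixelSize) != 1 || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be a single positive number")
  if (length(object@exposure) != 1 || !is.finite(object@exposure) ||
      object@exposure <= 0)
    msg <- c(msg, "exposure must be a single positive number")
  if (length(object@darkInterval) != 1 || is.na(object@darkInterval) ||
      object@darkInterval < 0)
    msg <- c(msg, "darkInterval must be >= 0")
  if (length(object@nFrames) != 1 || is.na(object@nFrames) ||
      object@nFrames < 0)
    msg <- c(msg, "nFrames must be >= 0")
  if (length(msg)) msg else TRUE
})

#' A set of single-molecule tracks
#'
#' The central container of the package: one row per localization, grouped
#' into tracks by `track_id`, with the acquisition metadata needed to convert
#' frames to seconds and pixels to micrometers. Coordinates are stored in
#' micrometers and frames are 0-based.
#'
#' @slot data data.frame with columns `track_id`, `frame`, `t`, `x`, `y`,
#'   `intensity`, `sigma`. Rows are sorted by (`track_id`, `frame`); frames
#'   are strictly increasing within a track and `t` is nondecreasing.
#' @slot meta an [AcquisitionMetadata-class] object.
#'
#' @seealso [TrackSet()], [readTracks()], [writeTracks()], [tracks()],
#'   [acqMeta()]
#' @export
setClass("TrackSet",
  representation(data = "data.frame", meta = "AcquisitionMetadata")
)

.TRACK_COLS <- c("track_id", "frame", "t", "x", "y", "intensity", "sigma")

setValidity("TrackSet", function(object) {
  d <- object@data
  msg <- character()
  missing_cols <- setdiff(.TRACK_COLS, names(d))
  if (length(missing_cols))
    return(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")))
  if (nrow(d) == 0) return(TRUE)
  if (any(d$frame < 0)) msg <- c(msg, "frames must be >= 0")
  # per-track checks on sorted data
  o <- order(d$track_id, d$frame)
  d <- d[o, , drop = FALSE]
  dup <- duplicated(d[, c("track_id", "frame")])
  if (any(dup)) {
    bad <- unique(d$track_id[dup])
    msg <- c(msg, sprintf("duplicate (track_id, frame) in track(s): %s",
                          paste(utils::head(bad, 5), collapse = ", ")))
  }
  tnonmono <- tapply(d$t, d$track_id, function(z) any(diff(z) < 0))
  if (any(unlist(tnonmono))) {
    bad <- names(tnonmono)[unlist(tnonmono)]
    msg <- c(msg, sprintf("time not nondecreasing in track(s): %s",
                          paste(utils::head(bad, 5), collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Motion state of a simulated molecule
#'
#' One kinetic state in the generative switching model: a label, a diffusion
#' coefficient, and an optional confinement radius (Inf = unconfined within
#' the nucleus).
#'
#' @slot label character, one of `"bound_specific"`, `"bound_nonspecific"`,
#'   `"diffusing"`.
#' @slot D numeric, diffusion coefficient in square micrometers per second;
#'   bound states have D at or near 0.
#' @slot confinementRadius numeric, confinement sphere radius in micrometers
#'   (Inf for unconfined).
#'
#' @export
setClass("MotionState",
  representation(label = "character", D = "numeric",
                 confinementRadius = "numeric"),
  prototype(label = "diffusing", D = 0, confinementRadius = Inf)
)

setValidity("MotionState", function(object) {
  msg <- character()
  if (!object@label %in% c("bound_specific", "bound_nonspecific", "diffusing"))
    msg <- c(msg, "label must be bound_specific, bound_nonspecific or diffusing")
  if (length(object@D) != 1 || is.na(object@D) || object@D < 0)
    msg <- c(msg, "D must be a single number >= 0")
  if (length(object@confinementRadius) != 1 || is.na(object@confinementRadius) ||
      object@confinementRadius <= 0)
    msg <- c(msg, "confinementRadius must be > 0 (Inf for unconfined)")
  if (length(msg)) msg else TRUE
})

#' Parameters of the ground-truth track simulator
#'
#' Generative counterparts of the quantities the analysis estimates:
#' per-state diffusion coefficients and confinement, state switching rates,
#' localization error, per-exposure photobleaching, and the depth of field
#' that causes defocalization loss.
#'
#' @slot nMolecules integer, number of molecules to simulate.
#' @slot states list of [MotionState-class] objects.
#' @slot switchRates numeric matrix (nStates x nStates) of switching rates in
#'   1/s; entry (i, j) is the rate of switching from state i to state j.
#'   Diagonal ignored.
#' @slot nucleusRadius numeric, radius (um) of the spherical compartment all
#'   molecules are confined to (may be Inf for an effectively unbounded
#'   medium).
#' @slot frameExposure numeric, exposure per frame (s).
#' @slot darkInterval numeric, dark time between exposures (s).
#' @slot nFrames integer, number of frames.
#' @slot localizationSigma numeric, per-axis localization error sd (um).
#' @slot bleachProbPerExposure numeric in \[0, 1\]: probability that a
#'   molecule photobleaches at each exposure. Bleaching is per exposure, not
#'   per second, because dark intervals do not illuminate.
#' @slot depthOfField numeric, axial detection slab thickness (um); molecules
#'   whose axial position leaves +/- depthOfField/2 are lost (Inf disables).
#' @slot seed integer, RNG seed.
#'
#' @seealso [simulateTracks()]
#' @export
setClass("SimulationParams",
  representation(
    nMolecules = "integer", states = "list", switchRates = "matrix",
    nucleusRadius = "numeric", frameExposure = "numeric",
    darkInterval = "numeric", nFrames = "integer",
    localizationSigma = "numeric", bleachProbPerExposure = "numeric",
    depthOfField = "numeric", seed = "integer"
  )
)

setValidity("SimulationParams", function(object) {
  msg <- character()
  ns <- length(object@states)
  if (ns < 1) msg <- c(msg, "at least one state is required")
  if (!all(vapply(object@states, is, logical(1), "MotionState")))
    msg <- c(msg, "states must be a list of MotionState objects")
  if (object@nMolecules < 1) msg <- c(msg, "nMolecules must be >= 1")
  if (object@nFrames < 2) msg <- c(msg, "nFrames must be >= 2")
  if (!all(dim(object@switchRates) == c(ns, ns)))
    msg <- c(msg, "switchRates must be an nStates x nStates matrix")
  if (any(!is.finite(object@switchRates[row(object@switchRates) !=
                                        col(object@switchRates)])) ||
      any(object@switchRates[row(object@switchRates) !=
                             col(object@switchRates)] < 0))
    msg <- c(msg, "off-diagonal switchRates must be finite and >= 0")
  if (is.na(object@nucleusRadius) || object@nucleusRadius <= 0)
    msg <- c(msg, "nucleusRadius must be > 0")
  if (!is.finite(object@frameExposure) || object@frameExposure <= 0)
    msg <- c(msg, "frameExposure must be > 0")
  if (is.na(object@darkInterval) || object@darkInterval < 0)
    msg <- c(msg, "darkInterval must be >= 0")
  if (!is.finite(object@localizationSigma) || object@localizationSigma < 0)
    msg <- c(msg, "localizationSigma must be >= 0")
  if (is.na(object@bleachProbPerExposure) ||
      object@bleachProbPerExposure < 0 || object@bleachProbPerExposure > 1)
    msg <- c(msg, "bleachProbPerExposure must be in [0, 1]")
  if (is.na(object@depthOfField) || object@depthOfField <= 0)
    msg <- c(msg, "depthOfField must be > 0 (Inf to disable)")
  if (length(msg)) msg else TRUE
})

#' Ground truth of a simulation
#'
#' The unobserved truth behind a simulated [TrackSet-class]: the realized
#' state path of every molecule, the true dwell time of every binding event,
#' the frame at which each molecule bleached, and the generative per-state
#' diffusion coefficients and long-run occupancies. Used by parameter-recovery
#' tests; never available for real data.
#'
#' @slot statePath data.frame with columns `molecule`, `state`, `tStart`,
#'   `tEnd` (seconds), one row per sojourn.
#' @slot dwells data.frame with columns `molecule`, `state`, `dwell` (s), one
#'   row per binding event (sojourn in a bound state).
#' @slot bleachFrame integer vector, 0-based frame index at which each
#'   molecule bleached (NA if never).
#' @slot trueD named numeric, diffusion coefficient per state label.
#' @slot trueFractions named numeric, realized fraction of molecule-time
#'   spent in each state.
#'
#' @export
setClass("GroundTruth",
  representation(statePath = "data.frame", dwells = "data.frame",
                 bleachFrame = "integer", trueD = "numeric",
                 trueFractions = "numeric")
)

#' Survival distribution of bound dwell times
#'
#' Fraction of bound molecules whose observed dwell is at least t, on a grid
#' of multiples of the frame interval, together with the bound fraction
#' C_eq used for normalization and the provenance of any photobleaching
#' correction applied.
#'
#' @slot times numeric, dwell-time grid (s), multiples of the frame interval.
#' @slot S numeric, surviving fraction at each grid time.
#' @slot counts numeric, number of segments surviving at each grid time
#'   (before normalization); used as fit weights.
#' @slot n0 integer, number of bound segments.
#' @slot normalization character, `"raw"` or `"bound_fraction"`.
#' @slot correction character, `"none"`, `"intrinsic"`, `"whole_reference"`
#'   or `"immobile_fraction"`.
#' @slot Ceq numeric, bound fraction (bound detections over all detections).
#' @slot dt numeric, frame interval (s).
#' @slot provenance list, free-form record of how the curve was built
#'   (correction parameters, warnings, r_max, n_min, ...).
#'
#' @seealso [buildSurvival()], [correctPhotobleaching()], [fitDwellModels()]
#' @export
setClass("SurvivalCurve",
  representation(times = "numeric", S = "numeric", counts = "numeric",
                 n0 = "integer", normalization = "character",
                 correction = "character", Ceq = "numeric", dt = "numeric",
                 provenance = "list")
)

setValidity("SurvivalCurve", function(object) {
  msg <- character()
  if (length(object@times) != length(object@S) ||
      length(object@times) != length(object@counts))
    msg <- c(msg, "times, S and counts must have equal length")
  if (any(diff(object@times) <= 0)) msg <- c(msg, "times must be ascending")
  if (!object@normalization %in% c("raw", "bound_fraction"))
    msg <- c(msg, "normalization must be raw or bound_fraction")
  if (!object@correction %in%
      c("none", "intrinsic", "whole_reference", "immobile_fraction"))
    msg <- c(msg, "unknown correction")
  if (is.na(object@Ceq) || object@Ceq < 0 || object@Ceq > 1)
    msg <- c(msg, "Ceq must be in [0, 1]")
  if (object@correction == "none" && any(diff(object@S) > 1e-12))
    msg <- c(msg, "uncorrected S must be nonincreasing")
  if (length(object@S) && object@S[1] > 1 + 1e-12)
    msg <- c(msg, "S at the first time must be <= 1")
  if (length(msg)) msg else TRUE
})

#' A fitted dwell-time model
#'
#' One model family fitted to a survival curve: exponential mixtures with
#' 1-3 components, a power law, or a power-law + exponential hybrid, with
#' the Bayesian information criterion used for selection across families.
#'
#' @slot family character: `"exp_1"`, `"exp_2"`, `"exp_3"`, `"power_law"`,
#'   or `"power_plus_exp"`.
#' @slot params data.frame of fitted parameters. Exponential families: one
#'   row per component with columns `A` (amplitude), `tau` (s), sorted by
#'   `tau`. Power law: `A`, `beta`. Hybrid: a row with `A`, `tau` for the
#'   exponential part and a row with `A`, `beta` for the power-law part.
#' @slot fractions numeric, relative sub-population fractions (amplitudes
#'   normalized to sum to 1); empty for power law.
#' @slot Ceq numeric, model value at the first fitted grid point (bound
#'   fraction implied by the fit, on the scale of the input curve).
#' @slot BIC numeric, Bayesian information criterion of the fit.
#' @slot logLik numeric, Gaussian log-likelihood of the weighted log-scale
#'   residuals.
#' @slot nPoints integer, number of fitted grid points.
#' @slot converged logical.
#' @slot residSummary numeric, named summary of the log-scale residuals
#'   (rmse, max_abs).
#'
#' @seealso [fitDwellModels()], [deriveKinetics()]
#' @export
setClass("DwellModelFit",
  representation(family = "character", params = "data.frame",
                 fractions = "numeric", Ceq = "numeric", BIC = "numeric",
                 logLik = "numeric", nPoints = "integer",
                 converged = "logical", residSummary = "numeric")
)

#' A set of dwell-model fits with the BIC-selected best family
#'
#' @slot fits named list of [DwellModelFit-class] (one per converged family).
#' @slot best character, name of the selected family.
#' @slot bicTable numeric, named vector of BIC per converged family.
#'
#' @export
setClass("DwellFitSet",
  representation(fits = "list", best = "character", bicTable = "numeric")
)

#' Binding kinetics derived from a bi-exponential dwell fit
#'
#' Quantities derived from the two bound sub-states (non-specific and
#' specific): residence times, the average residence time, the number of
#' sites sampled per search, the search time, and the pseudo on-rate
#' (and true on-rate when the accessible-motif fraction S_eq is supplied).
#'
#' @slot Ceq numeric, bound fraction.
#' @slot FNS,FS numeric, fractions of bound molecules in the non-specific
#'   and specific sub-states (normalized to sum to 1).
#' @slot tauNS,tauS numeric, residence times (s) of the two sub-states.
#' @slot tauRes numeric, average residence time (s).
#' @slot tauSearch numeric, search time (s).
#' @slot Ntrials numeric, average number of sites sampled before specific
#'   binding, (F_S + F_NS) / F_S.
#' @slot kOnStar numeric, pseudo on-rate 1 / tauSearch (1/s).
#' @slot Seq numeric, accessible-motif fraction (NA when not supplied).
#' @slot kOn numeric, true on-rate kOnStar / Seq (NA when Seq not supplied).
#' @slot kOffNS,kOffS numeric, off-rates 1/tauNS and 1/tauS (1/s).
#'
#' @seealso [deriveKinetics()]
#' @export
setClass("BindingKinetics",
  representation(Ceq = "numeric", FNS = "numeric", FS = "numeric",
                 tauNS = "numeric", tauS = "numeric", tauRes = "numeric",
                 tauSearch = "numeric", Ntrials = "numeric",
                 kOnStar = "numeric", Seq = "numeric", kOn = "numeric",
                 kOffNS = "numeric", kOffS = "numeric")
)

#' Mean squared displacement curve
#'
#' Time-averaged MSD over overlapping windows, per track or count-weighted
#' over an ensemble of tracks.
#'
#' @slot lags numeric, lag times (s), ascending.
#' @slot msd numeric, mean squared displacement (um^2) at each lag.
#' @slot counts numeric, number of displacement pairs contributing per lag.
#' @slot source character, `"single_track"` or `"ensemble"`.
#'
#' @seealso [computeMSD()], [fitDiffusion()], [fitAlphaRc()]
#' @export
setClass("MSDCurve",
  representation(lags = "numeric", msd = "numeric", counts = "numeric",
                 source = "character")
)

setValidity("MSDCurve", function(object) {
  msg <- character()
  if (length(object@lags) != length(object@msd) ||
      length(object@lags) != length(object@counts))
    msg <- c(msg, "lags, msd and counts must have equal length")
  if (any(object@lags <= 0) || any(diff(object@lags) <= 0))
    msg <- c(msg, "lags must be positive ascending")
  if (any(object@msd < 0)) msg <- c(msg, "msd must be >= 0")
  if (any(object@counts < 1)) msg <- c(msg, "counts must be >= 1")
  if (!object@source %in% c("single_track", "ensemble"))
    msg <- c(msg, "source must be single_track or ensemble")
  if (length(msg)) msg else TRUE
})

#' Confinement and anomalous-diffusion fit of an MSD curve
#'
#' @slot D numeric, diffusion coefficient (um^2/s) from the confined-motion
#'   fit.
#' @slot Rc numeric, confinement radius (um); Inf when the fit is unbounded.
#' @slot alpha numeric, anomalous exponent from the log-log slope.
#' @slot motionClass character, `"brownian"`, `"super_diffusive"` or
#'   `"sub_diffusive"` (dead band alpha in \[0.9, 1.1\] -> brownian).
#' @slot flags character, diagnostic flags (e.g. `"rc_unbounded"`).
#'
#' @seealso [fitAlphaRc()]
#' @export
setClass("ConfinementFit",
  representation(D = "numeric", Rc = "numeric", alpha = "numeric",
                 motionClass = "character", flags = "character")
)

#' Gaussian-mixture decomposition of log10 diffusion coefficients
#'
#' @slot k integer, number of components selected by BIC.
#' @slot weights numeric, mixing weights (sum to 1), slow to fast.
#' @slot means numeric, component means of log10(D / um^2 s^-1), ascending.
#' @slot sds numeric, component standard deviations.
#' @slot BIC numeric, BIC of the selected model.
#' @slot bicTable numeric, named BIC per candidate k.
#' @slot logLik numeric, log-likelihood of the selected model.
#'
#' @seealso [fitLogDMixture()]
#' @export
setClass("DiffusionStates",
  representation(k = "integer", weights = "numeric", means = "numeric",
                 sds = "numeric", BIC = "numeric", bicTable = "numeric",
                 logLik = "numeric")
)

setValidity("DiffusionStates", function(object) {
  msg <- character()
  if (abs(sum(object@weights) - 1) > 1e-6)
    msg <- c(msg, "weights must sum to 1")
  if (length(object@means) != object@k || length(object@sds) != object@k ||
      length(object@weights) != object@k)
    msg <- c(msg, "weights, means, sds must have length k")
  if (length(msg)) msg else TRUE
})
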