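#' @include AllClasses.R
NULL

#' Extract the localization table of a TrackSet
#'
#' @param x a [TrackSet-class].
#' @return data.frame with one row per localization.
#' @export
setGeneric("tracks", function(x) standardGeneric("tracks"))

#' Extract acquisition metadata
#'
#' @param x an object carrying an [AcquisitionMetadata-class].
#' @return the metadata object.
#' @export
setGeneric("acqMeta", function(x) standardGeneric("acqMeta"))

#' Frame interval (exposure + dark interval), in seconds
#'
#' @param x an [AcquisitionMetadata-class] or [TrackSet-class].
#' @return numeric scalar, seconds between successive frames.
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))

#' Number of tracks in a TrackSet
#'
#' @param x a [TrackSet-class].
#' @return integer.
#' @export
setGeneric("nTracks", function(x) standardGeneric("nTracks"))

#' Track identifiers
#'
#' @param x a [TrackSet-class].
#' @return vector of unique track ids, in table order.
#' @export
setGeneric("trackIds", function(x) standardGeneric("trackIds"))

#' Bound fraction C_eq of a survival curve
#'
#' @param x a [SurvivalCurve-class].
#' @return numeric scalar in \[0, 1\].
#' @export
setGeneric("boundFraction", function(x) standardGeneric("boundFraction"))

#' Dwell-time grid of a survival curve
#'
#' @param x a [SurvivalCurve-class].
#' @return numeric vector of times (s).
#' @export
setGeneric("survTimes", function(x) standardGeneric("survTimes"))

#' Surviving fraction of a survival curve
#'
#' @param x a [SurvivalCurve-class].
#' @return numeric vector, same length as [survTimes()].
#' @export
setGeneric("survProb", function(x) standardGeneric("survProb"))

#' Best (BIC-selected) fit of a DwellFitSet
#'
#' @param x a [DwellFitSet-class].
#' @return a [DwellModelFit-class].
#' @export
setGeneric("bestFit", function(x) standardGeneric("bestFit"))

#' Fitted parameters of a dwell-model fit
#'
#' @param x a [DwellModelFit-class].
#' @return data.frame of parameters (see the class documentation).
#' @export
setGeneric("fitParams", function(x) standardGeneric("fitParams"))

#' @describeIn tracks localization table
#' @export
setMethod("tracks", "TrackSet", function(x) x@data)

#' @describeIn acqMeta metadata of a TrackSet
#' @export
setMethod("acqMeta", "TrackSet", function(x) x@meta)

#' @describeIn frameInterval from metadata
#' @export
setMethod("frameInterval", "AcquisitionMetadata",
          function(x) x@exposure + x@darkInterval)

#' @describeIn frameInterval from a TrackSet's metadata
#' @export
setMethod("frameInterval", "TrackSet", function(x) frameInterval(x@meta))

#' @describeIn nTracks number of distinct track ids
#' @export
setMethod("nTracks", "TrackSet",
          function(x) length(unique(x@data$track_id)))

#' @describeIn trackIds unique ids in table order
#' @export
setMethod("trackIds", "TrackSet", function(x) unique(x@data$track_id))

#' @describeIn boundFraction C_eq slot
#' @export
setMethod("boundFraction", "SurvivalCurve", function(x) x@Ceq)

#' @describeIn survTimes time grid
#' @export
setMethod("survTimes", "SurvivalCurve", function(x) x@times)

#' @describeIn survProb surviving fraction
#' @export
setMethod("survProb", "SurvivalCurve", function(x) x@S)

#' @describeIn bestFit the selected family's fit
#' @export
setMethod("bestFit", "DwellFitSet", function(x) x@fits[[x@best]])

#' @describeIn fitParams parameter table
#' @export
setMethod("fitParams", "DwellModelFit", function(x) x@params)

setMethod("show", "AcquisitionMetadata", function(object) {
  cat(sprintf(
    "AcquisitionMetadata: %s\n  pixel %.4g um, exposure %.4g s, dark %.4g s (frame interval %.4g s), %d frames\n",
    if (nzchar(object@label)) object@label else "<unlabeled>",
    object@pixelSize, object@exposure, object@darkInterval,
    frameInterval(object), object@nFrames))
})

setMethod("show", "TrackSet", function(object) {
  n <- nTracks(object)
  cat(sprintf("TrackSet: %d track(s), %d localization(s)\n",
              n, nrow(object@data)))
  if (n > 0) {
    len <- table(object@data$track_id)
    cat(sprintf("  track length: median %d, range %d-%d frames\n",
                as.integer(stats::median(len)), min(len), max(len)))
  }
  show(object@meta)
})

setMethod("show", "SurvivalCurve", function(object) {
  cat(sprintf(
    "SurvivalCurve: %d segment(s), %d grid point(s), dt %.4g s\n  normalization: %s; correction: %s; C_eq = %.4g\n",
    object@n0, length(object@times), object@dt, object@normalization,
    object@correction, object@Ceq))
})

setMethod("show", "DwellModelFit", function(object) {
  cat(sprintf("DwellModelFit [%s]: BIC %.2f (%d points, %s)\n",
              object@family, object@BIC, object@nPoints,
              if (object@converged) "converged" else "NOT converged"))
  print(object@params, row.names = FALSE)
})

setMethod("show", "DwellFitSet", function(object) {
  cat("DwellFitSet; BIC by family:\n")
  print(round(sort(object@bicTable), 2))
  cat(sprintf("selected: %s\n", object@best))
})

setMethod("show", "BindingKinetics", function(object) {
  cat(sprintf(
    paste0("BindingKinetics:\n  C_eq = %.4g; F_NS = %.4g, F_S = %.4g\n",
           "  tau_NS = %.4g s, tau_S = %.4g s, tau_res = %.4g s\n",
           "  tau_search = %.4g s, N_trials = %.4g, k_on* = %.4g 1/s\n"),
    object@Ceq, object@FNS, object@FS, object@tauNS, object@tauS,
    object@tauRes, object@tauSearch, object@Ntrials, object@kOnStar))
  if (!is.na(object@kOn))
    cat(sprintf("  S_eq = %.4g => k_on = %.4g 1/s\n", object@Seq, object@kOn))
})

setMethod("show", "MSDCurve", function(object) {
  cat(sprintf("MSDCurve (%s): %d lag(s), %.4g-%.4g s\n",
              object@source, length(object@lags),
              min(object@lags), max(object@lags)))
})

setMethod("show", "ConfinementFit", function(object) {
  cat(sprintf(
    "ConfinementFit: D = %.4g um^2/s, R_c = %.4g um, alpha = %.3g (%s)%s\n",
    object@D, object@Rc, object@alpha, object@motionClass,
    if (length(object@flags)) paste0(" [", paste(object@flags, collapse = ","), "]")
    else ""))
})

setMethod("show", "DiffusionStates", function(object) {
  cat(sprintf("DiffusionStates: k = %d (BIC %.2f)\n", object@k, object@BIC))
  print(data.frame(weight = round(object@weights, 4),
                   mean_log10D = round(object@means, 4),
                   sd = round(object@sds, 4)), row.names = FALSE)
})
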