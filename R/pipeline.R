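#' @include AllClasses.R simulate.R survival.R dwellfit.R msd.R
NULL

.PIPELINE_KEYS <- c("seed", "out_dir", "stages", "tracks", "meta",
                    "simulate", "survival", "msd")

.cfgMeta <- function(cfg) {
  m <- cfg$meta
  if (is.null(m)) m <- list()
  AcquisitionMetadata(
    pixelSize = m$pixel_size %||% 0.1,
    exposure = m$exposure %||% 0.2,
    darkInterval = m$dark_interval %||% 0,
    nFrames = m$n_frames %||% 100L,
    label = m$label %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.cfgStates <- function(spec) {
  lapply(spec, function(s)
    MotionState(label = s$label %||% "diffusing", D = s$D %||% 0,
                confinementRadius = s$confinement_radius %||% Inf))
}

#' Run the analysis pipeline from a configuration
#'
#' Executes the requested stages in order (`simulate`, then `survival`
#' and/or `msd`) from a YAML file or an equivalent named list, writes the
#' simulated tracks (CSV) and a JSON report embedding the fully resolved
#' configuration and seed, and returns the report invisibly. All
#' randomness flows from the single `seed` key, so the same configuration
#' always produces byte-identical reports.
#'
#' Top-level keys: `seed`, `out_dir`, `stages`, `tracks` (CSV path when
#' not simulating), `meta` (`pixel_size`, `exposure`, `dark_interval`,
#' `n_frames`), `simulate` (`n_molecules`, `states`, `switch_rates`,
#' `nucleus_radius`, `localization_sigma`, `bleach_prob_per_exposure`,
#' `depth_of_field`), `survival` (`r_max`, `n_min`, `correction`,
#' `reference_tracks`, `s_eq`), `msd` (`max_lag`, `n_points`, `k_max`).
#' Unknown keys are an error.
#'
#' @param config path to a YAML configuration file, or a named list.
#' @param outDir output directory override.
#' @return the report list, invisibly; side effects: `tracks.csv` (when
#'   simulating) and `report.json` under the output directory.
#' @export
runPipeline <- function(config, outDir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  unknown <- setdiff(names(cfg), .PIPELINE_KEYS)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  seed <- cfg$seed %||% 0L
  stages <- cfg$stages %||% c("simulate", "survival", "msd")
  bad <- setdiff(stages, c("simulate", "survival", "msd"))
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  outDir <- outDir %||% cfg$out_dir %||% "."
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  meta <- .cfgMeta(cfg)
  report <- list(config = cfg, seed = seed)
  ts <- NULL

  if ("simulate" %in% stages) {
    sc <- cfg$simulate
    if (is.null(sc)) stop("config error: simulate stage requested without a 'simulate' block")
    states <- .cfgStates(sc$states %||% list(list(label = "diffusing", D = 0.5)))
    rates <- sc$switch_rates
    rates <- if (is.null(rates)) matrix(0, length(states), length(states))
             else do.call(rbind, lapply(rates, unlist))
    params <- SimulationParams(
      nMolecules = sc$n_molecules %||% 100L, states = states,
      switchRates = rates, nucleusRadius = sc$nucleus_radius %||% 1,
      frameExposure = meta@exposure, darkInterval = meta@darkInterval,
      nFrames = meta@nFrames,
      localizationSigma = sc$localization_sigma %||% 0.02,
      bleachProbPerExposure = sc$bleach_prob_per_exposure %||% 0,
      depthOfField = sc$depth_of_field %||% Inf, seed = seed)
    sim <- simulateTracks(params, pixelSize = meta@pixelSize)
    ts <- sim$tracks
    writeTracks(ts, file.path(outDir, "tracks.csv"))
    report$simulate <- list(n_molecules = params@nMolecules,
                            n_tracks = nTracks(ts),
                            true_fractions = as.list(sim$truth@trueFractions))
  } else if (!is.null(cfg$tracks)) {
    ts <- readTracks(cfg$tracks, meta)
  }

  if (any(c("survival", "msd") %in% stages) && is.null(ts))
    stop("config error: survival/msd stages need tracks ",
         "(a 'tracks' path or a simulate stage)")

  if ("survival" %in% stages) {
    sv <- cfg$survival %||% list()
    rMax <- sv$r_max %||% 0.22
    nMin <- sv$n_min %||% 3L
    segs <- classifyBound(ts, rMax = rMax, nMin = nMin)
    curve <- buildSurvival(segs, ts)
    corr <- sv$correction %||% "none"
    if (corr == "intrinsic") {
      curve <- correctPhotobleaching(curve, "intrinsic", detectionCounts(ts))
    } else if (corr %in% c("whole_reference", "immobile_fraction")) {
      if (is.null(sv$reference_tracks))
        stop("config error: ", corr, " correction needs reference_tracks")
      ref <- readTracks(sv$reference_tracks, meta)
      refCurve <- buildSurvival(classifyBound(ref, rMax = rMax,
                                              nMin = nMin), ref)
      curve <- correctPhotobleaching(curve, corr, refCurve)
    }
    fits <- fitDwellModels(curve, seed = seed)
    best <- bestFit(fits)
    kin <- if (best@family == "exp_2" && curve@Ceq > 0 && curve@Ceq < 1)
      tryCatch(deriveKinetics(best, curve@Ceq, Seq = sv$s_eq),
               error = function(e) NULL) else NULL
    report$survival <- list(
      r_max = rMax, n_min = nMin, correction = corr,
      n_segments = nrow(segs), c_eq = curve@Ceq,
      times = curve@times, S = curve@S,
      bic = as.list(fits@bicTable), best_family = fits@best,
      best_params = best@params[, c("component", "A", "tau", "beta")],
      kinetics = if (is.null(kin)) NULL else list(
        tau_ns = kin@tauNS, tau_s = kin@tauS, tau_res = kin@tauRes,
        tau_search = kin@tauSearch, n_trials = kin@Ntrials,
        k_on_star = kin@kOnStar, k_on = kin@kOn))
  }

  if ("msd" %in% stages) {
    mc <- cfg$msd %||% list()
    curve <- computeMSD(ts, maxLag = mc$max_lag %||% 20)
    dfit <- fitDiffusion(curve, nPoints = mc$n_points %||% 4)
    confFit <- if (length(curve@lags) >= 8)
      fitAlphaRc(curve) else NULL
    Ds <- trackDiffusion(ts, nPoints = mc$n_points %||% 4)
    states <- if (length(Ds) >= 10)
      tryCatch(fitLogDMixture(Ds, kMax = mc$k_max %||% 3, seed = seed),
               error = function(e) NULL) else NULL
    report$msd <- list(
      lags = curve@lags, msd = curve@msd,
      D_ensemble = dfit$D, offset = dfit$offset,
      alpha = if (is.null(confFit)) NULL else confFit@alpha,
      r_c = if (is.null(confFit)) NULL else confFit@Rc,
      motion_class = if (is.null(confFit)) NULL else confFit@motionClass,
      n_track_D = length(Ds),
      states = if (is.null(states)) NULL else list(
        k = states@k, weights = states@weights, means = states@means,
        sds = states@sds))
  }

  writeReport(report, file.path(outDir, "report.json"))
  invisible(report)
}
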