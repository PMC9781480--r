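#' @include AllClasses.R survival.R
NULL

# run expr with a temporary RNG state seeded by `seed`
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv())
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  eval.parent(substitute(expr))
}

# ---- dwell-model families -------------------------------------------------
# Each family maps a log-parameter vector to model values; amplitudes and
# time constants are fitted in log space so positivity is structural.

.dwellModelValue <- function(family, par, t) {
  p <- exp(par)
  switch(family,
    exp_1 = ,
    exp_2 = ,
    exp_3 = {
      k <- length(p) / 2
      A <- p[seq_len(k)]; tau <- p[k + seq_len(k)]
      drop(exp(-outer(t, 1 / tau)) %*% A)
    },
    power_law = p[1] * t^(-p[2]),
    power_plus_exp = p[1] * exp(-t / p[2]) + p[3] * t^(-p[4]),
    stop("unknown family: ", family))
}

.dwellNPar <- c(exp_1 = 2, exp_2 = 4, exp_3 = 6, power_law = 2,
                power_plus_exp = 4)

.dwellStart <- function(family, t, y, dt) {
  y1 <- y[1]
  tmax <- max(t)
  tspan <- function(k) {
    g <- exp(seq(log(max(dt, min(t))), log(tmax), length.out = k + 2))
    g[2:(k + 1)]
  }
  switch(family,
    exp_1 = log(c(y1, tspan(1))),
    exp_2 = log(c(rep(y1 / 2, 2), tspan(2))),
    exp_3 = log(c(rep(y1 / 3, 3), tspan(3))),
    power_law = log(c(y1 * t[1]^0.5, 0.5)),
    power_plus_exp = log(c(y1 / 2, tspan(1), y1 / 2 * t[1]^0.5, 0.5)))
}

# weighted least squares on log S for one family, with multi-start;
# returns NULL if every start fails
.fitDwellFamily <- function(family, t, y, w, nStarts = 5, seed = 0, dt) {
  logy <- log(y)
  sw <- sqrt(w / mean(w))
  resid <- function(par) {
    m <- .dwellModelValue(family, par, t)
    if (any(!is.finite(m)) || any(m <= 0)) return(rep(1e6, length(t)))
    sw * (logy - log(m))
  }
  base <- .dwellStart(family, t, y, dt)
  starts <- .withSeed(seed, {
    c(list(base),
      lapply(seq_len(max(0, nStarts - 1)), function(i)
        base + stats::rnorm(length(base), 0, 0.7)))
  })
  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, fn = resid,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, maxfev = 10000)),
      error = function(e) NULL)
    if (is.null(fit) || !fit$info %in% c(1:3, 5) ||
        !is.finite(fit$deviance)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  best
}

# Model-selection likelihood: successive grid points of a survival curve
# share segments, so residuals on S are strongly correlated and an iid
# Gaussian likelihood badly over-rewards flexible families. The
# increments of the curve (dwells falling in each grid bin, plus the
# censored tail mass) are multinomial and independent, so the BIC is
# computed from that likelihood, with the number of segments as the
# sample size.
.survBIC <- function(S, model, n0, nPar) {
  K <- length(S)
  shapeE <- S / S[1]
  nb <- n0 * c(pmax(-diff(shapeE), 0), shapeE[K])
  shapeM <- model / model[1]
  p <- c(pmax(-diff(shapeM), 1e-300), max(shapeM[K], 1e-300))
  p <- p / sum(p)
  logLik <- sum(nb * log(p))
  list(logLik = logLik, BIC = nPar * log(n0) - 2 * logLik)
}

# plain k-exponential least-squares fit of a curve (used for the
# immobile-fraction reference); returns list(A, tau) sorted by tau
.fitExpComponents <- function(t, S, k = 3, w = NULL, seed = 0) {
  ok <- is.finite(S) & S > 0
  t <- t[ok]; S <- S[ok]
  w <- if (is.null(w)) rep(1, length(t)) else pmax(w[ok], 1e-12)
  family <- paste0("exp_", k)
  fit <- .fitDwellFamily(family, t, S, w, nStarts = 5, seed = seed,
                         dt = min(t))
  if (is.null(fit)) stop("reference exponential fit did not converge")
  p <- exp(fit$par)
  A <- p[seq_len(k)]; tau <- p[k + seq_len(k)]
  o <- order(tau)
  list(A = A[o], tau = tau[o])
}

#' Fit dwell-time models to a survival curve and select by BIC
#'
#' Fits exponential mixtures with 1-3 components
#' (`S(t) = sum_i A_i exp(-t / tau_i)`), a power law (`A t^-beta`), and a
#' power-law + exponential hybrid (`A_1 exp(-t/tau_1) + A_2 t^-beta`) to
#' the (corrected) survival curve, by weighted least squares on log S with
#' weights proportional to the segment counts at each grid point. Each
#' family is fitted from 5 multi-start initializations (time constants
#' log-spaced between the frame interval and the curve span; fixed seed).
#' Families are compared by the Bayesian information criterion
#' `k ln(n0) - 2 lnL`, computed uniformly across families from the
#' multinomial likelihood of the per-bin dwell counts implied by the
#' fitted curve (with the censored tail as its own bin and the number of
#' segments n0 as the sample size); successive survival grid points share
#' segments, so a likelihood built on independent increments is used
#' rather than one on the correlated log-S residuals. The lowest-BIC
#' family is selected. As an identifiability guard the hybrid is only eligible if
#' its BIC beats both of its parents (single exponential and power law) by
#' at least 2. Leading grid points on the initial plateau (below the
#' shortest observable dwell) carry no information and are dropped before
#' fitting.
#'
#' @param curve a [SurvivalCurve-class] with at least 8 usable grid points
#'   (typically photobleaching-corrected).
#' @param families character, subset of `"exp_1"`, `"exp_2"`, `"exp_3"`,
#'   `"power_law"`, `"power_plus_exp"`.
#' @param nStarts number of multi-start initializations per family.
#' @param seed RNG seed for the multi-start jitter.
#' @return a [DwellFitSet-class]; families whose fits fail to converge are
#'   excluded from selection (an error is raised if all fail).
#' @seealso [deriveKinetics()]
#' @export
fitDwellModels <- function(curve,
                           families = c("exp_1", "exp_2", "exp_3",
                                        "power_law", "power_plus_exp"),
                           nStarts = 5, seed = 0) {
  stopifnot(is(curve, "SurvivalCurve"))
  families <- match.arg(families, several.ok = TRUE)
  t <- curve@times; S <- curve@S; w <- curve@counts
  ok <- is.finite(S) & S > 0 & w > 0
  t <- t[ok]; S <- S[ok]; w <- w[ok]
  # drop the leading plateau: grid points before the shortest observable
  # dwell, identified as the flat prefix of the survivor counts
  drops <- which(diff(w) < 0)
  i0 <- if (length(drops)) drops[1] else 1L
  if (i0 < length(t)) {
    t <- t[i0:length(t)]; S <- S[i0:length(S)]; w <- w[i0:length(w)]
  }
  if (length(t) < 8)
    stop("need at least 8 usable grid points, got ", length(t))
  fits <- list()
  for (fam in families) {
    raw <- .fitDwellFamily(fam, t, S, w, nStarts = nStarts, seed = seed,
                           dt = curve@dt)
    if (is.null(raw)) next
    m <- .dwellModelValue(fam, raw$par, t)
    r <- log(S) - log(m)
    ic <- .survBIC(S, m, curve@n0, .dwellNPar[[fam]])
    p <- exp(raw$par)
    if (fam %in% c("exp_1", "exp_2", "exp_3")) {
      k <- length(p) / 2
      A <- p[seq_len(k)]; tau <- p[k + seq_len(k)]
      o <- order(tau)
      params <- data.frame(component = paste0("exp", seq_len(k)),
                           A = A[o], tau = tau[o], beta = NA_real_)
      fractions <- A[o] / sum(A)
    } else if (fam == "power_law") {
      params <- data.frame(component = "power", A = p[1], tau = NA_real_,
                           beta = p[2])
      fractions <- numeric(0)
    } else {
      params <- data.frame(component = c("exp", "power"),
                           A = c(p[1], p[3]), tau = c(p[2], NA),
                           beta = c(NA, p[4]))
      fractions <- c(exp = p[1], power = p[3]) / (p[1] + p[3])
    }
    fits[[fam]] <- new("DwellModelFit", family = fam, params = params,
                       fractions = fractions, Ceq = m[1], BIC = ic$BIC,
                       logLik = ic$logLik, nPoints = length(t),
                       converged = TRUE,
                       residSummary = c(rmse = sqrt(mean(r^2)),
                                        max_abs = max(abs(r))))
  }
  if (!length(fits)) stop("all dwell-model fits failed to converge")
  bic <- vapply(fits, function(f) f@BIC, numeric(1))
  eligible <- bic
  if ("power_plus_exp" %in% names(eligible)) {
    parents <- bic[intersect(c("exp_1", "power_law"), names(bic))]
    if (!length(parents) ||
        bic[["power_plus_exp"]] > min(parents) - 2)
      eligible <- eligible[names(eligible) != "power_plus_exp"]
  }
  best <- names(eligible)[which.min(eligible)]
  new("DwellFitSet", fits = fits, best = best, bicTable = bic)
}

#' Derive binding kinetics from a bi-exponential dwell fit
#'
#' Interprets the two bound sub-states of an `exp_2` fit as non-specific
#' (shorter residence) and specific (longer residence) chromatin binding
#' and derives: the average residence time
#' `tau_res = F_NS/(F_NS+F_S) tau_NS + F_S/(F_NS+F_S) tau_S`; the number
#' of sites sampled per search `N_trials = (F_S + F_NS)/F_S`; the search
#' time `tau_search = (1 - C_eq)/C_eq * tau_res`; the pseudo on-rate
#' `k_on* = 1/tau_search`; and, when the accessible-motif fraction `Seq`
#' is supplied, the true on-rate `k_on = k_on*/Seq`.
#'
#' @param fit a [DwellModelFit-class] of family `exp_2`. Power-law fits
#'   are refused: no specific residence times can be estimated from
#'   power-law fits.
#' @param Ceq bound fraction in (0, 1), typically [boundFraction()] of the
#'   fitted curve.
#' @param Seq optional accessible-motif fraction in (0, 1\].
#' @return a [BindingKinetics-class].
#' @examples
#' fit <- new("DwellModelFit", family = "exp_2",
#'            params = data.frame(component = c("exp1", "exp2"),
#'                                A = c(0.75, 0.25), tau = c(1, 9),
#'                                beta = NA_real_),
#'            fractions = c(0.75, 0.25), Ceq = 0.25, BIC = 0, logLik = 0,
#'            nPoints = 10L, converged = TRUE, residSummary = c(rmse = 0))
#' deriveKinetics(fit, Ceq = 0.25)  # tau_res 3 s, tau_search 9 s
#' @export
deriveKinetics <- function(fit, Ceq, Seq = NULL) {
  stopifnot(is(fit, "DwellModelFit"))
  if (fit@family == "power_law")
    stop("No specific residence times can be estimated from Power Law fits")
  if (fit@family != "exp_2")
    stop("kinetics derivation requires a bi-exponential (exp_2) fit; got ",
         fit@family)
  if (!is.finite(Ceq) || Ceq <= 0 || Ceq >= 1)
    stop("Ceq must lie strictly inside (0, 1); got ", Ceq)
  taus <- fit@params$tau
  fr <- fit@fractions / sum(fit@fractions)
  iNS <- which.min(taus); iS <- which.max(taus)
  tauNS <- taus[iNS]; tauS <- taus[iS]
  FNS <- fr[iNS]; FS <- fr[iS]
  tauRes <- FNS * tauNS + FS * tauS
  stopifnot(tauRes >= min(tauNS, tauS) - 1e-12,
            tauRes <= max(tauNS, tauS) + 1e-12)
  tauSearch <- (1 - Ceq) / Ceq * tauRes
  kOnStar <- 1 / tauSearch
  if (!is.null(Seq)) {
    if (Seq <= 0 || Seq > 1) stop("Seq must be in (0, 1]")
    kOn <- kOnStar / Seq
  } else {
    Seq <- NA_real_; kOn <- NA_real_
  }
  new("BindingKinetics", Ceq = Ceq, FNS = unname(FNS), FS = unname(FS),
      tauNS = tauNS, tauS = tauS, tauRes = unname(tauRes),
      tauSearch = unname(tauSearch), Ntrials = unname((FS + FNS) / FS),
      kOnStar = unname(kOnStar), Seq = Seq, kOn = unname(kOn),
      kOffNS = 1 / tauNS, kOffS = 1 / tauS)
}
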