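# Damped-harmonic-oscillator model of nucleosome phasing:
# WPS(d) = exp(-kappa d) + A exp(-lambda d) cos(omega d - phi) + b,
# fitted by two-stage non-linear least squares.

#' Construct a named oscillator parameter vector
#'
#' @param kappa exponential trend decay constant, 1/bp (>= 0).
#' @param A oscillation amplitude, WPS units.
#' @param lambda oscillation decay rate, 1/bp (>= 0).
#' @param omega angular frequency, radians/bp (> 0); period = 2*pi/omega.
#' @param phi cosine phase displacement, radians (wrapped to [0, 2*pi)).
#' @param b residual offset, WPS units.
#' @return named numeric of length 6.
#' @export
oscillatorParams <- function(kappa, A, lambda, omega, phi, b) {
  stopifnot(kappa >= 0, lambda >= 0, omega > 0)
  c(kappa = kappa, A = A, lambda = lambda, omega = omega,
    phi = phi %% (2 * pi), b = b)
}

#' Evaluate the phasing model
#'
#' WPS(d) = exp(-kappa d) + A exp(-lambda d) cos(omega d - phi) + b, for
#' signed distance d (bp from the TSS). Note the first term carries no
#' amplitude coefficient, so at d < 0 it rises above 1; the model is
#' evaluated exactly as written.
#'
#' @param params named numeric from [oscillatorParams()] (or an
#'   [OscillatorFit-class], whose parameters are used).
#' @param d numeric distances in bp.
#' @return numeric model values.
#' @export
modelPredict <- function(params, d) {
  if (is(params, "OscillatorFit")) params <- oscParams(params)
  exp(-params[["kappa"]] * d) +
    params[["A"]] * exp(-params[["lambda"]] * d) *
      cos(params[["omega"]] * d - params[["phi"]]) +
    params[["b"]]
}

#' Two-stage non-linear least-squares fit of the phasing model
#'
#' Stage 1 fits the exponential trend exp(-kappa d) + b; stage 2 fits the
#' damped oscillator A exp(-lambda d) cos(omega d - phi) to the stage-1
#' residuals, multi-starting the phase at 0, pi/2, pi and 3*pi/2 to guard
#' the cosine's nonconvexity (best residual sum of squares wins; ties go
#' to the smallest lambda). Box bounds keep the period in an 80-400 bp
#' band and the decay rates in [0, 0.1]. The amplitude is sign-normalised
#' to A >= 0 (phi shifted by pi when needed) and phi wrapped to [0, 2*pi).
#' Optimiser failure yields `converged = FALSE`, never an error.
#'
#' Because stage 1 sees the oscillation as unmodelled structure, the pure
#' two-stage estimates of kappa and b carry a small leakage bias; with
#' `polish = TRUE` (default) a final joint least-squares pass over all six
#' coefficients, initialised at the two-stage estimates, removes it. The
#' staged fit then serves as the convergence aid it is meant to be.
#'
#' @param profile a [WpsProfile-class] (its smoothed track is fitted) or a
#'   numeric vector named by distance.
#' @param fitRegion distance window in bp (default c(-185, 925): the NFR
#'   plus the first five downstream nucleosomes).
#' @param minPoints minimum observations required in the region.
#' @param polish run the joint refinement pass (default TRUE).
#' @return an [OscillatorFit-class].
#' @export
fitTwoStage <- function(profile, fitRegion = c(-185, 925),
                        minPoints = 500L, polish = TRUE) {
  if (is(profile, "WpsProfile")) {
    d <- wpsDistance(profile)
    y <- wpsSmoothed(profile)
  } else {
    d <- as.numeric(names(profile))
    y <- as.numeric(profile)
  }
  sel <- d >= fitRegion[1] & d <= fitRegion[2] & !is.na(y)
  d <- d[sel]; y <- y[sel]
  if (length(d) < minPoints)
    stop("profile does not cover the fit region (", length(d),
         " points, need >= ", minPoints, ")")
  ctrl <- minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-8,
                                     maxfev = 10000)
  dat <- data.frame(d = d, y = y)

  stage1 <- tryCatch(
    minpack.lm::nlsLM(y ~ exp(-kappa * d) + b, data = dat,
                      start = list(kappa = 1e-3, b = mean(y)),
                      lower = c(0, -Inf), upper = c(0.1, Inf),
                      control = ctrl),
    error = function(e) NULL)
  if (is.null(stage1)) {
    pars <- oscillatorParams(0, 0, 0, 2 * pi / 185, 0, mean(y))
    return(new("OscillatorFit", params = pars, converged = FALSE,
               rmse = NA_real_, stage1Rmse = NA_real_,
               fitRegion = as.numeric(fitRegion),
               nPoints = length(d)))
  }
  c1 <- stats::coef(stage1)
  resid1 <- y - (exp(-c1[["kappa"]] * d) + c1[["b"]])
  stage1Rmse <- sqrt(mean(resid1^2))

  rng <- diff(range(y))
  A0 <- max(abs(resid1))
  rdat <- data.frame(d = d, r = resid1)
  best <- NULL
  for (phi0 in c(0, pi / 2, pi, 3 * pi / 2)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        r ~ A * exp(-lambda * d) * cos(omega * d - phi), data = rdat,
        start = list(A = A0, lambda = 1e-3, omega = 2 * pi / 185,
                     phi = phi0),
        lower = c(-10 * max(rng, 1e-12), 0, 2 * pi / 400, -2 * pi),
        upper = c(10 * max(rng, 1e-12), 0.1, 2 * pi / 80, 4 * pi),
        control = ctrl),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(stats::resid(fit)^2)
    lam <- stats::coef(fit)[["lambda"]]
    if (is.null(best) || sse < best$sse - 1e-12 ||
        (abs(sse - best$sse) <= 1e-12 && lam < best$lambda))
      best <- list(fit = fit, sse = sse, lambda = lam)
  }
  if (is.null(best)) {
    pars <- oscillatorParams(max(c1[["kappa"]], 0), 0, 0, 2 * pi / 185, 0,
                             c1[["b"]])
    return(new("OscillatorFit", params = pars, converged = FALSE,
               rmse = stage1Rmse, stage1Rmse = stage1Rmse,
               fitRegion = as.numeric(fitRegion), nPoints = length(d)))
  }
  c2 <- stats::coef(best$fit)
  kap <- max(c1[["kappa"]], 0); bb <- c1[["b"]]
  A <- c2[["A"]]; lam <- max(c2[["lambda"]], 0)
  om <- c2[["omega"]]; phi <- c2[["phi"]]
  if (polish) {
    joint <- tryCatch(
      minpack.lm::nlsLM(
        y ~ exp(-kappa * d) + A * exp(-lambda * d) * cos(omega * d - phi)
            + b,
        data = dat,
        start = list(kappa = kap, A = A, lambda = lam, omega = om,
                     phi = phi, b = bb),
        lower = c(0, -10 * max(rng, 1e-12), 0, 2 * pi / 400, -2 * pi,
                  -Inf),
        upper = c(0.1, 10 * max(rng, 1e-12), 0.1, 2 * pi / 80, 4 * pi,
                  Inf),
        control = ctrl),
      error = function(e) NULL)
    if (!is.null(joint)) {
      cj <- stats::coef(joint)
      kap <- cj[["kappa"]]; A <- cj[["A"]]; lam <- cj[["lambda"]]
      om <- cj[["omega"]]; phi <- cj[["phi"]]; bb <- cj[["b"]]
    }
  }
  if (A < 0) { A <- -A; phi <- phi + pi } # cos(x - (phi+pi)) = -cos(x - phi)
  pars <- oscillatorParams(kap, A, lam, om, phi, bb)
  rmse <- sqrt(mean((y - modelPredict(pars, d))^2))
  new("OscillatorFit", params = pars, converged = TRUE, rmse = rmse,
      stage1Rmse = stage1Rmse, fitRegion = as.numeric(fitRegion),
      nPoints = length(d))
}

.fitParamMatrix <- function(fits, convergedOnly = TRUE) {
  keep <- if (convergedOnly) vapply(fits, isConverged, logical(1))
          else rep(TRUE, length(fits))
  mat <- do.call(rbind, lapply(fits[keep], oscParams))
  if (!is.null(mat)) mat <- cbind(mat, period = 2 * pi / mat[, "omega"])
  mat
}

#' Coefficient of variation of fitted parameters across samples
#'
#' CV = SD / |mean| per parameter (including the derived period), over
#' converged fits only. Parameters with mean 0 are flagged NA.
#'
#' @param fits list of [OscillatorFit-class] objects.
#' @return named numeric of CVs over kappa, A, lambda, omega, phi, b and
#'   period.
#' @export
parameterCv <- function(fits) {
  mat <- .fitParamMatrix(fits)
  if (is.null(mat) || nrow(mat) < 3L) stop("need >= 3 converged fits")
  apply(mat, 2, function(v)
    if (mean(v) == 0) NA_real_ else stats::sd(v) / abs(mean(v)))
}

#' Correlate fitted parameters with a per-sample covariate
#'
#' Pearson r, two-sided p and BH q per parameter; non-converged fits and
#' missing covariate values are dropped pairwise.
#'
#' @param fits list of [OscillatorFit-class], one per sample.
#' @param covariate numeric per sample (same order as `fits`).
#' @return data.frame: parameter, r, p, q.
#' @export
parameterCorrelates <- function(fits, covariate) {
  conv <- vapply(fits, isConverged, logical(1))
  ok <- conv & !is.na(covariate)
  if (sum(ok) < 3L) stop("need >= 3 paired observations")
  if (stats::sd(covariate[ok]) == 0) stop("zero-variance covariate")
  mat <- .fitParamMatrix(fits[ok], convergedOnly = FALSE)
  res <- apply(mat, 2, function(v) {
    if (stats::sd(v) == 0) return(c(r = NA_real_, p = NA_real_))
    ct <- stats::cor.test(v, covariate[ok], method = "pearson")
    c(r = unname(ct$estimate), p = ct$p.value)
  })
  out <- data.frame(parameter = colnames(mat), r = res["r", ],
                    p = res["p", ])
  out$q <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Summarise fitted periods over a cohort
#'
#' @param fits list of [OscillatorFit-class].
#' @return named numeric: median, mean, sd of the period (bp) over
#'   converged fits, plus n_converged.
#' @export
periodSummary <- function(fits) {
  conv <- vapply(fits, isConverged, logical(1))
  per <- vapply(fits[conv], oscPeriod, numeric(1))
  c(median = stats::median(per), mean = mean(per), sd = stats::sd(per),
    n_converged = sum(conv))
}
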