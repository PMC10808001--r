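#' Instrument-trace analyses
#'
#' The small closed-form analyses behind the membrane-biophysics readouts:
#' Langmuir-monolayer compression modulus, single-exponential relaxation
#' fitting, heteronuclear NOE ratios, DPH fluorescence anisotropy, and DSC
#' thermogram baseline correction with peak extraction.
#'
#' @name biophysics
NULL

#' Compression modulus of a Langmuir isotherm
#'
#' Cs^-1 = -A * (dpi/dA), evaluated by central differences on the
#' (optionally Savitzky-Golay smoothed) pressure trace. Lower values mean
#' softer, more compressible monolayers.
#'
#' @param A mean molecular area (A^2/molecule), monotone (decreasing during
#'   compression).
#' @param pi_mNm surface pressure (mN/m), same length as `A`.
#' @param smoothing `"none"` (default) or `"savitzky-golay"`.
#' @param sg_window,sg_order Savitzky-Golay filter length (odd) and
#'   polynomial order.
#' @param sort if TRUE, non-monotone input is sorted by area; otherwise
#'   non-monotone A is an error.
#' @return data.frame with `A`, `pi`, `cs_inv` (mN/m).
#' @export
compression_modulus <- function(A, pi_mNm,
                                smoothing = c("none", "savitzky-golay"),
                                sg_window = 11L, sg_order = 3L, sort = FALSE) {
  smoothing <- match.arg(smoothing)
  stopifnot(length(A) == length(pi_mNm), length(A) >= 5L)
  dA <- diff(A)
  if (any(dA >= 0) && any(dA <= 0)) {
    if (!sort) stop("mean molecular area is not monotone; pass sort = TRUE")
    o <- order(A)
    A <- A[o]; pi_mNm <- pi_mNm[o]
  }
  p <- pi_mNm
  if (smoothing == "savitzky-golay") {
    w <- min(sg_window, if (length(p) %% 2L == 1L) length(p) else length(p) - 1L)
    p <- signal::sgolayfilt(p, p = sg_order, n = w)
  }
  n <- length(A)
  dpda <- numeric(n)
  dpda[1] <- (p[2] - p[1]) / (A[2] - A[1])
  dpda[n] <- (p[n] - p[n - 1]) / (A[n] - A[n - 1])
  if (n > 2) dpda[2:(n - 1)] <- (p[3:n] - p[1:(n - 2)]) / (A[3:n] - A[1:(n - 2)])
  data.frame(A = A, pi = pi_mNm, cs_inv = -A * dpda)
}

#' Mean compression modulus over a surface-pressure band
#'
#' @param cs data.frame from [compression_modulus()].
#' @param band pressure band in mN/m; the default 25-35 is the
#'   physiological range of membrane surface pressures.
#' @return mean Cs^-1 over points whose pressure lies inside the band.
#' @export
mean_cs_inv <- function(cs, band = c(25, 35)) {
  sel <- cs$pi >= band[1] & cs$pi <= band[2]
  if (!any(sel)) stop("no isotherm points inside the pressure band")
  mean(cs$cs_inv[sel])
}

#' Fit a single-exponential decay h = A * exp(-R * t)
#'
#' Nonlinear least squares initialized from a log-linear regression on the
#' positive heights. Used for NMR R1/R2 relaxation series.
#'
#' @param t delay times (s or ms; units are the caller's).
#' @param h peak heights.
#' @return list with `A`, `R` (reciprocal of the time unit), `residuals`,
#'   `sigma` (residual standard error), `decaying` (FALSE when the best-fit
#'   rate is not positive; flagged with a warning).
#' @export
fit_exponential_decay <- function(t, h) {
  stopifnot(length(t) == length(h), length(t) >= 3L,
            length(unique(t)) >= 2L, all(t >= 0))
  pos <- h > 0
  init <- if (sum(pos) >= 2L) {
    cf <- stats::coef(stats::lm(log(h[pos]) ~ t[pos]))
    list(A = exp(cf[[1]]), R = -cf[[2]])
  } else list(A = max(abs(h)), R = 1 / (max(t) - min(t) + .Machine$double.eps))
  fit <- tryCatch(
    minpack.lm::nlsLM(h ~ A * exp(-R * t),
                      start = list(A = init$A, R = init$R),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = identity)
  if (inherits(fit, "error")) {
    # degenerate surfaces (e.g. constant heights): profile R directly with
    # the conditionally optimal amplitude A(R) = sum(h e)/sum(e^2)
    rss <- function(R) {
      e <- exp(-R * t)
      A <- sum(h * e) / sum(e * e)
      sum((h - A * e)^2)
    }
    span <- 10 / (max(t) - min(t))
    R <- stats::optimize(rss, c(-span, span))$minimum
    if (abs(R) < 1e-8) R <- 0
    e <- exp(-R * t)
    A <- sum(h * e) / sum(e * e)
    res <- h - A * e
    out <- list(A = A, R = R, residuals = res,
                sigma = sqrt(sum(res^2) / max(1, length(t) - 2)),
                decaying = R > 0)
    if (!out$decaying) warning("fitted rate is not positive: data do not decay")
    return(out)
  }
  co <- stats::coef(fit)
  decaying <- co[["R"]] > 0
  if (!decaying) warning("fitted rate is not positive: data do not decay")
  list(A = co[["A"]], R = co[["R"]], residuals = stats::residuals(fit),
       sigma = stats::sigma(fit), decaying = decaying)
}

#' Heteronuclear NOE ratio I/I0
#'
#' @param I on-resonance (saturated) intensities.
#' @param I0 off-resonance (reference) intensities; zeros are an error.
#' @param sigma_I,sigma_I0 optional intensity uncertainties for first-order
#'   error propagation.
#' @return numeric ratio vector; if uncertainties are given, a data.frame
#'   with `ratio` and `sigma`.
#' @export
het_noe <- function(I, I0, sigma_I = NULL, sigma_I0 = NULL) {
  stopifnot(length(I) == length(I0))
  if (any(I0 == 0)) stop("I0 = 0 at position(s) ",
                         paste(which(I0 == 0), collapse = ", "))
  r <- I / I0
  if (is.null(sigma_I) && is.null(sigma_I0)) return(r)
  if (is.null(sigma_I)) sigma_I <- 0
  if (is.null(sigma_I0)) sigma_I0 <- 0
  data.frame(ratio = r,
             sigma = abs(r) * sqrt((sigma_I / I)^2 + (sigma_I0 / I0)^2))
}

#' Fluorescence anisotropy from channel intensities
#'
#' r = (I_par - g * I_perp) / (I_par + 2 * g * I_perp), with the gamma
#' factor g correcting the detector sensitivity difference (default 1.171,
#' calibrated with DPH in methanol).
#'
#' @param I_par,I_perp parallel/perpendicular channel intensities (>= 0).
#' @param g gamma factor.
#' @return anisotropy value(s).
#' @export
anisotropy <- function(I_par, I_perp, g = 1.171) {
  if (any(I_par < 0) || any(I_perp < 0)) stop("negative intensities")
  denom <- I_par + 2 * g * I_perp
  if (any(denom <= 0)) stop("non-positive denominator")
  (I_par - g * I_perp) / denom
}

#' DSC thermogram baseline correction and peak extraction
#'
#' Subtracts the mean of the last `baseline_n` points (taken well beyond
#' the phase transition), reports the dominant transition temperature Tm as
#' the global maximum of the corrected signal, and any additional local
#' maxima above a prominence threshold as secondary peaks.
#'
#' @param temperature temperature axis, degrees C, strictly increasing.
#' @param cp heat-capacity signal, same length.
#' @param baseline_n number of trailing points averaged for the baseline
#'   (default 15).
#' @param min_prominence secondary peaks must rise at least this fraction of
#'   the main corrected peak height above their surroundings (default 0.1).
#' @return list with `Tm`, `peak_height` (baseline-corrected), `baseline`,
#'   `corrected` (full corrected trace), `secondary_peaks` (data.frame of
#'   `T`, `height`), `boundary` (TRUE when the global maximum sits at the
#'   trace boundary, flagged unreliable).
#' @export
thermogram_peak <- function(temperature, cp, baseline_n = 15L,
                            min_prominence = 0.1) {
  n <- length(temperature)
  stopifnot(length(cp) == n, n >= baseline_n + 5L,
            all(diff(temperature) > 0))
  baseline <- mean(cp[(n - baseline_n + 1L):n])
  corr <- cp - baseline
  imax <- which.max(corr)
  boundary <- imax == 1L || imax == n
  if (boundary) warning("thermogram maximum at trace boundary: unreliable Tm")
  pk <- tryCatch(
    pracma::findpeaks(corr, minpeakheight = min_prominence * corr[imax],
                      minpeakdistance = 3L),
    error = function(e) NULL)
  sec <- if (!is.null(pk)) {
    idx <- pk[, 2]
    idx <- idx[idx != imax]
    data.frame(T = temperature[idx], height = corr[idx])
  } else data.frame(T = numeric(0), height = numeric(0))
  list(Tm = temperature[imax], peak_height = corr[imax], baseline = baseline,
       corrected = corr, secondary_peaks = sec, boundary = boundary)
}
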