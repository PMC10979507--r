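## Second-order cumulant pipeline: excitation-energy autocorrelation ->
## spectral density J(w) -> line shape g(t) -> homogeneous spectrum ->
## static-disorder-broadened absorption, with window averaging.
##
## Unit conventions (hbar = 1): energies/frequencies in cm^-1, times
## converted from fs to "cm" via t_cm = 2 pi c t so that a phase is
## nu[cm^-1] * t[cm].

#' Excitation-energy trajectory
#'
#' @param times Uniform time grid, fs (length >= 2).
#' @param energies Excitation energy U(t) per frame, eV.
#' @param temperature Temperature, K.
#' @return List of class `EnergyTrajectory`.
#' @export
energyTrajectory <- function(times, energies, temperature = 300) {
  stopifnot(length(times) >= 2, length(times) == length(energies))
  dt <- diff(times)
  if (max(abs(dt - dt[1])) > 1e-9 * max(abs(dt)))
    stop("data error: non-uniform time grid")
  structure(list(times = as.numeric(times), energies = as.numeric(energies),
                 temperature = temperature, dt = dt[1]),
            class = "EnergyTrajectory")
}

#' Fluctuation autocorrelation of an energy trajectory
#'
#' Unbiased lag estimator of `c_UU(t) = <dU(t) dU(0)>` with
#' `dU = U - <U>`, computed by FFT; `c_UU(0)` equals the sample variance
#' (1/N normalization).
#'
#' @param trajectory An [energyTrajectory()].
#' @param maxLagFraction Keep lags up to this fraction of the series length
#'   (long-lag unbiased estimates are noisy).
#' @return List with `times` (lag grid, fs), `acf` (eV^2), `meanEnergy`
#'   (eV) and the trajectory `temperature`.
#' @export
energyAutocorrelation <- function(trajectory, maxLagFraction = 0.5) {
  u <- trajectory$energies - mean(trajectory$energies)
  n <- length(u)
  npad <- 2^ceiling(log2(2 * n))
  f <- stats::fft(c(u, rep(0, npad - n)))
  s <- Re(stats::fft(Mod(f)^2, inverse = TRUE)) / npad
  lags <- 0:(floor(maxLagFraction * (n - 1)))
  acf <- s[lags + 1] / (n - lags)
  list(times = lags * trajectory$dt, acf = acf,
       meanEnergy = mean(trajectory$energies),
       temperature = trajectory$temperature)
}

#' Damp an autocorrelation to zero over a time window
#'
#' Multiplies by a cosine-squared switch that is 1 at t = 0, monotone on
#' the taper, and exactly 0 from `window` on.
#'
#' @param correlation Output of [energyAutocorrelation()].
#' @param window Damping window, fs (must not exceed the series duration).
#' @return Same structure with damped `acf`, truncated at the window.
#' @export
dampCorrelation <- function(correlation, window = 10000) {
  if (window <= 0) stop("parameter error: window must be positive")
  tmax <- max(correlation$times)
  if (window > tmax + 1e-9)
    stop("parameter error: damping window exceeds the series duration")
  keep <- correlation$times <= window
  t <- correlation$times[keep]
  sw <- cos(pi / 2 * t / window)^2
  sw[t >= window] <- 0
  out <- correlation
  out$times <- t
  out$acf <- correlation$acf[keep] * sw
  out
}

#' Spectral density from a damped autocorrelation
#'
#' `J(w) = beta w int_0^inf c_UU(t) cos(w t) dt` (classical prefactor;
#' equal to the standard `(beta w / 2)` times the full-line transform of
#' the even correlation function). `prefactor = "tanh"` replaces `beta w/2`
#' by `tanh(beta w / 2)` (a common quantum-correction variant); peak
#' positions are unaffected.
#'
#' @param correlation Damped output of [dampCorrelation()].
#' @param temperature Temperature, K (defaults to the trajectory's).
#' @param frequencies Output grid, cm^-1 (default: up to 4000 cm^-1 or
#'   Nyquist, whichever is smaller).
#' @param prefactor "classical" or "tanh".
#' @return List of class `SpectralDensity` with `frequencies` (cm^-1) and
#'   `values` (cm^-1).
#' @export
spectralDensity <- function(correlation, temperature = NULL,
                            frequencies = NULL,
                            prefactor = c("classical", "tanh")) {
  prefactor <- match.arg(prefactor)
  temperature <- temperature %||% correlation$temperature
  if (temperature <= 0) stop("parameter error: temperature must be positive")
  dtcm <- (correlation$times[2] - correlation$times[1]) * .const$fs_to_cm
  nyq <- pi / dtcm
  if (is.null(frequencies))
    frequencies <- seq(1, min(4000, floor(nyq)), by = 1)
  tcm <- correlation$times * .const$fs_to_cm
  c2 <- correlation$acf * .const$eV_cm1^2
  wts <- rep(dtcm, length(tcm)); wts[c(1, length(tcm))] <- dtcm / 2
  ct <- as.numeric(cos(outer(frequencies, tcm)) %*% (c2 * wts))
  beta <- 1 / (.const$kB_cm1 * temperature)
  pf <- switch(prefactor,
    classical = beta * frequencies,
    tanh = 2 * tanh(beta * frequencies / 2))
  J <- pf * ct
  if (any(!is.finite(J))) stop("numerical error: non-finite spectral density")
  structure(list(frequencies = frequencies, values = J,
                 temperature = temperature, prefactor = prefactor),
            class = "SpectralDensity")
}

#' Reorganization energy of a spectral density
#'
#' `lambda = (1/pi) int J(w)/w dw`, cm^-1.
#'
#' @param density A `SpectralDensity`.
#' @return Scalar, cm^-1.
#' @export
reorganizationEnergy <- function(density) {
  w <- density$frequencies
  dw <- c(diff(w), utils::tail(diff(w), 1))
  sum(density$values / w * dw) / pi
}

#' Second-order cumulant line shape function g(t)
#'
#' `g(t) = (1/pi) int dw J(w)/w^2 [coth(beta w / 2)(1 - cos wt) - i sin wt]`
#' evaluated by quadrature over the density grid. `g(0) = 0` and
#' `g'(0) = -i lambda` with lambda the reorganization energy.
#'
#' @param density A `SpectralDensity`.
#' @param temperature Temperature, K (defaults to the density's).
#' @param times Time grid, fs.
#' @return List with `times` (fs) and complex `g`.
#' @export
lineshapeG <- function(density, temperature = NULL, times) {
  temperature <- temperature %||% density$temperature
  if (temperature <= 0) stop("parameter error: temperature must be positive")
  w <- density$frequencies
  if (any(w <= 0)) stop("quadrature error: J must be sampled on w > 0")
  beta <- 1 / (.const$kB_cm1 * temperature)
  dw <- c(diff(w), utils::tail(diff(w), 1))
  Jw2 <- density$values / w^2 * dw / pi
  cth <- 1 / tanh(beta * w / 2)
  tcm <- times * .const$fs_to_cm
  g <- complex(length.out = length(tcm))
  chunk <- 512L
  for (i0 in seq(1, length(tcm), by = chunk)) {
    ii <- i0:min(i0 + chunk - 1L, length(tcm))
    wt <- outer(w, tcm[ii])
    re <- as.numeric(crossprod(Jw2 * cth, 1 - cos(wt)))
    im <- -as.numeric(crossprod(Jw2, sin(wt)))
    g[ii] <- complex(real = re, imaginary = im)
  }
  list(times = times, g = g, temperature = temperature)
}

#' Homogeneous absorption spectrum from a line shape function
#'
#' Half-Fourier transform of `exp(-g(t))` centered at the mean excitation
#' energy: `sigma(w) = Re int_0^inf dt exp(-i(w - w_mean) t) exp(-g(t))`,
#' normalized to unit maximum. If `exp(-g)` has not decayed at the end of
#' the grid, a cosine-squared window is applied automatically (with a
#' warning).
#'
#' @param g Output of [lineshapeG()].
#' @param meanEnergy Mean excitation energy, eV.
#' @param frequencies Output grid, cm^-1 (default: +-3000 cm^-1 around the
#'   mean).
#' @return List of class `AbsorptionSpectrum` with `frequencies` (cm^-1)
#'   and `intensity` (max 1).
#' @export
homogeneousSpectrum <- function(g, meanEnergy, frequencies = NULL) {
  if (abs(g$g[1]) > 1e-10) stop("g(0) must be 0")
  nu0 <- meanEnergy * .const$eV_cm1
  if (is.null(frequencies))
    frequencies <- seq(nu0 - 3000, nu0 + 3000, by = 2)
  tcm <- g$times * .const$fs_to_cm
  f <- exp(-g$g)
  tailAmp <- max(Mod(utils::tail(f, max(1L, length(f) %/% 50))))
  if (tailAmp > 0.01 * max(Mod(f))) {
    warning("exp(-g) not decayed at the end of the time grid; applying a ",
            "cosine-squared window")
    f <- f * cos(pi / 2 * seq(0, 1, length.out = length(f)))^2
  }
  wts <- rep(1, length(tcm)); wts[c(1, length(tcm))] <- 0.5
  dtcm <- tcm[2] - tcm[1]
  dnu <- outer(frequencies - nu0, tcm)
  I <- as.numeric((cos(dnu) %*% (Re(f) * wts)) + (sin(dnu) %*% (Im(f) * wts))) * dtcm
  ## Re[e^{-i dnu t} f] = cos * Re f + sin * Im f
  I <- pmax(I, 0)
  if (max(I) <= 0) stop("numerical error: empty spectrum")
  structure(list(frequencies = frequencies, intensity = I / max(I),
                 meanEnergy = meanEnergy),
            class = "AbsorptionSpectrum")
}

#' Add Gaussian static disorder to a spectrum
#'
#' Inhomogeneous broadening by energy shifts drawn from a Gaussian of the
#' given full width at half maximum: exact convolution by default, or
#' seeded Monte-Carlo averaging of shifted copies.
#'
#' @param spectrum An `AbsorptionSpectrum`.
#' @param fwhm Disorder FWHM, cm^-1 (>= 0; 0 returns the input).
#' @param method "convolution" (exact limit) or "sampling".
#' @param nSamples Number of Monte-Carlo samples (sampling method).
#' @param seed Integer seed (sampling method).
#' @return An `AbsorptionSpectrum`, renormalized to unit maximum.
#' @export
addStaticDisorder <- function(spectrum, fwhm = 400,
                              method = c("convolution", "sampling"),
                              nSamples = 1000L, seed = 1L) {
  stopifnot(fwhm >= 0)
  if (fwhm == 0) return(spectrum)
  method <- match.arg(method)
  nu <- spectrum$frequencies
  I <- spectrum$intensity
  sd_ <- fwhm / (2 * sqrt(2 * log(2)))
  if (method == "convolution") {
    dnu <- nu[2] - nu[1]
    half <- ceiling(4 * sd_ / dnu)
    kern <- stats::dnorm(seq(-half, half) * dnu, sd = sd_)
    kern <- kern / sum(kern)
    out <- stats::convolve(c(rep(0, half), I, rep(0, half)), rev(kern),
                           type = "filter")
    out <- pmax(out, 0)                      # FFT round-off can dip below 0
  } else {
    ## empirical-kernel averaging: bin the sampled shifts on the grid
    ## spacing and convolve once (identical in distribution to averaging
    ## shifted copies, and O(n log n))
    set.seed(seed)
    shifts <- stats::rnorm(nSamples, sd = sd_)
    dnu <- nu[2] - nu[1]
    half <- ceiling((4 * sd_ + dnu) / dnu)
    bins <- round(shifts / dnu)
    bins <- bins[abs(bins) <= half]
    kern <- tabulate(bins + half + 1L, nbins = 2L * half + 1L)
    kern <- kern / sum(kern)
    out <- stats::convolve(c(rep(0, half), I, rep(0, half)), rev(kern),
                           type = "filter")
    out <- pmax(out, 0)
  }
  structure(list(frequencies = nu, intensity = out / max(out),
                 meanEnergy = spectrum$meanEnergy),
            class = "AbsorptionSpectrum")
}

#' Window-averaged spectral pipeline with confidence band
#'
#' Splits the trajectory into non-overlapping windows, applies a pipeline
#' (any function mapping an `EnergyTrajectory` to a curve with
#' `frequencies` and values) per window, and returns the mean curve with a
#' 95% normal-approximation confidence band across windows.
#'
#' @param trajectory An [energyTrajectory()].
#' @param windowLength Window length, fs.
#' @param compute Function of one `EnergyTrajectory` returning a list with
#'   `frequencies` and either `values` or `intensity`.
#' @return List with `frequencies`, `mean`, `lower`, `upper`, `nWindows`.
#' @export
windowAverage <- function(trajectory, windowLength, compute) {
  n <- length(trajectory$times)
  wlen <- floor(windowLength / trajectory$dt)
  nW <- n %/% wlen
  if (nW < 2) {
    warning("fewer than 2 windows; returning the single-window result ",
            "without a confidence band")
    res <- compute(trajectory)
    vals <- res$values %||% res$intensity
    return(list(frequencies = res$frequencies, mean = vals,
                lower = vals, upper = vals, nWindows = 1L))
  }
  curves <- NULL
  freqs <- NULL
  for (k in seq_len(nW)) {
    idx <- ((k - 1) * wlen + 1):(k * wlen)
    sub <- energyTrajectory(trajectory$times[idx], trajectory$energies[idx],
                            trajectory$temperature)
    res <- compute(sub)
    vals <- res$values %||% res$intensity
    if (is.null(curves)) {
      curves <- matrix(0, length(vals), nW)
      freqs <- res$frequencies
    }
    curves[, k] <- vals
  }
  m <- rowMeans(curves)
  se <- apply(curves, 1, stats::sd) / sqrt(nW)
  list(frequencies = freqs, mean = m, lower = m - 1.96 * se,
       upper = m + 1.96 * se, nWindows = nW)
}
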