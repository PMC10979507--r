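cst <- ehConstants()

test_that("the autocorrelation estimator matches analytic oracles", {
  ## constant energy: identically zero
  tr0 <- energyTrajectory(0:99, rep(3.1, 100))
  expect_true(all(energyAutocorrelation(tr0)$acf == 0))
  ## undamped cosine mode: c(t) = A^2 cos(w t) / 2 and c(0) = variance
  tr <- makeEnergyTrajectory(data.frame(freq_cm1 = 1400, coupling_eV = 0.05),
                             nSteps = 16384, dt = 1, seed = 2)
  ac <- energyAutocorrelation(tr)
  omega <- 1400 * cst$fs_to_cm
  expect_lt(max(abs(ac$acf[1:2000] - 0.05^2 / 2 * cos(omega * ac$times[1:2000]))),
            1e-5)
  expect_equal(ac$acf[1], var(tr$energies) * (length(tr$energies) - 1) /
                 length(tr$energies), tolerance = 1e-12)
  ## Cauchy-Schwarz at every lag for an arbitrary real series
  set.seed(76)
  trR <- energyTrajectory(0:511, 3 + cumsum(rnorm(512, sd = 0.01)))
  acR <- energyAutocorrelation(trR, maxLagFraction = 0.25)
  expect_true(all(acR$acf[1] >= abs(acR$acf) - 1e-12))
  expect_error(energyTrajectory(c(0, 1, 3), c(1, 2, 3)), "non-uniform")
})

test_that("damping is a monotone C1 switch hitting exactly zero", {
  tr <- makeEnergyTrajectory(data.frame(freq_cm1 = 900, coupling_eV = 0.02),
                             nSteps = 4096, dt = 1, seed = 3)
  ac <- energyAutocorrelation(tr)
  dc <- dampCorrelation(ac, window = 2000)
  expect_equal(dc$acf[1], ac$acf[1])                       # t = 0 unchanged
  expect_equal(dc$acf[dc$times == 2000], 0)                # exact zero
  expect_true(all(abs(dc$acf) <= abs(ac$acf[seq_along(dc$acf)]) + 1e-15))
  expect_error(dampCorrelation(ac, window = -1), "positive")
  expect_error(dampCorrelation(ac, window = 1e9), "duration")
})

test_that("the spectral density localizes modes and integrates consistently", {
  tr <- makeEnergyTrajectory(data.frame(freq_cm1 = 1400, coupling_eV = 0.05),
                             nSteps = 16384, dt = 1, seed = 2)
  dc <- dampCorrelation(energyAutocorrelation(tr), window = 8000)
  J <- spectralDensity(dc)
  expect_equal(J$frequencies[which.max(J$values)], 1400, tolerance = 1)
  expect_true(all(is.finite(J$values)))
  ## zero correlation -> zero density
  dc0 <- dc; dc0$acf <- dc0$acf * 0
  expect_true(all(spectralDensity(dc0)$values == 0))
  ## damped cosine: Lorentzian-like peak at the mode, width ~ 1/tau
  tr2 <- makeEnergyTrajectory(data.frame(freq_cm1 = 800, coupling_eV = 0.03,
                                         damping_fs = 300),
                              nSteps = 32768, dt = 1, seed = 3)
  dc2 <- dampCorrelation(energyAutocorrelation(tr2), window = 4000)
  J2 <- spectralDensity(dc2)
  expect_lt(abs(J2$frequencies[which.max(J2$values)] - 800), 25)
  ## Parseval-style check: int J * 2 / (pi beta w) dw = c(0) within 2%
  Jf <- spectralDensity(dc2, frequencies = seq(0.5, 6000, by = 0.5))
  beta <- 1 / (cst$kB_cm1 * 300)
  lhs <- sum(Jf$values * 2 / (pi * beta * Jf$frequencies) * 0.5) / cst$eV_cm1^2
  expect_lt(abs(lhs / dc2$acf[1] - 1), 0.02)
  ## a constant shift of U leaves J unchanged
  trS <- energyTrajectory(tr2$times, tr2$energies + 2.5, tr2$temperature)
  JS <- spectralDensity(dampCorrelation(energyAutocorrelation(trS),
                                        window = 4000))
  expect_lt(max(abs(JS$values - J2$values)), 1e-10)
})

test_that("the line shape function has the cumulant small-t structure", {
  w0 <- 1400; S <- 0.8
  nus <- seq(1, 4000, by = 1)
  Jd <- structure(list(frequencies = nus,
                       values = pi * S * w0^2 * dnorm(nus, w0, 8),
                       temperature = 300, prefactor = "classical"),
                  class = "SpectralDensity")
  expect_equal(reorganizationEnergy(Jd), S * w0, tolerance = 1e-2)
  ts <- seq(0, 600, by = 0.25)
  gf <- lineshapeG(Jd, 300, ts)
  expect_equal(Mod(gf$g[1]), 0)
  dgdt <- (gf$g[2] - gf$g[1]) / ((ts[2] - ts[1]) * cst$fs_to_cm)
  expect_lt(abs(Im(dgdt) + S * w0) / (S * w0), 0.01)      # g'(0) = -i lambda
  expect_true(all(Re(gf$g) >= -1e-12))
  ## J = 0 gives g = 0
  J0 <- Jd; J0$values <- J0$values * 0
  expect_true(all(Mod(lineshapeG(J0, 300, ts)$g) == 0))
  ## single sharp mode: Re g periodic with the mode period
  period <- 2 * pi / (w0 * cst$fs_to_cm)
  gPer <- lineshapeG(Jd, 300, c(0.123, 0.123 + period))
  expect_lt(abs(Re(gPer$g[2]) - Re(gPer$g[1])), S * 2e-3)
})

test_that("a single-mode spectrum is a Huang-Rhys progression", {
  w0 <- 1400; S <- 0.8
  nus <- seq(1, 4000, by = 1)
  Jd <- structure(list(frequencies = nus,
                       values = pi * S * w0^2 * dnorm(nus, w0, 8),
                       temperature = 300, prefactor = "classical"),
                  class = "SpectralDensity")
  ts <- seq(0, 3000, by = 0.25)
  gf <- lineshapeG(Jd, 300, ts)
  nu0 <- 3 * cst$eV_cm1
  spec <- suppressWarnings(homogeneousSpectrum(gf, meanEnergy = 3,
    frequencies = seq(nu0 - 2000, nu0 + 5000, by = 2)))
  I <- spec$intensity; nu <- spec$frequencies
  ## progression spacing: peaks at nu0 + k w0
  pk <- which(diff(sign(diff(I))) == -2) + 1
  pk <- pk[I[pk] > 0.05]
  expect_lt(max(abs((nu[pk] - nu0) %% w0 + (-w0) *
                    ((nu[pk] - nu0) %% w0 > w0 / 2))), 30)
  ## integrated line intensities: I1/I0 ~ S (n + 1)
  area <- function(center) sum(I[abs(nu - center) < w0 / 2])
  nbar <- 1 / (exp(w0 / (cst$kB_cm1 * 300)) - 1)
  expect_lt(abs(area(nu0 + w0) / area(nu0) - S * (nbar + 1)) / S, 0.05)
  ## g = 0: sinc-like line centered exactly at the mean energy
  g0 <- lineshapeG(structure(list(frequencies = nus, values = nus * 0,
                                  temperature = 300,
                                  prefactor = "classical"),
                             class = "SpectralDensity"), 300,
                   seq(0, 400, by = 0.5))
  s0 <- suppressWarnings(homogeneousSpectrum(g0, meanEnergy = 3))
  expect_equal(s0$frequencies[which.max(s0$intensity)], nu0, tolerance = 3)
})

test_that("the spectrum is stable under time-grid refinement", {
  w0 <- 1200; S <- 0.5
  nus <- seq(1, 4000, by = 1)
  Jd <- structure(list(frequencies = nus,
                       values = pi * S * w0^2 * dnorm(nus, w0, 15),
                       temperature = 300, prefactor = "classical"),
                  class = "SpectralDensity")
  nu0 <- 3 * cst$eV_cm1
  grid <- seq(nu0 - 2000, nu0 + 4000, by = 4)
  sp1 <- suppressWarnings(homogeneousSpectrum(
    lineshapeG(Jd, 300, seq(0, 2000, by = 0.5)), 3, grid))
  sp2 <- suppressWarnings(homogeneousSpectrum(
    lineshapeG(Jd, 300, seq(0, 2000, by = 0.25)), 3, grid))
  expect_lt(max(abs(sp1$intensity - sp2$intensity)), 0.01)
})

test_that("static disorder broadens exactly and reproducibly", {
  nu0 <- 3 * cst$eV_cm1
  grid <- seq(nu0 - 2500, nu0 + 2500, by = 1)
  delta <- structure(list(frequencies = grid,
                          intensity = as.numeric(abs(grid - nu0) < 10),
                          meanEnergy = 3), class = "AbsorptionSpectrum")
  expect_identical(addStaticDisorder(delta, 0), delta)
  conv <- addStaticDisorder(delta, 400)
  half <- range(conv$frequencies[conv$intensity > 0.5])
  expect_lt(abs(diff(half) - 400), 8)
  ## two seeds agree within Monte-Carlo tolerance
  s1 <- addStaticDisorder(delta, 400, method = "sampling",
                          nSamples = 1e6, seed = 1)
  s2 <- addStaticDisorder(delta, 400, method = "sampling",
                          nSamples = 1e6, seed = 2)
  expect_lt(max(abs(s1$intensity - s2$intensity)), 0.05)
  expect_true(all(conv$intensity >= 0) && max(conv$intensity) == 1)
})

test_that("window averaging produces bands with the right scaling", {
  ## periodic signal: identical windows, zero-width band
  t <- 0:8191
  trP <- energyTrajectory(t, 3 + 0.05 * cos(2 * pi * t / 256), 300)
  pipe <- function(tr) {
    ac <- energyAutocorrelation(tr)
    spectralDensity(dampCorrelation(ac, window = max(ac$times)),
                    300, frequencies = seq(10, 500, by = 5))
  }
  wa <- windowAverage(trP, 2048, pipe)
  expect_equal(wa$nWindows, 4L)
  expect_lt(max(wa$upper - wa$lower), 1e-8 * max(abs(wa$mean)))
  ## stochastic signal: doubling the window count shrinks the band ~1/sqrt(2)
  tr <- makeEnergyTrajectory(data.frame(freq_cm1 = 400, coupling_eV = 0.04,
                                        damping_fs = 120),
                             nSteps = 32768, dt = 1, seed = 7)
  wa1 <- windowAverage(tr, 8192, pipe)
  wa2 <- windowAverage(tr, 4096, pipe)
  expect_equal(wa1$nWindows, 4L)
  expect_equal(wa2$nWindows, 8L)
  r <- mean(wa2$upper - wa2$lower) / mean(wa1$upper - wa1$lower)
  expect_gt(r, 0.4); expect_lt(r, 1.1)
  ## single window: warning, no band
  expect_warning(w1 <- windowAverage(trP, 1e6, pipe), "fewer than 2")
  expect_identical(w1$nWindows, 1L)
})

test_that("a prescribed overdamped density is recovered end to end", {
  ## OU mode: c(t) = A^2 exp(-t/tau) cos(w t) with w -> 0 gives the
  ## Drude-like J(w) = beta w A^2 gamma / (gamma^2 + w^2)
  A <- 0.04; tau <- 150
  freqs <- seq(2, 400, by = 2)
  Jbar <- rowMeans(vapply(1:4, function(sd_) {
    tr <- makeEnergyTrajectory(data.frame(freq_cm1 = 0.5, coupling_eV = A,
                                          damping_fs = tau),
                               nSteps = 65536, dt = 1, seed = 10 + sd_)
    dc <- dampCorrelation(energyAutocorrelation(tr), window = 3000)
    spectralDensity(dc, frequencies = freqs)$values
  }, numeric(length(freqs))))
  gamma <- 1 / (tau * cst$fs_to_cm)                     # cm^-1
  beta <- 1 / (cst$kB_cm1 * 300)
  Jth <- beta * freqs * (A * cst$eV_cm1)^2 *
    gamma / (gamma^2 + freqs^2)
  pk <- which.max(Jth)
  expect_lt(abs(Jbar[pk] - Jth[pk]) / Jth[pk], 0.05)
})
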