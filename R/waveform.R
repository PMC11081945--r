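#' Fluid properties
#'
#' Incompressible Newtonian fluid. Blood in the sizing study is rho = 1055
#' kg/m^3, mu = 0.004 Pa s; the closed-form validation cases use a
#' blood-mimicking fluid at rho = 1200 kg/m^3, mu = 0.0038 Pa s.
#'
#' @param density Density (kg/m^3).
#' @param viscosity Dynamic viscosity (Pa s).
#' @return An object of class `fluid_properties`.
#' @export
fluid_properties <- function(density = 1055, viscosity = 0.004) {
  if (density <= 0 || viscosity <= 0)
    stop("density and viscosity must be positive", call. = FALSE)
  structure(list(density = density, viscosity = viscosity,
                 nu = viscosity / density),
            class = "fluid_properties")
}

#' Pulsatile inlet waveform
#'
#' Cross-section-mean inlet velocity as a truncated Fourier series,
#' `U(t) = U0 * (1 + sum_k Re(c_k exp(i k w t)))` with `w = 2*pi/T`. The
#' waveform must stay positive (no inlet flow reversal) and have a systolic
#' peak between 1.2x and 3x the mean.
#'
#' @param mean_velocity Cycle-mean inlet velocity U0 (m/s).
#' @param period Cardiac period T (s).
#' @param harmonics Complex vector `c_k`, k = 1..K (K <= 8), relative to the
#'   mean. Empty for steady flow.
#' @return An object of class `pulsatile_waveform`.
#' @export
pulsatile_waveform <- function(mean_velocity, period = 1.0, harmonics = complex(0)) {
  if (mean_velocity <= 0 || period <= 0)
    stop("mean velocity and period must be positive", call. = FALSE)
  if (length(harmonics) > 8) stop("at most 8 harmonics are supported", call. = FALSE)
  wf <- structure(list(mean_velocity = mean_velocity, period = period,
                       harmonics = as.complex(harmonics)),
                  class = "pulsatile_waveform")
  if (length(harmonics) > 0) {
    tt <- seq(0, period, length.out = 2001)
    u <- mean_inlet_velocity(wf, tt)
    if (min(u) <= 0)
      stop("waveform reverses at the inlet: instantaneous mean velocity must stay positive",
           call. = FALSE)
    ratio <- max(u) / mean_velocity
    if (ratio < 1.2 || ratio > 3)
      stop(sprintf("waveform peak/mean ratio %.2f outside the physiological range [1.2, 3]", ratio),
           call. = FALSE)
  }
  wf
}

#' Internal-carotid-like default waveform
#'
#' A smooth four-harmonic pulse with its systolic peak at t/T = 0.15 and peak
#' velocity twice the mean, qualitatively matching internal carotid artery flow
#' traces. It is a documented fixture of this package, not a measured
#' waveform.
#'
#' @param mean_velocity Cycle-mean inlet velocity (m/s), default 0.25.
#' @param period Cardiac period (s), default 1.0.
#' @return A [pulsatile_waveform()].
#' @export
ica_waveform <- function(mean_velocity = 0.25, period = 1.0) {
  a <- c(0.65, 0.25, 0.08, 0.02)      # amplitudes; sum = 1 so peak = 2x mean
  t_peak <- 0.15 * period
  k <- seq_along(a)
  ck <- a * exp(-1i * k * 2 * pi * t_peak / period)
  pulsatile_waveform(mean_velocity, period, ck)
}

#' Instantaneous cross-section-mean inlet velocity
#'
#' @param waveform A [pulsatile_waveform()].
#' @param t Time(s) (s); vectorized.
#' @return Mean velocity (m/s).
#' @export
mean_inlet_velocity <- function(waveform, t) {
  w <- 2 * pi / waveform$period
  u <- rep(1, length(t))
  for (k in seq_along(waveform$harmonics))
    u <- u + Re(waveform$harmonics[k] * exp(1i * k * w * t))
  waveform$mean_velocity * u
}

#' Womersley number of a waveform harmonic in a channel
#'
#' `alpha = (H/2) * sqrt(k * w * rho / mu)` for harmonic k.
#'
#' @param waveform A [pulsatile_waveform()].
#' @param fluid A [fluid_properties()].
#' @param channel_height Channel height H (mm).
#' @param harmonic Harmonic index (default 1, the fundamental).
#' @return Dimensionless Womersley number.
#' @export
womersley_number <- function(waveform, fluid, channel_height, harmonic = 1L) {
  H <- channel_height * 1e-3
  w <- 2 * pi / waveform$period
  (H / 2) * sqrt(harmonic * w / fluid$nu)
}

#' Pulsatile plane-channel inlet velocity profile
#'
#' Closed-form fully developed profile for the waveform: the steady harmonic
#' contributes the plane-Poiseuille parabola scaled to its mean; each
#' oscillatory harmonic contributes the plane-channel Womersley solution
#' `g(y) = 1 - cosh(lam*(y - H/2)) / cosh(lam*H/2)` with
#' `lam = sqrt(i k w / nu)`, normalized to its cross-channel mean so the
#' profile integrates exactly to the instantaneous mean velocity times H.
#'
#' @param waveform A [pulsatile_waveform()].
#' @param fluid A [fluid_properties()].
#' @param channel_height Channel height H (mm).
#' @param t Time (s), scalar.
#' @param y Heights at which to evaluate (mm, measured from the lower wall);
#'   defaults to 101 equispaced points across the channel.
#' @return Numeric vector of axial velocities (m/s) at `y`.
#' @export
womersley_inlet_profile <- function(waveform, fluid, channel_height, t,
                                    y = NULL) {
  H <- channel_height * 1e-3
  if (is.null(y)) y <- seq(0, channel_height, length.out = 101)
  ym <- y * 1e-3
  eta <- ym / H
  u <- waveform$mean_velocity * 6 * eta * (1 - eta)  # steady parabola, mean U0
  w <- 2 * pi / waveform$period
  for (k in seq_along(waveform$harmonics)) {
    lam <- sqrt(1i * k * w / fluid$nu)
    g <- 1 - cosh(lam * (ym - H / 2)) / cosh(lam * H / 2)
    gbar <- 1 - tanh(lam * H / 2) / (lam * H / 2)
    amp <- waveform$mean_velocity * waveform$harmonics[k]
    u <- u + Re(amp * (g / gbar) * exp(1i * k * w * t))
  }
  u
}
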