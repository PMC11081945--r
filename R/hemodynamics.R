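# Cell-centered velocity components from the staggered fields.
cell_center_velocity <- function(snapshot, domain) {
  nx <- domain$nx; ny <- domain$ny
  uc <- 0.5 * (snapshot$u[1:nx, , drop = FALSE] + snapshot$u[2:(nx + 1L), , drop = FALSE])
  vc <- 0.5 * (snapshot$v[, 1:ny, drop = FALSE] + snapshot$v[, 2:(ny + 1L), drop = FALSE])
  list(uc = uc, vc = vc)
}

snapshot_inlet_flux <- function(snapshot, domain) {
  rows <- which(domain$lab[1L, ] > 0L)
  sum(snapshot$u[1L, rows]) * domain$h * 1e-3
}

#' Index of the systole snapshot
#'
#' Systole is the instant of maximum inlet flux within the retained (final)
#' cycle.
#'
#' @param series A [run_flow()] result.
#' @return Integer snapshot index.
#' @export
systole_index <- function(series) {
  q <- vapply(series$snapshots, snapshot_inlet_flux, numeric(1), series$domain)
  which.max(q)
}

#' Aneurysm inflow rate
#'
#' Integral over the neck faces of the positive (into-sac) normal velocity,
#' per unit depth. In this 2D cross-section the analog of the 3D volumetric
#' inflow is an area flux, reported in mm^2/s.
#'
#' @param snapshot A single state from a `flow_series` (fields `u`, `v`, `p`).
#' @param domain The `grid_domain` the snapshot was computed on.
#' @return Inflow rate (mm^2/s).
#' @export
inflow_rate <- function(snapshot, domain) {
  if (length(domain$neck_cols) == 0)
    stop("domain has no neck faces", call. = FALSE)
  vneck <- snapshot$v[cbind(domain$neck_cols, domain$j_neck)]
  sum(pmax(vneck, 0)) * (domain$h * 1e-3) * 1e6
}

#' Average intra-aneurysmal velocity
#'
#' Area-weighted mean velocity magnitude over the sac fluid cells.
#'
#' @inheritParams inflow_rate
#' @return Mean speed (m/s).
#' @export
average_sac_velocity <- function(snapshot, domain) {
  sac <- domain$lab == 2L
  if (!any(sac)) stop("domain has an empty sac region", call. = FALSE)
  cc <- cell_center_velocity(snapshot, domain)
  mean(sqrt(cc$uc[sac]^2 + cc$vc[sac]^2))
}

#' Energy loss across the aneurysm
#'
#' Difference between the total-pressure energy fluxes (p + rho |u|^2 / 2,
#' advected by the axial velocity) through the proximal and distal measurement
#' planes, normalized by the sac area (the 2D analog of a volume
#' normalization), in W/m^3. Negative values are clamped to zero with a
#' warning.
#'
#' @inheritParams inflow_rate
#' @param fluid A [fluid_properties()].
#' @param normalize `"sac"` (default) divides by the sac area, `"domain"` by
#'   the whole fluid area.
#' @return Energy loss (W/m^3).
#' @export
energy_loss <- function(snapshot, domain, fluid, normalize = c("sac", "domain")) {
  normalize <- match.arg(normalize)
  if (is.na(domain$i_p) || is.na(domain$i_d))
    stop("domain has no proximal/distal measurement planes", call. = FALSE)
  h_si <- domain$h * 1e-3
  plane_flux <- function(iu) {
    if (iu <= 1L || iu > domain$nx)
      stop("measurement plane lies outside the fluid domain", call. = FALSE)
    rows <- which(domain$lab[iu - 1L, ] > 0L & domain$lab[iu, ] > 0L)
    rows <- rows[rows <= domain$n_chan]
    u_f <- snapshot$u[iu, rows]
    # v and p interpolated to the u-face
    v_f <- 0.25 * (snapshot$v[iu - 1L, rows] + snapshot$v[iu - 1L, rows + 1L] +
                     snapshot$v[iu, rows] + snapshot$v[iu, rows + 1L])
    p_f <- 0.5 * (snapshot$p[iu - 1L, rows] + snapshot$p[iu, rows])
    sum(u_f * (p_f + 0.5 * fluid$density * (u_f^2 + v_f^2))) * h_si
  }
  area <- if (normalize == "sac") domain$sac_area else sum(domain$lab > 0L) * domain$h^2
  el <- (plane_flux(domain$i_p) - plane_flux(domain$i_d)) / (area * 1e-6)
  if (el < 0) {
    warning(sprintf("negative energy loss (%.3e W/m^3) clamped to zero", el), call. = FALSE)
    el <- 0
  }
  el
}

#' Wall shear stress on the sac wall
#'
#' Signed tangential viscous stress at each sac wall face from a one-sided
#' second-order difference of the wall-parallel velocity (no-slip wall value
#' zero): `tau = mu * (9 u1 - u2) / (3 h)` with `u1`, `u2` the tangential
#' cell-center velocities half and one-and-a-half cells into the fluid
#' (first-order fallback where only one fluid cell is available). The tangent
#' direction is fixed per face (+x for horizontal walls, +y for vertical), so
#' signs are comparable across time.
#'
#' @inheritParams inflow_rate
#' @param mu Dynamic viscosity (Pa s).
#' @return List with `faces` (data.frame: i, j, side, tau) and `avg`, the
#'   area-weighted sac-average of |tau| (Pa).
#' @export
wall_shear_stress <- function(snapshot, domain, mu) {
  if (is.null(domain$sac_walls) || nrow(domain$sac_walls) == 0)
    stop("domain has no sac wall faces", call. = FALSE)
  cc <- cell_center_velocity(snapshot, domain)
  h_si <- domain$h * 1e-3
  fl <- domain$lab > 0L
  w <- domain$sac_walls
  tau <- numeric(nrow(w))
  for (r in seq_len(nrow(w))) {
    i <- w$i[r]; j <- w$j[r]; side <- w$side[r]
    if (side %in% c("N", "S")) {
      step <- if (side == "N") -1L else 1L      # into the fluid
      u1 <- cc$uc[i, j]
      j2 <- j + step
      u2 <- if (j2 >= 1L && j2 <= domain$ny && fl[i, j2]) cc$uc[i, j2] else NA_real_
    } else {
      step <- if (side == "E") -1L else 1L
      u1 <- cc$vc[i, j]
      i2 <- i + step
      u2 <- if (i2 >= 1L && i2 <= domain$nx && fl[i2, j]) cc$vc[i2, j] else NA_real_
    }
    tau[r] <- if (is.na(u2)) mu * 2 * u1 / h_si else mu * (9 * u1 - u2) / (3 * h_si)
  }
  list(faces = cbind(w, tau = tau), avg = mean(abs(tau)))
}

# Signed tau matrix (faces x snapshots) over the retained cycle.
wss_series <- function(series, mu) {
  domain <- series$domain
  taus <- vapply(series$snapshots,
                 function(s) wall_shear_stress(s, domain, mu)$faces$tau,
                 numeric(nrow(domain$sac_walls)))
  tt <- series$snapshot_times
  if (abs((tt[length(tt)] - tt[1]) - series$waveform$period) > 1e-9)
    stop("snapshot series does not cover exactly one full cycle", call. = FALSE)
  list(tau = taus, t = tt)
}

trapz_weights <- function(t) {
  n <- length(t)
  w <- numeric(n)
  w[1] <- (t[2] - t[1]) / 2
  w[n] <- (t[n] - t[n - 1]) / 2
  if (n > 2) w[2:(n - 1)] <- (t[3:n] - t[1:(n - 2)]) / 2
  w
}

#' Time-averaged wall shear stress (TAWSS)
#'
#' Cycle-mean of |tau| per sac wall face, then sac-averaged.
#'
#' @param series A [run_flow()] result covering one full cycle.
#' @param mu Dynamic viscosity (Pa s).
#' @return TAWSS (Pa).
#' @export
tawss <- function(series, mu) {
  ws <- wss_series(series, mu)
  wts <- trapz_weights(ws$t)
  T <- ws$t[length(ws$t)] - ws$t[1]
  mean(abs(ws$tau) %*% wts / T)
}

#' Oscillatory shear index (OSI)
#'
#' Per face, `0.5 * (1 - |integral tau dt| / integral |tau| dt)` over the
#' cycle (0/0 defined as 0), then sac-averaged. 0 for unidirectional shear,
#' 0.5 for fully reversing shear.
#'
#' @inheritParams tawss
#' @return OSI, dimensionless, between 0 and 0.5.
#' @export
osi <- function(series, mu) {
  ws <- wss_series(series, mu)
  wts <- trapz_weights(ws$t)
  num <- abs(as.numeric(ws$tau %*% wts))
  den <- as.numeric(abs(ws$tau) %*% wts)
  o <- ifelse(den > 0, 0.5 * (1 - num / den), 0)
  mean(o)
}

#' Reduction rate of a hemodynamic parameter
#'
#' `100 * (baseline - stented) / baseline`, reported to two decimals
#' (half-away-from-zero rounding, matching conventional table presentation).
#'
#' @param baseline Unstented value (> 0).
#' @param stented Stented value, same units.
#' @return Percent reduction.
#' @examples
#' reduction_rate(473.4, 202.4)  # 57.25
#' @export
reduction_rate <- function(baseline, stented) {
  if (any(baseline <= 0)) stop("baseline must be positive", call. = FALSE)
  round_half_away(100 * (baseline - stented) / baseline, 2L)
}

#' Summarize the hemodynamics of a flow series
#'
#' Computes the six parameters of the sizing study from the final-cycle
#' snapshots: inflow rate, average sac velocity and energy loss at systole
#' (the snapshot of peak inlet flux), plus sac-averaged WSS at systole, TAWSS
#' and OSI.
#'
#' @param series A [run_flow()] result on an aneurysm domain.
#' @return An object of class `hemodynamic_summary`.
#' @export
hemodynamic_summary <- function(series) {
  domain <- series$domain
  mu <- series$fluid$viscosity
  isys <- systole_index(series)
  sys <- series$snapshots[[isys]]
  out <- structure(list(
    inflow_rate = inflow_rate(sys, domain),
    avg_velocity = average_sac_velocity(sys, domain),
    energy_loss = energy_loss(sys, domain, series$fluid),
    wss_systole = wall_shear_stress(sys, domain, mu)$avg,
    tawss = tawss(series, mu),
    osi = osi(series, mu),
    systole_time = sys$t
  ), class = "hemodynamic_summary")
  out
}

#' @export
print.hemodynamic_summary <- function(x, ...) {
  cat(sprintf("Hemodynamic summary (systole at t = %.3f s)\n  inflow rate  %10.4g mm^2/s\n  avg velocity %10.4g m/s\n  energy loss  %10.4g W/m^3\n  WSS systole  %10.4g Pa\n  TAWSS        %10.4g Pa\n  OSI          %10.4g\n",
              x$systole_time, x$inflow_rate, x$avg_velocity, x$energy_loss,
              x$wss_systole, x$tawss, x$osi))
  invisible(x)
}

#' Baseline-vs-stented reduction report
#'
#' Pairs an unstented and a stented summary and computes percent reduction
#' rates per parameter.
#'
#' @param baseline,stented [hemodynamic_summary()] objects.
#' @param meta Named list of scenario metadata (parent diameter, MCR, pore
#'   density, kappa, ...), stored as-is.
#' @return An object of class `reduction_report`.
#' @export
reduction_report <- function(baseline, stented, meta = list()) {
  pars <- c("inflow_rate", "avg_velocity", "energy_loss",
            "wss_systole", "tawss", "osi")
  rates <- vapply(pars, function(p) {
    b <- baseline[[p]]
    if (b <= 0) NA_real_ else reduction_rate(b, stented[[p]])
  }, numeric(1))
  structure(list(baseline = baseline, stented = stented,
                 reduction = rates, meta = meta),
            class = "reduction_report")
}

#' @export
print.reduction_report <- function(x, ...) {
  if (length(x$meta))
    cat(sprintf("Scenario: %s\n",
                paste(names(x$meta), vapply(x$meta, function(m) format(m, digits = 4), ""),
                      sep = " = ", collapse = ", ")))
  for (p in names(x$reduction))
    cat(sprintf("  %-12s %12.4g -> %12.4g  (reduction %6.2f%%)\n",
                p, x$baseline[[p]], x$stented[[p]], x$reduction[[p]]))
  invisible(x)
}
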