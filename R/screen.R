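#' Homogenize a deployed braid into a permeable neck screen
#'
#' The deployed braid crossing the aneurysm neck is represented in the flow
#' solver as a thin permeable screen rather than as resolved struts. An
#' Ergun-type packed-bed correlation with the wire diameter as the grain scale
#' supplies the Darcy permeability and the inertial (Forchheimer) coefficient:
#' `k = d_w^2 * eps^3 / (A * (1 - eps)^2)` and `C = B * (1 - eps) /
#' (d_w * eps^3)` with porosity `eps = 1 - MCR` and standard constants
#' `A = 150`, `B = 3.5`.
#'
#' @param deployed A [deploy()] result with `mcr < 1`.
#' @param thickness Screen thickness (mm); defaults to two wire diameters
#'   (two crossing wire layers).
#' @param ergun_A,ergun_B Ergun constants (viscous and inertial); the packed-
#'   bed defaults are exposed because woven-screen correlations differ.
#' @return An object of class `screen_properties` with `porosity`,
#'   `thickness` (mm), `permeability` (mm^2), `inertial_coeff` (1/mm), `mcr`
#'   and `wire_diameter` (mm).
#' @export
screen_from_braid <- function(deployed, thickness = NULL,
                              ergun_A = 150, ergun_B = 3.5) {
  stopifnot(inherits(deployed, "deployed_braid"))
  if (deployed$mcr >= 1)
    stop("impermeable screen: MCR = 1; treat the neck as a wall instead", call. = FALSE)
  d_w <- deployed$braid$wire_diameter
  eps <- 1 - deployed$mcr
  if (is.null(thickness)) thickness <- 2 * d_w
  structure(list(
    porosity = eps,
    thickness = thickness,
    permeability = d_w^2 * eps^3 / (ergun_A * (1 - eps)^2),
    inertial_coeff = ergun_B * (1 - eps) / (d_w * eps^3),
    mcr = deployed$mcr,
    wire_diameter = d_w
  ), class = "screen_properties")
}

#' @export
print.screen_properties <- function(x, ...) {
  cat(sprintf("Neck screen: porosity %.3f (MCR %.1f%%), thickness %.3f mm\n  permeability %.3e mm^2, inertial coefficient %.3e /mm\n",
              x$porosity, 100 * x$mcr, x$thickness, x$permeability, x$inertial_coeff))
  invisible(x)
}

#' Darcy-Forchheimer momentum sink of a screen
#'
#' Force density exerted by the screen on the fluid,
#' `-(mu/k) u - (rho C / 2) |u| u`, in SI units. In the solver this sink acts
#' only over the screen thickness at the neck.
#'
#' @param props A [screen_from_braid()] result.
#' @param velocity Velocity vector (m/s), length 2, or an n x 2 matrix.
#' @param rho Fluid density (kg/m^3).
#' @param mu Dynamic viscosity (Pa s).
#' @return Force density (N/m^3), same shape as `velocity`.
#' @export
momentum_sink <- function(props, velocity, rho, mu) {
  stopifnot(inherits(props, "screen_properties"))
  v <- if (is.matrix(velocity)) velocity else matrix(velocity, nrow = 1)
  if (!all(is.finite(v)) || !is.finite(rho) || !is.finite(mu))
    stop("momentum_sink requires finite inputs", call. = FALSE)
  k_si <- props$permeability * 1e-6      # mm^2 -> m^2
  C_si <- props$inertial_coeff * 1e3     # 1/mm -> 1/m
  speed <- sqrt(rowSums(v^2))
  f <- -(mu / k_si) * v - (rho * C_si / 2) * speed * v
  if (is.matrix(velocity)) f else as.numeric(f)
}

#' Through-screen Darcy-Forchheimer flux under a fixed pressure drop
#'
#' Standalone 1D balance: solves `(mu/k) v + (rho C / 2) v^2 = dp / t_s` for
#' the through-screen velocity. Used to check that calibrated study screens
#' pass strictly less flow as MCR rises.
#'
#' @param props A [screen_from_braid()] result.
#' @param dp Pressure drop across the screen (Pa).
#' @param rho Fluid density (kg/m^3).
#' @param mu Dynamic viscosity (Pa s).
#' @return Superficial velocity through the screen (m/s).
#' @export
screen_throughflow <- function(props, dp, rho, mu) {
  stopifnot(inherits(props, "screen_properties"), dp >= 0)
  k_si <- props$permeability * 1e-6
  C_si <- props$inertial_coeff * 1e3
  t_si <- props$thickness * 1e-3
  a <- rho * C_si / 2
  b <- mu / k_si
  g <- dp / t_si
  if (a == 0) return(g / b)
  (-b + sqrt(b^2 + 4 * a * g)) / (2 * a)
}
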