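#' Write a study configuration to a YAML file
#'
#' Serializes the geometry, braid, fluid, waveform and solver blocks of a
#' [study_config()] as structured key-value text. Complex waveform harmonics
#' are stored as `re`/`im` pairs.
#'
#' @param config A [study_config()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_study_config <- function(config, path) {
  stopifnot(inherits(config, "study_config"))
  wf <- config$waveform
  lst <- list(
    geometry = list(sac_radius = config$sac_radius,
                    neck_width = config$neck_width,
                    parent_diameters = config$parent_diameters),
    braid = list(device_diameter = config$device_diameter,
                 n_wires = config$n_wires,
                 wire_diameter = config$wire_diameter,
                 matched_mcr = config$matched_mcr,
                 cap_fraction = config$cap_fraction,
                 mcr_targets = config$mcr_targets),
    fluid = list(density = config$fluid$density,
                 viscosity = config$fluid$viscosity),
    waveform = list(mean_velocity = wf$mean_velocity,
                    period = wf$period,
                    harmonics_re = Re(wf$harmonics),
                    harmonics_im = Im(wf$harmonics)),
    solver = list(h = config$h,
                  cfl = config$solver$cfl,
                  n_cycles = config$solver$n_cycles,
                  snapshots_per_cycle = config$solver$snapshots_per_cycle,
                  tol = config$solver$tol,
                  u_design_factor = config$solver$u_design_factor,
                  diff_safety = config$solver$diff_safety),
    out_dir = config$out_dir
  )
  yaml::write_yaml(lst, path, precision = 15L)
  invisible(path)
}

#' Read a study configuration from a YAML file
#'
#' @param path A YAML file produced by [write_study_config()] (or edited by
#'   hand with the same block structure). Missing blocks fall back to the
#'   [study_config()] defaults.
#' @return A [study_config()].
#' @export
read_study_config <- function(path) {
  lst <- yaml::read_yaml(path)
  g <- lst$geometry %||% list()
  b <- lst$braid %||% list()
  f <- lst$fluid %||% list()
  w <- lst$waveform %||% list()
  s <- lst$solver %||% list()
  waveform <- if (length(w) == 0) ica_waveform() else
    pulsatile_waveform(w$mean_velocity, w$period,
                       complex(real = w$harmonics_re %||% numeric(0),
                               imaginary = w$harmonics_im %||% numeric(0)))
  def <- study_config()
  study_config(
    parent_diameters = g$parent_diameters %||% def$parent_diameters,
    mcr_targets = b$mcr_targets %||% def$mcr_targets,
    device_diameter = b$device_diameter %||% def$device_diameter,
    n_wires = b$n_wires %||% def$n_wires,
    wire_diameter = b$wire_diameter %||% def$wire_diameter,
    matched_mcr = b$matched_mcr,
    cap_fraction = b$cap_fraction %||% def$cap_fraction,
    sac_radius = g$sac_radius %||% def$sac_radius,
    neck_width = g$neck_width %||% def$neck_width,
    h = s$h %||% def$h,
    fluid = fluid_properties(f$density %||% 1055, f$viscosity %||% 0.004),
    waveform = waveform,
    solver = simulation_config(cfl = s$cfl %||% 0.4,
                               n_cycles = s$n_cycles %||% 3L,
                               snapshots_per_cycle = s$snapshots_per_cycle %||% 50L,
                               tol = s$tol %||% 1e-6,
                               u_design_factor = s$u_design_factor %||% 1.3,
                               diff_safety = s$diff_safety %||% 0.6),
    out_dir = lst$out_dir
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
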