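#' Sizing-study configuration
#'
#' Configures the full experiment: one braided device deployed across several
#' parent-artery diameters, each scenario compared against its unstented
#' baseline. Defaults reproduce the reference study conditions: a 4.0 mm
#' device in 3.0/3.5/4.0/4.5 mm arteries with measured per-scenario MCR
#' targets 25.5/29.4/37.2/48.0% (5.0 mm is excluded: it exceeds the braid's
#' maximum free diameter, i.e. inadequate wall apposition).
#'
#' @param parent_diameters Ascending vessel diameters (mm).
#' @param mcr_targets One MCR target (fraction) per diameter; the compaction
#'   factor of each scenario is calibrated to it.
#' @param device_diameter Nominal device diameter (mm).
#' @param n_wires,wire_diameter Braid construction, see [braid_spec()].
#' @param matched_mcr MCR at nominal (matched-size) free deployment used to
#'   calibrate the nominal braid angle; defaults to the target of the matched
#'   scenario if present, else 0.372.
#' @param cap_fraction When a vessel exceeds the braid's maximum free
#'   diameter, the braid deploys at this fraction of the maximum (incomplete
#'   apposition), and compaction makes up the coverage. Default 0.97.
#' @param sac_radius,neck_width Aneurysm geometry (mm), see
#'   [build_sidewall_model()].
#' @param h Grid spacing (mm), default 0.2.
#' @param fluid A [fluid_properties()] (default: blood, 1055 kg/m^3,
#'   0.004 Pa s).
#' @param waveform A [pulsatile_waveform()] (default: [ica_waveform()]).
#' @param solver A [simulation_config()].
#' @param out_dir Optional output directory for the CSV/JSON report and logs.
#' @return An object of class `study_config`.
#' @export
study_config <- function(parent_diameters = c(3.0, 3.5, 4.0, 4.5),
                         mcr_targets = c(0.255, 0.294, 0.372, 0.480),
                         device_diameter = 4.0,
                         n_wires = 48L, wire_diameter = 0.030,
                         matched_mcr = NULL, cap_fraction = 0.97,
                         sac_radius = 5.0, neck_width = 4.0,
                         h = 0.2,
                         fluid = fluid_properties(),
                         waveform = ica_waveform(),
                         solver = simulation_config(),
                         out_dir = NULL) {
  if (is.unsorted(parent_diameters, strictly = TRUE))
    stop("parent_diameters must be strictly ascending", call. = FALSE)
  if (length(mcr_targets) != length(parent_diameters))
    stop("need one MCR target per parent diameter", call. = FALSE)
  if (is.null(matched_mcr)) {
    i <- match(device_diameter, parent_diameters)
    matched_mcr <- if (!is.na(i)) mcr_targets[i] else 0.372
  }
  structure(list(parent_diameters = parent_diameters, mcr_targets = mcr_targets,
                 device_diameter = device_diameter, n_wires = n_wires,
                 wire_diameter = wire_diameter, matched_mcr = matched_mcr,
                 cap_fraction = cap_fraction,
                 sac_radius = sac_radius, neck_width = neck_width, h = h,
                 fluid = fluid, waveform = waveform, solver = solver,
                 out_dir = out_dir),
            class = "study_config")
}

# Calibrate the braid for one scenario: cap the deployment diameter if the
# vessel is wider than the braid can open, then root-find the compaction
# factor that reproduces the target MCR.
calibrate_scenario <- function(braid, d_vessel, target_mcr, cap_fraction) {
  d_max <- max_free_diameter(braid)
  capped <- d_vessel > cap_fraction * d_max
  d_eff <- if (capped) cap_fraction * d_max else d_vessel
  kappa <- calibrate_compaction(braid, d_eff, target_mcr)
  deployed <- deploy(braid, d_eff, kappa)
  list(deployed = deployed, kappa = kappa, capped = capped, d_eff = d_eff)
}

#' Run the flow-diverter sizing study
#'
#' For each parent diameter: builds and rasterizes the sidewall-aneurysm
#' geometry, calibrates the braid compaction to the scenario's MCR target
#' (capping the deployment diameter with a logged note when the vessel exceeds
#' the braid's maximum free diameter), homogenizes the deployed braid into a
#' neck screen, runs the unstented baseline and stented pulsatile simulations,
#' and summarizes hemodynamics and reduction rates. A failing scenario is
#' recorded as failed and the remaining scenarios continue. The pipeline is
#' fully deterministic.
#'
#' @param config A [study_config()].
#' @param quiet Suppress progress messages.
#' @return An object of class `study_result`: `reports` (one
#'   [reduction_report()] or failure record per scenario), `table` (the
#'   Table-1-shaped data.frame, see [study_table()]), `braid` (the calibrated
#'   [braid_spec()]) and `logs`. If `config$out_dir` is set, writes
#'   `study_report.csv`, `study_report.json` and per-scenario logs there.
#' @export
run_study <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "study_config"))
  braid <- calibrate_nominal_angle(
    braid_spec(config$n_wires, config$wire_diameter, config$device_diameter),
    config$matched_mcr)
  say <- function(...) if (!quiet) message(sprintf(...))
  say("calibrated nominal braid angle: %.2f deg (max free diameter %.3f mm)",
      braid$nominal_angle, max_free_diameter(braid))

  reports <- vector("list", length(config$parent_diameters))
  logs <- vector("list", length(config$parent_diameters))
  names(reports) <- names(logs) <- sprintf("D%.1f", config$parent_diameters)

  for (k in seq_along(config$parent_diameters)) {
    d <- config$parent_diameters[k]
    target <- config$mcr_targets[k]
    reports[[k]] <- tryCatch({
      cal <- calibrate_scenario(braid, d, target, config$cap_fraction)
      if (cal$capped)
        say("scenario D = %.1f mm: vessel exceeds max free diameter; braid deployed at %.3f mm",
            d, cal$d_eff)
      screen <- screen_from_braid(cal$deployed)
      spec <- build_sidewall_model(d, config$sac_radius, config$neck_width)
      domain <- rasterize(spec, config$h)
      say("scenario D = %.1f mm: MCR %.1f%% (kappa %.3f), %d x %d grid, baseline run ...",
          d, 100 * cal$deployed$mcr, cal$kappa, domain$nx, domain$ny)
      base <- run_flow(domain, config$fluid, config$waveform, config$solver)
      say("scenario D = %.1f mm: stented run ...", d)
      sten <- run_flow(domain, config$fluid, config$waveform, config$solver,
                       screen = screen)
      logs[[k]] <- list(
        parent_diameter = d, kappa = cal$kappa, capped = cal$capped,
        d_eff = cal$d_eff, mcr = cal$deployed$mcr,
        pore_density = cal$deployed$pore_density,
        screen = unclass(screen), dt = base$dt,
        baseline_periodicity = base$periodicity_residual,
        stented_periodicity = sten$periodicity_residual,
        baseline_max_divergence = base$max_divergence,
        stented_max_divergence = sten$max_divergence)
      reduction_report(hemodynamic_summary(base), hemodynamic_summary(sten),
                       meta = list(parent_diameter = d,
                                   mcr = cal$deployed$mcr,
                                   pore_density = cal$deployed$pore_density,
                                   kappa = cal$kappa, capped = cal$capped))
    }, error = function(e) {
      warning(sprintf("scenario D = %.1f mm failed: %s", d, conditionMessage(e)),
              call. = FALSE)
      structure(list(parent_diameter = d, error = conditionMessage(e)),
                class = "scenario_failure")
    })
  }

  res <- structure(list(reports = reports, table = study_table(reports),
                        braid = braid, logs = logs, config = config),
                   class = "study_result")
  if (!is.null(config$out_dir)) write_study_outputs(res, config$out_dir)
  res
}

#' Tabulate study reports in the shape of the reference summary table
#'
#' @param reports List of [reduction_report()]s (failures are skipped), or a
#'   `study_result`.
#' @return A data.frame with columns `parent_diameter_mm`, `mcr_pct`,
#'   `pore_density_per_mm2`, then each parameter's stented value and percent
#'   reduction rate (`*_rr_pct`).
#' @export
study_table <- function(reports) {
  if (inherits(reports, "study_result")) reports <- reports$reports
  ok <- Filter(function(r) inherits(r, "reduction_report"), reports)
  if (length(ok) == 0) return(data.frame())
  rows <- lapply(ok, function(r) data.frame(
    parent_diameter_mm = r$meta$parent_diameter,
    mcr_pct = 100 * r$meta$mcr,
    pore_density_per_mm2 = r$meta$pore_density,
    energy_loss = r$stented$energy_loss,
    energy_loss_rr_pct = r$reduction[["energy_loss"]],
    avg_velocity = r$stented$avg_velocity,
    avg_velocity_rr_pct = r$reduction[["avg_velocity"]],
    inflow = r$stented$inflow_rate,
    inflow_rr_pct = r$reduction[["inflow_rate"]]
  ))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

write_study_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(res$table, file.path(out_dir, "study_report.csv"),
                   row.names = FALSE)
  trend <- if (nrow(res$table) >= 3) trend_check(res)[c("pass", "violations")]
  jsonlite::write_json(
    list(table = res$table,
         braid = unclass(res$braid),
         trend = trend,
         logs = res$logs),
    file.path(out_dir, "study_report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}

#' @export
print.study_result <- function(x, ...) {
  cat("Flow-diverter sizing study\n")
  print(x$table, digits = 4)
  if (nrow(x$table) >= 3) {
    tc <- trend_check(x)
    cat(sprintf("Monotone-trend check: %s\n", if (tc$pass) "pass" else "FAIL"))
  }
  invisible(x)
}

#' Check the monotone-trend and plateau findings
#'
#' Diagnoses whether the reduction rates of energy loss, average velocity and
#' inflow each increase strictly with MCR across the scenarios, and tabulates
#' successive increments for the plateau observation (the gain from matching
#' to undersizing being smaller than from worst oversizing to matching).
#'
#' @param reports A `study_result`, or a data.frame shaped like
#'   [study_table()], or a list of reduction reports.
#' @return A list: `pass` (all three rates strictly increasing), `violations`
#'   (character description of each violating pair), `increments` (successive
#'   differences per parameter) and `plateau_params` (parameters whose final
#'   increment is smaller than the cumulative increase over the earlier
#'   scenarios).
#' @export
trend_check <- function(reports) {
  tab <- if (is.data.frame(reports)) reports else study_table(reports)
  if (nrow(tab) < 3)
    stop("trend check needs at least 3 scenarios", call. = FALSE)
  tab <- tab[order(tab$mcr_pct), ]
  pars <- c("energy_loss_rr_pct", "avg_velocity_rr_pct", "inflow_rr_pct")
  violations <- character(0)
  increments <- list()
  for (p in pars) {
    d <- diff(tab[[p]])
    increments[[p]] <- d
    bad <- which(d <= 0)
    for (b in bad)
      violations <- c(violations, sprintf(
        "%s not increasing from MCR %.1f%% (%.2f) to %.1f%% (%.2f)",
        p, tab$mcr_pct[b], tab[[p]][b], tab$mcr_pct[b + 1], tab[[p]][b + 1]))
  }
  # plateau: the final (matching -> undersizing) gain is smaller than the
  # cumulative gain from the worst oversizing up to matching
  plateau <- vapply(increments, function(d)
    d[length(d)] < sum(d[-length(d)]), logical(1))
  list(pass = length(violations) == 0, violations = violations,
       increments = increments,
       plateau_params = names(plateau)[plateau])
}
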