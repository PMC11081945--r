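test_that("steady channel flow converges to the Poiseuille solution", {
  pv <- poiseuille_validation()
  expect_lt(pv$profile_err, 0.01)
  expect_lt(pv$tau_err, 0.01)
  expect_lt(pv$result$max_divergence, 1e-8)
})

test_that("oscillatory channel flow matches the closed-form Womersley solution", {
  wv <- womersley_validation()
  expect_lt(wv$l2_err, 0.02)
  # error shrinks under refinement; the closed form is the exact limit, so
  # the observed order comes straight from the error ratio of the finer pair
  errs <- wv$convergence$metrics$l2_err
  expect_true(all(diff(errs) < 0))
  expect_gt(log2(errs[2] / errs[3]), 1.3)
})

test_that("aneurysm-case metrics converge under grid refinement", {
  # impulsively started steady inflow integrated to a fixed time; the sac
  # metrics at that instant must approach a grid-independent limit
  case <- function(h) {
    dom <- rasterize(build_sidewall_model(4.0, vessel_length = 30), h)
    wf <- pulsatile_waveform(0.25, period = 0.1)
    res <- run_flow(dom, fluid_properties(), wf,
                    simulation_config(n_cycles = 4L), init = "zero")
    s <- res$snapshots[[length(res$snapshots)]]
    c(sac_velocity = average_sac_velocity(s, dom),
      inflow = inflow_rate(s, dom))
  }
  gc <- grid_convergence(case, c(0.4, 0.2, 0.1))
  m <- gc$metrics
  expect_lt(abs(m$sac_velocity[2] - m$sac_velocity[3]),
            abs(m$sac_velocity[1] - m$sac_velocity[2]))
  expect_lt(abs(m$inflow[2] - m$inflow[3]), abs(m$inflow[1] - m$inflow[2]))
})

test_that("mass is conserved globally over the final cycle", {
  for (run in list(womersley_validation()$run,
                   coarse_runs()$baseline, coarse_runs()$stented)) {
    tr <- run$trace
    final <- tr$t > (run$config$n_cycles - 1) * run$waveform$period + 1e-12
    qin <- sum(tr$inlet_flux[final]) * run$dt
    qout <- sum(tr$outlet_flux[final]) * run$dt
    expect_lt(abs(qin - qout) / qin, 1e-3)
    # per-snapshot divergence stays at solver tolerance
    expect_lt(run$max_divergence, 1e-8)
  }
})

test_that("pulsatile aneurysm runs are stable, periodic and deterministic", {
  runs <- coarse_runs()
  for (run in list(runs$baseline, runs$stented)) {
    expect_true(all(is.finite(run$trace$kinetic_energy)))
    # kinetic energy stays bounded by a flow-scale estimate (no blow-up)
    ke_scale <- 0.5 * run$fluid$density * (2 * 0.25 * 1.5)^2 *
      sum(run$domain$lab > 0) * (run$domain$h * 1e-3)^2
    expect_lt(max(run$trace$kinetic_energy), ke_scale)
    # transients decay: periodicity residual shrinks cycle over cycle
    expect_lt(run$periodicity_residual[2], run$periodicity_residual[1])
  }
  # determinism: identical configuration gives bitwise-identical fields
  rerun <- run_flow(runs$domain, fluid_properties(), ica_waveform(),
                    simulation_config())
  last <- length(rerun$snapshots)
  expect_identical(rerun$snapshots[[last]]$u, runs$baseline$snapshots[[last]]$u)
  expect_identical(rerun$snapshots[[last]]$p, runs$baseline$snapshots[[last]]$p)
})

test_that("a vanishing screen reproduces the unstented flow", {
  runs <- coarse_runs()
  # Ergun properties at mcr = 1e-9: permeability ~ d_w^2/(150 mcr^2) -> huge
  open <- structure(list(porosity = 1 - 1e-9, thickness = 0.06,
                         permeability = 0.03^2 / (150 * 1e-18),
                         inertial_coeff = 3.5e-9 / 0.03, mcr = 1e-9,
                         wire_diameter = 0.030),
                    class = "screen_properties")
  with_open <- run_flow(runs$domain, fluid_properties(), ica_waveform(),
                        simulation_config(), screen = open)
  last <- length(with_open$snapshots)
  expect_equal(with_open$snapshots[[last]]$u,
               runs$baseline$snapshots[[last]]$u, tolerance = 1e-6)
})

test_that("the stented run suppresses through-neck velocities", {
  runs <- coarse_runs()
  isys <- systole_index(runs$baseline)
  dom <- runs$domain
  vb <- runs$baseline$snapshots[[isys]]$v[cbind(dom$neck_cols, dom$j_neck)]
  vs <- runs$stented$snapshots[[isys]]$v[cbind(dom$neck_cols, dom$j_neck)]
  expect_lt(max(abs(vs)), 0.05 * max(abs(vb)))
})

test_that("grid convergence harness validates its inputs and reports orders", {
  expect_error(grid_convergence(function(h) c(m = h), c(0.4, 0.2)), "3 levels")
  expect_error(grid_convergence(function(h) c(m = h), c(0.4, 0.3, 0.2)), "halving")
  gc <- grid_convergence(function(h) c(m = 1 + h^2, q = 2 + h), c(0.4, 0.2, 0.1))
  expect_equal(gc$orders$order[gc$orders$metric == "m"], 2, tolerance = 1e-10)
  expect_equal(gc$orders$order[gc$orders$metric == "q"], 1, tolerance = 1e-10)
})

test_that("solver configuration guards hold", {
  expect_error(simulation_config(cfl = 0.6), "cfl")
  expect_error(simulation_config(n_cycles = 2), "n_cycles")
  cfg <- simulation_config()
  expect_equal(cfg$n_cycles, 3L)
  expect_equal(cfg$snapshots_per_cycle, 50L)
})
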