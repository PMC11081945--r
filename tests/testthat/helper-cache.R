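# Heavy fixtures computed once per test session and shared between the module
# tests and the acceptance suite.

.fdhemo_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fdhemo_cache, inherits = FALSE))
    assign(name, force(expr), envir = .fdhemo_cache)
  get(name, envir = .fdhemo_cache, inherits = FALSE)
}

# Calibrated study braid (nominal angle from the matched-size MCR).
study_braid <- function() cached("braid", {
  calibrate_nominal_angle(braid_spec(), 0.372)
})

# The four calibrated deployment scenarios (3.0/3.5/4.0/4.5 mm).
study_deployments <- function() cached("deployments", {
  b <- study_braid()
  d <- c(3.0, 3.5, 4.0, 4.5)
  m <- c(0.255, 0.294, 0.372, 0.480)
  Map(function(dv, mt) fdhemo:::calibrate_scenario(b, dv, mt, 0.97), d, m)
})

# Steady Poiseuille channel at h = H/40 from rest, plus closed-form errors.
poiseuille_validation <- function() cached("poiseuille", {
  H <- 4; h <- H / 40
  dom <- channel_domain(H, 4, h)
  fl <- fluid_properties(1055, 0.004)
  U0 <- 0.25
  res <- run_steady(dom, fl, U0, rtol = 1e-7, init = "zero")
  s <- res$snapshots[[1]]
  iu <- round(dom$nx / 2)
  y <- (seq_len(dom$ny) - 0.5) * h
  exact <- U0 * 6 * (y / H) * (1 - y / H)
  profile_err <- max(abs(s$u[iu, ] - exact)) / max(exact)
  uc <- 0.5 * (s$u[iu, ] + s$u[iu + 1L, ])
  tau <- fl$viscosity * (9 * uc[1] - uc[2]) / (3 * h * 1e-3)
  tau_exact <- 6 * fl$viscosity * U0 / (H * 1e-3)
  list(result = res, profile_err = profile_err,
       tau = tau, tau_exact = tau_exact,
       tau_err = abs(tau - tau_exact) / tau_exact)
})

# Single-harmonic oscillatory channel versus the closed-form Womersley
# solution at three grid levels (finest h = H/40, CFL 0.25); returns the
# relative L2 error per level and the finest-level run.
womersley_case <- function(h, keep_run = FALSE) {
  H <- 4
  fl <- fluid_properties(1055, 0.004)
  wf <- pulsatile_waveform(0.25, period = 1.0, harmonics = c(0.5 + 0i))
  dom <- channel_domain(H, 2, h)
  cfg <- simulation_config(cfl = 0.25)
  res <- run_flow(dom, fl, wf, cfg)
  iu <- as.integer(round(1.2 / h)) + 1L  # sample plane fixed at x = 1.2 mm
  y <- (seq_len(dom$ny) - 0.5) * h
  num <- 0; den <- 0
  for (k in seq_along(res$snapshots)) {
    s <- res$snapshots[[k]]
    exact <- womersley_inlet_profile(wf, fl, H, s$t, y = y)
    num <- num + sum((s$u[iu, ] - exact)^2)
    den <- den + sum(exact^2)
  }
  out <- c(l2_err = sqrt(num / den))
  if (keep_run) attr(out, "run") <- res
  out
}

womersley_validation <- function() cached("womersley", {
  conv <- grid_convergence(womersley_case, c(0.4, 0.2, 0.1))
  fine <- womersley_case(0.1, keep_run = TRUE)
  list(convergence = conv, l2_err = as.numeric(fine["l2_err"]),
       run = attr(fine, "run"))
})

# Full sizing study at the reference conditions (h = 0.2 mm, 3 cycles).
study_result_cached <- function() cached("study", {
  run_study(study_config(), quiet = TRUE)
})

# Cheap aneurysm domain + coarse pulsatile runs for structural tests.
coarse_domain <- function() cached("coarse_domain", {
  rasterize(build_sidewall_model(4.0, vessel_length = 30), 0.4)
})

coarse_runs <- function() cached("coarse_runs", {
  dom <- coarse_domain()
  fl <- fluid_properties()
  wf <- ica_waveform()
  cfg <- simulation_config()
  base <- run_flow(dom, fl, wf, cfg)
  scr <- screen_from_braid(study_deployments()[[3]]$deployed)
  sten <- run_flow(dom, fl, wf, cfg, screen = scr)
  list(domain = dom, baseline = base, stented = sten)
})
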