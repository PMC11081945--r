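#' Solver configuration
#'
#' Numerical parameters of the projection-method flow solver. The time step is
#' fixed per run: the advective limit uses a design peak velocity
#' (`u_design_factor` x centerline peak of the inlet waveform) and is combined
#' with the explicit-diffusion limit, then rounded down so that an integer
#' number of steps lands exactly on every snapshot time.
#'
#' @param cfl Advective CFL number (<= 0.5), default 0.4.
#' @param n_cycles Number of cardiac cycles to integrate (>= 3); hemodynamic
#'   analysis uses the final cycle.
#' @param snapshots_per_cycle Snapshots retained per cycle (default 50; the
#'   final cycle stores both endpoints, so 51 states).
#' @param tol Pressure-solve/divergence tolerance (1/s) used by the
#'   divergence invariant check; the Poisson solve itself is direct.
#' @param u_design_factor Safety margin on the design peak velocity for the
#'   advective time-step limit (default 1.3).
#' @param diff_safety Fraction of the explicit diffusion limit `h^2/(4 nu)`
#'   (default 0.6, leaving headroom for the slightly stiffer quadratic wall
#'   ghosts).
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(cfl = 0.4, n_cycles = 3L, snapshots_per_cycle = 50L,
                              tol = 1e-6, u_design_factor = 1.3, diff_safety = 0.6) {
  if (cfl <= 0 || cfl > 0.5) stop("cfl must lie in (0, 0.5]", call. = FALSE)
  if (n_cycles < 3) stop("n_cycles must be >= 3 (analysis on the final cycle)", call. = FALSE)
  if (snapshots_per_cycle < 4) stop("need at least 4 snapshots per cycle", call. = FALSE)
  structure(list(cfl = cfl, n_cycles = as.integer(n_cycles),
                 snapshots_per_cycle = as.integer(snapshots_per_cycle),
                 tol = tol, u_design_factor = u_design_factor,
                 diff_safety = diff_safety),
            class = "simulation_config")
}

# Face-state matrices for the staggered grid (see src/solver_kernels.cpp).
face_states <- function(domain) {
  fl <- domain$lab > 0L
  nx <- domain$nx; ny <- domain$ny
  ustate <- matrix(0L, nx + 1L, ny)
  ustate[1L, ] <- ifelse(fl[1L, ], 2L, 0L)
  ustate[nx + 1L, ] <- ifelse(fl[nx, ], 3L, 0L)
  if (nx > 1) ustate[2:nx, ] <- ifelse(fl[1:(nx - 1), ] & fl[2:nx, ], 1L, 0L)
  vstate <- matrix(0L, nx, ny + 1L)
  if (ny > 1) vstate[, 2:ny] <- ifelse(fl[, 1:(ny - 1)] & fl[, 2:ny], 1L, 0L)
  list(ustate = ustate, vstate = vstate)
}

# Per-face screen drag coefficients (SI): linear (Darcy, 1/s) and quadratic
# (Forchheimer, 1/m) parts, scaled by thickness/cell-height so the thin
# screen smeared over one cell exerts the same total force. The screen lies
# on the neck line, so it crosses exactly the neck v-faces: the drag resists
# through-screen (normal) flow. Tangential faces sit half a cell off the
# screen plane and carry no drag; loading them would impose an artificial
# blockage of the parent-channel flow (see the methods vignette).
screen_coefficients <- function(domain, fluid, screen) {
  nx <- domain$nx; ny <- domain$ny
  au_lin <- matrix(0, nx + 1L, ny); au_quad <- matrix(0, nx + 1L, ny)
  av_lin <- matrix(0, nx, ny + 1L); av_quad <- matrix(0, nx, ny + 1L)
  if (!is.null(screen)) {
    k_si <- screen$permeability * 1e-6
    C_si <- screen$inertial_coeff * 1e3
    t_si <- screen$thickness * 1e-3
    h_si <- domain$h * 1e-3
    A_lin <- (fluid$viscosity / k_si) / fluid$density * (t_si / h_si)
    A_quad <- (C_si / 2) * (t_si / h_si)
    jn <- domain$j_neck
    av_lin[domain$neck_cols, jn] <- A_lin
    av_quad[domain$neck_cols, jn] <- A_quad
  }
  list(au_lin = au_lin, au_quad = au_quad, av_lin = av_lin, av_quad = av_quad)
}

# Variable-coefficient pressure Poisson operator -div(beta grad p) over fluid
# cells, with homogeneous Neumann at walls/inlet and Dirichlet p = 0 on the
# outlet face; returns the CHOLMOD factorization. beta = 1/(1 + dt * a_darcy)
# matches the implicit Darcy treatment in predictor and corrector.
build_pressure_solver <- function(domain, bu, bv) {
  fl <- domain$lab > 0L
  nx <- domain$nx; ny <- domain$ny
  nfl <- sum(fl)
  id <- matrix(0L, nx, ny)
  id[fl] <- seq_len(nfl)
  cells <- which(fl, arr.ind = TRUE)
  ci <- cells[, 1]; cj <- cells[, 2]; cid <- id[fl]

  ti <- integer(0); tj <- integer(0); tx <- numeric(0)
  diag_acc <- numeric(nfl)
  add_dir <- function(di, dj, wfun) {
    ni <- ci + di; nj <- cj + dj
    ok <- ni >= 1L & ni <= nx & nj >= 1L & nj <= ny
    ok[ok] <- fl[cbind(ni[ok], nj[ok])]
    if (!any(ok)) return(invisible(NULL))
    w <- wfun(ci[ok], cj[ok])
    ti <<- c(ti, cid[ok]); tj <<- c(tj, id[cbind(ni[ok], nj[ok])]); tx <<- c(tx, -w)
    diag_acc[cid[ok]] <<- diag_acc[cid[ok]] + w
    invisible(NULL)
  }
  add_dir(1L, 0L, function(i, j) bu[cbind(i + 1L, j)])   # east face
  add_dir(-1L, 0L, function(i, j) bu[cbind(i, j)])       # west face
  add_dir(0L, 1L, function(i, j) bv[cbind(i, j + 1L)])   # north face
  add_dir(0L, -1L, function(i, j) bv[cbind(i, j)])       # south face
  # outlet Dirichlet: ghost p = -p for cells in the last column
  out_cells <- which(ci == nx)
  diag_acc[cid[out_cells]] <- diag_acc[cid[out_cells]] + 2

  h_si <- domain$h * 1e-3
  M <- Matrix::sparseMatrix(
    i = c(ti, seq_len(nfl)), j = c(tj, seq_len(nfl)),
    x = c(tx, diag_acc) / h_si^2, dims = c(nfl, nfl)
  )
  M <- Matrix::forceSymmetric(M, uplo = "L")
  list(chol = Matrix::Cholesky(M, LDL = FALSE), fl = fl, nfl = nfl)
}

# Assemble everything needed to advance the flow; internal.
solver_operators <- function(domain, fluid, waveform, config, screen = NULL) {
  h_si <- domain$h * 1e-3
  nu <- fluid$nu
  # fixed time step: advective design limit + diffusive limit, aligned to
  # snapshot times
  tt <- seq(0, waveform$period, length.out = 512)
  peak_mean <- max(mean_inlet_velocity(waveform, tt))
  u_design <- config$u_design_factor * 1.5 * peak_mean
  dt_adv <- config$cfl * h_si / u_design
  dt_diff <- config$diff_safety * h_si^2 / (4 * nu)
  dt_lim <- min(dt_adv, dt_diff)
  nsnap <- config$snapshots_per_cycle
  n_sub <- max(1L, as.integer(ceiling(waveform$period / (nsnap * dt_lim))))
  dt <- waveform$period / (nsnap * n_sub)

  st <- face_states(domain)
  sc <- screen_coefficients(domain, fluid, screen)
  bu <- 1 / (1 + dt * sc$au_lin)
  bv <- 1 / (1 + dt * sc$av_lin)
  ps <- build_pressure_solver(domain, bu, bv)

  inlet_rows <- which(domain$lab[1L, ] > 0L)
  y_in <- (inlet_rows - 0.5) * domain$h
  list(domain = domain, fluid = fluid, waveform = waveform, config = config,
       screen = screen, h_si = h_si, nu = nu, dt = dt, n_sub = n_sub,
       ustate = st$ustate, vstate = st$vstate,
       au_lin = sc$au_lin, au_quad = sc$au_quad,
       av_lin = sc$av_lin, av_quad = sc$av_quad,
       bu = bu, bv = bv, pressure = ps,
       inlet_rows = inlet_rows, y_in = y_in,
       outlet_rows = which(domain$lab[domain$nx, ] > 0L))
}

# Initial state: fully developed inlet profile replicated along the channel
# (divergence-free on this grid), zero in the sac; or rest.
initial_state <- function(ops, init = c("profile", "zero")) {
  init <- match.arg(init)
  d <- ops$domain
  U <- matrix(0, d$nx + 1L, d$ny)
  V <- matrix(0, d$nx, d$ny + 1L)
  if (init == "profile") {
    prof <- womersley_inlet_profile(ops$waveform, ops$fluid, d$wall_y, 0, y = ops$y_in)
    chan_rows <- intersect(seq_len(d$n_chan), ops$inlet_rows)
    for (j in chan_rows) U[, j] <- prof[match(j, ops$inlet_rows)]
    # zero any face touching a solid cell (sac rows are untouched: profile
    # rows are channel rows, which span the whole length)
    U[ops$ustate == 0L] <- 0
  }
  list(u = U, v = V, p = matrix(0, d$nx, d$ny), t = 0)
}

#' Advance the flow by one projection step
#'
#' One fixed-dt step: explicit second-order-upwind advection and explicit
#' diffusion with semi-implicit screen drag, a variable-coefficient pressure
#' Poisson solve (direct, CHOLMOD), and velocity correction.
#'
#' @param state List with staggered `u`, `v` (m/s), `p` (Pa) and time `t` (s).
#' @param ops Operator set from the internal `solver_operators()`; exposed via
#'   [run_flow()] for typical use.
#' @return Updated state; attribute `maxvel` carries the max face speed.
#' @keywords internal
flow_step <- function(state, ops) {
  d <- ops$domain
  tn <- state$t + ops$dt
  prof <- womersley_inlet_profile(ops$waveform, ops$fluid, d$wall_y, tn, y = ops$y_in)
  U <- state$u
  U[cbind(1L, ops$inlet_rows)] <- prof
  pr <- predictor_step(U, state$v, ops$ustate, ops$vstate, d$lab,
                       ops$au_lin, ops$au_quad, ops$av_lin, ops$av_quad,
                       ops$dt, ops$h_si, ops$nu)
  if (isTRUE(pr$bad))
    stop(sprintf("solver diverged (non-finite velocity) at t = %.4f s during the predictor step", tn),
         call. = FALSE)
  if (pr$maxvel * ops$dt / ops$h_si > 0.95)
    stop(sprintf("solver unstable: CFL %.2f > 0.95 at t = %.4f s; reduce cfl or increase u_design_factor",
                 pr$maxvel * ops$dt / ops$h_si, tn), call. = FALSE)
  b <- -(ops$fluid$density / ops$dt) * pr$div[ops$pressure$fl]
  pvec <- as.numeric(Matrix::solve(ops$pressure$chol, b, system = "A"))
  P <- matrix(0, d$nx, d$ny)
  P[ops$pressure$fl] <- pvec
  co <- corrector_step(pr$us, pr$vs, P, ops$ustate, ops$vstate,
                       ops$bu, ops$bv, ops$dt / (ops$fluid$density * ops$h_si))
  out <- list(u = co$u, v = co$v, p = P, t = tn)
  attr(out, "maxvel") <- pr$maxvel
  out
}

inlet_flux <- function(state, ops) sum(state$u[1L, ops$inlet_rows]) * ops$h_si
outlet_flux <- function(state, ops) sum(state$u[ops$domain$nx + 1L, ops$outlet_rows]) * ops$h_si

#' Run a pulsatile flow simulation
#'
#' Integrates the 2D incompressible Navier-Stokes equations over `n_cycles`
#' cardiac cycles on the rasterized domain, with the Womersley-type inlet, a
#' zero-pressure outlet, rigid no-slip walls, and (optionally) the permeable
#' neck screen. Snapshots of the final cycle are retained for hemodynamic
#' analysis; the inlet/outlet flux traces cover all cycles. The algorithm is
#' fully deterministic.
#'
#' @param domain A [rasterize()] or [channel_domain()] result.
#' @param fluid A [fluid_properties()].
#' @param waveform A [pulsatile_waveform()].
#' @param config A [simulation_config()].
#' @param screen Optional [screen_from_braid()] result; `NULL` for the
#'   unstented baseline.
#' @param init Initial condition: fully developed `"profile"` (default) or
#'   `"zero"`.
#' @return An object of class `flow_series`: snapshot list (`u`, `v`, `p`,
#'   `t`) covering the final cycle (both endpoints), flux and kinetic-energy
#'   traces for all cycles, per-cycle periodicity residuals (L2 velocity
#'   difference between consecutive cycle-end states), the time step, and the
#'   maximum post-projection divergence observed.
#' @export
run_flow <- function(domain, fluid, waveform, config = simulation_config(),
                     screen = NULL, init = "profile") {
  ops <- solver_operators(domain, fluid, waveform, config, screen)
  state <- initial_state(ops, init)
  nsnap <- config$snapshots_per_cycle
  steps_per_cycle <- nsnap * ops$n_sub
  n_steps <- config$n_cycles * steps_per_cycle

  t_all <- numeric(n_steps); q_in <- numeric(n_steps); q_out <- numeric(n_steps)
  ke <- numeric(n_steps)
  snapshots <- vector("list", nsnap + 1L)
  cycle_ends <- vector("list", config$n_cycles + 1L)
  cycle_ends[[1L]] <- state[c("u", "v")]
  final_start <- (config$n_cycles - 1L) * steps_per_cycle
  max_div <- 0

  for (s in seq_len(n_steps)) {
    state <- flow_step(state, ops)
    t_all[s] <- state$t
    q_in[s] <- inlet_flux(state, ops)
    q_out[s] <- outlet_flux(state, ops)
    ke[s] <- 0.5 * fluid$density * (sum(state$u^2) + sum(state$v^2)) * ops$h_si^2
    if (s %% steps_per_cycle == 0L)
      cycle_ends[[s %/% steps_per_cycle + 1L]] <- state[c("u", "v")]
    if (s == final_start)
      snapshots[[1L]] <- state
    if (s > final_start && (s - final_start) %% ops$n_sub == 0L)
      snapshots[[(s - final_start) %/% ops$n_sub + 1L]] <- state
    if (s %% steps_per_cycle == 0L) {
      dv <- max_divergence(state$u, state$v, domain$lab, ops$h_si)
      max_div <- max(max_div, dv)
    }
  }
  resid <- vapply(seq_len(config$n_cycles - 1L) + 1L, function(c2) {
    a <- cycle_ends[[c2]]; b <- cycle_ends[[c2 + 1L]]
    sqrt(sum((a$u - b$u)^2) + sum((a$v - b$v)^2)) * ops$h_si
  }, numeric(1))

  structure(list(
    domain = domain, fluid = fluid, waveform = waveform, config = config,
    screen = screen, dt = ops$dt,
    snapshots = snapshots,
    snapshot_times = vapply(snapshots, `[[`, numeric(1), "t"),
    trace = data.frame(t = t_all, inlet_flux = q_in, outlet_flux = q_out,
                       kinetic_energy = ke),
    periodicity_residual = resid,
    max_divergence = max_div
  ), class = "flow_series")
}

#' @export
print.flow_series <- function(x, ...) {
  cat(sprintf("Flow series: %d cycles at dt = %.3e s (%d snapshots of the final cycle)\n  periodicity residual by cycle: %s\n  max post-projection divergence: %.2e 1/s\n",
              x$config$n_cycles, x$dt, length(x$snapshots),
              paste(sprintf("%.3e", x$periodicity_residual), collapse = ", "),
              x$max_divergence))
  invisible(x)
}

#' Run a steady-inflow simulation to convergence
#'
#' Steady counterpart of [run_flow()] used by validation and grid-convergence
#' cases: constant inlet profile, steps until the velocity field stops
#' changing.
#'
#' @param domain,fluid,screen As in [run_flow()].
#' @param mean_velocity Steady cross-section-mean inlet velocity (m/s).
#' @param cfl,u_design_factor,diff_safety As in [simulation_config()].
#' @param rtol Convergence threshold: max per-step velocity change below
#'   `rtol * mean_velocity` (default 1e-7).
#' @param max_time Physical time cap (s).
#' @param init Initial condition, `"zero"` (default: the flow must develop) or
#'   `"profile"`.
#' @return A single-state `flow_series`-like list with the converged snapshot.
#' @export
run_steady <- function(domain, fluid, mean_velocity, screen = NULL,
                       cfl = 0.4, u_design_factor = 1.3, diff_safety = 0.6,
                       rtol = 1e-7, max_time = 20, init = "zero") {
  waveform <- pulsatile_waveform(mean_velocity, period = 1.0)
  config <- simulation_config(cfl = cfl, n_cycles = 3L, snapshots_per_cycle = 50L,
                              u_design_factor = u_design_factor,
                              diff_safety = diff_safety)
  ops <- solver_operators(domain, fluid, waveform, config, screen)
  state <- initial_state(ops, init)
  repeat {
    prev_u <- state$u; prev_v <- state$v
    state <- flow_step(state, ops)
    delta <- max(max(abs(state$u - prev_u)), max(abs(state$v - prev_v)))
    if (delta < rtol * mean_velocity) break
    if (state$t > max_time)
      stop(sprintf("steady run did not converge within %.1f s of physical time (residual %.3e)",
                   max_time, delta / mean_velocity), call. = FALSE)
  }
  structure(list(domain = domain, fluid = fluid, waveform = waveform,
                 config = config, screen = screen, dt = ops$dt,
                 snapshots = list(state), snapshot_times = state$t,
                 trace = NULL,
                 periodicity_residual = numeric(0),
                 max_divergence = max_divergence(state$u, state$v, domain$lab, ops$h_si)),
            class = "flow_series")
}

#' Grid-convergence harness
#'
#' Runs a case at three or more grid spacings (each level halving `h`) and
#' reports the metrics per level together with the observed convergence order
#' from Richardson extrapolation over successive level triples,
#' `order = log2(|m1 - m2| / |m2 - m3|)`. Non-monotone differences yield `NA`
#' orders and are reported, not raised.
#'
#' @param case A function `h -> named numeric vector` of metrics (e.g.
#'   sac-averaged velocity and inflow rate, or an error against a closed
#'   form).
#' @param h_levels Grid spacings (mm), descending, each level half the
#'   previous; at least 3.
#' @return A list with `metrics` (data.frame, one row per level) and `orders`
#'   (data.frame of observed orders per metric and triple).
#' @export
grid_convergence <- function(case, h_levels) {
  if (length(h_levels) < 3)
    stop("grid convergence needs at least 3 levels", call. = FALSE)
  h_levels <- as.numeric(h_levels)
  if (any(diff(h_levels) >= 0) ||
      any(abs(h_levels[-1] / h_levels[-length(h_levels)] - 0.5) > 1e-8))
    stop("h_levels must be descending with each level halving h", call. = FALSE)
  rows <- lapply(h_levels, function(h) as.data.frame(as.list(case(h))))
  metrics <- cbind(h = h_levels, do.call(rbind, rows))
  ord <- lapply(seq_len(length(h_levels) - 2L), function(k) {
    m1 <- unlist(rows[[k]]); m2 <- unlist(rows[[k + 1L]]); m3 <- unlist(rows[[k + 2L]])
    d12 <- abs(m1 - m2); d23 <- abs(m2 - m3)
    o <- ifelse(d23 > 0 & d12 > 0, log2(d12 / d23), NA_real_)
    data.frame(triple = k, metric = names(o), order = as.numeric(o),
               row.names = NULL)
  })
  list(metrics = metrics, orders = do.call(rbind, ord))
}
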