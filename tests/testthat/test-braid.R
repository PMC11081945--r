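test_that("maximum free diameter follows wire inextensibility", {
  b <- braid_spec(48, 0.030, 4.0, 75)
  expect_equal(max_free_diameter(b), 4.0 / sin(75 * pi / 180), tolerance = 1e-12)
  # fully circumferential braid cannot expand at all (thin wire so the
  # nominal state is still feasible at this extreme angle)
  b90 <- braid_spec(48, 1e-6, 4.0, 89.99)
  expect_equal(max_free_diameter(b90), 4.0, tolerance = 1e-4)
  # a 5.0 mm vessel is unreachable for any nominal angle >= asin(4/5)
  for (a0 in c(53.14, 60, 75, 85)) {
    bb <- braid_spec(48, 0.030, 4.0, a0)
    expect_lt(max_free_diameter(bb), 5.0)
    expect_error(deploy(bb, 5.0), "over-expansion")
  }
})

test_that("deployment kinematics match the analytic chain", {
  b <- braid_spec(48, 0.030, 4.0, 75)
  # nominal state is a fixed point
  nom <- deploy(b, 4.0, 1)
  expect_equal(nom$deployed_angle, 75, tolerance = 1e-10)
  expect_equal(nom$foreshortening, 1, tolerance = 1e-12)
  # worked example: D = 3.5 mm free deployment
  d35 <- deploy(b, 3.5, 1)
  alpha <- asin((3.5 / 4) * sin(75 * pi / 180))
  s_perp <- (2 * pi * 3.5 / 48) * cos(alpha)
  expect_equal(d35$s_perp, s_perp, tolerance = 1e-12)
  expect_equal(d35$mcr, 1 - (1 - 0.030 / s_perp)^2, tolerance = 1e-12)
  expect_equal(d35$mcr, 0.230, tolerance = 2e-3)
  # vanishing wire width covers nothing
  thin <- braid_spec(48, 1e-9, 4.0, 75)
  expect_lt(deploy(thin, 3.5, 1)$mcr, 1e-6)
  # compaction strictly increases coverage at fixed diameter
  mcrs <- vapply(c(1, 1.2, 1.5, 2, 3), function(k) deploy(b, 3.5, k)$mcr, numeric(1))
  expect_true(all(diff(mcrs) > 0))
  expect_error(deploy(b, 3.5, 0.9), "kappa")
})

test_that("analytic MCR agrees with the Monte-Carlo rasterization oracle", {
  b <- braid_spec(48, 0.030, 4.0, 75)
  d35 <- deploy(b, 3.5, 1)
  o <- mcr_oracle(d35, n_samples = 2e5, seed = 11)
  expect_lt(abs(o$mcr - d35$mcr), 3 * o$se)
  # deterministic given the seed, and does not disturb the global RNG stream
  set.seed(123); before <- runif(1)
  o2 <- mcr_oracle(d35, n_samples = 2e5, seed = 11)
  expect_identical(o$mcr, o2$mcr)
  set.seed(123)
  expect_identical(runif(1), before)
  # degenerate cells
  zero <- d35; zero$braid$wire_diameter <- 0
  expect_equal(mcr_oracle(zero, 1e4, 1)$mcr, 0)
  full <- d35; full$braid$wire_diameter <- d35$s_perp
  expect_equal(mcr_oracle(full, 1e4, 1)$mcr, 1)
})

test_that("analytic MCR tracks the oracle across a randomized sweep", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(c(32L, 48L, 64L), 1)
    a0 <- runif(1, 55, 85)
    dw <- runif(1, 0.02, 0.05)
    b <- try(braid_spec(n, dw, 4.0, a0), silent = TRUE)
    if (inherits(b, "try-error")) next
    D <- runif(1, 2.5, 0.999 * max_free_diameter(b))
    k <- runif(1, 1, 1.5)
    dep <- suppressWarnings(deploy(b, D, k))
    if (dep$mcr >= 1) next
    o <- mcr_oracle(dep, n_samples = 1e5, seed = rep)
    expect_lt(abs(o$mcr - dep$mcr), 3 * o$se)
  }
})

test_that("nominal-angle calibration round-trips and is monotone", {
  b0 <- braid_spec()
  b <- calibrate_nominal_angle(b0, 0.372)
  expect_equal(deploy(b, 4.0, 1)$mcr, 0.372, tolerance = 1e-6)
  # larger target -> steeper nominal angle
  angles <- vapply(c(0.2, 0.3, 0.372, 0.45),
                   function(m) calibrate_nominal_angle(b0, m)$nominal_angle,
                   numeric(1))
  expect_true(all(diff(angles) > 0))
  expect_error(calibrate_nominal_angle(b0, 0), "in \\(0, 1\\)")
  expect_error(calibrate_nominal_angle(b0, 1), "in \\(0, 1\\)")
})

test_that("compaction calibration round-trips and is monotone in the target", {
  b <- study_braid()
  free <- deploy(b, 3.0, 1)$mcr
  expect_equal(calibrate_compaction(b, 3.0, free), 1)
  expect_error(calibrate_compaction(b, 3.0, free - 0.05), "non-physical")
  for (m in c(0.255, 0.30, 0.40)) {
    k <- calibrate_compaction(b, 3.0, m)
    expect_equal(deploy(b, 3.0, k)$mcr, m, tolerance = 1e-6)
  }
  ks <- vapply(c(0.22, 0.255, 0.30, 0.40),
               function(m) calibrate_compaction(b, 3.0, m), numeric(1))
  expect_true(all(diff(ks) > 0))
})

test_that("free-deployment MCR increases with vessel diameter over the sizing range", {
  # coverage is minimized at D0/(sqrt(2) sin a0) ~ 2.94 mm; above that point
  # (the whole oversizing-to-undersizing range of the study) it increases
  # strictly up to the maximal free diameter
  b <- study_braid()
  d_min <- b$nominal_diameter / (sqrt(2) * sin(b$nominal_angle * pi / 180))
  expect_lt(d_min, 3.0)
  ds <- seq(3.0, 0.995 * max_free_diameter(b), length.out = 15)
  mcrs <- vapply(ds, function(d) deploy(b, d, 1)$mcr, numeric(1))
  expect_true(all(diff(mcrs) > 0))
})

test_that("the four calibrated scenarios reproduce the measured MCRs in order", {
  deps <- study_deployments()
  mcr <- vapply(deps, function(x) x$deployed$mcr, numeric(1))
  expect_equal(unname(mcr), c(0.255, 0.294, 0.372, 0.480), tolerance = 1e-6)
  pd <- vapply(deps, function(x) x$deployed$pore_density, numeric(1))
  expect_true(all(diff(pd) > 0))  # pore density and MCR increase together
  # only the undersized vessel needs the apposition cap
  expect_equal(vapply(deps, function(x) x$capped, logical(1)),
               c(D3 = FALSE, D3.5 = FALSE, D4 = FALSE, D4.5 = TRUE),
               ignore_attr = TRUE)
})

test_that("braid_sweep tabulates deployments", {
  tab <- braid_sweep(study_braid(), c(3.0, 3.5, 4.0))
  expect_equal(nrow(tab), 3)
  expect_true(all(diff(tab$mcr) > 0))
  expect_named(tab, c("d_vessel", "kappa", "deployed_angle", "s_perp", "mcr",
                      "pore_density", "foreshortening"))
})
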