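fake_table <- function(rates) {
  data.frame(parent_diameter_mm = seq(3, by = 0.5, length.out = nrow(rates)),
             mcr_pct = seq(25, by = 8, length.out = nrow(rates)),
             pore_density_per_mm2 = seq(28, by = 10, length.out = nrow(rates)),
             energy_loss = 1, energy_loss_rr_pct = rates[, 1],
             avg_velocity = 1, avg_velocity_rr_pct = rates[, 2],
             inflow = 1, inflow_rr_pct = rates[, 3])
}

test_that("trend check passes monotone tables and names violating pairs", {
  good <- fake_table(cbind(c(50, 52, 56, 56.1), c(57, 80, 83, 84), c(57, 71, 76, 77)))
  tc <- trend_check(good)
  expect_true(tc$pass)
  expect_length(tc$violations, 0)
  # the plateau: later increments smaller than earlier ones
  expect_setequal(tc$plateau_params,
                  c("energy_loss_rr_pct", "avg_velocity_rr_pct", "inflow_rr_pct"))

  shuffled <- good
  shuffled$inflow_rr_pct <- c(57, 76, 71, 77)
  tc2 <- trend_check(shuffled)
  expect_false(tc2$pass)
  expect_match(tc2$violations, "inflow_rr_pct", all = FALSE)
  expect_match(tc2$violations, "33.0", all = FALSE)  # the violating MCR

  expect_error(trend_check(good[1:2, ]), "3 scenarios")
})

test_that("study configuration validates its scenario lists", {
  expect_error(study_config(parent_diameters = c(4, 3.5)), "ascending")
  expect_error(study_config(mcr_targets = c(0.3, 0.4)), "one MCR target")
  cfg <- study_config()
  expect_equal(cfg$matched_mcr, 0.372)  # picked from the matched scenario
  expect_equal(cfg$parent_diameters, c(3.0, 3.5, 4.0, 4.5))
})

test_that("the published reference table reproduces its consistent cells", {
  ref <- reference_scenarios()
  expect_equal(nrow(ref), 4)
  expect_equal(ref$mcr_pct, c(25.5, 29.4, 37.2, 48.0))
  expect_true(all(diff(ref$pore_density_per_mm2) > 0))
  for (par in c("energy_loss", "avg_velocity", "inflow")) {
    rec <- reduction_rate(ref[[paste0(par, "_baseline")]],
                          ref[[paste0(par, "_stented")]])
    printed <- ref[[paste0(par, "_rr_pct")]]
    consistent <- ref[[paste0(par, "_consistent")]]
    expect_identical(rec[consistent], printed[consistent])
    # the flagged cells differ only by one unit in the last printed digit
    expect_true(all(abs(rec[!consistent] - printed[!consistent]) <= 0.041))
  }
})

test_that("a coarse two-scenario study orchestrates end to end", {
  cfg <- study_config(parent_diameters = c(4.0, 4.5),
                      mcr_targets = c(0.372, 0.480),
                      h = 0.4,
                      out_dir = file.path(tempdir(), "fdhemo-mini-study"))
  res <- run_study(cfg, quiet = TRUE)
  expect_s3_class(res, "study_result")
  expect_equal(nrow(res$table), 2)
  expect_true(all(res$table$inflow_rr_pct > 0))
  expect_true(all(res$table$energy_loss_rr_pct > 0))
  expect_true(all(res$table$avg_velocity_rr_pct > 0))
  expect_true(all(diff(res$table$mcr_pct) > 0))
  expect_true(all(diff(res$table$pore_density_per_mm2) > 0))
  # report files written
  expect_true(file.exists(file.path(cfg$out_dir, "study_report.csv")))
  expect_true(file.exists(file.path(cfg$out_dir, "study_report.json")))
  # the capped 4.5 mm scenario is logged as such
  expect_true(res$logs[["D4.5"]]$capped)
  expect_false(res$logs[["D4.0"]]$capped)

  # scenario independence: a single-diameter study reproduces the same row
  solo <- run_study(study_config(parent_diameters = 4.0, mcr_targets = 0.372,
                                 h = 0.4), quiet = TRUE)
  expect_equal(solo$table, res$table[1, ], ignore_attr = TRUE)

  # determinism: identical config gives a byte-identical CSV
  cfg2 <- cfg; cfg2$out_dir <- file.path(tempdir(), "fdhemo-mini-study-2")
  res2 <- run_study(cfg2, quiet = TRUE)
  expect_identical(readLines(file.path(cfg$out_dir, "study_report.csv")),
                   readLines(file.path(cfg2$out_dir, "study_report.csv")))
})

test_that("a failing scenario is recorded without aborting the study", {
  # 5.0 mm parent artery: braid cannot reach the vessel and the apposition
  # cap cannot recreate so low an MCR target -> recorded failure
  cfg <- study_config(parent_diameters = c(4.0, 5.0),
                      mcr_targets = c(0.372, 0.10),
                      h = 0.4)
  expect_warning(res <- run_study(cfg, quiet = TRUE), "failed")
  expect_s3_class(res$reports[["D5.0"]], "scenario_failure")
  expect_equal(nrow(res$table), 1)
})

test_that("study configuration round-trips through YAML", {
  cfg <- study_config(parent_diameters = c(3.5, 4.0),
                      mcr_targets = c(0.294, 0.372),
                      h = 0.25, wire_diameter = 0.033)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_study_config(cfg, path)
  back <- read_study_config(path)
  expect_equal(back$parent_diameters, cfg$parent_diameters)
  expect_equal(back$mcr_targets, cfg$mcr_targets)
  expect_equal(back$wire_diameter, 0.033)
  expect_equal(back$h, 0.25)
  expect_equal(back$waveform$harmonics, cfg$waveform$harmonics)
  expect_equal(back$solver$cfl, cfg$solver$cfl)
})
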