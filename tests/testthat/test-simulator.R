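params <- default_parameters()

test_that("fertiliser events land in the right pools of the top layer", {
  prof <- tiny_profile(n_lay = 2)
  led <- new_ledger(prof)
  prof2 <- apply_management(prof, list(kind = "mineral_fertiliser",
                                       total_n = 12, ammoniacal_n = 6), led)
  expect_equal(prof2$nh4, c(6, 0))
  expect_equal(prof2$no3, c(6, 0))
  expect_equal(led$fertiliser, 12)

  prof3 <- apply_management(prof, list(kind = "slurry",
                                       total_n = 22, ammoniacal_n = 10))
  expect_equal(prof3$nh4[1], 10)
  expect_equal(prof3$org_n[1], 12)
  expect_equal(prof3$no3[1], 0)

  # zero-amount and cut events change no pool
  expect_identical(apply_management(prof, list(kind = "mineral_fertiliser",
                                               total_n = 0, ammoniacal_n = 0)),
                   prof)
  expect_identical(apply_management(prof, list(kind = "cut", total_n = 0,
                                               ammoniacal_n = 0)), prof)
  expect_error(apply_management(prof, list(kind = "mineral_fertiliser",
                                           total_n = 5, ammoniacal_n = 6)),
               "ammoniacal")
})

test_that("legacy first-order rates follow the modified first-order form", {
  tp <- params$transport
  tp$legacy_k_nitr <- 0.1
  expect_equal(legacy_first_order_rates(1, 0, 1, 1, 1, tp)$nitr, 0.1)
  expect_equal(legacy_first_order_rates(0, 1, 1, 1, 1, tp)$nitr, 0)
  expect_equal(legacy_first_order_rates(1, 1, 0, 0, 0, tp)$denit, 0)
  expect_equal(legacy_first_order_rates(2, 4, 0.5, 0.6, 0.8, tp)$denit,
               tp$legacy_k_denit * 4 * 0.5 * 0.6 * 0.8)
})

test_that("an empty profile stays empty: zero fluxes, decaying biomass", {
  prof <- tiny_profile(m_b = 0.1, b_d = 0.1)
  run <- run_simulation(prof, const_forcing(prof, 10), params = params)
  expect_equal(run$summary$cum_no, 0)
  expect_equal(run$summary$cum_n2o, 0)
  expect_equal(run$summary$cum_n2, 0)
  expect_lt(run$profile$m_b, 0.1)   # maintenance-only decline
  expect_lt(run$profile$b_d, 0.1)   # death-only decline
})

test_that("runs are deterministic and restartable from a saved state", {
  prof <- tiny_profile(nh4 = 2, no3 = 3, doc = 1, m_b = 0.05, b_d = 0.05)
  f2 <- const_forcing(prof, 2, theta = theta_for_wfps(0.8))
  r_full <- run_simulation(prof, f2, params = params)
  r_full2 <- run_simulation(prof, f2, params = params)
  expect_identical(r_full$fluxes, r_full2$fluxes)

  # run day 1, then restart day 2 from the saved state
  f1 <- const_forcing(prof, 1, theta = theta_for_wfps(0.8))
  r1 <- run_simulation(prof, f1, params = params)
  f_day2 <- forcing_series(f2$dates[2], f2$t_soil[2, , drop = FALSE],
                           f2$theta[2, , drop = FALSE])
  r2 <- run_simulation(r1$profile, f_day2, params = params)
  expect_equal(r2$fluxes$n2o_flux, r_full$fluxes$n2o_flux[2], tolerance = 1e-12)
  expect_equal(r2$profile$no3, r_full$profile$no3, tolerance = 1e-12)
})

test_that("gap-filled or mismatched inputs are rejected up front", {
  prof <- tiny_profile()
  dates <- as.Date("2000-01-01") + c(0, 1, 3)
  expect_error(forcing_series(dates, matrix(10, 3, 1), matrix(0.2, 3, 1)),
               "gap")
  f <- const_forcing(prof, 5)
  ev <- management_events(data.frame(date = "2001-01-01",
                                     kind = "mineral_fertiliser",
                                     total_n = 1, ammoniacal_n = 0.5))
  expect_error(run_simulation(prof, f, ev, params), "outside")
  expect_error(forcing_series(f$dates, f$t_soil, f$theta + 2), "0, 1")
})

test_that("microbial and legacy modes produce gap-free series of equal shape", {
  prof <- tiny_profile(nh4 = 3, no3 = 3, doc = 1, m_b = 0.05, b_d = 0.05)
  f <- const_forcing(prof, 20, theta = theta_for_wfps(0.7))
  rm_ <- run_simulation(prof, f, params = params, mode = "microbial")
  rl <- run_simulation(prof, f, params = params, mode = "legacy")
  expect_identical(dim(rm_$fluxes), dim(rl$fluxes))
  expect_identical(rm_$fluxes$date, rl$fluxes$date)
  # legacy mode cannot speciate the gas mix
  expect_true(all(is.na(rl$fluxes$n2o_flux)))
  expect_gt(sum(rl$fluxes$denitrified_legacy), 0)
  # both close their ledgers
  expect_lt(abs(ledger_residual(rm_$ledger, rm_$profile)), 1e-9)
  expect_lt(abs(ledger_residual(rl$ledger, rl$profile)), 1e-9)
})

test_that("a fertilised run closes the whole-run N budget", {
  prof <- tiny_profile(n_lay = 3, nh4 = 1, no3 = 1, doc = 2,
                       m_b = 0.05, b_d = 0.05)
  f <- const_forcing(prof, 60, theta = theta_for_wfps(0.75), uptake = 0.02)
  ev <- management_events(data.frame(
    date = c("2000-03-10", "2000-04-10"),
    kind = c("mineral_fertiliser", "slurry"),
    total_n = c(10, 22), ammoniacal_n = c(5, 10)))
  run <- run_simulation(prof, f, ev, params)
  led <- run$ledger
  residual <- ledger_residual(led, run$profile)
  expect_lt(abs(residual), 1e-6 * max(1, led$fertiliser))
  expect_equal(led$fertiliser, 32)
  expect_gt(led$uptake, 0)
  expect_gt(run$summary$cum_n2o, 0)
})

test_that("forcing and management files round-trip through delimited text", {
  prof <- tiny_profile(n_lay = 2)
  f <- const_forcing(prof, 4, uptake = 0.01, doc_input = 0.1)
  dir <- withr::local_tempdir()
  fp <- file.path(dir, "forcing.csv")
  write_forcing(f, fp)
  f2 <- read_forcing(fp)
  expect_equal(f2$dates, f$dates)
  expect_equal(unname(f2$t_soil), unname(f$t_soil))
  expect_equal(unname(f2$theta), unname(f$theta))
  expect_equal(f2$uptake, f$uptake)

  ev <- bush_fixture()$management$an
  mp <- file.path(dir, "events.csv")
  write_management(ev, mp)
  ev2 <- read_management(mp)
  expect_equal(ev2$date, ev$date)
  expect_equal(ev2$total_n, ev$total_n)
})

test_that("run_model drives a full configured run and writes outputs", {
  dir <- withr::local_tempdir()
  fx <- bush_fixture()
  spec <- fx$forcing_spec
  spec$seed <- 7L
  f <- generate_forcing(spec, fx$thicknesses)
  write_forcing(f, file.path(dir, "forcing.csv"))
  write_management(fx$management$an, file.path(dir, "events.csv"))
  writeLines(c("forcing_file: forcing.csv",
               "management_file: events.csv",
               "run_start: 1998-01-01", "run_end: 1998-12-31",
               paste0("out_dir: ", file.path(dir, "out"))),
             file.path(dir, "cfg.txt"))
  run <- run_model(file.path(dir, "cfg.txt"))
  expect_s3_class(run, "ngas_run")
  expect_equal(nrow(run$fluxes), 365)
  out <- utils::read.csv(file.path(dir, "out", "daily_fluxes.csv"))
  expect_equal(nrow(out), 365)
  expect_true(all(c("n2o_flux", "n2o_flux_ha") %in% names(out)))
  expect_equal(out$n2o_flux_ha, out$n2o_flux * 1e4)
})
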