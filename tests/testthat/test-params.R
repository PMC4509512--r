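test_that("calibrated defaults expose every published constant by name", {
  p <- default_parameters()
  golden <- list(
    "nitrifier.gamma_gn" = 4.87,
    "nitrifier.d_dn" = 1.44,
    "nitrifier.epsilon_n" = 0.67,
    "nitrifier.n_nmax" = 0.004,
    "denitrifier.guilds.no3.gamma_gd" = 13.65,
    "denitrifier.guilds.no2.gamma_gd" = 7.83,
    "denitrifier.guilds.no.gamma_gd" = 8.28,
    "denitrifier.guilds.n2o.gamma_gd" = 8.81,
    "denitrifier.guilds.no3.y_n" = 0.65,
    "denitrifier.guilds.no2.y_n" = 0.17,
    "denitrifier.guilds.no.y_n" = 0.75,
    "denitrifier.guilds.n2o.y_n" = 0.24,
    "denitrifier.guilds.no3.m_n" = 2.16,
    "denitrifier.guilds.no2.m_n" = 8.38,
    "denitrifier.guilds.n2o.m_n" = 1.90,
    "denitrifier.guilds.no.m_n" = 1.90,
    "nitrifier.km_doc" = 9.45,
    "nitrifier.km_no3" = 16.65,
    "nitrifier.km_nh4" = 18.53,
    "denitrifier.m_c" = 0.0031,
    "denitrifier.y_c" = 0.503
  )
  for (nm in names(golden))
    expect_identical(param_get(p, nm), golden[[nm]], label = nm)
})

test_that("parameter sets round-trip through file save/load bit-identically", {
  p <- default_parameters()
  tf <- withr::local_tempfile(fileext = ".txt")
  write_params_file(p, tf)
  expect_identical(load_params_file(tf), p)

  # non-default values (including awkward decimals) survive too
  p2 <- param_set(p, "nitrifier.q10", 2.0000001)
  p2 <- param_set(p2, "denitrifier.guilds.no2.km_n", 1 / 3)
  write_params_file(p2, tf)
  expect_identical(load_params_file(tf), p2)
})

test_that("invariant violations are rejected with the field named", {
  p <- default_parameters()
  p$nitrifier$epsilon_n <- 0
  expect_error(validate_params(p), "epsilon_n")
  p <- default_parameters()
  p$nitrifier$phi_no <- 0.6
  p$nitrifier$phi_n2o <- 0.5
  expect_error(validate_params(p), "phi")
  p <- default_parameters()
  p$denitrifier$guilds$no3$y_n <- -1
  expect_error(validate_params(p), "y_n")
  p <- default_parameters()
  p$transport$fr_lower <- 0.95
  expect_error(validate_params(p), "fr_lower")
  p <- default_parameters()
  p$denitrifier$guilds <- p$denitrifier$guilds[c("no2", "no3", "no", "n2o")]
  expect_error(validate_params(p), "guilds")
})

test_that("param_get/param_set address nested fields and reject unknown names", {
  p <- default_parameters()
  expect_equal(param_get(p, "denitrifier.guilds.no2.m_n"), 8.38)
  p2 <- param_set(p, "nitrifier.q10", 3.1)
  expect_equal(p2$nitrifier$q10, 3.1)
  expect_error(param_get(p, "nitrifier.gamma_typo"), "unknown parameter")
  expect_error(param_set(p, "nitrifier.epsilon_n", 0), "epsilon_n")
})

test_that("a minimal config fills every default and honours overrides", {
  dir <- withr::local_tempdir()
  prof <- tiny_profile()
  f <- const_forcing(prof, 3)
  write_forcing(f, file.path(dir, "forcing.csv"))
  writeLines("forcing_file: forcing.csv", file.path(dir, "cfg.txt"))
  cfg <- load_config(file.path(dir, "cfg.txt"))
  expect_s3_class(cfg, "ngas_config")
  expect_identical(cfg$params, default_parameters())
  expect_equal(cfg$mode, "microbial")

  writeLines(c("forcing_file: forcing.csv", "nitrifier.q10: 2.5"),
             file.path(dir, "cfg2.txt"))
  expect_equal(load_config(file.path(dir, "cfg2.txt"))$params$nitrifier$q10, 2.5)

  writeLines(c("forcing_file: forcing.csv", "nitrifer.q10: 2.5"),
             file.path(dir, "cfg3.txt"))
  expect_error(load_config(file.path(dir, "cfg3.txt")), "unknown key")

  expect_error(load_config(file.path(dir, "absent.txt")), "not found")
})
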