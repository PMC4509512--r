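test_that("Q10 temperature response matches its closed form", {
  expect_equal(temperature_response(20, 2.0, 20), 1.0)
  expect_equal(temperature_response(30, 2.0, 20), 2.0)
  expect_equal(temperature_response(10, 3.0, 20), 1 / 3)
  expect_error(temperature_response(10, 0, 20), "q10")
  # monotone increasing and strictly positive over a sweep
  t <- seq(-10, 40, by = 0.5)
  v <- temperature_response(t, 2.4, 20)
  expect_true(all(v > 0))
  expect_true(all(diff(v) > 0))
})

test_that("WFPS is water content over porosity, clipped at saturation", {
  porosity <- 1 - 1.53 / 2.65
  expect_equal(wfps(0, 1.53, 2.65), 0)
  expect_equal(wfps(porosity, 1.53, 2.65), 1.0)
  expect_equal(wfps(porosity / 2, 1.53, 2.65), 0.5)
  expect_error(wfps(0.2, 2.7, 2.65), "rho_d")
  expect_error(wfps(-0.1, 1.53, 2.65), "theta")
  # measured theta above the porosity estimate is clipped, not rejected
  ngas_log_clear()
  expect_equal(wfps(porosity + 0.05, 1.53, 2.65), 1.0)
  expect_match(ngas_log_entries(), "clipped", all = FALSE)
})

test_that("nitrification moisture response reproduces the quadratic and its branches", {
  expect_equal(moisture_response_nitrification(0.2), 0.6)
  expect_equal(moisture_response_nitrification(0.3),
               -11.25 * 0.3^2 + 11.75 * 0.3 - 1.9)  # 0.6125
  expect_equal(moisture_response_nitrification(0.5), 1.0)  # quadratic 1.1625, capped
  # documented discontinuities at the window edges
  expect_equal(moisture_response_nitrification(0.75),
               -11.25 * 0.75^2 + 11.75 * 0.75 - 1.9)  # 0.584375
  expect_equal(moisture_response_nitrification(0.750001), 0.6)
  expect_equal(moisture_response_nitrification(0.299999), 0.6)
  expect_error(moisture_response_nitrification(1.2), "0, 1")
  w <- seq(0, 1, by = 0.01)
  expect_true(all(moisture_response_nitrification(w) >= 0 &
                    moisture_response_nitrification(w) <= 1))
})

test_that("substrate response is Michaelis-Menten with the printed half-saturations", {
  expect_equal(substrate_response(0, 9.45), 0)
  for (km in c(9.45, 16.65, 18.53))
    expect_equal(substrate_response(km, km), 0.5)
  expect_error(substrate_response(-1, 9.45), ">= 0")
  expect_error(substrate_response(1, 0), "km")
  # equivalence with an independent algebraic form at random points
  set.seed(42)
  s <- stats::runif(100, 0, 500)
  km <- stats::runif(100, 0.1, 50)
  expect_equal(substrate_response(s, km), 1 / (1 + km / s), tolerance = 1e-12)
  # monotone, saturating below 1
  v <- substrate_response(seq(0, 1000, by = 1), 16.65)
  expect_true(all(diff(v) > 0) && all(v < 1))
})

test_that("pH curves honour the documented qualitative constraints", {
  expect_lte(ph_response(4.0, "nitrifier"), 0.05)
  expect_gte(ph_response(7.0, "nitrifier"), 0.95)
  expect_error(ph_response(5, "no_such_curve"), "unknown pH curve")
  # deterministic on repeat calls
  expect_identical(ph_response(5.0, "denit_no3"), ph_response(5.0, "denit_no3"))
  # every shipped curve maps [3, 9] into [0, 1] and is continuous (small steps)
  grid <- seq(3, 9, by = 0.01)
  for (id in names(default_ph_curves())) {
    v <- ph_response(grid, id)
    expect_true(all(v >= 0 & v <= 1), label = id)
    expect_lt(max(abs(diff(v))), 0.05, label = id)
  }
  # out-of-range pH clamps to the endpoint value
  expect_equal(ph_response(2, "denit_n2o"), ph_response(3, "denit_n2o"))
  expect_equal(ph_response(11, "denit_n2o"), ph_response(9, "denit_n2o"))
})

test_that("pH knot tables load from delimited text", {
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("ph,f", "3,0", "5,0.5", "9,1"), tf)
  cv <- load_ph_knots(tf, "custom")
  expect_equal(ph_response(4, cv), 0.25)
  expect_equal(ph_response(7, cv), 0.75)
})

test_that("anaerobic fraction ramps linearly between the WFPS thresholds", {
  tp <- default_parameters()$transport
  expect_equal(anaerobic_fraction(0.5, tp), 0)
  expect_equal(anaerobic_fraction(0.9, tp), 1)
  expect_equal(anaerobic_fraction(0.75, tp), 0.5)
  w <- sort(stats::runif(50))
  f <- anaerobic_fraction(w, tp)
  expect_true(all(f >= 0 & f <= 1))
  expect_true(all(diff(f) >= 0))
})
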